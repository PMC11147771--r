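# Cohort statistics: contingency tests, percentage formatting with the
# reporting convention used in the clinical tables, MRD response tables,
# rank-based differential expression with BH FDR, classic preranked gene-set
# enrichment, and Kaplan-Meier survival with log-rank comparison.

#' Contingency-table test (Pearson chi-squared / Fisher)
#'
#' Pearson chi-squared without continuity correction, or Fisher's exact
#' test (2x2). `method = "auto"` picks Fisher for a 2x2 table with any
#' expected count below 5.
#'
#' @param tab Matrix of non-negative integer counts, at least 2x2.
#' @param method `"chi2"`, `"fisher"` or `"auto"`.
#' @return List: `statistic` (chi-squared statistic; `NA` for Fisher),
#'   `p`, `method`.
#' @export
crosstab_test <- function(tab, method = c("chi2", "fisher", "auto")) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need at least a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("table has a zero-margin row or column")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (method == "auto") {
    method <- if (all(dim(tab) == 2) && any(expected < 5)) "fisher"
              else "chi2"
  }
  if (method == "fisher") {
    if (!all(dim(tab) == 2)) stop("fisher test restricted to 2x2 tables")
    ft <- stats::fisher.test(tab)
    list(statistic = NA_real_, p = ft$p.value, method = "fisher")
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), p = ct$p.value, method = "chi2")
  }
}

#' Format a percentage with the clinical-table rounding convention
#'
#' Computes `100 * count / n` and rounds half away from zero to the given
#' number of decimals, returning the printed string (e.g. 37/39 at 0
#' decimals gives "95"; 21/230 at 1 decimal gives "9.1").
#'
#' @param count Numerator (0 <= count <= n).
#' @param n Denominator.
#' @param decimals Decimal places (default 0).
#' @return Character; `NA` when `n` is 0.
#' @export
format_rate <- function(count, n, decimals = 0) {
  if (n == 0) return(NA_character_)
  stopifnot(count >= 0, count <= n)
  x <- 100 * count / n
  f <- 10 ^ decimals
  rounded <- sign(x) * floor(abs(x) * f + 0.5) / f
  formatC(rounded, format = "f", digits = decimals)
}

#' MRD response table by molecular subgroup
#'
#' Cross-tabulates molecular MRD response categories (MolCR / MolIMR /
#' MolFail) against subgroup assignments, one row per subgroup plus a total
#' row, with rates formatted by [format_rate()]. Samples with
#' an MRD category but no assignment are counted under `"unassigned"`.
#'
#' @param assignments Data frame (`sample`, `subgroup`).
#' @param mrd Data frame (`sample`, `mrd_category`); rows with `NA`
#'   category are dropped.
#' @param stratum Optional data frame (`sample`, `immunophenotype`) plus
#'   `stage` to restrict the table to one immunophenotype stratum.
#' @param stage Immunophenotype stage to keep when `stratum` is given.
#' @return Data frame: subgroup, n, molcr, molimr, molfail counts and
#'   formatted `*_rate` columns (rates `NA` for empty subgroups).
#' @export
mrd_response_table <- function(assignments, mrd, stratum = NULL,
                               stage = NULL) {
  mrd <- mrd[!is.na(mrd$mrd_category), , drop = FALSE]
  if (!is.null(stratum) && !is.null(stage)) {
    keep <- stratum$sample[stratum$immunophenotype == stage]
    mrd <- mrd[mrd$sample %in% keep, , drop = FALSE]
  }
  sg <- stats::setNames(assignments$subgroup, assignments$sample)
  mrd$subgroup <- ifelse(mrd$sample %in% names(sg),
                         unname(sg[mrd$sample]), "unassigned")
  groups <- c(intersect(c(tall_subgroups(), "unclassified", "unassigned"),
                        unique(mrd$subgroup)))
  rows <- lapply(c(groups, "total"), function(g) {
    sub <- if (g == "total") mrd else mrd[mrd$subgroup == g, , drop = FALSE]
    n <- nrow(sub)
    counts <- vapply(c("MolCR", "MolIMR", "MolFail"), function(cat)
      sum(sub$mrd_category == cat), integer(1))
    data.frame(subgroup = g, n = n,
               molcr = counts[1], molimr = counts[2], molfail = counts[3],
               molcr_rate = format_rate(counts[1], n),
               molimr_rate = format_rate(counts[2], n),
               molfail_rate = format_rate(counts[3], n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-gene Mann-Whitney differential expression
#'
#' Two-sided Mann-Whitney U test per gene between two sample groups: exact
#' p-values for combined n <= 12 without ties, normal approximation with
#' tie correction otherwise.
#'
#' @param expr Expression matrix (genes x samples), any monotone scale.
#' @param group_a,group_b Disjoint character vectors of sample ids.
#' @return Data frame: gene, U statistic, p.
#' @export
mann_whitney_de <- function(expr, group_a, group_b) {
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups overlap")
  }
  stopifnot(length(group_a) >= 2, length(group_b) >= 2,
            all(c(group_a, group_b) %in% colnames(expr)))
  exact <- (length(group_a) + length(group_b)) <= 12
  res <- t(apply(expr, 1, function(x) {
    a <- x[group_a]; b <- x[group_b]
    if (length(unique(c(a, b))) == 1) {   # fully tied: no evidence
      return(c(U = length(a) * length(b) / 2, p = 1))
    }
    ties <- anyDuplicated(c(a, b)) > 0
    wt <- suppressWarnings(stats::wilcox.test(
      a, b, exact = exact && !ties, correct = TRUE))
    c(U = unname(wt$statistic), p = wt$p.value)
  }))
  data.frame(gene = rownames(expr), U = res[, "U"], p = res[, "p"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up q-values with monotonicity enforcement, preserving the
#' input order; `NA` p-values propagate as `NA`.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classic preranked gene-set enrichment
#'
#' Unweighted Kolmogorov-Smirnov running-sum enrichment: walking down the
#' ranking, set members increment the sum by 1/|S| and non-members decrement
#' it by 1/(N-|S|); the enrichment score is the extremum of the running sum.
#' Significance by gene-label permutation with the add-one estimator
#' (two-sided on |ES|); BH q-values across sets.
#'
#' @param ranked Named numeric vector of per-gene statistics, sorted in the
#'   desired ranking order (it is re-sorted decreasing if not).
#' @param gene_sets Named list of character vectors.
#' @param n_permutations Number of permutations (default 1000).
#' @param seed Random seed.
#' @return Data frame: set, size (in-universe), es, p, q.
#' @export
preranked_enrichment <- function(ranked, gene_sets, n_permutations = 1000,
                                 seed = 1) {
  if (is.unsorted(rev(ranked))) ranked <- sort(ranked, decreasing = TRUE)
  universe <- names(ranked)
  N <- length(universe)
  es_stat <- function(hit) {
    n_hit <- sum(hit)
    run <- cumsum(ifelse(hit, 1 / n_hit, -1 / (N - n_hit)))
    run[which.max(abs(run))]
  }
  set.seed(seed)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(gene_sets[[nm]], universe)
    if (length(members) < 2) {
      stop("gene set '", nm, "' has fewer than 2 genes in the universe")
    }
    hit <- universe %in% members
    es <- es_stat(hit)
    perm <- vapply(seq_len(n_permutations), function(b)
      es_stat(sample(hit)), numeric(1))
    p <- (1 + sum(abs(perm) >= abs(es))) / (n_permutations + 1)
    data.frame(set = nm, size = length(members), es = es, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with a survival-at-time accessor
#' (right-continuous step function, S(0) = 1).
#'
#' @param time Follow-up times in months (>= 0).
#' @param event Event indicator (1 = death, 0 = censored).
#' @return List of class `tall_km`: the `survival::survfit` object `fit`
#'   and `surv_at(t)`, a vectorized accessor for S(t).
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop("empty survival data")
  if (any(time < 0)) stop("negative survival times")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  times <- fit$time; surv <- fit$surv
  surv_at <- function(t) {
    vapply(t, function(tt) {
      i <- which(times <= tt)
      if (length(i) == 0) 1 else surv[max(i)]
    }, numeric(1))
  }
  structure(list(fit = fit, surv_at = surv_at), class = "tall_km")
}

#' k-sample log-rank test
#'
#' @param time Follow-up times in months.
#' @param event Event indicator (1 = death).
#' @param strata Stratum label per subject (>= 2 distinct values).
#' @return List: `statistic` (chi-squared), `df`, `p`.
#' @export
logrank <- function(time, event, strata) {
  strata <- as.factor(droplevels(factor(strata)))
  if (nlevels(strata) < 2) stop("need at least two strata")
  sd <- survival::survdiff(survival::Surv(time, event) ~ strata)
  df <- nlevels(strata) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}
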