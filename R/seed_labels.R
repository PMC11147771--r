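# Rule-based reference labeling from oncogene overexpression and curated
# driver fusions. These labels seed the machine-learning classifier, so the
# scoring is deliberately conservative: a panel is satisfied only when every
# defining oncogene is clearly overexpressed (robust z above threshold) and
# no exclusion gene is.

#' Robust overexpression scores per oncogene panel
#'
#' For each gene the score is a robust z across the cohort,
#' \eqn{z = (x - median) / (1.4826 \cdot MAD + \epsilon)}, computed on
#' log2(fpkm+1) values. A panel's score for a sample is the minimum z over
#' its defining genes (every defining gene must be high); the maximum z over
#' its exclusion genes is reported alongside. Panels with a defining gene
#' absent from the matrix are marked unevaluable.
#'
#' @param expr Expression matrix on the log2(fpkm+1) scale, genes in rows,
#'   samples in columns.
#' @param panels Oncogene panels ([tall_oncogene_panels()]).
#' @param eps Guard added to the scaled MAD so constant genes score 0.
#' @return List with `z` (gene x sample robust z for panel genes),
#'   `panel_scores` and `exclusion_scores` (sample x panel matrices;
#'   exclusion score is `-Inf` for panels without exclusion genes) and
#'   `unevaluable` (character vector of panel names).
#' @export
overexpression_scores <- function(expr, panels = tall_oncogene_panels(),
                                  eps = 1e-8) {
  all_genes <- unique(unlist(lapply(panels, function(p)
    c(p$defining, p$excluded))))
  present <- intersect(all_genes, rownames(expr))
  z <- matrix(NA_real_, nrow = length(present), ncol = ncol(expr),
              dimnames = list(present, colnames(expr)))
  for (g in present) {
    x <- expr[g, ]
    med <- stats::median(x)
    scale <- stats::mad(x) + eps   # mad() already includes the 1.4826 factor
    z[g, ] <- (x - med) / scale
  }
  unevaluable <- names(panels)[vapply(panels, function(p)
    !all(p$defining %in% present), logical(1))]
  ps <- matrix(NA_real_, nrow = ncol(expr), ncol = length(panels),
               dimnames = list(colnames(expr), names(panels)))
  es <- matrix(-Inf, nrow = ncol(expr), ncol = length(panels),
               dimnames = list(colnames(expr), names(panels)))
  for (nm in names(panels)) {
    if (nm %in% unevaluable) next
    def <- panels[[nm]]$defining
    ps[, nm] <- if (length(def) == 1) z[def, ] else
      apply(z[def, , drop = FALSE], 2, min)
    exc <- intersect(panels[[nm]]$excluded, present)
    if (length(exc) > 0) {
      es[, nm] <- if (length(exc) == 1) z[exc, ] else
        apply(z[exc, , drop = FALSE], 2, max)
    }
  }
  list(z = z, panel_scores = ps, exclusion_scores = es,
       unevaluable = unevaluable)
}

#' Assign rule-based seed labels
#'
#' Per sample: (1) a curated driver fusion, if present, determines the label
#' (source `fusion_rule`); (2) otherwise the satisfied oncogene panel (panel
#' score at or above `z_threshold` and all exclusion genes below it) with
#' the highest score wins (source `expression_rule`), ties broken by panel
#' specificity order HOXA13 > TLX1 > TLX3 > NKX2 > LMO1 > TAL1/LMO > HOXA >
#' LYL1/LMO2 > TAL2; (3) otherwise no label.
#'
#' @param scores Result of [overexpression_scores()].
#' @param fusions Fusion-call data frame (`sample`, `fusion`); may be `NULL`.
#' @param z_threshold Robust-z threshold for "clear" overexpression
#'   (default 3).
#' @param driver_map Curated fusion-to-subgroup map
#'   ([tall_driver_fusions()]).
#' @return Data frame: sample, label (`NA` when no rule fires), source
#'   (`fusion_rule`/`expression_rule`/`NA`), top panel score.
#' @export
assign_seed_labels <- function(scores, fusions = NULL, z_threshold = 3,
                               driver_map = tall_driver_fusions()) {
  samples <- rownames(scores$panel_scores)
  precedence <- tall_subgroups()
  fmap <- list()
  if (!is.null(fusions) && nrow(fusions) > 0) {
    drv <- fusions[fusions$fusion %in% names(driver_map), , drop = FALSE]
    fmap <- split(unname(driver_map[drv$fusion]), drv$sample)
  }
  label <- rep(NA_character_, length(samples))
  source <- rep(NA_character_, length(samples))
  top <- rep(NA_real_, length(samples))
  for (i in seq_along(samples)) {
    s <- samples[i]
    fl <- unique(fmap[[s]])
    if (length(fl) == 1) {
      label[i] <- fl; source[i] <- "fusion_rule"
      top[i] <- scores$panel_scores[i, fl]
      next
    }
    ps <- stats::setNames(scores$panel_scores[i, ],
                          colnames(scores$panel_scores))
    es <- stats::setNames(scores$exclusion_scores[i, ],
                          colnames(scores$exclusion_scores))
    ok <- !is.na(ps) & ps >= z_threshold & es < z_threshold
    if (any(ok)) {
      cand <- names(ps)[ok]
      cand <- cand[order(-ps[cand], match(cand, precedence))]
      label[i] <- cand[1]; source[i] <- "expression_rule"
      top[i] <- ps[cand[1]]
    }
  }
  data.frame(sample = samples, label = label, source = source,
             top_score = top, stringsAsFactors = FALSE)
}

#' Build the labeled reference (training) set
#'
#' Keeps only samples that received a seed label, reports per-class counts
#' and flags classes too small to stratify.
#'
#' @param seed_labels Data frame from [assign_seed_labels()].
#' @param min_class_size Classes below this size are flagged
#'   non-stratifiable (default 2).
#' @return List: `samples` (ids), `labels` (named character), `class_counts`
#'   (table), `non_stratifiable` (class names).
#' @export
build_reference_set <- function(seed_labels, min_class_size = 2) {
  keep <- !is.na(seed_labels$label)
  if (!any(keep)) stop("no labeled samples: cannot build a reference set")
  labs <- stats::setNames(seed_labels$label[keep], seed_labels$sample[keep])
  counts <- table(labs)
  list(samples = names(labs), labels = labs, class_counts = counts,
       non_stratifiable = names(counts)[counts < min_class_size])
}
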