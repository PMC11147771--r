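# Methylation arm: CpG filtering, top-variance selection, PCA + k-means
# clustering into the four methylation clusters, and a bump-hunting DMR
# caller with a permutation family-wise error null.

#' Filter CpG sites by variant overlap and sex chromosomes
#'
#' Removes dbSNP-related CpGs with minor allele frequency above 0.01 and all
#' sites on sex chromosomes.
#'
#' @param beta Beta-value matrix, CpGs in rows (named), samples in columns.
#' @param annotation Site annotation data frame (`cpg_id`, `chrom`, `pos`,
#'   `maf`, `sex_chrom`, `island_flag`) covering every row of `beta`.
#' @return List: `beta` and `annotation` (filtered, same order), and
#'   `removed` (named counts per rule; a site failing both rules is counted
#'   under the MAF rule).
#' @export
filter_cpgs <- function(beta, annotation) {
  missing <- setdiff(rownames(beta), annotation$cpg_id)
  if (length(missing) > 0) {
    stop("no annotation for site(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "")
  }
  ann <- annotation[match(rownames(beta), annotation$cpg_id), ]
  bad_maf <- ann$maf > 0.01
  bad_sex <- ann$sex_chrom & !bad_maf
  keep <- !(bad_maf | ann$sex_chrom)
  list(beta = beta[keep, , drop = FALSE],
       annotation = ann[keep, , drop = FALSE],
       removed = c(maf = sum(bad_maf), sex_chrom = sum(bad_sex)))
}

#' Select the most variable CpGs
#'
#' Ranks sites by variance across samples (ties broken by site id) and keeps
#' the top `k` (default 2000, the number used for methylation subgroup
#' discovery).
#'
#' @param beta Beta-value matrix, CpGs in rows.
#' @param k Number of sites to keep.
#' @return The reduced matrix.
#' @export
top_variable_cpgs <- function(beta, k = 2000) {
  stopifnot(k >= 1)
  if (k > nrow(beta)) {
    warning("k exceeds the number of sites; returning all ", nrow(beta))
    k <- nrow(beta)
  }
  v <- apply(beta, 1, stats::var)
  ord <- order(-v, rownames(beta))
  beta[sort(ord[seq_len(k)]), , drop = FALSE]
}

#' Cluster samples by methylation profile
#'
#' Standardizes each CpG, computes principal components over samples and
#' runs k-means (50 random starts, fixed seed) on the leading components.
#' Clusters are renamed M1..Mk in decreasing size order.
#'
#' @param beta Reduced beta matrix (e.g. from [top_variable_cpgs()]), CpGs
#'   in rows, samples in columns.
#' @param n_clusters Number of clusters (default 4).
#' @param n_pcs Number of principal components fed to k-means (default 10).
#' @param seed Random seed for k-means initialization.
#' @return Named character vector of cluster labels (M1..Mk) per sample,
#'   with the PCA scores as attribute `scores`.
#' @export
cluster_methylation <- function(beta, n_clusters = 4, n_pcs = 10, seed = 1) {
  if (n_clusters > ncol(beta)) {
    stop("more clusters requested than samples available")
  }
  sds <- apply(beta, 1, stats::sd)
  std <- (beta - rowMeans(beta)) / (sds + 1e-12)
  pca <- stats::prcomp(t(std), center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pca$x))
  scores <- pca$x[, seq_len(n_pcs), drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(scores, centers = n_clusters, nstart = 50,
                      iter.max = 100)
  sizes <- table(km$cluster)
  ord <- order(-as.vector(sizes), as.integer(names(sizes)))
  relabel <- stats::setNames(paste0("M", seq_len(n_clusters)),
                             names(sizes)[ord])
  labels <- stats::setNames(unname(relabel[as.character(km$cluster)]),
                            colnames(beta))
  attr(labels, "scores") <- scores
  labels
}

#' Group CpGs into genomic clusters by gap distance
#'
#' Consecutive CpGs on one chromosome separated by at most `max_gap` bases
#' share a cluster; clusters never span chromosomes. This defines the units
#' within which group differences are smoothed and candidate regions are
#' formed.
#'
#' @param annotation Site annotation (`chrom`, `pos`), sorted by position
#'   within each chromosome.
#' @param max_gap Maximum intra-cluster gap in bases (default 500).
#' @return Integer cluster index per site.
#' @export
define_cpg_clusters <- function(annotation, max_gap = 500) {
  n <- nrow(annotation)
  if (n == 0) return(integer())
  for (ch in unique(annotation$chrom)) {
    p <- annotation$pos[annotation$chrom == ch]
    if (is.unsorted(p)) {
      stop("positions on ", ch, " are not sorted ascending")
    }
    if (anyDuplicated(p)) warning("duplicate positions on ", ch)
  }
  new_chrom <- c(TRUE, annotation$chrom[-1] != annotation$chrom[-n])
  gap <- c(0L, diff(annotation$pos))
  cumsum(new_chrom | (!new_chrom & gap > max_gap))
}

# Running-mean smoothing of column vectors within CpG clusters: window
# min(window, cluster size), centered, truncated at cluster edges. Works on
# a matrix (sites x replicates) via a global cumulative sum; windows are
# contiguous index ranges that never leave their cluster.
smooth_by_cluster <- function(d, clusters, window = 5) {
  m <- nrow(d)
  idx <- seq_len(m)
  cl_start <- ave(idx, clusters, FUN = min)
  cl_end <- ave(idx, clusters, FUN = max)
  cl_size <- cl_end - cl_start + 1L
  w <- pmin(window, cl_size)
  h <- floor(w / 2)
  lo <- pmax(idx - h, cl_start)
  hi <- pmin(idx + h, cl_end)
  cs <- apply(d, 2, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = m)
  up <- cs[hi, , drop = FALSE]
  down <- rbind(0, cs)[lo, , drop = FALSE]
  (up - down) / (hi - lo + 1)
}

# Candidate regions of one smoothed difference vector: maximal same-sign
# runs with |smoothed| >= cutoff, confined to a CpG cluster. Returns indices
# and areas.
find_regions <- function(smoothed, cutoff, clusters) {
  state <- ifelse(abs(smoothed) >= cutoff & smoothed != 0, sign(smoothed), 0)
  key <- paste(clusters, state)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  in_region <- state[starts] != 0
  list(start = starts[in_region], end = ends[in_region],
       area = vapply(which(in_region), function(i)
         sum(abs(smoothed[starts[i]:ends[i]])), numeric(1)),
       sign = state[starts[in_region]])
}

# Max region area of one smoothed vector under its own quantile cutoff
# (0 when no site passes).
max_region_area <- function(smoothed, cutoff_quantile, clusters) {
  cutoff <- stats::quantile(abs(smoothed), cutoff_quantile, names = FALSE)
  reg <- find_regions(smoothed, cutoff, clusters)
  if (length(reg$area) == 0) 0 else max(reg$area)
}

#' Bump-hunting differentially methylated regions with permutation FWER
#'
#' Per CpG the difference statistic is mean beta of the focus group minus
#' the rest; differences are smoothed within genomic CpG clusters by a
#' running mean (window `min(window, cluster size)`); the candidate cutoff
#' is the `cutoff_quantile` of the genome-wide absolute smoothed values;
#' candidate regions are maximal same-sign runs above the cutoff, scored by
#' their area (sum of absolute smoothed differences). The null is built
#' from `B` global permutations of the sample group labels, each processed
#' exactly like the observed data (including its own quantile cutoff) and
#' summarized by its maximum region area; the family-wise p-value of a
#' region uses the add-one estimator
#' \eqn{(1 + \#\{perm max \ge area\}) / (B + 1)}, so it is never zero.
#'
#' @param beta Beta-value matrix, CpGs in rows, samples in columns
#'   (typically after [filter_cpgs()]).
#' @param groups Group label per sample; with more than two distinct labels
#'   supply `focus` for a one-vs-rest contrast.
#' @param annotation Site annotation aligned to `beta` rows (`chrom`,
#'   `pos`), sorted within chromosomes.
#' @param focus Focus group label (required when `groups` has > 2 levels).
#' @param cutoff_quantile Quantile defining the candidate cutoff
#'   (default 0.99).
#' @param max_gap Maximum intra-cluster gap in bases (default 500).
#' @param window Running-mean window (default 5).
#' @param B Number of label permutations (default 1000).
#' @param seed Random seed for the permutations.
#' @return Data frame of class `tall_dmr` in BED6+ layout: `chrom`, `start`,
#'   `end` (0-based half-open), `name`, `area`, `strand` ("."), `value`
#'   (mean smoothed difference), `n_cpgs`, `fwer_p`; sorted, disjoint
#'   regions with constant sign. Attributes: `cutoff`, `perm_max_areas`.
#' @export
bumphunt <- function(beta, groups, annotation, focus = NULL,
                     cutoff_quantile = 0.99, max_gap = 500, window = 5,
                     B = 1000, seed = 1) {
  stopifnot(ncol(beta) == length(groups), nrow(beta) == nrow(annotation),
            B >= 1)
  groups <- as.character(groups)
  if (is.null(focus)) {
    lev <- sort(unique(groups))
    if (length(lev) != 2) {
      stop("groups has ", length(lev), " levels; supply `focus` for a ",
           "one-vs-rest contrast")
    }
    focus <- lev[1]
  }
  in_focus <- groups == focus
  n1 <- sum(in_focus); n0 <- sum(!in_focus)
  if (n1 < 2 || n0 < 2) stop("each group needs at least 2 samples")

  ord <- order(annotation$chrom, annotation$pos)
  annotation <- annotation[ord, , drop = FALSE]
  beta <- beta[ord, , drop = FALSE]
  clusters <- define_cpg_clusters(annotation, max_gap)

  # contrast vectors: observed labels in column 1, B permutations after
  set.seed(seed)
  contrast <- matrix(0, nrow = ncol(beta), ncol = B + 1L)
  contrast[, 1] <- ifelse(in_focus, 1 / n1, -1 / n0)
  for (b in seq_len(B)) {
    perm <- in_focus[sample.int(length(in_focus))]
    contrast[, b + 1L] <- ifelse(perm, 1 / n1, -1 / n0)
  }
  d <- beta %*% contrast
  sm <- smooth_by_cluster(d, clusters, window)

  cutoff <- stats::quantile(abs(sm[, 1]), cutoff_quantile, names = FALSE)
  obs <- find_regions(sm[, 1], cutoff, clusters)
  perm_max <- vapply(seq_len(B), function(b)
    max_region_area(sm[, b + 1L], cutoff_quantile, clusters), numeric(1))

  k <- length(obs$area)
  out <- data.frame(
    chrom = if (k) annotation$chrom[obs$start] else character(),
    start = if (k) annotation$pos[obs$start] else integer(),
    end = if (k) annotation$pos[obs$end] + 1L else integer(),
    name = if (k) sprintf("dmr_%03d", seq_len(k)) else character(),
    area = if (k) obs$area else numeric(),
    strand = if (k) rep(".", k) else character(),
    value = if (k) vapply(seq_len(k), function(i)
      mean(sm[obs$start[i]:obs$end[i], 1]), numeric(1)) else numeric(),
    n_cpgs = if (k) obs$end - obs$start + 1L else integer(),
    fwer_p = if (k) vapply(obs$area, function(a)
      (1 + sum(perm_max >= a)) / (B + 1), numeric(1)) else numeric(),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "perm_max_areas") <- perm_max
  class(out) <- c("tall_dmr", "data.frame")
  out
}
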