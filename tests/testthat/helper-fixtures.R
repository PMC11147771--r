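# Shared fixtures, all generated in code.

# Small cohort for unit tests.
small_cohort <- function(seed = 1, n = 120, effect = NULL, n_genes = 200,
                         n_cpgs = 1500, noise_sd = 1) {
  generate_cohort(
    tall_cohort_config(n_samples = n, n_genes = n_genes, n_cpgs = n_cpgs,
                       noise_sd = noise_sd, seed = seed),
    tall_subgroup_specs(effect = effect))
}

# Methylation fixture: 100 null CpGs plus an optional implanted block of
# `block_size` consecutive CpGs (gaps <= 500 bp) elevated by `shift` in
# group A; 20 samples per group.
dmr_fixture <- function(seed, shift = 0.3, block_size = 10,
                        with_block = TRUE, n_per_group = 20,
                        n_null = 100) {
  set.seed(seed)
  n_cpg <- n_null + block_size
  gaps <- sample(c(50, 100, 800), n_cpg - 1, replace = TRUE,
                 prob = c(0.6, 0.2, 0.2))
  start <- 30
  gaps[start:(start + block_size - 2)] <- 50   # block stays in one cluster
  pos <- cumsum(c(1000, gaps))
  annot <- data.frame(cpg_id = sprintf("cg%03d", seq_len(n_cpg)),
                      chrom = "chr1", pos = pos, maf = 0,
                      sex_chrom = FALSE, island_flag = TRUE,
                      stringsAsFactors = FALSE)
  n <- 2 * n_per_group
  beta <- matrix(pmin(pmax(stats::rnorm(n_cpg * n, 0.5, 0.1), 0), 1),
                 n_cpg, n,
                 dimnames = list(annot$cpg_id, sprintf("S%02d", seq_len(n))))
  groups <- rep(c("A", "B"), each = n_per_group)
  block <- start:(start + block_size - 1)
  if (with_block) {
    beta[block, groups == "A"] <- pmin(
      beta[block, groups == "A"] + shift, 1)
  }
  list(beta = beta, annot = annot, groups = groups, block = block)
}

# Brute-force reimplementation of the bump-hunt area statistic: group mean
# difference, truncated centered running mean within gap-defined clusters,
# regions as same-sign runs above the quantile cutoff. Used as an
# independent oracle for bumphunt().
brute_force_regions <- function(beta, groups, annot, focus,
                                cutoff_quantile = 0.99, max_gap = 500,
                                window = 5) {
  ord <- order(annot$chrom, annot$pos)
  annot <- annot[ord, ]; beta <- beta[ord, , drop = FALSE]
  d <- rowMeans(beta[, groups == focus, drop = FALSE]) -
    rowMeans(beta[, groups != focus, drop = FALSE])
  # gap clusters
  cl <- integer(nrow(annot)); cl[1] <- 1L
  for (i in 2:nrow(annot)) {
    new <- annot$chrom[i] != annot$chrom[i - 1] ||
      annot$pos[i] - annot$pos[i - 1] > max_gap
    cl[i] <- cl[i - 1] + as.integer(new)
  }
  sm <- numeric(length(d))
  for (i in seq_along(d)) {
    members <- which(cl == cl[i])
    w <- min(window, length(members))
    h <- floor(w / 2)
    lo <- max(i - h, members[1]); hi <- min(i + h, members[length(members)])
    sm[i] <- mean(d[lo:hi])
  }
  cutoff <- as.numeric(stats::quantile(abs(sm), cutoff_quantile))
  regions <- list()
  i <- 1
  while (i <= length(sm)) {
    if (abs(sm[i]) >= cutoff && sm[i] != 0) {
      j <- i
      while (j + 1 <= length(sm) && cl[j + 1] == cl[i] &&
             sign(sm[j + 1]) == sign(sm[i]) &&
             abs(sm[j + 1]) >= cutoff) j <- j + 1
      regions[[length(regions) + 1]] <- data.frame(
        start_idx = i, end_idx = j, area = sum(abs(sm[i:j])),
        chrom = annot$chrom[i], start = annot$pos[i],
        end = annot$pos[j] + 1L)
      i <- j + 1
    } else i <- i + 1
  }
  list(smoothed = sm, cutoff = cutoff,
       regions = if (length(regions)) do.call(rbind, regions) else NULL)
}

# Marker profiles for the immunophenotype rules.
profile_thymic <- c(cyCD3 = 90, CD7 = 95, CD1a = 80, CD4 = 70, CD8 = 60,
                    sCD3 = 40)
profile_early <- c(cyCD3 = 90, CD7 = 95, CD5 = 5, CD2 = 60, sCD3 = 0,
                   CD4 = 0, CD8 = 0, CD1a = 0)
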