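# Synthetic multi-omics T-ALL cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: nine
# molecular subgroups at published cohort proportions, subgroup-specific
# oncogene block overexpression on a log-normal fpkm baseline, driver fusions
# at subgroup frequencies (at most one per sample, mirroring the mutual
# exclusivity of driver lesions), four methylation clusters with global
# CpG-island hypomethylation of the TAL1-fusion cluster, implanted DMR blocks
# with recorded coordinates, and a clinical table (immunophenotype markers,
# blast content, MRD triples, exponential survival) consistent with the
# package's rule systems.

#' Marker genes used by the subgroup-defining oncogene panels
#' @return Character vector of marker gene symbols.
#' @keywords internal
panel_marker_genes <- function(specs = tall_subgroup_specs()) {
  unique(c(unlist(lapply(tall_oncogene_panels(), function(p)
    c(p$defining, p$excluded))),
    unlist(lapply(specs, function(s) names(s$oncogene_panel)))))
}

#' Simulate a subgroup-structured expression matrix
#'
#' Per-gene baseline means are drawn from a normal distribution on the log2
#' fpkm scale; each sample's subgroup adds its panel effect (log2 units) to
#' the subgroup's oncogenes; independent normal noise is added and values are
#' exponentiated back to the fpkm scale. HOXA13 samples elevate HOXA13, EVX1
#' and HOTTIP while anterior HOXA genes stay at baseline.
#'
#' @param labels Character vector of true subgroup labels, one per sample.
#' @param specs Subgroup specifications ([tall_subgroup_specs()]).
#' @param config Cohort configuration ([tall_cohort_config()]).
#' @param sample_ids Optional sample identifiers (default S0001...).
#' @return Non-negative fpkm-scale matrix, genes in rows, samples in columns.
#' @export
simulate_expression <- function(labels, specs, config,
                                sample_ids = NULL) {
  unknown <- setdiff(unique(labels), names(specs))
  if (length(unknown) > 0) {
    stop("unknown subgroup label(s): ", paste(unknown, collapse = ", "))
  }
  n <- length(labels)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n))
  markers <- panel_marker_genes(specs)
  n_bg <- max(config$n_genes - length(markers), 0L)
  genes <- c(markers, sprintf("G%04d", seq_len(n_bg)))
  mu <- stats::rnorm(length(genes), config$baseline_mean, config$baseline_sd)
  names(mu) <- genes
  log2x <- matrix(stats::rnorm(length(genes) * n, mean = 0,
                               sd = config$noise_sd),
                  nrow = length(genes), ncol = n,
                  dimnames = list(genes, sample_ids))
  log2x <- log2x + mu
  for (j in seq_len(n)) {
    panel <- specs[[labels[j]]]$oncogene_panel
    if (length(panel) > 0) {
      log2x[names(panel), j] <- log2x[names(panel), j] + panel
    }
  }
  pmax(2 ^ log2x - 1, 0)
}

#' Simulate driver fusion calls
#'
#' Draws at most one driver fusion per sample from the subgroup's
#' driver-fusion frequencies; a small passenger-fusion rate exercises the
#' curated-driver filter downstream.
#'
#' @inheritParams simulate_expression
#' @param passenger_prob Probability of an additional non-driver passenger
#'   fusion call per sample.
#' @return Data frame with columns `sample`, `gene5`, `gene3`, `fusion`,
#'   `breakpoint` (possibly zero rows).
#' @export
simulate_fusions <- function(labels, specs, sample_ids = NULL,
                             passenger_prob = 0.05) {
  n <- length(labels)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n))
  rows <- list()
  for (j in seq_len(n)) {
    fus <- specs[[labels[j]]]$driver_fusions
    if (length(fus) > 0) {
      u <- stats::runif(1)
      cum <- cumsum(fus)
      hit <- which(u <= cum)
      if (length(hit) > 0) {
        nm <- names(fus)[hit[1]]
        parts <- strsplit(nm, "::", fixed = TRUE)[[1]]
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sample_ids[j], gene5 = parts[1], gene3 = parts[2],
          fusion = nm,
          breakpoint = sprintf("chr%d:%d", sample.int(22, 1),
                               sample.int(2e8, 1)),
          stringsAsFactors = FALSE)
      }
    }
    if (stats::runif(1) < passenger_prob) {
      g5 <- sprintf("PSG%03d", sample.int(500, 1))
      g3 <- sprintf("PSG%03d", sample.int(500, 1))
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample_ids[j], gene5 = g5, gene3 = g3,
        fusion = paste0(g5, "::", g3),
        breakpoint = sprintf("chr%d:%d", sample.int(22, 1),
                             sample.int(2e8, 1)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(sample = character(), gene5 = character(),
                      gene3 = character(), fusion = character(),
                      breakpoint = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Simulate a CpG array layout with implanted signature coordinates
#'
#' Builds a site annotation (id, chromosome, 0-based position, minor allele
#' frequency of any overlapping variant, sex-chromosome flag, CpG-island
#' flag) organized as island runs of closely spaced CpGs plus isolated
#' sites, and chooses per-cluster signature sites: one contiguous 10-CpG DMR
#' block per methylation cluster (recorded as ground truth) plus scattered
#' signature sites. Signature sites are restricted to clean autosomal
#' sites (MAF <= 0.01, non-sex) so they survive the standard filters.
#'
#' @param config Cohort configuration.
#' @param n_scatter Scattered signature sites per cluster.
#' @param block_size CpGs per implanted DMR block.
#' @return List with `annotation` (data frame), `signatures` (per-cluster
#'   list of site ids and signs) and `dmr_truth` (data frame of implanted
#'   block coordinates).
#' @export
simulate_cpg_sites <- function(config, n_scatter = 120, block_size = 10) {
  n <- config$n_cpgs
  chrom <- character(n); pos <- integer(n); island <- logical(n)
  i <- 1L
  cur_chrom <- 1L
  cur_pos <- 1000L
  while (i <= n) {
    if (stats::runif(1) < 0.35) {   # island run
      len <- min(sample(8:15, 1), n - i + 1L)
      p <- cur_pos + cumsum(c(0L, rep(50L, len - 1L)))
      idx <- i:(i + len - 1L)
      chrom[idx] <- paste0("chr", cur_chrom)
      pos[idx] <- p
      island[idx] <- TRUE
      cur_pos <- p[len] + sample(2000:20000, 1)
      i <- i + len
    } else {                        # isolated CpG
      chrom[i] <- paste0("chr", cur_chrom)
      pos[i] <- cur_pos
      island[i] <- FALSE
      cur_pos <- cur_pos + sample(2000:20000, 1)
      i <- i + 1L
    }
    if (cur_pos > 5e7) {            # move to next chromosome
      cur_chrom <- cur_chrom + 1L
      cur_pos <- 1000L
      if (cur_chrom > 22L) cur_chrom <- 1L  # wrap; chrX added below
    }
  }
  # relabel the final ~5% of sites as chrX (sex-chromosome filter fodder)
  n_x <- max(round(0.05 * n), 1L)
  x_idx <- (n - n_x + 1L):n
  chrom[x_idx] <- "chrX"
  maf <- ifelse(stats::runif(n) < 0.05, stats::runif(n, 0, 0.1), 0)
  annotation <- data.frame(
    cpg_id = sprintf("cg%06d", seq_len(n)),
    chrom = chrom, pos = pos, maf = maf,
    sex_chrom = chrom %in% c("chrX", "chrY"),
    island_flag = island, stringsAsFactors = FALSE)

  clean <- !annotation$sex_chrom & annotation$maf <= 0.01
  clusters <- paste0("M", 1:4)
  # candidate island runs: maximal runs of consecutive clean island rows on
  # one chromosome, long enough to host a block
  run_id <- cumsum(c(TRUE, diff(as.integer(factor(annotation$chrom))) != 0 |
                       diff(annotation$pos) > 500 |
                       diff(as.integer(annotation$island_flag)) != 0))
  run_ok <- annotation$island_flag & clean
  runs <- split(seq_len(n)[run_ok], run_id[run_ok])
  runs <- runs[vapply(runs, length, integer(1)) >= block_size]
  if (length(runs) < length(clusters)) {
    stop("not enough island runs to implant DMR blocks; increase n_cpgs")
  }
  picked <- sample(length(runs), length(clusters))
  signatures <- list(); dmr_rows <- list(); used <- integer()
  for (ci in seq_along(clusters)) {
    block <- runs[[picked[ci]]][seq_len(block_size)]
    used <- c(used, block)
    dmr_rows[[ci]] <- data.frame(
      cluster = clusters[ci],
      chrom = annotation$chrom[block[1]],
      start = annotation$pos[block[1]],
      end = annotation$pos[block[length(block)]] + 1L,
      n_cpgs = block_size,
      shift = config$methylation_shift,
      stringsAsFactors = FALSE)
    signatures[[clusters[ci]]] <- list(block = annotation$cpg_id[block])
  }
  scatter_pool <- setdiff(which(clean), used)
  for (ci in seq_along(clusters)) {
    sc <- sample(scatter_pool, min(n_scatter, length(scatter_pool)))
    scatter_pool <- setdiff(scatter_pool, sc)
    signatures[[clusters[ci]]]$scatter <- annotation$cpg_id[sc]
    signatures[[clusters[ci]]]$scatter_sign <-
      sample(c(-1, 1), length(sc), replace = TRUE)
  }
  list(annotation = annotation, signatures = signatures,
       dmr_truth = do.call(rbind, dmr_rows))
}

#' Simulate a beta-value methylation matrix
#'
#' Baseline betas are beta-distributed (low at CpG islands, high elsewhere).
#' Each cluster's samples gain that cluster's implanted block (positive
#' shift) and scattered signature shifts; cluster M2 additionally receives a
#' global negative offset over CpG-island sites, emulating the global
#' hypomethylation of the TAL1-fusion methylation cluster. Values are
#' clipped to [0, 1].
#'
#' @param cluster_labels Character vector in M1..M4, one per sample.
#' @param sites Result of [simulate_cpg_sites()].
#' @param config Cohort configuration.
#' @param sample_ids Optional sample identifiers.
#' @return Beta-value matrix, CpGs in rows, samples in columns.
#' @export
simulate_methylation <- function(cluster_labels, sites, config,
                                 sample_ids = NULL) {
  stopifnot(all(cluster_labels %in% paste0("M", 1:4)))
  n <- length(cluster_labels)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n))
  annot <- sites$annotation
  m <- nrow(annot)
  base <- ifelse(annot$island_flag,
                 stats::rbeta(m, 2, 8), stats::rbeta(m, 8, 2))
  beta <- matrix(stats::rnorm(m * n, 0, config$methylation_noise_sd),
                 nrow = m, ncol = n,
                 dimnames = list(annot$cpg_id, sample_ids))
  beta <- beta + base
  idx <- stats::setNames(seq_len(m), annot$cpg_id)
  for (cl in unique(cluster_labels)) {
    cols <- which(cluster_labels == cl)
    sig <- sites$signatures[[cl]]
    if (!is.null(sig)) {
      beta[idx[sig$block], cols] <-
        beta[idx[sig$block], cols] + config$methylation_shift
      beta[idx[sig$scatter], cols] <-
        beta[idx[sig$scatter], cols] +
        sig$scatter_sign * config$methylation_shift
    }
    if (cl == "M2") {
      beta[annot$island_flag, cols] <-
        beta[annot$island_flag, cols] + config$m2_global_shift
    }
  }
  pmin(pmax(beta, 0), 1)
}

#' Simulate the clinical table
#'
#' Draws an immunophenotype stage from the subgroup's stage weights and a
#' marker profile satisfying that stage's antigen pattern (with an ETP
#' profile, CD5 < 25 plus a myeloid/stem marker, at the given rate among
#' early-stage samples); an MRD category from the subgroup's response
#' probabilities, back-converted to a (value, sensitivity, quantifiable)
#' triple that re-categorizes exactly; and overall survival from an
#' exponential event-time model with rate -ln(os3y)/36 per month,
#' administratively censored at the configured horizon.
#'
#' @inheritParams simulate_expression
#' @param etp_prob Probability that an early-stage sample carries an ETP
#'   immunophenotype.
#' @return List with `clinical` (data frame) and `truth` (stage, ETP flag
#'   and MRD category actually drawn).
#' @export
simulate_clinical <- function(labels, specs, config, sample_ids = NULL,
                              etp_prob = 0.32) {
  n <- length(labels)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n))
  stages <- character(n); etp <- logical(n); mrd_cat <- character(n)
  markers <- c("cyCD3", "sCD3", "CD7", "CD5", "CD2", "CD4", "CD8", "CD1a",
               "CD13", "CD33", "CD34", "CD117", "HLADR")
  prof <- matrix(NA_real_, nrow = n, ncol = length(markers),
                 dimnames = list(sample_ids, markers))
  mrd_value <- numeric(n); mrd_sens <- rep(1e-4, n)
  mrd_quant <- logical(n)
  os_months <- numeric(n); os_event <- integer(n)
  pos <- function(k = 1) stats::runif(k, 40, 100)
  neg <- function(k = 1) stats::runif(k, 0, 15)
  any_ <- function(k = 1) stats::runif(k, 0, 100)
  for (j in seq_len(n)) {
    s <- specs[[labels[j]]]
    stage <- sample(names(s$immunophenotype_weights), 1,
                    prob = s$immunophenotype_weights)
    stages[j] <- stage
    p <- c(cyCD3 = stats::runif(1, 60, 100), CD7 = stats::runif(1, 60, 100))
    if (stage == "thymic") {
      p <- c(p, CD1a = pos(), CD4 = pos(), CD8 = pos(), sCD3 = any_(),
             CD5 = any_(), CD2 = any_())
    } else if (stage == "early") {
      if (stats::runif(1) < 0.5) {   # CD2- pattern
        p <- c(p, CD2 = neg(), sCD3 = neg(), CD1a = neg(), CD5 = any_(),
               CD4 = any_(), CD8 = any_())
      } else {                       # CD5- CD2+ pattern
        p <- c(p, CD5 = neg(), CD2 = pos(), sCD3 = neg(), CD4 = neg(),
               CD8 = neg(), CD1a = neg())
      }
    } else {                         # mature
      p <- c(p, CD5 = pos(), CD2 = pos(), CD1a = neg(), sCD3 = any_(),
             CD4 = any_(), CD8 = any_())
    }
    is_etp <- stage == "early" && stats::runif(1) < etp_prob
    etp[j] <- is_etp
    myeloid <- c("CD13", "CD33", "CD34", "CD117", "HLADR")
    my <- stats::setNames(neg(5), myeloid)
    if (is_etp) {
      p["CD5"] <- stats::runif(1, 0, 15)
      my[sample(myeloid, 1)] <- stats::runif(1, 30, 100)
    }
    prof[j, names(p)] <- p
    prof[j, myeloid] <- my
    # MRD category and back-converted triple
    cat_j <- sample(c("MolCR", "MolIMR", "MolFail"), 1,
                    prob = c(s$molcr_prob, s$molimr_prob, s$molfail_prob))
    mrd_cat[j] <- cat_j
    if (cat_j == "MolCR") {
      mrd_value[j] <- 0; mrd_quant[j] <- TRUE
    } else if (cat_j == "MolIMR") {
      if (stats::runif(1) < 0.5) {
        mrd_value[j] <- stats::runif(1, 1e-6, 1e-4)
        mrd_quant[j] <- TRUE
      } else {
        mrd_value[j] <- NA_real_; mrd_quant[j] <- FALSE
      }
    } else {
      mrd_value[j] <- 10 ^ stats::runif(1, -4 + 1e-6, -1)
      mrd_quant[j] <- TRUE
    }
    # exponential overall survival, administrative censoring
    rate <- if (s$os3y >= 1) 0 else -log(s$os3y) / 36
    t_raw <- if (rate > 0) stats::rexp(1, rate) else Inf
    os_event[j] <- as.integer(t_raw <= config$censor_horizon_months)
    os_months[j] <- min(t_raw, config$censor_horizon_months)
  }
  clinical <- data.frame(sample = sample_ids,
                         blast_pct = round(stats::runif(n, 30, 100), 1),
                         prof,
                         mrd_value = mrd_value,
                         mrd_sensitivity = mrd_sens,
                         mrd_quantifiable = mrd_quant,
                         mrd_timepoint = rep("after consolidation I", n),
                         os_months = os_months, os_event = os_event,
                         stringsAsFactors = FALSE, check.names = FALSE)
  truth <- data.frame(sample = sample_ids, immunophenotype = stages,
                      etp = etp, mrd_category = mrd_cat,
                      stringsAsFactors = FALSE)
  list(clinical = clinical, truth = truth)
}

#' Generate a complete synthetic multi-omics T-ALL cohort
#'
#' Draws hidden subgroup labels from the spec proportions, then simulates
#' expression, fusion calls, methylation (cluster membership follows the
#' subgroup-to-cluster map in the specs) and the clinical table. The cohort
#' is a deterministic function of (config, specs, seed).
#'
#' @param config Cohort configuration ([tall_cohort_config()]).
#' @param specs Subgroup specifications ([tall_subgroup_specs()]).
#' @return Object of class `tall_cohort`: a list with elements `expression`
#'   (fpkm matrix), `fusions`, `methylation` (list: `beta`, `annotation`),
#'   `clinical`, `truth` (hidden subgroup, methylation cluster, stage, ETP,
#'   MRD category), `dmr_truth`, `config`, `specs`.
#' @export
generate_cohort <- function(config = tall_cohort_config(),
                            specs = tall_subgroup_specs()) {
  validate_subgroup_specs(specs)
  set.seed(config$seed)
  n <- config$n_samples
  sample_ids <- if (n > 0) sprintf("S%04d", seq_len(n)) else character()
  props <- vapply(specs, function(s) s$proportion, numeric(1))
  labels <- if (n > 0) {
    sample(names(specs), n, replace = TRUE, prob = props)
  } else character()
  expr <- simulate_expression(labels, specs, config, sample_ids)
  fusions <- simulate_fusions(labels, specs, sample_ids)
  clusters <- vapply(labels, function(l) specs[[l]]$methylation_cluster,
                     character(1), USE.NAMES = FALSE)
  sites <- simulate_cpg_sites(config)
  beta <- simulate_methylation(clusters, sites, config, sample_ids)
  clin <- simulate_clinical(labels, specs, config, sample_ids)
  truth <- data.frame(sample = sample_ids, subgroup = labels,
                      methylation_cluster = clusters,
                      stringsAsFactors = FALSE)
  truth <- merge(truth, clin$truth, by = "sample", sort = FALSE)
  structure(list(expression = expr, fusions = fusions,
                 methylation = list(beta = beta,
                                    annotation = sites$annotation),
                 clinical = clin$clinical, truth = truth,
                 dmr_truth = sites$dmr_truth,
                 config = config, specs = specs),
            class = "tall_cohort")
}

#' @export
print.tall_cohort <- function(x, ...) {
  cat("Synthetic T-ALL cohort:", ncol(x$expression), "samples,",
      nrow(x$expression), "genes,", nrow(x$methylation$beta), "CpGs\n")
  if (nrow(x$truth) > 0) {
    print(table(subgroup = x$truth$subgroup))
  }
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes expression and methylation matrices as TSV (first column the
#' gene/CpG identifier), fusions and site annotation as TSV, clinical and
#' truth tables as CSV, and the configuration as a flat key=value file.
#'
#' @param cohort A `tall_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mat <- function(m, path, id_col) {
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- id_col
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  files <- file.path(dir, c("expression.tsv", "methylation.tsv",
                            "cpg_annotation.tsv", "fusions.tsv",
                            "clinical.csv", "truth.csv", "config.txt"))
  write_mat(cohort$expression, files[1], "gene")
  write_mat(cohort$methylation$beta, files[2], "cpg_id")
  utils::write.table(cohort$methylation$annotation, files[3], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$fusions, files[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(cohort$clinical, files[5], row.names = FALSE)
  utils::write.csv(cohort$truth, files[6], row.names = FALSE)
  cfg <- cohort$config
  writeLines(paste0(names(cfg), "=", unlist(cfg)), files[7])
  invisible(files)
}
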