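# End-to-end orchestration: simulate -> seed-label -> classify (dual
# reference) -> tiered assignment -> methylation -> cohort statistics.

#' Adjusted Rand index between two partitions
#'
#' @param a,b Two label vectors of equal length.
#' @return Numeric ARI in [-1, 1]; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# External reference cohorts use their own subgroup vocabulary; this is the
# inverse direction of tall_label_map() for the names that differ.
external_vocabulary <- function() {
  c("TAL1/LMO" = "TAL1", "LYL1/LMO2" = "LMO2_LYL1", "NKX2" = "NKX2-1")
}

#' Run the T-ALL subtyping pipeline end to end
#'
#' Generates an internal synthetic cohort plus an external reference cohort
#' (same subgroup structure, its own label vocabulary and seed), derives
#' rule-based seed labels, trains one classifier per reference cohort,
#' performs the tiered assignment, clusters the methylation data and calls
#' DMRs for the hypomethylated cluster, and computes the clinical statistics
#' layer (MRD response table, risk groups, survival). Deterministic given
#' the configuration seed.
#'
#' @param config Cohort configuration ([tall_cohort_config()]); its `seed`
#'   drives every stage.
#' @param specs Subgroup specifications.
#' @param stages Character subset of
#'   `c("simulate", "label", "classify", "assign", "methylation", "stats")`;
#'   later stages require earlier ones.
#' @param z_threshold Seed-label robust-z threshold.
#' @param dmr_permutations Label permutations for the DMR null.
#' @return List of class `tall_pipeline_report` with per-stage results and
#'   a `summary` list of headline numbers.
#' @export
run_tall_pipeline <- function(config = tall_cohort_config(),
                              specs = tall_subgroup_specs(),
                              stages = c("simulate", "label", "classify",
                                         "assign", "methylation", "stats"),
                              z_threshold = 3,
                              dmr_permutations = 200) {
  known <- c("simulate", "label", "classify", "assign", "methylation",
             "stats")
  stopifnot(all(stages %in% known))
  report <- list(stages = stages, summary = list())
  if (length(stages) == 0) {
    class(report) <- "tall_pipeline_report"
    return(report)
  }
  need <- function(s) s %in% stages

  cohort <- NULL
  if (need("simulate") || length(stages) > 0) {
    cohort <- generate_cohort(config, specs)
    report$cohort <- cohort
    report$summary$n_samples <- ncol(cohort$expression)
  }

  log_expr <- log2(cohort$expression + 1)
  seed_labels <- NULL
  if (need("label")) {
    scores <- overexpression_scores(log_expr)
    seed_labels <- assign_seed_labels(scores, cohort$fusions,
                                      z_threshold = z_threshold)
    ref <- build_reference_set(seed_labels)
    agree <- mean(ref$labels ==
                    cohort$truth$subgroup[match(ref$samples,
                                                cohort$truth$sample)])
    report$seed_labels <- seed_labels
    report$reference_set <- ref
    report$summary$seed_label_agreement <- agree
    report$summary$seed_labeled_fraction <-
      length(ref$samples) / ncol(cohort$expression)
  }

  if (need("classify")) {
    if (is.null(seed_labels)) stop("'classify' requires the 'label' stage")
    ext_config <- config
    ext_config$seed <- config$seed + 1000L
    ext_cohort <- generate_cohort(ext_config, specs)
    vocab <- external_vocabulary()
    ext_labels <- ifelse(ext_cohort$truth$subgroup %in% names(vocab),
                         vocab[ext_cohort$truth$subgroup],
                         ext_cohort$truth$subgroup)
    harm <- harmonize_features(cohort$expression, ext_cohort$expression)
    ref <- report$reference_set
    int_labels <- rep(NA_character_, ncol(harm$a))
    names(int_labels) <- colnames(harm$a)
    int_labels[ref$samples] <- ref$labels
    fit_int <- fit_fold(t(harm$a), int_labels,
                        train_idx = match(ref$samples, colnames(harm$a)),
                        fold_seed = config$seed)
    fit_ext <- fit_fold(t(harm$b), ext_labels,
                        train_idx = seq_len(ncol(harm$b)),
                        fold_seed = config$seed + 1L)
    pred_int <- predict_subtype(fit_int$model, harm$a)
    pred_ext <- predict_subtype(fit_ext$model, harm$a)
    report$pred_internal <- pred_int
    report$pred_external <- pred_ext
    report$feature_space <- harm$genes
    report$selected_genes <- union(fit_int$selected_genes,
                                   fit_ext$selected_genes)
  }

  if (need("assign")) {
    if (is.null(report$pred_internal)) {
      stop("'assign' requires the 'classify' stage")
    }
    assignment <- assign_cohort(
      report$pred_internal[, c("sample", "label")],
      report$pred_external[, c("sample", "label")],
      expr = log_expr, fusions = cohort$fusions,
      feature_genes = report$selected_genes,
      z_threshold = z_threshold)
    report$assignment <- assignment
    report$summary$tier_counts <- assignment$tier_counts
    n <- nrow(assignment$assignments)
    report$summary$unclassified_fraction <-
      assignment$tier_counts[["unclassified"]] / n
    labeled <- assignment$assignments$subgroup != "unclassified"
    report$summary$assignment_agreement <- mean(
      assignment$assignments$subgroup[labeled] ==
        cohort$truth$subgroup[match(assignment$assignments$sample[labeled],
                                    cohort$truth$sample)])
  }

  if (need("methylation")) {
    filt <- filter_cpgs(cohort$methylation$beta,
                        cohort$methylation$annotation)
    top <- top_variable_cpgs(filt$beta, k = min(2000, nrow(filt$beta)))
    clusters <- cluster_methylation(top, n_clusters = 4,
                                    seed = config$seed)
    truth_cl <- cohort$truth$methylation_cluster[
      match(names(clusters), cohort$truth$sample)]
    report$methylation_clusters <- clusters
    report$summary$methylation_ari <- adjusted_rand_index(clusters,
                                                          truth_cl)
    # DMRs for the truth hypomethylated cluster (one-vs-rest)
    groups <- ifelse(truth_cl == "M2", "M2", "rest")
    if (sum(groups == "M2") >= 2 && sum(groups == "rest") >= 2) {
      dmrs <- bumphunt(filt$beta, groups, filt$annotation, focus = "M2",
                       B = dmr_permutations, seed = config$seed)
      report$dmrs <- dmrs
      report$summary$n_dmrs_fwer05 <- sum(dmrs$fwer_p < 0.05)
    }
    island <- filt$annotation$island_flag
    m2_mean <- mean(filt$beta[island, truth_cl == "M2"])
    rest_mean <- mean(filt$beta[island, truth_cl != "M2"])
    report$summary$m2_island_beta_deficit <- rest_mean - m2_mean
  }

  if (need("stats")) {
    pheno <- phenotype_cohort(cohort$clinical)
    report$phenotypes <- pheno
    asg <- if (!is.null(report$assignment)) {
      report$assignment$assignments[, c("sample", "subgroup")]
    } else {
      cohort$truth[, c("sample", "subgroup")]
    }
    report$mrd_table <- mrd_response_table(asg, pheno)
    risk <- assign_risk_group(asg$subgroup)
    clin <- cohort$clinical[match(asg$sample, cohort$clinical$sample), ]
    keep <- !is.na(risk)
    if (length(unique(risk[keep])) >= 2) {
      lr <- logrank(clin$os_months[keep], clin$os_event[keep], risk[keep])
      report$summary$risk_logrank_p <- lr$p
    }
    tlx1 <- asg$subgroup == "TLX1"
    if (sum(tlx1) >= 2) {
      km <- km_estimate(clin$os_months[tlx1], clin$os_event[tlx1])
      report$summary$tlx1_os3y <- km$surv_at(36)
    }
    total <- report$mrd_table[report$mrd_table$subgroup == "total", ]
    report$summary$molcr_rate_total <- 100 * total$molcr / total$n
  }

  class(report) <- "tall_pipeline_report"
  report
}

#' @export
print.tall_pipeline_report <- function(x, ...) {
  cat("T-ALL pipeline report; stages:", paste(x$stages, collapse = ", "),
      "\n")
  for (nm in names(x$summary)) {
    v <- x$summary[[nm]]
    if (is.numeric(v) && length(v) == 1) {
      cat(sprintf("  %-28s %.4g\n", nm, v))
    }
  }
  invisible(x)
}
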