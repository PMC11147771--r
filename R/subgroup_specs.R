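#' Canonical T-ALL molecular subgroup labels
#'
#' The nine molecular subgroups defined by aberrant oncogene expression in
#' adult T-ALL, in the precedence order used when several oncogene panels are
#' satisfied at once (most specific signature first).
#'
#' @return Character vector of the nine subgroup labels.
#' @export
tall_subgroups <- function() {
  c("HOXA13", "TLX1", "TLX3", "NKX2", "LMO1",
    "TAL1/LMO", "HOXA", "LYL1/LMO2", "TAL2")
}

#' Oncogene panels defining the T-ALL subgroups
#'
#' Each subgroup is defined by a set of genes that must all be overexpressed
#' (`defining`) and a set that must not be (`excluded`). The panels
#' operationalize the expression signatures of the nine subgroups: TLX1, TLX3,
#' NKX2-1 and TAL2 by a single driving transcription factor; LMO1 as
#' LMO1 overexpression on a TAL-class background; TAL1/LMO as TAL1 plus LMO2
#' without LMO1; LYL1/LMO2 by the immature stem-cell signature (LYL1, LMO2,
#' MEF2C); HOXA by anterior/mid cluster genes (HOXA9, HOXA10); and HOXA13 by
#' the posterior signature HOXA13 + EVX1 + HOTTIP with silent anterior HOXA
#' genes.
#'
#' @return Named list; each element has character vectors `defining` and
#'   `excluded` (disjoint within a panel).
#' @export
tall_oncogene_panels <- function() {
  panels <- list(
    "HOXA13"    = list(defining = c("HOXA13", "EVX1", "HOTTIP"),
                       excluded = c("HOXA9")),
    "TLX1"      = list(defining = "TLX1", excluded = character()),
    "TLX3"      = list(defining = "TLX3", excluded = character()),
    "NKX2"      = list(defining = "NKX2-1", excluded = "TLX1"),
    "LMO1"      = list(defining = c("LMO1", "TAL1"), excluded = character()),
    "TAL1/LMO"  = list(defining = c("TAL1", "LMO2"), excluded = "LMO1"),
    "HOXA"      = list(defining = c("HOXA9", "HOXA10"), excluded = "HOXA13"),
    "LYL1/LMO2" = list(defining = c("LYL1", "LMO2", "MEF2C"),
                       excluded = c("TAL1", "HOXA9")),
    "TAL2"      = list(defining = "TAL2", excluded = character())
  )
  for (nm in names(panels)) {
    stopifnot(length(intersect(panels[[nm]]$defining,
                               panels[[nm]]$excluded)) == 0L)
  }
  panels
}

#' Curated driver-fusion map
#'
#' Maps recurrent driver fusion transcripts to the molecular subgroup they
#' define. Fusion calls are filtered against this curated list before being
#' used for labeling or assignment; fusions absent from the map are treated
#' as passengers.
#'
#' @return Named character vector: names are fusion identifiers
#'   (`GENE5::GENE3`), values are subgroup labels.
#' @export
tall_driver_fusions <- function() {
  c("STIL::TAL1"         = "TAL1/LMO",
    "TCF7::TAL1"         = "TAL1/LMO",
    "TRB::TLX1"          = "TLX1",
    "TLX3::BCL11B"       = "TLX3",
    "SET::NUP214"        = "HOXA",
    "KMT2A::MLLT1"       = "HOXA",
    "PICALM::MLLT10"     = "HOXA",
    "MIR181A1HG::HOTTIP" = "HOXA13",
    "TRB::NKX2-1"        = "NKX2",
    "TRA::LMO2"          = "LYL1/LMO2")
}

#' Molecular risk-group map
#'
#' Risk classification of the molecular subgroups by 3-year overall survival:
#' good (TLX1, NKX2, LMO1), intermediate (HOXA), poor (LYL1/LMO2, HOXA13,
#' TAL1/LMO, TLX3). TAL2 (a single-sample entity without an outcome stratum)
#' and unclassified samples carry no risk group.
#'
#' @return Named character vector over the nine subgroups; TAL2 maps to `NA`.
#' @export
tall_risk_map <- function() {
  c("TLX1" = "good", "NKX2" = "good", "LMO1" = "good",
    "HOXA" = "intermediate",
    "LYL1/LMO2" = "poor", "HOXA13" = "poor", "TAL1/LMO" = "poor",
    "TLX3" = "poor",
    "TAL2" = NA_character_)
}

#' Default subgroup specifications for the synthetic cohort generator
#'
#' One specification per molecular subgroup, parameterizing cohort
#' proportions, the subgroup-defining oncogene overexpression panel (log2
#' effect sizes), driver-fusion frequencies, the target methylation cluster,
#' immunophenotype stage weights, molecular MRD response probabilities and
#' 3-year overall survival. Defaults encode the published adult T-ALL cohort
#' structure: subgroup frequencies from the 209 subgroup-assigned samples of
#' a 230-patient cohort, MRD category rates per subgroup, and subgroup 3y-OS
#' figures (HOXA13's printed 2y-OS converted to a 3y figure under the
#' exponential event-time model).
#'
#' @param effect Optional single log2 effect size overriding every panel
#'   gene's overexpression effect (used to study signal strength); `NULL`
#'   keeps the per-gene defaults.
#' @return Named list of subgroup specs; proportions sum to 1 and each spec's
#'   MRD probabilities sum to 1.
#' @export
tall_subgroup_specs <- function(effect = NULL) {
  specs <- list(
    "TLX1" = list(
      proportion = 44 / 209,
      oncogene_panel = c("TLX1" = 6),
      driver_fusions = c("TRB::TLX1" = 15 / 44),
      methylation_cluster = "M3",
      immunophenotype_weights = c(early = 0, thymic = 1, mature = 0),
      molcr_prob = 37 / 39, molimr_prob = 0 / 39, molfail_prob = 2 / 39,
      os3y = 0.92),
    "HOXA" = list(
      proportion = 50 / 209,
      oncogene_panel = c("HOXA9" = 6, "HOXA10" = 5, "MEF2C" = 3, "BAALC" = 3),
      driver_fusions = c("SET::NUP214" = 12 / 50, "KMT2A::MLLT1" = 6 / 50,
                         "PICALM::MLLT10" = 5 / 50),
      methylation_cluster = "M1",
      immunophenotype_weights = c(early = 23, thymic = 19, mature = 4) / 46,
      molcr_prob = 24 / 37, molimr_prob = 9 / 37, molfail_prob = 4 / 37,
      os3y = 0.70),
    "TAL1/LMO" = list(
      proportion = 30 / 209,
      oncogene_panel = c("TAL1" = 6, "LMO2" = 5),
      driver_fusions = c("STIL::TAL1" = 14 / 30, "TCF7::TAL1" = 1 / 30),
      methylation_cluster = "M2",
      immunophenotype_weights = c(early = 2, thymic = 17, mature = 9) / 28,
      molcr_prob = 11 / 22, molimr_prob = 6 / 22, molfail_prob = 5 / 22,
      os3y = 0.56),
    "LYL1/LMO2" = list(
      proportion = 32 / 209,
      oncogene_panel = c("LYL1" = 5, "LMO2" = 5, "MEF2C" = 4, "BAALC" = 4),
      driver_fusions = c("TRA::LMO2" = 2 / 32),
      methylation_cluster = "M4",
      immunophenotype_weights = c(early = 15, thymic = 3, mature = 10) / 28,
      molcr_prob = 3 / 9, molimr_prob = 4 / 9, molfail_prob = 2 / 9,
      os3y = 0.55),
    "TLX3" = list(
      proportion = 26 / 209,
      oncogene_panel = c("TLX3" = 6),
      driver_fusions = c("TLX3::BCL11B" = 0.2),
      methylation_cluster = "M1",
      immunophenotype_weights = c(early = 7, thymic = 10, mature = 6) / 23,
      molcr_prob = 9 / 18, molimr_prob = 5 / 18, molfail_prob = 4 / 18,
      os3y = 0.62),
    "LMO1" = list(
      proportion = 15 / 209,
      oncogene_panel = c("LMO1" = 6, "TAL1" = 5),
      driver_fusions = c(),
      methylation_cluster = "M2",
      immunophenotype_weights = c(early = 0, thymic = 9, mature = 6) / 15,
      molcr_prob = 9 / 11, molimr_prob = 0 / 11, molfail_prob = 2 / 11,
      os3y = 0.92),
    "HOXA13" = list(
      proportion = 7 / 209,
      oncogene_panel = c("HOXA13" = 6, "EVX1" = 5, "HOTTIP" = 5),
      driver_fusions = c("MIR181A1HG::HOTTIP" = 3 / 7),
      methylation_cluster = "M4",
      immunophenotype_weights = c(early = 6, thymic = 0, mature = 1) / 7,
      molcr_prob = 1 / 3, molimr_prob = 1 / 3, molfail_prob = 1 / 3,
      os3y = 0.33 ^ (36 / 24)),
    "NKX2" = list(
      proportion = 4 / 209,
      oncogene_panel = c("NKX2-1" = 6),
      driver_fusions = c("TRB::NKX2-1" = 0.5),
      methylation_cluster = "M3",
      immunophenotype_weights = c(early = 0, thymic = 3, mature = 1) / 4,
      molcr_prob = 1, molimr_prob = 0, molfail_prob = 0,
      os3y = 1.0),
    "TAL2" = list(
      proportion = 1 / 209,
      oncogene_panel = c("TAL2" = 6),
      driver_fusions = c(),
      methylation_cluster = "M1",
      immunophenotype_weights = c(early = 0, thymic = 1, mature = 0),
      molcr_prob = 0, molimr_prob = 1, molfail_prob = 0,
      os3y = 1.0)
  )
  if (!is.null(effect)) {
    stopifnot(is.numeric(effect), length(effect) == 1L, effect >= 0)
    for (nm in names(specs)) {
      specs[[nm]]$oncogene_panel[] <- effect
    }
  }
  validate_subgroup_specs(specs)
  specs
}

#' Validate a list of subgroup specifications
#'
#' Checks the structural invariants of a spec list: proportions sum to one,
#' MRD probabilities sum to one per subgroup, effect sizes are non-negative,
#' immunophenotype weights are a distribution, and methylation clusters are
#' in M1..M4.
#'
#' @param specs Named list as returned by [tall_subgroup_specs()].
#' @return The specs, invisibly; stops with a configuration error otherwise.
#' @export
validate_subgroup_specs <- function(specs) {
  if (length(specs) == 0L || is.null(names(specs))) {
    stop("specs must be a non-empty named list")
  }
  props <- vapply(specs, function(s) s$proportion, numeric(1))
  if (abs(sum(props) - 1) > 1e-9) {
    stop("subgroup proportions must sum to 1 (got ", sum(props), ")")
  }
  for (nm in names(specs)) {
    s <- specs[[nm]]
    mrd <- s$molcr_prob + s$molimr_prob + s$molfail_prob
    if (abs(mrd - 1) > 1e-9) {
      stop("MRD category probabilities for ", nm, " must sum to 1")
    }
    if (any(s$oncogene_panel < 0)) {
      stop("oncogene effect sizes for ", nm, " must be >= 0")
    }
    if (abs(sum(s$immunophenotype_weights) - 1) > 1e-9) {
      stop("immunophenotype weights for ", nm, " must sum to 1")
    }
    if (!s$methylation_cluster %in% paste0("M", 1:4)) {
      stop("methylation cluster for ", nm, " must be one of M1..M4")
    }
    if (s$os3y < 0 || s$os3y > 1) {
      stop("os3y for ", nm, " must be in [0,1]")
    }
  }
  invisible(specs)
}

#' Default synthetic cohort configuration
#'
#' @param n_samples Number of patients to simulate (default 230, the size of
#'   the cohort structure being emulated).
#' @param n_genes Number of genes in the expression matrix (marker genes plus
#'   background; default 1000).
#' @param n_cpgs Number of CpG sites on the synthetic array (default 5000).
#' @param baseline_mean,baseline_sd Log2-scale mean and dispersion of
#'   per-gene baseline expression.
#' @param noise_sd Log2-scale expression noise per sample.
#' @param methylation_shift Per-cluster beta offset magnitude for cluster
#'   signature sites.
#' @param m2_global_shift Global beta offset applied to CpG-island sites of
#'   hypomethylated cluster M2 (negative = hypomethylation).
#' @param methylation_noise_sd Beta-value noise.
#' @param censor_horizon_months Administrative censoring horizon for overall
#'   survival, in months.
#' @param seed Random seed for the generator.
#' @return List of class `tall_cohort_config`.
#' @export
tall_cohort_config <- function(n_samples = 230, n_genes = 1000,
                               n_cpgs = 5000,
                               baseline_mean = 3, baseline_sd = 1,
                               noise_sd = 1,
                               methylation_shift = 0.3,
                               m2_global_shift = -0.2,
                               methylation_noise_sd = 0.05,
                               censor_horizon_months = 60,
                               seed = 1L) {
  stopifnot(n_samples >= 0, n_samples == round(n_samples),
            n_genes >= 1, n_genes == round(n_genes),
            n_cpgs >= 1, n_cpgs == round(n_cpgs),
            noise_sd >= 0, methylation_noise_sd >= 0,
            censor_horizon_months > 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_cpgs = as.integer(n_cpgs),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd,
                 methylation_shift = methylation_shift,
                 m2_global_shift = m2_global_shift,
                 methylation_noise_sd = methylation_noise_sd,
                 censor_horizon_months = censor_horizon_months,
                 seed = as.integer(seed)),
            class = "tall_cohort_config")
}
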