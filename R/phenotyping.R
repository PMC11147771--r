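# Clinical rule systems: immunophenotype staging, the ETP flag, molecular
# MRD response categories, molecular risk grouping and blast-content sample
# eligibility.

# Antigen patterns per maturation stage. "+" = obligatory positive,
# "-" = obligatory negative, NA = unconstrained ("+/-"). Early T-ALL has two
# alternative patterns. cyCD3+ and CD7+ (T-lineage) are checked separately.
stage_patterns <- list(
  early_1 = c(CD5 = NA, CD2 = "-", sCD3 = "-", CD4 = NA, CD8 = NA,
              CD1a = "-"),
  early_2 = c(CD5 = "-", CD2 = "+", sCD3 = "-", CD4 = "-", CD8 = "-",
              CD1a = "-"),
  thymic  = c(CD5 = NA, CD2 = NA, sCD3 = NA, CD4 = "+", CD8 = "+",
              CD1a = "+"),
  mature  = c(CD5 = "+", CD2 = "+", sCD3 = NA, CD4 = NA, CD8 = NA,
              CD1a = "-")
)

marker_positive <- function(value, cutoff) {
  if (is.null(value) || is.na(value)) return(NA)
  value >= cutoff
}

pattern_matches <- function(profile, pattern, cutoff) {
  for (m in names(pattern)) {
    want <- pattern[[m]]
    if (is.na(want)) next
    got <- marker_positive(profile[[m]], cutoff)
    if (is.na(got)) return(FALSE)          # cannot confirm an obligatory marker
    if (want == "+" && !got) return(FALSE)
    if (want == "-" && got) return(FALSE)
  }
  TRUE
}

#' Classify the T-ALL immunophenotype maturation stage
#'
#' Subclassifies a T-lineage marker profile into early, thymic or mature
#' T-ALL by its obligatory antigen pattern: CD1a positivity defines thymic
#' (with CD4+ and CD8+); early T-ALL is CD1a-negative with an sCD3-negative
#' immature pattern (either CD2- or CD5-/CD2+/CD4-/CD8-); mature T-ALL is
#' CD1a-negative with CD5+ and CD2+. Markers annotated "+/-" in the stage
#' definitions are unconstrained. Profiles matching no pattern return
#' `"unclassifiable"` rather than erroring.
#'
#' @param profile Named numeric vector (or one-row list/data frame) of
#'   antigen expression percentages in [0, 100]; missing markers allowed
#'   (`NA`). Recognized names: cyCD3, sCD3, CD7, CD5, CD2, CD4, CD8, CD1a.
#' @param positivity_cutoff Percentage at or above which a marker counts as
#'   positive (default 20, the usual flow-cytometry convention).
#' @return One of `"early"`, `"thymic"`, `"mature"`, `"unclassifiable"`.
#' @export
classify_immunophenotype <- function(profile, positivity_cutoff = 20) {
  profile <- as.list(profile)
  vals <- unlist(profile[!vapply(profile, is.na, logical(1))])
  if (length(vals) > 0 && (any(vals < 0) || any(vals > 100))) {
    stop("marker percentages must lie in [0, 100]")
  }
  cy <- marker_positive(profile$cyCD3, positivity_cutoff)
  cd7 <- marker_positive(profile$CD7, positivity_cutoff)
  if (is.na(cy) || is.na(cd7) || !cy || !cd7) {
    stop("not a T-lineage profile: cyCD3+ and CD7+ are required")
  }
  hits <- names(stage_patterns)[vapply(stage_patterns, function(p)
    pattern_matches(profile, p, positivity_cutoff), logical(1))]
  hits <- unique(sub("_[12]$", "", hits))
  if (length(hits) == 1) hits else "unclassifiable"
}

#' Flag an early-T-cell-precursor (ETP) immunophenotype
#'
#' ETP-ALL is defined by weak or absent CD5 expression (< 25%) together with
#' co-expression of at least one myeloid or stem-cell marker (CD13, CD33,
#' CD34, CD117, HLA-DR).
#'
#' @inheritParams classify_immunophenotype
#' @return `TRUE`/`FALSE`, or `NA` when CD5 or every myeloid/stem marker is
#'   missing (indeterminate).
#' @export
flag_etp <- function(profile, positivity_cutoff = 20) {
  profile <- as.list(profile)
  myeloid <- c("CD13", "CD33", "CD34", "CD117", "HLADR")
  my_vals <- unlist(profile[intersect(myeloid, names(profile))])
  if (is.null(profile$CD5) || is.na(profile$CD5)) return(NA)
  if (length(my_vals) == 0 || all(is.na(my_vals))) return(NA)
  cd5_low <- profile$CD5 < 25
  any_my <- any(my_vals >= positivity_cutoff, na.rm = TRUE)
  cd5_low && any_my
}

#' Categorize a minimal residual disease (MRD) measurement
#'
#' Molecular response after consolidation relative to the 1e-4 threshold:
#' MolCR is MRD-negative with an assay sensitivity of at least 1e-4; MolIMR
#' is MRD-positive but below or at 1e-4 or positive-not-quantifiable;
#' MolFail is MRD above 1e-4. A negative result whose assay sensitivity is
#' worse than 1e-4 cannot claim MolCR and returns `NA` with an
#' insufficient-sensitivity flag.
#'
#' @param value MRD load as a fraction (0 = negative); `NA` allowed for
#'   non-quantifiable positives.
#' @param sensitivity Assay detection limit as a fraction (> 0).
#' @param quantifiable Logical; `FALSE` marks a positive signal that could
#'   not be quantified.
#' @return Character `"MolCR"`, `"MolIMR"` or `"MolFail"`, with attribute
#'   `insufficient_sensitivity = TRUE` (value `NA`) for underpowered
#'   negatives.
#' @export
categorize_mrd <- function(value, sensitivity = 1e-4, quantifiable = TRUE) {
  stopifnot(sensitivity > 0)
  if (!is.na(value) && value < 0) stop("mrd value must be >= 0")
  if (!quantifiable) return("MolIMR")       # positive, not quantifiable
  if (is.na(value)) stop("quantifiable record requires a value")
  if (value == 0) {
    if (sensitivity <= 1e-4) return("MolCR")
    return(structure(NA_character_, insufficient_sensitivity = TRUE))
  }
  if (value > 1e-4) "MolFail" else "MolIMR"
}

#' Assign the molecular risk group of a subgroup
#'
#' Good risk: TLX1, NKX2, LMO1; intermediate risk: HOXA; poor risk:
#' LYL1/LMO2, HOXA13, TAL1/LMO, TLX3. TAL2 (no outcome stratum) and
#' unclassified samples have no risk group (`NA`).
#'
#' @param subgroup Character vector of subgroup labels (the nine molecular
#'   subgroups or `"unclassified"`).
#' @return Character vector in \{good, intermediate, poor, NA\}.
#' @export
assign_risk_group <- function(subgroup) {
  map <- tall_risk_map()
  ok <- subgroup %in% c(names(map), "unclassified")
  if (any(!ok)) {
    stop("unknown subgroup label(s): ",
         paste(unique(subgroup[!ok]), collapse = ", "))
  }
  out <- rep(NA_character_, length(subgroup))
  known <- subgroup %in% names(map)
  out[known] <- unname(map[subgroup[known]])
  out
}

#' Blast-content eligibility of a sample for an assay
#'
#' Transcriptome sequencing requires at least 20% blasts; methylation
#' profiling and the targeted mutation panel require at least 60%. Both
#' thresholds are inclusive.
#'
#' @param blast_pct Blast percentage in [0, 100].
#' @param assay One of `"rnaseq"`, `"methylation"`, `"mutation_panel"`.
#' @return Logical.
#' @export
check_sample_eligibility <- function(blast_pct,
                                     assay = c("rnaseq", "methylation",
                                               "mutation_panel")) {
  assay <- match.arg(assay)
  if (any(is.na(blast_pct)) || any(blast_pct < 0) || any(blast_pct > 100)) {
    stop("blast_pct must lie in [0, 100]")
  }
  threshold <- if (assay == "rnaseq") 20 else 60
  blast_pct >= threshold
}

#' Phenotype a clinical table
#'
#' Applies [classify_immunophenotype()], [flag_etp()] and
#' [categorize_mrd()] to every row of a clinical data frame (one row per
#' sample, antigen columns named as in [classify_immunophenotype()]).
#'
#' @param clinical Clinical data frame with a `sample` column, antigen
#'   columns, and `mrd_value`, `mrd_sensitivity`, `mrd_quantifiable`.
#' @param positivity_cutoff Marker positivity cutoff in percent.
#' @return Data frame: sample, immunophenotype, etp, mrd_category.
#' @export
phenotype_cohort <- function(clinical, positivity_cutoff = 20) {
  markers <- c("cyCD3", "sCD3", "CD7", "CD5", "CD2", "CD4", "CD8", "CD1a",
               "CD13", "CD33", "CD34", "CD117", "HLADR")
  n <- nrow(clinical)
  stage <- character(n); etp <- logical(n); mrd <- character(n)
  for (i in seq_len(n)) {
    prof <- as.list(clinical[i, intersect(markers, names(clinical))])
    stage[i] <- classify_immunophenotype(prof, positivity_cutoff)
    etp[i] <- flag_etp(prof, positivity_cutoff)
    mrd[i] <- categorize_mrd(clinical$mrd_value[i],
                             clinical$mrd_sensitivity[i],
                             clinical$mrd_quantifiable[i])
  }
  data.frame(sample = clinical$sample, immunophenotype = stage, etp = etp,
             mrd_category = mrd, stringsAsFactors = FALSE)
}
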