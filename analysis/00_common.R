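# Shared plumbing for the analysis drivers: fixed study seed, output
# locations, and plain-text matrix IO.

library(tallsubtypes)

STUDY_SEED <- 20240514L
RESULTS_DIR <- file.path("results")
COHORT_DIR <- file.path(RESULTS_DIR, "cohort")

study_config <- function() {
  tall_cohort_config(n_samples = 230, n_genes = 1000, n_cpgs = 5000,
                     seed = STUDY_SEED)
}

read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

ensure_results <- function() {
  dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
}
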