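#!/usr/bin/env Rscript
# Cross-validated subtype classification on the seed-labeled reference set:
# LASSO multinomial feature selection + random forest inside a 10-fold
# stratified CV with untouched test folds. Writes results/cv_oof.csv.

source(file.path("analysis", "00_common.R"))
ensure_results()

expr <- read_matrix(file.path(COHORT_DIR, "expression.tsv"))
labels <- utils::read.csv(file.path(RESULTS_DIR, "seed_labels.csv"))
ref <- build_reference_set(labels)

x <- t(log2(expr[, ref$samples] + 1))
cv <- suppressWarnings(stratified_cv(x, ref$labels, k = 10,
                                     seed = STUDY_SEED))
utils::write.csv(cv$oof, file.path(RESULTS_DIR, "cv_oof.csv"),
                 row.names = FALSE)

print(cv)
cat("\nGenes selected per fold:",
    paste(vapply(cv$selected_genes, length, integer(1)), collapse = ", "),
    "\n")
cat("Out-of-fold accuracy:", round(cv$accuracy, 3), "\n")
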