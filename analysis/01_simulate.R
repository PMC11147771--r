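#!/usr/bin/env Rscript
# Generate the synthetic adult T-ALL study cohort: 230 patients, nine
# molecular subgroups at the published proportions, with expression, driver
# fusions, methylation, and clinical tables. Writes results/cohort/.

source(file.path("analysis", "00_common.R"))
ensure_results()

cohort <- generate_cohort(study_config(), tall_subgroup_specs())
files <- write_cohort(cohort, COHORT_DIR)

cat("Simulated cohort of", ncol(cohort$expression), "samples\n")
print(table(subgroup = cohort$truth$subgroup))
cat("\nDriver fusions per curated event:\n")
print(table(cohort$fusions$fusion[
  cohort$fusions$fusion %in% names(tall_driver_fusions())]))
cat("\nWrote:", paste(basename(files), collapse = ", "),
    "to", COHORT_DIR, "\n")
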