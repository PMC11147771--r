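#!/usr/bin/env Rscript
# Apply the clinical rule systems to the simulated clinical table:
# immunophenotype staging, ETP flag, MRD response categories and assay
# eligibility. Writes results/phenotypes.csv.

source(file.path("analysis", "00_common.R"))
ensure_results()

clinical <- utils::read.csv(file.path(COHORT_DIR, "clinical.csv"),
                            check.names = FALSE)
pheno <- phenotype_cohort(clinical)
pheno$rnaseq_eligible <- vapply(clinical$blast_pct, check_sample_eligibility,
                                logical(1), assay = "rnaseq")
pheno$methylation_eligible <- vapply(clinical$blast_pct,
                                     check_sample_eligibility,
                                     logical(1), assay = "methylation")
utils::write.csv(pheno, file.path(RESULTS_DIR, "phenotypes.csv"),
                 row.names = FALSE)

cat("Immunophenotype distribution:\n")
print(table(pheno$immunophenotype))
cat("\nETP rate among early T-ALL:",
    format_rate(
      sum(pheno$etp & pheno$immunophenotype == "early", na.rm = TRUE),
      sum(pheno$immunophenotype == "early")), "%\n")
cat("MRD categories:\n")
print(table(pheno$mrd_category))
cat("Methylation-eligible (>=60% blasts):",
    sum(pheno$methylation_eligible), "of", nrow(pheno), "\n")
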