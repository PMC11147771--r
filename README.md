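# tallsubtypes

Molecular subtype classification and multi-omics cohort analysis for adult
T-cell acute lymphoblastic leukemia (T-ALL).

## The problem

T-ALL is driven by aberrant overexpression of specific oncogenes (TAL1,
TAL2, TLX1, TLX3, NKX2-1, the HOXA cluster, LMO1/2, LYL1), and cohorts
partition into molecular subgroups with distinct immunophenotypes,
DNA-methylation patterns, treatment response and survival. Unlike B-cell
precursor ALL, these subgroups are not yet part of routine risk
stratification, and most published definitions come from pediatric cohorts.
This package re-implements, as a tested and reusable pipeline, the analysis
chain needed to define and exploit such subgroups in an adult cohort:

1. **Synthetic cohort generator** — multi-omics cohorts (expression, driver
   fusions, methylation, clinical) with hidden ground-truth subgroup labels,
   parameterized to the published adult cohort structure (nine subgroups,
   subgroup-specific oncogene panels, driver-fusion frequencies, four
   methylation clusters with global CpG-island hypomethylation of the
   TAL1-fusion cluster, MRD response rates, subgroup-dependent exponential
   survival). Patient-level data of such studies are controlled-access; the
   generator makes every stage testable without any download.
2. **Seed labeling** — rule-based reference labels from robust-z oncogene
   overexpression scores, `z = (x − median)/(1.4826·MAD + ε)` on
   log2(fpkm+1), panel score = min over defining genes, with exclusion genes
   and curated driver fusions.
3. **Subtype classifier** — shared-feature harmonization across two
   reference cohorts, LASSO multinomial feature selection
   (`cv.glmnet`, alpha = 1, minimum cross-validated deviance), 500-tree
   random forest, inside a 10-fold randomized stratified cross-validation
   whose test folds stay untouched by selection and training.
4. **Tiered assignment** — consensus of the internal and external
   classifiers, then curated driver fusions, then manual rescue (panel
   z ≥ 3 plus maximal Spearman correlation ≥ 0.5 to a subgroup centroid),
   else unclassified; the tiers partition the cohort.
5. **Methylation arm** — MAF > 0.01 and sex-chromosome CpG filters,
   top-2000-variance PCA + k-means clustering (k = 4), and a bump-hunting
   DMR caller: running-mean-smoothed group differences within genomic CpG
   clusters, area statistic `area = Σ|smoothed|`, family-wise p-values from
   label permutations, `p = (1 + #{perm max ≥ area})/(B + 1)`.
6. **Clinical statistics** — immunophenotype staging (cyCD3+/CD7+ with
   CD1a defining thymic), the ETP rule (CD5 < 25% plus myeloid/stem
   markers), MRD response categories around the 1e-4 threshold
   (MolCR/MolIMR/MolFail), molecular risk groups, Pearson χ²/Fisher,
   Mann–Whitney with BH FDR, classic preranked enrichment, Kaplan–Meier
   and log-rank survival.

## Worked example

The numbered drivers under `analysis/` run the whole study on a simulated
230-patient cohort (seed 20240514) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # cohort -> results/cohort/
Rscript analysis/02_phenotype.R     # immunophenotype, ETP, MRD categories
Rscript analysis/03_seed_labels.R   # rule-based reference labels
Rscript analysis/04_classifier.R    # 10-fold stratified CV on the reference
Rscript analysis/05_assignment.R    # tiered final assignment
Rscript analysis/06_methylation.R   # clusters M1-M4 + DMRs
Rscript analysis/07_cohort_stats.R  # MRD table, risk groups, survival
```

Selected output of that run, and what it means:

```
Seed-labeled 167 of 230 samples ( 73 %)
Agreement with hidden truth on labeled samples: 100 %
```

The conservative overexpression rule labels 73% of the cohort and every
label matches the hidden simulation truth — precision-first by design; the
classifier and rescue tiers recover the rest:

```
10-fold stratified CV: accuracy 0.993 (folds 0.933-1.000)

Tiered subgroup assignment of 230 samples
  consensus     194 (84%)
  fusion         10 (4%)
  manual         14 (6%)
  unclassified   12 (5%)
```

The methylation arm recovers the planted structure — four clusters
(adjusted Rand index 1 against the simulated truth) and the global
CpG-island hypomethylation of the TAL1-fusion cluster:

```
Mean island beta, M2 vs rest: 0.054 vs 0.204
Candidate regions: 25 ; family-wise p < 0.05: 2
```

And the clinical layer reproduces the response/outcome gradient the
subgroup parameterization encodes (molecular complete response 93% in TLX1
vs 28% in LYL1/LMO2; total 69%):

```
3-year overall survival by molecular risk group:
          risk   n  os3y
1         good  66 0.909
2 intermediate  52 0.692
3         poor 100 0.540
Log-rank across risk groups: chi-squared = 41.77 , df = 2 , p = 8.51e-10
```

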