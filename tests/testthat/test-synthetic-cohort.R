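test_that("empty cohort produces empty tables without error", {
  co <- generate_cohort(tall_cohort_config(n_samples = 0, n_genes = 50,
                                           n_cpgs = 600, seed = 1))
  expect_s3_class(co, "tall_cohort")
  expect_equal(ncol(co$expression), 0)
  expect_equal(nrow(co$fusions), 0)
  expect_equal(ncol(co$methylation$beta), 0)
  expect_equal(nrow(co$clinical), 0)
  expect_equal(nrow(co$truth), 0)
})

test_that("generation is deterministic given the seed", {
  cfg <- tall_cohort_config(n_samples = 40, n_genes = 80, n_cpgs = 800,
                            seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$fusions, b$fusions)
  expect_identical(a$methylation$beta, b$methylation$beta)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
})

test_that("subgroup frequencies match the spec proportions at large n", {
  specs <- tall_subgroup_specs()
  co <- generate_cohort(tall_cohort_config(n_samples = 2000, n_genes = 30,
                                           n_cpgs = 600, seed = 5), specs)
  freq <- table(factor(co$truth$subgroup, levels = names(specs))) / 2000
  props <- vapply(specs, function(s) s$proportion, numeric(1))
  # multinomial sampling keeps every class within 3 percentage points
  expect_true(all(abs(freq - props) < 0.03))
})

test_that("cohort invariants hold: shared ids, non-negative fpkm, betas in [0,1]", {
  co <- small_cohort(seed = 11, n = 60)
  ids <- colnames(co$expression)
  expect_identical(ids, colnames(co$methylation$beta))
  expect_identical(ids, co$clinical$sample)
  expect_identical(ids, co$truth$sample)
  expect_true(all(co$fusions$sample %in% ids))
  expect_true(all(co$expression >= 0))
  expect_true(all(co$methylation$beta >= 0 & co$methylation$beta <= 1))
})

test_that("zero effect sizes leave panel genes at baseline", {
  cfg <- tall_cohort_config(n_samples = 300, n_genes = 300, n_cpgs = 600,
                            seed = 21)
  co <- generate_cohort(cfg, tall_subgroup_specs(effect = 0))
  lx <- log2(co$expression + 1)
  # TLX1 expression in TLX1 samples vs the rest: no shift
  tlx1 <- co$truth$subgroup == "TLX1"
  p <- stats::wilcox.test(lx["TLX1", tlx1], lx["TLX1", !tlx1])$p.value
  expect_gt(p, 0.01)
})

test_that("a strong oncogene effect lifts the marker above the baseline tail", {
  cfg <- tall_cohort_config(n_samples = 200, n_genes = 300, n_cpgs = 600,
                            seed = 31)
  co <- generate_cohort(cfg, tall_subgroup_specs(effect = 6))
  lx <- log2(co$expression + 1)
  tlx1 <- which(co$truth$subgroup == "TLX1")
  baseline <- lx["TLX1", -tlx1]
  expect_true(all(lx["TLX1", tlx1] >
                    stats::quantile(baseline, 0.99) - 1e-9))
})

test_that("HOXA13 samples elevate the posterior signature but not anterior HOXA", {
  specs <- tall_subgroup_specs(effect = 6)
  cfg <- tall_cohort_config(n_samples = 400, n_genes = 100, n_cpgs = 600,
                            seed = 41)
  co <- generate_cohort(cfg, specs)
  lx <- log2(co$expression + 1)
  h13 <- co$truth$subgroup == "HOXA13"
  expect_gte(sum(h13), 3)
  for (g in c("HOXA13", "EVX1", "HOTTIP")) {
    expect_gt(mean(lx[g, h13]) - mean(lx[g, !h13]), 3)
  }
  expect_lt(abs(mean(lx["HOXA9", h13]) - mean(lx["HOXA9", !h13])), 1.5)
})

test_that("unknown subgroup labels are rejected", {
  cfg <- tall_cohort_config(n_samples = 2, n_genes = 30, n_cpgs = 600)
  expect_error(simulate_expression(c("TLX1", "NOPE"), tall_subgroup_specs(),
                                   cfg),
               "unknown subgroup")
})

test_that("M2 samples are globally hypomethylated at island CpGs", {
  co <- small_cohort(seed = 51, n = 80)
  island <- co$methylation$annotation$island_flag
  cl <- co$truth$methylation_cluster
  m2 <- mean(co$methylation$beta[island, cl == "M2"])
  for (other in c("M1", "M3", "M4")) {
    expect_lt(m2, mean(co$methylation$beta[island, cl == other]))
  }
})

test_that("zero methylation shift removes cluster separation", {
  cfg <- tall_cohort_config(n_samples = 60, n_genes = 30, n_cpgs = 1200,
                            methylation_shift = 0, m2_global_shift = 0,
                            seed = 61)
  co <- generate_cohort(cfg)
  cl <- co$truth$methylation_cluster
  means <- tapply(seq_along(cl), cl, function(ix)
    mean(co$methylation$beta[, ix]))
  expect_lt(diff(range(means)), 0.02)
})

test_that("clinical triples round-trip through MRD categorization", {
  co <- small_cohort(seed = 71, n = 150)
  back <- phenotype_cohort(co$clinical)
  expect_identical(back$mrd_category, co$truth$mrd_category)
  # the simulated stage and ETP flag also re-derive from the marker profile
  expect_identical(back$immunophenotype, co$truth$immunophenotype)
  expect_identical(back$etp, co$truth$etp)
})

test_that("degenerate MRD and survival parameters behave as specified", {
  specs <- tall_subgroup_specs()
  for (nm in names(specs)) {
    specs[[nm]]$molcr_prob <- 1
    specs[[nm]]$molimr_prob <- 0
    specs[[nm]]$molfail_prob <- 0
    specs[[nm]]$os3y <- 1
  }
  co <- generate_cohort(tall_cohort_config(n_samples = 100, n_genes = 30,
                                           n_cpgs = 600, seed = 81), specs)
  expect_true(all(co$truth$mrd_category == "MolCR"))
  expect_true(all(co$clinical$os_event == 0))
  expect_true(all(co$clinical$os_months ==
                    co$config$censor_horizon_months))
})

test_that("exponential survival reproduces the target 3-year rate", {
  specs <- tall_subgroup_specs()
  for (nm in names(specs)) specs[[nm]]$os3y <- 0.5
  co <- generate_cohort(tall_cohort_config(n_samples = 5000, n_genes = 20,
                                           n_cpgs = 600, seed = 91), specs)
  km <- km_estimate(co$clinical$os_months, co$clinical$os_event)
  expect_lt(abs(km$surv_at(36) - 0.5), 0.03)
})

test_that("invalid spec proportions raise a configuration error", {
  specs <- tall_subgroup_specs()
  specs[["TLX1"]]$proportion <- specs[["TLX1"]]$proportion + 0.1
  expect_error(generate_cohort(tall_cohort_config(n_samples = 5,
                                                  n_cpgs = 600), specs),
               "sum to 1")
})

test_that("cohorts written to disk are plain text and re-readable", {
  co <- small_cohort(seed = 101, n = 10, n_genes = 40, n_cpgs = 800)
  dir <- withr::local_tempdir()
  files <- write_cohort(co, dir)
  expect_true(all(file.exists(files)))
  expr <- utils::read.delim(file.path(dir, "expression.tsv"),
                            check.names = FALSE)
  expect_equal(expr$gene, rownames(co$expression))
  expect_equal(as.matrix(expr[, -1]), co$expression,
               ignore_attr = TRUE, tolerance = 1e-8)
  clin <- utils::read.csv(file.path(dir, "clinical.csv"),
                          check.names = FALSE)
  expect_equal(clin$sample, co$clinical$sample)
})
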