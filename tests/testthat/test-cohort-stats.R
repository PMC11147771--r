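test_that("chi-squared matches the hand formula and homogeneous tables give p=1", {
  res0 <- crosstab_test(matrix(10, 2, 2), "chi2")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  res <- crosstab_test(matrix(c(20, 10, 10, 20), 2, 2), "chi2")
  expect_equal(res$statistic, 100 / 15)   # hand: sum (O-E)^2 / E
  expect_error(crosstab_test(matrix(c(0, 0, 5, 5), 2, 2), "chi2"),
               "zero-margin")
  expect_error(crosstab_test(matrix(1:3, 1, 3)), "2x2")
})

test_that("Fisher's exact p matches hypergeometric enumeration", {
  tab <- matrix(c(5, 0, 0, 5), 2, 2)
  res <- crosstab_test(tab, "fisher")
  # oracle: enumerate all tables with the fixed margins, sum probabilities
  # no larger than the observed table's
  probs <- dhyper(0:5, 5, 5, 5)
  p_exact <- sum(probs[probs <= dhyper(5, 5, 5, 5) + 1e-12])
  expect_equal(p_exact, 2 / 252)
  expect_equal(res$p, p_exact, tolerance = 1e-9)
  expect_error(crosstab_test(matrix(1, 3, 3), "fisher"), "2x2")
})

test_that("auto method picks Fisher only for sparse 2x2 tables", {
  expect_equal(crosstab_test(matrix(c(2, 8, 7, 3), 2, 2), "auto")$method,
               "fisher")
  expect_equal(crosstab_test(matrix(c(20, 20, 20, 20), 2, 2),
                             "auto")$method, "chi2")
  expect_equal(crosstab_test(matrix(2, 3, 3), "auto")$method, "chi2")
})

test_that("percentage formatting follows the half-away-from-zero convention", {
  expect_equal(format_rate(37, 39, 0), "95")
  expect_equal(format_rate(21, 230, 1), "9.1")
  expect_equal(format_rate(0, 5, 0), "0")
  expect_equal(format_rate(1, 8, 0), "13")   # 12.5 rounds up
  expect_equal(format_rate(1, 3, 1), "33.3")
  expect_true(is.na(format_rate(0, 0, 0)))
  expect_error(format_rate(6, 5, 0))
})

test_that("the MRD response table reproduces the published total row", {
  # per-subgroup MolCR/MolIMR/MolFail counts of the 139-sample response
  # table; the total row must come out as 95/25/19 with rates 68/18/14
  counts <- list("TLX1" = c(37, 0, 2), "HOXA" = c(24, 9, 4),
                 "TAL1/LMO" = c(11, 6, 5), "TLX3" = c(9, 5, 4),
                 "LMO1" = c(9, 0, 2), "LYL1/LMO2" = c(3, 4, 2),
                 "NKX2" = c(2, 0, 0), "TAL2" = c(0, 1, 0))
  cats <- c("MolCR", "MolIMR", "MolFail")
  rows <- do.call(rbind, lapply(names(counts), function(sg) {
    data.frame(subgroup = sg,
               mrd_category = rep(cats, counts[[sg]]))
  }))
  rows$sample <- sprintf("P%03d", seq_len(nrow(rows)))
  tab <- mrd_response_table(rows[, c("sample", "subgroup")],
                            rows[, c("sample", "mrd_category")])
  total <- tab[tab$subgroup == "total", ]
  expect_equal(total$n, 139)
  expect_equal(c(total$molcr, total$molimr, total$molfail), c(95, 25, 19))
  expect_equal(c(total$molcr_rate, total$molimr_rate, total$molfail_rate),
               c("68", "18", "14"))
  tlx1 <- tab[tab$subgroup == "TLX1", ]
  expect_equal(c(tlx1$molcr_rate, tlx1$molfail_rate), c("95", "5"))
  # row sums equal subgroup sample counts and rates recompute from counts
  expect_true(all(tab$molcr + tab$molimr + tab$molfail == tab$n))
  expect_equal(tab$molcr_rate,
               mapply(format_rate, tab$molcr, tab$n))
})

test_that("unassigned and empty subgroups are handled in the MRD table", {
  asg <- data.frame(sample = "P1", subgroup = "TLX1")
  mrd <- data.frame(sample = c("P1", "P2"),
                    mrd_category = c("MolCR", "MolFail"))
  tab <- mrd_response_table(asg, mrd)
  expect_true("unassigned" %in% tab$subgroup)
  expect_equal(tab$n[tab$subgroup == "unassigned"], 1)
})

test_that("Mann-Whitney exact p matches rank enumeration for extreme data", {
  expr <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
                 dimnames = list("g1", paste0("S", 1:6)))
  res <- mann_whitney_de(expr, paste0("S", 1:3), paste0("S", 4:6))
  expect_equal(res$U, 0)
  # oracle: of the choose(6,3)=20 equally likely group assignments, only
  # the two most extreme reach |U - 4.5| >= 4.5, so two-sided p = 2/20
  u_all <- apply(utils::combn(6, 3), 2, function(ix)
    sum(rank(1:6)[ix]) - 3 * 4 / 2)
  p_enum <- mean(abs(u_all - 4.5) >= abs(0 - 4.5))
  expect_equal(p_enum, 0.1)
  expect_equal(res$p, p_enum)
})

test_that("identical groups and overlapping groups are handled", {
  expr <- matrix(rep(c(1, 2, 3), 2), 1, 6,
                 dimnames = list("g1", paste0("S", 1:6)))
  res <- mann_whitney_de(expr, paste0("S", 1:3), paste0("S", 4:6))
  expect_equal(res$p, 1)
  const <- matrix(5, 1, 6, dimnames = list("g1", paste0("S", 1:6)))
  expect_equal(mann_whitney_de(const, paste0("S", 1:3),
                               paste0("S", 4:6))$p, 1)
  expect_error(mann_whitney_de(expr, paste0("S", 1:3), paste0("S", 3:6)),
               "overlap")
})

test_that("Mann-Whitney keeps its nominal type-I error on null data", {
  set.seed(9)
  expr <- matrix(stats::rnorm(1000 * 20), 1000, 20,
                 dimnames = list(sprintf("g%04d", 1:1000),
                                 sprintf("S%02d", 1:20)))
  res <- mann_whitney_de(expr, sprintf("S%02d", 1:10),
                         sprintf("S%02d", 11:20))
  rate <- mean(res$p < 0.05)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 1000)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("BH adjustment matches the hand step-up and is order-preserving", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.04, 0.01, 0.03, 0.02)
  expect_equal(bh_fdr(p), rep(0.04, 4))         # input order preserved
  q <- bh_fdr(c(0.001, 0.5, 0.02, NA))
  expect_true(is.na(q[4]))
  expect_true(all(q >= c(0.001, 0.5, 0.02, NA), na.rm = TRUE))
  expect_error(bh_fdr(c(0.5, 1.2)))
})

test_that("enrichment score hits its extremes and reverses with the ranking", {
  ranked <- stats::setNames(seq(10, 1), paste0("g", 1:10))
  top <- preranked_enrichment(ranked, list(topset = paste0("g", 1:3)),
                              n_permutations = 99, seed = 1)
  expect_equal(top$es, 1)
  bottom <- preranked_enrichment(ranked, list(bot = paste0("g", 8:10)),
                                 n_permutations = 99, seed = 1)
  expect_equal(bottom$es, -1)
  # reversing the ranking (negating the statistic) negates the score
  rev_ranked <- stats::setNames(-seq(10, 1), paste0("g", 1:10))
  rev_top <- preranked_enrichment(rev_ranked,
                                  list(topset = paste0("g", 1:3)),
                                  n_permutations = 99, seed = 1)
  expect_equal(rev_top$es, -1)
  expect_error(preranked_enrichment(ranked, list(void = c("zz", "g1"))),
               "fewer than 2")
})

test_that("a uniformly interleaved set is not enriched", {
  ranked <- stats::setNames(seq(100, 1), sprintf("g%03d", 1:100))
  hits <- sprintf("g%03d", seq(5, 100, by = 5))
  high_p <- vapply(1:10, function(s)
    preranked_enrichment(ranked, list(interleaved = hits),
                         n_permutations = 200, seed = s)$p,
    numeric(1))
  expect_gte(mean(high_p > 0.5), 0.9)
  # oracle: brute-force running sum for the observed statistic
  hit <- names(ranked) %in% hits
  run <- cumsum(ifelse(hit, 1 / 20, -1 / 80))
  expect_lt(max(abs(run)), 0.25)
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  km0 <- km_estimate(c(3, 8, 12), c(0, 0, 0))
  expect_equal(km0$surv_at(c(0, 5, 20)), c(1, 1, 1))
  km <- km_estimate(c(5, 10, 15), c(0, 1, 0))
  # at t=10 two subjects remain at risk and one dies: S(10) = 1/2
  expect_equal(km$surv_at(10), 0.5)
  expect_equal(km$surv_at(9.9), 1)
  expect_equal(km$surv_at(20), 0.5)
  expect_error(km_estimate(numeric(), integer()), "empty")
  expect_error(km_estimate(c(-1, 2), c(1, 0)), "negative")
  # S is non-increasing and within [0,1]
  set.seed(12)
  km2 <- km_estimate(stats::rexp(50, 0.05), stats::rbinom(50, 1, 0.7))
  s <- km2$surv_at(seq(0, 100, by = 5))
  expect_true(all(diff(s) <= 0))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("log-rank separates extreme strata and is null on identical ones", {
  t0 <- c(1, 2, 3, 4, 5)
  same <- logrank(c(t0, t0), c(1, 1, 0, 1, 0, 1, 1, 0, 1, 0),
                  rep(c("a", "b"), each = 5))
  expect_equal(same$statistic, 0, tolerance = 1e-9)
  expect_equal(same$p, 1, tolerance = 1e-9)
  extreme <- logrank(c(rep(1, 20), rep(2, 20)),
                     c(rep(1, 20), rep(0, 20)),
                     rep(c("dead", "alive"), each = 20))
  expect_lt(extreme$p, 0.001)
  expect_error(logrank(t0, c(1, 1, 0, 1, 0), rep("a", 5)), "two strata")
})

test_that("log-rank keeps its nominal size under equal exponential groups", {
  set.seed(31)
  rejections <- vapply(1:500, function(i) {
    time <- stats::rexp(40, 0.05)
    event <- as.integer(time < 30)
    time <- pmin(time, 30)
    logrank(time, event, rep(c("a", "b"), each = 20))$p < 0.05
  }, logical(1))
  rate <- mean(rejections)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 500)
  expect_gte(rate, ci[1] - 0.005)
  expect_lte(rate, ci[2] + 0.005)
})
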