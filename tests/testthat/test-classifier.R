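make_toy <- function(n_per_class = 30, n_genes = 40, effect = 6,
                     noise = 0.5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(stats::rnorm(n * n_genes, 0, noise), n, n_genes,
              dimnames = list(sprintf("S%03d", 1:n),
                              sprintf("g%03d", 1:n_genes)))
  y <- rep(c("A", "B"), each = n_per_class)
  x[y == "B", 1] <- x[y == "B", 1] + effect   # g001 carries the signal
  list(x = x, y = y)
}

test_that("feature harmonization intersects, orders and dedups genes", {
  a <- matrix(1:6, 3, 2, dimnames = list(c("g1", "g2", "g3"),
                                         c("s1", "s2")))
  b <- matrix(1:6, 3, 2, dimnames = list(c("g2", "g3", "g4"),
                                         c("t1", "t2")))
  h <- harmonize_features(a, b, apply_log = FALSE)
  expect_equal(h$genes, c("g2", "g3"))
  expect_equal(rownames(h$a), rownames(h$b))
  # identical gene sets: projection is the identity up to ordering
  h2 <- harmonize_features(a, a, apply_log = FALSE)
  expect_equal(h2$a, a[sort(rownames(a)), ])
  # duplicated symbol: the highest-mean row is kept, with a warning
  a_dup <- rbind(a, g2 = c(100, 100))
  expect_warning(h3 <- harmonize_features(a_dup, b, apply_log = FALSE),
                 "duplicated")
  expect_equal(unname(h3$a["g2", ]), c(100, 100))
  expect_error(harmonize_features(
    matrix(1, 1, 1, dimnames = list("x", "s")),
    matrix(1, 1, 1, dimnames = list("y", "s"))), "no shared genes")
})

test_that("log2(fpkm+1) transform is applied when requested", {
  a <- matrix(c(0, 1, 3, 7), 2, 2, dimnames = list(c("g1", "g2"), NULL))
  h <- harmonize_features(a, a)
  expect_equal(unname(h$a), log2(unname(a) + 1))
})

test_that("lasso selection finds the discriminating gene", {
  toy <- make_toy(n_per_class = 50, effect = 6, noise = 0.5, seed = 11)
  sel <- lasso_select(toy$x, toy$y)
  # oracle: the gene with the best univariate separation must be selected
  auc_rank <- apply(toy$x, 2, function(g)
    abs(stats::wilcox.test(g[toy$y == "A"],
                           g[toy$y == "B"])$statistic / (50 * 50) - 0.5))
  expect_equal(names(which.max(auc_rank)), "g001")
  expect_true("g001" %in% sel)
  expect_error(lasso_select(toy$x, rep("A", nrow(toy$x))),
               "at least two classes")
})

test_that("the penalty path starts empty and selection grows as it relaxes", {
  toy <- make_toy(seed = 21)
  fit <- glmnet::glmnet(toy$x, factor(toy$y), family = "multinomial",
                        alpha = 1)
  nz <- fit$df
  expect_equal(nz[1], 0)                  # strongest penalty: nothing
  expect_gte(nz[length(nz)], nz[1])
})

test_that("random forest separates a separable toy and records classes", {
  toy <- make_toy(seed = 31)
  model <- train_random_forest(toy$x[, 1:5], toy$y, n_trees = 200)
  expect_s3_class(model, "tall_subtype_model")
  expect_equal(model$classes, c("A", "B"))
  pred <- predict_subtype(model, t(toy$x[, 1:5]))
  expect_equal(pred$label, toy$y)          # resubstitution on separable data
  expect_true(all(abs(rowSums(as.matrix(pred[, c("A", "B")])) - 1) < 1e-9))
})

test_that("shuffled labels give chance-level out-of-bag accuracy", {
  toy <- make_toy(n_per_class = 40, seed = 41)
  set.seed(42)
  y_perm <- sample(toy$y)
  model <- train_random_forest(toy$x, y_perm, n_trees = 300)
  oob <- 1 - model$forest$err.rate[300, "OOB"]
  expect_lt(abs(oob - 0.5), 0.1)           # majority class frequency 0.5
})

test_that("an uninformative constant feature predicts at chance", {
  set.seed(51)
  x <- matrix(1, 60, 1, dimnames = list(sprintf("S%02d", 1:60), "g001"))
  y <- rep(c("A", "B"), each = 30)
  model <- train_random_forest(x, y, n_trees = 100)
  pred <- predict_subtype(model, t(x))
  expect_lt(abs(mean(pred$label == y) - 0.5), 0.2)
})

test_that("prediction imputes missing genes and refuses >50% missing", {
  toy <- make_toy(seed = 61)
  model <- train_random_forest(toy$x[, 1:10], toy$y, n_trees = 100)
  newx <- t(toy$x[, 1:6])                  # 4 of 10 genes missing
  expect_warning(pred <- predict_subtype(model, newx), "imputing")
  expect_equal(nrow(pred), nrow(toy$x))
  expect_error(predict_subtype(model, t(toy$x[, 1:4, drop = FALSE])),
               "missing")
})

test_that("an all-zero sample yields a valid probability vector", {
  toy <- make_toy(seed = 71)
  model <- train_random_forest(toy$x[, 1:5], toy$y, n_trees = 100)
  zero <- matrix(0, 5, 1, dimnames = list(colnames(toy$x)[1:5], "Z1"))
  pred <- predict_subtype(model, zero)
  expect_equal(sum(as.numeric(pred[1, c("A", "B")])), 1, tolerance = 1e-9)
  expect_true(pred$label %in% c("A", "B"))
})

test_that("stratified folds split classes within one sample of proportionality", {
  set.seed(81)
  x <- matrix(stats::rnorm(100 * 5), 100, 5,
              dimnames = list(sprintf("S%03d", 1:100), paste0("g", 1:5)))
  y <- rep(c("A", "B"), each = 50)
  cv <- stratified_cv(x, y, k = 10, seed = 3, n_trees = 50, nlambda = 30)
  split_tab <- table(cv$folds, y)
  expect_true(all(split_tab == 5))         # 5 + 5 per fold
  expect_setequal(cv$oof$sample, rownames(x))
  expect_true(all(table(cv$oof$sample) == 1))
})

test_that("cross-validation is a pure function of its seed", {
  toy <- make_toy(n_per_class = 30, n_genes = 20, seed = 91)
  cv1 <- stratified_cv(toy$x, toy$y, k = 5, seed = 7, n_trees = 50,
                       nlambda = 30)
  cv2 <- stratified_cv(toy$x, toy$y, k = 5, seed = 7, n_trees = 50,
                       nlambda = 30)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$oof, cv2$oof)
  cv3 <- stratified_cv(toy$x, toy$y, k = 5, seed = 8, n_trees = 50,
                       nlambda = 30)
  expect_false(identical(cv3$folds, cv1$folds))
})

test_that("corrupting held-out labels does not alter training artifacts", {
  toy <- make_toy(n_per_class = 30, n_genes = 20, seed = 101)
  y <- toy$y
  folds <- stats::setNames(rep(1:5, length.out = 60), rownames(toy$x))
  test_idx <- which(folds == 1)
  train_idx <- which(folds != 1)
  fit_clean <- tallsubtypes:::fit_fold(toy$x, y, train_idx, fold_seed = 5,
                                       nlambda = 30, n_trees = 50)
  y_bad <- y
  y_bad[test_idx] <- sample(c("A", "B"), length(test_idx), replace = TRUE)
  fit_bad <- tallsubtypes:::fit_fold(toy$x, y_bad, train_idx, fold_seed = 5,
                                     nlambda = 30, n_trees = 50)
  expect_identical(fit_clean$selected_genes, fit_bad$selected_genes)
  expect_identical(fit_clean$model$forest$forest,
                   fit_bad$model$forest$forest)
})

test_that("small classes are excluded from CV with a flag", {
  toy <- make_toy(n_per_class = 30, n_genes = 20, seed = 111)
  y <- toy$y
  y[1:3] <- "C"                            # 3-member class, k = 5
  cv <- stratified_cv(toy$x, y, k = 5, seed = 7, n_trees = 50,
                      nlambda = 30)
  expect_equal(cv$excluded_classes, "C")
  expect_false("C" %in% cv$oof$truth)
  expect_error(stratified_cv(toy$x[1:8, ], y[1:8], k = 5, seed = 1),
               "smaller k")
})
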