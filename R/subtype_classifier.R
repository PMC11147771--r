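# Machine-learning subtype classifier: shared-feature harmonization across
# cohorts, L1-penalized multinomial feature selection (glmnet), random-forest
# training, and 10-fold randomized stratified cross-validation in which the
# test fold stays untouched by feature selection and training.

#' Harmonize two expression matrices to a shared feature space
#'
#' Restricts both matrices to the intersection of their gene identifiers in
#' deterministic (lexicographic) order and, by default, applies the
#' log2(fpkm+1) transform. Duplicated gene symbols are deduplicated by
#' keeping the row with the highest mean, with a warning.
#'
#' @param a,b Expression matrices, genes in rows, samples in columns.
#' @param apply_log Apply log2(x+1) to the projected matrices.
#' @return List: `genes` (shared feature space), `a`, `b` (projected
#'   matrices with identical row order).
#' @export
harmonize_features <- function(a, b, apply_log = TRUE) {
  dedup <- function(m, tag) {
    dup <- duplicated(rownames(m)) | duplicated(rownames(m), fromLast = TRUE)
    if (any(dup)) {
      warning("duplicated gene symbols in ", tag,
              "; keeping highest-mean row: ",
              paste(unique(rownames(m)[dup]), collapse = ", "))
      keep <- unlist(lapply(split(seq_len(nrow(m)), rownames(m)),
                            function(ix) ix[which.max(rowMeans(
                              m[ix, , drop = FALSE]))]))
      m <- m[sort(keep), , drop = FALSE]
    }
    m
  }
  a <- dedup(a, "first matrix"); b <- dedup(b, "second matrix")
  genes <- sort(intersect(rownames(a), rownames(b)))
  if (length(genes) == 0) stop("no shared genes between the two matrices")
  a <- a[genes, , drop = FALSE]; b <- b[genes, , drop = FALSE]
  if (apply_log) { a <- log2(a + 1); b <- log2(b + 1) }
  list(genes = genes, a = a, b = b)
}

# Stratified fold ids: within each class, shuffled indices are dealt
# round-robin over k folds, so per-fold class counts differ by at most one.
stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  offset <- 0L
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- 1L + (seq_along(idx) - 1L + offset) %% k
    offset <- offset + length(idx)   # balance fold sizes across classes
  }
  folds
}

#' L1-penalized multinomial feature selection
#'
#' Fits a multinomial logistic regression with lasso penalty (alpha = 1)
#' over a descending penalty path, chooses the penalty by internal
#' cross-validated multinomial deviance, and returns every gene with a
#' nonzero coefficient in any class at the chosen penalty.
#'
#' @param x Numeric matrix, samples in rows, genes (features) in columns.
#' @param labels Class labels (factor or character), one per row of `x`.
#' @param n_inner_folds Internal CV folds (default 10; reduced to the
#'   smallest class size when necessary). Fold ids are stratified by class.
#' @param nlambda Number of penalties on the path (default 100).
#' @param lambda_choice `"min"` (minimum-deviance penalty, default) or
#'   `"1se"`.
#' @return Character vector of selected gene names, with attribute
#'   `lambda` (the chosen penalty).
#' @export
lasso_select <- function(x, labels, n_inner_folds = 10, nlambda = 100,
                         lambda_choice = c("min", "1se")) {
  lambda_choice <- match.arg(lambda_choice)
  labels <- factor(labels)
  # internal CV needs every class present in every training split: classes
  # with fewer than 3 members cannot guarantee that and are left out of the
  # selection fit (they still reach the forest)
  tiny <- names(table(labels))[table(labels) < 3]
  if (length(tiny) > 0) {
    warning("class(es) too small for penalized selection, excluded: ",
            paste(tiny, collapse = ", "))
    keep <- !(labels %in% tiny)
    x <- x[keep, , drop = FALSE]
    labels <- droplevels(labels[keep])
  }
  if (nlevels(labels) < 2) stop("need at least two classes for selection")
  k <- max(3, min(n_inner_folds, min(table(labels))))
  foldid <- stratified_folds(as.character(labels), k)
  cv <- glmnet::cv.glmnet(x, labels, family = "multinomial", alpha = 1,
                          type.measure = "deviance", foldid = foldid,
                          nlambda = nlambda)
  lam <- if (lambda_choice == "min") cv$lambda.min else cv$lambda.1se
  coefs <- glmnet::coef.glmnet(cv$glmnet.fit, s = lam)
  nz <- unique(unlist(lapply(coefs, function(cc) {
    rn <- rownames(cc)[as.vector(cc != 0)]
    setdiff(rn, "(Intercept)")
  })))
  structure(sort(nz), lambda = lam)
}

#' Train the random-forest subtype classifier
#'
#' @param x Numeric matrix, samples in rows, selected genes in columns.
#' @param labels Class labels, one per row.
#' @param n_trees Number of trees (default 500).
#' @param mtry Features per split; default `sqrt(p)`.
#' @return Object of class `tall_subtype_model`: the forest plus the feature
#'   list, class order, per-class training counts and training medians (used
#'   to impute genes missing at prediction time).
#' @export
train_random_forest <- function(x, labels, n_trees = 500, mtry = NULL) {
  labels <- factor(labels)
  if (any(table(labels) == 0)) labels <- droplevels(labels)
  if (ncol(x) == 0) stop("no selected genes to train on")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  constant <- apply(x, 2, function(col) length(unique(col)) <= 1L)
  if (all(constant)) {
    # nothing to split on: degenerate model predicting the class prior
    return(structure(list(forest = NULL, genes = colnames(x),
                          classes = levels(labels),
                          class_counts = table(labels),
                          priors = table(labels) / length(labels),
                          medians = apply(x, 2, stats::median)),
                     class = "tall_subtype_model"))
  }
  colnames_x <- colnames(x)
  xs <- x
  colnames(xs) <- make.names(colnames_x)   # forest needs syntactic names
  rf <- randomForest::randomForest(x = xs, y = labels, ntree = n_trees,
                                   mtry = mtry)
  structure(list(forest = rf, genes = colnames_x,
                 classes = levels(labels),
                 class_counts = table(labels),
                 medians = apply(x, 2, stats::median)),
            class = "tall_subtype_model")
}

#' Predict molecular subtypes
#'
#' Genes missing from the input matrix are imputed at the training median
#' (with a warning); prediction is refused when more than half of the
#' model's genes are absent. Labels are the argmax of the class-probability
#' vector with lexicographic tie-break.
#'
#' @param model A `tall_subtype_model`.
#' @param expr Expression matrix on the training scale (log2(fpkm+1)),
#'   genes in rows, samples in columns.
#' @return Data frame: `sample`, `label`, plus one probability column per
#'   class (each row sums to 1).
#' @export
predict_subtype <- function(model, expr) {
  missing <- setdiff(model$genes, rownames(expr))
  if (length(missing) > length(model$genes) / 2) {
    stop("more than half of the model's genes are missing (",
         length(missing), "/", length(model$genes), ")")
  }
  x <- matrix(NA_real_, nrow = ncol(expr), ncol = length(model$genes),
              dimnames = list(colnames(expr), model$genes))
  present <- setdiff(model$genes, missing)
  x[, present] <- t(expr[present, , drop = FALSE])
  if (length(missing) > 0) {
    warning("imputing ", length(missing),
            " missing gene(s) at training median")
    for (g in missing) x[, g] <- model$medians[[g]]
  }
  colnames(x) <- make.names(model$genes)
  if (is.null(model$forest)) {      # prior-only degenerate model
    prob <- matrix(rep(as.numeric(model$priors), each = nrow(x)),
                   nrow = nrow(x),
                   dimnames = list(rownames(x), model$classes))
  } else {
    prob <- stats::predict(model$forest, newdata = x, type = "prob")
  }
  prob <- prob / rowSums(prob)
  label <- apply(prob, 1, function(p) {
    best <- which(p == max(p))
    sort(colnames(prob)[best])[1]    # deterministic lexicographic tie-break
  })
  out <- data.frame(sample = colnames(expr), label = unname(label),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(prob))
}

# Fit one CV fold on training rows only; never looks at test-row labels.
fit_fold <- function(x, labels, train_idx, fold_seed, n_inner_folds = 10,
                     n_trees = 500, nlambda = 100) {
  set.seed(fold_seed)
  sel <- lasso_select(x[train_idx, , drop = FALSE], labels[train_idx],
                      n_inner_folds = n_inner_folds, nlambda = nlambda)
  if (length(sel) == 0) sel <- colnames(x)   # degenerate path: keep all
  model <- train_random_forest(x[train_idx, sel, drop = FALSE],
                               labels[train_idx], n_trees = n_trees)
  list(selected_genes = as.character(sel), model = model)
}

#' Stratified cross-validation of the subtype classifier
#'
#' Randomized stratified k-fold CV in which feature selection,
#' hyper-parameters and training use only the 90% training split of each
#' fold; the held-out 10% is exclusively used for prediction. Classes with
#' fewer members than `k` are excluded from the CV (flagged in the report).
#' The whole procedure is a deterministic function of
#' (matrix, labels, k, seed).
#'
#' @param x Numeric matrix, samples in rows (named), genes in columns.
#' @param labels Class labels, one per row.
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling fold assignment, inner CV folds and
#'   forest randomness.
#' @param n_trees,nlambda,n_inner_folds Passed through to the fold fits.
#' @param folds Optional precomputed fold assignment (named integer vector
#'   over the retained samples), overriding the stratified draw.
#' @return Object of class `tall_cv_report`: out-of-fold predictions,
#'   fold map, per-fold accuracy, per-class recall, overall accuracy,
#'   per-fold selected genes, excluded classes and the seed.
#' @export
stratified_cv <- function(x, labels, k = 10, seed = 1,
                          n_trees = 500, nlambda = 100, n_inner_folds = 10,
                          folds = NULL) {
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  if (is.null(rownames(x))) rownames(x) <- sprintf("S%04d", seq_len(nrow(x)))
  counts <- table(labels)
  excluded <- names(counts)[counts < k]
  keep <- !(labels %in% excluded)
  x <- x[keep, , drop = FALSE]; labels <- labels[keep]
  if (nrow(x) < 2 * k) {
    stop("fewer than 2k samples after class filtering; use a smaller k")
  }
  set.seed(seed)
  if (is.null(folds)) {
    folds <- stats::setNames(stratified_folds(labels, k), rownames(x))
  } else {
    folds <- folds[rownames(x)]
  }
  oof <- vector("list", k)
  fold_acc <- numeric(k)
  selected <- vector("list", k)
  for (i in seq_len(k)) {
    test_idx <- which(folds == i)
    train_idx <- which(folds != i)
    fit <- fit_fold(x, labels, train_idx, fold_seed = seed + i,
                    n_inner_folds = n_inner_folds, n_trees = n_trees,
                    nlambda = nlambda)
    selected[[i]] <- fit$selected_genes
    pred <- predict_subtype(fit$model,
                            t(x[test_idx, , drop = FALSE]))
    pred$truth <- labels[test_idx]
    pred$fold <- i
    fold_acc[i] <- mean(pred$label == pred$truth)
    oof[[i]] <- pred[, c("sample", "fold", "truth", "label")]
  }
  oof <- do.call(rbind, oof)
  recall <- vapply(sort(unique(labels)), function(cl) {
    mean(oof$label[oof$truth == cl] == cl)
  }, numeric(1))
  structure(list(oof = oof, folds = folds, fold_accuracy = fold_acc,
                 class_recall = recall,
                 accuracy = mean(oof$label == oof$truth),
                 selected_genes = selected,
                 excluded_classes = excluded, k = k, seed = seed),
            class = "tall_cv_report")
}

#' @export
print.tall_cv_report <- function(x, ...) {
  cat(sprintf("%d-fold stratified CV: accuracy %.3f (folds %.3f-%.3f)\n",
              x$k, x$accuracy, min(x$fold_accuracy), max(x$fold_accuracy)))
  if (length(x$excluded_classes) > 0) {
    cat("excluded classes (<k members):",
        paste(x$excluded_classes, collapse = ", "), "\n")
  }
  print(round(x$class_recall, 3))
  invisible(x)
}
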