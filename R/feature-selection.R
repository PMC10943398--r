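# Dual machine-learning biomarker selection: cross-validated L1-penalised
# logistic regression and linear-SVM recursive feature elimination, with the
# biomarker set defined as the intersection of the two selections.

# Mean binomial deviance of predicted probabilities, clamped away from 0/1.
binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

#' LASSO feature selection with cross-validated penalty choice
#'
#' Fits an L1-penalised logistic regression over a grid of penalties
#' (features standardised internally), estimates out-of-sample binomial
#' deviance by stratified k-fold cross-validation, picks the penalty with the
#' minimum mean CV deviance, and returns the features with nonzero
#' coefficients at that penalty in a final fit on all samples.
#'
#' @param X Numeric matrix, samples x features, with feature colnames.
#' @param y Binary labels (0/1, two-level factor, or case/control).
#' @param lambda_grid Decreasing positive penalty grid; default is 50
#'   log-spaced values spanning `[1e-3, 1] * lambda_max`, where `lambda_max`
#'   is the smallest penalty shrinking all coefficients to zero.
#' @param k_folds Number of stratified CV folds (default 5).
#' @param seed Seed controlling fold assignment.
#' @return List with `selected` (character vector), `lambda` (chosen
#'   penalty), `cv_deviance` (per-grid-point mean deviance) and
#'   `lambda_grid`.
#' @export
lasso_select <- function(X, y, lambda_grid = NULL, k_folds = 5, seed = 1) {
  y <- binarize_labels(y)
  if (length(unique(y)) < 2) stop("`y` must contain both classes")
  if (min(table(y)) < k_folds)
    stop("need at least `k_folds` samples in each class")
  if (!is.null(lambda_grid) && length(lambda_grid) == 0)
    stop("`lambda_grid` must be non-empty")
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  if (is.null(lambda_grid)) {
    Xs <- scale(X)
    Xs[, attr(Xs, "scaled:scale") == 0] <- 0
    lambda_max <- max(abs(crossprod(Xs, y - mean(y)))) / nrow(X)
    lambda_grid <- exp(seq(log(lambda_max), log(1e-3 * lambda_max),
                           length.out = 50))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  folds <- stratified_folds(y, k_folds, seed)
  dev <- matrix(NA_real_, nrow = k_folds, ncol = length(lambda_grid))
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                          lambda = lambda_grid, standardize = TRUE)
    pr <- stats::predict(fit, X[!tr, , drop = FALSE], type = "response")
    # glmnet may drop trailing lambdas; align by fitted lambda values
    got <- match(signif(fit$lambda, 10), signif(lambda_grid, 10))
    for (j in seq_along(got))
      if (!is.na(got[j]))
        dev[f, got[j]] <- binomial_deviance(y[!tr], pr[, j])
  }
  mean_dev <- colMeans(dev, na.rm = TRUE)
  best <- which.min(mean_dev)
  lam <- lambda_grid[best]
  final <- glmnet::glmnet(X, y, family = "binomial", lambda = lambda_grid,
                          standardize = TRUE)
  beta <- stats::coef(final, s = lam, exact = FALSE)[-1, 1]
  list(selected = names(beta)[beta != 0], lambda = lam,
       cv_deviance = mean_dev, lambda_grid = lambda_grid)
}

# Squared-weight scores of a linear SVM fitted to (X, y). X is assumed
# standardised already; y a 0/1 vector.
svm_weight_scores <- function(X, y, cost) {
  fit <- e1071::svm(X, factor(y), kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- crossprod(fit$coefs, fit$SV)
  drop(w)^2
}

#' SVM recursive feature elimination
#'
#' Repeatedly fits a linear maximum-margin classifier, scores features by
#' their squared weights, and removes the `elimination_step` lowest-scoring
#' features, recording the removal order. The ranking is the reverse of
#' removal order (survivors first). The selected set is the prefix of the
#' ranking whose size minimises stratified cross-validated misclassification
#' error over the sizes visited by the recursion; ties go to the smaller
#' size. Features are standardised internally, so the result is invariant to
#' positive rescaling of any column.
#'
#' @param X Numeric matrix, samples x features, with feature colnames.
#' @param y Binary labels.
#' @param elimination_step Features removed per iteration (>= 1). If the
#'   step reaches or exceeds the number of features still active, all but the
#'   top-scoring one are removed.
#' @param k_folds Stratified CV folds for prefix-size selection.
#' @param cost SVM cost parameter (default 1).
#' @param seed Seed controlling fold assignment.
#' @return List with `ranking` (character, best first), `selected`
#'   (character prefix), `cv_error` (named per-size mean CV error).
#' @export
svm_rfe_rank <- function(X, y, elimination_step = 1, k_folds = 5, cost = 1,
                         seed = 1) {
  y <- binarize_labels(y)
  if (length(unique(y)) < 2) stop("`y` must contain both classes")
  if (elimination_step < 1) stop("`elimination_step` must be >= 1")
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0

  active <- colnames(Xs)
  removed <- character(0)
  sizes <- integer(0)
  while (length(active) > 1) {
    sizes <- c(sizes, length(active))
    sc <- svm_weight_scores(Xs[, active, drop = FALSE], y, cost)
    ord <- order(sc, decreasing = FALSE)  # worst first
    k <- min(elimination_step, length(active) - 1)
    drop_now <- active[ord[seq_len(k)]]
    removed <- c(removed, drop_now)
    active <- setdiff(active, drop_now)
  }
  sizes <- c(sizes, 1L)
  ranking <- c(active, rev(removed))

  folds <- stratified_folds(y, k_folds, seed)
  cand <- sort(unique(sizes))
  err <- vapply(cand, function(s) {
    feats <- ranking[seq_len(s)]
    mean(vapply(seq_len(k_folds), function(f) {
      tr <- folds != f
      fit <- e1071::svm(Xs[tr, feats, drop = FALSE], factor(y[tr]),
                        kernel = "linear", cost = cost, scale = FALSE)
      pred <- stats::predict(fit, Xs[!tr, feats, drop = FALSE])
      mean(as.character(pred) != as.character(y[!tr]))
    }, numeric(1)))
  }, numeric(1))
  names(err) <- cand
  best_size <- cand[which.min(err)]  # which.min takes the first, i.e. smallest
  list(ranking = ranking, selected = ranking[seq_len(best_size)],
       cv_error = err)
}

#' Intersection of two feature selections
#'
#' @param a,b Character vectors of selected feature names.
#' @return Sorted character vector `a` intersect `b`.
#' @export
intersect_selections <- function(a, b) sort(intersect(a, b))

#' Identify key biomarker genes by dual machine-learning selection
#'
#' Convenience wrapper running [lasso_select()] and [svm_rfe_rank()] on the
#' expression of a candidate gene set (e.g. the DE genes intersected with a
#' curated panel) and returning the intersection of the two selections as the
#' key biomarker genes.
#'
#' @param matrix_ An [expression_matrix].
#' @param genes Candidate gene symbols (rows of the matrix) to select from.
#' @param k_folds,seed,elimination_step,cost Passed to the two selectors.
#' @return List with `lasso` and `svmrfe` (the raw selector outputs),
#'   `key_genes`, `cv_folds`, `seed`.
#' @export
select_biomarkers <- function(matrix_, genes, k_folds = 5, seed = 1,
                              elimination_step = 1, cost = 1) {
  genes <- intersect(genes, rownames(matrix_$values))
  if (length(genes) == 0) stop("no candidate genes present in the matrix")
  X <- t(matrix_$values[genes, , drop = FALSE])
  y <- matrix_$samples$group
  las <- lasso_select(X, y, k_folds = k_folds, seed = seed)
  rfe <- svm_rfe_rank(X, y, elimination_step = elimination_step,
                      k_folds = k_folds, cost = cost, seed = seed)
  list(lasso = las, svmrfe = rfe,
       key_genes = intersect_selections(las$selected, rfe$selected),
       cv_folds = k_folds, seed = seed)
}
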