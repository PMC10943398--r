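# ROC/AUC diagnostics for single genes and for the combined biomarker panel,
# including evaluation on an independent validation cohort.

#' ROC curve and AUC for a score vector
#'
#' The curve is obtained by sweeping every distinct score as a threshold
#' (predict positive when score >= threshold), yielding non-decreasing
#' (fpr, tpr) points from (0, 0) to (1, 1). The AUC is computed by the
#' Mann-Whitney rank formulation — the probability that a random positive
#' scores above a random negative, ties counting 1/2 — which equals the
#' trapezoidal area under the curve.
#'
#' @param scores Per-sample numeric scores (higher = more case-like).
#' @param labels Binary labels (1/case = positive).
#' @return An object of class `roc_result`: list with `auc`, `curve`
#'   (data.frame `threshold`, `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  y <- binarize_labels(labels)
  if (length(scores) != length(y)) stop("lengths differ")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks for ties
  auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[y == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[y == 0] >= t), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] != 1 || curve$tpr[nrow(curve)] != 1)
    curve <- rbind(curve, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.3f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Combined-panel diagnostic score
#'
#' Scores evaluation samples with a model of the full biomarker panel fitted
#' on training samples. The default rule is an unpenalised logistic
#' regression on the panel genes, returning fitted linear predictors; if the
#' fit is unstable (perfect separation or non-convergence) a small ridge
#' penalty is used instead, so scoring never fails. The alternative rule
#' `method = "mean_z"` averages the per-gene z-scores (standardised on the
#' training samples, sign-oriented by the training case-minus-control mean
#' difference), a model-free composite.
#'
#' @param X_train,X_eval Numeric matrices, samples x genes, sharing the
#'   panel columns.
#' @param y_train Binary training labels.
#' @param genes Panel gene names (subset of both matrices' columns).
#' @param method `"logistic"` (default) or `"mean_z"`.
#' @param ridge_lambda Ridge penalty used only on unstable logistic fits.
#' @return Numeric vector of evaluation scores (one per row of `X_eval`).
#' @export
combined_panel_score <- function(X_train, y_train, X_eval, genes,
                                 method = c("logistic", "mean_z"),
                                 ridge_lambda = 1e-3) {
  method <- match.arg(method)
  if (!all(genes %in% colnames(X_train)) || !all(genes %in% colnames(X_eval)))
    stop("`genes` must be columns of both matrices")
  y <- binarize_labels(y_train)
  Xtr <- X_train[, genes, drop = FALSE]
  Xev <- X_eval[, genes, drop = FALSE]
  if (method == "mean_z") {
    mu <- colMeans(Xtr); sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    sgn <- sign(colMeans(Xtr[y == 1, , drop = FALSE]) -
                  colMeans(Xtr[y == 0, , drop = FALSE]))
    sgn[sgn == 0] <- 1
    z <- sweep(sweep(Xev, 2, mu), 2, sdv, "/")
    return(drop(z %*% sgn) / length(genes))
  }
  df <- as.data.frame(Xtr)
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = cbind(y = y, df), family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  unstable <- !fit$converged ||
    any(abs(stats::coef(fit)[-1]) > 1e3, na.rm = TRUE) ||
    anyNA(stats::coef(fit))
  if (unstable) {
    Xg <- as.matrix(Xtr); Xe <- as.matrix(Xev)
    if (ncol(Xg) == 1) {  # glmnet needs >= 2 columns; duplicate is harmless
      Xg <- cbind(Xg, Xg); Xe <- cbind(Xe, Xe)
    }
    rf <- suppressWarnings(
      glmnet::glmnet(Xg, y, family = "binomial", alpha = 0,
                     lambda = ridge_lambda, standardize = TRUE))
    beta <- as.numeric(stats::coef(rf))
    return(drop(cbind(1, Xe) %*% beta))
  }
  drop(cbind(1, as.matrix(Xev)) %*% stats::coef(fit))
}

#' Per-gene and combined-panel ROC summary
#'
#' Computes a ROC/AUC per key gene (each gene's expression as the score,
#' oriented so AUC >= 0.5 on the evaluated cohort, as conventional for
#' diagnostic markers) and for the combined panel score, optionally on an
#' independent validation cohort. By default the per-gene and combined
#' models are fit (oriented) on the evaluated cohort itself, mirroring the
#' per-cohort ROC presentation; pass a discovery cohort via `train` to reuse
#' discovery coefficients instead.
#'
#' @param matrix_ The [expression_matrix] to evaluate.
#' @param genes Key gene symbols.
#' @param train Optional [expression_matrix] used to fit the combined model
#'   (default: `matrix_` itself).
#' @param method Combined-score rule, see [combined_panel_score()].
#' @return List with `per_gene` (data.frame `gene`, `auc`), `combined` (a
#'   `roc_result`), and `roc` (named list of per-gene `roc_result`s).
#' @export
panel_roc <- function(matrix_, genes, train = NULL, method = "logistic") {
  genes <- intersect(genes, rownames(matrix_$values))
  if (length(genes) == 0) stop("no panel genes in the matrix")
  y <- matrix_$samples$group
  rocs <- lapply(genes, function(g) {
    sc <- matrix_$values[g, ]
    r <- roc_auc(sc, y)
    if (r$auc < 0.5) r <- roc_auc(-sc, y)
    r
  })
  names(rocs) <- genes
  tr <- train %||% matrix_
  comb <- combined_panel_score(t(tr$values), tr$samples$group,
                               t(matrix_$values), genes, method = method)
  list(per_gene = data.frame(gene = genes,
                             auc = vapply(rocs, `[[`, numeric(1), "auc")),
       combined = roc_auc(comb, y),
       roc = rocs)
}
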