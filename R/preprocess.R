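#' Merge expression cohorts and correct batch offsets
#'
#' Restricts all input matrices to their common genes, concatenates samples,
#' and removes additive batch effects. The default correction is a per-gene
#' location adjustment: within each batch the gene's mean is shifted to the
#' gene's grand mean, so after correction every batch has the same per-gene
#' mean while the grand mean and all within-batch contrasts are preserved.
#' `method = "combat"` instead applies the empirical-Bayes location-scale
#' adjustment of `sva::ComBat` (requires the sva package).
#'
#' @param matrices A single [expression_matrix] or a list of them. Batch
#'   labels must be distinct across inputs if sample sets overlap in naming;
#'   each matrix keeps its own batch labels.
#' @param method `"mean_center"` (default) or `"combat"`.
#' @return A merged, batch-corrected [expression_matrix] over the common
#'   genes.
#' @export
merge_and_correct <- function(matrices, method = c("mean_center", "combat")) {
  method <- match.arg(method)
  if (inherits(matrices, "expression_matrix")) matrices <- list(matrices)
  if (length(matrices) < 1) stop("need at least one expression matrix")
  common <- Reduce(intersect, lapply(matrices, function(m) rownames(m$values)))
  if (length(common) == 0) stop("no genes shared across input matrices")
  values <- do.call(cbind, lapply(matrices, function(m)
    m$values[common, , drop = FALSE]))
  samples <- do.call(rbind, lapply(matrices, function(m) {
    s <- m$samples
    s$subcluster <- s$subcluster %||% rep(NA_integer_, nrow(s))
    s[c("sample_id", "group", "batch", "subcluster")]
  }))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids across inputs")
  batch <- samples$batch
  tab <- table(batch)
  if (length(tab) > 1) {
    if (any(tab < 2)) stop("every batch needs at least 2 samples")
    if (method == "combat") {
      if (!requireNamespace("sva", quietly = TRUE))
        stop("method='combat' requires the sva package")
      values <- sva::ComBat(dat = values, batch = batch)
    } else {
      grand <- rowMeans(values)
      for (b in names(tab)) {
        idx <- batch == b
        values[, idx] <- values[, idx] -
          rowMeans(values[, idx, drop = FALSE]) + grand
      }
    }
  }
  expression_matrix(values, group = samples$group, batch = batch,
                    subcluster = samples$subcluster)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: p-values are sorted, `p_(i)` is
#' multiplied by `n/i`, cumulative minima are taken from the largest rank
#' down, results are capped at 1 and returned in the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# Method-of-moments fit of a scaled-inverse-chi-square prior to per-gene
# sample variances s2 with common df d, working on log(s2). Returns
# list(d0, s0_sq); d0 may be Inf (all variances shrunk to s0_sq).
fit_variance_prior <- function(s2, d) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2 || d <= 0) return(list(d0 = 0, s0_sq = NA_real_))
  z <- log(s2)
  ev <- stats::var(z) - trigamma(d / 2)
  bias_d <- digamma(d / 2) - log(d / 2)
  if (ev <= 1e-8) {
    return(list(d0 = Inf, s0_sq = exp(mean(z) - bias_d)))
  }
  # solve trigamma(d0/2) = ev for d0; trigamma is strictly decreasing
  f <- function(y) trigamma(y) - ev
  root <- stats::uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-12)$root
  d0 <- 2 * root
  s0_sq <- exp(mean(z) - bias_d + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Per-gene differential expression between case and control
#'
#' Computes, for every gene, the log2 fold change (case minus control, data
#' already log2), a two-sample t statistic with Welch-Satterthwaite degrees
#' of freedom, a two-sided p-value, and the Benjamini-Hochberg adjusted
#' p-value. A gene is flagged DE when its linear fold change exceeds
#' `fc_threshold` in either direction (`|log2fc| > log2(fc_threshold)`) and
#' its adjusted p-value (raw p-value if `use_adjusted = FALSE`) is below
#' `alpha`.
#'
#' With `moderation = TRUE` (the default) gene-wise group variances are
#' shrunk toward a common prior fitted across all genes: a scaled
#' inverse-chi-square prior `(d0, s0^2)` is estimated by method of moments on
#' the log pooled variances, and each group variance becomes
#' `(d0*s0^2 + d_i*s_i^2) / (d0 + d_i)` with the group df inflated to
#' `d_i + d0` in the Satterthwaite formula. With prior df `d0 = 0` the
#' statistic reduces exactly to the unmoderated Welch t.
#'
#' @param matrix_ An [expression_matrix] with at least 2 samples per group.
#' @param fc_threshold Linear fold-change gate (> 1); default 1.2.
#' @param alpha Significance gate on the (adjusted) p-value; default 0.05.
#' @param moderation Shrink variances toward the common prior (default TRUE).
#' @param use_adjusted Gate on the BH-adjusted p (default) or the raw p.
#' @param prior Optional list `(d0, s0_sq)` overriding the fitted variance
#'   prior (expert use; `d0 = 0` reproduces the unmoderated statistic
#'   exactly).
#' @return A data.frame with columns `gene`, `log2fc`, `t_stat`, `p_raw`,
#'   `p_adj`, `is_de`, `direction`.
#' @export
differential_expression <- function(matrix_, fc_threshold = 1.2, alpha = 0.05,
                                    moderation = TRUE, use_adjusted = TRUE,
                                    prior = NULL) {
  if (fc_threshold <= 1) stop("`fc_threshold` must exceed 1")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  grp <- matrix_$samples$group
  i1 <- grp == "case"; i2 <- grp == "control"
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per group")
  X1 <- matrix_$values[, i1, drop = FALSE]
  X2 <- matrix_$values[, i2, drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- apply(X1, 1, stats::var); v2 <- apply(X2, 1, stats::var)
  d1 <- n1 - 1; d2 <- n2 - 1
  lfc <- m1 - m2

  d0 <- 0; s0 <- NA_real_
  if (moderation) {
    if (is.null(prior)) {
      pooled <- (d1 * v1 + d2 * v2) / (d1 + d2)
      prior <- fit_variance_prior(pooled, d1 + d2)
    }
    d0 <- prior$d0; s0 <- prior$s0_sq
  }
  if (is.infinite(d0)) {
    v1s <- rep(s0, length(v1)); v2s <- rep(s0, length(v2))
    df1 <- Inf; df2 <- Inf
  } else if (d0 > 0) {
    v1s <- (d0 * s0 + d1 * v1) / (d0 + d1)
    v2s <- (d0 * s0 + d2 * v2) / (d0 + d2)
    df1 <- d1 + d0; df2 <- d2 + d0
  } else {
    v1s <- v1; v2s <- v2
    df1 <- d1; df2 <- d2
  }
  se2 <- v1s / n1 + v2s / n2
  tt <- ifelse(se2 > 0, lfc / sqrt(se2),
               ifelse(lfc == 0, 0, sign(lfc) * Inf))
  df <- if (is.infinite(df1)) rep(Inf, length(tt)) else
    se2^2 / ((v1s / n1)^2 / df1 + (v2s / n2)^2 / df2)
  df[!is.finite(df) & is.finite(tt) & tt == 0] <- 1  # zero-variance genes
  p <- ifelse(is.infinite(tt), 0,
              ifelse(se2 > 0, 2 * stats::pt(-abs(tt), df), 1))
  p_adj <- bh_adjust(p)
  gate_p <- if (use_adjusted) p_adj else p
  is_de <- (abs(lfc) > log2(fc_threshold)) & (gate_p < alpha)
  data.frame(gene = rownames(matrix_$values), log2fc = lfc, t_stat = tt,
             p_raw = p, p_adj = p_adj, is_de = is_de,
             direction = ifelse(lfc >= 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect differentially expressed genes with a curated gene panel
#'
#' Returns the genes flagged DE that are also members of the curated panel
#' (e.g. the differentially expressed cuproptosis-related genes, the DECuGs,
#' when the panel is the curated cuproptosis gene list).
#'
#' @param de_results Data.frame from [differential_expression()].
#' @param panel Character vector of panel gene symbols.
#' @return Character vector (sorted) of panel genes flagged DE; possibly empty.
#' @export
intersect_panel <- function(de_results, panel) {
  sort(intersect(de_results$gene[de_results$is_de], panel))
}
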