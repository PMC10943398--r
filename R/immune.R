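# Immune-fraction analyses: deconvolution-confidence filtering, Spearman
# gene-fraction correlation, and rank-sum group contrasts. The fractions
# themselves come from an external deconvolution tool (e.g. CIBERSORT) or
# from simulate_fractions(); deconvolution is consumed, never re-implemented.

fraction_columns <- function(fractions) {
  setdiff(names(fractions), "deconv_p")
}

#' Filter samples by deconvolution confidence
#'
#' Keeps the samples whose per-sample deconvolution p-value is below `alpha`
#' (the conventional gate on CIBERSORT output).
#'
#' @param fractions Data.frame of cell-type fractions with a `deconv_p`
#'   column and sample rownames.
#' @param alpha Threshold on the deconvolution p-value (default 0.05).
#' @return The filtered data.frame (possibly zero rows).
#' @export
filter_samples <- function(fractions, alpha = 0.05) {
  if (!"deconv_p" %in% names(fractions))
    stop("`fractions` must contain a `deconv_p` column")
  fractions[fractions$deconv_p < alpha, , drop = FALSE]
}

# Spearman rho with a two-sided p from the t approximation
# t = rho * sqrt((n-2)/(1-rho^2)). Returns c(rho, p); NA for constant input.
spearman_rho_p <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(c(NA_real_, NA_real_))
  rho <- stats::cor(x, y, method = "spearman")
  n <- length(x)
  if (abs(rho) >= 1) return(c(rho, 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho, 2 * stats::pt(-abs(tstat), n - 2))
}

#' Spearman correlation between a gene and every immune cell type
#'
#' Rank correlation (ties get average ranks) of a gene's per-sample
#' expression against each cell-type fraction column, with a two-sided
#' p-value from the t approximation on rho. Cell types with a constant
#' fraction column (or a constant gene vector) are flagged with `NA` and
#' excluded from the extreme-pair attributes.
#'
#' @param gene_values Named or ordered numeric vector, one value per row of
#'   `fractions`.
#' @param fractions Data.frame of cell-type fractions (a `deconv_p` column,
#'   if present, is ignored).
#' @return Data.frame with columns `cell_type`, `rho`, `p`; attributes
#'   `max_pair` and `min_pair` give the cell types with the largest and
#'   smallest defined rho.
#' @export
spearman_correlate <- function(gene_values, fractions) {
  cols <- fraction_columns(fractions)
  if (length(gene_values) != nrow(fractions))
    stop("`gene_values` must match the rows of `fractions`")
  if (length(gene_values) < 4) stop("need at least 4 paired observations")
  res <- t(vapply(cols, function(ct) spearman_rho_p(gene_values, fractions[[ct]]),
                  numeric(2)))
  out <- data.frame(cell_type = cols, rho = res[, 1], p = res[, 2],
                    row.names = NULL, stringsAsFactors = FALSE)
  ok <- !is.na(out$rho)
  attr(out, "max_pair") <- if (any(ok)) out$cell_type[ok][which.max(out$rho[ok])] else NA
  attr(out, "min_pair") <- if (any(ok)) out$cell_type[ok][which.min(out$rho[ok])] else NA
  out
}

#' Gene-by-cell-type Spearman correlation table
#'
#' Correlates each listed gene with every cell-type fraction, adjusting
#' p-values by Benjamini-Hochberg within each gene. By default only case
#' samples are used, matching the framing of biomarker-immunocyte
#' correlations within the disease cohort; `cohort = "all"` pools cases and
#' controls.
#'
#' @param matrix_ An [expression_matrix].
#' @param genes Gene symbols to correlate.
#' @param fractions Fraction data.frame with rownames matching sample ids (a
#'   `deconv_p` column is ignored; filter first with [filter_samples()]).
#' @param cohort `"case"` (default) or `"all"`.
#' @return Data.frame with columns `gene`, `cell_type`, `rho`, `p`, `p_adj`.
#' @export
gene_cell_correlations <- function(matrix_, genes, fractions,
                                   cohort = c("case", "all")) {
  cohort <- match.arg(cohort)
  keep <- if (cohort == "case") matrix_$samples$group == "case" else
    rep(TRUE, nrow(matrix_$samples))
  ids <- intersect(matrix_$samples$sample_id[keep], rownames(fractions))
  if (length(ids) < 4) stop("fewer than 4 samples shared with `fractions`")
  fr <- fractions[ids, , drop = FALSE]
  do.call(rbind, lapply(genes, function(g) {
    gv <- matrix_$values[g, ids]
    tab <- spearman_correlate(gv, fr)
    ok <- !is.na(tab$p)
    tab$p_adj <- NA_real_
    tab$p_adj[ok] <- bh_adjust(tab$p[ok])
    cbind(gene = g, tab)
  }))
}

#' Wilcoxon rank-sum contrast of cell-type fractions between two groups
#'
#' Two-sided rank-sum test per cell type. The exact null distribution is
#' enumerated when both groups have at most 10 samples and there are no
#' ties; otherwise the normal approximation with tie-corrected variance is
#' used. P-values are BH-adjusted across cell types.
#'
#' @param fractions Data.frame of cell-type fractions (a `deconv_p` column is
#'   ignored).
#' @param labels Binary per-sample labels aligned with the rows.
#' @return Data.frame with columns `cell_type`, `statistic` (rank-sum W of
#'   the first group), `p`, `p_adj`.
#' @export
compare_groups <- function(fractions, labels) {
  cols <- fraction_columns(fractions)
  lab <- binarize_labels(labels)
  if (length(lab) != nrow(fractions))
    stop("`labels` must have one entry per row of `fractions`")
  if (length(unique(lab)) < 2) stop("both groups must be non-empty")
  res <- t(vapply(cols, function(ct) {
    a <- fractions[[ct]][lab == 1]
    b <- fractions[[ct]][lab == 0]
    exact <- length(a) <= 10 && length(b) <= 10 &&
      !any(duplicated(c(a, b)))
    wt <- stats::wilcox.test(a, b, exact = exact, correct = FALSE)
    c(unname(wt$statistic), wt$p.value)
  }, numeric(2)))
  data.frame(cell_type = cols, statistic = res[, 1], p = res[, 2],
             p_adj = bh_adjust(res[, 2]), row.names = NULL,
             stringsAsFactors = FALSE)
}
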