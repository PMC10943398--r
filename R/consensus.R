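# Resampling consensus clustering of case samples on the key-gene
# expression submatrix, with k chosen from the behaviour of the consensus
# CDF (delta-area elbow), plus the subcluster contrast and PCA display.

# Pairwise sample distance for the inner clustering step. "pearson" is
# 1 - Pearson correlation between sample profiles (undefined correlations,
# from constant profiles, are treated as 0, i.e. distance 1).
sample_dist <- function(X, distance) {
  if (distance == "euclidean") return(stats::dist(X))
  cc <- suppressWarnings(stats::cor(t(X)))
  cc[!is.finite(cc)] <- 0
  stats::as.dist(1 - cc)
}

# Exact area under the empirical CDF of consensus values over [0, 1].
cdf_area <- function(vals) {
  v <- sort(vals)
  m <- length(v)
  if (m == 0) return(0)
  # integral of the step ECDF from 0 to 1
  sum(diff(c(v, 1)) * seq_len(m) / m)
}

# Proportion of ambiguous clustering: fraction of pairwise consensus values
# falling strictly inside (lo, hi). 0 means perfectly crisp consensus.
pac_score <- function(vals, lo = 0.1, hi = 0.9) {
  mean(vals > lo & vals < hi)
}

#' Resampling consensus clustering
#'
#' For each candidate number of clusters k, repeatedly subsamples a fraction
#' `p_item` of the samples, clusters each subsample by agglomerative
#' hierarchical clustering, and records for every sample pair the fraction
#' of co-sampled runs in which the pair co-clustered (the consensus index;
#' pairs never co-sampled get consensus 0). The empirical CDF of the
#' upper-triangle consensus values is summarised two ways: by its area (the
#' delta-area of k being the relative increase of that area over k-1) and by
#' the proportion of ambiguous clustering (PAC), the fraction of consensus
#' values falling strictly inside `pac_bounds` — the fluctuating middle of
#' the CDF. The default `k_rule = "pac"` chooses the k whose consensus CDF
#' fluctuates least (minimum PAC, ties to the smaller k); `k_rule = "delta"`
#' instead takes the largest k whose delta-area exceeds `delta_threshold`
#' (the smallest candidate if none does). Final labels come from
#' hierarchical clustering of `1 - consensus` at the chosen k.
#'
#' @param X Numeric matrix, samples x genes (e.g. the transposed key-gene
#'   submatrix).
#' @param k_range Candidate cluster numbers, all >= 2 (default 2:6).
#' @param H Number of resampling iterations (default 1000; a warning is
#'   logged below 10).
#' @param p_item Fraction of samples drawn per iteration, in (0, 1].
#' @param distance `"pearson"` (1 - correlation, default) or `"euclidean"`.
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param k_rule `"pac"` (default) or `"delta"`, see above.
#' @param delta_threshold Delta-area elbow threshold for `k_rule = "delta"`
#'   (default 0.1).
#' @param pac_bounds Lower and upper consensus bounds defining ambiguity for
#'   the PAC score (default `c(0.1, 0.9)`).
#' @param k_override Optional integer forcing the chosen k.
#' @param seed Integer seed; the full resampling loop is deterministic given
#'   the seed.
#' @return An object of class `consensus_result`: list with `consensus`
#'   (named list of per-k consensus matrices), `cdf` (per-k sorted consensus
#'   values), `area`, `delta_area`, `pac`, `chosen_k`, `labels` (named
#'   cluster ids at the chosen k), and `params`.
#' @export
consensus_cluster <- function(X, k_range = 2:6, H = 1000, p_item = 0.8,
                              distance = c("pearson", "euclidean"),
                              linkage = "average",
                              k_rule = c("pac", "delta"),
                              delta_threshold = 0.1,
                              pac_bounds = c(0.1, 0.9),
                              k_override = NULL, seed = 1) {
  distance <- match.arg(distance)
  k_rule <- match.arg(k_rule)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2)) stop("all k in `k_range` must be >= 2")
  if (p_item <= 0 || p_item > 1) stop("`p_item` must be in (0, 1]")
  if (H < 10) warning("H < 10 resampling iterations; consensus unstable")
  n <- nrow(X)
  if (n < max(k_range) * 2)
    stop("need at least 2*max(k_range) samples")
  ids <- rownames(X) %||% sprintf("S%d", seq_len(n))
  m <- ceiling(p_item * n)

  co_sample <- matrix(0, n, n)
  co_cluster <- stats::setNames(
    lapply(k_range, function(k) matrix(0, n, n)), as.character(k_range))
  withr::with_seed(seed, {
    for (h in seq_len(H)) {
      idx <- sort(sample.int(n, m))
      hc <- stats::hclust(sample_dist(X[idx, , drop = FALSE], distance),
                          method = linkage)
      co_sample[idx, idx] <- co_sample[idx, idx] + 1
      for (k in k_range) {
        cl <- stats::cutree(hc, k)
        same <- outer(cl, cl, "==")
        kk <- as.character(k)
        co_cluster[[kk]][idx, idx] <- co_cluster[[kk]][idx, idx] + same
      }
    }
  })
  consensus <- lapply(co_cluster, function(cc) {
    cons <- ifelse(co_sample > 0, cc / co_sample, 0)
    diag(cons) <- 1
    dimnames(cons) <- list(ids, ids)
    cons
  })
  upper_vals <- lapply(consensus, function(cm) sort(cm[upper.tri(cm)]))
  area <- vapply(upper_vals, cdf_area, numeric(1))
  delta <- c(NA_real_, diff(area) / utils::head(area, -1))
  names(delta) <- names(area)
  pac <- vapply(upper_vals, pac_score, numeric(1),
                lo = pac_bounds[1], hi = pac_bounds[2])

  if (!is.null(k_override)) {
    chosen <- as.integer(k_override)
    if (!chosen %in% k_range) stop("`k_override` must be in `k_range`")
  } else if (k_rule == "pac") {
    chosen <- k_range[which.min(pac)]  # which.min -> first, i.e. smallest k
  } else {
    above <- which(!is.na(delta) & delta > delta_threshold)
    chosen <- if (length(above) > 0) k_range[max(above)] else k_range[1]
  }
  cm <- consensus[[as.character(chosen)]]
  hc_final <- stats::hclust(stats::as.dist(1 - cm), method = linkage)
  labels <- stats::setNames(stats::cutree(hc_final, chosen), ids)

  structure(list(consensus = consensus, cdf = upper_vals, area = area,
                 delta_area = delta, pac = pac, chosen_k = chosen,
                 labels = labels,
                 params = list(H = H, p_item = p_item, linkage = linkage,
                               distance = distance, seed = seed,
                               k_rule = k_rule,
                               delta_threshold = delta_threshold,
                               pac_bounds = pac_bounds)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result over k = {%s}: chosen k = %d\n",
              paste(names(x$area), collapse = ", "), x$chosen_k))
  cat("  cluster sizes:", paste(table(x$labels), collapse = "/"), "\n")
  cat("  CDF area:", paste(sprintf("%s=%.3f", names(x$area), x$area),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Per-gene contrast between two consensus subclusters
#'
#' Wilcoxon rank-sum test of each listed gene's expression between the two
#' subclusters, BH-adjusted across genes. Exactly two clusters are required
#' (pairwise contrasts over more clusters are out of scope).
#'
#' @param matrix_ An [expression_matrix] (typically case samples only).
#' @param labels Named cluster labels covering the matrix's samples.
#' @param genes Gene symbols to test.
#' @return Data.frame with columns `gene`, `statistic`, `p`, `p_adj`.
#' @export
subcluster_contrast <- function(matrix_, labels, genes) {
  ids <- intersect(matrix_$samples$sample_id, names(labels))
  lab <- labels[ids]
  if (length(unique(lab)) != 2) stop("exactly 2 clusters required")
  expr <- matrix_$values[genes, ids, drop = FALSE]
  fr <- as.data.frame(t(expr))
  res <- compare_groups(fr, as.integer(lab == unique(lab)[1]))
  data.frame(gene = res$cell_type, statistic = res$statistic, p = res$p,
             p_adj = res$p_adj, stringsAsFactors = FALSE)
}

#' Principal-component embedding of samples
#'
#' Projects samples onto the top right singular directions of the
#' column-centred data (no scaling), for displaying subcluster separation.
#'
#' @param X Numeric matrix, samples x genes.
#' @param n_components Number of components (1 <= n <= min(dim)).
#' @return Matrix samples x components of coordinates; attribute
#'   `variance` holds the per-component variances (non-increasing).
#' @export
pca_embed <- function(X, n_components = 2) {
  if (n_components <= 0) stop("`n_components` must be positive")
  if (n_components > min(dim(X))) stop("`n_components` exceeds data rank bound")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  coords <- pc$x[, seq_len(n_components), drop = FALSE]
  attr(coords, "variance") <- pc$sdev[seq_len(n_components)]^2
  coords
}
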