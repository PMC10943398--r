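#' Expression matrix with sample metadata
#'
#' Container for a log2-scale gene expression matrix (genes in rows, samples
#' in columns) together with per-sample group and batch labels. This is the
#' common currency of the pipeline: the synthetic-data generator produces it,
#' batch correction and differential expression consume it.
#'
#' @param values Numeric matrix, genes x samples, log2 scale. Must have
#'   unique, non-empty rownames (gene symbols) and colnames (sample ids), and
#'   all entries finite.
#' @param group Character or factor of length `ncol(values)` with levels
#'   `"case"` and/or `"control"`.
#' @param batch Vector of length `ncol(values)` with one batch label per
#'   sample. Defaults to a single batch.
#' @param subcluster Optional per-sample subcluster label (`NA` allowed for
#'   control samples).
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (the matrix) and `samples` (a data.frame with columns
#'   `sample_id`, `group`, `batch` and optionally `subcluster`).
#' @export
expression_matrix <- function(values, group, batch = rep("b1", ncol(values)),
                              subcluster = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  if (!all(is.finite(values)))
    stop("all expression values must be finite")
  group <- as.character(group)
  if (length(group) != ncol(values))
    stop("`group` must have one label per sample")
  if (!all(group %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")
  batch <- as.character(batch)
  if (length(batch) != ncol(values))
    stop("`batch` must have one label per sample")
  samples <- data.frame(sample_id = colnames(values), group = group,
                        batch = batch, stringsAsFactors = FALSE)
  if (!is.null(subcluster)) {
    if (length(subcluster) != ncol(values))
      stop("`subcluster` must have one label per sample")
    samples$subcluster <- subcluster
  }
  structure(list(values = values, samples = samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", names(table(x$samples$group)),
                            table(x$samples$group)), collapse = ", ")))
  cat(sprintf("  batches: %s\n",
              paste(unique(x$samples$batch), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# Subset an expression_matrix by sample index, keeping metadata in sync.
subset_samples <- function(em, idx) {
  sub <- em$samples[idx, , drop = FALSE]
  expression_matrix(em$values[, idx, drop = FALSE],
                    group = sub$group, batch = sub$batch,
                    subcluster = sub$subcluster)
}
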