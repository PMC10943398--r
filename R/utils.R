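# Internal helpers shared across modules.

# Stratified fold assignment: every class is spread as evenly as possible
# across folds. Returns an integer vector of fold ids in 1..k.
stratified_folds <- function(y, k, seed) {
  y <- as.integer(as.factor(y))
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Coerce labels to 0/1 with "case"/second factor level = 1.
binarize_labels <- function(y) {
  if (is.numeric(y) && all(y %in% c(0, 1))) return(as.integer(y))
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    if (all(y %in% c("case", "control")))
      return(as.integer(y == "case"))
    f <- factor(y)
    if (nlevels(f) != 2) stop("labels must be binary")
    return(as.integer(f) - 1L)
  }
  stop("labels must be binary (0/1, two-level factor, or case/control)")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
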