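make_em <- function(values, group, batch = rep("b1", ncol(values))) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  expression_matrix(values, group = group, batch = batch)
}

test_that("batch correction equalises batch means and preserves grand means", {
  withr::with_seed(1, {
    base <- matrix(stats::rnorm(20 * 6, 6, 1), 20, 6)
  })
  delta <- stats::rnorm(20, 0, 2)
  m1 <- make_em(base, rep(c("case", "control"), 3), rep("b1", 6))
  m2 <- make_em(base + delta, rep(c("case", "control"), 3), rep("b2", 6))
  colnames(m2$values) <- sprintf("t%d", 1:6)
  m2$samples$sample_id <- colnames(m2$values)
  merged <- merge_and_correct(list(m1, m2))
  for (b in c("b1", "b2")) {
    bm <- rowMeans(merged$values[, merged$samples$batch == b])
    expect_true(all(abs(bm - rowMeans(merged$values)) < 1e-8))
  }
  grand_before <- rowMeans(cbind(base, base + delta))
  expect_true(all(abs(rowMeans(merged$values) - grand_before) < 1e-8))
  # within-batch contrasts untouched up to the removed offset
  corr1 <- merged$values[, merged$samples$batch == "b1"]
  expect_true(all(abs(sweep(corr1, 1, rowMeans(corr1)) -
                        sweep(base, 1, rowMeans(base))) < 1e-8))
})

test_that("merging degenerate inputs behaves per contract", {
  m <- make_em(matrix(1:12 + 0, 3, 4), rep(c("case", "control"), 2))
  out <- merge_and_correct(m)
  expect_identical(out$values, m$values)

  m2 <- make_em(matrix(1:12 + 0, 3, 4), rep(c("case", "control"), 2))
  rownames(m2$values) <- c("x1", "x2", "x3")
  colnames(m2$values) <- sprintf("t%d", 1:4)
  m2$samples$sample_id <- colnames(m2$values)
  expect_error(merge_and_correct(list(m, m2)), "no genes shared")

  m3 <- make_em(matrix(1:6 + 0, 3, 2), c("case", "control"), c("bA", "bB"))
  expect_error(merge_and_correct(m3), "at least 2 samples")
})

test_that("unmoderated statistics match the hand-computed Welch t", {
  em <- make_em(matrix(c(1, 2, 3, 3, 4, 5), nrow = 1),
                rep(c("case", "control"), each = 3))
  de <- differential_expression(em, moderation = FALSE)
  expect_equal(de$t_stat, -2.449, tolerance = 1e-3)
  expect_equal(de$log2fc, -2)
  expect_equal(de$p_raw, 2 * stats::pt(-abs(-2.449490), 4), tolerance = 1e-4)
  expect_equal(de$p_raw, 0.0705, tolerance = 1e-3)
  expect_identical(de$direction, "down")
})

test_that("identical groups give t = 0, p = 1, not DE", {
  vals <- matrix(rep(c(1, 2, 3), 2), nrow = 1)
  em <- make_em(vals, rep(c("case", "control"), each = 3))
  for (mod in c(TRUE, FALSE)) {
    de <- differential_expression(em, moderation = mod)
    expect_identical(de$t_stat, 0)
    expect_identical(de$p_raw, 1)
    expect_false(de$is_de)
  }
  # zero variance in both groups, equal means
  em0 <- make_em(matrix(2, 1, 6), rep(c("case", "control"), each = 3))
  de0 <- differential_expression(em0, moderation = FALSE)
  expect_identical(de0$t_stat, 0)
  expect_identical(de0$p_raw, 1)
})

test_that("DE gate combines the fold-change and adjusted-p thresholds", {
  withr::with_seed(2, {
    n <- 40
    vals <- rbind(big = c(stats::rnorm(n, 8, 0.1), stats::rnorm(n, 7, 0.1)),
                  small = c(stats::rnorm(n, 8, 0.05), stats::rnorm(n, 7.9, 0.05)),
                  null = stats::rnorm(2 * n, 6, 0.1))
  })
  em <- make_em(vals, rep(c("case", "control"), each = n))
  de <- differential_expression(em)
  expect_true(de$is_de[de$gene == "big"])       # |lfc|~1, tiny p
  expect_false(de$is_de[de$gene == "small"])    # significant but |FC| < 1.2
  expect_false(de$is_de[de$gene == "null"])
  expect_true(abs(de$log2fc[de$gene == "small"]) < log2(1.2))
  expect_true(de$p_adj[de$gene == "small"] < 0.05)
})

test_that("moderation with zero prior weight equals the unmoderated t", {
  withr::with_seed(3, {
    vals <- matrix(stats::rnorm(200 * 12, 5, 1), 200, 12)
  })
  em <- make_em(vals, rep(c("case", "control"), each = 6))
  un <- differential_expression(em, moderation = FALSE)
  # Welch oracle via t.test
  oracle <- apply(vals, 1, function(v)
    stats::t.test(v[1:6], v[7:12])$statistic)
  expect_equal(un$t_stat, unname(oracle), tolerance = 1e-12)
  # zero-weight prior reduces exactly to the unmoderated statistic
  z <- differential_expression(em, moderation = TRUE,
                               prior = list(d0 = 0, s0_sq = 1))
  expect_equal(z$t_stat, un$t_stat, tolerance = 1e-12)
  expect_equal(z$p_raw, un$p_raw, tolerance = 1e-12)
  # the fitted prior shrinks but preserves the ordering of evidence
  mo <- differential_expression(em, moderation = TRUE)
  expect_true(stats::cor(mo$t_stat, un$t_stat) > 0.95)
})

test_that("BH adjustment matches the step-up definition and is order-safe", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  withr::with_seed(4, {
    for (i in 1:50) {
      p <- stats::runif(sample(1:50, 1))
      expect_equal(bh_adjust(p), bh_bruteforce(p), tolerance = 1e-12)
      perm <- sample(length(p))
      expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
    }
  })
})

test_that("panel intersection returns the DE genes within the panel", {
  de <- data.frame(gene = c("A", "B", "C", "D"),
                   is_de = c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(intersect_panel(de, c("B", "C", "E")), c("B", "C"))
  expect_identical(intersect_panel(de, c("X", "Y")), character(0))
  expect_identical(intersect_panel(de, c("A", "B", "C")), c("A", "B", "C"))
})
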