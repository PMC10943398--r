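test_that("simulated cohorts are reproducible and internally consistent", {
  a <- simulate_cohort(10, 10, 100, seed = 42)
  b <- simulate_cohort(10, 10, 100, seed = 42)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(10, 10, 100, seed = 43)
  expect_false(identical(a$expr$values, c2$expr$values))

  # truth-table set invariants over random argument draws
  withr::with_seed(7, {
    for (i in 1:25) {
      args <- list(n_case = sample(2:30, 1), n_control = sample(2:30, 1),
                   n_genes = sample(10:200, 1),
                   de_fraction = stats::runif(1, 0, 0.5),
                   panel_size = sample(1:40, 1), key_size = sample(0:8, 1),
                   batch_count = sample(1:3, 1), seed = i)
      sim <- do.call(simulate_cohort, args)
      tr <- sim$truth
      expect_true(all(tr$key_genes %in% tr$panel_genes))
      expect_true(all(tr$key_genes %in% tr$de_genes))
      expect_setequal(names(tr$effect_sizes), tr$de_genes)
      expect_setequal(names(tr$subcluster_labels),
                      sim$expr$samples$sample_id[sim$expr$samples$group == "case"])
      expect_true(all(tr$subcluster_labels %in% 1:2))
      expect_length(tr$batch_labels, ncol(sim$expr$values))
    }
  })
})

test_that("de_fraction = 0 plants nothing and invalid arguments error", {
  sim <- simulate_cohort(5, 5, 50, de_fraction = 0, seed = 1)
  expect_length(sim$truth$de_genes, 0)
  expect_length(sim$truth$key_genes, 0)
  expect_error(simulate_cohort(1, 5, 50), "2 samples")
  expect_error(simulate_cohort(5, 5, 5), "n_genes")
  expect_error(simulate_cohort(5, 5, 50, noise_sd = 0), "noise_sd")
})

test_that("planted DE genes are recovered by the DE stage", {
  sim <- simulate_cohort(30, 30, 1000, de_fraction = 0.05, lfc_mean = 1,
                         noise_sd = 0.5, seed = 11)
  de <- differential_expression(merge_and_correct(sim$expr))
  sens <- mean(sim$truth$de_genes %in% de$gene[de$is_de])
  expect_gte(sens, 0.9)
})

test_that("fraction rows lie on the simplex with valid p-values", {
  fr <- simulate_fractions(50, n_celltypes = 22, seed = 3)
  vals <- as.matrix(fr[, setdiff(names(fr), "deconv_p")])
  expect_true(all(abs(rowSums(vals) - 1) < 1e-9))
  expect_true(all(vals >= 0))
  expect_true(all(fr$deconv_p >= 0 & fr$deconv_p <= 1))
  expect_error(simulate_fractions(10, concentration = 0), "concentration")
  expect_error(simulate_fractions(10, n_celltypes = 1), "n_celltypes")
})

test_that("fraction-gene link strength controls the planted correlation", {
  null_rho <- vapply(1:20, function(s) {
    g <- withr::with_seed(100 + s, stats::rnorm(200))
    fr <- simulate_fractions(200, linked_gene_values = g,
                             link_strength = 0, seed = s)
    spearman_correlate(g, fr)$rho[1]
  }, numeric(1))
  expect_true(all(abs(null_rho) < 0.2))

  linked <- vapply(1:20, function(s) {
    g <- withr::with_seed(200 + s, stats::rnorm(200))
    fr <- simulate_fractions(200, linked_gene_values = g,
                             link_strength = 0.8, seed = s)
    tab <- spearman_correlate(g, fr)
    c(tab$rho[1], tab$p[1])
  }, numeric(2))
  expect_true(all(linked[1, ] > 0.4))
  expect_true(all(linked[2, ] < 0.01))
})

test_that("interaction tables wire planted pairs and respect bounds", {
  si <- simulate_interactions(50, 10, 10, planted_pairs = 3,
                              shared_per_planted = 10,
                              background_rate = 0, seed = 5)
  for (i in 1:3) {
    mset <- si$mrna_mirna$mirna_id[si$mrna_mirna$target_id ==
                                     si$truth$planted_pairs$mrna[i]]
    lset <- si$lncrna_mirna$mirna_id[si$lncrna_mirna$target_id ==
                                       si$truth$planted_pairs$lncrna[i]]
    expect_gte(length(intersect(mset, lset)), 10)
  }
  expect_identical(si$truth$mirna_universe_size,
                   length(unique(c(si$mrna_mirna$mirna_id,
                                   si$lncrna_mirna$mirna_id))))

  none <- simulate_interactions(50, 10, 10, planted_pairs = 0,
                                shared_per_planted = 0,
                                background_rate = 0, seed = 5)
  expect_identical(nrow(none$mrna_mirna), 0L)
  expect_identical(nrow(none$lncrna_mirna), 0L)
  expect_error(simulate_interactions(10, 5, 5, 1, shared_per_planted = 11),
               "shared_per_planted")
})

test_that("fully shared planted pairs reach hypergeometric p of zero", {
  si <- simulate_interactions(6, 3, 3, planted_pairs = 1,
                              shared_per_planted = 6,
                              background_rate = 0, seed = 2)
  pr <- si$truth$planted_pairs
  mset <- unique(si$mrna_mirna$mirna_id[si$mrna_mirna$target_id == pr$mrna])
  lset <- unique(si$lncrna_mirna$mirna_id[si$lncrna_mirna$target_id == pr$lncrna])
  N <- si$truth$mirna_universe_size
  x <- length(intersect(mset, lset))
  expect_identical(x, min(length(mset), length(lset)))
  expect_identical(hypergeom_competing_test(N, length(mset), length(lset), x), 0)
})
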