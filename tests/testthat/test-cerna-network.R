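test_that("hypergeometric tail matches brute-force pmf summation", {
  for (N in c(5, 8, 12)) {
    for (n in 0:N) for (m in 0:N) for (x in 0:min(n, m)) {
      expect_equal(hypergeom_competing_test(N, n, m, x, "as_printed"),
                   hyper_tail_bruteforce(N, n, m, x, "as_printed"),
                   tolerance = 1e-12)
      expect_equal(hypergeom_competing_test(N, n, m, x, "at_least_x"),
                   hyper_tail_bruteforce(N, n, m, x, "at_least_x"),
                   tolerance = 1e-12)
    }
  }
})

test_that("worked hypergeometric values and tail ordering hold", {
  expect_equal(hypergeom_competing_test(10, 3, 4, 2, "as_printed"), 4 / 120,
               tolerance = 1e-12)
  expect_equal(hypergeom_competing_test(10, 3, 4, 2, "at_least_x"), 40 / 120,
               tolerance = 1e-12)
  expect_identical(hypergeom_competing_test(10, 3, 4, 3, "as_printed"), 0)
  # strictly-greater tail is never larger than the at-least tail
  withr::with_seed(12, {
    for (i in 1:50) {
      N <- sample(4:40, 1); n <- sample(0:N, 1); m <- sample(0:N, 1)
      x <- sample(0:min(n, m), 1)
      expect_lte(hypergeom_competing_test(N, n, m, x, "as_printed"),
                 hypergeom_competing_test(N, n, m, x, "at_least_x"))
    }
  })
  expect_error(hypergeom_competing_test(10, 3, 4, -1), "non-negative")
  expect_error(hypergeom_competing_test(10, 11, 4, 2), "exceed")
})

test_that("pearson co-expression matches hand computations", {
  expect_equal(coexpression_pcc(c(1, 2, 3, 4), c(1, 2, 3, 4))$pcc, 1)
  expect_equal(coexpression_pcc(1:5, -2 * (1:5) + 7)$pcc, -1)
  # 3-point worked value padded to meet the minimum-pairs contract is not
  # possible; check the formula directly on 4 points against cor.test
  withr::with_seed(13, {
    for (i in 1:50) {
      n <- sample(4:20, 1)
      x <- stats::rnorm(n); y <- stats::rnorm(n)
      got <- coexpression_pcc(x, y)
      ct <- stats::cor.test(x, y)
      expect_equal(got$pcc, unname(ct$estimate), tolerance = 1e-12)
      expect_equal(got$p, ct$p.value, tolerance = 1e-12)
    }
  })
  expect_error(coexpression_pcc(1:3, 1:3), "at least 4")
  expect_false(coexpression_pcc(rep(1, 5), 1:5)$defined)
})

test_that("a planted pair is scored, retained, and assembled correctly", {
  # one pair sharing 2 miRNAs of a 6-miRNA universe: N=6, n=3, m=2, x=2
  mm <- data.frame(mirna_id = c("mi1", "mi2", "mi3", "mi4", "mi5", "mi6"),
                   target_id = c("M1", "M1", "M1", "M2", "M2", "M2"),
                   target_kind = "mRNA")
  lm <- data.frame(mirna_id = c("mi1", "mi2"),
                   target_id = c("L1", "L1"), target_kind = "lncRNA")
  withr::with_seed(14, {
    x <- stats::rnorm(50)
    vals <- rbind(M1 = x, M2 = stats::rnorm(50),
                  L1 = 0.9 * x + sqrt(1 - 0.81) * stats::rnorm(50))
  })
  colnames(vals) <- sprintf("s%d", 1:50)
  em <- expression_matrix(vals, group = rep("case", 50))
  out <- build_cerna_network(mm, lm, em, key_genes = c("M1", "M2"))
  cand <- out$candidates
  pair <- cand[cand$lncrna == "L1" & cand$mrna == "M1", ]
  expect_identical(pair$N, 6L)
  expect_identical(pair$n, 3L)
  expect_identical(pair$m, 2L)
  expect_identical(pair$x, 2L)
  expect_identical(pair$p_hyper, 0)  # x = min(n, m)
  expect_true(pair$retained)
  expect_false(any(cand$retained[cand$mrna == "M2"]))
  nodes <- out$network$nodes
  expect_setequal(nodes$id, c("L1", "M1", "mi1", "mi2"))
  expect_setequal(nodes$type[match(c("mi1", "mi2"), nodes$id)],
                  c("miRNA", "miRNA"))
})

test_that("independent expression blocks retention despite p_hyper = 0", {
  mm <- data.frame(mirna_id = sprintf("mi%d", 1:6), target_id = "M1",
                   target_kind = "mRNA")
  lm <- data.frame(mirna_id = sprintf("mi%d", 1:6), target_id = "L1",
                   target_kind = "lncRNA")
  blocked <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      vals <- rbind(M1 = stats::rnorm(60), L1 = stats::rnorm(60))
    })
    colnames(vals) <- sprintf("s%d", 1:60)
    em <- expression_matrix(vals, group = rep("case", 60))
    out <- build_cerna_network(mm, lm, em, key_genes = "M1")
    expect_identical(out$candidates$p_hyper, 0)
    !out$candidates$retained
  }, logical(1))
  expect_gte(mean(blocked), 0.95)
})

test_that("empty interaction tables give empty candidates and network", {
  mm <- data.frame(mirna_id = character(0), target_id = character(0),
                   target_kind = character(0))
  em <- expression_matrix(matrix(stats::rnorm(8), 2, 4,
                                 dimnames = list(c("a", "b"),
                                                 sprintf("s%d", 1:4))),
                          group = rep("case", 4))
  out <- build_cerna_network(mm, mm, em, key_genes = "a")
  expect_identical(nrow(out$candidates), 0L)
  expect_identical(nrow(out$network$nodes), 0L)
})

test_that("planted competing pairs dominate background pairs", {
  si <- simulate_interactions(200, 30, 30, planted_pairs = 5,
                              shared_per_planted = 20,
                              background_rate = 0.02, seed = 15)
  out <- build_cerna_network(si$mrna_mirna, si$lncrna_mirna, si$expression,
                             key_genes = unique(si$mrna_mirna$target_id))
  cand <- out$candidates
  key <- paste(cand$lncrna, cand$mrna)
  planted <- key %in% paste(si$truth$planted_pairs$lncrna,
                            si$truth$planted_pairs$mrna)
  expect_lt(stats::median(cand$p_hyper[planted]),
            stats::median(cand$p_hyper[!planted]))
  expect_true(all(cand$retained[planted]))
})

test_that("hub ranking orders lncRNAs by degree then betweenness", {
  # star: lncRNA centre with 5 miRNA leaves
  star_nodes <- data.frame(name = c("L", sprintf("mi%d", 1:5)),
                           type = c("lncRNA", rep("miRNA", 5)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = "L", to = sprintf("mi%d", 1:5)),
    directed = FALSE, vertices = star_nodes)
  net <- structure(list(graph = g, nodes = data.frame(
    id = star_nodes$name, type = star_nodes$type,
    degree = as.numeric(igraph::degree(g)),
    betweenness = as.numeric(igraph::betweenness(g)))),
    class = "cerna_network")
  hubs <- rank_hubs(net)
  expect_identical(hubs$id[1], "L")
  expect_identical(hubs$degree[1], 5)
  expect_identical(hubs$betweenness[1], 10)

  # path a-b-c-d betweenness 0/2/2/0
  pg <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "c"), to = c("b", "c", "d")),
    directed = FALSE)
  bc <- igraph::betweenness(pg, directed = FALSE, normalized = FALSE)
  expect_equal(unname(bc[c("a", "b", "c", "d")]), c(0, 2, 2, 0))

  # equal degree, unequal betweenness: higher betweenness ranks first
  edges <- data.frame(from = c("L1", "L1", "M1", "mi3", "L2", "L2"),
                      to = c("mi1", "mi2", "mi1", "M1", "mi3", "mi4"))
  g2 <- igraph::graph_from_data_frame(edges, directed = FALSE)
  types <- c(L1 = "lncRNA", mi1 = "miRNA", mi2 = "miRNA", M1 = "mRNA",
             mi3 = "miRNA", L2 = "lncRNA", mi4 = "miRNA")
  nd <- data.frame(id = igraph::V(g2)$name,
                   type = unname(types[igraph::V(g2)$name]),
                   degree = as.numeric(igraph::degree(g2)),
                   betweenness = as.numeric(igraph::betweenness(g2)))
  net2 <- structure(list(graph = g2, nodes = nd), class = "cerna_network")
  hubs2 <- rank_hubs(net2)
  expect_identical(hubs2$degree[1], hubs2$degree[2])
  expect_gte(hubs2$betweenness[1], hubs2$betweenness[2])
})

test_that("igraph betweenness agrees with path enumeration on tiny graphs", {
  withr::with_seed(16, {
    for (i in 1:30) {
      nv <- sample(4:8, 1)
      verts <- sprintf("v%d", seq_len(nv))
      pairs <- utils::combn(verts, 2)
      keep <- stats::runif(ncol(pairs)) < 0.45
      if (!any(keep)) keep[1] <- TRUE
      edges <- data.frame(from = pairs[1, keep], to = pairs[2, keep])
      g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = data.frame(name = verts))
      got <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
      want <- betweenness_bruteforce(edges, verts)
      expect_equal(unname(got[verts]), unname(want[verts]), tolerance = 1e-9)
    }
  })
})
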