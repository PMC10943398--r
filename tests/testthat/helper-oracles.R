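# Independent brute-force oracles used to verify the analytical routines.
# These deliberately share no code with the implementations they check.

# Step-up BH by direct construction.
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Upper-tail hypergeometric probability by explicit pmf summation.
# choose() returns 0 for impossible terms, so no special-casing is needed.
hyper_tail_bruteforce <- function(N, n, m, x, convention = "as_printed") {
  q <- if (convention == "as_printed") x else x - 1
  if (q < 0) return(1)
  k <- 0:q
  1 - sum(choose(m, k) * choose(N - m, n - k)) / choose(N, n)
}

# Exact two-sided rank-sum p-value by full enumeration of group assignments.
# Returns the same two-sided rule as the exact Wilcoxon test: double the
# smaller tail of the Mann-Whitney U statistic, capped at 1.
wilcox_enum_p <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  u_stat <- function(idx) {
    x <- pool[idx]; y <- pool[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_stat(seq_len(n1))
  us <- apply(utils::combn(length(pool), n1), 2, u_stat)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Unnormalised shortest-path betweenness by explicit path enumeration
# (all simple paths per ordered pair, keep the shortest ones, split evenly).
# Feasible only for tiny graphs.
betweenness_bruteforce <- function(edges, vertices) {
  adj <- lapply(vertices, function(v)
    unique(c(edges$to[edges$from == v], edges$from[edges$to == v])))
  names(adj) <- vertices
  all_paths <- function(from, to) {
    paths <- list()
    walk <- function(v, seen) {
      if (v == to) { paths[[length(paths) + 1]] <<- seen; return() }
      for (w in adj[[v]]) if (!w %in% seen) walk(w, c(seen, w))
    }
    walk(from, from)
    paths
  }
  bc <- stats::setNames(numeric(length(vertices)), vertices)
  pairs <- utils::combn(vertices, 2)
  for (j in seq_len(ncol(pairs))) {
    s <- pairs[1, j]; t <- pairs[2, j]
    ps <- all_paths(s, t)
    if (length(ps) == 0) next
    lens <- vapply(ps, length, integer(1))
    sp <- ps[lens == min(lens)]
    for (p in sp)
      for (v in setdiff(p, c(s, t)))
        bc[v] <- bc[v] + 1 / length(sp)
  }
  bc
}

# Two-blob sample matrix (samples x genes) with opposite gene-profile
# patterns, so both correlation and euclidean distances separate the blobs.
make_blobs <- function(n_per = 10, n_genes = 6, center = 5, sd = 0.1,
                       seed = 1) {
  withr::with_seed(seed, {
    pattern <- rep(c(center, -center), length.out = n_genes)
    X <- rbind(
      matrix(stats::rnorm(n_per * n_genes, rep(pattern, each = n_per), sd),
             n_per, n_genes),
      matrix(stats::rnorm(n_per * n_genes, rep(-pattern, each = n_per), sd),
             n_per, n_genes))
  })
  rownames(X) <- sprintf("s%02d", seq_len(2 * n_per))
  X
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
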