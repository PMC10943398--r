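# Competing-endogenous-RNA network inference: hypergeometric shared-miRNA
# test for candidate lncRNA-mRNA pairs, Pearson co-expression filter,
# network assembly, and hub ranking by degree then betweenness.

#' Hypergeometric test for a competing lncRNA-mRNA pair
#'
#' Given a miRNA universe of size `N`, an mRNA targeted by `n` miRNAs, an
#' lncRNA targeted by `m` miRNAs, and `x` shared miRNAs, returns the upper
#' hypergeometric tail probability of the shared count. Two conventions are
#' supported: `"as_printed"` evaluates
#' `P = 1 - sum_{k=0}^{x} C(m,k) C(N-m,n-k) / C(N,n)`, the probability of
#' sharing strictly more than `x` miRNAs; `"at_least_x"` sums only to
#' `x - 1`, the conventional P(X >= x). Evaluation is exact and log-stable
#' (no Monte Carlo); combinatorially impossible terms contribute zero
#' probability.
#'
#' @param N Total distinct miRNAs in the interaction data.
#' @param n miRNAs associated with the mRNA.
#' @param m miRNAs associated with the lncRNA.
#' @param x Shared miRNAs, `0 <= x <= min(n, m)`.
#' @param convention `"as_printed"` (default) or `"at_least_x"`.
#' @return The tail probability in \[0, 1\].
#' @export
hypergeom_competing_test <- function(N, n, m, x,
                                     convention = c("as_printed",
                                                    "at_least_x")) {
  convention <- match.arg(convention)
  if (any(c(N, n, m, x) < 0)) stop("arguments must be non-negative")
  if (n > N || m > N) stop("`n` and `m` cannot exceed `N`")
  if (x > min(n, m)) stop("`x` cannot exceed min(n, m)")
  q <- if (convention == "as_printed") x else x - 1
  # X ~ Hypergeometric(white = m, black = N - m, drawn = n)
  stats::phyper(q, m, N - m, n, lower.tail = FALSE)
}

#' Pearson co-expression of a candidate pair
#'
#' Sample Pearson correlation coefficient with a two-sided p-value from the
#' t reference with n - 2 degrees of freedom.
#'
#' @param x_values,y_values Paired numeric vectors (>= 4 finite pairs).
#' @return List with `pcc` and `p`; both `NA` (with `defined = FALSE`) when
#'   either vector has zero variance.
#' @export
coexpression_pcc <- function(x_values, y_values) {
  if (length(x_values) != length(y_values)) stop("lengths differ")
  ok <- is.finite(x_values) & is.finite(y_values)
  x <- x_values[ok]; y <- y_values[ok]
  if (length(x) < 4) stop("need at least 4 paired finite observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(pcc = NA_real_, p = NA_real_, defined = FALSE))
  r <- stats::cor(x, y)
  nn <- length(x)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((nn - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), nn - 2)
  }
  list(pcc = r, p = p, defined = TRUE)
}

validate_interactions <- function(tab, kind) {
  need <- c("mirna_id", "target_id")
  if (!all(need %in% names(tab)))
    stop("interaction table needs `mirna_id` and `target_id` columns")
  if (nrow(tab) > 0 && (any(tab$mirna_id == "") || any(tab$target_id == "")))
    stop("empty identifiers in interaction table")
  tab[!duplicated(tab[need]), , drop = FALSE]
}

#' Build the lncRNA-miRNA-mRNA competing-endogenous-RNA network
#'
#' Candidate pairs are every (lncRNA, mRNA-in-`key_genes`) combination
#' sharing at least one miRNA. Each candidate is scored by the
#' hypergeometric shared-miRNA test (with `N` the distinct miRNA count over
#' both tables) and by Pearson co-expression of the two transcripts. A pair
#' is retained when `p_hyper < alpha_hyper`, `pcc > pcc_min` and
#' `p_pcc < alpha_pcc`. The network contains the retained pairs, their
#' shared miRNAs, the corresponding miRNA-target edges, and a direct
#' lncRNA-mRNA competing edge per retained pair; degree and betweenness are
#' computed on the assembled undirected graph.
#'
#' @param mrna_mirna,lncrna_mirna Interaction data.frames with columns
#'   `mirna_id`, `target_id` (duplicate edges dropped).
#' @param expression An [expression_matrix] containing the tested mRNAs and
#'   lncRNAs; transcripts missing from it are logged and excluded from the
#'   co-expression stage (never retained).
#' @param key_genes Non-empty set of mRNA symbols to test.
#' @param alpha_hyper Gate on the hypergeometric p (default 0.01).
#' @param pcc_min,alpha_pcc Co-expression gates (defaults 0.3, 0.01).
#' @param convention Tail convention, see [hypergeom_competing_test()].
#' @param cohort Samples used for co-expression: `"all"` (default) or
#'   `"case"`.
#' @param adjust_hyper Apply BH across candidate hypergeometric p-values
#'   before gating (default FALSE: raw thresholds, as conventional for this
#'   screen).
#' @return List with `candidates` (data.frame: `lncrna`, `mrna`, `N`, `n`,
#'   `m`, `x`, `p_hyper`, `pcc`, `p_pcc`, `retained`) and `network`, a
#'   `cerna_network` object (list with the igraph `graph` and a `nodes`
#'   data.frame: `id`, `type`, `degree`, `betweenness`).
#' @export
build_cerna_network <- function(mrna_mirna, lncrna_mirna, expression,
                                key_genes, alpha_hyper = 0.01,
                                pcc_min = 0.3, alpha_pcc = 0.01,
                                convention = c("as_printed", "at_least_x"),
                                cohort = c("all", "case"),
                                adjust_hyper = FALSE) {
  convention <- match.arg(convention)
  cohort <- match.arg(cohort)
  if (length(key_genes) == 0) stop("`key_genes` must be non-empty")
  mm <- validate_interactions(mrna_mirna, "mRNA")
  lm <- validate_interactions(lncrna_mirna, "lncRNA")
  N <- length(unique(c(mm$mirna_id, lm$mirna_id)))

  missing_int <- setdiff(key_genes, unique(mm$target_id))
  if (length(missing_int) > 0)
    message(sprintf("%d key gene(s) absent from the mRNA interaction table: %s",
                    length(missing_int),
                    paste(utils::head(missing_int, 5), collapse = ", ")))
  mm <- mm[mm$target_id %in% key_genes, , drop = FALSE]
  mrna_sets <- split(mm$mirna_id, mm$target_id)
  lnc_sets <- split(lm$mirna_id, lm$target_id)

  empty <- data.frame(lncrna = character(0), mrna = character(0),
                      N = integer(0), n = integer(0), m = integer(0),
                      x = integer(0), p_hyper = numeric(0), pcc = numeric(0),
                      p_pcc = numeric(0), retained = logical(0))
  if (length(mrna_sets) == 0 || length(lnc_sets) == 0)
    return(list(candidates = empty, network = assemble_network(empty, mm, lm)))

  cand <- do.call(rbind, lapply(names(lnc_sets), function(l) {
    do.call(rbind, lapply(names(mrna_sets), function(g) {
      x <- length(intersect(lnc_sets[[l]], mrna_sets[[g]]))
      if (x < 1) return(NULL)
      data.frame(lncrna = l, mrna = g, N = N,
                 n = length(unique(mrna_sets[[g]])),
                 m = length(unique(lnc_sets[[l]])), x = x,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(cand))
    return(list(candidates = empty, network = assemble_network(empty, mm, lm)))

  cand$p_hyper <- mapply(function(N, n, m, x)
    hypergeom_competing_test(N, n, m, x, convention),
    cand$N, cand$n, cand$m, cand$x)

  keep <- if (cohort == "case") expression$samples$group == "case" else
    rep(TRUE, nrow(expression$samples))
  vals <- expression$values[, keep, drop = FALSE]
  have <- rownames(vals)
  cand$pcc <- NA_real_; cand$p_pcc <- NA_real_
  no_expr <- unique(c(setdiff(cand$lncrna, have), setdiff(cand$mrna, have)))
  if (length(no_expr) > 0)
    message(sprintf("%d transcript(s) lack expression; their pairs skip the PCC stage: %s",
                    length(no_expr),
                    paste(utils::head(no_expr, 5), collapse = ", ")))
  for (i in seq_len(nrow(cand))) {
    if (cand$lncrna[i] %in% have && cand$mrna[i] %in% have) {
      cp <- coexpression_pcc(vals[cand$mrna[i], ], vals[cand$lncrna[i], ])
      cand$pcc[i] <- cp$pcc; cand$p_pcc[i] <- cp$p
    }
  }
  p_gate <- if (adjust_hyper) bh_adjust(cand$p_hyper) else cand$p_hyper
  cand$retained <- p_gate < alpha_hyper &
    !is.na(cand$pcc) & cand$pcc > pcc_min & cand$p_pcc < alpha_pcc
  rownames(cand) <- NULL
  list(candidates = cand, network = assemble_network(cand, mm, lm))
}

# Assemble the igraph network from retained candidate pairs plus the
# miRNA-target edges of their shared miRNAs.
assemble_network <- function(cand, mm, lm) {
  ret <- cand[cand$retained %||% logical(0), , drop = FALSE]
  edges <- data.frame(from = character(0), to = character(0))
  types <- character(0)
  if (nrow(ret) > 0) {
    mrna_sets <- split(mm$mirna_id, mm$target_id)
    lnc_sets <- split(lm$mirna_id, lm$target_id)
    for (i in seq_len(nrow(ret))) {
      l <- ret$lncrna[i]; g <- ret$mrna[i]
      shared <- intersect(lnc_sets[[l]], mrna_sets[[g]])
      edges <- rbind(edges,
                     data.frame(from = g, to = shared),
                     data.frame(from = l, to = shared),
                     data.frame(from = l, to = g))
      types[g] <- "mRNA"; types[l] <- "lncRNA"
      types[shared] <- "miRNA"
    }
    edges <- edges[!duplicated(edges), , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = if (length(types) > 0)
                                       data.frame(name = names(types),
                                                  type = unname(types)) else
                                       data.frame(name = character(0),
                                                  type = character(0)))
  nodes <- data.frame(
    id = igraph::V(g)$name %||% character(0),
    type = igraph::V(g)$type %||% character(0),
    degree = as.numeric(igraph::degree(g)),
    betweenness = as.numeric(igraph::betweenness(g, directed = FALSE,
                                                 normalized = FALSE)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(graph = g, nodes = nodes), class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  tt <- table(factor(x$nodes$type, levels = c("lncRNA", "miRNA", "mRNA")))
  cat(sprintf("cerna_network: %d nodes (%d lncRNA, %d miRNA, %d mRNA), %d edges\n",
              nrow(x$nodes), tt["lncRNA"], tt["miRNA"], tt["mRNA"],
              igraph::ecount(x$graph)))
  invisible(x)
}

#' Rank lncRNA hubs by degree and betweenness
#'
#' Orders the lncRNA nodes of a ceRNA network by decreasing degree, breaking
#' ties by decreasing (unnormalised shortest-path) betweenness centrality and
#' then by identifier. The first row is the hub lncRNA.
#'
#' @param network A `cerna_network` from [build_cerna_network()].
#' @return Data.frame `id`, `degree`, `betweenness` of lncRNA nodes, ranked;
#'   zero rows when the network has no lncRNA nodes.
#' @export
rank_hubs <- function(network) {
  nd <- network$nodes[network$nodes$type == "lncRNA", , drop = FALSE]
  nd <- nd[order(-nd$degree, -nd$betweenness, nd$id), , drop = FALSE]
  rownames(nd) <- NULL
  nd[c("id", "degree", "betweenness")]
}
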