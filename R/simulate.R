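#' Simulate a two-group expression cohort with known ground truth
#'
#' Generates a log2-scale expression matrix for a case/control cohort with
#' planted differentially expressed (DE) genes, additive batch offsets, a
#' curated gene panel containing a small set of key biomarker genes, and a
#' planted two-subcluster structure among the case samples. Every planted
#' feature is reported in a truth table so downstream stages (differential
#' expression, feature selection, consensus clustering) can be scored against
#' ground truth.
#'
#' The generative model: per-gene baseline means are drawn from
#' `N(baseline_mean, baseline_sd)` on the log2 scale; i.i.d. Gaussian noise
#' with standard deviation `noise_sd` is added per observation. A fraction
#' `de_fraction` of genes receive a signed log2 shift in case samples whose
#' magnitude is `lfc_mean` scaled by a uniform factor in
#' `[1 - lfc_jitter, 1 + lfc_jitter]` and whose sign is random. Samples are assigned to `batch_count` batches at
#' random (each batch non-empty) and each (gene, batch) cell receives an
#' additive offset drawn from `N(0, batch_sd)`. The key genes are a subset of
#' the planted DE genes and are additionally shifted by `subcluster_shift`
#' (log2 units) in a random half of the case samples, planting a
#' two-subcluster structure.
#'
#' @param n_case,n_control Number of case / control samples (each >= 2).
#' @param n_genes Number of genes (>= 10).
#' @param de_fraction Fraction of genes planted as DE, in \[0, 1\].
#' @param lfc_mean Mean absolute log2 fold change of planted DE genes.
#' @param lfc_jitter Relative spread of DE effect magnitudes: each planted
#'   gene's |log2 shift| is `lfc_mean` times a uniform draw from
#'   `[1 - lfc_jitter, 1 + lfc_jitter]`. Set 0 to plant `lfc_mean` exactly.
#' @param batch_count Number of batches (>= 1).
#' @param batch_sd Standard deviation of per-(gene, batch) additive offsets.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian noise (> 0).
#' @param panel_size Size of the curated gene panel (the study curated 63
#'   cuproptosis genes; that is the default).
#' @param key_size Number of key biomarker genes planted inside
#'   `panel intersect de_genes` (default 6, the study's key-gene count).
#' @param subcluster_shift Log2 shift of key genes distinguishing the two
#'   planted case subclusters.
#' @param baseline_mean,baseline_sd Location and spread of per-gene baseline
#'   means on the log2 scale.
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   output.
#'
#' @return A list with elements `expr` (an [expression_matrix] whose sample
#'   metadata includes `subcluster`) and `truth`, a list with fields
#'   `de_genes`, `panel_genes`, `key_genes`, `effect_sizes` (named per-DE-gene
#'   log2 shifts), `subcluster_labels` (named, case samples only) and
#'   `batch_labels` (named, all samples).
#' @export
simulate_cohort <- function(n_case, n_control, n_genes,
                            de_fraction = 0.05, lfc_mean = 1.0,
                            lfc_jitter = 0.25,
                            batch_count = 2, batch_sd = 0.5,
                            noise_sd = 0.5,
                            panel_size = 63, key_size = 6,
                            subcluster_shift = 1.0,
                            baseline_mean = 6, baseline_sd = 2,
                            seed = 1) {
  if (n_case < 2 || n_control < 2) stop("need at least 2 samples per group")
  if (n_genes < 10) stop("`n_genes` must be >= 10")
  if (noise_sd <= 0) stop("`noise_sd` must be positive")
  if (de_fraction < 0 || de_fraction > 1) stop("`de_fraction` must be in [0,1]")
  if (batch_count < 1) stop("`batch_count` must be >= 1")
  n <- n_case + n_control

  withr::with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    sample_ids <- c(sprintf("case_%03d", seq_len(n_case)),
                    sprintf("ctrl_%03d", seq_len(n_control)))
    group <- rep(c("case", "control"), c(n_case, n_control))

    n_de <- round(de_fraction * n_genes)
    de_genes <- if (n_de > 0) sample(genes, n_de) else character(0)
    effects <- if (n_de > 0) {
      stats::setNames(sample(c(-1, 1), n_de, replace = TRUE) *
                        lfc_mean * stats::runif(n_de, 1 - lfc_jitter,
                                                1 + lfc_jitter),
                      de_genes)
    } else stats::setNames(numeric(0), character(0))

    key_size <- min(key_size, length(de_genes))
    key_genes <- if (key_size > 0) sample(de_genes, key_size) else character(0)
    panel_pool <- setdiff(genes, key_genes)
    panel_extra <- sample(panel_pool, min(max(panel_size - key_size, 0),
                                          length(panel_pool)))
    panel_genes <- c(key_genes, panel_extra)

    # batches: random assignment, forced non-empty
    batch <- sample(rep_len(seq_len(batch_count), n))
    batch <- sprintf("batch%d", batch)

    # planted case subclusters: half the cases form subcluster 2
    subcluster <- rep(NA_integer_, n)
    case_idx <- which(group == "case")
    sub2 <- sample(case_idx, floor(n_case / 2))
    subcluster[case_idx] <- 1L
    subcluster[sub2] <- 2L

    mu <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    values <- matrix(stats::rnorm(n_genes * n, mean = mu, sd = noise_sd),
                     nrow = n_genes, ncol = n,
                     dimnames = list(genes, sample_ids))
    if (n_de > 0)
      values[de_genes, group == "case"] <-
        values[de_genes, group == "case"] + effects
    if (length(key_genes) > 0 && length(sub2) > 0)
      values[key_genes, sub2] <- values[key_genes, sub2] + subcluster_shift
    if (batch_sd > 0) {
      for (b in unique(batch)) {
        offs <- stats::rnorm(n_genes, 0, batch_sd)
        values[, batch == b] <- values[, batch == b] + offs
      }
    }
  })

  expr <- expression_matrix(values, group = group, batch = batch,
                            subcluster = subcluster)
  truth <- list(
    de_genes = de_genes,
    panel_genes = panel_genes,
    key_genes = key_genes,
    effect_sizes = effects,
    subcluster_labels = stats::setNames(subcluster[group == "case"],
                                        sample_ids[group == "case"]),
    batch_labels = stats::setNames(batch, sample_ids)
  )
  list(expr = expr, truth = truth)
}

#' Simulate immune-cell fraction tables with a planted gene link
#'
#' Emulates the output of a bulk deconvolution tool (22 immune cell types by
#' default): per-sample fractions on the simplex plus a per-sample
#' deconvolution p-value. Rows are drawn from a symmetric Dirichlet
#' distribution (gamma normalisation) with concentration `concentration`; the
#' first cell type's weight is multiplied by
#' `exp(2 * link_strength * z)`, where `z` is the standardised value of
#' `linked_gene_values`, before renormalisation. This plants a rank
#' correlation between the designated cell type and the linked gene whose
#' sign matches `sign(link_strength)` and whose magnitude grows with
#' `|link_strength|`, without asserting any particular deconvolution model.
#'
#' @param n_samples Number of samples (rows).
#' @param n_celltypes Number of cell types (>= 2; default 22).
#' @param concentration Symmetric Dirichlet concentration (> 0).
#' @param linked_gene_values Numeric vector of length `n_samples`; the
#'   expression of the gene to link. Defaults to standard normal draws.
#' @param link_strength Real in \[-1, 1\]; 0 plants no association.
#' @param sig_fraction Fraction of samples given a deconvolution p-value
#'   below 0.05 (the rest are uniform on \[0.05, 1\]).
#' @param seed Integer seed.
#'
#' @return A data.frame with `n_celltypes` fraction columns (each row summing
#'   to 1), a `deconv_p` column, and rownames giving sample ids. The linked
#'   cell type is the first column (`celltype_01`); attribute
#'   `linked_celltype` records its name.
#' @export
simulate_fractions <- function(n_samples, n_celltypes = 22,
                               concentration = 1,
                               linked_gene_values = NULL,
                               link_strength = 0,
                               sig_fraction = 0.9,
                               seed = 1) {
  if (n_celltypes < 2) stop("`n_celltypes` must be >= 2")
  if (concentration <= 0) stop("`concentration` must be positive")
  if (abs(link_strength) > 1) stop("`link_strength` must be in [-1, 1]")
  withr::with_seed(seed, {
    if (is.null(linked_gene_values))
      linked_gene_values <- stats::rnorm(n_samples)
    if (length(linked_gene_values) != n_samples)
      stop("`linked_gene_values` must have length `n_samples`")
    w <- matrix(stats::rgamma(n_samples * n_celltypes, shape = concentration),
                nrow = n_samples)
    z <- as.numeric(scale(linked_gene_values))
    if (any(!is.finite(z))) z <- rep(0, n_samples)  # constant gene
    w[, 1] <- w[, 1] * exp(2 * link_strength * z)
    fr <- w / rowSums(w)
    sig <- stats::runif(n_samples) < sig_fraction
    deconv_p <- ifelse(sig, stats::runif(n_samples, 0, 0.05),
                       stats::runif(n_samples, 0.05, 1))
  })
  out <- as.data.frame(fr)
  names(out) <- sprintf("celltype_%02d", seq_len(n_celltypes))
  rownames(out) <- sprintf("S%03d", seq_len(n_samples))
  out$deconv_p <- deconv_p
  attr(out, "linked_celltype") <- "celltype_01"
  out
}

#' Simulate miRNA interaction tables with planted competing pairs
#'
#' Builds miRNA-mRNA and miRNA-lncRNA edge lists over a shared miRNA universe
#' together with a paired expression matrix. Each planted (lncRNA, mRNA) pair
#' is wired to a common random set of `shared_per_planted` miRNAs, so the
#' pair shares at least that many miRNAs; every other (miRNA, target) edge is
#' included independently with probability `background_rate`, so background
#' pairs share miRNAs only by chance. Expression for planted partners is
#' drawn bivariate normal with Pearson correlation `planted_pcc`; all other
#' transcripts are independent.
#'
#' @param n_mirna Size of the miRNA universe.
#' @param n_mrna,n_lncrna Number of mRNAs / lncRNAs.
#' @param planted_pairs Number of planted competing (lncRNA, mRNA) pairs;
#'   pair `i` links `lncRNA_i` with `mRNA_i` (requires
#'   `planted_pairs <= min(n_mrna, n_lncrna)` so partners are distinct).
#' @param shared_per_planted miRNAs wired to both members of each planted
#'   pair (<= `n_mirna`).
#' @param background_rate Probability of an independent background edge.
#' @param planted_pcc Target Pearson correlation of planted partners' expression.
#' @param n_samples Number of expression samples generated.
#' @param seed Integer seed.
#'
#' @return A list with `mrna_mirna` and `lncrna_mirna` (data.frames with
#'   columns `mirna_id`, `target_id`, `target_kind`), `expression` (an
#'   [expression_matrix] over the mRNAs and lncRNAs; all samples labelled
#'   `case`), and `truth` with `planted_pairs` (data.frame `lncrna`, `mrna`),
#'   `mirna_universe_size` (distinct miRNAs across both tables),
#'   `background_rate` and `planted_pcc`.
#' @export
simulate_interactions <- function(n_mirna, n_mrna, n_lncrna,
                                  planted_pairs, shared_per_planted,
                                  background_rate = 0.02,
                                  planted_pcc = 0.6,
                                  n_samples = 100,
                                  seed = 1) {
  if (shared_per_planted > n_mirna)
    stop("`shared_per_planted` cannot exceed `n_mirna`")
  if (planted_pairs > min(n_mrna, n_lncrna))
    stop("`planted_pairs` cannot exceed min(n_mrna, n_lncrna)")
  if (background_rate < 0 || background_rate > 1)
    stop("`background_rate` must be in [0, 1]")
  mirnas <- sprintf("miR-%03d", seq_len(n_mirna))
  mrnas <- sprintf("MRNA%03d", seq_len(n_mrna))
  lncrnas <- sprintf("LNC%03d", seq_len(n_lncrna))

  withr::with_seed(seed, {
    m_adj <- matrix(stats::runif(n_mirna * n_mrna) < background_rate,
                    nrow = n_mirna, dimnames = list(mirnas, mrnas))
    l_adj <- matrix(stats::runif(n_mirna * n_lncrna) < background_rate,
                    nrow = n_mirna, dimnames = list(mirnas, lncrnas))
    planted <- data.frame(lncrna = character(0), mrna = character(0))
    if (planted_pairs > 0) {
      planted <- data.frame(lncrna = lncrnas[seq_len(planted_pairs)],
                            mrna = mrnas[seq_len(planted_pairs)],
                            stringsAsFactors = FALSE)
      for (i in seq_len(planted_pairs)) {
        shared <- sample(mirnas, shared_per_planted)
        m_adj[shared, planted$mrna[i]] <- TRUE
        l_adj[shared, planted$lncrna[i]] <- TRUE
      }
    }
    # expression: planted partners bivariate normal at planted_pcc
    expr <- matrix(stats::rnorm((n_mrna + n_lncrna) * n_samples),
                   nrow = n_mrna + n_lncrna,
                   dimnames = list(c(mrnas, lncrnas),
                                   sprintf("S%03d", seq_len(n_samples))))
    if (planted_pairs > 0 && planted_pcc != 0) {
      for (i in seq_len(planted_pairs)) {
        x <- expr[planted$mrna[i], ]
        eps <- stats::rnorm(n_samples)
        expr[planted$lncrna[i], ] <-
          planted_pcc * x + sqrt(1 - planted_pcc^2) * eps
      }
    }
    expr <- expr * 1.5 + 6  # place on a log2-intensity-like scale
  })

  adj_to_edges <- function(adj, kind) {
    idx <- which(adj, arr.ind = TRUE)
    data.frame(mirna_id = rownames(adj)[idx[, 1]],
               target_id = colnames(adj)[idx[, 2]],
               target_kind = rep(kind, nrow(idx)), stringsAsFactors = FALSE)
  }
  mm <- adj_to_edges(m_adj, "mRNA")
  lm <- adj_to_edges(l_adj, "lncRNA")
  truth <- list(planted_pairs = planted,
                mirna_universe_size =
                  length(unique(c(mm$mirna_id, lm$mirna_id))),
                background_rate = background_rate,
                planted_pcc = planted_pcc)
  em <- expression_matrix(expr, group = rep("case", ncol(expr)))
  list(mrna_mirna = mm, lncrna_mirna = lm, expression = em, truth = truth)
}
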