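---
title: "Methods: cuproptosis biomarker screening and ceRNA inference in sepsis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cuproptosis biomarker screening and ceRNA inference in sepsis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuprosep)
```

# Overview

`cuprosep` implements an integrated analysis for screening copper-dependent
cell-death (cuproptosis) related diagnostic biomarkers in sepsis bulk
transcriptomes, and for placing those biomarkers in a lncRNA–miRNA–mRNA
competing-endogenous-RNA (ceRNA) context. The stages are:

1. **Preprocessing** — merge cohorts, correct additive batch offsets, call
   differential expression on log2 data, and intersect the differentially
   expressed genes (DEGs) with a curated cuproptosis gene panel to obtain
   the panel DEGs (DECuGs).
2. **Dual machine-learning selection** — cross-validated L1-penalised
   logistic regression (LASSO) and linear SVM recursive feature elimination
   (SVM-RFE); the biomarker set is the intersection of the two selections.
3. **Immune correlation** — Spearman correlation of biomarker expression
   with deconvolved immune-cell fractions, and rank-sum contrasts of
   fractions between groups.
4. **Consensus subtyping** — resampling consensus clustering of case
   samples on the biomarker submatrix, with the cluster number chosen from
   the consensus CDF.
5. **ceRNA inference** — a hypergeometric shared-miRNA test for candidate
   lncRNA–mRNA competing pairs, a Pearson co-expression filter, network
   assembly, and hub ranking by degree and betweenness.
6. **Diagnostics** — ROC/AUC for single genes and a combined panel score,
   including on a held-out validation cohort.

Every stage is exercised against planted ground truth from the
synthetic-data generator, so the package is fully testable without any
external download. Real inputs (expression TSVs, GMT panels, CIBERSORT-style
fraction tables, interaction edge lists) use the same readers.

# Differential expression

Expression is assumed log2-scale. For gene $g$ with case/control means
$\bar x_1, \bar x_2$ and group variances $s_1^2, s_2^2$, the unmoderated
statistic is the Welch $t$,
$t_g = (\bar x_1 - \bar x_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}$, with
Satterthwaite degrees of freedom and a two-sided p-value. P-values are
adjusted by Benjamini–Hochberg, and a gene is flagged DE when its linear
fold change exceeds 1.2 in either direction ($|\log_2\mathrm{FC}| >
\log_2 1.2$) and its **adjusted** p-value is below 0.05. The fold-change
gate is interpreted on the linear scale because "FC" conventionally means a
linear ratio on log2 data; the significance gate uses the adjusted p by
default because the screening convention is FDR-controlled, with a raw-p
gate available (`use_adjusted = FALSE`) since both conventions are common
in microarray screens.

## Variance moderation

With thousands of genes and few samples, gene-wise variances are noisy. We
shrink them toward a common prior: a scaled inverse-chi-square prior
$(d_0, s_0^2)$ is fitted by method of moments on the log pooled variances
(the excess of $\mathrm{Var}(\log s^2)$ over $\psi'(d/2)$ identifies
$d_0$ via the trigamma function; the mean identifies $s_0^2$), and each
*group* variance is replaced by
$\tilde s_i^2 = (d_0 s_0^2 + d_i s_i^2)/(d_0 + d_i)$ with the group df
inflated to $d_i + d_0$ in the Satterthwaite formula. Shrinking the two
group variances separately (rather than the pooled variance) keeps the
statistic an exact generalisation of the Welch $t$: with $d_0 = 0$ the
moderated and unmoderated statistics coincide identically, which is the
package's testable contract for the moderation path. When the observed
spread of log variances is no larger than the sampling noise, $d_0$ is
infinite and all genes share $s_0^2$.

## Batch correction

The default correction is a per-gene location adjustment: within each batch
the gene's mean is shifted to its grand mean. This makes per-batch means
equal (to numerical precision) while preserving the grand mean and all
within-batch contrasts — a fully testable contract. An empirical-Bayes
location-scale adjustment (ComBat) is available via `method = "combat"`
for data with batch-specific variance inflation. Batch correction requires
at least two samples per batch; confounded designs (a batch containing only
cases) will remove biology together with the batch offset, which is the
user's responsibility to avoid.

# Dual machine-learning biomarker selection

**LASSO.** An L1-penalised logistic model is fitted over a 50-point
log-spaced penalty grid spanning $[10^{-3}, 1] \times \lambda_{\max}$,
where $\lambda_{\max}$ is the data-derived penalty that shrinks every
coefficient to zero. The penalty minimising the mean cross-validated
binomial deviance over stratified, seeded folds is chosen (the minimum
rule, not the 1-SE rule, as the least surprising default), and the
selection is the set of nonzero coefficients at that penalty refitted on
all samples. Features are standardised internally, so selections are
invariant to positive rescaling of any column.

**SVM-RFE.** A linear soft-margin SVM (cost 1) is fitted repeatedly;
features are scored by squared weight $w_j^2$ and the lowest-scoring
`elimination_step` features are removed each round. The ranking is the
reverse removal order. The selected set is the ranking prefix whose size
minimises stratified cross-validated misclassification error over the sizes
visited by the recursion, ties going to the smaller model. The linear
kernel and squared-weight criterion are the canonical RFE choices; the cost
parameter, fold count and grid are package defaults, not study-reported
values, since the study does not state them.

The biomarker set ("key genes") is the exact intersection of the two
selections. On synthetic cohorts with 6 genes of log2 effect 1.0 planted
among 200 (noise sd 0.5, 60 samples per class), the intersection recovers
on average more than 5 of the 6 planted genes across 20 seeds, with both
selector-specific recovery rates above 95% for a single strong planted
feature.

# Immune-fraction analyses

Immune-cell fractions are consumed as input (e.g. CIBERSORT output with 22
cell types and a per-sample deconvolution p-value); deconvolution itself is
out of scope. Samples are filtered at deconvolution p < 0.05. Spearman's
rho is computed on average ranks with a two-sided p-value from the
$t$-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$; constant vectors give
a flagged, excluded result. Correlations are computed on case samples by
default — biomarker–immunocyte relationships within the disease cohort —
with an all-samples mode available, since pooling cases and controls can
manufacture correlation from group differences alone. Multiple testing is
BH-adjusted within each gene across cell types, a conservative and simple
convention. Group contrasts use the two-sided Wilcoxon rank-sum test,
exact by enumeration when both groups have at most 10 samples and no ties,
and the tie-corrected normal approximation otherwise.

# Consensus clustering

For each candidate $k$, `H` subsamples of a fraction `p_item = 0.8` of the
case samples are clustered by average-linkage agglomerative clustering on
the $1 - $ Pearson-correlation distance between sample profiles (Euclidean
distance is available; correlation distance matches the expression-pattern
framing of transcriptomic subtyping). The consensus index of a sample pair
is the fraction of co-sampled runs in which it co-clustered; never
co-sampled pairs are assigned consensus 0, a documented convention that is
immaterial at the default `H`.

**Choosing k.** The empirical CDF of the pairwise consensus values is
summarised by its exact area and by the proportion of ambiguous clustering
(PAC): the fraction of consensus values strictly inside $(0.1, 0.9)$. The
default rule selects the $k$ with minimum PAC, ties to the smaller $k$ —
the direct formalisation of choosing the CDF with "minimum fluctuation": a
perfectly stable clustering has all consensus values at 0 or 1 and PAC 0.
A delta-area elbow rule (largest $k$ whose relative area increase exceeds
0.1) is also implemented (`k_rule = "delta"`), but it is not the default
because the area under the consensus CDF keeps growing when clean clusters
are split — on a two-blob benchmark with near-zero noise the delta-areas
for $k = 3 \ldots 6$ are all near or above the threshold, so the elbow rule
over-partitions data that the PAC rule handles exactly. Defaults are
`H = 1000` resamples for analysis (`H = 100` in tests and benchmarks, which
is sufficient for crisp structure) and `k_range = 2:6`. The chosen $k$ is
overridable. Final labels come from hierarchical clustering of
$1 - $consensus.

Subcluster contrasts reuse the rank-sum machinery per gene with BH
adjustment, and are restricted to exactly two clusters; the PCA display is
a plain projection onto the top right singular directions of the
column-centred matrix.

# ceRNA network inference

Candidate competing pairs are all (lncRNA, key mRNA) combinations sharing
at least one miRNA. With $N$ the distinct miRNA count over both interaction
tables (the least ambiguous reading of "total miRNAs in the interaction
data"), $n$ and $m$ the miRNA counts of the mRNA and lncRNA, and $x$ the
shared count, the default test statistic is

$$P \;=\; 1 - \sum_{k=0}^{x} \frac{\binom{m}{k}\binom{N-m}{n-k}}{\binom{N}{n}},$$

the probability of sharing *strictly more than* $x$ miRNAs. This is the
citable form used by the screening convention this package follows; the
conventional $P(X \ge x)$ variant (summing to $x - 1$) is selectable, and
is never smaller. Evaluation is exact and log-stable through the
hypergeometric distribution function — no Monte Carlo — and is verified
against brute-force pmf summation for every valid configuration with
$N \le 12$.

Retained pairs must satisfy $P < 0.01$ (0.05 acceptable via flag; both
gates appear in this screening literature, and the stricter final filter is
the default), Pearson co-expression $> 0.3$, and co-expression p $< 0.01$,
with the co-expression p from the $t$ reference on $n-2$ df. No multiple-
testing correction is applied to the hypergeometric p by default (raw
thresholds are the convention for this screen); BH is available behind a
flag. Co-expression uses all samples by default since competing-RNA
relationships are not group-specific; a case-only mode exists.

The network contains each retained pair, its shared miRNAs, the
corresponding miRNA–target edges, and a direct lncRNA–mRNA competing edge.
Hubs are the lncRNA nodes ranked by degree, then unnormalised shortest-path
betweenness (equal-length paths split evenly), then identifier; betweenness
is verified against a path-enumeration oracle on small random graphs.

# Diagnostics

The ROC curve sweeps all distinct thresholds; the AUC uses the
Mann–Whitney rank formulation with ties counting one half, which equals the
trapezoidal area under the curve to machine precision (an identity the
tests assert on 1,000 random draws). Single-gene ROCs are oriented so AUC
$\ge 0.5$, the standard convention for diagnostic markers. The combined
panel score is an unpenalised logistic model's linear predictor — the
simplest reproducible combination rule; when the fit is unstable (perfect
separation) a small ridge penalty stabilises it, so scoring never fails. A
model-free alternative (mean of sign-oriented per-gene z-scores) is
available. For validation cohorts the default refits per cohort, mirroring
per-cohort ROC presentation; passing a discovery cohort as `train` reuses
discovery coefficients instead.

# The synthetic-data generator

`simulate_cohort()` draws per-gene baseline means from
$\mathcal N(6, 2^2)$ on the log2 scale with i.i.d. Gaussian noise
(sd 0.5 by default) — a deliberately simple stand-in for log2 microarray
intensities that keeps $t$-statistic assumptions exercisable. DE genes
(fraction 0.05 by default) receive a random-signed log2 shift of magnitude
`lfc_mean` jittered by ±25% (`lfc_jitter`); batches receive additive
per-gene offsets ($\mathcal N(0, 0.5^2)$); a curated panel of 63 genes
contains 6 planted key genes, which are additionally shifted in a random
half of the cases to plant a two-subcluster structure — mirroring a
discovery design of roughly two hundred cases and one hundred controls
with a 63-gene panel and 6 key biomarkers. `simulate_fractions()` draws
simplex rows from a symmetric Dirichlet and perturbs one cell type by
$\exp(2\,\text{link\_strength}\,z)$ of a standardised linked gene — a
monotone perturbation giving a tunable rank correlation without claiming
any deconvolution model. `simulate_interactions()` wires each planted
(lncRNA, mRNA) pair to a common random miRNA set and adds independent
background edges, with partner expression drawn bivariate normal at the
target correlation.

What the generator does **not** emulate: probe-level artifacts, heavy-tailed
or count noise, correlated gene modules, compositional coupling between
fractions and expression, GEO file dialects, or single-cell data. Passing
tests therefore demonstrate correctness of the algorithms under clean,
known-truth conditions — not robustness to every pathology of real
transcriptomes.

# Numerical choices and degenerate inputs

- Zero-variance genes with equal group means give $t = 0$, $p = 1$; with
  unequal means the unmoderated statistic is infinite with $p = 0$.
- Undefined correlations (constant vectors) are flagged and excluded from
  extremes rather than propagated as NA surprises.
- The hypergeometric test treats combinatorially impossible terms as
  zero-probability contributions, never errors.
- Tie-breaks: smaller model size in SVM-RFE prefix selection; smaller $k$
  at equal PAC; identifier order for equal-degree, equal-betweenness hubs.
- All stochastic routines are pure functions of their arguments including
  the seed (`withr::with_seed`), so pipeline reruns are byte-identical.
- Benchmark problem sizes used throughout the tests (e.g. 20-sample blob
  benchmarks, 200-gene selection cohorts, $N \le 12$ oracle sweeps) were
  chosen to make planted structure unambiguous while keeping the whole
  suite fast.

# Worked example

```{r example, eval = FALSE}
set.seed(1)
cfg <- pipeline_config(output_dir = "demo_run", seed = 1)
manifest <- run_pipeline(cfg)
manifest$key_genes
```

The run directory then contains the DE table, the selection report, the
immune correlation table, cluster labels and delta-area/PAC summaries, the
ceRNA candidate and hub tables with a GraphML export, per-gene and combined
AUCs, and a `manifest.json` recording seeds, thresholds, the configuration
hash and per-stage record counts.

# Known limitations

- The mean-centering batch correction removes location offsets only and
  assumes batch is not confounded with group.
- The moderated test assumes roughly chi-square-distributed gene variances;
  heavy departures push the prior toward zero weight, gracefully reverting
  to Welch.
- Consensus clustering quality depends on `H`; below ~50 resamples the PAC
  estimate itself is noisy (a warning fires below 10).
- Hypergeometric screening treats interaction tables as ground truth;
  database noise propagates directly into candidate p-values.
- The combined panel's logistic refit on small validation cohorts can be
  optimistic; the `mean_z` rule is the conservative alternative.
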