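# cuprosep

Cuproptosis-related biomarker discovery and ceRNA network inference for
sepsis transcriptomics.

Sepsis outcomes track both immune dysregulation and mitochondrial
metabolism, and copper-dependent cell death (cuproptosis) sits at that
intersection: its effector genes are lipoylated TCA-cycle components.
`cuprosep` is for bioinformaticians who want to screen bulk case/control
transcriptomes (e.g. merged microarray cohorts) for cuproptosis-related
diagnostic biomarkers and characterise them downstream — against immune
cell composition, expression subtypes, and a lncRNA–miRNA–mRNA competing
endogenous RNA (ceRNA) network — with every stage testable against planted
synthetic ground truth.

## What it computes

- **DECuG screening.** Per-gene Welch/moderated *t* on log2 expression after
  per-gene batch-mean correction; a gene is differentially expressed when
  its linear fold change exceeds 1.2 and its Benjamini–Hochberg adjusted
  p-value is below 0.05; DEGs are intersected with a curated cuproptosis
  panel.
- **Dual machine-learning selection.** Key biomarkers are the intersection
  of cross-validated LASSO-logistic selection and linear SVM recursive
  feature elimination (squared-weight criterion, CV-chosen prefix size).
- **Immune correlation.** Spearman ρ between biomarkers and deconvolved
  immune-cell fractions (deconvolution p < 0.05 sample filter), Wilcoxon
  rank-sum group contrasts (exact for small untied groups).
- **Consensus subtyping.** Resampling consensus clustering of case samples
  on the biomarker submatrix; k chosen by minimum proportion of ambiguous
  clustering of the consensus CDF.
- **ceRNA inference.** For each (lncRNA, key mRNA) pair sharing x of the N
  interaction-table miRNAs (n for the mRNA, m for the lncRNA), the
  competing-pair probability

  P = 1 − Σ_{k=0}^{x} C(m,k) C(N−m, n−k) / C(N,n),

  evaluated exactly; pairs are retained at P < 0.01 with Pearson
  co-expression > 0.3 (p < 0.01), assembled into a typed network, and hub
  lncRNAs ranked by degree then betweenness.
- **Diagnostics.** ROC/AUC per gene (Mann–Whitney rank formulation, ties
  half-weighted) and for a combined logistic panel score, on discovery or
  held-out validation cohorts.

## Worked example

```r
library(cuprosep)

sim  <- simulate_cohort(n_case = 60, n_control = 40, n_genes = 1000, seed = 1)
expr <- merge_and_correct(sim$expr)          # equalise batch means
de   <- differential_expression(expr)        # |FC| > 1.2, BH p < 0.05
decug <- intersect_panel(de, sim$truth$panel_genes)
sel  <- select_biomarkers(expr, decug, seed = 1)
sel$key_genes
#> [1] "G0037" "G0471" "G0802" "G0836"
pr <- panel_roc(expr, sel$key_genes)
pr$per_gene
#>        gene       auc
#> G0037 G0037 0.7129167
#> G0471 G0471 0.9795833
#> G0802 G0802 0.9587500
#> G0836 G0836 0.9783333
pr$combined
#> roc_result: AUC = 1.000 (60 positives, 40 negatives)
```

The cohort plants 50 DE genes (8 survive the panel intersection here); the
dual selection returns 4 key genes, all of which are genuinely planted
biomarkers (`sim$truth$key_genes`). Each key gene discriminates case from
control on its own (AUC 0.71–0.98) and the combined logistic panel
separates the groups completely on this cohort. A competing-pair test for
a lncRNA and mRNA sharing 20 of 200 miRNAs:

```r
hypergeom_competing_test(N = 200, n = 24, m = 23, x = 20)
#> [1] 3.58459e-23
```

The full pipeline — preprocessing through ceRNA and ROC, with every
intermediate table and a run manifest written to disk — is one call:

```r
manifest <- run_pipeline(pipeline_config(output_dir = "demo_run", seed = 1))
```

or from a shell, `Rscript inst/scripts/run_pipeline.R --out demo_run --seed 1`
(a YAML config with all thresholds is accepted via `--config`).

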