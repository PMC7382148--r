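# proteorank

Cross-tissue integration and rank aggregation of quantitative
(TMT-style) proteome cohorts, built for the kind of multi-study
Alzheimer's disease analysis where brain cortex, cerebrospinal fluid
(CSF) and serum proteomes — discovery and reference cohorts, human and
mouse — must be combined into one prioritized protein list.

No single small cohort resolves a biomarker panel. What proteorank
quantifies is *consistency*: for a protein observed in $N$ datasets
with significance ranks normalized to $r_i = \mathrm{rank}_i/N_i \in
(0,1]$, the order-statistics score

$$Q = N!\,V_N,\qquad V_0=1,\qquad
V_k=\sum_{i=1}^{k}(-1)^{i-1}\frac{r_{N-k+1}^{\,i}}{i!}V_{k-i}$$

is the joint probability that $N$ independent uniforms would all sit
at or below the observed sorted ranks — small $Q$ means consistently
top-ranked. $Q$ is calibrated by permuting protein labels within each
list ($B = 1000$), pooling null $Q$ per availability stratum, taking
add-one empirical p-values, and adjusting with Benjamini–Hochberg.
Integration is tiered: cohorts → tissue rankings → final list, with a
biofluid-evidence filter before the last step.

Around that core the package provides, as tibble-first functions with
`tidy()`/`glance()`/`autoplot()` methods:

- `read_dataset()` / `write_dataset()` — TSV protein-by-sample
  matrices with sample sheets; strict validation, `NA` (never 0) for
  missing intensities;
- `preprocess_dataset()` — log2 median normalization, erythrocyte
  contamination scoring, Huber residualization (group-protected),
  MAD-based outlier-sample removal, `pca_qc()`;
- `fit_moderated_t()` — empirical-Bayes moderated t (d0/s0² by
  digamma/trigamma moment matching), Z-scored fold changes,
  `bh_adjust()`, `call_de()` with the conventional threshold presets;
- `abundance_rank()` / `depth_detection_curve()` — why low-abundance
  modules need ultra-deep profiling;
- `overlap_de_sets()` / `direction_pattern()` / `annotate_overlap()` —
  cross-tissue and cross-species DE-set comparison with mitochondrial
  fractions;
- `rank_proteins()`, `q_statistic()`, `tiered_integration()` — the
  aggregation engine (permutation core in C++);
- `load_gmt()` / `run_enrichment()` — preranked set-permutation GSEA
  with BH FDR;
- `simulate_study()` / `simulate_mouse_counterpart()` — a synthetic
  multi-cohort generator with planted cross-tissue signatures, a
  correlated low-abundance mitochondrial module, a blood-contamination
  covariate and per-dataset profiling depth, plus the full ground-truth
  manifest;
- `run_pipeline()` — one call from simulation to enrichment, with TSV
  outputs and a seed/hash manifest (`inst/scripts/run-pipeline.R` is a
  thin command-line wrapper).

## Worked example

```r
library(proteorank)

cfg <- sim_config(n_proteins = 600, datasets = default_sim_datasets(600),
                  n_signature = 10, mito_module_size = 20,
                  n_outlier_samples = 3, seed = 11)
res <- run_pipeline(cfg, seed = 11, B_rank = 200, B_gsea = 500,
                    n_random_sets = 10)
res
#> <pipeline_result> 5 datasets; final ranking of 91 proteins; 2/12 sets enriched

# the 3 planted contamination outliers were flagged and removed:
res$preprocessed$csf_disc$outliers
#> [1] "csf_disc_S13" "csf_disc_S14" "csf_disc_S15"

# planted signature proteins concentrate at the top of the final list:
ir <- res$ranking
median(ir$final_rank[ir$protein %in% res$truth$signature_ids]) / nrow(ir)
#> [1] 0.06043956

tidy(res$enrichment)[1:3, c("set", "size", "es", "p_emp", "fdr")]
#> # A tibble: 3 x 5
#>   set                  size    es   p_emp    fdr
#> 1 planted_signature      10 0.912 0.00200 0.0120
#> 2 planted_mito_module    20 0.831 0.00200 0.0120
#> 3 random_01              10 0.761 0.0878  0.230
```

Reading the numbers: after preprocessing and per-dataset moderated-t
DE, the tiered integration retained 91 proteins with biofluid
evidence; the 10 planted signature proteins have median final rank at
the 6th percentile of that list, and both planted gene sets reach
enrichment FDR ≈ 0.012 while the best random set does not (FDR 0.23).
`autoplot()` on the DE results, PCA coordinates, depth curves and the
integrated ranking gives the standard figures.

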