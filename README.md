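# survattrib

Benchmarking post-hoc attribution methods for deep discrete-time
survival models on high-dimensional, transcriptome-like data.

## The problem

When a neural survival model predicts patient risk from gene
expression, which genes drive the prediction? Post-hoc explanation
methods answer differently, and on co-expressed (collinear) gene data
some answers are unstable or wrong. This package is for computational
biologists and methodologists who need to *choose* an attribution
method for survival modeling and want that choice grounded in
measurable criteria rather than habit.

`survattrib` builds the full comparison loop:

- a **self-normalizing survival network** (SNN): four SELU /
  Alpha-Dropout blocks of width 256 and a J-bin discrete-hazard head,
  trained with Adam (lr 2e-4, L1 = L2 = 1e-5) under warmup + early
  stopping with dual checkpoints (lowest validation loss, highest
  validation C-index; the C-index snapshot is preferred);
- **six attribution methods** against that network's forward/gradient
  interface: Integrated Gradients, GradientSHAP, DeepLIFT (Rescale),
  DeepSHAP, ε-rule Layer-wise Relevance Propagation, and permutation
  feature importance (PFI) on the concordance index;
- a **three-axis evaluation** of each method's top-k genes across
  repeated cross-validation: prognostic enrichment (univariate Cox,
  count of p < 0.05), knowledge-base consistency (GMT gene-set hits),
  and explanation stability (mean pairwise Kuncheva index,
  KI = (rn − k²)/(k(n − k)));
- a **min-max composite score** in [0, 3] ranking the methods, plus a
  statistics layer (Friedman with Kendall's W, exact Wilcoxon
  signed-rank, BH correction, Spearman / partial Spearman, bootstrap
  CIs);
- a **synthetic cohort generator** with block co-expression structure
  (one latent factor per block), planted log-hazard effects, and
  uniform censoring, so the whole pipeline runs against known ground
  truth with no downloads.

The model's scalar risk — the quantity every method explains — is the
negative cumulative predicted survival, Risk = −Σ_t S(t), where
S(t) = Π_{l≤t}(1 − h_l) from the network's conditional hazards h_l.

## Worked example

```r
library(survattrib)

cfg <- synthetic_config(n_samples = 300, n_genes = 120, n_blocks = 12,
                        n_prognostic = 10, seed = 7)
cohort <- generate_cohort(cfg)

res <- run_benchmark(
  cohort$expression, cohort$survival,
  methods = c("deepshap", "integrated_gradients", "pfi"),
  k = 30, n_repeats = 1, n_folds = 3,
  training = training_config(max_epochs = 60),
  seed = 42)

aggregate(cbind(c_index, prognostic_count) ~ method, res$metrics, median)
#>                 method  c_index prognostic_count
#> 1             deepshap 0.812246               23
#> 2 integrated_gradients 0.812246               24
#> 3                  pfi 0.812246               26

res$stability[, c("method", "mean_kuncheva")]
#>                 method mean_kuncheva
#> 1             deepshap     0.1851852
#> 2 integrated_gradients     0.1851852
#> 3                  pfi     0.2000000
```

Reading this: each of the 3 folds trains one network (fold C-indices
0.74–0.85; the `c_index` column is per fold, so its median is shared
across methods). Of each method's top-30 genes, 21–27 per fold are
significant univariate Cox prognostic factors (p < 0.05) — far above
the ~1.5 expected for random genes — and each method's top-30 sets
overlap across folds well above chance (KI > 0, where 0 is the
chance-corrected baseline). On a cohort this small and easy the three
methods behave similarly; the methods separate sharply on the harder
default cohort (400 samples, 300 genes, 20 planted genes), where the
gradient/propagation methods recover most planted genes with stability
around 0.25 while PFI trails — see the acceptance suite. Ground truth
for any synthetic cohort is in `cohort$truth$prognostic_gene_ids`.

`benchmark_report(res)` adds the composite ranking and the statistical
comparisons; `write_cohort()` / `read_cohort()` round-trip cohorts as
TSV + GMT + JSON. A thin CLI wrapping these functions is installed at
`system.file("cli", "survattrib", package = "survattrib")` with
subcommands `simulate`, `run`, `report`, `all`.

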