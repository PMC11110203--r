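# plaquekg

Association mining between clinical symptom phenotypes and coronary
artery plaque types (calcified, noncalcified, mixed) on a heterogeneous
clinical–molecular knowledge graph, for researchers working at the
interface of EMR phenotyping and network biology.

The package fuses three layers — a patient-derived symptom/plaque
co-occurrence network, symptom→gene and plaque→gene annotation sets
(GMT), and a confidence-scored protein–protein interaction network
(combined score ≥ 400) — into one graph, then scores every
(symptom, plaque) pair through three channels:

- **topology**: Dijkstra shortest-path distance *d(s,t)* and the
  point-to-network value *e(s)* = ‖profile(s) − centroid‖₂ over the
  vector of distances from *s* to every plaque node;
- **association rules**: Apriori lift
  supp(s∧t) / (supp(s)·supp(t)) over patient transactions, plus a small
  convolutional network trained on per-patient masked lift matrices whose
  predictions are contrasted into a pair-level correction score;
- **biology**: Wang-measure GO semantic similarity between the pair's
  gene sets, combined by best-match average.

Pairs are labelled by a random walk with restart
p ← (1−r)·W·p + r·p₀ seeded at each plaque (the walk's stationary score
is the pair's judgment value) and classified with a k-nearest-neighbour
model (k = 6, stratified 10-fold cross-validation) in three ablation
configurations: A (all channels), B (topology + association), C
(semantic similarity only). Retained pairs define a hub-gene set that
feeds WGCNA-style module detection (soft-thresholded |cor|^β adjacency,
topological overlap, average-linkage clustering, module eigengenes,
module–trait correlation), exact hypergeometric enrichment, and ROC
validation of module signatures on labelled expression data.

A synthetic-study generator with planted associations and expression
modules makes the full pipeline runnable and testable with no external
downloads.

## Worked example

```r
library(plaquekg)

cfg <- generator_config(n_patients = 2000, effect_size = 2,
                        true_pair_density = 0.15, seed = 1)
run <- run_pipeline(cfg, run_modules = FALSE)
run$ablation$summary
#> # A tibble: 3 × 4
#>   config channels          pooled_auc mean_fold_auc
#>   <chr>  <chr>                  <dbl>         <dbl>
#> 1 A      topo+assoc+semsim      0.956         0.969
#> 2 B      topo+assoc             0.956         0.969
#> 3 C      semsim                 0.714         0.735
```

The full-channel model (A) separates walk-labelled positive pairs from
negatives with a pooled cross-validated AUC of 0.956 on this seed, while
semantic similarity alone (C) reaches 0.714 — the ablation ordering the
method predicts. Selection at score cutoff 0.5 recovered 16 pairs, all
16 of them planted ground-truth associations (precision 1.0), with 159
hub genes from their annotation sets:

```r
sel <- run$selection
sel$counts
#>    pairs symptoms  plaques    genes
#>       16       11        3      159
dplyr::inner_join(sel$pairs, run$study$truth$true_pairs,
                  by = c("symptom", "plaque")) |> nrow()
#> [1] 16
```

Downstream, `detect_modules()` on a planted expression design (3 modules
of 40 genes, within-module correlation 0.5, case shift 2 s.d. on module
1) recovers the planted partition with adjusted Rand index ≥ 0.9, and the
module-1 signature separates cases from controls with ROC AUC ≈ 0.99
(`signature_roc()`), falling to ≈ 0.5 when the planted shift is zero.

Result objects are tidyverse-friendly: `tidy()`/`glance()` methods for
cross-validation reports, module assignments and ROC curves, and
`autoplot()` for ROC and ablation curves plus `plot_module_trait()` and
`plot_soft_threshold()` diagnostics.

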