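# microstatr

EEG **microstate** analysis for two-group clinical cohorts, with a fully
synthetic, ground-truth-known test bed.

Resting-state EEG alternates between a few quasi-stable scalp topographies
("microstates", canonically labeled A–D) that persist for tens of
milliseconds. Their temporal parameters — per-class **duration**,
**occurrence** rate, **coverage** and **transition probabilities** — shift
in neurodegenerative disease and track cognitive and cerebrospinal-fluid
biomarkers. This package implements the complete analysis chain used in
clinical microstate studies of Alzheimer's disease, end to end:

* deterministic preprocessing: zero-phase 0.1–40 Hz band-pass + 48–52 Hz
  notch, downsampling to 500 Hz, non-overlapping 2-s epochs, automated
  bad-channel repair, ±100 µV rejection, average reference;
* segmentation: topographies at peaks of the global field power
  `GFP(t) = sqrt(mean_c (v_c - v̄)²)` on a 2–20 Hz copy, clustered by
  polarity-invariant **atomize–agglomerate hierarchical clustering**
  (AAHC) whose centroids are the GFP-weighted first principal axis — the
  exact maximizer of each cluster's **global explained variance**
  contribution `Σ (GFP_t · corr(v_t, T_label(t)))² / Σ GFP_t²`;
* model-order selection by an incremental-GEV-gain stopping rule (with a
  `force_k = 4` override), group-template averaging with optimal
  permutation matching and canonical A–D labeling, per-sample backfitting;
* statistics: Shapiro-gated t / Mann–Whitney-z comparisons with
  Benjamini–Hochberg FDR within metric families, covariate-adjusted
  partial rank correlations, stepwise (p-enter/p-remove) regression;
* classification: CART decision tree on all microstate values, stratified
  8:2 split, five-fold cross-validation, ROC/AUC;
* a synthetic-cohort generator (semi-Markov gamma-dwell label dynamics,
  alpha-carrier topographies, spatially correlated sensor noise, planted
  group effects and metric–covariate correlations) so every stage is
  testable against known ground truth.

## Worked example

Segment one synthetic recording and recover its generating structure:

```r
library(microstatr)

lay  <- make_layout(60)                         # 60-sensor scalp cap
tmpl <- make_templates(lay, k = 4, seed = 1)    # ground-truth maps
dyn  <- dynamics_spec(k = 4, mean_dwell = 0.07) # 70 ms gamma dwells
lab  <- simulate_labels(dyn, n_samples = 30000, sfreq = 500, seed = 1)
rec  <- synthesize_recording(tmpl, lab, snr = 5, sfreq = 500, seed = 1,
                             layout = lay)

ep  <- average_reference(make_epochs(
         apply_filters(rec, band = c(2, 20), notch = NULL), 2))
seg <- run_microstate_analysis(ep, seed = 1)
seg$k
#> selected k: 4
seg$clustering$sets[["4"]]$gev
#> GEV at k = 4: 0.97
apply(abs(seg$templates$maps %*% t(tmpl$maps)), 2, max)
#> template recovery |r|: 0.998 0.998 0.999 0.999
```

The incremental-gain rule recovers the four generating classes, and the
AAHC templates match the ground-truth maps at |r| ≥ 0.998. Backfitting and
`compute_metrics()` then give durations/occurrences/coverages whose
identities (`coverage = duration × occurrence`, coverages summing to 1)
hold to 1e-9.

Cohort-level statistics on a default 56-case / 38-control cohort (class-C
dwell lengthened by 6 ms in the case group; ρ = −0.40 planted between
class-C duration and CSF Aβ₁₋₄₂):

```r
ch  <- simulate_cohort(cohort_spec(seed = 1), lay, tmpl, dyn)
tab <- compare_groups(ch$metrics, "group",
                      families = list(duration = paste0("duration_", LETTERS[1:4])))
#>    variable mean_1 mean_2         test statistic p_raw p_fdr
#>  duration_A 0.0694 0.0715            t    -0.991 0.324 0.324
#>  duration_B 0.0689 0.0701 mann-whitney    -1.048 0.295 0.324
#>  duration_C 0.0746 0.0688            t     2.312 0.023 0.092
#>  duration_D 0.0703 0.0674            t     1.272 0.206 0.324
```

Only the class with the planted effect reaches raw significance
(p = 0.023); at this realistic effect size (d ≈ 0.5) the FDR-adjusted
value is borderline, as it is in published cohorts. The partial rank
correlation adjusted for sex, age and education recovers the planted
negative association in attenuated form
(`rho = -0.245, p = 0.0765, n = 56` for one seed; across seeds the
estimate is centered near the Spearman image of −0.40), and
`classify_cohort()` reports the per-class precision/recall/F1/support
table, CV fold accuracies and AUC for a decision tree on all 28
microstate features — near chance (accuracy 0.53, AUC 0.49 here) when the
only group signal is one weak duration shift, which is the honest
expectation for these conditions.

A complete run — simulation, preprocessing, segmentation, statistics,
classification, with every table and a provenance record written to disk —
is one call:

```r
run_pipeline(default_config(), out_dir = "demo-out")
```

or, from a shell, `Rscript inst/scripts/microstate_pipeline.R all
--seed 1 --out demo-out` (YAML configuration via `--config`).

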