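---
title: "EEG microstate analysis with microstatr: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG microstate analysis with microstatr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstatr)
```

## The model

Resting-state EEG spends most of its time in one of a handful of
quasi-stable scalp potential topographies — *microstates* — that persist
for tens of milliseconds before switching abruptly. The package
implements the standard analysis chain for characterizing them:

1. **Preprocessing** — zero-phase band-pass (0.1–40 Hz) and notch
   (48–52 Hz) filtering, downsampling to 500 Hz, segmentation into
   non-overlapping 2-s epochs, automated bad-channel repair, ±100 µV
   epoch rejection, whole-head average reference.
2. **Segmentation** — the global field power
   $\mathrm{GFP}(t) = \sqrt{\tfrac1C\sum_c (v_c(t)-\bar v(t))^2}$
   is computed on a 2–20 Hz copy of the epochs; topographies at GFP peaks
   are clustered by polarity-invariant atomize–agglomerate hierarchical
   clustering (AAHC); the number of classes $k$ is chosen by an
   incremental-gain rule on the global explained variance (GEV).
3. **Backfitting and dynamics** — each sample is assigned to the template
   with the highest absolute spatial correlation; label runs yield per-class
   *duration* (s), *occurrence* (s⁻¹), *coverage*, and jointly normalized
   *transition probabilities*.
4. **Statistics** — two-group comparisons (Shapiro–Wilk-gated t /
   Mann–Whitney U with tie-corrected z), Benjamini–Hochberg FDR within
   metric families, covariate-adjusted partial rank correlations, stepwise
   linear regression.
5. **Classification** — a CART decision tree on all per-subject microstate
   values, stratified 8:2 split, five-fold cross-validation, ROC/AUC.

### AAHC and its centroid

Peak maps start as singleton clusters. At every step the cluster with the
lowest GEV contribution is *atomized*: its members are freed and
reassigned, one by one, to the surviving cluster whose centroid they
correlate with most strongly in absolute value; centroids of clusters that
gained members are then recomputed. For average-referenced maps $m_i$ the
contribution of a cluster with template $\hat t$ is
$\sum_{i \in c}\bigl(\mathrm{GFP}_i\,\mathrm{corr}(m_i,\hat t)\bigr)^2
 = \tfrac1C\sum_{i\in c} (m_i^\top \hat t)^2$,
which is maximized exactly by the first principal axis of the cluster's
scatter matrix $\sum_i m_i m_i^\top$. The package therefore uses that
principal axis as the centroid: it is simultaneously the GEV-optimal
template and immune to polarity flips (the scatter matrix is invariant
under $m_i \to -m_i$). On small problems the resulting GEV equals the
exhaustive best partition (verified in the test suite by complete
enumeration over two-cluster partitions of eight maps).

Determinism is pinned by explicit tie rules: the atomization victim with
equal contribution is the cluster with fewer members, then the lowest
index; reassignment ties go to the lowest cluster index.

### Choosing k

GEV is recorded at every $k$ from 8 down to 2; the selected $k$ is the
smallest whose gain to $k+1$ falls below `gev_gain_threshold` (default
0.01), or `k_max` if the gain never drops below it. A `force_k` override
reproduces the fixed $k=4$ convention of the clinical literature; the
canonical labels A–D are assigned by optimally matching the averaged
group templates against built-in idealized gradients (two diagonal maps,
an anterior–posterior map, a central-peaked map).

## The synthetic cohort generator

Because the analysis must be testable without patient data, the package
generates cohorts with known ground truth:

* **Layout** — a deterministic Fibonacci-spiral cap of `n_channels`
  sensors on the upper unit hemisphere (z ≥ −0.2).
* **Templates** — differences of Gaussian blobs at antipodal points,
  average-referenced and unit-normalized; candidates with pairwise
  |spatial correlation| ≥ 0.8 are redrawn.
* **Label dynamics** — a semi-Markov chain: gamma-distributed dwell times
  (mean `mean_dwell` = 70 ms, coefficient of variation
  `dwell_dispersion` = 0.5) with successor classes drawn from a
  zero-diagonal transition-weight matrix. Gamma rather than geometric
  dwell decouples mean from dispersion, matching the over-dispersion of
  empirical dwell distributions.
* **Signal** — the active template carried by a 10 Hz oscillation
  $\sin(2\pi f t + \pi/4)$ scaled to 15 µV. The GFP then follows the
  rectified $|\sin|$ amplitude envelope with two peaks per cycle
  (≈ 20 s⁻¹ at 10 Hz, the realistic GFP peak rate), and the field
  polarity reverses every half-cycle — the physical reason microstate
  clustering treats a map and its negation as the same state. The π/4
  phase offset keeps the 500 Hz sample grid away from exact carrier
  zeros, where the topography would carry no class information.
* **Noise** — white sensor noise smoothed across neighboring channels
  with a Gaussian kernel of the inter-sensor distance (making
  bad-channel detection nontrivial), scaled so that
  RMS(signal)/RMS(noise) equals `snr`.
* **Covariates** — demographic, cognitive and CSF columns drawn per group
  at the scale of a typical AD/HC cohort; requested metric–covariate
  correlations are planted by the exact mixture
  $\mathrm{cov} = \rho\, z(\mathrm{metric}) + \sqrt{1-\rho^2}\,
  z_{\mathrm{noise}}$, so the target ρ is analytic. The default cohort is
  56 cases / 38 controls with the case group's class-C dwell lengthened
  by 6 ms and ρ = −0.40 (duration_C vs CSF Aβ₁₋₄₂) and +0.45 (duration_C
  vs Stroop dot-naming) planted.

### Choosing the default noise level

GEV is GFP²-weighted, so high-envelope samples — which also have the best
instantaneous signal-to-noise — dominate it; the backfit GEV is therefore
far less sensitive to broadband noise than a naive variance argument
suggests. Measured on the default generator, recording-level `snr` of 2
still yields GEV ≈ 0.94. The default `snr = 0.5` was calibrated so that
synthetic cohorts land where real resting-state cohorts do (group-mean
GEV ≈ 0.77–0.79, i.e. the non-microstate background is comparable to the
template-locked component). Model-order selection is unaffected: the
4-class structure is still recovered at `snr = 0.5`.

### What the generator does *not* emulate

No ocular or muscle artifacts (hence no ICA; the preprocessing hook
accepts externally computed decompositions but never computes one), no
volume-conduction forward model, no 1/f background spectrum, no
inter-regional phase structure — the whole field passes through the
carrier's zeros simultaneously, which real multi-generator EEG does not
do. Consequently, passing tests demonstrate correctness of the algorithms
under the stated model, not clinical validity on real recordings.

## Numerical choices and degenerate inputs

* Zero-phase (forward–backward) Butterworth filters throughout, so
  microstate boundaries are never phase-shifted; the DC offset is removed
  before high-pass filtering to shrink edge transients.
* Average reference is enforced before every topographic computation;
  maps with zero spatial variance raise an explicit undefined-correlation
  error in correlation, and inherit the neighboring label during
  backfitting (next valid label at epoch starts).
* Truncated epoch-edge runs are *included* in duration averages, which
  keeps the identity coverage = duration × occurrence exact to 1e-9; the
  flags are stored so the alternative can be computed.
* Transition probabilities are normalized jointly over all ordered class
  pairs (zero diagonal), so the off-diagonal entries sum to 1; zero
  observed transitions yield missing values, not zeros.
* `mean_duration` is defined as total labeled time / total number of
  runs. (Published tables sometimes print a "mean duration" exceeding
  every per-class duration, which no weighted mean of class durations can
  do; this package's definition is the arithmetically consistent one.)
* Bad-channel rules are automated surrogates for visual criteria:
  amplitude and flat-line rules use a 20% epoch-fraction threshold, and
  the neighbor-deviation rule compares each channel to the mean of its 4
  nearest neighbors *that passed the first two rules*, so one loud
  channel cannot implicate its whole neighborhood. More than 25% bad
  channels aborts with a data-quality error.

## Segment fragmentation and `min_segment_ms`

Per-sample argmax backfitting is exquisitely sensitive to isolated label
flips: a flip rate of a few percent — inevitable near GFP troughs, where
the template component vanishes while noise and filter ringing do not —
multiplies the run count several-fold and collapses mean durations (at
`snr = 5`, ≈ 19 ms observed against a configured 70 ms dwell). This is a
known property of microstate segmentation and the reason the field's
toolboxes offer minimum-segment smoothing. The package follows the
convention of applying *no* smoothing by default (`min_segment_ms = 0`);
with `min_segment_ms = 20` the configured dwell is recovered within 15%
at `snr ≥ 5`. Group *differences* in dwell survive fragmentation in
attenuated form, which is why the statistics stage detects the planted
class-C prolongation from ground-truth metrics far more powerfully than
from heavily fragmented backfit metrics.

## Statistical conventions

* Normality gating: Shapiro–Wilk at α = 0.05 in *both* groups selects the
  equal-variance t-test; otherwise a Mann–Whitney U with tie-corrected
  normal approximation, reported as z. Two-sided throughout.
* FDR families follow the metric blocks (global, durations, occurrences,
  coverages, transitions). The family partition changes adjusted p-values
  and is therefore stored with every result row.
* Partial rank correlation: rank-transform, residualize on
  [1, covariates], Pearson-correlate residuals — the SPSS-compatible
  "partial Spearman". With no covariates it equals Spearman exactly.
* Stepwise regression uses p-value entry/removal (defaults 0.05/0.10,
  the SPSS convention); collinear candidates are blocked by a rank check.
  Both standardized and unstandardized coefficients are reported, with
  95% confidence intervals on the latter.
* The classification split is stratified even though an unstratified
  "random split" is the literature convention, because with a 38-subject
  control group an unstratified 20% draw can produce unusable partitions.
  The tree is CART/Gini with no depth limit, minimum leaf 1 and no
  hyperparameter tuning; cross-validation estimates generalization while
  the reported model is refit on all training data.

## Problem sizes used by the test-suite

The suite exercises the full chain at desk scale: 20-seed model-order
recovery on 60-channel, 60-s recordings; an end-to-end 20-subject demo at
19 channels and 60 s; null calibration over 200 replicate cohorts of
30 + 30 subjects at 15 s using ground-truth label sequences (no raw EEG
synthesis, which the metrics never require); and exhaustive-enumeration
oracles on ≤ 8 maps. These sizes were chosen to make every property
measurable in seconds to minutes while keeping sampling error well below
the asserted tolerances.

## Known limitations

* AAHC is a greedy heuristic; global GEV optimality is guaranteed only on
  the small enumerable problems the oracle suite covers.
* The EDF writer/reader supports the continuous, common-sampling-rate
  subset of the format (16-bit, one physical range per channel); FIF is
  not supported.
* Stepwise selection inherits the known inferential caveats of p-value
  driven model search; the selection trace is reported so any model can
  be audited or replayed.
* With two classes and small test sets, the tree's ROC is built from few
  distinct leaf probabilities and the AUC is correspondingly coarse.
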