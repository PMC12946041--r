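---
title: "Quantifying the sustained posterior negativity: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the sustained posterior negativity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spnlab)
```

`spnlab` implements the complete statistical machinery of a brief-exposure
visual symmetry EEG experiment: parametric octagon stimuli, a synthetic
study generator, automated epoch screening, spatiotemporal cluster-based
permutation inference, SPN quantification, signal-detection behavior, and
trial-subsampling reliability. This vignette explains the models behind
each stage, the parameters that matter, and the choices we made where the
design was genuinely open.

## The scientific setting

Mirror-symmetric visual patterns evoke a *sustained posterior negativity*
(SPN): from roughly 250 ms after stimulus onset, event-related potentials
(ERPs) over occipito-parietal sensors are more negative for symmetric than
for asymmetric patterns. The analysis problem has two linked parts:

1. **Detection** — find where and when symmetric and asymmetric ERPs
   diverge, without pre-committing to a latency or scalp region. The
   standard tool is the cluster-based permutation test, which controls the
   family-wise error rate over the full electrode-by-time grid.
2. **Quantification** — once an effect exists, summarize it per participant
   as the mean S − A amplitude difference over a region of interest (ROI),
   either data-driven (the significant cluster) or canonical (O1, O2, Oz,
   PO3, PO4, PO7, PO8 in 250–600 ms), and relate it to behavior.

## Stimulus generator

Stimuli are octagons inscribed in a circle of radius 0.75 degrees of visual
angle. Every vertex of the regular template is rotated about the origin by
an angular jitter uniform on ±20°, keeping the radial distance fixed.
Asymmetric stimuli jitter all eight vertices independently. Symmetric
stimuli jitter two *anchors* — one from each reflection orbit of the
template — and generate the other six by reflections across the
object-frame vertical and horizontal axes; the shape is then rotated by 45°
or 135°, so both mirror axes are oblique on the display.

Geometric guarantees, all tested:

* every vertex sits at radius 0.75 to within 1e-9, in both conditions;
* symmetric stimuli pass an exact reflection check about both display axes;
* jittered asymmetric stimuli are essentially never accidentally symmetric;
* when a symmetric stimulus is elongated, its principal axis (eigenvector
  of the second-moment tensor) coincides with one of its mirror axes.

One geometric subtlety is worth recording. Because six symmetric vertices
are reflections, half of the polygon's vertex gaps carry a uniform ±40°
perturbation (2 × jitter of one anchor) where the independent construction
gives a triangular one. Mean perimeter and area therefore differ between
conditions by a small *intrinsic* amount — about 0.5% and 2% respectively —
not by sampling error. Radial extent ("global size") is matched exactly.
Tests assert the practical property (relative difference below 3%) rather
than an exact distributional match, which this construction cannot deliver.

## Synthetic study generator

The generator (`sim_config()`, `simulate_behavior()`, `simulate_epochs()`)
exists so that every downstream stage is exercisable, at the study's scale,
without any recordings. Its defaults are the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_participants` | 23 | cohort size after exclusion |
| `n_trials` | 120 | trials per participant, ~50/50 split |
| `dprime_mean`, `dprime_sd` | 1.88, 0.65 | population sensitivity (d′ ≥ 0, truncated) |
| `criterion_mean`, `criterion_sd` | −0.14, 0.23 | population bias (negative = liberal) |
| `spn_amp_mean`, `spn_amp_sd` | −0.45, 0.63 µV | group SPN and between-subject SD |
| `spn_window_ms`, `spn_peak_ms` | 250–600, 390 | temporal support and peak |
| `spatial_sigma_mm` | 45 | Gaussian footprint of the effect |
| `noise_sd_uv` | 5 | per-trial, per-channel noise SD |
| `noise_exponent` | 1 | 1/f^χ spectral slope |
| `fs_hz`, `epoch_span_ms` | 256, −500…1000 | sampling grid |

Behavior follows the equal-variance Gaussian signal-detection model: a
participant with sensitivity d′ and criterion c responds "symmetric" with
probability Φ(d′/2 − c) on symmetric trials and Φ(−d′/2 − c) on asymmetric
trials. With the default population values this implies ~82.4% accuracy,
consistent with the behavioral summaries the pipeline later computes.

Epochs are 1/f noise plus condition-common P1/N1-like deflections (+2.5 µV
at 110 ms, −3 µV at 170 ms — chosen as typical early-component amplitudes;
they cancel exactly in S − A) plus, on symmetric trials, the SPN itself.
Three generator choices deserve explanation:

* **Calibrated amplitude.** The SPN's spatial profile is a Gaussian in
  sensor distance to the canonical-ROI centroid, *re-centered to zero mean
  across the montage* (an average-referenced scalp field is mean-zero, so
  a posterior negativity must be balanced by diffuse anterior positivity),
  and the spatio-temporal profile is normalized so the mean over the ROI
  electrodes × window equals the subject's amplitude exactly. Consequences:
  re-referencing and baseline correction leave the injected amplitude
  invariant, and "recover −0.45 µV" is a well-posed parameter-recovery
  check rather than a moving target. A side effect of the mean-zero field
  is a genuine anterior positive counterpart that the cluster test may
  detect as a (much weaker) positive cluster; real average-referenced data
  behave the same way.
* **Noise scale.** `noise_sd_uv = 5` represents cleaned single-trial
  posterior EEG after 0.5–40 Hz band-passing and ICA artifact removal.
  With ~49 correct trials per condition this adds ≈0.15 µV of trial noise
  to each subject's SPN estimate — small against the 0.63 µV
  between-subject SD, so the implied effect size stays near d_z ≈ −0.7.
* **Injection on all symmetric trials.** The correct-only filter is still
  exercised (incorrect trials are removed before averaging), but the
  generative model stays simple; `inject_correct_only = TRUE` switches to
  injection on correct trials only.

Seeding is counter-based: the master seed expands into substreams per
(purpose, participant) — and per (m, permutation, participant) in the
reliability module — so any subset of the simulation is reproducible in
isolation. What the generator does *not* emulate: volume conduction from
dipolar sources (channels are spatially independent in their noise), eye
and muscle artifacts, drifts, and trial-to-trial latency jitter of the
components. Passing tests therefore validate the *statistics*, not the
biophysics.

## Preprocessing and epoch screening

`baseline_correct()` subtracts each channel's −200–0 ms mean;
`rereference_average()` subtracts the scalp-channel mean per sample. Both
are linear projections on disjoint axes and commute (tested). Windows are
specified in ms and mapped to the 256 Hz grid with inclusive endpoints.

`screen_epochs()` implements the three automated rejection criteria on
scalp channels:

* **amplitude**: any |value| > 120 µV within −200–600 ms;
* **trend**: a least-squares line over the full epoch whose *total fitted
  change* exceeds 75 µV with R² > 0.50. The threshold is in µV, not µV/s,
  which identifies it as change-over-window — the convention of
  minimal-slope rejection in common EEG practice;
* **kurtosis**: per channel × epoch excess kurtosis, z-scored within
  participant — per channel across epochs ("local") and as the
  across-channel mean per epoch ("global") — flagged at |z| > 7. The
  z-scoring axes are our documented interpretation of the tool-flavored
  "local/global" shorthand; the threshold and the local/global distinction
  are as stated.

Correctness filtering precedes the quality screen, matching the stated
order. The order matters: kurtosis z-scores depend on which epochs are
present, and the tests include a constructed counter-example where
swapping the two stages changes the retained count.

## Cluster-based permutation inference

Per participant, trials are averaged within condition; condition
differences are tested point-wise with a paired t (equivalently a
one-sample t on S − A differences, df = n − 1). Samples with two-tailed
p < 0.05 are clustered: spatial neighbors (sensors < 35 mm apart) at the
same time sample, plus adjacent time samples at the same sensor — no
diagonal links, the common sensor-time default. Cluster mass is the sum of
t values; members share sign.

Family-wise error is controlled with the max-statistic null: each
permutation flips the sign of every subject's whole difference map
independently (the within-subject exchange of condition labels), and the
maximum |mass| over that permutation's clusters is recorded. A cluster's
corrected p is (1 + #{null ≥ |mass|}) / (B + 1), significant at p ≤ 0.05 —
one conservative two-sided convention through a single absolute-mass null.
Design notes:

* The exchange unit is the subject (sign-flip of difference maps), the
  standard within-subject scheme. Zero-variance points get t = 0 rather
  than ±∞ so degenerate synthetic inputs cannot form spurious clusters.
* Sensors with no neighbor under 35 mm (TP9/TP10 on the packaged montage)
  stay in the graph; they can only ever form single-sensor clusters.
* `exhaustive_null()` enumerates all 2^n sign assignments (n ≤ 16) and is
  the ground-truth oracle for the Monte Carlo engine; the suite checks
  agreement to ±0.02 at B = 5000 and family-wise error calibration over
  200 zero-effect datasets at a reduced grid (16 channels × 64 samples ×
  12 subjects — sizes chosen to make 200 × 1000 permutations cheap while
  keeping the graph non-trivial).

The packaged montage is a synthetic idealization: standard 10-20/10-10
proportional geometry on a 94 mm sphere, with TP9/TP10 at mastoid level as
they are physically mounted on a 64-channel actiCAP (on the idealized
sphere ring they would have neighbors, contradicting the cap's actual
isolation at 35 mm). At 35 mm it yields a mean of ~3.8 neighbors per
sensor with TP9/TP10 isolated.

## SPN quantification, lateralization, behavior

`spn_amplitude()` follows the fixed order: window mean per electrode per
condition → electrode-wise S − A difference → mean over electrodes. All
steps are linear so the order cannot change the value (a regression test
asserts agreement with the reversed order to 1e-12); fixing it makes
reports reproducible to the digit. The cluster-derived ROI is always
recomputed from the pipeline's own cluster output, never hard-coded.

Lateralization indices normalize a right-minus-left difference by the sum
of absolute hemispheric means, so defined values lie in [−1, 1]. The
hemispheric sets are the ROI electrodes with odd (left) and even (right)
10-20 suffixes, midline excluded — the conventional reading of "the same
left- and right-hemisphere electrode sets". The condition-based variant
returns two values per participant (one per condition), and its one-sample
test pools them (2n observations), matching a t with df = 2n − 1 for
n participants; this pooling is an interpretation inferred from the
degrees of freedom such analyses report, and is flagged as such.

Signal-detection metrics clamp hit and false-alarm rates to
[1/(2N), 1 − 1/(2N)] per class before the inverse-normal transform — the
simple standard correction. The chance gate uses the binomial (1 − α)
quantile convention, which yields 69/120 at α = 0.05; the strict
tail-test convention (smallest k with P(X ≥ k) < α) gives 70 and is
available behind `rule = "strict"`. Pearson correlations carry Fisher-z
intervals with SE 1/√(n − 3), and `correlation_power()` implements the
matching two-sided power approximation.

## Fixed-cohort subsampling reliability

For each per-condition count m and permutation, the module draws without
replacement m symmetric and m asymmetric trial-level ROI means within every
participant, forms each participant's SPN as mean(S) − mean(A), and runs a
one-tailed t test (H₁: SPN < 0). Reliability at m is the proportion of
permutations with p < 0.05, with an exact Clopper–Pearson interval; the
mean SPN across permutations and its 2.5–97.5% band are reported alongside.
The cohort is fixed and balanced, so the largest testable m is capped by
the participant with the fewest usable epochs in either condition.

Trial-level ROI means are computed once and resampled as scalars — the
average of averages is identical to re-averaging the epochs, and the
permutation loop becomes trivial arithmetic. Note a statistical subtlety
the tests respect: *within one dataset* the permutations share the cohort,
so a single dataset's reliability is not a binomial draw around the test
level; the null calibration test therefore draws one permutation from each
of many independent zero-effect cohorts.

## Numerical conventions and degenerate inputs

* Windows are ms intervals, inclusive of the nearest grid sample at or
  inside each bound; sample indices never appear in interfaces.
* Zero-variance t statistics, zero-denominator lateralization indices, and
  zero-variance correlations are flagged (t = 0 / NA with a warning), not
  propagated as infinities.
* Peak latency ties break to the earliest sample.
* The permutation p estimator includes the observed labeling, so p is
  never zero; with B permutations the smallest attainable p is 1/(B + 1).
* Reflection-coincident vertices in the stimulus generator (probability
  zero events at the jitter boundary) are rejected and resampled.

## Problem sizes used by the test suite

The suite validates the statistics at sizes a laptop handles comfortably:
family-wise error over 200 reduced-grid null datasets at B = 1000; oracle
agreement on an 8-subject instance (2^8 enumerable); parameter recovery on
20 full-scale cohorts (23 × 120 trials × 64 channels); 10,000 stimuli for
the geometric guarantees; one full-scale cohort for the subsampling curve
at B = 500. `scripts/acceptance.R` re-runs one full cohort end-to-end with
B = 2000 cluster permutations and B = 1000 subsampling permutations.

## Known limitations

* The generator's channels carry independent noise; real EEG is spatially
  correlated through volume conduction, which typically makes cluster
  tests *more* powerful spatially than the synthetic case suggests.
* The canonical-ROI calibration of the injected amplitude means recovery
  checks are exact for that ROI; the cluster-derived ROI recovers a
  slightly different (usually similar) value because its electrodes and
  window are data-driven.
* Continuous-data preprocessing (filtering, line-noise removal, ICA,
  interpolation) is out of scope; the pipeline starts from epoched data.
* Bayesian effect summaries (Bayes factors, HDIs) are not implemented;
  frequentist intervals and effect sizes are.
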