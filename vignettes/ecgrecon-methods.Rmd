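---
title: "Reconstructing 12-lead ECGs from reduced lead sets: models, measurement and the regression-to-the-mean evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing 12-lead ECGs from reduced lead sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A standard clinical ECG has 12 leads, but only 8 carry independent
information: the four "augmented" limb leads are exact linear combinations of
leads I and II (Einthoven/Goldberger relations, implemented in
`derive_limb_leads()`). Wearable devices record one lead (typically lead I)
or two (I and II). Both lie in the frontal plane of the cardiac dipole;
the precordial chest leads (V1–V6) additionally see the anterior–posterior
(z) component, which is close to orthogonal to lead I. The question this
package operationalises is whether a deep network can nevertheless recover
the precordial leads from the frontal ones — and, more importantly, how such
a claim should be *evaluated*. The package's statistical battery is designed
around a specific failure mode: a network that cannot recover subject-specific
spatial information can still achieve a low average error by predicting
something close to the population-mean waveform, modulated by the input lead.
That behaviour — regression to the mean — looks excellent on RMSE but is
clinically useless, because precisely the individual deviations (e.g. ST-level
shifts orthogonal to the input lead) are what diagnosis needs.

## Synthetic cohorts from a dipole model

`generate_cohort()` renders records from an explicit cardiac-dipole model
(`dipole_model()`): each wave (P, Q, R, S, T) is a Gaussian bump per spatial
axis, an explicit ST plateau sits between the J point and T onset (so ST-level
markers have nonzero targets), and the 8 independent leads are fixed
unit-vector projections of the dipole. Leads I and II project only frontal
(x, y) components; V3's projection is dominated by z and is therefore nearly
orthogonal to lead I, mirroring the geometry that makes single-lead
reconstruction hard. Limb leads are always derived, never simulated, so the
lead-algebra identities hold exactly in every record.

Subjects vary (`population_config()`, `sample_subject()`) in heart rate
(Normal(70, 10) bpm truncated to (45, 120)), electrical-axis rotation
(azimuth and elevation Normal(0, 25) degrees), per-wave per-axis amplitude
multipliers (log-normal, coefficient of variation 0.35), a shared habitus
factor `global_scale` (log-normal, sigma 0.2), RR jitter, white measurement
noise (5–15 uV) and sinusoidal baseline wander (20–60 uV at 0.15–0.4 Hz).
Amplitudes were chosen so the mean marker values land in normal adult ranges
(R in V3 around 1 mV, S in V2 around 1 mV, T in V3 around 0.5 mV, ST levels
of tens of uV). Two structural properties matter more than any single value:

* **Weak inter-lead amplitude coupling.** Because the per-axis amplitude
  multipliers are independent, the R amplitude in lead I shares little
  information with the R amplitude in V3; only `global_scale` (and, weakly,
  the axis rotation) couples them. Under the defaults the squared correlation
  between R(I) and R(V3) stays below 0.2 — the regime real normal ECGs show —
  and setting `shared_sigma = 0` drives it below 0.05. This is the property
  that makes faithful reconstruction genuinely hard and the evaluation
  informative.
* **Ground-truth fiducials.** Every record carries per-beat fiducials
  computed from the *continuous* model at 0.1–0.2 ms resolution, using the
  same conventions the sample-domain delineator implements. They are never
  re-detected from the samples, so the measurement module can be validated
  against them, standing in for the commercial measurement system the package
  deliberately avoids.

The first beat starts 0.35 s into the record (clear of the delineator's edge
margin); subsequent onsets follow the subject's RR with jitter. The T wave is
rate-adapted by scaling its latency from the J anchor and its width by
sqrt(RR / 857 ms), keeping beats well formed across the heart-rate range.

What the generator does *not* emulate: pathology (infarction, conduction
blocks), non-dipolar local potentials (e.g. fractionated QRS), respiration,
electrode motion artefacts, or realistic coloured noise. Tests passing on
these cohorts therefore show that the pipeline's algebra, optimisation,
measurement and statistics behave as specified — not that any conclusion
transfers quantitatively to a real cohort.

## Measurement without a proprietary oracle

Commercial systems (the usual measurement oracle in this literature) are
closed; the package ships an open, deterministic delineator with documented
conventions, applied identically to real and reconstructed records:

* Beat detection on one designated lead (default II): 5–25 Hz zero-phase
  band-pass, squared derivative, 150 ms integration, threshold at 20% of the
  integrated maximum, 200 ms refractory period.
* All landmark placement on the *RMS composite* of the (configurable) lead
  set, baseline-corrected per beat and floor-subtracted. A single lead is not
  identifiable for this purpose: an unlucky axis rotation can cancel the S,
  T or even R deflection in any one lead, while the 3D dipole cannot vanish
  in all eight at once.
* R anchor: earliest composite local maximum within 75% of the QRS-window
  maximum (with parabolic peak-height interpolation on the sampled side), a
  deterministic tie-break for morphologies where the R and S deflections have
  comparable composite magnitude.
* On/offsets (QRS onset/offset, P onset): first point where the composite
  stays below 5% of the relevant peak for at least 8 ms.
* T end by the tangent method (steepest downslope extrapolated to baseline);
  T onset placed symmetrically; ST-midpoint marker (STM) at the temporal
  midpoint of J point and T onset — the exact rule used by commercial systems
  is unpublished, so this explicit convention keeps results comparable across
  runs.
* Amplitudes per lead relative to the PR-segment median baseline (R and S as
  positive magnitudes, T signed); intervals (RR, QT, PR, QRS duration) from
  the shared fiducials; per-record values are medians over beats, the open
  analogue of measuring on a median beat.

On noise-free cohorts the delineator recovers the generator's analytic
fiducials to within ~2 samples and amplitude markers to within 2% (10 uV
floor for markers near zero, where "R amplitude" in a lead without a positive
deflection is ill-defined); intervals agree within 4 ms.

When reconstructions are evaluated (`evaluate_reconstruction()`), both real
and reconstructed records are measured fully independently, but the *input*
leads are excluded from the landmark composite. This keeps the two
measurements informationally symmetric and makes the population-mean
baseline's markers exactly constant across subjects, which is the analytic
extreme the verdict is calibrated against.

## Reconstruction models

The generator (`build_generator()`) is a 1D U-Net: six strided convolutions
(leaky rectifier, reflection padding) halve-or-fifth the time axis down to a
bottleneck, six upsample-convolutions (rectifier) rebuild it, skip
connections join down-block *i* to up-block *6 − i*, the output activation is
a hyperbolic tangent, and inverted dropout (rate 0.5) acts on the three
deepest up-blocks during training. Signals are scaled by `amplitude_scale`
(default 6000 uV, covering physiological R amplitudes with headroom) so the
tanh range is meaningful. Because six stride-2 stages would require lengths
divisible by 64 — which neither 5000 nor 2000 samples is — the stride ladder
defaults to (2, 2, 2, 5, 5, 5), whose product 1000 divides both supported
geometries; any other ladder can be configured. Two presets exist: `full`
(channels 32–512, kernel 15, 5000 samples) and `desk` (channels 24–96,
kernel 9, 2000 samples), the latter sized for single-CPU training in minutes.

The discriminator (`build_discriminator()`) is a patch critic: seven strided
convolutions with leaky rectifiers and a linear head score a randomly
positioned 8-lead x 800-sample patch, one offset per training batch, shared
between the real and generated batch so the comparison is aligned. With the
Wasserstein objective the head is unsquashed (a critic); a sigmoid head is
available for the probabilistic variant. All forward and backward passes —
including the exact double-backpropagation of the gradient penalty — are
implemented against compiled batched conv1d kernels and verified against
finite differences in the test suite.

## Training

`train_gan()` optimises the critic with the Wasserstein loss plus gradient
penalty (weight 10) and the generator with the adversarial score plus an L1
reconstruction term (weight 100); the penalty and L1 weights follow the
canonical values of the objectives this combination descends from, since no
specific weights are otherwise established, and are config-overridable. Adam
uses learning rate 1e-4 with beta1 = 0.5, beta2 = 0.9 (5e-5 for the pure-MSE
U-Net variant, `train_unet()`, which is less stable at 1e-4). Each network's
gradient is additionally clipped to global norm 1. The critic updates after
every batch, the generator after every other batch (the counter runs across
epochs, so E epochs of B batches give E·B critic updates and ceil(E·B/2)
generator updates). Per-epoch train/validation mean absolute errors are
recorded and the generator from the epoch with minimal validation error is
returned. Training is bitwise reproducible given the seed, which drives
shuffling, patch offsets, dropout masks and penalty interpolates.

Desk-scale study conditions (used by the test suite and the acceptance
script): 200 subjects, 4 s records at 500 Hz, 80/10/10 split, batch 16,
20 epochs, fixed seed. Full-scale conditions (10 s records, batch 32,
1000 epochs) are retained as the `full` preset for real-data use.

Two baselines frame the GAN: `baseline_mean_predictor()` returns the
per-sample average of the training targets for any input (the analytic
regression-to-the-mean extreme), and `baseline_linear()` fits the best
instantaneous (samplewise) linear map from the input lead(s) to each target
lead — the purely mathematical information linear algebra can extract.

## The evaluation battery

`evaluate_reconstruction()` computes, per reconstructed lead and for the
marker set {R, S, T, STM} x {V1, V2, V3, V6} plus the global intervals:

* **RMSE per lead** over all test samples (uV).
* **Error percentiles** (5/10/90/95%) of reconstructed − real marker values,
  by linear interpolation between order statistics (R quantile type 7; cells
  with fewer than 20 records are flagged unstable).
* **Means and variances**: two-sided t-test on means — paired by record,
  because the same test subjects underlie both groups; the unpaired variant
  is available — and a two-sided F-test on the variance ratio. Degenerate
  cells (all differences zero, or both variances zero) are flagged instead of
  tested.
* **Bland–Altman agreement**: error against real value, mean difference,
  limits of agreement at ±1.96 SD of the differences, the squared Pearson
  correlation of error with the real value, and the least-squares slope.
  Unbiased reconstruction gives slope ≈ 0; a constant prediction gives slope
  −1 and R² = 1 exactly.
* **Inter-lead correlations**: squared correlation between each precordial
  marker and the (always real) lead-I marker, computed with real and with
  reconstructed precordial values. Faithful reconstruction preserves these;
  mean-plus-input reconstruction inflates them.
* **Verdict**: a cell is flagged for regression to the mean when all three
  signatures hold — variance ratio < 1 with F-test p < 0.05, negative
  Bland–Altman slope, and inflated inter-lead R² (a zero-variance
  reconstructed marker counts as the degenerate extreme of the latter two).

Every statistic is cross-checked in the tests against independently coded
brute-force implementations, and the F-test's type-I error is verified by
simulation at its nominal 5%.

## Numerical and design choices

* Percentile convention: R type 7 (linear interpolation between closest
  ranks) — stated because percentile tables depend on it.
* Limits of agreement use 1.96 SD everywhere.
* The t-test is paired by default; this is a deliberate reading of the
  study design (same records in both groups) where a plain "t-test" would be
  ambiguous.
* ADC quantization at 1 uV resolution on WFDB write; reading is the exact
  inverse, and mV-stored records are rescaled to uV on load.
* Degenerate inputs (flat signals, constant markers, zero-variance groups)
  are flagged explicitly rather than producing silent zeros or NaNs.
* Problem sizes in the test suite — 50-record noise-free cohorts for
  measurement validation, the 200-record desk cohort for the training study,
  1000 replicates of n = 500 for F-test calibration — were chosen as the
  smallest sizes at which each property is stable across seeds.

## Known limitations

* The desk-scale GAN is a scaled-down analogue, and a short optimisation
  budget interacts with the architecture: beat *timing* can only come from
  the input lead, so early training tends to grow input-amplitude
  pass-through before learning to attenuate it toward the conditional mean.
  In the desk run the error-slope and inter-lead-inflation signatures appear
  clearly on the near-orthogonal lead, while significant variance shrinkage
  appears only on some marker cells; the full three-signature verdict on
  every cell is a property of longer training. The test suite asserts
  exactly what the desk run computes, and the acceptance script reports the
  measured variance ratio rather than assuming it.
* The delineator is tuned to normal morphology; it makes no attempt at
  arrhythmic or pathological beats, and its conventions (5% thresholds, 75%
  R-anchor rule, tangent T end) are choices, not a standard.
* Real-data mode expects WFDB records that satisfy the lead-count and
  sampling-rate checks; it has been exercised against this package's own
  writer, not against every WFDB variant in the wild.
* Conclusions about real single-lead wearables require the full-scale preset,
  a real cohort and a clinical measurement system; the package's claim is
  about the *machinery* for making such an assessment honest.
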