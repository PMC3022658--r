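---
title: "Models and methods behind timemapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind timemapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(timemapr)
```

`timemapr` analyses how schizotypal perceptual aberrations of time relate
to behaviour and to evoked-potential (EP) microstate dynamics during
self-projection in time. This vignette documents the models, the synthetic
cohort the package generates in place of undeposited raw data, the
numerical choices, and what the package's tests do and do not establish.

## The latent-trait generative model

No raw data from the original study are publicly available, so everything
downstream is exercised on synthetic cohorts with a known generative
structure. One latent schizotypy trait $z \sim N(0,1)$ per subject drives
all four observed families:

* **tPAS items** (20, rated 1–10): latent value
  $b + \ell z + \varepsilon_i$, $\varepsilon_i \sim N(0, \sigma_I^2)$,
  rounded and clipped to $\{1,\dots,10\}$; the scale score is the mean
  rating.
* **PAS items** (35, true/false): endorsed with probability
  $\mathrm{logit}^{-1}(\beta_0 + \beta z)$; the score is the endorsement
  count.
* **Reaction times**: per trial, $\text{RT} = \mu_c + u_s + \gamma z$
  times a mean-one lognormal within-trial factor, with condition means
  $\mu_c$ = 475.3 / 401.1 / 480.1 ms (Past/Now/Future), subject offset
  $u_s \sim N(0, 70^2)$ ms and within-trial SD 120 ms. Error rates are
  9.2 / 6.1 / 9.8 % and are deliberately *not* trait-coupled (accuracy
  correlations are null results).
* **Time-map duration**: per subject and condition,
  $d_{sc} = \delta_c + \kappa z + e_{sc}$, rounded to whole samples, with
  $\delta_c$ = 110.2 / 39.2 / 105.0 ms.

The published between-subject duration SDs (12.3 / 8.4 / 15.2 ms) are
treated as *total* SDs, so the residual SD is
$\sqrt{\text{SD}_c^2 - \kappa^2}$ and generated cohorts reproduce the
printed SDs; adding the full printed SD on top of the trait term would
double-count the trait's share.

### Calibration

The constants (`trait_calibration()`) were fixed once by large-$n$
simulation so that default cohorts reproduce the group-level targets:
tPAS mean ≈ 4.45, SD ≈ 1.23; PAS mean ≈ 5.9; tPAS–PAS $r \approx 0.57$;
tPAS–RT $r \approx 0.69$; tPAS–duration $r \approx 0.59$. Because item
ratings are rounded and clipped, the calibration is necessarily empirical:
nominal loadings are attenuated by the floor at 1, so the frozen values
(`tpas_loading` 2.0, `tpas_item_sd` 6.4) are larger than the *effective*
ones (≈ 0.96 and ≈ 3.4 on the score scale).

One structural limitation is worth knowing. With purely
Bernoulli-logistic PAS items, the binomial noise floor at the calibrated
endorsement rate (~0.17) ties the PAS score SD to the PAS–trait
correlation. Matching the three correlation targets above forces
$\mathrm{corr}(\text{PAS}, z) \approx 0.73$ and hence a PAS SD of ≈ 3.3 —
inside the range reported across real samples (2.1–5.6), but below the
pooled 4.7. Real PAS distributions are overdispersed (zero-inflated);
the generator does not model that, and consequently its PAS–RT
correlation (~0.64) sits slightly below the published 0.68.

### EP generation

EPs are 192-channel, 2048 Hz, 0–800 ms (half-open window ⇒ 1638 samples)
sequences of quasi-stable topographic segments: six mutually orthogonal,
zero-mean, unit-GFP template maps (random rotations of degree-1–3
spherical harmonics on the montage, hence spatially smooth), each active
over one segment and scaled by a raised-sine envelope
(floor 25 % of the 5 µV peak) so GFP varies within segments and the
fitting problem is not degenerate. The fourth segment, onset 350 ms, is
the time-map; its duration follows the model above. The remaining
segments have fixed nominal durations jittered between subjects
(SD 12 ms) — real component latencies vary, and without the jitter the
epoch-remainder segment would be an exact algebraic complement of the
time-map, indistinguishable from it by condition sensitivity. Spatial
Gaussian noise (1 µV) is added and every sample is average-referenced.
The montage is a synthetic Fibonacci-lattice cap (no manufacturer layout
is tabulated); the electrode geometry only needs to be quasi-uniform.

What the generator does *not* emulate: trial-level EEG (the evoked is
drawn directly, so epoch-count effects on evoked SNR are out of frame),
spatially correlated noise, polarity-inverting components, latency *drift
within* a segment, and overlapping (non-piecewise-stable) sources. Tests
passing on this generator therefore establish correctness of the
estimators under the microstate model's own assumptions, not robustness
to their violation in real data.

## Microstate segmentation and statistics

Segmentation is a modified spatial k-means on the concatenated
group-average EPs of the three conditions: initial templates are randomly
drawn normalised time-point maps; each sample joins the template with the
highest spatial (Pearson, channel-wise) correlation, and templates are
re-estimated as the normalised mean of their assigned maps; best of 20
restarts by global explained variance (GFP²-weighted squared correlation).
Assignment is polarity-*sensitive* by default: these are evoked, not
resting-state, topographies, and component polarity carries meaning. A
`polarity = FALSE` flag switches to squared-correlation assignment with
dominant-eigenvector template updates. Ties assign to the lowest template
index; the iteration stops when no label changes.

Model order uses the cross-validation criterion
$\sigma_q^2 = \sum_t \left(u_t^\top u_t - (a_{L_t}^\top u_t)^2\right) / (T(N-1))$,
$CV(q) = \sigma_q^2\,((N-1)/(N-1-q))^2$, with unit-norm templates $a$.
The criterion itself is computed exactly in this published form, but the
package's default *selection rule* is the knee of the CV curve (largest
second difference of $\log CV$), not the raw argmin. The reason is
numerical, and visible in `ms_select_q()$scores`: at $N = 192$ electrodes
the penalty grows by only ~1 % per added map while k-means keeps absorbing
noise variance, so the argmin drifts to the top of whatever range is
scanned and near-duplicate templates then split segments at back-fit. At
the electrode counts for which the criterion was originally described
(~20) the two rules agree, as they do on noiseless data with a planted
model order (where CV reaches numerical zero and the smallest such $q$ is
selected). `rule = "argmin"` restores the plain minimiser.

Back-fitting assigns every sample of an individual EP to its
best-correlating template; duration is assigned samples × sampling
interval, GFP is the mean global field power over assigned samples
(recorded as missing for maps absent from a subject's EP). Runs shorter
than `min_duration_samples` can be absorbed into the better-correlating
flanking run; the default (1, i.e. off) reflects that no temporal
constraint is part of the analysis. Low-GFP samples are still assigned.

Per map, duration and GFP go into a one-way within-subject ANOVA
(explicit sum-of-squares decomposition; $F$ on $(k-1, (k-1)(n-1))$
degrees of freedom, no sphericity correction by default since the
conventional report for this design is the plain $F(2, 26)$;
Greenhouse–Geisser is available via `gg = TRUE`). When noise-free inputs
drive the residual sum of squares to zero the fit is flagged as perfect
separation rather than dividing by zero — and only if the condition
effect is non-zero; a map with literally constant durations has nothing
to test. The **time-map is identified programmatically** as the template
with the smallest duration-ANOVA p value (perfect separation with a real
effect outranks any finite p).

Score correlations use each subject's measure averaged over the three
conditions, unweighted — conditions have equal trial counts by design;
whether the original analysis used the grand mean or condition-wise
values is not stated, so this is a documented assumption. The same
convention is used for RT (`correlate_scores_with_behavior()`).

## Source localisation

The head is a three-shell concentric sphere (brain/skull/scalp radii
87/92/100 mm; conductivities 0.33/0.0042/0.33 S/m). The lead field is the
classical Legendre-series expansion; interface conditions are solved per
harmonic degree as a small linear system in scalp-radius units (the raw
powers overflow double precision), truncated at degree 60 by default —
adequate for sources kept within 95 % of the brain radius by
`source_grid()`. The default 12 mm lattice yields ~1200 nodes; this
spherical stand-in replaces any anatomy-based model, so outputs are
coordinates relative to the sphere and deliberately carry no anatomical
labels.

The inverse prior is a local autoregressive average: node activity is
shrunk towards a distance-law ($d^{-2}$ by default) weighted average of
neighbours within 2.1× the grid spacing, per moment coordinate. The
autoregressive coefficient is 0.95, not 1: with exact neighbourhood
averaging the structural matrix $I - A$ annihilates uniform fields and
the prior covariance degenerates. With the neighbourhood disabled the
operator reduces exactly to the classical regularised minimum norm, which
the tests exploit as an oracle. Regularisation defaults to 5 % of the
mean eigenvalue of $L W^{-1} L^\top$; `choose_lambda()` offers an
L-curve corner scan for a specific map. Localisation error for planted
superficial dipoles is at the grid-spacing scale (noiseless), grows with
sensor noise, and is worse for deep sources — the expected behaviour of
minimum-norm-family inverses.

## Problem sizes and reproducibility

Every stochastic function takes an integer seed; fixed seeds give
bit-identical cohorts, EPs and fits, and `run_all()` derives per-stage
seeds from one master seed. The package's own test suite runs the full
study-scale pipeline (14 subjects, 192 channels, 2048 Hz) once; repeated
and replication-style checks (parameter recovery across seeds, type-I
calibration of the duration ANOVA with 200 replicate cohorts, null-
coupling runs) use reduced montages (16–32 channels), reduced sampling
rates (256–512 Hz) and smaller cohorts, sizes chosen to keep the suite
quick while leaving every code path identical. The 200-subject
correlation check likewise runs at 32 channels / 512 Hz; duration
recovery is unaffected because back-fitting recovers planted boundaries
to the sample at these noise levels.

## Known limitations

* The generator's PAS marginal distribution is thinner-tailed than real
  PAS data (see Calibration); its item-level tPAS statistics are
  unconstrained beyond the scale-level targets, since no per-item
  statistics exist to calibrate against.
* The PAS scoring key is configurable but defaults to all-true; the
  official key belongs to the original instrument.
* Microstate results assume piecewise-stable topographies; the CV-knee
  rule, like any model-order heuristic, can be off by one on data whose
  CV curve has no clear knee.
* The spherical head model supports algorithmic validation, not
  anatomical inference.
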