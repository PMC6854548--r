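---
title: "Source-space oscillatory analysis of MEG: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-space oscillatory analysis of MEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megsource)
```

# Overview

`megsource` implements a two-phase source-space analysis of
magnetoencephalography (MEG) recordings of the kind used to dissociate
cortical responses to different semantic relations between written words:

1. **Whole-brain localisation.** Epoched sensor data are scanned with
   vectorised LCMV beamformers on a regular source lattice; noise-normalised
   total oscillatory power (the Neural Activity Index, NAI) is mapped in
   broad frequency bands and 200 ms windows, and post-stimulus ("active")
   maps are contrasted against a pre-trial ("passive") window with paired
   t statistics thresholded by a permutation maximum statistic.
2. **Point-of-interest (POI) time-frequency contrasts.** At selected
   source points, per-trial virtual-electrode time courses are decomposed
   with the Stockwell transform; evoked percent signal change is resampled
   to a 25 ms × 2 Hz tile grid and condition differences are tested per
   tile with dual significance criteria and a Monte-Carlo cluster-extent
   correction.

Because raw recordings from the motivating paradigm cannot be archived, the
package ships a first-class synthetic-data generator with known ground
truth, and all validation — unit, property and acceptance tests, and the
`scripts/acceptance.R` report — runs end to end on simulated cohorts.

# Forward model

The conductor is a homogeneous sphere. The external magnetic field of a
current dipole then has a closed analytic form with two well-known
consequences that the test-suite checks to machine precision: the radial
component of the dipole moment is externally silent, and the field does not
depend on the sphere radius (only on its centre). Sensors are ideal point
magnetometers placed on a Fibonacci-spiral spherical cap (248 channels,
0.12 m helmet radius and 120° coverage by default) with radially outward
orientations; the head frame has its origin at the sphere centre, metres,
z toward the vertex.

"Multiple spheres" head models are supported as per-channel sphere
overrides (`spherical_head_model(channel_centers=, channel_radii=)`). This
matters for the beamformer: with a *single* sphere every per-point lead
field has exact rank 2 (the radial orientation is silent), so the
three-orientation unit-gain constraint cannot be enforced in full.
`lcmv_weights()` therefore truncates silent orientations by SVD (relative
singular-value tolerance `rank_tol = 1e-7`) and enforces unit gain on the
remaining subspace; with full-rank lead fields (per-channel spheres, or any
generic matrix) the exact 3 × 3 identity constraint holds to `1e-8` and
better. Lead fields of effective rank < 2 are rejected.

Sources within 1 nm of a sphere centre are rejected rather than
regularised — the field formula is singular there — and the lattice
constructor drops the exact centre point for the same reason.

# Synthetic data

`simulate_epochs()` builds per-participant epoch sets (default 678.17 Hz,
1500 ms epochs from −800 ms to +700 ms around the second-word onset; four
conditions: taxonomic, strong thematic, weak thematic, unrelated; 95 trials
per related condition at full scale, scaled down via `trial_scale` for
simulations) as the sum of three components:

* **Ground-truth effects** (`dipole_effect`): windowed cosines with a Hann
  amplitude envelope at a carrier frequency, forward-projected through the
  lead field. The `phase_locked_fraction` of the amplitude keeps a constant
  phase across trials (evoked content); the remainder receives a fresh
  uniform phase per trial and cancels in the trial average (induced
  content). Per-participant amplitude factors are jittered
  (`participant_amp_sd`, default 10%) to create between-subject variance.
* **Background brain noise**: `n_noise_dipoles` (default 200, reduced in
  fast tests) random interior dipoles with unit-RMS 1/f time courses. This
  gives the spatially structured covariance a beamformer needs to be
  non-degenerate.
* **White sensor noise** (`sensor_noise_sd`, tesla).

The generator's noise levels are chosen for testability — localisation and
recovery properties are exercised at signal-to-noise ratios where they are
decidable in minutes — rather than calibrated to any particular recording
system; no empirical SNR figures exist for the motivating data. The
simulator reproduces the *statistical structure* the analysis assumes
(evoked vs induced content, condition-dependent amplitudes, 1/f background,
between-participant variability) but not eye blinks, sensor drifts or
head-movement artefacts, so passing tests demonstrate correctness of the
analysis machinery, not robustness to every artefact of real data.
Artefact rejection is a simple amplitude threshold (`reject_epochs`),
an automatic stand-in for visual inspection.

Catch-trial behaviour (`simulate_behaviour`) draws per-participant mean RT
and accuracy as condition means plus participant offsets plus residual
noise; the default means give a strong>weak thematic effect on both
measures and matched taxonomic vs weak thematic performance. Participants
whose overall catch accuracy falls below 75% are excluded (strict
inequality), after which each pairwise contrast is a paired two-tailed
t test; with 19 retained participants every contrast has 18 degrees of
freedom.

# Beamforming and the Neural Activity Index

Covariance matrices are estimated per condition and analysis window after
zero-phase 4th-order Butterworth band-passing. The filter is applied in the
frequency domain as |H(ω)|², the squared magnitude of the digital
Butterworth design — the transfer function of forward–backward filtering —
which avoids per-trial transient handling and is fast over many short
epochs. Covariances are regularised by diagonal loading scaled by the mean
diagonal of a noise covariance (`lambda_rel`, default 0.05); the loading
rule is fixed here because the motivating description cites external
software without printing its formula. The default noise covariance is
estimated from the passive window (−700..−500 ms) with identical filtering;
an identity-based alternative (`identity_noise_cov`) is provided.

Weights per point are `W = (L'C⁻¹L)⁻¹L'C⁻¹` (with the SVD rank handling
above). Source power sums the three orientation outputs as the trace of the
projected covariance, and

NAI(p) = tr(W C_active W') / tr(W N W'),

which equals 1 everywhere when the data equal the noise (checked to 1e-6),
is invariant to global rescaling and channel reordering, and removes the
depth-dependent noise amplification of raw minimum-variance power.
Weights are recomputed per condition and window by default; sharing weights
across conditions is possible by passing a common covariance to
`lcmv_weights()` explicitly.

# Whole-brain inference

`active_passive_tmap()` forms the paired t statistic per lattice point
across participants; zero-variance points get t = 0 and a flag (rather than
±∞ poisoning the maximum). `permutation_threshold()` relabels the two
windows per participant — a sign flip of the paired difference — and
records the maximum |t| over points per permutation; the observed map is
thresholded at the configured quantile (default the top 5%) of those
maxima. Whole-map flipping is the default because it preserves the spatial
covariance of the maps, the standard requirement for maximum-statistic
inference; independent per-point flipping is available as an explicit mode,
and the two agree exactly on a single-point lattice. The test is two-sided
via |t|; zero-t points never survive. For n ≤ 20 participants the full set
of 2ⁿ sign patterns can be enumerated (`exhaustive = TRUE`), which the
tests compare against brute-force enumeration. Family-wise error under a
simulated global null is checked at reduced scale (200 cohorts × 500
permutations × 100 points) against the 99% binomial interval around
α = 0.05.

# Stockwell transform and tiles

`stockwell()` implements the standard FFT formulation of the S-transform:
for frequency bin k the spectrum is shifted by k, windowed with the
Gaussian voice `exp(−2π²m²/k²)` evaluated on principal-alias offsets m, and
inverse transformed. The window width scales inversely with frequency —
the transform's defining trade of temporal for spectral resolution along
the axis. Two identities anchor the tests: linearity, and the marginal
identity that the time average of S(τ, f) equals the Fourier coefficient
H(f) (the m = 0 voice passes unchanged). A direct-summation (non-FFT)
implementation written independently in the test helpers must agree to
1e-8. A note on provenance: descriptions of the original analysis mention
a filter-bank variant with automatic padding; that variant is not specified
anywhere we can verify, so the package implements the standard
Gaussian-window transform and records the divergence here.

Evoked power transforms the trial average; total power averages per-trial
power; both sum squared magnitude over the three virtual-electrode
orientations before any normalisation. By convexity evoked ≤ total holds
pointwise for every trial set, and with a single trial they coincide —
both are asserted in the tests.

Percent signal change is computed per frequency bin against the mean power
in the −700..−500 ms pre-trial baseline. Within a condition contrast the
baseline is pooled across the conditions entering the analysis (the mean of
the per-condition baseline levels), so all conditions of a participant
share one denominator per frequency bin. This pooling is not cosmetic:
with per-condition baselines, baseline noise scales entire frequency rows
of one condition's map and injects strongly row-correlated structure into
condition differences, which measurably destroys the specificity of the
downstream cluster inference. Percent change (rather than dB or a ratio)
keeps the null at 0 and bounded below by −100, both directly testable.

Tiles are half-open, lower/left-edge labelled means over
[t, t+25 ms) × [f, f+2 Hz); the −800..700 ms × 5–50 Hz defaults give a
60 × 23 grid (60 time steps; frequency edges 5, 7, …, 49).

# Tile statistics, dual criteria, cluster extent

Per tile, `tile_condition_test()` computes the paired t of condition A − B
across participants and one-sample t's of each condition against 0%
change. A tile enters the statistical contours iff (a) the condition
difference is significant at α = .05 and (b) at least one contributing
condition departs from baseline at α = .01; inequalities are strict.

The difference p-values are Holm-adjusted across the tiles of the analysis
before criterion (a) is applied (`p_adjust_method`, default `"holm"`;
`"none"` gives raw tile-wise thresholds). This mirrors the original
mixed-model analysis, whose tile contrasts controlled experiment-wise
error within each site-by-contrast analysis — the subsequent cluster-extent
correction then only has to control error across the family of twelve
analyses (four sites × three contrasts, Bonferroni). The adjustment is
load-bearing: with raw per-tile thresholds, significant noise tiles on
S-transform-smooth maps arrive in blobs of roughly the transform's
resolution (about 3 × 3 tiles at 20 Hz), which a cluster null that assumes
*randomly scattered* significant tiles cannot distinguish from signal; in
end-to-end null simulations the cohort-level false-alarm rate was then far
above its nominal level, and with the adjustment it returns below it.

`cluster_null()` estimates the distribution of the maximal connected
cluster when `round(fill_rate × n_tiles)` tiles are scattered uniformly
without replacement (fill rate = the observed fraction of tiles showing a
significant between-condition difference). Connectivity is 4 (edge
adjacency) by default — the conservative choice, since "contiguous" is
otherwise undefined — with 8 available and surfaced in every report.
`min_cluster_size()` returns the smallest extent k with
P(max cluster ≥ k) < α / n_analyses (default .05/12). Clusters below k are
reported separately as the "dashed" set rather than silently discarded.
The labelling algorithm is iterative minimum-label propagation, verified
against a recursive flood fill on random grids and against exhaustive
placement enumeration on all grids up to 3 × 3.

The computed k* for the full 60 × 23 grid at 7.5% fill and α = .05/12 is
8 under 4-connectivity (11 under 8-connectivity) with 10,000 simulations;
`scripts/acceptance.R` recomputes and reports it. Published analyses of
this design quote a six-tile threshold at the same fill rate; the
difference is expected to turn on the grid extent and adjacency rule of
the original simulation, neither of which is recoverable, so the package
treats the threshold as data-dependent output rather than a constant.

# Problem sizes used in validation

The shipped tests and the acceptance script run at deliberately reduced
scale, chosen so the full validation completes in minutes on one CPU while
every statistical check retains its meaning: 16–32 channels, 10–20 trials
per condition, 19 participants per simulated cohort, 20 cohorts for
recovery/specificity rates, 200 cohorts × 500 permutations for FWER
calibration, lattices restricted to a few-centimetre box around the scene
at the full 5 mm spacing, and 400–10,000 Monte-Carlo draws for
cluster-extent nulls. All seeds are explicit, and identical configurations
are bit-reproducible.

# Known limitations

* The spherical conductor and point magnetometers idealise real head
  geometry and pickup coils; no coregistration to anatomy is provided, and
  coordinates remain in the head frame (POI names are labels only).
* The per-tile t tests with Holm adjustment are a stand-in for the original
  spatial-correlation mixed model; they preserve its decision surface
  (tile-wise significance → dual criteria → cluster extent) but not its
  exact operating characteristics.
* The shipped end-to-end specificity checks cover the no-effect global
  null. Under an exchangeable null in which both conditions share a
  strong, identical evoked response, residual anti-conservatism of the
  scatter-based cluster null cannot be excluded in general and should be
  re-examined for designs that depart from the shipped settings.
* Epochs serialise to a documented plain-text layout (YAML + full-precision
  TSV) rather than binary neuroimaging containers; NAI volumes export to
  NIfTI.
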