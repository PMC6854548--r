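# megsource

Source-space oscillatory analysis of MEG recordings in R: spherical-conductor
forward modelling, vectorised LCMV beamforming with noise-normalised power
maps, permutation maximum-statistic whole-brain contrasts,
Stockwell-transform time-frequency analysis at points of interest, and
condition contrasts on time-frequency tiles with dual significance criteria
and Monte-Carlo cluster-extent correction.

The package is aimed at electrophysiologists who analyse epoched
multichannel MEG in two phases — a coarse whole-brain localisation of
oscillatory responses followed by fine time-frequency contrasts at selected
source points — and at methodologists who want every stage of such a
pipeline testable against known ground truth. Because paradigms of this
kind often cannot archive raw participant data, `megsource` ships a
synthetic-data generator that injects oscillatory dipole sources with
condition-dependent amplitudes into realistic background noise, so the
whole pipeline is validated end to end on simulated cohorts.

## The models at the core

**Forward model.** The external field of a current dipole **q** at
**r**₀ inside a homogeneous conducting sphere has the closed analytic form

> **B**(**r**) = μ₀ / (4π F²) · (F **q**×**r**₀ − (**q**×**r**₀·**r**) ∇F)

with F = a(Ra + R² − **r**₀·**r**). Two classical consequences are enforced
to machine precision in the tests: a radial dipole is externally silent,
and the field is independent of the sphere radius. Per-channel sphere
overrides ("multiple spheres") are supported.

**Beamformer.** For lead field L (channels × 3) and regularised data
covariance C, the vectorised LCMV weights are

> W = (LᵀC⁻¹L)⁻¹ LᵀC⁻¹,

unit-gain on the source orientations and minimum-variance elsewhere. With a
single-sphere conductor the lead field has exact rank 2 (the silent radial
orientation), which `lcmv_weights()` handles by SVD truncation. Source
power is the trace over the three orientations, and the Neural Activity
Index NAI = tr(W C_active Wᵀ) / tr(W N Wᵀ) normalises by projected noise
power, removing depth-dependent noise amplification.

**Inference.** Whole-brain active-vs-passive contrasts use paired t maps
thresholded by the permutation maximum statistic (window relabelling =
sign-flipping per participant, max |t| over the lattice per permutation).
POI contrasts test 25 ms × 2 Hz tiles of baseline-normalised evoked power:
a tile enters the statistical contours iff the condition difference is
significant at p < .05 (Holm-adjusted across the analysis's tiles) and at
least one condition departs from baseline at p < .01; surviving tiles are
then filtered by a Monte-Carlo cluster-extent threshold computed from the
observed fill rate, Bonferroni-corrected across the family of analyses.

## Worked example: localising an injected oscillatory source

```r
library(megsource)

head <- spherical_head_model()                     # 9 cm sphere, origin at centre
sens <- build_sensor_array(32, helmet_radius = 0.12, coverage_angle = 120, seed = 1)

cfg <- sim_config(sensors = sens, head = head,
                  conditions = c("taxonomic", "thematic_strong"),
                  n_trials = 12, n_participants = 1,
                  n_noise_dipoles = 30, seed = 7)

src <- c(0.02, 0.01, 0.05)                         # ground-truth location (m)
eff <- dipole_effect(src, freq = 30, window = c(150, 450),
                     amplitude = c(taxonomic = 5e-8, thematic_strong = 5e-8),
                     phase_locked_fraction = 0.5)

ep  <- simulate_epochs(cfg, list(eff))$epochs[[1]]
lat <- source_lattice(head, spacing = 0.005,
                      extent = c(0.02, 0.02, 0.02), origin = src)
LF  <- lead_field(head, lat, sens)

noise <- estimate_covariance(ep, c(-700, -500), band = c(25, 35))
vol   <- nai_volume(ep, LF, band = c(25, 35),
                    active_window = c(150, 450), noise_cov = noise)

max(vol$nai)                        # 6.1
lat$points[which.max(vol$nai), ]    # 0.02 0.01 0.05
median(vol$nai)                     # 0.75
```

The 30 Hz burst injected at (0.02, 0.01, 0.05) m produces a peak
noise-normalised power of 6.1 at exactly the injected lattice point — zero
localisation error at the 5 mm lattice spacing — while the background
median stays near the noise floor. `run_wholebrain()` wraps this scan over
bands and windows with permutation thresholding; `run_poi()` runs the
tile-statistics phase at a named point of interest and returns the tested
grids, masks, fill rates and cluster contours.

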