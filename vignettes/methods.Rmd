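---
title: "Methods: simulated OPM-MEG, beamforming, spectral features and microcircuit inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated OPM-MEG, beamforming, spectral features and microcircuit inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(opmgamma)
```

This vignette is the package's own account of its models and of the design
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The analysis problem

Drifting-grating stimulation induces gamma-band (30–80 Hz) oscillations in
primary visual cortex and suppresses occipital alpha. Across development the
induced gamma response changes from a broadband child pattern to a
narrowband adult rhythm near 50–60 Hz, and the working hypothesis is that
this reflects maturation of cortical excitation–inhibition (E-I) balance:
rising inhibition and falling excitation in the superficial layers. The
pipeline quantifies this in two complementary ways: (i) band-wise Spearman
correlations of stimulus-induced amplitude change with age, and (ii) a
canonical-microcircuit (CMC) neural-mass model fitted to each subject's
stimulus-vs-rest relative spectrum, whose intrinsic gain ratio G12/G11
(excitatory vs inhibitory coupling between superficial pyramidal cells and
interneurons) indexes superficial E-I balance.

Because no recordings ship with the package, a synthetic-data module
generates every input with known ground truth, which is what makes each
stage testable closed-loop.

## Sensor arrays and the forward model

`build_sensor_array()` places sensor housings quasi-uniformly (a Fibonacci
lattice with a small seeded jitter) on a posterior-weighted spherical cap at
a 6.5 mm standoff from a spherical scalp (default radius 90 mm), mimicking
a rigid helmet with visual-cortex coverage. Each housing carries an
orthonormal axis triad (radial first); dual-axis sensors use the radial and
first tangential axes. Defaults mirror the two study sites: 64 triaxial
sensors (192 channels) at a 50 Hz site and 40 dual-axis sensors
(80 channels) at a 60 Hz site, both sampled at 1200 Hz.

Fields are computed with the analytic current-dipole-in-conducting-sphere
solution (Sarvas). This is the one deliberate model substitution in the
package: the original analysis used a single-shell surface model fitted to
pseudo-MRIs, which requires anatomy that a desk-scale artifact does not
have. At these sensor distances the two produce near-identical dipolar
topographies; the sphere solution additionally gives two exact invariants
used by the tests — a dipole at the centre and any radial dipole moment
produce zero external field. A consequence carried through the beamformer:
the per-voxel 3-column gain matrix has rank 2, so the radial direction is
excluded (eigenvalues below 1e-8 of the maximum) before the
minimum-eigenvalue orientation is taken.

## The simulated subject

A trial is 1 s of stimulation followed by a uniformly jittered
1250 ± 200 ms rest; 60 trials by default. The dipolar source time course
sums:

- a broadband white "floor" (default 20 nAm SD), the reference for all
  relative amplitudes;
- an alpha oscillator (band-filtered noise, ±1.5 Hz around the profile's
  alpha frequency) suppressed by a fixed fraction during stimulation;
- a narrowband gamma component (filtered noise, centre ± 4 Hz) and a
  broadband 30–80 Hz component, both gated to the stimulus window with
  50 ms cosine ramps.

Component amplitudes are specified as target relative envelope changes: a
profile value ρ is converted to the in-band source power that makes the
band-limited Hilbert envelope rise by ρ against the floor
(`P = ((1+ρ)² − 1) · P_floor,band`), so the numbers that enter the profile
are approximately the numbers the time-frequency analysis reads back.

The age → profile mapping (`age_profile()`) is a documented generative
convenience: alpha peak 7.5 + 0.06·age Hz, alpha suppression 0.35,
broadband gamma 0.08, narrowband gamma 0.02 + 0.009·age at a centre
45 + 0.35·age Hz capped at 60 Hz. It qualitatively reproduces the
child-to-adult evolution (broadband, weak gamma in children; strong
narrowband ~57 Hz gamma in adults) without claiming those coefficients from
any measured cohort.

Interference includes per-channel white sensor noise (default ~15 fT/√Hz
equivalent), a spatially homogeneous drift (three slowly varying random
field directions), mains noise at the site line frequency plus two
harmonics, and optional flagged bad channels, high-variance trials and
frontal-weighted biphasic blink transients whose reference traces are
returned so artifact removal is testable without real electro-oculography.
No per-subject SNR is reported by the source study, so the floor amplitude
was calibrated once so that pipeline-derived relative changes fall in the
~0.1–0.6 range of the adult gamma literature, and not revisited.

## Preprocessing

Fixed order: bad channels → notch → band-pass → epoching → trial rejection
→ artifact removal → homogeneous field correction.

- Bad channels: the original study used manual inspection, which is not
  reproducible; the package flags channels whose median log-PSD over
  1–150 Hz deviates from the cross-channel median by more than 3.5 scaled
  MADs (either direction), plus dead channels (variance < 1e-30 T²). The
  threshold is configuration.
- Filters: zero-phase 2nd-order notches (2 Hz half-width) at the line
  frequency and two harmonics, then a zero-phase 4th-order 1–150 Hz
  Butterworth band-pass. Zero-phase filtering is implemented as the squared
  magnitude response applied in the frequency domain with reflection
  padding — the transfer function of forward–backward application — because
  the per-trial, per-band filtering load makes time-domain `filtfilt`
  the pipeline's bottleneck.
- Epochs are half-open [-1, 2) s windows, so 3 s at 1200 Hz is exactly
  3600 samples.
- Trial rejection: pooled (channels × samples) per-trial variance, single
  pass, strict `> mean + 3 SD`. Pooling is a choice the source text leaves
  open; per-channel maxima would reject more aggressively.
- Artifact removal defaults to regression on reference traces
  (deterministic); without references a seeded fastICA-style decomposition
  removes components correlating |r| > 0.7 with a supplied template.
- Homogeneous field correction projects out the column space of the
  channels × 3 orientation matrix; it is applied after epoching (the
  original order is unstated) and is idempotent by construction.
- `match_trial_counts()` equalizes group mean retained-trial counts (to
  within one trial) by seeded random removal from the richest group,
  matching the stated outcome of the original matching procedure rather
  than per-subject counts.

## Beamforming and spectral features

Weights are computed once from the 1–150 Hz broadband covariance over all
retained trials, regularized by diagonal loading with 5 % of the largest
eigenvalue, and reused for every contrast and virtual electrode. Pseudo-T
images contrast 30–80 Hz (gamma) or 6–14 Hz (alpha) covariances between the
0.3–1 s and -0.8 to -0.1 s windows. The source text does not print its
pseudo-T normalization; the package uses the symmetric bounded form
`(P_on − P_off)/(P_on + P_off)` because it is scale-free, bounded in
[-1, 1], and zero for equal covariances. Peaks are localized on a coarse
4 mm grid and refined on a fine grid in a box around the coarse peak
(replacing an atlas-based region with a configurable box); exact ties take
the lowest voxel index.

The time-frequency spectrum uses 45 overlapping bands, 4 Hz wide with 2 Hz
spacing. The ladder's ceiling defaults to 93 Hz, i.e. bands (1,5) … (89,93)
with centres 3–91 Hz: that is the only packing consistent with the stated
band count and with every band named in the reports (5–9, 9–13, 11–15,
29–33, 51–55 Hz). The statistical family excludes the lowest band, whose
lower edge sits on the 1 Hz high-pass cutoff, reconciling the 45-band
construction with the 44-comparison family; which band the original family
dropped is unknowable from the text, and this rule is the package's own.

The model input feature is
`|(PSD_on − PSD_off)/PSD_off|` from Hann-tapered per-trial periodograms
zero-padded to a 0.25 Hz grid and averaged over trials (the estimator is
unnamed in the source; the absolute value is taken after trial averaging).
Cohort spectra are scaled by one common factor so the grand average has
unit area, and an alpha Gaussian (amplitude ≥ 0, centre 8–13 Hz, width
0.5–4 Hz, fit on the 6–15 Hz segment with three starts) is subtracted, with
negative remainders clipped to zero. The pipeline consults the spectrum's
`alpha_removed` stage flag and skips the remover for inputs already free of
an alpha peak — in particular for model-generated cohort spectra, where the
constrained Gaussian would otherwise bite into the circuit's low-beta
resonance.

Peak alpha frequency is the 6–14 Hz maximum of the rest-window periodogram
after subtracting a log-log linear aperiodic fit (3–40 Hz); a peak counts
only if it is prominent relative to the residual spread of the bump-free
16–40 Hz region (3.5 scaled MADs), so pure 1/f input rarely yields one.
Aperiodic modelling appears nowhere else in the pipeline.

## The canonical microcircuit and its inversion

Four populations — spiny stellate (ss), superficial pyramidal (sp),
inhibitory interneurons (ii), deep pyramidal (dp) — each follow a
second-order synaptic kernel (`v̇ = i`,
`i̇ = κu − 2κi − κ²v`). Thirteen signed gains wire them
(`cmc_connection_table()`); G5 (ss→ii), G11 (ii→sp, inhibitory) and G12
(sp→ii, excitatory) are anchored to their described roles, the remaining
wiring follows the standard canonical-microcircuit convention, and the
count (13 gains, 4 fixed) adopts the stated fixed set {G1, G3, G10, G13}
over the conflicting "G1–G12" caption. Innovations (white + 1/f) drive the
stellate population; the output is the superficial-pyramidal membrane
potential. Linearization about the resting point with a constant
operating-point gain makes the predicted spectrum an exact linear-systems
computation, `output_gain · |H(f)|² · (white + pink/f)`.

Default numerics (rate constants 256, 128, 256, 64 s⁻¹; slope 60; gains of
order 1–8; prior log-scaling variance 1/8) were chosen by design
exploration before the tests were frozen, against three requirements: a
damped gamma resonance near 43 Hz and a separable low-beta resonance near
13 Hz (two spectrally distinct loops make G5/G11/G12 identifiable, where a
single-resonance circuit leaves a compensation ridge along the
self-inhibition gains); stability of at least 99 % of prior draws (G1,
which is fixed and therefore never rescaled by a draw, supplies the damping
margin); and unit area of the default spectrum over 1–100 Hz so model
output lives on the scale of area-normalized relative spectra.

Inversion is maximum-a-posteriori estimation of the free log-scalings under
a Gaussian observation model on `log(spectrum + 1e-6)` over 4–100 Hz, by
Gauss–Newton iteration with Levenberg damping. Two numerical safeguards
were added after observing failures: a fixed fan of six extra deterministic
start offsets along the loop-gain directions (the posterior is multimodal
for strongly perturbed circuits — without the fan a few percent of cohort
fits miss the basin entirely), and a quasi-Newton polish from the best
candidate and the prior mean (curvature-only steps stall on the shallow
ridge between gains). Both keep the fit bit-deterministic: identical inputs
give identical fits. The default observation SD (0.05 on the log scale)
matches the declared observation noise of the synthetic cohorts; the
reported `F` is the Laplace free energy (accuracy minus prior and volume
complexity). Non-convergent fits are returned flagged, never discarded.
Empirical priors recentre the prior means on the grand-average posterior,
with variances unchanged and the fixed set untouched.

One measured limitation: under 5 % observation noise the Laplace posterior
SDs of the G5/G11/G12 log-scalings are 0.13–0.15, so any single fit carries
irreducible error of that order; recovery checks therefore assert the
estimator's central tendency over a handful of seeded replicates, and
cohort-level claims use rank correlations, which are robust to the
shrinkage this noise level forces.

## Cohorts and trajectory statistics

`simulate_cmc_cohort()` draws each subject's free log-scalings from the
priors and adds age-linked linear drifts (centred at the cohort mid-age) on
log G12 (-0.02/yr), log G11 (+0.02/yr) and log G5 (+0.02/yr) — a declining
superficial E-I ratio and rising stellate drive, the hypothesis under
study; observation noise is multiplicative log-normal, 5 %. Unstable draws
are redrawn. With 60 subjects these slopes put the true G12/G11-age rank
correlation near -0.7; estimation noise attenuates the fitted correlation
to roughly -0.4, detectable under the 10-comparison family but not
trivially so — the cohort sits deliberately in the regime where estimator
quality matters.

Two details of the empirical-prior stage matter at cohort scale. The
common normalization factor is a known deterministic rescaling, so the
pipeline folds it into the model's output gain rather than letting the
grand-average fit attribute a ~1 log-unit scale shift to circuit
parameters. And the grand average is taken in the log domain (geometric
mean): the arithmetic mean of heterogeneous spectra is broader than any
member's spectrum and would recentre the priors on a circuit that no
subject has, which measurably attenuates the recovered age trends;
log-domain averaging matches the fit's log-Gaussian observation model.

Spearman correlations are tie-corrected with two-sided p-values from the
t-approximation (n − 2 df); an exact permutation p is available for
n ≤ 12. Bonferroni families follow the two reports: 44 bands (threshold
0.05/44, reported as 0.0011) and 10 parameters — the nine free gains plus
G12/G11 (threshold 0.005). The composition of the 10-member family is a
reasoned reconstruction; the deep ratio G6/G9 and the free energy F are
reported uncorrected and labelled exploratory. Group bins (2–4, 5–8, 9–13,
21–24, 25–28, 29–34 years) are descriptive only; correlations always use
continuous age.

## The end-to-end cohort and what passing shows

`run_pipeline()` simulates a cohort twice over: sensor-level recordings
(whose gamma phenomenology drifts with age) feed the beamformer/TFS branch,
and a spectrum-level CMC cohort with the same ages feeds the model-fitting
branch. The generative CMC parameters of the sensor-level source are not
defined — its gamma is phenomenological filtered noise — so parameter
recovery is meaningful only against the spectrum-level branch, and that is
where the E-I trend is assessed.

The demonstration configuration (`run_config()`) runs 12 subjects with 16
sensors, 600 Hz, 16 trials, a 4 mm coarse and 2 mm fine grid; the
acceptance cohort uses 60 subjects with the same per-subject sizes. These
sizes are the package's choice of a desk-scale problem; per-operation
defaults keep the full study conditions (64 triaxial sensors, 1200 Hz, 60
trials). The acceptance cohort pins the alpha peak at 9.5 Hz
(`fixed_alpha_freq`): under the drifting default profile the alpha peak
moves into the 9–13 Hz measurement band with age, which *mechanically*
produces a negative 9–13 Hz modulation trend — a real property of that
generator, not an analysis error — whereas the null 9–13 Hz expectation
belongs to a cohort whose alpha profile does not drift. The drifting
profile is exercised separately by the trajectory tests (positive
peak-alpha-frequency trend; opposite-signed 5–9 and 11–15 Hz trends).

What passing does and does not show: the generator produces stationary
Gaussian band-limited components, one fixed dipole, spherical geometry and
ideal sensors. Passing therefore validates the machinery — geometry,
filters, covariances, weights, features, the optimizer, the statistics —
not the biology: real OPM data add head movement, sensor nonlinearity,
correlated environmental noise, non-Gaussian artifacts and anatomical
variability that this artifact deliberately leaves out.

## Numerical choices and degenerate inputs

- Zero-phase filtering: squared-magnitude frequency response with
  reflection padding to a 2-3-5-smooth length.
- LCMV: rank-deficient voxel gain matrices (fewer than two usable
  directions) are flagged and zeroed; orientation sign is fixed by the
  first-nonzero-positive rule.
- Pseudo-T: 0 where both window powers are 0; negative projected powers
  (numerical) are clipped with a warning.
- Alpha remover: optimizer failure at all three starts returns the input
  unchanged, flagged.
- `fit_spectrum`: instability anywhere in parameter space is treated as an
  infeasible step, never an error, except at the prior mean itself.
- All simulators draw from per-call seeded generators and restore the
  caller's RNG state; identical seeds give bit-identical outputs.

## Known limitations

- The sphere forward model ignores realistic head geometry; localization
  statements are relative to its own geometry.
- The CMC wiring beyond the anchored connections is conventional, not
  derived from the source analysis, whose table is unpublished.
- The MAP + Laplace inversion is a deterministic stand-in for full
  variational schemes; it suffices for intersubject comparison, which is
  the only use made of `F` here.
- Single-subject gain estimates carry ~0.13–0.15 posterior SD at the
  declared noise level; only cohort-level rank statements are robust at
  these problem sizes. For joint downward shifts of the superficial-loop
  gains, the posterior mode additionally carries a reproducible upward bias
  on the inhibitory gain G11 of about 0.16 log units (verified to be the
  global optimum, not an optimizer artifact): the likelihood ridge between
  the loop gains is asymmetric, and occasional realizations excurse along
  it by 0.4 or more. Recovery summaries for that direction should be read
  with this in mind.
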