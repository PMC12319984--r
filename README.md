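# opmgamma

Developmental trajectories of visual gamma oscillations and cortical
excitation–inhibition (E-I) balance, rebuilt as a tested, desk-scale R
pipeline for wearable optically-pumped-magnetometer MEG (OPM-MEG), with a
synthetic-data generator standing in for human recordings.

## Who this is for

Researchers studying stimulus-induced gamma oscillations across development
with wearable MEG. Visual gratings induce narrowband gamma (30–80 Hz) in
primary visual cortex whose amplitude and peak frequency mature from
childhood to adulthood; a canonical-microcircuit (CMC) neural-mass model
fitted to the stimulus-vs-rest relative spectrum attributes that maturation
to intrinsic connection gains — in particular the ratio of the excitatory
(G12) to inhibitory (G11) coupling between superficial pyramidal cells and
inhibitory interneurons, an index of superficial-layer E-I balance. The
package implements every stage of that analysis chain so each one can be
validated closed-loop against known synthetic ground truth.

## What it implements

- **synthetic data** — multi-axis sensor arrays on a posterior spherical
  cap; continuous recordings with a V1 dipole expressing gated gamma
  (broadband in children, narrowband ~50–60 Hz in adults), alpha
  suppression, sensor noise, homogeneous-field drift, mains interference,
  bad channels, high-variance trials, blink transients; and spectrum-level
  cohorts drawn from the CMC model with age-linked drifts of
  log G12, log G11, log G5 (`build_sensor_array`,
  `simulate_subject_recording`, `simulate_cmc_cohort`).
- **preprocessing** — MAD-based bad-channel detection, zero-phase notch
  (mains + 2 harmonics) and 1–150 Hz band-pass, [-1, 2) s epochs, mean+3SD
  trial-variance rejection, artifact regression / seeded ICA, homogeneous
  field correction, cross-group trial matching (`preprocess_recording`).
- **beamforming** — analytic conducting-sphere (Sarvas) lead fields; scalar
  LCMV weights from the broadband covariance with 5 % Tikhonov loading;
  gamma (30–80 Hz) and alpha (6–14 Hz) pseudo-T contrasts between the
  0.3–1 s stimulus and -0.8 to -0.1 s rest windows,
  `(P_on − P_off) / (P_on + P_off)`; dual-resolution peak localization and
  virtual electrodes (`compute_lead_field`, `lcmv_scalar_weights`,
  `pseudo_t_image`, `virtual_timecourse`).
- **spectra** — 45 overlapping bands (4 Hz wide, 2 Hz apart), Hilbert
  envelopes, baseline-normalized time-frequency spectra; the DCM input
  feature `|(PSD_on − PSD_off)/PSD_off|` with cohort area-normalization and
  removal of an 8–13 Hz alpha Gaussian; rest-window peak-alpha frequency
  (`hilbert_tfs`, `relative_psd`, `fit_and_remove_alpha_gaussian`).
- **microcircuit model** — a linearised four-population CMC (spiny
  stellate, superficial/deep pyramidal, interneurons) with gains G1–G13
  (G1, G3, G10, G13 fixed); spectral forward prediction
  `output_gain · |H(f)|² · (white + pink/f)`; empirical priors from the
  grand-average fit; deterministic MAP inversion (Gauss–Newton with
  Levenberg damping plus quasi-Newton polish) with a Laplace free-energy
  `F`; E-I ratios G12/G11 and G6/G9 (`forward_spectrum`, `fit_spectrum`,
  `ei_ratios`).
- **trajectories** — tie-corrected Spearman correlations against age with
  Bonferroni families of 44 bands (threshold 0.0011) and 10 parameters
  (threshold 0.005); peak-location and alpha-trend reports
  (`spectrum_age_correlation`, `parameter_age_correlation`).

## Worked example

```r
library(opmgamma)

arr <- build_sensor_array(64, 3, head_radius = 0.09, line_freq = 50, seed = 1)
length(arr$channel_labels)
#> [1] 192

# a desk-scale subject: 16 triaxial sensors, 600 Hz, 16 trials
arr16 <- build_sensor_array(16, 3, head_radius = 0.09, line_freq = 50,
                            seed = 2)
sim <- simulate_subject_recording(source_spec(age_years = 30), arr16,
                                  n_trials = 16, fs = 600, seed = 7)
res <- analyze_subject(sim$recording, cfg = run_config())
round(res$gamma_peak * 1e3, 1)          # pseudo-T gamma peak, mm
#> [1]   8 -64  14                       # seeded dipole: (5, -62, 12) mm
round(max(res$band_change), 3)          # strongest stimulus-induced change
#> [1] 0.466                             # in the 53-57 Hz band
round(res$paf, 2)                       # rest-window peak alpha frequency
#> [1] 9.23                              # generative alpha peak: 9.3 Hz
```

The localization error here is 4.1 mm on a 4 mm grid, the band of maximal
relative amplitude change contains the injected 55.5 Hz narrowband gamma
centre, and the rest alpha peak is recovered to the spectral resolution.
`run_pipeline(run_config(...))` chains the full cohort analysis — sensor
simulation, preprocessing, beamforming, spectra, empirical-prior CMC fits
and the trajectory statistics — and returns the cohort table plus the
band/parameter/alpha/peak correlation reports.

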