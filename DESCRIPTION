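Package: opmgamma
Title: Developmental Trajectories of Visual Gamma Oscillations and Cortical
    Excitation-Inhibition Balance from Simulated OPM-MEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale analysis pipeline for wearable magnetoencephalography
    (OPM-MEG) studies of visual gamma oscillations across development. Provides
    a synthetic-data generator for multi-axis magnetometer arrays and
    age-parameterised cohorts, sensor-space preprocessing (notch and band-pass
    filtering, variance-based trial rejection, artifact regression, homogeneous
    field correction), an LCMV beamformer with analytic conducting-sphere lead
    fields and pseudo-T contrast imaging, Hilbert-envelope time-frequency
    spectra and stimulus-versus-rest relative spectral features, a linearised
    canonical-microcircuit neural-mass model with maximum-a-posteriori spectral
    inversion and free-energy reporting, and cohort-level Spearman/Bonferroni
    trajectory statistics for band amplitudes and excitation-inhibition gain
    ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
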