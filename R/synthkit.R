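# Synthetic OPM-MEG data: posterior sensor arrays, subject-level recordings
# with a primary-visual-cortex dipolar source, and spectrum-level cohorts
# generated from the canonical-microcircuit forward model with known ground
# truth.

#' Build a multi-axis magnetometer array over occipital cortex
#'
#' Sensors are placed quasi-uniformly (Fibonacci lattice with a small seeded
#' jitter) on a posterior-weighted spherical cap at a 6.5 mm standoff from
#' the scalp sphere, approximating a rigid helmet whose coverage favours the
#' visual cortices. Each sensor carries an orthonormal axis set (radial
#' first); dual-axis sensors measure the radial and first tangential
#' components.
#'
#' @param n_sensors number of sensor housings (>= 8).
#' @param n_axes measurement axes per sensor, 2 or 3.
#' @param head_radius scalp sphere radius in metres.
#' @param line_freq mains frequency of the site, 50 or 60 Hz.
#' @param seed integer seed; identical seeds give identical arrays.
#' @param cap_half_angle angular radius of the covered cap (radians).
#' @return Object of class `sensor_array` with `channel_labels`,
#'   `positions` (channels x 3, m), `orientations` (channels x 3, unit),
#'   `sensor_ids`, `n_axes_per_sensor`, `line_freq`, `head_radius`.
#' @examples
#' arr <- build_sensor_array(64, 3, 0.09, 50, seed = 1)
#' length(arr$channel_labels)  # 192 channels
#' @export
build_sensor_array <- function(n_sensors, n_axes, head_radius = 0.09,
                               line_freq = 50, seed = 1,
                               cap_half_angle = 1.25) {
  if (!n_axes %in% c(2, 3)) stop("n_axes must be 2 or 3")
  if (n_sensors < 8) stop("need at least 8 sensors")
  if (!line_freq %in% c(50, 60)) stop("line_freq must be 50 or 60 Hz")
  radius <- head_radius + 0.0065
  # cap axis: posterior and slightly superior (head frame x right,
  # y anterior, z superior)
  axis0 <- unit(c(0, -1, 0.35))
  golden <- pi * (3 - sqrt(5))
  with_seed(seed, {
    jitter_t <- stats::rnorm(n_sensors, 0, 0.01)
    jitter_p <- stats::rnorm(n_sensors, 0, 0.01)
    phi0 <- stats::runif(1, 0, 2 * pi)
  })
  i <- seq_len(n_sensors)
  tfrac <- pmin(pmax((i - 0.5) / n_sensors + jitter_t, 1e-4), 1 - 1e-4)
  theta <- acos(1 - tfrac * (1 - cos(cap_half_angle)))
  phi <- phi0 + i * golden + jitter_p
  # local frame with z along the cap axis
  ez <- axis0
  ex <- unit(cross3(ez, c(0, 0, 1)))
  ey <- cross3(ez, ex)
  dirs <- outer(sin(theta) * cos(phi), ex) +
          outer(sin(theta) * sin(phi), ey) +
          outer(cos(theta), ez)
  sens_pos <- dirs * radius
  axes_names <- c("RAD", "TAN1", "TAN2")[seq_len(n_axes)]
  pos <- matrix(0, n_sensors * n_axes, 3)
  ori <- matrix(0, n_sensors * n_axes, 3)
  labels <- character(n_sensors * n_axes)
  sensor_ids <- integer(n_sensors * n_axes)
  for (s in seq_len(n_sensors)) {
    er <- unit(sens_pos[s, ])
    helper <- if (abs(er[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    t1 <- unit(cross3(er, helper))
    t2 <- cross3(er, t1)
    A <- rbind(er, t1, t2)[seq_len(n_axes), , drop = FALSE]
    rows <- (s - 1) * n_axes + seq_len(n_axes)
    pos[rows, ] <- matrix(sens_pos[s, ], n_axes, 3, byrow = TRUE)
    ori[rows, ] <- A
    labels[rows] <- sprintf("S%03d-%s", s, axes_names)
    sensor_ids[rows] <- s
  }
  structure(list(channel_labels = labels, positions = pos,
                 orientations = ori, sensor_ids = sensor_ids,
                 n_axes_per_sensor = n_axes, line_freq = line_freq,
                 head_radius = head_radius),
            class = "sensor_array")
}

#' Age-dependent spectral profile of the simulated visual cortex source
#'
#' Maps age to the generative spectral phenomenology: the alpha peak drifts
#' upward slowly, alpha suppression is constant, broadband gamma is
#' age-invariant, and a narrowband gamma component emerges with age, its
#' centre rising towards the adult 50-60 Hz range (capped at 60 Hz).
#'
#' @param age_years age in years.
#' @return A list of profile fields consumed by [source_spec()].
#' @export
age_profile <- function(age_years) {
  list(
    alpha_freq = 7.5 + 0.06 * age_years,
    alpha_suppression = 0.35,
    gamma_broad_amp = 0.08,
    gamma_narrow_amp = 0.02 + 0.009 * age_years,
    gamma_centre = min(45 + 0.35 * age_years, 60)
  )
}

#' Specification of a simulated dipolar source
#'
#' @param age_years subject age; defaults for the spectral profile are
#'   taken from [age_profile()] and can be overridden.
#' @param dipole_position position in metres, strictly inside the sphere
#'   (default: primary visual cortex, ~2.4 cm deep to the occipital scalp).
#' @param dipole_orientation dipole moment direction (normalised
#'   internally); tangential orientations are visible to MEG.
#' @param sphere conductor sphere (`centre`, `radius`, m).
#' @param ... profile overrides (`alpha_freq`, `alpha_suppression`,
#'   `gamma_broad_amp`, `gamma_narrow_amp`, `gamma_centre`).
#' @return Object of class `source_spec`.
#' @export
source_spec <- function(age_years,
                        dipole_position = c(0.005, -0.062, 0.012),
                        dipole_orientation = c(1, 0, 0),
                        sphere = list(centre = c(0, 0, 0), radius = 0.09),
                        ...) {
  prof <- age_profile(age_years)
  dots <- list(...)
  bad <- setdiff(names(dots), names(prof))
  if (length(bad)) stop("unknown profile field(s): ",
                        paste(bad, collapse = ", "))
  prof[names(dots)] <- dots
  if (sqrt(sum((dipole_position - sphere$centre)^2)) >= sphere$radius) {
    stop("dipole must lie strictly inside the conductor sphere")
  }
  if (prof$alpha_suppression < 0 || prof$alpha_suppression > 1) {
    stop("alpha suppression fraction must lie in [0, 1]")
  }
  if (prof$gamma_narrow_amp < 0 || prof$gamma_broad_amp < 0) {
    stop("amplitudes must be nonnegative")
  }
  structure(c(list(age_years = age_years,
                   dipole_position = dipole_position,
                   dipole_orientation = unit(dipole_orientation),
                   sphere = sphere), prof),
            class = "source_spec")
}

#' Noise and artifact configuration for the recording simulator
#'
#' @param sensor_noise_sd per-sample white sensor noise (T); the default
#'   corresponds to ~15 fT/sqrt(Hz) at a 1200 Hz sampling rate.
#' @param hfc_drift_amp amplitude of the spatially homogeneous interference
#'   drift (T).
#' @param line_amp mains interference amplitude at the fundamental (T);
#'   harmonics are attenuated by half per order.
#' @param n_noisy_channels,n_dead_channels channels given 20x noise or near
#'   zero signal (flagged in the ground truth, not in the recording).
#' @param n_highvar_trials trials injected with a large broadband burst.
#' @param blink_rate mean blink-transient rate (per second).
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(sensor_noise_sd = 3.7e-13,
                         hfc_drift_amp = 3e-12,
                         line_amp = 1e-12,
                         n_noisy_channels = 0,
                         n_dead_channels = 0,
                         n_highvar_trials = 0,
                         blink_rate = 0) {
  structure(list(sensor_noise_sd = sensor_noise_sd,
                 hfc_drift_amp = hfc_drift_amp,
                 line_amp = line_amp,
                 n_noisy_channels = n_noisy_channels,
                 n_dead_channels = n_dead_channels,
                 n_highvar_trials = n_highvar_trials,
                 blink_rate = blink_rate),
            class = "noise_config")
}

# cosine-ramped stimulus gate over a sample grid (ramp in seconds)
stim_gate <- function(n, onsets, fs, dur = 1, ramp = 0.05) {
  g <- numeric(n)
  nr <- round(ramp * fs)
  up <- (1 - cos(pi * seq_len(nr) / nr)) / 2
  for (o in onsets) {
    a <- o + 1
    b <- min(o + round(dur * fs), n)
    if (a > n) next
    g[a:b] <- 1
    ru <- a:min(a + nr - 1, n)
    g[ru] <- pmin(g[ru], up[seq_along(ru)])
    rd <- b:min(b + nr - 1, n)
    g[rd] <- pmax(g[rd] - up[seq_along(rd)], 0)
  }
  g
}

#' Simulate a subject-level OPM recording
#'
#' Generates a continuous multichannel recording: a visual-cortex dipole
#' expressing a stimulus-gated gamma response (narrowband plus broadband
#' 30-80 Hz, 50 ms cosine ramps) and ongoing alpha that is suppressed
#' during stimulation, projected to the sensors through the conducting-
#' sphere forward model, plus white sensor noise, a spatially homogeneous
#' interference drift, mains noise at the site line frequency and two
#' harmonics, and optional flagged bad channels, high-variance trials and
#' blink-like transients. Trials are 1 s of stimulation followed by a
#' jittered 1250 +/- 200 ms rest.
#'
#' @param spec A `source_spec`.
#' @param array A `sensor_array`.
#' @param n_trials number of stimulus trials.
#' @param fs sampling rate (Hz, >= 600).
#' @param noise_cfg A `noise_config`.
#' @param seed integer seed; identical arguments and seed give identical
#'   recordings.
#' @param source_floor_nAm standard deviation of the ongoing broadband
#'   source floor, nanoampere-metres; profile amplitudes express the
#'   stimulus-induced relative envelope change against this floor.
#' @return List with `recording` (class `recording`: `data` channels x
#'   samples in tesla, `fs`, `events`, `bad_channels`, `array`) and `truth`
#'   (ground-truth record: source time course, gate, blink reference,
#'   injected bad channels and trials, component scales).
#' @export
simulate_subject_recording <- function(spec, array, n_trials = 60,
                                       fs = 1200,
                                       noise_cfg = noise_config(),
                                       seed = 1,
                                       source_floor_nAm = 20) {
  stopifnot(inherits(spec, "source_spec"), inherits(array, "sensor_array"))
  if (n_trials < 1) stop("need at least one trial")
  if (fs < 600) stop("sampling rate must be at least 600 Hz")
  nch <- nrow(array$positions)
  with_seed(seed, {
    jit <- stats::runif(n_trials, 1.050, 1.450)       # rest 1250 +/- 200 ms
    pad <- 1.5
    onsets <- integer(n_trials)
    t0 <- pad
    for (k in seq_len(n_trials)) {
      onsets[k] <- round(t0 * fs)
      t0 <- t0 + 1 + jit[k]
    }
    n <- onsets[n_trials] + round((2.2) * fs)
    tt <- seq_len(n) / fs
    gate <- stim_gate(n, onsets, fs)

    nyq <- fs / 2
    floor_sd <- source_floor_nAm * 1e-9
    # per-band floor amplitude in a 4 Hz analysis band; profile amplitudes
    # are the target relative envelope changes against this in-band floor
    band_frac <- sqrt(4 / nyq)
    scale_rel <- function(rel, overlap = 0.55) {
      # power needed in the analysis band for relative envelope change rel
      floor_sd * band_frac * sqrt(max((1 + rel)^2 - 1, 0) / overlap)
    }

    src_floor <- stats::rnorm(n, 0, floor_sd)
    alpha_raw <- bp_filter(stats::rnorm(n), c(spec$alpha_freq - 1.5,
                                              spec$alpha_freq + 1.5), fs)
    # alpha is narrow (~3 Hz wide) so most of its power falls in one band
    alpha_sd <- scale_rel(1.0, overlap = 0.9)  # prominent rest alpha bump
    alpha <- alpha_raw / stats::sd(alpha_raw) * alpha_sd *
      (1 - spec$alpha_suppression * gate)
    gnb_raw <- bp_filter(stats::rnorm(n), c(spec$gamma_centre - 4,
                                            spec$gamma_centre + 4), fs)
    gnb <- gnb_raw / stats::sd(gnb_raw) * scale_rel(spec$gamma_narrow_amp) *
      gate
    gbb_raw <- bp_filter(stats::rnorm(n), c(30, 80), fs)
    # broadband component: spread over 50 Hz, ~4/50 of power per band
    gbb <- gbb_raw / stats::sd(gbb_raw) *
      scale_rel(spec$gamma_broad_amp, overlap = 4 / 50) * gate
    source_tc <- src_floor + alpha + gnb + gbb

    # forward projection
    B <- sarvas_field(array$positions, spec$dipole_position,
                      spec$dipole_orientation, spec$sphere$centre)
    gain <- as.numeric(rowSums(B * array$orientations))   # T per A m
    data <- outer(gain, source_tc)

    # sensor white noise
    data <- data + matrix(stats::rnorm(nch * n, 0, noise_cfg$sensor_noise_sd),
                          nch, n)
    # spatially homogeneous drift: slow random field direction(s)
    if (noise_cfg$hfc_drift_amp > 0) {
      for (k in 1:3) {
        drift <- bp_filter(stats::rnorm(n), c(0.1, 0.7), fs, order = 2)
        drift <- drift / stats::sd(drift) * noise_cfg$hfc_drift_amp
        u <- unit(stats::rnorm(3))
        data <- data + outer(as.numeric(array$orientations %*% u), drift)
      }
    }
    # mains interference and 2 harmonics, common phase, per-channel gain
    if (noise_cfg$line_amp > 0) {
      for (h in 1:3) {
        f <- array$line_freq * h
        if (f < nyq * 0.95) {
          ph <- stats::runif(1, 0, 2 * pi)
          amp <- noise_cfg$line_amp / 2^(h - 1) *
            (0.5 + stats::runif(nch))
          data <- data + outer(amp, sin(2 * pi * f * tt + ph))
        }
      }
    }
    # blink-like transients: frontal-weighted biphasic 1-4 Hz waves
    blink_ref <- numeric(n)
    if (noise_cfg$blink_rate > 0) {
      nblink <- stats::rpois(1, noise_cfg$blink_rate * n / fs)
      if (nblink > 0) {
        centers <- sort(stats::runif(nblink, 0.3, n / fs - 0.3))
        for (cc in centers) {
          tb <- (tt - cc)
          w <- -tb * exp(-tb^2 / (2 * 0.08^2))   # biphasic, ~2 Hz content
          blink_ref <- blink_ref + w / max(abs(w))
        }
        wfront <- pmax(array$positions[, 2], 0) + 0.15 * array$head_radius
        wfront <- wfront / max(wfront)
        data <- data + outer(wfront * 5e-12, blink_ref)
      }
    }
    # flagged bad channels
    bad <- character(0)
    if (noise_cfg$n_noisy_channels > 0 || noise_cfg$n_dead_channels > 0) {
      idx <- sample(nch, noise_cfg$n_noisy_channels +
                      noise_cfg$n_dead_channels)
      noisy <- idx[seq_len(noise_cfg$n_noisy_channels)]
      dead <- setdiff(idx, noisy)
      for (j in noisy) data[j, ] <- data[j, ] +
          stats::rnorm(n, 0, 20 * noise_cfg$sensor_noise_sd)
      for (j in dead) data[j, ] <- data[j, ] * 1e-6
      bad <- array$channel_labels[idx]
    }
    # high-variance trials
    hv <- integer(0)
    if (noise_cfg$n_highvar_trials > 0) {
      hv <- sort(sample(n_trials, noise_cfg$n_highvar_trials))
      for (k in hv) {
        a <- onsets[k]; b <- min(a + fs, n)
        data[, a:b] <- data[, a:b] +
          matrix(stats::rnorm(nch * (b - a + 1), 0,
                              10 * noise_cfg$sensor_noise_sd),
                 nch, b - a + 1)
      }
    }
  })
  events <- data.frame(sample = onsets, label = "stim_on",
                       stringsAsFactors = FALSE)
  rec <- structure(list(data = data, fs = fs, events = events,
                        bad_channels = character(0), array = array),
                   class = "recording")
  truth <- list(source_tc = source_tc, gate = gate, blink_ref = blink_ref,
                injected_bad_channels = bad, highvar_trials = hv,
                dipole_position = spec$dipole_position,
                dipole_orientation = spec$dipole_orientation,
                gain = gain, profile = spec, seed = seed)
  list(recording = rec, truth = truth)
}

#' Specification of a spectrum-level cohort
#'
#' Each subject's true circuit is drawn from the log-scaling priors, with
#' age-linked linear drifts (centred on the cohort mid-age) on the log
#' scalings of G12, G11 and G5. The defaults encode the developmental
#' hypothesis under study: superficial excitation (G12) falls and
#' inhibition (G11) rises with age, so the E-I ratio G12/G11 declines,
#' while the stellate-to-interneuron drive G5 rises.
#'
#' @param n_subjects cohort size (>= 2).
#' @param age_range sampled uniformly (years).
#' @param slope_logG12,slope_logG11,slope_logG5 drift of the log scalings
#'   per year of age.
#' @param noise_level standard deviation of the multiplicative log-normal
#'   observation noise on each spectral value.
#' @param seed integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 40, age_range = c(2, 34),
                        slope_logG12 = -0.02, slope_logG11 = 0.02,
                        slope_logG5 = 0.02, noise_level = 0.05,
                        seed = 1) {
  if (n_subjects < 2) stop("need at least 2 subjects")
  if (noise_level < 0) stop("noise level must be nonnegative")
  structure(list(n_subjects = n_subjects, age_range = age_range,
                 slope_logG12 = slope_logG12, slope_logG11 = slope_logG11,
                 slope_logG5 = slope_logG5, noise_level = noise_level,
                 seed = seed),
            class = "cohort_spec")
}

#' Simulate a cohort of relative spectra from the microcircuit model
#'
#' For every subject: draw the free log-scalings from the priors, add the
#' age-linked drifts, push through [forward_spectrum()], and apply
#' multiplicative log-normal observation noise. Ground truth is returned
#' alongside each spectrum.
#'
#' @param spec A `cohort_spec`.
#' @param freqs frequency grid (Hz), strictly increasing within (0, 150].
#' @param base Reference parameters (scaled by the drawn log-scalings).
#' @param priors Priors supplying the free-parameter set and variances.
#' @return List with `subjects` (per subject: `id`, `age_years`, `spectrum`
#'   (a `rel_spectrum`), `true_theta`, `true_params`, `true_ei`) and the
#'   input `spec`.
#' @export
simulate_cmc_cohort <- function(spec, freqs = seq(1, 100, by = 0.25),
                                base = cmc_default_params(),
                                priors = default_priors()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (any(freqs <= 0) || any(freqs > 150) || any(diff(freqs) <= 0)) {
    stop("freqs must be strictly increasing within (0, 150]")
  }
  free <- priors$free
  mid <- mean(spec$age_range)
  subjects <- with_seed(spec$seed, {
    ages <- stats::runif(spec$n_subjects, spec$age_range[1],
                         spec$age_range[2])
    lapply(seq_len(spec$n_subjects), function(i) {
      repeat {
        th <- stats::rnorm(length(free), 0, sqrt(1 / 8))
        names(th) <- free
        th["G12"] <- th["G12"] + spec$slope_logG12 * (ages[i] - mid)
        th["G11"] <- th["G11"] + spec$slope_logG11 * (ages[i] - mid)
        th["G5"] <- th["G5"] + spec$slope_logG5 * (ages[i] - mid)
        s <- tryCatch(forward_spectrum(apply_scalings(base, th), freqs),
                      error = function(e) NULL)
        if (!is.null(s)) break                 # redraw unstable circuits
      }
      y <- s * exp(stats::rnorm(length(freqs), 0, spec$noise_level))
      p_true <- apply_scalings(base, th)
      list(id = sprintf("sub-%03d", i), age_years = ages[i],
           spectrum = rel_spectrum(freqs, y, subject_id = sprintf("sub-%03d", i),
                                   age_years = ages[i], normalized = TRUE,
                                   alpha_removed = TRUE),
           true_theta = th, true_params = p_true,
           true_ei = ei_ratios(p_true))
    })
  })
  list(subjects = subjects, spec = spec, freqs = freqs)
}
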