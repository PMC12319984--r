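# Shared fixture builders; everything is generated in code.

tiny_array <- function(n_sensors = 12, n_axes = 3, seed = 11) {
  build_sensor_array(n_sensors, n_axes, head_radius = 0.09, line_freq = 50,
                     seed = seed)
}

# a clean multichannel recording carrying a pure dipolar source time course
dipole_recording <- function(array, source_tc, fs = 600,
                             dip = c(0.005, -0.062, 0.012),
                             ori = c(1, 0, 0), events = NULL) {
  B <- sarvas_field(array$positions, dip, ori / sqrt(sum(ori^2)))
  gain <- rowSums(B * array$orientations)
  data <- outer(gain, source_tc)
  if (is.null(events)) events <- data.frame(sample = integer(0),
                                            label = character(0))
  structure(list(data = data, fs = fs, events = events,
                 bad_channels = character(0), array = array),
            class = "recording")
}

# epochs holding given trial data (trials x channels x samples)
make_epochs <- function(data, fs = 600, tmin = -1, array = NULL) {
  structure(list(data = data, tmin = tmin,
                 tmax = tmin + dim(data)[3] / fs, fs = fs,
                 retained_trial_ids = seq_len(dim(data)[1]),
                 array = array),
            class = "epochs")
}

# minimal stand-in for a fitted model, for trajectory-statistics tests
fake_fit <- function(G, F = 0, converged = TRUE) {
  p <- cmc_default_params()
  p$G[names(G)] <- G
  structure(list(params = p, F = F, converged = converged,
                 theta = numeric(0)), class = "cmc_fit")
}
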