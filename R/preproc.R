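# Sensor-space preprocessing: channel vetting, filtering, epoching,
# variance-based trial rejection, artifact removal, homogeneous field
# correction and cross-group trial matching. No operation mutates its
# input; removals are reported in the returned objects.

#' Automated bad-channel detection
#'
#' Flags channels whose median log power spectral density over 1-150 Hz
#' deviates from the cross-channel median by more than `threshold` scaled
#' median absolute deviations in either direction (high noise or low
#' signal), plus channels that are essentially dead (variance below
#' 1e-30 T^2). Strict inequality: a channel at exactly the threshold is
#' kept.
#'
#' @param rec A `recording` (>= 8 channels).
#' @param threshold MAD multiple.
#' @return Character vector of flagged channel labels.
#' @export
detect_bad_channels <- function(rec, threshold = 3.5) {
  nch <- nrow(rec$data)
  if (nch < 8) stop("bad-channel statistics need at least 8 channels")
  n <- ncol(rec$data)
  nwin <- min(2^floor(log2(n)), 4096)
  nseg <- max(1L, n %/% nwin)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1))
  freqs <- (seq_len(nwin %/% 2)) * rec$fs / nwin
  keep <- freqs >= 1 & freqs <= 150
  med_logpsd <- numeric(nch)
  variances <- numeric(nch)
  for (ch in seq_len(nch)) {
    x <- rec$data[ch, ]
    variances[ch] <- stats::var(x)
    p <- numeric(sum(keep))
    for (sgm in seq_len(nseg)) {
      xs <- x[((sgm - 1) * nwin + 1):(sgm * nwin)]
      X <- stats::fft((xs - mean(xs)) * hann)
      p <- p + (Mod(X)^2)[2:(nwin %/% 2 + 1)][keep]
    }
    med_logpsd[ch] <- stats::median(log10(p / nseg + 1e-300))
  }
  ctr <- stats::median(med_logpsd)
  sc <- stats::mad(med_logpsd)
  dev <- if (sc > 0) abs(med_logpsd - ctr) / sc else numeric(nch)
  flagged <- dev > threshold | variances < 1e-30
  labels <- if (!is.null(rec$array)) rec$array$channel_labels else
    as.character(seq_len(nch))
  structure(labels[flagged], deviations = stats::setNames(dev, labels))
}

#' Notch and band-pass filter a recording
#'
#' Zero-phase notch filters (2 Hz half-width) at the mains frequency and
#' two harmonics, followed by a zero-phase 4th-order 1-150 Hz Butterworth
#' band-pass.
#'
#' @param rec A `recording`.
#' @param line_freq mains frequency (Hz); defaults to the array's.
#' @param bandpass length-2 band edges (Hz).
#' @param notch_halfwidth half-width of each notch (Hz).
#' @return A new filtered `recording`.
#' @export
filter_recording <- function(rec, line_freq = NULL, bandpass = c(1, 150),
                             notch_halfwidth = 2) {
  if (is.null(line_freq)) line_freq <- rec$array$line_freq
  fs <- rec$fs
  if (fs <= 2 * 3 * line_freq) {
    stop("sampling rate too low for the third line-noise harmonic")
  }
  if (fs <= 2 * bandpass[2]) stop("sampling rate too low for the band-pass")
  out <- rec
  X <- rec$data
  filts <- lapply(1:3, function(h) {
    f0 <- line_freq * h
    signal::butter(2, c(f0 - notch_halfwidth, f0 + notch_halfwidth) / (fs / 2),
                   type = "stop")
  })
  bp <- signal::butter(4, bandpass / (fs / 2), type = "pass")
  out$data <- zp_filter_rows(X, c(filts, list(bp)))
  out
}

#' Segment a recording into stimulus-locked epochs
#'
#' One trial per onset event, covering `[tmin, tmax)` relative to onset
#' (half-open, so a 3 s epoch at 1200 Hz holds exactly 3600 samples).
#' Events too close to the recording edges are dropped with a warning.
#'
#' @param rec A `recording`.
#' @param tmin,tmax epoch window (s) relative to each event.
#' @return Object of class `epochs`: `data` (trials x channels x samples),
#'   `tmin`, `tmax`, `fs`, `retained_trial_ids`, `array`.
#' @export
epoch_trials <- function(rec, tmin = -1, tmax = 2) {
  fs <- rec$fs
  nsamp <- round((tmax - tmin) * fs)
  n <- ncol(rec$data)
  onsets <- rec$events$sample
  first <- onsets + round(tmin * fs)
  ok <- first >= 1 & (first + nsamp - 1) <= n
  if (any(!ok)) {
    warning(sum(!ok), " event(s) too close to the recording edge; dropped")
  }
  keep <- which(ok)
  if (!length(keep)) stop("no epochable events")
  data <- array(0, c(length(keep), nrow(rec$data), nsamp))
  for (k in seq_along(keep)) {
    a <- first[keep[k]]
    data[k, , ] <- rec$data[, a:(a + nsamp - 1)]
  }
  structure(list(data = data, tmin = tmin, tmax = tmax, fs = fs,
                 retained_trial_ids = keep, array = rec$array),
            class = "epochs")
}

#' Reject trials with outlying variance
#'
#' Per-trial variance is pooled over channels and samples; trials whose
#' variance exceeds mean + 3 SD (computed once over all trials; strict
#' inequality) are removed.
#'
#' @param ep An `epochs` object (>= 5 trials).
#' @param n_sd rejection threshold in standard deviations.
#' @return List with `epochs` (trimmed) and `rejected` (original trial ids).
#' @export
reject_high_variance_trials <- function(ep, n_sd = 3) {
  ntr <- dim(ep$data)[1]
  if (ntr < 5) stop("trial rejection needs at least 5 trials")
  v <- vapply(seq_len(ntr), function(k) stats::var(as.vector(ep$data[k, , ])),
              numeric(1))
  thr <- mean(v) + n_sd * stats::sd(v)
  bad <- which(v > thr)
  if (length(bad) == ntr) stop("all trials rejected: pathological input")
  out <- ep
  keep <- setdiff(seq_len(ntr), bad)
  out$data <- ep$data[keep, , , drop = FALSE]
  out$retained_trial_ids <- ep$retained_trial_ids[keep]
  list(epochs = out, rejected = ep$retained_trial_ids[bad])
}

#' Remove artifact components from epochs
#'
#' With reference traces (the simulator's ground-truth blink trace, or a
#' recorded electro-oculogram), each channel's least-squares projection onto
#' the references is subtracted (regression mode; deterministic). Without
#' references, a seeded fastICA-style decomposition is run and components
#' correlating above `cor_threshold` in absolute value with any template
#' are projected out (simulation mode).
#'
#' @param ep An `epochs` object.
#' @param references list of trials x samples matrices (or vectors,
#'   recycled across trials), time-aligned with the epochs.
#' @param templates artifact templates for ICA mode (same layout).
#' @param n_components,cor_threshold,seed ICA-mode settings.
#' @return List with `epochs` (cleaned) and `report`.
#' @export
remove_artifact_components <- function(ep, references = list(),
                                       templates = list(),
                                       n_components = 20,
                                       cor_threshold = 0.7, seed = 1) {
  ntr <- dim(ep$data)[1]; nch <- dim(ep$data)[2]; ns <- dim(ep$data)[3]
  flatten <- function(x) {
    if (is.vector(x)) x <- matrix(x, ntr, length(x), byrow = TRUE)
    if (ncol(x) != ns || nrow(x) != ntr) {
      stop("reference length mismatch with the epochs")
    }
    as.vector(t(x))
  }
  X <- matrix(0, nch, ntr * ns)   # channels x concatenated samples
  for (tr in seq_len(ntr)) {
    X[, ((tr - 1) * ns + 1):(tr * ns)] <- ep$data[tr, , ]
  }
  out <- ep
  if (length(references)) {
    R <- vapply(references, flatten, numeric(ntr * ns))
    keepref <- apply(R, 2, function(r) stats::var(r) > 0)
    report <- list(mode = "regression", n_references = sum(keepref))
    if (any(keepref)) {
      # intercept column so the projection is exact for un-demeaned data
      R <- cbind(1, R[, keepref, drop = FALSE])
      beta <- solve(crossprod(R), crossprod(R, t(X)))
      X <- X - t(R %*% beta)
    }
  } else if (length(templates)) {
    mix <- fast_ica(X, n_components = min(n_components, nch), seed = seed)
    Tm <- vapply(templates, flatten, numeric(ntr * ns))
    cors <- abs(stats::cor(t(mix$S), Tm))
    bad <- which(apply(cors, 1, max) > cor_threshold)
    report <- list(mode = "ica", removed_components = bad)
    if (length(bad)) {
      X <- X - mix$A[, bad, drop = FALSE] %*% mix$S[bad, , drop = FALSE]
    }
  } else {
    report <- list(mode = "none", removed_components = integer(0))
  }
  for (tr in seq_len(ntr)) {
    out$data[tr, , ] <- X[, ((tr - 1) * ns + 1):(tr * ns)]
  }
  list(epochs = out, report = report)
}

# Compact symmetric fastICA (logcosh contrast) on whitened data; X is
# channels x samples. Returns sources S (k x samples) and mixing A
# (channels x k) such that X ~ A S + mean.
fast_ica <- function(X, n_components, seed = 1, max_iter = 200, tol = 1e-6) {
  mu <- rowMeans(X)
  Xc <- X - mu
  cv <- tcrossprod(Xc) / (ncol(Xc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  k <- min(n_components, sum(eg$values > eg$values[1] * 1e-10))
  K <- diag(1 / sqrt(eg$values[1:k])) %*% t(eg$vectors[, 1:k])
  Z <- K %*% Xc                                  # whitened, k x n
  W <- with_seed(seed, matrix(stats::rnorm(k * k), k, k))
  sym_decorrelate <- function(W) {
    s <- eigen(W %*% t(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(s$values)) %*% t(s$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gp <- rowMeans(1 - G^2)
    W1 <- (G %*% t(Z)) / ncol(Z) - diag(gp) %*% W
    W1 <- sym_decorrelate(W1)
    d <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (d < tol) break
  }
  S <- W %*% Z
  A <- sweep(Xc %*% t(S), 2, rowSums(S^2), "/")   # LS mixing, nch x k
  list(S = S, A = A, W = W)
}

#' Homogeneous field correction
#'
#' Projects out the spatially uniform field component using the channel
#' orientation matrix N (channels x 3): every time sample is multiplied by
#' `I - N (N'N)^-1 N'`. The projector is symmetric and idempotent with
#' exactly three zero eigenvalues when N has full column rank.
#'
#' @param ep An `epochs` object.
#' @param array A `sensor_array`; defaults to the one carried by `ep`.
#' @return A corrected `epochs` object.
#' @export
homogeneous_field_correction <- function(ep, array = ep$array) {
  N <- array$orientations
  if (nrow(N) < 6) stop("homogeneous field correction needs >= 6 channels")
  if (qr(N)$rank < 3) {
    stop("channel orientations cannot resolve a homogeneous field (rank < 3)")
  }
  P <- diag(nrow(N)) - N %*% solve(crossprod(N), t(N))
  out <- ep
  for (tr in seq_len(dim(ep$data)[1])) {
    out$data[tr, , ] <- P %*% ep$data[tr, , ]
  }
  out
}

#' Match trial counts across age groups
#'
#' Iteratively removes one uniformly drawn trial from a random subject of
#' the group with the highest mean retained-trial count, until every group
#' mean is within one trial of the lowest group mean. Seeded and logged.
#'
#' @param epochs_list list of `epochs`, one per subject.
#' @param groups group label per subject (>= 2 distinct groups).
#' @param seed integer seed.
#' @return List with `epochs_list` (trimmed), `removals` (data.frame:
#'   subject, trial id) and `group_means`.
#' @export
match_trial_counts <- function(epochs_list, groups, seed = 1) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  counts <- vapply(epochs_list, function(e) dim(e$data)[1], integer(1))
  removals <- data.frame(subject = integer(0), trial_id = integer(0))
  with_seed(seed, {
    repeat {
      gm <- tapply(counts, groups, mean)
      if (max(gm) - min(gm) <= 1) break
      gtop <- names(gm)[which.max(gm)]
      cand <- which(groups == gtop)
      s <- cand[sample.int(length(cand), 1)]
      if (counts[s] <= 1) stop("a subject would reach 0 trials")
      k <- sample.int(counts[s], 1)
      removals <- rbind(removals, data.frame(
        subject = s, trial_id = epochs_list[[s]]$retained_trial_ids[k]))
      keep <- setdiff(seq_len(counts[s]), k)
      epochs_list[[s]]$data <-
        epochs_list[[s]]$data[keep, , , drop = FALSE]
      epochs_list[[s]]$retained_trial_ids <-
        epochs_list[[s]]$retained_trial_ids[keep]
      counts[s] <- counts[s] - 1L
    }
  })
  list(epochs_list = epochs_list, removals = removals,
       group_means = tapply(counts, groups, mean))
}

#' Standard preprocessing chain for one recording
#'
#' Fixed order: bad-channel removal, notch + band-pass filtering, epoching,
#' variance-based trial rejection, artifact regression against reference
#' traces, homogeneous field correction. Returns the cleaned epochs plus a
#' log of every removal.
#'
#' @param rec A `recording`.
#' @param references artifact reference traces (see
#'   [remove_artifact_components()]).
#' @param tmin,tmax epoch window (s).
#' @return List with `epochs`, `log`.
#' @export
preprocess_recording <- function(rec, references = list(),
                                 tmin = -1, tmax = 2) {
  bad <- detect_bad_channels(rec)
  keep <- !(rec$array$channel_labels %in% bad)
  rec2 <- rec
  rec2$data <- rec$data[keep, , drop = FALSE]
  rec2$bad_channels <- bad
  arr <- rec$array
  arr$channel_labels <- arr$channel_labels[keep]
  arr$positions <- arr$positions[keep, , drop = FALSE]
  arr$orientations <- arr$orientations[keep, , drop = FALSE]
  arr$sensor_ids <- arr$sensor_ids[keep]
  rec2$array <- arr
  rec2 <- filter_recording(rec2)
  ep <- epoch_trials(rec2, tmin, tmax)
  rej <- reject_high_variance_trials(ep)
  # references are continuous traces: cut to the retained epochs
  refs_ep <- lapply(references, function(r) {
    fs <- rec$fs
    nsamp <- round((tmax - tmin) * fs)
    onsets <- rec$events$sample[rej$epochs$retained_trial_ids]
    t(vapply(onsets, function(o) {
      a <- o + round(tmin * fs)
      r[a:(a + nsamp - 1)]
    }, numeric(nsamp)))
  })
  refs_ep <- refs_ep[vapply(refs_ep, function(r) any(r != 0), logical(1))]
  art <- remove_artifact_components(rej$epochs, references = refs_ep)
  ep2 <- homogeneous_field_correction(art$epochs)
  list(epochs = ep2,
       log = list(bad_channels = bad, rejected_trials = rej$rejected,
                  artifact = art$report,
                  n_trials = dim(ep2$data)[1]))
}
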