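test_that("bad-channel detection flags noisy and dead channels only", {
  arr <- tiny_array(8, 3, seed = 2)
  set.seed(1)
  n <- 6000
  data <- matrix(rnorm(24 * n, 0, 1e-13), 24, n)
  rec <- structure(list(data = data, fs = 600,
                        events = data.frame(sample = integer(0),
                                            label = character(0)),
                        bad_channels = character(0), array = arr),
                   class = "recording")
  expect_length(detect_bad_channels(rec), 0)

  rec2 <- rec
  rec2$data[5, ] <- rnorm(n, 0, 1e-11)   # 100x noise
  rec2$data[17, ] <- 0                   # dead
  expect_setequal(detect_bad_channels(rec2),
                  arr$channel_labels[c(5, 17)])

  small <- rec; small$data <- rec$data[1:7, ]
  expect_error(detect_bad_channels(small), "8 channels")
})

test_that("the bad-channel rule uses a strict inequality at its threshold", {
  arr <- tiny_array(8, 3, seed = 2)
  set.seed(2)
  n <- 4096
  base <- matrix(rnorm(24 * n, 0, 1e-13), 24, n)
  rec <- structure(list(data = base, fs = 600,
                        events = data.frame(sample = integer(0),
                                            label = character(0)),
                        bad_channels = character(0), array = arr),
                   class = "recording")
  dev <- attr(detect_bad_channels(rec), "deviations")
  dmax <- max(dev)
  # a channel sitting exactly at the threshold is retained ...
  expect_length(detect_bad_channels(rec, threshold = dmax), 0)
  # ... and flagged as soon as the threshold drops below its deviation
  just_under <- detect_bad_channels(rec, threshold = dmax * (1 - 1e-9))
  expect_identical(as.character(just_under), names(which.max(dev)))
})

test_that("filtering removes mains and DC but preserves the passband", {
  arr <- tiny_array(8, 2, seed = 3)
  fs <- 1200
  tt <- seq(0, 10, by = 1 / fs)[-1]
  mk_rec <- function(x) {
    structure(list(data = matrix(x, 16, length(x), byrow = TRUE),
                   fs = fs,
                   events = data.frame(sample = integer(0),
                                       label = character(0)),
                   bad_channels = character(0), array = arr),
              class = "recording")
  }
  rec50 <- mk_rec(sin(2 * pi * 50 * tt) * 1e-12)
  out50 <- filter_recording(rec50, line_freq = 50)
  mid <- 2000:10000
  expect_lt(sqrt(mean(out50$data[1, mid]^2)),
            0.01 * sqrt(mean(rec50$data[1, mid]^2)))

  rec40 <- mk_rec(sin(2 * pi * 40 * tt) * 1e-12)
  out40 <- filter_recording(rec40, line_freq = 50)
  expect_equal(sqrt(mean(out40$data[1, mid]^2)),
               sqrt(mean(rec40$data[1, mid]^2)), tolerance = 0.02)

  recdc <- mk_rec(rep(1e-12, length(tt)))
  outdc <- filter_recording(recdc, line_freq = 50)
  expect_lt(max(abs(outdc$data[1, mid])), 1e-14)

  expect_error(filter_recording(mk_rec(tt * 0), line_freq = 50 * 5),
               "sampling rate")
})

test_that("epoching uses the half-open window convention", {
  arr <- tiny_array(8, 2, seed = 3)
  fs <- 1200
  n <- fs * 200
  events <- data.frame(sample = round(seq(2, 196, length.out = 60) * fs),
                       label = "stim_on")
  rec <- structure(list(data = matrix(0, 16, n), fs = fs, events = events,
                        bad_channels = character(0), array = arr),
                   class = "recording")
  ep <- epoch_trials(rec, -1, 2)
  expect_equal(dim(ep$data), c(60, 16, 3600))
  expect_identical(ep$retained_trial_ids, 1:60)

  rec$events <- rbind(data.frame(sample = 100, label = "stim_on"), events)
  expect_warning(ep2 <- epoch_trials(rec, -1, 2), "dropped")
  expect_equal(dim(ep2$data)[1], 60)
})

test_that("trial variance rejection is single-pass with a strict threshold", {
  set.seed(4)
  base <- array(rnorm(20 * 4 * 100), c(20, 4, 100))
  same <- array(rep(base[1, , ], each = 20), c(20, 4, 100))
  ep <- make_epochs(same)
  out <- reject_high_variance_trials(ep)
  expect_length(out$rejected, 0)

  ep2 <- make_epochs(base)
  ep2$data[7, , ] <- ep2$data[7, , ] * sqrt(50)
  out2 <- reject_high_variance_trials(ep2)
  expect_identical(out2$rejected, 7L)
  expect_equal(dim(out2$epochs$data)[1], 19)

  # a trial exactly at mean + 3 SD is retained (strict inequality); the
  # other trials need spread (with equal co-trials a lone outlier sits at
  # z = (n-1)/sqrt(n) regardless of its size), so give them a ramp of
  # variances and solve for the boundary variance of the last trial
  vo <- seq(0.7, 1.3, length.out = 15)
  f <- function(v16) {
    vv <- c(vo, v16)
    v16 - (mean(vv) + 3 * sd(vv))
  }
  v16 <- uniroot(f, c(1.31, 1e6))$root
  dat <- array(0, c(16, 1, 200))
  set.seed(5)
  zz <- rnorm(200); zz <- (zz - mean(zz)) / sd(zz)
  for (k in 1:15) dat[k, 1, ] <- zz * sqrt(vo[k])
  dat[16, 1, ] <- zz * sqrt(v16)
  out3 <- reject_high_variance_trials(make_epochs(dat))
  expect_length(out3$rejected, 0)
  # nudging it above the boundary rejects it
  dat[16, 1, ] <- zz * sqrt(v16 * 1.02)
  out4 <- reject_high_variance_trials(make_epochs(dat))
  expect_identical(out4$rejected, 16L)
})

test_that("regression mode removes reference-shaped artifacts exactly", {
  set.seed(6)
  ntr <- 4; nch <- 6; ns <- 300
  ref <- matrix(rnorm(ntr * ns), ntr, ns)
  dat <- array(0, c(ntr, nch, ns))
  wts <- runif(nch, 0.5, 2)
  for (tr in 1:ntr) dat[tr, , ] <- outer(wts, ref[tr, ])
  ep <- make_epochs(dat)
  out <- remove_artifact_components(ep, references = list(ref))
  expect_lt(max(abs(out$epochs$data)), 1e-10)
  expect_identical(out$report$mode, "regression")

  # no references, no templates: identity
  ep2 <- make_epochs(array(rnorm(ntr * nch * ns), c(ntr, nch, ns)))
  out2 <- remove_artifact_components(ep2)
  expect_equal(out2$epochs$data, ep2$data)

  expect_error(remove_artifact_components(ep, references = list(ref[, 1:10])),
               "mismatch")
})

test_that("ICA mode removes an injected blink-like component", {
  set.seed(7)
  ntr <- 6; nch <- 18; ns <- 400
  dat <- array(rnorm(ntr * nch * ns, 0, 0.3), c(ntr, nch, ns))
  tt <- seq_len(ns) / 200
  blink <- matrix(0, ntr, ns)
  for (tr in 1:ntr) {
    c0 <- runif(1, 0.6, 1.4)
    blink[tr, ] <- -(tt - c0) * exp(-(tt - c0)^2 / (2 * 0.08^2)) * 8
  }
  topo <- runif(nch)
  for (tr in 1:ntr) dat[tr, , ] <- dat[tr, , ] + outer(topo, blink[tr, ])
  ep <- make_epochs(dat)
  out <- remove_artifact_components(ep, templates = list(blink),
                                    n_components = 10, seed = 2)
  expect_gt(length(out$report$removed_components), 0)
  cleaned <- out$epochs$data
  cors <- vapply(seq_len(nch), function(ch)
    abs(cor(as.vector(t(cleaned[, ch, ])), as.vector(t(blink)))), numeric(1))
  expect_lt(max(cors), 0.1)
})

test_that("homogeneous field correction annihilates uniform fields and is idempotent", {
  arr <- tiny_array(12, 3, seed = 8)
  N <- arr$orientations
  ns <- 200
  b <- sin(seq_len(ns) / 10)
  dat <- array(0, c(2, nrow(N), ns))
  for (tr in 1:2) dat[tr, , ] <- outer(as.numeric(N %*% c(1, 0, 0)), b)
  ep <- make_epochs(dat, array = arr)
  out <- homogeneous_field_correction(ep)
  expect_lt(max(abs(out$data)), 1e-15 * max(abs(dat)))

  set.seed(9)
  ep2 <- make_epochs(array(rnorm(2 * nrow(N) * ns), c(2, nrow(N), ns)),
                     array = arr)
  once <- homogeneous_field_correction(ep2)
  twice <- homogeneous_field_correction(once)
  expect_equal(twice$data, once$data, tolerance = 1e-12)

  P <- diag(nrow(N)) - N %*% solve(crossprod(N), t(N))
  ev <- eigen(P, symmetric = TRUE)$values
  expect_equal(sort(ev)[1:3], rep(0, 3), tolerance = 1e-12)
  expect_equal(sort(ev, decreasing = TRUE)[1:(nrow(N) - 3)],
               rep(1, nrow(N) - 3), tolerance = 1e-12)
})

test_that("HFC retains most dipolar source variance on a triaxial array", {
  arr <- build_sensor_array(64, 3, seed = 10)
  set.seed(10)
  src <- rnorm(500)
  rec <- dipole_recording(arr, src)
  ep <- make_epochs(array(rec$data, c(1, dim(rec$data))), array = arr)
  out <- homogeneous_field_correction(ep)
  v0 <- sum(ep$data^2); v1 <- sum(out$data^2)
  expect_gte(v1 / v0, 0.9)
})

test_that("trial matching equalizes group means deterministically", {
  mk <- function(n) make_epochs(array(rnorm(n * 2 * 50), c(n, 2, 50)))
  set.seed(11)
  eps <- list(mk(50), mk(50), mk(43), mk(43))
  grp <- c("A", "A", "B", "B")
  out <- match_trial_counts(eps, grp, seed = 3)
  gm <- out$group_means
  expect_lte(max(gm) - min(gm), 1)
  expect_equal(unname(gm["B"]), 43)
  out2 <- match_trial_counts(eps, grp, seed = 3)
  expect_identical(out$removals, out2$removals)

  expect_identical(nrow(match_trial_counts(list(mk(10), mk(10)),
                                           c("A", "B"))$removals), 0L)
  expect_error(match_trial_counts(eps, rep("A", 4)), "2 groups")
})
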