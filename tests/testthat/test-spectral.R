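test_that("the default ladder has 45 bands including every named band", {
  lad <- band_ladder()
  expect_equal(nrow(lad), 45)
  expect_equal(c(lad$low[1], lad$high[1]), c(1, 5))
  expect_equal(c(lad$low[45], lad$high[45]), c(89, 93))
  pairs <- paste(lad$low, lad$high)
  for (b in list(c(11, 15), c(29, 33), c(51, 55), c(5, 9), c(9, 13))) {
    expect_true(paste(b[1], b[2]) %in% pairs)
  }
  lad3 <- band_ladder(1, 9, 2, 4)
  expect_equal(nrow(lad3), 3)
  expect_equal(lad3$low, c(1, 3, 5))
  expect_error(band_ladder(1, 100, 4, 2), "bandwidth")
})

test_that("the Hilbert envelope of a matched sinusoid is one", {
  fs <- 600
  tt <- seq(1 / fs, 5, by = 1 / fs)
  x <- sin(2 * pi * 10 * tt)
  lad <- band_ladder(9, 14, 2, 4)[1, ]   # band (9, 13)
  tfs <- hilbert_tfs(matrix(x, 1), lad, fs, tmin = 0, baseline = c(1, 4))
  # relative change of a stationary signal is ~0 once the 4 Hz-wide
  # band-pass has settled (~0.25 s transition; stay 1 s clear of edges)
  inner_bp <- tfs$times > 1 & tfs$times < 4
  expect_lt(max(abs(tfs$values[1, inner_bp])), 0.02)
  # direct identity on the analytic signal away from edges
  env <- Mod(analytic_signal(x))
  inner <- seq_along(x)[tt > 0.5 & tt < 4.5]
  expect_equal(mean(env[inner]), 1, tolerance = 0.02)
  expect_true(all(abs(env[inner] - 1) < 0.02))
})

test_that("TFS rows are exactly baseline-centred and bounded below", {
  fs <- 600
  set.seed(1)
  series <- matrix(rnorm(4 * 3 * fs), 4)
  lad <- band_ladder(5, 30, 2, 4)
  tfs <- hilbert_tfs(series, lad, fs, tmin = -1)
  bidx <- tfs$times >= -0.8 & tfs$times < -0.1
  expect_equal(unname(rowMeans(tfs$values[, bidx])), rep(0, nrow(lad)),
               tolerance = 1e-12)
  expect_true(all(tfs$values >= -1))
})

test_that("collapse_tfs returns window means per band", {
  fs <- 100
  lad <- band_ladder(5, 20, 2, 4)
  tfs <- structure(list(values = matrix(0, nrow(lad), 300),
                        times = seq(-1, 2, length.out = 300),
                        ladder = lad, baseline = c(-0.8, -0.1), fs = fs),
                   class = "tfs")
  expect_equal(unname(collapse_tfs(tfs)), rep(0, nrow(lad)))
  tfs$values[3, ] <- 0.25
  expect_equal(unname(collapse_tfs(tfs)[3]), 0.25)
})

test_that("a 40 percent 60 Hz amplitude increase reads off the TFS at 0.40", {
  fs <- 1200
  tt <- seq(-1, 2 - 1 / fs, by = 1 / fs)
  set.seed(2)
  ntr <- 12
  series <- matrix(0, ntr, length(tt))
  ramp <- function(t, a, b) {           # 50 ms cosine ramps
    w <- numeric(length(t))
    w[t >= a & t < b] <- 1
    ru <- t >= a & t < a + 0.05
    w[ru] <- (1 - cos(pi * (t[ru] - a) / 0.05)) / 2
    rd <- t >= b - 0.05 & t < b
    w[rd] <- (1 + cos(pi * (t[rd] - (b - 0.05)) / 0.05)) / 2
    w
  }
  g <- ramp(tt, 0.25, 1.05)   # full 1.4x plateau across the 0.3-1 s window
  for (tr in seq_len(ntr)) {
    ph <- runif(1, 0, 2 * pi)
    series[tr, ] <- (1 + 0.4 * g) * sin(2 * pi * 60 * tt + ph) +
      rnorm(length(tt), 0, 0.02)
  }
  lad <- band_ladder()
  tfs <- hilbert_tfs(series, lad[lad$low == 59, ], fs, tmin = -1)
  val <- collapse_tfs(tfs, c(0.3, 1))
  expect_lt(abs(unname(val) - 0.40), 0.05)
})

test_that("relative PSD folds suppression through the absolute value", {
  fs <- 1200
  tt <- seq(-1, 2 - 1 / fs, by = 1 / fs)
  on <- tt >= 0.3 & tt < 1
  set.seed(3)
  ntr <- 16
  mk <- function(scale_on) {
    series <- matrix(0, ntr, length(tt))
    for (tr in seq_len(ntr)) {
      amp <- ifelse(on, scale_on, 1)
      series[tr, ] <- amp * sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi)) +
        rnorm(length(tt), 0, 0.02)
    }
    series
  }
  # alpha suppressed to 25 percent power (amplitude 0.5): |0.25 - 1| = 0.75
  sp <- relative_psd(mk(0.5), fs)
  at10 <- which.min(abs(sp$freqs - 10))
  expect_lt(abs(sp$values[at10] - 0.75), 0.05)
  # doubled power: (2 - 1) / 1 = 1
  sp2 <- relative_psd(mk(sqrt(2)), fs)
  expect_equal(sp2$values[at10], 1, tolerance = 0.1)
  # global rescaling invariance
  x <- mk(0.5)
  spa <- relative_psd(x, fs); spb <- relative_psd(x * 7.3, fs)
  expect_equal(spa$values, spb$values, tolerance = 1e-9)
})

test_that("stationary noise gives a near-zero relative PSD", {
  fs <- 600
  set.seed(4)
  series <- matrix(rnorm(200 * 3 * fs), 200)
  sp <- relative_psd(series, fs)
  expect_lt(median(sp$values), 0.15)
})

test_that("cohort normalization preserves ratios and is idempotent", {
  f <- seq(1, 100, by = 0.5)
  s1 <- rel_spectrum(f, rep(2 / 99, length(f)))   # area 2
  out1 <- normalize_cohort_spectra(list(s1))
  expect_equal(out1$scale_factor, 0.5, tolerance = 1e-9)
  expect_equal(trapz_area(f, out1$spectra[[1]]$values), 1, tolerance = 1e-9)

  s2 <- rel_spectrum(f, rep(1 / 99, length(f)))
  s3 <- rel_spectrum(f, rep(3 / 99, length(f)))
  out2 <- normalize_cohort_spectra(list(s2, s3))
  expect_equal(out2$scale_factor, 0.5, tolerance = 1e-9)
  a2 <- trapz_area(f, out2$spectra[[1]]$values)
  a3 <- trapz_area(f, out2$spectra[[2]]$values)
  expect_equal(c(a2, a3), c(0.5, 1.5), tolerance = 1e-9)
  # pairwise ratios preserved at every frequency
  expect_equal(out2$spectra[[2]]$values / out2$spectra[[1]]$values,
               s3$values / s2$values, tolerance = 1e-12)
  # idempotent after the first application
  out3 <- normalize_cohort_spectra(out2$spectra)
  expect_equal(out3$scale_factor, 1, tolerance = 1e-9)
})

test_that("the alpha Gaussian is recovered and removed within tolerance", {
  f <- seq(1, 100, by = 0.25)
  y <- exp(-(f - 10)^2 / (2 * 1.5^2)) + 0.05
  out <- fit_and_remove_alpha_gaussian(rel_spectrum(f, y))
  expect_equal(out$peak$centre, 10, tolerance = 0.1)
  expect_lt(out$spectrum$values[f == 10], 0.06)

  flat <- rel_spectrum(f, rep(0.2, length(f)))
  outf <- fit_and_remove_alpha_gaussian(flat)
  expect_equal(outf$spectrum$values, flat$values, tolerance = 0.01 * 0.2)

  y20 <- 0.05 + exp(-(f - 20)^2 / (2 * 1.5^2))
  out20 <- fit_and_remove_alpha_gaussian(rel_spectrum(f, y20))
  at20 <- which(f == 20)
  expect_equal(out20$spectrum$values[at20], y20[at20], tolerance = 0.1)
})

test_that("peak alpha frequency finds true bumps and ignores 1/f noise", {
  fs <- 600
  set.seed(5)
  ntr <- 20
  n <- fs  # 1 s of rest per trial
  tt <- seq_len(n) / fs
  series <- t(vapply(seq_len(ntr), function(tr)
    sin(2 * pi * 10 * tt + runif(1, 0, 2 * pi)) + rnorm(n, 0, 0.5),
    numeric(n)))
  out <- peak_alpha_frequency(series, fs)
  expect_true(out$found)
  expect_equal(out$paf, 10, tolerance = 0.25)

  # two bumps: the larger one wins
  series2 <- t(vapply(seq_len(ntr), function(tr)
    0.6 * sin(2 * pi * 8 * tt + runif(1, 0, 2 * pi)) +
    1.0 * sin(2 * pi * 12 * tt + runif(1, 0, 2 * pi)) + rnorm(n, 0, 0.3),
    numeric(n)))
  out2 <- peak_alpha_frequency(series2, fs)
  expect_equal(out2$paf, 12, tolerance = 0.3)

  # pure aperiodic noise: detection rate < 10 percent
  found <- 0L
  for (rep_i in 1:40) {
    pink <- t(vapply(seq_len(10), function(tr) {
      x <- rnorm(n)
      as.numeric(stats::filter(x, 0.95, method = "recursive"))
    }, numeric(n)))
    if (peak_alpha_frequency(pink, fs)$found) found <- found + 1L
  }
  expect_lt(found / 40, 0.10)
})
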