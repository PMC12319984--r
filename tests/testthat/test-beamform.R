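test_that("sphere lead fields are silent at the centre and for radial moments", {
  arr <- tiny_array(16, 3, seed = 1)
  B0 <- sarvas_field(arr$positions, c(0, 0, 0), c(0, 1, 0))
  expect_lt(max(abs(B0)), 1e-25)
  rd <- c(0.01, -0.05, 0.02)
  Br <- sarvas_field(arr$positions, rd, unit(rd))
  expect_lt(max(abs(Br)), 1e-20)
  # linearity in the moment
  q <- c(0.3, 0.2, -0.5)
  B1 <- sarvas_field(arr$positions, rd, q)
  B2 <- sarvas_field(arr$positions, rd, 2 * q)
  expect_equal(B2, 2 * B1, tolerance = 1e-12)
})

test_that("lead-field grids reject voxels outside the sphere", {
  arr <- tiny_array(8, 3, seed = 2)
  g <- rbind(c(0, 0, 0), c(0, -0.095, 0))
  expect_error(compute_lead_field(g, arr), "inside")
  lf <- compute_lead_field(rbind(c(0, 0, 0), c(0, -0.05, 0.01)), arr)
  expect_equal(max(abs(lf$gains[[1]])), 0, tolerance = 1e-25)
})

test_that("band covariance recovers a rank-1 common signal", {
  arr <- tiny_array(8, 3, seed = 3)
  nch <- 24; fs <- 600
  set.seed(3)
  mix <- rnorm(nch)
  ns <- 1200
  dat <- array(0, c(8, nch, ns))
  for (tr in 1:8) {
    s <- sin(2 * pi * 40 * seq_len(ns) / fs + runif(1, 0, 2 * pi))
    dat[tr, , ] <- outer(mix, s) +
      matrix(rnorm(nch * ns, 0, 1e-3), nch, ns)
  }
  ep <- make_epochs(dat, fs = fs, tmin = -1, array = arr)
  C <- band_covariance(ep, c(30, 50), c(-0.5, 0.5))
  e1 <- eigen(C, symmetric = TRUE)$vectors[, 1]
  cs <- abs(sum(e1 * mix) / sqrt(sum(mix^2)))
  expect_gt(cs, 0.99)
  expect_error(band_covariance(ep, c(50, 30)), "empty")
  expect_warning(band_covariance(ep, c(2, 40), c(-0.5, 0.5)), "cycles")
})

test_that("Tikhonov loading adds 5 percent of the top eigenvalue", {
  expect_equal(tikhonov_regularize(diag(2)), 1.05 * diag(2))
  expect_equal(tikhonov_regularize(diag(c(4, 1))), diag(c(4.2, 1.2)))
  Z <- matrix(0, 3, 3)
  expect_equal(tikhonov_regularize(Z), Z)
  expect_error(tikhonov_regularize(matrix(1:4, 2)), "symmetric")
})

test_that("LCMV weights are unit gain and shrink with stronger loading", {
  arr <- tiny_array(16, 3, seed = 4)
  set.seed(4)
  src <- rnorm(2000)
  rec <- dipole_recording(arr, src * 1e-9)
  C <- tcrossprod(rec$data) / (ncol(rec$data) - 1)
  C <- C + diag(nrow(C)) * max(diag(C)) * 1e-4     # small diagonal loading
  sphere <- list(centre = c(0, 0, 0), radius = 0.09)
  grid <- make_grid(0.008, sphere,
                    box = rbind(c(-0.03, -0.08, -0.02), c(0.03, -0.03, 0.04)))
  lf <- compute_lead_field(grid, arr, sphere)
  w5 <- lcmv_scalar_weights(lf, tikhonov_regularize(C, 0.05))
  for (v in which(w5$ok)) {
    l <- lf$gains[[v]] %*% w5$orientations[v, ]
    expect_equal(as.numeric(w5$weights[v, ] %*% l), 1, tolerance = 1e-6)
  }
  w50 <- lcmv_scalar_weights(lf, tikhonov_regularize(C, 0.5))
  n5 <- sqrt(rowSums(w5$weights^2))
  n50 <- sqrt(rowSums(w50$weights^2))
  expect_true(all(n50 <= n5 * (1 + 1e-9)))
})

test_that("pseudo-T is bounded, zero at equal covariances, one at silent rest", {
  arr <- tiny_array(10, 3, seed = 5)
  set.seed(5)
  rec <- dipole_recording(arr, rnorm(1500) * 1e-9)
  C <- tcrossprod(rec$data) / 1499 + diag(30) * 1e-30
  sphere <- list(centre = c(0, 0, 0), radius = 0.09)
  grid <- make_grid(0.01, sphere,
                    box = rbind(c(-0.02, -0.08, -0.01), c(0.02, -0.04, 0.03)))
  lf <- compute_lead_field(grid, arr, sphere)
  wts <- lcmv_scalar_weights(lf, tikhonov_regularize(C))
  img0 <- pseudo_t_image(wts, C, C)
  expect_equal(max(abs(img0$values[wts$ok])), 0)
  img1 <- pseudo_t_image(wts, C, C * 0)
  expect_equal(unname(img1$values[wts$ok]), rep(1, sum(wts$ok)))
  img <- pseudo_t_image(wts, C, C * 3)
  expect_true(all(img$values[wts$ok] >= -1 & img$values[wts$ok] <= 1))
})

test_that("peak_voxel breaks exact ties by the lowest voxel index", {
  img <- structure(list(values = c(0.2, 0.9, 0.9, 0.1),
                        grid = matrix(seq_len(12) / 1000, 4, 3),
                        spacing = 0.004),
                   class = "pseudo_t_image")
  pk <- peak_voxel(img, "max")
  expect_identical(pk$index, 2L)
  pk2 <- peak_voxel(img, "min")
  expect_identical(pk2$index, 4L)
  img$values <- rep(NA_real_, 4)
  expect_error(peak_voxel(img, "max"), "finite")
})

test_that("virtual electrode reconstructs a noiseless source", {
  arr <- tiny_array(20, 3, seed = 6)
  set.seed(6)
  src <- bp_filter(rnorm(3000), c(5, 80), 600) * 1e-9
  dip <- c(0.004, -0.06, 0.012)
  rec <- dipole_recording(arr, src, dip = dip)
  C <- tcrossprod(rec$data) / (ncol(rec$data) - 1)
  sphere <- list(centre = c(0, 0, 0), radius = 0.09)
  lf <- compute_lead_field(matrix(dip, 1, 3), arr, sphere)
  wts <- lcmv_scalar_weights(lf, tikhonov_regularize(C))
  ep <- make_epochs(array(rec$data, c(1, dim(rec$data))), fs = 600,
                    array = arr)
  vt <- virtual_timecourse(wts, 1, ep)
  expect_gt(abs(cor(vt[1, ], src)), 0.99)
  ep0 <- ep; ep0$data[] <- 0
  expect_equal(max(abs(virtual_timecourse(wts, 1, ep0))), 0)
  # linearity
  ep2 <- ep; ep2$data <- ep$data * 2
  expect_equal(virtual_timecourse(wts, 1, ep2), 2 * vt, tolerance = 1e-12)
})

test_that("a seeded dipolar source is localized within one grid step", {
  arr <- tiny_array(24, 3, seed = 7)
  fs <- 600
  set.seed(7)
  n <- 6000
  gate <- rep(rep(c(0, 1), each = fs), length.out = n)
  src <- (bp_filter(rnorm(n), c(40, 60), fs) * gate +
          bp_filter(rnorm(n), c(1, 100), fs) * 0.2) * 1e-9
  dip <- c(0.006, -0.058, 0.014)
  rec <- dipole_recording(arr, src, dip = dip)
  # without sensor noise the covariances are rank-1 along one spatial
  # vector and the pseudo-T is constant; add noise at ~10 dB below signal
  sig_rms <- sqrt(mean(rec$data^2))
  rec$data <- rec$data + matrix(rnorm(length(rec$data), 0, sig_rms / 3),
                                nrow(rec$data))
  sphere <- list(centre = c(0, 0, 0), radius = 0.09)
  grid <- make_grid(0.004, sphere,
                    box = rbind(c(-0.02, -0.08, -0.02), c(0.03, -0.03, 0.04)))
  lf <- compute_lead_field(grid, arr, sphere)
  C <- tcrossprod(rec$data) / (n - 1)
  wts <- lcmv_scalar_weights(lf, tikhonov_regularize(C))
  idx_on <- gate > 0.5; idx_off <- !idx_on
  Con <- tcrossprod(rec$data[, idx_on]) / (sum(idx_on) - 1)
  Coff <- tcrossprod(rec$data[, idx_off]) / (sum(idx_off) - 1)
  img <- pseudo_t_image(wts, Con, Coff)
  pk <- peak_voxel(img, "max")
  expect_lte(sqrt(sum((pk$coord - dip)^2)), 0.004 + 1e-9)
})
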