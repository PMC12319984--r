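# Small shared helpers.

# Run code with a temporary RNG state so generators are deterministic per
# seed without disturbing the caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

trapz_area <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

unit <- function(v) v / sqrt(sum(v^2))

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# squared-magnitude response of a digital IIR filter on the length-n FFT
# grid; applying it in the frequency domain is the zero-phase
# (forward-backward) use of the filter
filt_mag2 <- function(flt, n) {
  z <- exp(-1i * 2 * pi * seq(0, n - 1) / n)
  B <- Reduce(`+`, lapply(seq_along(flt$b),
                          function(k) flt$b[k] * z^(k - 1)))
  A <- Reduce(`+`, lapply(seq_along(flt$a),
                          function(k) flt$a[k] * z^(k - 1)))
  Mod(B / A)^2
}

# zero-phase filtering of the rows of X by the product of the squared
# magnitude responses of `filts`, with reflection padding against edge
# transients. `analytic = TRUE` returns the band-limited analytic signal
# (complex), whose modulus is the Hilbert envelope.
zp_filter_rows <- function(X, filts, pad = NULL, analytic = FALSE) {
  vec <- is.vector(X)
  if (vec) X <- matrix(X, 1)
  ns <- ncol(X)
  if (is.null(pad)) pad <- min(ns - 1, 256)
  # pad to a 2-3-5-smooth length so the FFT stays fast
  n <- stats::nextn(ns + 2 * pad, c(2, 3, 5))
  pre <- (n - ns) %/% 2
  post <- n - ns - pre
  pre <- min(pre, ns - 1); post <- min(post, ns - 1)
  Xp <- cbind(X[, pre:1, drop = FALSE], X,
              X[, ns:(ns - post + 1), drop = FALSE])
  if (ncol(Xp) < n) {
    Xp <- cbind(Xp, matrix(0, nrow(Xp), n - ncol(Xp)))
  }
  n <- ncol(Xp)
  m2 <- Reduce(`*`, lapply(filts, filt_mag2, n = n))
  if (analytic) {
    h <- numeric(n)
    if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2 }
    else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
    m2 <- m2 * h
  }
  Y <- matrix(0i, nrow(Xp), n)
  for (r in seq_len(nrow(Xp))) {
    Y[r, ] <- stats::fft(stats::fft(Xp[r, ]) * m2, inverse = TRUE) / n
  }
  out <- Y[, (pre + 1):(pre + ns), drop = FALSE]
  if (!analytic) out <- Re(out)
  if (vec) out <- drop(out)
  out
}

# Zero-phase 4th-order Butterworth band-pass of a vector
bp_filter <- function(x, band, fs, order = 4) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  zp_filter_rows(x, list(bf))
}

# Analytic signal via the frequency-domain construction; magnitude is the
# instantaneous (Hilbert) envelope.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
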