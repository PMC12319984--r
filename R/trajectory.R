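# Cohort-level statistics: Spearman correlations against age with
# Bonferroni control over the two reporting families (44 frequency bands;
# 10 microcircuit parameters).

#' Age-group bins used for reporting
#'
#' Six bins: 2-4, 5-8, 9-13, 21-24, 25-28 and 29-34 years (inclusive).
#' Correlations always use continuous age; the bins are for descriptive
#' summaries only.
#'
#' @param age_years numeric ages.
#' @return factor of bin labels (NA outside all bins).
#' @export
age_group_bins <- function(age_years) {
  lo <- c(2, 5, 9, 21, 25, 29)
  hi <- c(4, 8, 13, 24, 28, 34)
  lab <- sprintf("%d-%d", lo, hi)
  out <- rep(NA_character_, length(age_years))
  for (k in seq_along(lo)) {
    out[age_years >= lo[k] & age_years <= hi[k] + 1 - 1e-9] <- lab[k]
  }
  factor(out, levels = lab)
}

#' Tie-corrected Spearman correlation with a t-approximation p-value
#'
#' Rank correlation of `x` and `y`; the two-sided p-value uses the
#' t-distribution with n - 2 degrees of freedom. For n <= 12 an exact
#' permutation p-value can be requested instead.
#'
#' @param x,y numeric vectors (n >= 5).
#' @param exact use the exact permutation distribution (n <= 12 only).
#' @return List with `rho`, `p`, `n`.
#' @export
spearman <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 5) stop("Spearman correlation needs n >= 5")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: rank correlation undefined")
  }
  rho <- stats::cor(rank(x), rank(y))
  if (exact) {
    if (n > 12) stop("exact permutation p only for n <= 12")
    perms <- permutations_of(n)
    ry <- rank(y)
    rx <- rank(x)
    stat <- abs(rho)
    cnt <- 0L
    for (i in seq_len(nrow(perms))) {
      if (abs(stats::cor(rx, ry[perms[i, ]])) >= stat - 1e-12) cnt <- cnt + 1L
    }
    p <- cnt / nrow(perms)
  } else {
    if (abs(rho) >= 1) {
      p <- 2 * stats::pt(-Inf, n - 2)   # 0: monotone relation
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), n - 2)
    }
    p <- max(p, .Machine$double.xmin)
  }
  list(rho = rho, p = p, n = n)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m`. The reporting helper rounds to two significant figures
#' (0.05/44 is reported as 0.0011; 0.05/10 as 0.005).
#'
#' @param alpha family-wise error level.
#' @param m number of comparisons.
#' @return The corrected threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1) {
  if (m < 1 || alpha <= 0 || alpha >= 1) stop("invalid alpha or m")
  alpha / m
}

#' @rdname bonferroni_threshold
#' @export
bonferroni_threshold_reported <- function(alpha = 0.05, m = 1) {
  signif(bonferroni_threshold(alpha, m), 2)
}

correlation_result <- function(measure, rho, p, n, m, alpha = 0.05) {
  thr <- bonferroni_threshold(alpha, m)
  data.frame(measure = measure, rho = rho, p = p, n = n, m = m,
             threshold = thr, significant = !is.na(p) & p < thr,
             stringsAsFactors = FALSE)
}

#' Band-wise correlation of stimulus-induced amplitude change with age
#'
#' Spearman correlation of the collapsed per-band relative change against
#' age, for the 44-band family (the ladder minus its lowest band, whose
#' lower edge sits on the 1 Hz high-pass cutoff), Bonferroni-corrected at
#' m = 44.
#'
#' @param band_change subjects x bands matrix of collapsed relative change
#'   (columns named by band centre).
#' @param ages numeric ages (years).
#' @param drop_lowest exclude the lowest band from the corrected family.
#' @param alpha family-wise error level.
#' @return data.frame of `correlation_result` rows (one per band, ordered
#'   by centre) with attribute `significant_range` (Hz range covered by
#'   contiguous significant bands, or NULL).
#' @export
spectrum_age_correlation <- function(band_change, ages, drop_lowest = TRUE,
                                     alpha = 0.05) {
  if (nrow(band_change) != length(ages)) stop("subject count mismatch")
  if (any(!is.finite(band_change))) {
    bad <- which(rowSums(!is.finite(band_change)) > 0)[1]
    stop("missing band values for subject ", bad)
  }
  cols <- seq_len(ncol(band_change))
  if (drop_lowest) cols <- cols[-1]
  m <- length(cols)
  res <- do.call(rbind, lapply(cols, function(j) {
    s <- spearman(ages, band_change[, j])
    correlation_result(colnames(band_change)[j], s$rho, s$p, s$n, m, alpha)
  }))
  sig <- which(res$significant)
  rng <- NULL
  if (length(sig)) {
    centres <- as.numeric(res$measure)
    runs <- split(sig, cumsum(c(1, diff(sig) != 1)))
    main <- runs[[which.max(lengths(runs))]]
    rng <- c(centres[min(main)] - 2, centres[max(main)] + 2)
  }
  attr(res, "significant_range") <- rng
  res
}

#' Correlation of fitted microcircuit parameters with age
#'
#' The corrected family has ten members: the nine free connection gains
#' (G2, G4, G5, G6, G7, G8, G9, G11, G12) plus the superficial E-I ratio
#' G12/G11, Bonferroni-corrected at m = 10 (threshold 0.005). The deep
#' ratio G6/G9 and the free energy F are reported uncorrected as
#' exploratory diagnostics.
#'
#' @param fits list of `cmc_fit` objects.
#' @param ages numeric ages (years).
#' @param alpha family-wise error level.
#' @return data.frame of `correlation_result` rows; exploratory rows carry
#'   `m = 1` and `exploratory = TRUE`.
#' @export
parameter_age_correlation <- function(fits, ages, alpha = 0.05) {
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (sum(conv) < 5) stop("need at least 5 converged fits")
  fits <- fits[conv]; ages <- ages[conv]
  gfree <- c("G2", "G4", "G5", "G6", "G7", "G8", "G9", "G11", "G12")
  vals <- vapply(fits, function(f) {
    ei <- ei_ratios(f)
    c(f$params$G[gfree], superficial_EI = ei$superficial,
      deep_EI = ei$deep, F = f$F)
  }, numeric(12))
  family <- c(gfree, "superficial_EI")
  m <- length(family)
  # a degenerate (constant) estimate carries no rank information; report it
  # as NA rather than aborting the whole family
  safe_sp <- function(x) {
    tryCatch(spearman(ages, x),
             error = function(e) list(rho = NA_real_, p = NA_real_,
                                      n = length(x)))
  }
  res <- do.call(rbind, lapply(family, function(nm) {
    s <- safe_sp(vals[nm, ])
    correlation_result(nm, s$rho, s$p, s$n, m, alpha)
  }))
  extra <- do.call(rbind, lapply(c("deep_EI", "F"), function(nm) {
    s <- safe_sp(vals[nm, ])
    correlation_result(nm, s$rho, s$p, s$n, 1, alpha)
  }))
  res$exploratory <- FALSE
  extra$exploratory <- TRUE
  rbind(res, extra)
}

#' Age trend of pseudo-T peak coordinates
#'
#' Uncorrected Spearman correlation of each peak coordinate axis with age,
#' plus per-group mean and SD summaries.
#'
#' @param coords subjects x 3 matrix of peak coordinates (m or mm).
#' @param ages numeric ages (years).
#' @return List with `results` (one row per axis) and `group_summary`.
#' @export
peak_location_age_trend <- function(coords, ages) {
  axes <- c("x", "y", "z")
  res <- do.call(rbind, lapply(1:3, function(k) {
    s <- spearman(ages, coords[, k])
    correlation_result(paste0("peak_", axes[k]), s$rho, s$p, s$n, 1)
  }))
  grp <- age_group_bins(ages)
  gs <- do.call(rbind, lapply(levels(grp), function(g) {
    idx <- which(grp == g)
    if (!length(idx)) return(NULL)
    data.frame(group = g, n = length(idx),
               mx = mean(coords[idx, 1]), my = mean(coords[idx, 2]),
               mz = mean(coords[idx, 3]),
               sx = stats::sd(coords[idx, 1]), sy = stats::sd(coords[idx, 2]),
               sz = stats::sd(coords[idx, 3]))
  }))
  list(results = res, group_summary = gs)
}

#' Alpha-band trend report
#'
#' Spearman-vs-age results for the collapsed modulation in the 5-9, 9-13
#' and 11-15 Hz bands (from the alpha-peak virtual electrode), flagged both
#' uncorrected and under the 44-band family threshold, plus the rest-window
#' peak-alpha-frequency trend (uncorrected).
#'
#' @param band_change subjects x bands matrix (columns named by centre).
#' @param ages numeric ages.
#' @param paf per-subject peak alpha frequency (Hz; NAs dropped pairwise).
#' @param alpha family-wise error level.
#' @return data.frame with columns of [spectrum_age_correlation()] plus
#'   `significant_uncorrected`.
#' @export
alpha_trend_report <- function(band_change, ages, paf = NULL, alpha = 0.05) {
  bands <- c("7", "11", "13")   # centres of (5,9), (9,13), (11,15)
  missing_b <- setdiff(bands, colnames(band_change))
  if (length(missing_b)) stop("band ladder lacks centres ",
                              paste(missing_b, collapse = ", "))
  rows <- lapply(bands, function(b) {
    s <- spearman(ages, band_change[, b])
    r <- correlation_result(paste0("band_", b, "Hz"), s$rho, s$p, s$n, 44,
                            alpha)
    r$significant_uncorrected <- r$p < alpha
    r
  })
  if (!is.null(paf)) {
    ok <- is.finite(paf)
    if (sum(ok) >= 5) {
      s <- spearman(ages[ok], paf[ok])
      r <- correlation_result("peak_alpha_frequency", s$rho, s$p, s$n, 1,
                              alpha)
      r$significant_uncorrected <- r$p < alpha
      rows <- c(rows, list(r))
    }
  }
  do.call(rbind, rows)
}
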