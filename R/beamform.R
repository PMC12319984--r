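# LCMV beamformer with analytic current-dipole-in-conducting-sphere lead
# fields (Sarvas). All geometry is handled internally in metres, head frame:
# x right, y anterior, z superior, sphere centre at the origin by default.

MU0_OVER_4PI <- 1e-7

#' Magnetic field of a current dipole in a conducting sphere
#'
#' Analytic (Sarvas) solution for the field outside a homogeneous conducting
#' sphere. The field of a radially oriented dipole vanishes everywhere
#' outside the sphere, and a dipole at the centre is silent.
#'
#' @param r_sens channels x 3 matrix of sensor positions (m), relative to
#'   the head frame origin.
#' @param r_dip length-3 dipole position (m).
#' @param q length-3 dipole moment (A m).
#' @param centre sphere centre (m).
#' @return channels x 3 matrix of the magnetic field vector (T) at each
#'   sensor position.
#' @export
sarvas_field <- function(r_sens, r_dip, q, centre = c(0, 0, 0)) {
  r <- sweep(r_sens, 2, centre)          # sensor positions wrt centre
  r0 <- as.numeric(r_dip - centre)
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  a <- sweep(r, 2, r0)                   # r - r0
  an <- sqrt(rowSums(a^2))
  rn <- sqrt(rowSums(r^2))
  ar <- rowSums(a * r)
  # F = a (r a + r^2 - r0 . r); with r0 = r - a, r0 . r = r^2 - a . r
  FF <- an * (rn * an + ar)
  c1 <- an^2 / rn + ar / an + 2 * an + 2 * rn
  c2 <- an + 2 * rn + ar / an
  gradF <- r * c1 - matrix(r0, nrow(r), 3, byrow = TRUE) * c2
  qxr0_dot_r <- as.numeric(r %*% qxr0)
  B <- (matrix(qxr0, nrow(r), 3, byrow = TRUE) * FF - gradF * qxr0_dot_r) *
    (MU0_OVER_4PI / FF^2)
  B[!is.finite(B)] <- 0
  B
}

#' Regular voxel grid inside a sphere or box
#'
#' @param spacing isotropic voxel spacing (m).
#' @param sphere list with `centre` (m) and `radius` (m); voxels are kept
#'   strictly inside `radius * inner_frac`.
#' @param box optional 2 x 3 matrix (rows = lower, upper corners, m)
#'   restricting the grid, e.g. an occipital region of interest.
#' @param inner_frac fraction of the sphere radius retained (keeps voxels
#'   away from the surface where the scalar lead field degenerates).
#' @return voxels x 3 matrix of coordinates (m) with attribute `spacing`.
#' @export
make_grid <- function(spacing, sphere, box = NULL, inner_frac = 0.9) {
  r <- sphere$radius * inner_frac
  ctr <- sphere$centre
  ax <- lapply(1:3, function(k) {
    lo <- ctr[k] - r; hi <- ctr[k] + r
    if (!is.null(box)) { lo <- max(lo, box[1, k]); hi <- min(hi, box[2, k]) }
    if (lo > hi) return(numeric(0))
    seq(ceiling(lo / spacing) * spacing, hi, by = spacing)
  })
  g <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  d2 <- rowSums(sweep(g, 2, ctr)^2)
  g <- g[d2 < r^2, , drop = FALSE]
  attr(g, "spacing") <- spacing
  g
}

#' Lead field of a sensor array over a voxel grid
#'
#' For each voxel, the Sarvas field of unit dipoles along the three
#' Cartesian axes is projected onto each channel's orientation, giving a
#' channels x 3 gain matrix (T per A m).
#'
#' @param grid voxels x 3 matrix (m), all strictly inside the sphere.
#' @param array A `sensor_array` (see [build_sensor_array()]).
#' @param sphere list with `centre` and `radius` (m).
#' @return Object of class `lead_field`: list with `grid`, `gains` (list of
#'   channels x 3 matrices), `sphere`.
#' @export
compute_lead_field <- function(grid, array, sphere = list(centre = c(0, 0, 0),
                                                          radius = 0.09)) {
  grid <- as.matrix(grid)
  d <- sqrt(rowSums(sweep(grid, 2, sphere$centre)^2))
  if (any(d >= sphere$radius)) {
    stop("all grid voxels must lie strictly inside the conductor sphere")
  }
  pos <- array$positions
  ori <- array$orientations
  gains <- vector("list", nrow(grid))
  # geometry factors are shared by the three Cartesian unit moments
  r <- sweep(pos, 2, sphere$centre)
  rn <- sqrt(rowSums(r^2))
  for (v in seq_len(nrow(grid))) {
    r0 <- grid[v, ] - sphere$centre
    a <- sweep(r, 2, r0)
    an <- sqrt(rowSums(a^2))
    ar <- rowSums(a * r)
    FF <- an * (rn * an + ar)
    c1 <- an^2 / rn + ar / an + 2 * an + 2 * rn
    c2 <- an + 2 * rn + ar / an
    gradF <- r * c1 - matrix(r0, nrow(r), 3, byrow = TRUE) * c2
    L <- matrix(0, nrow(pos), 3)
    I3 <- diag(3)
    for (ax in 1:3) {
      qxr0 <- cross3(I3[ax, ], r0)
      qdr <- as.numeric(r %*% qxr0)
      B <- (matrix(qxr0, nrow(r), 3, byrow = TRUE) * FF - gradF * qdr) *
        (MU0_OVER_4PI / FF^2)
      B[!is.finite(B)] <- 0
      L[, ax] <- rowSums(B * ori)
    }
    gains[[v]] <- L
  }
  structure(list(grid = grid, spacing = attr(grid, "spacing"),
                 gains = gains, sphere = sphere),
            class = "lead_field")
}

#' Band-limited covariance matrix from epoched data
#'
#' Zero-phase band-pass filters every trial, then forms the sample
#' covariance over the concatenated window samples of all trials, with the
#' channel mean removed per trial.
#'
#' @param ep An `epochs` object.
#' @param band length-2 Hz pair (low, high); `NULL` skips filtering (the
#'   broadband case, for data already band-limited 1-150 Hz).
#' @param window length-2 window (s) relative to stimulus onset.
#' @return channels x channels covariance matrix (T^2).
#' @export
band_covariance <- function(ep, band = NULL, window = c(ep$tmin, ep$tmax)) {
  if (!is.null(band) && band[1] >= band[2]) stop("empty frequency band")
  if (window[1] < ep$tmin - 1e-9 || window[2] > ep$tmax + 1e-9) {
    stop("window outside the epoch")
  }
  if (!is.null(band)) {
    ncyc <- (window[2] - window[1]) * band[1]
    if (ncyc < 3) {
      warning(sprintf("window holds %.1f cycles of %g Hz (< 3)",
                      ncyc, band[1]))
    }
  }
  fs <- ep$fs
  nsamp <- dim(ep$data)[3]
  idx <- which(seq_len(nsamp) - 1 >= round((window[1] - ep$tmin) * fs) &
               seq_len(nsamp) - 1 < round((window[2] - ep$tmin) * fs))
  nch <- dim(ep$data)[2]
  C <- matrix(0, nch, nch)
  nacc <- 0L
  bf <- if (!is.null(band)) {
    signal::butter(4, band / (fs / 2), type = "pass")
  } else NULL
  for (tr in seq_len(dim(ep$data)[1])) {
    X <- ep$data[tr, , , drop = TRUE]        # channels x samples
    if (!is.null(bf)) X <- zp_filter_rows(X, list(bf))
    X <- X[, idx, drop = FALSE]
    X <- X - rowMeans(X)
    C <- C + tcrossprod(X)
    nacc <- nacc + length(idx)
  }
  C / (nacc - 1L)
}

#' Tikhonov (diagonal-loading) regularization
#'
#' Adds 5 percent (by default) of the largest eigenvalue to the diagonal.
#'
#' @param C symmetric positive semi-definite matrix.
#' @param fraction loading fraction of the maximum eigenvalue.
#' @return Regularized matrix `C + fraction * lambda_max * I`.
#' @export
tikhonov_regularize <- function(C, fraction = 0.05) {
  if (!isSymmetric(unname(C), tol = 1e-8)) stop("covariance must be symmetric")
  lmax <- max(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  C + fraction * lmax * diag(nrow(C))
}

#' Scalar LCMV beamformer weights
#'
#' Per voxel, the source orientation maximising beamformer output power is
#' the generalized eigenvector of the 3x3 matrix `t(L) C^-1 L` with the
#' smallest non-degenerate eigenvalue. In a conducting sphere the radial
#' direction is magnetically silent, so the (numerically zero) eigenvalue
#' belonging to it is excluded before the minimum is taken; a voxel whose
#' gain matrix retains fewer than two usable directions is flagged and its
#' weights zeroed. The weight vector is the unit-gain minimum-variance
#' filter `w = (l' C^-1 l)^-1 l' C^-1` with `l = L eta`.
#'
#' @param lf A `lead_field`.
#' @param C_reg Regularized covariance (invertible).
#' @return Object of class `bf_weights`: `weights` (voxels x channels),
#'   `orientations` (voxels x 3), `ok` (logical per voxel), plus the grid.
#' @export
lcmv_scalar_weights <- function(lf, C_reg) {
  Cinv <- solve(C_reg)
  nv <- nrow(lf$grid)
  nch <- ncol(Cinv)
  W <- matrix(0, nv, nch)
  ORI <- matrix(0, nv, 3)
  ok <- logical(nv)
  for (v in seq_len(nv)) {
    L <- lf$gains[[v]]
    CL <- Cinv %*% L
    M <- crossprod(L, CL)
    eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
    usable <- eg$values > max(eg$values) * 1e-8
    if (sum(usable) < 2) next
    k <- max(which(usable))               # smallest non-degenerate eigenvalue
    eta <- eg$vectors[, k]
    nz <- which(abs(eta) > 1e-12)[1]
    if (sign(eta[nz]) < 0) eta <- -eta
    l <- as.numeric(L %*% eta)
    Cl <- as.numeric(Cinv %*% l)
    denom <- sum(l * Cl)
    if (!is.finite(denom) || denom <= 0) next
    W[v, ] <- Cl / denom
    ORI[v, ] <- eta
    ok[v] <- TRUE
  }
  structure(list(weights = W, orientations = ORI, ok = ok,
                 grid = lf$grid, spacing = lf$spacing),
            class = "bf_weights")
}

#' Pseudo-T contrast image
#'
#' Voxel-wise normalized power difference between stimulus (ON) and rest
#' (OFF) covariance windows: `(P_on - P_off) / (P_on + P_off)`, bounded in
#' [-1, 1], positive for a stimulus-induced power increase.
#'
#' @param wts A `bf_weights`.
#' @param C_on,C_off band-limited window covariances.
#' @param band,windows optional metadata stored with the image.
#' @return Object of class `pseudo_t_image` with `values` per voxel.
#' @export
pseudo_t_image <- function(wts, C_on, C_off, band = NULL, windows = NULL) {
  W <- wts$weights
  p_on <- rowSums((W %*% C_on) * W)
  p_off <- rowSums((W %*% C_off) * W)
  neg <- (p_on < 0) | (p_off < 0)
  if (any(neg)) {
    warning("negative projected power at ", sum(neg), " voxel(s); clipped to 0")
    p_on[p_on < 0] <- 0
    p_off[p_off < 0] <- 0
  }
  denom <- p_on + p_off
  val <- ifelse(denom > 0, (p_on - p_off) / denom, 0)
  val[!wts$ok] <- NA_real_
  structure(list(values = val, grid = wts$grid, spacing = wts$spacing,
                 band = band, windows = windows),
            class = "pseudo_t_image")
}

#' Peak voxel of a pseudo-T image
#'
#' @param img A `pseudo_t_image`.
#' @param sign `"max"` for the strongest increase, `"min"` for the strongest
#'   suppression.
#' @param roi optional 2 x 3 matrix (lower, upper corners, m) restricting
#'   the search.
#' @return Named list with `coord` (m), `value` and `index` (row of the
#'   grid). Ties are broken by the lowest voxel index.
#' @export
peak_voxel <- function(img, sign = c("max", "min"), roi = NULL) {
  sign <- match.arg(sign)
  v <- img$values
  keep <- rep(TRUE, length(v))
  if (!is.null(roi)) {
    g <- img$grid
    keep <- g[, 1] >= roi[1, 1] & g[, 1] <= roi[2, 1] &
            g[, 2] >= roi[1, 2] & g[, 2] <= roi[2, 2] &
            g[, 3] >= roi[1, 3] & g[, 3] <= roi[2, 3]
  }
  idx <- which(keep & !is.na(v))
  if (!length(idx)) stop("no finite voxels in the region of interest")
  vv <- if (sign == "max") v[idx] else -v[idx]
  best <- idx[which.max(vv)]     # which.max returns the first maximum
  list(coord = img$grid[best, ], value = v[best], index = best)
}

#' Virtual-electrode time course at a voxel
#'
#' Applies the voxel's unit-gain spatial filter to the broadband epoch data,
#' giving a trials x samples source time series in dipole-moment units.
#'
#' @param wts A `bf_weights`.
#' @param voxel voxel index into the grid.
#' @param ep An `epochs` object (broadband data).
#' @return trials x samples matrix (A m).
#' @export
virtual_timecourse <- function(wts, voxel, ep) {
  if (!wts$ok[voxel]) stop("voxel ", voxel, " has no valid weights")
  w <- wts$weights[voxel, ]
  ntr <- dim(ep$data)[1]
  out <- matrix(0, ntr, dim(ep$data)[3])
  for (tr in seq_len(ntr)) {
    out[tr, ] <- as.numeric(w %*% ep$data[tr, , , drop = TRUE])
  }
  out
}
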