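# Non-uniform Fourier encoding.
#
# Gridding implementation: 2x-oversampled FFT with Kaiser-Bessel
# interpolation, expressed as  s = W F Z D x  where D is the (real)
# deapodization, Z zero-padding, F the unnormalized 2D DFT and W a real
# sparse interpolation matrix. The adjoint D' Z' F^H W' is therefore the
# exact numerical adjoint of the forward map, not an approximation.
# Normalized k units: cycles per resolution element, in [-0.5, 0.5).

kb_beta <- function(width, sigma = 2) {
  pi * sqrt((width / sigma)^2 * (sigma - 0.5)^2 - 0.8)
}

# continuous Fourier transform of the KB interpolation kernel
kb_ft <- function(nu, width, beta) {
  arg2 <- beta^2 - (pi * width * nu)^2
  out <- numeric(length(arg2))
  pos <- arg2 > 0
  out[pos] <- sinh(sqrt(arg2[pos])) / sqrt(arg2[pos])
  out[!pos] <- sinc_safe(sqrt(-arg2[!pos]))
  width * out / besselI(beta, 0)
}

sinc_safe <- function(x) ifelse(abs(x) < 1e-8, 1, sin(x) / x)

fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 / 2 + 1):n1, 1:(n1 / 2)), c((n2 / 2 + 1):n2, 1:(n2 / 2))]
}
ifftshift2 <- fftshift2  # even sizes only, shift is its own inverse

#' Build a NUFFT plan for a trajectory on a given image grid
#'
#' @param traj `spiral_trajectory` (or list with a `coords` array).
#' @param n image grid size (pixels, square, even).
#' @param oversamp grid oversampling factor. @param width kernel width
#'   (grid units of the oversampled grid).
#' @return object of class `nufft_plan`.
#' @export
nufft_plan <- function(traj, n, oversamp = 2, width = 8L) {
  kx <- as.vector(t(traj$coords[, , 1]))
  ky <- as.vector(t(traj$coords[, , 2]))   # sample-major within arm
  m <- length(kx)
  g <- as.integer(round(oversamp * n))
  g <- g + (4L - g %% 4L) %% 4L            # checkerboard trick needs g % 4 == 0
  beta <- kb_beta(width)
  half <- width / 2

  # interpolation weights: for each sample, width x width grid neighbours
  ux <- kx * g + g / 2 + 1   # fractional 1-based grid position
  uy <- ky * g + g / 2 + 1
  offs <- seq_len(width) - 1
  ix0 <- ceiling(ux - half)
  iy0 <- ceiling(uy - half)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  ixm <- outer(ix0, offs, `+`)            # m x width
  iym <- outer(iy0, offs, `+`)
  wxm <- matrix(0, m, width); wym <- matrix(0, m, width)
  for (j in seq_len(width)) {
    dx <- ux - ixm[, j]; dy <- uy - iym[, j]
    wxm[, j] <- ifelse(abs(dx) <= half,
                       besselI(beta * sqrt(pmax(1 - (dx / half)^2, 0)), 0), 0)
    wym[, j] <- ifelse(abs(dy) <= half,
                       besselI(beta * sqrt(pmax(1 - (dy / half)^2, 0)), 0), 0)
  }
  wxm <- wxm / besselI(beta, 0); wym <- wym / besselI(beta, 0)
  ixm <- (ixm - 1) %% g          # wrap, 0-based
  iym <- (iym - 1) %% g
  rows <- rep(seq_len(m), width * width)
  cols <- integer(m * width * width); vals <- numeric(m * width * width)
  at <- 0L
  for (jx in seq_len(width)) for (jy in seq_len(width)) {
    idx <- at + seq_len(m)
    cols[idx] <- iym[, jy] + 1L + g * ixm[, jx]   # row-index = y, col = x
    vals[idx] <- wxm[, jx] * wym[, jy]
    at <- at + m
  }
  W <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(m, g * g))

  xs <- (seq_len(n) - (n / 2 + 1)) / g
  dax <- kb_ft(xs, width, beta)
  deapod <- 1 / outer(dax, dax)            # n x n, real
  # fftshift/ifftshift of the even grid are realized as checkerboard
  # phase multiplications folded into the deapodization (image side)
  # and the sparse weights (frequency side); requires g % 4 == 0
  cb1 <- (-1)^(seq_len(g) - 1)
  cbg <- outer(cb1, cb1)
  i0 <- g / 2 - n / 2
  deapod_cb <- deapod * cbg[i0 + seq_len(n), i0 + seq_len(n)]
  cbvec <- as.vector(cbg)
  W@x <- W@x * cbvec[rep(seq_len(g * g), diff(W@p))]   # column scaling
  structure(list(W = W, Wt = Matrix::t(W), deapod = deapod,
                 deapod_cb = deapod_cb, n = n, g = g,
                 m = m, width = width, beta = beta,
                 kx = kx, ky = ky),
            class = "nufft_plan")
}

pad_center <- function(img, g) {
  n <- nrow(img)
  out <- matrix(0i, g, g)
  i0 <- g / 2 - n / 2
  out[i0 + seq_len(n), i0 + seq_len(n)] <- img
  out
}
crop_center <- function(big, n) {
  g <- nrow(big)
  i0 <- g / 2 - n / 2
  big[i0 + seq_len(n), i0 + seq_len(n)]
}

# forward: complex image (n x n) -> complex sample vector (m)
nufft_apply <- function(plan, img) {
  p <- pad_center(img * plan$deapod_cb, plan$g)
  fv <- as.vector(stats::fft(p))
  s2 <- plan$W %*% cbind(Re(fv), Im(fv))
  complex(real = s2[, 1], imaginary = s2[, 2])
}

# exact adjoint of nufft_apply; w = optional per-sample real weights
nufft_apply_adj <- function(plan, s, w = NULL) {
  if (!is.null(w)) s <- s * w
  g2 <- plan$Wt %*% cbind(Re(s), Im(s))
  f <- matrix(complex(real = g2[, 1], imaginary = g2[, 2]), plan$g, plan$g)
  p <- stats::fft(f, inverse = TRUE)
  crop_center(p, plan$n) * plan$deapod_cb
}

#' Multi-coil forward non-uniform Fourier encoding
#'
#' Evaluates per-coil k-space samples of a coil-weighted image on the
#' trajectory's sample locations.
#'
#' @param image complex (or real) `n x n` matrix.
#' @param coils a [coil_sensitivities] object (or `NULL` for one unit coil).
#' @param traj `spiral_trajectory`. @param plan optional precomputed
#'   [nufft_plan]. @param exact use the exact (slow) discrete transform.
#' @param arm_times optional per-arm time stamps (s).
#' @return a `kspace_bundle`: complex array `n_arms x n_samples x n_coils`
#'   plus `arm_times` and the trajectory.
#' @export
nufft_forward <- function(image, coils = NULL, traj, plan = NULL,
                          exact = FALSE, arm_times = NULL) {
  n <- nrow(image)
  if (is.null(coils)) coils <- unit_coil(n)
  if (!identical(dim(coils$maps)[1:2], dim(image)))
    stop("coil map grid does not match image grid")
  nc <- coils$n_coils
  na <- dim(traj$coords)[1]; ns <- dim(traj$coords)[2]
  if (!exact && is.null(plan)) plan <- nufft_plan(traj, n)
  samples <- array(0i, dim = c(na, ns, nc))
  for (c in seq_len(nc)) {
    wimg <- as.matrix(image) * coils$maps[, , c]
    sv <- if (exact) {
      ndft_fwd_cpp(wimg, as.vector(t(traj$coords[, , 1])),
                   as.vector(t(traj$coords[, , 2])))
    } else nufft_apply(plan, wimg)
    samples[, , c] <- matrix(sv, na, ns, byrow = TRUE)
  }
  if (is.null(arm_times)) arm_times <- (seq_len(na) - 1) * traj$dwell_s * ns
  structure(list(samples = samples, arm_times = arm_times, traj = traj),
            class = "kspace_bundle")
}

#' Adjoint (gridding) reconstruction with coil combination
#'
#' Density-compensated adjoint non-uniform Fourier transform of each
#' coil, combined by conjugate-sensitivity weighting normalized by the
#' sum of squared magnitudes.
#'
#' @param kspace `kspace_bundle`. @param coils [coil_sensitivities] or
#'   `NULL`. @param traj trajectory; defaults to the bundle's.
#' @param use_dcf apply density-compensation weights.
#' @param plan,exact as in [nufft_forward].
#' @return complex image matrix.
#' @export
nufft_adjoint <- function(kspace, coils = NULL, traj = NULL, use_dcf = TRUE,
                          plan = NULL, exact = FALSE, n = NULL) {
  if (is.null(traj)) traj <- kspace$traj
  dims <- dim(kspace$samples)
  if (!identical(dims[1:2], dim(traj$coords)[1:2]))
    stop("k-space sample shape does not match trajectory")
  if (is.null(n)) n <- if (!is.null(coils)) dim(coils$maps)[1] else
    round(traj$fov_mm / traj$res_mm)
  if (is.null(coils)) coils <- unit_coil(n)
  nc <- coils$n_coils
  if (dims[3] != nc) stop("coil count mismatch")
  w <- if (use_dcf) as.vector(t(density_compensation(traj))) else NULL
  if (!exact && is.null(plan)) plan <- nufft_plan(traj, n)
  num <- matrix(0i, n, n)
  for (c in seq_len(nc)) {
    sv <- as.vector(t(kspace$samples[, , c]))
    img <- if (exact) {
      ndft_adj_cpp(sv, as.vector(t(traj$coords[, , 1])),
                   as.vector(t(traj$coords[, , 2])), n,
                   if (is.null(w)) rep(1, length(sv)) else w)
    } else nufft_apply_adj(plan, sv, w)
    num <- num + Conj(coils$maps[, , c]) * img
  }
  rss2 <- apply(abs(coils$maps)^2, c(1, 2), sum)
  num / (rss2 + 1e-8)
}
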