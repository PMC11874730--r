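#' Design a variable-density center-out spiral trajectory
#'
#' Constructs an interleaved 2D spiral in normalized k-space units
#' (cycles per resolution element, so that the maximum radius is 0.5).
#' The azimuthal undersampling factor -- the number of identical
#' interleaves Nyquist-rate sampling would require divided by the number
#' actually played out -- follows a linear profile in \eqn{|k|} between
#' `center_under` and `edge_under`. The arm shape is obtained by
#' integrating \eqn{d\theta/dr = 2\pi N_{fov} / (n_{arms} R(r))} with
#' \eqn{N_{fov} = \mathrm{FOV}/\Delta x} and resampling the curve at
#' constant arc-length spacing.
#'
#' The per-arm sample count is derived from the sequence timing: readout
#' duration = `duty` x `tr_s`, dwell time = 1 / (pixel bandwidth x matrix
#' size). Pass `n_samples` to override.
#'
#' @param fov_mm reconstructed field of view (mm).
#' @param res_mm spatial resolution (mm); sets \eqn{k_{max}}.
#' @param n_arms number of interleaves per real-time frame.
#' @param center_under,edge_under target undersampling factors at the
#'   k-space center and edge.
#' @param n_samples readout points per arm; `NULL` derives it from timing.
#' @param tr_s repetition time (s). @param duty readout fraction of TR.
#' @param pixel_bw_hz receiver pixel bandwidth (Hz/pixel).
#' @param matrix_px reconstruction matrix size (pixels); default
#'   `round(fov_mm / res_mm)`.
#' @param rotation_offset global rotation of the whole pattern (radians).
#' @return an object of class `spiral_trajectory` with fields `coords`
#'   (array `n_arms x n_samples x 2`), `arm_offsets`, `n_arms`,
#'   `n_samples`, `dwell_s`, `fov_mm`, `res_mm`, `rotation_offset`.
#' @export
design_spiral <- function(fov_mm, res_mm, n_arms = 13L,
                          center_under = 5, edge_under = 15,
                          n_samples = NULL, tr_s = 3.7e-3, duty = 0.7,
                          pixel_bw_hz = 407, matrix_px = NULL,
                          rotation_offset = 0) {
  if (!is.numeric(fov_mm) || fov_mm <= 0 || !is.numeric(res_mm) || res_mm <= 0)
    stop("fov_mm and res_mm must be positive")
  if (n_arms < 1L) stop("n_arms must be >= 1")
  if (is.null(matrix_px)) matrix_px <- round(fov_mm / res_mm)
  n_fov <- fov_mm / res_mm          # Nyquist interleaf-count basis
  kmax <- 0.5

  if (is.null(n_samples)) {
    dwell <- 1 / (pixel_bw_hz * matrix_px)
    n_samples <- max(16L, as.integer(floor(duty * tr_s / dwell)) + 1L)
  } else {
    n_samples <- as.integer(n_samples)
    dwell <- duty * tr_s / max(1L, n_samples - 1L)
  }

  # dense radius grid; theta and arc length by trapezoidal integration
  rg <- seq(0, kmax, length.out = 8192L)
  und <- center_under + (edge_under - center_under) * rg / kmax
  dthdr <- 2 * pi * n_fov / (n_arms * und)
  theta_g <- pracma::cumtrapz(rg, dthdr)[, 1]
  speed <- sqrt(1 + (rg * dthdr)^2)
  s_g <- pracma::cumtrapz(rg, speed)[, 1]

  s_i <- seq(0, s_g[length(s_g)], length.out = n_samples)
  r_i <- stats::approx(s_g, rg, xout = s_i, ties = "ordered")$y
  th_i <- stats::approx(rg, theta_g, xout = r_i, ties = "ordered")$y
  r_i[1] <- 0; th_i[1] <- 0

  offs <- rotation_offset + 2 * pi * (seq_len(n_arms) - 1) / n_arms
  coords <- array(0, dim = c(n_arms, n_samples, 2L))
  for (a in seq_len(n_arms)) {
    ang <- th_i + offs[a]
    coords[a, , 1] <- r_i * cos(ang)
    coords[a, , 2] <- r_i * sin(ang)
  }
  structure(list(coords = coords, arm_offsets = offs, n_arms = n_arms,
                 n_samples = n_samples, dwell_s = dwell,
                 rotation_offset = rotation_offset,
                 fov_mm = fov_mm, res_mm = res_mm,
                 center_under = center_under, edge_under = edge_under,
                 n_fov = n_fov),
            class = "spiral_trajectory")
}

#' @export
print.spiral_trajectory <- function(x, ...) {
  cat(sprintf(
    "Spiral trajectory: %d arm(s) x %d samples, FOV %.0f mm, res %.2f mm\n",
    x$n_arms, x$n_samples, x$fov_mm, x$res_mm))
  cat(sprintf("  k_max %.4f (normalized), dwell %.2f us, rotation offset %.4f rad\n",
              max(sqrt(x$coords[, , 1]^2 + x$coords[, , 2]^2)),
              x$dwell_s * 1e6, x$rotation_offset))
  invisible(x)
}

#' Rotate a trajectory by a fixed angle
#' @param traj a `spiral_trajectory`. @param angle rotation (radians).
#' @return rotated `spiral_trajectory`.
#' @export
rotate_trajectory <- function(traj, angle) {
  co <- cos(angle); si <- sin(angle)
  kx <- traj$coords[, , 1, drop = FALSE]
  ky <- traj$coords[, , 2, drop = FALSE]
  out <- traj
  out$coords[, , 1] <- co * kx - si * ky
  out$coords[, , 2] <- si * kx + co * ky
  out$arm_offsets <- traj$arm_offsets + angle
  out$rotation_offset <- traj$rotation_offset + angle
  out
}

#' Concatenate the arms of several trajectories into one composite
#' @param trajs list of `spiral_trajectory` objects sharing geometry.
#' @return composite `spiral_trajectory` whose arms are stacked in order.
#' @export
combine_trajectories <- function(trajs) {
  stopifnot(length(trajs) >= 1)
  base <- trajs[[1]]
  coords <- do.call(abind3, lapply(trajs, function(t) t$coords))
  out <- base
  out$coords <- coords
  out$n_arms <- dim(coords)[1]
  out$arm_offsets <- unlist(lapply(trajs, function(t) t$arm_offsets))
  out
}

# rbind for (arms x samples x 2) arrays
abind3 <- function(...) {
  xs <- list(...)
  ns <- vapply(xs, function(x) dim(x)[1], 1L)
  out <- array(0, dim = c(sum(ns), dim(xs[[1]])[2], 2L))
  at <- 0L
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

#' Largest-gap rotation schedule for repeated spiral patterns
#'
#' The first pattern is unrotated. Each subsequent pattern is rotated so
#' that its arms bisect the largest angular gap in the union of all arm
#' angles played out so far; ties are broken by the gap with the smallest
#' starting angle.
#'
#' @param n_patterns number of pattern repetitions to schedule.
#' @param n_arms arms per pattern.
#' @return numeric vector of rotation offsets (radians), first element 0.
#' @export
rotation_schedule <- function(n_patterns, n_arms = 13L) {
  if (n_patterns < 1L) stop("n_patterns must be >= 1")
  offsets <- numeric(n_patterns)
  if (n_patterns == 1L) return(offsets)
  base <- 2 * pi * (seq_len(n_arms) - 1) / n_arms
  for (p in 2:n_patterns) {
    angles <- sort(unique(round(
      as.vector(outer(offsets[1:(p - 1)], base, `+`)) %% (2 * pi), 12)))
    gaps <- diff(c(angles, angles[1] + 2 * pi))
    big <- which(gaps > max(gaps) - 1e-9)
    pick <- big[which.min(angles[big])]   # tie-break: smallest start angle
    mid <- angles[pick] + gaps[pick] / 2
    offsets[p] <- mid %% (2 * pi / n_arms)
  }
  offsets
}

#' Construct a gradient system transfer function
#'
#' A GSTF models the gradient chain as a linear time-invariant system:
#' the spectrum of a nominal gradient waveform is multiplied by the
#' complex response to obtain the waveform actually played out. The
#' synthetic default combines a small group delay with a first-order
#' low-pass, a shape typical of measured gradient responses.
#'
#' @param freq_hz strictly increasing non-negative frequency axis.
#' @param response complex response at `freq_hz` (one axis), or a matrix
#'   with one column per gradient axis.
#' @return object of class `gstf`.
#' @export
gstf <- function(freq_hz, response) {
  if (any(diff(freq_hz) <= 0)) stop("frequency axis must be strictly increasing")
  response <- as.matrix(response)
  if (abs(freq_hz[1]) < 1e-12 && any(Mod(response[1, ]) > 1 + 1e-9))
    stop("GSTF magnitude at 0 Hz must not exceed 1")
  structure(list(freq_hz = freq_hz, response = response), class = "gstf")
}

#' @rdname gstf
#' @param delay_s group delay (s). @param fc_hz low-pass corner (Hz).
#' @param fmax_hz,n frequency axis extent and length.
#' @export
make_gstf <- function(delay_s = 2e-6, fc_hz = 50e3, fmax_hz = 500e3, n = 512L) {
  f <- seq(0, fmax_hz, length.out = n)
  h <- exp(-2i * pi * f * delay_s) / (1 + 1i * f / fc_hz)
  gstf(f, h)
}

#' Apply a gradient system transfer function to a waveform
#'
#' Frequency-domain multiplication of the (zero-padded) waveform spectrum
#' by the transfer response, with conjugate symmetry enforced so the
#' output is real.
#'
#' @param waveform numeric vector, or matrix with one column per axis.
#' @param g a [gstf] object. @param dt sample interval (s).
#' @return corrected waveform, same shape as the input.
#' @export
apply_gstf <- function(waveform, g, dt) {
  one_axis <- is.null(dim(waveform))
  wv <- as.matrix(waveform)
  n <- nrow(wv)
  npad <- 2^ceiling(log2(2 * n))
  f <- c(seq(0, npad / 2), seq(-npad / 2 + 1, -1)) / (npad * dt)
  fa <- abs(f[seq_len(npad)])
  if (max(fa) > max(g$freq_hz) + 1e-9)
    warning("waveform bandwidth exceeds GSTF frequency axis; response clamped at the last value")
  out <- wv
  for (ax in seq_len(ncol(wv))) {
    hcol <- g$response[, min(ax, ncol(g$response))]
    hre <- stats::approx(g$freq_hz, Re(hcol), xout = fa, rule = 2, ties = "ordered")$y
    him <- stats::approx(g$freq_hz, Im(hcol), xout = fa, rule = 2, ties = "ordered")$y
    h <- complex(real = hre, imaginary = him)
    h[f[seq_len(npad)] < 0] <- Conj(h[f[seq_len(npad)] < 0])
    spec <- stats::fft(c(wv[, ax], rep(0, npad - n)))
    out[, ax] <- Re(stats::fft(spec * h, inverse = TRUE) / npad)[seq_len(n)]
  }
  if (one_axis) drop(out) else out
}

#' Integrate gradient waveforms to a k-space trajectory
#'
#' \eqn{k(t) = \gamma \int_0^t G(t') dt'} by cumulative trapezoidal
#' integration, with \eqn{k(0) = 0}. With `gamma_hz_per_t` in Hz/T and
#' gradients in T/m, k is returned in cycles/m.
#'
#' @param waveform gradient waveform (vector or matrix, columns = axes).
#' @param dt sample interval (s).
#' @param gamma_hz_per_t gyromagnetic ratio (Hz/T); default proton.
#' @return trajectory with the same shape as `waveform`.
#' @export
gradients_to_kspace <- function(waveform, dt, gamma_hz_per_t = 42.577478518e6) {
  one_axis <- is.null(dim(waveform))
  wv <- as.matrix(waveform)
  if (any(!is.finite(wv))) stop("waveform must be finite")
  t <- dt * (seq_len(nrow(wv)) - 1)
  k <- apply(wv, 2, function(g) pracma::cumtrapz(t, g)[, 1]) * gamma_hz_per_t
  if (one_axis) drop(k) else k
}

#' Sampling-density compensation weights for a spiral trajectory
#'
#' Analytic area-element weights for interleaved center-out readouts:
#' parameterizing k-space by arc length along an arm and the rotation
#' angle between arms, the Jacobian gives the per-sample cell area
#' \eqn{w = |k| \, |dr/ds| \, \Delta s \, (2\pi / n_{arms})}. The center
#' sample receives the area of the disc of radius \eqn{\Delta s / 2}
#' shared between all arms. For purely radial readouts this reduces to
#' weights proportional to \eqn{|k|}.
#'
#' @param traj a `spiral_trajectory` (possibly composite).
#' @return matrix `n_arms x n_samples` of positive weights (k-space area
#'   units, normalized k in cycles/pixel).
#' @export
density_compensation <- function(traj) {
  kx <- traj$coords[, , 1, drop = FALSE]
  ky <- traj$coords[, , 2, drop = FALSE]
  na <- dim(kx)[1]; ns <- dim(kx)[2]
  w <- matrix(0, na, ns)
  for (a in seq_len(na)) {
    x <- kx[a, , 1]; y <- ky[a, , 1]
    r <- sqrt(x^2 + y^2)
    if (ns == 1L) { w[a, ] <- 1; next }
    ds <- sqrt(diff(x)^2 + diff(y)^2)
    dsm <- c(ds[1], (ds[-1] + ds[-length(ds)]) / 2, ds[length(ds)])
    drds <- c(diff(r)[1] / ds[1],
              (r[-(1:2)] - r[seq_len(ns - 2)]) / (ds[-1] + ds[-length(ds)]),
              diff(r)[ns - 1] / ds[ns - 1])
    w[a, ] <- pmax(r * abs(drds) * dsm * 2 * pi / na, 0)
    w[a, r < dsm / 2] <- pi * (dsm[r < dsm / 2] / 2)^2 / na
  }
  w[w <= 0] <- min(w[w > 0])
  w
}

#' Measure the azimuthal undersampling factor of a designed spiral
#'
#' Computed from the generated coordinates of arm 1 by finite
#' differences: the Nyquist-required interleaf count at radius `r` is
#' \eqn{2\pi N_{fov} \, dr/d\theta}, which is divided by the number of
#' arms actually present.
#'
#' @param traj a `spiral_trajectory`. @param r radii (normalized, in
#'   `[0, 0.5]`) at which to evaluate.
#' @return numeric vector of undersampling factors at `r`.
#' @export
undersampling_factor <- function(traj, r) {
  x <- traj$coords[1, , 1]; y <- traj$coords[1, , 2]
  rad <- sqrt(x^2 + y^2)
  th <- signal::unwrap(atan2(y, x))
  th <- th - th[2]                       # angle measured from the first ray
  i <- 2:length(rad)                     # r = 0 carries no angle
  dthdr_mid <- diff(th[i]) / diff(rad[i])
  r_mid <- (rad[i][-1] + rad[i][-length(i)]) / 2
  dthdr <- stats::approx(r_mid, dthdr_mid, xout = r, rule = 2,
                         ties = "ordered")$y
  2 * pi * traj$n_fov / (dthdr * traj$n_arms)
}
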