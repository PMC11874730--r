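# Coil sensitivities: simulation and adaptive estimation.

#' Coil sensitivity container
#' @param maps complex array `n x n x n_coils`.
#' @return object of class `coil_sensitivities`.
#' @export
coil_sensitivities <- function(maps) {
  if (length(dim(maps)) == 2L) maps <- array(maps, dim = c(dim(maps), 1L))
  if (any(!is.finite(Re(maps))) || any(!is.finite(Im(maps))))
    stop("coil maps must be finite")
  structure(list(maps = maps, n_coils = dim(maps)[3]),
            class = "coil_sensitivities")
}

unit_coil <- function(n) {
  coil_sensitivities(array(1 + 0i, dim = c(n, n, 1L)))
}

#' Simulate smooth random phased-array coil sensitivities
#'
#' Coils are modelled as complex Gaussian lobes centered outside the
#' field of view on a ring (mimicking surface coil elements), with
#' a smooth linear phase. Placement jitter, lobe width and phase vary
#' with the seed so that repeated simulations produce distinct arrays.
#'
#' @param n image grid size. @param n_coils number of elements.
#' @param seed integer seed (reproducible maps).
#' @param smoothness lobe width relative to the grid; `Inf` gives
#'   constant maps.
#' @return a [coil_sensitivities] object.
#' @export
simulate_coils <- function(n, n_coils = 8L, seed = 1L, smoothness = 0.8) {
  if (n_coils < 1L) stop("n_coils must be >= 1")
  rs <- local_rng(seed)
  xs <- (seq_len(n) - (n / 2 + 1)) / n
  X <- matrix(xs, n, n, byrow = TRUE)   # column -> x
  Y <- matrix(xs, n, n)                 # row    -> y
  maps <- array(0i, dim = c(n, n, n_coils))
  for (c in seq_len(n_coils)) {
    if (is.infinite(smoothness)) { maps[, , c] <- 1 + 0i; next }
    ang <- 2 * pi * (c - 1) / n_coils + rs$runif(1, -0.15, 0.15)
    rad <- 0.62 + rs$runif(1, -0.05, 0.05)
    cx <- rad * cos(ang); cy <- rad * sin(ang)
    w <- smoothness * (0.45 + rs$runif(1, -0.08, 0.08))
    mag <- exp(-((X - cx)^2 + (Y - cy)^2) / (2 * w^2))
    ph <- 2 * pi * (rs$runif(1, -0.3, 0.3) * X + rs$runif(1, -0.3, 0.3) * Y) +
      rs$runif(1, 0, 2 * pi)
    maps[, , c] <- mag * exp(1i * ph)
  }
  coil_sensitivities(maps)
}

#' Adaptive (Walsh-style) coil sensitivity estimation
#'
#' Per-pixel dominant eigenvector of the local coil covariance matrix,
#' computed from per-coil complex images (typically a temporal average of
#' gridding reconstructions). Maps are normalized to unit
#' root-sum-of-squares per pixel. Optionally the estimation runs on a
#' spatially subsampled grid and is bilinearly interpolated back, which
#' exploits the smoothness of receive fields.
#'
#' @param coil_images complex array `n x n x n_coils`.
#' @param block_size half-width of the local averaging block (pixels).
#' @param subsample_factor integer spatial subsampling (1 = none).
#' @return a [coil_sensitivities] object.
#' @export
estimate_coils_adaptive <- function(coil_images, block_size = 1L,
                                    subsample_factor = 1L) {
  d <- dim(coil_images)
  if (length(d) == 2L) coil_images <- array(coil_images, c(d, 1L))
  d <- dim(coil_images)
  n <- d[1]; nc <- d[3]
  if (all(abs(coil_images) == 0)) stop("all-zero coil images")
  sub <- as.integer(subsample_factor)
  grid <- if (sub > 1L) seq(1L, n, by = sub) else seq_len(n)
  ng <- length(grid)
  est <- array(0i, dim = c(ng, ng, nc))
  for (jj in seq_len(ng)) {
    j <- grid[jj]
    jr <- max(1, j - block_size):min(n, j + block_size)
    for (ii in seq_len(ng)) {
      i <- grid[ii]
      ir <- max(1, i - block_size):min(n, i + block_size)
      Y <- matrix(coil_images[ir, jr, ], ncol = nc)
      R <- crossprod(Conj(Y), Y)        # nc x nc local covariance
      v <- eigen(R, symmetric = TRUE)$vectors[, 1]
      v <- v * exp(-1i * Arg(v[1]))     # phase-reference first coil
      est[ii, jj, ] <- v
    }
  }
  if (sub > 1L) {
    full <- array(0i, dim = c(n, n, nc))
    for (c in seq_len(nc)) {
      full[, , c] <- bilinear_upsample(Re(est[, , c]), grid, n) +
        1i * bilinear_upsample(Im(est[, , c]), grid, n)
    }
    est <- full
  }
  rss <- sqrt(apply(abs(est)^2, c(1, 2), sum))
  for (c in seq_len(dim(est)[3])) est[, , c] <- est[, , c] / pmax(rss, 1e-12)
  coil_sensitivities(est)
}

bilinear_upsample <- function(m, grid, n) {
  # interpolate values at (grid x grid) onto the full 1..n lattice
  f1 <- apply(m, 2, function(col)
    stats::approx(grid, col, xout = seq_len(n), rule = 2, ties = "ordered")$y)
  t(apply(f1, 1, function(row)
    stats::approx(grid, row, xout = seq_len(n), rule = 2, ties = "ordered")$y))
}

#' CG-SENSE reconstruction of non-Cartesian multi-coil data
#'
#' Conjugate-gradient solution of the normal equations
#' \eqn{E^H E x = E^H y} of the coil-weighted non-uniform Fourier system
#' \eqn{E}. Runs a fixed number of iterations (no stopping tolerance) and
#' returns the final iterate as the interim image estimate.
#'
#' @param kspace `kspace_bundle`. @param traj trajectory (defaults to the
#'   bundle's). @param coils [coil_sensitivities]. @param n_iter number
#'   of CG iterations. @param plan,exact as in [nufft_forward].
#' @param track_residuals keep the normal-equation residual norms as an
#'   attribute `residuals`.
#' @return complex image matrix (attribute `residuals` when requested).
#' @export
cg_sense <- function(kspace, traj = NULL, coils = NULL, n_iter = 10L,
                     plan = NULL, exact = FALSE, track_residuals = FALSE) {
  if (n_iter < 1L) stop("n_iter must be >= 1")
  if (is.null(traj)) traj <- kspace$traj
  n <- if (!is.null(coils)) dim(coils$maps)[1] else
    round(traj$fov_mm / traj$res_mm)
  if (is.null(coils)) coils <- unit_coil(n)
  nc <- coils$n_coils
  if (!exact && is.null(plan)) plan <- nufft_plan(traj, n)
  kxv <- as.vector(t(traj$coords[, , 1]))
  kyv <- as.vector(t(traj$coords[, , 2]))
  ones <- rep(1, length(kxv))

  fwd1 <- function(img) {
    if (exact) lapply(seq_len(nc), function(c)
      ndft_fwd_cpp(img * coils$maps[, , c], kxv, kyv))
    else lapply(seq_len(nc), function(c)
      nufft_apply(plan, img * coils$maps[, , c]))
  }
  adj1 <- function(slist) {
    out <- matrix(0i, n, n)
    for (c in seq_len(nc)) {
      im <- if (exact) ndft_adj_cpp(slist[[c]], kxv, kyv, n, ones)
      else nufft_apply_adj(plan, slist[[c]])
      out <- out + Conj(coils$maps[, , c]) * im
    }
    out
  }
  AhA <- function(img) adj1(fwd1(img))

  y <- lapply(seq_len(nc), function(c) as.vector(t(kspace$samples[, , c])))
  b <- adj1(y)
  scal <- max(Mod(b))
  if (scal == 0) scal <- 1
  b <- b / scal                         # conditioning-friendly scaling
  x <- matrix(0i, n, n)
  r <- b
  p <- r
  rs <- sum(Mod(r)^2)
  resids <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    Ap <- AhA(p)
    alpha <- rs / Re(sum(Conj(p) * Ap))
    x <- x + alpha * p
    if (any(!is.finite(Re(x)))) stop(sprintf("CG-SENSE diverged at iteration %d", it))
    r <- r - alpha * Ap
    rs_new <- sum(Mod(r)^2)
    resids[it] <- sqrt(rs_new)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  out <- x * scal
  if (track_residuals) attr(out, "residuals") <- resids * scal
  out
}
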