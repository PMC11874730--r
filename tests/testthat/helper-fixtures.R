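# Shared fixtures, built once per test run.

fixture_env <- new.env()

# small desk trajectory: 13 arms on a 64-pixel field of view
desk_traj <- function(n_samples = 200) {
  key <- paste0("traj", n_samples)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- design_spiral(64 * 3, 3, n_arms = 13L,
                                        n_samples = n_samples)
  fixture_env[[key]]
}

desk_frame <- function(seed = 3L, phase = 0) {
  key <- paste0("frame", seed, "_", phase)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- phantom_frame(phantom_config(grid = 64, seed = seed),
                                        phase)
  fixture_env[[key]]
}

# a Cartesian full grid expressed as a trajectory (one arm per k point)
cartesian_traj <- function(n) {
  kk <- (seq_len(n) - (n / 2 + 1)) / n
  g <- expand.grid(ky = kk, kx = kk)
  structure(list(coords = array(c(g$kx, g$ky), dim = c(n * n, 1, 2)),
                 n_arms = n * n, n_samples = 1L, dwell_s = 1e-5,
                 fov_mm = n * 3, res_mm = 3,
                 arm_offsets = rep(0, n * n), rotation_offset = 0,
                 n_fov = n),
            class = "spiral_trajectory")
}

# plain-R brute-force non-uniform DFT (independent of the package path)
ndft_reference <- function(img, kx, ky) {
  n <- nrow(img)
  xs <- seq_len(n) - (n / 2 + 1)
  out <- complex(length(kx))
  for (s in seq_along(kx)) {
    ph <- outer(xs * ky[s], xs * kx[s], `+`)   # row -> y, col -> x
    out[s] <- sum(img * exp(-2i * pi * ph))
  }
  out
}

# brute-force largest-gap bisection oracle for the rotation schedule
schedule_oracle <- function(n_patterns, n_arms) {
  offsets <- 0
  base <- 2 * pi * (seq_len(n_arms) - 1) / n_arms
  while (length(offsets) < n_patterns) {
    ang <- sort(unique(round(as.vector(outer(offsets, base, `+`)) %% (2 * pi),
                             12)))
    gaps <- diff(c(ang, ang[1] + 2 * pi))
    big <- which(gaps > max(gaps) - 1e-9)
    pick <- big[which.min(ang[big])]
    offsets <- c(offsets, (ang[pick] + gaps[pick] / 2) %% (2 * pi / n_arms))
  }
  offsets
}

max_angular_gap <- function(angles) {
  a <- sort(angles %% (2 * pi))
  max(diff(c(a, a[1] + 2 * pi)))
}

# cached simulated sessions for the gating tests
desk_session <- function(mode = "breathhold", duration = 10, seed = 7,
                         arrhythmia = FALSE, n_coils = 6) {
  key <- paste(mode, duration, seed, arrhythmia, n_coils, sep = "_")
  if (is.null(fixture_env[[key]])) {
    cfg <- phantom_config(grid = 64, seed = seed)
    fixture_env[[key]] <- simulate_session(cfg, mode, duration,
                                           n_coils = n_coils,
                                           arrhythmia = arrhythmia)
  }
  fixture_env[[key]]
}

# numeric gradient of f at x[i]
num_grad <- function(f, x, i, h = 1e-6) {
  xp <- x; xp[i] <- xp[i] + h
  xm <- x; xm[i] <- xm[i] - h
  (f(xp) - f(xm)) / (2 * h)
}
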