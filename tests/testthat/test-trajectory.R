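# Spiral design, rotation scheduling, GSTF application, gradient
# integration and density compensation.

test_that("spiral reaches k_max = 0.5 and starts at the center", {
  tr <- design_spiral(592, 1.29, 13)
  r <- sqrt(tr$coords[, , 1]^2 + tr$coords[, , 2]^2)
  expect_equal(max(r), 0.5, tolerance = 1e-6)
  expect_true(all(r[, 1] < 1e-6))        # center-out, needed for self-gating
})

test_that("arms are rotated copies of arm 1", {
  tr <- design_spiral(592, 1.29, 13)
  a <- 2 * pi / 13
  rot <- cbind(cos(a) * tr$coords[1, , 1] - sin(a) * tr$coords[1, , 2],
               sin(a) * tr$coords[1, , 1] + cos(a) * tr$coords[1, , 2])
  expect_lt(max(abs(rot - tr$coords[2, , ])), 1e-9)
})

test_that("undersampling is ~5 at the center, ~15 at the edge, monotone", {
  tr <- design_spiral(592, 1.29, 13)
  expect_equal(round(undersampling_factor(tr, 0.01)), 5)
  expect_equal(round(undersampling_factor(tr, 0.5)), 15)
  prof <- undersampling_factor(tr, seq(0.02, 0.5, length.out = 40))
  expect_true(all(diff(prof) > -1e-6))
})

test_that("invalid geometry is rejected", {
  expect_error(design_spiral(-1, 1.29), "positive")
  expect_error(design_spiral(592, 0), "positive")
})

test_that("rotation schedule bisects the largest gap (brute-force oracle)", {
  expect_equal(rotation_schedule(1, 13), 0)
  expect_equal(rotation_schedule(3, 13), c(0, pi / 13, pi / 26),
               tolerance = 1e-12)
  s4 <- rotation_schedule(4, 13)
  expect_equal(s4[4], 3 * pi / 26, tolerance = 1e-12)
  # after 4 patterns all gaps are equal to pi/26
  ang <- as.vector(outer(s4, 2 * pi * (0:12) / 13, `+`)) %% (2 * pi)
  gaps <- diff(c(sort(ang), min(ang) + 2 * pi))
  expect_equal(max(gaps), pi / 26, tolerance = 1e-9)
  # general agreement with the independent oracle
  for (np in c(2, 5, 8)) {
    expect_equal(rotation_schedule(np, 13), schedule_oracle(np, 13),
                 tolerance = 1e-9)
    expect_equal(rotation_schedule(np, 7), schedule_oracle(np, 7),
                 tolerance = 1e-9)
  }
})

test_that("8 rotated patterns tile k-space with near-uniform arm angles", {
  offs <- rotation_schedule(8, 13)
  ang <- as.vector(outer(offs, 2 * pi * (0:12) / 13, `+`)) %% (2 * pi)
  expect_equal(length(unique(round(ang, 9))), 104)
  expect_lte(max_angular_gap(ang), 2 * (2 * pi / 104) + 1e-9)
})

test_that("GSTF application: identity, pure delay, low-pass, linearity", {
  dt <- 1e-5
  n <- 256
  tvec <- (seq_len(n) - 1) * dt
  wf <- exp(-((tvec - 1e-3) / 2e-4)^2)    # smooth bump
  f <- seq(0, 1 / dt, length.out = 4096)
  ident <- gstf(f, rep(1 + 0i, 4096))
  expect_lt(max(abs(apply_gstf(wf, ident, dt) - wf)), 1e-9)
  delay <- gstf(f, exp(-2i * pi * f * 2 * dt))
  out <- apply_gstf(wf, delay, dt)
  expect_lt(max(abs(out[-(1:2)] - wf[seq_len(n - 2)])), 1e-5)
  half <- gstf(f, rep(0.5 + 0i, 4096))
  expect_lt(max(abs(apply_gstf(wf, half, dt) - wf / 2)), 1e-9)
  # linearity
  wf2 <- sin(2 * pi * 300 * tvec)
  g <- make_gstf()
  lhs <- apply_gstf(2 * wf + 3 * wf2, g, dt)
  rhs <- 2 * apply_gstf(wf, g, dt) + 3 * apply_gstf(wf2, g, dt)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("gstf objects validate their invariants", {
  expect_error(gstf(c(0, 1, 1), rep(1 + 0i, 3)), "increasing")
  expect_error(gstf(c(0, 1), c(1.1 + 0i, 1)), "0 Hz")
  g <- make_gstf()
  expect_lte(Mod(g$response[1, 1]), 1 + 1e-9)
})

test_that("gradient integration: constant, zero, nulled rewinder", {
  dt <- 1e-5
  g <- rep(1e-3, 100)
  k <- gradients_to_kspace(g, dt)
  expect_equal(k[1], 0)
  expect_equal(diff(k), rep(k[2], 99), tolerance = 1e-9)
  expect_true(all(gradients_to_kspace(rep(0, 50), dt) == 0))
  # triangular rewinder scaled to null the zeroth moment exactly
  readout <- rep(1e-3, 60)
  tri <- c(seq(0, -1, length.out = 21), seq(-1, 0, length.out = 21)[-1])
  wf <- c(readout, tri)
  m_read <- pracma::trapz((seq_along(wf) - 1) * dt, c(readout, tri * 0))
  m_tri <- pracma::trapz((seq_along(wf) - 1) * dt, c(readout * 0, tri))
  wf <- c(readout, tri * (-m_read / m_tri))
  k <- gradients_to_kspace(wf, dt)
  expect_lt(abs(k[length(k)]) / max(abs(k)), 1e-6)
})

test_that("density compensation: radial ~ |k|, positivity, single sample", {
  # uniform radial spokes expressed as a trajectory
  ns <- 40; na <- 16
  coords <- array(0, dim = c(na, ns, 2))
  r <- seq(0, 0.5, length.out = ns)
  for (a in seq_len(na)) {
    th <- 2 * pi * (a - 1) / na
    coords[a, , 1] <- r * cos(th)
    coords[a, , 2] <- r * sin(th)
  }
  spokes <- structure(list(coords = coords, n_arms = na, n_samples = ns,
                           dwell_s = 1e-5, fov_mm = 64 * 3, res_mm = 3,
                           arm_offsets = 2 * pi * (0:(na - 1)) / na,
                           rotation_offset = 0, n_fov = 64),
                      class = "spiral_trajectory")
  w <- density_compensation(spokes)
  ratio <- w[1, 5:ns] / r[5:ns]
  expect_lt(diff(range(ratio)) / mean(ratio), 0.05)
  expect_true(all(w > 0))
  expect_true(all(is.finite(w)))
  one <- structure(list(coords = array(0, c(1, 1, 2)), n_arms = 1L,
                        n_samples = 1L, dwell_s = 1e-5, fov_mm = 3,
                        res_mm = 3, arm_offsets = 0, rotation_offset = 0,
                        n_fov = 1),
                   class = "spiral_trajectory")
  expect_equal(as.numeric(density_compensation(one)), 1)
  expect_true(all(density_compensation(design_spiral(592, 1.29, 13)) > 0))
})
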