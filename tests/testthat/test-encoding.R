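# Non-uniform Fourier encoding, coil simulation/estimation, CG-SENSE.

test_that("forward encoding matches DC and point-source expectations", {
  n <- 16
  tr <- design_spiral(n * 3, 3, n_arms = 4, n_samples = 30)
  img <- matrix(0.7, n, n)
  ks <- nufft_forward(img + 0i, NULL, tr, exact = TRUE)
  expect_equal(Mod(ks$samples[1, 1, 1]), sum(img), tolerance = 1e-9)
  pt <- matrix(0i, n, n); pt[n / 2 + 1, n / 2 + 1] <- 1
  ks2 <- nufft_forward(pt, NULL, tr, exact = TRUE)
  expect_lt(diff(range(Mod(ks2$samples))), 1e-9)
})

test_that("gridding forward agrees with brute-force NDFT at 1e-5 on 16x16", {
  set.seed(2)
  n <- 16
  img <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
  tr <- design_spiral(n * 3, 3, n_arms = 4, n_samples = 40)
  ks <- nufft_forward(img, NULL, tr)
  kx <- as.vector(t(tr$coords[, , 1])); ky <- as.vector(t(tr$coords[, , 2]))
  ref <- ndft_reference(img, kx, ky)
  got <- as.vector(t(ks$samples[, , 1]))
  expect_lt(max(abs(got - ref)) / max(abs(ref)), 1e-5)
  # the compiled exact mode agrees with the plain-R sum at 1e-10
  ks_ex <- nufft_forward(img, NULL, tr, exact = TRUE)
  expect_lt(max(abs(as.vector(t(ks_ex$samples[, , 1])) - ref)) / max(abs(ref)),
            1e-10)
})

test_that("forward/adjoint pass the inner-product adjoint test", {
  set.seed(4)
  n <- 16
  tr <- design_spiral(n * 3, 3, n_arms = 4, n_samples = 40)
  img <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n)
  y <- complex(real = rnorm(4 * 40), imaginary = rnorm(4 * 40))
  # gridding mode
  pl <- nufft_plan(tr, n)
  ax <- spiralcine:::nufft_apply(pl, img)
  aty <- spiralcine:::nufft_apply_adj(pl, y)
  lhs <- sum(Conj(ax) * y); rhs <- sum(Conj(img) * aty)
  denom <- sqrt(sum(Mod(ax)^2)) * sqrt(sum(Mod(y)^2))
  expect_lt(abs(lhs - rhs) / denom, 1e-3)
  # exact mode
  ax <- spiralcine:::ndft_fwd_cpp(img, as.vector(t(tr$coords[, , 1])),
                     as.vector(t(tr$coords[, , 2])))
  aty <- spiralcine:::ndft_adj_cpp(y, as.vector(t(tr$coords[, , 1])),
                      as.vector(t(tr$coords[, , 2])), n, rep(1, length(y)))
  lhs <- sum(Conj(ax) * y); rhs <- sum(Conj(img) * aty)
  expect_lt(abs(lhs - rhs) / (sqrt(sum(Mod(ax)^2)) * sqrt(sum(Mod(y)^2))),
            1e-10)
})

test_that("zero k-space grids to a zero image; dense spiral recovers the phantom", {
  fr <- desk_frame()
  tdense <- design_spiral(64 * 3, 3, n_arms = 32, center_under = 0.5,
                          edge_under = 0.9, n_samples = 700)
  ks <- nufft_forward(fr$image + 0i, NULL, tdense)
  ks0 <- ks; ks0$samples[] <- 0i
  expect_true(all(Mod(nufft_adjoint(ks0, NULL, tdense, n = 64)) == 0))
  rec <- nufft_adjoint(ks, NULL, tdense, use_dcf = TRUE, n = 64)
  expect_lte(nrmse(Mod(rec), fr$image), 0.05)
})

test_that("simulated coils are reproducible, smooth, and constant when asked", {
  c1 <- simulate_coils(32, 6, seed = 9)
  c2 <- simulate_coils(32, 6, seed = 9)
  expect_identical(c1$maps, c2$maps)
  c3 <- simulate_coils(32, 6, seed = 10)
  expect_false(identical(c1$maps, c3$maps))
  cc <- simulate_coils(32, 1, smoothness = Inf)
  expect_true(all(cc$maps == 1 + 0i))
  # total variation of the magnitude stays below a smoothness bound
  for (c in 1:6) {
    m <- abs(c1$maps[, , c])
    tv <- sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
    expect_lt(tv / sum(m + 1e-9), 0.2)
  }
})

test_that("adaptive coil estimation recovers simulated maps", {
  fr <- desk_frame()
  coils <- simulate_coils(64, 8, seed = 5)
  ci <- array(0i, c(64, 64, 8))
  for (c in 1:8) ci[, , c] <- coils$maps[, , c] * fr$image
  est <- estimate_coils_adaptive(ci)
  rss <- sqrt(apply(abs(coils$maps)^2, c(1, 2), sum))
  supp <- fr$image > 0.15
  for (c in 1:8) {
    ref <- abs(coils$maps[, , c]) / rss
    expect_lt(max(abs(abs(est$maps[, , c]) - ref)[supp]), 0.02)
  }
  expect_error(estimate_coils_adaptive(array(0i, c(8, 8, 2))), "zero")
  # single uniform coil -> constant-magnitude map
  u <- estimate_coils_adaptive(array(0.5 + 0i, c(16, 16, 1)))
  expect_lt(diff(range(abs(u$maps))), 1e-9)
})

test_that("subsampled estimation is consistent with full resolution on smooth maps", {
  coils <- simulate_coils(64, 8, seed = 5)
  ci <- array(0i, c(64, 64, 8))
  for (c in 1:8) ci[, , c] <- coils$maps[, , c]
  full <- estimate_coils_adaptive(ci)
  sub <- estimate_coils_adaptive(ci, subsample_factor = 4L)
  for (c in 1:8)
    expect_lt(max(abs(abs(sub$maps[, , c]) - abs(full$maps[, , c]))), 0.05)
})

test_that("CG-SENSE matches the inverse DFT on a fully sampled Cartesian grid", {
  n <- 16
  tc <- cartesian_traj(n)
  truth <- matrix(0, n, n); truth[5:12, 6:10] <- 1; truth[8, 8] <- 2
  ks <- nufft_forward(truth + 0i, NULL, tc, exact = TRUE)
  rec <- cg_sense(ks, tc, NULL, n_iter = 10, exact = TRUE,
                  track_residuals = TRUE)
  expect_lt(max(Mod(rec - truth)) / max(truth), 1e-3)
  res <- attr(rec, "residuals")
  expect_true(all(res[-1] <= 1.01 * res[-length(res)] + 1e-12))
})

test_that("CG-SENSE beats density-compensated gridding on undersampled data", {
  fr <- desk_frame()
  tr <- desk_traj()
  coils <- simulate_coils(64, 8, seed = 5)
  ks <- nufft_forward(fr$image + 0i, coils, tr)
  grid <- nufft_adjoint(ks, coils, tr, use_dcf = TRUE)
  cg <- cg_sense(ks, tr, coils, n_iter = 10)
  expect_lt(nrmse(Mod(cg), fr$image), nrmse(Mod(grid), fr$image))
})

test_that("CG-SENSE converges to the phantom on an overdetermined system", {
  fr <- desk_frame()
  tdense <- design_spiral(64 * 3, 3, n_arms = 26, center_under = 1,
                          edge_under = 2, n_samples = 500)
  coils <- simulate_coils(64, 8, seed = 6)
  ks <- nufft_forward(fr$image + 0i, coils, tdense)
  rec <- cg_sense(ks, tdense, coils, n_iter = 30)
  expect_lte(nrmse(Mod(rec), fr$image), 0.02)
})

test_that("shape mismatches raise errors", {
  tr <- desk_traj()
  coils <- simulate_coils(32, 2, seed = 1)
  expect_error(nufft_forward(matrix(1, 64, 64), coils, tr), "grid")
  ks <- nufft_forward(matrix(1, 32, 32) + 0i, coils,
                      design_spiral(32 * 3, 3, n_samples = 60))
  ks$samples <- ks$samples[, 1:10, , drop = FALSE]
  expect_error(nufft_adjoint(ks, coils), "shape")
})
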