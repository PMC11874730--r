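# Neural-network engine and the disentangled model surface.

test_that("layer gradients match numerical differentiation", {
  set.seed(1)
  # convolution
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  dy <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  g <- spiralcine:::conv2d_bw_cpp(x, w, dy, dim(x))
  for (i in c(4, 30, 70)) {
    num <- num_grad(function(z) sum(spiralcine:::conv2d_fw_cpp(z, w, b, dim(x)) * dy), x, i)
    expect_equal(g$dx[i], num, tolerance = 1e-5)
  }
  for (i in c(2, 25, 50)) {
    num <- num_grad(function(z) {
      dim(z) <- dim(w); sum(spiralcine:::conv2d_fw_cpp(x, z, b, dim(x)) * dy)
    }, w, i)
    expect_equal(g$dw[i], num, tolerance = 1e-5)
  }
  # batch normalization (training mode, batch statistics)
  bn <- spiralcine:::bn_layer(3)
  xb <- array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  R <- array(rnorm(length(xb)), dim(xb))
  spiralcine:::zero_grads(list(bn))
  invisible(bn$fw(xb, TRUE))
  dxb <- bn$bw(R)
  for (i in c(11, 60, 120)) {
    num <- num_grad(function(z) {
      dim(z) <- dim(xb); v <- sum(bn$fw(z, TRUE) * R); bn$cache <- list(); v
    }, xb, i)
    expect_equal(dxb[i], num, tolerance = 1e-4)
  }
  num <- num_grad(function(v) {
    old <- bn$gamma[2]; bn$gamma[2] <- v
    out <- sum(bn$fw(xb, TRUE) * R); bn$cache <- list(); bn$gamma[2] <- old
    out
  }, bn$gamma[2], 1)
  expect_equal(bn$ggamma[2], num, tolerance = 1e-4)
  # channel softmax
  sm <- spiralcine:::softmax_layer()
  xs <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  Rs <- array(rnorm(length(xs)), dim(xs))
  invisible(sm$fw(xs))
  dxs <- sm$bw(Rs)
  for (i in c(7, 40)) {
    num <- num_grad(function(z) {
      dim(z) <- dim(xs); v <- sum(sm$fw(z) * Rs); sm$cache <- list(); v
    }, xs, i)
    expect_equal(dxs[i], num, tolerance = 1e-5)
  }
})

test_that("model-level gradients are exact on the continuous paths", {
  # checks the VAE, FiLM decoder and refinement U-Net through the full
  # multi-task objective (the anatomy path uses a straight-through
  # surrogate whose analytic gradient intentionally differs from the
  # piecewise-constant numeric one)
  set.seed(42)
  cfg <- xsdnet_config(grid = 8L, base_width = 4L, depth = 2L, seed = 3L)
  model <- xsdnet_new(cfg)
  B <- 2
  x <- array(runif(8 * 8 * B), c(8, 8, 1, B))
  tg <- array(runif(8 * 8 * B), c(8, 8, 1, B))
  mk <- array(sample(0:3, 8 * 8 * B, TRUE), c(8, 8, 1, B))
  eps <- matrix(rnorm(B * 8), B)
  fwd_loss <- function() {
    out <- spiralcine:::xsdnet_forward(model, x, x, train = TRUE, eps = eps)
    enc2 <- spiralcine:::cbind4(out$dec, out$a_bin)
    st2 <- model$vae$fw(enc2, TRUE)
    mu_re <- st2[, 1:8, drop = FALSE]
    ft <- spiralcine:::perc_features_nograd(model, spiralcine:::as4(tg))
    fr <- model$perc$fw(out$rec, TRUE)
    v <- spiralcine:::compute_loss_bundle(model, out, tg, mk, mu_re, fr,
                                          ft)$total
    spiralcine:::clear_caches(model$layers_all)
    v
  }
  spiralcine:::zero_grads(model$layers_all)
  ls <- spiralcine:::xsdnet_step(model, x, x, tg, mk, eps = eps)
  expect_true(is.finite(ls$total))
  for (grp in list(model$vae$layers, model$film$layers,
                   model$refine$layers)) {
    lay <- grp[[1]]
    for (p in lay$param_names[1]) {
      g <- lay[[paste0("g", p)]]
      i <- which.max(abs(g))
      h <- 1e-5
      orig <- lay[[p]][i]
      lay[[p]][i] <- orig + h; lp <- fwd_loss()
      lay[[p]][i] <- orig - h; lm <- fwd_loss()
      lay[[p]][i] <- orig
      expect_equal(g[i], (lp - lm) / (2 * h), tolerance = 1e-3)
    }
  }
})

test_that("anatomy encoding yields 8 normalized soft factors, deterministically", {
  model <- xsdnet_new(xsdnet_config(grid = 16L, base_width = 4L, seed = 5L))
  img <- matrix(runif(256), 16)
  f1 <- encode_anatomy(model, img)
  f2 <- encode_anatomy(model, img)
  expect_equal(dim(f1), c(16L, 16L, 8L, 1L))
  expect_identical(f1, f2)
  sums <- apply(f1[, , , 1], c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_true(all(f1 >= 0 & f1 <= 1))
  expect_error(encode_anatomy(model, matrix(NaN, 16, 16)), "finite")
})

test_that("binarization thresholds at 0.5 and is idempotent; ST gradient is identity", {
  f <- array(c(0.49, 0.51, 0.5, 0.999), c(2, 2, 1, 1))
  b <- binarize(f)
  expect_equal(as.numeric(b), c(0, 1, 0, 1))
  expect_identical(binarize(b), b)
  # straight-through surrogate: the training path propagates gradients
  # unchanged through the threshold while the hard output is flat
  model <- xsdnet_new(xsdnet_config(grid = 8L, base_width = 4L, depth = 2L,
                                    seed = 1L))
  x <- array(runif(64), c(8, 8, 1, 1))
  out <- spiralcine:::xsdnet_forward(model, x, x, train = TRUE,
                        eps = matrix(0, 1, 8))
  spiralcine:::clear_caches(model$layers_all)
  expect_true(all(out$a_bin %in% c(0, 1)))
  # numeric gradient of the hard threshold is zero almost everywhere
  expect_equal(num_grad(function(v) binarize(array(v, c(1, 1, 1, 1)))[1],
                        0.3, 1), 0)
})

test_that("segmentor returns 4-class probabilities from 3 conv layers", {
  model <- xsdnet_new(xsdnet_config(grid = 16L, base_width = 4L, seed = 5L))
  f <- array((runif(16 * 16 * 8) > 0.5) * 1, c(16, 16, 8, 1))
  p <- segment_factors(model, f)
  expect_equal(dim(p), c(16L, 16L, 4L, 1L))
  sums <- apply(p[, , , 1], c(1, 2), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  lbl <- apply(p[, , , 1], c(1, 2), which.max) - 1
  expect_true(all(lbl %in% 0:3))
  # exactly 3 convolutional layers before the classifier
  expect_equal(length(Filter(function(l) !is.null(l$W) &&
                               length(dim(l$W)) == 4,
                             model$segm$layers)), 3L)
})

test_that("modality vector has length 8; inference returns the mean; KL closed form", {
  model <- xsdnet_new(xsdnet_config(grid = 16L, base_width = 4L, seed = 5L))
  img <- matrix(runif(256), 16)
  mv <- encode_modality(model, img)
  expect_equal(ncol(mv$mean), 8L)
  expect_equal(ncol(mv$logvar), 8L)
  expect_identical(mv$sample, mv$mean)
  mv2 <- encode_modality(model, img, sample = TRUE, seed = 2)
  expect_false(identical(mv2$sample, mv2$mean))
  kl0 <- 0.5 * sum(0^2 + exp(0) - 1 - 0)
  expect_equal(kl0, 0)
})

test_that("FiLM decoding responds to the modality vector, not the grid", {
  model <- xsdnet_new(xsdnet_config(grid = 16L, base_width = 4L, seed = 5L))
  f <- array((runif(16 * 16 * 8) > 0.5) * 1, c(16, 16, 8, 1))
  z1 <- rep(0, 8); z2 <- c(2, -1, 0.5, 0, 1, -2, 0.3, 0)
  d1 <- decode_film(model, f, z1)
  d2 <- decode_film(model, f, z2)
  expect_equal(dim(d1)[1:2], c(16L, 16L))
  expect_gt(sum(abs(d1 - d2)), 1e-6)
  f0 <- array(0, c(16, 16, 8, 1))
  expect_true(all(is.finite(decode_film(model, f0, z1))))
})

test_that("refinement preserves the grid and rejects mismatches", {
  model <- xsdnet_new(xsdnet_config(grid = 16L, base_width = 4L, seed = 5L))
  dec <- matrix(runif(256), 16); interim <- matrix(runif(256), 16)
  r1 <- refine(model, dec, interim)
  expect_equal(dim(r1)[1:2], c(16L, 16L))
  r2 <- refine(model, dec, interim)
  expect_identical(r1, r2)
  expect_error(refine(model, dec, matrix(0, 8, 8)), "grid")
})

test_that("perfect predictions zero the matching loss components", {
  model <- xsdnet_new(xsdnet_config(grid = 16L, base_width = 4L, seed = 5L))
  img <- matrix(runif(256), 16)
  mk <- matrix(sample(0:3, 256, TRUE), 16)
  p <- spiralcine:::one_hot_mask(array(mk, c(16, 16, 1, 1)), 4)
  z <- matrix(rnorm(8), 1)
  ls <- compute_losses(model, seg_p = p, rec = img, mu = matrix(0, 1, 8),
                       logvar = matrix(0, 1, 8), z = z, mu_re = z,
                       target_image = img, target_mask = mk)
  expect_equal(ls$kl, 0)
  expect_equal(ls$modality, 0)
  expect_equal(ls$recon, 0)
  expect_lt(ls$dice, 1e-4)
  expect_equal(ls$total,
               with(model$config$loss_weights,
                    seg * ls$seg + kl * ls$kl + modality * ls$modality +
                      recon * ls$recon))
})

test_that("Dice loss is 0 against itself and 1 against the complement", {
  mk <- matrix(sample(0:1, 64, TRUE), 8)
  expect_equal(dice(mk, mk, 1L), 1)
  expect_equal(dice(mk, 1 - mk, 1L), 0)
})

test_that("modality swap changes the decoded image but not the anatomy", {
  model <- xsdnet_new(xsdnet_config(grid = 16L, base_width = 4L, seed = 5L))
  img1 <- matrix(runif(256), 16)
  img2 <- matrix(runif(256) * 0.3, 16)
  f1 <- binarize(encode_anatomy(model, img1))
  z1 <- encode_modality(model, img1, f1)$mean
  z2 <- encode_modality(model, img2, binarize(encode_anatomy(model, img2)))$mean
  d_own <- decode_film(model, f1, z1)
  d_swp <- decode_film(model, f1, z2)
  expect_gt(mean(abs(d_own - d_swp)), 0)     # contrast controlled by z
  f1_again <- binarize(encode_anatomy(model, img1))
  expect_identical(f1, f1_again)             # anatomy untouched by the swap
})

test_that("parameter count is finite and reported; forward pass is fast", {
  model <- xsdnet_new(xsdnet_config(grid = 64L, seed = 2L))
  np <- spiralcine:::n_params(model$layers_all)
  expect_true(is.finite(np) && np > 1000)
  expect_output(print(model), "parameters")
  img <- matrix(runif(64 * 64), 64)
  invisible(predict(model, img))             # warm up
  t0 <- Sys.time()
  invisible(predict(model, img))
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
})
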