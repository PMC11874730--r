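# Disentangled joint reconstruction-and-segmentation model.
#
# Two latent spaces factorize a cardiac frame: an anatomy space of 8
# binary channel maps (spatial, contrast-free) produced by a U-Net and
# thresholding with a straight-through gradient, and a modality space of
# 8 reals produced by a variational encoder, capturing contrast. A FiLM-
# conditioned decoder re-renders the image from both latents; a shallow
# segmentor reads LV / myocardium / RV masks off the anatomy factors;
# and a refinement U-Net fuses the decoded image with the CG-SENSE
# interim estimate into the final reconstruction.

#' Model configuration
#'
#' @param grid input image size (pixels, power-of-two friendly).
#' @param base_width channels of the first U-Net level.
#' @param depth anatomy U-Net depth (number of resolution levels).
#' @param n_factors anatomy channels. @param zdim modality vector length.
#' @param n_classes segmentation classes (background, LV, myocardium, RV).
#' @param vae_sees_factors feed the anatomy factors to the modality
#'   encoder alongside the image.
#' @param factor_gain multiplier on the anatomy logits before the
#'   channel softmax; values above 1 sharpen the soft factors so less
#'   boundary detail is lost to binarization.
#' @param loss_weights named list: seg, kl, modality, recon.
#' @param perc_l1 weight of the pixelwise L1 term inside the
#'   reconstruction loss.
#' @param lrelu_alpha negative slope of LeakyReLU activations.
#' @param seed weight-initialization seed.
#' @return list of class `xsdnet_config`.
#' @export
xsdnet_config <- function(grid = 64L, base_width = 8L, depth = 3L,
                          n_factors = 8L, zdim = 8L, n_classes = 4L,
                          vae_sees_factors = TRUE, factor_gain = 1,
                          loss_weights = list(seg = 10, kl = 0.01,
                                              modality = 1, recon = 1),
                          perc_l1 = 1, lrelu_alpha = 0.1, seed = 1L) {
  structure(as.list(environment()), class = "xsdnet_config")
}

build_unet <- function(cin, cout, w, depth, rng, alpha) {
  u <- new.env(parent = emptyenv())
  wl <- w * 2^(seq_len(depth) - 1)
  u$enc <- lapply(seq_len(depth - 1), function(l) list(
    c1 = conv_layer(if (l == 1) cin else wl[l - 1], wl[l], rng),
    a1 = lrelu_layer(alpha),
    c2 = conv_layer(wl[l], wl[l], rng), a2 = lrelu_layer(alpha),
    pool = pool_layer()))
  u$bot <- list(c1 = conv_layer(wl[max(1, depth - 1)], wl[depth], rng),
                a1 = lrelu_layer(alpha),
                c2 = conv_layer(wl[depth], wl[depth], rng),
                a2 = lrelu_layer(alpha))
  u$dec <- lapply(rev(seq_len(depth - 1)), function(l) list(
    up = upsample_layer(),
    red = conv_layer(wl[l + 1], wl[l], rng), ar = lrelu_layer(alpha),
    c1 = conv_layer(2 * wl[l], wl[l], rng), a1 = lrelu_layer(alpha),
    c2 = conv_layer(wl[l], wl[l], rng), a2 = lrelu_layer(alpha)))
  u$head <- conv_layer(wl[1], cout, rng)
  u$depth <- depth
  u$skips <- list()
  u$fw <- function(x, train = FALSE) {
    h <- as4(x)
    skips <- vector("list", depth - 1)
    for (l in seq_len(depth - 1)) {
      lv <- u$enc[[l]]
      h <- lv$a2$fw(lv$c2$fw(lv$a1$fw(lv$c1$fw(h, train), train), train), train)
      skips[[l]] <- h
      h <- lv$pool$fw(h, train)
    }
    h <- u$bot$a2$fw(u$bot$c2$fw(u$bot$a1$fw(u$bot$c1$fw(h, train), train),
                                 train), train)
    for (i in seq_along(u$dec)) {
      l <- depth - i                      # level being restored
      lv <- u$dec[[i]]
      h <- lv$ar$fw(lv$red$fw(lv$up$fw(h, train), train), train)
      h <- cbind4(h, skips[[l]])
      h <- lv$a2$fw(lv$c2$fw(lv$a1$fw(lv$c1$fw(h, train), train), train), train)
    }
    u$head$fw(h, train)
  }
  u$bw <- function(dy) {
    dh <- u$head$bw(dy)
    dskips <- vector("list", depth - 1)
    for (i in rev(seq_along(u$dec))) {
      l <- depth - i
      lv <- u$dec[[i]]
      dh <- lv$c1$bw(lv$a1$bw(lv$c2$bw(lv$a2$bw(dh))))
      nc <- dim(dh)[3] / 2
      dskips[[l]] <- dh[, , nc + seq_len(nc), , drop = FALSE]
      dh <- lv$up$bw(lv$red$bw(lv$ar$bw(dh[, , seq_len(nc), , drop = FALSE])))
    }
    dh <- u$bot$c1$bw(u$bot$a1$bw(u$bot$c2$bw(u$bot$a2$bw(dh))))
    for (l in rev(seq_len(depth - 1))) {
      lv <- u$enc[[l]]
      dh <- lv$pool$bw(dh) + dskips[[l]]
      dh <- lv$c1$bw(lv$a1$bw(lv$c2$bw(lv$a2$bw(dh))))
    }
    dh
  }
  u$layers <- collect_layers(list(u$enc, u$bot, u$dec, u$head))
  u
}

cbind4 <- function(a, b) {
  a <- as4(a); b <- as4(b)
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

build_segmentor <- function(n_factors, n_classes, w, rng, alpha) {
  s <- new.env(parent = emptyenv())
  s$c1 <- conv_layer(n_factors, w, rng); s$b1 <- bn_layer(w)
  s$a1 <- lrelu_layer(alpha)
  s$c2 <- conv_layer(w, w, rng); s$b2 <- bn_layer(w)
  s$a2 <- lrelu_layer(alpha)
  s$c3 <- conv_layer(w, n_classes, rng)
  s$sm <- softmax_layer()
  s$fw <- function(x, train = FALSE) {
    h <- s$a1$fw(s$b1$fw(s$c1$fw(as4(x), train), train), train)
    h <- s$a2$fw(s$b2$fw(s$c2$fw(h, train), train), train)
    s$sm$fw(s$c3$fw(h, train), train)
  }
  s$bw <- function(dy) {
    dh <- s$c3$bw(s$sm$bw(dy))
    dh <- s$c2$bw(s$b2$bw(s$a2$bw(dh)))
    s$c1$bw(s$b1$bw(s$a1$bw(dh)))
  }
  s$layers <- collect_layers(list(s$c1, s$b1, s$c2, s$b2, s$c3, s$sm,
                                  s$a1, s$a2))
  s
}

build_vae_enc <- function(cin, w, grid, zdim, rng, alpha) {
  v <- new.env(parent = emptyenv())
  v$c1 <- conv_layer(cin, w, rng); v$a1 <- lrelu_layer(alpha)
  v$p1 <- pool_layer()
  v$c2 <- conv_layer(w, 2 * w, rng); v$a2 <- lrelu_layer(alpha)
  v$p2 <- pool_layer()
  v$c3 <- conv_layer(2 * w, 2 * w, rng); v$a3 <- lrelu_layer(alpha)
  v$p3 <- pool_layer()
  v$fl <- flatten_layer()
  v$d1 <- dense_layer(2 * w * (grid / 8)^2, 64, rng)
  v$ad <- lrelu_vec_layer(alpha)
  v$d2 <- dense_layer(64, 2 * zdim, rng)
  v$fw <- function(x, train = FALSE) {
    h <- v$p1$fw(v$a1$fw(v$c1$fw(as4(x), train), train), train)
    h <- v$p2$fw(v$a2$fw(v$c2$fw(h, train), train), train)
    h <- v$p3$fw(v$a3$fw(v$c3$fw(h, train), train), train)
    v$d2$fw(v$ad$fw(v$d1$fw(v$fl$fw(h, train), train), train), train)
  }
  v$bw <- function(dy) {
    dh <- v$fl$bw(v$d1$bw(v$ad$bw(v$d2$bw(dy))))
    dh <- v$c3$bw(v$a3$bw(v$p3$bw(dh)))
    dh <- v$c2$bw(v$a2$bw(v$p2$bw(dh)))
    v$c1$bw(v$a1$bw(v$p1$bw(dh)))
  }
  v$layers <- collect_layers(list(v$c1, v$a1, v$p1, v$c2, v$a2, v$p2,
                                  v$c3, v$a3, v$p3, v$fl, v$d1, v$ad, v$d2))
  v
}

build_film_dec <- function(n_factors, zdim, rng, alpha, w = 8L) {
  f <- new.env(parent = emptyenv())
  w2 <- max(8L, w %/% 2L)
  f$c1 <- conv_layer(n_factors, w, rng); f$f1 <- film_layer(w, zdim, rng)
  f$a1 <- lrelu_layer(alpha)
  f$c2 <- conv_layer(w, w, rng); f$f2 <- film_layer(w, zdim, rng)
  f$a2 <- lrelu_layer(alpha)
  f$c3 <- conv_layer(w, w2, rng); f$f3 <- film_layer(w2, zdim, rng)
  f$a3 <- lrelu_layer(alpha)
  f$c4 <- conv_layer(w2, 1, rng)
  f$fw <- function(factors, z, train = FALSE) {
    h <- f$a1$fw(f$f1$fw(f$c1$fw(as4(factors), train), z, train), train)
    h <- f$a2$fw(f$f2$fw(f$c2$fw(h, train), z, train), train)
    h <- f$a3$fw(f$f3$fw(f$c3$fw(h, train), z, train), train)
    f$c4$fw(h, train)
  }
  f$bw <- function(dy) {
    dh <- f$c4$bw(dy)
    g3 <- f$f3$bw(f$a3$bw(dh)); dh <- f$c3$bw(g3$dx)
    g2 <- f$f2$bw(f$a2$bw(dh)); dh <- f$c2$bw(g2$dx)
    g1 <- f$f1$bw(f$a1$bw(dh)); dh <- f$c1$bw(g1$dx)
    list(dfactors = dh, dz = g1$dz + g2$dz + g3$dz)
  }
  f$layers <- collect_layers(list(f$c1, f$f1, f$a1, f$c2, f$f2, f$a2,
                                  f$c3, f$f3, f$a3, f$c4))
  f
}

build_perceptual <- function(rng, alpha) {
  p <- new.env(parent = emptyenv())
  p$c1 <- conv_layer(1, 8, rng); p$a1 <- lrelu_layer(alpha)
  p$p1 <- pool_layer()
  p$c2 <- conv_layer(8, 16, rng); p$a2 <- lrelu_layer(alpha)
  p$p2 <- pool_layer()
  p$c3 <- conv_layer(16, 16, rng)
  p$fw <- function(x, train = FALSE) {
    f1 <- p$a1$fw(p$c1$fw(as4(x), train), train)
    f2 <- p$a2$fw(p$c2$fw(p$p1$fw(f1, train), train), train)
    f3 <- p$c3$fw(p$p2$fw(f2, train), train)
    list(f1, f2, f3)
  }
  p$bw <- function(dfeats) {
    dh <- p$p2$bw(p$c3$bw(dfeats[[3]]))
    dh <- p$p1$bw(p$c2$bw(p$a2$bw(dh + dfeats[[2]])))
    p$c1$bw(p$a1$bw(dh + dfeats[[1]]))
  }
  p$layers <- collect_layers(list(p$c1, p$a1, p$p1, p$c2, p$a2, p$p2, p$c3))
  p$frozen <- TRUE
  p
}

#' Construct an untrained joint reconstruction-and-segmentation model
#'
#' @param config an [xsdnet_config].
#' @return object of class `xsdnet` (untrained; fit with [xsdnet_train]).
#' @export
xsdnet_new <- function(config = xsdnet_config()) {
  rng <- new_rng_init(derive_seed(config$seed, "weights"))
  a <- config$lrelu_alpha
  w <- config$base_width
  m <- list(
    config = config,
    anat = build_unet(1L, config$n_factors, w, config$depth, rng, a),
    anat_sm = softmax_layer(),
    segm = build_segmentor(config$n_factors, config$n_classes, w, rng, a),
    vae = build_vae_enc(if (config$vae_sees_factors)
      1L + config$n_factors else 1L, w, config$grid, config$zdim, rng, a),
    film = build_film_dec(config$n_factors, config$zdim, rng, a, w),
    refine = build_unet(2L, 1L, w, 2L, rng, a),
    perc = build_perceptual(rng, a),
    history = NULL, trained = FALSE)
  m$layers_trainable <- c(m$anat$layers, list(m$anat_sm), m$segm$layers,
                          m$vae$layers, m$film$layers, m$refine$layers)
  m$layers_all <- c(m$layers_trainable, m$perc$layers)
  class(m) <- "xsdnet"
  m
}

#' Normalize an interim magnitude image for the model
#'
#' Scales by the 99th percentile of the interim estimate (clamped copy
#' is not taken; values slightly above 1 are allowed).
#' @param img magnitude image. @param q reference quantile.
#' @return list `image` (normalized), `scale` (the divisor).
#' @export
normalize_interim <- function(img, q = 0.99) {
  s <- stats::quantile(abs(img), q, names = FALSE)
  if (s <= 0) s <- max(abs(img), 1e-12)
  list(image = img / s, scale = s)
}

# --- forward / backward -----------------------------------------------------

xsdnet_forward <- function(model, x, interim, train = FALSE, eps = NULL,
                           hard = TRUE) {
  cfg <- model$config
  x <- as4(x); interim <- as4(interim)
  if (any(!is.finite(x))) stop("non-finite model input")
  B <- dim(x)[4]
  gain <- if (is.null(cfg$factor_gain)) 1 else cfg$factor_gain
  a_logits <- model$anat$fw(x, train) * gain
  a_soft <- model$anat_sm$fw(a_logits, train)
  if (hard) {
    a_bin <- (a_soft > 0.5) * 1
    dim(a_bin) <- dim(a_soft)
  } else a_bin <- a_soft   # soft warm-up (training only)
  seg_p <- model$segm$fw(a_bin, train)
  enc_in <- if (cfg$vae_sees_factors) cbind4(x, a_bin) else x
  st <- model$vae$fw(enc_in, train)
  mu <- st[, seq_len(cfg$zdim), drop = FALSE]
  lv <- st[, cfg$zdim + seq_len(cfg$zdim), drop = FALSE]
  lv <- pmax(pmin(lv, 8), -8)
  if (train) {
    if (is.null(eps)) eps <- matrix(stats::rnorm(B * cfg$zdim), B)
    z <- mu + exp(lv / 2) * eps
  } else { eps <- matrix(0, B, cfg$zdim); z <- mu }
  dec <- model$film$fw(a_bin, z, train)
  rec <- model$refine$fw(cbind4(dec, interim), train) + interim
  list(a_soft = a_soft, a_bin = a_bin, seg_p = seg_p, mu = mu, lv = lv,
       z = z, eps = eps, dec = dec, rec = rec, x = x, interim = interim)
}

# peek-free frozen feature extraction (caches dropped immediately)
perc_features_nograd <- function(model, x) {
  lens <- lapply(model$perc$layers, function(l) length(l$cache))
  f <- model$perc$fw(as4(x))
  for (i in seq_along(model$perc$layers)) {
    l <- model$perc$layers[[i]]
    while (length(l$cache) > lens[[i]]) l$cache[[length(l$cache)]] <- NULL
  }
  f
}

one_hot_mask <- function(mask, n_classes) {
  mask <- as4(mask)
  d <- dim(mask)
  out <- array(0, c(d[1], d[2], n_classes, d[4]))
  for (c in seq_len(n_classes)) out[, , c, ] <- (mask[, , 1, ] == (c - 1)) * 1
  out
}

soft_dice_terms <- function(p, t) {
  d <- dim(p)
  sp <- bc_sum(p, d); st <- bc_sum(t, d); spt <- bc_sum(p * t, d) # (B x C)
  list(sp = sp, st = st, spt = spt)
}

#' Compute the multi-task loss bundle
#'
#' Segmentation = soft Dice loss + cross-entropy (averaged over classes
#' and pixels); KL divergence of the modality posterior against the unit
#' Gaussian; modality reconstruction = mean absolute difference between
#' the drawn modality vector and its re-encoding from the decoded image;
#' reconstruction = perceptual feature distance (3 depths of a frozen
#' random convolutional pyramid) plus a pixelwise L1 term.
#'
#' @param outputs forward-pass outputs (as produced internally; see
#'   [xsdnet_losses_from_arrays] for a direct array interface).
#' @param target_image,target_mask targets on the model grid.
#' @param model an `xsdnet`. @param mu_re re-encoded modality mean.
#' @return list of loss components and the weighted `total`.
#' @keywords internal
compute_loss_bundle <- function(model, outputs, target_image, target_mask,
                                mu_re, feats_rec, feats_tgt) {
  cfg <- model$config
  wts <- cfg$loss_weights
  p <- outputs$seg_p
  t1h <- one_hot_mask(target_mask, cfg$n_classes)
  d <- dim(p)
  npx <- d[1] * d[2] * d[4]
  ce <- -sum(t1h * log(pmax(p, 1e-8))) / npx
  dt <- soft_dice_terms(p, t1h)
  dice_c <- 2 * dt$spt / (dt$sp + dt$st + 1e-6)
  dice_loss <- 1 - mean(dice_c)
  seg <- ce + dice_loss
  B <- d[4]
  kl <- 0.5 * sum(outputs$mu^2 + exp(outputs$lv) - 1 - outputs$lv) / B
  modality <- mean(abs(outputs$z - mu_re))
  perc <- 0
  for (i in seq_along(feats_rec))
    perc <- perc + mean((feats_rec[[i]] - feats_tgt[[i]])^2)
  l1 <- mean(abs(outputs$rec - as4(target_image)))
  recon <- perc + cfg$perc_l1 * l1
  total <- wts$seg * seg + wts$kl * kl + wts$modality * modality +
    wts$recon * recon
  list(seg = seg, ce = ce, dice = dice_loss, kl = kl, modality = modality,
       recon = recon, perceptual = perc, l1 = l1, total = total)
}

# One full training step on a batch; returns the loss bundle.
xsdnet_step <- function(model, x, interim, target_image, target_mask,
                        eps = NULL, hard = TRUE) {
  cfg <- model$config
  wts <- cfg$loss_weights
  out <- xsdnet_forward(model, x, interim, train = TRUE, eps = eps,
                        hard = hard)
  # re-encode the decoded image (factors treated as constant input here)
  enc_in2 <- if (cfg$vae_sees_factors) cbind4(out$dec, out$a_bin) else out$dec
  st2 <- model$vae$fw(enc_in2, TRUE)
  mu_re <- st2[, seq_len(cfg$zdim), drop = FALSE]
  feats_tgt <- perc_features_nograd(model, as4(target_image))
  feats_rec <- model$perc$fw(out$rec, TRUE)
  losses <- compute_loss_bundle(model, out, target_image, target_mask,
                                mu_re, feats_rec, feats_tgt)

  # ---- backward
  d <- dim(out$seg_p); B <- d[4]
  # reconstruction path
  dfeats <- lapply(seq_along(feats_rec), function(i)
    wts$recon * 2 * (feats_rec[[i]] - feats_tgt[[i]]) / length(feats_rec[[i]]))
  drec <- model$perc$bw(dfeats) +
    wts$recon * cfg$perc_l1 * sign(out$rec - as4(target_image)) /
      length(out$rec)
  dstack <- model$refine$bw(drec)        # residual add handled below
  ddec <- dstack[, , 1, , drop = FALSE]
  # modality reconstruction path (through the second encoder pass)
  sgn <- sign(out$z - mu_re)
  dz <- wts$modality * sgn / length(sgn)
  dmu_re <- -dz
  dst2 <- cbind(dmu_re, matrix(0, B, cfg$zdim))
  denc2 <- model$vae$bw(dst2)
  ddec <- ddec + denc2[, , 1, , drop = FALSE]   # factor channels detached
  # FiLM decoder
  g <- model$film$bw(ddec)
  dz <- dz + g$dz
  dabin <- g$dfactors
  # reparameterization + KL
  dmu <- dz + wts$kl * out$mu / B
  dlv <- dz * out$eps * 0.5 * exp(out$lv / 2) +
    wts$kl * 0.5 * (exp(out$lv) - 1) / B
  denc1 <- model$vae$bw(cbind(dmu, dlv))
  if (cfg$vae_sees_factors)
    dabin <- dabin + denc1[, , 1 + seq_len(cfg$n_factors), , drop = FALSE]
  # segmentation path
  t1h <- one_hot_mask(target_mask, cfg$n_classes)
  npx <- d[1] * d[2] * d[4]
  dp_ce <- -t1h / pmax(out$seg_p, 1e-8) / npx
  dt <- soft_dice_terms(out$seg_p, t1h)
  S <- dt$sp + dt$st + 1e-6
  nC <- d[3] * B
  dp_dice <- -(2 * expand_bc(1 / S, d) * t1h -
                 expand_bc(2 * dt$spt / S^2, d)) / nC
  dabin <- dabin + model$segm$bw(wts$seg * (dp_ce + dp_dice))
  # straight-through binarization: gradient passes unchanged
  dasoft <- dabin
  model$anat$bw(model$anat_sm$bw(dasoft) *
                  (if (is.null(cfg$factor_gain)) 1 else cfg$factor_gain))
  losses
}

# --- public operation surface ----------------------------------------------

#' Encode an image into soft anatomy factors
#' @param model an `xsdnet`. @param image normalized magnitude image
#'   (matrix) or batch array.
#' @return array `H x W x n_factors x B` of soft factors in `[0, 1]`.
#' @export
encode_anatomy <- function(model, image) {
  if (any(!is.finite(image))) stop("non-finite input image")
  gain <- if (is.null(model$config$factor_gain)) 1 else
    model$config$factor_gain
  out <- model$anat_sm$fw(model$anat$fw(as4(image)) * gain)
  clear_caches(model$layers_all)
  out
}

#' Threshold soft anatomy factors to binary maps
#'
#' Inference-time hard threshold at 0.5. During training the gradient of
#' this operation is treated as the identity (straight-through), which
#' is what [xsdnet_train] uses internally.
#' @param factors soft factor array.
#' @return binary array of the same shape.
#' @export
binarize <- function(factors) {
  out <- (factors > 0.5) * 1
  dim(out) <- dim(factors)
  out
}

#' Segment binary anatomy factors into class probabilities
#' @param model an `xsdnet`. @param factors binary factor array.
#' @return array `H x W x 4 x B` of class probabilities.
#' @export
segment_factors <- function(model, factors) {
  out <- model$segm$fw(as4(factors))
  clear_caches(model$layers_all)
  out
}

#' Encode the modality (contrast) vector of an image
#' @param model an `xsdnet`. @param image normalized image.
#' @param factors binary anatomy factors (required when the model was
#'   configured with `vae_sees_factors`).
#' @param sample draw a reparameterized sample (training behaviour);
#'   default returns the mean.
#' @param seed seed for the draw.
#' @return list `mean`, `logvar`, `sample` (each `B x 8`).
#' @export
encode_modality <- function(model, image, factors = NULL, sample = FALSE,
                            seed = 1L) {
  cfg <- model$config
  x <- as4(image)
  enc_in <- if (cfg$vae_sees_factors) {
    if (is.null(factors)) factors <- binarize(encode_anatomy(model, image))
    cbind4(x, factors)
  } else x
  st <- model$vae$fw(enc_in)
  clear_caches(model$layers_all)
  mu <- st[, seq_len(cfg$zdim), drop = FALSE]
  lv <- pmax(pmin(st[, cfg$zdim + seq_len(cfg$zdim), drop = FALSE], 8), -8)
  s <- if (sample) {
    rs <- local_rng(seed)
    mu + exp(lv / 2) * matrix(rs$rnorm(length(mu)), nrow(mu))
  } else mu
  list(mean = mu, logvar = lv, sample = s)
}

#' Decode an image from anatomy factors and a modality vector
#' @param model an `xsdnet`. @param factors binary factors.
#' @param z modality vector (`B x 8` matrix or length-8 vector).
#' @return decoded image array `H x W x 1 x B`.
#' @export
decode_film <- function(model, factors, z) {
  if (is.null(dim(z))) z <- matrix(z, 1)
  out <- model$film$fw(as4(factors), z)
  clear_caches(model$layers_all)
  out
}

#' Refine a decoded image using the CG-SENSE interim estimate
#' @param model an `xsdnet`. @param decoded,interim images on one grid.
#' @return refined reconstruction, same grid.
#' @export
refine <- function(model, decoded, interim) {
  decoded <- as4(decoded); interim <- as4(interim)
  if (!identical(dim(decoded)[1:2], dim(interim)[1:2]))
    stop("decoded and interim grids differ")
  out <- model$refine$fw(cbind4(decoded, interim)) + interim
  clear_caches(model$layers_all)
  out
}

#' Loss bundle for given outputs and targets (inference-style)
#'
#' Convenience wrapper recomputing every loss component from arrays; the
#' weighted total uses the model's configured loss weights.
#' @param model an `xsdnet`. @param seg_p class probabilities.
#' @param rec refined reconstruction. @param mu,logvar,z modality
#'   statistics. @param mu_re re-encoded modality mean.
#' @param target_image,target_mask targets.
#' @return named list of losses (`seg`, `kl`, `modality`, `recon`,
#'   `total`, plus sub-terms).
#' @export
compute_losses <- function(model, seg_p, rec, mu, logvar, z, mu_re,
                           target_image, target_mask) {
  outputs <- list(seg_p = as4(seg_p), mu = mu, lv = logvar, z = z,
                  rec = as4(rec))
  feats_tgt <- perc_features_nograd(model, as4(target_image))
  feats_rec <- perc_features_nograd(model, as4(rec))
  compute_loss_bundle(model, outputs, target_image, target_mask, mu_re,
                      feats_rec, feats_tgt)
}

#' Joint reconstruction and segmentation of interim images
#'
#' @param object a trained `xsdnet`.
#' @param interim one interim magnitude image (matrix) or a list of
#'   them; complex CG-SENSE outputs are accepted (magnitude is taken).
#' @param ... unused.
#' @return for a single image: list `recon`, `seg_prob`, `mask`,
#'   `factors`, `z`, `scale`; for a list input, a list of such results.
#' @export
predict.xsdnet <- function(object, interim, ...) {
  single <- !is.list(interim)
  if (single) interim <- list(interim)
  res <- lapply(interim, function(im) {
    im <- Mod(as.matrix(im))
    nm <- normalize_interim(im)
    out <- xsdnet_forward(object, nm$image, nm$image, train = FALSE)
    clear_caches(object$layers_all)
    mask <- apply(out$seg_p[, , , 1], c(1, 2), which.max) - 1L
    list(recon = out$rec[, , 1, 1] * nm$scale,
         seg_prob = out$seg_p[, , , 1], mask = mask,
         factors = out$a_bin[, , , 1], z = out$z[1, ], scale = nm$scale)
  })
  if (single) res[[1]] else res
}

#' @export
print.xsdnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("xSDNet model (%s): grid %d, %d anatomy factors, z length %d\n",
              if (x$trained) "trained" else "untrained",
              cfg$grid, cfg$n_factors, cfg$zdim))
  cat(sprintf("  U-Net depth %d, base width %d; %s parameters\n",
              cfg$depth, cfg$base_width,
              format(n_params(x$layers_all), big.mark = ",")))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs; final val Dice(LV) %.3f, val NRMSE %.4f\n",
                nrow(x$history), x$history$val_dice_lv[nrow(x$history)],
                x$history$val_nrmse[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.xsdnet <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("\nTraining history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.xsdnet <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$train_total, type = "l", xlab = "epoch",
                 ylab = "training loss (total)", main = "Loss")
  graphics::plot(h$epoch, h$val_dice_lv, type = "l", xlab = "epoch",
                 ylab = "validation LV Dice", ylim = c(0, 1),
                 main = "Validation Dice")
  invisible(x)
}
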