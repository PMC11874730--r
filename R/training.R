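# Training: dataset mixing, augmentation, optimization loop.

#' Compose one training epoch from acquired and simulated pools
#'
#' All samples of the acquired pool (`set2`) are pooled with `n_set1`
#' samples drawn without replacement from the simulated pool, freshly
#' per epoch (seeded by the pair (seed, epoch)), and the union is
#' shuffled.
#'
#' @param set2 list of acquired samples. @param set1_pool list of
#'   simulated samples. @param n_set1 draw size. @param seed root seed.
#' @param epoch epoch number (1-based).
#' @return shuffled list of samples.
#' @export
make_epoch_dataset <- function(set2, set1_pool, n_set1, seed, epoch) {
  if (n_set1 > 0 && length(set1_pool) == 0)
    stop("empty simulated pool with n_set1 > 0")
  if (n_set1 > length(set1_pool) && n_set1 > 0)
    stop(sprintf("n_set1 = %d exceeds pool size %d", n_set1,
                 length(set1_pool)))
  rs <- local_rng(derive_seed(seed, paste0("epoch", epoch)))
  picked <- if (n_set1 > 0) set1_pool[rs$sample(length(set1_pool), n_set1)]
  else list()
  all <- c(set2, picked)
  all[rs$sample(length(all))]
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

#' Random flip / right-angle rotation augmentation
#'
#' Draws a horizontal and/or vertical flip combined with a rotation by
#' an angle in \{0, 90, 180, 270\} degrees and applies the identical
#' transform to the input image, target image and label mask (the
#' transforms are pixel permutations, so label counts are preserved).
#'
#' @param sample list with `input`, `target`, `mask` matrices.
#' @param seed draw seed; pass `transform` to repeat a specific one.
#' @param transform optional list `(flip_h, flip_v, angle)`.
#' @return augmented sample; the transform used is attached as
#'   attribute `"transform"`.
#' @export
augment <- function(sample, seed = 1L, transform = NULL) {
  if (is.null(transform)) {
    rs <- local_rng(derive_seed(seed, "augment"))
    transform <- list(flip_h = rs$runif(1) < 0.5,
                      flip_v = rs$runif(1) < 0.5,
                      angle = c(0, 90, 180, 270)[rs$sample(4, 1)])
  }
  tf <- function(m) {
    if (transform$flip_h) m <- m[, ncol(m):1, drop = FALSE]
    if (transform$flip_v) m <- m[nrow(m):1, , drop = FALSE]
    for (i in seq_len(transform$angle / 90)) m <- rot90cw(m)
    m
  }
  out <- sample
  out$input <- tf(sample$input)
  out$target <- tf(sample$target)
  out$mask <- tf(sample$mask)
  attr(out, "transform") <- transform
  out
}

#' Build a phantom training set of interim/target pairs
#'
#' Mirrors the structure of acquired cine training data: per "subject" a
#' phantom anatomy is drawn (LV size, wall thickness, heart position,
#' tissue contrast), and that subject contributes a complete cine series
#' of `phases_per_subject` uniformly spaced cardiac phases — so
#' end-diastole and end-systole are covered for every geometry.
#' Undersampled spiral raw data are simulated per frame with per-sample
#' random coils and the CG-SENSE interim input is reconstructed. Input
#' and target are normalized jointly by the interim's 99th percentile.
#'
#' @param n total number of samples. @param grid image size.
#' @param seed seed. @param traj trajectory (default: the 13-interleave
#'   design at the phantom field of view). @param n_coils coils.
#' @param noise_level k-space noise fraction.
#' @param phases_per_subject cine frames per drawn anatomy.
#' @return list of samples (`input`, `target`, `mask`, `phase`,
#'   `subject`).
#' @export
make_phantom_training_set <- function(n, grid = 64L, seed = 1L, traj = NULL,
                                      n_coils = 8L, noise_level = 0,
                                      phases_per_subject = 20L) {
  if (is.null(traj)) traj <- design_spiral(grid * 3, 3, n_arms = 13L)
  plan <- nufft_plan(traj, grid)
  rs <- local_rng(derive_seed(seed, "trainset"))
  lapply(seq_len(n), function(i) {
    subj <- (i - 1) %/% phases_per_subject + 1
    rs_s <- local_rng(derive_seed(seed, paste0("subj", subj)))
    r_ed <- 22 + rs_s$runif(1, -6, 10)  # spans apical through basal slices
    efa <- rs_s$runif(1, 0.5, 0.7)      # areal ejection fraction
    cfg <- phantom_config(
      grid = grid, seed = derive_seed(seed, paste0("ph", subj)),
      r_endo_ed_mm = r_ed, r_endo_es_mm = r_ed * sqrt(1 - efa),
      wall_ed_mm = 7 + rs_s$runif(1, -1.5, 2),
      heart_center_mm = c(rs_s$runif(1, -14, 2), rs_s$runif(1, -10, 6)),
      intensities = list(blood = 1,
                         myocardium = 0.25 + rs_s$runif(1, 0, 0.15),
                         fat = 0.75 + rs_s$runif(1, 0, 0.2),
                         tissue = 0.15 + rs_s$runif(1, 0, 0.1)))
    phase <- ((i - 1) %% phases_per_subject) / phases_per_subject
    fr <- phantom_frame(cfg, phase)
    pair <- make_set1_pair(fr, traj, n_coils = n_coils,
                           seed = derive_seed(seed, paste0("coil", i)),
                           plan = plan, noise_level = noise_level)
    nm <- normalize_interim(pair$input)
    list(input = nm$image, target = pair$target / nm$scale, mask = pair$mask,
         phase = phase, subject = subj)
  })
}

batch_arrays <- function(samples) {
  H <- nrow(samples[[1]]$input); B <- length(samples)
  x <- array(0, c(H, H, 1, B)); tg <- x
  mk <- array(0L, c(H, H, 1, B))
  for (i in seq_len(B)) {
    x[, , 1, i] <- samples[[i]]$input
    tg[, , 1, i] <- samples[[i]]$target
    mk[, , 1, i] <- samples[[i]]$mask
  }
  list(x = x, target = tg, mask = mk)
}

snapshot_params <- function(layers) {
  lapply(layers, function(l) lapply(l$param_names, function(p) l[[p]]))
}
restore_params <- function(layers, snap) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (j in seq_along(l$param_names)) l[[l$param_names[j]]] <- snap[[i]][[j]]
  }
  invisible(NULL)
}

#' Fit the joint reconstruction-and-segmentation model
#'
#' Trains with an adaptive-moment (Adam) optimizer on the multi-task
#' loss. Per epoch, the acquired training pool is combined with a fresh
#' draw from the simulated pool ([make_epoch_dataset]) and optionally
#' augmented by random flips / right-angle rotations. Validation Dice
#' and reconstruction error are logged each epoch and the best-
#' validation weights are restored at the end.
#'
#' @param train_data list of samples (`input`, `target`, `mask`).
#' @param val_data validation samples (same structure).
#' @param config an [xsdnet_config].
#' @param epochs,batch_size,lr optimization settings.
#' @param set1_pool optional simulated pool mixed in per epoch.
#' @param n_set1 samples drawn from `set1_pool` each epoch.
#' @param augment_data apply random flip/rotation augmentation.
#' @param warmup_epochs number of initial epochs trained with soft
#'   anatomy factors before switching to hard straight-through
#'   binarization (dense early gradient flow; the inference path is
#'   always binary).
#' @param seed seed for batching, augmentation and the modality draw.
#' @param verbose print a per-epoch line.
#' @return a trained object of class `xsdnet` with `$history`.
#' @export
xsdnet_train <- function(train_data, val_data, config = xsdnet_config(),
                         epochs = 30L, batch_size = 8L, lr = 1e-3,
                         set1_pool = list(), n_set1 = 0L,
                         augment_data = TRUE, warmup_epochs = 2L,
                         seed = 1L, verbose = FALSE) {
  model <- xsdnet_new(config)
  rs <- local_rng(derive_seed(seed, "train"))
  t_glob <- 0L
  hist <- list()
  best <- list(score = -Inf, snap = NULL)
  for (ep in seq_len(epochs)) {
    epd <- make_epoch_dataset(train_data, set1_pool, n_set1, seed, ep)
    if (augment_data)
      epd <- lapply(seq_along(epd), function(i)
        augment(epd[[i]], seed = derive_seed(seed, sprintf("aug%d_%d", ep, i))))
    nb <- ceiling(length(epd) / batch_size)
    ep_losses <- numeric(0)
    for (bi in seq_len(nb)) {
      idx <- ((bi - 1) * batch_size + 1):min(bi * batch_size, length(epd))
      ba <- batch_arrays(epd[idx])
      eps <- matrix(rs$rnorm(length(idx) * config$zdim), length(idx))
      zero_grads(model$layers_all)
      ls <- xsdnet_step(model, ba$x, ba$x, ba$target, ba$mask, eps = eps,
                        hard = ep > warmup_epochs)
      if (!is.finite(ls$total))
        stop(sprintf("non-finite loss at epoch %d, batch %d", ep, bi))
      t_glob <- t_glob + 1L
      adam_step(model$layers_trainable, lr = lr, t = t_glob)
      ep_losses <- c(ep_losses, ls$total)
    }
    vm <- evaluate_xsdnet(model, val_data)
    hist[[ep]] <- data.frame(epoch = ep, train_total = mean(ep_losses),
                             val_dice_lv = vm$dice_lv,
                             val_nrmse = vm$nrmse_refined,
                             val_nrmse_interim = vm$nrmse_interim)
    score <- vm$dice_lv - vm$nrmse_refined
    if (score > best$score)
      best <- list(score = score, snap = snapshot_params(model$layers_trainable))
    if (verbose)
      cat(sprintf("epoch %3d  loss %.4f  val LV Dice %.3f  val NRMSE %.4f\n",
                  ep, mean(ep_losses), vm$dice_lv, vm$nrmse_refined))
  }
  if (!is.null(best$snap)) restore_params(model$layers_trainable, best$snap)
  clear_caches(model$layers_all)
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model
}

#' Evaluate a model on a sample list
#' @param model an `xsdnet`. @param samples list of samples.
#' @return list `dice_lv`, `dice_myo`, `dice_rv`, `nrmse_refined`,
#'   `nrmse_interim`.
#' @export
evaluate_xsdnet <- function(model, samples) {
  dl <- dm <- dr <- nr <- ni <- numeric(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    out <- xsdnet_forward(model, s$input, s$input, train = FALSE)
    clear_caches(model$layers_all)
    mask <- apply(out$seg_p[, , , 1], c(1, 2), which.max) - 1L
    dl[i] <- dice(mask, s$mask, 1L)
    dm[i] <- dice(mask, s$mask, 2L)
    dr[i] <- dice(mask, s$mask, 3L)
    nr[i] <- nrmse(out$rec[, , 1, 1], s$target)
    ni[i] <- nrmse(s$input, s$target)
  }
  list(dice_lv = mean(dl), dice_myo = mean(dm), dice_rv = mean(dr),
       nrmse_refined = mean(nr), nrmse_interim = mean(ni))
}
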