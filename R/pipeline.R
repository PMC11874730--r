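# End-to-end orchestration: simulate -> self-gate -> CG-SENSE -> model
# -> ejection-fraction report. Every stage is timed and logged; frames
# are reconstructed individually (no temporal model), so frame order is
# irrelevant to the result.

#' Run configuration for an end-to-end experiment
#'
#' @param seed single global seed; all module seeds derive from it.
#' @param grid image size. @param mode acquisition mode.
#' @param duration_s acquisition duration per slice (s).
#' @param n_slices short-axis slices. @param n_coils coil elements.
#' @param arrhythmia lognormal RR draws.
#' @param n_phases self-gated phases per RR.
#' @param cg_iters CG-SENSE iterations.
#' @param phantom_overrides named list of [phantom_config] overrides.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, grid = 64L, mode = "freebreathing",
                       duration_s = 5.7, n_slices = 1L, n_coils = 8L,
                       arrhythmia = FALSE, n_phases = 20L, cg_iters = 10L,
                       phantom_overrides = list()) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline on simulated sessions
#'
#' For each slice: simulates a spiral session, estimates coil maps from
#' the temporal-average gridding image, detects cardiac triggers from
#' the DC navigator, reconstructs every real-time frame with CG-SENSE,
#' applies the joint reconstruction-and-segmentation model, builds the
#' LV volume curve and finally reports the ejection fraction across
#' slices.
#'
#' @param config a [run_config]. @param model a trained `xsdnet`.
#' @param use_oracle_masks use the simulator's ground-truth masks
#'   instead of the model segmentation (model may then be `NULL`).
#' @param estimate_coils estimate coil maps from the data (adaptive
#'   method) instead of using the simulator's true maps.
#' @return list of class `spiralcine_run`: `ef` report, `slices` (per
#'   slice: recon frames, masks, volume curve, triggers), `timing` log.
#' @export
run_end_to_end <- function(config, model = NULL,
                           use_oracle_masks = FALSE,
                           estimate_coils = FALSE) {
  if (is.null(model) && !use_oracle_masks)
    stop("stage model: a trained model is required unless use_oracle_masks")
  log <- list()
  tic <- function() Sys.time()
  lap <- function(stage, t0, n = 1L) {
    log[[length(log) + 1]] <<- data.frame(
      stage = stage, seconds = as.numeric(Sys.time() - t0, units = "secs"),
      n = n)
  }
  slices <- vector("list", config$n_slices)
  curves <- vector("list", config$n_slices)
  for (sl in seq_len(config$n_slices)) {
    ph_args <- c(list(grid = config$grid,
                      seed = derive_seed(config$seed, paste0("slice", sl))),
                 config$phantom_overrides)
    # apex-to-base scaling of the LV radius across slices
    if (config$n_slices > 1L) {
      sc <- 0.75 + 0.5 * (sl - 1) / max(1, config$n_slices - 1)
      base_cfg <- do.call(phantom_config, ph_args)
      ph_args$r_endo_ed_mm <- base_cfg$r_endo_ed_mm * sc
      ph_args$r_endo_es_mm <- base_cfg$r_endo_es_mm * sc
    }
    pcfg <- do.call(phantom_config, ph_args)
    t0 <- tic()
    ses <- simulate_session(pcfg, config$mode, config$duration_s,
                            n_coils = config$n_coils,
                            arrhythmia = config$arrhythmia)
    lap("simulate", t0)

    n_pat <- length(ses$truth$frames)
    n_arms <- ses$truth$base_traj$n_arms
    t0 <- tic()
    coils <- if (estimate_coils) {
      avg <- coil_average_images(ses)
      estimate_coils_adaptive(avg, subsample_factor = 2L)
    } else ses$truth$coils
    lap("coils", t0)

    t0 <- tic()
    sig <- extract_dc(ses$kspace)
    trg <- detect_triggers(sig)
    bins <- make_phase_bins(ses$kspace$arm_times, trg,
                            n_phases = config$n_phases)
    lap("selfgate", t0)

    t0 <- tic()
    plans <- new.env()
    recons <- vector("list", n_pat)
    for (p in seq_len(n_pat)) {
      bundle <- subset_bundle(ses$kspace, (p - 1) * n_arms + seq_len(n_arms))
      key <- sprintf("o%d", ses$truth$orient[p])
      if (is.null(plans[[key]]))
        plans[[key]] <- nufft_plan(bundle$traj, config$grid)
      recons[[p]] <- cg_sense(bundle, coils = coils,
                              n_iter = config$cg_iters, plan = plans[[key]])
    }
    lap("cgsense", t0, n_pat)

    t0 <- tic()
    if (use_oracle_masks) {
      masks <- lapply(ses$truth$frames, `[[`, "mask")
      recon_imgs <- lapply(recons, Mod)
    } else {
      pred <- predict(model, recons)
      masks <- lapply(pred, `[[`, "mask")
      recon_imgs <- lapply(pred, `[[`, "recon")
    }
    lap("model", t0, n_pat)

    t0 <- tic()
    times <- vapply(ses$truth$frames, `[[`, 0, "time_s")
    vc <- volume_curve(masks, times, pcfg$px_mm^2, pcfg$slice_mm)
    vc <- detect_extrema(vc)
    curves[[sl]] <- vc
    lap("analysis", t0)
    slices[[sl]] <- list(recons = recon_imgs, masks = masks, curve = vc,
                         triggers = trg, truth = ses$truth)
  }
  ef <- ejection_fraction(curves)
  out <- list(ef = ef, slices = slices,
              timing = do.call(rbind, log), config = config)
  class(out) <- "spiralcine_run"
  out
}

# temporal-average per-coil gridding images (coil map input)
coil_average_images <- function(ses) {
  n <- ses$truth$config$grid
  nc <- dim(ses$kspace$samples)[3]
  plan <- NULL
  acc <- array(0i, c(n, n, nc))
  traj <- ses$kspace$traj
  plan <- nufft_plan(traj, n)
  w <- as.vector(t(density_compensation(traj)))
  for (c in seq_len(nc)) {
    sv <- as.vector(t(ses$kspace$samples[, , c]))
    acc[, , c] <- nufft_apply_adj(plan, sv, w)
  }
  acc
}

#' @export
print.spiralcine_run <- function(x, ...) {
  cat(sprintf("spiralcine run: %d slice(s), mode %s, %.1f s/slice\n",
              x$config$n_slices, x$config$mode, x$config$duration_s))
  cat(sprintf("  EF %.1f%%  (EDV %.1f ml, ESV %.1f ml)\n",
              x$ef$ef_percent, x$ef$edv_ml, x$ef$esv_ml))
  invisible(x)
}

#' Aggregate per-stage timing of a pipeline run
#'
#' @param log timing data.frame of a `spiralcine_run` (or the run
#'   itself).
#' @return data.frame with per-stage mean seconds per frame/call and
#'   totals; empty log gives an empty report.
#' @export
report_timing <- function(log) {
  if (inherits(log, "spiralcine_run")) log <- log$timing
  if (is.null(log) || nrow(log) == 0)
    return(data.frame(stage = character(0), mean_s = numeric(0),
                      mean_s_per_frame = numeric(0), total_s = numeric(0)))
  agg <- do.call(rbind, lapply(split(log, log$stage), function(d)
    data.frame(stage = d$stage[1], mean_s = mean(d$seconds),
               mean_s_per_frame = sum(d$seconds) / sum(d$n),
               total_s = sum(d$seconds))))
  rownames(agg) <- NULL
  agg[order(agg$stage), ]
}
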