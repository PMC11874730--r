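# DC self-gating: navigator extraction, trigger detection, binning,
# segmented assembly and frame-phase matching.

test_that("DC extraction: static object gives a flat detrended series", {
  n <- 32
  tr <- design_spiral(n * 3, 3, n_samples = 60)
  img <- phantom_frame(phantom_config(grid = n, seed = 1), 0)$image
  arms <- do.call(combine_trajectories, list(rep(list(tr), 10)))
  ks <- nufft_forward(img + 0i, NULL, arms,
                      arm_times = (0:(arms$n_arms - 1)) * 3.7e-3)
  sig <- extract_dc(ks)
  expect_equal(length(sig$dc), arms$n_arms)
  expect_lt(stats::sd(sig$dc), 1e-6 * sum(img))
  ks0 <- ks; ks0$samples[] <- 0i
  expect_true(all(extract_dc(ks0, detrend_window_s = 0)$dc == 0))
})

test_that("non-center-out trajectories are rejected for gating", {
  tr <- desk_traj()
  tr$coords[, 1, 1] <- 0.3
  ks <- list(samples = array(1i, c(13, tr$n_samples, 1)),
             arm_times = (0:12) * 3.7e-3, traj = tr)
  class(ks) <- "kspace_bundle"
  expect_error(extract_dc(ks), "center-out")
})

test_that("cardiac pulsation dominates the navigator spectrum", {
  ses <- desk_session("breathhold", duration = 10, seed = 7)
  sig <- extract_dc(ses$kspace)
  # pattern-level signal; spectrum peak should sit near 1/RR = 1 Hz
  sp <- Mod(stats::fft(sig$dc - mean(sig$dc)))
  freqs <- (seq_along(sp) - 1) * sig$fs / length(sp)
  band <- freqs > 0.2 & freqs < 5
  fpk <- freqs[band][which.max(sp[band])]
  rr <- mean(diff(ses$truth$triggers))
  df <- sig$fs / length(sp)
  expect_lt(abs(fpk - 1 / rr), 2 * df + 0.05)
})

test_that("triggers of a synthetic sinusoidal navigator are recovered", {
  fs <- 1 / 0.0481
  tt <- seq(0, 10, by = 1 / fs)
  sig <- structure(list(dc = sin(2 * pi * 1.2 * tt), times = tt, fs = fs),
                   class = "gating_signal")
  trg <- detect_triggers(sig)
  expect_gte(length(trg), 10)
  expect_lte(length(trg), 12)
  expect_lt(abs(stats::median(diff(trg)) - 1 / 1.2), 0.0481)
})

test_that("constant navigators raise an insufficient-heartbeats error", {
  fs <- 20
  sig <- structure(list(dc = rep(1, 100), times = (0:99) / fs, fs = fs),
                   class = "gating_signal")
  expect_error(detect_triggers(sig), "insufficient heartbeats")
})

test_that("arrhythmic RR intervals are recovered within one pattern duration", {
  ses <- desk_session("freebreathing", duration = 12, seed = 11,
                      arrhythmia = TRUE)
  trg <- detect_triggers(extract_dc(ses$kspace))
  rr_true <- diff(ses$truth$triggers)
  rr_det <- diff(trg)
  # align detected triggers to truth by nearest-neighbour matching
  for (i in seq_along(trg)[-length(trg)]) {
    j <- which.min(abs(ses$truth$triggers - trg[i]))
    if (j < length(ses$truth$triggers) && i < length(trg))
      expect_lt(abs(rr_det[i] - rr_true[j]), ses$frame_s + 1e-9)
  }
})

test_that("segmented assembly collects 8 x 13 arms with distinct angles", {
  ses <- desk_session("breathhold", duration = 10, seed = 7)
  trg <- detect_triggers(extract_dc(ses$kspace))
  bins <- make_phase_bins(ses$kspace$arm_times, trg, n_phases = 20)
  seg <- assemble_segmented(ses$kspace, bins, phase = 5, n_heartbeats = 8)
  expect_equal(dim(seg$samples)[1], 104)
  expect_equal(length(unique(round(seg$traj$arm_offsets %% (2 * pi), 9))),
               104)
  expect_error(assemble_segmented(ses$kspace, bins, phase = 5,
                                  n_heartbeats = 50), "heartbeat")
})

test_that("one heartbeat reproduces a single real-time pattern", {
  ses <- desk_session("breathhold", duration = 10, seed = 7)
  trg <- detect_triggers(extract_dc(ses$kspace))
  bins <- make_phase_bins(ses$kspace$arm_times, trg, n_phases = 20)
  seg <- assemble_segmented(ses$kspace, bins, phase = 5, n_heartbeats = 1)
  expect_equal(dim(seg$samples)[1], 13)
  # the 13 arms form one contiguous acquired pattern
  arms <- match(seg$arm_times, ses$kspace$arm_times)
  expect_equal(length(unique((arms - 1) %/% 13)), 1)
})

test_that("arm accounting conserves: assigned + discarded = total", {
  ses <- desk_session("freebreathing", duration = 12, seed = 11,
                      arrhythmia = TRUE)
  trg <- detect_triggers(extract_dc(ses$kspace))
  bins <- make_phase_bins(ses$kspace$arm_times, trg, n_phases = 20)
  asg <- bins$assignment
  n_assigned <- sum(!is.na(asg$phase))
  n_discarded <- sum(is.na(asg$phase))
  expect_equal(n_assigned + n_discarded, length(ses$kspace$arm_times))
  expect_true(all(asg$phase[!is.na(asg$phase)] %in% 0:19))
  expect_true(all(diff(bins$trigger_times) > 0))
})

test_that("segmented reconstruction beats any single-frame reconstruction", {
  # static-phase phantom: contraction disabled so every phase is identical
  cfg <- phantom_config(grid = 64, seed = 13, r_endo_es_mm = 25,
                        r_endo_ed_mm = 25)
  ses <- simulate_session(cfg, "breathhold", duration_s = 10, n_coils = 6)
  trg <- detect_triggers(extract_dc(ses$kspace))
  bins <- make_phase_bins(ses$kspace$arm_times, trg, n_phases = 20)
  seg <- assemble_segmented(ses$kspace, bins, phase = 5, n_heartbeats = 8)
  coils <- ses$truth$coils
  img_seg <- nufft_adjoint(seg, coils, use_dcf = TRUE)
  truth <- ses$truth$frames[[1]]$image
  err_seg <- nrmse(Mod(img_seg), truth)
  one <- spiralcine:::subset_bundle(ses$kspace, 1:13)
  err_one <- nrmse(Mod(nufft_adjoint(one, coils, use_dcf = TRUE)), truth)
  expect_lt(err_seg, err_one)
})

test_that("frames map to the nearest self-gated phase", {
  trg <- c(0, 1, 2, 3)
  bins <- make_phase_bins(seq(0, 3, by = 0.05), trg, n_phases = 20)
  expect_equal(match_frames(1.0, bins), 0L)        # at a trigger
  expect_equal(match_frames(1.5, bins), 10L)       # mid RR
  expect_equal(match_frames(c(0.26), bins), 5L)
})

test_that("matched frames agree with generator phase labels", {
  ses <- desk_session("breathhold", duration = 10, seed = 7)
  trg <- detect_triggers(extract_dc(ses$kspace))
  bins <- make_phase_bins(ses$kspace$arm_times, trg, n_phases = 20)
  times <- vapply(ses$truth$frames, `[[`, 0, "time_s")
  truefrac <- vapply(ses$truth$frames, `[[`, 0, "phase_frac")
  ph <- match_frames(times, bins)
  ok <- !is.na(ph)
  matched_frac <- ph[ok] / bins$n_phases
  # trigger lag shifts the phase origin; compare modulo a constant offset
  d <- (matched_frac - truefrac[ok]) %% 1
  d <- pmin(d, 1 - d)
  off <- stats::median(d)
  dev <- abs(d - off)
  expect_lt(stats::quantile(dev, 0.9, names = FALSE), 1 / (2 * bins$n_phases) + 1e-9)
})
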