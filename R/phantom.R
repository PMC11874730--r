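# Dynamic short-axis cardiac phantom.
#
# Geometry: concentric-circle LV blood pool and myocardium, a crescent-
# shaped RV hugging the epicardium, a body ellipse of soft tissue with a
# subcutaneous fat rim. Contraction between end-diastole and end-systole
# follows a raised-cosine phase law; myocardial cross-section area is
# conserved so the wall thickens in systole. All regions are analytic,
# giving exact ground-truth masks and cavity areas.

#' Configuration for the dynamic cardiac phantom
#'
#' @param grid image matrix size (pixels, even).
#' @param px_mm pixel size (mm); default keeps a 192 mm field of view.
#' @param slice_mm slice thickness (mm).
#' @param r_endo_ed_mm,r_endo_es_mm LV endocardial radius at
#'   end-diastole / end-systole.
#' @param wall_ed_mm myocardial wall thickness at end-diastole.
#' @param rv_offset_frac,rv_radius_frac RV crescent placement and size
#'   relative to the epicardial radius.
#' @param intensities named list of tissue intensities
#'   (blood, myocardium, fat, tissue).
#' @param rr_s mean RR interval (s). @param rr_var Gaussian fractional RR
#'   variability (regular rhythm). @param rr_sdlog lognormal sigma for
#'   arrhythmic RR draws.
#' @param resp_amp_mm,resp_period_s respiratory in-plane translation.
#' @param noise_level complex k-space noise, as a fraction of the mean DC
#'   magnitude.
#' @param heart_center_mm LV center position (mm, image coordinates).
#' @param seed integer seed.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(grid = 128L, px_mm = 192 / grid, slice_mm = 8,
                           r_endo_ed_mm = 25, r_endo_es_mm = 25 * sqrt(0.4),
                           wall_ed_mm = 8,
                           rv_offset_frac = 0.95, rv_radius_frac = 0.85,
                           intensities = list(blood = 1, myocardium = 0.3,
                                              fat = 0.85, tissue = 0.2),
                           rr_s = 1.0, rr_var = 0.03, rr_sdlog = 0.25,
                           resp_amp_mm = 8, resp_period_s = 4,
                           noise_level = 0, heart_center_mm = c(-8, -4),
                           seed = 1L) {
  if (r_endo_es_mm > r_endo_ed_mm) stop("ES radius must not exceed ED radius")
  if (rr_var < 0 || rr_var >= 1) stop("rr_var must be in [0, 1)")
  if (any(unlist(intensities) < 0)) stop("intensities must be >= 0")
  fov <- grid * px_mm
  if (2 * (r_endo_ed_mm + wall_ed_mm) > 0.9 * fov)
    stop("heart geometry exceeds the grid")
  structure(as.list(environment()), class = "phantom_config")
}

contraction <- function(phase_frac) (1 - cos(2 * pi * phase_frac)) / 2

phantom_geometry <- function(config, phase_frac) {
  ctr <- contraction(phase_frac)
  r_en <- config$r_endo_ed_mm -
    (config$r_endo_ed_mm - config$r_endo_es_mm) * ctr
  epi_ed <- config$r_endo_ed_mm + config$wall_ed_mm
  myo_area <- epi_ed^2 - config$r_endo_ed_mm^2   # conserved (times pi)
  r_ep <- sqrt(r_en^2 + myo_area)
  rv_scale <- 1 - 0.25 * ctr
  list(r_endo = r_en, r_epi = r_ep,
       rv_out = config$rv_radius_frac * r_ep * rv_scale,
       rv_cx = -config$rv_offset_frac * r_ep, rv_cy = 0)
}

#' Render one phantom frame at a cardiac phase
#'
#' @param config [phantom_config]. @param phase_frac cardiac phase in
#'   `[0, 1)` (0 = end-diastole). @param time_s time stamp.
#' @param shift_mm in-plane translation (respiration), length-2.
#' @return object of class `phantom_frame`: magnitude `image`, label
#'   `mask` (0 background, 1 LV, 2 myocardium, 3 RV), `time_s`,
#'   `phase_frac`, `lv_area_mm2` (mask-derived) and `r_endo_mm`.
#' @export
phantom_frame <- function(config, phase_frac, time_s = 0,
                          shift_mm = c(0, 0)) {
  g <- phantom_geometry(config, phase_frac)
  n <- config$grid
  px <- config$px_mm
  ax <- (seq_len(n) - (n / 2 + 1)) * px
  X <- matrix(ax, n, n, byrow = TRUE) - shift_mm[1]
  Y <- matrix(ax, n, n) - shift_mm[2]
  cx <- config$heart_center_mm[1]; cy <- config$heart_center_mm[2]
  r2 <- (X - cx)^2 + (Y - cy)^2
  body_a <- 0.46 * config$fov; body_b <- 0.38 * config$fov
  body <- (X / body_a)^2 + (Y / body_b)^2
  rv2 <- (X - cx - g$rv_cx)^2 + (Y - cy - g$rv_cy)^2

  mask <- matrix(0L, n, n)
  mask[body <= 1] <- 4L                                  # soft tissue
  mask[body <= 1 & body >= 0.80] <- 5L                   # fat rim
  mask[rv2 <= g$rv_out^2 & r2 > (1.12 * g$r_epi)^2] <- 3L
  mask[r2 <= g$r_epi^2] <- 2L
  mask[r2 <= g$r_endo^2] <- 1L

  iv <- config$intensities
  lut <- c(0, iv$blood, iv$myocardium, iv$blood, iv$tissue, iv$fat)
  image <- matrix(lut[mask + 1L], n, n)
  image <- smooth3(image)                                # mild partial volume
  mask[mask > 3L] <- 0L
  structure(list(image = image, mask = mask, time_s = time_s,
                 phase_frac = phase_frac,
                 lv_area_mm2 = sum(mask == 1L) * px^2,
                 r_endo_mm = g$r_endo, r_epi_mm = g$r_epi,
                 px_mm = px, slice_mm = config$slice_mm),
            class = "phantom_frame")
}

smooth3 <- function(m) {
  k <- c(0.25, 0.5, 0.25)
  pad <- rbind(m[1, ], m, m[nrow(m), ])
  v <- k[1] * pad[seq_len(nrow(m)), ] + k[2] * pad[seq_len(nrow(m)) + 1, ] +
    k[3] * pad[seq_len(nrow(m)) + 2, ]
  pad2 <- cbind(v[, 1], v, v[, ncol(v)])
  k[1] * pad2[, seq_len(ncol(m))] + k[2] * pad2[, seq_len(ncol(m)) + 1] +
    k[3] * pad2[, seq_len(ncol(m)) + 2]
}

#' Generate a cine series of phantom frames
#'
#' @param config [phantom_config]. @param n_frames number of frames.
#' @param times optional frame times (s); default spans one cardiac
#'   cycle uniformly. @param phases optional explicit phase fractions.
#' @return list of [phantom_frame] objects.
#' @export
generate_cine_phantom <- function(config, n_frames, times = NULL,
                                  phases = NULL) {
  if (is.null(phases)) {
    if (is.null(times)) {
      phases <- (seq_len(n_frames) - 1) / n_frames
      times <- phases * config$rr_s
    } else phases <- (times %% config$rr_s) / config$rr_s
  } else if (is.null(times)) times <- phases * config$rr_s
  lapply(seq_len(n_frames), function(i)
    phantom_frame(config, phases[i], times[i]))
}

#' Simulate one spiral training pair (interim input, clean targets)
#'
#' Pipeline for simulated training data: random coil sensitivities are
#' superimposed on a magnitude frame, undersampled spiral raw data are
#' produced by the forward non-uniform Fourier operator, and the interim
#' network input is obtained by CG-SENSE iterations. Targets are the
#' original frame and its label mask, untouched.
#'
#' @param frame [phantom_frame]. @param traj single-frame spiral
#'   trajectory. @param n_coils coils to simulate. @param seed seed for
#'   the coil draw (vary per sample). @param n_iter CG iterations.
#' @param plan optional shared [nufft_plan] for `traj`.
#' @param noise_level complex k-space noise fraction of mean DC.
#' @return list `input` (interim magnitude), `target` (frame image),
#'   `mask` (frame labels), `coils`.
#' @export
make_set1_pair <- function(frame, traj, n_coils = 8L, seed = 1L,
                           n_iter = 10L, plan = NULL, noise_level = 0) {
  n <- nrow(frame$image)
  coils <- simulate_coils(n, n_coils, seed = seed)
  ks <- nufft_forward(frame$image, coils, traj, plan = plan)
  if (noise_level > 0) {
    rs <- local_rng(derive_seed(seed, "set1noise"))
    dc <- mean(abs(ks$samples[, 1, ]))
    nz <- rs$rnorm(length(ks$samples), sd = noise_level * dc)
    nz2 <- rs$rnorm(length(ks$samples), sd = noise_level * dc)
    ks$samples <- ks$samples + array(complex(real = nz, imaginary = nz2),
                                     dim = dim(ks$samples))
  }
  interim <- cg_sense(ks, traj, coils, n_iter = n_iter, plan = plan)
  list(input = Mod(interim), target = frame$image, mask = frame$mask,
       coils = coils)
}

#' Simulate a full spiral acquisition session
#'
#' Emits spiral arms in acquisition order. The 13-arm pattern is
#' repeated within each heartbeat and rotated to the next largest-gap
#' orientation at the first pattern boundary after each detected R-wave
#' (one orientation per heartbeat). Breath-hold mode uses regular RR
#' intervals with small Gaussian variability; free-breathing mode adds
#' sinusoidal in-plane translation, and arrhythmia is modelled by
#' lognormal RR draws (`arrhythmia = TRUE`).
#'
#' @param config [phantom_config]. @param mode `"breathhold"` or
#'   `"freebreathing"`. @param duration_s acquisition duration (s).
#' @param n_patterns number of rotation-schedule orientations.
#' @param n_coils simulated coil elements. @param arrhythmia draw RR
#'   from a lognormal distribution.
#' @param tr_s repetition time per arm (s). @param n_arms arms/pattern.
#' @return list with `kspace` (a `kspace_bundle` whose trajectory is the
#'   composite of all emitted patterns), `truth` (frames, masks, trigger
#'   times, RR sequence, per-pattern orientation/phase, coils, config)
#'   and `frame_s` (pattern duration).
#' @export
simulate_session <- function(config, mode = c("breathhold", "freebreathing"),
                             duration_s, n_patterns = 8L, n_coils = 8L,
                             arrhythmia = FALSE, tr_s = 3.7e-3,
                             n_arms = 13L) {
  mode <- match.arg(mode)
  frame_s <- n_arms * tr_s
  if (duration_s < 2 * frame_s) stop("duration too short for one frame")
  n_pat <- as.integer(floor(duration_s / frame_s))
  rs <- local_rng(derive_seed(config$seed, "session"))

  # RR sequence covering the duration
  n_beats <- ceiling(duration_s / (config$rr_s * 0.4)) + 2L
  rr <- if (arrhythmia) {
    config$rr_s * rs$rlnorm(n_beats, -config$rr_sdlog^2 / 2, config$rr_sdlog)
  } else {
    config$rr_s * (1 + config$rr_var * rs$rnorm(n_beats))
  }
  rr <- pmax(rr, 3 * frame_s)
  triggers <- c(0, cumsum(rr))
  triggers <- triggers[triggers <= duration_s + max(rr)]
  if (duration_s < rr[1]) stop("duration must cover at least one RR interval")

  offsets <- rotation_schedule(n_patterns, n_arms)
  base <- design_spiral(config$grid * config$px_mm, config$px_mm,
                        n_arms = n_arms, tr_s = tr_s)
  coils <- simulate_coils(config$grid, n_coils,
                          seed = derive_seed(config$seed, "coils"))
  rot <- lapply(offsets, function(o) rotate_trajectory(base, o))
  plans <- lapply(rot, function(t) nufft_plan(t, config$grid))

  pat_t0 <- (seq_len(n_pat) - 1) * frame_s
  beat_of <- findInterval(pat_t0, triggers)            # 1-based heartbeat
  orient <- (beat_of - 1L) %% n_patterns + 1L          # one orientation/beat
  ns <- base$n_samples
  samples <- array(0i, dim = c(n_pat * n_arms, ns, n_coils))
  frames <- vector("list", n_pat)
  for (p in seq_len(n_pat)) {
    tm <- pat_t0[p] + frame_s / 2
    h <- findInterval(tm, triggers)
    phase <- (tm - triggers[h]) / (triggers[h + 1] - triggers[h])
    shift <- c(0, 0)
    if (mode == "freebreathing" && config$resp_amp_mm > 0)
      shift <- c(0, config$resp_amp_mm *
                   sin(2 * pi * tm / config$resp_period_s))
    fr <- phantom_frame(config, phase, time_s = tm, shift_mm = shift)
    frames[[p]] <- fr
    ks <- nufft_forward(fr$image, coils, rot[[orient[p]]],
                        plan = plans[[orient[p]]])
    samples[(p - 1) * n_arms + seq_len(n_arms), , ] <- ks$samples
  }
  if (config$noise_level > 0) {
    dc <- mean(abs(samples[, 1, ]))
    nz <- rs$rnorm(length(samples), sd = config$noise_level * dc)
    nz2 <- rs$rnorm(length(samples), sd = config$noise_level * dc)
    samples <- samples + array(complex(real = nz, imaginary = nz2),
                               dim = dim(samples))
  }
  traj_all <- combine_trajectories(rot[orient])
  arm_times <- rep(pat_t0, each = n_arms) + (seq_len(n_arms) - 1) * tr_s
  ks <- structure(list(samples = samples, arm_times = arm_times,
                       traj = traj_all), class = "kspace_bundle")
  list(kspace = ks, frame_s = frame_s,
       truth = list(frames = frames, triggers = triggers, rr = rr,
                    orient = orient, pattern_t0 = pat_t0, coils = coils,
                    base_traj = base, offsets = offsets, config = config,
                    mode = mode))
}
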