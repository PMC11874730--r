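# DC-signal cardiac self-gating.
#
# Center-out spiral arms re-acquire the k-space center every repetition
# time; the magnitude of that DC sample tracks blood volume in the
# slice and provides a cardiac navigator without ECG.

#' Extract the DC self-gating signal from a k-space bundle
#'
#' Takes the first readout sample of every arm (which must lie at the
#' k-space center), combines coils by root-sum-of-squares and removes a
#' moving-average baseline.
#'
#' @param kspace `kspace_bundle` from a center-out trajectory.
#' @param detrend_window_s moving-average baseline window (s);
#'   `0` disables detrending.
#' @return object of class `gating_signal`: `dc` (per-arm magnitude),
#'   `times` (s), `fs` (Hz).
#' @export
extract_dc <- function(kspace, detrend_window_s = 2) {
  traj <- kspace$traj
  r0 <- sqrt(traj$coords[, 1, 1]^2 + traj$coords[, 1, 2]^2)
  if (any(r0 > 1e-6)) stop("trajectory is not center-out (first sample off-center)")
  dc <- sqrt(apply(abs(kspace$samples[, 1, , drop = FALSE])^2, 1, sum))
  times <- kspace$arm_times
  fs <- 1 / stats::median(diff(times))
  if (detrend_window_s > 0 && length(dc) > 4) {
    w <- max(3L, round(detrend_window_s * fs))
    if (w %% 2L == 0L) w <- w + 1L
    if (w > length(dc)) w <- length(dc) - (1L - length(dc) %% 2L)
    base <- stats::filter(dc, rep(1 / w, w), sides = 2)
    base[is.na(base)] <- mean(dc)
    dc <- dc - as.numeric(base)
  }
  structure(list(dc = as.numeric(dc), times = times, fs = fs),
            class = "gating_signal")
}

#' Detect cardiac triggers in a self-gating signal
#'
#' Zero-phase band-pass filtering (4th-order Butterworth, forward-
#' backward) followed by peak detection with a minimum separation of
#' `0.5 / band[2]` seconds. One trigger per heartbeat is returned.
#'
#' @param signal a `gating_signal`. @param band pass band (Hz).
#' @return numeric vector of trigger times (s).
#' @export
detect_triggers <- function(signal, band = c(0.5, 3)) {
  x <- signal$dc
  fs <- signal$fs
  dur <- diff(range(signal$times))
  if (dur <= 2 / band[1])
    warning("signal shorter than two periods of the lower band edge")
  wn <- pmin(band / (fs / 2), 0.99)
  bf <- signal::butter(2, wn, type = "pass")  # filtfilt doubles the order
  xf <- as.numeric(signal::filtfilt(bf, x - mean(x)))
  if (stats::sd(xf) < 1e-12 * max(1, max(abs(x))))
    stop("insufficient heartbeats: gating signal has no cardiac variation")
  minsep <- max(1L, round(0.5 / band[2] * fs))
  pk <- pracma::findpeaks(xf, minpeakdistance = minsep,
                          minpeakheight = 0.25 * max(xf),
                          peakpat = "[+]{1,}[0]*[-]{1,}")
  if (is.null(pk) || nrow(pk) < 2) stop("insufficient heartbeats: fewer than 2 peaks detected")
  trg <- sort(signal$times[pk[, 2]])
  # forward-backward filtering rings near the record edges; drop peaks there
  margin <- 0.5 / band[2]
  trg <- trg[trg >= signal$times[1] + margin &
               trg <= signal$times[length(signal$times)] - margin]
  if (length(trg) < 2) stop("insufficient heartbeats: fewer than 2 peaks detected")
  trg
}

#' Bin spiral arms into cardiac phases
#'
#' Assigns every arm acquired between two triggers a heartbeat index and
#' a cardiac phase (linear time fraction of the RR interval). Heartbeats
#' whose RR deviates from the median by more than `rr_tol` are discarded
#' as ectopic; arms outside any complete RR interval are discarded too,
#' so that assigned + discarded = total.
#'
#' @param arm_times arm time stamps (s). @param triggers trigger times.
#' @param n_phases number of cardiac phases per RR.
#' @param rr_tol fractional RR tolerance around the median.
#' @return object of class `cardiac_phase_bins` with `trigger_times`,
#'   `n_phases` and `assignment` (data.frame arm/heartbeat/phase, NA for
#'   discarded arms).
#' @export
make_phase_bins <- function(arm_times, triggers, n_phases = 20L,
                            rr_tol = 0.4) {
  if (any(diff(triggers) <= 0)) stop("trigger times must be strictly increasing")
  rr <- diff(triggers)
  ok_beat <- abs(rr - stats::median(rr)) <= rr_tol * stats::median(rr)
  h <- findInterval(arm_times, triggers)
  valid <- h >= 1 & h < length(triggers)
  valid[valid] <- ok_beat[h[valid]]
  phase <- rep(NA_integer_, length(arm_times))
  beat <- rep(NA_integer_, length(arm_times))
  frac <- (arm_times[valid] - triggers[h[valid]]) / rr[h[valid]]
  phase[valid] <- pmin(as.integer(floor(frac * n_phases)), n_phases - 1L)
  beat[valid] <- h[valid]
  structure(list(trigger_times = triggers, n_phases = as.integer(n_phases),
                 assignment = data.frame(arm = seq_along(arm_times),
                                         heartbeat = beat, phase = phase)),
            class = "cardiac_phase_bins")
}

#' Assemble a segmented (multi-heartbeat) k-space for one cardiac phase
#'
#' For the requested phase, collects one complete rotated pattern from
#' each of `n_heartbeats` heartbeats (the pattern whose arms fall in the
#' phase bin), yielding a composite of `n_heartbeats x n_arms` arms with
#' distinct rotation offsets.
#'
#' @param kspace session `kspace_bundle`. @param bins
#'   `cardiac_phase_bins`. @param phase requested phase index (0-based).
#' @param n_heartbeats heartbeats to combine. @param n_arms arms per
#'   pattern.
#' @return composite `kspace_bundle`.
#' @export
assemble_segmented <- function(kspace, bins, phase, n_heartbeats = 8L,
                               n_arms = 13L) {
  asg <- bins$assignment
  pat <- (asg$arm - 1L) %/% n_arms               # pattern index per arm
  cand <- asg[!is.na(asg$phase) & asg$phase == phase, ]
  if (nrow(cand) == 0) stop("no arms in requested phase")
  beats <- sort(unique(cand$heartbeat))
  if (length(beats) < n_heartbeats)
    stop(sprintf("only %d heartbeat(s) available, %d requested",
                 length(beats), n_heartbeats))
  target_frac <- (phase + 0.5) / bins$n_phases
  used_orient <- numeric(0)    # rotation offsets already in the composite
  sel <- integer(0)
  for (hb in beats[seq_len(n_heartbeats)]) {
    # all complete patterns inside this heartbeat are candidates; the one
    # nearest the requested phase (with a not-yet-used rotation) is taken
    pats <- unique(pat[!is.na(asg$heartbeat) & asg$heartbeat == hb])
    opts <- list()
    for (pp in pats) {
      arms <- which(pat == pp)
      if (length(arms) != n_arms) next
      if (any(is.na(asg$heartbeat[arms])) || any(asg$heartbeat[arms] != hb))
        next                                      # pattern must sit in one beat
      tmid <- mean(kspace$arm_times[arms])
      rrh <- diff(bins$trigger_times)[hb]
      fr <- (tmid - bins$trigger_times[hb]) / rrh
      key <- round(min(kspace$traj$arm_offsets[arms]) %% (2 * pi / n_arms), 9)
      opts[[length(opts) + 1]] <- list(arms = arms, key = key,
                                       d = abs(fr - target_frac))
    }
    if (length(opts) == 0) next
    ord <- order(vapply(opts, `[[`, 0, "d"))
    fresh <- ord[!vapply(opts[ord], function(o)
      any(abs(o$key - used_orient) < 1e-9), TRUE)]
    pick <- if (length(fresh)) opts[[fresh[1]]] else opts[[ord[1]]]
    used_orient <- c(used_orient, pick$key)
    sel <- c(sel, pick$arms)
  }
  if (length(sel) < n_heartbeats * n_arms)
    stop(sprintf("only %d complete pattern(s) found for phase %d, %d heartbeats requested",
                 length(sel) / n_arms, phase, n_heartbeats))
  subset_bundle(kspace, sel)
}

subset_bundle <- function(kspace, arm_idx) {
  traj <- kspace$traj
  out_traj <- traj
  out_traj$coords <- traj$coords[arm_idx, , , drop = FALSE]
  out_traj$n_arms <- length(arm_idx)
  out_traj$arm_offsets <- traj$arm_offsets[arm_idx]
  structure(list(samples = kspace$samples[arm_idx, , , drop = FALSE],
                 arm_times = kspace$arm_times[arm_idx], traj = out_traj),
            class = "kspace_bundle")
}

#' Match real-time frames to self-gated cardiac phases
#'
#' Each frame time is converted to a cardiac phase fraction of its RR
#' interval and assigned the self-gated phase whose representative
#' phase-time (`phase / n_phases`) is nearest; ties resolve to the
#' earlier phase.
#'
#' @param frame_times frame mid-times (s). @param bins
#'   `cardiac_phase_bins`.
#' @return integer vector of phase indices (0-based, NA outside RRs).
#' @export
match_frames <- function(frame_times, bins) {
  trg <- bins$trigger_times
  rr <- diff(trg)
  h <- findInterval(frame_times, trg)
  out <- rep(NA_integer_, length(frame_times))
  ok <- h >= 1 & h < length(trg)
  frac <- (frame_times[ok] - trg[h[ok]]) / rr[h[ok]]
  centers <- (seq_len(bins$n_phases) - 1) / bins$n_phases
  out[ok] <- vapply(frac, function(f) {
    d <- abs(f - centers)
    which(d <= min(d) + 1e-12)[1] - 1L     # tie -> earlier phase
  }, 1L)
  out
}
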