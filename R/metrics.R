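# Cardiac function quantification and image/mask quality metrics.

#' Left-ventricular volume of a labelled mask
#'
#' @param mask integer mask (0 background, 1 LV, 2 myocardium, 3 RV).
#' @param pixel_area_mm2 pixel area (mm^2).
#' @param slice_thickness_mm slice thickness (mm).
#' @param label label counted as blood pool.
#' @return volume in ml.
#' @export
mask_volume <- function(mask, pixel_area_mm2, slice_thickness_mm = 8,
                        label = 1L) {
  sum(mask == label) * pixel_area_mm2 * slice_thickness_mm / 1000
}

#' Build a volume curve from a mask series
#'
#' @param masks list of label masks (one per frame).
#' @param times frame times (s).
#' @param pixel_area_mm2,slice_thickness_mm,label as in [mask_volume].
#' @return object of class `volume_curve` (`times`, `volume_ml`;
#'   extrema slots filled by [detect_extrema]).
#' @export
volume_curve <- function(masks, times, pixel_area_mm2,
                         slice_thickness_mm = 8, label = 1L) {
  v <- vapply(masks, mask_volume, 0, pixel_area_mm2 = pixel_area_mm2,
              slice_thickness_mm = slice_thickness_mm, label = label)
  structure(list(times = times, volume_ml = v,
                 maxima = integer(0), minima = integer(0)),
            class = "volume_curve")
}

#' Detect end-diastolic / end-systolic extrema of a volume curve
#'
#' Light smoothing (3-frame moving average) followed by local maximum /
#' minimum detection with a minimum temporal separation; alternation is
#' enforced by dropping the lesser of adjacent same-type extrema.
#'
#' @param curve a `volume_curve`. @param min_separation_s minimum time
#'   between same-type extrema (s).
#' @return the curve with `maxima` / `minima` index slots filled.
#' @export
detect_extrema <- function(curve, min_separation_s = 0.3) {
  v <- curve$volume_ml
  n <- length(v)
  if (n < 3) stop("curve too short for extremum detection")
  vs <- as.numeric(stats::filter(v, rep(1 / 3, 3), sides = 2))
  vs[1] <- v[1]; vs[n] <- v[n]
  dt <- stats::median(diff(curve$times))
  sep <- max(1L, round(min_separation_s / dt))
  mx <- find_extrema(vs, sep, maxima = TRUE)
  mn <- find_extrema(vs, sep, maxima = FALSE)
  if (length(mx) == 0 || length(mn) == 0)
    stop("no extrema found (monotone or flat volume curve)")
  alt <- enforce_alternation(vs, mx, mn)
  curve$maxima <- alt$maxima
  curve$minima <- alt$minima
  curve$smoothed <- vs
  curve
}

find_extrema <- function(v, sep, maxima = TRUE) {
  x <- if (maxima) v else -v
  pk <- pracma::findpeaks(x, minpeakdistance = sep,
                          peakpat = "[+]{1,}[0]*[-]{1,}")
  if (is.null(pk)) return(integer(0))
  sort(pk[, 2])
}

enforce_alternation <- function(v, mx, mn) {
  ev <- rbind(data.frame(i = mx, type = 1L), data.frame(i = mn, type = -1L))
  ev <- ev[order(ev$i), ]
  keep <- rep(TRUE, nrow(ev))
  j <- 1L
  for (k in seq_len(nrow(ev))[-1]) {
    if (ev$type[k] == ev$type[j]) {
      better_k <- if (ev$type[k] == 1L) v[ev$i[k]] > v[ev$i[j]] else
        v[ev$i[k]] < v[ev$i[j]]
      if (better_k) { keep[j] <- FALSE; j <- k } else keep[k] <- FALSE
    } else j <- k
  }
  ev <- ev[keep, ]
  list(maxima = ev$i[ev$type == 1L], minima = ev$i[ev$type == -1L])
}

#' Ejection fraction from per-slice volume curves
#'
#' Per slice, the end-diastolic volume is the median of the detected
#' local maxima and the end-systolic volume the median of the minima
#' (robust across the multiple cardiac cycles covered in real time).
#' Slice volumes are summed and EF = 100 (EDV - ESV) / EDV.
#'
#' @param curves list of `volume_curve` objects (extrema detected; if
#'   missing they are detected with defaults).
#' @return list `ef_percent`, `edv_ml`, `esv_ml`, `per_slice`.
#' @export
ejection_fraction <- function(curves) {
  if (inherits(curves, "volume_curve")) curves <- list(curves)
  per <- lapply(curves, function(cv) {
    if (length(cv$maxima) == 0 || length(cv$minima) == 0)
      cv <- detect_extrema(cv)
    list(ed = stats::median(cv$volume_ml[cv$maxima]),
         es = stats::median(cv$volume_ml[cv$minima]))
  })
  edv <- sum(vapply(per, `[[`, 0, "ed"))
  esv <- sum(vapply(per, `[[`, 0, "es"))
  if (edv <= 0) stop("end-diastolic volume is zero")
  list(ef_percent = 100 * (edv - esv) / edv, edv_ml = edv, esv_ml = esv,
       per_slice = per)
}

#' Dice-Sorensen overlap coefficient
#' @param mask_a,mask_b label masks. @param label label to compare.
#' @return Dice in `[0, 1]`; two empty masks give 1.
#' @export
dice <- function(mask_a, mask_b, label = 1L) {
  a <- mask_a == label; b <- mask_b == label
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Normalized root-mean-square error
#' @param img image to assess. @param ref reference image; normalization
#'   is by the reference value range.
#' @export
nrmse <- function(img, ref) nrmse_range(as.numeric(img), as.numeric(ref))

#' Peak signal-to-noise ratio (dB); identical images give `Inf`
#' @param img,ref images on a common grid.
#' @export
psnr <- function(img, ref) {
  mse <- mean((as.numeric(img) - as.numeric(ref))^2)
  if (mse == 0) return(Inf)
  10 * log10(diff(range(ref))^2 / mse)
}

#' Structural similarity index (mean SSIM, Gaussian 11x11 window)
#' @param img,ref images on a common grid.
#' @param dynamic_range value range `L`; default from the reference.
#' @export
ssim <- function(img, ref, dynamic_range = diff(range(ref))) {
  img <- as.matrix(img); ref <- as.matrix(ref)
  L <- if (dynamic_range > 0) dynamic_range else 1
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  g <- stats::dnorm(seq(-5, 5), sd = 1.5); g <- g / sum(g)
  blur <- function(m) gauss_sep(m, g)
  mu1 <- blur(img); mu2 <- blur(ref)
  s11 <- blur(img * img) - mu1^2
  s22 <- blur(ref * ref) - mu2^2
  s12 <- blur(img * ref) - mu1 * mu2
  smap <- ((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
    ((mu1^2 + mu2^2 + c1) * (s11 + s22 + c2))
  mean(smap)
}

gauss_sep <- function(m, g) {
  # separable filtering with edge replication
  r <- (length(g) - 1) / 2
  n1 <- nrow(m); n2 <- ncol(m)
  pad <- m[c(rep(1, r), seq_len(n1), rep(n1, r)), ]
  v <- matrix(0, n1, n2)
  for (i in seq_along(g)) v <- v + g[i] * pad[(i - 1) + seq_len(n1), ]
  pad2 <- v[, c(rep(1, r), seq_len(n2), rep(n2, r))]
  out <- matrix(0, n1, n2)
  for (i in seq_along(g)) out <- out + g[i] * pad2[, (i - 1) + seq_len(n2)]
  out
}
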