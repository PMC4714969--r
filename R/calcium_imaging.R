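# Ratiometric ciliary Ca2+ pipeline for the SSTR3-mCherry-GCaMP6s sensor:
# masking on the Ca2+-insensitive mCherry channel, background-subtracted
# ratio images, bleed-through estimation and correction, Hill-equation
# calibration against free [Ca2+], and analytic inversion back to [Ca2+].

#' Two-channel fluorescence stack
#'
#' Paired GCaMP6s (green) and mCherry (red) frames with acquisition metadata.
#' Frames are numeric matrices (or 3-D arrays y x x x t) in detector units.
#' Non-sequential scanning (used so that beating cilia occupy the same pixels
#' in both channels) leaks green emission into the red detector, so
#' downstream ratios must be bleed-through corrected.
#'
#' @param green,red Matrices or congruent 3-D arrays of intensities.
#' @param pixel_size_um Pixel size, um.
#' @param frame_interval_s Frame interval, s.
#' @param bit_depth Detector bit depth (8, 12 or 16).
#' @param scan_mode `"non_sequential"` or `"sequential"`.
#' @return Object of class `two_channel_stack`.
#' @export
two_channel_stack <- function(green, red, pixel_size_um, frame_interval_s,
                              bit_depth = 12L,
                              scan_mode = c("non_sequential", "sequential")) {
  scan_mode <- match.arg(scan_mode)
  if (is.matrix(green)) green <- array(green, c(dim(green), 1L))
  if (is.matrix(red)) red <- array(red, c(dim(red), 1L))
  if (!identical(dim(green), dim(red))) {
    stop("green and red stacks must have identical dimensions", call. = FALSE)
  }
  if (!bit_depth %in% c(8L, 12L, 16L)) {
    stop("`bit_depth` must be 8, 12 or 16", call. = FALSE)
  }
  structure(list(green = green, red = red, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 bit_depth = as.integer(bit_depth), scan_mode = scan_mode),
            class = "two_channel_stack")
}

#' Cilium mask from the mCherry channel
#'
#' True where `threshold <= red < saturation_level`: pixels with sensor
#' expression but below detector saturation. mCherry is Ca2+-insensitive, so
#' the mask does not bias the ratio toward high- or low-Ca2+ pixels.
#'
#' @param red_frame Matrix of red-channel intensities.
#' @param threshold Minimum intensity counted as sensor-positive.
#' @param saturation_level Intensity at (or above) which pixels are excluded;
#'   defaults to the bit-depth maximum for `bit_depth` if given.
#' @param bit_depth Optional bit depth used for the default saturation level.
#' @return Logical matrix. Attribute `empty` is TRUE (with a warning) when no
#'   pixel passes.
#' @export
make_cilium_mask <- function(red_frame, threshold, saturation_level = NULL,
                             bit_depth = 12L) {
  if (is.null(saturation_level)) saturation_level <- 2^bit_depth - 1
  if (threshold >= saturation_level) {
    stop("`threshold` must be below `saturation_level`", call. = FALSE)
  }
  mask <- red_frame >= threshold & red_frame < saturation_level
  if (!any(mask)) {
    warning("empty cilium mask: no pixel between threshold and saturation")
    attr(mask, "empty") <- TRUE
  } else {
    attr(mask, "empty") <- FALSE
  }
  mask
}

#' Background-subtracted ratio image
#'
#' Per masked pixel, (G - bg_g) / (R - bg_r). Pixels whose background-
#' subtracted red signal falls at or below a denominator floor (default 1% of
#' the red dynamic range) are dropped (set NA) to avoid ratio blow-up; the
#' number dropped is reported as an attribute.
#'
#' @param stack A [two_channel_stack()] (single frame used unless `frame` given).
#' @param mask Logical matrix from [make_cilium_mask()].
#' @param background_g,background_r Background intensities (scalars, e.g. the
#'   mode of a cilium-free region).
#' @param frame Frame index.
#' @param floor Denominator floor; default `0.01 * 2^bit_depth`.
#' @return Matrix of ratios, NA off-mask and at dropped pixels; attributes
#'   `n_dropped` and `mask_mean` (mean ratio over retained masked pixels).
#' @export
ratio_image <- function(stack, mask, background_g = 0, background_r = 0,
                        frame = 1L, floor = NULL) {
  stopifnot(inherits(stack, "two_channel_stack"))
  if (is.null(floor)) floor <- 0.01 * 2^stack$bit_depth
  g <- stack$green[, , frame] - background_g
  r <- stack$red[, , frame] - background_r
  out <- matrix(NA_real_, nrow(g), ncol(g))
  ok <- mask & r > floor
  n_dropped <- sum(mask & !ok)
  out[ok] <- g[ok] / r[ok]
  if (n_dropped > 0 && n_dropped == sum(mask)) {
    warning("all masked pixels dropped: red signal at or below the denominator floor")
  }
  attr(out, "n_dropped") <- n_dropped
  attr(out, "mask_mean") <- if (any(ok)) mean(out[ok]) else NA_real_
  out
}

#' Bleed-through slope from a red-free specimen
#'
#' With cells expressing GCaMP6s alone, any red-channel signal is green
#' emission leaking into the red detector. An ordinary least-squares line of
#' leak intensity against green intensity gives the bleed-through coefficient
#' alpha (slope), used downstream as a ratio offset.
#'
#' @param green_means Green-channel ROI means (>= 3 values).
#' @param leak_means Red-channel (bleed-through) ROI means, same length.
#' @return List of class `bleedthrough_fit`: `alpha`, `intercept`,
#'   `r_squared`, `n_points`, `alpha_se`.
#' @export
estimate_bleedthrough <- function(green_means, leak_means) {
  if (length(green_means) != length(leak_means) || length(green_means) < 3) {
    stop("need >= 3 paired green/leak observations", call. = FALSE)
  }
  if (stats::sd(green_means) == 0) {
    stop("green intensities are constant; slope is unidentifiable", call. = FALSE)
  }
  fit <- stats::lm(leak_means ~ green_means)
  s <- summary(fit)
  structure(list(alpha = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared,
                 n_points = length(green_means),
                 alpha_se = s$coefficients[2, 2]),
            class = "bleedthrough_fit")
}

#' Bleed-through-corrected ratio
#'
#' A_c = raw ratio - alpha. Negative results are reported, not clamped, so
#' that averaging across cilia stays unbiased.
#'
#' @param raw_ratio Raw F_GCaMP6s / F_mCherry ratio (vector allowed).
#' @param alpha Bleed-through coefficient (>= 0), e.g. from
#'   [estimate_bleedthrough()].
#' @return Corrected ratio A_c.
#' @export
correct_ratio <- function(raw_ratio, alpha) {
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  raw_ratio - alpha
}

#' Hill response curve
#'
#' R(Ca) = R_min + (R_max - R_min) * Ca^n / (EC50^n + Ca^n).
#'
#' @param ca_nM Free calcium, nM.
#' @param hill List or `hill_fit` with `R_min`, `R_max`, `EC50_nM`, `n_H`.
#' @return Predicted ratio.
#' @export
hill_forward <- function(ca_nM, hill) {
  cn <- (ca_nM / hill$EC50_nM)^hill$n_H
  hill$R_min + (hill$R_max - hill$R_min) * cn / (1 + cn)
}

#' Fit the Hill equation to a calibration curve
#'
#' Weighted least squares of corrected ratio against free [Ca2+], with
#' bounds R_min >= 0 and n_H in (0.3, 6). Starting values come from the data
#' range and the log-midpoint of the concentration span.
#'
#' @param free_ca_nM Free calcium levels, nM (>= 5 levels spanning the
#'   transition recommended).
#' @param A_c Corrected ratios, one per level (or per observation).
#' @param weights Optional non-negative fit weights (e.g. 1/SEM^2).
#' @return Object of class `hill_fit`: `R_min`, `R_max`, `EC50_nM`, `n_H`,
#'   `covariance`, `residuals`, `data`.
#' @export
fit_hill <- function(free_ca_nM, A_c, weights = NULL) {
  if (length(free_ca_nM) != length(A_c)) stop("length mismatch", call. = FALSE)
  if (length(unique(free_ca_nM)) < 4) {
    stop("need >= 4 distinct concentration levels to identify 4 parameters",
         call. = FALSE)
  }
  stopifnot_positive(free_ca_nM = free_ca_nM)
  if (is.null(weights)) weights <- rep(1, length(A_c))
  if (diff(range(A_c)) < .Machine$double.eps^0.5 * max(1, abs(mean(A_c)))) {
    warning("flat calibration data: degenerate fit (no dynamic range)")
    return(structure(list(R_min = mean(A_c), R_max = mean(A_c),
                          EC50_nM = NA_real_, n_H = NA_real_,
                          covariance = NULL, residuals = A_c - mean(A_c),
                          data = data.frame(free_ca_nM = free_ca_nM, A_c = A_c,
                                            weight = weights),
                          degenerate = TRUE),
                     class = "hill_fit"))
  }
  o <- order(free_ca_nM)
  rho <- suppressWarnings(stats::cor(log(free_ca_nM), A_c))
  if (any(diff(A_c[o][!duplicated(free_ca_nM[o])]) < 0) && isTRUE(rho < 0.9)) {
    warning("calibration points are not monotone in [Ca2+]")
  }
  start <- list(R_min = max(min(A_c), 1e-6),
                R_max = max(A_c),
                EC50 = exp(mean(log(range(free_ca_nM)))),
                n = 1.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      A_c ~ R_min + (R_max - R_min) * (free_ca_nM / EC50)^n /
        (1 + (free_ca_nM / EC50)^n),
      start = start, weights = weights,
      lower = c(R_min = 0, R_max = 1e-9, EC50 = min(free_ca_nM) / 100, n = 0.3),
      upper = c(R_min = Inf, R_max = Inf, EC50 = max(free_ca_nM) * 100, n = 6),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    stop("Hill fit did not converge: ", conditionMessage(fit), call. = FALSE)
  }
  cf <- stats::coef(fit)
  structure(list(R_min = unname(cf["R_min"]), R_max = unname(cf["R_max"]),
                 EC50_nM = unname(cf["EC50"]), n_H = unname(cf["n"]),
                 covariance = stats::vcov(fit),
                 residuals = as.numeric(stats::resid(fit)),
                 data = data.frame(free_ca_nM = free_ca_nM, A_c = A_c,
                                   weight = weights),
                 degenerate = FALSE),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: R_min = %.4g, R_max = %.4g, EC50 = %.4g nM, n_H = %.3g (n = %d points)\n",
              x$R_min, x$R_max, x$EC50_nM, x$n_H, nrow(x$data)))
  invisible(x)
}

#' Default Hill parameters for the ciliary GCaMP6s/mCherry sensor
#'
#' The published calibration reports only the sensor's operating point
#' (corrected ratio 0.2 at 165 nM free calcium), not the fitted Hill
#' parameters. These defaults pin the curve to that operating point:
#' with R_min = 0.05, R_max = 1.2 and n_H = 2 (GCaMP6s-like cooperativity),
#' the EC50 solving 0.2 = R_min + (R_max - R_min) c/(1 + c) with
#' c = (165/EC50)^n_H is 426 nM, in the range reported for GCaMP6s in situ.
#' Used as the simulation ground truth for calibration studies.
#'
#' @return List: `R_min`, `R_max`, `EC50_nM`, `n_H`.
#' @examples
#' hill_forward(165, sensor_hill_defaults())  # 0.200
#' @export
sensor_hill_defaults <- function() {
  list(R_min = 0.05, R_max = 1.2, EC50_nM = 426, n_H = 2)
}

#' Invert a ratio to free calcium
#'
#' Analytic inversion of the Hill equation:
#' Ca = EC50 * ((A_c - R_min)/(R_max - A_c))^(1/n_H). Only defined strictly
#' inside the sensor's dynamic range (R_min, R_max).
#'
#' @param A_c Corrected ratio(s).
#' @param hill A [fit_hill()] result (or compatible list).
#' @return Free calcium, nM.
#' @export
ratio_to_calcium <- function(A_c, hill) {
  if (any(A_c <= hill$R_min)) {
    stop(sprintf("ratio %.4g at or below R_min = %.4g: below the sensor's dynamic range",
                 min(A_c), hill$R_min), call. = FALSE)
  }
  if (any(A_c >= hill$R_max)) {
    stop(sprintf("ratio %.4g at or above R_max = %.4g: above the sensor's dynamic range",
                 max(A_c), hill$R_max), call. = FALSE)
  }
  hill$EC50_nM * ((A_c - hill$R_min) / (hill$R_max - A_c))^(1 / hill$n_H)
}

#' Normalize a ratio time series to its baseline
#'
#' Divides the ratio trace by R_0, the mean over a baseline window (default:
#' the first frame), giving the conventional R/R_0 display trace.
#'
#' @param time_s Times, s.
#' @param ratio Ratio values, same length.
#' @param baseline_frames Number of initial frames averaged for R_0.
#' @param roi_label Optional ROI label carried through.
#' @return data.frame of class `ratio_timeseries`: `time_s`, `ratio`,
#'   `ratio_norm`; attribute `R0`.
#' @export
normalize_timeseries <- function(time_s, ratio, baseline_frames = 1L,
                                 roi_label = NA_character_) {
  if (length(time_s) != length(ratio)) stop("length mismatch", call. = FALSE)
  if (baseline_frames < 1 || baseline_frames > length(ratio)) {
    stop("`baseline_frames` out of range", call. = FALSE)
  }
  R0 <- mean(ratio[seq_len(baseline_frames)])
  if (!is.finite(R0) || R0 <= 0) {
    stop("baseline ratio R_0 must be positive", call. = FALSE)
  }
  out <- data.frame(time_s = time_s, ratio = ratio, ratio_norm = ratio / R0,
                    roi_label = roi_label)
  attr(out, "R0") <- R0
  class(out) <- c("ratio_timeseries", class(out))
  out
}

#' Build a calibration curve from per-level corrected ratios
#'
#' Aggregates replicate corrected ratios per free-[Ca2+] level into
#' mean +/- SEM and fits the Hill equation to the means (weighted by
#' 1/SEM^2 when replicates are available).
#'
#' @param free_ca_nM Concentration per observation, nM.
#' @param A_c Corrected ratio per observation.
#' @return List of class `calibration_curve`: `table` (free_ca_nM, mean_Ac,
#'   sem, n) and `hill` ([fit_hill()] result).
#' @export
calibration_curve <- function(free_ca_nM, A_c) {
  lev <- sort(unique(free_ca_nM))
  tab <- do.call(rbind, lapply(lev, function(l) {
    v <- A_c[free_ca_nM == l]
    data.frame(free_ca_nM = l, mean_Ac = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v))
  }))
  w <- if (all(is.finite(tab$sem)) && all(tab$sem > 0)) 1 / tab$sem^2 else NULL
  hill <- fit_hill(tab$free_ca_nM, tab$mean_Ac, weights = w)
  structure(list(table = tab, hill = hill), class = "calibration_curve")
}
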