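# Analysis of voltage-clamp current sweeps: leak subtraction, capacitive
# transient parameters (Q, C_m, tau, R_series), I-V curves, single-channel
# amplitude histograms and open probability.

#' A set of voltage-clamp sweeps
#'
#' Container for one recording: a shared time base, a samples x sweeps current
#' matrix in pA, and the command-voltage protocol that produced it.
#'
#' @param time_s Sample times, s (uniformly spaced from 0).
#' @param sweeps_pA Numeric matrix, one column per sweep, `length(time_s)` rows
#'   (a vector is treated as a single sweep).
#' @param protocol List with `holding_mV`, `step_mV` (step amplitude relative
#'   to holding; one value, or one per sweep), `step_on_s`, `step_off_s`.
#' @param sampling_rate_Hz Sampling rate; inferred from `time_s` if missing.
#' @param filter_Hz Hardware filter bandwidth, or `NA` if none recorded.
#' @return Object of class `sweep_set`.
#' @export
sweep_set <- function(time_s, sweeps_pA, protocol,
                      sampling_rate_Hz = NULL, filter_Hz = NA_real_) {
  if (is.vector(sweeps_pA)) sweeps_pA <- matrix(sweeps_pA, ncol = 1L)
  if (nrow(sweeps_pA) != length(time_s)) {
    stop("each sweep must have one sample per time point", call. = FALSE)
  }
  if (is.null(sampling_rate_Hz)) {
    sampling_rate_Hz <- 1 / stats::median(diff(time_s))
  }
  needed <- c("holding_mV", "step_mV", "step_on_s", "step_off_s")
  if (!all(needed %in% names(protocol))) {
    stop("protocol must contain: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (protocol$step_on_s < time_s[1] || protocol$step_off_s > time_s[length(time_s)]) {
    stop("protocol step must lie inside the trace window", call. = FALSE)
  }
  structure(list(time_s = time_s, sweeps_pA = sweeps_pA, protocol = protocol,
                 sampling_rate_Hz = sampling_rate_Hz, filter_Hz = filter_Hz),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("Sweep set: %d sweeps x %d samples @ %.4g kHz; step %+g mV (%g-%g s)\n",
              ncol(x$sweeps_pA), nrow(x$sweeps_pA), x$sampling_rate_Hz / 1000,
              x$protocol$step_mV[1], x$protocol$step_on_s, x$protocol$step_off_s))
  invisible(x)
}

step_index <- function(time_s, protocol) {
  which(time_s >= protocol$step_on_s & time_s < protocol$step_off_s)
}

# mean current over the final `frac` of the step window
steady_state_current <- function(time_s, trace, protocol, frac = 0.2) {
  idx <- step_index(time_s, protocol)
  tail_idx <- idx[time_s[idx] >= protocol$step_off_s -
                    frac * (protocol$step_off_s - protocol$step_on_s)]
  mean(trace[tail_idx])
}

#' P/N-style leak subtraction
#'
#' Removes passive (linear) current components from a test sweep using
#' current responses to hyperpolarizing leak steps: the leak responses are
#' summed, inverted, scaled by `dV_test / (n * |dV_leak|)` and subtracted
#' from the test sweep. For a purely linear circuit the corrected trace is
#' identically zero (to the noise floor), leaving only active currents.
#'
#' @param test_sweep_pA Current response to the depolarizing test step, pA.
#' @param leak_sweeps_pA Matrix (or vector for one) of current responses to
#'   the hyperpolarizing leak step, aligned to the same step onset.
#' @param dV_test_mV Test step amplitude, mV (> 0).
#' @param dV_leak_mV Leak step amplitude, mV (< 0; opposite sign to test).
#' @return Leak-subtracted current trace, pA.
#' @export
subtract_leak <- function(test_sweep_pA, leak_sweeps_pA, dV_test_mV, dV_leak_mV) {
  if (is.vector(leak_sweeps_pA)) leak_sweeps_pA <- matrix(leak_sweeps_pA, ncol = 1L)
  if (nrow(leak_sweeps_pA) != length(test_sweep_pA)) {
    stop("leak sweeps must match the test sweep length", call. = FALSE)
  }
  if (sign(dV_test_mV) == sign(dV_leak_mV) || dV_test_mV == 0 || dV_leak_mV == 0) {
    stop("test and leak steps must be non-zero and of opposite sign", call. = FALSE)
  }
  summed <- rowSums(leak_sweeps_pA)
  scale <- dV_test_mV / (ncol(leak_sweeps_pA) * abs(dV_leak_mV))
  test_sweep_pA - scale * (-summed)
}

#' Capacitive-transient analysis
#'
#' Extracts charge, membrane capacitance, charging time constant and series
#' resistance from the capacitive current evoked by a (hyperpolarizing)
#' voltage step. Sweeps are averaged, the steady-state current (mean of the
#' final 20% of the step) is subtracted, the transient is integrated
#' (trapezoidal rule, step onset to step end) to give the transferred charge
#' Q, and a single exponential is fitted from the transient extremum to the
#' step end to give tau. Then C_m = Q/|dV| and R_series = tau/C_m.
#'
#' @param sweeps A [sweep_set()] whose protocol is a single voltage step.
#' @param dV_mV Step amplitude, mV; taken from the protocol if missing.
#' @param n_average Number of sweeps to average (default: all).
#' @param steady_frac Fraction of the step used for the steady-state estimate.
#' @return List of class `transient_fit` with `Q_pC`, `C_m_pF`, `tau_ms`,
#'   `R_series_MOhm`, `steady_state_pA`, `fit_rmse_pA`, `degenerate` flag.
#' @export
analyze_capacitive_transient <- function(sweeps, dV_mV = NULL, n_average = NULL,
                                         steady_frac = 0.2) {
  stopifnot(inherits(sweeps, "sweep_set"))
  p <- sweeps$protocol
  if (is.null(dV_mV)) dV_mV <- p$step_mV[1]
  if (is.null(n_average)) n_average <- ncol(sweeps$sweeps_pA)
  if (n_average > ncol(sweeps$sweeps_pA)) {
    stop("`n_average` exceeds the number of sweeps", call. = FALSE)
  }
  tr <- rowMeans(sweeps$sweeps_pA[, seq_len(n_average), drop = FALSE])
  t <- sweeps$time_s
  idx <- step_index(t, p)
  baseline <- mean(tr[t < p$step_on_s])
  if (!is.finite(baseline)) baseline <- 0
  ss <- steady_state_current(t, tr, p, steady_frac)
  trans <- tr[idx] - ss
  tt <- t[idx]

  Q_pC <- sum(diff(tt) * (head(trans, -1) + tail(trans, -1)) / 2)  # pA*s = pC
  C_m_pF <- 1000 * abs(Q_pC) / abs(dV_mV)                          # pC/mV = nF

  peak_rel <- which.max(abs(trans))
  amp0 <- trans[peak_rel]
  degenerate <- abs(amp0) < .Machine$double.eps^0.5
  if (!degenerate && sign(amp0) > 0 && dV_mV < 0) {
    warning("positive-going transient on a hyperpolarizing step; check polarity")
  }

  tau_ms <- NA_real_; rmse <- NA_real_
  if (!degenerate) {
    tf <- tt[peak_rel:length(tt)] - tt[peak_rel]
    yf <- trans[peak_rel:length(trans)]
    tau0 <- if (C_m_pF > 0) {
      # seed from the charge: Q = amp * tau for a single exponential
      max(abs(Q_pC / amp0), diff(tt)[1])
    } else diff(range(tf)) / 5
    fit <- tryCatch(
      minpack.lm::nlsLM(yf ~ a * exp(-tf / tau), start = list(a = amp0, tau = tau0),
                        lower = c(a = -Inf, tau = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      stop("transient exponential fit failed: ", conditionMessage(fit), call. = FALSE)
    }
    tau_ms <- stats::coef(fit)[["tau"]] * 1000
    rmse <- sqrt(mean(stats::resid(fit)^2))
  }

  R_series_MOhm <- if (is.finite(tau_ms) && C_m_pF > 0) 1000 * tau_ms / C_m_pF else NA_real_
  structure(list(Q_pC = abs(Q_pC), C_m_pF = C_m_pF, tau_ms = tau_ms,
                 R_series_MOhm = R_series_MOhm, steady_state_pA = ss,
                 fit_rmse_pA = rmse, n_averaged = n_average,
                 degenerate = isTRUE(degenerate) || C_m_pF == 0),
            class = "transient_fit")
}

#' @export
print.transient_fit <- function(x, ...) {
  cat(sprintf("Capacitive transient: Q = %.4g pC, C_m = %.4g pF, tau = %.4g ms, R_series = %.4g MOhm (rmse %.3g pA, n = %d)\n",
              x$Q_pC, x$C_m_pF, x$tau_ms, x$R_series_MOhm, x$fit_rmse_pA, x$n_averaged))
  invisible(x)
}

#' Current-voltage relation across recordings
#'
#' Builds a mean +/- SEM I-V curve from one or more recordings sharing the
#' same voltage-step ladder. Steady-state mode averages the final 20% of each
#' step; peak mode takes the signed extremum within the step.
#'
#' @param recordings List of [sweep_set()] objects; within each, sweep `i`
#'   corresponds to `protocol$step_mV[i]` (relative to holding).
#' @param mode `"steady_state"` or `"peak"`.
#' @param steady_frac Fraction of the step used in steady-state mode.
#' @return data.frame of class `iv_curve`: `voltage_mV` (absolute command),
#'   `current_pA`, `sem_pA`, `n`.
#' @export
build_iv <- function(recordings, mode = c("steady_state", "peak"),
                     steady_frac = 0.2) {
  mode <- match.arg(mode)
  if (inherits(recordings, "sweep_set")) recordings <- list(recordings)
  ladder <- recordings[[1]]$protocol$step_mV
  for (r in recordings) {
    if (!isTRUE(all.equal(r$protocol$step_mV, ladder))) {
      stop("all recordings must share the same voltage-step ladder", call. = FALSE)
    }
  }
  per_rec <- vapply(recordings, function(r) {
    idx <- step_index(r$time_s, r$protocol)
    vapply(seq_len(ncol(r$sweeps_pA)), function(i) {
      tr <- r$sweeps_pA[, i]
      if (mode == "steady_state") {
        steady_state_current(r$time_s, tr, r$protocol, steady_frac)
      } else {
        seg <- tr[idx]
        seg[which.max(abs(seg))]
      }
    }, numeric(1))
  }, numeric(length(ladder)))
  per_rec <- matrix(per_rec, nrow = length(ladder))
  n <- ncol(per_rec)
  out <- data.frame(
    voltage_mV = recordings[[1]]$protocol$holding_mV + ladder,
    current_pA = rowMeans(per_rec),
    sem_pA = if (n > 1) apply(per_rec, 1, stats::sd) / sqrt(n) else NA_real_,
    n = n
  )
  out <- out[order(out$voltage_mV), ]
  rownames(out) <- NULL
  class(out) <- c("iv_curve", class(out))
  out
}

#' Zero-phase Gaussian low-pass filter
#'
#' Smooths a trace with a unit-DC-gain Gaussian kernel whose -3 dB cutoff is
#' `cutoff_Hz` (sigma_t = sqrt(ln 2) / (2 pi f_c)). Symmetric convolution with
#' edge replication, so no phase shift is introduced.
#'
#' @param trace Numeric vector.
#' @param cutoff_Hz Cutoff frequency; must be below Nyquist.
#' @param sampling_rate_Hz Sampling rate of `trace`.
#' @return Filtered trace, same length.
#' @export
offline_filter <- function(trace, cutoff_Hz, sampling_rate_Hz) {
  if (cutoff_Hz >= sampling_rate_Hz / 2) {
    stop("`cutoff_Hz` must be below the Nyquist frequency", call. = FALSE)
  }
  sigma_s <- sqrt(log(2)) / (2 * pi * cutoff_Hz)
  sigma_n <- sigma_s * sampling_rate_Hz
  half <- max(1L, ceiling(4 * sigma_n))
  k <- exp(-0.5 * ((-half:half) / sigma_n)^2)
  k <- k / sum(k)
  padded <- c(rep(trace[1], half), trace, rep(trace[length(trace)], half))
  out <- stats::filter(padded, k, sides = 2)
  as.numeric(out[(half + 1):(half + length(trace))])
}

#' Amplitude histogram of current samples
#'
#' All-point mode bins every sample; open-point mode keeps only samples whose
#' deviation from baseline exceeds `fraction` of the full single-channel
#' amplitude (same sign as `full_amplitude_pA`), the conventional criterion
#' for resolving the open-level distribution.
#'
#' @param traces Numeric vector or matrix of baseline-subtracted current, pA.
#' @param mode `"all_point"` or `"open_point"`.
#' @param bin_width_pA Histogram bin width, pA (> 0).
#' @param full_amplitude_pA Full single-channel amplitude (required for
#'   open-point mode), pA.
#' @param fraction Fractional-amplitude threshold for open points.
#' @param baseline_pA Baseline current level, pA.
#' @return List of class `amplitude_histogram`: `bin_centers_pA`, `counts`,
#'   `mode`, `threshold_pA` (open-point only).
#' @export
amplitude_histogram <- function(traces, mode = c("all_point", "open_point"),
                                bin_width_pA = 0.05, full_amplitude_pA = NULL,
                                fraction = 0.9, baseline_pA = 0) {
  mode <- match.arg(mode)
  if (bin_width_pA <= 0) stop("`bin_width_pA` must be > 0", call. = FALSE)
  x <- as.numeric(traces)
  threshold <- NULL
  if (mode == "open_point") {
    if (is.null(full_amplitude_pA)) {
      stop("open-point mode requires `full_amplitude_pA`", call. = FALSE)
    }
    threshold <- baseline_pA + fraction * full_amplitude_pA
    dev <- (x - baseline_pA) * sign(full_amplitude_pA)
    x <- x[dev >= fraction * abs(full_amplitude_pA)]
  }
  if (!length(x)) {
    return(structure(list(bin_centers_pA = numeric(0), counts = integer(0),
                          mode = mode, threshold_pA = threshold),
                     class = "amplitude_histogram"))
  }
  lo <- floor(min(x) / bin_width_pA) * bin_width_pA
  hi <- ceiling(max(x) / bin_width_pA) * bin_width_pA
  if (hi <= lo) hi <- lo + bin_width_pA
  breaks <- seq(lo - bin_width_pA / 2, hi + bin_width_pA / 2, by = bin_width_pA)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  structure(list(bin_centers_pA = h$mids, counts = h$counts, mode = mode,
                 threshold_pA = threshold),
            class = "amplitude_histogram")
}

#' Single-channel open probability
#'
#' P_o estimated by time-averaging baseline-subtracted, leak-free current over
#' a window and dividing by the unitary amplitude: the fraction of time the
#' channel conducts. Estimates outside [0, 1] (multi-channel patches,
#' baseline drift) are reported clamped with a warning.
#'
#' @param sweeps A [sweep_set()] of baseline-subtracted current.
#' @param i_single_pA Unitary current amplitude, pA (non-zero; same sign as
#'   the openings).
#' @param window_s Length-2 numeric `(start, end)` in seconds; defaults to the
#'   protocol step window.
#' @return Estimated open probability in [0, 1].
#' @export
open_probability <- function(sweeps, i_single_pA, window_s = NULL) {
  stopifnot(inherits(sweeps, "sweep_set"))
  if (i_single_pA == 0) stop("`i_single_pA` must be non-zero", call. = FALSE)
  t <- sweeps$time_s
  if (is.null(window_s)) {
    window_s <- c(sweeps$protocol$step_on_s, sweeps$protocol$step_off_s)
  }
  if (window_s[1] < t[1] || window_s[2] > t[length(t)] || window_s[2] <= window_s[1]) {
    stop("`window_s` must lie inside the trace", call. = FALSE)
  }
  idx <- which(t >= window_s[1] & t < window_s[2])
  p <- mean(sweeps$sweeps_pA[idx, ]) / i_single_pA
  if (p < 0 || p > 1) {
    warning(sprintf("raw P_o estimate %.3g outside [0, 1]; clamped (multi-channel patch or baseline error?)", p))
    p <- min(max(p, 0), 1)
  }
  p
}
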