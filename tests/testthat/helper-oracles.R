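# Independent oracles used to validate the closed-form implementations.

# Brute-force explicit-Euler integration of the series-R / parallel-RC
# circuit (SI units), interpolated onto `times`. Step size adapts to the
# circuit time constant. Returns current in pA relative to holding.
rc_euler_oracle <- function(circuit, protocol, times) {
  Rs <- circuit$r_series_MOhm * 1e6
  Rm <- circuit$r_m_MOhm * 1e6
  C <- circuit$c_m_pF * 1e-12
  tau <- C * if (is.infinite(Rm)) Rs else Rs * Rm / (Rs + Rm)
  # integer substep grid: dt divides the sampling interval exactly and the
  # step edges are placed by index, so both solutions see the discontinuity
  # at the same instant
  dt_samp <- stats::median(diff(times))
  n_sub <- max(1L, ceiling(dt_samp / (tau / 2000)))
  dt <- dt_samp / n_sub
  m <- (length(times) - 1L) * n_sub + 1L
  i_on <- round(protocol$step_on_s / dt) + 1L
  i_off <- round(protocol$step_off_s / dt) + 1L
  vcmd <- numeric(m)
  vcmd[i_on:min(m, i_off - 1L)] <- protocol$step_mV * 1e-3
  vc <- numeric(m)
  g_m <- if (is.infinite(Rm)) 0 else 1 / Rm
  for (i in 2:m) {
    vc[i] <- vc[i - 1] + dt * ((vcmd[i - 1] - vc[i - 1]) / Rs -
                                 vc[i - 1] * g_m) / C
  }
  keep <- seq(1L, m, by = n_sub)
  (vcmd[keep] - vc[keep]) / Rs / 1e-12
}

# default two-state gating model with stationary open probability p
gating_for_po <- function(p, total_rate = 500, i_single = 1.4, n_channels = 1L) {
  gating_model(open_rate_per_s = p * total_rate,
               close_rate_per_s = (1 - p) * total_rate,
               i_single_pA = i_single, n_channels = n_channels)
}

# measure one calibration level: mask on red, background-subtracted ratio,
# bleed-through correction
measure_level <- function(stack, alpha, background, threshold = 200) {
  m <- make_cilium_mask(stack$red[, , 1], threshold = threshold,
                        bit_depth = stack$bit_depth)
  ri <- ratio_image(stack, m, background_g = background, background_r = background)
  correct_ratio(attr(ri, "mask_mean"), alpha)
}

hill_truth_default <- list(R_min = 0.05, R_max = 1.2, EC50_nM = 300, n_H = 2)
# a second truth set, pinned to the sensor's published operating point
# (ratio 0.2 at 165 nM), is available as ciliaphys::sensor_hill_defaults()
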