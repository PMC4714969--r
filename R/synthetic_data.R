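# Seeded synthetic-data generators. Each generator is an explicit forward
# model of what the corresponding analysis assumes (RC circuit, two-state
# Markov gating, Hill-governed two-channel fluorescence, beating kymographs,
# Ca2+ fronts, drifting beads) and returns the data together with a
# machine-readable ground-truth record, so every pipeline stage can be
# validated without raw recordings.

#' Simulation configuration
#'
#' Master seed and noise model shared by the generators. Identical configs
#' give bit-identical output. Each generated artifact draws from its own RNG
#' stream derived from the master seed by a fixed per-generator offset plus a
#' caller-supplied counter, so adding a generator call never perturbs the
#' streams of existing ones.
#'
#' @param seed Master integer seed.
#' @param current_noise_pA RMS of the additive Gaussian current noise, pA
#'   (at the simulated bandwidth).
#' @param photon_gain Counts per photon for the Poisson shot-noise stage of
#'   image generation.
#' @param read_noise_sd Gaussian read noise SD, counts.
#' @param geometry Default [cilium_geometry()].
#' @param pixel_size_um Default image pixel size, um.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, current_noise_pA = 1, photon_gain = 1,
                       read_noise_sd = 2, geometry = cilium_geometry(),
                       pixel_size_um = 0.1) {
  structure(list(seed = as.integer(seed), current_noise_pA = current_noise_pA,
                 photon_gain = photon_gain, read_noise_sd = read_noise_sd,
                 geometry = geometry, pixel_size_um = pixel_size_um),
            class = "sim_config")
}

# per-artifact stream seed; double arithmetic stays exact below 2^53 and the
# result is reduced below 2^31 - 1
stream_seed <- function(cfg, offset, counter = 0L) {
  as.integer((abs(as.numeric(cfg$seed)) * 2654435 + offset * 97 + counter) %%
               2147483647)
}

#' Two-state gating model for a voltage-gated channel
#'
#' Open/close rates of a two-state Markov channel; the stationary open
#' probability is open_rate / (open_rate + close_rate).
#'
#' @param open_rate_per_s,close_rate_per_s Transition rates, 1/s (> 0).
#' @param i_single_pA Unitary current, pA.
#' @param n_channels Number of independent channels in the patch.
#' @return Object of class `gating_model` with a `p_open` element.
#' @export
gating_model <- function(open_rate_per_s, close_rate_per_s, i_single_pA = 1.4,
                         n_channels = 1L) {
  stopifnot_positive(open_rate_per_s = open_rate_per_s,
                     close_rate_per_s = close_rate_per_s)
  structure(list(open_rate_per_s = open_rate_per_s,
                 close_rate_per_s = close_rate_per_s,
                 i_single_pA = i_single_pA, n_channels = as.integer(n_channels),
                 p_open = open_rate_per_s / (open_rate_per_s + close_rate_per_s)),
            class = "gating_model")
}

#' Boltzmann activation model for a macroscopic Ca_V conductance
#'
#' Steady-state activation 1/(1 + exp(-(V - V_half)/slope)), first-order
#' approach with time constant `activation_tau_ms`, ohmic driving force
#' toward `e_rev_mV`.
#'
#' @param g_max_nS Maximal conductance, nS.
#' @param v_half_mV Half-activation voltage, mV.
#' @param slope_mV Activation slope factor, mV (> 0).
#' @param e_rev_mV Reversal potential, mV.
#' @param activation_tau_ms Activation time constant, ms.
#' @return Object of class `cav_activation_model`.
#' @export
cav_activation_model <- function(g_max_nS = 3, v_half_mV = -10, slope_mV = 6,
                                 e_rev_mV = 60, activation_tau_ms = 2) {
  stopifnot_positive(slope_mV = slope_mV, activation_tau_ms = activation_tau_ms)
  if (g_max_nS < 0) stop("`g_max_nS` must be >= 0", call. = FALSE)
  structure(list(g_max_nS = g_max_nS, v_half_mV = v_half_mV,
                 slope_mV = slope_mV, e_rev_mV = e_rev_mV,
                 activation_tau_ms = activation_tau_ms),
            class = "cav_activation_model")
}

# exact linear response of the series-R / parallel-RC circuit to a voltage
# step of dV (mV) applied at t0: current in pA at times t (s).
rc_step_response <- function(t, t0, dV_mV, circuit) {
  rs <- circuit$r_series_MOhm; rm <- circuit$r_m_MOhm; cm <- circuit$c_m_pF
  tau_s <- clamp_time_constant(circuit) / 1000
  i_ss <- if (is.infinite(rm)) 0 else dV_mV / (rs + rm) * 1000   # mV/MOhm = nA -> pA
  i_0 <- dV_mV / rs * 1000
  out <- numeric(length(t))
  after <- t >= t0
  out[after] <- i_ss + (i_0 - i_ss) * exp(-(t[after] - t0) / tau_s)
  out
}

#' Simulate a capacitive-transient voltage-clamp recording
#'
#' Exact piecewise-exponential solution of the access-resistor + parallel
#' R_m/C_m circuit for a rectangular voltage step (step-on and step-off
#' responses superposed; the circuit is linear), plus seeded Gaussian current
#' noise. Currents are relative to the holding steady state.
#'
#' @param circuit An [equivalent_circuit()].
#' @param protocol List: `holding_mV`, `step_mV`, `step_on_s`, `step_off_s`.
#' @param n_sweeps Number of independent noisy sweeps.
#' @param cfg A [sim_config()].
#' @param sampling_rate_Hz Sampling rate (capacitive currents are typically
#'   digitised fast; default 50 kHz).
#' @param duration_s Trace duration; default pads 20% around the step.
#' @param counter Stream counter distinguishing repeated calls.
#' @return A [sweep_set()] with attribute `truth` (circuit parameters and the
#'   noiseless trace).
#' @export
simulate_patch_recording <- function(circuit, protocol, n_sweeps = 100,
                                     cfg = sim_config(),
                                     sampling_rate_Hz = 50000,
                                     duration_s = NULL, counter = 0L) {
  stopifnot(inherits(circuit, "equivalent_circuit"))
  if (is.null(duration_s)) {
    duration_s <- protocol$step_off_s + 0.2 * (protocol$step_off_s - protocol$step_on_s)
  }
  t <- seq(0, duration_s, by = 1 / sampling_rate_Hz)
  clean <- rc_step_response(t, protocol$step_on_s, protocol$step_mV, circuit) +
    rc_step_response(t, protocol$step_off_s, -protocol$step_mV, circuit)
  sweeps <- with_seed(stream_seed(cfg, 1L, counter), {
    matrix(stats::rnorm(length(t) * n_sweeps, sd = cfg$current_noise_pA),
           ncol = n_sweeps) + clean
  })
  ss <- sweep_set(t, sweeps, protocol, sampling_rate_Hz = sampling_rate_Hz)
  attr(ss, "truth") <- list(
    c_m_pF = circuit$c_m_pF, r_series_MOhm = circuit$r_series_MOhm,
    r_m_MOhm = circuit$r_m_MOhm, tau_ms = clamp_time_constant(circuit),
    Q_pC = abs(circuit$c_m_pF * protocol$step_mV) / 1000 *
      (if (is.infinite(circuit$r_m_MOhm)) 1 else
        (circuit$r_m_MOhm / (circuit$r_m_MOhm + circuit$r_series_MOhm))^2),
    clean_trace_pA = clean)
  ss
}

#' Simulate a single-channel patch recording
#'
#' Continuous-time two-state Markov gating per channel (exponential dwell
#' times, stationary initial state), summed over channels, scaled by the
#' unitary amplitude, with seeded Gaussian noise.
#'
#' @param gating A [gating_model()].
#' @param pulse_duration_s Duration of each sweep, s.
#' @param n_sweeps Number of sweeps.
#' @param cfg A [sim_config()].
#' @param sampling_rate_Hz Sampling rate (default 20 kHz).
#' @param noise_sd_pA Noise SD; default a fifth of the unitary amplitude so
#'   that open and closed levels remain resolvable.
#' @param counter Stream counter.
#' @return A [sweep_set()] (protocol: a 0 mV test pulse spanning the sweep)
#'   with attribute `truth` (`p_open`, per-sweep occupancy fraction).
#' @export
simulate_single_channel <- function(gating, pulse_duration_s = 0.4,
                                    n_sweeps = 9, cfg = sim_config(),
                                    sampling_rate_Hz = 20000,
                                    noise_sd_pA = NULL, counter = 0L) {
  stopifnot(inherits(gating, "gating_model"))
  dt <- 1 / sampling_rate_Hz
  mean_dwell <- 1 / max(gating$open_rate_per_s, gating$close_rate_per_s)
  if (mean_dwell < 5 * dt) {
    warning("mean dwell time < 5 samples: gating under-resolved at this sampling rate")
  }
  if (is.null(noise_sd_pA)) noise_sd_pA <- abs(gating$i_single_pA) / 5
  n <- round(pulse_duration_s * sampling_rate_Hz)
  t <- (seq_len(n) - 1L) * dt
  sim <- with_seed(stream_seed(cfg, 2L, counter), {
    occ <- matrix(0, n, n_sweeps)
    for (s in seq_len(n_sweeps)) {
      for (ch in seq_len(gating$n_channels)) {
        state <- stats::runif(1) < gating$p_open  # stationary start
        tt <- 0
        while (tt < pulse_duration_s) {
          rate <- if (state) gating$close_rate_per_s else gating$open_rate_per_s
          dwell <- stats::rexp(1, rate)
          if (state) {
            # sample j (time (j-1) dt) is open iff tt <= (j-1) dt < tt + dwell
            i0 <- ceiling(tt / dt + 1)
            i1 <- min(n, ceiling((tt + dwell) / dt + 1) - 1L)
            if (i1 >= i0) occ[i0:i1, s] <- occ[i0:i1, s] + 1
          }
          tt <- tt + dwell
          state <- !state
        }
      }
    }
    noise <- matrix(stats::rnorm(n * n_sweeps, sd = noise_sd_pA), ncol = n_sweeps)
    list(occ = occ, noise = noise)
  })
  sweeps <- sim$occ * gating$i_single_pA + sim$noise
  proto <- list(holding_mV = -80, step_mV = 80, step_on_s = 0,
                step_off_s = t[n])
  ss <- sweep_set(t, sweeps, proto, sampling_rate_Hz = sampling_rate_Hz)
  attr(ss, "truth") <- list(p_open = gating$p_open,
                            i_single_pA = gating$i_single_pA,
                            occupancy_fraction = colMeans(sim$occ) / gating$n_channels)
  ss
}

boltzmann_act <- function(v_mV, act) 1 / (1 + exp(-(v_mV - act$v_half_mV) / act$slope_mV))

#' Simulate a macroscopic Ca_V current family under voltage clamp
#'
#' For each command step, a Boltzmann-activated conductance with first-order
#' activation kinetics, an ohmic leak through R_m and the capacitive
#' transient of the access circuit. With `apply_rs_error`, the membrane
#' voltage is solved self-consistently per time step from
#' V_m = V_cmd - I * R_series (damped fixed-point iteration, 1 uV tolerance),
#' reproducing the series-resistance distortion of high-access recordings;
#' the truth record keeps the undistorted current.
#'
#' @param circuit An [equivalent_circuit()] (finite `r_m_MOhm` gives the leak).
#' @param act A [cav_activation_model()].
#' @param protocol List: `holding_mV`, `step_mV` (vector: the step ladder),
#'   `step_on_s`, `step_off_s`.
#' @param apply_rs_error Solve V_m self-consistently if TRUE.
#' @param cfg A [sim_config()].
#' @param sampling_rate_Hz Sampling rate (default 20 kHz).
#' @param counter Stream counter.
#' @return A [sweep_set()] (one sweep per ladder step) with attribute `truth`
#'   (`undistorted_pA` matrix, `v_m_mV` matrix, model parameters).
#' @export
simulate_cav_current <- function(circuit, act, protocol, apply_rs_error = FALSE,
                                 cfg = sim_config(), sampling_rate_Hz = 20000,
                                 counter = 0L) {
  stopifnot(inherits(circuit, "equivalent_circuit"),
            inherits(act, "cav_activation_model"))
  dt <- 1 / sampling_rate_Hz
  duration <- protocol$step_off_s + 0.2 * (protocol$step_off_s - protocol$step_on_s)
  t <- seq(0, duration, by = dt)
  steps <- protocol$step_mV
  n <- length(t)
  cur <- matrix(0, n, length(steps))
  undist <- matrix(0, n, length(steps))
  vm_rec <- matrix(0, n, length(steps))
  tau_act_s <- act$activation_tau_ms / 1000
  for (k in seq_along(steps)) {
    # linear (leak + capacitive) component: exact closed form
    lin <- rc_step_response(t, protocol$step_on_s, steps[k], circuit) +
      rc_step_response(t, protocol$step_off_s, -steps[k], circuit)
    v_cmd <- ifelse(t >= protocol$step_on_s & t < protocol$step_off_s,
                    protocol$holding_mV + steps[k], protocol$holding_mV)
    m <- boltzmann_act(protocol$holding_mV, act)
    m_u <- m
    vm <- v_cmd[1]
    for (i in seq_len(n)) {
      # undistorted: V_m == command
      m_u <- m_u + dt / tau_act_s * (boltzmann_act(v_cmd[i], act) - m_u)
      undist[i, k] <- act$g_max_nS * m_u * (v_cmd[i] - act$e_rev_mV)
      if (apply_rs_error) {
        vm_new <- vm
        for (it in seq_len(100)) {
          i_ion <- act$g_max_nS * m * (vm_new - act$e_rev_mV)
          v_next <- v_cmd[i] - i_ion * circuit$r_series_MOhm / 1000
          v_next <- 0.5 * vm_new + 0.5 * v_next  # damping
          if (abs(v_next - vm_new) < 1e-3) { vm_new <- v_next; break }
          vm_new <- v_next
          if (it == 100) stop("series-resistance fixed point did not converge: loss-of-clamp regime",
                              call. = FALSE)
        }
        vm <- vm_new
      } else {
        vm <- v_cmd[i]
      }
      m <- m + dt / tau_act_s * (boltzmann_act(vm, act) - m)
      cur[i, k] <- act$g_max_nS * m * (vm - act$e_rev_mV)
      vm_rec[i, k] <- vm
    }
    cur[, k] <- cur[, k] + lin
  }
  noisy <- with_seed(stream_seed(cfg, 3L, counter), {
    cur + matrix(stats::rnorm(length(cur), sd = cfg$current_noise_pA), nrow = n)
  })
  ss <- sweep_set(t, noisy, protocol, sampling_rate_Hz = sampling_rate_Hz)
  attr(ss, "truth") <- list(undistorted_pA = undist, v_m_mV = vm_rec,
                            act = act, circuit = circuit)
  ss
}

# paint an anti-aliased Gaussian-profile curve onto an image (in place
# semantics via return); pts is an n x 2 matrix of (x, y) pixel coords.
paint_curve <- function(img, pts, amplitude, sigma_px = 1) {
  ny <- nrow(img); nx <- ncol(img)
  half <- ceiling(3 * sigma_px)
  for (j in seq_len(nrow(pts))) {
    cx <- pts[j, 1]; cy <- pts[j, 2]
    x_lo <- max(1L, floor(cx - half)); x_hi <- min(nx, ceiling(cx + half))
    y_lo <- max(1L, floor(cy - half)); y_hi <- min(ny, ceiling(cy + half))
    if (x_lo > x_hi || y_lo > y_hi) next
    xs <- x_lo:x_hi; ys <- y_lo:y_hi
    dx2 <- outer(rep(1, length(ys)), (xs - cx)^2)
    dy2 <- outer((ys - cy)^2, rep(1, length(xs)))
    patch <- amplitude * exp(-(dx2 + dy2) / (2 * sigma_px^2))
    img[ys, xs] <- pmax(img[ys, xs], patch)
  }
  img
}

# a gently curved cilium polyline of physical length `len_um`
random_cilium_curve <- function(len_um, pixel_size_um, nx, ny) {
  len_px <- len_um / pixel_size_um
  margin <- len_px / 2 + 6
  x0 <- stats::runif(1, margin, nx - margin)
  y0 <- stats::runif(1, margin, ny - margin)
  ang <- stats::runif(1, 0, 2 * pi)
  curv <- stats::runif(1, -0.3, 0.3)
  s <- seq(0, 1, length.out = max(8L, ceiling(len_px)))
  theta <- ang + curv * s
  x <- cumsum(c(0, diff(s)) * len_px * cos(theta))
  y <- cumsum(c(0, diff(s)) * len_px * sin(theta))
  # centre the curve on (x0, y0) so it stays inside the frame
  cbind(x0 + x - mean(x), y0 + y - mean(y))
}

poisson_read_noise <- function(img, cfg) {
  # photon_gain = 0 disables shot noise (ideal detector)
  shot <- if (cfg$photon_gain > 0) {
    stats::rpois(length(img), lambda = pmax(img, 0) / cfg$photon_gain) *
      cfg$photon_gain
  } else as.numeric(img)
  matrix(shot + stats::rnorm(length(img), sd = cfg$read_noise_sd),
         nrow = nrow(img))
}

#' Simulate a two-channel sensor-calibration image set
#'
#' For each free-[Ca2+] level, paints cilium-shaped curves on a dark
#' background: the red (mCherry) channel carries the expression level, the
#' green (GCaMP6s) channel is red x Hill([Ca2+]), and under non-sequential
#' scanning a fraction `alpha` of the green signal leaks into the red
#' detector. Poisson shot noise and Gaussian read noise are added per
#' channel.
#'
#' @param hill_truth List: `R_min`, `R_max`, `EC50_nM`, `n_H`.
#' @param alpha_truth Bleed-through coefficient (green into red).
#' @param ca_levels_nM Free calcium per level, nM.
#' @param cfg A [sim_config()] (geometry and image noise).
#' @param n_cilia Curves painted per level.
#' @param img_px Image side length, pixels.
#' @param red_amplitude Peak red intensity (expression level), counts.
#' @param background Additive background, counts.
#' @param scan_mode Non-sequential (bleed-through present) or sequential.
#' @param counter Stream counter.
#' @return List of class `calibration_sim`: `stacks` (one
#'   [two_channel_stack()] per level), `footprints` (true painted masks) and
#'   `truth` (all parameters).
#' @export
simulate_calibration_stack <- function(hill_truth, alpha_truth = 0.03,
                                       ca_levels_nM = c(50, 100, 165, 300, 1000, 3000, 10000),
                                       cfg = sim_config(), n_cilia = 4,
                                       img_px = 160, red_amplitude = 1500,
                                       background = 50,
                                       scan_mode = c("non_sequential", "sequential"),
                                       counter = 0L) {
  scan_mode <- match.arg(scan_mode)
  stopifnot_positive(ca_levels_nM = ca_levels_nM)
  res <- with_seed(stream_seed(cfg, 4L, counter), {
    lapply(ca_levels_nM, function(ca) {
      red_true <- matrix(0, img_px, img_px)
      for (i in seq_len(n_cilia)) {
        pts <- random_cilium_curve(cfg$geometry$length_um, cfg$pixel_size_um,
                                   img_px, img_px)
        red_true <- paint_curve(red_true, pts, red_amplitude, sigma_px = 1)
      }
      footprint <- red_true > red_amplitude * 0.1
      green_true <- red_true * hill_forward(ca, hill_truth)
      red_meas <- if (scan_mode == "non_sequential") {
        red_true + alpha_truth * green_true
      } else red_true
      g <- poisson_read_noise(green_true + background, cfg)
      r <- poisson_read_noise(red_meas + background, cfg)
      list(stack = two_channel_stack(g, r, cfg$pixel_size_um, 1,
                                     bit_depth = 12L, scan_mode = scan_mode),
           footprint = footprint)
    })
  })
  structure(list(stacks = lapply(res, `[[`, "stack"),
                 footprints = lapply(res, `[[`, "footprint"),
                 truth = list(hill = hill_truth, alpha = alpha_truth,
                              ca_levels_nM = ca_levels_nM,
                              background = background,
                              red_amplitude = red_amplitude,
                              scan_mode = scan_mode)),
            class = "calibration_sim")
}

#' Simulate paired observations for bleed-through estimation
#'
#' Emulates imaging a red-free, GCaMP6s-only specimen: green ROI means span a
#' wide intensity range and the red channel carries only the leak
#' alpha x green plus noise.
#'
#' @param alpha_truth Bleed-through slope.
#' @param n_points Number of ROI observations.
#' @param cfg A [sim_config()].
#' @param green_range Range of green ROI means, counts.
#' @param noise_sd Gaussian noise on the leak means, counts.
#' @param counter Stream counter.
#' @return data.frame `green`, `leak` with attribute `truth`.
#' @export
simulate_bleedthrough_data <- function(alpha_truth = 0.03, n_points = 24,
                                       cfg = sim_config(),
                                       green_range = c(200, 3000),
                                       noise_sd = 5, counter = 0L) {
  out <- with_seed(stream_seed(cfg, 5L, counter), {
    g <- stats::runif(n_points, green_range[1], green_range[2])
    l <- alpha_truth * g + stats::rnorm(n_points, sd = noise_sd)
    data.frame(green = g, leak = l)
  })
  attr(out, "truth") <- list(alpha = alpha_truth)
  out
}

#' Simulate a beating-cilium image stack
#'
#' Renders a cilium sweeping across a fixed horizontal analysis line: a
#' Gaussian-profile bright spot whose position along the line oscillates
#' sinusoidally and which is visible during one half of each beat cycle (the
#' stroke crossing the line), so the line-integrated intensity pulses once
#' per beat. A frequency schedule allows mid-record changes (e.g. drug
#' wash-in).
#'
#' @param frequency_Hz Beat frequency; scalar, or a data.frame
#'   `time_s`, `frequency_Hz` for a piecewise-constant schedule. 0 renders a
#'   static cilium.
#' @param fps Frames per second (must be >= 4 x the largest frequency).
#' @param duration_s Record duration, s.
#' @param cfg A [sim_config()].
#' @param img_px `c(ny, nx)` frame size.
#' @param amplitude_px Oscillation amplitude along the line, px.
#' @param counter Stream counter.
#' @return An [image_stack()] with attributes `line` (the analysis line,
#'   n x 2 (x, y)) and `truth` (frequency schedule).
#' @export
simulate_beating_stack <- function(frequency_Hz, fps = 200, duration_s = 2,
                                   cfg = sim_config(), img_px = c(40, 80),
                                   amplitude_px = 12, counter = 0L) {
  sched <- if (is.data.frame(frequency_Hz)) frequency_Hz else
    data.frame(time_s = 0, frequency_Hz = frequency_Hz)
  if (fps < 4 * max(sched$frequency_Hz)) {
    stop("undersampled: fps must be >= 4x the beat frequency", call. = FALSE)
  }
  nt <- round(duration_s * fps)
  t <- (seq_len(nt) - 1L) / fps
  f_of_t <- sched$frequency_Hz[findInterval(t, sched$time_s)]
  phase <- 2 * pi * cumsum(f_of_t) / fps
  ny <- img_px[1]; nx <- img_px[2]
  row <- ny / 2
  xc <- nx / 2
  frames <- with_seed(stream_seed(cfg, 6L, counter), {
    arr <- array(0, c(ny, nx, nt))
    for (i in seq_len(nt)) {
      img <- matrix(0, ny, nx)
      bright <- if (f_of_t[i] == 0) 1 else max(0, sin(phase[i]))^2
      if (bright > 0) {
        x <- xc + amplitude_px * cos(phase[i])
        img <- paint_curve(img, cbind(x, row), 1000 * bright, sigma_px = 1.5)
      }
      arr[, , i] <- img + matrix(stats::rnorm(ny * nx, sd = cfg$read_noise_sd),
                                 ny, nx)
    }
    arr
  })
  st <- image_stack(frames, frame_interval_s = 1 / fps,
                    pixel_size_um = cfg$pixel_size_um)
  attr(st, "line") <- cbind(c(2, nx - 1), c(row, row))
  attr(st, "truth") <- list(schedule = sched)
  st
}

#' Simulate a Ca2+-front line-scan kymograph
#'
#' Constant-velocity mode: a sigmoidal fluorescence front crosses position x
#' at stimulus_time + x/velocity. Diffusion mode: 1-D diffusion from a
#' clamped base reservoir solved on a grid (crossing times then scale as
#' position squared). An optional first-order low-pass emulates indicator
#' binding kinetics.
#'
#' @param velocity_um_s Front velocity (exclusive with `D_um2_s`); `Inf`
#'   renders a spatially instantaneous rise.
#' @param D_um2_s Diffusion coefficient (exclusive with `velocity_um_s`).
#' @param cfg A [sim_config()] (geometry gives the cilium length).
#' @param fps Line-scan rate, lines/s.
#' @param duration_s Record duration.
#' @param stimulus_time_s Uncaging time.
#' @param rise_time_s Width of the sigmoidal rise at one position.
#' @param indicator_tau_s Indicator low-pass time constant (0 = instantaneous).
#' @param amplitude Fluorescence change amplitude, counts.
#' @param counter Stream counter.
#' @return A [kymograph()] (rows base to tip) with attribute `truth`.
#' @export
simulate_front_linescan <- function(velocity_um_s = NULL, D_um2_s = NULL,
                                    cfg = sim_config(), fps = 100,
                                    duration_s = 2, stimulus_time_s = 0.2,
                                    rise_time_s = 0.02, indicator_tau_s = 0,
                                    amplitude = 1000, counter = 0L) {
  if (is.null(velocity_um_s) == is.null(D_um2_s)) {
    stop("give exactly one of `velocity_um_s` or `D_um2_s`", call. = FALSE)
  }
  L <- cfg$geometry$length_um
  pos <- seq(0, L, by = cfg$pixel_size_um)
  nt <- round(duration_s * fps)
  t <- (seq_len(nt) - 1L) / fps
  clean <- matrix(0, length(pos), nt)
  if (!is.null(velocity_um_s)) {
    for (i in seq_along(pos)) {
      arrive <- stimulus_time_s + if (is.infinite(velocity_um_s)) 0 else
        pos[i] / velocity_um_s
      clean[i, ] <- amplitude / (1 + exp(-(t - arrive) / (rise_time_s / 4)))
    }
  } else {
    # 1-D diffusion on [0, L]: concentration clamped at the base reservoir,
    # no-flux tip, zero initial condition. Exact eigenfunction series
    # C/C0 = 1 - sum_n 4/((2n+1)pi) sin(lambda_n x) exp(-D lambda_n^2 t),
    # lambda_n = (2n+1)pi/(2L), evaluated on the sampling grid. Every
    # position saturates to the reservoir level, so half-plateau crossing
    # times follow the t ~ x^2/D scaling law away from the tip.
    nterm <- 400L
    lam <- (2 * seq_len(nterm) - 1) * pi / (2 * L)
    bn <- 4 / ((2 * seq_len(nterm) - 1) * pi)
    dtp <- pmax(t - stimulus_time_s, 0)
    decay <- exp(-outer(lam^2 * D_um2_s, dtp))        # nterm x nt
    for (i in seq_along(pos)) {
      val <- amplitude * (1 - colSums(bn * sin(lam * pos[i]) * decay))
      val[dtp == 0] <- 0
      clean[i, ] <- pmax(val, 0)
    }
  }
  if (indicator_tau_s > 0) {
    a <- (1 / fps) / indicator_tau_s
    for (i in seq_len(nrow(clean))) {
      y <- clean[i, 1]
      for (j in seq_len(nt)) {
        y <- y + a * (clean[i, j] - y)
        clean[i, j] <- y
      }
    }
  }
  noisy <- with_seed(stream_seed(cfg, 7L, counter), {
    clean + matrix(stats::rnorm(length(clean), sd = cfg$read_noise_sd),
                   nrow = nrow(clean))
  })
  k <- kymograph(noisy, pixel_size_um = cfg$pixel_size_um,
                 frame_interval_s = 1 / fps)
  attr(k, "truth") <- list(velocity_um_s = velocity_um_s, D_um2_s = D_um2_s,
                           stimulus_time_s = stimulus_time_s,
                           length_um = L,
                           time_to_tip_s = if (!is.null(velocity_um_s) &&
                                               is.finite(velocity_um_s))
                             L / velocity_um_s else NA_real_)
  k
}

#' Simulate a drifting bead field
#'
#' Beads drift in a common direction at per-bead velocities around the mean,
#' with Gaussian positional jitter; beads enter at staggered times and leave
#' the field of view. Emits per-frame detections (no identities, as a
#' detector would) plus per-bead ground truth.
#'
#' @param mean_velocity_um_s Mean drift speed.
#' @param n_beads Number of beads.
#' @param jitter_sd_um Per-frame Gaussian jitter SD, um.
#' @param fps Frame rate.
#' @param duration_s Record duration.
#' @param cfg A [sim_config()].
#' @param velocity_sd_um_s SD of per-bead velocities.
#' @param fov_um `c(width, height)` of the field of view, um.
#' @param pixel_size_um Pixel size for the emitted detections.
#' @param counter Stream counter.
#' @return List of class `bead_field_sim`: `detections` (data.frame `frame`,
#'   `x`, `y` in px), `truth` (per-bead data.frame `bead`, `velocity_um_s`,
#'   `n_frames`), plus the scales.
#' @export
simulate_bead_field <- function(mean_velocity_um_s = 86, n_beads = 12,
                                jitter_sd_um = 0.1, fps = 100, duration_s = 4,
                                cfg = sim_config(), velocity_sd_um_s = 5,
                                fov_um = c(100, 40), pixel_size_um = 0.5,
                                counter = 0L) {
  nt <- round(duration_s * fps)
  out <- with_seed(stream_seed(cfg, 8L, counter), {
    vel <- pmax(1e-3, stats::rnorm(n_beads, mean_velocity_um_s, velocity_sd_um_s))
    enter <- sample.int(max(1L, nt - 8L), n_beads, replace = TRUE)
    y0 <- stats::runif(n_beads, 0.1 * fov_um[2], 0.9 * fov_um[2])
    x0 <- stats::runif(n_beads, 0, 0.3 * fov_um[1])
    det <- list(); truth_n <- integer(n_beads)
    for (b in seq_len(n_beads)) {
      for (f in enter[b]:nt) {
        x <- x0[b] + vel[b] * (f - enter[b]) / fps
        if (x > fov_um[1]) break
        jx <- stats::rnorm(1, sd = jitter_sd_um)
        jy <- stats::rnorm(1, sd = jitter_sd_um)
        det[[length(det) + 1L]] <- c(f, (x + jx) / pixel_size_um,
                                     (y0[b] + jy) / pixel_size_um)
        truth_n[b] <- truth_n[b] + 1L
      }
    }
    m <- do.call(rbind, det)
    list(detections = data.frame(frame = as.integer(m[, 1]), x = m[, 2], y = m[, 3]),
         truth = data.frame(bead = seq_len(n_beads), velocity_um_s = vel,
                            n_frames = truth_n))
  })
  out$detections <- out$detections[order(out$detections$frame), ]
  rownames(out$detections) <- NULL
  structure(list(detections = out$detections, truth = out$truth,
                 pixel_size_um = pixel_size_um, frame_interval_s = 1 / fps),
            class = "bead_field_sim")
}
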