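# Sweep-level analyses against generator ground truth and analytic oracles.

test_that("leak subtraction cancels any linear circuit exactly and scales correctly", {
  circ <- equivalent_circuit(18.5, 180, r_m_MOhm = 500)
  proto_t <- list(holding_mV = -80, step_mV = 60, step_on_s = 0.01, step_off_s = 0.06)
  proto_l <- list(holding_mV = -80, step_mV = -20, step_on_s = 0.01, step_off_s = 0.06)
  cfg <- sim_config(seed = 21, current_noise_pA = 0)
  act0 <- cav_activation_model(g_max_nS = 0)
  test_sw <- simulate_cav_current(circ, act0, proto_t, cfg = cfg)$sweeps_pA[, 1]
  leak_sw <- simulate_cav_current(circ, act0, proto_l, cfg = cfg)$sweeps_pA[, 1]
  corr <- subtract_leak(test_sw, cbind(leak_sw, leak_sw, leak_sw), 60, -20)
  expect_lt(max(abs(corr)), 1e-9 * max(abs(test_sw)))
  # a different (R, C) pair cancels just as exactly: pure linearity
  circ2 <- equivalent_circuit(7, 45, r_m_MOhm = 90)
  t2 <- simulate_cav_current(circ2, act0, proto_t, cfg = cfg)$sweeps_pA[, 1]
  l2 <- simulate_cav_current(circ2, act0, proto_l, cfg = cfg)$sweeps_pA[, 1]
  expect_lt(max(abs(subtract_leak(t2, cbind(l2, l2, l2), 60, -20))),
            1e-9 * max(abs(t2)))
  expect_error(subtract_leak(t2, cbind(l2, l2, l2), -60, -20), "opposite sign")
  expect_error(subtract_leak(t2[-1], cbind(l2, l2, l2), 60, -20), "length")
})

test_that("leak subtraction recovers an injected active current", {
  circ <- equivalent_circuit(18.5, 30, r_m_MOhm = 500)
  act <- cav_activation_model(g_max_nS = 2, v_half_mV = -10, slope_mV = 6,
                              e_rev_mV = 60, activation_tau_ms = 2)
  proto_t <- list(holding_mV = -80, step_mV = 70, step_on_s = 0.01, step_off_s = 0.06)
  proto_l <- list(holding_mV = -80, step_mV = -20, step_on_s = 0.01, step_off_s = 0.06)
  cfg <- sim_config(seed = 22, current_noise_pA = 0.5)
  sw <- simulate_cav_current(circ, act, proto_t, cfg = cfg)
  lk <- simulate_cav_current(circ, cav_activation_model(g_max_nS = 0), proto_l,
                             cfg = cfg, counter = 1L)
  corr <- subtract_leak(sw$sweeps_pA[, 1],
                        cbind(lk$sweeps_pA[, 1], lk$sweeps_pA[, 1], lk$sweeps_pA[, 1]),
                        70, -20)
  truth <- attr(sw, "truth")$undistorted_pA[, 1]
  inside <- sw$time_s > 0.02 & sw$time_s < 0.06  # past the capacitive transient
  # corrected-trace noise SD: test noise plus 3 scaled leak sweeps
  sd_corr <- 0.5 * sqrt(1 + 3 * (70 / (3 * 20))^2)
  expect_lt(max(abs(corr[inside] - truth[inside])), 5.5 * sd_corr)
})

test_that("capacitive transient analysis recovers C_m, tau, R_series across a parameter grid", {
  # step long relative to the slowest tau on the grid (9 ms), so the
  # steady-state window is transient-free
  proto <- list(holding_mV = -80, step_mV = -20, step_on_s = 0.005, step_off_s = 0.105)
  grid <- expand.grid(c_m = c(5, 20, 30), r_s = c(10, 180, 300))
  for (i in seq_len(nrow(grid))) {
    circ <- equivalent_circuit(grid$c_m[i], grid$r_s[i])
    ss <- simulate_patch_recording(circ, proto, n_sweeps = 2,
                                   cfg = sim_config(seed = 30 + i, current_noise_pA = 0))
    fit <- analyze_capacitive_transient(ss)
    expect_equal(fit$C_m_pF, grid$c_m[i], tolerance = 0.02)
    expect_equal(fit$R_series_MOhm, grid$r_s[i], tolerance = 0.02)
    expect_equal(fit$Q_pC, grid$c_m[i] * 20 / 1000, tolerance = 0.02)
  }
})

test_that("transient charge equals C dV and the closed form matches brute-force integration", {
  proto <- list(holding_mV = -80, step_mV = -20, step_on_s = 0.005, step_off_s = 0.03)
  circ <- equivalent_circuit(20, 18)
  ss <- simulate_patch_recording(circ, proto, n_sweeps = 1,
                                 cfg = sim_config(seed = 1, current_noise_pA = 0))
  fit <- analyze_capacitive_transient(ss)
  expect_equal(fit$Q_pC, 0.4, tolerance = 5e-3)      # Q = C dV = 20 pF * 20 mV
  expect_equal(fit$tau_ms, 0.36, tolerance = 5e-3)
  # oracle equivalence, including a leaky membrane
  for (circ2 in list(circ, equivalent_circuit(20, 18, r_m_MOhm = 800),
                     equivalent_circuit(18.5, 180, r_m_MOhm = 2000))) {
    ss2 <- simulate_patch_recording(circ2, proto, n_sweeps = 1,
                                    cfg = sim_config(seed = 1, current_noise_pA = 0))
    ode <- rc_euler_oracle(circ2, proto, ss2$time_s)
    rel <- max(abs(ode - ss2$sweeps_pA[, 1])) / max(abs(ss2$sweeps_pA[, 1]))
    expect_lt(rel, 1e-3)
  }
})

test_that("degenerate and misused transient inputs are flagged", {
  proto <- list(holding_mV = -80, step_mV = -20, step_on_s = 0.005, step_off_s = 0.03)
  t <- seq(0, 0.035, by = 1 / 50000)
  flat <- sweep_set(t, matrix(0, length(t), 2), proto)
  fit <- analyze_capacitive_transient(flat)
  expect_true(fit$degenerate)
  expect_equal(fit$Q_pC, 0)
  expect_equal(fit$C_m_pF, 0)
  ss <- simulate_patch_recording(equivalent_circuit(20, 18), proto, n_sweeps = 2,
                                 cfg = sim_config(seed = 2, current_noise_pA = 0))
  expect_error(analyze_capacitive_transient(ss, n_average = 5), "exceeds")
})

test_that("I-V construction: ohmic line, peak location, and n = 1 SEM flag", {
  # ohmic 10 GOhm seal: slope 0.1 pA/mV through the origin
  t <- seq(0, 0.12, by = 1e-4)
  steps <- seq(-100, 100, by = 20)
  proto <- list(holding_mV = 0, step_mV = steps, step_on_s = 0.01, step_off_s = 0.11)
  sweeps <- vapply(steps, function(s) {
    ifelse(t >= 0.01 & t < 0.11, s * 0.1, 0)
  }, numeric(length(t)))
  rec <- sweep_set(t, sweeps, proto)
  iv <- build_iv(list(rec, rec), mode = "steady_state")
  expect_equal(iv$current_pA, iv$voltage_mV * 0.1, tolerance = 1e-9)
  expect_equal(iv$sem_pA, rep(0, length(steps)))
  iv1 <- build_iv(rec, mode = "steady_state")
  expect_true(all(is.na(iv1$sem_pA)))
  expect_true(all(iv1$n == 1))
  # peak of a simulated Ca_V family sits at the generator's peak-current
  # voltage once passive components are removed
  circ <- equivalent_circuit(18.5, 5, r_m_MOhm = 5000)
  act <- cav_activation_model(g_max_nS = 3, v_half_mV = -10, slope_mV = 6,
                              e_rev_mV = 60, activation_tau_ms = 2)
  protoc <- list(holding_mV = -80, step_mV = seq(10, 140, 10),
                 step_on_s = 0.01, step_off_s = 0.11)
  protol <- list(holding_mV = -80, step_mV = -20, step_on_s = 0.01, step_off_s = 0.11)
  sw <- simulate_cav_current(circ, act, protoc, cfg = sim_config(seed = 40, current_noise_pA = 0))
  lk <- simulate_cav_current(circ, cav_activation_model(g_max_nS = 0), protol,
                             cfg = sim_config(seed = 40, current_noise_pA = 0))
  corrected <- vapply(seq_along(protoc$step_mV), function(k) {
    subtract_leak(sw$sweeps_pA[, k],
                  cbind(lk$sweeps_pA[, 1], lk$sweeps_pA[, 1], lk$sweeps_pA[, 1]),
                  protoc$step_mV[k], -20)
  }, numeric(nrow(sw$sweeps_pA)))
  swc <- sweep_set(sw$time_s, corrected, protoc)
  truth <- attr(sw, "truth")$undistorted_pA
  iv_pk <- build_iv(swc, mode = "peak")
  idx <- which(sw$time_s >= 0.01 & sw$time_s < 0.11)
  pk_truth <- apply(truth[idx, ], 2, function(z) z[which.max(abs(z))])
  expect_equal(iv_pk$voltage_mV[which.min(iv_pk$current_pA)],
               (protoc$holding_mV + protoc$step_mV)[which.min(pk_truth)])
  # mismatched ladders refuse to average
  proto_b <- proto; proto_b$step_mV <- steps + 5
  rec_b <- sweep_set(t, sweeps, proto_b)
  expect_error(build_iv(list(rec, rec_b)), "ladder")
})

test_that("Gaussian offline filter: unity DC gain, unit-area impulse response, noise bandwidth", {
  fs <- 20000
  expect_equal(offline_filter(rep(3.7, 500), 1000, fs), rep(3.7, 500),
               tolerance = 1e-9)
  imp <- c(rep(0, 250), 1, rep(0, 250))
  resp <- offline_filter(imp, 1000, fs)
  expect_equal(sum(resp), 1, tolerance = 1e-6)
  expect_equal(which.max(resp), 251)   # zero phase
  # white-noise variance shrinks by sum(k^2) = 1/(2 sigma_n sqrt(pi))
  sigma_n <- sqrt(log(2)) / (2 * pi * 1000) * fs
  expected_ratio <- 1 / (2 * sigma_n * sqrt(pi))
  set.seed(99)
  x <- rnorm(200000)
  ratio <- var(offline_filter(x, 1000, fs)) / var(x)
  expect_equal(ratio, expected_ratio, tolerance = 0.02)
  expect_error(offline_filter(x[1:100], 11000, fs), "Nyquist")
})

test_that("amplitude histograms: open-point threshold, bimodality, empty case", {
  h <- amplitude_histogram(c(0, 1.4), "open_point", full_amplitude_pA = 1.4)
  expect_equal(h$threshold_pA, 1.26)   # 0.9 x 1.4 pA
  expect_error(amplitude_histogram(1:5, "open_point"), "full_amplitude")
  expect_error(amplitude_histogram(1:5, bin_width_pA = 0), "bin_width")
  # two-level trace: all-point histogram is bimodal at 0 and 1.4 pA
  gm <- gating_for_po(0.3)
  ss <- simulate_single_channel(gm, 0.4, 6, sim_config(seed = 50),
                                sampling_rate_Hz = 5000, noise_sd_pA = 0.15)
  h2 <- amplitude_histogram(ss$sweeps_pA, "all_point", bin_width_pA = 0.05)
  ord <- order(h2$counts, decreasing = TRUE)
  top_closed <- h2$bin_centers_pA[ord][which(abs(h2$bin_centers_pA[ord]) < 0.3)[1]]
  top_open <- h2$bin_centers_pA[ord][which(abs(h2$bin_centers_pA[ord] - 1.4) < 0.3)[1]]
  expect_lt(abs(top_closed), 0.11)
  expect_lt(abs(top_open - 1.4), 0.11)
  # no openings: open-point histogram is empty
  flat <- amplitude_histogram(rep(0, 1000), "open_point", full_amplitude_pA = 1.4)
  expect_length(flat$counts, 0)
})

test_that("open probability: fixed points and convergence to the Markov stationary value", {
  t <- seq(0, 0.1, by = 1e-4)
  proto <- list(holding_mV = -80, step_mV = 80, step_on_s = 0, step_off_s = max(t))
  always <- sweep_set(t, matrix(1.4, length(t), 2), proto)
  expect_equal(open_probability(always, 1.4), 1)
  never <- sweep_set(t, matrix(0, length(t), 2), proto)
  expect_equal(open_probability(never, 1.4), 0)
  # stationary P_o = 0.32: the 9-sweep estimate is within sampling error and
  # the 900-sweep estimate is much closer (law of large numbers)
  gm <- gating_for_po(0.32)
  s9 <- simulate_single_channel(gm, 0.4, 9, sim_config(seed = 60),
                                sampling_rate_Hz = 5000)
  p9 <- open_probability(s9, 1.4)
  s900 <- simulate_single_channel(gm, 0.4, 900, sim_config(seed = 61),
                                  sampling_rate_Hz = 2000, noise_sd_pA = 0.1)
  p900 <- open_probability(s900, 1.4)
  expect_lt(abs(p9 - 0.32), 0.12)
  expect_lt(abs(p900 - 0.32), 0.015)
  expect_lt(abs(p900 - 0.32), abs(p9 - 0.32) + 0.01)
  expect_error(open_probability(s9, 1.4, window_s = c(0, 10)), "inside")
})
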