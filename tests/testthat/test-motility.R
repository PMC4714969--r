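# Kymographs, beat frequency, front velocity, bead tracking.

test_that("reslicing: static stacks give identical columns and axis-aligned lines equal row extraction", {
  set.seed(5)
  frame <- matrix(runif(40 * 60), 40, 60)
  st <- image_stack(array(rep(frame, 5), c(40, 60, 5)), 0.01, 0.1)
  line <- cbind(c(3, 50), c(20, 20))   # horizontal, row 20
  k <- reslice_kymograph(st, line)
  expect_true(all(apply(k$data, 1, function(r) diff(range(r)) == 0)))
  # oracle: direct row extraction at integer sample points
  expect_equal(k$data[, 1], frame[20, 3:50], tolerance = 1e-12)
  # width 1 equals plain sampling; width 3 averages neighbours
  k3 <- reslice_kymograph(st, line, width_px = 3)
  expect_equal(k3$data[, 1], colMeans(frame[19:21, 3:50]), tolerance = 1e-12)
  expect_error(reslice_kymograph(st, cbind(c(0, 10), c(5, 5))), "bounds")
})

test_that("beat frequency counts one band per cycle and is invariant to intensity scaling", {
  st <- simulate_beating_stack(10, fps = 200, duration_s = 2,
                               cfg = sim_config(seed = 100))
  k <- reslice_kymograph(st, attr(st, "line"), width_px = 3)
  bf <- beat_frequency(k, windows = list(c(0, 1), c(1, 2)))
  expect_equal(bf$frequency_Hz, c(10, 10))
  # intensity scaling and offset do not change the count
  k2 <- k; k2$data <- 3 * k$data + 100
  expect_equal(beat_frequency(k2, windows = list(c(0, 1)))$frequency_Hz, 10)
  expect_error(beat_frequency(k, windows = list(c(0, 5))), "window")
})

test_that("beat frequency recovers generator draws across the physiological range", {
  freqs <- c(5.75, 8.3, 12.4, 18.5)
  for (i in seq_along(freqs)) {
    st <- simulate_beating_stack(freqs[i], fps = 200, duration_s = 2,
                                 cfg = sim_config(seed = 110 + i))
    k <- reslice_kymograph(st, attr(st, "line"))
    bf <- beat_frequency(k, windows = list(c(0, 2)))
    expect_lt(abs(bf$frequency_Hz - freqs[i]), 0.5)
  }
  # halted cilium: flat trace, 0 Hz, low-signal flag
  st0 <- simulate_beating_stack(0, fps = 100, duration_s = 2,
                                cfg = sim_config(seed = 120))
  k0 <- reslice_kymograph(st0, attr(st0, "line"))
  bf0 <- beat_frequency(k0)
  expect_equal(bf0$frequency_Hz, 0)
  expect_true(bf0$low_signal)
})

test_that("beat frequency tracks a mid-record frequency change across analysis windows", {
  sched <- data.frame(time_s = c(0, 1.5), frequency_Hz = c(12, 7))
  st <- simulate_beating_stack(sched, fps = 200, duration_s = 3,
                               cfg = sim_config(seed = 130))
  k <- reslice_kymograph(st, attr(st, "line"))
  bf <- beat_frequency(k, windows = list(c(0, 1), c(2, 3)))
  expect_lt(abs(bf$frequency_Hz[1] - 12), 1)
  expect_lt(abs(bf$frequency_Hz[2] - 7), 1)
})

test_that("front velocity: constant wave exact, two-slope wave returns the distal slope, instantaneous flagged", {
  ls <- simulate_front_linescan(velocity_um_s = 20, cfg = sim_config(seed = 140),
                                fps = 200)
  tr <- front_velocity(ls, stimulus_time_s = attr(ls, "truth")$stimulus_time_s)
  expect_equal(tr$velocity_um_s, 20, tolerance = 0.02)
  expect_equal(tr$time_to_tip_s, 11.5 / 20, tolerance = 0.02)
  expect_false(tr$unresolved)
  # two-slope wave built directly: proximal 8 um/s, distal 30 um/s
  pos <- seq(0, 11.5, by = 0.1)
  t <- seq(0, 2, by = 1 / 200)
  arrive <- ifelse(pos <= 5.75, 0.2 + pos / 8, 0.2 + 5.75 / 8 + (pos - 5.75) / 30)
  dat <- t(vapply(arrive, function(a) 1000 / (1 + exp(-(t - a) / 0.004)),
                  numeric(length(t))))
  k2 <- kymograph(dat, 0.1, 1 / 200)
  tr2 <- front_velocity(k2, stimulus_time_s = 0.2)
  expect_equal(tr2$velocity_um_s, 30, tolerance = 0.05)
  # all positions rising in one frame cannot be resolved
  ls_inf <- simulate_front_linescan(velocity_um_s = Inf,
                                    cfg = sim_config(seed = 141), fps = 100)
  tr3 <- front_velocity(ls_inf, stimulus_time_s = 0.2)
  expect_true(tr3$unresolved)
  expect_gte(tr3$velocity_um_s, 11.5 / (1 / 100))
})

test_that("diffusion-mode crossing times scale as position squared over the proximal span", {
  ld <- simulate_front_linescan(D_um2_s = 25, cfg = sim_config(seed = 150),
                                fps = 200, duration_s = 15, stimulus_time_s = 0.5)
  fd <- front_velocity(ld, stimulus_time_s = 0.5)
  L <- attr(ld, "truth")$length_um
  ok <- fd$crossing_times_s > 0.5 & fd$positions_um >= 1.2 &
    fd$positions_um <= 0.4 * L
  ex <- unname(coef(lm(log(fd$crossing_times_s[ok] - 0.5) ~
                         log(fd$positions_um[ok])))[2])
  expect_lt(abs(ex - 2), 0.1)
})

test_that("bead linking: simple track, crossing beads, and the 4-frame rule", {
  # one bead at 1 px/frame
  det <- data.frame(frame = 1:10, x = 1:10, y = rep(5, 10))
  trks <- track_beads(det, max_link_distance_px = 2)
  expect_length(trks, 1)
  expect_equal(trks[[1]]$x_px, as.numeric(1:10))
  # two beads crossing in y while separated in x by more than the gate
  det2 <- rbind(data.frame(frame = 1:10, x = seq(1, 28, 3), y = rep(5, 10)),
                data.frame(frame = 1:10, x = seq(28, 1, -3), y = rep(5.5, 10)))
  trks2 <- track_beads(det2, max_link_distance_px = 4)
  expect_length(trks2, 2)
  expect_true(all(vapply(trks2, function(tr) length(tr$frame_indices), integer(1)) == 10))
  # a bead visible for 3 frames is discarded
  det3 <- rbind(det, data.frame(frame = 1:3, x = c(50, 51, 52), y = rep(20, 3)))
  trks3 <- track_beads(det3, max_link_distance_px = 2)
  expect_length(trks3, 1)
  expect_equal(attr(trks3, "n_discarded"), 1)
})

test_that("bead velocity: exact arithmetic, jitter floor for stationary beads", {
  tr <- structure(list(frame_indices = 1:11, x_px = seq(0, 10), y_px = rep(0, 11),
                       pixel_size_um = 0.5, frame_interval_s = 0.01),
                  class = "bead_track")
  v <- bead_velocity(tr)
  expect_equal(v$velocity_um_s, 50)   # 0.5 um/frame at 100 fps
  expect_equal(v$displacement_velocity_um_s, 50)
  # stationary bead with jitter: pathwise speed approaches the analytic floor
  # E|step| = sigma * sqrt(pi) for 2-D Gaussian jitter of per-coordinate SD sigma
  set.seed(33)
  n <- 4000; sig <- 0.2
  trj <- structure(list(frame_indices = seq_len(n),
                        x_px = rnorm(n, sd = sig), y_px = rnorm(n, sd = sig),
                        pixel_size_um = 1, frame_interval_s = 0.01),
                   class = "bead_track")
  vj <- bead_velocity(trj)
  floor_um_s <- sig * sqrt(pi) / 0.01
  expect_equal(vj$velocity_um_s, floor_um_s, tolerance = 0.05)
  expect_lt(vj$displacement_velocity_um_s, 0.1 * vj$velocity_um_s)
})

test_that("tracking plus velocimetry recovers generator velocities over a speed grid", {
  for (v in c(20, 60, 100, 150)) {
    # jitter at most 10% of the per-frame displacement
    jit <- 0.1 * v / 100
    sim <- simulate_bead_field(mean_velocity_um_s = v, n_beads = 8,
                               jitter_sd_um = jit, fps = 100, duration_s = 3,
                               cfg = sim_config(seed = 160 + v),
                               velocity_sd_um_s = v * 0.05)
    trks <- track_beads(sim$detections,
                        max_link_distance_px = 3 * v / 100 / sim$pixel_size_um + 2,
                        pixel_size_um = sim$pixel_size_um,
                        frame_interval_s = sim$frame_interval_s)
    est <- summarize_bead_velocities(trks)$mean_velocity_um_s
    truth <- mean(sim$truth$velocity_um_s[sim$truth$n_frames >= 4])
    expect_lt(abs(est - truth) / truth, 0.05)
  }
})
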