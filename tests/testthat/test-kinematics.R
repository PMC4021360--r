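test_that("pitch from a pure gravitational signal matches arcsin(a/g)", {
  # constant 4.9 m s^-2 => asin(0.5) = 30 deg; constant 0 => level swimming
  p30 <- pitch_from_accel(rep(4.9, 32 * 240), rate_hz = 32, cutoff_hz = 0.5)
  expect_true(all(abs(p30$pitch_deg - 30) < 0.1))
  p0 <- pitch_from_accel(rep(0, 32 * 240), rate_hz = 32, cutoff_hz = 0.5)
  expect_true(all(abs(p0$pitch_deg) < 1e-9))
  expect_equal(p30$time_s, 0:239)
})

test_that("low-pass filtering recovers pitch under stroking that saturates the raw signal", {
  # 2 Hz stroke of amplitude 6 on top of 4.9: raw |a| exceeds 9.8 at peaks,
  # so the unfiltered conversion is undefined there, but the static
  # component is recovered after filtering
  t32 <- seq(0, 240, by = 1 / 32)
  a <- 4.9 + 6 * sin(2 * pi * 2 * t32)
  expect_gt(max(abs(a)), 9.8)
  expect_true(any(is.na(suppressWarnings(asin(a / 9.8)))))
  p <- pitch_from_accel(a, rate_hz = 32, cutoff_hz = 0.5)
  expect_false(anyNA(p$pitch_deg))
  expect_true(all(abs(p$pitch_deg - 30) < 1))
})

test_that("samples whose static component exceeds g are undefined, not clipped", {
  p <- pitch_from_accel(rep(10.5, 32 * 240), rate_hz = 32, cutoff_hz = 0.5)
  expect_true(all(is.na(p$pitch_deg)))
})

test_that("pitch estimation validates its input", {
  expect_error(pitch_from_accel(rep(1, 50), rate_hz = 32, cutoff_hz = 0.5),
               "warm-up")
  expect_error(pitch_from_accel(c(NA, rep(1, 32 * 240)), 32, 0.5), "non-finite")
  expect_error(pitch_from_accel(rep(1, 320), rate_hz = 0.8, cutoff_hz = 0.5),
               "rate_hz > 2")
})

test_that("vertical speed is the per-second depth difference", {
  expect_equal(vertical_speed(c(0, 1.5, 3.0, 4.5)), c(1.5, 1.5, 1.5))
  expect_equal(vertical_speed(rep(7, 5)), rep(0, 4))
  expect_error(vertical_speed(3), "at least 2")
})

test_that("swim speed follows U = d / (t sin(theta))", {
  expect_equal(swim_speed(50, 25, 90), 2.0)
  expect_equal(swim_speed(30, 20, asin(0.75) * 180 / pi), 2.0)
  expect_error(swim_speed(30, 20, 0), "theta")
  expect_error(swim_speed(30, 20, 91), "theta")
  expect_error(swim_speed(-1, 20, 45), "d must be positive")
  expect_error(swim_speed(30, 0, 45), "t must be positive")
  # algebraic identity: U * sin(theta) * t = d
  set.seed(1)
  d <- runif(50, 5, 50); t <- runif(50, 5, 60); th <- runif(50, 5, 90)
  U <- swim_speed(d, t, th)
  expect_equal(U * sin(th * pi / 180) * t, d, tolerance = 1e-12)
})

test_that("segmentation recovers programmed phase boundaries of a square dive", {
  # 30 s descent to 50 m, 60 s bottom, 25 s ascent
  des <- noiseless_design(bottom_range_s = c(60, 60))
  dv <- simulate_dive_sensors(U_descent = 50 / 30 / sin(pi / 3),
                              U_ascent = 50 / 25 / sin(pi / 3),
                              pitch_descent_deg = 60, pitch_ascent_deg = 60,
                              target_depth_m = 50, bottom_s = 60, design = des)
  pitch <- pitch_from_accel(dv$fast$accel_surge, 32, 0.5)
  seg <- segment_phases(dv$slow$depth_m, pitch, 50)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$phase, c("descent", "ascent"))
  durations <- seg$end_s - seg$start_s
  expect_lt(abs(durations[1] - 30), 2)
  expect_lt(abs(durations[2] - 25), 2)
  expect_lt(seg$end_s[1], seg$start_s[2])  # descent precedes ascent, bottom excluded
})

test_that("a trace that never submerges yields no phases", {
  set.seed(3)
  n <- 120
  depth <- abs(rnorm(n, 0.2, 0.1))
  accel <- rnorm(32 * n, 0, 0.2)
  pitch <- pitch_from_accel(accel, 32, 0.5)
  seg <- segment_phases(depth, pitch, 30)
  expect_equal(nrow(seg), 0)
})

test_that("two consecutive dives are indexed in time order", {
  des <- noiseless_design()
  d1 <- simulate_dive_sensors(1.7, 1.7, 60, 60, 40, 20, des)
  d2 <- simulate_dive_sensors(1.5, 1.5, 60, 60, 40, 20, des)
  depth <- c(d1$slow$depth_m, d2$slow$depth_m)
  surge <- c(d1$fast$accel_surge, d2$fast$accel_surge)
  pitch <- pitch_from_accel(surge, 32, 0.5)
  seg <- segment_phases(depth, pitch, 40)
  expect_equal(seg$dive_index, c(1L, 1L, 2L, 2L))
  expect_true(all(diff(seg$start_s) > 0))
})

test_that("a dive that never reaches the target depth is flagged and skipped", {
  des <- noiseless_design()
  dv <- simulate_dive_sensors(1.7, 1.7, 60, 60, 20, 20, des)
  pitch <- pitch_from_accel(dv$fast$accel_surge, 32, 0.5)
  expect_warning(seg <- segment_phases(dv$slow$depth_m, pitch, 40),
                 "never reached the target depth")
  expect_equal(nrow(seg), 0)
})

test_that("phase summaries recover programmed speeds end to end", {
  des <- experiment_design(seed = 11)  # default noise and stroking
  set.seed(11)
  dv <- simulate_dive_sensors(1.7, 1.9, 60, 60, 50, 30, des)
  tr <- sensor_trace("t1", dv$slow$depth_m, dv$fast$accel_surge, dv$fast$accel_heave)
  ph <- summarize_phases(tr, meta_row(depth = 50))
  expect_equal(nrow(ph), 2)
  desc <- ph[ph$phase == "descent", ]
  asc <- ph[ph$phase == "ascent", ]
  expect_lt(abs(desc$U - 1.7) / 1.7, 0.02)
  expect_lt(abs(asc$U - 1.9) / 1.9, 0.02)
  expect_gt(asc$U, desc$U)  # programmed asymmetry is recovered
  # Eq.-2 identity holds for every summary row
  expect_equal(ph$U * sin(ph$theta_deg * pi / 180) * ph$t, ph$d,
               tolerance = 1e-12)
  expect_true(all(ph$U >= ph$v_vertical - 1e-9))
})

test_that("summarize_phases is deterministic and empty for dive-free traces", {
  des <- experiment_design(seed = 5)
  set.seed(5)
  dv <- simulate_dive_sensors(1.6, 1.8, 55, 65, 30, 25, des)
  tr <- sensor_trace("t1", dv$slow$depth_m, dv$fast$accel_surge, dv$fast$accel_heave)
  ph1 <- summarize_phases(tr, meta_row(depth = 30))
  ph2 <- summarize_phases(tr, meta_row(depth = 30))
  expect_identical(ph1, ph2)
  flat <- sensor_trace("t2", rep(0.1, 120), rnorm(3840, 0, 0.1), rnorm(3840, 0, 0.1))
  empty <- summarize_phases(flat, meta_row(trial_id = "t2", depth = 30))
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("trial_id", "dive_index", "phase", "d", "t",
                        "theta_deg", "v_vertical", "U"))
})

test_that("noiseless constant-pitch input recovers pitch to 0.1 degrees", {
  des <- noiseless_design()
  dv <- simulate_dive_sensors(1.7, 1.7, 60, 60, 50, 30, des)
  tr <- sensor_trace("t1", dv$slow$depth_m, dv$fast$accel_surge, dv$fast$accel_heave)
  ph <- summarize_phases(tr, meta_row(depth = 50))
  expect_true(all(abs(ph$theta_deg - 60) < 0.1))
})
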