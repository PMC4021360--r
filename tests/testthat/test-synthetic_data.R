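test_that("a noiseless vertical dive hits the programmed profile exactly", {
  des <- noiseless_design()
  dv <- simulate_dive_sensors(U_descent = 2, U_ascent = 2,
                              pitch_descent_deg = 90, pitch_ascent_deg = 90,
                              target_depth_m = 50, bottom_s = 30, design = des,
                              lead_s = 15)
  # descent covers 50 m in 25 s
  expect_equal(dv$truth$t_descent, 25)
  expect_equal(dv$slow$depth_m[dv$slow$time_s == 15 + 25], 50)
  # surge equals -g during descent (head-down vertical), +g during ascent
  desc32 <- dv$fast$time_s > 16 & dv$fast$time_s < 39
  expect_true(all(abs(dv$fast$accel_surge[desc32] + 9.8) < 1e-9))
  asc32 <- dv$fast$time_s > 71 & dv$fast$time_s < 94
  expect_true(all(abs(dv$fast$accel_surge[asc32] - 9.8) < 1e-9))
})

test_that("noiseless dives conserve depth = U * sin(pitch) * duration", {
  sim <- simulate_experiment(noiseless_design(depths = c(20, 50),
                                              dives_per_cell = 1))
  tru <- sim$truth
  expect_equal(tru$U_descent * sin(tru$pitch_descent * pi / 180) * tru$t_descent,
               tru$target_depth_m, tolerance = 1e-9)
  expect_equal(tru$U_ascent * sin(tru$pitch_ascent * pi / 180) * tru$t_ascent,
               tru$target_depth_m, tolerance = 1e-9)
})

test_that("infeasible programmed dives are rejected", {
  des <- noiseless_design()
  expect_error(simulate_dive_sensors(0, 1.7, 60, 60, 30, 20, des),
               "non-positive vertical speed")
  expect_error(simulate_dive_sensors(5, 5, 90, 90, 10, 20, des),
               "shorter than 4 s")
})

test_that("the experiment produces one trial per cell and the right dive count", {
  des <- experiment_design(depths = 30, dives_per_cell = 2, seed = 2)
  sim <- simulate_experiment(des)
  expect_equal(nrow(sim$meta), 3 * 4 * 1)   # animals x conditions x depths
  expect_equal(nrow(sim$truth), 3 * 4 * 1 * 2)
  expect_equal(length(sim$traces), nrow(sim$meta))
  # default design emulates the study scale: 180 dives across 60 trials
  def <- experiment_design()
  expect_equal(length(def$depths) * nrow(def$animals) *
                 length(def$conditions) * def$dives_per_cell, 180)
})

test_that("identical seeds give byte-identical files, different seeds differ", {
  des <- small_design(seed = 123)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_experiment(des, out_dir = d1)
  simulate_experiment(des, out_dir = d2)
  files <- list.files(d1)
  expect_gt(length(files), 0)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  d3 <- withr::local_tempdir()
  simulate_experiment(small_design(seed = 124), out_dir = d3)
  tid <- grep("_32hz", files, value = TRUE)[1]
  expect_false(identical(readLines(file.path(d1, tid)),
                         readLines(file.path(d3, tid))))
})

test_that("seeds change the noise but not the ground-truth structure when effect SDs are zero", {
  des_a <- experiment_design(depths = 30, dives_per_cell = 1, seed = 1,
                             animal_sd = 0, residual_sd = 0, pitch_jitter_sd = 0,
                             bottom_range_s = c(30, 30))
  des_b <- des_a; des_b$seed <- 2
  sa <- simulate_experiment(des_a)
  sb <- simulate_experiment(des_b)
  cols <- c("U_descent", "U_ascent", "pitch_descent", "pitch_ascent",
            "t_descent", "t_ascent")
  expect_equal(sa$truth[, cols], sb$truth[, cols], tolerance = 1e-12)
  expect_false(identical(sa$traces[[1]]$slow$depth_m,
                         sb$traces[[1]]$slow$depth_m))
})

test_that("the speed table follows the programmed linear model", {
  # zero noise, zero effects: all speeds equal the baseline
  st0 <- simulate_speed_table(experiment_design(
    seed = 3, drag_effect = 0, phase_effect = 0, animal_sd = 0, residual_sd = 0))
  expect_true(all(st0$records$U == 1.7))
  # programmed drag effect is recovered by the difference of condition means
  st <- simulate_speed_table(experiment_design(seed = 31, animal_sd = 0),
                             n_records = 2000)
  rec <- st$records
  diff_means <- mean(rec$U[rec$drag == 1]) - mean(rec$U[rec$drag == 0])
  se <- 0.15 * sqrt(1 / sum(rec$drag == 1) + 1 / sum(rec$drag == 0))
  expect_lt(abs(diff_means - (-0.45)), 2 * se + 1e-9)
})

test_that("effect-estimate precision shrinks as 1/sqrt(n)", {
  est_sd <- function(n, seeds = 1:40) {
    ests <- vapply(seeds, function(s) {
      rec <- simulate_speed_table(experiment_design(seed = 6000 + s,
                                                    animal_sd = 0),
                                  n_records = n)$records
      mean(rec$U[rec$drag == 1]) - mean(rec$U[rec$drag == 0])
    }, numeric(1))
    sd(ests)
  }
  s_small <- est_sd(120)
  s_big <- est_sd(480)
  expect_equal(s_small / s_big, 2, tolerance = 0.5)
})

test_that("default control speeds sit in the observed 1.4-2.0 band with tubes slower", {
  sim <- simulate_experiment(experiment_design(seed = 14))
  ph <- suppressWarnings(process_trials_from_memory(sim))
  rec <- speed_records(ph, sim$meta)
  ctrl_desc <- mean(rec$U[rec$drag == 0 & rec$phase == 0])
  ctrl_asc <- mean(rec$U[rec$drag == 0 & rec$phase == 1])
  expect_gt(ctrl_desc, 1.4); expect_lt(ctrl_desc, 2.0)
  expect_gt(ctrl_asc, 1.4); expect_lt(ctrl_asc, 2.0)
  tube_desc <- mean(rec$U[rec$drag == 1 & rec$phase == 0])
  tube_asc <- mean(rec$U[rec$drag == 1 & rec$phase == 1])
  expect_lt(tube_desc, ctrl_desc)
  expect_lt(tube_asc, ctrl_asc)
})
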