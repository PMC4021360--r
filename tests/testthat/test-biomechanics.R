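test_that("surface area follows the two-thirds allometry", {
  expect_equal(surface_area(1, 1), 1)
  expect_equal(surface_area(213.6, 0.056), 0.056 * 213.6^(2 / 3))
  expect_equal(surface_area(213.6, 0.056), 2.0, tolerance = 0.01)
  expect_equal(surface_area(2 * 150) / surface_area(150), 2^(2 / 3))
  expect_error(surface_area(-1), "positive")
})

test_that("oxygen consumption converts to watts at 20.1 J/ml", {
  expect_equal(rmr_to_power(1.0), 335.0)
  expect_equal(rmr_to_power(0), 0)
  expect_equal(rmr_to_power(2.0), 670.0)
  expect_error(rmr_to_power(-0.1), "non-negative")
})

test_that("cost of transport has the k/U + drag-power structure", {
  p <- biomech_params(k = 335, C_D = 0.004, S = 2.0)
  expect_equal(cot(1.0, p), 335 + 0.5 * 1027 * 0.004 * 2 / 0.12, tolerance = 1e-12)
  expect_equal(cot(1.0, p), 369.2, tolerance = 1e-3)
  # mechanical term scales as U^2; metabolic term vanishes at high U
  mech <- function(U) cot(U, p) - p$k / U
  expect_equal(mech(2) / mech(1), 4, tolerance = 1e-12)
  expect_lt(p$k / 1e6, cot(1e6, p))
  expect_error(cot(0, p), "positive")
  expect_error(cot(-1, p), "positive")
})

test_that("closed-form optimal speed equals the numeric COT argmin", {
  set.seed(42)
  for (i in 1:50) {
    p <- biomech_params(k = runif(1, 50, 2000), C_D = runif(1, 0.002, 0.01),
                        S = runif(1, 0.5, 5), eps_p = runif(1, 0.3, 1),
                        eps_A = runif(1, 0.05, 0.5), rho_w = runif(1, 1000, 1050),
                        lam = runif(1, 0.5, 4))
    u_star <- optimal_speed(p)
    num <- stats::optimize(cot, c(0.05, 10), p = p, tol = 1e-10)$minimum
    expect_equal(u_star, num, tolerance = 1e-6)
    # convexity: COT higher on either side of the optimum
    expect_gt(cot(u_star * 1.1, p), cot(u_star, p))
    expect_gt(cot(u_star * 0.9, p), cot(u_star, p))
  }
})

test_that("optimal speed obeys the cube-root scaling laws", {
  p <- biomech_params(k = 335, C_D = 0.004, S = 2.0)
  p8 <- biomech_params(k = 8 * 335, C_D = 0.004, S = 2.0)
  expect_equal(optimal_speed(p8), 2 * optimal_speed(p), tolerance = 1e-12)
  pcd <- biomech_params(k = 335, C_D = 8 * 0.004, S = 2.0)
  expect_equal(optimal_speed(pcd), optimal_speed(p) / 2, tolerance = 1e-12)
  # and does not depend on any buoyancy or depth input: the parameter set
  # simply has no such field
  expect_named(unclass(p), c("k", "C_D", "S", "eps_p", "eps_A", "rho_w", "lam"))
})

test_that("metabolic-power calibration inverts the optimal-speed relation", {
  p <- biomech_params(k = 1, C_D = 0.004, S = surface_area(142.5))
  k <- calibrate_metabolic_power(1.8, p)
  p2 <- biomech_params(k = k, C_D = 0.004, S = surface_area(142.5))
  expect_equal(optimal_speed(p2), 1.8, tolerance = 1e-12)
})

test_that("tube wetted area follows cylinder geometry", {
  expect_equal(tube_wetted_area(tube_spec(include_end_caps = FALSE)),
               2 * pi * 0.125 * 0.35, tolerance = 1e-12)
  expect_equal(tube_wetted_area(tube_spec(include_end_caps = FALSE)),
               0.2749, tolerance = 1e-4)
  expect_equal(tube_wetted_area(tube_spec()),
               2 * (pi * 0.125 * 0.35 + 2 * pi * 0.0625^2), tolerance = 1e-12)
  expect_equal(tube_wetted_area(tube_spec()), 0.3240, tolerance = 1e-4)
  expect_equal(tube_wetted_area(tube_spec(count = 0)), 0)
})

test_that("the composite drag coefficient is an area-weighted mixture", {
  spec <- tube_spec()
  expect_equal(combined_cd(0.004, 2.003, spec), 0.01333, tolerance = 1e-3)
  # mixture identity: equal coefficients are unchanged
  spec_eq <- tube_spec(C_D_tube = 0.004)
  expect_equal(combined_cd(0.004, 2.0, spec_eq), 0.004, tolerance = 1e-12)
  # always strictly between the two inputs
  set.seed(7)
  for (i in 1:25) {
    cda <- runif(1, 0.002, 0.01)
    s <- tube_spec(C_D_tube = runif(1, 0.02, 0.2))
    cc <- combined_cd(cda, runif(1, 1, 3), s)
    expect_gt(cc, min(cda, s$C_D_tube))
    expect_lt(cc, max(cda, s$C_D_tube))
  }
})

test_that("drag-increase ratios fall with initial drag and with body mass", {
  grid <- seq(0.002, 0.01, by = 0.0005)
  masses <- c(142.5, 162, 213.6)
  curve <- cd_increase_curve(grid, masses)
  for (m in masses) {
    r <- curve$ratio[curve$M_b == m]
    expect_true(all(diff(r) < 0))
    expect_gt(r[1], r[length(r)])
  }
  for (cd in grid) {
    r <- curve$ratio[curve$C_D0 == cd]
    expect_true(all(diff(r) < 0))  # masses are in increasing order
  }
  # without tubes the ratio is identically 1
  none <- cd_increase_curve(grid, masses, spec = tube_spec(count = 0))
  expect_true(all(none$ratio == 1))
  expect_error(cd_increase_curve(c(0.002, 0.05), masses), "0, 0.02")
})

test_that("body-composition buoyancy arithmetic is exact", {
  dens <- c(lipid = 900.7, lean = 1100)
  # mixture density exactly seawater => neutral
  lf_neutral <- (1 / 1027 - 1 / 1100) / (1 / 900.7 - 1 / 1100)
  expect_equal(buoyancy_from_composition(180, lf_neutral, dens), 0,
               tolerance = 1e-9)
  # nearly all-lipid body floats hard
  expect_equal(buoyancy_from_composition(100, 1 - 1e-12, dens),
               (1027 * 100 / 900.7 - 100) * 9.8, tolerance = 1e-6)
  expect_equal(buoyancy_from_composition(100, 1 - 1e-12, dens), 137.5,
               tolerance = 0.1)
  # strictly increasing in lipid fraction
  f <- seq(0.12, 0.27, by = 0.01)
  b <- buoyancy_from_composition(180, f, dens)
  expect_true(all(diff(b) > 0))
  expect_error(buoyancy_from_composition(180, 1.2, dens), "lipid_frac")
})

test_that("ballast sizing matches the buoyancy difference and is antisymmetric", {
  a <- animal_params("x", M_b = 180, rmr_lpm = 1, lipid_frac = 0.18)
  same <- ballast_for_target(a, 0.18)
  expect_equal(same$ballast_mass_in_water_kg, 0)
  expect_equal(same$air_volume_l, 0)
  expect_equal(same$condition, "C")

  down <- ballast_for_target(a, 0.13)
  expect_equal(down$condition, "BN")
  expect_gt(down$ballast_mass_in_water_kg, 0)
  expect_equal(down$air_volume_l, 0)
  # order of magnitude of the study's lead sheets (1.3-1.7 kg in water)
  expect_gt(down$ballast_mass_in_water_kg, 0.5)
  expect_lt(down$ballast_mass_in_water_kg, 5)

  up <- ballast_for_target(a, 0.25)
  expect_equal(up$condition, "BP")
  expect_gt(up$air_volume_l, 0)
  expect_equal(up$ballast_mass_in_water_kg, 0)

  # round trip: applying the ballast to the current buoyancy recovers the
  # target net buoyancy exactly
  recovered <- down$current_buoyancy_N - 9.8 * down$ballast_mass_in_water_kg
  expect_equal(recovered, down$net_buoyancy_N, tolerance = 1e-9)
  recovered_up <- up$current_buoyancy_N + 9.8 * 1027 * up$air_volume_l / 1000
  expect_equal(recovered_up, up$net_buoyancy_N, tolerance = 1e-9)

  # antisymmetry: swapping current and target switches lead for air
  a2 <- animal_params("x", M_b = 180, rmr_lpm = 1, lipid_frac = 0.13)
  back <- ballast_for_target(a2, 0.18)
  expect_equal(back$condition, "BP")
  expect_equal(9.8 * 1027 * back$air_volume_l / 1000,
               9.8 * down$ballast_mass_in_water_kg, tolerance = 1e-9)
})

test_that("parameter constructors reject invalid values", {
  expect_error(biomech_params(k = -1, C_D = 0.004, S = 2), "positive")
  expect_error(biomech_params(k = 335, C_D = 0.004, S = 2, eps_p = 1.2), "<= 1")
  expect_error(animal_params("x", M_b = 180, C_D0 = 0.05, rmr_lpm = 1), "C_D0")
  expect_error(tube_spec(count = -1), "count")
})
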