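#' Design of a simulated buoyancy/drag dive experiment
#'
#' Describes the simulated experiment from which all synthetic data are
#' drawn: three trained sea lions diving to fixed feeding depths under four
#' harness conditions (`C` control, `AD` added drag, `BN` negative and `BP`
#' positive buoyancy, the latter three carrying a pair of tubes). Each
#' animal x condition x depth cell is one trial containing `dives_per_cell`
#' dives recorded as a 1 Hz depth stream plus 32 Hz two-axis acceleration.
#'
#' Per-dive programmed swim speeds follow the linear model the analysis
#' assumes:
#' `U = baseline + drag_effect*[tubes] + phase_effect*[ascent] + animal offset + N(0, residual_sd)`.
#'
#' Defaults emulate the study conditions: masses spanning 142.5-213.6 kg,
#' depths 10-50 m, 3 dives per cell (180 dives, close to the 186 of the
#' experiment), control-condition speeds inside the 1.4-2.0 m s^-1 band,
#' tube conditions slower by 0.45 m s^-1, ascents faster by 0.15 m s^-1,
#' stroking at 1.5 Hz (well above the 0.5 Hz pitch filter cutoff).
#'
#' @param animals Data frame with `animal_id` and `M_b` (kg).
#' @param conditions Conditions to simulate (subset of C, AD, BN, BP).
#' @param depths Fixed dive depths (m).
#' @param dives_per_cell Dives per animal x condition x depth trial.
#' @param baseline_U Control descent mean speed (m s^-1).
#' @param drag_effect Additive speed effect of carrying tubes (m s^-1).
#' @param phase_effect Additive speed effect of the ascent phase (m s^-1).
#' @param animal_sd SD of the per-animal random speed offset (m s^-1).
#' @param residual_sd Per-dive-phase residual SD (m s^-1).
#' @param depth_sd Depth sensor noise SD (m).
#' @param accel_sd Accelerometer noise SD (m s^-2).
#' @param stroke_hz,stroke_amp Stroking oscillation frequency (Hz) and
#'   amplitude (m s^-2).
#' @param pitch_descent_deg,pitch_ascent_deg Mean transit pitch magnitudes
#'   (degrees, in (10, 90]).
#' @param pitch_jitter_sd Per-dive SD of the programmed pitch (degrees).
#' @param bottom_range_s Range of the bottom (feeding) hold duration (s).
#' @param surface_s Surface interval before/between/after dives (s).
#' @param seed Integer seed; all randomness in the generators flows from it.
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(animals = data.frame(
                                animal_id = c("F97HA", "F00BO", "F97SI"),
                                M_b = c(142.5, 178.0, 213.6)),
                              conditions = c("C", "AD", "BN", "BP"),
                              depths = c(10, 20, 30, 40, 50),
                              dives_per_cell = 3,
                              baseline_U = 1.7,
                              drag_effect = -0.45,
                              phase_effect = 0.15,
                              animal_sd = 0.10,
                              residual_sd = 0.15,
                              depth_sd = 0.05,
                              accel_sd = 0.2,
                              stroke_hz = 1.5,
                              stroke_amp = 1.5,
                              pitch_descent_deg = 60,
                              pitch_ascent_deg = 60,
                              pitch_jitter_sd = 3,
                              bottom_range_s = c(20, 40),
                              surface_s = 15,
                              seed = 1L) {
  stopifnot(all(conditions %in% c("C", "AD", "BN", "BP")),
            dives_per_cell >= 1, all(depths > 0), baseline_U > 0,
            animal_sd >= 0, residual_sd >= 0, depth_sd >= 0, accel_sd >= 0,
            pitch_descent_deg > 10, pitch_descent_deg <= 90,
            pitch_ascent_deg > 10, pitch_ascent_deg <= 90,
            length(bottom_range_s) == 2, bottom_range_s[1] <= bottom_range_s[2])
  structure(as.list(environment()), class = "experiment_design")
}

# truncate a programmed speed away from zero so every dive is swimmable
.min_speed <- 0.3

#' Simulate the sensor record of a single dive
#'
#' Builds the noiseless kinematic skeleton of one dive — surface lead-in,
#' linear descent at constant pitch and speed, constant-depth bottom hold,
#' linear ascent, surface tail — then adds depth sensor noise, the
#' gravitational surge component `9.8 * sin(pitch)`, a stroking sinusoid
#' (surge, with the dorso-ventral axis in quadrature) while submerged, and
#' accelerometer noise. Consumes the current R RNG stream.
#'
#' @param U_descent,U_ascent Programmed swim speeds along the path (m s^-1).
#' @param pitch_descent_deg,pitch_ascent_deg Programmed pitch magnitudes
#'   (degrees in (0, 90]).
#' @param target_depth_m Fixed dive depth (m).
#' @param bottom_s Bottom hold duration (s).
#' @param design An [experiment_design()] (noise/stroke/surface settings).
#' @param lead_s Surface time before the descent starts (s).
#' @return List with `slow` (data.frame time_s/depth_m), `fast` (data.frame
#'   time_s/accel_surge/accel_heave) on local time grids starting at 0, and
#'   `truth` (one-row data frame of programmed values incl. phase
#'   boundaries).
#' @export
simulate_dive_sensors <- function(U_descent, U_ascent, pitch_descent_deg,
                                  pitch_ascent_deg, target_depth_m, bottom_s,
                                  design = experiment_design(), lead_s = design$surface_s) {
  vz_d <- U_descent * sin(pitch_descent_deg * pi / 180)
  vz_a <- U_ascent * sin(pitch_ascent_deg * pi / 180)
  if (vz_d <= 0 || vz_a <= 0)
    stop("simulate_dive_sensors: programmed speeds/pitches give non-positive vertical speed")
  t_desc <- target_depth_m / vz_d
  t_asc <- target_depth_m / vz_a
  if (t_desc < 4 || t_asc < 4)
    stop("simulate_dive_sensors: transit shorter than 4 s cannot be resolved at 1 Hz; ",
         "lower the programmed speed or increase the depth")
  s1 <- lead_s
  s2 <- s1 + t_desc
  s3 <- s2 + bottom_s
  s4 <- s3 + t_asc
  total <- ceiling(s4 + design$surface_s)

  depth_of <- function(t) {
    ifelse(t < s1, 0,
      ifelse(t < s2, (t - s1) * vz_d,
        ifelse(t < s3, target_depth_m,
          ifelse(t < s4, target_depth_m - (t - s3) * vz_a, 0))))
  }
  pitch_of <- function(t) {
    ifelse(t >= s1 & t < s2, -pitch_descent_deg,
      ifelse(t >= s3 & t < s4, pitch_ascent_deg, 0))
  }

  t1 <- 0:total
  depth <- depth_of(t1) + stats::rnorm(length(t1), 0, design$depth_sd)
  depth <- pmax(depth, -0.45)

  rate <- 32
  t32 <- seq(0, by = 1 / rate, length.out = (total + 1) * rate)
  phase0 <- stats::runif(1, 0, 2 * pi)
  submerged <- depth_of(t32) > 0.5
  stroke <- design$stroke_amp * submerged
  surge <- .g * sin(pitch_of(t32) * pi / 180) +
    stroke * sin(2 * pi * design$stroke_hz * t32 + phase0) +
    stats::rnorm(length(t32), 0, design$accel_sd)
  heave <- stroke * cos(2 * pi * design$stroke_hz * t32 + phase0) +
    stats::rnorm(length(t32), 0, design$accel_sd)

  truth <- data.frame(U_descent = U_descent, U_ascent = U_ascent,
                      pitch_descent = pitch_descent_deg,
                      pitch_ascent = pitch_ascent_deg,
                      t_descent = t_desc, t_ascent = t_asc,
                      bottom_s = bottom_s,
                      desc_start_s = s1, desc_end_s = s2,
                      asc_start_s = s3, asc_end_s = s4)
  list(slow = data.frame(time_s = t1, depth_m = depth),
       fast = data.frame(time_s = t32, accel_surge = surge, accel_heave = heave),
       truth = truth)
}

#' Simulate the full dive experiment
#'
#' Generates one trial (a [sensor_trace()] file pair) per animal x condition
#' x depth cell, each holding `dives_per_cell` dives, plus the trial
#' metadata table and a ground-truth table of every programmed quantity.
#' Animal random offsets are drawn once per run from
#' `N(0, animal_sd)`; per-dive speeds add the drag and phase effects and a
#' residual draw. Everything is deterministic given `design$seed`; the same
#' seed reproduces byte-identical files.
#'
#' @param design An [experiment_design()].
#' @param out_dir Optional directory; when given, traces are written with
#'   [write_sensor_trace()] and the metadata with [write_trial_meta()].
#' @return List with `traces` (named list of `sensor_trace`), `meta`
#'   (validated [trial_meta()] table), `truth` (one row per dive with
#'   programmed speeds, pitches and phase boundaries) and `animal_offsets`.
#' @export
simulate_experiment <- function(design = experiment_design(), out_dir = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  set.seed(design$seed)
  animals <- design$animals
  offsets <- stats::setNames(stats::rnorm(nrow(animals), 0, design$animal_sd),
                             animals$animal_id)
  traces <- list()
  meta_rows <- list()
  truth_rows <- list()
  for (ai in seq_len(nrow(animals))) {
    for (cond in design$conditions) {
      for (dep in design$depths) {
        trial_id <- sprintf("%s_%s_%02dm", animals$animal_id[ai], cond, dep)
        slow <- NULL; fast <- NULL
        t_off <- 0
        for (k in seq_len(design$dives_per_cell)) {
          tubes <- as.numeric(cond != "C")
          U_d <- design$baseline_U + design$drag_effect * tubes +
            offsets[ai] + stats::rnorm(1, 0, design$residual_sd)
          U_a <- design$baseline_U + design$drag_effect * tubes +
            design$phase_effect + offsets[ai] + stats::rnorm(1, 0, design$residual_sd)
          U_d <- max(U_d, .min_speed); U_a <- max(U_a, .min_speed)
          p_d <- min(90, max(15, design$pitch_descent_deg + stats::rnorm(1, 0, design$pitch_jitter_sd)))
          p_a <- min(90, max(15, design$pitch_ascent_deg + stats::rnorm(1, 0, design$pitch_jitter_sd)))
          bottom <- stats::runif(1, design$bottom_range_s[1], design$bottom_range_s[2])
          dv <- simulate_dive_sensors(U_d, U_a, p_d, p_a, dep, bottom, design,
                                      lead_s = design$surface_s)
          dv$slow$time_s <- dv$slow$time_s + t_off
          dv$fast$time_s <- dv$fast$time_s + t_off
          slow <- rbind(slow, dv$slow)
          fast <- rbind(fast, dv$fast)
          tr <- dv$truth
          tr$trial_id <- trial_id
          tr$animal_id <- animals$animal_id[ai]
          tr$condition <- cond
          tr$target_depth_m <- dep
          tr$dive_index <- k
          tr[, grep("_s$", names(tr))] <- tr[, grep("_s$", names(tr))] + t_off
          truth_rows[[length(truth_rows) + 1L]] <- tr
          t_off <- t_off + nrow(dv$slow)
        }
        traces[[trial_id]] <- sensor_trace(
          trial_id, depth_m = slow$depth_m,
          accel_surge = fast$accel_surge, accel_heave = fast$accel_heave,
          time_1hz = slow$time_s, time_32hz = fast$time_s)
        meta_rows[[trial_id]] <- data.frame(
          trial_id = trial_id, animal_id = animals$animal_id[ai],
          condition = cond, body_mass_kg = animals$M_b[ai],
          target_depth_m = dep)
      }
    }
  }
  meta <- trial_meta(do.call(rbind, meta_rows))
  rownames(meta) <- NULL
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  if (!is.null(out_dir)) {
    for (tr in traces) write_sensor_trace(tr, out_dir)
    write_trial_meta(meta, file.path(out_dir, "trials.csv"))
    utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  }
  list(traces = traces, meta = meta, truth = truth, animal_offsets = offsets)
}

#' Simulate a tidy swim-speed table for the mixed-model stage
#'
#' Draws dive-phase speed records directly from the linear mixed model the
#' statistical stage assumes, bypassing the sensor-level simulation:
#' `U = baseline + drag_effect*[tubes] + phase_effect*[ascent] + b_animal + e`,
#' with `b_animal ~ N(0, animal_sd^2)` and `e ~ N(0, residual_sd^2)`.
#' Records are allocated round-robin over the animal x condition x depth x
#' phase cells so any total count divides as evenly as possible.
#'
#' @param design An [experiment_design()].
#' @param n_records Total number of dive-phase records; default
#'   `2 * dives_per_cell * (number of cells)` (both phases of every dive).
#' @return List with `records` (data frame with `animal_id`, `U`, `drag`,
#'   `phase`, `buoyancy`, `M_b`, `depth`) and `coefficients` (the programmed
#'   generating values).
#' @export
simulate_speed_table <- function(design = experiment_design(), n_records = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  set.seed(design$seed)
  animals <- design$animals
  cells <- expand.grid(animal_id = animals$animal_id,
                       condition = design$conditions,
                       depth = design$depths,
                       phase = c("descent", "ascent"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (is.null(n_records))
    n_records <- design$dives_per_cell * nrow(cells)
  reps <- rep(seq_len(nrow(cells)), length.out = n_records)
  rec <- cells[reps, , drop = FALSE]
  offsets <- stats::setNames(stats::rnorm(nrow(animals), 0, design$animal_sd),
                             animals$animal_id)
  rec$M_b <- animals$M_b[match(rec$animal_id, animals$animal_id)]
  rec$drag <- as.numeric(rec$condition != "C")
  rec$buoyancy <- ifelse(rec$condition == "BN", -1,
                         ifelse(rec$condition == "BP", 1, 0))
  rec$U <- design$baseline_U + design$drag_effect * rec$drag +
    design$phase_effect * (rec$phase == "ascent") +
    offsets[rec$animal_id] +
    stats::rnorm(nrow(rec), 0, design$residual_sd)
  rec$U <- pmax(rec$U, .min_speed)
  rownames(rec) <- NULL
  list(records = rec[, c("animal_id", "U", "drag", "phase", "buoyancy",
                         "M_b", "depth", "condition")],
       coefficients = c(intercept = design$baseline_U,
                        drag = design$drag_effect,
                        phase = design$phase_effect,
                        animal_sd = design$animal_sd,
                        residual_sd = design$residual_sd),
       animal_offsets = offsets)
}
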