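# Small designs used across tests: full sensor-level simulation is expensive,
# so most tests run on one depth / few dives and only the acceptance suite
# runs the full default experiment.

small_design <- function(seed = 1L, ...) {
  experiment_design(depths = c(30, 50), dives_per_cell = 1, seed = seed, ...)
}

# noiseless design: deterministic kinematics, no sensor noise, no stroking
noiseless_design <- function(seed = 1L, ...) {
  experiment_design(animal_sd = 0, residual_sd = 0, depth_sd = 0,
                    accel_sd = 0, stroke_amp = 0, pitch_jitter_sd = 0,
                    seed = seed, ...)
}

# match phase summaries to the generator's ground truth; returns a data frame
# with recovered and programmed speed, pitch and duration per phase
join_truth <- function(phases, truth) {
  m <- match(paste(phases$trial_id, phases$dive_index),
             paste(truth$trial_id, truth$dive_index))
  stopifnot(!anyNA(m))
  desc <- phases$phase == "descent"
  data.frame(phases,
             U_prog = ifelse(desc, truth$U_descent[m], truth$U_ascent[m]),
             theta_prog = ifelse(desc, truth$pitch_descent[m], truth$pitch_ascent[m]),
             t_prog = ifelse(desc, truth$t_descent[m], truth$t_ascent[m]))
}

# one-trial metadata row
meta_row <- function(trial_id = "t1", depth = 50, condition = "C") {
  trial_meta(data.frame(trial_id = trial_id, animal_id = "F97HA",
                        condition = condition, body_mass_kg = 142.5,
                        target_depth_m = depth))
}

# summarize every trial of an in-memory simulation
process_trials_from_memory <- function(sim, params = kin_params()) {
  do.call(rbind, lapply(seq_len(nrow(sim$meta)), function(i)
    summarize_phases(sim$traces[[sim$meta$trial_id[i]]], sim$meta[i, ], params)))
}
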