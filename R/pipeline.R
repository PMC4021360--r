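#' Configuration of a full simulate-process-model-compare run
#'
#' @param out_dir Output directory for the run's tables and report.
#' @param seed Integer seed; forwarded to the experiment design.
#' @param design An [experiment_design()]; its seed is overridden by `seed`.
#' @param params A [kin_params()].
#' @param animals Named list of [animal_params()]; defaults
#'   [default_animals()]. Must cover every animal in the design.
#' @param spec A [tube_spec()] describing the attached tubes.
#' @param stages Named logical vector enabling the pipeline stages
#'   `simulate`, `process`, `model`, `compare`.
#' @param write_traces Also write the simulated trace file pairs under
#'   `out_dir/traces`? Default FALSE (the tables and report are always
#'   written when a stage runs).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("diveoptim_run_"), seed = 1L,
                       design = experiment_design(seed = seed),
                       params = kin_params(),
                       animals = default_animals(),
                       spec = tube_spec(),
                       stages = c(simulate = TRUE, process = TRUE,
                                  model = TRUE, compare = TRUE),
                       write_traces = FALSE) {
  design$seed <- seed
  st <- c(simulate = TRUE, process = TRUE, model = TRUE, compare = TRUE)
  st[names(stages)] <- stages
  structure(list(out_dir = out_dir, seed = seed, design = design,
                 params = params, animals = animals, spec = spec,
                 stages = st, write_traces = write_traces),
            class = "run_config")
}

#' Compare measured swim speeds to the predicted optima
#'
#' For every animal x condition cell: the mean measured swim speed (pooled
#' over descent and ascent, since the cost-of-transport model predicts a
#' single optimum regardless of phase) against the model's optimal speed,
#' computed with the animal's baseline drag coefficient for the control
#' condition and with the tube-composite coefficient ([combined_cd()]) for
#' the tube conditions.
#'
#' @param phases Phase-summary table.
#' @param animals Named list of [animal_params()].
#' @param meta A [trial_meta()] table.
#' @param spec A [tube_spec()].
#' @return Data frame with one row per animal x condition: mean measured
#'   `U_measured` (and its n), predicted `U_opt`, `C_D_used`, and absolute /
#'   relative differences.
#' @export
compare_to_optimal <- function(phases, animals, meta, spec = tube_spec()) {
  if (nrow(phases) == 0) stop("compare_to_optimal: empty phase table")
  rec <- speed_records(phases, meta)
  missing <- setdiff(unique(rec$animal_id), names(animals))
  if (length(missing))
    stop("compare_to_optimal: no animal parameters for: ",
         paste(missing, collapse = ", "))
  cells <- unique(rec[, c("animal_id", "condition")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    id <- cells$animal_id[i]; cond <- cells$condition[i]
    sel <- rec$animal_id == id & rec$condition == cond
    a <- animals[[id]]
    p <- animal_biomech(a, spec = if (cond == "C") NULL else spec)
    u_opt <- optimal_speed(p)
    u_meas <- mean(rec$U[sel])
    data.frame(animal_id = id, condition = cond, n_phases = sum(sel),
               U_measured = u_meas, U_opt = u_opt, C_D_used = p$C_D,
               abs_diff = u_meas - u_opt,
               rel_diff = (u_meas - u_opt) / u_opt)
  })
  out <- do.call(rbind, rows)
  out[order(out$animal_id, out$condition), ]
}

.stage <- function(report, name, out_dir, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    writeLines(paste0("FAILED at stage '", name, "': ", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("run_pipeline: stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  report$timings_s[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  list(report = report, value = res)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate the experiment, process
#' traces into phase summaries, rank the mixed models by AIC, and compare
#' measured speeds with the cost-of-transport optima — writing
#' `trials.csv`, `phases.csv`, `models.csv`, `comparison.csv` and a
#' machine-readable `report.json` under `config$out_dir`. The report
#' contains no timestamps, so a rerun with the same config and seed
#' produces an identical report; any stage error aborts the run, names the
#' failing stage and leaves a `FAILED` marker next to the partial outputs.
#'
#' @param config A [run_config()].
#' @return The report, invisibly: a list with per-condition x phase speed
#'   summaries, the model-selection table, the measured-vs-optimal
#'   comparison and provenance (seed, design echo, package version).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(config$out_dir, "FAILED"))
  report <- list(provenance = list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("diveoptim")),
    design = config$design[!vapply(config$design, is.data.frame, TRUE)],
    animals = config$design$animals,
    stages = as.list(config$stages)),
    timings_s = list())
  sim <- NULL; phases <- NULL; sel <- NULL; comparison <- NULL

  if (config$stages[["simulate"]]) {
    st <- .stage(report, "simulate", config$out_dir, {
      out <- simulate_experiment(config$design,
                                 out_dir = if (config$write_traces)
                                   file.path(config$out_dir, "traces") else NULL)
      write_trial_meta(out$meta, file.path(config$out_dir, "trials.csv"))
      out
    })
    report <- st$report; sim <- st$value
    report$n_trials <- nrow(sim$meta)
    report$n_dives <- nrow(sim$truth)
  }

  if (config$stages[["process"]]) {
    if (is.null(sim)) stop("run_pipeline: 'process' requires the simulate stage")
    st <- .stage(report, "process", config$out_dir, {
      ph <- do.call(rbind, lapply(seq_len(nrow(sim$meta)), function(i) {
        summarize_phases(sim$traces[[sim$meta$trial_id[i]]], sim$meta[i, ],
                         config$params)
      }))
      utils::write.csv(ph, file.path(config$out_dir, "phases.csv"), row.names = FALSE)
      ph
    })
    report <- st$report; phases <- st$value
    rec <- speed_records(phases, sim$meta)
    agg <- stats::aggregate(U ~ condition + phase, data = transform(
      rec, phase = ifelse(phase == 1, "ascent", "descent")),
      FUN = function(u) c(mean = mean(u), sd = stats::sd(u), n = length(u)))
    report$speed_summary <- data.frame(condition = agg$condition,
                                       phase = agg$phase,
                                       mean = agg$U[, "mean"],
                                       sd = agg$U[, "sd"], n = agg$U[, "n"])
  }

  if (config$stages[["model"]]) {
    if (is.null(phases)) stop("run_pipeline: 'model' requires the process stage")
    st <- .stage(report, "model", config$out_dir, {
      rec <- speed_records(phases, sim$meta)
      sel <- select_model(rec)
      utils::write.csv(sel$table, file.path(config$out_dir, "models.csv"),
                       row.names = FALSE)
      sel
    })
    report <- st$report; sel <- st$value
    top <- sel$fits[[1]]
    report$model_selection <- sel$table
    report$top_model <- list(terms = top$fixed_terms,
                             coefficients = as.list(top$coefficients),
                             sigma_re = top$sigma_re,
                             sigma_res = top$sigma_res,
                             aic = top$aic)
  }

  if (config$stages[["compare"]]) {
    if (is.null(phases)) stop("run_pipeline: 'compare' requires the process stage")
    st <- .stage(report, "compare", config$out_dir, {
      cmp <- compare_to_optimal(phases, config$animals, sim$meta, config$spec)
      utils::write.csv(cmp, file.path(config$out_dir, "comparison.csv"),
                       row.names = FALSE)
      cmp
    })
    report <- st$report; comparison <- st$value
    report$comparison <- comparison
  }

  report$timings_s <- NULL  # keep report.json free of run-dependent values
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(report)
}
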