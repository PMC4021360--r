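# Canonical units for each stream column. Depth is metres, positive down,
# surface = 0; acceleration in m s^-2, positive toward the head (surge) /
# venter-to-dorsum (heave); times are seconds from trial start.
.canonical_units <- c(time_s = "s", depth_m = "m", temp_c = "C",
                      accel_surge = "m s-2", accel_heave = "m s-2")

#' Construct a mixed-rate sensor trace for one trial
#'
#' A trial record holds two rectangular streams sampled at different rates:
#' a slow stream (depth and optional temperature, typically 1 Hz) and a fast
#' stream (longitudinal and dorso-ventral acceleration, typically 32 Hz).
#' The streams are kept separate; nothing is resampled.
#'
#' @param trial_id Trial identifier (also the file-name stem on disk).
#' @param depth_m Depth series (m, positive down). NA allowed.
#' @param accel_surge,accel_heave Acceleration series (m s^-2), same length.
#' @param temp_c Optional temperature series (deg C), same length as depth.
#' @param depth_rate_hz,accel_rate_hz Sampling rates (Hz).
#' @param time_1hz,time_32hz Optional explicit time stamps (s from trial
#'   start); default regular grids at the declared rates.
#' @return An object of class `sensor_trace`.
#' @export
sensor_trace <- function(trial_id, depth_m, accel_surge, accel_heave,
                         temp_c = NULL, depth_rate_hz = 1, accel_rate_hz = 32,
                         time_1hz = NULL, time_32hz = NULL) {
  n1 <- length(depth_m)
  n32 <- length(accel_surge)
  if (is.null(time_1hz)) time_1hz <- seq(0, by = 1 / depth_rate_hz, length.out = n1)
  if (is.null(time_32hz)) time_32hz <- seq(0, by = 1 / accel_rate_hz, length.out = n32)
  tr <- structure(list(
    trial_id = as.character(trial_id),
    depth_rate_hz = depth_rate_hz,
    accel_rate_hz = accel_rate_hz,
    slow = data.frame(time_s = time_1hz, depth_m = depth_m,
                      temp_c = if (is.null(temp_c)) rep(NA_real_, n1) else temp_c),
    fast = data.frame(time_s = time_32hz, accel_surge = accel_surge,
                      accel_heave = accel_heave)
  ), class = "sensor_trace")
  validate_sensor_trace(tr)
}

#' Validate a sensor trace against its structural invariants
#'
#' Checks (and never silently repairs): at least two samples per stream;
#' strictly increasing time; constant sampling interval matching the
#' declared rate; depth >= -0.5 m (small surface noise allowed); finite
#' accelerations; fast-stream length equal to `rate ratio x slow length`
#' within one slow-sample's worth of fast samples.
#'
#' @param trace A `sensor_trace`.
#' @param rate_tol Relative tolerance on the sampling interval. Default 0.01.
#' @return The trace, invisibly usable, if valid; otherwise an error.
#' @export
validate_sensor_trace <- function(trace, rate_tol = 0.01) {
  stopifnot(inherits(trace, "sensor_trace"))
  if (nrow(trace$slow) < 2L || nrow(trace$fast) < 2L)
    stop("sensor_trace: each stream needs at least 2 samples")
  for (stream in c("slow", "fast")) {
    tm <- trace[[stream]]$time_s
    if (any(!is.finite(tm)) || any(diff(tm) <= 0))
      stop("sensor_trace: time must be finite and strictly increasing (", stream, " stream)")
    rate <- if (stream == "slow") trace$depth_rate_hz else trace$accel_rate_hz
    dt <- diff(tm)
    if (any(abs(dt - 1 / rate) > rate_tol / rate))
      stop("sensor_trace: sampling interval deviates from declared rate_hz=",
           rate, " by more than tolerance (", stream, " stream)")
  }
  d <- trace$slow$depth_m
  if (any(d[is.finite(d)] < -0.5))
    stop("sensor_trace: depth_m below -0.5 m violates the positive-down convention")
  a <- c(trace$fast$accel_surge, trace$fast$accel_heave)
  if (any(is.na(a)) || any(!is.finite(a)))
    stop("sensor_trace: acceleration streams must be finite")
  ratio <- trace$accel_rate_hz / trace$depth_rate_hz
  if (abs(nrow(trace$fast) - ratio * nrow(trace$slow)) > ratio)
    stop("sensor_trace: fast stream length must be ", ratio,
         " x slow stream length within one slow sample")
  trace
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf("sensor_trace '%s': %d samples @ %g Hz (depth), %d @ %g Hz (accel), %.0f s\n",
              x$trial_id, nrow(x$slow), x$depth_rate_hz,
              nrow(x$fast), x$accel_rate_hz, max(x$slow$time_s)))
  invisible(x)
}

.write_stream <- function(df, path, trial_id, rate_hz, digits = 10) {
  units <- .canonical_units[names(df)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# trial_id=%s", trial_id),
               sprintf("# rate_hz=%.10g", rate_hz),
               sprintf("# units=%s", paste(names(df), units, sep = ":", collapse = ","))),
             con)
  out <- df
  for (j in seq_along(out)) out[[j]] <- formatC(out[[j]], digits = digits, format = "g")
  out[is.na(df)] <- ""
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  path
}

#' Write a sensor trace to a pair of CSV files
#'
#' Writes `<trial_id>_1hz.csv` (time, depth, temperature) and
#' `<trial_id>_32hz.csv` (time, accelerations) under `dir`. Each file starts
#' with `#`-prefixed `key=value` header lines declaring the trial id,
#' sampling rate and per-column units; missing values are written as empty
#' fields. Values keep 10 significant digits, so a read-back reproduces the
#' arrays to well below 1e-9 relative error.
#'
#' @param trace A valid `sensor_trace`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the two file paths (slow, fast), invisibly.
#' @export
write_sensor_trace <- function(trace, dir) {
  validate_sensor_trace(trace)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, mode = 2) != 0) stop("write_sensor_trace: directory not writable: ", dir)
  slow_path <- file.path(dir, paste0(trace$trial_id, "_1hz.csv"))
  fast_path <- file.path(dir, paste0(trace$trial_id, "_32hz.csv"))
  .write_stream(trace$slow, slow_path, trace$trial_id, trace$depth_rate_hz)
  .write_stream(trace$fast, fast_path, trace$trial_id, trace$accel_rate_hz)
  invisible(c(slow_path, fast_path))
}

.read_stream <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("read_sensor_trace: file not found: ", path)
  lines <- readLines(path, n = 50)
  hdr_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in hdr_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  if (is.null(meta$rate_hz)) stop("read_sensor_trace: header missing rate_hz in ", path)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!is.null(schema)) {
    # schema maps canonical name -> file column name; entries absent from
    # this stream's file belong to the other stream
    for (canon in names(schema)) {
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  units <- character(0)
  if (!is.null(meta$units)) {
    pairs <- strsplit(strsplit(meta$units, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    units <- stats::setNames(vapply(pairs, `[`, "", 2), vapply(pairs, `[`, "", 1))
    if (!is.null(schema)) {
      idx <- match(names(units), unlist(schema))
      names(units)[!is.na(idx)] <- names(schema)[idx[!is.na(idx)]]
    }
  }
  for (col in intersect(names(units), names(.canonical_units))) {
    if (units[[col]] != .canonical_units[[col]])
      stop("read_sensor_trace: unit error for '", col, "': got '", units[[col]],
           "', expected '", .canonical_units[[col]], "' in ", path)
  }
  list(df = df, rate_hz = as.numeric(meta$rate_hz),
       trial_id = meta$trial_id %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a sensor trace from its CSV file pair
#'
#' Counterpart of [write_sensor_trace()]: reads `<trial_id>_1hz.csv` and
#' `<trial_id>_32hz.csv` from `dir`, checks the declared units against the
#' package's canonical units (metres, m s^-2, seconds), verifies the
#' declared sampling rates against the time stamps, and returns a validated
#' [sensor_trace()]. Streams are never resampled.
#'
#' @param dir Directory holding the file pair.
#' @param trial_id Trial identifier (file-name stem).
#' @param schema Optional named character vector mapping canonical column
#'   names (`time_s`, `depth_m`, `temp_c`, `accel_surge`, `accel_heave`) to
#'   the column names used in the files.
#' @return A validated `sensor_trace`.
#' @export
read_sensor_trace <- function(dir, trial_id, schema = NULL) {
  slow <- .read_stream(file.path(dir, paste0(trial_id, "_1hz.csv")), schema)
  fast <- .read_stream(file.path(dir, paste0(trial_id, "_32hz.csv")), schema)
  need_slow <- c("time_s", "depth_m")
  need_fast <- c("time_s", "accel_surge", "accel_heave")
  miss <- setdiff(need_slow, names(slow$df))
  if (length(miss)) stop("read_sensor_trace: missing column '", miss[1], "' in 1 Hz stream")
  miss <- setdiff(need_fast, names(fast$df))
  if (length(miss)) stop("read_sensor_trace: missing column '", miss[1], "' in 32 Hz stream")
  sensor_trace(trial_id,
               depth_m = slow$df$depth_m,
               accel_surge = fast$df$accel_surge,
               accel_heave = fast$df$accel_heave,
               temp_c = if ("temp_c" %in% names(slow$df)) slow$df$temp_c else NULL,
               depth_rate_hz = slow$rate_hz, accel_rate_hz = fast$rate_hz,
               time_1hz = slow$df$time_s, time_32hz = fast$df$time_s)
}

#' Construct and validate a per-trial metadata table
#'
#' One row per trial: trial id, animal id, experimental condition, body mass
#' that morning and the fixed feeding depth of the trial's dives.
#' Conditions: `C` (harness only), `AD` (flooded tubes: added drag), `BN`
#' (lead-ballasted tubes: negative buoyancy), `BP` (air-filled tubes:
#' positive buoyancy).
#'
#' @param df Data frame with columns `trial_id`, `animal_id`, `condition`,
#'   `body_mass_kg`, `target_depth_m`.
#' @param max_depth_m Ceiling on target depth (m). Default 50.
#' @return The validated data frame, with `condition` as a factor.
#' @export
trial_meta <- function(df, max_depth_m = 50) {
  need <- c("trial_id", "animal_id", "condition", "body_mass_kg", "target_depth_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trial_meta: missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$condition %in% c("C", "AD", "BN", "BP")))
    stop("trial_meta: condition must be one of C, AD, BN, BP")
  if (any(df$target_depth_m <= 0) || any(df$target_depth_m > max_depth_m))
    stop("trial_meta: target_depth_m must lie in (0, ", max_depth_m, "]")
  if (any(df$body_mass_kg <= 0)) stop("trial_meta: body_mass_kg must be positive")
  df$condition <- factor(df$condition, levels = c("C", "AD", "BN", "BP"))
  df
}

#' Read / write the trial metadata table
#'
#' @param path CSV path (one row per trial).
#' @param meta Data frame accepted by [trial_meta()].
#' @param ... Passed to [trial_meta()] (e.g. `max_depth_m`).
#' @return `read_trial_meta` returns the validated data frame;
#'   `write_trial_meta` returns `path` invisibly.
#' @export
read_trial_meta <- function(path, ...) {
  if (!file.exists(path)) stop("read_trial_meta: file not found: ", path)
  trial_meta(utils::read.csv(path, comment.char = "#"), ...)
}

#' @rdname read_trial_meta
#' @export
write_trial_meta <- function(meta, path) {
  meta <- trial_meta(as.data.frame(meta))
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
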