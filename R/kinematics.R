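# Gravitational acceleration used throughout the pitch conversion. 9.8 m s^-2
# exactly: samples whose filtered longitudinal acceleration exceeds this in
# magnitude cannot be converted to an angle and are marked undefined.
.g <- 9.8

#' Segmentation and filtering parameters for dive-phase extraction
#'
#' @param cutoff_hz Low-pass cutoff separating the gravitational (static)
#'   from the stroking (dynamic) component of acceleration. Default 0.5 Hz,
#'   below typical otariid stroke frequencies (> 1 Hz).
#' @param pitch_thresh_deg Pitch magnitude that counts as "heading down/up"
#'   (degrees). Default 10.
#' @param sustain_s Seconds the pitch threshold must be sustained to start a
#'   phase. Default 3.
#' @param submerge_thresh_m Depth that counts as submerged (m). Default 2.
#' @param surface_thresh_m Depth that counts as back at the surface (m).
#'   Default 0.5.
#' @param depth_tol_m Slack below the target depth at which the descent is
#'   considered to have reached it (m). Default 2.
#' @param max_gap_frac Maximum tolerated fraction of undefined pitch samples
#'   within a phase before the dive is flagged. Default 0.25.
#' @param refine Refine phase boundaries by extrapolating the interior
#'   constant vertical speed to the surface and the target depth (see
#'   [segment_phases()])? Default TRUE.
#' @param interior_frac Two fractions of the target depth bounding the
#'   interior of a transit phase over which the mean pitch is taken; kept
#'   well clear of the phase edges, where the low-pass pitch estimate is
#'   still settling. Default c(0.2, 0.8).
#' @param fit_frac Two fractions of the target depth bounding the depth
#'   samples used for the boundary-refinement line fit. Wider than
#'   `interior_frac` (the depth ramp, unlike the filtered pitch, is clean
#'   right up to the phase edges). Default c(0.1, 0.9).
#' @return A list of class `kin_params`.
#' @export
kin_params <- function(cutoff_hz = 0.5, pitch_thresh_deg = 10, sustain_s = 3,
                       submerge_thresh_m = 2, surface_thresh_m = 0.5,
                       depth_tol_m = 2, max_gap_frac = 0.25,
                       refine = TRUE, interior_frac = c(0.2, 0.8),
                       fit_frac = c(0.1, 0.9)) {
  stopifnot(cutoff_hz > 0, pitch_thresh_deg > 0, sustain_s >= 1,
            submerge_thresh_m > surface_thresh_m, surface_thresh_m > 0,
            depth_tol_m >= 0, max_gap_frac > 0, max_gap_frac < 1,
            length(interior_frac) == 2, interior_frac[1] < interior_frac[2],
            length(fit_frac) == 2, fit_frac[1] < fit_frac[2])
  structure(as.list(environment()), class = "kin_params")
}

# Zero-phase Butterworth low-pass with reflection padding. signal::filtfilt
# starts from zero initial conditions, which corrupts the first/last few
# time constants; padding with edge-reflected data pushes the transient
# outside the retained window.
.lowpass <- function(x, rate_hz, cutoff_hz, order = 2) {
  npad <- min(length(x) - 1L, ceiling(3 * rate_hz / cutoff_hz))
  pad_l <- 2 * x[1] - x[seq(npad + 1, 2)]
  pad_r <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - npad)]
  bf <- signal::butter(order, cutoff_hz / (rate_hz / 2), type = "low")
  y <- signal::filtfilt(bf, c(pad_l, x, pad_r))
  y[seq(npad + 1, npad + length(x))]
}

#' Pitch angle from longitudinal acceleration
#'
#' Extracts the gravitational (static) component of the surge acceleration
#' with a zero-phase low-pass filter and converts it to pitch:
#' `pitch = asin(static / 9.8)` in degrees, negative = head-down. Samples
#' whose static component exceeds 9.8 m s^-2 in magnitude cannot be
#' converted and are returned as NA. The result is decimated to 1 Hz by
#' averaging each second's defined samples (NA when more than half the
#' second is undefined), aligned with the depth samples.
#'
#' @param accel_surge Longitudinal acceleration (m s^-2), sampled at
#'   `rate_hz`, positive toward the head.
#' @param rate_hz Sampling rate (Hz). Must exceed `2 * cutoff_hz`.
#' @param cutoff_hz Low-pass cutoff (Hz). Default 0.5.
#' @return A data frame (`pitch_series`) with `time_s` (1 Hz, starting at 0)
#'   and `pitch_deg` in \[-90, 90\] or NA.
#' @export
pitch_from_accel <- function(accel_surge, rate_hz = 32, cutoff_hz = 0.5) {
  if (!(rate_hz > 2 * cutoff_hz) || cutoff_hz <= 0)
    stop("pitch_from_accel: need rate_hz > 2 * cutoff_hz > 0")
  if (any(!is.finite(accel_surge)))
    stop("pitch_from_accel: non-finite acceleration input")
  if (length(accel_surge) < 3 * rate_hz / cutoff_hz)
    stop("pitch_from_accel: series shorter than the filter warm-up (",
         ceiling(3 * rate_hz / cutoff_hz), " samples)")
  static <- .lowpass(accel_surge, rate_hz, cutoff_hz)
  pitch <- ifelse(abs(static) > .g, NA_real_, asin(pmin(1, pmax(-1, static / .g))) * 180 / pi)
  # decimate to 1 Hz: mean of each second's defined samples
  nsec <- floor(length(pitch) / rate_hz)
  idx <- rep(seq_len(nsec), each = rate_hz)
  p1 <- vapply(seq_len(nsec), function(i) {
    block <- pitch[idx == i]
    if (mean(is.na(block)) > 0.5) NA_real_ else mean(block, na.rm = TRUE)
  }, numeric(1))
  structure(data.frame(time_s = seq_len(nsec) - 1, pitch_deg = p1),
            class = c("pitch_series", "data.frame"))
}

#' Vertical speed from the depth series
#'
#' First differences of depth over each 1 s interval; positive while
#' descending (depth is positive down).
#'
#' @param depth_m Depth series at 1 Hz (m).
#' @return Numeric vector of length `length(depth_m) - 1` (m s^-1).
#' @export
vertical_speed <- function(depth_m) {
  if (length(depth_m) < 2) stop("vertical_speed: need at least 2 samples")
  diff(depth_m)
}

#' Swim speed along the movement path
#'
#' Converts a transit phase's fixed depth, duration and mean absolute pitch
#' into speed along the swimming path: `U = d / (t * sin(theta))`. With
#' theta = 90 deg (vertical dive) this reduces to the vertical speed `d/t`;
#' shallower pitches lengthen the path and increase U above the vertical
#' speed.
#'
#' @param d Fixed (target) depth of the dive (m), > 0.
#' @param t Phase duration (s), > 0.
#' @param theta_deg Mean absolute pitch over the phase, in (0, 90\].
#' @return Swim speed (m s^-1). Vectorised.
#' @export
swim_speed <- function(d, t, theta_deg) {
  if (any(!is.finite(d)) || any(d <= 0)) stop("swim_speed: d must be positive")
  if (any(!is.finite(t)) || any(t <= 0)) stop("swim_speed: t must be positive")
  if (any(!is.finite(theta_deg)) || any(theta_deg <= 0) || any(theta_deg > 90))
    stop("swim_speed: theta_deg must lie in (0, 90]; the speed along the path is undefined otherwise")
  d / (t * sin(theta_deg * pi / 180))
}

# first index >= from at which `cond` (logical vector) holds for `len`
# consecutive samples; NA if none
.first_sustained <- function(cond, from, len) {
  cond[is.na(cond)] <- FALSE
  n <- length(cond)
  if (from > n) return(NA_integer_)
  r <- rle(cond[from:n])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= len)
  if (!length(ok)) return(NA_integer_)
  from + starts[ok[1]] - 1L
}

#' Segment a trace into descent and ascent phases
#'
#' Identifies dives (excursions below the submergence threshold) and, within
#' each, the descent (from the first sustained head-down pitch until the
#' target depth is reached) and the ascent (from the first sustained head-up
#' pitch after the bottom until the surface). The bottom interval is
#' excluded. Dives that never get within `depth_tol_m` of the target depth,
#' or whose candidate phases have too many undefined pitch samples, are
#' flagged, skipped and reported with a warning.
#'
#' With `params$refine = TRUE` (default) the threshold-based boundaries are
#' refined: a line is fit to the depth samples in the interior of each
#' transit (between `interior_frac` of the target depth, where vertical
#' speed is constant in a quasi-steady transit) and extrapolated to the
#' surface (0 m) and to the target depth. This removes the 1 Hz
#' quantisation and threshold-offset bias from the durations, which matters
#' for shallow dives whose transit lasts only a few seconds.
#'
#' @param depth_m Depth series at 1 Hz (m, positive down).
#' @param pitch A `pitch_series` from [pitch_from_accel()], aligned with
#'   `depth_m` (same 1 Hz grid from time 0).
#' @param target_depth_m The dive's fixed feeding depth (m).
#' @param params A [kin_params()] object.
#' @return Data frame with columns `dive_index`, `phase`
#'   ("descent"/"ascent"), `start_s`, `end_s` (possibly fractional when
#'   refined). Empty (0 rows) when no dive is found.
#' @export
segment_phases <- function(depth_m, pitch, target_depth_m, params = kin_params()) {
  stopifnot(inherits(params, "kin_params"))
  if (target_depth_m <= params$submerge_thresh_m)
    stop("segment_phases: target_depth_m must exceed the submergence threshold")
  n <- min(length(depth_m), nrow(pitch))
  d <- depth_m[seq_len(n)]
  p <- pitch$pitch_deg[seq_len(n)]
  tm <- seq_len(n) - 1  # 1 Hz grid starting at 0
  out <- data.frame(dive_index = integer(0), phase = character(0),
                    start_s = numeric(0), end_s = numeric(0))

  submerged <- !is.na(d) & d > params$submerge_thresh_m
  r <- rle(submerged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  epi <- which(r$values)
  dive_index <- 0L
  prev_end <- 1L
  for (e in epi) {
    i0 <- starts[e]; i1 <- ends[e]
    if (max(d[i0:i1], na.rm = TRUE) < target_depth_m - params$depth_tol_m) {
      warning("segment_phases: dive starting at t=", tm[i0],
              " s never reached the target depth; flagged and skipped")
      prev_end <- i1
      next
    }
    # descent start: first sustained head-down pitch after the previous dive
    ds <- .first_sustained(p < -params$pitch_thresh_deg, prev_end, params$sustain_s)
    if (is.na(ds) || ds > i1) { prev_end <- i1; next }
    # descent end: first sample at/below target - tol
    de <- ds + which(d[ds:i1] >= target_depth_m - params$depth_tol_m)[1] - 1L
    # ascent start: first sustained head-up pitch after the descent end
    as_ <- .first_sustained(p > params$pitch_thresh_deg, de + 1L, params$sustain_s)
    if (is.na(as_)) { prev_end <- i1; next }
    # ascent end: first return to the surface threshold
    ae_rel <- which(d[as_:n] <= params$surface_thresh_m)
    if (!length(ae_rel)) { prev_end <- i1; next }
    ae <- as_ + ae_rel[1] - 1L

    gap_desc <- mean(is.na(p[ds:de]))
    gap_asc <- mean(is.na(p[as_:ae]))
    if (gap_desc > params$max_gap_frac || gap_asc > params$max_gap_frac) {
      warning("segment_phases: dive starting at t=", tm[ds],
              " s has undefined pitch over more than ",
              round(100 * params$max_gap_frac), "% of a phase; flagged and skipped")
      prev_end <- ae
      next
    }
    dive_index <- dive_index + 1L
    bounds <- rbind(descent = c(tm[ds], tm[de]), ascent = c(tm[as_], tm[ae]))
    if (params$refine) {
      bounds["descent", ] <- .refine_bounds(tm, d, ds, de, target_depth_m,
                                            params, descending = TRUE) %||%
        bounds["descent", ]
      bounds["ascent", ] <- .refine_bounds(tm, d, as_, ae, target_depth_m,
                                           params, descending = FALSE) %||%
        bounds["ascent", ]
    }
    out <- rbind(out, data.frame(dive_index = dive_index,
                                 phase = c("descent", "ascent"),
                                 start_s = bounds[, 1], end_s = bounds[, 2]))
    prev_end <- ae
  }
  rownames(out) <- NULL
  out
}

# Fit depth ~ time over the interior of a transit and extrapolate to the
# surface (0 m) and the target depth; returns c(start, end) in seconds, or
# NULL when fewer than 3 interior samples are available or the fit is
# degenerate (refinement then falls back to the threshold boundaries).
.refine_bounds <- function(tm, d, i0, i1, target, params, descending) {
  lo <- params$fit_frac[1] * target
  hi <- params$fit_frac[2] * target
  idx <- i0:i1
  idx <- idx[!is.na(d[idx]) & d[idx] >= lo & d[idx] <= hi]
  if (length(idx) < 3) return(NULL)
  fit <- stats::lm.fit(cbind(1, tm[idx]), d[idx])
  a <- fit$coefficients[2]; b <- fit$coefficients[1]
  if (!is.finite(a) || (descending && a <= 0) || (!descending && a >= 0)) return(NULL)
  t_surface <- -b / a
  t_target <- (target - b) / a
  bounds <- if (descending) c(t_surface, t_target) else c(t_target, t_surface)
  # guard: refined boundaries must stay near the threshold-based ones
  if (abs(bounds[1] - tm[i0]) > 5 || abs(bounds[2] - tm[i1]) > 5) return(NULL)
  bounds
}

#' Per-phase kinematic summaries for one trial
#'
#' Composes [pitch_from_accel()], [segment_phases()] and [swim_speed()]:
#' for every detected descent and ascent, reports the phase duration, the
#' mean absolute pitch over the phase's defined samples (interior samples
#' when refinement is on), the mean vertical speed and the pitch-corrected
#' swim speed `U = d / (t * sin(theta))` with `d` the trial's target depth.
#'
#' @param trace A [sensor_trace()].
#' @param meta_row One row of a [trial_meta()] table (list or 1-row data
#'   frame with `trial_id`, `target_depth_m`).
#' @param params A [kin_params()].
#' @return Data frame with one row per phase: `trial_id`, `dive_index`,
#'   `phase`, `d`, `t`, `theta_deg`, `v_vertical`, `U`. Zero rows when the
#'   trace contains no dive.
#' @export
summarize_phases <- function(trace, meta_row, params = kin_params()) {
  validate_sensor_trace(trace)
  target <- meta_row$target_depth_m
  pitch <- pitch_from_accel(trace$fast$accel_surge, trace$accel_rate_hz,
                            params$cutoff_hz)
  seg <- segment_phases(trace$slow$depth_m, pitch, target, params)
  empty <- data.frame(trial_id = character(0), dive_index = integer(0),
                      phase = character(0), d = numeric(0), t = numeric(0),
                      theta_deg = numeric(0), v_vertical = numeric(0),
                      U = numeric(0))
  if (nrow(seg) == 0) return(empty)
  d1 <- trace$slow$depth_m
  tm <- seq_along(d1) - 1
  rows <- lapply(seq_len(nrow(seg)), function(i) {
    s <- seg[i, ]
    # integer-grid samples covered by the phase
    i0 <- max(1L, ceiling(s$start_s) + 1L)
    i1 <- min(length(d1), floor(s$end_s) + 1L)
    lo <- params$interior_frac[1] * target
    hi <- params$interior_frac[2] * target
    in_phase <- i0:i1
    interior <- in_phase[!is.na(d1[in_phase]) & d1[in_phase] >= lo & d1[in_phase] <= hi]
    use <- if (params$refine && length(interior) >= 3) interior else in_phase
    theta <- mean(abs(pitch$pitch_deg[use]), na.rm = TRUE)
    theta <- min(theta, 90)
    t_phase <- s$end_s - s$start_s
    vs <- vertical_speed(d1[min(use):max(use)])
    data.frame(trial_id = trace$trial_id, dive_index = s$dive_index,
               phase = s$phase, d = target, t = t_phase, theta_deg = theta,
               v_vertical = mean(abs(vs)),
               U = swim_speed(target, t_phase, theta))
  })
  do.call(rbind, rows)
}

#' Process a directory of trials into a phase table
#'
#' Reads every trial listed in the metadata table from `dir` (file pairs
#' written by [write_sensor_trace()]) and stacks their
#' [summarize_phases()] output.
#'
#' @param dir Directory with the trace file pairs.
#' @param meta A [trial_meta()] table.
#' @param params A [kin_params()].
#' @return Data frame of phase summaries across all trials.
#' @export
process_trials <- function(dir, meta, params = kin_params()) {
  res <- lapply(seq_len(nrow(meta)), function(i) {
    trace <- read_sensor_trace(dir, meta$trial_id[i])
    summarize_phases(trace, meta[i, ], params)
  })
  do.call(rbind, res)
}
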