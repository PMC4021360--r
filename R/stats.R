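# The five candidate fixed effects for the swim-speed model and their
# column names in a speed-record table.
.candidate_terms <- c(drag = "drag", phase = "phase", buoyancy = "buoyancy",
                      M_b = "M_b", depth = "depth")

#' Build swim-speed records from phase summaries and trial metadata
#'
#' Joins the kinematic phase table to the trial metadata and encodes the
#' model covariates: `drag` is binary (1 for any tube condition AD/BN/BP,
#' 0 for control), `phase` is binary (1 = ascent), `buoyancy` is an ordered
#' score (-1 ballasted, 0 control/flooded, +1 air-filled; optionally the
#' estimated net force in N via `buoyancy_N`), plus body mass and depth.
#'
#' @param phases Phase-summary data frame from [summarize_phases()] /
#'   [process_trials()].
#' @param meta A [trial_meta()] table.
#' @param buoyancy_N Optional named vector of net buoyant forces (N) per
#'   condition to use instead of the ordinal -1/0/+1 score.
#' @return Data frame of speed records, one per dive-phase.
#' @export
speed_records <- function(phases, meta, buoyancy_N = NULL) {
  m <- match(phases$trial_id, meta$trial_id)
  if (any(is.na(m))) stop("speed_records: phases reference trials absent from meta")
  cond <- as.character(meta$condition[m])
  buoy <- if (is.null(buoyancy_N)) {
    ifelse(cond == "BN", -1, ifelse(cond == "BP", 1, 0))
  } else {
    unname(buoyancy_N[cond])
  }
  data.frame(animal_id = meta$animal_id[m],
             U = phases$U,
             drag = as.numeric(cond != "C"),
             phase = as.numeric(phases$phase == "ascent"),
             buoyancy = buoy,
             M_b = meta$body_mass_kg[m],
             depth = meta$target_depth_m[m],
             condition = cond)
}

#' Fit a Gaussian linear mixed model of swim speed
#'
#' Fits `U ~ 1 + <fixed_terms> + (1 | animal_id)` by maximum likelihood
#' (ML, not REML, so log-likelihoods and AIC are comparable across models
#' with different fixed effects). Candidate terms: `drag`, `phase`,
#' `buoyancy`, `M_b`, `depth`.
#'
#' A boundary (singular) fit with zero between-animal variance is returned
#' with `sigma_re = 0` and `singular = TRUE`, not raised as an error.
#'
#' @param records Speed-record data frame (see [speed_records()] or
#'   [simulate_speed_table()]); `phase` may be given as "descent"/"ascent"
#'   strings or 0/1.
#' @param fixed_terms Character vector, a subset of the five candidate
#'   terms. Empty = intercept-only.
#' @return An object of class `model_fit`: list with `fixed_terms`,
#'   `coefficients` (intercept + one per term), `se`, `sigma_re`,
#'   `sigma_res`, `loglik`, `n_params` (fixed effects incl. intercept + 2
#'   variance components), `aic = 2 * n_params - 2 * loglik`, `n_obs`,
#'   `singular`, and the underlying `lme4` fit as `fit`.
#' @export
fit_lmm <- function(records, fixed_terms = character(0)) {
  records <- as.data.frame(records)
  if (is.character(records$phase) || is.factor(records$phase))
    records$phase <- as.numeric(as.character(records$phase) == "ascent")
  bad <- setdiff(fixed_terms, .candidate_terms)
  if (length(bad)) stop("fit_lmm: unknown term(s): ", paste(bad, collapse = ", "))
  if (length(unique(records$animal_id)) < 2)
    stop("fit_lmm: need records from at least 2 animals to estimate a random intercept")
  n_fixed <- length(fixed_terms) + 1L
  if (nrow(records) < n_fixed + 2L + 2L)
    stop("fit_lmm: too few records for ", n_fixed, " fixed-effect parameters")
  X <- stats::model.matrix(
    stats::reformulate(c("1", fixed_terms)), data = records)
  if (qr(X)$rank < ncol(X)) {
    keep <- qr(X)$pivot[seq_len(qr(X)$rank)]
    stop("fit_lmm: rank-deficient design; collinear term(s): ",
         paste(setdiff(colnames(X), colnames(X)[keep]), collapse = ", "))
  }
  fml <- stats::as.formula(paste(
    "U ~", paste(c("1", fixed_terms), collapse = " + "), "+ (1 | animal_id)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = records, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))))
  vc <- lme4::VarCorr(fit)
  sigma_re <- attr(vc$animal_id, "stddev")[[1]]
  # boundary fit: no resolvable between-animal variance (absolute floor
  # covers the all-but-noise-free case where both variances underflow)
  singular <- lme4::isSingular(fit) || sigma_re < 1e-6 * stats::sd(records$U)
  if (singular && sigma_re < 1e-6 * stats::sd(records$U)) sigma_re <- 0
  ll <- as.numeric(stats::logLik(fit))
  n_params <- n_fixed + 2L
  structure(list(fixed_terms = fixed_terms,
                 coefficients = lme4::fixef(fit),
                 se = stats::setNames(sqrt(diag(as.matrix(stats::vcov(fit)))),
                                      names(lme4::fixef(fit))),
                 sigma_re = sigma_re,
                 sigma_res = stats::sigma(fit),
                 loglik = ll,
                 n_params = n_params,
                 aic = 2 * n_params - 2 * ll,
                 n_obs = nrow(records),
                 singular = singular,
                 fit = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  terms <- if (length(x$fixed_terms)) paste(x$fixed_terms, collapse = " + ") else "1"
  cat(sprintf("Swim-speed LMM (ML): U ~ %s + (1 | animal)\n", terms))
  print(round(x$coefficients, 4))
  cat(sprintf("  sigma_re = %.4g, sigma_res = %.4g, logLik = %.2f, AIC = %.2f%s\n",
              x$sigma_re, x$sigma_res, x$loglik, x$aic,
              if (x$singular) " (singular fit)" else ""))
  invisible(x)
}

#' All subsets of the candidate fixed-effect terms
#'
#' @param terms Character vector of candidate terms.
#' @return List of character vectors (including the empty set), ordered by
#'   size then lexicographically.
#' @export
candidate_sets <- function(terms = unname(.candidate_terms)) {
  sets <- list(character(0))
  for (k in seq_along(terms)) {
    combos <- utils::combn(sort(terms), k, simplify = FALSE)
    sets <- c(sets, combos)
  }
  sets
}

#' Rank candidate swim-speed models by AIC
#'
#' Fits every candidate fixed-effect subset (all 32 subsets of drag, phase,
#' buoyancy, body mass and depth by default) with [fit_lmm()] and ranks the
#' fits by AIC, breaking ties by fewer terms and then lexicographically by
#' the term names.
#'
#' @param records Speed-record data frame.
#' @param sets List of character vectors of terms; default [candidate_sets()].
#' @return A list of class `model_selection`: `table` (data frame with one
#'   row per model: `terms`, `n_terms`, `loglik`, `n_params`, `aic`,
#'   `delta_aic`, in rank order) and `fits` (the `model_fit` objects in the
#'   same order).
#' @export
select_model <- function(records, sets = candidate_sets()) {
  fits <- lapply(sets, function(s) fit_lmm(records, s))
  lab <- vapply(fits, function(f) {
    if (length(f$fixed_terms)) paste(sort(f$fixed_terms), collapse = "+") else "(intercept)"
  }, "")
  tab <- data.frame(terms = lab,
                    n_terms = vapply(fits, function(f) length(f$fixed_terms), 1L),
                    loglik = vapply(fits, function(f) f$loglik, 1),
                    n_params = vapply(fits, function(f) f$n_params, 1L),
                    aic = vapply(fits, function(f) f$aic, 1))
  ord <- order(tab$aic, tab$n_terms, tab$terms)
  tab <- tab[ord, ]
  fits <- fits[ord]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits), class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Swim-speed model selection (ML, AIC ascending):\n")
  print(utils::head(transform(x$table, loglik = round(loglik, 2),
                              aic = round(aic, 2),
                              delta_aic = round(delta_aic, 2)), 10))
  invisible(x)
}
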