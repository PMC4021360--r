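#!/usr/bin/env Rscript

# Step 3: which covariates predict swim speed?
#
# Gaussian linear mixed models of swim speed with a per-animal random
# intercept, fit by ML over all 32 subsets of {drag, phase, buoyancy, body
# mass, depth} and ranked by AIC. The generator put real effects only on
# drag (tubes slow the animals down) and dive phase (ascents are faster):
# drag and phase should dominate the ranking, with buoyancy, mass and depth
# contributing nothing beyond AIC's usual tolerance for one spurious term.

suppressMessages(library(diveoptim))

meta <- read_trial_meta("results/simulation/trials.csv")
phases <- read.csv("results/phases.csv")
records <- speed_records(phases, meta)
cat("Fitting 32 candidate models to", nrow(records), "dive-phase records...\n")

sel <- select_model(records)
write.csv(sel$table, "results/models.csv", row.names = FALSE)
cat("Wrote results/models.csv. Top of the AIC ranking:\n")
print(head(transform(sel$table, loglik = round(loglik, 1), aic = round(aic, 1),
                     delta_aic = round(delta_aic, 1)), 5), row.names = FALSE)

top <- sel$fits[[1]]
cat("\nBest model: U ~", paste(c("1", top$fixed_terms), collapse = " + "),
    "+ (1 | animal)\n")
print(round(top$coefficients, 3))
cat(sprintf("Random-intercept SD %.3f, residual SD %.3f (programmed: 0.10, 0.15)\n",
            top$sigma_re, top$sigma_res))

stopifnot(all(c("drag", "phase") %in% top$fixed_terms))
rank_dp <- which(sel$table$terms == "drag+phase")
cat(sprintf("\nDrag and phase are both retained; {drag, phase} alone ranks #%d (delta AIC %.1f).\n",
            rank_dp, sel$table$delta_aic[rank_dp]))
extra <- setdiff(top$fixed_terms, c("drag", "phase"))
if (length(extra)) {
  cat("Spurious term(s) retained this run:", paste(extra, collapse = ", "),
      "with estimate(s)", paste(round(top$coefficients[extra], 3), collapse = ", "),
      "-- AIC admits a noise covariate whenever its LRT statistic exceeds 2\n",
      "(about a 16% chance per term), so this is expected behaviour, and the\n",
      "spurious estimates are near zero next to drag's.\n")
} else {
  cat("No spurious covariate survived the penalty in this run.\n")
}
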