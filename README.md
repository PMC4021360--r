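# diveoptim

Drag, buoyancy and optimal swim speed in diving Steller sea lions — a
tested reimplementation of the analysis behind controlled dive trials in
which three trained sea lions dove to fixed depths (10–50 m) wearing a
harness with a pair of PVC tubes that manipulated their drag and buoyancy
(control `C`, added drag `AD`, lead-ballasted `BN`, air-filled `BP`), while
a logger recorded depth at 1 Hz and two-axis acceleration at 32 Hz.

The package is for biologging / dive-biomechanics researchers who want the
full chain as reusable, unit-tested functions:

1. **biologger I/O** — mixed-rate CSV trace pairs with unit-checked
   headers, trial metadata (`read_sensor_trace()`, `trial_meta()`, ...);
2. **kinematics** — pitch from the gravitational component of surge
   acceleration (zero-phase low-pass, `asin(a/9.8)`), descent/ascent
   segmentation, and pitch-corrected swim speed
   `U = d / (t sin θ)` (`pitch_from_accel()`, `segment_phases()`,
   `summarize_phases()`);
3. **biomechanics** — the cost-of-transport model and its closed-form
   optimum

   `U_opt = (ε_p ε_A k / (ρ_w λ C_D S))^(1/3)`

   which rises with metabolic power `k` and falls with drag area `C_D S`,
   and is independent of buoyancy and depth by construction; plus the
   composite drag coefficient of an animal carrying tubes, allometric
   wetted area `S = 0.056 M_b^(2/3)`, and buoyancy/ballast arithmetic
   (`cot()`, `optimal_speed()`, `combined_cd()`, `ballast_for_target()`);
4. **stats** — Gaussian mixed models `U ~ terms + (1 | animal)` fit by ML
   and ranked by AIC over all 32 subsets of {drag, phase, buoyancy, body
   mass, depth} (`fit_lmm()`, `select_model()`);
5. **synthetic data** — a generator emulating the experimental design with
   known ground truth, so every stage is validated end to end
   (`experiment_design()`, `simulate_experiment()`).

## Worked example

```r
library(diveoptim)

# the COT model for a 142.5 kg sea lion calibrated to a 1.8 m/s optimum
# at the control drag coefficient C_D = 0.004
a <- default_animals()$F97HA
p <- animal_biomech(a)
optimal_speed(p)                         # 1.8  (m/s)
cot(optimal_speed(p), p)                 # 254.2 J/m at the optimum ...
cot(1.0, p)                              # 331.2 J/m crawling
cot(3.0, p)                              # 337.0 J/m sprinting

# carrying the tube pair: composite drag coefficient and slower optimum
pt <- animal_biomech(a, spec = tube_spec())
pt$C_D                                   # 0.0157 (vs 0.004 bare)
optimal_speed(pt)                        # 1.14 m/s

# simulate a trial and recover the programmed speeds from the raw streams
des <- experiment_design(depths = c(30, 50), dives_per_cell = 1, seed = 42)
sim <- simulate_experiment(des)
summarize_phases(sim$traces[["F97HA_C_50m"]],
                 sim$meta[sim$meta$trial_id == "F97HA_C_50m", ])
#>      trial_id dive_index   phase  d    t theta_deg v_vertical    U
#> 1 F97HA_C_50m          1 descent 50 34.0      54.6       1.48 1.81
#> 2 F97HA_C_50m          1  ascent 50 33.2      61.8       1.51 1.71
```

The programmed speeds for that dive were 1.81 (descent) and 1.71 m/s
(ascent): the pitch-corrected estimates recover them to well under 1%
despite 1.5 Hz stroking, sensor noise and 1 Hz depth sampling.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic data
and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # 180 dives, 60 trial file pairs
Rscript analysis/02_kinematics.R      # phases.csv + recovery report
Rscript analysis/03_model_selection.R # 32-model AIC table, best model
Rscript analysis/04_optimal_speed.R   # optima, drag-ratio curve, comparison
```

Step 2 reports ~100% of phases recovered within 2% of the programmed
speeds; step 3 finds drag (≈ −0.44 m/s) and phase (≈ +0.15 m/s) retained in
the best model with buoyancy/depth estimates near zero; step 4 tabulates
the several-fold drag-coefficient increase from the tubes (larger for
smaller animals) and the corresponding drop of the predicted optimum.

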