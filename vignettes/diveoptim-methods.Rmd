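---
title: "Methods: swim speed, drag and the cost-of-transport optimum in diving sea lions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: swim speed, drag and the cost-of-transport optimum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diveoptim)
```

## The scientific question

Breath-hold divers transiting between the surface and a feeding depth are
expected to swim at the speed that minimises their cost of transport (COT),
the metabolic energy spent per metre. Theory predicts that this optimum
depends on the animal's metabolic rate and its drag, but **not** on its
buoyancy or on how deep it is diving. `diveoptim` implements the full chain
needed to examine that prediction with controlled dive trials: trained
Steller sea lions diving to fixed depths (10–50 m) while a harness-mounted
pair of PVC tubes manipulates their drag (flooded tubes), buoyancy (lead
ballast or enclosed air) or neither (control), with a depth/acceleration
logger on the harness recording every dive.

## The cost-of-transport model

For steady swimming at speed $U$ the package models

$$\mathrm{COT}(U) = \frac{k}{U} +
  \frac{\tfrac{1}{2}\,\rho_w \lambda C_D S\, U^2}{\varepsilon_p \varepsilon_A},$$

where $k$ is resting metabolic power (W), $\rho_w$ seawater density
(1027 kg m⁻³), $\lambda$ the active-to-passive drag ratio, $C_D$ the drag
coefficient referenced to the total wetted surface area $S$ (m²), and
$\varepsilon_p$, $\varepsilon_A$ the propeller and aerobic efficiencies.
The first term is the resting metabolism spread over the distance covered;
the second is the mechanical power to overcome drag, divided by $U$ to give
energy per metre and inflated by the two efficiencies. `cot()` is strictly
convex on $U > 0$ and its unique minimiser (`optimal_speed()`) is

$$U_{opt} = \left(\frac{\varepsilon_p \varepsilon_A k}
  {\rho_w \lambda C_D S}\right)^{1/3}.$$

Buoyancy, pitch and depth do not appear: the model structurally cannot make
$U_{opt}$ depend on them, which is the prediction the experiment probes.
Because the closed form is derived (by differentiating COT) rather than
copied, the test suite verifies it two independent ways: against a numeric
golden-section minimisation of `cot()` over 1,000 random parameter sets
(relative agreement 1e-6), and against published worked examples that
exploit the cube-root dependence on $C_D$ alone, in which every other
parameter cancels (1.8 → 1.6 m s⁻¹ and 1.7 → 1.5 m s⁻¹ when $C_D$ moves
from 0.004 to 0.0056).

### Parameter defaults and provenance

| parameter | default | unit | origin |
|---|---|---|---|
| $\varepsilon_p$ | 0.8 | — | published (California sea lion experiments) |
| $\varepsilon_A$ | 0.15 | — | published (same source) |
| $\lambda$ | 1 | — | published convention |
| $\rho_w$ | 1027 | kg m⁻³ | published |
| $C_D$ (bare animal) | 0.004 | — | published control-condition mean; measured range 0.0025–0.0098 |
| $S$ | $0.056\,M_b^{2/3}$ | m² | allometric form is published; the coefficient 0.056 is a package default chosen to give ≈2.0 m² at 213.6 kg. All published benchmarks recomputed here are ratios in which it cancels. |
| O₂→energy | 20.1 | J ml⁻¹ | published conversion |
| tube geometry | 12.5 cm × 35 cm, pair | — | published |
| $C_{D,\mathrm{tube}}$ | 0.071 | — | published (3:1 cylinder on a surface, +10%) |

Per-animal resting metabolic rates were published only in a companion
respirometry paper, so `default_animals()` instead *calibrates* each
animal's metabolic power by inverting the optimal-speed relation at the
published control optima (1.8, 1.7, 1.8 m s⁻¹ at $C_D = 0.004$); the
implied 0.89–1.19 l O₂ min⁻¹ are physiologically plausible for 140–210 kg
sea lions. Likewise only the largest animal's mass (213.6 kg) and the group
range (142.5–213.6 kg) are published; the middle animal's 178 kg is a
package default. Nothing downstream that is checked against published
numbers depends on these defaults.

### Composite drag of animal + tubes

The tubes' drag is combined with the animal's as drag area over wetted
area:

$$C_{D,\mathrm{comb}} = \frac{C_{D,a} S_a + C_{D,t} S_t}{S_a + S_t},$$

a convex combination, so the composite always lies between the two inputs.
Tube wetted area uses cylinder geometry, including the two end faces by
default (the tubes are sealed with end caps; `include_end_caps = FALSE`
gives the lateral-surface-only alternative since the original computation
is ambiguous on this point). `cd_increase_curve()` tabulates
$C_{D,\mathrm{comb}}/C_{D,0}$ over the measured range of initial
coefficients (0.002–0.01) and body masses: the ratio falls with both,
i.e. attachments penalise clean-bodied, small animals the most.

### Buoyancy and ballast arithmetic

Body composition is treated as a two-compartment lipid/lean mixture with
densities 900.7 and 1100 kg m⁻³ (user-overridable placeholders; the exact
mass-specific buoyancies live in cited prior work). `ballast_for_target()`
converts a target lipid fraction into lead weight-in-water (kg) or enclosed
air (l); with the defaults, simulating a 13% body-composition animal from
an 18% one requires lead of the same order as the 1.3–1.7 kg sheets used
in the trials.

## From raw sensor streams to swim speed

The logger records depth at 1 Hz and two-axis acceleration at 32 Hz.

**Pitch** (`pitch_from_accel()`): the gravitational component of surge
acceleration is isolated with a second-order zero-phase Butterworth
low-pass (forward–backward filtering, reflection-padded because plain
`signal::filtfilt` starts from zero state and corrupts the edges), then
converted by $\theta = \arcsin(a_{static}/9.8)$ and block-averaged to 1 Hz.
The cutoff default is 0.5 Hz: sea lion stroking exceeds 1 Hz, so gravity
and stroking separate cleanly; at 1.5 Hz the double-pass attenuates a
stroke sinusoid by ~99%. Samples whose static component still exceeds
9.8 m s⁻² are undefined (NA), never clipped, and excluded from phase means;
a phase with more than 25% undefined pitch flags its dive.

**Segmentation** (`segment_phases()`): a dive is an excursion beyond 2 m.
The descent runs from the first sustained (≥3 s) pitch below −10° until
depth first reaches the target minus 2 m; the ascent from the first
sustained pitch above +10° after the bottom until depth returns within
0.5 m of the surface. These thresholds turn the usual verbal phase
definitions (the animal heads down; it reaches the feeding depth; it
returns to the surface) into reproducible rules; they are all tunable in
`kin_params()`.

**Boundary refinement**: at 1 Hz, threshold crossings quantise phase
boundaries to whole seconds and the target-minus-2-m end rule ends descents
early, biases of 1–2 s. A 50 m transit lasts ~34 s and shrugs this off; a
10 m transit lasts ~7 s and a 2% speed error is 0.14 s, far below the
sampling resolution. Since the transits are quasi-steady (near-constant
vertical speed — the same property that justifies the speed model), the
package refines the boundaries by fitting a line to the interior depth
samples of each transit (between 10% and 90% of the target depth by
default) and extrapolating it to the surface and to the target depth. With
refinement the default synthetic experiment recovers programmed speeds to
within 2% for ≈99% of phases at every depth; `refine = FALSE` restores
the raw threshold boundaries.

**Swim speed**: each phase is summarised by its duration $t$, mean absolute
pitch $\theta$ over the well-settled interior (20–80% of target depth, kept
clear of the filter's ~±0.75 s transition at the phase edges), and
$U = d/(t \sin\theta)$ with $d$ the trial's fixed depth — vertical speed
corrected to speed along the swimming path. The identity
$U \sin\theta\, t = d$ holds exactly by construction and is asserted
property-style in the tests.

## The mixed-model stage

Each dive contributes a descent and an ascent record. Candidate
explanatory variables for $U$: `drag` (binary: tubes present in AD/BN/BP
vs absent in C), `phase` (descent/ascent), `buoyancy` (ordered −1/0/+1
for ballasted/neutral/air-filled, with an option to use estimated net force
in newtons), body mass and dive depth. `fit_lmm()` fits
$U \sim \text{terms} + (1\,|\,\text{animal})$ with `lme4::lmer` under
**maximum likelihood** (not REML) so that log-likelihoods — and therefore
AIC — are comparable across different fixed-effect sets.
`select_model()` fits all 32 subsets and ranks by
$\mathrm{AIC} = 2p - 2\ell$, where $p$ counts the intercept, the fixed
effects and both variance components; ties break toward fewer terms. The
original analysis did not state its ML/REML choice or parameter-counting
convention, which is one reason its printed AIC of −139 is not reproduced
here (the other being that the raw data were never deposited).

Degenerate inputs are handled explicitly: a boundary fit with no
resolvable between-animal variance is returned with `sigma_re = 0` and a
`singular` flag rather than an error (and its ML log-likelihood then equals
the closed-form OLS log-likelihood, asserted in the tests against that
independent oracle); a rank-deficient design errors naming the collinear
term; single-animal data are rejected.

**A known property of AIC worth stating plainly**: AIC retains a spurious
covariate whenever twice its log-likelihood gain exceeds 2, which for a
1-df noise term happens with probability ≈0.16 regardless of sample size.
With three noise candidates (buoyancy, mass, depth) the probability that
the exact set {drag, phase} tops the ranking is therefore bounded near
$0.84^3 \approx 0.60$ even in ideal data; with only three animals, body
mass (a group-level covariate) can additionally masquerade as the random
intercept. The test suite measures exactly this: drag and phase are
essentially always *retained*, but the exact two-term set wins only ~half
of replicates. Any conclusion of the form "buoyancy and depth have no
effect" should therefore rest on the near-zero estimated coefficients and
effect-containing top sets, not on exact-set recovery.

## What the synthetic data do and do not emulate

`experiment_design()` defaults encode the study conditions: 3 animals
(142.5–213.6 kg), four conditions, depths 10–50 m, 3 dives per cell = 180
dives (the experiment had 186, unevenly distributed; the balanced design is
a package choice), control speeds ~1.7 m s⁻¹ (descent) falling inside the
reported 1.4–2.0 m s⁻¹ control band, tubes slowing dives by 0.45 m s⁻¹ and
ascents faster by 0.15 m s⁻¹ (the study reported both directions but no
effect sizes; these are package choices of realistic magnitude), per-animal
offsets of SD 0.10 and residual SD 0.15 m s⁻¹, transit pitch 60° ± 3°,
stroking at 1.5 Hz / 1.5 m s⁻², depth noise 0.05 m, accelerometer noise
0.2 m s⁻². All randomness flows from one integer seed; identical seeds
reproduce byte-identical files.

The generator emulates: mixed-rate streams, gravitational + stroking +
noise structure of surge/heave, piecewise-linear quasi-steady dive
profiles, condition/phase/animal effects on speed. It does **not**
emulate: stroke-and-glide gaits, speed ramp-up at phase starts (the
mechanism the original authors suspected behind the faster ascents),
bottom-phase feeding kinematics, depth-sensor drift, or buoyancy actually
altering the dive kinematics. Passing recovery tests therefore shows the
estimators are unbiased and appropriately precise under the model's own
assumptions — not that real sea lion data are this clean.

## Numerical and design choices

* $g = 9.8$ m s⁻² exactly, matching the undefined-pitch threshold.
* Pitch samples that cannot be converted are excluded, never interpolated.
* Interior windows: line fit over 10–90% of target depth (the simulated
  depth ramp is clean to the edges), pitch mean over 20–80% (the filtered
  pitch is not); both tunable.
* Refined boundaries are sanity-clamped to within 5 s of the threshold
  boundaries and fall back to them when fewer than 3 interior samples
  exist.
* `simulate_dive_sensors()` rejects programmed transits shorter than 4 s
  as unresolvable at 1 Hz.
* Problem sizes in the shipped tests and analysis scripts: the full
  180-dive experiment for end-to-end recovery; 100 replicates × 32 models
  for selection behaviour; 200 replicates for coefficient coverage; 1,000
  random parameter sets for the closed-form-vs-numeric oracle.
* Speed-table replicates use 186 dive-phase records, the study's dive
  count, allocated round-robin over cells.

## Known limitations

* The empirical tables of the original study (per-animal dive counts, the
  AIC of −139, the exact speed distributions) are not reproducible: the
  raw biologger records were never deposited. Everything quantitative here
  is validated on synthetic data plus the published worked examples.
* The COT model is steady-state: no acceleration-reaction, no
  stroke-and-glide, no thermoregulatory costs, $\lambda$ fixed at 1.
* The tube composite uses wetted-area-referenced drag for the tubes, as the
  original calculation states; a frontal-area alternative would change the
  composite's magnitude (not its monotonicities) and is not implemented.
* With three animals, group-level covariates (body mass) are weakly
  identified against the random intercept; this is a property of the
  design, not of the estimator.
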