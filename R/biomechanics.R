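#' Biomechanical parameter set for the cost-of-transport model
#'
#' Bundles the parameters of the cost-of-transport (COT) model for a
#' steadily swimming breath-hold diver: metabolic power, drag properties and
#' the efficiencies converting chemical energy into thrust.
#'
#' @param k Basal/resting metabolic power (J s^-1, i.e. W). See
#'   [rmr_to_power()] to convert an oxygen consumption rate.
#' @param C_D Drag coefficient of the gliding animal referenced to total
#'   wetted surface area (dimensionless).
#' @param S Total wetted surface area (m^2). See [surface_area()].
#' @param eps_p Propeller efficiency: fraction of muscle work converted to
#'   propulsive work (dimensionless, in (0, 1]). Default 0.8.
#' @param eps_A Aerobic efficiency: fraction of chemical energy converted to
#'   muscle work (dimensionless, in (0, 1]). Default 0.15.
#' @param rho_w Seawater density (kg m^-3). Default 1027.
#' @param lam Ratio of the drag of an actively swimming animal to that of a
#'   passively gliding one (dimensionless). Default 1.
#'
#' @return An object of class `biomech_params` (a validated list).
#' @seealso [cot()], [optimal_speed()]
#' @export
biomech_params <- function(k, C_D, S, eps_p = 0.8, eps_A = 0.15,
                           rho_w = 1027, lam = 1) {
  p <- list(k = k, C_D = C_D, S = S, eps_p = eps_p, eps_A = eps_A,
            rho_w = rho_w, lam = lam)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("biomech_params: '", nm, "' must be a single positive finite number")
  }
  if (p$eps_p > 1 || p$eps_A > 1)
    stop("biomech_params: efficiencies eps_p and eps_A must be <= 1")
  structure(p, class = "biomech_params")
}

#' @export
print.biomech_params <- function(x, ...) {
  cat("Cost-of-transport model parameters:\n")
  cat(sprintf("  metabolic power k     = %.4g W\n", x$k))
  cat(sprintf("  drag coefficient C_D  = %.4g (wetted-area referenced)\n", x$C_D))
  cat(sprintf("  wetted surface area S = %.4g m^2\n", x$S))
  cat(sprintf("  efficiencies eps_p, eps_A = %.3g, %.3g; lambda = %.3g; rho_w = %.4g kg m^-3\n",
              x$eps_p, x$eps_A, x$lam, x$rho_w))
  cat(sprintf("  optimal swim speed    = %.4g m s^-1\n", optimal_speed(x)))
  invisible(x)
}

#' Wetted surface area from body mass
#'
#' Allometric wetted surface area assuming geometric similarity:
#' `S = area_coef * M_b^(2/3)`.
#'
#' @param M_b Body mass (kg), positive.
#' @param area_coef Allometric coefficient (m^2 kg^(-2/3)). Default 0.056,
#'   which gives about 2.0 m^2 for a 213.6 kg Steller sea lion.
#' @return Wetted surface area (m^2). Vectorised over `M_b`.
#' @export
surface_area <- function(M_b, area_coef = 0.056) {
  if (any(!is.finite(M_b)) || any(M_b <= 0))
    stop("surface_area: M_b must be positive and finite")
  if (!is.finite(area_coef) || area_coef <= 0)
    stop("surface_area: area_coef must be positive and finite")
  area_coef * M_b^(2 / 3)
}

#' Convert resting oxygen consumption to metabolic power
#'
#' Converts a resting metabolic rate measured in water (l O2 min^-1) to
#' power using 20.1 J per ml O2.
#'
#' @param rmr_lpm Oxygen consumption rate (litres O2 per minute), >= 0.
#' @return Metabolic power (J s^-1). Vectorised.
#' @export
rmr_to_power <- function(rmr_lpm) {
  if (any(!is.finite(rmr_lpm)) || any(rmr_lpm < 0))
    stop("rmr_to_power: rmr_lpm must be non-negative and finite")
  rmr_lpm * 1000 * 20.1 / 60
}

#' Cost of transport at a given swim speed
#'
#' Metabolic energy required to move a unit distance (J m^-1) at steady
#' speed `U`:
#'
#' `COT(U) = k / U + 0.5 * rho_w * lam * C_D * S * U^2 / (eps_p * eps_A)`
#'
#' The first term is time-dependent (basal metabolism spread over distance),
#' the second is the mechanical cost of overcoming drag, inflated by the
#' propulsive and aerobic efficiencies. The function is strictly convex on
#' U > 0 and minimised at [optimal_speed()].
#'
#' @param U Swim speed along the movement path (m s^-1), > 0. Vectorised.
#' @param p A [biomech_params()] object.
#' @return Cost of transport (J m^-1).
#' @export
cot <- function(U, p) {
  stopifnot(inherits(p, "biomech_params"))
  if (any(!is.finite(U)) || any(U <= 0))
    stop("cot: U must be positive and finite")
  p$k / U + 0.5 * p$rho_w * p$lam * p$C_D * p$S * U^2 / (p$eps_p * p$eps_A)
}

#' Optimal swim speed minimising the cost of transport
#'
#' Closed-form minimiser of [cot()]:
#'
#' `U_opt = (eps_p * eps_A * k / (rho_w * lam * C_D * S))^(1/3)`
#'
#' The optimal speed scales as the cube root of metabolic power over drag
#' area and — by construction — does not depend on buoyancy, pitch angle or
#' dive depth, which the model does not take as inputs.
#'
#' @param p A [biomech_params()] object.
#' @return Optimal swim speed (m s^-1).
#' @export
optimal_speed <- function(p) {
  stopifnot(inherits(p, "biomech_params"))
  (p$eps_p * p$eps_A * p$k / (p$rho_w * p$lam * p$C_D * p$S))^(1 / 3)
}

#' Metabolic power implied by an observed optimal speed
#'
#' Inverts the optimal-speed relation: returns the metabolic power `k` for
#' which [optimal_speed()] equals `U_opt` with the other parameters held at
#' the values in `p`. Useful for calibrating the model to a printed or
#' measured optimal speed when direct metabolic measurements are
#' unavailable.
#'
#' @param U_opt Target optimal swim speed (m s^-1), > 0.
#' @param p A [biomech_params()] object; its `k` is ignored.
#' @return Metabolic power k (J s^-1).
#' @export
calibrate_metabolic_power <- function(U_opt, p) {
  stopifnot(inherits(p, "biomech_params"))
  if (!is.finite(U_opt) || U_opt <= 0)
    stop("calibrate_metabolic_power: U_opt must be positive and finite")
  U_opt^3 * p$rho_w * p$lam * p$C_D * p$S / (p$eps_p * p$eps_A)
}

#' Specification of attached cylindrical tubes
#'
#' Geometry and drag coefficient of PVC tubes attached to the harness to
#' manipulate drag and buoyancy.
#'
#' @param diameter Tube diameter (m). Default 0.125.
#' @param length Tube length (m). Default 0.35.
#' @param count Number of tubes. Default 2 (one pair). May be 0.
#' @param C_D_tube Drag coefficient of the tubes referenced to their wetted
#'   area. Default 0.071 (a 3:1 cylinder on a surface).
#' @param include_end_caps Include the two circular end faces in the wetted
#'   area (tubes sealed with end caps)? Default TRUE.
#' @return An object of class `tube_spec`.
#' @export
tube_spec <- function(diameter = 0.125, length = 0.35, count = 2L,
                      C_D_tube = 0.071, include_end_caps = TRUE) {
  if (!is.finite(diameter) || diameter <= 0 || !is.finite(length) || length <= 0)
    stop("tube_spec: diameter and length must be positive")
  if (!is.numeric(count) || length(count) != 1L || count < 0 || count != round(count))
    stop("tube_spec: count must be a non-negative integer")
  if (!is.finite(C_D_tube) || C_D_tube <= 0)
    stop("tube_spec: C_D_tube must be positive")
  structure(list(diameter = diameter, length = length, count = as.integer(count),
                 C_D_tube = C_D_tube, include_end_caps = isTRUE(include_end_caps)),
            class = "tube_spec")
}

#' Total wetted surface area of the attached tubes
#'
#' Lateral cylinder area `pi * diameter * length` per tube, plus the two end
#' faces `2 * pi * (diameter/2)^2` when `include_end_caps` is set, times the
#' tube count.
#'
#' @param spec A [tube_spec()].
#' @return Wetted area (m^2); 0 when `count = 0`.
#' @export
tube_wetted_area <- function(spec) {
  stopifnot(inherits(spec, "tube_spec"))
  per <- pi * spec$diameter * spec$length
  if (spec$include_end_caps) per <- per + 2 * pi * (spec$diameter / 2)^2
  spec$count * per
}

#' Composite drag coefficient of animal plus tubes
#'
#' Area-weighted mixture of the two drag coefficients: the summed drag area
#' (each C_D times its wetted area) divided by the total wetted area,
#'
#' `C_D_comb = (C_D_animal * S_animal + C_D_tube * S_tube) / (S_animal + S_tube)`
#'
#' so the result always lies between the animal's and the tubes' own
#' coefficients.
#'
#' @param C_D_animal Drag coefficient of the bare animal.
#' @param S_animal Wetted surface area of the animal (m^2).
#' @param spec A [tube_spec()].
#' @return Composite drag coefficient (dimensionless).
#' @export
combined_cd <- function(C_D_animal, S_animal, spec) {
  stopifnot(inherits(spec, "tube_spec"))
  if (any(!is.finite(C_D_animal)) || any(C_D_animal <= 0))
    stop("combined_cd: C_D_animal must be positive")
  if (any(!is.finite(S_animal)) || any(S_animal <= 0))
    stop("combined_cd: S_animal must be positive")
  S_tube <- tube_wetted_area(spec)
  if (S_tube == 0) return(C_D_animal)  # nothing attached
  total <- S_animal + S_tube
  if (any(total <= 0)) stop("combined_cd: total wetted area must be positive")
  (C_D_animal * S_animal + spec$C_D_tube * S_tube) / total
}

#' Drag-coefficient increase ratio across initial drag and body size
#'
#' For each combination of initial drag coefficient and body mass, the ratio
#' of the composite coefficient (animal + tubes) to the initial one. The
#' ratio decreases with the initial coefficient (attachments matter more on
#' cleaner bodies) and with body mass (smaller animals have less wetted area
#' over which to dilute the tubes' drag).
#'
#' @param C_D0_grid Initial animal drag coefficients, each in (0, 0.02].
#' @param M_b_list Body masses (kg).
#' @param area_coef Allometric coefficient passed to [surface_area()].
#' @param spec A [tube_spec()].
#' @return A data frame with columns `C_D0`, `M_b`, `C_D_comb`, `ratio`.
#' @export
cd_increase_curve <- function(C_D0_grid, M_b_list, area_coef = 0.056,
                              spec = tube_spec()) {
  if (any(C_D0_grid <= 0) || any(C_D0_grid > 0.02))
    stop("cd_increase_curve: C_D0 grid must lie in (0, 0.02]")
  grid <- expand.grid(C_D0 = C_D0_grid, M_b = M_b_list,
                      KEEP.OUT.ATTRS = FALSE)
  S <- surface_area(grid$M_b, area_coef)
  grid$C_D_comb <- combined_cd(grid$C_D0, S, spec)
  grid$ratio <- grid$C_D_comb / grid$C_D0
  grid
}

#' Net buoyant force from body composition
#'
#' Treats the body as a two-compartment mixture of lipid and lean tissue
#' with fixed densities. Body volume is
#' `V = M_b * (lipid_frac / rho_lipid + (1 - lipid_frac) / rho_lean)` and
#' the net buoyant force `(rho_w * V - M_b) * 9.8` N (positive = floats).
#'
#' @param M_b Body mass (kg).
#' @param lipid_frac Total body lipid as a fraction of body mass, in (0, 1).
#' @param densities Named numeric vector `c(lipid = ..., lean = ...)` in
#'   kg m^-3. Defaults `c(lipid = 900.7, lean = 1100)`.
#' @param rho_w Seawater density (kg m^-3). Default 1027.
#' @return Net buoyant force (N, positive up). Vectorised over `lipid_frac`.
#' @export
buoyancy_from_composition <- function(M_b, lipid_frac,
                                      densities = c(lipid = 900.7, lean = 1100),
                                      rho_w = 1027) {
  if (any(lipid_frac <= 0) || any(lipid_frac >= 1))
    stop("buoyancy_from_composition: lipid_frac must be in (0, 1)")
  if (any(densities <= 0) || is.null(names(densities)) ||
      !all(c("lipid", "lean") %in% names(densities)))
    stop("buoyancy_from_composition: densities must be positive and named 'lipid', 'lean'")
  V <- M_b * (lipid_frac / densities[["lipid"]] +
                (1 - lipid_frac) / densities[["lean"]])
  (rho_w * V - M_b) * 9.8
}

#' Ballast or air volume needed to simulate a target body composition
#'
#' Computes the net buoyancy at the animal's current and target lipid
#' fractions and expresses the difference as either lead ballast
#' (weight-in-water, kg; target less buoyant) or enclosed air volume
#' (litres; target more buoyant).
#'
#' @param animal An [animal_params()] object (uses `M_b`, `lipid_frac`).
#' @param target_lipid_frac Lipid fraction to simulate, in (0, 1).
#' @param densities,rho_w As in [buoyancy_from_composition()].
#' @return An object of class `buoyancy_state`: list with `condition`
#'   ("BN", "BP" or "C"), `net_buoyancy_N` (at the target composition),
#'   `ballast_mass_in_water_kg` and `air_volume_l`.
#' @export
ballast_for_target <- function(animal, target_lipid_frac,
                               densities = c(lipid = 900.7, lean = 1100),
                               rho_w = 1027) {
  stopifnot(inherits(animal, "animal_params"))
  F_cur <- buoyancy_from_composition(animal$M_b, animal$lipid_frac, densities, rho_w)
  F_tgt <- buoyancy_from_composition(animal$M_b, target_lipid_frac, densities, rho_w)
  dF <- F_tgt - F_cur
  ballast <- 0
  air <- 0
  condition <- "C"
  if (dF < 0) {
    ballast <- -dF / 9.8
    condition <- "BN"
  } else if (dF > 0) {
    air <- dF / (9.8 * rho_w) * 1000
    condition <- "BP"
  }
  structure(list(condition = condition, net_buoyancy_N = F_tgt,
                 current_buoyancy_N = F_cur,
                 ballast_mass_in_water_kg = ballast, air_volume_l = air),
            class = "buoyancy_state")
}

#' Per-animal physical and metabolic parameters
#'
#' @param animal_id Animal identifier.
#' @param M_b Body mass (kg).
#' @param area_coef Allometric surface-area coefficient (m^2 kg^(-2/3)).
#' @param C_D0 Baseline (no-tube) drag coefficient, in (0.001, 0.02).
#' @param rmr_lpm Resting metabolic rate in water (l O2 min^-1).
#' @param lipid_frac Total body lipid fraction, in (0, 1).
#' @return An object of class `animal_params`.
#' @export
animal_params <- function(animal_id, M_b, area_coef = 0.056, C_D0 = 0.004,
                          rmr_lpm, lipid_frac = 0.18) {
  if (!is.finite(M_b) || M_b <= 0) stop("animal_params: M_b must be positive")
  if (!is.finite(C_D0) || C_D0 <= 0.001 || C_D0 >= 0.02)
    stop("animal_params: C_D0 must lie in (0.001, 0.02)")
  if (!is.finite(lipid_frac) || lipid_frac <= 0 || lipid_frac >= 1)
    stop("animal_params: lipid_frac must be in (0, 1)")
  if (!is.finite(rmr_lpm) || rmr_lpm < 0)
    stop("animal_params: rmr_lpm must be non-negative")
  structure(list(animal_id = as.character(animal_id), M_b = M_b,
                 area_coef = area_coef, C_D0 = C_D0, rmr_lpm = rmr_lpm,
                 lipid_frac = lipid_frac),
            class = "animal_params")
}

#' Biomechanical parameter set for one animal
#'
#' Assembles a [biomech_params()] object from an animal's mass, surface-area
#' allometry, metabolic rate and a drag coefficient (baseline by default, or
#' the tube-composite coefficient when `spec` is supplied).
#'
#' @param animal An [animal_params()] object.
#' @param spec Optional [tube_spec()]; when given, the drag coefficient is
#'   the composite of animal and tubes via [combined_cd()].
#' @param ... Further arguments (efficiencies, `rho_w`, `lam`) passed to
#'   [biomech_params()].
#' @return A [biomech_params()] object.
#' @export
animal_biomech <- function(animal, spec = NULL, ...) {
  stopifnot(inherits(animal, "animal_params"))
  S <- surface_area(animal$M_b, animal$area_coef)
  C_D <- animal$C_D0
  if (!is.null(spec)) C_D <- combined_cd(animal$C_D0, S, spec)
  biomech_params(k = rmr_to_power(animal$rmr_lpm), C_D = C_D, S = S, ...)
}

#' Default study animals
#'
#' Three adult female Steller sea lions spanning 142.5 to 213.6 kg. Only the
#' largest animal's mass and the overall range are published; the middle
#' mass is a package default. Resting metabolic rates are calibrated so that
#' each animal's optimal swim speed at the reported control drag coefficient
#' (C_D = 0.004) matches the reported control-condition optima
#' (1.8, 1.7 and 1.8 m s^-1).
#'
#' @param area_coef Surface-area allometric coefficient.
#' @param C_D0 Baseline drag coefficient applied to all animals.
#' @return Named list of [animal_params()] objects (F97HA, F00BO, F97SI).
#' @export
default_animals <- function(area_coef = 0.056, C_D0 = 0.004) {
  specs <- list(F97HA = list(M_b = 142.5, U_opt = 1.8, lipid = 0.18),
                F00BO = list(M_b = 178.0, U_opt = 1.7, lipid = 0.18),
                F97SI = list(M_b = 213.6, U_opt = 1.8, lipid = 0.18))
  out <- lapply(names(specs), function(id) {
    s <- specs[[id]]
    S <- surface_area(s$M_b, area_coef)
    # invert the optimal-speed relation for k, then back to l O2/min
    p0 <- biomech_params(k = 1, C_D = C_D0, S = S)
    k <- calibrate_metabolic_power(s$U_opt, p0)
    animal_params(id, M_b = s$M_b, area_coef = area_coef, C_D0 = C_D0,
                  rmr_lpm = k * 60 / 20100, lipid_frac = s$lipid)
  })
  names(out) <- names(specs)
  out
}
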