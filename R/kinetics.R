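# Pointwise kinetic laws. These are the building blocks the integrator
# evaluates at every step; each is exported so the model algebra can be
# inspected and tested in isolation. Units are cm-g-min throughout.

#' Dissolution rate constant k = IDR / Cs
#'
#' The Noyes-Whitney rate constant \eqn{k = D/h} (diffusion coefficient
#' over the particle boundary-layer thickness) is not measurable directly;
#' it is obtained as the ratio of the intrinsic dissolution rate to the
#' solubility, \eqn{k = IDR / C_s}, in cm/min.
#'
#' @param intrinsic_dissolution_rate IDR in g/cm^2/min (non-negative).
#' @param solubility saturation solubility \eqn{C_s} in g/cm^3 (positive).
#' @return rate constant in cm/min.
#' @export
#' @examples
#' dissolution_rate_constant(0.50e-3, 17.70e-3)  # moxifloxacin, ~0.028 cm/min
dissolution_rate_constant <- function(intrinsic_dissolution_rate, solubility) {
  if (any(solubility <= 0)) stop_invalid("solubility", "must be positive")
  if (any(intrinsic_dissolution_rate < 0))
    stop_invalid("intrinsic_dissolution_rate", "must be non-negative")
  intrinsic_dissolution_rate / solubility
}

#' Particle diameter of a shrinking monodisperse powder
#'
#' All particles are assumed smooth, spherical and of equal size, so the
#' particle count is fixed and each particle shrinks uniformly as the
#' powder dissolves: \eqn{d_t = (M_t d_0^3 / M_0)^{1/3}}.
#'
#' @param mass_solid remaining solid mass \eqn{M_t} in g (vectorised).
#' @param dose initial powder mass \eqn{M_0} in g.
#' @param initial_diameter initial particle diameter \eqn{d_0} in cm.
#' @return particle diameter \eqn{d_t} in cm.
#' @export
#' @examples
#' particle_diameter_at(50e-6 / 8, 50e-6, 2.9e-4)  # half the diameter
particle_diameter_at <- function(mass_solid, dose, initial_diameter) {
  check_positive(dose, "dose")
  check_positive(initial_diameter, "initial_diameter")
  if (any(mass_solid < 0) || any(mass_solid > dose * (1 + 1e-12)))
    stop("invalid state: mass_solid must lie in [0, dose]", call. = FALSE)
  (pmin(mass_solid, dose) * initial_diameter^3 / dose)^(1 / 3)
}

#' Total surface area of the shrinking powder
#'
#' With a fixed particle count \eqn{N = 6 M_0 / (\pi d_0^3 \rho)}, the
#' total area at time t is \eqn{S_t = \pi d_t^2 N = 6 M_0 d_t^2 / (d_0^3 \rho)}.
#' Equivalently \eqn{S_t / S_0 = (M_t / M_0)^{2/3}}.
#'
#' @inheritParams particle_diameter_at
#' @param particle_density powder density \eqn{\rho} in g/cm^3.
#' @return total surface area in cm^2.
#' @export
#' @examples
#' total_surface_area(50e-6, 50e-6, 2.9e-4, 1.0)  # initial area ~1.03 cm^2
total_surface_area <- function(mass_solid, dose, initial_diameter,
                               particle_density) {
  check_positive(particle_density, "particle_density")
  d_t <- particle_diameter_at(mass_solid, dose, initial_diameter)
  6 * dose * d_t^2 / (initial_diameter^3 * particle_density)
}

#' Drug concentration in the mucus simulant
#'
#' @param mass_dissolved dissolved drug mass in g.
#' @param mucus_volume donor volume \eqn{V_d} in cm^3.
#' @return donor concentration \eqn{C} in g/cm^3.
#' @export
donor_concentration <- function(mass_dissolved, mucus_volume) {
  if (any(mucus_volume <= 0)) stop_invalid("mucus_volume", "must be positive")
  mass_dissolved / mucus_volume
}

#' Noyes-Whitney dissolution mass rate
#'
#' \eqn{dM/dt = k S_t (C_s - C)}, clamped at zero once the film is
#' saturated (\eqn{C \ge C_s}): precipitation is not modelled, so the
#' driving force never goes negative.
#'
#' @param k dissolution rate constant in cm/min.
#' @param surface_area total particle surface area \eqn{S_t} in cm^2.
#' @param solubility \eqn{C_s} in g/cm^3.
#' @param concentration current donor concentration \eqn{C} in g/cm^3.
#' @return dissolution rate in g/min (non-negative).
#' @export
dissolution_mass_rate <- function(k, surface_area, solubility, concentration) {
  if (any(k < 0)) stop_invalid("k", "must be non-negative")
  if (any(surface_area < 0)) stop_invalid("surface_area", "must be non-negative")
  pmax(0, k * surface_area * (solubility - concentration))
}

#' Fraction of the dose that has left the donor film
#'
#' The depletion fraction \eqn{f_d} drives the growth of the drug-free
#' layer in the unstirred donor. Drug in the receiver and drug already
#' swept into the collection tubes have both left the mucus, so both
#' count: \eqn{f_d = (M_{receiver} + M_{collected}) / M_0}.
#'
#' @param state a [system_state()] (or any list with `mass_receiver` and
#'   `mass_collected` in g).
#' @param dose total dose \eqn{M_0} in g.
#' @return \eqn{f_d} in \[0, 1\].
#' @export
depletion_fraction <- function(state, dose) {
  check_positive(dose, "dose")
  fd <- (state$mass_receiver + state$mass_collected) / dose
  if (any(fd < -1e-12) || any(fd > 1 + 1e-9))
    stop("invalid state: depletion fraction outside [0, 1]", call. = FALSE)
  pmin(pmax(fd, 0), 1)
}

#' Membrane permeability coefficient
#'
#' The simulated permeability is the experimental coefficient rescaled to
#' the simulated diffusion-barrier thickness. Well-stirred donor:
#' \eqn{P = P_{exp} h_{exp} / h_m}, constant in time. Unstirred donor: the
#' depletion zone of thickness \eqn{h_d = f_d h_t} adds series resistance,
#' \eqn{P_t = P_{exp} h_{exp} / (h_m + f_d h_t)}, which decreases as drug
#' leaves the film.
#'
#' @param stirring `"well_stirred"` or `"unstirred"`.
#' @param permeability_exp experimental permeability \eqn{P_{exp}} in cm/min.
#' @param membrane_thickness_exp \eqn{h_{exp}} in cm.
#' @param membrane_thickness simulated membrane thickness \eqn{h_m} in cm.
#' @param depletion_frac \eqn{f_d} in \[0, 1\] (unstirred only; vectorised).
#' @param film_thickness mucus film thickness \eqn{h_t} in cm (unstirred
#'   only).
#' @return permeability coefficient in cm/min.
#' @export
#' @examples
#' permeability("well_stirred", 1.8e-4, 62.5e-4, 62.5e-4)
#' permeability("unstirred", 5.3e-4, 62.5e-4, 62.5e-4,
#'              depletion_frac = 1, film_thickness = 50.9e-4)
permeability <- function(stirring = c("well_stirred", "unstirred"),
                         permeability_exp, membrane_thickness_exp,
                         membrane_thickness,
                         depletion_frac = 0, film_thickness = NULL) {
  stirring <- match.arg(stirring)
  check_positive(permeability_exp, "permeability_exp")
  check_positive(membrane_thickness_exp, "membrane_thickness_exp")
  check_positive(membrane_thickness, "membrane_thickness")
  if (stirring == "well_stirred")
    return(permeability_exp * membrane_thickness_exp / membrane_thickness)
  check_positive(film_thickness, "film_thickness")
  if (any(depletion_frac < 0) || any(depletion_frac > 1 + 1e-9))
    stop_invalid("depletion_frac", "must lie in [0, 1]")
  permeability_exp * membrane_thickness_exp /
    (membrane_thickness + depletion_frac * film_thickness)
}

#' Permeation rate across the membrane
#'
#' Fick's first law across the lumped barrier:
#' \eqn{PS (C_{mucus} - C_{perfusate})}. The rate is signed; back-flux is
#' permitted by the law although it does not arise in the scenarios
#' modelled here (the receiver stays far below the donor).
#'
#' @param p permeability coefficient in cm/min.
#' @param membrane_area membrane area \eqn{S} in cm^2.
#' @param conc_mucus donor concentration in g/cm^3.
#' @param conc_perfusate receiver concentration in g/cm^3.
#' @return permeation rate in g/min.
#' @export
permeation_rate <- function(p, membrane_area, conc_mucus, conc_perfusate) {
  if (any(p < 0)) stop_invalid("p", "must be non-negative")
  if (any(membrane_area < 0)) stop_invalid("membrane_area", "must be non-negative")
  p * membrane_area * (conc_mucus - conc_perfusate)
}

#' Collection rate into the sampling tubes
#'
#' Perfusate leaves the well-mixed receiver at flow rate Q carrying drug
#' at the receiver bulk concentration: rate = \eqn{C_{perfusate} Q}.
#'
#' @param conc_perfusate receiver concentration in g/cm^3.
#' @param perfusate_flow flow rate \eqn{Q} in cm^3/min.
#' @return collection rate in g/min.
#' @export
collection_rate <- function(conc_perfusate, perfusate_flow) {
  if (any(perfusate_flow < 0)) stop_invalid("perfusate_flow", "must be non-negative")
  conc_perfusate * perfusate_flow
}

#' Saturation capacity of the donor film
#'
#' The largest drug mass the mucus film can hold in solution,
#' \eqn{C_s V_d}. Doses above this leave excess undissolved solid until
#' permeation has removed enough drug; doses below it dissolve completely
#' (given time). For ethionamide (\eqn{C_s} = 0.46 mg/mL) in 25 uL this is
#' 11.5 ug, so a 50 ug particle dose is solubility-limited.
#'
#' @param solubility \eqn{C_s} in g/cm^3.
#' @param mucus_volume \eqn{V_d} in cm^3.
#' @return mass in g.
#' @export
saturation_capacity <- function(solubility, mucus_volume) {
  if (any(solubility <= 0)) stop_invalid("solubility", "must be positive")
  if (any(mucus_volume <= 0)) stop_invalid("mucus_volume", "must be positive")
  solubility * mucus_volume
}
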