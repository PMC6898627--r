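# Parameter containers. Everything is validated on construction so the
# kinetic laws and the integrator can assume well-formed inputs.

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

check_positive <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value <= 0)
    stop_invalid(field, "must be a single finite positive number")
  value
}

check_nonneg <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value < 0)
    stop_invalid(field, "must be a single finite non-negative number")
  value
}

#' Physicochemical and transport constants of a drug
#'
#' Bundles the per-drug constants that drive the model: aqueous solubility
#' \eqn{C_s}, intrinsic dissolution rate (IDR), initial particle diameter
#' \eqn{d_0}, particle density \eqn{\rho}, the experimentally measured
#' permeability coefficient \eqn{P_{exp}} and the membrane thickness
#' \eqn{h_{exp}} at which it was measured. All values are in cm-g-min
#' units (see [units]).
#'
#' The composite quantities actually used by the kinetics are the
#' dissolution rate constant \eqn{k = IDR / C_s} (cm/min) and the
#' experimental permeability \eqn{P_{exp}} rescaled to the simulated
#' membrane thickness; the diffusion coefficient and boundary-layer
#' thickness never appear independently.
#'
#' @param name drug label (character).
#' @param solubility saturation solubility \eqn{C_s} in g/cm^3.
#' @param intrinsic_dissolution_rate IDR in g/cm^2/min (flux per unit area
#'   of a compacted disc under fixed hydrodynamics).
#' @param particle_diameter initial particle diameter \eqn{d_0} in cm
#'   (respirable particles are 1-5 um, i.e. 1e-4 to 5e-4 cm).
#' @param particle_density particle density \eqn{\rho} in g/cm^3.
#' @param permeability_exp experimental permeability coefficient
#'   \eqn{P_{exp}} in cm/min.
#' @param membrane_thickness_exp thickness \eqn{h_{exp}} (cm) of the
#'   membrane used when \eqn{P_{exp}} was measured.
#' @return an object of class `drug_params`.
#' @seealso [apparatus_params()], [run_spec()], [preset()]
#' @export
#' @examples
#' moxi <- drug_params("moxifloxacin",
#'   solubility = 17.70e-3, intrinsic_dissolution_rate = 0.50e-3,
#'   particle_diameter = 2.9e-4, particle_density = 1.0,
#'   permeability_exp = 1.8e-4, membrane_thickness_exp = 62.5e-4)
#' moxi
drug_params <- function(name, solubility, intrinsic_dissolution_rate,
                        particle_diameter, particle_density = 1.0,
                        permeability_exp, membrane_thickness_exp) {
  if (!is.character(name) || length(name) != 1L)
    stop_invalid("name", "must be a single character string")
  obj <- structure(list(
    name = name,
    solubility = check_positive(solubility, "solubility"),
    intrinsic_dissolution_rate =
      check_positive(intrinsic_dissolution_rate, "intrinsic_dissolution_rate"),
    particle_diameter = check_positive(particle_diameter, "particle_diameter"),
    particle_density = check_positive(particle_density, "particle_density"),
    permeability_exp = check_positive(permeability_exp, "permeability_exp"),
    membrane_thickness_exp =
      check_positive(membrane_thickness_exp, "membrane_thickness_exp")
  ), class = "drug_params")
  obj
}

#' @export
print.drug_params <- function(x, ...) {
  cat("Drug parameters:", x$name, "\n")
  cat(sprintf("  solubility Cs          %.4g g/cm^3 (%.4g mg/mL)\n",
              x$solubility, g_per_cm3_to_mg_per_ml(x$solubility)))
  cat(sprintf("  IDR                    %.4g g/cm^2/min\n",
              x$intrinsic_dissolution_rate))
  cat(sprintf("  rate constant k=IDR/Cs %.4g cm/min\n",
              dissolution_rate_constant(x$intrinsic_dissolution_rate, x$solubility)))
  cat(sprintf("  particle diameter d0   %.4g cm (%.3g um)\n",
              x$particle_diameter, cm_to_um(x$particle_diameter)))
  cat(sprintf("  particle density rho   %.4g g/cm^3\n", x$particle_density))
  cat(sprintf("  permeability Pexp      %.4g cm/min at hexp = %.4g cm\n",
              x$permeability_exp, x$membrane_thickness_exp))
  invisible(x)
}

#' Geometry and flow of the perfusion cell
#'
#' Describes the flow-through dissolution cell: the membrane over which
#' the mucus simulant is spread, the receiver compartment beneath it and
#' the perfusate flow that sweeps permeated drug into collection tubes.
#' The mucus film thickness is derived, not stored:
#' \eqn{h_t = V_d / S} (25 uL over 4.91 cm^2 gives about 50.9 um), and is
#' recomputed whenever the mucus volume changes, e.g. in a sweep.
#'
#' @param membrane_area exposed membrane area \eqn{S} in cm^2.
#' @param membrane_thickness simulated membrane thickness \eqn{h_m} in cm.
#' @param mucus_volume donor (mucus simulant) volume \eqn{V_d} in cm^3.
#' @param receiver_volume perfusate volume in the receiver \eqn{V_r} in cm^3.
#' @param perfusate_flow perfusate flow rate \eqn{Q} in cm^3/min (may be 0
#'   for a closed receiver).
#' @return an object of class `apparatus_params`.
#' @export
#' @examples
#' app <- apparatus_params()
#' film_thickness(app) * 1e4   # film thickness in um
apparatus_params <- function(membrane_area = 4.91,
                             membrane_thickness = 62.5e-4,
                             mucus_volume = 25e-3,
                             receiver_volume = 500e-3,
                             perfusate_flow = 0.4) {
  structure(list(
    membrane_area = check_positive(membrane_area, "membrane_area"),
    membrane_thickness = check_positive(membrane_thickness, "membrane_thickness"),
    mucus_volume = check_positive(mucus_volume, "mucus_volume"),
    receiver_volume = check_positive(receiver_volume, "receiver_volume"),
    perfusate_flow = check_nonneg(perfusate_flow, "perfusate_flow")
  ), class = "apparatus_params")
}

#' @export
print.apparatus_params <- function(x, ...) {
  cat("Perfusion-cell apparatus:\n")
  cat(sprintf("  membrane area S        %.4g cm^2\n", x$membrane_area))
  cat(sprintf("  membrane thickness hm  %.4g cm (%.3g um)\n",
              x$membrane_thickness, cm_to_um(x$membrane_thickness)))
  cat(sprintf("  mucus volume Vd        %.4g cm^3 (%.3g uL)\n",
              x$mucus_volume, cm3_to_ul(x$mucus_volume)))
  cat(sprintf("  film thickness ht      %.4g cm (%.3g um)\n",
              film_thickness(x), cm_to_um(film_thickness(x))))
  cat(sprintf("  receiver volume Vr     %.4g cm^3\n", x$receiver_volume))
  cat(sprintf("  perfusate flow Q       %.4g cm^3/min\n", x$perfusate_flow))
  invisible(x)
}

#' Mucus film thickness
#'
#' The donor film thickness \eqn{h_t = V_d / S}: the mucus simulant volume
#' spread uniformly over the membrane area. This is the thickness entering
#' the depletion-zone resistance in the unstirred donor model.
#'
#' @param apparatus an [apparatus_params()] object.
#' @return film thickness in cm.
#' @export
film_thickness <- function(apparatus) {
  apparatus$mucus_volume / apparatus$membrane_area
}

#' Run specification: dose, dose form, stirring mode and numerics
#'
#' @param dose total drug mass placed in the film, in g.
#' @param dose_form `"particles"` for a suspension of respirable particles
#'   (dissolution followed by permeation) or `"solution"` for pre-dissolved
#'   drug (permeation only). A solution dose is placed entirely in the
#'   dissolved stock even if it exceeds the saturation capacity
#'   \eqn{C_s V_d}; the solubility cap applies to dissolving particles
#'   only (no precipitation is modelled).
#' @param stirring `"well_stirred"` (homogeneous donor, constant
#'   permeability) or `"unstirred"` (a depletion zone of thickness
#'   \eqn{f_d h_t} grows as drug leaves the donor and adds series
#'   resistance).
#' @param t_end simulation horizon in min.
#' @param dt fixed integration step in min.
#' @param integrator `"rk4"` (default) or `"euler"`.
#' @param output_every spacing of stored output points in min; must be a
#'   multiple of `dt`.
#' @return an object of class `run_spec`.
#' @export
#' @examples
#' run_spec(dose = 50e-6, dose_form = "solution", stirring = "well_stirred")
run_spec <- function(dose,
                     dose_form = c("particles", "solution"),
                     stirring = c("well_stirred", "unstirred"),
                     t_end = 120, dt = 0.01,
                     integrator = c("rk4", "euler"),
                     output_every = 1) {
  dose_form <- match.arg(dose_form)
  stirring <- match.arg(stirring)
  integrator <- match.arg(integrator)
  check_positive(dose, "dose")
  check_positive(t_end, "t_end")
  check_positive(dt, "dt")
  check_positive(output_every, "output_every")
  if (dt > t_end) stop_invalid("dt", "must not exceed t_end")
  stride <- output_every / dt
  if (abs(stride - round(stride)) > 1e-8)
    stop_invalid("output_every", "must be an integer multiple of dt")
  structure(list(
    dose = dose, dose_form = dose_form, stirring = stirring,
    t_end = t_end, dt = dt, integrator = integrator,
    output_every = output_every
  ), class = "run_spec")
}

#' @export
print.run_spec <- function(x, ...) {
  cat(sprintf("Run: %g ug as %s, %s donor; %s, dt = %g min, t_end = %g min\n",
              g_to_ug(x$dose), x$dose_form, sub("_", "-", x$stirring),
              toupper(x$integrator), x$dt, x$t_end))
  invisible(x)
}

#' System state: the four mass stocks
#'
#' A snapshot of the four compartments at one time point: undissolved
#' solid in the film, dissolved drug in the mucus simulant, drug in the
#' receiver perfusate, and drug already swept into the collection tubes.
#' Their sum is conserved and equals the dose.
#'
#' @param t time in min.
#' @param mass_solid,mass_dissolved,mass_receiver,mass_collected stock
#'   masses in g, all non-negative.
#' @return an object of class `system_state` (a named list).
#' @export
system_state <- function(t = 0, mass_solid = 0, mass_dissolved = 0,
                         mass_receiver = 0, mass_collected = 0) {
  for (f in c("mass_solid", "mass_dissolved", "mass_receiver", "mass_collected"))
    check_nonneg(get(f), f)
  check_nonneg(t, "t")
  structure(list(t = t, mass_solid = mass_solid,
                 mass_dissolved = mass_dissolved,
                 mass_receiver = mass_receiver,
                 mass_collected = mass_collected),
            class = "system_state")
}

initial_state <- function(run) {
  if (run$dose_form == "particles")
    system_state(0, mass_solid = run$dose)
  else
    system_state(0, mass_dissolved = run$dose)
}
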