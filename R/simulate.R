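# Four-stock compartmental model and its fixed-step integrator.
#
# Stocks: solid particles -> dissolved in mucus -> receiver perfusate ->
# collection tubes. The right-hand side is assembled from the pointwise
# kinetic laws in kinetics.R; integration is fixed-step RK4 (or Euler for
# parity with simple stock-and-flow tools), with a per-step projection so
# no stock is driven below zero when a fixed step overshoots exhaustion.

# Build a fast derivative closure over the scenario constants.
# Returns function(m) -> c(d_solid, d_dissolved, d_receiver, d_collected).
make_derivative <- function(drug, apparatus, run) {
  M0 <- run$dose
  particles <- run$dose_form == "particles"
  well <- run$stirring == "well_stirred"
  Cs <- drug$solubility
  k <- drug$intrinsic_dissolution_rate / Cs
  d0 <- drug$particle_diameter
  rho <- drug$particle_density
  S <- apparatus$membrane_area
  Vd <- apparatus$mucus_volume
  Vr <- apparatus$receiver_volume
  Q <- apparatus$perfusate_flow
  ht <- Vd / S
  p_num <- drug$permeability_exp * drug$membrane_thickness_exp
  hm <- apparatus$membrane_thickness
  p_const <- p_num / hm
  area0 <- 6 * M0 / (d0 * rho)

  function(m) {
    conc <- m[2L] / Vd
    conc_p <- m[3L] / Vr
    if (particles && m[1L] > 0) {
      # S_t = S_0 (M_t/M_0)^(2/3): shrinking monodisperse spheres
      diss <- k * area0 * (max(m[1L], 0) / M0)^(2 / 3) * (Cs - conc)
      if (diss < 0) diss <- 0
    } else diss <- 0
    p <- if (well) p_const else p_num / (hm + (m[3L] + m[4L]) / M0 * ht)
    perm <- p * S * (conc - conc_p)
    coll <- conc_p * Q
    c(-diss, diss - perm, perm - coll, coll)
  }
}

#' Instantaneous mass rates of the four stocks
#'
#' Evaluates the model right-hand side at one state: dissolution moves
#' mass from solid to dissolved (zero for a solution dose), permeation
#' moves it from dissolved to the receiver, and collection sweeps it from
#' the receiver (an ideally mixed, constant-volume compartment whose
#' outflow is at its bulk concentration) into the tubes.
#'
#' @param state a [system_state()].
#' @param drug a [drug_params()].
#' @param apparatus an [apparatus_params()].
#' @param run a [run_spec()].
#' @return named numeric vector of rates (g/min) for `mass_solid`,
#'   `mass_dissolved`, `mass_receiver`, `mass_collected`; they sum to zero.
#' @export
#' @examples
#' pre <- preset("moxifloxacin_table1")
#' st <- system_state(0, mass_dissolved = pre$run$dose)
#' mass_rates(st, pre$drug, pre$apparatus,
#'            run_spec(pre$run$dose, "solution", "well_stirred"))
mass_rates <- function(state, drug, apparatus, run) {
  m <- c(state$mass_solid, state$mass_dissolved,
         state$mass_receiver, state$mass_collected)
  if (any(!is.finite(m)) || any(m < 0))
    stop("invalid state: stock masses must be finite and non-negative",
         call. = FALSE)
  if (state$mass_solid > run$dose * (1 + 1e-9))
    stop("invalid state: mass_solid exceeds the dose", call. = FALSE)
  r <- make_derivative(drug, apparatus, run)(m)
  names(r) <- c("mass_solid", "mass_dissolved", "mass_receiver", "mass_collected")
  r
}

# Shift any (small, overshoot-induced) negative mass downstream so the
# projection conserves total mass exactly.
project_nonnegative <- function(m) {
  for (i in 1:3) {
    if (m[i] < 0) {
      m[i + 1L] <- m[i + 1L] + m[i]
      m[i] <- 0
    }
  }
  if (m[4L] < 0) m[4L] <- 0
  m
}

#' Simulate dissolution and permeation over the run horizon
#'
#' Integrates the four-stock model with a fixed-step scheme (classical
#' RK4 by default, forward Euler optionally) from the initial condition
#' implied by the dose form: the full dose as solid particles, or fully
#' pre-dissolved. After each step, stocks are projected to be
#' non-negative (the tiny overshoot a fixed step can produce as the solid
#' or dissolved stock empties is passed downstream, conserving mass).
#'
#' @inheritParams mass_rates
#' @return an object of class `permeation_sim` with components
#'   \describe{
#'     \item{times}{stored time grid (min), spaced `run$output_every`.}
#'     \item{states}{data frame of the four stock masses (g) at each
#'       stored time.}
#'     \item{snapshots}{data frame of derived quantities at each stored
#'       time: donor and receiver concentrations (g/cm^3), particle
#'       diameter (cm), particle surface area (cm^2), permeability
#'       (cm/min), depletion-zone thickness (cm).}
#'     \item{pct_collected}{cumulative percent of the dose in the
#'       collection tubes.}
#'     \item{drug, apparatus, run}{the inputs.}
#'     \item{metadata}{integrator, step size, package version.}
#'   }
#' @export
#' @examples
#' pre <- preset("ethionamide_table1")
#' run <- run_spec(50e-6, "solution", "well_stirred",
#'                 t_end = 60, dt = 0.05)
#' sim <- simulate_permeation(pre$drug, pre$apparatus, run)
#' time_to_fraction(sim, 0.5)
simulate_permeation <- function(drug, apparatus, run) {
  stopifnot(inherits(drug, "drug_params"),
            inherits(apparatus, "apparatus_params"),
            inherits(run, "run_spec"))
  deriv <- make_derivative(drug, apparatus, run)
  dt <- run$dt
  n_steps <- round(run$t_end / dt)
  stride <- round(run$output_every / dt)
  n_out <- floor(n_steps / stride) + 1L
  out <- matrix(0, nrow = n_out, ncol = 5L)
  colnames(out) <- c("t", "mass_solid", "mass_dissolved",
                     "mass_receiver", "mass_collected")
  st0 <- initial_state(run)
  m <- c(st0$mass_solid, st0$mass_dissolved, st0$mass_receiver,
         st0$mass_collected)
  out[1L, ] <- c(0, m)
  rk4 <- run$integrator == "rk4"
  row <- 1L
  for (i in seq_len(n_steps)) {
    if (rk4) {
      k1 <- deriv(m)
      k2 <- deriv(project_nonnegative(m + dt / 2 * k1))
      k3 <- deriv(project_nonnegative(m + dt / 2 * k2))
      k4 <- deriv(project_nonnegative(m + dt * k3))
      m <- m + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    } else {
      m <- m + dt * deriv(m)
    }
    m <- project_nonnegative(m)
    if (any(!is.finite(m)))
      stop(sprintf("integration failure: non-finite state at step %d (t = %g min)",
                   i, i * dt), call. = FALSE)
    if (i %% stride == 0L) {
      row <- row + 1L
      out[row, ] <- c(i * dt, m)
    }
  }
  out <- out[seq_len(row), , drop = FALSE]
  states <- as.data.frame(out)

  fd <- (states$mass_receiver + states$mass_collected) / run$dose
  snap <- data.frame(
    donor_conc = states$mass_dissolved / apparatus$mucus_volume,
    receiver_conc = states$mass_receiver / apparatus$receiver_volume,
    particle_diameter = if (run$dose_form == "particles")
      particle_diameter_at(pmin(states$mass_solid, run$dose), run$dose,
                           drug$particle_diameter)
    else rep(0, nrow(states)),
    surface_area = if (run$dose_form == "particles")
      total_surface_area(pmin(states$mass_solid, run$dose), run$dose,
                         drug$particle_diameter, drug$particle_density)
    else rep(0, nrow(states)),
    permeability = permeability(run$stirring, drug$permeability_exp,
                                drug$membrane_thickness_exp,
                                apparatus$membrane_thickness,
                                depletion_frac = pmin(fd, 1),
                                film_thickness = film_thickness(apparatus)),
    depletion_thickness = if (run$stirring == "unstirred")
      pmin(fd, 1) * film_thickness(apparatus) else rep(0, nrow(states))
  )

  structure(list(
    times = states$t,
    states = states,
    snapshots = snap,
    pct_collected = 100 * states$mass_collected / run$dose,
    drug = drug, apparatus = apparatus, run = run,
    metadata = list(
      integrator = run$integrator, dt = run$dt,
      output_every = run$output_every,
      package_version = as.character(utils::packageVersion("mucosim"))
    )
  ), class = "permeation_sim")
}

#' @export
print.permeation_sim <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Permeation simulation: %s, %g ug as %s, %s donor\n",
              x$drug$name, g_to_ug(x$run$dose), x$run$dose_form,
              sub("_", "-", x$run$stirring)))
  cat(sprintf("  %s, dt = %g min, horizon = %g min, %d stored points\n",
              toupper(x$metadata$integrator), x$metadata$dt,
              x$run$t_end, n))
  cat(sprintf("  collected at end: %.2f%% of dose\n", x$pct_collected[n]))
  t50 <- time_to_fraction(x, 0.5)
  if (!is.na(t50)) cat(sprintf("  t50 = %.1f min\n", t50))
  invisible(x)
}

#' Earliest time at which a fraction of the dose has been collected
#'
#' Interpolates linearly on the stored cumulative-collection grid and
#' returns the earliest time at which `pct_collected` reaches
#' `100 * fraction`. Returns `NA_real_` if the horizon ends first.
#'
#' @param result a `permeation_sim` from [simulate_permeation()].
#' @param fraction target fraction of the dose, in (0, 1].
#' @return time in min, or `NA_real_` if the fraction is not reached.
#' @export
time_to_fraction <- function(result, fraction) {
  stopifnot(inherits(result, "permeation_sim"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop_invalid("fraction", "must lie in (0, 1]")
  pct <- result$pct_collected
  if (length(pct) == 0L) stop("empty simulation result", call. = FALSE)
  target <- 100 * fraction
  idx <- which(pct >= target)
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1L]
  if (i == 1L) return(result$times[1L])
  t0 <- result$times[i - 1L]; t1 <- result$times[i]
  p0 <- pct[i - 1L]; p1 <- pct[i]
  if (p1 == p0) return(t1)
  t0 + (target - p0) / (p1 - p0) * (t1 - t0)
}
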