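# One-at-a-time parameter sweeps: mucus volume, perfusate flow, and the
# two membrane thicknesses (experimental hexp and simulated hm). Each
# sweep value is substituted into a copy of the base scenario; changing
# the mucus volume also changes the derived film thickness h_t = Vd / S.

#' Specify a one-at-a-time parameter sweep
#'
#' @param parameter which parameter to vary: `"mucus_volume"` (cm^3;
#'   also rescales the film thickness \eqn{h_t = V_d/S}),
#'   `"perfusate_flow"` (cm^3/min), `"hexp"` (cm; the membrane thickness
#'   at which \eqn{P_{exp}} was measured, entering the permeability
#'   numerator) or `"hm"` (cm; the simulated membrane thickness, entering
#'   the denominator).
#' @param values strictly increasing positive magnitudes in cm-g-min
#'   units.
#' @param drug,apparatus,run the base scenario (see [drug_params()],
#'   [apparatus_params()], [run_spec()]).
#' @param checkpoints times (min) at which the percent collected is
#'   tabulated; must lie within `[0, run$t_end]`.
#' @return an object of class `sweep_spec`.
#' @export
#' @examples
#' pre <- preset("ethionamide_table1")
#' sweep_spec("mucus_volume", ul_to_cm3(c(25, 50, 100)),
#'            pre$drug, pre$apparatus, pre$run)
sweep_spec <- function(parameter = c("mucus_volume", "perfusate_flow",
                                     "hexp", "hm"),
                       values, drug, apparatus, run,
                       checkpoints = c(15, 30, 60, 120)) {
  parameter <- match.arg(parameter)
  if (length(values) == 0L || any(!is.finite(values)) || any(values <= 0))
    stop_invalid("values", "must be non-empty, finite and positive")
  if (is.unsorted(values, strictly = TRUE))
    stop_invalid("values", "must be strictly increasing")
  if (any(checkpoints < 0) || any(checkpoints > run$t_end))
    stop_invalid("checkpoints", "must lie within [0, t_end]")
  stopifnot(inherits(drug, "drug_params"),
            inherits(apparatus, "apparatus_params"),
            inherits(run, "run_spec"))
  structure(list(parameter = parameter, values = as.numeric(values),
                 drug = drug, apparatus = apparatus, run = run,
                 checkpoints = sort(checkpoints)),
            class = "sweep_spec")
}

apply_sweep_value <- function(spec, value) {
  drug <- spec$drug
  app <- spec$apparatus
  switch(spec$parameter,
    mucus_volume = { app$mucus_volume <- value },
    perfusate_flow = { app$perfusate_flow <- value },
    hexp = { drug$membrane_thickness_exp <- value },
    hm = { app$membrane_thickness <- value }
  )
  list(drug = drug, apparatus = app)
}

#' Run a one-at-a-time sensitivity sweep
#'
#' Simulates the base scenario once per sweep value (all runs share the
#' integrator settings of the base run) and tabulates the percent of the
#' dose collected at each checkpoint. A per-checkpoint ordering verdict
#' summarises the direction of the effect across the sweep values.
#'
#' @param spec a [sweep_spec()].
#' @return an object of class `sweep_result` with components `parameter`,
#'   `values`, `results` (list of `permeation_sim`), `checkpoint_table`
#'   (data frame with columns `parameter_value`, `checkpoint_min`,
#'   `pct_collected`) and `ordering` (data frame with the per-checkpoint
#'   direction — `"increasing"`, `"decreasing"`, `"mixed"` or `"flat"` —
#'   and the maximum pairwise spread in percent of dose).
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  results <- lapply(spec$values, function(v) {
    sc <- apply_sweep_value(spec, v)
    simulate_permeation(sc$drug, sc$apparatus, spec$run)
  })
  rows <- lapply(seq_along(spec$values), function(i) {
    data.frame(parameter_value = spec$values[i],
               checkpoint_min = spec$checkpoints,
               pct_collected = single_scenario_report(results[[i]],
                                                      spec$checkpoints))
  })
  tab <- do.call(rbind, rows)
  ordering <- do.call(rbind, lapply(spec$checkpoints, function(cp) {
    pct <- tab$pct_collected[tab$checkpoint_min == cp]
    d <- diff(pct)
    spread <- max(pct) - min(pct)
    direction <-
      if (spread < 1e-9) "flat"
      else if (all(d > 0)) "increasing"
      else if (all(d < 0)) "decreasing"
      else "mixed"
    data.frame(checkpoint_min = cp, direction = direction,
               max_spread = spread)
  }))
  structure(list(parameter = spec$parameter, values = spec$values,
                 results = results, checkpoint_table = tab,
                 ordering = ordering, spec = spec),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sensitivity sweep over %s (%d values)\n",
              x$parameter, length(x$values)))
  tab <- stats::reshape(x$checkpoint_table, direction = "wide",
                        idvar = "parameter_value",
                        timevar = "checkpoint_min")
  names(tab) <- sub("pct_collected\\.", "t=", names(tab))
  print(tab, row.names = FALSE, digits = 4)
  cat("Ordering by checkpoint:\n")
  print(x$ordering, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Percent collected at checkpoint times for one simulation
#'
#' Reads the cumulative percent collected off the stored output grid,
#' interpolating linearly between stored points.
#'
#' @param result a `permeation_sim`.
#' @param checkpoints times in min, all within the stored horizon.
#' @return numeric vector of percent of dose collected, one per
#'   checkpoint.
#' @export
single_scenario_report <- function(result, checkpoints) {
  stopifnot(inherits(result, "permeation_sim"))
  if (any(checkpoints < 0) || any(checkpoints > max(result$times)))
    stop("checkpoint beyond the simulated horizon", call. = FALSE)
  stats::approx(result$times, result$pct_collected, xout = checkpoints,
                rule = 1)$y
}

#' Write a sweep checkpoint table as CSV
#'
#' Columns: `parameter_value`, `checkpoint_min`, `pct_collected`.
#'
#' @param sweep a `sweep_result`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_checkpoint_table <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  utils::write.csv(sweep$checkpoint_table, path, row.names = FALSE)
  invisible(path)
}
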