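# Time-series serialization and the seeded fixture generator for the
# fitting stage.

timeseries_columns <- c("time_min", "mass_solid_g", "mass_dissolved_g",
                        "mass_receiver_g", "mass_collected_g",
                        "pct_collected", "donor_conc_g_cm3",
                        "receiver_conc_g_cm3", "permeability_cm_min",
                        "particle_diameter_cm")

#' Write a simulation time series to CSV
#'
#' One row per stored output point, full-precision decimal rendering (a
#' re-parse reproduces the stored doubles bit for bit). Run provenance
#' (all input parameters, integrator, step size, package version) is
#' echoed to a YAML sidecar at `<path>.meta.yaml`.
#'
#' @param result a `permeation_sim` from [simulate_permeation()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_timeseries <- function(result, path) {
  stopifnot(inherits(result, "permeation_sim"))
  df <- data.frame(
    time_min = result$times,
    mass_solid_g = result$states$mass_solid,
    mass_dissolved_g = result$states$mass_dissolved,
    mass_receiver_g = result$states$mass_receiver,
    mass_collected_g = result$states$mass_collected,
    pct_collected = result$pct_collected,
    donor_conc_g_cm3 = result$snapshots$donor_conc,
    receiver_conc_g_cm3 = result$snapshots$receiver_conc,
    permeability_cm_min = result$snapshots$permeability,
    particle_diameter_cm = result$snapshots$particle_diameter
  )
  lines <- c(paste(timeseries_columns, collapse = ","),
             apply(df, 1L, function(r)
               paste(sprintf("%.17g", r), collapse = ",")))
  tryCatch(suppressWarnings(writeLines(lines, path)),
           error = function(e)
             stop(sprintf("cannot write time series to `%s`: %s",
                          path, conditionMessage(e)), call. = FALSE))
  meta <- list(
    drug = unclass(result$drug),
    apparatus = unclass(result$apparatus),
    run = unclass(result$run),
    integrator = result$metadata$integrator,
    dt_min = result$metadata$dt,
    output_every_min = result$metadata$output_every,
    package_version = result$metadata$package_version
  )
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read back a simulation time series written by [write_timeseries()]
#'
#' @param path CSV path.
#' @return a data frame with the columns written by [write_timeseries()].
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  missing <- setdiff(timeseries_columns, names(df))
  if (length(missing))
    stop(sprintf("time-series CSV is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

#' Generate a synthetic donor-decay fixture
#'
#' Produces a noisy donor concentration-time series for exercising the
#' fitting stage: an exponential decay
#' \eqn{C_d(t) = C_{d0} \exp(-P_{exp} S t / V_d)} on the standard
#' apparatus geometry, multiplied by seeded log-normal noise
#' (multiplicative noise matches the additive-on-the-log-scale error
#' model the ln-linear regression assumes). The same spec always yields
#' the same series; the caller's RNG state is left untouched.
#'
#' @param true_permeability generating \eqn{P_{exp}} in cm/min.
#' @param n_points number of equally spaced samples (the first at t = 0).
#' @param t_max last sampling time in min.
#' @param noise_sigma standard deviation of the log-scale noise
#'   (dimensionless; 0 gives an exact exponential).
#' @param seed integer seed; fully determines the output.
#' @param conc0 initial donor concentration in g/cm^3 (default 2.0 mg/mL,
#'   i.e. 50 ug in 25 uL).
#' @param mucus_volume donor volume in cm^3.
#' @param membrane_area membrane area in cm^2.
#' @return a [concentration_series()].
#' @export
#' @examples
#' fx <- generate_fixture(5.3e-4, n_points = 30, t_max = 40,
#'                        noise_sigma = 0.02, seed = 7)
#' estimate_permeability(fx)
generate_fixture <- function(true_permeability, n_points = 30L, t_max = 60,
                             noise_sigma = 0, seed = 1L,
                             conc0 = 2.0e-3, mucus_volume = 25e-3,
                             membrane_area = 4.91) {
  check_positive(true_permeability, "true_permeability")
  check_positive(t_max, "t_max")
  check_nonneg(noise_sigma, "noise_sigma")
  if (n_points < 2L) stop_invalid("n_points", "must be at least 2")
  tt <- seq(0, t_max, length.out = n_points)
  clean <- conc0 * exp(-true_permeability * membrane_area * tt / mucus_volume)
  noise <- rep(1, n_points)
  if (noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed))
        rm(".Random.seed", envir = globalenv())
      else
        assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
    noise <- exp(stats::rnorm(n_points, mean = 0, sd = noise_sigma))
  }
  concentration_series(tt, clean * noise, mucus_volume, membrane_area)
}

#' Write a concentration series as CSV
#'
#' Columns `time_min` and `donor_conc_mg_per_mL`, the format read by
#' [read_concentration_csv()].
#'
#' @param series a [concentration_series()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_concentration_csv <- function(series, path) {
  stopifnot(inherits(series, "concentration_series"))
  df <- data.frame(time_min = series$times,
                   donor_conc_mg_per_mL =
                     g_per_cm3_to_mg_per_ml(series$concentrations))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
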