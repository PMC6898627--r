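# YAML configuration loading and the shipped drug presets. Config keys
# carry their units explicitly (e.g. mucus_volume_uL); conversion to the
# internal cm-g-min system happens here and only here.

config_schema <- list(
  top = c("label", "drug", "apparatus", "run"),
  drug = c("name", "solubility_mg_per_mL",
           "intrinsic_dissolution_rate_mg_per_cm2_min",
           "particle_diameter_um", "particle_density_g_per_cm3",
           "permeability_exp_cm_per_min", "membrane_thickness_exp_um"),
  apparatus = c("membrane_area_cm2", "membrane_thickness_um",
                "mucus_volume_uL", "receiver_volume_uL",
                "perfusate_flow_mL_per_min"),
  run = c("dose_ug", "dose_form", "stirring", "t_end_min", "dt_min",
          "integrator", "output_every_min")
)

check_keys <- function(got, allowed, section) {
  unknown <- setdiff(got, allowed)
  if (length(unknown))
    stop(sprintf("unknown key(s) in config section `%s`: %s",
                 section, paste(unknown, collapse = ", ")), call. = FALSE)
}

need_key <- function(lst, key, section) {
  if (is.null(lst[[key]]))
    stop(sprintf("config section `%s` is missing required key `%s`",
                 section, key), call. = FALSE)
  lst[[key]]
}

#' Load a scenario configuration from a YAML file
#'
#' The file has `label`, `drug`, `apparatus` and `run` sections whose
#' keys name their units explicitly (`mucus_volume_uL`,
#' `solubility_mg_per_mL`, ...). Values are converted to the internal
#' cm-g-min system and validated; unknown keys are rejected with a
#' listing. See the shipped preset files under
#' `system.file("extdata", package = "mucosim")` for the full schema.
#'
#' @param path path to a YAML config file.
#' @return a `preset` object: a list with elements `label`, `drug`
#'   ([drug_params()]), `apparatus` ([apparatus_params()]) and `run`
#'   ([run_spec()]).
#' @export
#' @examples
#' cfg <- system.file("extdata", "moxifloxacin_table1.yaml",
#'                    package = "mucosim")
#' load_config(cfg)
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  check_keys(names(cfg), config_schema$top, "(top level)")
  for (section in c("drug", "apparatus", "run")) {
    if (is.null(cfg[[section]]))
      stop(sprintf("config is missing the `%s` section", section),
           call. = FALSE)
    check_keys(names(cfg[[section]]), config_schema[[section]], section)
  }
  d <- cfg$drug
  drug <- drug_params(
    name = need_key(d, "name", "drug"),
    solubility = mg_per_ml_to_g_per_cm3(
      need_key(d, "solubility_mg_per_mL", "drug")),
    intrinsic_dissolution_rate = 1e-3 *
      need_key(d, "intrinsic_dissolution_rate_mg_per_cm2_min", "drug"),
    particle_diameter = um_to_cm(need_key(d, "particle_diameter_um", "drug")),
    particle_density = need_key(d, "particle_density_g_per_cm3", "drug"),
    permeability_exp = need_key(d, "permeability_exp_cm_per_min", "drug"),
    membrane_thickness_exp = um_to_cm(
      need_key(d, "membrane_thickness_exp_um", "drug"))
  )
  a <- cfg$apparatus
  apparatus <- apparatus_params(
    membrane_area = need_key(a, "membrane_area_cm2", "apparatus"),
    membrane_thickness = um_to_cm(
      need_key(a, "membrane_thickness_um", "apparatus")),
    mucus_volume = ul_to_cm3(need_key(a, "mucus_volume_uL", "apparatus")),
    receiver_volume = ul_to_cm3(
      need_key(a, "receiver_volume_uL", "apparatus")),
    perfusate_flow = need_key(a, "perfusate_flow_mL_per_min", "apparatus")
  )
  r <- cfg$run
  run <- run_spec(
    dose = ug_to_g(need_key(r, "dose_ug", "run")),
    dose_form = need_key(r, "dose_form", "run"),
    stirring = need_key(r, "stirring", "run"),
    t_end = if (is.null(r$t_end_min)) 120 else r$t_end_min,
    dt = if (is.null(r$dt_min)) 0.01 else r$dt_min,
    integrator = if (is.null(r$integrator)) "rk4" else r$integrator,
    output_every = if (is.null(r$output_every_min)) 1 else r$output_every_min
  )
  structure(list(label = if (is.null(cfg$label)) basename(path) else cfg$label,
                 drug = drug, apparatus = apparatus, run = run),
            class = "preset")
}

#' @export
print.preset <- function(x, ...) {
  cat("Preset:", x$label, "\n")
  print(x$drug); print(x$apparatus); print(x$run)
  invisible(x)
}

#' Shipped drug presets
#'
#' `preset()` loads one of the presets shipped with the package;
#' `list_presets()` names them. `"moxifloxacin_table1"` and
#' `"ethionamide_table1"` carry the reference parameter sets for the two
#' anti-tubercular drugs (solubility, IDR, particle size, permeability)
#' together with the standard apparatus (25 uL mucus simulant on a
#' 4.91 cm^2 membrane, 500 uL receiver, 0.4 mL/min perfusate flow,
#' 62.5 um hydrated membrane) and a 50 ug particle dose.
#'
#' @param name preset name, one of `list_presets()`.
#' @return `preset()`: a `preset` object (see [load_config()]);
#'   `list_presets()`: a character vector.
#' @export
#' @examples
#' list_presets()
#' preset("ethionamide_table1")$drug$solubility   # 0.46 mg/mL in g/cm^3
preset <- function(name) {
  path <- system.file("extdata", paste0(name, ".yaml"), package = "mucosim")
  if (path == "")
    stop(sprintf("unknown preset `%s`; available: %s", name,
                 paste(list_presets(), collapse = ", ")), call. = FALSE)
  load_config(path)
}

#' @rdname preset
#' @export
list_presets <- function() {
  files <- list.files(system.file("extdata", package = "mucosim"),
                      pattern = "\\.yaml$")
  sub("\\.yaml$", "", files)
}
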