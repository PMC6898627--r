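# Reference scenarios built in code (independently of the shipped YAML
# presets) so preset-loading bugs cannot mask kinetics bugs.

ref_drug <- function(name = c("moxifloxacin", "ethionamide")) {
  name <- match.arg(name)
  if (name == "moxifloxacin")
    drug_params("moxifloxacin",
                solubility = 17.70e-3,
                intrinsic_dissolution_rate = 0.50e-3,
                particle_diameter = 2.9e-4,
                particle_density = 1.0,
                permeability_exp = 1.8e-4,
                membrane_thickness_exp = 62.5e-4)
  else
    drug_params("ethionamide",
                solubility = 0.46e-3,
                intrinsic_dissolution_rate = 0.06e-3,
                particle_diameter = 3.6e-4,
                particle_density = 1.0,
                permeability_exp = 5.3e-4,
                membrane_thickness_exp = 62.5e-4)
}

ref_apparatus <- function(...) apparatus_params(...)

# Minimal permeation_sim stand-in for readout helpers that only need the
# stored grid.
fake_sim <- function(times, pct) {
  structure(list(times = times, pct_collected = pct), class = "permeation_sim")
}
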