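Package: mucosim
Title: Dissolution and Membrane Permeation of Respirable Particles in a Thin Mucus Film
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartmental simulation of inhaled drug dissolution and
    permeation in a flow-through dissolution cell: respirable (1-5 um)
    monodisperse particles dissolve by Noyes-Whitney shrinking-sphere
    kinetics in a ~50 um mucus-simulant film spread on a dialysis
    membrane, dissolved drug permeates into a perfused receiver, and the
    perfusate is swept into collection tubes. Both a well-stirred donor
    and an unstirred donor with a growing depletion zone are modelled.
    Includes drug presets for moxifloxacin and ethionamide,
    one-at-a-time sensitivity sweeps (mucus volume, perfusate flow,
    membrane thickness), permeability-coefficient estimation by
    ln-linear regression of donor concentration decay, a seeded fixture
    generator for the fitting stage, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
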