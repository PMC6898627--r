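# mucosim

Compartmental simulation of *in vitro* dissolution testing for inhaled
dry powders. In the apparatus being modelled, respirable (1–5 µm) drug
particles are deposited into a thin film of mucus simulant — 25 µL
spread over a 4.91 cm² dialysis membrane, i.e. about 50 µm deep — drug
dissolves, permeates the membrane into a 500 µL perfused receiver, and
the perfusate is collected continuously. `mucosim` is for formulation
and biopharmaceutics scientists who want to predict and interpret such
permeation profiles before (or instead of) running the bench experiment:
it answers questions like *is this drug's permeation dissolution-limited
or membrane-limited?* and *which apparatus parameters actually matter?*

## The model

Four mass stocks — solid particles, dissolved drug in mucus, drug in the
receiver, drug collected — connected by three kinetic laws (cm–g–min
units throughout):

- **Dissolution** (Noyes–Whitney, shrinking monodisperse spheres):
  `dM/dt = k·S_t·(Cs − C)` with `k = IDR/Cs` and
  `S_t = S_0·(M_t/M_0)^(2/3)`; the driving force is clamped at zero at
  saturation.
- **Permeation** (Fick, lumped barrier): `P·S·(C_mucus − C_perfusate)`.
  With a well-stirred donor `P = P_exp·h_exp/h_m` is constant; with an
  unstirred donor a depletion zone of thickness `f_d·h_t` grows as the
  fraction `f_d` of dose leaves the film, giving
  `P_t = P_exp·h_exp/(h_m + f_d·h_t)`.
- **Collection**: `C_perfusate·Q` out of an ideally mixed receiver.

Integration is fixed-step RK4 (Euler selectable), with per-step
clamping so no stock goes negative; mass balance holds to floating
point. Presets ship for two anti-tubercular drugs of contrasting
solubility, moxifloxacin (17.70 mg/mL) and ethionamide (0.46 mg/mL).
The package also estimates the permeability coefficient from donor
concentration decay (`ln C_d = ln C_d0 − P·S·t/V_d`) by OLS, runs
one-at-a-time sensitivity sweeps, and generates seeded noisy fixtures
for the fitting stage.

## Worked example

```r
library(mucosim)

pre <- preset("ethionamide_table1")   # 50 ug particles, standard cell
sim <- simulate_permeation(pre$drug, pre$apparatus, pre$run)
sim
#> Permeation simulation: ethionamide, 50 ug as particles, well-stirred donor
#>   RK4, dt = 0.01 min, horizon = 120 min, 121 stored points
#>   collected at end: 100.00% of dose
#>   t50 = 23.3 min

single_scenario_report(sim, c(15, 30, 60, 120))
#> [1] 31.12475 64.94637 98.08245 99.99611

# the same dose pre-dissolved permeates much faster: dissolution of the
# poorly soluble particles, not the membrane, is rate-limiting
run_sol <- run_spec(50e-6, "solution", "well_stirred", t_end = 120, dt = 0.01)
time_to_fraction(simulate_permeation(pre$drug, pre$apparatus, run_sol), 0.99)
#> [1] 45.90424

# recover a permeability coefficient from a noisy donor-decay series
fx <- generate_fixture(5.3e-4, n_points = 30, t_max = 40,
                       noise_sigma = 0.02, seed = 7)
estimate_permeability(fx)
#> Permeability fit (ln Cd vs t):
#>   Pexp = 0.0005181 cm/min, Cd0 = 0.001978 g/cm^3
#>   R^2 = 0.99760 over 12 points, t in [0, 15.1724] min (cumulative permeation <= 80%)
```

The first readouts say a 50 µg ethionamide particle dose delivers ~31%
of dose by 15 min and ~98% by 60 min, while the pre-dissolved dose
reaches 99% collected at 45.9 min; the gap is the dissolution
limitation (25 µL of film can only hold 11.5 µg of ethionamide in
solution at a time). The fit recovers the generating permeability
(5.3e-4 cm/min) within ~2% from 2%-noise data.

A command-line interface wraps the same functions
(`system.file("cli", "mucosim", package = "mucosim")`), with subcommands
`simulate`, `sweep`, `fit`, `preset` and `fixture`.

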