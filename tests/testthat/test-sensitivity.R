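# One-at-a-time sweeps: directional effects of mucus volume, membrane
# thicknesses and perfusate flow, and the checkpoint-table plumbing.

sweep_run <- function(dt = 0.05, t_end = 120, form = "particles",
                      stirring = "well_stirred", dose = 50e-6)
  run_spec(dose, form, stirring, t_end = t_end, dt = dt)

test_that("increasing mucus volume slows permeation for both drugs", {
  vols <- ul_to_cm3(c(25, 50, 100))
  for (nm in c("moxifloxacin", "ethionamide")) {
    drug <- ref_drug(nm)
    for (stir in c("well_stirred", "unstirred")) {
      sw <- run_sweep(sweep_spec("mucus_volume", vols, drug,
                                 ref_apparatus(), sweep_run(stirring = stir)))
      at60 <- subset(sw$checkpoint_table, checkpoint_min == 60)
      expect_true(all(diff(at60$pct_collected) < 0),
                  label = paste(nm, stir, "volume ordering at 60 min"))
      expect_equal(sw$ordering$direction[sw$ordering$checkpoint_min == 60],
                   "decreasing")
    }
  }
})

test_that("for the dissolution-limited drug the depletion zone compounds the volume effect", {
  # larger volume raises both donor dilution and the film thickness h_t,
  # so for ethionamide the volume-induced spread is larger unstirred at
  # every checkpoint
  vols <- ul_to_cm3(c(25, 50, 100))
  drug <- ref_drug("ethionamide")
  ws <- run_sweep(sweep_spec("mucus_volume", vols, drug, ref_apparatus(),
                             sweep_run(stirring = "well_stirred")))
  us <- run_sweep(sweep_spec("mucus_volume", vols, drug, ref_apparatus(),
                             sweep_run(stirring = "unstirred")))
  expect_true(all(us$ordering$max_spread >= ws$ordering$max_spread))
})

test_that("film thickness tracks the swept mucus volume", {
  spec <- sweep_spec("mucus_volume", ul_to_cm3(c(25, 100)),
                     ref_drug("ethionamide"), ref_apparatus(),
                     sweep_run(dt = 0.1, t_end = 30, stirring = "unstirred"),
                     checkpoints = c(15, 30))
  sw <- run_sweep(spec)
  # quadrupling the volume quadruples h_t, so the depletion resistance
  # at matched depletion fraction is larger: permeability at the end of
  # the 100 uL run must be below the 25 uL run's
  p_small <- tail(sw$results[[1]]$snapshots$permeability, 1)
  p_large <- tail(sw$results[[2]]$snapshots$permeability, 1)
  expect_lt(p_large, p_small)
})

test_that("perfusate flow has no significant effect on collection", {
  flows <- c(0.2, 0.4, 0.8)
  for (nm in c("moxifloxacin", "ethionamide")) {
    for (stir in c("well_stirred", "unstirred")) {
      sw <- run_sweep(sweep_spec("perfusate_flow", flows, ref_drug(nm),
                                 ref_apparatus(), sweep_run(stirring = stir)))
      expect_lt(max(sw$ordering$max_spread), 5)
    }
  }
})

test_that("thicker simulated membranes slow permeation", {
  hms <- um_to_cm(c(30, 60, 90))
  for (nm in c("moxifloxacin", "ethionamide")) {
    sw <- run_sweep(sweep_spec("hm", hms, ref_drug(nm), ref_apparatus(),
                               sweep_run()))
    at60 <- subset(sw$checkpoint_table, checkpoint_min == 60)
    expect_true(all(diff(at60$pct_collected) < 0), label = nm)
  }
})

test_that("larger experimental membrane thickness speeds permeation", {
  # hexp enters the permeability numerator: P = Pexp * hexp / h_T
  hexps <- um_to_cm(c(60, 80, 100))
  sw <- run_sweep(sweep_spec("hexp", hexps, ref_drug("moxifloxacin"),
                             ref_apparatus(),
                             sweep_run(form = "solution",
                                       stirring = "unstirred")))
  for (cp in c(15, 30, 60)) {
    at <- subset(sw$checkpoint_table, checkpoint_min == cp)
    expect_true(all(diff(at$pct_collected) > 0))
  }
})

test_that("reported orderings are invariant to halving the step", {
  vols <- ul_to_cm3(c(25, 50, 100))
  coarse <- run_sweep(sweep_spec("mucus_volume", vols,
                                 ref_drug("ethionamide"), ref_apparatus(),
                                 sweep_run(dt = 0.1, t_end = 60,
                                           stirring = "unstirred"),
                                 checkpoints = c(15, 30, 60)))
  fine <- run_sweep(sweep_spec("mucus_volume", vols,
                               ref_drug("ethionamide"), ref_apparatus(),
                               sweep_run(dt = 0.05, t_end = 60,
                                         stirring = "unstirred"),
                               checkpoints = c(15, 30, 60)))
  expect_equal(coarse$ordering$direction, fine$ordering$direction)
})

test_that("checkpoint readout interpolates the stored grid", {
  sim <- simulate_permeation(ref_drug("ethionamide"), ref_apparatus(),
                             run_spec(50e-6, "solution", "well_stirred",
                                      t_end = 80, dt = 0.02))
  expect_equal(single_scenario_report(sim, 0), 0)
  expect_gte(single_scenario_report(sim, 60), 99)
  expect_error(single_scenario_report(sim, 200), "beyond")
  mid <- single_scenario_report(sim, 10.5)
  expect_gt(mid, single_scenario_report(sim, 10))
  expect_lt(mid, single_scenario_report(sim, 11))
})

test_that("sweep results are well-formed and serialisable", {
  spec <- sweep_spec("perfusate_flow", c(0.2, 0.4), ref_drug("moxifloxacin"),
                     ref_apparatus(), sweep_run(dt = 0.1, t_end = 30),
                     checkpoints = c(10, 30))
  sw <- run_sweep(spec)
  expect_equal(nrow(sw$checkpoint_table), 2 * 2)
  expect_named(sw$checkpoint_table,
               c("parameter_value", "checkpoint_min", "pct_collected"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_checkpoint_table(sw, path)
  back <- read.csv(path)
  expect_equal(back$pct_collected, sw$checkpoint_table$pct_collected)
  expect_error(sweep_spec("perfusate_flow", c(0.4, -0.2),
                          ref_drug("moxifloxacin"), ref_apparatus(),
                          sweep_run(dt = 0.1, t_end = 30)),
               "values")
  expect_error(sweep_spec("perfusate_flow", c(0.4, 0.2),
                          ref_drug("moxifloxacin"), ref_apparatus(),
                          sweep_run(dt = 0.1, t_end = 30)),
               "increasing")
})
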