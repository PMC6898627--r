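# Four-stock integrator: conservation, monotonicity, convergence and
# agreement with independent oracles.

test_that("mass rates vanish at equilibrium states and match hand arithmetic", {
  drug <- ref_drug("moxifloxacin")
  app <- ref_apparatus()
  run <- run_spec(50e-6, "particles", "well_stirred")
  empty <- system_state(0)
  expect_equal(unname(mass_rates(empty, drug, app, run)), rep(0, 4))
  run_sol <- run_spec(50e-6, "solution", "well_stirred")
  done <- system_state(200, mass_collected = 50e-6)
  expect_equal(unname(mass_rates(done, drug, app, run_sol)), rep(0, 4))
  # pre-dissolved reference state at t = 0: permeation = Pexp*S*(M0/Vd)
  st0 <- system_state(0, mass_dissolved = 50e-6)
  r <- mass_rates(st0, drug, app, run_sol)
  expect_equal(unname(r[["mass_receiver"]]), 1.768e-6, tolerance = 1e-3)
  expect_equal(sum(r), 0)
  expect_error(mass_rates(system_state(0, mass_solid = 60e-6),
                          drug, app, run), "invalid state")
})

test_that("mass is conserved and stocks stay ordered for both integrators", {
  drug <- ref_drug("ethionamide")
  app <- ref_apparatus()
  for (integ in c("rk4", "euler")) {
    for (form in c("particles", "solution")) {
      for (stir in c("well_stirred", "unstirred")) {
        run <- run_spec(50e-6, form, stir, t_end = 60, dt = 0.02,
                        integrator = integ)
        sim <- simulate_permeation(drug, app, run)
        total <- with(sim$states,
                      mass_solid + mass_dissolved + mass_receiver +
                        mass_collected)
        expect_lt(max(abs(total - 50e-6)), 1e-6 * 50e-6)
        expect_true(all(as.matrix(sim$states[-1]) >= 0))
        expect_true(all(diff(sim$states$mass_solid) <= 1e-15))
        expect_true(all(diff(sim$states$mass_collected) >= 0))
        expect_true(all(diff(sim$pct_collected) >= 0))
        expect_true(all(sim$pct_collected <= 100 + 1e-9))
      }
    }
  }
})

test_that("donor concentration never exceeds solubility for particle doses", {
  drug <- ref_drug("ethionamide")
  run <- run_spec(50e-6, "particles", "well_stirred", t_end = 60, dt = 0.02)
  sim <- simulate_permeation(drug, ref_apparatus(), run)
  expect_true(all(sim$snapshots$donor_conc <= drug$solubility * (1 + 1e-9)))
})

test_that("well-stirred solution run matches the closed-form chain solution", {
  drug <- ref_drug("ethionamide")
  app <- ref_apparatus()
  run <- run_spec(50e-6, "solution", "well_stirred", t_end = 90, dt = 0.01)
  sim <- simulate_permeation(drug, app, run)
  cf <- closed_form_solution_run(sim$times, 50e-6,
                                 drug$permeability_exp,
                                 drug$membrane_thickness_exp,
                                 app$membrane_thickness,
                                 app$membrane_area, app$mucus_volume,
                                 app$receiver_volume, app$perfusate_flow)
  expect_lt(max(abs(sim$states$mass_dissolved - cf$donor)) / 50e-6, 1e-5)
  expect_lt(max(abs(sim$states$mass_collected - cf$collected)) / 50e-6, 1e-5)
})

test_that("with a sink receiver the donor decays as M0 exp(-PSt/Vd)", {
  drug <- ref_drug("ethionamide")
  app <- ref_apparatus(perfusate_flow = 1e3)  # effectively instant washout
  run <- run_spec(50e-6, "solution", "well_stirred", t_end = 30, dt = 0.005)
  sim <- simulate_permeation(drug, app, run)
  a <- drug$permeability_exp * app$membrane_area / app$mucus_volume
  expected <- 50e-6 * exp(-a * 30)
  got <- sim$states$mass_dissolved[sim$times == 30]
  expect_equal(got, expected, tolerance = 1e-3)
})

test_that("RK4 agrees with small-step Euler, both in-package and naive", {
  drug <- ref_drug("ethionamide")
  app <- ref_apparatus()
  rk <- simulate_permeation(drug, app,
                            run_spec(50e-6, "particles", "unstirred",
                                     t_end = 30, dt = 0.01))
  eu <- simulate_permeation(drug, app,
                            run_spec(50e-6, "particles", "unstirred",
                                     t_end = 30, dt = 0.001,
                                     integrator = "euler"))
  n <- length(rk$times)
  expect_lt(abs(rk$pct_collected[n] - eu$pct_collected[n]), 0.1)
  # fully independent forward-Euler oracle written from the equations
  run <- run_spec(50e-6, "particles", "unstirred", t_end = 30, dt = 0.01)
  oracle <- naive_euler_oracle(drug, app, run, dt = 1e-3, t_end = 30)
  expect_lt(abs(rk$pct_collected[n] -
                  100 * oracle[["collected"]] / 50e-6), 0.1)
})

test_that("depletion zone only adds resistance: unstirred never leads", {
  app <- ref_apparatus()
  for (nm in c("moxifloxacin", "ethionamide")) {
    drug <- ref_drug(nm)
    ws <- simulate_permeation(drug, app,
                              run_spec(50e-6, "particles", "well_stirred",
                                       t_end = 120, dt = 0.02))
    us <- simulate_permeation(drug, app,
                              run_spec(50e-6, "particles", "unstirred",
                                       t_end = 120, dt = 0.02))
    expect_true(all(us$pct_collected <= ws$pct_collected + 1e-9))
    expect_true(all(us$snapshots$depletion_thickness >= 0))
    expect_equal(ws$snapshots$depletion_thickness,
                 rep(0, length(ws$times)))
  }
})

test_that("fast dissolution collapses the particle run onto the solution run", {
  base <- ref_drug("ethionamide")
  fast <- drug_params(base$name, base$solubility,
                      base$intrinsic_dissolution_rate * 1e3,
                      base$particle_diameter, base$particle_density,
                      base$permeability_exp, base$membrane_thickness_exp)
  app <- ref_apparatus()
  # use a sub-saturation dose so the solution and suspension see the
  # same driving concentration once dissolution is instantaneous
  dose <- 10e-6
  part <- simulate_permeation(fast, app,
                              run_spec(dose, "particles", "well_stirred",
                                       t_end = 60, dt = 0.01))
  sol <- simulate_permeation(fast, app,
                             run_spec(dose, "solution", "well_stirred",
                                      t_end = 60, dt = 0.01))
  expect_lt(max(abs(part$pct_collected - sol$pct_collected)), 0.5)
})

test_that("time_to_fraction interpolates and flags unreached targets", {
  sim <- fake_sim(c(0, 1, 2), c(0, 50, 100))
  expect_equal(time_to_fraction(sim, 0.5), 1)
  expect_equal(time_to_fraction(sim, 0.25), 0.5)
  expect_equal(time_to_fraction(sim, 1), 2)
  expect_error(time_to_fraction(sim, 0), "fraction")
  expect_error(time_to_fraction(sim, 1.5), "fraction")
  expect_true(is.na(time_to_fraction(fake_sim(c(0, 1), c(0, 10)), 0.5)))
})
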