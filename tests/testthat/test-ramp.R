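# reversible-inactivation model: velocity, entropy solver, simulation, fitting

test_that("velocity is the Eyring rate damped by 1 + K_inact", {
  T <- to_kelvin(35)
  # K_inact = 1 exactly when dG_inact = 0 at T: dS = dH/T
  m_half <- inactivation_model(dH_rxn = 11, dH_inact = 80, dS_inact = 80 / T,
                               amplitude = 2)
  expect_equal(k_inact(m_half, T), 1, tolerance = 1e-12)
  uninhibited <- 2 * eyring_rate(11, T)
  expect_equal(velocity(m_half, T), uninhibited / 2, tolerance = 1e-12)
  # enormous inactivation enthalpy: K -> 0, uninhibited limit
  m_free <- inactivation_model(dH_rxn = 11, dH_inact = 500, dS_inact = 0.1,
                               amplitude = 2)
  expect_equal(velocity(m_free, T), uninhibited, tolerance = 1e-9)
  # v never exceeds the uninhibited Eyring velocity
  m <- inactivation_model(dH_rxn = 11, dH_inact = 100,
                          dS_inact = solve_entropy_for_optimum(11, 100, 318.15))
  Ts <- seq(280, 345, by = 0.5)
  expect_true(all(velocity(m, Ts) <= m$amplitude * eyring_rate(11, Ts)))
  expect_error(velocity(m, -1), "positive")
})

test_that("solve_entropy_for_optimum places the argmax where asked", {
  # defining identity: K(T_opt) = f/(1-f) with f = (dH_rxn + R T)/dH_inact
  for (case in list(c(11, 100, 318.15), c(8.3, 100, 312.15),
                    c(11.5, 150, 331.15), c(5, 60, 300))) {
    dHr <- case[1]; dHi <- case[2]; Topt <- case[3]
    dS <- solve_entropy_for_optimum(dHr, dHi, Topt)
    m <- inactivation_model(dH_rxn = dHr, dH_inact = dHi, dS_inact = dS)
    f <- (dHr + R_KCAL * Topt) / dHi
    expect_equal(k_inact(m, Topt), f / (1 - f), tolerance = 1e-10)
    # fine-grid argmax oracle
    grid <- seq(283, 343, by = 0.01)
    v <- velocity(m, grid)
    expect_lt(abs(grid[which.max(v)] - Topt), 0.05)
    # unimodal on the window: increasing before, decreasing after
    expect_true(all(diff(v[grid < Topt - 0.5]) > 0))
    expect_true(all(diff(v[grid > Topt + 0.5]) < 0))
  }
  # precondition: no interior optimum when dH_inact too small
  expect_error(solve_entropy_for_optimum(11, 11, 318.15), "no interior optimum")
  # dH_inact just above the bound: K(T_opt) >> 1
  dHi <- 11 + R_KCAL * 318.15 + 0.05
  dS <- solve_entropy_for_optimum(11, dHi, 318.15)
  m <- inactivation_model(dH_rxn = 11, dH_inact = dHi, dS_inact = dS)
  expect_gt(k_inact(m, 318.15), 100)
})

test_that("simulate_ramp integrates the forward model accurately", {
  dS <- solve_entropy_for_optimum(11, 100, 318.15)
  m <- inactivation_model(dH_rxn = 11, dH_inact = 100, dS_inact = dS,
                          amplitude = 1e9)
  proto <- ramp_protocol(10, 10, 360, 1)
  tr <- simulate_ramp(m, proto)
  expect_equal(nrow(tr), 361)
  expect_true(all(diff(tr$absorbance) >= 0)) # noiseless trace non-decreasing
  expect_equal(tr$temperature_C[c(1, 361)], c(10, 70))
  # halving the integrator step barely changes the result
  A10 <- topt:::.integrate_ramp(m, tr$time_s, proto$T_start, proto$rate, substeps = 10)
  A20 <- topt:::.integrate_ramp(m, tr$time_s, proto$T_start, proto$rate, substeps = 20)
  expect_lt(max(abs(A10 - A20)) / max(A20), 1e-6)
  # constant temperature, negligible inactivation: exactly linear absorbance
  m_lin <- inactivation_model(dH_rxn = 11, dH_inact = 500, dS_inact = 0,
                              amplitude = 1e9)
  tr_const <- simulate_ramp(m_lin, ramp_protocol(25, 0, 100, 1))
  expect_equal(tr_const$absorbance,
               velocity(m_lin, to_kelvin(25)) * tr_const$time_s,
               tolerance = 1e-9)
  # an astronomically high barrier gives a flat trace at zero
  m_flat <- inactivation_model(dH_rxn = 250, dH_inact = 100, dS_inact = 0.3,
                               amplitude = 1)
  expect_equal(max(simulate_ramp(m_flat, proto)$absorbance), 0, tolerance = 1e-30)
  # determinism under a seed
  t1 <- simulate_ramp(m, proto, noise_cv = 0.005, seed = 9)
  t2 <- simulate_ramp(m, proto, noise_cv = 0.005, seed = 9)
  expect_identical(t1, t2)
})

test_that("noiseless simulate -> fit round trip recovers the model within 1%", {
  dS <- solve_entropy_for_optimum(11, 100, 318.15)
  m <- inactivation_model(dH_rxn = 11, dH_inact = 100, dS_inact = dS,
                          amplitude = 5e-3 / velocity(
                            inactivation_model(dH_rxn = 11, dH_inact = 100,
                                               dS_inact = dS), 318.15))
  tr <- simulate_ramp(m, ramp_protocol(10, 10, 360, 1))
  fit <- fit_ramp(tr, n_starts = 8, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$theta[["dH_rxn"]], 11, tolerance = 0.01)
  expect_equal(fit$theta[["dH_inact"]], 100, tolerance = 0.01)
  expect_equal(fit$theta[["T_half"]], 100 / dS, tolerance = 0.01)
  expect_equal(fit$model$amplitude, m$amplitude, tolerance = 0.01)
  expect_equal(fit$T_opt_K, 318.15, tolerance = 0.05)
})

test_that("T_opt survives realistic multiplicative noise within 1 K", {
  sc <- gen_ramp_scenario("Chimera4", seed = 21, noise_cv = 0.005)
  fit <- fit_ramp(sc$trace, n_starts = 8, seed = 2)
  expect_true(fit$converged)
  expect_lt(abs(to_celsius(fit$T_opt_K) - sc$t_opt_C), 1)
  # T_opt lies inside the trace's temperature range
  expect_gte(fit$T_opt_K, to_kelvin(min(sc$trace$temperature_C)))
  expect_lte(fit$T_opt_K, to_kelvin(max(sc$trace$temperature_C)))
})

test_that("a trace without inactivation is fitted as effectively uninhibited", {
  m <- inactivation_model(dH_rxn = 11, dH_inact = 500, dS_inact = 0.2,
                          amplitude = 1e9)
  tr <- simulate_ramp(m, ramp_protocol(10, 10, 360, 1))
  fit <- fit_ramp(tr, n_starts = 8, seed = 3)
  # fitted velocity reproduces the generating (pure Eyring) velocity closely
  Ts <- to_kelvin(seq(12, 68, 2))
  expect_equal(velocity(fit$model, Ts) / velocity(m, Ts), rep(1, length(Ts)),
               tolerance = 0.01)
})

test_that("relative_rate_curve and optimum_shift are internally consistent", {
  scA <- gen_ramp_scenario("AHA", seed = 5)
  scC <- gen_ramp_scenario("Chimera4", seed = 6)
  fA <- fit_ramp(scA$trace, n_starts = 8, seed = 5)
  fC <- fit_ramp(scC$trace, n_starts = 8, seed = 6)
  # optima built 6 K apart via the entropy solver
  expect_equal(optimum_shift(fA, fC), 6, tolerance = 1)
  expect_equal(optimum_shift(fA, fC), -optimum_shift(fC, fA))
  expect_equal(optimum_shift(fA, fA), 0)
  grid <- seq(15, 65, by = 0.25)
  rc <- relative_rate_curve(fC, grid)
  expect_equal(max(rc$rel_rate), 1)
  expect_true(all(rc$rel_rate > 0))
  # curve max sits at the fitted optimum, and the pre-optimum limb rises
  expect_equal(grid[which.max(rc$rel_rate)], to_celsius(fC$T_opt_K),
               tolerance = 0.25)
  expect_true(all(diff(rc$rel_rate[grid < to_celsius(fC$T_opt_K)]) > 0))
  # a grid containing only the optimum returns exactly 1
  expect_equal(relative_rate_curve(fC, to_celsius(fC$T_opt_K))$rel_rate, 1)
  bad <- fA; bad$converged <- FALSE
  expect_error(optimum_shift(bad, fC), "converged")
  expect_error(relative_rate_curve(fC, numeric(0)), "empty")
})

test_that("trace validation rejects short or narrow inputs", {
  sc <- gen_ramp_scenario("AHA", seed = 1)
  expect_error(fit_ramp(sc$trace[1:10, ]), ">= 20 samples")
  expect_error(fit_ramp(sc$trace[1:60, ]), "span")
  expect_error(fit_ramp(sc$trace[, 1:2]), "missing column")
})
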