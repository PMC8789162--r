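test_that("rate laws reproduce limiting cases and direct arithmetic", {
  p <- ref_params()

  # zero O2: respiration off, fermentation maximal
  r0 <- respiration_rates(0, 0, p)
  expect_equal(r0$rO2, 0)
  expect_equal(r0$rCO2, p$Vmf_CO2)

  # half-saturation identity at pCO2 = 0
  rh <- respiration_rates(p$Km_O2, 0, p)
  expect_equal(rh$rO2, p$Vm_O2 / 2)

  # direct arithmetic evaluation at pO2 = 10, pCO2 = 5
  r <- respiration_rates(10, 5, p)
  rO2_hand <- 0.283 * 10 / ((4.43 + 10) * (1 + 5 / 182.5))
  rCO2_hand <- 0.637 * rO2_hand + 0.136 / (1 + 10 / 0.187)
  expect_equal(r$rO2, rO2_hand, tolerance = 1e-12)
  expect_equal(r$rCO2, rCO2_hand, tolerance = 1e-12)

  expect_error(respiration_rates(-1, 0, p), "nonnegative")
})

test_that("inverse-Kmn storage round-trips exactly and 0 means no inhibition", {
  p <- kinetic_params(Vm_O2 = 1, Km_O2 = 2, Kmn_CO2 = 182.5, rq = 0.5,
                      Vmf_CO2 = 0.1, Kmf_O2 = 0.2)
  expect_identical(p$Kmn_CO2, 182.5)
  p2 <- kinetic_params(Vm_O2 = 1, Km_O2 = 2, inv_Kmn_CO2 = 0, rq = 0.5,
                       Vmf_CO2 = 0.1, Kmf_O2 = 0.2)
  expect_identical(p2$Kmn_CO2, Inf)
  # no inhibition: rate independent of pCO2
  expect_equal(respiration_rates(5, 0, p2)$rO2,
               respiration_rates(5, 50, p2)$rO2)
  expect_error(kinetic_params(Vm_O2 = 1, Km_O2 = 2, Kmn_CO2 = 100,
                              rq = 1.2, Vmf_CO2 = 0.1, Kmf_O2 = 0.2),
               "rq")
})

test_that("Arrhenius scaling matches the scalar exponential and composes", {
  p <- ref_params()
  arr <- arrhenius_params(Ea_O2 = 70, Ea_CO2 = 60, Tr = 293.15)

  expect_equal(arrhenius_adjust(p, arr, 293.15), p)
  arr0 <- arrhenius_params(Ea_O2 = 0, Ea_CO2 = 0)
  expect_equal(arrhenius_adjust(p, arr0, 310), p)

  # independent scalar evaluation at 283.15 K
  fac <- exp(70e3 / 8.314462618 * (1 / 293.15 - 1 / 283.15))
  p2 <- arrhenius_adjust(p, arr, 283.15)
  expect_equal(p2$Vm_O2, p$Vm_O2 * fac, tolerance = 1e-12)
  expect_identical(p2$Km_O2, p$Km_O2)

  # forward then backward from the new reference restores the original
  arr_back <- arrhenius_params(Ea_O2 = 70, Ea_CO2 = 60, Tr = 283.15)
  p3 <- arrhenius_adjust(p2, arr_back, 293.15)
  expect_equal(p3$Vm_O2, p$Vm_O2, tolerance = 1e-14)
  expect_equal(p3$Vmf_CO2, p$Vmf_CO2, tolerance = 1e-14)
})

test_that("outflow balances net gas production", {
  jar <- jar_setup()
  expect_equal(outflow_rate(2e-3, 0.1, 0.1, jar), 2e-3)
  jar0 <- jar_setup(mp = 0)
  expect_equal(outflow_rate(2e-3, 0.3, 0.1, jar0), 2e-3)

  # independent evaluation at air with the reference parameters
  p <- ref_params()
  r <- respiration_rates(21, 0, p)
  qhand <- 2e-3 + (r$rCO2 - r$rO2) * 4 * 3.6e-3 * 8.314462618 * 293.15 /
    (1000 * 101.325)
  expect_equal(outflow_rate(2e-3, r$rO2, r$rCO2, jar), qhand,
               tolerance = 1e-12)
})

test_that("rhs conserves total gas for equimolar closed-jar exchange", {
  p <- kinetic_params(Vm_O2 = 0.283, Km_O2 = 4.43, Kmn_CO2 = 182.5,
                      rq = 1, Vmf_CO2 = 0, Kmf_O2 = 0.187)
  jar <- jar_setup(mode = "closed")
  d <- jar_rhs(0, c(15, 5), NULL, p, jar)
  expect_equal(sum(d), 0, tolerance = 1e-14)

  # pass-through steady state: inlet equals current state, no fruit
  jar0 <- jar_setup(mp = 0)
  prof <- control_profile(c(2e-3, 15, 5), te = 24)
  expect_equal(jar_rhs(1, c(15, 5), prof, ref_params(), jar0), c(0, 0),
               tolerance = 1e-14)

  # closed-jar initial slope from air, by hand
  r <- respiration_rates(21, 0, ref_params())
  kr <- 4 * 3.6e-3 * 8.314462618 * 293.15 / (1000 * 5e-3)
  expect_equal(jar_rhs(0, c(21, 0), NULL, ref_params(), jar),
               c(-kr * r$rO2, kr * r$rCO2), tolerance = 1e-12)
})

test_that("simulated trajectories satisfy the qualitative physics", {
  grid <- small_grid(96)
  p <- ref_params()

  # no fruit + inlet at the initial state: nothing happens
  jar0 <- jar_setup(mp = 0)
  prof <- control_profile(c(2e-3, 21, 0), te = 24)
  tr <- simulate_jar(jar0, prof, p, grid)
  expect_lt(max(abs(tr$states[, 1] - 21)), 1e-6)
  expect_lt(max(abs(tr$states[, 2])), 1e-6)

  # zero-rate parameters in a closed jar: constant trajectory
  pz <- kinetic_params(Vm_O2 = 0, Km_O2 = 4.43, Kmn_CO2 = 182.5,
                       rq = 0.637, Vmf_CO2 = 0, Kmf_O2 = 0.187)
  trz <- simulate_jar(jar_setup(mode = "closed"), prof, pz, grid)
  expect_lt(max(abs(sweep(trz$states, 2, c(21, 0)))), 1e-9)

  # closed jar, reference params: O2 falls, CO2 rises monotonically
  trc <- simulate_jar(jar_setup(mode = "closed"), prof, p, grid)
  expect_true(all(diff(trc$states[, 1]) < 0))
  expect_true(all(diff(trc$states[, 2]) > 0))
  expect_true(all(trc$states > -1e-5))
})

test_that("closed-jar equimolar exchange conserves pO2 + pCO2 over 24 h", {
  p <- kinetic_params(Vm_O2 = 0.283, Km_O2 = 4.43, Kmn_CO2 = 182.5,
                      rq = 1, Vmf_CO2 = 0, Kmf_O2 = 0.187)
  jar <- jar_setup(mode = "closed")
  prof <- control_profile(c(1e-4, 0, 0), te = 24)
  tr <- simulate_jar(jar, prof, p, small_grid(48))
  tot <- rowSums(tr$states)
  expect_lt(max(abs(tot - 21)), 10 * 1e-6 * 21 + 1e-5)
})

test_that("flow-through jar without fruit converges to inlet composition", {
  jar <- jar_setup(mp = 0)
  Qin <- 4e-3
  t10 <- 10 * jar$Vj / Qin
  prof <- control_profile(c(Qin, 5, 12), te = t10)
  tr <- simulate_jar(jar, prof, ref_params(),
                     experiment_grid(te = t10, N = 20))
  expect_equal(unname(tr$states[20, ]), c(5, 12), tolerance = 1e-3)
})

test_that("adaptive integrator matches a fixed-step RK4 oracle", {
  jar <- jar_setup()
  grid <- small_grid(48)
  prof <- bench_profile()
  p <- ref_params()
  tr <- simulate_jar(jar, prof, p, grid)        # default tolerances
  oracle <- rk4_oracle(jar, prof, p, grid, dt = 1 / 3600)
  rel <- abs(tr$states - oracle) / pmax(abs(oracle), 1)
  expect_lt(max(rel), 1e-3)
})

test_that("measurement covariance is diagonal, floored and linear in y", {
  n <- ref_noise()
  expect_equal(measurement_cov(c(0, 0), n), diag(c(0.01, 0.01)))
  n0 <- noise_params(0, 0, 0.01)
  expect_equal(measurement_cov(c(10, 5), n0), diag(c(0.01, 0.01)))
  v <- measurement_cov(c(21, 0), n)
  expect_equal(diag(v), c(0.063 * 21 + 0.01, 0.01), tolerance = 1e-12)
  expect_error(noise_params(floor = 0), "floor")
})

test_that("measurement sampling is reproducible and has the stated variance", {
  jar <- jar_setup(mode = "closed")
  prof <- control_profile(c(1e-4, 0, 0), te = 24)
  tr <- simulate_jar(jar, prof, ref_params(), experiment_grid(24, 4))
  n <- ref_noise()

  m1 <- sample_measurements(tr, n, seed = 42)
  m2 <- sample_measurements(tr, n, seed = 42)
  expect_identical(m1, m2)

  # degenerate noise: measurements collapse onto the trajectory
  tiny <- noise_params(0, 0, 1e-12)
  m0 <- sample_measurements(tr, tiny, seed = 1)
  expect_lt(max(abs(m0$yO2 - tr$states[, 1])), 1e-4)

  # Monte-Carlo variance at one time point vs the closed form
  one <- list(times = tr$times[2],
              states = tr$states[2, , drop = FALSE])
  class(one) <- "trajectory"
  set.seed(7)
  draws <- replicate(10000, {
    m <- sample_measurements(one, n)
    c(m$yO2, m$yCO2)
  })
  v_hat <- apply(draws, 1, var)
  v_true <- diag(measurement_cov(one$states[1, ], n))
  expect_lt(max(abs(v_hat / v_true - 1)), 0.05)
})

test_that("profiles index intervals right-continuously and check bounds", {
  u <- rbind(c(1e-3, 21, 0), c(2e-3, 0, 10))
  prof <- control_profile(u, te = 24)
  expect_equal(unname(control_at(prof, 0)[1, ]), u[1, ])
  expect_equal(unname(control_at(prof, 11.999)[1, ]), u[1, ])
  expect_equal(unname(control_at(prof, 12)[1, ]), u[2, ])
  expect_equal(unname(control_at(prof, 24)[1, ]), u[2, ])
  expect_error(control_profile(c(5e-3, 0, 0), te = 24), "bounds")

  # design CSV round trip
  f <- tempfile(fileext = ".csv")
  write_design(prof, f)
  prof2 <- read_design(f)
  expect_equal(prof2$u, prof$u, tolerance = 1e-9)
  expect_equal(prof2$te, 24)
})

test_that("measurement grid excludes t = 0 and includes t = te", {
  g <- experiment_grid(24, 1440)
  expect_equal(length(g$times), 1440)
  expect_gt(min(g$times), 0)
  expect_equal(max(g$times), 24)
  expect_equal(g$times[1], 24 / 1440)
})
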