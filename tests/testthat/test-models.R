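test_that("1:1 simulation handles zero concentration and the steady-state limit", {
  sched <- phase_schedule()
  s0 <- simulate_langmuir(cmpd11_params(), conc = 0, sched)
  expect_true(all(s0$response == 0))

  # at C = 1000 KD and long injection, the plateau approaches Rmax C/(C+KD)
  p <- kinetic_params("langmuir_1to1", 1e6, 1e-3, 100)
  long <- phase_schedule(t_assoc = 5e4, t_dissoc = 0, dt = 50)
  s <- simulate_langmuir(p, conc = 1e-6, long)
  expect_equal(max(s$response), 100 * 1e-6 / (1e-6 + 1e-9), tolerance = 1e-6)
})

test_that("closed-form 1:1 trace matches adaptive ODE integration", {
  sched <- phase_schedule()
  s <- simulate_langmuir(cmpd11_params(), conc = 1e-9, sched)
  o <- ode_oracle_1to1(5.9e6, 8.5e-5, 100, 1e-9, sched)
  expect_equal(s$time, o$time)
  expect_lt(max(abs(s$response - o$response)) / max(o$response), 1e-6)
  i120 <- which(abs(s$time - 120) < 1e-9)
  expect_equal(s$response[i120], o$response[i120],
               tolerance = 1e-6)
})

test_that("closed forms agree with the ODE oracle over a random parameter sweep", {
  set.seed(42)
  sched <- phase_schedule(60, 120, 1)
  for (i in 1:25) {
    ka <- 10^stats::runif(1, 4, 7)
    kd <- 10^stats::runif(1, -5, -2)
    C <- 10^stats::runif(1, -11, -6)
    Rmax <- stats::runif(1, 20, 200)
    s <- simulate_langmuir(kinetic_params("langmuir_1to1", ka, kd, Rmax), C, sched)
    o <- ode_oracle_1to1(ka, kd, Rmax, C, sched)
    denom <- max(max(abs(o$response)), 1e-9)
    expect_lt(max(abs(s$response - o$response)) / denom, 1e-6)
  }
})

test_that("1:1 association rises monotonically, dissociation falls, response bounded", {
  set.seed(7)
  sched <- phase_schedule(60, 120, 0.5)
  for (i in 1:10) {
    ka <- 10^stats::runif(1, 4, 7); kd <- 10^stats::runif(1, -5, -2)
    C <- 10^stats::runif(1, -10, -7); Rmax <- 100
    s <- simulate_langmuir(kinetic_params("langmuir_1to1", ka, kd, Rmax), C, sched)
    ia <- s$time <= 60
    expect_true(all(diff(s$response[ia]) >= 0))
    expect_true(all(diff(s$response[!ia]) <= 0))
    expect_true(all(s$response >= 0 & s$response <= Rmax + 1e-12))
  }
})

test_that("heterogeneous-ligand trace is the superposition of its two sites", {
  sched <- phase_schedule(120, 300, 1)
  p <- kinetic_params("heterogeneous_ligand", 1e6, 1e-3, 60, 1e5, 1e-2, 40)
  s <- simulate_heterogeneous_ligand(p, 1e-7, sched)
  s1 <- simulate_langmuir(kinetic_params("langmuir_1to1", 1e6, 1e-3, 60), 1e-7, sched)
  s2 <- simulate_langmuir(kinetic_params("langmuir_1to1", 1e5, 1e-2, 40), 1e-7, sched)
  expect_equal(s$response, s1$response + s2$response)
  expect_true(all(s$response <= 100 + 1e-12))

  # degenerate second site
  p0 <- kinetic_params("heterogeneous_ligand", 1e6, 1e-3, 60, 1e5, 1e-2, 0)
  expect_equal(simulate_heterogeneous_ligand(p0, 1e-7, sched)$response, s1$response)

  # identical sites collapse onto one 1:1 trace with summed capacity
  pid <- kinetic_params("heterogeneous_ligand", 1e6, 1e-3, 50, 1e6, 1e-3, 50)
  ref <- simulate_langmuir(kinetic_params("langmuir_1to1", 1e6, 1e-3, 100), 1e-7, sched)
  expect_equal(simulate_heterogeneous_ligand(pid, 1e-7, sched)$response,
               ref$response)
})

test_that("bivalent-analyte model reduces to 1:1 and conserves surface capacity", {
  sched <- phase_schedule(60, 120, 1)
  # second step switched off: doubled first-attachment rate and no R2
  p0 <- kinetic_params("bivalent_analyte", 5e4, 1e-3, 80, 1e-30, 1e-3)
  s0 <- simulate_bivalent_analyte(p0, 1e-7, sched)
  ref <- simulate_langmuir(kinetic_params("langmuir_1to1", 1e5, 1e-3, 80), 1e-7, sched)
  expect_equal(s0$response, ref$response, tolerance = 1e-7)
  expect_lt(max(abs(attr(s0, "components")[, "R2"])), 1e-8)

  # zero concentration from an all-zero state stays identically zero
  p <- kinetic_params("bivalent_analyte", 1e5, 1e-3, 80, 1e-3, 5e-3)
  expect_true(all(simulate_bivalent_analyte(p, 0, sched)$response == 0))

  # occupied + free capacity equals Rmax throughout
  set.seed(11)
  for (i in 1:5) {
    pp <- kinetic_params("bivalent_analyte", 10^stats::runif(1, 4, 6),
                         10^stats::runif(1, -4, -2), 80,
                         10^stats::runif(1, -5, -2), 10^stats::runif(1, -4, -2))
    s <- simulate_bivalent_analyte(pp, 10^stats::runif(1, -8, -6), sched)
    comp <- attr(s, "components")
    expect_true(all(comp >= -1e-8))
    free <- 80 - comp[, 1L] - comp[, 2L]
    expect_true(all(free >= -1e-8))
    expect_equal(comp[, 1L] + comp[, 2L] + free, rep(80, nrow(comp)),
                 tolerance = 1e-8)
  }
})

test_that("heterogeneous-analyte model competes two species for one capacity", {
  sched <- phase_schedule(60, 120, 1)
  p <- kinetic_params("heterogeneous_analyte", 2e5, 2e-3, 90, 5e4, 8e-3)
  # species B absent: reduces to 1:1 in species A
  sA <- simulate_heterogeneous_analyte(p, 1e-7, 0, sched)
  ref <- simulate_langmuir(kinetic_params("langmuir_1to1", 2e5, 2e-3, 90), 1e-7, sched)
  expect_equal(sA$response, ref$response, tolerance = 1e-7)

  # indistinguishable species at c/2 each behave like one species at c
  pid <- kinetic_params("heterogeneous_analyte", 2e5, 2e-3, 90, 2e5, 2e-3)
  s2 <- simulate_heterogeneous_analyte(pid, 5e-8, 5e-8, sched)
  ref2 <- simulate_langmuir(kinetic_params("langmuir_1to1", 2e5, 2e-3, 90), 1e-7, sched)
  expect_equal(s2$response, ref2$response, tolerance = 1e-6)

  # shared capacity is never exceeded, over a parameter sweep
  set.seed(3)
  for (i in 1:5) {
    pp <- kinetic_params("heterogeneous_analyte", 10^stats::runif(1, 4, 6),
                         10^stats::runif(1, -4, -2), 90,
                         10^stats::runif(1, 4, 6), 10^stats::runif(1, -4, -2))
    s <- simulate_heterogeneous_analyte(pp, 10^stats::runif(1, -7, -5),
                                        10^stats::runif(1, -7, -5), sched)
    expect_true(all(s$response <= 90 + 1e-8))
  }
})

test_that("equilibrium_response matches the isotherm and the t->inf closed form", {
  p <- cmpd11_params()
  KD <- 8.5e-5 / 5.9e6
  expect_equal(equilibrium_response(p, KD), 50, tolerance = 1e-12)
  expect_equal(equilibrium_response(p, 1.44e-11), 50, tolerance = 1e-2)
  expect_equal(equilibrium_response(p, 1), 100, tolerance = 1e-6)

  ph <- kinetic_params("heterogeneous_ligand", 1e6, 1e-3, 60, 1e5, 1e-2, 40)
  expect_equal(equilibrium_response(ph, 10), 100, tolerance = 1e-5)

  # equals the association closed form evaluated at t = 50/(ka C + kd)
  ka <- 1e6; kd <- 1e-3; C <- 1e-7
  t50 <- 50 / (ka * C + kd)
  sched <- phase_schedule(t_assoc = t50 * 1.2, t_dissoc = 0, dt = t50 / 100)
  s <- simulate_langmuir(kinetic_params("langmuir_1to1", ka, kd, 100), C, sched)
  i <- which.min(abs(s$time - t50))
  expect_equal(s$response[i],
               equilibrium_response(kinetic_params("langmuir_1to1", ka, kd, 100), C),
               tolerance = 1e-9)
})

test_that("kd_from_rates computes KD = kd/ka with propagated errors", {
  expect_equal(kd_from_rates(1, 1)$KD, 1)
  r <- kd_from_rates(5.9e6, 8.5e-5)
  expect_equal(r$KD, 8.5e-5 / 5.9e6)
  expect_equal(r$KD, 1.44e-11, tolerance = 5e-3)
  expect_equal(kd_from_rates(4.8e4, 4.0e-4)$KD, 8.3e-9, tolerance = 5e-3)

  # exact scale consistency on integer inputs
  expect_identical(kd_from_rates(3, 7)$KD * 5, kd_from_rates(3 * 5, 7 * 5)$KD * 5)
  expect_identical(kd_from_rates(6, 14)$KD, kd_from_rates(3, 7)$KD)

  rse <- kd_from_rates(5.9e6, 8.5e-5, se_ka = 1.3e6, se_kd = 2.5e-5)
  expect_equal(rse$se_KD,
               rse$KD * sqrt((1.3 / 5.9)^2 + (2.5 / 8.5)^2))
})

test_that("model constructors and simulators validate their inputs", {
  expect_error(kinetic_params("langmuir_1to1", -1, 1e-3, 100), "ka1")
  expect_error(kinetic_params("langmuir_1to1", 1e6, 0, 100), "kd1")
  expect_error(kinetic_params("heterogeneous_ligand", 1e6, 1e-3, 50), "ka2")
  expect_error(phase_schedule(dt = 200), "dt")
  expect_error(phase_schedule(t_assoc = 0), "t_assoc")
  expect_error(simulate_langmuir(cmpd11_params(), conc = -1), "conc")
  ph <- kinetic_params("heterogeneous_ligand", 1e6, 1e-3, 50, 1e5, 1e-2, 50)
  expect_error(simulate_langmuir(ph, 1e-9), "langmuir_1to1")
  expect_error(equilibrium_response(
    kinetic_params("bivalent_analyte", 1e5, 1e-3, 80, 1e-3, 5e-3), 1e-9),
    "supports")
  expect_error(kd_from_rates(-1, 1), "positive")
})
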