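test_that("noise-free global 1:1 fit recovers the generating rate constants", {
  set <- generate_sensorgram_series(cmpd11_params(), ladder_pM(),
                                    phase_schedule(), noise_spec(sd = 0))
  f <- global_fit(set$active, "langmuir_1to1", fit_options(starts = 4, seed = 1))
  expect_true(f$converged)
  expect_equal(unname(f$estimates["ka1"]), 5.9e6, tolerance = 1e-3)
  expect_equal(unname(f$estimates["kd1"]), 8.5e-5, tolerance = 1e-3)
  expect_equal(unname(f$estimates["Rmax1"]), 100, tolerance = 1e-3)
  # derived KD is exactly kd/ka of the same estimates
  expect_identical(f$KD, unname(f$estimates["kd1"] / f$estimates["ka1"]))
})

test_that("noise-free heterogeneous-ligand fit recovers both sites", {
  truth <- c(ka1 = 5.9e6, kd1 = 8.5e-5, Rmax1 = 60, ka2 = 5.9e5, kd2 = 8.5e-3,
             Rmax2 = 40)
  p <- kinetic_params("heterogeneous_ligand", truth["ka1"], truth["kd1"],
                      truth["Rmax1"], truth["ka2"], truth["kd2"], truth["Rmax2"])
  set <- generate_sensorgram_series(p, serial_dilution(1e-9, 2, 5),
                                    phase_schedule(), noise_spec(sd = 0))
  f <- global_fit(set$active, "heterogeneous_ligand", fit_options(starts = 8, seed = 1))
  # sites may come out in either order
  est <- f$estimates
  if (est["kd1"] > est["kd2"])
    est <- est[c("ka2", "kd2", "Rmax2", "ka1", "kd1", "Rmax1")]
  expect_equal(unname(est), unname(truth), tolerance = 1e-3)
})

test_that("noise-free ODE-model fits recover the generating parameters", {
  sched <- phase_schedule(90, 240, 3)
  concs <- serial_dilution(4e-7, 4, 3)
  truth_b <- c(ka1 = 1e5, kd1 = 5e-3, Rmax1 = 80, ka2 = 2e-3, kd2 = 1e-3)
  pb <- kinetic_params("bivalent_analyte", 1e5, 5e-3, 80, 2e-3, 1e-3)
  sb <- generate_sensorgram_series(pb, concs, sched, noise_spec(sd = 0))
  fb <- global_fit(sb$active, "bivalent_analyte", fit_options(starts = 8, seed = 2))
  expect_equal(unname(fb$estimates[names(truth_b)]), unname(truth_b),
               tolerance = 1e-2)

  truth_h <- c(ka1 = 2e5, kd1 = 2e-3, Rmax1 = 90, ka2 = 5e4, kd2 = 8e-3)
  ph <- kinetic_params("heterogeneous_analyte", 2e5, 2e-3, 90, 5e4, 8e-3)
  sh <- generate_sensorgram_series(ph, concs, sched, noise_spec(sd = 0),
                                   concs_b = concs / 2)
  fh <- global_fit(sh$active, "heterogeneous_analyte",
                   fit_options(starts = 6, seed = 2))
  expect_equal(unname(fh$estimates[names(truth_h)]), unname(truth_h),
               tolerance = 1e-2)
})

test_that("noisy 1:1 fits cover the truth within three standard errors", {
  for (s in c(101, 202, 303)) {
    set <- generate_sensorgram_series(cmpd11_params(), ladder_pM(),
                                      phase_schedule(), noise_spec(sd = 0.5, seed = s))
    f <- global_fit(reference_set(set), "langmuir_1to1",
                    fit_options(starts = 4, seed = 1))
    expect_lt(abs(f$estimates["ka1"] - 5.9e6), 3 * f$se["ka1"])
    expect_lt(abs(f$estimates["kd1"] - 8.5e-5), 3 * f$se["kd1"])
  }
})

test_that("a degenerate second site leaves the 1:1 and heterogeneous fits equivalent", {
  p <- kinetic_params("heterogeneous_ligand", 5.9e6, 8.5e-5, 100, 5.9e5, 8.5e-3, 0)
  set <- generate_sensorgram_series(p, ladder_pM(), phase_schedule(),
                                    noise_spec(sd = 0))
  f1 <- global_fit(set$active, "langmuir_1to1", fit_options(starts = 4, seed = 1))
  # with Rmax2 = 0 the second site is unidentifiable; the optimizer may stop
  # on the iteration cap, in which case the best candidate is still reported
  fh <- tryCatch(
    global_fit(set$active, "heterogeneous_ligand", fit_options(starts = 4, seed = 1)),
    sprkin_convergence_error = function(e) e$fit)
  # both reach an essentially perfect fit of the same data
  expect_lt(abs(fh$rss - f1$rss), 1e-9 * (1 + f1$rss))
  # the richer model can never do worse than its nested special case
  expect_lte(fh$rss, f1$rss + 1e-9)
})

test_that("fit results are invariant to a concentration unit change", {
  set <- generate_sensorgram_series(cmpd11_params(), ladder_pM(),
                                    phase_schedule(), noise_spec(sd = 0.2, seed = 9))
  f_M <- global_fit(set$active, "langmuir_1to1", fit_options(starts = 4, seed = 1))
  # express concentrations in nM: ka carries the inverse unit change
  curves_nM <- lapply(set$active$curves, function(cv)
    sensorgram(cv$time, cv$response, cv$conc * 1e9, cv$schedule, cv$label))
  ser_nM <- sensorgram_series(curves_nM, "nM units")
  f_nM <- global_fit(ser_nM, "langmuir_1to1",
                     fit_options(starts = 4, seed = 1,
                                 ka_bounds = c(1e2, 1e9) * 1e-9))
  expect_equal(unname(f_nM$estimates["ka1"]) * 1e9,
               unname(f_M$estimates["ka1"]), tolerance = 1e-4)
  expect_equal(unname(f_nM$estimates["kd1"]), unname(f_M$estimates["kd1"]),
               tolerance = 1e-4)
  expect_equal(f_nM$KD * 1e-9, f_M$KD, tolerance = 1e-4)
})

test_that("model comparison selects by AICc and degenerates gracefully", {
  set <- generate_sensorgram_series(cmpd11_params(), ladder_pM(),
                                    phase_schedule(), noise_spec(sd = 0.5, seed = 17))
  ser <- reference_set(set)
  rep1 <- compare_models(ser, "langmuir_1to1", fit_options(starts = 2, seed = 1))
  expect_identical(rep1$selected, "langmuir_1to1")

  rep2 <- compare_models(ser, c("langmuir_1to1", "heterogeneous_ligand"),
                         fit_options(starts = 4, seed = 1))
  expect_identical(rep2$selected, "langmuir_1to1")
  # the winner is within the 2-unit tie band of the minimal AICc
  expect_lte(rep2$table$aicc[rep2$table$kind == rep2$selected] -
               min(rep2$table$aicc), 2)
  expect_true(all(rep2$table$rss >= 0))
})

test_that("fold_difference reproduces the published affinity contrasts", {
  kd_asf <- kd_from_rates(4.8e4, 4.0e-4)$KD
  kd_11 <- kd_from_rates(5.9e6, 8.5e-5)$KD
  fold <- fold_difference(kd_asf, kd_11)
  expect_equal(fold, 578, tolerance = 1e-2)
  expect_lte(fold, 600)
  expect_equal(fold_difference(4.2e-4, 8.5e-5), 4.94, tolerance = 1e-2)
  expect_identical(fold_difference(3e-9, 3e-9), 1)
  expect_error(fold_difference(-1, 1), "positive")
})

test_that("global_fit validates its inputs", {
  sched <- phase_schedule(60, 120, 1)
  one <- sensorgram_series(list(simulate_langmuir(cmpd11_params(), 1e-10, sched)))
  expect_error(global_fit(one, "langmuir_1to1"), "2 distinct")
  coarse <- phase_schedule(60, 120, 10)
  few <- sensorgram_series(list(simulate_langmuir(cmpd11_params(), 1e-10, coarse),
                                simulate_langmuir(cmpd11_params(), 2e-10, coarse)))
  expect_error(global_fit(few, "langmuir_1to1"), "10 samples")
})
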