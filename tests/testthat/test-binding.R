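test_that("dissociation generator obeys the mono-exponential decay", {
  tr <- simulate_dissociation_trace(koff = 0.014, b0 = 3000, nonspecific = 300,
                                    times = c(0, log(2) / 0.014), noise_cv = 0)
  expect_equal(tr$total[1], 3300)
  expect_equal(tr$total[2] - tr$nonspecific[2], 1500, tolerance = 1e-9)

  t1 <- simulate_dissociation_trace(noise_cv = 0.05, seed = 31)
  t2 <- simulate_dissociation_trace(noise_cv = 0.05, seed = 31)
  expect_identical(t1$total, t2$total)
  expect_error(simulate_dissociation_trace(koff = -1), "koff")
})

test_that("noiseless dissociation fit recovers koff and the analytic half-life", {
  fit <- fit_dissociation(simulate_dissociation_trace(koff = 0.014))
  expect_equal(fit$koff, 0.014, tolerance = 1e-9)
  expect_equal(fit$half_life, log(2) / 0.014, tolerance = 1e-9)
  expect_equal(fit$half_life, 49.51, tolerance = 1e-4)
  expect_equal(fit$koff * fit$half_life, log(2), tolerance = 1e-12)
})

test_that("flat and empty dissociation traces are flagged or rejected", {
  flat <- fit_dissociation(simulate_dissociation_trace(koff = 0))
  expect_false(isTRUE(flat$dissociating))
  tr <- simulate_dissociation_trace()
  tr$total <- tr$nonspecific
  expect_error(fit_dissociation(tr), "all zero")
})

test_that("noisy dissociation traces give < 10% median error over 20 seeds", {
  errs <- vapply(1:20, function(s) {
    tr <- simulate_dissociation_trace(koff = 0.014, noise_cv = 0.05,
                                      seed = 700 + s)
    abs(fit_dissociation(tr)$koff - 0.014) / 0.014
  }, numeric(1L))
  expect_lt(median(errs), 0.10)
})

test_that("Cheng-Prusoff conversion and its limits", {
  expect_equal(cheng_prusoff(2e-9, 1e-9, 1e-9), 1e-9)
  # [L] -> 0 limit: Ki -> IC50
  expect_equal(cheng_prusoff(5e-9, 1e-15, 1e-9), 5e-9, tolerance = 1e-5)
  # Ki strictly decreases as [L]/Kd increases at fixed IC50
  kis <- cheng_prusoff(1e-8, c(0.1, 1, 10) * 1e-9, 1e-9)
  expect_true(all(diff(kis) < 0))
})

test_that("competition curve generator satisfies its defining identities", {
  cur <- simulate_competition_curve(pki = 8.74, radioligand_conc = 1e-9,
                                    radioligand_kd = 0.5e-9, noise_cv = 0)
  expect_equal(cur$params$ic50, 10^(-8.74) * 3, tolerance = 1e-12)

  ic50 <- cur$params$ic50
  at_ic50 <- simulate_competition_curve(pki = 8.74, radioligand_kd = 0.5e-9,
                                        inhibitor_concs = c(ic50, 1e-15, rep(1e-6, 4)),
                                        noise_cv = 0)
  expect_equal(at_ic50$bound[1], 200 + (2000 - 200) / 2, tolerance = 1e-9)
  expect_equal(at_ic50$bound[2], 2000, tolerance = 1e-3)
})

test_that("noiseless competition round trip recovers pKi", {
  cur <- simulate_competition_curve(pki = 8.74)
  fit <- fit_competition(cur, radioligand_conc = 1e-9, radioligand_kd = 0.3e-9)
  expect_equal(fit$pki, 8.74, tolerance = 1e-3)
  expect_true(fit$in_range)
})

test_that("a curve without an inflection in range is flagged", {
  cur <- simulate_competition_curve(pki = 8.74,
                                    inhibitor_concs = 10^seq(-16, -14.5,
                                                             length.out = 8))
  fit <- fit_competition(cur, radioligand_conc = 1e-9, radioligand_kd = 0.3e-9)
  expect_false(isTRUE(fit$in_range))
})

test_that("noisy competition curves give < 10% median pKi error over 20 seeds", {
  errs <- vapply(1:20, function(s) {
    cur <- simulate_competition_curve(pki = 8.74, noise_cv = 0.05,
                                      seed = 800 + s)
    f <- fit_competition(cur, radioligand_conc = 1e-9,
                         radioligand_kd = 0.3e-9)
    abs(f$pki - 8.74) / 8.74
  }, numeric(1L))
  expect_lt(median(errs), 0.10)
})

test_that("saturation binding round trip is exact and hits the half-max point", {
  cur <- simulate_saturation_curve(kd = 1.5, bmax = 1000)
  fit <- fit_saturation(cur)
  expect_equal(fit$kd, 1.5, tolerance = 1e-9)
  expect_equal(fit$bmax, 1000, tolerance = 1e-9)

  at_kd <- simulate_saturation_curve(kd = 1.5, bmax = 1000,
                                     concs = c(1.5, 0, 10^seq(-1, 1, length.out = 4)))
  expect_equal(at_kd$total[1] - at_kd$nonspecific[1], 500)
  expect_equal(at_kd$total[2], 0)
})

test_that("receptor copies convert to per-area density", {
  expect_equal(receptors_per_area(424035, 5235), 81.0, tolerance = 1e-4)
  expect_equal(receptors_per_area(5235, 5235), 1.0)
  expect_equal(receptors_per_area(0, 5235), 0)
  expect_error(receptors_per_area(100, 0))
})
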