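test_that("monomeric QB calibration averages converged fits", {
  fits <- calib_fits("2", 10L)
  cal <- calibrate_monomeric_qb(fits, laser_power = 2)
  expect_equal(cal$qb, mean(vapply(fits, function(f) f$qb, numeric(1L))))
  expect_equal(cal$n, 10L)

  # a single fit is its own mean
  one <- calibrate_monomeric_qb(fits[[1]], laser_power = 2)
  expect_equal(one$qb, fits[[1]]$qb)

  # unconverged fits are rejected
  bad <- fits[[1]]
  bad$converged <- FALSE
  expect_error(calibrate_monomeric_qb(c(fits[1:3], list(bad)), 2), "converged")
  expect_error(calibrate_monomeric_qb(list(), 2), "no fits")
})

test_that("QB-to-MEU conversion anchors 1.00 MEU per laser power", {
  cal <- meu_calibration(c("2" = 11.01, "6" = 24.31),
                         meu_mean = 0.994, meu_sd = 0.206)
  expect_equal(qb_to_meu(11.01, cal, 2), 1.0)
  expect_equal(qb_to_meu(24.31, cal, 6), 1.0)
  expect_equal(qb_to_meu(22.02, cal, 2), 2.0)
  expect_error(qb_to_meu(10, cal, 4), "not registered")
})

test_that("monomer threshold is mean + 2 SD", {
  expect_equal(monomer_threshold(0.994, 0.206), 1.406)
  expect_equal(monomer_threshold(1.0, 0), 1.0)
  expect_equal(monomer_threshold(0, 0.5), 1.0)
  expect_error(monomer_threshold(1, -0.1))
})

test_that("classification scores ties as monomeric", {
  expect_equal(as.character(classify_roi(1.406, 1.406)), "monomeric")
  expect_equal(as.character(classify_roi(1.407, 1.406)), "dimeric/oligomeric")
  expect_equal(as.character(classify_roi(0.8, 1.406)), "monomeric")
})

test_that("dimer/oligomer fraction is a bounded, permutation-invariant percentage", {
  labs <- classify_roi(c(rep(2, 33), rep(1, 11)), 1.406)
  expect_equal(dimer_oligomer_fraction(labs), 75.0)
  expect_equal(dimer_oligomer_fraction(classify_roi(rep(1, 5), 1.406)), 0)
  expect_equal(dimer_oligomer_fraction(classify_roi(c(1, 2), 1.406)), 50)
  set.seed(2)
  perm <- sample(labs)
  expect_equal(dimer_oligomer_fraction(perm), dimer_oligomer_fraction(labs))
  expect_error(dimer_oligomer_fraction(character(0)))
})

test_that("surface density divides corrected intensity by QB and beam area", {
  expect_equal(surface_density(1431.3, 0, 11.01), 130.0)
  expect_equal(surface_density(50, 50, 11.01), 0)
  psf <- gaussian_psf()
  # synthetic image at known truth
  cfg <- simulation_config(density = 130, qb = 11.01, psf = psf,
                           image_shape = c(64L, 64L), seed = 42)
  img <- simulate_membrane_image(cfg)
  dens <- surface_density(mean(img$data), offset = 10, monomeric_qb = 11.01,
                          psf = psf)
  expect_lt(abs(dens - 130) / 130, 0.10)
})

test_that("RoI selection bias fractions behave as ratios of means", {
  expect_equal(roi_selection_bias(100, 100)$fractions, 1.0)
  expect_equal(roi_selection_bias(80, 100)$fractions, 0.8)
  u <- matrix(5, 20, 20)
  roi_means <- c(mean(u[1:10, 1:10]), mean(u[5:15, 2:12]))
  rb <- roi_selection_bias(mean(u), roi_means)
  expect_equal(rb$fractions, c(1, 1))
  expect_error(roi_selection_bias(10, c(1, 0)), "> 0")
})

test_that("MEU distribution summary recovers Gaussian parameters and verdicts", {
  set.seed(352)
  x <- rnorm(352, 0.994, 0.206)
  d <- fit_meu_distribution(x)
  expect_lt(abs(d$mean - 0.994), 3 * 0.206 / sqrt(352))
  expect_lt(abs(d$sd - 0.206), 3 * 0.206 / sqrt(2 * 351))
  expect_true(d$normality$normal)
  expect_equal(sum(d$table$frequency), 352)
  expect_equal(d$table$meu[2] - d$table$meu[1], 0.1)

  # constant vector: SD 0, test not applicable
  dc <- fit_meu_distribution(rep(1, 20))
  expect_equal(dc$sd, 0)
  expect_false(dc$normality$applicable)

  # 50/50 mixture of well-separated Gaussians is rejected as normal
  set.seed(99)
  mix <- c(rnorm(100, 1, 0.1), rnorm(100, 2, 0.1))
  expect_false(fit_meu_distribution(mix)$normality$normal)

  expect_error(fit_meu_distribution(1:5), "at least 8")
})

test_that("D'Agostino-Pearson omnibus statistic matches the reference implementation", {
  # expected values frozen from scipy.stats.normaltest on identical input
  set.seed(11)
  x1 <- round(rnorm(60, 1, 0.2), 6)
  x2 <- round(c(rnorm(30, 1, 0.1), rnorm(30, 2, 0.1)), 6)
  r1 <- dagostino_pearson(x1)
  expect_equal(r1$statistic, 0.3427272829, tolerance = 1e-8)
  expect_equal(r1$p_value, 0.8425151443, tolerance = 1e-8)
  r2 <- dagostino_pearson(x2)
  expect_equal(r2$statistic, 1159.3775849359, tolerance = 1e-8)
})

test_that("two-sided 2-sigma Gaussian mass is the conventional 95.44%", {
  expect_equal(floor(gaussian_central_mass(2) * 100) / 100, 95.44)
})

test_that("concentration-response tables aggregate MEU and dimer fraction", {
  d <- data.frame(concentration = rep(c(1e-9, 1e-8), each = 4),
                  meu = c(1.8, 2.0, 1.9, 2.1, 1.0, 1.1, 0.9, 1.2))
  tab <- concentration_response(d, threshold = 1.406)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$dimer_fraction, c(100, 0))
  expect_true(!is.unsorted(tab$concentration))

  # identical data at two concentrations gives identical summaries
  d2 <- data.frame(concentration = rep(c(1, 2), each = 3),
                   meu = rep(c(1.0, 1.5, 2.0), 2))
  tab2 <- concentration_response(d2, threshold = 1.406)
  expect_equal(tab2$mean_meu[1], tab2$mean_meu[2])
  expect_equal(tab2$dimer_fraction[1], tab2$dimer_fraction[2])

  expect_error(concentration_response(d[d$concentration == 1e-9, ],
                                      threshold = 1.406), "2 concentrations")
})

test_that("a generated dimer-fraction series is recovered within binomial error", {
  set.seed(7)
  fracs <- c(0.8, 0.5, 0.2)
  concs <- c(1e-9, 1e-8, 1e-7)
  n <- 60
  rows <- do.call(rbind, lapply(seq_along(concs), function(i) {
    dimer <- runif(n) < fracs[i]
    data.frame(concentration = concs[i],
               meu = ifelse(dimer, rnorm(n, 2, 0.1), rnorm(n, 1, 0.1)))
  }))
  tab <- concentration_response(rows, threshold = 1.406)
  for (i in seq_along(concs)) {
    se <- sqrt(fracs[i] * (1 - fracs[i]) / n) * 100
    expect_lt(abs(tab$dimer_fraction[i] - 100 * fracs[i]), 3 * se + 1e-9)
  }
})
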