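test_that("RoI histogram extraction conserves counts and bins correctly", {
  m <- matrix(7, 5, 5)
  h <- extract_roi_histogram(m)
  expect_equal(sum(h$counts), 25)
  expect_equal(sum(h$counts > 0), 1L)
  expect_true(h$bin_edges[1] <= 7 && 7 < h$bin_edges[2])

  m2 <- matrix(c(1, 1, 2, 3), 2, 2)
  h2 <- extract_roi_histogram(m2, bin_width = 1)
  expect_equal(h2$counts, c(2L, 1L, 1L))

  # conservation on arbitrary input, with an RoI
  set.seed(8)
  m3 <- matrix(rnorm(400, 50, 10), 20, 20)
  h3 <- extract_roi_histogram(m3, roi = c(2, 3, 10, 12))
  expect_equal(sum(h3$counts), 120)

  expect_error(extract_roi_histogram(m3, roi = c(15, 15, 10, 10)), "outside")
  expect_error(extract_roi_histogram(m3, roi = c(1, 1, 0, 5)), "empty")
})

test_that("moment initializer inverts exact moments to machine precision", {
  psf <- gaussian_psf()
  rho <- 100; eps <- 11.01; sd0 <- 2; off <- 10
  mu <- off + rho * eps * psf$a1
  v <- sd0^2 + rho * eps^2 * psf$a2
  init <- spida_moments_init(mu, var = v, psf = psf, noise_sd = sd0, offset = off)
  expect_equal(init$epsilon, eps, tolerance = 1e-12)
  expect_equal(init$rho, rho, tolerance = 1e-12)
  expect_false(init$degenerate)
})

test_that("moment initializer flags images with no emitter signal", {
  psf <- gaussian_psf()
  flat <- matrix(10, 40, 40)
  h <- extract_roi_histogram(flat)
  init <- spida_moments_init(h, psf = psf, noise_sd = 2, offset = 10)
  expect_true(init$degenerate)
})

test_that("moment initializer recovers truth within 15% on noisy 64x64 RoIs", {
  psf <- gaussian_psf()
  res <- t(vapply(1:50, function(s) {
    cfg <- simulation_config(density = 100, qb = 11.01, psf = psf,
                             image_shape = c(64L, 64L), seed = 3000 + s)
    img <- simulate_membrane_image(cfg)
    h <- extract_roi_histogram(img)
    init <- spida_moments_init(h, psf = psf, noise_sd = 2, offset = 10)
    c(init$epsilon, init$rho)
  }, numeric(2L)))
  expect_lt(abs(median(res[, 1]) - 11.01) / 11.01, 0.15)
  expect_lt(abs(median(res[, 2]) - 100) / 100, 0.15)
})

test_that("SpIDA fit recovers monomer brightness and density within 10%", {
  psf <- gaussian_psf()
  cf <- t(vapply(calib_fits("2", 20L), function(f) coef(f), numeric(2L)))
  expect_lt(abs(median(cf[, "qb"]) - 11.01) / 11.01, 0.10)
  expect_lt(abs(median(cf[, "density"]) - 130) / 130, 0.10)
  expect_true(all(vapply(calib_fits("2", 20L), function(f) f$converged,
                         logical(1L))))
})

test_that("a pure-dimer field doubles the apparent quantal brightness", {
  fits <- mixture_fits(1, n_roi = 8L)
  qb <- vapply(fits, function(f) f$qb, numeric(1L))
  expect_lt(abs(mean(qb) - 22.02) / 22.02, 0.10)
})

test_that("apparent brightness rises monotonically with dimer fraction", {
  # total monomer-equivalents held fixed across fractions
  fracs <- c(0, 0.5, 1)
  mean_qb <- vapply(fracs, function(f) {
    mean(vapply(mixture_fits(f, n_roi = 8L), function(x) x$qb, numeric(1L)))
  }, numeric(1L))
  expect_true(all(diff(mean_qb) > 0))
  expect_lt(abs(mean_qb[1] - 11.01) / 11.01, 0.10)
  expect_lt(abs(mean_qb[3] - 22.02) / 22.02, 0.10)
})

test_that("a noise-only image yields a degenerate or near-zero-density fit", {
  set.seed(12)
  img <- confocal_image(matrix(rnorm(64 * 64, 10, 2), 64, 64),
                        pixel_size = 0.05, offset = 10, noise_sd = 2)
  fit <- spida(img)
  expect_true(fit$degenerate || fit$density < 1)
})

test_that("the fit is invariant to a correctly supplied offset shift", {
  psf <- gaussian_psf()
  cfg <- simulation_config(density = 60, qb = 11.01, psf = psf, offset = 10,
                           image_shape = c(64L, 64L), seed = 123)
  img <- simulate_membrane_image(cfg)
  f1 <- spida(img, psf = psf)
  shifted <- confocal_image(img$data + 500, pixel_size = img$pixel_size,
                            offset = img$offset + 500, noise_sd = img$noise_sd)
  f2 <- spida(shifted, psf = psf)
  expect_equal(f1$qb, f2$qb, tolerance = 1e-4)
  expect_equal(f1$density, f2$density, tolerance = 1e-4)
})

test_that("fit methods expose coefficients, pmf, residuals and simulation", {
  f <- calib_fits("2", 1L)[[1]]
  expect_named(coef(f), c("qb", "density"))
  pr <- predict(f)
  expect_equal(sum(pr$pmf), 1, tolerance = 1e-6)
  expect_equal(length(residuals(f)), length(fitted(f)))
  sim <- simulate(f, nsim = 1, seed = 1, image_shape = c(32L, 32L))
  expect_s3_class(sim[[1]], "confocal_image")
  expect_output(print(summary(f)), "quantal brightness")
})

test_that("fits on small regions are refused", {
  img <- matrix(rnorm(100, 10, 2), 10, 10)
  expect_error(spida(img, psf = gaussian_psf(), noise_sd = 2, offset = 10),
               "32 x 32")
})
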