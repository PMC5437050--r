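#' Extract the pixel-intensity histogram of a region of interest
#'
#' SpIDA operates on the histogram of pixel intensities within a rectangular
#' RoI. Bins are uniform, of width \code{bin_width}, aligned to multiples of
#' the bin width, and cover the observed range; the counts always sum to the
#' number of RoI pixels.
#'
#' @param image a [confocal_image()] or a plain numeric matrix.
#' @param roi NULL for the whole image, or c(x0, y0, width, height) in pixels,
#'   0-based, half-open (x = column, y = row).
#' @param bin_width histogram bin width in intensity units (default 1).
#' @return an \code{"intensity_histogram"} with \code{bin_edges},
#'   \code{counts}, \code{mids}, \code{n_pixels}, \code{bin_width}.
#' @export
extract_roi_histogram <- function(image, roi = NULL, bin_width = 1) {
  m <- if (inherits(image, "confocal_image")) image$data else image
  stopifnot(is.matrix(m), bin_width > 0)
  if (!is.null(roi)) {
    roi <- as.numeric(roi)
    if (length(roi) != 4L) stop("roi must be c(x0, y0, width, height)")
    x0 <- roi[1L]; y0 <- roi[2L]; w <- roi[3L]; h <- roi[4L]
    if (w < 1 || h < 1) stop("empty RoI")
    if (x0 < 0 || y0 < 0 || x0 + w > ncol(m) || y0 + h > nrow(m))
      stop("RoI extends outside the image")
    m <- m[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), drop = FALSE]
  }
  v <- as.vector(m)
  if (length(v) == 0L) stop("empty RoI")
  lo <- floor(min(v) / bin_width) * bin_width
  nb <- floor((max(v) - lo) / bin_width) + 1L
  idx <- pmin(floor((v - lo) / bin_width) + 1L, nb)
  counts <- tabulate(idx, nbins = nb)
  edges <- lo + (0:nb) * bin_width
  structure(
    list(bin_edges = edges, counts = counts,
         mids = edges[-length(edges)] + bin_width / 2,
         n_pixels = length(v), bin_width = bin_width),
    class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("Intensity histogram: %d pixels, %d bins of width %g over [%g, %g]\n",
              x$n_pixels, length(x$counts), x$bin_width,
              x$bin_edges[1], x$bin_edges[length(x$bin_edges)]))
  invisible(x)
}

# weighted sample moments of a histogram (bin midpoints)
hist_moments <- function(h) {
  n <- h$n_pixels
  mu <- sum(h$counts * h$mids) / n
  v <- sum(h$counts * (h$mids - mu)^2) / (n - 1)
  list(mean = mu, var = v)
}

#' Analytic pixel-intensity distribution of the SpIDA model
#'
#' Computes the probability mass over an intensity grid for the
#' compound-Poisson (super-Poissonian) model of an analog confocal detector:
#' emitters of brightness \code{epsilon} (per monomer) arranged as a spatial
#' Poisson process of density \code{rho}, blurred by the PSF and read out with
#' Gaussian noise on a baseline offset. The log characteristic function is
#' \deqn{\log\varphi(\omega) = \rho \sum_m p_m \sum_k a_k
#'   (e^{i\omega m\varepsilon w_k} - 1) - \sigma_0^2\omega^2/2 +
#'   i\omega\,\mathrm{offset}}
#' where \code{{w_k, a_k}} are the PSF profile values and area elements of the
#' radial discretization stored in the [gaussian_psf()]; the pmf is obtained
#' by inverse FFT on the supplied grid.
#'
#' The analytic first two moments are \code{mean = offset + rho*ebar*a1} and
#' \code{var = sd0^2 + rho*<m^2>*epsilon^2*a2} (with \code{ebar} the mean
#' per-cluster brightness); the returned pmf matches them to high accuracy
#' when the grid is wide enough.
#'
#' @param rho cluster density per um^2 (>= 0).
#' @param epsilon quantal brightness per monomer (intensity units, >= 0).
#' @param psf a [gaussian_psf()].
#' @param noise_sd Gaussian read-noise SD.
#' @param offset detector baseline.
#' @param grid numeric vector of equally spaced intensity grid points (bin
#'   centres) at which to evaluate the pmf; its length should be a power of
#'   two for FFT efficiency.
#' @param multiplicity_probs named probability vector over oligomer sizes
#'   (default pure monomer); a cluster of size m has brightness m*epsilon.
#' @param check if TRUE (default), reject grids that truncate more than 1e-6
#'   of the probability mass.
#' @return numeric vector of probabilities, one per grid point (grid spacing
#'   implicitly the bin width).
#' @export
spida_pmf <- function(rho, epsilon, psf, noise_sd, offset, grid,
                      multiplicity_probs = c("1" = 1), check = TRUE) {
  stopifnot(rho >= 0, epsilon >= 0, noise_sd >= 0, inherits(psf, "gaussian_psf"))
  n <- length(grid)
  if (n < 8L) stop("intensity grid too short")
  delta <- grid[2L] - grid[1L]
  p <- as.numeric(multiplicity_probs)
  mult <- as.numeric(names(multiplicity_probs))
  # signed FFT frequencies
  k <- c(0:(ceiling(n / 2) - 1L), -(floor(n / 2)):-1L)
  omega <- 2 * pi * k / (n * delta)
  lcf <- complex(real = rep(0, n))
  if (rho > 0 && epsilon > 0) {
    for (j in seq_along(mult)) {
      # sum over annuli: a_k * (exp(i w eps m psf_k) - 1), vectorized over omega
      ph <- outer(omega, mult[j] * epsilon * psf$w)   # n x n_annuli
      lcf <- lcf + (rho * p[j]) *
        as.vector((cos(ph) - 1) %*% psf$area + 1i * (sin(ph) %*% psf$area))
    }
  }
  lcf <- lcf - 0.5 * noise_sd^2 * omega^2 + 1i * omega * offset
  phi <- exp(lcf)
  pmf <- Re(stats::fft(phi * exp(-1i * omega * grid[1L]))) / n
  if (check) {
    tot <- sum(pmf)
    edge <- sum(pmf[c(1:3, (n - 2):n)])
    if (abs(tot - 1) > 1e-6 || edge > 1e-6)
      stop("intensity grid too narrow for the model mass (truncation > 1e-6)")
  }
  pmf
}

#' Build a power-of-two intensity grid covering the model mass
#'
#' @param rho,epsilon,psf,noise_sd,offset model parameters as in [spida_pmf()]
#' @param multiplicity_probs oligomer size distribution
#' @param span half-width in SDs of the model distribution (default 8)
#' @param delta grid spacing (default 1 intensity unit)
#' @param include optional numeric range the grid must also cover
#' @return numeric vector of grid points
#' @export
spida_grid <- function(rho, epsilon, psf, noise_sd, offset,
                       multiplicity_probs = c("1" = 1), span = 8, delta = 1,
                       include = NULL) {
  p <- as.numeric(multiplicity_probs)
  m <- as.numeric(names(multiplicity_probs))
  mu <- offset + rho * sum(p * m) * epsilon * psf$a1
  sdv <- sqrt(noise_sd^2 + rho * sum(p * m^2) * epsilon^2 * psf$a2)
  lo <- mu - span * sdv - 4 * delta
  hi <- mu + span * sdv + 4 * delta
  if (!is.null(include)) {
    lo <- min(lo, min(include) - 2 * delta)
    hi <- max(hi, max(include) + 2 * delta)
    # snap to the lattice of the included points (histogram bin centres) so
    # model grid points coincide exactly with observed bins
    ref <- min(include)
    lo <- ref - delta * ceiling((ref - lo) / delta)
  }
  n <- 2^ceiling(log2((hi - lo) / delta + 1))
  n <- max(n, 64)
  seq(lo, by = delta, length.out = n)
}

#' Monte-Carlo oracle for the pixel-intensity distribution
#'
#' Brute-force check of the analytic model: simulates \code{n_pixels}
#' independent pixels by drawing, for each, a Poisson number of emitter
#' clusters uniformly in the PSF truncation disc around the pixel, summing
#' their PSF-weighted brightness, and adding offset and read noise. Returns
#' the intensity histogram of the simulated values.
#'
#' @inheritParams spida_pmf
#' @param n_pixels number of independent pixels to simulate (>= 1e4).
#' @param seed RNG seed.
#' @param bin_width histogram bin width.
#' @return an \code{"intensity_histogram"}.
#' @export
spida_mc_histogram <- function(rho, epsilon, psf, noise_sd, offset, n_pixels,
                               multiplicity_probs = c("1" = 1), seed = NULL,
                               bin_width = 1) {
  stopifnot(n_pixels >= 1e4)
  if (!is.null(seed)) set.seed(seed)
  Tr <- psf$trunc_radius
  lambda <- rho * pi * Tr^2
  p <- as.numeric(multiplicity_probs)
  msz <- as.numeric(names(multiplicity_probs))
  vals <- numeric(n_pixels)
  chunk <- max(1L, floor(2e7 / max(lambda, 1)))
  i <- 1L
  while (i <= n_pixels) {
    j <- min(n_pixels, i + chunk - 1L)
    nn <- j - i + 1L
    counts <- stats::rpois(nn, lambda)
    tot <- sum(counts)
    sig <- numeric(nn)
    if (tot > 0L) {
      r <- Tr * sqrt(stats::runif(tot))
      m <- msz[sample.int(length(p), tot, replace = TRUE, prob = p)]
      contrib <- m * epsilon * exp(-2 * r^2 / psf$e2_radius^2)
      idx <- rep.int(seq_len(nn), counts)
      agg <- rowsum(contrib, idx)
      sig[as.integer(rownames(agg))] <- agg
    }
    vals[i:j] <- offset + sig +
      if (noise_sd > 0) stats::rnorm(nn, 0, noise_sd) else 0
    i <- j + 1L
  }
  extract_roi_histogram(matrix(vals, nrow = 1L), bin_width = bin_width)
}

#' Moment-based initializer for the SpIDA fit
#'
#' Inverts the first two moment identities of the compound-Poisson model:
#' \code{epsilon0 = (var - sd0^2)/(mean - offset) * (a1/a2)} and
#' \code{rho0 = (mean - offset)/(epsilon0 * a1)}. Exact when given exact
#' moments of a pure-monomer field.
#'
#' @param x an \code{"intensity_histogram"} (moments taken from bin
#'   midpoints), or a numeric mean (then supply \code{var}).
#' @param var sample variance when \code{x} is a numeric mean.
#' @param psf a [gaussian_psf()].
#' @param noise_sd,offset detector calibration.
#' @return list with \code{epsilon}, \code{rho} and a \code{degenerate} flag
#'   (TRUE when the moments carry no emitter signal, i.e. variance <= noise
#'   variance or mean <= offset; then epsilon is NA and rho is 0).
#' @export
spida_moments_init <- function(x, var = NULL, psf, noise_sd, offset) {
  if (inherits(x, "intensity_histogram")) {
    mom <- hist_moments(x)
    mu <- mom$mean; v <- mom$var
  } else {
    stopifnot(is.numeric(x), !is.null(var))
    mu <- x; v <- var
  }
  if (v <= noise_sd^2 || mu <= offset)
    return(list(epsilon = NA_real_, rho = 0, degenerate = TRUE))
  eps <- (v - noise_sd^2) / (mu - offset) * (psf$a1 / psf$a2)
  rho <- (mu - offset) / (eps * psf$a1)
  list(epsilon = eps, rho = rho, degenerate = FALSE)
}

#' Fit the SpIDA model to a region of interest
#'
#' The central estimator of the package: fits the single-population
#' compound-Poisson intensity model to the pixel histogram of a confocal
#' image region, returning the quantal brightness (intensity units per
#' fluorescent entity) and the entity surface density (per um^2). Detector
#' offset and read-noise SD are calibration inputs, not free parameters.
#'
#' The fit minimizes the weighted least-squares distance between observed and
#' model-predicted bin counts (weights 1/max(expected, 1), a chi-square-like
#' objective) over \code{(rho, epsilon)}, parameterized on the log scale and
#' started from the moment initializer.
#'
#' @param x a [confocal_image()], a numeric matrix, or an
#'   \code{"intensity_histogram"}.
#' @param roi optional RoI (see [extract_roi_histogram()]) when \code{x} is an
#'   image; the fit requires at least a 32 x 32 px region.
#' @param psf a [gaussian_psf()].
#' @param noise_sd,offset detector calibration; taken from the image metadata
#'   when \code{x} is a \code{confocal_image} and not supplied.
#' @param bin_width histogram bin width (default 1 intensity unit).
#' @param init optional list(epsilon, rho) starting values.
#' @return An object of class \code{"spida"} with components \code{qb}
#'   (fitted quantal brightness), \code{density} (entities per um^2),
#'   \code{chi2}, \code{df}, \code{converged}, \code{degenerate}, \code{se}
#'   (asymptotic standard errors), the histogram, fitted counts and inputs.
#' @examples
#' cfg <- simulation_config(density = 50, qb = 11.01, image_shape = c(64, 64),
#'                          seed = 1)
#' img <- simulate_membrane_image(cfg)
#' fit <- spida(img, psf = cfg$psf)
#' coef(fit)
#' @export
spida <- function(x, roi = NULL, psf = gaussian_psf(), noise_sd = NULL,
                  offset = NULL, bin_width = 1, init = NULL) {
  if (inherits(x, "intensity_histogram")) {
    h <- x
  } else {
    if (inherits(x, "confocal_image")) {
      if (is.null(noise_sd)) noise_sd <- x$noise_sd
      if (is.null(offset)) offset <- x$offset
    }
    h <- extract_roi_histogram(x, roi, bin_width)
  }
  if (is.null(noise_sd) || is.null(offset))
    stop("noise_sd and offset must be supplied (or carried by the confocal_image)")
  if (h$n_pixels < 32 * 32)
    stop("SpIDA fit requires a region of at least 32 x 32 pixels")

  init0 <- spida_moments_init(h, psf = psf, noise_sd = noise_sd, offset = offset)
  if (is.null(init)) init <- init0
  out <- list(histogram = h, psf = psf, noise_sd = noise_sd, offset = offset,
              init = init0, call = match.call())
  if (isTRUE(init$degenerate)) {
    out <- c(out, list(qb = NA_real_, density = 0, chi2 = NA_real_,
                       df = NA_integer_, converged = FALSE, degenerate = TRUE,
                       se = c(qb = NA_real_, density = NA_real_),
                       fitted_counts = NULL, grid = NULL))
    class(out) <- "spida"
    return(out)
  }

  obj <- function(par) {
    eps <- exp(par[1L]); rho <- exp(par[2L])
    grid <- spida_grid(rho, eps, psf, noise_sd, offset, delta = bin_width,
                       include = range(h$mids))
    if (length(grid) > 2^15) return(1e12)
    pmf <- spida_pmf(rho, eps, psf, noise_sd, offset, grid, check = FALSE)
    pmf[pmf < 0] <- 0
    expc <- h$n_pixels * pmf
    oc <- numeric(length(grid))
    ix <- round((h$mids - grid[1L]) / bin_width) + 1L
    keep <- ix >= 1L & ix <= length(grid)
    oc[ix[keep]] <- h$counts[keep]
    sum((oc - expc)^2 / pmax(expc, 1)) +
      # mass the grid failed to cover counts as pure error
      sum(h$counts[!keep])
  }
  par0 <- log(c(max(init$epsilon, 1e-3), max(init$rho, 1e-4)))
  opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  eps <- exp(opt$par[1L]); rho <- exp(opt$par[2L])

  grid <- spida_grid(rho, eps, psf, noise_sd, offset, delta = bin_width,
                     include = range(h$mids))
  pmf <- spida_pmf(rho, eps, psf, noise_sd, offset, grid, check = FALSE)
  pmf[pmf < 0] <- 0
  fitted_counts <- h$n_pixels * pmf
  df <- max(1L, sum(fitted_counts > 0.5) - 2L)

  # asymptotic covariance from the chi-square surface: cov ~ 2 H^-1
  se <- c(qb = NA_real_, density = NA_real_)
  Hs <- try(stats::optimHess(opt$par, obj), silent = TRUE)
  if (!inherits(Hs, "try-error")) {
    cv <- try(2 * solve(Hs), silent = TRUE)
    if (!inherits(cv, "try-error") && all(diag(cv) > 0)) {
      # delta method back from log scale
      se <- c(qb = eps * sqrt(cv[1L, 1L]), density = rho * sqrt(cv[2L, 2L]))
    }
  }
  out <- c(out, list(qb = eps, density = rho, chi2 = opt$value, df = df,
                     converged = opt$convergence == 0L, degenerate = FALSE,
                     se = se, fitted_counts = fitted_counts, grid = grid))
  class(out) <- "spida"
  out
}

#' @export
print.spida <- function(x, digits = 4, ...) {
  cat("SpIDA fit (single population)\n")
  if (x$degenerate) {
    cat("  degenerate: no emitter signal above the detector noise floor\n")
    return(invisible(x))
  }
  cat(sprintf("  quantal brightness: %s intensity units per entity\n",
              format(x$qb, digits = digits)))
  cat(sprintf("  density:            %s entities per um^2\n",
              format(x$density, digits = digits)))
  cat(sprintf("  chi2 = %s on %d bins-2 df; converged: %s\n",
              format(x$chi2, digits = digits), x$df, x$converged))
  invisible(x)
}

#' @export
summary.spida <- function(object, ...) {
  object$moments <- hist_moments(object$histogram)
  class(object) <- c("summary.spida", class(object))
  object
}

#' @export
print.summary.spida <- function(x, digits = 4, ...) {
  print.spida(x, digits = digits)
  if (!x$degenerate) {
    cat(sprintf("  std. errors: qb %s, density %s\n",
                format(x$se[["qb"]], digits = digits),
                format(x$se[["density"]], digits = digits)))
    cat(sprintf("  moment start: qb %s, density %s\n",
                format(x$init$epsilon, digits = digits),
                format(x$init$rho, digits = digits)))
  }
  cat(sprintf("  RoI: %d px, mean %s, var %s\n", x$histogram$n_pixels,
              format(x$moments$mean, digits = digits),
              format(x$moments$var, digits = digits)))
  invisible(x)
}

#' @export
coef.spida <- function(object, ...) {
  c(qb = object$qb, density = object$density)
}

#' Model pmf of a fitted SpIDA object on its intensity grid
#' @param object a \code{"spida"} fit
#' @param grid optional intensity grid (bin centres); defaults to the fit grid
#' @param ... unused
#' @return data.frame with \code{intensity} and \code{pmf}
#' @export
predict.spida <- function(object, grid = NULL, ...) {
  if (object$degenerate) stop("degenerate fit has no model pmf")
  if (is.null(grid)) grid <- object$grid
  pmf <- spida_pmf(object$density, object$qb, object$psf, object$noise_sd,
                   object$offset, grid, check = FALSE)
  data.frame(intensity = grid, pmf = pmf)
}

#' @export
fitted.spida <- function(object, ...) object$fitted_counts

#' @export
residuals.spida <- function(object, type = c("pearson", "raw"), ...) {
  type <- match.arg(type)
  if (object$degenerate) stop("degenerate fit has no residuals")
  oc <- numeric(length(object$grid))
  ix <- round((object$histogram$mids - object$grid[1L]) /
                object$histogram$bin_width) + 1L
  keep <- ix >= 1L & ix <= length(object$grid)
  oc[ix[keep]] <- object$histogram$counts[keep]
  r <- oc - object$fitted_counts
  if (type == "pearson") r <- r / sqrt(pmax(object$fitted_counts, 1))
  r
}

#' @export
plot.spida <- function(x, ...) {
  if (x$degenerate) stop("degenerate fit: nothing to plot")
  h <- x$histogram
  plot(h$mids, h$counts, type = "h", col = "grey60",
       xlab = "pixel intensity", ylab = "pixel count",
       main = "SpIDA intensity histogram fit", ...)
  lines(x$grid, x$fitted_counts * (h$bin_width / (x$grid[2] - x$grid[1])),
        col = "red3", lwd = 2)
  legend("topright", bty = "n", lwd = c(NA, 2), pch = c(124, NA),
         col = c("grey60", "red3"), legend = c("observed", "model"))
  invisible(x)
}

#' Simulate an image from a fitted SpIDA model
#'
#' Draws a synthetic monomer-population image whose emitters have the fitted
#' quantal brightness and density, using the fit's PSF and detector
#' calibration — useful for posterior-predictive style checks.
#'
#' @param object a \code{"spida"} fit
#' @param nsim number of images
#' @param seed RNG seed
#' @param image_shape pixels, default 64 x 64
#' @param pixel_size um, default 0.05
#' @param ... unused
#' @return a list of [confocal_image()]s (length \code{nsim})
#' @export
simulate.spida <- function(object, nsim = 1, seed = NULL,
                           image_shape = c(64L, 64L), pixel_size = 0.05, ...) {
  if (object$degenerate) stop("degenerate fit: nothing to simulate")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    cfg <- simulation_config(density = object$density, qb = object$qb,
                             psf = object$psf, offset = object$offset,
                             noise_sd = object$noise_sd,
                             pixel_size = pixel_size,
                             image_shape = image_shape, seed = NULL)
    simulate_membrane_image(cfg)
  })
}
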