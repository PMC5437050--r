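#' Simulation settings for synthetic confocal images
#'
#' Bundles everything needed to render a plasma-membrane image of point
#' emitters with an analog confocal detector: emitter density and oligomer
#' composition, per-monomer quantal brightness, PSF, detector offset and
#' Gaussian read noise, pixel geometry, and the RNG seed.
#'
#' @param density emitter clusters per um^2 (a cluster of multiplicity m holds
#'   m fluorophores at one point).
#' @param multiplicity_probs named numeric vector of probabilities over
#'   oligomer sizes, e.g. \code{c("1" = 0.5, "2" = 0.5)}; must sum to 1.
#' @param qb intensity units contributed by a single fluorophore centred on a
#'   pixel (quantal brightness per monomer).
#' @param psf a [gaussian_psf()].
#' @param offset detector baseline (intensity units).
#' @param noise_sd SD of additive Gaussian read noise (intensity units).
#' @param pixel_size pixel edge length in um.
#' @param image_shape integer vector c(rows, cols) in pixels.
#' @param laser_power nominal laser power setting (percent) carried as
#'   metadata into the rendered image.
#' @param seed integer RNG seed or NULL.
#' @return a \code{"simulation_config"} list.
#' @export
simulation_config <- function(density, multiplicity_probs = c("1" = 1),
                              qb = 11.01, psf = gaussian_psf(),
                              offset = 10, noise_sd = 2,
                              pixel_size = 0.05,
                              image_shape = c(256L, 256L),
                              laser_power = 2, seed = NULL) {
  stopifnot(density >= 0, qb >= 0, noise_sd >= 0, pixel_size > 0,
            length(image_shape) == 2L, all(image_shape >= 1))
  p <- as.numeric(multiplicity_probs)
  m <- as.integer(names(multiplicity_probs))
  if (anyNA(m) || any(m < 1L)) stop("multiplicity_probs must be named by integer oligomer sizes >= 1")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) stop("multiplicity_probs must be non-negative and sum to 1")
  structure(
    list(density = density, multiplicity_probs = stats::setNames(p, m),
         qb = qb, psf = psf, offset = offset, noise_sd = noise_sd,
         pixel_size = pixel_size, image_shape = as.integer(image_shape),
         laser_power = laser_power, seed = seed),
    class = "simulation_config")
}

#' Sample a field of point emitters
#'
#' Draws emitter cluster positions from a homogeneous spatial Poisson process
#' over the imaged region extended by a margin strip on every side, and
#' assigns each cluster an i.i.d. oligomer multiplicity. The margin ensures
#' edge pixels of a rendered image see the same emitter statistics as interior
#' pixels.
#'
#' @param density clusters per um^2 (>= 0).
#' @param multiplicity_probs as in [simulation_config()].
#' @param width,height region dimensions in um.
#' @param margin margin strip width in um (must be at least the PSF
#'   truncation radius when the field is rendered).
#' @param seed integer seed or NULL to use the current RNG state.
#' @return An \code{"emitter_field"} with positions (um), multiplicities, and
#'   the region geometry.
#' @export
sample_emitter_field <- function(density, multiplicity_probs = c("1" = 1),
                                 width, height, margin = 0.75, seed = NULL) {
  if (density < 0) stop("density must be >= 0")
  stopifnot(width > 0, height > 0, margin >= 0)
  p <- as.numeric(multiplicity_probs)
  m <- as.integer(names(multiplicity_probs))
  if (anyNA(m) || any(m < 1L) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("invalid multiplicity_probs")
  if (!is.null(seed)) set.seed(seed)
  w2 <- width + 2 * margin
  h2 <- height + 2 * margin
  n <- stats::rpois(1L, density * w2 * h2)
  x <- stats::runif(n, -margin, width + margin)
  y <- stats::runif(n, -margin, height + margin)
  mult <- if (n > 0L) m[sample.int(length(p), n, replace = TRUE, prob = p)] else integer(0)
  structure(
    list(x = x, y = y, multiplicity = mult,
         width = width, height = height, margin = margin, n = n),
    class = "emitter_field")
}

#' @export
print.emitter_field <- function(x, ...) {
  cat(sprintf("Emitter field: %d clusters over %.2f x %.2f um (+%.2f um margin)\n",
              x$n, x$width, x$height, x$margin))
  if (x$n > 0) {
    tb <- table(x$multiplicity)
    cat("  multiplicities:", paste(sprintf("%sx%s", tb, names(tb)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Confocal image container
#'
#' A 2D analog intensity grid with the acquisition metadata SpIDA needs:
#' pixel size, laser power, detector offset and read-noise SD.
#'
#' @param data numeric matrix of pixel intensities.
#' @param pixel_size pixel edge length in um.
#' @param laser_power laser power setting (percent).
#' @param offset detector baseline (intensity units).
#' @param noise_sd read-noise SD (intensity units).
#' @return a \code{"confocal_image"}.
#' @export
confocal_image <- function(data, pixel_size, laser_power = NA_real_,
                           offset = 0, noise_sd = 0) {
  stopifnot(is.matrix(data), all(is.finite(data)), pixel_size > 0)
  structure(
    list(data = data, pixel_size = pixel_size, laser_power = laser_power,
         offset = offset, noise_sd = noise_sd),
    class = "confocal_image")
}

#' @export
print.confocal_image <- function(x, ...) {
  cat(sprintf("Confocal image: %d x %d px, pixel %.3f um (%.2f x %.2f um)\n",
              nrow(x$data), ncol(x$data), x$pixel_size,
              nrow(x$data) * x$pixel_size, ncol(x$data) * x$pixel_size))
  cat(sprintf("  laser power %s%%, offset %.3g, read-noise SD %.3g\n",
              format(x$laser_power), x$offset, x$noise_sd))
  cat(sprintf("  intensity range [%.2f, %.2f], mean %.2f\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' Render an analog confocal image from an emitter field
#'
#' Each pixel value is the detector offset plus the PSF-weighted sum of all
#' cluster contributions evaluated at the pixel centre plus Gaussian read
#' noise: \code{I(p) = offset + sum_i m_i * qb * PSF(|p - x_i|) + N(0, sd)}.
#' Rendering is deterministic given the field and the config seed (which
#' drives only the read noise here; draw the field with its own seed).
#'
#' @param field an [sample_emitter_field()] result whose region matches
#'   \code{cfg$image_shape * cfg$pixel_size}.
#' @param cfg a [simulation_config()].
#' @return a [confocal_image()].
#' @export
render_confocal_image <- function(field, cfg) {
  stopifnot(inherits(field, "emitter_field"), inherits(cfg, "simulation_config"))
  psf <- cfg$psf
  if (field$margin < psf$trunc_radius)
    stop("field margin (", field$margin, " um) is smaller than the PSF truncation radius (",
         psf$trunc_radius, " um); edge pixels would be biased")
  nr <- cfg$image_shape[1L]
  nc <- cfg$image_shape[2L]
  px <- cfg$pixel_size
  if (abs(field$width - nc * px) > 1e-9 || abs(field$height - nr * px) > 1e-9)
    stop("field region does not match image_shape * pixel_size")
  img <- matrix(0, nr, nc)
  # pixel centres: column j spans x in [(j-1)*px, j*px), row i likewise in y
  xc <- (seq_len(nc) - 0.5) * px
  yc <- (seq_len(nr) - 0.5) * px
  Tr <- psf$trunc_radius
  R2 <- psf$e2_radius^2
  for (i in seq_len(field$n)) {
    ex <- field$x[i]; ey <- field$y[i]
    jlo <- max(1L, ceiling((ex - Tr) / px + 0.5)); jhi <- min(nc, floor((ex + Tr) / px + 0.5))
    ilo <- max(1L, ceiling((ey - Tr) / px + 0.5)); ihi <- min(nr, floor((ey + Tr) / px + 0.5))
    if (jlo > jhi || ilo > ihi) next
    dx2 <- (xc[jlo:jhi] - ex)^2
    dy2 <- (yc[ilo:ihi] - ey)^2
    patch <- (field$multiplicity[i] * cfg$qb) * outer(exp(-2 * dy2 / R2), exp(-2 * dx2 / R2))
    # circular truncation, matching the radial discretization of the model
    patch[outer(dy2, dx2, "+") > Tr^2] <- 0
    img[ilo:ihi, jlo:jhi] <- img[ilo:ihi, jlo:jhi] + patch
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (cfg$noise_sd > 0)
    img <- img + matrix(stats::rnorm(nr * nc, 0, cfg$noise_sd), nr, nc)
  confocal_image(img + cfg$offset, pixel_size = px,
                 laser_power = cfg$laser_power,
                 offset = cfg$offset, noise_sd = cfg$noise_sd)
}

#' Simulate a full monomer/oligomer membrane image in one call
#'
#' Convenience wrapper: samples an emitter field matched to the configured
#' image geometry (margin = PSF truncation radius) and renders it. The seed
#' drives both the field and the read noise.
#'
#' @param cfg a [simulation_config()].
#' @return a [confocal_image()].
#' @export
simulate_membrane_image <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  field <- sample_emitter_field(cfg$density, cfg$multiplicity_probs,
                                width = cfg$image_shape[2L] * cfg$pixel_size,
                                height = cfg$image_shape[1L] * cfg$pixel_size,
                                margin = cfg$psf$trunc_radius, seed = NULL)
  cfg2 <- cfg
  cfg2$seed <- NULL  # keep the RNG stream continuous field -> noise
  render_confocal_image(field, cfg2)
}
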