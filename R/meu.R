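#' Mean monomeric quantal brightness at one laser power
#'
#' Averages the fitted quantal brightness of RoIs imaged on cells expressing a
#' known-monomeric reference fluorophore at a single laser power setting. The
#' result anchors 1.00 Monomeric Equivalent Unit (MEU) for that power.
#'
#' @param fits list of [spida()] fits (all must have converged).
#' @param laser_power laser power setting (percent) the fits were acquired at.
#' @param statistic "mean" (default, matching how calibration values are
#'   normally reported) or "median".
#' @return list with \code{qb} (the monomeric QB), \code{sem}, \code{n},
#'   \code{laser_power}.
#' @export
calibrate_monomeric_qb <- function(fits, laser_power, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (length(fits) == 0L) stop("no fits supplied")
  if (inherits(fits, "spida")) fits <- list(fits)
  ok <- vapply(fits, function(f) inherits(f, "spida") && isTRUE(f$converged) &&
                 !isTRUE(f$degenerate), logical(1L))
  if (!all(ok)) stop("all fits must be converged, non-degenerate SpIDA fits (",
                     sum(!ok), " are not)")
  qbs <- vapply(fits, function(f) f$qb, numeric(1L))
  est <- if (statistic == "mean") mean(qbs) else stats::median(qbs)
  list(qb = est, sem = stats::sd(qbs) / sqrt(length(qbs)), n = length(qbs),
       laser_power = laser_power)
}

#' Monomeric-equivalent-unit calibration model
#'
#' Holds the per-laser-power monomeric quantal brightness, the Gaussian
#' parameters of the pooled calibration MEU distribution, and the
#' monomer/dimer classification threshold (mean + 2 SD of the calibration
#' MEUs).
#'
#' @param monomeric_qb named numeric vector of monomeric QB keyed by laser
#'   power, e.g. \code{c("2" = 11.01, "6" = 24.31)}.
#' @param meus pooled calibration MEU values (each RoI's QB divided by the
#'   monomeric QB at its own power). Optional; when omitted, supply
#'   \code{meu_mean} and \code{meu_sd} directly.
#' @param meu_mean,meu_sd Gaussian parameters of the calibration MEU
#'   distribution (ignored when \code{meus} is given).
#' @return a \code{"meu_calibration"} with elements \code{monomeric_qb},
#'   \code{meu_mean}, \code{meu_sd}, \code{threshold}, \code{n_observations}
#'   and, when computed from data, the [fit_meu_distribution()] result.
#' @export
meu_calibration <- function(monomeric_qb, meus = NULL,
                            meu_mean = NULL, meu_sd = NULL) {
  qb <- as.numeric(monomeric_qb)
  if (is.null(names(monomeric_qb)) || any(!is.finite(qb)) || any(qb <= 0))
    stop("monomeric_qb must be a named (by laser power) vector of positive values")
  dist <- NULL
  if (!is.null(meus)) {
    dist <- fit_meu_distribution(meus)
    meu_mean <- dist$mean; meu_sd <- dist$sd
    n <- length(meus)
  } else {
    if (is.null(meu_mean) || is.null(meu_sd))
      stop("supply either meus or both meu_mean and meu_sd")
    n <- NA_integer_
  }
  structure(
    list(monomeric_qb = stats::setNames(qb, names(monomeric_qb)),
         meu_mean = meu_mean, meu_sd = meu_sd,
         threshold = monomer_threshold(meu_mean, meu_sd),
         n_observations = n, distribution = dist),
    class = "meu_calibration")
}

#' @export
print.meu_calibration <- function(x, ...) {
  cat("MEU calibration\n")
  for (p in names(x$monomeric_qb))
    cat(sprintf("  laser %s%%: monomeric QB = %.4g intensity units == 1.00 MEU\n",
                p, x$monomeric_qb[[p]]))
  cat(sprintf("  calibration MEU: mean %.4g, SD %.4g%s\n", x$meu_mean, x$meu_sd,
              if (is.na(x$n_observations)) "" else sprintf(" (n = %d)", x$n_observations)))
  cat(sprintf("  monomer threshold (mean + 2 SD): %.4g MEU\n", x$threshold))
  invisible(x)
}

#' Convert quantal brightness to Monomeric Equivalent Units
#'
#' Divides a fitted QB by the monomeric QB registered for the same laser
#' power. No cross-power extrapolation is performed: an unregistered power is
#' an error, because quantal brightness scales with excitation intensity.
#'
#' @param qb quantal brightness value(s), intensity units.
#' @param calibration a [meu_calibration()].
#' @param laser_power the power the QB was measured at.
#' @return MEU value(s): 1.0 = monomer, 2.0 = dimer.
#' @export
qb_to_meu <- function(qb, calibration, laser_power) {
  stopifnot(inherits(calibration, "meu_calibration"))
  key <- as.character(laser_power)
  if (!key %in% names(calibration$monomeric_qb))
    stop("laser power '", key, "' is not registered in the calibration (",
         paste(names(calibration$monomeric_qb), collapse = ", "), ")")
  qb / calibration$monomeric_qb[[key]]
}

#' Gaussian summary of a calibration MEU distribution
#'
#' Computes the sample mean and SD of pooled calibration MEUs, tests
#' normality with the D'Agostino-Pearson omnibus test (plus the skewness and
#' kurtosis components), and bins the values for reporting (bin size 0.1 MEU
#' by convention). Statistics always use the unbinned values.
#'
#' @param meus numeric vector of MEU values (n >= 8).
#' @param bin_size reporting bin width (default 0.1 MEU).
#' @return list with \code{mean}, \code{sd}, \code{n}, \code{normality}
#'   (statistic, p-value, skewness, kurtosis, \code{normal} verdict at
#'   p > 0.05, and an \code{applicable} flag, FALSE for degenerate input),
#'   and \code{table} (data.frame of bin mids and frequencies).
#' @export
fit_meu_distribution <- function(meus, bin_size = 0.1) {
  meus <- as.numeric(meus)
  if (length(meus) < 8L) stop("need at least 8 MEU values")
  mu <- mean(meus); sdv <- stats::sd(meus)
  if (sdv == 0) {
    norm <- list(statistic = NA_real_, p_value = NA_real_,
                 skewness = NA_real_, kurtosis = NA_real_,
                 normal = NA, applicable = FALSE)
  } else {
    norm <- dagostino_pearson(meus)
  }
  lo <- floor(min(meus) / bin_size) * bin_size
  nb <- floor((max(meus) - lo) / bin_size) + 1L
  idx <- pmin(floor((meus - lo) / bin_size) + 1L, nb)
  tab <- data.frame(meu = lo + (seq_len(nb) - 0.5) * bin_size,
                    frequency = tabulate(idx, nbins = nb))
  list(mean = mu, sd = sdv, n = length(meus), normality = norm, table = tab)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino 1970) and kurtosis
#' (Anscombe & Glynn 1983) into the K^2 statistic, referred to a chi-square
#' distribution with 2 df.
#'
#' @param x numeric vector, n >= 8.
#' @return list with \code{statistic} (K^2), \code{p_value}, the sample
#'   \code{skewness} (g1) and \code{kurtosis} (excess, g2), the component
#'   z-scores, \code{normal} (p > 0.05) and \code{applicable}.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("constant input")
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2

  # skewness component
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis component
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  denom <- 1 + xx * sqrt(2 / (a - 4))
  # sign-preserving cube root; denom < 0 occurs for strongly platykurtic data
  cr <- sign(denom) * abs((1 - 2 / a) / abs(denom))^(1 / 3)
  z2 <- ((1 - 2 / (9 * a)) - cr) / sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  list(statistic = k2, p_value = p, skewness = g1, kurtosis = b2 - 3,
       z_skewness = z1, z_kurtosis = z2, normal = p > 0.05, applicable = TRUE)
}

#' Monomer classification threshold
#'
#' The threshold separating predominantly monomeric from dimeric/oligomeric
#' RoIs is the mean + 2 SD of the calibration MEU distribution.
#'
#' @param meu_mean,meu_sd Gaussian parameters of the calibration MEUs
#'   (\code{meu_sd >= 0}).
#' @return threshold in MEU.
#' @examples
#' monomer_threshold(0.994, 0.206)  # 1.406
#' @export
monomer_threshold <- function(meu_mean, meu_sd) {
  stopifnot(meu_sd >= 0)
  meu_mean + 2 * meu_sd
}

#' Central mass of a Gaussian within k SDs of its mean
#'
#' The two-sided coverage conventionally quoted alongside a mean + k SD cut:
#' for k = 2 this is the familiar 95.44 percent.
#'
#' @param k number of SDs (default 2).
#' @return percentage of a normal population within mean +/- k SD.
#' @export
gaussian_central_mass <- function(k = 2) {
  100 * (2 * stats::pnorm(k) - 1)
}

#' Classify RoIs as monomeric or dimeric/oligomeric
#'
#' A RoI whose MEU is less than or equal to the threshold is scored
#' monomeric; above it, dimeric/oligomeric. Ties go to monomeric.
#'
#' @param meu MEU value(s), finite.
#' @param threshold classification threshold ([monomer_threshold()]); either
#'   a number or a [meu_calibration()].
#' @return factor with levels \code{"monomeric"}, \code{"dimeric/oligomeric"}.
#' @export
classify_roi <- function(meu, threshold) {
  if (inherits(threshold, "meu_calibration")) threshold <- threshold$threshold
  stopifnot(all(is.finite(meu)), is.finite(threshold))
  factor(ifelse(meu <= threshold, "monomeric", "dimeric/oligomeric"),
         levels = c("monomeric", "dimeric/oligomeric"))
}

#' Percentage of RoIs containing predominantly dimers/oligomers
#'
#' @param labels a factor from [classify_roi()] (or character vector with the
#'   same levels).
#' @return percentage in [0, 100].
#' @export
dimer_oligomer_fraction <- function(labels) {
  if (length(labels) == 0L) stop("no labels")
  100 * mean(labels == "dimeric/oligomeric")
}

#' Receptor surface density from mean fluorescence intensity
#'
#' The mean background-corrected pixel intensity equals
#' \code{density * qb * a1} (with \code{a1} the beam area of the PSF in um^2),
#' so dividing the offset-corrected mean intensity by the monomeric quantal
#' brightness and the beam area yields the density of monomer-equivalent
#' fluorophores per um^2. With \code{psf = NULL} the beam-area convention is
#' collapsed to unit area and the result is simply \code{mean / qb} (a
#' per-beam-area count, as some SpIDA implementations report).
#'
#' @param mean_intensity mean RoI (or image) pixel intensity.
#' @param offset detector baseline to subtract.
#' @param monomeric_qb monomeric quantal brightness at the acquisition laser
#'   power (> 0).
#' @param psf a [gaussian_psf()] providing the beam area, or NULL for the
#'   unit-area convention.
#' @return molecules per um^2 (or per beam area when \code{psf} is NULL).
#' @export
surface_density <- function(mean_intensity, offset = 0, monomeric_qb, psf = NULL) {
  stopifnot(monomeric_qb > 0)
  area <- if (is.null(psf)) 1 else psf$a1
  (mean_intensity - offset) / (monomeric_qb * area)
}

#' RoI selection bias check
#'
#' Compares the mean fluorescence intensity of the whole background-corrected
#' image with each analysed RoI's mean: fractions near 1 indicate the RoIs
#' sample the cell's receptor population without bias toward bright or dim
#' regions.
#'
#' @param image_mean mean intensity of the whole background-corrected image.
#' @param roi_means vector of per-RoI mean intensities (> 0).
#' @return list with \code{fractions} (image_mean / roi_mean per RoI),
#'   \code{mean}, \code{sem}.
#' @export
roi_selection_bias <- function(image_mean, roi_means) {
  if (any(roi_means <= 0)) stop("RoI means must be > 0")
  fr <- image_mean / roi_means
  list(fractions = fr, mean = mean(fr),
       sem = if (length(fr) > 1L) stats::sd(fr) / sqrt(length(fr)) else NA_real_)
}

#' Concentration-response summary of MEU and dimer fraction
#'
#' Aggregates per-RoI classifications measured at a series of ligand
#' concentrations into a table of mean MEU (with SEM) and the percentage of
#' dimeric/oligomeric RoIs per concentration, sorted by concentration.
#'
#' @param data data.frame with columns \code{concentration}, \code{meu} and
#'   either \code{label} (from [classify_roi()]) or a threshold to classify
#'   with via the \code{threshold} argument.
#' @param threshold optional threshold used when \code{data$label} is absent.
#' @return data.frame with one row per concentration: \code{concentration},
#'   \code{n}, \code{mean_meu}, \code{sem_meu}, \code{dimer_fraction}.
#' @export
concentration_response <- function(data, threshold = NULL) {
  stopifnot(is.data.frame(data), all(c("concentration", "meu") %in% names(data)))
  if (!"label" %in% names(data)) {
    if (is.null(threshold)) stop("supply labels or a threshold")
    data$label <- classify_roi(data$meu, threshold)
  }
  concs <- sort(unique(data$concentration))
  if (length(concs) < 2L) stop("need at least 2 concentrations")
  rows <- lapply(concs, function(cc) {
    d <- data[data$concentration == cc, ]
    data.frame(concentration = cc, n = nrow(d),
               mean_meu = mean(d$meu),
               sem_meu = stats::sd(d$meu) / sqrt(nrow(d)),
               dimer_fraction = dimer_oligomer_fraction(d$label))
  })
  do.call(rbind, rows)
}
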