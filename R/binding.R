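#' Simulate a radioligand dissociation experiment
#'
#' Infinite-dilution dissociation: after washout, specifically bound
#' radioligand decays mono-exponentially, \code{B(t) = b0 exp(-koff t)}, on
#' top of a constant nonspecific component. A paired nonspecific series
#' (defined experimentally with an excess of unlabelled competitor) is
#' returned alongside the total.
#'
#' @param koff dissociation rate constant in 1/min (>= 0; default 0.014).
#' @param b0 specifically bound counts at t = 0.
#' @param nonspecific nonspecific counts (constant over time).
#' @param times sampling times in minutes.
#' @param noise_cv coefficient of variation of multiplicative Gaussian noise
#'   applied to each measured value (default 0 = noiseless).
#' @param seed RNG seed.
#' @return a \code{"dissociation_trace"} with \code{times}, \code{total},
#'   \code{nonspecific} and the generating parameters.
#' @export
simulate_dissociation_trace <- function(koff = 0.014, b0 = 3000,
                                        nonspecific = 300,
                                        times = seq(0, 150, by = 10),
                                        noise_cv = 0, seed = NULL) {
  if (koff < 0) stop("koff must be >= 0")
  stopifnot(b0 >= 0, nonspecific >= 0, noise_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  total <- b0 * exp(-koff * times) + nonspecific
  ns <- rep(nonspecific, length(times))
  if (noise_cv > 0) {
    total <- total * (1 + stats::rnorm(length(times), 0, noise_cv))
    ns <- ns * (1 + stats::rnorm(length(times), 0, noise_cv))
  }
  structure(list(times = times, total = total, nonspecific = ns,
                 params = list(koff = koff, b0 = b0,
                               nonspecific = nonspecific, noise_cv = noise_cv)),
            class = "dissociation_trace")
}

#' Fit mono-exponential radioligand dissociation
#'
#' Subtracts the paired nonspecific series pointwise and fits
#' \code{B(t) = B0 exp(-koff t)} to the specific binding. Reports the rate
#' constant and the dissociation half-life ln2 / koff.
#'
#' @param x a \code{"dissociation_trace"}, or times vector (then supply
#'   \code{total} and \code{nonspecific}).
#' @param total,nonspecific counts series when \code{x} is a times vector.
#' @return a \code{"kinetic_fit"} with \code{koff} (1/min), \code{half_life}
#'   (min), \code{b0}, \code{converged}, and \code{dissociating} (FALSE when
#'   the series shows no decay, in which case the rate is flagged rather
#'   than trusted).
#' @export
fit_dissociation <- function(x, total = NULL, nonspecific = NULL) {
  if (inherits(x, "dissociation_trace")) {
    times <- x$times; total <- x$total; nonspecific <- x$nonspecific
  } else {
    times <- as.numeric(x)
  }
  stopifnot(length(times) >= 6L, length(total) == length(times),
            length(nonspecific) == length(times))
  spec <- total - nonspecific
  if (all(abs(spec) < .Machine$double.eps^0.5)) stop("specific binding is all zero")
  b00 <- max(spec[1L], max(spec) * 0.5)
  # log-linear start from the positive early points
  pos <- spec > 0
  k0 <- if (sum(pos) >= 2L) {
    sl <- stats::coef(stats::lm(log(spec[pos]) ~ times[pos]))[2L]
    max(-sl, 1e-6)
  } else 1e-3
  fit <- try(minpack.lm::nlsLM(
    spec ~ b0 * exp(-koff * times),
    start = list(b0 = b00, koff = k0), lower = c(0, 0),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    out <- list(koff = NA_real_, half_life = NA_real_, b0 = NA_real_,
                converged = FALSE, dissociating = NA, fit = NULL,
                times = times, specific = spec)
  } else {
    cf <- stats::coef(fit)
    koff <- cf[["koff"]]
    # flat trace: no measurable decay across the observation window
    dissociating <- is.finite(koff) && koff * max(times) > 1e-6
    out <- list(koff = koff,
                half_life = if (koff > 0) log(2) / koff else Inf,
                b0 = cf[["b0"]], converged = TRUE,
                dissociating = dissociating, fit = fit,
                times = times, specific = spec)
  }
  class(out) <- "kinetic_fit"
  out
}

#' @export
print.kinetic_fit <- function(x, digits = 4, ...) {
  cat("Radioligand dissociation fit\n")
  if (!x$converged) {
    cat("  did not converge\n")
    return(invisible(x))
  }
  if (!isTRUE(x$dissociating)) {
    cat("  flagged: no measurable dissociation over the observation window\n")
    return(invisible(x))
  }
  cat(sprintf("  koff = %s /min, half-life = %s min, B0 = %s counts\n",
              format(x$koff, digits = digits),
              format(x$half_life, digits = digits),
              format(x$b0, digits = digits)))
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) {
  c(koff = object$koff, half_life = object$half_life, b0 = object$b0)
}

#' Cheng-Prusoff conversion between IC50 and Ki
#'
#' \code{Ki = IC50 / (1 + [L]/Kd)} for a competition assay run at radioligand
#' concentration \code{[L]} with radioligand affinity \code{Kd}.
#'
#' @param ic50 half-maximal inhibitory concentration (M).
#' @param radioligand_conc radioligand concentration [L] (M).
#' @param radioligand_kd radioligand equilibrium Kd (M).
#' @return Ki in M.
#' @export
cheng_prusoff <- function(ic50, radioligand_conc, radioligand_kd) {
  stopifnot(radioligand_conc > 0, radioligand_kd > 0)
  ic50 / (1 + radioligand_conc / radioligand_kd)
}

#' Simulate a one-site competition binding curve
#'
#' Bound radioligand as a function of inhibitor concentration with Hill
#' slope 1: \code{bound([I]) = NS + (B0 - NS) / (1 + [I]/IC50)}, where the
#' IC50 is derived from the inhibitor's pKi via the inverse Cheng-Prusoff
#' relation \code{IC50 = Ki (1 + [L]/Kd)}.
#'
#' @param pki inhibitor affinity as -log10(Ki in M); default the spiperone
#'   self-competition value 8.74.
#' @param radioligand_conc radioligand concentration (M), default 1 nM.
#' @param radioligand_kd radioligand Kd (M), default 0.3 nM.
#' @param b0 bound counts with no inhibitor; \code{ns} nonspecific counts.
#' @param ns nonspecific counts.
#' @param inhibitor_concs inhibitor concentrations (M), default 10 log-spaced
#'   values spanning the IC50.
#' @param noise_cv multiplicative Gaussian noise CV (default 0).
#' @param seed RNG seed.
#' @return a \code{"competition_curve"} with \code{concs}, \code{bound} and
#'   the generating parameters (including the implied \code{ic50}).
#' @export
simulate_competition_curve <- function(pki = 8.74, radioligand_conc = 1e-9,
                                       radioligand_kd = 0.3e-9,
                                       b0 = 2000, ns = 200,
                                       inhibitor_concs = 10^seq(-11.5, -6.5,
                                                                length.out = 10),
                                       noise_cv = 0, seed = NULL) {
  stopifnot(all(inhibitor_concs > 0), radioligand_conc > 0, radioligand_kd > 0,
            b0 >= ns, noise_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  ki <- 10^(-pki)
  ic50 <- ki * (1 + radioligand_conc / radioligand_kd)
  bound <- ns + (b0 - ns) / (1 + inhibitor_concs / ic50)
  if (noise_cv > 0)
    bound <- bound * (1 + stats::rnorm(length(bound), 0, noise_cv))
  structure(list(concs = inhibitor_concs, bound = bound,
                 params = list(pki = pki, ic50 = ic50,
                               radioligand_conc = radioligand_conc,
                               radioligand_kd = radioligand_kd,
                               b0 = b0, ns = ns, noise_cv = noise_cv)),
            class = "competition_curve")
}

#' Fit a one-site competition binding curve
#'
#' Fits \code{bound = NS + (B0 - NS)/(1 + [I]/IC50)} (Hill slope fixed at 1)
#' with the IC50 parameterized on the log10 scale, then converts to Ki and
#' pKi via Cheng-Prusoff.
#'
#' @param x a \code{"competition_curve"}, or inhibitor concentrations (M;
#'   then supply \code{bound}).
#' @param bound bound counts when \code{x} is a concentration vector.
#' @param radioligand_conc,radioligand_kd assay constants for the
#'   Cheng-Prusoff conversion (M).
#' @return a \code{"competition_fit"} with \code{ic50}, \code{ki}, \code{pki},
#'   \code{b0}, \code{ns}, \code{converged}, and \code{in_range} (FALSE when
#'   the fitted IC50 falls outside the tested concentration range, i.e. the
#'   curve shows no inflection in range and the estimate is flagged).
#' @export
fit_competition <- function(x, bound = NULL, radioligand_conc, radioligand_kd) {
  if (inherits(x, "competition_curve")) {
    concs <- x$concs; bound <- x$bound
  } else {
    concs <- as.numeric(x)
  }
  stopifnot(length(concs) >= 6L, length(bound) == length(concs),
            all(concs > 0))
  lc <- log10(concs)
  b00 <- max(bound); ns0 <- max(min(bound), 0)
  # start log IC50 at the concentration where binding crosses halfway
  half <- (b00 + ns0) / 2
  i0 <- which.min(abs(bound - half))
  fit <- try(minpack.lm::nlsLM(
    bound ~ ns + (b0 - ns) / (1 + 10^(lc - lic50)),
    start = list(b0 = b00, ns = ns0, lic50 = lc[i0]),
    lower = c(0, 0, min(lc) - 6), upper = c(Inf, Inf, max(lc) + 6),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    out <- list(ic50 = NA_real_, ki = NA_real_, pki = NA_real_,
                b0 = NA_real_, ns = NA_real_, converged = FALSE,
                in_range = NA, fit = NULL, concs = concs, bound = bound)
  } else {
    cf <- stats::coef(fit)
    ic50 <- 10^cf[["lic50"]]
    ki <- cheng_prusoff(ic50, radioligand_conc, radioligand_kd)
    out <- list(ic50 = ic50, ki = ki, pki = -log10(ki),
                b0 = cf[["b0"]], ns = cf[["ns"]], converged = TRUE,
                in_range = ic50 >= min(concs) && ic50 <= max(concs),
                fit = fit, concs = concs, bound = bound)
  }
  class(out) <- "competition_fit"
  out
}

#' @export
print.competition_fit <- function(x, digits = 4, ...) {
  cat("One-site competition fit (Hill slope 1)\n")
  if (!x$converged) {
    cat("  did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("  IC50 = %s M, Ki = %s M, pKi = %s\n",
              format(x$ic50, digits = digits), format(x$ki, digits = digits),
              format(x$pki, digits = digits)))
  if (!isTRUE(x$in_range))
    cat("  flagged: IC50 outside the tested concentration range\n")
  invisible(x)
}

#' @export
coef.competition_fit <- function(object, ...) {
  c(ic50 = object$ic50, ki = object$ki, pki = object$pki)
}

#' Simulate a saturation binding experiment
#'
#' Specific binding follows a one-site hyperbola
#' \code{Bmax [L]/(Kd + [L])}; nonspecific binding rises linearly with
#' ligand concentration, as measured in the presence of excess unlabelled
#' competitor. Total = specific + nonspecific.
#'
#' @param kd equilibrium dissociation constant in nM (default 1.5).
#' @param bmax maximal specific binding (counts).
#' @param ns_slope nonspecific counts per nM of ligand.
#' @param concs ligand concentrations in nM (default 10 log-spaced points
#'   over 0.019-14 nM).
#' @param noise_cv multiplicative Gaussian noise CV.
#' @param seed RNG seed.
#' @return a \code{"saturation_curve"} with \code{concs} (nM), \code{total},
#'   \code{nonspecific} and parameters.
#' @export
simulate_saturation_curve <- function(kd = 1.5, bmax = 1000, ns_slope = 10,
                                      concs = 10^seq(log10(0.019), log10(14),
                                                     length.out = 10),
                                      noise_cv = 0, seed = NULL) {
  stopifnot(kd > 0, bmax >= 0, ns_slope >= 0, all(concs >= 0), noise_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  spec <- bmax * concs / (kd + concs)
  ns <- ns_slope * concs
  total <- spec + ns
  if (noise_cv > 0) {
    total <- total * (1 + stats::rnorm(length(total), 0, noise_cv))
    ns <- ns * (1 + stats::rnorm(length(ns), 0, noise_cv))
  }
  structure(list(concs = concs, total = total, nonspecific = ns,
                 params = list(kd = kd, bmax = bmax, ns_slope = ns_slope,
                               noise_cv = noise_cv)),
            class = "saturation_curve")
}

#' Fit a one-site saturation binding curve
#'
#' Subtracts the measured nonspecific series pointwise and fits the specific
#' binding to \code{Bmax [L]/(Kd + [L])}.
#'
#' @param x a \code{"saturation_curve"}, or ligand concentrations (then
#'   supply \code{total} and \code{nonspecific}).
#' @param total,nonspecific bound counts series.
#' @return a \code{"saturation_fit"} with \code{kd} (same units as the
#'   concentrations), \code{bmax}, \code{converged}.
#' @export
fit_saturation <- function(x, total = NULL, nonspecific = NULL) {
  if (inherits(x, "saturation_curve")) {
    concs <- x$concs; total <- x$total; nonspecific <- x$nonspecific
  } else {
    concs <- as.numeric(x)
  }
  stopifnot(length(concs) >= 6L, length(total) == length(concs),
            length(nonspecific) == length(concs))
  spec <- total - nonspecific
  bmax0 <- max(spec)
  kd0 <- concs[which.min(abs(spec - bmax0 / 2))]
  fit <- try(minpack.lm::nlsLM(
    spec ~ bmax * concs / (kd + concs),
    start = list(bmax = bmax0, kd = max(kd0, min(concs[concs > 0]))),
    lower = c(0, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    out <- list(kd = NA_real_, bmax = NA_real_, converged = FALSE, fit = NULL,
                concs = concs, specific = spec)
  } else {
    cf <- stats::coef(fit)
    out <- list(kd = cf[["kd"]], bmax = cf[["bmax"]], converged = TRUE,
                fit = fit, concs = concs, specific = spec)
  }
  class(out) <- "saturation_fit"
  out
}

#' @export
print.saturation_fit <- function(x, digits = 4, ...) {
  cat("One-site saturation binding fit\n")
  if (!x$converged) {
    cat("  did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("  Kd = %s, Bmax = %s\n", format(x$kd, digits = digits),
              format(x$bmax, digits = digits)))
  invisible(x)
}

#' @export
coef.saturation_fit <- function(object, ...) {
  c(kd = object$kd, bmax = object$bmax)
}

#' Receptor density from whole-cell copy number
#'
#' Converts receptor copies per cell into a surface density given the cell
#' surface area.
#'
#' @param copies_per_cell receptor copies per cell (> 0 allowed to be 0).
#' @param surface_area_um2 cell surface area in um^2 (> 0).
#' @return receptors per um^2.
#' @examples
#' receptors_per_area(424035, 5235)  # ~81 receptors per um^2
#' @export
receptors_per_area <- function(copies_per_cell, surface_area_um2) {
  stopifnot(copies_per_cell >= 0, surface_area_um2 > 0)
  copies_per_cell / surface_area_um2
}
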