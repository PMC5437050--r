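#' Simulate a FRAP experiment
#'
#' Generates the three intensity series a FRAP analysis consumes: the bleached
#' spot (Fs), a background region (Fb) and a control region on a non-bleached
#' cell (Fc). Recovery after the bleach event is mono-exponential,
#' \deqn{F_s(t) = bg + [floor + \frac{mf}{100}(pre - floor)(1 - e^{-t\ln 2/t_{1/2}})]\, d(t)}
#' with \code{floor = prebleach_level - bleach_depth} and \code{d(t)} an
#' exponential acquisition-photobleaching decay calibrated so the control
#' trace ends at \code{r} times its starting value. Defaults reproduce a
#' typical basolateral-membrane acquisition: 5 pre-bleach and 44 recovery
#' frames at 2.5 s intervals.
#'
#' @param t_half recovery half-time in seconds (> 0).
#' @param mobile_fraction percent of the bleached pool that recovers (0-100).
#' @param prebleach_level,bleach_depth,background_level intensity units.
#' @param control_bleach_rate end/start ratio r of the control trace
#'   (acquisition photobleaching across the whole series); 1 = none.
#' @param n_prebleach,n_recovery frame counts (defaults 5 and 44).
#' @param frame_interval seconds between frames (default 2.5).
#' @param noise_sd SD of additive Gaussian noise applied to every series
#'   (intensity units, default 0).
#' @param noise_cv coefficient of variation of multiplicative Gaussian noise
#'   (default 0); use this to state noise as a percentage of each measured
#'   value, as for the binding-curve generators.
#' @param seed RNG seed.
#' @return a \code{"frap_trace"} with \code{times}, \code{Fs}, \code{Fb},
#'   \code{Fc}, \code{n_prebleach} and the generating parameters.
#' @export
simulate_frap_trace <- function(t_half = 9.6, mobile_fraction = 79.4,
                                prebleach_level = 100, bleach_depth = 70,
                                background_level = 5,
                                control_bleach_rate = 0.95,
                                n_prebleach = 5L, n_recovery = 44L,
                                frame_interval = 2.5, noise_sd = 0,
                                noise_cv = 0, seed = NULL) {
  stopifnot(t_half > 0, mobile_fraction >= 0, mobile_fraction <= 100,
            bleach_depth >= 0, bleach_depth <= prebleach_level,
            control_bleach_rate > 0, n_prebleach >= 1, n_recovery >= 1,
            frame_interval > 0, noise_sd >= 0, noise_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  nf <- n_prebleach + n_recovery
  times <- (seq_len(nf) - 1) * frame_interval
  decay <- control_bleach_rate^((times - times[1L]) / (times[nf] - times[1L]))
  floorv <- prebleach_level - bleach_depth
  k <- log(2) / t_half
  tp <- times - times[n_prebleach + 1L]  # time since first post-bleach frame
  level <- c(rep(prebleach_level, n_prebleach),
             floorv + mobile_fraction / 100 * bleach_depth *
               (1 - exp(-k * tp[(n_prebleach + 1L):nf])))
  Fs <- background_level + level * decay
  Fb <- rep(background_level, nf)
  Fc <- prebleach_level * decay
  if (noise_sd > 0) {
    Fs <- Fs + stats::rnorm(nf, 0, noise_sd)
    Fb <- Fb + stats::rnorm(nf, 0, noise_sd)
    Fc <- Fc + stats::rnorm(nf, 0, noise_sd)
  }
  if (noise_cv > 0) {
    Fs <- Fs * (1 + stats::rnorm(nf, 0, noise_cv))
    Fb <- Fb * (1 + stats::rnorm(nf, 0, noise_cv))
    Fc <- Fc * (1 + stats::rnorm(nf, 0, noise_cv))
  }
  structure(
    list(times = times, Fs = Fs, Fb = Fb, Fc = Fc,
         n_prebleach = as.integer(n_prebleach),
         params = list(t_half = t_half, mobile_fraction = mobile_fraction,
                       prebleach_level = prebleach_level,
                       bleach_depth = bleach_depth,
                       background_level = background_level,
                       control_bleach_rate = control_bleach_rate,
                       frame_interval = frame_interval, noise_sd = noise_sd)),
    class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("FRAP trace: %d pre-bleach + %d recovery frames, %.3g s interval\n",
              x$n_prebleach, length(x$times) - x$n_prebleach,
              x$times[2] - x$times[1]))
  invisible(x)
}

#' Background- and photobleaching-correct a FRAP trace
#'
#' Applies the standard correction \code{F = (Fs - Fb) / r} with
#' \code{r = Fc_end / Fc_0} (the acquisition-photobleaching ratio of the
#' control region), then normalizes so the pre-bleach mean maps to 100 and
#' the first post-bleach frame to 0.
#'
#' @param trace a \code{"frap_trace"} (or list with \code{times}, \code{Fs},
#'   \code{Fb}, \code{Fc}, \code{n_prebleach}).
#' @return a \code{"frap_corrected"} with \code{times}, \code{F} (0-100
#'   normalized), \code{n_prebleach}, \code{r}, and a \code{flagged} field
#'   set when the first post-bleach frame is not below the pre-bleach mean.
#' @export
correct_frap_trace <- function(trace) {
  np <- trace$n_prebleach
  nf <- length(trace$times)
  stopifnot(np >= 1L, nf > np, length(trace$Fs) == nf,
            length(trace$Fb) == nf, length(trace$Fc) == nf)
  fc0 <- trace$Fc[1L]
  if (!is.finite(fc0) || fc0 <= 0) stop("control trace starts at Fc0 <= 0")
  r <- trace$Fc[nf] / fc0
  f <- (trace$Fs - trace$Fb) / r
  pre <- mean(f[seq_len(np)])
  post0 <- f[np + 1L]
  flagged <- post0 >= pre
  fn <- 100 * (f - post0) / (pre - post0)
  structure(
    list(times = trace$times, F = fn, n_prebleach = np, r = r,
         flagged = flagged),
    class = "frap_corrected")
}

#' Fit a one-phase exponential FRAP recovery
#'
#' Fits \code{F(t) = plateau * (1 - exp(-k t))} to the post-bleach frames of
#' a corrected, 0-100 normalized recovery series (time measured from the
#' first post-bleach frame). On that scale the plateau is the mobile fraction
#' in percent and the half-time is ln2 / k.
#'
#' @param x a \code{"frap_corrected"} object, or a numeric normalized series
#'   (then supply \code{times} and \code{n_prebleach}).
#' @param times frame times in seconds (full series).
#' @param n_prebleach number of pre-bleach frames at the start of the series.
#' @return a \code{"frap_fit"} with \code{t_half} (s), \code{mobile_fraction}
#'   (percent), \code{k} (per s), \code{plateau}, \code{converged}, and the
#'   underlying \code{nls} fit.
#' @export
fit_frap_recovery <- function(x, times = NULL, n_prebleach = NULL) {
  if (inherits(x, "frap_corrected")) {
    f <- x$F; times <- x$times; n_prebleach <- x$n_prebleach
  } else {
    f <- as.numeric(x)
    if (is.null(times) || is.null(n_prebleach))
      stop("supply times and n_prebleach with a plain series")
  }
  post <- (n_prebleach + 1L):length(f)
  if (length(post) < 10L) stop("need at least 10 post-bleach frames")
  tp <- times[post] - times[post[1L]]
  y <- f[post]
  if (diff(range(y)) < 1e-10) {
    # flat series: plateau is its level, rate unidentifiable
    out <- list(t_half = NA_real_, mobile_fraction = mean(y), k = NA_real_,
                plateau = mean(y), converged = TRUE, fit = NULL,
                times = tp, F = y)
    class(out) <- "frap_fit"
    return(out)
  }
  plateau0 <- mean(y[tp >= max(tp) * 0.7])
  if (!is.finite(plateau0) || plateau0 <= 0) plateau0 <- max(max(y), 1)
  # crude half-time guess: first time the series passes half the plateau
  ih <- which(y >= plateau0 / 2)
  t50 <- if (length(ih)) tp[ih[1L]] else max(tp) / 4
  k0 <- log(2) / max(t50, tp[2L] / 2, 1e-6)
  fit <- try(minpack.lm::nlsLM(
    y ~ plateau * (1 - exp(-k * tp)),
    start = list(plateau = plateau0, k = k0),
    lower = c(0, 1e-8), upper = c(200, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    out <- list(t_half = NA_real_, mobile_fraction = NA_real_, k = NA_real_,
                plateau = NA_real_, converged = FALSE, fit = NULL,
                times = tp, F = y)
  } else {
    cf <- stats::coef(fit)
    out <- list(t_half = log(2) / cf[["k"]], mobile_fraction = cf[["plateau"]],
                k = cf[["k"]], plateau = cf[["plateau"]], converged = TRUE,
                fit = fit, times = tp, F = y)
  }
  class(out) <- "frap_fit"
  out
}

#' @export
print.frap_fit <- function(x, digits = 4, ...) {
  cat("FRAP one-phase exponential fit\n")
  if (!x$converged) {
    cat("  did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("  t1/2 = %s s, mobile fraction = %s%%, k = %s /s\n",
              format(x$t_half, digits = digits),
              format(x$mobile_fraction, digits = digits),
              format(x$k, digits = digits)))
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...) {
  c(t_half = object$t_half, mobile_fraction = object$mobile_fraction,
    k = object$k)
}

#' @export
predict.frap_fit <- function(object, times = NULL, ...) {
  if (!object$converged) stop("fit did not converge")
  if (is.null(times)) times <- object$times
  object$plateau * (1 - exp(-object$k * times))
}

#' @export
residuals.frap_fit <- function(object, ...) {
  object$F - predict(object)
}

#' @export
plot.frap_fit <- function(x, ...) {
  plot(x$times, x$F, pch = 16, col = "grey40",
       xlab = "time since bleach (s)", ylab = "normalized fluorescence (%)",
       main = "FRAP recovery", ...)
  if (x$converged) {
    tt <- seq(0, max(x$times), length.out = 200)
    lines(tt, predict(x, tt), col = "red3", lwd = 2)
  }
  invisible(x)
}
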