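#' Run the simulate - fit - calibrate - classify workflow
#'
#' Orchestrates the full quaternary-structure pipeline on synthetic data:
#' renders monomer calibration images per laser power, fits each RoI with
#' [spida()], builds the MEU calibration and monomer threshold, then (when
#' sample conditions are configured) simulates, fits and classifies mixture
#' images against that calibration. All outputs are plain text (CSV/YAML) in
#' \code{outdir}, and a manifest records the configuration, seed and package
#' version so the run is reproducible from the manifest alone.
#'
#' @param config a list, or the path of a YAML file holding one, with fields:
#'   \describe{
#'     \item{seed}{integer master seed (every image seed derives from it).}
#'     \item{pixel_size, psf_e2_radius, offset, noise_sd, roi_size}{imaging
#'       defaults (um, um, intensity units, intensity units, pixels).}
#'     \item{calibration}{list of per-power settings: each a list with
#'       \code{laser_power}, \code{qb} (true monomeric brightness),
#'       \code{density} (molecules per um^2) and \code{n_roi}.}
#'     \item{sample}{optional list of conditions to classify: each a list
#'       with \code{name}, \code{laser_power}, \code{qb}, \code{density},
#'       \code{dimer_fraction} (0-1) and \code{n_roi}.}
#'   }
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the calibration object, per-power fit
#'   tables, and the classification table (NULL when no sample stage ran).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE))
  }
  stage("config", {
    stopifnot(is.list(config), !is.null(config$seed),
              !is.null(config$calibration))
  })
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  px <- config$pixel_size %||% 0.05
  psf <- gaussian_psf(config$psf_e2_radius %||% 0.25)
  offset <- config$offset %||% 10
  noise_sd <- config$noise_sd %||% 2
  roi <- config$roi_size %||% 64L
  seed <- as.integer(config$seed)

  fit_condition <- function(qb, density, dimer_fraction, laser_power, n_roi,
                            seed0) {
    probs <- if (dimer_fraction > 0)
      stats::setNames(c(1 - dimer_fraction, dimer_fraction), c("1", "2"))
    else c("1" = 1)
    lapply(seq_len(n_roi), function(i) {
      cfg <- simulation_config(density = density, multiplicity_probs = probs,
                               qb = qb, psf = psf, offset = offset,
                               noise_sd = noise_sd, pixel_size = px,
                               image_shape = c(roi, roi),
                               laser_power = laser_power,
                               seed = seed0 + i)
      spida(simulate_membrane_image(cfg), psf = psf)
    })
  }

  calib_fits <- list()
  stage("calibrate", {
    for (j in seq_along(config$calibration)) {
      cc <- config$calibration[[j]]
      fits <- fit_condition(cc$qb, cc$density, 0, cc$laser_power,
                            cc$n_roi, seed + j * 10000L)
      key <- as.character(cc$laser_power)
      calib_fits[[key]] <- fits
      write_fit_table(fits, file.path(outdir,
                                      sprintf("calibration_fits_power%s.csv", key)))
    }
  })
  calibration <- stage("calibrate", {
    qb_by_power <- vapply(calib_fits, function(fits)
      calibrate_monomeric_qb(fits, NA)$qb, numeric(1L))
    meus <- unlist(lapply(names(calib_fits), function(key)
      vapply(calib_fits[[key]], function(f) f$qb, numeric(1L)) / qb_by_power[[key]]))
    meu_calibration(qb_by_power, meus = meus)
  })
  stage("calibrate", {
    yaml::write_yaml(list(
      monomeric_qb = as.list(calibration$monomeric_qb),
      meu_mean = calibration$meu_mean, meu_sd = calibration$meu_sd,
      threshold = calibration$threshold,
      n_observations = calibration$n_observations),
      file.path(outdir, "calibration.yml"))
  })

  classification <- NULL
  if (!is.null(config$sample)) {
    classification <- stage("classify", {
      rows <- list()
      for (j in seq_along(config$sample)) {
        sc <- config$sample[[j]]
        key <- as.character(sc$laser_power)
        if (!key %in% names(calibration$monomeric_qb))
          stop("laser power '", key, "' is not registered in the calibration")
        fits <- fit_condition(sc$qb, sc$density, sc$dimer_fraction %||% 0,
                              sc$laser_power, sc$n_roi,
                              seed + 500000L + j * 10000L)
        qbs <- vapply(fits, function(f) f$qb, numeric(1L))
        meus <- qb_to_meu(qbs, calibration, sc$laser_power)
        means <- vapply(fits, function(f) hist_moments(f$histogram)$mean,
                        numeric(1L))
        rows[[j]] <- data.frame(
          condition = sc$name %||% paste0("condition", j),
          roi_id = seq_along(fits), qb = qbs, meu = meus,
          density = surface_density(means, offset,
                                    calibration$monomeric_qb[[key]], psf),
          label = classify_roi(meus, calibration))
      }
      do.call(rbind, rows)
    })
    stage("classify", {
      utils::write.csv(classification,
                       file.path(outdir, "classification.csv"),
                       row.names = FALSE)
      summ <- do.call(rbind, lapply(split(classification,
                                          classification$condition),
                                    function(d) data.frame(
        condition = d$condition[1L], n = nrow(d), mean_meu = mean(d$meu),
        mean_density = mean(d$density),
        dimer_fraction = dimer_oligomer_fraction(d$label))))
      utils::write.csv(summ, file.path(outdir, "summary.csv"),
                       row.names = FALSE)
    })
  }

  stage("manifest", {
    yaml::write_yaml(list(
      package = "spidar",
      version = as.character(utils::packageVersion("spidar")),
      seed = seed, config = config),
      file.path(outdir, "manifest.yml"))
  })
  invisible(list(calibration = calibration, calibration_fits = calib_fits,
                 classification = classification))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
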