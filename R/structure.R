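#' Generate synthetic helix-bundle C-alpha frames
#'
#' Builds a set of coordinate frames holding one C-alpha atom per labelled
#' Ballesteros-Weinstein position, arranged as independent residue pairs whose
#' pairwise distances fluctuate around configured means with Gaussian jitter
#' (a stand-in for thermal motion across trajectory snapshots). Each pair is
#' placed in its own region of space so pairs do not interact.
#'
#' @param pair_means data.frame with columns \code{a}, \code{b} (BW labels,
#'   e.g. "4.50", "5.50") and \code{mean} (distance in Angstrom, > 0).
#'   Default: the three transmembrane interface pairs of a class-A GPCR at
#'   apo-like separations.
#' @param jitter_sd per-frame Gaussian SD of each pair distance (Angstrom).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return a \code{"helix_frames"} object: \code{coords} array
#'   (frames x labels x 3, Angstrom, with dimnames), \code{labels}, and
#'   \code{pairs}.
#' @export
generate_helix_frames <- function(pair_means = data.frame(
                                    a = c("1.35", "3.40", "4.50"),
                                    b = c("2.65", "6.44", "5.50"),
                                    mean = c(12.0, 10.0, 11.0)),
                                  jitter_sd = 0.5, n_frames = 100L,
                                  seed = NULL) {
  stopifnot(is.data.frame(pair_means),
            all(c("a", "b", "mean") %in% names(pair_means)),
            all(pair_means$mean > 0), jitter_sd >= 0, n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  labels <- c(rbind(pair_means$a, pair_means$b))
  if (anyDuplicated(labels)) stop("pair labels must be distinct across pairs")
  np <- nrow(pair_means)
  coords <- array(0, dim = c(n_frames, 2L * np, 3L),
                  dimnames = list(NULL, labels, c("x", "y", "z")))
  for (p in seq_len(np)) {
    d <- stats::rnorm(n_frames, pair_means$mean[p], jitter_sd)
    d[d < 0.1] <- 0.1
    base_y <- (p - 1) * 60  # keep pairs far apart
    coords[, 2L * p - 1L, ] <- cbind(0, base_y, 0)[rep(1, n_frames), ]
    coords[, 2L * p, ] <- cbind(d, base_y, 0)
  }
  structure(list(coords = coords, labels = labels,
                 pairs = pair_means, n_frames = as.integer(n_frames)),
            class = "helix_frames")
}

#' @export
print.helix_frames <- function(x, ...) {
  cat(sprintf("Helix C-alpha frames: %d frames, labels %s\n", x$n_frames,
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Per-frame distance between two labelled positions
#'
#' Euclidean C-alpha distance between two Ballesteros-Weinstein positions in
#' every frame, with summary statistics.
#'
#' @param frames a \code{"helix_frames"} object (from
#'   [generate_helix_frames()] or [read_helix_frames()]).
#' @param label_a,label_b BW position labels; both must be present in every
#'   frame.
#' @return a \code{"distance_summary"}: \code{pair}, \code{distances}
#'   (Angstrom, per frame), \code{mean}, \code{sd}, \code{sem},
#'   \code{n_frames}.
#' @export
pair_distance_series <- function(frames, label_a, label_b) {
  stopifnot(inherits(frames, "helix_frames"))
  lbl <- dimnames(frames$coords)[[2L]]
  if (!(label_a %in% lbl) || !(label_b %in% lbl))
    stop("label '", setdiff(c(label_a, label_b), lbl)[1L],
         "' is missing from the frames")
  d3 <- frames$coords[, label_a, , drop = FALSE] -
    frames$coords[, label_b, , drop = FALSE]
  d <- sqrt(rowSums(matrix(d3, nrow = dim(frames$coords)[1L])^2))
  n <- length(d)
  structure(list(pair = paste(label_a, label_b, sep = "-"), distances = d,
                 mean = mean(d), sd = stats::sd(d),
                 sem = stats::sd(d) / sqrt(n), n_frames = n),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Pair %s: %s +/- %s A (mean +/- SEM, n = %d frames)\n", x$pair,
              format(x$mean, digits = digits), format(x$sem, digits = digits),
              x$n_frames))
  invisible(x)
}

#' Ligand-versus-apo differences in inter-helix distances
#'
#' For each residue pair, the difference between the mean distance under a
#' ligand condition and in the apo receptor, with propagated standard error.
#' When per-frame distances are available for more than one condition a
#' one-way ANOVA with Tukey multiple comparisons across all groups (apo
#' included) is run per pair.
#'
#' @param condition named list of \code{"distance_summary"} objects for one
#'   ligand condition, keyed by pair label (a single summary is accepted),
#'   or a list of such lists keyed by condition name.
#' @param apo matching \code{"distance_summary"} (or list keyed by pair) for
#'   the apo receptor.
#' @return a \code{"distance_delta"} object: \code{table} (data.frame with
#'   condition, pair, delta, se) and \code{tukey} (named list of TukeyHSD
#'   results per pair, when computable).
#' @export
distance_delta_summary <- function(condition, apo) {
  as_pairlist <- function(x) {
    if (inherits(x, "distance_summary")) {
      stats::setNames(list(x), x$pair)
    } else x
  }
  apo <- as_pairlist(apo)
  # single condition vs named list of conditions
  if (inherits(condition, "distance_summary") ||
      all(vapply(condition, inherits, logical(1L), "distance_summary"))) {
    condition <- list(condition = as_pairlist(condition))
  } else {
    condition <- lapply(condition, as_pairlist)
  }
  rows <- list()
  frames_by_pair <- list()
  for (cn in names(condition)) {
    for (pr in names(condition[[cn]])) {
      if (!pr %in% names(apo)) stop("pair '", pr, "' missing from apo summary")
      cs <- condition[[cn]][[pr]]; as <- apo[[pr]]
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cn, pair = pr,
        delta = cs$mean - as$mean,
        se = sqrt(cs$sem^2 + as$sem^2))
      frames_by_pair[[pr]] <- rbind(
        frames_by_pair[[pr]],
        data.frame(group = cn, distance = cs$distances))
    }
  }
  tukey <- list()
  for (pr in names(frames_by_pair)) {
    df <- rbind(data.frame(group = "apo", distance = apo[[pr]]$distances),
                frames_by_pair[[pr]])
    df$group <- factor(df$group)
    if (nlevels(df$group) >= 2L && all(table(df$group) >= 2L)) {
      fit <- stats::aov(distance ~ group, data = df)
      tukey[[pr]] <- stats::TukeyHSD(fit)
    }
  }
  structure(list(table = do.call(rbind, rows), tukey = tukey),
            class = "distance_delta")
}

#' @export
print.distance_delta <- function(x, digits = 4, ...) {
  cat("Inter-helix distance changes versus apo (Angstrom)\n")
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Write helix frames as a multi-MODEL PDB with a label mapping table
#'
#' One C-alpha ATOM record per labelled position per MODEL, plus a CSV
#' mapping Ballesteros-Weinstein labels to chain/residue numbers (the PDB
#' format itself cannot carry the labels).
#'
#' @param frames a \code{"helix_frames"} object.
#' @param pdb_file output PDB path.
#' @param mapping_file output CSV path (columns bw_label, chain, resid).
#' @return invisibly, the mapping data.frame.
#' @export
write_helix_frames <- function(frames, pdb_file, mapping_file) {
  stopifnot(inherits(frames, "helix_frames"))
  labels <- dimnames(frames$coords)[[2L]]
  mapping <- data.frame(bw_label = labels, chain = "A",
                        resid = 100L + seq_along(labels))
  con <- file(pdb_file, "w")
  on.exit(close(con))
  for (f in seq_len(frames$n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    for (j in seq_along(labels)) {
      xyz <- frames$coords[f, j, ]
      writeLines(sprintf(
        "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        j, mapping$chain[j], mapping$resid[j], xyz[1L], xyz[2L], xyz[3L]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  utils::write.csv(mapping, mapping_file, row.names = FALSE)
  invisible(mapping)
}

#' Read labelled C-alpha frames from a multi-MODEL PDB
#'
#' Reads every MODEL with bio3d and extracts the C-alpha coordinates of the
#' residues listed in the mapping table, returning them keyed by
#' Ballesteros-Weinstein label.
#'
#' @param pdb_file multi-MODEL PDB path.
#' @param mapping mapping data.frame (bw_label, chain, resid) or the path of
#'   the CSV written by [write_helix_frames()].
#' @return a \code{"helix_frames"} object.
#' @export
read_helix_frames <- function(pdb_file, mapping) {
  if (is.character(mapping)) mapping <- utils::read.csv(mapping,
                                                        colClasses = c("character", "character", "integer"))
  stopifnot(all(c("bw_label", "chain", "resid") %in% names(mapping)))
  pdb <- bio3d::read.pdb(pdb_file, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_frames <- nrow(xyz)
  labels <- mapping$bw_label
  coords <- array(NA_real_, dim = c(n_frames, length(labels), 3L),
                  dimnames = list(NULL, labels, c("x", "y", "z")))
  for (j in seq_along(labels)) {
    sel <- bio3d::atom.select(pdb, elety = "CA", chain = mapping$chain[j],
                              resno = mapping$resid[j], verbose = FALSE)
    if (length(sel$xyz) != 3L)
      stop("label '", labels[j], "' (chain ", mapping$chain[j], ", resid ",
           mapping$resid[j], ") not found exactly once in every frame")
    coords[, j, ] <- xyz[, sel$xyz, drop = FALSE]
  }
  structure(list(coords = coords, labels = labels, pairs = NULL,
                 n_frames = n_frames),
            class = "helix_frames")
}
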