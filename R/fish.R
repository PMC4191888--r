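# Locus geometry: FISH-style probe-pair distance and radial-position
# analyses, plus a synthetic table generator bridging simulation to
# measurement-style data.

#' Mean square distance versus genomic distance
#'
#' Aggregates a probe-pair distance table into the FISH-side profile: for
#' each unique genomic distance `g` (Mb) the mean of the squared 3D distance
#' `R^2` (um^2), its standard error over measurements, and the measurement
#' count (so a 30-150 measurements-per-point design can be checked). Genomic
#' distances represented by a single measurement are excluded with a warning.
#'
#' @param records a data frame with columns `genomic_distance` (Mb, > 0) and
#'   `distance` (um, >= 0), e.g. from [read_probe_pairs()] or
#'   [synthesize_fish_table()].
#' @return a data frame with columns `genomic_distance`, `msd`, `sem`, `n`.
#' @export
msd_vs_genomic <- function(records) {
  if (is.null(records) || nrow(records) == 0) stopf("empty probe-pair table")
  need <- c("genomic_distance", "distance")
  if (!all(need %in% names(records)))
    stopf("probe-pair table needs columns: %s", paste(need, collapse = ", "))
  if (any(records$genomic_distance <= 0)) stopf("genomic distances must be > 0")
  if (any(records$distance < 0)) stopf("3D distances must be >= 0")
  r2 <- split(records$distance^2, records$genomic_distance)
  n <- vapply(r2, length, 0L)
  if (any(n < 2)) {
    warning(sprintf("%d genomic distance(s) with a single measurement excluded",
                    sum(n < 2)), call. = FALSE)
    r2 <- r2[n >= 2]
    n <- n[n >= 2]
  }
  if (length(r2) == 0) stopf("no genomic distance has >= 2 measurements")
  data.frame(genomic_distance = as.numeric(names(r2)),
             msd = vapply(r2, mean, 0),
             sem = vapply(r2, function(v) sd(v) / sqrt(length(v)), 0),
             n = as.integer(n), row.names = NULL)
}

#' Normalised radial nuclear position
#'
#' `p_n = r_o / r_n`: the distance of a labelled locus from the nuclear
#' centre of gravity (`r_o`), divided by the length of the line from the
#' centre through the locus to the nuclear envelope (`r_n`). 0 is the
#' nuclear centre, 1 the periphery; the ratio is invariant under rescaling
#' both measurements. Vectorised.
#'
#' @param r_o centre-to-locus distance, um (`0 <= r_o <= r_n`).
#' @param r_n centre-to-envelope distance through the locus, um (> 0).
#' @return numeric vector of positions in `[0, 1]`.
#' @export
radial_position <- function(r_o, r_n) {
  if (any(r_n <= 0)) stopf("r_n must be > 0")
  if (any(r_o < 0) || any(r_o > r_n)) stopf("r_o must satisfy 0 <= r_o <= r_n")
  r_o / r_n
}

#' Synthesise a FISH-style probe-pair table from an ensemble
#'
#' Emulates probe-pair distance measurements from simulated conformations:
#' for every conformation and probe pair, the genomic distance is
#' `|i - j| * mb_per_monomer` Mb and the measured 3D distance is the scaled
#' true distance plus isotropic Gaussian localisation noise of standard
#' deviation `noise_sd` um per axis (microscopy localisation accuracy is
#' better than 50 nm, hence the 0.05 um default ceiling). With zero noise the
#' table reproduces the simulated distances exactly; with noise,
#' `E[R^2] = scale^2 * <R^2>_sim + 3 * noise_sd^2` (law of total variance).
#'
#' @param ensemble a `dl_ensemble` (or list of conformations).
#' @param probe_positions monomer indices of the labelled probes (>= 2).
#' @param scale um per lattice unit (> 0).
#' @param mb_per_monomer Mb of genomic DNA per monomer (> 0).
#' @param noise_sd localisation noise per axis, um (default 0.05).
#' @param seed integer seed for the noise.
#' @return a probe-pair data frame with columns `pair_id`, `probe_a`,
#'   `probe_b`, `genomic_distance` (Mb), `distance` (um), `experiment`
#'   (conformation index).
#' @export
synthesize_fish_table <- function(ensemble, probe_positions, scale = 0.1,
                                  mb_per_monomer = 0.1, noise_sd = 0.05,
                                  seed = NULL) {
  confs <- if (inherits(ensemble, "dl_ensemble")) ensemble$conformations
           else ensemble
  if (length(confs) == 0) stopf("empty ensemble")
  N <- confs[[1]]$N
  probe_positions <- as.integer(probe_positions)
  if (any(probe_positions < 1 | probe_positions > N))
    stopf("probe positions must lie in [1, N]")
  if (length(unique(probe_positions)) < 2) stopf("need >= 2 distinct probes")
  if (scale <= 0 || mb_per_monomer <= 0)
    stopf("scale and mb_per_monomer must be > 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  probes <- sort(unique(probe_positions))
  pairs <- t(utils::combn(probes, 2))
  with_local_seed(seed, {
    out <- lapply(seq_along(confs), function(ci) {
      pos <- confs[[ci]]$positions
      d <- pos[pairs[, 2], , drop = FALSE] - pos[pairs[, 1], , drop = FALSE]
      v <- scale * d
      if (noise_sd > 0)
        v <- v + matrix(rnorm(length(v), 0, noise_sd), nrow(v), 3)
      data.frame(
        pair_id = sprintf("m%04d_m%04d", pairs[, 1], pairs[, 2]),
        probe_a = pairs[, 1], probe_b = pairs[, 2],
        genomic_distance = (pairs[, 2] - pairs[, 1]) * mb_per_monomer,
        distance = sqrt(rowSums(v^2)),
        experiment = ci)
    })
    do.call(rbind, out)
  })
}

#' Read / write probe-pair distance tables
#'
#' Tab-separated tables with columns `pair_id`, `probe_a`, `probe_b`,
#' `genomic_distance` (Mb), `distance` (um), `experiment`; only
#' `genomic_distance` and `distance` are required on read.
#'
#' @param path file path.
#' @return `read_probe_pairs`: the table as a data frame.
#' @export
read_probe_pairs <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("genomic_distance", "distance") %in% names(tab)))
    stopf("%s lacks the genomic_distance / distance columns", path)
  tab
}

#' @rdname read_probe_pairs
#' @param records a probe-pair data frame.
#' @export
write_probe_pairs <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write radial-position tables
#'
#' Tab-separated tables with columns `probe_id`, `r_o` (um), `r_n` (um).
#' [radial_position()] converts them to normalised positions.
#'
#' @param path file path.
#' @return `read_radial_table`: the table as a data frame.
#' @export
read_radial_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("r_o", "r_n") %in% names(tab)))
    stopf("%s lacks the r_o / r_n columns", path)
  tab
}

#' @rdname read_radial_table
#' @param records a radial-position data frame.
#' @export
write_radial_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
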