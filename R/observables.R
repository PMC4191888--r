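# Ensemble observables: MSD vs contour distance, plateau compaction,
# normalised profiles, parameter-space heat maps, loop counts.

#' Mean square distance versus contour separation
#'
#' For each contour separation `s`, the mean over all monomer pairs
#' `(i, i + s)` and all conformations of the squared spatial distance, in
#' lattice units squared - the simulation analogue of the FISH mean square
#' distance versus genomic distance. The standard error is computed over
#' conformation-level means, since pairs within one conformation are
#' correlated; conformations are the independent units.
#'
#' @param ensemble a `dl_ensemble` (or plain list of `dl_conformation`s).
#' @param separations contour separations `s` to evaluate (default all
#'   `1..N-1`; `0` is allowed and trivially 0).
#' @return an object of class `dl_msd_profile`: a data frame with columns
#'   `s`, `msd`, `sem`, `n_pairs`, and attributes `n_monomers`,
#'   `n_conformations`.
#' @export
msd_profile <- function(ensemble, separations = NULL) {
  confs <- if (inherits(ensemble, "dl_ensemble")) ensemble$conformations
           else ensemble
  if (length(confs) == 0) stopf("empty ensemble")
  N <- confs[[1]]$N
  separations <- sort(unique(as.integer(separations %||% seq_len(N - 1))))
  if (any(separations < 0 | separations > N - 1))
    stopf("separations must lie in [0, N - 1]")
  nc <- length(confs)
  per_conf <- matrix(0, nc, length(separations))
  for (ci in seq_len(nc)) {
    pos <- confs[[ci]]$positions
    for (k in seq_along(separations)) {
      s <- separations[k]
      if (s == 0) next
      d <- pos[(1 + s):N, , drop = FALSE] - pos[seq_len(N - s), , drop = FALSE]
      per_conf[ci, k] <- mean(rowSums(d^2))
    }
  }
  msd <- colMeans(per_conf)
  sem <- if (nc > 1) apply(per_conf, 2, sd) / sqrt(nc) else rep(NA_real_, ncol(per_conf))
  out <- data.frame(s = separations, msd = msd, sem = sem,
                    n_pairs = (N - separations) * nc)
  attr(out, "n_monomers") <- N
  attr(out, "n_conformations") <- nc
  class(out) <- c("dl_msd_profile", "data.frame")
  out
}

#' MSD plateau level
#'
#' The compaction readout: the saturation level of the MSD-versus-contour
#' distance curve, estimated as the mean of `msd` over the top tercile of
#' separations (`s >= ceiling(2N/3)`), weighted by the pair counts. The
#' estimator is fixed by definition so plateau values are comparable across
#' runs and parameter cells.
#'
#' @param profile a [msd_profile()] result covering separations up to at
#'   least `0.8 * N`.
#' @return numeric plateau value (same units as `msd`).
#' @export
plateau_level <- function(profile) {
  N <- attr(profile, "n_monomers")
  if (is.null(N)) stopf("profile lacks its n_monomers attribute")
  if (max(profile$s) < 0.8 * N)
    stopf("profile covers s up to %d; plateau needs coverage to >= 0.8 N = %.0f",
          max(profile$s), 0.8 * N)
  top <- profile$s >= ceiling(2 * N / 3)
  if (!any(top)) stopf("no separations in the top tercile (s >= %d)",
                       ceiling(2 * N / 3))
  sum(profile$msd[top] * profile$n_pairs[top]) / sum(profile$n_pairs[top])
}

#' Normalise an MSD profile by a reference plateau
#'
#' Divides `msd` and `sem` by a reference plateau level (for instance the
#' plateau of the `p_short = p_long = 0.03` run), yielding the dimensionless
#' profiles used to compare compaction across looping regimes.
#'
#' @param profile a [msd_profile()] result.
#' @param reference_plateau positive reference value (`MSD_ref`).
#' @return the normalised `dl_msd_profile`, with attribute
#'   `reference_plateau`.
#' @export
normalize_profile <- function(profile, reference_plateau) {
  if (!is.numeric(reference_plateau) || reference_plateau <= 0)
    stopf("reference_plateau must be positive")
  profile$msd <- profile$msd / reference_plateau
  profile$sem <- profile$sem / reference_plateau
  attr(profile, "reference_plateau") <- reference_plateau
  profile
}

#' @export
print.dl_msd_profile <- function(x, ...) {
  cat(sprintf("<dl_msd_profile> N = %d, %d conformations, s in [%d, %d]\n",
              attr(x, "n_monomers"), attr(x, "n_conformations"),
              min(x$s), max(x$s)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more separations\n", nrow(x) - 6))
  invisible(x)
}

#' @export
plot.dl_msd_profile <- function(x, log = "xy", ...) {
  keep <- x$s > 0 & x$msd > 0
  plot(x$s[keep], x$msd[keep], log = log, xlab = "contour separation s (monomers)",
       ylab = expression("<R"^2 * "> (lattice units"^2 * ")"), pch = 16, ...)
  ok <- keep & !is.na(x$sem) & x$msd - x$sem > 0
  segments(x$s[ok], x$msd[ok] - x$sem[ok], x$s[ok], x$msd[ok] + x$sem[ok])
  invisible(x)
}

#' Plateau-compaction heat map over looping-parameter space
#'
#' Runs the full protocol for every `(p_short, p_long)` grid cell and records
#' the MSD plateau level - the compaction landscape in looping-parameter
#' space. Cell seeds are derived by hashing the base seed with the cell
#' coordinates (and replicate index), so scans are reproducible and
#' order-independent; with an output file the scan is resumable (completed
#' cells are skipped) and per-cell failures are recorded without stopping the
#' scan.
#'
#' @param p_short_values,p_long_values grid axis values.
#' @param N monomer count.
#' @param lattice a [lattice_params()] object.
#' @param looping base [looping_params()]; each cell overrides `p_short` and
#'   `p_long`.
#' @param protocol a [protocol_params()] object; its `seed` is the scan base
#'   seed.
#' @param layout domain layout for domain-mode scans.
#' @param n_reps independent replicate runs per cell (plateaus averaged).
#' @param file optional path of a long-format TSV manifest
#'   (`p_short, p_long, rep, plateau, n_conformations, seed`); used both for
#'   incremental output and for resuming.
#' @return an object of class `dl_heatmap`: `p_short`, `p_long`, the plateau
#'   `matrix` (rows = p_short, columns = p_long) and the `manifest` data
#'   frame.
#' @export
heatmap_scan <- function(p_short_values, p_long_values, N,
                         lattice = lattice_params(64),
                         looping = looping_params(),
                         protocol = protocol_params(), layout = NULL,
                         n_reps = 1L, file = NULL) {
  cells <- expand.grid(p_short = p_short_values, p_long = p_long_values,
                       rep = seq_len(n_reps))
  done <- NULL
  if (!is.null(file) && file.exists(file)) {
    done <- utils::read.table(file, header = TRUE, sep = "\t")
  }
  rows <- vector("list", nrow(cells))
  tail_s <- seq(ceiling(2 * N / 3), N - 1)
  for (r in seq_len(nrow(cells))) {
    ps <- cells$p_short[r]; pl <- cells$p_long[r]; rep_i <- cells$rep[r]
    if (!is.null(done) &&
        any(abs(done$p_short - ps) < 1e-12 & abs(done$p_long - pl) < 1e-12 &
            done$rep == rep_i)) {
      hit <- which(abs(done$p_short - ps) < 1e-12 &
                   abs(done$p_long - pl) < 1e-12 & done$rep == rep_i)[1]
      rows[[r]] <- done[hit, , drop = FALSE]
      next
    }
    cell_seed <- derive_seed(protocol$seed, ps, pl, rep_i)
    cell_loop <- looping
    cell_loop$p_short <- ps; cell_loop$p_long <- pl
    cell_prot <- protocol
    cell_prot$seed <- cell_seed
    plateau <- tryCatch({
      ens <- run_protocol(N, lattice, cell_loop, layout, cell_prot)
      plateau_level(msd_profile(ens, separations = tail_s))
    }, error = function(e) {
      warning(sprintf("cell (p_short = %g, p_long = %g, rep %d) failed: %s",
                      ps, pl, rep_i, conditionMessage(e)), call. = FALSE)
      NA_real_
    })
    row <- data.frame(p_short = ps, p_long = pl, rep = rep_i,
                      plateau = plateau,
                      n_conformations = protocol$n_conformations,
                      seed = cell_seed)
    rows[[r]] <- row
    if (!is.null(file)) {
      frow <- row
      frow$plateau <- sprintf("%.17g", frow$plateau)  # exact float round-trip
      utils::write.table(frow, file, sep = "\t", row.names = FALSE,
                         col.names = !file.exists(file), append = file.exists(file),
                         quote = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (all(is.na(manifest$plateau))) stopf("every heat-map cell failed")
  agg <- stats::aggregate(plateau ~ p_short + p_long, data = manifest,
                          FUN = mean, na.action = stats::na.omit)
  mat <- matrix(NA_real_, length(p_short_values), length(p_long_values),
                dimnames = list(p_short = format(p_short_values),
                                p_long = format(p_long_values)))
  for (r in seq_len(nrow(agg))) {
    i <- match(TRUE, abs(p_short_values - agg$p_short[r]) < 1e-12)
    j <- match(TRUE, abs(p_long_values - agg$p_long[r]) < 1e-12)
    mat[i, j] <- agg$plateau[r]
  }
  structure(list(p_short = p_short_values, p_long = p_long_values,
                 plateau = mat, manifest = manifest),
            class = "dl_heatmap")
}

#' @export
print.dl_heatmap <- function(x, ...) {
  cat(sprintf("<dl_heatmap> %d x %d (p_short x p_long) plateau grid\n",
              length(x$p_short), length(x$p_long)))
  print(round(x$plateau, 2))
  invisible(x)
}

#' @export
plot.dl_heatmap <- function(x, ...) {
  image(seq_along(x$p_short), seq_along(x$p_long), x$plateau, axes = FALSE,
        xlab = expression(p[short]), ylab = expression(p[long]),
        main = "MSD plateau (compaction) in looping-parameter space", ...)
  axis(1, seq_along(x$p_short), labels = format(x$p_short))
  axis(2, seq_along(x$p_long), labels = format(x$p_long))
  invisible(x)
}

#' Mean long-range loop count of an ensemble
#'
#' Mean over conformations of the number of long-range loop bonds
#' (`|i - j| > cutoff`), with its standard error - the quantity whose
#' indirect increase under short-range loop depletion drives compaction.
#'
#' @param ensemble a `dl_ensemble` (or list of conformations).
#' @param cutoff contour-separation threshold; `NULL` resolves to
#'   `round(0.05 * N)`.
#' @return a list with `mean`, `sem`, and the per-conformation counts
#'   `n_long`.
#' @export
mean_long_loop_count <- function(ensemble, cutoff = NULL) {
  confs <- if (inherits(ensemble, "dl_ensemble")) ensemble$conformations
           else ensemble
  if (length(confs) == 0) stopf("empty ensemble")
  nl <- vapply(confs, function(cf) as.numeric(loop_stats(cf, cutoff)$n_long), 0)
  list(mean = mean(nl),
       sem = if (length(nl) > 1) sd(nl) / sqrt(length(nl)) else NA_real_,
       n_long = nl)
}
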