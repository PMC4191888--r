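# Plain-text conformation snapshots and XYZ export.

#' Write / read a conformation snapshot
#'
#' Plain-text format: one header line `N L mcs_clock`, then one line per
#' monomer `index x y z` (1-based indices, unwrapped lattice coordinates),
#' then one line per loop bond `i j expires_at`. Monomer and bond lines are
#' distinguished by field count (4 vs 3).
#'
#' @param conf a `dl_conformation`.
#' @param path file path.
#' @return `write_conformation` returns `path` invisibly;
#'   `read_conformation` the parsed `dl_conformation`.
#' @export
write_conformation <- function(conf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d %.0f", conf$N, conf$L, conf$mcs_clock), con)
  pos <- conf$positions
  writeLines(sprintf("%d %d %d %d", seq_len(conf$N),
                     pos[, 1], pos[, 2], pos[, 3]), con)
  lb <- conf$loop_bonds
  if (nrow(lb) > 0)
    writeLines(sprintf("%d %d %d", lb[, 1], lb[, 2], lb[, 3]), con)
  invisible(path)
}

#' @rdname write_conformation
#' @export
read_conformation <- function(path) {
  lines <- readLines(path)
  hdr <- as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 3) stopf("%s: malformed header (want 'N L mcs_clock')", path)
  N <- as.integer(hdr[1])
  if (length(lines) < 1 + N) stopf("%s: truncated snapshot", path)
  body <- strsplit(trimws(lines[-1]), "\\s+")
  nf <- lengths(body)
  mono <- body[nf == 4]
  if (length(mono) != N) stopf("%s: expected %d monomer lines, found %d",
                               path, N, length(mono))
  m <- matrix(as.integer(unlist(mono)), ncol = 4, byrow = TRUE)
  pos <- m[order(m[, 1]), 2:4, drop = FALSE]
  bonds <- body[nf == 3]
  lb <- if (length(bonds) > 0)
    matrix(as.integer(unlist(bonds)), ncol = 3, byrow = TRUE)
  new_conformation(pos, lb, hdr[3], hdr[2])
}

#' Export a conformation as XYZ
#'
#' For visualisation in molecular viewers: element tags encode domain
#' membership (`C` for looped-domain monomers, `N` for linkers, `C`
#' throughout without a layout).
#'
#' @param conf a `dl_conformation`.
#' @param path file path.
#' @param layout optional [build_domain_layout()] result for element tags.
#' @export
write_xyz <- function(conf, path, layout = NULL) {
  elem <- rep("C", conf$N)
  if (!is.null(layout)) elem[layout$domain_id == 0] <- "N"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("%d", conf$N),
               sprintf("dynloop conformation, mcs = %.0f", conf$mcs_clock)), con)
  pos <- conf$positions
  writeLines(sprintf("%s %d %d %d", elem, pos[, 1], pos[, 2], pos[, 3]), con)
  invisible(path)
}

#' Write / read an MSD profile as TSV
#'
#' Columns `s`, `msd`, `sem`, `n_pairs`; the header comment line carries the
#' `n_monomers` / `n_conformations` attributes needed by [plateau_level()].
#'
#' @param profile a `dl_msd_profile`.
#' @param path file path.
#' @export
write_msd_profile <- function(profile, path) {
  con <- file(path, "w")
  writeLines(sprintf("# n_monomers=%d n_conformations=%d",
                     attr(profile, "n_monomers"),
                     attr(profile, "n_conformations")), con)
  close(con)
  suppressWarnings(
    utils::write.table(as.data.frame(profile), path, sep = "\t",
                       row.names = FALSE, quote = FALSE, append = TRUE))
  invisible(path)
}

#' Write a heat map as matrix-form TSV
#'
#' The plateau matrix with `p_short` values as row names and `p_long` values
#' as column headers; the long-format companion (one row per cell with seed
#' and replicate) is produced by [heatmap_scan()]'s `file` argument.
#'
#' @param hm a `dl_heatmap`.
#' @param path file path.
#' @export
write_heatmap <- function(hm, path) {
  m <- as.data.frame(hm$plateau)
  names(m) <- format(hm$p_long)
  out <- cbind(p_short = format(hm$p_short), m)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_msd_profile
#' @export
read_msd_profile <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- regmatches(hdr, gregexpr("[a-z_]+=[0-9]+", hdr))[[1]]
  vals <- setNames(as.integer(sub(".*=", "", meta)), sub("=.*", "", meta))
  out <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  attr(out, "n_monomers") <- unname(vals["n_monomers"])
  attr(out, "n_conformations") <- unname(vals["n_conformations"])
  class(out) <- c("dl_msd_profile", "data.frame")
  out
}
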