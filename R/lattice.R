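# Lattice polymer: bond fluctuation representation, local moves, validation.

#' Lattice parameters
#'
#' The simulation lattice is a periodic cube of edge `L` sites. `L` is chosen
#' large relative to the polymer so that periodic images never interact; the
#' full-scale default is `L = 500`, test presets use `L = 64`.
#'
#' @param L lattice edge length in sites (`>= 16`).
#' @param periodic boundary flag; always `TRUE` (kept for config round-trips).
#' @return an object of class `dl_lattice`.
#' @export
lattice_params <- function(L = 500L, periodic = TRUE) {
  L <- as.integer(L)
  if (is.na(L) || L < 16L) stopf("L must be an integer >= 16, got %s", L)
  if (!isTRUE(periodic)) stopf("only periodic boundaries are supported")
  structure(list(L = L, periodic = TRUE), class = "dl_lattice")
}

#' Allowed bond vectors of the 3D bond fluctuation method
#'
#' The classic three-dimensional bond fluctuation set: all integer vectors of
#' squared length 4, 5, 6, 9 or 10 (108 vectors; the permutation/sign-flip
#' classes of (2,0,0), (2,1,0), (2,1,1), (2,2,1), (3,0,0), (3,1,0)). Squared
#' length 8 and anything above 10 are excluded, which together with single
#' unit-step moves makes chain crossing impossible.
#'
#' @return an integer matrix with one allowed vector per row.
#' @export
allowed_bond_vectors <- function() {
  v <- cpp_allowed_bond_vectors()
  colnames(v) <- c("dx", "dy", "dz")
  v
}

# TRUE for separation vectors that are legal bonds.
is_allowed_vector <- function(d) {
  s2 <- rowSums(d^2)
  s2 %in% c(4, 5, 6, 9, 10) & apply(abs(d) <= 3, 1, all)
}

new_conformation <- function(positions, loop_bonds, mcs_clock, L) {
  storage.mode(positions) <- "integer"
  colnames(positions) <- c("x", "y", "z")
  if (is.null(loop_bonds) || nrow(loop_bonds) == 0) {
    loop_bonds <- matrix(integer(0), 0, 3)
  }
  storage.mode(loop_bonds) <- "integer"
  colnames(loop_bonds) <- c("i", "j", "expires_at")
  structure(
    list(positions = positions, loop_bonds = loop_bonds,
         mcs_clock = as.numeric(mcs_clock), L = as.integer(L),
         N = nrow(positions)),
    class = "dl_conformation")
}

#' Construct a conformation from raw parts
#'
#' Builds a `dl_conformation` from a position matrix and an optional loop-bond
#' matrix - mainly for constructing reference geometries (straight rods,
#' hand-placed bonds) in analyses and tests. Set `check = FALSE` to build a
#' deliberately invalid conformation, e.g. to exercise
#' [validate_conformation()].
#'
#' @param positions integer `N x 3` matrix of unwrapped lattice positions.
#' @param loop_bonds optional integer matrix with columns `i`, `j`,
#'   `expires_at`.
#' @param mcs_clock elapsed MCS.
#' @param L lattice edge length.
#' @param check validate the result (default) and fail on violations.
#' @return a `dl_conformation`.
#' @export
conformation <- function(positions, loop_bonds = NULL, mcs_clock = 0, L = 500L,
                         check = TRUE) {
  out <- new_conformation(as.matrix(positions), loop_bonds, mcs_clock, L)
  if (check) {
    bad <- validate_conformation(out)
    if (length(bad) > 0)
      stopf("invalid conformation: %s", paste(bad, collapse = "; "))
  }
  out
}

#' Initialise a random self-avoiding walk
#'
#' Grows an `N`-monomer self-avoiding chain on the lattice by sequential
#' placement with random allowed bond vectors; a trapped growth restarts from
#' scratch, and repeated failure (a lattice too dense for the chain) is an
#' explicit error. Monomers occupy 2x2x2 cubes of lattice sites; positions are
#' the cube corners and are kept unwrapped (only occupancy checks wrap).
#'
#' @param N monomer count (`>= 2`).
#' @param lattice a [lattice_params()] object (or bare edge length).
#' @param seed integer seed; the walk is reproducible given the seed.
#' @param max_restarts growth restarts allowed before failing.
#' @return a `dl_conformation` with no loop bonds and `mcs_clock = 0`.
#' @export
init_saw <- function(N, lattice = lattice_params(), seed, max_restarts = 200L) {
  if (is.numeric(lattice)) lattice <- lattice_params(lattice)
  N <- as.integer(N)
  if (is.na(N) || N < 2L) stopf("N must be an integer >= 2")
  pos <- cpp_init_saw(N, lattice$L, as.numeric(seed), as.integer(max_restarts))
  new_conformation(pos, NULL, 0, lattice$L)
}

#' @export
print.dl_conformation <- function(x, ...) {
  cat(sprintf(
    "<dl_conformation> N = %d monomers, L = %d, mcs_clock = %s, %d loop bond%s\n",
    x$N, x$L, format(x$mcs_clock, big.mark = ","), nrow(x$loop_bonds),
    if (nrow(x$loop_bonds) == 1) "" else "s"))
  invisible(x)
}

#' Attempt a single local move
#'
#' One elementary Monte Carlo move: a monomer is moved by one lattice unit in
#' one of the six axis directions. The move is accepted iff the entering sites
#' of its 2x2x2 cube are free (excluded volume) and every bond incident to the
#' monomer - backbone and loop - remains an allowed bond vector; otherwise the
#' conformation is unchanged. By default monomer and direction are drawn
#' uniformly from the seeded stream; either can be forced for testing.
#'
#' @param conf a `dl_conformation`.
#' @param monomer optional monomer index (1-based) to force.
#' @param direction optional direction in 1..6 = (+x, -x, +y, -y, +z, -z).
#' @param seed seed for the random choices when not forced.
#' @return a list with elements `moved` (logical), `monomer`, `direction`,
#'   and `conformation` (the possibly updated `dl_conformation`).
#' @export
attempt_move <- function(conf, monomer = NULL, direction = NULL, seed = NULL) {
  res <- cpp_attempt_move(conf$positions, conf$loop_bonds, conf$L,
                          if (is.null(monomer)) 0L else as.integer(monomer),
                          if (is.null(direction)) 0L else as.integer(direction),
                          auto_seed(seed))
  out <- new_conformation(res$positions, conf$loop_bonds, conf$mcs_clock, conf$L)
  list(moved = res$moved, monomer = res$monomer, direction = res$direction,
       conformation = out)
}

# Shared driver behind mcs_sweep / attempt_loop_updates / run_protocol phases.
run_engine <- function(conf, n_mcs, looping = NULL, layout = NULL, seed,
                       moves_per_mcs = conf$N, save_interval = 0,
                       max_saves = 0L, rg_interval = 0, log_events = FALSE) {
  lp <- looping %||% looping_params(mode = "homogeneous", p_homogeneous = 0)
  mode <- match(lp$mode, c("homogeneous", "uniform_adapted", "domain_adapted")) - 1L
  cutoff <- resolve_cutoff(lp, conf$N)
  dom <- integer(0)
  if (lp$mode == "domain_adapted") {
    if (is.null(layout)) stopf("domain_adapted looping requires a domain layout")
    if (layout$N != conf$N)
      stopf("layout is for N = %d but conformation has N = %d", layout$N, conf$N)
    dom <- layout$domain_id
  }
  res <- cpp_run(conf$positions, conf$loop_bonds, conf$L,
                 as.numeric(n_mcs), conf$mcs_clock,
                 as.integer(moves_per_mcs), mode,
                 lp$p_short, lp$p_long, lp$p_homogeneous %||% 0, cutoff,
                 dom, isTRUE(lp$linkers_inert), lp$t_bond,
                 as.integer(lp$max_bonds_per_monomer), as.numeric(seed),
                 as.numeric(save_interval), as.integer(max_saves),
                 as.numeric(rg_interval), isTRUE(log_events))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run Monte Carlo sweeps
#'
#' One Monte Carlo step (MCS) is `N` single-monomer move attempts, after which
#' the clock advances by one and - when looping parameters are supplied - the
#' loop bonds are updated: expired bonds dissociate, then formation trials run
#' over all currently proximal unbonded pairs (see [attempt_loop_updates()]).
#'
#' @param conf a `dl_conformation`.
#' @param n_mcs number of sweeps to run.
#' @param looping optional [looping_params()]; `NULL` runs plain self-avoiding
#'   dynamics with no loop updates.
#' @param layout a [build_domain_layout()] result, required in domain mode.
#' @param seed seed for this call's random stream.
#' @param log_events record a formation/dissociation event log.
#' @param moves_per_mcs move attempts per MCS; defaults to `N`. Zero gives a
#'   pure loop-update pass.
#' @return the updated `dl_conformation`, with attributes `attempts`,
#'   `accepts` and (if requested) `events` (a data frame with columns
#'   mcs, event, i, j, lifetime).
#' @export
mcs_sweep <- function(conf, n_mcs = 1, looping = NULL, layout = NULL,
                      seed = NULL, log_events = FALSE,
                      moves_per_mcs = conf$N) {
  res <- run_engine(conf, n_mcs, looping, layout, auto_seed(seed),
                    moves_per_mcs = moves_per_mcs, log_events = log_events)
  out <- new_conformation(res$positions, res$loop_bonds, res$mcs_clock, conf$L)
  attr(out, "attempts") <- res$attempts
  attr(out, "accepts") <- res$accepts
  if (log_events) attr(out, "events") <- events_frame(res$events)
  out
}

events_frame <- function(ev) {
  data.frame(mcs = ev$mcs,
             event = c("form", "break")[ev$event],
             i = ev$i, j = ev$j, lifetime = ev$lifetime)
}

#' Validate a conformation
#'
#' Checks every structural invariant: pairwise excluded volume of the 2x2x2
#' monomer cubes (on the wrapped lattice), backbone and loop-bond separation
#' vectors in the allowed set, loop bonds connecting only non-adjacent
#' monomers with in-range indices. All violations are reported, not just the
#' first.
#'
#' @param conf a `dl_conformation`.
#' @return an object of class `dl_validation`: a character vector of violation
#'   messages (zero-length iff the conformation is valid), with a `details`
#'   attribute holding the offending pairs.
#' @export
validate_conformation <- function(conf) {
  msgs <- character(0)
  details <- list()
  pos <- conf$positions
  N <- nrow(pos)
  L <- conf$L

  # excluded volume: all 8N wrapped cube sites must be distinct
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  sites <- do.call(rbind, lapply(seq_len(8), function(k) {
    sweep(pos, 2, -corners[k, ], "+") %% L
  }))
  key <- (sites[, 1] * L + sites[, 2]) * L + sites[, 3]
  owner <- rep(seq_len(N), 8)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    bad <- split(owner[dup], key[dup])
    pairs <- unique(do.call(rbind, lapply(bad, function(o) {
      o <- sort(unique(o))
      if (length(o) >= 2) t(utils::combn(o, 2)) else NULL
    })))
    msgs <- c(msgs, sprintf("excluded volume violated for %d monomer pair(s)",
                            nrow(pairs)))
    details$overlap_pairs <- pairs
  }

  if (N >= 2) {
    bb <- diff(pos)
    ok <- is_allowed_vector(bb)
    if (!all(ok)) {
      msgs <- c(msgs, sprintf("%d backbone bond(s) outside the allowed vector set",
                              sum(!ok)))
      details$bad_backbone <- which(!ok)
    }
  }

  lb <- conf$loop_bonds
  if (nrow(lb) > 0) {
    if (any(lb[, "i"] < 1 | lb[, "j"] > N)) {
      msgs <- c(msgs, "loop bond indices out of range")
      details$bad_index <- lb[lb[, "i"] < 1 | lb[, "j"] > N, , drop = FALSE]
    }
    adj <- abs(lb[, "j"] - lb[, "i"]) < 2
    if (any(adj)) {
      msgs <- c(msgs, sprintf("%d loop bond(s) between adjacent monomers", sum(adj)))
      details$adjacent_bonds <- lb[adj, , drop = FALSE]
    }
    d <- pos[lb[, "j"], , drop = FALSE] - pos[lb[, "i"], , drop = FALSE]
    ok <- is_allowed_vector(d)
    if (!all(ok)) {
      msgs <- c(msgs, sprintf("%d loop bond(s) outside the allowed vector set",
                              sum(!ok)))
      details$bad_loop_vectors <- lb[!ok, , drop = FALSE]
    }
  }

  structure(msgs, details = details, class = "dl_validation")
}

#' @export
print.dl_validation <- function(x, ...) {
  if (length(x) == 0) cat("conformation valid: no violations\n")
  else cat(paste0("- ", unclass(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Is a conformation valid?
#' @param conf a `dl_conformation`.
#' @return `TRUE` iff [validate_conformation()] reports nothing.
#' @export
is_valid_conformation <- function(conf) length(validate_conformation(conf)) == 0

#' Spatially proximal monomer pairs
#'
#' All unordered non-adjacent pairs whose separation vector is itself an
#' allowed bond vector - the loop-formation candidates, since any larger
#' proximity cutoff would admit unrepresentable bonds. The default method
#' queries the occupancy lattice (spatial binning); `method = "brute"` is the
#' O(N^2) all-pairs scan the binned query must reproduce.
#'
#' @param conf a `dl_conformation`.
#' @param method `"binned"` (occupancy lookup) or `"brute"` (all-pairs scan).
#' @return an integer matrix with columns `i`, `j` (`i < j - 1`), ordered by
#'   `(i, j)`.
#' @export
proximal_pairs <- function(conf, method = c("binned", "brute")) {
  method <- match.arg(method)
  if (method == "binned") {
    out <- cpp_proximal_pairs(conf$positions, conf$L)
  } else {
    pos <- conf$positions
    N <- nrow(pos)
    ii <- integer(0); jj <- integer(0)
    for (i in seq_len(N - 2)) {
      js <- (i + 2):N
      d <- pos[js, , drop = FALSE] - matrix(pos[i, ], length(js), 3, byrow = TRUE)
      hit <- is_allowed_vector(d)
      ii <- c(ii, rep(i, sum(hit))); jj <- c(jj, js[hit])
    }
    out <- cbind(i = ii, j = jj)
  }
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}
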