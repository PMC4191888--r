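# Loop dynamics: formation/dissociation rules of the Dynamic Loop model.

#' Looping parameters
#'
#' Control parameters of the Dynamic Loop bond dynamics. In
#' `"uniform_adapted"` mode (the adapted DL model) a proximal non-adjacent
#' pair `(i, j)` forms a bond with probability `p_short` when the contour
#' separation `|i - j|` is at most `short_cutoff` and `p_long` otherwise. In
#' `"domain_adapted"` mode the probability is `p_short` for pairs inside the
#' same looped domain, `p_long` for pairs in different looped domains and 0
#' when either monomer is on a linker (set `linkers_inert = FALSE` to let
#' linker monomers participate in long-range looping instead).
#' `"homogeneous"` mode applies a single probability `p_homogeneous` to all
#' eligible pairs, as in the first equilibration phase.
#'
#' A formed bond receives a lifetime drawn from a Poisson distribution with
#' mean `t_bond` MCS (full-scale default 8000) and dissociates when its
#' absolute expiry time is reached. Backbone bonds never break.
#'
#' @param mode one of `"uniform_adapted"`, `"domain_adapted"`, `"homogeneous"`.
#' @param p_short,p_long formation probabilities per eligible encounter and
#'   MCS, in `[0, 1]`.
#' @param short_cutoff contour-separation threshold in monomers separating
#'   short- from long-range loops; `NULL` resolves to `round(0.05 * N)` at run
#'   time (short loops span less than 5 percent of the chain; 50 for the
#'   full-scale 1050-monomer polymer).
#' @param block_size monomers per domain/linker block in domain mode.
#' @param t_bond mean loop-bond lifetime in MCS.
#' @param p_homogeneous single probability for homogeneous mode.
#' @param max_bonds_per_monomer loop bonds a monomer may hold at once; the
#'   default 1 treats each monomer as a single binding site.
#' @param linkers_inert in domain mode, whether linker monomers are excluded
#'   from all looping (default) or loop at `p_long`.
#' @return an object of class `dl_looping`.
#' @export
looping_params <- function(mode = c("uniform_adapted", "domain_adapted",
                                    "homogeneous"),
                           p_short = 0.03, p_long = 0.03, short_cutoff = NULL,
                           block_size = 50L, t_bond = 8000,
                           p_homogeneous = NULL, max_bonds_per_monomer = 1L,
                           linkers_inert = TRUE) {
  mode <- match.arg(mode)
  for (p in c(p_short, p_long, p_homogeneous))
    if (!is.null(p) && (p < 0 || p > 1))
      stopf("looping probabilities must lie in [0, 1]")
  if (!is.null(short_cutoff) && short_cutoff < 2)
    stopf("short_cutoff must be >= 2")
  if (block_size < 2) stopf("block_size must be >= 2")
  if (t_bond < 0) stopf("t_bond must be >= 0")
  if (max_bonds_per_monomer < 1) stopf("max_bonds_per_monomer must be >= 1")
  structure(
    list(mode = mode, p_short = p_short, p_long = p_long,
         short_cutoff = if (is.null(short_cutoff)) NULL else as.integer(short_cutoff),
         block_size = as.integer(block_size), t_bond = t_bond,
         p_homogeneous = p_homogeneous,
         max_bonds_per_monomer = as.integer(max_bonds_per_monomer),
         linkers_inert = isTRUE(linkers_inert)),
    class = "dl_looping")
}

resolve_cutoff <- function(looping, N) {
  if (!is.null(looping$short_cutoff)) return(looping$short_cutoff)
  max(2L, as.integer(round(0.05 * N)))
}

#' Build an alternating domain/linker layout
#'
#' Assigns monomers to alternating blocks of `b` monomers, beginning and
#' ending with a linker: for `N = 1050`, `b = 50` this is the 21-block layout
#' of 10 looped (highly active) domains interspersed among 11 linker (lowly
#' active) blocks.
#'
#' @param N monomer count; must equal `b * (2k + 1)` for integer `k >= 1`.
#' @param b block size in monomers.
#' @return an object of class `dl_domain_layout`: a list with `block` (factor
#'   of block labels per monomer), `domain_id` (integer per monomer, 0 on
#'   linkers, 1..k inside looped domains), `n_domains`, `n_linkers`, `N`, `b`.
#' @export
build_domain_layout <- function(N, b) {
  N <- as.integer(N); b <- as.integer(b)
  if (b < 2) stopf("block size b must be >= 2")
  nblocks <- N / b
  if (N %% b != 0 || nblocks %% 2 != 1 || nblocks < 3)
    stopf(paste("N must equal b * (2k + 1) for integer k >= 1 so the",
                "alternating layout closes on a linker; got N = %d, b = %d"),
          N, b)
  k <- (nblocks - 1) / 2
  block_idx <- rep(seq_len(nblocks), each = b)
  is_domain <- block_idx %% 2 == 0          # blocks 2, 4, ... are domains
  domain_id <- integer(N)
  domain_id[is_domain] <- (block_idx[is_domain]) / 2
  labels <- ifelse(is_domain, paste0("domain_", block_idx / 2),
                   paste0("linker_", (block_idx + 1) / 2))
  structure(
    list(block = factor(labels, levels = unique(labels)),
         domain_id = domain_id, n_domains = as.integer(k),
         n_linkers = as.integer(k + 1), N = N, b = b),
    class = "dl_domain_layout")
}

#' @export
print.dl_domain_layout <- function(x, ...) {
  cat(sprintf("<dl_domain_layout> N = %d, block size %d: %d looped domains, %d linkers\n",
              x$N, x$b, x$n_domains, x$n_linkers))
  invisible(x)
}

#' Loop formation probability for a monomer pair
#'
#' The per-encounter bond formation probability for a non-adjacent pair under
#' the current rule; see [looping_params()] for the three modes. Vectorised
#' over `i` and `j`.
#'
#' @param i,j monomer indices (1-based), `|i - j| >= 2`.
#' @param params a [looping_params()] object.
#' @param layout a [build_domain_layout()] result (domain mode only).
#' @param N polymer length, needed only when `short_cutoff` is unresolved.
#' @return numeric vector of probabilities.
#' @export
looping_probability <- function(i, j, params, layout = NULL, N = NULL) {
  if (any(abs(i - j) < 2)) stopf("looping requires non-adjacent monomers (|i - j| >= 2)")
  switch(params$mode,
    homogeneous = rep(params$p_homogeneous %||% 0, length(i)),
    uniform_adapted = {
      cutoff <- params$short_cutoff %||%
        resolve_cutoff(params, N %||% stopf("supply N to resolve short_cutoff"))
      ifelse(abs(i - j) <= cutoff, params$p_short, params$p_long)
    },
    domain_adapted = {
      if (is.null(layout)) stopf("domain_adapted mode requires a domain layout")
      di <- layout$domain_id[i]; dj <- layout$domain_id[j]
      p <- ifelse(di == dj, params$p_short, params$p_long)
      if (params$linkers_inert) p[di == 0 | dj == 0] <- 0
      else p[di == 0 | dj == 0] <- params$p_long
      p[di == 0 & dj == 0 & !params$linkers_inert] <- params$p_long
      p
    })
}

#' Sample loop-bond lifetimes
#'
#' Draws from the Poisson distribution with mean `t_bond` MCS used to set
#' bond expiry times, from the same generator family as the simulation engine.
#'
#' @param t_bond mean lifetime in MCS (`>= 0`; 0 is the degenerate
#'   point mass at 0).
#' @param n number of draws.
#' @param seed integer seed; `NULL` derives one from R's RNG.
#' @return integer vector of lifetimes in MCS.
#' @export
sample_lifetime <- function(t_bond, n = 1L, seed = NULL) {
  if (t_bond < 0) stopf("t_bond must be >= 0")
  cpp_poisson_draws(as.integer(n), as.numeric(t_bond), auto_seed(seed))
}

#' Run one loop-update pass
#'
#' The per-MCS bond bookkeeping, run once with no move attempts: the clock
#' advances by one MCS, bonds whose expiry time has been reached dissociate,
#' then each currently proximal unbonded pair (both endpoints below
#' `max_bonds_per_monomer`) undergoes a Bernoulli formation trial at its
#' [looping_probability()], in seeded random order; a formed bond expires at
#' `mcs_clock + ` a [sample_lifetime()] draw.
#'
#' @inheritParams mcs_sweep
#' @param params a [looping_params()] object.
#' @return a list with `conformation` (updated) and `events` (data frame with
#'   columns mcs, event, i, j, lifetime).
#' @export
attempt_loop_updates <- function(conf, params, layout = NULL, seed = NULL) {
  res <- run_engine(conf, 1, params, layout, auto_seed(seed),
                    moves_per_mcs = 0L, log_events = TRUE)
  list(conformation = new_conformation(res$positions, res$loop_bonds,
                                       res$mcs_clock, conf$L),
       events = events_frame(res$events))
}

#' Loop-bond counts and size histogram
#'
#' Counts short-range (`|i - j| <= cutoff`) and long-range loop bonds of a
#' conformation and tabulates loop sizes.
#'
#' @param conf a `dl_conformation`.
#' @param cutoff contour-separation threshold; `NULL` resolves to
#'   `round(0.05 * N)`.
#' @return a list with `n_short`, `n_long`, and `histogram` (a table of loop
#'   spans `|i - j|`; empty when there are no bonds).
#' @export
loop_stats <- function(conf, cutoff = NULL) {
  cutoff <- cutoff %||% max(2L, as.integer(round(0.05 * conf$N)))
  lb <- conf$loop_bonds
  if (nrow(lb) == 0)
    return(list(n_short = 0L, n_long = 0L, histogram = table(integer(0))))
  span <- abs(lb[, "j"] - lb[, "i"])
  list(n_short = sum(span <= cutoff), n_long = sum(span > cutoff),
       histogram = table(span))
}
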