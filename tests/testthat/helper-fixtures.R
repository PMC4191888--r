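# Shared fixtures, all built in code.

# A straight rod along x with bond vector (2,0,0).
make_rod <- function(N, L = 500L, bonds = NULL) {
  pos <- cbind(2L * (seq_len(N) - 1L) + 10L, 10L, 10L)
  conformation(pos, loop_bonds = bonds, L = L, check = is.null(bonds))
}

# A modest equilibrated conformation with active loops, cached per session.
equilibrated_conf <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      conf <- init_saw(105, lattice_params(64), seed = 42)
      cache <<- mcs_sweep(conf, 2000,
                          looping = looping_params(p_short = 0.1, p_long = 0.04),
                          seed = 43)
    }
    cache
  }
})

# Small production ensemble shared by observable tests.
small_ensemble <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(run_protocol(
        105, lattice_params(64),
        looping_params(p_short = 0.05, p_long = 0.03),
        protocol = protocol_params(2e4, 1e5, 500, 15, seed = 7)))
    }
    cache
  }
})

# Independent brute-force MSD oracle: O(N^2) per conformation, pooled pairs.
oracle_msd <- function(confs, separations) {
  N <- confs[[1]]$N
  vapply(separations, function(s) {
    if (s == 0) return(0)
    vals <- unlist(lapply(confs, function(cf) {
      sapply(seq_len(N - s), function(i)
        sum((cf$positions[i + s, ] - cf$positions[i, ])^2))
    }))
    mean(vals)
  }, 0)
}

# Independent Rg^2 oracle via the pairwise-distance identity:
# Rg^2 = (1 / 2N^2) * sum_ij |r_i - r_j|^2.
oracle_rg2 <- function(conf) {
  pos <- conf$positions
  d2 <- as.matrix(stats::dist(pos))^2
  sum(d2) / (2 * nrow(pos)^2)
}
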