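# Simulation protocol: SAW init, two-phase equilibration, production
# sampling, and independence control via the Rg^2 autocorrelation time.

#' Squared radius of gyration
#'
#' Mean squared distance of the monomers from their centroid, in lattice
#' units squared. Positions are stored unwrapped along the backbone, so no
#' periodic-image correction is needed.
#'
#' @param conf a `dl_conformation`.
#' @return numeric scalar.
#' @export
rg_squared <- function(conf) {
  pos <- conf$positions
  ctr <- colMeans(pos)
  mean(rowSums(sweep(pos, 2, ctr)^2))
}

#' Autocorrelation time of a time series
#'
#' Estimates the exponential decay time of the normalised autocorrelation
#' function, as used on the Rg^2 series to decide when two saved
#' conformations are independent (spacing of at least `5 * tau_ac` MCS). The
#' fit is a log-linear regression of the autocorrelation over the initial
#' decay, down to correlation 0.05; a series that decorrelates within one
#' sampling interval returns `dt / 2`.
#'
#' @param series numeric vector sampled at regular intervals (>= 50 points,
#'   non-constant).
#' @param dt sampling interval in MCS.
#' @return `tau_ac` in MCS, with attributes `acf` (the correlations used) and
#'   `lags_used`.
#' @export
autocorrelation_time <- function(series, dt = 1) {
  n <- length(series)
  if (n < 50) stopf("autocorrelation fit needs >= 50 samples, got %d", n)
  if (stats::sd(series) == 0) stopf("series is constant; autocorrelation undefined")
  rho <- as.numeric(stats::acf(series, lag.max = max(2L, n %/% 3),
                               plot = FALSE, demean = TRUE)$acf)[-1]
  k <- which(rho <= 0.05)
  kmax <- if (length(k) == 0) length(rho) else max(1L, min(k) - 1L)
  lags <- seq_len(kmax)
  r <- rho[lags]
  keep <- r > 0
  if (!any(keep)) {
    tau <- dt / 2
    attr(tau, "acf") <- rho[1]
    attr(tau, "lags_used") <- integer(0)
    return(tau)
  }
  # WLS in log space: the sampling noise of the autocorrelation is roughly
  # lag-independent, so var(log rho) ~ 1/rho^2 and the optimal weights are
  # rho^2; equal weights would let the noisy tail dominate the fit
  fit <- stats::lm(log(r[keep]) ~ 0 + lags[keep], weights = r[keep]^2)
  slope <- unname(stats::coef(fit)[1])
  tau <- if (slope >= 0) dt * kmax else -dt / slope
  attr(tau, "acf") <- r
  attr(tau, "lags_used") <- lags[keep]
  tau
}

#' Protocol parameters
#'
#' The run schedule: a first equilibration with homogeneous looping, a second
#' equilibration under the target rule, then production sampling in which a
#' conformation is saved every `save_interval` MCS until `n_conformations`
#' snapshots exist. The full-scale schedule is `1e8 + 1e8` MCS equilibration
#' with snapshots every `1e7` MCS and at least 1000 conformations; test
#' presets scale all counts down.
#'
#' @param equil1_mcs MCS for the homogeneous equilibration phase.
#' @param equil2_mcs MCS for the heterogeneous (target-rule) phase.
#' @param save_interval MCS between saved conformations in production.
#' @param n_conformations snapshots to collect (`>= 1`).
#' @param seed base integer seed; all phases derive their streams from it.
#' @param homogeneous_p looping probability for phase 1; `NULL` defaults to
#'   `(p_short + p_long) / 2`, a neutral warm start between the two regimes.
#' @return an object of class `dl_protocol`.
#' @export
protocol_params <- function(equil1_mcs = 1e4, equil2_mcs = 1e4,
                            save_interval = 1e3, n_conformations = 20L,
                            seed = 1L, homogeneous_p = NULL) {
  if (any(c(equil1_mcs, equil2_mcs, save_interval) < 0))
    stopf("MCS counts must be >= 0")
  if (n_conformations < 1) stopf("n_conformations must be >= 1")
  structure(list(equil1_mcs = equil1_mcs, equil2_mcs = equil2_mcs,
                 save_interval = save_interval,
                 n_conformations = as.integer(n_conformations),
                 seed = as.integer(seed), homogeneous_p = homogeneous_p),
            class = "dl_protocol")
}

#' Run the full simulation protocol
#'
#' Initialises a random self-avoiding walk, equilibrates first under
#' homogeneous looping and then under the target rule, and samples an
#' ensemble of conformations in production. The Rg^2 trace is recorded
#' during production (ten points per save interval) and used to estimate the
#' autocorrelation time `tau_ac` retrospectively; if `save_interval` is below
#' `5 * tau_ac` the ensemble is flagged with a warning and thinning guidance
#' rather than aborted. Every phase draws from a stream derived from the base
#' seed, so runs are bitwise replayable.
#'
#' @param N monomer count; defaults to `layout$N` when a layout is given.
#' @param lattice a [lattice_params()] object.
#' @param looping a [looping_params()] object (the target rule).
#' @param layout a [build_domain_layout()] result, required in domain mode.
#' @param protocol a [protocol_params()] object.
#' @param log_events keep the loop event log of the production phase.
#' @return an object of class `dl_ensemble`: conformations, snapshot MCS
#'   times, the production `rg2` data frame, `tau_ac`, acceptance counters,
#'   the full configuration and its fingerprint.
#' @export
run_protocol <- function(N = NULL, lattice = lattice_params(),
                         looping = looping_params(), layout = NULL,
                         protocol = protocol_params(), log_events = FALSE) {
  if (is.null(N)) {
    if (is.null(layout)) stopf("supply N (or a domain layout that fixes it)")
    N <- layout$N
  }
  if (looping$mode == "domain_adapted") {
    if (is.null(layout)) stopf("domain_adapted looping requires a domain layout")
    if (layout$N != N) stopf("layout N (%d) differs from N (%d)", layout$N, N)
  }
  config <- list(N = N, lattice = lattice, looping = looping,
                 layout = if (!is.null(layout)) list(N = layout$N, b = layout$b),
                 protocol = protocol)
  fp <- dl_fingerprint(config)

  conf <- init_saw(N, lattice, seed = protocol$seed)

  p_hom <- protocol$homogeneous_p %||% ((looping$p_short + looping$p_long) / 2)
  hom <- looping_params(mode = "homogeneous", p_homogeneous = p_hom,
                        t_bond = looping$t_bond,
                        max_bonds_per_monomer = looping$max_bonds_per_monomer)
  if (protocol$equil1_mcs > 0) {
    res <- run_engine(conf, protocol$equil1_mcs, hom, NULL,
                      derive_seed(protocol$seed, "equil1"))
    conf <- new_conformation(res$positions, res$loop_bonds, res$mcs_clock, conf$L)
  }
  if (protocol$equil2_mcs > 0) {
    res <- run_engine(conf, protocol$equil2_mcs, looping, layout,
                      derive_seed(protocol$seed, "equil2"))
    conf <- new_conformation(res$positions, res$loop_bonds, res$mcs_clock, conf$L)
  }

  n_mcs <- protocol$save_interval * protocol$n_conformations
  rg_int <- max(1, floor(protocol$save_interval / 10))
  res <- run_engine(conf, n_mcs, looping, layout,
                    derive_seed(protocol$seed, "production"),
                    save_interval = protocol$save_interval,
                    max_saves = protocol$n_conformations,
                    rg_interval = rg_int, log_events = log_events)

  confs <- lapply(res$snapshots, function(s)
    new_conformation(s$positions, s$loop_bonds, s$mcs, conf$L))
  rg2 <- data.frame(mcs = res$rg2_mcs, value = res$rg2)

  tau_ac <- NA_real_
  if (nrow(rg2) >= 50 && stats::sd(rg2$value) > 0) {
    tau_ac <- tryCatch(as.numeric(autocorrelation_time(rg2$value, dt = rg_int)),
                       error = function(e) NA_real_)
    if (!is.na(tau_ac) && protocol$save_interval < 5 * tau_ac)
      warning(sprintf(
        paste("save_interval (%g MCS) is below 5 * tau_ac (%.0f MCS);",
              "thin the ensemble to every %.0f MCS for independent snapshots"),
        protocol$save_interval, 5 * tau_ac, 5 * tau_ac), call. = FALSE)
  }

  structure(
    list(conformations = confs, mcs = res$snapshot_mcs, rg2 = rg2,
         tau_ac = tau_ac, N = N, L = lattice$L, config = config,
         fingerprint = fp,
         events = if (log_events) events_frame(res$events),
         attempts = res$attempts, accepts = res$accepts),
    class = "dl_ensemble")
}

#' @export
print.dl_ensemble <- function(x, ...) {
  cat(sprintf("<dl_ensemble> %d conformations of N = %d (L = %d), %s mode\n",
              length(x$conformations), x$N, x$L, x$config$looping$mode))
  cat(sprintf("  config %s, tau_ac = %s MCS, move acceptance %.1f%%\n",
              x$fingerprint,
              if (is.na(x$tau_ac)) "n/a" else sprintf("%.0f", x$tau_ac),
              100 * x$accepts / max(1, x$attempts)))
  invisible(x)
}

#' @export
summary.dl_ensemble <- function(object, ...) {
  nb <- vapply(object$conformations, function(cf) nrow(cf$loop_bonds), 0)
  rg <- vapply(object$conformations, rg_squared, 0)
  out <- list(n_conformations = length(object$conformations),
              N = object$N, mode = object$config$looping$mode,
              tau_ac = object$tau_ac,
              rg2_mean = mean(rg), rg2_sem = sd(rg) / sqrt(length(rg)),
              bonds_mean = mean(nb), bonds_range = range(nb))
  class(out) <- "summary.dl_ensemble"
  out
}

#' @export
print.summary.dl_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d conformations, N = %d, %s looping\n",
              x$n_conformations, x$N, x$mode))
  cat(sprintf("  Rg^2 = %.1f +/- %.1f lattice units^2\n", x$rg2_mean, x$rg2_sem))
  cat(sprintf("  loop bonds per conformation: mean %.1f (range %d-%d)\n",
              x$bonds_mean, x$bonds_range[1], x$bonds_range[2]))
  cat(sprintf("  tau_ac = %s MCS\n",
              if (is.na(x$tau_ac)) "n/a" else sprintf("%.0f", x$tau_ac)))
  invisible(x)
}

#' @export
plot.dl_ensemble <- function(x, ...) {
  plot(x$rg2$mcs, x$rg2$value, type = "l", xlab = "MCS",
       ylab = expression(R[g]^2 ~ "(lattice units"^2 * ")"),
       main = "Production-phase radius of gyration", ...)
  invisible(x)
}
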