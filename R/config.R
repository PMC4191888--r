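# Configuration files, run directories and the command-line surface.
# The CLI script (inst/cli/dlsim.R) is a thin wrapper over these functions.

config_spec <- list(
  polymer  = c("n_monomers"),
  lattice  = c("L"),
  looping  = c("mode", "p_short", "p_long", "t_bond"),
  protocol = c("equil1_mcs", "equil2_mcs", "save_interval", "n_conformations",
               "seed"))

#' Read / write / validate a run configuration
#'
#' A run configuration is a YAML file with sections `polymer` (n_monomers),
#' `lattice` (L), `looping` ([looping_params()] fields), optional `layout`
#' (block_size, present for domain mode), `protocol` ([protocol_params()]
#' fields) and optional `output` (dir). Parsing validates the required keys
#' and names any missing one; emitting and re-parsing a configuration
#' round-trips identically.
#'
#' @param path YAML file path.
#' @return `read_run_config`: a validated nested list of class
#'   `dl_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config a configuration list (as from [read_run_config()] or
#'   [dl_preset()]).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  for (section in names(config_spec)) {
    if (is.null(config[[section]]))
      stopf("config is missing the '%s' section", section)
    missing <- setdiff(config_spec[[section]], names(config[[section]]))
    if (length(missing) > 0)
      stopf("config section '%s' is missing key(s): %s",
            section, paste(missing, collapse = ", "))
  }
  if (identical(config$looping$mode, "domain_adapted") &&
      is.null(config$layout$block_size))
    stopf("config is missing the 'layout' section key: block_size")
  structure(config, class = "dl_run_config")
}

config_objects <- function(config) {
  lk <- config$looping
  looping <- looping_params(
    mode = lk$mode, p_short = lk$p_short, p_long = lk$p_long,
    short_cutoff = lk$short_cutoff, block_size = lk$block_size %||% 50L,
    t_bond = lk$t_bond, p_homogeneous = lk$p_homogeneous,
    max_bonds_per_monomer = lk$max_bonds_per_monomer %||% 1L,
    linkers_inert = lk$linkers_inert %||% TRUE)
  pk <- config$protocol
  protocol <- protocol_params(
    equil1_mcs = pk$equil1_mcs, equil2_mcs = pk$equil2_mcs,
    save_interval = pk$save_interval, n_conformations = pk$n_conformations,
    seed = pk$seed, homogeneous_p = pk$homogeneous_p)
  layout <- NULL
  if (!is.null(config$layout$block_size))
    layout <- build_domain_layout(config$polymer$n_monomers,
                                  config$layout$block_size)
  list(N = config$polymer$n_monomers,
       lattice = lattice_params(config$lattice$L),
       looping = looping, protocol = protocol, layout = layout)
}

#' Shipped configuration presets
#'
#' `"test"` is the reduced desk-scale preset (N = 105, L = 64, short
#' equilibrations) used throughout the test suite; `"full_scale"` echoes the
#' cluster-scale study conditions (N = 1050, L = 500, short cutoff 50,
#' t_bond = 8000 MCS, 1e8 + 1e8 MCS equilibration, snapshots every 1e7 MCS,
#' 1000 conformations) and is intended for long batch runs, not desk use.
#'
#' @param name preset name.
#' @param seed base seed stored in the preset.
#' @return a `dl_run_config`.
#' @export
dl_preset <- function(name = c("test", "full_scale"), seed = 1L) {
  name <- match.arg(name)
  cfg <- switch(name,
    test = list(
      polymer  = list(n_monomers = 105L),
      lattice  = list(L = 64L),
      looping  = list(mode = "uniform_adapted", p_short = 0.03, p_long = 0.03,
                      t_bond = 8000, max_bonds_per_monomer = 1L),
      protocol = list(equil1_mcs = 1e4, equil2_mcs = 1e4, save_interval = 1e3,
                      n_conformations = 20L, seed = as.integer(seed)),
      output   = list(dir = "runs/test")),
    full_scale = list(
      polymer  = list(n_monomers = 1050L),
      lattice  = list(L = 500L),
      looping  = list(mode = "uniform_adapted", p_short = 0.12, p_long = 0.04,
                      short_cutoff = 50L, t_bond = 8000,
                      max_bonds_per_monomer = 1L),
      protocol = list(equil1_mcs = 1e8, equil2_mcs = 1e8, save_interval = 1e7,
                      n_conformations = 1000L, seed = as.integer(seed)),
      output   = list(dir = "runs/full_scale")))
  validate_run_config(cfg)
}

#' Simulate from a configuration (CLI backend)
#'
#' Executes [run_protocol()] for a configuration and writes a run directory:
#' `config.yaml` (the configuration as run), `manifest.yaml` (seed, package
#' version, config fingerprint, snapshot schedule), `snapshots/conf_NNNN.txt`
#' (the [write_conformation()] format), `rg2.tsv`, and `events.tsv` when
#' event logging is on.
#'
#' @param config a `dl_run_config`, or the path of a YAML config file.
#' @param out_dir output directory; defaults to the config's `output$dir`.
#' @param log_events record the production-phase loop event log.
#' @return the run directory path, invisibly.
#' @export
cli_simulate <- function(config, out_dir = NULL, log_events = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  out_dir <- out_dir %||% config$output$dir %||% stopf("no output directory given")
  obj <- config_objects(config)
  ens <- run_protocol(obj$N, obj$lattice, obj$looping, obj$layout,
                      obj$protocol, log_events = log_events)
  dir.create(file.path(out_dir, "snapshots"), recursive = TRUE,
             showWarnings = FALSE)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  for (k in seq_along(ens$conformations))
    write_conformation(ens$conformations[[k]],
                       file.path(out_dir, "snapshots", sprintf("conf_%04d.txt", k)))
  utils::write.table(ens$rg2, file.path(out_dir, "rg2.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(ens$events))
    utils::write.table(ens$events, file.path(out_dir, "events.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(
    seed = obj$protocol$seed,
    package_version = as.character(utils::packageVersion("dynloop")),
    fingerprint = ens$fingerprint,
    n_snapshots = length(ens$conformations),
    snapshot_mcs = ens$mcs,
    tau_ac = if (is.na(ens$tau_ac)) "n/a" else ens$tau_ac),
    file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

read_run_dir <- function(run_dir) {
  snaps <- sort(list.files(file.path(run_dir, "snapshots"),
                           pattern = "^conf_.*\\.txt$", full.names = TRUE))
  if (length(snaps) == 0) stopf("no snapshots found under %s", run_dir)
  lapply(snaps, read_conformation)
}

#' Analyse a run directory (CLI backend)
#'
#' Recomputes the requested observables from the snapshots of a
#' [cli_simulate()] run directory and writes them as TSV: `msd.tsv` (the MSD
#' profile), `plateau.tsv` (one line), `loops.tsv` (per-snapshot short/long
#' loop counts). Idempotent.
#'
#' @param run_dir a run directory with a `snapshots/` subdirectory.
#' @param analyses subset of `c("msd", "plateau", "loops")`.
#' @param cutoff loop-span cutoff for `loops`; `NULL` resolves to 5 percent
#'   of the chain length.
#' @return the paths written, invisibly.
#' @export
cli_analyze <- function(run_dir, analyses = c("msd", "plateau", "loops"),
                        cutoff = NULL) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  confs <- read_run_dir(run_dir)
  out <- character(0)
  profile <- NULL
  if (any(c("msd", "plateau") %in% analyses))
    profile <- msd_profile(confs)
  if ("msd" %in% analyses) {
    p <- file.path(run_dir, "msd.tsv")
    write_msd_profile(profile, p)
    out <- c(out, p)
  }
  if ("plateau" %in% analyses) {
    p <- file.path(run_dir, "plateau.tsv")
    utils::write.table(
      data.frame(plateau = plateau_level(profile),
                 n_conformations = length(confs)),
      p, sep = "\t", row.names = FALSE, quote = FALSE)
    out <- c(out, p)
  }
  if ("loops" %in% analyses) {
    p <- file.path(run_dir, "loops.tsv")
    stats <- lapply(confs, loop_stats, cutoff = cutoff)
    utils::write.table(
      data.frame(snapshot = seq_along(confs),
                 mcs = vapply(confs, function(cf) cf$mcs_clock, 0),
                 n_short = vapply(stats, `[[`, 0L, "n_short"),
                 n_long = vapply(stats, `[[`, 0L, "n_long")),
      p, sep = "\t", row.names = FALSE, quote = FALSE)
    out <- c(out, p)
  }
  invisible(out)
}

#' Parameter-space scan (CLI backend)
#'
#' Runs [heatmap_scan()] for a configuration extended with `scan` keys
#' (`p_short_values`, `p_long_values`, optional `n_reps`) and writes the
#' long-format heat-map TSV. Rerunning resumes: completed cells are read
#' from the existing TSV, only missing cells are computed.
#'
#' @param config a `dl_run_config` with a `scan` section, or a YAML path.
#' @param out_dir output directory (default: the config's `output$dir`).
#' @return the `dl_heatmap`, invisibly.
#' @export
cli_scan <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  if (is.null(config$scan$p_short_values) || is.null(config$scan$p_long_values))
    stopf("config is missing the 'scan' section keys: p_short_values, p_long_values")
  out_dir <- out_dir %||% config$output$dir %||% stopf("no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- config_objects(config)
  hm <- heatmap_scan(unlist(config$scan$p_short_values),
                     unlist(config$scan$p_long_values),
                     N = obj$N, lattice = obj$lattice, looping = obj$looping,
                     protocol = obj$protocol, layout = obj$layout,
                     n_reps = config$scan$n_reps %||% 1L,
                     file = file.path(out_dir, "heatmap.tsv"))
  write_heatmap(hm, file.path(out_dir, "heatmap_matrix.tsv"))
  invisible(hm)
}

#' Generate the bundled test fixtures
#'
#' Writes small deterministic assets used by the test suite: a 105-monomer
#' self-avoiding walk, a short equilibrated ensemble (snapshot files), a
#' synthetic FISH-style probe-pair table, a domain-layout table, and a
#' manifest listing every asset with a content hash. Byte-identical across
#' runs for a given seed; no downloads.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return the manifest data frame, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(file.path(dir, "ensemble"), recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  saw <- init_saw(105, lattice_params(64), seed = seed)
  p <- file.path(dir, "saw105.txt")
  write_conformation(saw, p)
  paths <- c(paths, p)

  # deliberately short run: fixture assets, not production statistics
  ens <- suppressWarnings(run_protocol(
    105, lattice_params(64),
    looping_params(p_short = 0.03, p_long = 0.03),
    protocol = protocol_params(
      equil1_mcs = 2e3, equil2_mcs = 2e3,
      save_interval = 500, n_conformations = 10L,
      seed = derive_seed(seed, "fixture-ensemble"))))
  for (k in seq_along(ens$conformations)) {
    p <- file.path(dir, "ensemble", sprintf("conf_%04d.txt", k))
    write_conformation(ens$conformations[[k]], p)
    paths <- c(paths, p)
  }

  fish <- synthesize_fish_table(ens, probe_positions = c(1, 26, 53, 79, 105),
                                scale = 0.1, mb_per_monomer = 0.1,
                                noise_sd = 0.03,
                                seed = derive_seed(seed, "fixture-fish"))
  p <- file.path(dir, "fish_table_synthetic.tsv")
  write_probe_pairs(fish, p)
  paths <- c(paths, p)

  layout <- build_domain_layout(105, 5)
  p <- file.path(dir, "domain_layout.tsv")
  utils::write.table(
    data.frame(monomer = seq_len(105), block = as.character(layout$block),
               domain_id = layout$domain_id),
    p, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  manifest <- data.frame(
    asset = sub(paste0("^", dir, "/?"), "", paths),
    hash = vapply(paths, function(f)
      hex8(fnv1a(paste(readLines(f), collapse = "\n"))), ""),
    row.names = NULL)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
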