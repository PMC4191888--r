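# MSD profiles, plateau estimator, normalisation, heat maps, loop counts.

test_that("msd_profile is exact on a straight rod", {
  rod <- make_rod(30)
  prof <- msd_profile(list(rod))
  expect_equal(prof$msd, 4 * prof$s^2)
  expect_equal(prof$n_pairs, 30 - prof$s)
})

test_that("msd_profile equals the brute-force all-pairs oracle", {
  ens <- small_ensemble()
  sep <- c(1, 2, 5, 10, 40, 70, 104)
  prof <- msd_profile(ens, separations = sep)
  expect_equal(prof$msd, oracle_msd(ens$conformations, sep))
  # s = N - 1: one pair per conformation
  expect_equal(prof$n_pairs[prof$s == 104], length(ens$conformations))
  # s = 0 is trivially zero
  expect_equal(msd_profile(ens, separations = 0)$msd, 0)
  expect_error(msd_profile(list()), "empty")
})

test_that("plateau estimator is the pair-weighted top-tercile mean", {
  expect_equal(plateau_level(msd_profile(list(make_rod(10)),
                                         separations = 1:9)),
               (3 * 4 * 49 + 2 * 4 * 64 + 1 * 4 * 81) / 6)

  # constant profile: plateau equals the constant
  const <- msd_profile(list(make_rod(12)))
  const$msd <- rep(7, nrow(const))
  expect_equal(plateau_level(const), 7)

  # saturating profile: plateau within 2% of the known asymptote
  sat <- msd_profile(list(make_rod(90)))
  sat$msd <- 500 * (1 - exp(-sat$s / 8))
  expect_lt(abs(plateau_level(sat) - 500) / 500, 0.02)

  # insufficient coverage errors
  short <- msd_profile(list(make_rod(90)), separations = 1:40)
  expect_error(plateau_level(short), "0.8")
})

test_that("normalisation divides msd and sem by the reference", {
  ens <- small_ensemble()
  prof <- msd_profile(ens)
  ref <- plateau_level(prof)
  norm <- normalize_profile(prof, ref)
  expect_equal(plateau_level(norm), 1.0)
  expect_equal(norm$sem, prof$sem / ref)
  half <- normalize_profile(prof, 2 * ref)
  expect_equal(plateau_level(half), 0.5)
  expect_error(normalize_profile(prof, 0), "positive")
})

test_that("msd profiles round-trip through TSV", {
  prof <- msd_profile(small_ensemble(), separations = c(1, 5, 70, 104))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_msd_profile(prof, path)
  back <- read_msd_profile(path)
  expect_equal(back$msd, prof$msd)
  expect_equal(attr(back, "n_monomers"), attr(prof, "n_monomers"))
  expect_equal(plateau_level(back), plateau_level(prof))
})

test_that("heatmap_scan fills the grid deterministically and resumes", {
  prot <- protocol_params(2e3, 2e3, 400, 8, seed = 31)
  hm <- suppressWarnings(
    heatmap_scan(c(0.02, 0.05), c(0.02, 0.05), N = 60,
                 lattice = lattice_params(64), protocol = prot))
  expect_equal(dim(hm$plateau), c(2, 2))
  expect_true(all(is.finite(hm$plateau)))
  expect_equal(nrow(hm$manifest), 4)

  # determinism: same base seed, same grid -> identical plateaus
  hm2 <- suppressWarnings(
    heatmap_scan(c(0.02, 0.05), c(0.02, 0.05), N = 60,
                 lattice = lattice_params(64), protocol = prot))
  expect_identical(hm$plateau, hm2$plateau)

  # resume: pre-existing manifest rows are not recomputed
  path <- withr::local_tempfile(fileext = ".tsv")
  t0 <- Sys.time()
  hm3 <- suppressWarnings(
    heatmap_scan(c(0.02, 0.05), c(0.02, 0.05), N = 60,
                 lattice = lattice_params(64), protocol = prot, file = path))
  first <- as.numeric(Sys.time() - t0, units = "secs")
  t0 <- Sys.time()
  hm4 <- suppressWarnings(
    heatmap_scan(c(0.02, 0.05), c(0.02, 0.05), N = 60,
                 lattice = lattice_params(64), protocol = prot, file = path))
  second <- as.numeric(Sys.time() - t0, units = "secs")
  expect_identical(hm3$plateau, hm4$plateau)
  expect_lt(second, first / 2)

  # matrix-form TSV export
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write_heatmap(hm, mpath)
  mat <- utils::read.table(mpath, header = TRUE, sep = "\t")
  expect_equal(dim(mat), c(2, 3))  # p_short column + one column per p_long
  expect_equal(mat[, 2], unname(hm$plateau[, 1]))
})

test_that("degenerate zero-looping cell matches the plain SAW run", {
  prot <- protocol_params(1e3, 1e3, 200, 6, seed = 33)
  hm <- suppressWarnings(
    heatmap_scan(0, 0, N = 60, lattice = lattice_params(64),
                 protocol = prot))
  prot$seed <- derive_seed(prot$seed, 0, 0, 1L)
  ens <- suppressWarnings(run_protocol(
    60, lattice_params(64), looping_params(p_short = 0, p_long = 0),
    protocol = prot))
  plateau <- plateau_level(msd_profile(ens, seq(ceiling(2 * 60 / 3), 59)))
  expect_equal(hm$plateau[1, 1], plateau)
  expect_equal(nrow(ens$conformations[[1]]$loop_bonds), 0)
})

test_that("mean long-loop count averages per-conformation counts", {
  a <- make_rod(100, bonds = rbind(c(1L, 61L, 9L), c(10L, 90L, 9L)))
  b <- make_rod(100, bonds = rbind(c(1L, 61L, 9L), c(10L, 90L, 9L),
                                   c(20L, 80L, 9L), c(2L, 70L, 9L)))
  res <- mean_long_loop_count(list(a, b), cutoff = 50)
  expect_equal(res$mean, 3)
  expect_equal(res$sem, 1)
  zero <- mean_long_loop_count(list(make_rod(10)), cutoff = 5)
  expect_equal(zero$mean, 0)
})
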