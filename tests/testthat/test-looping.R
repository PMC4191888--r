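# Loop dynamics: domain layouts, formation probabilities, lifetimes,
# per-MCS bond updates.

test_that("domain layout alternates linker/domain blocks with correct counts", {
  full <- build_domain_layout(1050, 50)
  expect_equal(full$n_domains, 10L)
  expect_equal(full$n_linkers, 11L)
  expect_equal(length(full$domain_id), 1050L)
  # begins and ends with a linker; blocks are 50 monomers
  expect_equal(full$domain_id[1:50], rep(0L, 50))
  expect_equal(full$domain_id[1001:1050], rep(0L, 50))
  expect_equal(full$domain_id[51:100], rep(1L, 50))
  expect_equal(sum(full$domain_id == 0), 11L * 50L)

  test_preset <- build_domain_layout(105, 5)
  expect_equal(test_preset$n_domains, 10L)
  expect_equal(test_preset$n_linkers, 11L)

  expect_error(build_domain_layout(100, 50), "2k \\+ 1")
  expect_error(build_domain_layout(104, 5), "2k \\+ 1")
})

test_that("looping probability follows the short/long contour rule", {
  p <- looping_params(p_short = 0.12, p_long = 0.04, short_cutoff = 50)
  expect_equal(looping_probability(10, 40, p), 0.12)
  expect_equal(looping_probability(10, 60, p), 0.12)   # |i-j| = 50 is short
  expect_equal(looping_probability(10, 200, p), 0.04)
  # vectorised, symmetric in i/j
  expect_equal(looping_probability(c(10, 200), c(40, 10), p), c(0.12, 0.04))
  expect_error(looping_probability(10, 11, p), "non-adjacent")
  # unresolved cutoff defaults to 5% of the chain
  p2 <- looping_params(p_short = 0.1, p_long = 0.02)
  expect_equal(looping_probability(1, 6, p2, N = 105), 0.1)   # |i-j| = 5
  expect_equal(looping_probability(1, 7, p2, N = 105), 0.02)  # |i-j| = 6
})

test_that("domain-mode probabilities respect domains and inert linkers", {
  layout <- build_domain_layout(1050, 50)
  p <- looping_params(mode = "domain_adapted", p_short = 0.16, p_long = 0.02)
  # monomer 30 lies in the first linker: no looping at all
  expect_equal(looping_probability(30, 900, p, layout), 0)
  # same looped domain (51..100)
  expect_equal(looping_probability(60, 90, p, layout), 0.16)
  # different looped domains
  expect_equal(looping_probability(60, 160, p, layout), 0.02)
  # Methods-style reading: linkers loop long-range
  p2 <- looping_params(mode = "domain_adapted", p_short = 0.16, p_long = 0.02,
                       linkers_inert = FALSE)
  expect_equal(looping_probability(30, 900, p2, layout), 0.02)
  expect_error(looping_probability(60, 90, p), "layout")
})

test_that("lifetimes are Poisson with mean t_bond", {
  expect_equal(sample_lifetime(0, n = 100, seed = 1), rep(0L, 100))
  draws <- sample_lifetime(8000, n = 1e5, seed = 2)
  se <- sqrt(8000 / 1e5)
  expect_lt(abs(mean(draws) - 8000), 3 * se)
  expect_lt(abs(var(draws) / 8000 - 1), 0.05)
  expect_identical(sample_lifetime(8000, n = 10, seed = 3),
                   sample_lifetime(8000, n = 10, seed = 3))
  # small-mean regime uses a different sampler; check moments there too
  small <- sample_lifetime(5, n = 1e5, seed = 4)
  expect_lt(abs(mean(small) - 5), 3 * sqrt(5 / 1e5))
  expect_lt(abs(var(small) / 5 - 1), 0.05)
})

test_that("zero looping probability never forms bonds", {
  conf <- init_saw(60, lattice_params(64), seed = 1)
  lp <- looping_params(p_short = 0, p_long = 0)
  out <- mcs_sweep(conf, 300, looping = lp, seed = 2, log_events = TRUE)
  expect_equal(nrow(out$loop_bonds), 0)
  expect_equal(nrow(attr(out, "events")), 0)
})

test_that("p = 1 with zero lifetime forms a bond and breaks it next MCS", {
  # two chain ends held proximal: monomers 1 and 4 at separation (2,1,0)
  pos <- rbind(c(10L, 10L, 10L), c(12L, 11L, 12L), c(14L, 12L, 10L),
               c(12L, 11L, 10L))
  conf <- conformation(pos, L = 64)
  lp <- looping_params(p_short = 1, p_long = 1, t_bond = 0)
  step1 <- attempt_loop_updates(conf, lp, seed = 1)
  expect_gte(nrow(step1$conformation$loop_bonds), 1)
  expect_true(all(step1$events$event == "form"))
  expect_equal(step1$events$lifetime[1], 0)
  step2 <- attempt_loop_updates(step1$conformation, lp, seed = 2)
  expect_true("break" %in% step2$events$event)
})

test_that("event log replays against the looping rule", {
  conf <- init_saw(105, lattice_params(64), seed = 3)
  lp <- looping_params(p_short = 0.12, p_long = 0.04)
  out <- mcs_sweep(conf, 500, looping = lp, seed = 4, log_events = TRUE)
  ev <- attr(out, "events")
  forms <- ev[ev$event == "form", ]
  expect_gt(nrow(forms), 0)
  # every formed bond had positive probability and non-adjacent endpoints
  expect_true(all(abs(forms$j - forms$i) >= 2))
  probs <- looping_probability(forms$i, forms$j, lp, N = 105)
  expect_true(all(probs > 0))
  expect_true(all(forms$lifetime >= 0))
  # bond conservation: forms minus breaks equals the surviving bonds
  expect_equal(nrow(forms) - sum(ev$event == "break"),
               nrow(out$loop_bonds))
})

test_that("max_bonds_per_monomer caps the per-monomer loop count", {
  for (cap in c(1L, 2L)) {
    lp <- looping_params(p_short = 0.5, p_long = 0.2,
                         max_bonds_per_monomer = cap)
    conf <- init_saw(80, lattice_params(64), seed = 5)
    out <- mcs_sweep(conf, 300, looping = lp, seed = 6)
    lb <- out$loop_bonds
    if (nrow(lb) > 0) {
      counts <- table(c(lb[, "i"], lb[, "j"]))
      expect_lte(max(counts), cap)
    }
  }
})

test_that("domain mode never bonds a linker monomer", {
  layout <- build_domain_layout(105, 5)
  lp <- looping_params(mode = "domain_adapted", p_short = 0.2, p_long = 0.05)
  conf <- init_saw(105, lattice_params(64), seed = 7)
  out <- mcs_sweep(conf, 1000, looping = lp, layout = layout, seed = 8,
                   log_events = TRUE)
  ev <- attr(out, "events")
  touched <- unique(c(ev$i, ev$j, out$loop_bonds[, "i"], out$loop_bonds[, "j"]))
  expect_gt(length(touched), 0)  # the run did form loops
  expect_true(all(layout$domain_id[touched] != 0))
})

test_that("loop_stats counts short and long loops and conserves totals", {
  rod <- make_rod(100, bonds = rbind(c(1L, 61L, 100L), c(6L, 11L, 100L)))
  st <- loop_stats(rod, cutoff = 50)
  expect_equal(st$n_short, 1L)
  expect_equal(st$n_long, 1L)
  expect_equal(as.integer(st$histogram), c(1L, 1L))
  expect_equal(names(st$histogram), c("5", "60"))

  empty <- make_rod(10)
  st0 <- loop_stats(empty, cutoff = 5)
  expect_equal(st0$n_short + st0$n_long, 0L)
  expect_equal(length(st0$histogram), 0L)

  # conservation across an evolving trajectory
  conf <- equilibrated_conf()
  for (k in 1:5) {
    conf <- mcs_sweep(conf, 20,
                      looping = looping_params(p_short = 0.1, p_long = 0.04),
                      seed = 50 + k)
    st <- loop_stats(conf, cutoff = 5)
    expect_equal(st$n_short + st$n_long, nrow(conf$loop_bonds))
  }
})

test_that("bond count is stationary after equilibration", {
  lp <- looping_params(p_short = 0.08, p_long = 0.03)
  counts <- matrix(NA_real_, 3, 2)
  for (r in 1:3) {
    conf <- init_saw(60, lattice_params(64), seed = 60 + r)
    conf <- mcs_sweep(conf, 3e4, looping = lp, seed = 160 + r)
    for (w in 1:2) {
      n <- numeric(20)
      for (k in 1:20) {
        conf <- mcs_sweep(conf, 500, looping = lp, seed = 1000 * r + 10 * w + k)
        n[k] <- nrow(conf$loop_bonds)
      }
      counts[r, w] <- mean(n)
    }
  }
  # window means drift by less than 20% of the mean level, in every replicate
  drift <- abs(counts[, 2] - counts[, 1]) / rowMeans(counts)
  expect_true(all(drift < 0.2))
})
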