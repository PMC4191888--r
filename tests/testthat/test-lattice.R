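# Lattice representation, allowed bond vectors, local moves, validation.

test_that("allowed bond vector set is the classic 108-vector set", {
  v <- allowed_bond_vectors()
  expect_equal(nrow(v), 108)
  # closed under sign flips and coordinate permutations
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_setequal(key(v), key(-v))
  expect_setequal(key(v), key(v[, c(2, 3, 1)]))
  s2 <- rowSums(v^2)
  expect_setequal(unique(s2), c(4, 5, 6, 9, 10))
  expect_true(all(key(rbind(c(2, 0, 0), c(3, 1, 0), c(2, 2, 1))) %in% key(v)))
  # squared length 8 excluded (chain crossing); minimum bond length 2
  expect_false("2 2 0" %in% key(v))
  expect_false("1 0 0" %in% key(v))
  expect_true(all(s2 >= 4 & s2 <= 10))
})

test_that("init_saw builds valid, seed-reproducible conformations", {
  conf <- init_saw(2, lattice_params(64), seed = 1)
  d <- conf$positions[2, ] - conf$positions[1, ]
  expect_true(sum(d^2) %in% c(4, 5, 6, 9, 10))

  conf <- init_saw(100, lattice_params(64), seed = 7)
  expect_length(validate_conformation(conf), 0)
  expect_equal(conf$mcs_clock, 0)
  expect_equal(nrow(conf$loop_bonds), 0)

  again <- init_saw(100, lattice_params(64), seed = 7)
  expect_identical(conf$positions, again$positions)
  other <- init_saw(100, lattice_params(64), seed = 8)
  expect_false(identical(conf$positions, other$positions))
})

test_that("init_saw fails explicitly on an impossibly dense lattice", {
  expect_error(init_saw(4000, lattice_params(16), seed = 1, max_restarts = 2),
               "failed")
  expect_error(init_saw(1, lattice_params(64), seed = 1), "N must be")
  expect_error(lattice_params(8), "L must be")
})

test_that("attempt_move accepts exactly the geometrically legal dimer moves", {
  # dimer with bond (2,0,0): brute-force all 6 directions for monomer 2.
  # +x stretches to (3,0,0) legal; -x gives (1,0,0) illegal (length < 2);
  # lateral moves give (2,1,0)-type vectors, all legal.
  rod <- make_rod(2)
  outcomes <- vapply(1:6, function(d)
    attempt_move(rod, monomer = 2, direction = d)$moved, TRUE)
  expect_identical(outcomes, c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))

  # dimer with bond (3,1,0): +x would reach (4,1,0), illegal
  conf <- conformation(rbind(c(10L, 10L, 10L), c(13L, 11L, 10L)), L = 64)
  expect_false(attempt_move(conf, monomer = 2, direction = 1)$moved)
  expect_true(attempt_move(conf, monomer = 2, direction = 2)$moved)
})

test_that("excluded volume rejects overlapping moves", {
  # monomer 3 sits two sites above monomer 1; its -y move keeps both its
  # bonds legal but would overlap monomer 1's cube
  pos <- rbind(c(10L, 10L, 10L), c(8L, 11L, 9L), c(10L, 12L, 10L))
  conf <- conformation(pos, L = 64)
  res <- attempt_move(conf, monomer = 3, direction = 4)  # -y onto monomer 1
  expect_false(res$moved)
  expect_identical(res$conformation$positions, conf$positions)
})

test_that("single-site moves are reversible", {
  rod <- make_rod(2)
  fwd <- attempt_move(rod, monomer = 2, direction = 3)  # +y
  expect_true(fwd$moved)
  back <- attempt_move(fwd$conformation, monomer = 2, direction = 4)  # -y
  expect_true(back$moved)
  expect_identical(back$conformation$positions, rod$positions)
})

test_that("moves never break an active loop bond", {
  # loop bond (1,3) at maximum extension (3,1,0): the +x move of monomer 3
  # would stretch it to an illegal (4,1,0) and must be rejected, while -x is
  # legal in every respect
  pos <- rbind(c(10L, 10L, 10L), c(11L, 12L, 12L), c(13L, 11L, 10L))
  bonds <- cbind(1L, 3L, 10L^6)
  conf <- conformation(pos, loop_bonds = bonds, L = 64, check = FALSE)
  expect_length(validate_conformation(conf), 0)
  expect_false(attempt_move(conf, monomer = 3, direction = 1)$moved)
  expect_true(attempt_move(conf, monomer = 3, direction = 2)$moved)
})

test_that("mcs_sweep performs N attempts per MCS and advances the clock", {
  conf <- init_saw(10, lattice_params(64), seed = 3)
  out <- mcs_sweep(conf, 1, seed = 4)
  expect_equal(attr(out, "attempts"), 10)
  expect_equal(out$mcs_clock, 1)
  out <- mcs_sweep(out, 7, seed = 5)
  expect_equal(attr(out, "attempts"), 70)
  expect_equal(out$mcs_clock, 8)
})

test_that("a sweep with zero move attempts leaves positions unchanged", {
  conf <- equilibrated_conf()
  out <- mcs_sweep(conf, 5, seed = 9, moves_per_mcs = 0)
  expect_identical(out$positions, conf$positions)
  expect_equal(out$mcs_clock, conf$mcs_clock + 5)
})

test_that("invariants hold after many sweeps with active looping", {
  conf <- init_saw(50, lattice_params(64), seed = 11)
  lp <- looping_params(p_short = 0.1, p_long = 0.05)
  for (k in 1:20) {
    conf <- mcs_sweep(conf, 5, looping = lp, seed = k)
    expect_length(validate_conformation(conf), 0)
  }
})

test_that("validate_conformation reports each violation class", {
  # coincident monomers
  pos <- rbind(c(10L, 10L, 10L), c(12L, 10L, 10L), c(10L, 10L, 10L))
  bad <- conformation(pos, L = 64, check = FALSE)
  msgs <- validate_conformation(bad)
  expect_match(paste(msgs, collapse = " "), "excluded volume")
  # adjacent-monomer loop bond
  rod <- make_rod(5, bonds = cbind(3L, 4L, 100L))
  msgs <- validate_conformation(rod)
  expect_match(paste(msgs, collapse = " "), "adjacent")
  # illegal backbone vector
  pos <- rbind(c(10L, 10L, 10L), c(14L, 10L, 10L))
  msgs <- validate_conformation(conformation(pos, L = 64, check = FALSE))
  expect_match(paste(msgs, collapse = " "), "backbone")
})

test_that("proximal pairs on a rod match contour geometry and the oracle", {
  rod <- make_rod(10)
  pp <- proximal_pairs(rod)
  # corners 2 apart in x: |i-j|=1 adjacent (excluded); 4 apart not allowed;
  # no pair is within sqrt(10) other than backbone neighbours
  expect_equal(nrow(pp), 0)
  expect_equal(nrow(proximal_pairs(rod, "brute")), 0)

  # two monomers at separation (4,0,0) are not proximal
  conf <- conformation(rbind(c(10L, 10L, 10L), c(14L, 10L, 10L)), L = 64,
                       check = FALSE)
  expect_equal(nrow(proximal_pairs(conf)), 0)
})

test_that("binned proximal-pair query equals the all-pairs scan", {
  for (seed in c(1, 2, 3)) {
    conf <- mcs_sweep(init_saw(200, lattice_params(64), seed = seed), 50,
                      seed = seed + 100)
    expect_identical(unname(proximal_pairs(conf)),
                     unname(proximal_pairs(conf, "brute")))
  }
  conf <- equilibrated_conf()
  pp <- proximal_pairs(conf)
  expect_identical(unname(pp), unname(proximal_pairs(conf, "brute")))
  expect_true(all(pp[, 2] - pp[, 1] >= 2))
})

test_that("trajectories are bitwise reproducible for a fixed seed", {
  lp <- looping_params(p_short = 0.08, p_long = 0.03)
  run <- function() {
    conf <- init_saw(60, lattice_params(64), seed = 5)
    mcs_sweep(conf, 200, looping = lp, seed = 6)
  }
  a <- run(); b <- run()
  expect_identical(a$positions, b$positions)
  expect_identical(a$loop_bonds, b$loop_bonds)
})

test_that("conformation snapshots round-trip through the text format", {
  conf <- equilibrated_conf()
  path <- withr::local_tempfile(fileext = ".txt")
  write_conformation(conf, path)
  back <- read_conformation(path)
  expect_identical(back$positions, conf$positions)
  expect_identical(back$loop_bonds, conf$loop_bonds)
  expect_equal(back$mcs_clock, conf$mcs_clock)
  expect_equal(back$L, conf$L)
})
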