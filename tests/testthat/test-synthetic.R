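test_that("markov chain sampler honours absorbing, deterministic and stochastic matrices", {
  # absorbing identity, start 0
  s <- markov_chain_spec(diag(2), n_steps = 50, seed = 1, start = 0)
  expect_equal(sample_markov_chain(s)[[1]], rep(0L, 50))
  # deterministic alternation
  s <- markov_chain_spec(matrix(c(0, 1, 1, 0), 2, byrow = TRUE),
                         n_steps = 4, seed = 1, start = 0)
  expect_equal(sample_markov_chain(s)[[1]], c(0L, 1L, 0L, 1L))
  # law of large numbers against a direct-counting oracle
  T <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  s <- markov_chain_spec(T, n_steps = 1e5, seed = 42)
  x <- sample_markov_chain(s)[[1]]
  C <- count_oracle(x, 1, 2)
  expect_lt(max(abs(C / rowSums(C) - T)), 0.01)
  # chi-square goodness of fit per row, alpha = 0.01, on an independent chain
  x2 <- sample_markov_chain(markov_chain_spec(T, n_steps = 1e5, seed = 11))[[1]]
  C2 <- count_oracle(x2, 1, 2)
  for (i in 1:2) {
    p <- stats::chisq.test(C2[i, ], p = T[i, ])$p.value
    expect_gt(p, 0.01)
  }
})

test_that("markov chain spec validation names the offending row", {
  T <- matrix(c(0.9, 0.2, 0.2, 0.8), 2, byrow = TRUE)
  expect_error(markov_chain_spec(T, 10), "row 1")
  expect_error(markov_chain_spec(matrix(c(1.2, -0.2, 0, 1), 2, byrow = TRUE), 10),
               "\\[0, 1\\]")
  # two absorbing states both reachable from the start
  T2 <- matrix(c(0.5, 0.25, 0.25, 0, 1, 0, 0, 0, 1), 3, byrow = TRUE)
  expect_error(markov_chain_spec(T2, 10, start = 0), "recurrent")
})

test_that("seeded determinism gives identical chains, different seeds differ", {
  T <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  a <- sample_markov_chain(markov_chain_spec(T, 1000, seed = 7))[[1]]
  b <- sample_markov_chain(markov_chain_spec(T, 1000, seed = 7))[[1]]
  c <- sample_markov_chain(markov_chain_spec(T, 1000, seed = 8))[[1]]
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("harmonic Langevin sampling satisfies equipartition", {
  spec <- langevin_spec("harmonic", kT = 0.6, friction = 1, dt = 0.01,
                        n_steps = 1e6, seed = 5, pot_par = list(k = 1.5))
  sim <- simulate_langevin(spec)
  x <- sim$features$values[, 1]
  expect_lt(abs(mean(x)), 0.05)
  expect_lt(abs(var(x) / (0.6 / 1.5) - 1), 0.05)
})

test_that("zero-temperature harmonic relaxation decays monotonically", {
  spec <- langevin_spec("harmonic", kT = 0, dt = 0.01, n_steps = 500,
                        seed = 1, x0 = 1)
  x <- simulate_langevin(spec)$features$values[, 1]
  expect_true(all(diff(x) < 0))
  expect_lt(x[500], 0.01)
})

test_that("symmetric double well equilibrates to equal basin occupancies", {
  spec <- langevin_spec("double-well", kT = kBT(298), dt = 0.01,
                        n_steps = 1e6, seed = 11,
                        pot_par = list(h = 2, a = 1))
  sim <- simulate_langevin(spec)
  occ <- mean(sim$basins == 1)
  expect_lt(abs(occ - 0.5), 0.075)   # ~3 sigma at the observed transition count
})

test_that("unstable time steps are diagnosed via the bounding box", {
  spec <- langevin_spec("harmonic", kT = 1, dt = 3, n_steps = 1000,
                        seed = 1, x0 = 1, box = 50, pot_par = list(k = 1))
  expect_error(simulate_langevin(spec), "bounding box")
})

test_that("fast-noise dimensions are appended and seed-deterministic", {
  spec <- langevin_spec("double-well", n_steps = 500, seed = 2,
                        n_noise_dims = 3)
  sim <- simulate_langevin(spec)
  expect_equal(ncol(sim$features$values), 4)
  sim2 <- simulate_langevin(spec)
  expect_identical(sim$features$values, sim2$features$values)
})

test_that("toy duplex flip moves the lesion away from its partner", {
  d0 <- build_toy_duplex(toy_duplex_spec(flip_angle = 0))
  d180 <- build_toy_duplex(toy_duplex_spec(flip_angle = 180))
  s0 <- duplex_cv_selections(d0)
  dist0 <- com_distance(frame_coords(d0), s0$lesion, s0$partner)
  dist180 <- com_distance(frame_coords(d180), s0$lesion, s0$partner)
  expect_gt(dist180, dist0)
  # flip 0 is the minimum over the sweep
  sweep_d <- vapply(seq(0, 350, by = 10), function(a) {
    dd <- build_toy_duplex(toy_duplex_spec(flip_angle = a))
    com_distance(frame_coords(dd), s0$lesion, s0$partner)
  }, numeric(1))
  expect_equal(which.min(sweep_d), 1)
})

test_that("CPDb is strictly monotone in the flip angle over (0, 180)", {
  angs <- seq(0, 180, by = 10)
  cp <- vapply(angs, function(a) {
    d <- build_toy_duplex(toy_duplex_spec(flip_angle = a))
    s <- duplex_cv_selections(d)
    cpdb(frame_coords(d), cpdb_spec(s$p1, s$p2, s$p3, s$p4))
  }, numeric(1))
  dcp <- diff(cp)
  # strictly monotone in one consistent direction (no wrap inside the sweep)
  expect_true(all(dcp > 0) || all(dcp < 0))
  # rotation about the p2-p3 axis changes the torsion linearly: 10 deg steps
  expect_equal(abs(dcp), rep(10, length(dcp)), tolerance = 1e-6)
})

test_that("toy duplex atom count and labels are invariant across the sweep", {
  ref <- build_toy_duplex(toy_duplex_spec(flip_angle = 0, seed = 3))
  for (a in c(45, 170, 300)) {
    d <- build_toy_duplex(toy_duplex_spec(flip_angle = a, seed = 3))
    expect_identical(d$atoms, ref$atoms)
  }
  expect_error(toy_duplex_spec(n_base_pairs = 2), "flanking")
})

test_that("five-basin potential exposes consistent closed forms and gradient", {
  pot <- potential("five-basin-2D")
  expect_equal(nrow(pot$minima), 5)
  # numerical vs analytic gradient at random points
  set.seed(1)
  for (i in 1:5) {
    x <- runif(2, -2.5, 2.5)
    num <- vapply(1:2, function(d) {
      h <- 1e-6; e <- c(0, 0); e[d] <- h
      (pot$fun(x + e) - pot$fun(x - e)) / (2 * h)
    }, numeric(1))
    expect_equal(pot$grad(x), num, tolerance = 1e-5)
  }
  # deepest basin is the first (maps to macrostate 1)
  vals <- apply(pot$minima, 1, pot$fun)
  expect_equal(which.min(vals), 1)
})
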