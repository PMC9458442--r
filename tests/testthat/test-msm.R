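test_that("transition counting matches hand counts and the pair-loop oracle", {
  expect_equal(count_transitions(c(0L, 1L, 0L, 1L), 1),
               matrix(c(0, 2, 1, 0), 2, byrow = TRUE))
  expect_equal(count_transitions(c(0L, 0L, 0L), 2, n_states = 2),
               matrix(c(1, 0, 0, 0), 2, byrow = TRUE))
  set.seed(50)
  s <- sample(0:3, 500, replace = TRUE)
  for (lag in c(1, 5)) {
    expect_equal(count_transitions(s, lag), count_oracle(s, lag, 4))
  }
  # segment-aware: no pair crosses the boundary
  s2 <- c(0L, 0L, 1L, 1L)
  C <- count_transitions(s2, 1, boundaries = c(1, 3))
  expect_equal(C, matrix(c(1, 0, 0, 1), 2, byrow = TRUE))
  expect_error(count_transitions(c(0L, 1L), 5), "segment")
})

test_that("largest connected set finds the biggest strongly connected block", {
  C <- matrix(0, 5, 5)
  C[1:3, 1:3] <- 1; C[4:5, 4:5] <- 1
  expect_equal(largest_connected_set(C), 0:2)
  expect_equal(largest_connected_set(matrix(1, 4, 4)), 0:3)
  # random sparse matrices vs the reachability oracle
  for (seed in 1:5) {
    set.seed(seed)
    C <- matrix(rbinom(64, 1, 0.2), 8, 8)
    comp <- scc_oracle(C)
    sizes <- table(comp)
    want_size <- max(sizes)
    got <- largest_connected_set(C)
    expect_equal(length(got), as.integer(want_size))
    expect_equal(length(unique(comp[got + 1])), 1L)
  }
})

test_that("reversible MLE reproduces symmetric and two-state closed forms", {
  fit <- reversible_mle(matrix(5, 2, 2))
  expect_equal(fit$T, matrix(0.5, 2, 2), tolerance = 1e-10)
  expect_equal(fit$pi, c(0.5, 0.5), tolerance = 1e-10)
  # any 2-state chain satisfies detailed balance: MLE = row-normalized counts
  C <- matrix(c(90, 10, 20, 80), 2, byrow = TRUE)
  fit2 <- reversible_mle(C)
  expect_equal(fit2$T, C / rowSums(C), tolerance = 1e-8)
})

test_that("reversible MLE beats the symmetrized plug-in estimate in likelihood", {
  loglik <- function(T, C) sum(C[C > 0] * log(T[C > 0]))
  for (seed in 1:5) {
    set.seed(seed)
    C <- matrix(rpois(16, 20) + 1, 4, 4)
    fit <- reversible_mle(C)
    Tsym <- (C + t(C)) / rowSums(C + t(C))
    expect_gte(loglik(fit$T, C), loglik(Tsym, C) - 1e-9)
    # detailed balance to 1e-8
    F <- fit$pi * fit$T
    expect_lt(max(abs(F - t(F))), 1e-8)
    expect_equal(rowSums(fit$T), rep(1, 4), tolerance = 1e-10)
    expect_equal(as.numeric(fit$pi %*% fit$T), fit$pi, tolerance = 1e-8)
  }
})

test_that("a known 5-state chain is recovered within tight tolerances", {
  # reversible birth-death chain
  k <- 5
  T <- diag(rep(0.75, k))
  for (i in 1:(k - 1)) { T[i, i + 1] <- 0.15; T[i + 1, i] <- 0.10 }
  T[1, 1] <- 1 - 0.15; T[k, k] <- 1 - 0.10
  pi_true <- 1.5^(0:4); pi_true <- pi_true / sum(pi_true)
  spec <- markov_chain_spec(T, n_steps = 1e6, seed = 123)
  x <- sample_markov_chain(spec)[[1]]
  m <- markov_model(x, lag = 1)
  expect_equal(length(m$active_set), k)
  expect_lt(max(abs(m$T - T)), 0.01)
  expect_lt(max(abs(m$pi - pi_true)), 0.005)
})

test_that("implied timescales recover the closed form and are lag-invariant", {
  # 2-state chain with lambda2 = 0.8
  T <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  x <- sample_markov_chain(markov_chain_spec(T, 5e5, seed = 7))[[1]]
  its <- implied_timescales(x, lags = c(1, 2, 4), n_its = 1)
  t_true <- -1 / log(0.8)
  expect_equal(its[1, 1], t_true, tolerance = 0.05)
  # Markovian plateau across lags
  expect_lt(max(abs(its[, 1] - t_true)) / t_true, 0.1)
  # eigenvalue near 1 gives an infinity-safe value
  m <- markov_model(x, lag = 1)
  m$eigen$values[2] <- 1 - 1e-15
  expect_true(is.finite(timescales(m, 1)) && timescales(m, 1) > 1e300)
})

test_that("macrostate free energies follow the Boltzmann inversion", {
  expect_equal(macrostate_free_energy(c(0.5, 0.5)), c(0, 0))
  w <- c(exp(-1) / (1 + exp(-1)), 1 / (1 + exp(-1)))
  expect_equal(macrostate_free_energy(w, kT = 1), c(1, 0))
  # brute-force formula and rescaling invariance
  set.seed(52)
  p <- runif(4); p <- p / sum(p)
  g <- macrostate_free_energy(p, temperature = 310)
  kT <- 0.0019872041 * 310
  direct <- -kT * log(p); direct <- direct - min(direct)
  expect_equal(g, direct, tolerance = 1e-12)
  expect_equal(macrostate_free_energy(7 * p, temperature = 310), g,
               tolerance = 1e-12)
  expect_warning(macrostate_free_energy(c(0.5, 0)), "empty")
})

test_that("PCCA+ recovers block structure and degenerate limits", {
  # two 2-state blocks with tiny inter-block rates
  eps <- 1e-4
  C <- matrix(c(500, 450, 1, 1,
                450, 500, 1, 1,
                1, 1, 500, 450,
                1, 1, 450, 500), 4, byrow = TRUE)
  m <- markov_model_from_counts(C, lag = 1)
  p2 <- pcca(m, 2)
  expect_equal(p2$crisp[1], p2$crisp[2])
  expect_equal(p2$crisp[3], p2$crisp[4])
  expect_false(p2$crisp[1] == p2$crisp[3])
  expect_equal(rowSums(p2$memberships), rep(1, 4), tolerance = 1e-10)
  expect_true(all(p2$memberships >= 0 & p2$memberships <= 1))
  # M = k resolves every microstate
  pk <- pcca(m, 4)
  expect_equal(sort(unique(pk$crisp)), 1:4)
  expect_equal(unname(apply(pk$memberships, 1, max)), rep(1, 4),
               tolerance = 1e-6)
  # M = 1 is the trivial partition
  p1 <- pcca(m, 1)
  expect_equal(p1$free_energy, 0)
  # spectral support error
  expect_error(pcca(m, 4 + 1), "M")
})

test_that("Chapman-Kolmogorov validates Markov data and rejects periodic forcing", {
  T <- matrix(c(0.95, 0.05, 0, 0.05, 0.90, 0.05, 0, 0.05, 0.95), 3,
              byrow = TRUE)
  x <- sample_markov_chain(markov_chain_spec(T, 2e5, seed = 9))[[1]]
  m <- markov_model(x, lag = 1)
  sets <- list(0L, 1L, 2L)
  ck <- chapman_kolmogorov(m, sets, factors = 1:5, n_boot = 40, seed = 2)
  expect_true(ck$pass)
  # k = 1: predicted equals estimated identically
  expect_equal(ck$predicted[, , 1], ck$estimated[, , 1], tolerance = 1e-12)
  # period-4 forced labels are strongly non-Markovian at lag 1
  s <- rep(c(0L, 0L, 1L, 1L), 2500)
  mp <- markov_model(s, lag = 1)
  ckp <- chapman_kolmogorov(mp, list(0L, 1L), factors = 1:3, n_boot = 40,
                            seed = 3)
  expect_false(ckp$pass)
  # factors beyond the data are dropped with a warning
  short <- markov_model(x[1:500], lag = 100)
  expect_warning(chapman_kolmogorov(short, sets, factors = c(1, 2, 50),
                                    n_boot = 5, seed = 1), "dropped")
})

test_that("model objects simulate, summarize and serialize", {
  T <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  x <- sample_markov_chain(markov_chain_spec(T, 5e4, seed = 4))[[1]]
  m <- markov_model(x, lag = 1)
  s <- summary(m)
  expect_lt(s$detailed_balance_residual, 1e-8)
  y <- simulate(m, nsim = 1000, seed = 5)
  expect_equal(length(y), 1000)
  expect_identical(y, simulate(m, nsim = 1000, seed = 5))
  f <- tempfile(fileext = ".json")
  write_msm(m, f)
  back <- read_msm(f)
  expect_equal(back$T, m$T, tolerance = 1e-12)
  expect_equal(back$pi, m$pi, tolerance = 1e-12)
})
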