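test_that("the extended system preserves the Boltzmann marginal when unbiased", {
  # with hills off and ABF off the x-marginal is exp(-V/kT): var = kT/k
  r <- meta_eabf("harmonic", grid = c(-4, 4), n_bins = 64, n_steps = 5e5,
                 kT = 0.6, dt = 0.005, hill_height = 0, abf = FALSE,
                 pot_par = list(k = 1.2), seed = 4)
  x <- r$traj[, 1]
  expect_lt(abs(var(x) / (0.6 / 1.2) - 1), 0.05)
  expect_lt(abs(mean(x)), 0.05)
})

test_that("runs are seed-deterministic", {
  a <- meta_eabf("double-well", n_steps = 1e5, seed = 9, pot_par = list(h = 3))
  b <- meta_eabf("double-well", n_steps = 1e5, seed = 9, pot_par = list(h = 3))
  expect_identical(a$traj, b$traj)
  expect_identical(a$counts, b$counts)
})

test_that("the ABF accumulator estimates the analytic mean force", {
  k <- 2; ku <- 120
  r <- meta_eabf("harmonic", grid = c(-2, 2), n_bins = 40, n_steps = 6e6,
                 kT = 0.6, dt = 0.002, ku = ku, hill_height = 0,
                 pot_par = list(k = k), seed = 5)
  ctr <- bin_centers(r)
  # the accumulated spring force ku*(xi - lambda) averages to -A'(lambda):
  # its negation estimates the gradient along lambda, whose exact value for
  # a harmonic well is the spring-mollified curvature k*ku/(k+ku)
  est <- -r$abf_force_sum / pmax(r$abf_counts, 1)
  core <- which(r$abf_counts > 10000 & abs(ctr) > 0.5 & abs(ctr) < 1.4)
  expect_gt(length(core), 10)
  k_eff <- k * ku / (k + ku)
  expect_lt(max(abs(est[core] - k_eff * ctr[core])), 0.05 * k_eff * 1.4)
  # and it tracks the analytic V' = k*xi within 5% on average
  expect_lt(mean(abs(est[core] - k * ctr[core]) / abs(k * ctr[core])), 0.05)
})

test_that("a flat periodic landscape is sampled uniformly and yields a flat PMF", {
  r <- meta_eabf("flat", grid = c(-180, 180), n_bins = 72, periodic = TRUE,
                 n_steps = 8e6, dt = 1, seed = 2)
  occ <- colSums(r$counts)
  expect_lt(max(abs(occ / mean(occ) - 1)), 0.10)
  p <- estimate_pmf(r)
  expect_lt(diff(range(p$dG)), 0.3)
  # periodic closure: the two ends of the profile meet within the error scale
  expect_lt(abs(p$dG[1] - p$dG[nrow(p)]), 0.3)
})

test_that("CZAR recovers a harmonic PMF curvature within 10%", {
  r <- meta_eabf("harmonic", grid = c(-1.5, 1.5), n_bins = 60, n_steps = 1e6,
                 pot_par = list(k = 2), seed = 2)
  p <- estimate_pmf(r)
  fit <- stats::lm(dG ~ I(center^2), data = as.data.frame(p))
  expect_lt(abs(2 * stats::coef(fit)[2] / 2 - 1), 0.10)
})

test_that("a constructed 5 kcal/mol double-well barrier is recovered within 0.5", {
  r <- meta_eabf("double-well", grid = c(-1.6, 1.6), n_bins = 64,
                 n_steps = 2e6, pot_par = list(h = 5, a = 1), seed = 2)
  p <- estimate_pmf(r)
  b <- extract_barriers(p)
  expect_false(b$barrier_free)
  expect_lt(abs(b$forward - 5.0), 0.5)
  expect_lt(abs(b$reverse - 5.0), 0.5)
  # minima near +-1
  expect_equal(sort(abs(b$minima$position))[1:2], c(1, 1), tolerance = 0.15)
  # standard errors come out finite on well-sampled bins
  expect_true(all(is.finite(p$se)))
})

test_that("barrier extraction reads asymmetric, monotone and random profiles", {
  # asymmetric double well shaped like a rotational PMF:
  # minima at 0 and 1.5, maximum 5.3 -> forward 5.3, reverse 3.8
  prof <- c(0, 2.6, 5.3, 3.4, 1.5)
  b <- extract_barriers(prof, centers = c(-80, -20, 10, 50, 90))
  expect_equal(b$forward, 5.3, tolerance = 1e-9)
  expect_equal(b$reverse, 3.8, tolerance = 1e-9)
  # monotone profile is barrier-free
  bm <- extract_barriers(seq(5, 0, length.out = 30), centers = 1:30)
  expect_true(bm$barrier_free)
  expect_equal(bm$forward, 0)
  # random smooth profiles vs an exhaustive grid-scan oracle
  for (seed in 1:4) {
    set.seed(seed)
    xx <- seq(0, 1, length.out = 120)
    gg <- as.numeric(2 * sin(2 * pi * xx * sample(2:4, 1)) +
                     cumsum(rnorm(120, sd = 0.02)))
    bb <- extract_barriers(gg, centers = xx)
    if (!bb$barrier_free) {
      mins <- which(diff(sign(diff(c(Inf, gg, Inf)))) > 0)
      r <- mins[1]; p_ <- mins[length(mins)]
      top <- max(gg[r:p_])
      expect_equal(bb$forward, top - gg[r], tolerance = 1e-9)
      expect_equal(bb$reverse, top - gg[p_], tolerance = 1e-9)
    }
  }
})

test_that("unvisited interior bins are flagged rather than interpolated", {
  r <- meta_eabf("double-well", grid = c(-1.6, 1.6), n_bins = 32,
                 n_steps = 2e5, pot_par = list(h = 3, a = 1), seed = 3)
  # knock out an interior bin: the estimator must refuse to bridge the gap
  r$counts[, 16] <- 0
  expect_error(estimate_pmf(r, min_count = 10), "unvisited")
  # a run that never leaves one well reports too few usable bins
  r2 <- meta_eabf("harmonic", grid = c(-40, 40), n_bins = 64, n_steps = 2e4,
                  hill_height = 0, abf = FALSE, pot_par = list(k = 50),
                  seed = 3)
  expect_error(estimate_pmf(r2, min_count = 200), "fewer than 3 bins")
})

test_that("PMF profiles write to delimited text", {
  r <- meta_eabf("harmonic", grid = c(-1.5, 1.5), n_bins = 30, n_steps = 2e5,
                 pot_par = list(k = 2), seed = 6)
  p <- estimate_pmf(r, min_count = 50)
  f <- tempfile(fileext = ".tsv")
  write_pmf(p, f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(back$dG, p$dG, tolerance = 1e-9)
})
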