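# Extended-system adaptive biasing force + metadynamics (meta-eABF) on a
# 1-D collective variable over analytic potentials, with CZAR free-energy
# estimation and barrier extraction.

#' Run a meta-eABF simulation
#'
#' A fictitious particle lambda is coupled harmonically (stiffness `ku`) to
#' the collective variable xi = x of an overdamped Langevin particle on an
#' analytic potential. An adaptive biasing force (the negative running mean
#' of the spring force in lambda's bin, ramped in over `n_full` samples)
#' plus metadynamics Gaussians deposited along lambda every `hill_stride`
#' steps progressively flatten the sampled landscape. Accumulators for the
#' CZAR estimator (biased marginal of xi and conditional mean spring
#' stretch) are collected in `n_blocks` time blocks for block-average
#' errors.
#'
#' Defaults follow common biasing-engine conventions: `n_full = 200`
#' samples, Gaussian height 0.1 kcal/mol, width 2 bins, stride 1000 steps,
#' fictitious kT equal to the physical kT, and `ku` chosen so the thermal
#' coupling fluctuation `sqrt(kT/ku)` equals one bin width.
#'
#' @param pot One of `"harmonic"`, `"double-well"`, `"flat"` or a 1-D
#'   [potential()] object (`"flat"` is only meaningful with
#'   `periodic = TRUE`).
#' @param grid `c(min, max)` of the CV grid (must cover the reachable range).
#' @param n_bins Number of CV bins.
#' @param periodic Treat the CV as periodic on the grid (angles).
#' @param n_steps Number of integration steps.
#' @param kT Thermal energy (kcal/mol).
#' @param dt,friction Integrator time step and friction (both particles).
#' @param ku Coupling stiffness; default `kT / bin_width^2`.
#' @param n_full ABF ramp-in sample count per bin.
#' @param hill_height,hill_width,hill_stride Metadynamics parameters
#'   (kcal/mol, CV units, steps); `hill_height = 0` disables deposition.
#' @param abf Enable the adaptive biasing force.
#' @param x0 Start position (default grid midpoint or first minimum).
#' @param n_blocks Time blocks for error estimation.
#' @param record_stride Thinning of the returned trajectory.
#' @param seed Integer seed.
#' @param pot_par Parameters forwarded to [potential()].
#' @return An object of class `meta_eabf` holding the accumulators, the
#'   thinned `(x, lambda)` trajectory and all run parameters.
#' @export
meta_eabf <- function(pot = "double-well", grid = c(-1.6, 1.6), n_bins = 64,
                      periodic = FALSE, n_steps = 2e6, kT = kBT(298),
                      dt = 1e-4, friction = 1, ku = NULL, n_full = 200,
                      hill_height = 0.1, hill_width = NULL, hill_stride = 1000,
                      abf = TRUE, x0 = NULL, n_blocks = 5, record_stride = 100,
                      seed = 1L, pot_par = list()) {
  if (identical(pot, "flat")) {
    pobj <- list(id = "flat", cpp_id = 2L, par = numeric(0), dim = 1L,
                 fun = function(x) 0, grad = function(x) 0,
                 minima = matrix(mean(grid), 1, 1))
  } else {
    pobj <- if (inherits(pot, "potential")) pot else potential(pot, pot_par)
    .stop_if(pobj$dim != 1L, "meta-eABF engine handles 1-D potentials")
  }
  bw <- diff(grid) / n_bins
  if (is.null(ku)) ku <- kT / bw^2
  if (is.null(hill_width)) hill_width <- 2 * bw
  if (is.null(x0)) x0 <- pobj$minima[1, 1]
  .stop_if(x0 < grid[1] || x0 > grid[2], "x0 outside the CV grid")
  # stability check on the stiffest harmonic scale present
  .stop_if(dt * ku / friction > 0.5,
           "unstable dt: dt*ku/friction = %.3g > 0.5", dt * ku / friction)
  cpp_pot <- if (identical(pobj$id, "flat")) 0L else pobj$cpp_id
  cpp_par <- if (identical(pobj$id, "flat")) c(k = 0) else pobj$par
  set.seed(.derive_seed(seed, .seed_offsets[["meta_eabf"]]))
  res <- cpp_meta_eabf(cpp_pot, cpp_par, x0, dt, kT, friction, friction,
                       ku, as.integer(n_steps), grid[1], grid[2],
                       as.integer(n_bins), periodic,
                       as.integer(if (abf) n_full else -1L),
                       hill_height, hill_width, as.integer(hill_stride),
                       as.integer(n_blocks), as.integer(record_stride))
  structure(c(res, list(grid = grid, n_bins = n_bins, bin_width = bw,
                        periodic = periodic, kT = kT, ku = ku,
                        potential = pobj, n_steps = n_steps, seed = seed)),
            class = "meta_eabf")
}

#' @export
print.meta_eabf <- function(x, ...) {
  visited <- sum(colSums(x$counts) > 0)
  cat(sprintf("meta-eABF run: %g steps, %d/%d bins visited, %d boundary reflection(s)\n",
              x$n_steps, visited, x$n_bins, x$n_reflections))
  invisible(x)
}

#' Bin centers of a meta-eABF grid
#' @param x A `meta_eabf` object.
#' @export
bin_centers <- function(x) x$grid[1] + (seq_len(x$n_bins) - 0.5) * x$bin_width

#' Estimate the PMF by the CZAR estimator
#'
#' The free-energy gradient along the CV is
#' `A'(xi) = -kT d ln rho(xi)/d xi + ku (<lambda>_xi - xi)` where `rho` is
#' the biased marginal of xi and `<lambda>_xi` the conditional mean of the
#' extended variable; the gradient is integrated by the trapezoid rule and
#' min-shifted to zero. Per-bin standard errors come from block averaging
#' over the run's time blocks. Unvisited interior bins are an error: the
#' profile is never silently interpolated.
#'
#' @param x A `meta_eabf` object.
#' @param min_count Minimum samples per reported bin.
#' @return An object of class `pmf_profile`: data frame columns `center`,
#'   `dG` (kcal/mol, min 0), `se`.
#' @export
estimate_pmf <- function(x, min_count = 200) {
  stopifnot(inherits(x, "meta_eabf"))
  ctr <- bin_centers(x)
  cnt_tot <- colSums(x$counts)
  visited <- which(cnt_tot >= min_count)
  .stop_if(length(visited) < 3, "fewer than 3 bins have %d samples", min_count)
  rng <- range(visited)
  gap <- setdiff(seq(rng[1], rng[2]), visited)
  .stop_if(length(gap) > 0 && !x$periodic,
           "unvisited interior bin(s) at CV = %s: no silent interpolation",
           paste(signif(ctr[gap], 3), collapse = ", "))
  pmf_from <- function(cnt, sdisp) {
    n <- length(cnt)
    lr <- ifelse(cnt > 0, log(cnt), NA_real_)
    grad <- rep(NA_real_, n)
    h <- x$bin_width
    if (x$periodic) {
      ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
      grad <- -x$kT * (lr[ip] - lr[im]) / (2 * h)
    } else {
      grad[2:(n - 1)] <- -x$kT * (lr[3:n] - lr[1:(n - 2)]) / (2 * h)
      grad[1] <- -x$kT * (lr[2] - lr[1]) / h
      grad[n] <- -x$kT * (lr[n] - lr[n - 1]) / h
    }
    grad <- grad + x$ku * ifelse(cnt > 0, sdisp / cnt, NA_real_)
    # trapezoid integration over the visited range
    g <- grad[visited]
    dg <- c(0, cumsum((g[-1] + g[-length(g)]) / 2 * h))
    dg
  }
  dG <- pmf_from(cnt_tot, colSums(x$sum_disp))
  nb <- nrow(x$counts)
  block_pmfs <- matrix(NA_real_, nb, length(visited))
  for (b in seq_len(nb)) {
    ok <- all(x$counts[b, visited] > 0)
    if (!ok) next
    pb <- pmf_from(x$counts[b, ], x$sum_disp[b, ])
    block_pmfs[b, ] <- pb - mean(pb)
  }
  nblk <- sum(stats::complete.cases(block_pmfs))
  se <- if (nblk >= 2)
    apply(block_pmfs, 2, sd, na.rm = TRUE) / sqrt(nblk) else rep(NA_real_, length(visited))
  out <- data.frame(center = ctr[visited], dG = dG - min(dG), se = se)
  structure(out, class = c("pmf_profile", "data.frame"),
            periodic = x$periodic, kT = x$kT)
}

#' @export
plot.pmf_profile <- function(x, ...) {
  plot(x$center, x$dG, type = "l", xlab = "collective variable",
       ylab = expression(Delta * G ~ "(kcal/mol)"), ...)
  if (any(is.finite(x$se)))
    arrows(x$center, x$dG - x$se, x$center, x$dG + x$se,
           angle = 90, code = 3, length = 0.02, col = "grey50")
  invisible(x)
}

#' Write a PMF profile as delimited text
#' @param x A `pmf_profile`.
#' @param file Path.
#' @export
write_pmf <- function(x, file) {
  write.table(as.data.frame(x), file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Extract barrier heights from a free-energy profile
#'
#' Locates local minima and maxima on a binned (optionally periodic)
#' profile. The forward barrier is the highest point between the reactant
#' and product minima minus the reactant minimum; the reverse barrier is
#' the analogue from the product side. A monotone profile is barrier-free
#' (0).
#'
#' @param x A `pmf_profile`, or a numeric profile with `centers`.
#' @param centers Bin centers when `x` is numeric.
#' @param reactant Index (into minima, by position order) of the reactant
#'   minimum; default the first.
#' @param product Index of the product minimum; default the last.
#' @return List: `forward`, `reverse` (kcal/mol), `minima`, `maxima`
#'   (data frames of position and height), `barrier_free` flag.
#' @export
extract_barriers <- function(x, centers = NULL, reactant = 1L, product = NULL) {
  if (inherits(x, "pmf_profile")) {
    g <- x$dG; ctr <- x$center; periodic <- isTRUE(attr(x, "periodic"))
  } else {
    g <- as.numeric(x)
    ctr <- if (is.null(centers)) seq_along(g) else centers
    periodic <- FALSE
  }
  n <- length(g)
  .stop_if(n < 3, "profile too short")
  is_min <- is_max <- logical(n)
  for (i in seq_len(n)) {
    if (!periodic && (i == 1 || i == n)) {
      # endpoints count as extrema of the open profile
      nb <- if (i == 1) g[2] else g[n - 1]
      is_min[i] <- g[i] < nb; is_max[i] <- g[i] > nb
    } else {
      l <- if (i == 1) g[n] else g[i - 1]
      r <- if (i == n) g[1] else g[i + 1]
      is_min[i] <- g[i] <= l && g[i] <= r && (g[i] < l || g[i] < r)
      is_max[i] <- g[i] >= l && g[i] >= r && (g[i] > l || g[i] > r)
    }
  }
  mins <- which(is_min); maxs <- which(is_max)
  if (length(mins) < 2) {
    return(list(forward = 0, reverse = 0,
                minima = data.frame(position = ctr[mins], dG = g[mins]),
                maxima = data.frame(position = ctr[maxs], dG = g[maxs]),
                barrier_free = TRUE))
  }
  ri <- mins[reactant]
  pi_ <- if (is.null(product)) mins[length(mins)] else mins[product]
  between <- if (ri <= pi_) seq(ri, pi_) else seq(pi_, ri)
  top <- max(g[between])
  list(forward = top - g[ri], reverse = top - g[pi_],
       minima = data.frame(position = ctr[mins], dG = g[mins]),
       maxima = data.frame(position = ctr[maxs], dG = g[maxs]),
       barrier_free = FALSE)
}
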