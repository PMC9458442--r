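# Microstate clustering, transition counting, reversible maximum-likelihood
# Markov state model estimation and implied timescales.

# k-means++ seeding (greedy D^2 sampling) for deterministic-given-seed init
.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    p <- d2 / sum(d2)
    centers[j + 1, ] <- X[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j + 1, ])^2))
  }
  centers
}

#' Microstate clustering by k-means
#'
#' Standard k-means with k-means++ initialization at a fixed seed. For long
#' trajectories the centers may be fitted on a uniform subsample
#' (`fit_sample`) and every frame then assigned to its nearest center.
#'
#' @param fs A [feature_series()] (typically TICA projections) or matrix.
#' @param k Number of microstates (>= 2).
#' @param seed Integer seed (global; the clustering seed is derived from it).
#' @param fit_sample Number of frames used for fitting; `NULL` = all.
#' @param iter_max Maximum k-means iterations.
#' @return A `microstates` object: `centers` (k x m), `labels` (0-based,
#'   one per frame), `boundaries`, `inertia`, `k`.
#' @export
kmeans_cluster <- function(fs, k, seed = 1L, fit_sample = NULL,
                           iter_max = 100L) {
  X <- if (inherits(fs, "feature_series")) fs$values else as.matrix(fs)
  boundaries <- if (inherits(fs, "feature_series")) fs$boundaries else 1L
  .stop_if(k < 2, "k must be >= 2")
  .stop_if(nrow(X) < k, "need at least k frames")
  set.seed(.derive_seed(seed, .seed_offsets[["kmeans"]]))
  fit_idx <- if (is.null(fit_sample) || fit_sample >= nrow(X)) seq_len(nrow(X))
             else sort(sample.int(nrow(X), fit_sample))
  Xf <- X[fit_idx, , drop = FALSE]
  init <- .kmeanspp_init(Xf, k)
  if (anyDuplicated(init) > 0)   # degenerate duplicated frames: jitter init
    init <- init + rnorm(length(init), sd = 1e-8 + sd(Xf) * 1e-6)
  km <- suppressWarnings(stats::kmeans(Xf, centers = init,
                                       iter.max = iter_max, algorithm = "Lloyd"))
  labels <- cpp_assign_centers(X, km$centers)
  inertia <- sum((X - km$centers[labels + 1L, , drop = FALSE])^2)
  structure(list(centers = km$centers, labels = labels,
                 boundaries = boundaries, inertia = inertia, k = as.integer(k)),
            class = "microstates")
}

#' @export
print.microstates <- function(x, ...) {
  cat(sprintf("microstates: k = %d over %d frames, inertia %.4g\n",
              x$k, length(x$labels), x$inertia))
  invisible(x)
}

# normalize the many accepted discrete-trajectory inputs to a list of
# integer vectors of 0-based labels
.as_dtraj_list <- function(labels, boundaries = NULL) {
  if (inherits(labels, "microstates"))
    return(.as_dtraj_list(labels$labels, labels$boundaries))
  if (is.list(labels)) return(lapply(labels, as.integer))
  labels <- as.integer(labels)
  if (is.null(boundaries)) boundaries <- 1L
  lapply(.segment_rows(length(labels), as.integer(boundaries)),
         function(r) labels[r])
}

#' Count microstate transitions at a lag
#'
#' Sliding-window counts `Cij = #{(t, t+lag): s(t)=i, s(t+lag)=j}` within
#' each segment; pairs never straddle segment boundaries.
#'
#' @param labels A `microstates` object, a list of integer vectors, or one
#'   integer vector (0-based states) with optional `boundaries`.
#' @param lag Lag in frames (>= 1).
#' @param n_states Matrix size; default `max(label) + 1`.
#' @param boundaries Segment starts when `labels` is a plain vector.
#' @return `n_states x n_states` count matrix.
#' @export
count_transitions <- function(labels, lag, n_states = NULL, boundaries = NULL) {
  dtrajs <- .as_dtraj_list(labels, boundaries)
  lag <- as.integer(lag)
  .stop_if(lag < 1, "lag must be >= 1")
  .stop_if(all(lengths(dtrajs) <= lag),
           "lag %d is not shorter than any segment", lag)
  if (is.null(n_states)) n_states <- max(unlist(dtrajs)) + 1L
  C <- matrix(0, n_states, n_states)
  for (s in dtrajs) {
    if (length(s) <= lag) next
    from <- s[seq_len(length(s) - lag)]
    to <- s[-seq_len(lag)]
    idx <- from * n_states + to + 1L        # row-major linear index
    C <- C + matrix(tabulate(idx, nbins = n_states^2), n_states,
                    byrow = TRUE)
  }
  unname(C)
}

#' Largest strongly connected set of a count matrix
#'
#' Vertices of the largest strongly connected component of the directed
#' graph with an edge wherever `Cij > 0`. Ties are broken in favour of the
#' component with the larger total count.
#'
#' @param C Non-negative square count matrix.
#' @return Sorted 0-based state indices.
#' @export
largest_connected_set <- function(C) {
  .stop_if(nrow(C) != ncol(C) || any(C < 0), "C must be non-negative square")
  g <- igraph::graph_from_adjacency_matrix(C > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")$membership
  sizes <- table(comp)
  big <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(big) > 1) {
    wt <- vapply(big, function(cl) sum(C[comp == cl, comp == cl]), numeric(1))
    big <- big[which.max(wt)]
  }
  sort(which(comp == big[1])) - 1L
}

#' Reversible maximum-likelihood transition matrix
#'
#' Maximizes the likelihood `prod Tij^Cij` subject to detailed balance
#' `pi_i Tij = pi_j Tji` by the standard self-consistent fixed-point
#' iteration on symmetric pair weights `x_ij`.
#'
#' @param C Count matrix restricted to an irreducible state set.
#' @param tol Convergence threshold on the max relative change of `pi`.
#' @param max_iter Maximum sweeps.
#' @return List with `T` (row-stochastic), `pi` (stationary distribution).
#' @export
reversible_mle <- function(C, tol = 1e-10, max_iter = 1e6) {
  k <- nrow(C)
  Cs <- C + t(C)
  ci <- rowSums(C)
  .stop_if(any(ci == 0), "state with no outgoing counts: restrict to the connected set")
  x <- Cs / sum(Cs)           # initial symmetric weights
  xi <- rowSums(x)
  for (it in seq_len(max_iter)) {
    denom <- outer(ci / xi, ci / xi, `+`)
    x_new <- Cs / denom
    x_new <- x_new / sum(x_new)
    xi_new <- rowSums(x_new)
    delta <- max(abs(xi_new - xi) / pmax(xi_new, 1e-300))
    x <- x_new; xi <- xi_new
    if (delta < tol) {
      T <- x / xi
      diag(T)[rowSums(x) == 0] <- 1
      return(list(T = T, pi = xi / sum(xi), iterations = it))
    }
  }
  stop(sprintf("reversible MLE did not converge: last residual %.3e", delta),
       call. = FALSE)
}

# eigendecomposition of a reversible T via the pi-symmetrized matrix;
# returns real eigenvalues (descending) and left/right eigenvectors
.rev_eigen <- function(T, pi) {
  s <- sqrt(pi)
  S <- (T * outer(s, 1 / s))
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  ord <- order(es$values, decreasing = TRUE)
  vals <- es$values[ord]
  Y <- es$vectors[, ord, drop = FALSE]
  right <- Y / s
  left <- Y * s
  # normalize: right eigenvector 1 is the constant, left 1 is pi
  sc <- right[1, 1]
  right <- right / sc; left <- left * sc
  list(values = vals, right = right, left = left)
}

#' Estimate a reversible Markov state model
#'
#' Counts sliding-window transitions at the given lag, restricts to the
#' largest strongly connected set, and fits the reversible
#' maximum-likelihood transition matrix with its stationary distribution
#' and spectrum.
#'
#' @param labels Discrete trajectories (see [count_transitions()]).
#' @param lag Lag time in frames.
#' @param boundaries Segment starts when `labels` is a plain vector.
#' @param dt Physical time per frame (for reporting only).
#' @return An object of class `msm`: `T`, `pi`, `active_set` (0-based
#'   original state indices), `count_matrix` (full), `eigen`
#'   (values/left/right), `lag`, `dtrajs`.
#' @export
markov_model <- function(labels, lag = 1L, boundaries = NULL, dt = 1) {
  dtrajs <- .as_dtraj_list(labels, boundaries)
  C <- count_transitions(dtrajs, lag)
  active <- largest_connected_set(C)
  Ca <- C[active + 1L, active + 1L, drop = FALSE]
  fit <- reversible_mle(Ca)
  eg <- .rev_eigen(fit$T, fit$pi)
  structure(list(T = fit$T, pi = fit$pi, active_set = active,
                 count_matrix = C, eigen = eg, lag = as.integer(lag),
                 dt = dt, dtrajs = dtrajs,
                 n_states_total = nrow(C)),
            class = "msm")
}

#' @rdname markov_model
#' @param C A precomputed count matrix (for workflows that already counted
#'   transitions).
#' @export
markov_model_from_counts <- function(C, lag = 1L, dt = 1) {
  active <- largest_connected_set(C)
  Ca <- C[active + 1L, active + 1L, drop = FALSE]
  fit <- reversible_mle(Ca)
  eg <- .rev_eigen(fit$T, fit$pi)
  structure(list(T = fit$T, pi = fit$pi, active_set = active,
                 count_matrix = C, eigen = eg, lag = as.integer(lag),
                 dt = dt, dtrajs = NULL, n_states_total = nrow(C)),
            class = "msm")
}

#' @export
print.msm <- function(x, ...) {
  cat(sprintf("Reversible MSM: %d/%d states in the active set, lag = %d frame(s)\n",
              length(x$active_set), x$n_states_total, x$lag))
  cat("leading eigenvalues:",
      paste(sprintf("%.4f", head(x$eigen$values, 5)), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.msm <- function(object, n_timescales = 5, ...) {
  ts <- timescales(object, n_timescales)
  out <- list(n_active = length(object$active_set),
              lag = object$lag, timescales = ts,
              pi_range = range(object$pi),
              detailed_balance_residual =
                max(abs(object$pi * object$T - t(object$pi * object$T))))
  class(out) <- "summary.msm"
  out
}

#' @export
print.summary.msm <- function(x, ...) {
  cat(sprintf("MSM with %d active states at lag %d\n", x$n_active, x$lag))
  cat("implied timescales (frames):",
      paste(sprintf("%.3g", x$timescales), collapse = " "), "\n")
  cat(sprintf("detailed-balance residual: %.2e\n", x$detailed_balance_residual))
  invisible(x)
}

#' Stationary distribution
#' @param object An `msm`.
#' @param ... Unused.
#' @return Stationary probabilities over the active set.
#' @export
stationary_distribution <- function(object, ...) {
  stopifnot(inherits(object, "msm"))
  object$pi
}

#' Implied relaxation timescales of a fitted model
#'
#' `t_i = -lag / log(lambda_i)` for the eigenvalues below the stationary
#' one. Non-positive eigenvalues are excluded; eigenvalues within 1e-12 of
#' 1 give an infinity-safe large value.
#'
#' @param object An `msm`.
#' @param n Number of timescales.
#' @return Numeric vector in frames.
#' @export
timescales <- function(object, n = 5) {
  lam <- object$eigen$values[-1]
  lam <- lam[lam > 0]
  lam <- head(lam, n)
  ifelse(lam >= 1 - 1e-12, .Machine$double.xmax, -object$lag / log(lam))
}

#' Implied timescales across lag times
#'
#' Re-estimates the model at each lag and tabulates the slowest implied
#' timescales; a plateau across lags indicates Markovian behaviour at that
#' lag. Eigenvalues that are non-positive are excluded (their count is
#' reported in attribute `"n_excluded"`).
#'
#' @param labels Discrete trajectories (see [count_transitions()]).
#' @param lags Integer vector of lags (>= 2 values recommended).
#' @param n_its Number of timescales per lag.
#' @param boundaries Segment starts for plain-vector input.
#' @return Matrix `length(lags) x n_its` with rownames = lags; attribute
#'   `"plateau"` flags lags whose slowest timescale is within 10% of the
#'   next lag's.
#' @export
implied_timescales <- function(labels, lags, n_its = 5, boundaries = NULL) {
  dtrajs <- .as_dtraj_list(labels, boundaries)
  lags <- sort(as.integer(lags))
  n_excluded <- 0L
  out <- matrix(NA_real_, length(lags), n_its,
                dimnames = list(lags, paste0("t", seq_len(n_its) + 1L)))
  for (i in seq_along(lags)) {
    m <- markov_model(dtrajs, lag = lags[i])
    lam <- m$eigen$values[-1]
    n_excluded <- n_excluded + sum(lam <= 0)
    ts <- timescales(m, n_its)
    out[i, seq_along(ts)] <- ts
  }
  if (n_excluded > 0)
    warning(sprintf("%d non-positive eigenvalue(s) excluded", n_excluded))
  if (length(lags) > 1) {
    rel <- abs(diff(out[, 1])) / out[-nrow(out), 1]
    attr(out, "plateau") <- c(rel < 0.1, NA)
  }
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Simulate a discrete trajectory from a fitted model
#'
#' @param object An `msm`.
#' @param nsim Number of steps.
#' @param seed Integer seed.
#' @param start Start state (0-based index into the active set); default
#'   drawn from the stationary distribution.
#' @param ... Unused.
#' @return Integer vector of 0-based active-set state indices.
#' @export
simulate.msm <- function(object, nsim = 1000, seed = 1L, start = NULL, ...) {
  set.seed(.derive_seed(seed, .seed_offsets[["markov"]]))
  if (is.null(start)) start <- sample.int(length(object$pi), 1, prob = object$pi) - 1L
  cpp_sample_markov_chain(object$T, as.integer(nsim), as.integer(start))
}

#' Serialize / restore an MSM as JSON
#' @param object An `msm`.
#' @param file Path.
#' @export
write_msm <- function(object, file) {
  obj <- object[c("T", "pi", "active_set", "count_matrix", "lag", "dt")]
  jsonlite::write_json(obj, file, digits = NA, matrix = "rowmajor", auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_msm
#' @export
read_msm <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  obj$T <- as.matrix(obj$T); obj$count_matrix <- as.matrix(obj$count_matrix)
  obj$eigen <- .rev_eigen(obj$T, obj$pi)
  obj$n_states_total <- nrow(obj$count_matrix)
  structure(obj, class = "msm")
}
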