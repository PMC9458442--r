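# Transition path theory: committors, reactive flux, rates, and pathway
# decomposition between source and sink state sets.

#' Forward and backward committors
#'
#' The forward committor q+ solves the discrete boundary-value problem
#' `sum_j Tij q+_j = q+_i` for states outside A and B, with q+ = 0 on A and
#' 1 on B, by a direct linear solve. The backward committor is computed on
#' the time-reversed chain; for reversible models it equals `1 - q+`.
#'
#' @param object An [markov_model()] fit, or a list with `T` and `pi`.
#' @param A,B Disjoint non-empty 0-based state index sets (indices into the
#'   active set / rows of `T`).
#' @return List with `q_plus` and `q_minus`.
#' @export
committor <- function(object, A, B) {
  T <- object$T; pi <- object$pi
  k <- nrow(T)
  A <- as.integer(A); B <- as.integer(B)
  .stop_if(length(A) == 0 || length(B) == 0, "A and B must be non-empty")
  .stop_if(length(intersect(A, B)) > 0, "A and B must be disjoint")
  .stop_if(any(c(A, B) < 0 | c(A, B) >= k), "state index out of range [0, %d)", k)
  if (length(A) + length(B) == k)
    warning("A and B cover all states: committor is trivially 0/1")
  solve_bvp <- function(Tm, src, snk) {
    q <- numeric(k); q[snk + 1] <- 1
    free <- setdiff(seq_len(k), c(src, snk) + 1L)
    if (length(free) > 0) {
      Am <- diag(length(free)) - Tm[free, free, drop = FALSE]
      b <- rowSums(Tm[free, snk + 1L, drop = FALSE])
      q[free] <- solve(Am, b)
    }
    q
  }
  q_plus <- solve_bvp(T, A, B)
  Trev <- t(T * pi) / pi      # time-reversed transition matrix
  q_minus <- solve_bvp(Trev, B, A)
  list(q_plus = q_plus, q_minus = q_minus)
}

#' Monte-Carlo committor estimate
#'
#' Estimates the forward committor by direct chain simulation: the fraction
#' of `n_rep` chains started in each state that reach B before A. A
#' simulation-based cross-check for [committor()].
#'
#' @param T Row-stochastic transition matrix.
#' @param A,B Disjoint 0-based source and sink sets.
#' @param n_rep Replicates per start state.
#' @param max_steps Cap on chain length per replicate.
#' @param seed Integer seed.
#' @return Estimated forward committor per state.
#' @export
mc_committor <- function(T, A, B, n_rep = 10000, max_steps = 10000, seed = 1L) {
  set.seed(.derive_seed(seed, .seed_offsets[["mc_oracle"]]))
  cpp_hitting_prob(T, as.integer(A), as.integer(B),
                   as.integer(n_rep), as.integer(max_steps))
}

#' Reactive flux network between two state sets
#'
#' Gross flux `f_ij = pi_i q-_i Tij q+_j` (i != j), net flux
#' `f+_ij = max(0, f_ij - f_ji)`, total A->B flux `F` (flow out of A in the
#' net network) and rate `F / sum_i pi_i q-_i`, all per lag time.
#'
#' @param object A fitted [markov_model()].
#' @param A,B Disjoint 0-based source and sink sets (active-set indices).
#' @return An object of class `tpt`: committors, `gross`, `net`,
#'   `total_flux`, `rate`, `A`, `B`, `pi`, `lag`, `dt`.
#' @export
tpt <- function(object, A, B) {
  stopifnot(inherits(object, "msm"))
  qq <- committor(object, A, B)
  T <- object$T; pi <- object$pi; k <- nrow(T)
  gross <- outer(pi * qq$q_minus, qq$q_plus) * T
  diag(gross) <- 0
  net <- pmax(gross - t(gross), 0)
  Fr <- sum(net[A + 1L, , drop = FALSE])
  rate <- Fr / sum(pi * qq$q_minus)
  structure(list(q_plus = qq$q_plus, q_minus = qq$q_minus,
                 gross = gross, net = net, total_flux = Fr, rate = rate,
                 A = as.integer(A), B = as.integer(B), pi = pi,
                 lag = object$lag, dt = object$dt),
            class = "tpt")
}

#' @export
print.tpt <- function(x, ...) {
  cat(sprintf("TPT flux network: |A| = %d, |B| = %d over %d states\n",
              length(x$A), length(x$B), length(x$q_plus)))
  cat(sprintf("total A->B flux %.4g per lag, rate %.4g per lag\n",
              x$total_flux, x$rate))
  invisible(x)
}

#' Construct a flux network directly from a net flux matrix
#'
#' For analyses that start from an externally specified (e.g. literature)
#' net flux network rather than a fitted model. Total flux is the flow out
#' of A.
#'
#' @param net Non-negative net flux matrix (0-based states = row index - 1).
#' @param A,B Disjoint 0-based source and sink sets.
#' @return A `tpt` object (committors unset).
#' @export
flux_network <- function(net, A, B) {
  net <- as.matrix(net)
  .stop_if(any(net < 0), "net flux must be non-negative")
  structure(list(q_plus = NULL, q_minus = NULL, gross = NULL, net = net,
                 total_flux = sum(net[as.integer(A) + 1L, , drop = FALSE]),
                 rate = NA_real_, A = as.integer(A), B = as.integer(B),
                 pi = NULL, lag = 1L, dt = 1),
            class = "tpt")
}

# is any state of B reachable from any state of A using edges of W > 0?
# deterministic BFS expanding neighbours in ascending state order
.bfs_path <- function(W, A, B) {
  k <- nrow(W)
  inB <- logical(k); inB[B + 1L] <- TRUE
  parent <- rep(NA_integer_, k)
  visited <- logical(k)
  queue <- sort(A + 1L)
  visited[queue] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    if (inB[v]) {
      path <- v
      while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
      return(path - 1L)
    }
    nb <- which(W[v, ] > 0 & !visited)
    if (length(nb) > 0) {
      visited[nb] <- TRUE
      parent[nb] <- v
      queue <- c(queue, nb)
    }
  }
  NULL
}

#' Decompose net flux into pathways
#'
#' Iterative bottleneck (widest-path) decomposition: repeatedly find the
#' A->B path whose minimum edge flux (capacity) is maximal (ties broken by
#' fewer edges via breadth-first search expanding states in ascending
#' order), subtract its capacity from its edges, and record
#' `fraction = capacity / total_flux`. An exhaustive decomposition
#' reconstructs the net flux matrix exactly and its fractions sum to 1.
#'
#' @param x A `tpt` object (from [tpt()] or [flux_network()]).
#' @param max_paths Stop after this many paths.
#' @param fraction Stop once the cumulative fraction reaches this value.
#' @return Data frame with columns `path` (dash-separated 0-based states),
#'   `flux`, `fraction`; attribute `"residual_flux"` holds what remains.
#' @export
decompose_pathways <- function(x, max_paths = Inf, fraction = 1) {
  stopifnot(inherits(x, "tpt"))
  W <- x$net
  # keep only edges that can carry A->B reactive flux
  W[, x$A + 1L] <- 0
  W[x$B + 1L, ] <- 0
  Ftot <- x$total_flux
  paths <- character(0); fluxes <- numeric(0)
  cum <- 0
  while (length(paths) < max_paths && cum < fraction - 1e-12) {
    edges <- sort(unique(W[W > 0]))
    if (length(edges) == 0) break
    # largest capacity c such that A->B is connected on edges >= c
    lo <- 1L; hi <- length(edges); best <- NULL
    while (lo <= hi) {
      mid <- (lo + hi) %/% 2L
      sub <- W; sub[sub < edges[mid]] <- 0
      p <- .bfs_path(sub, x$A, x$B)
      if (!is.null(p)) { best <- p; lo <- mid + 1L } else hi <- mid - 1L
    }
    if (is.null(best)) break
    idx <- cbind(best[-length(best)] + 1L, best[-1] + 1L)
    cap <- min(W[idx])
    W[idx] <- W[idx] - cap
    paths <- c(paths, paste(best, collapse = "-"))
    fluxes <- c(fluxes, cap)
    cum <- cum + cap / Ftot
  }
  if (length(paths) == 0)
    warning("A and B are disconnected in the net flux network")
  out <- data.frame(path = paths, flux = fluxes,
                    fraction = if (Ftot > 0) fluxes / Ftot else NA_real_,
                    stringsAsFactors = FALSE)
  attr(out, "residual_flux") <- sum(W[x$A + 1L, , drop = FALSE])
  out
}

#' Coarse-grain a flux network onto a macrostate partition
#'
#' Sums micro net fluxes over partition blocks and reports per-pair rates.
#' The pair rate from macrostate I to J is the block flux divided by the
#' stationary weight of I (per lag time); with `ns_per_frame` given, rates
#' are also converted to physical inverse nanoseconds.
#'
#' @param x A `tpt` object from [tpt()].
#' @param partition A [pcca()] partition or integer vector of macrostate
#'   labels (1..M) per active microstate.
#' @param ns_per_frame Physical time per frame (optional).
#' @return List with `flux` (M x M macro net flux), `rate_per_lag`,
#'   optionally `rate_per_ns`, `A_macro`, `B_macro`, `total_flux`.
#' @export
coarse_grain_flux <- function(x, partition, ns_per_frame = NULL) {
  stopifnot(inherits(x, "tpt"))
  crisp <- if (inherits(partition, "pcca")) partition$crisp else as.integer(partition)
  .stop_if(length(crisp) != nrow(x$net),
           "partition covers %d states but the flux network has %d",
           length(crisp), nrow(x$net))
  M <- max(crisp)
  Fm <- matrix(0, M, M)
  for (I in seq_len(M)) for (J in seq_len(M)) if (I != J)
    Fm[I, J] <- sum(x$net[crisp == I, crisp == J, drop = FALSE])
  pi_macro <- if (is.null(x$pi)) rep(NA_real_, M) else
    vapply(seq_len(M), function(I) sum(x$pi[crisp == I]), numeric(1))
  rate <- Fm / pi_macro
  out <- list(flux = Fm, rate_per_lag = rate,
              A_macro = sort(unique(crisp[x$A + 1L])),
              B_macro = sort(unique(crisp[x$B + 1L])),
              pi_macro = pi_macro, total_flux = x$total_flux)
  if (!is.null(ns_per_frame)) out$rate_per_ns <- rate / (x$lag * ns_per_frame)
  out
}

#' Serialize a flux network to JSON
#' @param x A `tpt` object.
#' @param file Path.
#' @param pathways Optional result of [decompose_pathways()].
#' @export
write_tpt <- function(x, file, pathways = NULL) {
  obj <- list(A = x$A, B = x$B, q_plus = x$q_plus, q_minus = x$q_minus,
              net = x$net, total_flux = x$total_flux, rate = x$rate)
  if (!is.null(pathways)) obj$pathways <- pathways
  jsonlite::write_json(obj, file, digits = NA, matrix = "rowmajor",
                       auto_unbox = TRUE, dataframe = "rows")
  invisible(file)
}
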