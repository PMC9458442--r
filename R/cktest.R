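# Chapman-Kolmogorov validation: does the model estimated at lag tau,
# propagated as T(tau)^k, predict what a model re-estimated at lag k*tau
# measures on the macrostate sets?

# set-to-set transition probabilities p_IJ = sum_{i in I} pi_i [Tk]_{i,J} / pi_I
# sets are lists of 0-based original microstate ids
.set_probs <- function(T, pi, active, sets, k = 1L) {
  Tk <- T
  if (k > 1) for (i in seq_len(k - 1)) Tk <- Tk %*% T
  M <- length(sets)
  P <- matrix(NA_real_, M, M)
  for (I in seq_len(M)) {
    ii <- match(intersect(sets[[I]], active), active)
    if (length(ii) == 0) next
    wi <- pi[ii] / sum(pi[ii])
    for (J in seq_len(M)) {
      jj <- match(intersect(sets[[J]], active), active)
      if (length(jj) == 0) { P[I, J] <- NA_real_; next }
      P[I, J] <- sum(wi * rowSums(Tk[ii, jj, drop = FALSE]))
    }
  }
  P
}

# crisp pcca partition -> list of original 0-based microstate id sets
.macro_sets <- function(partition) {
  if (inherits(partition, "pcca"))
    return(lapply(seq_len(partition$M),
                  function(I) partition$active_set[partition$crisp == I]))
  .stop_if(!is.list(partition), "partition must be a pcca object or list of state sets")
  partition
}

# bootstrap replicas of the discrete trajectories: resample whole segments
# when several are available, otherwise contiguous blocks of one segment
.bootstrap_dtrajs <- function(dtrajs, min_len, n_blocks = 20L) {
  if (length(dtrajs) >= 2) {
    return(dtrajs[sample.int(length(dtrajs), length(dtrajs), replace = TRUE)])
  }
  s <- dtrajs[[1]]
  bl <- max(min_len + 1L, length(s) %/% n_blocks)
  starts <- seq(1L, length(s) - bl + 1L, by = bl)
  picked <- sample(starts, length(starts), replace = TRUE)
  lapply(picked, function(a) s[a:(a + bl - 1L)])
}

#' Chapman-Kolmogorov test
#'
#' Compares, for each lag multiple k in `factors`, the macrostate
#' self-transition probabilities predicted by propagating the model
#' (`T(tau)^k`) against those estimated by refitting the model at lag
#' `k*tau`. Uncertainty bands on the prediction come from trajectory
#' bootstrap resampling; the test passes when every estimated
#' per-macrostate probability lies within the band.
#'
#' @param object A fitted [markov_model()].
#' @param partition A [pcca()] partition or list of 0-based microstate sets.
#' @param factors Integer lag multiples (k = 1 is the identity check).
#' @param n_boot Bootstrap replicates for the confidence bands.
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `cktest`: arrays `predicted`, `estimated`,
#'   `lower`, `upper` of dimension `M x M x length(factors)`, logical
#'   `pass`, and the factors actually used.
#' @export
chapman_kolmogorov <- function(object, partition, factors = 1:5,
                               n_boot = 100, conf = 0.95, seed = 1L) {
  stopifnot(inherits(object, "msm"))
  sets <- .macro_sets(partition)
  M <- length(sets)
  factors <- sort(unique(as.integer(factors)))
  .stop_if(any(factors < 1), "factors must be >= 1")
  max_seg <- max(lengths(object$dtrajs))
  usable <- factors[factors * object$lag < max_seg]
  if (length(usable) < length(factors))
    warning(sprintf("factor(s) %s exceed the longest segment and were dropped",
                    paste(setdiff(factors, usable), collapse = ",")))
  factors <- usable
  K <- length(factors)
  dims <- c(M, M, K)
  pred <- est <- lo <- hi <- array(NA_real_, dims)
  for (ki in seq_len(K)) {
    k <- factors[ki]
    pred[, , ki] <- .set_probs(object$T, object$pi, object$active_set, sets, k)
    mk <- if (k == 1) object else markov_model(object$dtrajs, lag = k * object$lag)
    est[, , ki] <- .set_probs(mk$T, mk$pi, mk$active_set, sets, 1L)
  }
  # bootstrap the lag-tau model, propagate each replica
  set.seed(.derive_seed(seed, .seed_offsets[["bootstrap"]]))
  boot <- array(NA_real_, c(M, M, K, n_boot))
  for (b in seq_len(n_boot)) {
    db <- .bootstrap_dtrajs(object$dtrajs, object$lag)
    mb <- try(markov_model(db, lag = object$lag), silent = TRUE)
    if (inherits(mb, "try-error")) next
    for (ki in seq_len(K))
      boot[, , ki, b] <- .set_probs(mb$T, mb$pi, mb$active_set, sets, factors[ki])
  }
  a <- (1 - conf) / 2
  for (ki in seq_len(K)) for (I in seq_len(M)) for (J in seq_len(M)) {
    v <- boot[I, J, ki, ]
    v <- v[is.finite(v)]
    if (length(v) > 0) {
      lo[I, J, ki] <- quantile(v, a, names = FALSE)
      hi[I, J, ki] <- quantile(v, 1 - a, names = FALSE)
    }
  }
  diag_ok <- vapply(seq_len(K), function(ki) {
    d_est <- diag(est[, , ki]); d_lo <- diag(lo[, , ki]); d_hi <- diag(hi[, , ki])
    all(d_est >= d_lo - 1e-12 & d_est <= d_hi + 1e-12, na.rm = TRUE)
  }, logical(1))
  structure(list(factors = factors, predicted = pred, estimated = est,
                 lower = lo, upper = hi, pass_by_factor = diag_ok,
                 pass = all(diag_ok), conf = conf, M = M),
            class = "cktest")
}

#' @export
print.cktest <- function(x, ...) {
  cat(sprintf("Chapman-Kolmogorov test, %d macrostates, factors %s: %s\n",
              x$M, paste(x$factors, collapse = ","),
              if (x$pass) "PASS" else "FAIL"))
  for (ki in seq_along(x$factors)) {
    cat(sprintf(" k=%d  pred(diag): %s | est: %s\n", x$factors[ki],
                paste(sprintf("%.3f", diag(x$predicted[, , ki])), collapse = " "),
                paste(sprintf("%.3f", diag(x$estimated[, , ki])), collapse = " ")))
  }
  invisible(x)
}

#' @export
plot.cktest <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, x$M), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (I in seq_len(x$M)) {
    pr <- x$predicted[I, I, ]; es <- x$estimated[I, I, ]
    lo <- x$lower[I, I, ]; hi <- x$upper[I, I, ]
    plot(x$factors, pr, type = "b", ylim = range(c(pr, es, lo, hi), na.rm = TRUE),
         xlab = "lag multiple k", ylab = sprintf("p%d%d(k tau)", I, I),
         main = sprintf("macrostate %d", I), ...)
    lines(x$factors, es, type = "b", lty = 2, col = 2)
    lines(x$factors, lo, lty = 3); lines(x$factors, hi, lty = 3)
  }
  invisible(x)
}
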