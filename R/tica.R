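# Time-lagged independent component analysis: the linear reduction that
# extracts the slowest-decorrelating combinations of input features by
# solving the generalized eigenproblem C(tau) U = C(0) U Lambda.

#' Instantaneous and time-lagged covariance matrices
#'
#' For mean-free data r(t), `Cij(tau) = <ri(t) rj(t+tau)>` averaged over all
#' lagged pairs `t = 1 .. N - tau` within each segment (pairs never straddle
#' segment boundaries; the normalization is the number of lagged pairs).
#' With `reversible = TRUE` (default) the symmetrized equilibrium estimator
#' is used: both time directions contribute, which makes `Ctau` symmetric
#' and all TICA eigenvalues real.
#'
#' @param fs A mean-free [feature_series()].
#' @param lag Lag time in frames (>= 1, shorter than every segment).
#' @param reversible Use the symmetrized estimator.
#' @return List with matrices `C0` and `Ctau` and the pair count `n_pairs`.
#' @export
time_lagged_covariances <- function(fs, lag, reversible = TRUE) {
  stopifnot(inherits(fs, "feature_series"))
  lag <- as.integer(lag)
  .stop_if(lag < 1, "lag must be >= 1")
  X <- fs$values
  segs <- .segment_rows(nrow(X), fs$boundaries)
  lens <- lengths(segs)
  short <- which(lens <= lag)
  .stop_if(length(short) > 0,
           "segment %d (length %d) is not longer than lag %d",
           short[1], lens[short[1]], lag)
  d <- ncol(X)
  C0 <- matrix(0, d, d); Ct <- matrix(0, d, d); n <- 0
  for (rows in segs) {
    a <- X[rows[seq_len(length(rows) - lag)], , drop = FALSE]
    b <- X[rows[-seq_len(lag)], , drop = FALSE]
    if (reversible) {
      C0 <- C0 + (crossprod(a) + crossprod(b)) / 2
      Ct <- Ct + (crossprod(a, b) + crossprod(b, a)) / 2
    } else {
      C0 <- C0 + crossprod(a)
      Ct <- Ct + crossprod(a, b)
    }
    n <- n + nrow(a)
  }
  C0 <- C0 / n; Ct <- (Ct + t(Ct)) / (2 * n)
  dimnames(C0) <- dimnames(Ct) <- NULL
  list(C0 = C0, Ctau = Ct, n_pairs = n)
}

#' Solve the TICA generalized eigenproblem
#'
#' Solves `Ctau U = C0 U Lambda` by whitening with a truncated inverse
#' square root of `C0`: eigendirections of `C0` with eigenvalue below
#' `epsilon * trace(C0)` are dropped (pairwise-distance features are
#' strongly collinear). Eigenpairs are sorted by descending eigenvalue;
#' each eigenvector's largest-magnitude component is made positive, and
#' columns are C0-orthonormal.
#'
#' @param C0,Ctau Covariance matrices from [time_lagged_covariances()].
#' @param epsilon Relative truncation floor for `C0` eigenvalues.
#' @return List with `values`, `vectors` (d x m), and `n_dropped`.
#' @export
solve_tica <- function(C0, Ctau, epsilon = 1e-10) {
  e0 <- eigen((C0 + t(C0)) / 2, symmetric = TRUE)
  keep <- e0$values > epsilon * sum(abs(e0$values))
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("solve_tica: dropped %d rank-deficient dimension(s)", n_dropped))
  .stop_if(!any(keep), "C0 is numerically zero")
  W <- e0$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[keep]), sum(keep))
  M <- t(W) %*% Ctau %*% W
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(es$values, decreasing = TRUE)
  U <- W %*% es$vectors[, ord, drop = FALSE]
  lam <- es$values[ord]
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  list(values = lam, vectors = U, n_dropped = n_dropped)
}

#' Fit a TICA model
#'
#' Centers the data, estimates lagged covariances, solves the generalized
#' eigenproblem and fixes the output dimension either directly (`dim`) or
#' by cumulative kinetic variance: the smallest m with
#' `sum(lambda_i^2, i <= m) / sum(lambda_i^2 over positive lambda) >=
#' var_frac`.
#'
#' @param fs A [feature_series()] (centered internally if needed).
#' @param lag Lag time in frames.
#' @param dim Number of components to retain, or `NULL`.
#' @param var_frac Kinetic variance fraction in (0, 1], used when `dim` is
#'   `NULL` (default 0.9).
#' @param scale Scale projections by eigenvalues (kinetic map); default off.
#' @param reversible,epsilon See [time_lagged_covariances()], [solve_tica()].
#' @return An object of class `tica` with fields `lag`, `mean`, `C0`,
#'   `Ctau`, `values`, `vectors`, `m`, `kinetic_variance`.
#' @export
tica <- function(fs, lag, dim = NULL, var_frac = 0.9, scale = FALSE,
                 reversible = TRUE, epsilon = 1e-10) {
  stopifnot(inherits(fs, "feature_series"))
  mu <- colMeans(fs$values)
  fs_c <- if (max(abs(mu)) > 1e-12) mean_free(fs) else fs
  cov <- time_lagged_covariances(fs_c, lag, reversible = reversible)
  sol <- solve_tica(cov$C0, cov$Ctau, epsilon = epsilon)
  lam <- sol$values
  kv <- lam^2
  tot <- sum(kv[lam > 0])
  if (is.null(dim)) {
    .stop_if(var_frac <= 0 || var_frac > 1, "var_frac must lie in (0, 1]")
    npos <- sum(lam > 0)
    cum <- cumsum(kv[seq_len(npos)]) / tot
    m <- if (var_frac == 1) npos else which(cum >= var_frac)[1]
  } else {
    .stop_if(dim > length(lam),
             "requested %d components but only %d available", dim, length(lam))
    m <- as.integer(dim)
  }
  structure(list(lag = lag, mean = mu, C0 = cov$C0, Ctau = cov$Ctau,
                 values = lam, vectors = sol$vectors, m = m,
                 kinetic_variance = kv / tot, scale = scale,
                 n_dropped = sol$n_dropped, d = ncol(fs$values)),
            class = "tica")
}

#' @export
print.tica <- function(x, ...) {
  cat(sprintf("TICA model: lag %d, %d -> %d dimensions (%d rank-deficient dropped)\n",
              x$lag, x$d, x$m, x$n_dropped))
  cat("leading eigenvalues:",
      paste(sprintf("%.4f", head(x$values, 5)), collapse = " "), "\n")
  cat(sprintf("cumulative kinetic variance at m: %.3f\n",
              sum(x$kinetic_variance[seq_len(x$m)])))
  invisible(x)
}

#' Project features onto the TICA space
#'
#' `z(t)' = r(t)' U` using the first m independent components of a fitted
#' model.
#'
#' @param object A fitted [tica()] model.
#' @param newdata A [feature_series()] or matrix with the model's feature
#'   dimension.
#' @param m Number of components (default: the model's retained dimension).
#' @param ... Unused.
#' @return A [feature_series()] of projected coordinates `tic1..ticm`.
#' @export
predict.tica <- function(object, newdata, m = object$m, ...) {
  .stop_if(m > ncol(object$vectors),
           "m = %d exceeds the %d available components", m, ncol(object$vectors))
  is_fs <- inherits(newdata, "feature_series")
  X <- if (is_fs) newdata$values else as.matrix(newdata)
  .stop_if(ncol(X) != object$d, "newdata has %d features, model expects %d",
           ncol(X), object$d)
  U <- object$vectors[, seq_len(m), drop = FALSE]
  if (object$scale) U <- sweep(U, 2, object$values[seq_len(m)], `*`)
  Z <- sweep(X, 2, object$mean) %*% U
  colnames(Z) <- paste0("tic", seq_len(m))
  feature_series(Z, dt = if (is_fs) newdata$dt else 1,
                 boundaries = if (is_fs) newdata$boundaries else 1L)
}

#' Serialize / restore a TICA model as JSON
#' @param object A `tica` model.
#' @param file Path.
#' @return `file` invisibly; `read_tica` returns the restored model.
#' @export
write_tica <- function(object, file) {
  stopifnot(inherits(object, "tica"))
  obj <- unclass(object)
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(file)
}

#' @rdname write_tica
#' @export
read_tica <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  for (f in c("C0", "Ctau", "vectors")) obj[[f]] <- as.matrix(obj[[f]])
  structure(obj, class = "tica")
}
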