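# PCCA+ metastable coarse-graining and stationary-weight free energies.

#' PCCA+ macrostate assignment
#'
#' Perron-cluster cluster analysis on the top-M right eigenvectors of a
#' reversible transition matrix. Vertex microstates are located
#' deterministically by the inner simplex algorithm (successive
#' furthest-point orthogonalization on rows of the eigenvector matrix), the
#' membership matrix is the linear map sending those vertices to the unit
#' simplex corners, and small infeasibilities are clipped and renormalized.
#' Macrostates are relabeled by decreasing stationary weight, so macrostate
#' 1 is always the most stable.
#'
#' @param object A fitted [markov_model()].
#' @param M Number of macrostates (2 <= M <= number of positive eigenvalues).
#' @param temperature Temperature (K) for the free-energy table.
#' @return An object of class `pcca`: `memberships` (k x M, rows in `[0,1]`
#'   summing to 1), `crisp` (1..M per active microstate), `pi_macro`,
#'   `free_energy` (kcal/mol, min = 0), `M`.
#' @export
pcca <- function(object, M, temperature = 298) {
  stopifnot(inherits(object, "msm"))
  k <- length(object$pi)
  .stop_if(M < 1 || M > k, "M must lie in [1, %d]", k)
  if (M == 1) {
    memb <- matrix(1, k, 1)
    crisp <- rep(1L, k)
  } else {
    .stop_if(object$eigen$values[M] <= 0,
             paste("only %d eigenvalues are positive: the spectral gap does",
                   "not support M = %d macrostates; reduce M"),
             sum(object$eigen$values > 0), M)
    X <- object$eigen$right[, seq_len(M), drop = FALSE]
    # inner simplex algorithm: pick M rows spanning the eigenvector simplex
    # (translate to the furthest row, then successively deflate each chosen
    # vertex direction and take the row of largest remaining norm)
    vertices <- integer(M)
    O <- X
    vertices[1] <- which.max(rowSums(O^2))
    O <- sweep(O, 2, O[vertices[1], ])
    for (j in seq_len(M - 1) + 1L) {
      vertices[j] <- which.max(rowSums(O^2))
      v <- O[vertices[j], ]
      if (sum(v^2) > 1e-300)
        O <- O - (O %*% v) %*% t(v) / sum(v^2)
    }
    A <- solve(X[vertices, , drop = FALSE])
    memb <- X %*% A
    memb <- pmax(memb, 0)
    memb <- memb / rowSums(memb)
    crisp <- max.col(memb, ties.method = "first")
  }
  pi_macro <- vapply(seq_len(M), function(I) sum(object$pi[crisp == I]),
                     numeric(1))
  ord <- order(pi_macro, decreasing = TRUE)
  memb <- memb[, ord, drop = FALSE]
  crisp <- match(crisp, ord)
  pi_macro <- pi_macro[ord]
  dg <- macrostate_free_energy(pi_macro, temperature = temperature)
  structure(list(memberships = memb, crisp = as.integer(crisp),
                 pi_macro = pi_macro, free_energy = dg, M = as.integer(M),
                 temperature = temperature,
                 active_set = object$active_set),
            class = "pcca")
}

#' @export
print.pcca <- function(x, ...) {
  cat(sprintf("PCCA+ partition into %d macrostates\n", x$M))
  df <- data.frame(macrostate = seq_len(x$M),
                   n_micro = tabulate(x$crisp, x$M),
                   pi = signif(x$pi_macro, 4),
                   dG_kcal_mol = signif(x$free_energy, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Best label agreement under relabeling
#'
#' Fraction of positions where two categorical labelings agree, maximized
#' over all permutations of the second labeling's classes. Used to compare
#' recovered macrostates against ground-truth basin labels, whose numbering
#' is arbitrary.
#'
#' @param truth,labels Integer vectors of equal length with classes 1..M.
#' @return Agreement fraction in `[0, 1]`.
#' @export
label_agreement <- function(truth, labels) {
  .stop_if(length(truth) != length(labels), "labelings differ in length")
  M <- max(truth, labels)
  .stop_if(M > 8, "permutation matching supports up to 8 classes")
  conf <- matrix(0, M, M)
  tab <- table(factor(truth, 1:M), factor(labels, 1:M))
  conf[seq_len(M), seq_len(M)] <- tab
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- 0
  for (p in perms(seq_len(M)))
    best <- max(best, sum(conf[cbind(seq_len(M), p)]))
  best / length(truth)
}

#' Macrostate free energies from stationary weights
#'
#' `dG(s_I) = -kB T log(sum_{j in s_I} pi_j)`, shifted so the minimum is 0.
#' Free energies are invariant under uniform rescaling of the weights.
#'
#' @param weights Stationary macrostate weights (any positive scale), or a
#'   `pcca` object together with `pi`.
#' @param temperature Temperature in K (kB = 0.0019872041 kcal/mol/K).
#' @param kT Thermal energy override (set `kT = 1` for unit mode).
#' @return Free energies in kcal/mol (or kT units), minimum 0; empty
#'   macrostates yield `Inf` with a warning.
#' @export
macrostate_free_energy <- function(weights, temperature = 298, kT = NULL) {
  if (is.null(kT)) kT <- kBT(temperature)
  w <- as.numeric(weights)
  if (any(w <= 0)) warning("empty macrostate: infinite free energy flagged")
  g <- ifelse(w > 0, -kT * log(w), Inf)
  g - min(g)
}
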