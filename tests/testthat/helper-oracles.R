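# Brute-force oracles and small fixture builders shared across the suite.

# random reversible k-state chain from symmetric positive weights
make_reversible_chain <- function(k, seed, diag_boost = k) {
  set.seed(seed)
  S <- matrix(runif(k * k), k)
  S <- S + t(S)
  diag(S) <- diag(S) + diag_boost
  list(T = S / rowSums(S), pi = rowSums(S) / sum(S))
}

# minimal msm-like object accepted by tpt()/committor()
as_msm <- function(T, pi, lag = 1L) {
  structure(list(T = T, pi = pi, lag = lag, dt = 1), class = "msm")
}

# explicit-summation center of mass
com_oracle <- function(P, m) unname(colSums(P * m) / sum(m))

# per-pair distance loop
pairdist_oracle <- function(coords, ia, ib) {
  nf <- dim(coords)[1]
  out <- matrix(NA_real_, nf, length(ia) * length(ib))
  col <- 0
  for (i in ia) for (j in ib) {
    col <- col + 1
    for (t in seq_len(nf))
      out[t, col] <- sqrt(sum((coords[t, i, ] - coords[t, j, ])^2))
  }
  out
}

# double-loop time-lagged covariance (single segment, mean-free input)
cov_oracle <- function(X, lag, reversible = TRUE) {
  N <- nrow(X); d <- ncol(X)
  C0 <- matrix(0, d, d); Ct <- matrix(0, d, d)
  for (t in seq_len(N - lag)) {
    a <- X[t, ]; b <- X[t + lag, ]
    if (reversible) {
      C0 <- C0 + (outer(a, a) + outer(b, b)) / 2
      Ct <- Ct + (outer(a, b) + outer(b, a)) / 2
    } else {
      C0 <- C0 + outer(a, a)
      Ct <- Ct + outer(a, b)
    }
  }
  n <- N - lag
  list(C0 = C0 / n, Ctau = (Ct + t(Ct)) / (2 * n))
}

# pair-loop transition counts
count_oracle <- function(s, lag, n_states) {
  C <- matrix(0, n_states, n_states)
  for (t in seq_len(length(s) - lag))
    C[s[t] + 1, s[t + lag] + 1] <- C[s[t] + 1, s[t + lag] + 1] + 1
  C
}

# strongly connected components by exhaustive reachability
scc_oracle <- function(C) {
  k <- nrow(C)
  R <- (C > 0) | diag(k)
  for (m in seq_len(k)) R <- (R %*% R) > 0    # transitive closure
  comp <- rep(NA_integer_, k); cl <- 0
  for (i in seq_len(k)) {
    if (!is.na(comp[i])) next
    cl <- cl + 1
    comp[which(R[i, ] & R[, i])] <- cl
  }
  comp
}

# random rigid motion applied to every frame of a coords array
apply_rigid <- function(coords, seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  shift <- rnorm(3, sd = 5)
  out <- coords
  for (t in seq_len(dim(coords)[1]))
    out[t, , ] <- sweep(matrix(coords[t, , ], ncol = 3) %*% t(R), 2, shift, `+`)
  out
}

# tiny random trajectory fixture
random_traj <- function(n_frames, n_atoms, seed, dt = 1, boundaries = 1L) {
  set.seed(seed)
  coords <- array(rnorm(n_frames * n_atoms * 3, sd = 3), c(n_frames, n_atoms, 3))
  atoms <- data.frame(elety = rep(c("C1", "N1", "O1", "P"),
                                  length.out = n_atoms),
                      resid = "DT", resno = rep(seq_len(max(1, n_atoms %/% 4)),
                                                each = 4)[seq_len(n_atoms)],
                      chain = "A")
  md_trajectory(coords, atoms, dt = dt, boundaries = boundaries)
}
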