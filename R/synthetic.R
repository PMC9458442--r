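# Synthetic data generators: every input the analysis pipeline consumes can
# be produced here with recorded ground truth, standing in for microsecond
# MD trajectories at desk scale.

# one global integer seed; components derive their own by fixed offsets
.derive_seed <- function(seed, offset) as.integer((seed + offset) %% 2147483647L)
.seed_offsets <- c(markov = 101L, langevin = 202L, duplex = 303L,
                   kmeans = 404L, bootstrap = 505L, mc_oracle = 606L,
                   meta_eabf = 707L)

#' Specification of a discrete Markov chain generator
#'
#' @param transition_matrix Row-stochastic square matrix.
#' @param n_steps Chain length.
#' @param n_trajectories Number of independent chains.
#' @param seed Integer seed.
#' @param start Start state(s), 0-based; recycled across trajectories.
#' @return A validated `markov_chain_spec`.
#' @export
markov_chain_spec <- function(transition_matrix, n_steps, n_trajectories = 1L,
                              seed = 1L, start = 0L) {
  T <- as.matrix(transition_matrix)
  .stop_if(nrow(T) != ncol(T), "transition matrix must be square")
  .stop_if(any(T < 0 | T > 1), "transition probabilities must lie in [0, 1]")
  bad <- which(abs(rowSums(T) - 1) > 1e-12)
  .stop_if(length(bad) > 0,
           "row %d of the transition matrix sums to %.15g, not 1",
           bad[1], rowSums(T)[bad[1]])
  .stop_if(n_steps < 1, "n_steps must be positive")
  # a single recurrent communicating class must be reachable from the start
  start <- as.integer(start)
  .stop_if(any(start < 0 | start >= nrow(T)), "start state out of range")
  R <- (T > 0) | diag(nrow(T)) > 0
  for (i in seq_len(nrow(T))) R <- (R %*% R) > 0
  reach <- which(colSums(R[start + 1L, , drop = FALSE] > 0) > 0)
  .stop_if(.n_recurrent_classes(T[reach, reach, drop = FALSE]) != 1L,
           "more than one recurrent communicating class is reachable from the start state(s)")
  structure(list(transition_matrix = T, n_steps = as.integer(n_steps),
                 n_trajectories = as.integer(n_trajectories),
                 seed = as.integer(seed),
                 start = as.integer(start)),
            class = "markov_chain_spec")
}

# recurrent classes = strongly connected components with no outgoing edges
.n_recurrent_classes <- function(T) {
  g <- igraph::graph_from_adjacency_matrix(T > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")$membership
  n_rec <- 0L
  for (cl in unique(comp)) {
    inside <- comp == cl
    if (all(T[inside, !inside, drop = FALSE] == 0)) n_rec <- n_rec + 1L
  }
  n_rec
}

#' Sample discrete Markov chains
#'
#' @param spec A [markov_chain_spec()].
#' @return List of integer vectors of 0-based states, one per trajectory.
#' @export
sample_markov_chain <- function(spec) {
  stopifnot(inherits(spec, "markov_chain_spec"))
  set.seed(.derive_seed(spec$seed, .seed_offsets[["markov"]]))
  start <- rep_len(spec$start, spec$n_trajectories)
  k <- nrow(spec$transition_matrix)
  .stop_if(any(start < 0 | start >= k), "start state out of range [0, %d)", k)
  lapply(seq_len(spec$n_trajectories), function(i)
    cpp_sample_markov_chain(spec$transition_matrix, spec$n_steps, start[i]))
}

# ---- analytic potentials -------------------------------------------------

#' Analytic potentials for the Langevin and meta-eABF engines
#'
#' `harmonic`: V = k/2 x^2 (any dimension). `double-well`: V = h((x/a)^2-1)^2
#' with minima at -a, +a and barrier h at 0. `five-basin-2D`: a sum of five
#' inverted Gaussians arranged as a connected network of metastable basins
#' (deepest basin first), plus a steep confining wall; emulates a free-energy
#' landscape with five macrostates linked by channels of different depth.
#'
#' @param id One of `"harmonic"`, `"double-well"`, `"five-basin-2D"`.
#' @param par Named parameter overrides (e.g. `k`, `h`, `a`, `depths`).
#' @return A `potential` object with fields `fun` (V), `grad`, `dim`,
#'   `minima` (matrix of basin centers, one row each), `barrier` where
#'   closed-form, and the packed parameters used by the compiled sampler.
#' @export
potential <- function(id = c("harmonic", "double-well", "five-basin-2D"),
                      par = list()) {
  id <- match.arg(id)
  if (id == "harmonic") {
    k <- par$k %||% 1
    obj <- list(id = id, cpp_id = 0L, dim = par$dim %||% 1L,
                par = c(k = k), centers = matrix(0, 1, 1),
                fun = function(x) 0.5 * k * sum(x^2),
                grad = function(x) k * x,
                minima = matrix(0, 1, par$dim %||% 1L), barrier = NA_real_)
  } else if (id == "double-well") {
    h <- par$h %||% 2; a <- par$a %||% 1
    obj <- list(id = id, cpp_id = 1L, dim = 1L, par = c(h = h, a = a),
                centers = matrix(0, 1, 1),
                fun = function(x) h * ((x / a)^2 - 1)^2,
                grad = function(x) h * 4 * (x / a) * ((x / a)^2 - 1) / a,
                minima = matrix(c(-a, a), 2, 1), barrier = h)
  } else {
    ctr <- par$centers %||% matrix(c(-2.0,  0.0,
                                     -0.6,  1.3,
                                     -0.6, -1.3,
                                      1.2,  1.3,
                                      1.6, -1.0), 5, 2, byrow = TRUE)
    depths <- par$depths %||% c(3.7, 2.9, 3.3, 2.9, 2.5)
    sigma  <- par$sigma  %||% rep(0.5, nrow(ctr))
    wall   <- c(par$wall_k %||% 1.0, par$wall_c %||% 0.0, par$wall_w %||% 3.5)
    cmat <- cbind(ctr, depths, sigma)
    fun <- function(x) {
      v <- sum(-depths * exp(-((x[1] - ctr[, 1])^2 + (x[2] - ctr[, 2])^2) /
                               (2 * sigma^2)))
      v + wall[1] * sum(((x - wall[2]) / wall[3])^8)
    }
    grad <- function(x) {
      e <- depths * exp(-((x[1] - ctr[, 1])^2 + (x[2] - ctr[, 2])^2) /
                          (2 * sigma^2))
      g <- c(sum(e * (x[1] - ctr[, 1]) / sigma^2),
             sum(e * (x[2] - ctr[, 2]) / sigma^2))
      g + wall[1] * 8 * ((x - wall[2]) / wall[3])^7 / wall[3]
    }
    obj <- list(id = id, cpp_id = 2L, dim = 2L, par = wall, centers = cmat,
                fun = fun, grad = grad, minima = ctr, barrier = NA_real_)
  }
  structure(obj, class = "potential")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specification of an overdamped Langevin simulation
#'
#' Dynamics: `x <- x - (dt/friction) * grad V(x) + sqrt(2 kT dt / friction) * xi`
#' with standard-normal `xi`. Optionally appends fast orthogonal noise
#' dimensions (AR(1) with short correlation time) to emulate the many
#' kinetically irrelevant degrees of freedom of real features.
#'
#' @param potential_id Potential name or a [potential()] object.
#' @param kT Thermal energy, kcal/mol (default `kBT(298)`).
#' @param friction Friction coefficient (inverse time units).
#' @param dt Time step.
#' @param n_steps Number of steps.
#' @param seed Integer seed.
#' @param x0 Start position (defaults to the first basin center).
#' @param n_noise_dims Fast-noise columns appended to the output.
#' @param noise_rho,noise_sd AR(1) coefficient and stationary sd of the noise.
#' @param box Bounding half-width; escaping it raises an error (unstable dt).
#' @param pot_par Parameter overrides forwarded to [potential()].
#' @return A `langevin_spec`.
#' @export
langevin_spec <- function(potential_id = "five-basin-2D", kT = kBT(298),
                          friction = 1, dt = 0.01, n_steps = 1e5L, seed = 1L,
                          x0 = NULL, n_noise_dims = 0L, noise_rho = 0.2,
                          noise_sd = 0.5, box = 100, pot_par = list()) {
  pot <- if (inherits(potential_id, "potential")) potential_id else
    potential(potential_id, pot_par)
  .stop_if(dt <= 0 || friction <= 0 || kT < 0,
           "dt and friction must be positive, kT non-negative")
  if (is.null(x0)) x0 <- pot$minima[1, ]
  .stop_if(length(x0) != pot$dim, "x0 must have length %d", pot$dim)
  structure(list(potential = pot, kT = kT, friction = friction, dt = dt,
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 x0 = x0, n_noise_dims = as.integer(n_noise_dims),
                 noise_rho = noise_rho, noise_sd = noise_sd, box = box),
            class = "langevin_spec")
}

#' Simulate overdamped Langevin dynamics
#'
#' @param spec A [langevin_spec()].
#' @return List with `features` (a [feature_series()] of positions plus any
#'   noise columns) and `basins` (0-based index of the nearest potential
#'   basin center per frame — the ground-truth label).
#' @export
simulate_langevin <- function(spec) {
  stopifnot(inherits(spec, "langevin_spec"))
  pot <- spec$potential
  set.seed(.derive_seed(spec$seed, .seed_offsets[["langevin"]]))
  res <- cpp_langevin(pot$cpp_id, pot$par, pot$centers, spec$x0,
                      spec$dt, spec$kT, spec$friction, spec$n_steps, spec$box)
  X <- res$x
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (spec$n_noise_dims > 0) {
    innov_sd <- spec$noise_sd * sqrt(1 - spec$noise_rho^2)
    N <- vapply(seq_len(spec$n_noise_dims), function(j) {
      as.numeric(stats::filter(rnorm(spec$n_steps, sd = innov_sd),
                               spec$noise_rho, method = "recursive"))
    }, numeric(spec$n_steps))
    colnames(N) <- paste0("noise", seq_len(spec$n_noise_dims))
    X <- cbind(X, N)
  }
  basins <- cpp_assign_centers(res$x, pot$minima)
  list(features = feature_series(X, dt = spec$dt), basins = basins)
}

# ---- toy duplex ----------------------------------------------------------

#' Specification of an idealized toy DNA duplex
#'
#' A geometric fixture, not a physical B-DNA model: each base is an
#' idealized planar six-membered ring, each residue carries one backbone P
#' atom, and the central base pair of strand 1 holds the "lesion" (residue
#' name TG) whose flip angle is an explicit construction parameter. Used to
#' validate collective-variable code against known geometry.
#'
#' @param n_base_pairs Number of base pairs (>= 3: the flip axis needs
#'   flanking phosphates, and CPDb needs flanking base pairs).
#' @param flip_angle Flip angle in degrees, `[0, 360)`; 0 = stacked in-helix
#'   facing the partner, 180 = extrahelical on the major-groove side.
#' @param rise Helical rise per base pair (Angstrom).
#' @param twist Helical twist per base pair (degrees). The default 0 builds
#'   an untwisted ladder whose flip axis is exactly vertical, keeping the
#'   full 0-360 sweep free of steric clashes; nonzero twists are allowed
#'   but the interatomic-distance invariant is still enforced.
#' @param seed Integer seed (kept for interface symmetry; construction is
#'   deterministic).
#' @return A `toy_duplex_spec`.
#' @export
toy_duplex_spec <- function(n_base_pairs = 5L, flip_angle = 0, rise = 3.4,
                            twist = 0, seed = 1L) {
  .stop_if(n_base_pairs < 3,
           "n_base_pairs must be >= 3 (flanking base pairs required)")
  .stop_if(flip_angle < 0 || flip_angle >= 360,
           "flip_angle must lie in [0, 360)")
  structure(list(n_base_pairs = as.integer(n_base_pairs),
                 flip_angle = flip_angle, rise = rise, twist = twist,
                 seed = as.integer(seed)),
            class = "toy_duplex_spec")
}

# rotate points about the axis through a with unit direction u by ang degrees
.rotate_about_axis <- function(P, a, u, ang) {
  th <- ang * pi / 180
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(P, 2, a) %*% t(R), 2, a, `+`)
}

#' Build a toy duplex trajectory frame
#'
#' The lesion base ring is rotated rigidly about the axis through its two
#' flanking backbone phosphates, so the pseudodihedral CPDb built on those
#' phosphates is by construction a strictly monotone function of
#' `flip_angle` on (0, 180).
#'
#' @param spec A [toy_duplex_spec()].
#' @return A single-frame [md_trajectory()] with attributes `lesion` and
#'   `partner` giving the residue numbers of the flipping base and its
#'   complementary partner.
#' @export
build_toy_duplex <- function(spec) {
  stopifnot(inherits(spec, "toy_duplex_spec"))
  n <- spec$n_base_pairs
  ring_r <- 1.39          # ring circumradius
  ring_R <- 3.0           # ring-center distance from the helix axis
  back_R <- 8.9           # backbone P radius
  ring_names <- c("N1", "C2", "N3", "C4", "C5", "C6")

  coords <- NULL; elety <- character(0); resid <- character(0)
  resno <- integer(0); chain <- character(0)
  m <- (n + 1L) %/% 2L    # lesion base pair index
  add <- function(xyz, ety, rid, rno, ch) {
    n_new <- nrow(xyz)
    coords <<- rbind(coords, xyz)
    elety <<- c(elety, rep_len(ety, n_new))
    resid <<- c(resid, rep_len(rid, n_new))
    resno <<- c(resno, rep_len(rno, n_new))
    chain <<- c(chain, rep_len(ch, n_new))
  }
  ring_at <- function(az_deg, z) {
    # planar hexagon normal to the helix axis, centered ring_R from the axis
    az <- az_deg * pi / 180
    ctr <- c(ring_R * cos(az), ring_R * sin(az), z)
    ang <- (0:5) * 60 * pi / 180
    cbind(ctr[1] + ring_r * cos(ang + az), ctr[2] + ring_r * sin(ang + az),
          ctr[3])
  }
  for (i in seq_len(n)) {
    z <- (i - 1) * spec$rise
    phi <- (i - 1) * spec$twist
    # strand 1 residue i (5'->3'): P radially behind the base, then the ring;
    # the radial P placement makes the flip axis, the in-helix ring and the
    # partner ring collinear, so flip 0 is the exact COM-distance minimum
    add(cbind(back_R * cos(phi * pi / 180),
              back_R * sin(phi * pi / 180), z - spec$rise / 2),
        "P", if (i == m) "TG" else "DT", i, "A")
    add(ring_at(phi, z), ring_names, if (i == m) "TG" else "DT", i, "A")
    # strand 2 partner residue (numbered 2n+1-i, antiparallel convention)
    add(cbind(back_R * cos((phi + 180) * pi / 180),
              back_R * sin((phi + 180) * pi / 180), z + spec$rise / 2),
        "P", "DA", 2L * n + 1L - i, "B")
    add(ring_at(phi + 180, z), ring_names, "DA", 2L * n + 1L - i, "B")
  }
  atoms <- data.frame(elety = elety, resid = resid, resno = resno,
                      chain = chain, stringsAsFactors = FALSE)

  if (spec$flip_angle != 0) {
    les_ring <- which(atoms$resno == m & atoms$chain == "A" & atoms$elety != "P")
    p5 <- which(atoms$resno == m & atoms$chain == "A" & atoms$elety == "P")
    p3 <- which(atoms$resno == m + 1L & atoms$chain == "A" & atoms$elety == "P")
    a <- coords[p5, ]; b <- coords[p3, ]
    coords[les_ring, ] <- .rotate_about_axis(coords[les_ring, , drop = FALSE],
                                             a, b - a, spec$flip_angle)
  }
  d <- as.matrix(stats::dist(coords))
  .stop_if(any(d[upper.tri(d)] < 0.5), "degenerate geometry: atoms closer than 0.5 A")

  traj <- md_trajectory(array(coords, c(1, nrow(coords), 3)), atoms)
  attr(traj, "lesion") <- m
  attr(traj, "partner") <- 2L * n + 1L - m
  traj
}

#' Atom selections for the standard flip CVs on a toy duplex
#'
#' Returns the four center-of-mass groups of the flip pseudodihedral CPDb
#' (flanking base pairs; 5' and 3' flanking phosphates; the flipping base
#' ring) plus lesion/partner ring selections for COM-distance features.
#'
#' @param traj A toy duplex built by [build_toy_duplex()].
#' @return List of [atom_selection()] objects: `p1`, `p2`, `p3`, `p4`,
#'   `lesion`, `partner`.
#' @export
duplex_cv_selections <- function(traj) {
  a <- traj$atoms
  m <- attr(traj, "lesion"); pr <- attr(traj, "partner")
  n <- max(a$resno[a$chain == "A"])
  flank <- c(m - 1L, m + 1L)
  flank_partner <- 2L * n + 1L - flank
  idx_p1 <- which((a$chain == "A" & a$resno %in% flank |
                   a$chain == "B" & a$resno %in% flank_partner) & a$elety != "P")
  list(
    p1 = atom_selection(traj, idx_p1),
    p2 = atom_selection(traj, which(a$chain == "A" & a$resno == m & a$elety == "P")),
    p3 = atom_selection(traj, which(a$chain == "A" & a$resno == m + 1L & a$elety == "P")),
    p4 = atom_selection(traj, which(a$chain == "A" & a$resno == m & a$elety != "P")),
    lesion = atom_selection(traj, which(a$chain == "A" & a$resno == m & a$elety != "P")),
    partner = atom_selection(traj, which(a$chain == "B" & a$resno == pr & a$elety != "P"))
  )
}
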