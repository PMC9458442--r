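# Geometric observables for base flipping: centers of mass, COM separation,
# the CPDb flip pseudodihedral, atom torsions, hydrogen-bond occupancy,
# RMSD and RMSF.

#' Atom selection with masses
#'
#' @param traj An [md_trajectory()] (used for bounds checking and masses).
#' @param indices 1-based atom indices.
#' @param masses Optional masses (amu); default taken from the trajectory.
#' @return An `atom_selection`.
#' @export
atom_selection <- function(traj, indices, masses = NULL) {
  indices <- as.integer(indices)
  .stop_if(length(indices) == 0, "empty atom selection")
  .stop_if(anyDuplicated(indices) > 0, "duplicate atom indices in selection")
  .stop_if(any(indices < 1 | indices > n_atoms(traj)),
           "atom index out of range [1, %d]", n_atoms(traj))
  if (is.null(masses)) masses <- traj$atoms$mass[indices]
  .stop_if(any(masses <= 0), "masses must be strictly positive")
  structure(list(indices = indices, masses = masses), class = "atom_selection")
}

#' Center of mass of an atom selection
#'
#' @param frame An atoms x 3 coordinate matrix (one frame), e.g. from
#'   [frame_coords()].
#' @param sel An [atom_selection()].
#' @return Length-3 numeric vector (Angstrom).
#' @export
center_of_mass <- function(frame, sel) {
  stopifnot(inherits(sel, "atom_selection"))
  .stop_if(max(sel$indices) > nrow(frame), "selection exceeds frame atoms")
  w <- sel$masses / sum(sel$masses)
  colSums(frame[sel$indices, , drop = FALSE] * w)
}

#' Center-of-mass separation distance
#'
#' @inheritParams center_of_mass
#' @param sel_a,sel_b Two [atom_selection()]s.
#' @return Euclidean COM distance (Angstrom); symmetric in its arguments.
#' @export
com_distance <- function(frame, sel_a, sel_b) {
  sqrt(sum((center_of_mass(frame, sel_a) - center_of_mass(frame, sel_b))^2))
}

.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

# signed torsion of four ordered points, IUPAC convention, (-180, 180]
.torsion_points <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  .stop_if(sum(b1^2) < 1e-20 || sum(b2^2) < 1e-20 || sum(b3^2) < 1e-20,
           "undefined torsion: two consecutive points coincide")
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  .stop_if(sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20,
           "undefined torsion: three consecutive points are colinear")
  b2h <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(.cross3(n1, n2) * b2h), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Specification of the flip pseudodihedral CPDb
#'
#' CPDb is the torsion over four centers of mass: p1 the flanking base
#' pairs, p2 and p3 the flanking phosphate groups, p4 the six-membered ring
#' of the flipping pyrimidine.
#'
#' @param p1,p2,p3,p4 [atom_selection()]s (non-empty; they may share atoms).
#' @return A `cpdb_spec`.
#' @export
cpdb_spec <- function(p1, p2, p3, p4) {
  for (s in list(p1, p2, p3, p4)) stopifnot(inherits(s, "atom_selection"))
  structure(list(p1 = p1, p2 = p2, p3 = p3, p4 = p4), class = "cpdb_spec")
}

#' Flip pseudodihedral angle CPDb
#'
#' @inheritParams center_of_mass
#' @param spec A [cpdb_spec()].
#' @return Signed angle in degrees, range (-180, 180].
#' @export
cpdb <- function(frame, spec) {
  stopifnot(inherits(spec, "cpdb_spec"))
  .torsion_points(center_of_mass(frame, spec$p1), center_of_mass(frame, spec$p2),
                  center_of_mass(frame, spec$p3), center_of_mass(frame, spec$p4))
}

#' Torsion angle over four atoms
#'
#' Same convention as [cpdb()] with singleton selections.
#'
#' @inheritParams center_of_mass
#' @param indices Four distinct 1-based atom indices.
#' @return Signed angle in degrees, range (-180, 180].
#' @export
torsion <- function(frame, indices) {
  .stop_if(length(indices) != 4 || anyDuplicated(indices) > 0,
           "torsion requires four distinct atom indices")
  .torsion_points(frame[indices[1], ], frame[indices[2], ],
                  frame[indices[3], ], frame[indices[4], ])
}

#' Per-frame CPDb series over a trajectory
#' @param traj An [md_trajectory()].
#' @param spec A [cpdb_spec()].
#' @return Numeric vector, one angle per frame.
#' @export
cpdb_series <- function(traj, spec) {
  vapply(seq_len(n_frames(traj)), function(i) cpdb(frame_coords(traj, i), spec),
         numeric(1))
}

#' Geometric hydrogen-bond criterion
#'
#' A frame counts as bonded when the donor-acceptor distance is at most
#' `distance_cutoff` and the donor-hydrogen-acceptor angle is at least
#' `angle_cutoff` (field-standard defaults 3.5 Angstrom / 120 degrees).
#'
#' @param donor,hydrogen,acceptor 1-based atom indices.
#' @param distance_cutoff Angstrom, positive.
#' @param angle_cutoff Degrees in (0, 180].
#' @return An `hbond_spec`.
#' @export
hbond_spec <- function(donor, hydrogen, acceptor,
                       distance_cutoff = 3.5, angle_cutoff = 120) {
  .stop_if(distance_cutoff <= 0, "distance_cutoff must be positive")
  .stop_if(angle_cutoff <= 0 || angle_cutoff > 180,
           "angle_cutoff must lie in (0, 180]")
  structure(list(donor = as.integer(donor), hydrogen = as.integer(hydrogen),
                 acceptor = as.integer(acceptor),
                 distance_cutoff = distance_cutoff,
                 angle_cutoff = angle_cutoff),
            class = "hbond_spec")
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' @param traj An [md_trajectory()].
#' @param spec An [hbond_spec()].
#' @return Fraction of frames in `[0, 1]` satisfying both criteria.
#' @export
hbond_occupancy <- function(traj, spec) {
  stopifnot(inherits(spec, "hbond_spec"))
  nf <- n_frames(traj)
  .stop_if(nf < 1, "empty trajectory")
  idx <- c(spec$donor, spec$hydrogen, spec$acceptor)
  .stop_if(any(idx < 1 | idx > n_atoms(traj)), "hbond atom index out of range")
  D <- traj$coords[, spec$donor, , drop = FALSE]
  H <- traj$coords[, spec$hydrogen, , drop = FALSE]
  A <- traj$coords[, spec$acceptor, , drop = FALSE]
  dDA <- sqrt(rowSums((D - A)[, 1, , drop = TRUE]^2))
  v1 <- (D - H)[, 1, , drop = TRUE]; v2 <- (A - H)[, 1, , drop = TRUE]
  if (nf == 1) { v1 <- matrix(v1, 1); v2 <- matrix(v2, 1); dDA <- sqrt(sum((D - A)^2)) }
  cosang <- rowSums(v1 * v2) / (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  mean(dDA <= spec$distance_cutoff & ang >= spec$angle_cutoff)
}

# trajectory (selection) -> bio3d-style frames x 3n xyz matrix
.as_xyz <- function(traj, sel = NULL) {
  idx <- if (is.null(sel)) seq_len(n_atoms(traj)) else sel$indices
  co <- traj$coords[, idx, , drop = FALSE]
  t(matrix(aperm(co, c(3L, 2L, 1L)), ncol = dim(co)[1]))
}

.check_superposable <- function(xyz_ref) {
  P <- matrix(xyz_ref, ncol = 3, byrow = TRUE)
  .stop_if(nrow(P) < 3, "superposition requires at least 3 atoms")
  s <- svd(scale(P, scale = FALSE))$d
  .stop_if(sum(s > 1e-8) < 2, "superposition requires non-colinear atoms")
}

#' RMSD time series after optimal superposition
#'
#' Root-mean-square deviation of each frame from a reference after
#' least-squares rigid-body (Kabsch) superposition.
#'
#' @param traj An [md_trajectory()].
#' @param reference Reference frame index (default 1) or an atoms x 3 matrix.
#' @param sel Optional [atom_selection()] restricting the comparison.
#' @param fit Superpose before measuring (default TRUE).
#' @return Numeric vector of per-frame RMSD (Angstrom).
#' @export
rmsd_series <- function(traj, reference = 1L, sel = NULL, fit = TRUE) {
  X <- .as_xyz(traj, sel)
  ref <- if (is.matrix(reference)) {
    idx <- if (is.null(sel)) seq_len(nrow(reference)) else sel$indices
    as.numeric(t(reference[idx, , drop = FALSE]))
  } else X[reference, ]
  if (fit) .check_superposable(ref)
  as.numeric(bio3d::rmsd(ref, X, fit = fit))
}

#' Root-mean-square fluctuation per atom (or per residue)
#'
#' All frames are superposed onto the time-averaged structure (obtained by a
#' fit to the first frame, averaging, then refitting); RMSF is the per-atom
#' root mean square deviation about the time-mean position. With
#' `per_residue = TRUE`, per-atom values are aggregated by mass-weighted
#' mean within each residue.
#'
#' @param traj An [md_trajectory()].
#' @param sel Optional [atom_selection()].
#' @param per_residue Aggregate to residues (nucleotide profile).
#' @return Numeric vector of RMSF values (Angstrom); named by residue when
#'   aggregated.
#' @export
rmsf <- function(traj, sel = NULL, per_residue = FALSE) {
  X <- .as_xyz(traj, sel)
  .check_superposable(X[1, ])
  inds <- seq_len(ncol(X))
  f1 <- bio3d::fit.xyz(X[1, ], X, fixed.inds = inds, mobile.inds = inds)
  mu <- colMeans(f1)
  f2 <- bio3d::fit.xyz(mu, f1, fixed.inds = inds, mobile.inds = inds)
  mu2 <- colMeans(f2)
  dev2 <- sweep(f2, 2, mu2)^2
  # colMeans(dev2) has x,y,z interleaved per atom; sum the three components
  per_atom <- sqrt(colSums(matrix(colMeans(dev2), nrow = 3)))
  if (!per_residue) return(per_atom)
  idx <- if (is.null(sel)) seq_len(n_atoms(traj)) else sel$indices
  key <- paste(traj$atoms$chain[idx], traj$atoms$resno[idx])
  w <- traj$atoms$mass[idx]
  out <- vapply(split(seq_along(idx), key),
                function(j) sum(per_atom[j] * w[j]) / sum(w[j]), numeric(1))
  out[unique(key)]
}
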