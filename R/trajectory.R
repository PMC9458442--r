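#' Trajectory container
#'
#' A multi-frame Cartesian coordinate trajectory with atom and residue labels.
#' Coordinates are stored as a `frames x atoms x 3` array in Angstrom.
#' `boundaries` records the first frame (1-based) of each independent
#' trajectory segment, so that downstream time-lagged estimators never pair
#' frames across segments.
#'
#' @param coords Numeric array `frames x atoms x 3`, or a `frames x 3*atoms`
#'   matrix in bio3d xyz layout.
#' @param atoms Data frame with columns `elety` (atom name), `resid`
#'   (residue name), `resno` (residue number) and optionally `chain`.
#' @param dt Time between frames (arbitrary units, default 1).
#' @param boundaries Integer vector of 1-based segment start frames.
#' @return An object of class `md_traj`.
#' @export
md_trajectory <- function(coords, atoms, dt = 1, boundaries = 1L) {
  if (is.matrix(coords)) {
    n_at <- ncol(coords) / 3L
    coords <- aperm(array(t(coords), c(3L, n_at, nrow(coords))), c(3L, 2L, 1L))
  }
  .stop_if(length(dim(coords)) != 3L || dim(coords)[3] != 3L,
           "coords must be a frames x atoms x 3 array")
  .stop_if(nrow(atoms) != dim(coords)[2],
           "atoms table has %d rows but coords has %d atoms",
           nrow(atoms), dim(coords)[2])
  .stop_if(anyNA(coords), "coords contain missing values")
  boundaries <- as.integer(boundaries)
  .stop_if(boundaries[1] != 1L || is.unsorted(boundaries, strictly = TRUE),
           "boundaries must be strictly increasing and start at 1")
  .stop_if(any(boundaries > dim(coords)[1]), "boundary beyond last frame")
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$mass)) atoms$mass <- atom_mass(atoms$elety)
  structure(list(coords = coords, atoms = atoms, dt = dt,
                 boundaries = boundaries),
            class = "md_traj")
}

#' @export
print.md_traj <- function(x, ...) {
  cat(sprintf("md_traj: %d frame(s), %d atoms, %d segment(s)\n",
              n_frames(x), n_atoms(x), length(x$boundaries)))
  cat(sprintf("residues: %s\n",
              paste(unique(paste0(x$atoms$resid, x$atoms$resno)), collapse = " ")))
  invisible(x)
}

#' @rdname md_trajectory
#' @param traj An `md_traj` object.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname md_trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' Extract one frame as an atoms x 3 coordinate matrix
#' @param traj An `md_traj`.
#' @param i Frame index (1-based).
#' @export
frame_coords <- function(traj, i = 1L) {
  .stop_if(i < 1L || i > n_frames(traj), "frame %d out of range", i)
  matrix(traj$coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

# standard atomic masses (amu) keyed by leading element letter of the atom name
.mass_table <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                 P = 30.973762, S = 32.06)

#' Guess atomic masses from atom names
#'
#' Uses the first alphabetic character of the atom name (PDB convention for
#' the organic/backbone atoms handled here: H, C, N, O, P, S).
#' @param elety Character vector of atom names.
#' @return Numeric vector of masses in amu.
#' @export
atom_mass <- function(elety) {
  el <- toupper(substr(gsub("^[0-9']+", "", elety), 1, 1))
  m <- .mass_table[el]
  .stop_if(anyNA(m), "unknown element for atom name(s): %s",
           paste(unique(elety[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Read a PDB trajectory
#'
#' Reads one or more (multi-MODEL) PDB files and concatenates them into a
#' single [md_trajectory()], recording a segment boundary at the start of
#' each file so lagged estimators never cross file boundaries.
#'
#' @param paths Character vector of PDB file paths.
#' @param dt Time between frames.
#' @return An `md_traj`.
#' @export
read_trajectory <- function(paths, dt = 1) {
  .stop_if(length(paths) == 0, "no input paths")
  xyz <- NULL; atoms <- NULL; boundaries <- integer(0); off <- 0L
  for (p in paths) {
    .stop_if(!file.exists(p), "input file does not exist: %s", p)
    pdb <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
    a <- pdb$atom[, c("elety", "resid", "resno", "chain")]
    x <- pdb$xyz
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    if (is.null(atoms)) {
      atoms <- a
    } else {
      .stop_if(nrow(a) != nrow(atoms),
               "atom count mismatch in %s: %d vs %d", p, nrow(a), nrow(atoms))
    }
    boundaries <- c(boundaries, off + 1L)
    off <- off + nrow(x)
    xyz <- rbind(xyz, x)
  }
  md_trajectory(xyz, atoms, dt = dt, boundaries = boundaries)
}

#' Write a trajectory as a multi-MODEL PDB file
#'
#' @param traj An `md_traj`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  nf <- n_frames(traj)
  xyz <- t(matrix(aperm(traj$coords, c(3L, 2L, 1L)), ncol = nf))
  bio3d::write.pdb(file = file, xyz = xyz,
                   elety = traj$atoms$elety, resid = traj$atoms$resid,
                   resno = traj$atoms$resno, chain = traj$atoms$chain)
  invisible(file)
}
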