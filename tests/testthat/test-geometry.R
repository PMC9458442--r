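test_that("center of mass matches midpoint, weighted mean and summation oracle", {
  traj <- random_traj(1, 5, seed = 1)
  fr <- frame_coords(traj)
  fr[1, ] <- c(0, 0, 0); fr[2, ] <- c(2, 0, 0)
  sel_eq <- atom_selection(traj, 1:2, masses = c(1, 1))
  expect_equal(center_of_mass(fr, sel_eq), c(x = 1, y = 0, z = 0))
  sel_w <- atom_selection(traj, 1:2, masses = c(1, 3))
  expect_equal(center_of_mass(fr, sel_w), c(x = 1.5, y = 0, z = 0))
  sel_all <- atom_selection(traj, 1:5)
  expect_equal(unname(center_of_mass(fr, sel_all)),
               com_oracle(fr, traj$atoms$mass), tolerance = 1e-12)
  expect_error(atom_selection(traj, integer(0)), "empty")
})

test_that("COM distance is Euclidean, symmetric and satisfies the triangle inequality", {
  traj <- random_traj(1, 9, seed = 2)
  fr <- frame_coords(traj)
  a <- atom_selection(traj, 1:3); b <- atom_selection(traj, 4:6)
  c3 <- atom_selection(traj, 7:9)
  expect_equal(com_distance(fr, a, a), 0)
  fr2 <- fr; fr2[1, ] <- c(0, 0, 0); fr2[2, ] <- c(3, 4, 0)
  s1 <- atom_selection(traj, 1); s2 <- atom_selection(traj, 2)
  expect_equal(com_distance(fr2, s1, s2), 5)
  expect_equal(com_distance(fr, a, b), com_distance(fr, b, a))
  expect_equal(com_distance(fr, a, b),
               sqrt(sum((center_of_mass(fr, a) - center_of_mass(fr, b))^2)))
  expect_lte(com_distance(fr, a, c3),
             com_distance(fr, a, b) + com_distance(fr, b, c3))
})

test_that("torsion reproduces textbook geometries and the atan2 sign convention", {
  traj <- random_traj(1, 4, seed = 3)
  fr <- frame_coords(traj)
  # planar cis
  fr[1, ] <- c(0, 1, 0); fr[2, ] <- c(0, 0, 0)
  fr[3, ] <- c(1, 0, 0); fr[4, ] <- c(1, 1, 0)
  expect_equal(torsion(fr, 1:4), 0)
  # +-90 out of plane, sign fixed by the convention
  fr[4, ] <- c(1, 0, 1)
  t1 <- torsion(fr, 1:4)
  expect_equal(abs(t1), 90)
  # trans geometry
  fr[4, ] <- c(1, -1, 0)
  expect_equal(abs(torsion(fr, 1:4)), 180)
  # mirror image flips the sign
  fr[4, ] <- c(1, 0, 1)
  frm <- fr; frm[, 3] <- -frm[, 3]
  expect_equal(torsion(frm, 1:4), -t1)
  # degenerate colinear axis
  frc <- fr; frc[1, ] <- c(0, 0, 0); frc[2, ] <- c(1, 0, 0)
  frc[3, ] <- c(2, 0, 0)
  expect_error(torsion(frc, 1:4), "colinear")
  frc[2, ] <- frc[1, ]
  expect_error(torsion(frc, 1:4), "coincide")
})

test_that("torsion agrees with an independent dihedral implementation", {
  for (seed in 1:5) {
    set.seed(seed)
    P <- matrix(rnorm(12, sd = 2), 4, 3)
    traj <- md_trajectory(array(P, c(1, 4, 3)),
                         data.frame(elety = c("C1", "C2", "C3", "C4"),
                                    resid = "DT", resno = 1, chain = "A"))
    ours <- torsion(frame_coords(traj), 1:4)
    ref <- bio3d::torsion.xyz(as.numeric(t(P)), atm.inc = 4)
    expect_equal(ours, as.numeric(ref[1]), tolerance = 1e-6)
  }
})

test_that("cpdb equals torsion on singleton selections and is rigid-motion invariant", {
  traj <- random_traj(3, 8, seed = 4)
  sels <- lapply(1:4, function(i) atom_selection(traj, i))
  spec <- cpdb_spec(sels[[1]], sels[[2]], sels[[3]], sels[[4]])
  fr <- frame_coords(traj, 2)
  expect_equal(cpdb(fr, spec), torsion(fr, 1:4))
  # invariance under random rigid motions, 1e-9 degrees
  grp <- cpdb_spec(atom_selection(traj, 1:2), atom_selection(traj, 3),
                   atom_selection(traj, 4:5), atom_selection(traj, 6:8))
  base <- cpdb(fr, grp)
  for (seed in 1:5) {
    moved <- apply_rigid(traj$coords, seed)
    fr2 <- matrix(moved[2, , ], ncol = 3)
    expect_equal(cpdb(fr2, grp), base, tolerance = 1e-9)
    expect_equal(torsion(fr2, 1:4), torsion(fr, 1:4), tolerance = 1e-9)
  }
})

test_that("hydrogen-bond occupancy matches a per-frame boolean oracle", {
  # constructed 10-frame trajectory: bond criteria met in exactly half
  nf <- 10
  coords <- array(0, c(nf, 3, 3))
  for (t in seq_len(nf)) {
    dDA <- if (t <= 5) 2.9 else 4.2        # beyond 3.5 A in the second half
    coords[t, 1, ] <- c(0, 0, 0)           # donor
    coords[t, 2, ] <- c(1, 0, 0)           # hydrogen (D-H-A near 180)
    coords[t, 3, ] <- c(dDA, 0, 0)         # acceptor
  }
  atoms <- data.frame(elety = c("O6", "HO6", "N1"), resid = c("TG", "TG", "DA"),
                      resno = c(1, 1, 2), chain = "A")
  traj <- md_trajectory(coords, atoms)
  spec <- hbond_spec(1, 2, 3)
  expect_equal(hbond_occupancy(traj, spec), 0.5)
  # all frames bonded
  traj2 <- traj; traj2$coords[, 3, 1] <- 3.0
  expect_equal(hbond_occupancy(traj2, spec), 1.0)
  # random geometry vs explicit loop
  rt <- random_traj(100, 3, seed = 9)
  occ <- hbond_occupancy(rt, spec)
  ok <- vapply(seq_len(100), function(t) {
    fr <- frame_coords(rt, t)
    d <- sqrt(sum((fr[1, ] - fr[3, ])^2))
    v1 <- fr[1, ] - fr[2, ]; v2 <- fr[3, ] - fr[2, ]
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    d <= 3.5 && ang >= 120
  }, logical(1))
  expect_equal(occ, mean(ok))
})

test_that("occupancy is monotone in both cutoffs", {
  rt <- random_traj(200, 3, seed = 10)
  dcuts <- c(2, 3.5, 5, 8)
  occ_d <- vapply(dcuts, function(dc)
    hbond_occupancy(rt, hbond_spec(1, 2, 3, distance_cutoff = dc)), numeric(1))
  expect_true(all(diff(occ_d) >= 0))
  acuts <- c(30, 90, 150)
  occ_a <- vapply(acuts, function(ac)
    hbond_occupancy(rt, hbond_spec(1, 2, 3, angle_cutoff = ac)), numeric(1))
  expect_true(all(diff(occ_a) <= 0))
})

test_that("RMSD is zero under rigid motion and matches the closed form without fitting", {
  traj <- random_traj(4, 10, seed = 11)
  # frame identical to the reference
  expect_equal(rmsd_series(traj, reference = 1)[1], 0, tolerance = 1e-8)
  # pure translation and full rigid motion removed by fitting
  moved <- traj
  moved$coords[2, , ] <- sweep(matrix(traj$coords[1, , ], ncol = 3), 2,
                               c(5, 5, 5), `+`)
  moved$coords[3, , ] <- apply_rigid(traj$coords, 5)[1, , ]
  r <- rmsd_series(moved, reference = 1)
  expect_lt(r[2], 1e-6)
  expect_lt(r[3], 1e-6)
  # random unit displacements, no fitting: closed-form RMSD
  set.seed(12)
  disp <- matrix(rnorm(30), 10, 3)
  disp <- disp / sqrt(rowSums(disp^2))
  shifted <- traj
  shifted$coords[2, , ] <- traj$coords[1, , ] + disp
  expect_equal(rmsd_series(shifted, reference = 1, fit = FALSE)[2], 1,
               tolerance = 1e-10)
  expect_error(rmsd_series(random_traj(2, 2, seed = 1)), "3 atoms")
})

test_that("RMSF measures per-atom fluctuation and aggregates per residue", {
  # atom 1 oscillates along x with known RMS amplitude 1; a wide static
  # scaffold of 12 atoms pins the superposition so little of the motion is
  # absorbed into the rigid-body fit
  nf <- 200; na <- 13
  set.seed(13)
  base <- rbind(c(0, 0, 0), matrix(rnorm(36, sd = 12), 12, 3))
  coords <- array(NA_real_, c(nf, na, 3))
  for (t in seq_len(nf)) coords[t, , ] <- base
  amp <- sqrt(2) * sin(2 * pi * seq_len(nf) / nf)
  coords[, 1, 1] <- coords[, 1, 1] + amp
  atoms <- data.frame(elety = rep("C1", na), resid = "DT",
                      resno = c(1, rep(2, na - 1)), chain = "A")
  traj <- md_trajectory(coords, atoms)
  f <- rmsf(traj)
  expect_equal(unname(f[1]), 1, tolerance = 0.1)
  expect_lt(max(f[-1]), 0.2)
  fr <- rmsf(traj, per_residue = TRUE)
  expect_equal(length(fr), 2)
  expect_gt(fr[1], fr[2])
})
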