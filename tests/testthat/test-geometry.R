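# Convex-hull ECD expansion, loop RMSD, RMSF, glycan tracking, COM
# displacement.

# one-CA-per-chain pentamer with hand-set coordinates
pentagon_ensemble <- function(r = 10, nframes = 3, rot = 0, shift = c(0, 0)) {
  sys <- make_system(elety = rep("CA", 5), resid = "ALA", resno = 1,
                     chain = LETTERS[1:5], element = "C")
  th <- 2 * pi * (0:4) / 5 + rot
  m <- cbind(r * cos(th) + shift[1], r * sin(th) + shift[2], 0)
  xyz <- matrix(rep(as.numeric(t(m)), nframes), nrow = nframes,
                byrow = TRUE)
  list(sys = sys,
       ens = trajectory_ensemble(sys, list(xyz)),
       sels = lapply(LETTERS[1:5], function(ch)
         select_atoms(sys, chains = ch)))
}

test_that("pentagon hull area matches the shoelace closed form", {
  p <- pentagon_ensemble(r = 10)
  hull <- ecd_hull_area(p$ens, p$sels)
  expect_equal(hull$mean, 2.5 * 100 * sin(2 * pi / 5), tolerance = 1e-6)
  expect_equal(hull$mean, 237.764129, tolerance = 1e-6)
  # all frames identical: per-frame SEM of areas is zero
  expect_equal(stats::sd(hull$per_frame[[1]]), 0)
})

test_that("hull ignores interior points and is rigid-motion invariant", {
  sys <- make_system(elety = rep("CA", 5), resid = "ALA", resno = 1,
                     chain = LETTERS[1:5], element = "C")
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
              c(0.5, 0.5, 0))
  ens <- trajectory_ensemble(sys, list(matrix(as.numeric(t(sq)),
                                              nrow = 1)))
  sels <- lapply(LETTERS[1:5], function(ch) select_atoms(sys, chains = ch))
  expect_equal(ecd_hull_area(ens, sels)$mean, 1.0)

  base <- ecd_hull_area(pentagon_ensemble(r = 7)$ens,
                        pentagon_ensemble(r = 7)$sels)$mean
  rot <- pentagon_ensemble(r = 7, rot = 1.1, shift = c(30, -12))
  expect_equal(ecd_hull_area(rot$ens, rot$sels)$mean, base)
})

test_that("degenerate collinear COMs give area zero with a warning", {
  sys <- make_system(elety = rep("CA", 3), resid = "ALA", resno = 1,
                     chain = c("A", "B", "C"), element = "C")
  line <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  ens <- trajectory_ensemble(sys, list(matrix(as.numeric(t(line)),
                                              nrow = 1)))
  sels <- lapply(c("A", "B", "C"), function(ch)
    select_atoms(sys, chains = ch))
  expect_warning(h <- ecd_hull_area(ens, sels), "degenerate")
  expect_equal(h$mean, 0)
})

test_that("loop RMSD is zero for repeats and rigid motion, and recovers
           a planted 1 A displacement", {
  # large anchor (40 residues) so the fit drag from the 3-residue loop
  # displacement stays small
  fx <- loop_fixture(n = 40, loop = 18:20)
  fr0 <- as.numeric(t(fx$base))

  ens <- trajectory_ensemble(fx$sys,
                             list(matrix(rep(fr0, 4), nrow = 4,
                                         byrow = TRUE)))
  expect_equal(loop_rmsd(ens, fx$loop)$per_frame[[1]], rep(0, 4))

  shifted <- sweep(fx$base, 2, c(3, 4, 0), "+")
  ens2 <- trajectory_ensemble(fx$sys,
                              list(rbind(fr0, as.numeric(t(shifted)))))
  expect_equal(loop_rmsd(ens2, fx$loop)$per_frame[[1]], c(0, 0),
               tolerance = 1e-8)

  moved <- fx$base
  moved[fx$loop$eleno, 1] <- moved[fx$loop$eleno, 1] + 1
  ens3 <- trajectory_ensemble(fx$sys,
                              list(rbind(fr0, as.numeric(t(moved)))))
  r <- loop_rmsd(ens3, fx$loop)$per_frame[[1]][2]
  # the 12 loop atoms drag the 40-atom fit slightly; ~1 A up to that bias
  expect_equal(r, 1.0, tolerance = 0.1)
  expect_gt(r, 0.5)
})

test_that("RMSF closed forms: static zero, two-point alternation, and
           planted amplitude ordering", {
  fx <- loop_fixture()
  fr0 <- as.numeric(t(fx$base))
  sel1 <- select_atoms(fx$sys, chains = "A", resno = 5, atoms = "calpha")
  anchor <- select_atoms(fx$sys, chains = "A", resno = c(1:3, 8:10),
                         atoms = "backbone")

  ens <- trajectory_ensemble(fx$sys,
                             list(matrix(rep(fr0, 6), nrow = 6,
                                         byrow = TRUE)))
  expect_equal(rmsf(ens, sel1, fit_selection = anchor)$mean, 0)

  # atom alternating +-1 A about its mean in a frozen frame -> RMSF 1
  alt <- matrix(rep(fr0, 6), nrow = 6, byrow = TRUE)
  col <- 3 * sel1$eleno - 2
  alt[, col] <- alt[, col] + rep(c(-1, 1), 3)
  ens2 <- trajectory_ensemble(fx$sys, list(alt))
  expect_equal(rmsf(ens2, sel1, fit_selection = anchor)$mean, 1.0,
               tolerance = 1e-8)

  # planted amplitude ordering is preserved
  set.seed(1)
  big <- matrix(rep(fr0, 400), nrow = 400, byrow = TRUE)
  sel2 <- select_atoms(fx$sys, chains = "A", resno = 6, atoms = "calpha")
  for (ax in 0:2) {
    big[, 3 * sel1$eleno - 2 + ax] <-
      big[, 3 * sel1$eleno - 2 + ax] + rnorm(400, sd = 0.5)
    big[, 3 * sel2$eleno - 2 + ax] <-
      big[, 3 * sel2$eleno - 2 + ax] + rnorm(400, sd = 1.5)
  }
  ens3 <- trajectory_ensemble(fx$sys, list(big))
  r1 <- rmsf(ens3, sel1, fit_selection = anchor)$mean
  r2 <- rmsf(ens3, sel2, fit_selection = anchor)$mean
  expect_lt(r1, r2)
  expect_error(rmsf(trajectory_ensemble(fx$sys,
                                        list(matrix(fr0, nrow = 1))),
                    sel1),
               "at least two frames")
})

test_that("glycan tracking reports orientation and planted density", {
  spec <- synthetic_spec(
    seed = 12, n_frames = 30, n_replicas = 1,
    glycan_anchors = data.frame(chain = "B", resno = 138, n_sugars = 4,
                                sway = 0))
  gen <- generate_trajectory(build_pentamer_template(spec))
  tr <- track_glycan(gen$ensemble, anchor = list("B", 138),
                     terminal = list("B", 504))
  # static glycan: constant orientation, zero RMSF
  expect_equal(stats::sd(tr$replicas[[1]]$orientation[, "x"]), 0)
  expect_equal(tr$rmsf$mean, 0)
  expect_equal(unname(tr$terminal_xy_sd), c(0, 0))

  # terminal on a circle of radius 5 about the anchor
  sys <- make_system(elety = c("CA", "O5"), resid = c("ASN", "MAN"),
                     resno = c(138, 501), chain = "B",
                     element = c("C", "O"))
  ang <- seq(0, 2 * pi, length.out = 12)
  xyz <- t(vapply(ang, function(a)
    c(0, 0, 0, 5 * cos(a), 5 * sin(a), 0), numeric(6)))
  tr2 <- track_glycan(trajectory_ensemble(sys, list(xyz)),
                      anchor = list("B", 138), terminal = list("B", 501),
                      glycan_selection = select_atoms(sys, atoms = "O5"),
                      fit_selection = select_atoms(sys, atoms = "CA"))
  expect_equal(sqrt(rowSums(tr2$replicas[[1]]$orientation^2)),
               rep(5, 12))
})

test_that("COM displacement splits magnitude and radial component", {
  sys <- make_ca_system(2, chain = "A")
  mk <- function(p1, p2) as.numeric(t(rbind(p1, p2)))
  # radially inward move by 2.61 A between windows
  xyz <- rbind(mk(c(10, 0, 0), c(12, 0, 0)),
               mk(c(10, 0, 0), c(12, 0, 0)),
               mk(c(10 - 2.61, 0, 0), c(12 - 2.61, 0, 0)),
               mk(c(10 - 2.61, 0, 0), c(12 - 2.61, 0, 0)))
  ens <- trajectory_ensemble(sys, list(xyz))
  sel <- select_atoms(sys, chains = "A")
  cd <- com_displacement(ens, sel, 1:2, 3:4)
  expect_equal(cd$radial, -2.61)
  expect_equal(cd$magnitude, 2.61)

  # pure rotation about z: radial zero, magnitude positive
  th <- pi / 3
  rot <- rbind(mk(c(10, 0, 0), c(12, 0, 0)),
               mk(10 * c(cos(th), sin(th), 0), 12 * c(cos(th), sin(th), 0)))
  cd2 <- com_displacement(trajectory_ensemble(sys, list(rot)), sel, 1, 2)
  expect_equal(cd2$radial, 0, tolerance = 1e-12)
  expect_gt(cd2$magnitude, 0)

  # no motion
  cd3 <- com_displacement(ens, sel, 1, 2)
  expect_equal(cd3$magnitude, 0)
  expect_error(com_displacement(ens, sel, integer(0), 3:4), "empty")
  expect_error(com_displacement(ens, sel, 1:3, 3:4), "disjoint")
})
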