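# HOLE-style profiling, gate bookkeeping, water accounting, and the
# permeability contingency test.

test_that("analytic ring: 12 atoms (vdW 1.7) on a 5 A circle give 3.30 A", {
  phi <- 2 * pi * (0:11) / 12
  fr <- as.numeric(t(cbind(5 * cos(phi), 5 * sin(phi), 0)))
  r <- pore_radius_at(fr, 0, rep(1.7, 12), 1:12)
  expect_equal(r$radius, 3.30, tolerance = 1e-3)

  # ring displaced to (1, 0): optimum moves off-axis, radius unchanged
  fr2 <- as.numeric(t(cbind(1 + 5 * cos(phi), 5 * sin(phi), 0)))
  r2 <- pore_radius_at(fr2, 0, rep(1.7, 12), 1:12)
  expect_equal(r2$radius, 3.30, tolerance = 5e-3)
  expect_equal(r2$center, c(1, 0), tolerance = 0.05)
})

test_that("two concentric rings give a monotone funnel profile", {
  fx <- make_ring_fixture(list(
    list(n = 16, r = 3 + 1.7, z = 0, vdw = 1.7, cx = 0, cy = 0),
    list(n = 16, r = 6 + 1.7, z = 10, vdw = 1.7, cx = 0, cy = 0)))
  sys <- make_ca_system(nrow(fx$coords))
  sys$atoms$vdw <- fx$vdw
  prof <- pore_profile(fx$frame, sys, reference_point = c(0, 0, 0),
                       zlim = c(0, 10), step = 5)
  expect_lt(prof$radius[prof$z == 0], prof$radius[prof$z == 10])
  expect_equal(prof$radius[prof$z == 0], 3.0, tolerance = 0.02)
  expect_equal(prof$radius[prof$z == 10], 6.0, tolerance = 0.02)
})

test_that("empty planes report the end radius and radii stay in range", {
  fr <- as.numeric(t(cbind(5, 0, 0)))
  r <- pore_radius_at(fr, 60, 1.7, 1)
  expect_equal(r$radius, 25)
  r2 <- pore_radius_at(fr, 0, 1.7, 1, end_radius = 10)
  expect_lte(r2$radius, 10)
  expect_gte(r2$radius, 0)
})

test_that("profiler matches the exhaustive brute-force oracle on
           randomised ring fixtures", {
  set.seed(99)
  for (k in 1:6) {
    rings <- lapply(seq_len(sample(2:3, 1)), function(zi)
      list(n = sample(12:18, 1), r = runif(1, 3, 6),
           z = (zi - 1) * 3, vdw = sample(c(1.7, 1.55, 1.52), 1),
           cx = runif(1, -1, 1), cy = runif(1, -1, 1)))
    fx <- make_ring_fixture(rings)
    for (z in c(0, 1.5, 3)) {
      imp <- pore_radius_at(fx$frame, z, fx$vdw, fx$idx)$radius
      orc <- oracle_pore_radius(fx$coords, fx$vdw, z)
      expect_equal(imp, orc, tolerance = 0.05)
    }
  }
})

test_that("pore radius is invariant under z-rotation and z-translation", {
  fx <- make_ring_fixture(list(
    list(n = 14, r = 4.5, z = 0, vdw = 1.7, cx = 0.5, cy = -0.3)))
  base <- pore_radius_at(fx$frame, 0, fx$vdw, fx$idx)$radius
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  m2 <- fx$coords %*% R
  m2[, 3] <- m2[, 3] + 7
  r2 <- pore_radius_at(as.numeric(t(m2)), 7, fx$vdw, fx$idx)$radius
  expect_equal(r2, base, tolerance = 0.02)
})

test_that("shrinking every ring radius by delta lowers r(z) by delta", {
  mk <- function(rr) {
    spec <- synthetic_spec(seed = 8, n_frames = 3, n_replicas = 1,
                           pore_radius_schedule = list(AG = rr, HCS2 = rr,
                                                       DG = rr))
    gen <- generate_trajectory(build_pentamer_template(spec))
    gs <- select_atoms(gen$ensemble$system, resno = 291, atoms = "calpha")
    gate_trace(gen$ensemble, gs)$mean
  }
  expect_equal(mk(2.0) - mk(1.5), 0.5, tolerance = 5e-3)
})

test_that("gate closure bookkeeping at the 1.25 A threshold", {
  # scheduled 70% at 2.0 A / 30% at 1.0 A -> closure probability 0.30
  sched <- rep(2.0, 10); sched[c(2, 5, 9)] <- 1.0
  spec <- synthetic_spec(seed = 13, n_frames = 10, n_replicas = 2,
                         pore_radius_schedule = list(AG = sched,
                                                     HCS2 = 2, DG = 2))
  gen <- generate_trajectory(build_pentamer_template(spec))
  gs <- select_atoms(gen$ensemble$system, resno = 291, atoms = "calpha")
  tr <- gate_trace(gen$ensemble, gs)
  expect_equal(tr$closure_probability, 0.30)
  expect_equal(sort(unique(round(tr$per_frame[[1]], 2))), c(1.0, 2.0))
  # constant schedule: mean 2.0 within grid tolerance, SEM ~ 0
  spec2 <- synthetic_spec(seed = 14, n_frames = 5, n_replicas = 2,
                          pore_radius_schedule = list(AG = 2, HCS2 = 2,
                                                      DG = 2))
  gen2 <- generate_trajectory(build_pentamer_template(spec2))
  gs2 <- select_atoms(gen2$ensemble$system, resno = 291, atoms = "calpha")
  tr2 <- gate_trace(gen2$ensemble, gs2)
  expect_equal(tr2$mean, 2.0, tolerance = 0.01)
  expect_equal(tr2$sem, 0, tolerance = 1e-6)

  # a frame at exactly 1.25 A counts as closed / non-permeable
  expect_warning(
    pt <- permeability_test(list(a = c(1.25, 2.0), b = c(2.0, 2.0))),
    "expected cell count")
  expect_equal(unname(pt$table["a", "non_permeable"]), 1)
  expect_equal(unname(pt$closure_probability[["a"]]), 0.5)
  # closure probability + permeable fraction = 1
  expect_equal(pt$closure_probability[["a"]] +
                 pt$table["a", "permeable"] / 2, 1)
})

test_that("water histogram counts column waters into half-open bins", {
  spec <- synthetic_spec(seed = 15, n_frames = 4, n_replicas = 1,
                         water_bin_counts = c(0L, 0L, 0L, 0L, 0L, 7L, 0L,
                                              2L, 0L, 0L),
                         n_decoy_waters = 3)
  gen <- generate_trajectory(build_pentamer_template(spec))
  wh <- water_histogram(gen$ensemble)
  expect_equal(wh$mean, c(0, 0, 0, 0, 0, 7, 0, 2, 0, 0))
  # bin totals = number of in-column waters, decoys excluded
  expect_equal(colSums(wh$per_frame[[1]]), rep(9, 4))
  expect_identical(wh$per_frame[[1]],
                   gen$ground_truth$water_bins[[1]])

  # oxygen exactly on an edge goes to the upper bin; off-column excluded
  sysw <- make_system(elety = c("O", "O"), resid = "HOH", resno = 1:2,
                      chain = "W", element = "O")
  xyz <- matrix(c(0, 0, 2, 2.6, 0, 1), nrow = 1)
  whw <- water_histogram(trajectory_ensemble(sysw, list(xyz)),
                         zlim = c(0, 4), bin = 2)
  expect_equal(unname(whw$mean), c(0, 1))
})

test_that("water-wire continuity through the gate region", {
  mk_wat <- function(zs, xs = 0) {
    n <- length(zs)
    sysw <- make_system(elety = rep("O", n), resid = "HOH", resno = 1:n,
                        chain = "W", element = "O")
    trajectory_ensemble(sysw,
                        list(matrix(as.numeric(t(cbind(xs, 0, zs))),
                                    nrow = 1)))
  }
  expect_equal(water_wire_fraction(mk_wat(c(-4, -2, 0, 2, 4)))$fraction, 1)
  expect_equal(water_wire_fraction(mk_wat(c(-4, -2, 2, 4)))$fraction, 0)
  # scheduled wire fraction is recovered exactly
  spec <- synthetic_spec(seed = 16, n_frames = 100, n_replicas = 2,
                         water_wire_schedule = 0.43)
  gen <- generate_trajectory(build_pentamer_template(spec))
  expect_equal(water_wire_fraction(gen$ensemble)$fraction, 0.43)
  expect_equal(gen$ground_truth$wire_fraction, c(0.43, 0.43))
})

test_that("permeability chi-squared matches the closed-form oracle and
           sweeps the threshold", {
  # constructed counts: 302/698 vs 598/402
  ra <- c(rep(1.0, 698), rep(2.0, 302))
  rb <- c(rep(1.0, 402), rep(2.0, 598))
  pt <- permeability_test(list(A = ra, B = rb))
  tab <- rbind(c(302, 698), c(598, 402))
  expect_equal(pt$statistic, oracle_chisq_2x2(tab), tolerance = 1e-10)
  expect_equal(unname(pt$df), 1)
  expect_lt(pt$p_value, 1e-10)

  # identical rows: statistic 0, p = 1
  pt0 <- permeability_test(list(A = ra, B = ra))
  expect_equal(unname(pt0$statistic), 0)
  expect_equal(pt0$p_value, 1)

  # systems differing only above 1.4 A: flat statistic below, signal above
  ra2 <- c(rep(1.35, 50), rep(1.45, 50))
  rb2 <- c(rep(1.35, 50), rep(1.55, 50))
  expect_warning(pt2 <- permeability_test(list(A = ra2, B = rb2)),
                 "expected cell count")
  sens <- pt2$sensitivity
  expect_true(all(sens$statistic[sens$threshold < 1.4] == 0))
  expect_gt(max(sens$statistic[sens$threshold >= 1.45]), 10)
})
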