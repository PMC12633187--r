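# Synthetic generator: construction rules, determinism, and exactness of
# the planted ground truth, cross-checked by independent re-measurement
# of the emitted files.

test_that("template obeys the construction rules of the spec", {
  spec <- synthetic_spec(
    seed = 1, n_frames = 2, n_replicas = 1,
    glycan_anchors = data.frame(chain = "A", resno = 138, n_sugars = 8))
  tpl <- build_pentamer_template(spec)
  at <- tpl$system$atoms

  expect_setequal(unique(at$chain), LETTERS[1:5])
  expect_equal(sum(at$chain == "A" & at$resno == 138 & at$resid == "ASN" &
                   at$elety == "CA"), 1)
  expect_equal(sum(at$resid == "MAN" & at$elety == "O5" &
                   at$chain == "A"), 8)
})

test_that("same spec and seed give byte-identical PDB output", {
  spec <- synthetic_spec(
    seed = 77, n_frames = 10, n_replicas = 2,
    planted_bridges = data.frame(chain_a = "B", resno_a = 90,
                                 resid_a = "GLU", chain_b = "A",
                                 resno_b = 126, resid_b = "ARG",
                                 occupancy = 0.5),
    glycan_anchors = data.frame(chain = "B", resno = 138, n_sugars = 3,
                                sway = 0.5))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(build_pentamer_template(spec),
                generate_trajectory(build_pentamer_template(spec)), d1)
  write_fixture(build_pentamer_template(spec),
                generate_trajectory(build_pentamer_template(spec)), d2)
  expect_no_diff_files(d1, d2)
})

test_that("spec validation catches inconsistent plants", {
  expect_error(synthetic_spec(seed = 1, planted_bridges = data.frame(
    chain_a = "Z", resno_a = 1, resid_a = "ASP",
    chain_b = "A", resno_b = 2, resid_b = "LYS", occupancy = 0.5)),
    "absent chain")
  expect_error(synthetic_spec(seed = 1, planted_bridges = data.frame(
    chain_a = "A", resno_a = 1, resid_a = "ASP",
    chain_b = "B", resno_b = 2, resid_b = "LYS", occupancy = 1.7)),
    "occupancy")
  expect_error(synthetic_spec(seed = 1,
                              pore_radius_schedule = list(AG = -0.5)),
               ">= 0")
})

test_that("planted occupancies are realised as exact frame counts", {
  spec <- synthetic_spec(
    seed = 10, n_frames = 100, n_replicas = 2,
    planted_bridges = data.frame(
      chain_a = c("B", "C"), resno_a = c(90L, 72L),
      resid_a = c("ASP", "GLU"),
      chain_b = c("A", "B"), resno_b = c(126L, 132L),
      resid_b = c("LYS", "ARG"),
      occupancy = c(0.60, 0.33)))
  gen <- generate_trajectory(build_pentamer_template(spec))
  gt <- gen$ground_truth$bridge_occupancy
  # 0.60 representable exactly; 0.33 realised as round(33)/100
  expect_equal(gt$occupancy[gt$pair == 1], c(0.60, 0.60))
  expect_equal(gt$occupancy[gt$pair == 2], c(0.33, 0.33))

  # exact per-frame presence, counted independently from the geometry
  xyz <- gen$ensemble$replicas[[1]]
  at <- gen$ensemble$system$atoms
  ia <- which(at$chain == "B" & at$resno == 90 & at$elety == "CG")
  ib <- which(at$chain == "A" & at$resno == 126 & at$elety == "NZ")
  d <- sqrt((xyz[, 3 * ia - 2] - xyz[, 3 * ib - 2])^2 +
            (xyz[, 3 * ia - 1] - xyz[, 3 * ib - 1])^2 +
            (xyz[, 3 * ia] - xyz[, 3 * ib])^2)
  expect_equal(sum(d < 4.0), 60)
})

test_that("changing the seed preserves planted targets exactly", {
  mk <- function(seed) {
    spec <- synthetic_spec(
      seed = seed, n_frames = 50, n_replicas = 1,
      planted_bridges = data.frame(chain_a = "B", resno_a = 90,
                                   resid_a = "ASP", chain_b = "A",
                                   resno_b = 126, resid_b = "LYS",
                                   occupancy = 0.40),
      pore_radius_schedule = list(AG = 1.8, HCS2 = 1.8, DG = 1.8),
      water_wire_schedule = 0.30)
    generate_trajectory(build_pentamer_template(spec))
  }
  g1 <- mk(1); g2 <- mk(2)
  expect_false(identical(g1$ensemble$replicas, g2$ensemble$replicas))
  expect_equal(g1$ground_truth$bridge_occupancy$occupancy,
               g2$ground_truth$bridge_occupancy$occupancy)
  expect_equal(g1$ground_truth$wire_fraction,
               g2$ground_truth$wire_fraction)
  expect_equal(g1$ground_truth$gate_radius$AG,
               g2$ground_truth$gate_radius$AG)
})

test_that("emitted files reproduce the ground truth by direct text-level
           re-measurement", {
  spec <- synthetic_spec(
    seed = 21, n_frames = 40, n_replicas = 1,
    planted_bridges = data.frame(chain_a = "B", resno_a = 90,
                                 resid_a = "ASP", chain_b = "A",
                                 resno_b = 126, resid_b = "LYS",
                                 occupancy = 0.45),
    pore_radius_schedule = list(AG = 2.2, HCS2 = 2.2, DG = 2.2))
  tpl <- build_pentamer_template(spec)
  gen <- generate_trajectory(tpl)
  dir <- withr::local_tempdir()
  write_fixture(tpl, gen, dir)

  occ <- oracle_pdb_pair_occupancy(
    file.path(dir, "replica_1.pdb"),
    list(elety = "CG", chain = "B", resno = 90),
    list(elety = "NZ", chain = "A", resno = 126))
  expect_equal(occ, 0.45)

  # planted AG radius against the exhaustive fine-grid oracle
  m <- matrix(gen$ensemble$replicas[[1]][1, ], ncol = 3, byrow = TRUE)
  at <- tpl$system$atoms
  keep <- at$element != "H" & at$resid != "HOH"
  r <- oracle_pore_radius(m[keep, , drop = FALSE], at$vdw[keep], z = 0)
  expect_equal(r, 2.2, tolerance = 0.01)
})

test_that("planted correlation blocks give the target sample correlation", {
  pair <- data.frame(chain = "C", resno = c(800L, 802L), resid = "ALA",
                     x = c(10, 14), y = 0, z = 10)
  spec <- synthetic_spec(
    seed = 5, n_frames = 4000, n_replicas = 1, scaffold_residues = 6,
    extra_residues = pair,
    correlation_blocks = list(list(nodes = pair[, c("chain", "resno")],
                                   rho = 0.8)))
  gen <- generate_trajectory(build_pentamer_template(spec))
  xyz <- gen$ensemble$replicas[[1]]
  at <- gen$ensemble$system$atoms
  i <- which(at$chain == "C" & at$resno == 800)
  j <- which(at$chain == "C" & at$resno == 802)
  # direct sample correlation of 3-D displacements (no package code)
  di <- scale(xyz[, (3 * i - 2):(3 * i)], scale = FALSE)
  dj <- scale(xyz[, (3 * j - 2):(3 * j)], scale = FALSE)
  rho <- sum(di * dj) / sqrt(sum(di^2) * sum(dj^2))
  expect_equal(rho, 0.8, tolerance = 0.05)
})
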