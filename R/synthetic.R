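## Seeded synthetic pentamer systems with planted, exactly known ground
## truth for every analysis stage.
##
## The generator builds a geometric toy channel: five chains with C5
## symmetry about the z axis, an extracellular scaffold ring (backbone
## beads at ~25 A radius, z ~ 18-28 A), three transmembrane gate rings of
## pore-lining atoms whose inscribed radius follows a per-frame schedule,
## an axial water column, optional glycan pseudo-chains anchored on
## asparagines, and free "network node" residues carrying planted
## correlated motions. There is no force field and no integrator: every
## observable is constructed, so its exact value is known.

.run_seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  force(expr)
}

#' Specification for a synthetic pentamer system
#'
#' All schedules and plants are per replica of `n_frames` frames; target
#' occupancies and fractions are realised as exact integer frame counts
#' (`round(target * n_frames)`), with the achieved value recorded in the
#' ground truth.
#'
#' @param seed integer master seed; fixed seed gives bit-identical output.
#' @param n_chains number of chains (>= 3; default 5).
#' @param n_frames frames per replica (>= 2).
#' @param n_replicas number of independent replicas.
#' @param scaffold_residues extracellular scaffold residues per chain.
#' @param planted_bridges data.frame with columns `chain_a, resno_a,
#'   resid_a` (GLU/ASP), `chain_b, resno_b, resid_b` (ARG/LYS),
#'   `occupancy` in \[0,1\], and optional `near`, `far` terminal-atom
#'   distances (A, default 3.5 / 6.0) straddling the 4 A cutoff.
#' @param planted_hbonds data.frame with columns `chain_d, resno_d,
#'   chain_a, resno_a, occupancy` and optional `near`, `far`
#'   donor-acceptor distances (default 3.0 / 5.5).
#' @param pore_radius_schedule named list `gate -> schedule` for gates
#'   `"AG"`, `"HCS2"`, `"DG"`; each schedule a numeric vector (recycled to
#'   `n_frames`, shared by replicas) or a list of per-replica vectors.
#'   Values are target inscribed radii (A, >= 0).
#' @param water_bin_counts integer vector of water counts per 2 A z-bin
#'   over \[-10, 10); waters are placed inside the 5x5 A axial column.
#' @param n_decoy_waters waters parked outside the column (x = 8 A).
#' @param water_wire_schedule either a fraction in \[0,1\] (realised as an
#'   exact frame count per replica) or a logical vector of length
#'   `n_frames`; in wire frames an unbroken 2 A-spaced water chain spans
#'   z in \[-4, 4\], otherwise its central water is parked away.
#' @param glycan_anchors data.frame with columns `chain, resno, n_sugars`
#'   and optional `sway` (A; rigid per-frame Gaussian sway of the whole
#'   glycan, expected atom RMSF = sqrt(3) * sway).
#' @param extra_residues data.frame `chain, resno, resid, x, y, z` of
#'   single-CA residues (network nodes, planted paths).
#' @param correlation_blocks list of `list(nodes = data.frame(chain,
#'   resno), rho)`; node atoms of each block move along a common random
#'   direction with population pairwise correlation exactly `rho`
#'   (in \[0, 1\]).
#' @param motion_amplitude standard deviation (A) of planted node motion.
#' @param node_jitter sd (A) of independent jitter given to extra
#'   residues outside every correlation block (0 disables).
#' @param hull_expansion_schedule per-frame radial scale factor applied to
#'   the scaffold in xy (default 1); scales hull area by its square.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed,
                           n_chains = 5L,
                           n_frames = 100L,
                           n_replicas = 2L,
                           scaffold_residues = 12L,
                           planted_bridges = NULL,
                           planted_hbonds = NULL,
                           pore_radius_schedule = list(AG = 2.0,
                                                       HCS2 = 2.0,
                                                       DG = 2.0),
                           water_bin_counts = NULL,
                           n_decoy_waters = 0L,
                           water_wire_schedule = NULL,
                           glycan_anchors = NULL,
                           extra_residues = NULL,
                           correlation_blocks = NULL,
                           motion_amplitude = 0.3,
                           node_jitter = 0.05,
                           hull_expansion_schedule = 1) {
  stopifnot(n_chains >= 3, n_frames >= 2, n_replicas >= 1)
  chains <- LETTERS[seq_len(n_chains)]
  chk_occ <- function(x, what) {
    if (any(x < 0 | x > 1))
      stop(what, ": target occupancy must lie in [0, 1]")
  }
  if (!is.null(planted_bridges)) {
    planted_bridges <- as.data.frame(planted_bridges)
    if (is.null(planted_bridges$near)) planted_bridges$near <- 3.5
    if (is.null(planted_bridges$far)) planted_bridges$far <- 6.0
    chk_occ(planted_bridges$occupancy, "planted_bridges")
    if (any(planted_bridges$near >= 4.0 | planted_bridges$far <= 4.0))
      stop("planted bridge near/far distances must straddle the 4 A cutoff")
    bad <- !(planted_bridges$chain_a %in% chains &
             planted_bridges$chain_b %in% chains)
    if (any(bad))
      stop("planted bridge references absent chain: pair ",
           which(bad)[1])
  }
  if (!is.null(planted_hbonds)) {
    planted_hbonds <- as.data.frame(planted_hbonds)
    if (is.null(planted_hbonds$near)) planted_hbonds$near <- 3.0
    if (is.null(planted_hbonds$far)) planted_hbonds$far <- 5.5
    chk_occ(planted_hbonds$occupancy, "planted_hbonds")
    if (any(planted_hbonds$near > 3.5 | planted_hbonds$far <= 3.5))
      stop("planted hbond near/far distances must straddle the 3.5 A cutoff")
  }
  sched <- lapply(pore_radius_schedule, function(s) {
    if (is.list(s)) lapply(s, function(v) rep_len(as.numeric(v), n_frames))
    else rep_len(as.numeric(s), n_frames)
  })
  if (any(unlist(sched) < 0)) stop("pore radius schedule values must be >= 0")
  if (!all(names(sched) %in% c("AG", "HCS2", "DG")))
    stop("gate labels must be among AG, HCS2, DG")
  if (!is.null(glycan_anchors)) {
    glycan_anchors <- as.data.frame(glycan_anchors)
    if (is.null(glycan_anchors$sway)) glycan_anchors$sway <- 0
    if (any(!glycan_anchors$chain %in% chains))
      stop("glycan anchor references absent chain")
  }
  if (!is.null(correlation_blocks)) {
    for (b in correlation_blocks) {
      if (b$rho < 0 || b$rho > 1)
        stop("correlation block rho must lie in [0, 1]")
    }
  }
  if (!is.null(water_wire_schedule) && !is.logical(water_wire_schedule)) {
    chk_occ(water_wire_schedule, "water_wire_schedule")
  }
  if (!is.null(water_wire_schedule) && !is.null(water_bin_counts)) {
    # the wire stripe (z in [-4, 4] inside the column) must hold only the
    # scheduled wire chain, or planted bin waters would bridge it
    inside <- 4:7   # bins [-4,-2), [-2,0), [0,2), [2,4)
    if (any(water_bin_counts[inside[inside <=
                                    length(water_bin_counts)]] > 0))
      stop("water_bin_counts inside the wire stripe (bins spanning ",
           "[-4, 4)) must be 0 when a water-wire schedule is planted")
  }
  structure(list(seed = as.integer(seed), n_chains = as.integer(n_chains),
                 chains = chains,
                 n_frames = as.integer(n_frames),
                 n_replicas = as.integer(n_replicas),
                 scaffold_residues = as.integer(scaffold_residues),
                 planted_bridges = planted_bridges,
                 planted_hbonds = planted_hbonds,
                 pore_radius_schedule = sched,
                 water_bin_counts = water_bin_counts,
                 n_decoy_waters = as.integer(n_decoy_waters),
                 water_wire_schedule = water_wire_schedule,
                 glycan_anchors = glycan_anchors,
                 extra_residues = extra_residues,
                 correlation_blocks = correlation_blocks,
                 motion_amplitude = motion_amplitude,
                 node_jitter = node_jitter,
                 hull_expansion_schedule =
                   rep_len(hull_expansion_schedule, n_frames)),
            class = "synthetic_spec")
}

# z positions of the three gate rings (A): activation gate at the
# reference plane, second hydrophobic constriction below it, then the
# desensitisation gate. 6 A spacing keeps each gate's +-2 A slab
# minimum independent of its neighbours even when one closes fully.
.GATE_Z <- c(AG = 0, HCS2 = -6, DG = -12)
.GATE_RESNO <- c(AG = 291L, HCS2 = 257L, DG = 249L)
.RING_PER_CHAIN <- 3L   # pore-lining ring atoms contributed per chain
.SCAFFOLD_R <- 25       # scaffold placement radius (A)

#' Build the static pentamer template for a synthetic spec
#'
#' Lays out all atoms at their reference positions and records the index
#' maps the trajectory generator animates. Deterministic: same spec gives
#' byte-identical topology.
#'
#' @param spec a [synthetic_spec()].
#' @return object of class `pentamer_template` with elements `system`
#'   (a [molecular_system()]), `xyz0` (reference frame vector) and
#'   `layout` (index bookkeeping).
#' @export
build_pentamer_template <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  chains <- spec$chains
  theta <- 2 * pi * (seq_along(chains) - 1) / length(chains)
  names(theta) <- chains

  rows <- list(); coords <- list(); bonds <- list()
  add_atom <- function(elety, element, resid, resno, chain, x, y, z) {
    rows[[length(rows) + 1L]] <<- data.frame(
      elety = elety, element = element, resid = resid,
      resno = as.integer(resno), chain = chain, stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- c(x, y, z)
    length(rows)
  }
  used_resno <- new.env(parent = emptyenv())
  claim_resno <- function(chain, resno, what) {
    key <- paste(chain, resno)
    if (!is.null(used_resno[[key]]))
      stop("residue collision in spec: ", what, " reuses ", key)
    used_resno[[key]] <- what
  }

  ## extracellular scaffold: backbone beads, symmetric about each chain
  ## axis so every chain COM sits exactly on a pentagon vertex
  S <- spec$scaffold_residues
  alpha <- if (S > 1) (seq_len(S) - 1) / (S - 1) * 0.5 - 0.25 else 0
  scaffold_idx <- list()
  for (ch in chains) {
    idx <- integer(0)
    for (j in seq_len(S)) {
      claim_resno(ch, j, "scaffold")
      a <- theta[ch] + alpha[j]
      cx <- .SCAFFOLD_R * cos(a); cy <- .SCAFFOLD_R * sin(a)
      zj <- 18 + 0.8 * j
      idx <- c(idx,
               add_atom("N",  "N", "GLY", j, ch, cx, cy, zj + 0.45),
               add_atom("CA", "C", "GLY", j, ch, cx, cy, zj),
               add_atom("C",  "C", "GLY", j, ch, cx, cy, zj - 0.45),
               add_atom("O",  "O", "GLY", j, ch, cx, cy, zj - 0.90))
    }
    scaffold_idx[[ch]] <- idx
  }
  # closed-form pentagon circumradius of scaffold chain COMs (backbone
  # atoms share each residue's xy; mass weighting cancels by symmetry)
  r_eff <- .SCAFFOLD_R * mean(cos(alpha))

  ## planted salt bridges: acid terminal fixed, base terminal animated
  bridge_layout <- NULL
  pb <- spec$planted_bridges
  if (!is.null(pb)) {
    bl <- list()
    for (i in seq_len(nrow(pb))) {
      ca <- pb$chain_a[i]; cb <- pb$chain_b[i]
      mid <- (theta[ca] + theta[cb]) / 2
      if (abs(theta[ca] - theta[cb]) > pi) mid <- mid + pi
      # 3 A vertical stacking: near-formed pairs of one plant stay > 4 A
      # from every other plant's atoms at the same interface
      zb <- 15 - 3 * (i - 1)
      px <- 22 * cos(mid); py <- 22 * sin(mid)
      acid_term <- switch(pb$resid_a[i], GLU = "CD", ASP = "CG",
                          stop("bridge ", i, ": resid_a must be GLU or ASP"))
      base_term <- switch(pb$resid_b[i], ARG = "CZ", LYS = "NZ",
                          stop("bridge ", i, ": resid_b must be ARG or LYS"))
      claim_resno(ca, pb$resno_a[i], paste0("bridge", i, ".acid"))
      claim_resno(cb, pb$resno_b[i], paste0("bridge", i, ".base"))
      add_atom("CA", "C", pb$resid_a[i], pb$resno_a[i], ca, px, py, zb + 1)
      ia <- add_atom(acid_term, "C", pb$resid_a[i], pb$resno_a[i], ca,
                     px, py, zb)
      add_atom("CA", "C", pb$resid_b[i], pb$resno_b[i], cb, px, py, zb - 2)
      # unit direction of approach: tangential at the interface
      ux <- -sin(mid); uy <- cos(mid)
      ib <- add_atom(base_term, if (base_term == "NZ") "N" else "C",
                     pb$resid_b[i], pb$resno_b[i], cb,
                     px + pb$far[i] * ux, py + pb$far[i] * uy, zb)
      bl[[i]] <- list(acid = ia, base = ib, origin = c(px, py, zb),
                      u = c(ux, uy, 0), near = pb$near[i], far = pb$far[i])
    }
    bridge_layout <- bl
  }

  ## planted hydrogen bonds: serine-like donor (OG-HG1), threonine-like
  ## acceptor (OG1); hydrogen kept on the donor-acceptor line
  hb_layout <- NULL
  hb <- spec$planted_hbonds
  if (!is.null(hb)) {
    hl <- list()
    for (i in seq_len(nrow(hb))) {
      cd <- hb$chain_d[i]; cacc <- hb$chain_a[i]
      mid <- (theta[cd] + theta[cacc]) / 2
      if (abs(theta[cd] - theta[cacc]) > pi) mid <- mid + pi
      zb <- 32 + 3 * (i - 1)   # above the scaffold shell (z <= ~28)
      px <- 22 * cos(mid); py <- 22 * sin(mid)
      ux <- -sin(mid); uy <- cos(mid)
      claim_resno(cd, hb$resno_d[i], paste0("hbond", i, ".donor"))
      claim_resno(cacc, hb$resno_a[i], paste0("hbond", i, ".acceptor"))
      add_atom("CA", "C", "SER", hb$resno_d[i], cd, px - ux, py - uy, zb)
      id <- add_atom("OG", "O", "SER", hb$resno_d[i], cd, px, py, zb)
      ih <- add_atom("HG1", "H", "SER", hb$resno_d[i], cd,
                     px + ux, py + uy, zb)
      add_atom("CA", "C", "THR", hb$resno_a[i], cacc,
               px + (hb$far[i] + 1) * ux, py + (hb$far[i] + 1) * uy, zb)
      ia <- add_atom("OG1", "O", "THR", hb$resno_a[i], cacc,
                     px + hb$far[i] * ux, py + hb$far[i] * uy, zb)
      bonds[[length(bonds) + 1L]] <- c(id, ih)
      hl[[i]] <- list(donor = id, hydrogen = ih, acceptor = ia,
                      origin = c(px, py, zb), u = c(ux, uy, 0),
                      near = hb$near[i], far = hb$far[i])
    }
    hb_layout <- hl
  }

  ## transmembrane gate rings: one leucine per chain per gate (its CA
  ## defines the gate plane) plus pore-lining ring atoms on a circle
  ## whose radius is animated by the schedule
  ## each gate also carries a containment wall ring 3 A outside the
  ## pore-lining ring (standing in for the helix bundle bulk) so the
  ## planar maximal-sphere search cannot escape outward
  gate_layout <- list()
  for (g in names(spec$pore_radius_schedule)) {
    zg <- .GATE_Z[[g]]
    ring_idx <- integer(0); ring_phi <- numeric(0); ca_idx <- integer(0)
    wall_idx <- integer(0); wall_phi <- numeric(0)
    m_total <- .RING_PER_CHAIN * length(chains)
    r0 <- spec$pore_radius_schedule[[g]]
    r0 <- if (is.list(r0)) r0[[1]][1] else r0[1]
    for (k in seq_along(chains)) {
      ch <- chains[k]
      claim_resno(ch, .GATE_RESNO[[g]], paste0("gate.", g))
      ca_idx <- c(ca_idx,
                  add_atom("CA", "C", "LEU", .GATE_RESNO[[g]], ch,
                           9 * cos(theta[ch]), 9 * sin(theta[ch]), zg))
      for (m in seq_len(.RING_PER_CHAIN)) {
        phi <- 2 * pi * ((.RING_PER_CHAIN * (k - 1) + m - 1) / m_total)
        ring_idx <- c(ring_idx,
                      add_atom(paste0("CP", m), "C", "LEU",
                               .GATE_RESNO[[g]], ch,
                               (r0 + 1.70) * cos(phi), (r0 + 1.70) * sin(phi),
                               zg))
        ring_phi <- c(ring_phi, phi)
        wphi <- phi + pi / m_total
        wall_idx <- c(wall_idx,
                      add_atom(paste0("CW", m), "C", "LEU",
                               .GATE_RESNO[[g]], ch,
                               (r0 + 4.70) * cos(wphi),
                               (r0 + 4.70) * sin(wphi), zg))
        wall_phi <- c(wall_phi, wphi)
      }
    }
    gate_layout[[g]] <- list(z = zg, ca = ca_idx, ring = ring_idx,
                             phi = ring_phi, wall = wall_idx,
                             wall_phi = wall_phi, vdw = 1.70)
  }

  ## axial water column (binned plants), wire chain, and decoys
  water_layout <- list(bin_edges = seq(-10, 10, by = 2))
  wb <- spec$water_bin_counts
  add_water <- function(resno, x, y, z) {
    io <- add_atom("O", "O", "HOH", resno, "W", x, y, z)
    add_atom("H1", "H", "HOH", resno, "W", x + 0.96, y, z)
    add_atom("H2", "H", "HOH", resno, "W", x - 0.24, y + 0.93, z)
    io
  }
  wat_resno <- 0L
  if (!is.null(wb)) {
    edges <- water_layout$bin_edges
    o_idx <- integer(0)
    for (b in seq_along(wb)) {
      nb <- wb[b]
      if (nb == 0) next
      for (i in seq_len(nb)) {
        wat_resno <- wat_resno + 1L
        ang <- 2.399963 * wat_resno   # golden-angle spiral, |x|,|y| <= 0.6
        zb <- edges[b] + 0.3 + 1.4 * (i - 1) / max(1, nb - 1)
        if (nb == 1) zb <- edges[b] + 1
        o_idx <- c(o_idx, add_water(wat_resno, 0.6 * cos(ang),
                                    0.6 * sin(ang), zb))
      }
    }
    water_layout$binned_o <- o_idx
  }
  if (!is.null(spec$water_wire_schedule)) {
    zw <- seq(-4, 4, by = 2)
    wire_o <- integer(0)
    for (z in zw) {
      wat_resno <- wat_resno + 1L
      wire_o <- c(wire_o, add_water(wat_resno, 0.2, 0.2, z))
    }
    water_layout$wire_o <- wire_o
    water_layout$wire_toggle <- wire_o[3]   # the z = 0 link
    water_layout$park <- c(20, 20, 40)
  }
  if (spec$n_decoy_waters > 0) {
    for (i in seq_len(spec$n_decoy_waters)) {
      wat_resno <- wat_resno + 1L
      add_water(wat_resno, 8, 0, -11 + i * 0.5)
    }
  }

  ## glycan pseudo-chains: ASN anchor, mannose-like sugars marching
  ## inward, each sugar carrying a ring O5
  glycan_layout <- NULL
  ga <- spec$glycan_anchors
  if (!is.null(ga)) {
    gl <- list()
    for (i in seq_len(nrow(ga))) {
      ch <- ga$chain[i]; a <- theta[ch]
      claim_resno(ch, ga$resno[i], paste0("glycan", i, ".anchor"))
      ica <- add_atom("CA", "C", "ASN", ga$resno[i], ch,
                      20 * cos(a), 20 * sin(a), 19)
      add_atom("ND2", "N", "ASN", ga$resno[i], ch,
               19.3 * cos(a), 19.3 * sin(a), 19)
      sugar_atoms <- integer(0); o5 <- integer(0)
      for (s in seq_len(ga$n_sugars[i])) {
        rs <- 500L + 20L * (i - 1L) + s
        claim_resno(ch, rs, paste0("glycan", i, ".sugar"))
        rr <- 19 - 1.8 * s
        ic1 <- add_atom("C1", "C", "MAN", rs, ch,
                        rr * cos(a), rr * sin(a), 19 - 0.3 * s)
        io5 <- add_atom("O5", "O", "MAN", rs, ch,
                        (rr - 0.7) * cos(a), (rr - 0.7) * sin(a),
                        19 - 0.3 * s + 0.4)
        sugar_atoms <- c(sugar_atoms, ic1, io5)
        o5 <- c(o5, io5)
      }
      gl[[i]] <- list(chain = ch, resno = ga$resno[i], anchor_ca = ica,
                      sugar_atoms = sugar_atoms, o5 = o5,
                      terminal_o5 = o5[length(o5)], sway = ga$sway[i])
    }
    glycan_layout <- gl
  }

  ## free single-CA residues (network nodes, planted allosteric chains)
  extra_idx <- NULL
  ex <- spec$extra_residues
  if (!is.null(ex)) {
    ex <- as.data.frame(ex)
    extra_idx <- integer(nrow(ex))
    for (i in seq_len(nrow(ex))) {
      if (!ex$chain[i] %in% chains)
        stop("extra residue references absent chain: row ", i)
      claim_resno(ex$chain[i], ex$resno[i], "extra")
      extra_idx[i] <- add_atom("CA", "C",
                               if (is.null(ex$resid)) "ALA" else ex$resid[i],
                               ex$resno[i], ex$chain[i],
                               ex$x[i], ex$y[i], ex$z[i])
    }
  }

  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  xyz0 <- as.numeric(t(do.call(rbind, coords)))
  bonds <- if (length(bonds)) do.call(rbind, bonds) else NULL
  system <- molecular_system(atoms, bonds = bonds)

  structure(list(system = system, xyz0 = xyz0, spec = spec,
                 layout = list(theta = theta, scaffold = scaffold_idx,
                               r_eff = r_eff,
                               bridges = bridge_layout, hbonds = hb_layout,
                               gates = gate_layout, water = water_layout,
                               glycans = glycan_layout,
                               extra = extra_idx)),
            class = "pentamer_template")
}

# exact planted frame membership: round(target * n) frames drawn without
# replacement; the achieved fraction (an integer count) is what gets
# recorded in the ground truth
.planted_frames <- function(target, n) {
  k <- round(target * n)
  if (k == 0) integer(0) else sort(sample.int(n, k))
}

#' Generate replica trajectories with planted ground truth
#'
#' Animates a [build_pentamer_template()] system: planted contacts sit at
#' their near distance in exactly `round(occupancy * n_frames)` frames per
#' replica, gate ring radii follow their schedules exactly, water-wire
#' continuity follows its schedule, glycans sway rigidly, and correlation
#' block nodes move with their planted population correlation. All
#' randomness derives from `spec$seed`.
#'
#' @param template a `pentamer_template`.
#' @param label system label for the ensemble.
#' @return list with `ensemble` (a [trajectory_ensemble()]) and
#'   `ground_truth` (planted values, see details in the package vignette).
#' @export
generate_trajectory <- function(template, label = "synthetic") {
  stopifnot(inherits(template, "pentamer_template"))
  spec <- template$spec
  lay <- template$layout
  nf <- spec$n_frames; nr <- spec$n_replicas
  na <- n_atoms(template$system)

  .run_seeded(spec$seed, {
    gt <- list(vdw_table = .VDW_TABLE, r_eff = lay$r_eff,
               n_frames = nf, n_replicas = nr)
    reps <- vector("list", nr)
    gt_bridge <- list(); gt_hbond <- list(); gt_wire <- numeric(0)
    gt_bins <- list()

    ## block machinery shared across replicas: fixed direction per block
    blocks <- spec$correlation_blocks
    block_dirs <- NULL
    block_nodes_idx <- list()
    node_atom_idx <- function(ch, rn) {
      at <- template$system$atoms
      hit <- which(at$chain == ch & at$resno == rn &
                   at$elety %in% c("CA", "O5"))
      if (!length(hit)) stop("correlation block references absent node ",
                             ch, ":", rn)
      hit[length(hit)]   # O5 for sugars, CA otherwise
    }
    if (!is.null(blocks)) {
      block_dirs <- lapply(blocks, function(b) {
        v <- stats::rnorm(3); v / sqrt(sum(v^2))
      })
      block_nodes_idx <- lapply(blocks, function(b) {
        mapply(node_atom_idx, b$nodes$chain, b$nodes$resno)
      })
    }
    in_block <- unique(unlist(block_nodes_idx))

    for (r in seq_len(nr)) {
      xyz <- matrix(template$xyz0, nrow = nf, ncol = 3 * na, byrow = TRUE)

      ## hull expansion: radial xy scaling of the scaffold
      s <- spec$hull_expansion_schedule
      if (any(s != 1)) {
        for (idx in unlist(lay$scaffold)) {
          xyz[, 3 * idx - 2] <- xyz[, 3 * idx - 2] * s
          xyz[, 3 * idx - 1] <- xyz[, 3 * idx - 1] * s
        }
      }

      ## salt bridges
      if (!is.null(lay$bridges)) {
        for (i in seq_along(lay$bridges)) {
          b <- lay$bridges[[i]]
          on <- .planted_frames(spec$planted_bridges$occupancy[i], nf)
          d <- rep(b$far, nf); d[on] <- b$near
          for (ax in 1:3)
            xyz[, 3 * b$base - 3 + ax] <- b$origin[ax] + d * b$u[ax]
          gt_bridge[[length(gt_bridge) + 1L]] <- data.frame(
            pair = i, replica = r, occupancy = length(on) / nf)
        }
      }

      ## hydrogen bonds (hydrogen stays on the D->A line)
      if (!is.null(lay$hbonds)) {
        for (i in seq_along(lay$hbonds)) {
          h <- lay$hbonds[[i]]
          on <- .planted_frames(spec$planted_hbonds$occupancy[i], nf)
          d <- rep(h$far, nf); d[on] <- h$near
          for (ax in 1:3)
            xyz[, 3 * h$acceptor - 3 + ax] <- h$origin[ax] + d * h$u[ax]
          gt_hbond[[length(gt_hbond) + 1L]] <- data.frame(
            pair = i, replica = r, occupancy = length(on) / nf)
        }
      }

      ## gate rings follow their schedules exactly
      for (g in names(lay$gates)) {
        gl <- lay$gates[[g]]
        sched <- spec$pore_radius_schedule[[g]]
        sched_r <- if (is.list(sched)) sched[[min(r, length(sched))]]
                   else sched
        R <- sched_r + gl$vdw
        for (m in seq_along(gl$ring)) {
          idx <- gl$ring[m]
          xyz[, 3 * idx - 2] <- R * cos(gl$phi[m])
          xyz[, 3 * idx - 1] <- R * sin(gl$phi[m])
        }
        for (m in seq_along(gl$wall)) {
          idx <- gl$wall[m]
          xyz[, 3 * idx - 2] <- (R + 3) * cos(gl$wall_phi[m])
          xyz[, 3 * idx - 1] <- (R + 3) * sin(gl$wall_phi[m])
        }
        gt$gate_radius[[g]][[r]] <- sched_r
      }

      ## water wire schedule: park / restore the central link
      wire_frames <- NULL
      if (!is.null(spec$water_wire_schedule)) {
        ws <- spec$water_wire_schedule
        wire_frames <- if (is.logical(ws)) which(rep_len(ws, nf))
                       else .planted_frames(ws, nf)
        off <- setdiff(seq_len(nf), wire_frames)
        tog <- lay$water$wire_toggle
        for (idx in tog + 0:2) {  # O, H1, H2 are consecutive
          shift <- template$xyz0[(3 * idx - 2):(3 * idx)] -
                   template$xyz0[(3 * tog - 2):(3 * tog)]
          for (ax in 1:3)
            xyz[off, 3 * idx - 3 + ax] <- lay$water$park[ax] + shift[ax]
        }
        gt_wire[r] <- length(wire_frames) / nf
      }

      ## per-frame water bin ground truth (column waters only)
      if (!is.null(lay$water$binned_o) || !is.null(lay$water$wire_o)) {
        edges <- lay$water$bin_edges
        counts <- matrix(0L, nrow = length(edges) - 1, ncol = nf)
        tally <- function(z, frames) {
          b <- findInterval(z, edges, rightmost.closed = FALSE)
          if (b >= 1 && b <= nrow(counts))
            counts[b, frames] <<- counts[b, frames] + 1L
        }
        for (idx in lay$water$binned_o)
          tally(template$xyz0[3 * idx], seq_len(nf))
        if (!is.null(lay$water$wire_o)) {
          for (idx in lay$water$wire_o) {
            z <- template$xyz0[3 * idx]
            if (idx == lay$water$wire_toggle) tally(z, wire_frames)
            else tally(z, seq_len(nf))
          }
        }
        gt_bins[[r]] <- counts
      }

      ## rigid glycan sway
      if (!is.null(lay$glycans)) {
        for (gl in lay$glycans) {
          if (gl$sway <= 0) next
          sway <- matrix(stats::rnorm(3 * nf, sd = gl$sway), ncol = 3)
          for (idx in gl$sugar_atoms)
            for (ax in 1:3)
              xyz[, 3 * idx - 3 + ax] <- xyz[, 3 * idx - 3 + ax] + sway[, ax]
        }
      }

      ## correlated node motions: a_i(t) = sqrt(rho) g(t) + sqrt(1-rho) e_i(t)
      if (!is.null(blocks)) {
        for (bi in seq_along(blocks)) {
          rho <- blocks[[bi]]$rho
          g <- stats::rnorm(nf)
          u <- block_dirs[[bi]]
          for (idx in block_nodes_idx[[bi]]) {
            a <- sqrt(rho) * g + sqrt(1 - rho) * stats::rnorm(nf)
            a <- a * spec$motion_amplitude
            for (ax in 1:3)
              xyz[, 3 * idx - 3 + ax] <- xyz[, 3 * idx - 3 + ax] + a * u[ax]
          }
        }
      }

      ## independent jitter on non-block extra-residue nodes
      if (!is.null(lay$extra) && spec$node_jitter > 0) {
        for (idx in setdiff(lay$extra, in_block)) {
          for (ax in 1:3)
            xyz[, 3 * idx - 3 + ax] <- xyz[, 3 * idx - 3 + ax] +
              stats::rnorm(nf, sd = spec$node_jitter)
        }
      }

      reps[[r]] <- xyz
    }

    if (length(gt_bridge)) gt$bridge_occupancy <- do.call(rbind, gt_bridge)
    if (length(gt_hbond)) gt$hbond_occupancy <- do.call(rbind, gt_hbond)
    if (length(gt_wire)) gt$wire_fraction <- gt_wire
    if (length(gt_bins)) gt$water_bins <- gt_bins
    gt$hull_area <- (2.5 * lay$r_eff^2 * sin(2 * pi / 5)) *
      spec$hull_expansion_schedule^2
    if (!is.null(blocks))
      gt$correlation <- lapply(seq_along(blocks), function(bi)
        list(nodes = blocks[[bi]]$nodes, rho = blocks[[bi]]$rho,
             atom_idx = block_nodes_idx[[bi]]))
    if (!is.null(lay$glycans))
      gt$glycan_rmsf <- vapply(lay$glycans,
                               function(g) sqrt(3) * g$sway, numeric(1))

    list(ensemble = trajectory_ensemble(template$system, reps,
                                        label = label),
         ground_truth = gt)
  })
}

#' Write a synthetic system to plain-text fixture files
#'
#' Emits `topology.pdb` (reference coordinates), one multi-model PDB per
#' replica (`replica_<k>.pdb`) and `ground_truth.json`.
#'
#' @param template a `pentamer_template`.
#' @param generated result of [generate_trajectory()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_fixture <- function(template, generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  at <- template$system$atoms
  wr <- function(file, xyz) {
    bio3d::write.pdb(file = file, xyz = xyz, resno = at$resno,
                     resid = at$resid, elety = at$elety, chain = at$chain,
                     elesy = at$element)
  }
  topo <- file.path(dir, "topology.pdb")
  wr(topo, matrix(template$xyz0, nrow = 1))
  paths <- topo
  for (r in seq_along(generated$ensemble$replicas)) {
    p <- file.path(dir, sprintf("replica_%d.pdb", r))
    wr(p, generated$ensemble$replicas[[r]])
    paths <- c(paths, p)
  }
  gj <- file.path(dir, "ground_truth.json")
  gt <- generated$ground_truth
  gt$water_bins <- lapply(gt$water_bins, function(m) unname(as.matrix(m)))
  jsonlite::write_json(gt, gj, digits = NA, auto_unbox = TRUE)
  invisible(c(paths, gj))
}
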