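## HOLE-style pore radius profiling, gate traces and closure
## probabilities, water occupancy histograms, water-wire continuity, and
## the permeable/non-permeable contingency test.
##
## The pore radius at a z level is the radius of the largest sphere
## centred in that plane (near the pore axis) that touches no atom's vdW
## sphere: r(z) = max over plane points c of [min over atoms a of
## (|c - a| - vdw_a)], found by a coarse-to-fine 2-D grid search plus a
## Nelder-Mead polish. This reproduces the HOLE geometry without the
## original simulated-annealing walk; equivalence is enforced against a
## brute-force fine-grid oracle in the test suite.

# residue names treated as solvent (excluded from the profiling atom set)
.WATER_RESID <- c("HOH", "TIP3", "WAT", "SOL")

# clearance function: for plane points (gx, gy) at height z, the minimal
# vdW-corrected distance to any atom (compiled kernel)
.clearance <- function(gx, gy, z, ax, ay, az, avdw) {
  .clearance_cpp(as.numeric(gx), as.numeric(gy), z, ax, ay, az, avdw)
}

# staged grid maximisation of the clearance field in one plane, on
# pre-extracted atom coordinate vectors
.pore_radius_core <- function(ax, ay, az, vdw, z, center_xy, end_radius,
                              search_halfwidth) {
  # clearance at the axis point bounds the achievable maximum over the
  # search square (the clearance field is 1-Lipschitz), so atoms that
  # stay above that bound everywhere in the square can never be the
  # binding contact and are dropped before the grid search
  d0 <- sqrt((ax - center_xy[1])^2 + (ay - center_xy[2])^2 + (az - z)^2) -
    vdw
  if (!length(d0) || min(d0) >= end_radius)
    return(list(radius = end_radius, center = center_xy))
  bound <- min(end_radius, max(min(d0), 0) + search_halfwidth * sqrt(2))
  near <- which(d0 <= bound + search_halfwidth * sqrt(2) + 0.5)
  ax <- ax[near]; ay <- ay[near]; az <- az[near]; av <- vdw[near]

  # coarse pass over the whole square, then local refinement around the
  # best few coarse candidates (guards against near-tied optima)
  g <- seq(-search_halfwidth, search_halfwidth, by = 0.25)
  gx <- rep(center_xy[1] + g, times = length(g))
  gy <- rep(center_xy[2] + g, each = length(g))
  f <- .clearance(gx, gy, z, ax, ay, az, av)
  seeds <- utils::head(order(f, decreasing = TRUE), 3)
  best_r <- -Inf; best_c <- center_xy
  for (b in seeds) {
    cx <- gx[b]; cy <- gy[b]
    for (s in list(c(0.30, 0.05), c(0.06, 0.01))) {
      gg <- seq(-s[1], s[1], by = s[2])
      hx <- rep(cx + gg, times = length(gg))
      hy <- rep(cy + gg, each = length(gg))
      ff <- .clearance(hx, hy, z, ax, ay, az, av)
      bb <- which.max(ff)
      cx <- hx[bb]; cy <- hy[bb]
    }
    if (ff[bb] > best_r) { best_r <- ff[bb]; best_c <- c(cx, cy) }
  }
  list(radius = min(max(best_r, 0), end_radius), center = best_c)
}

#' Maximal inscribed pore radius in one z plane
#'
#' Coarse-to-fine grid maximisation of the clearance field (final grid
#' spacing 0.007 A); the search is confined to a square of half-width
#' `search_halfwidth` around `center_xy`.
#'
#' @param frame length-3N coordinate vector or N x 3 matrix.
#' @param z plane height (A).
#' @param vdw per-atom vdW radii for the profiling atom set.
#' @param atom_idx indices of profiling atoms within the frame.
#' @param center_xy xy point the search is confined around (pore axis).
#' @param end_radius radius cap: larger clearances report `end_radius`
#'   (open mouth).
#' @param search_halfwidth half-width (A) of the square search region
#'   around `center_xy`.
#' @return list with `radius` (clamped to \[0, end_radius\]) and `center`
#'   (optimal xy).
#' @export
pore_radius_at <- function(frame, z, vdw, atom_idx, center_xy = c(0, 0),
                           end_radius = 25, search_halfwidth = 4) {
  m <- frame_matrix(frame)
  .pore_radius_core(m[atom_idx, 1], m[atom_idx, 2], m[atom_idx, 3], vdw,
                    z, center_xy, end_radius, search_halfwidth)
}

# default profiling atom set: non-solvent heavy atoms
.profile_atoms <- function(system, atom_selection = NULL) {
  if (!is.null(atom_selection)) return(atom_selection$eleno)
  at <- system$atoms
  which(at$element != "H" & !(at$resid %in% .WATER_RESID))
}

#' Pore radius profile along the channel axis
#'
#' @param frame one frame (length-3N vector or N x 3 matrix).
#' @param system a `molecular_system`.
#' @param reference_point xyz of the profiling origin; by convention the
#'   COM of the activation-gate C-alpha atoms (see [gate_reference()]).
#' @param zlim z range profiled (default: reference z +- `end_radius`).
#' @param step z grid spacing (A).
#' @param end_radius radius cap (A; default 25).
#' @param atom_selection optional [select_atoms()] restriction of the
#'   profiling atom set (default: all non-solvent heavy atoms).
#' @param search_halfwidth search half-width around the axis (A).
#' @return data.frame with `z` and `radius`.
#' @export
pore_profile <- function(frame, system, reference_point = c(0, 0, 0),
                         zlim = NULL, step = 0.5, end_radius = 25,
                         atom_selection = NULL, search_halfwidth = 4) {
  idx <- .profile_atoms(system, atom_selection)
  vdw <- system$atoms$vdw[idx]
  if (is.null(zlim))
    zlim <- reference_point[3] + c(-end_radius, end_radius)
  zs <- seq(zlim[1], zlim[2], by = step)
  m <- frame_matrix(frame)
  ax <- m[idx, 1]; ay <- m[idx, 2]; az <- m[idx, 3]
  r <- vapply(zs, function(z)
    .pore_radius_core(ax, ay, az, vdw, z, reference_point[1:2],
                      end_radius, search_halfwidth)$radius,
    numeric(1))
  data.frame(z = zs, radius = r)
}

#' Gate reference point: COM of gate C-alpha atoms
#'
#' @param frame one frame.
#' @param gate_selection [select_atoms()] result holding the gate
#'   residues' C-alpha atoms.
#' @return xyz vector.
#' @export
gate_reference <- function(frame, gate_selection) {
  com_point(frame, gate_selection$eleno, gate_selection$mass)
}

#' Per-gate minimum radius trace and closure probability
#'
#' The gate slab is the z of the gate C-alpha COM +- `slab_halfwidth`;
#' the per-frame gate radius is the minimum profile radius within the
#' slab. Closure probability is the fraction of frames with radius <=
#' `threshold` (a frame at exactly the threshold counts as closed /
#' non-permeable).
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param gate_selection gate C-alpha selection (defines the slab).
#' @param threshold closure/permeability threshold (A; default 1.25, a
#'   representative water radius).
#' @param slab_halfwidth slab half-width (A).
#' @param step z spacing inside the slab (A).
#' @param end_radius,atom_selection,search_halfwidth see [pore_profile()].
#' @return list of class `gate_trace`: `per_frame` (per-replica radius
#'   vectors), `replica_mean`, `mean`, `sem`, `closure_probability`
#'   (pooled frames), `closure_per_replica`, `threshold`.
#' @export
gate_trace <- function(ensemble, gate_selection, threshold = 1.25,
                       slab_halfwidth = 2, step = 1.0, end_radius = 25,
                       atom_selection = NULL, search_halfwidth = 2) {
  system <- ensemble$system
  idx <- .profile_atoms(system, atom_selection)
  vdw <- system$atoms$vdw[idx]
  per_frame <- lapply(ensemble$replicas, function(xyz) {
    vapply(seq_len(nrow(xyz)), function(f) {
      m <- frame_matrix(xyz[f, ])
      ref <- com_point(m, gate_selection$eleno, gate_selection$mass)
      ax <- m[idx, 1]; ay <- m[idx, 2]; az <- m[idx, 3]
      zs <- seq(ref[3] - slab_halfwidth, ref[3] + slab_halfwidth, by = step)
      min(vapply(zs, function(z)
        .pore_radius_core(ax, ay, az, vdw, z, ref[1:2], end_radius,
                          search_halfwidth)$radius,
        numeric(1)))
    }, numeric(1))
  })
  rm_ <- vapply(per_frame, mean, numeric(1))
  st <- replicate_stats(rm_)
  pooled <- unlist(per_frame)
  structure(list(per_frame = per_frame, replica_mean = rm_,
                 mean = st$mean, sem = st$sem,
                 closure_probability = mean(pooled <= threshold),
                 closure_per_replica = vapply(per_frame, function(v)
                   mean(v <= threshold), numeric(1)),
                 threshold = threshold),
            class = "gate_trace")
}

# water oxygen atom indices
.water_oxygens <- function(system, water_resid = .WATER_RESID) {
  at <- system$atoms
  which(at$resid %in% water_resid & at$element == "O")
}

#' Water occupancy histogram along the pore axis
#'
#' Counts water oxygens inside the square 5x5 A axial column (|x - cx| <=
#' halfwidth and |y - cy| <= halfwidth) in half-open 2 A z-bins
#' \[edge_k, edge_{k+1}) anchored at the reference z.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param column_center_xy xy of the column axis (default: origin /
#'   activation-gate reference).
#' @param zlim z extent binned (default c(-10, 10) about the reference).
#' @param halfwidth column half-width (A; 2.5 gives the 5x5 A cross
#'   section).
#' @param bin z-bin width (A).
#' @param water_resid residue names identifying waters.
#' @return list of class `water_histogram`: `bin_edges`, `per_frame`
#'   (per-replica matrices bins x frames), `replica_mean` (bins x
#'   replicas), `mean`, `sem` (per bin).
#' @export
water_histogram <- function(ensemble, column_center_xy = c(0, 0),
                            zlim = c(-10, 10), halfwidth = 2.5, bin = 2.0,
                            water_resid = .WATER_RESID) {
  oid <- .water_oxygens(ensemble$system, water_resid)
  edges <- seq(zlim[1], zlim[2], by = bin)
  nb <- length(edges) - 1
  if (!length(oid)) {
    warning("no waters in system; empty histogram", call. = FALSE)
    return(structure(list(bin_edges = edges,
                          per_frame = NULL,
                          replica_mean = matrix(0, nb,
                                                length(ensemble$replicas)),
                          mean = rep(0, nb), sem = rep(NA_real_, nb)),
                     class = "water_histogram"))
  }
  per_frame <- lapply(ensemble$replicas, function(xyz) {
    counts <- matrix(0L, nb, nrow(xyz))
    for (f in seq_len(nrow(xyz))) {
      x <- xyz[f, 3 * oid - 2]; y <- xyz[f, 3 * oid - 1]
      z <- xyz[f, 3 * oid]
      inside <- abs(x - column_center_xy[1]) <= halfwidth &
                abs(y - column_center_xy[2]) <= halfwidth
      b <- findInterval(z[inside], edges, rightmost.closed = FALSE)
      b <- b[b >= 1 & b <= nb]
      if (length(b)) {
        tb <- tabulate(b, nbins = nb)
        counts[, f] <- tb
      }
    }
    counts
  })
  rmean <- vapply(per_frame, rowMeans, numeric(nb))
  rmean <- matrix(rmean, nrow = nb)
  structure(list(bin_edges = edges, per_frame = per_frame,
                 replica_mean = rmean,
                 mean = rowMeans(rmean),
                 sem = if (ncol(rmean) >= 2)
                   apply(rmean, 1, stats::sd) / sqrt(ncol(rmean))
                 else rep(NA_real_, nb)),
            class = "water_histogram")
}

#' Fraction of frames with a continuous water wire through a gate
#'
#' A frame has a wire when a chain of in-column water oxygens with
#' consecutive O-O distances <= `o_o_cutoff` connects the lower to the
#' upper face of the gate region (the gate slab extended to
#' `region_halfwidth`); a water links a face when its axial distance to
#' that face is within the O-O cutoff.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param gate_z z of the gate (e.g. from [gate_reference()]).
#' @param region_halfwidth half-height of the wire region (A; the 2 A
#'   slab extended by 2 A on each side).
#' @param o_o_cutoff O-O connectivity cutoff (A).
#' @param column_center_xy,column_halfwidth axial column restriction.
#' @param water_resid residue names identifying waters.
#' @return list: `fraction` (pooled frames), `per_replica`, `per_frame`
#'   logical vectors.
#' @export
water_wire_fraction <- function(ensemble, gate_z = 0, region_halfwidth = 4,
                                o_o_cutoff = 3.5,
                                column_center_xy = c(0, 0),
                                column_halfwidth = 2.5,
                                water_resid = .WATER_RESID) {
  oid <- .water_oxygens(ensemble$system, water_resid)
  lo <- gate_z - region_halfwidth; hi <- gate_z + region_halfwidth
  per_frame <- lapply(ensemble$replicas, function(xyz) {
    vapply(seq_len(nrow(xyz)), function(f) {
      x <- xyz[f, 3 * oid - 2]; y <- xyz[f, 3 * oid - 1]
      z <- xyz[f, 3 * oid]
      keep <- abs(x - column_center_xy[1]) <= column_halfwidth &
              abs(y - column_center_xy[2]) <= column_halfwidth &
              z >= lo & z <= hi
      if (!any(keep)) return(FALSE)
      px <- x[keep]; py <- y[keep]; pz <- z[keep]
      n <- length(px)
      d <- as.matrix(stats::dist(cbind(px, py, pz)))
      adj <- d <= o_o_cutoff
      # label connected components by repeated neighbour expansion
      comp <- seq_len(n)
      repeat {
        new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]),
                      numeric(1))
        if (all(new == comp)) break
        comp <- new
      }
      touches_lo <- (pz - lo) <= o_o_cutoff
      touches_hi <- (hi - pz) <= o_o_cutoff
      any(vapply(unique(comp), function(cc)
        any(touches_lo[comp == cc]) && any(touches_hi[comp == cc]),
        logical(1)))
    }, logical(1))
  })
  pooled <- unlist(per_frame)
  list(fraction = mean(pooled),
       per_replica = vapply(per_frame, mean, numeric(1)),
       per_frame = per_frame)
}

#' Chi-squared permeability test with threshold sensitivity sweep
#'
#' Classifies every frame of each system as permeable (gate radius >
#' threshold) or non-permeable (radius <= threshold), forms the systems x
#' {permeable, non-permeable} contingency table, and applies the Pearson
#' chi-squared test (no continuity correction, k - 1 degrees of freedom).
#' The sensitivity test recomputes the statistic over a threshold sweep.
#'
#' @param radii_by_system named list: per system, the pooled per-frame
#'   gate radii (A).
#' @param threshold classification threshold (A; default 1.25).
#' @param sweep thresholds for the sensitivity curve.
#' @return list of class `permeability_table`: `table` (systems x 2),
#'   `statistic`, `df`, `p_value`, `closure_probability` per system,
#'   `sensitivity` (data.frame threshold/statistic), `expected_warning`.
#' @export
permeability_test <- function(radii_by_system, threshold = 1.25,
                              sweep = seq(1.0, 1.5, by = 0.05)) {
  if (length(radii_by_system) < 2)
    stop("need at least two systems to compare")
  make_tab <- function(thr) {
    t(vapply(radii_by_system, function(r)
      c(permeable = sum(r > thr), non_permeable = sum(r <= thr)),
      numeric(2)))
  }
  tab <- make_tab(threshold)
  if (any(colSums(tab) == 0)) {
    # all frames on one side in every system: no association testable
    ct <- list(statistic = 0, parameter = nrow(tab) - 1, p.value = 1,
               expected = tab)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  }
  low_expected <- any(ct$expected < 5)
  if (low_expected)
    warning("expected cell count < 5; consider an exact test",
            call. = FALSE)
  sens <- data.frame(
    threshold = sweep,
    statistic = vapply(sweep, function(thr) {
      tt <- make_tab(thr)
      if (any(colSums(tt) == 0)) return(0)
      suppressWarnings(stats::chisq.test(tt, correct = FALSE)$statistic)
    }, numeric(1)))
  structure(list(table = tab,
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = ct$p.value,
                 closure_probability = vapply(radii_by_system, function(r)
                   mean(r <= threshold), numeric(1)),
                 sensitivity = sens,
                 expected_warning = low_expected),
            class = "permeability_table")
}
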