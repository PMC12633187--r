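## ECD expansion (convex hull of subunit COMs), internal-loop RMSD,
## RMSF, glycan tracking, and segment COM displacement.

# mass-weighted COM of a selection in each frame of a replica matrix
.com_series <- function(xyz, sel) {
  idx <- sel$eleno
  w <- sel$mass / sum(sel$mass)
  x <- xyz[, 3 * idx - 2, drop = FALSE] %*% w
  y <- xyz[, 3 * idx - 1, drop = FALSE] %*% w
  z <- xyz[, 3 * idx, drop = FALSE] %*% w
  cbind(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
}

#' ECD expansion: convex-hull area of subunit COMs
#'
#' Projects each subunit's extracellular-domain center of mass onto the
#' xy (membrane) plane and measures, per frame, the area of the convex
#' hull of those points. Fewer than three distinct points (collinear or
#' coincident COMs) give area 0 with a warning.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param ecd_selections list of [select_atoms()] results, one per
#'   subunit.
#' @return list of class `hull_series`: `per_frame` (list of per-replica
#'   area vectors, A^2), `replica_mean`, `mean`, `sem`.
#' @export
ecd_hull_area <- function(ensemble, ecd_selections) {
  if (length(ecd_selections) < 3)
    stop("need at least three subunit selections")
  per_frame <- lapply(ensemble$replicas, function(xyz) {
    coms <- lapply(ecd_selections, function(sel) .com_series(xyz, sel))
    vapply(seq_len(nrow(xyz)), function(f) {
      pts <- do.call(rbind, lapply(coms, function(cm) cm[f, c("x", "y")]))
      a <- hull_area_xy(pts)
      if (a == 0)
        warning("degenerate COM polygon in frame ", f, "; area 0",
                call. = FALSE)
      a
    }, numeric(1))
  })
  rm_ <- vapply(per_frame, mean, numeric(1))
  st <- replicate_stats(rm_)
  structure(list(per_frame = per_frame, replica_mean = rm_,
                 mean = st$mean, sem = st$sem), class = "hull_series")
}

#' Internal-loop RMSD against the first frame
#'
#' Every frame is least-squares superposed onto frame 1 of its replica
#' using the fit selection (by default the whole-subunit backbone), then
#' the loop backbone RMSD is measured without further fitting. This
#' isolates internal loop motion from rigid subunit drift.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param loop_selection [select_atoms()] result for the loop backbone.
#' @param fit_selection selection used for superposition (default: the
#'   backbone of the loop's chain(s)).
#' @return list of class `loop_rmsd_series`: `per_frame` (per-replica
#'   RMSD vectors, A; frame 1 is 0), `replica_mean`, `mean`, `sem`.
#' @export
loop_rmsd <- function(ensemble, loop_selection, fit_selection = NULL) {
  system <- ensemble$system
  if (is.null(fit_selection))
    fit_selection <- select_atoms(system,
                                  chains = unique(loop_selection$chain),
                                  atoms = "backbone")
  lidx <- loop_selection$eleno
  fidx <- fit_selection$eleno
  per_frame <- lapply(ensemble$replicas, function(xyz) {
    ref <- frame_matrix(xyz[1, ])
    vapply(seq_len(nrow(xyz)), function(f) {
      m <- kabsch_fit(frame_matrix(xyz[f, ]), ref, fidx)
      sqrt(mean(rowSums((m[lidx, , drop = FALSE] -
                         ref[lidx, , drop = FALSE])^2)))
    }, numeric(1))
  })
  rm_ <- vapply(per_frame, mean, numeric(1))
  st <- replicate_stats(rm_)
  structure(list(per_frame = per_frame, replica_mean = rm_,
                 mean = st$mean, sem = st$sem), class = "loop_rmsd_series")
}

#' Root-mean-square fluctuation per atom
#'
#' RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2) after superposing every frame
#' onto the time-averaged structure (one refinement pass: fit to frame 1,
#' average, re-fit to the average). The fit selection defaults to all
#' backbone atoms; pass a stable-core selection to measure fluctuations
#' against a rigid reference frame.
#'
#' @param ensemble a `trajectory_ensemble` (>= 2 frames per replica).
#' @param selection atoms whose RMSF is reported.
#' @param fit_selection atoms used for superposition.
#' @return list of class `rmsf_result`: `per_replica` (matrix atoms x
#'   replicas, A), `atom` (selection table), `replica_mean` (mean RMSF
#'   over selected atoms per replica), `mean`, `sem`.
#' @export
rmsf <- function(ensemble, selection, fit_selection = NULL) {
  if (any(n_frames(ensemble) < 2))
    stop("RMSF needs at least two frames per replica")
  system <- ensemble$system
  if (is.null(fit_selection))
    fit_selection <- select_atoms(system, atoms = "backbone")
  sidx <- selection$eleno
  fidx <- fit_selection$eleno
  per_rep <- vapply(ensemble$replicas, function(xyz) {
    ref <- frame_matrix(xyz[1, ])
    fitted <- superpose_replica(xyz, ref, fidx)
    avg <- frame_matrix(colMeans(fitted))
    fitted <- superpose_replica(fitted, avg, fidx)
    avg <- frame_matrix(colMeans(fitted))
    dx <- sweep(fitted[, 3 * sidx - 2, drop = FALSE], 2, avg[sidx, 1])
    dy <- sweep(fitted[, 3 * sidx - 1, drop = FALSE], 2, avg[sidx, 2])
    dz <- sweep(fitted[, 3 * sidx, drop = FALSE], 2, avg[sidx, 3])
    sqrt(colMeans(dx^2 + dy^2 + dz^2))
  }, numeric(length(sidx)))
  per_rep <- matrix(per_rep, nrow = length(sidx))
  rm_ <- colMeans(per_rep)
  st <- replicate_stats(rm_)
  structure(list(per_replica = per_rep, atom = selection,
                 replica_mean = rm_, mean = st$mean, sem = st$sem),
            class = "rmsf_result")
}

#' Welch t-test on replica-level RMSF means
#'
#' Replicas are the statistical unit (frames within a run are
#' autocorrelated).
#'
#' @param rmsf_a,rmsf_b [rmsf()] results with >= 2 replicas each.
#' @return `htest` from [stats::t.test()].
#' @export
compare_rmsf <- function(rmsf_a, rmsf_b) {
  if (length(rmsf_a$replica_mean) < 2 || length(rmsf_b$replica_mean) < 2)
    stop("Welch test needs >= 2 replicas per system")
  stats::t.test(rmsf_a$replica_mean, rmsf_b$replica_mean)
}

#' Track a glycan's anchor and terminal sugar
#'
#' Per frame: coordinates of the glycosylated asparagine's C-alpha and of
#' the terminal sugar's reference atom (ring O5 by default), their
#' orientation vector (terminal - anchor), a 2-D summary of terminal xy
#' positions, and the glycan RMSF over its ring atoms.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param anchor list/vector `(chain, resno)` of the asparagine anchor.
#' @param terminal list/vector `(chain, resno)` of the terminal sugar.
#' @param terminal_atom reference atom name on the terminal sugar.
#' @param glycan_selection optional selection of all glycan ring atoms
#'   for the RMSF (defaults to all `C1`/`O5` atoms of the terminal
#'   sugar's chain with resno >= 500, the generator's sugar numbering).
#' @param fit_selection superposition selection passed to [rmsf()].
#' @return list of class `glycan_track`: per-replica lists of `anchor`,
#'   `terminal` (frames x 3), `orientation`, plus `terminal_xy_mean`,
#'   `terminal_xy_sd`, and `rmsf` (an `rmsf_result` or `NULL`).
#' @export
track_glycan <- function(ensemble, anchor, terminal, terminal_atom = "O5",
                         glycan_selection = NULL, fit_selection = NULL) {
  system <- ensemble$system
  asel <- select_atoms(system, chains = anchor[[1]],
                       resno = as.integer(anchor[[2]]), atoms = "CA")
  tsel <- select_atoms(system, chains = terminal[[1]],
                       resno = as.integer(terminal[[2]]),
                       atoms = terminal_atom)
  tracks <- lapply(ensemble$replicas, function(xyz) {
    a <- .com_series(xyz, asel)
    t_ <- .com_series(xyz, tsel)
    list(anchor = a, terminal = t_, orientation = t_ - a)
  })
  txy <- do.call(rbind, lapply(tracks, function(t) t$terminal[, c("x", "y")]))
  gs <- glycan_selection
  if (is.null(gs)) {
    cand <- system$atoms[system$atoms$chain == terminal[[1]] &
                         system$atoms$resno >= 500 &
                         system$atoms$elety %in% c("C1", "O5"), ]
    if (nrow(cand)) { class(cand) <- class(asel); gs <- cand }
  }
  rf <- if (!is.null(gs) && all(n_frames(ensemble) >= 2))
    rmsf(ensemble, gs, fit_selection = fit_selection) else NULL
  structure(list(replicas = tracks,
                 terminal_xy_mean = colMeans(txy),
                 terminal_xy_sd = apply(txy, 2, stats::sd),
                 rmsf = rf), class = "glycan_track")
}

#' Center-of-mass displacement between two trajectory windows
#'
#' COM averaged within a reference and a final window of frames; reports
#' the displacement magnitude and its radial component relative to the
#' pore (z) axis, negative = inward.
#'
#' @param ensemble a `trajectory_ensemble` (windows indexed within each
#'   replica; results averaged over replicas).
#' @param selection atoms whose COM is tracked.
#' @param ref_window,final_window integer frame ranges (disjoint).
#' @return data.frame per replica with `magnitude` and `radial` (A), plus
#'   attributes `mean_magnitude`, `mean_radial`.
#' @export
com_displacement <- function(ensemble, selection, ref_window, final_window) {
  if (!length(ref_window) || !length(final_window))
    stop("empty frame window")
  if (length(intersect(ref_window, final_window)))
    stop("reference and final windows must be disjoint")
  res <- do.call(rbind, lapply(ensemble$replicas, function(xyz) {
    cm <- .com_series(xyz, selection)
    c0 <- colMeans(cm[ref_window, , drop = FALSE])
    c1 <- colMeans(cm[final_window, , drop = FALSE])
    d <- c1 - c0
    data.frame(magnitude = sqrt(sum(d^2)),
               radial = sqrt(sum(c1[1:2]^2)) - sqrt(sum(c0[1:2]^2)))
  }))
  attr(res, "mean_magnitude") <- mean(res$magnitude)
  attr(res, "mean_radial") <- mean(res$radial)
  res
}
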