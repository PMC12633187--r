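## Salt-bridge and hydrogen-bond detection, occupancy aggregation across
## replicas, and the cross-system comparison filter.
##
## Geometric criteria: a salt bridge is present in a frame when the acid
## terminal carbon (Asp CG / Glu CD) lies strictly within 4 A of the base
## terminal atom (Arg CZ / Lys NZ). A hydrogen bond is present when donor
## and acceptor are polar (N, O, S, F), the donor-acceptor distance is
## <= 3.5 A, and the D-H...A arrangement deviates from linearity by <= 20
## degrees. Occupancy is the fraction of frames a contact is present;
## cross-replica SEM uses the sample SD over replicas.

#' Contact detection criteria
#'
#' @param saltbridge_cutoff terminal-atom distance cutoff in A (strict
#'   `<`; default 4.0).
#' @param hbond_distance_cutoff donor-acceptor cutoff in A (`<=`;
#'   default 3.5).
#' @param hbond_angle_cutoff maximum deviation from D-H...A linearity in
#'   degrees (default 20).
#' @param polar_elements elements eligible as donors/acceptors.
#' @return a `contact_criteria` list.
#' @export
contact_criteria <- function(saltbridge_cutoff = 4.0,
                             hbond_distance_cutoff = 3.5,
                             hbond_angle_cutoff = 20,
                             polar_elements = c("N", "O", "S", "F")) {
  stopifnot(saltbridge_cutoff > 0, hbond_distance_cutoff > 0,
            hbond_angle_cutoff > 0, hbond_angle_cutoff <= 90)
  structure(list(saltbridge_cutoff = saltbridge_cutoff,
                 hbond_distance_cutoff = hbond_distance_cutoff,
                 hbond_angle_cutoff = hbond_angle_cutoff,
                 polar_elements = polar_elements),
            class = "contact_criteria")
}

# terminal-atom roles: the paper names atom roles, not PDB names;
# operationalised as Asp CG / Glu CD (acid) and Arg CZ / Lys NZ (base).
.ACID_TERM <- c(ASP = "CG", GLU = "CD")
.BASE_TERM <- c(ARG = "CZ", LYS = "NZ")

#' Enumerate candidate salt-bridge pairs
#'
#' All acid x base residue pairs with their defining terminal atoms;
#' inter-chain by default. Acid/base residues lacking their terminal atom
#' are skipped with a warning (incomplete side chains).
#'
#' @param system a `molecular_system`.
#' @param inter_chain restrict to residue pairs on different chains.
#' @return data.frame, one row per candidate pair, with the terminal atom
#'   indices `i` (acid) and `j` (base) and a canonical `pair` label.
#' @export
enumerate_saltbridge_pairs <- function(system, inter_chain = TRUE) {
  at <- system$atoms
  res <- unique(at[, c("chain", "resno", "resid")])
  term_of <- function(row, table) {
    want <- table[[row$resid]]
    hit <- which(at$chain == row$chain & at$resno == row$resno &
                 at$elety == want)
    if (!length(hit)) {
      warning("residue ", row$chain, ":", row$resno, " (", row$resid,
              ") lacks terminal atom ", want, "; skipped", call. = FALSE)
      return(NA_integer_)
    }
    hit[1]
  }
  acids <- res[res$resid %in% names(.ACID_TERM), , drop = FALSE]
  bases <- res[res$resid %in% names(.BASE_TERM), , drop = FALSE]
  if (!nrow(acids) || !nrow(bases))
    return(data.frame(pair = character(0), i = integer(0), j = integer(0)))
  out <- list()
  for (ai in seq_len(nrow(acids))) {
    ia <- term_of(acids[ai, ], .ACID_TERM)
    if (is.na(ia)) next
    for (bi in seq_len(nrow(bases))) {
      if (inter_chain && acids$chain[ai] == bases$chain[bi]) next
      ib <- term_of(bases[bi, ], .BASE_TERM)
      if (is.na(ib)) next
      out[[length(out) + 1L]] <- data.frame(
        pair = paste0(acids$chain[ai], ":", acids$resno[ai], ":",
                      acids$resid[ai], "-", bases$chain[bi], ":",
                      bases$resno[bi], ":", bases$resid[bi]),
        i = ia, j = ib, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(pair = character(0), i = integer(0), j = integer(0)))
  do.call(rbind, out)
}

#' Detect salt bridges in one frame
#'
#' @param frame length-3N coordinate vector (or N x 3 matrix).
#' @param system a `molecular_system`.
#' @param criteria a [contact_criteria()].
#' @param pairs candidate pairs from [enumerate_saltbridge_pairs()]
#'   (enumerated automatically when `NULL`).
#' @return the pair table with a logical `present` column and the
#'   terminal-atom `distance` in A.
#' @export
detect_salt_bridges <- function(frame, system, criteria = contact_criteria(),
                                pairs = NULL) {
  if (is.null(pairs)) pairs <- enumerate_saltbridge_pairs(system)
  m <- frame_matrix(frame)
  d <- sqrt(rowSums((m[pairs$i, , drop = FALSE] -
                     m[pairs$j, , drop = FALSE])^2))
  pairs$distance <- d
  pairs$present <- d < criteria$saltbridge_cutoff
  pairs
}

# map each hydrogen to its donor heavy atom: explicit bonds when the
# topology carries them, else nearest polar heavy atom within 1.25 A in
# the reference frame
.hydrogen_donors <- function(system, frame) {
  at <- system$atoms
  h_idx <- which(at$element == "H")
  if (!length(h_idx)) return(NULL)
  donors <- integer(length(h_idx))
  if (!is.null(system$bonds)) {
    b <- system$bonds
    for (k in seq_along(h_idx)) {
      hit <- c(b[b[, 2] == h_idx[k], 1], b[b[, 1] == h_idx[k], 2])
      donors[k] <- if (length(hit)) hit[1] else NA_integer_
    }
  } else donors[] <- NA_integer_
  need <- which(is.na(donors))
  if (length(need)) {
    m <- frame_matrix(frame)
    heavy <- which(at$element != "H")
    for (k in need) {
      d <- sqrt(colSums((t(m[heavy, , drop = FALSE]) - m[h_idx[k], ])^2))
      j <- heavy[which.min(d)]
      donors[k] <- if (min(d) <= 1.25) j else NA_integer_
    }
  }
  keep <- !is.na(donors)
  data.frame(h = h_idx[keep], donor = donors[keep])
}

#' Enumerate candidate hydrogen-bond triplets
#'
#' Donor = polar heavy atom with an attached hydrogen; acceptor = any
#' polar heavy atom of a different residue. Donors without an assignable
#' hydrogen are skipped with a warning.
#'
#' @inheritParams detect_salt_bridges
#' @param inter_chain restrict to donor/acceptor on different chains.
#' @return data.frame of (donor, hydrogen, acceptor) atom indices with a
#'   residue-level `pair` label.
#' @export
enumerate_hbond_triplets <- function(system, frame, inter_chain = TRUE,
                                     criteria = contact_criteria()) {
  at <- system$atoms
  hd <- .hydrogen_donors(system, frame)
  polar <- which(at$element %in% criteria$polar_elements)
  donors_with_h <- if (is.null(hd)) integer(0) else
    intersect(unique(hd$donor), polar)
  if (!length(donors_with_h)) {
    warning("no polar donors with assignable hydrogens", call. = FALSE)
    return(data.frame(pair = character(0), donor = integer(0),
                      hydrogen = integer(0), acceptor = integer(0)))
  }
  out <- list()
  for (d in donors_with_h) {
    hs <- hd$h[hd$donor == d]
    for (a in polar) {
      if (a == d) next
      if (at$chain[a] == at$chain[d] && at$resno[a] == at$resno[d]) next
      if (inter_chain && at$chain[a] == at$chain[d]) next
      for (h in hs)
        out[[length(out) + 1L]] <- data.frame(
          pair = paste0(at$chain[d], ":", at$resno[d], ":", at$resid[d],
                        "-", at$chain[a], ":", at$resno[a], ":", at$resid[a]),
          donor = d, hydrogen = h, acceptor = a, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Detect hydrogen bonds in one frame
#'
#' @inheritParams detect_salt_bridges
#' @param triplets candidate triplets from [enumerate_hbond_triplets()]
#'   (enumerated from this frame when `NULL`).
#' @param inter_chain passed to the enumerator.
#' @return the triplet table with `distance` (D-A, A), `deviation`
#'   (degrees from linearity) and `present`.
#' @export
detect_hbonds <- function(frame, system, criteria = contact_criteria(),
                          triplets = NULL, inter_chain = TRUE) {
  if (is.null(triplets))
    triplets <- enumerate_hbond_triplets(system, frame,
                                         inter_chain = inter_chain,
                                         criteria = criteria)
  m <- frame_matrix(frame)
  if (!nrow(triplets)) {
    triplets$distance <- numeric(0); triplets$deviation <- numeric(0)
    triplets$present <- logical(0)
    return(triplets)
  }
  D <- m[triplets$donor, , drop = FALSE]
  H <- m[triplets$hydrogen, , drop = FALSE]
  A <- m[triplets$acceptor, , drop = FALSE]
  da <- sqrt(rowSums((D - A)^2))
  v1 <- D - H; v2 <- A - H
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  cosang <- pmin(1, pmax(-1, cosang))
  deviation <- 180 - acos(cosang) * 180 / pi
  triplets$distance <- da
  triplets$deviation <- deviation
  triplets$present <- da <= criteria$hbond_distance_cutoff &
    deviation <= criteria$hbond_angle_cutoff
  triplets
}

#' Contact occupancy across an ensemble
#'
#' Per-replica occupancy (present frames / total frames), cross-replica
#' mean and SEM, and the per-replica mean of the z-scored distance series
#' (frame-wise distances standardised within the system, pooling frames
#' of all replicas).
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param mode `"saltbridge"` or `"hbond"`.
#' @param criteria a [contact_criteria()].
#' @param pairs optional candidate table ([enumerate_saltbridge_pairs()]
#'   / [enumerate_hbond_triplets()]); enumerated when `NULL`.
#' @param level for hbond mode: `"pair"` counts a residue pair once per
#'   frame when any of its triplets qualifies; `"triplet"` keeps each
#'   donor-hydrogen-acceptor triplet separate.
#' @param inter_chain passed to the enumerators.
#' @return data.frame with one row per contact: `pair`, per-replica
#'   occupancies (`occ_rep<k>`), `mean_occupancy`, `sem_occupancy`
#'   (`NA` with a single replica), `mean_zdist`.
#' @export
contact_occupancy <- function(ensemble, mode = c("saltbridge", "hbond"),
                              criteria = contact_criteria(), pairs = NULL,
                              level = c("pair", "triplet"),
                              inter_chain = TRUE) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  if (sum(n_frames(ensemble)) == 0) stop("ensemble has zero frames")
  system <- ensemble$system
  if (is.null(pairs)) {
    pairs <- if (mode == "saltbridge")
      enumerate_saltbridge_pairs(system, inter_chain = inter_chain)
    else enumerate_hbond_triplets(system, ensemble$replicas[[1]][1, ],
                                  inter_chain = inter_chain,
                                  criteria = criteria)
  }
  if (!nrow(pairs)) stop("no candidate contacts in system")

  present_per_rep <- list(); dist_per_rep <- list()
  for (r in seq_along(ensemble$replicas)) {
    xyz <- ensemble$replicas[[r]]
    nf <- nrow(xyz)
    pres <- matrix(FALSE, nf, nrow(pairs))
    dst <- matrix(NA_real_, nf, nrow(pairs))
    for (f in seq_len(nf)) {
      det <- if (mode == "saltbridge")
        detect_salt_bridges(xyz[f, ], system, criteria, pairs)
      else detect_hbonds(xyz[f, ], system, criteria, triplets = pairs)
      pres[f, ] <- det$present
      dst[f, ] <- det$distance
    }
    present_per_rep[[r]] <- pres
    dist_per_rep[[r]] <- dst
  }

  key <- pairs$pair
  if (mode == "hbond" && level == "pair") {
    groups <- split(seq_along(key), key)
    present_per_rep <- lapply(present_per_rep, function(m)
      vapply(groups, function(g) as.numeric(rowSums(m[, g, drop = FALSE]) > 0),
             numeric(nrow(m))))
    dist_per_rep <- lapply(dist_per_rep, function(m)
      vapply(groups, function(g) apply(m[, g, drop = FALSE], 1, min),
             numeric(nrow(m))))
    key <- names(groups)
  }
  nc <- length(key)

  occ <- vapply(present_per_rep,
                function(m) colMeans(m + 0), numeric(nc))
  occ <- matrix(occ, nrow = nc)
  pooled <- do.call(rbind, dist_per_rep)
  mu <- colMeans(pooled); sdv <- apply(pooled, 2, stats::sd)
  zmean <- vapply(dist_per_rep, function(m) {
    z <- sweep(sweep(m, 2, mu), 2, ifelse(sdv > 0, sdv, 1), "/")
    colMeans(z)
  }, numeric(nc))
  zmean <- matrix(zmean, nrow = nc)

  out <- data.frame(pair = key, stringsAsFactors = FALSE)
  for (r in seq_len(ncol(occ))) out[[paste0("occ_rep", r)]] <- occ[, r]
  out$mean_occupancy <- rowMeans(occ)
  out$sem_occupancy <- if (ncol(occ) >= 2)
    apply(occ, 1, stats::sd) / sqrt(ncol(occ)) else NA_real_
  out$mean_zdist <- rowMeans(zmean)
  out[order(out$pair), , drop = FALSE]
}

#' Compare contact occupancies between two systems
#'
#' Reconciles the pair universes (pairs absent from one system enter with
#' occupancy 0), computes `delta = mean_B - mean_A`, and flags pairs whose
#' absolute difference strictly exceeds the threshold (the "> 10%"
#' inclusion filter). Output is sorted by |delta| descending, ties broken
#' by pair label.
#'
#' @param occ_a,occ_b outputs of [contact_occupancy()] for systems A/B.
#' @param threshold inclusion threshold on the occupancy difference
#'   (fraction; default 0.10).
#' @param fdr when `TRUE` and both inputs carry per-replica occupancy
#'   columns (>= 2 replicas), adds a per-pair Welch t-test on replica
#'   occupancies with Benjamini-Hochberg adjusted q-values alongside the
#'   raw deltas. Off by default: the occupancy-difference filter is the
#'   primary inclusion rule.
#' @return data.frame with `pair`, `occupancy_a`, `occupancy_b`, `delta`,
#'   `included` (and `p_value`, `q_value` when `fdr = TRUE`).
#' @export
compare_systems <- function(occ_a, occ_b, threshold = 0.10, fdr = FALSE) {
  all_pairs <- sort(union(occ_a$pair, occ_b$pair))
  oa <- occ_a$mean_occupancy[match(all_pairs, occ_a$pair)]
  ob <- occ_b$mean_occupancy[match(all_pairs, occ_b$pair)]
  oa[is.na(oa)] <- 0; ob[is.na(ob)] <- 0
  delta <- ob - oa
  # strict "exceeds": a 1e-9 guard keeps exact k/n fractions whose binary
  # representation lands an ulp above the threshold on the excluded side
  included <- (abs(delta) - threshold) > 1e-9
  out <- data.frame(pair = all_pairs, occupancy_a = oa, occupancy_b = ob,
                    delta = delta, included = included,
                    stringsAsFactors = FALSE)
  if (fdr) {
    reps <- function(occ) occ[, grep("^occ_rep", names(occ)),
                              drop = FALSE]
    ra <- reps(occ_a); rb <- reps(occ_b)
    if (ncol(ra) < 2 || ncol(rb) < 2)
      stop("fdr = TRUE needs per-replica occupancies from >= 2 replicas")
    pv <- vapply(all_pairs, function(p) {
      va <- as.numeric(ra[match(p, occ_a$pair), ])
      vb <- as.numeric(rb[match(p, occ_b$pair), ])
      va[is.na(va)] <- 0; vb[is.na(vb)] <- 0
      if (stats::sd(va) == 0 && stats::sd(vb) == 0)
        return(if (mean(va) == mean(vb)) 1 else 0)
      stats::t.test(va, vb)$p.value
    }, numeric(1))
    out$p_value <- unname(pv)
    out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  }
  out[order(-abs(out$delta), out$pair), , drop = FALSE]
}
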