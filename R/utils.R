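## Shared numeric helpers and element tables.
## Coordinate convention follows bio3d: a trajectory replica is a numeric
## matrix with one row per frame and 3*N columns (x1,y1,z1,x2,...), in
## Angstrom. A single frame is a length-3N vector or an N x 3 matrix.

# Bondi-like vdW radii (Angstrom) used for fixtures and as the default
# pore-profiling radius set; unknown elements fall back to carbon.
.VDW_TABLE <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                P = 1.80, F = 1.47)

# Atomic masses (u) for center-of-mass computations.
.MASS_TABLE <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                 H = 1.008, P = 30.974, F = 18.998)

#' Van der Waals radius lookup
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii in Angstrom. Unknown elements get the
#'   carbon radius (1.70 A) with a warning.
#' @keywords internal
vdw_radius <- function(element) {
  r <- .VDW_TABLE[toupper(element)]
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    warning("unknown element(s) ", paste(bad, collapse = ", "),
            "; using fallback vdW radius 1.70 A", call. = FALSE)
    r[is.na(r)] <- 1.70
  }
  unname(r)
}

#' @keywords internal
atomic_mass <- function(element) {
  m <- .MASS_TABLE[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

# Infer element from a PDB atom name: strip digits/primes, first letter wins
# (fixture atom names are all single-letter elements).
.guess_element <- function(elety) {
  nm <- gsub("[0-9']", "", trimws(elety))
  substr(nm, 1, 1)
}

# Reshape a length-3N frame vector to an N x 3 coordinate matrix.
frame_matrix <- function(frame) {
  if (is.matrix(frame) && ncol(frame) == 3) return(frame)
  matrix(frame, ncol = 3, byrow = TRUE)
}

# Flatten an N x 3 coordinate matrix back to a length-3N vector.
frame_vector <- function(mat) as.numeric(t(mat))

# Column indices of atoms `idx` inside a 3N frame/trajectory layout.
xyz_cols <- function(idx) {
  as.integer(t(vapply(idx, function(i) (3L * i - 2L):(3L * i),
                      integer(3))))
}

# Mass-weighted center of mass of atoms `idx` in one frame.
com_point <- function(frame, idx, mass) {
  m <- frame_matrix(frame)[idx, , drop = FALSE]
  w <- mass / sum(mass)
  colSums(m * w)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fits `mobile` onto `ref` using the atom subset `fit_idx`
#' and applies the resulting rotation + translation to all atoms.
#'
#' @param mobile N x 3 coordinate matrix to transform.
#' @param ref N x 3 reference coordinates (same atom order).
#' @param fit_idx integer indices of atoms used to compute the fit
#'   (default: all atoms).
#' @return transformed N x 3 matrix.
#' @keywords internal
kabsch_fit <- function(mobile, ref, fit_idx = seq_len(nrow(ref))) {
  A <- mobile[fit_idx, , drop = FALSE]
  B <- ref[fit_idx, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(sweep(mobile, 2, ca) %*% t(R), 2, cb, "+")
}

# Superpose every frame of a replica matrix onto reference coordinates.
superpose_replica <- function(xyz, ref_mat, fit_idx) {
  out <- xyz
  for (f in seq_len(nrow(xyz))) {
    out[f, ] <- frame_vector(kabsch_fit(frame_matrix(xyz[f, ]), ref_mat,
                                        fit_idx))
  }
  out
}

# Polygon area of a 2-D point set via convex hull + shoelace.
hull_area_xy <- function(pts) {
  pts <- unique(round(pts, 10))
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts)
  if (length(h) < 3) return(0)
  abs(pracma::polyarea(pts[h, 1], pts[h, 2]))
}

# mean / standard error across replicate-level values (SEM needs n >= 2).
replicate_stats <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0) stop("no values to aggregate", call. = FALSE)
  list(mean = mean(x),
       sem = if (n >= 2) stats::sd(x) / sqrt(n) else NA_real_,
       n = n)
}
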