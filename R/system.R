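## Molecular system and trajectory-ensemble containers.
##
## A `molecular_system` is the topology: an atom table plus an optional
## chain -> subunit-role map and an optional bond list (used to attach
## hydrogens to their donors). A `trajectory_ensemble` holds one or more
## replica coordinate matrices (frames x 3N, Angstrom) for that system.

#' Construct a molecular system
#'
#' @param atoms data.frame with columns `eleno` (dense 1..N atom index),
#'   `elety` (atom name), `element`, `resid` (residue name), `resno`,
#'   `chain`, and optionally `vdw` (Angstrom; filled from the element table
#'   when absent).
#' @param roles optional named character vector mapping chain id to a
#'   subunit role (e.g. `c(A = "beta", B = "alpha", ...)`).
#' @param bonds optional two-column integer matrix/data.frame of bonded
#'   atom index pairs (used for donor-hydrogen assignment).
#' @return an object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, roles = NULL, bonds = NULL) {
  need <- c("eleno", "elety", "element", "resid", "resno", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  atoms$eleno <- as.integer(atoms$eleno)
  if (!identical(atoms$eleno, seq_len(nrow(atoms))))
    stop("atom indices must be dense 1..N in order")
  if (is.null(atoms$vdw)) atoms$vdw <- vdw_radius(atoms$element)
  if (any(!is.finite(atoms$vdw)) || any(atoms$vdw <= 0))
    stop("every atom needs a positive vdW radius")
  key <- paste(atoms$chain, atoms$resno, trimws(atoms$elety))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate atom identity (chain resno name): ", dup)
  }
  atoms$mass <- atomic_mass(atoms$element)
  if (!is.null(bonds)) {
    bonds <- as.matrix(bonds)[, 1:2, drop = FALSE]
    storage.mode(bonds) <- "integer"
  }
  structure(list(atoms = atoms, roles = roles, bonds = bonds),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("molecular_system:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chains (",
      paste(sort(unique(x$atoms$chain)), collapse = " "), ")\n")
  invisible(x)
}

#' Number of atoms in a system
#' @param system a `molecular_system`.
#' @export
n_atoms <- function(system) nrow(system$atoms)

#' Load a topology from a PDB file
#'
#' Reads ATOM/HETATM records via bio3d and builds a [molecular_system()].
#' Element symbols come from the element column when present, otherwise
#' from the atom name; vdW radii from the built-in element table (unknown
#' elements fall back to 1.70 A with a warning). Duplicate
#' (chain, resno, atom-name) identities are a hard error.
#'
#' @param path PDB file path.
#' @param roles optional chain-role map (see [molecular_system()]).
#' @return a `molecular_system`.
#' @export
load_system <- function(path, roles = NULL) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  elem <- trimws(a$elesy)
  no_elem <- is.na(elem) | elem == ""
  elem[no_elem] <- .guess_element(a$elety[no_elem])
  atoms <- data.frame(eleno = seq_len(nrow(a)),
                      elety = trimws(a$elety),
                      element = elem,
                      resid = trimws(a$resid),
                      resno = a$resno,
                      chain = a$chain,
                      stringsAsFactors = FALSE)
  molecular_system(atoms, roles = roles)
}

#' Bundle replica coordinate matrices into an ensemble
#'
#' @param system the `molecular_system` all replicas share.
#' @param replicas list of frames x 3N coordinate matrices (Angstrom).
#' @param label system label (e.g. an assembly name).
#' @return a `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(system, replicas, label = "system") {
  if (!inherits(system, "molecular_system")) stop("need a molecular_system")
  if (!length(replicas)) stop("need at least one replica")
  nc <- 3L * n_atoms(system)
  for (k in seq_along(replicas)) {
    r <- replicas[[k]]
    if (!is.matrix(r)) r <- matrix(r, nrow = 1)
    if (ncol(r) != nc)
      stop(sprintf("replica %d: expected %d coordinates per frame, got %d",
                   k, nc, ncol(r)))
    if (any(!is.finite(r))) stop("replica ", k, ": non-finite coordinates")
    replicas[[k]] <- r
  }
  structure(list(system = system, replicas = replicas, label = label),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("trajectory_ensemble '", x$label, "': ", length(x$replicas),
      " replica(s) x ", paste(vapply(x$replicas, nrow, 1L), collapse = "/"),
      " frames, ", n_atoms(x$system), " atoms\n", sep = "")
  invisible(x)
}

#' Number of frames per replica
#' @param ensemble a `trajectory_ensemble`.
#' @export
n_frames <- function(ensemble) vapply(ensemble$replicas, nrow, integer(1))

#' Load replica trajectories for a system
#'
#' Each path becomes one replica. Multi-model PDB (`.pdb`) and DCD
#' (`.dcd`) are supported; the atom count of every file must match the
#' system exactly (mismatch is a hard error, no partial ensemble).
#'
#' @param system a `molecular_system`.
#' @param paths character vector of trajectory files.
#' @param label system label.
#' @return a `trajectory_ensemble` with one replica per path, frame order
#'   preserved.
#' @export
load_trajectory <- function(system, paths, label = "system") {
  reps <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("trajectory file not found: ", p)
    ext <- tolower(tools::file_ext(p))
    xyz <- switch(ext,
      pdb = bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)$xyz,
      dcd = bio3d::read.dcd(p, verbose = FALSE),
      xtc = stop("XTC trajectories are not supported; supply multi-model ",
                 "PDB or DCD: ", p),
      stop("unrecognised trajectory format: ", p))
    xyz <- as.matrix(xyz)
    got <- ncol(xyz) / 3
    if (got != n_atoms(system))
      stop(sprintf("atom count mismatch in %s: expected %d, got %d",
                   p, n_atoms(system), got))
    xyz
  })
  trajectory_ensemble(system, reps, label = label)
}

#' Select residues and atoms from a system
#'
#' Structured selection by chain, residue number and atom-name class. The
#' result is deterministic (topology order) and never silently empty.
#'
#' @param system a `molecular_system`.
#' @param chains chain ids to include (default: all).
#' @param resno residue numbers to include (default: all). Every requested
#'   residue must exist in every requested chain.
#' @param atoms one of `"all"`, `"backbone"` (N, CA, C, O), `"calpha"`,
#'   `"heavy"` (non-hydrogen), or a character vector of atom names.
#' @param resid optional residue-name filter (e.g. `"HOH"`).
#' @return a `residue_selection`: data.frame of selected atoms (a subset of
#'   the atom table, `eleno` giving the atom indices).
#' @export
select_atoms <- function(system, chains = NULL, resno = NULL,
                         atoms = "all", resid = NULL) {
  at <- system$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chains)) keep <- keep & at$chain %in% chains
  if (!is.null(resno)) {
    keep <- keep & at$resno %in% resno
    ch <- if (is.null(chains)) unique(at$chain) else chains
    for (c1 in ch) {
      present <- unique(at$resno[at$chain == c1])
      missing <- setdiff(resno, present)
      if (length(missing) && !is.null(chains))
        stop("chain ", c1, " has no residue(s) ",
             paste(missing, collapse = ", "))
    }
  }
  if (!is.null(resid)) keep <- keep & at$resid %in% resid
  if (identical(atoms, "backbone")) {
    keep <- keep & at$elety %in% c("N", "CA", "C", "O")
  } else if (identical(atoms, "calpha")) {
    keep <- keep & at$elety == "CA"
  } else if (identical(atoms, "heavy")) {
    keep <- keep & at$element != "H"
  } else if (!identical(atoms, "all")) {
    keep <- keep & at$elety %in% atoms
  }
  sel <- at[keep, , drop = FALSE]
  if (nrow(sel) == 0)
    stop("selection is empty (chains=", paste(chains, collapse = ","),
         " resno=", paste(utils::head(resno, 5), collapse = ","),
         " atoms=", paste(atoms, collapse = ","), ")")
  class(sel) <- c("residue_selection", class(sel))
  sel
}

#' Read named selection blocks from a YAML config
#'
#' The config holds the study's named selections (gate residues, loop
#' ranges, ECD ranges, glycan anchors, interface pair lists) as plain
#' lists; this is a thin wrapper kept so configs travel with the data.
#'
#' @param path YAML file.
#' @return named list of selection blocks.
#' @export
read_selection_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
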