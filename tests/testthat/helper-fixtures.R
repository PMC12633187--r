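# Fixture builders and independent brute-force oracles shared by the
# suite. Oracles deliberately share no code with the package internals:
# distances, grids and path enumerations are recomputed from first
# principles.

# --- tiny system builders -------------------------------------------------

# bare system from an atom table sketch (elements guessed from names)
make_system <- function(elety, resid, resno, chain,
                        element = substr(gsub("[0-9]", "", elety), 1, 1)) {
  molecular_system(data.frame(
    eleno = seq_along(elety), elety = elety, element = element,
    resid = resid, resno = as.integer(resno), chain = chain,
    stringsAsFactors = FALSE))
}

# acid/base terminal-atom pair system: Glu CD on chain A, base on chain B
make_bridge_system <- function(base_resid = "ARG") {
  base_term <- if (base_resid == "ARG") "CZ" else "NZ"
  make_system(elety = c("CA", "CD", "CA", base_term),
              resid = c("GLU", "GLU", base_resid, base_resid),
              resno = c(10, 10, 20, 20),
              chain = c("A", "A", "B", "B"),
              element = c("C", "C", "C",
                          if (base_term == "NZ") "N" else "C"))
}

bridge_frame <- function(base_xyz) {
  as.numeric(t(rbind(c(0, 0, 5), c(0, 0, 0), c(base_xyz[1], base_xyz[2],
                                               base_xyz[3] + 5), base_xyz)))
}

# donor (Ser OG-HG1) / acceptor (Thr OG1) system with an explicit D-H bond
make_hbond_system <- function() {
  atoms <- data.frame(
    eleno = 1:5,
    elety = c("CA", "OG", "HG1", "CA", "OG1"),
    element = c("C", "O", "H", "C", "O"),
    resid = c("SER", "SER", "SER", "THR", "THR"),
    resno = c(1L, 1L, 1L, 2L, 2L),
    chain = c("A", "A", "A", "B", "B"), stringsAsFactors = FALSE)
  molecular_system(atoms, bonds = cbind(2L, 3L))
}

# donor at origin, hydrogen 1 A towards +x; acceptor placed so the
# donor-acceptor distance is `da` and the D-H...A arrangement deviates
# exactly `dev` degrees from linearity (angle controlled at the H)
hbond_frame <- function(da, dev) {
  phi <- dev * pi / 180
  r <- -cos(phi) + sqrt(cos(phi)^2 - 1 + da^2)
  a <- c(1 + r * cos(phi), r * sin(phi), 0)
  as.numeric(t(rbind(c(-1.5, 0, 0), c(0, 0, 0), c(1, 0, 0),
                     a + c(1.5, 0, 0), a)))
}

# ring fixture: atoms on a circle (plus optional containment wall) at one
# or more z levels; returns list(system, frame, vdw)
make_ring_fixture <- function(rings, wall = TRUE) {
  coords <- NULL; vdw <- NULL
  for (rg in rings) {
    nat <- rg$n
    phi <- 2 * pi * (seq_len(nat) - 1) / nat
    coords <- rbind(coords, cbind(rg$cx + rg$r * cos(phi),
                                  rg$cy + rg$r * sin(phi), rg$z))
    vdw <- c(vdw, rep(rg$vdw, nat))
    if (wall) {
      wn <- 24
      wphi <- 2 * pi * (seq_len(wn) - 1) / wn
      coords <- rbind(coords, cbind(rg$cx + (rg$r + 3) * cos(wphi),
                                    rg$cy + (rg$r + 3) * sin(wphi), rg$z))
      vdw <- c(vdw, rep(1.7, wn))
    }
  }
  list(coords = coords, frame = as.numeric(t(coords)), vdw = vdw,
       idx = seq_len(nrow(coords)))
}

# single-CA residue chain system with hand-set coordinates, for geometry
# and network fixtures
make_ca_system <- function(n, chain = "A", resno = seq_len(n)) {
  make_system(elety = rep("CA", n), resid = rep("ALA", n),
              resno = resno, chain = rep(chain, length.out = n),
              element = rep("C", n))
}

# n-residue chain with backbone and a designated loop range
loop_fixture <- function(n = 10, loop = 4:6) {
  atoms <- expand.grid(elety = c("N", "CA", "C", "O"), resno = 1:n,
                       stringsAsFactors = FALSE)
  sys <- make_system(elety = atoms$elety, resid = "ALA",
                     resno = atoms$resno, chain = "A",
                     element = substr(atoms$elety, 1, 1))
  base <- cbind(rep(seq_len(n), each = 4) * 3.8 +
                  rep(c(0, 0.5, 1.0, 1.5), n),
                rep(c(0, 1, 0, -1), n),
                rep(c(0, 0, 1, 1), n))
  list(sys = sys, base = base,
       loop = select_atoms(sys, chains = "A", resno = loop,
                           atoms = "backbone"))
}

# --- independent oracles --------------------------------------------------

# exhaustive fine-grid plane search (two-pass: 0.05 full square, 0.01
# local), independent of the profiler's staged search
oracle_pore_radius <- function(coords, vdw, z, hw = 4, cap = 25) {
  f <- function(gx, gy) {
    best <- rep(Inf, length(gx))
    for (i in seq_len(nrow(coords)))
      best <- pmin(best, sqrt((gx - coords[i, 1])^2 +
                              (gy - coords[i, 2])^2 +
                              (z - coords[i, 3])^2) - vdw[i])
    best
  }
  g <- seq(-hw, hw, by = 0.05)
  gx <- rep(g, times = length(g)); gy <- rep(g, each = length(g))
  v <- f(gx, gy); b <- which.max(v)
  g2 <- seq(-0.08, 0.08, by = 0.01)
  hx <- rep(gx[b] + g2, times = length(g2))
  hy <- rep(gy[b] + g2, each = length(g2))
  min(max(max(f(hx, hy)), 0), cap)
}

# closed-form Pearson chi-squared for a 2x2 table (no correction)
oracle_chisq_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c_ + d
  n * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
}

# shoelace polygon area on an ordered vertex cycle
oracle_shoelace <- function(pts) {
  n <- nrow(pts)
  j <- c(2:n, 1)
  abs(sum(pts[, 1] * pts[j, 2] - pts[j, 1] * pts[, 2])) / 2
}

# exhaustive simple-path enumeration on a small weighted edge list
# (data.frame i, j, w with 1-based vertex ids); returns all simple paths
# s -> t with their weights
oracle_all_paths <- function(edges, n, s, t) {
  nbr <- lapply(seq_len(n), function(v) {
    rows <- which(edges$i == v | edges$j == v)
    list(v = ifelse(edges$i[rows] == v, edges$j[rows], edges$i[rows]),
         w = edges$w[rows])
  })
  paths <- list(); weights <- numeric(0)
  rec <- function(v, used, w, trail) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- trail
      weights[length(weights) + 1L] <<- w
      return(invisible())
    }
    nb <- nbr[[v]]
    for (k in seq_along(nb$v)) {
      u <- nb$v[k]
      if (used[u]) next
      used[u] <- TRUE
      rec(u, used, w + nb$w[k], c(trail, u))
      used[u] <- FALSE
    }
  }
  used <- logical(n); used[s] <- TRUE
  rec(s, used, 0, s)
  list(paths = paths, weights = weights)
}

# betweenness from the exhaustive path enumeration: for every pair,
# split credit over tied shortest paths; normalise by the number of
# node pairs a vertex can lie between, (n-1)(n-2)/2
oracle_betweenness <- function(edges, n) {
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      ap <- oracle_all_paths(edges, n, s, t)
      if (!length(ap$weights)) next
      wmin <- min(ap$weights)
      sp <- ap$paths[abs(ap$weights - wmin) < 1e-12]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        btw[v] <- btw[v] +
          mean(vapply(sp, function(p) v %in% p, logical(1)))
      }
    }
  }
  btw / choose(n - 1, 2)
}

# direct per-frame distance count for a planted pair in an emitted
# multi-model PDB file (text-level re-measurement, no package readers)
oracle_pdb_pair_occupancy <- function(pdb_path, sel_a, sel_b, cutoff = 4.0) {
  lines <- readLines(pdb_path)
  grab <- function(sel) {
    hit <- startsWith(lines, "ATOM") &
      trimws(substr(lines, 13, 16)) == sel$elety &
      substr(lines, 22, 22) == sel$chain &
      trimws(substr(lines, 23, 26)) == as.character(sel$resno)
    cbind(as.numeric(substr(lines[hit], 31, 38)),
          as.numeric(substr(lines[hit], 39, 46)),
          as.numeric(substr(lines[hit], 47, 54)))
  }
  a <- grab(sel_a); b <- grab(sel_b)
  stopifnot(nrow(a) == nrow(b), nrow(a) > 0)
  mean(sqrt(rowSums((a - b)^2)) < cutoff)
}

expect_no_diff_files <- function(dir1, dir2) {
  f1 <- sort(list.files(dir1, recursive = TRUE))
  f2 <- sort(list.files(dir2, recursive = TRUE))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)),
                     info = paste("file differs:", f))
  }
}
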