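## Correlation-weighted dynamical networks and allosteric pathway
## extraction: contact maps, displacement correlation matrices, graph
## construction with w = -ln|C| edge weights, exact suboptimal-path
## enumeration, betweenness centrality, and cross-replica hub
## conservation.

#' Network node table for a system
#'
#' One node per protein residue (its C-alpha atom) and per glycan sugar
#' (its ring O5 atom); hydrogens and solvent are never nodes.
#'
#' @param system a `molecular_system`.
#' @param chains,resno optional restriction of the node universe.
#' @return data.frame with `node` (chain:resno label), `chain`, `resno`,
#'   `atom` (node atom index), `resid`.
#' @export
network_nodes <- function(system, chains = NULL, resno = NULL) {
  at <- system$atoms
  keep <- (at$elety == "CA" & !(at$resid %in% .WATER_RESID)) |
          (at$elety == "O5" & at$resid == "MAN")
  if (!is.null(chains)) keep <- keep & at$chain %in% chains
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  nd <- at[keep, c("chain", "resno", "resid", "eleno")]
  if (!nrow(nd)) stop("no network nodes in selection")
  data.frame(node = paste0(nd$chain, ":", nd$resno),
             chain = nd$chain, resno = nd$resno, resid = nd$resid,
             atom = nd$eleno, stringsAsFactors = FALSE)
}

#' Persistence-filtered residue contact map
#'
#' Nodes are adjacent when any heavy-atom pair of their residues lies
#' within `distance_cutoff` in at least `persistence` of the replica's
#' frames (strict threshold: exactly 74% of frames at persistence 0.75 is
#' not adjacent). Edges between sequence-adjacent residues of the same
#' chain (i, i+1) are removed afterwards to suppress trivial backbone
#' correlations.
#'
#' @param replica frames x 3N coordinate matrix.
#' @param system a `molecular_system`.
#' @param nodes node table from [network_nodes()].
#' @param distance_cutoff heavy-atom contact cutoff (A; default 4.5).
#' @param persistence minimum contact fraction of frames (default 0.75).
#' @return symmetric logical adjacency matrix (nodes x nodes).
#' @export
contact_map <- function(replica, system, nodes, distance_cutoff = 4.5,
                        persistence = 0.75) {
  at <- system$atoms
  nn <- nrow(nodes)
  heavy <- lapply(seq_len(nn), function(i)
    which(at$chain == nodes$chain[i] & at$resno == nodes$resno[i] &
          at$element != "H"))
  nf <- nrow(replica)
  hits <- matrix(0L, nn, nn)
  for (f in seq_len(nf)) {
    m <- frame_matrix(replica[f, ])
    # residue COM prefilter: pairs further apart than cutoff + residue
    # extents cannot have a heavy-atom contact
    cm <- t(vapply(heavy, function(ix) colMeans(m[ix, , drop = FALSE]),
                   numeric(3)))
    ext <- vapply(seq_len(nn), function(i)
      max(sqrt(rowSums((m[heavy[[i]], , drop = FALSE] -
                        matrix(cm[i, ], length(heavy[[i]]), 3,
                               byrow = TRUE))^2))), numeric(1))
    dcm <- as.matrix(stats::dist(cm))
    for (i in seq_len(nn - 1)) {
      for (j in (i + 1):nn) {
        if (dcm[i, j] > distance_cutoff + ext[i] + ext[j]) next
        dmin <- min(sqrt(outer(m[heavy[[i]], 1], m[heavy[[j]], 1], "-")^2 +
                         outer(m[heavy[[i]], 2], m[heavy[[j]], 2], "-")^2 +
                         outer(m[heavy[[i]], 3], m[heavy[[j]], 3], "-")^2))
        if (dmin <= distance_cutoff) hits[i, j] <- hits[i, j] + 1L
      }
    }
  }
  adj <- (hits + t(hits)) / nf >= persistence
  diag(adj) <- FALSE
  # remove sequence-adjacent same-chain edges
  for (i in seq_len(nn - 1)) {
    for (j in (i + 1):nn) {
      if (nodes$chain[i] == nodes$chain[j] &&
          abs(nodes$resno[i] - nodes$resno[j]) == 1)
        adj[i, j] <- adj[j, i] <- FALSE
    }
  }
  dimnames(adj) <- list(nodes$node, nodes$node)
  adj
}

#' Displacement cross-correlation matrix of network nodes
#'
#' C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>), with dr_i(t) the
#' node atom's displacement from its time average after rigid
#' superposition of every frame onto the mean structure. The fit
#' selection defaults to all node atoms; supply a stable-core selection
#' to measure against a rigid reference.
#'
#' @param replica frames x 3N matrix (>= 10 frames).
#' @param nodes node table from [network_nodes()].
#' @param fit_idx atom indices used for superposition (`NULL` = node
#'   atoms; `NA` = skip superposition, frames assumed pre-aligned).
#' @return symmetric correlation matrix with unit diagonal;
#'   zero-variance nodes get 0 off-diagonal with a warning.
#' @export
correlation_matrix <- function(replica, nodes, fit_idx = NULL) {
  if (nrow(replica) < 10) stop("need >= 10 frames for correlations")
  if (is.null(fit_idx)) fit_idx <- nodes$atom
  xyz <- replica
  if (!(length(fit_idx) == 1 && is.na(fit_idx))) {
    ref <- frame_matrix(xyz[1, ])
    xyz <- superpose_replica(xyz, ref, fit_idx)
    avg <- frame_matrix(colMeans(xyz))
    xyz <- superpose_replica(xyz, avg, fit_idx)
  }
  idx <- nodes$atom
  dx <- scale(xyz[, 3 * idx - 2, drop = FALSE], scale = FALSE)
  dy <- scale(xyz[, 3 * idx - 1, drop = FALSE], scale = FALSE)
  dz <- scale(xyz[, 3 * idx, drop = FALSE], scale = FALSE)
  cov3 <- (crossprod(dx) + crossprod(dy) + crossprod(dz)) / nrow(xyz)
  v <- diag(cov3)
  zero <- v <= .Machine$double.eps
  if (any(zero))
    warning(sum(zero), " zero-variance node(s); correlations set to 0",
            call. = FALSE)
  denom <- sqrt(ifelse(zero, 1, v))
  C <- cov3 / outer(denom, denom)
  C[zero, ] <- 0; C[, zero] <- 0
  diag(C) <- 1
  dimnames(C) <- list(nodes$node, nodes$node)
  C
}

#' Build the weighted residue network
#'
#' Edges connect adjacent node pairs with nonzero correlation, weighted
#' w_ij = -ln|C_ij| so strongly (anti)correlated contacts are short.
#'
#' @param adjacency logical adjacency from [contact_map()].
#' @param C correlation matrix over the same node order.
#' @return an undirected `igraph` graph with edge attributes `weight`
#'   and `correlation`.
#' @export
build_graph <- function(adjacency, C) {
  stopifnot(identical(dim(adjacency), dim(C)))
  n <- nrow(adjacency)
  keep <- adjacency & abs(C) > 0
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  ij <- which(keep, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = rownames(adjacency))
  if (nrow(ij)) {
    g <- igraph::add_edges(g, as.vector(t(ij)))
    cvals <- C[ij]
    g <- igraph::set_edge_attr(g, "correlation", value = cvals)
    g <- igraph::set_edge_attr(g, "weight", value = -log(abs(cvals)))
  }
  g
}

#' Optimal and suboptimal paths between two nodes
#'
#' Exact enumeration of every simple path whose total weight is within
#' `tolerance` of the optimum, by depth-first search with an admissible
#' bound (remaining shortest-path distance to the sink); per-node visit
#' frequency is the fraction of returned paths containing the node.
#'
#' @param graph weighted graph from [build_graph()].
#' @param source,sink node names.
#' @param tolerance absolute weight slack; `NULL` = 10% of the optimal
#'   path weight.
#' @return list of class `path_ensemble`: `paths` (list of node-name
#'   vectors, optimal first, sorted by weight), `weights`,
#'   `optimal_weight`, `visit_frequency` (named, in \[0,1\]), `source`,
#'   `sink`, `reachable`.
#' @export
suboptimal_paths <- function(graph, source, sink, tolerance = NULL) {
  vs <- igraph::V(graph)$name
  s <- match(source, vs); t_ <- match(sink, vs)
  if (is.na(s) || is.na(t_)) stop("source/sink not in graph")
  if (s == t_) {
    out <- list(paths = list(source), weights = 0, optimal_weight = 0,
                visit_frequency = stats::setNames(1, source),
                source = source, sink = sink, reachable = TRUE)
    class(out) <- "path_ensemble"
    return(out)
  }
  dist_to_sink <- as.numeric(igraph::distances(graph, v = igraph::V(graph),
                                               to = t_))
  if (!is.finite(dist_to_sink[s])) {
    out <- list(paths = list(), weights = numeric(0),
                optimal_weight = NA_real_,
                visit_frequency = stats::setNames(numeric(0), character(0)),
                source = source, sink = sink, reachable = FALSE)
    class(out) <- "path_ensemble"
    return(out)
  }
  opt <- dist_to_sink[s]
  if (is.null(tolerance)) tolerance <- 0.1 * opt
  budget <- opt + tolerance + 1e-12
  adj <- lapply(seq_along(vs), function(v) {
    e <- igraph::incident(graph, v)
    if (!length(e)) return(list(v = integer(0), w = numeric(0)))
    ends <- igraph::ends(graph, e, names = FALSE)
    other <- ifelse(ends[, 1] == v, ends[, 2], ends[, 1])
    list(v = other, w = igraph::edge_attr(graph, "weight", e))
  })
  paths <- list(); weights <- numeric(0)
  visited <- logical(length(vs))
  walk <- function(v, w_so_far, trail) {
    if (v == t_) {
      paths[[length(paths) + 1L]] <<- trail
      weights[length(weights) + 1L] <<- w_so_far
      return(invisible())
    }
    nb <- adj[[v]]
    for (k in seq_along(nb$v)) {
      u <- nb$v[k]
      if (visited[u]) next
      w2 <- w_so_far + nb$w[k]
      if (w2 + dist_to_sink[u] > budget) next
      visited[u] <<- TRUE
      walk(u, w2, c(trail, u))
      visited[u] <<- FALSE
    }
  }
  visited[s] <- TRUE
  walk(s, 0, s)
  ord <- order(weights, vapply(paths, function(p)
    paste(vs[p], collapse = ">"), character(1)))
  paths <- paths[ord]; weights <- weights[ord]
  freq <- stats::setNames(numeric(length(vs)), vs)
  for (p in paths) freq[p] <- freq[p] + 1
  freq <- freq / max(1, length(paths))
  out <- list(paths = lapply(paths, function(p) vs[p]),
              weights = weights, optimal_weight = weights[1],
              visit_frequency = freq[freq > 0],
              source = source, sink = sink, reachable = TRUE)
  class(out) <- "path_ensemble"
  out
}

#' Weighted betweenness centrality of every node
#'
#' Standard shortest-path betweenness on the weighted graph, shortest-path
#' ties split fractionally, normalised by the number of node pairs.
#'
#' @param graph weighted graph from [build_graph()].
#' @return named numeric vector in \[0, 1\].
#' @export
node_betweenness <- function(graph) {
  igraph::betweenness(graph, directed = FALSE, normalized = TRUE)
}

#' Cross-replica conservation of pathway residues
#'
#' A node's recurrence is the fraction of replicas whose path ensemble
#' visits it; conserved hubs strictly exceed the threshold (a node in 3
#' of 4 replicas, recurrence 0.75, is not conserved at threshold 0.75).
#' Source and sink nodes are excluded.
#'
#' @param path_ensembles list of [suboptimal_paths()] results, one per
#'   replica, sharing the same source and sink.
#' @param threshold conservation threshold (default 0.75).
#' @return data.frame with `node`, `recurrence`, `conserved`, sorted by
#'   recurrence descending.
#' @export
conservation <- function(path_ensembles, threshold = 0.75) {
  if (length(path_ensembles) < 2) stop("need >= 2 replicas")
  ends <- unique(unlist(lapply(path_ensembles, function(pe)
    c(pe$source, pe$sink))))
  per_rep <- lapply(path_ensembles, function(pe)
    setdiff(unique(unlist(pe$paths)), ends))
  nodes <- sort(unique(unlist(per_rep)))
  rec <- vapply(nodes, function(nd)
    mean(vapply(per_rep, function(p) nd %in% p, logical(1))), numeric(1))
  out <- data.frame(node = nodes, recurrence = rec,
                    conserved = rec > threshold, stringsAsFactors = FALSE)
  out[order(-out$recurrence, out$node), , drop = FALSE]
}

#' Export a network graph to portable text formats
#'
#' Writes the weighted residue network as an edge-list CSV (node labels,
#' correlation, weight) and as GraphML.
#'
#' @param graph weighted graph from [build_graph()].
#' @param prefix output path prefix; writes `<prefix>_edges.csv` and
#'   `<prefix>.graphml`.
#' @return invisibly, the written file paths.
#' @export
write_network <- function(graph, prefix) {
  ends <- igraph::ends(graph, igraph::E(graph))
  df <- data.frame(from = ends[, 1], to = ends[, 2],
                   correlation = igraph::E(graph)$correlation,
                   weight = igraph::E(graph)$weight,
                   stringsAsFactors = FALSE)
  p1 <- paste0(prefix, "_edges.csv")
  utils::write.csv(df, p1, row.names = FALSE, quote = FALSE)
  p2 <- paste0(prefix, ".graphml")
  igraph::write_graph(graph, p2, format = "graphml")
  invisible(c(p1, p2))
}

#' Correlation summary over the edges of returned paths
#'
#' Fraction of path edges with |C| at or above the reporting threshold
#' and their mean |C| — the coupling-strength summary used to judge
#' whether extracted pathways reflect real correlated motion.
#'
#' @param graph weighted graph from [build_graph()].
#' @param path_ensemble a [suboptimal_paths()] result.
#' @param threshold reporting threshold on |C| (default 0.5).
#' @return list with `fraction_ge_threshold`, `mean_abs_correlation`,
#'   `n_edges`.
#' @export
path_edge_correlations <- function(graph, path_ensemble, threshold = 0.5) {
  eids <- integer(0)
  for (p in path_ensemble$paths) {
    if (length(p) < 2) next
    eids <- c(eids, igraph::get_edge_ids(graph,
                                         as.vector(rbind(p[-length(p)],
                                                         p[-1]))))
  }
  eids <- unique(eids[eids > 0])
  if (!length(eids))
    return(list(fraction_ge_threshold = NA_real_,
                mean_abs_correlation = NA_real_, n_edges = 0L))
  cc <- abs(igraph::E(graph)$correlation[eids])
  list(fraction_ge_threshold = mean(cc >= threshold),
       mean_abs_correlation = mean(cc), n_edges = length(eids))
}
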