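# Dynamical network construction, suboptimal paths, betweenness, and
# conservation, with exhaustive-enumeration oracles on small graphs.

# build an igraph directly from an edge list with planted correlations
graph_from_edges <- function(edges, n, names = paste0("n", seq_len(n))) {
  adj <- matrix(FALSE, n, n, dimnames = list(names, names))
  C <- diag(n); dimnames(C) <- list(names, names)
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]
    adj[i, j] <- adj[j, i] <- TRUE
    C[i, j] <- C[j, i] <- exp(-edges$w[k])
  }
  build_graph(adj, C)
}

test_that("edge weights follow w = -ln|C| and zero correlations drop out", {
  nm <- c("a", "b", "c")
  adj <- matrix(TRUE, 3, 3, dimnames = list(nm, nm)); diag(adj) <- FALSE
  C <- diag(3); dimnames(C) <- list(nm, nm)
  C["a", "b"] <- C["b", "a"] <- 1
  C["b", "c"] <- C["c", "b"] <- 0.5
  C["a", "c"] <- C["c", "a"] <- 0
  g <- build_graph(adj, C)
  expect_equal(igraph::ecount(g), 2)
  w <- igraph::E(g)$weight
  ends <- igraph::ends(g, igraph::E(g))
  expect_equal(w[apply(ends, 1, function(e) setequal(e, c("a", "b")))], 0)
  expect_equal(w[apply(ends, 1, function(e) setequal(e, c("b", "c")))],
               log(2))
  # anticorrelation shortens paths the same way
  C["a", "c"] <- C["c", "a"] <- -0.5
  g2 <- build_graph(adj, C)
  expect_equal(igraph::ecount(g2), 3)
})

test_that("contact map applies the persistence threshold strictly and
           excludes sequence-adjacent residues", {
  sys <- make_ca_system(3, chain = "A", resno = c(10, 11, 20))
  nodes <- network_nodes(sys)
  mk_frames <- function(n_close, n_far, d_far = 9) {
    close_fr <- as.numeric(t(rbind(c(0, 0, 0), c(3, 0, 0), c(1.5, 3, 0))))
    far_fr <- as.numeric(t(rbind(c(0, 0, 0), c(3, 0, 0),
                                 c(1.5, d_far, 0))))
    rbind(matrix(rep(close_fr, n_close), ncol = 9, byrow = TRUE),
          matrix(rep(far_fr, n_far), ncol = 9, byrow = TRUE))
  }
  # A:10 and A:20 within 4.5 in 75% of frames -> adjacent (>= threshold)
  adj <- contact_map(mk_frames(75, 25), sys, nodes)
  expect_true(adj["A:10", "A:20"])
  # 74% -> not adjacent (strict threshold)
  adj2 <- contact_map(mk_frames(74, 26), sys, nodes)
  expect_false(adj2["A:10", "A:20"])
  # residues i, i+1 in permanent contact still get no edge
  expect_false(adj["A:10", "A:11"])
})

test_that("correlation matrix recovers exact construction cases", {
  sys <- make_ca_system(3, chain = "A", resno = c(1, 3, 5))
  nodes <- network_nodes(sys)
  set.seed(2)
  d <- rnorm(60)
  xyz <- matrix(0, nrow = 60, ncol = 9)
  xyz[, 1] <- d          # node 1 moves along x
  xyz[, 4] <- d          # node 2 identical -> C = 1
  xyz[, 7] <- -d         # node 3 opposite  -> C = -1
  C <- correlation_matrix(xyz, nodes, fit_idx = NA)
  expect_equal(C[1, 2], 1)
  expect_equal(C[1, 3], -1)
  expect_equal(diag(C), c(`A:1` = 1, `A:3` = 1, `A:5` = 1))
  # zero-variance node: off-diagonal zeroed with a warning
  xyz[, 7] <- 0
  expect_warning(C2 <- correlation_matrix(xyz, nodes, fit_idx = NA),
                 "zero-variance")
  expect_equal(C2[1, 3], 0)
  expect_equal(C2[3, 3], 1)
})

test_that("suboptimal path enumeration matches the exhaustive oracle", {
  # spec example: s-a-t (1 + 1) plus direct s-t (5)
  edges <- data.frame(i = c(1, 2, 1), j = c(2, 3, 3), w = c(1, 1, 5))
  g <- graph_from_edges(edges, 3, c("s", "a", "t"))
  pe0 <- suboptimal_paths(g, "s", "t", tolerance = 0)
  expect_equal(pe0$paths, list(c("s", "a", "t")))
  expect_equal(pe0$optimal_weight, 2)
  pe3 <- suboptimal_paths(g, "s", "t", tolerance = 3)
  expect_equal(length(pe3$paths), 2)
  expect_equal(pe3$weights, c(2, 5))
  expect_equal(unname(pe3$visit_frequency[["a"]]), 0.5)

  # trivial and unreachable endpoints
  pe_same <- suboptimal_paths(g, "s", "s")
  expect_equal(pe_same$paths, list("s"))
  g2 <- igraph::add_vertices(g, 1, name = "iso")
  pe_no <- suboptimal_paths(g2, "s", "iso")
  expect_false(pe_no$reachable)
  expect_equal(length(pe_no$paths), 0)

  # randomised graphs up to 12 nodes against exhaustive enumeration
  set.seed(31)
  for (k in 1:8) {
    n <- sample(5:12, 1)
    full <- expand.grid(i = 1:n, j = 1:n)
    full <- full[full$i < full$j, ]
    m <- full[runif(nrow(full)) < 0.45, ]
    if (!nrow(m)) next
    m$w <- round(runif(nrow(m), 0.2, 2), 3)
    g3 <- graph_from_edges(m, n)
    orc <- oracle_all_paths(m, n, 1, n)
    pe <- suboptimal_paths(g3, "n1", paste0("n", n), tolerance = 0.6)
    if (!length(orc$weights)) {
      expect_false(pe$reachable)
      next
    }
    keep <- orc$weights <= min(orc$weights) + 0.6 + 1e-12
    expected <- sort(vapply(orc$paths[keep], function(p)
      paste(paste0("n", p), collapse = ">"), character(1)))
    got <- sort(vapply(pe$paths, paste, character(1), collapse = ">"))
    expect_identical(got, expected)
    expect_equal(sort(pe$weights), sort(orc$weights[keep]),
                 tolerance = 1e-12)
  }
})

test_that("betweenness matches the oracle and the closed-form cases", {
  # path graph a-b-c: only intermediary has betweenness 1 (normalised)
  edges <- data.frame(i = c(1, 2), j = c(2, 3), w = c(1, 1))
  g <- graph_from_edges(edges, 3, c("a", "b", "c"))
  b <- node_betweenness(g)
  expect_equal(unname(b[c("a", "b", "c")]), c(0, 1, 0))

  # equal-weight triangle: nothing routes through a third node
  tri <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3), w = c(1, 1, 1))
  expect_equal(unname(node_betweenness(graph_from_edges(tri, 3))),
               c(0, 0, 0))

  # randomised graphs vs the enumeration oracle
  set.seed(17)
  for (k in 1:5) {
    n <- sample(5:9, 1)
    full <- expand.grid(i = 1:n, j = 1:n)
    full <- full[full$i < full$j, ]
    m <- full[runif(nrow(full)) < 0.5, ]
    if (nrow(m) < n) next
    m$w <- round(runif(nrow(m), 0.2, 2), 3)
    g3 <- graph_from_edges(m, n)
    expect_equal(unname(node_betweenness(g3)), oracle_betweenness(m, n),
                 tolerance = 1e-10)
  }
})

test_that("uniform weight scaling preserves rankings and betweenness", {
  set.seed(5)
  edges <- data.frame(i = c(1, 1, 2, 2, 3, 4), j = c(2, 3, 3, 4, 5, 5),
                      w = round(runif(6, 0.3, 1.5), 3))
  g1 <- graph_from_edges(edges, 5)
  e2 <- edges; e2$w <- e2$w * 3
  g2 <- graph_from_edges(e2, 5)
  p1 <- suboptimal_paths(g1, "n1", "n5", tolerance = 0.5)
  p2 <- suboptimal_paths(g2, "n1", "n5", tolerance = 1.5)
  expect_identical(p1$paths, p2$paths)
  expect_equal(p2$weights, 3 * p1$weights)
  expect_equal(node_betweenness(g2), node_betweenness(g1))
})

test_that("conservation uses a strict recurrence threshold and excludes
           endpoints", {
  mk_pe <- function(nodes) {
    structure(list(paths = list(c("s", nodes, "t")), source = "s",
                   sink = "t"), class = "path_ensemble")
  }
  pes <- list(mk_pe(c("x", "y")), mk_pe(c("x", "y")), mk_pe(c("x", "z")),
              mk_pe(c("x", "y")))
  cons <- conservation(pes)
  expect_equal(cons$recurrence[cons$node == "x"], 1.0)
  expect_true(cons$conserved[cons$node == "x"])
  # 3 of 4 = 0.75: NOT conserved under the strict "more than" rule
  expect_equal(cons$recurrence[cons$node == "y"], 0.75)
  expect_false(cons$conserved[cons$node == "y"])
  # endpoints never appear
  expect_false(any(cons$node %in% c("s", "t")))
})

test_that("network export writes edge-list CSV and GraphML", {
  edges <- data.frame(i = c(1, 2), j = c(2, 3), w = c(0.5, 1))
  g <- graph_from_edges(edges, 3, c("a", "b", "c"))
  pref <- file.path(withr::local_tempdir(), "net")
  paths <- write_network(g, pref)
  df <- read.csv(paste0(pref, "_edges.csv"))
  expect_equal(nrow(df), 2)
  expect_setequal(names(df), c("from", "to", "correlation", "weight"))
  g2 <- igraph::read_graph(paste0(pref, ".graphml"), format = "graphml")
  expect_equal(igraph::ecount(g2), 2)
})
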