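unitCoupling <- function(n) new("CouplingMatrix",
  mat = matrix(1, n, n), kind = "dynamic_rMI", meta = list())

test_that("RIN construction applies contact and occupancy rules", {
  tr <- collinearTrace()
  arr <- array(coords(tr), c(1, 3, 3))
  arr[1, , ] <- coords(tr)
  ens <- new("Ensemble", coords = arr, times = 1, ids = tr@ids,
             resnames = tr@resnames, provenance = list())
  g <- buildRin(ens, unitCoupling(3), caCutoff = 7.5)
  expect_equal(nrow(g@edges), 2)                 # 1-3 is 7.6 A apart
  expect_setequal(paste(g@edges$i, g@edges$j), c("1 2", "2 3"))

  ## occupancy boundary: present in exactly half the frames is retained
  arr2 <- array(0, c(10, 3, 3))
  near <- coords(tr)
  far <- near; far[3, 1] <- 20
  for (f in 1:10) arr2[f, , ] <- if (f <= 4) near else far
  ens2 <- new("Ensemble", coords = arr2, times = 1:10, ids = tr@ids,
              resnames = tr@resnames, provenance = list())
  g2 <- buildRin(ens2, unitCoupling(3))
  expect_false("2 3" %in% paste(g2@edges$i, g2@edges$j))  # 4/10 dropped

  arr3 <- arr2[c(1:4, 5:10)[1:8], , , drop = FALSE]       # 4 of 8 = 0.5
  ens3 <- new("Ensemble", coords = arr3, times = 1:8, ids = tr@ids,
              resnames = tr@resnames, provenance = list())
  g3 <- buildRin(ens3, unitCoupling(3))
  expect_true("2 3" %in% paste(g3@edges$i, g3@edges$j))

  expect_error(buildRin(ens, unitCoupling(5)), "mismatch")
})

test_that("edge lengths come from the coupling matrix via -log r", {
  tr <- collinearTrace()
  arr <- array(coords(tr), c(1, 3, 3))
  cm <- matrix(exp(-2), 3, 3); diag(cm) <- 1
  cm[1, 2] <- cm[2, 1] <- exp(-1)
  ens <- new("Ensemble", coords = arr, times = 1, ids = tr@ids,
             resnames = tr@resnames, provenance = list())
  g <- buildRin(ens, new("CouplingMatrix", mat = cm, kind = "dynamic_rMI",
                         meta = list()))
  e12 <- g@edges$w[g@edges$i == 1 & g@edges$j == 2]
  e23 <- g@edges$w[g@edges$i == 2 & g@edges$j == 3]
  expect_equal(e12, 1)
  expect_equal(e23, 2)
})

test_that("shortest paths satisfy the textbook cases", {
  tri <- residueGraph(3, c(1, 2, 1), c(2, 3, 3), w = c(1, 1, 3))
  p <- shortestPaths(tri)
  expect_equal(p@dist[1, 3], 2)
  expect_equal(p@counts[1, 3], 1)

  disc <- residueGraph(3, 1, 2)
  pd <- shortestPaths(disc)
  expect_equal(pd@dist[1, 3], Inf)
  expect_equal(pd@counts[1, 3], 0)
})

test_that("Floyd-Warshall distances match per-source Dijkstra", {
  set.seed(31)
  for (k in 1:30) {
    n <- sample(5:50, 1)
    g <- randomGraph(n, 0.15)
    D <- shortestPaths(g)@dist
    for (s in sample(n, min(5, n)))
      expect_equal(D[s, ], dijkstra(g, s), tolerance = 1e-9)
  }
})

test_that("betweenness by path counting matches enumeration and Brandes", {
  path3 <- residueGraph(3, c(1, 2), c(2, 3))
  expect_equal(nodeBetweenness(path3), c(0, 1, 0))
  expect_equal(edgeBetweenness(path3), c(2, 2))

  star <- residueGraph(4, c(1, 1, 1), c(2, 3, 4))
  expect_equal(nodeBetweenness(star), c(3, 0, 0, 0))

  c4 <- residueGraph(4, c(1, 2, 3, 1), c(2, 3, 4, 4))
  expect_equal(nodeBetweenness(c4), rep(0.5, 4), tolerance = 1e-12)

  ## bridge between two triangles dominates edge betweenness
  bt <- residueGraph(6, c(1, 2, 1, 4, 5, 4, 3), c(2, 3, 3, 5, 6, 6, 4))
  eb <- edgeBetweenness(bt)
  bridge <- which(bt@edges$i == 3 & bt@edges$j == 4)
  expect_true(all(eb[bridge] > eb[-bridge]))

  set.seed(37)
  for (k in 1:10) {
    n <- sample(5:12, 1)
    g <- randomGraph(n, 0.3)
    ref <- enumerateBetweenness(g)
    expect_equal(nodeBetweenness(g), ref$node, tolerance = 1e-9)
    expect_equal(edgeBetweenness(g), ref$edge, tolerance = 1e-9)
    ## independent Brandes implementation (igraph) as a second oracle
    ig <- igraph::graph_from_data_frame(
      data.frame(from = g@edges$i, to = g@edges$j, weight = g@edges$w),
      directed = FALSE, vertices = data.frame(name = seq_len(g@n)))
    expect_equal(nodeBetweenness(g),
                 unname(igraph::betweenness(ig)), tolerance = 1e-9)
    expect_equal(edgeBetweenness(g),
                 unname(igraph::edge_betweenness(ig)), tolerance = 1e-9)
  }
})

test_that("Girvan-Newman recovers planted modules", {
  edges <- rbind(t(combn(1:4, 2)), t(combn(5:8, 2)), c(4, 5))
  g <- residueGraph(8, edges[, 1], edges[, 2])
  gn <- girvanNewman(g)
  expect_setequal(lapply(gn@communities, sort), list(1:4, 5:8))

  ## the bridge is removed first
  eb <- edgeBetweenness(g)
  expect_equal(unname(unlist(
    g@edges[which.max(eb), c("i", "j")])), c(4, 5))

  k5 <- t(combn(1:5, 2))
  g5 <- residueGraph(5, k5[, 1], k5[, 2])
  expect_length(girvanNewman(g5)@communities, 1)

  edgeless <- residueGraph(4, integer(0), integer(0))
  expect_length(girvanNewman(edgeless)@communities, 4)
})

test_that("returned modularity is the brute-force maximum over partitions", {
  edges <- rbind(t(combn(1:4, 2)), t(combn(5:8, 2)), c(4, 5))
  g <- residueGraph(8, edges[, 1], edges[, 2])
  gn <- girvanNewman(g)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = g@edges$i, to = g@edges$j, weight = exp(-g@edges$w)),
    directed = FALSE, vertices = data.frame(name = 1:8))
  best <- max(vapply(allPartitions(8), function(memb)
    igraph::modularity(ig, memb, weights = igraph::E(ig)$weight),
    numeric(1)))
  expect_equal(gn@modularity, best, tolerance = 1e-9)
})

test_that("clique percolation follows the share rule", {
  sharedEdge <- residueGraph(4, c(1, 2, 1, 2, 3), c(2, 3, 3, 4, 4))
  cc <- kCliqueCommunities(sharedEdge, k = 3, share = "k-1")
  expect_length(cc@communities, 1)
  expect_equal(sort(cc@communities[[1]]), 1:4)

  sharedNode <- residueGraph(5, c(1, 2, 1, 3, 4, 3), c(2, 3, 3, 4, 5, 5))
  expect_length(kCliqueCommunities(sharedNode, 3, "k-1")@communities, 2)
  expect_length(kCliqueCommunities(sharedNode, 3, "k-2")@communities, 1)

  noTri <- residueGraph(4, c(1, 2, 3), c(2, 3, 4))
  expect_length(kCliqueCommunities(noTri, 3)@communities, 0)
})

test_that("community stability applies the strict 75% rule", {
  mk <- function(comms) new("CommunitySet", communities = comms,
                            membership = NA_integer_,
                            modularity = NA_real_, overlapping = FALSE,
                            stability = NA_real_)
  ident <- replicate(5, mk(list(1:4, 5:8)), simplify = FALSE)
  st <- communityStability(ident)
  expect_length(st@communities, 2)
  expect_equal(st@stability, c(1, 1))

  ## community present in 7 of 10 frames: 0.7 <= 0.75, dropped
  frames <- c(replicate(7, mk(list(1:4, 5:8)), simplify = FALSE),
              replicate(3, mk(list(1:8)), simplify = FALSE))
  st2 <- communityStability(frames)
  expect_length(st2@communities, 0)

  ## one-node fluctuation (Jaccard 0.8 >= 0.6) still matches
  fluct <- c(replicate(5, mk(list(1:5, 6:8)), simplify = FALSE),
             replicate(5, mk(list(1:4, 5:8)), simplify = FALSE))
  st3 <- communityStability(fluct)
  expect_gte(length(st3@communities), 2)
  expect_true(all(st3@stability == 1))

  expect_error(communityStability(list(mk(list(1:4)), mk(list(1:5)))),
               "node sets")
  expect_error(communityStability(list(mk(list(1:4)))), "at least 2")
})

test_that("a bridge widens the edge-centrality distribution", {
  ## dense symmetric graph vs the same graph with a pendant bridge module:
  ## the bridged variant has a fatter-tailed (higher-CV) edge centrality
  k6 <- t(combn(1:6, 2))
  dense <- residueGraph(6, k6[, 1], k6[, 2])
  cvDense <- sd(edgeBetweenness(dense)) / mean(edgeBetweenness(dense))
  bridged <- residueGraph(9, c(k6[, 1], 6, 7, 8, 7),
                          c(k6[, 2], 7, 8, 9, 9))
  ebB <- edgeBetweenness(bridged)
  cvBridged <- sd(ebB) / mean(ebB)
  expect_gt(cvBridged, cvDense)
})

test_that("two-lobe RIN communities separate the lobes", {
  tr <- makeTwoLobeToy(20, 20, seed = 1)
  ens <- runDmd(buildGoModel(tr), tr, nEvents = 1e5, temperature = 1,
                nu = 1, snapshotEvery = 1000, seed = 2)
  rmi <- dynamicRmi(ens)
  rin <- buildRin(ens, rmi)
  gn <- girvanNewman(rin)
  memb <- gn@membership
  ## no community mixes lobe-1 and lobe-2 residues (linker free to go
  ## either way, at most 2 misassigned)
  mixed <- vapply(gn@communities, function(cm)
    sum(cm <= 20) > 2 && sum(cm >= 24) > 2, logical(1))
  expect_false(any(mixed))
})
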