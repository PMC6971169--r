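test_that("canonical graphs reproduce closed-form metric values", {
  tri <- BinaryNetwork(completeAdj(3))
  k4 <- BinaryNetwork(completeAdj(4))
  k5 <- BinaryNetwork(completeAdj(5))
  star5 <- BinaryNetwork(starAdj(5))
  path3 <- BinaryNetwork(pathAdj(3))
  path4 <- BinaryNetwork(pathAdj(4))
  cyc4 <- BinaryNetwork(cycleAdj(4))
  empty <- BinaryNetwork(matrix(0, 4, 4))
  k4minus <- completeAdj(4); k4minus[1, 2] <- k4minus[2, 1] <- 0

  expect_equal(clusteringCoefficient(tri)$Cp, 1)
  expect_equal(clusteringCoefficient(star5)$Cp, 0)
  expect_equal(clusteringCoefficient(BinaryNetwork(k4minus))$Cp, 5 / 6)

  lp <- characteristicPathLength(k5)
  expect_equal(lp$Lp, 1)
  expect_equal(lp$reachableFraction, 1)
  expect_equal(characteristicPathLength(path4)$Lp, 10 / 6)
  disj <- characteristicPathLength(
    BinaryNetwork(adjFromEdges(4, list(c(1, 2), c(3, 4)))))
  expect_equal(disj$Lp, 1)                       # only the two edges are finite pairs
  expect_equal(disj$reachableFraction, 2 / 6)
  expect_true(is.na(characteristicPathLength(empty)$Lp))
  expect_equal(characteristicPathLength(empty)$reachableFraction, 0)

  expect_equal(globalEfficiency(k4), 1)
  expect_equal(globalEfficiency(path3), 5 / 6)   # distances {1, 1, 2}
  expect_equal(globalEfficiency(empty), 0)

  expect_equal(localEfficiency(tri), 1)
  expect_equal(localEfficiency(star5), 0)        # hub neighbourhood edgeless
  expect_equal(localEfficiency(k4), 1)

  expect_equal(unname(degreeCentrality(k4)), rep(3, 4))
  expect_equal(unname(degreeCentrality(star5)), c(4, 1, 1, 1, 1))
  expect_equal(unname(degreeCentrality(empty)), rep(0, 4))

  expect_equal(unname(betweennessCentrality(path3)), c(0, 1, 0))
  expect_equal(unname(betweennessCentrality(star5)), c(6, 0, 0, 0, 0))
  expect_equal(unname(betweennessCentrality(cyc4)), rep(0.5, 4))
})

test_that("metrics agree with brute-force oracles on small random graphs", {
  set.seed(20)
  for (i in 1:200) {
    n <- sample(4:8, 1)
    a <- erAdj(n, runif(1, 0.3, 0.8))
    if (sum(a) == 0) a <- pathAdj(n)
    net <- BinaryNetwork(a)
    expect_lt(max(abs(betweennessCentrality(net) - bruteBetweenness(a))), 1e-9)
    lp <- characteristicPathLength(net)
    expect_equal(lp$Lp, fwLp(a))
    expect_equal(globalEfficiency(net), fwEglob(a))
    expect_equal(unname(clusteringCoefficient(net)$nodal), bruteClustering(a))
  }
})

test_that("betweenness matches an independent library implementation", {
  library(igraph)
  set.seed(23)
  for (i in 1:20) {
    a <- erAdj(10, 0.4)
    g <- graph_from_adjacency_matrix(a, mode = "undirected")
    expect_lt(max(abs(betweennessCentrality(BinaryNetwork(a)) -
                        igraph::betweenness(g))), 1e-9)
  }
})

test_that("global metrics satisfy structural invariants", {
  set.seed(21)
  for (i in 1:25) {
    a <- randomConnectedAdj(sample(6:12, 1), 0.4)
    net <- BinaryNetwork(a)
    deg <- degreeCentrality(net)
    expect_equal(sum(deg), 2 * edgeCount(net))
    expect_true(all(betweennessCentrality(net) >= 0))
    lp <- characteristicPathLength(net)
    expect_gte(globalEfficiency(net) + 1e-12, 1 / lp$Lp)  # Jensen
    # isomorphism invariance
    perm <- sample(nrow(a))
    netP <- BinaryNetwork(a[perm, perm])
    expect_equal(clusteringCoefficient(netP)$Cp, clusteringCoefficient(net)$Cp)
    expect_equal(characteristicPathLength(netP)$Lp, lp$Lp)
    expect_equal(globalEfficiency(netP), globalEfficiency(net))
    expect_equal(localEfficiency(netP), localEfficiency(net))
    # adding an edge never decreases Eglob or any degree
    miss <- which(a == 0 & upper.tri(a), arr.ind = TRUE)
    if (nrow(miss) > 0) {
      e <- miss[sample(nrow(miss), 1), ]
      a2 <- a; a2[e[1], e[2]] <- a2[e[2], e[1]] <- 1
      expect_gte(globalEfficiency(BinaryNetwork(a2)), globalEfficiency(net))
      expect_true(all(degreeCentrality(BinaryNetwork(a2)) >= deg))
    }
  }
  # degree-1 nodes of a tree have zero betweenness
  tree <- BinaryNetwork(adjFromEdges(6, list(c(1, 2), c(1, 3), c(2, 4),
                                             c(2, 5), c(3, 6))))
  bt <- betweennessCentrality(tree)
  expect_true(all(bt[degreeCentrality(tree) == 1] == 0))
})

test_that("degree-preserving rewiring keeps degrees, is seeded, randomises edges", {
  set.seed(22)
  a <- erAdj(20, 0.3)
  net <- BinaryNetwork(a)
  r1 <- rewireDegreePreserving(net, seed = 7L)
  r2 <- rewireDegreePreserving(net, seed = 7L)
  r3 <- rewireDegreePreserving(net, seed = 8L)
  expect_identical(adjacency(r1), adjacency(r2))
  expect_false(identical(adjacency(r1), adjacency(r3)))
  expect_equal(sort(rowSums(adjacency(r1))), sort(rowSums(a)))
  expect_equal(rowSums(adjacency(r1)), rowSums(a))    # per-node, not just sorted
  expect_equal(edgeCount(r1), edgeCount(net))
  expect_false(identical(adjacency(r1), a))           # swaps actually happened
  expect_true(all(diag(adjacency(r1)) == 0))
  expect_warning(rk <- rewireDegreePreserving(BinaryNetwork(completeAdj(4))),
                 "complete graph")
  expect_identical(adjacency(rk), completeAdj(4))
})

test_that("small-world normalisation behaves as expected on reference graphs", {
  # complete graph: nulls coincide with the graph itself
  nm <- normalizedMetrics(BinaryNetwork(completeAdj(6)), nNull = 5, seed = 1L)
  expect_equal(nm$gamma, 1)
  expect_equal(nm$lambda, 1)
  expect_equal(nm$sigma, 1)

  # ring lattice: strongly clustered relative to degree-matched nulls
  ring <- BinaryNetwork(ringLatticeAdj(90, 8))
  nmRing <- normalizedMetrics(ring, nNull = 20, seed = 2L)
  expect_gt(nmRing$gamma, 1.5)
  expect_equal(nmRing$sigma, nmRing$gamma / nmRing$lambda, tolerance = 1e-12)

  # Erdos-Renyi graphs are statistically self-similar under rewiring
  set.seed(24)
  er <- BinaryNetwork(erAdj(90, 0.1))
  nmEr <- normalizedMetrics(er, nNull = 20, seed = 3L)
  expect_gt(nmEr$gamma, 0.8); expect_lt(nmEr$gamma, 1.2)
  expect_gt(nmEr$lambda, 0.9); expect_lt(nmEr$lambda, 1.1)
})

test_that("metric and nodal record tables have the contracted shape", {
  spec <- cohortSpec(nPerGroup = 1, nRois = 20, nModules = 4, seed = 33)
  coh <- simulateCohort(spec)
  zcs <- cohortConnectivity(coh)
  rec <- computeMetricRecords(zcs, sparsities = c(0.1, 0.3), nNull = 3, seed = 5L)
  expect_equal(nrow(rec), length(zcs) * 2)
  expect_true(all(c("Cp", "Lp", "Eglob", "Eloc", "gamma", "lambda", "sigma",
                    "reachable_fraction", "n_isolated") %in% names(rec)))
  expect_true(all(rec$Cp >= 0 & rec$Cp <= 1))
  expect_true(all(rec$Eglob >= 0 & rec$Eglob <= 1))
  expect_true(all(rec$Eloc >= 0 & rec$Eloc <= 1))
  expect_true(all(rec$Lp >= 1, na.rm = TRUE))
  expect_equal(rec$sigma, rec$gamma / rec$lambda, tolerance = 1e-12)
  nod <- computeNodalRecords(zcs, s = 0.1)
  expect_equal(nrow(nod), length(zcs) * 20)
  expect_true(all(nod$betweenness >= 0))
  # per network: sum of degrees = 2 x edge count at that sparsity
  tot <- tapply(nod$degree, paste(nod$subject_id, nod$session), sum)
  expect_true(all(tot == 2 * edgeCountForSparsity(20, 0.1)))
})
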