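test_that("closed-form statistics on canonical small graphs", {
  tri <- cliqueNetwork(c("a", "b", "c"))
  st <- networkStats(tri, seed = 1)
  expect_equal(st@L, 1)
  expect_equal(st@C, 1)
  expect_equal(st@K, 2)
  expect_equal(st@Q, 0)
  expect_equal(st@D, 1)

  # path a - b - c: distances 1, 1, 2
  pth <- netFromPairs(cbind(c("a", "b"), c("b", "c")), c("a", "b", "c"))
  expect_equal(averagePathLength(pth), 4 / 3)

  # 4-star: no neighbour-neighbour edges anywhere
  star <- netFromPairs(cbind(rep("h", 3), c("a", "b", "c")),
                       c("h", "a", "b", "c"))
  expect_equal(clusteringCoefficient(star), 0)

  # K4 minus one edge: clustering 5/6
  k4e <- adjacencyToNetwork({
    a <- matrix(TRUE, 4, 4); diag(a) <- FALSE; a[1, 2] <- a[2, 1] <- FALSE; a
  })
  expect_equal(clusteringCoefficient(k4e), 5 / 6)

  # components that are single edges all have distance one
  m <- netFromPairs(cbind(c("a", "c"), c("b", "d")), letters[1:4])
  expect_equal(averagePathLength(m), 1)
})

test_that("degree and density bookkeeping", {
  tri <- cliqueNetwork(c("a", "b", "c"))
  expect_equal(averageDegree(tri), 2)
  empty <- netFromPairs(cbind(character(), character()), letters[1:5])
  expect_equal(averageDegree(empty), 0)
  expect_equal(graphDensity(empty), 0)
  # adding one edge between isolated nodes raises K by 2/n
  one <- netFromPairs(cbind("a", "b"), letters[1:5])
  expect_equal(averageDegree(one) - averageDegree(empty), 2 / 5)
  expect_error(graphDensity(netFromPairs(cbind(character(), character()),
                                         "a")),
               "fewer than 2")
  expect_error(averagePathLength(empty), "edgeless")
})

test_that("modularity follows the Newman-Girvan form", {
  # two disconnected triangles in their own communities: Q = 0.5
  a <- matrix(FALSE, 6, 6)
  a[1, 2] <- a[2, 3] <- a[1, 3] <- TRUE
  a[4, 5] <- a[5, 6] <- a[4, 6] <- TRUE
  a <- a | t(a)
  net <- adjacencyToNetwork(a)
  part <- stats::setNames(rep(1:2, each = 3), geneIds(net))
  expect_equal(modularityScore(net, part), 0.5)
  # everything in one community scores zero
  expect_equal(modularityScore(net,
                               stats::setNames(rep(1L, 6), geneIds(net))), 0)
  # two triangles joined by a bridge: matches the e-matrix oracle
  ab <- a; ab[3, 4] <- ab[4, 3] <- TRUE
  netb <- adjacencyToNetwork(ab)
  expect_equal(modularityScore(netb, part),
               oracleModularity(ab, rep(1:2, each = 3)))
  expect_error(modularityScore(net, part[-1]), "cover")
})

test_that("community detection separates disconnected cliques", {
  a <- matrix(FALSE, 6, 6)
  a[1, 2] <- a[2, 3] <- a[1, 3] <- TRUE
  a[4, 5] <- a[5, 6] <- a[4, 6] <- TRUE
  a <- a | t(a)
  net <- adjacencyToNetwork(a)
  part <- detectCommunities(net, seed = 1)
  expect_equal(length(unique(part)), 2L)
  expect_equal(length(unique(part[1:3])), 1L)
  expect_equal(length(unique(part[4:6])), 1L)
  expect_equal(length(unique(detectCommunities(cliqueNetwork(letters[1:4]),
                                               seed = 1))), 1L)
  expect_error(detectCommunities(netFromPairs(cbind(character(), character()),
                                              "a"), 1), "edgeless")
})

test_that("detected partitions are near the exhaustive-search optimum", {
  set.seed(61)
  for (rep in 1:6) {
    n <- sample(5:7, 1)
    adj <- randomAdjacency(n, 0.45)
    if (sum(adj) == 0) next
    net <- adjacencyToNetwork(adj)
    q <- modularityScore(net, detectCommunities(net, seed = rep))
    allQ <- vapply(allPartitions(n), function(p) oracleModularity(adj, p),
                   numeric(1))
    expect_gte(q, stats::quantile(allQ, 0.95) - 1e-9)
  }
})

test_that("all five statistics match brute-force oracles on random graphs", {
  set.seed(62)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    adj <- randomAdjacency(n, stats::runif(1, 0.2, 0.7))
    net <- adjacencyToNetwork(adj)
    expect_equal(averageDegree(net), oracleDegree(adj))
    expect_equal(clusteringCoefficient(net), oracleClustering(adj))
    expect_equal(graphDensity(net), oracleDensity(adj))
    if (sum(adj) > 0) {
      expect_equal(averagePathLength(net), oraclePathLength(adj))
      part <- detectCommunities(net, seed = rep)
      expect_equal(modularityScore(net, part),
                   oracleModularity(adj, part[geneIds(net)]))
    }
  }
})

test_that("statistics are invariant under node relabeling", {
  set.seed(63)
  adj <- randomAdjacency(7, 0.4)
  net1 <- adjacencyToNetwork(adj, genes = sprintf("n%02d", 1:7))
  perm <- sample(7)
  net2 <- adjacencyToNetwork(adj[perm, perm], genes = sprintf("x%02d", 1:7))
  for (f in list(averagePathLength, clusteringCoefficient, averageDegree,
                 graphDensity))
    expect_equal(f(net1), f(net2))
})

test_that("the stats bundle degrades gracefully and stays self-consistent", {
  empty <- netFromPairs(cbind(character(), character()), letters[1:4])
  st <- networkStats(empty, seed = 1)
  expect_true(is.na(st@L))
  expect_true(is.na(st@Q))
  expect_equal(st@K, 0)
  expect_match(st@reasons[["L"]], "edgeless")
  # D = K / (n - 1) by construction for every computed bundle
  set.seed(64)
  for (rep in 1:5) {
    net <- adjacencyToNetwork(randomAdjacency(6, 0.5))
    st <- networkStats(net, seed = 2)
    expect_equal(st@D, st@K / (st@nNodes - 1))
  }
  # deterministic given seed
  net <- adjacencyToNetwork(randomAdjacency(8, 0.4))
  expect_equal(as.data.frame(networkStats(net, seed = 5)),
               as.data.frame(networkStats(net, seed = 5)))
})

test_that("cross-condition comparison emits signed differences per parameter", {
  set.seed(65)
  W1 <- matrix(stats::rnorm(36), 6, 6,
               dimnames = rep(list(sprintf("g%d", 1:6)), 2)); diag(W1) <- 0
  W2 <- W1; W2[1, 2] <- W2[1, 2] * 3
  grid <- c(0.2, 0.4)
  s1 <- statsTable(sweepThresholds(W1, grid), seed = 1)
  s2 <- statsTable(sweepThresholds(W2, grid), seed = 1)
  cmp <- compareStats(list(a = s1, b = s2), reference = "b")
  expect_equal(nrow(cmp), 2 * 5)
  expect_equal(cmp$difference, cmp$condition_value - cmp$reference_value)
  # identical conditions -> all differences zero
  cmp0 <- compareStats(list(a = s1, b = s1), reference = "b")
  expect_equal(cmp0$difference, rep(0, 10))
  # swapping reference and comparison flips the sign
  cmpRev <- compareStats(list(a = s1, b = s2), reference = "a")
  expect_equal(cmp$difference, -cmpRev$difference)
  s3 <- statsTable(sweepThresholds(W2, c(0.3, 0.5)), seed = 1)
  expect_error(compareStats(list(a = s1, b = s3), "a"), "grid")
})
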