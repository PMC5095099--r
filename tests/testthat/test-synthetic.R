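test_that("the planted structure obeys its layer contracts", {
  grn <- plantedGRN(20, avgRegulators = 2, seed = 7)
  W <- weightValues(grn)
  expect_equal(dim(W), c(20L, 20L))
  expect_equal(unname(diag(W)), rep(0, 20))
  expect_true(all(W[lower.tri(W)] == 0))  # acyclic by index order
  indeg <- colSums(W != 0)
  expect_equal(unname(indeg[1:2]), c(0, 0))  # two exogenous drivers
  anchors <- which(indeg == 1)
  expect_length(anchors, 12L)   # six reporter genes per driver
  expect_true(all(W[, anchors][W[, anchors] != 0] < 0))
  targets <- which(indeg >= 2)
  for (j in targets) expect_equal(sum(W[, j]), -2, tolerance = 1e-12)
  # determinism and seed sensitivity
  expect_identical(W, weightValues(plantedGRN(20, 2, seed = 7)))
  expect_false(identical(W, weightValues(plantedGRN(20, 2, seed = 8))))
  # no regulators at all -> empty structure
  expect_equal(sum(weightValues(plantedGRN(10, 0, seed = 1)) != 0), 0L)
  expect_error(plantedGRN(1), "at least 2")
  expect_error(plantedGRN(5, avgRegulators = 10), "avgRegulators")
})

test_that("simulated expression satisfies the generative fixed point", {
  grn <- plantedGRN(15, 2, seed = 3)
  ge <- simulateExpression(grn, 50, noiseSd = 0, seed = 4)
  v <- exprValues(ge)
  expect_true(all(v >= 0 & v <= 1))
  W <- weightValues(grn)
  for (j in which(colSums(W != 0) > 0)) {
    pred <- sigmoid(drop(crossprod(W[, j], v)) - grn@bias)
    expect_equal(unname(v[j, ]), unname(pred))
  }
  expect_identical(exprValues(simulateExpression(grn, 50, 0, seed = 4)), v)
  # noise perturbs but stays clipped to [0, 1]
  gn <- simulateExpression(grn, 50, noiseSd = 0.3, seed = 4)
  vn <- exprValues(gn)
  expect_true(all(vn >= 0 & vn <= 1))
  expect_false(identical(vn, v))
  expect_error(simulateExpression(grn, 0), "nSamples")
})

test_that("recovery metrics agree with exhaustive edge enumeration", {
  grn <- plantedGRN(8, 2, seed = 9)
  truthNet <- buildNetwork(weightValues(grn), 0)
  # the truth's own support scores perfectly
  perfect <- recoveryMetrics(grn, truthNet)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$signAccuracy, 1)
  # an empty inferred network: zero recall, undefined precision
  empty <- buildNetwork(weightValues(plantedGRN(8, 0, seed = 1)), 0.5)
  emptied <- new("RegulatoryNetwork", geneIds = geneIds(grn),
                 edges = edges(empty)[0, ], threshold = 1, method = "bp")
  none <- recoveryMetrics(grn, emptied)
  expect_equal(none$recall, 0)
  expect_true(is.na(none$precision))
  # against a brute-force confusion count for an arbitrary inferred set
  set.seed(10)
  Wr <- matrix(stats::rnorm(64), 8, 8,
               dimnames = dimnames(weightValues(grn)))
  diag(Wr) <- 0
  inferred <- buildNetwork(Wr, 0.2)
  got <- recoveryMetrics(grn, inferred)
  Wt <- weightValues(grn)
  tp <- fp <- fn <- 0
  genes <- geneIds(grn)
  e <- edges(inferred)
  for (i in 1:8) for (j in 1:8) {
    inf <- any(e$source == genes[i] & e$target == genes[j])
    tru <- Wt[i, j] != 0
    tp <- tp + (inf && tru); fp <- fp + (inf && !tru)
    fn <- fn + (!inf && tru)
  }
  expect_equal(got$precision, tp / (tp + fp))
  expect_equal(got$recall, tp / (tp + fn))
})

test_that("edge recovery degrades on average as noise grows", {
  recallAt <- function(noise, seed) {
    grn <- plantedGRN(12, 2, seed = seed)
    ge <- simulateExpression(grn, 80, noiseSd = noise, seed = seed + 1)
    wm <- trainNetwork(ge, bpControl(seed = seed + 2, maxCycles = 150L))
    recoveryMetrics(grn, buildNetwork(wm, 0.15))$recall
  }
  seeds <- 100 * (1:10)
  mr <- vapply(c(0, 0.05, 0.1), function(ns)
    mean(vapply(seeds, function(s) recallAt(ns, s), numeric(1))),
    numeric(1))
  expect_true(all(diff(mr) <= 0))
})
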