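test_that("degree difference ratio on hand-checked cases", {
  expect_equal(degreeDifferenceRatio(3, 1, 3, 1), 0)
  expect_equal(degreeDifferenceRatio(2, 1, 0, 0), 1)
  expect_equal(degreeDifferenceRatio(3, 1, 1, 1), 1 / 3)
  expect_equal(degreeDifferenceRatio(0, 0, 0, 0), 0)  # 0/0 convention
  expect_error(degreeDifferenceRatio(-1, 0, 0, 0), "non-negative")
})

test_that("eta is bounded, symmetric, and zero only without degree change", {
  set.seed(41)
  d <- matrix(stats::rpois(4 * 200, 3), ncol = 4)
  eta <- degreeDifferenceRatio(d[, 1], d[, 2], d[, 3], d[, 4])
  expect_true(all(eta >= 0 & eta <= 1))
  etaSwap <- degreeDifferenceRatio(d[, 3], d[, 4], d[, 1], d[, 2])
  expect_equal(eta, etaSwap)
  same <- d[, 1] == d[, 3] & d[, 2] == d[, 4]
  expect_equal(eta == 0, same)
})

test_that("ranking by eta orders changed genes first, ties by gene ID", {
  genes <- c("a", "b", "c", "d")
  netA <- netFromPairs(rbind(c("a", "b"), c("a", "c"), c("c", "d")), genes)
  netB <- netFromPairs(rbind(c("c", "d")), genes)
  rk <- rankByEta(netA, netB)
  # a and b both lose all their degree (eta 1); the tie breaks by gene ID
  expect_equal(rk$gene[1:2], c("a", "b"))
  expect_equal(rk$eta[rk$gene == "c"], 1 / 3)
  expect_equal(rk$eta[rk$gene == "d"], 0)
  expect_equal(rk$rank, 1:4)
  # identical networks: every eta zero, ranking falls back to gene order
  rkId <- rankByEta(netA, netA)
  expect_equal(rkId$gene, genes)
  expect_equal(rkId$eta, rep(0, 4))
  # swapping the networks leaves eta unchanged
  expect_equal(sort(rankByEta(netB, netA)$eta), sort(rk$eta))
  netO <- netFromPairs(cbind("x", "y"), c("x", "y"))
  expect_error(rankByEta(netA, netO), "gene set")
})

test_that("a gene whose wiring is rewired between conditions attains maximal eta", {
  genes <- sprintf("g%d", 1:6)
  base <- rbind(c("g1", "g2"), c("g2", "g3"), c("g5", "g6"))
  # condition B: g4 (isolated in A) gains edges; everything else unchanged
  rew <- rbind(base, c("g4", "g1"), c("g4", "g5"))
  rk <- rankByEta(netFromPairs(base, genes), netFromPairs(rew, genes))
  expect_equal(rk$gene[1], "g4")
  expect_equal(rk$eta[1], 1)
  expect_equal(max(rk$eta), rk$eta[1])
})

test_that("network DEG selection applies policy then set combination", {
  genes <- c("a", "b", "c", "d")
  netA <- netFromPairs(rbind(c("a", "b"), c("a", "c")), genes)
  netB <- netFromPairs(rbind(c("b", "c")), genes)
  rk1 <- rankByEta(netA, netB)
  rk2 <- rankByEta(netB, netA)
  # etaMin = 0 selects every gene with any degree change
  expect_equal(selectNetworkDegs(rk1, etaMin = 0),
               sort(rk1$gene[rk1$eta > 0]))
  expect_equal(selectNetworkDegs(rk1, rk2, topK = 1,
                                 combine = "intersection"),
               rk1$gene[1])
  u <- selectNetworkDegs(rk1, rk2, etaMin = 0.2, combine = "union")
  i <- selectNetworkDegs(rk1, rk2, etaMin = 0.2, combine = "intersection")
  expect_true(all(i %in% u))
  expect_error(selectNetworkDegs(rk1, topK = 10), "topK")
})

test_that("fold-change z-test calls match construction", {
  set.seed(43)
  base <- matrix(stats::runif(5 * 6, 0.3, 0.5), 5, 6)
  gA <- exprFixture(base)
  gB <- exprFixture(base)
  out <- foldChangeZTest(gA, gB)
  expect_equal(out$log2_fold_change, rep(0, 5))
  expect_false(any(out$is_deg))
  # doubling a mean with negligible variance is called confidently
  b2 <- base; b2[2, ] <- 2 * base[2, ] + stats::rnorm(6, sd = 1e-4)
  out2 <- foldChangeZTest(gA, exprFixture(b2))
  expect_gt(out2$log2_fold_change[2], 0.9)
  expect_lt(out2$p_value[2], 1e-6)
  expect_true(out2$is_deg[2])
  expect_error(foldChangeZTest(gA, exprFixture(base[, 1, drop = FALSE])),
               "2 samples")
})

test_that("the fold-change cutoff is inclusive at the boundary", {
  set.seed(44)
  gA <- exprFixture(matrix(stats::runif(3 * 8, 0.4, 0.6), 3, 8))
  vb <- exprValues(gA) * 1.4
  out <- foldChangeZTest(gA, exprFixture(vb))
  l2 <- out$log2_fold_change[1]
  expect_lt(out$p_value[1], 0.05)
  # threshold set exactly at the observed value: still a DEG (>= rule)
  outEq <- foldChangeZTest(gA, exprFixture(vb), fcThreshold = l2)
  expect_true(outEq$is_deg[1])
  outAbove <- foldChangeZTest(gA, exprFixture(vb),
                              fcThreshold = l2 + 1e-12)
  expect_false(outAbove$is_deg[1])
})

test_that("overlap report partitions the universe into four cells", {
  uni <- letters[1:10]
  ov <- overlapReport(c("a", "b"), c("c", "d", "e"), uni)
  expect_equal(unname(ov$counts), c(2L, 3L, 0L, 5L))
  expect_equal(sum(ov$counts), 10L)
  ovId <- overlapReport(c("a", "b"), c("a", "b"), uni)
  expect_equal(unname(ovId$counts), c(0L, 0L, 2L, 8L))
  set.seed(45)
  for (rep in 1:5) {
    s1 <- sample(uni, sample(0:10, 1))
    s2 <- sample(uni, sample(0:10, 1))
    ov <- overlapReport(s1, s2, uni)
    expect_equal(sum(ov$counts), 10L)
    expect_setequal(unlist(ov$members), uni)
  }
  expect_error(overlapReport(c("z"), c("a"), uni), "subsets")
})
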