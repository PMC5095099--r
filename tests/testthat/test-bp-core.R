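test_that("sigmoid transfer function", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(2), 1 / (1 + exp(-2)))
  expect_equal(round(sigmoid(2), 4), 0.8808)
  x <- seq(-30, 30, length.out = 101)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, 101))
  expect_true(all(diff(sigmoid(x)) > 0))
  expect_equal(sigmoid(c(-1e6, 1e6)), c(0, 1))  # saturates, no overflow
})

test_that("neuron forward pass subtracts the threshold", {
  expect_equal(bpForward(c(0, 0), 0, c(1, 1)), 0.5)
  expect_equal(bpForward(c(0, 0), -1, c(0.2, 0.9)), sigmoid(1))
  expect_equal(bpForward(1, 0, 1), sigmoid(1))
  expect_error(bpForward(c(1, 2), 0, 1), "length")
})

test_that("pattern error is half the squared deviation", {
  expect_equal(patternError(c(0.4, 0.6), c(0.4, 0.6)), 0)
  expect_equal(patternError(1, 0), 0.5)
  expect_equal(patternError(c(1, 0), c(0.5, 0.5)), 0.25)
  expect_error(patternError(1:2, 1:3), "length")
})

test_that("one back-propagation step follows the generalized delta rule", {
  ctrl <- bpControl(learningRate = 0.7, momentum = 0.5)
  # delta at o = 0.5, t = 1 is 0.25 * 0.5 = 0.125
  st <- backpropStep(c(0, 0), 0, c(0, 0), 1, ctrl, prevChange = c(0, 0))
  expect_equal(st$output, 0.5)
  expect_equal(st$delta, 0.125)
  expect_equal(st$change, c(0, 0))  # inputs are zero
  # change = learningRate * delta * x when no momentum history
  st2 <- backpropStep(0.2, 0, 0.5, 0.9, ctrl, prevChange = 0)
  expect_equal(st2$change, 0.7 * st2$delta * 0.5)
  expect_equal(st2$weights, 0.2 + st2$change)
  # momentum adds half of the previous change
  st3 <- backpropStep(0.2, 0, 0.5, 0.9, ctrl, prevChange = 0.1)
  expect_equal(st3$change, 0.7 * st3$delta * 0.5 + 0.5 * 0.1)
  # a perfectly predicted pattern produces no update
  target <- bpForward(0.3, -1, 0.6)
  st4 <- backpropStep(0.3, -1, 0.6, target, ctrl, prevChange = 0)
  expect_equal(st4$weights, 0.3)
})

test_that("hand-checked weight update: 0.2 -> 0.235 at lr 0.7, delta 0.1, x 0.5", {
  # weight 0.2, input 0.5, bias 0.1 puts the net input at zero, so o = 0.5;
  # target 0.9 then gives delta = 0.25 * 0.4 = 0.1 exactly
  st <- backpropStep(0.2, 0.1, 0.5, 0.9, bpControl(), prevChange = 0)
  expect_equal(st$output, 0.5)
  expect_equal(st$delta, 0.1)
  expect_equal(st$weights, 0.235)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    P <- sample(3:10, 1)
    w <- stats::runif(n, -1, 1)
    b <- stats::runif(1, -2, 2)
    X <- matrix(stats::runif(n * P), n, P)
    t <- stats::runif(P)
    g <- bpGradient(w, b, X, t)
    fd <- finiteDiffGradient(w, b, X, t)
    expect_lt(max(abs(g - fd)), 1e-6)
    expect_lt(abs(attr(g, "bias") - attr(fd, "bias")), 1e-6)
  }
})

test_that("training fits a noiseless realizable target below tolerance", {
  set.seed(21)
  n <- 6; P <- 60
  X <- matrix(stats::runif((n - 1) * P), n - 1, P)
  wTrue <- c(1.2, -2.5, 0.8, 0, 0)
  target <- sigmoid(drop(crossprod(X, wTrue)) + 1)  # bias -1
  m <- rbind(X, target)
  rownames(m) <- c(paste0("in", 1:(n - 1)), "out")
  colnames(m) <- paste0("s", 1:P)
  reg <- trainGeneRegressor(GeneExpression(m), "out", bpControl(seed = 3))
  expect_true(reg@converged)
  expect_lt(reg@finalError, 1e-2)
  expect_false("out" %in% names(reg@weights))
})

test_that("a constant half target with zero inputs never updates weights", {
  m <- rbind(matrix(0, 3, 10), rep(0.5, 10))
  rownames(m) <- c("a", "b", "c", "t")
  colnames(m) <- paste0("s", 1:10)
  ctrl <- bpControl(bias = 0, seed = 5, maxCycles = 20L)
  init <- stats::runif(3)  # any init: delta is 0 at every pattern? no --
  # delta is zero only if o equals t; with zero inputs o = sigmoid(-bias)
  # = 0.5 = t regardless of the weights, so updates vanish.
  reg <- trainGeneRegressor(GeneExpression(m), "t", ctrl, initWeights = init)
  expect_equal(unname(reg@weights), init)
  expect_true(reg@converged)
})

test_that("whole error decreases monotonically at small rate, no momentum", {
  set.seed(33)
  X <- matrix(stats::runif(3 * 20), 3, 20)
  target <- sigmoid(drop(crossprod(X, c(2, -1, 0.5))) + 1)
  m <- rbind(X, target)
  rownames(m) <- c("a", "b", "c", "t")
  colnames(m) <- paste0("s", 1:20)
  errs <- vapply(1:25, function(k) {
    trainGeneRegressor(GeneExpression(m), "t",
                       bpControl(learningRate = 0.05, momentum = 0,
                                 maxCycles = k, errorTolerance = 1e-12,
                                 seed = 9))@finalError
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("the assembled weight matrix has the contracted structure", {
  ge <- simulateExpression(plantedGRN(5, 1.5, seed = 2), 30, seed = 3)
  wm <- trainNetwork(ge, bpControl(seed = 4, maxCycles = 50L))
  W <- weightValues(wm)
  expect_equal(dim(W), c(5L, 5L))
  expect_equal(unname(diag(W)), rep(0, 5))
  expect_equal(rownames(W), geneIds(ge))
  # two genes: exactly two free entries
  two <- exprFixture(rbind(c(0.1, 0.9, 0.4), c(0.8, 0.2, 0.6)))
  wm2 <- trainNetwork(two, bpControl(seed = 4, maxCycles = 10L))
  expect_equal(sum(weightValues(wm2) == 0), 2L)  # only the diagonal
})

test_that("training is deterministic and regressors share one init vector", {
  ge <- simulateExpression(plantedGRN(6, 1.5, seed = 2), 25, seed = 3)
  a <- trainNetwork(ge, bpControl(seed = 11, maxCycles = 30L))
  b <- trainNetwork(ge, bpControl(seed = 11, maxCycles = 30L))
  expect_identical(weightValues(a), weightValues(b))
  # the standalone regressor with the shared init reproduces its column
  init <- bpgrn:::drawInitWeights(5, bpControl(seed = 11, maxCycles = 30L))
  reg <- trainGeneRegressor(ge, geneIds(ge)[3],
                            bpControl(seed = 11, maxCycles = 30L),
                            initWeights = init)
  expect_equal(unname(weightValues(a)[-3, 3]), unname(reg@weights))
})

test_that("converged regressors satisfy the fixed-point reconstruction", {
  grn <- plantedGRN(10, 2, seed = 6)
  ge <- simulateExpression(grn, 80, seed = 7)
  wm <- trainNetwork(ge, bpControl(seed = 8))
  pred <- predictExpression(wm, ge, bias = bpControl()@bias)
  v <- exprValues(ge)
  perGeneE <- 0.25 * rowSums((v - pred)^2)
  expect_true(all(perGeneE[wm@converged] < bpControl()@errorTolerance))
})
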