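## Single-layer sigmoid perceptrons trained by online back-propagation with
## momentum; one regressor per gene, assembled into a weight matrix.

#' Logistic (sigmoid) transfer function
#'
#' `1 / (1 + exp(-x))`, the neuron transfer function mapping a weighted input
#' sum to (0, 1). Saturates at the extremes without overflow.
#'
#' @param x numeric vector.
#' @return numeric vector in (0, 1).
#' @examples
#' sigmoid(0)       # 0.5
#' sigmoid(2)       # ~0.8808
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Forward pass of a single neuron
#'
#' Computes `sigmoid(sum(weights * inputs) - bias)`: the weighted input sum
#' minus the neuron threshold, passed through the sigmoid.
#'
#' @param weights,inputs numeric vectors of equal length.
#' @param bias the neuron threshold.
#' @return the neuron output in (0, 1).
#' @examples
#' bpForward(c(0, 0), -1, c(0.3, 0.7))  # sigmoid(1)
#' @export
bpForward <- function(weights, bias, inputs) {
  if (length(weights) != length(inputs))
    stop("'weights' and 'inputs' must have the same length")
  sigmoid(sum(weights * inputs) - bias)
}

#' Squared-error of one training pattern
#'
#' Half the sum of squared differences between desired and actual outputs,
#' `E^p = 1/2 * sum((t - o)^2)`.
#'
#' @param target,output numeric vectors of equal length.
#' @return non-negative pattern error.
#' @examples
#' patternError(1, 0)          # 0.5
#' patternError(c(1, 0), c(0.5, 0.5))  # 0.25
#' @export
patternError <- function(target, output) {
  if (length(target) != length(output))
    stop("'target' and 'output' must have the same length")
  0.5 * sum((target - output)^2)
}

#' Whole training error over all patterns
#'
#' `E = 1/2 * sum_P E^P` with `E^P` the per-pattern error of
#' [patternError()]; the quantity the stopping rule `E < errorTolerance`
#' tests.
#'
#' @param weights,bias the neuron parameters.
#' @param inputs numeric matrix, one column per training pattern.
#' @param targets numeric vector of desired outputs, one per pattern.
#' @return the whole error E.
#' @export
wholeError <- function(weights, bias, inputs, targets) {
  o <- sigmoid(drop(crossprod(inputs, weights)) - bias)
  0.25 * sum((targets - o)^2)
}

#' Analytic gradient of the whole error
#'
#' Gradient of [wholeError()] with respect to each weight (and, as attribute
#' `"bias"`, the bias): `dE/dw_i = -1/2 * sum_P delta^P x_i^P` with
#' `delta^P = o(1-o)(t-o)`. The online update of [backpropStep()] moves along
#' the negative of the per-pattern term of this gradient; the batch sum is
#' what finite differences can verify.
#'
#' @inheritParams wholeError
#' @return numeric gradient vector, with attribute `"bias"`.
#' @export
bpGradient <- function(weights, bias, inputs, targets) {
  o <- sigmoid(drop(crossprod(inputs, weights)) - bias)
  delta <- o * (1 - o) * (targets - o)
  g <- -0.5 * drop(inputs %*% delta)
  attr(g, "bias") <- 0.5 * sum(delta)  # d(net)/d(bias) = -1
  g
}

#' One online back-propagation update
#'
#' Processes a single training pattern: forward pass, output-neuron error
#' term `delta = o * (1 - o) * (t - o)`, then the generalized delta rule with
#' momentum, `change_i = learningRate * delta * x_i + momentum *
#' prevChange_i`. Returns the updated weights together with the applied
#' change vector, which feeds the next step's momentum term.
#'
#' @param weights current weight vector.
#' @param bias current threshold.
#' @param input one training pattern (same length as `weights`).
#' @param target desired output for this pattern.
#' @param control a [BPControl-class].
#' @param prevChange the change vector applied at the previous step.
#' @param prevBiasChange previous bias change (used when `biasTrainable`).
#' @return list with elements `weights`, `change`, `bias`, `biasChange`,
#'   `output`, `delta`.
#' @examples
#' st <- backpropStep(c(0.2), 0, c(0.5), 1, bpControl(), prevChange = c(0))
#' st$weights
#' @export
backpropStep <- function(weights, bias, input, target, control = bpControl(),
                         prevChange = rep(0, length(weights)),
                         prevBiasChange = 0) {
  if (length(input) != length(weights))
    stop("'input' and 'weights' must have the same length")
  o <- sigmoid(sum(weights * input) - bias)
  delta <- o * (1 - o) * (target - o)
  change <- control@learningRate * delta * input +
    control@momentum * prevChange
  biasChange <- 0
  if (control@biasTrainable) {
    biasChange <- control@learningRate * delta * (-1) +
      control@momentum * prevBiasChange
    bias <- bias + biasChange
  }
  list(weights = weights + change, change = change,
       bias = bias, biasChange = biasChange, output = o, delta = delta)
}

## Deterministic initial weights shared by all regressors of one run.
drawInitWeights <- function(n, control) {
  set.seed(control@seed)
  stats::runif(n, -control@initScale, control@initScale)
}

## Tight inner training loop (same arithmetic as backpropStep, inlined).
trainLoop <- function(X, targets, w, bias, control) {
  P <- ncol(X)
  lr <- control@learningRate
  mom <- control@momentum
  trainBias <- control@biasTrainable
  change <- rep(0, length(w))
  bchange <- 0
  E <- Inf
  cycles <- 0L
  for (cycle in seq_len(control@maxCycles)) {
    for (p in seq_len(P)) {
      xp <- X[, p]
      o <- 1 / (1 + exp(-(sum(w * xp) - bias)))
      delta <- o * (1 - o) * (targets[p] - o)
      change <- lr * delta * xp + mom * change
      w <- w + change
      if (trainBias) {
        bchange <- -lr * delta + mom * bchange
        bias <- bias + bchange
      }
    }
    cycles <- cycle
    E <- wholeError(w, bias, X, targets)
    if (E < control@errorTolerance) break
  }
  list(weights = w, bias = bias, finalError = E, cyclesRun = cycles,
       converged = E < control@errorTolerance)
}

#' Train the regressor predicting one gene from all others
#'
#' Fits a single-layer sigmoid perceptron whose inputs are the other n-1
#' genes' values and whose desired output is the target gene's value, by
#' iterating online back-propagation over all samples in stable column order.
#' Training stops once the whole error E drops below
#' `control@errorTolerance` or after `control@maxCycles` cycles.
#'
#' @param x a [GeneExpression-class] object or genes x samples matrix,
#'   expected on the [0, 1] scale (see [normalizeExpression()]).
#' @param targetGene the gene ID to predict.
#' @param control a [BPControl-class].
#' @param initWeights optional initial weight vector (length n-1); by default
#'   drawn uniformly from `[-initScale, initScale]` under `control@seed`.
#' @return a [GeneRegressor-class].
#' @examples
#' ge <- simulateExpression(plantedGRN(5, 1.5, seed = 1), 40, seed = 2)
#' trainGeneRegressor(ge, "g3", bpControl(seed = 3, maxCycles = 50))
#' @export
trainGeneRegressor <- function(x, targetGene, control = bpControl(),
                               initWeights = NULL) {
  v <- exprValues(x)
  if (nrow(v) < 2L) stop("need at least 2 genes")
  if (ncol(v) < 1L) stop("need at least 1 sample")
  genes <- rownames(v)
  if (!(targetGene %in% genes))
    stop("target gene '", targetGene, "' not in the matrix")
  tidx <- match(targetGene, genes)
  X <- v[-tidx, , drop = FALSE]          # (n-1) x P inputs
  targets <- v[tidx, ]
  if (is.null(initWeights)) initWeights <- drawInitWeights(nrow(X), control)
  if (length(initWeights) != nrow(X))
    stop("'initWeights' must have length n-1")
  fit <- trainLoop(X, targets, initWeights, control@bias, control)
  names(fit$weights) <- genes[-tidx]
  new("GeneRegressor", targetGene = targetGene, weights = fit$weights,
      bias = fit$bias, finalError = fit$finalError,
      cyclesRun = fit$cyclesRun, converged = fit$converged)
}

#' Train one regressor per gene and assemble the weight matrix
#'
#' Repeats [trainGeneRegressor()] for every gene. All regressors start from
#' the identical initial weight vector (drawn once from `control@seed`) so
#' the per-gene fits are comparable, and sample order is never shuffled, so
#' the result is fully deterministic given data and control. Column j of the
#' result holds the trained weights of the regressor for gene j; the
#' diagonal is identically zero.
#'
#' @inheritParams trainGeneRegressor
#' @return a [WeightMatrix-class] with per-gene error/convergence records.
#' @examples
#' ge <- simulateExpression(plantedGRN(5, 1.5, seed = 1), 40, seed = 2)
#' trainNetwork(ge, bpControl(seed = 3, maxCycles = 50))
#' @export
trainNetwork <- function(x, control = bpControl()) {
  v <- exprValues(x)
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 genes")
  genes <- rownames(v)
  init <- drawInitWeights(n - 1L, control)
  W <- matrix(0, n, n, dimnames = list(genes, genes))
  finalErrors <- numeric(n)
  cyclesRun <- integer(n)
  converged <- logical(n)
  names(finalErrors) <- names(cyclesRun) <- names(converged) <- genes
  for (j in seq_len(n)) {
    reg <- trainGeneRegressor(v, genes[j], control, initWeights = init)
    W[-j, j] <- reg@weights
    finalErrors[j] <- reg@finalError
    cyclesRun[j] <- reg@cyclesRun
    converged[j] <- reg@converged
  }
  WeightMatrix(W, finalErrors = finalErrors, cyclesRun = cyclesRun,
               converged = converged, control = control)
}

#' Reconstruct expression from a trained weight matrix
#'
#' Evaluates the fitted fixed-point relation: each gene's predicted value is
#' the sigmoid of the weighted sum of the other genes' observed values minus
#' the bias, i.e. `F(t(W) %*% x - bias)` column by column. When training
#' converged, the prediction reproduces the observed values up to the
#' training tolerance.
#'
#' @param W a [WeightMatrix-class] or plain zero-diagonal matrix.
#' @param x a [GeneExpression-class] object or genes x samples matrix.
#' @param bias the neuron threshold used in training.
#' @return a genes x samples matrix of predicted values.
#' @export
predictExpression <- function(W, x, bias = -1) {
  Wm <- if (is(W, "WeightMatrix")) weightValues(W) else W
  v <- exprValues(x)
  if (!identical(rownames(Wm), rownames(v)))
    stop("gene sets of weight matrix and expression matrix differ")
  sigmoid(crossprod(Wm, v) - bias)
}
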