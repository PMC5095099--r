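#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#' @importFrom S4Vectors metadata SimpleList
NULL

## ---------------------------------------------------------------------------
## GeneExpression: a genes x samples expression matrix
## ---------------------------------------------------------------------------

#' GeneExpression: a genes-by-samples expression matrix
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single numeric assay `"exprs"` with genes as rows and samples as columns,
#' plus an optional condition-group label. Validity enforces unique,
#' non-empty gene and sample identifiers and finite values, the contract all
#' downstream training and statistics code relies on.
#'
#' @slot group a length-one character label for the condition group the
#'   samples belong to (e.g. a temperature group), or `NA`.
#' @export
setClass("GeneExpression",
  contains = "SummarizedExperiment",
  slots = c(group = "character"),
  prototype = prototype(group = NA_character_)
)

setValidity("GeneExpression", function(object) {
  msg <- character()
  if (length(object@group) != 1L)
    msg <- c(msg, "'group' must be a single character label (or NA)")
  if (!("exprs" %in% names(assays(object))))
    msg <- c(msg, "assay 'exprs' is missing")
  else {
    v <- assay(object, "exprs")
    if (!is.numeric(v))
      msg <- c(msg, "assay 'exprs' must be numeric")
    else if (length(v) && !all(is.finite(v)))
      msg <- c(msg, "assay 'exprs' contains non-finite values")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)) ||
        any(!nzchar(rownames(v))))
      msg <- c(msg, "gene IDs (rownames) must be unique and non-empty")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)) ||
        any(!nzchar(colnames(v))))
      msg <- c(msg, "sample IDs (colnames) must be unique and non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneExpression object
#'
#' @param values numeric matrix, genes in rows and samples in columns.
#' @param geneIds,sampleIds character vectors of unique identifiers; default
#'   to the dimnames of `values`.
#' @param group optional condition-group label.
#' @return a [GeneExpression-class] object.
#' @examples
#' m <- matrix(runif(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' GeneExpression(m, group = "T12")
#' @export
GeneExpression <- function(values, geneIds = rownames(values),
                           sampleIds = colnames(values),
                           group = NA_character_) {
  if (!is.matrix(values) || length(values) == 0L)
    stop("'values' must be a non-empty matrix")
  force(geneIds); force(sampleIds)
  if (is.null(geneIds) || is.null(sampleIds))
    stop("gene and sample IDs are required")
  values <- matrix(as.numeric(values), nrow(values), ncol(values))
  rownames(values) <- as.character(geneIds)
  colnames(values) <- as.character(sampleIds)
  se <- SummarizedExperiment(assays = SimpleList(exprs = values))
  new("GeneExpression", se, group = as.character(group)[1L])
}

## ---------------------------------------------------------------------------
## BPControl: training hyper-parameters
## ---------------------------------------------------------------------------

#' Training hyper-parameters for the per-gene BP perceptrons
#'
#' @slot learningRate step-size of the gradient update, in (0,1).
#' @slot momentum fraction of the previous weight change carried into the
#'   current update, in (0,1).
#' @slot bias the neuron threshold subtracted from the weighted input sum;
#'   fixed (not trained) unless `biasTrainable`.
#' @slot maxCycles maximum number of passes over the training samples.
#' @slot errorTolerance stop training once the whole error E drops below this.
#' @slot initScale half-width of the uniform interval the initial weights are
#'   drawn from.
#' @slot seed integer seed all initialisation randomness derives from.
#' @slot biasTrainable logical; if `TRUE` the threshold is updated like a
#'   weight on a constant input of -1.
#' @export
setClass("BPControl",
  slots = c(
    learningRate  = "numeric",
    momentum      = "numeric",
    bias          = "numeric",
    maxCycles     = "integer",
    errorTolerance = "numeric",
    initScale     = "numeric",
    seed          = "integer",
    biasTrainable = "logical"
  )
)

setValidity("BPControl", function(object) {
  msg <- character()
  if (!(length(object@learningRate) == 1L &&
        object@learningRate > 0 && object@learningRate < 1))
    msg <- c(msg, "'learningRate' must be in (0, 1)")
  if (!(length(object@momentum) == 1L &&
        object@momentum >= 0 && object@momentum < 1))
    msg <- c(msg, "'momentum' must be in [0, 1)")
  if (!(length(object@maxCycles) == 1L && object@maxCycles >= 1L))
    msg <- c(msg, "'maxCycles' must be a positive integer")
  if (!(length(object@errorTolerance) == 1L && object@errorTolerance > 0))
    msg <- c(msg, "'errorTolerance' must be positive")
  if (!(length(object@initScale) == 1L && object@initScale > 0))
    msg <- c(msg, "'initScale' must be positive")
  if (length(msg)) msg else TRUE
})

#' Create a BPControl object
#'
#' Defaults follow the study configuration: learning rate 0.7, fixed
#' threshold -1, stopping at whole error E < 1e-2 or 1000 cycles.
#' Momentum (0.5) and the initialisation scale (0.1, i.e. "small random
#' values") are not pinned down by that configuration and are exposed here.
#'
#' @param learningRate,momentum,bias,maxCycles,errorTolerance,initScale,seed,biasTrainable
#'   see the slot documentation in [BPControl-class].
#' @return a validated [BPControl-class] object.
#' @examples
#' bpControl(learningRate = 0.7, seed = 42)
#' @export
bpControl <- function(learningRate = 0.7, momentum = 0.5, bias = -1,
                      maxCycles = 1000L, errorTolerance = 1e-2,
                      initScale = 0.1, seed = 1L, biasTrainable = FALSE) {
  new("BPControl",
      learningRate = as.numeric(learningRate),
      momentum = as.numeric(momentum),
      bias = as.numeric(bias),
      maxCycles = as.integer(maxCycles),
      errorTolerance = as.numeric(errorTolerance),
      initScale = as.numeric(initScale),
      seed = as.integer(seed),
      biasTrainable = isTRUE(biasTrainable))
}

## ---------------------------------------------------------------------------
## GeneRegressor: one trained perceptron
## ---------------------------------------------------------------------------

#' A trained single-gene regressor
#'
#' The perceptron predicting one target gene from the other n-1 genes. The
#' weight vector is named by input gene and never contains an entry for the
#' target itself (no self-regulation).
#'
#' @slot targetGene the gene this perceptron predicts.
#' @slot weights named numeric vector of trained input weights.
#' @slot bias the (possibly trained) threshold.
#' @slot finalError the whole error E at the last cycle.
#' @slot cyclesRun number of training cycles executed.
#' @slot converged `TRUE` if E dropped below the tolerance before the cycle
#'   cap.
#' @export
setClass("GeneRegressor",
  slots = c(
    targetGene = "character",
    weights    = "numeric",
    bias       = "numeric",
    finalError = "numeric",
    cyclesRun  = "integer",
    converged  = "logical"
  )
)

setValidity("GeneRegressor", function(object) {
  msg <- character()
  if (is.null(names(object@weights)))
    msg <- c(msg, "'weights' must be named by input gene")
  if (object@targetGene %in% names(object@weights))
    msg <- c(msg, "no self-regulation: target gene cannot be an input")
  if (length(object@finalError) == 1L && is.finite(object@finalError) &&
      object@finalError < 0)
    msg <- c(msg, "'finalError' must be non-negative")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## WeightMatrix: the assembled n x n trained weights
## ---------------------------------------------------------------------------

#' The assembled gene-gene weight matrix
#'
#' Entry `W[i, j]` is the trained weight of input gene i in the regressor
#' predicting gene j, i.e. the candidate regulatory edge i -> j. The diagonal
#' is identically zero (self-regulation is excluded by construction).
#'
#' @slot W numeric n x n matrix with identical row/column gene IDs.
#' @slot finalErrors per-target-gene whole error at end of training.
#' @slot cyclesRun per-target-gene cycles executed.
#' @slot converged per-target-gene convergence flags.
#' @slot control the [BPControl-class] used, or `NULL` when the matrix was
#'   built directly from numbers.
#' @export
setClass("WeightMatrix",
  slots = c(
    W           = "matrix",
    finalErrors = "numeric",
    cyclesRun   = "integer",
    converged   = "logical",
    control     = "ANY"
  )
)

setValidity("WeightMatrix", function(object) {
  msg <- character()
  W <- object@W
  if (nrow(W) != ncol(W))
    msg <- c(msg, "weight matrix must be square")
  if (is.null(rownames(W)) || is.null(colnames(W)) ||
      !identical(rownames(W), colnames(W)))
    msg <- c(msg, "row and column gene IDs must be identical")
  else if (anyDuplicated(rownames(W)))
    msg <- c(msg, "gene IDs must be unique")
  if (length(W) && any(diag(W) != 0))
    msg <- c(msg, "diagonal must be identically zero (no self-regulation)")
  if (length(W) && !all(is.finite(W)))
    msg <- c(msg, "weights must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a WeightMatrix from a plain matrix
#'
#' @param W square numeric matrix with identical row/column gene IDs and a
#'   zero diagonal.
#' @param finalErrors,cyclesRun,converged optional per-gene training records.
#' @param control optional [BPControl-class].
#' @return a [WeightMatrix-class] object.
#' @export
WeightMatrix <- function(W, finalErrors = numeric(), cyclesRun = integer(),
                         converged = logical(), control = NULL) {
  new("WeightMatrix", W = W, finalErrors = finalErrors,
      cyclesRun = as.integer(cyclesRun), converged = converged,
      control = control)
}

## ---------------------------------------------------------------------------
## RegulatoryNetwork
## ---------------------------------------------------------------------------

#' A signed directed regulatory network
#'
#' Produced by thresholding a weight matrix by incoming weight ratio, or by
#' thresholding a correlation matrix (the relevance baseline, in which case
#' edges come in symmetric pairs). Edges carry the raw weight, the weight
#' ratio in [0,1] and a sign (`"activation"` for positive weight,
#' `"inhibition"` for negative).
#'
#' @slot geneIds the node set (isolated genes remain nodes).
#' @slot edges data.frame with columns `source`, `target`, `weight`, `ratio`,
#'   `sign`.
#' @slot threshold the retention threshold the network was built at.
#' @slot method `"bp"` or `"pearson"`.
#' @export
setClass("RegulatoryNetwork",
  slots = c(
    geneIds   = "character",
    edges     = "data.frame",
    threshold = "numeric",
    method    = "character"
  )
)

setValidity("RegulatoryNetwork", function(object) {
  msg <- character()
  e <- object@edges
  need <- c("source", "target", "weight", "ratio", "sign")
  if (!all(need %in% names(e)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "gene IDs must be unique")
  if (nrow(e)) {
    if (any(e$source == e$target))
      msg <- c(msg, "self-loops are not allowed")
    if (!all(e$source %in% object@geneIds) ||
        !all(e$target %in% object@geneIds))
      msg <- c(msg, "edge endpoints must be in the gene set")
    if (any(e$ratio < 0 | e$ratio > 1))
      msg <- c(msg, "edge ratios must lie in [0, 1]")
    wrong <- ifelse(e$weight > 0, "activation", "inhibition") != e$sign
    if (any(wrong))
      msg <- c(msg, "sign must be 'activation' iff weight > 0")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## NetworkStats
## ---------------------------------------------------------------------------

#' The five topology statistics of one network
#'
#' Average path length `L`, average clustering coefficient `C`, average
#' degree `K`, modularity `Q` and graph density `D`, all computed on the
#' undirected projection of the network. Statistics that are undefined for a
#' degenerate network (e.g. `L` and `Q` on an edgeless graph) are `NA` with
#' the reason recorded.
#'
#' @slot L,C,K,Q,D the statistics (possibly `NA`).
#' @slot nNodes,nEdges node count and directed stored-edge count.
#' @slot threshold the threshold the network was built at.
#' @slot method `"bp"` or `"pearson"`.
#' @slot reasons named character vector explaining any `NA` statistic.
#' @export
setClass("NetworkStats",
  slots = c(
    L = "numeric", C = "numeric", K = "numeric", Q = "numeric", D = "numeric",
    nNodes = "integer", nEdges = "integer",
    threshold = "numeric", method = "character", reasons = "character"
  )
)

## ---------------------------------------------------------------------------
## CorrelationMatrix
## ---------------------------------------------------------------------------

#' Pairwise Pearson correlations between genes
#'
#' @slot r symmetric n x n correlation matrix; entries are `NA` where the
#'   correlation is undefined (a zero-variance gene).
#' @slot undefinedPairs data.frame (`gene1`, `gene2`) of undefined pairs.
#' @export
setClass("CorrelationMatrix",
  slots = c(r = "matrix", undefinedPairs = "data.frame")
)

setValidity("CorrelationMatrix", function(object) {
  r <- object@r
  msg <- character()
  if (nrow(r) != ncol(r) || !identical(rownames(r), colnames(r)))
    msg <- c(msg, "correlation matrix must be square with matching gene IDs")
  ok <- !is.na(r)
  if (any(abs(r[ok]) > 1 + 1e-12))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (!isTRUE(all.equal(r[ok], t(r)[ok], tolerance = 1e-12,
                        check.attributes = FALSE)))
    msg <- c(msg, "correlation matrix must be symmetric")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## PlantedGRN
## ---------------------------------------------------------------------------

#' A planted (ground-truth) regulatory structure
#'
#' The generative counterpart of the fitted model: every regulated gene's
#' expression is the sigmoid of a linear combination of its regulators minus
#' the bias. Genes are ordered so that regulators always precede their
#' targets (a DAG); genes with no regulators are exogenous drivers.
#'
#' @slot weights n x n true weight matrix, `weights[i, j]` the influence of
#'   gene i on gene j; zero diagonal.
#' @slot bias the threshold used in the generative sigmoid.
#' @export
setClass("PlantedGRN",
  slots = c(weights = "matrix", bias = "numeric")
)

setValidity("PlantedGRN", function(object) {
  W <- object@weights
  msg <- character()
  if (nrow(W) != ncol(W) || !identical(rownames(W), colnames(W)))
    msg <- c(msg, "'weights' must be square with matching gene IDs")
  if (length(W) && any(diag(W) != 0))
    msg <- c(msg, "diagonal must be zero")
  if (length(W) && any(W[lower.tri(W)] != 0))
    msg <- c(msg, "'weights' must be strictly upper-triangular (DAG order)")
  if (length(msg)) msg else TRUE
})
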