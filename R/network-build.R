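## Mapping the trained weight matrix to a signed directed network through the
## incoming weight-ratio threshold lambda.

#' Incoming weight-ratio matrix
#'
#' For each candidate edge i -> j the ratio `|W[i,j]| / sum_k |W[k,j]|`, the
#' share of target j's total absolute incoming weight contributed by source
#' i. Each column with any nonzero incoming weight sums to 1; columns with no
#' incoming weight are all zero.
#'
#' @param W a [WeightMatrix-class] or plain zero-diagonal square matrix.
#' @return n x n numeric ratio matrix with zero diagonal.
#' @examples
#' W <- matrix(0, 4, 4, dimnames = rep(list(paste0("g", 1:4)), 2))
#' W[2:4, 1] <- c(0.3, -0.1, 0.1)   # g2,g3,g4 -> g1
#' weightRatioMatrix(W)[, "g1"]     # 0, 0.6, 0.2, 0.2
#' @export
weightRatioMatrix <- function(W) {
  Wm <- if (is(W, "WeightMatrix")) weightValues(W) else W
  if (any(diag(Wm) != 0)) stop("weight matrix must have a zero diagonal")
  a <- abs(Wm)
  colSum <- colSums(a)
  colSum[colSum == 0] <- 1  # all-zero columns stay all-zero
  sweep(a, 2L, colSum, "/")
}

#' Build a regulatory network at one weight-ratio threshold
#'
#' Retains the directed edge i -> j exactly when its weight is nonzero and
#' its incoming weight ratio is at least `threshold` (edges exactly at the
#' threshold are kept; only strictly smaller ratios are removed). Each edge
#' carries its raw weight, its ratio, and a sign: `"activation"` for positive
#' weight, `"inhibition"` for negative.
#'
#' @param W a [WeightMatrix-class] or plain zero-diagonal square matrix.
#' @param threshold weight-ratio retention threshold in [0, 1].
#' @param ratios optional precomputed [weightRatioMatrix()] of `W`.
#' @param method label recorded on the network (default `"bp"`).
#' @return a [RegulatoryNetwork-class].
#' @examples
#' grn <- plantedGRN(6, 1.5, seed = 1)
#' buildNetwork(weightValues(grn), threshold = 0.5)
#' @export
buildNetwork <- function(W, threshold, ratios = weightRatioMatrix(W),
                         method = "bp") {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop("'threshold' must be a single value in [0, 1]")
  Wm <- if (is(W, "WeightMatrix")) weightValues(W) else W
  if (!identical(dim(Wm), dim(ratios)))
    stop("weight and ratio matrices must be conformable")
  genes <- rownames(Wm)
  keep <- which(Wm != 0 & ratios >= threshold, arr.ind = TRUE)
  e <- data.frame(
    source = genes[keep[, 1L]],
    target = genes[keep[, 2L]],
    weight = Wm[keep],
    ratio  = ratios[keep],
    stringsAsFactors = FALSE)
  e$sign <- ifelse(e$weight > 0, "activation", "inhibition")
  e <- e[order(e$target, e$source), , drop = FALSE]
  rownames(e) <- NULL
  new("RegulatoryNetwork", geneIds = genes, edges = e,
      threshold = threshold, method = method)
}

#' Build networks over a grid of weight-ratio thresholds
#'
#' One network per threshold. The default grid is the ten ratios 0.50 to
#' 0.95 in steps of 0.05; since the retained edge set shrinks as the
#' threshold grows, the networks are nested.
#'
#' @inheritParams buildNetwork
#' @param thresholds numeric vector of thresholds in [0, 1].
#' @return named list of [RegulatoryNetwork-class] objects, names the
#'   thresholds.
#' @export
sweepThresholds <- function(W, thresholds = defaultThresholdGrid(),
                            method = "bp") {
  if (length(thresholds) == 0L) stop("'thresholds' must be non-empty")
  Wm <- if (is(W, "WeightMatrix")) weightValues(W) else W
  ratios <- weightRatioMatrix(Wm)
  nets <- lapply(thresholds, function(th)
    buildNetwork(Wm, th, ratios = ratios, method = method))
  names(nets) <- format(thresholds, trim = TRUE)
  nets
}

#' The default ten-threshold grid
#'
#' @return `c(0.5, 0.55, ..., 0.95)`.
#' @export
defaultThresholdGrid <- function() seq(0.5, 0.95, by = 0.05)

## Undirected simple igraph projection shared by all topology statistics.
asUndirectedGraph <- function(net) {
  stopifnot(is(net, "RegulatoryNetwork"))
  g <- igraph::graph_from_data_frame(
    net@edges[, c("source", "target"), drop = FALSE],
    directed = TRUE,
    vertices = data.frame(name = net@geneIds, stringsAsFactors = FALSE))
  igraph::as_undirected(g, mode = "collapse")
}

#' Convert a regulatory network to an igraph object
#'
#' The directed graph with edge attributes `weight`, `ratio` and `sign`,
#' suitable for igraph analysis or GraphML export.
#'
#' @param net a [RegulatoryNetwork-class].
#' @return an igraph graph.
#' @export
asIgraph <- function(net) {
  stopifnot(is(net, "RegulatoryNetwork"))
  igraph::graph_from_data_frame(
    net@edges, directed = TRUE,
    vertices = data.frame(name = net@geneIds, stringsAsFactors = FALSE))
}

#' Directed in/out degree table of a network
#'
#' @param net a [RegulatoryNetwork-class].
#' @return data.frame with columns `gene`, `in_degree`, `out_degree`, one row
#'   per gene in `geneIds(net)` order.
#' @export
degreeTable <- function(net) {
  stopifnot(is(net, "RegulatoryNetwork"))
  e <- net@edges
  data.frame(
    gene = net@geneIds,
    in_degree = as.integer(table(factor(e$target, levels = net@geneIds))),
    out_degree = as.integer(table(factor(e$source, levels = net@geneIds))),
    stringsAsFactors = FALSE)
}
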