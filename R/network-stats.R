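## The five structural parameters L, C, K, Q, D, all computed on the
## undirected projection of the (directed) regulatory network, plus the
## cross-condition comparison table.

#' Average shortest-path length
#'
#' Mean shortest-path distance over all connected (mutually reachable)
#' unordered node pairs of the undirected projection. Pairs in different
#' components do not enter the average, so a network whose components are
#' single edges has L = 1.
#'
#' @param net a [RegulatoryNetwork-class].
#' @return the average path length (>= 1 when defined).
#' @export
averagePathLength <- function(net) {
  g <- asUndirectedGraph(net)
  if (igraph::ecount(g) == 0L)
    stop("average path length is undefined for an edgeless network")
  igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
}

#' Average clustering coefficient
#'
#' Per node, the fraction of possible edges among its neighbours (on the
#' undirected projection) that actually exist; nodes with fewer than two
#' neighbours contribute 0. The network statistic is the mean over all
#' nodes.
#'
#' @param net a [RegulatoryNetwork-class].
#' @return average clustering coefficient in [0, 1].
#' @export
clusteringCoefficient <- function(net) {
  g <- asUndirectedGraph(net)
  if (igraph::vcount(g) == 0L) return(0)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Average degree
#'
#' Mean over nodes of the number of distinct other nodes adjacent on the
#' undirected projection.
#'
#' @param net a [RegulatoryNetwork-class].
#' @return average degree K >= 0.
#' @export
averageDegree <- function(net) {
  g <- asUndirectedGraph(net)
  if (igraph::vcount(g) == 0L) return(0)
  mean(igraph::degree(g))
}

#' Graph density
#'
#' The ratio of existing undirected edges to the maximum possible,
#' equivalently `K / (n - 1)` with K the average degree; in [0, 1].
#'
#' @param net a [RegulatoryNetwork-class] with at least two nodes.
#' @return graph density D.
#' @export
graphDensity <- function(net) {
  n <- length(net@geneIds)
  if (n < 2L) stop("density is undefined for fewer than 2 nodes")
  averageDegree(net) / (n - 1)
}

#' Detect communities by greedy modularity maximisation
#'
#' Louvain-style multi-level modularity optimisation on the undirected
#' projection. Deterministic given `seed` (the seed is set immediately before
#' the optimisation).
#'
#' @param net a [RegulatoryNetwork-class] with at least one edge.
#' @param seed integer seed.
#' @return named integer vector mapping each gene to a community index in
#'   `1..k`.
#' @export
detectCommunities <- function(net, seed = 1L) {
  g <- asUndirectedGraph(net)
  if (igraph::ecount(g) == 0L)
    stop("community detection is undefined for an edgeless network")
  set.seed(as.integer(seed))
  cl <- igraph::cluster_louvain(g)
  mem <- igraph::membership(cl)
  out <- as.integer(mem)
  names(out) <- names(mem)
  # contiguous 1..k in order of first appearance
  out <- match(out, unique(out))
  names(out) <- names(mem)
  out[net@geneIds]
}

#' Modularity of a community partition
#'
#' The Newman-Girvan score `Q = sum_i (h_ii - alpha_i^2)` where `h_ii` is the
#' fraction of edges inside community i and `alpha_i` the fraction of edge
#' ends attached to community i, computed on the undirected projection.
#'
#' @param net a [RegulatoryNetwork-class] with at least one edge.
#' @param partition named integer vector covering every gene (as returned by
#'   [detectCommunities()]).
#' @return modularity Q.
#' @export
modularityScore <- function(net, partition) {
  g <- asUndirectedGraph(net)
  if (igraph::ecount(g) == 0L)
    stop("modularity is undefined for an edgeless network")
  if (!all(net@geneIds %in% names(partition)))
    stop("partition must cover every gene in the network")
  igraph::modularity(g, membership = partition[igraph::V(g)$name])
}

#' Compute the full statistics bundle for one network
#'
#' Bundles L, C, K, Q (on the partition found by [detectCommunities()]) and
#' D together with node/edge counts. Statistics that are undefined for the
#' given network (L and Q on an edgeless graph, D on a single node) are
#' reported as `NA` with the reason recorded in the `reasons` slot instead of
#' failing.
#'
#' @param net a [RegulatoryNetwork-class].
#' @param seed integer seed for the community detection.
#' @return a [NetworkStats-class] object.
#' @examples
#' tri <- cliqueNetwork(c("a", "b", "c"))
#' networkStats(tri)  # L=1 C=1 K=2 Q=0 D=1
#' @export
networkStats <- function(net, seed = 1L) {
  reasons <- character()
  grab <- function(what, fn) {
    tryCatch(fn(), error = function(e) {
      reasons[[what]] <<- conditionMessage(e)
      NA_real_
    })
  }
  L <- grab("L", function() averagePathLength(net))
  C <- grab("C", function() clusteringCoefficient(net))
  K <- grab("K", function() averageDegree(net))
  Q <- grab("Q", function() modularityScore(net, detectCommunities(net, seed)))
  D <- grab("D", function() graphDensity(net))
  do.call(new, list(Class = "NetworkStats", L = L, C = C, K = K, Q = Q,
                    D = D, nNodes = length(net@geneIds),
                    nEdges = nrow(net@edges), threshold = net@threshold,
                    method = net@method, reasons = reasons))
}

#' Statistics table over a list of networks
#'
#' @param nets a (typically named) list of [RegulatoryNetwork-class] objects,
#'   e.g. from [sweepThresholds()].
#' @param seed integer seed passed to [networkStats()].
#' @return data.frame with one row per network (columns threshold, L, C, K,
#'   Q, D, n_nodes, n_edges, method).
#' @export
statsTable <- function(nets, seed = 1L) {
  rows <- lapply(nets, function(nw) as.data.frame(networkStats(nw, seed)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare network statistics across conditions
#'
#' Given one statistics table per condition over the same threshold grid,
#' emits per threshold and per parameter the difference of each non-reference
#' condition to the reference (condition minus reference).
#'
#' @param statsList named list of data.frames from [statsTable()], one per
#'   condition, all over the identical threshold grid.
#' @param reference name of the reference condition in `statsList`.
#' @return data.frame with columns `threshold`, `parameter`, `comparison`,
#'   `condition_value`, `reference_value`, `difference`.
#' @export
compareStats <- function(statsList, reference) {
  if (!(reference %in% names(statsList)))
    stop("'reference' must name an element of 'statsList'")
  ref <- statsList[[reference]]
  params <- c("L", "C", "K", "Q", "D")
  others <- setdiff(names(statsList), reference)
  out <- list()
  for (cond in others) {
    tab <- statsList[[cond]]
    if (!isTRUE(all.equal(tab$threshold, ref$threshold)))
      stop("condition '", cond, "' uses a different threshold grid ",
           "than the reference")
    for (p in params) {
      out[[length(out) + 1L]] <- data.frame(
        threshold = tab$threshold,
        parameter = p,
        comparison = paste0(cond, "-", reference),
        condition_value = tab[[p]],
        reference_value = ref[[p]],
        difference = tab[[p]] - ref[[p]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Small closed-form network: a clique
#'
#' Convenience constructor of the complete network on the given genes (each
#' unordered pair connected by one directed edge of weight 1), mainly for
#' examples and sanity checks of the statistics.
#'
#' @param genes character vector of at least two gene IDs.
#' @return a [RegulatoryNetwork-class].
#' @export
cliqueNetwork <- function(genes = c("a", "b", "c")) {
  stopifnot(length(genes) >= 2L)
  pairs <- utils::combn(genes, 2L)
  e <- data.frame(source = pairs[1L, ], target = pairs[2L, ],
                  weight = 1, ratio = 1, sign = "activation",
                  stringsAsFactors = FALSE)
  new("RegulatoryNetwork", geneIds = genes, edges = e,
      threshold = 0, method = "bp")
}
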