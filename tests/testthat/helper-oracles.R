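# Independent brute-force oracles for the graph statistics and the BP
# gradient, deliberately written without igraph so they cross-check the
# implementation by a different route.

# symmetric logical adjacency matrix of a random undirected graph
randomAdjacency <- function(n, p) {
  a <- matrix(FALSE, n, n)
  a[upper.tri(a)] <- stats::runif(n * (n - 1) / 2) < p
  a | t(a)
}

# a RegulatoryNetwork whose undirected projection is the given adjacency
adjacencyToNetwork <- function(adj, genes = sprintf("n%02d", seq_len(nrow(adj)))) {
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  m <- nrow(idx)
  e <- data.frame(source = genes[idx[, 1L]], target = genes[idx[, 2L]],
                  weight = rep(1, m), ratio = rep(1, m),
                  sign = rep("activation", m), stringsAsFactors = FALSE)
  new("RegulatoryNetwork", geneIds = genes, edges = e,
      threshold = 0, method = "bp")
}

# all-pairs shortest paths by BFS from each node; Inf when unreachable
bfsAllDistances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    depth <- 0L
    seen <- rep(FALSE, n)
    seen[s] <- TRUE
    while (length(frontier)) {
      depth <- depth + 1L
      nxt <- integer()
      for (v in frontier) {
        nb <- which(adj[v, ] & !seen)
        d[s, nb] <- depth
        seen[nb] <- TRUE
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
  }
  d
}

oraclePathLength <- function(adj) {
  d <- bfsAllDistances(adj)
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals) & vals > 0]
  if (!length(vals)) NA_real_ else mean(vals)
}

oracleClustering <- function(adj) {
  n <- nrow(adj)
  ci <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ])
    if (length(nb) < 2L) return(0)
    pairs <- utils::combn(nb, 2L)
    mean(adj[cbind(pairs[1L, ], pairs[2L, ])])
  }, numeric(1))
  mean(ci)
}

oracleDegree <- function(adj) mean(rowSums(adj))

oracleDensity <- function(adj) {
  n <- nrow(adj)
  (sum(adj) / 2) / (n * (n - 1) / 2)
}

# Newman-Girvan modularity from first principles (degree-fraction form)
oracleModularity <- function(adj, membership) {
  m <- sum(adj) / 2
  if (m == 0) return(NA_real_)
  q <- 0
  for (s in unique(membership)) {
    inS <- membership == s
    mS <- sum(adj[inS, inS, drop = FALSE]) / 2
    dS <- sum(rowSums(adj)[inS])
    q <- q + mS / m - (dS / (2 * m))^2
  }
  q
}

# every partition of n items (restricted growth strings); n <= 8 only
allPartitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxUsed) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (b in seq_len(maxUsed + 1L))
      rec(c(prefix, b), max(maxUsed, b))
  }
  rec(integer(), 0L)
  out
}

# central finite difference of the whole training error
finiteDiffGradient <- function(weights, bias, inputs, targets, h = 1e-5) {
  g <- vapply(seq_along(weights), function(i) {
    wp <- weights; wp[i] <- wp[i] + h
    wm <- weights; wm[i] <- wm[i] - h
    (wholeError(wp, bias, inputs, targets) -
       wholeError(wm, bias, inputs, targets)) / (2 * h)
  }, numeric(1))
  attr(g, "bias") <- (wholeError(weights, bias + h, inputs, targets) -
                        wholeError(weights, bias - h, inputs, targets)) / (2 * h)
  g
}

# directed network from explicit source-target pairs (weight 1 unless given)
netFromPairs <- function(pairs, genes, weights = rep(1, nrow(pairs))) {
  e <- data.frame(source = as.character(pairs[, 1L]),
                  target = as.character(pairs[, 2L]),
                  weight = as.numeric(weights),
                  ratio = rep(1, length(weights)),
                  sign = ifelse(weights > 0, "activation", "inhibition"),
                  stringsAsFactors = FALSE)
  new("RegulatoryNetwork", geneIds = genes, edges = e,
      threshold = 0, method = "bp")
}

# small expression fixture with named genes/samples
exprFixture <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  GeneExpression(m)
}
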