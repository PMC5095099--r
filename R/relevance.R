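## The comparison baseline: Pearson relevance network with a correlation
## threshold, plus the zero-degree census.

#' Pairwise Pearson correlation matrix between genes
#'
#' Correlates every gene pair across samples. Pairs involving a
#' zero-variance (constant) gene have no defined correlation; they are
#' recorded in `undefinedPairs` and stored as `NA`, and never become edges.
#'
#' @param x a [GeneExpression-class] object or genes x samples matrix with at
#'   least two samples.
#' @return a [CorrelationMatrix-class].
#' @export
pearsonCorrelationMatrix <- function(x) {
  v <- exprValues(x)
  if (ncol(v) < 2L) stop("need at least 2 samples to correlate")
  r <- suppressWarnings(stats::cor(t(v), method = "pearson"))
  und <- which(is.na(r) & upper.tri(r), arr.ind = TRUE)
  undefinedPairs <- data.frame(
    gene1 = rownames(r)[und[, 1L]],
    gene2 = rownames(r)[und[, 2L]],
    stringsAsFactors = FALSE)
  new("CorrelationMatrix", r = r, undefinedPairs = undefinedPairs)
}

#' Build the Pearson relevance network
#'
#' Connects two genes wherever the magnitude of their Pearson correlation
#' reaches `rThreshold` (default 0.85). The network is undirected, encoded
#' as symmetric pairs of directed edges so that the same topology statistics
#' and degree machinery apply unchanged; the sign follows the sign of r
#' (negative correlation = inhibition) and the stored ratio is `|r|`.
#' Undefined correlations never form edges.
#'
#' @param corr a [CorrelationMatrix-class], or a [GeneExpression-class] /
#'   matrix from which one is computed.
#' @param rThreshold correlation-magnitude threshold in [0, 1].
#' @return a [RegulatoryNetwork-class] with `method = "pearson"`.
#' @export
relevanceNetwork <- function(corr, rThreshold = 0.85) {
  if (!is.numeric(rThreshold) || length(rThreshold) != 1L ||
      is.na(rThreshold) || rThreshold < 0 || rThreshold > 1)
    stop("'rThreshold' must be a single value in [0, 1]")
  if (!is(corr, "CorrelationMatrix"))
    corr <- pearsonCorrelationMatrix(corr)
  r <- corr@r
  genes <- rownames(r)
  hit <- which(upper.tri(r) & !is.na(r) & abs(r) >= rThreshold,
               arr.ind = TRUE)
  e <- data.frame(
    source = c(genes[hit[, 1L]], genes[hit[, 2L]]),
    target = c(genes[hit[, 2L]], genes[hit[, 1L]]),
    weight = c(r[hit], r[hit]),
    ratio  = c(abs(r[hit]), abs(r[hit])),
    stringsAsFactors = FALSE)
  e$sign <- ifelse(e$weight > 0, "activation", "inhibition")
  e <- e[order(e$target, e$source), , drop = FALSE]
  rownames(e) <- NULL
  new("RegulatoryNetwork", geneIds = genes, edges = e,
      threshold = rThreshold, method = "pearson")
}

#' Count genes with no incident edge
#'
#' The census used to judge how much of the gene set a network leaves
#' unconnected.
#'
#' @param net a [RegulatoryNetwork-class].
#' @return integer count of isolated genes.
#' @export
zeroDegreeCount <- function(net) {
  touched <- unique(c(net@edges$source, net@edges$target))
  sum(!(net@geneIds %in% touched))
}
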