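## Differential-gene determination: the degree-difference-ratio statistic
## between two condition networks, the fold-change/z-test comparator, and the
## overlap report.

#' Degree difference ratio between two condition networks
#'
#' For one gene with directed degrees (inA, outA) in the first network and
#' (inB, outB) in the second,
#' `eta = (|inA - inB| + |outA - outB|) / ((inA + outA) + (inB + outB))`.
#' The statistic lies in [0, 1]: 0 means identical degrees, 1 maximal
#' change. A gene isolated in both networks (0/0) is defined to have eta = 0
#' (no evidence of change). All arguments are vectorised.
#'
#' @param inA,outA,inB,outB non-negative integer degrees.
#' @return numeric vector of eta values in [0, 1].
#' @examples
#' degreeDifferenceRatio(2, 1, 0, 0)  # 1
#' degreeDifferenceRatio(3, 1, 1, 1)  # 1/3
#' @export
degreeDifferenceRatio <- function(inA, outA, inB, outB) {
  d <- cbind(inA, outA, inB, outB)
  if (any(d < 0)) stop("degrees must be non-negative")
  if (any(d != round(d))) stop("degrees must be integers")
  num <- abs(d[, 1L] - d[, 3L]) + abs(d[, 2L] - d[, 4L])
  den <- d[, 1L] + d[, 2L] + d[, 3L] + d[, 4L]
  unname(ifelse(den == 0, 0, num / den))
}

#' Rank genes by degree difference ratio
#'
#' Computes each gene's directed in/out degrees in the two networks, the
#' degree-difference ratio eta, and ranks genes by descending eta with ties
#' broken by gene ID for determinism.
#'
#' @param netA,netB two [RegulatoryNetwork-class] objects over the same gene
#'   set (typically the same condition pair at one threshold).
#' @return data.frame with columns `gene`, `in_a`, `out_a`, `in_b`, `out_b`,
#'   `eta`, `rank`, ordered by rank.
#' @export
rankByEta <- function(netA, netB) {
  if (!setequal(netA@geneIds, netB@geneIds))
    stop("the two networks must share the same gene set")
  da <- degreeTable(netA)
  db <- degreeTable(netB)
  db <- db[match(da$gene, db$gene), , drop = FALSE]
  eta <- degreeDifferenceRatio(da$in_degree, da$out_degree,
                               db$in_degree, db$out_degree)
  out <- data.frame(
    gene = da$gene,
    in_a = da$in_degree, out_a = da$out_degree,
    in_b = db$in_degree, out_b = db$out_degree,
    eta = eta, stringsAsFactors = FALSE)
  out <- out[order(-out$eta, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select network-based differential genes from eta rankings
#'
#' Applies a cutoff policy to each ranking — either `etaMin` (keep genes
#' whose eta reaches the cutoff; genes with eta = 0, i.e. no degree change,
#' are never selected) or `topK` (keep the K highest-ranked genes) — then
#' combines the per-comparison selections by union (default) or
#' intersection.
#'
#' @param ranking1 data.frame from [rankByEta()].
#' @param ranking2 optional second ranking over the same gene universe (e.g.
#'   the second condition pair); omit for a single comparison.
#' @param etaMin minimum eta for selection (default 0: any degree change).
#' @param topK alternative policy: number of top-ranked genes to keep.
#' @param combine `"union"` or `"intersection"`.
#' @return character vector of selected gene IDs (sorted).
#' @export
selectNetworkDegs <- function(ranking1, ranking2 = NULL, etaMin = 0,
                              topK = NULL,
                              combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  rankings <- list(ranking1)
  if (!is.null(ranking2)) {
    if (!setequal(ranking1$gene, ranking2$gene))
      stop("rankings must cover the same gene universe")
    rankings <- c(rankings, list(ranking2))
  }
  pick <- function(rk) {
    if (!is.null(topK)) {
      if (topK > nrow(rk)) stop("'topK' exceeds the number of genes")
      rk$gene[rk$rank <= topK]
    } else {
      rk$gene[rk$eta >= etaMin & rk$eta > 0]
    }
  }
  sets <- lapply(rankings, pick)
  out <- Reduce(if (combine == "union") union else intersect, sets)
  sort(out)
}

#' Fold-change and z-test differential genes
#'
#' The conventional comparator: per gene, `log2FC = log2((meanB + pc) /
#' (meanA + pc))` with a fixed pseudocount guarding against zero means on
#' [0, 1]-scaled data, and a two-sample unpaired z statistic
#' `(meanB - meanA) / sqrt(sA^2/nA + sB^2/nB)` with a two-sided normal p
#' value. A gene is called differential when `|log2FC| >= fcThreshold`
#' (inclusive) and `p < pThreshold`.
#'
#' @param groupA,groupB [GeneExpression-class] objects or matrices over the
#'   same genes, each with at least two samples.
#' @param fcThreshold minimum absolute log2 fold change (default 0.05).
#' @param pThreshold p-value cutoff (default 0.05).
#' @param pseudocount added to both group means before the ratio (default
#'   1e-6).
#' @return data.frame with columns `gene`, `mean_a`, `mean_b`,
#'   `log2_fold_change`, `z_statistic`, `p_value`, `is_deg`.
#' @export
foldChangeZTest <- function(groupA, groupB, fcThreshold = 0.05,
                            pThreshold = 0.05, pseudocount = 1e-6) {
  va <- exprValues(groupA)
  vb <- exprValues(groupB)
  if (!identical(rownames(va), rownames(vb)))
    stop("both groups must contain the same genes in the same order")
  if (ncol(va) < 2L || ncol(vb) < 2L)
    stop("each group needs at least 2 samples")
  ma <- rowMeans(va); mb <- rowMeans(vb)
  sa2 <- apply(va, 1L, stats::var)
  sb2 <- apply(vb, 1L, stats::var)
  se <- sqrt(sa2 / ncol(va) + sb2 / ncol(vb))
  z <- ifelse(se > 0, (mb - ma) / se,
              ifelse(mb == ma, 0, sign(mb - ma) * Inf))
  p <- 2 * stats::pnorm(-abs(z))
  l2fc <- log2((mb + pseudocount) / (ma + pseudocount))
  data.frame(
    gene = rownames(va), mean_a = ma, mean_b = mb,
    log2_fold_change = l2fc, z_statistic = z, p_value = p,
    is_deg = abs(l2fc) >= fcThreshold & p < pThreshold,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Overlap report between two differential-gene calls
#'
#' Partitions the gene universe into the four Venn cells: called only by the
#' network (eta) route, only by the fold-change route, by both, or by
#' neither.
#'
#' @param networkDegs,foldChangeDegs character vectors of gene IDs, both
#'   subsets of `universe`.
#' @param universe character vector of all genes considered.
#' @return list with `counts` (named integer vector `only_network`,
#'   `only_fold_change`, `both`, `neither`) and `members` (the corresponding
#'   gene ID lists).
#' @export
overlapReport <- function(networkDegs, foldChangeDegs, universe) {
  networkDegs <- unique(networkDegs)
  foldChangeDegs <- unique(foldChangeDegs)
  if (!all(networkDegs %in% universe) || !all(foldChangeDegs %in% universe))
    stop("differential-gene sets must be subsets of the universe")
  both <- intersect(networkDegs, foldChangeDegs)
  onlyN <- setdiff(networkDegs, foldChangeDegs)
  onlyF <- setdiff(foldChangeDegs, networkDegs)
  neither <- setdiff(universe, union(networkDegs, foldChangeDegs))
  list(
    counts = c(only_network = length(onlyN),
               only_fold_change = length(onlyF),
               both = length(both),
               neither = length(neither)),
    members = list(only_network = sort(onlyN),
                   only_fold_change = sort(onlyF),
                   both = sort(both),
                   neither = sort(neither)))
}
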