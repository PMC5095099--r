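#' @include AllClasses.R
NULL

#' Gene identifiers of an object
#' @param x an object holding genes.
#' @return character vector of gene IDs.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Sample identifiers of an object
#' @param x an object holding samples.
#' @return character vector of sample IDs.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Expression values as a plain matrix
#' @param x a [GeneExpression-class] object (or matrix, returned as is).
#' @return numeric genes x samples matrix.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' Condition-group label
#' @param x a [GeneExpression-class] object.
#' @return length-one character (possibly `NA`).
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' Edge table of a network
#' @param x a [RegulatoryNetwork-class].
#' @return data.frame with columns source, target, weight, ratio, sign.
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' Raw weight matrix
#' @param x a [WeightMatrix-class] or [PlantedGRN-class].
#' @return numeric n x n matrix.
#' @export
setGeneric("weightValues", function(x) standardGeneric("weightValues"))

## ----- methods --------------------------------------------------------------

#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneExpression", function(x) rownames(x))
#' @rdname geneIds
#' @export
setMethod("geneIds", "WeightMatrix", function(x) rownames(x@W))
#' @rdname geneIds
#' @export
setMethod("geneIds", "RegulatoryNetwork", function(x) x@geneIds)
#' @rdname geneIds
#' @export
setMethod("geneIds", "CorrelationMatrix", function(x) rownames(x@r))
#' @rdname geneIds
#' @export
setMethod("geneIds", "PlantedGRN", function(x) rownames(x@weights))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "GeneExpression", function(x) colnames(x))

#' @rdname exprValues
#' @export
setMethod("exprValues", "GeneExpression", function(x) assay(x, "exprs"))
#' @rdname exprValues
#' @export
setMethod("exprValues", "matrix", function(x) x)

#' @rdname groupLabel
#' @export
setMethod("groupLabel", "GeneExpression", function(x) x@group)

#' @rdname edges
#' @export
setMethod("edges", "RegulatoryNetwork", function(x) x@edges)

#' @rdname weightValues
#' @export
setMethod("weightValues", "WeightMatrix", function(x) x@W)
#' @rdname weightValues
#' @export
setMethod("weightValues", "PlantedGRN", function(x) x@weights)

## ----- show -----------------------------------------------------------------

setMethod("show", "GeneExpression", function(object) {
  cat("GeneExpression:", nrow(object), "genes x", ncol(object), "samples")
  if (!is.na(object@group)) cat(" [group ", object@group, "]", sep = "")
  cat("\n")
  v <- exprValues(object)
  cat("  values in [", format(min(v), digits = 4), ", ",
      format(max(v), digits = 4), "]\n", sep = "")
})

setMethod("show", "BPControl", function(object) {
  cat("BPControl: learningRate=", object@learningRate,
      " momentum=", object@momentum, " bias=", object@bias,
      " maxCycles=", object@maxCycles,
      " errorTolerance=", object@errorTolerance,
      " initScale=", object@initScale, " seed=", object@seed,
      " biasTrainable=", object@biasTrainable, "\n", sep = "")
})

setMethod("show", "GeneRegressor", function(object) {
  cat("GeneRegressor for", object@targetGene, "--",
      length(object@weights), "input weights;",
      "E =", format(object@finalError, digits = 4),
      "after", object@cyclesRun, "cycles",
      if (object@converged) "(converged)" else "(cycle cap reached)", "\n")
})

setMethod("show", "WeightMatrix", function(object) {
  n <- nrow(object@W)
  cat("WeightMatrix:", n, "x", n, "genes\n")
  if (length(object@converged))
    cat("  converged regressors:", sum(object@converged), "/", n, "\n")
})

setMethod("show", "RegulatoryNetwork", function(object) {
  cat("RegulatoryNetwork (", object@method, "): ",
      length(object@geneIds), " genes, ", nrow(object@edges),
      " directed edges at threshold ", object@threshold, "\n", sep = "")
  if (nrow(object@edges))
    cat("  activation:", sum(object@edges$sign == "activation"),
        " inhibition:", sum(object@edges$sign == "inhibition"), "\n")
})

setMethod("show", "NetworkStats", function(object) {
  cat("NetworkStats (", object@method, ", threshold ", object@threshold,
      "): ", object@nNodes, " nodes, ", object@nEdges, " edges\n", sep = "")
  cat("  L=", format(object@L, digits = 4),
      " C=", format(object@C, digits = 4),
      " K=", format(object@K, digits = 4),
      " Q=", format(object@Q, digits = 4),
      " D=", format(object@D, digits = 4), "\n", sep = "")
  if (length(object@reasons))
    cat("  undefined:", paste(names(object@reasons), object@reasons,
                              sep = ": ", collapse = "; "), "\n")
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat("CorrelationMatrix:", nrow(object@r), "genes;",
      nrow(object@undefinedPairs), "undefined pairs\n")
})

setMethod("show", "PlantedGRN", function(object) {
  W <- object@weights
  cat("PlantedGRN:", nrow(W), "genes,", sum(W != 0), "true edges, bias",
      object@bias, "\n")
})

#' Coerce NetworkStats to a one-row data.frame
#'
#' @param x a [NetworkStats-class] object.
#' @param row.names,optional,... ignored, for generic compatibility.
#' @return a one-row data.frame with columns threshold, L, C, K, Q, D,
#'   n_nodes, n_edges, method.
#' @export
as.data.frame.NetworkStats <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  data.frame(threshold = x@threshold, L = x@L, C = x@C, K = x@K,
             Q = x@Q, D = x@D, n_nodes = x@nNodes, n_edges = x@nEdges,
             method = x@method, stringsAsFactors = FALSE)
}
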