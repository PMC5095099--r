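## Plain-text interchange: expression and weight-matrix TSV, edge lists,
## stats JSON, GraphML, YAML pipeline configuration.

#' Read a genes x samples expression TSV
#'
#' Expects a header row of sample IDs and a first column of gene IDs. IDs
#' must be unique, rows rectangular and all cells numeric; violations raise
#' a parse error naming the offending gene and sample.
#'
#' @param path file path.
#' @param group optional group label attached to the result.
#' @return a [GeneExpression-class].
#' @export
readExpressionTsv <- function(path, group = NA_character_) {
  if (!file.exists(path)) stop("input file not found: ", path)
  fields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(fields)) > 1L)
    stop("ragged TSV '", path, "': rows have ",
         paste(unique(fields), collapse = "/"), " fields")
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "")
  if (ncol(raw) < 2L) stop("'", path, "' has no sample columns")
  geneIds <- raw[[1L]]
  sampleIds <- colnames(raw)[-1L]
  if (anyDuplicated(geneIds))
    stop("duplicated gene IDs in '", path, "': ",
         paste(unique(geneIds[duplicated(geneIds)]), collapse = ", "))
  if (anyDuplicated(sampleIds))
    stop("duplicated sample IDs in '", path, "': ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  v <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  v <- matrix(v, nrow = nrow(raw), ncol = length(sampleIds),
              dimnames = list(geneIds, sampleIds))
  if (anyNA(v)) {
    bad <- which(is.na(v), arr.ind = TRUE)[1L, ]
    stop("non-numeric value in '", path, "' at gene '",
         geneIds[bad[1L]], "', sample '", sampleIds[bad[2L]], "'")
  }
  GeneExpression(v, group = group)
}

#' Write a genes x samples expression TSV
#'
#' @param x a [GeneExpression-class] object or matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpressionTsv <- function(x, path) {
  v <- exprValues(x)
  writeMatrixTsv(v, path, cornerLabel = "gene")
}

#' Read a gene-gene weight matrix TSV
#'
#' @param path file path to an n x n TSV with gene IDs as header row and
#'   first column.
#' @return a [WeightMatrix-class].
#' @export
readWeightMatrixTsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, quote = "")
  genes <- as.character(raw[[1L]])
  W <- as.matrix(raw[-1L])
  mode(W) <- "numeric"
  dimnames(W) <- list(genes, colnames(raw)[-1L])
  WeightMatrix(W)
}

#' Write a gene-gene weight matrix TSV
#'
#' @param W a [WeightMatrix-class] or plain matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeWeightMatrixTsv <- function(W, path) {
  Wm <- if (is(W, "WeightMatrix")) weightValues(W) else W
  writeMatrixTsv(Wm, path, cornerLabel = "gene")
}

writeMatrixTsv <- function(m, path, cornerLabel = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(cornerLabel, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a network edge list TSV
#'
#' Columns: source, target, weight, ratio, sign, method.
#'
#' @param net a [RegulatoryNetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  e <- net@edges
  e$method <- rep(net@method, nrow(e))
  utils::write.table(e, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a network edge list TSV
#'
#' Inverse of [writeEdgeList()]. The full node set cannot be recovered from
#' edges alone, so it must be supplied (isolated genes would otherwise be
#' lost).
#'
#' @param path file path.
#' @param geneIds the complete node set.
#' @param threshold the threshold the network was built at (recorded only).
#' @return a [RegulatoryNetwork-class].
#' @export
readEdgeList <- function(path, geneIds, threshold = NA_real_) {
  e <- utils::read.delim(path, header = TRUE, sep = "\t",
                         check.names = FALSE, quote = "",
                         colClasses = c(source = "character",
                                        target = "character"))
  method <- if (nrow(e)) e$method[1L] else "bp"
  e <- e[, c("source", "target", "weight", "ratio", "sign"), drop = FALSE]
  new("RegulatoryNetwork", geneIds = as.character(geneIds), edges = e,
      threshold = as.numeric(threshold), method = method)
}

#' Export a network as GraphML
#'
#' Writes the directed network with `weight`, `ratio` and `sign` edge
#' attributes for use in external network viewers.
#'
#' @param net a [RegulatoryNetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
exportGraphML <- function(net, path) {
  igraph::write_graph(asIgraph(net), path, format = "graphml")
  invisible(path)
}

#' Write a statistics table as JSON
#'
#' One record per network: threshold, L, C, K, Q, D, node and edge counts,
#' method. `NA` statistics serialise as `null`.
#'
#' @param stats data.frame from [statsTable()] (or a single
#'   [NetworkStats-class]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStatsJson <- function(stats, path) {
  if (is(stats, "NetworkStats")) stats <- as.data.frame(stats)
  jsonlite::write_json(stats, path, dataframe = "rows", digits = NA,
                       na = "null", auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' The file mirrors the arguments of [pipelineConfig()]; fields `groups`
#' (named map of expression TSV paths) and `outDir` are required, everything
#' else falls back to the defaults.
#'
#' @param path YAML file path.
#' @return a validated pipeline configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, raw)
}
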