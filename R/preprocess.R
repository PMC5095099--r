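## Data processing: min-max normalization to [0,1] and block averaging.

#' Min-max normalize an expression matrix to [0, 1]
#'
#' Rescales each value as `(x - xmin) / (xmax - xmin)` where the minimum and
#' maximum are taken either within each gene record (`scope = "per_gene"`,
#' the default) or over the whole matrix (`scope = "global"`). In the
#' degenerate case `xmin == xmax` the output is defined as `xmin` itself; if
#' the raw data are unscaled this can leave values outside [0, 1], which is
#' reported with a warning.
#'
#' @param x a [GeneExpression-class] object or genes x samples matrix.
#' @param scope `"per_gene"` or `"global"`.
#' @return an object of the same kind as `x` with normalized values.
#' @examples
#' m <- matrix(c(2, 4, 6, 1, 1, 1), 2, 3, byrow = TRUE,
#'             dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
#' exprValues(normalizeExpression(GeneExpression(m)))
#' @export
normalizeExpression <- function(x, scope = c("per_gene", "global")) {
  scope <- match.arg(scope)
  v <- exprValues(x)
  if (length(v) == 0L) stop("empty expression matrix")
  if (!all(is.finite(v))) stop("expression values must be finite")
  out <- v
  if (scope == "global") {
    lo <- min(v); hi <- max(v)
    if (lo == hi) out[] <- lo else out <- (v - lo) / (hi - lo)
  } else {
    lo <- apply(v, 1L, min)
    hi <- apply(v, 1L, max)
    rng <- hi - lo
    flat <- rng == 0
    rng[flat] <- 1  # avoid 0/0; flat rows overwritten below
    out <- (v - lo) / rng
    if (any(flat)) out[flat, ] <- lo[flat]
  }
  if (any(out < 0 | out > 1))
    warning("degenerate constant records left values outside [0, 1]")
  replaceValues(x, out)
}

#' Average consecutive sample blocks
#'
#' Groups the samples into consecutive runs of `blockSize` (in stable input
#' column order) and replaces each run by its element-wise mean, reducing
#' sample-level noise. A trailing remainder of fewer than `blockSize` samples
#' is dropped, so the output has `floor(n_samples / blockSize)` samples
#' (e.g. 64, 63 and 64 samples reduce to 32, 31 and 32 at the default block
#' size of 2). Block sample IDs join the member IDs with `"+"`.
#'
#' @param x a [GeneExpression-class] object or genes x samples matrix.
#' @param blockSize positive integer number of samples per block.
#' @return an object of the same kind as `x` with averaged samples.
#' @examples
#' m <- matrix(1:12, 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' exprValues(blockAverage(GeneExpression(m)))
#' @export
blockAverage <- function(x, blockSize = 2L) {
  blockSize <- as.integer(blockSize)
  if (is.na(blockSize) || blockSize < 1L)
    stop("'blockSize' must be a positive integer")
  v <- exprValues(x)
  p <- ncol(v)
  if (p < blockSize)
    stop("need at least 'blockSize' samples (have ", p, ")")
  nb <- p %/% blockSize
  keep <- seq_len(nb * blockSize)
  idx <- matrix(keep, nrow = blockSize)
  out <- vapply(seq_len(nb),
                function(b) rowMeans(v[, idx[, b], drop = FALSE]),
                numeric(nrow(v)))
  out <- matrix(out, nrow = nrow(v), ncol = nb)
  rownames(out) <- rownames(v)
  colnames(out) <- vapply(seq_len(nb), function(b)
    paste(colnames(v)[idx[, b]], collapse = "+"), character(1))
  replaceValues(x, out, resizeSamples = TRUE)
}

## Put a new value matrix back into the container the user gave us.
replaceValues <- function(x, values, resizeSamples = FALSE) {
  if (is(x, "GeneExpression"))
    GeneExpression(values, group = groupLabel(x))
  else
    values
}
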