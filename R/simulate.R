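## Synthetic expression with a planted regulatory structure: the generative
## mirror of the fitted model, so inference, statistics and differential-gene
## detection can be benchmarked end to end.

#' Generate a planted regulatory structure
#'
#' Builds a sparse acyclic true weight matrix with three gene layers:
#'
#' \describe{
#'   \item{drivers}{`nDrivers` exogenous genes with no regulators; their
#'     values will be independent uniforms. Independence between drivers is
#'     what makes the planted edges identifiable downstream — with a single
#'     source of variation every gene is a monotone transform of the same
#'     scalar and regulators are hopelessly collinear.}
#'   \item{anchors}{`anchorsPerDriver` single-input "reporter" genes per
#'     driver, with negative weights spread over a range of operating points
#'     (from the near-linear -1.5 to the saturating -12). They carry each
#'     driver's signal at several different nonlinear gains, giving the
#'     driver's own regressor an invertible basis.}
#'   \item{targets}{the remaining genes, each combinatorially regulated by
#'     an expected `avgRegulators` (at least 2, Poisson-distributed) distinct
#'     drivers. Raw magnitudes are uniform on `[0.5, 1.5] * weightScale`
#'     with signs inhibitory at probability `signMix`, then shifted so the
#'     incoming weights sum to -2: with bias -1 the sigmoid argument is then
#'     centred at 0 over uniform inputs, keeping the target responsive
#'     (uncentred weights saturate the sigmoid and targets degenerate to
#'     near-constants).}
#' }
#'
#' @param nGenes number of genes (>= 2).
#' @param avgRegulators expected regulators per combinatorial target gene;
#'   must be smaller than `nGenes`. 0 gives an empty structure (no anchors
#'   or targets).
#' @param signMix probability that a raw target weight is inhibitory, in
#'   [0, 1] (the centring shift can flip realised signs; anchor weights are
#'   always inhibitory by construction).
#' @param weightScale typical raw magnitude of target weights.
#' @param bias generative threshold, matching the training default -1.
#' @param seed integer seed; the structure is deterministic given it.
#' @param nDrivers number of exogenous driver genes; default 2 below 30
#'   genes, then roughly one per 15 genes.
#' @param anchorsPerDriver reporter genes per driver; the default fills
#'   about 60\% of the gene set with anchors.
#' @return a [PlantedGRN-class].
#' @examples
#' plantedGRN(20, avgRegulators = 2, seed = 7)
#' @export
plantedGRN <- function(nGenes, avgRegulators = 2, signMix = 0.5,
                       weightScale = 4, bias = -1, seed = 1L,
                       nDrivers = if (nGenes < 10L) 1L else
                         max(2L, nGenes %/% 15L),
                       anchorsPerDriver = max(1L, min(
                         (nGenes * 3L) %/% (5L * nDrivers),
                         (nGenes - nDrivers - 1L) %/% nDrivers))) {
  nGenes <- as.integer(nGenes)
  if (is.na(nGenes) || nGenes < 2L) stop("'nGenes' must be at least 2")
  if (avgRegulators < 0 || avgRegulators >= nGenes)
    stop("'avgRegulators' must be in [0, nGenes)")
  if (signMix < 0 || signMix > 1) stop("'signMix' must be in [0, 1]")
  nDrivers <- as.integer(nDrivers)
  anchorsPerDriver <- as.integer(anchorsPerDriver)
  genes <- sprintf("g%0*d", nchar(nGenes), seq_len(nGenes))
  W <- matrix(0, nGenes, nGenes, dimnames = list(genes, genes))
  set.seed(as.integer(seed))
  if (avgRegulators > 0) {
    if (nDrivers < 1L || nDrivers * (1L + anchorsPerDriver) > nGenes)
      stop("driver/anchor layers exceed the gene set; reduce 'nDrivers' ",
           "or 'anchorsPerDriver'")
    opPoints <- c(-1.5, -3, -6, -12, -2, -4, -8, -2.5)
    j <- nDrivers
    for (i in seq_len(nDrivers)) {
      for (a in seq_len(anchorsPerDriver)) {
        j <- j + 1L
        op <- opPoints[(a - 1L) %% length(opPoints) + 1L]
        W[i, j] <- op * stats::runif(1L, 0.85, 1.15)
      }
    }
    for (jj in seq_len(nGenes)[-seq_len(j)]) {
      k <- min(nDrivers, max(2L, stats::rpois(1L, avgRegulators)))
      regs <- if (nDrivers == 1L) 1L else sample(nDrivers, k)
      w <- stats::runif(k, 0.5, 1.5) * weightScale *
        ifelse(stats::runif(k) < signMix, -1, 1)
      w <- w - (sum(w) + 2) / k
      W[regs, jj] <- w
    }
  }
  new("PlantedGRN", weights = W, bias = as.numeric(bias))
}

#' Simulate expression from a planted structure
#'
#' For each sample, driver genes (no regulators) draw values uniform on
#' [0, 1]; every regulated gene is then set, in topological order, to the
#' sigmoid of the weighted sum of its regulators minus the bias. Gaussian
#' measurement noise (sd `noiseSd`) is finally added to every gene —
#' drivers included, as on a real array — and clipped back into [0, 1].
#' With `noiseSd = 0` every regulated gene satisfies the generative
#' fixed-point relation exactly, so the output is directly learnable by the
#' training routine.
#'
#' @param grn a [PlantedGRN-class].
#' @param nSamples number of samples (>= 1).
#' @param noiseSd Gaussian noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param group optional group label for the result.
#' @return a [GeneExpression-class], values in [0, 1].
#' @examples
#' ge <- simulateExpression(plantedGRN(10, 2, seed = 7), 50, seed = 8)
#' range(exprValues(ge))
#' @export
simulateExpression <- function(grn, nSamples, noiseSd = 0, seed = 1L,
                               group = NA_character_) {
  stopifnot(is(grn, "PlantedGRN"))
  nSamples <- as.integer(nSamples)
  if (is.na(nSamples) || nSamples < 1L) stop("'nSamples' must be >= 1")
  if (noiseSd < 0) stop("'noiseSd' must be non-negative")
  W <- grn@weights
  n <- nrow(W)
  genes <- rownames(W)
  set.seed(as.integer(seed))
  v <- matrix(NA_real_, n, nSamples,
              dimnames = list(genes, sprintf("s%0*d", nchar(nSamples),
                                             seq_len(nSamples))))
  regulated <- colSums(W != 0) > 0
  v[!regulated, ] <- stats::runif(sum(!regulated) * nSamples)
  for (j in which(regulated)) {     # index order is topological
    regs <- which(W[, j] != 0)
    v[j, ] <- sigmoid(drop(crossprod(W[regs, j, drop = FALSE],
                                     v[regs, , drop = FALSE])) - grn@bias)
  }
  if (noiseSd > 0) {
    # measurement noise hits every gene, drivers included, after the
    # regulatory cascade has been evaluated on the clean signals
    v <- v + stats::rnorm(length(v), sd = noiseSd)
    v <- pmax(pmin(v, 1), 0)
  }
  GeneExpression(v, group = group)
}

#' Edge-recovery metrics against the planted truth
#'
#' Treats the nonzero entries of the planted weight matrix as true directed
#' edges and scores an inferred network against them: precision (`NA` when
#' the inferred network is empty), recall, and the fraction of true-positive
#' edges whose inferred sign (activation/inhibition) matches the sign of the
#' planted weight (`NA` when there are no true positives).
#'
#' @param truth a [PlantedGRN-class].
#' @param inferred a [RegulatoryNetwork-class] over the same genes.
#' @return list with `precision`, `recall`, `signAccuracy`, `nTrue`,
#'   `nInferred`, `nTruePositive`.
#' @export
recoveryMetrics <- function(truth, inferred) {
  if (!setequal(geneIds(truth), geneIds(inferred)))
    stop("truth and inferred network must share the same gene set")
  W <- truth@weights
  trueIdx <- which(W != 0, arr.ind = TRUE)
  trueKey <- paste(rownames(W)[trueIdx[, 1L]],
                   rownames(W)[trueIdx[, 2L]], sep = "\r")
  trueSign <- ifelse(W[trueIdx] > 0, "activation", "inhibition")
  names(trueSign) <- trueKey
  e <- inferred@edges
  infKey <- paste(e$source, e$target, sep = "\r")
  tpKey <- intersect(infKey, trueKey)
  nTP <- length(tpKey)
  precision <- if (length(infKey)) nTP / length(infKey) else NA_real_
  recall <- if (length(trueKey)) nTP / length(trueKey) else NA_real_
  signAccuracy <- if (nTP) {
    infSign <- e$sign[match(tpKey, infKey)]
    mean(infSign == trueSign[tpKey])
  } else NA_real_
  list(precision = precision, recall = recall, signAccuracy = signAccuracy,
       nTrue = length(trueKey), nInferred = length(infKey),
       nTruePositive = nTP)
}
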