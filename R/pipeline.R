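## The end-to-end pipeline: normalize -> block-average -> train -> threshold
## sweep -> statistics -> relevance baseline -> degree-difference DEGs ->
## fold-change comparator -> overlap report, with a run manifest.

#' Derive a stage-specific seed from the run seed
#'
#' All randomness in a pipeline run flows from one top-level seed; each stage
#' hashes its name (and an optional index) together with that seed so stages
#' can be re-run in isolation reproducibly. The result is always a positive
#' 32-bit integer.
#'
#' @param seed the top-level run seed.
#' @param stage a stage name such as `"train"`.
#' @param index optional integer sub-index (e.g. a group number).
#' @return an integer seed.
#' @export
stageSeed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729 +
                as.numeric(index) * 613) %% 2147483629 + 1)
}

#' Assemble and validate a pipeline configuration
#'
#' @param groups named list/vector of expression TSV paths, one per condition
#'   group (at least two groups for the differential stages).
#' @param outDir output directory (created if missing).
#' @param reference name of the reference group for comparisons; defaults to
#'   the second group, the middle condition in a three-group design.
#' @param scope normalization scope, `"per_gene"` or `"global"`.
#' @param blockSize samples per averaging block (default 2).
#' @param control a [BPControl-class] or a list of [bpControl()] arguments;
#'   its seed is derived from `seed` unless given explicitly.
#' @param thresholds weight-ratio grid for the sweep.
#' @param rThreshold correlation threshold of the relevance baseline.
#' @param degThreshold the single weight-ratio threshold at which the
#'   degree-difference comparison is run (default 0.85).
#' @param etaMin,topK,combine differential-gene selection policy, see
#'   [selectNetworkDegs()].
#' @param fcThreshold,pThreshold,pseudocount fold-change comparator settings,
#'   see [foldChangeZTest()].
#' @param seed top-level run seed.
#' @return a validated configuration list of class `"bpgrnPipelineConfig"`.
#' @export
pipelineConfig <- function(groups, outDir, reference = NULL,
                           scope = "per_gene", blockSize = 2L,
                           control = list(),
                           thresholds = defaultThresholdGrid(),
                           rThreshold = 0.85, degThreshold = 0.85,
                           etaMin = 0, topK = NULL, combine = "union",
                           fcThreshold = 0.05, pThreshold = 0.05,
                           pseudocount = 1e-6, seed = 1L) {
  groups <- unlist(groups)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("'groups' must be a named list of expression file paths")
  if (anyDuplicated(names(groups))) stop("group names must be unique")
  if (is.null(reference))
    reference <- names(groups)[min(2L, length(groups))]
  if (!(reference %in% names(groups)))
    stop("'reference' must be one of the group names")
  if (any(thresholds < 0 | thresholds > 1))
    stop("'thresholds' must lie in [0, 1]")
  if (is(control, "BPControl")) {
    ctrl <- control
  } else {
    if (!("seed" %in% names(control)))
      control$seed <- stageSeed(seed, "train")
    ctrl <- do.call(bpControl, control)
  }
  structure(list(
    groups = groups, outDir = outDir, reference = reference,
    scope = match.arg(scope, c("per_gene", "global")),
    blockSize = as.integer(blockSize), control = ctrl,
    thresholds = as.numeric(thresholds),
    rThreshold = rThreshold, degThreshold = degThreshold,
    etaMin = etaMin, topK = topK, combine = combine,
    fcThreshold = fcThreshold, pThreshold = pThreshold,
    pseudocount = pseudocount, seed = as.integer(seed)),
    class = "bpgrnPipelineConfig")
}

controlAsList <- function(ctrl) {
  list(learningRate = ctrl@learningRate, momentum = ctrl@momentum,
       bias = ctrl@bias, maxCycles = ctrl@maxCycles,
       errorTolerance = ctrl@errorTolerance, initScale = ctrl@initScale,
       seed = ctrl@seed, biasTrainable = ctrl@biasTrainable)
}

#' Run the full inference pipeline
#'
#' Executes every stage over all condition groups and writes all artifacts
#' to the configured output directory: processed expression, trained weight
#' matrices with training summaries, edge lists and statistics over the
#' threshold grid, the cross-condition statistics comparison, the Pearson
#' relevance baseline with its zero-degree census, degree-difference-ratio
#' rankings and selected differential genes, the fold-change comparator, the
#' overlap (Venn) report, and a manifest echoing the configuration. A stage
#' failure aborts with an error naming the stage; the manifest then records
#' which stages completed.
#'
#' @param config a configuration from [pipelineConfig()] or
#'   [readPipelineConfig()], or a path to a YAML config file.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the key in-memory results (`networks`,
#'   `stats`, `comparison`, `degEta`, `networkDegs`, `foldChange`,
#'   `foldChangeDegs`, `overlap`, `artifacts`).
#' @export
runPipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "bpgrnPipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  artifacts <- character()
  completed <- character()
  failed <- NULL

  writeManifest <- function() {
    manifest <- list(
      package = "bpgrn",
      version = as.character(utils::packageVersion("bpgrn")),
      seed = config$seed,
      config = list(
        groups = as.list(config$groups), reference = config$reference,
        scope = config$scope, blockSize = config$blockSize,
        control = controlAsList(config$control),
        thresholds = config$thresholds, rThreshold = config$rThreshold,
        degThreshold = config$degThreshold, etaMin = config$etaMin,
        topK = config$topK, combine = config$combine,
        fcThreshold = config$fcThreshold, pThreshold = config$pThreshold,
        pseudocount = config$pseudocount),
      stages_completed = completed,
      stage_failed = failed,
      artifacts = as.list(artifacts))
    jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }

  stage <- function(name, fn) {
    out <- tryCatch(fn(), error = function(e) {
      failed <<- list(stage = name, error = conditionMessage(e))
      writeManifest()
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    completed <<- c(completed, name)
    out
  }

  gnames <- names(config$groups)

  processed <- stage("preprocess", function() {
    out <- list()
    for (g in gnames) {
      ge <- readExpressionTsv(config$groups[[g]], group = g)
      ge <- normalizeExpression(ge, scope = config$scope)
      ge <- blockAverage(ge, config$blockSize)
      p <- file.path(config$outDir, paste0("processed_", g, ".tsv"))
      writeExpressionTsv(ge, p)
      artifacts <<- c(artifacts, p)
      say("preprocess: ", g, " -> ", nrow(ge), " genes x ", ncol(ge),
          " samples")
      out[[g]] <- ge
    }
    out
  })

  weights <- stage("train", function() {
    out <- list()
    for (g in gnames) {
      wm <- trainNetwork(processed[[g]], config$control)
      p <- file.path(config$outDir, paste0("weights_", g, ".tsv"))
      writeWeightMatrixTsv(wm, p)
      pj <- file.path(config$outDir, paste0("training_", g, ".json"))
      jsonlite::write_json(list(
        group = g, control = controlAsList(config$control),
        final_errors = as.list(wm@finalErrors),
        cycles_run = as.list(wm@cyclesRun),
        converged = as.list(wm@converged)),
        pj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      artifacts <<- c(artifacts, p, pj)
      say("train: ", g, " -> ", sum(wm@converged), "/", nrow(wm@W),
          " regressors converged")
      out[[g]] <- wm
    }
    out
  })

  networks <- stage("build", function() {
    out <- list()
    for (g in gnames) {
      nets <- sweepThresholds(weights[[g]], config$thresholds)
      for (i in seq_along(nets)) {
        p <- file.path(config$outDir, sprintf("edges_%s_thr%.2f.tsv", g,
                                              config$thresholds[i]))
        writeEdgeList(nets[[i]], p)
        artifacts <<- c(artifacts, p)
      }
      say("build: ", g, " -> edge counts ",
          paste(vapply(nets, function(nw) nrow(nw@edges), 1L),
                collapse = ", "))
      out[[g]] <- nets
    }
    out
  })

  stats <- stage("stats", function() {
    out <- list()
    for (g in gnames) {
      tab <- statsTable(networks[[g]], seed = stageSeed(config$seed, "stats"))
      p <- file.path(config$outDir, paste0("stats_", g, ".json"))
      writeStatsJson(tab, p)
      artifacts <<- c(artifacts, p)
      out[[g]] <- tab
    }
    out
  })

  comparison <- stage("compare", function() {
    if (length(gnames) < 2L) return(NULL)
    cmp <- compareStats(stats, config$reference)
    p <- file.path(config$outDir, "stats_comparison.tsv")
    utils::write.table(cmp, p, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <<- c(artifacts, p)
    cmp
  })

  baseline <- stage("baseline", function() {
    out <- list()
    for (g in gnames) {
      rn <- relevanceNetwork(pearsonCorrelationMatrix(processed[[g]]),
                             config$rThreshold)
      p <- file.path(config$outDir, paste0("relevance_edges_", g, ".tsv"))
      writeEdgeList(rn, p)
      tab <- statsTable(list(rn), seed = stageSeed(config$seed, "stats"))
      tab$zero_degree <- zeroDegreeCount(rn)
      pj <- file.path(config$outDir, paste0("relevance_stats_", g, ".json"))
      writeStatsJson(tab, pj)
      artifacts <<- c(artifacts, p, pj)
      say("baseline: ", g, " -> ", nrow(rn@edges) / 2L,
          " undirected edges, ", tab$zero_degree, " zero-degree genes")
      out[[g]] <- rn
    }
    out
  })

  deg <- stage("deg", function() {
    if (length(gnames) < 2L) return(NULL)
    others <- setdiff(gnames, config$reference)
    refNet <- buildNetwork(weights[[config$reference]],
                           config$degThreshold)
    rankings <- list()
    fcTabs <- list()
    fcSets <- list()
    for (g in others) {
      net <- buildNetwork(weights[[g]], config$degThreshold)
      rk <- rankByEta(net, refNet)
      p <- file.path(config$outDir,
                     paste0("deg_eta_", g, "_vs_", config$reference, ".tsv"))
      utils::write.table(rk, p, sep = "\t", quote = FALSE, row.names = FALSE)
      artifacts <<- c(artifacts, p)
      rankings[[g]] <- rk
      fc <- foldChangeZTest(processed[[config$reference]], processed[[g]],
                            fcThreshold = config$fcThreshold,
                            pThreshold = config$pThreshold,
                            pseudocount = config$pseudocount)
      pf <- file.path(config$outDir,
                      paste0("deg_foldchange_", g, "_vs_",
                             config$reference, ".tsv"))
      utils::write.table(fc, pf, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      artifacts <<- c(artifacts, pf)
      fcTabs[[g]] <- fc
      fcSets[[g]] <- fc$gene[fc$is_deg]
    }
    networkDegs <- selectNetworkDegs(
      rankings[[1L]],
      if (length(rankings) > 1L) rankings[[2L]] else NULL,
      etaMin = config$etaMin, topK = config$topK, combine = config$combine)
    fcDegs <- sort(Reduce(if (config$combine == "union") union
                          else intersect, fcSets))
    universe <- geneIds(refNet)
    ov <- overlapReport(networkDegs, fcDegs, universe)
    pv <- file.path(config$outDir, "venn.json")
    jsonlite::write_json(list(
      policy = list(etaMin = config$etaMin, topK = config$topK,
                    combine = config$combine,
                    degThreshold = config$degThreshold,
                    fcThreshold = config$fcThreshold,
                    pThreshold = config$pThreshold,
                    pseudocount = config$pseudocount),
      counts = as.list(ov$counts),
      members = ov$members),
      pv, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
    artifacts <<- c(artifacts, pv)
    say("deg: ", length(networkDegs), " network DEGs, ", length(fcDegs),
        " fold-change DEGs, ", ov$counts[["both"]], " overlapping")
    list(rankings = rankings, networkDegs = networkDegs,
         foldChange = fcTabs, foldChangeDegs = fcDegs, overlap = ov)
  })

  writeManifest()
  artifacts <- c(artifacts, file.path(config$outDir, "manifest.json"))
  invisible(list(
    processed = processed, weights = weights, networks = networks,
    stats = stats, comparison = comparison, baseline = baseline,
    degEta = deg$rankings, networkDegs = deg$networkDegs,
    foldChange = deg$foldChange, foldChangeDegs = deg$foldChangeDegs,
    overlap = deg$overlap, artifacts = artifacts))
}
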