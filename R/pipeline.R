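## Config-driven end-to-end workflow: (simulate or load expression) ->
## edge-frequency estimation -> threshold -> local-model fitting -> ECv ->
## per-line delta-ECv -> differential-edge extraction -> subnetwork ->
## optional transfer -> clustering -> optional survival comparison. Every
## intermediate is written in a documented plain-text format plus a JSON
## run manifest, and a fixed seed makes reruns byte-identical.

.cfgGet <- function(cfg, path, default = NULL) {
  cur <- cfg
  for (k in path) {
    if (is.null(cur[[k]])) return(default)
    cur <- cur[[k]]
  }
  cur
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key/value YAML mirroring every stage option of [runPipeline()].
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full workflow
#'
#' Executes the stages of the analysis in order and writes every
#' intermediate under \code{config$outDir}. Stage failures abort with a
#' stage-named diagnostic. See the package vignette for the configuration
#' keys; the minimal toy configuration is
#' \code{list(seed 1, outDir, simulate = list(), estimate = list(tIter = 100))}.
#'
#' @param config configuration list (or path to a YAML file).
#' @return the output directory, invisibly; side effect: artifact files and
#'   a run manifest.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  outDir <- .cfgGet(config, "outDir")
  if (is.null(outDir)) stop("config error: outDir is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(.cfgGet(config, "seed", 1L))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  manifest <- list(package = "ecvnet",
                   version = as.character(utils::packageVersion("ecvnet")),
                   rVersion = R.version.string,
                   seed = seed, config = config, outputs = list())
  keep <- function(tag, path) manifest$outputs[[tag]] <<- basename(path)

  ## -- expression: load or simulate --------------------------------------
  X <- stage("expression", {
    exprPath <- .cfgGet(config, "expression")
    if (!is.null(exprPath)) {
      xd <- readExpression(exprPath,
                           orientation = .cfgGet(config, "orientation",
                                                 "genes_in_rows"),
                           log2 = isTRUE(.cfgGet(config, "log2")))
      siPath <- .cfgGet(config, "sampleInfo")
      if (!is.null(siPath))
        xd <- expressionData(exprValues(xd), readSampleInfo(siPath))
      pct <- .cfgGet(config, c("filter", "meanPercentile"), 0)
      if (pct > 0) xd <- filterGenesByMeanPercentile(xd, pct)
      xd
    } else {
      sim <- .cfgGet(config, "simulate", list())
      gt <- makeGroundTruth(
        p = .cfgGet(sim, "p", 10L),
        nPerturbed = .cfgGet(sim, "nPerturbed", 3L),
        shift = .cfgGet(sim, "shift", 2),
        sigma = .cfgGet(sim, "sigma", 0.3),
        lines = .cfgGet(sim, "lines", 3L),
        conditions = .cfgGet(sim, "conditions", 2L),
        replicates = .cfgGet(sim, "replicates", 3L),
        seed = seed)
      simulateExpression(gt, seed = seed + 1L)
    }
  })
  writeExpression(X, file.path(outDir, "expression.tsv"))
  keep("expression", "expression.tsv")
  if (ncol(sampleInfo(X))) {
    writeSampleInfo(X, file.path(outDir, "sample_info.tsv"))
    keep("sampleInfo", "sample_info.tsv")
  }

  ## -- structure estimation ----------------------------------------------
  est <- .cfgGet(config, "estimate", list())
  cfg <- scoreConfig(M = .cfgGet(est, "M", 20L),
                     lambdaGrid = .cfgGet(est, "lambdaGrid",
                                          c(0.1, 1, 10, 100)),
                     ridgeEps = .cfgGet(est, "ridgeEps", 1e-8),
                     maxParents = .cfgGet(est, "maxParents", 3L))
  basal <- stage("estimate", {
    p <- ncol(exprValues(X))
    freqNet <- nnsrEstimate(X, tIter = .cfgGet(est, "tIter", 200L),
                            subsetSize = .cfgGet(est, "subsetSize",
                                                 min(30L, p)),
                            cfg = cfg, seed = seed)
    writeEdgeFrequencies(freqNet, file.path(outDir, "edge_frequencies.tsv"))
    keep("edgeFrequencies", "edge_frequencies.tsv")
    thresholdNetwork(freqNet, cutoff = .cfgGet(est, "cutoff", 0.1))
  })
  writeNetworkTsv(basal, file.path(outDir, "basal_network.tsv"))
  writeNetworkSif(basal, file.path(outDir, "basal_network.sif"))
  keep("basalNetwork", "basal_network.tsv")

  ## -- local models and ECv ----------------------------------------------
  models <- stage("fit", fitAllModels(X, basal, cfg))
  writeModelSet(models, file.path(outDir, "model_set.json"))
  keep("modelSet", "model_set.json")
  E <- stage("ecv", computeEcvMatrix(models, X))
  writeEcvMatrix(E, file.path(outDir, "ecv_matrix.tsv"))
  keep("ecvMatrix", "ecv_matrix.tsv")

  ## -- delta-ECv and extraction ------------------------------------------
  del <- .cfgGet(config, "delta", list())
  deltaTab <- stage("delta", {
    si <- sampleInfo(X)
    if (!"condition" %in% names(si))
      stop("sample annotations with a 'condition' column are required")
    treat <- .cfgGet(del, "treat", "treated")
    ctrl <- .cfgGet(del, "control", "control")
    byLine <- isTRUE(.cfgGet(del, "byLine", TRUE)) && "line" %in% names(si)
    groups <- if (byLine) {
      lns <- sort(unique(si$line))
      stats::setNames(lapply(lns, function(l) list(
        S = rownames(si)[si$condition == treat & si$line == l],
        T = rownames(si)[si$condition == ctrl & si$line == l])), lns)
    } else {
      list(pooled = list(S = rownames(si)[si$condition == treat],
                         T = rownames(si)[si$condition == ctrl]))
    }
    deltaEcvTable(E, groups)
  })
  utils::write.table(
    cbind(deltaTab[, c("parent", "child")],
          as.data.frame(lapply(deltaTab[, -(1:2), drop = FALSE],
                               function(x) sprintf("%.10g", x)))),
    file.path(outDir, "delta_ecv.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  keep("deltaEcv", "delta_ecv.tsv")
  extracted <- stage("extract",
    extractDifferentialEdges(deltaTab,
                             threshold = .cfgGet(del, "threshold", 1.0),
                             mode = .cfgGet(del, "mode", "all")))
  utils::write.table(
    if (nrow(extracted))
      cbind(extracted[, c("parent", "child")],
            as.data.frame(lapply(extracted[, -(1:2), drop = FALSE],
                                 function(x) sprintf("%.10g", x))))
    else extracted,
    file.path(outDir, "extracted_edges.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  keep("extractedEdges", "extracted_edges.tsv")

  ## -- subnetwork ---------------------------------------------------------
  subnet <- stage("subnet", buildSubnetwork(basal, extracted))
  writeSubnetworkTsv(subnet, file.path(outDir, "subnetwork.tsv"))
  writeNetworkSif(subnet, file.path(outDir, "subnetwork.sif"))
  if (length(subnet@nodes))
    writeSubnetworkGraphml(subnet, file.path(outDir, "subnetwork.graphml"))
  keep("subnetwork", "subnetwork.tsv")
  hubs <- hubNodes(subnet)
  utils::write.table(hubs, file.path(outDir, "hub_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  comp <- networkComponents(subnet)
  writeLines(vapply(comp, paste, character(1), collapse = "\t"),
             file.path(outDir, "components.txt"))

  ## -- optional transfer ---------------------------------------------------
  Ecluster <- E
  trPath <- .cfgGet(config, c("transfer", "expression"))
  if (!is.null(trPath)) {
    tr <- stage("transfer", {
      newX <- readExpression(trPath,
                             orientation = .cfgGet(config,
                                                   c("transfer", "orientation"),
                                                   "genes_in_rows"),
                             log2 = isTRUE(.cfgGet(config,
                                                   c("transfer", "log2"))))
      edgeSubset <- if (nrow(extracted)) extracted[, c("parent", "child")]
      else NULL
      transferEcv(models, newX, edges = edgeSubset,
                  rescale = isTRUE(.cfgGet(config, c("transfer", "rescale"))))
    })
    writeEcvMatrix(tr$ecv, file.path(outDir, "transfer_ecv.tsv"))
    writeLines(jsonlite::toJSON(tr$report, auto_unbox = TRUE, digits = NA),
               file.path(outDir, "transfer_report.json"))
    keep("transferEcv", "transfer_ecv.tsv")
    Ecluster <- tr$ecv
  }

  ## -- clustering and survival --------------------------------------------
  cl <- stage("cluster", {
    wardCluster(Ecluster, k = .cfgGet(config, c("cluster", "k"), 2L),
                axis = "samples")
  })
  utils::write.table(
    data.frame(sample = names(cl$labels), cluster = cl$labels),
    file.path(outDir, "cluster_labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(merge = seq_along(cl$heights),
               height = sprintf("%.10g", cl$heights)),
    file.path(outDir, "cluster_heights.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  keep("clusterLabels", "cluster_labels.tsv")

  surv <- .cfgGet(config, "survival")
  if (!is.null(surv)) {
    res <- stage("survival", {
      if (is.null(surv$path))
        stop("config error: survival stage requires survival$path")
      rec <- readSurvival(surv$path)
      maxDays <- .cfgGet(surv, "maxFollowUpDays", 2000)
      rec <- filterFollowUp(rec, maxDays)
      rec <- rec[rec$sample %in% names(cl$labels), , drop = FALSE]
      lr <- logrankTest(rec, cl$labels)
      list(records = rec, logrank = lr)
    })
    writeLines(jsonlite::toJSON(
      list(statistic = res$logrank$statistic, p = res$logrank$p,
           df = res$logrank$df, n = nrow(res$records)),
      auto_unbox = TRUE, digits = NA),
      file.path(outDir, "logrank.json"))
    km <- kmCurve(res$records, cl$labels)
    for (gname in names(km)) {
      utils::write.table(km[[gname]],
                         file.path(outDir, paste0("km_group", gname, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    keep("logrank", "logrank.json")
  }

  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             file.path(outDir, "manifest.json"))
  invisible(outDir)
}
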