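#' @include io.R network.R grouping.R differential.R
NULL

.config_hash <- function(config) {
  config$outputDir <- NULL  # analytic parameters only, not file locations
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Default pipeline configuration
#'
#' Returns the default configuration list for [runPipeline()], optionally
#' overridden by a YAML file and/or named arguments. Exactly one of the
#' \code{inputs} (file paths) or \code{simulate} (simulator parameters)
#' blocks must end up non-NULL.
#'
#' @param file optional YAML config file.
#' @param ... named overrides merged over the file values.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(file = NULL, ...) {
  config <- list(
    seed = 1L,
    gene = NULL,
    outputDir = NULL,
    inputs = NULL,      # list(methylation=, expression=, references=,
                        #      refClasses=, blocklists=, covariates=)
    simulate = NULL,    # list(k=, nProbes=, nGenes=, variantFold=,
                        #      nPerVariant=, noisePrecision=)
    nProbes = 500,
    k = NULL,
    kRange = NULL,
    deconvolution = list(nRestarts = 10, tol = 1e-6, maxIter = 2000),
    grouping = list(nRuns = 3, depth = 1),
    de = list(foldChange = 2, q = 0.05),
    network = list(lambda = NULL, lambdaPath = NULL, nSubsamples = 20,
                   instabilityThreshold = 0.05, pseudocount = 1,
                   covariate = "all"))
  merge2 <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge2(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  if (!is.null(file)) config <- merge2(config, yaml::read_yaml(file))
  dots <- list(...)
  if (length(dots)) config <- merge2(config, dots)
  config
}

#' Run the full two-stage histoepigenetic analysis
#'
#' Executes, in order: input loading (files or simulator) -> probe
#' filtering -> informative-probe selection -> methylation deconvolution
#' (with stability-based choice of k when \code{kRange} is set) ->
#' cell-type matching -> gene-centered consensus grouping (recursively when
#' \code{grouping$depth > 1}) -> per-group expression deconvolution ->
#' differential-expression calling -> GGM fitting with proportion
#' covariate nodes (StARS penalty selection unless \code{network$lambda}
#' is fixed) -> covariate stripping -> strong edges, the gene's
#' first-order neighborhood, and connectedness of the differential gene
#' sets. All artifacts are written under \code{outputDir} and stamped with
#' the configuration hash; reruns with identical config and seed are
#' bit-identical.
#'
#' @param config list from [pipelineConfig()] (or a YAML path).
#' @return list of results (proportions, matching, grouping, DE tables,
#'   networks, connectedness, provenance), invisibly also written to disk.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- pipelineConfig(file = config)
  if (is.null(config$gene)) stop("config$gene (gene of interest) is required")
  if (is.null(config$outputDir)) stop("config$outputDir is required")
  if (is.null(config$inputs) == is.null(config$simulate))
    stop("exactly one of config$inputs or config$simulate must be provided")
  seed <- as.integer(config$seed)
  hash <- .config_hash(config)
  outDir <- config$outputDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  # ---- stage 0: inputs ------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    inp <- .stage("simulate", {
      panel <- generateReferencePanel(
        k = sim$k, nProbes = sim$nProbes, nGenes = sim$nGenes,
        variantFold = sim$variantFold %||% 10, seed = seed,
        variantGene = config$gene)
      mix <- simulateMixtures(
        panel, nPerVariant = sim$nPerVariant,
        noisePrecision = sim$noisePrecision %||% 100, seed = seed + 1L)
      list(meth = methMixtures(mix), expr = exprMixtures(mix),
           refMeth = methProfiles(panel), refClasses = panel@classLabels,
           blocklists = list(), covariates = NULL,
           truth = mixtureTruth(mix))
    })
    truth <- inp$truth
  } else {
    io <- config$inputs
    inp <- .stage("load-inputs", {
      for (f in c(io$methylation, io$expression, io$references))
        if (!file.exists(f)) stop(sprintf("input file not found: %s", f))
      refMeth <- readMatrixTSV(io$references)
      list(meth = readMatrixTSV(io$methylation),
           expr = readMatrixTSV(io$expression),
           refMeth = refMeth,
           refClasses = io$refClasses %||% colnames(refMeth),
           blocklists = lapply(io$blocklists %||% character(0), readBlocklist),
           covariates = if (!is.null(io$covariates))
             utils::read.table(io$covariates, sep = "\t", header = TRUE,
                               row.names = 1) else NULL)
    })
  }

  # ---- stage 1: preprocessing ----------------------------------------
  meth <- .stage("preprocess", {
    m <- filterProbes(inp$meth, blocklists = inp$blocklists)
    if (!is.null(inp$covariates))
      m <- filterProbesByCovariates(m, inp$covariates)
    m
  })

  # ---- stage 2: probe selection and methylation deconvolution --------
  probes <- .stage("select-probes", {
    sel <- selectInformativeProbes(inp$refMeth, inp$refClasses,
                                   nProbes = config$nProbes)
    intersect(sel, rownames(meth))
  })
  decon <- .stage("deconvolve-methylation", {
    B <- meth[probes, , drop = FALSE]
    k <- config$k
    if (!is.null(config$kRange)) {
      ch <- chooseNumCellTypes(B, config$kRange, seed = seed + 2L)
      k <- ch$k
      message(sprintf("selected k = %d by bootstrap stability", k))
    }
    if (is.null(k)) k <- length(unique(inp$refClasses))
    dc <- config$deconvolution
    deconvolveMethylation(B, k, nRestarts = dc$nRestarts, tol = dc$tol,
                          maxIter = dc$maxIter, seed = seed + 3L,
                          refProfiles = inp$refMeth[
                            intersect(rownames(B), rownames(inp$refMeth)), ,
                            drop = FALSE])
  })
  matching <- .stage("match-cell-types", {
    m <- matchCellTypes(decon, references = inp$refMeth)
    rownames(decon@P) <- colnames(decon@M) <- make.unique(m$labels)
    m
  })
  P <- cellProportions(decon)
  writeMatrixTSV(t(P), file.path(outDir, "proportions.tsv"), "sample")

  cancerType <- grep("cancer", rownames(P), value = TRUE)[1]
  if (is.na(cancerType)) cancerType <- NULL

  # ---- stage 3: gene-centered grouping -------------------------------
  grouping <- .stage("group", {
    depth <- config$grouping$depth %||% 1
    if (depth > 1) {
      part <- recursivePartition(inp$expr, P, config$gene, depth = depth,
                                 nRuns = config$grouping$nRuns,
                                 seed = seed + 4L, cancerType = cancerType)
      labels <- rep("mid", ncol(inp$expr))
      names(labels) <- colnames(inp$expr)
      labels[part$groups[[1]]] <- "high"
      labels[part$groups[[length(part$groups)]]] <- "low"
      list(labels = labels, partition = part, consensus = NULL)
    } else {
      cons <- consensusGrouping(inp$expr, P, config$gene,
                                nRuns = config$grouping$nRuns,
                                seed = seed + 4L, cancerType = cancerType)
      list(labels = consensusLabels(cons), partition = NULL,
           consensus = cons)
    }
  })
  labDF <- data.frame(sample = names(grouping$labels),
                      group = unname(grouping$labels), config = hash)
  utils::write.table(labDF, file.path(outDir, "group_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- stage 4: per-group expression deconvolution and DE ------------
  hiS <- names(grouping$labels)[grouping$labels == "high"]
  loS <- names(grouping$labels)[grouping$labels == "low"]
  de <- .stage("differential-expression", {
    eHi <- deconvolveExpression(inp$expr[, hiS, drop = FALSE],
                                P[, hiS, drop = FALSE])
    eLo <- deconvolveExpression(inp$expr[, loS, drop = FALSE],
                                P[, loS, drop = FALSE])
    tables <- lapply(colnames(eHi@E), function(ct)
      cellTypeTTest(eHi, eLo, ct))
    names(tables) <- colnames(eHi@E)
    calls <- lapply(tables, callDE, foldChange = config$de$foldChange,
                    qThreshold = config$de$q)
    for (ct in names(tables))
      utils::write.table(tables[[ct]],
                         file.path(outDir, sprintf("de_%s.tsv", ct)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    list(tables = tables, calls = calls, exprHi = eHi, exprLo = eLo)
  })

  # ---- stage 5: network ----------------------------------------------
  network <- .stage("network", {
    deGenes <- unique(unlist(de$calls))
    geneSubset <- union(config$gene, deGenes)
    if (length(geneSubset) < 5) {
      message("fewer than 5 differential genes; building the network over all genes")
      geneSubset <- rownames(inp$expr)
    }
    nw <- config$network
    lambda <- nw$lambda
    if (is.null(lambda)) {
      vars <- .ggm_variables(inp$expr, geneSubset, P, nw$pseudocount,
                             nw$covariate)
      path <- nw$lambdaPath %||% exp(seq(log(0.6), log(0.05), length.out = 8))
      lambda <- starsSelect(t(vars$X), path, nSubsamples = nw$nSubsamples,
                            instabilityThreshold = nw$instabilityThreshold,
                            seed = seed + 5L)$lambda
      message(sprintf("StARS selected lambda = %.4g", lambda))
    }
    full <- fitGGM(inp$expr, geneSubset, P, lambda = lambda,
                   pseudocount = nw$pseudocount, covariate = nw$covariate)
    genesOnly <- stripCovariateNodes(full)
    exportNetwork(genesOnly, file.path(outDir, "network_edges.tsv"),
                  file.path(outDir, "network_nodes.tsv"))
    neighborhood <- neighborSubgraph(genesOnly, config$gene, order = 1)
    strong <- strongEdges(genesOnly)
    conn <- lapply(de$calls[vapply(de$calls, function(cl)
      length(intersect(unlist(cl), nodeNames(genesOnly))) >= 2, logical(1))],
      function(cl) connectednessTest(
        genesOnly, intersect(unlist(cl), nodeNames(genesOnly)),
        seed = seed + 6L))
    list(full = full, genes = genesOnly, neighborhood = neighborhood,
         strong = strong, connectedness = conn, lambda = lambda)
  })

  provenance <- list(configHash = hash, seed = seed,
                     package = as.character(utils::packageVersion("histoepi")),
                     nSamples = ncol(inp$expr), nProbes = length(probes),
                     k = nrow(P), date = format(Sys.time(), "%Y-%m-%d"))
  jsonlite::write_json(provenance, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  res <- list(proportions = P, deconvolution = decon, matching = matching,
              grouping = grouping, de = de, network = network,
              truth = truth, provenance = provenance)
  class(res) <- "histoepiPipeline"
  invisible(res)
}

#' @export
print.histoepiPipeline <- function(x, ...) {
  cat("histoepi pipeline result\n")
  cat("  samples:", ncol(x$proportions), " cell types:",
      nrow(x$proportions), "\n")
  cat("  groups:", paste(names(table(x$grouping$labels)),
                         table(x$grouping$labels), sep = "=",
                         collapse = ", "), "\n")
  cat("  network:", length(nodeNames(x$network$genes)), "gene nodes,",
      nrow(edgeTable(x$network$genes)), "edges at lambda =",
      x$network$lambda, "\n")
  invisible(x)
}
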