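#' Write a feature-by-sample matrix as TSV
#'
#' First column holds the feature IDs, header row the sample IDs.
#'
#' @param x numeric matrix with rownames.
#' @param path output file path.
#' @param idColumn name of the feature-ID column (default "feature").
#' @return invisibly, the path.
#' @export
writeMatrixTSV <- function(x, path, idColumn = "feature") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample TSV matrix
#'
#' @param path TSV file whose first column holds feature IDs.
#' @return numeric matrix with feature rownames.
#' @export
readMatrixTSV <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Read a probe blocklist (one probe ID per line)
#'
#' @param path plain-text file.
#' @return character vector of probe IDs.
#' @export
readBlocklist <- function(path) {
  ids <- readLines(path)
  ids[nzchar(trimws(ids))]
}

#' Write a simulated mixture set with its ground truth
#'
#' Writes the methylation and expression mixtures as TSV (first column =
#' feature ID, header = sample IDs), the true proportions as a sidecar TSV
#' (samples x cell types), and a JSON metadata record with the seed and
#' simulation parameters.
#'
#' @param mix a [MixtureSet-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "mixtures").
#' @return invisibly, named vector of the written paths.
#' @export
writeMixtureSet <- function(mix, dir, prefix = "mixtures") {
  stopifnot(is(mix, "MixtureSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    methylation = file.path(dir, paste0(prefix, "_methylation.tsv")),
    expression = file.path(dir, paste0(prefix, "_expression.tsv")),
    truth = file.path(dir, paste0(prefix, "_true_proportions.tsv")),
    metadata = file.path(dir, paste0(prefix, "_metadata.json")))
  writeMatrixTSV(mix@methylation, paths["methylation"], "probe")
  writeMatrixTSV(mix@expression, paths["expression"], "gene")
  writeMatrixTSV(t(mix@truth@P), paths["truth"], "sample")
  meta <- list(seed = mix@truth@seed, alpha = mix@truth@alpha,
               noisePrecision = mix@truth@noisePrecision,
               assignedVariant = as.list(mix@truth@assignedVariant))
  jsonlite::write_json(meta, paths["metadata"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Export a network as an edge list plus node attribute table
#'
#' Writes a weighted edge-list TSV (nodeA, nodeB, weight, strong) and a
#' node table marking covariate flags — a GraphML-compatible attribute
#' layout that igraph or Cytoscape can ingest directly.
#'
#' @param net a [GGMNetwork-class].
#' @param edgePath,nodePath output TSV paths.
#' @param nSd strong-edge threshold passed to [edgeTable()].
#' @return invisibly, the two paths.
#' @export
exportNetwork <- function(net, edgePath, nodePath, nSd = 1) {
  stopifnot(is(net, "GGMNetwork"))
  utils::write.table(edgeTable(net, nSd = nSd), edgePath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nodes <- data.frame(node = net@nodes, covariate = net@covariate,
                      degree = rowSums(net@adjacency),
                      stringsAsFactors = FALSE)
  utils::write.table(nodes, nodePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edges = edgePath, nodes = nodePath))
}
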