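#' @include AllClasses.R
NULL

#' Extract the cell-type proportion matrix
#'
#' @param object a [MethDeconvolution-class], [MixtureTruth-class] or
#'   [MixtureSet-class] object.
#' @return numeric matrix, cell types x samples; columns on the simplex.
#' @export
setGeneric("cellProportions", function(object) standardGeneric("cellProportions"))

#' @rdname cellProportions
#' @export
setMethod("cellProportions", "MethDeconvolution", function(object) object@P)

#' @rdname cellProportions
#' @export
setMethod("cellProportions", "MixtureTruth", function(object) object@P)

#' @rdname cellProportions
#' @export
setMethod("cellProportions", "MixtureSet", function(object) object@truth@P)

#' Extract cell-type methylation profiles
#'
#' @param object a [MethDeconvolution-class] or [ReferencePanel-class].
#' @return numeric matrix, probes x cell types, beta values.
#' @export
setGeneric("methProfiles", function(object) standardGeneric("methProfiles"))

#' @rdname methProfiles
#' @export
setMethod("methProfiles", "MethDeconvolution", function(object) object@M)

#' @rdname methProfiles
#' @export
setMethod("methProfiles", "ReferencePanel", function(object) object@methProfiles)

#' Extract expression profiles or estimated means
#'
#' @param object a [CellTypeExpression-class] or [ReferencePanel-class].
#' @return numeric matrix, genes x cell types (or expression classes).
#' @export
setGeneric("exprMeans", function(object) standardGeneric("exprMeans"))

#' @rdname exprMeans
#' @export
setMethod("exprMeans", "CellTypeExpression", function(object) object@E)

#' @rdname exprMeans
#' @export
setMethod("exprMeans", "ReferencePanel", function(object) object@exprProfiles)

#' Extract standard errors of cell-type expression means
#'
#' @param object a [CellTypeExpression-class].
#' @return numeric matrix, genes x cell types.
#' @export
setGeneric("exprSE", function(object) standardGeneric("exprSE"))

#' @rdname exprSE
#' @export
setMethod("exprSE", "CellTypeExpression", function(object) object@S)

#' Extract the methylation mixture matrix
#'
#' @param object a [MixtureSet-class].
#' @return numeric matrix, probes x samples.
#' @export
setGeneric("methMixtures", function(object) standardGeneric("methMixtures"))

#' @rdname methMixtures
#' @export
setMethod("methMixtures", "MixtureSet", function(object) object@methylation)

#' Extract the expression mixture matrix
#'
#' @param object a [MixtureSet-class].
#' @return numeric matrix, genes x samples.
#' @export
setGeneric("exprMixtures", function(object) standardGeneric("exprMixtures"))

#' @rdname exprMixtures
#' @export
setMethod("exprMixtures", "MixtureSet", function(object) object@expression)

#' Extract the ground truth of a simulated mixture set
#'
#' @param object a [MixtureSet-class].
#' @return a [MixtureTruth-class] object.
#' @export
setGeneric("mixtureTruth", function(object) standardGeneric("mixtureTruth"))

#' @rdname mixtureTruth
#' @export
setMethod("mixtureTruth", "MixtureSet", function(object) object@truth)

#' Extract consensus sample labels
#'
#' @param object a [GroupingResult-class].
#' @return named character vector of "high"/"low" labels.
#' @export
setGeneric("consensusLabels",
           function(object) standardGeneric("consensusLabels"))

#' @rdname consensusLabels
#' @export
setMethod("consensusLabels", "GroupingResult",
          function(object) object@consensusLabels)

#' Extract node names of a network
#'
#' @param object a [GGMNetwork-class].
#' @param covariates logical; include covariate nodes (default TRUE).
#' @return character vector of node names.
#' @export
setGeneric("nodeNames",
           function(object, covariates = TRUE) standardGeneric("nodeNames"))

#' @rdname nodeNames
#' @export
setMethod("nodeNames", "GGMNetwork", function(object, covariates = TRUE) {
  if (covariates) object@nodes else object@nodes[!object@covariate]
})

#' Extract the boolean adjacency matrix of a network
#'
#' @param object a [GGMNetwork-class].
#' @return symmetric logical-valued matrix with zero diagonal.
#' @export
setGeneric("adjacencyMatrix",
           function(object) standardGeneric("adjacencyMatrix"))

#' @rdname adjacencyMatrix
#' @export
setMethod("adjacencyMatrix", "GGMNetwork", function(object) object@adjacency)

#' Extract the regularized partial-correlation matrix
#'
#' @param object a [GGMNetwork-class].
#' @return symmetric numeric matrix with unit diagonal;
#'   \code{rho_ij = -Theta_ij / sqrt(Theta_ii Theta_jj)}.
#' @export
setGeneric("partialCor", function(object) standardGeneric("partialCor"))

#' @rdname partialCor
#' @export
setMethod("partialCor", "GGMNetwork", function(object) object@rho)

#' Tabulate the edges of a network
#'
#' One row per undirected edge of the selected adjacency, with the signed
#' partial-correlation weight and the strong-edge flag (weight exceeding the
#' mean edge weight by at least \code{nSd} standard deviations).
#'
#' @param object a [GGMNetwork-class].
#' @param nSd numeric(1), strong-edge threshold in standard deviations.
#' @return data.frame with columns nodeA, nodeB, weight, strong.
#' @export
setGeneric("edgeTable", function(object, nSd = 1) standardGeneric("edgeTable"))
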