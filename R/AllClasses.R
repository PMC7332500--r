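#' @import methods
NULL

.check_beta <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)
}

#' ReferencePanel: labeled cell-type reference profiles
#'
#' Holds per-cell-type methylation archetypes (beta values) and expression
#' profiles. When two cancer variants are present, they share the cancer
#' methylation archetype but differ in the expression of one gene (the
#' variant gene) by a configured fold.
#'
#' @slot methProfiles numeric matrix, probes x cell types, beta values in
#'   \[0, 1\]; one column per methylation archetype.
#' @slot exprProfiles numeric matrix, genes x expression classes,
#'   nonnegative linear-scale values. With two cancer variants this has one
#'   more column than \code{methProfiles}.
#' @slot classLabels character, methylation archetype names (column names
#'   of \code{methProfiles}).
#' @slot variantGene character(1), gene whose expression separates the two
#'   cancer variants; \code{NA} when there is a single variant.
#' @slot variantFold numeric(1), expression fold between the two cancer
#'   variants at \code{variantGene}.
#' @exportClass ReferencePanel
setClass("ReferencePanel",
  representation(
    methProfiles = "matrix",
    exprProfiles = "matrix",
    classLabels = "character",
    variantGene = "character",
    variantFold = "numeric"
  )
)

setValidity("ReferencePanel", function(object) {
  msg <- character()
  if (!.check_beta(object@methProfiles))
    msg <- c(msg, "methProfiles must be finite beta values in [0, 1]")
  if (!all(is.finite(object@exprProfiles)) || any(object@exprProfiles < 0))
    msg <- c(msg, "exprProfiles must be finite and nonnegative")
  if (ncol(object@methProfiles) < 2)
    msg <- c(msg, "at least 2 cell-type classes are required")
  if (length(object@classLabels) != ncol(object@methProfiles))
    msg <- c(msg, "classLabels must match methProfiles columns")
  if (!is.na(object@variantGene)) {
    if (!object@variantGene %in% rownames(object@exprProfiles))
      msg <- c(msg, "variantGene must be a row of exprProfiles")
    hi <- grep("_hi$", colnames(object@exprProfiles), value = TRUE)
    lo <- grep("_lo$", colnames(object@exprProfiles), value = TRUE)
    if (length(hi) == 1L && length(lo) == 1L) {
      ehi <- object@exprProfiles[object@variantGene, hi]
      elo <- object@exprProfiles[object@variantGene, lo]
      if (elo <= 0 || abs(ehi / elo - object@variantFold) > 1e-6 * object@variantFold)
        msg <- c(msg, "cancer variants must differ at variantGene by variantFold")
    }
  }
  if (length(msg)) msg else TRUE
})

#' MixtureTruth: ground truth of a simulated mixture set
#'
#' @slot P numeric matrix, cell types x samples; every column on the
#'   probability simplex.
#' @slot assignedVariant character, per-sample cancer-variant label.
#' @slot alpha numeric, Dirichlet concentration used for mixing.
#' @slot noisePrecision numeric(1), Beta-noise concentration applied to the
#'   methylation references (\code{NA} for noiseless mixing).
#' @slot seed integer(1), RNG seed used by the simulator.
#' @exportClass MixtureTruth
setClass("MixtureTruth",
  representation(
    P = "matrix",
    assignedVariant = "character",
    alpha = "numeric",
    noisePrecision = "numeric",
    seed = "integer"
  )
)

setValidity("MixtureTruth", function(object) {
  msg <- character()
  if (any(object@P < 0)) msg <- c(msg, "proportions must be nonnegative")
  if (any(abs(colSums(object@P) - 1) > 1e-12))
    msg <- c(msg, "proportion columns must sum to 1 within 1e-12")
  if (length(object@assignedVariant) != ncol(object@P))
    msg <- c(msg, "assignedVariant must cover every sample")
  if (length(msg)) msg else TRUE
})

#' MixtureSet: paired methylation/expression mixtures with ground truth
#'
#' @slot methylation numeric matrix, probes x samples, beta values.
#' @slot expression numeric matrix, genes x samples, linear-scale values.
#' @slot truth a [MixtureTruth-class] object.
#' @exportClass MixtureSet
setClass("MixtureSet",
  representation(
    methylation = "matrix",
    expression = "matrix",
    truth = "MixtureTruth"
  )
)

setValidity("MixtureSet", function(object) {
  msg <- character()
  if (!.check_beta(object@methylation))
    msg <- c(msg, "methylation mixtures must be beta values in [0, 1]")
  if (ncol(object@methylation) != ncol(object@expression) ||
      ncol(object@methylation) != ncol(object@truth@P))
    msg <- c(msg, "methylation, expression and truth must share samples")
  if (length(msg)) msg else TRUE
})

#' MethDeconvolution: constrained factorization of bulk methylation
#'
#' Result of factoring a bulk beta-value matrix B into cell-type methylation
#' profiles M (probes x k, entries in \[0, 1\]) and per-sample proportions P
#' (k x samples, columns on the simplex), minimizing ||B - M P||_F^2.
#'
#' @slot M numeric matrix, probes x k cell-type methylation profiles.
#' @slot P numeric matrix, k x samples proportions.
#' @slot restartRSS numeric, final residual sum of squares per restart.
#' @slot rssTrace numeric, RSS per iteration of the best restart.
#' @slot nIter integer(1), iterations used by the best restart.
#' @slot converged logical(1), convergence flag of the best restart.
#' @exportClass MethDeconvolution
setClass("MethDeconvolution",
  representation(
    M = "matrix",
    P = "matrix",
    restartRSS = "numeric",
    rssTrace = "numeric",
    nIter = "integer",
    converged = "logical"
  )
)

setValidity("MethDeconvolution", function(object) {
  msg <- character()
  if (!.check_beta(object@M))
    msg <- c(msg, "M must contain beta values in [0, 1]")
  if (any(object@P < 0) || any(abs(colSums(object@P) - 1) > 1e-8))
    msg <- c(msg, "P columns must be on the probability simplex (tol 1e-8)")
  if (ncol(object@M) != nrow(object@P))
    msg <- c(msg, "M columns must match P rows")
  if (length(msg)) msg else TRUE
})

#' CellTypeExpression: per-cell-type expression means and standard errors
#'
#' Estimated by regressing each gene's bulk values on fixed cell-type
#' proportions under a nonnegativity constraint; standard errors come from
#' the ordinary-least-squares covariance formula with residual degrees of
#' freedom nu = n_samples - k.
#'
#' @slot E numeric matrix, genes x k expression means (nonnegative unless
#'   fitted unconstrained).
#' @slot S numeric matrix, genes x k standard errors.
#' @slot nu numeric(1), residual degrees of freedom.
#' @slot nSamples integer(1), number of samples used in the regression.
#' @slot active logical matrix, genes x k; TRUE where the nonnegativity
#'   constraint was active (estimate pinned at zero).
#' @exportClass CellTypeExpression
setClass("CellTypeExpression",
  representation(
    E = "matrix",
    S = "matrix",
    nu = "numeric",
    nSamples = "integer",
    active = "matrix"
  )
)

setValidity("CellTypeExpression", function(object) {
  msg <- character()
  if (!identical(dim(object@E), dim(object@S)))
    msg <- c(msg, "E and S must have identical dimensions")
  if (any(object@S < 0, na.rm = TRUE))
    msg <- c(msg, "standard errors must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' GroupingResult: consensus sample grouping around a gene of interest
#'
#' @slot labelsPerRun character matrix, samples x runs of "high"/"low"
#'   labels (aligned across runs by estimated cancer-cell gene level).
#' @slot consensusLabels named character, majority-vote label per sample.
#' @slot agreement named numeric, per-sample fraction of runs agreeing with
#'   the consensus.
#' @slot nIterationsPerRun integer, iterations used by each run.
#' @slot converged logical, per-run convergence flags.
#' @slot gene character(1), gene of interest.
#' @slot groupGeneLevels named numeric, estimated cancer-cell expression of
#'   the gene per consensus group (high > low).
#' @exportClass GroupingResult
setClass("GroupingResult",
  representation(
    labelsPerRun = "matrix",
    consensusLabels = "character",
    agreement = "numeric",
    nIterationsPerRun = "integer",
    converged = "logical",
    gene = "character",
    groupGeneLevels = "numeric"
  )
)

setValidity("GroupingResult", function(object) {
  msg <- character()
  if (!all(object@consensusLabels %in% c("high", "low")))
    msg <- c(msg, "consensus labels must be 'high' or 'low'")
  if (length(object@consensusLabels) == 0)
    msg <- c(msg, "consensus must be defined for every sample")
  if (all(c("high", "low") %in% names(object@groupGeneLevels)) &&
      !is.na(object@groupGeneLevels["high"]) &&
      !is.na(object@groupGeneLevels["low"]) &&
      object@groupGeneLevels["high"] < object@groupGeneLevels["low"])
    msg <- c(msg, "group gene levels must order the labels (high >= low)")
  if (length(msg)) msg else TRUE
})

#' GGMNetwork: sparse Gaussian graphical model over genes and covariates
#'
#' @slot nodes character, node names (genes, plus covariate nodes carrying
#'   cell-proportion values).
#' @slot covariate logical, TRUE for covariate (cell-proportion) nodes.
#' @slot lambda numeric(1), graphical-lasso penalty.
#' @slot Theta numeric matrix, estimated precision matrix (symmetric,
#'   positive definite).
#' @slot rho numeric matrix, partial correlations
#'   rho_ij = -Theta_ij / sqrt(Theta_ii Theta_jj); unit diagonal.
#' @slot adjacency logical matrix, edge indicator from the off-diagonal
#'   support of Theta; symmetric with zero diagonal.
#' @slot muW numeric(1), mean of the signed weights of existing edges.
#' @slot sigmaW numeric(1), standard deviation of those weights.
#' @exportClass GGMNetwork
setClass("GGMNetwork",
  representation(
    nodes = "character",
    covariate = "logical",
    lambda = "numeric",
    Theta = "matrix",
    rho = "matrix",
    adjacency = "matrix",
    muW = "numeric",
    sigmaW = "numeric"
  )
)

setValidity("GGMNetwork", function(object) {
  msg <- character()
  p <- length(object@nodes)
  if (!all(dim(object@Theta) == p) || !all(dim(object@adjacency) == p))
    msg <- c(msg, "Theta and adjacency must be p x p for p nodes")
  if (p > 0) {
    if (max(abs(object@Theta - t(object@Theta))) > 1e-8)
      msg <- c(msg, "Theta must be symmetric")
    if (any(diag(object@adjacency) != 0))
      msg <- c(msg, "adjacency diagonal must be zero")
    if (!isTRUE(all.equal(object@adjacency, t(object@adjacency))))
      msg <- c(msg, "adjacency must be symmetric")
    if (max(abs(diag(object@rho) - 1)) > 1e-8)
      msg <- c(msg, "partial correlation diagonal must be 1")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReferencePanel", function(object) {
  cat("ReferencePanel:", ncol(object@methProfiles), "methylation archetypes,",
      ncol(object@exprProfiles), "expression classes\n")
  cat("  probes:", nrow(object@methProfiles),
      " genes:", nrow(object@exprProfiles), "\n")
  if (!is.na(object@variantGene))
    cat("  variant gene:", object@variantGene,
        sprintf("(fold %.3g between cancer variants)\n", object@variantFold))
})

setMethod("show", "MixtureSet", function(object) {
  cat("MixtureSet:", ncol(object@methylation), "samples;",
      nrow(object@methylation), "probes,", nrow(object@expression), "genes\n")
  cat("  variants:", paste(names(table(object@truth@assignedVariant)),
                           table(object@truth@assignedVariant),
                           sep = "=", collapse = ", "), "\n")
})

setMethod("show", "MethDeconvolution", function(object) {
  cat("MethDeconvolution: k =", ncol(object@M), "cell types,",
      ncol(object@P), "samples\n")
  cat(sprintf("  best RSS %.6g over %d restart(s); %d iterations; converged: %s\n",
              min(object@restartRSS), length(object@restartRSS),
              object@nIter, object@converged))
})

setMethod("show", "CellTypeExpression", function(object) {
  cat("CellTypeExpression:", nrow(object@E), "genes x", ncol(object@E),
      "cell types; nu =", object@nu, "\n")
})

setMethod("show", "GroupingResult", function(object) {
  tab <- table(object@consensusLabels)
  cat("GroupingResult for gene", object@gene, "\n")
  cat("  consensus:", paste(names(tab), tab, sep = "=", collapse = ", "),
      sprintf("; mean agreement %.3f\n", mean(object@agreement)))
  cat(sprintf("  cancer-cell gene level: high %.4g, low %.4g\n",
              object@groupGeneLevels["high"], object@groupGeneLevels["low"]))
})

setMethod("show", "GGMNetwork", function(object) {
  ne <- sum(object@adjacency[upper.tri(object@adjacency)])
  cat("GGMNetwork:", length(object@nodes), "nodes (",
      sum(object@covariate), "covariate ),", ne,
      "edges at lambda =", object@lambda, "\n")
  if (ne >= 2)
    cat(sprintf("  edge weights: mu = %.5g, sigma = %.5g\n",
                object@muW, object@sigmaW))
})
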