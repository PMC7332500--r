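#' @include glasso.R AllClasses.R
NULL

# assemble the standardized variables-x-samples matrix for the GGM stage
.ggm_variables <- function(G, geneSubset, P, pseudocount,
                           covariate = c("all", "drop-one", "none")) {
  covariate <- match.arg(covariate)
  G <- as.matrix(G)
  missing <- setdiff(geneSubset, rownames(G))
  if (length(missing))
    stop(sprintf("gene(s) not in G: %s", paste(missing, collapse = ", ")))
  X <- log2(G[geneSubset, , drop = FALSE] + pseudocount)
  covFlag <- rep(FALSE, nrow(X))
  if (!is.null(P) && covariate != "none") {
    if (is(P, "MethDeconvolution") || is(P, "MixtureTruth")) P <- P@P
    P <- as.matrix(P)
    if (ncol(P) != ncol(X)) stop("'P' columns must align with 'G' columns")
    if (is.null(rownames(P))) rownames(P) <- paste0("ct", seq_len(nrow(P)))
    if (covariate == "drop-one") P <- P[-nrow(P), , drop = FALSE]
    rownames(P) <- paste0("prop:", rownames(P))
    X <- rbind(X, P)
    covFlag <- c(covFlag, rep(TRUE, nrow(P)))
  }
  if (any(!is.finite(X))) stop("non-finite values in the network variables")
  v <- apply(X, 1, stats::var)
  if (any(v < 1e-12)) {
    warning(sprintf("dropping %d zero-variance variable(s)", sum(v < 1e-12)))
    covFlag <- covFlag[v >= 1e-12]
    X <- X[v >= 1e-12, , drop = FALSE]
  }
  X <- t(scale(t(X)))  # zero mean, unit variance per variable
  list(X = X, covariate = covFlag)
}

# build a GGMNetwork from a precision matrix
.ggm_from_theta <- function(Theta, nodes, covFlag, lambda) {
  rho <- .partial_cor(Theta)
  adj <- abs(Theta) > 1e-10
  diag(adj) <- FALSE
  adj <- adj | t(adj)
  mode(adj) <- "logical"
  w <- rho[upper.tri(rho)][adj[upper.tri(adj)]]
  dimnames(Theta) <- dimnames(rho) <- dimnames(adj) <- list(nodes, nodes)
  new("GGMNetwork", nodes = nodes, covariate = covFlag, lambda = lambda,
      Theta = Theta, rho = rho, adjacency = adj,
      muW = if (length(w)) mean(w) else NA_real_,
      sigmaW = if (length(w) >= 2) stats::sd(w) else NA_real_)
}

#' Fit a Gaussian graphical model over genes plus proportion covariates
#'
#' Variables are the log2-transformed (pseudocount-added) expression rows
#' of the selected genes PLUS the cell-proportion rows of P as
#' covariate-flagged nodes; all variables are standardized and the sparse
#' precision matrix is estimated by [graphicalLasso()] on their correlation
#' matrix. Edge weights are the signed regularized partial correlations.
#' Including the proportion nodes lets composition-driven covariation be
#' absorbed by gene-covariate edges instead of spurious gene-gene edges.
#'
#' @param G numeric matrix, genes x samples, linear-scale expression.
#' @param geneSubset character, genes to include as nodes.
#' @param P cell-type proportion matrix (or NULL for no covariate nodes).
#' @param lambda numeric(1) > 0, graphical-lasso penalty.
#' @param pseudocount numeric(1) added before log2 (default 1).
#' @param covariate "all" (every proportion row; default), "drop-one"
#'   (omit the last cell type to avoid simplex collinearity), or "none".
#' @return a [GGMNetwork-class].
#' @export
fitGGM <- function(G, geneSubset, P = NULL, lambda, pseudocount = 1,
                   covariate = c("all", "drop-one", "none")) {
  if (length(geneSubset) == 0) stop("'geneSubset' must be nonempty")
  if (!is.numeric(lambda) || lambda <= 0) stop("'lambda' must be > 0")
  if (ncol(as.matrix(G)) <= 2) stop("need more than 2 samples")
  vars <- .ggm_variables(G, geneSubset, P, pseudocount, covariate)
  S <- stats::cor(t(vars$X))
  fit <- graphicalLasso(S, lambda)
  .ggm_from_theta(fit$Theta, rownames(vars$X), vars$covariate, lambda)
}

#' StARS: stability-based selection of the graphical-lasso penalty
#'
#' For each penalty on a decreasing path, the graph is fitted on
#' \code{nSubsamples} random subsamples of size \code{floor(10 sqrt(n))};
#' per-edge selection frequencies f give edge instabilities 2f(1 - f),
#' averaged over all off-diagonal pairs into the graph instability. After
#' monotonizing the instability along the path (from the largest penalty
#' down), the selected penalty is the smallest one whose monotonized
#' instability stays at or below the threshold. A fixed-penalty override
#' bypasses selection entirely.
#'
#' @param X numeric matrix, samples x variables (already transformed).
#' @param lambdaPath decreasing numeric vector of penalties.
#' @param nSubsamples integer(1), subsamples per penalty (default 20).
#' @param instabilityThreshold numeric(1), default 0.05.
#' @param seed integer(1), RNG seed for subsampling.
#' @param fixedLambda numeric(1) or NULL; when given (e.g. 0.125) it is
#'   returned as the selection without subsampling.
#' @return list with \code{lambda} (selected), \code{instability} (raw per
#'   penalty), \code{monotone} (monotonized), \code{lambdaPath}.
#' @export
starsSelect <- function(X, lambdaPath, nSubsamples = 20,
                        instabilityThreshold = 0.05, seed = 1L,
                        fixedLambda = NULL) {
  if (!is.null(fixedLambda)) {
    return(list(lambda = fixedLambda, instability = NULL, monotone = NULL,
                lambdaPath = lambdaPath, fixed = TRUE))
  }
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 20) stop("StARS needs at least 20 samples")
  if (is.unsorted(rev(lambdaPath))) stop("'lambdaPath' must be decreasing")
  b <- min(n - 1L, floor(10 * sqrt(n)))
  nPairs <- p * (p - 1) / 2

  freq <- .with_seed(seed, function() {
    counts <- matrix(0, length(lambdaPath), nPairs)
    for (s in seq_len(nSubsamples)) {
      idx <- sample.int(n, b)
      S <- stats::cor(X[idx, , drop = FALSE])
      for (li in seq_along(lambdaPath)) {
        Theta <- graphicalLasso(S, lambdaPath[li])$Theta
        adj <- abs(Theta[upper.tri(Theta)]) > 1e-10
        counts[li, ] <- counts[li, ] + adj
      }
    }
    counts / nSubsamples
  })

  instab <- rowMeans(2 * freq * (1 - freq))
  monotone <- cummax(instab)  # path is decreasing in lambda
  ok <- monotone <= instabilityThreshold
  if (any(ok)) {
    lambda <- min(lambdaPath[ok])
  } else {
    lambda <- lambdaPath[1]
    warning("all penalties exceed the instability threshold; returning the largest")
  }
  list(lambda = lambda, instability = instab, monotone = monotone,
       lambdaPath = lambdaPath, fixed = FALSE)
}

#' Remove covariate nodes from a fitted network
#'
#' Restricts the network to its non-covariate (gene) nodes. The precision
#' and partial-correlation submatrices are retained as-is (no refit), so
#' gene-gene edge weights are bit-identical before and after; the
#' edge-weight statistics are recomputed over the remaining edges.
#' Idempotent: stripping twice equals stripping once.
#'
#' @param net a [GGMNetwork-class].
#' @return a [GGMNetwork-class] without covariate nodes.
#' @export
stripCovariateNodes <- function(net) {
  stopifnot(is(net, "GGMNetwork"))
  if (!any(net@covariate)) {
    warning("network has no covariate nodes; returning it unchanged")
    return(net)
  }
  keep <- which(!net@covariate)
  Theta <- net@Theta[keep, keep, drop = FALSE]
  rho <- net@rho[keep, keep, drop = FALSE]
  adj <- net@adjacency[keep, keep, drop = FALSE]
  w <- rho[upper.tri(rho)][adj[upper.tri(adj)]]
  new("GGMNetwork", nodes = net@nodes[keep],
      covariate = rep(FALSE, length(keep)), lambda = net@lambda,
      Theta = Theta, rho = rho, adjacency = adj,
      muW = if (length(w)) mean(w) else NA_real_,
      sigmaW = if (length(w) >= 2) stats::sd(w) else NA_real_)
}

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "GGMNetwork", function(object, nSd = 1) {
  ut <- upper.tri(object@adjacency)
  idx <- which(object@adjacency & ut, arr.ind = TRUE)
  w <- object@rho[cbind(idx[, 1], idx[, 2])]
  strong <- if (length(w) >= 2) {
    w > mean(w) + nSd * stats::sd(w)
  } else rep(FALSE, length(w))
  data.frame(nodeA = object@nodes[idx[, 1]],
             nodeB = object@nodes[idx[, 2]],
             weight = w, strong = strong,
             stringsAsFactors = FALSE)
})

#' Strong edges of a network
#'
#' Computes the mean and standard deviation of the signed weights of the
#' existing (nonzero) edges and returns the edges whose weight exceeds the
#' mean by at least \code{nSd} standard deviations
#' (\code{weight > mu_w + nSd * sigma_w}).
#'
#' @param net a [GGMNetwork-class].
#' @param nSd numeric(1), number of standard deviations (default 1).
#' @return data.frame (nodeA, nodeB, weight) of strong edges; empty with a
#'   warning when the network has fewer than 2 edges.
#' @export
strongEdges <- function(net, nSd = 1) {
  stopifnot(is(net, "GGMNetwork"))
  edges <- edgeTable(net, nSd = nSd)
  if (nrow(edges) < 2) {
    warning("fewer than 2 edges; no strong-edge statistics")
    return(edges[integer(0), c("nodeA", "nodeB", "weight")])
  }
  edges[edges$strong, c("nodeA", "nodeB", "weight")]
}

#' Permutation test of node-set connectedness (modularity)
#'
#' Observed statistic: number of edges in the subgraph induced by the
#' query node set. Null: edge counts of \code{nPerm} uniformly drawn node
#' sets of the same size. The p-value is
#' \code{(1 + #\{null >= observed\}) / (nPerm + 1)}. This is a permutation
#' edge-count statistic for module significance; it is not the CTD
#' encoding-length algorithm.
#'
#' @param net a [GGMNetwork-class].
#' @param nodeSet character, nodes of interest (>= 2, all in the network).
#' @param nPerm integer(1), permutations (default 10000).
#' @param seed integer(1), RNG seed.
#' @return list with \code{observed} (induced edge count), \code{p},
#'   \code{nPerm}, \code{nullMean}.
#' @export
connectednessTest <- function(net, nodeSet, nPerm = 10000, seed = 1L) {
  stopifnot(is(net, "GGMNetwork"))
  nodeSet <- unique(as.character(nodeSet))
  if (length(nodeSet) < 2) stop("'nodeSet' must contain at least 2 nodes")
  idx <- match(nodeSet, net@nodes)
  if (any(is.na(idx))) stop("all query nodes must be in the network")
  A <- net@adjacency * 1
  p <- length(net@nodes)
  m <- length(idx)
  if (m > p) stop("node set larger than the network")
  observed <- sum(A[idx, idx]) / 2

  null <- .with_seed(seed, function() {
    vapply(seq_len(nPerm), function(i) {
      s <- sample.int(p, m)
      sum(A[s, s]) / 2
    }, numeric(1))
  })
  list(observed = observed,
       p = (1 + sum(null >= observed)) / (nPerm + 1),
       nPerm = nPerm, nullMean = mean(null))
}

#' Edge enrichment of a node's neighborhood in a target set
#'
#' Hypergeometric upper-tail test of whether the node's neighbors overlap
#' the target set more than expected: universe = all other nodes,
#' K = target-set size, n = node degree, x = neighbors inside the target
#' set (delegates to [hypergeomOverlap()]).
#'
#' @param net a [GGMNetwork-class].
#' @param node character(1), node of interest.
#' @param targetSet character, candidate interactor nodes (excluding
#'   \code{node}).
#' @return list as returned by [hypergeomOverlap()]; degree 0 gives p = 1.
#' @export
edgeEnrichment <- function(net, node, targetSet) {
  stopifnot(is(net, "GGMNetwork"))
  i <- match(node, net@nodes)
  if (is.na(i)) stop(sprintf("node '%s' not in the network", node))
  targetSet <- setdiff(unique(as.character(targetSet)), node)
  if (!all(targetSet %in% net@nodes))
    stop("target set must be a subset of the network nodes")
  universe <- setdiff(net@nodes, node)
  neighbors <- net@nodes[net@adjacency[i, ]]
  hypergeomOverlap(neighbors, targetSet, universe)
}

#' Neighborhood subnetwork of a node
#'
#' Induced subnetwork on the node plus all nodes within graph distance
#' \code{order} (order 0 gives the singleton; order >= diameter gives the
#' whole connected component).
#'
#' @param net a [GGMNetwork-class].
#' @param node character(1), center node.
#' @param order integer(1) >= 0, neighborhood order (default 1).
#' @return a [GGMNetwork-class] restricted to the neighborhood.
#' @export
neighborSubgraph <- function(net, node, order = 1) {
  stopifnot(is(net, "GGMNetwork"))
  i <- match(node, net@nodes)
  if (is.na(i)) stop(sprintf("node '%s' not in the network", node))
  reach <- i
  frontier <- i
  d <- 0
  while (d < order && length(frontier)) {
    nxt <- which(rowSums(net@adjacency[, frontier, drop = FALSE]) > 0)
    frontier <- setdiff(nxt, reach)
    reach <- union(reach, frontier)
    d <- d + 1
  }
  keep <- sort(reach)
  Theta <- net@Theta[keep, keep, drop = FALSE]
  rho <- net@rho[keep, keep, drop = FALSE]
  adj <- net@adjacency[keep, keep, drop = FALSE]
  w <- rho[upper.tri(rho)][adj[upper.tri(adj)]]
  new("GGMNetwork", nodes = net@nodes[keep], covariate = net@covariate[keep],
      lambda = net@lambda, Theta = Theta, rho = rho, adjacency = adj,
      muW = if (length(w)) mean(w) else NA_real_,
      sigmaW = if (length(w) >= 2) stats::sd(w) else NA_real_)
}
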