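#' @include deconv-expression.R
NULL

# Cell-type expression of a single gene within one sample group:
# nonnegative regression of the gene's bulk values on the group's
# proportion columns.
.gene_level <- function(gRow, Psub) {
  drop(cpp_nnls_rows(matrix(gRow, nrow = 1), Psub))
}

#' Iterative group fit around a gene of interest
#'
#' The core partitioning algorithm: (1) samples are randomly split into two
#' groups; (2) each group's cell-type-specific expression of the gene is
#' estimated by proportion-conditioned regression; (3) for each sample and
#' each group, the predicted bulk value of the gene is the linear
#' combination of the sample's proportions with that group's cell-type
#' profile, and the distance is the absolute difference from the sample's
#' observed bulk value; (4) each sample is reassigned to the group with the
#' shorter distance (ties keep the current group); steps 2-4 repeat until
#' no sample is reassigned or \code{maxIter}. A group shrinking below
#' \code{k + 1} samples triggers a fresh random split (at most
#' \code{maxRestarts}).
#'
#' @param G numeric matrix, genes x samples, bulk linear-scale expression.
#' @param P numeric matrix, cell types x samples (or a
#'   [MethDeconvolution-class]).
#' @param gene character(1), row of G to group around.
#' @param seed integer(1), RNG seed for the initial split.
#' @param maxIter integer(1), iteration cap (0 returns the initial random
#'   split, unconverged).
#' @param maxRestarts integer(1), fresh-split attempts when a group empties.
#' @return list with \code{labels} (named integer 1/2), \code{nIter},
#'   \code{converged}, \code{geneLevels} (2 x k matrix, per-group
#'   cell-type expression of the gene) and \code{totalDistance}.
#' @export
iterativeGroupFit <- function(G, P, gene, seed = 1L, maxIter = 100,
                              maxRestarts = 10) {
  if (is(P, "MethDeconvolution") || is(P, "MixtureTruth")) P <- P@P
  G <- as.matrix(G); P <- as.matrix(P)
  if (!gene %in% rownames(G)) stop(sprintf("gene '%s' not found in G", gene))
  n <- ncol(G)
  k <- nrow(P)
  minGroup <- k + 1L
  if (n < 2 * minGroup)
    stop("each prospective group must have more than k samples")
  samples <- colnames(G)
  if (is.null(samples)) samples <- paste0("s", seq_len(n))
  gRow <- G[gene, ]

  fitOnce <- function(restart) .with_seed(seed + restart, function() {
    labels <- rep(1L, n)
    labels[sample.int(n, floor(n / 2))] <- 2L
    converged <- FALSE
    it <- 0L
    totalDist <- NA_real_
    levels <- NULL
    while (it < maxIter) {
      it <- it + 1L
      levels <- rbind(.gene_level(gRow[labels == 1L], P[, labels == 1L, drop = FALSE]),
                      .gene_level(gRow[labels == 2L], P[, labels == 2L, drop = FALSE]))
      pred <- levels %*% P                      # 2 x n predicted bulk values
      d <- abs(sweep(pred, 2, gRow))            # distances to observed bulk
      newLabels <- ifelse(d[1, ] < d[2, ], 1L,
                          ifelse(d[2, ] < d[1, ], 2L, labels))
      if (min(table(factor(newLabels, levels = 1:2))) < minGroup)
        return(NULL)                            # degenerate: ask for restart
      moved <- sum(newLabels != labels)
      labels <- newLabels
      totalDist <- sum(d[cbind(labels, seq_len(n))])
      if (moved == 0L) { converged <- TRUE; break }
    }
    if (is.null(levels))
      levels <- rbind(.gene_level(gRow[labels == 1L], P[, labels == 1L, drop = FALSE]),
                      .gene_level(gRow[labels == 2L], P[, labels == 2L, drop = FALSE]))
    names(labels) <- samples
    rownames(levels) <- c("group1", "group2")
    colnames(levels) <- rownames(P)
    list(labels = labels, nIter = it, converged = converged,
         geneLevels = levels, totalDistance = totalDist)
  })

  for (restart in 0:maxRestarts) {
    res <- fitOnce(restart)
    if (!is.null(res)) {
      if (restart > 0)
        message(sprintf("iterativeGroupFit: restarted %d time(s) after a group emptied",
                        restart))
      return(res)
    }
  }
  stop("iterativeGroupFit: groups kept shrinking below k + 1 samples after all restarts")
}

#' Consensus grouping over repeated iterative group fits
#'
#' Runs [iterativeGroupFit()] \code{nRuns} times (odd, for a strict
#' majority) with derived seeds, aligns each run's two groups by the
#' estimated cancer-cell expression of the gene (the group with the higher
#' level is "high"), and takes the per-sample majority label. The cancer
#' cell type is \code{cancerType} when given; otherwise the cell type with
#' the maximal pooled expression of the gene is used, with a message.
#'
#' @param G,P,gene as in [iterativeGroupFit()].
#' @param nRuns odd integer(1), number of complete rounds (default 3).
#' @param seed integer(1); run r uses \code{seed + 101 * (r - 1)}.
#' @param cancerType character(1) or integer(1), designated cancer cell
#'   type (row of P); NULL for automatic choice.
#' @param maxIter,maxRestarts passed to [iterativeGroupFit()].
#' @return a [GroupingResult-class]. Unconverged runs are included but
#'   flagged; an error is raised if no run converges.
#' @export
consensusGrouping <- function(G, P, gene, nRuns = 3, seed = 1L,
                              cancerType = NULL, maxIter = 100,
                              maxRestarts = 10) {
  if (is(P, "MethDeconvolution") || is(P, "MixtureTruth")) P <- P@P
  G <- as.matrix(G); P <- as.matrix(P)
  if (nRuns %% 2 == 0) stop("'nRuns' must be odd for a strict majority")
  ctNames <- rownames(P)
  if (is.null(ctNames)) ctNames <- paste0("ct", seq_len(nrow(P)))

  if (is.null(cancerType)) {
    pooled <- .gene_level(G[gene, ], P)
    cancerIdx <- which.max(pooled)
    message(sprintf("consensusGrouping: no cancer type designated; using '%s' (maximal %s expression)",
                    ctNames[cancerIdx], gene))
  } else {
    cancerIdx <- if (is.character(cancerType)) match(cancerType, ctNames)
                 else as.integer(cancerType)
    if (is.na(cancerIdx) || cancerIdx < 1 || cancerIdx > nrow(P))
      stop("'cancerType' does not name a row of P")
  }

  runs <- lapply(seq_len(nRuns), function(r)
    iterativeGroupFit(G, P, gene, seed = seed + 101L * (r - 1L),
                      maxIter = maxIter, maxRestarts = maxRestarts))
  conv <- vapply(runs, `[[`, logical(1), "converged")
  if (!any(conv)) stop("no run of the iterative group fit converged")
  if (!all(conv)) warning(sprintf("%d of %d runs did not converge", sum(!conv), nRuns))

  n <- ncol(G)
  samples <- names(runs[[1]]$labels)
  aligned <- vapply(runs, function(r) {
    lev <- r$geneLevels[, cancerIdx]
    hiGroup <- which.max(lev)
    ifelse(r$labels == hiGroup, "high", "low")
  }, character(n))
  rownames(aligned) <- samples

  votesHigh <- rowSums(aligned == "high")
  consensus <- ifelse(votesHigh * 2 > nRuns, "high", "low")
  names(consensus) <- samples
  agreement <- ifelse(consensus == "high", votesHigh, nRuns - votesHigh) / nRuns
  names(agreement) <- samples

  levHigh <- if (any(consensus == "high"))
    .gene_level(G[gene, consensus == "high"],
                P[, consensus == "high", drop = FALSE])[cancerIdx] else NA_real_
  levLow <- if (any(consensus == "low"))
    .gene_level(G[gene, consensus == "low"],
                P[, consensus == "low", drop = FALSE])[cancerIdx] else NA_real_

  new("GroupingResult",
      labelsPerRun = aligned,
      consensusLabels = consensus,
      agreement = agreement,
      nIterationsPerRun = vapply(runs, function(r) as.integer(r$nIter), integer(1)),
      converged = conv,
      gene = gene,
      groupGeneLevels = c(high = levHigh, low = levLow))
}

#' Recursive partition by repeated consensus splitting of the low group
#'
#' Applies [consensusGrouping()], keeps the high group, and recursively
#' re-splits the low group \code{depth - 1} more times, yielding
#' \code{depth + 1} groups ordered from highest to lowest cancer-cell
#' expression of the gene. The natural comparison pair is the first versus
#' the last group. Recursion stops early (with a message) when the low
#' group is too small to split.
#'
#' @param G,P,gene,nRuns,seed,cancerType as in [consensusGrouping()].
#' @param depth integer(1) >= 1, number of splits (default 2, giving 3
#'   groups).
#' @param ... passed to [consensusGrouping()].
#' @return list with \code{groups} (list of sample-ID vectors, highest to
#'   lowest) and \code{geneLevels} (cancer-cell gene expression per group).
#' @export
recursivePartition <- function(G, P, gene, depth = 2, nRuns = 3, seed = 1L,
                               cancerType = NULL, ...) {
  if (is(P, "MethDeconvolution") || is(P, "MixtureTruth")) P <- P@P
  G <- as.matrix(G); P <- as.matrix(P)
  if (depth < 1) stop("'depth' must be >= 1")
  k <- nrow(P)
  samples <- colnames(G)
  if (is.null(samples)) {
    samples <- paste0("s", seq_len(ncol(G)))
    colnames(G) <- samples
    colnames(P) <- samples
  }

  groups <- list()
  levels <- numeric(0)
  current <- samples
  lastLowLevel <- NA_real_
  for (d in seq_len(depth)) {
    if (length(current) < 2 * (k + 1)) {
      message("recursivePartition: low group too small to split; stopping early")
      break
    }
    res <- consensusGrouping(G[, current, drop = FALSE],
                             P[, current, drop = FALSE], gene,
                             nRuns = nRuns, seed = seed + 7L * (d - 1L),
                             cancerType = cancerType, ...)
    lab <- consensusLabels(res)
    groups[[length(groups) + 1L]] <- current[lab == "high"]
    levels <- c(levels, unname(res@groupGeneLevels["high"]))
    current <- current[lab == "low"]
    lastLowLevel <- unname(res@groupGeneLevels["low"])
  }
  groups[[length(groups) + 1L]] <- current
  levels <- c(levels, lastLowLevel)
  names(levels) <- paste0("group", seq_along(groups))
  names(groups) <- names(levels)
  list(groups = groups, geneLevels = levels)
}

#' Tercile concordance between two sample rankings
#'
#' Splits each ranking into three bins — top and bottom of size
#' \code{floor(n / 3)}, remainder to the middle bin — and reports, for the
#' top and bottom bins, how many samples the two rankings share and how
#' many are exclusive to each. Ties straddling a bin boundary are resolved
#' deterministically by sample ID order.
#'
#' @param scoreA,scoreB named numeric vectors over the same sample set;
#'   larger scores rank higher.
#' @return list with elements \code{top} and \code{bottom}, each a list of
#'   \code{shared}, \code{onlyA}, \code{onlyB} (counts) and the
#'   corresponding sample ID sets.
#' @export
tercileConcordance <- function(scoreA, scoreB) {
  if (is.null(names(scoreA)) || is.null(names(scoreB)))
    stop("scores must be named by sample ID")
  if (!setequal(names(scoreA), names(scoreB)))
    stop("the two rankings must cover the same sample set")
  scoreB <- scoreB[names(scoreA)]
  n <- length(scoreA)
  size <- floor(n / 3)
  if (size < 1) stop("need at least 3 samples")

  bins <- function(s) {
    ord <- names(s)[order(-s, names(s))]
    list(top = ord[seq_len(size)], bottom = rev(ord)[seq_len(size)])
  }
  a <- bins(scoreA)
  b <- bins(scoreB)
  cmp <- function(x, y) list(shared = length(intersect(x, y)),
                             onlyA = length(setdiff(x, y)),
                             onlyB = length(setdiff(y, x)),
                             sharedSamples = intersect(x, y),
                             onlyASamples = setdiff(x, y),
                             onlyBSamples = setdiff(y, x))
  list(top = cmp(a$top, b$top), bottom = cmp(a$bottom, b$bottom))
}
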