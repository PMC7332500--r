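#' Select cell-type-informative probes from a reference panel
#'
#' One-vs-rest probe selection: for every reference class, each probe is
#' tested by a two-sample Welch t test of that class against all other
#' classes; probes passing the p-value threshold are ranked by absolute
#' mean beta difference and taken round-robin across classes until
#' \code{nProbes} unique probes are collected. When any class has fewer
#' than two profiles (no within-class variance), selection falls back to
#' pure effect-size ranking, with a message.
#'
#' @param profiles a [ReferencePanel-class], or a numeric matrix of
#'   reference beta values (probes x profiles).
#' @param classLabels character, class of each profile column (ignored for
#'   a panel, which carries its own labels).
#' @param nProbes integer(1), number of probes to select (default 500).
#' @param pThreshold numeric(1), per-probe p-value cutoff (default 1e-5).
#' @return character vector of selected probe IDs (no duplicates); fewer
#'   than \code{nProbes} with a warning when not enough probes pass.
#' @export
selectInformativeProbes <- function(profiles, classLabels = NULL,
                                    nProbes = 500, pThreshold = 1e-5) {
  if (is(profiles, "ReferencePanel")) {
    classLabels <- profiles@classLabels
    profiles <- profiles@methProfiles
  }
  profiles <- as.matrix(profiles)
  if (is.null(classLabels)) classLabels <- colnames(profiles)
  classLabels <- as.character(classLabels)
  stopifnot(length(classLabels) == ncol(profiles))
  classes <- unique(classLabels)
  if (length(classes) < 2) stop("at least 2 reference classes are required")
  if (is.null(rownames(profiles)))
    rownames(profiles) <- sprintf("p%05d", seq_len(nrow(profiles)))

  effectOnly <- any(table(classLabels) < 2)
  if (effectOnly)
    message("selectInformativeProbes: a class has a single profile; ",
            "falling back to effect-size ranking")

  ranked <- lapply(classes, function(cl) {
    inC <- classLabels == cl
    a <- profiles[, inC, drop = FALSE]
    b <- profiles[, !inC, drop = FALSE]
    eff <- rowMeans(a) - rowMeans(b)
    if (!effectOnly) {
      na <- ncol(a); nb <- ncol(b)
      va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
      sepool <- sqrt(va / na + vb / nb)
      tstat <- eff / sepool
      df <- (va / na + vb / nb)^2 /
        (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
      p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
      p[!is.finite(p)] <- 1
      pass <- p < pThreshold
    } else {
      pass <- abs(eff) > 0
    }
    ids <- rownames(profiles)[pass]
    ids[order(abs(eff[pass]), decreasing = TRUE)]
  })

  if (all(lengths(ranked) == 0)) {
    warning("no probes discriminate the reference classes")
    return(character(0))
  }

  selected <- character(0)
  rank <- 1L
  while (length(selected) < nProbes && rank <= max(lengths(ranked))) {
    for (lst in ranked) {
      if (rank <= length(lst) && !(lst[rank] %in% selected) &&
          length(selected) < nProbes)
        selected <- c(selected, lst[rank])
    }
    rank <- rank + 1L
  }
  if (length(selected) < nProbes)
    warning(sprintf("only %d probes pass the threshold (requested %d)",
                    length(selected), nProbes))
  selected
}

#' Deconvolve bulk methylation into cell-type profiles and proportions
#'
#' Minimizes \code{||B - M P||_F^2} by alternating exact constrained least
#' squares: the P-step solves, per sample, least squares under
#' nonnegativity and sum-to-one (probability simplex) constraints; the
#' M-step solves, per probe, least squares under box constraints \[0, 1\].
#' The residual sum of squares is non-increasing across iterations by
#' construction. The best of \code{nRestarts} random restarts (Dirichlet(1)
#' initial proportions) is returned; when \code{refProfiles} is supplied,
#' the first restart is instead seeded by regressing B on the reference
#' profiles.
#'
#' @param B numeric matrix, informative probes x samples, beta values.
#' @param k integer(1), number of cell types; must be smaller than both
#'   dimensions of B.
#' @param nRestarts integer(1), random restarts (default 10).
#' @param tol numeric(1), relative-RSS convergence tolerance (default 1e-6).
#' @param maxIter integer(1), iteration cap per restart (default 2000).
#' @param seed integer(1), RNG seed for the restarts.
#' @param refProfiles optional numeric matrix (probes x k) of reference
#'   beta profiles used to seed the first restart.
#' @return a [MethDeconvolution-class]; a warning flags the (best) result
#'   when no restart converged.
#' @examples
#' panel <- generateReferencePanel(3, 120, 20, seed = 1)
#' mix <- simulateMixtures(panel, nPerVariant = 20, noisePrecision = NULL,
#'                         seed = 2)
#' fit <- deconvolveMethylation(methMixtures(mix), k = 3, nRestarts = 2,
#'                              seed = 3)
#' fit
#' @export
deconvolveMethylation <- function(B, k, nRestarts = 10, tol = 1e-6,
                                  maxIter = 2000, seed = 1L,
                                  refProfiles = NULL) {
  B <- as.matrix(B)
  if (any(!is.finite(B))) stop("'B' must be complete and finite")
  n <- ncol(B)
  k <- as.integer(k)
  if (k < 1) stop("'k' must be >= 1")
  ctNames <- paste0("ct", seq_len(k))

  if (k == 1L) {
    M <- matrix(pmin(pmax(rowMeans(B), 0), 1), ncol = 1,
                dimnames = list(rownames(B), ctNames))
    P <- matrix(1, 1, n, dimnames = list(ctNames, colnames(B)))
    rss <- sum((B - M %*% P)^2)
    return(new("MethDeconvolution", M = M, P = P, restartRSS = rss,
               rssTrace = rss, nIter = 1L, converged = TRUE))
  }
  if (k >= min(dim(B)))
    stop("'k' must be smaller than the number of probes and samples")

  fits <- .with_seed(seed, function() {
    lapply(seq_len(nRestarts), function(r) {
      if (r == 1L && !is.null(refProfiles)) {
        R <- as.matrix(refProfiles)
        common <- intersect(rownames(B), rownames(R))
        if (length(common) < k) stop("reference profiles must share probes with B")
        Pinit <- cpp_simplex_cols(B[common, , drop = FALSE],
                                  R[common, seq_len(k), drop = FALSE])
      } else {
        Pinit <- t(.rdirichlet(n, rep(1, k)))
      }
      cpp_als_deconv(B, Pinit, tol, as.integer(maxIter))
    })
  })

  rssAll <- vapply(fits, `[[`, numeric(1), "rss")
  best <- fits[[which.min(rssAll)]]
  if (!any(vapply(fits, `[[`, logical(1), "converged")))
    warning("no restart converged within 'maxIter'; returning best iterate")

  M <- pmin(pmax(best$M, 0), 1)
  P <- best$P
  P <- sweep(pmax(P, 0), 2, colSums(pmax(P, 0)), "/")
  dimnames(M) <- list(rownames(B), ctNames)
  dimnames(P) <- list(ctNames, colnames(B))
  new("MethDeconvolution", M = M, P = P, restartRSS = rssAll,
      rssTrace = as.numeric(best$rss_trace), nIter = as.integer(best$n_iter),
      converged = isTRUE(best$converged))
}

#' Choose the number of cell types by bootstrap stability
#'
#' For each candidate k, the samples are bootstrap-resampled \code{nBoot}
#' times and factorized; the stability score is the mean, over all pairs of
#' resamples, of the mean Pearson correlation between matched estimated
#' methylation profile columns (matching by [matchCellTypes]). The chosen
#' k* is the largest candidate whose score exceeds \code{stabilityFloor};
#' when no candidate reaches the floor the best-scoring k is returned with
#' a warning.
#'
#' @param B numeric matrix, probes x samples.
#' @param kRange integer vector of candidate cell-type counts.
#' @param nBoot integer(1), bootstrap resamples per k (default 10).
#' @param nRestarts integer(1), restarts per factorization (default 3).
#' @param stabilityFloor numeric(1), stability threshold (default 0.9).
#' @param seed integer(1), RNG seed.
#' @param ... passed to [deconvolveMethylation()].
#' @return list with \code{k} (selected k*) and \code{stability} (named
#'   score per candidate; k = 1 has stability 1 by construction).
#' @export
chooseNumCellTypes <- function(B, kRange, nBoot = 10, nRestarts = 3,
                               stabilityFloor = 0.9, seed = 1L, ...) {
  B <- as.matrix(B)
  kRange <- sort(unique(as.integer(kRange)))
  if (length(kRange) == 0) stop("'kRange' must be nonempty")
  if (any(kRange < 1) || any(kRange >= min(dim(B))))
    stop("'kRange' must lie within the valid bounds of the factorization")
  n <- ncol(B)

  scores <- .with_seed(seed, function() {
    vapply(kRange, function(k) {
      if (k == 1L) return(1)
      Ms <- lapply(seq_len(nBoot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        methProfiles(deconvolveMethylation(
          B[, idx, drop = FALSE], k, nRestarts = nRestarts,
          seed = sample.int(.Machine$integer.max, 1), ...))
      })
      pairCor <- utils::combn(nBoot, 2, function(pr) {
        m <- matchCellTypes(Ms[[pr[1]]], references = Ms[[pr[2]]])
        mean(diag(stats::cor(Ms[[pr[1]]],
                             Ms[[pr[2]]][, m$assignment, drop = FALSE])))
      })
      mean(pairCor)
    }, numeric(1))
  })
  names(scores) <- kRange

  ok <- scores >= stabilityFloor
  if (any(ok)) {
    kStar <- max(kRange[ok])
  } else {
    kStar <- kRange[which.max(scores)]
    warning("no candidate k reached the stability floor; returning the most stable")
  }
  list(k = kStar, stability = scores)
}

# all injections of seq_len(m) into seq_len(n), m <= n (list of index vectors)
.injections <- function(m, n) {
  if (m == 0) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == m) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (j in remaining) rec(c(prefix, j), setdiff(remaining, j))
  }
  rec(integer(0), seq_len(n))
  out
}

#' Match estimated cell-type columns to labeled references or markers
#'
#' Finds the one-to-one assignment of estimated columns to reference
#' columns that maximizes the total Pearson correlation over shared
#' features (or, in marker mode, the total mean marker expression per
#' label). Ties are broken by column index order. An assignment whose
#' total score is within 1e-6 of the runner-up is flagged ambiguous.
#'
#' @param est numeric matrix of estimated profiles (features x columns), or
#'   a [MethDeconvolution-class] / [CellTypeExpression-class].
#' @param references numeric matrix of labeled reference profiles sharing
#'   rownames with \code{est} (at least as many columns as \code{est}).
#' @param markers data.frame with columns \code{gene} and \code{label};
#'   used instead of \code{references} when supplied.
#' @return list with \code{labels} (per estimated column), \code{assignment}
#'   (reference column index per estimated column), \code{score},
#'   \code{ambiguous} flag, and the score matrix \code{scores}.
#' @export
matchCellTypes <- function(est, references = NULL, markers = NULL) {
  if (is(est, "MethDeconvolution")) est <- est@M
  if (is(est, "CellTypeExpression")) est <- est@E
  est <- as.matrix(est)
  kEst <- ncol(est)

  if (!is.null(markers)) {
    stopifnot(all(c("gene", "label") %in% colnames(markers)))
    labels <- unique(as.character(markers$label))
    S <- vapply(labels, function(l) {
      g <- intersect(markers$gene[markers$label == l], rownames(est))
      if (length(g) == 0) return(rep(NA_real_, kEst))
      colMeans(est[g, , drop = FALSE])
    }, numeric(kEst))
    S <- matrix(S, nrow = kEst, dimnames = list(colnames(est), labels))
    # scale per label so labels with large expression do not dominate
    S[!is.finite(S)] <- 0
    S <- sweep(S, 2, pmax(apply(abs(S), 2, max), 1e-300), "/")
    refNames <- labels
  } else {
    if (is.null(references)) stop("supply 'references' or 'markers'")
    references <- as.matrix(references)
    common <- intersect(rownames(est), rownames(references))
    if (is.null(rownames(est)) || is.null(rownames(references))) {
      if (nrow(est) != nrow(references))
        stop("references must share the feature space of the estimates")
      common <- seq_len(nrow(est))
    } else if (length(common) < 3) {
      stop("references must share the feature space of the estimates")
    }
    S <- suppressWarnings(stats::cor(est[common, , drop = FALSE],
                                     references[common, , drop = FALSE]))
    S[!is.finite(S)] <- 0
    refNames <- colnames(references)
    if (is.null(refNames)) refNames <- paste0("ref", seq_len(ncol(references)))
  }

  nRef <- ncol(S)
  if (nRef >= kEst) {
    # one-to-one injection of estimated columns into references
    cand <- .injections(kEst, nRef)
    totals <- vapply(cand, function(a) sum(S[cbind(seq_len(kEst), a)]),
                     numeric(1))
    bestIdx <- which.max(totals)  # first maximum: column-index tie-break
    assignment <- cand[[bestIdx]]
    labels <- refNames[assignment]
  } else {
    # fewer labels than columns (partial marker tables): inject labels
    # into columns; unmatched columns stay unlabeled
    cand <- .injections(nRef, kEst)
    totals <- vapply(cand, function(a) sum(S[cbind(a, seq_len(nRef))]),
                     numeric(1))
    bestIdx <- which.max(totals)
    labels <- rep(NA_character_, kEst)
    labels[cand[[bestIdx]]] <- refNames
    assignment <- match(labels, refNames)
  }
  ambiguous <- length(totals) > 1 &&
    (totals[bestIdx] - max(totals[-bestIdx])) < 1e-6
  if (ambiguous) message("matchCellTypes: assignment is ambiguous (tie within 1e-6)")

  list(labels = labels, assignment = assignment,
       score = totals[bestIdx], ambiguous = ambiguous, scores = S)
}
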