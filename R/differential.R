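#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement (via
#' \code{stats::p.adjust}); the input order is preserved.
#'
#' @param p numeric vector of p-values in \[0, 1\]; NA/NaN raise an error.
#' @return numeric vector of q-values, elementwise >= p and <= 1.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p))) stop("p-values must not contain NA/NaN")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cell-type-specific differential expression between two groups
#'
#' Per gene, computes a t test on the deconvoluted means and standard
#' errors of the chosen cell type:
#' \code{t = (mean_hi - mean_lo) / sqrt(se_hi^2 + se_lo^2)}, with degrees
#' of freedom from the Welch-Satterthwaite approximation over the two
#' groups' residual dofs (or their sum with \code{dfMethod = "sum"}), and a
#' two-sided p-value from the t distribution. Genes with a zero mean in
#' one group get a log2 fold change computed with a half-minimum
#' pseudo-value and are flagged. Active-nonnegativity flags from the
#' deconvolution are propagated. q-values are BH-adjusted across genes.
#'
#' @param hi,lo [CellTypeExpression-class] objects for the two groups.
#' @param cellType character(1) or integer(1), column to compare.
#' @param dfMethod "welch" (default) or "sum".
#' @return data.frame with one row per gene: gene, cellType, meanHi,
#'   meanLo, seHi, seLo, t, df, p, q, log2fc, plus flags (activeHi,
#'   activeLo, pseudoFC, degenerate).
#' @export
cellTypeTTest <- function(hi, lo, cellType, dfMethod = c("welch", "sum")) {
  stopifnot(is(hi, "CellTypeExpression"), is(lo, "CellTypeExpression"))
  dfMethod <- match.arg(dfMethod)
  ctH <- if (is.character(cellType)) match(cellType, colnames(hi@E)) else as.integer(cellType)
  ctL <- if (is.character(cellType)) match(cellType, colnames(lo@E)) else as.integer(cellType)
  if (is.na(ctH) || is.na(ctL)) stop("'cellType' not found in both groups")
  genes <- rownames(hi@E)
  if (!identical(genes, rownames(lo@E)))
    stop("the two groups must cover the same genes")
  if (hi@nu < 1 || lo@nu < 1) stop("residual dof >= 1 required for inference")

  mHi <- hi@E[, ctH]; mLo <- lo@E[, ctL]
  sHi <- hi@S[, ctH]; sLo <- lo@S[, ctL]
  sePool <- sqrt(sHi^2 + sLo^2)

  t <- (mHi - mLo) / sePool
  degenerate <- sePool == 0 & mHi != mLo
  t[sePool == 0 & mHi == mLo] <- 0
  df <- if (dfMethod == "welch") {
    (sHi^2 + sLo^2)^2 / (sHi^4 / hi@nu + sLo^4 / lo@nu)
  } else rep(hi@nu + lo@nu, length(t))
  df[sePool == 0] <- hi@nu + lo@nu
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[sePool == 0 & mHi == mLo] <- 1
  if (any(degenerate, na.rm = TRUE)) {
    warning(sprintf("%d gene(s) with zero SE but unequal means; p set to 0 sentinel",
                    sum(degenerate, na.rm = TRUE)))
    p[degenerate] <- 0
    t[degenerate] <- sign(mHi - mLo)[degenerate] * Inf
  }

  # fold change with half-minimum pseudo-value for zero means
  posMin <- min(c(mHi[mHi > 0], mLo[mLo > 0]), Inf)
  pseudo <- if (is.finite(posMin)) posMin / 2 else 1
  pseudoFC <- (mHi <= 0) | (mLo <= 0)
  mHiFC <- ifelse(mHi <= 0, pseudo, mHi)
  mLoFC <- ifelse(mLo <= 0, pseudo, mLo)
  log2fc <- log2(mHiFC / mLoFC)

  ok <- is.finite(p)
  q <- rep(NA_real_, length(p))
  q[ok] <- bhAdjust(p[ok])

  data.frame(
    gene = genes,
    cellType = colnames(hi@E)[ctH] %||% as.character(ctH),
    meanHi = mHi, meanLo = mLo, seHi = sHi, seLo = sLo,
    t = t, df = df, p = p, q = q, log2fc = log2fc,
    activeHi = hi@active[, ctH], activeLo = lo@active[, ctL],
    pseudoFC = pseudoFC, degenerate = degenerate,
    row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call differentially expressed genes
#'
#' Applies the joint fold-change and FDR filter: up-regulated genes have
#' \code{q < qThreshold} and \code{log2fc >= log2(foldChange)};
#' down-regulated genes the mirrored fold-change bound.
#'
#' @param records data.frame from [cellTypeTTest()] (needs columns
#'   \code{gene}, \code{q}, \code{log2fc}).
#' @param foldChange numeric(1), minimal linear fold change (default 2).
#' @param qThreshold numeric(1), FDR cutoff (default 0.05).
#' @return list with character vectors \code{up} and \code{down}.
#' @export
callDE <- function(records, foldChange = 2, qThreshold = 0.05) {
  stopifnot(all(c("gene", "q", "log2fc") %in% colnames(records)))
  lfc <- log2(foldChange)
  ok <- !is.na(records$q) & !is.na(records$log2fc)
  up <- records$gene[ok & records$q < qThreshold & records$log2fc >= lfc]
  down <- records$gene[ok & records$q < qThreshold & records$log2fc <= -lfc]
  list(up = as.character(up), down = as.character(down))
}

#' Hypergeometric overlap enrichment of two gene sets
#'
#' Upper-tail hypergeometric probability of observing at least the actual
#' overlap between a query set and a target set drawn from a common
#' universe: \code{p = P(X >= x)} with
#' \code{X ~ Hypergeometric(N, K, n)}, \code{x = |query \&\#8898; target|},
#' \code{K = |target|}, \code{n = |query|}, \code{N = |universe|}.
#'
#' @param query,target character vectors, subsets of \code{universe}.
#' @param universe character vector of all considered genes (nonempty).
#' @return list with \code{overlap}, \code{querySize}, \code{setSize},
#'   \code{universeSize} and \code{p}.
#' @examples
#' u <- paste0("g", 1:20)
#' hypergeomOverlap(u[1:4], u[c(1:3, 10, 11)], u)  # p = 155/4845
#' @export
hypergeomOverlap <- function(query, target, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("'universe' must be nonempty")
  query <- unique(as.character(query))
  target <- unique(as.character(target))
  if (!all(query %in% universe) || !all(target %in% universe))
    stop("query and target must be subsets of the universe")
  x <- length(intersect(query, target))
  K <- length(target)
  n <- length(query)
  N <- length(universe)
  p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  list(overlap = x, querySize = n, setSize = K, universeSize = N, p = p)
}
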