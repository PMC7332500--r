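#' Estimate cell-type-specific expression from fixed proportions
#'
#' For each gene g, solves \code{min || G[g, ] - e P ||^2} subject to
#' \code{e >= 0} (optionally unconstrained), where P is the cell-type
#' proportion matrix from the methylation stage. Standard errors come from
#' the ordinary-least-squares covariance formula
#' \code{S^2 = sigma2 * diag((P P')^-1)} with \code{sigma2 = RSS / nu} and
#' \code{nu = n_samples - k}; the unconstrained formula is used even when a
#' nonnegativity constraint is active, in which case the entry is flagged.
#' Expression must be on the linear scale (mixing is linear).
#'
#' @param G numeric matrix, genes x samples, nonnegative linear-scale
#'   expression; columns aligned with P.
#' @param P numeric matrix, cell types x samples, columns on the simplex
#'   (or a [MethDeconvolution-class] / [MixtureTruth-class]).
#' @param nonneg logical(1); constrain estimates to be nonnegative
#'   (default TRUE).
#' @return a [CellTypeExpression-class]. Cell types absent from every
#'   sample (rank-deficient P) yield NA columns with a warning.
#' @examples
#' P <- matrix(c(0.5, 0.5, 0.8, 0.2, 0.2, 0.8), 2, 3)
#' E <- matrix(c(10, 2, 0, 8), 2, 2)
#' fit <- deconvolveExpression(E %*% P, P)
#' exprMeans(fit)
#' @export
deconvolveExpression <- function(G, P, nonneg = TRUE) {
  if (is(P, "MethDeconvolution") || is(P, "MixtureTruth")) P <- P@P
  G <- as.matrix(G)
  P <- as.matrix(P)
  if (ncol(G) != ncol(P)) stop("'G' columns must align with 'P' columns")
  k <- nrow(P)
  n <- ncol(P)
  if (n <= k) stop("need more samples than cell types (nu >= 1)")
  ctNames <- rownames(P)
  if (is.null(ctNames)) ctNames <- paste0("ct", seq_len(k))

  absent <- rowSums(abs(P)) < 1e-12
  if (any(absent))
    warning(sprintf("cell type(s) %s absent from all samples; returned as NA",
                    paste(ctNames[absent], collapse = ", ")))
  use <- which(!absent)
  Pu <- P[use, , drop = FALSE]

  if (nonneg) {
    Eu <- cpp_nnls_rows(G, Pu)
  } else {
    Eu <- t(solve(Pu %*% t(Pu), Pu %*% t(G)))
  }
  resid <- G - Eu %*% Pu
  rss <- rowSums(resid^2)
  nu <- n - length(use)
  XtXinv <- solve(Pu %*% t(Pu))
  sigma2 <- rss / nu
  Su <- sqrt(outer(sigma2, diag(XtXinv)))

  # active nonnegativity constraint: estimate pinned at 0 while the
  # unconstrained solution is negative
  activeU <- matrix(FALSE, nrow(G), length(use))
  if (nonneg) {
    Eols <- t(solve(Pu %*% t(Pu), Pu %*% t(G)))
    activeU <- (Eu <= 0) & (Eols < -1e-12)
  }

  E <- S <- matrix(NA_real_, nrow(G), k, dimnames = list(rownames(G), ctNames))
  active <- matrix(NA, nrow(G), k, dimnames = list(rownames(G), ctNames))
  E[, use] <- Eu
  S[, use] <- Su
  active[, use] <- activeU
  S[!is.finite(S)] <- NA_real_

  new("CellTypeExpression", E = E, S = S, nu = as.numeric(nu),
      nSamples = as.integer(n), active = active)
}

#' Reconstruct predicted bulk expression from cell-type profiles
#'
#' Returns the linear combination \code{E P}: the bulk profile each sample
#' would show if its measured cell-type proportions mixed the estimated
#' cell-type expression profiles exactly.
#'
#' @param E a [CellTypeExpression-class] or a genes x k numeric matrix.
#' @param P numeric matrix, cell types x samples (or a
#'   [MethDeconvolution-class]).
#' @return numeric matrix, genes x samples.
#' @export
reconstructBulk <- function(E, P) {
  if (is(E, "CellTypeExpression")) E <- E@E
  if (is(P, "MethDeconvolution") || is(P, "MixtureTruth")) P <- P@P
  E <- as.matrix(E)
  P <- as.matrix(P)
  if (ncol(E) != nrow(P)) stop("'E' columns must match 'P' rows")
  E %*% P
}
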