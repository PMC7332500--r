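#' Graphical lasso: sparse precision-matrix estimation
#'
#' L1-penalized Gaussian maximum likelihood via block coordinate descent
#' (one lasso regression per variable per sweep). Off-diagonal entries are
#' penalized; the working covariance keeps \code{S_jj + lambda} on the
#' diagonal. At \code{lambda = 0} the estimate is the plain inverse of S.
#' Zeros in the returned precision matrix are exact (structural) zeros.
#'
#' @param S symmetric covariance or correlation matrix.
#' @param lambda numeric(1) >= 0, penalty.
#' @param tol numeric(1), convergence tolerance on the working covariance,
#'   relative to the average absolute off-diagonal of S (default 1e-6).
#' @param maxIter integer(1), sweep cap (default 200).
#' @return list with \code{Theta} (precision), \code{W} (estimated
#'   covariance), \code{nIter}, \code{converged}.
#' @examples
#' S <- cov(matrix(rnorm(500), 100, 5))
#' fit <- graphicalLasso(S, lambda = 0.2)
#' sum(fit$Theta[upper.tri(S)] != 0)
#' @export
graphicalLasso <- function(S, lambda, tol = 1e-6, maxIter = 200) {
  S <- as.matrix(S)
  if (!isSymmetric(S, tol = 1e-8)) stop("'S' must be symmetric")
  S <- (S + t(S)) / 2
  if (lambda < 0) stop("'lambda' must be >= 0")
  if (lambda == 0) {
    Theta <- solve(S)
    return(list(Theta = (Theta + t(Theta)) / 2, W = S, nIter = 0L,
                converged = TRUE))
  }
  fit <- cpp_glasso(S, lambda, tol, as.integer(maxIter))
  dimnames(fit$Theta) <- dimnames(S)
  dimnames(fit$W) <- dimnames(S)
  list(Theta = fit$Theta, W = fit$W, nIter = fit$n_iter,
       converged = fit$converged)
}

# partial correlations from a precision matrix: -Theta_ij / sqrt(T_ii T_jj)
.partial_cor <- function(Theta) {
  d <- 1 / sqrt(diag(Theta))
  rho <- -Theta * outer(d, d)
  diag(rho) <- 1
  rho
}
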