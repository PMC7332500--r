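#' @useDynLib histoepi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Simplex-constrained least squares
#'
#' Solves \code{min ||A x - b||^2} subject to \code{x >= 0} and
#' \code{sum(x) = 1} by an exact active-set method; both constraints hold
#' exactly at the returned solution (KKT residual below 1e-8).
#'
#' @param A numeric matrix (rows = observations).
#' @param b numeric vector, length \code{nrow(A)}.
#' @return numeric vector on the probability simplex.
#' @examples
#' A <- matrix(c(1, 0, 0.5, 0, 1, 0.5), ncol = 2)
#' solveSimplexLS(A, A %*% c(0.3, 0.7))
#' @export
solveSimplexLS <- function(A, b) {
  A <- as.matrix(A)
  stopifnot(is.numeric(A), length(b) == nrow(A), all(is.finite(A)),
            all(is.finite(b)))
  drop(cpp_simplex_ls(A, as.numeric(b)))
}

#' Box-constrained least squares
#'
#' Solves \code{min ||A x - b||^2} subject to \code{lo <= x <= hi}
#' elementwise by an exact active-set method. Upper bounds may be
#' \code{Inf} (nonnegative least squares when \code{lo = 0, hi = Inf}).
#'
#' @param A numeric matrix (rows = observations).
#' @param b numeric vector, length \code{nrow(A)}.
#' @param lo,hi numeric bounds, recycled to \code{ncol(A)}.
#' @return numeric vector within the bounds.
#' @examples
#' A <- matrix(rnorm(20), 10, 2)
#' solveBoxLS(A, A %*% c(2, -1), lo = 0, hi = Inf)
#' @export
solveBoxLS <- function(A, b, lo = 0, hi = Inf) {
  A <- as.matrix(A)
  k <- ncol(A)
  stopifnot(is.numeric(A), length(b) == nrow(A), all(is.finite(A)),
            all(is.finite(b)))
  lo <- rep_len(as.numeric(lo), k)
  hi <- rep_len(as.numeric(hi), k)
  stopifnot(all(lo <= hi))
  drop(cpp_box_ls(A, as.numeric(b), lo, hi))
}

# Dirichlet draws: n vectors of length(alpha), rows sum to 1.
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  zero <- rowSums(x) == 0
  if (any(zero)) x[zero, which.max(alpha)] <- 1  # pathological tiny alpha
  x / rowSums(x)
}

# Run fn() under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
.with_seed <- function(seed, fn) {
  seed <- as.integer(seed)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}
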