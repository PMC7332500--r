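# Shared fixture builders. Everything is generated in code at test time.

# Erdos-Renyi background network wrapped as a GGMNetwork (adjacency-only
# object for graph-statistic tests; Theta/rho are placeholders).
make_er_network <- function(p, prob, seed, clique = NULL) {
  set.seed(seed)
  A <- matrix(stats::runif(p * p) < prob, p, p)
  A[lower.tri(A, diag = TRUE)] <- FALSE
  A <- A | t(A)
  if (!is.null(clique)) A[clique, clique] <- TRUE
  diag(A) <- FALSE
  mode(A) <- "logical"
  nodes <- paste0("n", seq_len(p))
  dimnames(A) <- list(nodes, nodes)
  new("GGMNetwork", nodes = nodes, covariate = rep(FALSE, p), lambda = 0.1,
      Theta = diag(p), rho = diag(p), adjacency = A,
      muW = NA_real_, sigmaW = NA_real_)
}

# Network with prescribed edge weights on a path n1-n2-...-n(k+1);
# used for strong-edge rule tests.
make_weighted_network <- function(weights) {
  p <- length(weights) + 1
  nodes <- paste0("n", seq_len(p))
  adj <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  rho <- diag(p)
  dimnames(rho) <- list(nodes, nodes)
  for (i in seq_along(weights)) {
    adj[i, i + 1] <- adj[i + 1, i] <- TRUE
    rho[i, i + 1] <- rho[i + 1, i] <- weights[i]
  }
  w <- weights
  new("GGMNetwork", nodes = nodes, covariate = rep(FALSE, p), lambda = 0.1,
      Theta = diag(p), rho = rho, adjacency = adj,
      muW = mean(w), sigmaW = stats::sd(w))
}

# Purity-confounding scenario: two genes expressed in different cell types,
# samples varying in purity. Intrinsic lognormal noise (sd 0.4) keeps the
# log-scale bulk values inside the GGM's linear operating regime.
make_confounding_scenario <- function(seed, n = 500, sdg = 0.4) {
  set.seed(seed)
  purity <- stats::rbeta(n, 8, 8)
  P <- rbind(cancer = purity, stroma = 1 - purity)
  colnames(P) <- paste0("s", seq_len(n))
  G <- rbind(gA = 50 * purity * exp(stats::rnorm(n, sd = sdg)),
             gB = 40 * (1 - purity) * exp(stats::rnorm(n, sd = sdg)),
             gC = 20 * exp(stats::rnorm(n, sd = sdg)))
  colnames(G) <- colnames(P)
  list(G = G, P = P)
}

# Chain-structured precision matrix and a Gaussian sample from it.
make_chain_data <- function(p, n, seed, coef = 0.45) {
  Theta <- diag(p)
  for (i in seq_len(p - 1)) Theta[i, i + 1] <- Theta[i + 1, i] <- coef
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n) %*% chol(solve(Theta))
  list(Theta = Theta, X = X)
}

# Two-group cell-type expression simulation with planted cancer changes.
# Multiplicative lognormal noise with sd ~ noiseFrac of the mean.
make_de_simulation <- function(seed, nGenes = 200, nPer = 30, k = 3,
                               nPlanted = 40, fold = 2.5, noiseFrac = 0.1,
                               noiseType = c("multiplicative", "additive")) {
  noiseType <- match.arg(noiseType)
  set.seed(seed)
  ct <- c("stroma", "immune", "cancer")[seq_len(k)]
  E <- matrix(exp(stats::rnorm(nGenes * k, 3, 1)), nGenes, k,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)), ct))
  planted <- if (nPlanted > 0) sample(nGenes, nPlanted) else integer(0)
  Ehi <- E
  Ehi[planted, "cancer"] <- E[planted, "cancer"] * fold
  mkP <- function(n) {
    x <- matrix(stats::rgamma(n * k, 1), k)
    x <- sweep(x, 2, colSums(x), "/")
    rownames(x) <- ct
    colnames(x) <- paste0("s", seq_len(n))
    x
  }
  noisy <- function(M) {
    if (noiseType == "multiplicative")
      M * exp(matrix(stats::rnorm(length(M), 0, noiseFrac), nrow(M)))
    else  # per-gene homoskedastic, sd = noiseFrac of the gene's mean level
      M + matrix(stats::rnorm(length(M), 0, noiseFrac * rowMeans(M)),
                 nrow(M))
  }
  Phi <- mkP(nPer); Plo <- mkP(nPer)
  list(Ghi = noisy(Ehi %*% Phi), Glo = noisy(E %*% Plo),
       Phi = Phi, Plo = Plo,
       plantedGenes = rownames(E)[planted], cellTypes = ct)
}

# Exact upper-tail hypergeometric probability by direct enumeration of
# binomial coefficients (independent of stats::phyper).
hyper_upper_enum <- function(x, K, n, N) {
  kk <- x:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Brute-force bipartition oracle for the iterative group fit: enumerate all
# splits with both sides >= minSize and return the partition minimizing the
# total within-group fit distance for the gene.
bipartition_oracle <- function(gRow, P, minSize) {
  n <- length(gRow)
  best <- NULL
  bestDist <- Inf
  for (code in 1:(2^(n - 1) - 1)) {  # fix sample 1 in group 1 (symmetry)
    inG2 <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    if (sum(inG2) < minSize || sum(!inG2) < minSize) next
    d <- 0
    for (g in list(which(!inG2), which(inG2))) {
      e <- histoepi:::.gene_level(gRow[g], P[, g, drop = FALSE])
      d <- d + sum(abs(drop(e %*% P[, g, drop = FALSE]) - gRow[g]))
    }
    if (d < bestDist - 1e-12) {
      bestDist <- d
      best <- inG2
    }
  }
  list(split = best, dist = bestDist)
}
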