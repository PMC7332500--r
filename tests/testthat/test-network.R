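# Graphical lasso, StARS, covariate stripping, strong edges,
# connectedness and enrichment statistics.

test_that("graphical lasso satisfies its KKT optimality conditions", {
  set.seed(171)
  for (case in 1:6) {
    p <- sample(4:12, 1)
    X <- matrix(rnorm(300 * p), 300)
    X[, 2] <- 0.7 * X[, 1] + rnorm(300, sd = 0.5)
    S <- cor(X)
    lam <- runif(1, 0.05, 0.4)
    fit <- graphicalLasso(S, lam, tol = 1e-8, maxIter = 500)
    W <- solve(fit$Theta)
    expect_lt(max(abs(diag(W) - (diag(S) + lam))), 1e-8)
    off <- upper.tri(S)
    nz <- off & fit$Theta != 0
    z <- off & fit$Theta == 0
    if (any(nz))
      expect_lt(max(abs((S - W + lam * sign(fit$Theta))[nz])), 1e-8)
    if (any(z))
      expect_lte(max(abs((S - W)[z])), lam + 1e-8)
  }
})

test_that("two-variable closed form: soft-thresholded correlation", {
  r <- 0.6; lam <- 0.2
  S <- matrix(c(1, r, r, 1), 2)
  fit <- graphicalLasso(S, lam)
  # W12 = sign(r) (|r| - lambda); partial correlation = W12 / (1 + lambda)
  expect_equal(fit$W[1, 2], r - lam, tolerance = 1e-8)
  rho <- -fit$Theta[1, 2] / sqrt(prod(diag(fit$Theta)))
  expect_equal(rho, (r - lam) / (1 + lam), tolerance = 1e-8)
  # full shrinkage kills the edge
  expect_equal(graphicalLasso(S, 0.7)$Theta[1, 2], 0)
})

test_that("lambda = 0 returns the plain inverse; edges shrink with lambda", {
  set.seed(172)
  X <- matrix(rnorm(200 * 6), 200)
  S <- cor(X)
  expect_equal(graphicalLasso(S, 0)$Theta, solve(S), tolerance = 1e-10)
  counts <- vapply(c(0.05, 0.15, 0.3, 0.5), function(l) {
    Th <- graphicalLasso(S, l)$Theta
    sum(Th[upper.tri(Th)] != 0)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("partial correlations match the matrix-inversion oracle", {
  set.seed(173)
  for (case in 1:8) {
    p <- sample(3:8, 1)
    A <- matrix(rnorm(p * p), p)
    Theta <- crossprod(A) + diag(p) * 0.5
    rho <- histoepi:::.partial_cor(Theta)
    Sigma <- solve(Theta)
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      others <- setdiff(1:p, c(i, j))
      # oracle: correlation of residuals after regressing out the others
      S11 <- Sigma[c(i, j), c(i, j)]
      S12 <- Sigma[c(i, j), others, drop = FALSE]
      S22 <- Sigma[others, others, drop = FALSE]
      Cond <- S11 - S12 %*% solve(S22) %*% t(S12)
      expect_lt(abs(rho[i, j] - Cond[1, 2] / sqrt(Cond[1, 1] * Cond[2, 2])),
                1e-10)
    }
  }
  # worked example: Theta = [[2, -1], [-1, 2]] gives rho = 0.5
  expect_equal(histoepi:::.partial_cor(matrix(c(2, -1, -1, 2), 2))[1, 2], 0.5)
})

test_that("independent variables give an empty graph at strong penalty", {
  set.seed(174)
  X <- matrix(rnorm(500 * 10), 500)
  G <- t(2^X)  # positive linear-scale "expression"
  rownames(G) <- paste0("g", 1:10)
  net <- fitGGM(G, paste0("g", 1:10), P = NULL, lambda = 0.5,
                covariate = "none")
  expect_equal(sum(adjacencyMatrix(net)), 0)
})

test_that("StARS behaves on null data and honors the fixed-lambda override", {
  set.seed(175)
  X <- matrix(rnorm(200 * 12), 200)
  path <- exp(seq(log(0.6), log(0.05), length.out = 6))
  sel <- starsSelect(X, path, nSubsamples = 10, seed = 1)
  Th <- graphicalLasso(cor(X), sel$lambda)$Theta
  expect_lte(sum(Th[upper.tri(Th)] != 0), 0.01 * choose(12, 2) + 1)
  fixed <- starsSelect(X, path, fixedLambda = 0.125)
  expect_equal(fixed$lambda, 0.125)
  expect_true(fixed$fixed)
  net <- fitGGM(rbind(g1 = 2^X[, 1] + 2, g2 = 2^X[, 2] + 2), c("g1", "g2"),
                P = NULL, lambda = fixed$lambda, covariate = "none")
  expect_equal(net@lambda, 0.125)
})

test_that("StARS recovers a chain structure at workable error", {
  ch <- make_chain_data(p = 20, n = 400, seed = 176)
  sel <- starsSelect(ch$X, exp(seq(log(0.6), log(0.05), length.out = 8)),
                     seed = 2)
  Th <- graphicalLasso(cor(ch$X), sel$lambda)$Theta
  est <- Th != 0 & upper.tri(Th)
  tru <- ch$Theta != 0 & upper.tri(ch$Theta)
  tp <- sum(est & tru); fp <- sum(est & !tru); fn <- sum(!est & tru)
  expect_equal(fn, 0)               # StARS errs dense: no true edge is lost
  expect_gte(2 * tp / (2 * tp + fp + fn), 0.55)
})

test_that("covariate stripping removes only covariate nodes, idempotently", {
  sc <- make_confounding_scenario(seed = 3)
  net <- fitGGM(sc$G, rownames(sc$G), sc$P, lambda = 0.2)
  expect_equal(sum(net@covariate), 2)
  stripped <- stripCovariateNodes(net)
  expect_equal(length(nodeNames(stripped)), length(nodeNames(net)) - 2)
  expect_false(any(grepl("^prop:", nodeNames(stripped))))
  # gene-gene weights bit-identical (no refit)
  genes <- nodeNames(stripped)
  expect_identical(partialCor(net)[genes, genes], partialCor(stripped))
  expect_warning(again <- stripCovariateNodes(stripped), "no covariate")
  expect_identical(again@rho, stripped@rho)
})

test_that("proportion covariate nodes suppress the purity-driven edge", {
  hits <- vapply(1:5, function(s) {
    sc <- make_confounding_scenario(seed = s)
    w <- fitGGM(sc$G, rownames(sc$G), sc$P, lambda = 0.2)
    wo <- fitGGM(sc$G, rownames(sc$G), NULL, lambda = 0.2, covariate = "none")
    c(with = adjacencyMatrix(w)["gA", "gB"],
      without = adjacencyMatrix(wo)["gA", "gB"])
  }, logical(2))
  expect_lte(sum(hits["with", ]), 1)
  expect_gte(sum(hits["without", ]), 4)
})

test_that("strong edges are exactly those above mu + n_sd * sigma", {
  set.seed(177)
  # weight set engineered to have specific sample mean and sd
  mu <- -0.00492; sigma <- 0.0297
  z <- c(-1.6, -0.9, -0.3, 0.2, 0.5, 2.1)
  z <- (z - mean(z)) / sd(z)
  w <- mu + sigma * z
  net <- make_weighted_network(w)
  expect_equal(net@muW, mu, tolerance = 1e-12)
  expect_equal(net@sigmaW, sigma, tolerance = 1e-12)
  strong <- strongEdges(net)
  expect_setequal(strong$weight, w[w > mu + sigma])
  expect_gt(min(strong$weight), 0.02478)
  # monotone nesting of thresholds
  s2 <- strongEdges(net, nSd = 2)
  expect_true(all(s2$weight %in% strong$weight))
  # all-equal weights: no strong edges
  expect_warning(none <- strongEdges(make_weighted_network(rep(0.1, 4))),
                 NA)
  expect_equal(nrow(none), 0)
})

test_that("fewer than two edges yields an empty strong set with a warning", {
  net <- make_weighted_network(0.3)
  expect_warning(out <- strongEdges(net), "fewer than 2")
  expect_equal(nrow(out), 0)
})

test_that("a planted clique is detected; empty sets give p = 1", {
  net <- make_er_network(50, 0.05, seed = 42, clique = 1:5)
  res <- connectednessTest(net, paste0("n", 1:5), nPerm = 10000, seed = 1)
  expect_equal(res$observed, 10)
  expect_lte(res$p, 0.01)
  # a set with no induced edges sits at the null's minimum
  deg <- rowSums(adjacencyMatrix(net))
  iso <- names(sort(deg))[1:2]
  if (sum(adjacencyMatrix(net)[iso, iso]) == 0) {
    res0 <- connectednessTest(net, iso, nPerm = 2000, seed = 2)
    expect_gte(res0$p, 1 - 10 / 2001)
  }
})

test_that("connectedness p-values are calibrated under the null", {
  net <- make_er_network(100, 0.3, seed = 8)
  set.seed(178)
  ps <- vapply(1:100, function(i) {
    q <- sample(nodeNames(net), 21)
    connectednessTest(net, q, nPerm = 2000, seed = i)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("edge enrichment reduces to the hypergeometric overlap", {
  net <- make_er_network(21, 0.2, seed = 55)
  node <- nodeNames(net)[which.max(rowSums(adjacencyMatrix(net)))]
  nbrs <- nodeNames(net)[adjacencyMatrix(net)[node, ]]
  target <- unique(c(nbrs[seq_len(min(3, length(nbrs)))],
                     setdiff(nodeNames(net), c(node, nbrs))[1:2]))
  res <- edgeEnrichment(net, node, target)
  expect_equal(res$p, hyper_upper_enum(res$overlap, length(target),
                                       length(nbrs), 20), tolerance = 1e-12)
  # target = all other nodes: overlap equals the degree, p = 1
  all_t <- edgeEnrichment(net, node, setdiff(nodeNames(net), node))
  expect_equal(all_t$overlap, length(nbrs))
  expect_equal(all_t$p, 1)
  expect_equal(edgeEnrichment(net, node, character(0))$p, 1)
})

test_that("neighborhood subgraphs follow graph distance", {
  net <- make_weighted_network(c(0.2, 0.3))  # path n1 - n2 - n3
  sub1 <- neighborSubgraph(net, "n2", order = 1)
  expect_setequal(nodeNames(sub1), c("n1", "n2", "n3"))
  expect_equal(sum(adjacencyMatrix(sub1)) / 2, 2)
  expect_equal(nodeNames(neighborSubgraph(net, "n1", order = 0)), "n1")
  expect_setequal(nodeNames(neighborSubgraph(net, "n1", order = 5)),
                  c("n1", "n2", "n3"))
})
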