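# Iterative group fit, consensus, recursive partition, tercile concordance.

test_that("six-sample toy matches the exhaustive bipartition oracle", {
  P <- rbind(cancer = c(0.5, 0.7, 0.3, 0.5, 0.7, 0.3),
             stroma = c(0.5, 0.3, 0.7, 0.5, 0.3, 0.7))
  colnames(P) <- paste0("s", 1:6)
  # cancer-intrinsic gene level 100 vs 10, stroma 0
  g <- c(100 * P["cancer", 1:3], 10 * P["cancer", 4:6])
  G <- matrix(g, 1, dimnames = list("goi", colnames(P)))
  oracle <- bipartition_oracle(g, P, minSize = 3)
  oracleG2 <- which(oracle$split)
  expect_true(setequal(oracleG2, 1:3) || setequal(oracleG2, 4:6))
  expect_lt(oracle$dist, 1e-8)
  for (seed in 1:5) {
    res <- suppressMessages(iterativeGroupFit(G, P, "goi", seed = seed))
    expect_true(res$converged)
    split <- split(names(res$labels), res$labels)
    expect_setequal(split[[1]], paste0("s", if ("s1" %in% split[[1]]) 1:3 else 4:6))
  }
})

test_that("maxIter = 0 returns the initial random split, unconverged", {
  set.seed(91)
  sim <- make_de_simulation(seed = 5, nGenes = 10, nPer = 10, nPlanted = 0)
  G <- cbind(sim$Ghi, sim$Glo)
  P <- cbind(sim$Phi, sim$Plo)
  colnames(G) <- colnames(P) <- paste0("s", 1:20)
  res <- iterativeGroupFit(G, P, "g001", seed = 1, maxIter = 0)
  expect_false(res$converged)
  expect_equal(res$nIter, 0L)
  expect_equal(as.integer(sort(table(res$labels))), c(10L, 10L))
})

test_that("consensus recovers simulated variant labels and aligns runs", {
  panel <- generateReferencePanel(3, 120, 30, variantFold = 10, seed = 101)
  mix <- simulateMixtures(panel, nPerVariant = 25, noisePrecision = 100,
                          seed = 102)
  G <- exprMixtures(mix)
  P <- cellProportions(mix)
  res <- suppressMessages(consensusGrouping(G, P, panel@variantGene,
                                            nRuns = 3, seed = 103,
                                            cancerType = "cancer"))
  truth <- mixtureTruth(mix)@assignedVariant
  acc <- mean((consensusLabels(res) == "high") == (truth == "cancer_hi"))
  expect_gte(acc, 0.95)
  expect_gte(res@groupGeneLevels["high"], res@groupGeneLevels["low"])
  expect_true(all(res@agreement >= 2 / 3))
})

test_that("a single-variant null converges with agreeing group estimates", {
  panel <- generateReferencePanel(3, 120, 30, variantFold = 10, seed = 111)
  mix <- simulateMixtures(panel, nPerVariant = 20, noisePrecision = 100,
                          seed = 112)
  keep <- mixtureTruth(mix)@assignedVariant == "cancer_lo"
  G <- exprMixtures(mix)[, keep]
  P <- cellProportions(mix)[, keep]
  res <- suppressMessages(iterativeGroupFit(G, P, panel@variantGene, seed = 7))
  expect_true(res$converged)
  lev <- res$geneLevels[, "cancer"]
  expect_lt(abs(lev[1] - lev[2]) / mean(lev), 0.35)  # agree within noise
})

test_that("consensus is invariant to group relabeling (high/low alignment)", {
  panel <- generateReferencePanel(3, 120, 30, seed = 121)
  mix <- simulateMixtures(panel, nPerVariant = 20, noisePrecision = 100,
                          seed = 122)
  G <- exprMixtures(mix); P <- cellProportions(mix)
  r1 <- suppressMessages(consensusGrouping(G, P, panel@variantGene,
                                           seed = 123, cancerType = "cancer"))
  # reversing the sample order changes which random group is "group 1"
  # in each run, but not the aligned consensus
  idx <- rev(seq_len(ncol(G)))
  r2 <- suppressMessages(consensusGrouping(G[, idx], P[, idx],
                                           panel@variantGene,
                                           seed = 123, cancerType = "cancer"))
  agree <- mean(consensusLabels(r1)[colnames(G)] ==
                consensusLabels(r2)[colnames(G)])
  expect_gte(agree, 0.95)
})

test_that("recursive partition orders three planted variants", {
  set.seed(131)
  k <- 2; nPer <- 20
  lev <- c(100, 30, 5)
  P <- matrix(rgamma(k * 3 * nPer, 2), k)
  P <- sweep(P, 2, colSums(P), "/")
  rownames(P) <- c("cancer", "stroma")
  colnames(P) <- paste0("s", seq_len(3 * nPer))
  variant <- rep(1:3, each = nPer)
  goiBulk <- lev[variant] * P["cancer", ] + 0 * P["stroma", ]
  filler <- matrix(10 * P["stroma", ] + 5 * P["cancer", ], 1)
  G <- rbind(goi = goiBulk * exp(rnorm(3 * nPer, sd = 0.03)), filler)
  rownames(G) <- c("goi", "f1")
  colnames(G) <- colnames(P)
  res <- suppressMessages(recursivePartition(G, P, "goi", depth = 2,
                                             seed = 132,
                                             cancerType = "cancer"))
  expect_length(res$groups, 3)
  expect_true(all(diff(res$geneLevels) < 0))
  top <- res$groups[[1]]; bottom <- res$groups[[3]]
  expect_gte(mean(top %in% colnames(P)[variant == 1]), 0.9)
  expect_gte(mean(bottom %in% colnames(P)[variant == 3]), 0.9)
})

test_that("depth 1 equals a single consensus grouping", {
  panel <- generateReferencePanel(3, 120, 20, seed = 141)
  mix <- simulateMixtures(panel, nPerVariant = 15, noisePrecision = 100,
                          seed = 142)
  G <- exprMixtures(mix); P <- cellProportions(mix)
  cons <- suppressMessages(consensusGrouping(G, P, panel@variantGene,
                                             seed = 143, cancerType = "cancer"))
  part <- suppressMessages(recursivePartition(G, P, panel@variantGene,
                                              depth = 1, seed = 143,
                                              cancerType = "cancer"))
  expect_length(part$groups, 2)
  expect_setequal(part$groups[[1]],
                  names(consensusLabels(cons))[consensusLabels(cons) == "high"])
})

test_that("tercile concordance handles identical, reversed and middle shifts", {
  s <- setNames(9:1, paste0("x", 1:9))
  same <- tercileConcordance(s, s)
  expect_equal(same$top$shared, 3)
  expect_equal(same$top$onlyA, 0)
  expect_equal(same$bottom$shared, 3)
  revd <- tercileConcordance(s, setNames(1:9, paste0("x", 1:9)))
  expect_equal(revd$top$shared, 0)
  expect_equal(revd$top$onlyA, 3)
  # permuting scores only inside the middle bin leaves top/bottom intact
  s2 <- s
  s2[c("x4", "x5", "x6")] <- s[c("x6", "x4", "x5")]
  mid <- tercileConcordance(s, s2)
  expect_equal(mid$top$shared, 3)
  expect_equal(mid$bottom$shared, 3)
})

test_that("grouping accuracy is uncorrelated with tumor purity", {
  panel <- generateReferencePanel(4, 400, 30, variantFold = 10, seed = 151)
  mix <- simulateMixtures(panel, nPerVariant = 50, noisePrecision = 100,
                          seed = 152)
  G <- exprMixtures(mix); P <- cellProportions(mix)
  res <- suppressMessages(consensusGrouping(G, P, panel@variantGene,
                                            seed = 153, cancerType = "cancer"))
  truth <- mixtureTruth(mix)@assignedVariant
  correct <- (consensusLabels(res) == "high") == (truth == "cancer_hi")
  purity <- P["cancer", ]
  r <- if (sd(correct) == 0) 0 else cor(as.numeric(correct), purity)
  expect_lt(abs(r), 0.2)
  # bulk-value ranking, by contrast, is purity-driven: among truly
  # cancer-low samples, the bulk gene value still rises with purity
  bulk <- G[panel@variantGene, ]
  lowIdx <- truth == "cancer_lo"
  expect_gt(cor(bulk[lowIdx], purity[lowIdx]), 0.5)
})
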