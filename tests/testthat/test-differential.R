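# Cell-type t tests, BH adjustment, DE calling, hypergeometric overlap.

make_cte <- function(means, ses, nu = 28, active = NULL) {
  E <- as.matrix(means); S <- as.matrix(ses)
  if (is.null(active)) active <- matrix(FALSE, nrow(E), ncol(E))
  if (is.null(rownames(E))) rownames(E) <- paste0("g", seq_len(nrow(E)))
  rownames(S) <- rownames(E); rownames(active) <- rownames(E)
  colnames(E) <- colnames(S) <- colnames(active) <- paste0("ct", seq_len(ncol(E)))
  new("CellTypeExpression", E = E, S = S, nu = nu,
      nSamples = as.integer(nu + ncol(E)), active = active)
}

test_that("the t statistic matches its closed form", {
  hi <- make_cte(8, 0.5)
  lo <- make_cte(4, 0.5)
  rec <- cellTypeTTest(hi, lo, 1)
  expect_equal(rec$t, (8 - 4) / sqrt(0.25 + 0.25), tolerance = 1e-10)
  expect_equal(rec$t, 5.65685, tolerance = 1e-5)
  # Welch-Satterthwaite df with equal components reduces to 2 * nu
  expect_equal(rec$df, 2 * 28)
  expect_equal(rec$p, 2 * pt(-abs(rec$t), 56), tolerance = 1e-12)
})

test_that("identical groups give t = 0, p = 1; swapping groups negates t", {
  hi <- make_cte(c(5, 9), c(0.3, 0.7))
  expect_equal(cellTypeTTest(hi, hi, 1)$t, c(0, 0))
  expect_equal(cellTypeTTest(hi, hi, 1)$p, c(1, 1))
  lo <- make_cte(c(4, 11), c(0.4, 0.6))
  ab <- cellTypeTTest(hi, lo, 1)
  ba <- cellTypeTTest(lo, hi, 1)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
})

test_that("degenerate zero-SE records follow the stated contract", {
  hi <- make_cte(c(5, 8), c(0, 0))
  lo <- make_cte(c(5, 4), c(0, 0))
  expect_warning(rec <- cellTypeTTest(hi, lo, 1), "zero SE")
  expect_equal(rec$t[1], 0)
  expect_equal(rec$p[1], 1)
  expect_equal(rec$p[2], 0)
  expect_true(rec$degenerate[2])
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bhAdjust(0.37), 0.37)
  set.seed(161)
  p <- runif(50)
  q <- bhAdjust(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(q <= 1))
  # permutation invariance
  perm <- sample(50)
  expect_equal(bhAdjust(p[perm])[order(perm)], q)
  expect_error(bhAdjust(c(0.1, NA)), "NA")
})

test_that("DE calling applies the joint fold-change and FDR filter", {
  rec <- data.frame(gene = c("a", "b", "c", "d"),
                    q = c(0.01, 0.01, 0.06, 0.01),
                    log2fc = c(1.0, 0.9, 3, -2))
  de <- callDE(rec)
  expect_equal(de$up, "a")    # log2fc 1.0 meets FC = 2 exactly
  expect_equal(de$down, "d")  # b fails FC, c fails q
})

test_that("hypergeometric overlap matches the enumeration oracle", {
  u <- paste0("g", 1:20)
  res <- hypergeomOverlap(u[1:4], u[c(1:3, 10, 11)], u)
  expect_equal(res$overlap, 3)
  expect_equal(res$p, 155 / 4845, tolerance = 1e-12)
  expect_equal(res$p, hyper_upper_enum(3, 5, 4, 20), tolerance = 1e-12)
  set.seed(162)
  for (case in 1:10) {
    N <- sample(10:40, 1)
    uni <- paste0("x", seq_len(N))
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    q <- sample(uni, n); tg <- sample(uni, K)
    res <- hypergeomOverlap(q, tg, uni)
    expect_equal(res$p, hyper_upper_enum(res$overlap, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("hypergeometric edge cases: zero overlap and total overlap", {
  u <- paste0("g", 1:10)
  expect_equal(hypergeomOverlap(u[1:3], u[8:10], u)$p, 1)
  expect_equal(hypergeomOverlap(u, u, u)$p, 1)
  expect_error(hypergeomOverlap("a", "a", character(0)), "universe")
  expect_error(hypergeomOverlap("zz", u[1:2], u), "subset")
})

test_that("planted cancer-cell changes are found; null calls stay nominal", {
  sim <- make_de_simulation(seed = 10)
  hi <- deconvolveExpression(sim$Ghi, sim$Phi)
  lo <- deconvolveExpression(sim$Glo, sim$Plo)
  rec <- cellTypeTTest(hi, lo, "cancer")
  de <- callDE(rec)
  sens <- mean(sim$plantedGenes %in% de$up)
  expect_gte(sens, 0.8)
  fdr <- if (length(de$up)) mean(!de$up %in% sim$plantedGenes) else 0
  expect_lte(fdr, 0.1)
  # unchanged cell types produce (almost) no calls
  for (ct in c("stroma", "immune")) {
    deCt <- callDE(cellTypeTTest(hi, lo, ct))
    expect_lte(length(deCt$up) + length(deCt$down), 0.05 * 200)
  }
})

test_that("type-I error is nominal under a global null", {
  sim <- make_de_simulation(seed = 20, nGenes = 1000, nPlanted = 0,
                             noiseType = "additive")
  hi <- deconvolveExpression(sim$Ghi, sim$Phi)
  lo <- deconvolveExpression(sim$Glo, sim$Plo)
  rec <- cellTypeTTest(hi, lo, "cancer")
  rate <- mean(rec$p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
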