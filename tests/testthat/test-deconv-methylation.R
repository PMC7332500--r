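# Informative-probe selection, constrained factorization, stability-based
# choice of k, and cell-type matching.

test_that("one-vs-rest selection ranks a class's own probes first", {
  set.seed(31)
  # 3 classes x 3 replicate profiles; class A owns probes 1:10
  nP <- 60
  base <- matrix(0.1, nP, 12)
  cls <- rep(c("A", "B", "C"), each = 4)
  base[1:10, cls == "A"] <- 0.9
  base[11:20, cls == "B"] <- 0.9
  base[21:30, cls == "C"] <- 0.9
  prof <- pmin(pmax(base + rnorm(length(base), sd = 0.005), 0), 1)
  rownames(prof) <- sprintf("p%03d", seq_len(nP))
  sel <- selectInformativeProbes(prof, cls, nProbes = 30, pThreshold = 1e-5)
  expect_setequal(sel, sprintf("p%03d", 1:30))
})

test_that("selection falls back to effect ranking for single-profile panels", {
  panel <- generateReferencePanel(3, 120, 20, seed = 2)
  expect_message(sel <- selectInformativeProbes(panel, nProbes = 60),
                 "effect-size")
  expect_equal(length(sel), 60)
  expect_equal(anyDuplicated(sel), 0L)
})

test_that("too few passing probes returns all that pass, with a warning", {
  set.seed(32)
  prof <- matrix(runif(40, 0.4, 0.6), 20, 2,
                 dimnames = list(sprintf("p%02d", 1:20), NULL))
  prof[1:5, 1] <- 0.95; prof[1:5, 2] <- 0.05
  expect_warning(
    expect_message(sel <- selectInformativeProbes(prof, c("A", "B"),
                                                  nProbes = 500)),
    "only")
  expect_lt(length(sel), 500)
  expect_true(all(sprintf("p%02d", 1:5) %in% sel))
})

test_that("identical classes yield an empty selection with a warning", {
  prof <- matrix(0.5, 30, 2, dimnames = list(sprintf("p%02d", 1:30), NULL))
  expect_warning(
    expect_message(sel <- selectInformativeProbes(prof, c("A", "B"))),
    "no probes")
  expect_length(sel, 0)
})

test_that("proportions are recovered exactly when profiles are fixed", {
  M <- matrix(c(1, 0, 0.5, 0, 1, 0.5), ncol = 2)
  P <- matrix(c(0.3, 0.7, 0.6, 0.4), 2, 2)
  B <- M %*% P
  Pest <- histoepi:::cpp_simplex_cols(B, M)
  expect_lt(max(abs(Pest - P)), 1e-6)
})

test_that("blind factorization of noiseless 3-type mixtures is near-exact", {
  panel <- generateReferencePanel(3, 120, 20, seed = 41)
  mix <- simulateMixtures(panel, nPerVariant = 20, noisePrecision = NULL,
                          seed = 42)
  B <- methMixtures(mix)
  fit <- deconvolveMethylation(B, 3, nRestarts = 5, seed = 43)
  m <- matchCellTypes(fit, references = methProfiles(panel))
  ord <- order(m$assignment)
  r <- diag(cor(t(cellProportions(fit)[ord, ]), t(cellProportions(mix))))
  expect_true(all(r >= 0.999))
})

test_that("k = 1 reduces to the per-probe mean with unit proportions", {
  B <- matrix(runif(40), 10, 4, dimnames = list(paste0("p", 1:10), NULL))
  fit <- deconvolveMethylation(B, 1)
  expect_equal(unname(cellProportions(fit)), matrix(1, 1, 4))
  expect_equal(unname(methProfiles(fit))[, 1], unname(rowMeans(B)))
})

test_that("RSS is non-increasing and constraints hold exactly", {
  panel <- generateReferencePanel(3, 90, 10, seed = 51)
  mix <- simulateMixtures(panel, nPerVariant = 10, noisePrecision = 100,
                          seed = 52)
  fit <- deconvolveMethylation(methMixtures(mix), 3, nRestarts = 2, seed = 53)
  expect_true(all(diff(fit@rssTrace) <= 1e-9))
  P <- cellProportions(fit)
  expect_true(all(abs(colSums(P) - 1) < 1e-8))
  expect_true(all(P >= 0))
  M <- methProfiles(fit)
  expect_true(all(M >= 0 & M <= 1))
})

test_that("stability selects the generating number of cell types", {
  panel <- generateReferencePanel(3, 120, 10, seed = 61)
  mix <- simulateMixtures(panel, nPerVariant = 15, noisePrecision = 100,
                          seed = 62)
  ch <- chooseNumCellTypes(methMixtures(mix), kRange = 2:4, nBoot = 5,
                           nRestarts = 2, seed = 63)
  expect_equal(ch$k, 3)
  expect_equal(unname(ch$stability["3"] >= 0.9), TRUE)
})

test_that("k = 1 stability is 1 and pure noise declines with k", {
  set.seed(64)
  B <- matrix(runif(60 * 30), 60, 30,
              dimnames = list(paste0("p", 1:60), paste0("s", 1:30)))
  suppressWarnings(ch <- chooseNumCellTypes(B, kRange = c(1, 2, 4), nBoot = 4,
                                            nRestarts = 2, seed = 65))
  s <- ch$stability
  expect_equal(unname(s["1"]), 1)
  expect_true(s["2"] >= s["4"])  # monotone trend, not exact values
})

test_that("matching recovers identity and permutations", {
  panel <- generateReferencePanel(4, 160, 10, seed = 71)
  M <- methProfiles(panel)
  ident <- matchCellTypes(M, references = M)
  expect_equal(ident$assignment, 1:4)
  expect_equal(ident$labels, colnames(M))
  perm <- c(3, 1, 4, 2)
  res <- matchCellTypes(M[, perm], references = M)
  expect_equal(res$assignment, perm)
  expect_false(res$ambiguous)
})

test_that("marker tables label the cancer column", {
  set.seed(72)
  E <- matrix(exp(rnorm(60, 3, 1)), 20, 3,
              dimnames = list(paste0("g", 1:20), NULL))
  E["g5", 3] <- 1000  # marker gene high only in column 3
  markers <- data.frame(gene = c("g5", "g11"), label = c("cancer", "stroma"))
  E["g11", 1] <- 800
  res <- matchCellTypes(E, markers = markers)
  expect_equal(res$labels[3], "cancer")
  expect_equal(res$labels[1], "stroma")
})
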