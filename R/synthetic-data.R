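#' Generate a labeled reference panel with two cancer variants
#'
#' Builds \code{k} separable methylation archetypes and matched expression
#' profiles. Probes are split evenly across archetypes; a class's own probes
#' sit near beta 0.9 while all other classes sit near 0.1, so each class
#' owns at least \code{nProbes / (2k)} discriminative probes with a beta gap
#' of at least 0.6. Expression has \code{k + 1} columns: the \code{k - 1}
#' non-cancer classes plus two cancer variants ("cancer_hi", "cancer_lo")
#' that share the cancer methylation archetype and differ only in the
#' expression of \code{variantGene}, by a factor \code{variantFold}.
#'
#' @param k integer(1) >= 2, number of cell types (the last is the cancer
#'   type carrying the two expression variants).
#' @param nProbes integer(1) >= 10 * k, number of methylation probes.
#' @param nGenes integer(1) >= 1, number of genes.
#' @param variantFold numeric(1) > 1, expression fold between the cancer
#'   variants at the variant gene.
#' @param seed integer(1), RNG seed; identical seeds give identical panels.
#' @param variantGene character(1) or NULL; gene carrying the variant
#'   difference (default: the first gene).
#' @return a [ReferencePanel-class] object.
#' @examples
#' panel <- generateReferencePanel(k = 2, nProbes = 100, nGenes = 50,
#'                                 variantFold = 10, seed = 1)
#' panel
#' @export
generateReferencePanel <- function(k, nProbes, nGenes, variantFold = 10,
                                   seed = 1L, variantGene = NULL) {
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k < 2)
    stop("'k' must be a single finite value >= 2")
  if (!is.numeric(nProbes) || !is.finite(nProbes) || nProbes < 10 * k)
    stop("'nProbes' must be finite and >= 10 * k")
  if (!is.numeric(nGenes) || !is.finite(nGenes) || nGenes < 1)
    stop("'nGenes' must be a positive finite count")
  if (!is.numeric(variantFold) || !is.finite(variantFold) || variantFold <= 1)
    stop("'variantFold' must be finite and > 1")
  k <- as.integer(k); nProbes <- as.integer(nProbes); nGenes <- as.integer(nGenes)

  base <- c("stroma", "immune", "epithelial",
            if (k > 4) paste0("type_", seq_len(k - 4)))
  classes <- c(base[seq_len(k - 1)], "cancer")
  probes <- sprintf("cg%05d", seq_len(nProbes))
  genes <- sprintf("g%04d", seq_len(nGenes))
  if (is.null(variantGene)) variantGene <- genes[1]
  if (!variantGene %in% genes) genes[1] <- variantGene

  .with_seed(seed, function() {
    # methylation archetypes: block-structured bimodal betas, as on real
    # 450K arrays where unmethylated/methylated CpGs sit near (not at)
    # 0 and 1; truncation keeps the between-class gap >= 0.7
    owner <- rep(seq_len(k), length.out = nProbes)
    M <- matrix(pmin(stats::rbeta(nProbes * k, 2, 40), 0.15), nProbes, k,
                dimnames = list(probes, classes))
    for (c in seq_len(k)) {
      own <- owner == c
      M[own, c] <- 1 - pmin(stats::rbeta(sum(own), 2, 40), 0.15)
    }

    # expression: lognormal class profiles; the two cancer variants share
    # every gene except the variant gene
    exprClasses <- c(classes[-k], "cancer_hi", "cancer_lo")
    E <- matrix(exp(stats::rnorm(nGenes * (k - 1), mean = 3, sd = 1)),
                nGenes, k - 1)
    cancerBase <- exp(stats::rnorm(nGenes, mean = 3, sd = 1))
    E <- cbind(E, cancerBase, cancerBase)
    dimnames(E) <- list(genes, exprClasses)
    vLow <- 10
    E[variantGene, "cancer_hi"] <- vLow * variantFold
    E[variantGene, "cancer_lo"] <- vLow
    # keep the variant gene quiet elsewhere so cancer-intrinsic signal
    # dominates its bulk level
    if (k > 1) E[variantGene, seq_len(k - 1)] <- stats::runif(k - 1, 0, 1)

    new("ReferencePanel", methProfiles = M, exprProfiles = E,
        classLabels = classes, variantGene = variantGene,
        variantFold = variantFold)
  })
}

#' Simulate paired methylation/expression bulk mixtures with ground truth
#'
#' Draws one proportion vector per sample from a Dirichlet distribution and
#' uses the SAME vector to mix the methylation references and the matched
#' expression references, so the two data types are coupled exactly as in
#' bulk tissue. Each cancer variant contributes \code{nPerVariant} mixtures
#' (the default design is 50 + 50 = 100). Methylation noise resamples each
#' reference beta from a Beta distribution with mean equal to the reference
#' value and concentration \code{noisePrecision} (mean-preserving, support
#' \[0, 1\]); \code{NULL} skips noise so each mixture column equals the
#' exact linear combination. Expression mixing is deterministic by default;
#' \code{exprNoise = "poisson"} resamples summed per-gene contributions.
#'
#' @param panel a [ReferencePanel-class].
#' @param nPerVariant integer(1) >= 1, mixtures per cancer variant.
#' @param alpha numeric vector of length k, Dirichlet concentration
#'   (default uniform on the simplex).
#' @param noisePrecision positive numeric(1) or NULL, Beta-noise
#'   concentration applied to methylation references (default 100).
#' @param seed integer(1), RNG seed.
#' @param exprNoise "none" (default) or "poisson".
#' @return a [MixtureSet-class] containing methylation (probes x samples),
#'   expression (genes x samples) and a [MixtureTruth-class].
#' @examples
#' panel <- generateReferencePanel(3, 120, 40, variantFold = 10, seed = 1)
#' mix <- simulateMixtures(panel, nPerVariant = 10, seed = 2)
#' mix
#' @export
simulateMixtures <- function(panel, nPerVariant, alpha = NULL,
                             noisePrecision = 100, seed = 1L,
                             exprNoise = c("none", "poisson")) {
  stopifnot(is(panel, "ReferencePanel"))
  exprNoise <- match.arg(exprNoise)
  k <- ncol(panel@methProfiles)
  if (!is.numeric(nPerVariant) || nPerVariant < 1)
    stop("'nPerVariant' must be >= 1")
  nPerVariant <- as.integer(nPerVariant)
  if (is.null(alpha)) alpha <- rep(1, k)
  if (length(alpha) != k) stop("'alpha' must have length k")
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("'alpha' entries must be positive and finite")
  if (!is.null(noisePrecision) &&
      (!is.numeric(noisePrecision) || noisePrecision <= 0))
    stop("'noisePrecision' must be positive or NULL")

  variants <- c("cancer_hi", "cancer_lo")
  variants <- variants[variants %in% colnames(panel@exprProfiles)]
  if (length(variants) == 0) variants <- colnames(panel@exprProfiles)[k]
  n <- nPerVariant * length(variants)
  samples <- sprintf("s%03d", seq_len(n))
  assigned <- rep(variants, each = nPerVariant)
  names(assigned) <- samples

  M <- panel@methProfiles
  nonCancer <- colnames(panel@exprProfiles)[seq_len(k - 1)]

  .with_seed(seed, function() {
    P <- t(.rdirichlet(n, alpha))  # k x n
    dimnames(P) <- list(panel@classLabels, samples)

    B <- matrix(NA_real_, nrow(M), n, dimnames = list(rownames(M), samples))
    G <- matrix(NA_real_, nrow(panel@exprProfiles), n,
                dimnames = list(rownames(panel@exprProfiles), samples))
    for (j in seq_len(n)) {
      Mj <- M
      if (!is.null(noisePrecision)) {
        mu <- pmin(pmax(M, 1e-6), 1 - 1e-6)
        Mj <- matrix(stats::rbeta(length(mu), mu * noisePrecision,
                                  (1 - mu) * noisePrecision),
                     nrow(M), k, dimnames = dimnames(M))
      }
      B[, j] <- Mj %*% P[, j]
      Ej <- cbind(panel@exprProfiles[, nonCancer, drop = FALSE],
                  panel@exprProfiles[, assigned[j]])
      G[, j] <- Ej %*% P[, j]
    }
    if (exprNoise == "poisson") {
      G[] <- stats::rpois(length(G), lambda = G)
    }

    truth <- new("MixtureTruth", P = P, assignedVariant = assigned,
                 alpha = as.numeric(alpha),
                 noisePrecision = if (is.null(noisePrecision)) NA_real_
                                  else noisePrecision,
                 seed = as.integer(seed))
    new("MixtureSet", methylation = B, expression = G, truth = truth)
  })
}
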