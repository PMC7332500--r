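#' Filter methylation probes by missingness, chromosome and blocklists
#'
#' Removes probes with any missing beta value, probes on sex chromosomes,
#' and probes on supplied blocklists (e.g. cross-reactive or SNP-overlap
#' masks consumed as plain probe-ID lists). The filters are independent set
#' operations, so their application order does not change the result. A
#' per-criterion removal log is attached as the \code{"filterLog"}
#' attribute and reported via \code{message()}.
#'
#' @param meth numeric matrix, probes x samples, with probe IDs as
#'   rownames; values in \[0, 1\] or NA.
#' @param blocklists list of character vectors of probe IDs to drop (or a
#'   single character vector).
#' @param dropMissing logical(1); drop probes with any NA (default TRUE).
#' @param dropSexChromosomes logical(1); drop probes on chrX/chrY
#'   (requires \code{probeChrom}).
#' @param probeChrom named character vector mapping probe IDs to
#'   chromosomes (e.g. "chr1", "chrX").
#' @return the filtered matrix (input untouched), with attribute
#'   \code{filterLog}: named integer counts removed per criterion.
#' @examples
#' B <- matrix(runif(20), 10, 2,
#'             dimnames = list(sprintf("cg%02d", 1:10), c("s1", "s2")))
#' B[1, 1] <- NA
#' filterProbes(B, blocklists = list(c("cg02", "cg03")))
#' @export
filterProbes <- function(meth, blocklists = list(), dropMissing = TRUE,
                         dropSexChromosomes = FALSE, probeChrom = NULL) {
  meth <- as.matrix(meth)
  if (is.null(rownames(meth))) stop("'meth' must have probe IDs as rownames")
  if (is.character(blocklists)) blocklists <- list(blocklists)
  if (dropSexChromosomes && is.null(probeChrom))
    stop("'probeChrom' annotations are required to drop sex chromosomes")

  keep <- rep(TRUE, nrow(meth))
  names(keep) <- rownames(meth)
  log <- c(missing = 0L, sex_chromosome = 0L, blocklist = 0L)

  if (dropMissing) {
    bad <- rowSums(is.na(meth)) > 0
    log["missing"] <- sum(bad & keep)
    keep <- keep & !bad
  }
  if (dropSexChromosomes) {
    chr <- probeChrom[rownames(meth)]
    bad <- !is.na(chr) & chr %in% c("chrX", "chrY", "X", "Y")
    log["sex_chromosome"] <- sum(bad & keep)
    keep <- keep & !bad
  }
  if (length(blocklists)) {
    blocked <- rownames(meth) %in% unique(unlist(blocklists))
    log["blocklist"] <- sum(blocked & keep)
    keep <- keep & !blocked
  }

  if (!any(keep)) stop("no probes remain after filtering")
  out <- meth[keep, , drop = FALSE]
  attr(out, "filterLog") <- log
  message(sprintf("filterProbes: removed %d missing, %d sex-chromosome, %d blocklisted; %d probes remain",
                  log["missing"], log["sex_chromosome"], log["blocklist"],
                  nrow(out)))
  out
}

# Vectorized one-way ANOVA F-test p-values per probe for a factor covariate.
.anova_p <- function(B, f) {
  f <- droplevels(factor(f))
  n <- length(f)
  g <- nlevels(f)
  groupMeans <- vapply(levels(f), function(l)
    rowMeans(B[, f == l, drop = FALSE]), numeric(nrow(B)))
  counts <- as.numeric(table(f))
  grand <- rowMeans(B)
  ssb <- as.numeric((groupMeans - grand)^2 %*% counts)
  sst <- rowSums((B - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  Fstat <- (ssb / (g - 1)) / (ssw / (n - g))
  stats::pf(Fstat, g - 1, n - g, lower.tail = FALSE)
}

# Vectorized simple-linear-regression slope-test p-values per probe.
.slope_p <- function(B, x) {
  n <- length(x)
  r <- suppressWarnings(as.numeric(stats::cor(t(B), x)))
  r2 <- pmin(r^2, 1 - 1e-15)
  tstat <- r * sqrt((n - 2) / (1 - r2))
  2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
}

#' Filter probes associated with sample covariates
#'
#' Tests every probe against every covariate — one-way analysis-of-variance
#' F test for categorical covariates, simple linear-regression slope test
#' for continuous ones — adjusts p-values per covariate by
#' Benjamini-Hochberg, and removes probes significant for ANY covariate at
#' the FDR threshold. Samples missing a covariate value are dropped from
#' that covariate's test only; constant covariates are skipped with a
#' warning.
#'
#' @param meth numeric matrix, probes x samples, complete beta values.
#' @param covariates data.frame, rows = samples (matched to columns of
#'   \code{meth} by name when rownames are present, else by position);
#'   factor/character columns are treated as categorical, numeric as
#'   continuous.
#' @param fdrThreshold numeric(1), per-covariate FDR cutoff (default 0.01).
#' @return filtered matrix with attribute \code{covariateLog}: probes
#'   removed per covariate.
#' @export
filterProbesByCovariates <- function(meth, covariates, fdrThreshold = 0.01) {
  meth <- as.matrix(meth)
  if (is.null(covariates) || NCOL(covariates) == 0) return(meth)
  covariates <- as.data.frame(covariates)
  if (!is.null(rownames(covariates)) && !is.null(colnames(meth)) &&
      all(colnames(meth) %in% rownames(covariates))) {
    covariates <- covariates[colnames(meth), , drop = FALSE]
  } else if (nrow(covariates) != ncol(meth)) {
    stop("covariate rows must match methylation samples")
  }

  drop <- rep(FALSE, nrow(meth))
  log <- integer(0)
  for (nm in colnames(covariates)) {
    v <- covariates[[nm]]
    ok <- !is.na(v)
    if (sum(ok) < 3 || length(unique(v[ok])) < 2) {
      warning(sprintf("covariate '%s' is constant or too sparse; skipped", nm))
      next
    }
    Bsub <- meth[, ok, drop = FALSE]
    p <- if (is.numeric(v)) {
      if (any(!is.finite(v[ok]))) stop("continuous covariates must be finite")
      .slope_p(Bsub, v[ok])
    } else {
      f <- droplevels(factor(v[ok]))
      if (any(table(f) < 2)) {
        warning(sprintf("covariate '%s' has a level with < 2 samples; skipped",
                        nm))
        next
      }
      .anova_p(Bsub, f)
    }
    q <- stats::p.adjust(p, method = "BH")
    hit <- !is.na(q) & q < fdrThreshold
    log[nm] <- sum(hit)
    drop <- drop | hit
  }

  out <- meth[!drop, , drop = FALSE]
  if (nrow(out) == 0) stop("no probes remain after covariate filtering")
  attr(out, "covariateLog") <- log
  out
}
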