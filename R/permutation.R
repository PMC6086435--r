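#' Decompose a phenotype into structure and genotypic components
#'
#' Splits the observed trait Y into the population-structure component P
#' (least-squares fitted values of Y on the principal components plus an
#' intercept) and the residual genotypic component G = Y - P, so that
#' Y = P + G exactly. The conditional permutation test reshuffles only G,
#' preserving the structure signal.
#'
#' With \code{method = "marginal"}, P is instead the sum of the fitted
#' values of per-PC simple regressions (an alternative reading of averaging
#' each PC's effect); G is still Y - P, so the identity Y = P + G holds
#' either way, but P and G are no longer orthogonal.
#'
#' @param y numeric trait vector, no missing values.
#' @param pcs accession x k PC score matrix (rows aligned with \code{y}).
#' @param method "joint" (default) or "marginal".
#' @return list with elements \code{Y}, \code{P}, \code{G}.
#' @export
decomposePhenotype <- function(y, pcs, method = c("joint", "marginal")) {
  method <- match.arg(method)
  if (anyNA(y)) stop("trait values must be complete for the decomposition")
  pcs <- as.matrix(pcs)
  stopifnot(nrow(pcs) == length(y))
  if (method == "joint") {
    X <- cbind(1, pcs)
    if (qr(X)$rank < ncol(X)) stop("rank-deficient PC matrix")
    P <- as.numeric(X %*% qr.coef(qr(X), y))
  } else {
    P <- rep(mean(y), length(y))
    for (j in seq_len(ncol(pcs))) {
      pc <- pcs[, j]
      b <- stats::cov(pc, y) / stats::var(pc)
      P <- P + b * (pc - mean(pc))
    }
  }
  list(Y = y, P = P, G = y - P)
}

#' Genome-wide threshold from the conditional permutation test
#'
#' Determines the -log10(p) significance threshold while preserving the
#' population-structure component of the phenotype. The trait is decomposed
#' as Y = P + G (\code{\link{decomposePhenotype}}); in each permutation the
#' genotypic component is reshuffled (Fisher-Yates) and the reconstructed
#' trait P + Gr is rescanned with the same model and covariates over the
#' variants whose original scan reached \code{prefilter} (a computational
#' shortcut; maxima below that level are truncated). The genome-wide maximum
#' statistic of each permutation is recorded and the threshold is the
#' requested percentile of the maxima: with 1,000 permutations at the 95th
#' percentile, the 50th-largest maximum.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param pheno phenotype data.frame.
#' @param trait trait column name.
#' @param structure \linkS4class{StructureModel} with PCs (and kinship for
#'   \code{model = "mlm"}).
#' @param model "glm" or "mlm". For "mlm" the null-model variance ratio of
#'   the original fit is reused across permutations (P3D).
#' @param nPerm number of permutations (default 1000).
#' @param percentile percentile of the per-permutation maxima (default 95).
#' @param prefilter original-scan -log10(p) cutoff pre-selecting the
#'   rescanned variants (default 2); if no variant passes, all tested
#'   variants are used with a warning.
#' @param seed RNG seed for the permutations.
#' @param scan optional precomputed \linkS4class{AssociationResult} of the
#'   original trait under the same model (avoids rescanning).
#' @return a \linkS4class{ThresholdResult}.
#' @export
conditionalThreshold <- function(g, pheno, trait = "RL", structure,
                                 model = c("glm", "mlm"), nPerm = 1000L,
                                 percentile = 95, prefilter = 2,
                                 seed = 1L, scan = NULL) {
  model <- match.arg(model)
  if (!length(structure@pcs)) stop("structure must carry PC scores")
  if (is.null(scan)) {
    scan <- if (model == "glm") scanGLM(g, pheno, trait, structure)
            else scanMLM(g, pheno, trait, structure)
  }
  stopifnot(scan@model == model)
  tb <- scan@table
  sel <- which(tb$tested & tb$minusLog10P >= prefilter)
  usedFallback <- FALSE
  if (!length(sel)) {
    warning("no variant reached the prefilter; rescanning all tested variants")
    sel <- which(tb$tested)
    usedFallback <- TRUE
  }
  al <- .alignScan(g[sel, ], pheno, trait, structure@pcs)
  n <- length(al$y)
  df <- n - ncol(al$X) - 1L
  if (model == "glm") {
    X <- al$X
    D <- al$D
    transform <- function(y) y
  } else {
    K <- structure@kinship[al$accessions, al$accessions]
    nullFit <- .remlNull(al$y, al$X, K)
    sw <- nullFit$sqrtw
    Ut <- t(nullFit$U)
    X <- (Ut %*% al$X) * sw
    D <- (Ut %*% al$D) * sw
    transform <- function(y) as.numeric(Ut %*% y) * sw
  }
  dec <- decomposePhenotype(al$y, structure@pcs[al$accessions, , drop = FALSE])
  # snap a numerically-zero genotypic component to exact zero so that a
  # trait fully explained by structure yields identical permutations
  if (max(abs(dec$G)) < 1e-8 * max(1, stats::sd(al$y)))
    dec$G[] <- 0
  Q <- qr(X)
  Dt <- qr.resid(Q, D)
  Sxx <- colSums(Dt^2)
  tested <- Sxx > 1e-10 * max(1, n)
  set.seed(seed)
  maxima <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    yb <- dec$P + dec$G[sample.int(n)]
    yt <- qr.resid(Q, transform(yb))
    Sxy <- as.numeric(crossprod(Dt, yt))
    Syy <- sum(yt^2)
    beta <- Sxy / Sxx
    rss <- pmax(Syy - beta^2 * Sxx, 0)
    tval <- beta / sqrt(rss / df / Sxx)
    tval[beta == 0 & rss == 0] <- 0
    lp <- -(log(2) + stats::pt(-abs(tval), df, log.p = TRUE)) / log(10)
    lp[is.infinite(tval)] <- 320
    maxima[b] <- max(lp[tested])
  }
  k <- max(1L, floor(nPerm * (1 - percentile / 100)))
  new("ThresholdResult",
      threshold = sort(maxima, decreasing = TRUE)[k],
      maxima = maxima, percentile = percentile, nPerm = as.integer(nPerm),
      prefilter = prefilter, seed = as.integer(seed),
      usedFallback = usedFallback)
}

#' @rdname ThresholdResult-class
#' @export
setMethod("thresholdValue", "ThresholdResult", function(x) x@threshold)

setMethod("show", "ThresholdResult", function(object) {
  cat(sprintf(
    "ThresholdResult: -log10(p) >= %.3f (%gth percentile of %d permutation maxima)\n",
    object@threshold, object@percentile, object@nPerm))
  if (object@usedFallback)
    cat("  note: prefilter was empty; all variants were rescanned\n")
})
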