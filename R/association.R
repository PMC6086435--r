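## Internal: align genotypes with a phenotype vector and covariates.
## Missing dosages are mean-imputed per variant (association only).
.alignScan <- function(g, pheno, trait, pcs = NULL) {
  y <- pheno[[trait]]
  names(y) <- pheno$accession
  keep <- pheno$accession[!is.na(y)]
  keep <- intersect(keep, accessions(g))
  if (!is.null(pcs)) keep <- intersect(keep, rownames(pcs))
  if (length(keep) < 3) stop("fewer than 3 accessions shared across inputs")
  D <- t(dosage(g[, keep]))              # accessions x variants
  for (j in seq_len(ncol(D))) {
    nas <- is.na(D[, j])
    if (any(nas)) D[nas, j] <- mean(D[, j], na.rm = TRUE)
  }
  X <- cbind(`(Intercept)` = rep(1, length(keep)))
  if (!is.null(pcs)) X <- cbind(X, pcs[keep, , drop = FALSE])
  list(y = unname(y[keep]), D = D, X = X, accessions = keep)
}

## Internal: vectorized single-marker least squares of y on [X, d_j].
## Inputs may be pre-transformed (mixed model); df must be n - ncol(X) - 1
## on the original scale.
.scanCore <- function(y, X, D, df) {
  Q <- qr(X)
  yt <- qr.resid(Q, y)
  Dt <- qr.resid(Q, D)
  Sxx <- colSums(Dt^2)
  Sxy <- as.numeric(crossprod(Dt, yt))
  Syy <- sum(yt^2)
  tested <- Sxx > 1e-10 * max(1, nrow(D))
  beta <- ifelse(tested, Sxy / Sxx, NA_real_)
  rss <- pmax(Syy - beta^2 * Sxx, 0)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / Sxx)
  tval <- beta / se
  tval[tested & beta == 0 & se == 0] <- 0       # zero trait variance
  # -log10(p) via log-scale tail probabilities (stable far beyond p = 1e-300)
  lp <- -(log(2) + stats::pt(-abs(tval), df, log.p = TRUE)) / log(10)
  lp[is.infinite(tval)] <- 320                  # exact fit: cap beyond double
  lp[!tested] <- NA_real_
  beta[!tested] <- NA_real_
  se[!tested] <- NA_real_
  list(beta = beta, se = se, lp = lp, tested = tested)
}

.resultTable <- function(g, core) {
  v <- variantRanges(g)
  data.frame(
    variant = names(v),
    chrom = as.character(seqnames(v)),
    pos = GenomicRanges::start(v),
    ref = mcols(v)$ref,
    alt = mcols(v)$alt,
    maf = unname(maf(g)),
    beta = core$beta,
    se = core$se,
    minusLog10P = core$lp,
    tested = core$tested,
    stringsAsFactors = FALSE)
}

#' Principal components of the genotype matrix
#'
#' PCs of the column-standardized dosage matrix (accessions x variants;
#' missing dosages replaced by the variant mean), sorted by variance
#' explained. Zero-variance variants are dropped before standardization.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param k number of components (default 3).
#' @return a \linkS4class{StructureModel} with the \code{pcs} slot filled;
#'   rownames are accession ids.
#' @export
computePCs <- function(g, k = 3L) {
  n <- length(accessions(g))
  if (k >= n) stop("k must be smaller than the number of accessions")
  D <- t(dosage(g))
  for (j in seq_len(ncol(D))) {
    nas <- is.na(D[, j])
    if (any(nas)) D[nas, j] <- mean(D[, j], na.rm = TRUE)
  }
  sds <- apply(D, 2, stats::sd)
  D <- D[, sds > 0, drop = FALSE]
  D <- scale(D)
  sv <- svd(D, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(scores) <- list(accessions(g), paste0("PC", seq_len(k)))
  new("StructureModel", pcs = scores)
}

#' VanRaden method-1 kinship
#'
#' Centered-dosage cross-product scaled by \eqn{2 \sum_j p_j (1 - p_j)},
#' with \eqn{p_j} the ALT allele frequency. Missing dosages are mean-imputed
#' per variant. Symmetric by construction; a clone pair's mutual kinship
#' equals its self-kinship.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @return a \linkS4class{StructureModel} with the \code{kinship} slot filled.
#' @export
computeKinship <- function(g) {
  if (length(accessions(g)) < 2) stop("need at least 2 accessions")
  D <- t(dosage(g))
  allNA <- rowSums(!is.na(D)) == 0
  if (any(allNA))
    stop("accession(s) with no called genotypes: ",
         paste(accessions(g)[allNA], collapse = ", "))
  p <- colMeans(D, na.rm = TRUE) / 2
  for (j in seq_len(ncol(D))) {
    nas <- is.na(D[, j])
    if (any(nas)) D[nas, j] <- 2 * p[j]
  }
  Z <- sweep(D, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  K <- tcrossprod(Z) / denom
  K <- (K + t(K)) / 2
  dimnames(K) <- list(accessions(g), accessions(g))
  new("StructureModel", kinship = K)
}

#' @rdname StructureModel-class
#' @export
setMethod("pcScores", "StructureModel", function(x) x@pcs)

#' @rdname StructureModel-class
#' @export
setMethod("kinship", "StructureModel", function(x) x@kinship)

setMethod("show", "StructureModel", function(object) {
  cat("StructureModel:",
      if (length(object@pcs)) sprintf("%d PCs,", ncol(object@pcs)) else "no PCs,",
      if (length(object@kinship)) sprintf("kinship %dx%d", nrow(object@kinship),
                                          ncol(object@kinship)) else "no kinship",
      "\n")
  if (length(object@groups))
    cat(sprintf("  compressed into %d groups\n", length(unique(object@groups))))
})

#' Fixed-effects association scan (GLM with PC covariates)
#'
#' Per variant, ordinary least squares of the trait on an intercept, the
#' principal components and the ALT-allele dosage; the p-value is the
#' two-sided t-test of the dosage coefficient (n - k - 2 degrees of freedom
#' with k PCs). Monomorphic or covariate-collinear variants are flagged
#' untested rather than failing the scan.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param pheno phenotype data.frame (columns \code{accession} and the trait).
#' @param trait trait column name.
#' @param structure optional \linkS4class{StructureModel}; its PCs become
#'   covariates. \code{NULL} fits intercept-only (uncorrected scan).
#' @return an \linkS4class{AssociationResult}.
#' @export
scanGLM <- function(g, pheno, trait = "RL", structure = NULL) {
  pcs <- if (!is.null(structure) && length(structure@pcs)) structure@pcs else NULL
  al <- .alignScan(g, pheno, trait, pcs)
  df <- length(al$y) - ncol(al$X) - 1L
  core <- .scanCore(al$y, al$X, al$D, df)
  new("AssociationResult", table = .resultTable(g, core), model = "glm",
      nUsed = length(al$y))
}

## Internal: REML profile of the single-variance-component mixed model on
## the null (no-marker) design, via the spectral decomposition of K.
## Returns the variance ratio, transformed design and log-likelihood.
.remlNull <- function(y, X, K) {
  n <- length(y)
  eig <- eigen(K, symmetric = TRUE)
  lam <- eig$values
  if (min(lam) < -1e-8)
    warning("kinship not PSD; clipping negative eigenvalues at 0")
  lam <- pmax(lam, 0)
  U <- eig$vectors
  yt <- as.numeric(crossprod(U, y))
  Xt <- crossprod(U, X)
  q <- ncol(X)
  crit <- function(logr) {
    r <- exp(logr)
    w <- 1 / (r * lam + 1)
    sw <- sqrt(w)
    Xw <- Xt * sw
    yw <- yt * sw
    fit <- stats::lm.fit(Xw, yw)
    rss <- sum(fit$residuals^2)
    xtx <- crossprod(Xw)
    # REML log-likelihood up to a constant
    -0.5 * ((n - q) * log(rss / (n - q)) + sum(log(r * lam + 1)) +
              determinant(xtx, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(crit, c(-12, 12), maximum = TRUE, tol = 1e-6)
  r <- exp(opt$maximum)
  w <- 1 / (r * lam + 1)
  list(ratio = r, U = U, sqrtw = sqrt(w), logLik = opt$objective,
       lambda = lam)
}

## Internal: kinship-distance compression into `level` groups; returns the
## n x n effective kinship plus the grouping.
.compressKinship <- function(K, level) {
  n <- nrow(K)
  level <- max(1L, min(as.integer(level), n))
  if (level == n)
    return(list(K = K, groups = structure(seq_len(n), names = rownames(K))))
  dis <- stats::as.dist(max(K) - K)
  grp <- stats::cutree(stats::hclust(dis, method = "average"), k = level)
  Z <- outer(grp, seq_len(level), "==") * 1
  cnt <- colSums(Z)
  Kc <- t(Z) %*% K %*% Z / outer(cnt, cnt)
  Keff <- Z %*% Kc %*% t(Z)
  dimnames(Keff) <- dimnames(K)
  list(K = Keff, groups = grp)
}

#' Kinship mixed-model association scan (CMLM-style)
#'
#' Single-variance-component mixed model \eqn{y = \mu + PCs + g\beta + u + e}
#' with \eqn{Var(u) = \sigma^2_g K}. The variance ratio is estimated once by
#' REML on the null (no-marker) model through the spectral decomposition of
#' K and reused for every variant (population parameters previously
#' determined, "P3D"). With \code{compression}, accessions are clustered on
#' kinship distance into groups and the group-mean kinship replaces K before
#' fitting; \code{compression = "auto"} picks the group count from the grid
#' \{n, n/2, n/4\} by null-model REML likelihood, an integer fixes it, and
#' \code{NULL} (default) fits the uncompressed model.
#'
#' @inheritParams scanGLM
#' @param structure a \linkS4class{StructureModel} carrying kinship (and
#'   usually PCs).
#' @param compression NULL, "auto", or an integer group count.
#' @return an \linkS4class{AssociationResult} (model tag "mlm").
#' @export
scanMLM <- function(g, pheno, trait = "RL", structure, compression = NULL) {
  if (!length(structure@kinship)) stop("structure must carry a kinship matrix")
  pcs <- if (length(structure@pcs)) structure@pcs else NULL
  al <- .alignScan(g, pheno, trait, pcs)
  K <- structure@kinship[al$accessions, al$accessions]
  groups <- integer(0)
  if (!is.null(compression)) {
    if (identical(compression, "auto")) {
      n <- length(al$y)
      grid <- unique(pmax(2L, c(n, n %/% 2L, n %/% 4L)))
      fits <- lapply(grid, function(cl) {
        cmp <- .compressKinship(K, cl)
        list(cmp = cmp, fit = .remlNull(al$y, al$X, cmp$K))
      })
      best <- which.max(vapply(fits, function(f) as.numeric(f$fit$logLik),
                               numeric(1)))
      K <- fits[[best]]$cmp$K
      groups <- fits[[best]]$cmp$groups
    } else {
      cmp <- .compressKinship(K, compression)
      K <- cmp$K
      groups <- cmp$groups
    }
  }
  nullFit <- .remlNull(al$y, al$X, K)
  sw <- nullFit$sqrtw
  ystar <- as.numeric(crossprod(nullFit$U, al$y)) * sw
  Xstar <- crossprod(nullFit$U, al$X) * sw
  Dstar <- crossprod(nullFit$U, al$D) * sw
  df <- length(al$y) - ncol(al$X) - 1L
  core <- .scanCore(ystar, Xstar, Dstar, df)
  new("AssociationResult", table = .resultTable(g, core), model = "mlm",
      nUsed = length(al$y))
}

#' @rdname AssociationResult-class
#' @export
setMethod("scanTable", "AssociationResult", function(x) x@table)

#' @rdname AssociationResult-class
#' @export
setMethod("as.data.frame", "AssociationResult",
          function(x, row.names = NULL, optional = FALSE, ...) x@table)

setMethod("show", "AssociationResult", function(object) {
  tb <- object@table
  cat(sprintf("AssociationResult (%s): %d variants, %d tested, n = %d\n",
              object@model, nrow(tb), sum(tb$tested), object@nUsed))
  if (any(tb$tested))
    cat(sprintf("  max -log10(p) = %.2f at %s\n",
                max(tb$minusLog10P[tb$tested]),
                tb$variant[which.max(ifelse(tb$tested, tb$minusLog10P, -Inf))]))
})

#' Genomic inflation factor
#'
#' Median association chi-square divided by its null median (0.4549), a
#' standard check that structure correction is adequate (values near 1).
#'
#' @param res an \linkS4class{AssociationResult}.
#' @return lambda, the genomic inflation factor.
#' @export
genomicInflation <- function(res) {
  lp <- res@table$minusLog10P[res@table$tested]
  chi <- stats::qchisq(-lp * log(10), df = 1, lower.tail = FALSE, log.p = TRUE)
  stats::median(chi) / stats::qchisq(0.5, 1)
}
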