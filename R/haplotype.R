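#' Build gene-level haplotypes from defining variants
#'
#' The defining variants of a gene are its non-synonymous / large-effect ORF
#' variants plus its promoter variants (from
#' \code{\link{annotateVariants}}). Each accession's haplotype is the
#' ordered string of R (ref) / A (alt) calls at those variants, read from
#' homozygous dosages; accessions with any missing or heterozygous defining
#' call are excluded and counted (inbred-panel convention). Classes with
#' frequency at or above \code{majorMinFreq} are flagged major.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param gene gene id.
#' @param annot annotation table from \code{\link{annotateVariants}}.
#' @param majorMinFreq major-haplotype frequency threshold (default 0.05).
#' @param accessionSubset optional accessions to restrict to.
#' @return a \linkS4class{HaplotypeTable}.
#' @export
buildHaplotypes <- function(g, gene, annot, majorMinFreq = 0.05,
                            accessionSubset = NULL) {
  def <- annot[!is.na(annot$gene) & annot$gene == gene &
                 (annot$zone == "promoter" |
                    (annot$zone == "ORF" &
                       (annot$consequence %in%
                          c("nonsynonymous", "stop_gain", "stop_loss",
                            "start_loss", "frameshift", "inframe_indel") |
                          annot$largeEffect))), , drop = FALSE]
  if (!nrow(def)) stop("gene ", gene, " has no defining variants")
  vids <- def$variant[def$variant %in% variantIds(g)]
  v <- variantRanges(g)[vids]
  vids <- vids[order(as.character(seqnames(v)), GenomicRanges::start(v))]
  accs <- if (is.null(accessionSubset)) accessions(g)
          else intersect(accessionSubset, accessions(g))
  d <- dosage(g)[vids, accs, drop = FALSE]
  ok <- colSums(is.na(d) | d == 1) == 0
  hap <- apply(d[, ok, drop = FALSE], 2, function(col)
    paste(ifelse(col == 2, "A", "R"), collapse = ""))
  tab <- sort(table(hap), decreasing = TRUE)
  classes <- data.frame(haplotype = names(tab), count = as.integer(tab),
                        freq = as.numeric(tab) / sum(tab),
                        stringsAsFactors = FALSE)
  classes$major <- classes$freq >= majorMinFreq
  new("HaplotypeTable", geneId = gene, variantIds = vids,
      haplotypes = hap, classes = classes,
      nExcluded = as.integer(sum(!ok)))
}

setMethod("show", "HaplotypeTable", function(object) {
  cat(sprintf("HaplotypeTable for %s: %d defining variant(s), %d class(es), %d excluded\n",
              object@geneId, length(object@variantIds),
              nrow(object@classes), object@nExcluded))
})

## Internal: Duncan's multiple range test. Means sorted descending; the
## critical range for a span of p means uses the studentized-range quantile
## at the protection level 1 - (1 - alpha)^(p - 1). Step-down: a range
## declared non-significant protects all its sub-ranges untested. Returns
## letters plus the pairwise significance decisions.
.duncan <- function(means, ns, mse, df, alpha = 0.05) {
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]; n <- ns[ord]
  sig <- matrix(FALSE, k, k)        # TRUE = significantly different
  decided <- matrix(FALSE, k, k)
  for (span in k:2) {
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      if (decided[i, j]) next
      nh <- 2 / (1 / n[i] + 1 / n[j])    # harmonic mean for unequal n
      alphaP <- 1 - (1 - alpha)^(span - 1)
      crit <- stats::qtukey(1 - alphaP, span, df) * sqrt(mse / nh)
      if (m[i] - m[j] <= crit) {
        # protect: all pairs inside this range are non-significant
        for (a in i:j) for (b in a:j) decided[a, b] <- TRUE
      } else {
        sig[i, j] <- TRUE
        decided[i, j] <- TRUE
      }
    }
  }
  # letters: maximal runs of mutually non-significant sorted means
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !sig[i, j + 1L]) j <- j + 1L
    runs[[i]] <- c(i, j)
  }
  keep <- rep(TRUE, length(runs))
  for (a in seq_along(runs)) for (b in seq_along(runs)) {
    if (a != b && keep[a] && runs[[a]][1] >= runs[[b]][1] &&
        runs[[a]][2] <= runs[[b]][2] &&
        !(runs[[a]][1] == runs[[b]][1] && runs[[a]][2] == runs[[b]][2]))
      keep[a] <- FALSE
  }
  runs <- unique(runs[keep])
  letters <- rep("", k)
  for (r in seq_along(runs))
    for (i in runs[[r]][1]:runs[[r]][2])
      letters[i] <- paste0(letters[i], base::letters[r])
  out <- list(letters = character(k), sig = matrix(FALSE, k, k))
  out$letters[ord] <- letters
  sigFull <- matrix(FALSE, k, k)
  sigFull[ord, ord] <- sig | t(sig)
  out$sig <- sigFull
  out
}

#' Haplotype-phenotype test with Duncan letter grouping
#'
#' One-way ANOVA of the trait over the major haplotype classes (protected
#' test: the multiple range comparison only runs when the ANOVA rejects at
#' \code{alpha}). With exactly two major classes a Welch t-test replaces the
#' range test. Letters follow the usual convention: classes sharing a
#' letter were not declared significantly different.
#'
#' @param h a \linkS4class{HaplotypeTable}.
#' @param pheno phenotype data.frame.
#' @param trait trait column name.
#' @param scope optional accession ids restricting the comparison (e.g. one
#'   subpopulation); accessions outside the scope are never used.
#' @param alpha significance level (default 0.05).
#' @param minN minimum accessions per class (default 3).
#' @return data.frame (one row per major class): \code{haplotype}, \code{n},
#'   \code{mean}, \code{sd}, \code{letter}, plus attributes \code{anovaF},
#'   \code{anovaP}, \code{testP} (t-test p for two classes) and
#'   \code{scopeN}.
#' @export
anovaDuncan <- function(h, pheno, trait = "RL", scope = NULL, alpha = 0.05,
                       minN = 3L) {
  hap <- h@haplotypes
  if (!is.null(scope)) hap <- hap[names(hap) %in% scope]
  y <- pheno[[trait]][match(names(hap), pheno$accession)]
  keep <- !is.na(y)
  hap <- hap[keep]; y <- y[keep]
  major <- h@classes$haplotype[h@classes$major]
  inMajor <- hap %in% major
  hap <- hap[inMajor]; y <- y[inMajor]
  cnt <- table(hap)
  use <- names(cnt)[cnt >= minN]
  if (length(use) < 2)
    stop("need >= 2 major haplotype classes with n >= ", minN, " in scope")
  inUse <- hap %in% use
  hap <- factor(hap[inUse], levels = use)
  y <- y[inUse]
  means <- tapply(y, hap, mean)
  sds <- tapply(y, hap, stats::sd)
  ns <- as.integer(table(hap))
  k <- nlevels(hap)
  df <- length(y) - k
  sse <- sum((y - means[hap])^2)
  ssb <- sum(ns * (means - mean(y))^2)
  if (sse == 0 && ssb == 0) {
    Fv <- NA_real_; pv <- NA_real_   # all values identical: no difference
  } else if (sse == 0) {
    Fv <- Inf; pv <- 0
  } else {
    Fv <- (ssb / (k - 1)) / (sse / df)
    pv <- stats::pf(Fv, k - 1, df, lower.tail = FALSE)
  }
  out <- data.frame(haplotype = levels(hap), n = ns, mean = as.numeric(means),
                    sd = as.numeric(sds), letter = "a",
                    stringsAsFactors = FALSE)
  testP <- NA_real_
  if (k == 2L) {
    if (sse == 0 && means[1] != means[2]) testP <- 0
    else if (!is.na(Fv)) testP <- tryCatch(
      stats::t.test(y[hap == levels(hap)[1]],
                    y[hap == levels(hap)[2]])$p.value,
      error = function(e) NA_real_)
    if (!is.na(testP) && testP < alpha) out$letter <- c("a", "b")[
      rank(-out$mean, ties.method = "first")]
  } else if (!is.na(pv) && pv < alpha) {
    mse <- sse / df
    dl <- .duncan(as.numeric(means), ns, mse, df, alpha)
    out$letter <- dl$letters
    attr(out, "sigMatrix") <- dl$sig
  }
  attr(out, "anovaF") <- Fv
  attr(out, "anovaP") <- pv
  attr(out, "testP") <- testP
  attr(out, "scopeN") <- length(y)
  out
}

#' Resolve deferred candidate genes against haplotype evidence
#'
#' Genes deferred by \code{\link{integrateEvidence}} (all evidence present
#' except expression) are promoted to candidates when their
#' haplotype-phenotype test rejects at \code{alpha} in at least one scope,
#' matching the third expression pattern: no differential expression but
#' significant phenotypic differences between alleles.
#'
#' @param screen result of \code{\link{integrateEvidence}}.
#' @param hapPvalues named numeric: for each deferred gene, the smallest
#'   haplotype ANOVA / t-test p-value over the scopes examined (NA = test
#'   unavailable).
#' @param alpha significance level (default 0.05).
#' @return the screen list with updated \code{genes$status} and a
#'   \code{ledger} row appended for the final candidate count.
#' @export
finalizeDeferredCandidates <- function(screen, hapPvalues, alpha = 0.05) {
  genes <- screen$genes
  def <- which(genes$status == "deferred")
  for (i in def) {
    p <- hapPvalues[genes$gene[i]]
    genes$status[i] <- if (!is.na(p) && p < alpha) "candidate" else "excluded"
  }
  screen$genes <- genes
  screen$ledger <- rbind(screen$ledger, data.frame(
    stage = "haplotypeResolution",
    nGenes = sum(genes$status == "candidate"),
    nQtls = length(unique(genes$qtl[genes$status == "candidate"])),
    stringsAsFactors = FALSE))
  screen
}
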