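#' Run the full candidate-gene screen on a panel
#'
#' Convenience orchestration of the whole mapping-and-shortlisting strategy
#' on an in-memory panel (as produced by \code{\link{simulatePanel}} or
#' assembled from files): variant QC, principal components (and kinship for
#' the mixed model), the association scan, the conditional-permutation
#' genome-wide threshold, QTL interval calling, extreme-pool chi-square
#' screening in both cultivated subpopulations, variant-effect annotation,
#' the linkage-interval filter, expression filters, evidence integration
#' and haplotype-based resolution of genes deferred for lacking expression
#' evidence.
#'
#' @param panel list with elements \code{genotypes}, \code{phenotypes},
#'   \code{genes}, \code{expression}, \code{reference} and optionally
#'   \code{linkage}.
#' @param trait trait column name (default "RL").
#' @param model "mlm" (default) or "glm".
#' @param kPcs principal components used as covariates (default 3).
#' @param nPerm conditional permutations (default 200; raise to 1000 for
#'   production use).
#' @param percentile threshold percentile (default 95).
#' @param prefilter permutation prefilter on -log10(p) (default 2).
#' @param windowBp,minSnps QTL clustering rule (defaults 170 kb, 3 SNPs).
#' @param nPerPool extreme-pool size (default 20).
#' @param alpha significance level of the pooled test and haplotype tests.
#' @param maxMissing,minMaf QC thresholds (defaults 0.5 and 0.05).
#' @param seed seed for the permutation stage.
#' @return list: \code{scan}, \code{threshold}
#'   (\linkS4class{ThresholdResult}), \code{qtls}, \code{pools},
#'   \code{chi2}, \code{annotation}, \code{linkageKept}, \code{expression},
#'   \code{screen} (genes + stage ledger), \code{haplotypePvalues},
#'   \code{candidates} (final candidate gene ids), \code{structure}.
#' @export
runCandidateScreen <- function(panel, trait = "RL", model = c("mlm", "glm"),
                               kPcs = 3L, nPerm = 200L, percentile = 95,
                               prefilter = 2, windowBp = 170000L,
                               minSnps = 3L, nPerPool = 20L, alpha = 0.05,
                               maxMissing = 0.5, minMaf = 0.05, seed = 1L) {
  model <- match.arg(model)
  pheno <- panel$phenotypes
  cult <- pheno$accession[!is.na(pheno[[trait]])]
  g <- qcFilter(panel$genotypes[, cult], maxMissing, minMaf)
  structure <- computePCs(g, kPcs)
  if (model == "mlm")
    structure@kinship <- kinship(computeKinship(g))
  scan <- if (model == "mlm") scanMLM(g, pheno, trait, structure)
          else scanGLM(g, pheno, trait, structure)
  thr <- conditionalThreshold(g, pheno, trait, structure, model = model,
                              nPerm = nPerm, percentile = percentile,
                              prefilter = prefilter, seed = seed, scan = scan)
  qtls <- callQTLs(scan, thresholdValue(thr), windowBp = windowBp,
                   minSnps = minSnps, trait = trait)
  tb <- scanTable(scan)
  betaSign <- structure(sign(tb$beta), names = tb$variant)
  members <- unique(unlist(mcols(qtls)$members))
  chi2 <- list()
  for (sp in intersect(c("indica", "japonica"), unique(pheno$subpop))) {
    pools <- tryCatch(
      buildPools(pheno, structure, trait, sp, nPerPool = nPerPool),
      error = function(e) NULL)
    if (is.null(pools)) next
    chi2[[sp]] <- pooledChi2(g, pools, members, betaSign)
  }
  annot <- if (length(members))
    annotateVariants(g, panel$genes, panel$reference, members)
  else data.frame(variant = character(0), gene = character(0),
                  zone = character(0), consequence = character(0),
                  largeEffect = logical(0), aaChange = character(0),
                  spliceBoundary = logical(0))
  linkageKept <- if (!is.null(panel$linkage) && length(qtls))
    intersectLinkage(qtls, panel$linkage, panel$genotypes, members)
  else NULL
  universe <- unique(annot$gene[!is.na(annot$gene) &
                                  annot$zone %in% c("ORF", "promoter")])
  exprFlags <- expressionFilters(panel$expression, universe)
  screen <- integrateEvidence(qtls, annot, chi2, linkageKept, exprFlags,
                              alpha = alpha)
  ## haplotype resolution of deferred genes
  hapP <- numeric(0)
  deferred <- screen$genes$gene[screen$genes$status == "deferred"]
  for (gid in deferred) {
    p <- NA_real_
    for (sp in c("indica", "japonica")) {
      scopeAcc <- pheno$accession[pheno$subpop == sp]
      res <- tryCatch({
        h <- buildHaplotypes(g, gid, annot)
        ad <- anovaDuncan(h, pheno, trait, scope = scopeAcc, alpha = alpha)
        pv <- attr(ad, "anovaP")
        tp <- attr(ad, "testP")
        if (!is.na(tp)) tp else pv
      }, error = function(e) NA_real_)
      p <- min(p, res, na.rm = TRUE)
    }
    hapP[gid] <- if (is.finite(p)) p else NA_real_
  }
  screen <- finalizeDeferredCandidates(screen, hapP, alpha = alpha)
  list(scan = scan, threshold = thr, qtls = qtls, chi2 = chi2,
       annotation = annot, linkageKept = linkageKept,
       expression = exprFlags, screen = screen, haplotypePvalues = hapP,
       candidates = screen$genes$gene[screen$genes$status == "candidate"],
       structure = structure, genotypes = g)
}
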