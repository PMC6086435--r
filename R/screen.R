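#' Build extreme-phenotype pools within a typical subpopulation
#'
#' Selects the \code{nPerPool} highest- and lowest-trait accessions among
#' the "typical" members of a subpopulation. Typicality is judged on PC1:
#' with explicit \code{pc1Cuts = c(low, high)}, accessions between the cuts
#' are excluded and the subpopulation is taken from its own side (japonica
#' below \code{low}, indica above \code{high}, following the convention that
#' PC1 separates the subspecies); by default the middle 20\% of the panel's
#' PC1 scores forms the excluded band. Ties in the trait are broken by
#' accession id order.
#'
#' @param pheno phenotype data.frame (accession, trait, subpop).
#' @param structure \linkS4class{StructureModel} with PC scores.
#' @param trait trait column name.
#' @param subpop subpopulation to pool within ("indica" or "japonica").
#' @param nPerPool pool size (default 20).
#' @param pc1Cuts optional absolute PC1 cutoffs c(low, high).
#' @return list with elements \code{high}, \code{low} (accession ids),
#'   \code{subpop}, \code{trait}, \code{nTypical} and \code{zeroContrast}
#'   (TRUE when all typical trait values are equal).
#' @export
buildPools <- function(pheno, structure, trait = "RL", subpop = "japonica",
                       nPerPool = 20L, pc1Cuts = NULL) {
  pc1 <- structure@pcs[, 1]
  if (is.null(pc1Cuts))
    pc1Cuts <- unname(stats::quantile(pc1, c(0.4, 0.6)))
  ph <- pheno[pheno$subpop == subpop & !is.na(pheno[[trait]]), , drop = FALSE]
  ph <- ph[ph$accession %in% names(pc1), , drop = FALSE]
  sideLow <- mean(pc1[ph$accession]) < mean(pc1Cuts)
  typical <- if (sideLow) ph$accession[pc1[ph$accession] < pc1Cuts[1]]
             else ph$accession[pc1[ph$accession] > pc1Cuts[2]]
  if (length(typical) < 2L * nPerPool)
    stop(sprintf("only %d typical %s accession(s); need %d",
                 length(typical), subpop, 2L * nPerPool))
  tv <- pheno[[trait]][match(typical, pheno$accession)]
  ord <- order(tv, typical)
  list(high = typical[rev(ord)][seq_len(nPerPool)],
       low = typical[ord][seq_len(nPerPool)],
       subpop = subpop, trait = trait, nTypical = length(typical),
       zeroContrast = stats::var(tv) == 0)
}

#' Pooled allele-frequency chi-square test
#'
#' For each variant, a Pearson chi-square test (1 df, no continuity
#' correction) of the 2x2 table of allele copies (ref/alt x high/low pool),
#' missing calls excluded. \code{directionOk} is TRUE when the
#' trait-increasing allele (the ALT allele when the association effect is
#' positive, REF otherwise) is more frequent in the high pool.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param pools pool pair from \code{\link{buildPools}}.
#' @param variants variant ids to test (default: all).
#' @param betaSign named numeric/sign of the association effect per variant
#'   (used for the direction check; NA direction when absent).
#' @return data.frame: \code{variant}, \code{chi2}, \code{p},
#'   \code{directionOk}, \code{testable} (FALSE for zero-margin tables).
#' @export
pooledChi2 <- function(g, pools, variants = NULL, betaSign = NULL) {
  if (is.null(variants)) variants <- variantIds(g)
  d <- dosage(g)
  out <- data.frame(variant = variants, chi2 = NA_real_, p = NA_real_,
                    directionOk = NA, testable = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(variants)) {
    vh <- d[variants[i], pools$high]
    vl <- d[variants[i], pools$low]
    a <- sum(vh, na.rm = TRUE)                 # alt copies, high pool
    b <- 2 * sum(!is.na(vh)) - a               # ref copies, high pool
    cc <- sum(vl, na.rm = TRUE)
    dd <- 2 * sum(!is.na(vl)) - cc
    N <- a + b + cc + dd
    if (N == 0 || (a + b) == 0 || (cc + dd) == 0 ||
        (a + cc) == 0 || (b + dd) == 0) next
    chi2 <- N * (a * dd - b * cc)^2 /
      ((a + b) * (cc + dd) * (a + cc) * (b + dd))
    out$chi2[i] <- chi2
    out$p[i] <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    out$testable[i] <- TRUE
    if (!is.null(betaSign) && variants[i] %in% names(betaSign) &&
        !is.na(betaSign[variants[i]])) {
      pHigh <- a / (a + b); pLow <- cc / (cc + dd)
      out$directionOk[i] <- if (betaSign[variants[i]] > 0)
        pHigh > pLow else pHigh < pLow
    }
  }
  out
}

## Internal: coding-order genome positions of a gene's CDS (5' to 3').
.codingMap <- function(cds, minusStrand) {
  segs <- cds[order(GenomicRanges::start(cds))]
  pos <- unlist(lapply(seq_along(segs), function(i)
    GenomicRanges::start(segs)[i]:GenomicRanges::end(segs)[i]))
  if (minusStrand) rev(pos) else pos
}

.baseAt <- function(reference, chrom, pos) {
  as.character(Biostrings::subseq(reference[[chrom]], pos, pos))
}

.comp <- function(x) chartr("ACGT", "TGCA", x)

#' Annotate variants against gene models
#'
#' Assigns each variant a zone (ORF when inside a gene span, promoter when
#' inside the 2000-bp upstream promoter, otherwise intergenic) and, for
#' coding variants, a consequence from strand-aware codon translation with
#' the standard genetic code: synonymous, nonsynonymous, stop_gain,
#' stop_loss, start_loss, frameshift (InDel length not a multiple of 3),
#' inframe_indel, or noncoding (intronic/UTR). Variants within 2 bp of an
#' internal CDS junction are flagged splice-boundary. The large-effect flag
#' covers stop gain/loss, start loss, frameshift and splice-boundary
#' variants. The reference base at each position must match the VCF REF
#' allele or an error naming the position is raised.
#'
#' @param g a \linkS4class{GenotypeMatrix} (or its variant GRanges).
#' @param genes a \linkS4class{GeneModelSet}.
#' @param reference \link[Biostrings]{DNAStringSet} of chromosome sequences.
#' @param variants variant ids to annotate (default all).
#' @return data.frame: \code{variant}, \code{gene}, \code{zone},
#'   \code{consequence}, \code{largeEffect}, \code{aaChange},
#'   \code{spliceBoundary}.
#' @export
annotateVariants <- function(g, genes, reference, variants = NULL) {
  v <- if (is(g, "GenotypeMatrix")) variantRanges(g) else g
  if (!is.null(variants)) v <- v[variants]
  gr <- geneRanges(genes)
  prom <- promoterRanges(genes)
  out <- data.frame(variant = names(v), gene = NA_character_,
                    zone = "intergenic", consequence = NA_character_,
                    largeEffect = FALSE, aaChange = NA_character_,
                    spliceBoundary = FALSE, stringsAsFactors = FALSE)
  ovGene <- GenomicRanges::findOverlaps(v, gr)
  ovProm <- GenomicRanges::findOverlaps(v, prom)
  geneHit <- structure(rep(NA_integer_, length(v)))
  geneHit[S4Vectors::queryHits(ovGene)] <- S4Vectors::subjectHits(ovGene)
  promHit <- structure(rep(NA_integer_, length(v)))
  promHit[S4Vectors::queryHits(ovProm)] <- S4Vectors::subjectHits(ovProm)
  for (i in seq_along(v)) {
    chrom <- as.character(seqnames(v)[i])
    pos <- GenomicRanges::start(v)[i]
    refA <- mcols(v)$ref[i]
    altA <- mcols(v)$alt[i]
    refObs <- as.character(Biostrings::subseq(reference[[chrom]], pos,
                                              pos + nchar(refA) - 1L))
    if (refObs != refA)
      stop(sprintf("reference mismatch at %s:%d (VCF ref %s, sequence %s)",
                   chrom, pos, refA, refObs))
    gi <- geneHit[i]
    if (is.na(gi)) {
      if (!is.na(promHit[i])) {
        out$zone[i] <- "promoter"
        out$gene[i] <- names(prom)[promHit[i]]
      }
      next
    }
    out$zone[i] <- "ORF"
    out$gene[i] <- names(gr)[gi]
    cds <- cdsRanges(genes)[[gi]]
    minus <- as.character(strand(gr)[gi]) == "-"
    cdsStart <- GenomicRanges::start(cds)
    cdsEnd <- GenomicRanges::end(cds)
    inCds <- any(pos >= cdsStart & pos <= cdsEnd)
    # splice boundary: within 2 bp (intron side) of an internal CDS junction
    if (length(cds) > 1) {
      internal <- c(sort(cdsEnd)[-length(cds)], sort(cdsStart)[-1])
      bnd <- c(sort(cdsEnd)[-length(cds)] + 1L, sort(cdsEnd)[-length(cds)] + 2L,
               sort(cdsStart)[-1] - 1L, sort(cdsStart)[-1] - 2L)
      if (pos %in% bnd) {
        out$spliceBoundary[i] <- TRUE
        out$largeEffect[i] <- TRUE
      }
    }
    if (!inCds) {
      out$consequence[i] <- "noncoding"
      next
    }
    isSnp <- nchar(refA) == 1L && nchar(altA) == 1L
    if (!isSnp) {
      lenDiff <- abs(nchar(altA) - nchar(refA))
      out$consequence[i] <- if (lenDiff %% 3L != 0L) "frameshift"
                            else "inframe_indel"
      if (lenDiff %% 3L != 0L) out$largeEffect[i] <- TRUE
      next
    }
    cmap <- .codingMap(cds, minus)
    cpos <- match(pos, cmap)
    codonIdx <- (cpos - 1L) %/% 3L + 1L
    within <- (cpos - 1L) %% 3L + 1L
    codonPos <- cmap[(codonIdx - 1L) * 3L + 1:3]
    bases <- vapply(codonPos, function(p) .baseAt(reference, chrom, p),
                    character(1))
    if (minus) bases <- .comp(bases)
    refCodon <- paste(bases, collapse = "")
    altBases <- bases
    altBases[within] <- if (minus) .comp(altA) else altA
    altCodon <- paste(altBases, collapse = "")
    aaRef <- GENETIC_CODE_AA(refCodon)
    aaAlt <- GENETIC_CODE_AA(altCodon)
    out$aaChange[i] <- paste0(aaRef, codonIdx, aaAlt)
    cons <- if (aaRef == aaAlt) "synonymous"
      else if (codonIdx == 1L && aaRef == "M") "start_loss"
      else if (aaAlt == "*") "stop_gain"
      else if (aaRef == "*") "stop_loss"
      else "nonsynonymous"
    out$consequence[i] <- cons
    if (cons %in% c("stop_gain", "stop_loss", "start_loss"))
      out$largeEffect[i] <- TRUE
  }
  out
}

#' Expression-pattern filters for candidate genes
#'
#' For each gene, the RPKM ratio of robust-group root samples to
#' control-group root samples (a pseudo-count \code{eps} stabilises ratios
#' at near-zero expression), the differential flag (ratio > 1.3 or < 0.77),
#' and the root-specific flag (mean root RPKM >= 1 and mean shoot RPKM < 1).
#' Genes absent from the matrix get FALSE flags with a warning.
#'
#' @param expr SummarizedExperiment with assay \code{rpkm} and colData
#'   columns \code{tissue} (root/shoot) and \code{group} (robust/control).
#' @param geneIds genes to screen.
#' @param eps pseudo-count (default 0.1).
#' @param ratioHigh,ratioLow differential-expression bounds (defaults 1.3
#'   and 0.77).
#' @return data.frame: \code{gene}, \code{ratio}, \code{differential},
#'   \code{rootSpecific}.
#' @export
expressionFilters <- function(expr, geneIds, eps = 0.1,
                              ratioHigh = 1.3, ratioLow = 0.77) {
  m <- SummarizedExperiment::assay(expr, "rpkm")
  cd <- SummarizedExperiment::colData(expr)
  robustRoot <- cd$group == "robust" & cd$tissue == "root"
  controlRoot <- cd$group == "control" & cd$tissue == "root"
  rootS <- cd$tissue == "root"
  shootS <- cd$tissue == "shoot"
  out <- data.frame(gene = geneIds, ratio = NA_real_, differential = FALSE,
                    rootSpecific = FALSE, stringsAsFactors = FALSE)
  absent <- setdiff(geneIds, rownames(m))
  if (length(absent))
    warning("gene(s) absent from expression matrix: ",
            paste(absent, collapse = ", "))
  for (i in seq_along(geneIds)) {
    gid <- geneIds[i]
    if (!gid %in% rownames(m)) next
    ratio <- (mean(m[gid, robustRoot]) + eps) / (mean(m[gid, controlRoot]) + eps)
    out$ratio[i] <- ratio
    out$differential[i] <- ratio > ratioHigh || ratio < ratioLow
    out$rootSpecific[i] <- mean(m[gid, rootS]) >= 1 && mean(m[gid, shootS]) < 1
  }
  out
}

#' Integrate the four screening stages into a candidate-gene ledger
#'
#' Combines, per gene inside a QTL, the pooled chi-square evidence, the
#' linkage-interval filter, the variant-effect annotation and the
#' expression filters. A gene enters the universe when it has at least one
#' significant member variant in its ORF or promoter. Flags:
#' \itemize{
#'   \item \code{poolChi2Pass}: some member variant passes the pooled test
#'     (p < alpha with the trait-increasing allele enriched in the high
#'     pool) in at least one subpopulation pool pair;
#'   \item \code{linkagePass}: some member variant survives
#'     \code{\link{intersectLinkage}}; genes in QTLs not covered by any
#'     linkage interval keep a neutral (NA) flag, so GWAS-only QTLs are
#'     retained;
#'   \item \code{hasNonsynOrLargeEffect}: some ORF variant is
#'     non-synonymous or large-effect;
#'   \item \code{differential}, \code{rootSpecific}: expression filters.
#' }
#' Final status: \code{candidate} when the gene passes the pooled test, is
#' not contradicted by linkage, carries a non-synonymous or large-effect
#' variant and shows differential or root-specific expression;
#' \code{deferred} when only the expression evidence is missing (resolved
#' against the haplotype-phenotype test by
#' \code{\link{finalizeDeferredCandidates}}); otherwise \code{excluded}.
#'
#' @param qtls GRanges from \code{\link{callQTLs}}.
#' @param annot annotation table from \code{\link{annotateVariants}} for all
#'   QTL member variants.
#' @param chi2List list of \code{\link{pooledChi2}} tables (one per pool
#'   pair; a single data.frame is accepted).
#' @param linkageKept data.frame from \code{\link{intersectLinkage}}, or
#'   NULL when no linkage information exists.
#' @param exprFlags data.frame from \code{\link{expressionFilters}} covering
#'   the universe genes.
#' @param alpha pooled-test significance level (default 0.05, uncorrected;
#'   set e.g. \code{alpha = 0.05 / nTests} for a Bonferroni variant).
#' @return list with \code{genes} (per-gene evidence data.frame including
#'   \code{status}) and \code{ledger} (stage-by-stage gene/SNP counts).
#' @export
integrateEvidence <- function(qtls, annot, chi2List, linkageKept = NULL,
                              exprFlags, alpha = 0.05) {
  if (is.data.frame(chi2List)) chi2List <- list(chi2List)
  if (!length(qtls)) {
    genes0 <- data.frame(gene = character(0), qtl = character(0),
                         nSigVariants = integer(0), poolChi2Pass = logical(0),
                         poolChi2P = numeric(0), linkagePass = logical(0),
                         hasNonsynOrLargeEffect = logical(0),
                         differential = logical(0), rootSpecific = logical(0),
                         exprRatio = numeric(0), status = character(0))
    ledger0 <- data.frame(stage = c("gwas", "pooledChi2", "linkage",
                                    "effectAndExpression"),
                          nGenes = 0L, nQtls = 0L, stringsAsFactors = FALSE)
    return(list(genes = genes0, ledger = ledger0))
  }
  memberVariants <- unlist(mcols(qtls)$members)
  variant2qtl <- structure(rep(names(qtls), lengths(mcols(qtls)$members)),
                           names = memberVariants)
  an <- annot[annot$variant %in% memberVariants &
                annot$zone %in% c("ORF", "promoter") &
                !is.na(annot$gene), , drop = FALSE]
  universe <- unique(an$gene)
  qtlHasLinkage <- if (is.null(linkageKept)) character(0) else
    unique(linkageKept$qtl)
  rows <- lapply(universe, function(gid) {
    va <- an[an$gene == gid, , drop = FALSE]
    vids <- va$variant
    qtl <- variant2qtl[vids[1]]
    chi2Pass <- FALSE; chi2P <- NA_real_
    for (tab in chi2List) {
      sub <- tab[tab$variant %in% vids & tab$testable, , drop = FALSE]
      ok <- sub$p < alpha & !is.na(sub$directionOk) & sub$directionOk
      if (any(ok, na.rm = TRUE)) {
        chi2Pass <- TRUE
        chi2P <- min(chi2P, min(sub$p[which(ok)]), na.rm = TRUE)
      }
    }
    covered <- qtl %in% qtlHasLinkage
    linkagePass <- if (!covered) NA else any(linkageKept$variant %in% vids)
    nonsyn <- any(va$zone == "ORF" &
                    (va$consequence %in% c("nonsynonymous", "stop_gain",
                                           "stop_loss", "start_loss",
                                           "frameshift") | va$largeEffect))
    ef <- exprFlags[match(gid, exprFlags$gene), ]
    differential <- isTRUE(ef$differential)
    rootSpecific <- isTRUE(ef$rootSpecific)
    linkOk <- is.na(linkagePass) || linkagePass
    status <- if (chi2Pass && linkOk && nonsyn &&
                  (differential || rootSpecific)) "candidate"
      else if (chi2Pass && linkOk && nonsyn) "deferred"
      else "excluded"
    data.frame(gene = gid, qtl = qtl, nSigVariants = length(vids),
               poolChi2Pass = chi2Pass, poolChi2P = chi2P,
               linkagePass = linkagePass,
               hasNonsynOrLargeEffect = nonsyn,
               differential = differential, rootSpecific = rootSpecific,
               exprRatio = ef$ratio, status = status,
               stringsAsFactors = FALSE)
  })
  genes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), qtl = character(0),
               nSigVariants = integer(0), poolChi2Pass = logical(0),
               poolChi2P = numeric(0), linkagePass = logical(0),
               hasNonsynOrLargeEffect = logical(0), differential = logical(0),
               rootSpecific = logical(0), exprRatio = numeric(0),
               status = character(0))
  afterChi2 <- genes$gene[genes$poolChi2Pass]
  afterLink <- genes$gene[genes$poolChi2Pass &
                            (is.na(genes$linkagePass) | genes$linkagePass)]
  final <- genes$gene[genes$status %in% c("candidate", "deferred")]
  ledger <- data.frame(
    stage = c("gwas", "pooledChi2", "linkage", "effectAndExpression"),
    nGenes = c(length(universe), length(afterChi2), length(afterLink),
               length(final)),
    nQtls = c(length(unique(genes$qtl)),
              length(unique(genes$qtl[genes$poolChi2Pass])),
              length(unique(genes$qtl[genes$gene %in% afterLink])),
              length(unique(genes$qtl[genes$gene %in% final]))),
    stringsAsFactors = FALSE)
  list(genes = genes, ledger = ledger)
}
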