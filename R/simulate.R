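#' Create a simulation configuration
#'
#' Defaults describe the panel the package is exercised on: two cultivated
#' subpopulations (indica-like / japonica-like) of inbred accessions with an
#' upland sub-branch of japonica enriched for trait-increasing alleles, a
#' higher-diversity wild outgroup, LD-blocked genotypes, five planted causal
#' genes of small effect (0.5 trait SD per allele copy before heritability
#' scaling) and narrow-sense heritability 0.5.
#'
#' @param nAccessionsPerSubpop accessions per cultivated subpopulation
#'   (default 300, giving a 600-line panel).
#' @param nWild wild-outgroup accessions (default 50).
#' @param nChromosomes chromosomes (default 2).
#' @param chromLengthBp chromosome length in bp (default 2e6).
#' @param nVariants total variants (default 2000).
#' @param ldBlockBp LD-block width; within a block cultivated haplotypes are
#'   drawn from 4 block haplotypes per subpopulation (default 50 kb).
#' @param nGenes gene models placed on the genome (default 100).
#' @param nCausalGenes genes carrying planted causal variants (default 5).
#' @param causalEffectSd nominal additive effect per trait-increasing allele
#'   copy, trait SD units (default 0.5).
#' @param traitH2 heritability targeted by the noise scaling (default 0.5).
#' @param structureShiftSd trait shift added to japonica accessions, trait SD
#'   units (default 0.5).
#' @param uplandPyramidingBoost increment to the trait-increasing allele
#'   frequency in the upland sub-branch (default 0.2).
#' @param structureDiffFraction fraction of variants with divergent
#'   subpopulation frequencies (default 0.3).
#' @param mafRange ancestral (wild) allele-frequency range (default
#'   c(0.05, 0.5)).
#' @param missingRate per-call missing rate (default 0.02).
#' @param residualHetRate residual heterozygosity of the inbred lines
#'   (default 0.005).
#' @param indelFraction fraction of non-causal variants simulated as small
#'   InDels (default 0.05).
#' @param seed integer RNG seed (default 1).
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nAccessionsPerSubpop = 300L,
                             nWild = 50L,
                             nChromosomes = 2L,
                             chromLengthBp = 2000000L,
                             nVariants = 2000L,
                             ldBlockBp = 50000L,
                             nGenes = 100L,
                             nCausalGenes = 5L,
                             causalEffectSd = 0.5,
                             traitH2 = 0.5,
                             structureShiftSd = 0.5,
                             uplandPyramidingBoost = 0.2,
                             structureDiffFraction = 0.3,
                             mafRange = c(0.05, 0.5),
                             missingRate = 0.02,
                             residualHetRate = 0.005,
                             indelFraction = 0.05,
                             seed = 1L) {
  new("SimulationConfig",
      nAccessionsPerSubpop = as.integer(nAccessionsPerSubpop),
      nWild = as.integer(nWild),
      nChromosomes = as.integer(nChromosomes),
      chromLengthBp = as.integer(chromLengthBp),
      nVariants = as.integer(nVariants),
      ldBlockBp = as.integer(ldBlockBp),
      nGenes = as.integer(nGenes),
      nCausalGenes = as.integer(nCausalGenes),
      causalEffectSd = causalEffectSd,
      traitH2 = traitH2,
      structureShiftSd = structureShiftSd,
      uplandPyramidingBoost = uplandPyramidingBoost,
      structureDiffFraction = structureDiffFraction,
      mafRange = mafRange,
      missingRate = missingRate,
      residualHetRate = residualHetRate,
      indelFraction = indelFraction,
      seed = as.integer(seed))
}

GENETIC_CODE_AA <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(codon),
                                     no.init.codon = TRUE))
}

# Place non-overlapping gene models (two CDS exons, alternating strand) on
# regular slots with jitter; errors when the genome cannot hold them.
.placeGenes <- function(cfg) {
  perChrom <- rep(cfg@nGenes %/% cfg@nChromosomes, cfg@nChromosomes)
  extra <- cfg@nGenes %% cfg@nChromosomes
  if (extra > 0) perChrom[seq_len(extra)] <- perChrom[seq_len(extra)] + 1L
  maxLen <- 3000L
  spacing <- (cfg@chromLengthBp - 6000L) / max(perChrom)
  if (spacing < maxLen + 4200L)
    stop("infeasible config: ", cfg@nGenes, " genes do not fit on ",
         cfg@nChromosomes, " chromosome(s) of ", cfg@chromLengthBp, " bp")
  rows <- list()
  gi <- 0L
  for (ch in seq_len(cfg@nChromosomes)) {
    for (k in seq_len(perChrom[ch])) {
      gi <- gi + 1L
      slot0 <- 3000L + floor((k - 1L) * spacing)
      start <- slot0 + sample.int(floor(spacing / 5), 1L)
      len <- sample(1800:maxLen, 1L)
      # two exons; total CDS length a multiple of 3
      e1 <- 3L * sample(100:220, 1L)
      e2 <- 3L * sample(100:220, 1L)
      intron <- len - 200L - e1 - e2
      if (intron < 50L) { e2 <- 300L; intron <- len - 200L - e1 - e2 }
      rows[[gi]] <- data.frame(
        gene = sprintf("gene%03d", gi), chrom = paste0("chr", ch),
        start = start, end = start + len - 1L,
        strand = if (gi %% 2L == 0L) "-" else "+",
        ex1s = start + 100L, ex1e = start + 100L + e1 - 1L,
        ex2s = start + 100L + e1 + intron,
        ex2e = start + 100L + e1 + intron + e2 - 1L)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a structured inbred panel with planted root-trait QTLs
#'
#' Generates a complete synthetic data set: reference sequence, gene models,
#' LD-blocked genotypes for two cultivated subpopulations plus a wild
#' outgroup, a quantitative trait with planted additive causal variants and
#' a population-structure shift, an expression matrix with differential or
#' root-specific signal at the causal genes, and linkage-mapping QTL
#' intervals covering a subset of the causal genes.
#'
#' The single seed in the configuration drives one RNG stream; the draw
#' order is fixed (reference, gene placement, causal planting, variant
#' positions/alleles, group frequencies, genotypes, phenotype, expression,
#' linkage, heterozygosity/missingness), so identical configurations yield
#' byte-identical output.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{genotypes}
#'   (\linkS4class{GenotypeMatrix}; cultivated then wild accessions),
#'   \code{phenotypes} (data.frame: accession, RL, subpop, ecotype; wild
#'   rows have NA trait), \code{genes} (\linkS4class{GeneModelSet}),
#'   \code{expression} (SummarizedExperiment, assay \code{rpkm}),
#'   \code{linkage} (data.frame of linkage QTL intervals),
#'   \code{truth} (\linkS4class{PlantedTruth}) and \code{reference}
#'   (\link[Biostrings]{DNAStringSet}).
#' @export
simulatePanel <- function(config) {
  cfg <- config
  validObject(cfg)
  set.seed(cfg@seed)
  nSub <- cfg@nAccessionsPerSubpop
  chroms <- paste0("chr", seq_len(cfg@nChromosomes))
  chrLen <- structure(rep(cfg@chromLengthBp, cfg@nChromosomes), names = chroms)

  ## 1. reference sequence (character vectors for easy patching)
  refChars <- lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), cfg@chromLengthBp, replace = TRUE))
  names(refChars) <- chroms

  ## 2. gene models; patch start/stop codons into the reference
  if (cfg@nCausalGenes > cfg@nGenes)
    stop("infeasible config: more causal genes than genes")
  gtab <- .placeGenes(cfg)
  for (i in seq_len(nrow(gtab))) {
    ch <- gtab$chrom[i]
    if (gtab$strand[i] == "+") {
      refChars[[ch]][gtab$ex1s[i]:(gtab$ex1s[i] + 2L)] <- c("A", "T", "G")
      refChars[[ch]][(gtab$ex2e[i] - 2L):gtab$ex2e[i]] <- c("T", "A", "A")
    } else {
      refChars[[ch]][(gtab$ex2e[i] - 2L):gtab$ex2e[i]] <- c("C", "A", "T")
      refChars[[ch]][gtab$ex1s[i]:(gtab$ex1s[i] + 2L)] <- c("T", "T", "A")
    }
  }

  ## 3. plant causal variants (non-synonymous SNPs in causal-gene CDS)
  causalIdx <- sort(sample.int(cfg@nGenes, cfg@nCausalGenes))
  causalGenes <- gtab$gene[causalIdx]
  nSupport <- 6L
  causalPos <- integer(cfg@nCausalGenes)
  causalChrom <- character(cfg@nCausalGenes)
  causalRef <- causalAlt <- character(cfg@nCausalGenes)
  for (k in seq_len(cfg@nCausalGenes)) {
    gr <- gtab[causalIdx[k], ]
    nCodon1 <- (gr$ex1e - gr$ex1s + 1L) %/% 3L
    codon <- sample(2:(nCodon1 - 1L), 1L)   # skip terminal codons of exon 1
    if (gr$strand == "+") {
      base1 <- gr$ex1s + 3L * (codon - 1L)
      pos <- base1 + 1L                      # second codon position
      cd <- paste(refChars[[gr$chrom]][base1:(base1 + 2L)], collapse = "")
      within <- 2L
    } else {
      # coding order runs ex2e..ex2s then ex1e..ex1s; stay inside exon 2
      nCodon2 <- (gr$ex2e - gr$ex2s + 1L) %/% 3L
      codon <- sample(2:(nCodon2 - 1L), 1L)
      base1 <- gr$ex2e - 3L * (codon - 1L)   # genome pos of codon base 1
      pos <- base1 - 1L
      cd <- paste(rev(chartr("ACGT", "TGCA",
                             refChars[[gr$chrom]][(base1 - 2L):base1])),
                  collapse = "")
      within <- 2L
    }
    refBase <- refChars[[gr$chrom]][pos]
    aaRef <- GENETIC_CODE_AA(cd)
    for (alt in setdiff(c("A", "C", "G", "T"), refBase)) {
      cdAlt <- cd
      altCoding <- if (gr$strand == "+") alt else chartr("ACGT", "TGCA", alt)
      substr(cdAlt, within, within) <- altCoding
      if (GENETIC_CODE_AA(cdAlt) != aaRef) break
    }
    causalPos[k] <- pos
    causalChrom[k] <- gr$chrom
    causalRef[k] <- refBase
    causalAlt[k] <- alt
  }

  ## support variants: intergenic companions in LD with each causal variant
  inGeneOrPromoter <- function(ch, pos) {
    sel <- gtab$chrom == ch
    any(pos >= gtab$start[sel] - 2100L & pos <= gtab$end[sel] + 2100L)
  }
  supPos <- integer(0); supChrom <- character(0); supOf <- integer(0)
  for (k in seq_len(cfg@nCausalGenes)) {
    placed <- 0L; tries <- 0L
    while (placed < nSupport && tries < 500L) {
      tries <- tries + 1L
      off <- sample(c(-1L, 1L), 1L) * sample(3000:25000, 1L)
      pos <- causalPos[k] + off
      if (pos < 1L || pos > cfg@chromLengthBp) next
      if (inGeneOrPromoter(causalChrom[k], pos)) next
      if (pos %in% c(causalPos, supPos)) next
      supPos <- c(supPos, pos); supChrom <- c(supChrom, causalChrom[k])
      supOf <- c(supOf, k)
      placed <- placed + 1L
    }
    if (placed < nSupport)
      stop("infeasible config: could not place support variants near ",
           causalGenes[k])
  }

  ## 4. remaining variant positions and alleles
  nPlanted <- cfg@nCausalGenes * (1L + nSupport)
  if (cfg@nVariants <= nPlanted)
    stop("infeasible config: nVariants must exceed ", nPlanted,
         " planted variants")
  nOther <- cfg@nVariants - nPlanted
  othChrom <- sample(chroms, nOther, replace = TRUE)
  othPos <- integer(nOther)
  taken <- split(c(causalPos, supPos), c(causalChrom, supChrom))
  for (ch in chroms) {
    idx <- which(othChrom == ch)
    pool <- sample.int(cfg@chromLengthBp - 10L, length(idx) + 50L) + 5L
    pool <- setdiff(pool, taken[[ch]])[seq_along(idx)]
    othPos[idx] <- pool
  }
  isIndel <- rep(FALSE, nOther)
  isIndel[sample.int(nOther, round(cfg@indelFraction * nOther))] <- TRUE

  vChrom <- c(causalChrom, supChrom, othChrom)
  vPos <- c(causalPos, supPos, othPos)
  vRole <- c(rep("causal", cfg@nCausalGenes), rep("support", length(supPos)),
             rep("other", nOther))
  vOf <- c(seq_len(cfg@nCausalGenes), supOf, rep(NA_integer_, nOther))
  vRef <- vAlt <- character(length(vPos))
  vClass <- character(length(vPos))
  vRef[seq_len(cfg@nCausalGenes)] <- causalRef
  vAlt[seq_len(cfg@nCausalGenes)] <- causalAlt
  vClass[seq_len(cfg@nCausalGenes)] <- "SNP"
  for (i in (cfg@nCausalGenes + 1L):length(vPos)) {
    ch <- vChrom[i]; pos <- vPos[i]
    rb <- refChars[[ch]][pos]
    if (vRole[i] == "other" && isIndel[i - cfg@nCausalGenes - length(supPos)]) {
      if (stats::runif(1) < 0.5) {     # insertion
        ins <- paste(sample(c("A", "C", "G", "T"),
                            sample(1:3, 1L), replace = TRUE), collapse = "")
        vRef[i] <- rb; vAlt[i] <- paste0(rb, ins)
      } else {                          # deletion
        dl <- sample(1:3, 1L)
        vRef[i] <- paste(refChars[[ch]][pos:(pos + dl)], collapse = "")
        vAlt[i] <- rb
      }
      vClass[i] <- "InDel"
    } else {
      vRef[i] <- rb
      vAlt[i] <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
      vClass[i] <- "SNP"
    }
  }

  ## 5. group allele frequencies (frequency of the ALT allele)
  m <- length(vPos)
  pWild <- stats::runif(m, cfg@mafRange[1], cfg@mafRange[2])
  drift <- matrix(stats::rnorm(2 * m, 0, 0.08), m, 2)
  pSub <- pmin(pmax(pWild + drift, 0.02), 0.98)   # cols: indica, japonica
  diffSel <- stats::runif(m) < cfg@structureDiffFraction
  delta <- stats::runif(m, 0.2, 0.4) * sign(stats::rnorm(m))
  pSub[diffSel, 1] <- pmin(pmax(pSub[diffSel, 1] + delta[diffSel], 0.02), 0.98)
  pSub[diffSel, 2] <- pmin(pmax(pSub[diffSel, 2] - delta[diffSel], 0.02), 0.98)
  ## causal variants: ALT is the trait-increasing allele with a fixed
  ## wild < lowland < upland frequency ladder
  ci <- which(vRole == "causal")
  pWild[ci] <- 0.2
  pSub[ci, ] <- 0.4
  pUplandCausal <- 0.4 + cfg@uplandPyramidingBoost

  ## 6. accessions and genotypes (haploid alleles; dosage = 2 x allele)
  accIndica <- sprintf("IND%03d", seq_len(nSub))
  accJaponica <- sprintf("JAP%03d", seq_len(nSub))
  accWild <- sprintf("WILD%03d", seq_len(cfg@nWild))
  acc <- c(accIndica, accJaponica, accWild)
  nUpland <- round(0.4 * nSub)
  ecotype <- c(rep("lowland", nSub),
               rep(c("lowland", "upland"), c(nSub - nUpland, nUpland)),
               rep("wild", cfg@nWild))
  subpop <- rep(c("indica", "japonica", "wild"), c(nSub, nSub, cfg@nWild))
  uplandMask <- ecotype == "upland"

  A <- matrix(0L, m, length(acc))
  blockId <- paste0(vChrom, "_", (vPos - 1L) %/% cfg@ldBlockBp)
  hapBase <- which(vRole == "other")    # block-haplotype variants
  for (b in unique(blockId[hapBase])) {
    rows <- hapBase[blockId[hapBase] == b]
    for (s in 1:2) {
      hap <- matrix(stats::rbinom(4L * length(rows), 1L, rep(pSub[rows, s], each = 4L)),
                    nrow = 4L)
      cols <- if (s == 1) seq_len(nSub) else nSub + seq_len(nSub)
      pick <- sample.int(4L, length(cols), replace = TRUE)
      A[rows, cols] <- t(hap[pick, , drop = FALSE])
    }
  }
  # wild: independent draws at every variant
  wcols <- 2L * nSub + seq_len(cfg@nWild)
  A[hapBase, wcols] <- stats::rbinom(length(hapBase) * cfg@nWild, 1L,
                                     rep(pWild[hapBase], cfg@nWild))
  # causal variants: per-accession draws at group-specific frequencies
  for (k in seq_along(ci)) {
    p <- ifelse(subpop == "wild", 0.2,
                ifelse(uplandMask, pUplandCausal, 0.4))
    A[ci[k], ] <- stats::rbinom(length(acc), 1L, p)
  }
  # support variants: causal allele flipped with small probability
  si <- which(vRole == "support")
  for (i in si) {
    src <- ci[vOf[i]]
    flip <- stats::rbinom(length(acc), 1L, 0.08)
    A[i, ] <- ifelse(flip == 1L, 1L - A[src, ], A[src, ])
  }

  ## order variants along the genome
  ord <- order(match(vChrom, chroms), vPos)
  A <- A[ord, , drop = FALSE]
  vChrom <- vChrom[ord]; vPos <- vPos[ord]; vRef <- vRef[ord]
  vAlt <- vAlt[ord]; vClass <- vClass[ord]; vRole <- vRole[ord]
  vId <- sprintf("%s_%d", vChrom, vPos)
  causalVariantIds <- vId[vRole == "causal"]

  trueDosage <- 2L * A

  ## 7. phenotype (from the true, unmasked dosages)
  effNominal <- rep(cfg@causalEffectSd, cfg@nCausalGenes)
  names(effNominal) <- causalVariantIds
  cult <- subpop != "wild"
  gRaw <- as.numeric(effNominal %*% trueDosage[match(causalVariantIds, vId),
                                               cult, drop = FALSE])
  sdG <- stats::sd(gRaw)
  effectScale <- if (cfg@traitH2 > 0 && sdG > 0) sqrt(cfg@traitH2) / sdG else 0
  zG <- if (effectScale > 0) (gRaw - mean(gRaw)) * effectScale else
    rep(0, sum(cult))
  sShift <- cfg@structureShiftSd * as.numeric(subpop[cult] == "japonica")
  varS <- stats::var(sShift)
  varE <- 1 - cfg@traitH2 - varS
  if (varE < 0)
    stop("infeasible config: structureShiftSd too large for traitH2")
  trait <- 12 + zG + sShift + stats::rnorm(sum(cult), 0, sqrt(varE))
  pheno <- data.frame(
    accession = acc,
    RL = c(trait, rep(NA_real_, cfg@nWild))[match(acc, c(acc[cult], acc[!cult]))],
    subpop = subpop, ecotype = ecotype, stringsAsFactors = FALSE)

  ## 8. expression: 6 robust + 6 control varieties, root and shoot
  nVar <- 6L
  meta <- expand.grid(variety = sprintf("V%02d", seq_len(2L * nVar)),
                      tissue = c("root", "shoot"),
                      stringsAsFactors = FALSE)
  meta$group <- ifelse(as.integer(sub("V", "", meta$variety)) <= nVar,
                       "robust", "control")
  meta$replicate <- 1L
  meta$sample <- paste0(meta$variety, "_", meta$tissue)
  geneIds <- gtab$gene
  base <- exp(stats::rnorm(cfg@nGenes, log(5), 1))
  rpkm <- matrix(base, cfg@nGenes, nrow(meta)) *
    exp(matrix(stats::rnorm(cfg@nGenes * nrow(meta), 0, 0.15),
               cfg@nGenes, nrow(meta)))
  dimnames(rpkm) <- list(geneIds, meta$sample)
  ## causal genes: mostly differential in root, the last one root-specific
  rootSpecific <- causalGenes[cfg@nCausalGenes]
  diffGenes <- setdiff(causalGenes, rootSpecific)
  robustRoot <- meta$group == "robust" & meta$tissue == "root"
  for (gidx in seq_along(diffGenes)) {
    fold <- if (gidx %% 2L == 0L) 0.5 else 2
    rpkm[diffGenes[gidx], robustRoot] <- rpkm[diffGenes[gidx], robustRoot] * fold
  }
  rpkm[rootSpecific, meta$tissue == "root"] <-
    5 * exp(stats::rnorm(sum(meta$tissue == "root"), 0, 0.15))
  rpkm[rootSpecific, meta$tissue == "shoot"] <-
    0.2 * exp(stats::rnorm(sum(meta$tissue == "shoot"), 0, 0.15))
  expr <- SummarizedExperiment(
    assays = list(rpkm = rpkm),
    colData = DataFrame(meta[, c("sample", "variety", "tissue", "group",
                                 "replicate")], row.names = meta$sample))

  ## 9. residual heterozygosity and missingness
  dos <- trueDosage
  het <- matrix(stats::runif(length(dos)) < cfg@residualHetRate,
                nrow(dos), ncol(dos))
  dos[het] <- 1L
  miss <- matrix(stats::runif(length(dos)) < cfg@missingRate,
                 nrow(dos), ncol(dos))
  storage.mode(dos) <- "double"
  dos[miss] <- NA_real_

  ## 10. containers
  gr <- GRanges(vChrom, IRanges(vPos, width = 1L),
                seqinfo = GenomeInfoDb::Seqinfo(chroms, unname(chrLen)))
  names(gr) <- vId
  mcols(gr)$ref <- vRef
  mcols(gr)$alt <- vAlt
  mcols(gr)$vclass <- vClass
  genotypes <- GenotypeMatrix(dos, gr, acc)

  geneGr <- GRanges(gtab$chrom, IRanges(gtab$start, gtab$end),
                    strand = gtab$strand,
                    seqinfo = GenomeInfoDb::Seqinfo(chroms, unname(chrLen)))
  names(geneGr) <- gtab$gene
  cdsAll <- GRanges(rep(gtab$chrom, 2),
                    IRanges(c(gtab$ex1s, gtab$ex2s), c(gtab$ex1e, gtab$ex2e)),
                    strand = rep(gtab$strand, 2),
                    seqinfo = GenomeInfoDb::Seqinfo(chroms, unname(chrLen)))
  cdsList <- GenomicRanges::split(cdsAll,
                                  factor(rep(gtab$gene, 2), levels = gtab$gene))
  genes <- geneModelSet(geneGr, cdsList)

  reference <- Biostrings::DNAStringSet(
    vapply(refChars, paste, character(1), collapse = ""))
  names(reference) <- chroms

  ## 11. linkage QTL intervals for ~60% of causal genes, plus one decoy
  nLink <- max(1L, round(0.6 * cfg@nCausalGenes))
  linkGenes <- causalGenes[seq_len(nLink)]
  linkRows <- lapply(linkGenes, function(gid) {
    i <- match(gid, gtab$gene)
    cv <- causalVariantIds[match(gid, causalGenes)]
    dRow <- dos[match(cv, vId), cult]
    p1 <- acc[cult][which(dRow == 2)[1]]
    p2 <- acc[cult][which(dRow == 0)[1]]
    data.frame(chrom = gtab$chrom[i],
               start = max(1L, gtab$start[i] - 100000L),
               end = min(cfg@chromLengthBp, gtab$end[i] + 100000L),
               trait = "RL", parent1 = p1, parent2 = p2,
               stringsAsFactors = FALSE)
  })
  decoyGene <- gtab[sample(setdiff(seq_len(cfg@nGenes), causalIdx), 1L), ]
  linkRows[[length(linkRows) + 1L]] <- data.frame(
    chrom = decoyGene$chrom,
    start = max(1L, decoyGene$start - 100000L),
    end = min(cfg@chromLengthBp, decoyGene$end + 100000L),
    trait = "RL", parent1 = acc[1], parent2 = acc[2],
    stringsAsFactors = FALSE)
  linkage <- do.call(rbind, linkRows)

  truth <- new("PlantedTruth",
               causalGenes = causalGenes,
               causalVariants = causalVariantIds,
               increasingAllele = structure(rep("alt", cfg@nCausalGenes),
                                            names = causalVariantIds),
               effects = effNominal,
               effectScale = effectScale,
               groups = data.frame(accession = acc, subpop = subpop,
                                   ecotype = ecotype,
                                   stringsAsFactors = FALSE))

  list(genotypes = genotypes, phenotypes = pheno, genes = genes,
       expression = expr, linkage = linkage, truth = truth,
       reference = reference)
}

#' Realised heritability of a simulated panel
#'
#' Ratio of the variance of the planted genetic values (realised effects
#' times trait-increasing allele dosage) to the phenotypic variance, over
#' cultivated accessions. Used to verify that the generator hits the
#' configured heritability within sampling error.
#'
#' @param truth a \linkS4class{PlantedTruth}.
#' @param genotypes the panel \linkS4class{GenotypeMatrix}.
#' @param phenotypes the panel phenotype data.frame.
#' @param trait trait column name (default "RL").
#' @return the realised variance fraction.
#' @export
realizedH2 <- function(truth, genotypes, phenotypes, trait = "RL") {
  if (!setequal(phenotypes$accession, accessions(genotypes)))
    stop("accession sets of phenotypes and genotypes differ")
  cultAcc <- phenotypes$accession[!is.na(phenotypes[[trait]])]
  if (length(cultAcc) < 2)
    stop("need at least two phenotyped accessions (variance undefined)")
  g <- genotypes[truth@causalVariants, cultAcc]
  d <- dosage(g)
  # missing calls imputed at the variant mean; flip so copies count the
  # trait-increasing allele
  for (i in seq_len(nrow(d))) d[i, is.na(d[i, ])] <- mean(d[i, ], na.rm = TRUE)
  flip <- truth@increasingAllele[rownames(d)] == "ref"
  d[flip, ] <- 2 - d[flip, ]
  gv <- as.numeric((truth@effects * truth@effectScale) %*% d)
  y <- phenotypes[[trait]][match(cultAcc, phenotypes$accession)]
  stats::var(gv) / stats::var(y)
}
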