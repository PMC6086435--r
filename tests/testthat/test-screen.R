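test_that("extreme pools are the exact trait-order head and tail", {
  set.seed(61)
  n <- 120
  acc <- sprintf("acc%03d", 1:n)
  pc1 <- c(rnorm(60, -5), rnorm(60, 5))   # two clear PC1 clusters
  pcs <- matrix(pc1, n, 1, dimnames = list(acc, "PC1"))
  sm <- new("StructureModel", pcs = pcs)
  ph <- data.frame(accession = acc, RL = rnorm(n),
                   subpop = rep(c("japonica", "indica"), each = 60),
                   stringsAsFactors = FALSE)
  pools <- buildPools(ph, sm, "RL", "japonica", nPerPool = 20,
                      pc1Cuts = c(-1, 1))
  typical <- ph$accession[ph$subpop == "japonica" & pc1 < -1]
  tv <- ph$RL[match(typical, ph$accession)]
  ord <- order(tv, typical)
  expect_identical(sort(pools$low), sort(typical[ord][1:20]))
  expect_identical(sort(pools$high), sort(typical[rev(ord)][1:20]))
  expect_length(intersect(pools$high, pools$low), 0)
  # insufficient typical accessions
  expect_error(buildPools(ph, sm, "RL", "japonica", nPerPool = 50,
                          pc1Cuts = c(-1, 1)), "need")
  # all trait values equal: pools valid but flagged zero-contrast
  ph2 <- ph; ph2$RL <- 1
  pools2 <- buildPools(ph2, sm, "RL", "japonica", nPerPool = 20,
                       pc1Cuts = c(-1, 1))
  expect_true(pools2$zeroContrast)
  expect_length(pools2$high, 20)
})

test_that("pooled chi-square equals the hand Pearson formula", {
  # perfectly separated 40-vs-40 table: chi2 = 80
  d <- rbind(v1 = rep(c(2, 0), each = 20))
  colnames(d) <- sprintf("a%02d", 1:40)
  g <- makeGenotype(d)
  pools <- list(high = colnames(d)[1:20], low = colnames(d)[21:40])
  res <- pooledChi2(g, pools, "v1", betaSign = c(v1 = 1))
  expect_equal(res$chi2, 80, tolerance = 1e-12)
  expect_lt(res$p, 1e-15)
  expect_true(res$directionOk)
  # direction flips with the effect sign
  resNeg <- pooledChi2(g, pools, "v1", betaSign = c(v1 = -1))
  expect_false(resNeg$directionOk)
  # identical pool frequencies: chi2 = 0
  d2 <- rbind(v1 = rep(c(2, 0, 2, 0), each = 10))
  colnames(d2) <- colnames(d)
  res2 <- pooledChi2(makeGenotype(d2), pools, "v1")
  expect_equal(res2$chi2, 0, tolerance = 1e-12)
  # one pool all-missing: untestable
  d3 <- d; d3[1, 1:20] <- NA
  res3 <- pooledChi2(makeGenotype(d3), pools, "v1")
  expect_false(res3$testable)
  # random tables against the independently coded contingency formula
  set.seed(62)
  for (rep in 1:60) {
    dr <- rbind(v = sample(c(0, 1, 2, NA), 40, TRUE, c(.4, .1, .4, .1)))
    colnames(dr) <- colnames(d)
    rr <- pooledChi2(makeGenotype(dr), pools, "v")
    vh <- dr[1, 1:20]; vl <- dr[1, 21:40]
    a <- sum(vh, na.rm = TRUE); b <- 2 * sum(!is.na(vh)) - a
    cc <- sum(vl, na.rm = TRUE); dd <- 2 * sum(!is.na(vl)) - cc
    N <- a + b + cc + dd
    if ((a + b) * (cc + dd) * (a + cc) * (b + dd) == 0) {
      expect_false(rr$testable)
    } else {
      oracle <- N * (a * dd - b * cc)^2 /
        ((a + b) * (cc + dd) * (a + cc) * (b + dd))
      expect_equal(rr$chi2, oracle, tolerance = 1e-10)
      expect_equal(rr$p, pchisq(oracle, 1, lower.tail = FALSE),
                   tolerance = 1e-10)
    }
  }
})

test_that("coding-variant consequences follow the genetic code on both strands", {
  # plus-strand gene with a single CDS; hand-crafted codons
  refSeq <- paste0(strrep("T", 99),
                   "ATG", "TGG", "GCT", "AAA", "TAA",  # M W A K *
                   strrep("T", 100))
  reference <- Biostrings::DNAStringSet(c(chr1 = refSeq))
  genes <- GRanges("chr1", IRanges(100, 114), strand = "+",
                   seqinfo = GenomeInfoDb::Seqinfo("chr1", nchar(refSeq)))
  names(genes) <- "gPlus"
  gm <- geneModelSet(genes, GRangesList(gPlus = genes))
  mkv <- function(pos, ref, alt, cls = "SNP") {
    gr <- GRanges("chr1", IRanges(pos, width = 1))
    names(gr) <- "v"
    mcols(gr)$ref <- ref; mcols(gr)$alt <- alt; mcols(gr)$vclass <- cls
    gr
  }
  # TGG -> TGA (third base of codon 2): stop gained, large effect
  an <- annotateVariants(mkv(105, "G", "A"), gm, reference)
  expect_equal(an$consequence, "stop_gain")
  expect_true(an$largeEffect)
  expect_equal(an$aaChange, "W2*")
  # GCT -> GCC (third position): synonymous Ala/Ala
  an2 <- annotateVariants(mkv(108, "T", "C"), gm, reference)
  expect_equal(an2$consequence, "synonymous")
  expect_false(an2$largeEffect)
  # ATG -> CTG: start loss
  an3 <- annotateVariants(mkv(100, "A", "C"), gm, reference)
  expect_equal(an3$consequence, "start_loss")
  expect_true(an3$largeEffect)
  # TAA -> CAA: stop loss
  an4 <- annotateVariants(mkv(112, "T", "C"), gm, reference)
  expect_equal(an4$consequence, "stop_loss")
  # frameshift vs in-frame InDel
  an5 <- annotateVariants(mkv(107, "C", "CAT", "InDel"), gm, reference)
  expect_equal(an5$consequence, "frameshift")
  expect_true(an5$largeEffect)
  an6 <- annotateVariants(mkv(107, "C", "CATG", "InDel"), gm, reference)
  expect_equal(an6$consequence, "inframe_indel")
  expect_false(an6$largeEffect)
  # promoter and intergenic zones
  an7 <- annotateVariants(mkv(50, "T", "A"), gm, reference)
  expect_equal(an7$zone, "promoter")
  expect_equal(an7$gene, "gPlus")
  an8 <- annotateVariants(mkv(210, "T", "A"), gm, reference)
  expect_equal(an8$zone, "intergenic")
  # reference mismatch errors with the position
  expect_error(annotateVariants(mkv(105, "C", "A"), gm, reference),
               "chr1:105")
})

test_that("minus-strand annotation agrees with a full-CDS translate-and-diff oracle", {
  p <- simulatePanel(smallConfig(seed = 63, nGenes = 12L))
  gm <- p$genes; reference <- p$reference
  minusGenes <- which(as.character(strand(geneRanges(gm))) == "-")
  set.seed(64)
  for (rep in 1:40) {
    gi <- sample(minusGenes, 1)
    cds <- cdsRanges(gm)[[gi]]
    seg <- cds[sample(length(cds), 1)]
    pos <- sample(start(seg):end(seg), 1)
    chrom <- as.character(seqnames(seg))
    rb <- as.character(Biostrings::subseq(reference[[chrom]], pos, pos))
    alt <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
    gr <- GRanges(chrom, IRanges(pos, width = 1)); names(gr) <- "x"
    mcols(gr)$ref <- rb; mcols(gr)$alt <- alt; mcols(gr)$vclass <- "SNP"
    an <- annotateVariants(gr, gm, reference)
    # oracle: rebuild the entire CDS, substitute, reverse-complement, translate
    segs <- cds[order(start(cds))]
    seq0 <- paste(vapply(seq_along(segs), function(i)
      as.character(Biostrings::subseq(reference[[chrom]], start(segs)[i],
                                      end(segs)[i])), ""), collapse = "")
    cpos <- match(pos, unlist(lapply(seq_along(segs),
                                     function(i) start(segs)[i]:end(segs)[i])))
    seq1 <- seq0; substr(seq1, cpos, cpos) <- alt
    rc <- function(s) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    aa0 <- as.character(Biostrings::translate(Biostrings::DNAString(rc(seq0)),
                                              no.init.codon = TRUE))
    aa1 <- as.character(Biostrings::translate(Biostrings::DNAString(rc(seq1)),
                                              no.init.codon = TRUE))
    dpos <- which(strsplit(aa0, "")[[1]] != strsplit(aa1, "")[[1]])
    expCons <- if (!length(dpos)) "synonymous" else {
      a0 <- substr(aa0, dpos, dpos); a1 <- substr(aa1, dpos, dpos)
      if (dpos == 1 && a0 == "M") "start_loss"
      else if (a1 == "*") "stop_gain"
      else if (a0 == "*") "stop_loss"
      else "nonsynonymous"
    }
    expect_equal(an$consequence, expCons)
  }
})

test_that("expression filters apply the ratio band and root specificity", {
  meta <- data.frame(
    sample = c("r1", "r2", "c1", "c2", "rs1", "rs2", "cs1", "cs2"),
    variety = paste0("V", 1:8),
    tissue = rep(c("root", "shoot"), each = 4),
    group = rep(c("robust", "robust", "control", "control"), 2),
    replicate = 1L)
  m <- matrix(0, 4, 8, dimnames = list(paste0("g", 1:4), meta$sample))
  m["g1", ] <- c(1.3, 1.3, 1.0, 1.0, 1, 1, 1, 1)   # ratio 1.4/1.1 ~ 1.27
  m["g2", ] <- c(2.0, 2.0, 1.0, 1.0, 2, 2, 2, 2)   # clearly differential
  m["g3", ] <- c(5, 5, 5, 5, 0, 0, 0, 0)           # root specific
  m["g4", ] <- c(3, 3, 3, 3, 4, 4, 4, 4)           # neither
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = m),
    colData = S4Vectors::DataFrame(meta, row.names = meta$sample))
  ef <- expressionFilters(se, paste0("g", 1:4))
  expect_equal(ef$ratio[1], 1.4 / 1.1, tolerance = 1e-12)
  expect_false(ef$differential[1])   # 1.27 misses the 1.3 band with eps
  expect_true(ef$differential[2])
  expect_false(ef$differential[4])   # ratio exactly 1
  expect_equal(ef$ratio[4], 1, tolerance = 1e-12)
  expect_true(ef$rootSpecific[3])
  expect_false(ef$rootSpecific[4])
  expect_warning(ef2 <- expressionFilters(se, c("g1", "ghost")), "absent")
  expect_false(ef2$differential[2])
})

test_that("evidence integration applies the documented combination rule", {
  q <- GRanges(c("chr1", "chr2"), IRanges(c(1000, 1000), c(9000, 9000)))
  names(q) <- c("qtl1", "qtl2")
  mcols(q)$members <- IRanges::CharacterList(list(c("v1", "v2"), c("v3")))
  annot <- data.frame(
    variant = c("v1", "v2", "v3"),
    gene = c("gA", "gB", "gC"),
    zone = c("ORF", "promoter", "ORF"),
    consequence = c("stop_gain", NA, "synonymous"),
    largeEffect = c(TRUE, FALSE, FALSE),
    aaChange = NA, spliceBoundary = FALSE, stringsAsFactors = FALSE)
  chi2 <- data.frame(variant = c("v1", "v2", "v3"),
                     chi2 = c(30, 1, 25), p = c(1e-7, 0.4, 1e-6),
                     directionOk = c(TRUE, TRUE, TRUE), testable = TRUE,
                     stringsAsFactors = FALSE)
  exprFlags <- data.frame(gene = c("gA", "gB", "gC"),
                          ratio = c(2.0, 1.0, 2.5),
                          differential = c(TRUE, FALSE, TRUE),
                          rootSpecific = FALSE, stringsAsFactors = FALSE)
  # GWAS-only QTLs (no linkage information): neutral linkage flag
  out <- integrateEvidence(q, annot, chi2, NULL, exprFlags)
  gA <- out$genes[out$genes$gene == "gA", ]
  expect_true(gA$poolChi2Pass)
  expect_true(is.na(gA$linkagePass))
  expect_equal(gA$status, "candidate")  # stop_gain + ratio 2 + chi2 pass
  # gB fails chi2 (p = 0.4) and has no ORF variant -> excluded
  expect_equal(out$genes$status[out$genes$gene == "gB"], "excluded")
  # gC passes chi2 but its only ORF variant is synonymous -> excluded
  expect_equal(out$genes$status[out$genes$gene == "gC"], "excluded")
  # monotone screening ledger
  expect_true(all(diff(out$ledger$nGenes) <= 0))
  # chi2 direction failure excludes a gene even at tiny p
  chi2b <- chi2; chi2b$directionOk[1] <- FALSE
  out2 <- integrateEvidence(q, annot, chi2b, NULL, exprFlags)
  expect_equal(out2$genes$status[out2$genes$gene == "gA"], "excluded")
  # deferred path: expression evidence missing
  exprFlags2 <- exprFlags; exprFlags2$differential[1] <- FALSE
  out3 <- integrateEvidence(q, annot, chi2, NULL, exprFlags2)
  expect_equal(out3$genes$status[out3$genes$gene == "gA"], "deferred")
  fin <- finalizeDeferredCandidates(out3, c(gA = 0.001))
  expect_equal(fin$genes$status[fin$genes$gene == "gA"], "candidate")
  fin2 <- finalizeDeferredCandidates(out3, c(gA = 0.5))
  expect_equal(fin2$genes$status[fin2$genes$gene == "gA"], "excluded")
  # empty QTL list gives an empty ledger
  empty <- callQTLs(new("AssociationResult",
                        table = data.frame(variant = "v", chrom = "chr1",
                                           pos = 1L, ref = "A", alt = "G",
                                           maf = 0.3, beta = 1, se = 1,
                                           minusLog10P = 1, tested = TRUE),
                        model = "glm", nUsed = 10L), threshold = 4)
  outE <- integrateEvidence(empty, annot, chi2, NULL, exprFlags)
  expect_equal(nrow(outE$genes), 0)
})
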