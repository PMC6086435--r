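makeScan <- function(pos, lp, chrom = "chr1") {
  m <- length(pos)
  tb <- data.frame(
    variant = sprintf("%s_%d", chrom, pos), chrom = chrom, pos = pos,
    ref = "A", alt = "G", maf = 0.3, beta = 1, se = 0.1, minusLog10P = lp,
    tested = TRUE, stringsAsFactors = FALSE)
  new("AssociationResult", table = tb, model = "glm", nUsed = 100L)
}

# independent oracle: exhaustive enumeration of gap chains
chainOracle <- function(pos, window, minSnps) {
  pos <- sort(pos)
  chains <- list(); cur <- pos[1]
  for (p in pos[-1]) {
    if (p - cur[length(cur)] <= window) cur <- c(cur, p)
    else { chains[[length(chains) + 1]] <- cur; cur <- p }
  }
  chains[[length(chains) + 1]] <- cur
  Filter(function(ch) length(ch) >= minSnps, chains)
}

test_that("QTL calling follows the 3-SNP / 170-kb clustering rule", {
  # {100k, 200k, 300k}: one QTL spanning the three
  q <- callQTLs(makeScan(c(100000, 200000, 300000), c(5, 6, 5)), threshold = 4)
  expect_length(q, 1)
  expect_equal(start(q), 100000)
  expect_equal(end(q), 300000)
  expect_equal(mcols(q)$nSnps, 3L)
  expect_equal(mcols(q)$peakPos, 200000)
  # only two significant variants: below the 3-SNP rule
  q2 <- callQTLs(makeScan(c(100000, 200000), c(5, 5)), threshold = 4)
  expect_length(q2, 0)
  # gap 200 kb > window: two singleton chains, none emitted
  q3 <- callQTLs(makeScan(c(100000, 300000), c(5, 5)),
                 threshold = 4, windowBp = 170000)
  expect_length(q3, 0)
  # boundary: gap exactly 170 kb chains, 170001 splits
  q4 <- callQTLs(makeScan(c(1e5, 1e5 + 170000, 1e5 + 340000), c(5, 5, 5)),
                 threshold = 4)
  expect_length(q4, 1)
  q5 <- callQTLs(makeScan(c(1e5, 1e5 + 170001, 1e5 + 340002), c(5, 5, 5)),
                 threshold = 4)
  expect_length(q5, 0)
})

test_that("QTL calling equals the enumeration oracle on random fixtures", {
  set.seed(51)
  for (rep in 1:15) {
    pos <- sort(sample.int(3e6, 30))
    lp <- runif(30, 0, 8)
    res <- makeScan(pos, lp)
    thr <- 4
    q <- callQTLs(res, thr)
    oracle <- chainOracle(pos[lp >= thr], 170000, 3)
    expect_length(q, length(oracle))
    for (k in seq_along(oracle)) {
      expect_equal(start(q)[k], min(oracle[[k]]))
      expect_equal(end(q)[k], max(oracle[[k]]))
      expect_equal(mcols(q)$nSnps[k], length(oracle[[k]]))
    }
    # invariance to input order
    res2 <- res; res2@table <- res2@table[sample.int(30), ]
    q2 <- callQTLs(res2, thr)
    expect_equal(start(q2), start(q))
    expect_equal(mcols(q2)$nSnps, mcols(q)$nSnps)
    # raising the threshold never enlarges any span
    qHi <- callQTLs(res, thr + 1.5)
    for (k in seq_along(qHi)) {
      container <- which(start(q) <= start(qHi)[k] & end(q) >= end(qHi)[k])
      expect_gte(length(container), 1)
    }
  }
})

test_that("emitted QTLs satisfy their own invariants on a simulated panel", {
  p <- simulatePanel(smallConfig(seed = 52, nAccessionsPerSubpop = 80L,
                                 nVariants = 500L))
  cult <- p$phenotypes$accession[!is.na(p$phenotypes$RL)]
  g <- qcFilter(p$genotypes[, cult])
  sm <- computePCs(g, 3)
  res <- scanGLM(g, p$phenotypes, "RL", sm)
  thr <- 2   # modest cutoff: the invariants must hold at any threshold
  q <- callQTLs(res, thr)
  tb <- scanTable(res)
  expect_gte(length(q), 1)
  for (k in seq_along(q)) {
    mem <- tb[match(mcols(q)$members[[k]], tb$variant), ]
    expect_gte(nrow(mem), 3)
    expect_true(all(mem$minusLog10P >= thr))
    expect_true(all(diff(sort(mem$pos)) <= 170000))
    expect_true(start(q)[k] <= mcols(q)$peakPos[k] &&
                  mcols(q)$peakPos[k] <= end(q)[k])
  }
})

test_that("QTL overlap pairing matches a quadratic oracle", {
  a <- GRanges(c("chr1", "chr1", "chr2", "chr3"),
               IRanges(c(100, 5000, 100, 100), c(1000, 6000, 1000, 500)))
  names(a) <- paste0("a", 1:4)
  b <- GRanges(c("chr1", "chr1", "chr2", "chr2", "chr4", "chr1"),
               IRanges(c(900, 7000, 2000, 950, 1, 4000),
                       c(1500, 8000, 3000, 1100, 10, 4990)))
  names(b) <- paste0("b", 1:6)
  ov <- overlapQTLs(a, b, slackBp = 0)
  # quadratic oracle
  for (i in seq_along(a)) for (j in seq_along(b)) {
    hit <- as.character(seqnames(a)[i]) == as.character(seqnames(b)[j]) &&
      start(a)[i] <= end(b)[j] && start(b)[j] <= end(a)[i]
    inTable <- any(ov$qtlA == names(a)[i] & ov$qtlB == names(b)[j],
                   na.rm = TRUE)
    expect_identical(inTable, hit)
  }
  expect_true(all(ov$class[!is.na(ov$qtlA) & !is.na(ov$qtlB)] == "identical"))
  # with slack, near pairs become "nearby" with their gap distance
  ovS <- overlapQTLs(a, b, slackBp = 50)
  near <- ovS[ovS$class == "nearby", ]
  expect_true(all(near$distanceBp > 0 & near$distanceBp <= 50))
  expect_true(any(ovS$qtlA == "a2" & ovS$qtlB == "b6", na.rm = TRUE)) # gap 10
  # identical lists pair fully as identical
  ovI <- overlapQTLs(a, a)
  expect_true(all(names(a) %in% ovI$qtlA[ovI$class == "identical"]))
  # disjoint chromosomes: no pairs
  ovD <- overlapQTLs(a[3], b[5])
  expect_true(all(ovD$class == "unique"))
})

test_that("linkage intersection applies the parental-difference rule", {
  # 6 significant variants; linkage interval covers 2; 1 has differing parents
  d <- rbind(v1 = c(2, 2, 0, 0), v2 = c(2, 2, 2, 0), v3 = c(0, 2, 0, 2),
             v4 = c(2, 0, 2, 0), v5 = c(0, 0, 2, 2), v6 = c(2, 2, 0, 2))
  colnames(d) <- c("P1", "P2", "X1", "X2")
  pos <- c(1000, 2000, 5000, 6000, 9000, 12000)
  g <- makeGenotype(d, pos = pos)
  q <- GRanges("chr1", IRanges(500, 10000))
  names(q) <- "qtl1"
  mcols(q)$members <- IRanges::CharacterList(list(rownames(d)))
  linkage <- data.frame(chrom = "chr1", start = 4500, end = 6500,
                        trait = "RL", parent1 = "P1", parent2 = "P2",
                        stringsAsFactors = FALSE)
  kept <- intersectLinkage(q, linkage, g)
  # v3, v4 inside the overlap; v3 parents 0 vs 2 differ; v4 parents 2 vs 0 differ
  expect_setequal(kept$variant, c("v3", "v4"))
  # parents identical at a variant -> dropped
  linkage2 <- data.frame(chrom = "chr1", start = 500, end = 2500,
                         trait = "RL", parent1 = "P1", parent2 = "P2",
                         stringsAsFactors = FALSE)
  kept2 <- intersectLinkage(q, linkage2, g)
  expect_identical(kept2$variant, character(0))  # v1, v2 equal in parents
  # missing parent call -> dropped with a log entry
  d3 <- d; d3["v3", "P1"] <- NA
  g3 <- makeGenotype(d3, pos = pos)
  expect_message(kept3 <- intersectLinkage(q, linkage, g3), "missing")
  expect_setequal(kept3$variant, "v4")
  expect_equal(attr(kept3, "nMissingParent"), 1L)
  # absent parent errors with its name
  linkage4 <- linkage; linkage4$parent1 <- "NOPE"
  expect_error(intersectLinkage(q, linkage4, g), "NOPE")
})
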