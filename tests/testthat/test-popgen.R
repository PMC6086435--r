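test_that("nucleotide diversity matches its textbook definitions", {
  # two sequences differing at 1 of 100 sites: pi = 0.01
  d <- matrix(0, 5, 2, dimnames = list(sprintf("v%d", 1:5), c("s1", "s2")))
  d[3, 2] <- 2
  g <- makeGenotype(d, pos = c(10, 20, 30, 40, 50))
  region <- GRanges("chr1", IRanges(1, 100))
  st <- diversityStats(g, region, c("s1", "s2"), minN = 2)
  expect_equal(st$pi, 0.01, tolerance = 1e-12)
  expect_equal(st$S, 1L)
  # all sequences identical: pi = 0, theta = 0, D missing
  d0 <- matrix(2, 5, 4, dimnames = list(sprintf("v%d", 1:5), paste0("s", 1:4)))
  st0 <- diversityStats(makeGenotype(d0, pos = c(10, 20, 30, 40, 50)),
                        region, paste0("s", 1:4))
  expect_equal(st0$pi, 0)
  expect_equal(st0$thetaW, 0)
  expect_true(is.na(st0$tajimaD))
})

test_that("pi equals the exhaustive pairwise oracle and D the 1989 constants", {
  set.seed(81)
  for (rep in 1:5) {
    n <- 10; m <- 50; L <- 1100
    h <- matrix(rbinom(n * m, 1, rep(runif(m, 0.05, 0.95), n)), m, n)
    d <- 2 * h
    dimnames(d) <- list(sprintf("v%02d", 1:m), paste0("s", 1:n))
    g <- makeGenotype(d, pos = sort(sample(1000:2000, m)))
    region <- GRanges("chr1", IRanges(1000, 1000 + L - 1))
    st <- diversityStats(g, region, paste0("s", 1:n))
    # oracle 1: mean pairwise difference over all 45 pairs
    tot <- 0; np <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      tot <- tot + sum(h[, i] != h[, j]); np <- np + 1
    }
    expect_equal(st$pi, tot / np / L, tolerance = 1e-12)
    # oracle 2: Tajima's D from independently recomputed constants
    S <- sum(rowMeans(h) > 0 & rowMeans(h) < 1)
    a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
    Dexp <- (st$pi * L - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
    expect_equal(st$tajimaD, Dexp, tolerance = 1e-10)
    expect_equal(st$S, S)
  }
})

test_that("Tajima's D is negative under singleton excess, positive when balanced", {
  set.seed(82)
  n <- 20; m <- 40
  region <- GRanges("chr1", IRanges(1, 5000))
  signs <- vapply(1:20, function(r) {
    h <- matrix(0, m, n)
    for (i in 1:m) h[i, sample(n, 1)] <- 1   # every site a singleton
    d <- 2 * h
    dimnames(d) <- list(sprintf("v%02d", 1:m), paste0("s", 1:n))
    g <- makeGenotype(d, pos = sort(sample(1:5000, m)))
    diversityStats(g, region, paste0("s", 1:n))$tajimaD
  }, numeric(1))
  expect_true(all(signs < 0))
  # balanced intermediate frequencies push D positive
  h <- matrix(rep(rep(0:1, each = n / 2), m), m, n, byrow = TRUE)
  d <- 2 * h
  dimnames(d) <- list(sprintf("v%02d", 1:m), paste0("s", 1:n))
  g <- makeGenotype(d, pos = sort(sample(1:5000, m)))
  expect_gt(diversityStats(g, region, paste0("s", 1:n))$tajimaD, 0)
})

test_that("diversity ratios flag selection and annotate degenerate cases", {
  rep1 <- data.frame(gene = c("g1", "g2", "g3"), group = "nonLT",
                     pi = c(0.004, 0.002, 0.001), thetaW = 0, tajimaD = 0,
                     S = 1L, n = 10)
  rep2 <- data.frame(gene = c("g1", "g2", "g3"), group = "LT",
                     pi = c(0.0008, 0.002, 0), thetaW = 0, tajimaD = 0,
                     S = 1L, n = 10)
  rr <- diversityRatios(rbind(rep1, rep2), "nonLT", "LT")
  expect_equal(rr$ratio[rr$gene == "g1"], 5, tolerance = 1e-12)
  expect_true(rr$selectionFlag[rr$gene == "g1"])
  expect_equal(rr$ratio[rr$gene == "g2"], 1)
  expect_equal(rr$log2Ratio[rr$gene == "g2"], 0)
  expect_false(rr$selectionFlag[rr$gene == "g2"])
  expect_true(is.infinite(rr$ratio[rr$gene == "g3"]))
  expect_match(rr$note[rr$gene == "g3"], "infinite")
  expect_true(rr$selectionFlag[rr$gene == "g3"])
})

test_that("pyramiding frequencies respect fixed groups and drop unknown SNPs", {
  d <- rbind(v1 = c(2, 2, 2, 0, 0, 2), v2 = c(2, 2, 2, 2, 0, 0))
  colnames(d) <- c("u1", "u2", "u3", "w1", "w2", "w3")
  g <- makeGenotype(d)
  groups <- list(upland = c("u1", "u2", "u3"), wild = c("w1", "w2", "w3"))
  pr <- pyramidingProfile(g, c("v1", "v2"), groups,
                          increasing = c(v1 = "alt", v2 = "alt"))
  expect_equal(unname(pr$freq["upland"]), 1)
  expect_equal(unname(pr$freq["wild"]), mean(c(1 / 3, 1 / 3)))
  expect_equal(pr$detectedInWild, 2L)
  # ref-increasing alleles flip the frequency
  pr2 <- pyramidingProfile(g, "v1", groups, increasing = c(v1 = "ref"))
  expect_equal(unname(pr2$freq["upland"]), 0)
  expect_error(pyramidingProfile(g, character(0), groups, c()), "empty")
  expect_message(
    pr3 <- pyramidingProfile(g, c("v1", "ghost"), groups,
                             increasing = c(v1 = "alt", ghost = "alt")),
    "dropped")
  expect_equal(nrow(pr3$perSnp), 1)
})

test_that("neighbor joining recovers additive trees and round-trips Newick", {
  # 4 taxa with additive distances from ((A:1,B:2):1,(C:1,D:1))
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:1,D:1);")
  D <- ape::cophenetic.phylo(tr)
  njt <- njTree(D)
  expect_equal(ape::dist.topo(ape::unroot(tr), njt), 0,
               ignore_attr = TRUE)
  expect_equal(sort(ape::cophenetic.phylo(njt)[rownames(D), colnames(D)]),
               sort(D), tolerance = 1e-10)
  # 3 taxa: unique topology, three-point formula lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- njTree(D3)
  ed <- setNames(t3$edge.length[t3$edge[, 2] <= 3],
                 t3$tip.label[t3$edge[t3$edge[, 2] <= 3, 2]])
  expect_equal(unname(ed["A"]), (3 + 4 - 5) / 2)   # 1
  expect_equal(unname(ed["B"]), (3 + 5 - 4) / 2)   # 2
  expect_equal(unname(ed["C"]), (4 + 5 - 3) / 2)   # 3
  # duplicated accession gives a zero-length cherry
  d <- rbind(v1 = c(0, 0, 2, 2), v2 = c(0, 0, 2, 0), v3 = c(2, 2, 0, 0))
  colnames(d) <- c("A", "Adup", "B", "C")
  g <- makeGenotype(d)
  tg <- njTree(g)
  M <- ape::cophenetic.phylo(tg)
  expect_equal(M["A", "Adup"], 0, tolerance = 1e-12)
  # Newick round trip preserves topology and lengths
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tg, f)
  tg2 <- ape::read.tree(f)
  expect_true(ape::all.equal.phylo(tg, tg2, use.edge.length = TRUE))
  expect_error(njTree(g[, 1:2]), "at least 3")
})

test_that("IBS distance uses pairwise deletion and detects empty overlap", {
  d <- rbind(v1 = c(0, 2, NA), v2 = c(2, NA, 0), v3 = c(0, 0, 2))
  colnames(d) <- c("a", "b", "c")
  D <- ibsDistance(makeGenotype(d))
  expect_equal(D["a", "b"], 1 / 2)  # v1 mismatch, v3 match (v2 missing in b)
  expect_equal(D["a", "c"], 1)      # v2, v3 both mismatched; v1 missing in c
  dBad <- rbind(v1 = c(0, NA), v2 = c(NA, 2))
  colnames(dBad) <- c("a", "b")
  expect_error(ibsDistance(makeGenotype(dBad)), "share no called")
})

test_that("monophyly check finds the smallest containing clade", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,(D:1,E:1):2);")
  mc <- monophylyCheck(tr, c("A", "B"))
  expect_true(mc$isClustered)
  expect_setequal(mc$cladeTips, c("A", "B"))
  mc2 <- monophylyCheck(tr, c("A", "C"))
  expect_equal(mc2$purity, 2 / 3)
  expect_setequal(mc2$cladeTips, c("A", "B", "C"))
  expect_equal(monophylyCheck(tr, tr$tip.label)$purity, 1)
  expect_equal(monophylyCheck(tr, "D")$purity, 1)
  expect_error(monophylyCheck(tr, character(0)), "empty")
  expect_error(monophylyCheck(tr, "Z"), "not in tree")
})
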