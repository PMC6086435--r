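# Shared fixture builders. All data are generated in code at test time.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# GenotypeMatrix from a bare dosage matrix (variants x accessions)
makeGenotype <- function(d, pos = NULL, chrom = "chr1", ref = NULL,
                         alt = NULL, vclass = "SNP", seqlen = NA) {
  m <- nrow(d)
  if (is.null(pos)) pos <- seq(1000L, by = 1000L, length.out = m)
  if (is.null(rownames(d))) rownames(d) <- sprintf("v%03d", seq_len(m))
  if (is.null(colnames(d))) colnames(d) <- sprintf("acc%03d", seq_len(ncol(d)))
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  if (length(chrom) == 1) chrom <- rep(chrom, m)
  si <- if (is.na(seqlen)) NULL else
    GenomeInfoDb::Seqinfo(unique(chrom), rep(seqlen, length(unique(chrom))))
  gr <- if (is.null(si)) GRanges(chrom, IRanges(pos, width = 1L)) else
    GRanges(chrom, IRanges(pos, width = 1L), seqinfo = si)
  names(gr) <- rownames(d)
  mcols(gr)$ref <- ref
  mcols(gr)$alt <- alt
  mcols(gr)$vclass <- rep(vclass, length.out = m)
  GenotypeMatrix(d, gr, colnames(d))
}

# small, fast synthetic panel configuration
smallConfig <- function(seed = 1, ...) {
  args <- list(nAccessionsPerSubpop = 40L, nWild = 12L, nChromosomes = 2L,
               chromLengthBp = 1000000L, nVariants = 300L, ldBlockBp = 50000L,
               nGenes = 20L, nCausalGenes = 2L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulationConfig, args)
}

# structured null genotypes: two subpopulations with shifted frequencies,
# no causal variants; returns list(g, pheno, labels)
nullStructuredPanel <- function(nPerPop = 50, m = 1000, shift = 0.3,
                                diffFrac = 0.3, traitShift = 0.5) {
  n <- 2 * nPerPop
  p0 <- runif(m, 0.1, 0.5)
  delta <- ifelse(runif(m) < diffFrac, shift, 0) * sign(rnorm(m))
  p1 <- pmin(pmax(p0 + delta, 0.02), 0.98)
  p2 <- pmin(pmax(p0 - delta, 0.02), 0.98)
  a1 <- matrix(rbinom(m * nPerPop, 1, rep(p1, nPerPop)), m, nPerPop)
  a2 <- matrix(rbinom(m * nPerPop, 1, rep(p2, nPerPop)), m, nPerPop)
  d <- 2 * cbind(a1, a2)
  dimnames(d) <- list(sprintf("v%04d", seq_len(m)), sprintf("acc%03d", seq_len(n)))
  pos <- sort(sample.int(5e6, m))
  g <- makeGenotype(d, pos = pos)
  labels <- rep(c("popA", "popB"), each = nPerPop)
  y <- traitShift * (labels == "popA") + rnorm(n)
  pheno <- data.frame(accession = colnames(d), RL = y, subpop = labels,
                      stringsAsFactors = FALSE)
  list(g = g, pheno = pheno, labels = labels)
}

# mean silhouette width of a 1-d embedding against two labels
silhouette1d <- function(x, labels) {
  ulab <- unique(labels)
  s <- vapply(seq_along(x), function(i) {
    own <- labels[i]
    a <- mean(abs(x[i] - x[labels == own & seq_along(x) != i]))
    b <- min(vapply(setdiff(ulab, own), function(l)
      mean(abs(x[i] - x[labels == l])), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
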