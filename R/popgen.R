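## Internal: haploidize inbred dosages (0 -> 0, 2 -> 1, het/missing -> NA).
.haploid <- function(d) {
  h <- d / 2
  h[d == 1] <- NA_real_
  h
}

## Tajima's 1989 variance constants for sample size n.
.tajimaConstants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Nucleotide diversity, Watterson's theta and Tajima's D for a region
#'
#' SNP-table-based estimators for a group of inbred accessions treated as
#' haploid sequences (heterozygous residual calls are set missing). Per
#' site, the diversity contribution is \eqn{2\hat p(1-\hat p)\,n/(n-1)} with
#' the site-wise number of called sequences n (pairwise deletion); sites
#' with fewer than \code{minN} called sequences are skipped. The region
#' value divides by the region length L (monomorphic sites contribute 0), so
#' absolute values depend on the L convention while group ratios do not.
#' Watterson's theta is \eqn{S / (a_1 L)} with \eqn{a_1} evaluated at the
#' harmonic-mean site-wise n, and Tajima's D standardises \eqn{\pi L -
#' \theta_W L} with the 1989 variance constants at that n. D is undefined
#' (NA) when S = 0 or fewer than 4 sequences are available.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param region \link[GenomicRanges]{GRanges} of length 1 (the gene span).
#' @param group accession ids of the group.
#' @param minN minimum called sequences per site (default 4; the classic
#'   two-sequence definition of pi is recovered with \code{minN = 2}).
#' @return list: \code{pi}, \code{thetaW} (both per site), \code{tajimaD},
#'   \code{S}, \code{n} (harmonic-mean sequences), \code{L},
#'   \code{sitesUsed}.
#' @export
diversityStats <- function(g, region, group, minN = 4L) {
  stopifnot(length(region) == 1)
  v <- variantRanges(g)
  inReg <- as.character(seqnames(v)) == as.character(seqnames(region)) &
    GenomicRanges::start(v) >= GenomicRanges::start(region) &
    GenomicRanges::start(v) <= GenomicRanges::end(region) &
    mcols(v)$vclass == "SNP"
  L <- GenomicRanges::width(region)
  h <- .haploid(dosage(g)[inReg, group, drop = FALSE])
  nSite <- rowSums(!is.na(h))
  use <- nSite >= minN
  h <- h[use, , drop = FALSE]
  nSite <- nSite[use]
  if (!nrow(h))
    return(list(pi = 0, thetaW = 0, tajimaD = NA_real_, S = 0L,
                n = NA_real_, L = L, sitesUsed = 0L))
  p <- rowMeans(h, na.rm = TRUE)
  seg <- p > 0 & p < 1
  piSite <- 2 * p * (1 - p) * nSite / (nSite - 1)
  pi <- sum(piSite) / L
  S <- sum(seg)
  nH <- length(nSite) / sum(1 / nSite)      # harmonic mean of site-wise n
  nInt <- max(2L, round(nH))
  cst <- .tajimaConstants(nInt)
  thetaW <- S / cst$a1 / L
  tajD <- NA_real_
  if (S > 0 && nInt >= 4) {
    varD <- cst$e1 * S + cst$e2 * S * (S - 1)
    if (varD > 0) tajD <- (pi * L - thetaW * L) / sqrt(varD)
  }
  list(pi = pi, thetaW = thetaW, tajimaD = tajD, S = as.integer(S),
       n = nH, L = L, sitesUsed = nrow(h))
}

#' Per-gene diversity report over groups
#'
#' Runs \code{\link{diversityStats}} for every gene region and accession
#' group, mirroring the per-gene, per-ecotype diversity tables of selection
#' scans.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param genes a \linkS4class{GeneModelSet} (or named GRanges of regions).
#' @param groups named list of accession-id vectors.
#' @param geneIds genes to report (default all).
#' @param minN minimum called sequences per site.
#' @return data.frame: \code{gene}, \code{group}, \code{pi}, \code{thetaW},
#'   \code{tajimaD}, \code{S}, \code{n}.
#' @export
diversityReport <- function(g, genes, groups, geneIds = NULL, minN = 4L) {
  regions <- if (is(genes, "GeneModelSet")) geneRanges(genes) else genes
  if (!is.null(geneIds)) regions <- regions[geneIds]
  rows <- list()
  for (gi in seq_along(regions)) for (grp in names(groups)) {
    st <- diversityStats(g, regions[gi], groups[[grp]], minN = minN)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = names(regions)[gi], group = grp, pi = st$pi,
      thetaW = st$thetaW, tajimaD = st$tajimaD, S = st$S, n = st$n,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Diversity-ratio selection scan
#'
#' Ratios of nucleotide diversity between two groups per gene (e.g.
#' wild/japonica, or non-robust-root/robust-root within a subspecies), with
#' log2 transforms and a selection flag at ratio > \code{flagAbove}
#' (strongly reduced diversity in the denominator group). A zero
#' denominator yields an infinite, flagged ratio annotated as such; 0/0 is
#' reported undefined.
#'
#' @param report data.frame from \code{\link{diversityReport}}.
#' @param numerator,denominator group names.
#' @param flagAbove selection-flag threshold on the ratio (default 4).
#' @return data.frame: \code{gene}, \code{piNum}, \code{piDen},
#'   \code{ratio}, \code{log2Ratio}, \code{selectionFlag}, \code{note}.
#' @export
diversityRatios <- function(report, numerator, denominator, flagAbove = 4) {
  num <- report[report$group == numerator, ]
  den <- report[report$group == denominator, ]
  genes <- intersect(num$gene, den$gene)
  pn <- num$pi[match(genes, num$gene)]
  pd <- den$pi[match(genes, den$gene)]
  ratio <- ifelse(pd > 0, pn / pd, ifelse(pn > 0, Inf, NA_real_))
  note <- ifelse(pd > 0, "",
                 ifelse(pn > 0, "infinite: zero diversity in denominator",
                        "undefined: zero diversity in both groups"))
  data.frame(gene = genes, piNum = pn, piDen = pd, ratio = ratio,
             log2Ratio = log2(ratio),
             selectionFlag = !is.na(ratio) & ratio > flagAbove,
             note = note, stringsAsFactors = FALSE)
}

#' Trait-increasing allele pyramiding profile
#'
#' For a set of trait-associated SNPs with known trait-increasing alleles
#' (from the association effect sign, or supplied), computes each group's
#' mean trait-increasing allele frequency (allele copies, missing excluded)
#' and counts how many of the increasing alleles are detected in the wild
#' group, quantifying allele pyramiding along the
#' wild -> lowland -> upland gradient.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param snpSet variant ids.
#' @param groups named list of accession-id vectors; a group named
#'   \code{wild} drives the ancestral-detection count.
#' @param increasing named character ("ref"/"alt") per variant, or named
#'   numeric effect signs (positive = alt increases the trait).
#' @return list: \code{freq} (named per-group mean frequency),
#'   \code{perSnp} (data.frame of per-variant frequencies),
#'   \code{detectedInWild}, \code{absentInWild}.
#' @export
pyramidingProfile <- function(g, snpSet, groups, increasing) {
  if (!length(snpSet)) stop("empty SNP set")
  missing <- setdiff(snpSet, variantIds(g))
  if (length(missing)) {
    message(length(missing), " SNP(s) absent from genotypes; dropped")
    snpSet <- setdiff(snpSet, missing)
    if (!length(snpSet)) stop("no SNP of the set present in genotypes")
  }
  if (is.numeric(increasing))
    increasing <- ifelse(increasing > 0, "alt", "ref")
  incRef <- increasing[snpSet] == "ref"
  perSnp <- data.frame(variant = snpSet, stringsAsFactors = FALSE)
  freq <- numeric(0)
  for (grp in names(groups)) {
    d <- dosage(g)[snpSet, groups[[grp]], drop = FALSE]
    altCopies <- rowSums(d, na.rm = TRUE)
    tot <- 2 * rowSums(!is.na(d))
    f <- ifelse(tot > 0, altCopies / tot, NA_real_)
    f[incRef] <- 1 - f[incRef]
    perSnp[[grp]] <- f
    freq[grp] <- mean(f, na.rm = TRUE)
  }
  detected <- NA_integer_; absent <- NA_integer_
  if ("wild" %in% names(groups)) {
    fw <- perSnp[["wild"]]
    detected <- sum(!is.na(fw) & fw > 0)
    absent <- length(snpSet) - detected
  }
  list(freq = freq, perSnp = perSnp, detectedInWild = detected,
       absentInWild = absent)
}

#' Identity-by-state distance matrix
#'
#' Pairwise mismatch proportion of dosages (|di - dj| / 2, so a
#' heterozygous-homozygous pair counts half) over the variants called in
#' both accessions (pairwise deletion). Errors when a pair shares no called
#' variant.
#'
#' @param g a \linkS4class{GenotypeMatrix} (optionally pre-subset to a SNP
#'   set).
#' @return symmetric numeric matrix of distances in [0, 1].
#' @export
ibsDistance <- function(g) {
  d <- dosage(g)
  n <- ncol(d)
  called <- !is.na(d)
  d0 <- d; d0[!called] <- 0
  shared <- crossprod(called * 1)          # pairwise called counts
  num <- matrix(0, n, n)
  for (i in seq_len(n)) {
    diffs <- abs(d0[, i] - d0) / 2
    diffs[!(called[, i] & called)] <- 0
    num[i, ] <- colSums(diffs)
  }
  if (any(shared[upper.tri(shared)] == 0)) {
    idx <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)[1, ]
    stop(sprintf("accessions %s and %s share no called variant",
                 colnames(d)[idx[1]], colnames(d)[idx[2]]))
  }
  dist <- num / shared
  dimnames(dist) <- list(colnames(d), colnames(d))
  diag(dist) <- 0
  dist
}

#' Neighbor-joining tree from candidate-gene SNPs
#'
#' Saitou-Nei neighbor joining (via \code{\link[ape]{nj}}) on the IBS
#' mismatch distance; negative branch lengths are clipped to 0. On an
#' additive distance matrix the generating tree is recovered exactly.
#'
#' @param g a \linkS4class{GenotypeMatrix}, or a symmetric distance matrix.
#' @param snpSet optional variant ids restricting the distance computation.
#' @return an \code{ape} \code{phylo} tree (serialize with
#'   \code{\link[ape]{write.tree}}).
#' @export
njTree <- function(g, snpSet = NULL) {
  D <- if (is.matrix(g)) g else {
    if (!is.null(snpSet)) g <- g[snpSet, ]
    if (ncol(dosage(g)) < 3) stop("need at least 3 accessions")
    ibsDistance(g)
  }
  if (nrow(D) < 3) stop("need at least 3 accessions")
  tree <- ape::nj(stats::as.dist(D))
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Monophyly of a labelled accession set
#'
#' Finds the smallest clade (relative to the tree's root; supply
#' \code{outgroup} to root biologically, e.g. at a wild accession)
#' containing all labelled leaves and reports its purity, the fraction of
#' its leaves that are labelled. Purity 1 means the labelled set is
#' monophyletic.
#'
#' @param tree a \code{phylo} tree.
#' @param labels leaf names that should cluster.
#' @param outgroup optional leaf (or leaves) to root at first.
#' @return list: \code{isClustered} (purity == 1), \code{cladeTips},
#'   \code{purity}.
#' @export
monophylyCheck <- function(tree, labels, outgroup = NULL) {
  if (!length(labels)) stop("empty label set")
  if (!all(labels %in% tree$tip.label))
    stop("label(s) not in tree: ",
         paste(setdiff(labels, tree$tip.label), collapse = ", "))
  if (!is.null(outgroup))
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  if (length(labels) == 1L) {
    return(list(isClustered = TRUE, cladeTips = labels, purity = 1))
  }
  mrca <- ape::getMRCA(tree, labels)
  root <- length(tree$tip.label) + 1L
  tips <- if (mrca == root) tree$tip.label
          else ape::extract.clade(tree, mrca)$tip.label
  purity <- mean(tips %in% labels)
  list(isClustered = isTRUE(all.equal(purity, 1)), cladeTips = tips,
       purity = purity)
}
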