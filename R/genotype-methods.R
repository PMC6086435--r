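#' Construct a GenotypeMatrix
#'
#' @param dosage variants x accessions matrix of ALT-allele counts
#'   (0/1/2, NA = missing).
#' @param variants \link[GenomicRanges]{GRanges} named by variant id with
#'   metadata columns \code{ref}, \code{alt}, \code{vclass}.
#' @param accessions character accession ids (defaults to
#'   \code{colnames(dosage)}).
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
GenotypeMatrix <- function(dosage, variants, accessions = colnames(dosage)) {
  if (is.null(accessions))
    stop("accession ids required (colnames of dosage or `accessions`)")
  dosage <- as.matrix(dosage)
  rownames(dosage) <- names(variants)
  colnames(dosage) <- accessions
  new("GenotypeMatrix", dosage = dosage, variants = variants,
      accessions = as.character(accessions))
}

#' @rdname GenotypeMatrix-class
#' @export
setMethod("dosage", "GenotypeMatrix", function(x) x@dosage)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("accessions", "GenotypeMatrix", function(x) x@accessions)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("variantRanges", "GenotypeMatrix", function(x) x@variants)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("variantIds", "GenotypeMatrix", function(x) names(x@variants))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("dim", "GenotypeMatrix",
          function(x) c(length(x@variants), length(x@accessions)))

#' Minor allele frequency per variant
#'
#' Computed on allele copies (two per called genotype), missing calls
#' excluded. Heterozygous dosages contribute one copy of each allele.
#'
#' @rdname GenotypeMatrix-class
#' @export
setMethod("maf", "GenotypeMatrix", function(x) {
  d <- x@dosage
  altCopies <- rowSums(d, na.rm = TRUE)
  totCopies <- 2 * rowSums(!is.na(d))
  p <- ifelse(totCopies > 0, altCopies / totCopies, NA_real_)
  out <- pmin(p, 1 - p)
  names(out) <- names(x@variants)
  out
})

#' @rdname GenotypeMatrix-class
#' @export
setMethod("missingRate", "GenotypeMatrix", function(x) {
  out <- rowMeans(is.na(x@dosage))
  names(out) <- names(x@variants)
  out
})

#' @rdname GenotypeMatrix-class
#' @param i,j variant and accession subscripts (ids or indices).
#' @param ...,drop ignored.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_along(x@variants)
  if (missing(j)) j <- seq_along(x@accessions)
  if (is.character(i)) i <- match(i, names(x@variants))
  if (is.character(j)) j <- match(j, x@accessions)
  if (anyNA(i)) stop("unknown variant id in subscript")
  if (anyNA(j)) stop("unknown accession id in subscript")
  new("GenotypeMatrix",
      dosage = x@dosage[i, j, drop = FALSE],
      variants = x@variants[i],
      accessions = x@accessions[j])
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d variants x %d accessions\n",
              length(object@variants), length(object@accessions)))
  tab <- table(as.character(mcols(object@variants)$vclass))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(as.character(seqnames(object@variants))), collapse = ", ")))
  mr <- mean(is.na(object@dosage))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mr))
})

#' Filter variants on missing rate and minor allele frequency
#'
#' Retains exactly the variants with missing rate <= \code{maxMissing} and
#' MAF >= \code{minMaf} (allele-copy MAF, missing excluded), preserving
#' order. Matches the usual resequencing-panel QC of dropping variants with
#' more than 50\% missing calls or MAF below 5\%.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param maxMissing maximum tolerated per-variant missing rate, in [0,1].
#' @param minMaf minimum minor allele frequency, in [0,1].
#' @return the filtered \linkS4class{GenotypeMatrix}.
#' @export
qcFilter <- function(g, maxMissing = 0.5, minMaf = 0.05) {
  stopifnot(maxMissing >= 0, maxMissing <= 1, minMaf >= 0, minMaf <= 1)
  keep <- missingRate(g) <= maxMissing & !is.na(maf(g)) & maf(g) >= minMaf
  g[which(keep), ]
}

#' Greedy LD pruning
#'
#' Scans variants left to right in genome order and drops a variant when its
#' squared dosage correlation with any retained variant within
#' \code{windowBp} exceeds \code{r2Max}. Zero-variance variants have r^2
#' treated as 0 (they are never pruned for LD, though QC normally removes
#' them first). Correlations use pairwise-complete dosages.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param r2Max squared-correlation ceiling, in (0, 1].
#' @param windowBp window within which pairs are examined.
#' @return the pruned \linkS4class{GenotypeMatrix}.
#' @export
ldPrune <- function(g, r2Max = 0.3, windowBp = 500000L) {
  stopifnot(r2Max > 0, r2Max <= 1)
  v <- variantRanges(g)
  d <- dosage(g)
  chrom <- as.character(seqnames(v))
  pos <- GenomicRanges::start(v)
  keep <- logical(length(v))
  kept <- integer(0)
  for (i in seq_along(v)) {
    inWin <- kept[chrom[kept] == chrom[i] & pos[i] - pos[kept] <= windowBp]
    drop <- FALSE
    if (length(inWin)) {
      r <- suppressWarnings(
        stats::cor(d[i, ], t(d[inWin, , drop = FALSE]),
                   use = "pairwise.complete.obs"))
      r[is.na(r)] <- 0  # zero-variance convention
      if (any(r^2 > r2Max)) drop <- TRUE
    }
    if (!drop) {
      keep[i] <- TRUE
      kept <- c(kept, i)
    }
  }
  g[which(keep), ]
}
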