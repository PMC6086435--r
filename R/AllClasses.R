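#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList mcols mcols<- metadata
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

#' Accession-by-variant allele dosage container
#'
#' Holds biallelic variants (SNPs and small InDels) for a panel of largely
#' homozygous inbred accessions. Dosages count copies of the ALT allele
#' (0, 1 or 2); \code{NA} marks missing calls. Variants are rows, accessions
#' are columns, following the features-by-samples convention of
#' \linkS4class{SummarizedExperiment}.
#'
#' @slot dosage integer-like matrix, variants x accessions, values in
#'   \{0, 1, 2, NA\}.
#' @slot variants \link[GenomicRanges]{GRanges} of variant positions
#'   (1-based), named by variant id, with metadata columns \code{ref},
#'   \code{alt} (allele strings) and \code{vclass} ("SNP" or "InDel").
#' @slot accessions character vector of accession identifiers.
#' @export
setClass("GenotypeMatrix",
  representation(
    dosage = "matrix",
    variants = "GRanges",
    accessions = "character"
  )
)

setValidity("GenotypeMatrix", function(object) {
  msg <- NULL
  d <- object@dosage
  v <- object@variants
  if (nrow(d) != length(v))
    msg <- c(msg, "nrow(dosage) must equal length(variants)")
  if (ncol(d) != length(object@accessions))
    msg <- c(msg, "ncol(dosage) must equal length(accessions)")
  if (is.null(names(v)) && length(v) > 0)
    msg <- c(msg, "variants must be named by variant id")
  if (!all(c("ref", "alt", "vclass") %in% colnames(mcols(v))))
    msg <- c(msg, "variants must carry ref, alt and vclass metadata")
  bad <- d[!is.na(d)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  # positions strictly increasing within chromosome
  if (length(v) > 1) {
    sp <- split(GenomicRanges::start(v), as.character(seqnames(v)))
    if (!all(vapply(sp, function(p) all(diff(p) > 0) || length(p) < 2, logical(1))))
      msg <- c(msg, "variant positions must be strictly increasing within chromosome")
  }
  if (is.null(msg)) TRUE else msg
})

#' Gene models with strand-aware promoters
#'
#' A set of gene models: gene spans, CDS segments and the 2000-bp
#' strand-aware upstream promoter of each gene (truncated at chromosome
#' edges). Coordinates are 1-based inclusive throughout.
#'
#' @slot genes \link[GenomicRanges]{GRanges} of gene spans, named by gene id,
#'   with strand set.
#' @slot cds \link[GenomicRanges]{GRangesList} of CDS segments per gene
#'   (same names as \code{genes}).
#' @slot promoters \link[GenomicRanges]{GRanges} of promoter spans, named by
#'   gene id.
#' @export
setClass("GeneModelSet",
  representation(
    genes = "GRanges",
    cds = "GRangesList",
    promoters = "GRanges"
  )
)

setValidity("GeneModelSet", function(object) {
  msg <- NULL
  g <- object@genes
  if (length(g) && is.null(names(g)))
    msg <- c(msg, "genes must be named by gene id")
  if (!identical(names(object@cds), names(g)))
    msg <- c(msg, "cds must be named identically to genes")
  if (!identical(names(object@promoters), names(g)))
    msg <- c(msg, "promoters must be named identically to genes")
  if (length(g)) {
    cd <- unlist(object@cds, use.names = FALSE)
    idx <- rep(seq_along(g), lengths(object@cds))
    if (length(cd)) {
      if (any(GenomicRanges::start(cd) < GenomicRanges::start(g)[idx]) ||
          any(GenomicRanges::end(cd) > GenomicRanges::end(g)[idx]))
        msg <- c(msg, "CDS segment(s) outside their gene span")
      o <- order(idx, GenomicRanges::start(cd))
      same <- idx[o][-1] == idx[o][-length(o)]
      if (any(same & GenomicRanges::start(cd)[o][-1] <=
                GenomicRanges::end(cd)[o][-length(o)]))
        msg <- c(msg, "overlapping CDS segments within a gene")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Population-structure model: principal components, kinship, compression
#'
#' @slot pcs numeric matrix, accession x k principal-component scores
#'   (rownames are accession ids).
#' @slot kinship symmetric accession x accession relationship matrix
#'   (VanRaden method 1); may be empty when only PCs were computed.
#' @slot groups integer vector mapping accessions to compression groups
#'   (empty when uncompressed).
#' @slot groupKinship group-level kinship used by the compressed mixed model.
#' @export
setClass("StructureModel",
  representation(
    pcs = "matrix",
    kinship = "matrix",
    groups = "integer",
    groupKinship = "matrix"
  ),
  prototype(
    pcs = matrix(numeric(0), 0, 0),
    kinship = matrix(numeric(0), 0, 0),
    groups = integer(0),
    groupKinship = matrix(numeric(0), 0, 0)
  )
)

setValidity("StructureModel", function(object) {
  msg <- NULL
  K <- object@kinship
  if (length(K)) {
    if (nrow(K) != ncol(K)) msg <- c(msg, "kinship must be square")
    else if (max(abs(K - t(K))) > 1e-8) msg <- c(msg, "kinship must be symmetric")
  }
  if (is.null(msg)) TRUE else msg
})

#' Per-variant association scan result
#'
#' @slot table data.frame with one row per variant: \code{variant},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{maf},
#'   \code{beta} (trait units per ALT allele copy), \code{se},
#'   \code{minusLog10P} and \code{tested} (FALSE for monomorphic or
#'   collinear variants, whose statistics are NA).
#' @slot model "glm" or "mlm".
#' @slot nUsed number of accessions entering the fit.
#' @export
setClass("AssociationResult",
  representation(
    table = "data.frame",
    model = "character",
    nUsed = "integer"
  )
)

setValidity("AssociationResult", function(object) {
  tb <- object@table
  need <- c("variant", "chrom", "pos", "ref", "alt", "maf", "beta", "se",
            "minusLog10P", "tested")
  if (!all(need %in% colnames(tb)))
    return(paste("table must contain columns:", paste(need, collapse = ", ")))
  lp <- tb$minusLog10P[tb$tested]
  if (length(lp) && any(!is.finite(lp) | lp < 0))
    return("minusLog10P must be finite and >= 0 for tested variants")
  TRUE
})

#' Conditional-permutation genome-wide threshold
#'
#' @slot threshold genome-wide significance cutoff on the -log10(p) scale.
#' @slot maxima per-permutation genome-wide maximum -log10(p) statistics.
#' @slot percentile percentile of the maxima used (default 95).
#' @slot nPerm number of permutations.
#' @slot prefilter -log10(p) cutoff that pre-selected the rescanned variants.
#' @slot seed RNG seed used for the permutations.
#' @slot usedFallback TRUE when the prefiltered set was empty and all
#'   variants were rescanned instead.
#' @export
setClass("ThresholdResult",
  representation(
    threshold = "numeric",
    maxima = "numeric",
    percentile = "numeric",
    nPerm = "integer",
    prefilter = "numeric",
    seed = "integer",
    usedFallback = "logical"
  )
)

setValidity("ThresholdResult", function(object) {
  if (length(object@maxima) != object@nPerm)
    return("maxima must have length nPerm")
  if (any(!is.finite(object@maxima)))
    return("maxima must be finite")
  k <- max(1L, floor(object@nPerm * (1 - object@percentile / 100)))
  thr <- sort(object@maxima, decreasing = TRUE)[k]
  if (abs(thr - object@threshold) > 1e-9)
    return("threshold must equal the stated percentile of the stored maxima")
  TRUE
})

#' Gene-level haplotype table
#'
#' Haplotypes are the ordered ref/alt combinations an accession carries at a
#' gene's defining variants (non-synonymous / large-effect ORF variants and
#' promoter variants). Accessions with a missing or heterozygous call at any
#' defining variant are excluded and counted.
#'
#' @slot geneId gene identifier.
#' @slot variantIds defining variants, genome order.
#' @slot haplotypes named character vector, accession -> haplotype string
#'   over \{"R","A"\} (ref/alt at each defining variant).
#' @slot classes data.frame: \code{haplotype}, \code{count}, \code{freq},
#'   \code{major} (frequency >= the major-haplotype threshold).
#' @slot nExcluded accessions dropped for missing/heterozygous calls.
#' @export
setClass("HaplotypeTable",
  representation(
    geneId = "character",
    variantIds = "character",
    haplotypes = "character",
    classes = "data.frame",
    nExcluded = "integer"
  )
)

setValidity("HaplotypeTable", function(object) {
  if (nrow(object@classes) &&
      sum(object@classes$count) != length(object@haplotypes))
    return("class counts must sum to included accessions")
  TRUE
})

#' Synthetic-panel simulation configuration
#'
#' All tunable knobs of the synthetic two-subpopulation panel generator.
#' See \code{\link{simulationConfig}} for defaults and units.
#'
#' @slot nAccessionsPerSubpop accessions per cultivated subpopulation.
#' @slot nWild wild-outgroup accessions.
#' @slot nChromosomes,chromLengthBp genome shape.
#' @slot nVariants total variant count (SNPs plus a small InDel fraction).
#' @slot ldBlockBp width of the LD blocks within which haplotypes are shared.
#' @slot nGenes annotated gene models placed on the genome.
#' @slot nCausalGenes genes carrying planted trait alleles.
#' @slot causalEffectSd nominal additive effect per allele copy, trait SD units.
#' @slot traitH2 narrow-sense heritability targeted by the noise scaling.
#' @slot structureShiftSd subpopulation trait shift, trait SD units.
#' @slot uplandPyramidingBoost increment to the trait-increasing allele
#'   frequency in the upland sub-branch, in [0, 0.5].
#' @slot structureDiffFraction fraction of variants with divergent
#'   subpopulation allele frequencies.
#' @slot mafRange ancestral allele-frequency range (low < high).
#' @slot missingRate,residualHetRate missing-call and residual-heterozygosity
#'   rates.
#' @slot indelFraction fraction of variants simulated as small InDels.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
  representation(
    nAccessionsPerSubpop = "integer",
    nWild = "integer",
    nChromosomes = "integer",
    chromLengthBp = "integer",
    nVariants = "integer",
    ldBlockBp = "integer",
    nGenes = "integer",
    nCausalGenes = "integer",
    causalEffectSd = "numeric",
    traitH2 = "numeric",
    structureShiftSd = "numeric",
    uplandPyramidingBoost = "numeric",
    structureDiffFraction = "numeric",
    mafRange = "numeric",
    missingRate = "numeric",
    residualHetRate = "numeric",
    indelFraction = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  cnt <- c(nAccessionsPerSubpop = object@nAccessionsPerSubpop,
           nWild = object@nWild,
           nChromosomes = object@nChromosomes,
           chromLengthBp = object@chromLengthBp,
           nVariants = object@nVariants,
           ldBlockBp = object@ldBlockBp,
           nGenes = object@nGenes,
           nCausalGenes = object@nCausalGenes)
  if (any(cnt <= 0)) msg <- c(msg, "counts and lengths must be positive")
  fr <- c(object@traitH2, object@uplandPyramidingBoost,
          object@structureDiffFraction, object@missingRate,
          object@residualHetRate, object@indelFraction, object@mafRange)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  if (object@uplandPyramidingBoost > 0.5)
    msg <- c(msg, "uplandPyramidingBoost must lie in [0, 0.5]")
  if (length(object@mafRange) != 2 || object@mafRange[1] >= object@mafRange[2])
    msg <- c(msg, "mafRange must be (low, high) with low < high")
  if (object@nVariants < 10 * object@nChromosomes)
    msg <- c(msg, "need at least 10 variants per chromosome")
  if (is.null(msg)) TRUE else msg
})

#' Planted ground truth of a synthetic panel
#'
#' @slot causalGenes ids of genes carrying planted trait variants.
#' @slot causalVariants ids of the planted variants.
#' @slot increasingAllele named character ("ref" or "alt") giving the
#'   trait-increasing allele per causal variant.
#' @slot effects named numeric, nominal additive effect per copy of the
#'   trait-increasing allele (trait SD units, always nonzero).
#' @slot effectScale single multiplier applied to all effects so that the
#'   genetic variance fraction hits the configured heritability (0 when
#'   traitH2 = 0); realised effects are \code{effects * effectScale}.
#' @slot groups data.frame: \code{accession}, \code{subpop}
#'   (indica/japonica/wild), \code{ecotype} (lowland/upland/wild).
#' @export
setClass("PlantedTruth",
  representation(
    causalGenes = "character",
    causalVariants = "character",
    increasingAllele = "character",
    effects = "numeric",
    effectScale = "numeric",
    groups = "data.frame"
  )
)

setValidity("PlantedTruth", function(object) {
  if (!identical(names(object@increasingAllele), object@causalVariants))
    return("increasingAllele must be named by causalVariants")
  if (any(object@effects == 0))
    return("planted effects must be nonzero")
  TRUE
})
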