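#' Read a VCF file into a GenotypeMatrix
#'
#' Reads GT fields from a VCF v4.2 file. Only biallelic records are kept
#' (multiallelic records are skipped with a message). Dosages count ALT
#' allele copies; half calls and \code{./.} become missing.
#'
#' @param path VCF file (plain or bgzipped).
#' @param region optional \link[GenomicRanges]{GRanges} restricting the
#'   variants kept (overlap filter applied after reading).
#' @return a \linkS4class{GenotypeMatrix}.
#' @importFrom VariantAnnotation readVcf geno ref alt
#' @export
readGenotypeVcf <- function(path, region = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  nAlt <- lengths(VariantAnnotation::alt(vcf))
  if (any(nAlt != 1)) {
    message(sum(nAlt != 1), " multiallelic record(s) skipped")
    vcf <- vcf[nAlt == 1]
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  refA <- as.character(VariantAnnotation::ref(vcf))
  altA <- as.character(unlist(VariantAnnotation::alt(vcf)))
  gr <- GRanges(seqnames(rr), IRanges(GenomicRanges::start(rr), width = 1L),
                seqinfo = GenomeInfoDb::seqinfo(rr))
  names(gr) <- names(rr)
  mcols(gr)$ref <- refA
  mcols(gr)$alt <- altA
  mcols(gr)$vclass <- ifelse(nchar(refA) == nchar(altA) & nchar(refA) == 1L,
                             "SNP", "InDel")
  gt <- VariantAnnotation::geno(vcf)$GT
  d <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  d[gt %in% c("0/0", "0|0")] <- 0
  d[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  d[gt %in% c("1/1", "1|1")] <- 2
  g <- GenotypeMatrix(d, gr, colnames(gt))
  if (!is.null(region)) {
    keep <- IRanges::overlapsAny(variantRanges(g), region)
    g <- g[which(keep), ]
  }
  g
}

#' Write a GenotypeMatrix as VCF v4.2
#'
#' Emits one sample column per accession with a GT field; dosage 0/1/2
#' becomes \code{0/0}, \code{0/1}, \code{1/1} and missing becomes
#' \code{./.}.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param path output file (plain text is written).
#' @return \code{path}, invisibly.
#' @export
writeGenotypeVcf <- function(g, path) {
  v <- variantRanges(g)
  d <- dosage(g)
  gt <- matrix(".", nrow(d), ncol(d), dimnames = dimnames(d))
  gt[] <- c("0/0", "0/1", "1/1")[d + 1L]
  gt[is.na(d)] <- "./."
  sl <- GenomeInfoDb::seqlengths(v)
  contigs <- if (all(is.na(sl)))
    sprintf("##contig=<ID=%s>", GenomeInfoDb::seqlevels(v))
  else sprintf("##contig=<ID=%s,length=%d>", names(sl), sl)
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    contigs,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", accessions(g)), collapse = "\t"))
  body <- paste(as.character(seqnames(v)), GenomicRanges::start(v), names(v),
                mcols(v)$ref, mcols(v)$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  if (!nrow(d)) body <- character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Build a GeneModelSet, deriving strand-aware promoters
#'
#' The promoter of a gene is the 2000 bp upstream of the strand-aware
#' transcription start (gene start on +, gene end on -), truncated at the
#' chromosome edge when sequence lengths are known.
#'
#' @param genes named \link[GenomicRanges]{GRanges} of gene spans with strand.
#' @param cds \link[GenomicRanges]{GRangesList} of CDS segments, same names.
#' @param promoterBp promoter length upstream of the TSS (default 2000).
#' @return a \linkS4class{GeneModelSet}.
#' @export
geneModelSet <- function(genes, cds, promoterBp = 2000L) {
  plus <- as.character(strand(genes)) != "-"
  pStart <- ifelse(plus, GenomicRanges::start(genes) - promoterBp,
                   GenomicRanges::end(genes) + 1L)
  pEnd <- ifelse(plus, GenomicRanges::start(genes) - 1L,
                 GenomicRanges::end(genes) + promoterBp)
  pStart <- pmax(pStart, 1L)
  sl <- GenomeInfoDb::seqlengths(genes)[as.character(seqnames(genes))]
  if (!all(is.na(sl))) pEnd <- pmin(pEnd, ifelse(is.na(sl), pEnd, sl))
  prom <- GRanges(seqnames(genes), IRanges(pStart, pEnd),
                  strand = strand(genes),
                  seqinfo = GenomeInfoDb::seqinfo(genes))
  names(prom) <- names(genes)
  new("GeneModelSet", genes = genes, cds = cds, promoters = prom)
}

#' @rdname GeneModelSet-class
#' @export
setMethod("geneRanges", "GeneModelSet", function(x) x@genes)

#' @rdname GeneModelSet-class
#' @export
setMethod("cdsRanges", "GeneModelSet", function(x) x@cds)

#' @rdname GeneModelSet-class
#' @export
setMethod("promoterRanges", "GeneModelSet", function(x) x@promoters)

setMethod("show", "GeneModelSet", function(object) {
  cat(sprintf("GeneModelSet: %d genes, %d CDS segments\n",
              length(object@genes), sum(lengths(object@cds))))
})

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and CDS features (one transcript per gene).
#'
#' @param gm a \linkS4class{GeneModelSet}.
#' @param path output GFF3 file.
#' @return \code{path}, invisibly.
#' @importFrom rtracklayer export
#' @export
writeGeneModels <- function(gm, path) {
  genes <- gm@genes
  gid <- names(genes)
  tid <- paste0(gid, ".t1")
  feat <- c(
    GRanges(seqnames(genes), IRanges::ranges(genes), strand = strand(genes),
            type = "gene", ID = gid, Parent = NA_character_),
    GRanges(seqnames(genes), IRanges::ranges(genes), strand = strand(genes),
            type = "mRNA", ID = tid, Parent = gid))
  mcols(feat)$phase <- NA_integer_
  cdsAll <- unlist(gm@cds, use.names = FALSE)
  cdsGene <- rep(names(gm@cds), lengths(gm@cds))
  if (length(cdsAll)) {
    phase <- integer(length(cdsAll))
    for (gene1 in unique(cdsGene)) {
      sel <- which(cdsGene == gene1)
      minus <- as.character(strand(genes)[match(gene1, gid)]) == "-"
      ord <- sel[order(GenomicRanges::start(cdsAll)[sel],
                       decreasing = minus)]
      cum <- c(0L, cumsum(GenomicRanges::width(cdsAll)[ord]))
      phase[ord] <- (3L - cum[-length(cum)] %% 3L) %% 3L
    }
    cdsFeat <- GRanges(seqnames(cdsAll), IRanges::ranges(cdsAll),
                       strand = strand(genes)[match(cdsGene, gid)],
                       type = "CDS", ID = NA_character_,
                       Parent = paste0(cdsGene, ".t1"))
    mcols(cdsFeat)$phase <- phase
    feat <- c(feat, cdsFeat)
  }
  feat <- feat[order(as.character(seqnames(feat)), GenomicRanges::start(feat))]
  mcols(feat)$type <- factor(mcols(feat)$type, c("gene", "mRNA", "CDS"))
  rtracklayer::export(feat, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects gene/mRNA/CDS features with ID/Parent attributes (one transcript
#' per gene); promoters are rebuilt strand-aware.
#'
#' @param path GFF3 file.
#' @param promoterBp promoter length (default 2000).
#' @return a \linkS4class{GeneModelSet}.
#' @importFrom rtracklayer import
#' @export
readGeneModels <- function(path, promoterBp = 2000L) {
  gff <- rtracklayer::import(path, format = "gff3")
  genes <- gff[gff$type == "gene"]
  names(genes) <- genes$ID
  mrna <- gff[gff$type == "mRNA"]
  tx2gene <- structure(as.character(unlist(mrna$Parent)), names = mrna$ID)
  cds <- gff[gff$type == "CDS"]
  cdsGene <- tx2gene[as.character(unlist(cds$Parent))]
  mcols(cds) <- NULL
  cdsList <- S4Vectors::split(cds, factor(cdsGene, levels = names(genes)))
  genes <- GRanges(seqnames(genes), IRanges::ranges(genes),
                   strand = strand(genes), seqinfo = GenomeInfoDb::seqinfo(gff),
                   ID = NULL)
  names(genes) <- names(cdsList)
  geneModelSet(genes, cdsList, promoterBp = promoterBp)
}

#' Read / write the phenotype table
#'
#' Tab-separated, one row per accession: \code{accession}, trait columns
#' (e.g. \code{RL} root length in cm, \code{RT} root thickness in mm),
#' \code{subpop} and \code{ecotype} labels.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readPhenotypeTable <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (anyDuplicated(ph$accession))
    stop("phenotype table must have one row per accession")
  ph
}

#' @rdname readPhenotypeTable
#' @param pheno data.frame as returned by \code{\link{simulatePanel}}.
#' @export
writePhenotypeTable <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the expression matrix
#'
#' The RPKM matrix is a TSV with gene ids in the first column and one column
#' per sample; sample metadata (\code{sample}, \code{variety}, \code{tissue},
#' \code{group}, \code{replicate}) travels in a second TSV. In memory the
#' pair is a \link[SummarizedExperiment]{SummarizedExperiment} with assay
#' \code{rpkm}.
#'
#' @param matrixPath,metaPath TSV files.
#' @return a SummarizedExperiment.
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @export
readExpression <- function(matrixPath, metaPath) {
  m <- utils::read.delim(matrixPath, row.names = 1, check.names = FALSE)
  meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE)
  stopifnot(identical(colnames(m), meta$sample),
            all(c("tissue", "group") %in% colnames(meta)))
  SummarizedExperiment(assays = list(rpkm = as.matrix(m)),
                       colData = DataFrame(meta, row.names = meta$sample))
}

#' @rdname readExpression
#' @param se SummarizedExperiment with assay \code{rpkm}.
#' @export
writeExpression <- function(se, matrixPath, metaPath) {
  m <- SummarizedExperiment::assay(se, "rpkm")
  out <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(out, matrixPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(SummarizedExperiment::colData(se)),
                     metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrixPath)
}

#' Read / write linkage-mapping QTL intervals
#'
#' TSV with columns \code{chrom}, \code{start}, \code{end} (1-based
#' inclusive), \code{trait}, \code{parent1}, \code{parent2}. BED-style
#' 0-based half-open input can be converted with \code{bed = TRUE}.
#'
#' @param path TSV file.
#' @param bed if TRUE, treat start as 0-based half-open and convert.
#' @return data.frame of intervals.
#' @export
readLinkageQTLs <- function(path, bed = FALSE) {
  lk <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (bed) lk$start <- lk$start + 1L
  stopifnot(all(lk$start <= lk$end))
  lk
}

#' @rdname readLinkageQTLs
#' @param linkage data.frame of intervals.
#' @export
writeLinkageQTLs <- function(linkage, path) {
  utils::write.table(linkage, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a whole simulated panel to a directory
#'
#' Serializes genotypes (VCF), reference (FASTA), gene models (GFF3),
#' phenotypes, expression and linkage QTLs (TSV) under \code{dir}.
#'
#' @param panel list returned by \code{\link{simulatePanel}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writePanel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenotypeVcf(panel$genotypes, file.path(dir, "genotypes.vcf"))
  Biostrings::writeXStringSet(panel$reference, file.path(dir, "reference.fa"))
  writeGeneModels(panel$genes, file.path(dir, "genes.gff3"))
  writePhenotypeTable(panel$phenotypes, file.path(dir, "phenotypes.tsv"))
  writeExpression(panel$expression, file.path(dir, "rpkm.tsv"),
                  file.path(dir, "rpkm_samples.tsv"))
  writeLinkageQTLs(panel$linkage, file.path(dir, "linkage_qtls.tsv"))
  invisible(dir)
}

#' @rdname writePanel
#' @return \code{readPanel}: list with elements \code{genotypes},
#'   \code{reference}, \code{genes}, \code{phenotypes}, \code{expression},
#'   \code{linkage}.
#' @export
readPanel <- function(dir) {
  list(
    genotypes = readGenotypeVcf(file.path(dir, "genotypes.vcf")),
    reference = Biostrings::readDNAStringSet(file.path(dir, "reference.fa")),
    genes = readGeneModels(file.path(dir, "genes.gff3")),
    phenotypes = readPhenotypeTable(file.path(dir, "phenotypes.tsv")),
    expression = readExpression(file.path(dir, "rpkm.tsv"),
                                file.path(dir, "rpkm_samples.tsv")),
    linkage = readLinkageQTLs(file.path(dir, "linkage_qtls.tsv"))
  )
}
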