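#' Call QTL intervals from clustered significant variants
#'
#' Significant variants (-log10(p) >= threshold) are sorted along the genome
#' and chained while the gap between adjacent significant variants is at
#' most \code{windowBp} (single-linkage on gaps); chains with at least
#' \code{minSnps} members become QTL intervals. The defaults encode the
#' usual resequencing-panel rule: at least 3 clustered significant SNPs with
#' adjacent distances <= 170 kb (the LD decay scale of rice diversity
#' panels). The QTL span is the min..max member position, the peak is the
#' member with the largest -log10(p). Output is deterministic and invariant
#' to input variant order.
#'
#' @param res an \linkS4class{AssociationResult}.
#' @param threshold -log10(p) significance cutoff (typically from
#'   \code{\link{conditionalThreshold}}).
#' @param windowBp maximum gap between adjacent significant variants
#'   (default 170000).
#' @param minSnps minimum clustered significant variants (default 3).
#' @param population optional tag recorded on each interval (e.g. "whole",
#'   "indica").
#' @param trait optional trait tag.
#' @return \link[GenomicRanges]{GRanges} of QTL intervals, named qtl1...,
#'   with metadata columns \code{nSnps}, \code{peakVariant}, \code{peakPos},
#'   \code{peakLogP}, \code{members} (CharacterList), \code{population},
#'   \code{trait}. Empty when nothing clusters.
#' @export
callQTLs <- function(res, threshold, windowBp = 170000L, minSnps = 3L,
                     population = "whole", trait = NA_character_) {
  tb <- res@table
  sig <- tb[tb$tested & tb$minusLog10P >= threshold, , drop = FALSE]
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  empty <- GRanges()
  mcols(empty) <- DataFrame(nSnps = integer(0), peakVariant = character(0),
                            peakPos = integer(0), peakLogP = numeric(0),
                            members = IRanges::CharacterList(),
                            population = character(0), trait = character(0))
  if (!nrow(sig)) return(empty)
  newChain <- c(TRUE, sig$chrom[-1] != sig$chrom[-nrow(sig)] |
                  diff(sig$pos) > windowBp)
  chain <- cumsum(newChain)
  rows <- list(); members <- list()
  for (cid in unique(chain)) {
    mem <- sig[chain == cid, , drop = FALSE]
    if (nrow(mem) < minSnps) next
    peak <- which.max(mem$minusLog10P)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = mem$chrom[1], start = min(mem$pos), end = max(mem$pos),
      nSnps = nrow(mem), peakVariant = mem$variant[peak],
      peakPos = mem$pos[peak], peakLogP = mem$minusLog10P[peak],
      stringsAsFactors = FALSE)
    members[[length(members) + 1L]] <- mem$variant
  }
  if (!length(rows)) return(empty)
  tab <- do.call(rbind, rows)
  qtls <- GRanges(tab$chrom, IRanges(tab$start, tab$end))
  mcols(qtls) <- DataFrame(
    nSnps = tab$nSnps, peakVariant = tab$peakVariant, peakPos = tab$peakPos,
    peakLogP = tab$peakLogP, members = IRanges::CharacterList(members),
    population = population, trait = trait)
  names(qtls) <- paste0("qtl", seq_along(qtls))
  qtls
}

#' Pair QTL intervals across populations
#'
#' All interval pairs whose spans intersect after symmetric expansion by
#' \code{slackBp} are reported, classified "identical" (spans intersect
#' without slack) or "nearby" (intersect only with slack; the gap distance
#' is reported). Intervals with no partner appear as "unique" rows with an
#' NA partner. Interpretation of identical-vs-near is left to the user; no
#' merging is performed.
#'
#' @param a,b GRanges of QTL intervals (as from \code{\link{callQTLs}}),
#'   same trait.
#' @param slackBp symmetric expansion before testing intersection
#'   (default 0).
#' @return data.frame: \code{qtlA}, \code{qtlB}, \code{class},
#'   \code{distanceBp} (0 for overlapping pairs).
#' @export
overlapQTLs <- function(a, b, slackBp = 0L) {
  rows <- list()
  pairedA <- logical(length(a)); pairedB <- logical(length(b))
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (as.character(seqnames(a)[i]) != as.character(seqnames(b)[j])) next
    gap <- max(GenomicRanges::start(a)[i], GenomicRanges::start(b)[j]) -
      min(GenomicRanges::end(a)[i], GenomicRanges::end(b)[j])
    if (gap <= slackBp) {
      rows[[length(rows) + 1L]] <- data.frame(
        qtlA = names(a)[i], qtlB = names(b)[j],
        class = if (gap <= 0) "identical" else "nearby",
        distanceBp = max(0L, gap), stringsAsFactors = FALSE)
      pairedA[i] <- TRUE; pairedB[j] <- TRUE
    }
  }
  for (i in which(!pairedA))
    rows[[length(rows) + 1L]] <- data.frame(qtlA = names(a)[i], qtlB = NA,
                                            class = "unique", distanceBp = NA,
                                            stringsAsFactors = FALSE)
  for (j in which(!pairedB))
    rows[[length(rows) + 1L]] <- data.frame(qtlA = NA, qtlB = names(b)[j],
                                            class = "unique", distanceBp = NA,
                                            stringsAsFactors = FALSE)
  if (!length(rows))
    return(data.frame(qtlA = character(0), qtlB = character(0),
                      class = character(0), distanceBp = numeric(0)))
  do.call(rbind, rows)
}

#' Filter significant variants through linkage-mapping intervals
#'
#' Keeps the significant variants that (i) lie inside the intersection of a
#' GWAS QTL with a linkage-mapping interval and (ii) show a non-missing
#' dosage difference between the two parents of the linkage cross. Variants
#' with a missing parental call are dropped and counted.
#'
#' @param qtls GRanges from \code{\link{callQTLs}}.
#' @param linkage data.frame of linkage intervals (\code{chrom},
#'   \code{start}, \code{end}, \code{trait}, \code{parent1}, \code{parent2}).
#' @param g the panel \linkS4class{GenotypeMatrix} (parents must be present).
#' @param sigVariants character ids of significant variants to consider
#'   (defaults to all QTL members).
#' @return data.frame: \code{variant}, \code{chrom}, \code{pos}, \code{qtl},
#'   \code{linkageRow}; attribute \code{nMissingParent} counts variants
#'   dropped for missing parental calls.
#' @export
intersectLinkage <- function(qtls, linkage, g, sigVariants = NULL) {
  parents <- unique(c(linkage$parent1, linkage$parent2))
  absent <- setdiff(parents, accessions(g))
  if (length(absent))
    stop("parent accession(s) absent from genotypes: ",
         paste(absent, collapse = ", "))
  if (is.null(sigVariants))
    sigVariants <- unique(unlist(mcols(qtls)$members))
  v <- variantRanges(g)
  sigVariants <- intersect(sigVariants, names(v))
  vr <- v[sigVariants]
  rows <- list(); nMissing <- 0L
  for (li in seq_len(nrow(linkage))) {
    for (qi in seq_along(qtls)) {
      if (as.character(seqnames(qtls)[qi]) != linkage$chrom[li]) next
      is <- max(GenomicRanges::start(qtls)[qi], linkage$start[li])
      ie <- min(GenomicRanges::end(qtls)[qi], linkage$end[li])
      if (is > ie) next
      inBoth <- as.character(seqnames(vr)) == linkage$chrom[li] &
        GenomicRanges::start(vr) >= is & GenomicRanges::start(vr) <= ie
      for (k in which(inBoth)) {
        d1 <- dosage(g)[sigVariants[k], linkage$parent1[li]]
        d2 <- dosage(g)[sigVariants[k], linkage$parent2[li]]
        if (is.na(d1) || is.na(d2)) { nMissing <- nMissing + 1L; next }
        if (d1 == d2) next
        rows[[length(rows) + 1L]] <- data.frame(
          variant = sigVariants[k],
          chrom = as.character(seqnames(vr)[k]),
          pos = GenomicRanges::start(vr)[k],
          qtl = names(qtls)[qi], linkageRow = li,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(variant = character(0), chrom = character(0),
               pos = integer(0), qtl = character(0), linkageRow = integer(0))
  if (nMissing) message(nMissing, " variant-parent pair(s) dropped for missing calls")
  attr(out, "nMissingParent") <- nMissing
  out
}
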