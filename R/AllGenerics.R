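#' @rdname GenotypeMatrix-class
#' @param object,x a \linkS4class{GenotypeMatrix}.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("variantRanges", function(x) standardGeneric("variantRanges"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("maf", function(x) standardGeneric("maf"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("missingRate", function(x) standardGeneric("missingRate"))

#' @rdname StructureModel-class
#' @param x a \linkS4class{StructureModel}.
#' @export
setGeneric("pcScores", function(x) standardGeneric("pcScores"))

#' @rdname StructureModel-class
#' @export
setGeneric("kinship", function(x) standardGeneric("kinship"))

#' @rdname AssociationResult-class
#' @param x object to convert.
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))

#' @rdname ThresholdResult-class
#' @param x a \linkS4class{ThresholdResult}.
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))

#' @rdname GeneModelSet-class
#' @param x a \linkS4class{GeneModelSet}.
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("cdsRanges", function(x) standardGeneric("cdsRanges"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("promoterRanges", function(x) standardGeneric("promoterRanges"))
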