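#' @rdname MethylomeSample-class
#' @param object a `MethylomeSample`.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname MethylomeSample-class
#' @export
setGeneric("sampleGroup", function(object) standardGeneric("sampleGroup"))

#' @rdname GeneModels-class
#' @param object a `GeneModels`.
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname GeneModels-class
#' @export
setGeneric("geneRanges", function(object) standardGeneric("geneRanges"))

#' @rdname GeneModels-class
#' @export
setGeneric("exonRanges", function(object) standardGeneric("exonRanges"))

#' @rdname GeneRegionIndex-class
#' @param object a `GeneRegionIndex`.
#' @export
setGeneric("promoterRanges", function(object) standardGeneric("promoterRanges"))

#' @rdname GeneRegionIndex-class
#' @export
setGeneric("geneBodyRanges", function(object) standardGeneric("geneBodyRanges"))
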