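#' @rdname transcriptIds
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @rdname geneIds
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname splicedLengths
#' @export
setGeneric("splicedLengths", function(x) standardGeneric("splicedLengths"))

#' @rdname exonCounts
#' @export
setGeneric("exonCounts", function(x) standardGeneric("exonCounts"))

#' @rdname transcriptSpans
#' @export
setGeneric("transcriptSpans", function(x) standardGeneric("transcriptSpans"))

#' @rdname transcriptExons
#' @export
setGeneric("transcriptExons", function(x) standardGeneric("transcriptExons"))

#' @rdname spliceSequences
#' @export
setGeneric("spliceSequences", function(x) standardGeneric("spliceSequences"))

#' @rdname spliceSequences
#' @export
setGeneric("spliceSequences<-", function(x, value) standardGeneric("spliceSequences<-"))

#' @rdname geneSpans
#' @export
setGeneric("geneSpans", function(x) standardGeneric("geneSpans"))

#' @rdname geneExons
#' @export
setGeneric("geneExons", function(x) standardGeneric("geneExons"))

#' @rdname geneBiotypes
#' @export
setGeneric("geneBiotypes", function(x) standardGeneric("geneBiotypes"))

#' Fragments per kilobase of transcript per million mapped fragments
#'
#' `fpkm(count, length, librarySize)` evaluates the FPKM formula
#' `1e9 * count / (librarySize * length)` for numeric input;
#' `fpkm(x)` on an [ExpressionData-class] returns the derived FPKM
#' matrix (library size = column sum of counts).
#'
#' @param x Numeric count(s) or an [ExpressionData-class] object.
#' @param length Transcript length(s) in bp (> 0).
#' @param librarySize Total mapped fragments of the sample (> 0).
#' @return Numeric FPKM value(s), or the FPKM matrix.
#' @examples
#' fpkm(10, length = 1000, librarySize = 1e6)  # 10
#' @export
setGeneric("fpkm", function(x, length, librarySize) standardGeneric("fpkm"))

#' @rdname sampleGroups
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))
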