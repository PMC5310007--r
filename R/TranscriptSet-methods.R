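#' Construct a TranscriptSet
#'
#' @param exons Named [GenomicRanges::GRangesList], one element per
#'   transcript; exons are sorted on construction.
#' @param geneId Character vector of gene ids, one per transcript
#'   (recycled if length 1).
#' @param sequence Optional named [Biostrings::DNAStringSet] of spliced
#'   sequences.
#' @return A [TranscriptSet-class] object.
#' @examples
#' ex <- GenomicRanges::GRangesList(
#'     t1 = GenomicRanges::GRanges("chr1",
#'         IRanges::IRanges(c(100, 300), c(199, 399)), "+"))
#' ts <- TranscriptSet(ex, geneId = "g1")
#' splicedLengths(ts)
#' @export
TranscriptSet <- function(exons, geneId,
                          sequence = Biostrings::DNAStringSet()) {
    if (!is(exons, "GRangesList"))
        exons <- GRangesList(exons)
    exons <- endoapply_sort(exons)
    if (length(geneId) == 1L && length(exons) > 1L)
        geneId <- rep(geneId, length(exons))
    names(geneId) <- names(exons)
    new("TranscriptSet", exons = exons, geneId = geneId, sequence = sequence)
}

endoapply_sort <- function(grl) {
    # sort exons by start within each transcript without losing names
    S4Vectors::endoapply(grl, function(g) g[order(start(g))])
}

#' Transcript identifiers
#' @param x A [TranscriptSet-class].
#' @return Character vector of transcript ids.
#' @export
setMethod("transcriptIds", "TranscriptSet", function(x) names(x@exons))

#' Gene identifiers
#' @param x A [TranscriptSet-class] or [GeneAnnotation-class].
#' @return Character vector of gene ids (for a TranscriptSet, named by
#'   transcript id).
#' @export
setMethod("geneIds", "TranscriptSet", function(x) x@geneId)

#' Spliced transcript lengths
#' @param x A [TranscriptSet-class].
#' @return Integer vector of summed exon widths, named by transcript id.
#' @export
setMethod("splicedLengths", "TranscriptSet", function(x) {
    setNames(as.integer(sum(width(x@exons))), names(x@exons))
})

#' Exon counts per transcript
#' @param x A [TranscriptSet-class].
#' @return Integer vector named by transcript id.
#' @export
setMethod("exonCounts", "TranscriptSet", function(x) {
    setNames(S4Vectors::elementNROWS(x@exons), names(x@exons))
})

#' Genomic spans of transcripts
#' @param x A [TranscriptSet-class].
#' @return A [GenomicRanges::GRanges] of per-transcript spans (first
#'   exon start to last exon end) with `transcript_id` and `gene_id`
#'   metadata.
#' @export
setMethod("transcriptSpans", "TranscriptSet", function(x) {
    sp <- unlist(range(x@exons), use.names = FALSE)
    mcols(sp)$transcript_id <- names(x@exons)
    mcols(sp)$gene_id <- unname(x@geneId)
    names(sp) <- names(x@exons)
    sp
})

#' Exon structures
#' @param x A [TranscriptSet-class].
#' @return The underlying [GenomicRanges::GRangesList] of exons.
#' @export
setMethod("transcriptExons", "TranscriptSet", function(x) x@exons)

#' Spliced sequences
#'
#' Get or set the spliced sequences attached to a transcript set.
#' @param x A [TranscriptSet-class].
#' @param value A named [Biostrings::DNAStringSet].
#' @return A [Biostrings::DNAStringSet] (possibly empty).
#' @export
setMethod("spliceSequences", "TranscriptSet", function(x) x@sequence)

#' @rdname spliceSequences
#' @export
setReplaceMethod("spliceSequences", "TranscriptSet", function(x, value) {
    x@sequence <- value
    validObject(x)
    x
})

#' @describeIn TranscriptSet-class number of transcripts
#' @param x A TranscriptSet.
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@exons))

#' @describeIn TranscriptSet-class subset by index, id or logical
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = TRUE) {
    ex <- x@exons[i]
    seqs <- x@sequence
    if (length(seqs) > 0L)
        seqs <- seqs[names(seqs) %in% names(ex)]
    new("TranscriptSet", exons = ex, geneId = x@geneId[names(ex)],
        sequence = seqs)
})

setMethod("show", "TranscriptSet", function(object) {
    n <- length(object)
    cat("TranscriptSet with", n, "transcripts\n")
    if (n > 0L) {
        len <- splicedLengths(object)
        cat(sprintf("  spliced length: %d-%d bp (mean %.0f)\n",
                    min(len), max(len), mean(len)))
        cat(sprintf("  exons per transcript: %.2f (mean)\n",
                    mean(exonCounts(object))))
        cat(sprintf("  sequences attached: %d\n", length(object@sequence)))
    }
    invisible(NULL)
})

#' Construct a GeneAnnotation
#'
#' @param genes A [GenomicRanges::GRanges] of gene spans with `gene_id`
#'   and `biotype` metadata columns.
#' @param exons Named [GenomicRanges::GRangesList] of exon unions per
#'   gene.  Defaults to one exon covering each span.
#' @return A [GeneAnnotation-class] object.
#' @export
GeneAnnotation <- function(genes, exons = NULL) {
    if (is.null(exons)) {
        exons <- GRangesList(as.list(split(granges(genes),
            factor(mcols(genes)$gene_id, levels = mcols(genes)$gene_id))))
    }
    exons <- endoapply_sort(exons)
    new("GeneAnnotation", genes = genes, exons = exons)
}

#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneAnnotation", function(x) as.character(mcols(x@genes)$gene_id))

#' Gene spans
#' @param x A [GeneAnnotation-class].
#' @return [GenomicRanges::GRanges] of gene spans with metadata.
#' @export
setMethod("geneSpans", "GeneAnnotation", function(x) x@genes)

#' Per-gene exon unions
#' @param x A [GeneAnnotation-class].
#' @return Named [GenomicRanges::GRangesList].
#' @export
setMethod("geneExons", "GeneAnnotation", function(x) x@exons)

#' Gene biotypes
#' @param x A [GeneAnnotation-class].
#' @return Character vector named by gene id.
#' @export
setMethod("geneBiotypes", "GeneAnnotation", function(x) {
    setNames(as.character(mcols(x@genes)$biotype), geneIds(x))
})

#' @describeIn GeneAnnotation-class number of genes
#' @param x A GeneAnnotation.
#' @export
setMethod("length", "GeneAnnotation", function(x) length(x@genes))

setMethod("show", "GeneAnnotation", function(object) {
    bt <- table(geneBiotypes(object))
    cat("GeneAnnotation with", length(object), "genes (",
        paste(names(bt), as.integer(bt), collapse = ", "), ")\n")
    invisible(NULL)
})
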