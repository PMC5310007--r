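#' TranscriptSet: exon-structured transcript models
#'
#' A set of assembled transcript models on a genome.  Each transcript is
#' an ordered set of exons (a [GenomicRanges::GRangesList] element, all
#' exons on one chromosome and strand), carries the identifier of the
#' gene locus it was assembled from, and optionally its spliced
#' sequence.  This is the unit that enters lncRNA screening.
#'
#' Coordinates are 1-based inclusive throughout (the GRanges
#' convention); spliced length is the summed exon width.
#'
#' @slot exons A named [GenomicRanges::GRangesList], one element per
#'   transcript, exons sorted by start, non-overlapping.
#' @slot geneId Named character vector parallel to `exons` mapping
#'   transcript id to gene id.
#' @slot sequence A [Biostrings::DNAStringSet] of spliced sequences,
#'   named by transcript id.  May cover a subset of transcripts (or be
#'   empty); where present its width must equal the spliced length.
#'
#' @seealso [TranscriptSet()], [transcriptIds()], [splicedLengths()],
#'   [exonCounts()], [transcriptSpans()]
#' @export
setClass("TranscriptSet",
    slots = c(
        exons    = "GRangesList",
        geneId   = "character",
        sequence = "DNAStringSet"
    )
)

setValidity("TranscriptSet", function(object) {
    ex <- object@exons
    msg <- character()
    ids <- names(ex)
    if (length(ex) > 0L && (is.null(ids) || anyDuplicated(ids) || any(ids == "")))
        msg <- c(msg, "exons must be uniquely named by transcript_id")
    if (length(object@geneId) != length(ex))
        msg <- c(msg, "geneId must be parallel to exons")
    if (length(ex) > 0L && !identical(names(object@geneId), ids))
        msg <- c(msg, "names(geneId) must equal names(exons)")
    if (length(ex) > 0L) {
        st <- start(ex)
        en <- end(ex)
        unsorted <- any(vapply(st, is.unsorted, logical(1), strictly = FALSE))
        if (unsorted)
            msg <- c(msg, "exons must be sorted by start within each transcript")
        # non-overlap: next start must exceed previous end
        ovl <- any(mapply(function(s, e) {
            n <- length(s)
            n > 1L && any(s[-1L] <= e[-n])
        }, st, en))
        if (ovl)
            msg <- c(msg, "exons within a transcript must not overlap")
        nchrom <- vapply(ex, function(g)
            length(unique(as.character(seqnames(g)))), integer(1))
        nstr <- vapply(ex, function(g)
            length(unique(as.character(strand(g)))), integer(1))
        if (any(nchrom != 1L) || any(nstr != 1L))
            msg <- c(msg, "all exons of a transcript must share one chromosome and strand")
    }
    if (length(object@sequence) > 0L) {
        sid <- names(object@sequence)
        if (is.null(sid) || !all(sid %in% ids))
            msg <- c(msg, "sequence names must be transcript ids")
        else {
            sl <- sum(width(ex))[sid]
            if (any(Biostrings::width(object@sequence) != sl))
                msg <- c(msg, "sequence width must equal spliced length")
        }
    }
    if (length(msg)) msg else TRUE
})

#' GeneAnnotation: reference gene models
#'
#' Reference genes with span, strand, biotype and the union of their
#' exon intervals over isoforms.  This is the background against which
#' candidate lncRNAs are classified and cis targets are searched.
#'
#' @slot genes A [GenomicRanges::GRanges] of gene spans with metadata
#'   columns `gene_id` and `biotype` (`"protein_coding"` or `"other"`).
#' @slot exons A named [GenomicRanges::GRangesList] of per-gene exon
#'   unions, parallel to `genes`.
#'
#' @seealso [GeneAnnotation()], [geneIds()], [geneSpans()], [geneExons()]
#' @export
setClass("GeneAnnotation",
    slots = c(genes = "GRanges", exons = "GRangesList")
)

setValidity("GeneAnnotation", function(object) {
    g <- object@genes
    msg <- character()
    mc <- mcols(g)
    if (!all(c("gene_id", "biotype") %in% colnames(mc)))
        return("genes must carry gene_id and biotype metadata columns")
    if (anyDuplicated(mc$gene_id))
        msg <- c(msg, "gene_id values must be unique")
    if (!all(mc$biotype %in% c("protein_coding", "other")))
        msg <- c(msg, "biotype must be 'protein_coding' or 'other'")
    if (length(object@exons) != length(g) ||
        (length(g) > 0L && !identical(names(object@exons), as.character(mc$gene_id))))
        msg <- c(msg, "exons must be named by gene_id, parallel to genes")
    if (length(g) > 0L) {
        contained <- mapply(function(span_s, span_e, ex) {
            length(ex) == 0L || (min(start(ex)) >= span_s && max(end(ex)) <= span_e)
        }, start(g), end(g), as.list(object@exons))
        if (!all(contained))
            msg <- c(msg, "gene span must cover all its exons")
    }
    if (length(msg)) msg else TRUE
})

#' ExpressionData: counts, FPKM and a two-group design
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a
#' transcript-by-sample matrix of non-negative integer counts, per-row
#' transcript lengths (bp, `rowData(x)$length`), a two-level group
#' factor (`colData(x)$group`; the first level is the reference/control
#' group) and the derived FPKM assay.  FPKM is computed as
#' `1e9 * count / (librarySize * length)` with library size the column
#' sum of counts, so `fpkm == 0` exactly where `count == 0`.
#'
#' @seealso [ExpressionData()], [fpkm()], [sampleGroups()]
#' @export
setClass("ExpressionData", contains = "SummarizedExperiment")

setValidity("ExpressionData", function(object) {
    msg <- character()
    if (!all(c("counts", "fpkm") %in% assayNames(object)))
        return("assays 'counts' and 'fpkm' are required")
    cnt <- assay(object, "counts")
    if (any(cnt < 0) || any(cnt != round(cnt)))
        msg <- c(msg, "counts must be non-negative integers")
    if (!"length" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must carry transcript 'length'")
    else if (any(rowData(object)$length <= 0))
        msg <- c(msg, "transcript lengths must be positive")
    grp <- colData(object)$group
    if (is.null(grp) || !is.factor(grp) || nlevels(grp) != 2L)
        msg <- c(msg, "colData$group must be a two-level factor")
    else if (any(table(grp) == 0L))
        msg <- c(msg, "both groups must be non-empty")
    fp <- assay(object, "fpkm")
    if (any(fp < 0) || !identical(fp == 0, cnt == 0))
        msg <- c(msg, "fpkm must be >= 0 and zero exactly where counts are zero")
    if (length(msg)) msg else TRUE
})
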