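#' Construct an ExpressionData object
#'
#' Validates a transcript-by-sample count matrix against a two-group
#' design, attaches transcript lengths and derives the FPKM assay
#' (library size = column sum of counts).
#'
#' @param counts Integer matrix, transcripts x samples, with row and
#'   column names.
#' @param lengths Numeric vector of transcript lengths (bp), named by
#'   transcript id or parallel to `rownames(counts)`.
#' @param design A factor/character vector of group labels named by (or
#'   parallel to) the sample columns, with exactly two distinct groups.
#'   The first factor level is treated as the reference (control)
#'   group throughout.
#' @return An [ExpressionData-class] object with assays `counts` and
#'   `fpkm`.
#' @examples
#' cnt <- matrix(c(10L, 0L, 20L, 5L), 2,
#'     dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' ed <- ExpressionData(cnt, lengths = c(t1 = 1000, t2 = 500),
#'     design = c(s1 = "ctrl", s2 = "case"))
#' fpkm(ed)
#' @export
ExpressionData <- function(counts, lengths, design) {
    counts <- as.matrix(counts)
    if (length(counts) == 0L)
        stop("count matrix is empty")
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must have row (transcript) and column (sample) names")
    bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)
    if (nrow(bad) > 0L)
        stop(sprintf("invalid count at row '%s', column '%s': must be a non-negative integer",
                     rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]))
    storage.mode(counts) <- "integer"
    if (!is.null(names(lengths))) {
        missing <- setdiff(rownames(counts), names(lengths))
        if (length(missing))
            stop("no length for transcript(s): ",
                 paste(head(missing, 5L), collapse = ", "))
        lengths <- lengths[rownames(counts)]
    }
    if (any(lengths <= 0)) stop("transcript lengths must be positive")
    if (!is.null(names(design))) {
        missing <- setdiff(names(design), colnames(counts))
        if (length(missing))
            stop("design sample(s) missing from count matrix: ",
                 paste(missing, collapse = ", "))
        missing <- setdiff(colnames(counts), names(design))
        if (length(missing))
            stop("matrix sample(s) missing from design: ",
                 paste(missing, collapse = ", "))
        design <- design[colnames(counts)]
    }
    grp <- if (is.factor(design)) droplevels(design) else
        factor(design, levels = unique(design))
    if (nlevels(grp) != 2L)
        stop("design must define exactly two groups, got: ",
             paste(levels(grp), collapse = ", "))
    fp <- fpkmMatrix(counts, lengths)
    se <- SummarizedExperiment(
        assays = list(counts = counts, fpkm = fp),
        rowData = DataFrame(length = as.numeric(lengths),
                            row.names = rownames(counts)),
        colData = DataFrame(group = grp, row.names = colnames(counts)))
    new("ExpressionData", se)
}

fpkmMatrix <- function(counts, lengths) {
    libs <- colSums(counts)
    if (any(libs == 0))
        stop("sample(s) with zero total counts: ",
             paste(colnames(counts)[libs == 0], collapse = ", "))
    sweep(counts / lengths, 2L, libs, "/") * 1e9
}

#' @rdname fpkm
#' @export
setMethod("fpkm", "numeric", function(x, length, librarySize) {
    if (any(length <= 0)) stop("transcript length must be positive")
    if (any(librarySize <= 0)) stop("library size must be positive")
    1e9 * x / (librarySize * length)
})

#' @rdname fpkm
#' @export
setMethod("fpkm", "ExpressionData", function(x, length, librarySize) {
    assay(x, "fpkm")
})

#' Raw counts of an ExpressionData
#' @param object An [ExpressionData-class].
#' @return The integer count matrix.
#' @export
setMethod("counts", "ExpressionData", function(object) {
    assay(object, "counts")
})

#' Sample-to-group assignment
#' @param x An [ExpressionData-class].
#' @return Two-level factor named by sample; first level = reference
#'   (control) group.
#' @export
setMethod("sampleGroups", "ExpressionData", function(x) {
    setNames(colData(x)$group, colnames(x))
})

#' Transcript lengths stored in an ExpressionData
#' @param x An [ExpressionData-class].
#' @return Numeric vector named by transcript id.
#' @export
setMethod("splicedLengths", "ExpressionData", function(x) {
    setNames(rowData(x)$length, rownames(x))
})

setMethod("show", "ExpressionData", function(object) {
    grp <- sampleGroups(object)
    cat(sprintf("ExpressionData: %d transcripts x %d samples (%s)\n",
                nrow(object), ncol(object),
                paste(sprintf("%s n=%d", levels(grp), table(grp)),
                      collapse = " vs ")))
    invisible(NULL)
})
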