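# Standard-format IO: GTF (Ensembl/Cufflinks attribute dialect) read
# via rtracklayer with strict post-validation and written by a small
# deterministic formatter; FASTA via Biostrings (60-column wrap);
# counts/design/term-map/Ct TSVs with validation; truth/manifest JSON
# via jsonlite.

.GTF_CORE_ATTRS <- c("gene_id", "transcript_id")
.GTF_INTERNAL_COLS <- c("source", "type", "score", "phase")

#' Read a GTF file into transcripts and genes
#'
#' Parses exon records (other feature rows are ignored with a
#' message), groups them by `transcript_id` within `gene_id`, sorts
#' exons, and derives per-gene spans and exon unions.  Gene biotype is
#' taken from a `gene_biotype` (or `biotype`) attribute when present
#' (`"protein_coding"` kept as such, anything else becomes
#' `"other"`).  Unknown attributes are preserved on the exons and
#' round-trip through [writeGtf()].
#'
#' @param path Path to a tab-separated 9-column GTF file.
#' @return `list(genes = GeneAnnotation, transcripts =
#'   TranscriptSet)`.
#' @export
readGtf <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    gr <- rtracklayer::import(path, format = "gtf")
    isExon <- as.character(mcols(gr)$type) == "exon"
    nOther <- sum(!isExon)
    if (nOther > 0L)
        message(nOther, " non-exon feature row(s) ignored")
    gr <- gr[isExon]
    if (length(gr) == 0L) stop("no exon records in ", path)
    txid <- mcols(gr)$transcript_id
    if (is.null(txid) || anyNA(txid) || any(txid == ""))
        stop("parse error: exon record(s) without transcript_id attribute (",
             sum(is.na(txid) | txid == ""), " affected)")
    gid <- mcols(gr)$gene_id
    if (is.null(gid)) gid <- txid
    gid[is.na(gid)] <- txid[is.na(gid)]
    bt <- mcols(gr)$gene_biotype
    if (is.null(bt)) bt <- mcols(gr)$biotype
    txOrder <- unique(txid)
    exons <- S4Vectors::split(gr, factor(txid, levels = txOrder))
    geneOfTx <- setNames(gid[match(txOrder, txid)], txOrder)
    ts <- TranscriptSet(exons, geneId = geneOfTx)

    geneOrder <- unique(geneOfTx)
    spanList <- range(S4Vectors::split(granges(gr),
        factor(gid, levels = geneOrder)))
    multi <- S4Vectors::elementNROWS(spanList) != 1L
    if (any(multi))
        stop("gene(s) with exons on several chromosomes/strands: ",
             paste(head(geneOrder[multi], 5L), collapse = ", "))
    spans <- unlist(spanList, use.names = FALSE)
    biotype <- rep("other", length(geneOrder))
    if (!is.null(bt)) {
        btOfGene <- bt[match(geneOrder, gid)]
        biotype[!is.na(btOfGene) & btOfGene == "protein_coding"] <- "protein_coding"
    }
    mcols(spans)$gene_id <- geneOrder
    mcols(spans)$biotype <- biotype
    names(spans) <- geneOrder
    exUnion <- S4Vectors::endoapply(
        S4Vectors::split(granges(gr), factor(gid, levels = geneOrder)),
        reduce)
    genes <- GeneAnnotation(spans, exUnion)
    list(genes = genes, transcripts = ts)
}

.fmtAttr <- function(key, value) sprintf('%s "%s";', key, value)

#' Write a TranscriptSet as GTF
#'
#' Emits one `exon` row per exon in Cufflinks attribute dialect
#' (`key "value";` pairs), with `gene_id` and `transcript_id` first
#' and any extra exon metadata columns preserved as further
#' attributes.  Output is byte-deterministic for a given object.
#'
#' @param ts A [TranscriptSet-class].
#' @param path Output path.
#' @param source Value of the GTF source column.
#' @param geneAttrs Optional named character vector of per-gene
#'   attributes (e.g. `gene_biotype`), named by gene id.
#' @return `path`, invisibly.
#' @export
writeGtf <- function(ts, path, source = "caprilnc", geneAttrs = NULL) {
    ex <- transcriptExons(ts)
    flat <- unlist(ex, use.names = FALSE)
    txid <- rep(names(ex), S4Vectors::elementNROWS(ex))
    gid <- geneIds(ts)[txid]
    attrs <- paste0(.fmtAttr("gene_id", gid), " ",
                    .fmtAttr("transcript_id", txid))
    if (!is.null(geneAttrs) && length(geneAttrs) > 0L) {
        extra <- geneAttrs[gid]
        has <- !is.na(extra)
        attrs[has] <- paste0(attrs[has], " ",
                             .fmtAttr("gene_biotype", extra[has]))
    }
    mc <- mcols(flat)
    for (col in setdiff(colnames(mc), c(.GTF_CORE_ATTRS, .GTF_INTERNAL_COLS))) {
        v <- as.character(mc[[col]])
        has <- !is.na(v)
        attrs[has] <- paste0(attrs[has], " ", .fmtAttr(col, v[has]))
    }
    lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                     as.character(seqnames(flat)), source,
                     start(flat), end(flat),
                     as.character(strand(flat)), attrs)
    writeLines(lines, path)
    invisible(path)
}

#' Read spliced transcript sequences from FASTA
#'
#' @param path FASTA file path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readTranscriptFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    readDNAStringSet(path)
}

#' Write transcript sequences as FASTA (60-column wrap)
#'
#' @param seqs A named [Biostrings::DNAStringSet] (or a
#'   [TranscriptSet-class] with sequences attached).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTranscriptFasta <- function(seqs, path) {
    if (is(seqs, "TranscriptSet")) seqs <- spliceSequences(seqs)
    writeXStringSet(seqs, path, width = 60L)
    invisible(path)
}

#' Read a counts matrix and design into an ExpressionData
#'
#' The counts TSV has transcripts as rows (first column ids) and
#' samples as columns (header row); the design TSV has columns
#' `sample` and `group` mapping every sample column to one of two
#' groups.
#'
#' @param countsPath Path to the counts TSV.
#' @param designPath Path to the design TSV.
#' @param lengths Named numeric vector of transcript lengths (bp), or
#'   `NULL` to read a `length` column from the counts file.
#' @return An [ExpressionData-class].
#' @export
readCountsTsv <- function(countsPath, designPath, lengths = NULL) {
    df <- read.delim(countsPath, check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) == 0L || ncol(df) < 2L)
        stop("validation error: empty counts matrix in ", countsPath)
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
    if (is.null(lengths)) {
        if (!"length" %in% colnames(df))
            stop("no transcript lengths: supply `lengths` or a 'length' column")
        lengths <- setNames(as.numeric(df[["length"]]), ids)
        df <- df[, colnames(df) != "length", drop = FALSE]
    }
    for (j in seq_len(ncol(df))) {
        v <- suppressWarnings(as.numeric(df[[j]]))
        bad <- which(!is.finite(v) | v < 0 | v != round(v))
        if (length(bad))
            stop(sprintf("validation error: non-count value at row '%s', column '%s'",
                         ids[bad[1L]], colnames(df)[j]))
    }
    cnt <- as.matrix(df)
    rownames(cnt) <- ids
    des <- read.delim(designPath, stringsAsFactors = FALSE)
    if (!all(c("sample", "group") %in% colnames(des)))
        stop("design file must have columns 'sample' and 'group'")
    design <- setNames(des$group, des$sample)
    ExpressionData(cnt, lengths = lengths, design = design)
}

#' Write counts and design TSVs from an ExpressionData
#'
#' @param expr An [ExpressionData-class].
#' @param countsPath,designPath Output paths.
#' @param withLength Include the `length` column (default TRUE).
#' @return `countsPath`, invisibly.
#' @export
writeCountsTsv <- function(expr, countsPath, designPath = NULL,
                           withLength = TRUE) {
    cnt <- assay(expr, "counts")
    df <- data.frame(transcript_id = rownames(cnt), stringsAsFactors = FALSE)
    if (withLength) df$length <- rowData(expr)$length
    df <- cbind(df, as.data.frame(cnt))
    write.table(df, countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(designPath)) {
        grp <- sampleGroups(expr)
        write.table(data.frame(sample = names(grp),
                               group = as.character(grp)),
                    designPath, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(countsPath)
}

#' Read / write a two-column term-to-gene map
#'
#' TSV with columns `term_id` and `gene_id`, one membership per line.
#'
#' @param path File path.
#' @return `readTermMap`: a named list of gene-id vectors.
#' @export
readTermMap <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("term_id", "gene_id") %in% colnames(df)))
        stop("term map must have columns 'term_id' and 'gene_id'")
    split(df$gene_id, df$term_id)
}

#' @rdname readTermMap
#' @param termMap A named list of gene-id vectors.
#' @export
writeTermMap <- function(termMap, path) {
    df <- data.frame(term_id = rep(names(termMap), lengths(termMap)),
                     gene_id = unlist(termMap, use.names = FALSE))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write a qPCR Ct table TSV
#'
#' @param path File path.
#' @return `readCtTable`: a validated Ct data.frame.
#' @export
readCtTable <- function(path) {
    validateCtTable(read.delim(path, stringsAsFactors = FALSE,
                               check.names = FALSE))
}

#' @rdname readCtTable
#' @param ct A Ct table data.frame.
#' @export
writeCtTable <- function(ct, path) {
    write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write / read the ground-truth (or manifest) JSON
#'
#' @param x A list of vectors/data.frames.
#' @param path File path.
#' @return `readTruthJson`: the parsed list.
#' @export
writeTruthJson <- function(x, path) {
    write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
               dataframe = "columns", null = "null", na = "null")
    invisible(path)
}

#' @rdname writeTruthJson
#' @export
readTruthJson <- function(path) {
    read_json(path, simplifyVector = TRUE)
}
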