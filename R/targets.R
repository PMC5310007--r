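# Target-gene prediction for candidate lncRNAs: cis (protein-coding
# genes within 10 kb / 100 kb genomic windows of the lncRNA locus) and
# trans (expression Pearson correlation beyond +/-0.95 across all
# samples).

#' Cis target genes within genomic windows
#'
#' For each candidate lncRNA, finds every protein-coding gene whose
#' span lies within a window of the lncRNA span on the same chromosome
#' (either side, strand-agnostic).  Distance is the gap between spans
#' (0 for overlapping or abutting loci); window boundaries are
#' inclusive, and each pair is labelled with the smallest qualifying
#' window.
#'
#' @param lnc A [TranscriptSet-class] of candidate lncRNAs (or a
#'   [GenomicRanges::GRanges] of spans with `transcript_id` metadata).
#' @param genes A [GeneAnnotation-class].
#' @param windows Numeric vector of window half-widths in bp
#'   (default `c(10000, 100000)`, the 10 K / 100 K convention).
#' @return A data.frame with columns `lnc_id`, `gene_id`, `mode`
#'   (`"cis"`), `window` (smallest qualifying), `distance` (bp).
#' @export
cisTargets <- function(lnc, genes, windows = c(10000, 100000)) {
    windows <- sort(windows)
    spans <- if (is(lnc, "TranscriptSet")) transcriptSpans(lnc) else lnc
    coding <- geneSpans(genes)
    coding <- coding[mcols(coding)$biotype == "protein_coding"]
    empty <- data.frame(lnc_id = character(), gene_id = character(),
                        mode = character(), window = numeric(),
                        distance = numeric(), stringsAsFactors = FALSE)
    if (length(spans) == 0L || length(coding) == 0L) return(empty)
    hits <- findOverlaps(spans, coding, maxgap = max(windows),
                         ignore.strand = TRUE)
    if (length(hits) == 0L) return(empty)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    d <- distance(spans[qh], coding[sh], ignore.strand = TRUE)
    keep <- !is.na(d) & d <= max(windows)
    qh <- qh[keep]; sh <- sh[keep]; d <- d[keep]
    # smallest window w with d <= w:
    win <- vapply(d, function(x) windows[which(windows >= x)[1L]], numeric(1))
    out <- data.frame(lnc_id = mcols(spans)$transcript_id[qh],
                      gene_id = as.character(mcols(coding)$gene_id)[sh],
                      mode = "cis", window = win, distance = as.numeric(d),
                      stringsAsFactors = FALSE, row.names = NULL)
    out[order(out$lnc_id, out$distance, out$gene_id), , drop = FALSE]
}

#' Pearson product-moment correlation with domain validation
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The Pearson coefficient, or `NA` (with a warning) when
#'   either vector has zero variance.
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3L) stop("at least 3 paired samples are required")
    if (sd(x) == 0 || sd(y) == 0) {
        warning("zero variance: correlation undefined")
        return(NA_real_)
    }
    cor(x, y, method = "pearson")
}

#' Trans target genes by expression correlation
#'
#' Correlates the FPKM profile of every candidate lncRNA with every
#' protein-coding transcript across all samples (both groups pooled)
#' and keeps pairs with `r > threshold` or `r < -threshold` (strict
#' inequalities).  Rows with zero variance are skipped and counted in
#' a message.
#'
#' @param expr An [ExpressionData-class] covering all ids.
#' @param lncIds Character vector of candidate lncRNA transcript ids.
#' @param codingIds Character vector of protein-coding transcript ids.
#' @param threshold Absolute correlation cutoff, exclusive (default
#'   0.95).
#' @return A data.frame with columns `lnc_id`, `gene_id`, `mode`
#'   (`"trans"`), `r`.
#' @export
transTargets <- function(expr, lncIds, codingIds, threshold = 0.95) {
    if (ncol(expr) < 3L) stop("at least 3 samples are required")
    fp <- fpkm(expr)
    missing <- setdiff(c(lncIds, codingIds), rownames(fp))
    if (length(missing))
        stop("expression rows missing for: ",
             paste(head(missing, 10L), collapse = ", "))
    empty <- data.frame(lnc_id = character(), gene_id = character(),
                        mode = character(), r = numeric(),
                        stringsAsFactors = FALSE)
    if (length(lncIds) == 0L || length(codingIds) == 0L) return(empty)
    lncM <- fp[lncIds, , drop = FALSE]
    codM <- fp[codingIds, , drop = FALSE]
    sdL <- apply(lncM, 1L, sd)
    sdC <- apply(codM, 1L, sd)
    nSkip <- sum(sdL == 0) + sum(sdC == 0)
    if (nSkip > 0L)
        message(nSkip, " zero-variance row(s) skipped in trans correlation")
    lncM <- lncM[sdL > 0, , drop = FALSE]
    codM <- codM[sdC > 0, , drop = FALSE]
    if (nrow(lncM) == 0L || nrow(codM) == 0L) return(empty)
    r <- cor(t(lncM), t(codM), method = "pearson")
    hit <- which(r > threshold | r < -threshold, arr.ind = TRUE)
    if (nrow(hit) == 0L) return(empty)
    out <- data.frame(lnc_id = rownames(lncM)[hit[, 1L]],
                      gene_id = rownames(codM)[hit[, 2L]],
                      mode = "trans", r = r[hit],
                      stringsAsFactors = FALSE, row.names = NULL)
    out[order(out$lnc_id, out$gene_id), , drop = FALSE]
}

#' Merged per-lncRNA target report
#'
#' @param cis A data.frame from [cisTargets()].
#' @param trans A data.frame from [transTargets()].
#' @return A data.frame with one row per lncRNA having at least one
#'   target: `lnc_id`, `n_cis`, `n_trans`, `cis_targets`,
#'   `trans_targets` (comma-separated gene lists).
#' @export
targetTable <- function(cis, trans) {
    ids <- sort(unique(c(cis$lnc_id, trans$lnc_id)))
    if (length(ids) == 0L)
        return(data.frame(lnc_id = character(), n_cis = integer(),
                          n_trans = integer(), cis_targets = character(),
                          trans_targets = character(), stringsAsFactors = FALSE))
    cisBy <- split(cis$gene_id, factor(cis$lnc_id, levels = ids))
    transBy <- split(trans$gene_id, factor(trans$lnc_id, levels = ids))
    data.frame(lnc_id = ids,
               n_cis = vapply(cisBy, function(g) length(unique(g)), integer(1)),
               n_trans = vapply(transBy, function(g) length(unique(g)), integer(1)),
               cis_targets = vapply(cisBy, function(g)
                   paste(unique(g), collapse = ","), character(1)),
               trans_targets = vapply(transBy, function(g)
                   paste(unique(g), collapse = ","), character(1)),
               stringsAsFactors = FALSE, row.names = NULL)
}
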