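# Positional classification of candidate lncRNAs against the
# protein-coding annotation.  Decision cascade, in order:
#   1. antisense — >= 1 bp exonic overlap with a protein-coding gene's
#      exon on the opposite strand;
#   2. intronic  — span entirely inside one intron of a same-strand
#      protein-coding gene, zero exonic overlap;
#   3. lincRNA   — no overlap with any protein-coding gene span on
#      either strand.
# Anything else (e.g. same-strand exonic overlap) is "ambiguous" and
# excluded from the lncRNA set.  Antisense is tested first: exonic
# opposite-strand overlap is the stronger signal when a locus could
# also sit inside an intron.

#' Classify candidate lncRNAs as lincRNA, antisense or intronic
#'
#' @param lnc A [TranscriptSet-class] of candidate lncRNAs.
#' @param genes A [GeneAnnotation-class]; only `protein_coding` genes
#'   participate in the classification.
#' @return A data.frame with one row per candidate: `transcript_id`,
#'   `gene_id` (the candidate's own locus id), `biotype`
#'   (`"lincRNA"`, `"antisense"`, `"intronic"` or `"ambiguous"`) and
#'   `host_gene_id` (the overlapped/containing coding gene; `NA` for
#'   lincRNA and ambiguous).  The number of ambiguous records is
#'   reported via a message.
#' @export
classifyBiotype <- function(lnc, genes) {
    coding <- geneSpans(genes)
    coding <- coding[mcols(coding)$biotype == "protein_coding"]
    codingIds <- as.character(mcols(coding)$gene_id)
    codingEx <- geneExons(genes)[codingIds]

    spans <- transcriptSpans(lnc)
    n <- length(spans)
    biotype <- rep(NA_character_, n)
    host <- rep(NA_character_, n)
    if (n > 0L && length(coding) > 0L) {
        exUn <- unlist(codingEx, use.names = FALSE)
        exGene <- rep(codingIds, S4Vectors::elementNROWS(codingEx))
        lncEx <- transcriptExons(lnc)
        lncExFlat <- unlist(lncEx, use.names = FALSE)
        lncOfEx <- rep(seq_len(n), S4Vectors::elementNROWS(lncEx))

        # (1) antisense: exon-exon overlap, opposite strand
        hits <- findOverlaps(lncExFlat, exUn, ignore.strand = TRUE)
        opp <- as.character(strand(lncExFlat))[S4Vectors::queryHits(hits)] !=
            as.character(strand(exUn))[S4Vectors::subjectHits(hits)]
        hits <- hits[opp]
        if (length(hits)) {
            qi <- lncOfEx[S4Vectors::queryHits(hits)]
            gi <- exGene[S4Vectors::subjectHits(hits)]
            first <- !duplicated(qi)
            biotype[qi[first]] <- "antisense"
            host[qi[first]] <- gi[first]
        }

        # (2) intronic: span inside a same-strand gene span, no exonic
        # overlap with that gene => inside exactly one intron
        todo <- which(is.na(biotype))
        if (length(todo)) {
            within <- findOverlaps(spans[todo], coding, type = "within",
                                   ignore.strand = TRUE)
            same <- as.character(strand(spans[todo]))[S4Vectors::queryHits(within)] ==
                as.character(strand(coding))[S4Vectors::subjectHits(within)]
            within <- within[same]
            if (length(within)) {
                qh <- S4Vectors::queryHits(within)
                sh <- S4Vectors::subjectHits(within)
                exFree <- vapply(seq_along(qh), function(j) {
                    !any(IRanges::overlapsAny(ranges(spans[todo][qh[j]]),
                                              ranges(codingEx[[sh[j]]])))
                }, logical(1))
                within <- within[exFree]
                if (length(within)) {
                    qh <- S4Vectors::queryHits(within)
                    sh <- S4Vectors::subjectHits(within)
                    first <- !duplicated(qh)
                    biotype[todo[qh[first]]] <- "intronic"
                    host[todo[qh[first]]] <- codingIds[sh[first]]
                }
            }
        }

        # (3) lincRNA: no span overlap with any coding gene, either strand
        todo <- which(is.na(biotype))
        if (length(todo)) {
            anyOvl <- IRanges::overlapsAny(spans[todo], coding,
                                           ignore.strand = TRUE)
            biotype[todo[!anyOvl]] <- "lincRNA"
        }
        biotype[is.na(biotype)] <- "ambiguous"
    } else if (n > 0L) {
        biotype[] <- "lincRNA"
    }
    nAmb <- sum(biotype == "ambiguous")
    if (nAmb > 0L)
        message(nAmb, " candidate(s) matched no class (ambiguous) and are excluded")
    data.frame(transcript_id = transcriptIds(lnc),
               gene_id = unname(geneIds(lnc)),
               biotype = biotype,
               host_gene_id = host,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Tabulate lncRNA biotype classes
#'
#' @param records A data.frame from [classifyBiotype()].
#' @return Named integer vector with counts for `lincRNA`, `antisense`,
#'   `intronic` and `ambiguous`; the classified counts sum to the
#'   number of non-ambiguous records.
#' @export
biotypeSummary <- function(records) {
    classes <- c("lincRNA", "antisense", "intronic", "ambiguous")
    out <- setNames(integer(length(classes)), classes)
    if (nrow(records) > 0L) {
        tab <- table(factor(records$biotype, levels = classes))
        out[] <- as.integer(tab)
    }
    out
}
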