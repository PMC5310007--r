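# Candidate lncRNA screening: structural/expression pre-filters, ORF
# finding, three coding-potential scorers and the consensus rule.
# Transcripts called coding by ANY scorer are removed; candidates are
# the transcripts all three scorers agree are noncoding.

.charVec <- function(sequence) {
    s <- toupper(as.character(sequence))
    if (nchar(s) == 0L) character(0) else strsplit(s, "", fixed = TRUE)[[1L]]
}

.translateCodons <- function(codons) {
    aa <- GENETIC_CODE[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
}

.orfTable <- function(v, frames = 3L, translate = TRUE) {
    empty <- data.frame(frame = integer(), start = integer(),
                        end = integer(), length = integer(),
                        peptide = character(), incomplete = logical(),
                        stringsAsFactors = FALSE)
    n <- length(v)
    if (n < 3L) return(empty)
    out <- vector("list", frames)
    for (f in seq_len(frames) - 1L) {
        k <- (n - f) %/% 3L
        if (k < 1L) next
        idx <- seq.int(f + 1L, by = 3L, length.out = k)
        cod <- paste0(v[idx], v[idx + 1L], v[idx + 2L])
        atg <- which(cod == "ATG")
        if (!length(atg)) next
        stp <- which(cod %in% STOP_CODONS)
        # first in-frame stop strictly after each ATG (ATG is never a stop)
        pos <- findInterval(atg, stp) + 1L
        stop_cod <- ifelse(pos <= length(stp), stp[pos], NA_integer_)
        incomplete <- is.na(stop_cod)
        end_cod <- ifelse(incomplete, k, stop_cod)
        start <- idx[atg]
        end <- idx[end_cod] + 2L
        pep <- character(length(atg))
        if (translate) {
            for (j in seq_along(atg)) {
                last <- if (incomplete[j]) end_cod[j] else stop_cod[j] - 1L
                pep[j] <- .translateCodons(cod[atg[j]:last])
            }
        }
        out[[f + 1L]] <- data.frame(frame = f, start = start, end = end,
                                    length = end - start + 1L,
                                    peptide = pep, incomplete = incomplete,
                                    stringsAsFactors = FALSE)
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out)) return(empty)
    do.call(rbind, out)
}

#' Find open reading frames in a spliced transcript sequence
#'
#' Scans the forward reading frames for every ATG-to-stop ORF.  ORF
#' coordinates are 1-based inclusive on the spliced transcript; length
#' includes the stop codon; the reported peptide excludes it.  An
#' ATG run reaching the transcript end without an in-frame stop is
#' reported with `incomplete = TRUE` (its end is the last full codon)
#' and is excluded from longest-ORF selection downstream.  Codons
#' containing non-ACGT characters never match ATG or a stop and
#' translate to `X`.
#'
#' Only the three forward frames are scanned: strand-specific library
#' preparation means assembled transcripts are already oriented.
#'
#' @param sequence A character string, [Biostrings::DNAString] or
#'   length-1 [Biostrings::DNAStringSet] over `A,C,G,T,N`.
#' @param frames Number of forward frames to scan (default 3).
#' @return A data.frame with columns `frame` (0/1/2), `start`, `end`,
#'   `length` (nt), `peptide`, `incomplete`, ordered by frame then
#'   position.  Empty for sequences with no ATG.
#' @examples
#' findOrfs("ATGAAATAG")   # one ORF, length 9, peptide "MK"
#' @export
findOrfs <- function(sequence, frames = 3L) {
    if (is(sequence, "XStringSet")) {
        stopifnot(length(sequence) == 1L)
        sequence <- as.character(sequence[[1L]])
    }
    .orfTable(.charVec(sequence), frames = frames, translate = TRUE)
}

#' Longest complete ORF of a transcript
#'
#' @param orfs A data.frame from [findOrfs()].
#' @return The single row with the greatest length among complete ORFs
#'   (ties broken by frame then position), or a zero-row data.frame if
#'   none is complete.
#' @export
longestOrf <- function(orfs) {
    cand <- orfs[!orfs$incomplete, , drop = FALSE]
    if (nrow(cand) == 0L) return(cand)
    cand[which.max(cand$length), , drop = FALSE]
}

#' ORF-extent coding score
#'
#' Scores coding potential from the extent and coverage of the longest
#' complete ORF: `score = length/lengthThreshold +
#' coverage/coverageThreshold` with `coverage = ORF length / transcript
#' length`.  The call is `coding` when the ORF length reaches
#' `lengthThreshold` (default 300 nt) or the coverage reaches
#' `coverageThreshold` (default 0.5); both boundaries are inclusive.  A
#' transcript with no complete ORF scores 0 and is called noncoding.
#'
#' @param orfLength Longest-ORF length(s) in nt (0 when absent).
#' @param transcriptLength Spliced transcript length(s) in bp.
#' @param lengthThreshold,coverageThreshold Decision thresholds.
#' @return A data.frame with columns `score` and `call`
#'   (`"coding"`/`"noncoding"`), one row per input.
#' @export
orfCodingScore <- function(orfLength, transcriptLength,
                           lengthThreshold = 300, coverageThreshold = 0.5) {
    stopifnot(all(transcriptLength > 0))
    coverage <- orfLength / transcriptLength
    score <- orfLength / lengthThreshold + coverage / coverageThreshold
    call <- ifelse(orfLength >= lengthThreshold | coverage >= coverageThreshold,
                   "coding", "noncoding")
    data.frame(score = score, call = call, stringsAsFactors = FALSE)
}

#' Adjoining-triplet (hexamer) coding score
#'
#' Slides over in-frame hexamers (pairs of adjacent codons) and
#' averages the log-ratio of their frequency under a coding versus a
#' noncoding model, maximised over the three forward frames.  Positive
#' scores are called coding.  Hexamers containing non-ACGT characters
#' are skipped; sequences shorter than 6 nt score 0 (noncoding).
#'
#' @param sequence Character string / DNAString, or a
#'   [Biostrings::DNAStringSet] (vectorised).
#' @param tables `list(coding =, noncoding =)` of named log-frequency
#'   vectors over all 4096 hexamers; defaults to
#'   [defaultHexamerTables()].
#' @return A data.frame with columns `score` and `call`.
#' @export
tripletCodingScore <- function(sequence, tables = defaultHexamerTables()) {
    stopifnot(is.list(tables), all(c("coding", "noncoding") %in% names(tables)))
    seqs <- if (is(sequence, "XStringSet")) as.character(sequence)
            else as.character(sequence)
    delta <- tables$coding - tables$noncoding
    one <- function(s) {
        v <- .charVec(s)
        n <- length(v)
        best <- -Inf
        if (n >= 6L) {
            for (f in 0:2) {
                k <- (n - f) %/% 3L
                if (k < 2L) next
                idx <- seq.int(f + 1L, by = 3L, length.out = k)
                cod <- paste0(v[idx], v[idx + 1L], v[idx + 2L])
                hex <- paste0(cod[-k], cod[-1L])
                d <- delta[hex]
                d <- d[!is.na(d)]
                if (length(d)) best <- max(best, mean(d))
            }
        }
        if (!is.finite(best)) 0 else best
    }
    score <- vapply(seqs, one, numeric(1), USE.NAMES = FALSE)
    data.frame(score = score,
               call = ifelse(score > 0, "coding", "noncoding"),
               stringsAsFactors = FALSE)
}

#' Protein-motif scan over ORF translations
#'
#' Translates every ORF in all three forward frames (per-ORF segments:
#' a motif whose peptide would span a stop codon never matches) and
#' reports whether any translation contains any library motif as a
#' verbatim substring.
#'
#' @param sequence Character string / DNAString, or a
#'   [Biostrings::DNAStringSet] (vectorised).
#' @param motifLibrary Character vector of peptide motifs; defaults to
#'   [defaultMotifLibrary()].  An empty library never hits (with a
#'   warning).
#' @return A data.frame with columns `motifHit` (logical) and `call`.
#' @export
motifScan <- function(sequence, motifLibrary = defaultMotifLibrary()) {
    if (length(motifLibrary) == 0L) {
        warning("empty motif library: no transcript will be called coding by the motif scan")
    }
    seqs <- as.character(sequence)
    one <- function(s) {
        if (length(motifLibrary) == 0L) return(FALSE)
        orfs <- .orfTable(.charVec(s), translate = TRUE)
        if (nrow(orfs) == 0L) return(FALSE)
        any(vapply(motifLibrary, function(m)
            any(grepl(m, orfs$peptide, fixed = TRUE)), logical(1)))
    }
    hit <- vapply(seqs, one, logical(1), USE.NAMES = FALSE)
    data.frame(motifHit = hit,
               call = ifelse(hit, "coding", "noncoding"),
               stringsAsFactors = FALSE)
}

#' Structural and expression pre-filter for lncRNA candidates
#'
#' Keeps transcripts with spliced length strictly greater than
#' `minLength` (lncRNAs are transcripts greater than 200 nt), at least
#' `minExons` exons, and FPKM of at least `minFpkm` in one or more
#' samples.
#'
#' @param ts A [TranscriptSet-class].
#' @param expr An [ExpressionData-class] covering all transcripts in
#'   `ts`.
#' @param minLength Minimum spliced length in bp, exclusive (default
#'   200).
#' @param minExons Minimum exon count, inclusive (default 1).
#' @param minFpkm Minimum FPKM required in at least one sample
#'   (default 0.5).
#' @return `list(kept = TranscriptSet, attrition = named integer
#'   vector)` with per-rule attrition counts (`input`, `length`,
#'   `exons`, `fpkm`, `kept`); rules are applied in that order and a
#'   transcript is counted against the first rule it fails.
#' @export
basicFilter <- function(ts, expr, minLength = 200, minExons = 1,
                        minFpkm = 0.5) {
    ids <- transcriptIds(ts)
    missing <- setdiff(ids, rownames(expr))
    if (length(missing))
        stop("transcript(s) absent from expression data: ",
             paste(head(missing, 10L), collapse = ", "))
    len <- splicedLengths(ts)
    nex <- exonCounts(ts)
    maxFp <- apply(fpkm(expr)[ids, , drop = FALSE], 1L, max)
    failLen <- len <= minLength
    failEx <- !failLen & nex < minExons
    failFp <- !failLen & !failEx & maxFp < minFpkm
    keep <- !(failLen | failEx | failFp)
    list(kept = ts[keep],
         attrition = c(input = length(ids),
                       length = sum(failLen),
                       exons = sum(failEx),
                       fpkm = sum(failFp),
                       kept = sum(keep)))
}

#' Consensus noncoding call
#'
#' A transcript is kept as a candidate lncRNA only when all three
#' scorers call it noncoding; coding potential predicted by any of the
#' three removes it (intersection rule).
#'
#' @param verdicts A data.frame with columns `transcript_id`,
#'   `orf_call`, `triplet_call`, `motif_call`.
#' @return Character vector of candidate transcript ids.
#' @export
consensusCall <- function(verdicts) {
    need <- c("transcript_id", "orf_call", "triplet_call", "motif_call")
    miss <- setdiff(need, colnames(verdicts))
    if (length(miss))
        stop("missing scorer output column(s): ", paste(miss, collapse = ", "))
    calls <- verdicts[, c("orf_call", "triplet_call", "motif_call")]
    if (any(is.na(as.matrix(calls))))
        stop("NA scorer call for transcript(s): ",
             paste(verdicts$transcript_id[!complete.cases(calls)], collapse = ", "))
    keep <- calls$orf_call == "noncoding" &
        calls$triplet_call == "noncoding" &
        calls$motif_call == "noncoding"
    verdicts$transcript_id[keep]
}

#' Screen a transcript set for candidate lncRNAs
#'
#' Runs the full screening stage: the structural/expression
#' [basicFilter()], then the three coding-potential scorers
#' ([orfCodingScore()], [tripletCodingScore()], [motifScan()]) on the
#' survivors, and finally the [consensusCall()].  Externally produced
#' scorer calls (e.g. result tables of dedicated coding-potential
#' tools) can be supplied via `externalCalls` to bypass the internal
#' scorers.
#'
#' @param ts A [TranscriptSet-class] with spliced sequences attached.
#' @param expr An [ExpressionData-class] covering `ts`.
#' @param minLength,minExons,minFpkm Passed to [basicFilter()].
#' @param orfLengthThreshold,orfCoverageThreshold Passed to
#'   [orfCodingScore()].
#' @param hexamerTables Passed to [tripletCodingScore()].
#' @param motifLibrary Passed to [motifScan()].
#' @param externalCalls Optional data.frame with columns
#'   `transcript_id`, `orf_call`, `triplet_call`, `motif_call` covering
#'   all filtered transcripts; replaces the internal scorers.
#' @return `list(verdicts = data.frame, candidates = TranscriptSet,
#'   attrition = named integer vector)`.  `verdicts` has one row per
#'   transcript surviving the basic filter with the three scores, the
#'   three calls and the consensus.
#' @export
screenTranscripts <- function(ts, expr, minLength = 200, minExons = 1,
                              minFpkm = 0.5, orfLengthThreshold = 300,
                              orfCoverageThreshold = 0.5,
                              hexamerTables = defaultHexamerTables(),
                              motifLibrary = defaultMotifLibrary(),
                              externalCalls = NULL) {
    flt <- basicFilter(ts, expr, minLength = minLength, minExons = minExons,
                       minFpkm = minFpkm)
    kept <- flt$kept
    ids <- transcriptIds(kept)
    if (length(ids) == 0L) {
        verdicts <- data.frame(transcript_id = character(),
                               orf_length = integer(), orf_score = numeric(),
                               orf_call = character(), triplet_score = numeric(),
                               triplet_call = character(), motif_hit = logical(),
                               motif_call = character(), consensus = character(),
                               stringsAsFactors = FALSE)
        return(list(verdicts = verdicts, candidates = kept,
                    attrition = flt$attrition))
    }
    if (is.null(externalCalls)) {
        seqs <- spliceSequences(kept)
        missing <- setdiff(ids, names(seqs))
        if (length(missing))
            stop("no spliced sequence for transcript(s): ",
                 paste(head(missing, 10L), collapse = ", "))
        seqs <- seqs[ids]
        orfLen <- vapply(ids, function(id) {
            lo <- longestOrf(.orfTable(.charVec(seqs[[id]]), translate = FALSE))
            if (nrow(lo) == 0L) 0L else lo$length
        }, integer(1))
        orf <- orfCodingScore(orfLen, splicedLengths(kept)[ids],
                              lengthThreshold = orfLengthThreshold,
                              coverageThreshold = orfCoverageThreshold)
        trip <- tripletCodingScore(seqs, tables = hexamerTables)
        mot <- motifScan(seqs, motifLibrary = motifLibrary)
        verdicts <- data.frame(transcript_id = ids,
                               orf_length = unname(orfLen),
                               orf_score = orf$score, orf_call = orf$call,
                               triplet_score = trip$score,
                               triplet_call = trip$call,
                               motif_hit = mot$motifHit, motif_call = mot$call,
                               stringsAsFactors = FALSE, row.names = NULL)
    } else {
        need <- c("transcript_id", "orf_call", "triplet_call", "motif_call")
        if (!all(need %in% colnames(externalCalls)))
            stop("externalCalls must have columns: ", paste(need, collapse = ", "))
        m <- match(ids, externalCalls$transcript_id)
        if (anyNA(m))
            stop("externalCalls missing transcript(s): ",
                 paste(head(ids[is.na(m)], 10L), collapse = ", "))
        ec <- externalCalls[m, , drop = FALSE]
        verdicts <- data.frame(transcript_id = ids,
                               orf_length = NA_integer_, orf_score = NA_real_,
                               orf_call = ec$orf_call,
                               triplet_score = NA_real_,
                               triplet_call = ec$triplet_call,
                               motif_hit = ec$motif_call == "coding",
                               motif_call = ec$motif_call,
                               stringsAsFactors = FALSE, row.names = NULL)
    }
    candidateIds <- consensusCall(verdicts)
    verdicts$consensus <- ifelse(verdicts$transcript_id %in% candidateIds,
                                 "noncoding", "coding")
    list(verdicts = verdicts,
         candidates = kept[transcriptIds(kept) %in% candidateIds],
         attrition = c(flt$attrition,
                       coding_potential = length(ids) - length(candidateIds),
                       candidates = length(candidateIds)))
}
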