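# Shared fixtures and independent oracles.  Studies are memoised so
# several test files can reuse the same simulated data.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, make) {
    if (!exists(key, envir = .fixture_cache))
        assign(key, make(), envir = .fixture_cache)
    get(key, envir = .fixture_cache)
}

# a reduced study for fast unit tests
smallConfig <- function(seed = 11L, chromLength = 1.5e6, ...) {
    synthConfig(seed = seed, nCodingGenes = 60L, nLncLoci = 40L,
                nPlantedCis = 6L, plantedTransPairs = 6L,
                nGroupSpecific = 4L, chromLength = chromLength, ...)
}

smallStudy <- function() memo("smallStudy", function() {
    suppressMessages(simulateStudy(smallConfig()))
})

smallStudyTinyDisp <- function() memo("smallStudyTinyDisp", function() {
    suppressMessages(simulateStudy(smallConfig(nbDispersion = 1e-9)))
})

# hand-built two-exon transcript
toyTranscript <- function(id = "t1", chrom = "chr1", strand = "+",
                          starts = c(100, 300), ends = c(199, 399),
                          gene = "g1") {
    grl <- GenomicRanges::GRangesList(
        GenomicRanges::GRanges(chrom,
            IRanges::IRanges(starts, ends), strand))
    names(grl) <- id
    TranscriptSet(grl, geneId = stats::setNames(gene, id))
}

# TranscriptSet from a compact spec list:
# list(t1 = list(chrom=, strand=, starts=, ends=, gene=), ...)
makeTs <- function(spec, seqs = NULL) {
    grl <- GenomicRanges::GRangesList(lapply(spec, function(s)
        GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$starts, s$ends),
                               s$strand)))
    names(grl) <- names(spec)
    gid <- vapply(spec, function(s) s$gene, character(1))
    ts <- TranscriptSet(grl, geneId = stats::setNames(gid, names(spec)))
    if (!is.null(seqs))
        spliceSequences(ts) <- Biostrings::DNAStringSet(seqs)
    ts
}

# GeneAnnotation from a compact spec list:
# list(g1 = list(chrom=, strand=, exonStarts=, exonEnds=, biotype=), ...)
makeGenes <- function(spec) {
    exons <- GenomicRanges::GRangesList(lapply(spec, function(s)
        GenomicRanges::GRanges(s$chrom,
            IRanges::IRanges(s$exonStarts, s$exonEnds), s$strand)))
    names(exons) <- names(spec)
    spans <- unlist(range(exons), use.names = FALSE)
    S4Vectors::mcols(spans)$gene_id <- names(spec)
    S4Vectors::mcols(spans)$biotype <- vapply(spec, function(s)
        if (is.null(s$biotype)) "protein_coding" else s$biotype, character(1))
    names(spans) <- names(spec)
    GeneAnnotation(spans, exons)
}

# minimal ExpressionData
makeExpr <- function(counts, lengths = NULL,
                     groups = rep(c("ctrl", "case"),
                                  each = ncol(counts) / 2)) {
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("t%d", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
    if (is.null(lengths))
        lengths <- stats::setNames(rep(1000, nrow(counts)), rownames(counts))
    ExpressionData(counts, lengths = lengths,
                   design = stats::setNames(groups, colnames(counts)))
}

# encode a peptide with the generator's preferred codons (test-side
# copy kept deliberately simple)
encodePeptide <- function(pep) {
    usage <- codonUsageTable()
    aa <- Biostrings::GENETIC_CODE[names(usage)]
    pick <- vapply(split(names(usage), aa), function(cods)
        cods[which.max(usage[cods])], character(1))
    paste(pick[strsplit(pep, "")[[1]]], collapse = "")
}

# ---- independent oracles -------------------------------------------------

# brute-force ORF scan: every position, every frame, plain string ops
oracleOrfs <- function(seq) {
    n <- nchar(seq)
    stops <- c("TAA", "TAG", "TGA")
    out <- list()
    if (n >= 3) for (f in 0:2) {
        if (f + 3 > n) next
        starts <- seq(f + 1, n, by = 3)
        starts <- starts[starts + 2 <= n]
        for (s in starts) {
            if (substr(seq, s, s + 2) != "ATG") next
            found <- FALSE
            ends <- if (s + 3 + 2 <= n) seq(s + 3, n, by = 3) else integer(0)
            for (e in ends) {
                if (e + 2 > n) break
                if (substr(seq, e, e + 2) %in% stops) {
                    out[[length(out) + 1]] <-
                        c(frame = f, start = s, end = e + 2, incomplete = 0)
                    found <- TRUE
                    break
                }
            }
            if (!found)
                out[[length(out) + 1]] <- c(frame = f, start = s,
                                            end = 3 * ((n - f) %/% 3) + f,
                                            incomplete = 1)
        }
    }
    if (!length(out))
        return(data.frame(frame = integer(), start = integer(),
                          end = integer(), incomplete = integer()))
    as.data.frame(do.call(rbind, out))
}

# exhaustive hypergeometric upper tail from binomial coefficients
oracleFisher <- function(k, K, n, N) {
    lo <- max(0, K + n - N)
    hi <- min(K, n)
    if (k > hi) return(0)
    i <- max(k, lo):hi
    sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# plain-loop cis scan on raw coordinates
oracleCis <- function(lncDf, geneDf, windows = c(10000, 100000)) {
    windows <- sort(windows)
    out <- list()
    for (i in seq_len(nrow(lncDf))) for (j in seq_len(nrow(geneDf))) {
        if (lncDf$chrom[i] != geneDf$chrom[j]) next
        gap <- max(geneDf$start[j] - lncDf$end[i],
                   lncDf$start[i] - geneDf$end[j], 0) -
            (max(geneDf$start[j] - lncDf$end[i],
                 lncDf$start[i] - geneDf$end[j], 0) > 0)
        # 1-based gap: bases strictly between the spans
        gap <- if (geneDf$start[j] > lncDf$end[i])
            geneDf$start[j] - lncDf$end[i] - 1
        else if (lncDf$start[i] > geneDf$end[j])
            lncDf$start[i] - geneDf$end[j] - 1
        else 0
        if (gap > max(windows)) next
        out[[length(out) + 1]] <- data.frame(
            lnc_id = lncDf$id[i], gene_id = geneDf$id[j],
            window = windows[which(windows >= gap)[1]], distance = gap,
            stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(lnc_id = character(), gene_id = character(),
                          window = numeric(), distance = numeric()))
    df <- do.call(rbind, out)
    df[order(df$lnc_id, df$distance, df$gene_id), , drop = FALSE]
}

# textbook equal-variance two-sample t-test
oracleTtest <- function(x, y) {
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
    tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    2 * stats::pt(-abs(tt), df = nx + ny - 2)
}

# direct product-moment formula (no cor())
oraclePearson <- function(x, y) {
    n <- length(x)
    num <- sum(x * y) - n * mean(x) * mean(y)
    den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
    num / den
}
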