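# Shipped scoring constants: a biased sense-codon usage table driving
# both the coding-sequence generator and the default hexamer scorer
# tables, and a toy peptide motif library for the motif scanner.

STOP_CODONS <- c("TAA", "TAG", "TGA")

ALL_CODONS <- {
    b <- c("A", "C", "G", "T")
    as.vector(outer(outer(b, b, paste0), b, paste0))
}

SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

#' Shipped coding codon-usage table
#'
#' A strongly biased probability distribution over the 61 sense codons.
#' For each amino acid one "preferred" codon (the alphabetically first)
#' carries weight 8, the remaining synonymous codons weight 1; weights
#' are normalised to sum to one.  The bias is deliberately strong: it
#' gives the generator's planted coding regions a codon signature that
#' the hexamer (adjoining-triplet) scorer can separate from the uniform
#' background without any training data.
#'
#' @return Named numeric vector of probabilities over the sense codons.
#' @export
codonUsageTable <- function() {
    aa <- GENETIC_CODE[SENSE_CODONS]
    w <- numeric(length(SENSE_CODONS))
    names(w) <- SENSE_CODONS
    for (a in unique(aa)) {
        cods <- sort(SENSE_CODONS[aa == a])
        w[cods] <- 1
        w[cods[1L]] <- 8
    }
    w / sum(w)
}

#' Default hexamer log-frequency tables for the triplet scorer
#'
#' The coding table assigns each hexamer (a pair of adjoining codons)
#' the log product probability under [codonUsageTable()], with
#' stop-containing codons floored at a pseudo-probability of 1e-4.  The
#' noncoding table is the uniform background, `log(1/4096)` everywhere.
#' Both are named numeric vectors over all 4096 hexamers.
#'
#' @return `list(coding =, noncoding =)` of named numeric vectors.
#' @export
defaultHexamerTables <- function() {
    lq <- setNames(rep(log(1e-4), length(ALL_CODONS)), ALL_CODONS)
    usage <- codonUsageTable()
    lq[names(usage)] <- log(usage)
    hex <- as.vector(outer(ALL_CODONS, ALL_CODONS, paste0))
    coding <- setNames(as.vector(outer(lq, lq, "+")), hex)
    noncoding <- setNames(rep(-log(4096), length(hex)), hex)
    list(coding = coding, noncoding = noncoding)
}

#' Default peptide motif library
#'
#' A small set of peptide substrings standing in for a protein-domain
#' database.  The synthetic generator plants the first motif into every
#' coding ORF it emits, so the motif scanner has a recoverable signal;
#' real protein-family result tables can be supplied instead via the
#' `motifLibrary` argument of [motifScan()].
#'
#' @return Character vector of peptide motifs.
#' @export
defaultMotifLibrary <- function() {
    c("MKTAYIAKQR", "WLHGDPSQTV", "CPNGRWEEFA", "HDLKYTNWQS")
}
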