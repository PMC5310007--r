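# lncRNA vs mRNA feature comparison: expression level, transcript
# length, ORF length and exon number, summarised per class with a
# two-sample rank test per feature.

#' Compare genomic features of lncRNAs and coding transcripts
#'
#' Computes, per class and per feature, the mean, median, quartiles and
#' shared-break histogram counts, plus a two-sided Wilcoxon rank-sum p
#' per feature.  Features: `expression` (log10 of the maximum FPKM
#' across samples plus 1e-3), `length` (spliced, bp), `orf_length`
#' (longest complete ORF, nt; 0 when absent — requires attached
#' sequences) and `exons`.
#'
#' @param lnc A [TranscriptSet-class] of lncRNAs (non-empty, sequences
#'   attached).
#' @param coding A [TranscriptSet-class] of coding transcripts
#'   (non-empty, sequences attached).
#' @param expr An [ExpressionData-class] covering both sets.
#' @param bins Number of histogram bins per feature (default 20).
#' @return `list(summary = data.frame, histograms = list, values =
#'   list)`; `summary` has one row per class x feature with `n`,
#'   `mean`, `median`, `q1`, `q3` and the feature's rank-test
#'   `pvalue`; `histograms` holds per-feature shared breaks and
#'   per-class counts.
#' @export
featureSummary <- function(lnc, coding, expr, bins = 20L) {
    if (length(lnc) == 0L || length(coding) == 0L)
        stop("both classes must be non-empty")
    classVals <- function(ts) {
        ids <- transcriptIds(ts)
        fp <- fpkm(expr)
        missing <- setdiff(ids, rownames(fp))
        if (length(missing))
            stop("transcript(s) absent from expression data: ",
                 paste(head(missing, 5L), collapse = ", "))
        seqs <- spliceSequences(ts)
        if (!all(ids %in% names(seqs)))
            stop("spliced sequences required for ORF lengths")
        orfLen <- vapply(ids, function(id) {
            lo <- longestOrf(.orfTable(.charVec(seqs[[id]]), translate = FALSE))
            if (nrow(lo) == 0L) 0 else as.numeric(lo$length)
        }, numeric(1))
        list(expression = log10(apply(fp[ids, , drop = FALSE], 1L, max) + 1e-3),
             length = as.numeric(splicedLengths(ts)),
             orf_length = unname(orfLen),
             exons = as.numeric(exonCounts(ts)))
    }
    vl <- classVals(lnc)
    vc <- classVals(coding)
    feats <- names(vl)
    summ <- list(); hists <- list()
    for (f in feats) {
        p <- suppressWarnings(wilcox.test(vl[[f]], vc[[f]], exact = FALSE)$p.value)
        if (is.nan(p)) p <- 1   # all values tied across both classes
        for (cls in c("lncRNA", "mRNA")) {
            v <- if (cls == "lncRNA") vl[[f]] else vc[[f]]
            q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
            summ[[length(summ) + 1L]] <- data.frame(
                feature = f, class = cls, n = length(v), mean = mean(v),
                q1 = q[1L], median = q[2L], q3 = q[3L], pvalue = p,
                stringsAsFactors = FALSE)
        }
        rng <- range(c(vl[[f]], vc[[f]]))
        if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
        breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
        cut2 <- function(v) {
            idx <- pmin(pmax(findInterval(v, breaks, all.inside = TRUE), 1L), bins)
            tabulate(idx, nbins = bins)
        }
        hists[[f]] <- list(breaks = breaks,
                           lncRNA = cut2(vl[[f]]), mRNA = cut2(vc[[f]]))
    }
    list(summary = do.call(rbind, summ), histograms = hists,
         values = list(lncRNA = vl, mRNA = vc))
}

#' Plot the lncRNA vs mRNA feature comparison
#'
#' Density panels for the four features from [featureSummary()].
#'
#' @param fs The list returned by [featureSummary()].
#' @return A ggplot object (facetted by feature).
#' @export
plotFeatureComparison <- function(fs) {
    v <- fs$values
    df <- do.call(rbind, lapply(names(v), function(cls) {
        do.call(rbind, lapply(names(v[[cls]]), function(f) {
            data.frame(class = cls, feature = f, value = v[[cls]][[f]],
                       stringsAsFactors = FALSE)
        }))
    }))
    ggplot2::ggplot(df, ggplot2::aes(x = .data[["value"]], fill = .data[["class"]])) +
        ggplot2::geom_density(alpha = 0.5) +
        ggplot2::facet_wrap(~feature, scales = "free") +
        ggplot2::theme_minimal() +
        ggplot2::labs(x = NULL, y = "density", fill = NULL)
}
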