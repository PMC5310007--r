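# Two-group differential expression with a negative-binomial Wald
# test.  Per-transcript means are compared on the log scale with a
# delta-method standard error under NB variance mu + alpha*mu^2, using
# a trended dispersion pooled across transcripts (method-of-moments
# estimates smoothed against the mean by loess).  Fold changes are
# reported on group-mean FPKM with a pseudocount.

#' Trended dispersion estimate
#'
#' Method-of-moments per-transcript dispersions (pooled within-group
#' variance of size-factor normalised counts) smoothed against the mean
#' by robust loess on the log-mean axis.  Transcripts borrow strength
#' from the trend; the returned value is the trend evaluated at each
#' transcript's mean, floored at `1e-8`.
#'
#' @param expr An [ExpressionData-class].
#' @return Numeric vector of dispersions, named by transcript.
#' @export
estimateDispersionTrend <- function(expr) {
    cnt <- assay(expr, "counts")
    grp <- sampleGroups(expr)
    sf <- colSums(cnt) / mean(colSums(cnt))
    nc <- sweep(cnt, 2L, sf, "/")
    lv <- levels(grp)
    a <- grp == lv[1L]; b <- grp == lv[2L]
    na <- sum(a); nb <- sum(b)
    mu <- rowMeans(nc)
    vw <- ((na - 1L) * rowVars_(nc[, a, drop = FALSE]) +
           (nb - 1L) * rowVars_(nc[, b, drop = FALSE])) / (na + nb - 2L)
    wbar <- mean(1 / sf)
    alphaRaw <- (vw - mu * wbar) / mu^2
    use <- is.finite(alphaRaw) & mu > 0.5
    out <- rep(1e-8, nrow(cnt))
    names(out) <- rownames(cnt)
    if (sum(use) >= 10L) {
        x <- log(mu[use])
        y <- pmin(pmax(alphaRaw[use], -1), 10)
        fit <- loess(y ~ x, span = 0.5, degree = 1,
                     control = loess.control_safe())
        pred <- predict(fit, newdata = data.frame(x = log(pmax(mu, 0.5))))
        # outside the fitted range loess extrapolates linearly; clamp
        pred[!is.finite(pred)] <- median(y)
        out[] <- pmax(pred, 1e-8)
    } else if (any(use)) {
        out[] <- pmax(mean(pmin(pmax(alphaRaw[use], 0), 10)), 1e-8)
    }
    out
}

loess.control_safe <- function() stats::loess.control(surface = "direct")

rowVars_ <- function(m) {
    mu <- rowMeans(m)
    rowSums((m - mu)^2) / (ncol(m) - 1L)
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' For each transcript, group means of size-factor normalised counts
#' are compared on the log scale; the Wald statistic uses a
#' delta-method standard error with NB variance `mu + alpha*mu^2` and
#' the trended dispersion from [estimateDispersionTrend()] (or a
#' supplied value).  The two-sided p-value comes from the normal
#' reference distribution; Benjamini-Hochberg adjusted q-values are
#' reported alongside.  The log2 fold change is computed on group-mean
#' FPKM with a pseudocount (`log2((case + p)/(control + p))`), so
#' `direction` is `"up"` when expression is higher in the case (second
#' factor level) group.  All-zero transcripts are flagged untestable
#' with `p = 1` and `log2fc = 0`.
#'
#' @param expr An [ExpressionData-class]; the first group level is the
#'   control, the second the case.
#' @param dispersion Optional dispersion(s): a single value or a vector
#'   named by transcript.  Default: trended estimate from the data.
#' @param pseudocountFpkm Pseudocount (FPKM units) for the fold change
#'   (default 1).
#' @return A data.frame with columns `transcript_id`, `meanFpkmControl`,
#'   `meanFpkmCase`, `log2fc`, `stat`, `pvalue`, `padj`, `direction`
#'   (`"up"`/`"down"`), `untestable`.
#' @export
nbTest <- function(expr, dispersion = NULL, pseudocountFpkm = 1) {
    grp <- sampleGroups(expr)
    lv <- levels(grp)
    if (min(table(grp)) < 2L)
        stop("at least 2 samples per group are required")
    cnt <- assay(expr, "counts")
    fp <- fpkm(expr)
    if (is.null(dispersion)) {
        alpha <- estimateDispersionTrend(expr)
    } else if (length(dispersion) == 1L) {
        alpha <- rep(dispersion, nrow(cnt))
        names(alpha) <- rownames(cnt)
    } else {
        alpha <- dispersion[rownames(cnt)]
        if (anyNA(alpha)) stop("dispersion vector must cover all transcripts")
    }
    sf <- colSums(cnt) / mean(colSums(cnt))
    nc <- sweep(cnt, 2L, sf, "/")
    a <- grp == lv[1L]; b <- grp == lv[2L]
    na <- sum(a); nb <- sum(b)
    mA <- rowMeans(nc[, a, drop = FALSE])   # control
    mB <- rowMeans(nc[, b, drop = FALSE])   # case
    sA <- sum(1 / sf[a]); sB <- sum(1 / sf[b])
    c0 <- 0.5
    # Var(mean of normalised counts), NB variance per sample
    varA <- mA * sA / na^2 + alpha * mA^2 / na
    varB <- mB * sB / nb^2 + alpha * mB^2 / nb
    se2 <- varA / (mA + c0)^2 + varB / (mB + c0)^2
    stat <- (log(mB + c0) - log(mA + c0)) / sqrt(se2)
    pvalue <- 2 * pnorm(-abs(stat))
    fA <- rowMeans(fp[, a, drop = FALSE])
    fB <- rowMeans(fp[, b, drop = FALSE])
    log2fc <- log2((fB + pseudocountFpkm) / (fA + pseudocountFpkm))
    untestable <- mA == 0 & mB == 0
    pvalue[untestable] <- 1
    stat[untestable] <- 0
    log2fc[untestable] <- 0
    pvalue[stat == 0] <- 1
    padj <- p.adjust(pvalue, method = "BH")
    data.frame(transcript_id = rownames(cnt),
               meanFpkmControl = unname(fA), meanFpkmCase = unname(fB),
               log2fc = unname(log2fc), stat = unname(stat),
               pvalue = unname(pvalue), padj = unname(padj),
               direction = ifelse(log2fc >= 0, "up", "down"),
               untestable = unname(untestable),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarise differential-expression calls
#'
#' @param results A data.frame from [nbTest()].
#' @param alpha Significance threshold on the raw p-value (default
#'   0.05); use `results$padj` upstream if an FDR threshold is wanted.
#' @return Named integer vector `c(n_signif, n_up, n_down)`;
#'   `n_up + n_down == n_signif`.
#' @export
deSummary <- function(results, alpha = 0.05) {
    sig <- results$pvalue < alpha & !results$untestable
    c(n_signif = sum(sig),
      n_up = sum(sig & results$direction == "up"),
      n_down = sum(sig & results$direction == "down"))
}

#' Group-specific transcripts
#'
#' A transcript is specific to group A when its FPKM reaches
#' `presenceFpkm` in every A sample and stays at or below `absenceFpkm`
#' in every sample of the other group.  The two sets are disjoint by
#' construction (presence > absence).
#'
#' @param expr An [ExpressionData-class].
#' @param presenceFpkm Minimum FPKM in every on-group sample (default
#'   1.0).
#' @param absenceFpkm Maximum FPKM in every off-group sample (default
#'   0.1).
#' @param ids Optional transcript ids to restrict to (e.g. candidate
#'   lncRNAs).
#' @return Named list of two character vectors, one per group level.
#' @export
groupSpecific <- function(expr, presenceFpkm = 1.0, absenceFpkm = 0.1,
                          ids = NULL) {
    if (presenceFpkm <= absenceFpkm)
        stop("presenceFpkm must exceed absenceFpkm")
    fp <- fpkm(expr)
    if (!is.null(ids)) {
        missing <- setdiff(ids, rownames(fp))
        if (length(missing))
            stop("unknown transcript id(s): ", paste(head(missing, 5L), collapse = ", "))
        fp <- fp[ids, , drop = FALSE]
    }
    grp <- sampleGroups(expr)
    lv <- levels(grp)
    out <- setNames(vector("list", 2L), lv)
    for (k in 1:2) {
        on <- grp == lv[k]
        present <- rowSums(fp[, on, drop = FALSE] >= presenceFpkm) == sum(on)
        absent <- rowSums(fp[, !on, drop = FALSE] <= absenceFpkm) == sum(!on)
        out[[k]] <- rownames(fp)[present & absent]
    }
    out
}

#' Volcano-plot table
#'
#' @param results A data.frame from [nbTest()].
#' @param alpha Significance threshold on the raw p-value.
#' @return data.frame with `transcript_id`, `log2fc`, `negLog10P`
#'   (`-log10(p)`) and logical `significant`.
#' @export
volcanoTable <- function(results, alpha = 0.05) {
    data.frame(transcript_id = results$transcript_id,
               log2fc = results$log2fc,
               negLog10P = -log10(results$pvalue),
               significant = results$pvalue < alpha & !results$untestable,
               stringsAsFactors = FALSE, row.names = NULL)
}
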