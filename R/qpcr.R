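# Relative qPCR quantification by the 2^-ddCt method: target Ct
# normalised to a reference gene per sample (dCt), then to the
# calibrator-group mean (ddCt), fold change = 2^-ddCt.  Group
# comparison by equal-variance two-sided t-test on dCt values
# (replicates averaged per biological sample first).

#' Validate a Ct table
#'
#' @param ct A data.frame with columns `sample_id`, `group`, `gene`,
#'   `replicate`, `ct` (cycles, > 0).
#' @return The validated data.frame (invisibly re-typed).
#' @export
validateCtTable <- function(ct) {
    need <- c("sample_id", "group", "gene", "replicate", "ct")
    miss <- setdiff(need, colnames(ct))
    if (length(miss))
        stop("Ct table missing column(s): ", paste(miss, collapse = ", "))
    if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
        stop("Ct values must be positive finite cycle numbers")
    if (length(unique(ct$group)) != 2L)
        stop("Ct table must contain exactly two groups")
    ct
}

#' 2^-ddCt relative fold changes
#'
#' Per sample, `dCt = mean replicate Ct(target) - mean replicate
#' Ct(reference)`; `ddCt = dCt - mean dCt of the calibrator group`;
#' `fold = 2^-ddCt`.  The calibrator group's fold changes average 1 on
#' the log scale by construction, and the whole quantity is invariant
#' to adding a constant to all Ct values of a sample (the reference
#' normalisation cancels it).
#'
#' @param ct A Ct table (see [validateCtTable()]).
#' @param targetGene Gene to quantify.
#' @param calibratorGroup Group used as calibrator (e.g. the control
#'   group).
#' @param referenceGene Housekeeping gene used for normalisation
#'   (default `"beta-actin"`).
#' @return `list(perSample = data.frame, groupStats = data.frame)`:
#'   per-sample `dCt`, `ddCt` and `fold`; per-group mean fold and SD.
#' @examples
#' ct <- data.frame(
#'     sample_id = rep(c("p1", "c1"), each = 2),
#'     group = rep(c("pubertal", "prepubertal"), each = 2),
#'     gene = rep(c("tgt", "beta-actin"), 2),
#'     replicate = 1,
#'     ct = c(20, 15, 24, 15))
#' ddctFoldChange(ct, "tgt", "prepubertal")$perSample$fold  # 16, 1
#' @export
ddctFoldChange <- function(ct, targetGene, calibratorGroup,
                           referenceGene = "beta-actin") {
    ct <- validateCtTable(ct)
    if (!calibratorGroup %in% ct$group)
        stop("calibrator group '", calibratorGroup, "' not in Ct table")
    samples <- unique(ct[, c("sample_id", "group")])
    meanCt <- function(sid, gene) {
        v <- ct$ct[ct$sample_id == sid & ct$gene == gene]
        if (length(v) == 0L) NA_real_ else mean(v)
    }
    tgt <- vapply(samples$sample_id, meanCt, numeric(1), gene = targetGene)
    ref <- vapply(samples$sample_id, meanCt, numeric(1), gene = referenceGene)
    if (anyNA(ref))
        stop("reference gene '", referenceGene, "' not measured in sample(s): ",
             paste(samples$sample_id[is.na(ref)], collapse = ", "))
    if (anyNA(tgt))
        stop("target gene '", targetGene, "' not measured in sample(s): ",
             paste(samples$sample_id[is.na(tgt)], collapse = ", "))
    dCt <- tgt - ref
    calMean <- mean(dCt[samples$group == calibratorGroup])
    ddCt <- dCt - calMean
    fold <- 2^(-ddCt)
    perSample <- data.frame(sample_id = samples$sample_id,
                            group = samples$group, dCt = unname(dCt),
                            ddCt = unname(ddCt), fold = unname(fold),
                            stringsAsFactors = FALSE, row.names = NULL)
    groupStats <- do.call(rbind, lapply(unique(samples$group), function(g) {
        f <- fold[samples$group == g]
        data.frame(group = g, mean_fold = mean(f), sd_fold = sd(f),
                   n = length(f), stringsAsFactors = FALSE)
    }))
    list(perSample = perSample, groupStats = groupStats)
}

#' Two-group t-test on qPCR values with significance stars
#'
#' Equal-variance two-sided independent-samples t-test, by default on
#' dCt values (approximately normal), with the `*` (p < 0.05) / `**`
#' (p < 0.01) star convention.  When both groups have zero variance the
#' test degenerates: p = 1 for equal means, p = 0 otherwise.
#'
#' @param x,y Numeric vectors (>= 2 values each), e.g. per-sample dCt
#'   of the two groups.
#' @return `list(pvalue =, stars =)`.
#' @export
groupTtest <- function(x, y) {
    if (length(x) < 2L || length(y) < 2L)
        stop("at least 2 values per group are required")
    if (sd(x) == 0 && sd(y) == 0) {
        p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    } else {
        p <- t.test(x, y, var.equal = TRUE)$p.value
    }
    stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""
    list(pvalue = p, stars = stars)
}

#' qPCR analysis of one target gene
#'
#' Convenience wrapper: [ddctFoldChange()] plus [groupTtest()] on the
#' per-sample dCt values of the two groups.
#'
#' @inheritParams ddctFoldChange
#' @param testOn `"dCt"` (default) or `"fold"`: the scale the t-test
#'   is run on.
#' @return A one-row data.frame: `gene`, mean fold and SD per group,
#'   `pvalue`, `stars`.
#' @export
qpcrAnalysis <- function(ct, targetGene, calibratorGroup,
                         referenceGene = "beta-actin", testOn = c("dCt", "fold")) {
    testOn <- match.arg(testOn)
    res <- ddctFoldChange(ct, targetGene, calibratorGroup, referenceGene)
    ps <- res$perSample
    groupsv <- unique(ps$group)
    other <- setdiff(groupsv, calibratorGroup)
    col <- if (testOn == "dCt") "dCt" else "fold"
    tt <- groupTtest(ps[[col]][ps$group == other],
                     ps[[col]][ps$group == calibratorGroup])
    gs <- res$groupStats
    data.frame(gene = targetGene,
               calibrator_group = calibratorGroup,
               calibrator_mean_fold = gs$mean_fold[gs$group == calibratorGroup],
               calibrator_sd = gs$sd_fold[gs$group == calibratorGroup],
               case_group = other,
               case_mean_fold = gs$mean_fold[gs$group == other],
               case_sd = gs$sd_fold[gs$group == other],
               pvalue = tt$pvalue, stars = tt$stars,
               stringsAsFactors = FALSE, row.names = NULL)
}
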