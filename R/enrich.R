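# EASE-score functional enrichment: the one-sided Fisher exact
# (hypergeometric upper tail) test with the EASE jackknife (one query
# gene removed from the category overlap), Benjamini-Hochberg
# correction across tested terms.

.checkCounts <- function(k, K, n, N) {
    if (any(c(k, K, n, N) < 0) || any(c(k, K, n, N) != round(c(k, K, n, N))))
        stop("contingency counts must be non-negative integers")
    if (K > N || n > N) stop("K and n must not exceed N")
    if (k > min(K, n)) stop("k must not exceed min(K, n)")
    invisible(TRUE)
}

#' One-sided Fisher exact test (hypergeometric upper tail)
#'
#' Probability of observing `k` or more query genes in a category of
#' size `K`, for a query of size `n` drawn from a background of size
#' `N`: `P(X >= k)` for `X ~ Hypergeometric(K, N - K, n)`.
#'
#' @param k Query genes in the term.
#' @param K Background genes in the term.
#' @param n Query size.
#' @param N Background size.
#' @return The upper-tail p-value in `[0, 1]`.
#' @examples
#' fisherOneSided(0, 5, 5, 50)   # 1
#' @export
fisherOneSided <- function(k, K, n, N) {
    .checkCounts(k, K, n, N)
    if (k == 0) return(1)
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE score
#'
#' The conservative variant of the one-sided Fisher exact test used
#' for functional enrichment: one query gene is removed from the
#' category overlap before testing, `ease(k) = fisher(max(k - 1, 0))`,
#' so single-gene categories can never be significant.  Always at
#' least as large as the plain Fisher p.
#'
#' @inheritParams fisherOneSided
#' @return The EASE p-value in `[0, 1]`.
#' @export
easeScore <- function(k, K, n, N) {
    .checkCounts(k, K, n, N)
    fisherOneSided(max(k - 1, 0), K, n, N)
}

#' Term enrichment of a gene set
#'
#' Tests every term with at least one query member for
#' over-representation of the query against the background, reporting
#' both the plain one-sided Fisher p and the EASE score, with
#' Benjamini-Hochberg q-values over the tested terms.  Terms with no
#' background members are skipped.
#'
#' @param queryGenes Character vector of query gene ids (must be a
#'   subset of the background).
#' @param termMap Named list of character vectors (term id -> gene
#'   ids), or a two-column data.frame `(term_id, gene_id)`.
#' @param backgroundGenes Character vector of background gene ids.
#' @param alpha Significance threshold applied to the EASE p (default
#'   0.05).
#' @return A data.frame sorted by `ease_p` with columns `term_id`,
#'   `k`, `K`, `n`, `N`, `ease_p`, `fisher_p`, `bh_q`, `significant`.
#' @export
enrichTargets <- function(queryGenes, termMap, backgroundGenes,
                          alpha = 0.05) {
    if (is.data.frame(termMap)) {
        stopifnot(ncol(termMap) >= 2L)
        termMap <- split(as.character(termMap[[2L]]),
                         as.character(termMap[[1L]]))
    }
    queryGenes <- unique(queryGenes)
    backgroundGenes <- unique(backgroundGenes)
    offenders <- setdiff(queryGenes, backgroundGenes)
    if (length(offenders))
        stop("query gene(s) absent from background: ",
             paste(head(offenders, 10L), collapse = ", "))
    empty <- data.frame(term_id = character(), k = integer(), K = integer(),
                        n = integer(), N = integer(), ease_p = numeric(),
                        fisher_p = numeric(), bh_q = numeric(),
                        significant = logical(), stringsAsFactors = FALSE)
    if (length(queryGenes) == 0L || length(termMap) == 0L) return(empty)
    N <- length(backgroundGenes)
    n <- length(queryGenes)
    rows <- lapply(names(termMap), function(tid) {
        genes <- intersect(unique(termMap[[tid]]), backgroundGenes)
        K <- length(genes)
        if (K == 0L) return(NULL)
        k <- length(intersect(genes, queryGenes))
        if (k == 0L) return(NULL)
        data.frame(term_id = tid, k = k, K = K, n = n, N = N,
                   ease_p = easeScore(k, K, n, N),
                   fisher_p = fisherOneSided(k, K, n, N),
                   stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    out$bh_q <- p.adjust(out$ease_p, method = "BH")
    out$significant <- out$ease_p < alpha
    out <- out[order(out$ease_p, out$term_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}
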