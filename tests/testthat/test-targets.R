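# Cis window targeting (with brute-force oracle), Pearson
# correlation, trans targeting and the merged report.

.geneAt <- function(start, end, id = "g1") makeGenes(setNames(list(
    list(chrom = "chr1", strand = "+", exonStarts = start,
         exonEnds = end)), id))

.lncAt <- function(start, end, id = "l1") makeTs(setNames(list(
    list(chrom = "chr1", strand = "+", starts = start, ends = end,
         gene = paste0(id, "_loc"))), id))

test_that("cis windows are inclusive with gap distances", {
    # abutting: distance 0, smallest window
    res <- cisTargets(.lncAt(1000, 2000), .geneAt(2001, 3000))
    expect_equal(res$distance, 0)
    expect_equal(res$window, 10000)
    # gap exactly 10 kb is still inside the 10 kb window
    res <- cisTargets(.lncAt(1000, 2000), .geneAt(12001, 13000))
    expect_equal(res$distance, 10000)
    expect_equal(res$window, 10000)
    # one base beyond falls into the 100 kb window
    res <- cisTargets(.lncAt(1000, 2000), .geneAt(12002, 13000))
    expect_equal(res$distance, 10001)
    expect_equal(res$window, 100000)
    # beyond 100 kb: no pair
    res <- cisTargets(.lncAt(1000, 2000), .geneAt(102002, 103000))
    expect_equal(nrow(res), 0)
    # overlap: distance 0
    res <- cisTargets(.lncAt(1000, 2500), .geneAt(2001, 3000))
    expect_equal(res$distance, 0)
})

test_that("cis targeting equals the brute-force scan on random fixtures", {
    set.seed(61)
    for (rep in 1:300) {
        nL <- sample(2:6, 1); nG <- sample(3:10, 1)
        lncDf <- data.frame(id = sprintf("l%02d", 1:nL),
                            chrom = sample(c("chr1", "chr2"), nL, TRUE),
                            start = sample.int(500000, nL))
        lncDf$end <- lncDf$start + sample(200:3000, nL, TRUE)
        geneDf <- data.frame(id = sprintf("g%02d", 1:nG),
                             chrom = sample(c("chr1", "chr2"), nG, TRUE),
                             start = sample.int(500000, nG))
        geneDf$end <- geneDf$start + sample(500:8000, nG, TRUE)
        spans <- GenomicRanges::GRanges(lncDf$chrom,
            IRanges::IRanges(lncDf$start, lncDf$end), "+")
        S4Vectors::mcols(spans)$transcript_id <- lncDf$id
        gs <- GenomicRanges::GRanges(geneDf$chrom,
            IRanges::IRanges(geneDf$start, geneDf$end), "+")
        S4Vectors::mcols(gs)$gene_id <- geneDf$id
        S4Vectors::mcols(gs)$biotype <- "protein_coding"
        names(gs) <- geneDf$id
        ga <- GeneAnnotation(gs)
        got <- cisTargets(spans, ga)
        want <- oracleCis(lncDf, geneDf)
        expect_equal(nrow(got), nrow(want), info = sprintf("rep %d", rep))
        if (nrow(want)) {
            expect_identical(got$lnc_id, want$lnc_id)
            expect_identical(got$gene_id, want$gene_id)
            expect_equal(got$distance, want$distance)
            expect_equal(got$window, want$window)
        }
    }
})

test_that("cis pairs are invariant under genome reflection", {
    st <- smallStudy()
    lnc <- st$transcripts[st$truth$true_lnc_ids]
    before <- cisTargets(lnc, st$genes)
    L <- 2e6
    reflect <- function(gr) {
        GenomicRanges::GRanges(seqnames(gr),
            IRanges::IRanges(L - end(gr), L - start(gr)), strand(gr))
    }
    spans <- transcriptSpans(lnc)
    rs <- reflect(spans)
    S4Vectors::mcols(rs)$transcript_id <- S4Vectors::mcols(spans)$transcript_id
    gs <- geneSpans(st$genes)
    rg <- reflect(gs)
    S4Vectors::mcols(rg) <- S4Vectors::mcols(gs)
    names(rg) <- names(gs)
    after <- cisTargets(rs, GeneAnnotation(rg))
    key <- function(df) paste(df$lnc_id, df$gene_id, df$distance, df$window)
    expect_setequal(key(after), key(before))
})

test_that("pearsonR matches direct evaluation and affine limits", {
    x <- c(1, 2, 3, 4, 5, 6)
    expect_equal(pearsonR(x, x), 1)
    expect_equal(pearsonR(x, -2 * x + 7), -1)
    y <- c(2, 1, 4, 3, 6, 5)
    expect_equal(pearsonR(x, y), oraclePearson(x, y))
    expect_equal(pearsonR(x, y), 29 / 35, tolerance = 1e-10)
    set.seed(62)
    for (rep in 1:20) {
        a <- runif(1, 0.1, 5); b <- runif(1, -3, 3)
        u <- rnorm(6); v <- rnorm(6)
        expect_equal(pearsonR(a * u + b, v), pearsonR(u, v),
                     tolerance = 1e-10)
    }
    expect_warning(r <- pearsonR(rep(1, 4), c(1, 2, 3, 4)), "zero variance")
    expect_true(is.na(r))
    expect_error(pearsonR(1:2, 1:2), "at least 3")
})

test_that("trans threshold is strict and zero-variance rows are skipped", {
    # equal column sums keep FPKM proportional to counts, so the
    # doubled row has correlation exactly 1 with lnc1
    cnt <- matrix(c(10L, 20L, 30L, 40L, 50L, 60L,
                    20L, 40L, 60L, 80L, 100L, 120L,
                    5L, 5L, 5L, 5L, 5L, 5L,
                    165L, 135L, 105L, 75L, 45L, 15L), 4, 6, byrow = TRUE,
                  dimnames = list(c("lnc1", "geneDouble", "geneFlat",
                                    "filler"),
                                  sprintf("s%d", 1:6)))
    expect_true(all(colSums(cnt) == 200L))
    ed <- makeExpr(cnt)
    fp <- fpkm(ed)
    expect_equal(cor(fp["lnc1", ], fp["geneDouble", ]), 1)
    # r == threshold is excluded (strict inequality), r > threshold kept
    at <- suppressMessages(transTargets(ed, "lnc1", "geneDouble",
                                        threshold = 1))
    expect_equal(nrow(at), 0)
    below <- suppressMessages(transTargets(ed, "lnc1", "geneDouble",
                                           threshold = 0.999))
    expect_equal(nrow(below), 1)
    expect_equal(below$r, 1)
    expect_message(transTargets(ed, "lnc1", "geneFlat"), "zero-variance")
    res <- suppressMessages(transTargets(ed, "lnc1",
                                         c("geneDouble", "geneFlat"),
                                         threshold = 0.95))
    expect_false("geneFlat" %in% res$gene_id)
    expect_error(transTargets(makeExpr(cnt[, 1:2],
                                       groups = c("a", "b")), "lnc1",
                              "geneDouble"),
                 "at least 3 samples")
})

test_that("trans targeting equals the exhaustive correlation oracle", {
    set.seed(63)
    n <- 60
    cnt <- matrix(rpois(2 * n * 6, 40), 2 * n, 6,
                  dimnames = list(c(sprintf("l%03d", 1:n),
                                    sprintf("g%03d", 1:n)),
                                  sprintf("s%d", 1:6)))
    ed <- makeExpr(cnt)
    fp <- fpkm(ed)
    lids <- sprintf("l%03d", 1:n); gids <- sprintf("g%03d", 1:n)
    thr <- 0.7
    got <- suppressMessages(transTargets(ed, lids, gids, threshold = thr))
    want <- list()
    for (i in lids) for (j in gids) {
        if (sd(fp[i, ]) == 0 || sd(fp[j, ]) == 0) next
        r <- oraclePearson(fp[i, ], fp[j, ])
        if (r > thr || r < -thr)
            want[[length(want) + 1]] <- data.frame(lnc_id = i, gene_id = j,
                                                   r = r)
    }
    want <- if (length(want)) do.call(rbind, want) else
        data.frame(lnc_id = character(), gene_id = character(), r = numeric())
    want <- want[order(want$lnc_id, want$gene_id), ]
    expect_equal(nrow(got), nrow(want))
    expect_identical(got$lnc_id, want$lnc_id)
    expect_identical(got$gene_id, want$gene_id)
    expect_equal(got$r, want$r, tolerance = 1e-12)
})

test_that("planted trans pairs are recovered at tiny dispersion", {
    st <- smallStudyTinyDisp()
    tr <- st$truth$trans_pairs
    res <- suppressMessages(transTargets(st$expr, tr$lnc_id, tr$coding_tx))
    found <- paste(res$lnc_id, res$gene_id)
    expect_true(all(paste(tr$lnc_id, tr$coding_tx) %in% found))
})

test_that("the merged target table counts cis and trans per lncRNA", {
    cis <- data.frame(lnc_id = "l1", gene_id = "gA", mode = "cis",
                      window = 10000, distance = 0)
    trans <- data.frame(lnc_id = c("l1", "l1"), gene_id = c("gB", "gC"),
                        mode = "trans", r = c(0.99, -0.97))
    tab <- targetTable(cis, trans)
    expect_equal(nrow(tab), 1)
    expect_equal(tab$n_cis, 1)
    expect_equal(tab$n_trans, 2)
    expect_identical(tab$trans_targets, "gB,gC")
    expect_equal(nrow(targetTable(cis[0, ], trans[0, ])), 0)
})
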