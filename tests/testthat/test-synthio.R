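# Synthetic-study generator: determinism, planted geometry, planted
# expression effects, planted means.

test_that("identical seeds reproduce the study; different seeds move loci", {
    a <- suppressMessages(simulateStudy(smallConfig(seed = 5)))
    b <- suppressMessages(simulateStudy(smallConfig(seed = 5)))
    expect_identical(assay(a$expr, "counts"), assay(b$expr, "counts"))
    expect_identical(as.character(spliceSequences(a$transcripts)),
                     as.character(spliceSequences(b$transcripts)))
    expect_identical(a$truth, b$truth)
    expect_identical(start(transcriptSpans(a$transcripts)),
                     start(transcriptSpans(b$transcripts)))
    c <- suppressMessages(simulateStudy(smallConfig(seed = 6)))
    expect_false(identical(start(transcriptSpans(a$transcripts)),
                           start(transcriptSpans(c$transcripts))))
})

test_that("degenerate class fractions give a single class", {
    cfg <- smallConfig(seed = 3,
                       lncClassFractions = c(lincRNA = 1, antisense = 0,
                                             intronic = 0))
    ann <- generateAnnotation(cfg)
    expect_true(all(ann$truth$biotype == "lincRNA"))
})

test_that("zero cis offsets plant abutting lncRNA-gene pairs", {
    cfg <- smallConfig(seed = 4, plantedCisWindows = 0)
    ann <- generateAnnotation(cfg)
    cis <- ann$truth$cis_pairs
    expect_gt(nrow(cis), 0)
    expect_true(all(cis$distance == 0))
    # verified on the emitted coordinates, not just the truth record
    spans <- transcriptSpans(ann$transcripts)
    gs <- geneSpans(ann$genes)
    for (i in seq_len(nrow(cis))) {
        l <- spans[S4Vectors::mcols(spans)$transcript_id == cis$lnc_id[i]]
        g <- gs[S4Vectors::mcols(gs)$gene_id == cis$gene_id[i]]
        expect_equal(GenomicRanges::distance(l, g, ignore.strand = TRUE), 0)
    }
})

test_that("a chromosome too short to host the loci names the failure", {
    cfg <- smallConfig(seed = 2, chromLength = 4000)
    expect_error(generateAnnotation(cfg), "too short to place locus")
})

test_that("planted coding ORFs are ATG-initiated, stop-terminated and long", {
    st <- smallStudy()
    seqs <- spliceSequences(st$transcripts)
    for (id in head(st$truth$true_coding_ids, 15)) {
        s <- as.character(seqs[[id]])
        lo <- longestOrf(findOrfs(s))
        expect_equal(nrow(lo), 1)
        expect_identical(substr(s, lo$start, lo$start + 2), "ATG")
        expect_true(substr(s, lo$end - 2, lo$end) %in% c("TAA", "TAG", "TGA"))
        expect_gte(lo$length / nchar(s), 0.5)
    }
})

test_that("lncRNA sequences match spliced lengths and have short ORFs", {
    st <- smallStudy()
    seqs <- spliceSequences(st$transcripts)
    len <- splicedLengths(st$transcripts)
    expect_identical(unname(Biostrings::width(seqs[transcriptIds(st$transcripts)])),
                     unname(len))
    orfLens <- vapply(st$truth$true_lnc_ids, function(id) {
        lo <- longestOrf(findOrfs(as.character(seqs[[id]])))
        if (nrow(lo) == 0) 0L else lo$length
    }, integer(1))
    expect_true(all(orfLens <= len[st$truth$true_lnc_ids]))
    expect_lt(mean(orfLens), 200)   # incidental ORFs stay near the planted mean
})

test_that("generator recovers the configured lncRNA means over 1000+ loci", {
    cfg <- synthConfig(seed = 21, nCodingGenes = 300L, nLncLoci = 1100L,
                       nPlantedCis = 15L, chromLength = 8e6,
                       nChromosomes = 3L)
    ann <- generateAnnotation(cfg)
    lnc <- ann$truth$true_lnc_ids
    expect_gte(length(lnc), 1000)
    lenMean <- mean(splicedLengths(ann$transcripts)[lnc])
    expect_lt(abs(lenMean - cfg$lncLengthMean) / cfg$lncLengthMean, 0.05)
    exMean <- mean(exonCounts(ann$transcripts)[lnc])
    expect_lt(abs(exMean - cfg$lncExonMean) / cfg$lncExonMean, 0.05)
    lncOnly <- ann$transcripts[lnc]
    lncOnly <- generateSequences(lncOnly, ann$truth, cfg)
    seqs <- spliceSequences(lncOnly)
    orfMean <- mean(vapply(lnc, function(id) {
        lo <- longestOrf(findOrfs(as.character(seqs[[id]])))
        if (nrow(lo) == 0) 0 else as.numeric(lo$length)
    }, numeric(1)))
    expect_lt(abs(orfMean - cfg$lncOrfMean) / cfg$lncOrfMean, 0.05)
})

test_that("null DE configuration plants nothing", {
    cfg <- smallConfig(seed = 8, deFraction = 0)
    ann <- generateAnnotation(cfg)
    cts <- generateCounts(ann$transcripts, ann$truth, cfg)
    expect_length(cts$truth$de_ids, 0)
})

test_that("planted fold change matches the configured log2fc", {
    # large libraries + tiny dispersion make the empirical group-mean
    # ratio converge on 2^deLog2fc
    cfg <- smallConfig(seed = 9, deLog2fc = 1, nbDispersion = 1e-9,
                       librarySizes = rep(1e8, 6))
    ann <- generateAnnotation(cfg)
    cts <- generateCounts(ann$transcripts, ann$truth, cfg)
    cnt <- assay(cts$expr, "counts")
    grp <- sampleGroups(cts$expr)
    for (id in head(cts$truth$de_ids, 10)) {
        ratio <- mean(cnt[id, grp == "pubertal"]) /
            mean(cnt[id, grp == "prepubertal"])
        dir <- cts$truth$de_direction[[id]]
        expect_equal(log2(ratio), if (dir == "up") 1 else -1,
                     tolerance = 0.05)
    }
})

test_that("perfectly correlated planting reaches r ~ 1 at tiny dispersion", {
    cfg <- smallConfig(seed = 10, transTargetR = 1, nbDispersion = 1e-9)
    ann <- generateAnnotation(cfg)
    cts <- generateCounts(ann$transcripts, ann$truth, cfg)
    fp <- fpkm(cts$expr)
    tr <- cts$truth$trans_pairs
    r <- vapply(seq_len(nrow(tr)), function(i)
        cor(fp[tr$lnc_id[i], ], fp[tr$coding_tx[i], ]), numeric(1))
    expect_true(all(r > 0.99))
})

test_that("the planted term is the most enriched for its query", {
    st <- smallStudy()
    enr <- enrichTargets(st$truth$query_genes, st$termMap,
                         geneIds(st$genes))
    expect_identical(enr$term_id[1], st$truth$planted_term_id)
    expect_lt(enr$ease_p[1], min(enr$ease_p[-1]) + 1e-12)
    # a term with no query member is never tested (and scores 1)
    expect_false("TERM_ABSENT" %in% enr$term_id)
    expect_equal(easeScore(0, 10, length(st$truth$query_genes),
                           length(geneIds(st$genes))), 1)
})

test_that("group-specific lncRNAs have zero counts off-group", {
    st <- smallStudyTinyDisp()
    cnt <- assay(st$expr, "counts")
    grp <- sampleGroups(st$expr)
    gs <- st$truth$group_specific
    for (g in names(gs)) {
        off <- grp != g
        if (length(gs[[g]]))
            expect_true(all(cnt[gs[[g]], off] == 0))
    }
})

test_that("sample count below 2 per group is rejected", {
    expect_error(smallConfig(nSamplesPerGroup = 1L), NA)
    cfg <- smallConfig(seed = 2, nSamplesPerGroup = 1L,
                       librarySizes = rep(1e6, 2))
    ann <- generateAnnotation(cfg)
    expect_error(generateCounts(ann$transcripts, ann$truth, cfg),
                 "at least 2 samples")
})

test_that("class fractions must sum to one", {
    expect_error(synthConfig(lncClassFractions = c(0.5, 0.2, 0.2)),
                 "sum to 1")
})
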