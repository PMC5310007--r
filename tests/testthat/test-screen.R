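# Screening: ORF finding (with exhaustive oracle), the three
# coding-potential scorers, the basic filter and the consensus rule.

test_that("findOrfs matches hand-derived cases", {
    orfs <- findOrfs("ATGAAATAG")
    expect_equal(nrow(orfs), 1)
    expect_equal(orfs$length, 9)
    expect_identical(orfs$peptide, "MK")
    expect_false(orfs$incomplete)

    expect_equal(nrow(findOrfs("CCCCCCTTTT")), 0)

    nested <- findOrfs("ATGATGTAA")
    f0 <- nested[nested$frame == 0, ]
    expect_equal(sort(f0$start), c(1, 4))
    expect_equal(max(f0$length), 9)
})

test_that("ATG runs without a stop are incomplete and not the longest ORF", {
    orfs <- findOrfs("ATGAAAAAA")
    expect_true(all(orfs$incomplete[orfs$frame == 0]))
    expect_equal(nrow(longestOrf(orfs)), 0)
    # an N-containing codon is never a start or stop
    expect_equal(nrow(findOrfs("ANGAAATAG")), 0)
    orfs <- findOrfs("ATGTANAAATAGCC")
    expect_equal(longestOrf(orfs)$length, 12)   # TAN is not a stop
})

test_that("findOrfs agrees with the exhaustive positional scan", {
    set.seed(31)
    for (rep in 1:200) {
        n <- sample(0:60, 1)
        seq <- paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                            prob = c(24, 24, 24, 24, 4)), collapse = "")
        got <- findOrfs(seq)
        want <- oracleOrfs(seq)
        got <- got[order(got$frame, got$start), ]
        want <- want[order(want$frame, want$start), ]
        expect_equal(nrow(got), nrow(want), info = seq)
        if (nrow(want)) {
            expect_equal(got$start, want$start, info = seq)
            expect_equal(got$end, want$end, info = seq)
            expect_equal(as.integer(got$incomplete), want$incomplete,
                         info = seq)
        }
    }
})

test_that("ORF-extent scorer applies inclusive thresholds", {
    expect_identical(orfCodingScore(0, 1000)$call, "noncoding")
    expect_identical(orfCodingScore(0, 1000)$score, 0)
    expect_identical(orfCodingScore(300, 600)$call, "coding")   # coverage 0.5
    expect_identical(orfCodingScore(300, 10000)$call, "coding") # length 300
    expect_identical(orfCodingScore(105, 1180)$call, "noncoding")
    expect_identical(orfCodingScore(299, 10000)$call, "noncoding")
})

test_that("triplet scorer is symmetric under identical tables", {
    tab <- defaultHexamerTables()
    same <- list(coding = tab$coding, noncoding = tab$coding)
    res <- tripletCodingScore("ATGCATGCATGCATGC", tables = same)
    expect_equal(res$score, 0)
    expect_identical(res$call, "noncoding")
    short <- tripletCodingScore("ATGC")
    expect_equal(short$score, 0)
    expect_identical(short$call, "noncoding")
})

test_that("triplet scorer separates coding-model from background sequences", {
    set.seed(32)
    usage <- codonUsageTable()
    codingSeqs <- vapply(1:100, function(i)
        paste(sample(names(usage), 120, replace = TRUE, prob = usage),
              collapse = ""), character(1))
    bgSeqs <- vapply(1:100, function(i)
        paste(sample(c("A", "C", "G", "T"), 360, replace = TRUE),
              collapse = ""), character(1))
    expect_gte(mean(tripletCodingScore(codingSeqs)$call == "coding"), 0.95)
    expect_gte(mean(tripletCodingScore(bgSeqs)$call == "noncoding"), 0.95)
})

test_that("motif scan hits verbatim motifs and respects ORF segmentation", {
    motif <- defaultMotifLibrary()[1]
    hit <- motifScan(paste0("ATG", encodePeptide(motif), "TAA"))
    expect_true(hit$motifHit)
    expect_identical(hit$call, "coding")

    # motif peptide split across a stop codon: halves live in separate
    # ORF translations, so no hit
    left <- substr(motif, 2, 5); right <- substr(motif, 6, nchar(motif))
    seq <- paste0("ATG", encodePeptide(left), "TAA", encodePeptide(right))
    expect_false(motifScan(seq)$motifHit)

    expect_warning(res <- motifScan("ATGAAATAG", motifLibrary = character(0)),
                   "empty motif library")
    expect_identical(res$call, "noncoding")
})

test_that("basic filter applies strict length, exon and FPKM rules", {
    spec <- list(
        short = list(chrom = "chr1", strand = "+", starts = 1,
                     ends = 200, gene = "gA"),            # length 200: out
        mono = list(chrom = "chr1", strand = "+", starts = 1000,
                    ends = 1300, gene = "gB"),            # 1 exon
        silent = list(chrom = "chr1", strand = "+", starts = 2000,
                      ends = 2400, gene = "gC"),          # no expression
        good = list(chrom = "chr1", strand = "+", starts = c(3000, 3500),
                    ends = c(3200, 3700), gene = "gD"))
    ts <- makeTs(spec)
    cnt <- matrix(c(9L, 9L, 9L, 9L, 0L, 0L, 9L, 9L), 4, 2, byrow = TRUE,
                  dimnames = list(names(spec), c("s1", "s2")))
    ed <- makeExpr(cnt, lengths = setNames(splicedLengths(ts), names(spec)),
                   groups = c("ctrl", "case"))
    res <- basicFilter(ts, ed, minLength = 200, minExons = 2, minFpkm = 0.5)
    expect_setequal(transcriptIds(res$kept), "good")
    expect_equal(unname(res$attrition["length"]), 1)
    expect_equal(unname(res$attrition["exons"]), 2)
    expect_equal(unname(res$attrition["fpkm"]), 0)   # silent fails exons first

    neutral <- basicFilter(ts, ed, minLength = 200, minExons = 1, minFpkm = 0)
    expect_setequal(transcriptIds(neutral$kept), c("mono", "silent", "good"))

    zeroRow <- basicFilter(ts, ed, minLength = 100, minExons = 1, minFpkm = 0.5)
    expect_false("silent" %in% transcriptIds(zeroRow$kept))

    expect_error(basicFilter(ts, makeExpr(cnt[1:2, , drop = FALSE],
                                          groups = c("ctrl", "case"))),
                 "absent from expression")
})

test_that("consensus keeps only transcripts all scorers call noncoding", {
    v <- data.frame(transcript_id = c("a", "b", "c"),
                    orf_call = c("noncoding", "coding", "noncoding"),
                    triplet_call = c("noncoding", "noncoding", "noncoding"),
                    motif_call = c("noncoding", "noncoding", "coding"),
                    stringsAsFactors = FALSE)
    expect_identical(consensusCall(v), "a")
    expect_length(consensusCall(v[0, ]), 0)
    expect_error(consensusCall(v[, -2]), "missing scorer output")
})

test_that("flipping any call to coding never enlarges the candidate set", {
    set.seed(33)
    for (rep in 1:25) {
        n <- 12
        v <- data.frame(
            transcript_id = sprintf("t%02d", 1:n),
            orf_call = sample(c("coding", "noncoding"), n, replace = TRUE),
            triplet_call = sample(c("coding", "noncoding"), n, replace = TRUE),
            motif_call = sample(c("coding", "noncoding"), n, replace = TRUE),
            stringsAsFactors = FALSE)
        before <- consensusCall(v)
        col <- sample(c("orf_call", "triplet_call", "motif_call"), 1)
        i <- sample(n, 1)
        v[[col]][i] <- "coding"
        expect_true(all(consensusCall(v) %in% before))
    }
})

test_that("screening the synthetic study recovers the planted classes", {
    st <- smallStudy()
    res <- screenTranscripts(st$transcripts, st$expr)
    cand <- transcriptIds(res$candidates)
    expect_gte(mean(st$truth$true_lnc_ids %in% cand), 0.95)
    expect_lte(mean(st$truth$true_coding_ids %in% cand), 0.05)
    expect_identical(
        sort(consensusCall(res$verdicts)),
        sort(res$verdicts$transcript_id[res$verdicts$consensus == "noncoding"]))
})

test_that("external scorer tables bypass the internal scorers", {
    st <- smallStudy()
    ids <- transcriptIds(st$transcripts)
    ext <- data.frame(transcript_id = ids,
                      orf_call = ifelse(ids %in% st$truth$true_lnc_ids,
                                        "noncoding", "coding"),
                      triplet_call = "noncoding", motif_call = "noncoding",
                      stringsAsFactors = FALSE)
    res <- screenTranscripts(st$transcripts, st$expr, externalCalls = ext)
    expect_setequal(transcriptIds(res$candidates),
                    intersect(ids[ext$orf_call == "noncoding"],
                              res$verdicts$transcript_id))
})
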