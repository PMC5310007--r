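# Format IO: GTF coordinate handling, round trips, counts/design
# validation.

test_that("GTF records keep 1-based inclusive coordinates and lengths", {
    path <- withr::local_tempfile(fileext = ".gtf")
    writeLines(paste("chr1\tsrc\texon\t100\t200\t.\t+\t.",
                     'gene_id "g1"; transcript_id "t1";', sep = "\t"), path)
    got <- suppressMessages(readGtf(path))
    ex <- transcriptExons(got$transcripts)[["t1"]]
    expect_equal(start(ex), 100)
    expect_equal(end(ex), 200)
    expect_equal(unname(splicedLengths(got$transcripts)[["t1"]]), 101)
})

test_that("out-of-order exon rows are stored sorted", {
    path <- withr::local_tempfile(fileext = ".gtf")
    writeLines(c(
        paste("chr1\tsrc\texon\t300\t399\t.\t+\t.",
              'gene_id "g1"; transcript_id "t1";', sep = "\t"),
        paste("chr1\tsrc\texon\t100\t199\t.\t+\t.",
              'gene_id "g1"; transcript_id "t1";', sep = "\t")), path)
    got <- suppressMessages(readGtf(path))
    expect_equal(start(transcriptExons(got$transcripts)[["t1"]]), c(100, 300))
})

test_that("exon rows without transcript_id are a parse error", {
    path <- withr::local_tempfile(fileext = ".gtf")
    writeLines(paste("chr1\tsrc\texon\t100\t200\t.\t+\t.",
                     'gene_id "g1";', sep = "\t"), path)
    expect_error(suppressMessages(readGtf(path)), "transcript_id")
})

test_that("GTF write/read round-trips arbitrary transcript sets", {
    set.seed(71)
    for (rep in 1:20) {
        nTx <- sample(1:6, 1)
        spec <- lapply(seq_len(nTx), function(i) {
            k <- sample(1:4, 1)
            w <- sample(30:200, k, replace = TRUE)
            gaps <- if (k > 1) sample(50:400, k - 1, replace = TRUE) else integer(0)
            starts <- cumsum(c(sample(1:5000, 1), head(w, -1) + gaps))
            list(chrom = sample(c("chr1", "chr2"), 1),
                 strand = sample(c("+", "-"), 1),
                 starts = starts, ends = starts + w - 1)
        })
        names(spec) <- sprintf("tx%02d", seq_len(nTx))
        for (i in seq_along(spec))
            spec[[i]]$gene <- sprintf("g_%s_%s%d", spec[[i]]$chrom,
                                      spec[[i]]$strand, sample(1:2, 1))
        ts <- makeTs(spec)
        path <- withr::local_tempfile(fileext = ".gtf")
        writeGtf(ts, path)
        back <- suppressMessages(readGtf(path))$transcripts
        ids <- transcriptIds(ts)
        expect_setequal(transcriptIds(back), ids)
        for (id in ids) {
            a <- transcriptExons(back)[[id]]
            b <- transcriptExons(ts)[[id]]
            expect_identical(as.character(seqnames(a)), as.character(seqnames(b)))
            expect_identical(start(a), start(b))
            expect_identical(end(a), end(b))
            expect_identical(as.character(strand(a)), as.character(strand(b)))
        }
        expect_identical(geneIds(back)[ids], geneIds(ts)[ids])
    }
})

test_that("gene biotype and extra attributes survive the round trip", {
    st <- smallStudy()
    dir <- withr::local_tempdir()
    annotTs <- TranscriptSet(geneExons(st$genes),
                             geneId = setNames(geneIds(st$genes),
                                               geneIds(st$genes)))
    writeGtf(annotTs, file.path(dir, "ann.gtf"),
             geneAttrs = geneBiotypes(st$genes))
    back <- suppressMessages(readGtf(file.path(dir, "ann.gtf")))
    expect_true(all(geneBiotypes(back$genes) == "protein_coding"))
    expect_setequal(geneIds(back$genes), geneIds(st$genes))
})

test_that("FASTA sequences round-trip at 60 columns", {
    st <- smallStudy()
    path <- withr::local_tempfile(fileext = ".fa")
    writeTranscriptFasta(st$transcripts, path)
    lines <- readLines(path)
    expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
    back <- readTranscriptFasta(path)
    expect_identical(as.character(back),
                     as.character(spliceSequences(st$transcripts)))
})

test_that("counts/design TSVs round-trip an ExpressionData", {
    cnt <- matrix(c(3L, 0L, 7L, 2L), 2,
                  dimnames = list(c("t1", "t2"), c("s1", "s2")))
    ed <- makeExpr(cnt, groups = c("ctrl", "case"))
    dir <- withr::local_tempdir()
    writeCountsTsv(ed, file.path(dir, "c.tsv"), file.path(dir, "d.tsv"))
    back <- readCountsTsv(file.path(dir, "c.tsv"), file.path(dir, "d.tsv"))
    expect_identical(assay(back, "counts"), assay(ed, "counts"))
    expect_identical(fpkm(back), fpkm(ed))
    expect_identical(as.character(sampleGroups(back)),
                     as.character(sampleGroups(ed)))
})

test_that("a 3 + 3 design yields two groups of three", {
    st <- smallStudy()
    expect_equal(unname(table(sampleGroups(st$expr))), array(c(3L, 3L)),
                 ignore_attr = TRUE)
})

test_that("count validation names the offending cell", {
    dir <- withr::local_tempdir()
    writeLines(c("transcript_id\tlength\ts1\ts2",
                 "t1\t1000\t5\t-2"), file.path(dir, "c.tsv"))
    writeLines(c("sample\tgroup", "s1\tctrl", "s2\tcase"),
               file.path(dir, "d.tsv"))
    expect_error(readCountsTsv(file.path(dir, "c.tsv"),
                               file.path(dir, "d.tsv")),
                 "row 't1', column 's2'")
})

test_that("empty count matrices and mismatched designs are rejected", {
    dir <- withr::local_tempdir()
    writeLines("transcript_id\tlength\ts1\ts2", file.path(dir, "c.tsv"))
    writeLines(c("sample\tgroup", "s1\tctrl", "s2\tcase"),
               file.path(dir, "d.tsv"))
    expect_error(readCountsTsv(file.path(dir, "c.tsv"),
                               file.path(dir, "d.tsv")), "empty")
    cnt <- matrix(1L, 2, 2, dimnames = list(c("t1", "t2"), c("s1", "s2")))
    expect_error(ExpressionData(cnt, lengths = c(t1 = 1, t2 = 1),
                                design = c(s1 = "a", s3 = "b")),
                 "missing from")
})

test_that("truth JSON round-trips scalar and vector fields", {
    x <- list(ids = c("a", "b"), n = 3,
              pairs = data.frame(p = c("x", "y"), d = c(0, 10)))
    path <- withr::local_tempfile(fileext = ".json")
    writeTruthJson(x, path)
    back <- readTruthJson(path)
    expect_identical(back$ids, x$ids)
    expect_equal(back$n, 3)
    expect_identical(back$pairs$p, c("x", "y"))
})
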