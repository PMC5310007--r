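# Deterministic synthetic-study generator.  Emits a reference gene
# annotation, assembled transcript models (coding + lncRNA) with
# spliced sequences, a negative-binomial count matrix under a
# two-group 3 vs 3 design, a term->gene map with one planted enriched
# term, and a qPCR Ct table -- together with the planted ground truth
# for every downstream stage.  Everything is a pure function of the
# configuration; the seed fully determines all output.

#' Configuration of a synthetic lncRNA study
#'
#' Defaults emulate assembled goat hypothalamus transcript models at
#' desk scale: lncRNA mean spliced length 1180 nt versus mRNA 2869 nt,
#' lncRNA longest-ORF mean 105 nt, fewer exons than mRNA, a 3 vs 3
#' prepubertal/pubertal design with negative-binomial counts, planted
#' differentially expressed transcripts at |log2FC| = 2, planted cis
#' lncRNA-gene neighbours inside the 10/100 kb windows, planted
#' trans-correlated pairs at r = 0.99, and group-specific lncRNAs.
#' The lincRNA/antisense/intronic class fractions default to
#' 0.8/0.1/0.1.
#'
#' @param seed Integer seed; fully determines every output.
#' @param nChromosomes,chromLength Genome shape (bp per chromosome).
#' @param nCodingGenes,nLncLoci Locus counts (one transcript per
#'   locus).
#' @param lncClassFractions Named proportions for `lincRNA`,
#'   `antisense`, `intronic`; must sum to 1.
#' @param lncLengthMean,mrnaLengthMean Mean spliced lengths (bp;
#'   log-normal with these means).
#' @param lncOrfMean Mean longest-ORF length planted into lncRNA
#'   sequences (nt).
#' @param lncExonMean,mrnaExonMean Mean exon counts (shifted Poisson,
#'   `1 + Pois(mean - 1)`).
#' @param nSamplesPerGroup Samples per group (default 3; >= 2).
#' @param deFraction Fraction of transcripts with planted differential
#'   expression.
#' @param deLog2fc Planted |log2 fold change|.
#' @param nbDispersion NB dispersion alpha (variance `mu + alpha mu^2`);
#'   values below 1e-8 mean Poisson counts.
#' @param plantedCisWindows Gap distances (bp) at which planted cis
#'   lincRNAs sit from their anchor gene (cycled over
#'   `nPlantedCis` loci).
#' @param nPlantedCis Number of planted cis lincRNA-gene neighbours.
#' @param plantedTransPairs Number of planted trans-correlated
#'   lncRNA-gene pairs.
#' @param transTargetR Target in-sample Pearson correlation of planted
#'   trans pairs (in `[-1, 1]`).
#' @param nGroupSpecific Group-specific lncRNAs planted per group
#'   (expected count zero in the other group).
#' @param librarySizes Per-sample library-size scalings; default 1e6
#'   each (making FPKM arithmetic human-checkable).
#' @param intergenicGap Minimum gap (bp) between placed loci.
#' @param groupLabels Two group names; the first is the
#'   reference/calibrator (control) group.
#' @return A validated list of class `SynthConfig`.
#' @export
synthConfig <- function(seed = 1L, nChromosomes = 3L, chromLength = 3e6,
                        nCodingGenes = 400L, nLncLoci = 200L,
                        lncClassFractions = c(lincRNA = 0.8, antisense = 0.1,
                                              intronic = 0.1),
                        lncLengthMean = 1180, mrnaLengthMean = 2869,
                        lncOrfMean = 105, lncExonMean = 2.8,
                        mrnaExonMean = 9, nSamplesPerGroup = 3L,
                        deFraction = 0.1, deLog2fc = 2, nbDispersion = 0.1,
                        plantedCisWindows = c(0, 5000, 50000),
                        nPlantedCis = 15L, plantedTransPairs = 20L,
                        transTargetR = 0.99, nGroupSpecific = 10L,
                        librarySizes = NULL, intergenicGap = 1000,
                        groupLabels = c("prepubertal", "pubertal")) {
    cfg <- list(seed = as.integer(seed), nChromosomes = as.integer(nChromosomes),
                chromLength = chromLength, nCodingGenes = as.integer(nCodingGenes),
                nLncLoci = as.integer(nLncLoci),
                lncClassFractions = lncClassFractions,
                lncLengthMean = lncLengthMean, mrnaLengthMean = mrnaLengthMean,
                lncOrfMean = lncOrfMean, lncExonMean = lncExonMean,
                mrnaExonMean = mrnaExonMean,
                nSamplesPerGroup = as.integer(nSamplesPerGroup),
                deFraction = deFraction, deLog2fc = deLog2fc,
                nbDispersion = nbDispersion,
                plantedCisWindows = plantedCisWindows,
                nPlantedCis = as.integer(nPlantedCis),
                plantedTransPairs = as.integer(plantedTransPairs),
                transTargetR = transTargetR,
                nGroupSpecific = as.integer(nGroupSpecific),
                librarySizes = librarySizes, intergenicGap = intergenicGap,
                groupLabels = groupLabels)
    if (is.null(cfg$librarySizes))
        cfg$librarySizes <- rep(1e6, 2L * cfg$nSamplesPerGroup)
    if (abs(sum(cfg$lncClassFractions) - 1) > 1e-9)
        stop("lncClassFractions must sum to 1")
    if (any(cfg$lncClassFractions < 0))
        stop("lncClassFractions must be non-negative")
    pos <- c("chromLength", "lncLengthMean", "mrnaLengthMean", "lncOrfMean",
             "lncExonMean", "mrnaExonMean", "intergenicGap")
    for (f in pos) if (cfg[[f]] <= 0) stop(f, " must be positive")
    if (cfg$nbDispersion < 0) stop("nbDispersion must be >= 0")
    if (abs(cfg$transTargetR) > 1) stop("transTargetR must lie in [-1, 1]")
    if (any(cfg$plantedCisWindows < 0)) stop("plantedCisWindows must be >= 0")
    if (length(cfg$groupLabels) != 2L || anyDuplicated(cfg$groupLabels))
        stop("groupLabels must be two distinct labels")
    if (length(cfg$librarySizes) != 2L * cfg$nSamplesPerGroup)
        stop("librarySizes must have one entry per sample")
    class(cfg) <- "SynthConfig"
    cfg
}

# deterministic apportioning of nLncLoci over classes
.classCounts <- function(n, fractions) {
    raw <- n * fractions
    cnt <- floor(raw)
    left <- n - sum(cnt)
    if (left > 0) {
        ord <- order(raw - cnt, decreasing = TRUE)
        cnt[ord[seq_len(left)]] <- cnt[ord[seq_len(left)]] + 1L
    }
    as.integer(cnt)
}

# exon/intron structure of a transcript: splits a spliced length over
# nExons exons (>= 30 bp each) with intron widths from intronRange;
# forcedIntron = list(index, width) pins one intron's width.
.exonStructure <- function(totalLen, nExons, intronRange = c(80, 500),
                           forcedIntron = NULL) {
    nExons <- max(1L, min(nExons, totalLen %/% 30L))
    base <- 30L
    extra <- totalLen - base * nExons
    w <- runif(nExons) + 0.1
    add <- floor(extra * w / sum(w))
    add[1L] <- add[1L] + (extra - sum(add))
    exonW <- base + add
    intronW <- if (nExons > 1L)
        floor(runif(nExons - 1L, intronRange[1L], intronRange[2L] + 1))
    else integer(0)
    if (!is.null(forcedIntron) && nExons > 1L)
        intronW[forcedIntron$index] <- forcedIntron$width
    list(exonWidths = as.integer(exonW), intronWidths = as.integer(intronW),
         span = sum(exonW) + sum(intronW))
}

# absolute exon layout for a structure placed at `start` (1-based);
# kept as plain vectors so the full GRanges can be built in one shot
.structureExons <- function(struct, chrom, start, strand) {
    k <- length(struct$exonWidths)
    step <- struct$exonWidths + c(struct$intronWidths, 0L)
    starts <- start + c(0L, cumsum(step[-k]))
    list(chrom = chrom, strand = strand, starts = as.integer(starts),
         widths = struct$exonWidths,
         ends = as.integer(starts + struct$exonWidths - 1L))
}

# assemble a named GRangesList from a list of .structureExons layouts
.layoutToGrl <- function(layouts, ids) {
    k <- vapply(layouts, function(x) length(x$starts), integer(1))
    gr <- GRanges(
        rep(vapply(layouts, `[[`, character(1), "chrom"), k),
        IRanges(unlist(lapply(layouts, `[[`, "starts")),
                width = unlist(lapply(layouts, `[[`, "widths"))),
        rep(vapply(layouts, `[[`, character(1), "strand"), k))
    S4Vectors::split(gr, factor(rep(ids, k), levels = ids))
}

.drawLengths <- function(n, meanLen, minLen, sdlog = 0.45) {
    pmax(minLen, round(rlnorm(n, log(meanLen) - sdlog^2 / 2, sdlog)))
}

.drawExonCounts <- function(n, meanExons) {
    1L + rpois(n, meanExons - 1)
}

#' Generate the synthetic gene annotation and transcript models
#'
#' Places non-overlapping protein-coding genes and lncRNA loci on the
#' configured chromosomes: lincRNA loci intergenic (at least
#' `intergenicGap` from every gene, except planted cis loci, which sit
#' at the configured gap distances from their anchor gene), antisense
#' loci overlapping a coding gene's first exon on the opposite strand,
#' and intronic loci strictly inside one intron of a same-strand
#' coding gene.  Exon counts follow a shifted Poisson and spliced
#' lengths a log-normal with the configured means.
#'
#' @param config A [synthConfig()].
#' @return `list(genes = GeneAnnotation, transcripts = TranscriptSet,
#'   truth = list)`.  `truth` records the planted lncRNA/coding ids,
#'   per-lncRNA biotype and host gene, and the planted cis pairs with
#'   their gap distances.
#' @export
generateAnnotation <- function(config) {
    stopifnot(inherits(config, "SynthConfig"))
    set.seed(config$seed)
    nCls <- .classCounts(config$nLncLoci, config$lncClassFractions)
    names(nCls) <- names(config$lncClassFractions)
    nLinc <- nCls[["lincRNA"]]; nAnti <- nCls[["antisense"]]
    nIntr <- nCls[["intronic"]]
    nCis <- min(config$nPlantedCis, nLinc)
    nHosts <- nAnti + nIntr + nCis
    if (nHosts > config$nCodingGenes)
        stop("not enough coding genes to host antisense/intronic/cis loci")

    gid <- sprintf("XLOC_C%04d", seq_len(config$nCodingGenes))
    ltype <- rep(c("antisense", "intronic", "linc_cis", "linc"),
                 c(nAnti, nIntr, nCis, nLinc - nCis))
    lid <- sprintf("XLOC_L%04d", seq_along(ltype))
    # shuffle lnc order so classes are interleaved along the genome
    ord <- sample.int(length(ltype))
    ltype <- ltype[ord]; lid <- lid[ord]
    cisOffsets <- rep(config$plantedCisWindows,
                      length.out = sum(ltype == "linc_cis"))

    # pre-draw transcript shapes
    lncLen <- .drawLengths(length(lid), config$lncLengthMean, 210L)
    lncExN <- .drawExonCounts(length(lid), config$lncExonMean)
    mrnaLen <- .drawLengths(config$nCodingGenes, config$mrnaLengthMean, 350L)
    mrnaExN <- pmax(2L, .drawExonCounts(config$nCodingGenes, config$mrnaExonMean))

    # build unit list: each hosted lnc is attached to the next coding
    # gene; remaining coding genes and lincRNAs are standalone units
    hostAssign <- rep(NA_character_, length(lid))
    hosted <- which(ltype %in% c("antisense", "intronic", "linc_cis"))
    hostGenes <- sample(gid, length(hosted))
    hostAssign[hosted] <- hostGenes
    geneHostOf <- setNames(rep(NA_integer_, config$nCodingGenes), gid)
    geneHostOf[hostGenes] <- hosted

    units <- c(lapply(seq_len(config$nCodingGenes), function(i)
                   list(kind = "gene", gene = i)),
               lapply(which(is.na(hostAssign)), function(j)
                   list(kind = "linc", lnc = j)))
    units <- units[sample.int(length(units))]

    chromNames <- sprintf("chr%d", seq_len(config$nChromosomes))
    cursor <- setNames(rep(1000, config$nChromosomes), chromNames)
    geneEx <- vector("list", config$nCodingGenes)
    lncEx <- vector("list", length(lid))
    cisDistance <- setNames(numeric(sum(ltype == "linc_cis")),
                            lid[ltype == "linc_cis"])
    cisAnchor <- setNames(rep(NA_character_, length(cisDistance)),
                          names(cisDistance))
    cisK <- 0L
    chromOf <- function(u) chromNames[(u - 1L) %% config$nChromosomes + 1L]

    gapDraw <- function() config$intergenicGap +
        floor(runif(1, 0, 2 * config$intergenicGap))

    for (u in seq_along(units)) {
        un <- units[[u]]
        chrom <- chromOf(u)
        at <- cursor[[chrom]] + gapDraw()
        if (un$kind == "linc") {
            j <- un$lnc
            st <- .exonStructure(lncLen[j], lncExN[j])
            strand <- sample(c("+", "-"), 1L)
            if (at + st$span > config$chromLength)
                stop("chromosome ", chrom, " too short to place locus ", lid[j])
            lncEx[[j]] <- .structureExons(st, chrom, at, strand)
            cursor[[chrom]] <- at + st$span
            next
        }
        i <- un$gene
        j <- geneHostOf[[gid[i]]]
        gStrand <- sample(c("+", "-"), 1L)
        if (!is.na(j) && ltype[j] == "intronic") {
            lncSt <- .exonStructure(lncLen[j], lncExN[j])
            kEff <- max(2L, min(mrnaExN[i], mrnaLen[i] %/% 30L))
            intronIdx <- sample.int(kEff - 1L, 1L)
            gSt <- .exonStructure(mrnaLen[i], kEff,
                                  forcedIntron = list(index = intronIdx,
                                                      width = lncSt$span + 100L))
            if (at + gSt$span > config$chromLength)
                stop("chromosome ", chrom, " too short to place locus ", gid[i])
            gEx <- .structureExons(gSt, chrom, at, gStrand)
            geneEx[[i]] <- gEx
            lncStart <- gEx$ends[intronIdx] + 51L
            lncEx[[j]] <- .structureExons(lncSt, chrom, lncStart, gStrand)
            cursor[[chrom]] <- at + gSt$span
        } else if (!is.na(j) && ltype[j] == "antisense") {
            gSt <- .exonStructure(mrnaLen[i], mrnaExN[i])
            lncSt <- .exonStructure(lncLen[j], lncExN[j])
            span <- max(gSt$span, lncSt$span)
            if (at + span > config$chromLength)
                stop("chromosome ", chrom, " too short to place locus ", gid[i])
            geneEx[[i]] <- .structureExons(gSt, chrom, at, gStrand)
            lncStrand <- if (gStrand == "+") "-" else "+"
            # both first exons start at the unit origin: >= 1 bp exonic overlap
            lncEx[[j]] <- .structureExons(lncSt, chrom, at, lncStrand)
            cursor[[chrom]] <- at + span
        } else if (!is.na(j) && ltype[j] == "linc_cis") {
            cisK <- cisK + 1L
            d <- cisOffsets[cisK]
            gSt <- .exonStructure(mrnaLen[i], mrnaExN[i])
            lncSt <- .exonStructure(lncLen[j], lncExN[j])
            span <- gSt$span + d + 1L + lncSt$span
            if (at + span > config$chromLength)
                stop("chromosome ", chrom, " too short to place locus ", lid[j])
            geneEx[[i]] <- .structureExons(gSt, chrom, at, gStrand)
            lncStart <- at + gSt$span + d   # 1-based gap = d
            lncEx[[j]] <- .structureExons(lncSt, chrom, lncStart,
                                          sample(c("+", "-"), 1L))
            cisDistance[[lid[j]]] <- d
            cisAnchor[[lid[j]]] <- gid[i]
            cursor[[chrom]] <- at + span
        } else {
            gSt <- .exonStructure(mrnaLen[i], mrnaExN[i])
            if (at + gSt$span > config$chromLength)
                stop("chromosome ", chrom, " too short to place locus ", gid[i])
            geneEx[[i]] <- .structureExons(gSt, chrom, at, gStrand)
            cursor[[chrom]] <- at + gSt$span
        }
    }

    codingTx <- sub("XLOC", "TCONS", gid)
    lncTx <- sub("XLOC", "TCONS", lid)
    txIds <- c(codingTx, lncTx)
    transcripts <- TranscriptSet(.layoutToGrl(c(geneEx, lncEx), txIds),
                                 geneId = setNames(c(gid, lid), txIds))
    geneGrl <- .layoutToGrl(geneEx, gid)
    genesGr <- unlist(range(geneGrl), use.names = FALSE)
    mcols(genesGr)$gene_id <- gid
    mcols(genesGr)$biotype <- "protein_coding"
    names(genesGr) <- gid
    genes <- GeneAnnotation(genesGr, geneGrl)

    biotype <- ifelse(ltype %in% c("linc", "linc_cis"), "lincRNA", ltype)
    truth <- list(
        true_lnc_ids = lncTx,
        true_coding_ids = codingTx,
        biotype = setNames(biotype, lncTx),
        host_gene = setNames(hostAssign, lncTx),
        cis_pairs = data.frame(
            lnc_id = sub("XLOC", "TCONS", names(cisDistance)),
            gene_id = unname(cisAnchor),
            distance = unname(cisDistance),
            stringsAsFactors = FALSE, row.names = NULL))
    list(genes = genes, transcripts = transcripts, truth = truth)
}

.preferredCodon <- local({
    tab <- NULL
    function() {
        if (is.null(tab)) {
            usage <- codonUsageTable()
            aa <- GENETIC_CODE[names(usage)]
            tab <<- vapply(split(names(usage), aa), function(cods)
                cods[which.max(usage[cods])], character(1))
        }
        tab
    }
})

.encodePeptide <- function(pep) {
    paste(.preferredCodon()[strsplit(pep, "")[[1L]]], collapse = "")
}

# replace a random in-frame codon of ORF row `o` with a stop, avoiding
# the protected interval [p0, p1]
.injectStop <- function(v, o, p0, p1) {
    codStarts <- seq.int(o$start, o$end - 2L, by = 3L)
    ok <- codStarts + 2L < p0 | codStarts > p1
    ok[1L] <- FALSE   # keep the ATG so the split is a real shortening
    if (!any(ok)) return(NULL)
    cand <- codStarts[ok]
    at <- cand[sample.int(length(cand), 1L)]
    v[at:(at + 2L)] <- strsplit(sample(STOP_CODONS, 1L), "")[[1L]]
    v
}

.lncSequence <- function(len, orfMean) {
    v <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    target <- 3L * round(rlnorm(1, log(orfMean) - 0.25^2 / 2, 0.25) / 3)
    target <- max(9L, min(target, 3L * (len %/% 3L)))
    # plant one ORF of exactly `target` nt (ATG + sense codons + stop)
    nCod <- target %/% 3L
    p0 <- sample.int(len - target + 1L, 1L)
    body <- if (nCod > 2L) sample(SENSE_CODONS, nCod - 2L, replace = TRUE)
            else character(0)
    orfSeq <- strsplit(paste0("ATG", paste(body, collapse = ""),
                              sample(STOP_CODONS, 1L)), "")[[1L]]
    v[p0:(p0 + target - 1L)] <- orfSeq
    p1 <- p0 + target - 1L
    # suppress incidental ORFs longer than the planted one
    for (iter in seq_len(200L)) {
        orfs <- .orfTable(v, translate = FALSE)
        long <- orfs[!orfs$incomplete & orfs$length > target, , drop = FALSE]
        if (nrow(long) == 0L) break
        v2 <- .injectStop(v, long[1L, ], p0, p1)
        if (is.null(v2)) break
        v <- v2
    }
    paste(v, collapse = "")
}

.codingSequence <- function(len, motif) {
    v <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    orfLen <- 3L * max(min((len - 6L) %/% 3L, round(0.6 * len / 3)), 10L)
    usage <- codonUsageTable()
    nCod <- orfLen %/% 3L
    body <- sample(names(usage), nCod - 2L, replace = TRUE, prob = usage)
    motifDna <- .encodePeptide(motif)
    nm <- nchar(motifDna) %/% 3L
    at <- max(1L, (length(body) - nm) %/% 2L)
    if (length(body) >= at + nm - 1L)
        body[at:(at + nm - 1L)] <- substring(motifDna,
                                             seq(1L, nchar(motifDna), 3L),
                                             seq(3L, nchar(motifDna), 3L))
    orfSeq <- strsplit(paste0("ATG", paste(body, collapse = ""),
                              sample(STOP_CODONS, 1L)), "")[[1L]]
    p0 <- sample.int(len - orfLen + 1L, 1L)
    v[p0:(p0 + orfLen - 1L)] <- orfSeq
    paste(v, collapse = "")
}

#' Generate spliced sequences for the synthetic transcripts
#'
#' Coding transcripts receive a planted ATG-initiated ORF covering
#' roughly 60% of the transcript, built from the biased
#' [codonUsageTable()] and carrying the first [defaultMotifLibrary()]
#' motif; lncRNA sequences are uniform-background nucleotides with one
#' planted ORF of mean length `lncOrfMean` and all longer incidental
#' ORFs suppressed by in-frame stop injection.  Sequence length equals
#' each transcript's summed exon length.
#'
#' @param transcripts The [TranscriptSet-class] from
#'   [generateAnnotation()].
#' @param truth The truth list from [generateAnnotation()] (identifies
#'   coding vs lncRNA transcripts).
#' @param config The [synthConfig()].
#' @return The input TranscriptSet with sequences attached.
#' @export
generateSequences <- function(transcripts, truth, config) {
    set.seed(config$seed + 1L)
    len <- splicedLengths(transcripts)
    ids <- transcriptIds(transcripts)
    motif <- defaultMotifLibrary()[1L]
    seqs <- vapply(ids, function(id) {
        if (id %in% truth$true_coding_ids)
            .codingSequence(len[[id]], motif)
        else
            .lncSequence(len[[id]], config$lncOrfMean)
    }, character(1))
    spliceSequences(transcripts) <- DNAStringSet(setNames(seqs, ids))
    transcripts
}

# exact-sample-correlation profile pair on the mean scale: returns a
# 2 x S matrix of positive per-sample multipliers with Pearson
# correlation exactly r between the rows (affine-invariance of r).
# `zc` may be supplied so that successive pairs can share an
# antithetic latent profile (keeps library sizes stable).
.correlatedProfiles <- function(S, r, zc = NULL) {
    z <- rnorm(S); e <- rnorm(S)
    if (is.null(zc)) zc <- (z - mean(z)) / sd(z)
    ep <- e - mean(e) - zc * sum((e - mean(e)) * zc) / sum(zc^2)
    if (sd(ep) < 1e-12) ep <- rep(0, S) else ep <- ep / sd(ep)
    w <- r * zc + sqrt(max(0, 1 - r^2)) * ep
    a <- 0.9 / max(abs(zc))
    b <- if (max(abs(w)) < 1e-12) 0 else 0.9 / max(abs(w))
    rbind(1 + a * zc, 1 + b * w)
}

#' Generate the synthetic count matrix
#'
#' Counts are negative binomial with mean proportional to a
#' per-transcript base FPKM, the transcript length and the sample
#' library size, and dispersion `nbDispersion` (Poisson when below
#' 1e-8).  Planted DE transcripts have group means differing by
#' `deLog2fc`; planted trans pairs get per-sample expected FPKMs with
#' exact in-sample Pearson correlation `transTargetR`; group-specific
#' lncRNAs get expected count zero in the off group.
#'
#' @param transcripts The [TranscriptSet-class] (annotation order
#'   defines the matrix rows).
#' @param truth The truth list from [generateAnnotation()]; this
#'   function extends it with `de_ids`/`de_direction`, `trans_pairs`
#'   and `group_specific`.
#' @param config The [synthConfig()].
#' @return `list(expr = ExpressionData, truth = extended truth list)`.
#' @export
generateCounts <- function(transcripts, truth, config) {
    if (config$nSamplesPerGroup < 2L)
        stop("design error: at least 2 samples per group are required")
    set.seed(config$seed + 2L)
    ids <- transcriptIds(transcripts)
    len <- splicedLengths(transcripts)
    n <- length(ids)
    S <- 2L * config$nSamplesPerGroup
    grpLab <- config$groupLabels
    samples <- c(sprintf("%s_%d", grpLab[1L], seq_len(config$nSamplesPerGroup)),
                 sprintf("%s_%d", grpLab[2L], seq_len(config$nSamplesPerGroup)))
    design <- setNames(rep(grpLab, each = config$nSamplesPerGroup), samples)
    isCase <- design == grpLab[2L]

    baseFpkm <- setNames(rlnorm(n, log(15), 0.8), ids)
    E <- matrix(rep(baseFpkm, S), n, S, dimnames = list(ids, samples))

    lnc <- truth$true_lnc_ids
    lincs <- lnc[truth$biotype[lnc] == "lincRNA"]
    reserved <- character(0)

    # group-specific lncRNAs (zero expected count in the off group)
    gs <- list()
    for (g in 1:2) {
        pool <- setdiff(lincs, reserved)
        pick <- head(pool, 0L)
        if (config$nGroupSpecific > 0L && length(pool) > 0L)
            pick <- sample(pool, min(config$nGroupSpecific, length(pool)))
        gs[[grpLab[g]]] <- pick
        reserved <- c(reserved, pick)
        if (length(pick)) {
            on <- if (g == 2L) isCase else !isCase
            E[pick, ] <- 0
            E[pick, on] <- rlnorm(length(pick), log(20), 0.4)
        }
    }

    # planted trans-correlated pairs (high expression: count noise
    # would otherwise attenuate the empirical correlation)
    transLnc <- setdiff(lnc, reserved)
    transCod <- truth$true_coding_ids
    nTrans <- min(config$plantedTransPairs, length(transLnc), length(transCod))
    transPairs <- data.frame(lnc_id = character(), gene_id = character(),
                             coding_tx = character(), target_r = numeric(),
                             stringsAsFactors = FALSE)
    if (nTrans > 0L) {
        tl <- sample(transLnc, nTrans)
        tc <- sample(transCod, nTrans)
        zcPrev <- NULL
        for (p in seq_len(nTrans)) {
            # antithetic latent profiles in alternating pairs: the
            # planted loci are highly expressed, and opposite-signed
            # profiles keep the per-sample library sums (hence FPKM
            # scaling) nearly constant
            zcThis <- if (p %% 2L == 0L && !is.null(zcPrev)) -zcPrev else NULL
            prof <- .correlatedProfiles(S, config$transTargetR, zc = zcThis)
            zcPrev <- (prof[1L, ] - mean(prof[1L, ])) / sd(prof[1L, ])
            # base FPKM chosen so the expected count is ~10000 per
            # sample regardless of transcript length: shot noise would
            # otherwise attenuate the planted correlation
            bl <- 10000 * 1000 / len[[tl[p]]] * rlnorm(1, 0, 0.2)
            bc <- 10000 * 1000 / len[[tc[p]]] * rlnorm(1, 0, 0.2)
            E[tl[p], ] <- bl * prof[1L, ]
            E[tc[p], ] <- bc * prof[2L, ]
        }
        reserved <- c(reserved, tl, tc)
        transPairs <- data.frame(
            lnc_id = tl,
            gene_id = unname(geneIds(transcripts)[tc]),
            coding_tx = tc, target_r = config$transTargetR,
            stringsAsFactors = FALSE, row.names = NULL)
    }

    # planted differential expression
    pool <- setdiff(ids, reserved)
    nDe <- round(config$deFraction * n)
    deIds <- character(0); deDir <- character(0)
    if (nDe > 0L && length(pool) > 0L) {
        deIds <- sample(pool, min(nDe, length(pool)))
        up <- sample(c(TRUE, FALSE), length(deIds), replace = TRUE)
        deDir <- ifelse(up, "up", "down")
        fac <- 2^(ifelse(up, config$deLog2fc, -config$deLog2fc))
        E[deIds, isCase] <- E[deIds, isCase] * fac
    }

    mu <- E * (len[ids] / 1000) %o% (config$librarySizes / 1e6)
    counts <- matrix(0L, n, S, dimnames = list(ids, samples))
    draw <- if (config$nbDispersion < 1e-8)
        function(m) rpois(length(m), m)
    else
        function(m) rnbinom(length(m), mu = m, size = 1 / config$nbDispersion)
    counts[] <- draw(mu)
    # guard: screening requires every transcript observable somewhere
    allZero <- rowSums(counts) == 0L
    counts[allZero, 1L] <- 1L

    truth$de_ids <- deIds
    truth$de_direction <- setNames(deDir, deIds)
    truth$trans_pairs <- transPairs
    truth$group_specific <- gs
    list(expr = ExpressionData(counts, lengths = len, design = design),
         truth = truth)
}

#' Generate a term-to-gene map with one planted enriched term
#'
#' Random terms draw genes uniformly from the background (all coding
#' genes); one planted term contains a designated 10-gene query list
#' plus a few extra genes, so the query is maximally enriched in it.
#'
#' @param genes The [GeneAnnotation-class] (background = all gene ids).
#' @param config The [synthConfig()].
#' @param nTerms Number of random terms besides the planted one.
#' @param querySize Size of the designated query gene list.
#' @return `list(termMap = named list, plantedTermId, queryGenes)`.
#' @export
generateTermMap <- function(genes, config, nTerms = 40L, querySize = 10L) {
    set.seed(config$seed + 3L)
    bg <- geneIds(genes)
    query <- sample(bg, min(querySize, length(bg)))
    planted <- unique(c(query, sample(bg, 5L)))
    termMap <- lapply(seq_len(nTerms), function(i)
        sample(bg, min(floor(runif(1, 10, 41)), length(bg))))
    names(termMap) <- sprintf("TERM_%03d", seq_len(nTerms))
    termMap[["TERM_PLANTED"]] <- planted
    list(termMap = termMap, plantedTermId = "TERM_PLANTED",
         queryGenes = query)
}

#' Generate a synthetic qPCR Ct table
#'
#' Four target genes with true fold changes 4, 2, 1 and 0.5
#' (case vs calibrator) plus the reference gene, measured in every
#' sample with 3 technical replicates; per-sample global Ct shifts
#' exercise the reference normalisation.
#'
#' @param config The [synthConfig()].
#' @param noiseSd Replicate-level Ct noise (cycles).
#' @return `list(ct = data.frame, truth = data.frame(gene,
#'   true_fold))`.
#' @export
generateCtTable <- function(config, noiseSd = 0.1) {
    set.seed(config$seed + 4L)
    grpLab <- config$groupLabels
    nS <- config$nSamplesPerGroup
    samples <- data.frame(
        sample_id = c(sprintf("%s_%d", grpLab[1L], seq_len(nS)),
                      sprintf("%s_%d", grpLab[2L], seq_len(nS))),
        group = rep(grpLab, each = nS), stringsAsFactors = FALSE)
    genes <- c("qTARGET_A", "qTARGET_B", "qTARGET_C", "qTARGET_D")
    trueFold <- c(4, 2, 1, 0.5)
    shift <- setNames(-log2(trueFold), genes)   # ddCt = -log2(fold)
    sampleShift <- setNames(rnorm(nrow(samples), 0, 0.3), samples$sample_id)
    rows <- list()
    for (si in seq_len(nrow(samples))) {
        sid <- samples$sample_id[si]
        isCase <- samples$group[si] == grpLab[2L]
        for (g in c(genes, "beta-actin")) {
            base <- if (g == "beta-actin") 15 else 22 +
                if (isCase) shift[[g]] else 0
            ctv <- base + sampleShift[[sid]] + rnorm(3L, 0, noiseSd)
            rows[[length(rows) + 1L]] <- data.frame(
                sample_id = sid, group = samples$group[si], gene = g,
                replicate = 1:3, ct = ctv, stringsAsFactors = FALSE)
        }
    }
    list(ct = do.call(rbind, rows),
         truth = data.frame(gene = genes, true_fold = trueFold,
                            stringsAsFactors = FALSE))
}

#' Generate a complete synthetic study
#'
#' Runs [generateAnnotation()], [generateSequences()],
#' [generateCounts()], [generateTermMap()] and [generateCtTable()] and
#' assembles the results with the merged ground truth.
#'
#' @param config A [synthConfig()].
#' @return A list of class `SynthStudy` with elements `genes`,
#'   `transcripts` (sequences attached), `expr`, `termMap`,
#'   `queryGenes`, `ct`, `truth`, `config`.
#' @export
simulateStudy <- function(config = synthConfig()) {
    ann <- generateAnnotation(config)
    tx <- generateSequences(ann$transcripts, ann$truth, config)
    cts <- generateCounts(tx, ann$truth, config)
    tm <- generateTermMap(ann$genes, config)
    qp <- generateCtTable(config)
    truth <- cts$truth
    truth$planted_term_id <- tm$plantedTermId
    truth$query_genes <- tm$queryGenes
    truth$qpcr <- qp$truth
    out <- list(genes = ann$genes, transcripts = tx, expr = cts$expr,
                termMap = tm$termMap, queryGenes = tm$queryGenes,
                ct = qp$ct, truth = truth, config = config)
    class(out) <- "SynthStudy"
    out
}

#' @export
print.SynthStudy <- function(x, ...) {
    cat("SynthStudy (seed", x$config$seed, "):",
        length(x$truth$true_coding_ids), "coding +",
        length(x$truth$true_lnc_ids), "lncRNA transcripts,",
        ncol(x$expr), "samples\n")
    invisible(x)
}
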