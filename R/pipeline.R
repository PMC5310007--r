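# End-to-end orchestration: simulate (or load) a study, screen,
# classify, test differential expression, call group-specific lncRNAs,
# predict cis/trans targets, run enrichment, summarise features and
# analyse qPCR validation data.  Every stage is a pure function of
# (inputs, config); re-running with the same config reproduces
# byte-identical tables.  A manifest JSON records the seed, the
# parameters and per-stage attrition.

#' Default pipeline configuration
#'
#' All analysis thresholds appear as named keys with their
#' conventional values: 200 nt minimum length, raw p < 0.05 for
#' differential expression, |r| > 0.95 for trans targets, 10 kb and
#' 100 kb cis windows, EASE p < 0.05 for enrichment.
#'
#' @param seed Seed for the synthetic study.
#' @return A nested list of class `PipelineConfig`.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
    cfg <- list(
        synth = synthConfig(seed = seed),
        screen = list(min_length = 200, min_exons = 1, min_fpkm = 0.5,
                      orf_length_threshold = 300, orf_coverage_threshold = 0.5),
        de = list(alpha = 0.05),
        specific = list(presence_fpkm = 1.0, absence_fpkm = 0.1),
        targets = list(windows = c(10000, 100000), r_threshold = 0.95),
        enrich = list(alpha = 0.05),
        stages = list(enrich = TRUE, featurestats = TRUE, qpcr = TRUE))
    class(cfg) <- "PipelineConfig"
    cfg
}

.writeTable <- function(df, dir, name) {
    if (is.null(dir)) return(invisible(NULL))
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
}

#' Run the full lncRNA analysis pipeline
#'
#' Stages, in order: simulate -> screen -> biotype -> expression
#' (differential + group-specific) -> targets (cis + trans) -> enrich
#' -> featurestats -> qpcr.  Optional stages can be switched off via
#' `config$stages`.  When `outDir` is given, every stage's tables are
#' written there together with the study inputs (GTF, FASTA, counts,
#' design, truth JSON) and a `manifest.json`.
#'
#' @param config A [defaultPipelineConfig()]-style list.
#' @param outDir Output directory (created; `NULL` for in-memory
#'   only).
#' @param study An existing `SynthStudy` to analyse instead of
#'   simulating from `config$synth`.
#' @return Invisibly, a list with the study and all stage results
#'   (`screen`, `biotype`, `de`, `specific`, `cis`, `trans`,
#'   `targets`, `enrich`, `features`, `qpcr`, `manifest`).
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir = NULL,
                        study = NULL) {
    t0 <- Sys.time()
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    if (is.null(study)) study <- simulateStudy(config$synth)
    stages <- config$stages
    run <- function(stage, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", stage, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    if (!is.null(outDir)) {
        writeGtf(study$transcripts, file.path(outDir, "transcripts.gtf"))
        annotTs <- TranscriptSet(geneExons(study$genes),
                                 geneId = setNames(geneIds(study$genes),
                                                   geneIds(study$genes)))
        writeGtf(annotTs, file.path(outDir, "annotation.gtf"),
                 geneAttrs = geneBiotypes(study$genes))
        writeTranscriptFasta(study$transcripts,
                             file.path(outDir, "transcripts.fa"))
        writeCountsTsv(study$expr, file.path(outDir, "counts.tsv"),
                       file.path(outDir, "design.tsv"))
        writeTermMap(study$termMap, file.path(outDir, "term_map.tsv"))
        writeCtTable(study$ct, file.path(outDir, "ct_table.tsv"))
        writeTruthJson(study$truth, file.path(outDir, "truth.json"))
    }

    sc <- config$screen
    screen <- run("screen", screenTranscripts(
        study$transcripts, study$expr,
        minLength = sc$min_length, minExons = sc$min_exons,
        minFpkm = sc$min_fpkm,
        orfLengthThreshold = sc$orf_length_threshold,
        orfCoverageThreshold = sc$orf_coverage_threshold))
    .writeTable(screen$verdicts, outDir, "verdicts.tsv")

    biotype <- run("biotype",
                   classifyBiotype(screen$candidates, study$genes))
    .writeTable(biotype, outDir, "biotype.tsv")
    .writeTable(data.frame(class = names(biotypeSummary(biotype)),
                           count = as.integer(biotypeSummary(biotype))),
                outDir, "biotype_summary.tsv")

    de <- run("expression", nbTest(study$expr))
    .writeTable(de, outDir, "de.tsv")
    .writeTable(volcanoTable(de, alpha = config$de$alpha), outDir,
                "volcano.tsv")
    lncIds <- transcriptIds(screen$candidates)
    specific <- run("expression", groupSpecific(
        study$expr, presenceFpkm = config$specific$presence_fpkm,
        absenceFpkm = config$specific$absence_fpkm, ids = lncIds))
    .writeTable(data.frame(
        group = rep(names(specific), lengths(specific)),
        transcript_id = unlist(specific, use.names = FALSE)),
        outDir, "group_specific.tsv")

    keptBio <- biotype[biotype$biotype != "ambiguous", , drop = FALSE]
    lncSet <- screen$candidates[
        transcriptIds(screen$candidates) %in% keptBio$transcript_id]
    cis <- run("targets", cisTargets(lncSet, study$genes,
                                     windows = config$targets$windows))
    codingTx <- intersect(study$truth$true_coding_ids, rownames(study$expr))
    trans <- run("targets", transTargets(
        study$expr, transcriptIds(lncSet), codingTx,
        threshold = config$targets$r_threshold))
    # report trans partners by their gene locus id
    txGene <- geneIds(study$transcripts)
    trans$gene_id <- unname(txGene[trans$gene_id])
    targets <- targetTable(cis, trans)
    .writeTable(cis, outDir, "cis_targets.tsv")
    .writeTable(trans, outDir, "trans_targets.tsv")
    .writeTable(targets, outDir, "target_table.tsv")

    enrich <- NULL
    if (isTRUE(stages$enrich)) {
        query <- unique(c(cis$gene_id, trans$gene_id))
        background <- geneIds(study$genes)
        query <- intersect(query, background)
        enrich <- run("enrich", if (length(query))
            enrichTargets(query, study$termMap, background,
                          alpha = config$enrich$alpha)
            else NULL)
        if (!is.null(enrich)) .writeTable(enrich, outDir, "enrichment.tsv")
    }

    features <- NULL
    if (isTRUE(stages$featurestats)) {
        codingSet <- study$transcripts[
            transcriptIds(study$transcripts) %in% study$truth$true_coding_ids]
        features <- run("featurestats",
                        featureSummary(lncSet, codingSet, study$expr))
        .writeTable(features$summary, outDir, "feature_summary.tsv")
    }

    qpcr <- NULL
    if (isTRUE(stages$qpcr) && !is.null(study$ct)) {
        calib <- config$synth$groupLabels[1L]
        qpcr <- run("qpcr", do.call(rbind, lapply(
            setdiff(unique(study$ct$gene), "beta-actin"),
            function(g) qpcrAnalysis(study$ct, g, calib))))
        .writeTable(qpcr, outDir, "qpcr.tsv")
    }

    manifest <- list(
        package = "caprilnc",
        version = as.character(packageVersion("caprilnc")),
        timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
        seed = config$synth$seed,
        parameters = config[setdiff(names(config), "synth")],
        synth = config$synth[setdiff(names(unclass(config$synth)),
                                     "librarySizes")],
        stages = list(
            simulate = "run", screen = "run", biotype = "run",
            expression = "run",
            targets = "run",
            enrich = if (isTRUE(stages$enrich)) "run" else "skipped",
            featurestats = if (isTRUE(stages$featurestats)) "run" else "skipped",
            qpcr = if (isTRUE(stages$qpcr)) "run" else "skipped"),
        attrition = as.list(screen$attrition),
        n_candidates = length(transcriptIds(screen$candidates)),
        biotype_counts = as.list(biotypeSummary(biotype)),
        de_summary = as.list(deSummary(de, alpha = config$de$alpha)))
    if (!is.null(outDir))
        writeTruthJson(manifest, file.path(outDir, "manifest.json"))

    invisible(list(study = study, screen = screen, biotype = biotype,
                   de = de, specific = specific, cis = cis, trans = trans,
                   targets = targets, enrich = enrich, features = features,
                   qpcr = qpcr, manifest = manifest))
}

#' Recovery report against the planted ground truth
#'
#' Compares a pipeline run on a synthetic study with the study's
#' planted truth: screening sensitivity (true lncRNAs surviving the
#' screen) and coding contamination (true coding transcripts admitted),
#' biotype accuracy on classified true lncRNAs, differential-expression
#' power on the planted DE set, cis and trans recall, the planted
#' enrichment term's EASE p and rank, and group-specific recovery.
#'
#' @param run The list returned by [runPipeline()] on a synthetic
#'   study.
#' @param alpha Significance threshold for the DE power computation.
#' @return A named list of recovery metrics (proportions in `[0, 1]`).
#' @export
evaluateRun <- function(run, alpha = 0.05) {
    truth <- run$study$truth
    cand <- transcriptIds(run$screen$candidates)
    lnc <- truth$true_lnc_ids
    cod <- truth$true_coding_ids
    sens <- mean(lnc %in% cand)
    contam <- mean(cod %in% cand)

    bio <- run$biotype
    bio <- bio[bio$transcript_id %in% lnc, , drop = FALSE]
    bioAcc <- if (nrow(bio)) mean(bio$biotype ==
                                  truth$biotype[bio$transcript_id]) else NA_real_

    de <- run$de
    deIds <- intersect(truth$de_ids, de$transcript_id)
    power <- if (length(deIds))
        mean(de$pvalue[match(deIds, de$transcript_id)] < alpha) else NA_real_

    cisTruth <- truth$cis_pairs
    cisFound <- paste(run$cis$lnc_id, run$cis$gene_id)
    cisRecall <- if (nrow(cisTruth))
        mean(paste(cisTruth$lnc_id, cisTruth$gene_id) %in% cisFound)
        else NA_real_

    transTruth <- truth$trans_pairs
    transFound <- paste(run$trans$lnc_id, run$trans$gene_id)
    transRecall <- if (nrow(transTruth))
        mean(paste(transTruth$lnc_id, transTruth$gene_id) %in% transFound)
        else NA_real_

    plantedP <- NA_real_; plantedRank <- NA_integer_
    enr <- enrichTargets(truth$query_genes, run$study$termMap,
                         geneIds(run$study$genes))
    if (!is.null(enr) && nrow(enr)) {
        i <- match(truth$planted_term_id, enr$term_id)
        if (!is.na(i)) { plantedP <- enr$ease_p[i]; plantedRank <- i }
    }

    gsTruth <- truth$group_specific
    gsRecall <- if (length(gsTruth)) {
        found <- run$specific
        mean(unlist(lapply(names(gsTruth), function(g)
            gsTruth[[g]] %in% found[[g]])))
    } else NA_real_

    list(screen_sensitivity = sens, screen_contamination = contam,
         biotype_accuracy = bioAcc, de_power = power,
         cis_recall = cisRecall, trans_recall = transRecall,
         planted_term_ease_p = plantedP, planted_term_rank = plantedRank,
         group_specific_recall = gsRecall)
}
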