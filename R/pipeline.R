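# End-to-end orchestration: extract -> classify -> localize -> correct, with
# reproducible seeds and TSV hand-off between stages.

#' Run misassembly prediction end to end
#'
#' Metagenome mode (`mode = "meta"`): extracts contig-level features, scores
#' contigs with the random-forest ensemble, then localizes one breakpoint in
#' every contig whose score reaches `scoreThreshold`. Isolate mode
#' (`mode = "isolate"`): skips the classifier and calls breakpoints on all
#' contigs from window anomaly scores and read-breakpoint tracks under the
#' strict 0.95 / >5 / >0.2 thresholds.
#'
#' @param contigsFasta assembly FASTA path (or named `DNAStringSet`).
#' @param alignments BAM/SAM path (or a [ContigAlignments-class]).
#' @param mode `"meta"` or `"isolate"`.
#' @param model an [EnsembleModel-class] or model archive path (meta mode);
#'   alternatively supply `training = list(features, labels)` to fit one.
#' @param training optional list with `features` and `labels` to train an
#'   ensemble when no model is given.
#' @param outdir optional directory; when set, `scores.tsv`,
#'   `breakpoints.tsv`, and `run_manifest.txt` are written.
#' @param seed integer seed driving every stochastic stage.
#' @param minMapq,window,k,clipMin,endExclusion,minContig feature and
#'   localization parameters (defaults 10, 100, 25, 20, 300, 5000).
#' @param scoreThreshold score needed to localize/correct a contig in meta
#'   mode (default 0.8).
#' @param isolateThresholds numeric vector `c(score, count, ratio)` for
#'   isolate mode (default `c(0.95, 5, 0.2)`).
#' @return list with `scores` (meta mode), `breakpoints`, `windowAnomalies`,
#'   `model`, `insertModel`, and `skipped`.
#' @export
runPredict <- function(contigsFasta, alignments, mode = c("meta", "isolate"),
                       model = NULL, training = NULL, outdir = NULL,
                       seed = 1L, minMapq = 10L, window = 100L, k = 25L,
                       clipMin = 20L, endExclusion = 300L, minContig = 5000L,
                       scoreThreshold = 0.8,
                       isolateThresholds = c(0.95, 5, 0.2)) {
    mode <- match.arg(mode)
    contigs <- if (is.character(contigsFasta))
        Biostrings::readDNAStringSet(contigsFasta) else contigsFasta
    names(contigs) <- sub("\\s.*$", "", names(contigs))
    aln <- if (is.character(alignments))
        readContigAlignments(alignments, minMapq = minMapq, contigs = contigs)
        else alignments
    insertModel <- fitInsertSizeModel(aln)

    scores <- NULL
    if (mode == "meta") {
        cf <- extractFeatures(aln, contigs, insertModel, mode = "contig",
                              k = k, clipMin = clipMin)
        if (is.null(model) && !is.null(training))
            model <- trainEnsemble(training$features, training$labels,
                                   seed = seed)
        if (is.character(model)) model <- loadEnsemble(model)
        if (is.null(model))
            stop("meta mode needs a trained model or a labelled training table")
        scores <- scoreContigs(model, cf, minLength = minContig)
    }

    wf <- extractFeatures(aln, contigs, insertModel, mode = "window",
                          window = window, k = k, clipMin = clipMin)
    anomalies <- scoreWindowAnomalies(wf, seed = seed)

    rbTracks <- list()
    targets <- if (mode == "meta")
        scores$contig_id[!is.na(scores$score) & scores$score >= scoreThreshold]
        else unique(anomalies$contig_id)
    for (cid in targets)
        rbTracks[[cid]] <- readBreakpointTrack(
            buildPileup(aln, cid, contigs[[cid]], insertModel))

    if (mode == "meta") {
        bps <- list()
        for (cid in targets) {
            bp <- tryCatch(
                localizeBreakpoint(cid, unname(contigLengths(aln)[cid]),
                                   anomalies, rbTracks[[cid]],
                                   window = window,
                                   endExclusion = endExclusion),
                error = function(e) NULL)
            if (!is.null(bp)) bps[[cid]] <- bp
        }
        breakpoints <- if (length(bps)) do.call(rbind, bps) else
            data.frame(contig_id = character(0), position = integer(0),
                       anomaly_score = numeric(0), rb_count = integer(0),
                       rb_ratio = numeric(0), provenance = character(0))
    } else {
        breakpoints <- callBreakpointsIsolate(
            anomalies, rbTracks, contigLengths(aln),
            scoreThreshold = isolateThresholds[1],
            countThreshold = isolateThresholds[2],
            ratioThreshold = isolateThresholds[3],
            window = window, endExclusion = endExclusion)
    }
    rownames(breakpoints) <- NULL

    if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        if (!is.null(scores))
            write.table(scores, file.path(outdir, "scores.tsv"), sep = "\t",
                        quote = FALSE, row.names = FALSE)
        out <- breakpoints
        if (nrow(out) > 0L) out$position <- out$position + 1L # 1-based in text
        write.table(out, file.path(outdir, "breakpoints.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        writeLines(c(sprintf("mode=%s", mode), sprintf("seed=%d", seed),
                     sprintf("minMapq=%d", minMapq),
                     sprintf("window=%d", window), sprintf("k=%d", k),
                     sprintf("endExclusion=%d", endExclusion),
                     sprintf("minContig=%d", minContig),
                     sprintf("scoreThreshold=%g", scoreThreshold),
                     sprintf("package=contigMend %s",
                             as.character(utils::packageVersion("contigMend")))),
                   file.path(outdir, "run_manifest.txt"))
    }
    list(scores = scores, breakpoints = breakpoints,
         windowAnomalies = anomalies, model = model,
         insertModel = insertModel,
         skipped = attr(wf, "skipped"))
}

#' Run misassembly correction
#'
#' Applies [correctAssembly()] to the outputs of [runPredict()] and
#' optionally writes the corrected FASTA and plan.
#'
#' @param contigsFasta assembly FASTA path (or named `DNAStringSet`).
#' @param prediction result of [runPredict()] (or a list with `scores` and
#'   `breakpoints`).
#' @param outFasta optional corrected FASTA path.
#' @param planPath optional plan TSV path.
#' @param scoreThreshold,minFragment correction safeguards (defaults 0.8 and
#'   1000 bp).
#' @return the [correctAssembly()] result.
#' @export
runCorrect <- function(contigsFasta, prediction, outFasta = NULL,
                       planPath = NULL, scoreThreshold = 0.8,
                       minFragment = 1000L) {
    res <- correctAssembly(contigsFasta, prediction$scores,
                           prediction$breakpoints,
                           scoreThreshold = scoreThreshold,
                           minFragment = minFragment)
    if (!is.null(outFasta))
        writeCorrectedAssembly(res, outFasta, planPath = planPath)
    res
}
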