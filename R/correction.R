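# Correction: split misassembled contigs at breakpoints under the score and
# fragment-length safeguards.

#' Correct an assembly by splitting at breakpoints
#'
#' A contig is split into `[0, p)` and `[p, L)` at breakpoint `p` only when
#' its misassembly score is at least `scoreThreshold` (default 0.8) and both
#' fragments are at least `minFragment` bp (default 1000); otherwise the
#' contig is emitted unchanged with the skip reason. Isolate-mode calls may
#' carry several breakpoints per contig: they are applied sequentially left
#' to right, each cut re-checked against `minFragment` on the current
#' fragment and the remainder. Fragment ids are `<contig_id>_1`,
#' `<contig_id>_2`, ... and total emitted bases always equal total input
#' bases.
#'
#' @param contigs named `DNAStringSet` (or FASTA path) of the assembly.
#' @param calls data.frame from [scoreContigs()] (`contig_id`, `score`,
#'   `eligible`), or `NULL` in isolate mode (every contig with a breakpoint
#'   is treated as splittable).
#' @param breakpoints data.frame with `contig_id` and `position` (0-based).
#' @param scoreThreshold minimum score `S(c)` for correction (default 0.8,
#'   inclusive).
#' @param minFragment minimum fragment length in bp (default 1000).
#' @return list with `contigs` (corrected `DNAStringSet`) and `plan`
#'   (data.frame: `contig_id`, `action` one of keep/split/skip_low_score/
#'   skip_short_fragment, `breakpoints` used, `n_fragments`).
#' @export
correctAssembly <- function(contigs, calls, breakpoints,
                            scoreThreshold = 0.8, minFragment = 1000L) {
    if (is.character(contigs)) contigs <- Biostrings::readDNAStringSet(contigs)
    names(contigs) <- sub("\\s.*$", "", names(contigs))
    miss <- setdiff(unique(breakpoints$contig_id), names(contigs))
    if (length(miss) > 0L)
        stop("breakpoints reference contigs absent from the assembly: ",
             paste(head(miss, 5), collapse = ", "))
    bad <- breakpoints$position <= 0L |
        breakpoints$position >= Biostrings::width(contigs)[
            match(breakpoints$contig_id, names(contigs))]
    if (any(bad))
        stop("breakpoint outside the open interval (0, L) on ",
             paste(head(unique(breakpoints$contig_id[bad]), 5), collapse = ", "))

    scores <- if (is.null(calls)) NULL else
        setNames(calls$score, calls$contig_id)

    outSeqs <- list()
    plan <- list()
    for (cid in names(contigs)) {
        L <- Biostrings::width(contigs)[match(cid, names(contigs))]
        bp <- sort(unique(breakpoints$position[breakpoints$contig_id == cid]))
        action <- "keep"
        cuts <- integer(0)
        if (length(bp) > 0L) {
            s <- if (is.null(scores)) NA_real_ else unname(scores[cid])
            if (!is.null(scores) && (is.na(s) || s < scoreThreshold)) {
                action <- "skip_low_score"
            } else {
                last <- 0L
                for (p in bp) {
                    if (p - last >= minFragment && L - p >= minFragment) {
                        cuts <- c(cuts, p)
                        last <- p
                    }
                }
                action <- if (length(cuts) > 0L) "split" else "skip_short_fragment"
            }
        }
        if (action == "split") {
            edges <- c(0L, cuts, L)
            for (j in seq_len(length(edges) - 1L)) {
                nm <- sprintf("%s_%d", cid, j)
                outSeqs[[nm]] <- Biostrings::subseq(contigs[[cid]],
                                                    start = edges[j] + 1L,
                                                    end = edges[j + 1L])
            }
            nf <- length(edges) - 1L
        } else {
            outSeqs[[cid]] <- contigs[[cid]]
            nf <- 1L
        }
        plan[[cid]] <- data.frame(
            contig_id = cid, action = action,
            breakpoints = paste(cuts, collapse = ","),
            n_fragments = nf, stringsAsFactors = FALSE)
    }
    corrected <- Biostrings::DNAStringSet(outSeqs)
    list(contigs = corrected, plan = do.call(rbind, plan))
}

#' Write a corrected assembly
#'
#' FASTA wrapped at 80 columns; split fragments carry a
#' `corrected=<parent>:<start>-<end>` annotation (1-based inclusive source
#' interval) in the header.
#'
#' @param corrected result of [correctAssembly()].
#' @param path output FASTA path.
#' @param planPath optional TSV path for the correction plan.
#' @export
writeCorrectedAssembly <- function(corrected, path, planPath = NULL) {
    seqs <- corrected$contigs
    plan <- corrected$plan
    ann <- names(seqs)
    for (i in seq_len(nrow(plan))) {
        if (plan$action[i] != "split") next
        cid <- plan$contig_id[i]
        cuts <- as.integer(strsplit(plan$breakpoints[i], ",")[[1]])
        edges <- c(0L, cuts, sum(Biostrings::width(
            seqs[grepl(paste0("^", cid, "_[0-9]+$"), names(seqs))])))
        for (j in seq_len(plan$n_fragments[i])) {
            nm <- sprintf("%s_%d", cid, j)
            ann[ann == nm] <- sprintf("%s corrected=%s:%d-%d", nm, cid,
                                      edges[j] + 1L, edges[j + 1L])
        }
    }
    out <- seqs
    names(out) <- ann
    Biostrings::writeXStringSet(out, path, width = 80L)
    if (!is.null(planPath))
        write.table(plan, planPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
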