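# Breakpoint localization: isolation-forest anomaly scores over 100-bp
# windows combined with read-breakpoint ratios.

#' Anomaly-score all windows of a sample
#'
#' Fits one isolation forest over the usable window feature vectors of all
#' contigs in the sample (windows from many contigs form the background
#' population) and assigns each window the canonical isolation score in
#' (0, 1); higher = more anomalous. Deterministic for a fixed seed.
#'
#' @param windowFeatures data.frame from [extractFeatures()] in window mode.
#' @param nTrees,sampleSize isolation-forest parameters (see
#'   [isolationForest()]).
#' @param seed integer seed.
#' @return data.frame `contig_id`, `window_start` (0-based), `anomaly`,
#'   restricted to usable windows.
#' @export
scoreWindowAnomalies <- function(windowFeatures, nTrees = 100L,
                                 sampleSize = NULL, seed = 1L) {
    wf <- windowFeatures[windowFeatures$usable, , drop = FALSE]
    if (nrow(wf) < 2L) stop("need at least 2 usable windows to score anomalies")
    X <- as.matrix(wf[, featureManifest(), drop = FALSE])
    forest <- isolationForest(X, nTrees = nTrees, sampleSize = sampleSize,
                              seed = seed)
    data.frame(contig_id = wf$contig_id, window_start = wf$window_start,
               anomaly = isolationScore(forest, X), stringsAsFactors = FALSE)
}

#' Read-breakpoint track of a contig
#'
#' Per-base count of alignment boundaries that do not coincide with read ends
#' (soft/hard clips and supplementary splits) and the read breakpoint ratio:
#' the fraction of reads overlapping the base (by full extent) whose
#' alignment breaks there. The ratio is 0 where no reads map.
#'
#' @param track a [PileupTrack-class].
#' @return data.frame `pos` (0-based), `count`, `ratio`.
#' @export
readBreakpointTrack <- function(track) {
    cnt <- track@readBreakpointCount
    denom <- pmax(track@readsAtBase, cnt)
    ratio <- ifelse(denom > 0L, cnt / denom, 0)
    data.frame(pos = seq_len(track@length) - 1L, count = cnt, ratio = ratio)
}

# windows fully outside the terminal exclusion zone
.eligibleWindows <- function(anomalies, L, window, endExclusion) {
    anomalies[anomalies$window_start >= endExclusion &
              anomalies$window_start + window <= L - endExclusion, ,
              drop = FALSE]
}

#' Localize the misassembly breakpoint of one contig
#'
#' The error region is the eligible window (not overlapping the terminal
#' `endExclusion` bp, where mapping quality is poor) with the highest anomaly
#' score (leftmost on ties). Within it, the breakpoint is the position with
#' the highest read breakpoint ratio (leftmost on ties); if the window
#' contains no read breakpoints, the window's central position is reported
#' instead.
#'
#' @param contigId contig identifier.
#' @param L contig length (bp).
#' @param anomalies data.frame from [scoreWindowAnomalies()] (any contigs;
#'   filtered internally).
#' @param rb read-breakpoint track from [readBreakpointTrack()].
#' @param window window width in bp (default 100).
#' @param endExclusion terminal exclusion in bp (default 300).
#' @return one-row data.frame: `contig_id`, `position` (0-based),
#'   `anomaly_score`, `rb_count`, `rb_ratio`, `provenance`
#'   (`"ratio_max"` or `"window_center"`).
#' @export
localizeBreakpoint <- function(contigId, L, anomalies, rb, window = 100L,
                               endExclusion = 300L) {
    a <- anomalies[anomalies$contig_id == contigId, , drop = FALSE]
    a <- .eligibleWindows(a, L, window, endExclusion)
    if (nrow(a) == 0L)
        stop("no eligible windows on ", contigId,
             " after terminal exclusion; contig too short")
    a <- a[order(a$window_start), , drop = FALSE]
    best <- a[which.max(a$anomaly), , drop = FALSE]
    ws <- best$window_start
    idx <- seq.int(ws + 1L, min(ws + window, L)) # 1-based into tracks
    cnt <- rb$count[idx]
    if (any(cnt >= 1L)) {
        ratio <- rb$ratio[idx]
        off <- which.max(ratio)
        pos <- ws + off - 1L
        prov <- "ratio_max"
    } else {
        pos <- ws + window %/% 2L
        prov <- "window_center"
    }
    data.frame(contig_id = contigId, position = as.integer(pos),
               anomaly_score = best$anomaly,
               rb_count = rb$count[pos + 1L], rb_ratio = rb$ratio[pos + 1L],
               provenance = prov, stringsAsFactors = FALSE)
}

#' Isolate-genome breakpoint calling
#'
#' In isolate mode no classifier is applied: every window with anomaly score
#' strictly above `scoreThreshold` (default 0.95) is an error region, and
#' every position inside it with read breakpoint count strictly above
#' `countThreshold` (default 5) and ratio strictly above `ratioThreshold`
#' (default 0.2) is emitted as a misassembly breakpoint. The terminal
#' `endExclusion` bp of each contig are never considered. An empty result is
#' allowed.
#'
#' @param anomalies data.frame from [scoreWindowAnomalies()].
#' @param rbTracks named list of read-breakpoint tracks
#'   ([readBreakpointTrack()]) keyed by contig id.
#' @param lengths named integer vector of contig lengths.
#' @param scoreThreshold,countThreshold,ratioThreshold strict thresholds.
#' @param window window width (default 100).
#' @param endExclusion terminal exclusion (default 300).
#' @return data.frame of breakpoints (possibly 0 rows) with the same columns
#'   as [localizeBreakpoint()] plus `window_start`.
#' @export
callBreakpointsIsolate <- function(anomalies, rbTracks, lengths,
                                   scoreThreshold = 0.95, countThreshold = 5L,
                                   ratioThreshold = 0.2, window = 100L,
                                   endExclusion = 300L) {
    out <- list()
    hot <- anomalies[anomalies$anomaly > scoreThreshold, , drop = FALSE]
    for (i in seq_len(nrow(hot))) {
        cid <- hot$contig_id[i]
        L <- unname(lengths[cid])
        if (is.na(L)) next
        ws <- hot$window_start[i]
        if (ws < endExclusion || ws + window > L - endExclusion) next
        rb <- rbTracks[[cid]]
        idx <- seq.int(ws + 1L, min(ws + window, L))
        sel <- idx[rb$count[idx] > countThreshold & rb$ratio[idx] > ratioThreshold]
        for (p1 in sel) {
            out[[length(out) + 1L]] <- data.frame(
                contig_id = cid, position = p1 - 1L,
                anomaly_score = hot$anomaly[i], window_start = ws,
                rb_count = rb$count[p1], rb_ratio = rb$ratio[p1],
                provenance = "ratio_max", stringsAsFactors = FALSE)
        }
    }
    if (length(out) == 0L)
        return(data.frame(contig_id = character(0), position = integer(0),
                          anomaly_score = numeric(0), window_start = integer(0),
                          rb_count = integer(0), rb_ratio = numeric(0),
                          provenance = character(0), stringsAsFactors = FALSE))
    do.call(rbind, out)
}
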