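# Evaluation: contig-level classification counts, breakpoint error size,
# PR-curve area, binning quality from nucleotide overlaps.

#' Binning quality metrics from nucleotide overlaps
#'
#' For each bin, the representative genome is the genome covered by the
#' highest fraction of nucleotides from that bin (ties broken by
#' lexicographic genome id). Nucleotides of the bin belonging to the
#' representative genome are true positives (TP); the remaining bin
#' nucleotides are false positives (FP); representative-genome nucleotides
#' not covered by the bin are false negatives (FN). Then
#' `completeness = TP/(TP+FN)`, `purity = TP/(TP+FP)`,
#' `contamination = 1 - purity`, and
#' `F1 = 2 * completeness * purity / (completeness + purity)`.
#'
#' @param overlaps data.frame with columns `bin_id`, `genome_id`,
#'   `overlap_nt` (nucleotides of the bin covered by that genome).
#' @param binSizes named numeric vector: total nucleotides per bin.
#' @param genomeSizes named numeric vector: total nucleotides per genome.
#' @return data.frame with one row per bin: `bin_id`, `representative`,
#'   `TP`, `FP`, `FN`, `completeness`, `purity`, `contamination`, `f1`.
#' @export
binningMetrics <- function(overlaps, binSizes, genomeSizes) {
    bins <- unique(overlaps$bin_id)
    if (length(bins) == 0L) stop("empty overlap table: nothing to evaluate")
    rows <- lapply(bins, function(b) {
        sub <- overlaps[overlaps$bin_id == b, , drop = FALSE]
        if (sum(sub$overlap_nt) == 0 || is.na(binSizes[b]) || binSizes[b] <= 0)
            stop("empty bin: ", b)
        sub <- sub[order(-sub$overlap_nt, sub$genome_id), , drop = FALSE]
        rep <- sub$genome_id[1]
        TP <- sub$overlap_nt[1]
        FP <- unname(binSizes[b]) - TP
        FN <- unname(genomeSizes[rep]) - TP
        completeness <- TP / (TP + FN)
        purity <- TP / (TP + FP)
        data.frame(bin_id = b, representative = rep, TP = TP, FP = FP, FN = FN,
                   completeness = completeness, purity = purity,
                   contamination = 1 - purity,
                   f1 = 2 * completeness * purity / (completeness + purity),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Breakpoint error size
#'
#' Distance from a predicted breakpoint to the nearest truth junction, both
#' absolute (bp) and normalized by the contig length.
#'
#' @param predicted predicted breakpoint position(s), 0-based.
#' @param truthJunctions non-empty vector of truth junction positions.
#' @param L contig length in bp.
#' @return data.frame `predicted`, `error`, `normalized_error`.
#' @export
breakpointError <- function(predicted, truthJunctions, L) {
    if (length(truthJunctions) == 0L) stop("no truth junctions supplied")
    err <- vapply(predicted,
                  function(p) min(abs(p - truthJunctions)), numeric(1))
    data.frame(predicted = predicted, error = err,
               normalized_error = err / L)
}

#' Event-level classification counts
#'
#' TP = true misassemblies identified, FP = correctly assembled contigs
#' flagged as misassembled, FN = true misassemblies not identified; plus the
#' derived precision, recall, and F1.
#'
#' @param flagged contig ids called misassembled.
#' @param truthIds contig ids that are truly misassembled.
#' @param universe optional full contig id set; when supplied, ids outside it
#'   raise an error.
#' @return one-row data.frame `TP`, `FP`, `FN`, `precision`, `recall`, `f1`.
#' @export
classificationCounts <- function(flagged, truthIds, universe = NULL) {
    if (!is.null(universe)) {
        bad <- setdiff(c(flagged, truthIds), universe)
        if (length(bad) > 0L)
            stop("ids outside the contig universe: ",
                 paste(head(bad, 5), collapse = ", "))
    }
    TP <- length(intersect(flagged, truthIds))
    FP <- length(setdiff(flagged, truthIds))
    FN <- length(setdiff(truthIds, flagged))
    precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
    recall <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
        2 * precision * recall / (precision + recall) else NA_real_
    data.frame(TP = TP, FP = FP, FN = FN, precision = precision,
               recall = recall, f1 = f1)
}

#' Area under the precision-recall curve
#'
#' Step-wise average precision: scores are swept from high to low over the
#' distinct thresholds; each recall increment contributes the precision at
#' that threshold (ties grouped). Invariant under strictly monotone score
#' transforms.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels logical (or 0/1) truth labels.
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
    labels <- as.logical(labels)
    ok <- !is.na(scores) & !is.na(labels)
    scores <- scores[ok]
    labels <- labels[ok]
    nPos <- sum(labels)
    if (nPos == 0L || nPos == length(labels))
        stop("both classes must be present to compute AUPRC")
    o <- order(scores, decreasing = TRUE)
    s <- scores[o]
    y <- labels[o]
    cumTP <- cumsum(y)
    cumP <- seq_along(y)
    # group ties: evaluate at the last index of each distinct score
    lastOfGroup <- c(s[-length(s)] != s[-1], TRUE)
    tp <- cumTP[lastOfGroup]
    pp <- cumP[lastOfGroup]
    prec <- tp / pp
    rec <- tp / nPos
    dRec <- diff(c(0, rec))
    sum(dRec * prec)
}

#' Purity of split fragments against the truth segment map
#'
#' For each fragment produced by splitting a contig, the fraction of its
#' bases originating from the fragment's dominant truth segment. A fragment
#' mapping end-to-end to a single source-genome segment has purity 1; a
#' fragment is called pure when purity is at least `threshold`.
#'
#' @param plan correction plan from [correctAssembly()].
#' @param segments truth segment table from [injectMisassemblies()].
#' @param threshold purity threshold (default 0.95).
#' @return data.frame `fragment_id`, `contig_id`, `start`, `end`, `purity`,
#'   `pure`.
#' @export
fragmentPurity <- function(plan, segments, threshold = 0.95) {
    rows <- list()
    for (i in which(plan$action == "split")) {
        cid <- plan$contig_id[i]
        segs <- segments[segments$contig_id == cid, , drop = FALSE]
        L <- max(segs$cend)
        cuts <- as.integer(strsplit(plan$breakpoints[i], ",")[[1]])
        edges <- c(0L, cuts, L)
        for (j in seq_len(length(edges) - 1L)) {
            a <- edges[j]; b <- edges[j + 1L]
            ovl <- pmax(0L, pmin(b, segs$cend) - pmax(a, segs$cstart))
            purity <- max(ovl) / (b - a)
            rows[[length(rows) + 1L]] <- data.frame(
                fragment_id = sprintf("%s_%d", cid, j), contig_id = cid,
                start = a, end = b, purity = purity,
                pure = purity >= threshold, stringsAsFactors = FALSE)
        }
    }
    if (length(rows) == 0L)
        return(data.frame(fragment_id = character(0), contig_id = character(0),
                          start = integer(0), end = integer(0),
                          purity = numeric(0), pure = logical(0)))
    do.call(rbind, rows)
}

#' Count chimeric sequences against truth junctions
#'
#' A sequence (an original contig, or a fragment of one) is chimeric when a
#' truth junction lies strictly in its interior. Splitting exactly at a
#' junction therefore removes the chimera; a split far from the junction
#' leaves one chimeric fragment.
#'
#' @param plan correction plan from [correctAssembly()] (or `NULL` for the
#'   uncorrected assembly).
#' @param truth per-contig truth table from [injectMisassemblies()].
#' @return number of chimeric sequences.
#' @export
countChimericSequences <- function(plan, truth) {
    n <- 0L
    for (i in seq_len(nrow(truth))) {
        j <- truth$junction[i]
        if (is.na(j)) next
        L <- truth$length[i]
        cid <- truth$contig_id[i]
        edges <- c(0L, L)
        if (!is.null(plan)) {
            r <- which(plan$contig_id == cid)
            if (length(r) == 1L && plan$action[r] == "split")
                edges <- c(0L,
                           as.integer(strsplit(plan$breakpoints[r], ",")[[1]]),
                           L)
        }
        for (f in seq_len(length(edges) - 1L))
            if (edges[f] < j && j < edges[f + 1L]) n <- n + 1L
    }
    n
}
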