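# Feature extraction: the four feature families at contig level and per
# 100-bp window (read-pair consistency, standardized coverage, nucleotide
# variants, k-mer abundance difference).

.FEATURES <- c(
    "proper_frac", "mate_other_frac", "wrong_insert_frac",
    "wrong_orientation_frac", "clipped_frac", "supplementary_frac",
    "sigma_read_coverage", "sigma_fragment_coverage",
    "unusual_read_coverage_frac", "unusual_fragment_coverage_frac",
    "discordant_base_frac", "ambiguous_base_frac", "correct_base_frac",
    "kad_error_frac", "mean_abs_kad", "log_length")

#' Feature manifest
#'
#' The fixed, ordered names of the features shared by contig-level and
#' window-level feature vectors. Models refuse feature tables whose columns
#' do not match this manifest.
#'
#' @return character vector of feature names.
#' @export
featureManifest <- function() .FEATURES

#' Read-pair fraction features
#'
#' The proportion of each of the six read categories among all retained
#' primary reads mapping to the scope: the four mutually exclusive
#' pair-geometry classes (proper, mate on another contig, wrong insert size,
#' wrong orientation) plus the two independent flags (clipped,
#' supplementary).
#'
#' @param classified records data.frame as returned by [classifyPairs()].
#' @return named numeric vector of six fractions.
#' @export
pairFractionFeatures <- function(classified) {
    n <- nrow(classified)
    if (n == 0L) stop("no retained reads: pair fractions undefined")
    geo <- table(classified$pairClass) / n
    c(proper_frac = unname(geo["proper"]),
      mate_other_frac = unname(geo["mate_other_contig"]),
      wrong_insert_frac = unname(geo["wrong_insert"]),
      wrong_orientation_frac = unname(geo["wrong_orientation"]),
      clipped_frac = mean(classified$clipped),
      supplementary_frac = mean(classified$supplementary))
}

#' Standardized-coverage features
#'
#' Per-base coverage is standardized by the mean coverage of the contig, so
#' a value of 1 is the contig's typical depth. The features are the root mean
#' square deviation of the standardized coverage from 1 (for the read and
#' fragment tracks separately) and the fraction of bases whose standardized
#' coverage falls outside `bounds` (strict inequalities, default (0.5, 2)).
#'
#' @param track a [PileupTrack-class] object.
#' @param bounds length-2 numeric, the (low, high) usual-coverage band.
#' @return named numeric vector of four features.
#' @export
coverageFeatures <- function(track, bounds = c(0.5, 2)) {
    .covStats <- function(cov, prefix) {
        mu <- mean(cov)
        if (mu <= 0) stop("all-zero ", prefix, " coverage: features undefined")
        std <- cov / mu
        c(sqrt(mean((std - 1)^2)), mean(std < bounds[1] | std > bounds[2]))
    }
    r <- .covStats(track@readCoverage, "read")
    f <- .covStats(track@fragmentCoverage, "fragment")
    c(sigma_read_coverage = r[1], sigma_fragment_coverage = f[1],
      unusual_read_coverage_frac = r[2], unusual_fragment_coverage_frac = f[2])
}

#' Nucleotide-variant proportions
#'
#' At each position the mapped base calls are counted as correct (matching
#' the contig base), discordant (a different A/C/G/T), or ambiguous (N). The
#' features are the column-summed counts divided by the total number of
#' mapped bases over the scope.
#'
#' @param track a [PileupTrack-class] object.
#' @param scope optional 0-based half-open `c(start, end)` restricting the
#'   computation to a sub-interval of the contig.
#' @return named numeric vector `(discordant, ambiguous, correct)`.
#' @export
variantProportions <- function(track, scope = NULL) {
    idx <- if (is.null(scope)) seq_len(track@length) else
        seq.int(scope[1] + 1L, scope[2])
    disc <- sum(track@nDiscordant[idx])
    amb <- sum(track@nAmbiguous[idx])
    corr <- sum(track@nCorrect[idx])
    tot <- disc + amb + corr
    if (tot == 0L) stop("no mapped bases in scope: variant proportions undefined")
    c(discordant_base_frac = disc / tot, ambiguous_base_frac = amb / tot,
      correct_base_frac = corr / tot)
}

#' k-mer profile of a contig and its mapped reads
#'
#' Counts canonical k-mers (the lexicographic minimum of a k-mer and its
#' reverse complement) in the contig and tallies, for every k-mer present in
#' the contig, its abundance in the reads mapped to that contig. k-mers
#' containing non-ACGT bases are skipped.
#'
#' @param contigSeq contig sequence (`DNAString` or character).
#' @param readSeqs character vector of mapped read sequences (primary
#'   alignments; the full read including clipped tails).
#' @param k k-mer size (default 25).
#' @return list with elements `k`; per contig k-mer start position (0-based):
#'   `n` (copies in the contig), `c` (abundance in reads), `valid`; and
#'   `singleCopyAbundance`, the read abundances of the distinct single-copy
#'   contig k-mers.
#' @export
kmerProfile <- function(contigSeq, readSeqs, k = 25L) {
    stopifnot(k >= 3L)
    res <- .contigKmerCounts(as.character(contigSeq), as.character(readSeqs),
                             as.integer(k))
    list(k = as.integer(k), n = res$n, c = res$c, valid = res$valid,
         singleCopyAbundance = res$single_copy_abundance)
}

#' Estimate sequencing depth from single-copy k-mers
#'
#' The contig's sequencing depth `m` is the median read abundance of the
#' k-mers that occur exactly once in the contig.
#'
#' @param profile a profile from [kmerProfile()].
#' @return depth `m` (positive numeric).
#' @export
estimateDepth <- function(profile) {
    sc <- profile$singleCopyAbundance
    if (length(sc) == 0L)
        stop("no single-copy k-mers: depth cannot be estimated")
    m <- median(sc)
    if (m <= 0)
        stop("single-copy k-mers have no read support: depth cannot be estimated")
    m
}

#' k-mer abundance difference (KAD)
#'
#' `KAD = log2((c + m) / (m (n + 1)))` compares a k-mer's abundance `c` in
#' the mapped reads against its copy number `n` in the contig at sequencing
#' depth `m`. A k-mer whose KAD value falls outside `[-0.5, 0.5]` is an
#' error k-mer.
#'
#' @param c read abundance(s) of the k-mer (>= 0).
#' @param m sequencing depth (> 0).
#' @param n copy number(s) of the k-mer in the contig (>= 0).
#' @return numeric vector of KAD values.
#' @export
kadValue <- function(c, m, n) {
    if (any(m <= 0)) stop("sequencing depth m must be positive")
    log2((c + m) / (m * (n + 1)))
}

#' KAD error bases of a contig
#'
#' Scores every contig k-mer with [kadValue()]; a contig base is an error
#' base when at least one error k-mer (KAD outside `[-0.5, 0.5]`) covers it.
#' k-mers containing N are skipped and impose no flags.
#'
#' @param profile a profile from [kmerProfile()].
#' @param L contig length in bp.
#' @param m optional pre-computed depth; estimated via [estimateDepth()]
#'   when missing.
#' @return list with `kad` (per k-mer start position; NA where invalid),
#'   `errorKmer` (logical), `errorBase` (logical of length `L`), and `m`.
#' @export
kadErrorBases <- function(profile, L, m = NULL) {
    if (is.null(m)) m <- estimateDepth(profile)
    kad <- rep(NA_real_, length(profile$n))
    ok <- profile$valid
    kad[ok] <- kadValue(profile$c[ok], m, profile$n[ok])
    errK <- !is.na(kad) & (kad < -0.5 | kad > 0.5)
    errorBase <- logical(L)
    if (any(errK)) {
        p <- which(errK) - 1L # 0-based k-mer starts
        ir <- IRanges::IRanges(p + 1L, pmin(p + profile$k, L))
        errorBase <- as.integer(IRanges::coverage(ir, width = L)) > 0L
    }
    list(kad = kad, errorKmer = errK, errorBase = errorBase, m = m)
}

# sums of a per-base vector over consecutive non-overlapping tiles
.tileSums <- function(x, nw, window) {
    colSums(matrix(x[seq_len(nw * window)], nrow = window))
}

#' Assemble the feature vector(s) of one contig
#'
#' Computes the full feature manifest over the whole contig (`mode =
#' "contig"`) or over consecutive non-overlapping 100-bp tiles (`mode =
#' "window"`, final partial tile dropped). Per-base standardized coverage is
#' always relative to the contig-wide mean, so window features retain
#' coverage-level anomalies; contig-level pair fractions are per-read counts
#' while window-level fractions weight reads by their base overlap with the
#' window. Windows without mapped bases are returned with `usable = FALSE`
#' and NA features.
#'
#' In contig mode the terminal `trim` bp of the contig are excluded from the
#' feature scope whenever the remaining interior is at least 1000 bp: reads
#' clipped at contig ends and the fragment-coverage ramp-up there are mapping
#' artifacts shared by correctly and incorrectly assembled contigs (the same
#' rationale behind the 300-bp terminal exclusion applied during breakpoint
#' localization), while misassembly junctions are interior by construction.
#'
#' @param track a [PileupTrack-class] for the contig.
#' @param classified classified records from [classifyPairs()] for the contig.
#' @param kad result of [kadErrorBases()] for the contig.
#' @param mode `"contig"` or `"window"`.
#' @param window tile width in bp (default 100).
#' @param bounds unusual-coverage band (default (0.5, 2), strict).
#' @param trim terminal exclusion in bp for contig-level features (default
#'   300; ignored when the interior would drop below 1000 bp).
#' @return data.frame with `contig_id` (and `window_start`, 0-based, in
#'   window mode), `usable`, and the manifest features.
#' @export
assembleFeatures <- function(track, classified, kad, mode = c("contig", "window"),
                             window = 100L, bounds = c(0.5, 2), trim = 300L) {
    mode <- match.arg(mode)
    L <- track@length
    rmu <- mean(track@readCoverage)
    fmu <- mean(track@fragmentCoverage)
    if (rmu <= 0) stop("all-zero read coverage on ", track@contig)

    if (mode == "contig") {
        eff <- if (L - 2L * trim >= 1000L) trim else 0L
        idx <- seq.int(eff + 1L, L - eff)
        inner <- classified[classified$end > eff & classified$start < L - eff, ,
                            drop = FALSE]
        pf <- pairFractionFeatures(inner)
        covStats <- function(cov, what) {
            mu <- mean(cov[idx])
            if (mu <= 0) stop("all-zero ", what, " coverage: features undefined")
            std <- cov[idx] / mu
            c(sqrt(mean((std - 1)^2)),
              mean(std < bounds[1] | std > bounds[2]))
        }
        r <- covStats(track@readCoverage, "read")
        f <- covStats(track@fragmentCoverage, "fragment")
        cf <- c(sigma_read_coverage = r[1], sigma_fragment_coverage = f[1],
                unusual_read_coverage_frac = r[2],
                unusual_fragment_coverage_frac = f[2])
        vp <- variantProportions(track, c(eff, L - eff))
        kpos <- seq.int(eff + 1L, min(L - eff, length(kad$kad)))
        kv <- kad$kad[kpos]
        kv <- kv[!is.na(kv)]
        feat <- c(pf, cf, vp,
                  kad_error_frac = mean(kad$errorBase[idx]),
                  mean_abs_kad = if (length(kv) > 0) mean(abs(kv)) else 0,
                  log_length = log10(L))
        out <- data.frame(contig_id = track@contig, usable = TRUE,
                          t(feat[.FEATURES]), check.names = FALSE)
        rownames(out) <- NULL
        return(out)
    }

    if (L < window) stop("contig shorter than one window: ", track@contig)
    nw <- L %/% window
    starts <- (seq_len(nw) - 1L) * window

    # per-class base-overlap coverage for window pair fractions
    prim <- classified
    covOf <- function(sel) .coverageVector(prim$start[sel], prim$end[sel], L)
    classCov <- lapply(levels(prim$pairClass), function(cl) covOf(prim$pairClass == cl))
    names(classCov) <- levels(prim$pairClass)
    clipCov <- covOf(prim$clipped)
    suppCov <- covOf(prim$supplementary)
    totCov <- track@readCoverage

    totW <- .tileSums(totCov, nw, window)
    fracW <- function(cov) ifelse(totW > 0, .tileSums(cov, nw, window) / totW, NA_real_)

    stdR <- track@readCoverage / rmu
    stdF <- if (fmu > 0) track@fragmentCoverage / fmu else rep(NA_real_, L)
    sigW <- function(std) sqrt(.tileSums((std - 1)^2, nw, window) / window)
    unuW <- function(std) .tileSums(as.numeric(std < bounds[1] | std > bounds[2]),
                                    nw, window) / window

    disc <- .tileSums(track@nDiscordant, nw, window)
    amb <- .tileSums(track@nAmbiguous, nw, window)
    corr <- .tileSums(track@nCorrect, nw, window)
    base <- disc + amb + corr

    errW <- .tileSums(as.numeric(kad$errorBase), nw, window) / window
    # mean |KAD| over k-mers starting inside each window
    kadAbs <- abs(kad$kad)
    npos <- length(kadAbs)
    meanKadW <- vapply(seq_len(nw), function(i) {
        lo <- starts[i] + 1L
        hi <- min(starts[i] + window, npos)
        if (lo > hi) return(0)
        v <- kadAbs[lo:hi]
        v <- v[!is.na(v)]
        if (length(v) == 0L) 0 else mean(v)
    }, numeric(1))

    out <- data.frame(
        contig_id = track@contig, window_start = starts,
        usable = totW > 0 & base > 0 & fmu > 0,
        proper_frac = fracW(classCov$proper),
        mate_other_frac = fracW(classCov$mate_other_contig),
        wrong_insert_frac = fracW(classCov$wrong_insert),
        wrong_orientation_frac = fracW(classCov$wrong_orientation),
        clipped_frac = fracW(clipCov),
        supplementary_frac = fracW(suppCov),
        sigma_read_coverage = sigW(stdR),
        sigma_fragment_coverage = sigW(stdF),
        unusual_read_coverage_frac = unuW(stdR),
        unusual_fragment_coverage_frac = unuW(stdF),
        discordant_base_frac = ifelse(base > 0, disc / base, NA_real_),
        ambiguous_base_frac = ifelse(base > 0, amb / base, NA_real_),
        correct_base_frac = ifelse(base > 0, corr / base, NA_real_),
        kad_error_frac = errW,
        mean_abs_kad = meanKadW,
        log_length = log10(window),
        check.names = FALSE)
    out[!out$usable, .FEATURES] <- NA_real_
    rownames(out) <- NULL
    out
}

#' Extract contig- or window-level features for an assembly
#'
#' Loops [assembleFeatures()] over all contigs with mapped reads: builds the
#' pileup, classifies pairs, computes the KAD profile from the reads mapped
#' to each contig, and assembles the manifest features. Contigs whose
#' features are undefined (no coverage, no single-copy k-mers, or no proper
#' fragments) are skipped with a reason.
#'
#' @param aln a [ContigAlignments-class] object.
#' @param contigs named `DNAStringSet` of the assembly (or FASTA path).
#' @param model an [InsertSizeModel-class]; fitted from `aln` when missing.
#' @param mode `"contig"` or `"window"`.
#' @param window tile width in bp for window mode (default 100).
#' @param k k-mer size for KAD (default 25).
#' @param clipMin clip length for the clipped flag (default 20).
#' @param bounds unusual-coverage band (default (0.5, 2)).
#' @param trim terminal exclusion for contig-level features (default 300 bp;
#'   see [assembleFeatures()]).
#' @return data.frame of feature vectors; attribute `"skipped"` names the
#'   contigs excluded and why. In contig mode a `length` column is included.
#' @export
extractFeatures <- function(aln, contigs, model = NULL,
                            mode = c("contig", "window"), window = 100L,
                            k = 25L, clipMin = 20L, bounds = c(0.5, 2),
                            trim = 300L) {
    mode <- match.arg(mode)
    if (is.character(contigs)) contigs <- Biostrings::readDNAStringSet(contigs)
    names(contigs) <- sub("\\s.*$", "", names(contigs))
    if (is.null(model)) model <- fitInsertSizeModel(aln)
    rec <- aln@records
    ids <- names(aln@contigLengths)
    rows <- list()
    skipped <- character(0)
    for (cid in ids) {
        sub <- rec[rec$contig == cid, , drop = FALSE]
        prim <- sub[!sub$isSupplementary, , drop = FALSE]
        if (nrow(prim) == 0L) {
            skipped[cid] <- "no mapped reads"
            next
        }
        L <- unname(aln@contigLengths[cid])
        if (mode == "window" && L < window) {
            skipped[cid] <- "shorter than one window"
            next
        }
        res <- tryCatch({
            track <- buildPileup(aln, cid, contigs[[cid]], model)
            cl <- classifyPairs(sub, model, clipMin = clipMin)
            prof <- kmerProfile(contigs[[cid]], cl$seq, k = k)
            kad <- kadErrorBases(prof, L)
            assembleFeatures(track, cl, kad, mode = mode, window = window,
                             bounds = bounds, trim = trim)
        }, error = function(e) conditionMessage(e))
        if (is.character(res)) {
            skipped[cid] <- res
            next
        }
        if (mode == "contig") res$length <- L
        rows[[cid]] <- res
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "skipped") <- skipped
    out
}

#' Write a feature table as TSV
#'
#' @param features data.frame from [extractFeatures()].
#' @param path output file.
#' @export
writeFeatureTable <- function(features, path) {
    write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
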