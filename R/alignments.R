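# Alignment ingestion: SAM/BAM -> alignment records, insert-size model,
# read-pair classification, per-base pileup tracks.

PAIR_CLASSES <- c("proper", "mate_other_contig", "wrong_insert", "wrong_orientation")

.flagBit <- function(flag, bit) bitwAnd(flag, bit) > 0L

# leading/trailing clip lengths from CIGARs (vectorized; aligners emit a
# single S or H op per end, with at most a hard clip outside a soft clip)
.cigarClips <- function(cigar) {
    num <- function(x) { v <- suppressWarnings(as.integer(x)); ifelse(is.na(v), 0L, v) }
    lh <- num(sub("^([0-9]+)H.*$", "\\1", cigar, perl = TRUE))
    ls <- num(sub("^(?:[0-9]+H)?([0-9]+)S.*$", "\\1", cigar, perl = TRUE))
    rs <- num(sub("^.*?([0-9]+)S(?:[0-9]+H)?$", "\\1", cigar, perl = TRUE))
    rh <- num(sub("^.*?([0-9]+)H$", "\\1", cigar, perl = TRUE))
    cbind(left = lh + ls, right = rs + rh)
}

#' Load read-to-contig alignments
#'
#' Reads a coordinate-sorted indexed BAM file (or a SAM file, which is
#' converted, sorted, and indexed on the fly) and returns the retained
#' alignment records: unmapped and secondary alignments are dropped, records
#' below `minMapq` are dropped, supplementary alignments are retained but
#' flagged. SAM 1-based closed coordinates are converted to 0-based half-open.
#'
#' @param path BAM or SAM file. A BAM must be accompanied by a `.bai` index.
#' @param minMapq minimum mapping quality; lower-quality records are dropped
#'   (default 10). MAPQ 255 ("unavailable") is retained.
#' @param contigs optional named `DNAStringSet` (or FASTA path) of the
#'   assembly; contig names/lengths in the alignment header are checked
#'   against it.
#' @return a [ContigAlignments-class] object. The `records` data.frame has
#'   one row per retained alignment with columns `qname`, `contig`, `start`
#'   and `end` (0-based half-open), `mapq`, `isReverse`, `isFirstMate`,
#'   `isSupplementary`, `mateContig` (`NA` when unmapped/absent),
#'   `mateStart` (0-based), `mateReverse`, `tlen`, `clipLeft`, `clipRight`,
#'   `cigar`, `seq`, and `hasSupplementary` (TRUE when any supplementary
#'   record of the same read exists).
#' @export
readContigAlignments <- function(path, minMapq = 10L, contigs = NULL) {
    if (!file.exists(path)) stop("alignment file not found: ", path)
    isSam <- grepl("\\.sam$", path, ignore.case = TRUE)
    if (isSam) {
        dest <- tempfile(fileext = "")
        bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                                indexDestination = FALSE)
        sorted <- Rsamtools::sortBam(bam, destination = paste0(dest, "_sorted"))
        Rsamtools::indexBam(sorted)
        bamPath <- sorted
    } else {
        bamPath <- path
        if (!file.exists(paste0(path, ".bai")) &&
            !file.exists(sub("\\.bam$", ".bai", path)))
            stop("BAM index (.bai) missing for ", path,
                 "; sort and index the file first")
    }

    hdr <- Rsamtools::scanBamHeader(bamPath)[[1]]
    lens <- hdr$targets
    if (length(lens) == 0L) stop("alignment header declares no contigs: ", path)
    if (!is.null(contigs)) {
        if (is.character(contigs)) contigs <- Biostrings::readDNAStringSet(contigs)
        miss <- setdiff(names(lens), names(contigs))
        if (length(miss) > 0L)
            stop("contigs in alignment header absent from FASTA: ",
                 paste(head(miss, 5), collapse = ", "))
        bad <- names(lens)[lens != Biostrings::width(contigs)[match(names(lens), names(contigs))]]
        if (length(bad) > 0L)
            stop("contig length mismatch between header and FASTA: ",
                 paste(head(bad, 5), collapse = ", "))
    }

    param <- Rsamtools::ScanBamParam(
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                      isSecondaryAlignment = FALSE),
        what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
                 "mrnm", "mpos", "isize", "seq"))
    res <- Rsamtools::scanBam(bamPath, param = param)[[1]]
    keep <- which(is.na(res$mapq) | res$mapq >= minMapq)
    flag <- res$flag[keep]
    cigar <- res$cigar[keep]
    clips <- if (length(keep) > 0L) .cigarClips(cigar) else
        cbind(left = integer(0), right = integer(0))
    refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
    start0 <- res$pos[keep] - 1L
    rec <- data.frame(
        qname = as.character(res$qname[keep]),
        contig = as.character(res$rname[keep]),
        start = as.integer(start0),
        end = as.integer(start0 + refw),
        mapq = as.integer(res$mapq[keep]),
        isReverse = .flagBit(flag, 0x10L),
        isFirstMate = .flagBit(flag, 0x40L),
        isSupplementary = .flagBit(flag, 0x800L),
        mateContig = as.character(ifelse(.flagBit(flag, 0x8L), NA_character_,
                                         as.character(res$mrnm[keep]))),
        mateStart = as.integer(ifelse(.flagBit(flag, 0x8L), NA_integer_,
                                      res$mpos[keep] - 1L)),
        mateReverse = .flagBit(flag, 0x20L),
        tlen = as.integer(res$isize[keep]),
        clipLeft = clips[, "left"],
        clipRight = clips[, "right"],
        cigar = as.character(cigar),
        seq = as.character(res$seq)[keep],
        stringsAsFactors = FALSE
    )
    # flag primaries whose read has a supplementary alignment
    suppKey <- unique(paste(rec$qname, rec$isFirstMate)[rec$isSupplementary])
    rec$hasSupplementary <- paste(rec$qname, rec$isFirstMate) %in% suppKey
    new("ContigAlignments", records = rec,
        contigLengths = setNames(as.integer(lens), names(lens)),
        path = bamPath, minMapq = as.integer(minMapq))
}

#' Fit the insert-size model of a library
#'
#' Estimates the expected insert size mu as the median of the insert sizes of
#' forward-reverse oriented pairs with both mates on the same contig, and
#' sigma as the (unscaled) median absolute deviation of those insert sizes,
#' floored at `sigmaFloor`. Proper-pair bounds are `mu +/- 3 sigma`.
#'
#' @param aln a [ContigAlignments-class] object or its records data.frame.
#' @param sigmaFloor lower bound on sigma in bp (default 1) so that the
#'   proper window never collapses to zero width.
#' @return an [InsertSizeModel-class] object.
#' @export
fitInsertSizeModel <- function(aln, sigmaFloor = 1) {
    rec <- if (is(aln, "ContigAlignments")) aln@records else aln
    stopifnot(sigmaFloor > 0)
    use <- !rec$isSupplementary &
        !is.na(rec$mateContig) & rec$mateContig == rec$contig &
        !is.na(rec$tlen) & rec$tlen > 0L &
        !rec$isReverse & rec$mateReverse &
        rec$start <= rec$mateStart
    ins <- rec$tlen[use]
    if (length(ins) == 0L)
        stop("no usable read pairs to estimate the insert-size model")
    mu <- median(ins)
    sigma <- max(median(abs(ins - mu)), sigmaFloor)
    new("InsertSizeModel", mu = mu, sigma = sigma,
        lower = mu - 3 * sigma, upper = mu + 3 * sigma,
        nPairs = length(ins))
}

#' Classify read pairs against the insert-size model
#'
#' Assigns each primary alignment one of four mutually exclusive pair-geometry
#' classes, with precedence `mate_other_contig` > `wrong_orientation` >
#' `wrong_insert` > `proper`:
#' \itemize{
#'   \item `mate_other_contig`: mate unmapped, absent, or on another contig;
#'   \item `wrong_orientation`: mates on one contig but not forward-reverse
#'     with the forward mate leftmost;
#'   \item `wrong_insert`: consistent orientation but insert size outside
#'     `[mu - 3 sigma, mu + 3 sigma]`;
#'   \item `proper`: otherwise.
#' }
#' Two independent flags are set alongside: `clipped` when at least `clipMin`
#' bases are unaligned at either end of the read, and `supplementary` when
#' any part of the read has a supplementary alignment.
#'
#' @param aln a [ContigAlignments-class] object or records data.frame.
#' @param model an [InsertSizeModel-class].
#' @param clipMin minimum clip length in bp for the clipped flag (default 20).
#' @return the primary records data.frame with added columns `pairClass`
#'   (factor over the four classes), `clipped`, and `supplementary`.
#' @export
classifyPairs <- function(aln, model, clipMin = 20L) {
    rec <- if (is(aln, "ContigAlignments")) aln@records else aln
    rec <- rec[!rec$isSupplementary, , drop = FALSE]
    n <- nrow(rec)
    cls <- rep("proper", n)
    mateOther <- is.na(rec$mateContig) | rec$mateContig != rec$contig
    fw <- !rec$isReverse
    orientOK <- (fw & rec$mateReverse & rec$start <= rec$mateStart) |
        (!fw & !rec$mateReverse & rec$mateStart <= rec$start)
    orientOK[is.na(orientOK)] <- FALSE
    insertBad <- is.na(rec$tlen) | abs(rec$tlen) < model@lower |
        abs(rec$tlen) > model@upper
    cls[!mateOther & orientOK & insertBad] <- "wrong_insert"
    cls[!mateOther & !orientOK] <- "wrong_orientation"
    cls[mateOther] <- "mate_other_contig"
    rec$pairClass <- factor(cls, levels = PAIR_CLASSES)
    rec$clipped <- rec$clipLeft >= clipMin | rec$clipRight >= clipMin
    rec$supplementary <- rec$hasSupplementary
    rec
}

# reference positions (0-based) of 'N' base calls of one record
.ambiguousRefPos <- function(seq, cigar, start0) {
    noff <- as.integer(gregexpr("N", seq, fixed = TRUE)[[1]])
    if (length(noff) == 1L && noff[1] == -1L) return(integer(0))
    qr <- GenomicAlignments::cigarRangesAlongQuerySpace(cigar, ops = "M")[[1]]
    rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(cigar, ops = "M")[[1]]
    out <- integer(0)
    for (j in seq_along(qr)) {
        s <- IRanges::start(qr)[j]; e <- IRanges::end(qr)[j]
        hit <- noff[noff >= s & noff <= e]
        if (length(hit))
            out <- c(out, start0 + IRanges::start(rr)[j] - 1L + (hit - s))
    }
    out
}

.coverageVector <- function(start0, end0, L) {
    if (length(start0) == 0L) return(integer(L))
    ir <- IRanges::IRanges(start = pmax(start0, 0L) + 1L, end = pmin(end0, L))
    ir <- ir[IRanges::width(ir) > 0L]
    as.integer(IRanges::coverage(ir, width = L))
}

#' Build per-base pileup tracks for one contig
#'
#' Computes the per-base arrays used by all downstream features: read
#' coverage (primary aligned spans), fragment coverage (for each proper pair,
#' the interval from the leftmost mate start over the insert size, each pair
#' counted once), correct/discordant/ambiguous base-call counts against the
#' contig sequence (ambiguous = read base N), read-breakpoint counts, and
#' the per-base count of overlapping reads by full extent. Read breakpoints
#' are alignment boundaries that do not coincide with read ends: for a
#' left-side clip the count is deposited at the first aligned base, for a
#' right-side clip at the first clipped base, so both flanks of a chimeric
#' junction accumulate at the junction coordinate. Supplementary alignments
#' contribute to breakpoint counts but not to coverage.
#'
#' @param aln a [ContigAlignments-class] object (its BAM is consulted for
#'   base-level pileup) with records for `contig`.
#' @param contig contig identifier.
#' @param contigSeq `DNAString` (or character) sequence of the contig.
#' @param model an [InsertSizeModel-class] used to identify proper pairs.
#' @return a [PileupTrack-class] object.
#' @export
buildPileup <- function(aln, contig, contigSeq, model) {
    stopifnot(is(aln, "ContigAlignments"))
    L <- unname(aln@contigLengths[contig])
    if (is.na(L) || L <= 0L) stop("unknown contig: ", contig)
    rec <- aln@records[aln@records$contig == contig, , drop = FALSE]
    if (nrow(rec) > 0L && (min(rec$start) < 0L || max(rec$end) > L))
        stop("alignment beyond contig bounds on ", contig)
    prim <- rec[!rec$isSupplementary, , drop = FALSE]

    readCov <- .coverageVector(prim$start, prim$end, L)

    cl <- classifyPairs(rec, model)
    frag <- cl[cl$pairClass == "proper" & cl$tlen > 0L, , drop = FALSE]
    fragCov <- .coverageVector(frag$start, frag$start + frag$tlen, L)

    # base-call agreement via BAM pileup (A/C/G/T); N handled manually below
    nCorrect <- integer(L); nDiscordant <- integer(L); nAmbiguous <- integer(L)
    if (nrow(prim) > 0L) {
        gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(1L, L))
        pp <- Rsamtools::PileupParam(
            distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
            min_base_quality = 0L, min_mapq = aln@minMapq,
            max_depth = 10000000L, min_nucleotide_depth = 1L,
            include_deletions = FALSE, include_insertions = FALSE)
        sp <- Rsamtools::ScanBamParam(
            flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                          isSecondaryAlignment = FALSE,
                                          isSupplementaryAlignment = FALSE),
            which = gr)
        pu <- Rsamtools::pileup(aln@path, scanBamParam = sp, pileupParam = pp)
        pu <- pu[pu$nucleotide %in% c("A", "C", "G", "T"), , drop = FALSE]
        if (nrow(pu) > 0L) {
            refBase <- strsplit(as.character(contigSeq), "")[[1]]
            isMatch <- as.character(pu$nucleotide) == refBase[pu$pos]
            corr <- tapply(pu$count[isMatch], pu$pos[isMatch], sum)
            disc <- tapply(pu$count[!isMatch], pu$pos[!isMatch], sum)
            if (length(corr)) nCorrect[as.integer(names(corr))] <- as.integer(corr)
            if (length(disc)) nDiscordant[as.integer(names(disc))] <- as.integer(disc)
        }
        hasN <- grepl("N", prim$seq, fixed = TRUE)
        if (any(hasN)) {
            for (i in which(hasN)) {
                p <- .ambiguousRefPos(prim$seq[i], prim$cigar[i], prim$start[i])
                p <- p[p >= 0L & p < L]
                nAmbiguous[p + 1L] <- nAmbiguous[p + 1L] + 1L
            }
        }
    }

    # read breakpoints: left clip -> first aligned base; right clip -> first
    # clipped base (dropped if beyond the contig end)
    bp <- c(rec$start[rec$clipLeft >= 1L], rec$end[rec$clipRight >= 1L])
    bp <- bp[bp >= 0L & bp < L]
    rbCount <- integer(L)
    if (length(bp)) {
        tb <- tabulate(bp + 1L, nbins = L)
        rbCount <- as.integer(tb)
    }

    atBase <- .coverageVector(prim$start - prim$clipLeft,
                              prim$end + prim$clipRight, L)

    new("PileupTrack", contig = contig, length = L,
        readCoverage = readCov, fragmentCoverage = fragCov,
        nCorrect = nCorrect, nDiscordant = nDiscordant, nAmbiguous = nAmbiguous,
        readBreakpointCount = rbCount, readsAtBase = atBase)
}
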