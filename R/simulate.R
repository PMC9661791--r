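# Truth-labelled synthetic data: multi-genome community, chimeric contigs,
# paired-end reads, and analytically derived read-to-contig alignments.
#
# Reads are simulated from the source GENOMES and their alignments to the
# CONTIGS are derived by composing the read->genome and genome->contig
# coordinate maps. Misassembly signal (soft clips, discordant pairs,
# coverage shifts) therefore appears at chimera junctions exactly as
# geometry dictates, without running an aligner.

.BASES <- c("A", "C", "G", "T")

.randSeq <- function(len) {
    paste(sample(.BASES, len, replace = TRUE), collapse = "")
}

.revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a multi-genome community
#'
#' Generates `nGenomes` i.i.d. uniform-ACGT genome backbones with relative
#' abundances drawn from Lognormal(5, 2) and normalized to sum to 1.
#' Optional planted repeats copy a segment within a genome (`copies`
#' locations) or across genomes (`genomes` vector), emulating the repetitive
#' structure that causes misassemblies in real communities.
#'
#' @param nGenomes number of genomes (>= 2).
#' @param genomeLength genome length in bp (>= 10000).
#' @param repeatConfig optional list of repeat specs, each a list with
#'   `genome` (index), `length` (bp), and either `copies` (count of extra
#'   copies within the genome) or `genomes` (indices of other genomes that
#'   receive a copy).
#' @param seed integer seed; output is deterministic per seed.
#' @return list with `genomes` (named `DNAStringSet`), `abundance`
#'   (normalized, named), and `repeats` (data.frame of planted copies).
#' @export
simulateCommunity <- function(nGenomes = 10L, genomeLength = 100000L,
                              repeatConfig = NULL, seed = 1L) {
    if (nGenomes < 2L) stop("need at least 2 genomes")
    if (genomeLength < 10000L) stop("genomeLength must be >= 10000")
    .withSeed(seed, {
        seqs <- vapply(seq_len(nGenomes), function(i) .randSeq(genomeLength),
                       character(1))
        ids <- sprintf("genome_%02d", seq_len(nGenomes))
        reps <- list()
        for (rc in repeatConfig) {
            if (is.null(rc$genome) || is.null(rc$length))
                stop("repeat config entries need 'genome' and 'length'")
            g <- rc$genome
            len <- rc$length
            if (len >= genomeLength / 4) stop("repeat too long for genome")
            src <- sample.int(genomeLength - len, 1L)
            unit <- substring(seqs[g], src, src + len - 1L)
            targetGenomes <- if (!is.null(rc$genomes)) rc$genomes else
                rep(g, rc$copies %||% 1L)
            for (tg in targetGenomes) {
                at <- sample.int(genomeLength - len, 1L)
                substring(seqs[tg], at, at + len - 1L) <- unit
                reps[[length(reps) + 1L]] <- data.frame(
                    source_genome = ids[g], source_start = src - 1L,
                    length = len, target_genome = ids[tg], target_start = at - 1L)
            }
        }
        ab <- rlnorm(nGenomes, meanlog = 5, sdlog = 2)
        genomes <- Biostrings::DNAStringSet(setNames(seqs, ids))
        list(genomes = genomes,
             abundance = setNames(ab / sum(ab), ids),
             repeats = if (length(reps)) do.call(rbind, reps) else NULL)
    })
}

# Source intervals are laid out left to right along each genome with short
# random spacers: allocations never overlap (each genomic locus is assembled
# at most once) and the genome space packs without fragmentation. Positional
# uniformity is immaterial for i.i.d. backbones.
.allocSeq <- function(env, g, len, minSpacer = 50L, maxSpacer = 500L) {
    sp <- as.integer(floor(runif(1, minSpacer, maxSpacer + 1)))
    s <- env$cursor[g] + sp
    if (s + len > env$len[g]) return(NULL)
    env$cursor[g] <- s + len
    c(s, s + len)
}

# uniform draw among genomes with enough room left (excluding `exclude`)
.pickGenome <- function(env, need, exclude = integer(0)) {
    cand <- setdiff(seq_along(env$len), exclude)
    cand <- cand[env$len[cand] - env$cursor[cand] >= need + 500L]
    if (length(cand) == 0L) return(NA_integer_)
    if (length(cand) == 1L) cand else sample(cand, 1L)
}

#' Plant misassemblies into synthetic contigs
#'
#' Builds `nContigs` contigs of length `contigLength` from the community
#' genomes. Source intervals never overlap: they are laid out along each
#' genome, separated by short random spacers, so every genomic locus is
#' represented at most once across the assembly (as in a real de novo
#' assembly) and truth alignments are unambiguous. Source genomes are chosen
#' uniformly among those with room left. Each contig is, with probability `chimeraRate`, a chimera of
#' one of three types:
#' \itemize{
#'   \item `inter_translocation`: segments from two different genomes;
#'   \item `relocation`: two segments of one genome whose source intervals
#'     are at least `minGap` bp apart;
#'   \item `inversion`: a contiguous source interval whose second part is
#'     reverse-complemented.
#' }
#' The junction position is uniform within `[0.2 L, 0.8 L]` so breakpoints
#' remain detectable under the terminal exclusion used downstream. Clean
#' contigs are contiguous genome slices (source genome chosen uniformly;
#' abundance affects read depth, not contig origin).
#'
#' @param community output of [simulateCommunity()].
#' @param nContigs number of contigs.
#' @param contigLength contig length in bp (>= 7000).
#' @param chimeraRate per-contig probability of being a chimera, in `[0, 1]`.
#' @param typeMix named weights over the three chimera types.
#' @param minGap minimum genomic gap between relocation segments (default
#'   1000 bp).
#' @param seed integer seed.
#' @return list with `contigs` (named `DNAStringSet`), `truth` (per-contig
#'   data.frame: `contig_id`, `length`, `type`, `junction` 0-based or NA,
#'   `misassembled`), and `segments` (data.frame mapping contig intervals to
#'   genome intervals: `contig_id`, `seg`, `genome`, `gstart`, `gend`,
#'   `strand`, `cstart`, `cend`, all 0-based half-open).
#' @export
injectMisassemblies <- function(community, nContigs = 100L,
                                contigLength = 8000L, chimeraRate = 0.2,
                                typeMix = c(inter_translocation = 1,
                                            relocation = 1, inversion = 1),
                                minGap = 1000L, seed = 1L) {
    if (chimeraRate < 0 || chimeraRate > 1) stop("chimeraRate must be in [0, 1]")
    if (contigLength < 7000L) stop("contigLength must be >= 7000")
    genomes <- community$genomes
    gl <- Biostrings::width(genomes)
    gchar <- as.character(genomes)
    nG <- length(genomes)
    env <- new.env()
    env$len <- gl
    env$cursor <- integer(nG)

    .withSeed(seed, {
        isChim <- runif(nContigs) < chimeraRate
        types <- rep("none", nContigs)
        if (any(isChim))
            types[isChim] <- sample(names(typeMix), sum(isChim), replace = TRUE,
                                    prob = typeMix / sum(typeMix))
        seqs <- character(nContigs)
        truth <- vector("list", nContigs)
        segs <- vector("list", nContigs)
        for (i in seq_len(nContigs)) {
            cid <- sprintf("contig_%03d", i)
            L <- contigLength
            ty <- types[i]
            if (ty == "none") {
                g <- .pickGenome(env, L)
                if (is.na(g)) stop("genomes exhausted: reduce nContigs or contigLength")
                iv <- .allocSeq(env, g, L)
                seqs[i] <- substring(gchar[g], iv[1] + 1L, iv[2])
                segs[[i]] <- data.frame(contig_id = cid, seg = 1L,
                                        genome = names(genomes)[g],
                                        gstart = iv[1], gend = iv[2],
                                        strand = "+", cstart = 0L, cend = L)
                truth[[i]] <- data.frame(contig_id = cid, length = L,
                                         type = "none", junction = NA_integer_,
                                         misassembled = FALSE)
                next
            }
            j <- as.integer(round(runif(1L, 0.2, 0.8) * L))
            if (ty == "inter_translocation") {
                g1 <- .pickGenome(env, j)
                g2 <- .pickGenome(env, L - j, exclude = g1)
                if (is.na(g1) || is.na(g2)) stop("genomes exhausted")
                gs <- c(g1, g2)
                iv1 <- .allocSeq(env, gs[1], j)
                iv2 <- .allocSeq(env, gs[2], L - j)
                seqs[i] <- paste0(substring(gchar[gs[1]], iv1[1] + 1L, iv1[2]),
                                  substring(gchar[gs[2]], iv2[1] + 1L, iv2[2]))
                segs[[i]] <- data.frame(
                    contig_id = cid, seg = 1:2,
                    genome = names(genomes)[gs],
                    gstart = c(iv1[1], iv2[1]), gend = c(iv1[2], iv2[2]),
                    strand = "+", cstart = c(0L, j), cend = c(j, L))
            } else if (ty == "relocation") {
                g <- .pickGenome(env, L + minGap + 1000L)
                if (is.na(g)) stop("genomes exhausted")
                iv1 <- .allocSeq(env, g, j)
                iv2 <- .allocSeq(env, g, L - j, minSpacer = minGap,
                                 maxSpacer = minGap + 500L)
                if (is.null(iv1) || is.null(iv2))
                    stop("could not place relocation segments ",
                         minGap, " bp apart on ", names(genomes)[g])
                seqs[i] <- paste0(substring(gchar[g], iv1[1] + 1L, iv1[2]),
                                  substring(gchar[g], iv2[1] + 1L, iv2[2]))
                segs[[i]] <- data.frame(
                    contig_id = cid, seg = 1:2, genome = names(genomes)[g],
                    gstart = c(iv1[1], iv2[1]), gend = c(iv1[2], iv2[2]),
                    strand = "+", cstart = c(0L, j), cend = c(j, L))
            } else if (ty == "inversion") {
                g <- .pickGenome(env, L)
                if (is.na(g)) stop("genomes exhausted")
                iv <- .allocSeq(env, g, L)
                s1 <- substring(gchar[g], iv[1] + 1L, iv[1] + j)
                s2 <- substring(gchar[g], iv[1] + j + 1L, iv[2])
                seqs[i] <- paste0(s1, .revcomp(s2))
                segs[[i]] <- data.frame(
                    contig_id = cid, seg = 1:2, genome = names(genomes)[g],
                    gstart = c(iv[1], iv[1] + j), gend = c(iv[1] + j, iv[2]),
                    strand = c("+", "-"), cstart = c(0L, j), cend = c(j, L))
            } else stop("unknown misassembly type: ", ty)
            truth[[i]] <- data.frame(contig_id = cid, length = L, type = ty,
                                     junction = j, misassembled = TRUE)
        }
        contigs <- Biostrings::DNAStringSet(setNames(seqs,
                                                     sprintf("contig_%03d", seq_len(nContigs))))
        list(contigs = contigs,
             truth = do.call(rbind, truth),
             segments = do.call(rbind, segs))
    })
}

#' Simulate paired-end reads and their truth alignments
#'
#' Fragments are drawn from the source genomes proportionally to abundance
#' with insert sizes ~ Normal(`insertMu`, `insertSd`) (floored at
#' `readLength`), and i.i.d. substitution errors per base. Each mate is
#' aligned to the assembly analytically: the best-overlapping truth segment
#' (>= `minAligned` aligned bases; ties to the lexicographically first
#' contig) gives the primary alignment, with soft clips where the read
#' extends past the segment; a second disjoint segment overlap yields a
#' supplementary alignment. Pairs whose mates resolve to different contigs
#' (or whose mate is unmapped) become discordant exactly as geometry
#' dictates. A coordinate-sorted SAM with header is written.
#'
#' @param community output of [simulateCommunity()].
#' @param assembly output of [injectMisassemblies()].
#' @param samPath output SAM path.
#' @param meanDepth community-average sequencing depth; genome `g` is covered
#'   at `meanDepth * nGenomes * abundance[g]`.
#' @param readLength read length in bp (default 150).
#' @param insertMu,insertSd insert-size distribution (default 300 +/- 30).
#' @param subErrorRate per-base substitution error rate (default 0.002).
#' @param minAligned minimum aligned bases for a mapping (default 30).
#' @param fastqPrefix optional path prefix; when set, `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq` are written with all read pairs.
#' @param seed integer seed.
#' @return list with `sam` (path), `reads` (truth table of emitted records:
#'   coordinates, clips, orientation, mate info), and `nFragments`.
#' @export
simulateReads <- function(community, assembly, samPath,
                          meanDepth = 30, readLength = 150L,
                          insertMu = 300, insertSd = 30,
                          subErrorRate = 0.002, minAligned = 30L,
                          fastqPrefix = NULL, seed = 1L) {
    if (insertMu < 2 * readLength)
        stop("insertMu must be at least twice the read length")
    if (meanDepth <= 0) stop("meanDepth must be positive")
    genomes <- community$genomes
    ab <- community$abundance
    gl <- Biostrings::width(genomes)
    gchar <- as.character(genomes)
    nG <- length(genomes)
    segs <- assembly$segments
    contigs <- assembly$contigs
    cw <- setNames(Biostrings::width(contigs), names(contigs))

    .withSeed(seed, {
        depthG <- meanDepth * nG * ab
        nFrag <- pmax(0L, as.integer(round(depthG * gl / (2 * readLength))))
        frag <- data.frame(
            genome = rep(seq_len(nG), nFrag),
            flen = pmax(readLength,
                        as.integer(round(rnorm(sum(nFrag), insertMu, insertSd)))))
        frag$flen <- pmin(frag$flen, gl[frag$genome])
        frag$fstart <- as.integer(floor(runif(nrow(frag)) *
                                        (gl[frag$genome] - frag$flen + 1)))
        nF <- nrow(frag)
        frag$qname <- sprintf("frag_%07d", seq_len(nF))

        # mate genome intervals, 0-based half-open
        mates <- rbind(
            data.frame(fid = seq_len(nF), mate = 1L, genome = frag$genome,
                       a = frag$fstart, b = frag$fstart + readLength,
                       gstrand = "+"),
            data.frame(fid = seq_len(nF), mate = 2L, genome = frag$genome,
                       a = frag$fstart + frag$flen - readLength,
                       b = frag$fstart + frag$flen, gstrand = "-"))

        # genome-forward sequences with substitution errors
        gseq <- substring(gchar[mates$genome], mates$a + 1L, mates$b)
        nerr <- rbinom(nrow(mates), readLength, subErrorRate)
        for (i in which(nerr > 0L)) {
            at <- sample.int(readLength, nerr[i])
            s <- strsplit(gseq[i], "")[[1]]
            s[at] <- vapply(s[at],
                            function(bb) sample(setdiff(.BASES, bb), 1L), character(1))
            gseq[i] <- paste(s, collapse = "")
        }
        mates$gseq <- gseq

        # map mates onto truth segments
        segGr <- GenomicRanges::GRanges(
            segs$genome, IRanges::IRanges(segs$gstart + 1L, segs$gend),
            seqlengths = setNames(gl, names(genomes)))
        readGr <- GenomicRanges::GRanges(
            names(genomes)[mates$genome], IRanges::IRanges(mates$a + 1L, mates$b),
            seqlengths = setNames(gl, names(genomes)))
        ov <- GenomicRanges::findOverlaps(readGr, segGr)
        qh <- S4Vectors::queryHits(ov)
        sh <- S4Vectors::subjectHits(ov)
        ow <- IRanges::width(IRanges::pintersect(
            IRanges::ranges(readGr)[qh], IRanges::ranges(segGr)[sh]))
        keep <- ow >= minAligned
        hits <- data.frame(ri = qh[keep], si = sh[keep], ow = ow[keep])
        hits <- hits[order(hits$ri, -hits$ow, segs$contig_id[hits$si],
                           hits$si), , drop = FALSE]
        rank <- stats::ave(hits$ow, hits$ri, FUN = seq_along)
        hits$role <- ifelse(rank == 1, "primary",
                            ifelse(rank == 2, "supplementary", NA))
        hits <- hits[!is.na(hits$role), , drop = FALSE]

        # per-record alignment geometry
        m <- mates[hits$ri, , drop = FALSE]
        sg <- segs[hits$si, , drop = FALSE]
        istart <- pmax(m$a, sg$gstart)
        iend <- pmin(m$b, sg$gend)
        al <- iend - istart
        plus <- sg$strand == "+"
        cstart <- ifelse(plus, sg$cstart + (istart - sg$gstart),
                         sg$cstart + (sg$gend - iend))
        glClip <- istart - m$a
        grClip <- m$b - iend
        rec <- data.frame(
            ri = hits$ri, fid = m$fid, mate = m$mate, role = hits$role,
            qname = frag$qname[m$fid],
            contig = sg$contig_id,
            start = as.integer(cstart),
            end = as.integer(cstart + al),
            clipLeft = as.integer(ifelse(plus, glClip, grClip)),
            clipRight = as.integer(ifelse(plus, grClip, glClip)),
            reverse = (m$gstrand == "+") != plus,
            stringsAsFactors = FALSE)
        needRc <- which(rec$reverse == (m$gstrand == "+")) # seg "-" records
        rec$seq <- m$gseq
        if (length(needRc)) rec$seq[needRc] <- .revcomp(m$gseq[needRc])

        # resolve mate info from primary records
        prim <- rec[rec$role == "primary", , drop = FALSE]
        key <- paste(prim$fid, prim$mate)
        otherKey <- paste(prim$fid, 3L - prim$mate)
        oi <- match(otherKey, key)
        prim$mateContig <- prim$contig[oi]
        prim$mateStart <- prim$start[oi]
        prim$mateEnd <- prim$end[oi]
        prim$mateReverse <- prim$reverse[oi]
        same <- !is.na(prim$mateContig) & prim$mateContig == prim$contig
        span <- pmax(prim$end, prim$mateEnd) - pmin(prim$start, prim$mateStart)
        prim$tlen <- 0L
        lead <- same & (prim$start < prim$mateStart |
                        (prim$start == prim$mateStart & prim$mate == 1L))
        prim$tlen[same] <- ifelse(lead[same], span[same], -span[same])

        # SAM text
        recFlag <- function(df, supp) {
            fl <- 1L + ifelse(df$mate == 1L, 64L, 128L) +
                ifelse(df$reverse, 16L, 0L)
            if (supp) fl <- fl + 2048L
            fl
        }
        cigarOf <- function(df) {
            paste0(ifelse(df$clipLeft > 0L, paste0(df$clipLeft, "S"), ""),
                   df$end - df$start, "M",
                   ifelse(df$clipRight > 0L, paste0(df$clipRight, "S"), ""))
        }
        qual <- strrep("I", readLength)
        pflag <- recFlag(prim, FALSE) +
            ifelse(is.na(prim$mateContig), 8L, 0L) +
            ifelse(!is.na(prim$mateReverse) & prim$mateReverse, 32L, 0L)
        pline <- paste(prim$qname, pflag, prim$contig, prim$start + 1L, 60L,
                       cigarOf(prim),
                       ifelse(is.na(prim$mateContig), "=",
                              ifelse(prim$mateContig == prim$contig, "=",
                                     prim$mateContig)),
                       ifelse(is.na(prim$mateStart), prim$start + 1L,
                              prim$mateStart + 1L),
                       prim$tlen, prim$seq, qual, sep = "\t")

        supp <- rec[rec$role == "supplementary", , drop = FALSE]
        # supplementary only where a primary exists for the same mate
        supp <- supp[paste(supp$fid, supp$mate) %in% key, , drop = FALSE]
        if (nrow(supp) > 0L) {
            pi <- match(paste(supp$fid, supp$mate), key)
            sflag <- recFlag(supp, TRUE) +
                ifelse(is.na(prim$mateContig[pi]), 8L, 0L) +
                ifelse(!is.na(prim$mateReverse[pi]) & prim$mateReverse[pi], 32L, 0L)
            sline <- paste(supp$qname, sflag, supp$contig, supp$start + 1L, 60L,
                           cigarOf(supp),
                           ifelse(is.na(prim$mateContig[pi]), "=",
                                  ifelse(prim$mateContig[pi] == supp$contig, "=",
                                         prim$mateContig[pi])),
                           ifelse(is.na(prim$mateStart[pi]), supp$start + 1L,
                                  prim$mateStart[pi] + 1L),
                           0L, supp$seq, qual, sep = "\t")
        } else sline <- character(0)

        allRec <- rbind(prim[, c("contig", "start")],
                        supp[, c("contig", "start")])
        lines <- c(pline, sline)
        o <- order(factor(allRec$contig, levels = names(contigs)), allRec$start)
        hdr <- c("@HD\tVN:1.6\tSO:coordinate",
                 sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), unname(cw)))
        writeLines(c(hdr, lines[o]), samPath)

        if (!is.null(fastqPrefix)) {
            sequenced <- mates$gseq
            neg <- mates$gstrand == "-"
            sequenced[neg] <- .revcomp(mates$gseq[neg])
            for (mt in 1:2) {
                sel <- mates$mate == mt
                writeLines(paste0("@", frag$qname[mates$fid[sel]], "/", mt, "\n",
                                  sequenced[sel], "\n+\n", qual),
                           sprintf("%s_R%d.fastq", fastqPrefix, mt))
            }
        }

        truthReads <- prim
        truthReads$supp <- paste(prim$fid, prim$mate) %in%
            paste(supp$fid, supp$mate)
        list(sam = samPath, reads = truthReads, nFragments = nF,
             suppRecords = supp)
    })
}

#' Write community genomes or contigs as FASTA
#'
#' @param seqs a named `DNAStringSet`.
#' @param path output FASTA path.
#' @export
writeSimFasta <- function(seqs, path) {
    Biostrings::writeXStringSet(seqs, path, width = 80L)
    invisible(path)
}

#' Write the truth table of an assembly
#'
#' @param assembly output of [injectMisassemblies()].
#' @param path output TSV path.
#' @export
writeSimTruth <- function(assembly, path) {
    write.table(assembly$truth, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
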