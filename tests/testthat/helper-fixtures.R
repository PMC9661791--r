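# Shared fixtures: hand-built SAM files, brute-force oracles independent of
# the package's vectorized implementations, and cached simulations.

samLine <- function(qname, flag, rname, pos1, mapq, cigar, rnext = "*",
                    pnext = 0L, tlen = 0L, seq) {
    paste(qname, flag, rname, pos1, mapq, cigar, rnext, pnext, tlen, seq,
          strrep("I", nchar(seq)), sep = "\t")
}

writeSamFile <- function(lines, contigLens, path = tempfile(fileext = ".sam")) {
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", names(contigLens),
                     as.integer(contigLens)))
    writeLines(c(hdr, lines), path)
    path
}

# deterministic random DNA string
randDna <- function(n, seed = 1) {
    set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rcString <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# ---- brute-force oracles -------------------------------------------------

# KAD oracle: plain string hashing with table(), independent of the Rcpp path
kadOracle <- function(contig, reads, k) {
    kmersOf <- function(s) {
        n <- nchar(s)
        if (n < k) return(character(0))
        substring(s, seq_len(n - k + 1), seq_len(n - k + 1) + k - 1)
    }
    canon <- function(v) {
        ok <- !grepl("[^ACGT]", v)
        out <- rep(NA_character_, length(v))
        if (any(ok)) out[ok] <- pmin(v[ok], rcString(v[ok]))
        out
    }
    ck <- canon(kmersOf(contig))
    ntab <- table(ck[!is.na(ck)])
    rk <- canon(unlist(lapply(reads, kmersOf), use.names = FALSE))
    rtab <- table(rk[!is.na(rk)])
    cOf <- function(km) ifelse(km %in% names(rtab), as.numeric(rtab[km]), 0)
    single <- names(ntab)[ntab == 1]
    m <- median(cOf(single))
    kad <- rep(NA_real_, length(ck))
    ok <- !is.na(ck)
    kad[ok] <- log2((cOf(ck[ok]) + m) / (m * (as.numeric(ntab[ck[ok]]) + 1)))
    err <- !is.na(kad) & (kad < -0.5 | kad > 0.5)
    errorBase <- logical(nchar(contig))
    for (p in which(err)) errorBase[p:(p + k - 1)] <- TRUE
    list(m = m, kad = kad, errorBase = errorBase)
}

# AUPRC oracle: explicit sweep over every distinct threshold
auprcOracle <- function(scores, labels) {
    labels <- as.logical(labels)
    th <- sort(unique(scores), decreasing = TRUE)
    prec <- rec <- numeric(length(th))
    for (i in seq_along(th)) {
        flag <- scores >= th[i]
        prec[i] <- sum(flag & labels) / sum(flag)
        rec[i] <- sum(flag & labels) / sum(labels)
    }
    sum(diff(c(0, rec)) * prec)
}

# pair-class oracle: per-record if/else logic over a records data.frame
pairClassOracle <- function(rec, lower, upper) {
    vapply(seq_len(nrow(rec)), function(i) {
        r <- rec[i, ]
        if (is.na(r$mateContig) || r$mateContig != r$contig)
            return("mate_other_contig")
        fw <- !r$isReverse
        orientOK <- if (fw) r$mateReverse && r$start <= r$mateStart
                    else !r$mateReverse && r$mateStart <= r$start
        if (!isTRUE(orientOK)) return("wrong_orientation")
        if (is.na(r$tlen) || abs(r$tlen) < lower || abs(r$tlen) > upper)
            return("wrong_insert")
        "proper"
    }, character(1))
}

# ---- cached simulations --------------------------------------------------

.fixtureCache <- new.env(parent = emptyenv())

# small community fixture shared across module tests (seconds to build)
smallSim <- function() {
    if (!exists("small", .fixtureCache)) {
        cm <- simulateCommunity(nGenomes = 3, genomeLength = 30000, seed = 7)
        asm <- injectMisassemblies(cm, nContigs = 8, contigLength = 7000,
                                   chimeraRate = 0.4, seed = 8)
        cm$abundance[] <- 1 / 3
        sam <- tempfile(fileext = ".sam")
        sr <- simulateReads(cm, asm, sam, meanDepth = 20, seed = 9)
        aln <- readContigAlignments(sam, contigs = asm$contigs)
        model <- fitInsertSizeModel(aln)
        assign("small", list(cm = cm, asm = asm, sam = sam, sr = sr,
                             aln = aln, model = model), .fixtureCache)
    }
    get("small", .fixtureCache)
}

# one replicate at the study scale used by the acceptance tests
studyReplicate <- function(seed) {
    key <- paste0("rep", seed)
    if (!exists(key, .fixtureCache)) {
        cm <- simulateCommunity(nGenomes = 10, genomeLength = 100000,
                                seed = seed)
        asm <- injectMisassemblies(cm, nContigs = 100, contigLength = 8000,
                                   chimeraRate = 0.2, seed = seed + 1)
        sam <- tempfile(fileext = ".sam")
        sr <- simulateReads(cm, asm, sam, meanDepth = 30, seed = seed + 2)
        aln <- readContigAlignments(sam, contigs = asm$contigs)
        model <- fitInsertSizeModel(aln)
        cf <- extractFeatures(aln, asm$contigs, model, mode = "contig")
        lab <- asm$truth$misassembled[match(cf$contig_id, asm$truth$contig_id)]
        assign(key, list(cm = cm, asm = asm, sam = sam, sr = sr, aln = aln,
                         model = model, cf = cf, lab = lab), .fixtureCache)
    }
    get(key, .fixtureCache)
}
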