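# Synthetic community, planted misassemblies, and read/alignment simulation.

test_that("community generation is deterministic and lognormal", {
    c1 <- simulateCommunity(nGenomes = 3, genomeLength = 20000, seed = 5)
    c2 <- simulateCommunity(nGenomes = 3, genomeLength = 20000, seed = 5)
    expect_identical(as.character(c1$genomes), as.character(c2$genomes))
    expect_identical(c1$abundance, c2$abundance)
    expect_equal(sum(c1$abundance), 1)

    # median of natural-log abundances ~ 5 (meanlog of the lognormal)
    set.seed(1)
    draws <- replicate(10, {
        cm <- simulateCommunity(nGenomes = 100, genomeLength = 10000,
                                seed = sample.int(1e6, 1))
        # recover unnormalized scale only up to a constant; test the spread
        stats::sd(log(cm$abundance))
    })
    expect_gt(mean(draws), 1.5) # sdlog = 2, sample sd of 100 logs
    expect_lt(mean(draws), 2.5)
})

test_that("planted repeats appear at the requested copy number", {
    cm <- simulateCommunity(nGenomes = 2, genomeLength = 20000,
                            repeatConfig = list(list(genome = 1, length = 2000,
                                                     copies = 2)),
                            seed = 3)
    g1 <- as.character(cm$genomes[[1]])
    unit <- substring(g1, cm$repeats$target_start[1] + 1,
                      cm$repeats$target_start[1] + 2000)
    hits <- Biostrings::countPattern(unit, cm$genomes[[1]])
    expect_gte(hits, 2L)
})

test_that("chimera construction matches its truth record", {
    cm <- simulateCommunity(nGenomes = 4, genomeLength = 50000, seed = 11)
    asm <- injectMisassemblies(cm, nContigs = 12, contigLength = 7000,
                               chimeraRate = 0.5, seed = 12)
    tr <- asm$truth
    segs <- asm$segments
    expect_equal(tr$misassembled, tr$type != "none")
    expect_true(all(is.na(tr$junction[!tr$misassembled])))
    expect_true(all(tr$junction[tr$misassembled] >= 0.2 * 7000 &
                    tr$junction[tr$misassembled] <= 0.8 * 7000))
    gchar <- as.character(cm$genomes)
    for (i in seq_len(nrow(tr))) {
        cid <- tr$contig_id[i]
        s <- segs[segs$contig_id == cid, ]
        expect_equal(sum(s$gend - s$gstart), tr$length[i])
        expect_equal(nrow(s), if (tr$type[i] == "none") 1L else 2L)
        # reconstruct the contig from its truth segments
        parts <- vapply(seq_len(nrow(s)), function(j) {
            x <- substring(gchar[s$genome[j]], s$gstart[j] + 1, s$gend[j])
            if (s$strand[j] == "-") rcString(x) else x
        }, character(1))
        expect_equal(paste(parts, collapse = ""),
                     as.character(asm$contigs[[cid]]))
        if (tr$type[i] == "relocation")
            expect_gte(max(s$gstart) - min(s$gend[s$gstart == min(s$gstart)]),
                       1000L)
        if (tr$type[i] == "inter_translocation")
            expect_equal(length(unique(s$genome)), 2L)
    }
    # seeded chimera count is recorded exactly
    asm2 <- injectMisassemblies(cm, nContigs = 12, contigLength = 7000,
                                chimeraRate = 0.5, seed = 12)
    expect_identical(asm$truth, asm2$truth)
})

test_that("error-free reads are exact substrings of their source genome", {
    cm <- simulateCommunity(nGenomes = 2, genomeLength = 20000, seed = 21)
    cm$abundance[] <- 0.5
    asm <- injectMisassemblies(cm, nContigs = 4, contigLength = 7000,
                               chimeraRate = 0, seed = 22)
    sam <- tempfile(fileext = ".sam")
    sr <- simulateReads(cm, asm, sam, meanDepth = 5, subErrorRate = 0,
                        seed = 23)
    gch <- as.character(cm$genomes)
    reads <- sr$reads
    set.seed(1)
    for (i in sample(nrow(reads), 50)) {
        r <- reads[i, ]
        seq <- r$seq
        if (r$reverse) seq <- rcString(seq)
        found <- any(vapply(gch, function(g)
            Biostrings::countPattern(seq, Biostrings::DNAString(g)) > 0 ||
            Biostrings::countPattern(rcString(seq),
                                     Biostrings::DNAString(g)) > 0, TRUE))
        expect_true(found)
    }
})

test_that("realized coverage approaches the requested depth", {
    s <- smallSim() # uniform abundances, meanDepth 20
    clean <- s$asm$truth$contig_id[!s$asm$truth$misassembled][1]
    tr <- buildPileup(s$aln, clean, s$asm$contigs[[clean]], s$model)
    inner <- tr@readCoverage[500:6500] # away from edge ramps
    expect_lt(abs(mean(inner) - 20) / 20, 0.1)
})

test_that("junctions produce soft-clipped truth records at depth", {
    s <- smallSim()
    tr <- s$asm$truth
    reads <- s$sr$reads
    for (i in which(tr$misassembled)) {
        j <- tr$junction[i]
        cid <- tr$contig_id[i]
        sub <- reads[reads$contig == cid, ]
        nClip <- sum((sub$clipRight > 0 & sub$end == j) |
                     (sub$clipLeft > 0 & sub$start == j))
        expect_gte(nClip, 1L)
    }
})

test_that("simulation is deterministic per seed", {
    cm <- simulateCommunity(nGenomes = 2, genomeLength = 15000, seed = 31)
    asm <- injectMisassemblies(cm, nContigs = 2, contigLength = 7000,
                               chimeraRate = 0.5, seed = 32)
    s1 <- tempfile(fileext = ".sam"); s2 <- tempfile(fileext = ".sam")
    simulateReads(cm, asm, s1, meanDepth = 5, seed = 33)
    simulateReads(cm, asm, s2, meanDepth = 5, seed = 33)
    expect_identical(readLines(s1), readLines(s2))
})

test_that("degenerate simulator configs are rejected", {
    expect_error(simulateCommunity(nGenomes = 1), "at least 2")
    cm <- simulateCommunity(nGenomes = 2, genomeLength = 15000, seed = 41)
    expect_error(injectMisassemblies(cm, chimeraRate = 1.5), "\\[0, 1\\]")
    expect_error(injectMisassemblies(cm, contigLength = 5000), ">= 7000")
    asm <- injectMisassemblies(cm, nContigs = 2, chimeraRate = 0, seed = 42)
    expect_error(simulateReads(cm, asm, tempfile(), insertMu = 200,
                               readLength = 150),
                 "twice the read length")
})
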