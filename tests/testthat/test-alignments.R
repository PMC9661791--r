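# Alignment ingestion, insert-size model, pair classification, pileup tracks.

test_that("SAM loading keeps primary mapped reads and applies the MAPQ filter", {
    ctg <- randDna(60, seed = 1)
    lines <- c(
        samLine("r1", 0L, "c1", 1L, 60L, "20M", seq = substr(ctg, 1, 20)),
        samLine("r2", 0L, "c1", 5L, 0L, "20M", seq = substr(ctg, 5, 24)),
        samLine("r3", 0L, "c1", 9L, 5L, "20M", seq = substr(ctg, 9, 28)),
        samLine("r4", 0L, "c1", 13L, 20L, "20M", seq = substr(ctg, 13, 32)),
        samLine("r5", 4L, "*", 0L, 0L, "*", seq = strrep("A", 20)))
    sam <- writeSamFile(lines[1], c(c1 = 60L))
    aln <- readContigAlignments(sam, minMapq = 10)
    expect_equal(nrow(alignmentRecords(aln)), 1L)
    expect_equal(alignmentRecords(aln)$start, 0L)
    expect_equal(alignmentRecords(aln)$end, 20L)

    sam2 <- writeSamFile(lines[2:4], c(c1 = 60L))
    aln2 <- readContigAlignments(sam2, minMapq = 10)
    expect_equal(alignmentRecords(aln2)$qname, "r4")
})

test_that("loader errors on missing files, missing index, and header drift", {
    expect_error(readContigAlignments(tempfile(fileext = ".bam")), "not found")
    sam <- writeSamFile(samLine("r1", 0L, "c1", 1L, 60L, "10M",
                                seq = strrep("A", 10)), c(c1 = 50L))
    bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    expect_error(readContigAlignments(bam), "index")
    fasta <- Biostrings::DNAStringSet(c(other = strrep("A", 50)))
    expect_error(readContigAlignments(sam, contigs = fasta), "absent")
    fasta2 <- Biostrings::DNAStringSet(c(c1 = strrep("A", 49)))
    expect_error(readContigAlignments(sam, contigs = fasta2), "mismatch")
})

test_that("insert-size model matches the median/MAD definition", {
    mkPair <- function(id, tlen, pos = 1L) {
        c(samLine(id, 99L, "c1", pos, 60L, "50M", "=", pos + tlen - 50L,
                  tlen, strrep("A", 50)),
          samLine(id, 147L, "c1", pos + tlen - 50L, 60L, "50M", "=", pos,
                  -tlen, strrep("A", 50)))
    }
    sam <- writeSamFile(unlist(lapply(seq_along(c(280, 300, 320, 300, 340)),
        function(i) mkPair(paste0("p", i), c(280, 300, 320, 300, 340)[i]))),
        c(c1 = 1000L))
    m <- fitInsertSizeModel(readContigAlignments(sam))
    expect_equal(insertMu(m), 300)
    expect_equal(insertSigma(m), 20)
    expect_equal(unname(insertBounds(m)), c(240, 360))

    samZero <- writeSamFile(unlist(lapply(1:3, function(i)
        mkPair(paste0("q", i), 300L))), c(c1 = 1000L))
    mz <- fitInsertSizeModel(readContigAlignments(samZero), sigmaFloor = 1)
    expect_equal(insertMu(mz), 300)
    expect_equal(insertSigma(mz), 1) # zero spread floors at sigmaFloor

    samEmpty <- writeSamFile(samLine("u", 0L, "c1", 1L, 60L, "50M",
                                     seq = strrep("A", 50)), c(c1 = 1000L))
    expect_error(fitInsertSizeModel(readContigAlignments(samEmpty)),
                 "no usable")
})

test_that("pair classification follows the precedence and flag rules", {
    model <- new("InsertSizeModel", mu = 300, sigma = 20, lower = 240,
                 upper = 360, nPairs = 10L)
    lines <- c(
        # proper: insert 310, FR, same contig
        samLine("a", 99L, "c1", 11L, 60L, "50M", "=", 271L, 310L, strrep("A", 50)),
        # mate on another contig
        samLine("b", 97L, "c1", 11L, 60L, "50M", "c2", 100L, 0L, strrep("A", 50)),
        # wrong insert: 400 > 360
        samLine("c", 99L, "c1", 11L, 60L, "50M", "=", 361L, 400L, strrep("A", 50)),
        # wrong orientation: both mates forward
        samLine("d", 65L, "c1", 11L, 60L, "50M", "=", 200L, 239L, strrep("A", 50)),
        # clipped: 25 soft-clipped bases at one end
        samLine("e", 99L, "c1", 11L, 60L, "25S25M", "=", 271L, 310L, strrep("A", 50)))
    sam <- writeSamFile(lines, c(c1 = 2000L, c2 = 2000L))
    cl <- classifyPairs(readContigAlignments(sam), model)
    got <- setNames(as.character(cl$pairClass), cl$qname)
    expect_equal(unname(got[c("a", "b", "c", "d")]),
                 c("proper", "mate_other_contig", "wrong_insert",
                   "wrong_orientation"))
    expect_true(cl$clipped[cl$qname == "e"])
    expect_false(any(cl$clipped[cl$qname != "e"]))
})

test_that("classification agrees with a per-record oracle on the simulator", {
    s <- smallSim()
    cl <- classifyPairs(s$aln, s$model)
    oracle <- pairClassOracle(cl, s$model@lower, s$model@upper)
    expect_equal(as.character(cl$pairClass), oracle)
})

test_that("pileup coverage and fragment spans follow the definitions", {
    ctg <- randDna(500, seed = 2)
    model <- new("InsertSizeModel", mu = 300, sigma = 20, lower = 240,
                 upper = 360, nPairs = 10L)
    lines <- c(
        samLine("p", 99L, "c1", 51L, 60L, "100M", "=", 251L, 300L,
                substr(ctg, 51, 150)),
        samLine("p", 147L, "c1", 251L, 60L, "100M", "=", 51L, -300L,
                substr(ctg, 251, 350)))
    sam <- writeSamFile(lines, c(c1 = 500L))
    aln <- readContigAlignments(sam)
    tr <- buildPileup(aln, "c1", Biostrings::DNAString(ctg), model)
    expect_equal(sum(tr@readCoverage), 200L) # conservation of aligned bases
    expect_equal(unique(tr@readCoverage[51:150]), 1L)
    expect_equal(unique(tr@readCoverage[151:250]), 0L)
    # fragment span [50, 350) from the leftmost proper mate
    expect_equal(unique(tr@fragmentCoverage[51:350]), 1L)
    expect_equal(sum(tr@fragmentCoverage), 300L)

    samOne <- writeSamFile(samLine("r", 0L, "c1", 1L, 60L, "100M",
                                   seq = substr(ctg, 1, 100)), c(c1 = 500L))
    trOne <- buildPileup(readContigAlignments(samOne), "c1",
                         Biostrings::DNAString(ctg), model)
    expect_equal(unique(trOne@readCoverage[1:100]), 1L)
    expect_equal(sum(trOne@readCoverage), 100L)

    samNone <- writeSamFile(character(0), c(c1 = 500L))
    trNone <- buildPileup(readContigAlignments(samNone), "c1",
                          Biostrings::DNAString(ctg), model)
    expect_true(all(trNone@readCoverage == 0L))
    expect_true(all(trNone@fragmentCoverage == 0L))
    expect_true(all(trNone@readBreakpointCount == 0L))
})

test_that("pileup conservation and bounds hold on simulated data", {
    s <- smallSim()
    rec <- alignmentRecords(s$aln)
    nPairs <- length(unique(rec$qname))
    for (cid in names(contigLengths(s$aln))[1:3]) {
        tr <- buildPileup(s$aln, cid, s$asm$contigs[[cid]], s$model)
        prim <- rec[rec$contig == cid & !rec$isSupplementary, ]
        expect_equal(sum(tr@readCoverage), sum(prim$end - prim$start))
        expect_true(max(tr@fragmentCoverage) <= nPairs)
        expect_true(all(tr@nCorrect + tr@nDiscordant + tr@nAmbiguous <=
                        tr@readCoverage))
    }
})

test_that("simulator truth SAM is accepted unmodified and counts match", {
    s <- smallSim()
    rec <- alignmentRecords(s$aln)
    expect_equal(sum(!rec$isSupplementary), nrow(s$sr$reads))
    expect_equal(sum(rec$isSupplementary), nrow(s$sr$suppRecords))
})
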