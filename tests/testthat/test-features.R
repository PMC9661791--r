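# Feature families: pair fractions, standardized coverage, nucleotide
# variants (incl. the worked pileup example), KAD, and feature assembly.

mkTrack <- function(readCov, fragCov = readCov, L = length(readCov)) {
    z <- integer(L)
    new("PileupTrack", contig = "c1", length = L,
        readCoverage = as.integer(readCov),
        fragmentCoverage = as.integer(fragCov),
        nCorrect = z, nDiscordant = z, nAmbiguous = z,
        readBreakpointCount = z, readsAtBase = as.integer(readCov))
}

test_that("pair fractions partition the reads and flags are independent", {
    s <- smallSim()
    cl <- classifyPairs(s$aln, s$model)
    pf <- pairFractionFeatures(cl)
    expect_equal(sum(pf[c("proper_frac", "mate_other_frac",
                          "wrong_insert_frac", "wrong_orientation_frac")]), 1)
    expect_true(all(pf >= 0 & pf <= 1))
    # independent recount
    expect_equal(unname(pf["clipped_frac"]),
                 sum(cl$clipLeft >= 20 | cl$clipRight >= 20) / nrow(cl))
    expect_equal(unname(pf["proper_frac"]),
                 sum(as.character(cl$pairClass) == "proper") / nrow(cl))
    expect_error(pairFractionFeatures(cl[0, ]), "no retained reads")
})

test_that("standardized coverage sigma and unusual fraction match the formulas", {
    # two-level toy track: standardized {0.5, 1.5}, sigma 0.5
    toy <- mkTrack(c(rep(1L, 50), rep(3L, 50)))
    cf <- coverageFeatures(toy)
    expect_equal(unname(cf["sigma_read_coverage"]), 0.5)
    expect_equal(unname(cf["sigma_fragment_coverage"]), 0.5)
    expect_equal(unname(cf["unusual_read_coverage_frac"]), 0) # strict bounds

    uni <- mkTrack(rep(7L, 100))
    cfu <- coverageFeatures(uni)
    expect_equal(unname(cfu["sigma_read_coverage"]), 0)
    expect_equal(unname(cfu["unusual_read_coverage_frac"]), 0)

    spread <- mkTrack(c(rep(1L, 90), rep(31L, 10)))
    cfs <- coverageFeatures(spread)
    expect_equal(unname(cfs["unusual_read_coverage_frac"]),
                 mean(c(rep(1, 90), rep(31, 10)) / 4 > 2 |
                      c(rep(1, 90), rep(31, 10)) / 4 < 0.5))

    expect_error(coverageFeatures(mkTrack(rep(0L, 10))), "all-zero")
})

test_that("worked pileup example: six A, three T, one N gives counts 3/6/1", {
    ctg <- randDna(40, seed = 3)
    substr(ctg, 15, 15) <- "A"
    base <- substr(ctg, 11, 20)
    readWith <- function(b) { r <- base; substr(r, 5, 5) <- b; r }
    lines <- vapply(1:10, function(i) {
        b <- if (i <= 6) "A" else if (i <= 9) "T" else "N"
        samLine(paste0("r", i), 0L, "c1", 11L, 60L, "10M", seq = readWith(b))
    }, character(1))
    sam <- writeSamFile(lines, c(c1 = 40L))
    aln <- readContigAlignments(sam)
    model <- new("InsertSizeModel", mu = 300, sigma = 20, lower = 240,
                 upper = 360, nPairs = 1L)
    tr <- buildPileup(aln, "c1", Biostrings::DNAString(ctg), model)
    expect_equal(tr@nDiscordant[15], 3L)
    expect_equal(tr@nCorrect[15], 6L)
    expect_equal(tr@nAmbiguous[15], 1L)
    vp <- variantProportions(tr, scope = c(14, 15))
    expect_equal(unname(vp), c(3, 1, 6) / 10)
    # all-match contigs have zero discordant proportion
    expect_equal(unname(variantProportions(tr)["discordant_base_frac"]),
                 3 / sum(tr@nCorrect + tr@nDiscordant + tr@nAmbiguous))
})

test_that("variant proportions error without mapped bases", {
    tr <- mkTrack(rep(0L, 10))
    expect_error(variantProportions(tr), "no mapped bases")
})

test_that("KAD values follow the definition", {
    expect_equal(kadValue(10, 10, 1), 0)       # c = m, n = 1
    expect_equal(kadValue(30, 10, 1), 1.0)
    expect_equal(kadValue(0, 10, 1), -1.0)     # error k-mer: outside [-0.5, 0.5]
    expect_equal(kadValue(c(10, 30), 10, c(1, 1)), c(0, 1))
    expect_error(kadValue(5, 0, 1), "positive")
})

test_that("depth estimation is the median abundance of single-copy k-mers", {
    prof <- list(k = 5L, n = c(1L, 1L, 1L), c = c(12, 12, 12),
                 valid = rep(TRUE, 3), singleCopyAbundance = c(12, 12, 12))
    expect_equal(estimateDepth(prof), 12)
    prof$singleCopyAbundance <- c(10, 12, 14)
    expect_equal(estimateDepth(prof), 12)
    prof$singleCopyAbundance <- numeric(0)
    expect_error(estimateDepth(prof), "no single-copy")
    prof$singleCopyAbundance <- c(0, 0)
    expect_error(estimateDepth(prof), "no read support")
})

test_that("KAD error bases match the brute-force oracle", {
    k <- 15L
    ctg <- randDna(1500, seed = 4)
    # exactly uniform depth: every contig k-mer seen 5 times in the reads
    uniform <- rep(ctg, 5)
    kb <- kadErrorBases(kmerProfile(ctg, uniform, k = k), nchar(ctg))
    expect_equal(kb$m, 5)
    expect_equal(sum(kb$errorBase), 0L) # no errors anywhere
    expect_true(all(kb$kad == 0))

    # one substituted base in the contig vs the reads
    ctg2 <- ctg
    substr(ctg2, 700, 700) <- setdiff(c("A", "C", "G", "T"),
                                      substr(ctg, 700, 700))[1]
    prof2 <- kmerProfile(ctg2, uniform, k = k)
    kb2 <- kadErrorBases(prof2, nchar(ctg2))
    orc <- kadOracle(ctg2, uniform, k = k)
    expect_equal(kb2$m, orc$m)
    expect_equal(kb2$kad, unname(orc$kad))
    expect_equal(kb2$errorBase, orc$errorBase)
    expect_true(kb2$errorBase[700])
    flagged <- range(which(kb2$errorBase))
    expect_true(flagged[1] >= 700 - k + 1 && flagged[2] <= 700 + k - 1)

    # randomized instance: tiled reads with substitution errors (coverage
    # ramps at the ends are part of the instance; the oracle must agree)
    set.seed(5)
    starts <- seq(1, 1401, by = 20)
    reads3 <- substring(ctg, starts, starts + 99)
    for (i in sample(seq_along(reads3), 20)) {
        p <- sample.int(100, 1)
        substr(reads3[i], p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    prof3 <- kmerProfile(ctg, reads3, k = k)
    kb3 <- kadErrorBases(prof3, nchar(ctg))
    orc3 <- kadOracle(ctg, reads3, k = k)
    expect_equal(kb3$m, orc3$m)
    expect_equal(kb3$kad, unname(orc3$kad))
    expect_equal(kb3$errorBase, orc3$errorBase)
})

test_that("k-mers containing N are skipped", {
    ctg <- randDna(200, seed = 6)
    substr(ctg, 100, 100) <- "N"
    reads <- substring(ctg, seq(1, 151, 10), seq(1, 151, 10) + 49)
    prof <- kmerProfile(ctg, reads, k = 11L)
    covering <- 90:100 # k-mer starts whose window includes position 100
    expect_true(all(!prof$valid[covering]))
    expect_true(all(is.na(kadErrorBases(prof, 200, m = 5)$kad[covering])))
})

test_that("feature assembly tiles windows and shares one manifest", {
    s <- smallSim()
    cf <- extractFeatures(s$aln, s$asm$contigs, s$model, mode = "contig")
    expect_true(all(featureManifest() %in% colnames(cf)))
    expect_true(all(vapply(cf[, featureManifest()], is.numeric, TRUE)))
    fr <- grep("frac$", featureManifest(), value = TRUE)
    expect_true(all(cf[, fr] >= 0 & cf[, fr] <= 1))

    wf <- extractFeatures(s$aln, s$asm$contigs, s$model, mode = "window")
    expect_equal(unique(table(wf$contig_id)), 7000L %/% 100L)
    expect_equal(unique(wf$window_start %% 100), 0)
    u <- wf[wf$usable, ]
    expect_true(all(u[, fr] >= 0 & u[, fr] <= 1))
})
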