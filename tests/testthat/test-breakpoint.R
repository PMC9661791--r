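# Isolation forest, window anomaly scoring, read-breakpoint tracks, and
# breakpoint localization in both modes.

mkWindows <- function(n, outlier = NULL, seed = 1) {
    set.seed(seed)
    X <- as.data.frame(matrix(rnorm(n * length(featureManifest()), 0, 0.01),
                              nrow = n))
    colnames(X) <- featureManifest()
    if (!is.null(outlier)) X[outlier, ] <- X[outlier, ] + 3
    X$contig_id <- "c1"
    X$window_start <- (seq_len(n) - 1L) * 100L
    X$usable <- TRUE
    X
}

test_that("a planted outlier window attains the maximum anomaly score", {
    wf <- mkWindows(500, outlier = 250)
    an <- scoreWindowAnomalies(wf, seed = 4)
    expect_equal(which.max(an$anomaly), 250L)
    expect_gt(max(an$anomaly), 0.5)
    expect_true(all(an$anomaly > 0 & an$anomaly < 1))
})

test_that("identical windows score identically and below saturation", {
    wf <- mkWindows(50)
    wf[, featureManifest()] <- 0.3
    an <- scoreWindowAnomalies(wf, seed = 1)
    expect_equal(length(unique(an$anomaly)), 1L)
    expect_lt(max(an$anomaly), 0.95)
})

test_that("anomaly scoring is deterministic per seed", {
    wf <- mkWindows(200, outlier = 10, seed = 2)
    a1 <- scoreWindowAnomalies(wf, seed = 11)
    a2 <- scoreWindowAnomalies(wf, seed = 11)
    expect_identical(a1$anomaly, a2$anomaly)
    expect_error(scoreWindowAnomalies(wf[1, ]), "at least 2")
})

test_that("read-breakpoint ratio is count over overlapping reads", {
    z <- integer(50)
    cnt <- z; cnt[21] <- 4L
    at <- rep(10L, 50)
    tr <- new("PileupTrack", contig = "c1", length = 50L,
              readCoverage = at, fragmentCoverage = at,
              nCorrect = at, nDiscordant = z, nAmbiguous = z,
              readBreakpointCount = cnt, readsAtBase = at)
    rb <- readBreakpointTrack(tr)
    expect_equal(rb$count[21], 4L)
    expect_equal(rb$ratio[21], 0.4)
    expect_true(all(rb$ratio[-21] == 0))
    expect_true(all(rb$ratio >= 0 & rb$ratio <= 1))
})

test_that("localization picks the max-anomaly window then the max ratio", {
    an <- data.frame(contig_id = "c1",
                     window_start = seq(0L, 1900L, by = 100L),
                     anomaly = 0.2)
    an$anomaly[an$window_start == 800L] <- 0.9
    rb <- data.frame(pos = 0:1999, count = 0L, ratio = 0)
    rb$count[rb$pos %in% c(840, 860)] <- c(3L, 5L)
    rb$ratio[rb$pos %in% c(840, 860)] <- c(0.3, 0.5)
    bp <- localizeBreakpoint("c1", 2000L, an, rb)
    expect_equal(bp$position, 860L)
    expect_equal(bp$provenance, "ratio_max")
    expect_equal(bp$rb_count, 5L)

    # zero breakpoint reads in the window: centre fallback
    rb0 <- data.frame(pos = 0:1999, count = 0L, ratio = 0)
    bp0 <- localizeBreakpoint("c1", 2000L, an, rb0)
    expect_equal(bp0$position, 850L)
    expect_equal(bp0$provenance, "window_center")

    # global max inside the terminal 300 bp is ignored
    an2 <- an
    an2$anomaly[an2$window_start == 0L] <- 0.99
    bp2 <- localizeBreakpoint("c1", 2000L, an2, rb)
    expect_equal(bp2$position, 860L)

    # ties broken leftmost at the window level
    an3 <- an
    an3$anomaly[an3$window_start %in% c(700L, 1200L)] <- 0.95
    bp3 <- localizeBreakpoint("c1", 2000L, an3, rb0)
    expect_equal(bp3$position, 750L)

    expect_error(localizeBreakpoint("c1", 650L,
                                    data.frame(contig_id = "c1",
                                               window_start = c(0L, 100L),
                                               anomaly = c(0.5, 0.6)),
                                    rb0),
                 "no eligible windows")
})

test_that("isolate mode applies the strict 0.95 / >5 / >0.2 thresholds", {
    mkRb <- function(L, at, count, total = 20L) {
        cnt <- integer(L); cnt[at + 1L] <- count
        data.frame(pos = seq_len(L) - 1L, count = cnt,
                   ratio = cnt / total)
    }
    lens <- c(c1 = 2000L)
    an <- data.frame(contig_id = "c1", window_start = 800L, anomaly = 0.96)
    # count 6, ratio 0.3 -> emitted
    out <- callBreakpointsIsolate(an, list(c1 = mkRb(2000L, 850L, 6L)), lens)
    expect_equal(nrow(out), 1L)
    expect_equal(out$position, 850L)
    # count 5 (not > 5) -> not emitted
    out5 <- callBreakpointsIsolate(an, list(c1 = mkRb(2000L, 850L, 5L)), lens)
    expect_equal(nrow(out5), 0L)
    # ratio 0.2 exactly (not > 0.2) -> not emitted
    rbEq <- mkRb(2000L, 850L, 6L, total = 30L)
    expect_equal(nrow(callBreakpointsIsolate(an, list(c1 = rbEq), lens)), 0L)
    # anomaly below 0.95 -> empty result
    anLow <- transform(an, anomaly = 0.95)
    expect_equal(nrow(callBreakpointsIsolate(anLow,
                                             list(c1 = mkRb(2000L, 850L, 6L)),
                                             lens)), 0L)
    # windows in the terminal 300 bp are never considered
    anEnd <- data.frame(contig_id = "c1", window_start = 100L, anomaly = 0.99)
    expect_equal(nrow(callBreakpointsIsolate(anEnd,
                                             list(c1 = mkRb(2000L, 150L, 9L)),
                                             lens)), 0L)
})

test_that("junction windows dominate anomaly ranking on simulated chimeras", {
    s <- smallSim()
    wf <- extractFeatures(s$aln, s$asm$contigs, s$model, mode = "window")
    an <- scoreWindowAnomalies(wf, seed = 3)
    tr <- s$asm$truth
    juncScores <- cleanScores <- numeric(0)
    for (i in seq_len(nrow(tr))) {
        a <- an[an$contig_id == tr$contig_id[i], ]
        if (tr$misassembled[i]) {
            jw <- (tr$junction[i] %/% 100L) * 100L
            juncScores <- c(juncScores,
                            a$anomaly[abs(a$window_start - jw) <= 100])
        } else {
            inner <- a$anomaly[a$window_start >= 300 &
                               a$window_start <= 6600]
            cleanScores <- c(cleanScores, inner)
        }
    }
    expect_gt(median(juncScores), median(cleanScores))
    expect_lt(wilcox.test(juncScores, cleanScores,
                          alternative = "greater")$p.value, 1e-4)
})
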