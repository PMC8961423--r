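test_that("segment filtering applies the quality rules", {
    tab <- makeSegTable(slopes = c(60, -5, -15, 55),
                        durations = c(100, 50, 50, 100),
                        slopeSd = c(2, 2, 2, 12))
    out <- segments(filterSegments(tab))
    expect_identical(out$excluded, c(FALSE, FALSE, TRUE, TRUE))
    expect_identical(out$segIndex[!out$excluded], 1:2)

    allBad <- filterSegments(makeSegTable(30, 100, slopeSd = 50))
    expect_true(isTRUE(attr(allBad, "allExcluded")))
    expect_error(filterSegments(detectIntensitySteps(rep(c(2, 1), each = 10))),
                 "linear-mode")
})

test_that("pause classification reaches the documented fixed point", {
    # (100 s @ 60), (50 s @ 2), (100 s @ 50): initial time-weighted mean
    # 44.4, threshold 14.8 marks the 2 nt/s segment; recomputed mean 55.0
    tab <- classifyPauses(makeSegTable(c(60, 2, 50), c(100, 50, 100)))
    expect_identical(segments(tab)$isPause, c(FALSE, TRUE, FALSE))
    expect_equal(burstRate(tab), 55.0)

    flat <- classifyPauses(makeSegTable(c(50, 50, 50), c(10, 10, 10)))
    expect_false(any(segments(flat)$isPause))

    # monotone slopes 60, 25, 19: stable labeling marks nothing
    # (brute force over the 8 monotone-reachable labelings confirms the
    # empty set is the unique fixed point reachable from no pauses)
    mono <- classifyPauses(makeSegTable(c(60, 25, 19), c(50, 50, 50)))
    stable <- function(lbl, slopes) {
        m <- mean(slopes[!lbl])
        identical(lbl, slopes < m / 3)
    }
    expect_true(stable(segments(mono)$isPause, c(60, 25, 19)))
    expect_false(any(segments(mono)$isPause))
})

test_that("pause classification terminates with a monotone pause set", {
    set.seed(3)
    for (i in 1:20) {
        k <- sample(2:8, 1)
        tab <- makeSegTable(runif(k, -5, 70), runif(k, 20, 200))
        out <- classifyPauses(tab)
        s <- segments(out)
        np <- !s$isPause
        if (any(np)) {
            mw <- sum(s$duration[np] * s$slope[np]) / sum(s$duration[np])
            expect_true(all(s$slope[np] >= mw / 3))
            expect_true(all(s$slope[s$isPause] < mw / 3))
        }
    }
})

test_that("burst rate is the time-weighted non-pause average", {
    expect_equal(burstRate(makeSegTable(57, 100)), 57)
    expect_equal(burstRate(makeSegTable(c(40, 60), c(50, 50))), 50)
    expect_warning(br <- burstRate(classifyPauses(filterSegments(
        makeSegTable(30, 100, slopeSd = 50)))), "undefined")
    expect_true(is.na(br))
})

test_that("burst rate is invariant under subdividing a non-pause segment", {
    whole <- makeSegTable(c(60, 2, 50), c(100, 50, 100))
    split <- makeSegTable(c(60, 60, 2, 50), c(40, 60, 50, 100))
    expect_equal(burstRate(classifyPauses(whole)),
                 burstRate(classifyPauses(split)))
})

test_that("pause counting applies the duration and position rules", {
    mk <- function(dur, pos, resumed = TRUE) {
        slopes <- if (resumed) c(60, 1, 60) else c(60, 1)
        durs <- if (resumed) c(100, dur, 100) else c(100, dur)
        poss <- if (resumed) c(5, pos, 15) else c(5, pos)
        classifyPauses(makeSegTable(slopes, durs, positions = poss))
    }
    ok <- pauseStatistics(list(mk(30, 10)))
    expect_equal(ok$pauseProbability, 1)
    expect_equal(ok$recoveryFraction, 1)
    expect_equal(ok$transientDurations, 30)

    expect_equal(pauseStatistics(list(mk(15, 10)))$pauseProbability, 0)
    expect_equal(pauseStatistics(list(mk(30, 20)))$pauseProbability, 0)

    # a pause reaching the last frame is permanent even when resumed is FALSE
    perm <- pauseStatistics(list(mk(50, 10, resumed = FALSE)))
    expect_equal(perm$pauseProbability, 1)
    expect_equal(perm$recoveryFraction, 0)
    expect_length(perm$transientDurations, 0)

    expect_error(pauseStatistics(list(mk(30, 10)), terminatorPresent = TRUE),
                 "terminator")
})

test_that("ensembles without injected pauses measure ~zero pause probability", {
    p <- kymoPreset("ATP"); p@pauseRate <- 0
    ens <- simulateTranscriptionEnsemble(p, 100, seed = 19)
    ps <- pauseStatistics(burstRateEnsemble(ens$trajectories)$tables)
    expect_lte(ps$pauseProbability, 0.05)
})

test_that("Gaussian rate fits report the ML mean and SD", {
    expect_error(fitRateDistribution(c(1, 2, 3)), "at least 5")
    same <- fitRateDistribution(rep(57, 10))
    expect_equal(same$gaussMean, 57)
    expect_true(same$degenerate)
    set.seed(4)
    x <- rnorm(500, 57, 5.7)
    fit <- fitRateDistribution(x)
    expect_equal(fit$gaussMean, mean(x))
    expect_equal(fit$gaussSd, sd(x) * sqrt(499 / 500))
})

test_that("termination efficiency separates arrests from read-through", {
    arrest <- makeSegTable(c(60, 0.5), c(180, 500),
                           positions = c(8, 13.4))
    arrest@segments$isPause <- c(FALSE, TRUE)
    runoff <- makeSegTable(60, 320, positions = c(12))
    runoff@segments$positionStart <- 2.9
    runoff@segments$positionMid <- 12
    te <- terminationEfficiency(list(arrest, runoff))
    expect_equal(te$nTerminated, 1L)
    expect_equal(te$nEscaped, 1L)
    expect_equal(te$efficiency, 0.5)
})
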