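test_that("noiseless single lines yield one exact segment", {
    tr <- trajectory("m", positions = 2.9 + 0.057 * 5 * (0:49),
                     frameInterval = 5)
    st <- segmentTrajectory(tr)
    expect_identical(nrow(segments(st)), 1L)
    expect_equal(segments(st)$slope, 57)
    expect_equal(segments(st)$slopeSd, 0)
    # too-short traces degrade to a single segment, not an error
    short <- trajectory("s", positions = c(0, 1, 2, 3), frameInterval = 5)
    expect_identical(nrow(segments(segmentTrajectory(short))), 1L)
})

test_that("a noiseless two-phase trace breaks at the velocity change", {
    # 60 nt/s for 100 s then 0 nt/s for 100 s, 5 s frames
    pos <- c(0.06 * 5 * (0:20), rep(6, 20))
    st <- segmentTrajectory(trajectory("m", positions = pos,
                                       frameInterval = 5))
    expect_identical(nrow(segments(st)), 2L)
    expect_lt(abs(breakpoints(st) - 100), 5 + 1e-9)   # within one frame
    expect_equal(segments(st)$slope, c(60, 0), tolerance = 1e-6)
})

test_that("pure noise rarely triggers a split", {
    set.seed(12)
    nSingle <- sum(vapply(1:100, function(i) {
        tr <- trajectory("n", positions = rnorm(200, 5, 0.05),
                         frameInterval = 5)
        nrow(segments(segmentTrajectory(tr, penalty = 1))) == 1
    }, logical(1)))
    expect_gte(nSingle, 95)
})

test_that("segmentation agrees with the exhaustive RSS oracle", {
    dt <- 5
    cases <- list(
        c(rep(0.30, 12), rep(0, 12)),                        # 1 break
        c(rep(0.30, 10), rep(0, 10), rep(0.20, 10)),         # 2 breaks
        c(rep(0.30, 8), rep(0, 8), rep(0.25, 8), rep(-0.05, 8)) # 3 breaks
    )
    for (slopes in cases) {
        pos <- 2.9 + cumsum(c(0, slopes[-length(slopes)]))
        x <- (seq_along(pos) - 1) * dt
        tr <- trajectory("m", positions = pos, times = x)
        st <- segmentTrajectory(tr)
        k <- length(breakpoints(st))
        expect_gt(k, 0)
        oracle <- oracleBestBreaks(x, pos, k)
        idx <- breakIndices(st, x)
        expect_true(all(abs(idx - oracle$breaks) <= 1))
        expect_equal(tableRss(st, x, pos), oracle$rss, tolerance = 1e-9)
    }
})

test_that("accepted splits strictly reduce the residual sum of squares", {
    set.seed(5)
    pos <- c(0.3 * (0:19), rep(0.3 * 19, 20)) + rnorm(40, 0, 0.05)
    x <- (0:39) * 5
    tr <- trajectory("m", positions = pos, times = x)
    st <- segmentTrajectory(tr)
    if (length(breakpoints(st))) {
        split <- tableRss(st, x, pos)
        unsplit <- oracleSegRss(x, pos, 1, length(pos))
        expect_lt(split, unsplit)
    }
    expect_identical(st@mode, "linear")
})

test_that("segmentation is offset-invariant and time-shift equivariant", {
    set.seed(8)
    pos <- c(0.3 * (0:19), rep(5.7, 20)) + rnorm(40, 0, 0.03)
    x <- (0:39) * 5
    st0 <- segmentTrajectory(trajectory("m", positions = pos, times = x))
    stOff <- segmentTrajectory(trajectory("m", positions = pos + 3,
                                          times = x))
    expect_equal(breakpoints(stOff), breakpoints(st0))
    expect_equal(segments(stOff)$slope, segments(st0)$slope)
    stShift <- segmentTrajectory(trajectory("m", positions = pos,
                                            times = x + 100))
    expect_equal(breakpoints(stShift), breakpoints(st0) + 100)
})

test_that("two-segment breakpoints are found within two frames of truth", {
    set.seed(14)
    errs <- vapply(1:100, function(i) {
        pos <- c(0.3 * (0:39), rep(0.3 * 39, 40)) + rnorm(80, 0, 0.1)
        st <- segmentTrajectory(trajectory("m", positions = pos,
                                           frameInterval = 5))
        bp <- breakpoints(st)
        if (!length(bp)) return(Inf)
        min(abs(bp - 39 * 5)) / 5
    }, numeric(1))
    expect_lte(median(errs), 2)
})

test_that("intensity staircases resolve into their constant levels", {
    st <- detectIntensitySteps(rep(c(300, 200, 100, 0), each = 25))
    expect_identical(nrow(segments(st)), 4L)
    expect_equal(segments(st)$meanLevel, c(300, 200, 100, 0))
    expect_identical(countBleachSteps(st), 3L)

    flat <- detectIntensitySteps(rep(500, 50))
    expect_identical(nrow(segments(flat)), 1L)
    expect_identical(countBleachSteps(flat), 0L)
    expect_error(detectIntensitySteps(c(1, 2, 3)), "at least 4")
    expect_error(countBleachSteps(segmentTrajectory(
        trajectory("m", positions = 1:10))), "step-mode")
})

test_that("two-step traces are recovered at moderate noise", {
    set.seed(16)
    n3 <- sum(vapply(1:100, function(i) {
        y <- rep(c(2000, 1000, 0), each = 40) + rnorm(120, 0, 200)
        nrow(segments(detectIntensitySteps(y))) == 3
    }, logical(1)))
    expect_gte(n3, 90)
})

test_that("single-fluorophore traces bleach in one step", {
    set.seed(17)
    counts <- vapply(1:60, function(i) {
        sim <- simulateBleachTrace(1, 1000, bleachHalfLife = 60,
                                   noiseSd = 100, nFrames = 200)
        countBleachSteps(detectIntensitySteps(sim$intensity))
    }, integer(1))
    tab <- table(counts)
    expect_identical(names(tab)[which.max(tab)], "1")
})
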