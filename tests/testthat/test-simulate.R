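test_that("fixed-velocity noiseless traces advance exactly v * dt per frame", {
    p <- noiselessPreset()   # 57 nt/s, 5 s frames
    sim <- simulateTranscriptionTrace(p, seed = 1)
    d <- diff(positions(sim$trajectory))
    expect_equal(d, rep(0.285, length(d)), tolerance = 1e-6)
    expect_equal(sim$truth$trueVelocity, 57, tolerance = 1e-6)
})

test_that("forced termination arrests every trace at the terminator", {
    p <- noiselessPreset("terminator")
    p@terminationProb <- 1
    p@layout <- dnaLayout(terminatorPresent = TRUE)
    for (s in 1:5) {
        sim <- simulateTranscriptionTrace(p, seed = s)
        expect_equal(tail(positions(sim$trajectory), 1), 13.4,
                     tolerance = 1e-9)
        expect_true(sim$truth$terminated)
    }
})

test_that("ATP-preset velocities are drawn around the condition mean", {
    ens <- simulateTranscriptionEnsemble(kymoPreset("ATP"), 150, seed = 11)
    v <- vapply(ens$truths, function(t) t$trueVelocity, numeric(1))
    expect_lt(abs(mean(v) - 57.0), 2 * sd(v) / sqrt(length(v)))
})

test_that("truth pause intervals are non-overlapping and inside the trace", {
    p <- kymoPreset("ATP"); p@pauseRate <- 0.2
    for (s in 1:20) {
        sim <- simulateTranscriptionTrace(p, seed = s)
        pi <- sim$truth$pauseIntervals
        if (nrow(pi) < 1) next
        expect_true(all(pi$end > pi$start))
        expect_true(all(pi$end <= max(trajTimes(sim$trajectory)) + 1e-9))
        if (nrow(pi) > 1)
            expect_true(all(pi$start[-1] >= pi$end[-nrow(pi)] - 1e-9))
    }
})

test_that("degenerate outcome distributions are realized kinematically", {
    sim <- simulateCollisionEvent(outcomePreset("push"), seed = 3)
    expect_identical(sim$truth$trueOutcome, "push")
    rb <- positions(sim$roadblock)
    expect_gt(max(rb) - rb[1], 2)

    byp <- simulateCollisionEvent(outcomePreset("bypass"), seed = 3)
    expect_lt(max(positions(byp$roadblock)) - positions(byp$roadblock)[1], 2)
    expect_gt(max(positions(byp$pusher)) - 5.5, 4)
})

test_that("collision geometry precondition excludes close starts", {
    expect_error(simulateCollisionEvent(kymoPreset("ORC_collision"),
        roadblockPos = 2.5, seed = 1), "1 kb")
})

test_that("empirical outcome frequencies converge to the preset distribution", {
    p <- kymoPreset("ORC_collision")
    sims <- kymolyze:::withSeed(42, lapply(seq_len(4000), function(i)
        simulateCollisionEvent(p, seed = NA)))
    out <- vapply(sims, function(s) s$truth$trueOutcome, character(1))
    obs <- table(factor(out, levels = names(p@outcomeProbs)))
    gof <- suppressWarnings(
        stats::chisq.test(obs, p = p@outcomeProbs))
    expect_gt(gof$p.value, 0.001)
})

test_that("diffusion traces have the Brownian step variance", {
    expect_error(simulateDiffusionTrace(-1, 10), ">= 0")
    still <- simulateDiffusionTrace(0, 50, 0.5, seed = 1)
    expect_equal(var(positions(still$trajectory)), 0)
    one <- simulateDiffusionTrace(5, 1, 0.5, seed = 1)
    expect_length(positions(one$trajectory), 1)

    w <- simulateDiffusionTrace(19.4, 20000, 0.5, seed = 2)
    s2 <- var(diff(positions(w$trajectory)))
    expect_equal(s2, 2 * 19.4 * 0.5, tolerance = 0.05)

    # reflecting boundaries keep the walk on the substrate
    wr <- simulateDiffusionTrace(19.4, 2000, 0.5, seed = 3,
                                 layout = dnaLayout())
    expect_true(all(positions(wr$trajectory) >= 0 &
                    positions(wr$trajectory) <= 21))
})

test_that("noiseless bleaching traces step down to zero", {
    sim <- simulateBleachTrace(3, 1000, bleachHalfLife = 40, nFrames = 400,
                               seed = 7)
    expect_identical(sim$truth$trueStepCount, 3L)
    expect_length(sim$truth$bleachTimes, 3)
    expect_equal(tail(sim$counts, 1), 0)
    drops <- diff(sim$intensity)
    expect_true(all(drops <= 0))
    expect_equal(sum(drops < 0) >= 1, TRUE)

    tiny <- simulateBleachTrace(1, nFrames = 1, seed = 1)
    expect_length(tiny$intensity, 1)
})

test_that("dye survival follows the half-life law", {
    # per-unit survival to frame halfLife is 0.5 by construction
    counts <- simulateDyeSurvival(20000, 290, nFrames = 291, seed = 9)
    expect_equal(counts[291] / counts[1], 0.5, tolerance = 0.02)
})

test_that("generators are bit-reproducible under a fixed seed", {
    a <- simulateTranscriptionTrace(kymoPreset("ATP"), seed = 5)
    b <- simulateTranscriptionTrace(kymoPreset("ATP"), seed = 5)
    expect_identical(positions(a$trajectory), positions(b$trajectory))
    expect_identical(a$truth, b$truth)
    ca <- simulateCollisionEvent(kymoPreset("MCMDH_collision"), seed = 5)
    cb <- simulateCollisionEvent(kymoPreset("MCMDH_collision"), seed = 5)
    expect_identical(positions(ca$roadblock), positions(cb$roadblock))
    expect_identical(simulateDyeSurvival(100, 150, 200, seed = 3),
                     simulateDyeSurvival(100, 150, 200, seed = 3))
})

test_that("rendered kymographs place mass at the molecule position", {
    tr <- trajectory("m", positions = rep(5.5, 10), frameInterval = 5,
                     intensities = rep(100, 10))
    img <- renderKymograph(list(tr), psfSigma = 1, pixelScale = 0.175)
    expect_s4_class(img, "KymographImage")
    for (f in c(1, 5, 10))
        expect_equal(which.max(intensityMatrix(img)[, f]) - 1,
                     round(5.5 / 0.175))
    # two molecules 10 px apart give two resolvable ridges
    tr2 <- trajectory("m2", positions = rep(5.5 + 10 * 0.175, 10),
                      frameInterval = 5, intensities = rep(100, 10))
    img2 <- renderKymograph(list(tr, tr2), psfSigma = 1, pixelScale = 0.175)
    v <- intensityMatrix(img2)[, 1]
    locmax <- which(diff(sign(diff(v))) == -2) + 1
    expect_gte(length(locmax), 2)
    expect_warning(renderKymograph(list(trajectory("m3",
        positions = c(-2, 30))), pixelScale = 0.175), "clipped")
})

test_that("render-track round trip recovers positions and velocity", {
    p <- noiselessPreset()
    sim <- simulateTranscriptionTrace(p, seed = 2)
    img <- renderKymograph(list(sim$trajectory), psfSigma = 1.2,
                           background = 5, pixelScale = 0.175)
    trk <- trackKymograph(img)
    expect_length(trk, 1)
    tr <- trk[[1]]
    common <- intersect(tr@frames, sim$trajectory@frames)
    err <- positions(tr)[match(common, tr@frames)] -
        positions(sim$trajectory)[match(common, sim$trajectory@frames)]
    expect_lt(sqrt(mean(err^2)) / 0.175, 0.2)   # < 0.2 px RMS
    st <- segmentTrajectory(tr)
    expect_equal(segments(st)$slope[1], sim$truth$trueVelocity,
                 tolerance = 1 / 57)            # < 1 nt/s
})
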