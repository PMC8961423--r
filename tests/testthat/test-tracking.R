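gaussFrame <- function(center, amp = 100, sigma = 1.2, n = 120, bg = 0) {
    px <- seq_len(n) - 1
    amp * exp(-(px - center)^2 / (2 * sigma^2)) + bg
}

test_that("field flattening divides out the beam profile", {
    img <- kymographImage(matrix(runif(120 * 10, 50, 60), nrow = 120))
    flat <- flattenField(img, rep(3, 120))
    expect_equal(intensityMatrix(flat), intensityMatrix(img))

    # dividing a separable image by its own position-marginal flattens it
    profile <- seq(0.5, 2, length.out = 120)
    sep <- kymographImage(outer(profile, rep(7, 10)))
    out <- flattenField(sep, profile)
    expect_equal(max(out@data) - min(out@data), 0, tolerance = 1e-9)

    expect_error(flattenField(img, c(0, rep(1, 119))), "strictly positive")
    expect_error(flattenField(img, rep(1, 5)), "position extent")
})

test_that("drift correction removes a common stage drift", {
    tr <- trajectory("m", positions = 5 + 0.02 * (0:99), frameInterval = 5)
    fidConst <- trajectory("f", positions = rep(2, 100), frameInterval = 5)
    same <- correctDrift(list(tr), list(fidConst))
    expect_equal(positions(same[[1]]), positions(tr))

    drift <- 0.01 * (0:99) - mean(0.01 * (0:99))   # mean-referenced drift
    trD <- trajectory("m", positions = positions(tr) + drift,
                      frameInterval = 5)
    fidD <- trajectory("f", positions = 2 + drift, frameInterval = 5)
    fixed <- correctDrift(list(trD), list(fidD))
    expect_equal(positions(fixed[[1]]), positions(tr), tolerance = 1e-9)

    # single-frame fiducial gap is interpolated, not an error
    fidGap <- trajectory("f", positions = (2 + drift)[-50],
                         times = ((0:99) * 5)[-50], frames = (1:100)[-50])
    fixed2 <- correctDrift(list(trD), list(fidGap))
    # the missing frame shifts the fiducial's own time-mean slightly, so
    # recovery is exact only up to a sub-nm constant offset
    expect_equal(positions(fixed2[[1]]), positions(tr), tolerance = 1e-4)

    expect_error(correctDrift(list(tr), list()), "fiducial")
})

test_that("peak finding localizes subpixel and is translation-equivariant", {
    blank <- kymographImage(matrix(1, nrow = 120, ncol = 3))
    expect_identical(nrow(findPeaks(blank, 1)), 0L)

    img <- kymographImage(matrix(gaussFrame(50.3), ncol = 1))
    pk <- findPeaks(img, 1)
    expect_identical(nrow(pk), 1L)
    expect_lt(abs(pk$position - 50.3), 0.05)

    two <- kymographImage(matrix(gaussFrame(40, sigma = 1) +
                                 gaussFrame(43, sigma = 1), ncol = 1))
    expect_identical(nrow(findPeaks(two, 1)), 2L)

    # shifting the frame by k px shifts the detected position by exactly k
    for (k in c(3, 11)) {
        shifted <- kymographImage(matrix(gaussFrame(50.3 + k), ncol = 1))
        expect_equal(findPeaks(shifted, 1)$position, pk$position + k,
                     tolerance = 1e-3)
    }
})

test_that("annulus intensity integration matches its closed forms", {
    uni <- kymographImage(matrix(42, nrow = 60, ncol = 2))
    ii <- integrateIntensity(uni, 1, 30)
    expect_equal(ii$intensity, 0)
    expect_equal(ii$background, 42)

    delta <- matrix(0, nrow = 60, ncol = 1); delta[31, 1] <- 500
    expect_equal(integrateIntensity(kymographImage(delta), 1, 30)$intensity,
                 500)

    # Gaussian of area A on background B recovers ~ A times the inner mass
    A <- 1000; B <- 20; sigma <- 1
    w <- gaussFrame(30, amp = 1, sigma = sigma)
    v <- A * w / sum(w) + B
    got <- integrateIntensity(kymographImage(matrix(v, ncol = 1)), 1, 30)
    innerMass <- sum((A * w / sum(w))[abs(seq_len(120) - 1 - 30) <= 2])
    expect_equal(got$intensity, innerMass, tolerance = 0.05 * A)

    # linearity in image intensity
    img <- kymographImage(matrix(v, ncol = 1))
    img3 <- kymographImage(matrix(3 * v, ncol = 1))
    expect_equal(integrateIntensity(img3, 1, 30)$intensity,
                 3 * integrateIntensity(img, 1, 30)$intensity)

    expect_true(integrateIntensity(uni, 1, 1)$clipped)
})

test_that("greedy linking reconstructs sparse trajectories", {
    # two stationary molecules 10 px apart over 100 frames
    pk <- do.call(rbind, lapply(1:100, function(f)
        data.frame(frame = f, position = c(40, 50), intensity = 1)))
    trks <- linkPeaks(pk, pixelScale = 0.175, frameInterval = 5)
    expect_length(trks, 2)
    expect_true(all(vapply(trks, function(t) length(t@frames), 1L) == 100))

    # one molecule moving 0.3 kb/frame within maxJump 0.5 kb
    mv <- data.frame(frame = 1:50, position = (0.3 * (0:49)) / 0.175,
                     intensity = 1)
    expect_length(linkPeaks(mv, pixelScale = 0.175, maxJump = 0.5), 1)

    # crossing trajectories: nearest-neighbor keeps two tracks
    cr <- do.call(rbind, lapply(1:40, function(f)
        data.frame(frame = f, position = c(20 + 0.5 * f, 50 - 0.5 * f),
                   intensity = 1)))
    got <- linkPeaks(cr, pixelScale = 0.175, maxJump = 0.5)
    expect_length(got, 2)
})

test_that("localization error decreases monotonically with SNR", {
    set.seed(21)
    rmse <- vapply(c(5, 10, 20), function(snr) {
        errs <- vapply(1:60, function(i) {
            v <- gaussFrame(55.4, amp = 100) + rnorm(120, 0, 100 / snr)
            pk <- findPeaks(kymographImage(matrix(v, ncol = 1)), 1,
                            snrThreshold = 3)
            pk <- pk[abs(pk$position - 55.4) < 4, ]
            if (!nrow(pk)) return(NA_real_)
            pk$position[which.max(pk$intensity)] - 55.4
        }, numeric(1))
        sqrt(mean(errs^2, na.rm = TRUE))
    }, numeric(1))
    expect_true(all(diff(rmse) < 0))
})

test_that("dye half-life fitting recovers the survival constant", {
    x <- 0:499
    exact <- fitHalfLife(100 * 0.5^(x / 290))
    expect_equal(exact$b, 290, tolerance = 1e-6)
    expect_equal(exact$a, 100, tolerance = 1e-6)
    expect_false(exact$nonBleaching)

    flat <- fitHalfLife(rep(50, 200))
    expect_true(flat$nonBleaching)

    expect_error(fitHalfLife(rep(0, 100)), "all counts")
    expect_error(fitHalfLife(c(3, 2, 1)), "at least 5")

    # median recovery within 10% over simulation replicates
    set.seed(31)
    relErr <- vapply(1:100, function(i) {
        b <- fitHalfLife(simulateDyeSurvival(1000, 150, 600))$b
        abs(b - 150) / 150
    }, numeric(1))
    expect_lt(median(relErr), 0.10)
})

test_that("colocalization intervals match the geometric crossing", {
    a <- trajectory("a", positions = rep(5, 50), frameInterval = 5)
    b <- trajectory("b", positions = rep(5, 50), frameInterval = 5)
    full <- colocalize(a, b, tolerance = 0.5)
    expect_identical(nrow(full), 1L)
    expect_equal(c(full$tStart, full$tEnd), c(0, 49 * 5))

    far <- trajectory("c", positions = rep(10, 50), frameInterval = 5)
    expect_identical(nrow(colocalize(a, far, 0.5)), 0L)

    # converging lines: interval starts at the first frame with gap <= tol
    mv <- trajectory("d", positions = 10 - 0.1 * (0:49), frameInterval = 5)
    got <- colocalize(a, mv, tolerance = 0.5)
    firstFrame <- which(abs(10 - 0.1 * (0:49) - 5) <= 0.5)[1]
    expect_equal(got$tStart[1], (firstFrame - 1) * 5)

    disjoint <- trajectory("e", positions = rep(5, 10), frames = 100:109,
                           times = (99:108) * 5)
    expect_identical(nrow(colocalize(a, disjoint, 0.5)), 0L)
})
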