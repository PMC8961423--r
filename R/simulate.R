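#' Simulate a transcription trajectory
#'
#' Generates one RNA-polymerase position-vs-time trace with the statistical
#' structure of a flow-stretched-DNA transcription experiment: the molecule
#' starts at the promoter and advances at a per-molecule burst velocity drawn
#' from Normal(burstVelocityMean, burstVelocitySd) truncated to positive
#' values; pauses are inserted as a Poisson process in distance with rate
#' `pauseRate` per kb; each pause is permanent with probability
#' `1 - pauseRecoveryProb`, otherwise its duration is
#' `pauseDurationOffset + Exponential(pauseDurationMeanExcess)`. On a
#' terminator-bearing layout the trace arrests permanently at the terminator
#' with probability `terminationProb`. Independent Gaussian localization
#' noise is added per frame.
#'
#' @param preset a [SimulationPreset-class]
#' @param seed integer seed (NA to use the current RNG stream)
#' @param maxTime observation window (s)
#' @param moleculeId identifier for the trajectory
#' @return list with elements `trajectory` ([Trajectory-class]) and `truth`
#'   (ground-truth record: trueVelocity, pauseIntervals, terminated, ...)
#' @examples
#' sim <- simulateTranscriptionTrace(kymoPreset("ATP"), seed = 1)
#' sim$truth$trueVelocity
#' @export
simulateTranscriptionTrace <- function(preset, seed = NA, maxTime = 900,
                                       moleculeId = "mol1") {
    validObject(preset)
    if (preset@frameInterval <= 0)
        stop("invalid preset: frameInterval must be positive")
    withSeed(seed, {
        lay <- preset@layout
        dt <- preset@frameInterval
        vnt <- -1
        while (vnt <= 0)
            vnt <- rnorm(1, preset@burstVelocityMean, preset@burstVelocitySd)
        vkb <- vnt / 1000
        terminated <- lay@terminatorPresent &&
            runif(1) < preset@terminationProb
        stopX <- if (terminated) lay@terminatorPos else lay@length

        span <- lay@length - lay@promoterPos
        nP <- if (preset@pauseRate > 0) rpois(1, preset@pauseRate * span) else 0L
        pausePos <- sort(runif(nP, lay@promoterPos, lay@length))

        nodeT <- 0; nodeX <- lay@promoterPos
        curT <- 0; curX <- lay@promoterPos
        pauses <- emptyPauseIntervals()
        arrested <- FALSE
        for (p in pausePos) {
            if (p >= stopX) break
            tReach <- curT + (p - curX) / vkb
            if (runif(1) >= preset@pauseRecoveryProb) {   # permanent
                pauses <- rbind(pauses, data.frame(start = tReach, end = Inf,
                    type = "permanent", position = p))
                nodeT <- c(nodeT, tReach); nodeX <- c(nodeX, p)
                arrested <- TRUE
                terminated <- FALSE
                break
            }
            dur <- preset@pauseDurationOffset +
                rexp(1, 1 / preset@pauseDurationMeanExcess)
            pauses <- rbind(pauses, data.frame(start = tReach,
                end = tReach + dur, type = "transient", position = p))
            nodeT <- c(nodeT, tReach, tReach + dur)
            nodeX <- c(nodeX, p, p)
            curT <- tReach + dur; curX <- p
        }
        if (!arrested) {
            tStop <- curT + (stopX - curX) / vkb
            nodeT <- c(nodeT, tStop); nodeX <- c(nodeX, stopX)
            if (terminated) arrested <- TRUE else runoffT <- tStop
        }

        tEnd <- if (arrested) maxTime else min(runoffT, maxTime)
        times <- seq(0, max(tEnd, dt), by = dt)
        pos <- evalPiecewise(nodeT, nodeX, times)
        if (preset@localizationNoiseSd > 0)
            pos <- pos + rnorm(length(times), 0, preset@localizationNoiseSd)
        pos <- pmin(pmax(pos, 0), lay@length)
        ints <- preset@unitIntensity +
            rnorm(length(times), 0, preset@intensityNoiseSd)

        pauses <- pauses[pauses$start < tEnd, , drop = FALSE]
        pauses$end <- pmin(pauses$end, tEnd)

        traj <- trajectory(moleculeId, positions = pos, times = times,
            intensities = pmax(ints, 0), channel = "pusher",
            condition = preset@name)
        truth <- newTruthRecord(moleculeId, trueVelocity = vnt,
            pauseIntervals = pauses, terminated = terminated)
        list(trajectory = traj, truth = truth)
    })
}

#' Simulate an ensemble of transcription trajectories
#'
#' @param preset a [SimulationPreset-class]
#' @param n number of molecules
#' @param seed integer seed
#' @param maxTime observation window (s)
#' @return list with `trajectories` (list of [Trajectory-class]) and
#'   `truths` (list of ground-truth records)
#' @export
simulateTranscriptionEnsemble <- function(preset, n, seed = NA,
                                          maxTime = 900) {
    withSeed(seed, {
        sims <- lapply(seq_len(n), function(i)
            simulateTranscriptionTrace(preset, seed = NA, maxTime = maxTime,
                moleculeId = sprintf("mol%04d", i)))
        list(trajectories = lapply(sims, `[[`, "trajectory"),
             truths = lapply(sims, `[[`, "truth"))
    })
}

#' Simulate one pusher-roadblock collision event
#'
#' Samples a collision outcome from the preset's outcome probabilities and
#' realizes it kinematically: a transcribing pusher starts at the promoter
#' and encounters a roadblock bound at `roadblockPos`. Outcomes follow the
#' displacement taxonomy: push (roadblock carried to the DNA end), bypass
#' (pusher continues, roadblock displacement stays < 2 kb), pause (transient
#' pusher arrest at the roadblock, then pushing), stall (permanent arrest of
#' both), and roadblock/pusher ejection (the named molecule's intensity
#' drops to background permanently at the encounter).
#'
#' @param preset a [SimulationPreset-class]
#' @param roadblockPos roadblock position (kb); must exceed the promoter by
#'   more than 1 kb
#' @param seed integer seed
#' @param maxTime observation window (s)
#' @param roadblockCopies roadblock copy number (scales its intensity)
#' @param moleculeId identifier stem
#' @return list with `pusher`, `roadblock` ([Trajectory-class]) and `truth`
#'   (including `trueOutcome`)
#' @examples
#' ev <- simulateCollisionEvent(kymoPreset("ORC_collision"), seed = 1)
#' ev$truth$trueOutcome
#' @export
simulateCollisionEvent <- function(preset, roadblockPos = NULL, seed = NA,
                                   maxTime = 900, roadblockCopies = 1,
                                   moleculeId = "ev1") {
    validObject(preset)
    if (abs(sum(preset@outcomeProbs) - 1) > 1e-9)
        stop("invalid preset: outcomeProbs must sum to 1")
    lay <- preset@layout
    if (is.null(roadblockPos)) roadblockPos <- lay@ars1Pos
    if (roadblockPos <= lay@promoterPos + 1)
        stop("roadblockPos must exceed the promoter position by more than 1 kb")
    withSeed(seed, {
        dt <- preset@frameInterval
        L <- lay@length
        vnt <- -1
        while (vnt <= 0)
            vnt <- rnorm(1, preset@burstVelocityMean, preset@burstVelocitySd)
        vkb <- vnt / 1000
        outcome <- sample(OUTCOME_LEVELS, 1, prob = preset@outcomeProbs)
        tc <- (roadblockPos - lay@promoterPos) / vkb
        rb <- roadblockPos

        pusherNodes <- list(t = c(0, tc), x = c(lay@promoterPos, rb))
        rbNodes <- list(t = 0, x = rb)
        pusherEnd <- maxTime; rbEnd <- maxTime
        pusherEjectT <- NA_real_; rbEjectT <- NA_real_

        pushOn <- function(t0) {   # co-movement from (t0, rb) to the DNA end
            tRun <- t0 + (L - rb) / vkb
            list(t = c(t0, tRun), x = c(rb, L), tRun = tRun)
        }
        if (outcome == "push") {
            seg <- pushOn(tc)
            pusherNodes$t <- c(pusherNodes$t, seg$t[2])
            pusherNodes$x <- c(pusherNodes$x, L)
            rbNodes <- list(t = c(0, tc, seg$t[2]), x = c(rb, rb, L))
            pusherEnd <- min(seg$tRun, maxTime)
        } else if (outcome == "bypass") {
            nudge <- 0.3
            rbNodes <- list(t = c(0, tc, tc + 2 * dt),
                            x = c(rb, rb, rb + nudge))
            tRun <- tc + (L - rb) / vkb
            pusherNodes$t <- c(pusherNodes$t, tRun)
            pusherNodes$x <- c(pusherNodes$x, L)
            pusherEnd <- min(tRun, maxTime)
        } else if (outcome == "pause") {
            dp <- preset@pauseDurationOffset +
                rexp(1, 1 / preset@pauseDurationMeanExcess)
            dpMax <- maxTime - tc - (L - rb) / vkb - 10 * dt
            dp <- max(min(dp, dpMax), preset@pauseDurationOffset + 5)
            seg <- pushOn(tc + dp)
            pusherNodes$t <- c(pusherNodes$t, tc + dp, seg$t[2])
            pusherNodes$x <- c(pusherNodes$x, rb, L)
            rbNodes <- list(t = c(0, tc + dp, seg$t[2]), x = c(rb, rb, L))
            pusherEnd <- min(seg$tRun, maxTime)
        } else if (outcome == "stall") {
            pusherNodes$t <- c(pusherNodes$t, maxTime)
            pusherNodes$x <- c(pusherNodes$x, rb)
        } else if (outcome == "roadblock_eject") {
            rbEjectT <- tc
            tRun <- tc + (L - rb) / vkb
            pusherNodes$t <- c(pusherNodes$t, tRun)
            pusherNodes$x <- c(pusherNodes$x, L)
            pusherEnd <- min(tRun, maxTime)
        } else if (outcome == "pusher_eject") {
            pusherEjectT <- tc
            pusherNodes$t <- c(pusherNodes$t, maxTime)
            pusherNodes$x <- c(pusherNodes$x, rb)
        }

        mkTraj <- function(nodes, tEnd, ejectT, channel, baseInt) {
            times <- seq(0, max(tEnd, dt), by = dt)
            pos <- if (length(nodes$t) > 1)
                evalPiecewise(nodes$t, nodes$x, times)
            else rep(nodes$x, length(times))
            if (preset@localizationNoiseSd > 0)
                pos <- pos + rnorm(length(times), 0,
                                   preset@localizationNoiseSd)
            pos <- pmin(pmax(pos, 0), L)
            mu <- rep(baseInt, length(times))
            if (!is.na(ejectT)) mu[times >= ejectT] <- 0
            ints <- pmax(mu + rnorm(length(times), 0,
                                    preset@intensityNoiseSd), 0)
            trajectory(paste0(moleculeId, "_", channel), positions = pos,
                times = times, intensities = ints, channel = channel,
                condition = preset@name)
        }
        pusher <- mkTraj(pusherNodes, pusherEnd, pusherEjectT, "pusher",
                         preset@unitIntensity)
        roadblock <- mkTraj(rbNodes, rbEnd, rbEjectT, "roadblock",
                            preset@unitIntensity * roadblockCopies)
        truth <- newTruthRecord(moleculeId, trueVelocity = vnt,
            trueOutcome = outcome,
            trueCopyNumber = as.integer(roadblockCopies))
        list(pusher = pusher, roadblock = roadblock, truth = truth)
    })
}

#' Simulate a diffusive random-walk trajectory
#'
#' 1-D Gaussian random walk with per-step displacement variance
#' `2 * D * frameInterval`, plus independent localization noise. When a
#' [DnaLayout-class] is supplied the walk is reflected at 0 and at the DNA
#' length; by default the walk is unbounded.
#'
#' @param D diffusion coefficient (kbp^2/s), >= 0
#' @param nFrames number of frames (>= 1)
#' @param frameInterval frame interval (s)
#' @param noiseSd localization noise SD (kb)
#' @param seed integer seed
#' @param layout optional [DnaLayout-class] providing reflecting boundaries
#' @param start start position (kb); defaults to the ARS1 position when a
#'   layout is given, else 0
#' @param moleculeId identifier
#' @return list with `trajectory` and `truth` (`trueDiffusion = D`)
#' @examples
#' sim <- simulateDiffusionTrace(19.4, nFrames = 200, frameInterval = 0.5,
#'                               seed = 1)
#' @export
simulateDiffusionTrace <- function(D, nFrames, frameInterval = 0.5,
                                   noiseSd = 0, seed = NA, layout = NULL,
                                   start = NULL, moleculeId = "mol1") {
    if (D < 0) stop("D must be >= 0")
    if (nFrames < 1) stop("nFrames must be >= 1")
    withSeed(seed, {
        if (is.null(start))
            start <- if (is.null(layout)) 0 else layout@ars1Pos
        steps <- if (nFrames > 1)
            rnorm(nFrames - 1, 0, sqrt(2 * D * frameInterval)) else numeric()
        x <- start + c(0, cumsum(steps))
        if (!is.null(layout)) {
            L <- layout@length
            x <- x %% (2 * L)
            x <- ifelse(x > L, 2 * L - x, x)
        }
        if (noiseSd > 0) x <- x + rnorm(nFrames, 0, noiseSd)
        traj <- trajectory(moleculeId, positions = x,
            frameInterval = frameInterval, channel = "diffusing")
        list(trajectory = traj,
             truth = newTruthRecord(moleculeId, trueDiffusion = D))
    })
}

#' Simulate a stepwise photobleaching intensity trace
#'
#' Each of `nUnits` fluorophores bleaches independently at a geometric time
#' with per-frame survival probability `0.5^(1 / bleachHalfLife)`; the trace
#' is the number of surviving units times `unitIntensity` plus Gaussian
#' noise.
#'
#' @param nUnits number of fluorophore units (>= 1)
#' @param unitIntensity intensity per unit (a.u.)
#' @param bleachHalfLife dye half-life (frames)
#' @param noiseSd intensity noise SD (a.u.)
#' @param nFrames trace length (frames)
#' @param seed integer seed
#' @return list with `intensity` (numeric trace), `counts` (surviving units
#'   per frame) and `truth` (`bleachTimes` = last frame each unit is
#'   visible; `trueStepCount = nUnits`)
#' @examples
#' simulateBleachTrace(3, bleachHalfLife = 50, nFrames = 300, seed = 1)$truth
#' @export
simulateBleachTrace <- function(nUnits, unitIntensity = 1000,
                                bleachHalfLife = 290, noiseSd = 0,
                                nFrames = 1000, seed = NA) {
    if (nUnits < 1) stop("nUnits must be >= 1")
    withSeed(seed, {
        p <- 1 - 0.5 ^ (1 / bleachHalfLife)
        lastAlive <- 1L + rgeom(nUnits, p)   # visible on frames 1..lastAlive
        frames <- seq_len(nFrames)
        counts <- vapply(frames, function(f) sum(lastAlive >= f), integer(1))
        intensity <- counts * unitIntensity
        if (noiseSd > 0) intensity <- intensity + rnorm(nFrames, 0, noiseSd)
        truth <- newTruthRecord("bleach", bleachTimes = lastAlive,
            trueStepCount = as.integer(nUnits),
            trueCopyNumber = as.integer(nUnits))
        list(intensity = intensity, counts = counts, truth = truth)
    })
}

#' Simulate per-frame survival counts for a field of dyes
#'
#' Convenience wrapper used for dye-lifetime calibration: `nDyes` single
#' fluorophores with the given half-life, returning the number still
#' fluorescent at each frame (the per-frame detected-peak count of a
#' sparse single-dye field).
#'
#' @param nDyes number of dyes
#' @param bleachHalfLife dye half-life (frames)
#' @param nFrames number of frames
#' @param seed integer seed
#' @return integer vector of per-frame surviving-dye counts
#' @export
simulateDyeSurvival <- function(nDyes, bleachHalfLife, nFrames = 1000,
                                seed = NA) {
    withSeed(seed, {
        p <- 1 - 0.5 ^ (1 / bleachHalfLife)
        lastAlive <- 1L + rgeom(nDyes, p)
        vapply(seq_len(nFrames), function(f) sum(lastAlive >= f), integer(1))
    })
}

#' Simulate transverse (perpendicular-to-flow) position fluctuations
#'
#' Emulates the x-position scatter of DNA-bound versus surface-stuck
#' molecules used to validate bypass events: i.i.d. Gaussian positions whose
#' variance reflects DNA fluctuations (`"dna_fluctuating"`, variance
#' 0.156 px^2) or surface immobilization (`"surface_stuck"`, 0.015 px^2).
#'
#' @param condition `"dna_fluctuating"` or `"surface_stuck"`
#' @param nMolecules number of molecules
#' @param nFrames frames per molecule
#' @param seed integer seed
#' @param sdPx override of the per-frame position SD (px)
#' @return matrix (`nMolecules` x `nFrames`) of transverse positions (px)
#' @export
simulateTransversePositions <- function(condition = c("dna_fluctuating",
                                                      "surface_stuck"),
                                        nMolecules = 100, nFrames = 200,
                                        seed = NA, sdPx = NULL) {
    condition <- match.arg(condition)
    if (is.null(sdPx))
        sdPx <- if (condition == "dna_fluctuating") sqrt(0.156)
                else sqrt(0.015)
    withSeed(seed,
        matrix(rnorm(nMolecules * nFrames, 0, sdPx), nrow = nMolecules))
}

#' Render trajectories into a kymograph image
#'
#' Each trajectory is painted per frame as a 1-D Gaussian of integrated area
#' equal to its intensity, centered at `position / pixelScale` (0-based
#' pixel coordinates), on a constant background, with optional Poisson shot
#' noise. Positions outside the rendered range are clipped with a warning.
#'
#' @param trajectories list of [Trajectory-class]
#' @param psfSigma point-spread-function SD (px), > 0
#' @param background constant background level (a.u.)
#' @param pixelScale kb per pixel, > 0
#' @param nPixels number of position pixels; default covers 21 kb
#' @param shotNoise add Poisson noise to every pixel
#' @param seed integer seed (shot noise only)
#' @param frameInterval frame interval metadata (s); default from the first
#'   trajectory's time step
#' @return a [KymographImage-class]
#' @export
renderKymograph <- function(trajectories, psfSigma = 1, background = 0,
                            pixelScale = 0.175, nPixels = NULL,
                            shotNoise = FALSE, seed = NA,
                            frameInterval = NULL) {
    if (pixelScale <= 0) stop("pixelScale must be > 0")
    if (psfSigma <= 0) stop("psfSigma must be > 0")
    if (is.null(nPixels)) nPixels <- ceiling(21 / pixelScale)
    nFrames <- max(vapply(trajectories, function(tr) max(tr@frames),
                          integer(1)))
    if (is.null(frameInterval)) {
        tt <- trajectories[[1]]@times
        frameInterval <- if (length(tt) > 1) diff(tt)[1] else 1
    }
    img <- matrix(background, nrow = nPixels, ncol = nFrames)
    px <- seq_len(nPixels) - 1   # 0-based pixel centers
    clipped <- FALSE
    for (tr in trajectories) {
        centers <- tr@positions / pixelScale
        out <- centers < 0 | centers > nPixels - 1
        if (any(out)) { clipped <- TRUE
            centers <- pmin(pmax(centers, 0), nPixels - 1) }
        for (k in seq_along(tr@frames)) {
            w <- exp(-(px - centers[k])^2 / (2 * psfSigma^2))
            img[, tr@frames[k]] <- img[, tr@frames[k]] +
                tr@intensities[k] * w / sum(w)
        }
    }
    if (clipped) warning("trajectory positions outside the rendered range were clipped")
    if (shotNoise)
        img <- withSeed(seed,
            matrix(rpois(length(img), pmax(img, 0)), nrow = nPixels))
    kymographImage(img, pixelScale = pixelScale,
                   frameInterval = frameInterval,
                   channel = trajectories[[1]]@channel)
}
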