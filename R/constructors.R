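#' Construct a DNA layout
#'
#' @param length total DNA length (kb)
#' @param promoterPos,ars1Pos,widom601Pos,terminatorPos element positions (kb)
#' @param terminatorPresent logical
#' @return a [DnaLayout-class]
#' @examples
#' dnaLayout()
#' dnaLayout(terminatorPresent = TRUE)
#' @export
dnaLayout <- function(length = 21, promoterPos = 2.9, ars1Pos = 5.5,
                      widom601Pos = 10.1, terminatorPos = 13.4,
                      terminatorPresent = FALSE) {
    new("DnaLayout", length = length, promoterPos = promoterPos,
        ars1Pos = ars1Pos, widom601Pos = widom601Pos,
        terminatorPos = terminatorPos, terminatorPresent = terminatorPresent)
}

#' Construct a simulation preset
#'
#' Low-level constructor; most users want the named condition presets from
#' [kymoPreset()].
#'
#' @param name preset name
#' @param burstVelocityMean,burstVelocitySd burst velocity distribution (nt/s)
#' @param pauseRate pause events per kb
#' @param pauseRecoveryProb fraction of pauses that are transient
#' @param pauseDurationOffset,pauseDurationMeanExcess transient pause duration
#'   model (s): duration = offset + Exponential(meanExcess)
#' @param outcomeProbs named collision outcome probabilities (sum to 1)
#' @param diffusionCoeff diffusion coefficient (kbp^2/s)
#' @param terminationProb arrest probability at the terminator
#' @param frameInterval frame interval (s)
#' @param localizationNoiseSd localization noise SD (kb)
#' @param bleachHalfLife dye half-life (frames)
#' @param unitIntensity,intensityNoiseSd fluorophore intensity model (a.u.)
#' @param layout a [DnaLayout-class]
#' @param seed optional default seed
#' @return a [SimulationPreset-class]
#' @export
simulationPreset <- function(name = "custom",
        burstVelocityMean = 57, burstVelocitySd = 5.7,
        pauseRate = 0.03, pauseRecoveryProb = 0.40,
        pauseDurationOffset = 20, pauseDurationMeanExcess = 126.1,
        outcomeProbs = c(push = 1, bypass = 0, pause = 0, stall = 0,
                         roadblock_eject = 0, pusher_eject = 0),
        diffusionCoeff = 0, terminationProb = 0,
        frameInterval = 5, localizationNoiseSd = 0.05,
        bleachHalfLife = 290, unitIntensity = 1000,
        intensityNoiseSd = 100, layout = dnaLayout(), seed = NA_integer_) {
    new("SimulationPreset", name = name,
        burstVelocityMean = burstVelocityMean,
        burstVelocitySd = burstVelocitySd, pauseRate = pauseRate,
        pauseRecoveryProb = pauseRecoveryProb,
        pauseDurationOffset = pauseDurationOffset,
        pauseDurationMeanExcess = pauseDurationMeanExcess,
        outcomeProbs = outcomeProbs[OUTCOME_LEVELS],
        diffusionCoeff = diffusionCoeff, terminationProb = terminationProb,
        frameInterval = frameInterval,
        localizationNoiseSd = localizationNoiseSd,
        bleachHalfLife = bleachHalfLife, unitIntensity = unitIntensity,
        intensityNoiseSd = intensityNoiseSd, layout = layout,
        seed = as.integer(seed))
}

#' Named condition presets
#'
#' Returns the [SimulationPreset-class] for a named experimental condition:
#' \describe{
#'   \item{ATP}{transcription on naked DNA with ATP: burst velocity
#'     57.0 +/- 5.7 nt/s, 5 s frames.}
#'   \item{ATPgS}{transcription with ATP-gamma-S: 30.4 +/- 2.8 nt/s.}
#'   \item{MCM_sliding}{diffusive MCM double hexamer at high salt:
#'     D = 19.4 kbp^2/s, 0.5 s frames.}
#'   \item{ORC_collision}{RNAP vs ORC: bypass 21.5%, ORC ejection 17%.}
#'   \item{MCMDH_collision}{RNAP vs MCM double hexamer: push 81.3%, pause
#'     1.4%, stall 3.5%, RNAP ejection 13.8%.}
#'   \item{OCCM_collision}{RNAP vs OCCM: OCCM ejection 6.6%, RNAP ejection
#'     23.2%.}
#'   \item{terminator}{ATP kinetics on a terminator-bearing substrate with
#'     95% termination at 13.4 kb.}
#'   \item{LD555, LD655}{fast-frame photobleaching conditions with dye
#'     half-lives of 290 and 150 frames.}
#' }
#'
#' @param name one of `presetNames()`
#' @return a [SimulationPreset-class]
#' @examples
#' kymoPreset("ATP")
#' kymoPreset("ORC_collision")@outcomeProbs
#' @export
kymoPreset <- function(name = presetNames()) {
    name <- match.arg(name)
    switch(name,
        ATP = simulationPreset("ATP"),
        ATPgS = simulationPreset("ATPgS", burstVelocityMean = 30.4,
            burstVelocitySd = 2.8),
        MCM_sliding = simulationPreset("MCM_sliding", diffusionCoeff = 19.4,
            frameInterval = 0.5, pauseRate = 0),
        ORC_collision = simulationPreset("ORC_collision",
            outcomeProbs = c(push = 0.48, bypass = 0.215, pause = 0.03,
                stall = 0.03, roadblock_eject = 0.17, pusher_eject = 0.075)),
        MCMDH_collision = simulationPreset("MCMDH_collision",
            outcomeProbs = c(push = 0.813, bypass = 0, pause = 0.014,
                stall = 0.035, roadblock_eject = 0, pusher_eject = 0.138)),
        OCCM_collision = simulationPreset("OCCM_collision",
            burstVelocityMean = 30.4, burstVelocitySd = 2.8,
            outcomeProbs = c(push = 0.637, bypass = 0, pause = 0.030,
                stall = 0.035, roadblock_eject = 0.066,
                pusher_eject = 0.232)),
        terminator = simulationPreset("terminator", terminationProb = 0.95,
            layout = dnaLayout(terminatorPresent = TRUE)),
        LD555 = simulationPreset("LD555", frameInterval = 0.5,
            bleachHalfLife = 290),
        LD655 = simulationPreset("LD655", frameInterval = 0.5,
            bleachHalfLife = 150))
}

#' @rdname kymoPreset
#' @export
presetNames <- function() {
    c("ATP", "ATPgS", "MCM_sliding", "ORC_collision", "MCMDH_collision",
      "OCCM_collision", "terminator", "LD555", "LD655")
}

#' Construct a trajectory
#'
#' @param moleculeId molecule identifier
#' @param positions positions on DNA (kb)
#' @param times acquisition times (s); default `(frames - 1) * frameInterval`
#' @param frames integer frame indices; default `seq_along(positions)`
#' @param intensities intensities (a.u.); default 1
#' @param channel,condition labels
#' @param frameInterval used to derive `times` when not given (s)
#' @return a [Trajectory-class]
#' @examples
#' trajectory("m1", positions = c(2.9, 3.2, 3.5), frameInterval = 5)
#' @export
trajectory <- function(moleculeId, positions, times = NULL, frames = NULL,
                       intensities = NULL, channel = "default",
                       condition = "none", frameInterval = 1) {
    n <- length(positions)
    if (is.null(frames)) frames <- seq_len(n)
    if (is.null(times)) times <- (frames - 1) * frameInterval
    if (is.null(intensities)) intensities <- rep(1, n)
    new("Trajectory", moleculeId = as.character(moleculeId),
        channel = channel, frames = as.integer(frames),
        times = as.numeric(times), positions = as.numeric(positions),
        intensities = as.numeric(intensities), condition = condition)
}

#' Construct a kymograph image
#'
#' @param data position x frame intensity matrix
#' @param pixelScale kb per pixel
#' @param frameInterval s per frame
#' @param channel channel label
#' @return a [KymographImage-class]
#' @export
kymographImage <- function(data, pixelScale = 0.175, frameInterval = 5,
                           channel = "default") {
    new("KymographImage", data = data, pixelScale = pixelScale,
        frameInterval = frameInterval, channel = channel)
}

#' Construct an analysis configuration
#'
#' All arguments default to the standard thresholds; see
#' [AnalysisConfig-class].
#'
#' @param ... named slot overrides
#' @return an [AnalysisConfig-class]
#' @examples
#' analysisConfig()
#' analysisConfig(pauseFold = 2)
#' @export
analysisConfig <- function(...) new("AnalysisConfig", ...)

## ---- accessors -----------------------------------------------------------

#' @rdname Trajectory-class
#' @param object,x a Trajectory
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname Trajectory-class
#' @export
setMethod("positions", "Trajectory", function(x) x@positions)

#' @rdname Trajectory-class
#' @export
setGeneric("trajTimes", function(x) standardGeneric("trajTimes"))
#' @rdname Trajectory-class
#' @export
setMethod("trajTimes", "Trajectory", function(x) x@times)

#' @rdname Trajectory-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname Trajectory-class
#' @export
setMethod("intensities", "Trajectory", function(x) x@intensities)

#' @rdname Trajectory-class
#' @export
setGeneric("moleculeId", function(x) standardGeneric("moleculeId"))
#' @rdname Trajectory-class
#' @export
setMethod("moleculeId", "Trajectory", function(x) x@moleculeId)
#' @rdname SegmentTable-class
#' @export
setMethod("moleculeId", "SegmentTable", function(x) x@moleculeId)

#' @rdname SegmentTable-class
#' @param x a SegmentTable
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
#' @rdname SegmentTable-class
#' @export
setMethod("segments", "SegmentTable", function(x) x@segments)

#' @rdname SegmentTable-class
#' @export
setGeneric("breakpoints", function(x) standardGeneric("breakpoints"))
#' @rdname SegmentTable-class
#' @export
setMethod("breakpoints", "SegmentTable", function(x) x@breakpoints)

#' @rdname KymographImage-class
#' @param x a KymographImage
#' @export
setGeneric("pixelScale", function(x) standardGeneric("pixelScale"))
#' @rdname KymographImage-class
#' @export
setMethod("pixelScale", "KymographImage", function(x) x@pixelScale)

#' @rdname KymographImage-class
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname KymographImage-class
#' @export
setMethod("frameInterval", "KymographImage", function(x) x@frameInterval)
#' @rdname SimulationPreset-class
#' @export
setMethod("frameInterval", "SimulationPreset", function(x) x@frameInterval)

#' @rdname KymographImage-class
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))
#' @rdname KymographImage-class
#' @export
setMethod("intensityMatrix", "KymographImage", function(x) x@data)

## ---- show methods --------------------------------------------------------

setMethod("show", "DnaLayout", function(object) {
    cat(sprintf(
        "DnaLayout: %.1f kb | promoter %.1f | ARS1 %.1f | Widom601 %.1f%s\n",
        object@length, object@promoterPos, object@ars1Pos,
        object@widom601Pos,
        if (object@terminatorPresent)
            sprintf(" | terminator %.1f", object@terminatorPos) else ""))
})

setMethod("show", "SimulationPreset", function(object) {
    cat(sprintf("SimulationPreset '%s'\n", object@name))
    cat(sprintf("  velocity %.1f +/- %.1f nt/s | pause rate %.3f /kb (recovery %.0f%%)\n",
        object@burstVelocityMean, object@burstVelocitySd, object@pauseRate,
        100 * object@pauseRecoveryProb))
    cat(sprintf("  D %.1f kbp^2/s | termination %.0f%% | dt %.1f s | noise %.3f kb\n",
        object@diffusionCoeff, 100 * object@terminationProb,
        object@frameInterval, object@localizationNoiseSd))
    p <- object@outcomeProbs
    cat("  outcomes:", paste(sprintf("%s %.1f%%", names(p), 100 * p),
        collapse = ", "), "\n")
})

setMethod("show", "Trajectory", function(object) {
    n <- length(object@frames)
    cat(sprintf("Trajectory '%s' (%s): %d frames", object@moleculeId,
        object@channel, n))
    if (n) cat(sprintf(", t %.0f-%.0f s, pos %.2f-%.2f kb",
        min(object@times), max(object@times),
        min(object@positions), max(object@positions)))
    cat("\n")
})

setMethod("show", "KymographImage", function(object) {
    cat(sprintf(
        "KymographImage (%s): %d px x %d frames | %.3f kb/px | %.2f s/frame\n",
        object@channel, nrow(object@data), ncol(object@data),
        object@pixelScale, object@frameInterval))
})

setMethod("show", "SegmentTable", function(object) {
    cat(sprintf("SegmentTable '%s' (%s): %d segments, %d breakpoints\n",
        object@moleculeId, object@mode, nrow(object@segments),
        length(object@breakpoints)))
    if (nrow(object@segments))
        print(utils::head(object@segments[, c("tStart", "tEnd", "slope",
            "slopeSd", "meanLevel", "isPause", "excluded")], 8))
})

setMethod("show", "AnalysisConfig", function(object) {
    cat("AnalysisConfig:\n")
    cat(sprintf("  segment filter: slope SD > %.0f nt/s or rate < %.0f nt/s\n",
        object@sdFilter, object@negativeRateFloor))
    cat(sprintf("  pauses: > %.0f-fold reduced, > %.0f s, up to %.0f kb\n",
        object@pauseFold, object@pauseMinDuration, object@pausePositionMax))
    cat(sprintf("  collisions: approach < %.1f kb, exclude < %.1f kb, push > %.0f kb, bypass > %.0f kb\n",
        object@approachThreshold, object@exclusionSeparation,
        object@pushThreshold, object@bypassTranscriptionMin))
    cat(sprintf("  terminator: %.0f-%.0f kb, %.0f s / %.0f kb; bootstrap %d\n",
        object@terminatorRegion[1], object@terminatorRegion[2],
        object@stabilityMinTime, object@stabilityWindow,
        as.integer(object@bootstrapCycles)))
})
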