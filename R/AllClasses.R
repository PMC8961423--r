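#' @import methods
#' @importFrom stats approx coef cor density lm mad median nls
#'   residuals rexp rgeom rnorm rpois runif sd setNames var
#' @importFrom utils head read.csv tail write.csv
NULL

#' DNA substrate layout
#'
#' Positions of the functional elements on the linear, surface-tethered DNA
#' substrate, in kb from the promoter-proximal end. The default layout is a
#' 21-kb fragment carrying a T7 promoter at 2.9 kb, the ARS1 origin at
#' 5.5 kb, a Widom601 nucleosome-positioning sequence at 10.1 kb and
#' (optionally) a T7 terminator array at 13.4 kb.
#'
#' @slot length total DNA length (kb)
#' @slot promoterPos T7 promoter position (kb)
#' @slot ars1Pos ARS1 origin position (kb)
#' @slot widom601Pos Widom601 position (kb)
#' @slot terminatorPos T7 terminator position (kb); must lie in [12, 15]
#'   when present
#' @slot terminatorPresent logical; is the terminator array on this substrate
#' @export
setClass("DnaLayout",
    representation(length = "numeric", promoterPos = "numeric",
        ars1Pos = "numeric", widom601Pos = "numeric",
        terminatorPos = "numeric", terminatorPresent = "logical"),
    prototype(length = 21, promoterPos = 2.9, ars1Pos = 5.5,
        widom601Pos = 10.1, terminatorPos = 13.4, terminatorPresent = FALSE))

setValidity("DnaLayout", function(object) {
    msg <- character()
    if (!(object@promoterPos > 0 && object@promoterPos < object@ars1Pos &&
          object@ars1Pos < object@length))
        msg <- c(msg, "need 0 < promoterPos < ars1Pos < length")
    if (object@terminatorPresent &&
        (object@terminatorPos < 12 || object@terminatorPos > 15))
        msg <- c(msg, "terminatorPos must lie within [12, 15] kb when present")
    if (length(msg)) msg else TRUE
})

#' Simulation condition preset
#'
#' Full parameterization of the synthetic-data generator for one experimental
#' condition: per-molecule burst velocity distribution, pause kinetics,
#' collision outcome probabilities, diffusion coefficient, termination
#' probability, imaging parameters and dye photobleaching. Use
#' [kymoPreset()] for the named condition presets.
#'
#' @slot name preset name
#' @slot burstVelocityMean mean burst transcription velocity (nt/s)
#' @slot burstVelocitySd between-molecule velocity SD (nt/s)
#' @slot pauseRate pause events per kb transcribed
#' @slot pauseRecoveryProb probability a pause is transient
#' @slot pauseDurationOffset minimum transient pause duration (s)
#' @slot pauseDurationMeanExcess mean of the exponential excess duration (s)
#' @slot outcomeProbs named probabilities over the six collision outcomes
#' @slot diffusionCoeff 1-D diffusion coefficient (kbp^2/s)
#' @slot terminationProb probability of permanent arrest at the terminator
#' @slot frameInterval frame interval (s)
#' @slot localizationNoiseSd per-frame localization noise SD (kb)
#' @slot bleachHalfLife dye half-life (frames)
#' @slot unitIntensity intensity of one fluorophore unit (a.u.)
#' @slot intensityNoiseSd per-frame intensity noise SD (a.u.)
#' @slot layout a [DnaLayout-class]
#' @slot seed optional default seed
#' @export
setClass("SimulationPreset",
    representation(name = "character", burstVelocityMean = "numeric",
        burstVelocitySd = "numeric", pauseRate = "numeric",
        pauseRecoveryProb = "numeric", pauseDurationOffset = "numeric",
        pauseDurationMeanExcess = "numeric", outcomeProbs = "numeric",
        diffusionCoeff = "numeric", terminationProb = "numeric",
        frameInterval = "numeric", localizationNoiseSd = "numeric",
        bleachHalfLife = "numeric", unitIntensity = "numeric",
        intensityNoiseSd = "numeric", layout = "DnaLayout",
        seed = "integer"))

OUTCOME_LEVELS <- c("push", "bypass", "pause", "stall",
                    "roadblock_eject", "pusher_eject")

setValidity("SimulationPreset", function(object) {
    msg <- character()
    p <- object@outcomeProbs
    if (!setequal(names(p), OUTCOME_LEVELS))
        msg <- c(msg, "outcomeProbs must be named over the six outcomes")
    else {
        if (any(p < 0 | p > 1)) msg <- c(msg, "outcomeProbs must lie in [0,1]")
        if (abs(sum(p) - 1) > 1e-9) msg <- c(msg, "outcomeProbs must sum to 1")
    }
    if (object@burstVelocityMean <= 0) msg <- c(msg, "burstVelocityMean must be > 0")
    if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
    if (object@localizationNoiseSd < 0) msg <- c(msg, "localizationNoiseSd must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Single-molecule trajectory
#'
#' Per-molecule time series of position on DNA (kb) and integrated
#' fluorescence intensity (a.u.), with channel and condition labels.
#'
#' @slot moleculeId molecule identifier
#' @slot channel imaging channel label
#' @slot frames integer frame indices (1-based)
#' @slot times acquisition times (s), strictly increasing
#' @slot positions positions on DNA (kb)
#' @slot intensities background-subtracted intensities (a.u.)
#' @slot condition condition label
#' @export
setClass("Trajectory",
    representation(moleculeId = "character", channel = "character",
        frames = "integer", times = "numeric", positions = "numeric",
        intensities = "numeric", condition = "character"))

setValidity("Trajectory", function(object) {
    n <- length(object@frames)
    msg <- character()
    if (length(object@times) != n || length(object@positions) != n ||
        length(object@intensities) != n)
        msg <- c(msg, "frames, times, positions, intensities must have equal length")
    if (n > 1 && any(diff(object@times) <= 0))
        msg <- c(msg, "times must be strictly increasing")
    if (any(!is.finite(object@positions)))
        msg <- c(msg, "positions must be finite")
    if (length(msg)) msg else TRUE
})

#' Kymograph image
#'
#' A single-channel kymograph: a non-negative intensity matrix with rows
#' indexing position (pixels) and columns indexing frames, plus the pixel
#' scale and frame interval needed to map to physical units.
#'
#' @slot data position x frame intensity matrix
#' @slot pixelScale kb per pixel
#' @slot frameInterval s per frame
#' @slot channel channel label
#' @export
setClass("KymographImage",
    representation(data = "matrix", pixelScale = "numeric",
        frameInterval = "numeric", channel = "character"))

setValidity("KymographImage", function(object) {
    msg <- character()
    if (any(!is.finite(object@data))) msg <- c(msg, "data must be finite")
    if (object@pixelScale <= 0) msg <- c(msg, "pixelScale must be > 0")
    if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
    if (length(msg)) msg else TRUE
})

#' Change-point segment table
#'
#' Piecewise decomposition of one trace: in `"linear"` mode each segment is a
#' least-squares line (velocity in nt/s with its standard error); in `"step"`
#' mode each segment is a constant intensity level. Segments are contiguous
#' and cover the trace; interior boundaries are placed midway between the
#' samples flanking each change point.
#'
#' @slot moleculeId molecule identifier
#' @slot segments data.frame with columns tStart, tEnd, duration, slope,
#'   slopeSd, intercept, positionStart, positionMid, meanLevel, isPause,
#'   excluded, segIndex
#' @slot breakpoints interior boundary times (s), strictly increasing
#' @slot mode `"linear"` or `"step"`
#' @export
setClass("SegmentTable",
    representation(moleculeId = "character", segments = "data.frame",
        breakpoints = "numeric", mode = "character"))

setValidity("SegmentTable", function(object) {
    msg <- character()
    if (!object@mode %in% c("linear", "step"))
        msg <- c(msg, "mode must be 'linear' or 'step'")
    s <- object@segments
    if (nrow(s)) {
        if (any(s$tEnd <= s$tStart)) msg <- c(msg, "tEnd must exceed tStart")
        if (nrow(s) > 1 && any(abs(s$tStart[-1] - s$tEnd[-nrow(s)]) > 1e-8))
            msg <- c(msg, "segments must be contiguous")
    }
    if (length(object@breakpoints) > 1 && any(diff(object@breakpoints) <= 0))
        msg <- c(msg, "breakpoints must be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' Analysis thresholds
#'
#' The numeric rules applied when turning segment tables into transcription
#' and collision statistics. Defaults implement the standard analysis:
#' exclude segments with slope SD > 10 nt/s or rate < -10 nt/s; mark
#' segments with > 3-fold reduced velocity as pauses; count pauses > 20 s
#' occurring up to 19 kb; analyze collisions when proteins approach to
#' < 0.5 kb (excluding starting separations < 1 kb); push/bypass thresholds
#' 2 kb and 4 kb; terminator stability in the 12-15 kb region with a 120 s /
#' 2 kb rule; 10,000 bootstrap cycles.
#'
#' @slot sdFilter max slope SD (nt/s)
#' @slot negativeRateFloor min slope (nt/s)
#' @slot pauseFold fold-reduction defining a pause
#' @slot pauseMinDuration min counted pause duration (s)
#' @slot pausePositionMax max position of counted pauses (kb)
#' @slot approachThreshold collision approach distance (kb)
#' @slot exclusionSeparation min starting separation (kb)
#' @slot pushThreshold displacement separating push from non-push (kb)
#' @slot bypassTranscriptionMin min advance past the roadblock for bypass (kb)
#' @slot terminatorRegion terminator region (kb, length 2)
#' @slot stabilityMinTime residence-time rule at the terminator (s)
#' @slot stabilityWindow distance window for "remain" (kb)
#' @slot bootstrapCycles bootstrap resamples
#' @export
setClass("AnalysisConfig",
    representation(sdFilter = "numeric", negativeRateFloor = "numeric",
        pauseFold = "numeric", pauseMinDuration = "numeric",
        pausePositionMax = "numeric", approachThreshold = "numeric",
        exclusionSeparation = "numeric", pushThreshold = "numeric",
        bypassTranscriptionMin = "numeric", terminatorRegion = "numeric",
        stabilityMinTime = "numeric", stabilityWindow = "numeric",
        bootstrapCycles = "numeric"),
    prototype(sdFilter = 10, negativeRateFloor = -10, pauseFold = 3,
        pauseMinDuration = 20, pausePositionMax = 19,
        approachThreshold = 0.5, exclusionSeparation = 1, pushThreshold = 2,
        bypassTranscriptionMin = 4, terminatorRegion = c(12, 15),
        stabilityMinTime = 120, stabilityWindow = 2, bootstrapCycles = 10000))

setValidity("AnalysisConfig", function(object) {
    msg <- character()
    if (object@sdFilter <= 0 || object@pauseFold <= 0 ||
        object@pauseMinDuration <= 0 || object@approachThreshold <= 0 ||
        object@exclusionSeparation <= 0 || object@pushThreshold <= 0 ||
        object@bypassTranscriptionMin <= 0 || object@stabilityMinTime <= 0 ||
        object@stabilityWindow <= 0 || object@bootstrapCycles <= 0)
        msg <- c(msg, "thresholds must be positive")
    if (length(object@terminatorRegion) != 2 ||
        diff(object@terminatorRegion) <= 0)
        msg <- c(msg, "terminatorRegion must be an increasing length-2 range")
    if (length(msg)) msg else TRUE
})
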