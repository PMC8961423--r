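# Signal-loss test: the trace ends with a run of >= minRun frames at
# background (below half the initial intensity). Returns the time of loss or
# NA. Distinguishes permanent loss from blinking by requiring the run to
# persist to the trace end.
.signalLossTime <- function(traj, minRun = 3) {
    ints <- traj@intensities
    n <- length(ints)
    if (n < minRun) return(NA_real_)
    init <- median(head(ints, 5))
    if (init <= 0) return(NA_real_)
    low <- ints < 0.5 * init
    lastHigh <- if (any(!low)) max(which(!low)) else 0L
    if (n - lastHigh >= minRun) traj@times[lastHigh + 1] else NA_real_
}

#' Detect a pusher-roadblock collision
#'
#' An encounter is analyzed when the two molecules approach to less than
#' `approachThreshold` (default 0.5 kb). Pairs whose starting positions are
#' closer than `exclusionSeparation` (default 1 kb) are excluded, as are
#' pairs without overlapping frames.
#'
#' @param pusher,roadblock [Trajectory-class] objects
#' @param cfg an [AnalysisConfig-class]
#' @return list with `excluded` (logical), `reason` (when excluded), and for
#'   analyzable pairs `tApproach` (s), `collisionPosition` (kb, roadblock
#'   position at approach) and `minDistance` (kb). `tApproach` is NA when
#'   the approach threshold is never reached (no event).
#' @export
detectCollision <- function(pusher, roadblock, cfg = analysisConfig()) {
    if (length(pusher@frames) < 2 || length(roadblock@frames) < 2)
        stop("both trajectories must span at least 2 frames")
    common <- intersect(pusher@frames, roadblock@frames)
    if (!length(common))
        return(list(excluded = TRUE, reason = "no_overlap"))
    ip <- match(common, pusher@frames); ir <- match(common, roadblock@frames)
    if (abs(pusher@positions[ip[1]] - roadblock@positions[ir[1]]) <
        cfg@exclusionSeparation)
        return(list(excluded = TRUE, reason = "initial_proximity"))
    gap <- abs(pusher@positions[ip] - roadblock@positions[ir])
    hit <- which(gap < cfg@approachThreshold)
    if (!length(hit))
        return(list(excluded = FALSE, tApproach = NA_real_,
                    minDistance = min(gap)))
    k <- hit[1]
    list(excluded = FALSE, tApproach = pusher@times[ip[k]],
         collisionPosition = roadblock@positions[ir[k]],
         minDistance = min(gap), approachIndexRoadblock = ir[k],
         approachIndexPusher = ip[k])
}

#' Classify a collision outcome
#'
#' Applies the displacement taxonomy to a detected encounter. With `d` the
#' roadblock displacement after the approach (maximum position minus the
#' position at approach) and signal loss defined as intensity at background
#' for at least 3 consecutive frames persisting to the trace end, the
#' decision order is: (1) roadblock signal lost with `d` below the push
#' threshold: `roadblock_eject`; (2) pusher signal lost with small `d`:
#' `pusher_eject`; (3) `d` above the push threshold with a transient pusher
#' pause starting within 2 kb of the collision position: `pause`; (4) `d`
#' above the push threshold: `push`; (5) small `d` with the pusher
#' advancing more than 4 kb past the collision position: `bypass`; (6)
#' small `d` with a permanent pusher pause: `stall`. Anything else is
#' `unclassified`.
#'
#' @param event result of [detectCollision()] (must not be excluded)
#' @param pusher,roadblock [Trajectory-class] objects
#' @param pusherSegments classified [SegmentTable-class] of the pusher
#'   (after [filterSegments()] and [classifyPauses()])
#' @param cfg an [AnalysisConfig-class]
#' @return outcome label (character)
#' @export
classifyOutcome <- function(event, pusher, roadblock, pusherSegments,
                            cfg = analysisConfig()) {
    if (isTRUE(event$excluded)) stop("cannot classify an excluded event")
    if (is.na(event$tApproach)) stop("no encounter: tApproach is NA")
    push <- cfg@pushThreshold
    iA <- event$approachIndexRoadblock
    after <- roadblock@positions[iA:length(roadblock@positions)]
    d <- max(after) - after[1]

    rbLost <- .signalLossTime(roadblock)
    puLost <- .signalLossTime(pusher)
    if (!is.na(rbLost) && d < push) return("roadblock_eject")
    if (!is.na(puLost) && d < push) return("pusher_eject")

    s <- pusherSegments@segments
    keep <- !s$excluded
    pauseIdx <- which(s$isPause & keep)
    lastKeep <- if (any(keep)) max(which(keep)) else 0L
    transientNear <- FALSE
    permanentPause <- FALSE
    for (i in pauseIdx) {
        near <- abs(s$positionStart[i] - event$collisionPosition) < 2
        resumes <- any(which(keep & !s$isPause) > i)
        if (near && resumes) transientNear <- TRUE
        if (!resumes && i == lastKeep) permanentPause <- TRUE
    }
    if (d > push && transientNear) return("pause")
    if (d > push) return("push")

    pAfter <- pusher@positions[pusher@times >= event$tApproach]
    advance <- if (length(pAfter))
        max(pAfter) - event$collisionPosition else 0
    if (d < push && advance > cfg@bypassTranscriptionMin) return("bypass")
    if (d < push && permanentPause) return("stall")
    "unclassified"
}

#' Pushed distance of a roadblock
#'
#' Distance a protein was displaced along DNA: the maximum detected position
#' minus the loading site (the initial position).
#'
#' @param traj a [Trajectory-class] with >= 2 frames
#' @return pushed distance (kb)
#' @examples
#' pushedDistance(trajectory("m", positions = c(5.5, 10, 18.2, 15)))
#' @export
pushedDistance <- function(traj) {
    if (length(traj@positions) < 2) stop("need at least 2 frames")
    max(traj@positions) - traj@positions[1]
}

#' Estimate fluorophore copy number from intensity
#'
#' Copy number of a focus from its initial fluorescence intensity and the
#' mean intensity of a single unit obtained from photobleaching analysis.
#'
#' @param initialIntensity focus intensity (a.u.)
#' @param unitIntensity single-unit intensity (a.u.), > 0
#' @return integer copy number (minimum 1 for a detected focus)
#' @examples
#' estimateCopyNumber(2050, 1000)
#' @export
estimateCopyNumber <- function(initialIntensity, unitIntensity) {
    if (unitIntensity <= 0) stop("unitIntensity must be > 0")
    pmax(1L, as.integer(round(initialIntensity / unitIntensity)))
}

#' Classify protein stability at the termination site
#'
#' Once transcription-driven displacement has stopped permanently within the
#' terminator region (12-15 kb), the roadblock trajectory from the arrest
#' time onward is classified: `dissociate` if the protein stays on DNA for
#' less than 120 s; `remain` if it stays within 2 kb of the stop position
#' for more than 120 s; `slide_back` if it stays on DNA for more than 120 s
#' without staying within 2 kb.
#'
#' @param traj roadblock [Trajectory-class]
#' @param arrestTime time of the permanent stop (s)
#' @param cfg an [AnalysisConfig-class]
#' @return list with `call` (one of the three classes or `not_analyzed`),
#'   `stopPosition` (kb) and `timeOnDna` (s after the stop)
#' @export
classifyTerminatorStability <- function(traj, arrestTime,
                                        cfg = analysisConfig()) {
    sel <- traj@times >= arrestTime
    if (!any(sel)) stop("arrestTime beyond the trajectory")
    tt <- traj@times[sel]; pp <- traj@positions[sel]
    stopPos <- pp[1]
    region <- cfg@terminatorRegion
    if (stopPos < region[1] || stopPos > region[2])
        return(list(call = "not_analyzed", stopPosition = stopPos,
                    timeOnDna = NA_real_))
    loss <- .signalLossTime(traj)
    tEnd <- if (!is.na(loss) && loss > arrestTime) loss else max(tt)
    onDna <- tEnd - arrestTime
    call <- if (onDna < cfg@stabilityMinTime) "dissociate"
        else if (all(abs(pp[tt <= tEnd] - stopPos) < cfg@stabilityWindow))
            "remain"
        else "slide_back"
    list(call = call, stopPosition = stopPos, timeOnDna = onDna)
}

#' Classify an ensemble of collision events
#'
#' Runs [detectCollision()], pusher segmentation and [classifyOutcome()]
#' over a list of simulated or tracked pusher/roadblock pairs.
#'
#' @param events list of lists with elements `pusher` and `roadblock`
#' @param cfg an [AnalysisConfig-class]
#' @param penalty,minSegment passed to [segmentTrajectory()]
#' @return data.frame with one row per pair: `pusherId`, `roadblockId`,
#'   `excluded`, `reason`, `tApproach`, `outcome`, `pushedDistance`
#' @export
classifyCollisionEnsemble <- function(events, cfg = analysisConfig(),
                                      penalty = 1, minSegment = 3) {
    rows <- lapply(events, function(ev) {
        det <- detectCollision(ev$pusher, ev$roadblock, cfg)
        row <- data.frame(pusherId = ev$pusher@moleculeId,
            roadblockId = ev$roadblock@moleculeId,
            excluded = isTRUE(det$excluded),
            reason = if (isTRUE(det$excluded)) det$reason else "",
            tApproach = NA_real_, outcome = NA_character_,
            pushedDistance = pushedDistance(ev$roadblock),
            stringsAsFactors = FALSE)
        if (!isTRUE(det$excluded) && !is.na(det$tApproach)) {
            segs <- classifyPauses(filterSegments(
                segmentTrajectory(ev$pusher, penalty, minSegment), cfg), cfg)
            row$tApproach <- det$tApproach
            row$outcome <- classifyOutcome(det, ev$pusher, ev$roadblock,
                                           segs, cfg)
        }
        row
    })
    do.call(rbind, rows)
}
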