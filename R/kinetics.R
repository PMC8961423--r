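#' Filter poorly fitted segments
#'
#' Marks segments as excluded when the slope standard error exceeds
#' `sdFilter` (default 10 nt/s) or the slope falls below
#' `negativeRateFloor` (default -10 nt/s); retained segments are
#' re-indexed.
#'
#' @param table a linear-mode [SegmentTable-class]
#' @param cfg an [AnalysisConfig-class]
#' @return the table with the `excluded` flag set and `segIndex` renumbered
#'   over retained segments. If every segment is excluded, an attribute
#'   `allExcluded = TRUE` is set on the returned object.
#' @examples
#' tr <- trajectory("m1", positions = seq(0, 5, by = 0.25), frameInterval = 5)
#' filterSegments(segmentTrajectory(tr), analysisConfig())
#' @export
filterSegments <- function(table, cfg = analysisConfig()) {
    if (table@mode != "linear") stop("expected a linear-mode SegmentTable")
    s <- table@segments
    s$excluded <- s$slopeSd > cfg@sdFilter | s$slope < cfg@negativeRateFloor
    s$segIndex <- NA_integer_
    s$segIndex[!s$excluded] <- seq_len(sum(!s$excluded))
    table@segments <- s
    if (all(s$excluded)) attr(table, "allExcluded") <- TRUE
    table
}

# time-weighted (or plain) mean slope of retained non-pause segments
.nonPauseMean <- function(s, timeWeighted = TRUE) {
    np <- !s$isPause & !s$excluded
    if (!any(np)) return(NA_real_)
    if (timeWeighted)
        sum(s$duration[np] * s$slope[np]) / sum(s$duration[np])
    else mean(s$slope[np])
}

#' Classify pause segments
#'
#' Iterative fixed-point pause marking: starting from all retained segments
#' unmarked, the time-weighted mean slope of non-pause segments is computed
#' and every segment with a more than `pauseFold`-fold reduced velocity
#' (slope below mean / pauseFold) is marked as a pause; the mean is then
#' recomputed over the survivors until the labels are stable. The pause set
#' grows monotonically, so the iteration terminates in at most one pass per
#' segment.
#'
#' @param table a filtered linear-mode [SegmentTable-class]
#' @param cfg an [AnalysisConfig-class]
#' @param timeWeighted use the time-weighted non-pause mean (default) or the
#'   unweighted mean
#' @return the table with `isPause` set. If the iteration leaves no
#'   non-pause segments an attribute `degenerate = TRUE` is set.
#' @export
classifyPauses <- function(table, cfg = analysisConfig(),
                           timeWeighted = TRUE) {
    if (table@mode != "linear") stop("expected a linear-mode SegmentTable")
    s <- table@segments
    s$isPause <- FALSE
    repeat {
        m <- .nonPauseMean(s, timeWeighted)
        if (is.na(m)) break
        newPause <- !s$excluded & !s$isPause & s$slope < m / cfg@pauseFold
        if (!any(newPause)) break
        s$isPause <- s$isPause | newPause
    }
    table@segments <- s
    if (!any(!s$isPause & !s$excluded)) attr(table, "degenerate") <- TRUE
    table
}

#' Burst transcription rate
#'
#' Time-weighted average slope of retained non-pause segments (nt/s).
#'
#' @param table a linear-mode [SegmentTable-class] after [filterSegments()]
#'   and [classifyPauses()]
#' @return burst rate (nt/s); `NA` with a warning when no non-pause retained
#'   segment exists
#' @export
burstRate <- function(table) {
    m <- .nonPauseMean(table@segments, timeWeighted = TRUE)
    if (is.na(m)) warning("no retained non-pause segments: burst rate undefined")
    m
}

# counted pauses of one molecule: pause segments > minDuration, up to maxPos;
# transient if followed by a retained non-pause segment, else permanent
.countedPauses <- function(table, cfg) {
    s <- table@segments
    idx <- which(s$isPause & !s$excluded &
                 s$duration > cfg@pauseMinDuration &
                 s$positionMid <= cfg@pausePositionMax)
    if (!length(idx)) return(NULL)
    lastNonPause <- which(!s$isPause & !s$excluded)
    transient <- vapply(idx, function(i)
        any(lastNonPause > i), logical(1))
    data.frame(moleculeId = table@moleculeId,
        tStart = s$tStart[idx], tEnd = s$tEnd[idx],
        duration = s$duration[idx], position = s$positionMid[idx],
        type = ifelse(transient, "transient", "permanent"),
        stringsAsFactors = FALSE)
}

#' Ensemble pause statistics
#'
#' Counted pauses are pause segments longer than `pauseMinDuration`
#' (default 20 s) occurring up to `pausePositionMax` (default 19 kb).
#' A counted pause followed by further transcription (a later retained
#' non-pause segment) is transient, otherwise permanent; a pause segment
#' reaching the last frame is therefore permanent. The pause probability is
#' the fraction of molecules with at least one counted pause and is refused
#' on terminator-bearing substrates, which are not informative about
#' pausing.
#'
#' @param tables list of classified [SegmentTable-class] objects
#' @param cfg an [AnalysisConfig-class]
#' @param terminatorPresent does the substrate carry a terminator?
#' @return list with `pauseProbability` (NA when `terminatorPresent`),
#'   `recoveryFraction`, `transientDurations` (s), and the per-pause table
#'   `pauses`
#' @export
pauseStatistics <- function(tables, cfg = analysisConfig(),
                            terminatorPresent = FALSE) {
    if (terminatorPresent)
        stop(paste("pause probability is not defined on terminator-bearing",
                   "substrates; analyze a terminator-free condition"))
    plist <- lapply(tables, .countedPauses, cfg = cfg)
    pauses <- do.call(rbind, plist[!vapply(plist, is.null, logical(1))])
    nMol <- length(tables)
    if (is.null(pauses))
        return(list(pauseProbability = 0, recoveryFraction = NA_real_,
                    transientDurations = numeric(),
                    pauses = data.frame()))
    nPaused <- length(unique(pauses$moleculeId))
    trans <- pauses$type == "transient"
    list(pauseProbability = nPaused / nMol,
         recoveryFraction = sum(trans) / nrow(pauses),
         transientDurations = pauses$duration[trans],
         pauses = pauses)
}

#' Gaussian fit of a rate distribution
#'
#' Maximum-likelihood Gaussian fit of a set of burst rates (the sample mean
#' and ML standard deviation), reported as `gaussMean` +/- `gaussSd`.
#' Histogram-free and deterministic.
#'
#' @param rates numeric vector of rates (nt/s), length >= 5
#' @return list with `gaussMean`, `gaussSd`, `n`, `rates`, and `degenerate`
#'   (TRUE when the SD is zero)
#' @examples
#' fitRateDistribution(c(55, 57, 59, 56, 58))
#' @export
fitRateDistribution <- function(rates) {
    rates <- rates[is.finite(rates)]
    n <- length(rates)
    if (n < 5) stop("need at least 5 rates for a Gaussian fit")
    mu <- mean(rates)
    sdml <- sqrt(mean((rates - mu)^2))
    list(gaussMean = mu, gaussSd = sdml, n = n, rates = rates,
         degenerate = sdml == 0)
}

#' Per-molecule burst rates for an ensemble
#'
#' Runs segmentation, segment filtering, pause classification and the burst
#' rate for each trajectory. Molecules whose maximum displacement from the
#' loading site stays below `minTranscribedKb` never entered processive
#' transcription (stalled complexes that failed to restart) and carry no
#' defined transcription rate; their rate is NA.
#'
#' @param trajectories list of [Trajectory-class]
#' @param cfg an [AnalysisConfig-class]
#' @param penalty,minSegment passed to [segmentTrajectory()]
#' @param minTranscribedKb minimum transcribed distance (kb) for a molecule
#'   to contribute a burst rate
#' @return list with `rates` (named numeric, NA where undefined) and
#'   `tables` (classified [SegmentTable-class] objects, one per molecule)
#' @export
burstRateEnsemble <- function(trajectories, cfg = analysisConfig(),
                              penalty = 1, minSegment = 3,
                              minTranscribedKb = 2) {
    tables <- lapply(trajectories, function(tr)
        classifyPauses(filterSegments(segmentTrajectory(tr, penalty,
            minSegment), cfg), cfg))
    rates <- vapply(tables, function(tb)
        suppressWarnings(burstRate(tb)), numeric(1))
    moved <- vapply(trajectories, pushedDistance, numeric(1))
    rates[moved < minTranscribedKb] <- NA_real_
    names(rates) <- vapply(trajectories, moleculeId, character(1))
    list(rates = rates, tables = tables)
}

#' Termination efficiency at the terminator
#'
#' Among molecules whose transcription reaches the terminator region, the
#' fraction whose final permanent arrest lies within the region (terminated)
#' as opposed to transcribing past it (escaped). Molecules permanently
#' arrested upstream of the region never probe the terminator and are not
#' counted.
#'
#' @param tables list of classified [SegmentTable-class] objects
#' @param cfg an [AnalysisConfig-class]
#' @return list with `efficiency` (fraction), `nTerminated`, `nEscaped`
#' @export
terminationEfficiency <- function(tables, cfg = analysisConfig()) {
    region <- cfg@terminatorRegion
    status <- vapply(tables, function(tb) {
        s <- tb@segments
        keep <- !s$excluded
        if (!any(keep)) return("uninformative")
        posEnd <- 2 * s$positionMid - s$positionStart
        maxPos <- max(posEnd[keep], s$positionStart[keep])
        last <- max(which(keep))
        arrested <- s$isPause[last]   # final segment is an arrest
        arrestPos <- s$positionMid[last]
        if (arrested && arrestPos >= region[1] && arrestPos <= region[2])
            "terminated"
        else if (maxPos > region[2]) "escaped"
        else "uninformative"
    }, character(1))
    nT <- sum(status == "terminated"); nE <- sum(status == "escaped")
    list(efficiency = if (nT + nE) nT / (nT + nE) else NA_real_,
         nTerminated = nT, nEscaped = nE)
}
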