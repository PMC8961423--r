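# Kinetic change-point decomposition by BIC-penalized recursive binary
# segmentation. Piecewise-linear ("linear") model for position traces,
# piecewise-constant ("step") model for intensity traces. Per-segment RSS is
# computed in O(1) from prefix sums, so each candidate-split scan is linear
# in the segment length.

# prefix sums of x, y, x^2, xy, y^2 (leading 0 for easy range sums)
.prefix <- function(x, y) {
    list(Sx = c(0, cumsum(x)), Sy = c(0, cumsum(y)),
         Sxx = c(0, cumsum(x * x)), Sxy = c(0, cumsum(x * y)),
         Syy = c(0, cumsum(y * y)))
}

# RSS of segments (s..j) for a vector of starts s at fixed end j, vectorized
# over s via the prefix sums
.rssFrom <- function(P, s, j, linear) {
    m <- j - s + 1
    sx <- P$Sx[j + 1] - P$Sx[s]; sy <- P$Sy[j + 1] - P$Sy[s]
    sxx <- P$Sxx[j + 1] - P$Sxx[s]; sxy <- P$Sxy[j + 1] - P$Sxy[s]
    syy <- P$Syy[j + 1] - P$Syy[s]
    cyy <- syy - sy * sy / m
    if (!linear) return(pmax(cyy, 0))
    cxx <- sxx - sx * sx / m
    cxy <- sxy - sx * sy / m
    rss <- cyy - ifelse(cxx > 0, cxy * cxy / cxx, 0)
    pmax(rss, 0)
}

# Exact penalized change-point search (optimal partitioning): minimizes
# total RSS plus a per-segment penalty beta over all partitions with
# segments of at least minSeg points. beta is the BIC complexity cost of one
# additional segment under Gaussian noise: the segment's parameters (slope +
# intercept, or one level) plus 3/2 for the estimated change-point location
# (modified-BIC convention), times log(n), times the noise variance.
.segmentBreaks <- function(x, y, penalty, minSeg, linear) {
    n <- length(y)
    P <- .prefix(x, y)
    # noise variance from first differences (robust to slope); for a linear
    # trend the first differences are constant, so their MAD reflects noise
    s <- robustSd(diff(y))
    sigma2 <- max(s * s / 2, 1e-12)
    kPar <- if (linear) 3.5 else 2.5
    beta <- penalty * kPar * log(n) * sigma2
    Fcost <- c(0, rep(Inf, n))   # Fcost[i + 1] = optimal cost of y[1..i]
    prev <- integer(n)
    for (j in minSeg:n) {
        starts <- which(Fcost[seq_len(j - minSeg + 1)] < Inf)  # i + 1
        starts <- starts[starts == 1 | starts > minSeg]
        vals <- Fcost[starts] + .rssFrom(P, starts, j, linear) + beta
        k <- which.min(vals)
        Fcost[j + 1] <- vals[k]
        prev[j] <- starts[k] - 1
    }
    breaks <- integer()
    j <- n
    while (j > 0) {
        i <- prev[j]
        if (i > 0) breaks <- c(i, breaks)
        j <- i
    }
    breaks
}

.segmentStats <- function(x, y, i, j, linear) {
    m <- j - i + 1
    xs <- x[i:j]; ys <- y[i:j]
    if (linear && m >= 2 && stats::var(xs) > 0) {
        mx <- mean(xs); my <- mean(ys)
        cxx <- sum((xs - mx)^2)
        b <- sum((xs - mx) * (ys - my)) / cxx
        a <- my - b * mx
        rss <- sum((ys - a - b * xs)^2)
        se <- if (m > 2) sqrt(rss / (m - 2) / cxx) else 0
        list(slope = b, intercept = a, slopeSd = se,
             posStart = a + b * xs[1], posMid = a + b * mean(range(xs)),
             level = my)
    } else {
        list(slope = 0, intercept = mean(ys), slopeSd = 0,
             posStart = mean(ys), posMid = mean(ys), level = mean(ys))
    }
}

.buildSegmentTable <- function(moleculeId, x, y, breaks, linear) {
    n <- length(y)
    starts <- c(1, breaks + 1); ends <- c(breaks, n)
    # contiguous time bounds: interior boundaries midway between samples
    bTimes <- if (length(breaks)) (x[breaks] + x[breaks + 1]) / 2
              else numeric()
    tS <- c(x[1], bTimes); tE <- c(bTimes, x[n])
    segs <- do.call(rbind, lapply(seq_along(starts), function(k) {
        st <- .segmentStats(x, y, starts[k], ends[k], linear)
        data.frame(tStart = tS[k], tEnd = tE[k],
            duration = tE[k] - tS[k],
            slope = if (linear) st$slope * 1000 else 0,   # kb/s -> nt/s
            slopeSd = if (linear) st$slopeSd * 1000 else 0,
            intercept = st$intercept,
            positionStart = st$posStart, positionMid = st$posMid,
            meanLevel = st$level, isPause = FALSE, excluded = FALSE,
            segIndex = k)
    }))
    new("SegmentTable", moleculeId = moleculeId, segments = segs,
        breakpoints = bTimes, mode = if (linear) "linear" else "step")
}

#' Segment a trajectory into piecewise-linear regions
#'
#' Kinetic change-point fit of a position-vs-time trace: breakpoints are
#' chosen by recursive binary splitting, each candidate split maximizing the
#' reduction in residual sum of squares of per-segment least-squares lines;
#' a split is accepted iff it lowers the Bayesian information criterion
#' under Gaussian noise, with the noise variance estimated robustly from the
#' trace's first differences and `penalty` multiplying the BIC complexity
#' term. The result is deterministic for a fixed input. Slopes are reported
#' in nt/s (positions in kb; 1 kb = 1000 nt) together with their standard
#' errors.
#'
#' @param traj a [Trajectory-class]
#' @param penalty multiplier on the BIC complexity term (1 = plain BIC)
#' @param minSegment minimum segment length (frames)
#' @return a [SegmentTable-class] in `"linear"` mode. Traces shorter than
#'   `2 * minSegment` yield a single-segment table.
#' @examples
#' tr <- trajectory("m1", positions = c(seq(0, 5, by = 0.25),
#'                                      rep(5, 20)), frameInterval = 5)
#' segmentTrajectory(tr)
#' @export
segmentTrajectory <- function(traj, penalty = 1, minSegment = 3) {
    x <- traj@times; y <- traj@positions
    n <- length(y)
    if (n < 2)
        stop("trajectory must span at least 2 frames")
    breaks <- if (n >= 2 * minSegment)
        .segmentBreaks(x, y, penalty, minSegment, linear = TRUE)
    else integer()
    .buildSegmentTable(traj@moleculeId, x, y, breaks, linear = TRUE)
}

#' Segment an intensity trace into constant steps
#'
#' Same change-point search as [segmentTrajectory()] with a zero-slope
#' (constant-level) segment model, used for photobleaching step analysis.
#'
#' @param trace numeric intensity vector, or a [Trajectory-class] whose
#'   intensities are used
#' @param penalty multiplier on the BIC complexity term
#' @param minSegment minimum segment length (frames)
#' @param frameInterval frame interval (s) when `trace` is a bare vector
#' @param moleculeId identifier for the output table
#' @return a [SegmentTable-class] in `"step"` mode with per-segment
#'   `meanLevel`
#' @examples
#' detectIntensitySteps(rep(c(300, 200, 100, 0), each = 25))
#' @export
detectIntensitySteps <- function(trace, penalty = 1, minSegment = 3,
                                 frameInterval = 1, moleculeId = "trace") {
    if (is(trace, "Trajectory")) {
        x <- trace@times; y <- trace@intensities
        moleculeId <- trace@moleculeId
    } else {
        y <- as.numeric(trace)
        x <- (seq_along(y) - 1) * frameInterval
    }
    if (length(y) < 4) stop("intensity trace must span at least 4 frames")
    breaks <- if (length(y) >= 2 * minSegment)
        .segmentBreaks(x, y, penalty, minSegment, linear = FALSE)
    else integer()
    .buildSegmentTable(moleculeId, x, y, breaks, linear = FALSE)
}

#' Count photobleaching steps in a step-mode segment table
#'
#' Counts downward level transitions whose drop exceeds half the unit-step
#' estimate (the median downward drop); upward transitions (blinking) are
#' ignored.
#'
#' @param steps a [SegmentTable-class] in `"step"` mode
#' @param unitIntensity optional known single-fluorophore intensity; when
#'   omitted it is estimated as the median downward level drop
#' @return integer number of bleaching steps
#' @examples
#' countBleachSteps(detectIntensitySteps(rep(c(300, 200, 100, 0), each = 25)))
#' @export
countBleachSteps <- function(steps, unitIntensity = NULL) {
    if (steps@mode != "step") stop("expected a step-mode SegmentTable")
    lev <- steps@segments$meanLevel
    if (length(lev) < 2) return(0L)
    drops <- -diff(lev)
    down <- drops[drops > 0]
    if (!length(down)) return(0L)
    if (is.null(unitIntensity)) unitIntensity <- median(down)
    sum(drops > 0.5 * unitIntensity)
}
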