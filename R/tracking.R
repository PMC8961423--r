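#' Correct a kymograph for the excitation beam profile
#'
#' Divides every frame (column) by the illumination profile along the
#' position axis, normalized to mean 1, removing position-specific intensity
#' differences.
#'
#' @param image a [KymographImage-class]
#' @param profile strictly positive intensity profile, one value per
#'   position pixel
#' @return the flattened [KymographImage-class]
#' @export
flattenField <- function(image, profile) {
    if (length(profile) != nrow(image@data))
        stop("profile length must match the image position extent")
    if (any(profile <= 0))
        stop("invalid profile: entries must be strictly positive")
    p <- profile / mean(profile)
    image@data <- image@data / p
    image
}

#' Correct trajectories for stage drift
#'
#' The per-frame median displacement of surface-stuck fiducial trajectories
#' from their own time means is subtracted from every trajectory position.
#' Frames without fiducial coverage are corrected by linear interpolation.
#'
#' @param trajectories list of [Trajectory-class]
#' @param fiducials list of surface-stuck [Trajectory-class]
#' @return the corrected trajectory list
#' @export
correctDrift <- function(trajectories, fiducials) {
    if (!length(fiducials)) stop("need at least one fiducial trajectory")
    allFrames <- sort(unique(unlist(lapply(c(trajectories, fiducials),
        function(tr) tr@frames))))
    disp <- sapply(fiducials, function(f) {
        d <- rep(NA_real_, length(allFrames))
        d[match(f@frames, allFrames)] <- f@positions - mean(f@positions)
        d
    })
    drift <- apply(as.matrix(disp), 1, median, na.rm = TRUE)
    if (all(is.na(drift))) stop("fiducials cover no frames")
    if (any(is.na(drift))) {
        ok <- !is.na(drift)
        drift <- approx(allFrames[ok], drift[ok], xout = allFrames,
                        rule = 2)$y
    }
    lapply(trajectories, function(tr) {
        tr@positions <- tr@positions - drift[match(tr@frames, allFrames)]
        tr
    })
}

# least-squares 1-D Gaussian refinement in a +/- `win` px window around a
# candidate maximum; falls back to the intensity-weighted centroid when the
# nonlinear fit fails. Pixel coordinates are 0-based (pixel i -> i - 1).
.refinePeak <- function(v, idx, win = 4) {
    lo <- max(1, idx - win); hi <- min(length(v), idx + win)
    px <- (lo:hi) - 1
    vv <- v[lo:hi]
    base <- min(vv)
    fit <- tryCatch({
        df <- data.frame(px = px, vv = vv)
        start <- list(A = max(vv) - base, mu = idx - 1, s = 1.2, c = base)
        f <- suppressWarnings(
            nls(vv ~ A * exp(-(px - mu)^2 / (2 * s^2)) + c,
                data = df, start = start,
                control = list(warnOnly = TRUE, maxiter = 100)))
        co <- coef(f)
        list(mu = unname(co["mu"]), sigma = abs(unname(co["s"])))
    }, error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$mu) ||
        abs(fit$mu - (idx - 1)) > win) {
        w <- pmax(vv - base, 0)
        fit <- list(mu = sum(px * w) / max(sum(w), .Machine$double.eps),
                    sigma = NA_real_)
    }
    fit
}

#' Detect peaks in one kymograph frame
#'
#' Local maxima exceeding the background by `snrThreshold` times the robust
#' noise SD (median absolute deviation x 1.4826) are refined by a
#' least-squares 1-D Gaussian fit in a +/- 4 px window. Positions are
#' subpixel, in 0-based pixel coordinates.
#'
#' @param image a [KymographImage-class]
#' @param frame frame index (1-based column)
#' @param snrThreshold detection threshold in noise SDs
#' @return data.frame with columns `frame`, `position` (px), `intensity`
#'   (background-subtracted, via [integrateIntensity()]), `background`,
#'   `fitSigma`; zero rows when nothing is found
#' @export
findPeaks <- function(image, frame, snrThreshold = 5) {
    v <- image@data[, frame]
    n <- length(v)
    bg <- median(v)
    noise <- robustSd(v)
    thr <- bg + snrThreshold * max(noise, .Machine$double.eps)
    isMax <- c(FALSE, diff(v) > 0) & c(diff(v) < 0, FALSE) |
        (v == max(v) & seq_len(n) == which.max(v))
    cand <- which(isMax & v > thr)
    if (!length(cand))
        return(data.frame(frame = integer(), position = numeric(),
            intensity = numeric(), background = numeric(),
            fitSigma = numeric()))
    rows <- lapply(cand, function(idx) {
        fit <- .refinePeak(v, idx)
        ii <- integrateIntensity(image, frame, fit$mu)
        data.frame(frame = frame, position = fit$mu,
            intensity = ii$intensity, background = ii$background,
            fitSigma = fit$sigma)
    })
    do.call(rbind, rows)
}

#' Integrate spot intensity with annulus background subtraction
#'
#' Sums pixels within the inner radius (2 px) of the given position and
#' subtracts the median of the surrounding annulus (2 to 4 px) times the
#' inner pixel count, on the 1-D position axis. Positions closer than 4 px
#' to the image edge are integrated over the clipped windows and flagged.
#'
#' @param image a [KymographImage-class]
#' @param frame frame index (1-based)
#' @param position spot position (px, 0-based)
#' @param innerRadius,outerRadius integration radii (px)
#' @return list with `intensity` (clamped at 0, flagged when negative),
#'   `background` (per-pixel), `clipped`, `clamped`
#' @export
integrateIntensity <- function(image, frame, position, innerRadius = 2,
                               outerRadius = 4) {
    v <- image@data[, frame]
    n <- length(v)
    px <- seq_len(n) - 1
    d <- abs(px - position)
    inner <- d <= innerRadius
    annulus <- d > innerRadius & d <= outerRadius
    clipped <- position < outerRadius || position > n - 1 - outerRadius
    bg <- if (any(annulus)) median(v[annulus]) else 0
    raw <- sum(v[inner]) - bg * sum(inner)
    list(intensity = max(raw, 0), background = bg, clipped = clipped,
         clamped = raw < 0)
}

#' Link per-frame peaks into trajectories
#'
#' Greedy nearest-neighbor linking: within each frame, candidate
#' peak-to-track assignments are made in order of increasing distance; a
#' peak joins the track whose last position is nearest and within
#' `maxJump * (gap + 1)`, gaps up to `maxGap` frames are bridged, and
#' unmatched peaks seed new tracks. Ties are broken deterministically by
#' smaller position. Peak positions (px) are converted to kb via the pixel
#' scale.
#'
#' @param peaks data.frame of peaks (as from [findPeaks()], any number of
#'   frames), with columns `frame`, `position`, `intensity`
#' @param pixelScale kb per pixel
#' @param frameInterval s per frame
#' @param maxJump largest frame-to-frame displacement (kb)
#' @param maxGap largest bridged gap (frames)
#' @param channel channel label for the output
#' @return list of [Trajectory-class]
#' @export
linkPeaks <- function(peaks, pixelScale = 0.175, frameInterval = 5,
                      maxJump = 0.5, maxGap = 1, channel = "default") {
    if (!nrow(peaks)) return(list())
    peaks <- peaks[order(peaks$frame, peaks$position), ]
    tracks <- list()    # each: frames, pos (kb), ints, lastFrame, lastPos
    active <- integer()
    for (f in sort(unique(peaks$frame))) {
        sel <- peaks$frame == f
        pPos <- peaks$position[sel] * pixelScale
        pInt <- peaks$intensity[sel]
        active <- active[vapply(active, function(ti)
            f - tracks[[ti]]$lastFrame - 1 <= maxGap, logical(1))]
        assignedTrack <- rep(NA_integer_, length(pPos))
        if (length(active)) {
            cand <- expand.grid(pi = seq_along(pPos), ti = active)
            cand$gap <- f - vapply(cand$ti, function(ti)
                tracks[[ti]]$lastFrame, numeric(1))
            cand$d <- abs(pPos[cand$pi] - vapply(cand$ti, function(ti)
                tracks[[ti]]$lastPos, numeric(1)))
            cand <- cand[cand$d <= maxJump * cand$gap, ]
            cand <- cand[order(cand$d, pPos[cand$pi]), ]
            usedT <- integer()
            for (r in seq_len(nrow(cand))) {
                pi <- cand$pi[r]; ti <- cand$ti[r]
                if (!is.na(assignedTrack[pi]) || ti %in% usedT) next
                assignedTrack[pi] <- ti; usedT <- c(usedT, ti)
            }
        }
        for (k in seq_along(pPos)) {
            ti <- assignedTrack[k]
            if (is.na(ti)) {
                tracks[[length(tracks) + 1]] <- list(frames = f,
                    pos = pPos[k], ints = pInt[k], lastFrame = f,
                    lastPos = pPos[k])
                active <- c(active, length(tracks))
            } else {
                tr <- tracks[[ti]]
                tr$frames <- c(tr$frames, f); tr$pos <- c(tr$pos, pPos[k])
                tr$ints <- c(tr$ints, pInt[k])
                tr$lastFrame <- f; tr$lastPos <- pPos[k]
                tracks[[ti]] <- tr
            }
        }
    }
    lapply(seq_along(tracks), function(i) {
        tr <- tracks[[i]]
        trajectory(sprintf("track%03d", i), positions = tr$pos,
            times = (tr$frames - 1) * frameInterval, frames = tr$frames,
            intensities = tr$ints, channel = channel)
    })
}

#' Track a kymograph end to end
#'
#' Convenience wrapper: peak detection on every frame, intensity
#' integration, and nearest-neighbor linking.
#'
#' @param image a [KymographImage-class]
#' @param snrThreshold detection threshold in noise SDs
#' @param maxJump,maxGap linking parameters (see [linkPeaks()])
#' @return list of [Trajectory-class]
#' @export
trackKymograph <- function(image, snrThreshold = 5, maxJump = 0.5,
                           maxGap = 1) {
    pk <- do.call(rbind, lapply(seq_len(ncol(image@data)), function(f)
        findPeaks(image, f, snrThreshold)))
    if (is.null(pk) || !nrow(pk)) return(list())
    linkPeaks(pk, pixelScale = image@pixelScale,
        frameInterval = image@frameInterval, maxJump = maxJump,
        maxGap = maxGap, channel = image@channel)
}

#' Fit a dye half-life to per-frame peak counts
#'
#' Nonlinear least squares of the dye-survival model
#' `y = a * 0.5^(x / b)` to the number of detected fluorescent peaks per
#' frame, where `b` is the frame at which half the dyes have bleached.
#' `x` counts frames from 0 at the first frame.
#'
#' @param countsPerFrame non-negative integer vector, length >= 5
#' @return list with `a`, `b` (frames), `residualRms`, and `nonBleaching`
#'   (TRUE when the fitted half-life exceeds 10x the trace length)
#' @examples
#' fitHalfLife(100 * 0.5^((0:499) / 290))
#' @export
fitHalfLife <- function(countsPerFrame) {
    y <- as.numeric(countsPerFrame)
    if (length(y) < 5) stop("need at least 5 frames")
    if (any(y < 0)) stop("counts must be non-negative")
    if (all(y == 0)) stop("fit failure: all counts are zero")
    x <- seq_along(y) - 1
    n <- length(y)
    # log-linear initialization on the positive counts
    pos <- y > 0
    b0 <- tryCatch({
        sl <- coef(lm(log(y[pos]) ~ x[pos]))[2]
        if (sl < 0) -log(2) / sl else 10 * n
    }, error = function(e) n / 2)
    b0 <- min(max(b0, 1), 100 * n)
    if (b0 >= 10 * n)   # no measurable decay: flag instead of fitting
        return(list(a = mean(y), b = b0, residualRms = sd(y),
                    nonBleaching = TRUE))
    df <- data.frame(x = x, y = y)
    fit <- tryCatch(
        nls(y ~ a * 0.5^(x / b), data = df,
            start = list(a = max(y), b = b0),
            control = list(maxiter = 200)),
        error = function(e)
            minpack.lm::nlsLM(y ~ a * 0.5^(x / b), data = df,
                start = list(a = max(y), b = b0),
                control = minpack.lm::nls.lm.control(maxiter = 200)))
    co <- coef(fit)
    rms <- sqrt(mean(residuals(fit)^2))
    list(a = unname(co["a"]), b = unname(co["b"]), residualRms = rms,
         nonBleaching = unname(co["b"]) > 10 * n)
}

#' Colocalization intervals of two trajectories
#'
#' Maximal time intervals over the common frames where the two molecules
#' are within `tolerance` of each other.
#'
#' @param trajA,trajB [Trajectory-class] objects
#' @param tolerance distance threshold (kb)
#' @return data.frame with columns `tStart`, `tEnd` (s); zero rows when the
#'   frame ranges are disjoint or the molecules never colocalize
#' @export
colocalize <- function(trajA, trajB, tolerance = 0.5) {
    common <- intersect(trajA@frames, trajB@frames)
    empty <- data.frame(tStart = numeric(), tEnd = numeric())
    if (!length(common)) return(empty)
    ia <- match(common, trajA@frames); ib <- match(common, trajB@frames)
    near <- abs(trajA@positions[ia] - trajB@positions[ib]) <= tolerance
    if (!any(near)) return(empty)
    r <- rle(near)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- r$values
    data.frame(tStart = trajA@times[ia][starts[keep]],
               tEnd = trajA@times[ia][ends[keep]])
}
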