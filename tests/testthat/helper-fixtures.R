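# Build a linear-mode SegmentTable directly from per-segment slopes (nt/s),
# durations (s) and optional positions (kb), bypassing the change-point fit.
makeSegTable <- function(slopes, durations, slopeSd = 0, positions = NULL,
                         molecule = "m1") {
    k <- length(slopes)
    tS <- cumsum(c(0, utils::head(durations, -1)))
    tE <- tS + durations
    if (is.null(positions)) positions <- rep(10, k)
    segs <- data.frame(tStart = tS, tEnd = tE, duration = durations,
        slope = slopes, slopeSd = rep_len(slopeSd, k), intercept = 0,
        positionStart = positions, positionMid = positions,
        meanLevel = positions, isPause = FALSE, excluded = FALSE,
        segIndex = seq_len(k))
    methods::new("SegmentTable", moleculeId = molecule, segments = segs,
        breakpoints = tE[-k], mode = "linear")
}

# Exhaustive least-squares oracle: minimize total RSS of per-segment lines
# over all placements of exactly k interior breakpoints (independent of the
# package's search; plain lm per segment).
oracleSegRss <- function(x, y, i, j) {
    if (j - i < 1) return(0)
    xs <- x[i:j]; ys <- y[i:j]
    sum(stats::residuals(stats::lm(ys ~ xs))^2)
}

oracleBestBreaks <- function(x, y, k, minSeg = 3) {
    n <- length(y)
    cand <- seq(minSeg, n - minSeg)
    combos <- if (k == 1) matrix(cand, nrow = 1) else utils::combn(cand, k)
    best <- NULL; bestR <- Inf
    for (cc in seq_len(ncol(combos))) {
        b <- combos[, cc]
        if (any(diff(c(0, b, n)) < minSeg)) next
        bounds <- c(0, b, n)
        r <- 0
        for (s in seq_len(length(bounds) - 1))
            r <- r + oracleSegRss(x, y, bounds[s] + 1, bounds[s + 1])
        if (r < bestR - 1e-12) { bestR <- r; best <- b }
    }
    list(breaks = best, rss = bestR)
}

# interior breakpoint indices of a SegmentTable (last sample of each segment)
breakIndices <- function(tab, times) {
    bp <- breakpoints(tab)
    vapply(bp, function(b) max(which(times < b)), integer(1))
}

# total per-segment linear RSS of a SegmentTable's breakpoints on (x, y)
tableRss <- function(tab, x, y) {
    idx <- breakIndices(tab, x)
    bounds <- c(0, idx, length(y))
    r <- 0
    for (s in seq_len(length(bounds) - 1))
        r <- r + oracleSegRss(x, y, bounds[s] + 1, bounds[s + 1])
    r
}

# a noiseless, pause-free, fixed-velocity variant of a preset
noiselessPreset <- function(name = "ATP", velocity = 57) {
    p <- kymoPreset(name)
    p@burstVelocityMean <- velocity
    p@burstVelocitySd <- 1e-9
    p@pauseRate <- 0
    p@localizationNoiseSd <- 0
    p@intensityNoiseSd <- 0
    p
}

# degenerate-outcome collision preset
outcomePreset <- function(outcome, noiseless = TRUE) {
    p <- kymoPreset("ORC_collision")
    probs <- setNames(rep(0, 6), names(p@outcomeProbs))
    probs[outcome] <- 1
    p@outcomeProbs <- probs
    if (noiseless) {
        p@localizationNoiseSd <- 0
        p@intensityNoiseSd <- 0
    }
    p
}
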