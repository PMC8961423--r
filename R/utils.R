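# Evaluate expr under a local RNG stream; the caller's .Random.seed is
# untouched. All generator entry points funnel randomness through this.
withSeed <- function(seed, expr) {
    if (!is.null(seed) && !is.na(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        set.seed(as.integer(seed))
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
    }
    force(expr)
}

# Piecewise-linear position model: nodes (t, x); evaluated at arbitrary times.
evalPiecewise <- function(nodeT, nodeX, t) {
    stats::approx(nodeT, nodeX, xout = t, rule = 2, ties = "ordered")$y
}

# robust noise SD via median absolute deviation
robustSd <- function(x) stats::mad(x, constant = 1.4826)

newTruthRecord <- function(moleculeId, trueVelocity = NA_real_,
        pauseIntervals = emptyPauseIntervals(), trueOutcome = NA_character_,
        trueDiffusion = NA_real_, trueStepCount = NA_integer_,
        trueCopyNumber = NA_integer_, bleachTimes = integer(),
        terminated = FALSE) {
    list(moleculeId = moleculeId, trueVelocity = trueVelocity,
         pauseIntervals = pauseIntervals, trueOutcome = trueOutcome,
         trueDiffusion = trueDiffusion, trueStepCount = trueStepCount,
         trueCopyNumber = trueCopyNumber, bleachTimes = bleachTimes,
         terminated = terminated)
}

emptyPauseIntervals <- function() {
    data.frame(start = numeric(), end = numeric(), type = character(),
               position = numeric(), stringsAsFactors = FALSE)
}
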