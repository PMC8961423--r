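#' Time-averaged mean squared displacement
#'
#' MSD(tau) averaged over all pairs of samples separated by lag tau, for
#' lags up to `maxLagFraction` of the trace length. Requires uniform
#' sampling.
#'
#' @param traj a [Trajectory-class] with >= 10 frames
#' @param maxLagFraction largest lag as a fraction of the trace length
#' @return list with `lags` (s), `msd` (kbp^2) and `nPairs`
#' @examples
#' sim <- simulateDiffusionTrace(10, 100, 0.5, seed = 1)
#' head(computeMsd(sim$trajectory)$msd)
#' @export
computeMsd <- function(traj, maxLagFraction = 0.25) {
    x <- traj@positions; tt <- traj@times
    n <- length(x)
    if (n < 10) stop("need at least 10 frames for an MSD curve")
    dts <- diff(tt)
    if (max(abs(dts - dts[1])) > 1e-6 * dts[1])
        stop("non-uniform sampling: resample the trajectory to a fixed frame interval")
    maxLag <- max(1, floor(maxLagFraction * n))
    lags <- seq_len(maxLag)
    msd <- vapply(lags, function(k) mean((x[(k + 1):n] - x[1:(n - k)])^2),
                  numeric(1))
    list(lags = lags * dts[1], msd = msd, nPairs = n - lags)
}

#' Diffusion coefficient from an MSD curve
#'
#' Least-squares line through the origin over the first `nFitLags` MSD
#' points; for 1-D diffusion MSD(tau) = 2 D tau, so D is half the fitted
#' slope. A negative slope is clamped to D = 0 and flagged.
#'
#' @param curve result of [computeMsd()]
#' @param nFitLags number of lags used (>= 2)
#' @return list with `D` (kbp^2/s), `fitLagsUsed`, `rSquared`, `clamped`
#' @examples
#' estimateDiffusionCoefficient(list(lags = 1:4, msd = 2 * 19.4 * (1:4)))
#' @export
estimateDiffusionCoefficient <- function(curve, nFitLags = 4) {
    if (nFitLags < 2 || nFitLags > length(curve$lags))
        stop("nFitLags must be >= 2 and <= the curve length")
    tau <- curve$lags[seq_len(nFitLags)]
    m <- curve$msd[seq_len(nFitLags)]
    slope <- sum(m * tau) / sum(tau^2)
    ssTot <- sum(m^2)
    r2 <- if (ssTot > 0) 1 - sum((m - slope * tau)^2) / ssTot else NA_real_
    clamped <- slope < 0
    list(D = max(slope, 0) / 2, fitLagsUsed = nFitLags, rSquared = r2,
         clamped = clamped)
}

#' Population variance
#'
#' Variance with divisor N (the population convention):
#' sigma^2 = sum((x_i - mu)^2) / N.
#'
#' @param xs numeric vector, length >= 1
#' @return variance (units^2)
#' @examples
#' populationVariance(c(1, 2, 3))   # 2/3
#' @export
populationVariance <- function(xs) {
    if (!length(xs)) stop("empty input")
    mean((xs - mean(xs))^2)
}

#' Bootstrap standard error of the mean
#'
#' SD of the means of `cycles` resamples with replacement (default 10,000
#' cycles), seeded and reproducible.
#'
#' @param values numeric vector, length >= 2
#' @param cycles number of bootstrap resamples
#' @param seed integer seed
#' @return list with `mean`, `sem`, `cycles`
#' @examples
#' bootstrapSem(rnorm(50), cycles = 1000, seed = 1)
#' @export
bootstrapSem <- function(values, cycles = 10000, seed = NA) {
    n <- length(values)
    if (n < 2) stop("need at least 2 values")
    withSeed(seed, {
        idx <- sample.int(n, n * cycles, replace = TRUE)
        means <- colMeans(matrix(values[idx], nrow = n))
        list(mean = mean(values), sem = sd(means), cycles = cycles)
    })
}

#' Pearson correlation
#'
#' Product-moment correlation between two equal-length vectors. Zero
#' variance in either input yields NA with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return correlation in [-1, 1]
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y) || length(x) < 3)
        stop("x and y must have equal length >= 3")
    if (sd(x) == 0 || sd(y) == 0) {
        warning("zero variance: correlation undefined")
        return(NA_real_)
    }
    cor(x, y, method = "pearson")
}

#' Kernel density estimate of binding positions
#'
#' Gaussian-kernel density of positions on DNA over a regular grid spanning
#' `[0, dnaLength]`, renormalized to integrate to 1 over the grid.
#'
#' @param positions positions (kb), length >= 2
#' @param bandwidth kernel SD (kb); default Silverman's rule
#' @param dnaLength grid upper bound (kb)
#' @param gridSize number of grid points
#' @return list with `grid` (kb), `density` (1/kb), `bandwidth`
#' @examples
#' kd <- kdePositions(rnorm(200, 5.5, 0.3))
#' kd$grid[which.max(kd$density)]
#' @export
kdePositions <- function(positions, bandwidth = NULL, dnaLength = 21,
                         gridSize = 512) {
    if (length(positions) < 2) stop("need at least 2 positions")
    if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(positions)
    if (bandwidth <= 0) stop("bandwidth must be > 0")
    d <- density(positions, bw = bandwidth, from = 0, to = dnaLength,
                 n = gridSize)
    step <- d$x[2] - d$x[1]
    dens <- d$y / (sum(d$y) * step)   # renormalize over the grid
    list(grid = d$x, density = dens, bandwidth = bandwidth)
}
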