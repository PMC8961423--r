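# Canonical table formats: trajectories and ground truth as CSV, presets as
# YAML, kymographs as single-channel TIFF with a JSON metadata sidecar.

TRAJ_COLUMNS <- c("molecule_id", "channel", "frame", "time_s",
                  "position_kb", "intensity")

#' Write trajectories to the canonical CSV
#'
#' Columns: molecule_id, channel, frame, time_s, position_kb, intensity,
#' condition.
#'
#' @param trajectories list of [Trajectory-class]
#' @param path output CSV path
#' @export
writeTrajectories <- function(trajectories, path) {
    df <- do.call(rbind, lapply(trajectories, function(tr)
        data.frame(molecule_id = tr@moleculeId, channel = tr@channel,
            frame = tr@frames, time_s = tr@times,
            position_kb = tr@positions, intensity = tr@intensities,
            condition = tr@condition, stringsAsFactors = FALSE)))
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Read trajectories from the canonical CSV
#'
#' Validates the schema strictly (required columns, unique and monotone
#' frames per molecule, strictly increasing times) and reports offending
#' rows; rows are sorted by (molecule_id, frame).
#'
#' @param path CSV path
#' @return list of [Trajectory-class]
#' @export
readTrajectories <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    missing <- setdiff(TRAJ_COLUMNS, names(df))
    if (length(missing))
        stop("missing required column(s): ", paste(missing, collapse = ", "))
    df <- df[order(df$molecule_id, df$frame), ]
    if (!"condition" %in% names(df)) df$condition <- "none"
    lapply(split(df, df$molecule_id), function(d) {
        dup <- duplicated(d$frame)
        if (any(dup))
            stop(sprintf("duplicate frame %d for molecule '%s' (row %d)",
                d$frame[dup][1], d$molecule_id[1], which(dup)[1]))
        if (nrow(d) > 1 && any(diff(d$time_s) <= 0))
            stop(sprintf("non-monotone time for molecule '%s' at row %d",
                d$molecule_id[1], which(diff(d$time_s) <= 0)[1] + 1))
        trajectory(d$molecule_id[1], positions = d$position_kb,
            times = d$time_s, frames = d$frame,
            intensities = d$intensity, channel = d$channel[1],
            condition = d$condition[1])
    })
}

#' Write a segment table CSV
#'
#' @param tables list of [SegmentTable-class] (or a single table)
#' @param path output CSV path
#' @export
writeSegmentTable <- function(tables, path) {
    if (is(tables, "SegmentTable")) tables <- list(tables)
    df <- do.call(rbind, lapply(tables, function(tb) {
        s <- tb@segments
        data.frame(molecule_id = tb@moleculeId, seg_index = seq_len(nrow(s)),
            t_start_s = s$tStart, t_end_s = s$tEnd,
            slope_nt_s = s$slope, slope_sd_nt_s = s$slopeSd,
            mean_level = s$meanLevel, position_mid_kb = s$positionMid,
            is_pause = s$isPause, excluded = s$excluded, mode = tb@mode,
            stringsAsFactors = FALSE)
    }))
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Write a simulation preset as YAML
#'
#' @param preset a [SimulationPreset-class]
#' @param path output YAML path
#' @export
writePreset <- function(preset, path) {
    lay <- preset@layout
    yaml::write_yaml(list(
        name = preset@name,
        burst_velocity_mean = preset@burstVelocityMean,
        burst_velocity_sd = preset@burstVelocitySd,
        pause_rate = preset@pauseRate,
        pause_recovery_prob = preset@pauseRecoveryProb,
        pause_duration_offset = preset@pauseDurationOffset,
        pause_duration_mean_excess = preset@pauseDurationMeanExcess,
        outcome_probs = as.list(preset@outcomeProbs),
        diffusion_coeff = preset@diffusionCoeff,
        termination_prob = preset@terminationProb,
        frame_interval = preset@frameInterval,
        localization_noise_sd = preset@localizationNoiseSd,
        bleach_half_life = preset@bleachHalfLife,
        unit_intensity = preset@unitIntensity,
        intensity_noise_sd = preset@intensityNoiseSd,
        layout = list(length = lay@length, promoter_pos = lay@promoterPos,
            ars1_pos = lay@ars1Pos, widom601_pos = lay@widom601Pos,
            terminator_pos = lay@terminatorPos,
            terminator_present = lay@terminatorPresent)), path)
    invisible(path)
}

#' Read a simulation preset from YAML
#'
#' @param path YAML path
#' @return a [SimulationPreset-class]
#' @export
readPreset <- function(path) {
    y <- yaml::read_yaml(path)
    lay <- y$layout
    simulationPreset(name = y$name,
        burstVelocityMean = y$burst_velocity_mean,
        burstVelocitySd = y$burst_velocity_sd,
        pauseRate = y$pause_rate,
        pauseRecoveryProb = y$pause_recovery_prob,
        pauseDurationOffset = y$pause_duration_offset,
        pauseDurationMeanExcess = y$pause_duration_mean_excess,
        outcomeProbs = unlist(y$outcome_probs),
        diffusionCoeff = y$diffusion_coeff,
        terminationProb = y$termination_prob,
        frameInterval = y$frame_interval,
        localizationNoiseSd = y$localization_noise_sd,
        bleachHalfLife = y$bleach_half_life,
        unitIntensity = y$unit_intensity,
        intensityNoiseSd = y$intensity_noise_sd,
        layout = dnaLayout(length = lay$length,
            promoterPos = lay$promoter_pos, ars1Pos = lay$ars1_pos,
            widom601Pos = lay$widom601_pos,
            terminatorPos = lay$terminator_pos,
            terminatorPresent = lay$terminator_present))
}

#' Write a kymograph as TIFF with a JSON metadata sidecar
#'
#' The image is stored as a 32-bit float single-channel TIFF (intensities
#' rescaled to [0, 1] with the scale factor recorded in the sidecar); the
#' sidecar `<path>.json` carries pixel_scale_kb_per_px, frame_interval_s,
#' channel and intensity_scale.
#'
#' @param image a [KymographImage-class]
#' @param path output TIFF path
#' @export
writeKymographTiff <- function(image, path) {
    m <- image@data
    sc <- max(m, 1e-12)
    tiff::writeTIFF(m / sc, path, bits.per.sample = 32)
    jsonlite::write_json(list(pixel_scale_kb_per_px = image@pixelScale,
        frame_interval_s = image@frameInterval, channel = image@channel,
        intensity_scale = sc), paste0(path, ".json"), auto_unbox = TRUE,
        digits = NA)
    invisible(path)
}

#' Read a kymograph TIFF with its JSON metadata sidecar
#'
#' @param path TIFF path (sidecar `<path>.json` must exist)
#' @return a [KymographImage-class]
#' @export
readKymographTiff <- function(path) {
    side <- paste0(path, ".json")
    if (!file.exists(side)) stop("metadata sidecar not found: ", side)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    m <- tiff::readTIFF(path) * meta$intensity_scale
    kymographImage(m, pixelScale = meta$pixel_scale_kb_per_px,
        frameInterval = meta$frame_interval_s, channel = meta$channel)
}

#' Run a simulate-segment-analyze pipeline
#'
#' Executes the requested stages in order for one condition preset and
#' writes stage outputs plus a JSON report. Stages: `simulate` (trajectory
#' and truth CSVs), `segment` (segment table CSV), `transcription` (burst
#' rates, Gaussian fit, pause statistics with bootstrap SEMs). Identical
#' config and seed reproduce identical outputs.
#'
#' @param config list (or YAML path) with elements `preset` (a preset name
#'   or YAML path), `stages` (character vector), `n` (molecules), `seed`,
#'   and `outdir`
#' @return invisible list with the stage results and the report
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stages <- config$stages
    if (is.null(stages)) stages <- c("simulate", "segment", "transcription")
    known <- c("simulate", "segment", "transcription")
    if (length(setdiff(stages, known)))
        stop("unknown stage(s): ", paste(setdiff(stages, known),
             collapse = ", "))
    if ("segment" %in% stages && !"simulate" %in% stages)
        stop("stage dependency missing: 'segment' requires 'simulate'")
    if ("transcription" %in% stages && !"segment" %in% stages)
        stop("stage dependency missing: 'transcription' requires 'segment'")
    outdir <- if (is.null(config$outdir)) "." else config$outdir
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    preset <- if (is.character(config$preset) &&
                  file.exists(config$preset)) readPreset(config$preset)
              else kymoPreset(config$preset)
    n <- if (is.null(config$n)) 50 else config$n
    seed <- if (is.null(config$seed)) 1 else config$seed
    cfg <- analysisConfig()
    result <- list(config = config)

    ens <- simulateTranscriptionEnsemble(preset, n, seed = seed)
    writeTrajectories(ens$trajectories, file.path(outdir, "trajectories.csv"))
    truthDf <- do.call(rbind, lapply(ens$truths, function(tr)
        data.frame(molecule_id = tr$moleculeId,
            true_velocity_nt_s = tr$trueVelocity,
            n_pauses = nrow(tr$pauseIntervals),
            terminated = tr$terminated)))
    write.csv(truthDf, file.path(outdir, "truth.csv"), row.names = FALSE)
    result$trajectories <- ens$trajectories

    report <- list(preset = preset@name, n = n, seed = seed)
    if ("segment" %in% stages) {
        bre <- burstRateEnsemble(ens$trajectories, cfg)
        writeSegmentTable(bre$tables, file.path(outdir, "segments.csv"))
        result$tables <- bre$tables
        result$rates <- bre$rates
    }
    if ("transcription" %in% stages) {
        rates <- result$rates[is.finite(result$rates)]
        fit <- fitRateDistribution(rates)
        bs <- bootstrapSem(rates, cycles = cfg@bootstrapCycles, seed = seed)
        report$gauss_mean_nt_s <- fit$gaussMean
        report$gauss_sd_nt_s <- fit$gaussSd
        report$rate_sem_bootstrap <- bs$sem
        if (!preset@layout@terminatorPresent) {
            ps <- pauseStatistics(result$tables, cfg)
            report$pause_probability <- ps$pauseProbability
            report$pause_recovery_fraction <- ps$recoveryFraction
            report$mean_transient_pause_s <-
                if (length(ps$transientDurations))
                    mean(ps$transientDurations) else NA
        }
    }
    jsonlite::write_json(report, file.path(outdir, "report.json"),
        auto_unbox = TRUE, digits = NA, null = "null", na = "null")
    result$report <- report
    invisible(result)
}
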