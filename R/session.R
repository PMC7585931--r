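## Session orchestration: dark correction, epoching, trial averaging,
## ROI selection by the 1.5-SD rule, response magnitudes, concatenation.

#' Dark-correct intensity movies
#'
#' Subtracts the experiment's dark frame (acquired in the preceding
#' inter-experiment gap) from every frame of every wavelength movie,
#' clamping at zero; the number of clamped samples is reported.
#'
#' @param intensities list over wavelengths of frames x pixels matrices.
#' @param dark numeric pixel vector (the dark frame).
#' @return list of corrected matrices.
#' @export
darkCorrect <- function(intensities, dark) {
  if (is.null(dark)) stop("no dark frame available for this experiment")
  nClamped <- 0
  out <- lapply(intensities, function(m) {
    corr <- sweep(m, 2, dark, "-")
    nClamped <<- nClamped + sum(corr < 0)
    corr[corr < 0] <- 0
    corr
  })
  if (nClamped > 0)
    message(sprintf("darkCorrect: %d sample(s) clamped at 0", nClamped))
  out
}

#' Epoch a series or movie into stimulus-aligned trials
#'
#' Cuts one epoch per stimulus-train onset, aligned on onset, spanning
#' \code{preS} seconds before to \code{postS} seconds after. Trials whose
#' window overruns the record are excluded with a message; an error is
#' raised if no trial survives or no onset events exist.
#'
#' @param x numeric vector (series) or frames x pixels matrix (movie).
#' @param events event data.frame with stim_train_on rows.
#' @param preS,postS window extent around onset (s).
#' @param rateHz sampling rate of \code{x}.
#' @return A \linkS4class{TrialTensor}.
#' @export
epochTrials <- function(x, events, preS, postS, rateHz) {
  onsets <- events$time_s[events$kind == "stim_train_on"]
  if (!length(onsets)) stop("no stimulus-train onsets to epoch on")
  isMovie <- is.matrix(x)
  nT <- if (isMovie) nrow(x) else length(x)
  nWin <- round((preS + postS) * rateHz)
  timeAxis <- (seq_len(nWin) - 1) / rateHz - preS
  keep <- list()
  for (on in onsets) {
    i0 <- round((on - preS) * rateHz) + 1
    idx <- i0:(i0 + nWin - 1)
    if (idx[1] < 1 || idx[nWin] > nT) {
      message(sprintf("epochTrials: trial at %gs excluded (window overruns record)", on))
      next
    }
    keep[[length(keep) + 1]] <- idx
  }
  if (!length(keep)) stop("all trials excluded: windows overrun the record")
  n <- length(keep)
  if (isMovie) {
    vals <- array(NA_real_, c(n, nWin, ncol(x)))
    for (i in seq_len(n)) vals[i, , ] <- x[keep[[i]], , drop = FALSE]
  } else {
    vals <- array(NA_real_, c(n, nWin))
    for (i in seq_len(n)) vals[i, ] <- x[keep[[i]]]
  }
  new("TrialTensor", values = vals, timeAxisS = timeAxis,
      nTrials = as.integer(n))
}

setMethod("show", "TrialTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("TrialTensor: %d trials x %d time points%s, t = [%g, %g] s\n",
              d[1], d[2],
              if (length(d) == 3) sprintf(" x %d pixels", d[3]) else "",
              min(object@timeAxisS), max(object@timeAxisS)))
})

#' Trial average with per-timepoint spread
#'
#' @param tensor a \linkS4class{TrialTensor} with at least two trials.
#' @return list(mean, sd, timeAxisS, nTrials); mean and sd are vectors
#'   (series input) or time x pixels matrices (movie input).
#' @export
trialAverage <- function(tensor) {
  if (tensor@nTrials < 2)
    stop("trial SD undefined for fewer than 2 trials")
  v <- tensor@values
  n <- dim(v)[1]
  if (length(dim(v)) == 3) {
    m <- colMeans(v)                       # time x pixels
    s <- sqrt(pmax(colSums(v^2) - n * m^2, 0) / (n - 1))
  } else {
    m <- colMeans(v)
    s <- sqrt(pmax(colSums(v^2) - n * m^2, 0) / (n - 1))
  }
  list(mean = m, sd = s, timeAxisS = tensor@timeAxisS,
       nTrials = tensor@nTrials)
}

#' Select the activated whisker region of interest
#'
#' Thresholds a trial-averaged Hbt movie: a pixel enters the ROI when its
#' mean over the stimulation window exceeds its pre-stimulus mean by
#' \code{kSd} pre-stimulus standard deviations. Pixels with zero
#' pre-stimulus SD are excluded with a message; an empty result raises a
#' no-activation error.
#'
#' @param avgMovie time x pixels trial-averaged Hbt movie.
#' @param timeAxisS time axis of the movie (s, 0 = stimulus onset).
#' @param stimWindowS c(start, end) of the stimulation window (s).
#' @param prestimWindowS c(start, end) of the pre-stimulus window (s).
#' @param kSd threshold multiplier (default 1.5).
#' @param shape integer c(ny, nx) for the returned mask.
#' @param candidates optional logical vector restricting consideration
#'   (e.g. the cranial window); default all pixels.
#' @param sourceExperiment id recorded in the mask metadata.
#' @return A \linkS4class{RoiMask}.
#' @export
selectWhiskerRoi <- function(avgMovie, timeAxisS, stimWindowS,
                             prestimWindowS, kSd = 1.5,
                             shape, candidates = NULL,
                             sourceExperiment = "Exp7") {
  sIdx <- timeAxisS >= stimWindowS[1] & timeAxisS < stimWindowS[2]
  pIdx <- timeAxisS >= prestimWindowS[1] & timeAxisS < prestimWindowS[2]
  if (!any(sIdx) || !any(pIdx)) stop("empty stimulus or pre-stimulus window")
  stimMean <- colMeans(avgMovie[sIdx, , drop = FALSE])
  preMean <- colMeans(avgMovie[pIdx, , drop = FALSE])
  preSd <- apply(avgMovie[pIdx, , drop = FALSE], 2, sd)
  ok <- !is.na(preSd) & preSd > 0
  if (!is.null(candidates)) ok <- ok & candidates
  nZero <- sum(!is.na(preSd) & preSd == 0 &
               (is.null(candidates) | candidates))
  if (nZero > 0)
    message(sprintf("selectWhiskerRoi: %d zero-variance pixel(s) excluded", nZero))
  sel <- ok & (stimMean > preMean + kSd * preSd)
  if (!any(sel))
    stop("no activation: no pixel exceeded the ", kSd, "-SD threshold")
  new("RoiMask", pixels = matrix(sel, shape[1], shape[2]), kSd = kSd,
      sourceExperiment = sourceExperiment)
}

setMethod("show", "RoiMask", function(object) {
  cat(sprintf("RoiMask: %d px (k = %g SD, source %s)\n",
              sum(object@pixels), object@kSd, object@sourceExperiment))
})

#' Mean time series over a region of interest
#'
#' Unweighted mean over mask pixels per frame; missing (dead) pixels are
#' excluded from the average.
#'
#' @param movie frames x pixels matrix.
#' @param mask a \linkS4class{RoiMask} or logical vector/matrix.
#' @return numeric series.
#' @export
roiTimeseries <- function(movie, mask) {
  px <- if (is(mask, "RoiMask")) as.vector(mask@pixels) else as.vector(mask)
  if (!any(px)) stop("empty mask")
  rowMeans(movie[, px, drop = FALSE], na.rm = TRUE)
}

#' Mean response size over the stimulation window
#'
#' The single summary measure fed to the statistics stage: the mean of
#' (fractional series - 1) over the stimulation window.
#'
#' @param series fractional concentration series (1 = baseline).
#' @param timeAxisS time axis (s, 0 = stimulus onset).
#' @param stimWindowS c(start, end) of the stimulation window (s).
#' @return scalar fractional response.
#' @export
responseMagnitude <- function(series, timeAxisS, stimWindowS) {
  idx <- timeAxisS >= stimWindowS[1] & timeAxisS < stimWindowS[2]
  if (!any(idx)) stop("stimulation window outside the series")
  if (stimWindowS[1] < min(timeAxisS) || stimWindowS[2] > max(timeAxisS) + 1e-9)
    stop("stimulation window outside the series")
  mean(series[idx] - 1)
}

#' Concatenate per-experiment series into a session-long record
#'
#' Joins series in protocol order on a global session clock, marking the
#' inter-experiment gaps (dark-frame acquisition) rather than
#' interpolating across them.
#'
#' @param seriesList named list of numeric series, one per experiment, in
#'   protocol order.
#' @param protocol the protocol data.frame the session was acquired with.
#' @param rateHz common sampling rate of all series.
#' @return data.frame(time_s, value, experiment) with attribute
#'   \code{boundaries} (named start times) and \code{gap_s}.
#' @export
concatenateSession <- function(seriesList, protocol, rateHz) {
  gap <- attr(protocol, "gap_s")
  prot <- protocol[protocol$id %in% names(seriesList), , drop = FALSE]
  offsets <- cumsum(c(0, head(prot$total_length_s + gap, -1)))
  names(offsets) <- prot$id
  out <- list()
  for (id in prot$id) {
    s <- seriesList[[id]]
    expLen <- prot$total_length_s[prot$id == id]
    if (length(s) != round(expLen * rateHz))
      stop("series length of ", id, " inconsistent with protocol at ",
           rateHz, " Hz")
    out[[id]] <- data.frame(
      time_s = offsets[[id]] + (seq_along(s) - 1) / rateHz,
      value = s, experiment = id)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "boundaries") <- offsets
  attr(res, "gap_s") <- gap
  res
}

## baseline window (frame indices) for one experiment kind
baselineWindowFrames <- function(row, rateHz) {
  if (!is.na(row$n_trials)) {
    seq_len(round(row$stim_onset_s * rateHz))
  } else {
    seq_len(round(row$gas_switch_s * rateHz))
  }
}

#' Run the full analysis on a session recording
#'
#' Orchestrates dark correction, attenuation, Beer-Lambert unmixing, ROI
#' selection from the 16 s oxygen experiment, air-baseline estimation from
#' the oxygen-to-air record, per-experiment trial averages and response
#' magnitudes, vessel compartment extraction, and session concatenation.
#' Stage failures are re-raised tagged with the stage name.
#'
#' @param recording a \linkS4class{SessionRecording}.
#' @param table an \linkS4class{ExtinctionTable}.
#' @param paths a \linkS4class{PathLengthTable}.
#' @param config list of options: \code{kSd} (default 1.5),
#'   \code{roiSource} ("Exp7"), \code{vesselQuantile} (0.8),
#'   \code{assumedBaseline} (100 uM / 70\% oxygen),
#'   \code{settleWindowS} (air-baseline settle window; default the last
#'   third of the gas record), \code{keepMovies} (FALSE).
#' @return list of class "SessionResult": per-experiment series, trial
#'   averages, magnitudes, ROI, air baseline, compartments, concatenated
#'   record, and a stage log.
#' @export
runSession <- function(recording, table, paths, config = list()) {
  cfg <- modifyList(list(kSd = 1.5, roiSource = "Exp7",
                         vesselQuantile = 0.8,
                         assumedBaseline = baselineState(100, 0.70, "oxygen"),
                         settleWindowS = NULL, keepMovies = FALSE),
                    config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  prot <- recording@protocol
  prot <- prot[prot$id %in% names(recording@experiments), , drop = FALSE]
  rate <- recording@meta$frame_rate_hz
  shape <- recording@meta$shape
  log <- character()

  ## one experiment's movies in memory at a time
  unmixExperiment <- function(id) {
    row <- prot[prot$id == id, ]
    ex <- recording@experiments[[id]]
    corr <- stage(paste0("dark_correct[", id, "]"),
                  darkCorrect(ex$intensities, ex$dark))
    att <- stage(paste0("attenuation[", id, "]"),
                 computeAttenuation(corr, baselineWindowFrames(row, rate),
                                    recording@meta$wavelengths_nm, rate,
                                    shape))
    stage(paste0("unmix[", id, "]"),
          unmixStack(att, table, paths, cfg$assumedBaseline))
  }

  ## ROI and vessel compartments from the 16 s oxygen experiment, first
  roiId <- cfg$roiSource
  if (!roiId %in% prot$id)
    stop("stage roi: source experiment ", roiId, " missing from recording",
         call. = FALSE)
  roiRow <- prot[prot$id == roiId, ]
  cmRoiSrc <- unmixExperiment(roiId)
  roi <- stage("roi", {
    frac <- fractionalMovie(cmRoiSrc, "hbt")
    tens <- epochTrials(frac, recording@experiments[[roiId]]$events,
                        preS = roiRow$stim_onset_s,
                        postS = roiRow$trial_length_s - roiRow$stim_onset_s,
                        rateHz = rate)
    avg <- trialAverage(tens)
    selectWhiskerRoi(avg$mean, avg$timeAxisS,
                     stimWindowS = c(0, roiRow$stim_duration_s),
                     prestimWindowS = c(-roiRow$stim_onset_s, 0),
                     kSd = cfg$kSd, shape = shape,
                     sourceExperiment = roiId)
  })
  compartments <- stage("compartments", {
    ev <- recording@experiments[[roiId]]$events
    hbtAvg <- trialAverage(epochTrials(fractionalMovie(cmRoiSrc, "hbt"),
                                       ev, roiRow$stim_onset_s,
                                       roiRow$trial_length_s - roiRow$stim_onset_s,
                                       rate))
    hbrAvg <- trialAverage(epochTrials(fractionalMovie(cmRoiSrc, "hbr"),
                                       ev, roiRow$stim_onset_s,
                                       roiRow$trial_length_s - roiRow$stim_onset_s,
                                       rate))
    stimReg <- as.numeric(hbtAvg$timeAxisS >= 0 &
                          hbtAvg$timeAxisS < roiRow$stim_duration_s)
    pmHbt <- firstPrincipalMap(hbtAvg$mean, roi, stimulusRegressor = stimReg,
                               shape = shape)
    pmHbr <- firstPrincipalMap(hbrAvg$mean, roi, stimulusRegressor = stimReg,
                               shape = shape)
    masks <- vesselMasks(pmHbt, pmHbr, roi, quantile = cfg$vesselQuantile)
    list(hbtMap = pmHbt, hbrMap = pmHbr, masks = masks)
  })

  airBaseline <- NULL
  baselineFor <- function(kind) {
    if (kind %in% c("stim2s_air", "stim16s_air") && !is.null(airBaseline))
      airBaseline
    else cfg$assumedBaseline
  }

  ## protocol-order pass: ROI series, trial stats, compartment responses;
  ## the oxygen-to-air record also yields the per-session air baseline
  processExperiment <- function(id, cm) {
    row <- prot[prot$id == id, ]
    if (row$kind == "gas_to_air") {
      sw <- cfg$settleWindowS
      if (is.null(sw)) sw <- c(row$total_length_s * 2 / 3,
                               row$total_length_s)
      airBaseline <<- stage("air_baseline",
                            estimateAirBaseline(cm, cfg$assumedBaseline,
                                                sw, roi = roi))
      log <<- c(log, sprintf("air baseline: %.3g uM, SO2 %.3g",
                             hbtConc(airBaseline), airBaseline@so2))
    }
    b <- baselineFor(row$kind)
    cm@baseline <- b
    frac <- list(hbt = fractionalMovie(cm, "hbt"),
                 hbo = fractionalMovie(cm, "hbo"),
                 hbr = fractionalMovie(cm, "hbr"))
    series <- lapply(frac, roiTimeseries, mask = roi)
    res <- list(kind = row$kind, baseline = b, series = series)
    if (!is.na(row$n_trials)) {
      ev <- recording@experiments[[id]]$events
      res$trials <- lapply(series, function(s)
        epochTrials(s, ev, preS = row$stim_onset_s,
                    postS = row$trial_length_s - row$stim_onset_s,
                    rateHz = rate))
      res$average <- lapply(res$trials, trialAverage)
      res$magnitude <- vapply(res$average, function(a)
        responseMagnitude(a$mean, a$timeAxisS,
                          c(0, row$stim_duration_s)), numeric(1))
      ## compartment-mean trial-averaged responses (artery / vein)
      res$compartmentAverage <- lapply(compartments$masks, function(mk) {
        lapply(frac[c("hbt", "hbr")], function(f)
          trialAverage(epochTrials(roiTimeseries(f, mk), ev,
                                   row$stim_onset_s,
                                   row$trial_length_s - row$stim_onset_s,
                                   rate)))
      })
    }
    res
  }

  results <- list()
  concatSeries <- list()
  for (id in prot$id) {
    cm <- if (id == roiId) cmRoiSrc else unmixExperiment(id)
    if (id == roiId) cmRoiSrc <- NULL
    results[[id]] <- processExperiment(id, cm)
    concatSeries[[id]] <- results[[id]]$series$hbt
    rm(cm)
  }

  concat <- stage("concatenate",
                  concatenateSession(concatSeries, prot, rate))

  out <- list(experiments = results, roi = roi, airBaseline = airBaseline,
              compartments = compartments, concatenated = concat,
              protocol = prot, config = cfg, log = log)
  if (cfg$keepMovies) out$movies <- movies
  class(out) <- "SessionResult"
  out
}

#' @export
print.SessionResult <- function(x, ...) {
  cat("SessionResult:", length(x$experiments), "experiment(s)\n")
  cat("  ROI:", sum(x$roi@pixels), "px;")
  if (!is.null(x$airBaseline))
    cat(sprintf(" air baseline %.3g uM / %.3g;", hbtConc(x$airBaseline),
                x$airBaseline@so2))
  cat(" artery", sum(x$compartments$masks$artery@pixels), "px, vein",
      sum(x$compartments$masks$vein@pixels), "px\n")
  invisible(x)
}
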