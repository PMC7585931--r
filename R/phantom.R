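## Synthetic phantom forward model: compartmentalised cortical window,
## evoked responses, gas challenges, spreading-depression baseline
## perturbation, camera noise. Every simulated session carries its injected
## ground truth so downstream stages can be scored against truth.

#' Build a synthetic cortical-window phantom
#'
#' Draws a branching-free arterial curve and a draining vein as thick
#' curves inside a circular window mask, with parenchyma elsewhere in the
#' window and background outside; adds a circular stimulus-responsive
#' ("active") patch overlapping both vessels. Geometry is deterministic
#' given the seed (phase/curvature jitter only).
#'
#' @param shape integer c(ny, nx); at least 32 x 32.
#' @param seed integer seed for the geometry jitter.
#' @param baselineOxygen,baselineAir assumed baseline states for the two
#'   breathing conditions.
#' @param responseParams per-compartment response parameters; see
#'   \code{\link{defaultResponseParams}}.
#' @param noise list: i0 (baseline counts), shotScale, darkOffset, darkSd.
#' @param pixelUm pixel size metadata (micrometres).
#' @return A \linkS4class{Phantom}.
#' @examples
#' ph <- makePhantom(c(64, 64), seed = 1)
#' sapply(ph@masks, sum)
#' @export
makePhantom <- function(shape = c(64L, 64L), seed = 1,
                        baselineOxygen = baselineState(100, 0.70, "oxygen"),
                        baselineAir = baselineState(95, 0.62, "air"),
                        responseParams = defaultResponseParams(),
                        noise = list(i0 = 2000, shotScale = 1,
                                     darkOffset = 100, darkSd = 2),
                        pixelUm = 75) {
  shape <- as.integer(shape)
  ny <- shape[1]; nx <- shape[2]
  if (ny < 32 || nx < 32)
    stop("grid too small to place both vessels; need at least 32 x 32")
  set.seed(as.integer(seed))
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  rWin <- 0.45 * min(ny, nx)
  iy <- matrix(seq_len(ny), ny, nx)
  ix <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  window <- (iy - cy)^2 + (ix - cx)^2 <= rWin^2

  ## vessel offsets and bends are bounded so both curves always traverse
  ## the central active patch, for every seed
  halfw <- max(2, round(0.035 * nx))
  phaseA <- runif(1, 0, 2 * pi)
  phaseV <- runif(1, 0, 2 * pi)
  bendA <- runif(1, 0.03, 0.06) * nx
  bendV <- runif(1, 0.03, 0.06) * nx
  artX <- cx - 0.14 * nx + bendA * sin(2 * pi * seq_len(ny) / ny + phaseA)
  veinX <- cx + 0.14 * nx + bendV * sin(2 * pi * seq_len(ny) / ny + phaseV)
  artery <- window & abs(ix - artX[iy]) <= halfw
  vein <- window & abs(ix - veinX[iy]) <= halfw & !artery
  parenchyma <- window & !artery & !vein
  background <- !window

  rAct <- 0.30 * min(ny, nx)
  active <- (iy - cy)^2 + (ix - cx)^2 <= rAct^2
  active <- active & window

  new("Phantom", shape = shape,
      masks = list(artery = artery, vein = vein, parenchyma = parenchyma,
                   background = background),
      active = active, baselineOxygen = baselineOxygen,
      baselineAir = baselineAir, responseParams = responseParams,
      noise = noise, pixelUm = pixelUm, seed = as.numeric(seed))
}

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom %dx%d (%g um/px): artery %d, vein %d, parenchyma %d, active %d px\n",
              object@shape[1], object@shape[2], object@pixelUm,
              sum(object@masks$artery), sum(object@masks$vein),
              sum(object@masks$parenchyma), sum(object@active)))
})

#' Default per-compartment response parameters
#'
#' Gamma-variate response kernels per vascular compartment. Amplitudes are
#' micromolar changes at the plateau of a long stimulus (before scenario
#' scaling); the artery leads the vein in onset latency; deoxyhemoglobin
#' responses are negative-going with an extra lag. \code{undershootFrac}
#' is the fractional amplitude of the delayed negative lobe appended to
#' the Hbt response under the air condition only (largest in the arterial
#' compartment); under oxygen it is zero. The hypercapnia entry sets the
#' fractional Hbt gain and saturation rise of the global challenge
#' response and its ramp time constant.
#'
#' @return Nested list of parameters by compartment.
#' @export
defaultResponseParams <- function() {
  list(
    artery = list(ampHbt = 6, ampHbr = -1.5, latencyS = 0.6,
                  latencyHbrS = 1.1, kShape = 3, kScale = 0.8,
                  undershootFrac = 0.5),
    vein = list(ampHbt = 3, ampHbr = -2.5, latencyS = 1.6,
                latencyHbrS = 2.1, kShape = 3, kScale = 1.1,
                undershootFrac = 0.2),
    parenchyma = list(ampHbt = 2, ampHbr = -1.0, latencyS = 1.0,
                      latencyHbrS = 1.5, kShape = 3, kScale = 0.9,
                      undershootFrac = 0.15),
    hypercapnia = list(hbtGain = 0.15, so2Gain = 0.05, rampTauS = 15)
  )
}

## unit-area gamma kernel sampled on the frame grid, delayed by latency
gammaKernel <- function(latencyS, shape, scale, rateHz, lengthS = 40) {
  t <- seq(0, lengthS, by = 1 / rateHz)
  k <- ifelse(t > latencyS,
              dgamma(t - latencyS, shape = shape, scale = scale), 0)
  k
}

convolveDrive <- function(drive, kernel, rateHz) {
  n <- length(drive)
  y <- convolve(c(drive, numeric(length(kernel))),
                rev(c(kernel, numeric(n))), type = "open")
  y[seq_len(n)] / rateHz
}

#' Evoked compartment concentration time courses
#'
#' Convolves the stimulus train (boxcar between train-on and train-off
#' events) with per-compartment gamma-variate kernels to produce the
#' injected micromolar Hbt and Hbr changes. Under the air condition a
#' delayed negative lobe is appended to the Hbt response (post-stimulus
#' arterial undershoot); under oxygen the response is non-negative.
#' Amplitudes are scaled by the scenario's \code{evokedScale}.
#'
#' @param events event data.frame (time_s, kind, value) holding
#'   stim_train_on / stim_train_off markers.
#' @param lengthS record length (s).
#' @param rateHz frame rate.
#' @param params one compartment's entry of
#'   \code{\link{defaultResponseParams}}.
#' @param condition a \code{\link{conditionSpec}}.
#' @param breathing "oxygen" or "air".
#' @return list(dHbt, dHbr): micromolar series of length
#'   \code{lengthS * rateHz}.
#' @export
evokedTimecourse <- function(events, lengthS, rateHz, params,
                             condition = conditionSpec("wt", "chronic"),
                             breathing = c("oxygen", "air")) {
  breathing <- match.arg(breathing)
  n <- round(lengthS * rateHz)
  drive <- numeric(n)
  on <- events$time_s[events$kind == "stim_train_on"]
  off <- events$time_s[events$kind == "stim_train_off"]
  if (length(on)) {
    if (any(off > lengthS) || any(on < 0))
      stop("stimulus events outside the record")
    for (i in seq_along(on)) {
      idx <- seq(floor(on[i] * rateHz) + 1, ceiling(off[i] * rateHz))
      drive[idx] <- 1
    }
  }
  if (!any(drive > 0))
    return(list(dHbt = numeric(n), dHbr = numeric(n)))
  sc <- condition$evokedScale
  kM <- gammaKernel(params$latencyS, params$kShape, params$kScale, rateHz)
  main <- convolveDrive(drive, kM, rateHz)
  uf <- if (breathing == "air") params$undershootFrac else 0
  under <- if (uf > 0) {
    kU <- gammaKernel(params$latencyS + 2, 4, 2.2, rateHz)
    convolveDrive(drive, kU, rateHz)
  } else numeric(n)
  dHbt <- sc * params$ampHbt * (main - uf * under)
  kR <- gammaKernel(params$latencyHbrS, params$kShape, params$kScale * 1.2,
                    rateHz)
  dHbr <- sc * params$ampHbr * convolveDrive(drive, kR, rateHz)
  list(dHbt = dHbt, dHbr = dHbr)
}

#' Spreading-depression baseline multiplier
#'
#' Fractional baseline multiplier modelling recovery from a
#' spreading-depression-like event at session start: a damped cosine
#' (alternating constriction dip and dilation overshoot) relaxing
#' exponentially toward 1. Chronic scenarios return a constant 1.
#'
#' @param condition a \code{\link{conditionSpec}}.
#' @param lengthS series length (s).
#' @param rateHz sampling rate.
#' @param t0S session time of the first sample (s), so per-experiment
#'   segments of one session share a single global envelope.
#' @return numeric multiplier series.
#' @export
csdPerturbation <- function(condition, lengthS, rateHz, t0S = 0) {
  n <- round(lengthS * rateHz)
  t <- t0S + (seq_len(n) - 1) / rateHz
  if (condition$csdAmplitude == 0) return(rep(1, n))
  1 - condition$csdAmplitude * exp(-t / condition$csdTauS) *
    cos(2 * pi * t / condition$csdPeriodS)
}

## baseline (hbt, so2) trajectory for one experiment, before the
## spreading-depression multiplier and evoked additions
baselineTrajectory <- function(row, phantom, rateHz) {
  n <- round(row$total_length_s * rateHz)
  t <- (seq_len(n) - 1) / rateHz
  bo <- phantom@baselineOxygen; ba <- phantom@baselineAir
  ## first-order gas response: zero before onset, exponential saturation
  ## after it -- keeps the pre-switch baseline window exactly flat
  expRamp <- function(t0, tau) ifelse(t > t0, 1 - exp(-(t - t0) / tau), 0)
  if (row$kind %in% c("stim2s_oxygen", "stim16s_oxygen")) {
    list(hbt = rep(hbtConc(bo), n), so2 = rep(bo@so2, n))
  } else if (row$kind %in% c("stim2s_air", "stim16s_air")) {
    list(hbt = rep(hbtConc(ba), n), so2 = rep(ba@so2, n))
  } else if (row$kind == "gas_to_air") {
    s <- expRamp(row$gas_switch_s + 10, 20)
    list(hbt = hbtConc(bo) + s * (hbtConc(ba) - hbtConc(bo)),
         so2 = bo@so2 + s * (ba@so2 - bo@so2))
  } else if (row$kind == "gas_to_oxygen") {
    s <- expRamp(row$gas_switch_s + 10, 20)
    list(hbt = hbtConc(ba) + s * (hbtConc(bo) - hbtConc(ba)),
         so2 = ba@so2 + s * (bo@so2 - ba@so2))
  } else if (row$kind == "hypercapnia") {
    hp <- phantom@responseParams$hypercapnia
    tOff <- row$gas_switch_s + row$gas_duration_s
    rise <- expRamp(row$gas_switch_s, hp$rampTauS)
    s <- ifelse(t <= tOff, rise,
                (1 - exp(-row$gas_duration_s / hp$rampTauS)) *
                  exp(-(t - tOff) / hp$rampTauS))
    list(hbt = hbtConc(bo) * (1 + hp$hbtGain * s),
         so2 = pmin(1, bo@so2 + hp$so2Gain * s))
  } else stop("unknown experiment kind: ", row$kind)
}

#' Simulate a full imaging session
#'
#' Forward model: composes per-compartment concentration time courses
#' (baseline trajectory x spreading-depression multiplier + evoked
#' responses inside the active patch), maps them to per-wavelength
#' attenuation via the same modified Beer-Lambert relation the inversion
#' assumes (extinction x concentration change x mean path length), renders
#' intensities \code{I = i0 * exp(-dA)}, and adds signal-scaled Gaussian
#' shot noise plus a constant dark offset with Gaussian dark noise. Dark
#' frames and the exact event log are emitted; everything is seeded.
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param protocol protocol data.frame (\code{\link{defaultProtocol}} or
#'   \code{\link{shortProtocol}}).
#' @param condition a \code{\link{conditionSpec}}.
#' @param table an \linkS4class{ExtinctionTable}.
#' @param paths a \linkS4class{PathLengthTable}.
#' @param seed integer master seed.
#' @param frameRateHz effective per-wavelength frame rate (default 8).
#' @param noise logical; FALSE renders the noise-free forward model (and
#'   zero dark offset), used for round-trip validation.
#' @param experiments optional character vector of experiment ids to
#'   simulate (default: all).
#' @return A \linkS4class{SessionRecording}.
#' @export
simulateSession <- function(phantom, protocol, condition, table, paths,
                            seed = 1, frameRateHz = 8, noise = TRUE,
                            experiments = NULL) {
  wl <- pathWavelengths(paths)
  L <- meanPaths(paths)
  fac <- if (table@logBase == "log10") log(10) else 1
  eps <- t(vapply(wl, function(w) extinctionAt(table, w), numeric(2)))
  refHbo <- hboConc(phantom@baselineOxygen)
  refHbr <- hbrConc(phantom@baselineOxygen)

  gap <- attr(protocol, "gap_s")
  offsets <- cumsum(c(0, head(protocol$total_length_s + gap, -1)))
  names(offsets) <- protocol$id
  if (is.null(experiments)) experiments <- protocol$id

  ny <- phantom@shape[1]; nx <- phantom@shape[2]
  nPix <- ny * nx
  grpNames <- c("artery_act", "artery", "vein_act", "vein",
                "parenchyma_act", "parenchyma", "background")
  grpIdx <- integer(nPix)
  compOf <- c("artery", "artery", "vein", "vein", "parenchyma",
              "parenchyma", "background")
  actOf <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  for (gi in seq_along(grpNames)) {
    comp <- compOf[gi]
    sel <- as.vector(phantom@masks[[comp]]) &
      (as.vector(phantom@active) == actOf[gi] | comp == "background")
    grpIdx[sel] <- gi
  }

  expsOut <- list()
  truth <- list()
  for (ei in seq_len(nrow(protocol))) {
    row <- protocol[ei, ]
    if (!row$id %in% experiments) next
    set.seed(as.integer((as.numeric(seed) + 977 * ei) %% (2^31 - 1)))
    nT <- round(row$total_length_s * frameRateHz)
    events <- experimentEvents(row)
    breathing <- if (grepl("air$", row$kind) || row$kind == "stim2s_air" ||
                     row$kind == "stim16s_air") "air" else "oxygen"
    base <- baselineTrajectory(row, phantom, frameRateHz)
    m <- csdPerturbation(condition, row$total_length_s, frameRateHz,
                         t0S = offsets[[row$id]])
    evoked <- list()
    for (comp in c("artery", "vein", "parenchyma")) {
      evoked[[comp]] <- evokedTimecourse(events, row$total_length_s,
                                         frameRateHz,
                                         phantom@responseParams[[comp]],
                                         condition, breathing)
    }
    ## per-group concentration series (frames x groups)
    cHbo <- matrix(0, nT, length(grpNames))
    cHbr <- matrix(0, nT, length(grpNames))
    hbtB <- base$hbt * m
    so2B <- pmin(1, pmax(0, base$so2 * (1 - 0.5 * (1 - m))))
    for (gi in seq_along(grpNames)) {
      comp <- compOf[gi]
      if (comp == "background") next
      eHbt <- if (actOf[gi]) evoked[[comp]]$dHbt else 0
      eHbr <- if (actOf[gi]) evoked[[comp]]$dHbr else 0
      chbt <- hbtB + eHbt
      chbr <- (1 - so2B) * hbtB + eHbr
      cHbr[, gi] <- chbr
      cHbo[, gi] <- chbt - chbr
    }
    ## attenuation per wavelength per group, relative to the assumed
    ## oxygen reference state (constant offsets vanish on rebaselining)
    intens <- vector("list", length(wl))
    names(intens) <- as.character(wl)
    i0 <- phantom@noise$i0
    for (li in seq_along(wl)) {
      dAg <- matrix(0, nT, length(grpNames))
      for (gi in seq_along(grpNames)) {
        if (compOf[gi] == "background") next
        dAg[, gi] <- fac * (eps[li, "epsHbo"] * (cHbo[, gi] - refHbo) +
                            eps[li, "epsHbr"] * (cHbr[, gi] - refHbr)) *
          L[li] * 1e-6
      }
      iClean <- i0 * exp(-dAg[, grpIdx, drop = FALSE])
      if (noise) {
        iNoisy <- iClean +
          phantom@noise$shotScale * sqrt(iClean) * rnorm(length(iClean)) +
          phantom@noise$darkOffset +
          phantom@noise$darkSd * rnorm(length(iClean))
        iNoisy <- round(pmax(iNoisy, 0))   # whole camera counts
        storage.mode(iNoisy) <- "integer"
        intens[[li]] <- iNoisy
      } else {
        intens[[li]] <- iClean
      }
    }
    dark <- if (noise) {
      pmax(phantom@noise$darkOffset + phantom@noise$darkSd * rnorm(nPix), 0)
    } else numeric(nPix)
    expsOut[[row$id]] <- list(intensities = intens, dark = dark,
                              events = events, kind = row$kind,
                              breathing = breathing)
    truth[[row$id]] <- list(evoked = evoked, csd = m, baseline = base,
                            breathing = breathing)
  }
  new("SessionRecording",
      experiments = expsOut,
      protocol = protocol,
      meta = list(seed = seed, condition = condition,
                  wavelengths_nm = wl, frame_rate_hz = frameRateHz,
                  shape = phantom@shape, pixel_um = phantom@pixelUm,
                  phantom = phantom, noise = noise),
      truth = truth)
}

setMethod("show", "SessionRecording", function(object) {
  cat(sprintf("SessionRecording: %d experiment(s), %dx%d px @ %g Hz, seed %s\n",
              length(object@experiments), object@meta$shape[1],
              object@meta$shape[2], object@meta$frame_rate_hz,
              format(object@meta$seed)))
  cat("  experiments:", paste(names(object@experiments), collapse = ", "),
      "\n")
})

#' Simulate a multi-channel field potential record
#'
#' Stimulus-locked biphasic field potentials on 16 channels (100 um
#' spacing metadata) at 6 kHz, largest on the middle channels, plus
#' autoregressive low-frequency noise. Evoked amplitudes are identical
#' across scenario groups by construction (the neural null result); only
#' the noise realisation depends on the seed.
#'
#' @param protocol protocol data.frame.
#' @param condition a \code{\link{conditionSpec}}.
#' @param seed integer seed.
#' @param experimentId which stimulation experiment to render.
#' @param rateHz sampling rate (default 6000).
#' @param noiseSd noise scale (a.u.).
#' @return A \linkS4class{NeuralRecord}.
#' @export
simulateLfp <- function(protocol, condition, seed = 1,
                        experimentId = "Exp1", rateHz = 6000,
                        noiseSd = 40) {
  row <- protocol[protocol$id == experimentId, ]
  if (nrow(row) != 1) stop("unknown experiment id: ", experimentId)
  set.seed(as.integer(seed))
  nT <- round(row$total_length_s * rateHz)
  events <- experimentEvents(row)
  pulses <- events$time_s[events$kind == "stim_pulse"]
  ## biphasic impulse kernel: fast negative deflection, slower positive
  tk <- seq(0, 0.08, by = 1 / rateHz)
  kern <- -300 * exp(-((tk - 0.015) / 0.004)^2) +
    120 * exp(-((tk - 0.035) / 0.010)^2)
  chGain <- exp(-((1:16 - 5.5)^2) / (2 * 2.5^2))
  sig <- numeric(nT)
  for (p in pulses) {
    i0 <- floor(p * rateHz) + 1
    idx <- i0:min(nT, i0 + length(kern) - 1)
    sig[idx] <- sig[idx] + kern[seq_along(idx)]
  }
  samples <- matrix(0, 16, nT)
  for (ch in 1:16) {
    noise <- as.numeric(stats::filter(rnorm(nT, sd = noiseSd * 0.2),
                                      0.98, method = "recursive"))
    samples[ch, ] <- chGain[ch] * sig + noise
  }
  new("NeuralRecord", samples = samples, rateHz = rateHz,
      channelSpacingUm = 100, events = pulses)
}
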