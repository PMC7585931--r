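## Minimal electrophysiology stage: epoching and evoked field-potential
## averages over the middle cortical channels.

#' Epoch a multi-channel field potential record
#'
#' Cuts stimulus-aligned epochs around each event time. Events whose
#' window falls outside the record are excluded with a message.
#'
#' @param record a \linkS4class{NeuralRecord}.
#' @param events event times (s); default the record's stimulus pulses.
#' @param preMs,postMs window extent around each event (milliseconds).
#' @return array trials x channels x time, with attribute
#'   \code{timeAxisMs}.
#' @export
epochLfp <- function(record, events = record@events, preMs = 5,
                     postMs = 50) {
  if (!length(events)) stop("no events to epoch on")
  rate <- record@rateHz
  nT <- ncol(record@samples)
  nWin <- round((preMs + postMs) / 1000 * rate)
  keep <- list()
  for (ev in events) {
    i0 <- round((ev - preMs / 1000) * rate) + 1
    idx <- i0:(i0 + nWin - 1)
    if (idx[1] < 1 || idx[nWin] > nT) {
      message(sprintf("epochLfp: event at %gs excluded", ev))
      next
    }
    keep[[length(keep) + 1]] <- idx
  }
  if (!length(keep)) stop("all epochs excluded: windows overrun the record")
  out <- array(NA_real_, c(length(keep), nrow(record@samples), nWin))
  for (i in seq_along(keep)) out[i, , ] <- record@samples[, keep[[i]]]
  attr(out, "timeAxisMs") <- (seq_len(nWin) - 1) / rate * 1000 - preMs
  out
}

setMethod("show", "NeuralRecord", function(object) {
  cat(sprintf("NeuralRecord: %d ch x %d samples @ %g Hz (%g um spacing), %d pulses\n",
              nrow(object@samples), ncol(object@samples), object@rateHz,
              object@channelSpacingUm, length(object@events)))
})

#' Evoked field potential over a channel range
#'
#' Mean over trials, then over the requested channel subset (1-based,
#' inclusive; default the middle cortical channels 3-8).
#'
#' @param epochs trials x channels x time array from \code{\link{epochLfp}}.
#' @param channels integer channel indices (1-based).
#' @return numeric time series with the epochs' time axis attribute.
#' @export
evokedFieldPotential <- function(epochs, channels = 3:8) {
  nCh <- dim(epochs)[2]
  if (any(channels < 1) || any(channels > nCh))
    stop("channel index out of range 1..", nCh)
  trialMean <- apply(epochs[, channels, , drop = FALSE], c(2, 3), mean)
  out <- colMeans(trialMean)
  attr(out, "timeAxisMs") <- attr(epochs, "timeAxisMs")
  out
}

#' Averaged single-impulse response
#'
#' Re-epochs the record around every individual stimulus pulse of the
#' train and averages, yielding the mean response to one pulse. Windows
#' longer than the inter-pulse interval are clipped with a message.
#'
#' @param record a \linkS4class{NeuralRecord}.
#' @param pulseTimes pulse times (s); default the record's events.
#' @param preMs,postMs window around each pulse (ms).
#' @param channels channel subset for the average.
#' @return numeric time series (mean over pulses, trials and channels).
#' @export
impulseResponse <- function(record, pulseTimes = record@events,
                            preMs = 5, postMs = 50, channels = 3:8) {
  if (!length(pulseTimes)) stop("need at least one pulse per trial")
  ipi <- if (length(pulseTimes) > 1) min(diff(sort(pulseTimes))) else Inf
  if (postMs / 1000 > ipi) {
    postMs <- floor(ipi * 1000)
    message("impulseResponse: window clipped to the inter-pulse interval (",
            postMs, " ms)")
  }
  ep <- epochLfp(record, events = pulseTimes, preMs = preMs,
                 postMs = postMs)
  evokedFieldPotential(ep, channels = channels)
}
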