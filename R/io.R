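## Plain-text interchange and result persistence.

#' Write / read an event log CSV
#'
#' Interchange format: header \code{time_s,kind,value}, kinds
#' \code{stim_pulse}, \code{stim_train_on}, \code{stim_train_off},
#' \code{gas_switch}.
#'
#' @param events data.frame(time_s, kind, value).
#' @param path file path.
#' @export
writeEventLog <- function(events, path) {
  stopifnot(all(c("time_s", "kind", "value") %in% names(events)))
  write.table(events[, c("time_s", "kind", "value")], path, sep = ",",
              row.names = FALSE, quote = FALSE)
}

#' @rdname writeEventLog
#' @return \code{readEventLog}: the events data.frame.
#' @export
readEventLog <- function(path) {
  ev <- read.table(path, header = TRUE, sep = ",",
                   stringsAsFactors = FALSE)
  if (!all(c("time_s", "kind", "value") %in% names(ev)))
    stop("event log must have columns time_s, kind, value")
  ok <- c("stim_pulse", "stim_train_on", "stim_train_off", "gas_switch")
  if (!all(ev$kind %in% ok))
    stop("unknown event kind(s): ",
         paste(setdiff(unique(ev$kind), ok), collapse = ", "))
  ev[order(ev$time_s), , drop = FALSE]
}

#' Persist / restore a session result
#'
#' Saves the result bundle of \code{\link{runSession}} with R's native
#' serialisation, carrying the same logical layout (concentration series,
#' ROI mask, compartments, per-experiment statistics, configuration).
#'
#' @param result a "SessionResult" from \code{\link{runSession}}.
#' @param path file path.
#' @export
writeSessionResult <- function(result, path) {
  stopifnot(inherits(result, "SessionResult"))
  saveRDS(result, path)
}

#' @rdname writeSessionResult
#' @return \code{readSessionResult}: the restored result.
#' @export
readSessionResult <- function(path) {
  res <- readRDS(path)
  if (!inherits(res, "SessionResult")) stop("not a SessionResult file")
  res
}
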