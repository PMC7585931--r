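## Session protocol and scenario descriptors.

#' The eight-experiment imaging session protocol
#'
#' Returns the full session protocol as a data.frame of experiment
#' descriptors, in acquisition order:
#' \itemize{
#' \item Exp1/Exp2: 2 s whisker stimulation at 5 Hz under 100\% oxygen,
#'   30 trials of 25 s, stimulus 5 s after trial start (750 s each).
#' \item Exp3: gas transition oxygen to air, 750 s, switch at 105 s.
#' \item Exp4: as Exp1 but breathing air.
#' \item Exp5: 16 s stimulation at 5 Hz under air, 15 trials of 70 s,
#'   stimulus 10 s after trial start (1050 s).
#' \item Exp6: gas transition air back to oxygen, 750 s, switch at 105 s.
#' \item Exp7: as Exp5 under 100\% oxygen (1050 s).
#' \item Exp8: hypercapnia challenge, switch at 250 s, 250 s duration,
#'   250 s recovery (750 s).
#' }
#' Experiments are separated by a gap (attribute \code{gap_s}, ~3 min)
#' during which a dark frame is acquired.
#'
#' @return data.frame with columns id, kind, n_trials, trial_length_s,
#'   stim_onset_s, stim_duration_s, stim_rate_hz, gas_switch_s,
#'   gas_duration_s, total_length_s.
#' @examples
#' p <- defaultProtocol()
#' sum(p$n_trials[p$kind %in% c("stim2s_oxygen", "stim2s_air",
#'                              "stim16s_air", "stim16s_oxygen")])  # 120
#' @export
defaultProtocol <- function() {
  p <- data.frame(
    id = paste0("Exp", 1:8),
    kind = c("stim2s_oxygen", "stim2s_oxygen", "gas_to_air", "stim2s_air",
             "stim16s_air", "gas_to_oxygen", "stim16s_oxygen",
             "hypercapnia"),
    n_trials = c(30, 30, NA, 30, 15, NA, 15, NA),
    trial_length_s = c(25, 25, NA, 25, 70, NA, 70, NA),
    stim_onset_s = c(5, 5, NA, 5, 10, NA, 10, NA),
    stim_duration_s = c(2, 2, NA, 2, 16, NA, 16, NA),
    stim_rate_hz = c(5, 5, NA, 5, 5, NA, 5, NA),
    gas_switch_s = c(NA, NA, 105, NA, NA, 105, NA, 250),
    gas_duration_s = c(NA, NA, NA, NA, NA, NA, NA, 250),
    total_length_s = c(750, 750, 750, 750, 1050, 750, 1050, 750),
    stringsAsFactors = FALSE)
  attr(p, "gap_s") <- 180
  validateProtocol(p)
  p
}

#' @describeIn defaultProtocol desk-scale variant with the same structure
#'   but fewer trials and shorter gas records, for fast simulation; timing
#'   ratios (onsets, stimulus durations, rates, switch time) are unchanged.
#' @param nShort trials per 2 s-stimulation experiment.
#' @param nLong trials per 16 s-stimulation experiment.
#' @param gasLengthS length of the gas-transition records (s).
#' @param hypercapniaLengthS length of the hypercapnia record (s).
#' @export
shortProtocol <- function(nShort = 4, nLong = 3, gasLengthS = 300,
                          hypercapniaLengthS = 450) {
  p <- defaultProtocol()
  short <- p$kind %in% c("stim2s_oxygen", "stim2s_air")
  long <- p$kind %in% c("stim16s_air", "stim16s_oxygen")
  p$n_trials[short] <- nShort
  p$n_trials[long] <- nLong
  p$total_length_s[short] <- nShort * 25
  p$total_length_s[long] <- nLong * 70
  p$total_length_s[p$kind == "gas_to_air"] <- gasLengthS
  p$total_length_s[p$kind == "gas_to_oxygen"] <- gasLengthS
  hyp <- p$kind == "hypercapnia"
  p$gas_switch_s[hyp] <- min(250, hypercapniaLengthS / 3)
  p$gas_duration_s[hyp] <- p$gas_switch_s[hyp]
  p$total_length_s[hyp] <- hypercapniaLengthS
  attr(p, "gap_s") <- 30
  validateProtocol(p)
  p
}

validateProtocol <- function(p) {
  stopifnot(!anyDuplicated(p$id))
  tb <- !is.na(p$n_trials)
  if (any(p$total_length_s[tb] != p$n_trials[tb] * p$trial_length_s[tb]))
    stop("trial-based experiments must satisfy total = n_trials * trial_length")
  if (any(p$stim_onset_s[tb] + p$stim_duration_s[tb] >= p$trial_length_s[tb]))
    stop("stimulus must end before the trial does")
  invisible(p)
}

#' Stimulation event log for one experiment
#'
#' Expands a protocol row into the event table used by the simulator and
#' the epoching stage: train on/off markers and the individual stimulus
#' pulses (at \code{stim_rate_hz}) for trial experiments, or the gas switch
#' marker for gas experiments. Times are seconds from experiment start.
#'
#' @param row one row of a protocol data.frame.
#' @return data.frame time_s, kind, value.
#' @export
experimentEvents <- function(row) {
  if (!is.na(row$n_trials)) {
    ev <- list()
    for (tr in seq_len(row$n_trials)) {
      t0 <- (tr - 1) * row$trial_length_s + row$stim_onset_s
      pulses <- t0 + seq(0, by = 1 / row$stim_rate_hz,
                         length.out = row$stim_duration_s * row$stim_rate_hz)
      ev[[tr]] <- rbind(
        data.frame(time_s = t0, kind = "stim_train_on", value = tr),
        data.frame(time_s = pulses, kind = "stim_pulse", value = tr),
        data.frame(time_s = t0 + row$stim_duration_s, kind = "stim_train_off",
                   value = tr))
    }
    out <- do.call(rbind, ev)
    out[order(out$time_s), , drop = FALSE]
  } else if (!is.na(row$gas_switch_s)) {
    kinds <- if (row$kind == "hypercapnia") {
      data.frame(time_s = c(row$gas_switch_s,
                            row$gas_switch_s + row$gas_duration_s),
                 kind = "gas_switch", value = c(1, 0))
    } else {
      data.frame(time_s = row$gas_switch_s, kind = "gas_switch", value = 1)
    }
    kinds
  } else data.frame(time_s = numeric(), kind = character(),
                    value = numeric())
}

#' Scenario descriptor: group x session kind
#'
#' Encodes the simulated scenario: chronically prepared sessions have an
#' undisturbed baseline; acute sessions start during recovery from a
#' spreading-depression-like perturbation of baseline hemodynamics caused
#' by electrode insertion, larger in the Alzheimer-like ("ad") group, with
#' evoked responses scaled down relative to chronic sessions (more so for
#' "ad"). Chronic evoked responses are identical across groups.
#'
#' @param group "wt" (wild-type-like) or "ad" (Alzheimer-like).
#' @param sessionKind "chronic" or "acute".
#' @param csdAmplitude fractional initial baseline dip; defaults 0
#'   (chronic), 0.06 (acute wt), 0.12 (acute ad).
#' @param csdTauS exponential recovery time constant (s).
#' @param csdPeriodS oscillation period of the alternating
#'   constriction/dilation (s).
#' @param evokedScale multiplier on evoked response amplitudes; defaults 1
#'   (chronic), 0.7 (acute wt), 0.45 (acute ad).
#' @return list with the scenario parameters (class "ConditionSpec").
#' @export
conditionSpec <- function(group = c("wt", "ad"),
                          sessionKind = c("chronic", "acute"),
                          csdAmplitude = NULL, csdTauS = 1200,
                          csdPeriodS = 400, evokedScale = NULL) {
  group <- match.arg(group)
  sessionKind <- match.arg(sessionKind)
  if (is.null(csdAmplitude))
    csdAmplitude <- if (sessionKind == "chronic") 0
                    else if (group == "ad") 0.12 else 0.06
  if (is.null(evokedScale))
    evokedScale <- if (sessionKind == "chronic") 1
                   else if (group == "ad") 0.45 else 0.7
  if (sessionKind == "chronic" && csdAmplitude != 0)
    stop("chronic sessions have no spreading-depression perturbation")
  structure(list(group = group, sessionKind = sessionKind,
                 csdAmplitude = csdAmplitude, csdTauS = csdTauS,
                 csdPeriodS = csdPeriodS, evokedScale = evokedScale),
            class = "ConditionSpec")
}
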