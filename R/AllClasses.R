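## Central S4 data objects. Validity methods enforce the physical and
## bookkeeping invariants each container promises to downstream stages.

#' Hemoglobin extinction spectra
#'
#' Wavelength-indexed molar extinction coefficients of oxy- and
#' deoxyhemoglobin (cm^-1 M^-1). The \code{logBase} slot records whether the
#' tabulated values follow the base-10 ("log10") or natural-log ("ln")
#' convention; absorption coefficients for photon transport are always
#' returned in natural-log units.
#'
#' @slot wavelength numeric, strictly increasing wavelengths (nm).
#' @slot epsHbo numeric, oxyhemoglobin extinction per wavelength.
#' @slot epsHbr numeric, deoxyhemoglobin extinction per wavelength.
#' @slot logBase character, "log10" or "ln".
#' @slot source character, provenance note for the bundled table.
#' @exportClass ExtinctionTable
setClass("ExtinctionTable",
  representation(wavelength = "numeric", epsHbo = "numeric",
                 epsHbr = "numeric", logBase = "character",
                 source = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@wavelength)
    if (length(object@epsHbo) != n || length(object@epsHbr) != n)
      msg <- c(msg, "wavelength, epsHbo, epsHbr must have equal length")
    if (n < 2) msg <- c(msg, "need at least two tabulated wavelengths")
    if (any(object@wavelength <= 0)) msg <- c(msg, "wavelengths must be > 0")
    if (n >= 2 && any(diff(object@wavelength) <= 0))
      msg <- c(msg, "wavelengths must be strictly increasing")
    if (any(object@epsHbo <= 0) || any(object@epsHbr <= 0))
      msg <- c(msg, "extinction values must be > 0")
    if (!object@logBase %in% c("log10", "ln"))
      msg <- c(msg, "logBase must be 'log10' or 'ln'")
    if (length(msg)) msg else TRUE
  })

#' Bulk tissue optical properties
#'
#' @slot muA absorption coefficient (cm^-1, natural log).
#' @slot muS scattering coefficient (cm^-1).
#' @slot g scattering anisotropy (mean cosine, -1 < g < 1).
#' @slot n refractive index.
#' @exportClass OpticalProperties
setClass("OpticalProperties",
  representation(muA = "numeric", muS = "numeric", g = "numeric",
                 n = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@muA < 0) msg <- c(msg, "muA must be >= 0")
    if (object@muS <= 0) msg <- c(msg, "muS must be > 0")
    if (object@g <= -1 || object@g >= 1) msg <- c(msg, "g must be in (-1, 1)")
    if (object@n < 1) msg <- c(msg, "n must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Assumed baseline tissue hemodynamic state
#'
#' Total hemoglobin concentration and oxygen saturation assumed (or
#' estimated) for a breathing condition. The derived oxy/deoxy components
#' always sum exactly to the total.
#'
#' @slot hbtuM total hemoglobin (micromolar).
#' @slot so2 oxygen saturation, fraction in 0..1.
#' @slot condition breathing condition label, e.g. "oxygen" or "air".
#' @exportClass BaselineState
setClass("BaselineState",
  representation(hbtuM = "numeric", so2 = "numeric", condition = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@hbtuM) != 1 || object@hbtuM < 0)
      msg <- c(msg, "hbtuM must be a single value >= 0")
    if (length(object@so2) != 1 || object@so2 < 0 || object@so2 > 1)
      msg <- c(msg, "so2 must be a single value in 0..1")
    if (length(msg)) msg else TRUE
  })

#' Monte-Carlo path length estimate at one wavelength
#'
#' @slot wavelength nm.
#' @slot meanPathCm weight-weighted mean total path of remitted photons (cm).
#' @slot sePathCm Monte-Carlo standard error of the mean path (cm).
#' @slot nLaunched,nDetected photon counts.
#' @slot seed integer seed used for this wavelength.
#' @exportClass PathLengthEstimate
setClass("PathLengthEstimate",
  representation(wavelength = "numeric", meanPathCm = "numeric",
                 sePathCm = "numeric", nLaunched = "numeric",
                 nDetected = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nDetected > object@nLaunched)
      msg <- c(msg, "nDetected cannot exceed nLaunched")
    if (object@nDetected > 0 && object@meanPathCm <= 0)
      msg <- c(msg, "meanPathCm must be > 0 when photons were detected")
    if (object@sePathCm < 0) msg <- c(msg, "sePathCm must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Per-wavelength path length table for one baseline state
#'
#' @slot estimates list of \linkS4class{PathLengthEstimate}, one per imaging
#'   wavelength.
#' @slot baseline the \linkS4class{BaselineState} the absorption was derived
#'   from.
#' @exportClass PathLengthTable
setClass("PathLengthTable",
  representation(estimates = "list", baseline = "BaselineState"),
  validity = function(object) {
    ok <- vapply(object@estimates, is, logical(1), class2 = "PathLengthEstimate")
    if (!all(ok)) return("all estimates must be PathLengthEstimate objects")
    wl <- vapply(object@estimates, function(e) e@wavelength, numeric(1))
    if (anyDuplicated(wl)) return("duplicate wavelengths in table")
    TRUE
  })

#' Synthetic cortical window phantom
#'
#' Compartment masks (artery / vein / parenchyma / background outside the
#' window), per-compartment baseline states and response parameters, the
#' active (stimulus-responsive) patch, and camera noise parameters used by
#' the forward model.
#'
#' @slot shape integer ny, nx.
#' @slot masks named list of logical matrices: artery, vein, parenchyma,
#'   background (pairwise disjoint, covering the grid).
#' @slot active logical matrix marking the stimulus-responsive patch.
#' @slot baselineOxygen,baselineAir \linkS4class{BaselineState}s.
#' @slot responseParams named list (per compartment) of gamma-variate
#'   amplitudes and latencies, air undershoot fraction, hypercapnia gain.
#' @slot noise list: shotScale, darkOffset, darkSd (camera counts).
#' @slot pixelUm pixel size metadata (micrometres).
#' @slot seed integer seed the geometry was drawn with.
#' @exportClass Phantom
setClass("Phantom",
  representation(shape = "integer", masks = "list", active = "matrix",
                 baselineOxygen = "BaselineState", baselineAir = "BaselineState",
                 responseParams = "list", noise = "list", pixelUm = "numeric",
                 seed = "numeric"),
  validity = function(object) {
    msg <- character()
    need <- c("artery", "vein", "parenchyma", "background")
    if (!all(need %in% names(object@masks)))
      msg <- c(msg, "masks must contain artery, vein, parenchyma, background")
    else {
      m <- object@masks[need]
      tot <- Reduce(`+`, m)
      if (any(tot != 1)) msg <- c(msg, "masks must be disjoint and cover the grid")
      if (!any(m$artery)) msg <- c(msg, "artery mask is empty")
      if (!any(m$vein)) msg <- c(msg, "vein mask is empty")
    }
    if (length(msg)) msg else TRUE
  })

#' A simulated imaging session
#'
#' Per-experiment, per-wavelength intensity movies (camera counts, frames x
#' pixels), dark frames, the event log, acquisition metadata, and — because
#' the session is synthetic — the injected ground truth for scoring.
#'
#' @slot experiments named list (by experiment id); each element is a list
#'   with \code{intensities} (list over wavelengths of frames x pixels
#'   matrices), \code{dark} (pixel vector acquired in the preceding gap),
#'   and \code{events} (data.frame time_s, kind, value, local to the
#'   experiment).
#' @slot protocol data.frame of experiment descriptors (see
#'   \code{\link{defaultProtocol}}).
#' @slot meta list: seed, condition, wavelengths_nm, frame_rate_hz, shape,
#'   pixel_um.
#' @slot truth list of injected compartment concentration time courses and
#'   related ground truth, one entry per experiment.
#' @exportClass SessionRecording
setClass("SessionRecording",
  representation(experiments = "list", protocol = "data.frame",
                 meta = "list", truth = "list"),
  validity = function(object) {
    for (ex in object@experiments) {
      if (!all(c("intensities", "dark", "events") %in% names(ex)))
        return("each experiment needs intensities, dark, events")
      if (any(vapply(ex$intensities, function(m) any(m < 0), logical(1))))
        return("intensities must be non-negative")
    }
    TRUE
  })

#' Per-wavelength attenuation movies
#'
#' Natural-log attenuation changes relative to the baseline-window mean,
#' one frames x pixels matrix per wavelength. Dead pixels (non-positive
#' intensity inside the mask) are recorded by index and carried as NA.
#'
#' @slot values list over wavelengths of frames x pixels matrices.
#' @slot wavelengths numeric (nm).
#' @slot frameRateHz effective per-wavelength frame rate.
#' @slot shape integer ny, nx of the pixel grid.
#' @slot dead integer indices of excluded pixels.
#' @exportClass AttenuationStack
setClass("AttenuationStack",
  representation(values = "list", wavelengths = "numeric",
                 frameRateHz = "numeric", shape = "integer",
                 dead = "integer"),
  validity = function(object) {
    if (length(object@values) != length(object@wavelengths))
      return("one movie per wavelength required")
    TRUE
  })

#' Hemoglobin concentration-change movies
#'
#' Micromolar changes from baseline for Hbo, Hbr and Hbt (frames x pixels).
#' The conservation identity dHbt = dHbo + dHbr holds element-wise by
#' construction; fractional movies are derived on demand via
#' \code{\link{fractionalMovie}}.
#'
#' @slot dHbo,dHbr,dHbt numeric matrices, frames x pixels (micromolar).
#' @slot baseline \linkS4class{BaselineState} the changes are relative to.
#' @slot frameRateHz frames per second.
#' @slot shape integer ny, nx.
#' @slot dead integer indices of excluded pixels (columns of NA).
#' @exportClass ConcentrationMovies
setClass("ConcentrationMovies",
  representation(dHbo = "matrix", dHbr = "matrix", dHbt = "matrix",
                 baseline = "BaselineState", frameRateHz = "numeric",
                 shape = "integer", dead = "integer"),
  validity = function(object) {
    if (!identical(dim(object@dHbo), dim(object@dHbr)) ||
        !identical(dim(object@dHbo), dim(object@dHbt)))
      return("dHbo, dHbr, dHbt must share dimensions")
    d <- object@dHbt - (object@dHbo + object@dHbr)
    if (any(abs(d) > 0, na.rm = TRUE))
      return("dHbt must equal dHbo + dHbr exactly")
    TRUE
  })

#' Stimulus-activated region of interest
#'
#' @slot pixels logical matrix over the image grid.
#' @slot kSd standard-deviation threshold multiplier used.
#' @slot sourceExperiment id of the experiment the mask was derived from.
#' @exportClass RoiMask
setClass("RoiMask",
  representation(pixels = "matrix", kSd = "numeric",
                 sourceExperiment = "character"),
  validity = function(object) {
    if (!is.logical(object@pixels)) return("pixels must be logical")
    if (!any(object@pixels)) return("ROI mask is empty")
    TRUE
  })

#' First principal component of an image block
#'
#' @slot spatialMap numeric matrix of loadings (NA outside the analysis
#'   mask); unit Euclidean norm over in-mask pixels.
#' @slot temporalScore score per frame.
#' @slot explainedFraction fraction of variance explained in 0..1.
#' @slot signFixed logical, TRUE when the sign was aligned to the stimulus
#'   regressor.
#' @exportClass PrincipalMap
setClass("PrincipalMap",
  representation(spatialMap = "matrix", temporalScore = "numeric",
                 explainedFraction = "numeric", signFixed = "logical"),
  validity = function(object) {
    ef <- object@explainedFraction
    if (ef < 0 || ef > 1 + 1e-12) return("explainedFraction must be in 0..1")
    nrm <- sqrt(sum(object@spatialMap^2, na.rm = TRUE))
    if (abs(nrm - 1) > 1e-8) return("spatial map must have unit norm")
    TRUE
  })

#' Epoched trials
#'
#' @slot values numeric array, trials x time (x pixels when epoching a
#'   movie).
#' @slot timeAxisS time relative to stimulus-train onset (s).
#' @slot nTrials integer.
#' @exportClass TrialTensor
setClass("TrialTensor",
  representation(values = "array", timeAxisS = "numeric",
                 nTrials = "integer"),
  validity = function(object) {
    if (dim(object@values)[1] != object@nTrials)
      return("first array dimension must equal nTrials")
    if (dim(object@values)[2] != length(object@timeAxisS))
      return("second array dimension must match the time axis")
    TRUE
  })

#' Multi-channel field potential record
#'
#' @slot samples numeric matrix, channels x samples (16 channels).
#' @slot rateHz sampling rate (Hz).
#' @slot channelSpacingUm electrode site spacing metadata.
#' @slot events stimulus pulse times (s).
#' @exportClass NeuralRecord
setClass("NeuralRecord",
  representation(samples = "matrix", rateHz = "numeric",
                 channelSpacingUm = "numeric", events = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@samples) != 16L) msg <- c(msg, "expected 16 channels")
    if (object@rateHz <= 0) msg <- c(msg, "rateHz must be > 0")
    dur <- ncol(object@samples) / object@rateHz
    if (length(object@events) && (any(object@events < 0) ||
                                  any(object@events > dur)))
      msg <- c(msg, "events must lie within the record")
    if (length(msg)) msg else TRUE
  })

#' Mixed repeated-measures ANOVA result
#'
#' @slot table data.frame with one row per effect (group, within,
#'   interaction): sums of squares, df, F, p, and the error stratum each F
#'   was formed against.
#' @slot strata named numeric vector of error-stratum sums of squares.
#' @slot species which hemodynamic measure was analysed.
#' @exportClass AnovaResult
setClass("AnovaResult",
  representation(table = "data.frame", strata = "numeric",
                 species = "character"),
  validity = function(object) {
    need <- c("effect", "ss", "df1", "df2", "F", "p")
    if (!all(need %in% names(object@table)))
      return("table must have effect, ss, df1, df2, F, p")
    if (any(object@table$F < 0, na.rm = TRUE)) return("F must be >= 0")
    TRUE
  })
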