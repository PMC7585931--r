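## Hemoglobin spectra and chromophore -> absorption conversion.

#' The four imaging wavelengths (nm)
#'
#' Illumination wavelengths of the multispectral acquisition: 495, 559, 575
#' and 587 nm.
#' @export
imagingWavelengths <- function() c(495, 559, 575, 587)

#' Construct a baseline tissue state
#'
#' @param hbtuM total hemoglobin concentration (micromolar).
#' @param so2 oxygen saturation as a fraction in 0..1.
#' @param condition breathing-condition label ("oxygen" or "air").
#' @return A \linkS4class{BaselineState}.
#' @examples
#' baselineState(100, 0.70, "oxygen")
#' @export
baselineState <- function(hbtuM, so2, condition = "oxygen") {
  new("BaselineState", hbtuM = as.numeric(hbtuM), so2 = as.numeric(so2),
      condition = condition)
}

#' @describeIn baselineState oxyhemoglobin component (micromolar),
#'   \code{so2 * hbtuM}.
#' @param state a \linkS4class{BaselineState}.
#' @export
hboConc <- function(state) state@so2 * state@hbtuM

#' @describeIn baselineState deoxyhemoglobin component (micromolar),
#'   \code{(1 - so2) * hbtuM}.
#' @export
hbrConc <- function(state) state@hbtuM - hboConc(state)

#' @describeIn baselineState total hemoglobin (micromolar).
#' @export
hbtConc <- function(state) state@hbtuM

setMethod("show", "BaselineState", function(object) {
  cat(sprintf("BaselineState: Hbt %.4g uM, SO2 %.1f%% (%s)\n",
              object@hbtuM, 100 * object@so2, object@condition))
})

#' Construct bulk optical properties
#'
#' @param muA absorption coefficient (cm^-1, natural-log convention).
#' @param muS scattering coefficient (cm^-1).
#' @param g Henyey-Greenstein anisotropy.
#' @param n refractive index.
#' @return An \linkS4class{OpticalProperties}.
#' @export
opticalProperties <- function(muA, muS, g = 0.9, n = 1.4) {
  new("OpticalProperties", muA = as.numeric(muA), muS = as.numeric(muS),
      g = as.numeric(g), n = as.numeric(n))
}

#' Load a hemoglobin extinction table
#'
#' Reads a tab-separated spectra file with columns
#' \code{wavelength_nm  eps_hbo  eps_hbr} (cm^-1 M^-1) and validates it
#' against the imaging design: strictly increasing wavelengths and coverage
#' of every imaging wavelength. With no argument the bundled synthetic
#' compilation spanning 450-650 nm is loaded.
#'
#' @param source path to a TSV file, or NULL for the bundled table.
#' @param logBase convention of the tabulated values, "log10" (default) or
#'   "ln".
#' @param requireWavelengths wavelengths (nm) that must fall inside the
#'   tabulated range; defaults to \code{imagingWavelengths()}.
#' @return An \linkS4class{ExtinctionTable}.
#' @examples
#' tab <- loadExtinctionTable()
#' extinctionAt(tab, 559)
#' @export
loadExtinctionTable <- function(source = NULL, logBase = "log10",
                                requireWavelengths = imagingWavelengths()) {
  if (is.null(source)) {
    source <- system.file("extdata", "hb_extinction_synthetic.tsv",
                          package = "ois2d", mustWork = TRUE)
  }
  df <- read.table(source, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("wavelength_nm", "eps_hbo", "eps_hbr")
  if (!all(need %in% names(df)))
    stop("extinction file must have columns: ", paste(need, collapse = ", "))
  wl <- df$wavelength_nm
  if (any(diff(wl) <= 0))
    stop("wavelengths must be strictly increasing")
  for (w in requireWavelengths) {
    if (w < min(wl) || w > max(wl))
      stop(sprintf("spectra do not cover imaging wavelength %g nm", w))
  }
  new("ExtinctionTable", wavelength = as.numeric(wl),
      epsHbo = as.numeric(df$eps_hbo), epsHbr = as.numeric(df$eps_hbr),
      logBase = logBase, source = source)
}

setMethod("show", "ExtinctionTable", function(object) {
  cat(sprintf("ExtinctionTable: %d rows, %g-%g nm (%s convention)\n",
              length(object@wavelength), min(object@wavelength),
              max(object@wavelength), object@logBase))
})

#' Interpolate extinction coefficients at a wavelength
#'
#' Linear interpolation between the bracketing tabulated rows; exact at
#' tabulated wavelengths.
#'
#' @param table an \linkS4class{ExtinctionTable}.
#' @param wavelengthNm scalar wavelength (nm) inside the tabulated range.
#' @return Named numeric vector \code{c(epsHbo =, epsHbr =)}.
#' @export
extinctionAt <- function(table, wavelengthNm) {
  stopifnot(is(table, "ExtinctionTable"), length(wavelengthNm) == 1)
  wl <- table@wavelength
  if (wavelengthNm < min(wl) || wavelengthNm > max(wl))
    stop(sprintf("wavelength %g nm outside tabulated range [%g, %g]",
                 wavelengthNm, min(wl), max(wl)))
  c(epsHbo = approx(wl, table@epsHbo, xout = wavelengthNm)$y,
    epsHbr = approx(wl, table@epsHbr, xout = wavelengthNm)$y)
}

#' Absorption coefficient of a baseline state
#'
#' Converts the hemoglobin concentrations of a baseline state into the bulk
#' absorption coefficient at one wavelength:
#' \code{muA = ln(10) * (epsHbo * cHbo + epsHbr * cHbr)} with concentrations
#' in molar. The ln(10) factor applies when the table follows the base-10
#' convention; a natural-log table is used as-is. The result is always in
#' natural-log units, as required by photon transport.
#'
#' @param state a \linkS4class{BaselineState}.
#' @param wavelengthNm scalar wavelength (nm).
#' @param table an \linkS4class{ExtinctionTable}.
#' @return Absorption coefficient (cm^-1).
#' @examples
#' absorptionCoefficient(baselineState(100, 0.7), 575, loadExtinctionTable())
#' @export
absorptionCoefficient <- function(state, wavelengthNm, table) {
  eps <- extinctionAt(table, wavelengthNm)
  fac <- if (table@logBase == "log10") log(10) else 1
  fac * (eps[["epsHbo"]] * hboConc(state) * 1e-6 +
         eps[["epsHbr"]] * hbrConc(state) * 1e-6)
}
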