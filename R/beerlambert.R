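## Modified Beer-Lambert inversion: per-wavelength attenuation movies to
## hemoglobin concentration-change movies, and baseline re-estimation
## across gas transitions.

#' Attenuation movies from intensity movies
#'
#' Converts dark-corrected per-wavelength intensity movies into natural-log
#' attenuation changes relative to the temporal mean over a baseline
#' window: \code{dA(lambda, t, p) = -ln(I / I0bar)}. Pixels with a
#' non-positive intensity anywhere, or a non-positive baseline mean, are
#' flagged dead, excluded (NA) and counted.
#'
#' @param intensities list over wavelengths of frames x pixels matrices.
#' @param baselineWindow integer frame indices defining the baseline.
#' @param wavelengths numeric wavelengths (nm), one per movie.
#' @param frameRateHz effective per-wavelength frame rate.
#' @param shape integer c(ny, nx) of the pixel grid.
#' @return An \linkS4class{AttenuationStack}.
#' @export
computeAttenuation <- function(intensities, baselineWindow, wavelengths,
                               frameRateHz, shape) {
  stopifnot(length(intensities) == length(wavelengths),
            length(baselineWindow) >= 1)
  nT <- nrow(intensities[[1]])
  if (any(baselineWindow < 1) || any(baselineWindow > nT))
    stop("baseline window outside the record")
  ## flag dead pixels across all wavelengths before taking any logs
  dead <- logical(ncol(intensities[[1]]))
  for (m in intensities) {
    dead <- dead | (colSums(m <= 0) > 0)
    dead <- dead | (colMeans(m[baselineWindow, , drop = FALSE]) <= 0)
  }
  values <- vector("list", length(intensities))
  for (i in seq_along(intensities)) {
    m <- intensities[[i]]
    if (any(dead)) {
      m <- m * 1  # drop integer storage before masking
      m[, dead] <- NA_real_
    }
    i0 <- colMeans(m[baselineWindow, , drop = FALSE])
    dA <- -log(sweep(m, 2, i0, "/"))
    values[[i]] <- dA
  }
  nDead <- sum(dead)
  if (nDead > 0)
    message(sprintf("computeAttenuation: %d dead pixel(s) excluded", nDead))
  new("AttenuationStack", values = values, wavelengths = wavelengths,
      frameRateHz = frameRateHz, shape = as.integer(shape),
      dead = which(dead))
}

## 4 x 2 modified Beer-Lambert design matrix in micromolar units:
## dA(lambda_i) = fac * [eps_hbo(lambda_i), eps_hbr(lambda_i)] * L(lambda_i)
## %*% (dC_uM * 1e-6)
blDesignMatrix <- function(table, paths) {
  wl <- pathWavelengths(paths)
  L <- meanPaths(paths)
  fac <- if (table@logBase == "log10") log(10) else 1
  M <- matrix(0, length(wl), 2,
              dimnames = list(wl, c("dHbo", "dHbr")))
  for (i in seq_along(wl)) {
    eps <- extinctionAt(table, wl[i])
    M[i, ] <- fac * eps * L[i] * 1e-6
  }
  if (qr(M)$rank < 2)
    stop("rank-deficient unmixing design: wavelengths ",
         paste(wl, collapse = ", "), " give collinear extinction columns")
  M
}

#' Unmix a single attenuation 4-vector
#'
#' Ordinary least-squares solution of the modified Beer-Lambert system over
#' the imaging wavelengths (overdetermined, two unknowns); concentrations
#' are unconstrained in sign — deoxyhemoglobin washout appears as negative
#' changes.
#'
#' @param dA attenuation changes, one per wavelength.
#' @param table an \linkS4class{ExtinctionTable}.
#' @param paths a \linkS4class{PathLengthTable} on the same wavelengths.
#' @return Named vector \code{c(dHbo =, dHbr =)} in micromolar.
#' @export
unmixPixel <- function(dA, table, paths) {
  M <- blDesignMatrix(table, paths)
  stopifnot(length(dA) == nrow(M))
  sol <- qr.solve(M, dA)
  c(dHbo = sol[[1]], dHbr = sol[[2]])
}

#' Unmix an attenuation stack into concentration movies
#'
#' Applies the least-squares Beer-Lambert inversion to every frame and
#' pixel via the normal-equations pseudoinverse, and assembles the
#' concentration-change movies with the conservation identity
#' \code{dHbt = dHbo + dHbr} enforced by construction. Dead pixels
#' propagate as NA columns.
#'
#' @param att an \linkS4class{AttenuationStack}.
#' @param table an \linkS4class{ExtinctionTable}.
#' @param paths a \linkS4class{PathLengthTable}.
#' @param baseline the \linkS4class{BaselineState} the changes are relative
#'   to.
#' @return A \linkS4class{ConcentrationMovies}.
#' @export
unmixStack <- function(att, table, paths, baseline) {
  M <- blDesignMatrix(table, paths)
  if (!isTRUE(all.equal(as.numeric(pathWavelengths(paths)),
                        as.numeric(att@wavelengths))))
    stop("wavelengths of attenuation stack and path table differ")
  P <- solve(crossprod(M), t(M))     # 2 x 4 pseudoinverse
  dHbo <- matrix(0, nrow(att@values[[1]]), ncol(att@values[[1]]))
  dHbr <- dHbo
  for (i in seq_along(att@values)) {
    dHbo <- dHbo + P[1, i] * att@values[[i]]
    dHbr <- dHbr + P[2, i] * att@values[[i]]
  }
  new("ConcentrationMovies", dHbo = dHbo, dHbr = dHbr, dHbt = dHbo + dHbr,
      baseline = baseline, frameRateHz = att@frameRateHz,
      shape = att@shape, dead = att@dead)
}

#' Fractional concentration movie
#'
#' Ratio-to-baseline movie for one hemoglobin species:
#' \code{1 + dX / baselineX}. Baseline components are taken from the
#' movies' \linkS4class{BaselineState}.
#'
#' @param movies a \linkS4class{ConcentrationMovies}.
#' @param species "hbt", "hbo" or "hbr".
#' @return Frames x pixels matrix, 1 at baseline.
#' @export
fractionalMovie <- function(movies, species = c("hbt", "hbo", "hbr")) {
  species <- match.arg(species)
  b <- movies@baseline
  base <- switch(species, hbt = hbtConc(b), hbo = hboConc(b),
                 hbr = hbrConc(b))
  if (base <= 0)
    stop("baseline ", species, " is not positive; fractional movie undefined")
  d <- switch(species, hbt = movies@dHbt, hbo = movies@dHbo,
              hbr = movies@dHbr)
  1 + d / base
}

setMethod("show", "ConcentrationMovies", function(object) {
  cat(sprintf(
    "ConcentrationMovies: %d frames x %d pixels (%dx%d) @ %g Hz, %d dead\n",
    nrow(object@dHbt), ncol(object@dHbt), object@shape[1], object@shape[2],
    object@frameRateHz, length(object@dead)))
  cat("  baseline: "); show(object@baseline)
})

#' Estimate the air-breathing baseline from a gas-transition record
#'
#' Given concentration movies from the oxygen-to-air transition experiment,
#' averages the region-of-interest mean changes over a settle window after
#' the gas switch and shifts the assumed oxygen baseline accordingly:
#' new total hemoglobin is the oxygen total plus the mean Hbt change, new
#' saturation is the shifted oxy component over the new total.
#'
#' @param transitionMovies \linkS4class{ConcentrationMovies} of the
#'   oxygen-to-air record.
#' @param oxygenBaseline the assumed \linkS4class{BaselineState} under
#'   oxygen.
#' @param settleWindowS numeric c(start, end) in seconds after record
#'   start, after the switch, over which the shifted state is averaged.
#' @param roi optional \linkS4class{RoiMask}; default uses all live pixels.
#' @return A \linkS4class{BaselineState} with condition "air".
#' @export
estimateAirBaseline <- function(transitionMovies, oxygenBaseline,
                                settleWindowS, roi = NULL) {
  fr <- transitionMovies@frameRateHz
  nT <- nrow(transitionMovies@dHbt)
  if (diff(settleWindowS) <= 0)
    stop("settle window must have positive length")
  idx <- seq(floor(settleWindowS[1] * fr) + 1, ceiling(settleWindowS[2] * fr))
  if (max(idx) > nT) stop("settle window extends beyond the record")
  px <- if (is.null(roi)) {
    setdiff(seq_len(ncol(transitionMovies@dHbt)), transitionMovies@dead)
  } else which(as.vector(roi@pixels))
  dhbt <- mean(rowMeans(transitionMovies@dHbt[idx, px, drop = FALSE],
                        na.rm = TRUE))
  dhbo <- mean(rowMeans(transitionMovies@dHbo[idx, px, drop = FALSE],
                        na.rm = TRUE))
  airHbt <- hbtConc(oxygenBaseline) + dhbt
  airSo2 <- (hboConc(oxygenBaseline) + dhbo) / airHbt
  baselineState(airHbt, min(max(airSo2, 0), 1), condition = "air")
}
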