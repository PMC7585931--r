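## Monte-Carlo estimation of the mean remitted photon path length.
##
## Geometry: semi-infinite homogeneous slab, pencil beam at normal
## incidence, every photon crossing back through the entry surface is
## detected regardless of exit angle or lateral position (no Fresnel
## reflection at the boundary). Implicit-capture weighting: the photon
## weight is multiplied by the single-scattering albedo at each step, with
## Russian-roulette termination once the weight falls below wMin
## (survival probability pSurvive). The reported path length is the
## weight-weighted mean of the total geometric path of detected photons,
## i.e. the differential path length that scales concentration changes in
## the modified Beer-Lambert inversion.

mcSummary <- function(paths, weights, nLaunched, wavelength = NA_real_,
                      seed = NA_real_) {
  nDet <- length(paths)
  if (nDet == 0)
    stop("no photons remitted; cannot estimate a path length ",
         "(check muS > 0 and the step budget)")
  sw <- sum(weights)
  m <- sum(weights * paths) / sw
  neff <- sw^2 / sum(weights^2)
  v <- sum(weights * (paths - m)^2) / sw
  se <- sqrt(v / neff)
  new("PathLengthEstimate", wavelength = wavelength, meanPathCm = m,
      sePathCm = se, nLaunched = as.numeric(nLaunched),
      nDetected = as.numeric(nDet), seed = seed)
}

## Pure-R per-photon walker. Deliberately naive and independent of the
## compiled engine, but consuming the identical uniform stream: used as the
## bookkeeping oracle in the test suite, and available via engine =
## "reference".
photonWalkReference <- function(muA, muS, g, nPhotons, wMin, pSurvive,
                                maxSteps) {
  mut <- muA + muS
  albedo <- muS / mut
  paths <- numeric(0)
  weights <- numeric(0)
  for (i in seq_len(nPhotons)) {
    z <- 0; uz <- 1; w <- 1; path <- 0
    for (step in seq_len(maxSteps)) {
      u1 <- runif(1)
      s <- -log(u1) / mut
      znew <- z + uz * s
      if (uz < 0 && znew <= 0) {
        path <- path + (-z / uz)
        paths <- c(paths, path)
        weights <- c(weights, w)
        break
      }
      z <- znew
      path <- path + s
      w <- w * albedo
      u2 <- runif(1)
      u3 <- runif(1)
      if (g != 0) {
        tmp <- (1 - g * g) / (1 - g + 2 * g * u2)
        ct <- (1 + g * g - tmp * tmp) / (2 * g)
      } else ct <- 2 * u2 - 1
      st <- sqrt(max(0, 1 - ct * ct))
      phi <- 2 * pi * u3
      sz <- sqrt(max(0, 1 - uz * uz))
      uz <- if (abs(uz) > 0.99999) {
        if (uz >= 0) ct else -ct
      } else {
        -sz * st * cos(phi) + uz * ct
      }
      if (w < wMin) {
        u4 <- runif(1)
        if (u4 <= pSurvive) w <- w / pSurvive else break
      }
    }
  }
  list(paths = paths, weights = weights)
}

#' Simulate the remitted-photon path length at one wavelength
#'
#' Runs seeded Monte-Carlo photon transport through a homogeneous
#' semi-infinite tissue slab and returns the weight-weighted mean total
#' path of remitted photons with its Monte-Carlo standard error.
#'
#' @param props an \linkS4class{OpticalProperties}.
#' @param nPhotons number of photons to launch.
#' @param seed integer seed (the estimate is bit-reproducible).
#' @param wavelengthNm wavelength recorded in the estimate (metadata).
#' @param wMin roulette threshold on the photon weight.
#' @param pSurvive roulette survival probability.
#' @param maxSteps per-photon step budget (guards the pure-scattering
#'   limit, where return times are heavy-tailed).
#' @param engine "compiled" (default) or "reference" for the naive pure-R
#'   walker; both consume the identical random stream.
#' @return A \linkS4class{PathLengthEstimate}.
#' @examples
#' simulateRemittancePathlength(opticalProperties(2, 200), 1e4, seed = 1)
#' @export
simulateRemittancePathlength <- function(props, nPhotons, seed,
                                         wavelengthNm = NA_real_,
                                         wMin = 1e-4, pSurvive = 0.1,
                                         maxSteps = 1e6L,
                                         engine = c("compiled", "reference")) {
  stopifnot(is(props, "OpticalProperties"), nPhotons >= 1)
  engine <- match.arg(engine)
  set.seed(as.integer(seed))
  res <- if (engine == "compiled") {
    photon_walk_engine(props@muA, props@muS, props@g,
                       as.integer(nPhotons), wMin, pSurvive,
                       as.integer(maxSteps))
  } else {
    photonWalkReference(props@muA, props@muS, props@g,
                        as.integer(nPhotons), wMin, pSurvive,
                        as.integer(maxSteps))
  }
  mcSummary(res$paths, res$weights, nPhotons, wavelength = wavelengthNm,
            seed = as.numeric(seed))
}

setMethod("show", "PathLengthEstimate", function(object) {
  cat(sprintf(
    "PathLengthEstimate: %.4g cm (SE %.2g) at %g nm [%g/%g photons]\n",
    object@meanPathCm, object@sePathCm, object@wavelength,
    object@nDetected, object@nLaunched))
})

#' Per-wavelength scattering model
#'
#' Reduced scattering follows a power-law decay with wavelength,
#' \code{musPrime(lambda) = musPrimeRef * (lambda / refNm)^(-power)}, the
#' literature-typical form for cortical tissue; the full scattering
#' coefficient is \code{musPrime / (1 - g)}. Defaults: musPrimeRef = 20
#' cm^-1 at 560 nm, power = 1, g = 0.9, n = 1.4.
#'
#' @param musPrimeRef reduced scattering at the reference wavelength
#'   (cm^-1).
#' @param refNm reference wavelength (nm).
#' @param power power-law exponent.
#' @param g anisotropy.
#' @param n refractive index.
#' @return A function of wavelength returning an
#'   \linkS4class{OpticalProperties} template (muA = 0; filled in by
#'   \code{\link{pathlengthTable}}).
#' @export
scatterModel <- function(musPrimeRef = 20, refNm = 560, power = 1,
                         g = 0.9, n = 1.4) {
  force(musPrimeRef); force(refNm); force(power); force(g); force(n)
  function(wavelengthNm) {
    musPrime <- musPrimeRef * (wavelengthNm / refNm)^(-power)
    opticalProperties(muA = 0, muS = musPrime / (1 - g), g = g, n = n)
  }
}

## cache for path length tables, keyed on all determining inputs
.pathCache <- new.env(parent = emptyenv())

#' Monte-Carlo path length table for a baseline state
#'
#' Computes the absorption coefficient at each imaging wavelength from the
#' baseline hemoglobin state, runs the remittance simulation per wavelength
#' with deterministically derived sub-seeds, and returns the per-wavelength
#' mean path lengths. Results are cached in-session keyed on baseline,
#' optics, photon count and seed; a cache hit returns the identical table.
#'
#' @param baseline a \linkS4class{BaselineState}.
#' @param wavelengths wavelengths to simulate (nm); default
#'   \code{imagingWavelengths()}.
#' @param table an \linkS4class{ExtinctionTable}.
#' @param scatter per-wavelength scattering model from
#'   \code{\link{scatterModel}}.
#' @param nPhotons photons per wavelength.
#' @param seed master integer seed; wavelength i uses sub-seed
#'   \code{(seed + 7919 * i) mod (2^31 - 1)}.
#' @param ... passed to \code{\link{simulateRemittancePathlength}}.
#' @return A \linkS4class{PathLengthTable}.
#' @examples
#' paths <- pathlengthTable(baselineState(100, 0.7), nPhotons = 2000, seed = 1)
#' meanPaths(paths)
#' @export
pathlengthTable <- function(baseline, wavelengths = imagingWavelengths(),
                            table = loadExtinctionTable(),
                            scatter = scatterModel(), nPhotons = 1e5,
                            seed = 1, ...) {
  probe <- scatter(wavelengths[1])
  key <- paste(baseline@hbtuM, baseline@so2, baseline@condition,
               paste(wavelengths, collapse = ","),
               probe@muS, probe@g, probe@n, nPhotons, seed, sep = "|")
  if (!is.null(.pathCache[[key]])) return(.pathCache[[key]])
  ests <- vector("list", length(wavelengths))
  for (i in seq_along(wavelengths)) {
    wl <- wavelengths[i]
    props <- scatter(wl)
    props@muA <- absorptionCoefficient(baseline, wl, table)
    subSeed <- (as.numeric(seed) + 7919 * i) %% (2^31 - 1)
    ests[[i]] <- simulateRemittancePathlength(props, nPhotons, subSeed,
                                              wavelengthNm = wl, ...)
  }
  out <- new("PathLengthTable", estimates = ests, baseline = baseline)
  .pathCache[[key]] <- out
  out
}

#' @describeIn pathlengthTable wavelengths (nm) of a path length table.
#' @param x a \linkS4class{PathLengthTable}.
#' @export
pathWavelengths <- function(x)
  vapply(x@estimates, function(e) e@wavelength, numeric(1))

#' @describeIn pathlengthTable mean path lengths (cm), named by wavelength.
#' @export
meanPaths <- function(x) {
  p <- vapply(x@estimates, function(e) e@meanPathCm, numeric(1))
  names(p) <- pathWavelengths(x)
  p
}

#' @describeIn pathlengthTable Monte-Carlo standard errors (cm).
#' @export
sePaths <- function(x) {
  p <- vapply(x@estimates, function(e) e@sePathCm, numeric(1))
  names(p) <- pathWavelengths(x)
  p
}

setMethod("show", "PathLengthTable", function(object) {
  cat("PathLengthTable (baseline ", object@baseline@hbtuM, " uM, SO2 ",
      100 * object@baseline@so2, "%):\n", sep = "")
  for (e in object@estimates)
    cat(sprintf("  %g nm: %.4g cm (SE %.2g)\n", e@wavelength,
                e@meanPathCm, e@sePathCm))
})
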