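## Vessel compartmentalisation by principal component analysis of the
## hemodynamic image block within the activated region.

#' First principal component of an image block
#'
#' Removes the temporal mean per pixel and takes the first singular
#' component of the time x pixel matrix restricted to the analysis mask.
#' The component sign is fixed so the temporal score covaries positively
#' with the stimulus regressor (PCA sign being otherwise arbitrary); the
#' spatial map keeps unit norm so loadings stay proportional to response
#' amplitude.
#'
#' @param movie time x pixels matrix (at least 2 frames).
#' @param mask a \linkS4class{RoiMask} or logical vector/matrix selecting
#'   the analysis region (at least 2 pixels).
#' @param stimulusRegressor optional numeric regressor per frame used to
#'   fix the sign; default a constant (sign left as returned, flagged).
#' @param shape integer c(ny, nx) of the pixel grid.
#' @return A \linkS4class{PrincipalMap}; loadings are NA outside the mask.
#' @export
firstPrincipalMap <- function(movie, mask, stimulusRegressor = NULL,
                              shape) {
  px <- if (is(mask, "RoiMask")) as.vector(mask@pixels) else as.vector(mask)
  if (sum(px) < 2) stop("need at least 2 pixels in the analysis mask")
  X <- movie[, px, drop = FALSE]
  if (nrow(X) < 2) stop("need at least 2 frames")
  X <- sweep(X, 2, colMeans(X))
  if (all(abs(X) < .Machine$double.eps * 100))
    stop("degenerate input: movie has zero variance within the mask")
  sv <- svd(X)
  loading <- sv$v[, 1]
  score <- sv$u[, 1] * sv$d[1]
  explained <- sv$d[1]^2 / sum(sv$d^2)
  signFixed <- FALSE
  if (!is.null(stimulusRegressor)) {
    cv <- sum(score * (stimulusRegressor - mean(stimulusRegressor)))
    if (cv < 0) {
      loading <- -loading
      score <- -score
    }
    signFixed <- TRUE
  }
  mp <- matrix(NA_real_, shape[1], shape[2])
  mp[px] <- loading
  new("PrincipalMap", spatialMap = mp, temporalScore = score,
      explainedFraction = explained, signFixed = signFixed)
}

setMethod("show", "PrincipalMap", function(object) {
  cat(sprintf("PrincipalMap: %d px, %.1f%% variance%s\n",
              sum(!is.na(object@spatialMap)),
              100 * object@explainedFraction,
              if (object@signFixed) " (sign aligned to stimulus)" else ""))
})

#' Artery and vein masks from principal maps
#'
#' Arteries are the region-of-interest pixels whose Hbt first-component
#' loading exceeds its upper quantile; veins are the pixels whose absolute
#' Hbr loading exceeds its upper quantile, minus any artery pixels. The
#' two masks are disjoint by construction.
#'
#' @param hbtMap,hbrMap \linkS4class{PrincipalMap}s of the Hbt and Hbr
#'   image blocks on the same grid.
#' @param roi the activated-region \linkS4class{RoiMask}.
#' @param quantile upper-quantile threshold within the ROI (default 0.8).
#' @return list(artery =, vein =) of \linkS4class{RoiMask}s.
#' @export
vesselMasks <- function(hbtMap, hbrMap, roi, quantile = 0.8) {
  px <- roi@pixels
  lt <- hbtMap@spatialMap
  lr <- abs(hbrMap@spatialMap)
  if (!identical(dim(lt), dim(px)) || !identical(dim(lr), dim(px)))
    stop("principal maps and ROI must share the grid")
  thrT <- stats::quantile(lt[px], quantile, na.rm = TRUE)
  artery <- px & !is.na(lt) & lt > thrT
  if (!any(artery))
    stop("empty arterial compartment at quantile ", quantile,
         " (max loading ", format(max(lt[px], na.rm = TRUE)), ")")
  thrR <- stats::quantile(lr[px], quantile, na.rm = TRUE)
  vein <- px & !is.na(lr) & lr > thrR & !artery
  if (!any(vein))
    stop("empty venous compartment at quantile ", quantile,
         " after artery exclusion")
  list(artery = new("RoiMask", pixels = artery, kSd = NA_real_,
                    sourceExperiment = "pca_hbt"),
       vein = new("RoiMask", pixels = vein, kSd = NA_real_,
                  sourceExperiment = "pca_hbr"))
}

#' Compartment-mean fractional series
#'
#' Mask-mean fractional Hbt/Hbo/Hbr series for the artery and vein
#' compartments.
#'
#' @param movies a \linkS4class{ConcentrationMovies}.
#' @param masks list(artery =, vein =) of \linkS4class{RoiMask}s.
#' @return nested list \code{[[compartment]][[species]]} of numeric
#'   series.
#' @export
compartmentSeries <- function(movies, masks) {
  out <- list()
  for (comp in names(masks)) {
    if (!any(masks[[comp]]@pixels)) stop("empty ", comp, " mask")
    out[[comp]] <- list(
      hbt = roiTimeseries(fractionalMovie(movies, "hbt"), masks[[comp]]),
      hbo = roiTimeseries(fractionalMovie(movies, "hbo"), masks[[comp]]),
      hbr = roiTimeseries(fractionalMovie(movies, "hbr"), masks[[comp]]))
  }
  out
}
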