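#' Total sample variance of a Hellinger matrix
#'
#' Sum over species of the (n-1)-denominator sample variance of the
#' Hellinger-transformed abundances across stations. Equals the pair-weighted
#' mean of the empirical variogram when the distance classes cover all pairs.
#'
#' @param x a \code{\link{BenthicSite}} or a stations-by-species Hellinger
#'   matrix
#' @return scalar \code{s2} (Hellinger^2 units)
#' @export
setGeneric("totalVariance", function(x) standardGeneric("totalVariance"))

#' Hellinger-transformed abundance matrix
#'
#' @param x a \code{\link{BenthicSite}}
#' @return stations-by-species matrix with unit row sums of squares
#' @export
setGeneric("hellinger", function(x) standardGeneric("hellinger"))

#' Station coordinates
#' @param x a \code{\link{BenthicSite}}
#' @return two-column matrix (x_km, y_km), rownames = station ids
#' @export
setGeneric("stationCoords", function(x) standardGeneric("stationCoords"))

#' Province labels
#' @param x a \code{\link{BenthicSite}}
#' @return factor of per-station province labels
#' @export
setGeneric("provinces", function(x) standardGeneric("provinces"))

#' Continuous environmental covariates
#' @param x a \code{\link{BenthicSite}}
#' @return data.frame of per-station numeric covariates (may have 0 columns)
#' @export
setGeneric("envCovariates", function(x) standardGeneric("envCovariates"))

#' Build distance classes over station pairs
#'
#' @param x a \code{\link{BenthicSite}} or a two-column coordinate matrix
#' @param intervalKm class width in km; \code{NULL} selects the smallest of
#'   0.25, 0.50, 0.75 km that yields at most 12 classes under the cutoff
#' @param cutoffKm maximum usable distance; default half the maximum extent
#' @param minPairs pair count below which a class triggers a warning
#' @return a \code{\link{DistanceClassing}}
#' @export
setGeneric("buildClasses",
  function(x, intervalKm = NULL, cutoffKm = NULL, minPairs = 30L)
    standardGeneric("buildClasses"))

#' Class midpoints of a distance classing
#' @param x a \code{\link{DistanceClassing}} (or object carrying one)
#' @return numeric vector of class centers (km)
#' @export
setGeneric("classCenters", function(x) standardGeneric("classCenters"))

#' Pair counts per distance class
#' @param x a \code{\link{DistanceClassing}} (or object carrying one)
#' @return integer vector
#' @export
setGeneric("pairCounts", function(x) standardGeneric("pairCounts"))

#' Per-class variogram values
#' @param x an \code{\link{EmpiricalVariogram}}
#' @return numeric vector of gamma(h)
#' @export
setGeneric("gammaValues", function(x) standardGeneric("gammaValues"))

#' Derived range of a fitted variogram model
#'
#' The spherical and piecewise-linear families reach their sill at \code{a};
#' for the asymptotic families (exponential, Gaussian, logistic) the range is
#' the smallest distance at which the model reaches 95\% of its sill.
#'
#' @param object a \code{\link{VariogramFit}}
#' @param ... unused
#' @return range in km, or NA with a message when 95\% of the sill is below
#'   the nugget (range undefined)
#' @export
setGeneric("derivedRange", function(object, ...) standardGeneric("derivedRange"))

#' Best fit of a fit set
#' @param x a \code{\link{VariogramFitSet}}
#' @return the minimum-AICc \code{\link{VariogramFit}}
#' @export
setGeneric("bestFit", function(x) standardGeneric("bestFit"))

#' Per-family fit summary table
#' @param x a \code{\link{VariogramFitSet}}
#' @return data.frame with one row per attempted family
#' @export
setGeneric("fitTable", function(x) standardGeneric("fitTable"))

#' Explained fraction of community variance
#' @param x an \code{\link{RDAModel}}
#' @return scalar in [0, 1]
#' @export
setGeneric("explainedFraction", function(x) standardGeneric("explainedFraction"))
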