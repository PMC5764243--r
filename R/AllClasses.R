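#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom stats dist var sd qnorm lm coef confint rnorm rpois rmultinom runif
#'   nlminb optim setNames complete.cases cor quantile median
#' @importFrom utils read.csv write.csv head
NULL

#' Site container: species-by-station counts plus station metadata
#'
#' \code{BenthicSite} extends \code{SummarizedExperiment}: rows are taxa,
#' columns are stations. Two assays are carried: \code{"counts"} (raw
#' abundances) and \code{"hellinger"} (square root of within-sample relative
#' abundance, so each station column has unit sum of squares). Station
#' coordinates (\code{x_km}, \code{y_km}, projected planar, km), the
#' categorical habitat \code{province} and any continuous environmental
#' covariates live in \code{colData}.
#'
#' @slot .. see \code{\link[SummarizedExperiment]{SummarizedExperiment}}
#' @aliases BenthicSite-class
#' @exportClass BenthicSite
setClass("BenthicSite", contains = "SummarizedExperiment")

setValidity("BenthicSite", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("counts", "hellinger") %in% an))
    msg <- c(msg, "assays 'counts' and 'hellinger' are required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    hel <- SummarizedExperiment::assay(object, "hellinger")
    if (any(cts < 0)) msg <- c(msg, "counts must be nonnegative")
    if (any(colSums(cts) <= 0)) msg <- c(msg, "every station must have a positive count total")
    ss <- colSums(hel^2)
    if (any(abs(ss - 1) > 1e-8))
      msg <- c(msg, "hellinger columns must have unit sum of squares")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("x_km", "y_km", "province")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, "colData must contain x_km, y_km, province")
  else if (!all(is.finite(cd$x_km)) || !all(is.finite(cd$y_km)))
    msg <- c(msg, "station coordinates must be finite")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate station ids")
  if (length(msg)) msg else TRUE
})

#' Geographic distance classing of station pairs
#'
#' Pairwise Euclidean station distances binned into contiguous classes of
#' width \code{intervalKm}, half-open \code{[lower, upper)} except the final
#' class, which is closed at the cutoff so that \code{(0, cutoffKm]} is
#' covered. Only pairs at distances up to \code{cutoffKm} (default half the
#' maximum extent \code{hMax}) are usable for variogram estimation.
#'
#' @slot intervalKm class width (km)
#' @slot cutoffKm maximum usable distance (km)
#' @slot hMax maximum pairwise distance among stations (km)
#' @slot edges numeric vector of class edges, starting at 0
#' @slot centers arithmetic midpoints of the class edges (km)
#' @slot pairs list of two-column integer matrices (station indices a, b)
#' @slot nPairs integer pair count per class
#' @slot sampleIds station ids the indices refer to
#' @exportClass DistanceClassing
setClass("DistanceClassing",
  slots = c(intervalKm = "numeric", cutoffKm = "numeric", hMax = "numeric",
            edges = "numeric", centers = "numeric", pairs = "list",
            nPairs = "integer", sampleIds = "character"))

setValidity("DistanceClassing", function(object) {
  msg <- character()
  m <- length(object@centers)
  if (length(object@edges) != m + 1) msg <- c(msg, "edges must have length(centers)+1")
  if (is.unsorted(object@edges, strictly = TRUE)) msg <- c(msg, "edges must be strictly increasing")
  if (length(object@pairs) != m || length(object@nPairs) != m)
    msg <- c(msg, "pairs and nPairs must match the number of classes")
  if (any(object@nPairs != vapply(object@pairs, nrow, 0L)))
    msg <- c(msg, "nPairs must equal pair-list lengths")
  n <- length(object@sampleIds)
  if (sum(object@nPairs) > n * (n - 1) / 2) msg <- c(msg, "more pairs than n(n-1)/2")
  if (length(msg)) msg else TRUE
})

#' Empirical multivariate variogram
#'
#' Per distance class \eqn{h}, \eqn{\gamma(h)} is the sum over species of half
#' the mean squared difference of Hellinger-transformed abundances between the
#' station pairs in the class (Hellinger-squared units), with a per-class
#' standard error taken over pairs.
#'
#' @slot classing the \code{\link{DistanceClassing}} used
#' @slot gamma \eqn{\gamma(h)} per class (NA for empty classes)
#' @slot se standard error of \eqn{\gamma(h)} per class
#' @slot s2 total sample variance of the Hellinger matrix
#' @exportClass EmpiricalVariogram
setClass("EmpiricalVariogram",
  slots = c(classing = "DistanceClassing", gamma = "numeric",
            se = "numeric", s2 = "numeric"))

setValidity("EmpiricalVariogram", function(object) {
  msg <- character()
  m <- length(object@classing@centers)
  if (length(object@gamma) != m || length(object@se) != m)
    msg <- c(msg, "gamma and se must have one value per class")
  if (any(object@gamma < -1e-12, na.rm = TRUE)) msg <- c(msg, "gamma must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Fitted parametric variogram model
#'
#' One of the exponential, Gaussian, spherical, piecewise-linear or logistic
#' families fitted by pair-count-weighted least squares. \code{c0} is the
#' nugget, \code{c0 + c1} the sill, and \code{a} the rate/range parameter
#' (km, except the logistic where it has km^-2 semantics). The derived range
#' is \code{a} for the spherical and piecewise-linear families and the
#' distance where the model reaches 95\% of its sill for the asymptotic ones.
#'
#' @slot family model family name
#' @slot c0,c1,a fitted parameters
#' @slot sill \code{c0 + c1}
#' @slot rangeKm derived range (km; NA when undefined)
#' @slot aicc small-sample corrected AIC of the weighted fit
#' @slot rssWeighted pair-count-weighted residual sum of squares
#' @slot converged did the optimizer report convergence
#' @slot scaledNugget \code{c0 / s2} (NA until attached by selection)
#' @slot scaledRange \code{rangeKm / hMax} (NA until attached by selection)
#' @slot s2,hMax context carried from the empirical variogram
#' @slot nClasses number of usable classes in the fit
#' @exportClass VariogramFit
setClass("VariogramFit",
  slots = c(family = "character", c0 = "numeric", c1 = "numeric", a = "numeric",
            sill = "numeric", rangeKm = "numeric", aicc = "numeric",
            rssWeighted = "numeric", converged = "logical",
            scaledNugget = "numeric", scaledRange = "numeric",
            s2 = "numeric", hMax = "numeric", nClasses = "integer"))

setValidity("VariogramFit", function(object) {
  msg <- character()
  if (!object@family %in% variogramFamilies())
    msg <- c(msg, paste("unknown family:", object@family))
  if (object@c0 < 0 || object@c1 < 0) msg <- c(msg, "c0 and c1 must be nonnegative")
  if (object@a <= 0) msg <- c(msg, "a must be positive")
  if (abs(object@sill - (object@c0 + object@c1)) > 1e-12)
    msg <- c(msg, "sill must equal c0 + c1")
  if (length(msg)) msg else TRUE
})

#' Set of candidate variogram fits with the AICc winner
#'
#' @slot fits list of \code{\link{VariogramFit}} (may be shorter than five if
#'   some families failed to fit)
#' @slot best index of the minimum-AICc converged fit
#' @exportClass VariogramFitSet
setClass("VariogramFitSet", slots = c(fits = "list", best = "integer"))

#' Redundancy analysis of Hellinger abundances on an explanatory design
#'
#' Ordinary least squares of each column-centered Hellinger species profile on
#' the (centered) design, followed by eigenanalysis of the fitted covariance.
#' \code{fitted + residuals} reconstructs the centered response exactly.
#'
#' @slot design centered design matrix actually used (aliased columns dropped)
#' @slot terms names of the design columns supplied
#' @slot dropped names of columns dropped for rank deficiency
#' @slot Y column-centered Hellinger matrix (stations x species)
#' @slot fitted,residuals the OLS decomposition of \code{Y}
#' @slot eigenvalues canonical eigenvalues, descending (Hellinger^2 units)
#' @slot explainedFraction sum of canonical eigenvalues over \code{s2}
#' @slot aicc AICc of the multivariate least-squares fit
#' @slot s2 total variance of the Hellinger matrix
#' @slot sampleIds station ids (row order of \code{Y})
#' @exportClass RDAModel
setClass("RDAModel",
  slots = c(design = "matrix", terms = "character", dropped = "character",
            Y = "matrix", fitted = "matrix", residuals = "matrix",
            eigenvalues = "numeric", explainedFraction = "numeric",
            aicc = "numeric", s2 = "numeric", sampleIds = "character"))

setValidity("RDAModel", function(object) {
  msg <- character()
  if (max(abs(object@Y - object@fitted - object@residuals)) > 1e-8)
    msg <- c(msg, "fitted + residuals must reconstruct Y")
  if (object@explainedFraction < -1e-10 || object@explainedFraction > 1 + 1e-10)
    msg <- c(msg, "explainedFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Forward-selection result
#'
#' @slot model the refitted minimum-AICc \code{\link{RDAModel}}
#' @slot trace data.frame with one row per greedy step: variable, conditional
#'   eigenvalue gain (as a fraction of \code{s2}), cumulative fraction, AICc
#' @slot selected names of the variables retained at the AICc minimum
#' @exportClass RDASelection
setClass("RDASelection",
  slots = c(model = "RDAModel", trace = "data.frame", selected = "character"))

#' Province merge-search result
#'
#' @slot mergeMap named character vector mapping each original province to its
#'   merged group label
#' @slot aicc AICc of the winning configuration
#' @slot path data.frame of the greedy agglomeration path (nGroups,
#'   explainedFraction, aicc)
#' @exportClass ProvinceMerge
setClass("ProvinceMerge",
  slots = c(mergeMap = "character", aicc = "numeric", path = "data.frame"))

#' Multiscale ordination result
#'
#' Per distance class, the decomposition \eqn{\gamma = \gamma_{fit} +
#' \gamma_{res} + \gamma_{cross}} of the empirical variogram through an RDA
#' model, with the three spatial diagnostics: a Bonferroni-corrected envelope
#' around \eqn{\gamma(h)} testing scale dependence (whether
#' \eqn{\gamma_{fit}+\gamma_{res}} leaves the envelope), per-class Mantel
#' tests of residual autocorrelation, and a residual-stationarity check
#' (weighted slope of \eqn{\gamma_{res}} over the upper half of classes).
#'
#' @slot classing the \code{\link{DistanceClassing}} used
#' @slot table per-class data.frame (centers, pair counts, components,
#'   envelope, flags, Mantel statistics)
#' @slot alpha family-wise significance level
#' @slot nPerm Mantel permutation count (NA if tests not run)
#' @slot mTests number of classes counted in the Bonferroni corrections
#' @slot scaleDependent any class outside the envelope
#' @slot stationarityOk slope of residual variogram compatible with 0
#' @slot stationaritySlope,stationarityCI the fitted slope and its 95\% CI
#' @exportClass MSOResult
setClass("MSOResult",
  slots = c(classing = "DistanceClassing", table = "data.frame",
            alpha = "numeric", nPerm = "numeric", mTests = "integer",
            scaleDependent = "logical", stationarityOk = "logical",
            stationaritySlope = "numeric", stationarityCI = "numeric"))

#' Within/between-province variance partition
#'
#' The modified multiscale ordination in which geographic distance classes are
#' replaced by two "distance" classes: station pairs within the same province
#' and pairs in different provinces (plus an overall row over all pairs). The
#' site-level nugget \code{c0} from the selected variogram model can be
#' subtracted from \eqn{\gamma_{res}} to express explained fractions relative
#' to the variation actually resolved by the survey.
#'
#' @slot table data.frame with rows within/between/overall: pair counts,
#'   gamma components, nugget-adjusted residual and explained fraction,
#'   negative-residual flag
#' @slot c0 nugget subtracted (NA until adjustment applied)
#' @slot s2 total Hellinger variance of the site
#' @exportClass PartitionResult
setClass("PartitionResult",
  slots = c(table = "data.frame", c0 = "numeric", s2 = "numeric"))
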