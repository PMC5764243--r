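#' Supported variogram model families
#'
#' @return character vector of the five family names
#' @export
variogramFamilies <- function()
  c("exponential", "gaussian", "spherical", "linear", "logistic")

#' Parametric variogram model value
#'
#' Closed-form \eqn{\gamma_{model}(h)} for the five families. All are
#' nondecreasing in \eqn{h} with \eqn{\gamma(0) = c_0}; the spherical and
#' piecewise-linear families clamp at the sill \eqn{c_0 + c_1} for
#' \eqn{h \ge a}. For the logistic family \eqn{a} has km^-2 semantics
#' (\eqn{\gamma = c_0 + c_1 a h^2 / (1 + a h^2)}).
#'
#' @param family one of \code{variogramFamilies()}
#' @param c0,c1 nugget and partial sill (nonnegative)
#' @param a rate/range parameter (> 0)
#' @param h distances (>= 0), vectorized
#' @return numeric vector of model values
#' @examples
#' variogramModelValue("exponential", 0.21, 0.32, 0.89, c(0, 1, 5))
#' @export
variogramModelValue <- function(family, c0, c1, a, h) {
  family <- match.arg(family, variogramFamilies())
  if (a <= 0) stop("a must be positive")
  if (c0 < 0 || c1 < 0) stop("c0 and c1 must be nonnegative")
  if (any(h < 0)) stop("h must be nonnegative")
  switch(family,
    exponential = c0 + c1 * (1 - exp(-h / a)),
    gaussian    = c0 + c1 * (1 - exp(-h^2 / a^2)),
    spherical   = ifelse(h >= a, c0 + c1,
                         c0 + c1 * (1.5 * h / a - 0.5 * (h / a)^3)),
    linear      = ifelse(h >= a, c0 + c1, c0 + c1 * h / a),
    logistic    = c0 + c1 * a * h^2 / (1 + a * h^2))
}

# smallest h with gamma_model(h) = 0.95 * sill, by bracketing bisection
rangeByBisection <- function(family, c0, c1, a, tol = 1e-6) {
  target <- 0.95 * (c0 + c1)
  f <- function(h) variogramModelValue(family, c0, c1, a, h) - target
  hi <- 1
  while (f(hi) < 0 && hi < 1e12) hi <- hi * 2
  if (f(hi) < 0) return(NA_real_)
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

derivedRangeParams <- function(family, c0, c1, a) {
  family <- match.arg(family, variogramFamilies())
  if (family %in% c("spherical", "linear")) return(a)
  sill <- c0 + c1
  if (0.95 * sill < c0 || c1 <= 0) {
    warning("range undefined: 95% of the sill is below the nugget")
    return(NA_real_)
  }
  switch(family,
    exponential = -a * log(0.05 * sill / c1),
    gaussian    = a * sqrt(-log(0.05 * sill / c1)),
    logistic    = rangeByBisection(family, c0, c1, a))
}

#' @rdname derivedRange
#' @export
setMethod("derivedRange", "VariogramFit", function(object, ...)
  derivedRangeParams(object@family, object@c0, object@c1, object@a))

#' Range of the autocorrelated component of a fitted model
#'
#' Distance at which the model has gained 95\% of its partial sill above the
#' nugget (the smallest \eqn{h} with \eqn{\gamma(h) = c_0 + 0.95 c_1}) for
#' the asymptotic families, and \eqn{a} (where the sill is reached exactly)
#' for the spherical and piecewise-linear families. Unlike the sill-based
#' \code{\link{derivedRange}}, this measure is invariant to the nugget and
#' therefore comparable with the practical range of a generating spatial
#' covariance in recovery studies.
#'
#' @param fit a \code{\link{VariogramFit}}
#' @return range in km (NA when \code{c1 = 0})
#' @export
correlationRange <- function(fit) {
  stopifnot(is(fit, "VariogramFit"))
  if (fit@c1 <= 0) return(NA_real_)
  a <- fit@a
  switch(fit@family,
    exponential = -a * log(0.05),
    gaussian    = a * sqrt(-log(0.05)),
    spherical   = a,
    linear      = a,
    logistic    = sqrt(19 / a))
}

#' Construct a VariogramFit from explicit parameters
#'
#' Useful for evaluating published parameter sets; the derived range, sill
#' and scaled quantities are computed from the parameters.
#'
#' @param family model family
#' @param c0,c1,a parameters
#' @param s2 total variance for the scaled nugget (optional)
#' @param hMax maximum extent for the scaled range (optional)
#' @return a \code{\link{VariogramFit}} (aicc/rss are NA)
#' @examples
#' f <- variogramFit("exponential", c0 = 0.21, c1 = 0.32, a = 0.89)
#' derivedRange(f)
#' @export
variogramFit <- function(family, c0, c1, a, s2 = NA_real_, hMax = NA_real_) {
  family <- match.arg(family, variogramFamilies())
  rng <- suppressWarnings(derivedRangeParams(family, c0, c1, a))
  new("VariogramFit", family = family, c0 = c0, c1 = c1, a = a,
      sill = c0 + c1, rangeKm = rng, aicc = NA_real_, rssWeighted = NA_real_,
      converged = NA, scaledNugget = if (is.na(s2)) NA_real_ else c0 / s2,
      scaledRange = if (is.na(hMax)) NA_real_ else rng / hMax,
      s2 = s2, hMax = hMax, nClasses = NA_integer_)
}

#' Small-sample corrected AIC for a (weighted) least-squares fit
#'
#' \code{AICc = n log(RSS/n) + 2K + 2K(K+1)/(n-K-1)} with \code{K} counting
#' the error-variance parameter in addition to the model coefficients.
#'
#' @param rss residual sum of squares (weighted where the fit is weighted)
#' @param n number of observations
#' @param nParams number of model coefficients (K = nParams + 1)
#' @return scalar AICc
#' @export
aiccLeastSquares <- function(rss, n, nParams) {
  K <- nParams + 1
  if (n - K - 1 <= 0) stop("AICc undefined: n - K - 1 <= 0")
  rss <- max(rss, 1e-300)
  n * log(rss / n) + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

wlsObjective <- function(family, h, g, w) {
  function(p) sum(w * (g - variogramModelValue(family, p[1], p[2], p[3], h))^2)
}

#' Fit one variogram model family by weighted least squares
#'
#' Minimizes \eqn{\sum_h n_h (\gamma(h) - \gamma_{model}(h))^2} over
#' \eqn{c_0, c_1 \ge 0} and \eqn{a > 0}, from a grid of starting values
#' (\code{c0} at 25/50\% of the first class value, \code{a} at 25/50/100\% of
#' the cutoff), keeping the best converged result.
#'
#' @param empirical an \code{\link{EmpiricalVariogram}} with at least 4
#'   non-empty classes
#' @param family one of \code{variogramFamilies()}
#' @return a \code{\link{VariogramFit}}
#' @export
fitVariogramModel <- function(empirical, family) {
  family <- match.arg(family, variogramFamilies())
  ok <- !is.na(empirical@gamma)
  h <- empirical@classing@centers[ok]
  g <- empirical@gamma[ok]
  w <- as.numeric(empirical@classing@nPairs[ok])
  n <- length(h)
  if (n < 4) stop("at least 4 usable distance classes are required")
  cutoff <- empirical@classing@cutoffKm
  obj <- wlsObjective(family, h, g, w)

  aScale <- if (family == "logistic") 1 / cutoff^2 else cutoff
  starts <- expand.grid(c0 = c(0.25, 0.5) * max(g[1], 1e-4),
                        aFrac = c(0.25, 0.5, 1.0))
  lower <- c(0, 0, 1e-8 * aScale)
  upper <- c(max(g) * 2 + 1, max(g) * 2 + 1, 1e4 * aScale)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(starts$c0[i], max(max(g) - starts$c0[i], 1e-4),
            starts$aFrac[i] * aScale)
    res <- tryCatch(
      nlminb(p0, obj, lower = lower, upper = upper,
             control = list(iter.max = 500, eval.max = 1000,
                            rel.tol = 1e-12, x.tol = 1e-11)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    res$converged <- res$convergence == 0
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) stop("no starting value converged for family ", family)
  # polish with a second bounded quasi-Newton pass
  pol <- tryCatch(
    optim(best$par, obj, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(factr = 10, maxit = 500)),
    error = function(e) NULL)
  if (!is.null(pol) && is.finite(pol$value) && pol$value <= best$objective) {
    best$par <- pol$par
    best$objective <- pol$value
    best$converged <- best$converged || pol$convergence == 0
  }
  p <- best$par
  rng <- suppressWarnings(derivedRangeParams(family, p[1], p[2], p[3]))
  new("VariogramFit", family = family, c0 = p[1], c1 = p[2], a = p[3],
      sill = p[1] + p[2], rangeKm = rng,
      aicc = tryCatch(aiccLeastSquares(best$objective, n, 3),
                      error = function(e) NA_real_),
      rssWeighted = best$objective, converged = isTRUE(best$converged),
      scaledNugget = p[1] / empirical@s2,
      scaledRange = rng / empirical@classing@hMax,
      s2 = empirical@s2, hMax = empirical@classing@hMax,
      nClasses = as.integer(n))
}

#' Fit all five families and select by AICc
#'
#' Families whose fit fails outright are skipped; among the remaining fits the
#' minimum-AICc model wins. Ties are broken by the canonical family order of
#' \code{variogramFamilies()}, making the result independent of the order in
#' which families are tried.
#'
#' @param empirical an \code{\link{EmpiricalVariogram}}
#' @param families families to try (default all five)
#' @return a \code{\link{VariogramFitSet}}
#' @export
selectVariogramModel <- function(empirical, families = variogramFamilies()) {
  families <- match.arg(families, variogramFamilies(), several.ok = TRUE)
  fits <- list()
  for (fam in intersect(variogramFamilies(), families)) {
    f <- tryCatch(fitVariogramModel(empirical, fam),
                  error = function(e) NULL)
    if (!is.null(f)) fits[[fam]] <- f
  }
  if (!length(fits)) stop("all variogram model fits failed")
  aicc <- vapply(fits, function(f) f@aicc, 0)
  if (all(is.na(aicc))) stop("AICc unavailable for every family")
  best <- which(aicc == min(aicc, na.rm = TRUE))[1]
  new("VariogramFitSet", fits = fits, best = as.integer(best))
}

#' @rdname bestFit
#' @export
setMethod("bestFit", "VariogramFitSet", function(x) x@fits[[x@best]])

#' @rdname fitTable
#' @export
setMethod("fitTable", "VariogramFitSet", function(x) {
  do.call(rbind, lapply(x@fits, function(f)
    data.frame(family = f@family, c0 = f@c0, c1 = f@c1, a = f@a,
               sill = f@sill, range_km = f@rangeKm, aicc = f@aicc,
               rss_weighted = f@rssWeighted, converged = f@converged,
               scaled_nugget = f@scaledNugget, scaled_range = f@scaledRange,
               row.names = NULL)))
})

setMethod("show", "VariogramFit", function(object) {
  cat(sprintf("VariogramFit [%s]: c0 = %.4g, c1 = %.4g, a = %.4g\n",
              object@family, object@c0, object@c1, object@a))
  cat(sprintf("  sill = %.4g, range = %.4g km, AICc = %.4g\n",
              object@sill, object@rangeKm, object@aicc))
  if (!is.na(object@scaledNugget))
    cat(sprintf("  scaled nugget c0/s2 = %.3f, scaled range = %.3f\n",
                object@scaledNugget, object@scaledRange))
})

setMethod("show", "VariogramFitSet", function(object) {
  cat("VariogramFitSet of", length(object@fits), "families; winner:",
      object@fits[[object@best]]@family, "\n")
  print(fitTable(object), digits = 4)
})
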