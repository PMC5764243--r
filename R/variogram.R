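autoInterval <- function(cutoffKm, candidates = c(0.25, 0.50, 0.75),
                         maxClasses = 12L) {
  nClass <- ceiling(cutoffKm / candidates - 1e-9)
  ok <- which(nClass <= maxClasses)
  # smallest qualifying interval gives the most classes (<= maxClasses)
  if (length(ok)) candidates[ok[1]] else candidates[length(candidates)]
}

classifyPairs <- function(d, edges, cutoffKm) {
  m <- length(edges) - 1L
  idx <- findInterval(d, edges, rightmost.closed = FALSE, left.open = FALSE)
  # half-open [lower, upper), final class closed at the cutoff
  idx[d >= edges[m + 1L] & d <= cutoffKm + 1e-12] <- m
  idx[d > cutoffKm + 1e-12] <- NA_integer_
  idx[idx > m] <- NA_integer_
  idx
}

#' @rdname buildClasses
#' @export
setMethod("buildClasses", "BenthicSite",
  function(x, intervalKm = NULL, cutoffKm = NULL, minPairs = 30L)
    buildClasses(stationCoords(x), intervalKm, cutoffKm, minPairs))

#' @rdname buildClasses
#' @export
setMethod("buildClasses", "matrix",
  function(x, intervalKm = NULL, cutoffKm = NULL, minPairs = 30L) {
  if (nrow(x) < 2) stop("at least 2 stations are required")
  if (!all(is.finite(x))) stop("non-finite coordinates")
  D <- as.matrix(dist(x[, 1:2, drop = FALSE]))
  hMax <- max(D)
  if (hMax <= 0) stop("all pairwise distances are zero")
  if (is.null(cutoffKm)) cutoffKm <- hMax / 2
  if (cutoffKm <= 0) stop("cutoffKm must be positive")
  cutoffKm <- min(cutoffKm, hMax)
  if (is.null(intervalKm)) intervalKm <- autoInterval(cutoffKm)
  if (intervalKm <= 0) stop("intervalKm must be positive")

  m <- max(1L, as.integer(ceiling(cutoffKm / intervalKm - 1e-9)))
  edges <- c(intervalKm * (0:(m - 1L)), cutoffKm)
  if (m == 1L) edges <- c(0, cutoffKm)
  centers <- (edges[-1] + edges[-(m + 1L)]) / 2

  n <- nrow(x)
  ab <- which(upper.tri(D), arr.ind = TRUE)   # a < b, column-major order
  d <- D[ab]
  cls <- classifyPairs(d, edges, cutoffKm)
  nDrop <- sum(is.na(cls))
  if (nDrop > 0)
    message(sprintf("%d pair(s) beyond the %.3f km cutoff excluded", nDrop, cutoffKm))
  pairs <- lapply(seq_len(m), function(k) {
    sel <- which(!is.na(cls) & cls == k)
    matrix(ab[sel, , drop = FALSE], ncol = 2,
           dimnames = list(NULL, c("a", "b")))
  })
  nPairs <- vapply(pairs, nrow, 0L)
  low <- which(nPairs < minPairs)
  if (length(low))
    warning(sprintf("distance class(es) with fewer than %d pairs: %s",
                    minPairs, paste(round(centers[low], 3), collapse = ", ")))
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  new("DistanceClassing", intervalKm = intervalKm, cutoffKm = cutoffKm,
      hMax = hMax, edges = edges, centers = centers, pairs = pairs,
      nPairs = nPairs, sampleIds = ids)
})

#' @rdname classCenters
#' @export
setMethod("classCenters", "DistanceClassing", function(x) x@centers)
#' @rdname pairCounts
#' @export
setMethod("pairCounts", "DistanceClassing", function(x) x@nPairs)

setMethod("show", "DistanceClassing", function(object) {
  cat(sprintf("DistanceClassing: %d classes of %.3g km up to %.3g km (hMax %.3g km)\n",
              length(object@centers), object@intervalKm, object@cutoffKm,
              object@hMax))
  cat("  pairs per class:", paste(object@nPairs, collapse = " "), "\n")
})

# per-pair summed-over-species squared Hellinger difference, halved
pairSemivariances <- function(H, pairs) {
  D2 <- as.matrix(dist(H))^2
  lapply(pairs, function(p) {
    if (nrow(p) == 0) numeric(0) else D2[p] / 2
  })
}

#' Empirical multivariate variogram over distance classes
#'
#' For each class \eqn{h}, \eqn{\gamma(h)} sums over species half the mean
#' squared difference of Hellinger abundances across the station pairs in the
#' class. The per-class standard error is the standard deviation over pairs of
#' the per-pair (species-summed, halved) squared difference divided by
#' \eqn{\sqrt{n_h}}. Empty classes are reported as \code{NA}.
#'
#' @param site a \code{\link{BenthicSite}} (or stations-by-species Hellinger
#'   matrix whose rownames match the classing)
#' @param classing a \code{\link{DistanceClassing}} built on the same stations
#' @return an \code{\link{EmpiricalVariogram}}
#' @export
empiricalVariogram <- function(site, classing) {
  H <- if (is(site, "BenthicSite")) hellinger(site) else as.matrix(site)
  ids <- rownames(H)
  if (!identical(ids, classing@sampleIds))
    stop("sample ids of the community and the distance classing differ")
  vals <- pairSemivariances(H, classing@pairs)
  gamma <- vapply(vals, function(v) if (length(v)) mean(v) else NA_real_, 0)
  se <- vapply(vals, function(v)
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_, 0)
  new("EmpiricalVariogram", classing = classing, gamma = gamma, se = se,
      s2 = totalVariance(H))
}

#' @rdname gammaValues
#' @export
setMethod("gammaValues", "EmpiricalVariogram", function(x) x@gamma)
#' @rdname classCenters
#' @export
setMethod("classCenters", "EmpiricalVariogram", function(x) x@classing@centers)
#' @rdname pairCounts
#' @export
setMethod("pairCounts", "EmpiricalVariogram", function(x) x@classing@nPairs)

setMethod("show", "EmpiricalVariogram", function(object) {
  cat("EmpiricalVariogram (s2 =", format(object@s2, digits = 4), ")\n")
  print(as.data.frame(object), digits = 4)
})

#' Variogram table
#'
#' @param x an \code{\link{EmpiricalVariogram}}
#' @param ... unused
#' @return data.frame with class_center_km, n_pairs, gamma, se
#' @export
as.data.frame.EmpiricalVariogram <- function(x, ...) {
  data.frame(class_center_km = x@classing@centers,
             n_pairs = x@classing@nPairs,
             gamma = x@gamma, se = x@se)
}
setMethod("as.data.frame", "EmpiricalVariogram", as.data.frame.EmpiricalVariogram)
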