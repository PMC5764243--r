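#' @importFrom graphics plot lines points mtext
NULL

#' Decompose the empirical variogram through an RDA model
#'
#' Per distance class, the fitted and residual matrices of the RDA are pushed
#' through the multivariate variogram, giving \eqn{\gamma_{fit}(h)} and
#' \eqn{\gamma_{res}(h)}; the cross term is the remainder
#' \eqn{\gamma - \gamma_{fit} - \gamma_{res}} (twice the per-class covariance
#' of fitted and residual differences). The identity holds per class at
#' machine precision by construction of the three pair sums.
#'
#' @param model an \code{\link{RDAModel}}
#' @param classing a \code{\link{DistanceClassing}} on the same stations
#' @return an \code{\link{MSOResult}} with the component table filled and the
#'   diagnostic columns NA (see \code{\link{mso}} for the full set)
#' @export
msoDecompose <- function(model, classing) {
  if (!identical(model@sampleIds, classing@sampleIds))
    stop("sample ids of the RDA model and the distance classing differ")
  gAll <- pairSemivariances(model@Y, classing@pairs)
  gFit <- pairSemivariances(model@fitted, classing@pairs)
  gRes <- pairSemivariances(model@residuals, classing@pairs)
  mn <- function(v) if (length(v)) mean(v) else NA_real_
  gamma <- vapply(gAll, mn, 0)
  fit <- vapply(gFit, mn, 0)
  res <- vapply(gRes, mn, 0)
  seOf <- function(vs) vapply(vs, function(v)
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_, 0)
  se <- seOf(gAll)
  seRes <- seOf(gRes)
  tab <- data.frame(
    class_center_km = classing@centers,
    n_pairs = classing@nPairs,
    gamma = gamma, gamma_fit = fit, gamma_res = res,
    gamma_cross = gamma - fit - res, se = se, se_res = seRes,
    ci_lower = NA_real_, ci_upper = NA_real_, scale_flag = NA,
    mantel_r = NA_real_, mantel_p = NA_real_, mantel_sig = NA)
  new("MSOResult", classing = classing, table = tab, alpha = NA_real_,
      nPerm = NA_real_, mTests = NA_integer_, scaleDependent = NA,
      stationarityOk = NA, stationaritySlope = NA_real_,
      stationarityCI = c(NA_real_, NA_real_))
}

#' Bonferroni scale-dependence envelope
#'
#' Builds the Bonferroni-corrected point confidence interval
#' \eqn{\gamma(h) \pm z_{1-\alpha/(2m)} \cdot se(\gamma(h))} and flags classes
#' where \eqn{\gamma_{fit} + \gamma_{res}} falls outside it (equivalently,
#' where the cross term differs detectably from zero). \code{m} counts the
#' classes with at least \code{minPairs} pairs; smaller classes are excluded
#' with a warning. The relationship is called scale-dependent when any class
#' is flagged.
#'
#' @param msoResult output of \code{\link{msoDecompose}}
#' @param alpha family-wise level (default 0.05)
#' @param minPairs smallest class entering the correction (default 5)
#' @return the updated \code{\link{MSOResult}}
#' @export
scaleDependenceTest <- function(msoResult, alpha = 0.05, minPairs = 5L) {
  tab <- msoResult@table
  usable <- !is.na(tab$gamma) & tab$n_pairs >= max(2L, minPairs)
  if (any(!usable & tab$n_pairs > 0))
    warning("class(es) with too few pairs excluded from the Bonferroni correction")
  m <- sum(usable)
  if (m < 1) stop("no usable classes for the envelope")
  z <- qnorm(1 - alpha / (2 * m))
  tab$ci_lower <- ifelse(usable, tab$gamma - z * tab$se, NA_real_)
  tab$ci_upper <- ifelse(usable, tab$gamma + z * tab$se, NA_real_)
  s <- tab$gamma_fit + tab$gamma_res
  tab$scale_flag <- ifelse(usable, s < tab$ci_lower | s > tab$ci_upper, NA)
  out <- msoResult
  out@table <- tab
  out@alpha <- alpha
  out@mTests <- as.integer(m)
  out@scaleDependent <- any(tab$scale_flag, na.rm = TRUE)
  out
}

#' Per-class Mantel tests of residual spatial autocorrelation
#'
#' For each distance class, the Mantel statistic is the Pearson correlation
#' (over all station pairs) between the squared Euclidean residual distances
#' and the binary membership of the pair in that class. Least-squares
#' residuals are not exchangeable — the projection makes residual distances
#' systematically depend on the pair's design configuration — so the null
#' distribution is generated by Freedman-Lane permutation: station rows of
#' the residual matrix are permuted and re-projected through the model's
#' residual-maker before the distances are recomputed, so every permuted
#' replicate carries the same fitted-model structure as the observed one.
#' P-values are two-sided; significance is declared at \eqn{\alpha / m}
#' (Bonferroni over the \code{m} tested classes). Classes with fewer than
#' \code{minPairs} pairs are skipped with a warning.
#'
#' @param model an \code{\link{RDAModel}}
#' @param classing a \code{\link{DistanceClassing}} on the same stations
#' @param alpha family-wise level
#' @param nPerm number of permutations (>= 99)
#' @param minPairs smallest testable class
#' @return data.frame with class_center_km, mantel_r, mantel_p, mantel_sig
#' @export
mantelResidualTests <- function(model, classing, alpha = 0.05, nPerm = 999,
                                minPairs = 5L) {
  if (nPerm < 99) stop("nPerm must be at least 99")
  if (!identical(model@sampleIds, classing@sampleIds))
    stop("sample ids of the RDA model and the distance classing differ")
  R <- model@residuals
  n <- nrow(R)
  lt <- lower.tri(diag(n))
  npair <- sum(lt)
  memberOf <- matrix(0, npair, length(classing@pairs))
  linIdx <- matrix(NA_integer_, n, n)
  linIdx[lt] <- seq_len(npair)
  for (k in seq_along(classing@pairs)) {
    p <- classing@pairs[[k]]
    if (nrow(p)) memberOf[linIdx[cbind(p[, 2], p[, 1])], k] <- 1  # (b, a): b > a
  }
  testable <- classing@nPairs >= minPairs
  if (any(!testable))
    warning("class(es) with fewer than ", minPairs, " pairs skipped in Mantel tests")
  m <- sum(testable)
  out <- data.frame(class_center_km = classing@centers,
                    mantel_r = NA_real_, mantel_p = NA_real_, mantel_sig = NA)
  if (m == 0) return(out)

  Ms <- scale(memberOf[, testable, drop = FALSE])
  corStat <- function(Rm) {
    d <- as.matrix(dist(Rm))^2
    dv <- d[lt]
    if (sd(dv) == 0) return(rep(NA_real_, m))
    drop(crossprod(Ms, scale(dv))) / (npair - 1)
  }
  obs <- corStat(R)
  if (anyNA(obs)) {
    warning("degenerate residual distances; Mantel tests skipped")
    return(out)
  }
  # residual-maker of the fitted design (with intercept)
  X <- cbind(rep(1, n), model@design)
  ImP <- diag(n) - X %*% solve(crossprod(X), t(X))
  exceed <- rep(0L, m)
  for (b in seq_len(nPerm)) {
    rp <- corStat(ImP %*% R[sample.int(n), , drop = FALSE])
    exceed <- exceed + as.integer(abs(rp) >= abs(obs) - 1e-15)
  }
  pv <- (exceed + 1) / (nPerm + 1)
  out$mantel_r[testable] <- obs
  out$mantel_p[testable] <- pv
  out$mantel_sig[testable] <- pv < alpha / m
  out
}

#' Residual stationarity check
#'
#' Fits a weighted least-squares line to \eqn{\gamma_{res}(h)} over the upper
#' half of the distance classes, weighting each class by the inverse squared
#' standard error of its \eqn{\gamma_{res}} estimate (fixed-effect
#' meta-regression, so the slope's 95\% interval uses the known per-class
#' precisions rather than the few regression degrees of freedom). The
#' residuals are considered stationary when that interval covers zero; a
#' rising residual variogram at large distances indicates a spatially
#' structured driver missing from the model.
#'
#' @param msoResult output of \code{\link{msoDecompose}}
#' @return the updated \code{\link{MSOResult}} with
#'   \code{stationarityOk}, \code{stationaritySlope}, \code{stationarityCI}
#' @export
stationarityCheck <- function(msoResult) {
  tab <- msoResult@table
  ok <- !is.na(tab$gamma_res) & !is.na(tab$se_res) & tab$se_res > 0
  if (sum(ok) < 4) stop("at least 4 usable classes are required")
  tab <- tab[ok, ]
  mTot <- nrow(tab)
  upper <- tab[seq(floor(mTot / 2) + 1, mTot), ]
  if (nrow(upper) < 3) upper <- tab[seq(mTot - 2, mTot), ]
  w <- 1 / upper$se_res^2
  x <- upper$class_center_km
  y <- upper$gamma_res
  xbar <- sum(w * x) / sum(w)
  ybar <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xbar)^2)
  slope <- sum(w * (x - xbar) * y) / sxx
  # per-class se's ignore shared-station correlation between pairs, so allow
  # multiplicative overdispersion (fixed-effect meta-regression correction)
  k <- nrow(upper)
  resid <- y - ybar - slope * (x - xbar)
  phi <- if (k > 2) max(1, sum(w * resid^2) / (k - 2)) else 1
  seSlope <- sqrt(phi / sxx)
  ci <- slope + c(-1, 1) * qnorm(0.975) * seSlope
  out <- msoResult
  out@stationaritySlope <- slope
  out@stationarityCI <- ci
  out@stationarityOk <- ci[1] <= 0 && ci[2] >= 0
  out
}

#' Full multiscale ordination with diagnostics
#'
#' Runs \code{\link{msoDecompose}}, \code{\link{scaleDependenceTest}},
#' \code{\link{mantelResidualTests}} and \code{\link{stationarityCheck}} in
#' sequence.
#'
#' @param model an \code{\link{RDAModel}}
#' @param classing a \code{\link{DistanceClassing}}
#' @param alpha family-wise level for both Bonferroni procedures
#' @param nPerm Mantel permutations
#' @param seed optional integer seed for the permutations
#' @return a complete \code{\link{MSOResult}}
#' @export
mso <- function(model, classing, alpha = 0.05, nPerm = 999, seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  out <- msoDecompose(model, classing)
  out <- scaleDependenceTest(out, alpha = alpha)
  mt <- mantelResidualTests(model, classing, alpha = alpha, nPerm = nPerm)
  out@table$mantel_r <- mt$mantel_r
  out@table$mantel_p <- mt$mantel_p
  out@table$mantel_sig <- mt$mantel_sig
  out@nPerm <- nPerm
  out <- stationarityCheck(out)
  out
}

setMethod("show", "MSOResult", function(object) {
  cat("MSOResult over", length(object@classing@centers), "distance classes\n")
  print(object@table, digits = 4)
  if (!is.na(object@scaleDependent))
    cat("scale-dependent:", object@scaleDependent,
        "| residual stationarity ok:", object@stationarityOk, "\n")
})

#' @rdname classCenters
#' @export
setMethod("classCenters", "MSOResult", function(x) x@classing@centers)

#' MSO table
#' @param x an \code{\link{MSOResult}}
#' @param ... unused
#' @return the per-class data.frame
#' @export
as.data.frame.MSOResult <- function(x, ...) x@table
setMethod("as.data.frame", "MSOResult", as.data.frame.MSOResult)

#' Variogram diagnostic plot of an MSO result
#'
#' Empirical variogram with its Bonferroni envelope (lines), fitted variogram
#' (diamonds), residual variogram (squares, filled where the class Mantel
#' test is significant), and crosshairs at the fitted+residual sum.
#'
#' @param x an \code{\link{MSOResult}}
#' @param y unused
#' @param ... passed to \code{plot}
#' @return invisibly, \code{x}
#' @export
setMethod("plot", signature(x = "MSOResult", y = "missing"), function(x, y, ...) {
  tab <- x@table
  ylim <- range(c(tab$gamma, tab$gamma_fit, tab$gamma_res,
                  tab$ci_lower, tab$ci_upper), na.rm = TRUE)
  plot(tab$class_center_km, tab$gamma, type = "b", pch = 16, ylim = ylim,
       xlab = "distance class (km)", ylab = "semivariance (Hellinger^2)", ...)
  graphics::lines(tab$class_center_km, tab$ci_lower, lty = 2)
  graphics::lines(tab$class_center_km, tab$ci_upper, lty = 2)
  graphics::points(tab$class_center_km, tab$gamma_fit, pch = 5)
  sig <- isTRUE_vec(tab$mantel_sig)
  graphics::points(tab$class_center_km, tab$gamma_res, pch = ifelse(sig, 15, 0))
  graphics::points(tab$class_center_km, tab$gamma_fit + tab$gamma_res, pch = 3)
  graphics::mtext(paste(tab$n_pairs, collapse = "  "), side = 1, line = 3,
                  cex = 0.7)
  invisible(x)
})

isTRUE_vec <- function(v) !is.na(v) & v
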