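#' Within/between-province variogram decomposition
#'
#' The modified multiscale ordination: geographic distance classes are
#' replaced by two "distance" classes — station pairs within the same
#' province (class \code{within}) and pairs in different provinces
#' (\code{between}) — plus an \code{overall} row over all pairs. For each
#' class the empirical, fitted and residual semivariances are computed from
#' the RDA decomposition exactly as for geographic classes.
#'
#' @param model an \code{\link{RDAModel}}
#' @param provinceLabels per-station labels in the model's station order
#'   (factor or character), e.g. \code{provinces(site)}
#' @return a \code{\link{PartitionResult}} (nugget adjustment not yet
#'   applied; see \code{\link{nuggetAdjustedFractions}})
#' @export
withinBetweenDecompose <- function(model, provinceLabels) {
  lab <- as.character(provinceLabels)
  n <- length(model@sampleIds)
  if (length(lab) != n) stop("one province label per station is required")
  if (any(is.na(lab))) stop("every station needs a province label")
  sizes <- table(lab)
  if (any(sizes < 2))
    warning("province(s) with a single station contribute no within pairs: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
  ab <- which(upper.tri(diag(n)), arr.ind = TRUE)
  within <- lab[ab[, 1]] == lab[ab[, 2]]
  pairSets <- list(
    within = matrix(ab[within, , drop = FALSE], ncol = 2),
    between = matrix(ab[!within, , drop = FALSE], ncol = 2),
    overall = ab)
  comp <- function(M) vapply(pairSemivariances(M, pairSets), function(v)
    if (length(v)) mean(v) else NA_real_, 0)
  gamma <- comp(model@Y)
  fit <- comp(model@fitted)
  res <- comp(model@residuals)
  tab <- data.frame(
    class = names(pairSets),
    n_pairs = vapply(pairSets, nrow, 0L),
    gamma = gamma, gamma_fit = fit, gamma_res = res,
    gamma_cross = gamma - fit - res,
    adjusted_res = NA_real_, explained_adjusted = NA_real_,
    negative_flag = NA, row.names = NULL)
  new("PartitionResult", table = tab, c0 = NA_real_, s2 = model@s2)
}

#' Nugget-adjusted explained-variance fractions
#'
#' Subtracts the site-level nugget \code{c0} (small-scale variance below the
#' sampling interval, from the selected variogram model) from the residual
#' semivariance of each class and recomputes the explained fraction as
#' \eqn{\gamma_{fit} / (\gamma_{fit} + (\gamma_{res} - c_0))}. Where the
#' nugget exceeds the residual, the negative adjusted residual is reported
#' verbatim, the fraction set to 1 and the class flagged rather than
#' silently capped.
#'
#' @param partition a \code{\link{PartitionResult}}
#' @param c0 nonnegative nugget estimate (Hellinger^2 units)
#' @return the updated \code{\link{PartitionResult}}
#' @export
nuggetAdjustedFractions <- function(partition, c0) {
  if (!is.finite(c0) || c0 < 0) stop("c0 must be a nonnegative number")
  tab <- partition@table
  tab$adjusted_res <- tab$gamma_res - c0
  neg <- tab$adjusted_res < 0
  tab$negative_flag <- neg
  tab$explained_adjusted <- ifelse(
    neg, 1, tab$gamma_fit / (tab$gamma_fit + tab$adjusted_res))
  out <- partition
  out@table <- tab
  out@c0 <- c0
  out
}

setMethod("show", "PartitionResult", function(object) {
  cat("PartitionResult (within/between provinces)")
  if (!is.na(object@c0)) cat(sprintf(", nugget c0 = %.4f", object@c0))
  cat("\n")
  print(object@table, digits = 4)
})

#' Partition table
#' @param x a \code{\link{PartitionResult}}
#' @param ... unused
#' @return the class-by-statistics data.frame
#' @export
as.data.frame.PartitionResult <- function(x, ...) x@table
setMethod("as.data.frame", "PartitionResult", as.data.frame.PartitionResult)
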