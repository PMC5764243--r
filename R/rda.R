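#' Candidate explanatory variables for a site
#'
#' Continuous covariates are z-standardized; the categorical province labels
#' become one binary 1/0 indicator column per province (or per merged group
#' when a merge map is supplied). No reference level is dropped: each
#' indicator is its own candidate, and collinearity of the full set is
#' resolved by the rank-deficiency rule in \code{\link{fitRDA}}.
#'
#' @param site a \code{\link{BenthicSite}}
#' @param useEnv include the continuous covariates
#' @param useProvinces include province indicators
#' @param mergeMap optional named character vector mapping provinces to merged
#'   group labels (see \code{\link{mergeProvinces}})
#' @return numeric matrix of candidate columns (stations in rows)
#' @export
candidateMatrix <- function(site, useEnv = TRUE, useProvinces = TRUE,
                            mergeMap = NULL) {
  out <- NULL
  if (useEnv) {
    ev <- envCovariates(site)
    keep <- vapply(ev, function(v) sd(v) > 0, TRUE)
    ev <- ev[, keep, drop = FALSE]
    if (ncol(ev)) out <- scale(as.matrix(ev))
  }
  if (useProvinces) {
    prov <- as.character(provinces(site))
    if (!is.null(mergeMap)) {
      bad <- setdiff(unique(prov), names(mergeMap))
      if (length(bad)) stop("mergeMap lacks province(s): ", paste(bad, collapse = ", "))
      prov <- unname(mergeMap[prov])
    }
    lev <- sort(unique(prov))
    ind <- sapply(lev, function(l) as.numeric(prov == l))
    colnames(ind) <- paste0("province_", lev)
    ind <- ind[, apply(ind, 2, sd) > 0, drop = FALSE]
    out <- if (is.null(out)) ind else cbind(out, ind)
  }
  if (is.null(out) || ncol(out) == 0) stop("no usable candidate variables")
  rownames(out) <- colnames(site)
  out
}

#' Redundancy analysis of Hellinger abundances
#'
#' Each column-centered Hellinger species profile is regressed by ordinary
#' least squares on the centered design (equivalent to including an
#' intercept). Canonical eigenvalues come from the eigen-decomposition of the
#' fitted-value covariance; their sum over \code{s2} is the explained
#' fraction. Rank-deficient designs have aliased columns dropped with a
#' warning.
#'
#' @param site a \code{\link{BenthicSite}}
#' @param design numeric matrix of explanatory columns (stations in rows),
#'   e.g. from \code{\link{candidateMatrix}}; \code{NULL} fits the
#'   intercept-only null model
#' @param quiet suppress the rank-deficiency warning
#' @return an \code{\link{RDAModel}}
#' @export
fitRDA <- function(site, design = NULL, quiet = FALSE) {
  H <- hellinger(site)
  n <- nrow(H)
  Y <- scale(H, center = TRUE, scale = FALSE)
  attr(Y, "scaled:center") <- NULL
  s2 <- sum(Y^2) / (n - 1)
  terms <- character(0)
  dropped <- character(0)
  if (is.null(design) || ncol(as.matrix(design)) == 0) {
    X <- matrix(numeric(0), nrow = n, ncol = 0)
    fitted <- matrix(0, n, ncol(Y), dimnames = dimnames(Y))
  } else {
    X <- as.matrix(design)
    if (nrow(X) != n) stop("design rows must match the stations")
    if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
    terms <- colnames(X)
    if (n <= ncol(X) + 1)
      stop("more design columns than the sample size supports")
    Xc <- scale(X, center = TRUE, scale = FALSE)
    qrX <- qr(Xc, tol = 1e-9)
    if (qrX$rank < ncol(Xc)) {
      dropped <- colnames(Xc)[qrX$pivot[seq(qrX$rank + 1, ncol(Xc))]]
      if (!quiet)
        warning("rank-deficient design; dropping: ",
                paste(dropped, collapse = ", "))
      Xc <- Xc[, setdiff(colnames(Xc), dropped), drop = FALSE]
      terms <- colnames(Xc)
      qrX <- qr(Xc, tol = 1e-9)
    }
    fitted <- if (ncol(Xc)) qr.fitted(qrX, Y) else
      matrix(0, n, ncol(Y), dimnames = dimnames(Y))
    X <- Xc
  }
  residual <- Y - fitted
  ev <- eigen(crossprod(fitted) / (n - 1), symmetric = TRUE,
              only.values = TRUE)$values
  ev <- ev[ev > max(ev[1], 0) * 1e-12 & ev > 0]
  ev <- sort(ev, decreasing = TRUE)
  expl <- sum(diag(crossprod(fitted))) / (n - 1) / s2
  expl <- min(max(expl, 0), 1)
  K <- length(terms) + 2  # intercept + error variance
  aicc <- if (n - K - 1 > 0)
    aiccLeastSquares(sum(residual^2), n, length(terms) + 1) else NA_real_
  new("RDAModel", design = X, terms = terms, dropped = dropped,
      Y = Y, fitted = fitted, residuals = residual,
      eigenvalues = ev, explainedFraction = expl, aicc = aicc, s2 = s2,
      sampleIds = rownames(H))
}

#' @rdname explainedFraction
#' @export
setMethod("explainedFraction", "RDAModel", function(x) x@explainedFraction)

setMethod("show", "RDAModel", function(object) {
  cat(sprintf("RDAModel: %d stations, %d taxa, %d explanatory column(s)\n",
              nrow(object@Y), ncol(object@Y), length(object@terms)))
  cat(sprintf("  explained fraction = %.3f of s2 = %.4f; AICc = %.2f\n",
              object@explainedFraction, object@s2, object@aicc))
  if (length(object@dropped))
    cat("  dropped (aliased):", paste(object@dropped, collapse = ", "), "\n")
})

#' AICc of an RDA model
#'
#' \code{n log(RSS/n) + 2K + 2K(K+1)/(n-K-1)} with the residual sum of
#' squares pooled across species, \code{n} = stations and \code{K} = design
#' columns + 2 (intercept and error variance).
#'
#' @param model an \code{\link{RDAModel}}
#' @return scalar AICc
#' @export
aiccRDA <- function(model) {
  n <- nrow(model@Y)
  aiccLeastSquares(sum(model@residuals^2), n, length(model@terms) + 1)
}

#' Forward selection of explanatory variables by conditional eigenvalue
#'
#' At each step the candidate adding the most explained community variance is
#' appended (ties broken by column name order) and the step's AICc recorded;
#' selection stops when no candidate adds variance or the sample size cannot
#' support another column. The returned model truncates the greedy path at
#' its AICc minimum; the empty (intercept-only) model is a valid outcome.
#'
#' @param site a \code{\link{BenthicSite}}
#' @param candidates numeric candidate matrix, e.g.
#'   \code{\link{candidateMatrix}} output
#' @return an \code{\link{RDASelection}}
#' @export
forwardSelect <- function(site, candidates) {
  candidates <- as.matrix(candidates)
  if (ncol(candidates) < 1) stop("at least one candidate is required")
  if (is.null(colnames(candidates)))
    colnames(candidates) <- paste0("V", seq_len(ncol(candidates)))
  n <- ncol(site)
  null <- fitRDA(site, NULL)
  trace <- data.frame(step = 0L, variable = "(none)", eigenvalue = 0,
                      cumulative = 0, aicc = null@aicc,
                      stringsAsFactors = FALSE)
  chosen <- character(0)
  remaining <- colnames(candidates)
  current <- 0
  while (length(remaining) > 0 && n - (length(chosen) + 1 + 2) - 1 > 0) {
    gains <- vapply(remaining, function(v) {
      m <- suppressWarnings(
        fitRDA(site, candidates[, c(chosen, v), drop = FALSE], quiet = TRUE))
      m@explainedFraction - current
    }, 0)
    ord <- order(-gains, remaining)   # ties by name order
    bestVar <- remaining[ord[1]]
    if (gains[ord[1]] <= 1e-12) break
    chosen <- c(chosen, bestVar)
    remaining <- setdiff(remaining, bestVar)
    m <- suppressWarnings(
      fitRDA(site, candidates[, chosen, drop = FALSE], quiet = TRUE))
    current <- m@explainedFraction
    trace <- rbind(trace, data.frame(
      step = length(chosen), variable = bestVar,
      eigenvalue = gains[ord[1]], cumulative = current,
      aicc = m@aicc, stringsAsFactors = FALSE))
  }
  kBest <- trace$step[which.min(trace$aicc)]
  selected <- if (kBest == 0) character(0) else chosen[seq_len(kBest)]
  model <- suppressWarnings(fitRDA(
    site,
    if (length(selected)) candidates[, selected, drop = FALSE] else NULL,
    quiet = TRUE))
  new("RDASelection", model = model, trace = trace, selected = selected)
}

setMethod("show", "RDASelection", function(object) {
  cat("RDASelection:", length(object@selected), "variable(s) retained\n")
  print(object@trace, digits = 4)
})

rdaProvinceAicc <- function(site, prov, groups) {
  design <- tryCatch(
    candidateMatrix(site, useEnv = FALSE, useProvinces = TRUE,
                    mergeMap = groups),
    error = function(e) NULL)   # a single merged group = intercept-only model
  m <- suppressWarnings(fitRDA(site, design, quiet = TRUE))
  list(model = m, aicc = m@aicc, explained = m@explainedFraction)
}

#' Greedy agglomerative search for merged province groups
#'
#' Starting from singleton groups, repeatedly merges the pair of groups whose
#' merger least decreases the explained community variance, evaluating each
#' configuration's province-only RDA AICc; the configuration with minimum
#' AICc along the merge path is returned. Provinces with fewer than
#' \code{minStations} stations are first absorbed into the group with the
#' nearest Hellinger composition centroid (with a warning).
#'
#' @param site a \code{\link{BenthicSite}}
#' @param minStations smallest province size kept as its own starting group
#' @return a \code{\link{ProvinceMerge}}
#' @export
mergeProvinces <- function(site, minStations = 2L) {
  prov <- as.character(provinces(site))
  levs <- sort(unique(prov))
  if (length(levs) < 2) stop("at least 2 provinces are required")
  groups <- setNames(levs, levs)   # province -> group label
  H <- hellinger(site)

  centroid <- function(g) colMeans(H[groups[prov] == g, , drop = FALSE])
  sizes <- table(factor(groups[prov], levels = unique(groups)))
  small <- names(sizes)[sizes < minStations]
  for (g in small) {
    others <- setdiff(unique(groups), g)
    if (!length(others)) break
    d <- vapply(others, function(o) sum((centroid(g) - centroid(o))^2), 0)
    tgt <- others[order(d, others)][1]
    warning(sprintf("province group '%s' has < %d stations; merged into '%s'",
                    g, minStations, tgt))
    groups[groups == g] <- tgt
  }

  canon <- function(gr) { # stable group labels: concatenated member provinces
    lab <- vapply(unique(gr), function(g)
      paste(sort(names(gr)[gr == g]), collapse = ""), "")
    setNames(lab[match(gr, unique(gr))], names(gr))
  }
  groups <- canon(groups)
  ev <- rdaProvinceAicc(site, prov, groups)
  path <- data.frame(nGroups = length(unique(groups)),
                     explainedFraction = ev$explained, aicc = ev$aicc,
                     labels = paste(sort(unique(groups)), collapse = "|"),
                     stringsAsFactors = FALSE)
  bestMap <- groups
  bestAicc <- ev$aicc
  while (length(unique(groups)) > 1) {
    gl <- sort(unique(groups))
    cand <- utils::combn(gl, 2)
    expl <- apply(cand, 2, function(pr) {
      gr <- groups
      gr[gr == pr[2]] <- pr[1]
      rdaProvinceAicc(site, prov, canon(gr))$explained
    })
    pick <- order(-expl, cand[1, ], cand[2, ])[1]
    groups[groups == cand[2, pick]] <- cand[1, pick]
    groups <- canon(groups)
    ev <- rdaProvinceAicc(site, prov, groups)
    path <- rbind(path, data.frame(
      nGroups = length(unique(groups)), explainedFraction = ev$explained,
      aicc = ev$aicc, labels = paste(sort(unique(groups)), collapse = "|"),
      stringsAsFactors = FALSE))
    if (is.finite(ev$aicc) && (!is.finite(bestAicc) || ev$aicc < bestAicc)) {
      bestAicc <- ev$aicc
      bestMap <- groups
    }
  }
  new("ProvinceMerge", mergeMap = bestMap, aicc = bestAicc, path = path)
}

setMethod("show", "ProvinceMerge", function(object) {
  cat("ProvinceMerge:", length(unique(object@mergeMap)), "group(s), AICc",
      format(object@aicc, digits = 6), "\n")
  grp <- split(names(object@mergeMap), object@mergeMap)
  for (g in names(grp))
    cat(" ", g, "<-", paste(grp[[g]], collapse = " + "), "\n")
})
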