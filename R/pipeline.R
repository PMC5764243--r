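#' Run the full site analysis
#'
#' Orchestrates, in order: load or simulate the site, Hellinger transform,
#' distance classing, empirical variogram, five-family variogram fit with
#' AICc selection, province merge search plus forward selection of
#' explanatory variables, multiscale-ordination diagnostics, and the
#' within/between-province partition with nugget adjustment. Any stage
#' failure aborts with the stage name; stages completed so far are kept in
#' the partially filled report.
#'
#' @param site a \code{\link{BenthicSite}}, or \code{NULL} to simulate from
#'   \code{simConfig}
#' @param simConfig a \code{\link{syntheticConfig}} used when \code{site} is
#'   NULL
#' @param intervalKm distance-class width; NULL selects automatically
#' @param alpha family-wise level for the MSO diagnostics
#' @param nPerm Mantel permutations
#' @param seed integer seed recorded in the report and driving all
#'   randomness of the diagnostics
#' @param mergeSearch run \code{\link{mergeProvinces}} before selection
#' @param useEnv offer the continuous covariates as candidates
#' @param candidates optional explicit candidate matrix (stations in rows),
#'   overriding the default construction from covariates and provinces
#' @return a list of class \code{"siteReport"}: objects from every stage plus
#'   a flat \code{summary} list
#' @export
runSite <- function(site = NULL, simConfig = NULL, intervalKm = NULL,
                    alpha = 0.05, nPerm = 999, seed = 1L,
                    mergeSearch = TRUE, useEnv = TRUE, candidates = NULL) {
  report <- list(seed = seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (is.null(site)) {
    if (is.null(simConfig)) stop("provide a site or a simConfig")
    sim <- stage("simulate", simulateSite(simConfig))
    site <- sim$site
    report$truth <- sim$truth
  }
  report$site <- site
  set.seed(seed)

  report$classing <- stage("classes",
    suppressMessages(buildClasses(site, intervalKm = intervalKm)))
  report$variogram <- stage("variogram",
    empiricalVariogram(site, report$classing))
  report$fits <- stage("variogram_models",
    selectVariogramModel(report$variogram))
  best <- bestFit(report$fits)

  merge <- NULL
  if (is.null(candidates) && mergeSearch && nlevels(provinces(site)) >= 2)
    merge <- stage("merge_search",
      suppressWarnings(mergeProvinces(site)))
  report$merge <- merge
  cand <- if (!is.null(candidates)) candidates else
    stage("candidates", candidateMatrix(
      site, useEnv = useEnv, useProvinces = TRUE,
      mergeMap = if (is.null(merge)) NULL else merge@mergeMap))
  report$selection <- stage("forward_selection", forwardSelect(site, cand))
  model <- report$selection@model

  report$mso <- stage("mso",
    suppressWarnings(mso(model, report$classing, alpha = alpha,
                         nPerm = nPerm, seed = seed)))
  part <- stage("partition",
    suppressWarnings(withinBetweenDecompose(model, provinces(site))))
  report$partition <- stage("nugget_adjustment",
    nuggetAdjustedFractions(part, best@c0))

  ovr <- report$partition@table[report$partition@table$class == "overall", ]
  report$summary <- list(
    n_stations = ncol(site), n_species = nrow(site),
    s2 = totalVariance(site),
    interval_km = report$classing@intervalKm,
    cutoff_km = report$classing@cutoffKm,
    h_max_km = report$classing@hMax,
    selected_family = best@family,
    c0 = best@c0, c1 = best@c1, a = best@a,
    sill = best@sill, range_km = best@rangeKm,
    scaled_nugget = best@scaledNugget, scaled_range = best@scaledRange,
    selected_variables = report$selection@selected,
    explained_fraction = explainedFraction(model),
    explained_adjusted_overall = ovr$explained_adjusted,
    negative_flag_overall = ovr$negative_flag,
    scale_dependent = report$mso@scaleDependent,
    stationarity_ok = report$mso@stationarityOk,
    any_mantel_significant = any(report$mso@table$mantel_sig, na.rm = TRUE),
    seed = seed)
  class(report) <- "siteReport"
  report
}

#' @export
print.siteReport <- function(x, ...) {
  s <- x$summary
  cat("Site analysis report (seed", s$seed, ")\n")
  cat(sprintf("  %d stations, %d taxa, s2 = %.4f\n",
              s$n_stations, s$n_species, s$s2))
  cat(sprintf("  variogram: %s model, c0 = %.3f, sill = %.3f, range = %.3f km\n",
              s$selected_family, s$c0, s$sill, s$range_km))
  cat(sprintf("  scaled nugget = %.3f, scaled range = %.3f\n",
              s$scaled_nugget, s$scaled_range))
  cat("  selected variables:",
      if (length(s$selected_variables)) paste(s$selected_variables, collapse = ", ")
      else "(none)", "\n")
  cat(sprintf("  explained fraction = %.3f; nugget-adjusted overall = %.3f\n",
              s$explained_fraction, s$explained_adjusted_overall))
  cat(sprintf("  diagnostics: scale-dependent = %s; stationarity ok = %s; Mantel sig = %s\n",
              s$scale_dependent, s$stationarity_ok, s$any_mantel_significant))
  invisible(x)
}

#' Write a site report to disk
#'
#' Writes the stage tables as CSV (variogram, model fits, selection trace,
#' MSO table, partition table), the flat summary as JSON, and a manifest of
#' the files produced.
#'
#' @param report a \code{\link{runSite}} report
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest data.frame
#' @export
writeSiteReport <- function(report, dir) {
  stopifnot(inherits(report, "siteReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(dir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
  }
  put(as.data.frame(report$variogram), "variogram.csv")
  put(fitTable(report$fits), "variogram_fits.csv")
  put(report$selection@trace, "selection_trace.csv")
  put(as.data.frame(report$mso), "mso.csv")
  put(as.data.frame(report$partition), "partition.csv")
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "summary.json")
  manifest <- data.frame(file = files, stringsAsFactors = FALSE)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
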