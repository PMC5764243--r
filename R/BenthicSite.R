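#' Construct a BenthicSite from counts and a station table
#'
#' Stations with a zero count total are excluded with a warning (the Hellinger
#' transform is undefined for an empty sample), and species observed in no
#' retained station are dropped.
#'
#' @param counts stations-by-species numeric matrix (rownames = station ids)
#' @param stations data.frame with rownames matching the count rows and
#'   columns \code{x_km}, \code{y_km}, \code{province}, plus any continuous
#'   covariates
#' @return a \code{\link{BenthicSite}}
#' @examples
#' cts <- matrix(c(4, 1, 0, 2, 3, 5), 3, 2,
#'               dimnames = list(paste0("S", 1:3), c("spA", "spB")))
#' st <- data.frame(x_km = c(0, 1, 2), y_km = 0, province = c("A", "A", "B"),
#'                  row.names = rownames(cts))
#' BenthicSite(cts, st)
#' @export
BenthicSite <- function(counts, stations) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have station ids as rownames")
  if (anyDuplicated(rownames(counts))) stop("duplicate station ids in counts")
  if (!is.numeric(counts)) stop("non-numeric abundance values")
  if (any(!is.finite(counts))) stop("non-finite abundance values")
  if (any(counts < 0)) stop("negative abundance values")
  stations <- as.data.frame(stations)
  if (!all(rownames(counts) %in% rownames(stations)))
    stop("every count row needs a matching station row")
  stations <- stations[rownames(counts), , drop = FALSE]

  keep <- rowSums(counts) > 0
  if (!all(keep)) {
    warning(sprintf("excluding %d station(s) with zero total abundance: %s",
                    sum(!keep), paste(rownames(counts)[!keep], collapse = ", ")))
    counts <- counts[keep, , drop = FALSE]
    stations <- stations[keep, , drop = FALSE]
  }
  if (nrow(counts) == 0) stop("no stations with positive abundance")
  spKeep <- colSums(counts) > 0
  if (!all(spKeep)) counts <- counts[, spKeep, drop = FALSE]
  if (ncol(counts) < 1) stop("no species observed")

  hel <- hellingerTransform(counts)
  cd <- S4Vectors::DataFrame(stations)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = t(counts), hellinger = t(hel)), colData = cd)
  new("BenthicSite", se)
}

#' Hellinger transformation of an abundance matrix
#'
#' Square root of the within-sample relative abundance of each species,
#' \eqn{x_{ia} = \sqrt{y_{ia} / y_{+a}}}: each sample row becomes a unit
#' vector in the squared sense, so Euclidean distances between rows are
#' Hellinger distances.
#'
#' @param counts stations-by-species matrix with positive row totals
#' @return matrix of the same shape
#' @examples
#' hellingerTransform(rbind(c(4, 1), c(1, 1)))
#' @export
hellingerTransform <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) <= 0)) stop("zero row total: Hellinger transform undefined")
  out <- vegan::decostand(counts, method = "hellinger")
  out <- as.matrix(out)
  dimnames(out) <- dimnames(counts)
  out
}

#' @describeIn totalVariance of the site's Hellinger assay
#' @export
setMethod("totalVariance", "BenthicSite", function(x) {
  totalVariance(hellinger(x))
})

#' @describeIn totalVariance of a stations-by-species matrix
#' @export
setMethod("totalVariance", "matrix", function(x) {
  if (nrow(x) < 2) stop("at least 2 samples are required")
  sum(apply(x, 2, var))
})

#' @rdname hellinger
#' @export
setMethod("hellinger", "BenthicSite", function(x)
  t(SummarizedExperiment::assay(x, "hellinger")))

#' @rdname stationCoords
#' @export
setMethod("stationCoords", "BenthicSite", function(x) {
  cd <- SummarizedExperiment::colData(x)
  m <- cbind(x_km = cd$x_km, y_km = cd$y_km)
  rownames(m) <- colnames(x)
  m
})

#' @rdname provinces
#' @export
setMethod("provinces", "BenthicSite", function(x) {
  p <- SummarizedExperiment::colData(x)$province
  factor(as.character(p))
})

#' @rdname envCovariates
#' @export
setMethod("envCovariates", "BenthicSite", function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cd <- cd[, setdiff(colnames(cd), c("x_km", "y_km", "province")), drop = FALSE]
  num <- vapply(cd, is.numeric, TRUE)
  cd[, num, drop = FALSE]
})

setMethod("show", "BenthicSite", function(object) {
  cat("BenthicSite:", ncol(object), "stations x", nrow(object), "taxa\n")
  xy <- stationCoords(object)
  cat(sprintf("  extent: hMax = %.3f km; provinces: %s\n",
              max(dist(xy)),
              paste(levels(provinces(object)), collapse = " ")))
  cat(sprintf("  total Hellinger variance s2 = %.4f\n", totalVariance(object)))
  ev <- envCovariates(object)
  if (ncol(ev))
    cat("  covariates:", paste(colnames(ev), collapse = ", "), "\n")
})

#' Read a site from delimited community and station tables
#'
#' The community file has stations as rows (ids in the first column) and
#' species as columns; the stations file has columns \code{id}, \code{x_km},
#' \code{y_km}, \code{province}, then covariates. Files ending in
#' \code{.tsv}/\code{.txt} are read tab-separated, otherwise comma-separated.
#' The two tables are aligned on the intersection of their station ids
#' (community order preserved); unmatched ids are dropped with a message.
#'
#' @param communityPath,stationsPath paths to the two delimited text files
#' @return a \code{\link{BenthicSite}}
#' @export
readSite <- function(communityPath, stationsPath) {
  readTab <- function(path) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
    read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  }
  com <- readTab(communityPath)
  sta <- readTab(stationsPath)
  if (ncol(com) < 2) stop("community table needs an id column plus species columns")
  comIds <- as.character(com[[1]])
  if (anyDuplicated(comIds)) stop("duplicate sample ids in community table")
  staIds <- as.character(sta[[1]])
  if (anyDuplicated(staIds)) stop("duplicate sample ids in stations table")
  cts <- as.matrix(com[, -1, drop = FALSE])
  if (!is.numeric(cts)) stop("non-numeric abundance cells in community table")
  rownames(cts) <- comIds
  keep <- comIds %in% staIds
  dropped <- c(comIds[!keep], setdiff(staIds, comIds))
  if (length(dropped))
    message("dropped unmatched ids: ", paste(dropped, collapse = ", "))
  if (!any(keep)) stop("no sample ids shared by the two tables")
  cts <- cts[keep, , drop = FALSE]
  stations <- sta[match(rownames(cts), staIds), -1, drop = FALSE]
  rownames(stations) <- rownames(cts)
  for (v in c("x_km", "y_km"))
    if (!v %in% colnames(stations)) stop("stations table lacks column ", v)
  if (!"province" %in% colnames(stations)) stop("stations table lacks column province")
  BenthicSite(cts, stations)
}

#' Write the community and station tables of a site as CSV
#'
#' Inverse of \code{\link{readSite}}: writes \code{community.csv} and
#' \code{stations.csv} under \code{dir}.
#'
#' @param site a \code{\link{BenthicSite}}
#' @param dir output directory (created if needed)
#' @return invisibly, the two file paths
#' @export
writeSite <- function(site, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cts <- t(SummarizedExperiment::assay(site, "counts"))
  comPath <- file.path(dir, "community.csv")
  staPath <- file.path(dir, "stations.csv")
  write.csv(data.frame(id = rownames(cts), cts, check.names = FALSE),
            comPath, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(site))
  write.csv(data.frame(id = colnames(site), cd, check.names = FALSE),
            staPath, row.names = FALSE)
  invisible(c(comPath, staPath))
}
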