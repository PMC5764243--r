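test_that("variogram decomposition satisfies the fitted+residual+cross identity", {
  sim <- simulateSite(syntheticConfig(seed = 51, nStations = 40))
  site <- sim$site
  cls <- suppressWarnings(suppressMessages(buildClasses(site)))
  des <- suppressWarnings(candidateMatrix(site))
  m <- suppressWarnings(fitRDA(site, des, quiet = TRUE))
  ms <- msoDecompose(m, cls)
  tab <- ms@table
  # cross is stored as the remainder; verify against a brute-force cross sum
  for (k in seq_along(cls@pairs)) {
    if (nrow(cls@pairs[[k]]) == 0) next
    p <- cls@pairs[[k]]
    crossSum <- 0
    for (r in seq_len(nrow(p))) {
      df <- m@fitted[p[r, 1], ] - m@fitted[p[r, 2], ]
      dr <- m@residuals[p[r, 1], ] - m@residuals[p[r, 2], ]
      crossSum <- crossSum + 2 * sum(df * dr)
    }
    expect_equal(tab$gamma_cross[k], crossSum / (2 * nrow(p)), tolerance = 1e-12)
    expect_equal(tab$gamma[k],
                 tab$gamma_fit[k] + tab$gamma_res[k] + tab$gamma_cross[k],
                 tolerance = 1e-12)
    expect_equal(tab$gamma_fit[k], bruteGamma(m@fitted, p), tolerance = 1e-12)
    expect_equal(tab$gamma_res[k], bruteGamma(m@residuals, p), tolerance = 1e-12)
  }
  # pair-weighted total cross term vanishes over all pairs (OLS orthogonality)
  clsAll <- suppressWarnings(suppressMessages(
    buildClasses(site, cutoffKm = cls@hMax)))
  tabAll <- msoDecompose(m, clsAll)@table
  ok <- !is.na(tabAll$gamma_cross)
  expect_lt(abs(sum(tabAll$n_pairs[ok] * tabAll$gamma_cross[ok])) /
            sum(tabAll$n_pairs[ok]), 1e-10)
})

test_that("saturated and intercept-only models give degenerate decompositions", {
  prov <- rep(c("A", "B", "C"), each = 4)
  base <- rbind(c(10, 1, 1), c(1, 10, 1), c(1, 1, 10))
  site <- makeSite(base[match(prov, c("A", "B", "C")), ],
                   coords = cbind(seq_len(12) * 0.2, 0), province = prov)
  cls <- suppressWarnings(suppressMessages(buildClasses(site, intervalKm = 0.25)))
  mSat <- suppressWarnings(fitRDA(site, candidateMatrix(site, useEnv = FALSE),
                                  quiet = TRUE))
  tSat <- msoDecompose(mSat, cls)@table
  expect_true(all(abs(tSat$gamma_res) < 1e-12, na.rm = TRUE))
  expect_equal(tSat$gamma_fit, tSat$gamma, tolerance = 1e-10)

  mNull <- fitRDA(site, NULL)
  tNull <- msoDecompose(mNull, cls)@table
  expect_true(all(abs(tNull$gamma_fit) < 1e-14, na.rm = TRUE))
  expect_equal(tNull$gamma_res, tNull$gamma, tolerance = 1e-12)
})

test_that("the Bonferroni envelope flags an inflated cross term and only that", {
  sim <- simulateSite(syntheticConfig(seed = 52, nStations = 40))
  cls <- suppressWarnings(suppressMessages(buildClasses(sim$site)))
  m <- suppressWarnings(fitRDA(sim$site, candidateMatrix(sim$site), quiet = TRUE))
  ms <- msoDecompose(m, cls)
  # a saturated-style zero cross term cannot be flagged
  noCross <- ms
  noCross@table$gamma_fit <- noCross@table$gamma
  noCross@table$gamma_res <- 0
  out <- suppressWarnings(scaleDependenceTest(noCross))
  expect_false(out@scaleDependent)
  expect_true(all(out@table$ci_lower <= out@table$gamma &
                  out@table$gamma <= out@table$ci_upper, na.rm = TRUE))
  # push one class's component sum far outside the envelope
  bad <- ms
  k <- which(!is.na(bad@table$gamma) & bad@table$n_pairs >= 5)[2]
  bad@table$gamma_fit[k] <- bad@table$gamma[k] + 50 * bad@table$se[k]
  out2 <- suppressWarnings(scaleDependenceTest(bad))
  expect_true(out2@table$scale_flag[k])
  expect_true(out2@scaleDependent)
})

test_that("Mantel statistic matches vegan's on the same matrices", {
  sim <- simulateSite(syntheticConfig(seed = 53, nStations = 30))
  site <- sim$site
  cls <- suppressWarnings(suppressMessages(buildClasses(site)))
  m <- suppressWarnings(fitRDA(site, candidateMatrix(site, useEnv = FALSE),
                               quiet = TRUE))
  res <- suppressWarnings(
    mantelResidualTests(m, cls, nPerm = 99))
  D2 <- as.matrix(dist(m@residuals))^2
  n <- nrow(D2)
  for (k in which(cls@nPairs >= 5)) {
    mem <- matrix(0, n, n)
    p <- cls@pairs[[k]]
    mem[p] <- 1
    mem[p[, c(2, 1), drop = FALSE]] <- 1
    vr <- vegan::mantel(as.dist(D2), as.dist(mem), permutations = 0)
    expect_equal(res$mantel_r[k], unname(vr$statistic), tolerance = 1e-10)
  }
})

test_that("Mantel tests detect strong short-range residual autocorrelation", {
  # residuals dominated by a short-range field, intercept-only model
  sim <- simulateSite(syntheticConfig(seed = 54, nStations = 60,
                                      domainKm = c(4, 2), provinceEffect = 0,
                                      spatialSill = 1.5, spatialRangeKm = 0.4,
                                      nuggetFracTarget = 0, whiteNoiseSd = 0.05,
                                      meanTotalCount = 2000))
  cls <- suppressWarnings(suppressMessages(buildClasses(sim$site, intervalKm = 0.25)))
  m <- fitRDA(sim$site, NULL)
  set.seed(1)
  res <- suppressWarnings(mantelResidualTests(m, cls, nPerm = 199))
  expect_true(res$mantel_sig[1])
  expect_lt(res$mantel_r[1], 0)  # short-class pairs have small residual distances
})

test_that("Mantel permutations are reproducible under a fixed seed", {
  sim <- simulateSite(syntheticConfig(seed = 55, nStations = 30))
  cls <- suppressWarnings(suppressMessages(buildClasses(sim$site)))
  m <- suppressWarnings(fitRDA(sim$site, candidateMatrix(sim$site), quiet = TRUE))
  r1 <- suppressWarnings(mso(m, cls, nPerm = 99, seed = 7))
  r2 <- suppressWarnings(mso(m, cls, nPerm = 99, seed = 7))
  expect_identical(r1@table, r2@table)
})

test_that("stationarity check accepts flat and rejects rising residual variograms", {
  centers <- seq(0.125, 2.875, by = 0.25)
  m <- length(centers)
  mkRes <- function(res) {
    tab <- data.frame(class_center_km = centers, n_pairs = 100L,
                      gamma = res + 0.1, gamma_fit = 0.1, gamma_res = res,
                      gamma_cross = 0, se = 0.01, se_res = 0.01,
                      ci_lower = NA_real_, ci_upper = NA_real_, scale_flag = NA,
                      mantel_r = NA_real_, mantel_p = NA_real_, mantel_sig = NA)
    new("MSOResult", classing = fakeClassing(centers, rep(100L, m)),
        table = tab, alpha = NA_real_, nPerm = NA_real_, mTests = NA_integer_,
        scaleDependent = NA, stationarityOk = NA,
        stationaritySlope = NA_real_, stationarityCI = c(NA_real_, NA_real_))
  }
  flat <- stationarityCheck(mkRes(rep(0.3, m)))
  expect_true(flat@stationarityOk)
  rising <- stationarityCheck(mkRes(0.1 + 0.2 * centers))
  expect_false(rising@stationarityOk)
  expect_gt(rising@stationaritySlope, 0.15)

  few <- mkRes(rep(0.3, m))
  few@table <- few@table[1:3, ]
  expect_error(stationarityCheck(few), "at least 4")
})

test_that("diagnostics are invariant to species order and constant species", {
  sim <- simulateSite(syntheticConfig(seed = 56, nStations = 36))
  site <- sim$site
  cls <- suppressWarnings(suppressMessages(buildClasses(site)))
  des <- candidateMatrix(site, useEnv = FALSE)
  m <- suppressWarnings(fitRDA(site, des, quiet = TRUE))
  base <- msoDecompose(m, cls)@table

  counts <- t(SummarizedExperiment::assay(site, "counts"))
  perm <- sample(ncol(counts))
  site2 <- makeSite(counts[, perm], coords = stationCoords(site),
                    province = as.character(provinces(site)))
  m2 <- suppressWarnings(fitRDA(site2, des, quiet = TRUE))
  tab2 <- msoDecompose(m2, cls)@table
  expect_equal(tab2$gamma, base$gamma, tolerance = 1e-12)
  expect_equal(tab2$gamma_fit, base$gamma_fit, tolerance = 1e-12)
  expect_equal(tab2$gamma_res, base$gamma_res, tolerance = 1e-12)
})
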