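test_that("RDA decomposition is exact and orthogonal", {
  site <- randomSite(31, n = 20, s = 8)
  set.seed(32)
  X <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(colnames(site), c("u", "v", "w")))
  m <- fitRDA(site, X)
  expect_lt(max(abs(m@Y - m@fitted - m@residuals)), 1e-10)
  expect_lt(max(abs(crossprod(m@fitted, m@residuals))), 1e-10)
  # canonical eigenvalue sum equals the trace of the fitted covariance
  expect_equal(sum(m@eigenvalues), sum(diag(crossprod(m@fitted))) / 19,
               tolerance = 1e-10)
  expect_equal(explainedFraction(m), sum(m@eigenvalues) / m@s2,
               tolerance = 1e-10)
})

test_that("RDA agrees with vegan's constrained ordination", {
  site <- randomSite(33, n = 25, s = 6)
  set.seed(34)
  X <- matrix(rnorm(25 * 2), 25, 2, dimnames = list(colnames(site), c("u", "v")))
  m <- fitRDA(site, X)
  v <- vegan::rda(hellinger(site) ~ u + v, data = as.data.frame(X))
  expect_equal(unname(m@eigenvalues),
               unname(v$CCA$eig[seq_along(m@eigenvalues)]), tolerance = 1e-8)
  expect_equal(explainedFraction(m),
               unname(v$CCA$tot.chi / v$tot.chi), tolerance = 1e-8)
})

test_that("provinces that determine composition give a saturated fit", {
  prov <- rep(c("A", "B", "C"), each = 4)
  base <- rbind(c(10, 1, 1), c(1, 10, 1), c(1, 1, 10))
  counts <- base[match(prov, c("A", "B", "C")), ]
  site <- makeSite(counts, coords = cbind(seq_len(12), 0), province = prov)
  des <- candidateMatrix(site, useEnv = FALSE)
  m <- suppressWarnings(fitRDA(site, des))
  expect_equal(explainedFraction(m), 1, tolerance = 1e-10)
  expect_lt(max(abs(m@residuals)), 1e-10)
  # fitted values with province indicators are centered province centroids
  H <- hellinger(site)
  cent <- scale(H, scale = FALSE)
  for (p in c("A", "B", "C"))
    for (col in seq_len(ncol(H)))
      expect_equal(unique(round(m@fitted[prov == p, col], 10)),
                   round(mean(cent[prov == p, col]), 10))
})

test_that("rank-deficient designs drop aliased columns with a warning", {
  site <- randomSite(35, n = 15, s = 5, province = rep(c("A", "B", "C"), 5))
  des <- candidateMatrix(site, useEnv = FALSE)  # 3 indicators sum to 1
  expect_warning(m <- fitRDA(site, des), "rank-deficient")
  expect_equal(length(m@dropped), 1)
  expect_equal(length(m@terms), 2)
})

test_that("explained fraction of a pure noise column matches the null expectation", {
  set.seed(36)
  expl <- replicate(200, {
    site <- randomSite(sample.int(1e6, 1), n = 30, s = 5)
    X <- matrix(rnorm(30), 30, 1, dimnames = list(colnames(site), "noise"))
    explainedFraction(fitRDA(site, X))
  })
  expect_equal(mean(expl), 1 / 29, tolerance = 0.15)
})

test_that("explained fraction is monotone over nested designs", {
  site <- randomSite(37, n = 20, s = 6)
  set.seed(38)
  X <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(colnames(site), letters[1:4]))
  prev <- 0
  for (k in 1:4) {
    cur <- explainedFraction(fitRDA(site, X[, 1:k, drop = FALSE]))
    expect_gte(cur, prev - 1e-12)
    prev <- cur
  }
})

test_that("AICc penalizes useless columns", {
  site <- randomSite(39, n = 25, s = 6)
  set.seed(40)
  good <- hellinger(site)[, 1, drop = FALSE] + rnorm(25, 0, 0.01)
  colnames(good) <- "driver"
  noise <- matrix(rnorm(25), 25, 1, dimnames = list(NULL, "noise"))
  m1 <- fitRDA(site, good)
  m2 <- fitRDA(site, cbind(good, noise))
  expect_lt(m1@aicc, m2@aicc)
  expect_equal(aiccRDA(m1), m1@aicc)
})

test_that("forward selection picks real drivers and cuts duplicates", {
  site <- randomSite(41, n = 30, s = 6)
  H <- hellinger(site)
  set.seed(42)
  cand <- cbind(driver = H[, 2] + rnorm(30, 0, 0.005),
                copy = H[, 2] + rnorm(30, 0, 0.005),
                junk = rnorm(30))
  rownames(cand) <- colnames(site)
  sel <- forwardSelect(site, cand)
  # one of the two near-identical drivers enters first...
  expect_true(sel@trace$variable[2] %in% c("driver", "copy"))
  expect_true(any(c("driver", "copy") %in% sel@selected))
  # ...and its near-copy adds nothing, so AICc keeps only one of them
  expect_false(all(c("driver", "copy") %in% sel@selected))
})

test_that("greedy stepwise gains match an exhaustive conditional-gain oracle", {
  site <- randomSite(43, n = 40, s = 8)
  set.seed(44)
  cand <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(colnames(site), letters[1:5]))
  cand[, 1] <- cand[, 1] + 3 * hellinger(site)[, 1]
  cand[, 2] <- cand[, 2] + 2 * hellinger(site)[, 2]
  sel <- forwardSelect(site, cand)
  chosen <- character(0)
  for (stepRow in which(sel@trace$step > 0)) {
    remaining <- setdiff(letters[1:5], chosen)
    gains <- vapply(remaining, function(v)
      explainedFraction(fitRDA(site, cand[, c(chosen, v), drop = FALSE])), 0)
    expect_equal(sel@trace$variable[stepRow], remaining[which.max(gains)])
    chosen <- c(chosen, sel@trace$variable[stepRow])
  }
})

test_that("greedy province merging matches exhaustive search for three provinces", {
  # provinces A and B share a composition; C differs
  set.seed(45)
  prov <- rep(c("A", "B", "C"), each = 6)
  base <- rbind(c(8, 2, 2), c(8, 2, 2), c(2, 2, 8))
  counts <- base[match(prov, c("A", "B", "C")), ] + matrix(rpois(18 * 3, 1), 18, 3)
  site <- makeSite(counts, coords = cbind(seq_len(18) * 0.3, 0), province = prov)
  mrg <- suppressWarnings(mergeProvinces(site))

  # oracle: all five set partitions of {A,B,C}
  partitions <- list(
    c(A = "A", B = "B", C = "C"), c(A = "AB", B = "AB", C = "C"),
    c(A = "AC", B = "B", C = "AC"), c(A = "A", B = "BC", C = "BC"),
    c(A = "ABC", B = "ABC", C = "ABC"))
  aiccOf <- function(map) {
    des <- tryCatch(candidateMatrix(site, useEnv = FALSE, mergeMap = map),
                    error = function(e) NULL)
    suppressWarnings(fitRDA(site, des, quiet = TRUE))@aicc
  }
  best <- partitions[[which.min(vapply(partitions, aiccOf, 0))]]
  expect_equal(sort(unique(mrg@mergeMap[c("A", "B", "C")])),
               sort(unique(best)))
  expect_equal(mrg@mergeMap["A"] == mrg@mergeMap["B"], best["A"] == best["B"],
               ignore_attr = TRUE)
  # the identical pair must have merged
  expect_true(mrg@mergeMap["A"] == mrg@mergeMap["B"])
  expect_false(mrg@mergeMap["A"] == mrg@mergeMap["C"])
})

test_that("well-separated provinces are not merged", {
  sim <- simulateSite(syntheticConfig(seed = 46, nStations = 45, nProvinces = 3,
                                      provinceEffect = 3, spatialSill = 0,
                                      nuggetFracTarget = 0, whiteNoiseSd = 0.2))
  mrg <- suppressWarnings(mergeProvinces(sim$site))
  expect_equal(length(unique(mrg@mergeMap)), nlevels(provinces(sim$site)))
})
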