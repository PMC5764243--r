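test_that("model curves honour the nugget, sill and clamping boundaries", {
  for (fam in variogramFamilies())
    expect_equal(variogramModelValue(fam, 0.2, 0.3, 0.8, 0), 0.2,
                 info = fam)
  expect_equal(variogramModelValue("spherical", 0.1, 0.4, 0.6, 0.6), 0.5)
  expect_equal(variogramModelValue("linear", 0.1, 0.4, 0.6, 2), 0.5)
  # asymptotic approach to the sill
  expect_equal(variogramModelValue("exponential", 0.21, 0.32, 0.89, 50),
               0.53, tolerance = 1e-10)
  expect_error(variogramModelValue("exponential", 0.2, 0.3, -1, 1), "positive")
  expect_error(variogramModelValue("nope", 0.2, 0.3, 1, 1))
})

test_that("model curves are nondecreasing in distance for every family", {
  h <- seq(0, 5, by = 0.01)
  set.seed(21)
  for (fam in variogramFamilies())
    for (rep in 1:5) {
      v <- variogramModelValue(fam, runif(1, 0, 0.5), runif(1, 0, 0.5),
                               runif(1, 0.1, 3), h)
      expect_true(all(diff(v) > -1e-12), info = fam)
    }
})

test_that("derived ranges match closed forms and published arithmetic", {
  # spherical and piecewise linear reach the sill at a
  expect_equal(derivedRange(variogramFit("spherical", 0.18, 0.27, 0.57)), 0.57)
  expect_equal(derivedRange(variogramFit("linear", 0.16, 0.32, 0.79)), 0.79)
  # exponential: published parameter set reaches 95% of sill at 2.22 km
  expect_equal(round(derivedRange(variogramFit("exponential", 0.21, 0.32, 0.89)), 2),
               2.22)
  # zero nugget -> -a log(0.05)
  expect_equal(derivedRange(variogramFit("exponential", 0, 0.3, 1)),
               -log(0.05), tolerance = 1e-10)
  # gaussian closed form against direct inversion
  f <- variogramFit("gaussian", 0.1, 0.4, 0.9)
  expect_equal(variogramModelValue("gaussian", 0.1, 0.4, 0.9, derivedRange(f)),
               0.95 * 0.5, tolerance = 1e-9)
  # logistic solved numerically; oracle is the closed-form inversion
  fl <- variogramFit("logistic", 0.1, 0.4, 2)
  d <- 0.95 * 0.5 - 0.1
  expect_equal(derivedRange(fl), sqrt(d / (2 * (0.4 - d))), tolerance = 1e-5)
  # nugget above 95% of the sill: range undefined
  expect_warning(r <- derivedRange(variogramFit("exponential", 1, 0.01, 1)),
                 "undefined")
  expect_true(is.na(r))
})

test_that("weighted least squares recovers exact variogram models", {
  h <- seq(0.125, 2.375, by = 0.25)
  nP <- c(40L, 90L, 130L, 150L, 160L, 150L, 140L, 120L, 100L, 80L)
  g <- variogramModelValue("spherical", 0.2, 0.3, 1.0, h)
  emp <- fakeEmpirical(h, g, nP)
  fit <- fitVariogramModel(emp, "spherical")
  expect_equal(fit@c0, 0.2, tolerance = 1e-6)
  expect_equal(fit@c1, 0.3, tolerance = 1e-6)
  expect_equal(fit@a, 1.0, tolerance = 1e-6)
  expect_equal(fit@sill, fit@c0 + fit@c1)

  # flat variogram -> pure nugget
  flat <- fakeEmpirical(h, rep(0.4, 10), nP)
  ffit <- fitVariogramModel(flat, "exponential")
  expect_equal(ffit@c0, 0.4, tolerance = 1e-4)
  expect_lt(ffit@c1, 1e-3)

  expect_error(fitVariogramModel(fakeEmpirical(h[1:3], g[1:3], nP[1:3]),
                                 "spherical"), "4 usable")
})

test_that("AICc algebra behaves as expected", {
  # equal RSS, more parameters -> larger AICc
  expect_lt(aiccLeastSquares(1, 10, 3), aiccLeastSquares(1, 10, 4))
  # halving RSS lowers AICc by n log 2
  expect_equal(aiccLeastSquares(2, 10, 3) - aiccLeastSquares(1, 10, 3),
               10 * log(2), tolerance = 1e-12)
  expect_error(aiccLeastSquares(1, 5, 4), "undefined")
})

test_that("model selection finds the generating family and is order-stable", {
  h <- seq(0.125, 2.375, by = 0.25)
  nP <- c(40L, 90L, 130L, 150L, 160L, 150L, 140L, 120L, 100L, 80L)
  g <- variogramModelValue("spherical", 0.2, 0.3, 1.0, h)
  emp <- fakeEmpirical(h, g, nP, s2 = 0.5, hMax = 5)
  sel <- selectVariogramModel(emp)
  b <- bestFit(sel)
  # an equal-RSS family could tie, but the fit must be numerically exact
  expect_lt(b@rssWeighted, 1e-10)
  expect_equal(fitTable(sel)$family[sel@best], b@family)
  # order of the families argument must not change the winner
  selRev <- selectVariogramModel(emp, families = rev(variogramFamilies()))
  expect_equal(bestFit(selRev)@family, b@family)
  # scaled quantities attach against s2 and hMax
  expect_equal(b@scaledNugget, b@c0 / 0.5, tolerance = 1e-6)
  expect_equal(b@scaledRange, b@rangeKm / 5, tolerance = 1e-6)
})

test_that("noisy parameter recovery stays within Monte-Carlo error", {
  h <- seq(0.125, 2.375, by = 0.25)
  nP <- c(40L, 90L, 130L, 150L, 160L, 150L, 140L, 120L, 100L, 80L)
  truth <- c(c0 = 0.2, c1 = 0.3, a = 1.0)
  gTrue <- variogramModelValue("spherical", truth[1], truth[2], truth[3], h)
  set.seed(99)
  est <- t(replicate(100, {
    g <- pmax(gTrue + rnorm(10, 0, 0.02), 0)
    f <- fitVariogramModel(fakeEmpirical(h, g, nP), "spherical")
    c(f@c0, f@c1, f@a)
  }))
  bias <- colMeans(est) - truth
  sdms <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_true(all(abs(bias) < 3 * pmax(sdms, 0.005)))
  # median absolute error of the scaled nugget under noise is small
  expect_lt(median(abs(est[, 1] - 0.2)) / 0.5, 0.05)
})

test_that("model selection recovers an exponential truth in a plurality of reps", {
  h <- seq(0.125, 2.375, by = 0.25)
  nP <- c(40L, 90L, 130L, 150L, 160L, 150L, 140L, 120L, 100L, 80L)
  gTrue <- variogramModelValue("exponential", 0.15, 0.35, 0.5, h)
  set.seed(100)
  fams <- replicate(100, {
    g <- pmax(gTrue + rnorm(10, 0, 0.02), 0)
    bestFit(selectVariogramModel(fakeEmpirical(h, g, nP)))@family
  })
  tab <- sort(table(fams), decreasing = TRUE)
  expect_equal(names(tab)[1], "exponential")
})
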