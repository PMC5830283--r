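twoFactorPattern <- function() {
  cbind(rep(c(TRUE, FALSE), c(5, 4)), rep(c(FALSE, TRUE), c(5, 4)))
}

# population covariance implied by the scale's reported standardized loadings
populationCov <- function(rho = 0.5) {
  lam <- matrix(0, 9, 2)
  lam[1:5, 1] <- c(0.69, 0.71, 0.55, 0.30, 0.43)
  lam[6:9, 2] <- c(0.60, 0.62, 0.28, 0.54)
  impliedCovariance(lam, 1 - rowSums(lam^2), matrix(c(1, rho, rho, 1), 2))
}

test_that("implied covariance follows the factor structure", {
  expect_equal(impliedCovariance(matrix(0, 3, 1), c(1, 2, 3)),
               diag(c(1, 2, 3)))
  lam <- matrix(c(0.6, 0.8), 2, 1)
  S <- impliedCovariance(lam, c(0.64, 0.36))
  expect_equal(S[1, 2], 0.48)
  expect_equal(diag(S), c(1, 1))
  # orthogonal simple structure: no cross-block covariance
  lam2 <- rbind(c(0.7, 0), c(0.5, 0), c(0, 0.6), c(0, 0.4))
  S2 <- impliedCovariance(lam2, rep(0.5, 4), diag(2))
  expect_true(all(S2[1:2, 3:4] == 0))
  expect_error(impliedCovariance(lam, c(-0.1, 0.5)), "positive")
  expect_error(impliedCovariance(lam2, rep(0.5, 4), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("independence baseline has closed form", {
  S <- diag(c(2, 3, 4))
  bl <- baselineModel(S, 100)
  expect_equal(bl$chiSquare, 0, tolerance = 1e-12)
  expect_identical(baselineModel(diag(9), 344)$df, 36L)
  r <- 0.6
  S2 <- matrix(c(1, r, r, 1), 2)
  expect_equal(baselineModel(S2, 201)$discrepancy, -log(1 - r^2),
               tolerance = 1e-12)
  expect_error(baselineModel(matrix(1, 3, 3), 100), "singular")
})

test_that("fit indices reproduce the published two-model comparison arithmetic", {
  bl <- list(chiSquare = 800, df = 36)   # any baseline clearly worse than fit
  multi <- fitIndices(33.79, 26, 344, bl$chiSquare, bl$df, 28)
  uni <- fitIndices(58.48, 27, 344, bl$chiSquare, bl$df, 27)
  expect_equal(round(multi$rmsea, 2), 0.03)
  expect_equal(round(uni$rmsea, 2), 0.06)
  expect_equal(multi$aic, 89.79)
  expect_equal(uni$aic, 112.48)
  expect_equal(round(multi$pValue, 2), 0.14)
  expect_lt(uni$pValue, 0.01)
  # truncation at chi-square <= df
  expect_equal(fitIndices(20, 26, 344, 800, 36, 28)$rmsea, 0)
  expect_equal(fitIndices(20, 26, 344, 800, 36, 28)$cfi, 1)
})

test_that("a model fitted to its own implied covariance is a perfect fit", {
  S <- populationCov(0.5)
  model <- cfaModel(twoFactorPattern())
  fit <- fitCfa(S, NULL, 344, model)
  expect_lt(fit@chiSquare, 1e-6 * 343)
  expect_equal(fit@cfi, 1)
  expect_equal(fit@rmsea, 0)
  expect_identical(fit@df, 26L)
  expect_equal(abs(fit@loadings[1, 1]), 0.69, tolerance = 1e-3)
  expect_equal(fit@factorCov[1, 2], 0.5, tolerance = 1e-3)
  fit1 <- fitCfa(S, NULL, 344, cfaModel(matrix(TRUE, 9, 1)))
  expect_identical(fit1@df, 27L)
})

test_that("degrees of freedom and the AIC convention follow the mean-structure count", {
  S <- populationCov(0.5)
  f2 <- fitCfa(S, NULL, 344, cfaModel(twoFactorPattern()))
  f1 <- fitCfa(S, NULL, 344, cfaModel(matrix(TRUE, 9, 1)))
  expect_identical(f1@df - f2@df, 1L)
  expect_identical(f1@nFreeParams, 27L)
  expect_identical(f2@nFreeParams, 28L)
  expect_equal(f1@aic - f1@chiSquare, 2 * 27)
  expect_equal(f2@aic - f2@chiSquare, 2 * 28)
  # without the mean structure the same models have 18/19 parameters
  f2n <- fitCfa(S, NULL, 344, cfaModel(twoFactorPattern(), meanStructure = FALSE))
  expect_identical(f2n@nFreeParams, 19L)
  expect_identical(f2n@df, 26L)
})

test_that("the unidimensional model never out-fits the nested two-factor model", {
  set.seed(5)
  for (rep in 1:4) {
    W <- drop(stats::rWishart(1, 400, populationCov(0.5) / 400))
    f2 <- fitCfa(W, NULL, 344, cfaModel(twoFactorPattern()))
    f1 <- fitCfa(W, NULL, 344, cfaModel(matrix(TRUE, 9, 1)))
    expect_gte(f1@discrepancy, f2@discrepancy - 1e-8)
  }
})

test_that("sampling from the two-factor population favors the two-factor model", {
  set.seed(9)
  W <- drop(stats::rWishart(1, 343, populationCov(0.5) / 343))
  f2 <- fitCfa(W, NULL, 344, cfaModel(twoFactorPattern()))
  f1 <- fitCfa(W, NULL, 344, cfaModel(matrix(TRUE, 9, 1)))
  expect_lt(f2@rmsea, f1@rmsea)
  expect_gt(f2@cfi, f1@cfi)
})

test_that("loading standard errors are finite and shrink with N", {
  S <- drop(stats::rWishart(1, 343, populationCov(0.5) / 343))
  fitS <- fitCfa(S, NULL, 344, cfaModel(twoFactorPattern()))
  seS <- fitS@loadingSE[loadingPattern(lssdBank())]
  expect_true(all(is.finite(seS)))
  fitL <- fitCfa(S, NULL, 3440, cfaModel(twoFactorPattern()))
  seL <- fitL@loadingSE[loadingPattern(lssdBank())]
  expect_true(all(seL < seS))
})

test_that("covFromResponses uses listwise-complete rows as numeric scores", {
  x <- cbind(c(0, 1, 2, 3, NA), c(1, 1, 2, 0, 2), c(2, 0, 1, 1, 0))
  sm <- covFromResponses(x)
  expect_identical(sm$N, 4L)
  expect_equal(sm$cov, cov(x[1:4, ]))
  expect_equal(sm$means, colMeans(x[1:4, ]))
  expect_error(covFromResponses(x[c(1, 5), ]), "complete")
})
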