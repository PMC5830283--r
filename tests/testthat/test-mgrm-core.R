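test_that("cumulative probabilities follow the link with boundary conventions", {
  it <- itemParameters("i1", a = c(2.03, 0), d = c(-0.15, -2.60, -5.39))
  expect_equal(cumulativeProb(it, c(0, 0), 1), pnorm(-0.15), tolerance = 1e-12)
  expect_equal(round(cumulativeProb(it, c(0, 0), 1), 4), 0.4404)
  expect_identical(cumulativeProb(it, c(1.3, -0.4), 0), 1)
  expect_identical(cumulativeProb(it, c(1.3, -0.4), 4), 0)
  itl <- itemParameters("i1", a = c(2.03, 0), d = c(-0.15, -2.60, -5.39),
                        link = "logistic")
  expect_equal(cumulativeProb(itl, c(0.5, 2), 2), plogis(2.03 * 0.5 - 2.60))
  expect_error(cumulativeProb(it, c(0, 0), 5), "out of range")
  expect_error(cumulativeProb(it, c(NA, 0), 1), "finite")
  expect_error(cumulativeProb(it, c(Inf, 0), 1), "finite")
})

test_that("category probabilities telescope and match hand evaluation", {
  it <- itemParameters("i1", a = c(2.03, 0), d = c(-0.15, -2.60, -5.39))
  expect_equal(round(categoryProb(it, c(0, 0), 0), 4), 0.5596)
  expect_equal(round(categoryProb(it, c(0, 0), 1), 4), 0.4357)
  expect_equal(categoryProb(it, c(0, 0), 1),
               pnorm(-0.15) - pnorm(-2.60), tolerance = 1e-12)
  expect_error(categoryProb(it, c(0, 0), 4), "out of range")
})

test_that("category probabilities sum to one and boundaries are monotone, both links", {
  set.seed(41)
  for (link in c("probit", "logistic")) {
    bank <- lssdBank(link)
    for (rep in 1:20) {
      th <- rnorm(2, sd = 2)
      for (it in bank@items) {
        m <- length(it@d)
        p <- vapply(0:m, function(t) categoryProb(it, th, t), 1.0)
        expect_equal(sum(p), 1, tolerance = 1e-12)
        cum <- vapply(0:(m + 1), function(t) cumulativeProb(it, th, t), 1.0)
        expect_true(all(diff(cum) <= 0))
      }
    }
  }
})

test_that("boundary probabilities increase with a.theta and links agree in ordering", {
  it <- itemParameters("x", a = c(1.4, 0.6), d = c(0.8, -0.6, -2.1))
  itl <- itemParameters("x", a = c(1.4, 0.6), d = c(0.8, -0.6, -2.1),
                        link = "logistic")
  set.seed(7)
  for (rep in 1:25) {
    th1 <- rnorm(2); th2 <- rnorm(2)
    for (t in 1:3) {
      dp <- cumulativeProb(it, th1, t) - cumulativeProb(it, th2, t)
      dl <- cumulativeProb(itl, th1, t) - cumulativeProb(itl, th2, t)
      ds <- sum(it@a * th1) - sum(it@a * th2)
      expect_equal(sign(dp), sign(ds))
      expect_equal(sign(dp), sign(dl))
    }
  }
})

test_that("MDISC is the Euclidean norm, with simple-structure equality", {
  expect_equal(mdisc(itemParameters("n", a = c(3, 4), d = 0)), 5)
  bank <- lssdBank()
  expect_equal(unname(mdisc(bank)), unname(apply(abs(discrim(bank)), 1, max)),
               tolerance = 1e-12)
  expect_true(all(mdisc(bank) >= apply(abs(discrim(bank)), 1, max) - 1e-12))
  expect_error(mdisc(itemParameters("z", a = c(0, 0), d = 0)), "all-zero")
  expect_identical(mdiscQuality(c(2.03, 0.94, 0.3)), c("high", "medium", "low"))
})

test_that("item information matches a finite-difference oracle and is direction-symmetric", {
  bank <- lssdBank()
  it <- bank@items[[1]]
  for (th in list(c(0, 0), c(1, -0.5), c(-2, 1))) {
    expect_equal(itemInformation(it, th, c(1, 0)),
                 fdItemInformation(it, th, c(1, 0)), tolerance = 1e-6)
  }
  u <- c(0.6, 0.8)
  expect_equal(itemInformation(it, c(0.3, -0.2), u),
               itemInformation(it, c(0.3, -0.2), -u), tolerance = 1e-12)
  # default direction is the loading axis
  expect_equal(itemInformation(it, c(0, 0)), itemInformation(it, c(0, 0), c(1, 0)))
  expect_error(itemInformation(it, c(0, 0), c(0, 0)), "nonzero norm")
  expect_error(itemInformation(it, c(0, 0), c(1, 1)), "unit norm")
  # degenerate item carries no information in any direction
  z <- itemParameters("z", a = c(0, 0), d = 0)
  expect_equal(itemInformation(z, c(1.2, -0.7), c(1, 0)), 0)
})

test_that("test information grid is additive, nonnegative, and humps above -2 for the packaged bank", {
  bank <- lssdBank()
  grid <- testInformationGrid(bank, c(-4, 4), step = 0.2)
  ids <- itemIds(bank)
  expect_true(all(grid$test >= 0))
  expect_equal(grid$test, rowSums(grid[, ids]), tolerance = 1e-12)
  top <- grid[which.max(grid$test), ]
  expect_gt(top[[1]], -2)
  expect_gt(top[[2]], -2)
  # degenerate-only bank gives a flat zero surface
  zbank <- itemBank(list(itemParameters("z", a = c(0, 0), d = 0)),
                    loadingPattern = matrix(FALSE, 1, 2),
                    dimensionNames = c("f1", "f2"))
  zg <- testInformationGrid(zbank, c(-2, 2), step = 0.5)
  expect_true(all(zg$test == 0))
  expect_error(testInformationGrid(bank, c(-4, 4), step = 0), "positive")
})

test_that("ICC curves are monotone at the extremes, unimodal inside, and normalized", {
  bank <- lssdBank()
  icc <- iccCurves(bank@items[[1]], 1, c(-4, 4), step = 0.1)
  p0 <- icc$prob[icc$category == 0]
  p3 <- icc$prob[icc$category == 3]
  expect_true(all(diff(p0) < 0))
  expect_true(all(diff(p3) > 0))
  for (ct in 1:2) {
    pc <- icc$prob[icc$category == ct]
    peak <- which.max(pc)
    expect_true(all(diff(pc[seq_len(peak)]) >= 0))
    expect_true(all(diff(pc[peak:length(pc)]) <= 0))
  }
  sums <- tapply(icc$prob, icc$theta, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_error(iccCurves(bank@items[[1]], 2), "zero loading")
})

test_that("EAP scoring returns the prior for empty records and orders extreme responders", {
  bank <- lssdBank()
  allmiss <- eapScore(bank, rep(NA_integer_, 9))
  expect_true(allmiss$allMissing)
  expect_equal(unname(unlist(allmiss[1, 1:2])), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(unlist(allmiss[1, 3:4])), c(1, 1), tolerance = 1e-9)
  both <- eapScore(bank, rbind(rep(3L, 9), rep(0L, 9)),
                   latentCorr = matrix(c(1, .5, .5, 1), 2))
  expect_gt(both[1, 1], both[2, 1])
  expect_gt(both[1, 2], both[2, 2])
})

test_that("EAP posterior means agree with a dense trapezoid oracle", {
  bank <- toyBank2D()
  rho <- 0.4
  resp <- c(2L, 0L, 3L, 1L)
  got <- eapScore(bank, resp, latentCorr = matrix(c(1, rho, rho, 1), 2),
                  rule = quadratureRule(2, nPerDim = 21))
  want <- unname(trapezoidEap(resp, bank, rho))
  expect_equal(unname(unlist(got[1, 1:2])), want, tolerance = 1e-3)
})
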