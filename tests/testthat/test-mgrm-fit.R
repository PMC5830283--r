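test_that("E-step posterior equals the prior under a flat likelihood", {
  bank <- itemBank(list(itemParameters("z", a = c(0, 0), d = 0)),
                   loadingPattern = matrix(FALSE, 1, 2),
                   dimensionNames = c("f1", "f2"))
  rule <- quadratureRule(2, nPerDim = 11)
  es <- eStep(matrix(1L, 1, 1), bank, diag(2), rule)
  expect_equal(drop(es$posterior), rule@weights, tolerance = 1e-14)
})

test_that("E-step posterior rows are normalized and all-missing rows contribute nothing", {
  bank <- toyBank3()
  set.seed(3)
  th <- simulateTheta(40, 0.3, seed = 3)
  resp <- simulateResponses(th, bank, seed = 4)
  resp[5, ] <- NA_integer_
  rule <- quadratureRule(2, nPerDim = 15)
  es <- eStep(resp, bank, matrix(c(1, .3, .3, 1), 2), rule)
  expect_true(all(abs(rowSums(es$posterior) - 1) < 1e-12))
  expect_equal(es$posterior[5, ], rule@weights, tolerance = 1e-14)
  esDrop <- eStep(resp[-5, , drop = FALSE], bank, matrix(c(1, .3, .3, 1), 2), rule)
  expect_equal(es$loglik, esDrop$loglik, tolerance = 1e-10)
})

test_that("E-step marginal log-likelihood matches dense trapezoid integration", {
  bank <- toyBank3()
  th <- simulateTheta(50, 0.4, seed = 11)
  resp <- simulateResponses(th, bank, seed = 12)
  es <- eStep(resp, bank, matrix(c(1, .4, .4, 1), 2), quadratureRule(2, nPerDim = 21))
  want <- trapezoidLoglik(resp, bank, 0.4)
  expect_equal(es$loglik, want, tolerance = abs(want) * 1e-3)
})

test_that("item M-step respects the loading constraint and recovers a known item", {
  bank <- toyBank2D()
  truthItem <- bank@items[[1]]
  th <- simulateTheta(5000, 0, seed = 21)
  resp <- simulateResponses(th, bank, seed = 22)
  rule <- quadratureRule(2)
  es <- eStep(resp, bank, diag(2), rule)   # posterior at the generating values
  cnt <- PatternSeverity:::expectedCounts(es$posterior, resp[, 1], 4L)
  start <- itemParameters("t1", a = c(1, 0), d = c(1, 0, -1))
  up <- mStepItem(cnt, es$nodes, start, freeMask = c(TRUE, FALSE))
  expect_equal(up$item@a[2], 0)                       # fixed-zero untouched
  expect_lt(abs(up$item@a[1] - truthItem@a[1]), 0.1)  # slope recovered
  expect_lt(max(abs(up$item@d - truthItem@d)), 0.1)
})

test_that("an unobservable top category drives its boundary to the search box and is flagged", {
  rule <- quadratureRule(2, nPerDim = 11)
  K <- nrow(rule@nodes)
  cnt <- cbind(rule@weights * 60, rule@weights * 40, rule@weights * 0)
  start <- itemParameters("s", a = c(1, 0), d = c(0.5, -0.5))
  up <- mStepItem(cnt, rule@nodes, start, freeMask = c(TRUE, FALSE))
  expect_match(paste(up$flag, collapse = " "), "unidentified|boundary")
  expect_lt(up$item@d[2], -4)   # driven far past any data-supported value
})

test_that("latent correlation updates have unit diagonal and recover the truth", {
  bank <- lssdBank()
  rule <- quadratureRule(2)
  for (rho in c(0.5, 0)) {
    th <- simulateTheta(2000, rho, seed = 31)
    resp <- simulateResponses(th, bank, seed = 32)
    es <- eStep(resp, bank, matrix(c(1, rho, rho, 1), 2), rule)
    M <- crossprod(es$nodes, es$nodes * es$nodeCounts) / nrow(resp)
    R <- updateLatentCorr(M)
    expect_identical(diag(R), c(1, 1))
    expect_lt(abs(R[1, 2] - rho), 0.1)
    expect_lt(abs(PatternSeverity:::rhoMStep(M) - rho), 0.1)
  }
})

test_that("non-positive-definite pooled moments are repaired with a warning", {
  M <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_warning(R <- updateLatentCorr(M), "nearest-PD")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_identical(diag(R), c(1, 1))
})

test_that("maxIter = 0 returns the starting bank unconverged with an empty path", {
  bank <- toyBank2D()
  th <- simulateTheta(60, 0.3, seed = 41)
  resp <- simulateResponses(th, bank, seed = 42)
  fit <- fitMgrm(resp, bank, maxIter = 0L, startAtBank = TRUE)
  expect_false(converged(fit))
  expect_length(loglikPath(fit), 0)
  expect_equal(discrim(estimatedBank(fit)), discrim(bank))
})

test_that("EM log-likelihood path is nondecreasing and constraints hold at every exit", {
  bank <- toyBank2D()
  th <- simulateTheta(400, 0.5, seed = 51)
  resp <- simulateResponses(th, bank, seed = 52)
  fit <- fitMgrm(resp, bank, tol = 1e-3, maxIter = 500)
  expect_true(all(diff(loglikPath(fit)) > -1e-6))
  expect_true(all(discrim(estimatedBank(fit))[!loadingPattern(bank)] == 0))
  expect_true(converged(fit))
  expect_lt(abs(latentCorr(fit)[1, 2] - 0.5), 0.15)
})

test_that("refitting from the generating values barely moves at large n", {
  bank <- toyBank2D()
  th <- simulateTheta(5000, 0.5, seed = 61)
  resp <- simulateResponses(th, bank, seed = 62)
  tol <- 1e-4
  fit1 <- fitMgrm(resp, bank, tol = tol, maxIter = 1L, startAtBank = TRUE,
                  latentCorr = matrix(c(1, .5, .5, 1), 2))
  change <- max(abs(discrim(estimatedBank(fit1)) - discrim(bank)),
                abs(unlist(boundaries(estimatedBank(fit1))) - unlist(boundaries(bank))))
  ## one M-step jumps to the sample optimum of Q, which sits O(n^-1/2) from
  ## the generating values; 0.1 is a generous multiple of that at n = 5000
  expect_lt(change, 0.1)
})

test_that("EM solution matches a direct grid search on a 1-D two-item problem", {
  bank <- toyBank1D()
  set.seed(71)
  th <- matrix(rnorm(150), ncol = 1)
  resp <- simulateResponses(th, bank, seed = 72)
  rule <- quadratureRule(1, nPerDim = 21)
  fit <- fitMgrm(resp, bank, rule = rule, tol = 1e-6, maxIter = 500,
                 estimateCorr = FALSE)
  emLoglik <- utils::tail(loglikPath(fit), 1)

  marg <- function(a1, d1, a2, d2) {
    p1 <- pnorm(drop(rule@nodes) * a1 + d1)
    p2 <- pnorm(drop(rule@nodes) * a2 + d2)
    tab1 <- rbind(1 - p1, p1)
    tab2 <- rbind(1 - p2, p2)
    L <- tab1[resp[, 1] + 1L, ] * tab2[resp[, 2] + 1L, ]
    sum(log(drop(L %*% rule@weights)))
  }
  best <- -Inf
  centre <- c(1, 0, 1, 0); width <- 2
  for (stage in 1:5) {
    gr <- lapply(centre, function(c0) seq(c0 - width, c0 + width, length.out = 9))
    for (a1 in gr[[1]]) for (d1 in gr[[2]]) for (a2 in gr[[3]]) for (d2 in gr[[4]]) {
      v <- marg(a1, d1, a2, d2)
      if (v > best) { best <- v; centre <- c(a1, d1, a2, d2) }
    }
    width <- width / 3
  }
  expect_lt(abs(emLoglik - best), 1e-3)
})

test_that("empty categories are collapsed with a recorded remap", {
  bank <- toyBank2D()
  th <- simulateTheta(150, 0.3, seed = 81)
  resp <- simulateResponses(th, bank, seed = 82)
  resp[resp[, 2] == 3L, 2] <- 2L    # make category 3 of item 2 unobserved
  expect_message(fit <- fitMgrm(resp, bank, tol = 1e-3, maxIter = 60),
                 "collapsed")
  expect_true("t2" %in% names(fit@collapseMap))
  expect_length(boundaries(estimatedBank(fit))$t2, 2L)
})

test_that("standard errors are returned per free parameter and shrink with n", {
  bank <- toyBank3()
  sePer <- function(n) {
    th <- simulateTheta(n, 0.3, seed = 91)
    resp <- simulateResponses(th, bank, seed = 92)
    fit <- fitMgrm(resp, bank, tol = 1e-3, maxIter = 80, computeSE = TRUE)
    fit@standardErrors
  }
  se1 <- sePer(300)
  expect_named(se1, itemIds(bank))
  expect_length(se1$o1, 3L)            # one free slope + two boundaries
  expect_true(all(is.finite(unlist(se1))))
  se2 <- sePer(1200)
  expect_lt(median(unlist(se2)), median(unlist(se1)))
})

test_that("nonconforming responses are rejected before any iteration", {
  bank <- toyBank2D()
  expect_error(fitMgrm(matrix(5L, 4, 4), bank), "out-of-range")
  expect_error(fitMgrm(matrix(1L, 4, 3), bank), "columns")
  expect_error(fitMgrm(matrix(1L, 1, 4), bank), "2 respondents")
})
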