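## Confirmatory factor analysis by maximum likelihood, with the fit indices
## used to adjudicate unidimensional vs two-factor structure.

#' Model-implied covariance matrix
#'
#' The factor-analytic structure `Sigma = Lambda Psi Lambda' + Theta`, with
#' `Lambda` the loading matrix, `Psi` the factor covariance (unit diagonal)
#' and `Theta` the diagonal residual matrix.
#'
#' @param loadings item x factor loading matrix.
#' @param residuals positive residual variances, length = items.
#' @param factorCov factor covariance matrix, positive definite with unit
#'   diagonal (default identity).
#' @return symmetric positive-definite covariance matrix.
#' @examples
#' impliedCovariance(matrix(c(0.6, 0.8), 2), c(0.64, 0.36))
#' @export
impliedCovariance <- function(loadings, residuals,
                              factorCov = diag(ncol(loadings))) {
  loadings <- as.matrix(loadings)
  if (any(residuals <= 0)) stop("residual variances must be positive")
  ev <- eigen(factorCov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("factor covariance must be positive definite")
  if (any(abs(diag(factorCov) - 1) > 1e-8))
    stop("factor covariance must have unit diagonal")
  loadings %*% factorCov %*% t(loadings) + diag(residuals, nrow(loadings))
}

## ML discrepancy F = log|Sigma| + tr(S Sigma^-1) - log|S| - p
mlDiscrepancy <- function(S, Sigma) {
  p <- nrow(S)
  chS <- chol(Sigma)
  logdetSig <- 2 * sum(log(diag(chS)))
  logdetS <- determinant(S, logarithm = TRUE)$modulus[1L]
  logdetSig + sum(diag(S %*% chol2inv(chS))) - logdetS - p
}

#' Independence baseline model
#'
#' Fits the zero-covariance model (free variances, free means): closed form
#' `F_base = sum log s_ii - log |S|`, chi-square `(N - 1) F_base`, with
#' `p (p - 1) / 2` degrees of freedom. This is the reference model in the CFI.
#'
#' @param sampleCov sample covariance matrix.
#' @param N sample size.
#' @return list with `chiSquare`, `df`, `discrepancy`.
#' @export
baselineModel <- function(sampleCov, N) {
  d <- determinant(sampleCov, logarithm = TRUE)
  if (!is.finite(d$modulus[1L]) || d$sign <= 0) stop("singular sample covariance")
  Fb <- sum(log(diag(sampleCov))) - d$modulus[1L]
  list(chiSquare = (N - 1) * Fb, df = as.integer(nrow(sampleCov) *
         (nrow(sampleCov) - 1L) / 2L), discrepancy = Fb)
}

#' Fit indices from a chi-square summary
#'
#' `RMSEA = sqrt(max(chi2 - df, 0) / (df (N - 1)))`;
#' `CFI = 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)` clipped to
#' `[0, 1]`; `AIC = chi2 + 2 q` (the parameter count `q` includes intercepts
#' when a mean structure is used); `p` is the upper chi-square tail.
#'
#' @param chiSquare,df model chi-square and degrees of freedom.
#' @param N sample size.
#' @param baselineChiSquare,baselineDf independence-model reference.
#' @param q number of free parameters.
#' @return list with `cfi`, `rmsea`, `aic`, `pValue`.
#' @examples
#' fitIndices(33.79, 26, 344, 500, 36, 28)
#' @export
fitIndices <- function(chiSquare, df, N, baselineChiSquare, baselineDf, q) {
  stopifnot(df >= 1, N >= 2)
  num <- max(chiSquare - df, 0)
  den <- max(baselineChiSquare - baselineDf, num, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  if (cfi < 0 || cfi > 1) {
    warning("baseline fits worse-defined than the target model; CFI clipped")
    cfi <- min(max(cfi, 0), 1)
  }
  list(cfi = cfi,
       rmsea = sqrt(num / (df * (N - 1))),
       aic = chiSquare + 2 * q,
       pValue = pchisq(chiSquare, df, lower.tail = FALSE))
}

#' Fit a confirmatory factor model by maximum likelihood
#'
#' Minimizes the normal-theory ML discrepancy
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p` over the free loadings,
#' residual variances (log-parameterized for positivity) and factor
#' correlation(s), with factor variances fixed at 1 for identification.
#' `chi^2 = (N - 1) F_min`. With a saturated mean structure the means are
#' absorbed exactly by the sample means: they enter the parameter count `q`
#' (and hence AIC) but not the discrepancy. Degrees of freedom are
#' `p (p + 3) / 2 - q` with means, `p (p + 1) / 2 - q` without.
#'
#' @param sampleCov sample covariance matrix (positive definite).
#' @param sampleMeans sample mean vector (used only for reporting; may be NULL).
#' @param N sample size (> number of items).
#' @param model a [CfaModel-class].
#' @param floorFrac residual variances are floored at `floorFrac * s_jj`
#'   (Heywood protection); pinned items are flagged.
#' @param nStarts number of optimizer starts (default 3; the extra starts
#'   jitter the loadings).
#' @return a [CfaFit-class].
#' @export
fitCfa <- function(sampleCov, sampleMeans = NULL, N, model,
                   floorFrac = 1e-4, nStarts = 3L) {
  S <- as.matrix(sampleCov)
  p <- nrow(S)
  if (N <= p) stop("N must exceed the number of items")
  pat <- model@loadingPattern
  stopifnot(nrow(pat) == p)
  nf <- ncol(pat)
  whichFac <- apply(pat, 1L, which.max)
  nCorr <- if (nf > 1L) nf * (nf - 1L) / 2L else 0L
  floorV <- floorFrac * diag(S)

  unpack <- function(par) {
    lam <- matrix(0, p, nf)
    lam[cbind(seq_len(p), whichFac)] <- par[seq_len(p)]
    res <- pmax(exp(par[p + seq_len(p)]), floorV)
    Psi <- diag(nf)
    if (nCorr) {
      rho <- tanh(par[2L * p + seq_len(nCorr)])
      Psi[lower.tri(Psi)] <- rho
      Psi[upper.tri(Psi)] <- t(Psi)[upper.tri(Psi)]
    }
    list(lam = lam, res = res, Psi = Psi)
  }
  obj <- function(par) {
    pp <- unpack(par)
    Sigma <- pp$lam %*% pp$Psi %*% t(pp$lam) + diag(pp$res, p)
    out <- try(mlDiscrepancy(S, Sigma), silent = TRUE)
    if (inherits(out, "try-error") || !is.finite(out)) 1e10 else out
  }
  start0 <- c(0.7 * sqrt(diag(S)), log(0.5 * diag(S)), rep(atanh(0.3), nCorr))
  best <- NULL
  for (s in seq_len(nStarts)) {
    st <- start0
    if (s > 1L) st[seq_len(p)] <- st[seq_len(p)] * (0.5 + s / nStarts)
    o <- optim(st, obj, method = "BFGS",
               control = list(maxit = 1000L, reltol = 1e-14))
    o <- optim(o$par, obj, method = "BFGS",
               control = list(maxit = 1000L, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  pp <- unpack(best$par)
  ## sign convention: majority-positive loadings per factor
  for (f in seq_len(nf)) {
    sel <- whichFac == f
    if (sum(pp$lam[sel, f]) < 0) {
      pp$lam[sel, f] <- -pp$lam[sel, f]
      if (nf > 1L) for (g in seq_len(nf)) if (g != f)
        pp$Psi[f, g] <- pp$Psi[g, f] <- -pp$Psi[f, g]
    }
  }
  Fmin <- best$value
  heywood <- pp$res <= floorV * (1 + 1e-8)
  if (any(heywood))
    warning("Heywood case: residual variance floored for item(s) ",
            paste(which(heywood), collapse = ", "))
  q <- p + p + nCorr + if (model@meanStructure) p else 0L
  nMoments <- p * (p + 1L) / 2L + if (model@meanStructure) p else 0L
  df <- as.integer(nMoments - q)
  chi2 <- (N - 1) * Fmin
  bl <- baselineModel(S, N)
  fi <- fitIndices(chi2, df, N, bl$chiSquare, bl$df, q)
  se <- cfaLoadingSE(S, N, best$par, obj, p, nf, whichFac)
  new("CfaFit", loadings = pp$lam, loadingSE = se, residuals = pp$res,
      factorCov = pp$Psi, chiSquare = chi2, df = df, pValue = fi$pValue,
      cfi = fi$cfi, rmsea = fi$rmsea, aic = fi$aic,
      nFreeParams = as.integer(q), N = as.integer(N),
      baselineChiSquare = bl$chiSquare, baselineDf = as.integer(bl$df),
      discrepancy = Fmin, converged = best$convergence == 0L,
      heywood = heywood)
}

## Loading standard errors from the numerical Hessian of (N-1)/2 * F
## at the optimum (information-matrix approximation).
cfaLoadingSE <- function(S, N, par, obj, p, nf, whichFac, h = 1e-4) {
  k <- length(par)
  H <- matrix(NA_real_, k, k)
  f0 <- obj(par)
  fp <- vapply(seq_len(k), function(i) {
    e <- rep(0, k); e[i] <- h; obj(par + e)
  }, 1.0)
  fm <- vapply(seq_len(k), function(i) {
    e <- rep(0, k); e[i] <- h; obj(par - e)
  }, 1.0)
  for (i in seq_len(k)) {
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
    if (i < k) for (j in (i + 1L):k) {
      eij <- rep(0, k); eij[i] <- h; eij[j] <- h
      fij <- obj(par + eij)
      H[i, j] <- H[j, i] <- (fij - fp[i] - fp[j] + f0) / h^2
    }
  }
  seMat <- matrix(NA_real_, p, nf)
  ok <- try({
    covPar <- solve((N - 1) / 2 * H)
    seAll <- sqrt(pmax(diag(covPar), 0))
    seMat[cbind(seq_len(p), whichFac)] <- seAll[seq_len(p)]
  }, silent = TRUE)
  seMat
}

#' Sample covariance and means from a response matrix
#'
#' Treats the ordered categories as numeric scores (the plain-ML-on-ordinal
#' convention) and uses listwise-complete rows.
#'
#' @param responses respondent x item matrix, NA = missing.
#' @return list with `cov`, `means`, `N` (complete cases).
#' @export
covFromResponses <- function(responses) {
  responses <- as.matrix(responses)
  cc <- stats::complete.cases(responses)
  if (sum(cc) < 3L) stop("fewer than 3 complete cases")
  X <- responses[cc, , drop = FALSE]
  list(cov = cov(X), means = colMeans(X), N = as.integer(nrow(X)))
}

#' Standard one- and two-factor patterns for a simple-structure bank
#'
#' @param bank an [ItemBank-class] with simple structure.
#' @return list of [CfaModel-class]: `unidimensional`, `multidimensional`.
#' @export
cfaModelsFromBank <- function(bank) {
  pat <- loadingPattern(bank)
  list(unidimensional = cfaModel(matrix(TRUE, nItems(bank), 1L)),
       multidimensional = cfaModel(pat))
}
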