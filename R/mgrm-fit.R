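## Marginal maximum-likelihood estimation of the MGRM by EM.
##
## The E-step evaluates each respondent's posterior over the quadrature nodes;
## the M-step maximizes the expected complete-data log-likelihood item by item
## (bounded quasi-Newton over the free discriminations and all boundaries) and,
## when requested, the latent correlation. Because both M-steps maximize the
## discretized model's expected log-likelihood exactly, the marginal
## log-likelihood path is nondecreasing for deterministic rules.

validateResponses <- function(responses, bank) {
  if (!is.matrix(responses)) responses <- as.matrix(responses)
  if (ncol(responses) != nItems(bank))
    stop("responses have ", ncol(responses), " columns; bank has ",
         nItems(bank), " items")
  cats <- nCategories(bank)
  for (j in seq_len(ncol(responses))) {
    x <- responses[, j]
    bad <- which(!is.na(x) & (x < 0 | x > cats[j] - 1L | x != round(x)))
    if (length(bad))
      stop("item ", j, ": out-of-range or non-integer responses in rows ",
           paste(utils::head(bad, 5L), collapse = ", "))
  }
  storage.mode(responses) <- "integer"
  responses
}

#' E-step: posterior node weights and marginal log-likelihood
#'
#' For each respondent, the posterior probability over quadrature nodes is
#' proportional to prior weight times the graded-response likelihood of the
#' observed items (missing items drop out). Rows are normalized; the marginal
#' log-likelihood is the sum of log weighted likelihoods. An all-missing
#' respondent has the prior as posterior and contributes 0.
#'
#' @param responses respondent x item integer matrix (0-based, NA = missing).
#' @param bank current [ItemBank-class].
#' @param latentCorr D x D latent correlation (default identity).
#' @param rule a [QuadratureRule-class].
#' @return list with `posterior` (n x K, rows sum to 1), `loglik`,
#'   `nodeCounts` (expected respondents per node), `nodes` (the
#'   correlation-transformed node matrix the posterior lives on).
#' @export
eStep <- function(responses, bank, latentCorr = NULL, rule = quadratureRule(nDimensions(bank))) {
  D <- nDimensions(bank)
  if (is.null(latentCorr)) latentCorr <- diag(D)
  responses <- validateResponses(responses, bank)
  w <- rule@weights
  nodes <- latentNodes(rule, latentCorr)
  K <- nrow(nodes)
  n <- nrow(responses)
  L <- matrix(1, n, K)
  for (j in seq_len(nItems(bank))) {
    x <- responses[, j]
    obs <- !is.na(x)
    if (!any(obs)) next
    ptj <- t(categoryProbMatrix(bank@items[[j]], nodes))  # cats x K
    L[obs, ] <- L[obs, , drop = FALSE] * ptj[x[obs] + 1L, , drop = FALSE]
  }
  lmax <- apply(L, 1L, max)
  lmax[lmax == 0] <- 1        # impossible response pattern: flat posterior
  Ls <- L / lmax
  marg <- drop(Ls %*% w)
  loglik <- sum(log(marg) + log(lmax))
  post <- Ls * rep(w, each = n)
  post <- post / rowSums(post)
  list(posterior = post, loglik = loglik, nodeCounts = colSums(post),
       nodes = nodes)
}

## Expected category counts at each node for one item: K x (m + 1).
expectedCounts <- function(posterior, x, nCats) {
  obs <- !is.na(x)
  ind <- outer(x[obs], 0:(nCats - 1L), "==") * 1
  crossprod(posterior[obs, , drop = FALSE], ind)
}

#' M-step update of one item's parameters
#'
#' Maximizes the item's expected complete-data log-likelihood
#' `sum_k sum_t r_kt log P_t(node_k)` over the free discrimination entries and
#' all boundary parameters by bounded quasi-Newton (box `[-bound, bound]`).
#' Discriminations fixed at zero by the loading pattern are untouched. If the
#' optimum violates the decreasing-boundary ordering the boundaries are
#' re-sorted with a warning; estimates pinned at the box are flagged
#' (typically an unobserved extreme category driving a boundary off to
#' infinity).
#'
#' @param counts K x nCategories expected count matrix from the E-step.
#' @param nodes quadrature node matrix (K x D).
#' @param current the item's current [ItemParameters-class].
#' @param freeMask logical length-D mask of free discriminations (default:
#'   from the current nonzero pattern).
#' @param bound box half-width for all parameters (default 25).
#' @return list `item` (updated [ItemParameters-class]), `flag` (character,
#'   zero-length if clean).
#' @export
mStepItem <- function(counts, nodes, current, freeMask = current@a != 0,
                      bound = 25) {
  m <- length(current@d)
  stopifnot(ncol(counts) == m + 1L, nrow(counts) == nrow(nodes))
  free <- which(freeMask)
  nfree <- length(free)
  parts <- function(p) {
    a <- current@a
    a[free] <- p[seq_len(nfree)]
    d <- p[nfree + seq_len(m)]
    z <- outer(drop(nodes %*% a), d, "+")
    cum <- cbind(1, linkCdf(z, current@link), 0)
    dens <- cbind(0, linkPdf(z, current@link), 0)
    ## floor far below any data-relevant probability: bounds the otherwise
    ## astronomically stiff gradients where a category's mass underflows
    P <- pmax(cum[, 1:(m + 1L), drop = FALSE] - cum[, 2:(m + 2L), drop = FALSE],
              1e-10)
    list(z = z, dens = dens, P = P)
  }
  negEll <- function(p) -sum(counts * log(parts(p)$P))
  negGrad <- function(p) {
    pt <- parts(p)
    R <- counts / pt$P                               # K x (m+1)
    ## boundary d_u enters P_{t=u} with +f(z_u) and P_{t=u-1} with -f(z_u)
    gd <- colSums((R[, 1:m, drop = FALSE] -
                     R[, 2:(m + 1L), drop = FALSE]) *
                    pt$dens[, 2:(m + 1L), drop = FALSE])
    ## slopes: d/d s_k of sum_t r log P, then chain through nodes
    dP <- pt$dens[, 1:(m + 1L), drop = FALSE] - pt$dens[, 2:(m + 2L), drop = FALSE]
    gs <- rowSums(R * dP)
    ga <- -drop(crossprod(nodes[, free, drop = FALSE], gs))
    c(ga, gd)
  }
  p0 <- c(current@a[free], current@d)
  opt <- try(optim(p0, negEll, gr = negGrad, method = "L-BFGS-B",
                   lower = rep(-bound, length(p0)), upper = rep(bound, length(p0)),
                   control = list(maxit = 300L, factr = 1e5)), silent = TRUE)
  ## code 52 (abnormal line-search exit) near a stationary point still returns
  ## the best point found; accept any outcome that did not worsen the objective
  ok <- !inherits(opt, "try-error") && is.finite(opt$value) &&
    opt$value <= negEll(p0) + 1e-8
  if (!ok) {
    ## unbounded quasi-Newton rescue, clamped back into the box
    alt <- try(optim(p0, negEll, gr = negGrad, method = "BFGS",
                     control = list(maxit = 300L, reltol = 1e-12)), silent = TRUE)
    if (!inherits(alt, "try-error") && is.finite(alt$value)) {
      alt$par <- pmin(pmax(alt$par, -bound), bound)
      alt$value <- negEll(alt$par)
      if (alt$value <= negEll(p0) + 1e-8) {
        opt <- alt
        ok <- TRUE
      }
    }
  }
  if (!ok) {
    return(list(item = current,
                flag = paste0(current@itemId, ": M-step optimizer failed; previous values kept")))
  }
  flag <- character()
  a <- current@a
  a[free] <- opt$par[seq_len(nfree)]
  d <- opt$par[nfree + seq_len(m)]
  if (any(abs(opt$par) >= bound - 1e-6))
    flag <- c(flag, paste0(current@itemId, ": estimate at search boundary (unobserved extreme category?)"))
  if (any(colSums(counts) < 0.5))
    flag <- c(flag, paste0(current@itemId,
      ": a category has (near-)zero expected observations; its boundary is unidentified and drifts to the extreme"))
  if (m > 1L && any(diff(d) >= 0)) {
    warning("item '", current@itemId, "': boundary ordering violated; re-sorted")
    d <- sort(d, decreasing = TRUE)
    d <- d - cumsum(c(0, as.numeric(diff(d) == 0))) * 1e-6  # break exact ties
  }
  item <- itemParameters(current@itemId, a = a, d = d, link = current@link,
                         label = current@label)
  list(item = item, flag = flag)
}

#' Re-estimate the latent correlation from E-step output
#'
#' Given the pooled posterior second-moment matrix of the latent traits,
#' rescales it to a correlation matrix (unit diagonal); a non-positive-definite
#' pooled moment is repaired to the nearest positive-definite matrix with a
#' warning.
#'
#' @param secondMoment pooled D x D posterior moment `E[theta theta^T]`
#'   averaged over respondents.
#' @return symmetric positive-definite correlation matrix, unit diagonal.
#' @export
updateLatentCorr <- function(secondMoment) {
  M <- (secondMoment + t(secondMoment)) / 2
  if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
    warning("pooled moment matrix not positive definite; applying nearest-PD repair")
    M <- as.matrix(Matrix::nearPD(M, corr = FALSE)$mat)
  }
  R <- cov2cor(M)
  diag(R) <- 1
  R
}

## M-step for the latent correlation of a two-dimensional prior with unit
## variances: maximizes the expected Gaussian log-likelihood
## -(log(1 - rho^2) + (m11 + m22 - 2 rho m12) / (1 - rho^2)) at the pooled
## posterior second moment M (per respondent).
rhoMStep <- function(M, lower = -0.995, upper = 0.995) {
  g <- function(rho)
    -(log(1 - rho^2) + (M[1L, 1L] + M[2L, 2L] - 2 * rho * M[1L, 2L]) / (1 - rho^2))
  optimize(g, c(lower, upper), maximum = TRUE, tol = 1e-9)$maximum
}

## Drop categories never observed: responses are remapped onto 0..(k-1) over
## the observed categories and the item's boundary count shrinks accordingly.
collapseEmptyCategories <- function(responses, bank) {
  maps <- list()
  items <- bank@items
  for (j in seq_len(nItems(bank))) {
    cats <- 0:(nCategories(bank)[j] - 1L)
    seen <- sort(unique(responses[!is.na(responses[, j]), j]))
    if (length(seen) < 2L)
      stop("item ", j, " has fewer than 2 observed categories; cannot fit a graded model")
    if (length(seen) < length(cats)) {
      map <- stats::setNames(match(responses[, j], seen) - 1L, NULL)
      maps[[itemIds(bank)[j]]] <- stats::setNames(seq_along(seen) - 1L, seen)
      responses[, j] <- map
      it <- items[[j]]
      mNew <- length(seen) - 1L
      ## boundary for new category t is the old boundary of its source
      ## category (valid because the removed categories carry no data)
      dNew <- if (length(it@d) == length(cats) - 1L) it@d[seen[-1L]] else
        seq((mNew - 1) / 2, -(mNew - 1) / 2, length.out = mNew)
      items[[j]] <- itemParameters(it@itemId, a = it@a, d = dNew,
                                   link = it@link, label = it@label)
      message("item '", it@itemId, "': empty categories collapsed (",
              length(cats) - length(seen), " removed)")
    }
  }
  bank2 <- itemBank(items, loadingPattern = bank@loadingPattern,
                    dimensionNames = bank@dimensionNames,
                    categoryLabels = bank@categoryLabels)
  list(responses = responses, bank = bank2, maps = maps)
}

## Starting slopes: a quick linear CFA on the score covariance under the
## bank's own loading pattern; the standardized loading lambda maps to a
## slope via the underlying-variable correspondence a = lambda/sqrt(1-lambda^2)
## (attenuated by categorization, hence a mild understate, but item-specific
## and on the right ordering). Falls back to 1 when the CFA is not estimable
## (tiny banks, too few complete cases).
cfaStartSlopes <- function(bank, responses) {
  out <- try(suppressWarnings({
    sm <- covFromResponses(responses)
    f <- fitCfa(sm$cov, sm$means, sm$N,
                cfaModel(loadingPattern(bank)), nStarts = 1L)
    lam <- apply(abs(f@loadings / sqrt(diag(sm$cov))), 1L, max)
    pmin(lam / sqrt(pmax(1 - lam^2, 0.05)), 4)
  }), silent = TRUE)
  if (inherits(out, "try-error") || any(!is.finite(out)))
    rep(1, nItems(bank)) else out
}

## Starting values: free slopes from cfaStartSlopes (or flat 1), boundaries
## from the inverse link of the marginal cumulative category proportions,
## scaled by sqrt(1 + a^2) for the attenuation of the marginal curve. With no
## data, equally spaced descending boundaries symmetric about 0. Boundary
## starts respect the strict ordering even for tied empirical proportions.
startingBank <- function(bank, responses = NULL, slopes = NULL) {
  if (is.null(slopes)) slopes <- rep(1, nItems(bank))
  items <- lapply(seq_len(nItems(bank)), function(j) {
    it <- bank@items[[j]]
    m <- length(it@d)
    a <- ifelse(bank@loadingPattern[j, ], slopes[j], 0)
    d0 <- if (m == 1L) 0 else seq((m - 1) / 2, -(m - 1) / 2, length.out = m)
    if (!is.null(responses)) {
      x <- responses[!is.na(responses[, j]), j]
      if (length(x) >= 2L) {
        ph <- vapply(seq_len(m), function(t) mean(x >= t), 1.0)
        eps <- 1 / (2 * length(x))
        d0 <- qnorm(pmin(pmax(ph, eps), 1 - eps)) * sqrt(1 + sum(a^2))
        d0 <- sort(d0, decreasing = TRUE) - (seq_len(m) - 1L) * 1e-3
      }
    }
    itemParameters(it@itemId, a = a, d = d0, link = it@link, label = it@label)
  })
  itemBank(items, loadingPattern = bank@loadingPattern,
           dimensionNames = bank@dimensionNames,
           categoryLabels = bank@categoryLabels)
}

freeParamVector <- function(bank, corr, estimateCorr) {
  v <- unlist(lapply(seq_len(nItems(bank)), function(j) {
    it <- bank@items[[j]]
    c(it@a[bank@loadingPattern[j, ]], it@d)
  }))
  if (estimateCorr && nDimensions(bank) == 2L) v <- c(v, corr[1L, 2L])
  v
}

#' Fit the multidimensional graded response model by EM
#'
#' Marginal maximum likelihood under confirmatory simple-structure constraints:
#' alternates the quadrature E-step with per-item bounded quasi-Newton M-steps
#' (and an exact latent-correlation M-step for two dimensions) until the
#' maximum absolute change over all free parameters drops below `tol` or
#' `maxIter` is reached. Categories never observed in the data are collapsed
#' first, with the remap recorded in the result.
#'
#' @param responses respondent x item integer matrix (0-based, NA = missing).
#' @param bank initial [ItemBank-class]: supplies the loading pattern, link and
#'   category counts. By default the bank's parameter values are replaced by
#'   data-driven starting values (free discriminations 1, boundaries from the
#'   inverse link of the marginal cumulative category proportions); set
#'   `startAtBank = TRUE` to start from the bank's own parameters.
#' @param rule a [QuadratureRule-class] (default: 21-node-per-dimension tensor
#'   Gauss-Hermite).
#' @param tol convergence tolerance on the max absolute parameter change
#'   (default 1e-4).
#' @param maxIter maximum EM iterations (default 500; 0 returns the starting
#'   values unconverged).
#' @param estimateCorr estimate the latent correlation (default TRUE; only
#'   meaningful for D >= 2).
#' @param latentCorr starting (or fixed) latent correlation matrix.
#' @param startAtBank use the bank's parameter values as starting values
#'   (single EM run, no restarts).
#' @param startScales multipliers applied to the CFA-informed starting slopes,
#'   one EM run per scale (default 1); a run from the flat neutral start
#'   (slopes 1) is always added, and the run with the best final marginal
#'   log-likelihood is returned. Restarts guard against the local maxima the
#'   graded likelihood can have when extreme categories are sparse.
#' @param computeSE compute standard errors for the free item parameters by a
#'   cross-product (outer-product-of-scores) approximation (default FALSE).
#' @return an [MgrmFit-class].
#' @examples
#' \donttest{
#' bank <- lssdBank()
#' sim <- simulateStudy(n = 300, seed = 7)
#' fit <- fitMgrm(sim@responses, bank, tol = 1e-3, maxIter = 50)
#' }
#' @export
fitMgrm <- function(responses, bank, rule = NULL, tol = 1e-4, maxIter = 500L,
                    estimateCorr = TRUE, latentCorr = NULL,
                    startAtBank = FALSE, startScales = 1,
                    computeSE = FALSE) {
  stopifnot(is(bank, "ItemBank"))
  responses <- validateResponses(responses, bank)
  if (nrow(responses) < 2L) stop("need at least 2 respondents")
  D <- nDimensions(bank)
  if (is.null(rule)) rule <- quadratureRule(D)
  if (is.null(latentCorr)) latentCorr <- diag(D)
  cl <- collapseEmptyCategories(responses, bank)
  responses <- cl$responses
  emRun <- function(startBank) {
    cur <- startBank
    corr <- latentCorr
    path <- numeric(0)
    flags <- character(0)
    convergedFlag <- FALSE
    iter <- 0L
    if (maxIter > 0L) {
      for (iter in seq_len(maxIter)) {
        es <- eStep(responses, cur, corr, rule)
        path <- c(path, es$loglik)
        old <- freeParamVector(cur, corr, estimateCorr)
        items <- cur@items
        iterFlags <- character()
        for (j in seq_len(nItems(cur))) {
          cnt <- expectedCounts(es$posterior, responses[, j], nCategories(cur)[j])
          up <- mStepItem(cnt, es$nodes, items[[j]],
                          freeMask = cur@loadingPattern[j, ])
          items[[j]] <- up$item
          iterFlags <- c(iterFlags, up$flag)
        }
        cur <- itemBank(items, loadingPattern = cur@loadingPattern,
                        dimensionNames = cur@dimensionNames,
                        categoryLabels = cur@categoryLabels)
        if (estimateCorr && D >= 2L) {
          M <- crossprod(es$nodes, es$nodes * es$nodeCounts) / nrow(responses)
          if (D == 2L) {
            rho <- rhoMStep(M)
            corr <- matrix(c(1, rho, rho, 1), 2L)
          } else {
            corr <- updateLatentCorr(M)
          }
        }
        flags <- unique(c(flags, iterFlags))
        delta <- max(abs(freeParamVector(cur, corr, estimateCorr) - old))
        if (delta < tol) { convergedFlag <- TRUE; break }
      }
    }
    list(cur = cur, corr = corr, path = path, iter = iter,
         converged = convergedFlag, flags = flags,
         final = if (length(path)) utils::tail(path, 1L) else -Inf)
  }
  ## the marginal likelihood can be multimodal when extreme categories are
  ## sparse; run EM from CFA-informed slope starts (optionally rescaled) plus
  ## a flat neutral start, and keep the best final mode
  starts <- if (startAtBank) list(cl$bank) else {
    slopes <- cfaStartSlopes(cl$bank, cl$responses)
    c(lapply(startScales, function(s)
        startingBank(cl$bank, cl$responses, slopes * s)),
      list(startingBank(cl$bank, cl$responses)))
  }
  runs <- lapply(starts, emRun)
  best <- runs[[which.max(vapply(runs, `[[`, 1.0, "final"))]]
  se <- NULL
  if (computeSE) se <- mgrmStandardErrors(responses, best$cur, best$corr, rule)
  new("MgrmFit", bank = best$cur, latentCorr = best$corr,
      loglikPath = best$path, nIterations = best$iter,
      converged = best$converged, tolerance = tol,
      standardErrors = se, collapseMap = cl$maps, flags = best$flags)
}

## Outer-product-of-scores (BHHH) standard errors for the free item
## parameters, with per-respondent scores by central finite differences of
## the individual marginal log-likelihoods.
mgrmStandardErrors <- function(responses, bank, corr, rule, h = 1e-4) {
  perRespLoglik <- function(b) {
    w <- rule@weights
    nodes <- latentNodes(rule, corr)
    n <- nrow(responses)
    L <- matrix(1, n, nrow(nodes))
    for (j in seq_len(nItems(b))) {
      x <- responses[, j]
      obs <- !is.na(x)
      if (!any(obs)) next
      ptj <- t(categoryProbMatrix(b@items[[j]], nodes))
      L[obs, ] <- L[obs, , drop = FALSE] * ptj[x[obs] + 1L, , drop = FALSE]
    }
    log(pmax(drop(L %*% w), 1e-300))
  }
  perturb <- function(j, slot, idx, eps) {
    items <- bank@items
    it <- items[[j]]
    if (slot == "a") it@a[idx] <- it@a[idx] + eps else it@d[idx] <- it@d[idx] + eps
    items[[j]] <- it
    itemBank(items, loadingPattern = bank@loadingPattern,
             dimensionNames = bank@dimensionNames,
             categoryLabels = bank@categoryLabels)
  }
  specs <- list()
  for (j in seq_len(nItems(bank))) {
    for (idx in which(bank@loadingPattern[j, ]))
      specs[[length(specs) + 1L]] <- list(j = j, slot = "a", idx = idx)
    for (idx in seq_along(bank@items[[j]]@d))
      specs[[length(specs) + 1L]] <- list(j = j, slot = "d", idx = idx)
  }
  S <- vapply(specs, function(s) {
    (perRespLoglik(perturb(s$j, s$slot, s$idx, h)) -
       perRespLoglik(perturb(s$j, s$slot, s$idx, -h))) / (2 * h)
  }, numeric(nrow(responses)))
  info <- crossprod(S)
  seVec <- rep(NA_real_, length(specs))
  ok <- try({
    seVec <- sqrt(diag(solve(info)))
  }, silent = TRUE)
  out <- lapply(seq_len(nItems(bank)), function(j) {
    sel <- vapply(specs, function(s) s$j == j, TRUE)
    stats::setNames(seVec[sel], vapply(specs[sel], function(s)
      paste0(s$slot, s$idx), ""))
  })
  stats::setNames(out, itemIds(bank))
}
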