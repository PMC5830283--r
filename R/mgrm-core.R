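## The measurement model: multidimensional graded response probabilities,
## discrimination summaries, information functions and EAP severity scoring.

linkCdf <- function(z, link) {
  switch(link, probit = pnorm(z), logistic = plogis(z),
         stop("unknown link: ", link))
}

linkPdf <- function(z, link) {
  switch(link, probit = dnorm(z), logistic = dlogis(z),
         stop("unknown link: ", link))
}

#' Cumulative (boundary) response probability
#'
#' Probability that a respondent with severity vector `theta` endorses
#' category `t` *or above* of a graded item:
#' `P*_t(theta) = link(a . theta + d_t)` for `t = 1..m`, with the boundary
#' conventions `P*_0 = 1` and `P*_{m+1} = 0`.
#'
#' @param item an [ItemParameters-class].
#' @param theta numeric severity vector of length `D` (finite).
#' @param t boundary index, `0 <= t <= m + 1`; vectorized over `t`.
#' @return probability (vector along `t`).
#' @examples
#' it <- itemParameters("i1", a = c(2.03, 0), d = c(-0.15, -2.60, -5.39))
#' cumulativeProb(it, c(0, 0), 1)  # pnorm(-0.15)
#' @export
cumulativeProb <- function(item, theta, t) {
  stopifnot(is(item, "ItemParameters"))
  if (any(!is.finite(theta)) || length(theta) != length(item@a))
    stop("theta must be finite with length D = ", length(item@a))
  m <- length(item@d)
  if (any(t < 0L) || any(t > m + 1L))
    stop("boundary index t out of range [0, ", m + 1L, "]")
  z <- sum(item@a * theta)
  vapply(t, function(tt) {
    if (tt == 0L) 1 else if (tt == m + 1L) 0 else linkCdf(z + item@d[tt], item@link)
  }, 1.0)
}

#' Category response probability
#'
#' Probability of endorsing *exactly* category `t` (0-based):
#' `P_t = P*_t - P*_{t+1}`. Categories sum to one at every `theta`.
#'
#' @inheritParams cumulativeProb
#' @param t category index, `0 <= t <= m`; vectorized.
#' @return probability (vector along `t`).
#' @export
categoryProb <- function(item, theta, t) {
  m <- length(item@d)
  if (any(t < 0L) || any(t > m)) stop("category index t out of range [0, ", m, "]")
  cumulativeProb(item, theta, t) - cumulativeProb(item, theta, t + 1L)
}

## All category probabilities of one item at many theta points.
## thetaMat: K x D. Returns K x (m + 1).
categoryProbMatrix <- function(item, thetaMat) {
  m <- length(item@d)
  z <- drop(thetaMat %*% item@a)
  cum <- cbind(1, linkCdf(outer(z, item@d, "+"), item@link), 0)
  p <- cum[, 1:(m + 1L), drop = FALSE] - cum[, 2:(m + 2L), drop = FALSE]
  pmax(p, 0)
}

#' @describeIn mdisc Euclidean norm of one item's discrimination vector
#' @export
setMethod("mdisc", "ItemParameters", function(x) {
  if (all(x@a == 0)) stop("mdisc undefined for an item with all-zero discrimination")
  sqrt(sum(x@a^2))
})

#' @describeIn mdisc per-item MDISC for a whole bank
#' @export
setMethod("mdisc", "ItemBank",
          function(x) vapply(stats::setNames(x@items, itemIds(x)), mdisc, 1.0))

#' Classify item quality from MDISC
#'
#' Conventional cutoffs: above 1 is `"high"`, between 0.5 and 1 `"medium"`,
#' below 0.5 `"low"`.
#'
#' @param m MDISC value(s).
#' @return character vector.
#' @export
mdiscQuality <- function(m) {
  out <- ifelse(m > 1, "high", ifelse(m >= 0.5, "medium", "low"))
  as.character(out)
}

#' Directional item information
#'
#' Fisher information of a graded item about movement of `theta` in a given
#' unit direction `u`:
#' `I(theta, u) = (a . u)^2 * sum_t (f(z_t) - f(z_{t+1}))^2 / P_t`,
#' where `f` is the link density and `z_t = a . theta + d_t`. Under simple
#' structure the default direction is the item's own loading axis.
#'
#' @param item an [ItemParameters-class].
#' @param theta severity vector, length `D`.
#' @param direction unit vector of length `D`; default: the item's own
#'   (normalized) discrimination direction.
#' @return nonnegative scalar.
#' @export
itemInformation <- function(item, theta, direction = NULL) {
  a <- item@a
  if (all(a == 0)) {
    if (is.null(direction)) stop("degenerate item has no loading direction")
  }
  if (is.null(direction)) direction <- a / sqrt(sum(a^2))
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must have nonzero norm")
  if (abs(nrm - 1) > 1e-8) stop("direction must have unit norm")
  if (length(direction) != length(a)) stop("direction must have length D")
  m <- length(item@d)
  z <- sum(a * theta) + item@d
  dens <- c(0, linkPdf(z, item@link), 0)          # f at boundaries 0..m+1
  cum <- c(1, linkCdf(z, item@link), 0)
  p <- cum[1:(m + 1L)] - cum[2:(m + 2L)]
  dd <- dens[1:(m + 1L)] - dens[2:(m + 2L)]       # d/d(a.theta) of P_t, / 1
  keep <- p > 1e-300
  sum(a * direction)^2 * sum(dd[keep]^2 / p[keep])
}

#' Test (or item) information over a rectangular theta grid
#'
#' Evaluates, at every node of a tensor grid, the sum over the bank's items of
#' each item's information along its own loading direction. Items with an
#' all-zero discrimination vector contribute zero information.
#'
#' @param bank an [ItemBank-class].
#' @param axisRange numeric length-2 interval applied to every dimension
#'   (default `c(-4, 4)`), or a list of per-dimension intervals.
#' @param step grid spacing, `> 0` (default 0.1).
#' @return a data.frame in long format: one theta column per dimension, the
#'   per-item information columns, and `test` = their sum. Values are
#'   nonnegative everywhere.
#' @export
testInformationGrid <- function(bank, axisRange = c(-4, 4), step = 0.1) {
  stopifnot(is(bank, "ItemBank"))
  if (step <= 0) stop("step must be positive")
  D <- nDimensions(bank)
  if (!is.list(axisRange)) axisRange <- rep(list(axisRange), D)
  axes <- lapply(axisRange, function(r) seq(r[1L], r[2L], by = step))
  grid <- as.matrix(expand.grid(axes))
  colnames(grid) <- bank@dimensionNames
  K <- nrow(grid)
  info <- matrix(0, K, nItems(bank), dimnames = list(NULL, itemIds(bank)))
  for (j in seq_len(nItems(bank))) {
    it <- bank@items[[j]]
    if (all(it@a == 0)) next
    u <- it@a / sqrt(sum(it@a^2))
    m <- length(it@d)
    z <- outer(drop(grid %*% it@a), it@d, "+")     # K x m
    dens <- cbind(0, linkPdf(z, it@link), 0)
    cum <- cbind(1, linkCdf(z, it@link), 0)
    p <- cum[, 1:(m + 1L), drop = FALSE] - cum[, 2:(m + 2L), drop = FALSE]
    dd <- dens[, 1:(m + 1L), drop = FALSE] - dens[, 2:(m + 2L), drop = FALSE]
    ratio <- dd^2 / pmax(p, 1e-300)
    info[, j] <- sum(it@a * u)^2 * rowSums(ratio)
  }
  out <- data.frame(grid, info, test = rowSums(info), check.names = FALSE)
  attr(out, "kind") <- "test"
  out
}

#' Item characteristic curves along the item's own factor
#'
#' Category probabilities traced along one latent dimension with all other
#' coordinates held at the prior mean 0. For a well-behaved graded item the
#' first category is monotone decreasing in severity, the last monotone
#' increasing, and interior categories unimodal.
#'
#' @param item an [ItemParameters-class].
#' @param ownDimension index of the dimension the item loads on.
#' @param thetaRange interval (default `c(-4, 4)`).
#' @param step spacing (default 0.1).
#' @return long data.frame with columns `theta`, `category`, `prob`.
#' @export
iccCurves <- function(item, ownDimension, thetaRange = c(-4, 4), step = 0.1) {
  stopifnot(is(item, "ItemParameters"))
  D <- length(item@a)
  if (ownDimension < 1L || ownDimension > D) stop("ownDimension out of range")
  if (item@a[ownDimension] == 0)
    stop("item '", item@itemId, "' has zero loading on dimension ", ownDimension)
  th <- seq(thetaRange[1L], thetaRange[2L], by = step)
  grid <- matrix(0, length(th), D)
  grid[, ownDimension] <- th
  p <- categoryProbMatrix(item, grid)
  data.frame(theta = rep(th, ncol(p)),
             category = rep(seq_len(ncol(p)) - 1L, each = length(th)),
             prob = as.vector(p))
}

#' Expected a posteriori (EAP) severity scores
#'
#' Posterior mean and standard deviation of the latent severity vector for
#' each respondent, under a zero-mean multivariate normal prior with the
#' given latent correlation and the graded-response likelihood, integrated on
#' the supplied quadrature rule (the same machinery used in estimation).
#' Missing items contribute no likelihood term; an all-missing respondent is
#' returned as the prior mean with the prior SD and flagged.
#'
#' @param bank an [ItemBank-class].
#' @param responses integer vector (one respondent) or matrix (respondents x
#'   items), 0-based categories, NA = missing.
#' @param latentCorr D x D correlation matrix (default identity).
#' @param rule a [QuadratureRule-class]; default 21-node tensor Gauss-Hermite.
#' @return data.frame with per-dimension posterior means (`theta.*`), SDs
#'   (`sd.*`) and `allMissing` flag.
#' @export
eapScore <- function(bank, responses, latentCorr = NULL, rule = NULL) {
  stopifnot(is(bank, "ItemBank"))
  D <- nDimensions(bank)
  if (is.null(latentCorr)) latentCorr <- diag(D)
  if (is.null(rule)) rule <- quadratureRule(D)
  if (is.vector(responses)) responses <- matrix(responses, nrow = 1L)
  if (ncol(responses) != nItems(bank))
    stop("responses must have one column per bank item")
  w <- rule@weights
  nodes <- latentNodes(rule, latentCorr)
  K <- nrow(nodes)
  ptab <- lapply(bank@items, categoryProbMatrix, thetaMat = nodes)
  n <- nrow(responses)
  post <- matrix(rep(w, each = n), n, K)
  for (j in seq_len(nItems(bank))) {
    x <- responses[, j]
    obs <- !is.na(x)
    if (!any(obs)) next
    post[obs, ] <- post[obs, , drop = FALSE] *
      t(ptab[[j]])[x[obs] + 1L, , drop = FALSE]
  }
  norm <- rowSums(post)
  post <- post / norm
  mu <- post %*% nodes
  ex2 <- post %*% nodes^2
  sds <- sqrt(pmax(ex2 - mu^2, 0))
  out <- data.frame(mu, sds, allMissing = rowSums(!is.na(responses)) == 0L)
  names(out) <- c(paste0("theta.", bank@dimensionNames),
                  paste0("sd.", bank@dimensionNames), "allMissing")
  out
}
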