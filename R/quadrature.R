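## Quadrature rules for integrating against the latent-severity prior.

## Radical-inverse (van der Corput) digits of n in the given base.
radicalInverse <- function(n, base) {
  out <- numeric(length(n))
  f <- 1 / base
  n <- as.integer(n)
  while (any(n > 0L)) {
    out <- out + f * (n %% base)
    n <- n %/% base
    f <- f / base
  }
  out
}

#' Build a quadrature rule for the standard normal prior
#'
#' `gauss_hermite_tensor` tensors a one-dimensional Gauss-Hermite rule
#' (rescaled to the standard normal) across dimensions: deterministic, exact
#' for polynomial moments, `nPerDim^D` nodes. `quasi_monte_carlo` maps a
#' low-discrepancy Halton-type sequence (bases 2, 3, 5, ...), randomly shifted
#' modulo 1 under the given seed, through the normal quantile function
#' (correlated priors use Cholesky-transformed nodes, see [latentNodes()]), with
#' equal weights.
#'
#' @param D number of latent dimensions.
#' @param kind rule type.
#' @param nPerDim Gauss-Hermite nodes per dimension (default 21).
#' @param nPoints total quasi-Monte-Carlo points (default 2000).
#' @param seed integer seed for the QMC shift (default 1).
#' @return a [QuadratureRule-class].
#' @export
quadratureRule <- function(D, kind = c("gauss_hermite_tensor", "quasi_monte_carlo"),
                           nPerDim = 21L, nPoints = 2000L, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "gauss_hermite_tensor") {
    gh <- pracma::gaussHermite(nPerDim)
    x <- gh$x * sqrt(2)               # nodes for N(0, 1)
    w <- gh$w / sqrt(pi)
    axes <- rep(list(x), D)
    nodes <- as.matrix(expand.grid(axes))
    wgrid <- as.matrix(expand.grid(rep(list(w), D)))
    weights <- apply(wgrid, 1L, prod)
    rule <- new("QuadratureRule", kind = kind, nodes = unname(nodes),
                weights = weights / sum(weights), seed = NA_integer_)
  } else {
    primes <- c(2, 3, 5, 7, 11, 13, 17, 19)
    if (D > length(primes)) stop("QMC rule supports up to ", length(primes), " dimensions")
    set.seed(as.integer(seed))
    shift <- runif(D)
    idx <- seq_len(nPoints)
    u <- vapply(seq_len(D), function(d)
      (radicalInverse(idx, primes[d]) + shift[d]) %% 1, numeric(nPoints))
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    nodes <- qnorm(matrix(u, ncol = D))
    rule <- new("QuadratureRule", kind = kind, nodes = nodes,
                weights = rep(1 / nPoints, nPoints), seed = as.integer(seed))
  }
  rule
}

#' Nodes of a rule under a correlated latent prior
#'
#' Maps the standard-normal nodes through the Cholesky factor of the latent
#' correlation, so that the (unchanged) rule weights integrate exactly against
#' `N(0, corr)`. This keeps the Gauss-Hermite accuracy intact at any
#' correlation, unlike density reweighting of fixed nodes.
#'
#' @param rule a [QuadratureRule-class].
#' @param corr D x D correlation matrix, positive definite with unit diagonal.
#' @return K x D node matrix.
#' @export
latentNodes <- function(rule, corr) {
  stopifnot(is(rule, "QuadratureRule"))
  D <- ncol(rule@nodes)
  if (any(abs(diag(corr) - 1) > 1e-8)) stop("corr must have unit diagonal")
  if (all(abs(corr - diag(D)) < 1e-15)) return(rule@nodes)
  rule@nodes %*% chol(corr)
}
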