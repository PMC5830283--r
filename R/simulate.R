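## Synthetic respondent populations with the structure the analysis assumes:
## correlated bivariate-normal severities, graded-model category draws.

#' Draw correlated latent severities
#'
#' Samples `n` severity vectors from a zero-mean bivariate normal with unit
#' variances and the given correlation. Deterministic under the seed.
#'
#' @param n respondents.
#' @param latentCorr correlation in (-1, 1), default 0.5.
#' @param seed integer seed.
#' @return n x 2 matrix.
#' @export
simulateTheta <- function(n, latentCorr = 0.5, seed = 1L) {
  if (abs(latentCorr) >= 1) stop("latentCorr must lie strictly inside (-1, 1)")
  set.seed(as.integer(seed))
  Z <- matrix(rnorm(2L * n), n, 2L)
  Sigma <- matrix(c(1, latentCorr, latentCorr, 1), 2L)
  Z %*% chol(Sigma)
}

#' Draw graded-model responses at given severities
#'
#' Each cell is drawn from its item's category distribution at that
#' respondent's severity (inverse-CDF draw against the decreasing cumulative
#' boundary probabilities), then missing cells are inserted completely at
#' random at `missingRate`. Deterministic under the seed.
#'
#' @param theta respondent x D severity matrix.
#' @param bank an [ItemBank-class].
#' @param missingRate proportion in `[0, 1)`, default 0.
#' @param seed integer seed.
#' @return respondent x item integer matrix (0-based categories, NA missing).
#' @export
simulateResponses <- function(theta, bank, missingRate = 0, seed = 1L) {
  stopifnot(is(bank, "ItemBank"))
  theta <- as.matrix(theta)
  if (ncol(theta) != nDimensions(bank))
    stop("theta has ", ncol(theta), " columns; bank has D = ", nDimensions(bank))
  if (missingRate < 0 || missingRate >= 1) stop("missingRate must be in [0, 1)")
  set.seed(as.integer(seed))
  n <- nrow(theta)
  J <- nItems(bank)
  out <- matrix(NA_integer_, n, J, dimnames = list(NULL, itemIds(bank)))
  for (j in seq_len(J)) {
    it <- bank@items[[j]]
    z <- drop(theta %*% it@a)
    cum <- linkCdf(outer(z, it@d, "+"), it@link)   # n x m, decreasing in t
    u <- runif(n)
    out[, j] <- as.integer(rowSums(u < cum))
  }
  if (missingRate > 0) {
    miss <- matrix(runif(n * J) < missingRate, n, J)
    out[miss] <- NA_integer_
  }
  out
}

#' Simulate a full synthetic study
#'
#' The one-call generator for a respondent population with the default study
#' conditions: 344 respondents answering the packaged nine-item scale under
#' the two-factor graded model with latent correlation 0.5. Reproducible
#' bit-for-bit from the configuration and seed.
#'
#' @param n respondents (default 344).
#' @param latentCorr generating latent correlation (default 0.5).
#' @param bank generating [ItemBank-class] (default [lssdBank()]).
#' @param missingRate completely-at-random missing proportion (default 0).
#' @param seed integer seed.
#' @return a [SimulatedStudy-class].
#' @examples
#' sim <- simulateStudy(n = 100, seed = 11)
#' table(sim@responses[, 1])
#' @export
simulateStudy <- function(n = 344L, latentCorr = 0.5, bank = lssdBank(),
                          missingRate = 0, seed = 1L) {
  theta <- simulateTheta(n, latentCorr, seed = seed)
  resp <- simulateResponses(theta, bank, missingRate = missingRate,
                            seed = as.integer(seed) + 1L)
  new("SimulatedStudy", responses = resp, trueTheta = theta, bank = bank,
      latentCorr = matrix(c(1, latentCorr, latentCorr, 1), 2L),
      seed = as.integer(seed))
}

#' Write a simulated study to disk as a fixture directory
#'
#' Writes the response matrix (CSV, blank = missing), the generating bank
#' (structured text), the true severities (CSV) and a manifest echoing the
#' configuration and seed.
#'
#' @param dir output directory (created if needed).
#' @inheritParams simulateStudy
#' @return the [SimulatedStudy-class], invisibly.
#' @export
makeFixture <- function(dir, n = 344L, latentCorr = 0.5, bank = lssdBank(),
                        missingRate = 0, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateStudy(n = n, latentCorr = latentCorr, bank = bank,
                       missingRate = missingRate, seed = seed)
  writeResponseMatrix(sim@responses, file.path(dir, "responses.csv"))
  writeItemBank(bank, file.path(dir, "bank.txt"))
  th <- data.frame(sim@trueTheta)
  names(th) <- bank@dimensionNames
  utils::write.csv(th, file.path(dir, "true_theta.csv"), row.names = FALSE)
  writeLines(c("# simulated study manifest",
               paste0("n: ", n),
               paste0("latent_corr: ", latentCorr),
               paste0("missing_rate: ", missingRate),
               paste0("seed: ", seed),
               paste0("link: ", itemLink(bank)),
               paste0("items: ", paste(itemIds(bank), collapse = " "))),
             file.path(dir, "manifest.txt"))
  invisible(sim)
}
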