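## Classical test theory: internal-consistency reliability and the sample
## description block.

#' Cronbach's alpha with item-level diagnostics
#'
#' `alpha = k / (k - 1) * (1 - sum(item variances) / var(total score))`,
#' computed on listwise-complete rows with N - 1 variance denominators.
#' Also reports corrected item-total correlations (item vs the sum of the
#' remaining items) and alpha-if-item-deleted.
#'
#' @param responses respondent x item numeric matrix, NA = missing.
#' @param dropZeroVariance drop zero-variance items (with a warning) instead
#'   of erroring (default FALSE).
#' @return list of class `reliability`: `alpha`, `nItems`, `nComplete`,
#'   `itemTotalCorrelations`, `alphaIfDeleted`.
#' @examples
#' x <- matrix(sample(0:3, 200, TRUE), 50, 4)
#' cronbachAlpha(x)$alpha
#' @export
cronbachAlpha <- function(responses, dropZeroVariance = FALSE) {
  X <- as.matrix(responses)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 2L) stop("need at least 2 complete cases")
  vars <- apply(X, 2L, var)
  if (any(vars == 0)) {
    if (!dropZeroVariance)
      stop("zero-variance item(s): ", paste(which(vars == 0), collapse = ", "))
    warning("dropping zero-variance item(s): ",
            paste(which(vars == 0), collapse = ", "))
    X <- X[, vars > 0, drop = FALSE]
    vars <- vars[vars > 0]
  }
  k <- ncol(X)
  if (k < 2L) stop("need at least 2 items")
  total <- rowSums(X)
  vt <- var(total)
  if (vt == 0) stop("total-score variance is zero; alpha undefined")
  alpha <- k / (k - 1) * (1 - sum(vars) / vt)
  itc <- vapply(seq_len(k), function(j) cor(X[, j], total - X[, j]), 1.0)
  aid <- vapply(seq_len(k), function(j) {
    Xs <- X[, -j, drop = FALSE]
    (k - 1) / (k - 2) * (1 - sum(apply(Xs, 2L, var)) / var(rowSums(Xs)))
  }, 1.0)
  structure(list(alpha = alpha, nItems = k, nComplete = nrow(X),
                 itemTotalCorrelations = itc, alphaIfDeleted = aid),
            class = "reliability")
}

#' @export
print.reliability <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f (%d items, %d complete cases)\n",
              x$alpha, x$nItems, x$nComplete))
  invisible(x)
}

#' Stratum counts as a percentage table
#'
#' Percentages are `100 * count / total` to 2 decimal places, round-half-up by
#' default (a `"truncate"` mode chops instead of rounding, as some published
#' tables do); any stratum set whose counts do not sum to the stated total is
#' flagged with a warning, not an error.
#'
#' @param counts named nonnegative integer vector.
#' @param total stated total (> 0).
#' @param mode `"round"` (half-up) or `"truncate"`.
#' @return data.frame with `count` and `percentage` columns; attribute
#'   `sumsToTotal`.
#' @examples
#' demographicsSummary(c(male = 180, female = 164), 344)
#' @export
demographicsSummary <- function(counts, total, mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (total <= 0) stop("total must be positive")
  pct <- 100 * counts / total
  pct <- switch(mode,
                round = floor(pct * 100 + 0.5) / 100,   # half-up, not banker's
                truncate = trunc(pct * 100) / 100)
  ok <- sum(counts) == total
  if (!ok)
    warning("stratum counts sum to ", sum(counts), ", not the stated total ", total)
  out <- data.frame(count = as.integer(counts), percentage = pct,
                    row.names = names(counts))
  attr(out, "sumsToTotal") <- ok
  out
}
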