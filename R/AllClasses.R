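#' @import methods
#' @importFrom stats dnorm pnorm qnorm dlogis plogis rnorm runif optim optimize
#'   cov cov2cor pchisq var sd cor rbinom
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))

#' Parameters of one graded-response item
#'
#' Holds one item's discrimination vector `a` (length `D`, one slope per latent
#' dimension; entries fixed at 0 where the loading pattern forbids a loading)
#' and its ordered boundary ("easiness") parameters `d` (length `m`, strictly
#' decreasing), so the item has `m + 1` ordered response categories. The
#' cumulative probability of responding in category `t` or above is
#' `link(a . theta + d_t)` where `link` is the standard normal (probit) or
#' standard logistic CDF.
#'
#' @slot itemId single character label.
#' @slot label free-text symptom wording.
#' @slot a numeric discrimination vector, length `D`.
#' @slot d numeric boundary parameters, strictly decreasing, length `m >= 1`.
#' @slot link `"probit"` or `"logistic"`.
#'
#' @seealso [itemParameters()], [cumulativeProb()], [mdisc()]
#' @export
setClass("ItemParameters",
  representation(itemId = "character", label = "character",
                 a = "numeric", d = "numeric", link = "character"))

setValidity("ItemParameters", function(object) {
  msg <- character()
  if (length(object@itemId) != 1L) msg <- c(msg, "itemId must be a single label")
  if (length(object@a) < 1L || any(!is.finite(object@a)))
    msg <- c(msg, "a must be a finite vector of length >= 1")
  if (length(object@d) < 1L || any(!is.finite(object@d)))
    msg <- c(msg, "d must be a finite vector of length >= 1 (n_categories >= 2)")
  if (length(object@d) > 1L && any(diff(object@d) >= 0))
    msg <- c(msg, "d must be strictly decreasing (d_1 > d_2 > ... > d_m)")
  if (!object@link %in% c("probit", "logistic"))
    msg <- c(msg, "link must be 'probit' or 'logistic'")
  if (length(msg)) msg else TRUE
})

#' Construct an ItemParameters object
#'
#' @param itemId item label.
#' @param a discrimination vector (length `D`).
#' @param d strictly decreasing boundary parameters (length `m`).
#' @param link `"probit"` (default) or `"logistic"`.
#' @param label optional symptom wording; defaults to `itemId`.
#' @return an [ItemParameters-class] object.
#' @examples
#' it <- itemParameters("item1", a = c(2.03, 0), d = c(-0.15, -2.60, -5.39))
#' nCategories(it)
#' @export
itemParameters <- function(itemId, a, d, link = c("probit", "logistic"),
                           label = itemId) {
  link <- match.arg(link)
  new("ItemParameters", itemId = as.character(itemId), label = as.character(label),
      a = as.numeric(a), d = as.numeric(d), link = link)
}

#' A full graded-response scale: items, loading pattern, labels
#'
#' An ordered collection of [ItemParameters-class] sharing the same number of
#' latent dimensions `D` and the same link, together with the item-by-dimension
#' loading pattern (TRUE where a discrimination is free, FALSE where fixed at
#' zero) and category anchor labels. For a simple-structure scale every item
#' loads on exactly one dimension.
#'
#' @slot items list of [ItemParameters-class].
#' @slot loadingPattern logical item-by-dimension matrix.
#' @slot dimensionNames character, length `D`.
#' @slot categoryLabels character anchors shared across items (e.g.
#'   none/mild/middle/serious).
#' @seealso [itemBank()], [lssdBank()], [fitMgrm()]
#' @export
setClass("ItemBank",
  representation(items = "list", loadingPattern = "matrix",
                 dimensionNames = "character", categoryLabels = "character"))

setValidity("ItemBank", function(object) {
  msg <- character()
  if (!length(object@items)) msg <- c(msg, "bank must contain at least one item")
  if (!all(vapply(object@items, is, TRUE, "ItemParameters")))
    msg <- c(msg, "items must all be ItemParameters")
  D <- unique(vapply(object@items, function(x) length(x@a), 1L))
  if (length(D) != 1L) msg <- c(msg, "all items must share the same D")
  lk <- unique(vapply(object@items, function(x) x@link, ""))
  if (length(lk) != 1L) msg <- c(msg, "all items must share the same link")
  if (!is.logical(object@loadingPattern) ||
      nrow(object@loadingPattern) != length(object@items) ||
      (length(D) == 1L && ncol(object@loadingPattern) != D))
    msg <- c(msg, "loadingPattern must be an items x D logical matrix")
  if (length(D) == 1L && length(object@dimensionNames) != D)
    msg <- c(msg, "dimensionNames must have length D")
  for (j in seq_along(object@items)) {
    a <- object@items[[j]]@a
    if (any(a[!object@loadingPattern[j, ]] != 0))
      msg <- c(msg, sprintf("item %d has a nonzero discrimination where the pattern fixes 0", j))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ItemBank
#'
#' @param items list of [ItemParameters-class] objects.
#' @param loadingPattern logical item-by-dimension matrix of free loadings; by
#'   default inferred from nonzero discriminations.
#' @param dimensionNames names for the latent dimensions.
#' @param categoryLabels category anchor labels.
#' @return an [ItemBank-class].
#' @export
itemBank <- function(items, loadingPattern = NULL, dimensionNames = NULL,
                     categoryLabels = character()) {
  D <- length(items[[1L]]@a)
  if (is.null(loadingPattern)) {
    loadingPattern <- t(vapply(items, function(x) x@a != 0, logical(D)))
    if (D == 1L) loadingPattern <- matrix(loadingPattern, ncol = 1L)
  }
  if (is.null(dimensionNames)) dimensionNames <- paste0("dim", seq_len(D))
  new("ItemBank", items = items,
      loadingPattern = matrix(as.logical(loadingPattern), nrow = length(items)),
      dimensionNames = as.character(dimensionNames),
      categoryLabels = as.character(categoryLabels))
}

#' Quadrature rule for latent-trait integration
#'
#' Nodes and weights approximating integrals against the standard multivariate
#' normal prior. `gauss_hermite_tensor` is a deterministic tensor product of
#' Gauss-Hermite rules (exact reproducibility); `quasi_monte_carlo` is a
#' seeded, randomly shifted radical-inverse (Halton-type) sequence mapped
#' through the normal quantile function. Nodes and weights target the
#' *independent* standard normal prior; a latent correlation is applied by
#' Cholesky-transforming the nodes (see [latentNodes()]).
#'
#' @slot kind `"gauss_hermite_tensor"` or `"quasi_monte_carlo"`.
#' @slot nodes numeric K x D node matrix.
#' @slot weights numeric K, nonnegative, summing to 1.
#' @slot seed integer (QMC shift seed; NA for deterministic rules).
#' @seealso [quadratureRule()]
#' @export
setClass("QuadratureRule",
  representation(kind = "character", nodes = "matrix", weights = "numeric",
                 seed = "integer"))

setValidity("QuadratureRule", function(object) {
  msg <- character()
  if (any(object@weights < 0)) msg <- c(msg, "weights must be nonnegative")
  if (abs(sum(object@weights) - 1) > 1e-8) msg <- c(msg, "weights must sum to 1")
  if (nrow(object@nodes) != length(object@weights))
    msg <- c(msg, "node count must match weight count")
  if (length(msg)) msg else TRUE
})

#' Result of a marginal maximum-likelihood MGRM fit
#'
#' @slot bank estimated [ItemBank-class].
#' @slot latentCorr D x D latent correlation matrix (unit diagonal).
#' @slot loglikPath per-iteration marginal log-likelihood.
#' @slot nIterations number of EM iterations run.
#' @slot converged logical.
#' @slot tolerance convergence tolerance on the maximum absolute parameter change.
#' @slot standardErrors optional list of per-item SE vectors.
#' @slot collapseMap list of category remaps applied for empty categories.
#' @slot flags character vector of per-item warnings (boundary estimates etc.).
#' @seealso [fitMgrm()]
#' @export
setClass("MgrmFit",
  representation(bank = "ItemBank", latentCorr = "matrix",
                 loglikPath = "numeric", nIterations = "integer",
                 converged = "logical", tolerance = "numeric",
                 standardErrors = "listOrNULL", collapseMap = "list",
                 flags = "character"))

#' A confirmatory factor model pattern
#'
#' Free/fixed loading indicator with each item loading on exactly one factor,
#' factor variances fixed at 1 for identification, and (by default) a saturated
#' mean structure whose parameters are counted in q but absorbed exactly by the
#' sample means.
#'
#' @slot loadingPattern logical item x factor matrix.
#' @slot meanStructure logical.
#' @seealso [cfaModel()], [fitCfa()]
#' @export
setClass("CfaModel",
  representation(loadingPattern = "matrix", meanStructure = "logical"))

setValidity("CfaModel", function(object) {
  msg <- character()
  if (!is.logical(object@loadingPattern)) msg <- c(msg, "loadingPattern must be logical")
  if (any(rowSums(object@loadingPattern) != 1L))
    msg <- c(msg, "every item must load on exactly one factor (simple structure)")
  if (length(msg)) msg else TRUE
})

#' Construct a CfaModel
#'
#' @param loadingPattern logical item x factor matrix (each row exactly one TRUE).
#' @param meanStructure include a saturated mean structure in the parameter
#'   count (default TRUE).
#' @return a [CfaModel-class].
#' @examples
#' m2 <- cfaModel(cbind(rep(c(TRUE, FALSE), c(5, 4)), rep(c(FALSE, TRUE), c(5, 4))))
#' m1 <- cfaModel(matrix(TRUE, 9, 1))
#' @export
cfaModel <- function(loadingPattern, meanStructure = TRUE) {
  new("CfaModel", loadingPattern = matrix(as.logical(loadingPattern),
                                          nrow = nrow(loadingPattern)),
      meanStructure = meanStructure)
}

#' Result of a maximum-likelihood CFA
#'
#' @slot loadings item x factor loading estimates (0 where fixed).
#' @slot loadingSE standard errors of the free loadings (same shape, NA where fixed).
#' @slot residuals residual (uniqueness) variances.
#' @slot factorCov factor correlation matrix (unit diagonal).
#' @slot chiSquare,df,pValue likelihood-ratio test of the model.
#' @slot cfi,rmsea,aic fit indices.
#' @slot nFreeParams q, counting loadings, residuals, factor covariances and
#'   (if mean structure) intercepts.
#' @slot N sample size.
#' @slot baselineChiSquare,baselineDf independence-model reference.
#' @slot discrepancy minimized ML discrepancy F.
#' @slot converged logical.
#' @slot heywood logical per item: residual variance pinned at its positive floor.
#' @seealso [fitCfa()], [fitIndices()]
#' @export
setClass("CfaFit",
  representation(loadings = "matrix", loadingSE = "matrix",
                 residuals = "numeric", factorCov = "matrix",
                 chiSquare = "numeric", df = "integer", pValue = "numeric",
                 cfi = "numeric", rmsea = "numeric", aic = "numeric",
                 nFreeParams = "integer", N = "integer",
                 baselineChiSquare = "numeric", baselineDf = "integer",
                 discrepancy = "numeric", converged = "logical",
                 heywood = "logical"))

#' A simulated respondent population with its generating truth
#'
#' @slot responses integer respondent x item matrix (NA = missing).
#' @slot trueTheta respondent x D matrix of generating severities.
#' @slot bank the generating [ItemBank-class].
#' @slot latentCorr generating latent correlation matrix.
#' @slot seed integer seed; the dataset is reproducible bit-for-bit from
#'   (config, seed).
#' @seealso [simulateStudy()]
#' @export
setClass("SimulatedStudy",
  representation(responses = "matrix", trueTheta = "matrix", bank = "ItemBank",
                 latentCorr = "matrix", seed = "integer"))
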