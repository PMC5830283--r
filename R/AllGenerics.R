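#' @rdname accessors
#' @export
setGeneric("nItems", function(x) standardGeneric("nItems"))
#' @rdname accessors
#' @export
setGeneric("nDimensions", function(x) standardGeneric("nDimensions"))
#' @rdname accessors
#' @export
setGeneric("nCategories", function(x) standardGeneric("nCategories"))
#' @rdname accessors
#' @export
setGeneric("itemIds", function(x) standardGeneric("itemIds"))
#' @rdname accessors
#' @export
setGeneric("itemLabels", function(x) standardGeneric("itemLabels"))
#' @rdname accessors
#' @export
setGeneric("discrim", function(x) standardGeneric("discrim"))
#' @rdname accessors
#' @export
setGeneric("boundaries", function(x) standardGeneric("boundaries"))
#' @rdname accessors
#' @export
setGeneric("itemLink", function(x) standardGeneric("itemLink"))
#' @rdname accessors
#' @export
setGeneric("loadingPattern", function(x) standardGeneric("loadingPattern"))
#' @rdname accessors
#' @export
setGeneric("latentCorr", function(x) standardGeneric("latentCorr"))
#' @rdname accessors
#' @export
setGeneric("loglikPath", function(x) standardGeneric("loglikPath"))
#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' Multidimensional discrimination index (MDISC)
#'
#' The Euclidean norm of an item's discrimination vector: an overall summary
#' of how sharply the item separates respondents along its best-measured
#' direction of the latent space. Items with MDISC above 1 are conventionally
#' called high quality, between 0.5 and 1 medium quality.
#'
#' @param x an [ItemParameters-class] or [ItemBank-class].
#' @return a scalar (or per-item named vector for a bank).
#' @examples
#' mdisc(itemParameters("i1", a = c(3, 4), d = 0))  # 5
#' @export
setGeneric("mdisc", function(x) standardGeneric("mdisc"))

#' @describeIn accessors number of items in a bank / columns of responses
#' @export
setMethod("nItems", "ItemBank", function(x) length(x@items))
#' @describeIn accessors number of latent dimensions
#' @export
setMethod("nDimensions", "ItemBank", function(x) length(x@items[[1L]]@a))
#' @describeIn accessors categories of one item (m + 1)
#' @export
setMethod("nCategories", "ItemParameters", function(x) length(x@d) + 1L)
#' @describeIn accessors per-item category counts
#' @export
setMethod("nCategories", "ItemBank",
          function(x) vapply(x@items, nCategories, 1L))

#' Accessors for banks, items and fits
#'
#' @param x an object of this package's classes.
#' @name accessors
#' @return the requested component: ids/labels as character, `discrim` as the
#'   item-by-dimension slope matrix, `boundaries` as a list of decreasing
#'   d vectors, `latentCorr` as a correlation matrix.
NULL

#' @describeIn accessors item identifiers
#' @export
setMethod("itemIds", "ItemBank",
          function(x) vapply(x@items, function(i) i@itemId, ""))
#' @describeIn accessors symptom wording
#' @export
setMethod("itemLabels", "ItemBank",
          function(x) vapply(x@items, function(i) i@label, ""))
#' @describeIn accessors item-by-dimension discrimination matrix
#' @export
setMethod("discrim", "ItemBank", function(x) {
  m <- t(vapply(x@items, function(i) i@a, numeric(nDimensions(x))))
  if (nDimensions(x) == 1L) m <- matrix(m, ncol = 1L)
  dimnames(m) <- list(itemIds(x), x@dimensionNames)
  m
})
#' @describeIn accessors list of per-item boundary vectors
#' @export
setMethod("boundaries", "ItemBank",
          function(x) stats::setNames(lapply(x@items, function(i) i@d), itemIds(x)))
#' @describeIn accessors the shared link function name
#' @export
setMethod("itemLink", "ItemBank", function(x) x@items[[1L]]@link)
#' @describeIn accessors the shared link of one item
#' @export
setMethod("itemLink", "ItemParameters", function(x) x@link)
#' @describeIn accessors free/fixed loading indicator
#' @export
setMethod("loadingPattern", "ItemBank", function(x) x@loadingPattern)
#' @describeIn accessors estimated latent correlation of a fit
#' @export
setMethod("latentCorr", "MgrmFit", function(x) x@latentCorr)
#' @describeIn accessors marginal log-likelihood per EM iteration
#' @export
setMethod("loglikPath", "MgrmFit", function(x) x@loglikPath)
#' @describeIn accessors convergence flag
#' @export
setMethod("converged", "MgrmFit", function(x) x@converged)
#' @describeIn accessors estimated bank of a fit
#' @export
setGeneric("estimatedBank", function(x) standardGeneric("estimatedBank"))
#' @describeIn accessors estimated bank of a fit
#' @export
setMethod("estimatedBank", "MgrmFit", function(x) x@bank)

setMethod("show", "ItemParameters", function(object) {
  cat(sprintf("ItemParameters '%s' (%s link, %d categories)\n",
              object@itemId, object@link, nCategories(object)))
  cat("  a:", paste(format(object@a, digits = 3), collapse = " "), "\n")
  cat("  d:", paste(format(object@d, digits = 3), collapse = " "), "\n")
})

setMethod("show", "ItemBank", function(object) {
  cat(sprintf("ItemBank: %d items, %d dimensions (%s), %s link\n",
              nItems(object), nDimensions(object),
              paste(object@dimensionNames, collapse = ", "), itemLink(object)))
  md <- vapply(object@items, function(it)
    if (all(it@a == 0)) NA_real_ else sqrt(sum(it@a^2)), 1.0)
  tab <- data.frame(discrim(object), MDISC = round(md, 2),
                    check.names = FALSE)
  print(tab)
})

setMethod("show", "QuadratureRule", function(object) {
  cat(sprintf("QuadratureRule: %s, %d nodes in %d dimension(s)\n",
              object@kind, nrow(object@nodes), ncol(object@nodes)))
})

setMethod("show", "MgrmFit", function(object) {
  cat(sprintf("MgrmFit: %d items, %d EM iterations, %s (tol %.1e)\n",
              nItems(object@bank), object@nIterations,
              if (object@converged) "converged" else "NOT converged",
              object@tolerance))
  if (length(object@loglikPath))
    cat(sprintf("  marginal logLik: %.3f\n", utils::tail(object@loglikPath, 1L)))
  if (nrow(object@latentCorr) == 2L)
    cat(sprintf("  latent correlation: %.3f\n", object@latentCorr[1L, 2L]))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "CfaFit", function(object) {
  cat(sprintf("CfaFit: %d factors, N = %d\n", ncol(object@loadings), object@N))
  cat(sprintf("  chi^2 = %.2f on %d df, p = %.4g\n",
              object@chiSquare, object@df, object@pValue))
  cat(sprintf("  CFI = %.3f  RMSEA = %.3f  AIC = %.2f\n",
              object@cfi, object@rmsea, object@aic))
})

setMethod("show", "SimulatedStudy", function(object) {
  cat(sprintf("SimulatedStudy: %d respondents x %d items (seed %d)\n",
              nrow(object@responses), ncol(object@responses), object@seed))
  if (nrow(object@latentCorr) == 2L)
    cat(sprintf("  generating latent correlation: %.2f\n", object@latentCorr[1L, 2L]))
})
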