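#' Accessors for bimr S4 objects
#'
#' Small accessor generics so user code never reaches into slots:
#' `records()`, `traitName()`, `traitType()` for [StudyPanel-class];
#' `instruments()`, `auditLog()`, `nInstruments()` for
#' [HarmonizedSet-class]; `estimate()`, `stdErr()`, `confInt()`, `pValue()`,
#' `mrMethod()`, `nSnps()` for [MREstimate-class].
#'
#' @param x the object.
#' @return The corresponding slot value (a data.frame or scalar).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))
#' @rdname accessors
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))
#' @rdname accessors
#' @export
setGeneric("instruments", function(x) standardGeneric("instruments"))
#' @rdname accessors
#' @export
setGeneric("auditLog", function(x) standardGeneric("auditLog"))
#' @rdname accessors
#' @export
setGeneric("nInstruments", function(x) standardGeneric("nInstruments"))
#' @rdname accessors
#' @export
setGeneric("estimate", function(x) standardGeneric("estimate"))
#' @rdname accessors
#' @export
setGeneric("stdErr", function(x) standardGeneric("stdErr"))
#' @rdname accessors
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("mrMethod", function(x) standardGeneric("mrMethod"))
#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname accessors
#' @export
setMethod("records", "StudyPanel", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("traitName", "StudyPanel", function(x) x@traitName)
#' @rdname accessors
#' @export
setMethod("traitType", "StudyPanel", function(x) x@traitType)
#' @rdname accessors
#' @export
setMethod("instruments", "HarmonizedSet", function(x) x@instruments)
#' @rdname accessors
#' @export
setMethod("auditLog", "HarmonizedSet", function(x) x@audit)
#' @rdname accessors
#' @export
setMethod("nInstruments", "HarmonizedSet", function(x) nrow(x@instruments))
#' @rdname accessors
#' @export
setMethod("estimate", "MREstimate", function(x) x@beta)
#' @rdname accessors
#' @export
setMethod("stdErr", "MREstimate", function(x) x@se)
#' @rdname accessors
#' @export
setMethod("confInt", "MREstimate",
          function(x) c(lower = x@ciLow, upper = x@ciHigh))
#' @rdname accessors
#' @export
setMethod("pValue", "MREstimate", function(x) x@pvalue)
#' @rdname accessors
#' @export
setMethod("mrMethod", "MREstimate", function(x) x@method)
#' @rdname accessors
#' @export
setMethod("nSnps", "MREstimate", function(x) x@nSnps)
#' @rdname accessors
#' @export
setMethod("estimate", "MetaResult", function(x) x@pooled)
#' @rdname accessors
#' @export
setMethod("stdErr", "MetaResult", function(x) x@se)
#' @rdname accessors
#' @export
setMethod("confInt", "MetaResult",
          function(x) c(lower = x@ciLow, upper = x@ciHigh))

setMethod("show", "StudyPanel", function(object) {
  cat("StudyPanel:", object@traitName, sprintf("(%s)", object@traitType),
      "\n  variants:", nrow(object@records), "\n")
  if (!is.na(object@sdUnits)) cat("  SD units:", object@sdUnits, "\n")
  if (is.finite(object@nCases))
    cat("  cases/controls:", object@nCases, "/", object@nControls, "\n")
})

setMethod("show", "LDReference", function(object) {
  cat("LDReference:", nrow(object@entries), "pairs")
  if (!is.na(object@sampleN)) cat(" (reference n =", object@sampleN, ")")
  cat("\n")
})

setMethod("show", "HarmonizedSet", function(object) {
  cat("HarmonizedSet:", object@exposureName, "->", object@outcomeName, "\n")
  cat("  instruments:", nrow(object@instruments),
      "| dropped:", nrow(object@audit), "\n")
  if (nrow(object@instruments)) {
    tab <- table(object@instruments$action)
    cat("  actions:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s]  beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g, J = %d\n",
              object@method, object@beta, object@se, object@ciLow,
              object@ciHigh, object@pvalue, object@nSnps))
  if (is.finite(object@q))
    cat(sprintf("  Cochran Q = %.3g on %d df (p = %.3g)\n", object@q,
                as.integer(object@qDf), object@qP))
  if (is.finite(object@eggerIntercept))
    cat(sprintf("  Egger intercept = %.4g (p = %.3g)\n",
                object@eggerIntercept, object@eggerInterceptP))
  if (is.finite(object@pressoGlobalP))
    cat(sprintf("  PRESSO global p = %.3g; outliers: %s\n",
                object@pressoGlobalP,
                if (length(object@outliers)) paste(object@outliers,
                                                   collapse = ", ")
                else "none"))
})

setMethod("show", "MetaResult", function(object) {
  cat(sprintf("MetaResult: pooled = %.4g (se %.4g), 95%% CI [%.4g, %.4g]\n",
              object@pooled, object@se, object@ciLow, object@ciHigh))
  cat(sprintf("  tau2 = %.4g, Q = %.3g on %d df, I2 = %.1f%%, k = %d\n",
              object@tau2, object@q, object@qDf, 100 * object@i2,
              object@nStudies))
})

setMethod("show", "MinDetectableOR", function(object) {
  cat(sprintf("MinDetectableOR: %.2f / %.2f (grid step %.2g)\n",
              object@orLower, object@orUpper, object@gridStep))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: beta_causal = %.4g, J = %d, realized R2 = %.4g\n",
              object@betaCausal, length(object@gamma), object@realizedR2))
})
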