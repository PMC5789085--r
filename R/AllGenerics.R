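#' Accessors for network and module objects
#'
#' `moduleLabels()` returns the named gene-to-module integer vector (0 =
#' unassigned); `moduleSizes()` the per-module gene counts; `adjacency()`,
#' `similarity()` and `tom()` the corresponding matrices of a fitted
#' [CoexpressionNetwork-class]; `softPower()` the selected soft-thresholding
#' exponent; `fitCurve()` the scale-free fit index per candidate power.
#'
#' @param object a `CoexpressionNetwork`, `ModuleSet` or `BalancedForest`.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))

#' @rdname accessors
#' @export
setGeneric("moduleSizes", function(object) standardGeneric("moduleSizes"))

#' @rdname accessors
#' @export
setGeneric("similarity", function(object) standardGeneric("similarity"))

#' @rdname accessors
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))

#' @rdname accessors
#' @export
setGeneric("tom", function(object) standardGeneric("tom"))

#' @rdname accessors
#' @export
setGeneric("softPower", function(object) standardGeneric("softPower"))

#' @rdname accessors
#' @export
setGeneric("fitCurve", function(object) standardGeneric("fitCurve"))

#' @rdname accessors
#' @export
setGeneric("oobReport", function(object) standardGeneric("oobReport"))

#' @rdname accessors
#' @export
setMethod("moduleLabels", "ModuleSet", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("moduleSizes", "ModuleSet", function(object) {
  lab <- object@labels[object@labels > 0]
  if (!length(lab)) return(integer())
  tab <- table(factor(lab, levels = seq_len(max(lab))))
  stats::setNames(as.integer(tab), names(tab))
})

#' @rdname accessors
#' @export
setMethod("similarity", "CoexpressionNetwork", function(object) object@similarity)

#' @rdname accessors
#' @export
setMethod("adjacency", "CoexpressionNetwork", function(object) object@adjacency)

#' @rdname accessors
#' @export
setMethod("tom", "CoexpressionNetwork", function(object) object@tom)

#' @rdname accessors
#' @export
setMethod("softPower", "CoexpressionNetwork", function(object) object@power)

#' @rdname accessors
#' @export
setMethod("fitCurve", "CoexpressionNetwork", function(object) object@fitCurve)

#' @rdname accessors
#' @export
setMethod("oobReport", "BalancedForest", function(object) object@report)
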