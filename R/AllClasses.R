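#' @import methods
#' @importFrom stats cor sd var quantile prcomp pnorm qnorm rnorm runif rbinom
#'   rgamma rlnorm rnbinom pchisq pt phyper p.adjust hclust cutree as.dist
#'   lm.fit optimize splinefun dnbinom dpois complete.cases cor.test rpois
#'   setNames aggregate plnorm
#' @importFrom utils head read.delim write.table
NULL

#' Weighted co-expression network
#'
#' Holds the gene-gene Pearson similarity matrix, the soft-thresholding power
#' selected for scale-free topology, the resulting unsigned adjacency, the
#' topological overlap matrix (TOM), and the scale-free fit curve across the
#' candidate powers.
#'
#' @slot similarity symmetric gene x gene Pearson correlation matrix.
#' @slot power soft-thresholding exponent beta applied to `|similarity|`.
#' @slot adjacency unsigned adjacency `|s|^beta`, entries in `[0, 1]`.
#' @slot tom topological overlap matrix, entries in `[0, 1]`.
#' @slot fitCurve data.frame with columns `power`, `fit`, `slope`, the
#'   scale-free fit index of each candidate power.
#' @slot scaleFreeFit fit index achieved at the selected power.
#'
#' @export
setClass("CoexpressionNetwork",
  representation(
    similarity = "matrix",
    power = "numeric",
    adjacency = "matrix",
    tom = "matrix",
    fitCurve = "data.frame",
    scaleFreeFit = "numeric"
  )
)

setValidity("CoexpressionNetwork", function(object) {
  msg <- character()
  for (nm in c("similarity", "adjacency", "tom")) {
    m <- slot(object, nm)
    if (length(m) && !isSymmetric(unname(m), tol = 1e-8))
      msg <- c(msg, sprintf("'%s' must be symmetric", nm))
  }
  if (length(object@adjacency) &&
      (min(object@adjacency) < -1e-10 || max(object@adjacency) > 1 + 1e-10))
    msg <- c(msg, "adjacency entries must lie in [0, 1]")
  if (length(object@tom) && max(object@tom) > 1 + 1e-8)
    msg <- c(msg, "TOM entries must not exceed 1")
  if (length(object@power) && object@power < 1)
    msg <- c(msg, "power must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Module partition of a co-expression network
#'
#' Gene-to-module assignment from average-linkage (UPGMA) clustering of
#' `1 - TOM`. Label 0 marks unassigned (background) genes; positive labels are
#' ordered by decreasing module size.
#'
#' @slot labels named integer vector, one entry per gene; 0 = unassigned.
#' @slot dendrogram the `hclust` tree the partition was cut from.
#' @slot cutHeight static cut height applied to the dendrogram.
#' @slot minModuleSize smallest branch size retained as a module.
#' @slot mergeHistory data.frame recording eigengene-correlation merges
#'   (columns `from`, `into`, `cor`).
#'
#' @export
setClass("ModuleSet",
  representation(
    labels = "integer",
    dendrogram = "ANY",
    cutHeight = "numeric",
    minModuleSize = "numeric",
    mergeHistory = "data.frame"
  )
)

setValidity("ModuleSet", function(object) {
  msg <- character()
  lab <- object@labels
  if (is.null(names(lab))) msg <- c(msg, "labels must be named by gene")
  if (length(lab) && any(lab < 0)) msg <- c(msg, "labels must be >= 0")
  pos <- lab[lab > 0]
  if (length(pos)) {
    sizes <- table(pos)
    if (any(sizes < object@minModuleSize))
      msg <- c(msg, "every module must have size >= minModuleSize")
    if (!identical(sort(unique(as.integer(pos))), seq_len(max(pos))))
      msg <- c(msg, "positive labels must be contiguous 1..K")
  }
  if (length(msg)) msg else TRUE
})

#' Out-of-bag performance report of a balanced random forest
#'
#' @slot oobError overall out-of-bag misclassification rate.
#' @slot auc area under the ROC curve of OOB vote fractions (ties counted
#'   half), MHO as positive class.
#' @slot sensitivity,specificity OOB vote fractions thresholded at 0.5.
#' @slot confusion 2 x 2 confusion matrix (truth x prediction).
#' @slot votes per-sample OOB vote fraction for the positive (MHO) class.
#' @slot errOOB1 mean per-tree OOB misclassification rate.
#'
#' @export
setClass("RFReport",
  representation(
    oobError = "numeric",
    auc = "numeric",
    sensitivity = "numeric",
    specificity = "numeric",
    confusion = "matrix",
    votes = "numeric",
    errOOB1 = "numeric"
  )
)

setValidity("RFReport", function(object) {
  msg <- character()
  for (nm in c("oobError", "auc", "sensitivity", "specificity")) {
    x <- slot(object, nm)
    if (length(x) && (x < -1e-12 || x > 1 + 1e-12))
      msg <- c(msg, sprintf("'%s' must lie in [0, 1]", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Balanced random-forest fit
#'
#' Wraps a `randomForest` classifier trained with an equal-class (stratified,
#' minority-sized) bootstrap per tree, keeping the in-bag matrix so that
#' per-tree out-of-bag bookkeeping (permutation importance, per-tree error)
#' can be reconstructed exactly.
#'
#' @slot forest the fitted `randomForest` object (`keep.inbag = TRUE`).
#' @slot features the sample x feature training matrix.
#' @slot labels factor of class labels, reference level first.
#' @slot config list as produced by [rfConfig()].
#' @slot report an [RFReport-class] computed from the OOB votes.
#'
#' @export
setClass("BalancedForest",
  representation(
    forest = "ANY",
    features = "matrix",
    labels = "factor",
    config = "list",
    report = "RFReport"
  )
)

#' @describeIn CoexpressionNetwork-class compact display
#' @param object a `CoexpressionNetwork`
#' @export
setMethod("show", "CoexpressionNetwork", function(object) {
  cat("CoexpressionNetwork:", nrow(object@similarity), "genes\n")
  cat("  soft power:", object@power,
      " scale-free fit:", round(object@scaleFreeFit, 3), "\n")
  cat("  candidate powers evaluated:", nrow(object@fitCurve), "\n")
})

#' @describeIn ModuleSet-class compact display
#' @param object a `ModuleSet`
#' @export
setMethod("show", "ModuleSet", function(object) {
  sz <- moduleSizes(object)
  cat("ModuleSet:", length(object@labels), "genes,",
      length(sz), "modules (min size", object@minModuleSize, ")\n")
  if (length(sz)) {
    cat("  sizes:", paste(utils::head(sz, 10), collapse = ", "),
        if (length(sz) > 10) "...\n" else "\n")
  }
  cat("  unassigned:", sum(object@labels == 0), "\n")
})

#' @describeIn RFReport-class compact display
#' @param object an `RFReport`
#' @export
setMethod("show", "RFReport", function(object) {
  cat("RFReport: OOB error", round(object@oobError, 3),
      " AUC", round(object@auc, 3), "\n")
  cat("  sensitivity", round(object@sensitivity, 3),
      " specificity", round(object@specificity, 3), "\n")
})

#' @describeIn BalancedForest-class compact display
#' @param object a `BalancedForest`
#' @export
setMethod("show", "BalancedForest", function(object) {
  cat("BalancedForest:", object@forest$ntree, "trees,",
      ncol(object@features), "features,", length(object@labels), "samples\n")
  show(object@report)
})
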