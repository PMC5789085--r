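## Balanced random-forest classification of MHO status.
##
## Each tree is grown on a stratified bootstrap drawing the minority-class
## count from both classes (with replacement), so the 8-vs-21 imbalance
## does not dominate the error. mtry is floor(p/2) as specified (not the
## conventional sqrt(p)). OOB votes give the error, ROC/AUC, sensitivity
## and specificity; permutation importance follows the per-tree difference
## VIM_k = mean_t(errOOB2_t^k - errOOB1_t) with the permutation budget
## nPerm spread across trees.

#' @importFrom randomForest randomForest importance
NULL

#' Random-forest configuration
#'
#' @param ntree trees in the forest (default 10,000).
#' @param mtry candidate features per split; `NULL` (default) means
#'   `floor(p / 2)`.
#' @param nPerm total permutation draws for variable importance
#'   (default 1,000), spread across trees.
#' @param balanced grow each tree on an equal-class, minority-sized
#'   stratified bootstrap (default `TRUE`).
#' @param seed RNG seed; fixed seed gives identical forests, votes and
#'   importances.
#' @return list of class `"rfConfig"`.
#' @export
rfConfig <- function(ntree = 10000, mtry = NULL, nPerm = 1000,
                     balanced = TRUE, seed = 1) {
  stopifnot(ntree >= 1, nPerm >= 1)
  structure(list(ntree = as.integer(ntree), mtry = mtry,
                 nPerm = as.integer(nPerm), balanced = isTRUE(balanced),
                 seed = as.integer(seed)), class = "rfConfig")
}

.rf_labels <- function(labels) {
  if (is.numeric(labels)) labels <- c("MAO", "MHO")[labels + 1]
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 2) stop("labels contain a single class")
  if (all(c("MAO", "MHO") %in% levels(labels)))
    labels <- factor(labels, levels = c("MAO", "MHO"))
  labels
}

# Rank-based AUC of vote fractions for the positive class (ties half).
.auc_votes <- function(votes, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(rank(votes)[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Out-of-bag performance metrics from vote fractions
#'
#' AUC is the rank statistic of the positive-class OOB vote fractions
#' (tied pairs count one half); sensitivity and specificity threshold the
#' votes at 0.5 (a tie predicts the reference class).
#'
#' @param votes per-sample OOB vote fraction for the positive class, or a
#'   [BalancedForest-class] (its stored votes are used).
#' @param labels true labels (ignored for a `BalancedForest`).
#' @param positive positive class (default `"MHO"`).
#' @return an [RFReport-class].
#' @export
oobPerformance <- function(votes, labels = NULL, positive = "MHO") {
  if (is(votes, "BalancedForest")) {
    labels <- votes@labels
    votes <- votes@report@votes
  }
  labels <- .rf_labels(labels)
  is_pos <- labels == positive
  pred_pos <- votes > 0.5
  sens <- mean(pred_pos[is_pos])
  spec <- mean(!pred_pos[!is_pos])
  conf <- table(truth = labels,
                predicted = factor(ifelse(pred_pos, positive,
                                          setdiff(levels(labels), positive)),
                                   levels = levels(labels)))
  new("RFReport",
      oobError = mean(pred_pos != is_pos),
      auc = .auc_votes(votes, is_pos),
      sensitivity = sens, specificity = spec,
      confusion = unclass(conf), votes = as.numeric(votes),
      errOOB1 = NA_real_)
}

#' Train a balanced random-forest classifier
#'
#' Wraps `randomForest` with a stratified equal-class bootstrap (each tree
#' samples the minority-class count from both classes, with replacement),
#' `mtry = floor(p / 2)`, and in-bag bookkeeping retained so per-tree OOB
#' quantities can be reconstructed exactly. OOB votes are accumulated only
#' from trees where the sample was out of bag.
#'
#' @param features samples x features numeric matrix or data.frame.
#' @param labels two-class labels (`"MAO"`/`"MHO"`, or 0/1 with MAO = 0).
#' @param config an [rfConfig()].
#' @return a [BalancedForest-class]; its report holds OOB error, AUC,
#'   sensitivity, specificity, votes and the mean per-tree OOB error.
#' @export
trainRFBalanced <- function(features, labels, config = rfConfig()) {
  features <- as.matrix(features)
  if (ncol(features) == 0) stop("no features supplied")
  labels <- .rf_labels(labels)
  if (nrow(features) != length(labels))
    stop("features and labels disagree on sample count")
  p <- ncol(features)
  mtry <- if (is.null(config$mtry)) max(1L, floor(p / 2)) else config$mtry
  sampsize <- if (config$balanced)
    rep(min(table(labels)), nlevels(labels)) else nrow(features)
  set.seed(config$seed)
  rf <- randomForest::randomForest(
    x = features, y = labels, ntree = config$ntree, mtry = mtry,
    replace = TRUE, strata = labels, sampsize = sampsize,
    keep.forest = TRUE, keep.inbag = TRUE, norm.votes = TRUE)
  oob_trees <- rowSums(rf$inbag == 0)
  if (any(oob_trees == 0))
    stop("sample(s) never out of bag: increase ntree (",
         paste(rownames(features)[oob_trees == 0], collapse = ", "), ")")
  positive <- if ("MHO" %in% levels(labels)) "MHO"
              else levels(labels)[2]
  votes <- rf$votes[, positive]
  report <- oobPerformance(votes, labels, positive)
  report@errOOB1 <- mean(.per_tree_oob_error(rf, features, labels))
  new("BalancedForest", forest = rf, features = features,
      labels = labels, config = unclass(config), report = report)
}

# Per-tree OOB misclassification rates from the kept in-bag matrix.
.per_tree_oob_error <- function(rf, features, labels) {
  pred <- predict(rf, features, predict.all = TRUE)$individual
  oob <- rf$inbag == 0
  miss <- (pred != as.character(labels)) & oob
  colSums(miss) / colSums(oob)
}

#' Permutation variable importance
#'
#' For each feature `k`, the values of `k` are permuted and every tree is
#' re-evaluated on its out-of-bag samples;
#' `VIM_k = mean over trees and draws of (errOOB2^k_t - errOOB1_t)`.
#' The permutation budget `nPerm` is spread across trees:
#' `ceiling(nPerm / ntree)` independent permutation draws (at least one),
#' each drawn once across samples and applied within every tree's OOB set.
#' A constant feature has VIM 0 by definition.
#'
#' @param object a [BalancedForest-class].
#' @param nPerm total permutation budget (default: the training config's).
#' @param seed RNG seed (default: the training config's seed).
#' @return named numeric vector of raw importances, one per feature.
#' @export
permutationVIM <- function(object, nPerm = NULL, seed = NULL) {
  stopifnot(is(object, "BalancedForest"))
  rf <- object@forest
  X <- object@features
  labels <- as.character(object@labels)
  if (is.null(nPerm)) nPerm <- object@config$nPerm
  if (is.null(seed)) seed <- object@config$seed
  ntree <- rf$ntree
  ndraw <- max(1L, ceiling(nPerm / ntree))
  oob <- rf$inbag == 0
  oob_n <- colSums(oob)
  pred <- predict(rf, X, predict.all = TRUE)$individual
  err1 <- colSums((pred != labels) & oob) / oob_n

  set.seed(seed)
  vim <- stats::setNames(numeric(ncol(X)), colnames(X))
  n <- nrow(X)
  for (k in seq_len(ncol(X))) {
    if (length(unique(X[, k])) == 1) { vim[k] <- 0; next }
    d_sum <- 0
    for (d in seq_len(ndraw)) {
      Xp <- X
      Xp[, k] <- X[sample.int(n), k]
      predp <- predict(rf, Xp, predict.all = TRUE)$individual
      err2 <- colSums((predp != labels) & oob) / oob_n
      d_sum <- d_sum + mean(err2 - err1)
    }
    vim[k] <- d_sum / ndraw
  }
  vim
}

#' Data-driven variable selection
#'
#' Three steps, mirroring heuristic forest-based selection: (1) features
#' are ranked by their mean permutation VIM over `n_replicates`
#' independently seeded forests; (2) the noise threshold is the mean plus
#' two SDs of the magnitudes of the negative mean VIMs (features that can
#' only be noise) — or the smallest positive mean VIM when none are
#' negative — and features above it form the interpretation set; (3) a
#' nested forward pass over the ranked interpretation set records the OOB
#' AUC of each prefix (over `eval_replicates` seeded forests); the
#' prediction set is the smallest prefix whose mean AUC is within one
#' standard error of the best prefix.
#'
#' @param features samples x features matrix.
#' @param labels two-class labels.
#' @param config an [rfConfig()]; replicate `r` uses `seed + r`.
#' @param n_replicates forests averaged for the VIM ranking (default 25).
#' @param eval_replicates forests averaged per forward-pass prefix
#'   (default 5).
#' @return list of class `"VariableSelectionResult"`: `mean_vim`,
#'   `threshold`, `interpretation_set`, `prediction_set`, `trace`
#'   (prefix size, mean AUC, SE), `vim_replicates`. With no feature above
#'   the threshold, the sets are empty and a warning is raised.
#' @export
selectVariables <- function(features, labels, config = rfConfig(),
                            n_replicates = 25, eval_replicates = 5) {
  features <- as.matrix(features)
  labels <- .rf_labels(labels)
  p <- ncol(features)
  vims <- matrix(NA_real_, n_replicates, p,
                 dimnames = list(NULL, colnames(features)))
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r
    fit <- trainRFBalanced(features, labels, cfg)
    vims[r, ] <- permutationVIM(fit)
  }
  mean_vim <- colMeans(vims)
  neg <- mean_vim[mean_vim < 0]
  if (length(neg)) {
    threshold <- mean(abs(neg)) + 2 * (if (length(neg) > 1) stats::sd(abs(neg)) else 0)
    interp <- names(mean_vim)[mean_vim > threshold]
  } else {
    threshold <- min(mean_vim[mean_vim > 0])
    interp <- names(mean_vim)[mean_vim >= threshold]
  }
  interp <- interp[order(mean_vim[interp], decreasing = TRUE)]
  if (!length(interp)) {
    warning("no feature exceeds the noise threshold")
    return(structure(list(mean_vim = mean_vim, threshold = threshold,
                          interpretation_set = character(),
                          prediction_set = character(),
                          trace = data.frame(), vim_replicates = vims),
                     class = "VariableSelectionResult"))
  }
  trace <- data.frame(size = seq_along(interp), auc = NA_real_,
                      se = NA_real_)
  for (j in seq_along(interp)) {
    aucs <- vapply(seq_len(eval_replicates), function(r) {
      cfg <- config
      cfg$seed <- config$seed + 1000L + j * 100L + r
      cfg$mtry <- NULL
      trainRFBalanced(features[, interp[seq_len(j)], drop = FALSE],
                      labels, cfg)@report@auc
    }, numeric(1))
    trace$auc[j] <- mean(aucs)
    trace$se[j] <- stats::sd(aucs) / sqrt(eval_replicates)
  }
  best <- which.max(trace$auc)
  cut <- trace$auc[best] - trace$se[best]
  pred_size <- min(which(trace$auc >= cut))
  structure(list(mean_vim = mean_vim, threshold = threshold,
                 interpretation_set = interp,
                 prediction_set = interp[seq_len(pred_size)],
                 trace = trace, vim_replicates = vims),
            class = "VariableSelectionResult")
}

#' Rank the metabolic drivers of module-gene expression
#'
#' (a) For each gene, a random-forest regression of its expression on the
#' MHO-definition components (CRP, TG/HDL, glucose, HOMA-IR) records the
#' parameter with the largest permutation importance; the per-parameter
#' win counts identify the primary driver. (b) Each parameter alone, and
#' all parameters jointly, are used as balanced-forest classifiers of MHO
#' status, reporting the OOB AUC per model.
#'
#' @param expression samples x genes matrix (the associated module's
#'   genes).
#' @param clinical data.frame of the numeric metabolic parameters, one row
#'   per sample; constant columns are excluded with a warning.
#' @param labels two-class MHO/MAO labels.
#' @param config an [rfConfig()]; regressions use `mtry = floor(p/2)` over
#'   the parameters.
#' @return list of class `"DriverRanking"`: `top_parameter` (per gene),
#'   `counts` (per parameter), `single_auc` (named, one model per
#'   parameter), `combined_auc`.
#' @export
rankMetabolicDrivers <- function(expression, clinical, labels,
                                 config = rfConfig(ntree = 1000)) {
  expression <- as.matrix(expression)
  params <- as.matrix(clinical[vapply(clinical, is.numeric, TRUE)])
  keep <- apply(params, 2, function(x) stats::var(x) > 0) &
    !duplicated(t(params))
  if (!all(keep)) {
    warning("constant or duplicated parameter(s) excluded: ",
            paste(colnames(params)[!keep], collapse = ", "))
    params <- params[, keep, drop = FALSE]
  }
  if (!ncol(params)) stop("no usable parameters")
  labels <- .rf_labels(labels)
  mtry <- max(1L, floor(ncol(params) / 2))

  top <- character(ncol(expression))
  for (g in seq_len(ncol(expression))) {
    set.seed(config$seed + g)
    rf <- randomForest::randomForest(
      x = params, y = expression[, g], ntree = config$ntree, mtry = mtry,
      importance = TRUE)
    imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
    top[g] <- names(imp)[which.max(imp)]
  }
  names(top) <- colnames(expression)
  counts <- table(factor(top, levels = colnames(params)))

  single_auc <- vapply(colnames(params), function(pn) {
    cfg <- config
    cfg$mtry <- 1L
    trainRFBalanced(params[, pn, drop = FALSE], labels, cfg)@report@auc
  }, numeric(1))
  cfg <- config
  cfg$mtry <- mtry
  combined_auc <- trainRFBalanced(params, labels, cfg)@report@auc
  structure(list(top_parameter = top, counts = counts,
                 single_auc = single_auc, combined_auc = combined_auc),
            class = "DriverRanking")
}
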