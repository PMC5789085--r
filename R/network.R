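## Weighted co-expression network construction and module detection.
##
## Pearson similarity -> unsigned power adjacency |s|^beta -> scale-free
## topology check -> topological overlap matrix -> UPGMA dendrogram with a
## static height cut and a minimum module size -> eigengene-correlation
## module merging. The soft power is the smallest candidate whose log-log
## degree-distribution fit index reaches the required value (default 0.8).

#' Gene-gene Pearson similarity matrix
#'
#' @param logcpm gene x sample matrix (at least 3 samples). Genes with zero
#'   variance are an error: dropping them silently would break gene
#'   indexing downstream.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
similarityMatrix <- function(logcpm) {
  logcpm <- as.matrix(logcpm)
  if (ncol(logcpm) < 3) stop("need at least 3 samples")
  v <- apply(logcpm, 1, stats::var)
  if (any(v == 0)) {
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(logcpm)[v == 0], 10), collapse = ", "))
  }
  s <- stats::cor(t(logcpm))
  diag(s) <- 1
  s
}

#' Unsigned soft-threshold adjacency
#'
#' `a_ij = |s_ij|^beta` with unit diagonal. Raising the power suppresses
#' weak correlations while keeping the adjacency continuous in `[0, 1]`.
#'
#' @param s similarity (correlation) matrix.
#' @param beta soft-thresholding exponent, `>= 1`.
#' @return adjacency matrix.
#' @examples
#' softAdjacency(matrix(c(1, .5, .5, 1), 2), beta = 6)[1, 2] # 0.5^6
#' @export
softAdjacency <- function(s, beta) {
  if (beta < 1) stop("beta must be >= 1")
  a <- abs(s)^beta
  diag(a) <- 1
  a
}

#' Scale-free topology fit index
#'
#' Bins the connectivities `k_i = sum_{j != i} a_ij` into `n_bins`
#' equal-width bins and regresses `log10` mean frequency on `log10` mean
#' connectivity over the non-empty bins. The fit index is the regression
#' R-squared when the slope is negative (a decaying degree distribution),
#' and 0 otherwise.
#'
#' @param a adjacency matrix.
#' @param n_bins number of connectivity bins (default 10; reduced when
#'   there are fewer distinct connectivity values).
#' @return fit index in `[0, 1]`, with the regression slope attached as
#'   `attr(x, "slope")`.
#' @export
scaleFreeFit <- function(a, n_bins = 10) {
  k <- rowSums(a) - diag(a)
  k <- k[k > 0]
  n_distinct <- length(unique(signif(k, 10)))
  if (n_distinct < 2) {
    warning("all connectivities equal; scale-free fit undefined, returning 0")
    return(structure(0, slope = NA_real_))
  }
  if (n_distinct < n_bins) n_bins <- n_distinct
  brk <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, brk, include.lowest = TRUE)
  freq <- tapply(k, bin, length) / length(k)
  kmean <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0 & kmean > 0
  if (sum(ok) < 2) {
    warning("fewer than 2 usable bins; returning 0")
    return(structure(0, slope = NA_real_))
  }
  x <- log10(kmean[ok]); y <- log10(freq[ok])
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  structure(if (is.finite(slope) && slope < 0) r2 else 0,
            slope = unname(slope))
}

#' Select the soft-thresholding power
#'
#' Evaluates the scale-free fit index of `|s|^beta` over the candidate
#' powers and returns the smallest one reaching `fit_required`. If no
#' candidate qualifies, an error of class `"softThresholdError"` is thrown
#' carrying the full fit curve (a caller may inspect it and lower the
#' requirement explicitly).
#'
#' @param s similarity matrix.
#' @param candidate_powers increasing vector of candidate exponents
#'   (default `1:20`).
#' @param fit_required minimum acceptable fit index (default 0.8).
#' @param n_bins passed to [scaleFreeFit()].
#' @return list with `power`, `fit`, and `fit_curve` (data.frame with
#'   columns `power`, `fit`, `slope`).
#' @export
pickSoftThreshold <- function(s, candidate_powers = 1:20,
                              fit_required = 0.8, n_bins = 10) {
  if (!length(candidate_powers)) stop("no candidate powers supplied")
  abs_s <- abs(s)
  curve <- data.frame(power = candidate_powers, fit = NA_real_,
                      slope = NA_real_)
  for (i in seq_along(candidate_powers)) {
    a <- abs_s^candidate_powers[i]
    diag(a) <- 1
    f <- suppressWarnings(scaleFreeFit(a, n_bins))
    curve$fit[i] <- as.numeric(f)
    curve$slope[i] <- attr(f, "slope")
  }
  hit <- which(curve$fit >= fit_required)
  if (!length(hit)) {
    stop(errorCondition(
      sprintf("no candidate power reached fit index %.2f (best %.3f)",
              fit_required, max(curve$fit)),
      class = "softThresholdError", fit_curve = curve))
  }
  list(power = candidate_powers[hit[1]], fit = curve$fit[hit[1]],
       fit_curve = curve)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with `TOM_ii = 1`, where `k_i` is the connectivity excluding the
#' diagonal (standard unsigned TOM). Two genes overlap strongly when they
#' are directly connected and share neighbours.
#'
#' @param a symmetric adjacency matrix with entries in `[0, 1]`, unit
#'   diagonal.
#' @return TOM matrix in `[0, 1]`.
#' @export
topologicalOverlap <- function(a) {
  if (!isSymmetric(unname(a), tol = 1e-8)) stop("adjacency must be symmetric")
  if (min(a) < -1e-12 || max(a) > 1 + 1e-12)
    stop("adjacency entries must lie in [0, 1]")
  diag(a) <- 1
  k <- rowSums(a) - 1
  shared <- a %*% a - 2 * a            # sum_{u != i,j} a_iu a_uj (diag = 1)
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  tomm <- num / den
  diag(tomm) <- 1
  tomm[tomm > 1] <- 1
  tomm[tomm < 0] <- 0
  (tomm + t(tomm)) / 2
}

#' Build a co-expression network
#'
#' Convenience constructor: similarity, soft-threshold selection, adjacency
#' and TOM in one call.
#'
#' @param logcpm gene x sample log2-CPM matrix.
#' @inheritParams pickSoftThreshold
#' @return a [CoexpressionNetwork-class].
#' @export
buildNetwork <- function(logcpm, candidate_powers = 1:20,
                         fit_required = 0.8) {
  s <- similarityMatrix(logcpm)
  pick <- pickSoftThreshold(s, candidate_powers, fit_required)
  a <- softAdjacency(s, pick$power)
  new("CoexpressionNetwork", similarity = s, power = pick$power,
      adjacency = a, tom = topologicalOverlap(a),
      fitCurve = pick$fit_curve, scaleFreeFit = pick$fit)
}

#' Detect modules by UPGMA clustering of the TOM dissimilarity
#'
#' Average-linkage (UPGMA) hierarchical clustering of `1 - TOM`, cut at a
#' fixed height; branches smaller than `min_module_size` are left
#' unassigned (label 0). Module labels are ordered by decreasing size.
#'
#' @param tom topological overlap matrix (or a
#'   [CoexpressionNetwork-class], whose TOM slot is used).
#' @param min_module_size smallest gene count kept as a module (default 10).
#' @param cut_height static dendrogram cut height on the `1 - TOM` scale
#'   (default 0.99).
#' @return a [ModuleSet-class]. If no branch reaches the minimum size, all
#'   genes are unassigned and a warning is raised.
#' @export
clusterModules <- function(tom, min_module_size = 10, cut_height = 0.99) {
  if (is(tom, "CoexpressionNetwork")) tom <- tom@tom
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  # average linkage is monotone; repair floating-point height inversions
  if (is.unsorted(hc$height)) hc$height <- cummax(hc$height)
  raw <- stats::cutree(hc, h = cut_height)
  tab <- table(raw)
  big <- names(tab)[tab >= min_module_size]
  lab <- integer(length(raw))
  if (!length(big)) {
    warning("no branch reached the minimum module size; all unassigned")
  } else {
    ord <- big[order(tab[big], decreasing = TRUE)]
    for (m in seq_along(ord)) lab[raw == as.integer(ord[m])] <- m
  }
  names(lab) <- rownames(tom)
  new("ModuleSet", labels = lab, dendrogram = hc,
      cutHeight = cut_height, minModuleSize = min_module_size,
      mergeHistory = data.frame(from = integer(), into = integer(),
                                cor = numeric()))
}

#' Merge modules with highly correlated eigengenes
#'
#' Iteratively merges the module pair whose eigengene correlation is the
#' largest above `merge_cor` (dissimilarity below `1 - merge_cor`),
#' recomputing eigengenes after every merge, until no pair qualifies.
#'
#' @param partition a [ModuleSet-class].
#' @param logcpm the gene x sample matrix the modules were detected on.
#' @param merge_cor eigengene-correlation threshold (default 0.75).
#' @return the merged [ModuleSet-class]; merges are recorded in
#'   `@mergeHistory` and labels are re-ordered by size.
#' @export
mergeModules <- function(partition, logcpm, merge_cor = 0.75) {
  lab <- partition@labels
  history <- partition@mergeHistory
  repeat {
    mods <- sort(unique(lab[lab > 0]))
    if (length(mods) < 2) break
    me <- moduleEigengenes(logcpm, lab)$eigengenes
    cc <- stats::cor(me)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[best[1], best[2]] <= merge_cor) break
    from <- max(mods[best]); into <- min(mods[best])
    history <- rbind(history, data.frame(
      from = from, into = into, cor = cc[best[1], best[2]]))
    lab[lab == from] <- into
    lab[lab > from] <- lab[lab > from] - 1L   # keep labels contiguous
  }
  # re-rank by size (descending), keeping 0 for background
  mods <- sort(unique(lab[lab > 0]))
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(lab == m), integer(1))
    remap <- integer(max(mods))
    remap[mods[order(sizes, decreasing = TRUE)]] <- seq_along(mods)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  new("ModuleSet", labels = lab, dendrogram = partition@dendrogram,
      cutHeight = partition@cutHeight,
      minModuleSize = partition@minModuleSize, mergeHistory = history)
}
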