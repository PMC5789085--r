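## Count-matrix QC and normalization.
##
## CPM filtering (1 CPM in >= 3 samples), weighted trimmed-mean-of-M-values
## (TMM) scale factors, log2-CPM with a prior count, and PCA-based sample
## outlier flagging. Filtering uses raw-library CPM, before normalization;
## TMM follows the published defaults (30% M trim, 5% A trim, inverse
## asymptotic-variance weights, reference column by upper-quartile rule).

.check_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%d", seq_len(ncol(counts)))
  counts
}

#' Counts per million
#'
#' `cpm[g, s] = count[g, s] / libsize[s] * 1e6`, with the raw column sums as
#' library sizes unless effective (TMM-scaled) sizes are supplied.
#'
#' @param counts non-negative gene x sample matrix.
#' @param effective_libsizes optional per-sample library sizes overriding
#'   the column sums.
#' @return matrix of CPM values, same dimensions as `counts`.
#' @examples
#' computeCPM(matrix(c(100, 0), 2, 1,
#'   dimnames = list(c("a", "b"), "s1")) )
#' @export
computeCPM <- function(counts, effective_libsizes = NULL) {
  counts <- .check_counts(counts)
  lib <- if (is.null(effective_libsizes)) colSums(counts)
         else effective_libsizes
  if (any(lib <= 0)) {
    stop("zero or negative library size in sample(s): ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  }
  sweep(counts, 2, lib, "/") * 1e6
}

#' Remove genes with very low expression
#'
#' Retains exactly the genes achieving at least `min_cpm` counts per million
#' (raw-library CPM, pre-normalization) in at least `min_samples` samples;
#' both boundaries inclusive. Gene order is preserved and the operation is
#' idempotent.
#'
#' @param counts gene x sample count matrix.
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples minimum number of samples at or above the threshold
#'   (default 3).
#' @return the filtered count matrix (possibly with zero rows, with a
#'   warning).
#' @export
filterLowExpression <- function(counts, min_cpm = 1, min_samples = 3) {
  counts <- .check_counts(counts)
  keep <- rowSums(computeCPM(counts) >= min_cpm) >= min_samples
  if (!any(keep)) warning("no gene passed the expression filter")
  counts[keep, , drop = FALSE]
}

# Pairwise TMM factor of column `obs` against column `ref` (published
# algorithm: M/A trimming with precision weights).
.tmm_pair <- function(obs, ref, logratio_trim, abs_trim, a_cutoff) {
  nO <- sum(obs); nR <- sum(ref)
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
  fin <- is.finite(logR) & is.finite(absE) & (absE > a_cutoff)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR) ) {
    warning("all genes trimmed in TMM comparison; factor set to 1")
    return(1)
  }
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * abs_trim) + 1; hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
          rank(absE) >= loS & rank(absE) <= hiS
  if (!any(keep)) {
    warning("all genes trimmed in TMM comparison; factor set to 1")
    return(1)
  }
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) /
       sum(1 / v[keep], na.rm = TRUE)
  2^f
}

#' TMM normalization factors
#'
#' Weighted trimmed mean of M-values: for each sample, gene-wise log2
#' expression ratios against a reference sample (the column whose
#' upper-quartile CPM is closest to the mean upper quartile) are trimmed by
#' M-value (`logratio_trim` each tail) and by average abundance (`abs_trim`
#' each tail), then averaged with inverse asymptotic-variance weights.
#' Genes with a zero count in either sample drop out of the comparison.
#' Factors are rescaled to geometric mean 1.
#'
#' @param counts gene x sample count matrix with at least two samples.
#' @param logratio_trim two-sided M-value trim fraction (default 0.3).
#' @param abs_trim two-sided abundance trim fraction (default 0.05).
#' @param a_cutoff minimum average log2 abundance (default -1e10, i.e. off).
#' @return named per-sample factor vector, geometric mean 1. Effective
#'   library size = column sum x factor.
#' @examples
#' m <- matrix(rpois(200, 50), 20, 10)
#' f <- tmmFactors(m)
#' abs(exp(mean(log(f)))) - 1 < 1e-8
#' @export
tmmFactors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05,
                       a_cutoff = -1e10) {
  counts <- .check_counts(counts)
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    .tmm_pair(counts[, j], counts[, ref], logratio_trim, abs_trim, a_cutoff)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' TMM normalization result
#'
#' Convenience wrapper bundling [tmmFactors()], effective library sizes and
#' the [logCPM()] matrix.
#'
#' @inheritParams tmmFactors
#' @param prior_count offset added to counts before the log (default 0.5).
#' @return list with `factors`, `effective_libsize`, `logcpm`,
#'   `prior_count`.
#' @export
normalizeTMM <- function(counts, logratio_trim = 0.3, abs_trim = 0.05,
                         prior_count = 0.5) {
  counts <- .check_counts(counts)
  f <- tmmFactors(counts, logratio_trim, abs_trim)
  eff <- colSums(counts) * f
  list(factors = f, effective_libsize = eff,
       logcpm = logCPM(counts, effective_libsizes = eff,
                       prior_count = prior_count),
       prior_count = prior_count)
}

#' Log2 counts per million
#'
#' `log2((count + prior) / (effective libsize + 2 * prior) * 1e6)`;
#' strictly increasing in the count.
#'
#' @param counts gene x sample count matrix.
#' @param effective_libsizes per-sample effective library sizes (default:
#'   raw column sums).
#' @param prior_count small offset avoiding `log(0)` (default 0.5).
#' @return matrix of log2-CPM values.
#' @export
logCPM <- function(counts, effective_libsizes = NULL, prior_count = 0.5) {
  counts <- .check_counts(counts)
  lib <- if (is.null(effective_libsizes)) colSums(counts)
         else effective_libsizes
  log2(sweep(counts + prior_count, 2, lib + 2 * prior_count, "/") * 1e6)
}

#' Flag sample outliers in principal-component space
#'
#' Projects samples onto the top `n_pcs` principal components of the
#' (gene-centred) log-CPM matrix, standardizes each component
#' (median-centred, SD-scaled: with a few dozen samples the principal
#' scores of high-dimensional data are heavy-tailed and MAD scaling
#' over-flags), and flags samples whose Euclidean distance from the
#' centre exceeds `sd_threshold`.
#'
#' @param logcpm gene x sample matrix of log2-CPM values.
#' @param n_pcs number of components (default 2; reduced with a warning if
#'   fewer are available).
#' @param sd_threshold robust-SD distance cut-off (default 3).
#' @return named logical vector, `TRUE` for flagged samples, with the
#'   distances attached as `attr(x, "distance")`.
#' @export
pcaOutliers <- function(logcpm, n_pcs = 2, sd_threshold = 3) {
  logcpm <- as.matrix(logcpm)
  n <- ncol(logcpm)
  if (n < 3) stop("need at least 3 samples")
  max_pcs <- n - 1
  if (n_pcs > max_pcs) {
    warning(sprintf("n_pcs reduced from %d to %d (only %d samples)",
                    n_pcs, max_pcs, n))
    n_pcs <- max_pcs
  }
  keep <- apply(logcpm, 1, stats::var) > 0
  pc <- stats::prcomp(t(logcpm[keep, , drop = FALSE]),
                      center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  z <- apply(scores, 2, function(x) {
    s <- stats::sd(x)
    if (s == 0) return(rep(0, length(x)))
    (x - stats::median(x)) / s
  })
  d <- sqrt(rowSums(as.matrix(z)^2))
  out <- stats::setNames(d > sd_threshold, colnames(logcpm))
  attr(out, "distance") <- stats::setNames(d, colnames(logcpm))
  out
}
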