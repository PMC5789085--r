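## Negative-binomial differential expression.
##
## Per-gene NB GLMs with log link and library-size offsets; a two-level
## dispersion scheme (one common dispersion maximizing the summed Cox-Reid
## adjusted profile likelihood, plus tagwise dispersions shrunk toward the
## common value by a weighted-likelihood prior); likelihood-ratio tests for
## the group coefficient; deviance goodness-of-fit screening; a power
## simulation over fold-change x abundance strata; and delta-delta-Ct
## arithmetic for qPCR validation.

# One NB GLM fit at fixed dispersion phi (IRLS, log link, offsets).
.nb_irls <- function(y, X, offset, phi, maxit = 50, tol = 1e-8) {
  mu <- pmax(y, 1 / 6) + mean(y) / 10
  eta <- log(mu) - offset
  beta <- rep(0, ncol(X))
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    mu <- pmin(exp(eta + offset), 1e12)
    w <- mu / (1 + phi * mu)
    z <- eta + (y - mu) / mu
    wX <- X * w
    fit <- tryCatch(solve(crossprod(X, wX), crossprod(wX, z)),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    beta <- drop(fit)
    eta <- pmin(pmax(drop(X %*% beta), -45), 45)
    mu <- pmin(exp(eta + offset), 1e12)
    ll <- if (phi > 0)
      sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
    else sum(stats::dpois(y, mu, log = TRUE))
    if (!is.finite(ll)) return(NULL)
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) { converged <- TRUE; break }
    ll_old <- ll
  }
  w <- mu / (1 + phi * mu)
  xtwx <- crossprod(X, X * w)
  cr <- 0.5 * as.numeric(determinant(xtwx, logarithm = TRUE)$modulus)
  list(beta = beta, mu = mu, loglik = ll, cr = cr, converged = converged)
}

# Cox-Reid adjusted profile log-likelihood of one gene at dispersion phi.
.apl <- function(y, X, offset, phi) {
  fit <- .nb_irls(y, X, offset, phi)
  if (is.null(fit)) return(NA_real_)
  fit$loglik - fit$cr
}

.design_matrix <- function(group, covariates, n) {
  g <- .trait_numeric(group)
  if (length(g) != n) stop("group length mismatch")
  X <- cbind(`(Intercept)` = 1, group = g)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (is.null(colnames(cv))) colnames(cv) <- paste0("cov", seq_len(ncol(cv)))
    X <- cbind(X, cv)
  }
  X
}

#' Estimate common and tagwise NB dispersions
#'
#' The common dispersion maximizes the sum over genes of the Cox-Reid
#' adjusted profile log-likelihood (APL). Tagwise dispersions maximize the
#' weighted likelihood `APL_g(phi) + prior_n * mean_APL(phi)` with
#' `prior_n = prior_df / residual_df`, shrinking each gene toward the
#' common value; `prior_df = Inf` returns the common dispersion for every
#' gene. APLs are evaluated on a log-spaced dispersion grid around the
#' common value and spline-interpolated.
#'
#' @param counts filtered gene x sample count matrix (>= 2 samples per
#'   group; no replication is an error).
#' @param group binary group factor/vector (MAO reference).
#' @param covariates optional numeric covariates added to the design.
#' @param offsets log effective library sizes (default
#'   `log(colSums(counts))`).
#' @param prior_df prior degrees of freedom of the shrinkage (default 10).
#' @return list of class `"DispersionModel"`: `common`, `tagwise` (named),
#'   `prior_df`, `offsets`, `design`.
#' @export
estimateDispersions <- function(counts, group, covariates = NULL,
                                offsets = NULL, prior_df = 10) {
  counts <- .check_counts(counts)
  n <- ncol(counts)
  X <- .design_matrix(group, covariates, n)
  if (n - ncol(X) <= 0)
    stop("no residual degrees of freedom: dispersion unidentifiable")
  if (min(table(X[, "group"])) < 2)
    stop("need at least 2 samples per group")
  if (is.null(offsets)) offsets <- log(colSums(counts))
  use <- rowSums(counts) > 0
  ys <- counts[use, , drop = FALSE]

  sum_apl <- function(log_phi) {
    phi <- exp(log_phi)
    sum(vapply(seq_len(nrow(ys)), function(g)
      .apl(ys[g, ], X, offsets, phi), numeric(1)), na.rm = TRUE)
  }
  opt <- stats::optimize(sum_apl, interval = log(c(1e-4, 4)),
                         maximum = TRUE, tol = 1e-3)
  common <- exp(opt$maximum)

  tagwise <- rep(common, nrow(counts))
  names(tagwise) <- rownames(counts)
  if (is.finite(prior_df)) {
    grid <- common * 2^seq(-6, 6, length.out = 13)
    apl_mat <- vapply(grid, function(phi)
      vapply(seq_len(nrow(ys)), function(g)
        .apl(ys[g, ], X, offsets, phi), numeric(1)),
      numeric(nrow(ys)))
    shared <- colMeans(apl_mat, na.rm = TRUE)
    prior_n <- prior_df / (n - ncol(X))
    lg <- log(grid)
    tw <- vapply(seq_len(nrow(ys)), function(g) {
      obj <- apl_mat[g, ] + prior_n * shared
      if (any(!is.finite(obj))) return(common)
      f <- stats::splinefun(lg, obj)
      exp(stats::optimize(f, interval = range(lg),
                          maximum = TRUE, tol = 1e-4)$maximum)
    }, numeric(1))
    tagwise[use] <- tw
  }
  structure(list(common = common, tagwise = tagwise,
                 prior_df = prior_df, offsets = offsets, design = X),
            class = "DispersionModel")
}

#' Negative-binomial likelihood-ratio tests
#'
#' Per gene, fits the full NB GLM (intercept + group + covariates, log
#' link, log-library-size offsets) and the reduced model without the group
#' term at the gene's dispersion, and tests the group coefficient with
#' `LR = 2 * (l_full - l_reduced) ~ chi-square(1)`. The reported log2 fold
#' change is MHO versus the MAO reference (positive = higher in MHO). A
#' gene is flagged differentially expressed when `|log2FC| > 0` and the BH
#' q-value is at most `fdr`.
#'
#' @param counts gene x sample count matrix.
#' @param group binary group (MAO = 0 reference, MHO = 1).
#' @param covariates optional numeric covariates.
#' @param dispersions a `"DispersionModel"`, or a numeric dispersion
#'   (scalar or per-gene vector).
#' @param offsets log effective library sizes; defaults to the model's, or
#'   `log(colSums(counts))`.
#' @param fdr flagging threshold on the BH q-value (default 0.05).
#' @return data.frame (class `"DEResult"`), one row per gene: `gene`,
#'   `log2FC`, `avg_log2CPM`, `dispersion`, `LR`, `pvalue`, `qvalue`,
#'   `de_flag`. All-zero or non-converged genes carry `NA` statistics. The
#'   fitted full-model means and residual df are attached as attributes
#'   for [gofDeviance()].
#' @export
nbLRT <- function(counts, group, covariates = NULL, dispersions,
                  offsets = NULL, fdr = 0.05) {
  counts <- .check_counts(counts)
  n <- ncol(counts)
  X <- .design_matrix(group, covariates, n)
  X0 <- X[, colnames(X) != "group", drop = FALSE]
  if (inherits(dispersions, "DispersionModel")) {
    if (is.null(offsets)) offsets <- dispersions$offsets
    phi <- dispersions$tagwise[rownames(counts)]
    if (any(is.na(phi))) phi <- rep(dispersions$common, nrow(counts))
  } else {
    phi <- rep_len(dispersions, nrow(counts))
  }
  if (is.null(offsets)) offsets <- log(colSums(counts))

  G <- nrow(counts)
  log2fc <- lr <- rep(NA_real_, G)
  mu_fit <- matrix(NA_real_, G, n)
  for (g in seq_len(G)) {
    y <- counts[g, ]
    if (all(y == 0)) next
    f1 <- .nb_irls(y, X, offsets, phi[g])
    f0 <- .nb_irls(y, X0, offsets, phi[g])
    if (is.null(f1) || is.null(f0) || !f1$converged || !f0$converged) {
      message("gene ", rownames(counts)[g],
              ": NB fit did not converge; statistics set to NA")
      next
    }
    log2fc[g] <- f1$beta[2] / log(2)
    lr[g] <- max(2 * (f1$loglik - f0$loglik), 0)
    mu_fit[g, ] <- f1$mu
  }
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  avg <- rowMeans(logCPM(counts, effective_libsizes = exp(offsets)))
  out <- data.frame(gene = rownames(counts), log2FC = log2fc,
                    avg_log2CPM = avg, dispersion = phi, LR = lr,
                    pvalue = p, qvalue = q,
                    de_flag = !is.na(q) & abs(log2fc) > 0 & q <= fdr,
                    row.names = NULL)
  class(out) <- c("DEResult", "data.frame")
  attr(out, "fitted_mu") <- mu_fit
  attr(out, "df_residual") <- n - ncol(X)
  attr(out, "counts") <- counts
  out
}

#' Deviance goodness-of-fit screen
#'
#' Residual deviance of each gene's full-model fit against a chi-square
#' with the residual degrees of freedom (upper tail). Genes with
#' `p <= flag_p` have dispersions markedly at odds with the fitted model
#' and deserve inspection.
#'
#' @param de a `"DEResult"` from [nbLRT()] (carries the fitted means), or a
#'   count matrix if `mu`, `dispersions` and `df` are given explicitly.
#' @param mu,dispersions,df optional explicit fitted means, dispersions and
#'   residual df.
#' @param flag_p flagging threshold (default 0.01).
#' @return data.frame: `gene`, `deviance`, `df`, `gof_p`, `gof_flag`.
#'   Saturated fits (df = 0) give `NA`.
#' @export
gofDeviance <- function(de, mu = NULL, dispersions = NULL, df = NULL,
                        flag_p = 0.01) {
  if (inherits(de, "DEResult")) {
    counts <- attr(de, "counts")
    mu <- attr(de, "fitted_mu")
    df <- attr(de, "df_residual")
    dispersions <- de$dispersion
    genes <- de$gene
  } else {
    counts <- .check_counts(de)
    genes <- rownames(counts)
    if (is.null(mu) || is.null(dispersions) || is.null(df))
      stop("supply mu, dispersions and df when not passing a DEResult")
    dispersions <- rep_len(dispersions, nrow(counts))
  }
  dev <- vapply(seq_len(nrow(counts)), function(g) {
    y <- counts[g, ]; m <- mu[g, ]; phi <- dispersions[g]
    if (any(is.na(m))) return(NA_real_)
    t1 <- ifelse(y > 0, y * log(y / m), 0)
    t2 <- (y + 1 / phi) * log((y + 1 / phi) / (m + 1 / phi))
    2 * sum(t1 - t2)
  }, numeric(1))
  p <- if (df > 0) stats::pchisq(dev, df, lower.tail = FALSE)
       else rep(NA_real_, length(dev))
  data.frame(gene = genes, deviance = dev, df = df, gof_p = p,
             gof_flag = !is.na(p) & p <= flag_p)
}

#' Power to detect differential expression, by effect and abundance
#'
#' Simulates two-group NB count data over a grid of absolute log2 fold
#' changes and mean-count strata (equal numbers of null genes per stratum
#' keep the FDR realistic), runs [nbLRT()] at the known dispersion, and
#' reports per-cell power: the fraction of truly differential genes with
#' `q <= fdr` across simulations.
#'
#' @param n_per_group samples per group (default 8).
#' @param lfc_grid absolute log2 fold changes to probe.
#' @param mean_strata mean count levels to probe.
#' @param dispersion NB dispersion used both to simulate and to test.
#' @param fdr detection threshold on the BH q-value (default 0.15).
#' @param n_sims simulation replicates (default 3).
#' @param genes_per_cell differential genes per (lfc, mean) cell.
#' @param seed RNG seed.
#' @return data.frame: `lfc`, `mean_count`, `power`, `n_genes`.
#' @export
powerSimulation <- function(n_per_group = 8, lfc_grid = c(0.14, 0.5, 1),
                            mean_strata = c(20, 80, 500),
                            dispersion = 0.1, fdr = 0.15, n_sims = 3,
                            genes_per_cell = 50, seed = 1) {
  set.seed(seed)
  cells <- expand.grid(lfc = lfc_grid, mean_count = mean_strata)
  hits <- matrix(0, nrow(cells), n_sims)
  n <- 2 * n_per_group
  group <- rep(c(0, 1), each = n_per_group)
  for (s in seq_len(n_sims)) {
    lfc_gene <- mu_gene <- numeric(0)
    for (i in seq_len(nrow(cells))) {
      lfc_gene <- c(lfc_gene, rep(cells$lfc[i], genes_per_cell),
                    rep(0, genes_per_cell))
      mu_gene <- c(mu_gene, rep(cells$mean_count[i], 2 * genes_per_cell))
    }
    G <- length(lfc_gene)
    # split the fold change symmetrically around the stratum mean
    mu0 <- mu_gene * 2^(-lfc_gene / 2)
    mu1 <- mu_gene * 2^(lfc_gene / 2)
    mu <- cbind(matrix(mu0, G, n_per_group), matrix(mu1, G, n_per_group))
    counts <- matrix(stats::rnbinom(G * n, mu = as.vector(mu),
                                    size = 1 / dispersion), G, n)
    rownames(counts) <- sprintf("pg%05d", seq_len(G))
    de <- nbLRT(counts, group, dispersions = dispersion,
                offsets = rep(log(1e6), n), fdr = fdr)
    for (i in seq_len(nrow(cells))) {
      idx <- which(abs(lfc_gene - cells$lfc[i]) < 1e-12 &
                   mu_gene == cells$mean_count[i])
      idx <- idx[seq_len(genes_per_cell)]   # the truly-DE half of the cell
      hits[i, s] <- mean(de$qvalue[idx] <= fdr, na.rm = TRUE)
    }
  }
  data.frame(cells, power = rowMeans(hits),
             n_genes = genes_per_cell * n_sims)
}

#' Relative expression by the delta-delta-Ct method
#'
#' `dCt = Ct_target - mean(Ct_references)` per sample; `ddCt = mean dCt
#' (case) - mean dCt (control)`; fold change `= 2^(-ddCt)` (amplification
#' efficiency fixed at 2).
#'
#' @param ct_target per-sample Ct values of the target transcript.
#' @param ct_refs per-sample Ct values of the reference gene(s): vector or
#'   samples x references matrix (e.g. GAPDH and ACTB), averaged
#'   arithmetically.
#' @param groups per-sample group labels.
#' @param case,control which levels are compared (defaults `"MHO"` vs
#'   `"MAO"`).
#' @return list with `fold_change`, `ddct`, and per-group mean `dct`.
#' @examples
#' ddctRelativeExpression(c(24, 24, 25, 25), c(20, 20, 20, 20),
#'   groups = c("MHO", "MHO", "MAO", "MAO"))
#' @export
ddctRelativeExpression <- function(ct_target, ct_refs, groups,
                                   case = "MHO", control = "MAO") {
  ct_refs <- as.matrix(ct_refs)
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_refs)))
    stop("Ct values must be finite")
  if (nrow(ct_refs) != length(ct_target))
    stop("ct_refs must have one row per sample")
  groups <- as.character(groups)
  if (!any(groups == case)) stop("no samples in case group '", case, "'")
  if (!any(groups == control))
    stop("no samples in control group '", control, "'")
  dct <- ct_target - rowMeans(ct_refs)
  ddct <- mean(dct[groups == case]) - mean(dct[groups == control])
  list(fold_change = 2^(-ddct), ddct = ddct,
       dct_case = mean(dct[groups == case]),
       dct_control = mean(dct[groups == control]))
}
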