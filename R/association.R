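## Module eigengenes, module membership (MM), gene significance (GS),
## module-trait association under the dual significance rule, and
## hypergeometric gene-set enrichment.
##
## A module-trait association is reported significant only when (i) the
## BH-adjusted p-value of the (covariate-adjusted) eigengene-trait
## correlation is <= 0.05 AND (ii) the correlation between MM and GS over
## the module's member genes is > 0 with p <= 0.05 — the biological
## plausibility check that hub genes track the phenotype more closely than
## peripheral genes.

#' Module eigengene
#'
#' First principal component of the row-standardized module submatrix
#' across samples, scaled to unit variance, with the sign aligned so that
#' the eigengene correlates non-negatively with the module's mean
#' standardized expression.
#'
#' @param logcpm gene x sample matrix.
#' @param genes identifiers (or indices) of the module's genes, size >= 2.
#' @return list with `eigengene` (named numeric, one value per sample) and
#'   `variance_explained` (fraction of the standardized module variance
#'   carried by the first component).
#' @export
moduleEigengene <- function(logcpm, genes) {
  x <- as.matrix(logcpm)[genes, , drop = FALSE]
  if (nrow(x) < 2) stop("module must contain at least 2 genes")
  xs <- t(scale(t(x)))              # standardize each gene across samples
  if (any(!is.finite(xs))) stop("zero-variance gene in module")
  sv <- svd(xs)
  e <- sv$v[, 1]
  e <- e / stats::sd(e)
  if (stats::cor(e, colMeans(xs)) < 0) e <- -e
  list(eigengene = stats::setNames(e, colnames(x)),
       variance_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Eigengenes of every module in a partition
#'
#' @param logcpm gene x sample matrix.
#' @param labels a [ModuleSet-class] or a named integer label vector
#'   (0 = unassigned).
#' @return list with `eigengenes` (samples x modules matrix, columns
#'   `ME1`, `ME2`, ...) and `variance_explained` (per module).
#' @export
moduleEigengenes <- function(logcpm, labels) {
  if (is(labels, "ModuleSet")) labels <- moduleLabels(labels)
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no modules in partition")
  res <- lapply(mods, function(m)
    moduleEigengene(logcpm, names(labels)[labels == m]))
  me <- do.call(cbind, lapply(res, `[[`, "eigengene"))
  colnames(me) <- paste0("ME", mods)
  list(eigengenes = me,
       variance_explained = stats::setNames(
         vapply(res, `[[`, numeric(1), "variance_explained"),
         colnames(me)))
}

#' Module membership of a gene
#'
#' `MM = |cor(gene, eigengene)|`, in `[0, 1]`: how well the gene belongs
#' to the module (hub genes approach 1). The signed correlation is kept in
#' `attr(x, "signed")` for diagnostics.
#'
#' @param gene_profile expression of one gene across samples.
#' @param eigengene module eigengene over the same samples.
#' @return MM in `[0, 1]`.
#' @export
moduleMembership <- function(gene_profile, eigengene) {
  if (length(gene_profile) != length(eigengene))
    stop("profile and eigengene must have the same length")
  if (stats::sd(gene_profile) == 0 || stats::sd(eigengene) == 0)
    stop("zero-variance input")
  r <- stats::cor(gene_profile, eigengene)
  structure(abs(r), signed = r)
}

#' Gene significance
#'
#' `GS = |cor(gene, trait)|`; with a binary trait (MAO = 0 reference,
#' MHO = 1) this is the point-biserial correlation.
#'
#' @param gene_profile expression of one gene across samples.
#' @param trait numeric or two-level factor/binary vector.
#' @return GS in `[0, 1]`, signed value in `attr(x, "signed")`.
#' @export
geneSignificance <- function(gene_profile, trait) {
  trait <- .trait_numeric(trait)
  if (stats::sd(trait) == 0) stop("trait is constant")
  if (stats::sd(gene_profile) == 0) stop("gene profile is constant")
  r <- stats::cor(gene_profile, trait)
  structure(abs(r), signed = r)
}

.trait_numeric <- function(trait) {
  if (is.factor(trait) || is.character(trait)) {
    trait <- as.factor(trait)
    if (nlevels(trait) != 2) stop("trait must be binary or numeric")
    trait <- as.numeric(trait) - 1
  }
  as.numeric(trait)
}

.residualize <- function(y, covariates) {
  if (is.null(covariates) || !NCOL(covariates)) return(y - mean(y))
  x <- cbind(1, as.matrix(covariates))
  stats::lm.fit(x, y)$residuals
}

#' Module-trait association with the dual significance rule
#'
#' Correlates each module eigengene with the trait, optionally as a partial
#' correlation controlling covariates (both sides residualized on the
#' covariates, e.g. sex). Two-sided p-values come from the t distribution
#' with `n - 2 - n_covariates` degrees of freedom; BH adjustment is applied
#' across modules. For each module the MM-GS correlation is computed over
#' its member genes only. A module is flagged significant when
#' `q <= fdr` AND `MM-GS r > 0 with p <= 0.05`.
#'
#' @param eigengenes samples x modules matrix (from [moduleEigengenes()]).
#' @param trait binary (MAO = 0 reference, MHO = 1) or numeric trait.
#' @param covariates optional numeric matrix/data.frame of per-sample
#'   covariates; factors must be coded numerically by the caller.
#' @param logcpm,labels gene x sample matrix and module labels (or a
#'   [ModuleSet-class]) used for the MM-GS check; omit both to skip it
#'   (the flag then rests on the FDR criterion alone).
#' @param fdr module-trait FDR threshold (default 0.05).
#' @return data.frame, one row per module: `module`, `cor`, `p`, `q`,
#'   `mm_gs_cor`, `mm_gs_p`, `significant`.
#' @export
moduleTraitAssociation <- function(eigengenes, trait, covariates = NULL,
                                   logcpm = NULL, labels = NULL,
                                   fdr = 0.05) {
  eigengenes <- as.matrix(eigengenes)
  n <- nrow(eigengenes)
  if (n < 4) stop("need at least 4 samples")
  trait <- .trait_numeric(trait)
  ncov <- if (is.null(covariates)) 0L else NCOL(covariates)
  if (ncov) {
    cx <- as.matrix(covariates)
    fit <- stats::lm.fit(cbind(1, cx), trait)
    if (stats::sd(fit$residuals) < 1e-12)
      stop("covariates are collinear with the trait")
    tr <- fit$residuals
  } else tr <- trait - mean(trait)
  df <- n - 2 - ncov
  r <- apply(eigengenes, 2, function(e)
    stats::cor(.residualize(e, covariates), tr))
  tstat <- r * sqrt(df / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")

  mm_gs_cor <- mm_gs_p <- rep(NA_real_, ncol(eigengenes))
  if (!is.null(logcpm) && !is.null(labels)) {
    if (is(labels, "ModuleSet")) labels <- moduleLabels(labels)
    mods <- as.integer(sub("^ME", "", colnames(eigengenes)))
    for (i in seq_along(mods)) {
      genes <- names(labels)[labels == mods[i]]
      if (length(genes) < 3) next
      mm <- vapply(genes, function(g)
        as.numeric(moduleMembership(logcpm[g, ], eigengenes[, i])),
        numeric(1))
      gs <- vapply(genes, function(g)
        as.numeric(geneSignificance(logcpm[g, ], trait)), numeric(1))
      if (stats::sd(mm) == 0 || stats::sd(gs) == 0) next
      ct <- stats::cor.test(mm, gs)
      mm_gs_cor[i] <- unname(ct$estimate)
      mm_gs_p[i] <- ct$p.value
    }
  }
  sig <- q <= fdr &
    (is.na(mm_gs_cor) | (mm_gs_cor > 0 & mm_gs_p <= 0.05))
  data.frame(module = colnames(eigengenes), cor = r, p = p, q = q,
             mm_gs_cor = mm_gs_cor, mm_gs_p = mm_gs_p,
             significant = sig, row.names = NULL)
}

#' Read gene sets in GMT format
#'
#' Tab-separated: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(x) x[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, "", 1L)
  sets
}

#' One-sided hypergeometric gene-set enrichment
#'
#' For each set, the over-representation p-value
#' `P(X >= overlap)` under `Hypergeometric(universe, set, module)` —
#' equivalent to a one-sided Fisher exact test. BH adjustment across sets.
#'
#' @param module_genes character vector of module member genes (must be a
#'   subset of `universe`).
#' @param gene_sets named list of character vectors (e.g. [readGMT()]);
#'   each set is intersected with the universe.
#' @param universe character vector of all analysed genes.
#' @return data.frame per set: `set`, `overlap`, `set_size`, `module_size`,
#'   `universe_size`, `p`, `q`.
#' @export
hypergeometricEnrichment <- function(module_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  if (!all(module_genes %in% universe))
    stop("module_genes must be a subset of the universe")
  module_genes <- unique(module_genes)
  n_mod <- length(module_genes)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    ov <- length(intersect(set, module_genes))
    p <- stats::phyper(ov - 1, length(set),
                       length(universe) - length(set), n_mod,
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = length(set),
               module_size = n_mod, universe_size = length(universe),
               p = p)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
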