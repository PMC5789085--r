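## Seeded synthetic cohort generator.
##
## Emulates the statistical structure the downstream analysis assumes:
## negative-binomial counts with library-size variation, co-expressed gene
## modules driven by latent Gaussian factors, one module whose factor is
## shifted down in MHO subjects, and clinical covariates drawn from
## group-specific lognormal distributions calibrated to baseline
## characteristics typical of such cohorts (8 MHO vs 21 MAO).

.lnorm_pars <- function(mean, sd) {
  # arithmetic mean/sd -> lognormal meanlog/sdlog
  cv2 <- (sd / mean)^2
  sdlog <- sqrt(log1p(cv2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

.default_clinical_params <- function() {
  list(
    MHO = list(glucose = c(87, 6.57), hscrp = c(0.13, 0.09),
               homa_ir = c(1.99, 1.49), tg_hdl = c(0.98, 0.27),
               bmi = c(34, 6), age = c(41.88, 6.08), hdl = c(55, 10),
               p_female = 3 / 8, p_hypertensive = 0,
               p_smoker = 4 / 8, p_drinker = 3 / 8),
    MAO = list(glucose = c(92.62, 9.59), hscrp = c(0.36, 0.21),
               homa_ir = c(4.21, 2.97), tg_hdl = c(2.25, 1.21),
               bmi = c(37, 5), age = c(42.33, 5.97), hdl = c(45, 10),
               p_female = 14 / 21, p_hypertensive = 13 / 21,
               p_smoker = 10 / 21, p_drinker = 5 / 21)
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults define the reference analysis conditions: 8 MHO vs 21 MAO subjects,
#' 2,000 genes with three planted 50-gene co-expression modules, the first
#' module's latent factor shifted down by `assoc_effect` standard deviations
#' in MHO subjects, per-gene negative-binomial dispersions drawn from a
#' gamma prior (median ~ 0.08), and clinical covariates matching the
#' group-specific means and SDs of the cohort's baseline table.
#'
#' @param n_mho,n_mao group sizes (default 8 and 21).
#' @param n_genes total genes (default 2000).
#' @param module_sizes planted module sizes (default three modules of 50).
#' @param assoc_module_index which module is MHO-associated (default 1).
#' @param assoc_effect standardized downward shift of that module's latent
#'   factor in MHO samples (Cohen's d; default 1.5).
#' @param loading_mean,loading_sd Gaussian factor-loading distribution of
#'   module genes (log2 scale per factor SD; defaults 0.8 and 0.15).
#' @param baseline_logmean_range uniform range of per-gene baseline
#'   abundance, log2 counts (default `c(3, 10)`).
#' @param dispersion_shape,dispersion_scale gamma hyper-parameters of the
#'   per-gene NB dispersion phi (defaults 2 and 0.05: mean 0.1).
#' @param libsize_logmean,libsize_logsd log-normal library-size model
#'   (defaults `log(1e6)` and 0.2).
#' @param clinical_params per-group list of `c(mean, sd)` for `glucose`,
#'   `hscrp`, `homa_ir`, `tg_hdl`, `bmi`, `age`, `hdl` plus Bernoulli
#'   proportions; see `mhonet:::.default_clinical_params()` for the layout.
#' @param tg_hdl_factor_cor within-group correlation between the associated
#'   module's latent factor and TG/HDL (default 0.6), giving the driver
#'   ranking a recoverable ground truth.
#' @param de_logfc per-gene planted log2 fold change (MHO vs MAO), recycled
#'   or named; default 0 for all genes.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return validated list of class `"cohortConfig"`.
#' @export
cohortConfig <- function(n_mho = 8, n_mao = 21, n_genes = 2000,
                         module_sizes = c(50, 50, 50),
                         assoc_module_index = 1, assoc_effect = 1.5,
                         loading_mean = 0.8, loading_sd = 0.15,
                         baseline_logmean_range = c(3, 10),
                         dispersion_shape = 2, dispersion_scale = 0.05,
                         libsize_logmean = log(1e6), libsize_logsd = 0.2,
                         clinical_params = .default_clinical_params(),
                         tg_hdl_factor_cor = 0.6,
                         de_logfc = NULL, seed = 1) {
  cfg <- list(n_mho = as.integer(n_mho), n_mao = as.integer(n_mao),
              n_genes = as.integer(n_genes),
              module_sizes = as.integer(module_sizes),
              assoc_module_index = as.integer(assoc_module_index),
              assoc_effect = assoc_effect,
              loading_mean = loading_mean, loading_sd = loading_sd,
              baseline_logmean_range = baseline_logmean_range,
              dispersion_shape = dispersion_shape,
              dispersion_scale = dispersion_scale,
              libsize_logmean = libsize_logmean,
              libsize_logsd = libsize_logsd,
              clinical_params = clinical_params,
              tg_hdl_factor_cor = tg_hdl_factor_cor,
              de_logfc = de_logfc, seed = as.integer(seed))
  class(cfg) <- "cohortConfig"
  validateCohortConfig(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' @param config a [cohortConfig()] list.
#' @return the config, invisibly; invalid configs are rejected with an error.
#' @export
validateCohortConfig <- function(config) {
  with(config, {
    if (n_mho < 1 || n_mao < 1 || n_genes < 1)
      stop("group sizes and n_genes must be positive")
    if (any(module_sizes < 1)) stop("module sizes must be positive")
    if (sum(module_sizes) > n_genes)
      stop("sum(module_sizes) must not exceed n_genes")
    if (!assoc_module_index %in% seq_along(module_sizes))
      stop("assoc_module_index out of range")
    if (!is.finite(assoc_effect)) stop("assoc_effect must be finite")
    if (loading_sd <= 0 || libsize_logsd <= 0)
      stop("every sd must be > 0")
    if (dispersion_shape <= 0 || dispersion_scale <= 0)
      stop("dispersion hyper-parameters must be > 0")
    if (libsize_logmean <= 0) stop("libsize_logmean must be > 0")
    for (grp in c("MHO", "MAO"))
      for (v in c("glucose", "hscrp", "homa_ir", "tg_hdl", "bmi", "age"))
        if (any(clinical_params[[grp]][[v]] <= 0))
          stop(sprintf("clinical_params$%s$%s must be positive", grp, v))
    if (abs(tg_hdl_factor_cor) >= 1)
      stop("tg_hdl_factor_cor must be in (-1, 1)")
  })
  invisible(config)
}

.rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  # inverse-CDF truncation keeps the draw count (and the RNG stream) fixed
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Draw clinical covariates for subjects of one group. `zf` is the
# within-group standardized latent factor of the associated module, used to
# couple TG/HDL to module expression through a Gaussian copula.
.draw_clinical <- function(group, zf, config) {
  p <- config$clinical_params[[group]]
  n <- length(zf)
  draw_ln <- function(ms, n) {
    lp <- .lnorm_pars(ms[1], ms[2])
    stats::rlnorm(n, lp$meanlog, lp$sdlog)
  }
  r <- config$tg_hdl_factor_cor
  z <- r * zf + sqrt(1 - r^2) * stats::rnorm(n)
  lp <- .lnorm_pars(p$tg_hdl[1], p$tg_hdl[2])
  tg_hdl <- stats::qlnorm(stats::pnorm(z), lp$meanlog, lp$sdlog)
  hdl <- draw_ln(p$hdl, n)
  hyper <- stats::runif(n) < p$p_hypertensive
  sbp <- ifelse(hyper, .rtrunc_norm(n, 145, 10, lower = 131),
                .rtrunc_norm(n, 118, 7, upper = 130))
  dbp <- ifelse(hyper, .rtrunc_norm(n, 92, 8, lower = 70),
                .rtrunc_norm(n, 74, 6, upper = 85))
  bp_med <- hyper & stats::runif(n) < 0.5
  data.frame(
    sex = ifelse(stats::runif(n) < p$p_female, "F", "M"),
    age = .rtrunc_norm(n, p$age[1], p$age[2], lower = 30, upper = 55),
    bmi = .rtrunc_norm(n, p$bmi[1], p$bmi[2], lower = 30),
    sbp = sbp, dbp = dbp, bp_medication = bp_med,
    glucose = draw_ln(p$glucose, n),
    homa_ir = draw_ln(p$homa_ir, n),
    tg = tg_hdl * hdl, hdl = hdl, tg_hdl = tg_hdl,
    hscrp = draw_ln(p$hscrp, n),
    smoker = stats::runif(n) < p$p_smoker,
    drinker = stats::runif(n) < p$p_drinker,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic MHO/MAO cohort
#'
#' Draws a gene x sample negative-binomial count matrix with planted latent
#' factor co-expression modules, group-specific clinical covariates, and a
#' ground-truth record. Gene `g` of module `m` in sample `i` has mean
#' `2^(baseline_g + loading_g * f_m(i) + group_i * lfc_g) * L_i / L0` with
#' NB dispersion `phi_g`, where `f_m` is the module's standard-normal latent
#' factor (shifted by `-assoc_effect` in MHO samples for the associated
#' module), `L_i` the drawn library size and `L0 = exp(libsize_logmean)`.
#' Background genes have loading 0. TG/HDL is coupled to the associated
#' module's factor within groups (Gaussian copula).
#'
#' @param config a [cohortConfig()].
#' @param resample if `TRUE` (default), clinical draws that contradict the
#'   subject's assigned group under the MHO definition are redrawn via
#'   [resampleConsistentClinical()].
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, clinical covariates plus `group` in `colData`, and the truth
#'   record (module labels, loadings, baselines, dispersions, true log2FC,
#'   latent factors, group coding, seed) in `metadata(x)$truth`.
#' @examples
#' se <- generateCohort(cohortConfig(n_genes = 200,
#'   module_sizes = c(20, 20), seed = 7))
#' dim(se)
#' @export
generateCohort <- function(config, resample = TRUE) {
  validateCohortConfig(config)
  set.seed(config$seed)
  n <- config$n_mho + config$n_mao
  group <- c(rep(1L, config$n_mho), rep(0L, config$n_mao)) # MHO = 1
  glab <- ifelse(group == 1L, "MHO", "MAO")
  sample_ids <- sprintf("S%02d", seq_len(n))
  G <- config$n_genes
  gene_ids <- sprintf("g%04d", seq_len(G))

  module <- integer(G)
  idx <- 1L
  for (m in seq_along(config$module_sizes)) {
    module[idx:(idx + config$module_sizes[m] - 1L)] <- m
    idx <- idx + config$module_sizes[m]
  }
  loadings <- numeric(G)
  in_mod <- module > 0L
  loadings[in_mod] <- stats::rnorm(sum(in_mod), config$loading_mean,
                                   config$loading_sd)
  baseline <- stats::runif(G, config$baseline_logmean_range[1],
                           config$baseline_logmean_range[2])
  phi <- stats::rgamma(G, shape = config$dispersion_shape,
                       scale = config$dispersion_scale)
  libsize <- stats::rlnorm(n, config$libsize_logmean, config$libsize_logsd)

  K <- length(config$module_sizes)
  factors <- matrix(stats::rnorm(n * K), n, K,
                    dimnames = list(sample_ids, paste0("M", seq_len(K))))
  factors[, config$assoc_module_index] <-
    factors[, config$assoc_module_index] - config$assoc_effect * group

  lfc <- numeric(G)
  if (!is.null(config$de_logfc)) {
    if (!is.null(names(config$de_logfc))) {
      lfc[match(names(config$de_logfc), gene_ids)] <- config$de_logfc
    } else lfc <- rep_len(config$de_logfc, G)
  }

  log2mu <- matrix(baseline, G, n)
  for (m in seq_len(K)) {
    sel <- module == m
    log2mu[sel, ] <- log2mu[sel, ] + outer(loadings[sel], factors[, m])
  }
  log2mu <- log2mu + outer(lfc, as.numeric(group))
  mu <- 2^log2mu * rep(libsize / exp(config$libsize_logmean),
                       each = G)
  counts <- matrix(stats::rnbinom(G * n, mu = as.vector(mu),
                                  size = rep(1 / phi, times = n)),
                   G, n, dimnames = list(gene_ids, sample_ids))

  tmp <- vector("list", n)
  for (g in c("MHO", "MAO")) {
    ii <- which(glab == g)
    fz <- factors[ii, config$assoc_module_index]
    fz <- as.numeric(scale(fz))
    if (length(ii) == 1) fz <- 0
    drawn <- .draw_clinical(g, fz, config)
    for (k in seq_along(ii)) tmp[[ii[k]]] <- drawn[k, , drop = FALSE]
  }
  clinical <- do.call(rbind, tmp)
  rownames(clinical) <- sample_ids
  clinical$group <- glab

  if (resample)
    clinical <- resampleConsistentClinical(clinical, glab, config)

  truth <- structure(list(
    module = stats::setNames(module, gene_ids),
    loadings = stats::setNames(loadings, gene_ids),
    baseline = stats::setNames(baseline, gene_ids),
    dispersions = stats::setNames(phi, gene_ids),
    log2fc = stats::setNames(lfc, gene_ids),
    factors = factors,
    group = stats::setNames(group, sample_ids),
    seed = config$seed), class = "SyntheticTruth")

  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(clinical),
    metadata = list(truth = truth, config = config))
}

#' Redraw clinical values inconsistent with the assigned group
#'
#' Subjects whose drawn covariates do not classify back to their assigned
#' MHO/MAO label under the default MHO definition (Definition 3) are redrawn
#' from their group's distributions, up to `max_retries` times each. The
#' TG/HDL-to-factor coupling noise is redrawn; the subject's latent factor
#' contribution is not retained across redraws (the violating subjects are
#' by construction tail draws, so the coupling loss is negligible).
#'
#' @param clinical data.frame of clinical covariates (one row per subject).
#' @param labels assigned group labels, `"MHO"`/`"MAO"`.
#' @param config the [cohortConfig()] that generated the table.
#' @param max_retries per-subject redraw budget (default 100).
#' @param seed optional; when given, `set.seed` is called first so repeated
#'   calls are reproducible. Inside [generateCohort()] the running RNG
#'   stream is used instead.
#' @return the corrected data.frame. If any subject exhausts its budget a
#'   warning is raised and the offender indices are attached as
#'   `attr(x, "inconsistent")`.
#' @export
resampleConsistentClinical <- function(clinical, labels, config,
                                       max_retries = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- as.character(labels)
  stopifnot(nrow(clinical) == length(labels))
  keep_grp <- "group" %in% names(clinical)
  bad <- integer()
  for (i in seq_len(nrow(clinical))) {
    tries <- 0L
    while (classifyMHO(clinical[i, setdiff(names(clinical), "group"),
                                drop = FALSE])$label != labels[i]) {
      if (tries >= max_retries) { bad <- c(bad, i); break }
      redraw <- .draw_clinical(labels[i], stats::rnorm(1), config)
      clinical[i, names(redraw)] <- redraw
      tries <- tries + 1L
    }
  }
  if (length(bad)) {
    warning(sprintf(
      "%d subject(s) could not be made consistent within %d retries: %s",
      length(bad), max_retries, paste(rownames(clinical)[bad],
                                      collapse = ", ")))
    attr(clinical, "inconsistent") <- bad
  }
  clinical
}
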