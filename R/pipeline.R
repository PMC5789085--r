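## End-to-end orchestration of the three complementary strategies:
## co-expression modules -> module-trait association -> differential
## expression of associated-module genes -> balanced random-forest
## classification, variable selection and metabolic driver ranking.

#' Pipeline configuration
#'
#' Exactly one of `counts`/`clinical` (paths or objects) or `simulate`
#' (a [cohortConfig()]) must be supplied.
#'
#' @param simulate a [cohortConfig()] to generate the cohort, or `NULL`.
#' @param counts gene x sample count matrix (or TSV path), or `NULL`.
#' @param clinical clinical data.frame (or TSV path), or `NULL`.
#' @param min_cpm,min_samples expression filter (defaults 1 CPM in 3).
#' @param min_module_size,cut_height,fit_required,merge_cor network
#'   thresholds (defaults 10, 0.99, 0.8, 0.75).
#' @param fdr module-trait and DE FDR threshold (default 0.05).
#' @param covariate_sex adjust the module-trait correlation for sex
#'   (default `TRUE`).
#' @param de_all_genes test all filtered genes instead of only
#'   associated-module genes (default `FALSE`; note
#'   the multiple-testing universe is then the restricted set).
#' @param rf an [rfConfig()].
#' @param seed pipeline seed (default 1).
#' @return list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(simulate = NULL, counts = NULL, clinical = NULL,
                           min_cpm = 1, min_samples = 3,
                           min_module_size = 10, cut_height = 0.99,
                           fit_required = 0.8, merge_cor = 0.75,
                           fdr = 0.05, covariate_sex = TRUE,
                           de_all_genes = FALSE,
                           rf = rfConfig(ntree = 2000, nPerm = 1000),
                           seed = 1) {
  if (is.null(simulate) == (is.null(counts) || is.null(clinical)))
    stop("supply either 'simulate' or both 'counts' and 'clinical'")
  stopifnot(min_cpm >= 0, min_samples >= 1, min_module_size >= 2,
            cut_height > 0, cut_height <= 1, fit_required > 0,
            fit_required <= 1, merge_cor > 0, merge_cor < 1,
            fdr > 0, fdr < 1)
  structure(list(simulate = simulate, counts = counts, clinical = clinical,
                 min_cpm = min_cpm, min_samples = min_samples,
                 min_module_size = min_module_size,
                 cut_height = cut_height, fit_required = fit_required,
                 merge_cor = merge_cor, fdr = fdr,
                 covariate_sex = covariate_sex,
                 de_all_genes = de_all_genes, rf = rf,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

.load_table <- function(x) {
  if (is.character(x) && length(x) == 1)
    x <- utils::read.delim(x, row.names = 1, check.names = FALSE)
  x
}

#' Run the full analysis
#'
#' Simulate or load -> filter and TMM-normalize -> classify the phenotype
#' -> build the co-expression network at the scale-free soft threshold ->
#' detect and merge modules -> associate module eigengenes with MHO status
#' (sex-adjusted, dual significance rule) -> NB likelihood-ratio DE over
#' associated-module genes -> balanced random forest per associated
#' module, with variable selection and metabolic driver ranking. Identical
#' config and seed give an identical report.
#'
#' @param config a [pipelineConfig()].
#' @param out_dir optional directory; stage outputs (TSV) and
#'   `report.json` are written there.
#' @return list of class `"AnalysisReport"`; see the elements `qc`,
#'   `phenotype`, `network`, `modules`, `association`, `de`, `rf`,
#'   `selection`, `drivers`, `config`.
#' @export
runFullAnalysis <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  stage <- "input"
  report <- list(config = config, seed = config$seed,
                 version = as.character(utils::packageVersion("mhonet")))
  run <- function(stage_name, expr) {
    stage <<- stage_name
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage_name,
                   conditionMessage(e)), call. = FALSE))
  }

  if (!is.null(config$simulate)) {
    se <- run("simulate", generateCohort(config$simulate))
    counts <- SummarizedExperiment::assay(se, "counts")
    clinical <- as.data.frame(SummarizedExperiment::colData(se))
    report$truth <- S4Vectors::metadata(se)$truth
  } else {
    counts <- run("load", .check_counts(as.matrix(.load_table(config$counts))))
    clinical <- run("load", .load_table(config$clinical))
  }

  filtered <- run("preprocess",
                  filterLowExpression(counts, config$min_cpm,
                                      config$min_samples))
  norm <- run("preprocess", normalizeTMM(filtered))
  outliers <- run("preprocess", pcaOutliers(norm$logcpm))
  report$qc <- list(genes_input = nrow(counts),
                    genes_filtered = nrow(filtered),
                    tmm_factors = norm$factors,
                    outliers = names(outliers)[outliers])

  pheno <- run("phenotype", classifyCohort(clinical))
  trait <- as.integer(pheno$label == "MHO")
  if (stats::sd(trait) == 0)
    stop("pipeline stage 'phenotype' failed: single phenotype class")
  report$phenotype <- list(labels = stats::setNames(pheno$label,
                                                    rownames(clinical)),
                           n_mho = sum(trait), n_mao = sum(trait == 0))

  net <- run("network", buildNetwork(norm$logcpm,
                                     fit_required = config$fit_required))
  report$network <- list(power = softPower(net),
                         scale_free_fit = net@scaleFreeFit,
                         fit_curve = fitCurve(net))

  part <- run("modules", clusterModules(net, config$min_module_size,
                                        config$cut_height))
  part <- run("modules", mergeModules(part, norm$logcpm, config$merge_cor))
  report$modules <- list(labels = moduleLabels(part),
                         sizes = moduleSizes(part),
                         n_modules = length(moduleSizes(part)))
  if (!length(moduleSizes(part)))
    stop("pipeline stage 'modules' failed: no module detected")

  sex_cov <- if (config$covariate_sex)
    matrix(as.integer(clinical$sex == "F"), ncol = 1,
           dimnames = list(NULL, "sex")) else NULL
  me <- run("association", moduleEigengenes(norm$logcpm, part))
  assoc <- run("association",
               moduleTraitAssociation(me$eigengenes, trait, sex_cov,
                                      norm$logcpm, part, fdr = config$fdr))
  report$association <- assoc
  hit_modules <- as.integer(sub("^ME", "",
                                assoc$module[assoc$significant]))

  lab <- moduleLabels(part)
  de_genes <- if (config$de_all_genes || !length(hit_modules))
    rownames(filtered) else names(lab)[lab %in% hit_modules]
  de <- NULL
  if (length(hit_modules) || config$de_all_genes) {
    disp <- run("diffexpr",
                estimateDispersions(filtered[de_genes, , drop = FALSE],
                                    trait,
                                    offsets = log(norm$effective_libsize)))
    de <- run("diffexpr",
              nbLRT(filtered[de_genes, , drop = FALSE], trait,
                    dispersions = disp, fdr = config$fdr))
    de <- cbind(de, gof_p = gofDeviance(de)$gof_p)
  }
  report$de <- de

  report$rf <- report$selection <- list()
  if (length(hit_modules)) {
    for (m in hit_modules) {
      genes <- names(lab)[lab == m]
      feats <- t(norm$logcpm[genes, , drop = FALSE])
      cfg <- config$rf
      cfg$seed <- config$rf$seed + m
      fit <- run("rf_classify", trainRFBalanced(feats, trait, cfg))
      report$rf[[paste0("ME", m)]] <- oobReport(fit)
    }
    m1 <- hit_modules[1]
    genes <- names(lab)[lab == m1]
    feats <- t(norm$logcpm[genes, , drop = FALSE])
    sel_cfg <- config$rf
    sel_cfg$ntree <- min(config$rf$ntree, 500L)
    report$selection <- run("rf_classify",
                            selectVariables(feats, trait, sel_cfg,
                                            n_replicates = 10,
                                            eval_replicates = 3))
    drv <- clinical[, intersect(c("hscrp", "tg_hdl", "glucose", "homa_ir"),
                                names(clinical)), drop = FALSE]
    if (ncol(drv) >= 2) {
      report$drivers <- run("rf_classify",
                            rankMetabolicDrivers(feats, drv, trait,
                                                 rfConfig(ntree = 500,
                                                          seed = config$seed)))
    }
  }

  class(report) <- "AnalysisReport"
  if (!is.null(out_dir)) .write_report(report, filtered, norm, out_dir)
  report
}

.write_report <- function(report, filtered, norm, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE)
  wt(filtered, "filtered_counts.tsv")
  wt(data.frame(factor = norm$factors), "tmm_factors.tsv")
  wt(round(norm$logcpm, 4), "logcpm.tsv")
  wt(data.frame(module = report$modules$labels), "modules.tsv")
  wt(report$association, "module_trait.tsv")
  if (!is.null(report$de)) wt(report$de, "de.tsv")
  json <- list(
    seed = report$seed, version = report$version,
    qc = list(genes_input = report$qc$genes_input,
              genes_filtered = report$qc$genes_filtered,
              outliers = report$qc$outliers),
    phenotype = list(n_mho = report$phenotype$n_mho,
                     n_mao = report$phenotype$n_mao),
    network = list(power = report$network$power,
                   scale_free_fit = report$network$scale_free_fit),
    modules = list(n_modules = report$modules$n_modules,
                   sizes = as.list(report$modules$sizes)),
    association = report$association,
    n_de = if (!is.null(report$de)) sum(report$de$de_flag,
                                        na.rm = TRUE) else 0,
    rf = lapply(report$rf, function(r)
      list(oob_error = r@oobError, auc = r@auc,
           sensitivity = r@sensitivity, specificity = r@specificity)))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' @export
print.AnalysisReport <- function(x, ...) {
  cat("AnalysisReport (seed", x$seed, ")\n")
  cat("  genes:", x$qc$genes_input, "->", x$qc$genes_filtered,
      "after filtering\n")
  cat("  phenotype:", x$phenotype$n_mho, "MHO /", x$phenotype$n_mao,
      "MAO\n")
  cat("  soft power:", x$network$power, "(fit",
      round(x$network$scale_free_fit, 3), ")\n")
  cat("  modules:", x$modules$n_modules, "; significant:",
      sum(x$association$significant), "\n")
  if (!is.null(x$de))
    cat("  DE genes:", sum(x$de$de_flag, na.rm = TRUE), "of",
        nrow(x$de), "tested\n")
  for (nm in names(x$rf))
    cat("  RF", nm, ": AUC", round(x$rf[[nm]]@auc, 3), "\n")
  invisible(x)
}
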