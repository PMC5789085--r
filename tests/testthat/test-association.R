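# Eigengenes, module membership, gene significance, module-trait
# association with the dual rule, and hypergeometric enrichment.

test_that("moduleEigengene summarises a module and reports variance explained", {
  set.seed(2)
  n <- 20
  shared <- rnorm(n)
  x <- rbind(g1 = shared * 2 + 5, g2 = shared * -3 + 1, g3 = shared + 2)
  colnames(x) <- paste0("s", 1:n)
  me <- moduleEigengene(x, c("g1", "g3"))  # same standardized profile
  expect_equal(me$variance_explained, 1)
  expect_equal(sd(me$eigengene), 1)
  expect_equal(abs(cor(me$eigengene, shared)), 1)
  # sign convention: non-negative correlation with mean expression
  xs <- t(scale(t(x[c("g1", "g3"), ])))
  expect_gte(cor(me$eigengene, colMeans(xs)), 0)

  # two uncorrelated genes split the variance evenly
  y <- rbind(a = rnorm(200), b = rnorm(200))
  expect_equal(moduleEigengene(y, c("a", "b"))$variance_explained, 0.5,
               tolerance = 0.1)
  expect_error(moduleEigengene(x, "g1"), "at least 2")
})

test_that("eigengene is invariant (up to sign) to gene order and duplication", {
  set.seed(7)
  x <- matrix(rnorm(8 * 15), 8, 15,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:15)))
  e1 <- moduleEigengene(x, paste0("g", 1:8))$eigengene
  e2 <- moduleEigengene(x, paste0("g", 8:1))$eigengene
  expect_equal(abs(cor(e1, e2)), 1, tolerance = 1e-10)
  xd <- rbind(x, g1b = x["g1", ])
  e3 <- moduleEigengene(xd, rownames(xd))$eigengene
  expect_gt(abs(cor(e1, e3)), 0.95)
})

test_that("eigengene of a planted module tracks the latent factor; hub MM is maximal", {
  se <- small_cohort()
  truth <- S4Vectors::metadata(se)$truth
  lc <- logCPM(SummarizedExperiment::assay(se))
  genes <- names(truth$module)[truth$module == 1]
  me <- moduleEigengene(lc, genes)
  expect_gte(abs(cor(me$eigengene, truth$factors[, 1])), 0.9)

  # planted-module genes have higher MM than background genes
  mm_mod <- sapply(genes[1:20], function(g)
    as.numeric(moduleMembership(lc[g, ], me$eigengene)))
  bg <- names(truth$module)[truth$module == 0][1:20]
  mm_bg <- sapply(bg, function(g)
    as.numeric(moduleMembership(lc[g, ], me$eigengene)))
  expect_gt(mean(mm_mod), mean(mm_bg) + 0.3)
})

test_that("moduleMembership and geneSignificance are absolute correlations", {
  set.seed(3)
  e <- rnorm(12)
  expect_equal(as.numeric(moduleMembership(e, e)), 1)
  expect_equal(as.numeric(moduleMembership(-2 * e + 1, e)), 1)
  expect_equal(attr(moduleMembership(-2 * e + 1, e), "signed"), -1)
  noise <- rnorm(1000); e2 <- rnorm(1000)
  expect_lt(as.numeric(moduleMembership(noise, e2)), 0.1)
  expect_error(moduleMembership(rep(1, 12), e), "variance")

  trait <- rep(c(0, 1), 6)
  expect_equal(as.numeric(geneSignificance(trait, trait)), 1)
  g <- c(2, 4, 1, 5, 3, 6)
  tr <- c(0, 1, 0, 1, 0, 1)
  expect_equal(as.numeric(geneSignificance(g, tr)), abs(cor(g, tr)))
  expect_error(geneSignificance(g, rep(1, 6)), "constant")
})

test_that("moduleTraitAssociation reduces to plain correlation without covariates", {
  set.seed(5)
  n <- 24
  me <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("ME", 1:3)))
  trait <- rbinom(n, 1, 0.4)
  res <- moduleTraitAssociation(me, trait)
  for (j in 1:3) {
    ct <- cor.test(me[, j], trait)
    expect_equal(res$cor[j], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(res$p[j], ct$p.value, tolerance = 1e-10)
  }
  expect_equal(res$q, p.adjust(res$p, "BH"))
})

test_that("covariate adjustment is a partial correlation with reduced df", {
  set.seed(6)
  n <- 30
  sex <- rbinom(n, 1, 0.5)
  trait <- rbinom(n, 1, 0.4)
  e <- trait * 0.8 + sex * 0.5 + rnorm(n)
  me <- cbind(ME1 = e)
  res <- moduleTraitAssociation(me, trait, covariates = cbind(sex = sex))
  # oracle: correlate lm residuals, t with n - 3 df
  r_or <- cor(resid(lm(e ~ sex)), resid(lm(trait ~ sex)))
  t_or <- r_or * sqrt((n - 3) / (1 - r_or^2))
  expect_equal(res$cor, r_or, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(abs(t_or), n - 3, lower.tail = FALSE),
               tolerance = 1e-10)
  # trait perfectly explained by the covariate is an error
  expect_error(
    moduleTraitAssociation(me, trait, covariates = cbind(tr = trait)),
    "collinear")
})

test_that("the dual rule needs both FDR and a positive MM-GS correlation", {
  set.seed(8)
  n <- 40
  trait <- rep(c(0, 1), each = n / 2)
  f <- trait * 1.5 + rnorm(n)                    # associated factor
  # member genes with graded loadings: hub genes track the trait more
  load <- seq(0.2, 1.4, length.out = 15)
  x <- t(sapply(load, function(l) l * f + rnorm(n, sd = 0.8)))
  rownames(x) <- paste0("g", 1:15)
  colnames(x) <- paste0("s", 1:n)
  lab <- setNames(rep(1L, 15), rownames(x))
  me <- moduleEigengenes(x, lab)
  res <- moduleTraitAssociation(me$eigengenes, trait, logcpm = x,
                                labels = lab)
  expect_true(res$significant)
  expect_gt(res$mm_gs_cor, 0)
  expect_lte(res$mm_gs_p, 0.05)

  # an eigengene equal to the trait: r = 1, q ~ 0
  me2 <- cbind(ME1 = as.numeric(scale(trait)))
  r2 <- moduleTraitAssociation(me2, trait)
  expect_equal(r2$cor, 1, tolerance = 1e-6)
  expect_lt(r2$p, 1e-20)
})

test_that("null modules pass the dual rule in at most 5% of seeds", {
  flagged <- 0L
  n_seeds <- 25
  for (seed in seq_len(n_seeds)) {
    set.seed(seed + 400)
    n <- 29
    trait <- rep(c(1, 0), c(8, 21))
    x <- matrix(rnorm(60 * n), 60, n,
                dimnames = list(paste0("g", 1:60), paste0("s", 1:n)))
    lab <- setNames(rep(1:3, each = 20), rownames(x))
    me <- moduleEigengenes(x, lab)
    res <- moduleTraitAssociation(me$eigengenes, trait, logcpm = x,
                                  labels = lab)
    if (any(res$significant)) flagged <- flagged + 1L
  }
  expect_lte(flagged / n_seeds, 0.05)
})

test_that("hypergeometric enrichment matches exact enumeration and Fisher", {
  universe <- paste0("u", 1:20)
  module <- universe[1:10]
  sets <- list(hit = universe[1:5], miss = universe[16:18])
  res <- hypergeometricEnrichment(module, sets, universe)
  # exact enumeration: P(X >= 5) with all 5 set genes in the module
  p_exact <- choose(5, 5) * choose(15, 5) / choose(20, 10)
  expect_equal(res$p[res$set == "hit"], p_exact, tolerance = 1e-12)
  expect_equal(res$q, p.adjust(res$p, "BH"))
  # module == set == universe is certain: p = 1
  r1 <- hypergeometricEnrichment(universe, list(all = universe), universe)
  expect_equal(r1$p, 1)
  # zero overlap with a tiny set: p near 1
  expect_gt(res$p[res$set == "miss"], 0.9)
  expect_error(hypergeometricEnrichment(module, sets, character()),
               "universe")
  expect_error(hypergeometricEnrichment(c(module, "zz"), sets, universe),
               "subset")
})

test_that("readGMT parses sets written in GMT format", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\turl\tg9"), f)
  sets <- readGMT(f)
  expect_equal(sets, list(setA = c("g1", "g2", "g3"), setB = "g9"))
})
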