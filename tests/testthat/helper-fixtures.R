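# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

.cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small cohort for unit tests: quick to generate, modules recoverable when
# the TOM is constructed directly from the truth.
small_cohort <- function() {
  .cached("small_cohort",
          generateCohort(cohortConfig(n_genes = 400,
                                      module_sizes = c(40, 40),
                                      seed = 101)))
}

# The default study-scale cohort (2,000 genes, 29 samples, 3 x 50-gene
# modules, seed 1) together with its normalized expression, network and
# module partition; shared by the acceptance checks that all start from
# the generator defaults.
default_analysis <- function() {
  .cached("default_analysis", {
    se <- generateCohort(cohortConfig(seed = 1))
    counts <- SummarizedExperiment::assay(se, "counts")
    clinical <- as.data.frame(SummarizedExperiment::colData(se))
    filtered <- filterLowExpression(counts)
    norm <- normalizeTMM(filtered)
    net <- buildNetwork(norm$logcpm)
    part <- mergeModules(clusterModules(net), norm$logcpm)
    list(se = se, counts = counts, clinical = clinical,
         filtered = filtered, norm = norm, net = net, part = part,
         truth = S4Vectors::metadata(se)$truth,
         trait = as.integer(clinical$group == "MHO"))
  })
}

# A clinical record passing every Definition 3 criterion (the healthy
# group's column means).
mho_record <- function(...) {
  rec <- list(sex = "M", bmi = 34, sbp = 120, dbp = 80,
              bp_medication = FALSE, glucose = 87, homa_ir = 1.99,
              tg = 49, hdl = 50, hscrp = 0.13)
  mod <- list(...)
  rec[names(mod)] <- mod
  rec
}

# Block-structured adjacency: `k` blocks of size `b` with within-block
# weight `w_in`, background weight `w_out`, unit diagonal.
block_adjacency <- function(k = 3, b = 15, n_noise = 30,
                            w_in = 0.6, w_out = 0.001) {
  n <- k * b + n_noise
  a <- matrix(w_out, n, n)
  for (i in seq_len(k)) {
    idx <- ((i - 1) * b + 1):(i * b)
    a[idx, idx] <- w_in
  }
  diag(a) <- 1
  rownames(a) <- colnames(a) <- sprintf("g%03d", seq_len(n))
  a
}

# Brute-force TOM by the definitional double loop.
tom_bruteforce <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- sum(a[i, -c(i, j)] * a[-c(i, j), j]) + a[i, j]
    out[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# AUC by exhaustive pairwise comparison (ties count one half).
auc_pairwise <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Benjamini-Hochberg by the definitional step-up computation.
bh_definitional <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
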