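# Network construction: similarity, soft adjacency, scale-free fit,
# threshold selection, TOM, UPGMA module detection and merging.

test_that("similarityMatrix is the gene-wise Pearson correlation", {
  set.seed(1)
  x <- matrix(rnorm(4 * 10), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  x[2, ] <- -x[1, ]
  s <- similarityMatrix(x)
  expect_equal(diag(s), setNames(rep(1, 4), rownames(x)))
  expect_equal(s[1, 2], -1)
  expect_equal(unname(s[3, 4]), cor(x[3, ], x[4, ]))
  expect_true(isSymmetric(s))
  x[1, ] <- 7
  expect_error(similarityMatrix(x), "zero-variance")
})

test_that("softAdjacency is |s|^beta, unsigned, monotone in beta", {
  s <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(softAdjacency(s, 6)[1, 2], 0.5^6)
  expect_equal(softAdjacency(matrix(1, 1, 1), 3)[1, 1], 1)
  sneg <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_equal(softAdjacency(sneg, 6)[1, 2], 0.5^6)
  expect_error(softAdjacency(s, 0.5), "beta")
  # monotone decreasing in beta for |s| < 1, invariant at 0 and 1
  set.seed(3)
  r <- matrix(runif(25, -0.99, 0.99), 5, 5)
  r <- (r + t(r)) / 2; diag(r) <- 1
  a2 <- softAdjacency(r, 2); a6 <- softAdjacency(r, 6)
  off <- row(r) != col(r)
  expect_true(all(a6[off] <= a2[off]))
  rz <- r; rz[1, 2] <- rz[2, 1] <- 0
  expect_equal(softAdjacency(rz, 2)[1, 2], softAdjacency(rz, 9)[1, 2])
})

test_that("adjacency and TOM stay symmetric in [0,1] on random similarities", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(5:15, 1)
    r <- matrix(runif(n * n, -1, 1), n, n)
    r <- (r + t(r)) / 2; diag(r) <- 1
    a <- softAdjacency(r, sample(1:8, 1))
    expect_true(isSymmetric(a))
    expect_true(all(a >= 0 & a <= 1))
    tm <- topologicalOverlap(a)
    expect_true(isSymmetric(tm))
    expect_true(all(tm >= 0 & tm <= 1 + 1e-12))
  }
})

test_that("scaleFreeFit is high for a power-law degree sequence and zero for constant degrees", {
  # fabricate connectivities following k^-2: rows with constant
  # off-diagonal weight k_i/(n-1) have rowSums exactly k_i
  ks <- rep(1:10, times = round(300 / (1:10)^2))
  n <- length(ks)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) a[i, -i] <- ks[i] / (n - 1)
  diag(a) <- 1
  fit <- scaleFreeFit(a)
  expect_gt(as.numeric(fit), 0.9)
  expect_lt(attr(fit, "slope"), 0)

  # constant degrees: fit undefined, returned as 0 with a warning
  const <- matrix(0.5, 12, 12); diag(const) <- 1
  expect_warning(f0 <- scaleFreeFit(const), "equal")
  expect_equal(as.numeric(f0), 0)

  # increasing degree-frequency relation: slope >= 0 forces fit 0
  ks_inc <- rep(1:10, times = (1:10)^2 * 2)
  n2 <- length(ks_inc)
  a2 <- matrix(0, n2, n2)
  for (i in seq_len(n2)) a2[i, -i] <- ks_inc[i] / (n2 - 1)
  diag(a2) <- 1
  expect_equal(as.numeric(scaleFreeFit(a2)), 0)
})

test_that("scaleFreeFit equals an independent binned regression oracle", {
  set.seed(8)
  x <- matrix(rnorm(60 * 12), 60, 12); rownames(x) <- paste0("g", 1:60)
  a <- softAdjacency(similarityMatrix(x), 4)
  fit <- scaleFreeFit(a, n_bins = 8)
  # oracle: same binning, lm() instead of lm.fit on manual sums
  k <- rowSums(a) - 1
  bin <- cut(k, seq(min(k), max(k), length.out = 9), include.lowest = TRUE)
  freq <- as.numeric(table(bin)) / length(k)
  km <- tapply(k, bin, mean)
  ok <- freq > 0 & !is.na(km)
  mod <- lm(log10(freq[ok]) ~ log10(km[ok]))
  expected <- if (coef(mod)[2] < 0) summary(mod)$r.squared else 0
  expect_equal(as.numeric(fit), expected, tolerance = 1e-10)
})

test_that("pickSoftThreshold returns the smallest passing power with the full curve", {
  # a similarity whose power-law structure already fits at beta = 1
  ks <- rep(1:10, times = round(300 / (1:10)^2))
  n <- length(ks)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) s[i, -i] <- ks[i] / (n - 1)
  diag(s) <- 1
  pick <- pickSoftThreshold(s, candidate_powers = 1:5)
  expect_equal(pick$power, 1)
  expect_gte(pick$fit, 0.8)
  expect_equal(nrow(pick$fit_curve), 5)

  # no candidate can pass on a constant-degree similarity: typed error
  # carrying the fit curve
  const <- matrix(0.5, 15, 15); diag(const) <- 1
  err <- tryCatch(suppressWarnings(pickSoftThreshold(const, 1:4)),
                  error = function(e) e)
  expect_s3_class(err, "softThresholdError")
  expect_equal(nrow(err$fit_curve), 4)
})

test_that("TOM matches hand-evaluated small cases and the brute-force double loop", {
  # two connected nodes, no other edges
  a2 <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(topologicalOverlap(a2)[1, 2], 1)
  # disconnected pair with no shared neighbours
  a0 <- diag(3)
  expect_equal(topologicalOverlap(a0)[1, 2], 0)
  # 3-node toy, all pairwise 0.5: TOM = (0.25 + 0.5)/(1 + 1 - 0.5)
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 1
  expect_equal(topologicalOverlap(a3)[1, 2], 0.5)

  set.seed(9)
  for (n in c(5, 12, 20)) {
    r <- matrix(runif(n * n), n, n); r <- (r + t(r)) / 2; diag(r) <- 1
    a <- softAdjacency(r, 3)
    expect_equal(topologicalOverlap(a), tom_bruteforce(a),
                 tolerance = 1e-10)
  }
  expect_error(topologicalOverlap(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("clusterModules recovers planted blocks and honours the size rule", {
  a <- block_adjacency(k = 3, b = 15, n_noise = 30)
  part <- clusterModules(topologicalOverlap(a), min_module_size = 10)
  expect_length(moduleSizes(part), 3)
  lab <- moduleLabels(part)
  truth <- rep(c(1, 2, 3, 0), c(15, 15, 15, 30))
  for (m in 1:3) {
    det <- lab[truth == m]
    expect_equal(length(unique(det)), 1L)   # block stays together
    expect_gt(unique(det), 0)
  }
  # noise genes are unassigned
  expect_true(all(lab[truth == 0] == 0))

  # a 9-gene block cannot form a module at min size 10
  a9 <- block_adjacency(k = 1, b = 9, n_noise = 30)
  expect_warning(p9 <- clusterModules(topologicalOverlap(a9),
                                      min_module_size = 10))
  expect_length(moduleSizes(p9), 0)
  expect_true(all(moduleLabels(p9) == 0))

  # identical duplicate genes are each other's closest neighbours: they
  # join at the first (lowest) merge of the dendrogram
  set.seed(10)
  x <- matrix(rnorm(6 * 8), 6, 8, dimnames = list(paste0("g", 1:6), NULL))
  x[2, ] <- x[1, ]
  tm <- topologicalOverlap(softAdjacency(similarityMatrix(x), 2))
  hc <- clusterModules(tm, min_module_size = 2)@dendrogram
  pair <- cutree(hc, k = nrow(x) - 1)
  expect_equal(pair[["g1"]], pair[["g2"]])
})

test_that("mergeModules joins correlated-factor modules and leaves orthogonal ones", {
  set.seed(14)
  n <- 30
  make_block <- function(f, g, sd = 0.4) t(sapply(seq_len(g), function(i)
    f + rnorm(n, sd = sd)))
  f1 <- rnorm(n)
  f_same <- f1                       # duplicate latent factor
  f_orth <- rnorm(n)                 # independent factor
  x <- rbind(make_block(f1, 12), make_block(f_same, 12),
             make_block(f_orth, 12))
  rownames(x) <- paste0("g", seq_len(nrow(x)))
  lab <- setNames(rep(1:3, each = 12), rownames(x))
  hc <- hclust(dist(seq_len(nrow(x))))  # placeholder dendrogram
  part <- new("ModuleSet", labels = lab, dendrogram = hc, cutHeight = 0.99,
              minModuleSize = 10,
              mergeHistory = data.frame(from = integer(), into = integer(),
                                        cor = numeric()))
  merged <- mergeModules(part, x, merge_cor = 0.75)
  ml <- moduleLabels(merged)
  expect_length(moduleSizes(merged), 2)
  expect_equal(unname(ml[1]), unname(ml[13]))   # same factor: merged
  expect_false(unname(ml[1] == ml[25]))         # orthogonal: kept apart
  expect_equal(nrow(merged@mergeHistory), 1)

  # correlated factors at r ~ 0.9 merge; at r ~ 0.3 they do not
  for (rho in c(0.9, 0.3)) {
    f2 <- rho * f1 + sqrt(1 - rho^2) * rnorm(n)
    x2 <- rbind(make_block(f1, 12, sd = 0.2), make_block(f2, 12, sd = 0.2))
    rownames(x2) <- paste0("h", seq_len(nrow(x2)))
    lab2 <- setNames(rep(1:2, each = 12), rownames(x2))
    p2 <- new("ModuleSet", labels = lab2, dendrogram = hc, cutHeight = 0.99,
              minModuleSize = 10,
              mergeHistory = data.frame(from = integer(), into = integer(),
                                        cor = numeric()))
    m2 <- mergeModules(p2, x2, merge_cor = 0.75)
    if (rho == 0.9) expect_length(moduleSizes(m2), 1)
    else expect_length(moduleSizes(m2), 2)
  }
})
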