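# Balanced random forest: training, OOB metrics, permutation importance,
# variable selection and driver ranking.

toy_features <- function(n = 24, p = 6, sep = FALSE, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  if (sep) x[, 1] <- y * 3 + rnorm(n, sd = 0.2)
  list(x = x, y = y)
}

test_that("a perfectly separating feature gives zero OOB error and AUC 1", {
  d <- toy_features(sep = TRUE)
  fit <- trainRFBalanced(d$x, d$y, rfConfig(ntree = 300, seed = 2))
  r <- oobReport(fit)
  expect_lte(r@oobError, 0.05)
  expect_gte(r@auc, 0.99)
  expect_gte(r@sensitivity, 0.9)
  expect_gte(r@specificity, 0.9)
})

test_that("labels independent of features give chance-level AUC", {
  d <- toy_features(n = 40, seed = 5)
  fit <- trainRFBalanced(d$x, d$y, rfConfig(ntree = 500, seed = 3))
  expect_gt(oobReport(fit)@auc, 0.25)
  expect_lt(oobReport(fit)@auc, 0.75)
})

test_that("fixed seeds give bit-identical forests, votes and importances", {
  d <- toy_features(sep = TRUE)
  cfg <- rfConfig(ntree = 200, nPerm = 200, seed = 11)
  f1 <- trainRFBalanced(d$x, d$y, cfg)
  f2 <- trainRFBalanced(d$x, d$y, cfg)
  expect_identical(oobReport(f1)@votes, oobReport(f2)@votes)
  expect_identical(f1@forest$inbag, f2@forest$inbag)
  expect_identical(permutationVIM(f1), permutationVIM(f2))
})

test_that("each tree's bootstrap draws the minority count from both classes", {
  n <- 29
  y <- rep(c("MHO", "MAO"), c(8, 21))
  set.seed(4)
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  fit <- trainRFBalanced(x, y, rfConfig(ntree = 100, seed = 6))
  inbag <- fit@forest$inbag
  per_class <- rowsum(inbag, y)
  expect_true(all(per_class["MHO", ] == 8))
  expect_true(all(per_class["MAO", ] == 8))
})

test_that("degenerate inputs are rejected", {
  d <- toy_features()
  expect_error(trainRFBalanced(d$x, rep(1, nrow(d$x)),
                               rfConfig(ntree = 50)), "single class")
  expect_error(trainRFBalanced(d$x[, 0], d$y, rfConfig(ntree = 50)),
               "features")
})

test_that("oobPerformance matches the exhaustive pairwise AUC oracle", {
  y <- c(rep("MHO", 5), rep("MAO", 7))
  votes <- y == "MHO"
  perfect <- oobPerformance(as.numeric(votes), y)
  expect_equal(perfect@auc, 1)
  expect_equal(perfect@sensitivity, 1)
  expect_equal(perfect@specificity, 1)
  expect_equal(perfect@oobError, 0)
  flat <- oobPerformance(rep(0.4, 12), y)
  expect_equal(flat@auc, 0.5)

  set.seed(8)
  for (i in 1:6) {
    n <- sample(6:12, 1)
    lab <- sample(c("MHO", "MAO"), n, replace = TRUE,
                  prob = c(0.4, 0.6))
    if (length(unique(lab)) < 2) next
    v <- round(runif(n), 1)      # coarse grid forces ties
    r <- oobPerformance(v, lab)
    expect_equal(r@auc, auc_pairwise(v, lab == "MHO"), tolerance = 1e-12)
  }
})

test_that("permutation VIM separates signal from noise", {
  d <- toy_features(n = 30, p = 5, sep = TRUE, seed = 9)
  fit <- trainRFBalanced(d$x, d$y, rfConfig(ntree = 400, seed = 10))
  vim <- permutationVIM(fit, nPerm = 800)
  expect_equal(names(which.max(vim)), "f1")
  expect_gt(vim["f1"], 0.1)
  # noise importances are negligible next to the informative feature
  expect_lt(max(abs(vim[-1])), vim["f1"] / 4)
  # under a null forest (labels independent of every feature) the VIM of
  # any feature stays within 2 Monte-Carlo SDs of zero
  dn <- toy_features(n = 30, p = 5, sep = FALSE, seed = 21)
  fit0 <- trainRFBalanced(dn$x, dn$y, rfConfig(ntree = 400, seed = 22))
  null_vims <- sapply(1:10, function(s)
    permutationVIM(fit0, nPerm = 400, seed = 100 + s)[["f3"]])
  expect_lte(abs(mean(null_vims)),
             2 * sd(null_vims) / sqrt(length(null_vims)) + 1e-8)
  # a constant feature has VIM 0 by definition
  xc <- cbind(d$x, const = 1)
  fitc <- trainRFBalanced(xc, d$y, rfConfig(ntree = 200, seed = 12))
  expect_equal(unname(permutationVIM(fitc)["const"]), 0)
})

test_that("permutation VIM equals manual per-tree OOB bookkeeping on a small forest", {
  d <- toy_features(n = 14, p = 3, sep = TRUE, seed = 13)
  cfg <- rfConfig(ntree = 25, nPerm = 25, seed = 14)
  fit <- trainRFBalanced(d$x, d$y, cfg)
  rf <- fit@forest
  lv <- levels(fit@labels)

  walk_tree <- function(tr, x) {
    node <- 1
    while (tr[node, "status"] != -1) {
      node <- if (x[tr[node, "split var"]] <= tr[node, "split point"])
        tr[node, "left daughter"] else tr[node, "right daughter"]
    }
    lv[tr[node, "prediction"]]
  }
  trees <- lapply(seq_len(rf$ntree), function(t)
    randomForest::getTree(rf, t))
  manual_err <- function(X) {
    vapply(seq_len(rf$ntree), function(t) {
      oob <- which(rf$inbag[, t] == 0)
      pred <- vapply(oob, function(i) walk_tree(trees[[t]], X[i, ]),
                     character(1))
      mean(pred != as.character(fit@labels)[oob])
    }, numeric(1))
  }
  err1 <- manual_err(d$x)
  # replicate the permutation stream, then the per-tree difference average
  set.seed(cfg$seed)
  expected <- setNames(numeric(3), colnames(d$x))
  for (k in 1:3) {
    Xp <- d$x
    Xp[, k] <- d$x[sample.int(nrow(d$x)), k]
    expected[k] <- mean(manual_err(Xp) - err1)
  }
  expect_equal(permutationVIM(fit), expected, tolerance = 1e-12)
})

test_that("variable selection keeps informative features and little noise", {
  set.seed(15)
  n <- 30
  y <- rep(c(0, 1), each = n / 2)
  inf <- sapply(1:3, function(i) y * 1.5 + rnorm(n, sd = 0.6))
  colnames(inf) <- paste0("inf", 1:3)
  noise <- matrix(rnorm(n * 20), n, 20,
                  dimnames = list(NULL, paste0("ns", 1:20)))
  vs <- selectVariables(cbind(inf, noise), y,
                        rfConfig(ntree = 300, nPerm = 300, seed = 16),
                        n_replicates = 10, eval_replicates = 3)
  expect_gte(sum(grepl("^inf", vs$interpretation_set)), 2)
  expect_lte(sum(grepl("^ns", vs$prediction_set)), 2)
  expect_true(all(vs$prediction_set %in% vs$interpretation_set))
  expect_true(all(vs$mean_vim[vs$interpretation_set] > 0))

  # a single informative feature yields a one-feature prediction set
  one <- cbind(inf = y * 2 + rnorm(n, sd = 0.4), noise[, 1:6])
  vs1 <- selectVariables(one, y,
                         rfConfig(ntree = 300, nPerm = 300, seed = 17),
                         n_replicates = 10, eval_replicates = 3)
  expect_identical(vs1$prediction_set, "inf")
})

test_that("driver ranking identifies the simulated driver and handles duplicates", {
  set.seed(18)
  n <- 29
  clin <- data.frame(hscrp = rlnorm(n, -1, 0.5),
                     tg_hdl = rlnorm(n, 0.5, 0.4),
                     glucose = rlnorm(n, 4.5, 0.1),
                     homa_ir = rlnorm(n, 1, 0.5))
  y <- as.integer(clin$tg_hdl > median(clin$tg_hdl))
  expr <- sapply(1:15, function(g)
    2 * log(clin$tg_hdl) + rnorm(n, sd = 0.3))
  colnames(expr) <- paste0("g", 1:15)
  dr <- rankMetabolicDrivers(expr, clin, y, rfConfig(ntree = 300, seed = 19))
  expect_gte(mean(dr$top_parameter == "tg_hdl"), 0.9)
  expect_gte(dr$single_auc[["tg_hdl"]], max(dr$single_auc) - 1e-12)

  # expression independent of all parameters: no dominant winner
  expr0 <- matrix(rnorm(n * 16), n, 16,
                  dimnames = list(NULL, paste0("h", 1:16)))
  dr0 <- rankMetabolicDrivers(expr0, clin, y,
                              rfConfig(ntree = 300, seed = 20))
  expect_lt(max(dr0$counts) / sum(dr0$counts), 0.7)

  # duplicated parameter is excluded with a warning; original unaffected
  clin2 <- cbind(clin, tg_hdl_copy = clin$tg_hdl)
  expect_warning(
    dr2 <- rankMetabolicDrivers(expr, clin2, y,
                                rfConfig(ntree = 300, seed = 19)),
    "excluded")
  expect_identical(dr2$top_parameter, dr$top_parameter)
})
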