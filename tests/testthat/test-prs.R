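test_that("SNP score evaluates the selection formula literally", {
  row <- data.frame(beta_g = 0.5, p = 0.01, beta_age = 0.02,
                    beta_sex = 0.7, intercept = -1.0, converged = TRUE)
  expect_equal(snp_score(row), (0.5 / 0.01) * 0.02 + 0.7 - 1.0)  # 0.7
  expect_equal(snp_score(row, parse = "magnitude"),
               (0.5 / 0.01) * (0.02 + 0.7 - 1.0))
  # beta_g = 0 collapses to the covariate terms
  row0 <- transform(row, beta_g = 0)
  expect_equal(snp_score(row0), 0.7 - 1.0)
  # unfit rows are never scored
  rowu <- transform(row, converged = FALSE)
  expect_true(is.na(snp_score(rowu)))
  # p floor guards the division
  rowz <- transform(row, p = 0)
  expect_true(is.finite(snp_score(rowz)))
})

test_that("score ranking matches an independent recomputation", {
  set.seed(29)
  rows <- data.frame(beta_g = rnorm(50), p = runif(50, 1e-10, 1),
                     beta_age = rnorm(50, 0, 0.05),
                     beta_sex = rnorm(50, 0.5, 0.2),
                     intercept = rnorm(50, -1, 0.3), converged = TRUE)
  s <- snp_score(rows)
  oracle <- rows$beta_g / pmax(rows$p, 1e-300) * rows$beta_age +
    rows$beta_sex + rows$intercept
  expect_equal(order(abs(s)), order(abs(oracle)))
  expect_equal(s, oracle)
})

test_that("stratified split honours the 10% / 80-20 arithmetic", {
  tab <- data.frame(anxiety = rep(c(TRUE, FALSE), c(140, 860)))
  cfg <- prs_config(seed = 5L)
  sp <- split_data(tab, cfg)
  expect_equal(length(sp$test), 100L, tolerance = 0)
  expect_true(abs(length(sp$validation) - 180L) <= 1)
  expect_true(abs(length(sp$train) - 720L) <= 1)
  # disjoint and exhaustive
  all_idx <- sort(c(sp$test, sp$train, sp$validation))
  expect_identical(all_idx, seq_len(1000L))
  # class balance within 2 points of the overall prevalence
  for (s in sp) expect_lt(abs(mean(tab$anxiety[s]) - 0.14), 0.02)
  # reproducible
  expect_identical(sp, split_data(tab, cfg))
  expect_false(identical(sp, split_data(tab, prs_config(seed = 6L))))
})

test_that("split errors on tiny or single-class strata", {
  expect_error(split_data(data.frame(anxiety = rep(TRUE, 20)),
                          prs_config()), "at least 30")
  expect_error(split_data(data.frame(anxiety = rep(TRUE, 100)),
                          prs_config()), "single class")
})

test_that("ridge at lambda = 0 equals ordinary least squares", {
  set.seed(31)
  X <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  y <- rnorm(200)
  fit <- fit_ridge(X, y, lam = 0)
  ref <- stats::lm(y ~ X)
  expect_equal(unname(fit$weights), unname(coef(ref)[-1]), tolerance = 1e-8)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-8)
})

test_that("ridge matches the hand-derived one-feature solution", {
  # x = (0,1,2), y = (0,1,2), lambda = 1; sd(x) = 1 so the standardized
  # slope is sum(z*yc)/(sum(z^2)+lambda) = 2/3, intercept 1 - 2/3*1 = 1/3
  fit <- fit_ridge(matrix(c(0, 1, 2), ncol = 1,
                          dimnames = list(NULL, "x")),
                   c(0, 1, 2), lam = 1)
  expect_equal(unname(fit$weights), 2 / 3, tolerance = 1e-12)
  expect_equal(fit$intercept, 1 / 3, tolerance = 1e-12)
})

test_that("ridge agrees with an augmented-QR oracle, primal and dual", {
  set.seed(37)
  for (dims in list(c(60, 10), c(30, 80))) {  # n > p and p > n
    X <- matrix(rnorm(dims[1] * dims[2]), dims[1], dims[2])
    colnames(X) <- paste0("f", seq_len(dims[2]))
    y <- rnorm(dims[1])
    for (lam in c(0.1, 1, 10)) {
      fit <- fit_ridge(X, y, lam)
      ora <- ridge_aug_oracle(X, y, lam)
      expect_equal(unname(fit$weights), ora$weights, tolerance = 1e-8)
      expect_equal(fit$intercept, ora$intercept, tolerance = 1e-8)
    }
  }
})

test_that("infinite penalty shrinks weights to zero, intercept to mean(y)", {
  set.seed(41)
  X <- matrix(rnorm(100 * 4), 100, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- rnorm(100, 2)
  fit <- fit_ridge(X, y, lam = 1e9)
  expect_lt(max(abs(fit$weights)), 1e-5)
  expect_equal(fit$intercept, mean(y), tolerance = 1e-3)
})

test_that("singular penalty-free system advises a positive lambda", {
  X <- matrix(rnorm(20), 10, 2)
  X <- cbind(X, X[, 1] + X[, 2])
  colnames(X) <- c("a", "b", "c")
  expect_error(fit_ridge(X, rnorm(10), lam = 0), "lambda > 0")
})

test_that("ROC AUC equals exhaustive pair counting, with and without ties", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  # 6-point tied set
  s <- c(1, 2, 2, 2, 3, 3); l <- c(0, 0, 1, 0, 1, 1)
  expect_equal(roc_auc(s, l), auc_pairs(s, l))
  set.seed(43)
  for (i in 1:30) {
    sc <- sample(1:5, 20, replace = TRUE)  # heavy ties
    lb <- rbinom(20, 1, 0.4)
    if (sum(lb) %in% c(0, 20)) next
    expect_identical(roc_auc(sc, lb), auc_pairs(sc, lb))
  }
  # null calibration
  sc <- rnorm(10000); lb <- rbinom(10000, 1, 0.5)
  expect_lt(abs(roc_auc(sc, lb) - 0.5), 0.02)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("ROC AUC matches the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(47)
  sc <- rnorm(300)
  lb <- rbinom(300, 1, plogis(sc))
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(sc, lb), ref, tolerance = 1e-12)
})

# Small PRS-ready cohort with strong causal signal, shared across tests.
prs_fixture <- function() {
  if (is.null(fixture_env$prs)) {
    sp <- simulation_spec(n_samples = 700L, n_variants = 400L,
                          n_populations = 2L, fst = 0.02,
                          n_causal = 10L, causal_effect_sd = 0.8,
                          maf_range = c(0.1, 0.5), missing_rate = 0.005,
                          seed = 211L)
    sim <- simulate_genotypes(sp)
    ph <- simulate_phenotypes(sim$genotypes, sim$truth, sp)
    ids <- select_pca_snps(sim$genotypes, maf_min = 0.05, n_snps = 300L,
                           seed = 1L)
    pcs <- compute_pcs(sim$genotypes, ids, k = 10L)
    fixture_env$prs <- list(spec = sp, G = sim$genotypes, truth = sim$truth,
                            table = ph, pcs = pcs)
  }
  fixture_env$prs
}

test_that("a single all-inclusive threshold reduces to one ridge fit", {
  fx <- prs_fixture()
  cfg <- prs_config(thresholds = -Inf, ridge_lambda = 5, seed = 13L)
  split <- split_data(fx$table, cfg)
  non_test <- sort(c(split$train, split$validation))
  Gnt <- genotype_matrix(fx$G$dosage[non_test, , drop = FALSE],
                         fx$G$variants, fx$G$samples[non_test])
  rows <- gwas_scan(Gnt, fx$table[non_test, ], fx$pcs$scores[non_test, ],
                    model = "binary")
  model <- train_prs(fx$G, fx$table, fx$pcs, rows, cfg, split = split)
  expect_equal(model$n_snps, sum(rows$converged))
  expect_equal(nrow(model$sweep), 1L)
  # identical to a direct ridge fit on the same features
  means <- colMeans(fx$G$dosage[split$train, , drop = FALSE], na.rm = TRUE)
  names(means) <- fx$G$variants$id
  Xtr <- prs_features(subset_samples_dosage(fx$G, split$train),
                      fx$table[split$train, ],
                      fx$pcs$scores[split$train, ], model$snp_ids, means)
  direct <- fit_ridge(Xtr, as.numeric(fx$table$anxiety[split$train]), 5)
  expect_equal(unname(model$snp_weights),
               unname(direct$weights[model$snp_ids]), tolerance = 1e-10)
})

test_that("the PRS pipeline beats the covariate baseline and never leaks", {
  fx <- prs_fixture()
  cfg <- prs_config(ridge_lambda = 10, seed = 17L)
  res <- run_prs_pipeline(fx$G, fx$table, fx$pcs, cfg)
  expect_equal(res$model$audit$test_in_fit, 0L)
  expect_gt(res$model$test_auc, 0.5)
  expect_gt(res$model$test_auc, res$baselines$test_auc_age_sex_pcs)
  # reproducibility: identical config gives an identical model
  res2 <- run_prs_pipeline(fx$G, fx$table, fx$pcs, cfg)
  expect_identical(res$model$snp_ids, res2$model$snp_ids)
  expect_equal(res$model$test_auc, res2$model$test_auc)
  expect_equal(res$model$selected_threshold, res2$model$selected_threshold)
})

test_that("covariate-only baselines behave at the null and with signal", {
  fx <- prs_fixture()
  cfg <- prs_config(ridge_lambda = 1, seed = 19L)
  base <- covariate_only_model(fx$table, fx$pcs, cfg)
  expect_gt(base$test_auc_age_sex, 0.4)  # sex/age carry modest signal
  # permuted labels: no covariate signal left
  tab0 <- fx$table
  set.seed(61)
  tab0$anxiety <- sample(tab0$anxiety)
  base0 <- covariate_only_model(tab0, fx$pcs, cfg)
  expect_gt(base0$test_auc_age_sex, 0.3)
  expect_lt(base0$test_auc_age_sex, 0.7)
})

test_that("thresholds selecting nothing are skipped or raised", {
  fx <- prs_fixture()
  cfg <- prs_config(thresholds = c(1e300), seed = 13L)
  split <- split_data(fx$table, cfg)
  non_test <- sort(c(split$train, split$validation))
  Gnt <- genotype_matrix(fx$G$dosage[non_test, , drop = FALSE],
                         fx$G$variants, fx$G$samples[non_test])
  rows <- gwas_scan(Gnt, fx$table[non_test, ], fx$pcs$scores[non_test, ],
                    model = "binary")
  expect_error(suppressWarnings(
    train_prs(fx$G, fx$table, fx$pcs, rows, cfg, split = split)),
    "0 SNPs")
})
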