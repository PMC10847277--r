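test_that("anxiety binarization uses the clinical cutoff of 11", {
  expect_true(binarize_hads(11L))
  expect_false(binarize_hads(10L))
  expect_false(binarize_hads(0L))
  expect_identical(binarize_hads(c(0L, 10L, 11L, 21L)),
                   c(FALSE, FALSE, TRUE, TRUE))
  expect_error(binarize_hads(22L), "\\[0, 21\\]")
  expect_error(binarize_hads(-1L), "\\[0, 21\\]")
})

test_that("crude sex odds ratios reproduce the cohort table values", {
  # women vs men: cases 3,258 / 1,000; controls 15,573 / 10,232
  women <- contingency_or(3258, 15573, 1000, 10232)
  expect_equal(round(women$or, 2), 2.14)
  expect_lt(women$p, 1e-80)
  men <- contingency_or(1000, 10232, 3258, 15573)
  expect_equal(round(men$or, 2), 0.47)
  expect_equal(women$or * men$or, 1, tolerance = 1e-12)  # reciprocal
})

test_that("balanced tables give OR 1 and CIs contain the estimate", {
  res <- contingency_or(10, 10, 10, 10)
  expect_equal(res$or, 1)
  expect_gte(res$or, res$ci95[1])
  expect_lte(res$or, res$ci95[2])
  expect_false(res$corrected)
})

test_that("crude OR equals exp(coef) of the unadjusted logistic fit", {
  set.seed(53)
  for (i in 1:10) {
    cells <- sample(5:60, 4)  # a, b, c, d
    res <- contingency_or(cells[1], cells[2], cells[3], cells[4])
    y <- rep(c(1, 0, 1, 0), cells)
    x <- rep(c(1, 1, 0, 0), cells)
    ref <- stats::glm(y ~ x, family = binomial())
    expect_equal(res$or, exp(unname(coef(ref)["x"])), tolerance = 1e-6)
  }
})

test_that("zero cells trigger the Haldane-Anscombe correction or an error", {
  res <- contingency_or(0, 10, 5, 10)
  expect_true(res$corrected)
  expect_gt(res$or, 0)
  expect_error(contingency_or(0, 0, 5, 10), "margin")   # zero row
  expect_error(contingency_or(0, 5, 0, 10), "margin")   # zero column
})

test_that("adjusted OR recovers a known effect and flags separation", {
  set.seed(59)
  hits <- 0L
  for (i in 1:10) {
    n <- 5000
    age <- runif(n, 18, 80); sex <- rbinom(n, 1, 0.6)
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1.5 + log(1.5) * x + 0.01 * age + 0.3 * sex))
    res <- adjusted_or(x, y, data.frame(age = age, sex = sex))
    se <- (log(res$ci_hi) - log(res$or)) / qnorm(0.975)
    if (abs(log(res$or) - log(1.5)) <= 3 * se) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
  # null coverage: the CI contains 1 most of the time
  cover <- 0L
  for (i in 1:40) {
    n <- 400
    age <- runif(n, 18, 80); sex <- rbinom(n, 1, 0.6)
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + 0.01 * age))
    res <- adjusted_or(x, y, data.frame(age = age, sex = sex))
    if (res$ci_lo <= 1 && res$ci_hi >= 1) cover <- cover + 1L
  }
  expect_gte(cover, 33L)  # ~95% nominal, 40 draws
  # a predictor identical to the outcome separates
  y <- rbinom(200, 1, 0.3)
  res <- adjusted_or(as.numeric(y), y,
                     data.frame(age = runif(200, 18, 80),
                                sex = rbinom(200, 1, 0.5)))
  expect_true(res$separation)
})

test_that("caffeine group counts substitutions over the full alphabet", {
  expect_equal(assign_caffeine_group("AA", "CC"), 0L)
  expect_equal(assign_caffeine_group("AC", "TT"), 2L)
  expect_equal(assign_caffeine_group("AA", "TT"), 1L)
  g1 <- c("AA", "AC", "CC"); g2 <- c("CC", "CT", "TT")
  grid <- expand.grid(a = g1, b = g2, stringsAsFactors = FALSE)
  got <- assign_caffeine_group(grid$a, grid$b)
  want <- (grid$a %in% c("AC", "CC")) + (grid$b == "TT")
  expect_identical(as.integer(got), as.integer(want))
  expect_error(assign_caffeine_group("AT", "CC"), "rs762551")
  expect_error(assign_caffeine_group("AA", "CA"), "rs5751876")
})

test_that("alcohol group counts substitutions over the full alphabet", {
  expect_equal(assign_alcohol_group("GG", "CC"), 0L)
  expect_equal(assign_alcohol_group("AG", "CT"), 2L)
  expect_equal(assign_alcohol_group("AA", "CC"), 1L)
  g1 <- c("GG", "AG", "AA"); g2 <- c("CC", "CT", "TT")
  grid <- expand.grid(a = g1, b = g2, stringsAsFactors = FALSE)
  got <- assign_alcohol_group(grid$a, grid$b)
  want <- (grid$a %in% c("AA", "AG")) + (grid$b %in% c("TT", "CT"))
  expect_identical(as.integer(got), as.integer(want))
  expect_error(assign_alcohol_group("GC", "CC"), "rs671")
})

test_that("group summaries flag a shifted group and skip singletons", {
  set.seed(67)
  scores <- c(rnorm(600, 6, 4), rnorm(300, 8, 4))   # group 2 shifted +2
  groups <- rep(c(1L, 2L), c(600, 300))
  gs <- group_summary(scores, groups)
  expect_equal(gs$n, c(600L, 300L))
  expect_lt(gs$p_vs_overall[2], 0.05)
  expect_equal(gs$mean[2], 8, tolerance = 0.5)
  # singleton group: SD absent, test skipped
  gs1 <- group_summary(c(scores, 5), c(groups, 3L))
  expect_true(is.na(gs1$sd[3]))
  expect_true(is.na(gs1$p_vs_overall[3]))
  expect_error(group_summary(scores, rep(1L, 900)), "2 groups")
})

test_that("null group comparisons give roughly uniform p-values", {
  # each group is a small share of the cohort so the group-vs-overall
  # overlap (the group contributes to the overall mean) is negligible
  set.seed(71)
  pv <- as.vector(replicate(4, {
    v <- rnorm(5000, 6, 4)
    g <- sample(1:50, 5000, replace = TRUE)
    group_summary(v, g)$p_vs_overall
  }))
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni_adjust(0.03), 0.03)
  expect_equal(bonferroni_adjust(c(0.9, rep(0.2, 4)))[1], 1.0)
  expect_error(bonferroni_adjust(c(0, 0.5)), "\\(0, 1\\]")
})

test_that("multivariate model recovers configured covariate effects", {
  boosted <- list(age_per_decade = -0.15, female = 0.62,
                  sleep_hours = -0.2, coffee_cups = 0.2,
                  alcohol_group = 0.4, smoking_current = 0,
                  caffeine_marker = 0, alcohol_marker = 0)
  sp <- simulation_spec(n_samples = 10000L, n_variants = 30L, n_causal = 0L,
                        covariate_effects = boosted, seed = 223L)
  sim <- simulate_genotypes(sp)
  ph <- simulate_phenotypes(sim$genotypes, sim$truth, sp)
  fit <- multivariate_model(ph)
  co <- fit$coefficients
  for (term in c("age", "sex", "coffee_cups", "sleep_hours")) {
    ci <- co[co$term == term, ]
    expect_true(ci$ci_lo > 1 || ci$ci_hi < 1)
  }
  expect_gt(fit$auc, 0.6)
  # direction checks
  expect_gt(co$or[co$term == "sex"], 1)
  expect_lt(co$or[co$term == "sleep_hours"], 1)
  expect_gt(co$or[co$term == "coffee_cups"], 1)
})

test_that("multivariate model is null on permuted or effect-free cohorts", {
  # in-sample AUC carries a small optimism from ~10 fitted parameters, so
  # the null checks allow a margin above 0.5 that shrinks with n
  zero <- list(age_per_decade = 0, female = 0, sleep_hours = 0,
               coffee_cups = 0, alcohol_group = 0, smoking_current = 0,
               caffeine_marker = 0, alcohol_marker = 0)
  sp <- simulation_spec(n_samples = 10000L, n_variants = 20L, n_causal = 0L,
                        covariate_effects = zero, seed = 227L)
  sim <- simulate_genotypes(sp)
  ph <- simulate_phenotypes(sim$genotypes, sim$truth, sp)
  fit0 <- multivariate_model(ph)
  expect_lt(fit0$auc, 0.56)
  # permuting the outcome of the same cohort destroys any residual signal
  set.seed(73)
  ord <- sample(nrow(ph))
  ph$hads_a <- ph$hads_a[ord]
  ph$anxiety <- ph$anxiety[ord]
  fitp <- multivariate_model(ph)
  expect_lt(fitp$auc, 0.56)
})

test_that("cohort prevalence from the generator matches binarize_hads", {
  fx <- small_cohort()
  expect_identical(binarize_hads(fx$table$hads_a), fx$table$anxiety)
})
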