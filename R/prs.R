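# Polygenic risk score: per-SNP summary-statistic score, threshold sweep,
# ridge regression with covariates, nested train/validation selection and
# held-out test evaluation.

#' PRS configuration
#'
#' @param test_fraction fraction of the cohort carved out first as the
#'   held-out test set (default 0.10); these samples never touch the GWAS,
#'   the SNP scoring, or model fitting.
#' @param validation_fraction fraction of the remainder held out for
#'   threshold selection (default 0.20, i.e. an 80/20 train/validation
#'   split of the non-test data).
#' @param thresholds explicit score cutoffs, or `NULL` to sweep score
#'   quantiles at 20 geometrically spaced selected-set sizes, from all
#'   scored SNPs down to one (a deterministic stand-in for randomly probed
#'   thresholds that covers every sparsity scale).
#' @param ridge_lambda ridge penalty applied to all coefficients except the
#'   intercept, on internally standardized features. Not tuned inside the
#'   threshold sweep.
#' @param score_parse how the per-SNP score formula is read: `"literal"`
#'   (default) for `(beta_SNP / p) * beta_age + beta_sex + intercept`, or
#'   `"magnitude"` for `(beta_SNP / p) * (beta_age + beta_sex + intercept)`.
#' @param seed RNG seed for the splits.
#' @return object of class `prs_config`.
#' @export
prs_config <- function(test_fraction = 0.10, validation_fraction = 0.20,
                       thresholds = NULL, ridge_lambda = 1.0,
                       score_parse = c("literal", "magnitude"), seed = 1L) {
  stopifnot_scalar_number(test_fraction, "test_fraction", 1e-9, 1 - 1e-9)
  stopifnot_scalar_number(validation_fraction, "validation_fraction",
                          1e-9, 1 - 1e-9)
  stopifnot_scalar_number(ridge_lambda, "ridge_lambda", 0)
  structure(list(test_fraction = test_fraction,
                 validation_fraction = validation_fraction,
                 thresholds = thresholds,
                 ridge_lambda = ridge_lambda,
                 score_parse = match.arg(score_parse),
                 seed = as.integer(seed)),
            class = "prs_config")
}

#' Per-SNP selection score from GWAS summary statistics
#'
#' Combines each variant's association fit into a single selection score
#' used to rank SNPs for the risk model. The default `"literal"` parse is
#' `(beta_SNP / p) * beta_age + beta_sex + intercept`; the `"magnitude"`
#' parse multiplies `(beta_SNP / p)` by the sum of the covariate terms.
#' P-values are floored at 1e-300 to guard the division; rows flagged unfit
#' get `NA` and are never selected.
#'
#' @param rows summary-statistics `data.frame` (needs `beta_g`, `p`,
#'   `beta_age`, `beta_sex`, `intercept`, `converged`).
#' @param parse `"literal"` or `"magnitude"`.
#' @param p_floor lower bound applied to p-values before division.
#' @return numeric score vector aligned with `rows`.
#' @export
snp_score <- function(rows, parse = c("literal", "magnitude"),
                      p_floor = 1e-300) {
  parse <- match.arg(parse)
  p <- pmax(rows$p, p_floor)
  ratio <- rows$beta_g / p
  s <- if (parse == "literal") {
    ratio * rows$beta_age + rows$beta_sex + rows$intercept
  } else {
    ratio * (rows$beta_age + rows$beta_sex + rows$intercept)
  }
  s[!rows$converged | is.na(rows$p)] <- NA_real_
  s
}

#' Stratified test/train/validation split
#'
#' Carves out the test set first (stratified by the binary anxiety label),
#' then splits the remainder 80/20 into training and validation sets,
#' again stratified. The three index sets are disjoint and exhaustive and
#' reproducible from the config seed.
#'
#' @param table cohort `data.frame` with an `anxiety` column.
#' @param config a [prs_config()].
#' @return list of integer index vectors: `test`, `train`, `validation`.
#' @export
split_data <- function(table, config = prs_config()) {
  n <- nrow(table)
  if (n < 30L) stop("need at least 30 samples to split", call. = FALSE)
  lab <- as.logical(table$anxiety)
  if (anyNA(lab)) stop("anxiety label contains NA", call. = FALSE)
  with_seed(derive_seed(config$seed, 101L), {
    test <- integer(0)
    for (cls in unique(lab)) {
      idx <- which(lab == cls)
      k <- round(config$test_fraction * length(idx))
      test <- c(test, sample(idx, k))
    }
    rest <- setdiff(seq_len(n), test)
    validation <- integer(0)
    for (cls in unique(lab)) {
      idx <- rest[lab[rest] == cls]
      k <- round(config$validation_fraction * length(idx))
      validation <- c(validation, sample(idx, k))
    }
    train <- setdiff(rest, validation)
    out <- list(test = sort(test), train = sort(train),
                validation = sort(validation))
    for (nm in names(out)) {
      s <- out[[nm]]
      if (length(s) < 2L || length(unique(lab[s])) < 2L) {
        stop(nm, " split has fewer than 2 samples or a single class",
             call. = FALSE)
      }
    }
    out
  })
}

#' Ridge regression, closed form
#'
#' Solves the penalized least-squares objective
#' `sum_i (y_i - yhat_i)^2 + lambda * sum_j beta_j^2`
#' with an unpenalized intercept: features are standardized internally
#' (zero-variance columns get a zero coefficient), the penalized
#' coefficients solve `(Z'Z + lambda I) b = Z'(y - ybar)` (or its dual
#' `b = Z'(ZZ' + lambda I)^{-1}(y - ybar)` when features outnumber
#' samples), and weights are mapped back to the original feature scale.
#' At `lambda = 0` on a full-rank design this reduces to ordinary least
#' squares; as `lambda -> Inf` all penalized weights vanish and the
#' intercept tends to `mean(y)`.
#'
#' @param X numeric feature matrix (no missing entries; impute upstream).
#' @param y numeric response (binary labels as 0/1 for the risk model).
#' @param lam penalty `lambda >= 0`.
#' @return list: `weights` (original scale, named), `intercept`.
#' @export
fit_ridge <- function(X, y, lam = 1.0) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("fit_ridge requires complete data",
                                 call. = FALSE)
  stopifnot_scalar_number(lam, "lam", 0)
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  zero_var <- !is.finite(scl) | scl == 0
  scl[zero_var] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Z[, zero_var] <- 0
  yc <- y - mean(y)
  solve_or_fail <- function(A, b) {
    tryCatch(solve(A, b), error = function(e) {
      stop("ridge system is singular at lambda = ", lam,
           "; use lambda > 0", call. = FALSE)
    })
  }
  b <- if (p <= n) {
    drop(solve_or_fail(crossprod(Z) + diag(lam, p), crossprod(Z, yc)))
  } else {
    alpha <- solve_or_fail(tcrossprod(Z) + diag(lam, n), yc)
    drop(crossprod(Z, alpha))
  }
  w <- b / scl
  w[zero_var] <- 0
  names(w) <- colnames(X)
  list(weights = w, intercept = mean(y) - sum(w * ctr))
}

ridge_predict <- function(fit, X) {
  drop(as.matrix(X) %*% fit$weights) + fit$intercept
}

#' ROC AUC (midrank Mann-Whitney statistic)
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, counting ties as 1/2: the normalized rank-sum statistic.
#'
#' @param risk_scores numeric predictions.
#' @param labels binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(risk_scores, labels) {
  lab <- as.logical(labels)
  if (anyNA(lab) || anyNA(risk_scores)) {
    stop("roc_auc requires complete scores and labels", call. = FALSE)
  }
  np <- sum(lab); nn <- sum(!lab)
  if (np == 0L || nn == 0L) {
    stop("both classes must be present to compute ROC AUC", call. = FALSE)
  }
  r <- rank(risk_scores)  # midranks
  (sum(r[lab]) - np * (np + 1) / 2) / (np * nn)
}

# Feature matrix: selected SNP dosages (imputed with supplied column means)
# + age + sex + PCs.
prs_features <- function(G, table, pcs, snp_ids, impute_means) {
  parts <- list()
  if (length(snp_ids)) {
    D <- G$dosage[, match(snp_ids, G$variants$id), drop = FALSE]
    D <- mean_impute(D, impute_means[snp_ids])
    D[is.na(D)] <- 0  # SNPs with no observed training calls
    parts$snps <- D
  }
  covs <- cbind(age = table$age, sex = table$sex)
  if (!is.null(pcs)) {
    sc <- if (inherits(pcs, "pc_result")) pcs$scores else as.matrix(pcs)
    covs <- cbind(covs, sc)
  }
  do.call(cbind, c(parts, list(covs)))
}

#' Train the polygenic risk score model
#'
#' For each candidate threshold: select the SNPs whose selection score
#' ([snp_score()]) is at or above the threshold, assemble features
#' (selected dosages + age + sex + PCs), fit the ridge model on the
#' training set, and evaluate ROC AUC on the validation set. The model
#' with the highest validation AUC wins (ties broken toward fewer SNPs)
#' and is finally evaluated once on the held-out test set.
#'
#' Leakage guard: `summary_rows` must come from a GWAS run on the training
#' samples only -- test rows must never touch it, and including validation
#' rows biases the threshold selection. The split is carved out before any
#' fitting and the returned `audit` records that test indices never
#' intersect the fitting indices. [run_prs_pipeline()] wires this up
#' correctly end to end.
#'
#' @param G a QC-passed [genotype_matrix()].
#' @param table cohort `data.frame`.
#' @param pcs PC scores for all samples ([compute_pcs()] result or matrix).
#' @param summary_rows GWAS summary statistics computed on non-test samples.
#' @param config a [prs_config()].
#' @param split optional precomputed [split_data()] result (it is computed
#'   from the config seed otherwise).
#' @return object of class `prs_model`: selected threshold, SNP ids and
#'   weights, covariate weights, intercept, penalty, validation and test
#'   AUC, `n_snps`, the sweep table, and an `audit` list.
#' @export
train_prs <- function(G, table, pcs, summary_rows, config = prs_config(),
                      split = NULL) {
  if (is.null(split)) split <- split_data(table, config)
  scores <- snp_score(summary_rows, config$score_parse)
  usable <- !is.na(scores)
  if (!any(usable)) stop("no usable SNP scores", call. = FALSE)
  thresholds <- config$thresholds
  if (is.null(thresholds)) {
    # quantiles at 20 geometrically spaced selected-set sizes, from all
    # SNPs down to a single SNP: the useful models sit in the extreme
    # upper tail of the score distribution, which an evenly spaced
    # quantile grid cannot reach
    m_usable <- sum(usable)
    sizes <- unique(pmax(1L, round(m_usable * exp(
      seq(0, log(1 / m_usable), length.out = 20)))))
    thresholds <- unname(quantile(scores[usable],
                                  probs = 1 - sizes / m_usable))
  }
  train_means <- col_means_na(
    G$dosage[split$train, , drop = FALSE])
  names(train_means) <- G$variants$id
  lab <- as.logical(table$anxiety)

  sweep_tab <- data.frame(threshold = numeric(0), n_snps = integer(0),
                          validation_auc = numeric(0))
  best <- NULL
  for (th in thresholds) {
    sel <- summary_rows$id[usable & scores >= th]
    if (!length(sel)) {
      warning("threshold ", signif(th, 4), " selects 0 SNPs; skipped")
      next
    }
    Xtr <- prs_features(subset_samples_dosage(G, split$train),
                        table[split$train, ], pcs_rows(pcs, split$train),
                        sel, train_means)
    fit <- fit_ridge(Xtr, as.numeric(lab[split$train]), config$ridge_lambda)
    Xva <- prs_features(subset_samples_dosage(G, split$validation),
                        table[split$validation, ],
                        pcs_rows(pcs, split$validation), sel, train_means)
    va <- roc_auc(ridge_predict(fit, Xva), lab[split$validation])
    sweep_tab <- rbind(sweep_tab,
                       data.frame(threshold = th, n_snps = length(sel),
                                  validation_auc = va))
    if (is.null(best) || va > best$validation_auc ||
        (va == best$validation_auc && length(sel) < best$n_snps)) {
      best <- list(threshold = th, snp_ids = sel, fit = fit,
                   validation_auc = va, n_snps = length(sel))
    }
  }
  if (is.null(best)) {
    stop("every threshold selected 0 SNPs; nothing to fit", call. = FALSE)
  }
  Xte <- prs_features(subset_samples_dosage(G, split$test),
                      table[split$test, ], pcs_rows(pcs, split$test),
                      best$snp_ids, train_means)
  test_auc <- roc_auc(ridge_predict(best$fit, Xte), lab[split$test])
  w <- best$fit$weights
  is_snp <- names(w) %in% best$snp_ids
  structure(
    list(selected_threshold = best$threshold,
         snp_ids = best$snp_ids,
         snp_weights = w[is_snp],
         covariate_weights = w[!is_snp],
         intercept = best$fit$intercept,
         ridge_lambda = config$ridge_lambda,
         validation_auc = best$validation_auc,
         test_auc = test_auc,
         n_snps = best$n_snps,
         sweep = sweep_tab,
         split = split,
         train_means = train_means,
         audit = list(
           n_test = length(split$test),
           test_in_fit = length(intersect(split$test,
                                          c(split$train, split$validation))),
           score_parse = config$score_parse)),
    class = "prs_model"
  )
}

subset_samples_dosage <- function(G, rows) {
  list(dosage = G$dosage[rows, , drop = FALSE], variants = G$variants,
       samples = G$samples[rows])
}

pcs_rows <- function(pcs, rows) {
  if (is.null(pcs)) return(NULL)
  sc <- if (inherits(pcs, "pc_result")) pcs$scores else as.matrix(pcs)
  sc[rows, , drop = FALSE]
}

#' @export
print.prs_model <- function(x, ...) {
  cat("prs_model:", x$n_snps, "SNPs at score threshold",
      signif(x$selected_threshold, 4), "\n")
  cat(sprintf("  ridge lambda:    %g\n", x$ridge_lambda))
  cat(sprintf("  validation AUC:  %.4f\n", x$validation_auc))
  cat(sprintf("  test AUC:        %.4f\n", x$test_auc))
  invisible(x)
}

#' Covariate-only baseline models
#'
#' Fits the same ridge machinery on (age, sex) alone and on (age, sex,
#' PC1..k), using the same split, and reports the held-out test AUC of
#' both -- the baselines a genotype-based risk model must beat.
#'
#' @inheritParams train_prs
#' @return list: `test_auc_age_sex`, `test_auc_age_sex_pcs`,
#'   `validation_auc_age_sex`, `validation_auc_age_sex_pcs`.
#' @export
covariate_only_model <- function(table, pcs, config = prs_config(),
                                 split = NULL) {
  if (is.null(split)) split <- split_data(table, config)
  lab <- as.logical(table$anxiety)
  one <- function(with_pcs) {
    feat <- function(rows) {
      covs <- cbind(age = table$age[rows], sex = table$sex[rows])
      if (with_pcs) covs <- cbind(covs, pcs_rows(pcs, rows))
      covs
    }
    fit <- fit_ridge(feat(split$train), as.numeric(lab[split$train]),
                     config$ridge_lambda)
    list(validation = roc_auc(ridge_predict(fit, feat(split$validation)),
                              lab[split$validation]),
         test = roc_auc(ridge_predict(fit, feat(split$test)),
                        lab[split$test]))
  }
  a <- one(FALSE)
  b <- if (!is.null(pcs)) one(TRUE) else a
  list(test_auc_age_sex = a$test,
       test_auc_age_sex_pcs = b$test,
       validation_auc_age_sex = a$validation,
       validation_auc_age_sex_pcs = b$validation)
}

#' End-to-end PRS pipeline with leakage control
#'
#' Carves out the held-out test set first, runs the GWAS scan and SNP
#' scoring on the remaining samples only, then trains and selects the
#' ridge model via [train_prs()] and evaluates it once on the test set.
#'
#' @param G a QC-passed [genotype_matrix()].
#' @param table cohort `data.frame`.
#' @param pcs PC scores for all samples (or `NULL`).
#' @param config a [prs_config()].
#' @param model association model used for scoring (`"binary"` default).
#' @param workers parallel workers for the scan.
#' @return list: `model` (the [train_prs()] result), `baselines`
#'   (the [covariate_only_model()] result), `summary_rows`, `split`.
#' @export
run_prs_pipeline <- function(G, table, pcs = NULL, config = prs_config(),
                             model = "binary", workers = 1L) {
  split <- split_data(table, config)
  # GWAS and SNP scoring on the training split only: validation labels must
  # not inform the score ranking, or the threshold selection overfits them
  Gtr <- genotype_matrix(G$dosage[split$train, , drop = FALSE], G$variants,
                         G$samples[split$train])
  rows <- gwas_scan(Gtr, table[split$train, , drop = FALSE],
                    pcs_rows(pcs, split$train), model = model,
                    workers = workers)
  fit <- train_prs(G, table, pcs, rows, config, split = split)
  base <- covariate_only_model(table, pcs, config, split = split)
  list(model = fit, baselines = base, summary_rows = rows, split = split)
}
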