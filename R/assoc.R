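# Per-variant genome-wide association scans: logistic regression for the
# binary anxiety label, ordinary least squares for the continuous score.
# Covariates (age, sex, leading principal components) are adjusted in every
# model; missing dosages are handled complete-case per variant.

unfit_row <- function(meta, model, n) {
  data.frame(id = meta$id, chrom = meta$chrom, pos = meta$pos,
             ref = meta$ref, alt = meta$alt, model = model,
             beta_g = NA_real_, se = NA_real_, p = NA_real_,
             n = as.integer(n), beta_age = NA_real_, beta_sex = NA_real_,
             intercept = NA_real_, converged = FALSE,
             stringsAsFactors = FALSE)
}

assemble_row <- function(meta, model, n, est, se, p, cov_names) {
  data.frame(id = meta$id, chrom = meta$chrom, pos = meta$pos,
             ref = meta$ref, alt = meta$alt, model = model,
             beta_g = est[["g"]], se = se, p = p, n = as.integer(n),
             beta_age = if ("age" %in% cov_names) est[["age"]] else NA_real_,
             beta_sex = if ("sex" %in% cov_names) est[["sex"]] else NA_real_,
             intercept = est[["(Intercept)"]], converged = TRUE,
             stringsAsFactors = FALSE)
}

default_meta <- data.frame(id = "variant", chrom = ".", pos = 1L,
                           ref = ".", alt = ".", stringsAsFactors = FALSE)

#' Logistic association fit for one variant
#'
#' Maximum-likelihood logistic regression of a binary outcome on ALT-allele
#' dosage plus covariates, fitted by iteratively reweighted least squares
#' (tolerance 1e-8, at most 100 iterations). Reports the two-sided Wald
#' p-value for the dosage coefficient together with the fitted age and sex
#' coefficients and the intercept (consumed downstream by the per-SNP
#' score). Samples with a missing dosage or covariate are dropped for this
#' variant only. Non-convergence, (quasi-)separation or a rank-deficient
#' design yields a row flagged unfit (`converged = FALSE`, p absent)
#' rather than an error.
#'
#' @param dosage numeric dosage vector (`NA` = missing).
#' @param y binary outcome (0/1 or logical).
#' @param covars numeric matrix of covariates with named columns (columns
#'   named `age` and `sex` are copied into the output row).
#' @param meta one-row data.frame of variant metadata (id, chrom, pos, ref,
#'   alt); a placeholder is used if omitted.
#' @return One summary-statistics row (`data.frame`).
#' @export
fit_variant_binary <- function(dosage, y, covars = NULL, meta = default_meta) {
  y <- as.numeric(y)
  X <- cbind(`(Intercept)` = 1, covars, g = dosage)
  ok <- complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  yy <- y[ok]
  n <- length(yy)
  if (n == 0L || length(unique(yy)) < 2L || var(X[, "g"]) == 0) {
    return(unfit_row(meta, "binary", n))
  }
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, yy, family = binomial(),
                             control = glm.control(epsilon = 1e-8,
                                                   maxit = 100))),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || fit$rank < ncol(X)) {
    return(unfit_row(meta, "binary", n))
  }
  covmat <- wald_cov(fit$qr, fit$rank)
  if (is.null(covmat)) return(unfit_row(meta, "binary", n))
  est <- fit$coefficients
  se_g <- sqrt(covmat[["g"]])
  # separation guard: fitted probabilities collapsing to 0/1 or an absurd SE
  mu <- fit$fitted.values
  if (!is.finite(se_g) || se_g > 50 || abs(est[["g"]]) > 30 ||
      all(mu < 1e-8 | mu > 1 - 1e-8)) {
    return(unfit_row(meta, "binary", n))
  }
  z <- est[["g"]] / se_g
  p <- 2 * pnorm(-abs(z))
  if (p == 0) p <- .Machine$double.xmin  # keep p in (0, 1]
  assemble_row(meta, "binary", n, est, se_g, p, colnames(covars))
}

# Diagonal of the (dispersion-1) coefficient covariance from a glm.fit QR.
wald_cov <- function(qr_obj, rank) {
  R <- qr_obj$qr[seq_len(rank), seq_len(rank), drop = FALSE]
  R[lower.tri(R)] <- 0
  cov <- tryCatch(chol2inv(R), error = function(e) NULL)
  if (is.null(cov)) return(NULL)
  d <- diag(cov)
  names(d) <- colnames(qr_obj$qr)[qr_obj$pivot[seq_len(rank)]]
  d
}

#' Linear association fit for one variant
#'
#' Ordinary least squares of a continuous score (e.g. the 0-21 anxiety
#' score) on ALT-allele dosage plus covariates, with a two-sided t-test on
#' the dosage coefficient. Requires at least 3 residual degrees of freedom;
#' rank deficiency (e.g. constant dosage or duplicated covariates) yields
#' an unfit row.
#'
#' @inheritParams fit_variant_binary
#' @param score numeric outcome vector.
#' @return One summary-statistics row (`data.frame`).
#' @export
fit_variant_linear <- function(dosage, score, covars = NULL,
                               meta = default_meta) {
  X <- cbind(`(Intercept)` = 1, covars, g = dosage)
  ok <- complete.cases(X) & !is.na(score)
  X <- X[ok, , drop = FALSE]
  yy <- score[ok]
  n <- length(yy)
  df_res <- n - ncol(X)
  if (df_res < 3L || var(X[, "g"]) == 0) {
    return(unfit_row(meta, "continuous", n))
  }
  fit <- lm.fit(X, yy)
  if (fit$rank < ncol(X)) return(unfit_row(meta, "continuous", n))
  sigma2 <- sum(fit$residuals^2) / df_res
  covd <- wald_cov(fit$qr, fit$rank)
  if (is.null(covd)) return(unfit_row(meta, "continuous", n))
  est <- fit$coefficients
  se_g <- sqrt(sigma2 * covd[["g"]])
  tval <- est[["g"]] / se_g
  p <- 2 * pt(-abs(tval), df = df_res)
  if (p == 0) p <- .Machine$double.xmin  # keep p in (0, 1]
  assemble_row(meta, "continuous", n, est, se_g, p, colnames(covars))
}

#' Genome-wide association scan
#'
#' Applies the per-variant logistic (binary label) or linear (continuous
#' score) fit across all variants of a QC-passed genotype matrix, adjusting
#' for age, sex and the leading principal components. Output row order
#' follows the variant order and is identical for any worker count.
#'
#' @param G a QC-passed [genotype_matrix()].
#' @param table cohort `data.frame` with `age`, `sex` and the outcome.
#' @param pcs a [compute_pcs()] result, or a numeric score matrix, or
#'   `NULL` for no structure adjustment.
#' @param model `"binary"` (outcome `anxiety`) or `"continuous"` (outcome
#'   `hads_a`).
#' @param outcome optional outcome vector overriding the table column.
#' @param workers number of parallel workers (forked; results identical to
#'   the sequential scan).
#' @return summary-statistics `data.frame`, one row per variant.
#' @export
gwas_scan <- function(G, table, pcs = NULL,
                      model = c("binary", "continuous"),
                      outcome = NULL, workers = 1L) {
  model <- match.arg(model)
  if (nrow(table) != length(G$samples)) {
    stop("cohort table and genotype matrix sample counts differ",
         call. = FALSE)
  }
  covars <- cbind(age = table$age, sex = table$sex)
  if (!is.null(pcs)) {
    sc <- if (inherits(pcs, "pc_result")) pcs$scores else as.matrix(pcs)
    if (nrow(sc) != nrow(table)) {
      stop("PC scores do not match the cohort table", call. = FALSE)
    }
    covars <- cbind(covars, sc)
  }
  if (is.null(outcome)) {
    outcome <- if (model == "binary") table$anxiety else table$hads_a
  }
  fit_fun <- if (model == "binary") fit_variant_binary else fit_variant_linear
  one <- function(j) {
    fit_fun(G$dosage[, j], outcome, covars, G$variants[j, ])
  }
  idx <- seq_len(nrow(G$variants))
  rows <- if (workers > 1L) {
    parallel::mclapply(idx, one, mc.cores = workers)
  } else {
    lapply(idx, one)
  }
  do.call(rbind, rows)
}

#' Genome-wide significant variants
#'
#' Subset of fitted rows with `p` strictly below the genome-wide threshold
#' (default 5e-8; a p-value exactly at the threshold is excluded).
#'
#' @param rows summary-statistics `data.frame`.
#' @param alpha_gw significance threshold.
#' @return The significant subset, in input order.
#' @export
call_significant <- function(rows, alpha_gw = 5e-8) {
  if (!nrow(rows)) return(rows)
  rows[!is.na(rows$p) & rows$p < alpha_gw, , drop = FALSE]
}

#' Genomic inflation factor
#'
#' Median of the 1-df chi-square statistics implied by the p-values,
#' divided by the theoretical null median (`qchisq(0.5, 1)`, about 0.4549).
#' Values near 1 indicate well-calibrated tests; inflation above 1 signals
#' confounding such as uncorrected population stratification.
#'
#' @param rows summary-statistics `data.frame` (or a numeric p-value
#'   vector); at least 100 fitted p-values required.
#' @return lambda, a positive scalar.
#' @export
lambda_gc <- function(rows) {
  p <- if (is.data.frame(rows)) rows$p else rows
  p <- p[!is.na(p)]
  if (length(p) < 100L) {
    stop("need at least 100 fitted p-values for lambda_gc", call. = FALSE)
  }
  chi <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1)
}

#' Manhattan and QQ plot coordinates
#'
#' Pure data tables for the two standard GWAS diagnostics: `manhattan`
#' (cumulative genome coordinate vs -log10 p, ordered by chromosome and
#' position) and `qq` (expected vs observed -log10 p quantiles). Rendering
#' is left to the caller.
#'
#' @param rows summary-statistics `data.frame`.
#' @return list of two `data.frame`s: `manhattan`, `qq`.
#' @export
plot_data <- function(rows) {
  fitted <- rows[!is.na(rows$p), , drop = FALSE]
  if (!nrow(fitted)) {
    return(list(
      manhattan = data.frame(id = character(0), chrom = character(0),
                             pos = integer(0), coord = numeric(0),
                             neglog10p = numeric(0)),
      qq = data.frame(expected = numeric(0), observed = numeric(0))))
  }
  chrom_num <- suppressWarnings(as.numeric(sub("^chr", "", fitted$chrom)))
  ord <- order(chrom_num, fitted$chrom, fitted$pos)
  fitted <- fitted[ord, ]
  offsets <- c(0, cumsum(tapply(fitted$pos, factor(fitted$chrom,
                                levels = unique(fitted$chrom)), max)))
  chrom_idx <- match(fitted$chrom, unique(fitted$chrom))
  man <- data.frame(id = fitted$id, chrom = fitted$chrom, pos = fitted$pos,
                    coord = offsets[chrom_idx] + fitted$pos,
                    neglog10p = -log10(fitted$p),
                    stringsAsFactors = FALSE)
  obs <- sort(-log10(fitted$p), decreasing = TRUE)
  k <- length(obs)
  qq <- data.frame(expected = -log10((seq_len(k) - 0.5) / k), observed = obs)
  list(manhattan = man, qq = qq)
}
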