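# Non-genetic association statistics: score binarization, contingency-table
# and covariate-adjusted odds ratios, genotype-defined metabolism groups,
# group comparisons, Bonferroni adjustment, multivariate phenotype model.

#' Binarize an anxiety score at the clinical cutoff
#'
#' `TRUE` iff the 0-21 anxiety score is at or above 11, the conventional
#' cutoff for clinically significant anxiety symptoms; 8-10 (borderline)
#' and below count as no anxiety.
#'
#' @param score integer vector in `[0, 21]`.
#' @return logical vector.
#' @export
binarize_hads <- function(score) {
  if (anyNA(score) || any(score != as.integer(score)) ||
      any(score < 0 | score > 21)) {
    stop("scores must be integers in [0, 21]", call. = FALSE)
  }
  score >= 11
}

#' Crude odds ratio from a 2x2 contingency table
#'
#' Cells are ordered (exposed-case `a`, exposed-control `b`, unexposed-case
#' `c`, unexposed-control `d`); the odds ratio is `(a*d)/(b*c)` with a
#' Woolf 95% confidence interval on the log scale and a two-sided
#' chi-square p-value (continuity-corrected when any cell is below 5). A
#' Haldane-Anscombe 0.5 correction is applied to estimate and CI only when
#' a zero cell occurs, and flagged. Two zero cells in the same margin make
#' the odds ratio undefined.
#'
#' @param a,b,c,d non-negative counts.
#' @return object of class `contingency_result`: `or`, `ci95`, `p`,
#'   `counts` (the 2x2 matrix), `corrected`.
#' @export
contingency_or <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  tab <- matrix(cells, nrow = 2, byrow = TRUE,
                dimnames = list(exposure = c("exposed", "unexposed"),
                                outcome = c("case", "control")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("a zero row or column margin leaves the odds ratio undefined",
         call. = FALSE)
  }
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc[["a"]] * cc[["d"]]) / (cc[["b"]] * cc[["c"]])
  se_log <- sqrt(sum(1 / cc))
  ci <- exp(log(or) + c(-1, 1) * qnorm(0.975) * se_log)
  p <- suppressWarnings(
    chisq.test(tab, correct = any(cells < 5))$p.value)
  structure(list(or = unname(or), ci95 = unname(ci), p = p, counts = tab,
                 corrected = corrected),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("OR = %.2f [%.2f, %.2f], p = %.3g%s\n", x$or, x$ci95[1],
              x$ci95[2], x$p, if (x$corrected) " (0.5-corrected)" else ""))
  invisible(x)
}

#' Covariate-adjusted odds ratios
#'
#' Logistic regression of the binary outcome on one variable of interest
#' with age and sex as covariates. Numeric variables give a per-unit OR;
#' factors give one OR per non-reference level. Separation is flagged, not
#' raised.
#'
#' @param variable numeric vector or factor.
#' @param y binary outcome (0/1 or logical).
#' @param covars data.frame of covariates (default columns `age`, `sex`
#'   must be supplied by the caller).
#' @return `data.frame`: `term`, `or`, `ci_lo`, `ci_hi`, `p`, `separation`.
#' @export
adjusted_or <- function(variable, y, covars) {
  df <- data.frame(.y = as.numeric(y), .v = variable, covars)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = binomial(),
               control = glm.control(epsilon = 1e-8, maxit = 100)))
  sm <- summary(fit)$coefficients
  keep <- grep("^\\.v", rownames(sm))
  est <- sm[keep, 1]; se <- sm[keep, 2]; p <- sm[keep, 4]
  sep <- !fit$converged | se > 50 | abs(est) > 30
  data.frame(
    term = sub("^\\.v", "", rownames(sm)[keep]),
    or = exp(est),
    ci_lo = exp(est - qnorm(0.975) * se),
    ci_hi = exp(est + qnorm(0.975) * se),
    p = p,
    separation = sep,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Caffeine-intolerance group from two metabolism markers
#'
#' Counts "substitutions": one for a slow-metabolizer genotype at rs762551
#' (CYP1A2; `AC` or `CC`) and one for the caffeine-sensitive `TT` genotype
#' at rs5751876 (ADORA2A). Group 0 carries neither, group 1 one, group 2
#' both.
#'
#' @param gt_rs762551 genotype strings in `{AA, AC, CC}`.
#' @param gt_rs5751876 genotype strings in `{CC, CT, TT}`.
#' @return integer vector in `{0, 1, 2}`.
#' @export
assign_caffeine_group <- function(gt_rs762551, gt_rs5751876) {
  check_gt(gt_rs762551, c("AA", "AC", "CC"), "rs762551")
  check_gt(gt_rs5751876, c("CC", "CT", "TT"), "rs5751876")
  (gt_rs762551 %in% c("AC", "CC")) + (gt_rs5751876 == "TT")
}

#' Alcohol-intolerance group from two metabolism markers
#'
#' Counts "substitutions": one for an ALDH2-deficient genotype at rs671
#' (`AA` or `AG`) and one for a fast-ADH1B genotype at rs1229984 (`TT` or
#' `CT`). Group 0 carries neither (rs671 `GG` and rs1229984 `CC`), group 1
#' one, group 2 both.
#'
#' @param gt_rs671 genotype strings in `{GG, AG, AA}`.
#' @param gt_rs1229984 genotype strings in `{CC, CT, TT}`.
#' @return integer vector in `{0, 1, 2}`.
#' @export
assign_alcohol_group <- function(gt_rs671, gt_rs1229984) {
  check_gt(gt_rs671, c("GG", "AG", "AA"), "rs671")
  check_gt(gt_rs1229984, c("CC", "CT", "TT"), "rs1229984")
  (gt_rs671 %in% c("AA", "AG")) + (gt_rs1229984 %in% c("TT", "CT"))
}

check_gt <- function(x, alphabet, marker) {
  bad <- setdiff(unique(x), alphabet)
  if (length(bad)) {
    stop("invalid ", marker, " genotype(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(alphabet, collapse = "/"), ")", call. = FALSE)
  }
  invisible(x)
}

#' Per-group score summary with tests against the cohort mean
#'
#' Mean and SD of the score per group plus, per group, a two-sided
#' one-sample t-test of the group's scores against the overall cohort
#' mean. Groups of size 1 get `NA` SD and no test.
#'
#' @param values numeric scores (e.g. 0-21 anxiety or 0-42 total scores).
#' @param groups group labels, same length.
#' @return `data.frame`: `group`, `n`, `mean`, `sd`, `p_vs_overall`.
#' @export
group_summary <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length", call. = FALSE)
  }
  overall <- mean(values)
  gs <- sort(unique(groups))
  if (length(gs) < 2L) stop("need at least 2 groups", call. = FALSE)
  out <- lapply(gs, function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) sd(v) else NA_real_,
               p_vs_overall = if (length(v) > 1L && sd(v) > 0) {
                 t.test(v, mu = overall)$p.value
               } else NA_real_)
  })
  do.call(rbind, out)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` with `m` the number of tests.
#'
#' @param pvals p-values in (0, 1].
#' @return adjusted p-values, capped at 1.
#' @export
bonferroni_adjust <- function(pvals) {
  if (any(pvals <= 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "bonferroni")
}

#' Multivariate phenotype model of anxiety
#'
#' One logistic model of the binary anxiety label on age, sex, number of
#' children, marital status, alcohol-behavior group, daily coffee cups and
#' nightly sleep hours, with categorical variables one-hot encoded against
#' stated reference levels (no children, never married, alcohol group 1).
#' Reports the coefficient table as odds ratios and the in-sample ROC AUC
#' of the fitted probabilities.
#'
#' @param table cohort `data.frame` with the listed columns and `anxiety`.
#' @return list: `coefficients` (`data.frame` with `term`, `or`, `ci_lo`,
#'   `ci_hi`, `p`), `auc` (in-sample), `n`.
#' @export
multivariate_model <- function(table) {
  req <- c("anxiety", "age", "sex", "children", "marital_status",
           "alcohol_group", "coffee_cups", "sleep_hours")
  miss <- setdiff(req, names(table))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(
    y = as.numeric(table$anxiety),
    age = table$age,
    sex = table$sex,
    children = factor(table$children, levels = c("0", "1", "2", "3+")),
    marital_status = factor(table$marital_status,
                            levels = c("never_married", "married",
                                       "divorced", "widowed")),
    alcohol_group = factor(table$alcohol_group, levels = 1:3),
    coffee_cups = table$coffee_cups,
    sleep_hours = table$sleep_hours)
  df <- df[complete.cases(df), ]
  fit <- stats::glm(y ~ ., data = df, family = binomial())
  sm <- summary(fit)$coefficients
  coefs <- data.frame(
    term = rownames(sm),
    or = exp(sm[, 1]),
    ci_lo = exp(sm[, 1] - qnorm(0.975) * sm[, 2]),
    ci_hi = exp(sm[, 1] + qnorm(0.975) * sm[, 2]),
    p = sm[, 4],
    row.names = NULL, stringsAsFactors = FALSE)
  list(coefficients = coefs,
       auc = roc_auc(fit$fitted.values, df$y),
       n = nrow(df))
}
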