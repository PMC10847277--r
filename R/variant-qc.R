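# Variant-level quality control: PASS status, biallelic-only, Hardy-Weinberg
# exact test, minor allele frequency.

#' Hardy-Weinberg exact test
#'
#' Exact conditional test for Hardy-Weinberg equilibrium from genotype
#' counts. Conditioning on the observed allele counts, the heterozygote
#' count has the distribution
#' `P(h) = n! / (n_AA! h! n_aa!) * 2^h * nA! na! / (2n)!`;
#' the p-value sums the probabilities of all heterozygote configurations no
#' more probable than the observed one. Probabilities are accumulated via
#' the ratio recurrence `P(h+2)/P(h)` in log space for stability. The test
#' is symmetric in the two homozygote counts, and a monomorphic site (a
#' single attainable configuration) gives p = 1.
#'
#' For very common variants the enumeration length is the minor allele
#' count; above `enum_max` minor-allele copies a 1-df chi-square test on the
#' expected genotype counts is used instead (flagged via the
#' `"method"` attribute).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @param enum_max largest minor-allele count for which full enumeration is
#'   used; beyond it the chi-square approximation applies.
#' @return p-value in (0, 1], with attribute `method` = `"exact"` or
#'   `"chisq"`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa, enum_max = 1e6) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (length(counts) != 3L || anyNA(counts) || any(counts < 0)) {
    stop("genotype counts must be three non-negative numbers", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero: HWE test undefined",
                   call. = FALSE)
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  n_minor <- min(nA, na)
  if (n_minor == 0) return(structure(1, method = "exact"))
  if (n_minor > enum_max) {
    p_hat <- nA / (2 * n)
    expected <- n * c(p_hat^2, 2 * p_hat * (1 - p_hat), (1 - p_hat)^2)
    stat <- sum((counts - expected)^2 / expected)
    return(structure(min(1, pchisq(stat, df = 1, lower.tail = FALSE)),
                     method = "chisq"))
  }
  hs <- seq.int(n_minor %% 2, n_minor, by = 2)
  # log P(h) up to the common normalizing constant
  lp <- numeric(length(hs))
  h0 <- hs[1]
  lp[1] <- -lfactorial((nA - h0) / 2) - lfactorial(h0) -
    lfactorial((na - h0) / 2) + h0 * log(2)
  if (length(hs) > 1L) {
    for (i in 2:length(hs)) {
      h <- hs[i]
      # P(h)/P(h-2) = 4 * homA(h-2) * homa(h-2) / (h * (h-1))
      lp[i] <- lp[i - 1] +
        log(4) + log((nA - h) / 2 + 1) + log((na - h) / 2 + 1) -
        log(h) - log(h - 1)
    }
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hs)]
  if (is.na(obs)) {
    stop("heterozygote count inconsistent with allele totals", call. = FALSE)
  }
  p <- sum(pr[pr <= obs * (1 + 1e-12)])
  structure(min(1, p), method = "exact")
}

#' Minor allele frequency from dosages
#'
#' `min(f_alt, 1 - f_alt)` over non-missing calls, where `f_alt` is the
#' mean ALT dosage divided by 2.
#'
#' @param dosages numeric vector of 0/1/2 dosages, `NA` for missing.
#' @return minor allele frequency in `[0, 0.5]`.
#' @export
minor_allele_frequency <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("all dosages missing: MAF undefined", call. = FALSE)
  f <- mean(dosages[ok]) / 2
  min(f, 1 - f)
}

#' QC thresholds
#'
#' Defaults follow standard GWAS variant filtering: keep `PASS` variants
#' only, drop multiallelic records, drop variants violating Hardy-Weinberg
#' equilibrium at p < 1e-6, and drop variants with minor allele frequency
#' below 1% (a variant at exactly 1% is retained).
#'
#' @param hwe_p_min HWE exact-test p-value below which a variant is removed.
#' @param maf_min minor allele frequency below which a variant is removed.
#' @param require_pass drop variants whose FILTER is not `PASS`?
#' @param biallelic_only drop multiallelic records?
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(hwe_p_min = 1e-6, maf_min = 0.01,
                          require_pass = TRUE, biallelic_only = TRUE) {
  stopifnot_scalar_number(hwe_p_min, "hwe_p_min", 0, 1)
  stopifnot_scalar_number(maf_min, "maf_min", 0, 1)
  structure(list(hwe_p_min = hwe_p_min, maf_min = maf_min,
                 require_pass = isTRUE(require_pass),
                 biallelic_only = isTRUE(biallelic_only)),
            class = "qc_thresholds")
}

#' Apply variant QC filters
#'
#' Filters are applied in a fixed order -- non-PASS, multiallelic, HWE,
#' MAF -- and each removal reason is counted against the set surviving the
#' previous filters, so the per-reason counts in the report are
#' well-defined and auditable. Missing genotypes are excluded from both the
#' MAF and the HWE counts; a variant with no observed calls fails the MAF
#' filter. The operation is deterministic and idempotent.
#'
#' @param G a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list with elements `genotypes` (the filtered
#'   [genotype_matrix()]) and `report` (class `qc_report`: per-variant
#'   `maf`, `hwe_p` and fail flags, plus input/removed/surviving counts).
#' @export
apply_qc <- function(G, thresholds = qc_thresholds()) {
  if (!inherits(thresholds, "qc_thresholds")) {
    stop("`thresholds` must come from qc_thresholds()", call. = FALSE)
  }
  m <- nrow(G$variants)
  d <- G$dosage
  maf <- rep(NA_real_, m)
  hwe_p <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    dj <- d[, j]
    ok <- !is.na(dj)
    if (!any(ok)) next
    f <- mean(dj[ok]) / 2
    maf[j] <- min(f, 1 - f)
    cnt <- tabulate(pmin(dj[ok], 2) + 1L, nbins = 3L)
    hwe_p[j] <- hwe_exact_test(cnt[1], cnt[2], cnt[3])
  }

  alive <- rep(TRUE, m)
  flag_non_pass <- thresholds$require_pass &
    G$variants$filter_status != "PASS"
  removed_non_pass <- sum(alive & flag_non_pass)
  alive <- alive & !flag_non_pass

  flag_multi <- thresholds$biallelic_only & G$variants$n_alt_alleles > 1L
  removed_multi <- sum(alive & flag_multi)
  alive <- alive & !flag_multi

  flag_hwe <- !is.na(hwe_p) & hwe_p < thresholds$hwe_p_min
  removed_hwe <- sum(alive & flag_hwe)
  alive <- alive & !flag_hwe

  flag_maf <- is.na(maf) | maf < thresholds$maf_min
  removed_maf <- sum(alive & flag_maf)
  alive <- alive & !flag_maf

  fail_flags <- character(m)
  for (j in seq_len(m)) {
    fl <- c("non_pass", "multiallelic", "hwe", "maf")[
      c(flag_non_pass[j], flag_multi[j], flag_hwe[j], flag_maf[j])]
    fail_flags[j] <- paste(fl, collapse = ",")
  }

  if (!any(alive) && m > 0) warning("no variants survived QC")
  report <- structure(
    list(variants = data.frame(id = G$variants$id, maf = maf, hwe_p = hwe_p,
                               fail_flags = fail_flags,
                               surviving = alive,
                               stringsAsFactors = FALSE),
         counts = list(input = m,
                       removed_non_pass = removed_non_pass,
                       removed_multiallelic = removed_multi,
                       removed_hwe = removed_hwe,
                       removed_maf = removed_maf,
                       surviving = sum(alive)),
         thresholds = thresholds),
    class = "qc_report"
  )
  list(genotypes = subset_variants(G, which(alive)), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cn <- x$counts
  cat("Variant QC report\n")
  cat(sprintf("  input:        %d\n", cn$input))
  cat(sprintf("  non-PASS:     -%d\n", cn$removed_non_pass))
  cat(sprintf("  multiallelic: -%d\n", cn$removed_multiallelic))
  cat(sprintf("  HWE p < %g:   -%d\n", x$thresholds$hwe_p_min,
              cn$removed_hwe))
  cat(sprintf("  MAF < %g:     -%d\n", x$thresholds$maf_min,
              cn$removed_maf))
  cat(sprintf("  surviving:    %d\n", cn$surviving))
  invisible(x)
}
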