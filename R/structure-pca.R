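# Population-structure principal components used as association covariates,
# with a subsample stability check.

#' Select a random SNP subset for PCA
#'
#' Uniform random subsample, without replacement, of variants with minor
#' allele frequency at or above `maf_min`. If fewer than `n_snps` variants
#' qualify, all of them are taken (with a warning). Defaults follow common
#' practice for structure PCA on a genotyping-array-scale panel: 15,000
#' SNPs at MAF >= 5%.
#'
#' @param G a QC-passed [genotype_matrix()].
#' @param maf_min minimum minor allele frequency.
#' @param n_snps subset size.
#' @param seed RNG seed for the subsample (same seed, same subset).
#' @return character vector of selected variant ids.
#' @export
select_pca_snps <- function(G, maf_min = 0.05, n_snps = 15000L, seed = 1L) {
  m <- nrow(G$variants)
  maf <- vapply(seq_len(m), function(j) {
    dj <- G$dosage[, j]
    if (all(is.na(dj))) return(NA_real_)
    minor_allele_frequency(dj)
  }, numeric(1))
  qual <- which(!is.na(maf) & maf >= maf_min)
  if (!length(qual)) {
    stop("no variants with MAF >= ", maf_min, " available for PCA",
         call. = FALSE)
  }
  if (length(qual) <= n_snps) {
    if (length(qual) < n_snps) {
      warning("only ", length(qual), " variants qualify (requested ",
              n_snps, "); taking all of them")
    }
    return(G$variants$id[qual])
  }
  sel <- with_seed(seed, sample(qual, n_snps))
  G$variants$id[sort(sel)]
}

#' Compute principal components of the genotype matrix
#'
#' Missing dosages are mean-imputed per variant; columns are centered and
#' scaled to unit sample standard deviation (zero-variance columns are
#' dropped); the top-`k` components are extracted from the eigen
#' decomposition of the smaller of the two Gram matrices. The per-component
#' sign is fixed by making each component's largest-magnitude SNP loading
#' positive, so results are fully deterministic.
#'
#' @param G a [genotype_matrix()].
#' @param subset_ids variant ids to use (e.g. from [select_pca_snps()]).
#' @param k number of components (reduced with a warning if it exceeds the
#'   available rank).
#' @return An object of class `pc_result`: `scores` (samples x k, zero mean
#'   per column), `loadings` (SNPs x k), `component_variances`
#'   (non-increasing), `center`, `scale`, `snp_subset_ids` (columns
#'   actually used, zero-variance ones dropped).
#' @export
compute_pcs <- function(G, subset_ids, k = 10L) {
  if (!length(subset_ids)) stop("empty SNP subset", call. = FALSE)
  X <- mean_impute(G$dosage[, match(subset_ids, G$variants$id),
                            drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  keep <- which(is.finite(scl) & scl > 0)
  if (!length(keep)) stop("all subset SNPs have zero variance", call. = FALSE)
  X <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  n <- nrow(X); p <- ncol(X)
  kmax <- min(n - 1L, p)
  if (k > kmax) {
    warning("k reduced from ", k, " to ", kmax, " (rank limit)")
    k <- kmax
  }
  if (n <= p) {
    eg <- eigen(tcrossprod(X), symmetric = TRUE)
    ev <- pmax(eg$values[seq_len(k)], 0)
    U <- eg$vectors[, seq_len(k), drop = FALSE]
    scores <- U * rep(sqrt(ev), each = n)
    loadings <- crossprod(X, U)
    loadings <- sweep(loadings, 2, pmax(sqrt(ev), 1e-300), "/")
  } else {
    eg <- eigen(crossprod(X), symmetric = TRUE)
    ev <- pmax(eg$values[seq_len(k)], 0)
    loadings <- eg$vectors[, seq_len(k), drop = FALSE]
    scores <- X %*% loadings
  }
  # sign convention: largest-|loading| entry positive per component
  for (c in seq_len(k)) {
    i <- which.max(abs(loadings[, c]))
    if (loadings[i, c] < 0) {
      loadings[, c] <- -loadings[, c]
      scores[, c] <- -scores[, c]
    }
  }
  dimnames(scores) <- list(G$samples, paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(subset_ids[keep], paste0("PC", seq_len(k)))
  structure(
    list(scores = scores,
         loadings = loadings,
         component_variances = ev / max(n - 1L, 1L),
         center = ctr[keep], scale = scl[keep],
         snp_subset_ids = subset_ids[keep]),
    class = "pc_result"
  )
}

#' @export
print.pc_result <- function(x, ...) {
  k <- ncol(x$scores)
  tot <- sum(x$component_variances)
  cat("pc_result:", nrow(x$scores), "samples,", k, "components,",
      length(x$snp_subset_ids), "SNPs\n")
  cat("  variance shares:",
      paste(sprintf("%.3f", x$component_variances / tot), collapse = " "),
      "\n")
  invisible(x)
}

# Project (possibly new) samples onto stored loadings.
project_pcs <- function(pc, G) {
  X <- mean_impute(G$dosage[, match(pc$snp_subset_ids, G$variants$id),
                            drop = FALSE])
  X <- sweep(sweep(X, 2, pc$center), 2, pc$scale, "/")
  X %*% pc$loadings
}

#' Assess PCA stability across random SNP subsamples
#'
#' Repeats SNP subsampling + PCA `runs` times with independent subsets and
#' measures, against the first (reference) run, the mean over runs and
#' components of `1 - |Pearson correlation|` between matched component
#' scores. The result is scale- and sign-invariant; a mean variability
#' below 0.05 is flagged stable. If the qualifying SNP pool is no larger
#' than `n_snps`, every run uses the identical subset and the variability
#' is exactly 0.
#'
#' @param G a [genotype_matrix()].
#' @param runs number of subsample runs (>= 2).
#' @param k components compared.
#' @inheritParams select_pca_snps
#' @return list: `variability` (mean 1-|r|), `stable`
#'   (`variability < 0.05`), `per_component` (mean per component),
#'   `runs`.
#' @export
assess_stability <- function(G, runs = 50L, k = 10L, maf_min = 0.05,
                             n_snps = 15000L, seed = 1L) {
  if (runs < 2L) stop("`runs` must be >= 2", call. = FALSE)
  ref_ids <- select_pca_snps(G, maf_min, n_snps, seed = derive_seed(seed, 0L))
  ref <- suppressWarnings(compute_pcs(G, ref_ids, k))
  k_eff <- ncol(ref$scores)
  acc <- matrix(NA_real_, nrow = runs - 1L, ncol = k_eff)
  for (r in seq_len(runs - 1L)) {
    ids <- select_pca_snps(G, maf_min, n_snps, seed = derive_seed(seed, r))
    pcs <- suppressWarnings(compute_pcs(G, ids, k_eff))
    kk <- min(k_eff, ncol(pcs$scores))
    for (c in seq_len(kk)) {
      acc[r, c] <- 1 - abs(cor(ref$scores[, c], pcs$scores[, c]))
    }
  }
  per_component <- colMeans(acc, na.rm = TRUE)
  variability <- mean(acc, na.rm = TRUE)
  list(variability = variability,
       stable = variability < 0.05,
       per_component = per_component,
       runs = runs)
}
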