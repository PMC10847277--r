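#' Genotype matrix container
#'
#' Bundles a samples-by-variants dosage matrix (counts of ALT alleles, 0/1/2,
#' `NA` for missing calls) with per-variant metadata. Dosage orientation is
#' the count of ALT alleles, not minor alleles; minor allele frequency is
#' computed downstream irrespective of which allele is minor.
#'
#' @param dosage numeric matrix, samples in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}` (multiallelic records may carry the total
#'   non-reference allele count).
#' @param variants data.frame with one row per variant and columns
#'   `chrom`, `pos` (1-based), `id`, `ref`, `alt`, `filter_status`,
#'   `n_alt_alleles`.
#' @param samples character vector of sample identifiers, one per row.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `variants`, `samples`.
#' @export
genotype_matrix <- function(dosage, variants, samples) {
  dosage <- as.matrix(dosage)
  if (!is.data.frame(variants)) stop("`variants` must be a data.frame")
  req <- c("chrom", "pos", "id", "ref", "alt", "filter_status", "n_alt_alleles")
  miss <- setdiff(req, names(variants))
  if (length(miss)) {
    stop("`variants` is missing columns: ", paste(miss, collapse = ", "))
  }
  if (ncol(dosage) != nrow(variants)) {
    stop("dosage has ", ncol(dosage), " variants but metadata has ",
         nrow(variants), " rows")
  }
  if (nrow(dosage) != length(samples)) {
    stop("dosage has ", nrow(dosage), " samples but ", length(samples),
         " sample ids were given")
  }
  if (nrow(variants) && any(variants$pos < 1L)) {
    stop("variant positions must be 1-based (pos >= 1)")
  }
  if (nrow(variants) && any(variants$n_alt_alleles < 1L)) {
    stop("n_alt_alleles must be >= 1")
  }
  rownames(dosage) <- samples
  colnames(dosage) <- variants$id
  structure(
    list(dosage = dosage, variants = variants, samples = as.character(samples)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  if (nrow(x$variants)) {
    nm <- sum(is.na(x$dosage))
    cat(sprintf("  missing calls: %d (%.2f%%)\n", nm,
                100 * nm / length(x$dosage)))
    cat("  filters:", paste(names(table(x$variants$filter_status)),
                            table(x$variants$filter_status),
                            sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

# Subset variants (by id or index), keeping metadata in step.
subset_variants <- function(G, keep) {
  if (is.character(keep)) keep <- match(keep, G$variants$id)
  if (anyNA(keep)) stop("unknown variant ids in subset")
  genotype_matrix(G$dosage[, keep, drop = FALSE],
                  G$variants[keep, , drop = FALSE],
                  G$samples)
}
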