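# Readers/writers for the standard formats the pipeline touches.
# All coordinates are 1-based as in VCF; no half-open conversion anywhere.

#' Read a VCF into a genotype matrix
#'
#' Parses diploid `GT` calls into ALT-allele dosages: `0/0 -> 0`,
#' `0/1 -> 1`, `1/1 -> 2`, `./. -> NA`; phase separators (`|`) are ignored.
#' For multiallelic records the dosage is the total count of non-reference
#' alleles and `n_alt_alleles` records the ALT arity; such records are
#' retained here and removed (and counted) by [apply_qc()], which keeps the
#' QC report auditable.
#'
#' @param path path to a VCF (v4.x) file with a `GT` FORMAT field.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  m <- nrow(fix)
  samples <- colnames(v@gt)[-1]
  if (is.null(samples)) samples <- character(0)
  n <- length(samples)
  if (m > 0 && n > 0) {
    gt <- vcfR::extract.gt(v, element = "GT")
    dosage <- gt_to_dosage(gt)          # variants x samples
    dosage <- t(dosage)
  } else {
    dosage <- matrix(numeric(0), nrow = n, ncol = m)
  }
  alt <- if (m) fix$ALT else character(0)
  variants <- data.frame(
    chrom = if (m) fix$CHROM else character(0),
    pos = if (m) as.integer(fix$POS) else integer(0),
    id = if (m) fix$ID else character(0),
    ref = if (m) fix$REF else character(0),
    alt = alt,
    filter_status = if (m) ifelse(is.na(fix$FILTER), ".", fix$FILTER)
                    else character(0),
    n_alt_alleles = if (m) 1L + nchar(gsub("[^,]", "", alt)) else integer(0),
    stringsAsFactors = FALSE
  )
  genotype_matrix(dosage, variants, samples)
}

# GT strings -> numeric dosage matrix (count of non-reference alleles).
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  dos <- vapply(u, function(s) {
    if (is.na(s)) return(NA_real_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    sum(al != "0")
  }, numeric(1))
  out <- dos[match(as.vector(gt), u)]
  matrix(out, nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Write a genotype matrix as VCFv4.2
#'
#' Emits a minimal plain-text VCF with a `GT` FORMAT field. Dosages map back
#' to unphased genotypes (`0 -> 0/0`, `1 -> 0/1`, `>=2 -> 1/1`, `NA -> ./.`);
#' the FILTER column carries each variant's `filter_status`.
#'
#' @param G a [genotype_matrix()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=anxgwas",
    '##FILTER=<ID=PASS,Description="All filters passed">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  ), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", G$samples), collapse = "\t"), con)
  m <- nrow(G$variants)
  if (m) {
    gt_codes <- c("0/0", "0/1", "1/1")
    for (j in seq_len(m)) {
      d <- G$dosage[, j]
      gt <- ifelse(is.na(d), "./.", gt_codes[pmin(d, 2) + 1L])
      v <- G$variants[j, ]
      writeLines(paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".",
                         v$filter_status, ".", "GT", gt), collapse = "\t"),
                 con)
    }
  }
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Reads a tab-separated cohort table and validates its schema. Required
#' columns: `sample_id`, `age`, `sex` (female = 1, male = 0), `hads_a`
#' (integer 0-21). The binary `anxiety` label is recomputed as
#' `hads_a >= 11` (the clinical-anxiety cutoff). Categorical columns, when
#' present, are checked against their documented level sets.
#'
#' @param path path to the TSV file.
#' @return A validated `data.frame`.
#' @export
read_phenotypes <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "age", "sex", "hads_a")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stop("phenotype table is missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  hads_a <- tab$hads_a
  if (anyNA(hads_a) || any(hads_a != as.integer(hads_a)) ||
      any(hads_a < 0L | hads_a > 21L)) {
    stop("hads_a must be integers in [0, 21]", call. = FALSE)
  }
  tab$hads_a <- as.integer(hads_a)
  tab$anxiety <- binarize_hads(tab$hads_a)
  if (!all(tab$sex %in% c(0L, 1L))) {
    stop("sex must be coded 0 (male) / 1 (female)", call. = FALSE)
  }
  levels_ok <- list(
    smoking = c("never", "former", "current"),
    met_category = c("sedentary", "low", "moderate", "high"),
    marital_status = c("never_married", "married", "divorced", "widowed"),
    children = c("0", "1", "2", "3+"),
    employment = c("employed", "never_employed", "unemployed", "retired",
                   "disabled"),
    rs762551 = c("AA", "AC", "CC"),
    rs5751876 = c("CC", "CT", "TT"),
    rs671 = c("GG", "AG", "AA"),
    rs1229984 = c("CC", "CT", "TT")
  )
  for (col in intersect(names(levels_ok), names(tab))) {
    bad <- setdiff(unique(na.omit(tab[[col]])), levels_ok[[col]])
    if (length(bad)) {
      stop("column '", col, "' has unknown categories: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if ("alcohol_group" %in% names(tab) &&
      !all(na.omit(tab$alcohol_group) %in% 1:3)) {
    stop("alcohol_group must be 1, 2 or 3", call. = FALSE)
  }
  tab
}

summary_stat_cols <- c("id", "chrom", "pos", "ref", "alt", "model",
                       "beta_g", "se", "p", "n",
                       "beta_age", "beta_sex", "intercept", "converged")

#' Write association summary statistics
#'
#' Tab-separated, one row per variant per model, deterministic column order.
#' Numeric columns are serialized with full (17 significant digit) precision
#' so p-value thresholding (e.g. at 5e-8) is stable after a round trip.
#'
#' @param rows summary-statistics `data.frame` from [gwas_scan()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_summary_stats <- function(rows, path) {
  out <- rows[, summary_stat_cols, drop = FALSE]
  for (col in c("beta_g", "se", "p", "beta_age", "beta_sex", "intercept")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         sprintf("%.17g", out[[col]]))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read association summary statistics written by [write_summary_stats()]
#' @param path path to the TSV file.
#' @return A summary-statistics `data.frame`.
#' @export
read_summary_stats <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(pos = "integer", n = "integer",
                                   converged = "logical"))
  miss <- setdiff(summary_stat_cols, names(tab))
  if (length(miss)) {
    stop("summary-statistics file is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tab[, summary_stat_cols, drop = FALSE]
}
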