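# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# A small default cohort reused by io/structure/assoc tests.
small_cohort <- function() {
  if (is.null(fixture_env$small)) {
    sp <- simulation_spec(n_samples = 300L, n_variants = 120L,
                          n_causal = 10L, seed = 42L)
    sim <- simulate_genotypes(sp)
    ph <- simulate_phenotypes(sim$genotypes, sim$truth, sp)
    fixture_env$small <- list(spec = sp, G = sim$genotypes,
                              truth = sim$truth, table = ph)
  }
  fixture_env$small
}

# Hand-written VCF text exercising GT encodings and QC-relevant records.
write_fixture_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "chr1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\tv2\tC\tT\t.\tPASS\t.\tGT\t./.\t0|1\t0/0",
    "chr1\t300\tv3\tG\tA,T\t.\tPASS\t.\tGT\t0/1\t0/2\t1/2",
    "chr1\t400\tv4\tT\tC\t.\tLowQual\t.\tGT\t0/0\t0/1\t0/0"
  )
  writeLines(lines, path)
  path
}
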