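# Shared fixtures, all generated in code.

# Random genotype vector with a rare-variant profile.
rand_codes <- function(n, p_het = 0.05, p_hom = 0.02, p_miss = 0.01) {
  sample(0:3, n, replace = TRUE,
         prob = c(1 - p_het - p_hom - p_miss, p_het, p_hom, p_miss))
}

# Store written to a session tempdir from a dense sample x variant matrix.
tmp_store <- function(G, sample_ids = NULL) {
  store_from_matrix(G, tempfile(fileext = ".spg"), sample_ids = sample_ids)
}

sparse_rec <- function(codes) {
  nz <- which(codes != 0L)
  spgwas:::new_sparse_record(nz, codes[nz], length(codes))
}

# Covariate design with intercept, reproducible.
toy_design <- function(n, p_cov, seed = 1) {
  withr::with_seed(seed, {
    Xc <- cbind(1, matrix(rnorm(n * p_cov), n))
    colnames(Xc) <- c("(Intercept)",
                      if (p_cov > 0) paste0("C", seq_len(p_cov)))
    Xc
  })
}

# Minimal VCF written as text; gts is a variant x sample character matrix.
write_test_vcf <- function(gts, chrom = "1", pos = NULL, ref = "A",
                           alt = "C", ids = NULL) {
  m <- nrow(gts)
  n <- ncol(gts)
  if (is.null(pos)) pos <- seq_len(m)
  if (is.null(ids)) ids <- sprintf("rs%d", seq_len(m))
  path <- tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("SAMP%03d", seq_len(n))), collapse = "\t")
  )
  rows <- vapply(seq_len(m), function(i) {
    paste(c(chrom, pos[i], ids[i], rep(ref, 1), rep(alt[min(i, length(alt))], 1),
            ".", "PASS", ".", "GT", gts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

# Small simulated panel shared by engine tests.
quick_sim <- function(n = 400, m = 150, seed = 99, n_cov = 3, ...) {
  cfg <- sim_config(n_samples = n, n_variants = m, seed = seed,
                    n_covariates = n_cov, ...)
  sim <- simulate_store(cfg, tempfile(fileext = ".spg"))
  covar <- simulate_covariates(n, n_cov, seed = seed,
                               sample_ids = sim$store$sample_ids)
  list(cfg = cfg, sim = sim, covar = covar)
}
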