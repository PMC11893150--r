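# Seeded generator of biobank-like genotype panels with known ground truth.
#
# The generator emulates an exome panel: per-variant minor allele
# frequencies drawn from a Beta(0.08, 1) -- a heavy rare tail under which
# the large majority of variants sit below 1% MAF -- Hardy-Weinberg
# genotypes, a small completely-at-random missing-call rate, age/sex/PC-type
# covariates, and quantitative or binary phenotypes built from recorded
# covariate and genotype effects so estimator bias and coverage can be
# checked against truth.

#' Simulation configuration
#'
#' @param n_samples Cohort size.
#' @param n_variants Panel size.
#' @param maf_beta Shape parameters (a, b) of the Beta MAF distribution;
#'   the default `c(0.08, 1)` gives the heavy rare tail typical of exome
#'   panels. Draws are truncated to `[1/(2 n_samples), 0.5]`.
#' @param missing_rate Per-call missing probability (default 0.002).
#' @param n_covariates Covariate count: one sex column, one age column,
#'   the rest standard-normal PC-like columns (default 18).
#' @param causal_fraction Fraction of variants given a nonzero phenotype
#'   effect (default 0.01).
#' @param effect_sd SD of causal genotype effects (default 0.5).
#' @param covariate_effect_sd SD of covariate effects on phenotypes
#'   (default 0.05, on the raw covariate scale).
#' @param sigma Residual SD of quantitative phenotypes (default 1).
#' @param prevalence Target case fraction for binary phenotypes
#'   (default 0.1).
#' @param seed Mandatory integer seed; every simulate_* call is fully
#'   reproducible from it.
#' @return A validated list of class `spg_sim_config`.
#' @export
sim_config <- function(n_samples, n_variants, maf_beta = c(0.08, 1),
                       missing_rate = 0.002, n_covariates = 18L,
                       causal_fraction = 0.01, effect_sd = 0.5,
                       covariate_effect_sd = 0.05, sigma = 1,
                       prevalence = 0.1, seed) {
  if (missing(seed) || is.na(seed)) abort("a seed is mandatory")
  rates <- c(missing_rate, causal_fraction, prevalence)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (n_samples < 1 || n_variants < 0) abort("invalid panel dimensions")
  structure(
    list(n_samples = as.integer(n_samples),
         n_variants = as.integer(n_variants),
         maf_beta = maf_beta, missing_rate = missing_rate,
         n_covariates = as.integer(n_covariates),
         causal_fraction = causal_fraction, effect_sd = effect_sd,
         covariate_effect_sd = covariate_effect_sd, sigma = sigma,
         prevalence = prevalence, seed = as.integer(seed)),
    class = "spg_sim_config"
  )
}

#' Simulate a genotype store
#'
#' Draws per-variant MAFs from the configured Beta distribution (truncated
#' to `[1/(2n), 0.5]`), Hardy-Weinberg genotypes `Binomial(2, MAF)`,
#' inserts missing calls at `missing_rate`, and writes each variant through
#' [choose_encoding()] so rare variants land in the sparse difflist form.
#'
#' @param cfg An `spg_sim_config`.
#' @param path Output `.spg` path (sidecars written next to it).
#' @return List of class `spg_sim`: `store` (an `spg_store`) and `truth`
#'   (tibble: ID, maf, record_type).
#' @export
simulate_store <- function(cfg, path) {
  set.seed(cfg$seed)
  n <- cfg$n_samples
  m <- cfg$n_variants
  maf <- rbeta(m, cfg$maf_beta[1L], cfg$maf_beta[2L])
  maf <- pmin(pmax(maf, 1 / (2 * n)), 0.5)
  records <- vector("list", m)
  for (j in seq_len(m)) {
    g <- rbinom(n, 2L, maf[j])
    if (cfg$missing_rate > 0) {
      g[runif(n) < cfg$missing_rate] <- 3L
    }
    records[[j]] <- choose_encoding(g)
  }
  store <- write_store(records, n, path)
  truth <- tibble(ID = store$variants$ID, maf = maf,
                  record_type = store$record_type)
  structure(list(store = store, truth = truth, cfg = cfg),
            class = "spg_sim")
}

#' Simulate covariates
#'
#' One binary sex column, one age-like column (normal, mean 55, sd 8), and
#' `n_covariates - 2` standard-normal PC-like columns.
#'
#' @param n Sample count.
#' @param n_covariates Number of covariate columns (0 gives an IID-only
#'   table; engines then run intercept-only).
#' @param seed Integer seed.
#' @param sample_ids Optional IDs; defaults to the store convention
#'   `S000001, ...`
#' @return Tibble with IID and covariate columns SEX, AGE, PC1...
#' @export
simulate_covariates <- function(n, n_covariates = 18L, seed,
                                sample_ids = NULL) {
  set.seed(seed)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%06d", seq_len(n))
  out <- tibble(IID = sample_ids)
  if (n_covariates >= 1L) out$SEX <- rbinom(n, 1L, 0.5)
  if (n_covariates >= 2L) out$AGE <- rnorm(n, 55, 8)
  if (n_covariates >= 3L) {
    for (j in seq_len(n_covariates - 2L)) {
      out[[paste0("PC", j)]] <- rnorm(n)
    }
  }
  out
}

# Dosage matrix for phenotype construction: missing calls contribute their
# expectation 2*MAF so the recorded truth stays well defined.
sim_dosages <- function(sim, variant_idx) {
  store <- sim$store
  vapply(variant_idx, function(j) {
    g <- as.numeric(get_variant(store, j))
    g[g == 3] <- 2 * sim$truth$maf[j]
    g
  }, numeric(store$n_samples))
}

sim_linear_predictor <- function(sim, covar, cfg, seed) {
  set.seed(seed)
  n <- sim$store$n_samples
  m <- sim$store$n_variants
  cov_cols <- setdiff(names(covar), c("FID", "IID"))
  gamma <- if (length(cov_cols)) {
    rnorm(length(cov_cols), 0, cfg$covariate_effect_sd)
  } else numeric(0)
  n_causal <- round(cfg$causal_fraction * m)
  causal <- if (n_causal > 0) sort(sample.int(m, n_causal)) else integer(0)
  beta <- if (n_causal > 0) rnorm(n_causal, 0, cfg$effect_sd) else numeric(0)
  lp <- numeric(n)
  if (length(cov_cols)) {
    Xc <- as.matrix(covar[match(sim$store$sample_ids, covar$IID), cov_cols,
                          drop = FALSE])
    storage.mode(Xc) <- "double"
    lp <- lp + drop(Xc %*% gamma)
  }
  if (n_causal > 0) {
    G <- sim_dosages(sim, causal)
    lp <- lp + drop(G %*% beta)
  }
  truth_effects <- tibble(ID = sim$truth$ID[causal], beta = beta)
  list(lp = lp, gamma = setNames(gamma, cov_cols), effects = truth_effects)
}

#' Simulate a quantitative phenotype with known effects
#'
#' `y = Xc gamma + sum_causal beta_j g_j + N(0, sigma^2)`; covariate and
#' genotype effects are drawn per the config and recorded in the returned
#' truth tables. Missing genotypes contribute their expectation `2 MAF`.
#'
#' @param sim An `spg_sim` from [simulate_store()].
#' @param covar Covariate tibble from [simulate_covariates()] (IID-only for
#'   none).
#' @param cfg The `spg_sim_config`.
#' @param seed Seed for the effect draws and noise; defaults to
#'   `cfg$seed + 1`.
#' @param name Phenotype column name.
#' @return List: `pheno` (tibble IID, <name>), `effects` (tibble ID, beta
#'   for causal variants), `gamma` (named covariate effects).
#' @export
simulate_quant_pheno <- function(sim, covar, cfg, seed = cfg$seed + 1L,
                                 name = "PHENO1") {
  parts <- sim_linear_predictor(sim, covar, cfg, seed)
  n <- sim$store$n_samples
  y <- parts$lp + rnorm(n, 0, cfg$sigma)
  pheno <- tibble(IID = sim$store$sample_ids)
  pheno[[name]] <- y
  list(pheno = pheno, effects = parts$effects, gamma = parts$gamma)
}

#' Simulate a binary phenotype with known effects
#'
#' Logistic model on the same linear predictor as
#' [simulate_quant_pheno()]; the intercept is solved numerically so the
#' expected case fraction matches `cfg$prevalence`.
#'
#' @inheritParams simulate_quant_pheno
#' @return List: `pheno` (tibble IID, <name> in 0/1), `effects`, `gamma`,
#'   `intercept`.
#' @export
simulate_binary_pheno <- function(sim, covar, cfg, seed = cfg$seed + 2L,
                                  name = "PHENO1") {
  parts <- sim_linear_predictor(sim, covar, cfg, seed)
  lp <- parts$lp - mean(parts$lp)
  b0 <- uniroot(function(b) mean(plogis(b + lp)) - cfg$prevalence,
                c(-30, 30))$root
  y <- rbinom(length(lp), 1L, plogis(b0 + lp))
  pheno <- tibble(IID = sim$store$sample_ids)
  pheno[[name]] <- y
  list(pheno = pheno, effects = parts$effects, gamma = parts$gamma,
       intercept = b0)
}

#' Write simulated phenotype/covariate tables and truth to disk
#'
#' Companion to the `simulate` CLI subcommand: writes PLINK-2-style
#' `.pheno` / `.covar` TSVs and a JSON truth file next to the store.
#'
#' @param sim An `spg_sim`.
#' @param covar Covariate tibble.
#' @param quant Result of [simulate_quant_pheno()], or NULL.
#' @param binary Result of [simulate_binary_pheno()], or NULL.
#' @param prefix Output path prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_sim_outputs <- function(sim, covar, quant = NULL, binary = NULL,
                              prefix) {
  written <- character(0)
  write_tsv_hash <- function(df, path) {
    names(df)[1] <- paste0("#", names(df)[1])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  if (ncol(covar) > 1L) {
    written <- c(written, write_tsv_hash(covar, paste0(prefix, ".covar")))
  }
  pheno <- tibble(IID = sim$store$sample_ids)
  truth <- list(maf = sim$truth)
  if (!is.null(quant)) {
    pheno <- left_join(pheno, quant$pheno, by = "IID")
    truth$quant <- list(effects = quant$effects, gamma = as.list(quant$gamma))
  }
  if (!is.null(binary)) {
    pheno <- left_join(pheno, binary$pheno, by = "IID")
    truth$binary <- list(effects = binary$effects,
                         gamma = as.list(binary$gamma),
                         intercept = binary$intercept)
  }
  if (ncol(pheno) > 1L) {
    written <- c(written, write_tsv_hash(pheno, paste0(prefix, ".pheno")))
  }
  truth_path <- paste0(prefix, ".truth.json")
  writeLines(jsonlite::toJSON(truth, dataframe = "columns", digits = NA,
                              auto_unbox = TRUE), truth_path)
  invisible(c(written, truth_path))
}
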