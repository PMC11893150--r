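# Quantitative-trait association scan.
#
# Two modes:
#   standard        -- the full covariate set enters every per-variant model;
#                      sparse records without missing calls go through the
#                      O(p(k+p)) block-inverse path, everything else falls
#                      back to dense complete-case least squares.
#   qt_residualize  -- the covariates are regressed out of each phenotype
#                      once, then every variant is tested against the
#                      residuals with a two-parameter model that consumes the
#                      difflist directly and downdates at missing calls.
#
# Result rows are accumulated in pre-allocated column vectors indexed by
# (variant, phenotype) position, so output order is store order x phenotype
# order by construction and the per-variant cost stays flat.

# Fraction of the cohort above which a difflist is densified anyway: the
# O(kp) path loses its edge once k approaches n.
SPARSE_K_FRACTION <- 1 / 8

#' Residualize phenotypes on the covariates
#'
#' Fits each phenotype on the covariates once (complete cases per phenotype)
#' and returns the residuals; the per-variant loop then runs intercept +
#' genotype models against these residuals instead of refitting the
#' covariates millions of times.
#'
#' @param Y Numeric matrix or data frame of phenotypes (n x k), NA allowed.
#' @param Xc Covariate matrix including intercept (n x p_c), NA allowed.
#' @return List with `E` (n x k residual matrix, NA where a phenotype or
#'   covariate was missing or the phenotype was skipped) and `summary`
#'   (tibble: phenotype, n_complete, rss, skipped).
#' @export
residualize_phenotypes <- function(Y, Xc) {
  Y <- as.matrix(Y)
  Xc <- as.matrix(Xc)
  k <- ncol(Y)
  E <- matrix(NA_real_, nrow(Y), k, dimnames = dimnames(Y))
  info <- vector("list", k)
  cov_ok <- complete.cases(Xc)
  for (j in seq_len(k)) {
    use <- cov_ok & !is.na(Y[, j])
    n_use <- sum(use)
    if (n_use < ncol(Xc) + 3L) {
      warn(sprintf("phenotype %d has %d complete cases; skipped", j, n_use))
      info[[j]] <- tibble(phenotype = j, n_complete = n_use,
                          rss = NA_real_, skipped = TRUE)
      next
    }
    Xu <- Xc[use, , drop = FALSE]
    if (qr(Xu)$rank < ncol(Xu)) {
      abort("collinear covariates in residualization",
            class = "spgwas_collinear")
    }
    fit <- lm.fit(Xu, Y[use, j])
    E[use, j] <- fit$residuals
    info[[j]] <- tibble(phenotype = j, n_complete = n_use,
                        rss = sum(fit$residuals^2), skipped = FALSE)
  }
  list(E = E, summary = bind_rows(info))
}

#' Variant filter decision
#'
#' Decides from counts computed off the sparse record whether a variant is
#' tested or emitted as a skipped row: the alt-allele count must reach
#' `min_mac` and the nonmissing observation count `min_obs`.
#'
#' @param alt_ct Alt-allele count among analysis samples (sum of code-1 and
#'   twice code-2 entries).
#' @param obs_ct Nonmissing observation count.
#' @param min_mac Minimum alt-allele count (default 1).
#' @param min_obs Minimum observations (default p + 3, supplied by engines).
#' @return `NULL` when the variant passes, otherwise the skip reason string.
#' @export
apply_filters <- function(alt_ct, obs_ct, min_mac = 1, min_obs = 0) {
  if (alt_ct < min_mac) return("SKIPPED_MAC")
  if (obs_ct < min_obs) return("SKIPPED_OBS")
  NULL
}

# Pre-allocated (variant x phenotype) result accumulator.
new_acc <- function(m, pheno_names) {
  k <- length(pheno_names)
  n <- m * k
  list(k = k, pheno_names = pheno_names,
       obs = rep(NA_integer_, n), beta = rep(NA_real_, n),
       se = rep(NA_real_, n), stat = rep(NA_real_, n),
       p = rep(NA_real_, n), err = rep(".", n),
       method = rep(NA_character_, n))
}

acc_pos <- function(acc, v, j) (v - 1L) * acc$k + j

acc_to_assoc <- function(acc, variants, binary = FALSE) {
  m <- length(acc$obs) / acc$k
  vidx <- rep(seq_len(m), each = acc$k)
  out <- as_tibble(variants[vidx, c("CHROM", "POS", "ID", "REF", "ALT")])
  out$A1 <- out$ALT
  out$TEST <- "ADD"
  out$OBS_CT <- acc$obs
  if (binary) {
    out$OR <- exp(acc$beta)
    out$`LOG(OR)_SE` <- acc$se
    out$Z_STAT <- acc$stat
    out$P <- acc$p
    out$METHOD <- acc$method
  } else {
    out$BETA <- acc$beta
    out$SE <- acc$se
    out$T_STAT <- acc$stat
    out$P <- acc$p
  }
  out$ERRCODE <- acc$err
  out$PHENO <- rep(acc$pheno_names, times = m)
  class(out) <- c("spg_assoc", class(out))
  out
}

# Intersect store samples with phenotype/covariate tables; store order
# governs. Returns store-row indices and aligned covariate matrix (with
# intercept) plus phenotype matrix.
align_samples <- function(store, pheno, covar) {
  ids <- store$sample_ids
  keep <- ids %in% pheno$IID
  if (!is.null(covar)) keep <- keep & ids %in% covar$IID
  if (!any(keep)) {
    abort("no samples shared between store and phenotype/covariate tables")
  }
  sel <- which(keep)
  ids_sel <- ids[sel]
  Y <- as.matrix(pheno[match(ids_sel, pheno$IID),
                       setdiff(names(pheno), c("FID", "IID")), drop = FALSE])
  storage.mode(Y) <- "double"
  if (!is.null(covar) && ncol(covar) > 1L) {
    C <- as.matrix(covar[match(ids_sel, covar$IID),
                         setdiff(names(covar), c("FID", "IID")),
                         drop = FALSE])
    storage.mode(C) <- "double"
    Xc <- cbind("(Intercept)" = 1, C)
  } else {
    Xc <- matrix(1, length(sel), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  list(sel = sel, ids = ids_sel, Y = Y, Xc = Xc)
}

# Map a store-universe sparse record into the analysis subset. `map` is an
# integer vector of length store n_samples: position within the subset or NA.
subset_record <- function(record, map, n_sub) {
  pos <- map[record$sample]
  keep <- !is.na(pos)
  new_sparse_record(pos[keep], record$code[keep], n_sub)
}

#' Per-variant linear regression scan for quantitative traits
#'
#' Runs one additive-model linear regression per (variant, phenotype) pair.
#' In `standard` mode every model carries the full covariate set; rare
#' variants stored as difflists with no missing calls are fit through the
#' sparse Schur-complement path, all others through dense complete-case
#' least squares. In `qt_residualize` mode the covariates are regressed out
#' of each phenotype once and the per-variant models are intercept +
#' genotype against the residuals, consuming sparse records directly and
#' downdating the precomputed sums at missing genotypes.
#'
#' @param store An `spg_store`.
#' @param pheno Tibble with an `IID` column plus one numeric column per
#'   phenotype.
#' @param covar Optional tibble with `IID` plus covariate columns.
#' @param mode `"standard"` or `"qt_residualize"`.
#' @param min_mac Minimum alt-allele count to test a variant (default 1).
#' @param min_obs Minimum observations (default p + 3).
#' @return A tibble of class `spg_assoc` in PLINK-2 `.glm.linear` dialect:
#'   CHROM POS ID REF ALT A1 TEST OBS_CT BETA SE T_STAT P ERRCODE PHENO, in
#'   store order x phenotype order. Filtered variants appear as
#'   SKIPPED_MAC / SKIPPED_OBS rows, degenerate fits as DEGENERATE rows;
#'   they are never dropped silently.
#' @export
run_glm_quant <- function(store, pheno, covar = NULL,
                          mode = c("standard", "qt_residualize"),
                          min_mac = 1, min_obs = NULL) {
  mode <- arg_match(mode)
  al <- align_samples(store, pheno, covar)
  acc <- if (mode == "standard") {
    scan_standard(store, al, min_mac, min_obs)
  } else {
    scan_residualized(store, al, min_mac, min_obs)
  }
  acc_to_assoc(acc, store$variants)
}

scan_standard <- function(store, al, min_mac, min_obs) {
  Xc_all <- al$Xc
  Y <- al$Y
  cov_ok <- complete.cases(Xc_all)         # covariate-incomplete: global drop
  pheno_names <- colnames(Y)
  p <- ncol(Xc_all) + 1L
  if (is.null(min_obs)) min_obs <- p + 3
  acc <- new_acc(store$n_variants, pheno_names)
  # group phenotypes by identical missingness pattern so each group shares
  # one covariate precompute
  miss_pat <- apply(is.na(Y) | !cov_ok, 2L, paste, collapse = "")
  groups <- split(seq_len(ncol(Y)), miss_pat)
  for (grp in groups) {
    use <- cov_ok & !is.na(Y[, grp[1L]])
    sub <- which(use)
    n_sub <- length(sub)
    map <- rep(NA_integer_, store$n_samples)
    map[al$sel[sub]] <- seq_len(n_sub)
    Xc <- Xc_all[sub, , drop = FALSE]
    Yg <- Y[sub, grp, drop = FALSE]
    pre <- precompute_covariates(Xc, Yg)
    for (v in seq_len(store$n_variants)) {
      rec_sparse <- store$record_type[v] == RECORD_SPARSE
      rec <- subset_record(variant_entries(store, v), map, n_sub)
      miss <- rec$code == 3L
      n_miss <- sum(miss)
      alt_ct <- sum(rec$code[!miss])
      obs_ct <- n_sub - n_miss
      pos <- acc_pos(acc, v, grp)
      skip <- apply_filters(alt_ct, obs_ct, min_mac, min_obs)
      if (!is.null(skip)) {
        acc$obs[pos] <- obs_ct
        acc$err[pos] <- skip
        next
      }
      use_sparse <- n_miss == 0L && rec_sparse &&
        rec$k <= n_sub * SPARSE_K_FRACTION
      if (!use_sparse) {
        g <- numeric(n_sub)
        g[rec$sample] <- rec$code
        ok <- g != 3
        Xd <- cbind(Xc[ok, , drop = FALSE], GENO = g[ok])
      }
      for (j in seq_along(grp)) {
        res <- tryCatch({
          fit <- if (use_sparse) {
            sparse_ols_fit(pre, rec, Yg[, j], pheno = j)
          } else {
            dense_ols_fit(Xd, Yg[ok, j])
          }
          wald_stats(fit)
        }, spgwas_degenerate = function(e) NULL)
        pj <- pos[j]
        if (is.null(res)) {
          acc$obs[pj] <- obs_ct
          acc$err[pj] <- "DEGENERATE"
        } else {
          acc$obs[pj] <- if (use_sparse) obs_ct else sum(ok)
          acc$beta[pj] <- res$beta
          acc$se[pj] <- res$se
          acc$stat[pj] <- res$statistic
          acc$p[pj] <- res$p.value
        }
      }
    }
  }
  acc
}

scan_residualized <- function(store, al, min_mac, min_obs) {
  if (is.null(min_obs)) min_obs <- 2 + 3
  res <- residualize_phenotypes(al$Y, al$Xc)
  E <- res$E
  pheno_names <- colnames(al$Y)
  acc <- new_acc(store$n_variants, pheno_names)
  map <- rep(NA_integer_, store$n_samples)
  map[al$sel] <- seq_along(al$sel)
  base <- lapply(seq_len(ncol(E)), function(j) {
    e <- E[, j]
    ok <- !is.na(e)
    list(n = sum(ok), sum_e = sum(e[ok]), sum_ee = sum(e[ok]^2))
  })
  for (v in seq_len(store$n_variants)) {
    rec <- subset_record(variant_entries(store, v), map, length(al$sel))
    e_rec <- E[rec$sample, , drop = FALSE]
    for (j in seq_len(ncol(E))) {
      pj <- acc_pos(acc, v, j)
      if (base[[j]]$n == 0) {
        acc$err[pj] <- "SKIPPED_OBS"
        next
      }
      has_e <- !is.na(e_rec[, j])
      n_miss <- sum(rec$code == 3L & has_e)
      alt_ct <- sum(rec$code[rec$code != 3L & has_e])
      obs_ct <- base[[j]]$n - n_miss
      skip <- apply_filters(alt_ct, obs_ct, min_mac, min_obs)
      if (!is.null(skip)) {
        acc$obs[pj] <- obs_ct
        acc$err[pj] <- skip
        next
      }
      w <- tryCatch({
        fit <- residualized_sparse_fit(base[[j]], rec, E[, j])
        wald_stats(fit, n_obs = fit$obs_ct, p = 2L)
      }, spgwas_degenerate = function(err) NULL)
      if (is.null(w)) {
        acc$obs[pj] <- obs_ct
        acc$err[pj] <- "DEGENERATE"
      } else {
        acc$obs[pj] <- obs_ct
        acc$beta[pj] <- w$beta
        acc$se[pj] <- w$se
        acc$stat[pj] <- w$statistic
        acc$p[pj] <- w$p.value
      }
    }
  }
  acc
}

#' Write an association table as TSV
#'
#' PLINK-2 `.glm`-style output: tab-separated, `NA` rendered as `NA`. One
#' combined file with a PHENO column by default, or one file per phenotype.
#'
#' @param assoc Tibble from [run_glm_quant()], [firth_fallback_assoc()] or
#'   [cc_residualize_assoc()].
#' @param path Output path (combined) or prefix (per-phenotype files,
#'   `<path>.<PHENO>.glm.tsv`).
#' @param per_phenotype Write one file per phenotype instead of a combined
#'   table.
#' @return The path(s) written, invisibly.
#' @export
write_assoc <- function(assoc, path, per_phenotype = FALSE) {
  if (!per_phenotype) {
    utils::write.table(assoc, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  paths <- vapply(split(assoc, assoc$PHENO), function(a) {
    p <- sprintf("%s.%s.glm.tsv", path, a$PHENO[1L])
    utils::write.table(a[setdiff(names(a), "PHENO")], p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(unname(paths))
}
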