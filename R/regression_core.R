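# Linear-algebra kernel for per-variant least squares.
#
# Write the design as the block matrix X = (Xc x_g): Xc holds the intercept
# and covariates (p_c columns, shared by every variant), x_g is the genotype
# column. Then
#
#   X'X = | A  B |      A = Xc'Xc   (precomputed, inverted once)
#         | C  D |      B = Xc'x_g, C = B', D = x_g'x_g
#
# and with the Schur complement F = D - C A^{-1} B the block inverse is
#
#   (X'X)^{-1} = | A^{-1} + A^{-1} B F^{-1} C A^{-1}   -A^{-1} B F^{-1} |
#                | -F^{-1} C A^{-1}                      F^{-1}         |
#
# For a variant with k nonzero genotypes, B and D cost O(kp) and O(k); the
# completion costs O(p^2); beta-hat and RSS = y'y - (X'y)' beta follow in
# O(p(k+p)) without ever materializing the n x p design.

#' Precompute the covariate-only regression pieces
#'
#' Computes, once per scan, everything about the covariates that the
#' per-variant fits reuse: the Gram matrix `A = Xc'Xc`, its inverse, `Xc'y`
#' per phenotype and `y'y` per phenotype.
#'
#' @param Xc Numeric matrix, n x p_c, including the intercept column.
#' @param Y Numeric vector (one phenotype) or n x k matrix (several
#'   phenotypes sharing the same samples); no missing values.
#' @return An object of class `spg_precompute`.
#' @export
precompute_covariates <- function(Xc, Y) {
  Xc <- as.matrix(Xc)
  Y <- as.matrix(Y)
  if (nrow(Xc) != nrow(Y)) abort("Xc and Y must cover the same samples")
  if (is.null(colnames(Xc))) {
    colnames(Xc) <- c("(Intercept)", paste0("C", seq_len(ncol(Xc) - 1L)))[
      seq_len(ncol(Xc))]
  }
  qx <- qr(Xc)
  if (qx$rank < ncol(Xc)) {
    bad <- colnames(Xc)[qx$pivot[seq.int(qx$rank + 1L, ncol(Xc))]]
    abort(paste0("collinear covariates: ", paste(bad, collapse = ", ")),
          class = "spgwas_collinear")
  }
  A <- crossprod(Xc)
  kappa_est <- kappa(A, exact = FALSE)
  if (!is.finite(kappa_est) || kappa_est > 1e12) {
    abort("covariate Gram matrix is numerically singular (condition > 1e12)",
          class = "spgwas_collinear")
  }
  A_inv <- chol2inv(chol(A))
  structure(
    list(Xc = Xc, A = A, A_inv = A_inv, Xty = crossprod(Xc, Y),
         yty = colSums(Y^2), n = nrow(Xc), p_c = ncol(Xc)),
    class = "spg_precompute"
  )
}

#' @exportS3Method base::print
print.spg_precompute <- function(x, ...) {
  cat("<covariate precompute> n =", x$n, ", p_c =", x$p_c, ",",
      ncol(x$Xty), "phenotype(s)\n")
  invisible(x)
}

#' Complete (X'X)^-1 from the precomputed covariate block
#'
#' Given the covariate precompute and the genotype cross-products `B =
#' Xc'x_g` and `D = x_g'x_g`, evaluates the Schur complement
#' `F = D - B'A^{-1}B` and assembles the full (p_c+1) x (p_c+1) inverse by
#' the 2x2 block-inverse identity. The genotype column is last.
#'
#' @param pre An `spg_precompute`.
#' @param B Numeric p_c-vector, `Xc' x_g`.
#' @param D Scalar, `x_g' x_g`.
#' @return List with `inv` (the completed inverse) and `F` (the Schur
#'   complement, which is also `1/inv[p,p]`).
#' @export
block_complete_inverse <- function(pre, B, D) {
  B <- as.numeric(B)
  Ainv_B <- drop(pre$A_inv %*% B)
  Fs <- D - sum(B * Ainv_B)
  if (!is.finite(Fs) || Fs <= 1e-10 * abs(D)) {
    abort_degenerate(
      "genotype column is collinear with the covariates or constant")
  }
  p <- pre$p_c + 1L
  inv <- matrix(0, p, p)
  inv[seq_len(pre$p_c), seq_len(pre$p_c)] <-
    pre$A_inv + tcrossprod(Ainv_B) / Fs
  inv[seq_len(pre$p_c), p] <- -Ainv_B / Fs
  inv[p, seq_len(pre$p_c)] <- -Ainv_B / Fs
  inv[p, p] <- 1 / Fs
  list(inv = inv, F = Fs)
}

#' Genotype cross-products from a sparse record
#'
#' Accumulates `B = Xc'x_g`, `D = x_g'x_g` and `x_g'y` touching only the k
#' difflist entries; cost O(kp). The record must contain no missing calls
#' (code 3) -- callers route those to the dense complete-case path.
#'
#' @param Xc Covariate matrix (n x p_c, intercept included).
#' @param y Phenotype vector, length n.
#' @param record An `spg_sparse_record` over the same n samples.
#' @return List with `B`, `D`, `xg_t_y`.
#' @export
sparse_cross_products <- function(Xc, y, record) {
  if (any(record$code == 3L)) {
    abort("sparse cross-products require a record without missing calls")
  }
  if (record$k == 0L) {
    return(list(B = numeric(ncol(Xc)), D = 0, xg_t_y = 0))
  }
  g <- as.numeric(record$code)
  rows <- Xc[record$sample, , drop = FALSE]
  list(B = drop(crossprod(rows, g)),
       D = sum(g * g),
       xg_t_y = sum(g * y[record$sample]))
}

new_fit <- function(beta, rss, xtx_inv_gg, obs_ct, df) {
  structure(
    list(beta = beta, rss = max(rss, 0), xtx_inv_gg = xtx_inv_gg,
         obs_ct = as.integer(obs_ct), df = as.integer(df)),
    class = "spg_fit"
  )
}

#' Per-variant least squares directly on a sparse genotype list
#'
#' Completes the precomputed covariate block with the variant's
#' cross-products and solves for all coefficients and the residual sum of
#' squares in O(p(k+p)) operations, never building the n x p design.
#'
#' @inheritParams block_complete_inverse
#' @param record An `spg_sparse_record` with no missing calls.
#' @param y Phenotype vector over the same samples as `pre`.
#' @param pheno Column of the precompute's phenotype block to use.
#' @return An `spg_fit`: `beta` (genotype last), `rss`, `xtx_inv_gg`,
#'   `obs_ct`, `df`.
#' @export
sparse_ols_fit <- function(pre, record, y, pheno = 1L) {
  cp <- sparse_cross_products(pre$Xc, y, record)
  bc <- block_complete_inverse(pre, cp$B, cp$D)
  Xty <- c(pre$Xty[, pheno], cp$xg_t_y)
  beta <- drop(bc$inv %*% Xty)
  names(beta) <- c(colnames(pre$Xc), "GENO")
  rss <- pre$yty[pheno] - sum(Xty * beta)
  p <- pre$p_c + 1L
  new_fit(beta, rss, bc$inv[p, p], pre$n, pre$n - p)
}

#' Two-parameter fit with missing-genotype downdating
#'
#' The residualized path: the model is intercept + genotype against a
#' residual phenotype `e`. Whole-sample sums are precomputed once; every
#' missing call (code 3) in the difflist *subtracts* that sample's
#' contribution from them, and carrier terms (codes 1/2) accumulate the
#' genotype sums -- all in O(k), whatever the missingness pattern.
#'
#' @param base_sums List with `n`, `sum_e`, `sum_ee` taken over all samples
#'   with a nonmissing residual.
#' @param record An `spg_sparse_record`; codes 1/2/3 all allowed.
#' @param e Residual phenotype vector (NA where the phenotype or a
#'   covariate was missing; such samples are ignored entirely).
#' @return An `spg_fit` with `beta = c(GENO, (Intercept))` reordered to
#'   intercept-first for consistency, `rss`, `xtx_inv_gg`, `obs_ct`, `df`.
#' @export
residualized_sparse_fit <- function(base_sums, record, e) {
  usable <- !is.na(e[record$sample])
  sample <- record$sample[usable]
  code <- record$code[usable]
  miss <- code == 3L
  e_miss <- e[sample[miss]]
  n2 <- base_sums$n - sum(miss)
  sum_e <- base_sums$sum_e - sum(e_miss)
  sum_ee <- base_sums$sum_ee - sum(e_miss^2)
  g <- as.numeric(code[!miss])
  eg <- e[sample[!miss]]
  S_g <- sum(g)
  S_gg <- sum(g * g)
  S_ge <- sum(g * eg)
  det <- S_gg * n2 - S_g^2
  if (n2 < 3 || S_gg == 0 || det <= 1e-10 * S_gg * n2) {
    abort_degenerate("genotype constant among complete cases")
  }
  # normal equations [[S_gg, S_g], [S_g, n']] (beta_g, beta_0) = (S_ge, sum_e)
  beta_g <- (n2 * S_ge - S_g * sum_e) / det
  beta_0 <- (S_gg * sum_e - S_g * S_ge) / det
  rss <- sum_ee - beta_g * S_ge - beta_0 * sum_e
  beta <- c("(Intercept)" = beta_0, GENO = beta_g)
  new_fit(beta, rss, n2 / det, n2, n2 - 2L)
}

#' Ordinary dense least squares (fallback and test oracle)
#'
#' Textbook least squares through a QR factorization; used for dense
#' variants, for complete-case fits when a record carries missing calls in
#' standard mode, and as the brute-force oracle the sparse paths are tested
#' against.
#'
#' @param X Full design matrix (genotype column last), n x p.
#' @param y Phenotype vector, length n.
#' @return An `spg_fit`.
#' @export
dense_ols_fit <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) abort_degenerate("fewer observations than predictors")
  qx <- qr(X)
  if (qx$rank < p) abort_degenerate("design matrix is rank deficient")
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  # undo column pivoting if any
  piv <- qx$pivot
  xtx_inv[piv, piv] <- xtx_inv
  if (is.null(colnames(X))) names(beta) <- paste0("X", seq_len(p))
  new_fit(beta, rss, xtx_inv[p, p], n, n - p)
}

#' Wald statistics for the genotype coefficient
#'
#' Standard errors and p-values are simple functions of the fit:
#' `sigma^2 = RSS / (n - p)`, `SE = sqrt(sigma^2 * [(X'X)^{-1}]_gg)`,
#' `t = beta_g / SE`, two-sided p from the Student-t with `n - p` degrees of
#' freedom. A perfect fit (RSS = 0) reports p = 0 and sets a flag.
#'
#' @param fit An `spg_fit` (genotype coefficient last in `beta`).
#' @param n_obs Observations used; defaults to the fit's own count.
#' @param p Number of predictors; defaults to `length(fit$beta)`.
#' @return A one-row tibble: `beta`, `se`, `statistic`, `p.value`, `df`,
#'   `perfect_fit`.
#' @export
wald_stats <- function(fit, n_obs = fit$obs_ct, p = length(fit$beta)) {
  df <- n_obs - p
  if (df <= 0) abort_degenerate("no residual degrees of freedom")
  beta_g <- unname(fit$beta[length(fit$beta)])
  if (fit$rss == 0) {
    return(tibble(beta = beta_g, se = 0, statistic = Inf, p.value = 0,
                  df = df, perfect_fit = TRUE))
  }
  sigma2 <- fit$rss / df
  se <- sqrt(sigma2 * fit$xtx_inv_gg)
  tval <- beta_g / se
  pval <- 2 * pt(-abs(tval), df)
  tibble(beta = beta_g, se = se, statistic = tval,
         p.value = max(pval, 5e-324), df = df, perfect_fit = FALSE)
}

#' @exportS3Method base::print
print.spg_fit <- function(x, ...) {
  cat("<spg least-squares fit> p =", length(x$beta), ", n =", x$obs_ct,
      ", RSS =", format(x$rss), "\n")
  invisible(x)
}

#' @rdname tidy.spg_fit
#' @export
glance.spg_fit <- function(x, ...) {
  tibble(rss = x$rss, obs_ct = x$obs_ct, df = x$df,
         sigma = sqrt(x$rss / x$df))
}

#' Tidy a per-variant least-squares fit
#'
#' @param x An `spg_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient with the genotype row carrying
#'   Wald statistics; `glance()`: one-row model summary.
#' @export
tidy.spg_fit <- function(x, ...) {
  w <- wald_stats(x)
  tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = c(rep(NA_real_, length(x$beta) - 1L), w$se),
    statistic = c(rep(NA_real_, length(x$beta) - 1L), w$statistic),
    p.value = c(rep(NA_real_, length(x$beta) - 1L), w$p.value)
  )
}
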