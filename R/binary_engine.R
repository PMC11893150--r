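# Case-control association.
#
# Baseline: per-variant logistic regression (Newton-Raphson) on covariates +
# genotype, refit with Firth's Jeffreys-prior penalty whenever the ordinary
# fit fails to converge or walks off to the boundary (|beta| > 40 on the
# logit scale) -- the classic symptom of separation, which rare variants
# produce constantly.
#
# Accelerated mode (cc-residualize): the covariate-only model is fit ONCE,
# its linear predictor is frozen as a per-sample offset, and each variant is
# tested with a two-parameter (intercept + genotype) model on top of that
# offset.

loglik_binom <- function(y, eta) {
  # sum(y*eta - log(1 + exp(eta))), computed stably
  log1pe <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
  sum(y * eta - log1pe)
}

new_logit_fit <- function(beta, cov, converged, iterations, method,
                          terms = NULL) {
  if (!is.null(terms)) names(beta) <- terms
  structure(
    list(beta = beta, cov = cov, converged = converged,
         iterations = iterations, method = method),
    class = "spg_logit_fit"
  )
}

#' Logistic regression by Newton-Raphson with a fixed offset
#'
#' Maximum-likelihood logistic regression: Newton steps on the score
#' `X'(y - mu)` with observed information `X'WX`, `W = mu(1 - mu)`, a fixed
#' per-sample offset added to the linear predictor, and step-halving when a
#' step decreases the log-likelihood. Convergence requires the largest score
#' component to fall below `tol`; coefficients beyond 40 on the logit scale
#' mark the fit as diverged (separation).
#'
#' @param X Design matrix (n x p), intercept included.
#' @param y01 0/1 response vector.
#' @param offset Fixed per-sample additions to the linear predictor
#'   (default 0).
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the max absolute score component.
#' @return An `spg_logit_fit`: `beta`, `cov` (inverse information),
#'   `converged`, `iterations`, `method`.
#' @export
logistic_newton <- function(X, y01, offset = 0, max_iter = 25L, tol = 1e-8) {
  X <- as.matrix(X)
  p <- ncol(X)
  beta <- numeric(p)
  offset <- rep_len(offset, nrow(X))
  ll <- loglik_binom(y01, offset)
  cov <- matrix(NA_real_, p, p)
  for (it in seq_len(max_iter)) {
    eta <- offset + drop(X %*% beta)
    mu <- plogis(eta)
    score <- drop(crossprod(X, y01 - mu))
    info <- crossprod(X * (mu * (1 - mu)), X)
    cov <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(cov)) {
      return(new_logit_fit(beta, matrix(NA_real_, p, p), FALSE, it,
                           "logistic", colnames(X)))
    }
    if (max(abs(score)) < tol) {
      return(new_logit_fit(beta, cov, TRUE, it - 1L, "logistic", colnames(X)))
    }
    step <- drop(cov %*% score)
    new_beta <- beta + step
    new_ll <- loglik_binom(y01, offset + drop(X %*% new_beta))
    halvings <- 0L
    while ((!is.finite(new_ll) || new_ll < ll) && halvings < 10L) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- loglik_binom(y01, offset + drop(X %*% new_beta))
      halvings <- halvings + 1L
    }
    beta <- new_beta
    ll <- new_ll
    if (any(abs(beta) > 40)) {
      return(new_logit_fit(beta, cov, FALSE, it, "logistic", colnames(X)))
    }
  }
  new_logit_fit(beta, cov, FALSE, max_iter, "logistic", colnames(X))
}

#' Firth-penalized logistic regression
#'
#' Maximizes the Jeffreys-prior-penalized likelihood: the score is modified
#' by the hat-value term, `U*_j = sum_i (y_i - mu_i + h_i (1/2 - mu_i))
#' x_ij`, which keeps the estimates finite even under complete separation.
#' Step-halving is applied on the penalized log-likelihood
#' `l(beta) + log|X'WX| / 2`.
#'
#' @inheritParams logistic_newton
#' @return An `spg_logit_fit` with `method = "firth"`.
#' @export
firth_fit <- function(X, y01, offset = 0, max_iter = 50L, tol = 1e-8) {
  X <- as.matrix(X)
  p <- ncol(X)
  beta <- numeric(p)
  offset <- rep_len(offset, nrow(X))
  pen_ll <- function(b) {
    eta <- offset + drop(X %*% b)
    mu <- plogis(eta)
    info <- crossprod(X * (mu * (1 - mu)), X)
    d <- determinant(info, logarithm = TRUE)
    if (d$sign <= 0) return(-Inf)
    loglik_binom(y01, eta) + 0.5 * as.numeric(d$modulus)
  }
  ll <- pen_ll(beta)
  cov <- matrix(NA_real_, p, p)
  for (it in seq_len(max_iter)) {
    eta <- offset + drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    info <- crossprod(X * w, X)
    cov <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(cov)) {
      return(new_logit_fit(beta, matrix(NA_real_, p, p), FALSE, it, "firth",
                           colnames(X)))
    }
    h <- rowSums((X %*% cov) * X) * w          # hat-matrix diagonal
    score <- drop(crossprod(X, y01 - mu + h * (0.5 - mu)))
    if (max(abs(score)) < tol) {
      return(new_logit_fit(beta, cov, TRUE, it - 1L, "firth", colnames(X)))
    }
    step <- drop(cov %*% score)
    new_beta <- beta + step
    new_ll <- pen_ll(new_beta)
    halvings <- 0L
    while ((!is.finite(new_ll) || new_ll < ll) && halvings < 15L) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- pen_ll(new_beta)
      halvings <- halvings + 1L
    }
    beta <- new_beta
    ll <- new_ll
  }
  new_logit_fit(beta, cov, FALSE, max_iter, "firth", colnames(X))
}

#' @exportS3Method base::print
print.spg_logit_fit <- function(x, ...) {
  cat("<", x$method, " fit> ", if (x$converged) "converged" else
    "NOT converged", " in ", x$iterations, " iteration(s)\n", sep = "")
  invisible(x)
}

#' Tidy a logistic / Firth fit
#'
#' @param x An `spg_logit_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient with Wald SE, z and p;
#'   `glance()`: convergence summary.
#' @export
tidy.spg_logit_fit <- function(x, ...) {
  se <- sqrt(diag(x$cov))
  z <- x$beta / se
  tibble(
    term = names(x$beta) %||% paste0("X", seq_along(x$beta)),
    estimate = unname(x$beta), std.error = unname(se),
    statistic = unname(z), p.value = unname(2 * pnorm(-abs(z)))
  )
}

#' @rdname tidy.spg_logit_fit
#' @export
glance.spg_logit_fit <- function(x, ...) {
  tibble(method = x$method, converged = x$converged,
         iterations = x$iterations)
}

check_binary <- function(y) {
  vals <- unique(y[!is.na(y)])
  if (!all(vals %in% c(0, 1)) || length(vals) < 2L) {
    abort("binary phenotype must contain both 0s and 1s (after any 1/2 recoding)")
  }
}

# Shared scaffolding for the two binary modes. fit_variant(env, g, use) is
# called with the dense genotype vector over the analysis subset and must
# return an spg_logit_fit whose last coefficient is the genotype.
binary_scan <- function(store, pheno, covar, min_mac, min_obs, fit_variant,
                        p_model) {
  al <- align_samples(store, pheno, covar)
  if (ncol(al$Y) != 1L) {
    abort("binary engines take exactly one phenotype column")
  }
  y_all <- al$Y[, 1L]
  ok <- !is.na(y_all) & complete.cases(al$Xc)
  sub <- which(ok)
  y <- y_all[sub]
  check_binary(y)
  Xc <- al$Xc[sub, , drop = FALSE]
  n_sub <- length(sub)
  map <- rep(NA_integer_, store$n_samples)
  map[al$sel[sub]] <- seq_len(n_sub)
  if (is.null(min_obs)) min_obs <- p_model + 3
  env <- list(y = y, Xc = Xc, n_sub = n_sub)
  acc <- new_acc(store$n_variants, colnames(al$Y))
  for (v in seq_len(store$n_variants)) {
    rec <- subset_record(variant_entries(store, v), map, n_sub)
    g <- numeric(n_sub)
    g[rec$sample] <- rec$code
    use <- g != 3
    alt_ct <- sum(g[use])
    obs_ct <- sum(use)
    acc$obs[v] <- obs_ct
    skip <- apply_filters(alt_ct, obs_ct, min_mac, min_obs)
    if (is.null(skip) &&
        (alt_ct == 0 || all(g[use] == g[use][1L]))) {
      skip <- "DEGENERATE"
    }
    if (!is.null(skip)) {
      acc$err[v] <- skip
      next
    }
    fit <- tryCatch(fit_variant(env, g, use),
                    spgwas_degenerate = function(e) NULL)
    if (is.null(fit)) {
      acc$err[v] <- "DEGENERATE"
      next
    }
    p <- length(fit$beta)
    se <- sqrt(fit$cov[p, p])
    z <- unname(fit$beta[p]) / se
    acc$beta[v] <- unname(fit$beta[p])
    acc$se[v] <- se
    acc$stat[v] <- z
    acc$p[v] <- max(2 * pnorm(-abs(z)), 5e-324)
    acc$method[v] <- fit$method
    if (!fit$converged) acc$err[v] <- "UNCONVERGED"
  }
  acc_to_assoc(acc, store$variants, binary = TRUE)
}

firth_trigger <- function(fit) {
  !fit$converged || any(abs(fit$beta) > 40)
}

#' Case-control scan: logistic regression with Firth fallback
#'
#' Per variant, fits the full logistic model (covariates + genotype) by
#' Newton-Raphson; when it fails to converge or separates, refits with the
#' Firth penalty. The Wald z on the genotype coefficient is referred to the
#' standard normal; the fitting method is recorded per row.
#'
#' @inheritParams run_glm_quant
#' @param pheno Tibble with `IID` and exactly one 0/1 phenotype column.
#' @return Tibble in PLINK-2 `.glm.logistic.hybrid` dialect: CHROM POS ID
#'   REF ALT A1 TEST OBS_CT OR LOG(OR)_SE Z_STAT P METHOD ERRCODE PHENO.
#' @export
firth_fallback_assoc <- function(store, pheno, covar = NULL, min_mac = 1,
                                 min_obs = NULL) {
  fit_variant <- function(env, g, use) {
    X <- cbind(env$Xc[use, , drop = FALSE], GENO = g[use])
    fit <- logistic_newton(X, env$y[use])
    if (firth_trigger(fit)) fit <- firth_fit(X, env$y[use])
    fit
  }
  p_model <- if (is.null(covar)) 2L else ncol(covar)
  binary_scan(store, pheno, covar, min_mac, min_obs, fit_variant, p_model)
}

#' Case-control scan: frozen covariate offset (cc-residualize)
#'
#' The covariate-only model is fit once with the Firth penalty (robust to
#' quasi-separation in the covariates) and its linear predictor is frozen as
#' a per-sample offset; each variant is then tested with a two-parameter
#' (intercept + genotype) logistic model on top of the offset, falling back
#' to Firth when that fit does not converge. Covariate effects are thus
#' adjusted for but not refit per variant, which is what buys the speed; the
#' approximation degrades when a variant is strongly confounded with a
#' covariate.
#'
#' @inheritParams firth_fallback_assoc
#' @return Tibble as in [firth_fallback_assoc()].
#' @export
cc_residualize_assoc <- function(store, pheno, covar = NULL, min_mac = 1,
                                 min_obs = NULL) {
  offset_env <- new.env(parent = emptyenv())
  fit_variant <- function(env, g, use) {
    if (is.null(offset_env$eta)) {
      cov_fit <- firth_fit(env$Xc, env$y)
      if (!cov_fit$converged) {
        abort(paste0(
          "covariate-only model did not converge; check covariates for ",
          "separation or collinearity before using cc-residualize"))
      }
      offset_env$eta <- drop(env$Xc %*% cov_fit$beta)
    }
    X <- cbind("(Intercept)" = 1, GENO = g[use])
    off <- offset_env$eta[use]
    fit <- logistic_newton(X, env$y[use], offset = off)
    if (firth_trigger(fit)) fit <- firth_fit(X, env$y[use], offset = off)
    fit
  }
  binary_scan(store, pheno, covar, min_mac, min_obs, fit_variant, 2L)
}
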