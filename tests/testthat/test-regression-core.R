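# The sparse least-squares kernel against hand sums, brute-force linear
# algebra, and lm().

test_that("covariate precompute reproduces hand sums and inverts A", {
  pre <- precompute_covariates(matrix(1, 3, 1), c(1, 2, 3))
  expect_equal(unname(pre$A), matrix(3, 1, 1))
  expect_equal(unname(pre$Xty), matrix(6, 1, 1))
  expect_equal(unname(pre$yty), 14)
  withr::with_seed(31, {
    Xc <- cbind(1, matrix(rnorm(50 * 3), 50))
    pre2 <- precompute_covariates(Xc, rnorm(50))
    expect_equal(pre2$A_inv %*% pre2$A, diag(4), tolerance = 1e-10,
                 ignore_attr = TRUE)
  })
})

test_that("collinear covariates are rejected by name", {
  Xc <- cbind("(Intercept)" = 1, AGE = rnorm(30))
  Xc <- cbind(Xc, AGE_COPY = Xc[, "AGE"])
  err <- expect_error(precompute_covariates(Xc, rnorm(30)),
                      class = "spgwas_collinear")
  expect_match(conditionMessage(err), "AGE")
})

test_that("block completion equals brute-force inversion of the assembled matrix", {
  # decoupled blocks: A = I2, B = 0, D = 4
  pre <- list(A_inv = diag(2), p_c = 2L)
  bc <- block_complete_inverse(pre, c(0, 0), 4)
  expect_equal(bc$inv, diag(c(1, 1, 0.25)))
  expect_equal(bc$F, 4)
  # random SPD problems vs solve() on the assembled (p+1) x (p+1)
  withr::with_seed(32, {
    for (i in 1:20) {
      n <- 60
      Xc <- cbind(1, matrix(rnorm(n * 3), n))
      g <- rnorm(n)
      pre <- precompute_covariates(Xc, rnorm(n))
      B <- drop(crossprod(Xc, g))
      D <- sum(g^2)
      full <- crossprod(cbind(Xc, g))
      expect_equal(block_complete_inverse(pre, B, D)$inv,
                   unname(solve(full)), tolerance = 1e-9)
    }
  })
})

test_that("a genotype in the covariate span triggers the degenerate signal", {
  withr::with_seed(33, {
    n <- 40
    Xc <- cbind(1, rnorm(n))
    pre <- precompute_covariates(Xc, rnorm(n))
    g <- Xc[, 2]                      # exact copy of a covariate column
    B <- drop(crossprod(Xc, g))
    expect_error(block_complete_inverse(pre, B, sum(g^2)),
                 class = "spgwas_degenerate")
  })
})

test_that("sparse cross-products equal dense dot products and touch only carriers", {
  Xc <- cbind(c(1, 1, 1), c(0.5, -1, 2))
  # single het at sample 1
  rec <- sparse_rec(c(1L, 0L, 0L))
  cp <- sparse_cross_products(Xc, c(2, 5, 7), rec)
  expect_equal(cp$B, c(1, 0.5))
  expect_equal(cp$D, 1)
  expect_equal(cp$xg_t_y, 2)
  # k = 0
  cp0 <- sparse_cross_products(Xc, c(2, 5, 7), sparse_rec(integer(3)))
  expect_equal(cp0$B, c(0, 0))
  expect_equal(cp0$D, 0)
  expect_equal(cp0$xg_t_y, 0)
  withr::with_seed(34, {
    for (i in 1:20) {
      n <- 100
      Xc <- cbind(1, matrix(rnorm(n * 4), n))
      y <- rnorm(n)
      g <- rand_codes(n, p_miss = 0)
      cp <- sparse_cross_products(Xc, y, sparse_rec(g))
      expect_equal(cp$B, drop(crossprod(Xc, g)), tolerance = 1e-12)
      expect_equal(cp$D, sum(g^2), tolerance = 1e-12)
      expect_equal(cp$xg_t_y, sum(g * y), tolerance = 1e-12)
    }
    # cost contract: only the k carrier rows may be read -- poison the rest
    n <- 200
    g <- integer(n)
    g[c(5, 90)] <- c(1L, 2L)
    Xc <- cbind(1, rnorm(n))
    y <- rnorm(n)
    Xc[g == 0L, ] <- NaN
    y[g == 0L] <- NaN
    cp <- sparse_cross_products(Xc, y, sparse_rec(g))
    expect_true(all(is.finite(c(cp$B, cp$D, cp$xg_t_y))))
  })
})

test_that("sparse fit equals the dense oracle and never touches non-carrier rows", {
  withr::with_seed(35, {
    # perfect fit: y = x_g, intercept-only covariates
    n <- 30
    g <- integer(n)
    g[c(3, 17, 22)] <- c(1L, 2L, 1L)
    pre <- precompute_covariates(matrix(1, n, 1), as.numeric(g))
    fit <- sparse_ols_fit(pre, sparse_rec(g), as.numeric(g))
    expect_equal(unname(fit$beta), c(0, 1), tolerance = 1e-10)
    expect_equal(fit$rss, 0, tolerance = 1e-10)
    # handmade n = 6 toy vs the dense path
    Xc6 <- cbind(1, c(0.3, -1, 2, 0.7, 0, 1.4))
    y6 <- c(1.2, 0.4, -0.3, 2.2, 0.9, 1.1)
    g6 <- c(0L, 1L, 0L, 2L, 0L, 0L)
    pre6 <- precompute_covariates(Xc6, y6)
    f_sparse <- sparse_ols_fit(pre6, sparse_rec(g6), y6)
    f_dense <- dense_ols_fit(cbind(Xc6, g6), y6)
    expect_equal(unname(f_sparse$beta), unname(f_dense$beta),
                 tolerance = 1e-10)
    expect_equal(f_sparse$rss, f_dense$rss, tolerance = 1e-10)
    expect_equal(f_sparse$xtx_inv_gg, f_dense$xtx_inv_gg, tolerance = 1e-10)
    # oracle equivalence on random problems, including lm as referee
    for (i in 1:10) {
      n <- 150
      Xc <- cbind(1, matrix(rnorm(n * 3), n))
      y <- rnorm(n)
      g <- rand_codes(n, p_miss = 0)
      if (sum(g) == 0) next
      pre <- precompute_covariates(Xc, y)
      fs <- sparse_ols_fit(pre, sparse_rec(g), y)
      fd <- dense_ols_fit(cbind(Xc, GENO = g), y)
      expect_equal(unname(fs$beta), unname(fd$beta), tolerance = 1e-8)
      expect_equal(fs$rss, fd$rss, tolerance = 1e-8)
      ref <- lm(y ~ Xc[, -1] + g)
      expect_equal(unname(fs$beta), unname(coef(ref)), tolerance = 1e-8)
      expect_equal(fs$rss, sum(resid(ref)^2), tolerance = 1e-8)
    }
    # the per-variant work must not read non-carrier rows of Xc or y
    n <- 120
    g <- integer(n)
    g[c(11, 44, 80)] <- c(1L, 1L, 2L)
    Xc <- cbind(1, rnorm(n))
    y <- rnorm(n)
    pre <- precompute_covariates(Xc, y)
    pre$Xc[g == 0L, 2] <- NaN
    y_poison <- y
    y_poison[g == 0L] <- NaN
    fit <- sparse_ols_fit(pre, sparse_rec(g), y_poison)
    expect_true(all(is.finite(fit$beta)))
  })
})

test_that("missing-genotype downdate equals complete-case dense OLS", {
  withr::with_seed(36, {
    n <- 150
    e <- rnorm(n)
    e <- e - mean(e)
    base <- list(n = n, sum_e = sum(e), sum_ee = sum(e^2))
    # no missing entries: identical to the sparse fit with intercept only
    g <- rand_codes(n, p_miss = 0)
    pre <- precompute_covariates(matrix(1, n, 1), e)
    f_ref <- sparse_ols_fit(pre, sparse_rec(g), e)
    f_dd <- residualized_sparse_fit(base, sparse_rec(g), e)
    expect_equal(unname(f_dd$beta["GENO"]), unname(f_ref$beta[2]),
                 tolerance = 1e-10)
    expect_equal(f_dd$rss, f_ref$rss, tolerance = 1e-10)
    # arbitrary missingness patterns vs lm on the kept samples
    for (i in 1:50) {
      g <- rand_codes(n, p_het = 0.1, p_hom = 0.03, p_miss = 0.05)
      keep <- g != 3L
      if (length(unique(g[keep])) < 2 || sum(keep) < 3) next
      f_dd <- residualized_sparse_fit(base, sparse_rec(g), e)
      ref <- lm(e[keep] ~ g[keep])
      expect_equal(unname(f_dd$beta), unname(coef(ref)), tolerance = 1e-9)
      expect_equal(f_dd$rss, sum(resid(ref)^2), tolerance = 1e-9)
      expect_equal(f_dd$obs_ct, sum(keep))
      w <- wald_stats(f_dd, p = 2)
      sm <- summary(ref)$coefficients
      expect_equal(w$se, sm[2, 2], tolerance = 1e-9)
      expect_equal(w$p.value, sm[2, 4], tolerance = 1e-9)
    }
    # every carrier missing -> constant genotype among complete cases
    g_all_miss <- integer(n)
    g_all_miss[c(4, 9)] <- 3L
    expect_error(residualized_sparse_fit(base, sparse_rec(g_all_miss), e),
                 class = "spgwas_degenerate")
  })
})

test_that("dense OLS is a textbook fit with orthogonal residuals", {
  X <- cbind(1, c(0, 1, 2, 3))
  fit <- dense_ols_fit(X, c(1, 3, 5, 7))
  expect_equal(unname(fit$beta), c(1, 2), tolerance = 1e-12)
  expect_equal(fit$rss, 0, tolerance = 1e-12)
  withr::with_seed(37, {
    X2 <- cbind(1, matrix(rnorm(50 * 4), 50))
    y2 <- drop(X2 %*% rep(1, 5))
    f2 <- dense_ols_fit(X2, y2)
    expect_equal(unname(f2$beta), rep(1, 5), tolerance = 1e-9)
    for (i in 1:10) {
      y3 <- rnorm(50)
      f3 <- dense_ols_fit(X2, y3)
      resid <- y3 - drop(X2 %*% f3$beta)
      expect_lt(max(abs(crossprod(X2, resid))), 1e-8)
    }
    expect_error(dense_ols_fit(cbind(X2, X2[, 2]), rnorm(50)),
                 class = "spgwas_degenerate")
  })
})

test_that("Wald statistics match the t reference and lm summaries", {
  fit0 <- spgwas:::new_fit(c(a = 1, GENO = 0), rss = 8, xtx_inv_gg = 0.5,
                           obs_ct = 12, df = 10)
  w0 <- wald_stats(fit0)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p.value, 1)
  # n - p = 10, t = 2.228 sits at the classic 5% two-sided point
  se_target <- 1 / 2.228
  fit1 <- spgwas:::new_fit(c(a = 0, GENO = 1), rss = 10,
                           xtx_inv_gg = se_target^2, obs_ct = 12, df = 10)
  expect_equal(wald_stats(fit1)$p.value, 0.05, tolerance = 1e-3)
  withr::with_seed(38, {
    for (i in 1:20) {
      n <- 80
      X <- cbind(1, rnorm(n), rand_codes(n, p_miss = 0))
      if (sum(X[, 3]) == 0) next
      y <- rnorm(n) + 0.2 * X[, 3]
      fit <- dense_ols_fit(X, y)
      w <- wald_stats(fit)
      sm <- summary(lm(y ~ X[, -1]))$coefficients
      expect_equal(w$se, sm[3, 2], tolerance = 1e-6)
      expect_equal(w$statistic, sm[3, 3], tolerance = 1e-6)
      expect_equal(w$p.value, sm[3, 4], tolerance = 1e-6)
    }
  })
  # perfect fit flagged, p floored at 0
  fitp <- spgwas:::new_fit(c(a = 0, GENO = 2), rss = 0, xtx_inv_gg = 1,
                           obs_ct = 12, df = 10)
  wp <- wald_stats(fitp)
  expect_true(wp$perfect_fit)
  expect_equal(wp$p.value, 0)
})

test_that("Schur complement is nonnegative on Gram inputs and RSS never rises with the genotype", {
  withr::with_seed(39, {
    for (i in 1:30) {
      n <- 70
      Xc <- cbind(1, matrix(rnorm(n * 2), n))
      y <- rnorm(n)
      g <- rand_codes(n, p_miss = 0)
      pre <- precompute_covariates(Xc, y)
      B <- drop(crossprod(Xc, g))
      D <- sum(g^2)
      Fs <- D - drop(t(B) %*% pre$A_inv %*% B)
      expect_gte(Fs, -1e-9)
      if (sum(g) == 0) next
      fit_cov <- dense_ols_fit(Xc, y)
      fit_full <- tryCatch(sparse_ols_fit(pre, sparse_rec(g), y),
                           spgwas_degenerate = function(e) NULL)
      if (!is.null(fit_full)) {
        expect_lte(fit_full$rss, fit_cov$rss + 1e-10)
      }
    }
  })
})

test_that("fit objects tidy into coefficient tables", {
  withr::with_seed(40, {
    n <- 50
    X <- cbind("(Intercept)" = 1, C1 = rnorm(n), GENO = rand_codes(n, p_miss = 0))
    y <- rnorm(n)
    fit <- dense_ols_fit(X, y)
    td <- tidy(fit)
    expect_identical(td$term, c("(Intercept)", "C1", "GENO"))
    expect_equal(td$estimate, unname(fit$beta))
    expect_false(any(is.na(td$p.value[3])))
    gl <- glance(fit)
    expect_equal(gl$rss, fit$rss)
    expect_equal(gl$obs_ct, n)
  })
})
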