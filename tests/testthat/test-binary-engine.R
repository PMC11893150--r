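# Logistic / Firth machinery and the two case-control scan modes.

test_that("logistic Newton matches closed forms and glm", {
  # balanced response, intercept only -> logit(0.5) = 0
  y <- rep(c(0, 1), 20)
  f0 <- logistic_newton(matrix(1, 40, 1), y)
  expect_true(f0$converged)
  expect_equal(unname(f0$beta), 0, tolerance = 1e-10)
  # 2x2 table (30,10 / 10,30) -> log OR = log 9
  x <- rep(c(0, 1), each = 40)
  y2 <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  f2 <- logistic_newton(cbind(1, x), y2)
  expect_true(f2$converged)
  expect_equal(unname(f2$beta[2]), log(1 / 9), tolerance = 1e-8)
  f2b <- logistic_newton(cbind(1, x), 1 - y2)
  expect_equal(unname(f2b$beta[2]), log(9), tolerance = 1e-8)
  withr::with_seed(61, {
    for (i in 1:20) {
      n <- 150
      X <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
      yy <- rbinom(n, 1, plogis(drop(X %*% c(-0.3, 0.8, -0.5))))
      if (length(unique(yy)) < 2) next
      fit <- logistic_newton(X, yy)
      ref <- glm(yy ~ X[, -1], family = binomial)
      expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
      # glm evaluates its vcov at a slightly different stopping point
      expect_equal(sqrt(diag(fit$cov)),
                   unname(summary(ref)$coefficients[, 2]), tolerance = 1e-3)
    }
  })
})

test_that("offsets enter the linear predictor", {
  withr::with_seed(62, {
    n <- 300
    x <- rnorm(n)
    off <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.2 + x + off))
    fit <- logistic_newton(cbind(1, x), y, offset = off)
    ref <- glm(y ~ x + offset(off), family = binomial)
    expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  })
})

test_that("separation leaves logistic unconverged but Firth finite", {
  # perfectly separated toy data
  x <- c(rep(0, 10), rep(1, 10))
  y <- x
  X <- cbind(1, x)
  lf <- logistic_newton(X, y)
  expect_false(lf$converged)
  ff <- firth_fit(X, y)
  expect_true(ff$converged)
  expect_true(all(is.finite(ff$beta)))
  expect_lt(max(abs(ff$beta)), 10)
})

test_that("the Firth penalty vanishes asymptotically and matches an independent optimizer", {
  withr::with_seed(63, {
    n <- 4000
    x <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, plogis(0.1 * x))
    X <- cbind(1, x)
    lf <- logistic_newton(X, y)
    ff <- firth_fit(X, y)
    expect_lt(max(abs(lf$beta - ff$beta)), 1e-3)
  })
  withr::with_seed(12, {
    n <- 60
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.5 + x))
    X <- cbind(1, x)
    # independent oracle: generic quasi-Newton optimization of the
    # Jeffreys-penalized log-likelihood
    pen_nll <- function(b) {
      eta <- drop(X %*% b)
      mu <- plogis(eta)
      ll <- sum(y * eta - ifelse(eta > 0, eta + log1p(exp(-eta)),
                                 log1p(exp(eta))))
      -(ll + 0.5 * as.numeric(
        determinant(crossprod(X * (mu * (1 - mu)), X))$modulus))
    }
    o <- optim(c(0, 0), pen_nll, method = "BFGS",
               control = list(reltol = 1e-14))
    f <- firth_fit(X, y)
    expect_equal(unname(f$beta), o$par, tolerance = 1e-6)
  })
})

test_that("logit fits tidy into coefficient tables", {
  withr::with_seed(64, {
    n <- 200
    X <- cbind("(Intercept)" = 1, DOSE = rnorm(n))
    y <- rbinom(n, 1, plogis(X[, 2]))
    fit <- logistic_newton(X, y)
    td <- tidy(fit)
    expect_identical(td$term, c("(Intercept)", "DOSE"))
    expect_equal(td$statistic, unname(fit$beta / sqrt(diag(fit$cov))))
    gl <- glance(fit)
    expect_identical(gl$method, "logistic")
    expect_true(gl$converged)
  })
})

test_that("firth-fallback scan recovers a planted odds ratio and flags separated variants", {
  withr::with_seed(65, {
    n <- 4000
    g <- rbinom(n, 2, 0.3)
    G <- cbind(g, sapply(1:10, function(j) rand_codes(n)))
    st <- tmp_store(G)
    y <- rbinom(n, 1, plogis(-0.1 + log(2) * g))
    pheno <- tibble::tibble(IID = st$sample_ids, CC = y)
    a <- firth_fallback_assoc(st, pheno)
    expect_identical(names(a)[8:14],
                     c("OBS_CT", "OR", "LOG(OR)_SE", "Z_STAT", "P",
                       "METHOD", "ERRCODE"))
    hit <- a[a$ID == "var1", ]
    expect_identical(hit$METHOD, "logistic")
    expect_lt(abs(log(hit$OR) - log(2)), 3 * hit$`LOG(OR)_SE`)
    # a completely separated variant goes through the Firth fallback
    n2 <- 150
    g_sep <- c(rep(1L, 10), integer(n2 - 10))
    st2 <- tmp_store(cbind(g_sep, rbinom(n2, 2, 0.4)))
    a2 <- firth_fallback_assoc(
      st2, tibble::tibble(IID = st2$sample_ids, CC = g_sep))
    sep <- a2[a2$ID == "var1", ]
    expect_identical(sep$METHOD, "firth")
    expect_identical(sep$ERRCODE, ".")
    expect_true(is.finite(sep$P))
  })
})

test_that("null binary p-values are approximately uniform", {
  qs <- quick_sim(n = 1500, m = 800, seed = 66, n_cov = 2,
                  causal_fraction = 0, prevalence = 0.4)
  b <- simulate_binary_pheno(qs$sim, qs$covar, qs$cfg)
  a <- firth_fallback_assoc(qs$sim$store, b$pheno, qs$covar, min_mac = 5)
  p <- a$P[a$ERRCODE == "."]
  expect_gt(length(p), 250)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.06)
})

test_that("cc-residualize with no covariates equals firth-fallback", {
  qs <- quick_sim(n = 800, m = 120, seed = 67, n_cov = 0,
                  causal_fraction = 0.02, prevalence = 0.3)
  b <- simulate_binary_pheno(qs$sim, qs$covar, qs$cfg)
  a_full <- firth_fallback_assoc(qs$sim$store, b$pheno)
  a_cc <- cc_residualize_assoc(qs$sim$store, b$pheno)
  expect_identical(a_full$ERRCODE, a_cc$ERRCODE)
  # compare where the MLE exists: boundary fits (|log OR| blowing up under
  # one-sided separation) are stopping-rule noise in any implementation
  ok <- a_full$ERRCODE == "." & a_full$METHOD == "logistic" &
    a_cc$METHOD == "logistic" & abs(log(a_full$OR)) < 10
  expect_gt(sum(ok), 40)
  expect_equal(log(a_cc$OR[ok]), log(a_full$OR[ok]), tolerance = 1e-6)
  expect_equal(a_cc$P[ok], a_full$P[ok], tolerance = 1e-5)
})

test_that("cc-residualize tracks the full model when covariates are independent of genotype", {
  qs <- quick_sim(n = 4000, m = 2000, seed = 68, n_cov = 5,
                  causal_fraction = 0.01, prevalence = 0.3)
  b <- simulate_binary_pheno(qs$sim, qs$covar, qs$cfg)
  a_full <- firth_fallback_assoc(qs$sim$store, b$pheno, qs$covar)
  a_cc <- cc_residualize_assoc(qs$sim$store, b$pheno, qs$covar)
  ok <- a_full$ERRCODE == "." & a_cc$ERRCODE == "."
  # rank agreement where the Wald test is informative (MAC >= 10); ultra-rare
  # variants give noise-level p ~ 1 in both modes under different penalties
  mac <- vapply(seq_len(qs$sim$store$n_variants), function(j) {
    g <- get_variant(qs$sim$store, j)
    sum(g[g != 3L])
  }, numeric(1))
  sel <- ok & mac >= 10
  expect_gt(sum(sel), 500)
  rho <- stats::cor(-log10(a_full$P[sel]), -log10(a_cc$P[sel]),
                    method = "spearman")
  expect_gt(rho, 0.95)
  r2_sel <- stats::cor(-log10(a_full$P[sel]), -log10(a_cc$P[sel]))^2
  expect_gt(r2_sel, 0.98)
})

test_that("a strongly confounded variant separates the two binary modes detectably", {
  withr::with_seed(69, {
    n <- 3000
    g <- rbinom(n, 2, 0.3)
    conf <- g + rnorm(n, 0, 0.3)       # covariate nearly collinear with g
    y <- rbinom(n, 1, plogis(-0.5 + 1.0 * conf))
    G <- cbind(g, sapply(1:5, function(j) rand_codes(n)))
    st <- tmp_store(G)
    pheno <- tibble::tibble(IID = st$sample_ids, CC = y)
    covar <- tibble::tibble(IID = st$sample_ids, CONF = conf)
    a_full <- firth_fallback_assoc(st, pheno, covar)
    a_cc <- cc_residualize_assoc(st, pheno, covar)
    d <- abs(log10(a_full$P[1]) - log10(a_cc$P[1]))
    expect_gt(d, 0.05)
  })
})

test_that("binary engine validates its phenotype", {
  qs <- quick_sim(n = 100, m = 5, seed = 70, n_cov = 0)
  bad <- tibble::tibble(IID = qs$sim$store$sample_ids, Y = rnorm(100))
  expect_error(firth_fallback_assoc(qs$sim$store, bad), "binary")
  two <- tibble::tibble(IID = qs$sim$store$sample_ids,
                        A = rbinom(100, 1, 0.5), B = rbinom(100, 1, 0.5))
  expect_error(firth_fallback_assoc(qs$sim$store, two), "one phenotype")
})
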