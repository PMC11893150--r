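# Rank reduction of correlated phenotype panels.
#
# Deeply phenotyped cohorts carry many highly correlated measurements;
# scanning each one separately multiplies the association cost by the panel
# size. Taking the thin SVD of the (column-centered) phenotype matrix and
# keeping the smallest number of components that reach a requested fraction
# of variance lets the scan run on r << k component scores instead, with a
# loadings table to map component hits back to the original phenotypes.

#' Reduce a phenotype matrix by SVD
#'
#' Restricts to complete rows (any row with a missing phenotype is dropped),
#' centers each column (optionally standardizes), computes the thin SVD and
#' keeps the smallest rank `r` whose cumulative squared singular values
#' reach `var_explained`. Scores are `U_r S_r` (principal-component scores);
#' association t-statistics are invariant to this choice of scale.
#'
#' @param pheno Tibble with `IID` plus k >= 2 numeric phenotype columns, or
#'   a numeric matrix with rownames as IDs.
#' @param var_explained Fraction of variance to retain, in (0, 1].
#' @param standardize Also scale columns to unit variance before the SVD.
#' @return An object of class `spg_pheno_svd`: `scores` (tibble, IID +
#'   `SVD1..SVDr`), `loadings` (tibble, PHENO + `SVD1..SVDr`), `d`
#'   (singular values), `var_explained_cum`, `r`, `n_complete`.
#' @export
pheno_svd <- function(pheno, var_explained = 0.99, standardize = FALSE) {
  if (!is.numeric(var_explained) || length(var_explained) != 1L ||
      is.na(var_explained) || var_explained <= 0 || var_explained > 1) {
    abort("var_explained must be a single number in (0, 1]")
  }
  if (is.matrix(pheno)) {
    ids <- rownames(pheno) %||% sprintf("S%06d", seq_len(nrow(pheno)))
    Y <- pheno
  } else {
    ids <- pheno$IID
    Y <- as.matrix(pheno[setdiff(names(pheno), c("FID", "IID"))])
    storage.mode(Y) <- "double"
  }
  k <- ncol(Y)
  if (k < 2L) abort("phenotype matrix must have at least 2 columns")
  complete <- complete.cases(Y)
  if (sum(complete) < k + 2L) {
    abort(sprintf("only %d complete phenotype rows; need at least k + 2 = %d",
                  sum(complete), k + 2L))
  }
  Yc <- scale(Y[complete, , drop = FALSE], center = TRUE,
              scale = standardize)
  if (standardize && any(attr(Yc, "scaled:scale") == 0)) {
    abort("cannot standardize a constant phenotype column")
  }
  sv <- svd(Yc)
  tot <- sum(sv$d^2)
  if (tot == 0) abort("phenotype matrix has no variance after centering")
  cum <- cumsum(sv$d^2) / tot
  r <- which(cum >= var_explained - 1e-12)[1L]
  scores <- sv$u[, seq_len(r), drop = FALSE] %*%
    diag(sv$d[seq_len(r)], nrow = r)
  colnames(scores) <- paste0("SVD", seq_len(r))
  loadings <- sv$v[, seq_len(r), drop = FALSE]
  dimnames(loadings) <- list(colnames(Y), paste0("SVD", seq_len(r)))
  structure(
    list(
      scores = bind_cols(tibble(IID = ids[complete]), as_tibble(scores)),
      loadings = bind_cols(tibble(PHENO = colnames(Y)),
                           as_tibble(loadings)),
      d = sv$d, var_explained_cum = cum[seq_len(r)], r = r,
      var_explained = var_explained, n_complete = sum(complete),
      standardized = standardize
    ),
    class = "spg_pheno_svd"
  )
}

#' @exportS3Method base::print
print.spg_pheno_svd <- function(x, ...) {
  cat("<phenotype SVD> rank", x$r, "of", nrow(x$loadings),
      sprintf("phenotypes (%.4f of variance, threshold %.4f), n = %d\n",
              x$var_explained_cum[x$r], x$var_explained, x$n_complete))
  invisible(x)
}

#' Tidy a phenotype SVD
#'
#' @param x An `spg_pheno_svd`.
#' @param ... Unused.
#' @return `tidy()`: long loadings table (PHENO, component, loading);
#'   `glance()`: one row with rank and variance retained.
#' @export
tidy.spg_pheno_svd <- function(x, ...) {
  tidyr::pivot_longer(x$loadings, -"PHENO", names_to = "component",
                      values_to = "loading")
}

#' @rdname tidy.spg_pheno_svd
#' @export
glance.spg_pheno_svd <- function(x, ...) {
  tibble(r = x$r, n_phenotypes = nrow(x$loadings),
         n_complete = x$n_complete,
         var_explained = x$var_explained_cum[x$r],
         threshold = x$var_explained)
}

#' Scree plot of a phenotype SVD
#'
#' @param object An `spg_pheno_svd`.
#' @param ... Unused.
#' @return A ggplot: per-component variance fraction with the retained rank
#'   marked.
#' @export
autoplot.spg_pheno_svd <- function(object, ...) {
  frac <- object$d^2 / sum(object$d^2)
  df <- tibble(component = seq_along(frac), variance_fraction = frac,
               retained = seq_along(frac) <= object$r)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$variance_fraction,
                                   fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "component", y = "fraction of variance",
                  title = sprintf("phenotype SVD: rank %d retained", object$r))
}

#' Association scan on SVD component scores
#'
#' Treats the `r` component score columns as quantitative phenotypes and
#' delegates to [run_glm_quant()]; the loadings table rides along so
#' component-level associations can be mapped back to the original
#' phenotypes.
#'
#' @param store An `spg_store`.
#' @param svd An `spg_pheno_svd`.
#' @inheritParams run_glm_quant
#' @return List with `assoc` (tibble, as [run_glm_quant()]) and `loadings`
#'   (tibble).
#' @export
run_glm_components <- function(store, svd, covar = NULL,
                               mode = c("standard", "qt_residualize"),
                               min_mac = 1, min_obs = NULL) {
  assoc <- run_glm_quant(store, svd$scores, covar = covar, mode = mode,
                         min_mac = min_mac, min_obs = min_obs)
  list(assoc = assoc, loadings = svd$loadings)
}
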