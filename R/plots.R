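# Diagnostics for association scans.

#' Concordance between two association scans
#'
#' Joins two scans on (ID, PHENO), keeps rows both tested, and regresses
#' one scan's -log10 p on the other's -- the standard way to quantify how
#' faithfully an accelerated mode reproduces the full model.
#'
#' @param a,b Association tibbles sharing ID and PHENO columns.
#' @return One-row tibble: `n`, `r2`, `slope`, `intercept` of the
#'   `-log10 p(b) ~ -log10 p(a)` regression.
#' @export
concordance_stats <- function(a, b) {
  j <- dplyr::inner_join(
    dplyr::transmute(a, .data$ID, .data$PHENO, la = -log10(.data$P)),
    dplyr::transmute(b, .data$ID, .data$PHENO, lb = -log10(.data$P)),
    by = c("ID", "PHENO"))
  j <- dplyr::filter(j, is.finite(.data$la), is.finite(.data$lb))
  fit <- lm.fit(cbind(1, j$la), j$lb)
  r2 <- stats::cor(j$la, j$lb)^2
  tibble(n = nrow(j), r2 = r2, slope = fit$coefficients[2L],
         intercept = fit$coefficients[1L])
}

#' Scatter plot of two scans' -log10 p-values
#'
#' @inheritParams concordance_stats
#' @param labels Axis labels, length 2.
#' @return A ggplot with the identity line and the fitted R2/slope in the
#'   subtitle.
#' @export
plot_concordance <- function(a, b, labels = c("scan A", "scan B")) {
  st <- concordance_stats(a, b)
  j <- dplyr::inner_join(
    dplyr::transmute(a, .data$ID, .data$PHENO, la = -log10(.data$P)),
    dplyr::transmute(b, .data$ID, .data$PHENO, lb = -log10(.data$P)),
    by = c("ID", "PHENO"))
  ggplot2::ggplot(j, ggplot2::aes(x = .data$la, y = .data$lb)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::labs(
      x = bquote(-log[10] ~ p ~ .(labels[1L])),
      y = bquote(-log[10] ~ p ~ .(labels[2L])),
      subtitle = sprintf("R² = %.6f, slope = %.5f (n = %d)",
                         st$r2, st$slope, st$n))
}

#' Quantile-quantile plot of association p-values
#'
#' Observed vs expected -log10 p under the uniform null, per phenotype.
#'
#' @param assoc Association tibble (rows with `ERRCODE != "."` are dropped).
#' @return A ggplot.
#' @export
plot_qq <- function(assoc) {
  ok <- dplyr::filter(assoc, .data$ERRCODE == ".", !is.na(.data$P))
  df <- ok %>%
    group_by(.data$PHENO) %>%
    mutate(expected = -log10(stats::ppoints(dplyr::n()))[rank(.data$P,
                                                  ties.method = "first")],
           observed = -log10(.data$P)) %>%
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed,
                                   colour = .data$PHENO)) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::labs(x = expression(expected ~ -log[10] ~ p),
                  y = expression(observed ~ -log[10] ~ p))
}

#' QQ plot for an association scan
#'
#' @param object An `spg_assoc` tibble.
#' @param ... Unused.
#' @return A ggplot (see [plot_qq()]).
#' @export
autoplot.spg_assoc <- function(object, ...) plot_qq(object)
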