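#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot PCA scores
#'
#' @param object a [pca_genotypes()] result
#' @param pops optional [pop_map()] to colour individuals by colony
#' @param ... unused
#' @return a ggplot.
#' @export
autoplot.geno_pca <- function(object, pops = NULL, ...) {
  df <- object$scores
  if (!is.null(pops)) {
    idx <- match(df$individual_id, pops$individuals$individual_id)
    df$colony <- pops$individuals$colony[idx]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])) +
    ggplot2::theme_minimal()
  if (is.null(pops)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$colony))
}

#' Heatmap of pairwise linearized FST
#'
#' @param fst an `fst_matrix` from [pairwise_fst()]
#' @return a ggplot.
#' @export
plot_fst_heatmap <- function(fst) {
  df <- tidy(fst)
  ggplot2::ggplot(df, ggplot2::aes(.data$colony_a, .data$colony_b,
                                   fill = .data$linearized)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "FST/(1-FST)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an FST-outlier scan with its null envelope
#'
#' @param object an [fdist_scan()] result
#' @param fdr q-value threshold used to highlight outliers
#' @param ... unused
#' @return a ggplot.
#' @export
autoplot.outlier_scan <- function(object, fdr = 0.05, ...) {
  loci <- object$loci
  loci$outlier <- !is.na(loci$q) & loci$q <= fdr
  env <- object$envelope
  env$he_mid <- (env$he_lower + env$he_upper) / 2
  ggplot2::ggplot(loci, ggplot2::aes(.data$He, .data$theta)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier), size = 0.8) +
    ggplot2::geom_step(data = env,
                       ggplot2::aes(.data$he_mid, .data$theta_lower),
                       linetype = 2, colour = "grey40") +
    ggplot2::geom_step(data = env,
                       ggplot2::aes(.data$he_mid, .data$theta_upper),
                       linetype = 2, colour = "grey40") +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey30",
                                            "TRUE" = "red")) +
    ggplot2::labs(x = "pooled He", y = "per-locus FST") +
    ggplot2::theme_minimal()
}

#' Plot adjusted ABC posterior densities
#'
#' @param object an [adjust_posterior()] result
#' @param ... unused
#' @return a ggplot, one weighted-density facet per parameter.
#' @export
autoplot.abc_posterior <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$value,
                                   weight = .data$weight)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::facet_wrap(~param, scales = "free") +
    ggplot2::theme_minimal()
}
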