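#' QQ plot of per-SNP sex-difference p-values
#'
#' Expected against observed -log10 p with the y = x null line and the
#' genomic inflation factor in the subtitle.
#'
#' @param object A [snp_sexdiff()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sexdiff_z_table <- function(object, ...) {
  qs <- qq_summary(object)
  ggplot2::ggplot(qs$quantiles,
                  ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      title = attr(object, "trait_label") %||% "sex-difference z scores",
      subtitle = sprintf("lambda[GC] = %.3f", qs$lambda_gc)
    ) +
    ggplot2::theme_minimal()
}

#' Miami plot of a sex-stratified GWAS pair
#'
#' Female association -log10 p plotted upwards, male downwards, coloured by
#' alternating chromosome.
#'
#' @param pair A [harmonize_pair()] result.
#' @param sig Genome-wide significance line (default 5e-8).
#' @return A ggplot object.
#' @export
plot_miami <- function(pair, sig = 5e-8) {
  d <- as_tibble(pair) |>
    dplyr::arrange(.data$chr, .data$pos) |>
    dplyr::mutate(index = dplyr::row_number(),
                  shade = factor(.data$chr %% 2))
  long <- tidyr::pivot_longer(d[c("index", "chr", "shade", "p_f", "p_m")],
                              c("p_f", "p_m"), names_to = "sex",
                              values_to = "p")
  long$y <- ifelse(long$sex == "p_f", -log10(long$p), log10(long$p))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$index, y = .data$y,
                                     colour = .data$shade)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * -log10(sig),
                        linetype = "dotted", colour = "red") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey30") +
    ggplot2::scale_colour_manual(values = c("grey40", "steelblue")) +
    ggplot2::labs(x = "variant (genomic order)",
                  y = expression(-log[10](p) ~ "female (up) / male (down)"),
                  title = attr(pair, "trait_label")) +
    ggplot2::theme_minimal()
}

#' Heatmap of cross-trait sex-difference z-score correlations
#'
#' @param zcorr A tibble of [zcorr_jackknife()] rows (e.g. the `zcorr` table
#'   of a [run_full()] report).
#' @return A ggplot object.
#' @export
plot_zcorr_matrix <- function(zcorr) {
  d <- as_tibble(zcorr)
  sym <- dplyr::bind_rows(
    d,
    dplyr::rename(d, trait_a = "trait_b", trait_b = "trait_a"))
  sym$stars <- cut(sym$p, c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  ggplot2::ggplot(sym, ggplot2::aes(x = .data$trait_a, y = .data$trait_b,
                                    fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Point-range plot of sex-specific heritability estimates
#'
#' @param h2_table The `h2` table of a [run_full()] report (columns trait,
#'   sex, scale, estimate, std.error).
#' @param scale Which scale to show (default `"observed"`).
#' @return A ggplot object.
#' @export
plot_h2 <- function(h2_table, scale = "observed") {
  d <- dplyr::filter(as_tibble(h2_table), .data$scale == !!scale)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trait, y = .data$estimate,
                                  colour = .data$sex)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$estimate - .data$std.error,
                   ymax = .data$estimate + .data$std.error),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::scale_colour_manual(values = c(female = "firebrick",
                                            male = "steelblue")) +
    ggplot2::labs(x = NULL, y = expression(SNP - h^2), colour = NULL,
                  title = paste0("Sex-specific SNP heritability (", scale,
                                 " scale)")) +
    ggplot2::theme_minimal()
}
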