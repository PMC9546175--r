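#' ROC curve of a cross-validation result
#'
#' @param object A `"mirlog_cv"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mirlog_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
      colour = "grey60") +
    ggplot2::geom_path(colour = "#2c7fb8", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf(
        "Pooled out-of-fold ROC (mean AUC %.3f over %d repeats)",
        object$mean_auc, object$repeats
      )
    ) +
    ggplot2::theme_minimal()
}

#' Scree plot of the score-collinearity diagnostic
#'
#' @param diagnostic Tibble from [pca_diagnostic()].
#' @return A ggplot.
#' @export
plot_pca_diagnostic <- function(diagnostic) {
  ggplot2::ggplot(diagnostic, ggplot2::aes(x = .data$component)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$variance_ratio), fill = "#2c7fb8") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative), colour = "#d95f02") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative), colour = "#d95f02") +
    ggplot2::scale_x_continuous(breaks = diagnostic$component) +
    ggplot2::labs(
      x = "Principal component", y = "Explained variance ratio",
      title = "Collinearity among scoring systems"
    ) +
    ggplot2::theme_minimal()
}

#' Allele-frequency spectrum barplot
#'
#' @param spectrum An `"af_spectrum"` object from [af_spectrum()].
#' @return A ggplot.
#' @export
plot_af_spectrum <- function(spectrum) {
  bins <- mutate(spectrum$bins,
    bin = factor(
      sprintf("(%.0e, %.0e]", .data$lower, .data$upper),
      levels = sprintf("(%.0e, %.0e]", .data$lower, .data$upper)
    )
  )
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(
      x = "Allele frequency bin", y = "Variants",
      title = sprintf(
        "AF spectrum (%.0f%% ultra-rare)", 100 * spectrum$ultra_rare_fraction
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-site SNV density along mature miRNAs
#'
#' @param density Tibble from [per_base_density()].
#' @param seed_end Last seed position to highlight (default 8).
#' @return A ggplot.
#' @export
plot_per_base_density <- function(density, seed_end = 8) {
  ggplot2::ggplot(density, ggplot2::aes(x = .data$site, y = .data$per_1000)) +
    ggplot2::annotate("rect",
      xmin = 0.5, xmax = seed_end + 0.5, ymin = -Inf, ymax = Inf,
      alpha = 0.15, fill = "#d95f02"
    ) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(
      x = "Mature miRNA site", y = "SNVs per 1000 miRNAs",
      title = "Per-site variant density (seed shaded)"
    ) +
    ggplot2::theme_minimal()
}

#' Compare two deleteriousness-score distributions
#'
#' @param scores_a,scores_b Numeric score vectors.
#' @param labels Length-2 character vector naming the two groups.
#' @return A ggplot (overlaid densities).
#' @export
plot_score_comparison <- function(scores_a, scores_b,
                                  labels = c("observed", "all possible")) {
  df <- bind_rows(
    tibble(score = scores_a, group = labels[1]),
    tibble(score = scores_b, group = labels[2])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.4, colour = NA) +
    ggplot2::labs(x = "Deleteriousness score", y = "Density", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
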