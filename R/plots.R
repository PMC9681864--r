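#' Score-versus-grade distribution plot
#'
#' For each VE-ICANS score level, shows the distribution of clinical ICANS
#' grades as a box plot with the individual patient-days overlaid.
#'
#' @param x a `veicans_eval` or a data frame with `score` and `icans` columns.
#' @return a ggplot object.
#' @export
plot_score_distribution <- function(x) {
  preds <- if (inherits(x, "veicans_eval")) x$predictions else tibble::as_tibble(x)
  ggplot2::ggplot(preds, ggplot2::aes(x = .data$score, y = .data$icans,
                                      group = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.6,
                          colour = "grey35", fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, height = 0.05, alpha = 0.3, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red", size = 2) +
    ggplot2::labs(x = "VE-ICANS score", y = "ICANS grade") +
    ggplot2::theme_minimal()
}

#' Per-level discrimination plot
#'
#' AUC for discriminating grade 0 from grade >= x, with bootstrap confidence
#' band, across severity levels x.
#'
#' @param object a `veicans_eval`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.veicans_eval <- function(object, ...) {
  ggplot2::ggplot(object$auc, ggplot2::aes(x = .data$level, y = .data$auc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0.5, 1)) +
    ggplot2::labs(x = "ICANS comparison level x (0 vs ≥ x)", y = "AUC") +
    ggplot2::theme_minimal()
}

#' Coefficient profile plot
#'
#' Bar plot of the integer point values, slowing bins ordered by frequency
#' (showing how lower-frequency slowing carries more weight) followed by the
#' remaining scored features.
#'
#' @param object a `veicans_table` or `veicans_fit`.
#' @param ... unused.
#' @param nonzero_only drop zero-point features (default TRUE).
#' @return a ggplot object.
#' @export
plot_coefficients <- function(object, ..., nonzero_only = TRUE) {
  table <- if (inherits(object, "veicans_fit")) object$table else object
  vocab <- eeg_vocabulary()
  df <- tibble::tibble(feature = names(table$coefficients),
                       points = unname(table$coefficients))
  df$band <- vocab$band[match(df$feature, vocab$feature)]
  df$ord <- order(order(match(df$feature, vocab$feature)))
  if (nonzero_only) df <- df[df$points != 0, , drop = FALSE]
  df$feature <- factor(df$feature, levels = df$feature[order(df$ord)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$points,
                                   fill = .data$band)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "points") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_coefficients
#' @export
autoplot.veicans_fit <- function(object, ...) plot_coefficients(object, ...)

#' @rdname plot_coefficients
#' @export
autoplot.veicans_table <- function(object, ...) plot_coefficients(object, ...)

#' Feature correlation heatmap
#'
#' Heatmap of the Spearman correlation matrix between the binary EEG
#' features; undefined entries (constant features) are left blank.
#'
#' @param rho matrix from [spearman_features()] (or a feature table, which is
#'   converted first).
#' @return a ggplot object.
#' @export
plot_feature_correlation <- function(rho) {
  if (is.data.frame(rho)) rho <- spearman_features(rho)
  df <- tibble::as_tibble(as.table(rho), .name_repair = ~c("f1", "f2", "rho"))
  lev <- rownames(rho)
  df$f1 <- factor(df$f1, levels = lev)
  df$f2 <- factor(df$f2, levels = rev(lev))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f1, y = .data$f2, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#c51b7d", mid = "white",
                                  high = "#4d9221", limits = c(-1, 1),
                                  na.value = "grey92") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman ρ") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
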