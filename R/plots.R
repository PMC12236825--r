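# ggplot2 figure helpers for the result types.

#' Violin plot of activity by category
#'
#' @param records activity tibble (pooled rows are used)
#' @param categories tibble with `element_id`, `category`
#' @return a ggplot
#' @export
plot_activity_categories <- function(records, categories) {
  df <- records |>
    dplyr::filter(is.na(.data$replicate), !is.na(.data$log2_activity)) |>
    dplyr::left_join(categories[, c("element_id", "category")],
                     by = "element_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$log2_activity,
                                   fill = .data$category)) +
    ggplot2::geom_violin(scale = "width") +
    ggplot2::geom_boxplot(width = 0.1, fill = "white", outlier.size = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$assay)) +
    ggplot2::labs(x = NULL, y = "log2(activity)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   legend.position = "none")
}

#' Synergy matrix plot
#'
#' Tile plot of the interaction coefficient per motif pair and assay;
#' significant pairs are outlined.
#'
#' @param synergy output of [synergy_regression()]
#' @return a ggplot
#' @export
plot_synergy <- function(synergy) {
  ggplot2::ggplot(synergy, ggplot2::aes(x = .data$motif1, y = .data$motif2,
                                        fill = .data$beta_k)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(synergy, .data$significant),
                       fill = NA, colour = "black", linewidth = 0.6) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::facet_wrap(ggplot2::vars(.data$assay)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "beta_k") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname snv_regression
#' @param object an `snv_fit`
#' @method autoplot snv_fit
#' @export
autoplot.snv_fit <- function(object, ...) {
  eff <- object$effects
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$position, y = .data$beta,
                                    fill = .data$significant)) +
    ggplot2::geom_col(position = "identity", width = 0.8, alpha = 0.8) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "grey70"),
                               name = sprintf("p < %g", object$alpha)) +
    ggplot2::labs(title = sprintf("%s (%s)", object$cre_id, object$assay),
                  x = "position", y = "variant effect (log2)") +
    ggplot2::theme_bw()
}

#' @rdname perturbation_profile
#' @param object a `perturbation_profile`
#' @method autoplot perturbation_profile
#' @export
autoplot.perturbation_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object$profile,
                       ggplot2::aes(x = .data$position, y = .data$smoothed)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$score), colour = "grey75") +
    ggplot2::geom_line(colour = "steelblue", linewidth = 0.8) +
    ggplot2::labs(title = sprintf("%s (%s)", object$cre_id, object$assay),
                  x = "position", y = "MAD score") +
    ggplot2::theme_bw()
  if (nrow(object$sites) > 0) {
    p <- p + ggplot2::geom_segment(
      data = object$sites,
      ggplot2::aes(x = .data$start, xend = .data$end), y = 0, yend = 0,
      colour = "grey30", linewidth = 2, inherit.aes = FALSE)
  }
  p
}
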