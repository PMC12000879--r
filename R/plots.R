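#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for screen results
#'
#' `autoplot()` methods give the field's standard views: a ranked fitness
#' profile with the negative-control band, a volcano of interaction
#' coefficients against Wald P with the dual thresholds, and a stacked bar
#' of dispensability calls (by functional class when a library is given).
#'
#' @param object A result object from this package.
#' @param library Optional `ern_library` for class-wise panels.
#' @param ... Unused.
#' @return A ggplot object.
#' @name ern_plots
NULL

#' @rdname ern_plots
#' @export
autoplot.ern_fitness <- function(object, ...) {
  targets <- dplyr::filter(object, !.data$is_control) %>%
    arrange(dplyr::desc(.data$mean_score)) %>%
    mutate(rank = row_number())
  ctrl <- dplyr::filter(object, .data$is_control)
  p <- ggplot2::ggplot(targets, ggplot2::aes(x = .data$rank, y = .data$mean_score)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_score - .data$sem,
                   ymax = .data$mean_score + .data$sem),
      width = 0, colour = "grey70"
    ) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Genes ranked by fitness score",
                  y = "Fitness score (log2 vs plate controls)") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::theme_minimal()
  if (nrow(ctrl)) {
    band <- ctrl %>%
      group_by(.data$condition) %>%
      summarise(lo = min(.data$mean_score), hi = max(.data$mean_score),
                mid = mean(.data$mean_score), .groups = "drop")
    p <- p +
      ggplot2::geom_hline(data = band, ggplot2::aes(yintercept = .data$lo), linetype = "dotted") +
      ggplot2::geom_hline(data = band, ggplot2::aes(yintercept = .data$hi), linetype = "dotted") +
      ggplot2::geom_hline(data = band, ggplot2::aes(yintercept = .data$mid), linetype = "dashed")
  }
  p
}

#' @rdname ern_plots
#' @export
autoplot.ern_interaction_calls <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$coefficient,
                                       y = -log10(.data$wald_p),
                                       colour = .data$is_interactor)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = -log10(unique(object$p_threshold)),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * unique(object$coef_threshold),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey60", "TRUE" = "red3"),
                                 name = "Interactor") +
    ggplot2::labs(x = "Condition coefficient (log2)", y = "-log10 Wald P") +
    ggplot2::theme_minimal()
}

#' @rdname ern_plots
#' @export
autoplot.ern_dispensability <- function(object, library = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(library)) {
    df <- inner_join(df, select(library, "gene_id", "functional_class"), by = "gene_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$functional_class, fill = .data$call)) +
      ggplot2::geom_bar(position = "fill") +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "Fraction of class")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$call, fill = .data$call)) +
      ggplot2::geom_bar() +
      ggplot2::labs(x = NULL, y = "Genes")
  }
  p + ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1, name = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname ern_plots
#' @param calls An `ern_ptm_calls` tibble.
#' @export
plot_ptm_differential <- function(calls) {
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$form_id, y = .data$mean_log2fc,
                                      fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(unique(calls$lower), unique(calls$upper)),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::labs(x = NULL, y = "log2 L/H ratio vs reference") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
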