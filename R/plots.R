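## ggplot2 views of the result types.

#' Plot conformation probabilities
#'
#' Bar chart of the five class probabilities of one or more predictions.
#'
#' @param object A `conf_prediction` from [predict.conf_forest()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conf_prediction <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$.row <- factor(seq_len(nrow(df)))
  long <- tidyr::pivot_longer(
    df[, c(".row", "p_cidi", "p_cido", "p_codi", "p_codo", "p_wcd")],
    cols = -".row", names_to = "conformation", values_to = "probability"
  )
  long$conformation <- factor(
    dplyr::case_match(long$conformation,
                      "p_cidi" ~ "CIDI", "p_cido" ~ "CIDO",
                      "p_codi" ~ "CODI", "p_codo" ~ "CODO",
                      "p_wcd" ~ "wCD"),
    levels = CONFORMATION_LEVELS
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$conformation,
                                          y = .data$probability,
                                          fill = .data$conformation)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "probability") +
    ggplot2::theme_minimal()
  if (nrow(df) > 1) p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$.row))
  p
}

#' Manhattan-style plot of substructure enrichment
#'
#' -log10 p-value per (substructure, conformation) pair, with the
#' Bonferroni-corrected threshold drawn as a horizontal line.
#'
#' @param object An `enrichment_result` from [enrich_library()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$idx <- match(df$substructure_id, unique(df$substructure_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx,
                                   y = -log10(pmax(.data$p_value, 1e-300)),
                                   colour = .data$conformation,
                                   shape = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(df$alpha_corrected[1]),
                        linetype = "dashed") +
    ggplot2::labs(x = "substructure", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Scatter view of a labeled descriptor table
#'
#' @param data Data frame with descriptor columns and a `conformation`
#'   column.
#' @param x,y Descriptor names to plot (defaults: salt-bridge distance vs
#'   ring projection x).
#' @return A ggplot object.
#' @export
plot_descriptor_space <- function(data, x = "d1_saltbridge_dist",
                                  y = "d3_phe_proj_x") {
  stopifnot(all(c(x, y, "conformation") %in% names(data)))
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                     colour = .data$conformation)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::theme_minimal()
}
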