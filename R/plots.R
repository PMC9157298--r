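# ggplot2 visualisations for the main result types.

#' Plot a connectivity matrix as a heat map
#'
#' @param object A `connectivity_matrix` (masked entries show as blank).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  p <- nrow(object)
  df <- tidyr::expand_grid(i = seq_len(p), j = seq_len(p))
  df$value <- object[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "parcel", y = "parcel", fill = "dwPLI",
      title = paste(
        na.omit(c(
          attr(object, "subject"), attr(object, "state"),
          attr(object, "band")
        )),
        collapse = " / "
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot the significant components of an NBS result
#'
#' Draws each component's edges between parcel centroids (unit-circle layout
#' unless a parcellation with coordinates is supplied).
#'
#' @param object An `nbs_result`.
#' @param parcellation Optional `parcellation` providing centroids.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nbs_result <- function(object, parcellation = NULL, ...) {
  edges <- tidy(object, type = "edges")
  if (!nrow(edges)) {
    return(ggplot2::ggplot() +
      ggplot2::annotate("text", 0, 0, label = "no suprathreshold components") +
      ggplot2::theme_void())
  }
  nodes <- sort(unique(c(edges$i, edges$j)))
  if (!is.null(parcellation)) {
    coords <- parcellation$parcels[, c("parcel", "x", "y")]
  } else {
    all_p <- seq_len(max(nodes))
    ang <- 2 * pi * (all_p - 1) / length(all_p)
    coords <- tibble(parcel = all_p, x = cos(ang), y = sin(ang))
  }
  edges <- edges |>
    dplyr::left_join(coords, by = c(i = "parcel")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(coords, by = c(j = "parcel"))
  ggplot2::ggplot(edges) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y,
        linewidth = abs(.data$t), colour = .data$direction
      ),
      alpha = 0.8
    ) +
    ggplot2::geom_point(
      data = coords[coords$parcel %in% nodes, ],
      ggplot2::aes(x = .data$x, y = .data$y), size = 2
    ) +
    ggplot2::scale_linewidth(range = c(0.3, 1.6)) +
    ggplot2::facet_wrap(~component) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "direction", linewidth = "|t|") +
    ggplot2::theme_void()
}

#' Plot outcome correlations
#'
#' Dot plot of Spearman rho per network and score, flagging FDR-significant
#' tests.
#'
#' @param object An `outcome_correlations` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.outcome_correlations <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$rho, y = .data$score,
      colour = .data$p_fdr < 0.05, shape = .data$family
    )
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::facet_wrap(~network) +
    ggplot2::labs(x = "Spearman rho", y = NULL, colour = "FDR < 0.05") +
    ggplot2::theme_minimal()
}

#' Plot cytoarchitectonic test results
#'
#' Per-layer KS statistics with surrogate-FDR significance.
#'
#' @param object A `cyto_test_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cyto_test_result <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = factor(.data$layer), y = .data$D,
      fill = .data$p_fdr < 0.05
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~network) +
    ggplot2::labs(x = "cortical layer", y = "KS D", fill = "FDR < 0.05") +
    ggplot2::theme_minimal()
}
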