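#' Plot an NMDS ordination
#'
#' Scatter of the first two NMDS axes, optionally coloured/shaped by sample
#' metadata, with the stress value in the subtitle.
#'
#' @param object An `nmds_ord`.
#' @param metadata Optional sample metadata joined by `sample_id`; when given,
#'   points are coloured by `colour` and shaped by `shape`.
#' @param colour,shape Metadata column names (defaults `"zone"`,
#'   `"compartment"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nmds_ord <- function(object, metadata = NULL, colour = "zone",
                              shape = "compartment", ...) {
  df <- object$points
  mapping <- ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2)
  if (!is.null(metadata)) {
    df <- left_join(df, as_tibble(metadata), by = "sample_id")
    extra <- list()
    if (colour %in% names(df)) extra$colour <- rlang::sym(colour)
    if (shape %in% names(df)) extra$shape <- rlang::sym(shape)
    mapping <- utils::modifyList(mapping, ggplot2::aes(!!!extra))
  }
  ggplot2::ggplot(df, mapping) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(subtitle = sprintf("stress = %.3f", object$stress)) +
    ggplot2::theme_minimal()
}

#' Boxplots of alpha diversity by group
#'
#' @param alpha Output of [alpha_diversity] joined with sample metadata.
#' @param group Grouping column name (default `"zone"`).
#' @param metric Diversity column name (default `"shannon"`).
#' @return A ggplot object.
#' @export
plot_alpha_diversity <- function(alpha, group = "zone", metric = "shannon") {
  stopifnot(all(c(group, metric) %in% names(alpha)))
  ggplot2::ggplot(alpha, ggplot2::aes(x = .data[[group]],
                                      y = .data[[metric]],
                                      fill = .data[[group]])) +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::theme_minimal()
}

#' Plot zone-mean trend profiles
#'
#' Lines of zone-mean relative abundance along the gradient for the OTUs
#' labelled increased and decreased.
#'
#' @param object A `trend_classification` from [classify_trends].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trend_classification <- function(object, ...) {
  df <- object |>
    filter(.data$label %in% c("increased", "decreased")) |>
    select("otu_id", "label", dplyr::starts_with("mean_")) |>
    tidyr::pivot_longer(dplyr::starts_with("mean_"),
                        names_to = "zone", values_to = "abundance",
                        names_prefix = "mean_") |>
    mutate(zone = factor(.data$zone, levels = zone_levels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$zone, y = .data$abundance,
                                   group = .data$otu_id,
                                   colour = .data$label)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "bioclimatic zone (increasing aridity)",
                  y = "mean relative abundance") +
    ggplot2::theme_minimal()
}

#' Plot a co-occurrence network
#'
#' Force-directed layout with nodes coloured by class and edges by sign
#' (red = positive co-presence, black = negative mutual exclusion).
#'
#' @param object A `co_network`.
#' @param drop_isolated Hide degree-zero nodes (default `TRUE`).
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.co_network <- function(object, drop_isolated = TRUE, seed = 1L, ...) {
  g <- as_igraph(object)
  if (drop_isolated) {
    g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  }
  lay <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble(id = igraph::V(g)$name, class = igraph::V(g)$class,
                  x = lay[, 1], y = lay[, 2])
  el <- igraph::as_edgelist(g)
  edges <- tibble(from = el[, 1], to = el[, 2],
                  sign = igraph::E(g)$sign) |>
    left_join(select(nodes, "id", x0 = "x", y0 = "y"), by = c(from = "id")) |>
    left_join(select(nodes, "id", x1 = "x", y1 = "y"), by = c(to = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, colour = .data$sign),
      alpha = 0.5) +
    ggplot2::scale_colour_manual(values = c("+" = "red3", "-" = "black")) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$class),
      shape = 21, size = 3) +
    ggplot2::theme_void()
}
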