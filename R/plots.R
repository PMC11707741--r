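# ggplot2 views of the main result types.

#' Plot a chemical-space embedding
#'
#' @param object A `chem_space` tibble from [embed_chemical_space()].
#' @param colour Optional vector mapped to point colour.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot chem_space
#' @export
autoplot.chem_space <- function(object, colour = NULL, ...) {
  df <- tibble::as_tibble(object)
  lab <- if (attr(object, "method") == "pca") {
    ev <- attr(object, "explained_variance")
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ev[2]))
  } else {
    ggplot2::labs(
      x = "t-SNE 1", y = "t-SNE 2",
      subtitle = sprintf("KL divergence %.3f", attr(object, "kl_divergence")))
  }
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(
      if (!is.null(colour)) ggplot2::aes(colour = .data$colour) else NULL,
      alpha = 0.8) +
    lab + ggplot2::theme_minimal()
  p
}

#' Scatter plot of association-rule support, confidence and lift
#'
#' @param object An `assoc_rules` tibble from [derive_rules()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot assoc_rules
#' @export
autoplot.assoc_rules <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$support, y = .data$confidence,
                                   colour = .data$lift)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "support", y = "confidence", colour = "lift") +
    ggplot2::theme_minimal()
}

#' Plot a rule subnetwork
#'
#' Nodes are excipients; arrows point toward the consequent, colour
#' carries the chosen edge attribute.
#'
#' @param graph An igraph graph from [rule_subnetwork()].
#' @param edge_colour `"confidence"` or `"lift"`.
#' @param seed Layout seed.
#' @return A ggplot.
#' @export
plot_rule_network <- function(graph, edge_colour = c("confidence", "lift"),
                              seed = 1L) {
  edge_colour <- match.arg(edge_colour)
  if (igraph::vcount(graph) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty rule network"))
  }
  lay <- withr::with_seed(seed,
    igraph::layout_with_fr(igraph::as_undirected(graph)))
  nodes <- tibble::tibble(name = igraph::V(graph)$name,
                          x = lay[, 1], y = lay[, 2])
  el <- igraph::as_data_frame(graph, what = "edges")
  el$x <- nodes$x[match(el$from, nodes$name)]
  el$y <- nodes$y[match(el$from, nodes$name)]
  el$xend <- nodes$x[match(el$to, nodes$name)]
  el$yend <- nodes$y[match(el$to, nodes$name)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = el,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data[[edge_colour]]),
      arrow = ggplot2::arrow(length = ggplot2::unit(2.5, "mm")),
      linewidth = 0.7) +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$name), size = 2.8) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::theme_void()
}

#' Box plots of descriptors normalized to their ruleset limits
#'
#' Each descriptor is divided by its Rule-of-Five upper bound (molecular
#' weight, logP, HBD, HBA) or Veber upper bound (rotatable bonds, TPSA),
#' so the dashed line at 1 marks the limit.
#'
#' @param descriptors Descriptor tibble from [compute_descriptors()].
#' @return A ggplot.
#' @export
plot_ruleset_conformance <- function(descriptors) {
  limits <- c(mw = 500, logp = 5, hbd = 5, hba = 10, rbc = 10, tpsa = 140)
  df <- descriptors |>
    dplyr::select(dplyr::all_of(names(limits))) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "descriptor",
                        values_to = "value") |>
    dplyr::mutate(normalized = .data$value / limits[.data$descriptor])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$descriptor,
                                   y = .data$normalized)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "value / ruleset upper limit") +
    ggplot2::theme_minimal()
}
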