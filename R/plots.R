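# ggplot2 views. Network drawings use a force-directed layout computed with a
# fixed internal seed so the same network always draws the same picture.

#' Plot a chromatin interaction network
#'
#' Force-directed layout; nodes colored by connected component (or by
#' membership in one annotation), edge width scaled by supporting PET count,
#' mirroring the usual drawing of chromatin networks where edge width shows
#' interaction support.
#'
#' @param object A `chia_net`.
#' @param highlight Optional annotation name; nodes carrying it are colored.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chia_net <- function(object, highlight = NULL, ...) {
  nodes <- object$nodes
  edges <- object$edges
  if (nrow(nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::ggtitle("empty network"))
  }
  g <- as_igraph(object)
  xy <- withr::with_seed(42L, igraph::layout_with_fr(g))
  lay <- tibble(id = nodes$id, x = xy[, 1], y = xy[, 2],
                component = factor(nodes$component))
  if (!is.null(highlight)) {
    ids <- annotation_nodes(object, highlight)
    lay$fill_by <- ifelse(lay$id %in% ids, highlight, "other")
  } else {
    lay$fill_by <- lay$component
  }
  seg <- NULL
  if (nrow(edges) > 0) {
    seg <- tibble(
      x = lay$x[match(edges$node_a, lay$id)],
      y = lay$y[match(edges$node_a, lay$id)],
      xend = lay$x[match(edges$node_b, lay$id)],
      yend = lay$y[match(edges$node_b, lay$id)],
      pet = edges$pet_count
    )
  }
  p <- ggplot2::ggplot()
  if (!is.null(seg)) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$pet),
      color = "grey60"
    ) +
      ggplot2::scale_linewidth_continuous(range = c(0.2, 1.6), name = "PETs")
  }
  p +
    ggplot2::geom_point(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$fill_by), size = 2
    ) +
    ggplot2::labs(color = if (is.null(highlight)) "component" else "annotation") +
    ggplot2::theme_void()
}

#' Centrality distributions
#'
#' Faceted histograms of the four node centralities, a quick way to spot hub
#' and spoke structure in the network.
#'
#' @param centralities A [centrality()] tibble.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_centrality <- function(centralities, bins = 20) {
  long <- tidyr::pivot_longer(
    centralities,
    cols = c("degree", "betweenness", "closeness", "harmonic"),
    names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", color = "white") +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = NULL, y = "nodes") +
    ggplot2::theme_minimal()
}

#' Permutation null against the observed count
#'
#' @param x An `enrichment_result` from [pair_enrichment()].
#' @param ... Unused.
#' @return A ggplot object: histogram of permuted A-B edge counts with the
#'   observed count marked.
#' @export
autoplot.enrichment_result <- function(x, ...) {
  ggplot2::ggplot(tibble(count = x$perm_null), ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", color = "white") +
    ggplot2::geom_vline(xintercept = x$observed, color = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      x = paste0(x$annotation_a, "-", x$annotation_b, " edges per permutation"),
      y = "permutations",
      title = paste0("observed = ", x$observed, ", permutation p = ",
                     signif(x$p_permutation, 3))
    ) +
    ggplot2::theme_minimal()
}
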