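# Node centralities on the unweighted simple graph. PET counts are evidence
# for edges, not distances, so every shortest-path notion here counts hops.

#' Node centrality measures
#'
#' Computes, per node, the four standard centralities used to prioritize loci
#' in chromatin interaction networks:
#'
#' * `degree` — number of incident edges (interactions to distinct partners).
#' * `betweenness` — unnormalized shortest-path betweenness; each unordered
#'   node pair is counted once and tied shortest paths share credit
#'   fractionally (Brandes).
#' * `closeness` — component-scoped: for a node `v` in a component of size
#'   `k > 1`, `(k - 1) / sum of distances to the component`; isolated
#'   nodes get 0.
#' * `harmonic` — network-scoped mean reciprocal distance,
#'   `sum(1 / d(v, u)) / (N - 1)` over all other nodes with `1/Inf = 0`;
#'   robust to disconnected graphs.
#'
#' @param network A `chia_net`.
#' @param normalize_betweenness If `TRUE`, divide each node's betweenness by
#'   `(k - 1) * (k - 2) / 2` within its component (0 for components smaller
#'   than 3).
#' @return Tibble: `node`, `chrom`, `start`, `end`, `component`, `degree`,
#'   `betweenness`, `closeness`, `harmonic`.
#' @export
centrality <- function(network, normalize_betweenness = FALSE) {
  stopifnot(inherits(network, "chia_net"))
  nodes <- network$nodes
  n <- nrow(nodes)
  if (n == 0) {
    return(tibble(node = integer(), chrom = character(), start = integer(),
                  end = integer(), component = integer(), degree = integer(),
                  betweenness = double(), closeness = double(),
                  harmonic = double()))
  }
  g <- as_igraph(network)
  deg <- as.integer(igraph::degree(g))
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  cls <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
  cls[!is.finite(cls)] <- 0 # isolated nodes
  har <- if (n < 2) rep(0, n) else {
    igraph::harmonic_centrality(g, normalized = TRUE)
  }
  if (normalize_betweenness) {
    comp_sizes <- table(nodes$component)
    k <- as.integer(comp_sizes[as.character(nodes$component)])
    denom <- (k - 1) * (k - 2) / 2
    btw <- ifelse(denom > 0, btw / denom, 0)
  }
  tibble(
    node = nodes$id, chrom = nodes$chrom, start = nodes$start,
    end = nodes$end, component = nodes$component,
    degree = deg, betweenness = as.double(btw),
    closeness = as.double(cls), harmonic = as.double(har)
  )
}

#' Write the centrality table to CSV
#'
#' @param network A `chia_net`.
#' @param path Output path.
#' @param ... Passed to [centrality()].
#' @return `path`, invisibly.
#' @export
write_centrality <- function(network, path, ...) {
  utils::write.csv(centrality(network, ...), path, row.names = FALSE)
  invisible(path)
}
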