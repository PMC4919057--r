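# Network construction. Two approaches, following how chromatin interaction
# networks are usually assembled from paired-anchor data:
#   1. nodes = merged overlapping interaction anchors;
#   2. nodes = (merged) open-chromatin peaks that overlap at least one anchor,
#      which also filters interactions whose anchors fall outside peaks.
# Edges connect the nodes that the two anchors of an interaction land in,
# weighted by the number of supporting interactions and their summed PET
# counts. The graph is simple: self-loops (both anchors in one node) are not
# stored as edges, only counted in the build statistics.

new_chia_net <- function(nodes, edges, stats = NULL, params = list(),
                         annotations = list()) {
  structure(
    list(nodes = nodes, edges = edges, stats = stats,
         annotations = annotations, params = params),
    class = "chia_net"
  )
}

#' Merge interaction anchors into network nodes
#'
#' Approach-1 node definition: overlapping anchors (>= 1 shared bp, half-open)
#' are collapsed so that every anchor is contained in exactly one node.
#' Bookended anchors stay separate. Node ids are dense `0..N-1` in
#' (chrom, start) order.
#'
#' @param anchors Interval tibble of anchor coordinates.
#' @return Node tibble: `id`, `chrom`, `start`, `end`, `source`.
#' @export
merge_anchors <- function(anchors) {
  merged <- merge_intervals(anchors)
  tibble(
    id = seq_len(nrow(merged)) - 1L,
    chrom = merged$chrom, start = merged$start, end = merged$end,
    source = rep("merged_anchors", nrow(merged))
  )
}

#' Define nodes from open-chromatin peaks
#'
#' Approach-2 node definition: peaks are merged (in case the caller's peak set
#' has internal overlaps) and every merged peak that overlaps at least one
#' anchor becomes a node. Anchors overlapping no peak map to nothing, which
#' downstream filters the corresponding interactions as potential false
#' positives. An anchor spanning several peaks maps to all of them.
#'
#' @param anchors Interval tibble of anchor coordinates.
#' @param peaks Interval tibble (e.g. DNase-seq or ATAC-seq open-chromatin
#'   sites).
#' @return A list with `nodes` (tibble `id`, `chrom`, `start`, `end`,
#'   `source = "peak"`) and `anchor_map` (tibble `anchor` — 1-based row index
#'   into `anchors` — and `node`).
#' @export
define_nodes_from_peaks <- function(anchors, peaks) {
  anchors <- validate_intervals(anchors, "anchor")
  peaks <- merge_intervals(peaks)
  if (nrow(peaks) == 0) {
    warn("empty peak set: no nodes can be defined, all interactions will be filtered")
    return(list(
      nodes = tibble(id = integer(), chrom = character(), start = integer(),
                     end = integer(), source = character()),
      anchor_map = tibble(anchor = integer(), node = integer())
    ))
  }
  ov <- find_overlaps(anchors, peaks)
  used_peaks <- sort(unique(ov$subject))
  nodes <- tibble(
    id = seq_along(used_peaks) - 1L,
    chrom = peaks$chrom[used_peaks],
    start = peaks$start[used_peaks],
    end = peaks$end[used_peaks],
    source = rep("peak", length(used_peaks))
  )
  peak_to_node <- rep(NA_integer_, nrow(peaks))
  peak_to_node[used_peaks] <- nodes$id
  list(nodes = nodes,
       anchor_map = tibble(anchor = ov$query, node = peak_to_node[ov$subject]))
}

#' Build weighted edges from interactions
#'
#' Every interaction contributes the unordered node pairs formed by the nodes
#' its two anchors map to; pairs with identical nodes are self-loops and are
#' only counted. Per node pair, `interaction_count` adds 1 and `pet_count`
#' adds the interaction's PET count for each contributing interaction.
#'
#' @param interactions Interaction tibble ([read_interactions()] shape).
#' @param nodes Node tibble.
#' @param anchor_map Mapping from stacked anchor rows to node ids: a tibble
#'   with `anchor` in `1..2*nrow(interactions)` (anchor 1 of interaction `i`
#'   is row `i`, anchor 2 is row `nrow + i`) and `node`. When `NULL`, the
#'   mapping is computed by overlapping the anchors with `nodes`.
#' @return Edge tibble `node_a < node_b`, `interaction_count`, `pet_count`,
#'   `trans`, with an `"interaction_status"` attribute: per-interaction
#'   classification in `c("used", "self_loop", "unmapped")`.
#' @export
build_edges <- function(interactions, nodes, anchor_map = NULL) {
  n_int <- nrow(interactions)
  if (is.null(anchor_map)) {
    stacked <- stack_anchors(interactions)
    ov <- find_overlaps(stacked, nodes)
    anchor_map <- tibble(anchor = ov$query, node = nodes$id[ov$subject])
  }
  status <- rep("unmapped", n_int)
  empty_edges <- tibble(node_a = integer(), node_b = integer(),
                        interaction_count = integer(), pet_count = integer(),
                        trans = logical())
  if (n_int == 0) {
    return(structure(empty_edges, interaction_status = character()))
  }
  side <- ifelse(anchor_map$anchor > n_int, 2L, 1L)
  inter <- ifelse(side == 2L, anchor_map$anchor - n_int, anchor_map$anchor)
  m1 <- tibble(inter = inter[side == 1L], node = anchor_map$node[side == 1L])
  m2 <- tibble(inter = inter[side == 2L], node = anchor_map$node[side == 2L])
  pairs <- inner_join(m1, m2, by = "inter", relationship = "many-to-many")
  mapped_both <- intersect(unique(m1$inter), unique(m2$inter))
  status[mapped_both] <- "self_loop"  # upgraded to "used" below if any real pair
  pairs <- pairs |>
    mutate(node_a = pmin(.data$node.x, .data$node.y),
           node_b = pmax(.data$node.x, .data$node.y)) |>
    filter(.data$node_a != .data$node_b) |>
    distinct(.data$inter, .data$node_a, .data$node_b)
  status[unique(pairs$inter)] <- "used"
  if (nrow(pairs) == 0) {
    return(structure(empty_edges, interaction_status = status))
  }
  pairs$pet <- interactions$pet_count[pairs$inter]
  chrom_of <- setNames(nodes$chrom, as.character(nodes$id))
  edges <- pairs |>
    group_by(.data$node_a, .data$node_b) |>
    summarise(interaction_count = dplyr::n(),
              pet_count = as.integer(sum(.data$pet)), .groups = "drop") |>
    mutate(trans = chrom_of[as.character(.data$node_a)] !=
             chrom_of[as.character(.data$node_b)]) |>
    arrange(.data$node_a, .data$node_b)
  structure(edges, interaction_status = status)
}

stack_anchors <- function(interactions) {
  bind_rows(
    tibble(chrom = interactions$chrom1, start = interactions$start1,
           end = interactions$end1),
    tibble(chrom = interactions$chrom2, start = interactions$start2,
           end = interactions$end2)
  )
}

#' Label connected components
#'
#' Components of the undirected simple graph, labelled `0..C-1` in ascending
#' order of each component's smallest node id, so labels are deterministic.
#'
#' @param nodes Node tibble.
#' @param edges Edge tibble.
#' @return Integer vector of component labels aligned with `nodes` rows.
#' @export
network_components <- function(nodes, edges) {
  n <- nrow(nodes)
  if (n == 0) return(integer())
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(edges$node_a + 1L, edges$node_b + 1L))
  }
  memb <- igraph::components(g)$membership
  # relabel by minimum contained node id (node ids are row order here)
  first_seen <- match(unique(memb), memb)
  rank <- match(memb, memb[sort(first_seen)])
  as.integer(rank - 1L)
}

#' Build a chromatin interaction network
#'
#' The top-level constructor. Interactions below `min_pet` are dropped first;
#' nodes are then defined from the remaining anchors alone (`peaks = NULL`,
#' approach 1) or from open-chromatin peaks (approach 2); edges are built and
#' aggregated; connected components labelled. Build statistics account for
#' every input interaction:
#' `input = used + pet_filtered + self_loop + unmapped`.
#'
#' @param interactions Interaction tibble ([read_interactions()] shape).
#' @param peaks Optional interval tibble of peaks; switches to approach 2.
#' @param min_pet Minimum PET count an interaction needs to be used
#'   (default 1 = no filtering).
#' @return A `chia_net` object: `nodes`, `edges`, `stats`, `annotations`
#'   (empty), `params`.
#' @examples
#' ints <- tibble::tibble(
#'   chrom1 = "chr1", start1 = c(100, 120, 5000), end1 = c(300, 320, 5200),
#'   chrom2 = "chr1", start2 = c(9000, 9100, 9050), end2 = c(9200, 9300, 9250),
#'   pet_count = c(2L, 3L, 4L)
#' )
#' net <- build_network(ints)
#' glance(net)
#' @export
build_network <- function(interactions, peaks = NULL, min_pet = 1L) {
  interactions <- as_tibble(interactions)
  if (!"pet_count" %in% names(interactions)) interactions$pet_count <- 1L
  if (!"trans" %in% names(interactions)) {
    interactions$trans <- interactions$chrom1 != interactions$chrom2
  }
  if (min_pet < 1) abort("min_pet must be >= 1")
  n_input <- nrow(interactions)
  keep <- interactions$pet_count >= min_pet
  n_pet_filtered <- sum(!keep)
  used_int <- interactions[keep, , drop = FALSE]

  approach <- if (is.null(peaks)) "merged_anchors" else "peaks"
  if (is.null(peaks)) {
    anchors <- stack_anchors(used_int)
    nodes <- merge_anchors(anchors)
    anchor_map <- NULL
  } else {
    def <- define_nodes_from_peaks(stack_anchors(used_int), peaks)
    nodes <- def$nodes
    anchor_map <- def$anchor_map
  }
  edges <- build_edges(used_int, nodes, anchor_map)
  status <- attr(edges, "interaction_status")
  attr(edges, "interaction_status") <- NULL
  stats <- list(
    input = n_input,
    pet_filtered = n_pet_filtered,
    self_loop = sum(status == "self_loop"),
    unmapped = sum(status == "unmapped"),
    used = sum(status == "used")
  )
  if (stats$used == 0 && n_input > 0) {
    warn("no interactions survived filtering; network is empty")
  }
  nodes$component <- network_components(nodes, edges)
  new_chia_net(nodes = nodes, edges = edges, stats = stats,
               params = list(approach = approach, min_pet = min_pet))
}

#' Build a network directly from a node count and an edge list
#'
#' Constructs a `chia_net` with synthetic, non-overlapping node intervals from
#' an explicit graph topology. Useful for simulation studies and for applying
#' the network measures to graphs that did not come from interaction files.
#'
#' @param n_nodes Number of nodes; ids are `0..n_nodes-1`.
#' @param edges Two-column data frame / matrix of 0-based node id pairs
#'   (self-pairs are dropped, duplicates collapsed).
#' @param chrom Chromosome name used for the synthetic intervals.
#' @return A `chia_net`.
#' @export
network_from_edges <- function(n_nodes, edges = NULL, chrom = "chr1") {
  n_nodes <- as.integer(n_nodes)
  nodes <- tibble(
    id = seq_len(n_nodes) - 1L, chrom = chrom,
    start = (seq_len(n_nodes) - 1L) * 1000L,
    end = (seq_len(n_nodes) - 1L) * 1000L + 500L,
    source = "synthetic"
  )
  if (is.null(edges) || NROW(edges) == 0) {
    etbl <- tibble(node_a = integer(), node_b = integer(),
                   interaction_count = integer(), pet_count = integer(),
                   trans = logical())
  } else {
    edges <- as.data.frame(edges)
    a <- as.integer(pmin(edges[[1]], edges[[2]]))
    b <- as.integer(pmax(edges[[1]], edges[[2]]))
    keep <- a != b
    if (any(a < 0) || any(b >= n_nodes)) abort("edge endpoint outside 0..n_nodes-1")
    etbl <- distinct(tibble(node_a = a[keep], node_b = b[keep])) |>
      mutate(interaction_count = 1L, pet_count = 1L, trans = FALSE) |>
      arrange(.data$node_a, .data$node_b)
  }
  nodes$component <- network_components(nodes, etbl)
  new_chia_net(nodes = nodes, edges = etbl,
               stats = list(input = nrow(etbl), pet_filtered = 0L,
                            self_loop = 0L, unmapped = 0L, used = nrow(etbl)),
               params = list(approach = "explicit_edges", min_pet = 1L))
}

#' Convert a network to an igraph graph
#'
#' Vertices are in node-id order (vertex `i` is node id `i - 1`); edge
#' attributes `interaction_count` and `pet_count` are carried over. The graph
#' is undirected and simple.
#'
#' @param network A `chia_net`.
#' @return An igraph object.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "chia_net"))
  g <- igraph::make_empty_graph(n = nrow(network$nodes), directed = FALSE)
  if (nrow(network$edges) > 0) {
    g <- igraph::add_edges(
      g, rbind(network$edges$node_a + 1L, network$edges$node_b + 1L),
      attr = list(interaction_count = network$edges$interaction_count,
                  pet_count = network$edges$pet_count)
    )
  }
  igraph::set_vertex_attr(g, "name", value = as.character(network$nodes$id))
}

#' @export
print.chia_net <- function(x, ...) {
  cat("<chia_net> chromatin interaction network\n")
  cat("  nodes: ", nrow(x$nodes), "  edges: ", nrow(x$edges),
      "  components: ", n_components(x), "\n", sep = "")
  cat("  node definition: ", x$params$approach %||% "unknown", "\n", sep = "")
  if (!is.null(x$stats)) {
    cat("  interactions: ", x$stats$input, " input / ", x$stats$used,
        " used / ", x$stats$pet_filtered, " below min PET / ",
        x$stats$self_loop, " self-loop / ", x$stats$unmapped, " unmapped\n",
        sep = "")
  }
  if (length(x$annotations) > 0) {
    cat("  annotations: ", paste(names(x$annotations), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of connected components
#' @param network A `chia_net`.
#' @return Integer component count.
#' @export
n_components <- function(network) {
  if (nrow(network$nodes) == 0) 0L else length(unique(network$nodes$component))
}

#' Tidy a network into its node table
#'
#' @param x A `chia_net`.
#' @param ... Unused.
#' @return Node tibble with a `degree` column added.
#' @export
tidy.chia_net <- function(x, ...) {
  nodes <- x$nodes
  deg <- rep(0L, nrow(nodes))
  if (nrow(x$edges) > 0) {
    tab <- table(factor(c(x$edges$node_a, x$edges$node_b), levels = nodes$id))
    deg <- as.integer(tab)
  }
  nodes$degree <- deg
  nodes
}

#' One-row summary of a network
#'
#' @param x A `chia_net`.
#' @param ... Unused.
#' @return A one-row tibble: node/edge/component counts and the build
#'   statistics.
#' @export
glance.chia_net <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_components = n_components(x),
    n_input_interactions = x$stats$input %||% NA_integer_,
    n_used = x$stats$used %||% NA_integer_,
    n_pet_filtered = x$stats$pet_filtered %||% NA_integer_,
    n_self_loop = x$stats$self_loop %||% NA_integer_,
    n_unmapped = x$stats$unmapped %||% NA_integer_
  )
}

#' Serialize build statistics to JSON
#'
#' @param network A `chia_net`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
build_stats_json <- function(network, path = NULL) {
  js <- jsonlite::toJSON(network$stats, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
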