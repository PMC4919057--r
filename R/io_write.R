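# Writers. Coordinates go out exactly as they are held in memory: 0-based
# half-open, so write_*/read_* round-trip byte-stable tables.

#' Write interactions to BEDPE
#'
#' @param x Interaction tibble as produced by [read_interactions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(x, path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "pet_count")
  out <- x[, cols]
  if ("score" %in% names(x) && any(!is.na(x$score))) out$score <- x$score
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write intervals to BED
#' @param x Interval tibble (`chrom`, `start`, `end`, optional `name`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(x))
  readr::write_tsv(x[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a variant table (`chrom pos id`)
#' @param x Variant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(x, path) {
  cols <- intersect(c("chrom", "pos", "id"), names(x))
  readr::write_tsv(x[, cols], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a gene model table with a refGene-style header
#' @param x Gene tibble (`name`, `chrom`, `strand`, `tx_start`, `tx_end`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(x, path) {
  out <- tibble(name = x$name, chrom = x$chrom, strand = x$strand,
                txStart = x$tx_start, txEnd = x$tx_end)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_gene_list
#' @param x Character vector of gene symbols.
#' @param path Output path.
#' @export
write_gene_list <- function(x, path) {
  writeLines(x, path)
  invisible(path)
}

#' @rdname read_gene_pairs
#' @param x Tibble with `gene1`, `gene2`.
#' @export
write_gene_pairs <- function(x, path) {
  readr::write_tsv(x[, c("gene1", "gene2")], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

gml_quote <- function(x) paste0('"', gsub('"', "'", x), '"')

#' Export a network to Graph Modelling Language (GML)
#'
#' Writes the network in plain-text GML so it can be loaded into standard
#' graph tools (Cytoscape, igraph, networkx). Node blocks carry `id`, `label`
#' ("chrom:start-end"), `chrom`, `start`, `end`, `component` and a semicolon-
#' joined `annotations` string naming the annotation sets that hit the node;
#' edge blocks carry `interaction_count`, `pet_count` and `trans` (0/1).
#'
#' @param network A [build_network()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gml <- function(network, path) {
  stopifnot(inherits(network, "chia_net"))
  con <- tryCatch(suppressWarnings(file(path, open = "wt")),
                  error = function(e) abort(paste0("cannot write GML to ", path,
                                                   ": ", conditionMessage(e))))
  on.exit(close(con), add = TRUE)
  nodes <- network$nodes
  edges <- network$edges
  ann_by_node <- annotation_names_by_node(network)
  writeLines(c("graph [", "  directed 0"), con)
  if (nrow(nodes) > 0) {
    ann <- ann_by_node[as.character(nodes$id)]
    ann <- ifelse(is.na(ann), "", ann)
    blocks <- paste0(
      "  node [\n",
      "    id ", nodes$id, "\n",
      "    label ", gml_quote(interval_label(nodes$chrom, nodes$start, nodes$end)), "\n",
      "    chrom ", gml_quote(nodes$chrom), "\n",
      "    start ", nodes$start, "\n",
      "    end ", nodes$end, "\n",
      "    component ", nodes$component, "\n",
      "    annotations ", gml_quote(ann), "\n",
      "  ]"
    )
    writeLines(blocks, con)
  }
  if (nrow(edges) > 0) {
    blocks <- paste0(
      "  edge [\n",
      "    source ", edges$node_a, "\n",
      "    target ", edges$node_b, "\n",
      "    interaction_count ", edges$interaction_count, "\n",
      "    pet_count ", edges$pet_count, "\n",
      "    trans ", as.integer(edges$trans), "\n",
      "  ]"
    )
    writeLines(blocks, con)
  }
  writeLines("]", con)
  invisible(path)
}

# semicolon-joined annotation names per node id (character-keyed)
annotation_names_by_node <- function(network) {
  if (length(network$annotations) == 0) return(character())
  hits <- purrr::imap(network$annotations,
                      function(a, nm) tibble(node = a$hits$node, ann = nm))
  hits <- distinct(bind_rows(hits))
  agg <- hits |>
    group_by(.data$node) |>
    summarise(ann = paste(sort(unique(.data$ann)), collapse = ";"))
  setNames(agg$ann, as.character(agg$node))
}

#' Load a network from a GML file written by [write_gml()]
#'
#' Parses the file with igraph's GML reader and rebuilds the node/edge tables.
#' Build statistics are not stored in GML and come back as `NULL`; annotation
#' sets are restored as node memberships (the per-node feature records are not
#' serialized, the node label stands in as the feature id).
#'
#' @param path Path to a GML file.
#' @return A `chia_net` object.
#' @export
read_gml <- function(path) {
  g <- igraph::read_graph(path, format = "gml")
  n <- igraph::vcount(g)
  va <- function(nm, default) {
    if (nm %in% igraph::vertex_attr_names(g)) igraph::vertex_attr(g, nm) else default
  }
  nodes <- tibble(
    id = as.integer(va("id", seq_len(n) - 1L)),
    chrom = as.character(va("chrom", rep("?", n))),
    start = as.integer(va("start", rep(0L, n))),
    end = as.integer(va("end", rep(1L, n))),
    source = "gml",
    component = as.integer(va("component", rep(0L, n)))
  )
  el <- igraph::as_edgelist(g, names = FALSE)
  ea <- function(nm, default) {
    if (nm %in% igraph::edge_attr_names(g)) igraph::edge_attr(g, nm) else default
  }
  m <- nrow(el)
  a <- nodes$id[el[, 1]]; b <- nodes$id[el[, 2]]
  edges <- tibble(
    node_a = pmin(a, b), node_b = pmax(a, b),
    interaction_count = as.integer(ea("interaction_count", rep(1L, m))),
    pet_count = as.integer(ea("pet_count", rep(1L, m))),
    trans = as.logical(as.integer(ea("trans", rep(0L, m))))
  ) |> arrange(.data$node_a, .data$node_b)
  net <- new_chia_net(nodes = nodes, edges = edges, stats = NULL,
                      params = list(origin = path))
  ann <- va("annotations", rep("", n))
  ann_names <- unique(unlist(strsplit(ann[nzchar(ann)], ";", fixed = TRUE)))
  for (nm in ann_names) {
    idx <- grepl(paste0("(^|;)", nm, "(;|$)"), ann)
    net$annotations[[nm]] <- list(
      kind = "gml",
      hits = tibble(node = nodes$id[idx],
                    feature = interval_label(nodes$chrom[idx], nodes$start[idx],
                                             nodes$end[idx]))
    )
  }
  net
}

#' Write discovered target paths to CSV
#'
#' Writes the table produced by [discover_targets()] in the shape of a
#' target-discovery report: one row per (source, target gene, path), columns
#' `source_node`, `source_annotation`, `target_node`, `target_gene`,
#' `hop_distance`, `path` (node ids joined by ">"), `classification`.
#' Rows are sorted by (source_node, hop_distance, target_gene) so output is
#' stable across runs.
#'
#' @param targets A [discover_targets()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_target_table <- function(targets, path) {
  cols <- c("source_node", "source_annotation", "target_node", "target_gene",
            "hop_distance", "path", "classification")
  out <- as_tibble(targets)[, cols]
  out <- arrange(out, .data$source_node, .data$hop_distance,
                 .data$target_gene, .data$path)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
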