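# Target discovery: exhaustive shortest paths from source-annotated nodes
# (e.g. nodes harboring non-coding variants) to target-annotated nodes (e.g.
# nodes overlapping gene promoters), with genes classified as direct targets
# (same node or one edge away) or indirect targets (2-4 edges away by
# default) by their minimum hop distance.

resolve_node_set <- function(network, x, what) {
  ids <- if (is.character(x) && length(x) == 1) {
    annotation_nodes(network, x)
  } else {
    sort(unique(as.integer(x)))
  }
  if (length(ids) == 0) abort(paste0(what, " node set is empty"))
  bad <- setdiff(ids, network$nodes$id)
  if (length(bad) > 0) {
    abort(paste0(what, " contains unknown node id(s): ",
                 paste(head(bad, 3), collapse = ", ")))
  }
  ids
}

#' All shortest paths between two node sets
#'
#' For every (source, target) pair at hop distance `<= max_dist`, returns the
#' distance and *all* tied shortest paths. Pairs in different components are
#' omitted. A node that is both source and target yields a distance-0 row
#' whose single path is the node itself.
#'
#' @param network A `chia_net`.
#' @param sources,targets Node-id vectors, or the name of an annotation on
#'   the network.
#' @param max_dist Maximum hop distance to report (default 4).
#' @param max_paths_per_pair Safety cap on tied paths retained per pair; a
#'   warning is emitted if it truncates.
#' @return Tibble: `source_node`, `target_node`, `hop_distance`, `n_paths`,
#'   `paths` (list column of integer node-id vectors).
#' @export
shortest_paths_between <- function(network, sources, targets, max_dist = 4L,
                                   max_paths_per_pair = 1000L) {
  stopifnot(inherits(network, "chia_net"))
  if (max_dist < 0) abort("max_dist must be >= 0")
  src <- resolve_node_set(network, sources, "sources")
  tgt <- resolve_node_set(network, targets, "targets")
  g <- as_igraph(network)
  rows <- list()
  truncated <- FALSE
  for (s in src) {
    d <- as.vector(igraph::distances(g, v = s + 1L, to = tgt + 1L))
    qual <- tgt[is.finite(d) & d <= max_dist]
    if (length(qual) == 0) next
    dq <- d[is.finite(d) & d <= max_dist]
    far <- qual[qual != s]
    path_list <- list()
    if (length(far) > 0) {
      asp <- igraph::all_shortest_paths(g, from = s + 1L, to = far + 1L)$res
      ends <- vapply(asp, function(p) as.integer(p[length(p)]) - 1L, integer(1))
      path_list <- split(lapply(asp, function(p) as.integer(p) - 1L), ends)
    }
    for (j in seq_along(qual)) {
      t <- qual[j]
      paths <- if (t == s) list(s) else path_list[[as.character(t)]]
      if (length(paths) > max_paths_per_pair) {
        truncated <- TRUE
        paths <- paths[seq_len(max_paths_per_pair)]
      }
      rows[[length(rows) + 1L]] <- tibble(
        source_node = s, target_node = t,
        hop_distance = as.integer(dq[j]),
        n_paths = length(paths), paths = list(paths)
      )
    }
  }
  if (truncated) {
    warn(paste0("some pairs had more than ", max_paths_per_pair,
                " tied shortest paths; path lists were truncated ",
                "(distances and classifications are unaffected)"))
  }
  if (length(rows) == 0) {
    return(tibble(source_node = integer(), target_node = integer(),
                  hop_distance = integer(), n_paths = integer(),
                  paths = list()))
  }
  arrange(bind_rows(rows), .data$source_node, .data$hop_distance,
          .data$target_node)
}

#' Classify target genes as direct or indirect
#'
#' Each gene is scored by its minimum hop distance over all its
#' promoter-bearing nodes and all sources: distance `<= direct_max` makes it
#' a direct target (this includes distance 0, a gene promoter in the same
#' node as the source); a distance within `indirect_range` makes it indirect;
#' genes only reachable beyond the range are excluded (returned via the
#' `"excluded"` attribute).
#'
#' @param paths A [shortest_paths_between()] tibble.
#' @param gene_hits Tibble mapping `node` to `feature` (gene symbol), e.g.
#'   [annotation_hits()] of a gene annotation.
#' @param direct_max Maximum hop distance of a direct target (default 1).
#' @param indirect_range Inclusive hop-distance range of indirect targets
#'   (default `c(2, 4)`).
#' @return Tibble `gene`, `distance` (minimum), `classification`
#'   (`"direct"` / `"indirect"`).
#' @export
classify_targets <- function(paths, gene_hits, direct_max = 1L,
                             indirect_range = c(2L, 4L)) {
  if (length(indirect_range) != 2 || indirect_range[1] > indirect_range[2]) {
    abort("indirect_range must be c(lo, hi) with lo <= hi")
  }
  if (direct_max >= indirect_range[1]) {
    abort("direct_max must be below the indirect range (bounds overlap)")
  }
  gene_hits <- as_tibble(gene_hits)
  if ("gene" %in% names(gene_hits) && !"feature" %in% names(gene_hits)) {
    gene_hits <- rename(gene_hits, feature = "gene")
  }
  hit <- inner_join(as_tibble(paths)[, c("target_node", "hop_distance")],
                    gene_hits, by = c(target_node = "node"),
                    relationship = "many-to-many")
  if (nrow(hit) == 0) {
    out <- tibble(gene = character(), distance = integer(),
                  classification = character())
    attr(out, "excluded") <- character()
    return(out)
  }
  per_gene <- hit |>
    group_by(gene = .data$feature) |>
    summarise(distance = min(.data$hop_distance), .groups = "drop")
  per_gene$classification <- dplyr::case_when(
    per_gene$distance <= direct_max ~ "direct",
    per_gene$distance >= indirect_range[1] &
      per_gene$distance <= indirect_range[2] ~ "indirect",
    TRUE ~ NA_character_
  )
  excluded <- per_gene$gene[is.na(per_gene$classification)]
  out <- per_gene |>
    filter(!is.na(.data$classification)) |>
    arrange(.data$distance, .data$gene)
  attr(out, "excluded") <- excluded
  out
}

#' Discover gene targets of annotated source nodes
#'
#' Convenience pipeline: enumerate all shortest paths from a source
#' annotation (e.g. variant-bearing nodes) to the nodes of a gene annotation,
#' classify genes as direct/indirect, and return one row per
#' (source node, target gene, tied path) ready for [write_target_table()].
#'
#' @param network A `chia_net` with both annotations attached.
#' @param sources Name of the source annotation (or node-id vector).
#' @param genes Name of a gene-kind annotation whose features are gene
#'   symbols.
#' @param direct_max,indirect_range See [classify_targets()].
#' @param max_paths_per_pair See [shortest_paths_between()].
#' @return Tibble: `source_node`, `source_annotation`, `target_node`,
#'   `target_gene`, `hop_distance`, `path` (ids joined by ">"),
#'   `classification`. The per-gene summary is attached as attribute
#'   `"classification"`.
#' @export
discover_targets <- function(network, sources, genes, direct_max = 1L,
                             indirect_range = c(2L, 4L),
                             max_paths_per_pair = 1000L) {
  gene_hits <- annotation_hits(network, genes)
  paths <- shortest_paths_between(network, sources, genes,
                                  max_dist = indirect_range[2],
                                  max_paths_per_pair = max_paths_per_pair)
  cls <- classify_targets(paths, gene_hits, direct_max, indirect_range)
  src_name <- if (is.character(sources) && length(sources) == 1) sources else "sources"
  rows <- paths |>
    inner_join(gene_hits, by = c(target_node = "node"),
               relationship = "many-to-many") |>
    inner_join(cls, by = c(feature = "gene"))
  out <- rows |>
    tidyr::unnest_longer(col = "paths") |>
    mutate(
      source_annotation = src_name,
      target_gene = .data$feature,
      path = vapply(.data$paths, paste, character(1), collapse = ">")
    ) |>
    select("source_node", "source_annotation", "target_node", "target_gene",
           "hop_distance", "path", "classification") |>
    arrange(.data$source_node, .data$hop_distance, .data$target_gene,
            .data$path)
  attr(out, "classification") <- cls
  out
}

#' Nearest-TSS baseline assignment
#'
#' The conventional baseline for variant-to-gene assignment in the absence of
#' chromatin interaction data: each variant is associated with the gene(s)
#' whose TSS is closest on the same chromosome; ties report all tied genes.
#'
#' @param variants Tibble `chrom`, `pos` (+ optional `id`).
#' @param genes Gene tibble ([read_gene_table()] shape).
#' @return Tibble `chrom`, `pos`, `id`, `gene`, `tss`, `distance`; variants
#'   on chromosomes with no gene are absent from the table and counted in the
#'   `"summary"` attribute.
#' @export
nearest_tss <- function(variants, genes) {
  v <- as_tibble(variants)
  if (!"id" %in% names(v)) v$id <- paste0(v$chrom, ":", v$pos)
  g <- validate_genes(genes)
  joined <- v |>
    mutate(.variant = row_number()) |>
    inner_join(g[, c("chrom", "name", "tss")], by = "chrom",
               relationship = "many-to-many") |>
    mutate(distance = abs(.data$pos - .data$tss))
  out <- joined |>
    group_by(.data$.variant) |>
    slice_min(.data$distance, with_ties = TRUE) |>
    ungroup() |>
    select("chrom", "pos", "id", gene = "name", "tss", "distance") |>
    arrange(.data$chrom, .data$pos, .data$gene)
  unmatched <- setdiff(seq_len(nrow(v)), unique(joined$.variant))
  attr(out, "summary") <- list(n_variants = nrow(v),
                               n_unmatched = length(unmatched),
                               unmatched_ids = v$id[unmatched])
  out
}
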