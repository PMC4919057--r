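# Node annotation: mapping feature sets (intervals, variants, genes/promoters,
# gene lists) onto the nodes they overlap. Annotations live inside the
# chia_net object as named sets, so downstream target discovery and
# enrichment can refer to them by name.

#' Promoter windows from gene models
#'
#' One promoter per gene, spanning the TSS plus/minus `flank_bp`:
#' `[TSS - flank, TSS + flank + 1)` in half-open coordinates, clamped at 0.
#' The `+1` keeps the TSS base itself inside the window on both strands, so a
#' promoter is `2 * flank + 1` bp wide unless clamped. The default 2 kb flank
#' matches the common "2 kb up/downstream of the TSS" promoter definition.
#'
#' @param genes Gene tibble ([read_gene_table()] shape).
#' @param flank_bp Flank size in bp on each side of the TSS (default 2000).
#' @return Tibble `chrom`, `start`, `end`, `gene`.
#' @export
promoters_from_genes <- function(genes, flank_bp = 2000L) {
  if (flank_bp < 0) abort("flank_bp must be >= 0")
  genes <- validate_genes(genes)
  out <- tibble(
    chrom = genes$chrom,
    start = pmax(0L, as.integer(genes$tss - flank_bp)),
    end = as.integer(genes$tss + flank_bp + 1L),
    gene = genes$name
  )
  distinct(out)
}

#' Annotate network nodes with a feature set
#'
#' Overlaps a feature set with the node intervals and records, under `name`,
#' which features hit which nodes. Feature kinds:
#'
#' * `"interval"` — tibble `chrom,start,end` (+ optional `name`), e.g. peaks
#'   or enhancer calls; whole-interval overlap.
#' * `"variant"` — tibble `chrom,pos` (+ optional `id`); a variant is a 1-bp
#'   interval `[pos, pos + 1)`, so a variant sitting exactly on a node's
#'   half-open `end` does not hit it.
#' * `"gene"` — gene-model tibble; genes annotate nodes through their
#'   promoter windows (`flank_bp`), matching how gene targets are defined in
#'   network target discovery. Use `kind = "interval"` on the transcript span
#'   for whole-gene-body overlap.
#' * `"promoter"` — precomputed [promoters_from_genes()] tibble.
#' * `"gene_list"` — character vector of gene symbols; requires `genes=` to
#'   locate them. Symbols absent from the gene table are skipped and counted
#'   in the annotation's `n_skipped`.
#'
#' @param network A `chia_net`.
#' @param features The feature set (see above).
#' @param name Annotation name; must be unique unless `overwrite = TRUE`.
#' @param kind Feature kind.
#' @param flank_bp Promoter flank for gene-based kinds.
#' @param genes Gene table, required for `kind = "gene_list"`.
#' @param overwrite Replace an existing annotation of the same name.
#' @return The network with the annotation added (pipe-friendly).
#' @export
annotate_nodes <- function(network, features, name,
                           kind = c("interval", "variant", "gene", "promoter",
                                    "gene_list"),
                           flank_bp = 2000L, genes = NULL, overwrite = FALSE) {
  stopifnot(inherits(network, "chia_net"))
  kind <- match.arg(kind)
  if (name %in% names(network$annotations) && !overwrite) {
    abort(paste0("annotation '", name, "' already exists; use overwrite = TRUE"))
  }
  n_skipped <- 0L
  if (kind == "interval") {
    iv <- validate_intervals(features, "feature")
    feat_id <- if ("name" %in% names(iv)) iv$name else
      interval_label(iv$chrom, iv$start, iv$end)
  } else if (kind == "variant") {
    v <- as_tibble(features)
    if (!all(c("chrom", "pos") %in% names(v))) {
      abort("variant features need columns chrom and pos")
    }
    iv <- tibble(chrom = v$chrom, start = as.integer(v$pos),
                 end = as.integer(v$pos) + 1L)
    feat_id <- if ("id" %in% names(v)) v$id else paste0(v$chrom, ":", v$pos)
  } else if (kind == "gene") {
    pr <- promoters_from_genes(features, flank_bp)
    iv <- pr[, c("chrom", "start", "end")]
    feat_id <- pr$gene
  } else if (kind == "promoter") {
    pr <- as_tibble(features)
    if (!"gene" %in% names(pr)) abort("promoter features need a gene column")
    iv <- validate_intervals(pr, "promoter")[, c("chrom", "start", "end")]
    feat_id <- pr$gene
  } else { # gene_list
    if (is.null(genes)) abort("kind = 'gene_list' requires genes = <gene table>")
    listed <- unique(as.character(unlist(features)))
    gtab <- validate_genes(genes)
    hit_genes <- gtab[gtab$name %in% listed, , drop = FALSE]
    n_skipped <- length(setdiff(listed, gtab$name))
    pr <- promoters_from_genes(hit_genes, flank_bp)
    iv <- pr[, c("chrom", "start", "end")]
    feat_id <- pr$gene
  }
  ov <- find_overlaps(iv, network$nodes)
  hits <- tibble(node = network$nodes$id[ov$subject],
                 feature = feat_id[ov$query]) |>
    distinct() |>
    arrange(.data$node, .data$feature)
  network$annotations[[name]] <- list(
    kind = kind,
    hits = hits,
    n_features = nrow(iv),
    n_features_hit = dplyr::n_distinct(hits$feature),
    n_skipped = n_skipped,
    flank_bp = if (kind %in% c("gene", "gene_list")) flank_bp else NULL
  )
  network
}

#' Node ids carrying an annotation
#'
#' @param network A `chia_net`.
#' @param name Annotation name.
#' @return Sorted integer vector of node ids with at least one hit.
#' @export
annotation_nodes <- function(network, name) {
  ann <- network$annotations[[name]]
  if (is.null(ann)) {
    abort(paste0("no annotation named '", name, "' (have: ",
                 paste(names(network$annotations), collapse = ", "), ")"))
  }
  sort(unique(ann$hits$node))
}

#' Annotation hits as a tibble
#'
#' @param network A `chia_net`.
#' @param name Annotation name.
#' @return Tibble `node`, `feature`.
#' @export
annotation_hits <- function(network, name) {
  ann <- network$annotations[[name]]
  if (is.null(ann)) abort(paste0("no annotation named '", name, "'"))
  ann$hits
}

#' Superimpose a gene-pair network onto the chromatin network
#'
#' Takes external gene-gene interactions (for example protein-protein
#' interaction pairs) and reports every pair of distinct nodes whose annotated
#' genes form one of the input pairs — i.e. where the external interaction can
#' be placed on the chromatin network. Pairs whose genes both land on a single
#' node are excluded; pairs with a gene absent from the annotation are skipped
#' and counted.
#'
#' @param network A `chia_net` with a gene-kind annotation.
#' @param gene_pairs Tibble `gene1`, `gene2`.
#' @param annotation Name of the gene annotation to look genes up in.
#' @return Tibble `node_a`, `node_b` (`node_a < node_b`), `gene1`, `gene2`;
#'   attribute `summary` holds `n_pairs`, `n_placed`, `n_skipped`.
#' @export
superimpose_gene_network <- function(network, gene_pairs, annotation) {
  hits <- annotation_hits(network, annotation)
  gene_nodes <- split(hits$node, hits$feature)
  placed <- vector("list", nrow(gene_pairs))
  n_skipped <- 0L
  for (i in seq_len(nrow(gene_pairs))) {
    g1 <- gene_pairs$gene1[i]; g2 <- gene_pairs$gene2[i]
    n1 <- gene_nodes[[g1]]; n2 <- gene_nodes[[g2]]
    if (is.null(n1) || is.null(n2)) {
      n_skipped <- n_skipped + 1L
      next
    }
    grid <- expand.grid(a = n1, b = n2, KEEP.OUT.ATTRS = FALSE)
    grid <- grid[grid$a != grid$b, , drop = FALSE]
    if (nrow(grid) == 0) next
    placed[[i]] <- tibble(node_a = pmin(grid$a, grid$b),
                          node_b = pmax(grid$a, grid$b),
                          gene1 = g1, gene2 = g2) |> distinct()
  }
  out <- bind_rows(placed)
  if (nrow(out) == 0) {
    out <- tibble(node_a = integer(), node_b = integer(),
                  gene1 = character(), gene2 = character())
  }
  out <- arrange(out, .data$node_a, .data$node_b, .data$gene1, .data$gene2)
  attr(out, "summary") <- list(n_pairs = nrow(gene_pairs),
                               n_placed = dplyr::n_distinct(
                                 paste(out$gene1, out$gene2)),
                               n_skipped = n_skipped)
  out
}
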