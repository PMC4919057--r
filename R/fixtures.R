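# Synthetic fixture generator. Emits toy-scale versions of every input the
# package consumes (interactions, peaks, variants, gene table, gene lists,
# gene pairs) with planted ground truth: a known number of connected
# components, and source-variant -> target-gene pairs wired at exact hop
# distances. Planted paths are realized as dedicated chain components, so the
# planted distance cannot be short-circuited by random background edges.

#' Specify a synthetic fixture
#'
#' Builds the parameter object consumed by [generate_fixture()]. Defaults
#' describe a small but non-trivial network: a handful of random components
#' with geometric PET counts, plus chain components carrying the planted
#' variant-to-gene paths.
#'
#' @param n_components Number of random background components.
#' @param nodes_per_component Inclusive range of nodes per component.
#' @param edge_density Probability of each extra (non-spanning-tree) edge
#'   within a component, in (0, 1].
#' @param pet_geom_prob PET counts are `1 + rgeom(pet_geom_prob)`.
#' @param anchor_width_bp Inclusive range of node/anchor widths in bp.
#' @param n_variants Background variants placed inside random background
#'   nodes.
#' @param n_genes Background genes with TSS at random background node
#'   centers.
#' @param n_decoy_peaks Peaks placed in gaps so they overlap no anchor (they
#'   must not become nodes under peak-based construction).
#' @param planted_paths List of lists with a `hop` element each: one planted
#'   variant-to-gene path per entry, at exactly that hop distance.
#' @param flank_bp Promoter flank assumed when spacing nodes so that
#'   promoters never leak onto neighboring nodes.
#' @param seed Integer seed; fixed seed implies byte-identical output files.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_components = 3L, nodes_per_component = c(4L, 8L),
                         edge_density = 0.3, pet_geom_prob = 0.5,
                         anchor_width_bp = c(600L, 1200L), n_variants = 5L,
                         n_genes = 12L, n_decoy_peaks = 4L,
                         planted_paths = list(list(hop = 1L), list(hop = 3L)),
                         flank_bp = 2000L, seed = 1L) {
  spec <- list(n_components = as.integer(n_components),
               nodes_per_component = as.integer(nodes_per_component),
               edge_density = edge_density, pet_geom_prob = pet_geom_prob,
               anchor_width_bp = as.integer(anchor_width_bp),
               n_variants = as.integer(n_variants),
               n_genes = as.integer(n_genes),
               n_decoy_peaks = as.integer(n_decoy_peaks),
               planted_paths = planted_paths,
               flank_bp = as.integer(flank_bp), seed = as.integer(seed))
  if (spec$n_components < 0 || spec$n_variants < 0 || spec$n_genes < 0 ||
      spec$n_decoy_peaks < 0) {
    abort("fixture counts must be >= 0")
  }
  if (spec$edge_density <= 0 || spec$edge_density > 1) {
    abort("edge_density must be in (0, 1]")
  }
  if (length(spec$nodes_per_component) != 2 ||
      spec$nodes_per_component[1] < 1 ||
      spec$nodes_per_component[1] > spec$nodes_per_component[2]) {
    abort("nodes_per_component must be c(lo, hi), lo >= 1")
  }
  hops <- vapply(spec$planted_paths, function(p) as.integer(p$hop), integer(1))
  if (any(!is.finite(hops)) || any(hops < 0)) {
    abort("planted path hop distances must be finite and >= 0")
  }
  max_chain <- max(spec$nodes_per_component[2] * 10L, 100L)
  if (any(hops + 1L > max_chain)) {
    abort("a planted path is longer than the fixture scale allows")
  }
  structure(spec, class = "fixture_spec")
}

#' Generate a synthetic fixture
#'
#' Realizes a [fixture_spec()]: builds the planted network geometry, samples
#' interactions, and (optionally) writes every file format the package reads.
#' Rebuilding the network from the emitted files reproduces the planted
#' component count and the planted variant-to-gene hop distances exactly.
#'
#' @param spec A `fixture_spec` (or arguments for one via `...`).
#' @param dir Optional directory; when given, files are written there and
#'   their paths returned under `$files`.
#' @param ... Used to build a spec when `spec` is missing.
#' @return List with tibbles `interactions`, `peaks`, `variants`, `genes`,
#'   `gene_list`, `gene_pairs`, and `truth` (planted component count, node
#'   count, and a tibble of planted variant/gene/hop triples).
#' @export
generate_fixture <- function(spec = fixture_spec(...), dir = NULL, ...) {
  stopifnot(inherits(spec, "fixture_spec"))
  fx <- withr::with_seed(spec$seed, build_fixture_tables(spec))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- list(
      interactions = file.path(dir, "interactions.bedpe"),
      peaks = file.path(dir, "peaks.bed"),
      variants = file.path(dir, "variants.tsv"),
      genes = file.path(dir, "genes.tsv"),
      gene_list = file.path(dir, "gene_list.txt"),
      gene_pairs = file.path(dir, "gene_pairs.tsv")
    )
    write_interactions(fx$interactions, files$interactions)
    write_bed(fx$peaks, files$peaks)
    write_variants(fx$variants, files$variants)
    write_gene_table(fx$genes, files$genes)
    write_gene_list(fx$gene_list, files$gene_list)
    write_gene_pairs(fx$gene_pairs, files$gene_pairs)
    fx$files <- files
  }
  fx
}

build_fixture_tables <- function(spec) {
  chroms <- paste0("chr", 1:5)
  hops <- vapply(spec$planted_paths, function(p) as.integer(p$hop), integer(1))
  # a chain needs hop+1 nodes; a hop-0 plant still gets a 2-node component so
  # that its node is connected by at least one interaction and survives the
  # file round trip
  comp_sizes <- c(
    if (spec$n_components > 0)
      sample(seq(spec$nodes_per_component[1], spec$nodes_per_component[2]),
             spec$n_components, replace = TRUE),
    pmax(hops + 1L, 2L)
  )
  comp_kind <- c(rep("background", spec$n_components),
                 rep("chain", length(hops)))
  n_comp <- length(comp_sizes)

  # place nodes: one cursor per chromosome, wide gaps so promoters of one
  # node can never reach a neighboring node
  gap <- 2L * spec$flank_bp + 6000L
  cursor <- setNames(rep(50000L, length(chroms)), chroms)
  nodes <- vector("list", n_comp)
  for (ci in seq_len(n_comp)) {
    k <- comp_sizes[ci]
    chrom <- chroms[(ci - 1L) %% length(chroms) + 1L]
    widths <- sample(seq(spec$anchor_width_bp[1], spec$anchor_width_bp[2]),
                     k, replace = TRUE)
    starts <- integer(k)
    for (j in seq_len(k)) {
      starts[j] <- cursor[chrom]
      cursor[chrom] <- cursor[chrom] + widths[j] + gap
    }
    nodes[[ci]] <- tibble(comp = ci, local = seq_len(k), chrom = chrom,
                          start = starts, end = starts + widths)
  }
  nodes <- bind_rows(nodes)
  nodes$gid <- seq_len(nrow(nodes))
  nodes$center <- as.integer(floor((nodes$start + nodes$end) / 2))

  # component topologies
  edges <- list()
  for (ci in seq_len(n_comp)) {
    k <- comp_sizes[ci]
    gids <- nodes$gid[nodes$comp == ci]
    if (k < 2) next
    if (comp_kind[ci] == "chain") {
      edges[[ci]] <- tibble(a = gids[-k], b = gids[-1])
    } else {
      tree_to <- vapply(2:k, function(j) sample.int(j - 1L, 1L), integer(1))
      e <- tibble(a = gids[tree_to], b = gids[2:k])
      if (k > 2) {
        all_pairs <- utils::combn(seq_len(k), 2)
        extra <- !(paste(all_pairs[1, ], all_pairs[2, ]) %in%
                     paste(tree_to, 2:k)) &
          runif(ncol(all_pairs)) < spec$edge_density
        if (any(extra)) {
          e <- bind_rows(e, tibble(a = gids[all_pairs[1, extra]],
                                   b = gids[all_pairs[2, extra]]))
        }
      }
      edges[[ci]] <- e
    }
  }
  edges <- bind_rows(edges)
  if (nrow(edges) == 0) edges <- tibble(a = integer(), b = integer())

  # interactions: anchors are exactly the node intervals, 1-3 supporting
  # interactions per edge, geometric PET counts; half the pairs are written
  # anchor-2-first to exercise canonicalization on re-read
  ints <- list()
  for (i in seq_len(nrow(edges))) {
    n_rep <- 1L + rgeom(1, 0.6)
    for (r in seq_len(n_rep)) {
      na <- nodes[nodes$gid == edges$a[i], ]
      nb <- nodes[nodes$gid == edges$b[i], ]
      if (runif(1) < 0.5) { tmp <- na; na <- nb; nb <- tmp }
      ints[[length(ints) + 1L]] <- tibble(
        chrom1 = na$chrom, start1 = na$start, end1 = na$end,
        chrom2 = nb$chrom, start2 = nb$start, end2 = nb$end,
        pet_count = 1L + rgeom(1, spec$pet_geom_prob)
      )
    }
  }
  interactions <- if (length(ints) > 0) bind_rows(ints) else
    tibble(chrom1 = character(), start1 = integer(), end1 = integer(),
           chrom2 = character(), start2 = integer(), end2 = integer(),
           pet_count = integer())

  # isolated single-node components never enter the interaction file, so the
  # truth counts only components that contribute at least one interaction
  live_comps <- unique(nodes$comp[nodes$gid %in% c(edges$a, edges$b)])
  live_nodes <- nodes[nodes$comp %in% live_comps, , drop = FALSE]

  bg_nodes <- live_nodes[comp_kind[live_nodes$comp] == "background", ,
                         drop = FALSE]

  # planted variants and genes on the chain components
  planted <- list(); p_var <- list(); p_gene <- list()
  for (pi in seq_along(hops)) {
    ci <- spec$n_components + pi
    chain <- nodes[nodes$comp == ci, ]
    vid <- paste0("PLANT_VAR_", pi)
    gene <- paste0("PGENE_", pi)
    p_var[[pi]] <- tibble(chrom = chain$chrom[1], pos = chain$center[1],
                          id = vid)
    at <- hops[pi] + 1L # node of the chain sitting `hop` edges from node 1
    strand <- if (pi %% 2 == 0) "-" else "+"
    tss <- chain$center[at]
    p_gene[[pi]] <- tibble(
      name = gene, chrom = chain$chrom[at], strand = strand,
      tx_start = if (strand == "+") tss else pmax(0L, tss + 1L - 3000L),
      tx_end = if (strand == "+") tss + 3000L else tss + 1L
    )
    planted[[pi]] <- tibble(variant_id = vid, gene = gene, hop = hops[pi])
  }

  # background variants and genes go only on background nodes, never on the
  # chains, so they cannot shorten a planted distance
  bg_var <- bg_gene <- tibble()
  if (spec$n_variants > 0 && nrow(bg_nodes) > 0) {
    pick <- bg_nodes[sample.int(nrow(bg_nodes), spec$n_variants, replace = TRUE), ]
    off <- vapply(pick$end - pick$start,
                  function(w) sample.int(w, 1L) - 1L, integer(1))
    bg_var <- tibble(chrom = pick$chrom, pos = pick$start + off,
                     id = paste0("VAR_", seq_len(spec$n_variants)))
  }
  if (spec$n_genes > 0 && nrow(bg_nodes) > 0) {
    pick <- bg_nodes[sample.int(nrow(bg_nodes), spec$n_genes, replace = TRUE), ]
    strand <- sample(c("+", "-"), spec$n_genes, replace = TRUE)
    tss <- pick$center
    bg_gene <- tibble(
      name = paste0("GENE_", seq_len(spec$n_genes)), chrom = pick$chrom,
      strand = strand,
      tx_start = ifelse(strand == "+", tss, pmax(0L, tss + 1L - 3000L)),
      tx_end = ifelse(strand == "+", tss + 3000L, tss + 1L)
    )
  }
  variants <- bind_rows(c(p_var, list(bg_var)))
  genes <- bind_rows(c(p_gene, list(bg_gene)))
  genes <- distinct(genes, .data$name, .keep_all = TRUE)

  # peaks: the live node intervals themselves, plus decoys in the gaps
  peaks <- tibble(chrom = live_nodes$chrom, start = live_nodes$start,
                  end = live_nodes$end)
  if (spec$n_decoy_peaks > 0 && nrow(live_nodes) > 0) {
    base <- live_nodes[sample.int(nrow(live_nodes), spec$n_decoy_peaks,
                                  replace = TRUE), ]
    peaks <- bind_rows(peaks, tibble(chrom = base$chrom,
                                     start = base$end + 3000L,
                                     end = base$end + 3500L))
  }
  peaks <- distinct(arrange(peaks, .data$chrom, .data$start))

  all_gene_names <- genes$name
  gene_list <- sort(sample(all_gene_names,
                           max(1L, floor(length(all_gene_names) / 2))))
  gene_pairs <- if (length(all_gene_names) >= 2) {
    g1 <- sample(all_gene_names, min(6L, length(all_gene_names)))
    g2 <- vapply(g1, function(g) sample(setdiff(all_gene_names, g), 1L),
                 character(1))
    tibble(gene1 = unname(g1), gene2 = unname(g2))
  } else {
    tibble(gene1 = character(), gene2 = character())
  }

  list(
    interactions = interactions, peaks = peaks, variants = variants,
    genes = genes, gene_list = gene_list, gene_pairs = gene_pairs,
    truth = list(
      n_components = length(live_comps),
      n_nodes = nrow(live_nodes),
      n_edges = nrow(edges),
      planted = bind_rows(planted)
    )
  )
}
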