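# Enrichment of interactions between annotation classes. The question: do
# edges connecting an A-annotated node to a B-annotated node occur more often
# than expected if annotations were placed on nodes at random? Two nulls are
# provided: a theoretical one treating each edge as an independent uniform
# draw of an unordered node pair (one-tailed binomial test), and an empirical
# one permuting the annotation labels over nodes (the network is never
# rewired). Gene-list enrichment of discovered targets uses Fisher's exact
# test.

#' Observed A-B edge frequency
#'
#' Counts edges with one endpoint in `nodes_a` and the other in `nodes_b`
#' (each edge once). When the two sets are the same, this is the number of
#' edges internal to the set.
#'
#' @param network A `chia_net`, or an edge tibble with `node_a`/`node_b`.
#' @param nodes_a,nodes_b Integer node-id vectors.
#' @return Integer edge count.
#' @export
observed_pair_frequency <- function(network, nodes_a, nodes_b) {
  edges <- if (inherits(network, "chia_net")) network$edges else as_tibble(network)
  if (nrow(edges) == 0 || length(nodes_a) == 0 || length(nodes_b) == 0) {
    return(0L)
  }
  u <- edges$node_a
  v <- edges$node_b
  ina_u <- u %in% nodes_a; ina_v <- v %in% nodes_a
  inb_u <- u %in% nodes_b; inb_v <- v %in% nodes_b
  sum((ina_u & inb_v) | (inb_u & ina_v))
}

#' Expected probability that a random node pair is an A-B pair
#'
#' Under the theoretical null, an edge is a uniform draw among the
#' `choose(N, 2)` unordered node pairs. The probability that such a draw
#' joins an A node with a B node is the number of qualifying pairs divided by
#' `choose(N, 2)`; with `k = overlap_ab` nodes carrying both labels the
#' qualifying pair count is `n_a * n_b - k - choose(k, 2)` (subtracting the
#' self-pairings and the double-counted pairs internal to the overlap). For
#' `A = B` pass `overlap_ab = n_a`, giving `choose(n_a, 2) / choose(N, 2)`.
#'
#' @param n_nodes Total node count `N` (must be >= 2).
#' @param n_a,n_b Annotated node counts.
#' @param overlap_ab Number of nodes carrying both annotations (default 0).
#' @return Probability in `[0, 1]`.
#' @export
expected_pair_probability <- function(n_nodes, n_a, n_b, overlap_ab = 0L) {
  if (n_nodes < 2) abort("need at least 2 nodes for pair probabilities")
  if (n_a > n_nodes || n_b > n_nodes) abort("annotated counts exceed node count")
  if (overlap_ab > min(n_a, n_b)) abort("overlap_ab exceeds a set size")
  qualifying <- n_a * n_b - overlap_ab - choose(overlap_ab, 2)
  qualifying / choose(n_nodes, 2)
}

#' One-tailed binomial upper-tail p-value
#'
#' `P(X >= observed)` for `X ~ Binomial(n_edges, p)` — the probability of
#' seeing at least the observed number of A-B edges under the theoretical
#' null.
#'
#' @param observed Observed count.
#' @param n_edges Number of trials (edges).
#' @param p Per-edge success probability.
#' @return p-value in `[0, 1]`; `observed = 0` gives exactly 1.
#' @export
binomial_pvalue <- function(observed, n_edges, p) {
  stopifnot(observed >= 0, observed <= n_edges, p >= 0, p <= 1)
  if (observed == 0) return(1)
  pbinom(observed - 1, size = n_edges, prob = p, lower.tail = FALSE)
}

#' Permutation and binomial enrichment of an annotation pair
#'
#' Tests whether edges between annotation `a` and annotation `b` are more
#' frequent than random expectation. Each permutation relabels the nodes by a
#' uniform random permutation and maps both annotation sets through it
#' jointly, preserving the set sizes and their overlap, then recounts A-B
#' edges; the edge set itself is never touched. The permutation p-value uses
#' the add-one estimator `(1 + #{null >= observed}) / (n_perms + 1)`, so it
#' is never zero. The theoretical binomial test is computed alongside.
#'
#' @param network A `chia_net`.
#' @param a,b Annotation names on the network, or integer node-id vectors.
#' @param n_perms Number of permutations (default 1000).
#' @param seed Optional integer seed for reproducible permutations.
#' @return An `enrichment_result` object; see [tidy.enrichment_result()] for
#'   the tabular form. Fields: `annotation_a/b`, `observed`, `n_edges`,
#'   `p_theoretical` (per-edge probability), `p_binomial`, `perm_null`
#'   (integer vector), `p_permutation`, `n_perms`, `seed`.
#' @export
pair_enrichment <- function(network, a, b, n_perms = 1000L, seed = NULL) {
  stopifnot(inherits(network, "chia_net"))
  if (n_perms < 1) abort("n_perms must be >= 1")
  name_a <- if (is.character(a) && length(a) == 1) a else "set_a"
  name_b <- if (is.character(b) && length(b) == 1) b else "set_b"
  nodes_a <- resolve_node_set(network, a, "annotation a")
  nodes_b <- resolve_node_set(network, b, "annotation b")
  n <- nrow(network$nodes)
  edges <- network$edges
  observed <- observed_pair_frequency(network, nodes_a, nodes_b)
  p_theo <- expected_pair_probability(n, length(nodes_a), length(nodes_b),
                                      length(intersect(nodes_a, nodes_b)))
  p_binom <- binomial_pvalue(observed, nrow(edges), p_theo)

  # permutation null: joint relabeling of nodes, membership recomputed on
  # fixed edges; vectorized over edges per permutation
  ids <- network$nodes$id
  pos <- seq_len(n) # position of each node id in `ids`
  idx_a <- match(nodes_a, ids)
  idx_b <- match(nodes_b, ids)
  eu <- match(edges$node_a, ids)
  ev <- match(edges$node_b, ids)
  run_perms <- function() {
    vapply(seq_len(n_perms), function(i) {
      perm <- sample.int(n)
      in_a <- logical(n); in_a[perm[idx_a]] <- TRUE
      in_b <- logical(n); in_b[perm[idx_b]] <- TRUE
      sum((in_a[eu] & in_b[ev]) | (in_b[eu] & in_a[ev]))
    }, integer(1))
  }
  perm_null <- if (is.null(seed)) run_perms() else withr::with_seed(seed, run_perms())
  p_perm <- (1 + sum(perm_null >= observed)) / (n_perms + 1)
  structure(
    list(annotation_a = name_a, annotation_b = name_b,
         observed = observed, n_edges = nrow(edges),
         p_theoretical = p_theo, p_binomial = p_binom,
         perm_null = perm_null, p_permutation = p_perm,
         n_perms = n_perms, seed = seed),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> ", x$annotation_a, " -- ", x$annotation_b, "\n",
      sep = "")
  cat("  observed A-B edges: ", x$observed, " of ", x$n_edges,
      " (expected ", signif(x$p_theoretical * x$n_edges, 4), ")\n", sep = "")
  cat("  binomial p: ", signif(x$p_binomial, 4),
      "   permutation p: ", signif(x$p_permutation, 4),
      " (", x$n_perms, " perms)\n", sep = "")
  invisible(x)
}

#' Tidy an enrichment result into one row
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return One-row tibble (the permutation null vector is not included).
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(
    annotation_a = x$annotation_a, annotation_b = x$annotation_b,
    observed = x$observed, n_edges = x$n_edges,
    expected = x$p_theoretical * x$n_edges,
    p_theoretical = x$p_theoretical, p_binomial = x$p_binomial,
    p_permutation = x$p_permutation, n_perms = x$n_perms
  )
}

#' Enrichment across several annotation pairs with FDR control
#'
#' Runs [pair_enrichment()] for each requested pair of annotations (all
#' unordered pairs, including self-pairs, by default) and adds
#' Benjamini-Hochberg adjusted columns for both p-values. Multiple-testing
#' correction across annotation pairs is an extension beyond the single-pair
#' tests.
#'
#' @param network A `chia_net` with annotations.
#' @param pairs Optional 2-column data frame / matrix of annotation names;
#'   default all unordered pairs of the network's annotations.
#' @param n_perms,seed See [pair_enrichment()].
#' @return Tibble, one row per pair, with `q_binomial` and `q_permutation`
#'   columns.
#' @export
enrich_annotation_pairs <- function(network, pairs = NULL, n_perms = 1000L,
                                    seed = NULL) {
  if (is.null(pairs)) {
    nms <- names(network$annotations)
    if (length(nms) == 0) abort("network has no annotations")
    idx <- which(upper.tri(matrix(0, length(nms), length(nms)), diag = TRUE),
                 arr.ind = TRUE)
    pairs <- data.frame(a = nms[idx[, 1]], b = nms[idx[, 2]])
  }
  pairs <- as.data.frame(pairs)
  res <- purrr::map2(pairs[[1]], pairs[[2]], function(a, b) {
    s <- if (is.null(seed)) NULL else seed + match(paste(a, b), paste(pairs[[1]], pairs[[2]]))
    tidy(pair_enrichment(network, a, b, n_perms = n_perms, seed = s))
  })
  out <- bind_rows(res)
  out$q_binomial <- p.adjust(out$p_binomial, method = "BH")
  out$q_permutation <- p.adjust(out$p_permutation, method = "BH")
  out
}

#' Fisher's exact enrichment of a gene list among discovered targets
#'
#' Builds the 2x2 table (in target & in list, in target only, in list only,
#' neither) over a gene universe and tests enrichment one-tailed
#' (alternative "greater", i.e. the hypergeometric upper tail).
#'
#' @param target_genes Character vector of discovered target genes.
#' @param reference_list Character vector, e.g. known disease genes.
#' @param universe Character vector of all eligible genes (default behavior
#'   in pipelines: all genes annotated onto the network). Both inputs are
#'   intersected with it.
#' @return One-row tibble: `n_overlap`, `n_target`, `n_reference`,
#'   `n_universe`, `odds_ratio` (conditional MLE; may be `Inf`), `p_value`.
#'   The 2x2 table is attached as attribute `"table"`.
#' @export
fisher_enrichment <- function(target_genes, reference_list, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("gene universe is empty")
  tg <- intersect(unique(target_genes), universe)
  rf <- intersect(unique(reference_list), universe)
  k <- length(intersect(tg, rf))
  tab <- matrix(
    c(k, length(tg) - k,
      length(rf) - k, length(universe) - length(tg) - length(rf) + k),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("in_target", "not_target"), c("in_list", "not_list"))
  )
  ft <- fisher.test(tab, alternative = "greater")
  out <- tibble(
    n_overlap = k, n_target = length(tg), n_reference = length(rf),
    n_universe = length(universe),
    odds_ratio = unname(ft$estimate), p_value = ft$p.value
  )
  attr(out, "table") <- tab
  out
}
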