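demo_net <- function() {
  # nodes [0,500), [1000,1500), ... on chr1, path topology
  network_from_edges(4, data.frame(a = 0:2, b = 1:3))
}

test_that("promoters span TSS +/- flank, half-open, clamped at zero", {
  genes <- tibble::tibble(
    name = c("GP", "GC", "GM"), chrom = "chr1", strand = c("+", "+", "-"),
    tx_start = c(10000L, 500L, 10000L), tx_end = c(20000L, 4000L, 20000L)
  )
  pr <- promoters_from_genes(genes, 2000L)
  expect_equal(pr$start[pr$gene == "GP"], 8000L)
  expect_equal(pr$end[pr$gene == "GP"], 12001L)
  expect_equal(pr$start[pr$gene == "GC"], 0L)       # clamped
  expect_equal(pr$end[pr$gene == "GC"], 2501L)
  # minus strand: centered on tx_end - 1 = 19999
  expect_equal(pr$start[pr$gene == "GM"], 17999L)
  expect_equal(pr$end[pr$gene == "GM"], 22000L)
  # width 2*flank+1 unless clamped
  w <- pr$end - pr$start
  expect_equal(w[pr$gene != "GC"], rep(4001L, 2))
  expect_error(promoters_from_genes(genes, -1), "flank")
})

test_that("variant annotation respects half-open node boundaries", {
  net <- demo_net()  # node 0 = [0,500)
  v <- tibble::tibble(chrom = "chr1", pos = c(150L, 750L, 500L),
                      id = c("in0", "nowhere", "boundary"))
  net <- annotate_nodes(net, v, "vars", kind = "variant")
  hits <- annotation_hits(net, "vars")
  expect_equal(hits$feature, "in0")
  expect_equal(hits$node, 0L)
})

test_that("annotation hits equal a brute-force containment scan", {
  set.seed(411)
  net <- network_from_edges(30)
  feats <- random_intervals(120, chroms = "chr1", span = 30000L,
                            max_width = 800L)
  net <- annotate_nodes(net, feats, "f", kind = "interval")
  got <- annotation_hits(net, "f")
  want <- brute_overlaps(feats, net$nodes[, c("chrom", "start", "end")])
  want_hits <- unique(data.frame(node = net$nodes$id[want$subject],
                                 feature = paste0(feats$chrom[want$query], ":",
                                                  feats$start[want$query], "-",
                                                  feats$end[want$query])))
  want_hits <- want_hits[order(want_hits$node, want_hits$feature), ]
  rownames(want_hits) <- NULL
  expect_equal(as.data.frame(got), want_hits)
})

test_that("annotation names collide unless overwrite is requested", {
  net <- demo_net()
  v <- tibble::tibble(chrom = "chr1", pos = 100L)
  net <- annotate_nodes(net, v, "x", kind = "variant")
  expect_error(annotate_nodes(net, v, "x", kind = "variant"), "already exists")
  expect_silent(annotate_nodes(net, v, "x", kind = "variant", overwrite = TRUE))
})

test_that("hit counts are invariant to feature input order", {
  set.seed(412)
  net <- network_from_edges(15)
  feats <- random_intervals(60, chroms = "chr1", span = 15000L)
  a <- annotate_nodes(net, feats, "f", kind = "interval")
  b <- annotate_nodes(net, feats[sample.int(nrow(feats)), ], "f",
                      kind = "interval")
  expect_equal(annotation_hits(a, "f"), annotation_hits(b, "f"))
})

test_that("gene_list annotation skips unknown symbols and counts them", {
  net <- demo_net()
  genes <- tibble::tibble(name = c("G1", "G2"), chrom = "chr1",
                          strand = "+", tx_start = c(100L, 1200L),
                          tx_end = c(3100L, 4200L))
  net <- annotate_nodes(net, c("G1", "NOT_A_GENE"), "list",
                        kind = "gene_list", genes = genes, flank_bp = 100L)
  expect_equal(unique(annotation_hits(net, "list")$feature), "G1")
  expect_equal(net$annotations$list$n_skipped, 1L)
})

test_that("superimposed gene pairs land on the expected node pairs", {
  net <- demo_net()
  genes <- tibble::tibble(
    name = c("G1", "G2", "G3"), chrom = "chr1", strand = "+",
    tx_start = c(100L, 3100L, 200L), tx_end = c(600L, 3600L, 700L)
  )
  net <- annotate_nodes(net, genes, "genes", kind = "gene", flank_bp = 50L)
  # G1 and G3 on node 0, G2 on node 3
  pairs <- tibble::tibble(gene1 = c("G1", "G1", "MISSING"),
                          gene2 = c("G2", "G3", "G2"))
  out <- superimpose_gene_network(net, pairs, "genes")
  expect_equal(nrow(out), 1)   # G1-G3 same node -> excluded; MISSING skipped
  expect_equal(out$node_a, 0L)
  expect_equal(out$node_b, 3L)
  expect_equal(attr(out, "summary")$n_skipped, 1L)
})

test_that("superimposition equals the brute-force double loop on random input", {
  set.seed(413)
  net <- network_from_edges(12)
  gene_nodes <- data.frame(
    gene = paste0("G", 1:8),
    node = sample(0:11, 8, replace = TRUE)
  )
  genes <- tibble::tibble(
    name = gene_nodes$gene, chrom = "chr1", strand = "+",
    tx_start = net$nodes$start[match(gene_nodes$node, net$nodes$id)] + 10L,
    tx_end = net$nodes$start[match(gene_nodes$node, net$nodes$id)] + 400L
  )
  net <- annotate_nodes(net, genes, "genes", kind = "gene", flank_bp = 5L)
  pairs <- tibble::tibble(gene1 = sample(gene_nodes$gene, 10, replace = TRUE),
                          gene2 = sample(gene_nodes$gene, 10, replace = TRUE))
  got <- superimpose_gene_network(net, pairs, "genes")
  want <- list()
  for (i in seq_len(nrow(pairs))) {
    n1 <- gene_nodes$node[gene_nodes$gene == pairs$gene1[i]]
    n2 <- gene_nodes$node[gene_nodes$gene == pairs$gene2[i]]
    for (a in n1) for (b in n2) {
      if (a != b) want[[length(want) + 1]] <-
          data.frame(node_a = min(a, b), node_b = max(a, b),
                     gene1 = pairs$gene1[i], gene2 = pairs$gene2[i])
    }
  }
  want <- unique(do.call(rbind, want))
  want <- want[order(want$node_a, want$node_b, want$gene1, want$gene2), ]
  rownames(want) <- NULL
  expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
})
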