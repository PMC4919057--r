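test_that("shortest paths cover distance 0, chains, and tied diamonds", {
  path4 <- network_from_edges(4, data.frame(a = 0:2, b = 1:3))
  # source that is also a target: distance 0, path = itself
  sp0 <- shortest_paths_between(path4, 0L, c(0L, 3L), max_dist = 4)
  expect_equal(sp0$hop_distance, c(0L, 3L))
  expect_equal(sp0$paths[[1]], list(0L))
  expect_equal(sp0$paths[[2]], list(c(0L, 1L, 2L, 3L)))

  # diamond 0-1-3 / 0-2-3: both tied shortest paths retained
  diamond <- network_from_edges(4, data.frame(a = c(0, 0, 1, 2), b = c(1, 2, 3, 3)))
  spd <- shortest_paths_between(diamond, 0L, 3L, max_dist = 4)
  expect_equal(spd$hop_distance, 2L)
  got_paths <- lapply(spd$paths[[1]], as.integer)
  want_paths <- all_sps(adj_list(4, data.frame(a = c(0, 0, 1, 2),
                                               b = c(1, 2, 3, 3))), 1, 4)
  want_paths <- lapply(want_paths, function(p) as.integer(p - 1L))
  expect_setequal(lapply(got_paths, paste, collapse = ","),
                  lapply(want_paths, paste, collapse = ","))

  expect_error(shortest_paths_between(path4, 0L, 3L, max_dist = -1), "max_dist")
  # pairs beyond max_dist or in other components are omitted
  two_comp <- network_from_edges(4, data.frame(a = 0, b = 1))
  expect_equal(nrow(shortest_paths_between(two_comp, 0L, 3L, max_dist = 4)), 0)
})

test_that("every reported distance agrees with an independent BFS", {
  set.seed(414)
  for (rep in 1:5) {
    n <- sample(8:16, 1)
    ed <- random_graph_edges(n, 0.2)
    net <- network_from_edges(n, ed)
    adj <- adj_list(n, ed)
    sp <- shortest_paths_between(net, 0:2, 0:(n - 1), max_dist = 4)
    for (i in seq_len(nrow(sp))) {
      d <- bfs_dist(adj, sp$source_node[i] + 1L)
      expect_equal(sp$hop_distance[i], as.integer(d[sp$target_node[i] + 1L]))
      # every stored path has the right length and valid consecutive edges
      for (p in sp$paths[[i]]) {
        expect_equal(length(p) - 1L, sp$hop_distance[i])
        if (length(p) > 1) {
          for (k in seq_len(length(p) - 1)) {
            expect_true((p[k + 1] + 1L) %in% adj[[p[k] + 1L]])
          }
        }
      }
    }
  }
})

test_that("targets classify by minimum distance with direct/indirect bounds", {
  # chain 0-1-2-3-4-5 with genes at several distances from source node 0
  chain <- network_from_edges(6, data.frame(a = 0:4, b = 1:5))
  gene_hits <- tibble::tibble(
    node = c(0L, 1L, 3L, 5L, 2L, 1L),
    feature = c("G0", "G1", "G3", "G5", "GMIX", "GMIX")
  )
  paths <- shortest_paths_between(chain, 0L, sort(unique(gene_hits$node)),
                                  max_dist = 10)
  cls <- classify_targets(paths, gene_hits)
  expect_equal(cls$classification[cls$gene == "G0"], "direct")    # distance 0
  expect_equal(cls$classification[cls$gene == "G1"], "direct")    # 1 edge away
  expect_equal(cls$classification[cls$gene == "G3"], "indirect")  # 3 edges
  expect_false("G5" %in% cls$gene)                                # beyond 4
  expect_equal(attr(cls, "excluded"), "G5")
  # reachable at 1 and 2: the minimum rule wins
  expect_equal(cls$classification[cls$gene == "GMIX"], "direct")
  expect_equal(cls$distance[cls$gene == "GMIX"], 1L)

  expect_error(classify_targets(paths, gene_hits, direct_max = 2,
                                indirect_range = c(2, 4)), "overlap")
})

test_that("classification is order-invariant and monotone in the range", {
  set.seed(415)
  n <- 14
  ed <- random_graph_edges(n, 0.18)
  net <- network_from_edges(n, ed)
  gene_hits <- tibble::tibble(node = sample(0:(n - 1), 8, replace = TRUE),
                              feature = paste0("G", 1:8))
  paths <- shortest_paths_between(net, 0:1, 0:(n - 1), max_dist = 6)
  c1 <- classify_targets(paths, gene_hits, indirect_range = c(2L, 4L))
  c2 <- classify_targets(paths[sample.int(nrow(paths)), ], gene_hits,
                         indirect_range = c(2L, 4L))
  expect_equal(c1, c2, ignore_attr = TRUE)
  wide <- classify_targets(paths, gene_hits, indirect_range = c(2L, 6L))
  narrow_ind <- c1$gene[c1$classification == "indirect"]
  wide_ind <- wide$gene[wide$classification == "indirect"]
  expect_true(all(narrow_ind %in% wide_ind))
})

test_that("nearest TSS picks the closest gene with ties reported", {
  genes <- tibble::tibble(
    name = c("NEAR", "FAR", "TIE_L", "TIE_R", "OTHER"),
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr3"),
    strand = "+",
    tx_start = c(900L, 1200L, 900L, 1100L, 5L),
    tx_end = c(2000L, 2400L, 2000L, 2200L, 500L)
  )
  v <- tibble::tibble(chrom = c("chr1", "chr2", "chr1", "chrX"),
                      pos = c(1000L, 1000L, 900L, 50L),
                      id = c("v1", "v2", "on_tss", "lost"))
  nt <- nearest_tss(v, genes)
  expect_equal(nt$gene[nt$id == "v1"], "NEAR")
  expect_setequal(nt$gene[nt$id == "v2"], c("TIE_L", "TIE_R"))
  expect_equal(nt$distance[nt$id == "on_tss"], 0L)
  expect_false("lost" %in% nt$id)
  expect_equal(attr(nt, "summary")$n_unmatched, 1L)
  expect_equal(attr(nt, "summary")$unmatched_ids, "lost")
})

test_that("nearest TSS agrees with a linear scan on random inputs", {
  set.seed(416)
  genes <- tibble::tibble(
    name = paste0("G", 1:30), chrom = sample(c("chr1", "chr2"), 30, TRUE),
    strand = sample(c("+", "-"), 30, TRUE),
    tx_start = sample.int(50000L, 30)
  )
  genes$tx_end <- genes$tx_start + 1000L
  v <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 20, TRUE),
                      pos = sample.int(50000L, 20),
                      id = paste0("v", 1:20))
  nt <- nearest_tss(v, genes)
  tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1L)
  for (i in seq_len(nrow(v))) {
    same <- which(genes$chrom == v$chrom[i])
    dmin <- min(abs(v$pos[i] - tss[same]))
    got <- nt[nt$id == v$id[i], ]
    expect_equal(unique(got$distance), dmin)
    expect_setequal(got$gene, genes$name[same][abs(v$pos[i] - tss[same]) == dmin])
  }
})

test_that("target tables export one sorted row per source/gene/path", {
  diamond <- network_from_edges(5, data.frame(a = c(0, 0, 1, 2, 3),
                                              b = c(1, 2, 3, 3, 4)))
  genes <- tibble::tibble(
    name = c("GA", "GB"), chrom = "chr1", strand = "+",
    tx_start = c(3100L, 4100L), tx_end = c(3400L, 4400L)
  )
  net <- diamond |>
    annotate_nodes(tibble::tibble(chrom = "chr1", pos = 100L, id = "src"),
                   "vars", kind = "variant") |>
    annotate_nodes(genes, "genes", kind = "gene", flank_bp = 50L)
  tg <- discover_targets(net, "vars", "genes")
  # GA on node 3 at distance 2 via two tied paths; GB on node 4 at distance 3
  expect_equal(sum(tg$target_gene == "GA"), 2)
  expect_equal(unique(tg$classification[tg$target_gene == "GA"]), "indirect")
  expect_setequal(tg$path[tg$target_gene == "GA"], c("0>1>3", "0>2>3"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_target_table(tg, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(tg))
  expect_equal(names(back),
               c("source_node", "source_annotation", "target_node",
                 "target_gene", "hop_distance", "path", "classification"))
  expect_false(is.unsorted(back$hop_distance[back$source_node == 0]))
  # empty input -> header-only file
  write_target_table(tg[0, ], f)
  expect_equal(nrow(utils::read.csv(f)), 0)
})
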