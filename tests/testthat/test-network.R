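make_interactions <- function(pairs, nodes, pets = NULL) {
  # pairs: 2-column matrix of 1-based rows into `nodes` (interval tibble)
  pets <- pets %||% rep(1L, nrow(pairs))
  tibble::tibble(
    chrom1 = nodes$chrom[pairs[, 1]], start1 = nodes$start[pairs[, 1]],
    end1 = nodes$end[pairs[, 1]],
    chrom2 = nodes$chrom[pairs[, 2]], start2 = nodes$start[pairs[, 2]],
    end2 = nodes$end[pairs[, 2]],
    pet_count = as.integer(pets)
  )
}

`%||%` <- rlang::`%||%`

test_that("merge_anchors collapses transitive overlaps only", {
  a <- tibble::tibble(chrom = c("chr1", "chr1", "chr1"),
                      start = c(100L, 150L, 400L), end = c(200L, 300L, 500L))
  nodes <- merge_anchors(a)
  expect_equal(nodes$start, c(100L, 400L))
  expect_equal(nodes$end, c(300L, 500L))
  expect_equal(nodes$id, c(0L, 1L))

  b <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(100L, 100L),
                      end = c(200L, 200L))
  expect_equal(nrow(merge_anchors(b)), 2)  # no cross-chromosome merge
  expect_equal(nrow(merge_anchors(a[0, ])), 0)
})

test_that("merge_anchors agrees with the pairwise-overlap union-find oracle", {
  set.seed(404)
  a <- random_intervals(500, chroms = c("chr1", "chr2", "chr3"),
                        span = 20000L, max_width = 400L)
  got <- merge_anchors(a)
  want <- uf_merge_intervals(a)
  expect_equal(got$chrom, want$chrom)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  # every anchor is contained in exactly one node
  cover <- find_overlaps(a, got[, c("chrom", "start", "end")])
  expect_equal(sort(unique(cover$query)), seq_len(nrow(a)))
  by_anchor <- table(cover$query)
  expect_true(all(by_anchor == 1))
})

test_that("peak-defined nodes keep only anchor-overlapping peaks and fan out", {
  anchors <- tibble::tibble(chrom = "chr1", start = c(100L, 700L),
                            end = c(200L, 760L))
  peaks <- tibble::tibble(chrom = "chr1",
                          start = c(150L, 180L, 5000L), end = c(190L, 450L, 5100L))
  def <- define_nodes_from_peaks(anchors, peaks)
  # the two overlapping peaks merge into [150,450); the decoy is dropped
  expect_equal(def$nodes$start, 150L)
  expect_equal(def$nodes$end, 450L)
  expect_equal(def$anchor_map$anchor, 1L)  # anchor 2 maps to nothing

  # an anchor spanning two separated peaks maps to both
  peaks2 <- tibble::tibble(chrom = "chr1", start = c(100L, 160L),
                           end = c(140L, 190L))
  def2 <- define_nodes_from_peaks(anchors[1, ], peaks2)
  expect_equal(nrow(def2$nodes), 2)
  expect_equal(def2$anchor_map$node, c(0L, 1L))

  expect_warning(def3 <- define_nodes_from_peaks(anchors, peaks[0, ]),
                 "empty peak")
  expect_equal(nrow(def3$nodes), 0)
})

test_that("build_edges aggregates interactions per node pair", {
  nodes_iv <- tibble::tibble(chrom = "chr1", start = c(0L, 1000L),
                             end = c(500L, 1500L))
  ints <- make_interactions(rbind(c(1, 2), c(1, 2), c(2, 1)), nodes_iv,
                            pets = c(2L, 3L, 4L))
  net <- build_network(ints)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$interaction_count, 3L)
  expect_equal(net$edges$pet_count, 9L)
})

test_that("self-loop and unmapped interactions are counted, not stored", {
  nodes_iv <- tibble::tibble(chrom = "chr1", start = c(0L, 1000L, 9000L),
                             end = c(500L, 1500L, 9500L))
  # overlapping anchors within one merged node -> self loop
  ints <- tibble::tibble(
    chrom1 = "chr1", start1 = c(0L, 0L), end1 = c(500L, 400L),
    chrom2 = "chr1", start2 = c(1000L, 100L), end2 = c(1500L, 500L),
    pet_count = c(1L, 1L)
  )
  net <- build_network(ints)
  expect_equal(net$stats$self_loop, 1L)
  expect_equal(net$stats$used, 1L)
  expect_equal(nrow(net$edges), 1)

  # approach 2 with a peak covering only some anchors -> unmapped
  peaks <- tibble::tibble(chrom = "chr1", start = c(0L, 1000L),
                          end = c(500L, 1500L))
  ints2 <- make_interactions(rbind(c(1, 2), c(1, 3)), nodes_iv)
  net2 <- build_network(ints2, peaks = peaks)
  expect_equal(net2$stats$unmapped, 1L)
  expect_equal(net2$stats$used, 1L)
})

test_that("component labels match the union-find oracle on random graphs", {
  set.seed(405)
  for (rep in 1:100) {
    n <- sample(2:50, 1)
    ed <- random_graph_edges(n, runif(1, 0.02, 0.2))
    net <- network_from_edges(n, ed)
    want <- uf_partition(n, data.frame(a = ed$a + 1L, b = ed$b + 1L))
    expect_identical(net$nodes$component, want)
  }
})

test_that("isolated nodes each form a component; paths form one", {
  expect_equal(network_from_edges(5)$nodes$component, 0:4)
  path <- network_from_edges(4, data.frame(a = 0:2, b = 1:3))
  expect_equal(unique(path$nodes$component), 0L)
})

test_that("two planted cliques come out as two components", {
  nodes_iv <- tibble::tibble(chrom = "chr1",
                             start = seq(0L, 70000L, by = 10000L))
  nodes_iv$end <- nodes_iv$start + 500L
  cl1 <- t(utils::combn(1:4, 2))
  cl2 <- t(utils::combn(5:8, 2))
  ints <- make_interactions(rbind(cl1, cl2, cl1[1:4, ], cl2[1:4, ]), nodes_iv)
  net <- build_network(ints)
  expect_equal(n_components(net), 2)
  expect_equal(nrow(net$nodes), 8)
})

test_that("min_pet filtering can empty the network, with a warning", {
  nodes_iv <- tibble::tibble(chrom = "chr1", start = c(0L, 1000L),
                             end = c(500L, 1500L))
  ints <- make_interactions(rbind(c(1, 2)), nodes_iv, pets = 1L)
  expect_warning(net <- build_network(ints, min_pet = 5L), "empty")
  expect_equal(nrow(net$nodes), 0)
  expect_equal(net$stats$pet_filtered, 1L)
  expect_equal(net$stats$input, 1L)
})

test_that("approach 1 equals approach 2 when peaks are the anchor intervals", {
  set.seed(406)
  fx <- generate_fixture(fixture_spec(seed = 42L))
  ints <- canonical <- fx$interactions
  net1 <- build_network(ints)
  anchor_iv <- dplyr::bind_rows(
    tibble::tibble(chrom = ints$chrom1, start = ints$start1, end = ints$end1),
    tibble::tibble(chrom = ints$chrom2, start = ints$start2, end = ints$end2)
  )
  net2 <- build_network(ints, peaks = anchor_iv)
  expect_equal(net1$edges, net2$edges)
  expect_equal(net1$nodes$start, net2$nodes$start)
})

test_that("built networks satisfy the structural invariants", {
  set.seed(407)
  fx <- generate_fixture(fixture_spec(seed = 9L, n_components = 4L))
  net <- build_network(fx$interactions, min_pet = 2L)
  s <- net$stats
  expect_equal(s$input, s$used + s$pet_filtered + s$self_loop + s$unmapped)
  # node intervals pairwise non-overlapping per chromosome (sweep)
  by_chrom <- split(net$nodes, net$nodes$chrom)
  for (nb in by_chrom) {
    nb <- nb[order(nb$start), ]
    if (nrow(nb) > 1) expect_true(all(nb$start[-1] >= nb$end[-nrow(nb)]))
  }
  # degree sum = 2 |E|
  expect_equal(sum(tidy(net)$degree), 2 * nrow(net$edges))
  # every edge's endpoints share a component label
  comp <- setNames(net$nodes$component, net$nodes$id)
  expect_true(all(comp[as.character(net$edges$node_a)] ==
                    comp[as.character(net$edges$node_b)]))
  # edges reference valid node ids, no self loops stored
  expect_true(all(net$edges$node_a < net$edges$node_b))
  expect_true(all(c(net$edges$node_a, net$edges$node_b) %in% net$nodes$id))
})

test_that("glance and build_stats_json expose the construction statistics", {
  fx <- generate_fixture(fixture_spec(seed = 3L))
  net <- build_network(fx$interactions)
  g <- glance(net)
  expect_equal(g$n_nodes, nrow(net$nodes))
  expect_equal(g$n_input_interactions, nrow(fx$interactions))
  js <- jsonlite::fromJSON(build_stats_json(net))
  expect_equal(js$input, net$stats$input)
  expect_equal(js$used, net$stats$used)
})
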