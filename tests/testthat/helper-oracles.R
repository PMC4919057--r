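# Independent oracles used to cross-check the package implementation.
# Deliberately naive: union-find, O(n^2) scans, exhaustive path enumeration,
# direct hypergeometric summation. None of them share code with the package.

# ---- union-find ----------------------------------------------------------

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  parent[uf_find(parent, i)] <- uf_find(parent, j)
  parent
}

# canonical partition labels (0-based, ordered by smallest member) for n
# items and a 2-column 1-based edge matrix/data.frame
uf_partition <- function(n, edges) {
  parent <- seq_len(n)
  for (r in seq_len(NROW(edges))) {
    parent <- uf_union(parent, edges[[1]][r], edges[[2]][r])
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  match(roots, unique(roots)) - 1L
}

# merge intervals by union-find over all pairwise strict overlaps
uf_merge_intervals <- function(iv) {
  n <- nrow(iv)
  if (n == 0) return(iv[, c("chrom", "start", "end")])
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (iv$chrom[i] == iv$chrom[j] &&
          iv$start[i] < iv$end[j] && iv$start[j] < iv$end[i]) {
        pairs[[length(pairs) + 1]] <- c(i, j)
      }
    }
  }
  em <- if (length(pairs) > 0) do.call(rbind, pairs) else matrix(0L, 0, 2)
  lab <- uf_partition(n, data.frame(a = em[, 1], b = em[, 2]))
  out <- do.call(rbind, lapply(split(seq_len(n), lab), function(idx) {
    data.frame(chrom = iv$chrom[idx[1]], start = min(iv$start[idx]),
               end = max(iv$end[idx]))
  }))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# O(n^2) overlap scan
brute_overlaps <- function(query, subject) {
  hits <- list()
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(subject))) {
      if (query$chrom[i] == subject$chrom[j] &&
          query$start[i] < subject$end[j] &&
          subject$start[j] < query$end[i]) {
        hits[[length(hits) + 1]] <- c(i, j)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(query = integer(), subject = integer()))
  }
  m <- do.call(rbind, hits)
  out <- data.frame(query = m[, 1], subject = m[, 2])
  out[order(out$query, out$subject), , drop = FALSE]
}

# ---- exhaustive shortest-path machinery (small graphs) -------------------

# adjacency list (1-based) from a 0-based edge data frame
adj_list <- function(n, edges) {
  adj <- vector("list", n)
  for (r in seq_len(NROW(edges))) {
    a <- edges[[1]][r] + 1L; b <- edges[[2]][r] + 1L
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

bfs_dist <- function(adj, s) {
  n <- length(adj)
  d <- rep(Inf, n); d[s] <- 0
  queue <- s
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(d[w])) {
        d[w] <- d[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  d
}

# all shortest paths s -> t by recursive backtracking over BFS distances
all_sps <- function(adj, s, t) {
  d <- bfs_dist(adj, s)
  if (is.infinite(d[t])) return(list())
  if (s == t) return(list(s))
  walk <- function(v) {
    if (v == s) return(list(s))
    preds <- Filter(function(w) d[w] == d[v] - 1, adj[[v]])
    unlist(lapply(preds, function(w) {
      lapply(walk(w), function(p) c(p, v))
    }), recursive = FALSE)
  }
  walk(t)
}

# betweenness by full path enumeration: fractional credit per tied path,
# each unordered pair counted once, endpoints excluded
o_betweenness <- function(n, edges) {
  adj <- adj_list(n, edges)
  btw <- rep(0, n)
  if (n < 3) return(btw)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_sps(adj, s, t)
      if (length(paths) == 0) next
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        btw[inner] <- btw[inner] + 1 / length(paths)
      }
    }
  }
  btw
}

o_closeness <- function(n, edges) {
  adj <- adj_list(n, edges)
  vapply(seq_len(n), function(v) {
    d <- bfs_dist(adj, v)
    reach <- which(is.finite(d) & seq_len(n) != v)
    if (length(reach) == 0) return(0)
    length(reach) / sum(d[reach])
  }, numeric(1))
}

o_harmonic <- function(n, edges) {
  adj <- adj_list(n, edges)
  if (n < 2) return(rep(0, n))
  vapply(seq_len(n), function(v) {
    d <- bfs_dist(adj, v)
    sum(1 / d[-v]) / (n - 1)
  }, numeric(1))
}

# ---- hypergeometric summation -------------------------------------------

# P(overlap >= k) drawing n from universe N containing K successes
hyper_upper <- function(k, K, n, N) {
  if (k <= max(0, K + n - N)) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# ---- random generators ---------------------------------------------------

random_intervals <- function(n, chroms = c("chr1", "chr2"), span = 5000L,
                             max_width = 300L) {
  data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    start = sample.int(span, n, replace = TRUE) - 1L
  ) |>
    dplyr::mutate(end = start + sample.int(max_width, n, replace = TRUE))
}

# G(n, p) as a 0-based edge data frame
random_graph_edges <- function(n, p) {
  if (n < 2) return(data.frame(a = integer(), b = integer()))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(idx)) < p
  data.frame(a = idx[keep, 1] - 1L, b = idx[keep, 2] - 1L)
}
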