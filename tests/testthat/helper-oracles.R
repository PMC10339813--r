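# Brute-force graph-metric oracles, independent of the package's igraph
# path: plain-R BFS shortest paths, explicit shortest-path enumeration for
# betweenness, and direct triple/triangle counting.

# All-pairs shortest path lengths by BFS on an adjacency matrix (Inf if
# unreachable).
bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    lvl <- 0
    while (length(frontier)) {
      lvl <- lvl + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] == 1)) {
          if (d[s, w] > lvl) {
            d[s, w] <- lvl
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

# Enumerate every shortest path between a pair (list of node sequences).
bf_all_shortest_paths <- function(adj, s, t, d) {
  if (!is.finite(d[s, t])) return(list())
  if (s == t) return(list(s))
  out <- list()
  extend <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (w in which(adj[v, ] == 1)) {
      if (d[s, w] == d[s, v] + 1 && d[w, t] == d[s, t] - d[s, v] - 1) {
        extend(c(path, w))
      }
    }
  }
  extend(s)
  out
}

# Raw betweenness: node vector and per-edge values (edges keyed "i-j", i<j),
# fractional counting over tied shortest paths, unordered pairs.
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- bf_distances(adj)
  node <- numeric(n)
  edge <- list()
  ek <- function(a, b) paste(sort(c(a, b)), collapse = "-")
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) edge[[ek(idx[r, 1], idx[r, 2])]] <- 0
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- bf_all_shortest_paths(adj, s, t, d)
      np <- length(paths)
      if (np == 0) next
      for (p in paths) {
        inner <- p[-c(1, length(p))]
        for (v in inner) node[v] <- node[v] + 1 / np
        for (i in seq_len(length(p) - 1)) {
          k <- ek(p[i], p[i + 1])
          edge[[k]] <- edge[[k]] + 1 / np
        }
      }
    }
  }
  list(node = node, edge = unlist(edge))
}

bf_triangles_at <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) < 2) return(0)
    sum(adj[nb, nb]) / 2
  }, numeric(1))
}

bf_clustering_mean <- function(adj) {
  deg <- rowSums(adj)
  tri <- bf_triangles_at(adj)
  cc <- ifelse(deg >= 2, 2 * tri / (deg * (deg - 1)), 0)
  mean(cc)
}

bf_transitivity <- function(adj) {
  deg <- rowSums(adj)
  triples <- sum(deg * (deg - 1) / 2)
  if (triples == 0) return(0)
  tri_total <- sum(bf_triangles_at(adj)) / 3
  3 * tri_total / triples
}

bf_spl_ge <- function(adj) {
  d <- bf_distances(adj)
  diag(d) <- NA
  finite <- d[is.finite(d) & !is.na(d)]
  spl <- if (length(finite)) mean(finite) else 0
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  n <- nrow(adj)
  ge <- sum(inv, na.rm = TRUE) / (n * (n - 1))
  c(spl = spl, ge = ge)
}

bf_local_efficiency <- function(adj) {
  n <- nrow(adj)
  vals <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) < 2) return(0)
    unname(bf_spl_ge(adj[nb, nb, drop = FALSE])["ge"])
  }, numeric(1))
  mean(vals)
}

bf_assortativity <- function(adj) {
  idx <- which(adj == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  deg <- rowSums(adj)
  x <- deg[idx[, 1]]
  y <- deg[idx[, 2]]
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

# Newman modularity of a given membership vector.
bf_modularity <- function(adj, membership) {
  m2 <- sum(adj)
  if (m2 == 0) return(0)
  deg <- rowSums(adj)
  q <- 0
  for (c in unique(membership)) {
    v <- membership == c
    q <- q + sum(adj[v, v]) / m2 - (sum(deg[v]) / m2)^2
  }
  q
}

# Best modularity over all partitions into at most 2 blocks (enough when the
# optimum is a bipartition, as in the clique-pair fixtures used here).
bf_best_bipartition_modularity <- function(adj) {
  n <- nrow(adj)
  best <- -Inf
  for (code in 0:(2^(n - 1) - 1)) {
    memb <- c(0, as.integer(intToBits(code))[seq_len(n - 1)])
    best <- max(best, bf_modularity(adj, memb))
  }
  best
}

# Seeded random adjacency matrix on n nodes with edge probability p.
random_adjacency <- function(n, p, seed) {
  with_seed(seed, {
    a <- matrix(0, n, n)
    up <- which(upper.tri(a))
    a[up] <- as.integer(runif(length(up)) < p)
    a + t(a)
  })
}

random_permutation_of <- function(adj, seed) {
  with_seed(seed, {
    p <- sample(nrow(adj))
    adj[p, p]
  })
}

# Common small fixtures.
adj_complete <- function(n) { a <- matrix(1, n, n); diag(a) <- 0; a }
adj_path <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  a
}
adj_cycle <- function(n) { a <- adj_path(n); a[1, n] <- a[n, 1] <- 1; a }
adj_star <- function(leaves) {
  n <- leaves + 1
  a <- matrix(0, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1
  a
}
# Two cliques K_k joined by a single bridge edge (node k to node k+1).
adj_clique_pair <- function(k) {
  a <- matrix(0, 2 * k, 2 * k)
  a[1:k, 1:k] <- adj_complete(k)
  a[(k + 1):(2 * k), (k + 1):(2 * k)] <- adj_complete(k)
  a[k, k + 1] <- a[k + 1, k] <- 1
  a
}

with_seed <- psinetfs:::with_seed
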