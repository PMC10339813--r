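# Fourteen graph-topology features of a binary undirected network, in the
# fixed order DG, NB, CC, SPL, EB, GE, LE, TT, AC, SW, MD, MZ, HC, GIC.
# Node- and edge-level metrics are reduced to one scalar per network by the
# unweighted arithmetic mean, since each feature is a single classifier
# input. All degenerate cases return 0 (with a warning) rather than NaN, so
# feature tables are classifier-ready.

#' Ordered names of the 14 network features
#' @format character vector of length 14.
#' @export
feature_names_14 <- c("DG", "NB", "CC", "SPL", "EB", "GE", "LE", "TT",
                      "AC", "SW", "MD", "MZ", "HC", "GIC")

as_igraph <- function(net) {
  adj <- if (inherits(net, "binary_network")) net$adjacency else as.matrix(net)
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

net_adjacency <- function(net) {
  if (inherits(net, "binary_network")) net$adjacency else as.matrix(net)
}

#' Null-ensemble specification for small-worldness and motif z-score
#'
#' Degree-preserving (Maslov-Sneppen) rewiring ensemble. Defaults follow the
#' package convention of 100 surrogates with 10 rewiring attempts per edge.
#' `rewires_per_edge = 0` gives an ensemble of copies of the graph itself
#' (useful as a self-normalization check).
#'
#' @param n_random number of surrogate graphs (>= 1).
#' @param rewires_per_edge rewiring attempts per edge (>= 0).
#' @param seed integer seed making the ensemble reproducible.
#' @return object of class `null_ensemble_spec`.
#' @export
null_ensemble_spec <- function(n_random = 100, rewires_per_edge = 10, seed = 1) {
  check_number(n_random, "n_random", lower = 1, integer = TRUE)
  check_number(rewires_per_edge, "rewires_per_edge", lower = 0, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(list(n_random = as.integer(n_random),
                 rewires_per_edge = as.integer(rewires_per_edge),
                 seed = as.integer(seed)),
            class = "null_ensemble_spec")
}

make_null_ensemble <- function(g, ens) {
  n_iter <- ens$rewires_per_edge * igraph::ecount(g)
  with_seed(ens$seed, lapply(seq_len(ens$n_random), function(i) {
    if (n_iter == 0L) g else igraph::rewire(g, igraph::keeping_degseq(niter = n_iter))
  }))
}

#' Mean degree (DG)
#' @param net a [binary_network()] or adjacency matrix.
#' @return mean over nodes of edge count.
#' @export
degree_mean <- function(net) {
  mean(rowSums(net_adjacency(net)))
}

#' Mean node and edge betweenness (NB, EB)
#'
#' Raw (unnormalized) shortest-path betweenness with fractional counting of
#' tied shortest paths; unreachable pairs contribute 0. `NB` is the mean over
#' nodes, `EB` the mean over existing edges (0 for an edgeless graph).
#'
#' @inheritParams degree_mean
#' @return named numeric `c(NB, EB)`.
#' @export
betweenness_means <- function(net) {
  g <- as_igraph(net)
  nb <- mean(igraph::betweenness(g, directed = FALSE, normalized = FALSE))
  eb <- if (igraph::ecount(g) == 0L) 0 else {
    mean(igraph::edge_betweenness(g, directed = FALSE))
  }
  c(NB = nb, EB = eb)
}

#' Mean clustering coefficient and transitivity (CC, TT)
#'
#' `CC` is the mean over nodes of the local clustering coefficient
#' `2 T_i / (k_i (k_i - 1))`, with nodes of degree < 2 contributing 0.
#' `TT` is `3 * triangles / triples` (0 when there are no triples).
#'
#' @inheritParams degree_mean
#' @return named numeric `c(CC, TT)`.
#' @export
clustering_transitivity <- function(net) {
  g <- as_igraph(net)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc <- mean(ifelse(is.finite(cc), cc, 0))
  tt <- igraph::transitivity(g, type = "global")
  if (!is.finite(tt)) tt <- 0
  c(CC = cc, TT = tt)
}

#' Characteristic path length and global efficiency (SPL, GE)
#'
#' `SPL` is the mean shortest-path length over reachable ordered pairs
#' (i != j); if no pair is reachable it is 0. `GE` is the mean of `1/d_ij`
#' over all ordered pairs with `1/Inf = 0`, so disconnected graphs still get
#' finite values.
#'
#' @inheritParams degree_mean
#' @return named numeric `c(SPL, GE)`.
#' @export
path_metrics <- function(net) {
  g <- as_igraph(net)
  d <- igraph::distances(g)
  diag(d) <- NA
  finite <- d[is.finite(d) & !is.na(d)]
  spl <- if (length(finite)) mean(finite) else 0
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  n <- nrow(d)
  ge <- if (n > 1L) sum(inv, na.rm = TRUE) / (n * (n - 1L)) else 0
  c(SPL = spl, GE = ge)
}

#' Local efficiency (LE)
#'
#' Mean over nodes of the global efficiency of the subgraph induced by the
#' node's neighbours; nodes with fewer than 2 neighbours contribute 0.
#'
#' @inheritParams degree_mean
#' @return scalar local efficiency.
#' @export
local_efficiency <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  vals <- vapply(seq_len(n), function(v) {
    nb <- as.integer(igraph::neighbors(g, v))
    if (length(nb) < 2L) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    d <- igraph::distances(sub)
    diag(d) <- NA
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    k <- length(nb)
    sum(inv, na.rm = TRUE) / (k * (k - 1L))
  }, numeric(1L))
  mean(vals)
}

#' Degree assortativity (AC)
#'
#' Pearson correlation of the degrees at the two ends of each edge, counting
#' both orientations. Returns 0 with a warning when the degree variance over
#' edge ends is zero (e.g. regular graphs).
#'
#' @inheritParams degree_mean
#' @return assortativity coefficient in `[-1, 1]`.
#' @export
assortativity_coef <- function(net) {
  adj <- net_adjacency(net)
  idx <- which(adj == 1, arr.ind = TRUE)  # both orientations of each edge
  if (nrow(idx) == 0L) {
    warning("assortativity undefined for an edgeless graph; returning 0")
    return(0)
  }
  deg <- rowSums(adj)
  x <- deg[idx[, 1L]]
  y <- deg[idx[, 2L]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero degree variance over edge ends; returning 0")
    return(0)
  }
  stats::cor(x, y)
}

# Mean local clustering and reachable-pair SPL of an igraph object, the two
# ingredients normalized by the null ensemble.
.cc_of <- function(g) {
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  mean(ifelse(is.finite(cc), cc, 0))
}
.spl_of <- function(g) {
  d <- igraph::distances(g)
  diag(d) <- NA
  finite <- d[is.finite(d) & !is.na(d)]
  if (length(finite)) mean(finite) else 0
}

#' Small-worldness (SW)
#'
#' `SW = (CC / CC_rand) / (SPL / SPL_rand)` where `CC_rand` and `SPL_rand`
#' are ensemble means over degree-preserving rewired surrogates. Values
#' above 1 indicate small-world organization. Returns 0 with a warning when
#' the normalization is degenerate (`CC_rand`, `SPL_rand` or `SPL` equal 0).
#'
#' @inheritParams degree_mean
#' @param ens a [null_ensemble_spec()].
#' @param ensemble optional precomputed list of igraph surrogates (internal
#'   use, lets [feature_vector()] share one ensemble between SW and MZ).
#' @return small-worldness scalar.
#' @export
small_worldness <- function(net, ens = null_ensemble_spec(), ensemble = NULL) {
  g <- as_igraph(net)
  if (is.null(ensemble)) ensemble <- make_null_ensemble(g, ens)
  cc <- .cc_of(g)
  spl <- .spl_of(g)
  cc_r <- mean(vapply(ensemble, .cc_of, numeric(1L)))
  spl_r <- mean(vapply(ensemble, .spl_of, numeric(1L)))
  if (cc_r == 0 || spl_r == 0 || spl == 0) {
    warning("degenerate small-worldness normalization; returning 0")
    return(0)
  }
  (cc / cc_r) / (spl / spl_r)
}

#' Modularity (MD)
#'
#' Newman modularity Q of the partition found by greedy agglomerative
#' community optimization (deterministic). 0 for an edgeless graph.
#'
#' @inheritParams degree_mean
#' @return modularity Q of the selected partition.
#' @export
modularity_score <- function(net) {
  g <- as_igraph(net)
  if (igraph::ecount(g) == 0L) return(0)
  cl <- igraph::cluster_fast_greedy(g)
  igraph::modularity(cl)
}

triangle_count <- function(g) sum(igraph::count_triangles(g)) / 3

#' Motif z-score (MZ)
#'
#' Standardized excess of the triangle count relative to the
#' degree-preserving rewired ensemble:
#' `z = (T_real - mean(T_rand)) / sd(T_rand)` (sample sd). Returns 0 with a
#' warning when the ensemble variance is 0.
#'
#' @inheritParams small_worldness
#' @return motif z-score.
#' @export
motif_zscore <- function(net, ens = null_ensemble_spec(), ensemble = NULL) {
  g <- as_igraph(net)
  if (is.null(ensemble)) ensemble <- make_null_ensemble(g, ens)
  t_real <- triangle_count(g)
  t_rand <- vapply(ensemble, triangle_count, numeric(1L))
  s <- stats::sd(t_rand)
  if (!is.finite(s) || s == 0) {
    warning("zero triangle-count variance in null ensemble; returning 0")
    return(0)
  }
  (t_real - mean(t_rand)) / s
}

# Least-squares slope of log C(k) = -beta log k + c; returns beta.
.hc_regress <- function(k, ck) {
  fit <- stats::lm.fit(cbind(1, log(k)), log(ck))
  -unname(fit$coefficients[2L])
}

#' Hierarchy coefficient (HC)
#'
#' Exponent `beta` of the scaling `C(k) ~ k^-beta`, fitted by least squares
#' on `log C(k)` vs `log k`, where `C(k)` is the mean local clustering of
#' degree-`k` nodes; only nodes with degree >= 2 and positive clustering
#' qualify. Returns 0 with a warning when fewer than 2 distinct qualifying
#' degrees exist.
#'
#' @inheritParams degree_mean
#' @return hierarchy exponent (0 in the degenerate case).
#' @export
hierarchy_coefficient <- function(net) {
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  cl <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cl[!is.finite(cl)] <- 0
  ok <- deg >= 2 & cl > 0
  if (!any(ok)) {
    warning("no qualifying nodes for hierarchy fit; returning 0")
    return(0)
  }
  ck <- tapply(cl[ok], deg[ok], mean)
  k <- as.numeric(names(ck))
  if (length(k) < 2L) {
    warning("fewer than 2 distinct qualifying degrees; returning 0")
    return(0)
  }
  .hc_regress(k, as.numeric(ck))
}

#' Graph index complexity (GIC)
#'
#' `c = (lambda_max - 2 cos(pi / (n + 1))) / (n - 1 - 2 cos(pi / (n + 1)))`,
#' a normalization of the adjacency spectral radius between the path-graph
#' and complete-graph extremes, and `GIC = 4 c (1 - c)`. `c` is clamped to
#' `[0, 1]` so graphs sparser than a path (e.g. edgeless) give 0.
#'
#' @inheritParams degree_mean
#' @return graph index complexity in `[0, 1]`.
#' @export
graph_index_complexity <- function(net) {
  adj <- net_adjacency(net)
  n <- nrow(adj)
  if (n < 2L) return(0)
  lam <- max(eigen(adj, symmetric = TRUE, only.values = TRUE)$values)
  ref <- 2 * cos(pi / (n + 1))
  cc <- (lam - ref) / (n - 1 - ref)
  cc <- min(max(cc, 0), 1)
  4 * cc * (1 - cc)
}

#' Full 14-feature vector of a network
#'
#' Concatenates the features in the fixed order
#' DG, NB, CC, SPL, EB, GE, LE, TT, AC, SW, MD, MZ, HC, GIC. One rewired
#' null ensemble (seeded by `ens`) is shared by SW and MZ, so the vector is
#' deterministic given `ens$seed`. Non-finite values are mapped to 0 with a
#' warning; the result never contains NaN.
#'
#' @inheritParams small_worldness
#' @param quiet suppress degenerate-case warnings (used in bulk extraction).
#' @return named numeric vector of length 14.
#' @export
feature_vector <- function(net, ens = null_ensemble_spec(), quiet = FALSE) {
  compute <- function() {
    g <- as_igraph(net)
    ensemble <- make_null_ensemble(g, ens)
    v <- c(DG = degree_mean(net),
           betweenness_means(net)["NB"],
           clustering_transitivity(net)["CC"],
           path_metrics(net)["SPL"],
           betweenness_means(net)["EB"],
           path_metrics(net)["GE"],
           LE = local_efficiency(net),
           clustering_transitivity(net)["TT"],
           AC = assortativity_coef(net),
           SW = small_worldness(net, ens, ensemble = ensemble),
           MD = modularity_score(net),
           MZ = motif_zscore(net, ens, ensemble = ensemble),
           HC = hierarchy_coefficient(net),
           GIC = graph_index_complexity(net))
    names(v) <- feature_names_14
    bad <- !is.finite(v)
    if (any(bad)) {
      warning("non-finite features mapped to 0: ",
              paste(names(v)[bad], collapse = ", "))
      v[bad] <- 0
    }
    v
  }
  if (quiet) suppressWarnings(compute()) else compute()
}
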