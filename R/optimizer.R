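# Multi-objective particle swarm optimization with Gaussian differential
# mutation (MOPSO-GDM) and its baselines: plain MOPSO, MOPSO-M (polynomial
# mutation) and NSGA-II. Positions are real vectors in [0, 1]^D; for feature
# selection they are decoded to binary masks by strict thresholding.

#' Optimizer configuration
#'
#' Defaults follow the study protocol: 30 particles, 50 iterations, inertia
#' `w = 0.7`, learning factors `c1 = c2 = 2`, mutation rate 0.1, GDM weights
#' `p1 = p2 = 0.5`, decode threshold 0.5. Archive capacity, velocity clamp
#' and initialization are package conventions.
#'
#' @param n_particles swarm / population size.
#' @param n_iterations iterations (generations for NSGA-II).
#' @param w inertia weight.
#' @param c1,c2 cognitive and social learning factors.
#' @param mutation_rate per-particle mutation probability.
#' @param p1,p2 GDM weight coefficients.
#' @param decode_threshold mask decode threshold (strict `>`).
#' @param archive_capacity maximum archive size.
#' @param v_max per-dimension velocity clamp.
#' @param gdm_literal if `TRUE`, the Gaussian differential mutation output
#'   *replaces* the position (the update rule read literally); default
#'   `FALSE` adds it to the current position as a perturbation.
#' @param mutation_eta polynomial-mutation distribution index (MOPSO-M and
#'   NSGA-II).
#' @param sbx_eta SBX crossover distribution index (NSGA-II).
#' @param seed integer seed; fixes the whole run.
#' @return object of class `optimizer_config`.
#' @export
optimizer_config <- function(n_particles = 30, n_iterations = 50, w = 0.7,
                             c1 = 2, c2 = 2, mutation_rate = 0.1,
                             p1 = 0.5, p2 = 0.5, decode_threshold = 0.5,
                             archive_capacity = 100, v_max = 0.5,
                             gdm_literal = FALSE, mutation_eta = 20,
                             sbx_eta = 15, seed = 1) {
  check_number(n_particles, "n_particles", lower = 2, integer = TRUE)
  check_number(n_iterations, "n_iterations", lower = 1, integer = TRUE)
  check_number(w, "w", lower = 0)
  check_number(c1, "c1", lower = 0)
  check_number(c2, "c2", lower = 0)
  check_number(mutation_rate, "mutation_rate", lower = 0, upper = 1)
  check_number(p1, "p1", lower = 0, upper = 1)
  check_number(p2, "p2", lower = 0, upper = 1)
  check_number(decode_threshold, "decode_threshold", lower = 0, upper = 1)
  check_number(archive_capacity, "archive_capacity", lower = 1,
               integer = TRUE)
  check_number(v_max, "v_max", lower = .Machine$double.eps)
  check_number(mutation_eta, "mutation_eta", lower = 1)
  check_number(sbx_eta, "sbx_eta", lower = 1)
  check_number(seed, "seed", integer = TRUE)
  structure(list(n_particles = as.integer(n_particles),
                 n_iterations = as.integer(n_iterations),
                 w = w, c1 = c1, c2 = c2, mutation_rate = mutation_rate,
                 p1 = p1, p2 = p2, decode_threshold = decode_threshold,
                 archive_capacity = as.integer(archive_capacity),
                 v_max = v_max, gdm_literal = isTRUE(gdm_literal),
                 mutation_eta = mutation_eta, sbx_eta = sbx_eta,
                 seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Pareto dominance (minimization)
#'
#' @param u,v numeric objective vectors of equal length.
#' @return `TRUE` iff `u` is no worse in every objective and strictly better
#'   in at least one.
#' @export
dominates <- function(u, v) {
  if (length(u) != length(v)) stop("objective counts differ", call. = FALSE)
  all(u <= v) && any(u < v)
}

# Logical vector: which rows of the m x k objective matrix are non-dominated.
nondominated_rows <- function(M) {
  m <- nrow(M)
  keep <- rep(TRUE, m)
  for (i in seq_len(m)) {
    if (!keep[i]) next
    le <- M <= matrix(M[i, ], m, ncol(M), byrow = TRUE)
    lt <- M < matrix(M[i, ], m, ncol(M), byrow = TRUE)
    dom_by <- rowSums(le) == ncol(M) & rowSums(lt) > 0
    if (any(dom_by)) keep[i] <- FALSE
  }
  keep
}

# Crowding distance over objective space (boundary points get Inf).
crowding_distance <- function(M) {
  m <- nrow(M)
  if (m <= 2L) return(rep(Inf, m))
  cd <- numeric(m)
  for (j in seq_len(ncol(M))) {
    o <- order(M[, j])
    span <- M[o[m], j] - M[o[1L], j]
    cd[o[c(1L, m)]] <- Inf
    if (span > 0) {
      cd[o[2:(m - 1L)]] <- cd[o[2:(m - 1L)]] +
        (M[o[3:m], j] - M[o[1:(m - 2L)], j]) / span
    }
  }
  cd
}

#' Decode a real position to a binary feature mask
#'
#' Bit d is 1 iff `position[d] > threshold` (strict).
#'
#' @param position numeric vector in `[0, 1]^D`.
#' @param threshold decode threshold, default 0.5.
#' @return integer 0/1 vector.
#' @export
decode <- function(position, threshold = 0.5) {
  as.integer(position > threshold)
}

empty_archive <- function(dim, n_obj) {
  list(positions = matrix(numeric(0), 0L, dim),
       objectives = matrix(numeric(0), 0L, n_obj))
}

#' Insert candidates into a bounded Pareto archive
#'
#' Keeps the mutually non-dominated union; when over capacity, repeatedly
#' drops the most crowded entry (smallest crowding distance in objective
#' space).
#'
#' @param archive list with matrices `positions` and `objectives`.
#' @param positions candidate positions (matrix, rows) or one vector.
#' @param objectives matching objective rows.
#' @param capacity maximum archive size.
#' @return updated archive list.
#' @export
archive_update <- function(archive, positions, objectives, capacity = 100) {
  if (is.null(dim(positions))) positions <- matrix(positions, nrow = 1L)
  if (is.null(dim(objectives))) objectives <- matrix(objectives, nrow = 1L)
  pos <- rbind(archive$positions, positions)
  obj <- rbind(archive$objectives, objectives)
  keep <- nondominated_rows(obj)
  pos <- pos[keep, , drop = FALSE]
  obj <- obj[keep, , drop = FALSE]
  while (nrow(obj) > capacity) {
    cd <- crowding_distance(obj)
    drop <- which.min(cd)
    pos <- pos[-drop, , drop = FALSE]
    obj <- obj[-drop, , drop = FALSE]
  }
  list(positions = pos, objectives = obj)
}

# Binary tournament on archive crowding distance; returns one leader row per
# particle. Draw order is fixed for reproducibility across variants.
select_leaders <- function(archive, n) {
  m <- nrow(archive$positions)
  if (m == 1L) {
    return(archive$positions[rep(1L, n), , drop = FALSE])
  }
  cd <- crowding_distance(archive$objectives)
  a <- sample.int(m, n, replace = TRUE)
  b <- sample.int(m, n, replace = TRUE)
  pick <- ifelse(cd[a] >= cd[b], a, b)
  archive$positions[pick, , drop = FALSE]
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Polynomial mutation of one position vector (per-dimension prob 1/D).
poly_mutate <- function(x, eta) {
  d <- length(x)
  do <- stats::runif(d) < 1 / d
  if (!any(do)) return(x)
  u <- stats::runif(sum(do))
  delta <- ifelse(u < 0.5,
                  (2 * u)^(1 / (eta + 1)) - 1,
                  1 - (2 * (1 - u))^(1 / (eta + 1)))
  x[do] <- clamp01(x[do] + delta)
  x
}

evaluate_positions <- function(problem, X) {
  if (!is.null(problem$evaluate_matrix)) {
    out <- problem$evaluate_matrix(X)
  } else {
    out <- t(apply(X, 1L, problem$evaluate))
  }
  matrix(out, nrow = nrow(X))
}

# Core MOPSO engine. `mutation` is "none" (plain MOPSO), "gdm" (MOPSO-GDM)
# or "poly" (MOPSO-M). The per-particle mutation-gate uniform is drawn in
# every variant, so mutation_rate = 0 under "gdm" reproduces "none"
# bit-for-bit with a shared seed.
run_mopso_engine <- function(problem, cfg, mutation) {
  d <- problem$dim
  n <- cfg$n_particles
  rate <- if (mutation == "none") 0 else cfg$mutation_rate
  with_seed(cfg$seed, {
    X <- matrix(stats::runif(n * d), n, d)
    V <- matrix(0, n, d)
    F0 <- evaluate_positions(problem, X)
    P <- X
    Fp <- F0
    arch <- archive_update(empty_archive(d, ncol(F0)), X, F0,
                           cfg$archive_capacity)
    history <- vector("list", cfg$n_iterations)
    for (iter in seq_len(cfg$n_iterations)) {
      L <- select_leaders(arch, n)
      r1 <- matrix(stats::runif(n * d), n, d)
      r2 <- matrix(stats::runif(n * d), n, d)
      V <- cfg$w * V + cfg$c1 * r1 * (P - X) + cfg$c2 * r2 * (L - X)
      V <- pmin(pmax(V, -cfg$v_max), cfg$v_max)
      X <- clamp01(X + V)
      gate <- stats::runif(n)
      for (i in which(gate < rate)) {
        if (mutation == "gdm") {
          f12 <- stats::rnorm(2L)
          lr <- X[sample.int(n, 1L), ]
          pert <- cfg$p1 * f12[1L] * (P[i, ] - X[i, ]) +
            cfg$p2 * f12[2L] * (lr - X[i, ])
          X[i, ] <- clamp01(if (cfg$gdm_literal) pert else X[i, ] + pert)
        } else {
          X[i, ] <- poly_mutate(X[i, ], cfg$mutation_eta)
        }
      }
      Fx <- evaluate_positions(problem, X)
      for (i in seq_len(n)) {
        if (dominates(Fx[i, ], Fp[i, ])) {
          P[i, ] <- X[i, ]; Fp[i, ] <- Fx[i, ]
        } else if (!dominates(Fp[i, ], Fx[i, ]) &&
                   any(Fx[i, ] != Fp[i, ])) {
          if (stats::runif(1L) < 0.5) {
            P[i, ] <- X[i, ]; Fp[i, ] <- Fx[i, ]
          }
        }
      }
      arch <- archive_update(arch, X, Fx, cfg$archive_capacity)
      history[[iter]] <- iteration_record(iter, arch, problem)
    }
    list(archive = arch, history = do.call(rbind, history))
  })
}

iteration_record <- function(iter, arch, problem) {
  n_eval <- if (!is.null(problem$counters)) problem$counters$n_eval else NA_integer_
  n_distinct <- if (!is.null(problem$counters)) problem$counters$n_distinct else NA_integer_
  data.frame(iteration = iter, archive_size = nrow(arch$objectives),
             best_mean = min(rowMeans(arch$objectives)),
             n_eval = n_eval, n_distinct = n_distinct)
}

# --- NSGA-II ----------------------------------------------------------------

fast_nondominated_rank <- function(M) {
  m <- nrow(M)
  rank <- integer(m)
  remaining <- rep(TRUE, m)
  r <- 0L
  while (any(remaining)) {
    r <- r + 1L
    idx <- which(remaining)
    nd <- nondominated_rows(M[idx, , drop = FALSE])
    rank[idx[nd]] <- r
    remaining[idx[nd]] <- FALSE
  }
  rank
}

sbx_crossover <- function(a, b, eta) {
  d <- length(a)
  c1 <- a; c2 <- b
  if (stats::runif(1L) > 0.9) return(list(c1, c2))  # pc = 0.9
  do <- stats::runif(d) < 0.5
  u <- stats::runif(d)
  beta <- ifelse(u <= 0.5,
                 (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  h1 <- 0.5 * ((1 + beta) * a + (1 - beta) * b)
  h2 <- 0.5 * ((1 - beta) * a + (1 + beta) * b)
  c1[do] <- h1[do]; c2[do] <- h2[do]
  list(clamp01(c1), clamp01(c2))
}

run_nsga2_engine <- function(problem, cfg) {
  d <- problem$dim
  n <- cfg$n_particles
  with_seed(cfg$seed, {
    X <- matrix(stats::runif(n * d), n, d)
    Fx <- evaluate_positions(problem, X)
    history <- vector("list", cfg$n_iterations)
    arch <- NULL
    for (gen in seq_len(cfg$n_iterations)) {
      rank <- fast_nondominated_rank(Fx)
      cd <- numeric(n)
      for (r in unique(rank)) {
        idx <- which(rank == r)
        cd[idx] <- crowding_distance(Fx[idx, , drop = FALSE])
      }
      tourney <- function() {
        ab <- sample.int(n, 2L, replace = TRUE)
        i <- ab[1L]; j <- ab[2L]
        if (rank[i] < rank[j]) i
        else if (rank[j] < rank[i]) j
        else if (cd[i] >= cd[j]) i else j
      }
      kids <- matrix(0, n, d)
      k <- 1L
      while (k <= n) {
        pa <- X[tourney(), ]; pb <- X[tourney(), ]
        off <- sbx_crossover(pa, pb, cfg$sbx_eta)
        for (o in off) {
          if (k > n) break
          if (stats::runif(1L) < cfg$mutation_rate) {
            o <- poly_mutate(o, cfg$mutation_eta)
          }
          kids[k, ] <- o
          k <- k + 1L
        }
      }
      Fk <- evaluate_positions(problem, kids)
      allX <- rbind(X, kids)
      allF <- rbind(Fx, Fk)
      rank2 <- fast_nondominated_rank(allF)
      sel <- integer(0)
      for (r in sort(unique(rank2))) {
        idx <- which(rank2 == r)
        if (length(sel) + length(idx) <= n) {
          sel <- c(sel, idx)
        } else {
          cdr <- crowding_distance(allF[idx, , drop = FALSE])
          sel <- c(sel, idx[order(cdr, decreasing = TRUE)][seq_len(n - length(sel))])
          break
        }
      }
      X <- allX[sel, , drop = FALSE]
      Fx <- allF[sel, , drop = FALSE]
      nd <- nondominated_rows(Fx)
      arch <- archive_update(empty_archive(d, ncol(Fx)),
                             X[nd, , drop = FALSE], Fx[nd, , drop = FALSE],
                             cfg$archive_capacity)
      history[[gen]] <- iteration_record(gen, arch, problem)
    }
    list(archive = arch, history = do.call(rbind, history))
  })
}

#' Run a multi-objective optimization algorithm
#'
#' `"mopso"` is the same engine as `"mopso_gdm"` with the mutation disabled
#' (so `mutation_rate = 0` makes the two trajectories identical under a
#' shared seed); `"mopso_m"` uses polynomial mutation consistent with the
#' NSGA-II operator.
#'
#' @param problem a problem list exposing `dim`, `n_obj`, `evaluate(x)` (and
#'   optionally a vectorized `evaluate_matrix`), e.g. from
#'   [subset_problem()] or [zdt_problem()].
#' @param algorithm one of `"mopso_gdm"`, `"mopso"`, `"mopso_m"`, `"nsga2"`.
#' @param config an [optimizer_config()].
#' @return object of class `pareto_result`: list with `positions`,
#'   `objectives` (the final non-dominated archive), `masks` (if the problem
#'   decodes positions), `history` (per-iteration archive size, best mean
#'   objective, evaluation and distinct-mask counters), `algorithm`,
#'   `config`.
#' @export
run_optimizer <- function(problem,
                          algorithm = c("mopso_gdm", "mopso", "mopso_m",
                                        "nsga2"),
                          config = optimizer_config()) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(config, "optimizer_config"))
  out <- switch(algorithm,
    mopso_gdm = run_mopso_engine(problem, config, "gdm"),
    mopso = run_mopso_engine(problem, config, "none"),
    mopso_m = run_mopso_engine(problem, config, "poly"),
    nsga2 = run_nsga2_engine(problem, config))
  res <- list(algorithm = algorithm,
              positions = out$archive$positions,
              objectives = out$archive$objectives,
              history = out$history,
              config = config)
  if (!is.null(problem$decode)) {
    res$masks <- t(apply(out$archive$positions, 1L,
                         function(p) problem$decode(p)))
  }
  class(res) <- "pareto_result"
  res
}

#' @export
print.pareto_result <- function(x, ...) {
  cat(sprintf("<pareto_result> %s: %d non-dominated solutions, %d objectives\n",
              x$algorithm, nrow(x$objectives), ncol(x$objectives)))
  if (nrow(x$objectives)) {
    cat(sprintf("  best mean objective: %.4f\n",
                min(rowMeans(x$objectives))))
  }
  invisible(x)
}

#' @export
summary.pareto_result <- function(object, ...) {
  obj <- object$objectives
  cat(sprintf("%s archive (%d solutions)\n", object$algorithm, nrow(obj)))
  print(apply(obj, 2L, function(col) {
    c(min = min(col), median = stats::median(col), max = max(col))
  }))
  invisible(object)
}
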