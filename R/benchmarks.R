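# ZDT two-objective benchmark suite with analytic Pareto fronts, front
# quality metrics (IGD, hypervolume), and the desk-scale validation
# campaign (30 particles, 50 iterations, 20 trials, D in {10, 50}).
# ZDT5 is Boolean-coded and excluded.

zdt_ids <- c("zdt1", "zdt2", "zdt3", "zdt4", "zdt6")

#' Construct a ZDT benchmark problem
#'
#' Positions handed to the optimizer live in `[0, 1]^D` and are mapped
#' affinely onto the problem domain (`zdt4`: `x1` in `[0, 1]`, others in
#' `[-5, 5]`), keeping one optimizer code path. Evaluation is vectorized
#' over rows.
#'
#' @param id one of `"zdt1"`, `"zdt2"`, `"zdt3"`, `"zdt4"`, `"zdt6"`.
#' @param dim number of decision variables (study protocol: 10 or 50).
#' @return problem list with `id`, `dim`, `n_obj = 2`, `lower`, `upper`,
#'   `evaluate(u)` and `evaluate_matrix(U)` (encoded inputs),
#'   `eval_domain(x)` (domain-scale input with bounds checking).
#' @export
zdt_problem <- function(id = zdt_ids, dim = 10) {
  id <- match.arg(id)
  check_number(dim, "dim", lower = 2, integer = TRUE)
  dim <- as.integer(dim)
  lower <- rep(0, dim)
  upper <- rep(1, dim)
  if (id == "zdt4") {
    lower[-1L] <- -5
    upper[-1L] <- 5
  }
  eval_domain_matrix <- function(X) {
    X <- matrix(X, ncol = dim)
    lo <- matrix(lower, nrow(X), dim, byrow = TRUE)
    hi <- matrix(upper, nrow(X), dim, byrow = TRUE)
    if (any(X < lo - 1e-12) || any(X > hi + 1e-12)) {
      stop("point outside the ", toupper(id), " domain", call. = FALSE)
    }
    f1 <- switch(id,
      zdt6 = 1 - exp(-4 * X[, 1L]) * sin(6 * pi * X[, 1L])^6,
      X[, 1L])
    rest <- X[, -1L, drop = FALSE]
    g <- switch(id,
      zdt1 = ,
      zdt2 = ,
      zdt3 = 1 + 9 * rowSums(rest) / (dim - 1L),
      zdt4 = 1 + 10 * (dim - 1L) +
        rowSums(rest^2 - 10 * cos(4 * pi * rest)),
      zdt6 = 1 + 9 * (rowSums(rest) / (dim - 1L))^0.25)
    h <- switch(id,
      zdt1 = ,
      zdt4 = 1 - sqrt(f1 / g),
      zdt2 = ,
      zdt6 = 1 - (f1 / g)^2,
      zdt3 = 1 - sqrt(f1 / g) - (f1 / g) * sin(10 * pi * f1))
    cbind(f1 = f1, f2 = g * h)
  }
  to_domain <- function(U) {
    U <- matrix(U, ncol = dim)
    lo <- matrix(lower, nrow(U), dim, byrow = TRUE)
    hi <- matrix(upper, nrow(U), dim, byrow = TRUE)
    lo + U * (hi - lo)
  }
  list(id = id, dim = dim, n_obj = 2L, lower = lower, upper = upper,
       eval_domain = function(x) drop(eval_domain_matrix(x)),
       evaluate = function(u) drop(eval_domain_matrix(to_domain(u))),
       evaluate_matrix = function(U) eval_domain_matrix(to_domain(U)))
}

#' Evaluate a ZDT problem at a domain-scale point
#'
#' @param p a [zdt_problem()].
#' @param x decision vector in the problem domain.
#' @return numeric `c(f1, f2)`.
#' @export
zdt_eval <- function(p, x) {
  p$eval_domain(x)
}

#' Sample the analytic Pareto front of a ZDT problem
#'
#' A uniform grid is mapped through the known front equation at `g = 1`;
#' for the disconnected (`zdt3`) and non-uniform (`zdt6`) fronts, dominated
#' grid points are removed, which enumerates the true front segments.
#'
#' @param p a [zdt_problem()].
#' @param n_points number of reference points (>= 2), default 1000.
#' @return matrix with columns `f1`, `f2`, mutually non-dominated.
#' @export
analytic_front <- function(p, n_points = 1000) {
  check_number(n_points, "n_points", lower = 2, integer = TRUE)
  if (p$id %in% c("zdt1", "zdt4")) {
    f1 <- seq(0, 1, length.out = n_points)
    front <- cbind(f1 = f1, f2 = 1 - sqrt(f1))
  } else if (p$id == "zdt2") {
    f1 <- seq(0, 1, length.out = n_points)
    front <- cbind(f1 = f1, f2 = 1 - f1^2)
  } else if (p$id == "zdt3") {
    f1 <- seq(0, 1, length.out = 20L * n_points)
    front <- cbind(f1 = f1, f2 = 1 - sqrt(f1) - f1 * sin(10 * pi * f1))
    front <- front[nondominated_rows(front), , drop = FALSE]
    front <- front[seq(1L, nrow(front), length.out = min(n_points, nrow(front))), ,
                   drop = FALSE]
  } else { # zdt6
    x1 <- seq(0, 1, length.out = 20L * n_points)
    f1 <- 1 - exp(-4 * x1) * sin(6 * pi * x1)^6
    front <- unique(cbind(f1 = f1, f2 = 1 - f1^2))
    front <- front[nondominated_rows(front), , drop = FALSE]
    front <- front[order(front[, 1L]), , drop = FALSE]
    front <- front[seq(1L, nrow(front), length.out = min(n_points, nrow(front))), ,
                   drop = FALSE]
  }
  front
}

#' Inverted generational distance
#'
#' Mean over reference-front points of the Euclidean distance to the nearest
#' obtained point; 0 iff the archive covers every reference sample. Lower is
#' better.
#'
#' @param archive_objectives matrix of obtained objective vectors (rows).
#' @param reference_front matrix of reference front samples (rows).
#' @return nonnegative IGD value.
#' @export
igd <- function(archive_objectives, reference_front) {
  A <- matrix(archive_objectives, ncol = ncol(reference_front))
  if (nrow(A) == 0L || nrow(reference_front) == 0L) {
    stop("empty archive or reference front", call. = FALSE)
  }
  # squared distances via the expansion |a - r|^2 = |a|^2 + |r|^2 - 2 a.r
  a2 <- rowSums(A^2)
  r2 <- rowSums(reference_front^2)
  cross <- reference_front %*% t(A)
  d2 <- outer(r2, a2, "+") - 2 * cross
  mean(sqrt(pmax(apply(d2, 1L, min), 0)))
}

#' Two-objective hypervolume
#'
#' Area dominated by the archive and bounded by `ref` (points beyond `ref`
#' are clipped out). Larger is better.
#'
#' @param archive_objectives matrix of objective vectors (rows, minimized).
#' @param ref reference point, default `c(1.1, 1.1)`.
#' @return nonnegative hypervolume.
#' @export
hypervolume2 <- function(archive_objectives, ref = c(1.1, 1.1)) {
  A <- matrix(archive_objectives, ncol = 2L)
  A <- A[A[, 1L] < ref[1L] & A[, 2L] < ref[2L], , drop = FALSE]
  if (nrow(A) == 0L) return(0)
  A <- A[nondominated_rows(A), , drop = FALSE]
  A <- A[order(A[, 1L]), , drop = FALSE]
  x <- c(A[, 1L], ref[1L])
  sum((x[-1L] - x[-length(x)]) * (ref[2L] - A[, 2L]))
}

#' Run the ZDT validation campaign
#'
#' For every (algorithm, problem, dimension) cell, runs `n_trials` seeded
#' trials and scores the final archive by IGD against a 1000-point analytic
#' reference front (plus hypervolume). Trial seeds derive from `seed` by
#' counters, so cells are independent of each other.
#'
#' @param algorithms character vector of algorithm names
#'   (see [run_optimizer()]).
#' @param problems character vector of ZDT ids.
#' @param dims integer vector of dimensions.
#' @param config an [optimizer_config()]; its seed field is replaced per
#'   trial.
#' @param n_trials trials per cell (study protocol: 20).
#' @param seed campaign master seed.
#' @return object of class `zdt_campaign`: list with `results` (long data
#'   frame: algorithm, problem, dim, trial, igd, hypervolume) and `summary`
#'   (median and IQR IGD per cell, plus `front_attained` = median IGD < 0.1).
#' @export
zdt_campaign <- function(algorithms = c("mopso_gdm", "mopso", "mopso_m",
                                        "nsga2"),
                         problems = zdt_ids, dims = 10,
                         config = optimizer_config(), n_trials = 20,
                         seed = 1) {
  rows <- list()
  for (pid in problems) {
    for (d in dims) {
      prob <- zdt_problem(pid, dim = d)
      front <- analytic_front(prob, 1000L)
      for (alg in algorithms) {
        for (tr in seq_len(n_trials)) {
          cfg <- config
          cfg$seed <- sub_seed(seed, match(pid, zdt_ids), d,
                               match(alg, c("mopso_gdm", "mopso", "mopso_m",
                                            "nsga2")), tr)
          res <- run_optimizer(prob, alg, cfg)
          rows[[length(rows) + 1L]] <- data.frame(
            algorithm = alg, problem = pid, dim = d, trial = tr,
            igd = igd(res$objectives, front),
            hypervolume = hypervolume2(res$objectives),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(
    split(results, list(results$algorithm, results$problem, results$dim),
          drop = TRUE),
    function(df) {
      data.frame(algorithm = df$algorithm[1L], problem = df$problem[1L],
                 dim = df$dim[1L],
                 median_igd = stats::median(df$igd),
                 iqr_igd = stats::IQR(df$igd),
                 front_attained = stats::median(df$igd) < 0.1,
                 stringsAsFactors = FALSE)
    }))
  rownames(smry) <- NULL
  structure(list(results = results, summary = smry), class = "zdt_campaign")
}

#' @export
print.zdt_campaign <- function(x, ...) {
  cat("<zdt_campaign>\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Write campaign results to CSV
#'
#' @param campaign a `zdt_campaign`.
#' @param path output CSV path.
#' @export
write_campaign_csv <- function(campaign, path) {
  utils::write.csv(campaign$results, path, row.names = FALSE)
  invisible(path)
}
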