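# Internal helpers: validation, seeding, small numeric utilities.

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_field(field, "must be a single finite number")
  }
  if (x < lower || x > upper) {
    stop_field(field, sprintf("must be in [%s, %s]", lower, upper))
  }
  if (integer && x != round(x)) stop_field(field, "must be a whole number")
  invisible(x)
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random stream set from `seed`, then restores
#' the caller's stream, so seeded internals never perturb user-level
#' reproducibility.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based sub-stream derivation: mixes a base seed with integer
# coordinates so adding epochs/trials never reshuffles earlier ones.
# Result is a valid 32-bit seed.
sub_seed <- function(seed, ...) {
  ids <- c(...)
  val <- (as.double(seed) %% 2147483647) + 1
  for (i in ids) {
    val <- (val * 69069 + as.double(i) + 1) %% 2147483647
  }
  as.integer(val)
}

# min-max normalization to [0, 1] per column; constant columns map to 0.
minmax_normalize <- function(x) {
  x <- as.matrix(x)
  rng <- apply(x, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  span[span == 0] <- 1
  out <- sweep(sweep(x, 2L, rng[1L, ], "-"), 2L, span, "/")
  out[, rng[2L, ] - rng[1L, ] == 0] <- 0
  out
}
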