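# Wrapper objectives: cross-validated classification error of three
# classifier families (F1 SVM, F2 Gaussian naive Bayes, F3 linear
# discriminant) plus a Fisher-style distance measure (F4), evaluated on a
# masked feature subset.

#' Feature table with binary class labels
#'
#' @param table numeric samples x features matrix of finite values.
#' @param labels factor (or coercible) with exactly 2 levels, >= 2 samples
#'   per class.
#' @param feature_names optional column names; defaults to `colnames(table)`.
#' @param meta optional data frame of per-sample metadata (epoch id, band,
#'   subject), carried along unchanged.
#' @return object of class `feature_dataset` with fields `table`, `labels`,
#'   `feature_names`, `meta`.
#' @export
feature_dataset <- function(table, labels, feature_names = NULL, meta = NULL) {
  table <- as.matrix(table)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop_field("labels", "need exactly 2 classes")
  if (length(labels) != nrow(table)) {
    stop_field("labels", "length must match row count")
  }
  if (any(table(labels) < 2L)) {
    stop_field("labels", "need at least 2 samples per class")
  }
  if (!all(is.finite(table))) stop_field("table", "must be finite")
  if (is.null(feature_names)) {
    feature_names <- colnames(table)
    if (is.null(feature_names)) {
      feature_names <- sprintf("f%02d", seq_len(ncol(table)))
    }
  }
  colnames(table) <- feature_names
  structure(list(table = table, labels = labels,
                 feature_names = feature_names, meta = meta),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset> %d samples x %d features (%s)\n",
              nrow(x$table), ncol(x$table),
              paste(sprintf("%s: %d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

# Stratified fold assignment: within each class, a seeded shuffle is dealt
# cyclically over k folds. Returns an integer fold id per sample. Memoized
# by (labels, k, seed) since the wrapper search reuses one assignment.
.fold_cache <- new.env(parent = emptyenv())

make_folds <- function(labels, k = 10, seed = 1) {
  key <- paste(c(k, seed, as.integer(labels)), collapse = ",")
  hit <- .fold_cache[[key]]
  if (!is.null(hit)) return(hit)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  .fold_cache[[key]] <- fold
  fold
}

# --- classifier engines ------------------------------------------------------
# Each takes standardized train/test matrices and returns predicted labels
# for the test rows. SVM goes through e1071; NB and DA are closed-form
# implementations vectorized for the wrapper search's inner loop (their
# predictions are cross-checked against e1071::naiveBayes and MASS::lda in
# the test suite).

fitpred_svm <- function(xtr, ytr, xte) {
  v <- stats::var(as.vector(xtr))
  gam <- if (is.finite(v) && v > 0) 1 / (ncol(xtr) * v) else 1 / ncol(xtr)
  fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = 1, gamma = gam,
                    scale = FALSE)
  stats::predict(fit, xte)
}

colvars <- function(x) {
  n <- nrow(x)
  (colSums(x^2) - n * colMeans(x)^2) / (n - 1L)
}

fitpred_nb <- function(xtr, ytr, xte) {
  lev <- levels(ytr)
  scores <- vapply(lev, function(cl) {
    xi <- xtr[ytr == cl, , drop = FALSE]
    mu <- colMeans(xi)
    vr <- pmax(colvars(xi), 1e-9)
    prior <- log(nrow(xi) / nrow(xtr))
    # sum_j (x - mu)^2 / vr expanded to avoid per-class matrix copies
    w <- 1 / vr
    quad <- (xte^2 %*% w) - 2 * (xte %*% (mu * w)) + sum(mu^2 * w)
    as.numeric(-0.5 * quad) - 0.5 * sum(log(2 * pi * vr)) + prior
  }, numeric(nrow(xte)))
  factor(lev[max.col(matrix(scores, nrow(xte)))], levels = lev)
}

fitpred_da <- function(xtr, ytr, xte) {
  lev <- levels(ytr)
  x0 <- xtr[ytr == lev[1L], , drop = FALSE]
  x1 <- xtr[ytr == lev[2L], , drop = FALSE]
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  n0 <- nrow(x0); n1 <- nrow(x1)
  s <- (crossprod(x0) - n0 * tcrossprod(mu0) +
          crossprod(x1) - n1 * tcrossprod(mu1)) / (n0 + n1 - 2L)
  # ridge only if numerically singular
  w <- tryCatch(solve(s, mu1 - mu0), error = function(e) {
    solve(s + diag(1e-8 * max(diag(s), 1), ncol(s)), mu1 - mu0)
  })
  thr <- as.numeric(crossprod(w, (mu0 + mu1) / 2)) - log(n1 / n0)
  factor(lev[(as.numeric(xte %*% w) > thr) + 1L], levels = lev)
}

classifier_engine <- function(classifier) {
  switch(classifier, svm = fitpred_svm, nb = fitpred_nb, da = fitpred_da,
         stop("unknown classifier: ", classifier, call. = FALSE))
}

# z-score test columns by training-fold statistics only (sd 0 -> scale 1).
standardize_pair <- function(xtr, xte) {
  mu <- colMeans(xtr)
  sd <- sqrt(colvars(xtr))
  sd[sd == 0] <- 1
  list(tr = t((t(xtr) - mu) / sd),
       te = t((t(xte) - mu) / sd))
}

# Mean over folds of the per-fold error rate, for one or several classifier
# engines sharing the same folds and standardization.
cv_error_multi <- function(x, labels, fold, classifiers) {
  fold_ids <- sort(unique(fold))
  errs <- matrix(0, length(fold_ids), length(classifiers),
                 dimnames = list(NULL, classifiers))
  for (fi in seq_along(fold_ids)) {
    te <- fold == fold_ids[fi]
    sp <- standardize_pair(x[!te, , drop = FALSE], x[te, , drop = FALSE])
    ytr <- labels[!te]
    yte <- labels[te]
    for (cl in classifiers) {
      pred <- classifier_engine(cl)(sp$tr, ytr, sp$te)
      errs[fi, cl] <- mean(pred != yte)
    }
  }
  colMeans(errs)
}

cv_error_folds <- function(x, labels, fold, classifier) {
  unname(cv_error_multi(x, labels, fold, classifier))
}

#' Cross-validated classification error of a feature subset
#'
#' Mean misclassification rate over stratified folds (`kfold10`) or over all
#' single-sample holdouts (`loo`). Features are z-scored using training-fold
#' statistics only; fold shuffling is seeded.
#'
#' @param ds a [feature_dataset()].
#' @param mask logical or 0/1 vector selecting >= 1 feature.
#' @param classifier `"svm"`, `"nb"` (Gaussian naive Bayes) or `"da"`
#'   (linear discriminant).
#' @param scheme `"kfold10"` or `"loo"`.
#' @param seed fold-shuffle seed (ignored for `loo`).
#' @return error rate in `[0, 1]`.
#' @export
cv_error <- function(ds, mask, classifier = c("svm", "nb", "da"),
                     scheme = c("kfold10", "loo"), seed = 1) {
  classifier <- match.arg(classifier)
  scheme <- match.arg(scheme)
  mask <- as.logical(mask)
  if (length(mask) != ncol(ds$table)) {
    stop_field("mask", "length must match feature count")
  }
  if (!any(mask)) stop("empty mask: no features selected", call. = FALSE)
  x <- ds$table[, mask, drop = FALSE]
  fold <- if (scheme == "kfold10") {
    make_folds(ds$labels, 10L, seed)
  } else {
    seq_len(nrow(x))
  }
  cv_error_folds(x, ds$labels, fold, classifier)
}

#' Fisher-style distance objective (F4)
#'
#' `D_b` is the mean over samples of the distance to the *nearest* sample of
#' the other class; `D_w` the mean distance to the *farthest* other sample
#' of the same class (a singleton class contributes 0). Distances are
#' Euclidean on the masked columns as given (normalize upstream if desired).
#' `F4 = 1 / (1 + exp(-(D_w - D_b)))`, always in `(0, 1)`; smaller is
#' better (compact classes far apart).
#'
#' @inheritParams cv_error
#' @return F4 value in `(0, 1)`.
#' @export
distance_objective <- function(ds, mask) {
  mask <- as.logical(mask)
  if (length(mask) != ncol(ds$table)) {
    stop_field("mask", "length must match feature count")
  }
  if (!any(mask)) stop("empty mask: no features selected", call. = FALSE)
  x <- ds$table[, mask, drop = FALSE]
  n <- nrow(x)
  # squared-distance matrix via the Gram expansion (faster than dist() for
  # the wrapper search's repeated calls)
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d <- sqrt(pmax(d2, 0))
  same <- outer(ds$labels, ds$labels, "==")
  other <- d
  other[same] <- Inf                       # keep cross-class only
  db_i <- apply(other, 1L, min)
  within <- d
  within[!same] <- -Inf                    # keep same-class only
  diag(within) <- -Inf                     # exclude self
  dw_i <- pmax(apply(within, 1L, max), 0)  # singleton class contributes 0
  db <- mean(db_i)
  dw <- mean(dw_i)
  1 / (1 + exp(-(dw - db)))
}

#' Evaluate a feature mask into the 4-objective vector
#'
#' Computes `(F1, F2, F3, F4)` = (SVM, naive Bayes, discriminant-analysis CV
#' error, distance measure), all to be minimized. One stratified fold
#' assignment (from `seed`) is shared by the three classifiers so the error
#' rates are comparable. An empty mask gets the penalty vector
#' `(1, 1, 1, 1)`.
#'
#' @inheritParams cv_error
#' @return named numeric `c(F1, F2, F3, F4)`.
#' @export
evaluate_subset <- function(ds, mask, scheme = c("kfold10", "loo"), seed = 1) {
  scheme <- match.arg(scheme)
  mask <- as.logical(mask)
  if (!any(mask)) {
    return(c(F1 = 1, F2 = 1, F3 = 1, F4 = 1))
  }
  x <- ds$table[, mask, drop = FALSE]
  fold <- if (scheme == "kfold10") {
    make_folds(ds$labels, 10L, seed)
  } else {
    seq_len(nrow(x))
  }
  errs <- cv_error_multi(x, ds$labels, fold, c("svm", "nb", "da"))
  c(F1 = unname(errs["svm"]), F2 = unname(errs["nb"]),
    F3 = unname(errs["da"]), F4 = distance_objective(ds, mask))
}

#' Wrap a feature dataset as an optimizer problem
#'
#' Real-valued positions in `[0, 1]^D` are decoded to masks by strict
#' thresholding and scored with [evaluate_subset()]. Objective vectors are
#' memoized by mask (the search revisits masks), and the evaluator counts
#' total and distinct-mask evaluations.
#'
#' @param ds a [feature_dataset()].
#' @param scheme CV scheme for the three error objectives.
#' @param eval_seed seed for the shared fold assignment (one assignment per
#'   problem, so objective values are comparable across the search).
#' @param threshold decode threshold (default 0.5, strict `>`).
#' @return a problem list with fields `dim`, `n_obj`, `evaluate(position)`,
#'   `decode(position)`, `counters` (environment with `n_eval`,
#'   `n_distinct`), `feature_names`.
#' @export
subset_problem <- function(ds, scheme = "kfold10", eval_seed = 1,
                           threshold = 0.5) {
  cache <- new.env(parent = emptyenv())
  counters <- new.env(parent = emptyenv())
  counters$n_eval <- 0L
  counters$n_distinct <- 0L
  d <- ncol(ds$table)
  evaluate <- function(position) {
    mask <- decode(position, threshold)
    key <- paste(mask, collapse = "")
    counters$n_eval <- counters$n_eval + 1L
    hit <- cache[[key]]
    if (is.null(hit)) {
      hit <- evaluate_subset(ds, mask, scheme = scheme, seed = eval_seed)
      cache[[key]] <- hit
      counters$n_distinct <- counters$n_distinct + 1L
    }
    hit
  }
  list(dim = d, n_obj = 4L, evaluate = evaluate,
       decode = function(position) decode(position, threshold),
       counters = counters, feature_names = ds$feature_names,
       dataset = ds, scheme = scheme, eval_seed = eval_seed,
       threshold = threshold)
}
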