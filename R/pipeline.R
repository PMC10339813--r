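# End-to-end orchestration: labeled epochs -> per-band binary networks ->
# 14-feature vectors -> band-major feature table -> ANOVA screening ->
# single-feature classification -> multi-objective subset selection ->
# report.

#' Build the band-major feature table from labeled epochs
#'
#' For every epoch and band: band-pass filter, compute the coupling matrix,
#' threshold at `tau`, and extract the 14-feature vector. Columns are
#' ordered band-major (all 14 features of the first band, then the next), so
#' five bands give the 70-column layout whose bit positions match the
#' optimizer's particle encoding. The null-ensemble seed is derived per
#' (epoch, band) by counters, so the table is deterministic and insensitive
#' to epoch order changes elsewhere.
#'
#' @param epochs an `epoch_set` from [generate_coupled_epochs()], or a list
#'   of epoch lists with `samples`, `fs`, `group`, `epoch_id`.
#' @param tau binarization threshold, default 0.3.
#' @param ens a [null_ensemble_spec()].
#' @param bands character vector of band names, default all five.
#' @param method coupling measure, `"psi"` (default) or `"pli"`.
#' @return a [feature_dataset()] whose `meta` holds `epoch_id` and `group`;
#'   feature names are `"band:FEATURE"`.
#' @export
build_feature_table <- function(epochs, tau = 0.3,
                                ens = null_ensemble_spec(),
                                bands = names(eeg_bands),
                                method = "psi") {
  eps <- if (inherits(epochs, "epoch_set")) epochs$epochs else epochs
  stopifnot(length(eps) >= 1L)
  bands <- match.arg(bands, names(eeg_bands), several.ok = TRUE)
  n_ep <- length(eps)
  cols <- as.vector(vapply(bands, function(b) paste(b, feature_names_14,
                                                    sep = ":"),
                           character(14L)))
  tab <- matrix(NA_real_, n_ep, length(cols), dimnames = list(NULL, cols))
  groups <- character(n_ep)
  ids <- character(n_ep)
  for (e in seq_len(n_ep)) {
    ep <- eps[[e]]
    groups[e] <- as.character(ep$group)
    ids[e] <- as.character(if (is.null(ep$epoch_id)) e else ep$epoch_id)
    for (bi in seq_along(bands)) {
      fv <- tryCatch({
        be <- bandpass(ep, band = bands[bi])
        net <- binarize(connectivity_matrix(be, method = method), tau = tau)
        ens_e <- ens
        ens_e$seed <- sub_seed(ens$seed, e, bi)
        feature_vector(net, ens_e, quiet = TRUE)
      }, error = function(err) {
        stop(sprintf("feature extraction failed for epoch %s, band %s: %s",
                     ids[e], bands[bi], conditionMessage(err)),
             call. = FALSE)
      })
      tab[e, ((bi - 1L) * 14L + 1L):(bi * 14L)] <- fv
    }
  }
  feature_dataset(tab, factor(groups),
                  meta = data.frame(epoch_id = ids, group = groups,
                                    stringsAsFactors = FALSE))
}

#' Per-feature one-way ANOVA screening
#'
#' One-way ANOVA of each (band, feature) column against group, on min-max
#' normalized values; a column is flagged when `p < alpha` (the study
#' convention is P < 0.01). Zero-variance columns get `p = 1` with a
#' warning.
#'
#' @param ds a [feature_dataset()].
#' @param alpha significance threshold, default 0.01.
#' @return data frame: `feature`, `band`, `metric`, `f`, `p`, `significant`.
#' @export
anova_screen <- function(ds, alpha = 0.01) {
  x <- minmax_normalize(ds$table)
  g <- ds$labels
  out <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (stats::sd(v) == 0) {
      warning("zero-variance column ", colnames(x)[j], "; p set to 1")
      return(c(f = 0, p = 1))
    }
    fit <- stats::aov(v ~ g)
    s <- summary(fit)[[1L]]
    c(f = s[["F value"]][1L], p = s[["Pr(>F)"]][1L])
  })
  out <- do.call(rbind, out)
  nm <- colnames(ds$table)
  has_band <- grepl(":", nm, fixed = TRUE)
  data.frame(feature = nm,
             band = ifelse(has_band, sub(":.*$", "", nm), NA_character_),
             metric = ifelse(has_band, sub("^.*:", "", nm), nm),
             f = out[, "f"], p = out[, "p"],
             significant = out[, "p"] < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Single-feature SVM classification table
#'
#' Cross-validated SVM error of every (band, feature) column alone; the
#' desk analogue of the study's single-feature screening table.
#'
#' @param ds a [feature_dataset()] with `"band:FEATURE"` columns.
#' @param scheme CV scheme, default 10-fold.
#' @param seed fold seed.
#' @return bands x features numeric matrix of CV error rates.
#' @export
single_feature_table <- function(ds, scheme = "kfold10", seed = 1) {
  nm <- colnames(ds$table)
  stopifnot(all(grepl(":", nm, fixed = TRUE)))
  bands <- unique(sub(":.*$", "", nm))
  out <- matrix(NA_real_, length(bands), 14L,
                dimnames = list(bands, feature_names_14))
  for (j in seq_along(nm)) {
    mask <- seq_along(nm) == j
    b <- sub(":.*$", "", nm[j])
    f <- sub("^.*:", "", nm[j])
    out[b, f] <- cv_error(ds, mask, classifier = "svm", scheme = scheme,
                          seed = seed)
  }
  out
}

decode_mask_names <- function(mask, feature_names) {
  paste(feature_names[mask == 1L], collapse = ",")
}

#' Multi-objective feature-subset selection over a feature table
#'
#' Min-max normalizes the table, wraps it as a 4-objective subset problem
#' (shared fold assignment), runs each requested algorithm, and reports the
#' non-dominated sets with decoded `"band:FEATURE"` names, the mean error of
#' the three classifiers ("AVG"), the mean of all four objectives, the
#' minimum-AVG solution with its feature count, and the distinct-mask
#' evaluation counters. Optionally re-validates the final sets with
#' leave-one-out CV.
#'
#' @param ds a [feature_dataset()].
#' @param algorithms algorithms to run (see [run_optimizer()]).
#' @param config an [optimizer_config()]; per-algorithm run seeds and the
#'   shared evaluation seed derive from `config$seed`.
#' @param scheme CV scheme for the objectives.
#' @param normalize min-max normalize the table first (default TRUE).
#' @param revalidate_loo also re-score each final solution with
#'   leave-one-out CV (the study's re-validation protocol).
#' @return object of class `selection_report`: per-algorithm list with
#'   `solutions` (data frame: mask, features, n_features, F1..F4, avg3,
#'   avg4, and optionally loo_F1..loo_avg3), `best` (minimum-avg3 row),
#'   `n_eval`, `n_distinct`, `history`; plus `eval_seed`, `config`.
#' @export
run_selection <- function(ds,
                          algorithms = c("mopso_gdm", "mopso", "mopso_m",
                                         "nsga2"),
                          config = optimizer_config(),
                          scheme = "kfold10", normalize = TRUE,
                          revalidate_loo = FALSE) {
  tab <- if (normalize) minmax_normalize(ds$table) else ds$table
  nds <- feature_dataset(tab, ds$labels, feature_names = ds$feature_names,
                         meta = ds$meta)
  eval_seed <- sub_seed(config$seed, 9999L)
  per_alg <- list()
  for (alg in algorithms) {
    problem <- subset_problem(nds, scheme = scheme, eval_seed = eval_seed,
                              threshold = config$decode_threshold)
    cfg <- config
    cfg$seed <- sub_seed(config$seed,
                         match(alg, c("mopso_gdm", "mopso", "mopso_m",
                                      "nsga2")))
    res <- run_optimizer(problem, alg, cfg)
    obj <- res$objectives
    masks <- res$masks
    sol <- data.frame(
      mask = apply(masks, 1L, paste, collapse = ""),
      features = apply(masks, 1L, decode_mask_names, ds$feature_names),
      n_features = rowSums(masks),
      F1 = obj[, 1L], F2 = obj[, 2L], F3 = obj[, 3L], F4 = obj[, 4L],
      avg3 = rowMeans(obj[, 1:3, drop = FALSE]),
      avg4 = rowMeans(obj),
      stringsAsFactors = FALSE)
    if (revalidate_loo) {
      loo <- t(apply(masks, 1L, function(m) {
        if (sum(m) == 0L) return(c(1, 1, 1))
        c(cv_error(nds, m, "svm", "loo"),
          cv_error(nds, m, "nb", "loo"),
          cv_error(nds, m, "da", "loo"))
      }))
      sol$loo_F1 <- loo[, 1L]; sol$loo_F2 <- loo[, 2L]
      sol$loo_F3 <- loo[, 3L]; sol$loo_avg3 <- rowMeans(loo)
    }
    sol <- sol[order(sol$avg3), , drop = FALSE]
    rownames(sol) <- NULL
    per_alg[[alg]] <- list(solutions = sol,
                           best = sol[which.min(sol$avg3), , drop = FALSE],
                           n_eval = problem$counters$n_eval,
                           n_distinct = problem$counters$n_distinct,
                           history = res$history)
  }
  structure(list(algorithms = per_alg, eval_seed = eval_seed,
                 config = config, scheme = scheme, normalize = normalize),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  for (alg in names(x$algorithms)) {
    a <- x$algorithms[[alg]]
    b <- a$best
    cat(sprintf("  %-10s %3d solutions | best avg error %.4f with %d features (%s)\n",
                alg, nrow(a$solutions), b$avg3, b$n_features, b$features))
  }
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects every constant of the end-to-end run. `signal_spec` defaults to
#' the full study-scale synthetic preset (16 channels, 1024 Hz, 180 epochs
#' per group); pass a reduced spec for desk-scale runs.
#'
#' @param signal_spec a [coupled_signal_spec()].
#' @param tau binarization threshold.
#' @param bands bands to analyse.
#' @param ensemble a [null_ensemble_spec()].
#' @param optimizer an [optimizer_config()].
#' @param algorithms algorithms to run in the selection stage.
#' @param scheme CV scheme.
#' @param method coupling measure (`"psi"` or `"pli"`).
#' @param run_single_feature include the single-feature SVM table (slow).
#' @param revalidate_loo leave-one-out re-validation of final sets.
#' @param seed master seed: fixes synthetic data, ensembles, folds and
#'   optimizer runs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(signal_spec = coupled_signal_spec(),
                            tau = 0.3, bands = names(eeg_bands),
                            ensemble = null_ensemble_spec(),
                            optimizer = optimizer_config(),
                            algorithms = c("mopso_gdm", "mopso", "mopso_m",
                                           "nsga2"),
                            scheme = "kfold10", method = "psi",
                            run_single_feature = FALSE,
                            revalidate_loo = FALSE, seed = 1) {
  check_number(tau, "tau", lower = 0, upper = 1 - 1e-12)
  check_number(seed, "seed", integer = TRUE)
  structure(list(signal_spec = signal_spec, tau = tau, bands = bands,
                 ensemble = ensemble, optimizer = optimizer,
                 algorithms = algorithms, scheme = scheme, method = method,
                 run_single_feature = isTRUE(run_single_feature),
                 revalidate_loo = isTRUE(revalidate_loo),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Synthetic signals -> band networks -> feature table -> ANOVA screening
#' (-> single-feature table) -> multi-objective subset selection. One master
#' seed fixes every stage, so two invocations produce identical reports.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, all tabular artifacts are
#'   written as CSV plus a JSON run manifest (see [write_run_report()]).
#' @return object of class `run_report`: list with `features`
#'   (the [feature_dataset()]), `group_mean_psi` (per-band group-mean PSI
#'   matrices), `anova`, `single_feature` (or NULL), `selection`
#'   (a `selection_report`), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- config$signal_spec
  spec$seed <- sub_seed(config$seed, 1L)
  es <- generate_coupled_epochs(spec)
  ens <- config$ensemble
  ens$seed <- sub_seed(config$seed, 2L)
  ds <- build_feature_table(es, tau = config$tau, ens = ens,
                            bands = config$bands, method = config$method)
  gm <- group_mean_psi(es, bands = config$bands, method = config$method)
  screen <- anova_screen(ds)
  single <- if (config$run_single_feature) {
    single_feature_table(ds, scheme = config$scheme,
                         seed = sub_seed(config$seed, 3L))
  }
  opt <- config$optimizer
  opt$seed <- sub_seed(config$seed, 4L)
  sel <- run_selection(ds, algorithms = config$algorithms, config = opt,
                       scheme = config$scheme,
                       revalidate_loo = config$revalidate_loo)
  report <- structure(list(features = ds, group_mean_psi = gm,
                           anova = screen, single_feature = single,
                           selection = sel, config = config),
                      class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' Group-mean PSI matrices per band
#'
#' Averages the per-epoch connectivity matrices within each group, the
#' quantity used for group-level network visualization.
#'
#' @param epochs an `epoch_set` or list of labeled epochs.
#' @param bands band names.
#' @param method coupling measure.
#' @return nested list `band -> group -> matrix`.
#' @export
group_mean_psi <- function(epochs, bands = names(eeg_bands),
                           method = "psi") {
  eps <- if (inherits(epochs, "epoch_set")) epochs$epochs else epochs
  groups <- vapply(eps, function(e) as.character(e$group), character(1L))
  out <- list()
  for (b in bands) {
    mats <- lapply(eps, function(ep) {
      unclass(connectivity_matrix(bandpass(ep, band = b), method = method))
    })
    out[[b]] <- lapply(split(mats, groups), function(ms) {
      Reduce(`+`, ms) / length(ms)
    })
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  feature table: %d x %d | ANOVA flagged: %d/%d (P < 0.01)\n",
              nrow(x$features$table), ncol(x$features$table),
              sum(x$anova$significant), nrow(x$anova)))
  print(x$selection)
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits `features.csv` (long layout with epoch_id and group),
#' `anova.csv`, `single_feature.csv` (if computed),
#' `selection_<algorithm>.csv` per algorithm, `psi_<band>_<group>.csv`
#' group-mean matrices, and `manifest.json` with the configuration, seeds
#' and per-algorithm summaries.
#'
#' @param report a `run_report`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  feat <- data.frame(report$features$meta,
                     report$features$table, check.names = FALSE)
  utils::write.csv(feat, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(report$anova, file.path(out_dir, "anova.csv"),
                   row.names = FALSE)
  if (!is.null(report$single_feature)) {
    utils::write.csv(as.data.frame(report$single_feature),
                     file.path(out_dir, "single_feature.csv"))
  }
  for (b in names(report$group_mean_psi)) {
    for (g in names(report$group_mean_psi[[b]])) {
      write_matrix_csv(report$group_mean_psi[[b]][[g]],
                       file.path(out_dir, sprintf("psi_%s_%s.csv", b, g)))
    }
  }
  for (alg in names(report$selection$algorithms)) {
    utils::write.csv(report$selection$algorithms[[alg]]$solutions,
                     file.path(out_dir, sprintf("selection_%s.csv", alg)),
                     row.names = FALSE)
  }
  manifest <- list(
    seed = report$config$seed,
    tau = report$config$tau,
    bands = report$config$bands,
    method = report$config$method,
    scheme = report$config$scheme,
    optimizer = unclass(report$config$optimizer),
    ensemble = unclass(report$config$ensemble),
    eval_seed = report$selection$eval_seed,
    algorithms = lapply(report$selection$algorithms, function(a) {
      list(n_solutions = nrow(a$solutions),
           best_avg3 = a$best$avg3,
           best_features = a$best$features,
           best_n_features = a$best$n_features,
           n_eval = a$n_eval, n_distinct = a$n_distinct)
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Re-evaluate a reported mask and check it reproduces its objectives
#'
#' Report integrity invariant: every reported mask must re-evaluate to its
#' reported objective vector under the stored evaluation seed.
#'
#' @param report a `run_report` or `selection_report`.
#' @param ds the feature table the selection ran on (taken from a
#'   `run_report` automatically).
#' @return TRUE invisibly; stops with a message on mismatch.
#' @export
verify_report <- function(report, ds = NULL) {
  sel <- if (inherits(report, "run_report")) report$selection else report
  if (inherits(report, "run_report")) ds <- report$features
  stopifnot(!is.null(ds))
  tab <- if (sel$normalize) minmax_normalize(ds$table) else ds$table
  nds <- feature_dataset(tab, ds$labels, feature_names = ds$feature_names)
  for (alg in names(sel$algorithms)) {
    sols <- sel$algorithms[[alg]]$solutions
    for (r in seq_len(nrow(sols))) {
      mask <- as.integer(strsplit(sols$mask[r], "")[[1L]])
      got <- evaluate_subset(nds, mask, scheme = sel$scheme,
                             seed = sel$eval_seed)
      want <- unlist(sols[r, c("F1", "F2", "F3", "F4")])
      if (max(abs(got - want)) > 1e-10) {
        stop(sprintf("mask %s (%s) re-evaluates to different objectives",
                     sols$mask[r], alg), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}
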