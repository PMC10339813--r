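# Surrogate multichannel recordings with tunable per-band phase coupling,
# and planted-feature classification tables, so every downstream stage is
# testable without clinical data.

#' Specification of a two-group coupled-signal dataset
#'
#' Describes surrogate recordings for two groups ("A" and "B"): per band,
#' every channel mixes a shared band-limited driver (weight = coupling) with
#' private band-limited noise (weight = 1 - coupling), plus broadband noise.
#' Larger coupling gives higher pairwise phase synchronization in that band.
#' The default preset mirrors a 16-channel, 1024 Hz, 10-s-epoch design with
#' 180 epochs per group (12 epochs from each of 15 subjects), with group A
#' ("AD-like") coupled more weakly than group B, most strongly separated in
#' the alpha, beta and gamma bands.
#'
#' @param n_channels number of channels (>= 2).
#' @param fs sampling rate in Hz; must exceed twice the highest band edge.
#' @param epoch_len epoch length in seconds; `fs * epoch_len` must be whole.
#' @param n_epochs_per_group epochs per group.
#' @param band_coupling named list mapping band names (subset of
#'   `names(eeg_bands)`) to `c(groupA, groupB)` couplings in `[0, 1]`.
#' @param noise_sd standard deviation of the broadband noise floor.
#' @param epochs_per_subject epochs attributed to one subject id (manifest
#'   bookkeeping only).
#' @param seed integer seed; identical spec implies bit-identical output.
#' @return object of class `coupled_signal_spec`.
#' @export
coupled_signal_spec <- function(n_channels = 16,
                                fs = 1024,
                                epoch_len = 10,
                                n_epochs_per_group = 180,
                                band_coupling = list(
                                  delta = c(0.45, 0.50),
                                  theta = c(0.45, 0.50),
                                  alpha = c(0.35, 0.55),
                                  beta  = c(0.35, 0.55),
                                  gamma = c(0.35, 0.55)),
                                noise_sd = 0.5,
                                epochs_per_subject = 12,
                                seed = 1) {
  check_number(n_channels, "n_channels", lower = 2, integer = TRUE)
  check_number(fs, "fs", lower = .Machine$double.eps)
  check_number(epoch_len, "epoch_len", lower = .Machine$double.eps)
  check_number(n_epochs_per_group, "n_epochs_per_group", lower = 1,
               integer = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(epochs_per_subject, "epochs_per_subject", lower = 1,
               integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  if (!is.list(band_coupling) || is.null(names(band_coupling)) ||
      !all(names(band_coupling) %in% names(eeg_bands))) {
    stop_field("band_coupling",
               "must be a named list over canonical band names")
  }
  for (b in names(band_coupling)) {
    v <- band_coupling[[b]]
    if (!is.numeric(v) || length(v) != 2L || anyNA(v) ||
        any(v < 0) || any(v > 1)) {
      stop_field("band_coupling",
                 sprintf("couplings for band %s must be two values in [0, 1]", b))
    }
    if (fs <= 2 * eeg_bands[[b]][2L]) {
      stop_field("fs", sprintf("must exceed twice the %s upper edge (%g Hz)",
                               b, eeg_bands[[b]][2L]))
    }
  }
  n_samp <- fs * epoch_len
  if (abs(n_samp - round(n_samp)) > 1e-9) {
    stop_field("epoch_len", "fs * epoch_len must be an integer sample count")
  }
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 epoch_len = epoch_len,
                 n_epochs_per_group = as.integer(n_epochs_per_group),
                 band_coupling = band_coupling, noise_sd = noise_sd,
                 epochs_per_subject = as.integer(epochs_per_subject),
                 seed = as.integer(seed)),
            class = "coupled_signal_spec")
}

#' Generate labeled multichannel epochs with group-dependent phase coupling
#'
#' For each group and epoch, every channel is
#' `sum_bands [ coupling * shared_driver + (1 - coupling) * private_noise ]
#' + noise_sd * white`, where the drivers and private components are white
#' noise passed through the same zero-phase FIR band-pass filters used by
#' [bandpass()] and scaled to unit variance. Each (group, epoch) draws from
#' its own counter-derived sub-stream, so changing the epoch count never
#' reshuffles earlier epochs.
#'
#' @param spec a [coupled_signal_spec()].
#' @return object of class `epoch_set`: list with `epochs` (each a list with
#'   `samples` channels x time, `group` "A"/"B", `epoch_id`, `subject_id`,
#'   `fs`, `channel_names`), plus `fs`, `channel_names`, `spec`.
#' @export
generate_coupled_epochs <- function(spec) {
  stopifnot(inherits(spec, "coupled_signal_spec"))
  nt <- as.integer(round(spec$fs * spec$epoch_len))
  nch <- spec$n_channels
  ch_names <- default_channel_names(nch)
  bands <- names(spec$band_coupling)
  epochs <- vector("list", 2L * spec$n_epochs_per_group)
  k <- 0L
  for (gi in 1:2) {
    grp <- c("A", "B")[gi]
    for (e in seq_len(spec$n_epochs_per_group)) {
      k <- k + 1L
      epochs[[k]] <- with_seed(sub_seed(spec$seed, gi, e), {
        x <- matrix(0, nch, nt)
        for (b in bands) {
          coup <- spec$band_coupling[[b]][gi]
          driver <- unit_band_noise(nt, spec$fs, b)
          for (ch in seq_len(nch)) {
            priv <- unit_band_noise(nt, spec$fs, b)
            x[ch, ] <- x[ch, ] + coup * driver + (1 - coup) * priv
          }
        }
        if (spec$noise_sd > 0) {
          x <- x + matrix(stats::rnorm(nch * nt, sd = spec$noise_sd), nch, nt)
        }
        list(samples = x, group = grp,
             epoch_id = sprintf("%s%03d", grp, e),
             subject_id = sprintf("%s%02d", grp,
                                  ceiling(e / spec$epochs_per_subject)),
             fs = spec$fs, channel_names = ch_names)
      })
    }
  }
  structure(list(epochs = epochs, fs = spec$fs, channel_names = ch_names,
                 spec = spec),
            class = "epoch_set")
}

# White noise band-passed with the preprocessing filters, scaled to unit sd.
unit_band_noise <- function(nt, fs, band) {
  v <- zero_phase_filter(fir_coef(fs, eeg_bands[[band]]), stats::rnorm(nt))
  s <- stats::sd(v)
  if (s > 0) v / s else v
}

#' @export
print.epoch_set <- function(x, ...) {
  grp <- vapply(x$epochs, `[[`, character(1L), "group")
  cat(sprintf("<epoch_set> %d epochs (%s) | %d channels @ %g Hz\n",
              length(x$epochs),
              paste(sprintf("%s: %d", names(table(grp)), table(grp)),
                    collapse = ", "),
              length(x$channel_names), x$fs))
  invisible(x)
}

#' Write an epoch set as per-epoch delimited text plus a label manifest
#'
#' Each epoch becomes `<epoch_id>.tsv` (one column per channel, header row);
#' the manifest `manifest.csv` has columns `epoch_id`, `group`, `subject_id`.
#'
#' @param es an `epoch_set`.
#' @param dir output directory (created if missing).
#' @return the manifest data frame, invisibly.
#' @export
write_epochs_txt <- function(es, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- data.frame(
    epoch_id = vapply(es$epochs, `[[`, character(1L), "epoch_id"),
    group = vapply(es$epochs, `[[`, character(1L), "group"),
    subject_id = vapply(es$epochs, `[[`, character(1L), "subject_id"),
    stringsAsFactors = FALSE)
  for (ep in es$epochs) {
    write_recording_txt(ep, file.path(dir, paste0(ep$epoch_id, ".tsv")))
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Specification of a planted-feature classification table
#'
#' Balanced two-class table in which `informative_idx` columns carry a
#' standardized between-class mean shift of `effect_size` (unit variance)
#' and all other columns are class-independent standard normal noise.
#'
#' @param n_samples total samples (even; classes are balanced).
#' @param n_features number of feature columns.
#' @param informative_idx 1-based indices of informative columns.
#' @param effect_size standardized mean difference (>= 0).
#' @param seed integer seed.
#' @return object of class `planted_feature_spec`.
#' @export
planted_feature_spec <- function(n_samples = 360, n_features = 70,
                                 informative_idx = 1:5, effect_size = 2,
                                 seed = 1) {
  check_number(n_samples, "n_samples", lower = 4, integer = TRUE)
  if (n_samples %% 2L != 0L) stop_field("n_samples", "must be even")
  check_number(n_features, "n_features", lower = 1, integer = TRUE)
  check_number(effect_size, "effect_size", lower = 0)
  check_number(seed, "seed", integer = TRUE)
  informative_idx <- as.integer(informative_idx)
  if (length(informative_idx) &&
      (any(informative_idx < 1L) || any(informative_idx > n_features) ||
       anyDuplicated(informative_idx))) {
    stop_field("informative_idx",
               "must be distinct indices in 1..n_features")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 informative_idx = informative_idx,
                 effect_size = effect_size, seed = as.integer(seed)),
            class = "planted_feature_spec")
}

#' Generate a planted-feature table with binary labels
#'
#' @param spec a [planted_feature_spec()].
#' @return a [feature_dataset()] with classes "A"/"B"; the spec is attached
#'   as attribute `spec`.
#' @export
generate_planted_features <- function(spec) {
  stopifnot(inherits(spec, "planted_feature_spec"))
  n <- spec$n_samples
  d <- spec$n_features
  labels <- factor(rep(c("A", "B"), each = n / 2L))
  tab <- with_seed(spec$seed, {
    m <- matrix(stats::rnorm(n * d), n, d)
    shift <- spec$effect_size / 2
    m[labels == "A", spec$informative_idx] <-
      m[labels == "A", spec$informative_idx] - shift
    m[labels == "B", spec$informative_idx] <-
      m[labels == "B", spec$informative_idx] + shift
    m
  })
  colnames(tab) <- sprintf("f%02d", seq_len(d))
  ds <- feature_dataset(tab, labels)
  attr(ds, "spec") <- spec
  ds
}
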