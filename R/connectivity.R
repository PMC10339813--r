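# Instantaneous phase extraction, pairwise phase synchronization, per-band
# connectivity matrices, and thresholded binary networks.

#' Discrete analytic signal and instantaneous phase
#'
#' Frequency-domain construction of the analytic signal: the FFT spectrum is
#' doubled at positive frequencies and zeroed at negative frequencies
#' (Nyquist and DC retained), and the inverse transform gives
#' `x(t) + i * H[x](t)` with `H` the Hilbert transform. The instantaneous
#' amplitude is the modulus and the phase is `atan2(H[x], x)` in `(-pi, pi]`.
#'
#' A constant input is a documented degenerate case: amplitude 0 and phase 0
#' everywhere (the phase of a zero-bandwidth signal is undefined).
#'
#' @param x real numeric vector, length >= 8, finite.
#' @return object of class `analytic_signal`: list with `amplitude`,
#'   `phase`, `x` (the source), and `hilbert` (the Hilbert pair).
#' @export
analytic_signal <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("need at least 8 samples", call. = FALSE)
  if (!all(is.finite(x))) stop("input must be finite", call. = FALSE)
  if (max(x) == min(x)) {
    return(structure(list(amplitude = numeric(n), phase = numeric(n),
                          x = x, hilbert = numeric(n)),
                     class = "analytic_signal"))
  }
  z <- analytic_fft(x)
  structure(list(amplitude = Mod(z), phase = Arg(z), x = Re(z),
                 hilbert = Im(z)),
            class = "analytic_signal")
}

analytic_fft <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  mult <- numeric(n)
  mult[1L] <- 1
  if (n %% 2L == 0L) {
    mult[n / 2L + 1L] <- 1
    mult[2L:(n / 2L)] <- 2
  } else {
    mult[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * mult, inverse = TRUE) / n
}

# Phase matrix for a channels x time matrix (rows are channels).
phase_matrix <- function(samples) {
  t(apply(samples, 1L, function(ch) analytic_signal(ch)$phase))
}

#' Phase synchronization index of two signals
#'
#' `PSI = | mean_t exp(i * (phi_x(t) - phi_y(t))) |` with 1:1 frequency
#' locking, where the phases come from [analytic_signal()]. Ranges over
#' `[0, 1]`: 1 is perfect phase locking, 0 is no coupling. Symmetric and
#' invariant to positive amplitude scaling of either signal.
#'
#' @param x,y real numeric vectors of equal length.
#' @return synchrony value in `[0, 1]`.
#' @seealso [pli()] for the phase-lag index variant.
#' @export
psi <- function(x, y) {
  if (length(x) != length(y)) {
    stop("signals must have equal length", call. = FALSE)
  }
  px <- analytic_signal(x)$phase
  py <- analytic_signal(y)$phase
  Mod(mean(exp(1i * (px - py))))
}

#' Phase-lag index of two signals
#'
#' `PLI = | mean_t sign(sin(phi_x(t) - phi_y(t))) |`. Discards zero-lag
#' (and anti-phase) synchronization, making it insensitive to volume
#' conduction; offered as an optional alternative coupling measure.
#'
#' @inheritParams psi
#' @return value in `[0, 1]`.
#' @export
pli <- function(x, y) {
  if (length(x) != length(y)) {
    stop("signals must have equal length", call. = FALSE)
  }
  px <- analytic_signal(x)$phase
  py <- analytic_signal(y)$phase
  abs(mean(sign(sin(px - py))))
}

#' Pairwise connectivity matrix of a band-limited epoch
#'
#' Computes the coupling measure between every channel pair of a band-limited
#' epoch. The result is symmetric with zero diagonal (self-coupling is
#' excluded) and entries in `[0, 1]`.
#'
#' @param epoch a `band_epoch` from [bandpass()], or any list with a
#'   channels x time `samples` matrix.
#' @param method `"psi"` (default) or `"pli"`.
#' @return numeric n x n matrix of class `connectivity_matrix`, with
#'   attributes `band` and `method`; dimnames are channel names if present.
#' @export
connectivity_matrix <- function(epoch, method = c("psi", "pli")) {
  method <- match.arg(method)
  samples <- if (is.list(epoch)) epoch$samples else as.matrix(epoch)
  n <- nrow(samples)
  if (n < 2L) stop("need at least 2 channels", call. = FALSE)
  ph <- phase_matrix(samples)
  nt <- ncol(ph)
  if (method == "psi") {
    P <- exp(1i * ph)
    M <- Mod(P %*% Conj(t(P))) / nt
  } else {
    M <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      d <- sign(sin(sweep(ph[(i + 1L):n, , drop = FALSE], 2L, ph[i, ], "-")))
      M[i, (i + 1L):n] <- abs(rowMeans(d))
    }
    M <- M + t(M)
  }
  M <- (M + t(M)) / 2
  M[M > 1] <- 1
  diag(M) <- 0
  nm <- if (is.list(epoch) && !is.null(epoch$channel_names)) {
    epoch$channel_names
  } else {
    default_channel_names(n)
  }
  dimnames(M) <- list(nm, nm)
  structure(M, class = c("connectivity_matrix", "matrix"),
            band = if (is.list(epoch) && !is.null(epoch$band)) epoch$band else NA_character_,
            method = method)
}

#' Threshold a connectivity matrix into a binary network
#'
#' An edge is realized iff the coupling strictly exceeds `tau`; the diagonal
#' stays zero.
#'
#' @param cm connectivity matrix (symmetric, entries in `[0, 1]`).
#' @param tau threshold in `[0, 1)`; default 0.3.
#' @return a [binary_network()].
#' @export
binarize <- function(cm, tau = 0.3) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
      tau < 0 || tau >= 1) {
    stop("tau must be in [0, 1)", call. = FALSE)
  }
  adj <- (unclass(cm) > tau) * 1
  diag(adj) <- 0
  binary_network(adj, tau = tau, band = attr(cm, "band"))
}

#' Binary undirected network container
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @param tau threshold used to obtain it (NA if constructed directly).
#' @param band band label (optional).
#' @return object of class `binary_network` with fields `adjacency`, `tau`,
#'   `band`, `channel_names`.
#' @export
binary_network <- function(adjacency, tau = NA_real_, band = NA_character_) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) {
    stop_field("adjacency", "must be square")
  }
  if (!all(adjacency %in% c(0, 1))) stop_field("adjacency", "entries must be 0/1")
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    stop_field("adjacency", "must be symmetric")
  }
  if (any(diag(adjacency) != 0)) stop_field("adjacency", "diagonal must be 0")
  nm <- rownames(adjacency)
  if (is.null(nm)) nm <- default_channel_names(nrow(adjacency))
  dimnames(adjacency) <- list(nm, nm)
  structure(list(adjacency = adjacency, tau = tau, band = band,
                 channel_names = nm),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges (tau = %s)\n",
              nrow(x$adjacency), sum(x$adjacency) / 2,
              format(x$tau)), sep = "")
  invisible(x)
}

#' Write / read a square matrix as CSV with channel-name header
#'
#' Used for both PSI matrices and binary adjacencies.
#'
#' @param m square matrix (or `binary_network`, whose adjacency is written).
#' @param path file path.
#' @export
write_matrix_csv <- function(m, path) {
  if (inherits(m, "binary_network")) m <- m$adjacency
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}

#' Export a binary network as an edge list
#'
#' @param net a [binary_network()].
#' @param path optional CSV path; if `NULL` the data frame is returned only.
#' @return data frame with columns `node_i`, `node_j` (each edge once).
#' @export
edge_list <- function(net, path = NULL) {
  idx <- which(upper.tri(net$adjacency) & net$adjacency == 1, arr.ind = TRUE)
  df <- data.frame(node_i = net$channel_names[idx[, 1L]],
                   node_j = net$channel_names[idx[, 2L]],
                   stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
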