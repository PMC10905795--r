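# wPLI functional connectivity.
#
# wPLI_ij = |E{Im(X_i X_j*)}| / E{|Im(X_i X_j*)|}
#         = |E{|Im| sgn(Im)}| / E{|Im|}
#
# The expectation pools the imaginary cross-spectral samples over all
# 2-s Hann-tapered sliding windows (1-s overlap) and all in-band (1-45 Hz)
# frequency bins of the broadband analytic signal. wPLI is bounded in
# [0, 1], blind to zero-lag (volume-conducted) coupling, and maximal when
# the sign of the phase lag is consistent.

#' Analytic signal via the Hilbert transform
#'
#' Returns the analytic extension `x + i * H(x)` of each channel; the
#' magnitude is the instantaneous amplitude and the angle the
#' instantaneous phase. The input is expected to be band-limited already
#' (the preprocessing band-pass).
#'
#' @param x Numeric matrix (channels x samples) or vector.
#' @return Complex matrix (or vector) of the same shape.
#' @export
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  if (length(x) == 0) stopf("empty input")
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  X <- t(stats::mvfft(t(x)))
  z <- t(stats::mvfft(t(X * rep(h, each = nrow(x))), inverse = TRUE)) / n
  if (vec) z[1, ] else z
}

new_connectivity_matrix <- function(values, channel_names, scope,
                                    band = c(1, 45),
                                    n_epochs_consolidated = NA_integer_) {
  dimnames(values) <- list(channel_names, channel_names)
  structure(list(values = values, channel_names = channel_names,
                 scope = scope, band = band,
                 n_epochs_consolidated = n_epochs_consolidated),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d x %d wPLI, scope=%s, band %g-%g Hz%s\n",
              nrow(x$values), ncol(x$values), x$scope, x$band[1], x$band[2],
              if (!is.na(x$n_epochs_consolidated))
                sprintf(", consolidated over %d epochs", x$n_epochs_consolidated)
              else ""))
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("  mean off-diagonal wPLI %.3f (range %.3f-%.3f)\n",
              mean(off), min(off), max(off)))
  invisible(x)
}

#' wPLI connectivity of one epoch
#'
#' Slides 2-s Hann-tapered windows with 1-s step over the epoch's
#' analytic signal, collects the imaginary parts of the cross-spectra at
#' all in-band frequency bins, and evaluates the wPLI ratio per channel
#' pair. Pairs whose imaginary cross-spectrum is identically zero (e.g. a
#' channel against itself, or a purely zero-lag pair) are set to 0.
#'
#' @param epoch Channels x samples matrix (one epoch, band-limited).
#' @param fs Sampling rate (Hz).
#' @param window_s,overlap_s Window length and overlap in seconds.
#' @param band Frequency band of cross-spectral bins pooled into the
#'   expectation.
#' @param channel_names Channel names (defaults to rownames).
#' @return A `connectivity_matrix` with `scope = "epoch"`: symmetric,
#'   zero diagonal, entries in `[0, 1]`.
#' @export
wpli_epoch <- function(epoch, fs, window_s = 2, overlap_s = 1,
                       band = c(1, 45),
                       channel_names = rownames(epoch)) {
  nch <- nrow(epoch)
  nsamp <- ncol(epoch)
  wlen <- round(window_s * fs)
  step <- round((window_s - overlap_s) * fs)
  if (wlen > nsamp) stopf("window (%g s) longer than epoch (%g s)",
                          window_s, nsamp / fs)
  if (step < 1) stopf("overlap must be smaller than the window")
  channel_names <- channel_names %||% paste0("ch", seq_len(nch))

  z <- analytic_signal(epoch)
  starts <- seq(1, nsamp - wlen + 1, by = step)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, wlen - 1) / (wlen - 1))  # Hann
  freqs <- (seq_len(wlen) - 1) * fs / wlen
  keep <- which(freqs >= band[1] & freqs <= band[2])

  RE <- matrix(0, 0, nch); IM <- matrix(0, 0, nch)
  rows <- length(keep) * length(starts)
  RE <- matrix(NA_real_, rows, nch); IM <- matrix(NA_real_, rows, nch)
  r <- 0
  for (s in starts) {
    seg <- z[, s:(s + wlen - 1), drop = FALSE] * rep(taper, each = nch)
    spec <- stats::mvfft(t(seg))[keep, , drop = FALSE]
    RE[(r + 1):(r + length(keep)), ] <- Re(spec)
    IM[(r + 1):(r + length(keep)), ] <- Im(spec)
    r <- r + length(keep)
  }
  # Im(X_i conj(X_j)) = Im_i Re_j - Re_i Im_j, summed over all samples:
  num <- abs(crossprod(IM, RE) - crossprod(RE, IM))
  den <- matrix(0, nch, nch)
  for (j in seq_len(nch)) {
    cj <- IM * RE[, j] - RE * IM[, j]
    den[, j] <- colSums(abs(cj))
  }
  w <- ifelse(den > 0, num / den, 0)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w[w > 1] <- 1
  new_connectivity_matrix(w, channel_names, scope = "epoch", band = band)
}

#' Node degree of a connectivity pattern
#'
#' The degree of node i is the sum of its wPLI weights to all other
#' nodes (the intensity of its connectivity). With `mean = TRUE` the sum
#' is divided by the number of neighbours.
#'
#' @param cm A `connectivity_matrix`.
#' @param mean Report the mean weight per neighbour instead of the sum.
#' @return Named numeric vector, one value per channel.
#' @export
node_degree <- function(cm, mean = FALSE) {
  d <- rowSums(cm$values)
  if (mean) d <- d / (nrow(cm$values) - 1)
  stats::setNames(d, cm$channel_names)
}

#' Consolidate epoch connectivity into a session pattern
#'
#' Entrywise arithmetic mean of the epoch-level wPLI matrices.
#'
#' @param epoch_cms List of `connectivity_matrix` objects
#'   (`scope = "epoch"`, identical channel sets).
#' @return A `connectivity_matrix` with `scope = "session"` and
#'   `n_epochs_consolidated` recorded.
#' @export
consolidate_session <- function(epoch_cms) {
  if (length(epoch_cms) < 1) stopf("need at least one epoch matrix")
  nm <- epoch_cms[[1]]$channel_names
  for (cm in epoch_cms)
    if (!identical(cm$channel_names, nm))
      stopf("epoch matrices have mismatching channel sets")
  avg <- Reduce(`+`, lapply(epoch_cms, `[[`, "values")) / length(epoch_cms)
  new_connectivity_matrix(avg, nm, scope = "session",
                          band = epoch_cms[[1]]$band,
                          n_epochs_consolidated = length(epoch_cms))
}

#' Session connectivity from a preprocessed epoch array
#'
#' Computes epoch-level wPLI for every kept epoch and consolidates the
#' results into the session pattern.
#'
#' @param ep A usable `epoch_array`.
#' @param window_s,overlap_s,band Passed to [wpli_epoch()].
#' @return A session-scope `connectivity_matrix`.
#' @export
session_connectivity <- function(ep, window_s = 2, overlap_s = 1,
                                 band = c(1, 45)) {
  assert_usable(ep)
  kept <- which(ep$qc$keep)
  if (!length(kept)) stopf("no kept epochs")
  cms <- lapply(kept, function(e)
    wpli_epoch(matrix(ep$epochs[e, , ], dim(ep$epochs)[2]), ep$fs,
               window_s, overlap_s, band,
               channel_names = ep$montage$name))
  consolidate_session(cms)
}
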