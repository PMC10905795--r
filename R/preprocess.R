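# Preprocessing chain: resample -> band-pass -> epoch -> channel QC ->
# epoch QC -> common average reference. All decisions are deterministic;
# the visual-inspection steps of typical clinical workflows are replaced
# by configurable statistical thresholds.

# Zero-phase band-pass via a linear-phase Hamming FIR applied by FFT
# convolution (all channels in one matrix FFT) with exact group-delay
# compensation and reflection padding at the edges. A symmetric FIR
# delayed by its half order has exactly zero phase, which matters
# downstream: wPLI is a pure phase statistic.
fir_bandpass_matrix <- function(x, fs, low, high) {
  n <- ncol(x)
  tb <- min(max(low, 0.5), 2)               # transition bandwidth, Hz
  ord <- ceiling(3.3 * fs / tb)
  ord <- ord + ord %% 2                      # even order -> integer delay
  ord <- min(ord, 2 * (n - 1))
  h <- signal::fir1(ord, c(low, high) / (fs / 2), type = "pass")
  pad <- ord / 2
  li <- pmin(pad + 1, n):2                  # reflection pad indices
  ri <- (n - 1):max(n - pad, 1)
  li <- rev(rev(li)[seq_len(min(pad, length(li)))])
  ri <- ri[seq_len(min(pad, length(ri)))]
  xp <- cbind(x[, li, drop = FALSE], x, x[, ri, drop = FALSE])
  nf <- stats::nextn(ncol(xp) + ord, 2)
  H <- stats::fft(c(h, numeric(nf - length(h))))
  X <- stats::mvfft(t(cbind(xp, matrix(0, nrow(x), nf - ncol(xp)))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nf
  t(y)[, (length(li) + pad + 1):(length(li) + pad + n), drop = FALSE]
}

#' Resample and band-pass filter a recording
#'
#' Downsamples to `target_fs` (polyphase resampling) and applies a
#' zero-phase Hamming-window FIR band-pass. The default band (1-45 Hz)
#' and rate (500 Hz) match the analysis protocol.
#'
#' @param rec A [raw_recording()].
#' @param target_fs Target sampling rate (Hz); must not exceed `rec$fs`.
#' @param band Length-2 vector `c(low, high)` in Hz; must satisfy
#'   `low < high < target_fs / 2`.
#' @return The filtered [raw_recording()] at `target_fs`.
#' @export
resample_filter <- function(rec, target_fs = 500, band = c(1, 45)) {
  low <- band[1]; high <- band[2]
  if (!(low < high)) stopf("band must satisfy low < high")
  if (high >= target_fs / 2)
    stopf("band upper edge %g Hz is at or above Nyquist (%g Hz)",
          high, target_fs / 2)
  if (target_fs > rec$fs)
    stopf("`target_fs` (%g) must not exceed the recording rate (%g)",
          target_fs, rec$fs)
  data <- rec$data
  if (target_fs != rec$fs) {
    gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
    a <- round(target_fs * 1000); b <- round(rec$fs * 1000)
    g <- gcd(a, b)
    data <- t(apply(data, 1, function(x) signal::resample(x, a / g, b / g)))
  }
  data <- fir_bandpass_matrix(data, fs = target_fs, low = low, high = high)
  out <- rec
  out$data <- data
  rownames(out$data) <- rec$montage$name
  out$fs <- target_fs
  out
}

#' Cut a recording into non-overlapping fixed-length epochs
#'
#' @param rec A [raw_recording()].
#' @param epoch_length_s Epoch length in seconds (default 10).
#' @return An `epoch_array`; `n_epochs = floor(duration / epoch_length_s)`,
#'   any trailing remainder is discarded.
#' @export
epoch_recording <- function(rec, epoch_length_s = 10) {
  spe <- round(epoch_length_s * rec$fs)
  n_ep <- floor(ncol(rec$data) / spe)
  if (n_ep < 1)
    stopf("recording (%.1f s) is shorter than one %g-s epoch",
          recording_duration(rec), epoch_length_s)
  nch <- nrow(rec$data)
  ep <- aperm(array(rec$data[, seq_len(n_ep * spe)], c(nch, spe, n_ep)),
              c(3, 1, 2))
  new_epoch_array(ep, epoch_length_s, rec$fs, rec$montage,
                  rec$session_label, rec$patient_id)
}

#' Detect bad channels from band power and kurtosis
#'
#' Flags channels whose robust z-score (median/MAD with a floored scale)
#' of either log total power or signal kurtosis exceeds `z_threshold`,
#' computed over the concatenated kept epochs.
#'
#' @param ep An `epoch_array` (>= 4 channels).
#' @param z_threshold Robust z threshold (default 3).
#' @return Character vector of flagged channel names (possibly empty).
#' @export
detect_bad_channels <- function(ep, z_threshold = 3) {
  nch <- dim(ep$epochs)[2]
  if (nch < 4) stopf("need at least 4 channels")
  keep <- which(ep$qc$keep)
  x <- matrix(aperm(ep$epochs[keep, , , drop = FALSE], c(2, 3, 1)), nrow = nch)
  logp <- log(rowMeans(x^2) + .Machine$double.eps)
  xc <- x - rowMeans(x)
  m2 <- rowMeans(xc^2)
  kur <- rowMeans(xc^4) / m2^2
  kur[!is.finite(kur)] <- Inf               # flat channel: flag it
  # The log-power scale floor (0.75 log units) tolerates the genuine
  # static power heterogeneity of a montage (hub regions run hotter);
  # channels must deviate by far more than anatomy explains to be
  # flagged on power, while transient/spike contamination is caught by
  # the kurtosis criterion.
  z_p <- abs(robust_z(logp, floor = 0.75))
  z_k <- abs(robust_z(kur, floor = 0.5))
  bad <- ep$montage$name[z_p > z_threshold | z_k > z_threshold]
  if (length(bad) == nch) stopf("all channels flagged bad: unusable recording")
  bad
}

# Perrin-style spherical-spline basis: g(cos angle) as a truncated
# Legendre series with stiffness m = 4.
spline_g <- function(cosang, order = 20, m = 4) {
  p_prev <- matrix(1, nrow(cosang), ncol(cosang))  # P_0
  p_cur <- cosang                                   # P_1
  g <- (2 * 1 + 1) / (1^m * 2^m) * p_cur
  for (l in 2:order) {
    p_next <- ((2 * l - 1) * cosang * p_cur - (l - 1) * p_prev) / l
    g <- g + (2 * l + 1) / (l^m * (l + 1)^m) * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  g / (4 * pi)
}

#' Interpolate bad channels by spherical splines
#'
#' Replaces the data of the listed channels by spherical-spline
#' interpolation from the remaining channels using the montage's
#' unit-sphere positions. Good channels are untouched.
#'
#' @param ep An `epoch_array`.
#' @param bad Character vector of channel names to interpolate.
#' @param lambda Ridge regularisation of the spline solve.
#' @return The `epoch_array` with interpolated data and flags set.
#' @export
interpolate_channels <- function(ep, bad, lambda = 1e-5) {
  if (length(bad) == 0) return(ep)
  nm <- ep$montage$name
  if (!all(bad %in% nm)) stopf("unknown channel(s): %s",
                               paste(setdiff(bad, nm), collapse = ", "))
  good <- setdiff(nm, bad)
  if (length(good) < 4)
    stopf("interpolation needs >= 4 good channels (%d left)", length(good))
  pos <- as.matrix(ep$montage[, c("x", "y", "z")])
  rownames(pos) <- nm
  cos_gg <- pmin(pmax(tcrossprod(pos[good, , drop = FALSE]), -1), 1)
  cos_bg <- pmin(pmax(pos[bad, , drop = FALSE] %*% t(pos[good, , drop = FALSE]), -1), 1)
  G <- spline_g(cos_gg)
  Gb <- spline_g(matrix(cos_bg, nrow = length(bad)))
  ng <- length(good)
  A <- rbind(cbind(G + lambda * diag(ng), rep(1, ng)),
             c(rep(1, ng), 0))
  gi <- match(good, nm); bi <- match(bad, nm)
  n_ep <- dim(ep$epochs)[1]; spe <- dim(ep$epochs)[3]
  # solve once for all time points of all epochs
  Y <- matrix(aperm(ep$epochs[, gi, , drop = FALSE], c(2, 1, 3)), nrow = ng)
  sol <- solve(A, rbind(Y, 0))
  interp <- cbind(Gb, rep(1, length(bad))) %*% sol   # n_bad x (n_ep*spe)
  interp_arr <- aperm(array(interp, dim = c(length(bad), n_ep, spe)),
                      c(2, 1, 3))
  ep$epochs[, bi, ] <- interp_arr
  ep$qc$interpolated[bad] <- TRUE
  ep$qc$bad_channels <- union(ep$qc$bad_channels, bad)
  ep
}

#' Reject epochs by amplitude-probability criterion
#'
#' Computes, per channel, the robust z-score of each epoch's log RMS
#' amplitude across epochs (median/MAD with a floored scale); an epoch is
#' rejected when its worst channel exceeds `prob_z`. If the rejected
#' fraction exceeds 0.30 (strictly), the whole recording is marked
#' unusable and downstream stages refuse it.
#'
#' @param ep An `epoch_array`.
#' @param prob_z Rejection threshold (default 5).
#' @param max_fraction Recording-level rejection threshold (default 0.30,
#'   applied strictly: a rejected fraction of exactly 0.30 keeps the
#'   recording usable).
#' @return The `epoch_array` with `qc$keep` updated and, possibly,
#'   `qc$usable = FALSE`.
#' @export
reject_bad_epochs <- function(ep, prob_z = 5, max_fraction = 0.30) {
  n_ep <- dim(ep$epochs)[1]
  if (n_ep < 1) stopf("no epochs")
  nch <- dim(ep$epochs)[2]
  logrms <- log(sqrt(rowMeans(ep$epochs^2, dims = 2)) +
                  .Machine$double.eps)      # n_ep x nch
  z <- apply(logrms, 2, robust_z, floor = 0.1)
  z <- matrix(z, n_ep, nch)
  worst <- apply(abs(z), 1, max)
  rejected <- worst > prob_z
  ep$qc$keep <- ep$qc$keep & !rejected
  frac <- mean(rejected)
  if (frac > max_fraction) {
    ep$qc$usable <- FALSE
    ep$qc$reason <- sprintf("%.0f%% of epochs rejected (over %.0f%%)",
                            100 * frac, 100 * max_fraction)
  }
  ep
}

#' Re-reference epochs to the common average
#'
#' Subtracts the across-channel mean at every time sample. Idempotent.
#'
#' @param ep A usable `epoch_array`.
#' @return The re-referenced `epoch_array` (`reference = "common_average"`).
#' @export
rereference_average <- function(ep) {
  assert_usable(ep)
  n_ep <- dim(ep$epochs)[1]
  for (e in seq_len(n_ep)) {
    sl <- ep$epochs[e, , ]
    ep$epochs[e, , ] <- sweep(sl, 2, colMeans(sl), `-`)
  }
  ep$reference <- "common_average"
  ep
}

#' Run the full preprocessing chain on one recording
#'
#' Fixed stage order: [resample_filter()] -> [epoch_recording()] ->
#' [detect_bad_channels()] / [interpolate_channels()] ->
#' [reject_bad_epochs()] -> [rereference_average()].
#'
#' @param rec A [raw_recording()].
#' @param config A [pipeline_config()] (or list with the same fields).
#' @return A clean `epoch_array`, or one flagged unusable (re-referencing
#'   is skipped in that case).
#' @export
preprocess_recording <- function(rec, config = pipeline_config()) {
  rec <- resample_filter(rec, config$target_fs, config$band)
  ep <- epoch_recording(rec, config$epoch_length_s)
  bad <- detect_bad_channels(ep, config$z_channel)
  if (length(bad)) ep <- interpolate_channels(ep, bad)
  ep <- reject_bad_epochs(ep, config$z_epoch, config$max_bad_epoch_fraction)
  if (isTRUE(ep$qc$usable)) ep <- rereference_average(ep)
  ep
}
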