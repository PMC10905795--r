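# Core signal containers: raw recordings and epoched arrays.

#' Construct a raw multichannel recording
#'
#' A `raw_recording` holds one EEG session: a channels-by-samples signal
#' block (in microvolts) together with its sampling rate, montage, session
#' label (T1..T5) and patient identifier.
#'
#' @param data Numeric matrix, channels x samples; row order must follow
#'   the montage.
#' @param fs Sampling rate in Hz.
#' @param montage Data frame with columns `name`, `x`, `y`, `z`
#'   (see [doc_montage()]).
#' @param session_label Session label, one of `"T1"` .. `"T5"`.
#' @param patient_id Patient identifier string.
#' @param ground_truth Optional latent coupling matrix recorded by the
#'   synthetic generator (symmetric, zero diagonal).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(data, fs, montage = doc_montage(),
                          session_label = "T1", patient_id = "unknown",
                          ground_truth = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stopf("`data` must be a numeric channels x samples matrix")
  if (nrow(data) != nrow(montage))
    stopf("data has %d rows but the montage lists %d channels",
          nrow(data), nrow(montage))
  if (anyDuplicated(montage$name))
    stopf("channel names must be unique")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stopf("`fs` must be a single positive number")
  rownames(data) <- montage$name
  structure(
    list(data = data, fs = fs, montage = montage,
         session_label = session_label, patient_id = patient_id,
         ground_truth = ground_truth),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$patient_id, x$session_label, nrow(x$data), ncol(x$data),
              x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Number of seconds in a recording
#' @param rec A `raw_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

new_epoch_array <- function(epochs, epoch_length_s, fs, montage,
                            session_label, patient_id,
                            reference = "original", qc = NULL) {
  n_ep <- dim(epochs)[1]
  qc <- qc %||% list(
    keep = rep(TRUE, n_ep),
    interpolated = stats::setNames(rep(FALSE, nrow(montage)), montage$name),
    bad_channels = character(0),
    usable = TRUE,
    reason = NULL)
  structure(
    list(epochs = epochs, epoch_length_s = epoch_length_s, fs = fs,
         montage = montage, session_label = session_label,
         patient_id = patient_id, reference = reference, qc = qc),
    class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  cat(sprintf("<epoch_array> %s %s: %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
              x$patient_id, x$session_label, dim(x$epochs)[1],
              dim(x$epochs)[2], dim(x$epochs)[3], x$epoch_length_s, x$fs))
  cat(sprintf("  reference: %s; kept epochs: %d/%d; interpolated channels: %s; usable: %s\n",
              x$reference, sum(x$qc$keep), length(x$qc$keep),
              if (length(x$qc$bad_channels)) paste(x$qc$bad_channels, collapse = ",") else "none",
              x$qc$usable))
  invisible(x)
}

# Signal an error when a downstream stage receives an unusable recording.
assert_usable <- function(ep) {
  if (!isTRUE(ep$qc$usable))
    stop(structure(
      class = c("eegnetvar_unusable_recording", "error", "condition"),
      list(message = sprintf(
        "recording %s %s is marked unusable (%s)", ep$patient_id,
        ep$session_label, ep$qc$reason %||% "no reason recorded"),
        call = NULL)))
  invisible(ep)
}
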