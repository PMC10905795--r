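# File I/O: BrainVision (.vhdr/.eeg/.vmrk) and EDF recordings, cohort
# metadata CSV and ground-truth JSON sidecars. Readers enforce the
# canonical montage channel order.

#' Write a recording as BrainVision files
#'
#' Writes the text header (`.vhdr`), marker file (`.vmrk`) and binary
#' IEEE float32 multiplexed data (`.eeg`).
#'
#' @param rec A [raw_recording()].
#' @param stem Path stem (without extension).
#' @return Invisibly, the `.vhdr` path.
#' @export
write_brainvision <- function(rec, stem) {
  base <- basename(stem)
  vhdr <- paste0(stem, ".vhdr")
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    sprintf("; session=%s patient=%s", rec$session_label, rec$patient_id),
    "",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nrow(rec$data)),
    sprintf("SamplingInterval=%.6f", 1e6 / rec$fs),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$data)), rec$montage$name)
  ), vhdr, useBytes = TRUE)
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", base),
    "",
    "[Marker Infos]",
    sprintf("Mk1=New Segment,%s,1,1,0,0", rec$session_label)
  ), paste0(stem, ".vmrk"))
  con <- file(paste0(stem, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  invisible(vhdr)
}

parse_vhdr <- function(lines) {
  kv <- grep("^[A-Za-z0-9]+=", lines, value = TRUE)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(vals, keys)
}

read_brainvision_raw <- function(vhdr_path) {
  lines <- readLines(vhdr_path, warn = FALSE, encoding = "UTF-8")
  hdr <- parse_vhdr(lines)
  if (!identical(toupper(hdr[["DataFormat"]]), "BINARY") ||
      !identical(toupper(hdr[["DataOrientation"]]), "MULTIPLEXED"))
    stopf("only BINARY/MULTIPLEXED BrainVision files are supported")
  fmt <- toupper(hdr[["BinaryFormat"]])
  nch <- as.integer(hdr[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(hdr[["SamplingInterval"]])
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_info <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  ch_names <- vapply(ch_info, `[[`, character(1), 1)
  resol <- vapply(ch_info, function(f)
    if (length(f) >= 3 && nzchar(f[[3]])) as.numeric(f[[3]]) else 1,
    numeric(1))
  if (length(ch_names) != nch)
    stopf("malformed header: %d channel lines for %d channels",
          length(ch_names), nch)
  eeg_path <- file.path(dirname(vhdr_path), hdr[["DataFile"]])
  sz <- file.info(eeg_path)$size
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    vals <- readBin(con, numeric(), n = sz / 4, size = 4, endian = "little")
  } else if (fmt == "INT_16") {
    vals <- readBin(con, integer(), n = sz / 2, size = 2, endian = "little")
  } else stopf("unsupported BinaryFormat `%s`", fmt)
  n <- floor(length(vals) / nch)
  data <- matrix(vals[seq_len(n * nch)], nrow = nch) * resol
  rownames(data) <- ch_names
  session <- "T1"
  m <- regmatches(lines, regexpr("session=(T[1-5])", lines))
  if (length(m)) session <- sub("session=", "", m[[1]])
  pat <- "unknown"
  m <- regmatches(lines, regexpr("patient=([^ ]+)", lines))
  if (length(m)) pat <- sub("patient=", "", m[[1]])
  list(data = data, fs = fs, channel_names = ch_names,
       session_label = session, patient_id = pat)
}

pad_ascii <- function(x, width) {
  x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording as EDF
#'
#' European Data Format with 1-second data records and 16-bit samples;
#' the sampling rate must be an integer. The signal is truncated to
#' whole records.
#'
#' @param rec A [raw_recording()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (fs != round(fs)) stopf("EDF export needs an integer sampling rate")
  nch <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stopf("recording shorter than one 1-s EDF record")
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- apply(data, 1, min); pmax_ <- apply(data, 1, max)
  span <- pmax_ - pmin_
  pmin_[span == 0] <- pmin_[span == 0] - 1
  pmax_[span == 0] <- pmax_[span == 0] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  # write each element padded to its fixed field width (ASCII only)
  wr <- function(x, w) writeChar(paste0(pad_ascii(as.character(x), w),
                                        collapse = ""), con, eos = NULL)
  wr("0", 8)
  wr(rec$patient_id, 80)
  wr(sprintf("session %s", rec$session_label), 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(sprintf("%d", 256 * (1 + nch)), 8)
  wr("", 44)
  wr(sprintf("%d", n_rec), 8)
  wr("1", 8)
  wr(sprintf("%d", nch), 4)
  wr(rec$montage$name, 16)
  wr(rep("", nch), 80)
  wr(rep("uV", nch), 8)
  num8 <- function(x) {   # numeric in at most 8 ASCII characters
    s <- sprintf("%.5g", x)
    ifelse(nchar(s) > 8, sprintf("%.1e", x), s)
  }
  wr(num8(pmin_), 8)
  wr(num8(pmax_), 8)
  wr(rep(sprintf("%d", dmin), nch), 8)
  wr(rep(sprintf("%d", dmax), nch), 8)
  wr(rep("", nch), 80)
  wr(rep(sprintf("%d", fs), nch), 8)
  wr(rep("", nch), 32)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(nch)) {
      dig <- round((data[ch, idx] - pmin_[ch]) * scale[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)
  patient <- rd(80)
  recinfo <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (is.na(nch) || nch < 1) stopf("malformed EDF header")
  ch_names <- vapply(seq_len(nch), function(i) rd(16), character(1))
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), character(1)))
  for (i in seq_len(nch)) rd(80)
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), character(1)))
  for (i in seq_len(nch)) rd(32)
  data <- matrix(NA_real_, nch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nch)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2,
                     endian = "little")
      phys <- pmin_[ch] + (dig - dmin[ch]) *
        (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
      data[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys
    }
  }
  rownames(data) <- ch_names
  session <- "T1"
  m <- regmatches(recinfo, regexpr("T[1-5]", recinfo))
  if (length(m)) session <- m
  list(data = data, fs = spr[1] / dur, channel_names = ch_names,
       session_label = session, patient_id = patient)
}

#' Read a recording from disk
#'
#' Reads a BrainVision (`.vhdr`) or EDF (`.edf`) file and canonicalises
#' it against the montage: channel names are matched case-insensitively,
#' extra channels are dropped with a warning, missing channels are an
#' error, and the output rows follow the montage order.
#'
#' @param path File path (`.vhdr` or `.edf`).
#' @param format `"brainvision"`, `"edf"`, or `"auto"` (by extension).
#' @param montage Montage to enforce.
#' @return A [raw_recording()].
#' @export
read_recording <- function(path, format = c("auto", "brainvision", "edf"),
                           montage = doc_montage()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vhdr$", path, ignore.case = TRUE))
      "brainvision" else "edf"
  raw <- if (format == "brainvision") read_brainvision_raw(path)
         else read_edf_raw(path)
  have <- tolower(raw$channel_names)
  want <- tolower(montage$name)
  missing <- montage$name[!want %in% have]
  if (length(missing))
    stopf("file lacks %d montage channel(s): %s", length(missing),
          paste(missing, collapse = ", "))
  extra <- raw$channel_names[!have %in% want]
  if (length(extra))
    warnf("dropping %d channel(s) not in the montage: %s", length(extra),
          paste(extra, collapse = ", "))
  idx <- match(want, have)
  raw_recording(raw$data[idx, , drop = FALSE], raw$fs, montage,
                session_label = raw$session_label,
                patient_id = raw$patient_id)
}

#' Export a synthetic cohort to disk
#'
#' Writes each session as BrainVision (or EDF), cohort metadata
#' (patient id, group, CRS-R, seed) as CSV, and the ground-truth session
#' coupling matrices as a JSON sidecar.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param format `"brainvision"` or `"edf"`.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir, format = c("brainvision", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(patient_id = character(), group = character(),
                     crsr = integer(), seed = integer(),
                     stringsAsFactors = FALSE)
  truth <- list()
  for (p in cohort$patients) {
    p <- realize_sessions(p, cohort)
    meta <- rbind(meta, data.frame(
      patient_id = p$patient_id, group = p$group, crsr = p$crsr,
      seed = p$session_specs[[1]]$structure_seed,
      stringsAsFactors = FALSE))
    truth[[p$patient_id]] <- lapply(p$sessions, function(s)
      unname(s$ground_truth))
    for (s in p$sessions) {
      stem <- file.path(dir, sprintf("%s_%s", p$patient_id, s$session_label))
      if (format == "brainvision") write_brainvision(s, stem)
      else write_edf(s, paste0(stem, ".edf"))
    }
  }
  utils::write.csv(meta, file.path(dir, "cohort_metadata.csv"),
                   row.names = FALSE)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       digits = NA)
  invisible(dir)
}
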