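# Recording I/O: CSV matrix + YAML sidecar, and a minimal EDF reader/writer.

.sidecar_path <- function(path) paste0(sub("\\.(csv|tsv)$", "", path), ".yaml")

#' Write a recording as a CSV matrix with a YAML sidecar
#'
#' The matrix is written channels x samples with a leading `channel` column;
#' sampling rate and channel labels go to `<path minus extension>.yaml` so the
#' pair is self-describing.
#'
#' @param rec an `eeg_recording`.
#' @param path output `.csv` path.
#' @return invisibly, the sidecar path.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- data.frame(channel = rec$labels, rec$data, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  side <- .sidecar_path(path)
  yaml::write_yaml(list(fs = rec$fs, labels = as.list(rec$labels)), side)
  invisible(side)
}

#' Read a recording from a CSV/TSV matrix with a YAML sidecar
#'
#' @param path `.csv` or `.tsv` file, channels x samples; a leading `channel`
#'   column, if present, is used for labels.
#' @param sidecar optional sidecar path; defaults to `<path minus ext>.yaml`.
#'   The sidecar must provide `fs` and may provide `labels`.
#' @return an `eeg_recording`.
#' @export
read_recording_csv <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- .sidecar_path(path)
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  meta <- yaml::read_yaml(sidecar)
  if (is.null(meta$fs)) stop("sidecar must give the sampling rate `fs`")
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  labels <- NULL
  if ("channel" %in% names(df)) {
    labels <- as.character(df$channel)
    df$channel <- NULL
  }
  if (!is.null(meta$labels)) labels <- unlist(meta$labels)
  m <- as.matrix(df)
  dimnames(m) <- NULL
  eeg_recording(m, meta$fs, labels)
}

.edf_pad <- function(x, width) {
  s <- as.character(x)
  if (any(nchar(s) > width)) stop("EDF header field overflow")
  formatC(s, width = width, flag = "-")
}

# numeric to at most 8 ASCII chars (EDF physical min/max fields)
.edf_num <- function(x) {
  vapply(x, function(v) {
    for (digits in 7:1) {
      s <- sprintf("%.*g", digits, v)
      if (nchar(s) <= 8L) return(s)
    }
    stop("cannot format ", v, " in 8 characters")
  }, "")
}

#' Write a recording to a European Data Format (EDF) file
#'
#' Minimal EDF writer: one-second data records, 16-bit integers with
#' per-channel physical scaling in microvolts. The sampling rate must be a
#' whole number of samples per second and the recording is truncated to whole
#' seconds (with a warning) because EDF stores fixed-length records.
#'
#' @param rec an `eeg_recording`.
#' @param path output `.edf` path.
#' @return invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  ns <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1L) stop("recording shorter than one EDF record (1 s)")
  if (n_rec * fs < ncol(rec$data)) {
    warning("truncating recording to whole seconds for EDF")
  }
  dat <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- apply(dat, 1, min)
  pmax_ <- apply(dat, 1, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  # header fields hold 8 ASCII chars; widen the range slightly so the rounded
  # header values still bracket the data, and scale with the header values
  pmin_ <- as.numeric(.edf_num(pmin_ - abs(pmin_) * 1e-5 - 1e-6))
  pmax_ <- as.numeric(.edf_num(pmax_ + abs(pmax_) * 1e-5 + 1e-6))
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad("synthetic recording", 80),
    .edf_pad("mwtselect", 80),
    "01.01.00", "00.00.00",
    .edf_pad(256L * (1L + ns), 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8),
    .edf_pad(1, 8),
    .edf_pad(ns, 4)
  )
  sig <- paste0(
    paste(.edf_pad(rec$labels, 16), collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(rep(.edf_pad("uV", 8), ns), collapse = ""),
    paste(.edf_pad(.edf_num(pmin_), 8), collapse = ""),
    paste(.edf_pad(.edf_num(pmax_), 8), collapse = ""),
    paste(rep(.edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(.edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(rep(.edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(.edf_pad("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((dat[ch, idx] - pmin_[ch]) * scale[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read a European Data Format (EDF) recording
#'
#' Minimal reader for continuous EDF: equal sampling rate across channels,
#' 16-bit samples, physical scaling applied from the header.
#'
#' @param path `.edf` file.
#' @return an `eeg_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchar_) trimws(readChar(con, nchar_, useBytes = TRUE))
  rd(8)                                  # version
  rd(80); rd(80); rd(8); rd(8)           # patient, recording, date, time
  rd(8)                                  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)          # transducer
  for (i in seq_len(ns)) rd(8)           # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 1)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 1)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 1)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 1)
  for (i in seq_len(ns)) rd(80)          # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 1L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L) stop("EDF reader requires one rate across channels")
  fs <- spr[1] / dur
  out <- matrix(NA_real_, ns, n_rec * spr[1])
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      out[ch, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
        (dig - dmin[ch]) * gain[ch] + pmin_[ch]
    }
  }
  eeg_recording(out, fs, labels)
}
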