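#' Multichannel EEG recording container
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param labels character vector of channel labels (10-20 names for scalp
#'   EEG); defaults to the rownames of `data`.
#' @return object of class `eeg_recording`: list with `data`, `fs`, `labels`.
#' @export
eeg_recording <- function(data, fs, labels = rownames(data)) {
  data <- as.matrix(data)
  if (is.null(labels)) stop("channel labels are required")
  labels <- as.character(labels)
  if (length(labels) != nrow(data)) stop("one label per channel required")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive number")
  if (any(!is.finite(data))) stop("recording contains non-finite samples")
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs
  ))
  cat("channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

.apply_channels <- function(rec, fun) {
  out <- t(apply(rec$data, 1L, fun))
  eeg_recording(out, rec$fs, rec$labels)
}

#' Notch filter for power-line interference
#'
#' Second-order IIR notch (biquad), applied forward-backward per channel for
#' zero phase. The quality factor sets the -3 dB bandwidth `f0 / q`; the
#' default q = 30 removes a 50 Hz mains line while leaving the spectrum
#' outside roughly +/- 1 Hz untouched. Use `f0 = 60` for 60 Hz mains.
#'
#' @param rec an `eeg_recording`.
#' @param f0 notch frequency in Hz (must be below Nyquist).
#' @param q quality factor (dimensionless).
#' @return filtered `eeg_recording`.
#' @export
notch_filter <- function(rec, f0 = 50, q = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (f0 <= 0 || f0 >= rec$fs / 2) {
    stop("Nyquist error: notch frequency must lie in (0, fs/2)")
  }
  w0 <- 2 * pi * f0 / rec$fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  .apply_channels(rec, function(x) signal::filtfilt(b, a, x))
}

#' Band-pass filter for the EEG band of interest
#'
#' Butterworth IIR band-pass (order 4 by default), applied forward-backward
#' (zero phase) per channel so that later denoising comparisons are not
#' confounded by group delay. The conventional EEG limits are 0.5-64 Hz.
#'
#' @param rec an `eeg_recording`.
#' @param low,high corner frequencies in Hz, `0 < low < high < fs/2`.
#' @param order Butterworth design order.
#' @return filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 64, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2)) {
    stop("parameter error: need 0 < low < high < fs/2")
  }
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  .apply_channels(rec, function(x) signal::filtfilt(bf, x))
}

#' Cut a recording into fixed-length non-overlapping epochs
#'
#' @param rec an `eeg_recording`.
#' @param epoch_len epoch length in samples (256 = 1 s at 256 Hz, the scoring
#'   unit of the selection procedure).
#' @return object of class `eeg_epochs`: list with a channels x epochs x
#'   samples array `epochs`, `fs`, `labels`, `epoch_len`. Any trailing
#'   remainder shorter than one epoch is discarded with a warning.
#' @export
segment_epochs <- function(rec, epoch_len = 256L) {
  stopifnot(inherits(rec, "eeg_recording"))
  epoch_len <- as.integer(epoch_len)
  if (epoch_len < 1L) stop("epoch_len must be >= 1")
  n <- ncol(rec$data)
  n_ep <- n %/% epoch_len
  if (n_ep == 0L) stop("empty-epochs error: recording shorter than one epoch")
  rem <- n - n_ep * epoch_len
  if (rem > 0L) {
    warning(sprintf("discarding %d trailing samples (< one epoch)", rem))
  }
  arr <- array(NA_real_, dim = c(nrow(rec$data), n_ep, epoch_len),
               dimnames = list(rec$labels, NULL, NULL))
  for (e in seq_len(n_ep)) {
    arr[, e, ] <- rec$data[, ((e - 1L) * epoch_len + 1L):(e * epoch_len)]
  }
  structure(
    list(epochs = arr, fs = rec$fs, labels = rec$labels, epoch_len = epoch_len),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %d channels x %d epochs x %d samples @ %g Hz\n",
    dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3], x$fs
  ))
  invisible(x)
}

#' Standard 10-20 scalp-region grouping
#'
#' Groups the 19 scalp electrodes of the 10-20 system into the five recording
#' regions used for region-level wavelet selection: frontal (7 channels),
#' temporal (4), parietal (3), occipital (2) and central (3).
#'
#' @return named list mapping region name to channel labels.
#' @examples
#' lengths(default_region_map())
#' @export
default_region_map <- function() {
  list(
    frontal   = c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz"),
    temporal  = c("T3", "T4", "T5", "T6"),
    parietal  = c("P3", "P4", "Pz"),
    occipital = c("O1", "O2"),
    central   = c("C3", "C4", "Cz")
  )
}

# region lookup for a vector of channel labels, case-insensitive
.region_of <- function(labels, region_map) {
  keys <- tolower(unlist(region_map, use.names = FALSE))
  regs <- rep(names(region_map), lengths(region_map))
  idx <- match(tolower(labels), keys)
  if (anyNA(idx)) {
    stop("mapping error: channels not in region map: ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  regs[idx]
}
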