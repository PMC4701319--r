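.as_wavelet <- function(w) {
  if (inherits(w, "wavelet_spec")) w else wavelet_spec(w)
}

.check_mode <- function(mode) match.arg(mode, c("symmetric", "periodic"))

#' Single-level discrete wavelet transform
#'
#' Splits a signal into approximation (low-pass) and detail (high-pass)
#' coefficients by filtering and downsampling by two, the elementary step of
#' the Mallat filter-bank decomposition.
#'
#' Two boundary rules are provided. `"symmetric"` (default) extends the
#' signal by half-point reflection; coefficient vectors have length
#' `floor((n + f - 1) / 2)` for filter length `f` and reconstruction is exact.
#' `"periodic"` wraps indices modulo the (even) signal length; the transform
#' is then orthonormal, so it preserves energy exactly (Parseval) and keeps
#' `n/2` coefficients per branch. The symmetric rule is the denoising default
#' because it avoids wrap-around artifacts at epoch edges; the periodic rule
#' is exposed for exact energy bookkeeping.
#'
#' @param signal numeric vector.
#' @param w a `wavelet_spec` or wavelet name.
#' @param mode boundary extension, `"symmetric"` or `"periodic"`.
#' @return list with components `approx` and `detail`.
#' @export
dwt_level <- function(signal, w, mode = c("symmetric", "periodic")) {
  w <- .as_wavelet(w)
  mode <- .check_mode(mode)
  n <- length(signal)
  f <- length(w$dec_lo)
  if (mode == "symmetric") {
    if (n < f) {
      stop("decomposition depth error: signal (", n,
           " samples) shorter than filter (", f, " taps)")
    }
    out <- cpp_dwt_sym(as.numeric(signal), w$dec_lo, w$dec_hi)
  } else {
    if (n %% 2L != 0L || n < 2L) {
      stop("decomposition depth error: periodic mode requires even signal length")
    }
    out <- cpp_dwt_per(as.numeric(signal), w$dec_lo, w$dec_hi)
  }
  list(approx = out$a, detail = out$d)
}

#' Single-level inverse discrete wavelet transform
#'
#' Exact left-inverse of [dwt_level()] under the same boundary rule:
#' `idwt_level(dwt_level(x, w)$approx, dwt_level(x, w)$detail, w)`
#' reproduces `x` to machine precision.
#'
#' @param approx,detail coefficient vectors of equal length.
#' @param w a `wavelet_spec` or wavelet name.
#' @param mode boundary extension used at analysis time.
#' @param out_len target signal length; defaults to `2 * length(approx)` for
#'   periodic mode and `2 * length(approx) - f + 2` for symmetric mode.
#' @return numeric vector of length `out_len`.
#' @export
idwt_level <- function(approx, detail, w, mode = c("symmetric", "periodic"),
                       out_len = NULL) {
  w <- .as_wavelet(w)
  mode <- .check_mode(mode)
  if (length(approx) != length(detail)) {
    stop("reconstruction error: approximation/detail length mismatch")
  }
  f <- length(w$rec_lo)
  if (mode == "periodic") {
    x <- cpp_idwt_per(as.numeric(approx), as.numeric(detail), w$rec_lo, w$rec_hi)
    if (!is.null(out_len)) {
      if (out_len > length(x)) stop("reconstruction error: out_len too large")
      x <- x[seq_len(out_len)]
    }
    x
  } else {
    if (is.null(out_len)) out_len <- 2L * length(approx) - f + 2L
    if (out_len < 1L) stop("reconstruction error: out_len too small")
    cpp_idwt_sym(as.numeric(approx), as.numeric(detail), w$rec_lo, w$rec_hi,
                 as.integer(out_len))
  }
}

#' Multi-level wavelet decomposition
#'
#' Iterates [dwt_level()] on successive approximations, producing the
#' coefficient sets cD1 (finest) ... cDL and cA_L used for denoising and
#' sub-band analysis. A 256-sample epoch at five levels yields six coefficient
#' sets whose dyadic bands are given by [dyadic_band_map()].
#'
#' @inheritParams dwt_level
#' @param levels number of decomposition levels (>= 1).
#' @return object of class `wavelet_decomposition`: list with `approx` (cA_L),
#'   `details` (list cD1..cDL, finest first), `levels`, `wavelet`,
#'   `original_length`, `mode`, and the per-level input lengths needed for
#'   exact reconstruction.
#' @export
wavedec <- function(signal, w, levels = 5L, mode = c("symmetric", "periodic")) {
  w <- .as_wavelet(w)
  mode <- .check_mode(mode)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  if (mode == "periodic" && length(signal) %% 2L^levels != 0L) {
    stop("decomposition depth error: periodic mode needs length divisible by 2^levels")
  }
  a <- as.numeric(signal)
  details <- vector("list", levels)
  lens <- integer(levels)
  for (k in seq_len(levels)) {
    lens[k] <- length(a)
    step <- dwt_level(a, w, mode)
    details[[k]] <- step$detail
    a <- step$approx
  }
  structure(
    list(
      approx = a, details = details, levels = levels, wavelet = w,
      original_length = length(signal), mode = mode, input_lengths = lens
    ),
    class = "wavelet_decomposition"
  )
}

#' Multi-level wavelet reconstruction
#'
#' Exact inverse of [wavedec()].
#'
#' @param d a `wavelet_decomposition`.
#' @return numeric vector of length `d$original_length`.
#' @export
waverec <- function(d) {
  stopifnot(inherits(d, "wavelet_decomposition"))
  a <- d$approx
  for (k in rev(seq_len(d$levels))) {
    a <- idwt_level(a, d$details[[k]], d$wavelet, d$mode,
                    out_len = d$input_lengths[k])
  }
  a
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf(
    "<wavelet_decomposition> %s, %d levels, %d samples (%s extension)\n",
    x$wavelet$name, x$levels, x$original_length, x$mode
  ))
  lens <- c(vapply(x$details, length, 1L), length(x$approx))
  names(lens) <- c(paste0("cD", seq_len(x$levels)), paste0("cA", x$levels))
  print(lens)
  invisible(x)
}

#' Multiresolution (MRA) component reconstruction
#'
#' Reconstructs each dyadic sub-band component D1..DL and A_L by inverting the
#' decomposition with all other coefficient sets zeroed. By linearity the
#' components sum to the original signal, so sub-band powers computed from
#' them are an exact additive split of the signal.
#'
#' @param d a `wavelet_decomposition`.
#' @return named list of numeric vectors `D1`, ..., `DL`, `AL` (e.g. `A5`),
#'   each of the original signal length.
#' @export
mra_reconstruct <- function(d) {
  stopifnot(inherits(d, "wavelet_decomposition"))
  L <- d$levels
  zero <- d
  zero$approx <- numeric(length(d$approx))
  zero$details <- lapply(d$details, function(v) numeric(length(v)))
  comps <- vector("list", L + 1L)
  for (k in seq_len(L)) {
    dk <- zero
    dk$details[[k]] <- d$details[[k]]
    comps[[k]] <- waverec(dk)
  }
  da <- zero
  da$approx <- d$approx
  comps[[L + 1L]] <- waverec(da)
  names(comps) <- c(paste0("D", seq_len(L)), paste0("A", L))
  comps
}

.eeg_band_name <- function(low, high) {
  key <- paste(low, high)
  switch(key,
    "0 4"   = "delta",
    "4 8"   = "theta",
    "8 16"  = "alpha",
    "16 32" = "beta",
    "32 64" = "lower gamma",
    "64 128" = "higher gamma and noise",
    NA_character_
  )
}

#' Dyadic frequency-band map of a wavelet decomposition
#'
#' Each detail level k of an L-level decomposition covers the dyadic band
#' `[fs / 2^(k+1), fs / 2^k]` Hz and the final approximation covers
#' `[0, fs / 2^(L+1)]`; together they tile `[0, fs/2]` with no gaps or
#' overlaps. At the EEG-standard fs = 256 Hz and five levels the components
#' line up with the clinical bands: D1 64-128 Hz (higher gamma and noise),
#' D2 32-64 Hz (lower gamma), D3 16-32 Hz (beta), D4 8-16 Hz (alpha),
#' D5 4-8 Hz (theta), A5 0-4 Hz (delta).
#'
#' @param fs sampling rate in Hz.
#' @param levels number of decomposition levels.
#' @return data.frame with columns `component`, `low_hz`, `high_hz`,
#'   `eeg_band` (NA where the edges match no conventional EEG band), ordered
#'   D1 (highest band) to A_L.
#' @examples
#' dyadic_band_map(256, 5)
#' @export
dyadic_band_map <- function(fs, levels) {
  stopifnot(fs > 0, levels >= 1)
  k <- seq_len(levels)
  low <- fs / 2^(k + 1)
  high <- fs / 2^k
  comp <- paste0("D", k)
  map <- data.frame(
    component = c(comp, paste0("A", levels)),
    low_hz = c(low, 0),
    high_hz = c(high, fs / 2^(levels + 1)),
    stringsAsFactors = FALSE
  )
  map$eeg_band <- mapply(.eeg_band_name, map$low_hz, map$high_hz)
  map
}
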