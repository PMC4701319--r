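# Sub-band power and relative power from the multiresolution components.

#' Sub-band powers of the MRA components
#'
#' Power (sum of squared samples) of each reconstructed dyadic component.
#' At 256 Hz and five levels, D1 covers 64-128 Hz (higher gamma plus
#' broadband noise) and is excluded by default so the retained components
#' D2..D5 and A5 span the EEG band of interest (0-64 Hz).
#'
#' @param components named list from [mra_reconstruct()].
#' @param exclude component names left out (default `"D1"`).
#' @return named numeric vector of powers.
#' @export
band_powers <- function(components, exclude = "D1") {
  stopifnot(is.list(components), !is.null(names(components)))
  keep <- setdiff(names(components), exclude)
  vapply(components[keep], function(x) sum(x^2), 1)
}

#' Relative power
#'
#' Each band power divided by the total over the retained components, as a
#' percentage. Rows sum to 100 by construction.
#'
#' @param powers named nonnegative vector from [band_powers()].
#' @return named vector of percentages in `[0, 100]`.
#' @export
relative_power <- function(powers) {
  if (any(powers < 0)) stop("powers must be nonnegative")
  tot <- sum(powers)
  if (tot <= 0) stop("undefined-RP error: all band powers are zero")
  100 * powers / tot
}

.canonical_bands <- c(A5 = "delta", D5 = "theta", D4 = "alpha",
                      D3 = "beta", D2 = "gamma")

#' Relative band power per channel (and per region) of a recording
#'
#' Denoises every epoch of every channel with the selected wavelet, computes
#' the multiresolution components, accumulates sub-band powers across epochs,
#' and reports delta/theta/alpha/beta/(lower-)gamma relative power per
#' channel. With a region map, channel rows are averaged per region (the
#' default), or region powers can be pooled before normalizing
#' (`pooled = TRUE`).
#'
#' The five clinical bands require the canonical dyadic alignment, i.e. five
#' decomposition levels at fs = 256 Hz (D2 = 32-64 Hz lower gamma down to
#' A5 = 0-4 Hz delta); other sampling rates are reported under their dyadic
#' component names.
#'
#' @param rec an `eeg_recording`.
#' @param wavelet `wavelet_spec` or name (e.g. the selection winner).
#' @param epoch_len,levels,mode,rule,zero_d1 as in [denoise_epoch()].
#' @param denoise denoise epochs before the MRA (default `TRUE`).
#' @param region_map optional named list (see [default_region_map()]).
#' @param pooled with a region map: sum band powers over the region's
#'   channels before normalizing, instead of averaging channel percentages.
#' @return data.frame, one row per channel (and per region when a map is
#'   given), with one relative-power column per band; each row sums to 100.
#' @export
relative_power_table <- function(rec, wavelet, epoch_len = 256L, levels = 5L,
                                 mode = c("symmetric", "periodic"),
                                 rule = c("sure", "hybrid"), zero_d1 = FALSE,
                                 denoise = TRUE, region_map = NULL,
                                 pooled = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  w <- .as_wavelet(wavelet)
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  epochs <- segment_epochs(rec, epoch_len)
  n_ch <- dim(epochs$epochs)[1]
  n_ep <- dim(epochs$epochs)[2]
  pow <- NULL
  for (ch in seq_len(n_ch)) {
    acc <- NULL
    for (ep in seq_len(n_ep)) {
      x <- epochs$epochs[ch, ep, ]
      if (denoise) x <- denoise_epoch(x, w, levels, mode, rule, zero_d1)
      p <- band_powers(mra_reconstruct(wavedec(x, w, levels, mode)))
      acc <- if (is.null(acc)) p else acc + p
    }
    if (is.null(pow)) pow <- matrix(NA_real_, n_ch, length(acc),
                                    dimnames = list(epochs$labels, names(acc)))
    pow[ch, ] <- acc
  }
  canonical <- levels == 5L && rec$fs == 256
  band_names <- if (canonical) {
    unname(.canonical_bands[match(colnames(pow),
                                  names(.canonical_bands))])
  } else colnames(pow)
  order_ <- if (canonical) {
    match(c("delta", "theta", "alpha", "beta", "gamma"), band_names)
  } else seq_along(band_names)

  rp_rows <- t(apply(pow, 1, relative_power))
  colnames(rp_rows) <- band_names
  rp_rows <- rp_rows[, order_, drop = FALSE]
  out <- data.frame(channel = rownames(pow), rp_rows, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(region_map)) return(out)

  region <- .region_of(out$channel, region_map)
  if (pooled) {
    agg <- rowsum(pow, region)
    rp <- t(apply(agg, 1, relative_power))
  } else {
    rp <- rowsum(as.matrix(out[, -1L]), region) / as.vector(table(region)[sort(unique(region))])
    rp <- as.matrix(rp)
  }
  colnames(rp) <- band_names[if (pooled) seq_along(band_names) else order_]
  if (pooled) rp <- rp[, order_, drop = FALSE]
  data.frame(region = rownames(rp), rp, row.names = NULL, check.names = FALSE,
             stringsAsFactors = FALSE)
}
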