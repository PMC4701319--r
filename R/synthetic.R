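# Seeded synthetic EEG: 1/f-weighted band-limited background, ocular/muscle/
# line artifacts, 19-channel 10-20 montage, and wavelet-structured ground
# truth signals for recovery experiments.

# run code under a local RNG seed without touching the caller's RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.synth_band_edges <- list(
  delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 16),
  beta = c(16, 32), gamma = c(32, 64)
)

#' Synthetic EEG configuration
#'
#' Defaults emulate a 19-channel, 256 Hz, 60 s resting/working-memory style
#' recording: band-limited Gaussian background with a 1/f amplitude envelope
#' and microvolt-scale band weights (delta-dominant, clear occipital alpha),
#' high-amplitude slow ocular transients, broadband high-frequency muscle
#' bursts, and 50 Hz line interference.
#'
#' @param fs sampling rate, Hz.
#' @param duration recording length, seconds.
#' @param band_weights named RMS amplitudes (microvolt) of the delta, theta,
#'   alpha, beta and gamma background carriers.
#' @param pink_exponent exponent of the 1/f^a amplitude envelope applied
#'   within each band (a = 1: pink-like background).
#' @param ocular_rate,ocular_amp blink/eye-movement transients: mean events
#'   per second and peak amplitude (microvolt).
#' @param muscle_rate,muscle_amp high-frequency (64-128 Hz) burst artifacts:
#'   mean bursts per second and RMS amplitude within a burst.
#' @param line_freq,line_amp mains interference frequency (Hz) and amplitude.
#' @param region_modifiers named list: per region, a named multiplier vector
#'   applied to `band_weights` for that region's channels. The default boosts
#'   occipital alpha and frontal delta, the textbook topography.
#' @param seed integer seed fixing all randomness end to end; `NULL` uses the
#'   current RNG state.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(fs = 256, duration = 60,
                         band_weights = c(delta = 20, theta = 10, alpha = 15,
                                          beta = 5, gamma = 2),
                         pink_exponent = 1,
                         ocular_rate = 0.2, ocular_amp = 80,
                         muscle_rate = 0.1, muscle_amp = 10,
                         line_freq = 50, line_amp = 5,
                         region_modifiers = list(
                           occipital = c(alpha = 2),
                           frontal = c(delta = 1.5)
                         ),
                         seed = NULL) {
  stopifnot(fs > 0, duration > 0, all(band_weights >= 0))
  structure(
    list(
      fs = fs, duration = duration, band_weights = band_weights,
      pink_exponent = pink_exponent,
      ocular_rate = ocular_rate, ocular_amp = ocular_amp,
      muscle_rate = muscle_rate, muscle_amp = muscle_amp,
      line_freq = line_freq, line_amp = line_amp,
      region_modifiers = region_modifiers, seed = seed
    ),
    class = "synth_config"
  )
}

# band-limited noise carrier: white noise masked to [lo, hi] Hz in the
# frequency domain with a 1/f^(a/2) amplitude taper, unit RMS
.band_noise <- function(n, fs, lo, hi, pink_exponent) {
  freq <- seq(0, fs - fs / n, length.out = n)
  freq <- pmin(freq, fs - freq)                 # two-sided frequency axis
  mask <- freq >= lo & freq <= hi
  if (!any(mask)) return(numeric(n))
  spec <- stats::fft(stats::rnorm(n))
  taper <- numeric(n)
  taper[mask] <- pmax(freq[mask], fs / n)^(-pink_exponent / 2)
  x <- Re(stats::fft(spec * taper, inverse = TRUE)) / n
  r <- sqrt(mean(x^2))
  if (r > 0) x / r else x
}

#' Generate one channel of background EEG
#'
#' Sum of band-limited Gaussian carriers (delta through gamma, edges as in
#' the dyadic band map at 256 Hz), each with a 1/f amplitude envelope,
#' scaled to the configured RMS weights.
#'
#' @param cfg a `synth_config`.
#' @param band_weights optional override of `cfg$band_weights`.
#' @return numeric vector of `fs * duration` samples (microvolt).
#' @export
gen_background <- function(cfg, band_weights = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  w <- if (is.null(band_weights)) cfg$band_weights else band_weights
  n <- round(cfg$fs * cfg$duration)
  .with_seed(cfg$seed, {
    x <- numeric(n)
    for (b in names(.synth_band_edges)) {
      wb <- if (b %in% names(w)) w[[b]] else 0
      if (wb > 0) {
        e <- .synth_band_edges[[b]]
        x <- x + wb * .band_noise(n, cfg$fs, e[1], min(e[2], cfg$fs / 2),
                                  cfg$pink_exponent)
      }
    }
    x
  })
}

# raised-cosine bump of given width (samples), peak 1
.bump <- function(width) (1 - cos(2 * pi * seq_len(width) / (width + 1))) / 2

#' Add artifact classes to a clean signal
#'
#' Additive contamination: slow high-amplitude ocular transients
#' (raised-cosine bumps, 0.5-1 s wide, so their energy sits below 4 Hz),
#' short broadband muscle bursts band-limited to 64-128 Hz, and a sinusoidal
#' mains line. All amplitudes zero gives the identity.
#'
#' @param signal numeric vector.
#' @param cfg a `synth_config` (rates, amplitudes, line frequency, seed).
#' @return contaminated signal of the same length.
#' @export
add_artifacts <- function(signal, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- length(signal)
  fs <- cfg$fs
  .with_seed(if (is.null(cfg$seed)) NULL else cfg$seed + 1L, {
    x <- signal
    if (cfg$ocular_amp > 0 && cfg$ocular_rate > 0) {
      k <- stats::rpois(1, cfg$ocular_rate * n / fs)
      for (i in seq_len(k)) {
        width <- round(fs * stats::runif(1, 0.5, 1))
        start <- sample.int(max(n - width, 1L), 1L)
        amp <- cfg$ocular_amp * stats::runif(1, 0.5, 1) * sample(c(-1, 1), 1)
        idx <- start:(start + width - 1L)
        x[idx] <- x[idx] + amp * .bump(width)
      }
    }
    if (cfg$muscle_amp > 0 && cfg$muscle_rate > 0) {
      k <- stats::rpois(1, cfg$muscle_rate * n / fs)
      for (i in seq_len(k)) {
        width <- round(fs * stats::runif(1, 0.2, 0.5))
        start <- sample.int(max(n - width, 1L), 1L)
        burst <- .band_noise(width, fs, 64, min(128, fs / 2 * 0.999), 0)
        idx <- start:(start + width - 1L)
        x[idx] <- x[idx] + cfg$muscle_amp * .bump(width) * burst
      }
    }
    if (cfg$line_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      x <- x + cfg$line_amp * sin(2 * pi * cfg$line_freq * seq_len(n) / fs + phase)
    }
    x
  })
}

#' Generate a 19-channel synthetic EEG recording
#'
#' One independent background per 10-20 channel, with the configured
#' per-region band-weight modifiers applied (e.g. boosted occipital alpha),
#' plus artifacts. Fully deterministic under `cfg$seed`.
#'
#' @param cfg a `synth_config`.
#' @param region_map channel grouping (default [default_region_map()]).
#' @return an `eeg_recording` with the 19 standard labels.
#' @export
gen_recording <- function(cfg, region_map = default_region_map()) {
  stopifnot(inherits(cfg, "synth_config"))
  labels <- unlist(region_map, use.names = FALSE)
  n <- round(cfg$fs * cfg$duration)
  dat <- matrix(NA_real_, length(labels), n)
  .with_seed(cfg$seed, {
    ch_cfg <- cfg
    ch_cfg$seed <- NULL  # draws flow from the one outer stream
    for (i in seq_along(labels)) {
      region <- .region_of(labels[i], region_map)
      w <- cfg$band_weights
      mod <- cfg$region_modifiers[[region]]
      if (!is.null(mod)) w[names(mod)] <- w[names(mod)] * mod
      dat[i, ] <- add_artifacts(gen_background(ch_cfg, band_weights = w), ch_cfg)
    }
  })
  eeg_recording(dat, cfg$fs, labels)
}

#' Wavelet-structured test signal with known generating basis
#'
#' Draws a sparse random coefficient vector in the given wavelet's basis
#' (default 5% of coefficients nonzero, standard normal), reconstructs it,
#' and adds white Gaussian noise at the requested SNR. The generating wavelet
#' is then the ground-truth optimum for denoising-based recovery experiments.
#'
#' @param w `wavelet_spec` or name.
#' @param snr_db signal-to-noise ratio in dB (`Inf` for no noise).
#' @param length_out signal length; must be divisible by `2^levels`.
#' @param levels decomposition levels of the generating basis.
#' @param sparsity fraction of nonzero coefficients.
#' @param seed integer seed or `NULL`.
#' @return numeric vector with attribute `"clean"` holding the noiseless
#'   signal.
#' @export
gen_wavelet_structured <- function(w, snr_db = 10, length_out = 256L,
                                   levels = 5L, sparsity = 0.05, seed = NULL) {
  w <- .as_wavelet(w)
  d <- wavedec(numeric(length_out), w, levels, mode = "periodic")
  .with_seed(seed, {
    sparse_fill <- function(v) {
      nz <- stats::runif(length(v)) < sparsity
      v[nz] <- stats::rnorm(sum(nz))
      v
    }
    d$details <- lapply(d$details, sparse_fill)
    d$approx <- sparse_fill(d$approx)
    clean <- waverec(d)
    if (sum(clean^2) == 0 || !is.finite(snr_db)) {
      out <- clean
    } else {
      sd_noise <- sqrt(mean(clean^2)) / 10^(snr_db / 20)
      out <- clean + stats::rnorm(length_out, sd = sd_noise)
    }
    attr(out, "clean") <- clean
    out
  })
}
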