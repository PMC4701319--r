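#' Soft thresholding
#'
#' Shrinks each value toward zero by `t` and zeroes values of magnitude below
#' `t`: `y = sign(x) * max(|x| - t, 0)`.
#'
#' @param x numeric vector.
#' @param t nonnegative threshold.
#' @return numeric vector of the same length.
#' @export
soft_threshold <- function(x, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("parameter error: threshold must be a single nonnegative number")
  }
  sign(x) * pmax(abs(x) - t, 0)
}

#' Robust noise-scale estimate from detail coefficients
#'
#' The usual median-absolute-value estimator of the noise standard deviation
#' at one decomposition level: `sigma = median(|d|) / 0.6745`, the consistency
#' constant making it unbiased for Gaussian noise.
#'
#' @param detail numeric vector of detail coefficients.
#' @return nonnegative scalar estimate of the noise standard deviation.
#' @export
estimate_sigma <- function(detail) {
  if (length(detail) == 0L) stop("parameter error: empty coefficient vector")
  stats::median(abs(detail)) / 0.6745
}

# SURE objective for soft thresholding at threshold t, on standardized
# coefficients z = c / sigma: n - 2 #{|z| <= t} + sum(min(z, t)^2)
.sure_risk <- function(z, t) {
  length(z) - 2 * sum(abs(z) <= t) + sum(pmin(abs(z), t)^2)
}

#' SURE (rigrsure) threshold for one coefficient level
#'
#' Minimizes Stein's unbiased estimate of the soft-thresholding risk over the
#' candidate thresholds `{|c_i| / sigma}`, evaluated exhaustively via sorting,
#' and returns the minimizer rescaled by `sigma`. With `rule = "hybrid"` the
#' heuristic variant is used: when the standardized energy is too sparse for
#' SURE to be reliable the universal threshold `sigma * sqrt(2 log n)` is
#' taken, otherwise the smaller of the two.
#'
#' @param coeffs numeric vector of coefficients at one level.
#' @param sigma positive noise scale (see [estimate_sigma()]).
#' @param rule `"sure"` (pure rigrsure, default) or `"hybrid"`.
#' @return nonnegative threshold in coefficient units, never exceeding
#'   `max(|coeffs|)`.
#' @export
sure_threshold <- function(coeffs, sigma, rule = c("sure", "hybrid")) {
  rule <- match.arg(rule)
  n <- length(coeffs)
  if (n == 0L) stop("parameter error: empty coefficient vector")
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0) {
    stop("parameter error: sigma must be positive")
  }
  z2 <- sort((coeffs / sigma)^2)
  # risk at candidate t = sqrt(z2[k]); ties handled via the true count <= t
  cnt <- findInterval(z2, z2)
  risk <- n - 2 * cnt + cumsum(z2) + (n - seq_len(n)) * z2
  t_sure <- sigma * sqrt(z2[which.min(risk)])
  if (rule == "sure") return(t_sure)
  t_univ <- sigma * sqrt(2 * log(n))
  eta <- (sum(z2) - n) / n
  crit <- (log2(n))^1.5 / sqrt(n)
  if (eta < crit) t_univ else min(t_sure, t_univ)
}

#' Wavelet denoising of one epoch
#'
#' Decomposes the epoch ([wavedec()]), estimates a noise scale and a SURE
#' soft threshold independently at every detail level (level-dependent
#' thresholding), shrinks the detail coefficients, leaves the approximation
#' coefficients untouched, and reconstructs ([waverec()]). The output has the
#' same length as the input.
#'
#' @param epoch numeric vector (one epoch of one channel).
#' @param w a `wavelet_spec` or wavelet name.
#' @param levels number of decomposition levels (default 5).
#' @param mode boundary extension (see [dwt_level()]).
#' @param rule threshold rule (see [sure_threshold()]).
#' @param zero_d1 if `TRUE`, the finest detail level (D1, dominated by
#'   muscle/high-frequency noise at 256 Hz) is zeroed outright instead of
#'   merely thresholded. Default `FALSE` (threshold only).
#' @param report if `TRUE`, return `list(signal, report)` where `report` is a
#'   per-level data.frame of noise scales and thresholds.
#' @return denoised numeric vector, or a list when `report = TRUE`.
#' @export
denoise_epoch <- function(epoch, w, levels = 5L,
                          mode = c("symmetric", "periodic"),
                          rule = c("sure", "hybrid"),
                          zero_d1 = FALSE, report = FALSE) {
  rule <- match.arg(rule)
  d <- wavedec(epoch, w, levels, mode)
  sig <- thr <- numeric(d$levels)
  for (k in seq_len(d$levels)) {
    ck <- d$details[[k]]
    s <- estimate_sigma(ck)
    t <- if (s > 0) sure_threshold(ck, s, rule) else 0
    d$details[[k]] <- soft_threshold(ck, t)
    sig[k] <- s
    thr[k] <- t
  }
  if (zero_d1) d$details[[1L]] <- numeric(length(d$details[[1L]]))
  y <- waverec(d)
  if (!report) return(y)
  list(
    signal = y,
    report = data.frame(
      level = seq_len(d$levels), sigma = sig, threshold = thr,
      rule = rule, stringsAsFactors = FALSE
    )
  )
}
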