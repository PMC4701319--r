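# shared fixtures, built in code at test time

std_labels <- function() unlist(default_region_map(), use.names = FALSE)

# small multichannel recording of white noise with the standard 10-20 labels
noise_recording <- function(seconds = 2, fs = 256, seed = 1) {
  set.seed(seed)
  eeg_recording(matrix(rnorm(19 * fs * seconds), 19), fs, std_labels())
}

# single-channel recording holding one sinusoid
tone_recording <- function(freq, seconds = 10, fs = 256, amp = 1) {
  t <- seq(0, seconds - 1 / fs, by = 1 / fs)
  eeg_recording(matrix(amp * sin(2 * pi * freq * t), 1), fs, "Cz")
}

rms <- function(x) sqrt(mean(x^2))

# independent brute-force SURE risk minimizer (definitional form)
brute_force_sure <- function(coeffs, sigma) {
  z <- coeffs / sigma
  cand <- abs(z)
  risk <- vapply(cand, function(t) {
    length(z) - 2 * sum(abs(z) <= t) + sum(pmin(abs(z), t)^2)
  }, 1)
  sigma * cand[which.min(risk)]
}
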