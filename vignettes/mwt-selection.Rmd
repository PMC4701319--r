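---
title: "Selecting a mother wavelet for multichannel EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting a mother wavelet for multichannel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package answers

Wavelet processing of EEG — artifact denoising, dyadic decomposition,
sub-band feature extraction — starts from a choice of mother wavelet, and the
choice matters: a basis aligned with the signal's morphology concentrates the
cortical activity into few large coefficients, while a mismatched basis
smears it into many small ones that a denoising threshold will destroy.
`mwtselect` operationalizes this as a selection criterion. For each candidate
basis `w` and each one-second epoch `X` of the band-limited recording, it
computes the SURE soft-threshold denoised epoch `Y = denoise(X, w)` and the
Pearson cross-correlation `XCorr(X, Y)`. Candidates whose denoising preserves
the epoch best (after pooling within scalp regions and a one-way ANOVA with
Duncan's post-hoc ranking) are selected per region.

The candidate bank holds the 45 orthogonal wavelets Daubechies db1–db20,
Symlets sym1–sym20 and Coiflets coif1–coif5. Orthogonality is required: it
makes the DWT energy-preserving, so thresholding in the coefficient domain
has a direct signal-domain interpretation, and perfect reconstruction is
exact. Symlets conventionally start at order 2; `sym1` is aliased to the Haar
wavelet (`db1`) so that the bank counts exactly 45 members. Non-orthogonal
families (Morlet, Mexican hat, Meyer) are out of scope by the same argument.

## Filter-bank conventions

The transform is the Mallat two-channel filter bank. One fixed convention is
used throughout: the high-pass analysis filter is the alternating-sign
time-reversed scaling filter `g[n] = (-1)^n h[f-1-n]`; analysis is
correlation (`a_k = Σ_m h[m] x[2k+m]`) and synthesis convolution, so the
synthesis taps equal the analysis taps. Scaling-filter coefficients are taken
from the standard published tables for these families (shipped as plain text
in `inst/extdata/scaling_filters.csv`) and validated at load time against the
defining invariants: `Σh = √2`, unit norm, orthogonality to even shifts, and
`Σg = 0`.

Two boundary rules are provided because they serve different purposes:

* **symmetric** (default) — half-point reflection, the natural choice for
  denoising short epochs since it avoids the wrap-around discontinuity that
  periodic extension creates at epoch edges. Coefficient vectors carry
  `floor((n + f - 1)/2)` values per level and reconstruction is exact.
* **periodic** — indices wrap modulo the (even) signal length. The transform
  matrix is then orthonormal for any even length (the filters alias modulo
  n), which gives exact Parseval energy bookkeeping; tests of energy
  properties use this mode. It requires the length be divisible by
  `2^levels`.

The source recordings' epochs (256 samples at 256 Hz, five levels) satisfy
both modes. Perfect reconstruction holds below `1e-8` (observed ~`1e-10`)
for all 45 wavelets in both modes; with periodic extension coefficient energy
matches signal energy to ~`1e-11` relative.

Five levels at 256 Hz align the components with the clinical bands —
D1 64–128 Hz (higher gamma and broadband noise), D2 32–64 Hz (lower gamma),
D3 beta, D4 alpha, D5 theta, A5 delta — see `dyadic_band_map(256, 5)`.
"Gamma" in this package always means lower gamma (32–64 Hz): content above
64 Hz is outside the band-pass of interest and is carried by D1 only.

## Denoising: level-dependent SURE soft thresholding

Each epoch is decomposed to five levels; each detail level is thresholded
independently and the approximation is left untouched:

1. noise scale per level: `σ_k = median(|cD_k|) / 0.6745` (MAD estimator);
2. threshold per level: the minimizer of Stein's unbiased risk estimate
   `SURE(t) = n − 2·#{|c|/σ ≤ t} + Σ min(|c|/σ, t)²` over the candidate set
   `{|c_i|/σ}`, evaluated exhaustively after sorting (`O(n log n)`), rescaled
   by `σ_k` ("rigrsure");
3. soft shrinkage `y = sign(c)·max(|c| − t, 0)`.

A `rule = "hybrid"` variant falls back to the universal threshold
`σ√(2 log n)` when the standardized energy of a level is too sparse for SURE
to be reliable. A `zero_d1` flag additionally zeroes the finest detail level,
for users who prefer to treat the 64–128 Hz band as pure noise; the default
thresholds it like any other level, since muscle bursts are intermittent and
the band may carry signal.

Two design points deserve emphasis:

* **Per-level σ is load-bearing for selection.** Because σ_k is estimated
  from the same level it thresholds, a basis that fails to concentrate the
  signal sees its signal-bearing coefficients sit near the level's MAD floor
  and lose energy, while a matched basis lifts them far above it. Estimating
  σ once from the finest level (the common `sln` convention) would make
  thresholds tiny at deep levels and all 45 candidates nearly equivalent.
* **Narrowband signals are the known hard case.** A pure tone dominates the
  coefficients of its own level, so the level MAD *is* the tone's scale and
  SURE shrinks it substantially. This is inherent to level-dependent
  thresholding, not a defect of the implementation; the method is intended
  for broadband, sparsely-representable activity, and the improvement tests
  therefore use sparse broadband ground truth rather than tones. Similarly,
  soft thresholding shrinks even well-separated spikes by the threshold, so
  retained spike energy is `(1 − t/|c|)²` of the original — support is
  preserved exactly, amplitude is biased low.

Energy never grows under denoising in periodic mode (orthonormality plus
shrinkage); the scoring loop uses a compiled implementation asserted equal to
the R reference to `1e-10`.

## Scoring and regional inference

`XCorr` is the standard Pearson product-moment correlation (the covariance
sum divided by the *square root* of the product of centered sums of squares —
without the root the quantity would not be scale-invariant). Constant epochs
make it undefined; `score_all()` excludes such records and logs the count.
`X` is the band-limited epoch (after the 50 Hz notch and 0.5–64 Hz band-pass),
not the raw epoch, so line noise and drift do not enter the score.

Scores are pooled over channels × epochs within each region (frontal 7,
temporal 4, parietal 3, occipital 2, central 3 channels of the 10–20 montage)
and compared across the 45 wavelet groups by one-way ANOVA per region — the
default inference — with a two-way (region × wavelet) ANOVA available as a
diagnostic (`anova_twoway`, Type II sums of squares; for the balanced layouts
produced here the types coincide). Kolmogorov–Smirnov normality and Levene
homoscedasticity checks are provided for the assumption audit.

Duncan's multiple range test ranks the group means: for a stretch of `p`
ordered means the critical range is `R_p = q(1−α_p; p, df)·√(MSE/n_h)` with
protected level `α_p = 1 − (1−α)^(p−1)`, harmonic-mean group size `n_h`, and
studentized-range quantiles computed numerically (`stats::qtukey`, with a
bisection fallback on `ptukey` where its root finder fails to converge —
validated against the published tables at α = 0.05, df 10 and 20). Stretches
below their critical range, or contained in such a stretch, are homogeneous;
letters mark the maximal homogeneous stretches. The report's "equivalent"
set — candidates sharing a letter with the winner — captures the practical
outcome that several Symlets of neighboring order are often
indistinguishable. Ties in mean score are broken lexicographically by name.

## Relative band power

Band power is the sum of squares of each *reconstructed* MRA component
(not the raw coefficients), so that MRA additivity anchors the components to
the signal; under periodic extension the two conventions agree to numerical
tolerance for orthogonal wavelets, which is asserted as a cross-check in the
tests. D1 is excluded from the denominator: relative power is the share of
the 0–64 Hz total, and each row of an RP table sums to 100 by construction.
With a region map, channel percentages are averaged per region by default;
`pooled = TRUE` instead sums the region's band powers before normalizing.
Whether per-channel averaging or pooling better mirrors published regional
profiles is not decidable from first principles; averaging weights channels
equally and is the default.

## The synthetic generator

Real EEG with a known optimal basis does not exist, so validation rests on
two generators:

* `gen_recording()` — a 19-channel, 256 Hz surrogate: per band
  (delta…gamma), Gaussian noise masked to the band in the frequency domain
  with a `1/f` amplitude taper, scaled to microvolt RMS weights
  (delta-dominant by default, occipital alpha and frontal delta boosted by
  region modifiers); plus high-amplitude raised-cosine ocular transients
  (0.5–1 s, so their energy lies below 4 Hz), 64–128 Hz muscle bursts, and a
  50 Hz line. Amplitudes are on the few-to-100 µV scale of scalp EEG. All
  randomness flows from one seed; outputs are bit-identical under a fixed
  seed.
* `gen_wavelet_structured()` — ground truth for recovery experiments: a
  sparse random coefficient vector (5% nonzero) in a chosen wavelet's basis,
  reconstructed and corrupted with white noise at a set SNR. The generating
  wavelet is then the known-correct answer.

What the generator does *not* emulate: volume conduction and inter-channel
correlation, cardiac artifacts, non-stationarity across the recording, and
real cortical waveform morphology. Passing tests therefore demonstrate that
the pipeline recovers a planted sparse structure and calibrates its
statistics — not that any particular wavelet is optimal for human EEG.

## Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` compute, among others:

* perfect reconstruction and Parseval over all 45 wavelets on 256-sample
  epochs (tolerances `1e-8`);
* SURE thresholds equal to an exhaustive risk minimizer on hundreds of
  random instances of size ≤ 64;
* Duncan subsets on a four-group fixture against critical ranges from the
  published studentized-range tables, and `F = t²` agreement of the ANOVA
  with the two-group t-test;
* type-I calibration: with 45 equal groups, ANOVA rejects in ≤ 10% of 100
  seeded runs and Duncan isolates the top mean in ≤ 15%;
* the recovery experiment: 20 seeded runs of 19 channels × 10 epochs of
  sym9-structured signal at 10 dB SNR, scored against the full bank; the
  generating wavelet must rank in the top 3 of the mean ordering in ≥ 80% of
  runs (observed: rank 1 in 20/20).

These sizes (10-epoch channels for recovery, 60 s recordings for the
pipeline run) were chosen as the smallest at which the regional pools retain
their designed structure (e.g. 420 frontal values per wavelet at full
length); the statistics scale with, but do not depend on, the recording
length.

## Known limitations

* Selection is only as good as the XCorr criterion: it rewards bases whose
  thresholded representation preserves the *band-limited input*, which
  includes any residual in-band artifact.
* Narrowband-dominated epochs interact poorly with per-level noise
  estimation (above).
* The EDF reader/writer is minimal (continuous 16-bit records, one sampling
  rate): sufficient for round-tripping this package's outputs and standard
  continuous EDF, not a general EDF+ implementation.
* High gamma (> 64 Hz) is never analyzed; it lives in D1 together with
  muscle noise at this sampling rate.
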