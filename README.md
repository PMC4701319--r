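# mwtselect

Mother-wavelet selection and sub-band analysis for multichannel EEG.

## The problem

Wavelet denoising and decomposition of EEG requires choosing a mother wavelet
(MWT), and no single basis suits all channels, tasks, or scalp sites. This
package implements a data-driven selection pipeline for 10–20 multichannel
recordings: every candidate basis from a 45-member orthogonal bank —
Daubechies db1–db20, Symlets sym1–sym20, Coiflets coif1–coif5 — is used to
denoise each one-second epoch of the band-limited signal by level-dependent
SURE soft thresholding, and candidates are scored by how well the denoised
epoch Y preserves the band-limited epoch X, via the normalized
cross-correlation

    XCorr(X, Y) = Σ (X − X̄)(Y − Ȳ) / sqrt( Σ (X − X̄)² · Σ (Y − Ȳ)² )

A basis that represents the underlying cortical signal compactly concentrates
it into few large coefficients that survive thresholding (high XCorr); a
mismatched basis spreads it across many small coefficients that thresholding
destroys (low XCorr). Scores are pooled over the channels of five scalp
regions (frontal, temporal, parietal, occipital, central), compared by
one-way ANOVA, and ranked with Duncan's multiple range test, yielding a
winner per region together with the set of candidates statistically
indistinguishable from it.

The package also provides the surrounding machinery as reusable pieces: an
orthogonal filter-bank DWT/IDWT with multiresolution (MRA) reconstruction and
exact perfect-reconstruction/Parseval behavior, 50 Hz notch and 0.5–64 Hz
zero-phase band-pass preprocessing, the dyadic EEG band map at 256 Hz
(D2 = lower gamma 32–64 Hz, D3 = beta, D4 = alpha, D5 = theta, A5 = delta;
D1 = 64–128 Hz noise band), relative band power

    RP(%) = 100 · P(band) / P(0.5–64 Hz)

a seeded synthetic-EEG generator (1/f band-weighted background, ocular and
muscle artifacts, mains line) for end-to-end validation without patient data,
EDF and CSV+YAML I/O, and a command-line pipeline.

## Worked example

```r
library(mwtselect)

rec <- gen_recording(synth_config(duration = 10, seed = 42))
fit <- mwt_select(rec)     # notch + band-pass, epoch, denoise, score, rank
print(fit)
```

```
Mother-wavelet selection by region (alpha = 0.05 )
  frontal    winner sym9   mean xcorr 0.9709 (not separable from: sym5, sym7, sym6)
  temporal   winner sym9   mean xcorr 0.9594 (not separable from: sym6, coif2, sym10, sym7, sym8, sym5)
  parietal   winner sym9   mean xcorr 0.9605 (not separable from: sym5, sym7, sym8, sym6, sym10, coif2, coif3, sym11, sym13, sym4)
  occipital  winner sym9   mean xcorr 0.9280 (not separable from: sym5, sym7, coif2, sym6, sym8)
  central    winner sym9   mean xcorr 0.9567 (not separable from: coif2, sym6, sym7, sym5, coif3)
```

Each line gives the region's top-ranked wavelet, its mean epoch-level XCorr
across the region's channels, and the Duncan homogeneous subset around the
winner. `summary(fit)` adds the per-region ANOVA and ranking table with
Duncan letters; `coef(fit)` returns the winner's mean score per region;
`plot(fit)` draws the 45-wavelet mean-score profile per region.

Sub-band relative power after denoising with the selected basis:

```r
relative_power_table(rec, "sym9", region_map = default_region_map())
```

```
     region delta theta alpha  beta  gamma
1   central  74.6 10.11 14.75 0.481 0.0250
2   frontal  84.4  7.24  8.14 0.240 0.0127
3 occipital  50.3 11.10 37.24 1.343 0.0168
4  parietal  78.9  8.60 12.00 0.440 0.0187
5  temporal  69.6 11.89 17.77 0.695 0.0141
```

Rows sum to 100%; the generator's boosted occipital alpha shows up directly
in the occipital alpha share.

A shell pipeline wraps the same functions:

```sh
Rscript inst/cli/mwtselect.R simulate --seed 1 --out run1
Rscript inst/cli/mwtselect.R select --input run1/recording.csv --out run1
```

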