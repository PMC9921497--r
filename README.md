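# cissadwt

Removal of ocular (eye-blink / EOG) artifacts from **single-channel EEG**
recordings by circulant singular spectrum analysis (CiSSA) combined with
discrete-wavelet filtering, for anyone preprocessing portable or
few-channel EEG where ICA-style multichannel decompositions are not an
option: BCI pipelines, sleep and cognitive-load studies, ERP cleanup.

## Method

Blinks are high-amplitude, low-frequency (≲ 12 Hz) transients riding on
the EEG. The pipeline:

1. **CiSSA decomposition.** Each 10 s frame `s(1), …, s(t)` is embedded
   into an `L × S` Hankel trajectory matrix (`S = t − L + 1`, default
   `L = 18`). The circulant second-moment matrix with entries
   `M_n = ((L−n)/L)·γ̂(n) + (n/L)·γ̂(L−n)` (biased autocovariances `γ̂`)
   has Fourier eigenvectors `u_b = L^{−1/2}(1, e^{−i2πf_b}, …,
   e^{−i2πf_b(L−1)})`, `f_b = (b−1)/L`, so each eigenvector is pinned to
   a frequency. Conjugate pairs `{b, L+2−b}` are grouped into real rank-2
   projectors; projecting the trajectory matrix and diagonal-averaging
   (hankelizing) yields `G = L/2 + 1` frequency-ordered components
   ("IMFs") that sum to the input exactly — 10 components at `L = 18`.
2. **Blink identification.** Each component is scored by kurtosis
   `K = m₄/m₂²` and energy `E = Σ s(i)²`. Components exceeding *both*
   thresholds (default: mean + 1 SD of each score across components) are
   flagged as EOG-related; if none passes, the lowest-frequency component
   is flagged with a warning.
3. **Wavelet filtering.** The flagged-component sum is decomposed with a
   4-level `db4` Mallat cascade; the level-4 approximation (≈ 0–`fs`/32
   Hz, the blink band) is zeroed and the inverse transform keeps the
   residual EEG detail.
4. **Reconstruction.** Clean EEG `q̂` = unflagged components + detail
   residual; artifact `k̂` = removed approximation band. By linearity
   `q̂ + k̂ = s` exactly.

Evaluation metrics (for the mixing model `s = q + p·k`):
RRMSE `= RMS(k − k̂)/RMS(k)·100`, Pearson CC `(k, k̂)`,
SAR `= 10·log₁₀(σ(k)/σ(k̂ − k))` (real-data form
`10·log₁₀(σ(s)/σ(q̂ − s))`), and alpha-band (8–13 Hz) MAE between Welch
spectra of `s` and `q̂`.

A parametric generator supplies ground-truth validation data: pink-noise
EEG with a pronounced 10 Hz alpha resonance, and squared-half-sine blink
pulses (~0.35 s, every ~5 s).

## Worked example

```r
library(cissadwt)
q <- gen_eeg(2500, fs = 250, seed = 42)   # ground-truth EEG, 10 s
k <- gen_eog(2500, fs = 250, seed = 43)   # synthetic blink train
mix <- mix_signals(q, k, p = 1)           # contaminated recording

fit <- eog_clean(mix$s, fs = 250)
print(fit)
#> EOG artifact removal (circulant SSA + wavelet filter)
#>   2500 samples at 250 Hz, 1 segment(s) of ~10 s
#>   L = 18, db4, 4 levels, thresholds kt = auto, et = auto
#>   artifact variance removed: 2.2 (66.3% of input)

artifact_metrics(mix$s, fitted(fit), fs = 250, k = k, k_hat = residuals(fit))
#> Artifact-removal metrics (ground-truth mode)
#>   RRMSE:  29.4703 %
#>   CC:      0.9794
#>   SAR:     6.8600 dB
#>   MAE:    0.00552 over 8-13 Hz [welch(nperseg=256, overlap=0.5, hann)]
```

The blink estimate correlates at 0.98 with the injected artifact; the
alpha-band spectrum is nearly untouched (MAE ≈ 0.006 against a band
power two orders larger). `fitted()` returns the cleaned EEG,
`residuals()` the artifact estimate, and `summary()`/`plot()` show
per-segment diagnostics. `cissa()` exposes the bare decomposition,
`dwt()`/`idwt()` the wavelet layer, and `read_signal()`/`write_signal()`
handle delimited text and EDF files.

A command-line wrapper with `clean`, `decompose`, `metrics` and
`simulate` subcommands is installed at
`system.file("cli", "cissadwt", package = "cissadwt")`.

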