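# tendos — noise-robust T-wave end annotation for ECG

`tendos` automatically annotates the **T-wave end** (T offset, the endpoint
of the QT interval) in single-channel ECG recordings, and keeps the
annotation stable when the signal is noisy — the regime where classical
delineators fall apart. It is aimed at people processing long-term
ambulatory ECG (Holter / patch recordings) and at methodologists evaluating
T-end delineators under controlled noise.

## Method

Two ideas, combined:

**tSQI — a T-end signal quality index.** Run two independent T-end
delineators on the same cardiac cycles. With *A* cycles carrying both
estimates and *B* of them agreeing to within a grace period γ (strictly
|t₁ − t₂| < γ, default 50 ms),

    tSQI = B / (2A − B)  ∈ [0, 1].

Computed per cycle on a ±5 s neighbourhood, tSQI tracks *T-wave* quality
specifically — R-peak agreement indices (bSQI, also included) cannot see a
corrupted T wave behind clean QRS complexes.

**Optimal-shrinkage (OS) denoising, gated by tSQI.** Cycles with
tSQI < q (default 0.9) are denoised: the cycle's fixed-length template is
stacked with its ξ = 19 most similar neighbours into a p × 20 matrix,
whose singular values λᵢ — normalised by σ√m — pass through the
operator-norm optimal shrinker for the low-rank-plus-noise (spike) model:

    η*(y) = sqrt( (y² − β − 1 + sqrt((y² − β − 1)² − 4β)) / 2 )   for y ≥ 1 + √β,
    η*(y) = 0 otherwise,

with β the matrix aspect ratio and σ the library noise level (RMS deviation
from the per-coordinate median template). The base delineator then runs on
the denoised template. Clean cycles are left untouched — on clean signal
the "noise" is physiological beat-to-beat variation and OS would distort
the morphology; the gate is what makes the combination safe.

Three classical delineators are implemented and interchangeable: the
area-function method (`zhang`), the trapezium-area method (`carlos`) and a
dyadic-wavelet method (`martinez`, structural reimplementation). The tSQI
pair defaults to `zhang` + `martinez`.

Everything is testable offline: the package ships a synthetic ECG generator
with ground-truth fiducials, white-Gaussian and heavy-tailed ARMA(1,1)
noise models with exact SNR scaling, and the evaluation metrics (mean
absolute error summaries, paired signed-rank test).

## Worked example

```r
library(tendos)

# 60 s synthetic ECG at 250 Hz with known T-ends, drowned in ARMA(1,1)
# noise at 5 dB SNR
gen   <- gen_synth_ecg(synth_ecg_spec(duration_s = 60, seed = 42))
z     <- gen$record$samples[, 1]
noisy <- ecg_record(as.numeric(
           scale_to_snr(z, gen_arma11(length(z), noise_spec("arma11", seed = 3)), 5)),
         fs = 250)

res <- annotate_record(noisy, pipeline_config(), rpeaks = gen$rpeaks)
res
#> <pipeline_result> 59 cycles, 52 denoised (q=0.9), median tSQI 0.385, sigma=0.08681 mV

truth   <- gen$tends[seq_len(res$rpeaks$n)]
err_raw <- detection_errors(res$tends_raw, truth)   # delineator alone (q = 0)
err_os  <- detection_errors(res$tends,     truth)   # tSQI-gated OS pipeline
round(c(me_raw = mean(abs(err_raw)), me_os = mean(abs(err_os))), 2)
#> me_raw  me_os
#>  68.98  12.62
```

At 5 dB the noise drags the median per-cycle tSQI to 0.39, so 52 of 59
cycles are denoised; the mean absolute T-end error drops from ~69 ms to
~13 ms. On a clean record the same call leaves every cycle alone
(tSQI ≈ 1) and reproduces the plain delineator exactly — that bypass is
part of the test suite.

`vignette("tend-annotation")` documents the model, every tunable parameter,
and the design decisions.

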