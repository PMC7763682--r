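Package: tendos
Title: Noise-Robust T-Wave End Annotation for Single-Channel ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automatic annotation of the T-wave end (T offset) in ECG
    recordings, stabilized against noise. Implements a T-end signal quality
    index (tSQI) built from the agreement of two independent T-end
    delineators, and a per-cycle denoiser based on singular-value optimal
    shrinkage that is applied only to cardiac cycles whose tSQI falls below
    a threshold. Includes three classical T-end delineators (area-function,
    trapezium-area, and wavelet-based), a minimal WFDB and CSV reader and
    writer, Gaussian and ARMA(1,1) noise simulators with SNR scaling, a
    synthetic ECG generator with ground-truth fiducials, and the evaluation
    metrics (mean absolute detection error summaries and paired signed-rank
    testing) used to validate the method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
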