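# Shared fixtures, built in code.

# Small clean synthetic record with ground truth (memoised per seed/duration
# so several test files can reuse the same generation).
.fixture_env <- new.env(parent = emptyenv())

synth_fixture <- function(duration_s = 60, seed = 42, ...) {
  key <- paste(duration_s, seed, ...)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- gen_synth_ecg(
      synth_ecg_spec(duration_s = duration_s, seed = seed, ...))
  }
  .fixture_env[[key]]
}

# Preprocessed record + loaded R peaks for a fixture.
prepped_fixture <- function(duration_s = 60, seed = 42, ...) {
  key <- paste("prep", duration_s, seed, ...)
  if (is.null(.fixture_env[[key]])) {
    gen <- synth_fixture(duration_s, seed, ...)
    pre <- preprocess_ecg(gen$record)
    rp <- load_rpeaks(gen$rpeaks, pre)
    .fixture_env[[key]] <- list(gen = gen, pre = pre, rp = rp)
  }
  .fixture_env[[key]]
}

# Mean of |signed errors| in ms between a tend_annotation and truth indices.
mean_abs_err_ms <- function(ann, truth_idx, fs = 250) {
  e <- detection_errors(ann, truth_idx, fs = fs)
  mean(abs(e))
}
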