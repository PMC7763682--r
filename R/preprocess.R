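# Step 0: baseline-wander and powerline-interference removal.
#
# Baseline wander is estimated by a low-order Butterworth lowpass (cutoff
# `loff`, default 0.5 Hz) and subtracted from the signal, which preserves the
# QRS/T morphology while removing the drift. Powerline interference is
# removed by narrow second-order IIR notches at 50 and 60 Hz. Both filters
# are applied forward-backward (zero-phase): any phase distortion would shift
# the very T-end locations under study.

#' Preprocessing configuration
#'
#' @param loff Lowpass cutoff (Hz) of the baseline estimator. Default 0.5 Hz.
#' @param butter_order Butterworth order of the baseline estimator. Default 4.
#' @param notch_freqs Powerline notch centres in Hz. Default `c(50, 60)` so
#'   recordings of unknown origin are covered.
#' @param notch_q Notch quality factor (centre frequency / -3 dB bandwidth).
#'   Default 30, i.e. a 50 Hz notch about 1.7 Hz wide, leaving the T-wave
#'   band (< 10 Hz) untouched.
#' @param internal_fs Internal analysis sampling rate in Hz. Default 250.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(loff = 0.5, butter_order = 4L,
                              notch_freqs = c(50, 60), notch_q = 30,
                              internal_fs = 250) {
  stopifnot(loff > 0, loff < internal_fs / 2, butter_order >= 1,
            all(notch_freqs > 0), notch_q > 0, internal_fs > 0)
  structure(list(loff = loff, butter_order = as.integer(butter_order),
                 notch_freqs = notch_freqs, notch_q = notch_q,
                 internal_fs = internal_fs),
            class = "preprocess_config")
}

check_preprocess_input <- function(rec, cfg) {
  stopifnot(inherits(rec, "ecg_record"))
  if (!isTRUE(all.equal(rec$fs, cfg$internal_fs)))
    stop_tendos("bad_fs", sprintf(
      "record is at %g Hz; resample to the internal rate %g Hz first",
      rec$fs, cfg$internal_fs))
  warmup <- 3 * rec$fs / cfg$loff
  if (rec$n_samples < warmup)
    stop_tendos("too_short", sprintf(
      "record too short for baseline filter warm-up (need >= %d samples)",
      ceiling(warmup)))
}

#' Remove baseline wander
#'
#' Subtracts the low-frequency (<= `loff`) component, estimated by a
#' zero-phase Butterworth lowpass, from every channel.
#'
#' @param rec An [ecg_record()] at `cfg$internal_fs`.
#' @param cfg A [preprocess_config()].
#' @return The detrended [ecg_record()].
#' @export
remove_baseline <- function(rec, cfg = preprocess_config()) {
  check_preprocess_input(rec, cfg)
  bw <- signal::butter(cfg$butter_order, cfg$loff / (rec$fs / 2), type = "low")
  npad <- min(rec$n_samples - 1L, as.integer(round(3 * rec$fs / cfg$loff)))
  out <- apply(rec$samples, 2L, function(x) {
    x - zerophase_filter(bw$b, bw$a, x, npad = npad)
  })
  rec$samples <- as.matrix(out)
  rec
}

# RBJ-cookbook second-order IIR notch at f0 Hz with quality factor q.
notch_coefs <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1L], a = a / a[1L])
}

#' Remove powerline interference
#'
#' Applies a zero-phase second-order notch at each configured centre
#' frequency (those at or above Nyquist are skipped).
#'
#' @inheritParams remove_baseline
#' @return The filtered [ecg_record()].
#' @export
remove_powerline <- function(rec, cfg = preprocess_config()) {
  check_preprocess_input(rec, cfg)
  freqs <- cfg$notch_freqs[cfg$notch_freqs < rec$fs / 2 * 0.999]
  npad <- min(rec$n_samples - 1L, as.integer(3 * rec$fs))
  out <- rec$samples
  for (f0 in freqs) {
    nc <- notch_coefs(f0, rec$fs, cfg$notch_q)
    out <- apply(out, 2L, function(x) zerophase_filter(nc$b, nc$a, x, npad = npad))
    out <- as.matrix(out)
  }
  rec$samples <- out
  rec
}

#' Full preprocessing step
#'
#' Baseline removal followed by powerline notching, at the internal analysis
#' rate. Records at another rate are resampled first.
#'
#' @inheritParams remove_baseline
#' @return The preprocessed [ecg_record()].
#' @export
preprocess_ecg <- function(rec, cfg = preprocess_config()) {
  if (!isTRUE(all.equal(rec$fs, cfg$internal_fs)))
    rec <- resample_record(rec, cfg$internal_fs)
  remove_powerline(remove_baseline(rec, cfg), cfg)
}
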