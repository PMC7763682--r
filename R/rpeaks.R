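# Step 1: the R-peak series, either detected (two-moving-average QRS
# detector in the style of Elgendi) or loaded from provided annotations.

#' Construct an R-peak series
#'
#' @param indices Strictly increasing 1-based sample positions of R peaks.
#' @param fs Sampling rate in Hz.
#' @param source Detector name or `"manual"`.
#' @return An object of class `rpeak_series` with fields `indices`, `n`,
#'   `fs`, `source`. RR intervals outside the physiological 0.2--3 s range
#'   are flagged in the `suspect` field (logical, per interval).
#' @export
rpeak_series <- function(indices, fs, source = "manual") {
  indices <- as.integer(round(indices))
  if (length(indices) >= 2L && any(diff(indices) <= 0L))
    stop_tendos("non_monotone", "R-peak indices must be strictly increasing")
  rr <- diff(indices) / fs
  structure(list(indices = indices, n = length(indices), fs = as.numeric(fs),
                 source = as.character(source),
                 suspect = rr < 0.2 | rr > 3),
            class = "rpeak_series")
}

#' @export
print.rpeak_series <- function(x, ...) {
  cat(sprintf("<rpeak_series> %d peaks @ %g Hz (source: %s)\n",
              x$n, x$fs, x$source))
  invisible(x)
}

#' Detect R peaks with a two-moving-average QRS detector
#'
#' The signal is band-passed to the QRS band (8--20 Hz), squared, and two
#' moving averages are compared: a short one over the QRS duration (97.5 ms)
#' against a long one over a beat (611 ms) plus an offset proportional to the
#' mean signal energy. Contiguous stretches where the short average exceeds
#' the threshold and that are at least one QRS wide become candidate
#' complexes; each peak is then snapped to the extremum of the original
#' signal within +/- 40 ms. A 200 ms refractory rule keeps the larger of two
#' colliding candidates.
#'
#' @param rec A preprocessed [ecg_record()].
#' @param channel Channel to analyse (default 1).
#' @param qrs_win_s,beat_win_s,offset_frac Detector constants: QRS window,
#'   beat window, and the energy fraction added to the beat average.
#' @return An [rpeak_series()]; empty when the record contains no QRS-like
#'   activity (e.g. a flat signal).
#' @export
detect_rpeaks <- function(rec, channel = 1L, qrs_win_s = 0.0975,
                          beat_win_s = 0.611, offset_frac = 0.08) {
  stopifnot(inherits(rec, "ecg_record"))
  fs <- rec$fs
  if (rec$n_samples < 5 * fs)
    stop_tendos("too_short",
                "record shorter than 5 s: not enough context for the moving averages")
  x <- rec$samples[, channel]
  bp <- signal::butter(3, c(8, 20) / (fs / 2), type = "pass")
  xf <- zerophase_filter(bp$b, bp$a, x, npad = as.integer(fs))
  y <- xf^2
  w1 <- max(1L, as.integer(round(qrs_win_s * fs)))
  w2 <- max(w1 + 1L, as.integer(round(beat_win_s * fs)))
  ma_qrs <- moving_average(y, w1)
  ma_beat <- moving_average(y, w2)
  thr <- ma_beat + offset_frac * mean(y)
  on <- ma_qrs > thr
  if (!any(on)) return(rpeak_series(integer(0), fs, source = "elgendi_style"))
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= w1
  peaks <- integer(0)
  snap <- as.integer(round(0.040 * fs))
  for (j in which(keep)) {
    blk <- starts[j]:ends[j]
    p <- blk[which.max(y[blk])]
    lo <- max(1L, p - snap); hi <- min(rec$n_samples, p + snap)
    p <- (lo:hi)[which.max(abs(x[lo:hi]))]
    peaks <- c(peaks, p)
  }
  # refractory: drop the weaker of any pair closer than 200 ms
  if (length(peaks) >= 2L) {
    refr <- 0.2 * fs
    keep_pk <- rep(TRUE, length(peaks))
    last <- 1L
    for (k in 2L:length(peaks)) {
      if (peaks[k] - peaks[last] < refr) {
        if (abs(x[peaks[k]]) > abs(x[peaks[last]])) {
          keep_pk[last] <- FALSE; last <- k
        } else keep_pk[k] <- FALSE
      } else last <- k
    }
    peaks <- peaks[keep_pk]
  }
  rpeak_series(unique(peaks), fs, source = "elgendi_style")
}

#' Convert a provided annotation series into an R-peak series
#'
#' Used in evaluation mode, where R peaks are taken as known so that T-end
#' performance is isolated from R-peak detection errors. Indices are rescaled
#' from the annotation's sampling rate to the record's and validated against
#' the record bounds.
#'
#' @param ann An [ann_series()] of kind `"rpeak"`, or a bare numeric vector
#'   of 1-based indices already at the record's rate.
#' @param rec The [ecg_record()] the peaks refer to.
#' @return An [rpeak_series()] at `rec$fs`.
#' @export
load_rpeaks <- function(ann, rec) {
  stopifnot(inherits(rec, "ecg_record"))
  if (is.numeric(ann)) ann <- ann_series(ann, kind = "rpeak", fs = rec$fs)
  stopifnot(inherits(ann, "ann_series"))
  if (ann$kind != "rpeak")
    stop_tendos("bad_kind", "annotation series is not of kind 'rpeak'")
  if (length(ann$indices) == 0L)
    stop_tendos("no_rpeaks", "no R peaks in annotation series")
  # 1-based rescale: sample k at fs_a corresponds to time (k-1)/fs_a
  idx <- as.integer(round((ann$indices - 1L) * rec$fs / ann$fs)) + 1L
  if (any(diff(idx) <= 0L))
    stop_tendos("non_monotone", "R-peak series non-monotone after rescaling")
  if (idx[1L] < 1L || idx[length(idx)] > rec$n_samples)
    stop_tendos("out_of_range", "R-peak index outside record bounds")
  rpeak_series(idx, rec$fs, source = ann$source)
}
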