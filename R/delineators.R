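# Step 4 detectors: three interchangeable per-cycle T-end delineators.
#
# * zhang: area-function method. Inside a search window after the R peak,
#   the running area A(t) = sum_{k=t-W+1..t} (z(k) - z(t)) is maximal at the
#   T-end for a monophasic T wave; the maximisation is restricted to samples
#   after the T peak, where that property holds.
# * carlos: trapezium-area method. With the T peak (x_s, y_s) and a fixed
#   reference point (x_m, y_m) past the wave, the area of the trapezium with
#   horizontal parallel sides through y_s and y_r,
#   A(x_r) = (2 x_m - x_s - x_r) (y_s - y_r) / 2, is maximal where the
#   descending limb meets the baseline.
# * martinez: dyadic undecimated wavelet transform (quadratic-spline
#   derivative filters) at scales 16 and 32; the T peak sits at the zero
#   crossing between the dominant opposite-sign modulus-maxima pair, and the
#   T-end where |W| decays below a fraction of the last maximum.
#
# All three operate per cycle inside a search window expressed as fractions
# of the local RR interval, are equivariant under time shifts, and invariant
# under positive amplitude scaling.

#' Delineator configuration
#'
#' @param search_window Start and end of the per-cycle search window, as
#'   fractions of the local RR interval after the R peak. Default
#'   `c(0.15, 0.70)`: past the S wave, before the next P wave.
#' @param zhang_W Sliding-window length of the area function, in ms
#'   (default 128).
#' @param carlos_ref_offset Offset of the fixed reference point after the T
#'   peak, in ms (default 160).
#' @param wavelet_scales Dyadic scales tried in order by the wavelet
#'   delineator (default `c(16, 32)`; the coarser scale is the fallback).
#' @param twave_polarity `"auto"` (per cycle, from the dominant excursion in
#'   the search window), `"positive"` or `"negative"`.
#' @param martinez_frac Fraction of the last modulus maximum below which the
#'   wavelet magnitude must fall to mark the T-end (default 0.25).
#' @return A list of class `delineator_config`.
#' @export
delineator_config <- function(search_window = c(0.15, 0.70), zhang_W = 128,
                              carlos_ref_offset = 160,
                              wavelet_scales = c(16L, 32L),
                              twave_polarity = c("auto", "positive", "negative"),
                              martinez_frac = 0.25) {
  twave_polarity <- match.arg(twave_polarity)
  stopifnot(length(search_window) == 2L, search_window[1L] > 0,
            search_window[1L] < search_window[2L], search_window[2L] < 1,
            zhang_W > 0, carlos_ref_offset > 0, martinez_frac > 0,
            martinez_frac < 1)
  structure(list(search_window = search_window, zhang_W = zhang_W,
                 carlos_ref_offset = carlos_ref_offset,
                 wavelet_scales = as.integer(wavelet_scales),
                 twave_polarity = twave_polarity,
                 martinez_frac = martinez_frac),
            class = "delineator_config")
}

#' Construct a T-end annotation
#'
#' One entry per cardiac cycle, aligned with the R-peak series that produced
#' it; `NA` marks cycles without an estimate (the last cycle has no following
#' R peak and is always `NA`).
#'
#' @param tend_indices Integer sample indices (1-based) or `NA`, one per
#'   cycle.
#' @param detector Detector label (provenance).
#' @param fs Sampling rate in Hz.
#' @return An object of class `tend_annotation`.
#' @export
tend_annotation <- function(tend_indices, detector, fs) {
  structure(list(tend_indices = as.integer(round(tend_indices)),
                 detector = as.character(detector), fs = as.numeric(fs)),
            class = "tend_annotation")
}

#' @export
print.tend_annotation <- function(x, ...) {
  cat(sprintf("<tend_annotation detector=%s> %d cycles (%d with estimate) @ %g Hz\n",
              x$detector, length(x$tend_indices),
              sum(!is.na(x$tend_indices)), x$fs))
  invisible(x)
}

# --- wavelet machinery ------------------------------------------------------

.kernel_cache <- new.env(parent = emptyenv())

upsample_taps <- function(f, by) {
  if (by == 1L) return(f)
  out <- numeric((length(f) - 1L) * by + 1L)
  out[seq(1L, length(out), by = by)] <- f
  out
}

# Equivalent FIR kernel of the undecimated (a trous) quadratic-spline
# derivative wavelet at dyadic scale 2^j, with its centre position.
mz_kernel <- function(scale) {
  key <- as.character(scale)
  if (!is.null(.kernel_cache[[key]])) return(.kernel_cache[[key]])
  j <- as.integer(round(log2(scale)))
  stopifnot(2^j == scale, j >= 1L)
  h <- c(1, 3, 3, 1) / 8       # lowpass, centre 2.5
  g <- c(2, -2)                # derivative highpass, centre 1.5
  parts <- list()
  if (j > 1L) {
    for (lev in seq_len(j - 1L)) {
      parts <- c(parts, list(upsample_taps(h, 2L^(lev - 1L))))
    }
  }
  gk <- upsample_taps(g, 2L^(j - 1L))
  parts <- c(parts, list(gk))
  k <- Reduce(function(a, b) conv_full(a, b), parts)
  # centre of a convolution = sum of part centres - (number of parts - 1);
  # an upsampled symmetric/antisymmetric filter keeps its (fractional) centre
  # scaled: centre' = (centre - 1) * up + 1.
  cts <- vapply(parts, function(p) (length(p) + 1) / 2, numeric(1))
  center <- sum(cts) - (length(parts) - 1L)
  res <- list(k = k, center = as.integer(round(center)))
  .kernel_cache[[key]] <- res
  res
}

#' Undecimated wavelet transform of a signal at one dyadic scale
#'
#' @param x Numeric signal.
#' @param scale Dyadic scale (16 or 32 in practice).
#' @return Numeric vector of the same length, centre-aligned with `x`.
#' @keywords internal
mz_transform <- function(x, scale) {
  kc <- mz_kernel(scale)
  conv_centered(x, kc$k, kc$center)
}

# --- per-cycle primitives ---------------------------------------------------

cycle_window <- function(r, rr, frac, n) {
  lo <- r + as.integer(round(frac[1L] * rr))
  hi <- r + as.integer(round(frac[2L] * rr))
  lo <- max(lo, 1L)
  hi <- min(hi, n)
  if (hi - lo < 3L) return(NULL)
  lo:hi
}

cycle_polarity <- function(z, win, setting) {
  if (setting == "positive") return(1)
  if (setting == "negative") return(-1)
  s <- z[win] - stats::median(z[win])
  if (all(s == 0)) return(1)
  sign(s[which.max(abs(s))])
}

# Zhang area-function T-end for one cycle. `cums` is cumsum(z) with a leading
# 0, computed once per record, so window sums are O(1); the polarity flip is
# applied algebraically (area of pol * z equals pol * area of z).
tend_zhang_one <- function(z, cums, win, W, n, pol) {
  s <- pol * z[win]
  if (diff(range(s)) == 0) return(NA_integer_)
  tpk <- win[which.max(s)]
  cand <- win[win > tpk & win > W]
  if (length(cand) < 2L) return(NA_integer_)
  A <- pol * ((cums[cand + 1L] - cums[cand + 1L - W]) - W * z[cand])
  if (diff(range(A)) == 0) return(NA_integer_)
  cand[which.max(A)]
}

# Carlos trapezium-area T-end for one cycle, given the T-peak.
tend_carlos_one <- function(pz, tpeak, next_r, ref_off, guard, n) {
  if (is.na(tpeak)) return(NA_integer_)
  x_m <- min(tpeak + ref_off, next_r - guard, n)
  if (x_m <= tpeak + 2L) return(NA_integer_)
  x_r <- (tpeak + 1L):(x_m - 1L)
  A <- 0.5 * (2 * x_m - tpeak - x_r) * (pz[tpeak] - pz[x_r])
  if (diff(range(A)) == 0) return(NA_integer_)
  x_r[which.max(A)]
}

# Martinez wavelet T-end (and T-peak) for one cycle at one scale. `w` is the
# transform of the whole signal at that scale.
tend_martinez_one <- function(w, win, frac) {
  ww <- w[win]
  M <- max(abs(ww))
  if (!is.finite(M) || M == 0) return(list(tend = NA_integer_, tpeak = NA_integer_))
  nloc <- length(ww)
  d <- diff(ww)
  ext <- which(d[-length(d)] * d[-1L] < 0) + 1L       # interior local extrema
  ext <- union(ext, which.max(abs(ww)))
  ext <- sort(ext)
  j1 <- ext[which.max(abs(ww[ext]))]
  sig <- abs(ww[ext]) >= frac * M
  opp <- sign(ww[ext]) == -sign(ww[j1])
  after <- ext[sig & opp & ext > j1]
  before <- ext[sig & opp & ext < j1]
  if (length(after)) {
    ja <- j1; jb <- after[1L]
  } else if (length(before)) {
    ja <- before[length(before)]; jb <- j1
  } else {
    return(list(tend = NA_integer_, tpeak = NA_integer_))
  }
  seg <- ja:(jb - 1L)
  zc <- seg[which(ww[seg] * ww[seg + 1L] <= 0)]
  tpeak_rel <- if (length(zc)) {
    z1 <- zc[1L]
    if (abs(ww[z1]) <= abs(ww[z1 + 1L])) z1 else z1 + 1L
  } else as.integer(round((ja + jb) / 2))
  thr <- frac * abs(ww[jb])
  post <- which(abs(ww) < thr & seq_len(nloc) > jb)
  if (!length(post)) return(list(tend = NA_integer_, tpeak = win[tpeak_rel]))
  list(tend = win[post[1L]], tpeak = win[tpeak_rel])
}

# --- public per-record delineators ------------------------------------------

check_delineate_input <- function(rec, rp) {
  stopifnot(inherits(rec, "ecg_record"), inherits(rp, "rpeak_series"))
  if (rp$n < 2L)
    stop_tendos("too_few_peaks", "need at least 2 R peaks to delineate")
  if (!isTRUE(all.equal(rec$fs, rp$fs)))
    stop_tendos("bad_fs", "record and R-peak series sampling rates differ")
}

#' T-end delineation by the area-function (Zhang-style) method
#'
#' @param rec A preprocessed [ecg_record()].
#' @param rp An [rpeak_series()] on the record.
#' @param cfg A [delineator_config()].
#' @param channel Channel to analyse.
#' @return A [tend_annotation()] aligned with `rp` (the last cycle is `NA`).
#' @export
tend_zhang <- function(rec, rp, cfg = delineator_config(), channel = 1L) {
  check_delineate_input(rec, rp)
  z <- rec$samples[, channel]
  n <- length(z)
  fs <- rec$fs
  W <- max(2L, as.integer(round(cfg$zhang_W / 1000 * fs)))
  R <- rp$indices
  out <- rep(NA_integer_, rp$n)
  cums <- c(0, cumsum(z))
  for (i in seq_len(rp$n - 1L)) {
    rr <- R[i + 1L] - R[i]
    win <- cycle_window(R[i], rr, cfg$search_window, n)
    if (is.null(win)) next
    pol <- cycle_polarity(z, win, cfg$twave_polarity)
    out[i] <- tend_zhang_one(z, cums, win, W, n, pol)
  }
  tend_annotation(out, "zhang", fs)
}

#' T-end delineation by the wavelet (Martinez-style) method
#'
#' A faithful-in-structure reimplementation of the dyadic-wavelet delineator
#' (labelled `martinez_style` in outputs): scale 16 primary, scale 32 as
#' fallback when no modulus-maxima pair is found.
#'
#' @inheritParams tend_zhang
#' @return A list with `tends` (a [tend_annotation()]) and `tpeaks`
#'   (integer vector of per-cycle T-peak indices, `NA` where undetected).
#' @export
tend_martinez <- function(rec, rp, cfg = delineator_config(), channel = 1L) {
  check_delineate_input(rec, rp)
  z <- rec$samples[, channel]
  n <- length(z)
  R <- rp$indices
  wx <- lapply(cfg$wavelet_scales, function(s) mz_transform(z, s))
  tends <- rep(NA_integer_, rp$n)
  tpeaks <- rep(NA_integer_, rp$n)
  for (i in seq_len(rp$n - 1L)) {
    rr <- R[i + 1L] - R[i]
    win <- cycle_window(R[i], rr, cfg$search_window, n)
    if (is.null(win)) next
    for (w in wx) {
      res <- tend_martinez_one(w, win, cfg$martinez_frac)
      if (!is.na(res$tend)) break
    }
    tends[i] <- res$tend
    tpeaks[i] <- res$tpeak
  }
  list(tends = tend_annotation(tends, "martinez_style", rec$fs),
       tpeaks = tpeaks)
}

#' T-end delineation by the trapezium-area (Carlos-style) method
#'
#' Requires a per-cycle T-peak; when `tpeaks` is `NULL` the wavelet
#' delineator supplies them, with a local-extremum fallback for cycles where
#' it finds none.
#'
#' @inheritParams tend_zhang
#' @param tpeaks Optional integer vector of per-cycle T-peak indices.
#' @return A [tend_annotation()].
#' @export
tend_carlos <- function(rec, rp, tpeaks = NULL, cfg = delineator_config(),
                        channel = 1L) {
  check_delineate_input(rec, rp)
  z <- rec$samples[, channel]
  n <- length(z)
  fs <- rec$fs
  R <- rp$indices
  if (is.null(tpeaks)) tpeaks <- tend_martinez(rec, rp, cfg, channel)$tpeaks
  stopifnot(length(tpeaks) == rp$n)
  ref_off <- as.integer(round(cfg$carlos_ref_offset / 1000 * fs))
  guard <- as.integer(round(0.020 * fs))
  out <- rep(NA_integer_, rp$n)
  for (i in seq_len(rp$n - 1L)) {
    rr <- R[i + 1L] - R[i]
    win <- cycle_window(R[i], rr, cfg$search_window, n)
    if (is.null(win)) next
    pol <- cycle_polarity(z, win, cfg$twave_polarity)
    tp <- tpeaks[i]
    if (is.na(tp)) {                      # fallback: dominant excursion
      s <- pol * (z[win] - stats::median(z[win]))
      if (diff(range(s)) == 0) next
      tp <- win[which.max(s)]
    }
    out[i] <- tend_carlos_one(pol * z, tp, R[i + 1L], ref_off, guard, n)
  }
  tend_annotation(out, "carlos", fs)
}

#' Run a named delineator
#'
#' @param detector `"zhang"`, `"martinez"` or `"carlos"`.
#' @inheritParams tend_zhang
#' @return A [tend_annotation()].
#' @export
delineate <- function(rec, rp, detector = c("zhang", "martinez", "carlos"),
                      cfg = delineator_config(), channel = 1L) {
  detector <- match.arg(detector)
  switch(detector,
         zhang = tend_zhang(rec, rp, cfg, channel),
         martinez = tend_martinez(rec, rp, cfg, channel)$tends,
         carlos = tend_carlos(rec, rp, NULL, cfg, channel))
}

# Delineate a single cycle on a standalone template vector whose R peak sits
# at `r_local` and whose local RR interval is `rr` samples. Used on denoised
# templates; the returned index is in template coordinates.
delineate_template <- function(z, r_local, rr, detector, cfg, fs) {
  n <- length(z)
  win <- cycle_window(r_local, rr, cfg$search_window, n)
  if (is.null(win)) return(NA_integer_)
  pol <- cycle_polarity(z, win, cfg$twave_polarity)
  pz <- pol * z
  if (detector == "zhang") {
    W <- max(2L, as.integer(round(cfg$zhang_W / 1000 * fs)))
    cums <- c(0, cumsum(z))
    return(tend_zhang_one(z, cums, win, W, n, pol))
  }
  mz <- function() {
    for (s in cfg$wavelet_scales) {
      res <- tend_martinez_one(mz_transform(z, s), win, cfg$martinez_frac)
      if (!is.na(res$tend) || !is.na(res$tpeak)) return(res)
    }
    list(tend = NA_integer_, tpeak = NA_integer_)
  }
  if (detector == "martinez") return(mz()$tend)
  # carlos
  tp <- mz()$tpeak
  if (is.na(tp)) {
    s <- pz[win] - stats::median(pz[win])
    if (diff(range(s)) == 0) return(NA_integer_)
    tp <- win[which.max(s)]
  }
  ref_off <- as.integer(round(cfg$carlos_ref_offset / 1000 * fs))
  guard <- as.integer(round(0.020 * fs))
  tend_carlos_one(pz, tp, r_local + rr, ref_off, guard, n)
}
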