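# Synthetic ECG with ground-truth fiducials, and the two additive noise
# models (white Gaussian; ARMA(1,1) with Student-t(4) innovations) scaled to
# a prescribed SNR. Everything is bit-reproducible under a seed, so the whole
# toolkit is testable without external recordings.

#' Noise specification
#'
#' @param kind `"gaussian"` or `"arma11"`.
#' @param snr_db Desired signal-to-noise ratio in dB.
#' @param c,phi,theta ARMA(1,1) constants `X_t = phi X_{t-1} + c + Z_t +
#'   theta Z_{t-1}`; defaults 0.5, 0.5, -0.5 (note phi = -theta makes the
#'   polynomials cancel: the process is white t(4) noise around the
#'   stationary mean `c / (1 - phi)`).
#' @param seed Optional RNG seed.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("gaussian", "arma11"), snr_db = 10,
                       c = 0.5, phi = 0.5, theta = -0.5, seed = NULL) {
  kind <- match.arg(kind)
  if (abs(phi) >= 1) stop_tendos("nonstationary", "|phi| must be < 1")
  structure(list(kind = kind, snr_db = snr_db, c = c, phi = phi,
                 theta = theta, seed = seed),
            class = "noise_spec")
}

#' White Gaussian noise
#'
#' @param n Length.
#' @param seed Optional RNG seed (the caller's random stream is untouched).
#' @return Numeric vector of iid standard normal draws (unit population
#'   variance).
#' @export
gen_gaussian_noise <- function(n, seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, stats::rnorm(n))
}

#' ARMA(1,1) noise with Student-t(4) innovations
#'
#' Simulates `X_t = phi X_{t-1} + c + Z_t + theta Z_{t-1}` with heavy-tailed
#' t(4) innovations, discards a burn-in, and (by default) divides by the
#' realised sample SD so the returned vector has unit sample SD. The nonzero
#' stationary mean `c / (1 - phi)` is deliberately retained before the SD
#' normalisation; baseline removal downstream absorbs the resulting offset.
#'
#' @param n Length.
#' @param spec A [noise_spec()] (its `kind` is not checked here).
#' @param normalize Divide by the sample SD (default `TRUE`).
#' @param burn_in Samples discarded at the start (default 1000).
#' @return Numeric vector of length `n`.
#' @export
gen_arma11 <- function(n, spec = noise_spec("arma11"), normalize = TRUE,
                       burn_in = 1000L) {
  stopifnot(n >= 1)
  if (abs(spec$phi) >= 1) stop_tendos("nonstationary", "|phi| must be < 1")
  x <- with_seed(spec$seed, {
    total <- n + burn_in
    z <- stats::rt(total + 1L, df = 4)
    e <- spec$c + z[-1L] + spec$theta * z[-(total + 1L)]
    as.numeric(stats::filter(e, spec$phi, method = "recursive", init = 0))
  })
  x <- x[(burn_in + 1L):(burn_in + n)]
  if (normalize) x / stats::sd(x) else x
}

#' Scale unit-SD noise to a target SNR and add it to a signal
#'
#' The scale is `RMS(z) / 10^(snr_db / 20)`; with unit-sample-SD, near-zero
#' mean noise the realised SNR `20 log10(RMS(z) / RMS(scaled noise))` is
#' within 0.1 dB of the request.
#'
#' @param z Clean signal (numeric vector, nonzero RMS).
#' @param noise Unit-SD noise vector of the same length.
#' @param snr_db Desired SNR in dB.
#' @return The noisy signal `z + scale * noise`, with the scale attached as
#'   attribute `"noise_scale"`.
#' @export
scale_to_snr <- function(z, noise, snr_db) {
  stopifnot(length(z) == length(noise))
  rms <- sqrt(mean(z^2))
  if (rms == 0) stop_tendos("zero_signal", "signal has zero RMS")
  sc <- rms / 10^(snr_db / 20)
  structure(z + sc * noise, noise_scale = sc)
}

#' Realized signal-to-noise ratio of a noisy record
#'
#' `20 log10(RMS(z) / SD(noisy - z))`. Noise power is taken about the noise
#' mean: the ARMA(1,1) model retains its nonzero stationary mean through the
#' SD-normalisation, and that DC offset carries no in-band power (baseline
#' removal absorbs it), so it is excluded from the noise power.
#'
#' @param z Clean signal.
#' @param noisy The same signal with additive noise.
#' @return Realized SNR in dB.
#' @export
realized_snr <- function(z, noisy) {
  stopifnot(length(z) == length(noisy))
  d <- as.numeric(noisy) - as.numeric(z)
  20 * log10(sqrt(mean(z^2)) / stats::sd(d))
}

#' Synthetic ECG specification
#'
#' Quasi-periodic P-QRS-T cycles built as sums of Gaussians, with beat-to-beat
#' RR and amplitude variability and a known ground-truth T-end per beat
#' (`T centre + tend_sigmas * T width`, where the Gaussian has decayed to
#' about 1% of its peak for the default 3 sigmas).
#'
#' @param duration_s Record length in seconds (default 120).
#' @param fs Sampling rate in Hz (default 250).
#' @param mean_hr_bpm Mean heart rate (default 60).
#' @param rr_sd_frac Beat-to-beat RR standard deviation as a fraction of the
#'   mean RR (default 0.05, a typical resting HRV magnitude).
#' @param amp_sd_frac Per-wave amplitude jitter fraction (default 0.05).
#' @param wave_params Data frame with columns `wave`, `center_s` (offset from
#'   the R peak), `width_s` (Gaussian sigma), `amp_mv`; defaults approximate
#'   a lead-II morphology.
#' @param tend_sigmas Ground-truth T-end offset in T-width units (default 3).
#' @param seed Optional RNG seed.
#' @return A list of class `synth_ecg_spec`.
#' @export
synth_ecg_spec <- function(duration_s = 120, fs = 250, mean_hr_bpm = 60,
                           rr_sd_frac = 0.05, amp_sd_frac = 0.05,
                           wave_params = default_wave_params(),
                           tend_sigmas = 3, seed = NULL) {
  stopifnot(duration_s > 0, fs > 0, mean_hr_bpm > 0, rr_sd_frac >= 0,
            amp_sd_frac >= 0, all(wave_params$width_s > 0), tend_sigmas > 0)
  structure(list(duration_s = duration_s, fs = fs, mean_hr_bpm = mean_hr_bpm,
                 rr_sd_frac = rr_sd_frac, amp_sd_frac = amp_sd_frac,
                 wave_params = wave_params, tend_sigmas = tend_sigmas,
                 seed = seed),
            class = "synth_ecg_spec")
}

#' @rdname synth_ecg_spec
#' @export
default_wave_params <- function() {
  data.frame(
    wave = c("P", "Q", "R", "S", "T"),
    center_s = c(-0.210, -0.028, 0.000, 0.030, 0.300),
    width_s = c(0.028, 0.010, 0.011, 0.012, 0.030),
    amp_mv = c(0.12, -0.10, 1.00, -0.18, 0.35)
  )
}

#' Generate a synthetic ECG record with ground truth
#'
#' @param spec A [synth_ecg_spec()].
#' @return A list with `record` (an [ecg_record()]), `rpeaks` (true R-peak
#'   sample indices, 1-based), `tends` (true T-end indices, one per beat),
#'   `tpeaks` (true T-peak indices) and `spec`.
#' @export
gen_synth_ecg <- function(spec = synth_ecg_spec()) {
  stopifnot(inherits(spec, "synth_ecg_spec"))
  fs <- spec$fs
  n <- as.integer(round(spec$duration_s * fs))
  wp <- spec$wave_params
  rr_mean <- 60 / spec$mean_hr_bpm
  tw <- wp[wp$wave == "T", ]
  tend_off <- tw$center_s + spec$tend_sigmas * tw$width_s
  res <- with_seed(spec$seed, {
    # beat onsets: first R at 0.5 s, then jittered RR intervals
    r_times <- numeric(0)
    t <- 0.5
    max_t <- spec$duration_s - 0.6
    while (t <= max_t) {
      r_times <- c(r_times, t)
      rr <- rr_mean * (1 + spec$rr_sd_frac * stats::rnorm(1))
      rr <- min(max(rr, 0.4 * rr_mean), 1.6 * rr_mean)
      t <- t + rr
    }
    nb <- length(r_times)
    amps <- matrix(stats::rnorm(nb * nrow(wp), mean = 1, sd = spec$amp_sd_frac),
                   nrow = nb)
    list(r_times = r_times, amps = amps)
  })
  r_times <- res$r_times
  nb <- length(r_times)
  if (nb < 2L) stop_tendos("too_short", "spec produces fewer than 2 beats")
  if (any(diff(r_times) < tend_off + abs(min(wp$center_s)) + 0.02))
    stop_tendos("overlapping_beats",
                "RR intervals too short for the configured wave layout")
  x <- numeric(n)
  tgrid <- (seq_len(n) - 1L) / fs
  for (b in seq_len(nb)) {
    for (k in seq_len(nrow(wp))) {
      c0 <- r_times[b] + wp$center_s[k]
      w0 <- wp$width_s[k]
      a0 <- wp$amp_mv[k] * res$amps[b, k]
      lo <- max(1L, as.integer(floor((c0 - 5 * w0) * fs)) + 1L)
      hi <- min(n, as.integer(ceiling((c0 + 5 * w0) * fs)) + 1L)
      if (lo > hi) next
      seg <- lo:hi
      x[seg] <- x[seg] + a0 * exp(-((tgrid[seg] - c0)^2) / (2 * w0^2))
    }
  }
  to_idx <- function(t) as.integer(round(t * fs)) + 1L
  list(record = ecg_record(x, fs = fs, record_id = "synthetic"),
       rpeaks = to_idx(r_times),
       tends = to_idx(r_times + tend_off),
       tpeaks = to_idx(r_times + tw$center_s),
       spec = spec)
}
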