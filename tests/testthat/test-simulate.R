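# Noise generators, SNR scaling, synthetic ECG ground truth.

test_that("Gaussian noise is standard normal, reproducible, seed-isolated", {
  n <- 1e5
  x <- gen_gaussian_noise(n, seed = 3)
  expect_equal(x, gen_gaussian_noise(n, seed = 3))            # determinism
  expect_false(identical(x, gen_gaussian_noise(n, seed = 4)))
  expect_lt(abs(stats::sd(x) - 1), 0.01)
  expect_lt(abs(mean(x)), 3 / sqrt(n))
  # the caller's RNG stream is untouched
  set.seed(99); before <- stats::runif(1)
  set.seed(99); invisible(gen_gaussian_noise(10, seed = 1))
  expect_equal(stats::runif(1), before)
})

test_that("ARMA(1,1) with phi = -theta collapses to shifted white t(4) noise", {
  n <- 1e5
  spec <- noise_spec("arma11", seed = 9)
  raw <- gen_arma11(n, spec, normalize = FALSE)
  # polynomial cancellation: X_t = c/(1-phi) + Z_t, so lag-1 ACF ~ 0 and
  # the stationary mean is c/(1-phi) = 1
  expect_lt(abs(stats::acf(raw, plot = FALSE)$acf[2]), 3 / sqrt(n))
  expect_lt(abs(mean(raw) - 1), 0.05)
  # heavy tails: sample kurtosis far above the Gaussian 3
  expect_gt(mean((raw - mean(raw))^4) / stats::var(raw)^2, 3)
  # post-normalisation sample SD is 1 by construction
  expect_equal(stats::sd(gen_arma11(n, spec)), 1, tolerance = 1e-12)
  expect_equal(gen_arma11(1000, spec), gen_arma11(1000, spec))
  expect_error(gen_arma11(10, noise_spec("arma11", phi = 1.2)),
               class = "tendos_nonstationary")
  expect_error(noise_spec("arma11", phi = 1.2), class = "tendos_nonstationary")
})

test_that("SNR scaling: closed-form scale and realized SNR within 0.1 dB", {
  z <- sqrt(2) * sin(2 * pi * (0:9999) / 100)   # RMS exactly 1
  nz <- gen_gaussian_noise(10000, seed = 5)
  expect_equal(attr(scale_to_snr(z, nz, 20), "noise_scale"), 0.1)
  expect_equal(attr(scale_to_snr(z, nz, 0), "noise_scale"), 1)

  gen <- synth_fixture(60, 1)
  zs <- gen$record$samples[, 1]
  for (kind in c("gaussian", "arma11")) for (snr in c(5, 10)) {
    noise <- if (kind == "gaussian") gen_gaussian_noise(length(zs), seed = 2)
             else gen_arma11(length(zs), noise_spec("arma11", seed = 2))
    noisy <- scale_to_snr(zs, noise, snr)
    expect_lt(abs(realized_snr(zs, noisy) - snr), 0.1)
  }
  expect_error(scale_to_snr(numeric(100), gen_gaussian_noise(100, 1), 10),
               class = "tendos_zero_signal")
})

test_that("synthetic ECG: beat count, fiducial layout, degenerate variability", {
  gen <- gen_synth_ecg(synth_ecg_spec(duration_s = 120, mean_hr_bpm = 60,
                                      seed = 6))
  expect_true(abs(length(gen$rpeaks) - 120) <= 1)
  expect_true(all(gen$tends > gen$rpeaks))
  expect_true(all(gen$tends[-length(gen$tends)] < gen$rpeaks[-1]))
  expect_true(all(gen$tpeaks < gen$tends))
  # ground-truth rule: T-end = T centre + 3 * T width (up to the +/- 1
  # sample rounding of the continuous beat times)
  wp <- gen$spec$wave_params
  off <- (wp$center_s[wp$wave == "T"] + 3 * wp$width_s[wp$wave == "T"]) * 250
  expect_lte(max(abs((gen$tends - gen$rpeaks) - off)), 1)

  # zero variability -> identical cycles, near-zero library sigma
  gen0 <- synth_fixture(60, 5, rr_sd_frac = 0, amp_sd_frac = 0)
  rp0 <- load_rpeaks(gen0$rpeaks, gen0$record)
  expect_lt(estimate_sigma(build_library(gen0$record, rp0)), 1e-3)
  expect_equal(diff(gen0$rpeaks), rep(250L, length(gen0$rpeaks) - 1L))

  # bit-reproducible under a fixed seed
  again <- gen_synth_ecg(synth_ecg_spec(duration_s = 120, mean_hr_bpm = 60,
                                        seed = 6))
  expect_identical(gen$record$samples, again$record$samples)
  expect_identical(gen$tends, again$tends)

  # overlapping-beat guard
  expect_error(
    gen_synth_ecg(synth_ecg_spec(duration_s = 30, mean_hr_bpm = 160, seed = 1)),
    class = "tendos_overlapping_beats")
})
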