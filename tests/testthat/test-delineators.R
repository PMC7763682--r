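# The three T-end delineators: closed-form fixtures, ground-truth accuracy,
# and the shared invariants (shift equivariance, scale invariance, agreement).

fs <- 250

# A minimal two-beat host so a single analytic T wave can be delineated: one
# R spike at r1, the wave under test after it, and a second R spike closing
# the cycle.
host_record <- function(wave, wave_start, r1 = 251L, r2 = 1251L, n = 1500L) {
  x <- numeric(n)
  x[r1] <- 1.5
  x[r2] <- 1.5
  x[wave_start + seq_along(wave) - 1L] <- wave
  list(rec = ecg_record(x, fs = fs), rp = rpeak_series(c(r1, r2), fs))
}

test_that("area-function detector ends a half-cosine wave at its true end", {
  # u(t) = cos(pi t / (2T)) on [0, T]: descending limb, ends exactly at T
  Tlen <- 50L                              # 200 ms
  wave <- cos(pi * (0:Tlen) / (2 * Tlen))
  ws <- 401L                               # peak at 600 ms after R
  h <- host_record(wave, ws)
  got <- tend_zhang(h$rec, h$rp)$tend_indices[1]
  true_end <- ws + Tlen
  W <- round(0.128 * fs)
  expect_lt(abs(got - true_end), W / 2)
})

test_that("area-function detector: flat cycle yields a missing marker, clean ECG <= 20 ms", {
  h <- host_record(numeric(0), 300L)
  h$rec$samples[c(251, 1251), 1] <- 0      # fully constant signal
  expect_true(is.na(tend_zhang(h$rec, h$rp)$tend_indices[1]))

  fx <- prepped_fixture(120, 42)
  ann <- tend_zhang(fx$pre, fx$rp)
  expect_lte(mean_abs_err_ms(ann, fx$gen$tends[seq_len(fx$rp$n)]), 20)
})

test_that("trapezium-area criterion maximises at a slope-to-flat corner (brute force)", {
  # triangle descending from 1 at x_s to 0 at x = x_s + Tlen, flat after
  Tlen <- 25L
  wave <- c(seq(1, 0, length.out = Tlen + 1L), numeric(60))
  ws <- 401L
  h <- host_record(wave, ws)
  x_s <- ws                                # T peak at triangle apex
  x_m <- x_s + round(0.160 * fs)           # reference 160 ms later (on the flat)
  z <- h$rec$samples[, 1]
  # independent brute force of the trapezium area over all candidates
  cand <- (x_s + 1L):(x_m - 1L)
  area <- 0.5 * (2 * x_m - x_s - cand) * (z[x_s] - z[cand])
  oracle <- cand[which.max(area)]
  expect_lte(abs(oracle - (ws + Tlen)), 2)  # corner, to within 2 samples
  got <- tend_carlos(h$rec, h$rp, tpeaks = c(x_s, NA))$tend_indices[1]
  expect_equal(got, oracle)
})

test_that("trapezium-area detector is polarity-symmetric and accurate on clean ECG", {
  Tlen <- 25L
  wave <- c(seq(1, 0, length.out = Tlen + 1L), numeric(60))
  ws <- 401L
  h <- host_record(wave, ws)
  pos <- tend_carlos(h$rec, h$rp, tpeaks = c(ws, NA))$tend_indices[1]
  hneg <- h
  hneg$rec$samples[, 1] <- -h$rec$samples[, 1]
  neg <- tend_carlos(hneg$rec, hneg$rp, tpeaks = c(ws, NA))$tend_indices[1]
  expect_equal(neg, pos)

  fx <- prepped_fixture(120, 42)
  tp <- tend_martinez(fx$pre, fx$rp)$tpeaks
  ann <- tend_carlos(fx$pre, fx$rp, tp)
  expect_lte(mean_abs_err_ms(ann, fx$gen$tends[seq_len(fx$rp$n)]), 25)
})

test_that("wavelet detector ends a Gaussian bump near its tail and NAs a flat cycle", {
  sigma <- 8                                # 32 ms bump
  tt <- -40:40
  wave <- exp(-tt^2 / (2 * sigma^2))
  center <- 441L
  h <- host_record(wave, center - 40L)
  got <- tend_martinez(h$rec, h$rp)$tends$tend_indices[1]
  expect_false(is.na(got))
  # end within 3 sigma + 10 ms of the bump centre (the smoothed-derivative
  # magnitude decays below the threshold fraction around there)
  expect_lt(abs(got - center), 3 * sigma + 0.010 * fs)

  flat <- host_record(numeric(0), 300L)
  flat$rec$samples[, 1] <- 0
  expect_true(is.na(tend_martinez(flat$rec, flat$rp)$tends$tend_indices[1]))
})

test_that("wavelet detector stays within 20 ms of ground truth on clean ECG", {
  fx <- prepped_fixture(120, 42)
  ann <- tend_martinez(fx$pre, fx$rp)$tends
  expect_lte(mean_abs_err_ms(ann, fx$gen$tends[seq_len(fx$rp$n)]), 20)
})

test_that("all detectors are shift-equivariant and amplitude-scale invariant", {
  fx <- prepped_fixture(60, 42)
  pre <- fx$pre; rp <- fx$rp
  k <- 37L
  shifted <- ecg_record(c(numeric(k), pre$samples[, 1]), fs = fs)
  rp_s <- rpeak_series(rp$indices + k, fs)
  scaled <- pre
  scaled$samples <- pre$samples * 3.7

  for (det in c("zhang", "martinez", "carlos")) {
    base <- delineate(pre, rp, det)$tend_indices
    sh <- delineate(shifted, rp_s, det)$tend_indices
    sc <- delineate(scaled, rp, det)$tend_indices
    expect_equal(sh, base + k, info = det)
    expect_equal(sc, base, info = det)
    # R(i) < tend(i) < R(i+1) whenever present
    i <- which(!is.na(base))
    expect_true(all(base[i] > rp$indices[i] & base[i] < rp$indices[i + 1L]),
                info = det)
  }
})

test_that("the tSQI pair agrees within 50 ms on nearly all clean cycles", {
  fx <- prepped_fixture(120, 42)
  a <- tend_zhang(fx$pre, fx$rp)$tend_indices
  b <- tend_martinez(fx$pre, fx$rp)$tends$tend_indices
  both <- !is.na(a) & !is.na(b)
  agree <- abs(a[both] - b[both]) * 1000 / fs < 50
  expect_gte(mean(agree), 0.95)
})
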