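# Template library, noise-level estimate, and the optimal shrinker.

test_that("library geometry follows the 95% RR quantile rule", {
  # all RR = 200 samples -> w = 200, Lw = Rw = 100, p = 201
  R <- seq(301L, 4301L, by = 200L)
  rec <- ecg_record(seq_len(4601) * 1e-3, fs = 250)
  lib <- build_library(rec, rpeak_series(R, 250))
  expect_equal(lib$w, 200L)
  expect_equal(lib$Lw, 100L)
  expect_equal(lib$Rw, 100L)
  expect_equal(lib$p, 201L)
  expect_equal(ncol(lib$segments), length(R))
  # template i spans z[R(i) - Lw .. R(i) + Rw]
  expect_equal(lib$segments[, 3], ((R[3] - 100):(R[3] + 100)) * 1e-3)

  # first R too close to the start -> that cycle is excluded and mapped out
  R2 <- c(30L, R)
  lib2 <- build_library(rec, rpeak_series(R2, 250))
  expect_false(1L %in% lib2$cycle_index_map)
  expect_equal(ncol(lib2$segments), length(R))

  # constant signal -> identical segments
  lib3 <- build_library(ecg_record(rep(2, 4601), fs = 250),
                        rpeak_series(R, 250))
  expect_true(all(lib3$segments == 2))
})

test_that("cycle distances: identity, RRI arithmetic, l2 closed form", {
  R <- c(301L, 501L, 731L, 931L)   # RR = 200, 230, 200 (+ backward for last)
  rec <- ecg_record(stats::rnorm(1300), fs = 250)
  lib <- build_library(rec, rpeak_series(R, 250))
  expect_equal(cycle_distance(lib, 2, 2, "rri"), 0)
  expect_equal(cycle_distance(lib, 1, 1, "l2"), 0)
  expect_equal(cycle_distance(lib, 1, 2, "rri"), 30)
  # last cycle uses its backward interval (200)
  expect_equal(cycle_distance(lib, 1, 4, "rri"), 0)
  # s_b = s_a + c * 1 -> l2 distance c * sqrt(p)
  lib$segments[, 2] <- lib$segments[, 1] + 0.5
  expect_equal(cycle_distance(lib, 1, 2, "l2"), 0.5 * sqrt(lib$p))
})

test_that("neighbour selection keeps the cycle first and breaks ties by index", {
  p <- 7L
  segs <- matrix(stats::rnorm(p * 10), p, 10)
  lib <- structure(list(segments = segs, p = p, Lw = 3L, Rw = 3L, w = 6L,
                        cycle_index_map = 1:10,
                        rr_cycle = c(200, 210, 201, 205, 300, 200, 202, 250,
                                     199, 260),
                        fs = 250),
                   class = "template_library")
  S <- select_neighbors(lib, 1L, shrinkage_config(xi = 3, metric = "rri"))
  expect_equal(dim(S), c(p, 4L))
  expect_equal(S[, 1], segs[, 1])
  # distances from cycle 1 (rr 200): cycles 6 (0), 9 (1), 3 (1), 7 (2)...
  expect_equal(S[, 2], segs[, 6])
  expect_equal(S[, 3], segs[, 3])   # tie at distance 1: index 3 before 9
  expect_equal(S[, 4], segs[, 9])

  # all distances equal -> the xi lowest-index other cycles
  lib$rr_cycle <- rep(200, 10)
  S2 <- select_neighbors(lib, 5L, shrinkage_config(xi = 3, metric = "rri"))
  expect_equal(S2[, 2:4], segs[, 1:3])
  expect_error(select_neighbors(lib, 1L, shrinkage_config(xi = 20)),
               class = "tendos_library_too_small")
})

test_that("noise level estimate matches hand computation and recovers truth", {
  # n = 2, p = 2: s1 = (0,0), s2 = (2,2); medians (1,1); sigma = 1
  expect_equal(estimate_sigma(matrix(c(0, 0, 2, 2), nrow = 2)), 1)
  # identical cycles -> 0
  expect_equal(estimate_sigma(matrix(1, 5, 8)), 0)
  # fixed template + iid noise of SD 0.1, n = 500 -> within 10%
  set.seed(12)
  tmpl <- cos(seq(0, 2 * pi, length.out = 101))
  segs <- matrix(tmpl, 101, 500) + matrix(stats::rnorm(101 * 500, 0, 0.1),
                                          101, 500)
  expect_lt(abs(estimate_sigma(segs) - 0.1) / 0.1, 0.1)
})

test_that("optimal shrinker: threshold, closed forms, asymptote, continuity", {
  expect_equal(eta_star(1, 1), 0)
  expect_equal(eta_star(2, 1), 1)      # at the bulk edge 1 + sqrt(beta)
  expect_equal(eta_star(2.5, 1), 2)
  expect_error(eta_star(1, 0), class = "tendos_bad_beta")
  expect_error(eta_star(1, 1.5), class = "tendos_bad_beta")

  for (beta in c(0.1, 0.5, 1)) {
    y <- seq(0, 10, by = 0.01)
    e <- eta_star(y, beta)
    expect_true(all(e[y < 1 + sqrt(beta)] == 0))
    expect_true(all(e <= y + 1e-12))
    # the shrinker jumps to beta^(1/4) at the bulk edge (hard-threshold
    # discontinuity), is continuous on the kept region, and grows monotonely
    edge <- 1 + sqrt(beta)
    expect_equal(eta_star(edge, beta), beta^0.25)
    kept <- seq(edge, 10, by = 1e-3)
    expect_lt(max(abs(diff(eta_star(kept, beta)))), 5e-2)
    expect_true(all(diff(e) >= -1e-12))
    # eta*(y)/y -> 1 for large y
    expect_lt(abs(eta_star(50, beta) / 50 - 1), 1e-2)
  }
})

test_that("shrink_matrix: no-op at sigma 0, rank-1 passthrough, transpose and norm laws", {
  set.seed(21)
  S <- matrix(stats::rnorm(40), 5, 8)
  expect_identical(shrink_matrix(S, 0)$S_tilde, S)

  # strong rank-1 signal, tiny sigma: shrinkage is numerically invisible
  u <- stats::rnorm(30); v <- stats::rnorm(12)
  R1 <- 50 * tcrossprod(u / sqrt(sum(u^2)), v / sqrt(sum(v^2)))
  out <- shrink_matrix(R1, 1e-4)
  expect_equal(out$kept_rank, 1L)
  expect_lt(max(abs(out$S_tilde - R1)) / max(abs(R1)), 0.01)

  # transpose consistency and operator-norm non-expansion
  for (i in 1:5) {
    M <- matrix(stats::rnorm(48), sample(c(6, 8), 1))
    sg <- stats::runif(1, 0.1, 2)
    a <- shrink_matrix(M, sg)$S_tilde
    b <- t(shrink_matrix(t(M), sg)$S_tilde)
    expect_equal(a, b, tolerance = 1e-10)
    expect_lte(svd(a)$d[1], svd(M)$d[1] + 1e-10)
  }
  expect_error(shrink_matrix(matrix(c(1, NA, 3, 4), 2), 1),
               class = "tendos_nonfinite")
})

test_that("denoising a noisy library recovers templates and honours flags", {
  # clean generator with zero beat variability: sigma ~ 0, template preserved
  gen0 <- synth_fixture(60, 5, rr_sd_frac = 0, amp_sd_frac = 0)
  pre0 <- gen0$record                       # raw is fine for library cutting
  rp0 <- load_rpeaks(gen0$rpeaks, pre0)
  lib0 <- build_library(pre0, rp0)
  sg0 <- estimate_sigma(lib0)
  expect_lt(sg0, 1e-3)
  out0 <- denoise_cycle(lib0, 3L, sg0)
  expect_lt(max(abs(out0$denoised_segment - lib0$segments[, 3])), 1e-3)

  # noisy library at 5 dB: denoised template closer to the clean one for
  # nearly all cycles
  gen <- synth_fixture(120, 8, rr_sd_frac = 0, amp_sd_frac = 0)
  z <- gen$record$samples[, 1]
  noisy <- as.numeric(scale_to_snr(z, gen_gaussian_noise(length(z), seed = 3), 5))
  rp <- load_rpeaks(gen$rpeaks, gen$record)
  lib_clean <- build_library(gen$record, rp)
  lib_noisy <- build_library(ecg_record(noisy, 250), rp)
  sg <- estimate_sigma(lib_noisy)
  wins <- sapply(seq_len(ncol(lib_noisy$segments)), function(i) {
    den <- denoise_cycle(lib_noisy, i, sg)$denoised_segment
    ref <- lib_clean$segments[, i]
    sqrt(mean((den - ref)^2)) < sqrt(mean((lib_noisy$segments[, i] - ref)^2))
  })
  expect_gte(mean(wins), 0.9)

  # flag semantics: exactly the flagged subset changes
  flags <- rep(FALSE, ncol(lib_noisy$segments))
  expect_equal(denoise_library(lib_noisy, flags)$segments, lib_noisy$segments)
  flags[c(2, 5, 9)] <- TRUE
  den <- denoise_library(lib_noisy, flags)
  changed <- sapply(seq_along(flags), function(i) {
    !isTRUE(all.equal(den$segments[, i], lib_noisy$segments[, i]))
  })
  expect_equal(changed, flags)
  expect_true(all(!is.na(den$kept_rank[flags])))
})
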