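# Step 3: per-cycle template library and singular-value optimal shrinkage.
#
# Each cardiac cycle is cut into a fixed-length template centred on its R
# peak (half-width ceil(w/2), with w the rounded 95% quantile of the RR
# intervals). A low-quality cycle is denoised by assembling a p x (xi+1)
# matrix from the cycle and its xi most similar neighbours, and applying the
# operator-norm optimal shrinker to the singular values of that matrix under
# the low-rank-plus-white-noise (spike) model: values below the bulk edge
# 1 + sqrt(beta) are set to zero, the rest are mapped by
#   eta*(y) = sqrt((y^2 - beta - 1 + sqrt((y^2 - beta - 1)^2 - 4 beta)) / 2).
# Singular values are normalised as y = lambda / (sigma sqrt(m)), m the
# larger matrix dimension, under which the bulk-edge threshold holds; the
# reconstruction is scaled back by sigma sqrt(m).

#' Shrinkage configuration
#'
#' @param xi Number of neighbours per denoised cycle (default 19, i.e. a
#'   p x 20 data matrix).
#' @param metric Cycle-similarity metric: `"rri"` (absolute RR-interval
#'   difference, robust for arrhythmic beats) or `"l2"` (Euclidean distance
#'   between templates).
#' @return A list of class `shrinkage_config`.
#' @export
shrinkage_config <- function(xi = 19L, metric = c("rri", "l2")) {
  metric <- match.arg(metric)
  stopifnot(xi >= 1)
  structure(list(xi = as.integer(xi), metric = metric),
            class = "shrinkage_config")
}

#' Build the per-cycle template library
#'
#' `w` is the rounded 95% quantile of the RR intervals (in samples),
#' `Lw = Rw = ceiling(w / 2)`, and template i is
#' `z[R(i) - Lw .. R(i) + Rw]` (length `p = Lw + Rw + 1`). Cycles whose
#' window would leave the record are excluded; `cycle_index_map` maps library
#' columns back to cycle numbers.
#'
#' @param rec A preprocessed [ecg_record()].
#' @param rp An [rpeak_series()] with at least 2 peaks.
#' @param channel Channel to cut templates from.
#' @return A list of class `template_library` with fields `segments`
#'   (p x n matrix, one template per column), `w`, `Lw`, `Rw`, `p`,
#'   `cycle_index_map`, `rr_cycle` (per-cycle RR in samples, backward
#'   interval for the last cycle), `fs`.
#' @export
build_library <- function(rec, rp, channel = 1L) {
  stopifnot(inherits(rec, "ecg_record"), inherits(rp, "rpeak_series"))
  if (rp$n < 2L)
    stop_tendos("too_few_peaks", "need at least 2 R peaks to build a library")
  z <- rec$samples[, channel]
  R <- rp$indices
  rr <- diff(R)
  w <- as.integer(round(stats::quantile(rr, 0.95, names = FALSE)))
  Lw <- Rw <- as.integer(ceiling(w / 2))
  p <- Lw + Rw + 1L
  ok <- (R - Lw >= 1L) & (R + Rw <= length(z))
  if (sum(ok) < 2L)
    stop_tendos("too_few_cycles", "fewer than 2 cycles fit inside the record")
  keep <- which(ok)
  segs <- vapply(keep, function(i) z[(R[i] - Lw):(R[i] + Rw)], numeric(p))
  rr_cycle <- c(rr, rr[length(rr)])   # backward interval for the last cycle
  structure(list(segments = segs, w = w, Lw = Lw, Rw = Rw, p = p,
                 cycle_index_map = keep, rr_cycle = rr_cycle[keep],
                 fs = rp$fs),
            class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("<template_library> %d cycles, p=%d (w=%d, Lw=Rw=%d) @ %g Hz\n",
              ncol(x$segments), x$p, x$w, x$Lw, x$fs))
  invisible(x)
}

#' Distance between two library cycles
#'
#' @param lib A [build_library()] result.
#' @param a,b Library positions (columns).
#' @param metric `"rri"` (absolute difference of RR intervals, in samples;
#'   the last cycle uses its backward interval) or `"l2"`.
#' @return A non-negative scalar.
#' @export
cycle_distance <- function(lib, a, b, metric = c("rri", "l2")) {
  metric <- match.arg(metric)
  m <- ncol(lib$segments)
  stopifnot(a >= 1, a <= m, b >= 1, b <= m)
  if (metric == "rri") abs(lib$rr_cycle[a] - lib$rr_cycle[b])
  else sqrt(sum((lib$segments[, a] - lib$segments[, b])^2))
}

#' Assemble the neighbour data matrix of a cycle
#'
#' Column 1 is the cycle's own template; columns 2..xi+1 are the xi
#' smallest-distance other cycles, ties broken by ascending cycle index.
#'
#' @param lib A [build_library()] result.
#' @param i Library position of the cycle.
#' @param cfg A [shrinkage_config()].
#' @return A `p x (xi + 1)` numeric matrix.
#' @export
select_neighbors <- function(lib, i, cfg = shrinkage_config()) {
  m <- ncol(lib$segments)
  if (m < cfg$xi + 1L)
    stop_tendos("library_too_small", sprintf(
      "library has %d cycles; need at least xi + 1 = %d", m, cfg$xi + 1L))
  stopifnot(i >= 1, i <= m)
  others <- setdiff(seq_len(m), i)
  d <- if (cfg$metric == "rri") {
    abs(lib$rr_cycle[others] - lib$rr_cycle[i])
  } else {
    sqrt(colSums((lib$segments[, others, drop = FALSE] - lib$segments[, i])^2))
  }
  nb <- others[order(d, others)][seq_len(cfg$xi)]
  cbind(lib$segments[, i], lib$segments[, nb, drop = FALSE], deparse.level = 0)
}

#' Estimate the library noise level
#'
#' `sigma = sqrt( mean over all cycles i and coordinates k of
#' (s_i(k) - sbar(k))^2 )`, where `sbar(k)` is the per-coordinate median
#' across the whole library. Estimated once per record; note that on clean
#' signals the physiological beat-to-beat variation is counted as noise, so
#' sigma is overestimated there (the reason denoising is gated by tSQI).
#'
#' @param lib A [build_library()] result (or a bare p x n matrix).
#' @return The scalar noise level (same units as the signal).
#' @export
estimate_sigma <- function(lib) {
  segs <- if (inherits(lib, "template_library")) lib$segments else as.matrix(lib)
  stopifnot(ncol(segs) >= 2L)
  sbar <- apply(segs, 1L, stats::median)
  sqrt(mean((segs - sbar)^2))
}

#' Operator-norm optimal shrinker
#'
#' The asymptotically optimal singular-value map for the spike model under
#' operator-norm loss:
#' `eta*(y) = sqrt((y^2 - beta - 1 + sqrt((y^2 - beta - 1)^2 - 4 beta)) / 2)`
#' for `y >= 1 + sqrt(beta)`, and 0 below that bulk edge.
#'
#' @param y Normalised singular value(s), `y >= 0` (vectorised).
#' @param beta Matrix aspect ratio (smaller dimension / larger), in `(0, 1]`.
#' @return Shrunk value(s), same length as `y`.
#' @examples
#' eta_star(2.5, 1) # 2
#' @export
eta_star <- function(y, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta > 1)
    stop_tendos("bad_beta", "beta must be in (0, 1]")
  stopifnot(all(y >= 0))
  d <- y^2 - beta - 1
  keep <- y >= 1 + sqrt(beta)
  out <- numeric(length(y))
  disc <- pmax(d[keep]^2 - 4 * beta, 0)
  out[keep] <- sqrt((d[keep] + sqrt(disc)) / 2)
  out
}

#' Denoise a data matrix by optimal shrinkage
#'
#' The matrix is oriented so rows <= columns (transposed if needed), its SVD
#' is taken, the singular values are normalised by `sigma * sqrt(m)` (m the
#' larger dimension), mapped through [eta_star()], scaled back, and the
#' matrix reassembled (then transposed back). `sigma = 0` is a no-op.
#'
#' @param S Numeric matrix with finite entries.
#' @param sigma Noise level (>= 0), typically from [estimate_sigma()].
#' @return A list with `S_tilde` (denoised matrix, same shape as `S`),
#'   `kept_rank` (singular values surviving the shrinker), `beta`, `sigma`.
#' @export
shrink_matrix <- function(S, sigma) {
  S <- as.matrix(S)
  if (!all(is.finite(S))) stop_tendos("nonfinite", "matrix has non-finite entries")
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  if (sigma == 0)
    return(list(S_tilde = S, kept_rank = min(dim(S)), beta = min(dim(S)) / max(dim(S)),
                sigma = 0))
  transposed <- nrow(S) > ncol(S)
  X <- if (transposed) t(S) else S
  m <- ncol(X)                      # larger dimension
  beta <- nrow(X) / m
  sv <- svd(X)
  y <- sv$d / (sigma * sqrt(m))
  eta <- eta_star(y, beta)
  Xt <- sv$u %*% (sigma * sqrt(m) * eta * t(sv$v))
  list(S_tilde = if (transposed) t(Xt) else Xt,
       kept_rank = sum(eta > 0), beta = beta, sigma = sigma)
}

#' Denoise one cycle's template
#'
#' Assembles the neighbour matrix of cycle `i`, shrinks it, and returns the
#' first column as the denoised template.
#'
#' @param lib A [build_library()] result.
#' @param i Library position.
#' @param sigma Noise level (from [estimate_sigma()] on the full library).
#' @param cfg A [shrinkage_config()].
#' @return A list of class `shrink_outcome`: `denoised_segment` (length p),
#'   `sigma_hat`, `beta`, `kept_rank`.
#' @export
denoise_cycle <- function(lib, i, sigma = estimate_sigma(lib),
                          cfg = shrinkage_config()) {
  S <- select_neighbors(lib, i, cfg)
  sh <- shrink_matrix(S, sigma)
  structure(list(denoised_segment = sh$S_tilde[, 1L], sigma_hat = sigma,
                 beta = sh$beta, kept_rank = sh$kept_rank),
            class = "shrink_outcome")
}

#' Denoise the flagged subset of a library
#'
#' Cycles whose flag is `TRUE` are replaced by their optimally shrunk
#' template; all others are untouched. `sigma` is estimated once from the
#' full (pre-denoising) library.
#'
#' @param lib A [build_library()] result.
#' @param flags Logical vector, either per library column or per original
#'   cycle (mapped through `cycle_index_map`).
#' @param cfg A [shrinkage_config()].
#' @param sigma Optional noise level override.
#' @return The library with `segments` partially replaced, plus fields
#'   `sigma_hat`, `denoised` (logical per column) and `kept_rank` (integer
#'   per column, `NA` where untouched).
#' @export
denoise_library <- function(lib, flags, cfg = shrinkage_config(),
                            sigma = NULL) {
  m <- ncol(lib$segments)
  if (length(flags) != m) {
    if (max(lib$cycle_index_map) <= length(flags)) {
      flags <- flags[lib$cycle_index_map]
    } else {
      stop_tendos("misaligned", "flags not alignable with library cycles")
    }
  }
  if (is.null(sigma)) sigma <- estimate_sigma(lib)
  kept <- rep(NA_integer_, m)
  if (any(flags)) {
    for (i in which(flags)) {
      out <- denoise_cycle(lib, i, sigma, cfg)
      lib$segments[, i] <- out$denoised_segment
      kept[i] <- out$kept_rank
    }
  }
  lib$sigma_hat <- sigma
  lib$denoised <- as.logical(flags)
  lib$kept_rank <- kept
  lib
}
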