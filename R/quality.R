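# Step 2: the T-end signal quality index (tSQI), plus a bSQI-style R-peak
# agreement index for comparison.
#
# Two delineators are run on the same cycles; with A cycles carrying both
# estimates and B of them agreeing to within a grace period gamma, the index
# is tSQI = B / (2A - B), which is 1 for perfect agreement and 0 for none.
# Matching is per cycle (both detectors emit one estimate per R peak), with
# a *strict* |t1 - t2| < gamma criterion.

#' Quality configuration
#'
#' @param gamma_ms Grace period in ms (default 50).
#' @param q tSQI threshold in `[0, 1]` deciding when a cycle is denoised
#'   (default 0.9; `q = 0` disables denoising).
#' @param window_before,window_after Extent of the per-cycle evaluation
#'   segment around the cycle's R peak, in samples (default 1250 each, i.e.
#'   +/- 5 s at 250 Hz).
#' @return A list of class `quality_config`.
#' @export
quality_config <- function(gamma_ms = 50, q = 0.9,
                           window_before = 1250L, window_after = 1250L) {
  stopifnot(gamma_ms > 0, q >= 0, q <= 1, window_before > 0, window_after > 0)
  structure(list(gamma_ms = gamma_ms, q = q,
                 window_before = as.integer(window_before),
                 window_after = as.integer(window_after)),
            class = "quality_config")
}

#' Count matching T-end estimates between two delineators
#'
#' @param t1,t2 Two [tend_annotation()]s aligned to the same R-peak series
#'   (equal length, equal sampling rate).
#' @param gamma_ms Grace period in ms; a pair matches when the absolute time
#'   difference is strictly smaller than this.
#' @return A list with integer counts `A` (cycles where both estimates are
#'   present) and `B` (matched cycles among those).
#' @export
match_tends <- function(t1, t2, gamma_ms = 50) {
  stopifnot(inherits(t1, "tend_annotation"), inherits(t2, "tend_annotation"))
  if (length(t1$tend_indices) != length(t2$tend_indices))
    stop_tendos("misaligned",
                "annotations come from different R-peak series (lengths differ)")
  if (!isTRUE(all.equal(t1$fs, t2$fs)))
    stop_tendos("misaligned", "annotations have different sampling rates")
  both <- !is.na(t1$tend_indices) & !is.na(t2$tend_indices)
  A <- sum(both)
  diff_ms <- abs(t1$tend_indices[both] - t2$tend_indices[both]) * 1000 / t1$fs
  B <- sum(diff_ms < gamma_ms)
  list(A = as.integer(A), B = as.integer(B))
}

#' The tSQI value from match counts
#'
#' @param A Cycles with estimates from both detectors.
#' @param B Matched cycles (`0 <= B <= A`).
#' @return `B / (2A - B)`, in `[0, 1]`; defined as 0 when `A == 0` (no
#'   detections is the worst quality state).
#' @examples
#' compute_tsqi(12, 8) # 0.5
#' @export
compute_tsqi <- function(A, B) {
  stopifnot(A >= 0, B >= 0)
  if (B > A) stop_tendos("bad_counts", "B cannot exceed A")
  if (A == 0) return(0)
  B / (2 * A - B)
}

# Resolve a detector argument: a name, or a function(rec, rp) -> tend_annotation.
resolve_detector <- function(det) {
  if (is.function(det)) return(det)
  det <- match.arg(det, c("zhang", "martinez", "carlos"))
  function(rec, rp, cfg = delineator_config()) delineate(rec, rp, det, cfg)
}

#' Per-cycle tSQI on a local segment
#'
#' Evaluates the tSQI of cycle `i` on the segment
#' `[R(i) - window_before, R(i) + window_after]` (clipped to the record):
#' both delineators are run on the segment using the R peaks inside it, and
#' their per-cycle agreement yields the index. Fewer than two R peaks in the
#' window defines tSQI = 0 (flagged as low quality).
#'
#' @param rec A preprocessed [ecg_record()].
#' @param rp An [rpeak_series()].
#' @param i Cycle index (1-based position in `rp`).
#' @param det1,det2 Detector names (`"zhang"`, `"martinez"`, `"carlos"`) or
#'   functions `(rec, rp, cfg)` returning a [tend_annotation()].
#' @param cfg A [quality_config()].
#' @param dcfg A [delineator_config()] forwarded to the detectors.
#' @return A list of class `tsqi_result` with fields `A`, `B`, `gamma_ms`,
#'   `value`, `flagged` (TRUE when the window held fewer than 2 R peaks) and
#'   `denoise` (`value < q`).
#' @export
cycle_tsqi <- function(rec, rp, i, det1 = "zhang", det2 = "martinez",
                       cfg = quality_config(), dcfg = delineator_config()) {
  stopifnot(inherits(rec, "ecg_record"), inherits(rp, "rpeak_series"),
            i >= 1L, i <= rp$n)
  lo <- max(1L, rp$indices[i] - cfg$window_before)
  hi <- min(rec$n_samples, rp$indices[i] + cfg$window_after)
  inside <- rp$indices >= lo & rp$indices <= hi
  if (sum(inside) < 2L) {
    return(structure(list(A = 0L, B = 0L, gamma_ms = cfg$gamma_ms, value = 0,
                          flagged = TRUE, denoise = 0 < cfg$q),
                     class = "tsqi_result"))
  }
  sub <- rec
  sub$samples <- rec$samples[lo:hi, , drop = FALSE]
  sub$n_samples <- hi - lo + 1L
  subrp <- rpeak_series(rp$indices[inside] - lo + 1L, rp$fs, rp$source)
  f1 <- resolve_detector(det1)
  f2 <- resolve_detector(det2)
  m <- match_tends(f1(sub, subrp, dcfg), f2(sub, subrp, dcfg), cfg$gamma_ms)
  val <- compute_tsqi(m$A, m$B)
  structure(list(A = m$A, B = m$B, gamma_ms = cfg$gamma_ms, value = val,
                 flagged = FALSE, denoise = val < cfg$q),
            class = "tsqi_result")
}

#' bSQI: agreement of two R-peak detectors
#'
#' Greedy one-to-one nearest matching within the grace period; with
#' `A = max(n1, n2)` total detections and `B` matches, returns
#' `B / (2A - B)`.
#'
#' @param r1,r2 Two [rpeak_series()] (or bare index vectors) on the same
#'   record at the same rate.
#' @param gamma_ms Grace period in ms.
#' @param fs Sampling rate, required when `r1`/`r2` are bare vectors.
#' @return The bSQI value in `[0, 1]`.
#' @export
compute_bsqi <- function(r1, r2, gamma_ms = 50, fs = NULL) {
  get_idx <- function(r) {
    if (inherits(r, "rpeak_series")) list(idx = r$indices, fs = r$fs)
    else list(idx = as.integer(round(r)), fs = fs)
  }
  a <- get_idx(r1); b <- get_idx(r2)
  if (is.null(a$fs) || is.null(b$fs))
    stop_tendos("bad_fs", "supply `fs` when passing bare index vectors")
  if (!isTRUE(all.equal(a$fs, b$fs)))
    stop_tendos("misaligned", "R-peak series have different sampling rates")
  n1 <- length(a$idx); n2 <- length(b$idx)
  A <- max(n1, n2)
  if (A == 0L) return(0)
  gamma_samp <- gamma_ms / 1000 * a$fs
  # all candidate pairs within gamma, accepted greedily by increasing distance
  pairs <- expand.grid(i = seq_len(n1), j = seq_len(n2))
  pairs$d <- abs(a$idx[pairs$i] - b$idx[pairs$j])
  pairs <- pairs[pairs$d < gamma_samp, , drop = FALSE]
  pairs <- pairs[order(pairs$d, pairs$i, pairs$j), , drop = FALSE]
  used_i <- logical(n1); used_j <- logical(n2)
  B <- 0L
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (!used_i[i] && !used_j[j]) {
      used_i[i] <- TRUE; used_j[j] <- TRUE
      B <- B + 1L
    }
  }
  B / (2 * A - B)
}
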