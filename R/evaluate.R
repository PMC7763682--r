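# Evaluation metrics: per-recording mean absolute detection error (ME),
# robust summaries across recordings/rounds (median, mean absolute deviation
# about the median, 2.5-97.5% quantile interval), and the paired Wilcoxon
# signed-rank test between pipeline variants.

#' Per-cycle T-end detection errors
#'
#' `error(i) = (est(i) - truth(i)) * 1000 / fs` in ms, over cycles where both
#' sides carry an estimate; cycles missing on either side are excluded and
#' counted. With a second estimate channel supplied, each cycle keeps the
#' error of whichever channel is closer to the truth (two-channel best-of
#' selection).
#'
#' @param est A [tend_annotation()] or integer index vector.
#' @param truth Ground-truth [tend_annotation()] or index vector, cycle-aligned
#'   with `est`.
#' @param fs Sampling rate (Hz); required when both inputs are bare vectors.
#' @param est2 Optional second-channel estimate for best-of selection.
#' @return Numeric vector of signed errors in ms, with attribute
#'   `"n_excluded"` (cycles missing on either side).
#' @export
detection_errors <- function(est, truth, fs = NULL, est2 = NULL) {
  get_idx <- function(x) {
    if (inherits(x, "tend_annotation")) list(idx = x$tend_indices, fs = x$fs)
    else list(idx = as.integer(round(x)), fs = fs)
  }
  e <- get_idx(est); tr <- get_idx(truth)
  if (is.null(e$fs)) e$fs <- tr$fs
  if (is.null(e$fs)) stop_tendos("bad_fs", "supply `fs` with bare index vectors")
  if (length(e$idx) != length(tr$idx))
    stop_tendos("misaligned", "estimate and truth are not cycle-aligned")
  err <- (e$idx - tr$idx) * 1000 / e$fs
  if (!is.null(est2)) {
    e2 <- get_idx(est2)
    err2 <- (e2$idx - tr$idx) * 1000 / e$fs
    pick2 <- !is.na(err2) & (is.na(err) | abs(err2) < abs(err))
    err[pick2] <- err2[pick2]
  }
  keep <- !is.na(err)
  if (!any(keep)) stop_tendos("no_overlap", "no cycle has both estimate and truth")
  structure(err[keep], n_excluded = sum(!keep))
}

#' Summarise per-recording mean-error values
#'
#' @param me_values Non-empty numeric vector of per-recording (or per-round)
#'   mean absolute errors, in ms.
#' @return A list of class `eval_summary`: `median_me`, `mad_me` (mean
#'   absolute deviation about the median -- the "median +/- MAD" convention
#'   of the tables, not the robust MAD estimator), `q2_5`, `q97_5`
#'   (empirical quantiles, linear interpolation) and `n`.
#' @examples
#' summarize_me(c(4, 8, 12)) # median 8, MAD (4 + 0 + 4)/3
#' @export
summarize_me <- function(me_values) {
  me_values <- as.numeric(me_values)
  if (length(me_values) == 0L || anyNA(me_values))
    stop_tendos("empty_input", "me_values must be non-empty and free of NA")
  med <- stats::median(me_values)
  structure(list(median_me = med,
                 mad_me = mean(abs(me_values - med)),
                 q2_5 = unname(stats::quantile(me_values, 0.025, type = 7)),
                 q97_5 = unname(stats::quantile(me_values, 0.975, type = 7)),
                 n = length(me_values)),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("ME summary over %d values: median %.2f +/- %.2f (MAD) ms, 2.5-97.5%% [%.2f, %.2f]\n",
              x$n, x$median_me, x$mad_me, x$q2_5, x$q97_5))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided; zero differences are dropped. The exact null distribution is
#' used for n <= 25: via the signed-rank distribution when the |differences|
#' are tie-free, and by full enumeration of the 2^n sign assignments of the
#' midranks when ties are present (n <= 20; beyond that, and for n > 25, the
#' normal approximation with continuity correction is used).
#'
#' @param a,b Paired numeric vectors of equal length (>= 5).
#' @return A list with `statistic` (V), `p_value`, and `n_effective`
#'   (pairs after dropping zeros). When all differences are zero the test is
#'   degenerate: p = 1 with a warning.
#' @export
paired_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 5L)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n_effective = 0L))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0L
  if (n <= 25L && !ties) {
    ht <- stats::wilcox.test(d, exact = TRUE, correct = TRUE)
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                n_effective = n))
  }
  if (n <= 20L && ties) {
    # exact permutation: null distribution of V over all sign assignments
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)
    p <- min(1, 2 * min(mean(sums <= V + 1e-9), mean(sums >= V - 1e-9)))
    return(list(statistic = V, p_value = p, n_effective = n))
  }
  ht <- suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_effective = n)
}
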