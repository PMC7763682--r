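# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so package functions do not
#' disturb the global random stream. A `NULL` seed evaluates the expression
#' under the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  n <- length(x)
  if (w == 1L || n == 0L) return(x)
  cs <- cumsum(c(0, x))
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Zero-phase IIR filtering with odd-reflection padding at both ends, so that
# long-time-constant filters (e.g. a 0.5 Hz Butterworth) do not leave edge
# transients inside the record.
zerophase_filter <- function(b, a, x, npad = NULL) {
  n <- length(x)
  if (is.null(npad)) npad <- min(n - 1L, 3L * max(length(a), length(b)) * 32L)
  npad <- max(0L, min(as.integer(npad), n - 1L))
  if (npad > 0L) {
    head_pad <- 2 * x[1L] - x[(npad + 1L):2L]
    tail_pad <- 2 * x[n] - x[(n - 1L):(n - npad)]
    xe <- c(head_pad, x, tail_pad)
  } else {
    xe <- x
  }
  y <- signal::filter(b, a, xe)
  y <- rev(signal::filter(b, a, rev(y)))
  as.numeric(y[(npad + 1L):(npad + n)])
}

# Full linear convolution via FFT, zero-padded to a highly composite length
# (fft on awkward prime lengths is orders of magnitude slower).
conv_full <- function(x, k) {
  nout <- length(x) + length(k) - 1L
  nfft <- stats::nextn(nout, c(2L, 3L, 5L))
  fx <- stats::fft(c(x, numeric(nfft - length(x))))
  fk <- stats::fft(c(k, numeric(nfft - length(k))))
  Re(stats::fft(fx * fk, inverse = TRUE))[seq_len(nout)] / nfft
}

# Same-length convolution with an explicit kernel centre: the 1-based kernel
# position `center` is treated as lag zero, i.e. the output at sample t is
# sum_u k[u] * x[t - (u - center)]. The input is odd-reflected at both ends so
# waves near the record boundary are still transformed.
conv_centered <- function(x, k, center) {
  n <- length(x)
  m <- length(k)
  stopifnot(n > m, center >= 1L, center <= m)
  npad <- m
  left <- 2 * x[1L] - x[(npad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xe <- c(left, x, right)
  full <- conv_full(xe, k)
  start <- npad + center - 1L
  full[start + seq_len(n)]
}

# Greatest common divisor (for rational resampling factors).
gcd <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

# Best small rational approximation p/q ~= r via continued fractions.
rational_approx <- function(r, max_den = 1024L) {
  stopifnot(r > 0)
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  x <- r
  repeat {
    a <- floor(x)
    p2 <- a * p1 + p0
    q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    frac <- x - a
    if (frac < 1e-12) break
    x <- 1 / frac
  }
  c(p = as.integer(p1), q = as.integer(q1))
}

stop_tendos <- function(kind, msg) {
  cond <- structure(
    class = c(paste0("tendos_", kind), "tendos_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}
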