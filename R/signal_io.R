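# Reading, writing and resampling ECG records and annotation series.
#
# Two record dialects are supported: a minimal WFDB subset (format-16 .hea/.dat
# pairs, the PhysioNet layout) and a fixed CSV dialect with a single header
# line "fs=<Hz>" followed by one comma-separated row per sample. Annotation
# series travel either as MIT-format binary annotation files or as CSV.
#
# Convention: sample indices are 1-based inside R objects (idiomatic R), and
# 0-based in every file written by the toolkit; readers shift on import. Use
# `one_based = TRUE` when importing third-party CSV annotations that already
# count from 1.

#' Construct an ECG record
#'
#' An `ecg_record` holds one or more uniformly sampled channels (in
#' millivolts) together with the sampling rate. Runs of up to 5 consecutive
#' non-finite samples are repaired by linear interpolation; longer runs abort,
#' so a record never carries non-finite values downstream.
#'
#' @param samples Numeric vector (one channel) or matrix with one column per
#'   channel and one row per sample.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_names Optional character vector of channel labels.
#' @param record_id Optional record identifier.
#' @return An object of class `ecg_record` with fields `samples` (matrix),
#'   `fs`, `n_samples`, `channel_names`, `record_id`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 1 * seq(0, 2, by = 1 / 250)), fs = 250)
#' rec$n_samples
#' @export
ecg_record <- function(samples, fs, channel_names = NULL, record_id = "record") {
  if (is.null(dim(samples))) samples <- matrix(as.numeric(samples), ncol = 1L)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_tendos("bad_fs", "`fs` must be a single positive number")
  if (nrow(samples) < 1L)
    stop_tendos("empty_signal", "record has zero-length signal")
  samples <- apply(samples, 2L, repair_nonfinite)
  samples <- as.matrix(samples)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ncol(samples)))
  stopifnot(length(channel_names) == ncol(samples))
  structure(
    list(samples = samples, fs = as.numeric(fs), n_samples = nrow(samples),
         channel_names = as.character(channel_names),
         record_id = as.character(record_id)),
    class = "ecg_record"
  )
}

# Linearly interpolate runs of <= 5 non-finite samples; abort on longer runs
# (we will not invent signal).
repair_nonfinite <- function(x) {
  bad <- !is.finite(x)
  if (!any(bad)) return(x)
  r <- rle(bad)
  if (any(r$lengths[r$values] > 5L))
    stop_tendos("nonfinite_run",
                "record contains a run of more than 5 non-finite samples")
  if (all(bad)) stop_tendos("nonfinite_run", "record is entirely non-finite")
  idx <- seq_along(x)
  stats::approx(idx[!bad], x[!bad], xout = idx, rule = 2)$y
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'> %d samples x %d channel(s) @ %g Hz (%.1f s)\n",
              x$record_id, x$n_samples, ncol(x$samples), x$fs,
              x$n_samples / x$fs))
  invisible(x)
}

#' Construct an annotation series
#'
#' A light container for ordered fiducial sample positions (R peaks or T
#' ends) tied to a sampling rate.
#'
#' @param indices Strictly increasing integer sample positions (1-based).
#' @param kind `"rpeak"` or `"tend"`.
#' @param fs Sampling rate (Hz) the indices refer to.
#' @param source Free-text provenance (detector name or `"manual"`).
#' @return An object of class `ann_series`.
#' @export
ann_series <- function(indices, kind = c("rpeak", "tend"), fs, source = "manual") {
  kind <- match.arg(kind)
  indices <- as.integer(round(indices))
  if (length(indices) && any(diff(indices) <= 0L))
    stop_tendos("non_monotone", "annotation indices must be strictly increasing")
  if (length(indices) && indices[1L] < 1L)
    stop_tendos("out_of_range", "annotation indices must be >= 1")
  if (!is.numeric(fs) || fs <= 0) stop_tendos("bad_fs", "fs must be positive")
  structure(list(indices = indices, kind = kind, fs = as.numeric(fs),
                 source = as.character(source)),
            class = "ann_series")
}

#' @export
print.ann_series <- function(x, ...) {
  cat(sprintf("<ann_series kind=%s> %d indices @ %g Hz (source: %s)\n",
              x$kind, length(x$indices), x$fs, x$source))
  invisible(x)
}

#' Read an ECG record from disk
#'
#' @param path Path to a `.csv` file or to a WFDB record (the `.hea` file, or
#'   the record name without extension).
#' @param format `"auto"` (by extension), `"csv"` or `"wfdb"`.
#' @return An [ecg_record()].
#' @seealso [write_ecg()]
#' @export
read_ecg <- function(path, format = c("auto", "csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  switch(format, csv = read_ecg_csv(path), wfdb = read_ecg_wfdb(path))
}

#' Write an ECG record to disk
#'
#' @param rec An [ecg_record()].
#' @param path Destination; for WFDB, the record name (with or without `.hea`).
#' @param format `"csv"` or `"wfdb"`. WFDB output uses format 16 (16-bit
#'   two's-complement, little-endian) with a fixed gain of 1000 adu/mV.
#' @return Invisibly, the path written.
#' @export
write_ecg <- function(rec, path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "ecg_record"))
  switch(format, csv = write_ecg_csv(rec, path), wfdb = write_ecg_wfdb(rec, path))
  invisible(path)
}

read_ecg_csv <- function(path) {
  if (!file.exists(path)) stop_tendos("missing_file", paste("file not found:", path))
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("^fs=([0-9.eE+-]+)\\s*$", trimws(header)))[[1L]]
  if (length(m) != 2L)
    stop_tendos("malformed_header",
                "CSV record must start with a header line 'fs=<Hz>'")
  fs <- as.numeric(m[2L])
  body <- readLines(path)[-1L]
  if (!any(nzchar(trimws(body))))
    stop_tendos("empty_signal", "CSV record has no samples")
  dat <- utils::read.csv(text = body, header = FALSE)
  ecg_record(as.matrix(dat), fs = fs,
             record_id = sub("\\.csv$", "", basename(path), ignore.case = TRUE))
}

write_ecg_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fs=%.10g", rec$fs), con)
  utils::write.table(format(rec$samples, digits = 10, trim = TRUE,
                            scientific = FALSE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

# --- Minimal WFDB subset: format-16 single-segment records ------------------

WFDB_GAIN <- 1000  # adu per mV on write

read_ecg_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop_tendos("missing_file", paste("file not found:", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop_tendos("malformed_header", "WFDB header too short")
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(top) < 4L)
    stop_tendos("malformed_header",
                "WFDB header line must be '<name> <nsig> <fs> <N>'")
  nsig <- as.integer(top[2L]); fs <- as.numeric(top[3L]); n <- as.integer(top[4L])
  if (is.na(nsig) || is.na(fs) || is.na(n))
    stop_tendos("malformed_header", "WFDB header fields are not numeric")
  if (n < 1L) stop_tendos("empty_signal", "WFDB record declares zero samples")
  sig_lines <- lines[2L:(1L + nsig)]
  gains <- numeric(nsig); baselines <- integer(nsig); descs <- character(nsig)
  dat_file <- NULL
  for (i in seq_len(nsig)) {
    f <- strsplit(trimws(sig_lines[i]), "\\s+")[[1L]]
    if (length(f) < 3L) stop_tendos("malformed_header", "bad WFDB signal line")
    if (f[2L] != "16")
      stop_tendos("unsupported_format",
                  paste("only WFDB format 16 is supported, got", f[2L]))
    dat_file <- f[1L]
    gm <- regmatches(f[3L], regexec("^([0-9.eE+-]+)(\\(([0-9+-]+)\\))?(/.*)?$",
                                    f[3L]))[[1L]]
    gains[i] <- as.numeric(gm[2L])
    baselines[i] <- if (nzchar(gm[4L])) as.integer(gm[4L]) else 0L
    if (!is.finite(gains[i]) || gains[i] == 0) gains[i] <- 200
    descs[i] <- if (length(f) >= 9L) paste(f[9L:length(f)], collapse = " ")
                else paste0("ch", i)
  }
  dat_path <- file.path(dirname(hea), dat_file)
  if (!file.exists(dat_path))
    stop_tendos("missing_file", paste("file not found:", dat_path))
  raw <- readBin(dat_path, what = "integer", n = n * nsig, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < n * nsig)
    stop_tendos("malformed_header", "WFDB .dat file shorter than declared")
  mat <- matrix(as.numeric(raw), ncol = nsig, byrow = TRUE)
  for (i in seq_len(nsig)) mat[, i] <- (mat[, i] - baselines[i]) / gains[i]
  ecg_record(mat, fs = fs, channel_names = descs, record_id = top[1L])
}

write_ecg_wfdb <- function(rec, path) {
  base <- sub("\\.hea$", "", path)
  name <- basename(base)
  nsig <- ncol(rec$samples)
  adc <- round(rec$samples * WFDB_GAIN)
  adc[adc > 32767] <- 32767
  adc[adc < -32768] <- -32768
  hea <- c(sprintf("%s %d %.10g %d", name, nsig, rec$fs, rec$n_samples),
           sprintf("%s.dat 16 %d(0)/mV 16 0 %d 0 0 %s",
                   name, WFDB_GAIN, as.integer(adc[1L, ]), rec$channel_names))
  writeLines(hea, paste0(base, ".hea"))
  interleaved <- as.integer(t(adc))
  writeBin(interleaved, paste0(base, ".dat"), size = 2L, endian = "little")
}

# --- Annotation files -------------------------------------------------------

#' Read an annotation series
#'
#' @param path Path to a `.csv` annotation file (toolkit dialect) or an
#'   MIT-format binary annotation file.
#' @param format `"auto"` (by extension), `"csv"` or `"wfdb_ann"`.
#' @param one_based Set `TRUE` when importing an external CSV whose indices
#'   already count from 1; toolkit files are 0-based on disk.
#' @return An [ann_series()].
#' @export
read_annotations <- function(path, format = c("auto", "csv", "wfdb_ann"),
                             one_based = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb_ann"
  if (!file.exists(path)) stop_tendos("missing_file", paste("file not found:", path))
  if (format == "csv") {
    header <- trimws(readLines(path, n = 1L))
    m <- regmatches(header,
                    regexec("^fs=([0-9.eE+-]+),kind=(\\w+),source=(.*)$", header))[[1L]]
    if (length(m) != 4L)
      stop_tendos("malformed_header",
                  "annotation CSV must start with 'fs=<Hz>,kind=<kind>,source=<text>'")
    body <- readLines(path)[-1L]
    body <- body[nzchar(trimws(body))]
    idx <- if (length(body)) as.integer(body) else integer(0)
    if (!one_based) idx <- idx + 1L
    ann_series(idx, kind = m[3L], fs = as.numeric(m[2L]), source = m[4L])
  } else {
    read_wfdb_ann(path)
  }
}

#' Write an annotation series
#'
#' CSV output is the toolkit dialect (0-based indices, one per row, header
#' `fs=<Hz>,kind=<kind>,source=<text>`); `wfdb_ann` writes an MIT-format
#' binary annotation file (beat code NORMAL for R peaks, waveform-offset code
#' for T ends).
#'
#' @param ann An [ann_series()].
#' @param path Destination path.
#' @param format `"csv"` or `"wfdb_ann"`.
#' @return Invisibly, the path.
#' @export
write_annotations <- function(ann, path, format = c("csv", "wfdb_ann")) {
  format <- match.arg(format)
  stopifnot(inherits(ann, "ann_series"))
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("fs=%.10g,kind=%s,source=%s", ann$fs, ann$kind, ann$source),
               con)
    if (length(ann$indices))
      writeLines(as.character(ann$indices - 1L), con)
  } else {
    write_wfdb_ann(ann, path)
  }
  invisible(path)
}

# MIT annotation format: stream of little-endian 16-bit words, each carrying a
# 6-bit type code (high bits) and a 10-bit time increment from the previous
# annotation. Increments above 1023 are carried by a SKIP (59) pseudo-code
# followed by a 32-bit interval stored PDP-11 style (high 16-bit word first,
# both words little-endian). The stream ends with a zero word.
ANN_CODE <- c(rpeak = 1L, tend = 40L)  # NORMAL beat; waveform offset ')'

write_wfdb_ann <- function(ann, path) {
  code <- ANN_CODE[[ann$kind]]
  times0 <- ann$indices - 1L          # 0-based on disk
  words <- integer(0)
  prev <- 0L
  for (t in times0) {
    inc <- t - prev
    prev <- t
    if (inc > 1023L) {
      hi <- inc %/% 65536L
      lo <- inc %% 65536L
      words <- c(words, bitwShiftL(59L, 10L), hi, lo)
      inc <- 0L
    }
    words <- c(words, bitwOr(bitwShiftL(code, 10L), inc))
  }
  words <- c(words, 0L)
  # writeBin() wants signed 16-bit values
  signed <- ifelse(words > 32767L, words - 65536L, words)
  writeBin(as.integer(signed), path, size = 2L, endian = "little")
}

read_wfdb_ann <- function(path) {
  nbytes <- file.info(path)$size
  raw <- readBin(path, what = "integer", n = nbytes / 2, size = 2L,
                 signed = FALSE, endian = "little")
  times0 <- integer(0)
  codes <- integer(0)
  t <- 0L
  i <- 1L
  pending_skip <- 0L
  while (i <= length(raw)) {
    w <- raw[i]
    if (w == 0L) break
    code <- bitwShiftR(w, 10L)
    inc <- bitwAnd(w, 1023L)
    if (code == 59L) {
      hi <- raw[i + 1L]; lo <- raw[i + 2L]
      pending_skip <- hi * 65536L + lo
      i <- i + 3L
      next
    }
    t <- t + inc + pending_skip
    pending_skip <- 0L
    times0 <- c(times0, t)
    codes <- c(codes, code)
    i <- i + 1L
  }
  kind <- if (length(codes) && codes[1L] == ANN_CODE[["tend"]]) "tend" else "rpeak"
  # fs is not stored in MIT annotation files; caller rescales via load_rpeaks()
  ann_series(times0 + 1L, kind = kind, fs = 250, source = "wfdb_ann")
}

#' Resample an ECG record
#'
#' Rational-factor polyphase resampling (e.g. 200 to 250 Hz uses the exact
#' 5:4 ratio), preserving total duration to within one sample period.
#'
#' @param rec An [ecg_record()].
#' @param target_fs Target sampling rate in Hz (> 0).
#' @return A new [ecg_record()] at `target_fs`.
#' @export
resample_record <- function(rec, target_fs) {
  stopifnot(inherits(rec, "ecg_record"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0)
    stop_tendos("bad_fs", "`target_fs` must be a single positive number")
  if (isTRUE(all.equal(target_fs, rec$fs))) return(rec)
  pq <- rational_approx(target_fs / rec$fs)
  g <- gcd(pq[["p"]], pq[["q"]])
  p <- pq[["p"]] / g; q <- pq[["q"]] / g
  out <- apply(rec$samples, 2L, function(x) resample_poly(x, p, q))
  ecg_record(as.matrix(out), fs = target_fs, channel_names = rec$channel_names,
             record_id = rec$record_id)
}

# Rational-factor polyphase resampling by p/q: zero-stuff by p, apply a
# linear-phase FIR lowpass at the tighter of the two Nyquist limits with the
# group delay compensated exactly, keep every q-th sample. The input is
# odd-reflected at both ends so the filter ramp stays outside the signal.
resample_poly <- function(x, p, q, taps_per_phase = 10L) {
  if (p == q) return(x)
  n <- length(x)
  half <- taps_per_phase * max(p, q)
  L <- 2L * half + 1L
  h <- signal::fir1(L - 1L, 1 / max(p, q)) * p
  npad <- min(n - 1L, ceiling(L / p) + 1L)
  xe <- c(2 * x[1L] - x[(npad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - npad)])
  xu <- numeric(length(xe) * p)
  xu[seq(1L, by = p, length.out = length(xe))] <- xe
  y <- conv_full(xu, h)
  # output grid: sample k (1-based) sits at upsampled position 1+(k-1)*q of
  # the unpadded signal, offset by the pad and the FIR group delay
  n_out <- ceiling(n * p / q)
  pos <- half + npad * p + 1L + (seq_len(n_out) - 1L) * q
  y[pos]
}
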