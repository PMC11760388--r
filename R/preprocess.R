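# ---- zero-phase IIR filtering -----------------------------------------------
#
# stats::filter runs the FIR and recursive parts in C. Steady-state initial
# conditions (the input is treated as constant at its first value for all
# t < 0) plus odd-reflection padding suppress the edge transients that make a
# naive forward-backward pass unusable for low cut-off high-pass filters.

# One causal IIR pass, steady-state initialised at x[1].
iir_filter_steady <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nn <- max(length(a), length(b))
  b <- c(b, rep(0, nn - length(b)))
  a <- c(a, rep(0, nn - length(a)))
  xpre <- c(rep(x[1], nn - 1), x)
  u <- stats::filter(xpre, b, method = "convolution", sides = 1)
  u <- as.numeric(u)[nn:(nn - 1 + length(x))]
  y0 <- x[1] * sum(b) / sum(a)
  y <- stats::filter(u, -a[-1], method = "recursive",
                     init = rep(y0, nn - 1))
  as.numeric(y)
}

# Zero-phase filtering: forward pass, reverse, second pass, reverse; the
# signal is extended by odd reflection about both end points first.
filtfilt_zero_phase <- function(b, a, x) {
  nn <- max(length(a), length(b))
  pad <- min(3L * (nn - 1L), length(x) - 1L)
  xe <- c(2 * x[1] - x[(pad + 1):2], x,
          2 * x[length(x)] - x[(length(x) - 1):(length(x) - pad)])
  y <- iir_filter_steady(b, a, xe)
  y <- rev(iir_filter_steady(b, a, rev(y)))
  y[(pad + 1):(pad + length(x))]
}

#' Band-pass filter an ECG signal
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass. The default
#' 0.5--40 Hz band removes baseline drift and high-frequency noise while
#' preserving the ECG passband.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling frequency in Hz.
#' @param low,high Band edges in Hz; requires `0 < low < high < fs/2`.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, fs, low = 0.5, high = 40) {
  if (!(low > 0 && low < high)) stop_af("need 0 < low < high")
  if (high >= fs / 2) stop_af("high (%.3g Hz) must be below Nyquist (%.3g Hz)",
                              high, fs / 2)
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  filtfilt_zero_phase(bf$b, bf$a, x)
}

# ---- resampling --------------------------------------------------------------

# Windowed-sinc anti-aliasing low-pass used by resample_signal.
resample_kernel <- function(p, q) {
  half <- 10L * max(p, q)
  m <- seq(-half, half)
  cutoff <- 1 / max(p, q)              # in units of the upsampled Nyquist
  h <- cutoff * sinc(cutoff * m)
  w <- 0.54 + 0.46 * cos(pi * m / half)          # Hamming window
  h * w * p
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Rational resampling x (at fs) -> target_fs: zero-stuff by p, FFT-convolve
# with the windowed-sinc kernel, take every q-th sample.
resample_signal <- function(x, fs, target_fs) {
  if (target_fs <= 0) stop_af("target_fs must be > 0")
  if (fs == target_fs) return(x)
  den <- round(fs * 1e6); num <- round(target_fs * 1e6)
  g <- pracma_gcd(num, den)
  p <- num / g; q <- den / g
  n <- length(x)
  xu <- numeric(n * p)
  xu[seq(1, by = p, length.out = n)] <- x
  h <- resample_kernel(p, q)
  half <- (length(h) - 1L) / 2L
  yfull <- fft_convolve(xu, h)
  yc <- yfull[(half + 1):(half + length(xu))]
  n_out <- ceiling(n * p / q)
  yc[seq(1, by = q, length.out = n_out)]
}

pracma_gcd <- function(a, b) { while (b != 0) { t <- b; b <- a %% b; a <- t }; a }

fft_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nf <- nextn(n, 2)
  X <- fft(c(x, numeric(nf - length(x))))
  H <- fft(c(h, numeric(nf - length(h))))
  Re(fft(X * H, inverse = TRUE))[seq_len(n)] / nf
}

#' Resample an ECG record to a uniform sampling rate
#'
#' Polyphase-style anti-aliased rational resampling (zero-stuffing, windowed
#' sinc low-pass, decimation). Identity when `fs == target_fs`.
#'
#' @param record An [ecg_record()].
#' @param target_fs Target sampling frequency in Hz (default 128).
#' @return The record resampled to `target_fs`.
#' @export
resample_record <- function(record, target_fs = 128) {
  stopifnot(inherits(record, "af_ecg_record"))
  if (target_fs <= 0) stop_af("target_fs must be > 0")
  if (record$fs == target_fs) return(record)
  record$signals <- lapply(record$signals, resample_signal,
                           fs = record$fs, target_fs = target_fs)
  record$fs <- target_fs
  record
}

# ---- z-scoring ---------------------------------------------------------------

# Population-sd z-score; constant input maps to zeros with a "constant" flag.
zscore_vector <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) {
    out <- numeric(length(x))
    attr(out, "constant") <- TRUE
    return(out)
  }
  (x - m) / s
}

#' Z-score normalize a segment
#'
#' Subtracts the mean and divides by the population (1/N) standard deviation.
#' A constant segment maps to all zeros and is flagged with attribute
#' `constant = TRUE`.
#'
#' @param x Numeric segment vector.
#' @return Normalized vector with `|mean| < 1e-6` and `|sd - 1| < 1e-6`
#'   (unless constant).
#' @export
zscore <- function(x) zscore_vector(x)

# ---- segmentation ------------------------------------------------------------

#' Cut a record into fixed-length labeled windows
#'
#' Windows of `window_s` seconds start at 0 and advance by
#' `window_s - overlap_s`; any remainder shorter than a full window is
#' discarded. Each window is labeled AF (1) when AF/AFL rhythm covers at
#' least 50% of its duration, given rhythm annotation intervals.
#'
#' @param record An [ecg_record()] (uses the analysis channel).
#' @param intervals Rhythm intervals as returned by
#'   [parse_rhythm_annotations()]; may be `NULL` for unlabeled segmentation.
#' @param window_s Window length in seconds.
#' @param overlap_s Window overlap in seconds (must be `< window_s`).
#' @return A list of segments; each is a list with `x` (raw samples), `fs`,
#'   `label` (0/1 or `NA`), `start_sample` (0-based offset) and `record_id`.
#' @export
segment_record <- function(record, intervals = NULL, window_s = 30,
                           overlap_s = 0) {
  stopifnot(inherits(record, "af_ecg_record"))
  if (overlap_s >= window_s) stop_af("overlap_s must be < window_s")
  fs <- record$fs
  x <- record$signals[[record$analysis_channel]]
  n <- length(x)
  wlen <- round(window_s * fs)
  step <- round((window_s - overlap_s) * fs)
  if (n < wlen) return(list())
  n_seg <- (n - wlen) %/% step + 1L
  lapply(seq_len(n_seg) - 1L, function(k) {
    s0 <- k * step                       # 0-based start offset
    lab <- if (is.null(intervals)) NA_integer_ else {
      label_window(intervals, s0, s0 + wlen)
    }
    list(x = x[(s0 + 1):(s0 + wlen)], fs = fs, label = lab,
         start_sample = s0, record_id = record$record_id)
  })
}

# Majority-duration rule: AF iff AF/AFL rhythm covers >= 50% of the window.
label_window <- function(intervals, start, end) {
  af_cover <- 0
  for (iv in intervals) {
    ov <- min(end, iv$end_sample) - max(start, iv$start_sample)
    if (ov > 0 && rhythm_to_binary(iv$rhythm_code) == 1L) af_cover <- af_cover + ov
  }
  as.integer(af_cover >= (end - start) / 2)
}

# ---- QRS detection -----------------------------------------------------------

moving_average <- function(x, n) {
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_along(x) - n %/% 2L - 1L)
  hi <- pmin(length(x), seq_along(x) + (n - n %/% 2L) - 1L)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Detect R peaks with a Pan-Tompkins style detector
#'
#' Pipeline: 5--15 Hz band-pass, differentiation, squaring, 150 ms
#' moving-window integration, then adaptive thresholding of envelope maxima
#' with a 250 ms refractory period. The R position is refined as the largest
#' absolute band-passed deflection near each envelope peak. All thresholds
#' scale with the signal, so detections are amplitude-scale invariant.
#'
#' @param x Numeric signal (at least 2 s long).
#' @param fs Sampling frequency in Hz.
#' @return Strictly increasing 1-based R-peak indices (empty for flat input).
#' @export
detect_qrs <- function(x, fs) {
  if (length(x) < 2 * fs) stop_af("signal must be at least 2 s long")
  if (all(x == x[1])) return(integer(0))
  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xb <- filtfilt_zero_phase(bf$b, bf$a, x)
  d <- c(0, diff(xb))
  sq <- d^2
  env <- moving_average(sq, max(3L, round(0.150 * fs)))

  n <- length(env)
  is_peak <- c(FALSE, env[2:(n - 1)] > env[1:(n - 2)] &
                 env[2:(n - 1)] >= env[3:n], FALSE)
  cand <- which(is_peak & env > 0)
  if (length(cand) == 0) return(integer(0))

  init <- env[seq_len(min(n, 2L * fs))]
  spki <- max(init)
  npki <- mean(init)
  refractory <- round(0.25 * fs)
  search <- round(0.10 * fs)
  last <- -Inf
  peaks <- integer(0)
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (env[i] > thr && (i - last) >= refractory) {
      lo <- max(1L, i - search); hi <- min(length(xb), i + search)
      r <- lo + which.max(abs(xb[lo:hi])) - 1L
      peaks <- c(peaks, r)
      last <- i
      spki <- 0.875 * spki + 0.125 * env[i]
    } else if (env[i] <= thr) {
      npki <- 0.875 * npki + 0.125 * env[i]
    }
  }
  sort(unique(peaks))
}

# Second, independent beat detector: local maxima of the 150 ms
# moving-average energy envelope, with the same refractory rule. The squared
# signal keeps the tall narrow QRS dominant over the broad low T wave.
detect_beats_envelope <- function(x, fs) {
  if (all(x == x[1])) return(integer(0))
  env <- moving_average((x - mean(x))^2, max(3L, round(0.150 * fs)))
  n <- length(env)
  is_peak <- c(FALSE, env[2:(n - 1)] > env[1:(n - 2)] &
                 env[2:(n - 1)] >= env[3:n], FALSE)
  cand <- which(is_peak)
  if (length(cand) == 0) return(integer(0))
  thr <- 0.25 * stats::quantile(env[cand], 0.9, names = FALSE)
  cand <- cand[env[cand] > thr]
  refractory <- round(0.25 * fs)
  peaks <- integer(0); last <- -Inf
  for (i in cand[order(-env[cand])]) {
    if (all(abs(i - peaks) >= refractory)) peaks <- c(peaks, i)
  }
  sort(peaks)
}

# ---- bSQI --------------------------------------------------------------------

#' Beat signal-quality index of a segment
#'
#' Agreement between two independent beat detectors (the Pan-Tompkins style
#' detector and an envelope-maxima detector), matched greedily one-to-one
#' within `tolerance_ms`:
#' `bsqi = n_matched / (n_a + n_b - n_matched)`.
#' When both detectors find nothing the index is 0 and flagged.
#' The matching tolerance in samples is `ceiling(tolerance_ms / 1000 * fs)`.
#'
#' @param x Numeric segment (band-passed, pre-normalization).
#' @param fs Sampling frequency in Hz.
#' @param tolerance_ms Matching tolerance in milliseconds.
#' @return A list of class `af_quality_report`: `bsqi`,
#'   `n_beats_detector_a`, `n_beats_detector_b`, `n_matched`, `flag`.
#' @export
compute_bsqi <- function(x, fs, tolerance_ms = 150) {
  a <- detect_qrs(x, fs)
  b <- detect_beats_envelope(x, fs)
  tol <- ceiling(tolerance_ms / 1000 * fs)
  m <- match_beats(a, b, tol)
  flag <- length(a) == 0 && length(b) == 0
  bsqi <- if (length(a) + length(b) == 0) 0 else {
    m / (length(a) + length(b) - m)
  }
  structure(
    list(bsqi = bsqi, n_beats_detector_a = length(a),
         n_beats_detector_b = length(b), n_matched = m, flag = flag),
    class = "af_quality_report"
  )
}

# Greedy one-to-one matching: each a-beat takes the nearest unmatched b-beat
# within tolerance, in temporal order.
match_beats <- function(a, b, tol) {
  used <- rep(FALSE, length(b))
  m <- 0L
  for (ai in a) {
    if (length(b) == 0) break
    d <- abs(b - ai)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol) {
      used[j] <- TRUE
      m <- m + 1L
    }
  }
  m
}

#' Filter segments by signal quality
#'
#' Keeps exactly the segments whose bSQI is at least `threshold`; a dropped
#' primary segment drops its paired-lead segment as well.
#'
#' @param store A [segment_store()].
#' @param threshold Minimum bSQI (default 0.8).
#' @return The filtered store, with attribute `bsqi` giving the per-segment
#'   index values of the input.
#' @export
quality_filter <- function(store, threshold = 0.8) {
  stopifnot(inherits(store, "af_segment_store"))
  n <- nrow(store$segments)
  bsqi <- vapply(seq_len(n), function(i) {
    compute_bsqi(store$segments[i, ], store$fs)$bsqi
  }, numeric(1))
  keep <- bsqi >= threshold
  out <- subset_store(store, keep)
  attr(out, "bsqi") <- bsqi
  out
}

#' Run the full preprocessing pipeline on a record
#'
#' Fixed order: resample to `target_fs`, band-pass 0.5--40 Hz, segment into
#' windows, label from rhythm annotations, z-score, then drop segments with
#' bSQI below the threshold (bSQI is computed on the band-passed,
#' pre-normalization samples).
#'
#' @param record An [ecg_record()].
#' @param intervals Rhythm intervals or `NULL`.
#' @param target_fs Target sampling rate (Hz).
#' @param window_s,overlap_s Segmentation window and overlap (seconds).
#' @param bsqi_threshold Quality threshold; segments below it are excluded.
#' @return A [segment_store()] of surviving z-scored segments (primary and
#'   paired lead).
#' @export
preprocess_record <- function(record, intervals = NULL, target_fs = 128,
                              window_s = 30, overlap_s = 0,
                              bsqi_threshold = 0.8) {
  stopifnot(inherits(record, "af_ecg_record"))
  rec <- resample_record(record, target_fs)
  rec$signals <- lapply(rec$signals, bandpass, fs = rec$fs)
  segs <- segment_record(rec, intervals, window_s, overlap_s)
  if (length(segs) == 0) {
    return(segment_store(matrix(0, 0, round(window_s * target_fs)),
                         matrix(0, 0, round(window_s * target_fs)),
                         labels = integer(0), fs = target_fs))
  }
  pair_ch <- rec$paired_channel
  xp <- if (!is.na(pair_ch)) rec$signals[[pair_ch]] else NULL
  wlen <- round(window_s * target_fs)
  raw <- t(vapply(segs, function(s) s$x, numeric(wlen)))
  paired <- if (is.null(xp)) raw else {
    t(vapply(segs, function(s) xp[(s$start_sample + 1):(s$start_sample + wlen)],
             numeric(wlen)))
  }
  labels <- vapply(segs, function(s) s$label, integer(1))
  bsqi <- vapply(seq_len(nrow(raw)), function(i) {
    compute_bsqi(raw[i, ], target_fs)$bsqi
  }, numeric(1))
  keep <- bsqi >= bsqi_threshold
  znorm <- function(m) {
    if (nrow(m) == 0) return(m)
    t(apply(m, 1, function(r) as.numeric(zscore_vector(r))))
  }
  store <- segment_store(
    segments = znorm(raw[keep, , drop = FALSE]),
    paired_segments = znorm(paired[keep, , drop = FALSE]),
    labels = if (all(is.na(labels))) NULL else labels[keep],
    fs = target_fs,
    provenance = tibble::tibble(
      record_id = vapply(segs, function(s) s$record_id, character(1))[keep],
      start_sample = vapply(segs, function(s) s$start_sample, numeric(1))[keep]
    )
  )
  attr(store, "bsqi") <- bsqi
  store
}
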