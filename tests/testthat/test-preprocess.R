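test_that("resampling preserves length arithmetic and passband tones", {
  x <- sin(2 * pi * 5 * (0:2499) / 250)
  rec <- ecg_record(list(x, x * 0.5), fs = 250)
  out <- resample_record(rec, 128)
  expect_identical(length(out$signals[[1]]), 1280L)   # 2500*128/250
  expect_identical(out$fs, 128)

  # identity at matching rate is bit-exact
  rec128 <- ecg_record(list(x), fs = 128)
  expect_identical(resample_record(rec128, 128), rec128)

  # 5 Hz tone at 360 Hz survives with amplitude within 1%
  x5 <- sin(2 * pi * 5 * (0:3599) / 360)
  y <- resample_record(ecg_record(list(x5, x5), 360), 128)$signals[[1]]
  mid <- 100:(length(y) - 100)
  amp <- sqrt(2 * mean(y[mid]^2))
  expect_lt(abs(amp - 1), 0.01)

  expect_error(resample_record(rec, -1), "target_fs")
})

test_that("band-pass rejects DC, passes 10 Hz, stops 60 Hz", {
  dc <- bandpass(rep(3, 3840), 128)
  expect_lt(max(abs(dc)), 1e-3 * 3)

  s10 <- sin(2 * pi * 10 * (0:3839) / 128)
  y10 <- bandpass(s10, 128)
  expect_lt(abs(sqrt(mean(y10^2)) / sqrt(mean(s10^2)) - 1), 0.05)

  s60 <- sin(2 * pi * 60 * (0:3839) / 128)
  expect_lt(sqrt(mean(bandpass(s60, 128)^2)), 0.1)

  expect_error(bandpass(s10, 128, high = 70), "Nyquist")
})

test_that("segmentation window counts match exhaustive enumeration", {
  mk <- function(len_s, fs = 128) {
    ecg_record(list(numeric(round(len_s * fs)), numeric(round(len_s * fs))),
               fs = fs)
  }
  expect_length(segment_record(mk(100), NULL, 30, 0), 3)
  starts <- vapply(segment_record(mk(100), NULL, 30, 0), `[[`, numeric(1),
                   "start_sample")
  expect_identical(starts, c(0, 30, 60) * 128)
  expect_length(segment_record(mk(100), NULL, 30, 15), 5)
  expect_length(segment_record(mk(29), NULL, 30, 0), 0)

  # formula vs sliding-window enumeration on 100 random cases
  set.seed(20)
  for (rep in 1:100) {
    len_s <- runif(1, 5, 400)
    overlap <- sample(c(0, 15), 1)
    fs <- 128
    n <- round(len_s * fs)
    wlen <- 30 * fs
    step <- (30 - overlap) * fs
    oracle <- 0L
    s0 <- 0L
    while (s0 + wlen <= n) { oracle <- oracle + 1L; s0 <- s0 + step }
    expect_length(segment_record(mk(len_s), NULL, 30, overlap), oracle)
  }
})

test_that("windows are labeled by majority AF coverage", {
  fs <- 128
  rec <- ecg_record(list(numeric(90 * fs), numeric(90 * fs)), fs = fs)
  # AF covers [0, 40 s): window 0-30 fully AF, window 30-60 one third AF,
  # window 60-90 non-AF
  iv <- parse_rhythm_annotations(
    data.frame(sample = c(0, 40 * fs), aux = c("(AFIB", "(N")), 90 * fs)
  labs <- vapply(segment_record(rec, iv, 30, 0), `[[`, integer(1), "label")
  expect_identical(labs, c(1L, 0L, 0L))
  # exactly 50% coverage counts as AF (boundary of the majority rule)
  iv2 <- parse_rhythm_annotations(
    data.frame(sample = c(0, 45 * fs), aux = c("(AFIB", "(N")), 90 * fs)
  labs2 <- vapply(segment_record(rec, iv2, 30, 0), `[[`, integer(1), "label")
  expect_identical(labs2[2], 1L)
  # a window fully inside one interval inherits its binary code
  expect_identical(labs2[1], rhythm_to_binary("AFIB"))
  expect_identical(labs2[3], rhythm_to_binary("N"))
})

test_that("z-scoring uses population sd and guards constants", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-12)
  z <- zscore(c(5, 5, 5))
  expect_identical(as.numeric(z), c(0, 0, 0))
  expect_true(attr(z, "constant"))
  set.seed(5)
  x <- rnorm(1000, 3, 7)
  zx <- zscore(x)
  expect_lt(abs(mean(zx)), 1e-6)
  expect_lt(abs(sqrt(mean((zx - mean(zx))^2)) - 1), 1e-6)
})

test_that("QRS detection is accurate, scale-invariant, and safe on flats", {
  hits <- 0; total <- 0
  for (s in 1:5) {
    rec <- synthesize_record(synthetic_record_spec(
      if (s %% 2) "non-AF" else "AF", noise_sd = 0, seed = s))
    det <- detect_qrs(rec$signals$lead1, 128)
    tol <- round(0.04 * 128)
    hits <- hits + sum(vapply(rec$r_peaks, function(r) {
      any(abs(det - r) <= tol)
    }, logical(1)))
    total <- total + length(rec$r_peaks)
    # every detection is near a true beat
    expect_true(all(vapply(det, function(d) {
      any(abs(rec$r_peaks - d) <= tol)
    }, logical(1))))
    # amplitude-scale invariance
    expect_identical(det, detect_qrs(2 * rec$signals$lead1, 128))
  }
  expect_gte(hits / total, 0.99)

  expect_identical(detect_qrs(numeric(3840), 128), integer(0))
  expect_error(detect_qrs(numeric(100), 128), "2 s")
})

test_that("bSQI matching follows the agreement formula", {
  ns <- asNamespace("afcontrast")
  # brute-force matcher oracle on the documented example
  a <- c(100, 500, 900); b <- c(110, 520, 1300)
  tol <- ceiling(0.150 * 128)
  m <- ns$match_beats(a, b, tol)
  expect_identical(m, 2L)
  expect_equal(m / (length(a) + length(b) - m), 0.5)

  # greedy matching is one-to-one: duplicated b beats match once
  expect_identical(ns$match_beats(c(100, 104), c(102), tol), 1L)

  # random matching cases vs exhaustive assignment bound
  set.seed(8)
  for (rep in 1:20) {
    a <- sort(sample(2000, 8))
    b <- sort(sample(2000, 8))
    m <- ns$match_beats(a, b, 20)
    pairs <- sum(outer(a, b, function(x, y) abs(x - y) <= 20))
    expect_lte(m, min(length(a), length(b)))
    expect_lte(m, pairs)
    if (pairs == 0) expect_identical(m, 0L)
  }

  rec <- synthesize_record(synthetic_record_spec("non-AF", seed = 1))
  q <- compute_bsqi(bandpass(rec$signals$lead1, 128), 128)
  expect_s3_class(q, "af_quality_report")
  expect_gte(q$bsqi, 0)
  expect_lte(q$bsqi, 1)
  expect_lte(q$n_matched, min(q$n_beats_detector_a, q$n_beats_detector_b))

  qf <- compute_bsqi(numeric(3840), 128)
  expect_identical(qf$bsqi, 0)
  expect_true(qf$flag)
})

test_that("quality filtering keeps clean segments and drops corrupted ones", {
  ds <- make_synthetic_dataset(12, 0, seed = 31, noise_sd = 0.05)
  # re-create raw band-passed segments for filtering
  kept <- quality_filter(ds$labeled, threshold = 0.8)
  bsqi <- attr(kept, "bsqi")
  expect_identical(nrow(kept$segments), sum(bsqi >= 0.8))
  expect_gte(mean(bsqi >= 0.8), 0.99)         # clean set survives

  # half the samples replaced by strong noise: most segments fail
  noisy <- ds$labeled
  set.seed(9)
  for (i in seq_len(nrow(noisy$segments))) {
    idx <- sample(ncol(noisy$segments), ncol(noisy$segments) / 2)
    noisy$segments[i, idx] <- rnorm(length(idx), 0, 2)
  }
  kept_n <- quality_filter(noisy, threshold = 0.8)
  expect_lt(nrow(kept_n$segments) / nrow(noisy$segments), 0.5)
  # paired lead dropped together with its primary
  expect_identical(dim(kept_n$segments), dim(kept_n$paired_segments))
})

test_that("full preprocessing pipeline is deterministic end to end", {
  rec <- synthesize_record(synthetic_record_spec("AF", duration_s = 65,
                                                 seed = 12))
  er <- ecg_record(list(rec$signals$lead1, rec$signals$lead2), fs = 128,
                   lead_names = c("I", "II"), record_id = "synth")
  iv <- parse_rhythm_annotations(data.frame(sample = 0, aux = "(AFIB"),
                                 length(rec$signals$lead1))
  st1 <- preprocess_record(er, iv, window_s = 30, overlap_s = 15)
  st2 <- preprocess_record(er, iv, window_s = 30, overlap_s = 15)
  expect_identical(st1$segments, st2$segments)
  expect_identical(st1$labels, rep(1L, nrow(st1$segments)))
  expect_identical(ncol(st1$segments), 3840L)
  # z-scored output
  expect_lt(max(abs(rowMeans(st1$segments))), 1e-6)
})
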