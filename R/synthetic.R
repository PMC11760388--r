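#' Specification of a synthetic dual-lead ECG record
#'
#' Describes one simulated record used to exercise the full pipeline without
#' any PhysioNet download. Two rhythm classes are supported: `"non-AF"`
#' (regular RR intervals, visible P wave) and `"AF"` (irregular RR intervals,
#' absent P wave, superimposed fibrillatory oscillation in the 4--9 Hz band).
#'
#' Class-dependent defaults enforce the rhythm morphology: a non-AF record has
#' `f_wave_amplitude = 0`, an AF record has `p_wave_amplitude = 0`.
#'
#' @param rhythm_class `"AF"` or `"non-AF"`.
#' @param duration_s Record duration in seconds (> 0).
#' @param fs Sampling frequency in Hz.
#' @param mean_rr_s Mean RR interval in seconds (> 0.25).
#' @param rr_variability Coefficient of variation of RR intervals for the
#'   non-AF truncated-normal RR law. AF records use a truncated uniform law
#'   over `mean_rr_s * c(0.6, 1.4)` regardless of this value.
#' @param p_wave_amplitude P-wave amplitude (arbitrary units, R peak = 1 by
#'   default). Forced to 0 for AF.
#' @param f_wave_amplitude Fibrillatory-wave amplitude. Forced to 0 for
#'   non-AF.
#' @param f_wave_freq_hz Fibrillatory-wave frequency in Hz (physiological
#'   band 4--9 Hz).
#' @param r_amplitude R-wave amplitude (arbitrary units).
#' @param noise_sd Standard deviation of additive Gaussian noise per lead.
#' @param lead_gain_2 Multiplicative gain of the second lead.
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   records.
#' @return An object of class `af_synth_spec` (a named list).
#' @export
#' @examples
#' spec <- synthetic_record_spec("AF", seed = 1)
#' rec <- synthesize_record(spec)
#' length(rec$signals$lead1)
synthetic_record_spec <- function(rhythm_class = c("non-AF", "AF"),
                                  duration_s = 30,
                                  fs = 128,
                                  mean_rr_s = 0.8,
                                  rr_variability = 0.05,
                                  p_wave_amplitude = 0.15,
                                  f_wave_amplitude = 0.1,
                                  f_wave_freq_hz = 6,
                                  r_amplitude = 1.0,
                                  noise_sd = 0.02,
                                  lead_gain_2 = 0.7,
                                  seed = 1L) {
  rhythm_class <- match.arg(rhythm_class)
  if (duration_s <= 0) stop_af("duration_s must be > 0")
  if (fs <= 0) stop_af("fs must be > 0")
  if (rr_variability < 0) stop_af("rr_variability must be >= 0")
  if (mean_rr_s <= 0.25) stop_af("invalid spec: mean_rr_s must exceed 0.25 s")
  if (rhythm_class == "non-AF") f_wave_amplitude <- 0
  if (rhythm_class == "AF") p_wave_amplitude <- 0
  structure(
    list(
      rhythm_class = rhythm_class, duration_s = duration_s, fs = fs,
      mean_rr_s = mean_rr_s, rr_variability = rr_variability,
      p_wave_amplitude = p_wave_amplitude,
      f_wave_amplitude = f_wave_amplitude,
      f_wave_freq_hz = f_wave_freq_hz, r_amplitude = r_amplitude,
      noise_sd = noise_sd, lead_gain_2 = lead_gain_2,
      seed = as.integer(seed)
    ),
    class = "af_synth_spec"
  )
}

#' Draw an RR-interval sequence for a synthetic record
#'
#' Non-AF intervals come from a normal distribution with mean `mean_rr_s` and
#' standard deviation `rr_variability * mean_rr_s`, truncated below at
#' 0.25 s. AF intervals come from a uniform distribution on
#' `mean_rr_s * c(0.6, 1.4)` (coefficient of variation 0.4/sqrt(3), about
#' 0.23), also truncated at 0.25 s. Intervals are drawn until their sum
#' covers `duration_s`.
#'
#' @param spec An [synthetic_record_spec()] object.
#' @return Numeric vector of RR intervals in seconds.
#' @export
generate_rr_sequence <- function(spec) {
  stopifnot(inherits(spec, "af_synth_spec"))
  withr::with_seed(spec$seed, {
    draw <- function(n) {
      if (spec$rhythm_class == "AF") {
        lo <- max(0.25, spec$mean_rr_s * 0.6)
        runif(n, lo, spec$mean_rr_s * 1.4)
      } else {
        x <- rnorm(n, spec$mean_rr_s, spec$rr_variability * spec$mean_rr_s)
        # truncation at the physiological floor: redraw anything below 0.25 s
        while (any(bad <- x < 0.25)) {
          x[bad] <- rnorm(sum(bad), spec$mean_rr_s,
                          spec$rr_variability * spec$mean_rr_s)
        }
        x
      }
    }
    n_guess <- ceiling(spec$duration_s / spec$mean_rr_s) + 8L
    rr <- draw(n_guess)
    while (sum(rr) < spec$duration_s) rr <- c(rr, draw(8L))
    rr[seq_len(which(cumsum(rr) >= spec$duration_s)[1])]
  })
}

# Add a Gaussian bump of amplitude `amp`, center `center_s` (seconds) and
# width `sigma_s` to `sig` sampled at `fs`; evaluated out to 4 sigma.
add_bump <- function(sig, fs, center_s, amp, sigma_s) {
  n <- length(sig)
  i0 <- max(1L, floor((center_s - 4 * sigma_s) * fs) + 1L)
  i1 <- min(n, ceiling((center_s + 4 * sigma_s) * fs) + 1L)
  if (i0 > i1) return(sig)
  tt <- (seq(i0, i1) - 1) / fs
  sig[i0:i1] <- sig[i0:i1] + amp * exp(-(tt - center_s)^2 / (2 * sigma_s^2))
  sig
}

# Wave template offsets (s), amplitudes (relative) and widths (s) per beat.
beat_waves <- function(spec, t_amp_scale = 1) {
  list(
    p = list(dt = -0.16, amp = spec$p_wave_amplitude, sigma = 0.03),
    q = list(dt = -0.04, amp = -0.15 * spec$r_amplitude, sigma = 0.02),
    r = list(dt = 0.00, amp = spec$r_amplitude, sigma = 0.02),
    s = list(dt = 0.04, amp = -0.20 * spec$r_amplitude, sigma = 0.02),
    t = list(dt = 0.20, amp = 0.30 * spec$r_amplitude * t_amp_scale,
             sigma = 0.05)
  )
}

#' Synthesize a dual-lead ECG record with known R peaks
#'
#' Each beat is a superposition of Gaussian bumps for the P, Q, R, S and T
#' waves positioned relative to the R peak (P at -0.16 s for non-AF only,
#' Q at -0.04 s, R at 0, S at +0.04 s, T at +0.20 s). AF records add a
#' fibrillatory sinusoid `f_wave_amplitude * sin(2*pi*f_wave_freq_hz*t)` with
#' an independently jittered phase per beat interval, and have no P wave.
#' Lead 2 shares the R-peak timing exactly but differs in morphology: it is
#' `lead_gain_2` times the wave superposition with the T-wave amplitude
#' halved, plus its own independent noise draw.
#'
#' @param spec An [synthetic_record_spec()] object.
#' @return An object of class `af_synth_record`: list with `signals`
#'   (`lead1`, `lead2`), `fs`, `r_peaks` (1-based sample indices, shared by
#'   both leads), `rhythm_class` and `spec`.
#' @export
synthesize_record <- function(spec) {
  stopifnot(inherits(spec, "af_synth_spec"))
  fs <- spec$fs
  n <- round(spec$duration_s * fs)
  rr <- generate_rr_sequence(spec)
  r_times <- 0.35 + c(0, cumsum(rr))
  r_idx <- round(r_times * fs)                       # 0-based grid positions
  min_gap <- ceiling(0.25 * fs)
  for (k in seq_along(r_idx)[-1]) {
    r_idx[k] <- max(r_idx[k], r_idx[k - 1] + min_gap)
  }
  r_idx <- r_idx[r_idx <= n - 1L]
  r_sec <- r_idx / fs

  render <- function(t_amp_scale) {
    sig <- numeric(n)
    w <- beat_waves(spec, t_amp_scale)
    for (tc in r_sec) {
      for (wave in w) {
        if (wave$amp != 0) sig <- add_bump(sig, fs, tc + wave$dt, wave$amp,
                                           wave$sigma)
      }
    }
    sig
  }

  seeds <- derive_seeds(spec$seed, 3L, salt = 7L)
  waves1 <- render(1)
  waves2 <- render(0.5)

  fwave <- numeric(n)
  if (spec$f_wave_amplitude > 0) {
    tt <- (seq_len(n) - 1) / fs
    phases <- withr::with_seed(seeds[1],
                               runif(length(r_sec), 0, 2 * pi))
    # piecewise-constant phase: jitter re-drawn at each beat
    seg <- pmax(1L, pmin(findInterval(tt, r_sec) + 1L, length(phases)))
    fwave <- spec$f_wave_amplitude *
      sin(2 * pi * spec$f_wave_freq_hz * tt + phases[seg])
  }

  noise1 <- if (spec$noise_sd > 0) {
    withr::with_seed(seeds[2], rnorm(n, 0, spec$noise_sd))
  } else numeric(n)
  noise2 <- if (spec$noise_sd > 0) {
    withr::with_seed(seeds[3], rnorm(n, 0, spec$noise_sd))
  } else numeric(n)

  lead1 <- waves1 + fwave + noise1
  lead2 <- spec$lead_gain_2 * (waves2 + fwave) + noise2

  structure(
    list(
      signals = list(lead1 = lead1, lead2 = lead2),
      fs = fs,
      r_peaks = r_idx + 1L,                          # 1-based indices
      rhythm_class = spec$rhythm_class,
      spec = spec
    ),
    class = "af_synth_record"
  )
}

#' Generate a labeled + unlabeled synthetic segment-pair dataset
#'
#' Produces 30 s dual-lead segment pairs at `fs`, z-scored per lead, with
#' exact class balance `round(af_fraction * n)` AF segments in each set and
#' ground-truth R-peak positions retained for augmentation. The labeled and
#' unlabeled sets use disjoint random streams derived from `seed`.
#'
#' @param n_labeled,n_unlabeled Number of segment pairs per set.
#' @param af_fraction Fraction of AF segments in each set.
#' @param fs Sampling frequency in Hz.
#' @param seed Integer seed.
#' @param duration_s Segment duration in seconds.
#' @param noise_sd Per-lead additive noise standard deviation.
#' @return List with elements `labeled` and `unlabeled`, each a
#'   [segment_store()]; the unlabeled store has `labels = NULL`.
#' @export
make_synthetic_dataset <- function(n_labeled, n_unlabeled,
                                   af_fraction = 0.5, fs = 128, seed = 1L,
                                   duration_s = 30, noise_sd = 0.02) {
  stopifnot(n_labeled >= 0, n_unlabeled >= 0,
            af_fraction >= 0, af_fraction <= 1)
  build <- function(n, salt, with_labels) {
    t0 <- round(duration_s * fs)
    segs <- matrix(0, n, t0)
    paired <- matrix(0, n, t0)
    labels <- integer(n)
    rpk <- vector("list", n)
    if (n > 0) {
      n_af <- round(af_fraction * n)
      cls <- c(rep(1L, n_af), rep(0L, n - n_af))
      cls <- withr::with_seed(derive_seeds(seed, 1L, salt = salt + 100L),
                              sample(cls))
      seeds <- derive_seeds(seed, n, salt = salt)
      for (i in seq_len(n)) {
        spec <- synthetic_record_spec(
          rhythm_class = if (cls[i] == 1L) "AF" else "non-AF",
          duration_s = duration_s, fs = fs, noise_sd = noise_sd,
          seed = seeds[i]
        )
        rec <- synthesize_record(spec)
        segs[i, ] <- zscore_vector(rec$signals$lead1)
        paired[i, ] <- zscore_vector(rec$signals$lead2)
        labels[i] <- cls[i]
        rpk[[i]] <- rec$r_peaks
      }
    }
    segment_store(
      segments = segs, paired_segments = paired,
      labels = if (with_labels) labels else NULL,
      fs = fs, r_peaks = rpk,
      provenance = tibble::tibble(
        record_id = sprintf("synth-%s-%04d",
                            if (with_labels) "lab" else "unl",
                            seq_len(n)),
        start_sample = rep(0L, n)
      )
    )
  }
  list(
    labeled = build(n_labeled, salt = 11L, with_labels = TRUE),
    unlabeled = build(n_unlabeled, salt = 23L, with_labels = FALSE)
  )
}
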