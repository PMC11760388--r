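#' Augmentation configuration
#'
#' Settings of the domain-knowledge augmentation used for the strong view:
#' T-wave masking of `mask_fraction_c`% of beats (non-diagnostic region)
#' always, followed by vertical flipping (diagnostic region) with
#' probability `flip_probability`.
#'
#' @param mask_fraction_c Percentage of beats whose ST interval is masked
#'   (0--100, default 50).
#' @param mask_fill_value Value the masked region is set to; 0 is the
#'   post-z-score baseline.
#' @param flip_probability Probability of applying the vertical flip per
#'   sample (default 0.5).
#' @param seed Integer seed.
#' @return An object of class `af_augment_config`.
#' @export
augmentation_config <- function(mask_fraction_c = 50, mask_fill_value = 0,
                                flip_probability = 0.5, seed = 1L) {
  stopifnot(mask_fraction_c >= 0, mask_fraction_c <= 100,
            flip_probability >= 0, flip_probability <= 1)
  structure(list(mask_fraction_c = mask_fraction_c,
                 mask_fill_value = mask_fill_value,
                 flip_probability = flip_probability,
                 seed = as.integer(seed)),
            class = "af_augment_config")
}

#' Vertical flip (diagnostic-region augmentation)
#'
#' Elementwise negation `x_tilde = -x`; exploits the vertical symmetry of
#' P/QRS morphology to generate a hard positive without confusing P and f
#' waves. An involution.
#'
#' @param x Numeric segment.
#' @return The negated segment.
#' @export
vertical_flip <- function(x) -x

# Mask window of one beat, 1-based half-open [r + floor(0.05 fs),
# r + floor(0.30 fs)) relative to the R sample r, clipped to the segment.
t_mask_window <- function(r, fs, n) {
  lo <- r + floor(0.05 * fs)
  hi <- r + floor(0.30 * fs) - 1L
  if (lo > n) return(integer(0))
  seq(max(1L, lo), min(n, hi))
}

#' T-wave masking (non-diagnostic-region augmentation)
#'
#' Sets the ST interval -- the region from 50 ms to 300 ms after the R
#' wave -- of `c`% of the beats to a fixed value, removing T-wave
#' information so the encoder concentrates on the diagnostic P/QRS regions.
#' Exactly `round(c/100 * n_beats)` beats are selected uniformly without
#' replacement; windows are clipped at the segment end. The QRS
#' neighbourhood `[R - 50 ms, R + 50 ms)` is never touched.
#'
#' @param x Numeric segment.
#' @param r_peaks 1-based R-peak sample indices within the segment.
#' @param fs Sampling frequency in Hz.
#' @param c Percentage of beats to mask (0--100).
#' @param fill Fill value (default 0).
#' @param seed Integer seed for the beat selection.
#' @return The masked segment. With empty `r_peaks` the input is returned
#'   unchanged with attribute `no_beats = TRUE` and a warning.
#' @export
t_wave_mask <- function(x, r_peaks, fs, c = 50, fill = 0, seed = 1L) {
  stopifnot(c >= 0, c <= 100)
  if (length(r_peaks) == 0) {
    warning("no R peaks available; segment returned unmasked", call. = FALSE)
    attr(x, "no_beats") <- TRUE
    return(x)
  }
  if (any(r_peaks < 1 | r_peaks > length(x))) {
    stop_af("r_peaks outside segment bounds")
  }
  n_sel <- round(c / 100 * length(r_peaks))
  if (n_sel == 0) return(x)
  sel <- withr::with_seed(seed, sample(seq_along(r_peaks), n_sel))
  for (r in r_peaks[sel]) {
    w <- t_mask_window(r, fs, length(x))
    if (length(w)) x[w] <- fill
  }
  x
}

#' Domain-knowledge augmentation (strong view)
#'
#' Applies T-wave masking, then vertical flipping with probability
#' `flip_probability` (seeded Bernoulli). The weak view of a sample is the
#' unmodified preprocessed segment.
#'
#' @param x Numeric segment.
#' @param r_peaks 1-based R-peak indices.
#' @param config An [augmentation_config()].
#' @param fs Sampling frequency in Hz.
#' @return The augmented segment.
#' @export
domain_knowledge_augment <- function(x, r_peaks, config, fs = 128) {
  stopifnot(inherits(config, "af_augment_config"))
  seeds <- derive_seeds(config$seed, 2L, salt = 3L)
  out <- t_wave_mask(x, r_peaks, fs, c = config$mask_fraction_c,
                     fill = config$mask_fill_value, seed = seeds[1])
  flip <- withr::with_seed(seeds[2], runif(1) < config$flip_probability)
  if (flip) out <- vertical_flip(out)
  out
}

#' Comparison time-series augmentations
#'
#' The six generic augmentations used as ablation comparisons to the
#' domain-knowledge augmentation, with their standard parameter ranges:
#'
#' * `gaussian_noise`: add N(0, sd^2) noise, sd ~ U(0.01, 0.1)
#' * `baseline_wander`: add `Sw * sin(2*pi*fw*t)`, fw ~ U(1/30, 1/10) Hz,
#'   Sw ~ U(0.5, 0.6)
#' * `channel_scaling`: multiply by S ~ U(0.1, 5)
#' * `horizontal_flip`: reverse sample order, `x_tilde(t) = x(T0 - t + 1)`
#' * `time_warp`: split into `w` segments, stretch a random half of the
#'   sub-areas by `r`% and squeeze the other half by `r`%, re-concatenate
#'   and resample back to the original length; `(w, r) = (1, 5)` or
#'   `(3, 5)` with equal probability
#' * `random_mask`: set a uniformly chosen `c`% of samples (default
#'   `c = 20`) to `fill`
#'
#' @param x Numeric segment.
#' @param kind One of the six augmentation names above.
#' @param params Optional named list overriding kind-specific defaults
#'   (`sd_range`, `fw_range`, `sw_range`, `s_range`, `w_choices`, `r`,
#'   `c`, `fill`).
#' @param seed Integer seed.
#' @param fs Sampling frequency in Hz (used by `baseline_wander`).
#' @return The augmented segment, always of the original length.
#' @export
ablation_augment <- function(x, kind, params = list(), seed = 1L, fs = 128) {
  n <- length(x)
  withr::with_seed(seed, switch(
    kind,
    gaussian_noise = {
      r <- params$sd_range %||% c(0.01, 0.1)
      x + rnorm(n, 0, runif(1, r[1], r[2]))
    },
    baseline_wander = {
      fw <- runif(1, (params$fw_range %||% c(1 / 30, 1 / 10))[1],
                  (params$fw_range %||% c(1 / 30, 1 / 10))[2])
      sw <- runif(1, (params$sw_range %||% c(0.5, 0.6))[1],
                  (params$sw_range %||% c(0.5, 0.6))[2])
      x + sw * sin(2 * pi * fw * (seq_len(n) - 1) / fs)
    },
    channel_scaling = {
      r <- params$s_range %||% c(0.1, 5)
      x * runif(1, r[1], r[2])
    },
    horizontal_flip = rev(x),
    time_warp = {
      w <- sample(params$w_choices %||% c(1L, 3L), 1L)
      r <- (params$r %||% 5) / 100
      time_warp_signal(x, w, r)
    },
    random_mask = {
      c_pct <- params$c %||% 20
      fill <- params$fill %||% 0
      k <- round(c_pct / 100 * n)
      if (k > 0) x[sample(n, k)] <- fill
      x
    },
    stop_af("unknown augmentation kind: %s", kind)
  ))
}

# Piecewise stretch/squeeze: each of the w chunks is split into two equal
# sub-areas; one (chosen at random) is stretched by r, the other squeezed by
# r; the warped chunks are re-concatenated and linearly resampled back to
# the original length.
time_warp_signal <- function(x, w, r) {
  n <- length(x)
  bounds <- round(seq(0, n, length.out = w + 1))
  pieces <- list()
  for (k in seq_len(w)) {
    chunk <- x[(bounds[k] + 1):bounds[k + 1]]
    m <- length(chunk)
    half <- m %/% 2L
    a <- chunk[seq_len(half)]
    b <- chunk[(half + 1):m]
    stretch_first <- runif(1) < 0.5
    fa <- if (stretch_first) 1 + r else 1 - r
    fb <- if (stretch_first) 1 - r else 1 + r
    wa <- stats::approx(seq_along(a), a, n = max(2L, round(length(a) * fa)))$y
    wb <- stats::approx(seq_along(b), b, n = max(2L, round(length(b) * fb)))$y
    pieces[[k]] <- c(wa, wb)
  }
  y <- unlist(pieces)
  stats::approx(seq_along(y), y, n = n)$y
}

#' Build weak/strong view pairs for a batch
#'
#' The weak view is the preprocessed segment itself; the strong view applies
#' [domain_knowledge_augment()] per segment with per-segment derived seeds.
#'
#' @param X Matrix `B x T0` of preprocessed segments.
#' @param r_peaks List of 1-based R-peak index vectors (ground truth when
#'   available, else detector output).
#' @param config An [augmentation_config()].
#' @param fs Sampling frequency in Hz.
#' @return List with `weak` and `strong` matrices of identical shape.
#' @export
make_views <- function(X, r_peaks, config, fs = 128) {
  B <- nrow(X)
  strong <- X
  seeds <- derive_seeds(config$seed, max(B, 1L), salt = 5L)
  for (i in seq_len(B)) {
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    strong[i, ] <- domain_knowledge_augment(X[i, ], r_peaks[[i]], cfg_i, fs)
  }
  list(weak = X, strong = strong)
}
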