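# Independent reference implementations used as oracles: direct nested-loop
# evaluations of the contrastive objectives and small fixture builders.

ref_cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))

# Temporal contrastive loss, direct double loop over (i, t, t').
ref_temporal_loss <- function(h, h_tilde, tau) {
  B <- dim(h)[1]; T_ <- dim(h)[2]
  total <- 0
  for (i in seq_len(B)) {
    for (t in seq_len(T_)) {
      hit <- h[i, t, ]
      num <- exp(ref_cosine(hit, h_tilde[i, t, ]) / tau)
      den <- 0
      for (t2 in seq_len(T_)) {
        den <- den + exp(ref_cosine(hit, h_tilde[i, t2, ]) / tau)
        if (t2 != t) den <- den + exp(ref_cosine(hit, h[i, t2, ]) / tau)
      }
      total <- total - log(num / den) / T_
    }
  }
  total / B
}

# Channel contrastive loss, direct double loop over (i, j).
ref_channel_loss <- function(z, z_pair, tau) {
  B <- nrow(z)
  total <- 0
  for (i in seq_len(B)) {
    num <- exp(ref_cosine(z[i, ], z_pair[i, ]) / tau)
    den <- 0
    for (j in seq_len(B)) {
      den <- den + exp(ref_cosine(z[i, ], z_pair[j, ]) / tau)
      if (j != i) den <- den + exp(ref_cosine(z[i, ], z[j, ]) / tau)
    }
    total <- total - log(num / den)
  }
  total / B
}

# Supervised contrastive loss, direct triple loop; anchors with no positive
# contribute 0 and are dropped from the outer mean.
ref_label_loss <- function(reps, labels, tau) {
  n <- nrow(reps)
  li <- numeric(n)
  valid <- logical(n)
  for (i in seq_len(n)) {
    P <- setdiff(which(labels == labels[i]), i)
    A <- setdiff(seq_len(n), i)
    if (length(P) == 0) next
    valid[i] <- TRUE
    den <- sum(vapply(A, function(j) {
      exp(ref_cosine(reps[i, ], reps[j, ]) / tau)
    }, numeric(1)))
    li[i] <- -mean(vapply(P, function(p) {
      log(exp(ref_cosine(reps[i, ], reps[p, ]) / tau) / den)
    }, numeric(1)))
  }
  if (!any(valid)) return(0)
  sum(li) / sum(valid)
}

# Random unit-row matrix.
rand_unit_rows <- function(n, d) {
  M <- matrix(rnorm(n * d), n, d)
  M / sqrt(rowSums(M^2))
}

# Tiny encoder configuration for shape/gradient tests: T0 = 128 -> T = 2.
tiny_encoder_config <- function(use_projector = FALSE) {
  encoder_config(input_length = 128, channel_plan = c(2L, 3L, 3L, 4L, 4L, 4L),
                 encoder_dim = 6L, use_projector = use_projector)
}

# Small smoke-scale config: 3 s segments (384 samples -> T = 6).
smoke_encoder_config <- function() {
  encoder_config(input_length = 384, channel_plan = c(4L, 4L, 4L, 8L, 8L, 8L),
                 encoder_dim = 16L)
}

smoke_dataset <- function(n_labeled, n_unlabeled, seed = 7L) {
  make_synthetic_dataset(n_labeled, n_unlabeled, af_fraction = 0.5,
                         fs = 128, seed = seed, duration_s = 3)
}

# Numeric gradient of f at x (vector or matrix), central differences.
num_grad <- function(f, x, eps = 1e-6) {
  g <- x
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- xp[k] + eps
    xm <- x; xm[k] <- xm[k] - eps
    g[k] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# ---- WFDB fixture writers ----------------------------------------------------

# Write a two-channel WFDB record (header + signal) in format 16 or 212.
# adc: integer matrix n_samples x n_channels.
write_wfdb_fixture <- function(dir, name, adc, fs, gains, baselines,
                               lead_names, fmt = "16") {
  n_sig <- ncol(adc)
  hea <- file.path(dir, paste0(name, ".hea"))
  dat_name <- paste0(name, ".dat")
  lines <- sprintf("%s %d %g %d", name, n_sig, fs, nrow(adc))
  for (i in seq_len(n_sig)) {
    lines <- c(lines, sprintf("%s %s %g(%d)/mV 12 0 0 0 0 %s",
                              dat_name, fmt, gains[i], baselines[i],
                              lead_names[i]))
  }
  writeLines(lines, hea)
  inter <- as.vector(t(adc))                     # channel-interleaved
  con <- file(file.path(dir, dat_name), "wb")
  on.exit(close(con))
  if (fmt == "16") {
    writeBin(as.integer(inter), con, size = 2L, endian = "little")
  } else if (fmt == "212") {
    if (length(inter) %% 2 == 1) inter <- c(inter, 0L)
    u <- ifelse(inter < 0, inter + 4096L, inter)
    b <- integer(0)
    for (k in seq(1, length(u), by = 2)) {
      s1 <- u[k]; s2 <- u[k + 1]
      b <- c(b, s1 %% 256L,
             (s1 %/% 256L) + 16L * (s2 %/% 256L),
             s2 %% 256L)
    }
    writeBin(as.raw(b), con)
  } else stop("unsupported fixture format")
  invisible(file.path(dir, paste0(name, ".hea")))
}

# Write a MIT-format annotation file with rhythm-change aux strings.
# events: data.frame(sample, aux) with non-decreasing 0-based samples.
write_atr_fixture <- function(path, events, use_skip = FALSE) {
  bytes <- integer(0)
  word <- function(code, inc) {
    w <- code * 1024L + inc
    c(w %% 256L, w %/% 256L)
  }
  prev <- 0
  for (r in seq_len(nrow(events))) {
    delta <- events$sample[r] - prev
    prev <- events$sample[r]
    if (use_skip || delta > 1022) {
      bytes <- c(bytes, word(59L, 0L))
      hi <- delta %/% 65536; lo <- delta %% 65536
      bytes <- c(bytes, hi %% 256L, hi %/% 256L, lo %% 256L, lo %/% 256L)
      bytes <- c(bytes, word(28L, 0L))           # RHYTHM at accumulated time
    } else {
      bytes <- c(bytes, word(28L, delta))
    }
    aux <- events$aux[r]
    if (!is.na(aux)) {
      ab <- utf8ToInt(aux)
      bytes <- c(bytes, word(63L, length(ab)))
      if (length(ab) %% 2 == 1) ab <- c(ab, 0L)
      bytes <- c(bytes, ab)
    }
  }
  bytes <- c(bytes, 0L, 0L)
  con <- file(path, "wb")
  writeBin(as.raw(bytes), con)
  close(con)
  invisible(path)
}
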