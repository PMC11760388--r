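#' Configuration of the two-stage multi-level encoder
#'
#' The encoder has two parts: a convolutional feature extractor `f` (one
#' input convolution plus six residual blocks, each downsampling time by 2,
#' for a total downsampling of 64) producing a per-timestamp hidden
#' representation `h` of dimension `hidden_dim`, and a bidirectional LSTM
#' fusion network `g` whose last-time-step output, L2-normalized onto the
#' unit hypersphere, is the encoder representation `z` of dimension
#' `encoder_dim`.
#'
#' @param input_length Segment length in samples (default 3840 = 30 s at
#'   128 Hz). Must be divisible by 64.
#' @param channel_plan Output channels of the six residual blocks; the last
#'   entry is the hidden dimension `Dh`. The input convolution (kernel 7,
#'   stride 1) uses `channel_plan[1]` channels.
#' @param encoder_dim Dimension `Dz` of the encoder representation; must be
#'   even (the Bi-LSTM uses `encoder_dim / 2` hidden units per direction).
#' @param use_projector Add a two-layer MLP projector (output size `Dz`)
#'   used only inside the channel/label contrastive losses during
#'   pre-training; default off.
#' @return An object of class `af_encoder_config`.
#' @export
encoder_config <- function(input_length = 3840,
                           channel_plan = c(32, 64, 64, 128, 128, 128),
                           encoder_dim = 256,
                           use_projector = FALSE) {
  stopifnot(length(channel_plan) == 6)
  if (input_length %% 64 != 0) {
    stop_af("input_length must be divisible by the total downsampling (64)")
  }
  if (encoder_dim %% 2 != 0) stop_af("encoder_dim must be even")
  structure(
    list(input_length = as.integer(input_length),
         channel_plan = as.integer(channel_plan),
         hidden_dim = as.integer(channel_plan[6]),
         encoder_dim = as.integer(encoder_dim),
         lstm_hidden = as.integer(encoder_dim / 2),
         n_timesteps = as.integer(input_length / 64),
         use_projector = isTRUE(use_projector)),
    class = "af_encoder_config"
  )
}

#' Initialize encoder parameters
#'
#' Parameters are a nested list with disjoint sub-trees `f` (convolutional
#' extractor) and `g` (Bi-LSTM fusion network), plus `proj` when the
#' projector is enabled. Convolutions use He-normal initialization; LSTM
#' weights are uniform in `+/- 1/sqrt(H)` with forget-gate bias 1.
#'
#' @param config An [encoder_config()].
#' @param seed Integer seed.
#' @return Parameter tree (named nested list of numeric arrays).
#' @export
init_encoder <- function(config, seed = 1L) {
  stopifnot(inherits(config, "af_encoder_config"))
  cp <- config$channel_plan
  withr::with_seed(seed, {
    f <- list(conv0 = conv1d_init(7L, 1L, cp[1]))
    cin <- cp[1]
    for (blk in 1:6) {
      f[[paste0("block", blk)]] <- list(
        conv1 = conv1d_init(3L, cin, cp[blk]),
        conv2 = conv1d_init(3L, cp[blk], cp[blk], scale = 1 / sqrt(2)),
        shortcut = conv1d_init(1L, cin, cp[blk], scale = 1 / sqrt(2))
      )
      cin <- cp[blk]
    }
    g <- list(fwd = lstm_init(config$hidden_dim, config$lstm_hidden),
              bwd = lstm_init(config$hidden_dim, config$lstm_hidden))
    par <- list(f = f, g = g)
    if (config$use_projector) {
      par$proj <- list(lin1 = linear_init(config$encoder_dim,
                                          config$encoder_dim),
                       lin2 = linear_init(config$encoder_dim,
                                          config$encoder_dim))
    }
    par
  })
}

NORM_EPS <- 1e-12

l2_normalize_rows <- function(X) {
  n <- sqrt(rowSums(X^2))
  list(U = X / (n + NORM_EPS), norms = n)
}

# Backward through row-wise z = u / (||u|| + eps):
# dL/du = dz/(n+eps) - z (z . dz) / n
l2_normalize_rows_backward <- function(dU, U, norms) {
  inv <- 1 / (norms + NORM_EPS)
  dot <- rowSums(U * dU)
  dU * inv - U * (dot / pmax(norms, NORM_EPS))
}

# ---- forward / backward ------------------------------------------------------

# X: B x input_length matrix of segments.
encoder_forward <- function(par, config, X, cache = TRUE) {
  B <- nrow(X)
  if (ncol(X) != config$input_length) {
    stop_af("segment length %d does not match configured input_length %d",
            ncol(X), config$input_length)
  }
  caches <- list()
  M <- tm_from_batch(X)
  c0 <- conv1d_forward(M, B, par$f$conv0, K = 7L, stride = 1L, pad = 3L,
                       cache = cache)
  r0 <- relu_forward(c0$out)
  caches$conv0 <- c0$cache; caches$relu0 <- r0$mask
  M <- r0$out
  for (blk in 1:6) {
    p <- par$f[[paste0("block", blk)]]
    c1 <- conv1d_forward(M, B, p$conv1, K = 3L, stride = 2L, pad = 1L,
                         cache = cache)
    r1 <- relu_forward(c1$out)
    c2 <- conv1d_forward(r1$out, B, p$conv2, K = 3L, stride = 1L, pad = 1L,
                         cache = cache)
    sc <- conv1d_forward(M, B, p$shortcut, K = 1L, stride = 2L, pad = 0L,
                         cache = cache)
    r2 <- relu_forward(c2$out + sc$out)
    caches[[paste0("block", blk)]] <- list(c1 = c1$cache, relu1 = r1$mask,
                                           c2 = c2$cache, sc = sc$cache,
                                           relu2 = r2$mask)
    M <- r2$out
  }
  H <- M                                   # (B*T) x Dh time-major
  T_ <- nrow(H) / B
  if (T_ < 1) stop_af("empty hidden sequence")
  fwd <- lstm_forward(H, B, par$g$fwd, order = seq_len(T_), cache = cache)
  bwd <- lstm_forward(H, B, par$g$bwd, order = rev(seq_len(T_)), cache = cache)
  u <- cbind(fwd$out[tm_rows(T_, B), , drop = FALSE],
             bwd$out[tm_rows(T_, B), , drop = FALSE])
  nz <- l2_normalize_rows(u)
  list(h = H, z = nz$U, B = B,
       cache = if (cache) list(caches = caches, fwd = fwd$cache,
                               bwd = bwd$cache, u = u, norms = nz$norms,
                               z = nz$U, B = B, T_ = T_) else NULL)
}

# dH: (B*T) x Dh gradient on h (or NULL); dz: B x Dz gradient on z (or NULL).
encoder_backward <- function(par, config, cache, dH = NULL, dz = NULL) {
  B <- cache$B; T_ <- cache$T_
  grads <- list(f = list(), g = list())
  Dh <- config$hidden_dim
  dH_total <- if (is.null(dH)) matrix(0, B * T_, Dh) else dH

  if (!is.null(dz)) {
    du <- l2_normalize_rows_backward(dz, cache$z, cache$norms)
    Hd <- config$lstm_hidden
    dOut_f <- matrix(0, B * T_, Hd)
    dOut_b <- matrix(0, B * T_, Hd)
    dOut_f[tm_rows(T_, B), ] <- du[, 1:Hd, drop = FALSE]
    dOut_b[tm_rows(T_, B), ] <- du[, (Hd + 1):(2 * Hd), drop = FALSE]
    bf <- lstm_backward(dOut_f, par$g$fwd, cache$fwd)
    bb <- lstm_backward(dOut_b, par$g$bwd, cache$bwd)
    grads$g <- list(fwd = bf$grads, bwd = bb$grads)
    dH_total <- dH_total + bf$dX + bb$dX
  } else {
    grads$g <- list(fwd = tree_zeros_like(par$g$fwd),
                    bwd = tree_zeros_like(par$g$bwd))
  }

  dM <- dH_total
  for (blk in 6:1) {
    cc <- cache$caches[[paste0("block", blk)]]
    p <- par$f[[paste0("block", blk)]]
    dsum <- relu_backward(dM, cc$relu2)
    b2 <- conv1d_backward(dsum, p$conv2, cc$c2)
    bsc <- conv1d_backward(dsum, p$shortcut, cc$sc)
    dr1 <- relu_backward(b2$dM, cc$relu1)
    b1 <- conv1d_backward(dr1, p$conv1, cc$c1)
    grads$f[[paste0("block", blk)]] <- list(conv1 = b1$grads,
                                            conv2 = b2$grads,
                                            shortcut = bsc$grads)
    dM <- b1$dM + bsc$dM
  }
  d0 <- relu_backward(dM, cache$caches$relu0)
  b0 <- conv1d_backward(d0, par$f$conv0, cache$caches$conv0)
  grads$f$conv0 <- b0$grads
  grads$f <- grads$f[c("conv0", paste0("block", 1:6))]
  grads
}

# ---- public operations -------------------------------------------------------

#' Extract per-timestamp hidden representations
#'
#' Runs the convolutional feature extractor `f` on a batch of segments.
#'
#' @param par Encoder parameters from [init_encoder()].
#' @param config The matching [encoder_config()].
#' @param X Numeric matrix `B x input_length`, one segment per row.
#' @return Array `B x T x Dh` of hidden representations (`T =
#'   input_length / 64`).
#' @export
conv_extract <- function(par, config, X) {
  fw <- encoder_forward(par, config, X, cache = FALSE)
  tm_to_array(fw$h, nrow(X))
}

#' Fuse hidden representations into unit-norm encoder representations
#'
#' Runs the Bi-LSTM fusion network `g` over a batch of hidden
#' representations and returns the last-time-step output, L2-normalized onto
#' the unit hypersphere.
#'
#' @param par Encoder parameters from [init_encoder()].
#' @param config The matching [encoder_config()].
#' @param h Array `B x T x Dh` (e.g. from [conv_extract()]).
#' @return Matrix `B x Dz` with unit-norm rows.
#' @export
fuse_encode <- function(par, config, h) {
  stopifnot(length(dim(h)) == 3)
  B <- dim(h)[1]; T_ <- dim(h)[2]
  if (T_ == 0) stop_af("hidden sequence has zero time steps")
  H <- array_to_tm(h)
  fwd <- lstm_forward(H, B, par$g$fwd, order = seq_len(T_), cache = FALSE)
  bwd <- lstm_forward(H, B, par$g$bwd, order = rev(seq_len(T_)), cache = FALSE)
  u <- cbind(fwd$out[tm_rows(T_, B), , drop = FALSE],
             bwd$out[tm_rows(T_, B), , drop = FALSE])
  l2_normalize_rows(u)$U
}

#' Encode segments to representations
#'
#' Convenience wrapper: full encoder forward pass in batches.
#'
#' @param par,config Encoder parameters and configuration.
#' @param X Matrix `B x input_length`.
#' @param batch_size Forward-pass batch size.
#' @return Matrix `B x Dz` of unit-norm encoder representations.
#' @export
encode_segments <- function(par, config, X, batch_size = 64L) {
  n <- nrow(X)
  Z <- matrix(0, n, config$encoder_dim)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batch_size - 1L)
    Z[i:j, ] <- encoder_forward(par, config, X[i:j, , drop = FALSE],
                                cache = FALSE)$z
    i <- j + 1L
  }
  Z
}

#' Project an encoder representation (ablation only)
#'
#' Two affine layers with a rectifier in between; output size equals input
#' size. Only meaningful during pre-training inside the channel/label
#' contrastive losses; an error is raised when the projector is disabled.
#'
#' @param par,config Encoder parameters and configuration
#'   (`use_projector = TRUE`).
#' @param z Matrix `B x Dz`.
#' @return Matrix `B x Dz`.
#' @export
project <- function(par, config, z) {
  if (!config$use_projector || is.null(par$proj)) {
    stop_af("projector is disabled in this configuration")
  }
  projector_forward(par$proj, z, cache = FALSE)$out
}

projector_forward <- function(ppar, z, cache = TRUE) {
  a1 <- linear_forward(z, ppar$lin1)
  r1 <- relu_forward(a1)
  out <- linear_forward(r1$out, ppar$lin2)
  list(out = out,
       cache = if (cache) list(z = z, r1 = r1$out, mask = r1$mask) else NULL)
}

projector_backward <- function(dOut, ppar, cache) {
  b2 <- linear_backward(dOut, cache$r1, ppar$lin2)
  dr1 <- relu_backward(b2$dX, cache$mask)
  b1 <- linear_backward(dr1, cache$z, ppar$lin1)
  list(dz = b1$dX, grads = list(lin1 = b1$grads, lin2 = b2$grads))
}

# ---- classifier --------------------------------------------------------------

#' Configuration of the downstream classifier
#'
#' A three-layer MLP (`Dz -> hidden[1] -> hidden[2] -> n_classes`) with batch
#' normalization before each rectifier activation.
#'
#' @param input_dim Input dimension (encoder `Dz`).
#' @param hidden Widths of the two hidden layers.
#' @param n_classes Number of classes.
#' @return An object of class `af_classifier_config`.
#' @export
classifier_config <- function(input_dim, hidden = c(128L, 64L),
                              n_classes = 2L) {
  stopifnot(length(hidden) == 2)
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 n_classes = as.integer(n_classes)),
            class = "af_classifier_config")
}

init_classifier <- function(config, seed = 1L) {
  withr::with_seed(seed, {
    list(
      par = list(lin1 = linear_init(config$input_dim, config$hidden[1]),
                 bn1 = bn_init(config$hidden[1]),
                 lin2 = linear_init(config$hidden[1], config$hidden[2]),
                 bn2 = bn_init(config$hidden[2]),
                 lin3 = linear_init(config$hidden[2], config$n_classes)),
      state = list(bn1 = bn_state_init(config$hidden[1]),
                   bn2 = bn_state_init(config$hidden[2]))
    )
  })
}

classifier_forward <- function(clf, Z, training = FALSE, cache = TRUE) {
  a1 <- linear_forward(Z, clf$par$lin1)
  n1 <- bn_forward(a1, clf$par$bn1, clf$state$bn1, training)
  r1 <- relu_forward(n1$out)
  a2 <- linear_forward(r1$out, clf$par$lin2)
  n2 <- bn_forward(a2, clf$par$bn2, clf$state$bn2, training)
  r2 <- relu_forward(n2$out)
  scores <- linear_forward(r2$out, clf$par$lin3)
  clf$state$bn1 <- n1$state
  clf$state$bn2 <- n2$state
  list(scores = scores, clf = clf,
       cache = if (cache) list(Z = Z, bn1 = n1$cache, m1 = r1$mask,
                               r1 = r1$out, bn2 = n2$cache, m2 = r2$mask,
                               r2 = r2$out) else NULL)
}

classifier_backward <- function(dScores, clf, cache) {
  b3 <- linear_backward(dScores, cache$r2, clf$par$lin3)
  dr2 <- relu_backward(b3$dX, cache$m2)
  bn2 <- bn_backward(dr2, clf$par$bn2, cache$bn2)
  b2 <- linear_backward(bn2$dX, cache$r1, clf$par$lin2)
  dr1 <- relu_backward(b2$dX, cache$m1)
  bn1 <- bn_backward(dr1, clf$par$bn1, cache$bn1)
  b1 <- linear_backward(bn1$dX, cache$Z, clf$par$lin1)
  list(dZ = b1$dX,
       grads = list(lin1 = b1$grads, bn1 = bn1$grads, lin2 = b2$grads,
                    bn2 = bn2$grads, lin3 = b3$grads))
}

#' Class scores for encoder representations
#'
#' @param clf A classifier (from fine-tuning, or [init_classifier()]).
#' @param Z Matrix `B x Dz` of representations.
#' @return Matrix `B x n_classes` of pre-softmax scores.
#' @export
classify <- function(clf, Z) {
  classifier_forward(clf, Z, training = FALSE, cache = FALSE)$scores
}

softmax_rows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}
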