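# Minimal neural-network core: 1-D convolution, LSTM, linear and batch-norm
# layers with hand-derived backward passes, plus Adam. Batched signal tensors
# use a "time-major" layout: a (B*L) x C matrix whose row (t-1)*B + b holds
# sample t of batch element b. This keeps every convolution a single BLAS
# matrix product over gathered rows.

nn_rnorm <- function(n, sd) rnorm(n, 0, sd)

# ---- time-major layout helpers ----------------------------------------------

# B x L matrix of signals -> (B*L) x 1 time-major matrix
tm_from_batch <- function(X) matrix(as.vector(X), ncol = 1)

# rows of time step t (1..L) in a time-major matrix with batch size B
tm_rows <- function(t, B) (t - 1L) * B + seq_len(B)

# time-major (B*T) x D -> 3D array B x T x D
tm_to_array <- function(M, B) {
  T_ <- nrow(M) / B
  arr <- array(0, c(B, T_, ncol(M)))
  for (t in seq_len(T_)) arr[, t, ] <- M[tm_rows(t, B), , drop = FALSE]
  arr
}

array_to_tm <- function(arr) {
  d <- dim(arr)
  M <- matrix(0, d[1] * d[2], d[3])
  for (t in seq_len(d[2])) M[tm_rows(t, d[1]), ] <- arr[, t, ]
  M
}

# ---- conv1d ------------------------------------------------------------------

# He-normal init; `scale` dampens the two branches summed by a residual
# block (1/sqrt(2) each) so activation variance stays near 1 through the
# stack instead of doubling per block.
conv1d_init <- function(K, Cin, Cout, scale = 1) {
  list(W = matrix(nn_rnorm(K * Cin * Cout, scale * sqrt(2 / (K * Cin))),
                  K * Cin, Cout),
       b = numeric(Cout))
}

# Row indices in the padded time-major matrix feeding output position
# 1..Lout at kernel offset k.
conv1d_gather_idx <- function(k, B, Lout, stride) {
  tin <- stride * (seq_len(Lout) - 1L) + k
  rep((tin - 1L) * B, each = B) + seq_len(B)
}

# M: (B*L) x Cin time-major. Returns (B*Lout) x Cout plus cache for backward.
# The im2col matrix is never materialized at the R level: the compiled kernel
# accumulates one BLAS product per kernel offset over gathered row blocks of
# the padded input, so the cached state is just the layer input itself.
conv1d_forward <- function(M, B, par, K, stride, pad, cache = TRUE) {
  out <- cpp_conv1d_forward(M, par$W, par$b, B, K, stride, pad)
  list(out = out,
       cache = if (cache) list(M = M, B = B, K = K, stride = stride,
                               pad = pad) else NULL)
}

conv1d_backward <- function(dOut, par, cache) {
  cc <- cache
  res <- cpp_conv1d_backward(cc$M, par$W, dOut, cc$B, cc$K, cc$stride,
                             cc$pad)
  list(dM = res$dM, grads = list(W = res$dW, b = as.numeric(res$db)))
}

# ---- relu --------------------------------------------------------------------

relu_forward <- function(x) {
  if (is.matrix(x)) {
    res <- cpp_relu_forward(x)
    return(list(out = res$out, mask = res$mask))
  }
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

relu_backward <- function(dOut, mask) dOut * mask

# ---- linear ------------------------------------------------------------------

linear_init <- function(Din, Dout) {
  list(W = matrix(nn_rnorm(Din * Dout, sqrt(2 / Din)), Din, Dout),
       b = numeric(Dout))
}

linear_forward <- function(X, par) X %*% par$W + rep(par$b, each = nrow(X))

linear_backward <- function(dOut, X, par) {
  list(dX = tcrossprod(dOut, par$W),
       grads = list(W = crossprod(X, dOut), b = colSums(dOut)))
}

# ---- batch norm --------------------------------------------------------------

bn_init <- function(D) {
  list(gamma = rep(1, D), beta = numeric(D))
}

bn_state_init <- function(D) {
  list(mean = numeric(D), var = rep(1, D))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_forward <- function(X, par, state, training) {
  if (training) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu)
    v <- colMeans(xc^2)
    inv <- 1 / sqrt(v + BN_EPS)
    xhat <- sweep(xc, 2, inv, `*`)
    state$mean <- (1 - BN_MOMENTUM) * state$mean + BN_MOMENTUM * mu
    state$var <- (1 - BN_MOMENTUM) * state$var + BN_MOMENTUM * v
    cache <- list(xhat = xhat, inv = inv, xc = xc)
  } else {
    inv <- 1 / sqrt(state$var + BN_EPS)
    xhat <- sweep(sweep(X, 2, state$mean), 2, inv, `*`)
    cache <- NULL
  }
  out <- sweep(sweep(xhat, 2, par$gamma, `*`), 2, par$beta, `+`)
  list(out = out, state = state, cache = cache)
}

bn_backward <- function(dOut, par, cache) {
  n <- nrow(dOut)
  dgamma <- colSums(dOut * cache$xhat)
  dbeta <- colSums(dOut)
  dxhat <- sweep(dOut, 2, par$gamma, `*`)
  # standard batch-norm backward (population variance)
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
  dX <- sweep(t1 - t2, 2, cache$inv, `*`)
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}

# ---- LSTM --------------------------------------------------------------------

lstm_init <- function(Din, H) {
  r <- 1 / sqrt(H)
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1              # forget-gate bias
  list(Wx = matrix(runif(Din * 4 * H, -r, r), Din, 4 * H),
       Wh = matrix(runif(H * 4 * H, -r, r), H, 4 * H),
       b = b)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# H_tm: (B*T) x Din time-major input. `order` gives the processing order of
# time positions (1:T forward, T:1 backward). Returns per-position outputs
# (time-major, indexed by position, not processing step) and a cache.
lstm_forward <- function(H_tm, B, par, order, cache = TRUE) {
  T_ <- nrow(H_tm) / B
  Hd <- nrow(par$Wh)
  h <- matrix(0, B, Hd)
  cst <- matrix(0, B, Hd)
  out <- matrix(0, B * T_, Hd)
  steps <- if (cache) vector("list", T_) else NULL
  for (s in seq_len(T_)) {
    t_pos <- order[s]
    Xt <- H_tm[tm_rows(t_pos, B), , drop = FALSE]
    G <- Xt %*% par$Wx + h %*% par$Wh + rep(par$b, each = B)
    i_g <- sigmoid(G[, 1:Hd, drop = FALSE])
    f_g <- sigmoid(G[, (Hd + 1):(2 * Hd), drop = FALSE])
    g_g <- tanh(G[, (2 * Hd + 1):(3 * Hd), drop = FALSE])
    o_g <- sigmoid(G[, (3 * Hd + 1):(4 * Hd), drop = FALSE])
    c_prev <- cst
    cst <- f_g * c_prev + i_g * g_g
    tc <- tanh(cst)
    h_prev <- h
    h <- o_g * tc
    out[tm_rows(t_pos, B), ] <- h
    if (cache) {
      steps[[s]] <- list(Xt = Xt, i = i_g, f = f_g, g = g_g, o = o_g,
                         c = cst, c_prev = c_prev, tc = tc, h_prev = h_prev,
                         t_pos = t_pos)
    }
  }
  list(out = out, h_last = h,
       cache = if (cache) list(steps = steps, B = B, T_ = T_, Hd = Hd,
                               order = order) else NULL)
}

# dOut: (B*T) x Hd gradient on the per-position outputs (may be mostly zero).
lstm_backward <- function(dOut, par, cache) {
  B <- cache$B; T_ <- cache$T_; Hd <- cache$Hd
  dWx <- matrix(0, nrow(par$Wx), ncol(par$Wx))
  dWh <- matrix(0, nrow(par$Wh), ncol(par$Wh))
  db <- numeric(length(par$b))
  dh_next <- matrix(0, B, Hd)
  dc_next <- matrix(0, B, Hd)
  dX <- matrix(0, B * T_, nrow(par$Wx))
  for (s in rev(seq_len(T_))) {
    st <- cache$steps[[s]]
    dh <- dh_next + dOut[tm_rows(st$t_pos, B), , drop = FALSE]
    do_g <- dh * st$tc
    dc <- dc_next + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dc_next <- dc * st$f
    dG <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_g * st$o * (1 - st$o))
    dWx <- dWx + crossprod(st$Xt, dG)
    dWh <- dWh + crossprod(st$h_prev, dG)
    db <- db + colSums(dG)
    dh_next <- tcrossprod(dG, par$Wh)
    dX[tm_rows(st$t_pos, B), ] <- dX[tm_rows(st$t_pos, B), , drop = FALSE] +
      tcrossprod(dG, par$Wx)
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

# ---- parameter trees and Adam ------------------------------------------------

# Apply f(leaf_a, leaf_b) over two parallel nested lists of numeric arrays.
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    return(out)
  }
  f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, tree_map, f = f))
  f(a)
}

tree_zeros_like <- function(a) tree_map(function(x) x * 0, a)

# Global gradient-norm clipping (standard safeguard for BPTT training).
clip_global_norm <- function(grads, max_norm) {
  total <- sqrt(sum(unlist(tree_map(function(g) sum(g^2), grads))))
  if (is.finite(total) && total > max_norm) {
    grads <- tree_map(function(g) g * (max_norm / total), grads)
  }
  grads
}

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
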