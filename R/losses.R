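#' Cosine similarity of two vectors
#'
#' `u . v / (||u|| ||v||)`, the similarity used by every contrastive loss in
#' the package.
#'
#' @param u,v Nonzero numeric vectors of equal length.
#' @return A scalar in `[-1, 1]`.
#' @export
cosine_sim <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop_af("cosine similarity undefined for zero vector")
  sum(u * v) / (nu * nv)
}

# ---- shared InfoNCE machinery -----------------------------------------------
#
# Anchors are the rows of U (already row-normalized). The positive of anchor
# i is row i of V; negatives are all other rows of V (cross-view term) and
# all other rows of U (same-view term, self excluded). Returns the mean loss
# over anchors and, optionally, gradients with respect to the *normalized*
# rows.
infonce_cross_self <- function(U, V, tau, grad = FALSE) {
  n <- nrow(U)
  Sc <- tcrossprod(U, V) / tau
  Ss <- tcrossprod(U, U) / tau
  diag(Ss) <- -Inf                         # exclude the self term
  M <- cbind(Sc, Ss)
  mx <- apply(M, 1, max)
  E <- exp(M - mx)
  den <- rowSums(E)
  loss_i <- log(den) + mx - diag(Sc)
  loss <- mean(loss_i)
  if (!grad) return(list(loss = loss))
  P <- E / den
  Pc <- P[, 1:n, drop = FALSE]
  Ps <- P[, (n + 1):(2 * n), drop = FALSE]
  Pc_adj <- Pc; diag(Pc_adj) <- diag(Pc) - 1
  scale <- 1 / (n * tau)
  dU <- (Pc_adj %*% V + (Ps + t(Ps)) %*% U) * scale
  dV <- crossprod(Pc_adj, U) * scale
  list(loss = loss, dU = dU, dV = dV)
}

# Row-normalize, run `f` on the normalized rows, then push the returned
# gradients back through the normalization.
with_row_norm <- function(X, dUnorm) {
  nz <- l2_normalize_rows(X)
  l2_normalize_rows_backward(dUnorm, nz$U, nz$norms)
}

#' Temporal contrastive loss
#'
#' InfoNCE objective over per-timestamp hidden representations of two views
#' of the same samples. For anchor `h[i, t]` the positive is the same
#' timestamp of the other view, `h_tilde[i, t]`; negatives are all other
#' timestamps of both views within the same sample. Similarity is cosine;
#' the loss is averaged over timestamps and then over the batch.
#'
#' @param h,h_tilde Arrays `B x T x Dh`: hidden representations of the weak
#'   and strong views.
#' @param tau Temperature (> 0); default 1.
#' @return Scalar loss (0 when `T = 1`, where the denominator reduces to
#'   the positive term).
#' @export
temporal_contrastive_loss <- function(h, h_tilde, tau = 1.0) {
  stopifnot(identical(dim(h), dim(h_tilde)), length(dim(h)) == 3)
  if (dim(h)[2] == 0) stop_af("temporal loss undefined for T = 0")
  B <- dim(h)[1]
  total <- 0
  for (i in seq_len(B)) {
    U <- l2_normalize_rows(matrix(h[i, , ], dim(h)[2], dim(h)[3]))$U
    V <- l2_normalize_rows(matrix(h_tilde[i, , ], dim(h)[2], dim(h)[3]))$U
    total <- total + infonce_cross_self(U, V, tau)$loss
  }
  total / B
}

# Internal training version on time-major matrices; returns gradients with
# respect to the raw (unnormalized) hidden representations.
temporal_loss_tm <- function(H, Ht, B, tau, grad = FALSE) {
  T_ <- nrow(H) / B
  total <- 0
  dH <- if (grad) matrix(0, nrow(H), ncol(H)) else NULL
  dHt <- if (grad) matrix(0, nrow(H), ncol(H)) else NULL
  rows_i <- function(i) seq(i, by = B, length.out = T_)
  for (i in seq_len(B)) {
    ri <- rows_i(i)
    Xi <- H[ri, , drop = FALSE]
    Yi <- Ht[ri, , drop = FALSE]
    nx <- l2_normalize_rows(Xi)
    ny <- l2_normalize_rows(Yi)
    res <- infonce_cross_self(nx$U, ny$U, tau, grad = grad)
    total <- total + res$loss
    if (grad) {
      dH[ri, ] <- l2_normalize_rows_backward(res$dU, nx$U, nx$norms) / B
      dHt[ri, ] <- l2_normalize_rows_backward(res$dV, ny$U, ny$norms) / B
    }
  }
  list(loss = total / B, dH = dH, dHt = dHt)
}

#' Channel contrastive loss
#'
#' InfoNCE objective over encoder representations of two simultaneously
#' recorded leads. For anchor `z[i, ]` the positive is the time-aligned
#' other-lead representation `z_pair[i, ]`; negatives are the other samples'
#' representations of both leads within the batch.
#'
#' @param z,z_pair Matrices `B x Dz` with unit-norm rows.
#' @param tau Temperature (> 0); default 0.1.
#' @return Scalar loss (0 when `B = 1`).
#' @export
channel_contrastive_loss <- function(z, z_pair, tau = 0.1) {
  stopifnot(is.matrix(z), identical(dim(z), dim(z_pair)))
  if (nrow(z) == 0) stop_af("channel loss undefined for an empty batch")
  channel_loss_grad(z, z_pair, tau, grad = FALSE)$loss
}

channel_loss_grad <- function(z, z_pair, tau, grad = FALSE) {
  nx <- l2_normalize_rows(z)
  ny <- l2_normalize_rows(z_pair)
  res <- infonce_cross_self(nx$U, ny$U, tau, grad = grad)
  if (grad) {
    res$dU <- l2_normalize_rows_backward(res$dU, nx$U, nx$norms)
    res$dV <- l2_normalize_rows_backward(res$dV, ny$U, ny$norms)
  }
  res
}

#' Label contrastive loss (supervised contrastive objective)
#'
#' For each anchor, all other representations in the set that share its
#' label are positives; the denominator runs over every other
#' representation. Anchors without any positive contribute 0 and are
#' excluded from the outer average. During pre-training the loss is applied
#' to the multiview set of size 2B (weak and strong views, each carrying its
#' sample's label).
#'
#' @param reps Matrix `N x Dz` of representations (rows are normalized
#'   internally).
#' @param labels Length-`N` label vector.
#' @param tau Temperature (> 0); default 0.1.
#' @return Scalar loss.
#' @export
label_contrastive_loss <- function(reps, labels, tau = 0.1) {
  stopifnot(is.matrix(reps), nrow(reps) == length(labels))
  if (nrow(reps) < 2) stop_af("label loss needs at least 2 samples")
  label_loss_grad(reps, labels, tau, grad = FALSE)$loss
}

label_loss_grad <- function(reps, labels, tau, grad = FALSE) {
  n <- nrow(reps)
  nz <- l2_normalize_rows(reps)
  U <- nz$U
  S <- tcrossprod(U, U) / tau          # finite; self pairs excluded via masks
  Sx <- S
  diag(Sx) <- -Inf
  same <- outer(labels, labels, `==`)
  diag(same) <- FALSE
  nP <- rowSums(same)
  valid <- nP > 0
  if (!any(valid)) {
    warning("all anchors have empty positive sets; label loss is 0",
            call. = FALSE)
    return(list(loss = 0,
                dreps = if (grad) matrix(0, n, ncol(reps)) else NULL))
  }
  mx <- apply(Sx, 1, max)
  E <- exp(Sx - mx)
  den <- rowSums(E)
  lse <- log(den) + mx
  mean_pos <- rowSums(S * same) / pmax(nP, 1)
  loss_i <- ifelse(valid, lse - mean_pos, 0)
  n_valid <- sum(valid)
  loss <- sum(loss_i) / n_valid
  if (!grad) return(list(loss = loss))
  Q <- E / den                             # softmax over the other rows
  Gs <- Q - same / pmax(nP, 1)
  Gs[!valid, ] <- 0
  Gs <- Gs / (n_valid * tau)
  dU <- (Gs + t(Gs)) %*% U
  dreps <- l2_normalize_rows_backward(dU, U, nz$norms)
  list(loss = loss, dreps = dreps)
}

#' Loss weights with the semi-supervised switching rule
#'
#' Labeled batches weight the temporal, channel and label losses equally
#' (1/3 each); unlabeled batches use (1/2, 1/2, 0), dropping the label
#' loss. Weights always sum to 1.
#'
#' @param is_labeled Logical.
#' @return Numeric vector `c(lambda1, lambda2, lambda3)`.
#' @export
loss_weights <- function(is_labeled) {
  if (is_labeled) c(1, 1, 1) / 3 else c(0.5, 0.5, 0)
}

#' Loss configuration
#'
#' @param tau_temporal Temperature of the temporal loss (default 1.0).
#' @param tau_channel,tau_label Temperatures of the channel and label losses
#'   (default 0.1).
#' @param label_loss_views `"multiview"` applies the label loss to the 2B
#'   set of weak + strong view representations; `"single"` uses the B weak
#'   views only.
#' @return An object of class `af_loss_config`.
#' @export
loss_config <- function(tau_temporal = 1.0, tau_channel = 0.1,
                        tau_label = 0.1,
                        label_loss_views = c("multiview", "single")) {
  stopifnot(tau_temporal > 0, tau_channel > 0, tau_label > 0)
  structure(list(tau_temporal = tau_temporal, tau_channel = tau_channel,
                 tau_label = tau_label,
                 label_loss_views = match.arg(label_loss_views)),
            class = "af_loss_config")
}

#' Combined multiple contrastive loss
#'
#' `L = lambda1 * L_temporal + lambda2 * L_channel + lambda3 * L_label`,
#' with the semi-supervised switching rule of [loss_weights()].
#'
#' @param batch List with elements `h`, `h_tilde` (arrays `B x T x Dh`),
#'   `z`, `z_tilde`, `z_pair` (matrices `B x Dz`) and optionally `labels`.
#' @param config An [loss_config()].
#' @param is_labeled Logical; `TRUE` requires `batch$labels`.
#' @return List with `total`, per-term losses and the weights used.
#' @export
combined_loss <- function(batch, config = loss_config(), is_labeled = TRUE) {
  if (is_labeled && is.null(batch$labels)) {
    stop_af("labeled batch requires labels")
  }
  w <- loss_weights(is_labeled)
  lt <- temporal_contrastive_loss(batch$h, batch$h_tilde, config$tau_temporal)
  lc <- channel_contrastive_loss(batch$z, batch$z_pair, config$tau_channel)
  ll <- if (is_labeled) {
    reps <- if (config$label_loss_views == "multiview") {
      rbind(batch$z, batch$z_tilde)
    } else batch$z
    labs <- if (config$label_loss_views == "multiview") {
      rep(batch$labels, 2)
    } else batch$labels
    label_contrastive_loss(reps, labs, config$tau_label)
  } else 0
  list(total = w[1] * lt + w[2] * lc + w[3] * ll,
       temporal = lt, channel = lc, label = ll, weights = w)
}

#' Cross-entropy loss for AF classification
#'
#' Per-class binary cross-entropy on softmax probabilities, averaged over
#' the batch: `-(1/B) sum_j sum_i [y_i log y'_i + (1 - y_i) log(1 - y'_i)]`,
#' with probabilities clipped to `[1e-7, 1 - 1e-7]`.
#'
#' @param scores Matrix `B x C` of pre-softmax scores.
#' @param y_onehot Matrix `B x C` of one-hot labels.
#' @return Scalar loss.
#' @export
cross_entropy_loss <- function(scores, y_onehot) {
  if (!all(dim(scores) == dim(y_onehot))) {
    stop_af("scores and labels have mismatched shapes")
  }
  cross_entropy_grad(scores, y_onehot, grad = FALSE)$loss
}

CE_CLIP <- 1e-7

cross_entropy_grad <- function(scores, y_onehot, grad = FALSE) {
  B <- nrow(scores)
  P <- softmax_rows(scores)
  Pc <- pmin(pmax(P, CE_CLIP), 1 - CE_CLIP)
  loss <- -sum(y_onehot * log(Pc) + (1 - y_onehot) * log(1 - Pc)) / B
  if (!grad) return(list(loss = loss))
  inside <- (P > CE_CLIP) & (P < 1 - CE_CLIP)
  G <- (-(y_onehot / Pc) + (1 - y_onehot) / (1 - Pc)) * inside / B
  # backward through softmax: dL/ds = P * (G - rowSums(G * P))
  dS <- P * (G - rowSums(G * P))
  list(loss = loss, dScores = dS)
}

one_hot <- function(labels, n_classes = 2L) {
  Y <- matrix(0, length(labels), n_classes)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  Y
}
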