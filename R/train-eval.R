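#' Pre-training configuration
#'
#' @param epochs Number of pre-training epochs (default 40).
#' @param batch_size Pre-training batch size (default 256).
#' @param base_lr Initial Adam learning rate (default 0.001).
#' @param lr_gamma,lr_step Step decay: the learning rate is multiplied by
#'   `lr_gamma` every `lr_step` epochs (defaults 0.8 and 3).
#' @param seed Integer seed controlling initialization, shuffling and
#'   augmentation.
#' @return An object of class `af_pretrain_config`.
#' @export
pretrain_config <- function(epochs = 40L, batch_size = 256L, base_lr = 0.001,
                            lr_gamma = 0.8, lr_step = 3L, seed = 1L) {
  stopifnot(epochs > 0, batch_size >= 2)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), base_lr = base_lr,
                 lr_gamma = lr_gamma, lr_step = as.integer(lr_step),
                 seed = as.integer(seed)),
            class = "af_pretrain_config")
}

#' Fine-tuning configuration
#'
#' @param mode `"linear_probe"` (encoder frozen, classifier trained) or
#'   `"full_finetune"` (encoder and classifier updated jointly).
#' @param batch_size Fine-tuning batch size (default 512).
#' @param t_max Number of fine-tuning epochs (default 30).
#' @param eta_base Initial learning rate of the inverse-decay schedule
#'   (default 0.001); see [finetune_lr()].
#' @param holdout_fraction Fraction of the labeled data held out
#'   (stratified) for evaluation.
#' @param seed Integer seed (split, initialization, shuffling).
#' @return An object of class `af_finetune_config`.
#' @export
finetune_config <- function(mode = c("linear_probe", "full_finetune"),
                            batch_size = 512L, t_max = 30L,
                            eta_base = 0.001, holdout_fraction = 0.3,
                            seed = 1L) {
  if (t_max <= 0) stop_af("t_max must be > 0")
  structure(list(mode = match.arg(mode), batch_size = as.integer(batch_size),
                 t_max = as.integer(t_max), eta_base = eta_base,
                 holdout_fraction = holdout_fraction, seed = as.integer(seed)),
            class = "af_finetune_config")
}

#' Step-decay learning rate of the pre-training stage
#'
#' `lr = base_lr * gamma^floor(epoch / step)` with 0-based epochs.
#'
#' @param epoch Completed epochs (0-based).
#' @param base_lr Initial learning rate.
#' @param gamma Decay factor per step.
#' @param step Epochs per decay step.
#' @return The learning rate.
#' @export
step_lr <- function(epoch, base_lr = 0.001, gamma = 0.8, step = 3L) {
  stopifnot(epoch >= 0)
  base_lr * gamma^(epoch %/% step)
}

#' Inverse-decay learning rate of the fine-tuning stage
#'
#' `eta = eta_base / (1 + 10 * t_cur / t_max)^2`, applied per epoch
#' (`t_cur` = completed epochs).
#'
#' @param t_cur Current epoch (0-based, `0 <= t_cur <= t_max`).
#' @param eta_base Initial learning rate.
#' @param t_max Total number of epochs.
#' @return The learning rate.
#' @export
finetune_lr <- function(t_cur, eta_base = 0.001, t_max = 30L) {
  if (t_max <= 0) stop_af("t_max must be > 0")
  stopifnot(t_cur >= 0, t_cur <= t_max)
  eta_base / (1 + 10 * t_cur / t_max)^2
}

# Shuffled batch index list for one epoch; batches of fewer than 2 samples
# are dropped (a contrastive batch needs at least one negative).
epoch_batches <- function(n, batch_size, seed) {
  if (n == 0) return(list())
  idx <- withr::with_seed(seed, sample.int(n))
  starts <- seq(1L, n, by = batch_size)
  out <- lapply(starts, function(s) idx[s:min(n, s + batch_size - 1L)])
  out[vapply(out, length, integer(1)) >= 2L]
}

# Size-weighted deterministic interleaving of labeled/unlabeled batches:
# each source's batches are placed at evenly spaced fractional positions and
# merged in order.
interleave_sources <- function(n_lab, n_unl) {
  pos <- c(if (n_lab > 0) (seq_len(n_lab) - 0.5) / n_lab,
           if (n_unl > 0) (seq_len(n_unl) - 0.5) / n_unl)
  src <- c(rep("labeled", n_lab), rep("unlabeled", n_unl))
  src[order(pos, src)]
}

#' Semi-supervised contrastive pre-training
#'
#' Trains the two-stage encoder with the combined contrastive objective.
#' Each step draws a batch from one source (labeled or unlabeled,
#' interleaved proportionally to dataset sizes), builds the weak/strong view
#' pair of the primary lead via domain-knowledge augmentation, encodes both
#' views plus the weak second lead, and applies the weighted sum of the
#' temporal, channel and (for labeled batches) label contrastive losses:
#' weights (1/3, 1/3, 1/3) on labeled and (1/2, 1/2, 0) on unlabeled
#' batches. Optimization is Adam with a step-decay schedule.
#'
#' @param labeled A labeled [segment_store()] (may have 0 rows).
#' @param unlabeled An unlabeled [segment_store()] (may have 0 rows).
#' @param config An [pretrain_config()].
#' @param enc_config An [encoder_config()].
#' @param loss_cfg An [loss_config()].
#' @param aug_config An [augmentation_config()]; its seed is re-derived per
#'   step.
#' @return An object of class `af_checkpoint`: encoder parameters, configs
#'   and a per-step training log (tibble).
#' @export
pretrain <- function(labeled, unlabeled, config = pretrain_config(),
                     enc_config = encoder_config(),
                     loss_cfg = loss_config(),
                     aug_config = augmentation_config()) {
  M <- if (is.null(labeled)) 0L else nrow(labeled$segments)
  N <- if (is.null(unlabeled)) 0L else nrow(unlabeled$segments)
  if (M + N < 2) stop_af("pre-training requires at least one batch of data")

  par <- init_encoder(enc_config, seed = derive_seeds(config$seed, 1L))
  opt <- adam_init(par)
  log_rows <- list()

  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- step_lr(epoch, config$base_lr, config$lr_gamma, config$lr_step)
    sl <- derive_seeds(config$seed, 2L, salt = 1000L + epoch)
    lab_batches <- epoch_batches(M, config$batch_size, sl[1])
    unl_batches <- epoch_batches(N, config$batch_size, sl[2])
    order_src <- interleave_sources(length(lab_batches), length(unl_batches))
    li <- 0L; ui <- 0L
    for (step_i in seq_along(order_src)) {
      is_labeled <- order_src[step_i] == "labeled"
      if (is_labeled) { li <- li + 1L; idx <- lab_batches[[li]] } else {
        ui <- ui + 1L; idx <- unl_batches[[ui]]
      }
      store <- if (is_labeled) labeled else unlabeled
      step_seed <- derive_seeds(config$seed, 1L,
                                salt = 2000L + 131L * epoch + step_i)
      res <- pretrain_step(par, enc_config, loss_cfg, aug_config, store,
                           idx, is_labeled, step_seed)
      upd <- adam_step(par, res$grads, opt, lr)
      par <- upd$params; opt <- upd$state
      log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
        epoch = epoch, step = step_i,
        source = if (is_labeled) "labeled" else "unlabeled", lr = lr,
        loss_total = res$losses$total, loss_temporal = res$losses$temporal,
        loss_channel = res$losses$channel, loss_label = res$losses$label
      )
    }
  }
  structure(
    list(par = par, encoder_config = enc_config, loss_config = loss_cfg,
         pretrain_config = config,
         log = do.call(rbind, log_rows)),
    class = "af_checkpoint"
  )
}

# One pre-training step: forward three views, compute loss gradients,
# backpropagate through the encoder for each view and sum parameter
# gradients.
pretrain_step <- function(par, enc_config, loss_cfg, aug_config, store, idx,
                          is_labeled, step_seed) {
  X <- store$segments[idx, , drop = FALSE]
  Xp <- store$paired_segments[idx, , drop = FALSE]
  rpk <- if (!is.null(store$r_peaks)) store$r_peaks[idx] else {
    lapply(seq_len(nrow(X)), function(i) detect_qrs(X[i, ], store$fs))
  }
  aug <- aug_config; aug$seed <- step_seed
  views <- make_views(X, rpk, aug, fs = store$fs)

  fw_w <- encoder_forward(par, enc_config, views$weak)
  fw_s <- encoder_forward(par, enc_config, views$strong)
  fw_p <- encoder_forward(par, enc_config, Xp)

  w <- loss_weights(is_labeled)

  lt <- temporal_loss_tm(fw_w$h, fw_s$h, nrow(X), loss_cfg$tau_temporal,
                         grad = TRUE)

  use_proj <- enc_config$use_projector && !is.null(par$proj)
  proj_grads <- NULL
  if (use_proj) {
    pf_w <- projector_forward(par$proj, fw_w$z)
    pf_s <- projector_forward(par$proj, fw_s$z)
    pf_p <- projector_forward(par$proj, fw_p$z)
    cz_w <- pf_w$out; cz_s <- pf_s$out; cz_p <- pf_p$out
  } else {
    cz_w <- fw_w$z; cz_s <- fw_s$z; cz_p <- fw_p$z
  }

  lc <- channel_loss_grad(cz_w, cz_p, loss_cfg$tau_channel, grad = TRUE)

  dzc_w <- w[2] * lc$dU
  dzc_p <- w[2] * lc$dV
  dzc_s <- matrix(0, nrow(X), ncol(cz_w))
  ll_val <- 0
  if (is_labeled && w[3] > 0) {
    if (loss_cfg$label_loss_views == "multiview") {
      reps <- rbind(cz_w, cz_s)
      labs <- rep(store$labels[idx], 2)
      ll <- label_loss_grad(reps, labs, loss_cfg$tau_label, grad = TRUE)
      dzc_w <- dzc_w + w[3] * ll$dreps[seq_len(nrow(X)), , drop = FALSE]
      dzc_s <- dzc_s + w[3] * ll$dreps[nrow(X) + seq_len(nrow(X)), ,
                                       drop = FALSE]
    } else {
      ll <- label_loss_grad(cz_w, store$labels[idx], loss_cfg$tau_label,
                            grad = TRUE)
      dzc_w <- dzc_w + w[3] * ll$dreps
    }
    ll_val <- ll$loss
  }

  if (use_proj) {
    pb_w <- projector_backward(dzc_w, par$proj, pf_w$cache)
    pb_s <- projector_backward(dzc_s, par$proj, pf_s$cache)
    pb_p <- projector_backward(dzc_p, par$proj, pf_p$cache)
    dz_w <- pb_w$dz; dz_s <- pb_s$dz; dz_p <- pb_p$dz
    proj_grads <- tree_map2(`+`, tree_map2(`+`, pb_w$grads, pb_s$grads),
                            pb_p$grads)
  } else {
    dz_w <- dzc_w; dz_s <- dzc_s; dz_p <- dzc_p
  }

  # backward one view at a time, releasing each forward cache promptly to
  # bound peak memory
  g_w <- encoder_backward(par, enc_config, fw_w$cache,
                          dH = w[1] * lt$dH, dz = dz_w)
  fw_w$cache <- NULL
  g_s <- encoder_backward(par, enc_config, fw_s$cache,
                          dH = w[1] * lt$dHt, dz = dz_s)
  fw_s$cache <- NULL
  g_p <- encoder_backward(par, enc_config, fw_p$cache, dH = NULL, dz = dz_p)
  fw_p$cache <- NULL

  grads <- tree_map2(`+`, tree_map2(`+`, g_w, g_s), g_p)
  if (use_proj) grads$proj <- proj_grads

  list(grads = grads,
       losses = list(total = w[1] * lt$loss + w[2] * lc$loss + w[3] * ll_val,
                     temporal = lt$loss, channel = lc$loss, label = ll_val))
}

# ---- fine-tuning -------------------------------------------------------------

# Stratified train/holdout split, seeded.
stratified_split <- function(labels, holdout_fraction, seed) {
  test <- withr::with_seed(seed, {
    unlist(lapply(unique(labels), function(cl) {
      idx <- which(labels == cl)
      sample(idx, round(length(idx) * holdout_fraction))
    }))
  })
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

#' Fine-tune a pre-trained encoder for AF detection
#'
#' Trains the downstream classifier (three fully connected layers with batch
#' normalization before each rectifier) with per-class binary cross-entropy
#' on a stratified train split, using Adam and the inverse-decay learning
#' rate of [finetune_lr()], and evaluates on the held-out split. In
#' `"linear_probe"` mode the encoder parameters are frozen (bit-identical
#' before and after); in `"full_finetune"` mode encoder and classifier are
#' updated jointly. No augmentation is applied downstream.
#'
#' @param checkpoint An `af_checkpoint` from [pretrain()] (or
#'   [random_checkpoint()] for an untrained control).
#' @param store A labeled [segment_store()].
#' @param config An [finetune_config()].
#' @param clf_hidden Hidden widths of the classifier MLP.
#' @return An object of class `af_finetune`: encoder parameters, classifier,
#'   configs, the held-out [evaluate()] metrics and a training log.
#' @export
finetune <- function(checkpoint, store, config = finetune_config(),
                     clf_hidden = c(128L, 64L)) {
  stopifnot(inherits(checkpoint, "af_checkpoint"),
            inherits(store, "af_segment_store"))
  if (is.null(store$labels)) stop_af("fine-tuning requires labels")
  enc_config <- checkpoint$encoder_config
  if (ncol(store$segments) != enc_config$input_length) {
    stop_af("checkpoint incompatible: encoder expects length %d, data has %d",
            enc_config$input_length, ncol(store$segments))
  }
  par <- checkpoint$par
  split <- stratified_split(store$labels, config$holdout_fraction,
                            derive_seeds(config$seed, 1L, salt = 41L))
  Xtr <- store$segments[split$train, , drop = FALSE]
  ytr <- store$labels[split$train]
  Xte <- store$segments[split$test, , drop = FALSE]
  yte <- store$labels[split$test]

  clf_cfg <- classifier_config(enc_config$encoder_dim, clf_hidden)
  clf <- init_classifier(clf_cfg, seed = derive_seeds(config$seed, 1L,
                                                      salt = 43L))
  opt_clf <- adam_init(clf$par)
  linear <- config$mode == "linear_probe"
  if (linear) Ztr <- encode_segments(par, enc_config, Xtr)
  opt_enc <- if (!linear) adam_init(par) else NULL

  log_rows <- list()
  for (epoch in seq_len(config$t_max) - 1L) {
    lr <- finetune_lr(epoch, config$eta_base, config$t_max)
    # first-epoch warmup: damp the very first steps so an aggressive base
    # rate cannot collapse the pre-trained representation before the
    # optimizer state is populated
    if (epoch == 0L) lr <- lr * 0.1
    batches <- epoch_batches(length(ytr), config$batch_size,
                             derive_seeds(config$seed, 1L,
                                          salt = 3000L + epoch))
    ep_loss <- 0
    for (idx in batches) {
      Y <- one_hot(ytr[idx], clf_cfg$n_classes)
      if (linear) {
        Z <- Ztr[idx, , drop = FALSE]
        fw <- classifier_forward(clf, Z, training = TRUE)
        ce <- cross_entropy_grad(fw$scores, Y, grad = TRUE)
        bw <- classifier_backward(ce$dScores, clf, fw$cache)
        clf$state <- fw$clf$state
        upd <- adam_step(clf$par, clip_global_norm(bw$grads, 1), opt_clf, lr)
        clf$par <- upd$params; opt_clf <- upd$state
      } else {
        ef <- encoder_forward(par, enc_config, Xtr[idx, , drop = FALSE])
        fw <- classifier_forward(clf, ef$z, training = TRUE)
        ce <- cross_entropy_grad(fw$scores, Y, grad = TRUE)
        bw <- classifier_backward(ce$dScores, clf, fw$cache)
        clf$state <- fw$clf$state
        eg <- encoder_backward(par, enc_config, ef$cache, dH = NULL,
                               dz = bw$dZ)
        upd_c <- adam_step(clf$par, clip_global_norm(bw$grads, 1), opt_clf,
                           lr)
        clf$par <- upd_c$params; opt_clf <- upd_c$state
        upd_e <- adam_step(par, clip_global_norm(eg, 1), opt_enc, lr)
        par <- upd_e$params; opt_enc <- upd_e$state
      }
      ep_loss <- ep_loss + ce$loss * length(idx)
    }
    log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
      epoch = epoch, lr = lr, loss = ep_loss / length(ytr)
    )
  }

  Zte <- encode_segments(par, enc_config, Xte)
  pred <- max.col(classify(clf, Zte)) - 1L
  metrics <- evaluate(pred, yte)
  structure(
    list(par = par, clf = clf, encoder_config = enc_config,
         finetune_config = config, metrics = metrics,
         log = do.call(rbind, log_rows),
         holdout = list(index = split$test, truth = yte, pred = pred)),
    class = "af_finetune"
  )
}

#' Randomly initialized control checkpoint
#'
#' An encoder checkpoint without any pre-training, used as the control for
#' linear probing (representation-quality baseline).
#'
#' @param enc_config An [encoder_config()].
#' @param seed Integer seed.
#' @return An `af_checkpoint` with freshly initialized parameters.
#' @export
random_checkpoint <- function(enc_config = encoder_config(), seed = 1L) {
  structure(
    list(par = init_encoder(enc_config, seed = seed),
         encoder_config = enc_config, loss_config = loss_config(),
         pretrain_config = NULL, log = NULL),
    class = "af_checkpoint"
  )
}

#' Save / load a checkpoint
#'
#' @param checkpoint An `af_checkpoint` or `af_finetune` object.
#' @param path File path.
#' @return `load_checkpoint` returns the stored object.
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

# ---- evaluation --------------------------------------------------------------

#' Macro-averaged classification metrics
#'
#' Accuracy plus macro (unweighted class-mean) sensitivity, precision and
#' F1 from the confusion matrix. Zero-denominator cells contribute 0 and
#' set the `degenerate` flag.
#'
#' @param predictions Integer vector of predicted labels (0/1).
#' @param labels Integer vector of true labels (0/1), same length.
#' @return An object of class `af_metrics` with `acc`, `macro_sen`,
#'   `macro_pre`, `macro_f1`, the `confusion` matrix (rows = truth) and
#'   `degenerate`.
#' @export
evaluate <- function(predictions, labels) {
  if (length(predictions) == 0) stop_af("cannot evaluate an empty prediction set")
  if (length(predictions) != length(labels)) {
    stop_af("predictions and labels differ in length")
  }
  classes <- 0:1
  cm <- table(factor(labels, levels = classes),
              factor(predictions, levels = classes))
  cm <- matrix(as.numeric(cm), 2, 2,
               dimnames = list(truth = c("non-AF", "AF"),
                               pred = c("non-AF", "AF")))
  degenerate <- FALSE
  safe_div <- function(a, b) {
    if (b == 0) { degenerate <<- TRUE; return(0) }
    a / b
  }
  sen <- vapply(1:2, function(k) safe_div(cm[k, k], sum(cm[k, ])), numeric(1))
  pre <- vapply(1:2, function(k) safe_div(cm[k, k], sum(cm[, k])), numeric(1))
  f1 <- vapply(1:2, function(k) {
    if (pre[k] + sen[k] == 0) { degenerate <<- TRUE; 0 } else {
      2 * pre[k] * sen[k] / (pre[k] + sen[k])
    }
  }, numeric(1))
  structure(
    list(acc = sum(diag(cm)) / sum(cm), macro_sen = mean(sen),
         macro_pre = mean(pre), macro_f1 = mean(f1), confusion = cm,
         degenerate = degenerate),
    class = "af_metrics"
  )
}

#' @export
print.af_metrics <- function(x, ...) {
  cat(sprintf(paste0("<af_metrics> acc %.4f | macro sen %.4f | ",
                     "macro pre %.4f | macro F1 %.4f\n"),
              x$acc, x$macro_sen, x$macro_pre, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.af_metrics <- function(x, ...) {
  tibble::tibble(
    metric = c("accuracy", "macro_sensitivity", "macro_precision",
               "macro_f1"),
    value = c(x$acc, x$macro_sen, x$macro_pre, x$macro_f1)
  )
}

#' @exportS3Method generics::glance
glance.af_finetune <- function(x, ...) {
  tibble::tibble(
    mode = x$finetune_config$mode,
    epochs = x$finetune_config$t_max,
    n_holdout = length(x$holdout$truth),
    accuracy = x$metrics$acc,
    macro_f1 = x$metrics$macro_f1
  )
}

#' @exportS3Method generics::tidy
tidy.af_checkpoint <- function(x, ...) {
  if (is.null(x$log)) return(tibble::tibble())
  x$log
}
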