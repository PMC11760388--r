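test_that("learning-rate schedules match their formulas", {
  expect_identical(step_lr(0), 0.001)
  expect_identical(step_lr(2), 0.001)
  expect_identical(step_lr(3), 0.001 * 0.8)
  expect_identical(step_lr(6), 0.001 * 0.8^2)
  expect_equal(step_lr(6), 0.00064)

  expect_identical(finetune_lr(0), 0.001)
  expect_equal(finetune_lr(15, t_max = 30), 0.001 / 36)
  expect_equal(finetune_lr(30, t_max = 30), 0.001 / 121)
  expect_error(finetune_lr(1, t_max = 0), "t_max")
})

test_that("macro metrics match hand-computed confusion arithmetic", {
  # perfect prediction
  m <- evaluate(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(m$acc, 1); expect_equal(m$macro_f1, 1)
  expect_equal(m$macro_sen, 1); expect_equal(m$macro_pre, 1)

  # confusion [[8,2],[1,9]] (rows = truth)
  truth <- c(rep(0, 10), rep(1, 10))
  pred <- c(rep(0, 8), rep(1, 2), rep(1, 9), rep(0, 1))
  m2 <- evaluate(pred, truth)
  sen <- c(8 / 10, 9 / 10)
  pre <- c(8 / 9, 9 / 11)
  f1 <- 2 * pre * sen / (pre + sen)
  expect_equal(m2$acc, 17 / 20)
  expect_equal(m2$macro_sen, mean(sen))
  expect_equal(m2$macro_pre, mean(pre))
  expect_equal(m2$macro_f1, mean(f1))
  expect_equal(unname(m2$confusion), matrix(c(8, 1, 2, 9), 2, 2))

  # all-one-class predictor on a balanced set
  m3 <- evaluate(rep(1, 20), truth)
  expect_equal(m3$acc, 0.5)
  expect_equal(m3$macro_sen, 0.5)
  expect_true(m3$degenerate)

  expect_error(evaluate(integer(0), integer(0)), "empty")
  expect_error(evaluate(c(1, 0), c(1)), "length")

  td <- tidy(m2)
  expect_identical(td$metric[1], "accuracy")
  expect_equal(td$value[1], 0.85)
})

test_that("pre-training runs deterministically and logs the switching rule", {
  ds <- smoke_dataset(16, 16)
  cfg <- pretrain_config(epochs = 2, batch_size = 8, seed = 5)
  ck1 <- pretrain(ds$labeled, ds$unlabeled, cfg, smoke_encoder_config())
  ck2 <- pretrain(ds$labeled, ds$unlabeled, cfg, smoke_encoder_config())
  expect_identical(ck1$par, ck2$par)
  expect_identical(ck1$log, ck2$log)

  log <- ck1$log
  expect_true(all(log$loss_label[log$source == "unlabeled"] == 0))
  expect_true(all(log$loss_label[log$source == "labeled"] > 0))
  expect_true(all(abs(log$loss_total[log$source == "unlabeled"] -
                        (log$loss_temporal + log$loss_channel)[
                          log$source == "unlabeled"] / 2) < 1e-12))
  expect_true(all(abs(log$loss_total[log$source == "labeled"] -
                        (log$loss_temporal + log$loss_channel +
                           log$loss_label)[log$source == "labeled"] / 3) <
                    1e-12))
  # both sources appear, proportionally interleaved
  expect_setequal(unique(log$source), c("labeled", "unlabeled"))
  expect_identical(unique(log$lr), c(0.001))

  # labeled-only and unlabeled-only degenerate paths
  ck_l <- pretrain(ds$labeled, NULL, cfg, smoke_encoder_config())
  expect_true(all(ck_l$log$source == "labeled"))
  ck_u <- pretrain(NULL, ds$unlabeled, cfg, smoke_encoder_config())
  expect_true(all(ck_u$log$loss_label == 0))
  expect_error(pretrain(NULL, NULL, cfg, smoke_encoder_config()), "batch")
})

test_that("projector-enabled pre-training runs and keeps z unprojected", {
  ds <- smoke_dataset(12, 0)
  enc <- encoder_config(input_length = 384,
                        channel_plan = c(4L, 4L, 4L, 8L, 8L, 8L),
                        encoder_dim = 16L, use_projector = TRUE)
  ck <- pretrain(ds$labeled, NULL,
                 pretrain_config(epochs = 1, batch_size = 6, seed = 2), enc)
  expect_true(!is.null(ck$par$proj))
  # downstream encoding bypasses the projector entirely
  z <- encode_segments(ck$par, ck$encoder_config, ds$labeled$segments[1:3, ])
  expect_identical(dim(z), c(3L, 16L))
  expect_true(all(abs(sqrt(rowSums(z^2)) - 1) < 1e-5))
})

test_that("linear probing freezes the encoder; full fine-tuning updates it", {
  ds <- smoke_dataset(40, 0)
  ck <- pretrain(ds$labeled, NULL,
                 pretrain_config(epochs = 1, batch_size = 20, seed = 3),
                 smoke_encoder_config())
  probe <- finetune(ck, ds$labeled,
                    finetune_config("linear_probe", batch_size = 16,
                                    t_max = 5, seed = 4),
                    clf_hidden = c(8L, 4L))
  expect_identical(probe$par, ck$par)          # bit-identical parameters

  full <- finetune(ck, ds$labeled,
                   finetune_config("full_finetune", batch_size = 16,
                                   t_max = 2, seed = 4),
                   clf_hidden = c(8L, 4L))
  expect_false(identical(full$par, ck$par))
  changed <- mapply(function(a, b) !identical(a, b),
                    unlist(full$par$f, recursive = FALSE),
                    unlist(ck$par$f, recursive = FALSE))
  expect_true(any(changed))

  # evaluation artifacts are consistent
  expect_equal(sum(probe$metrics$confusion),
               length(probe$holdout$truth))
  g <- glance(probe)
  expect_identical(g$mode, "linear_probe")
  expect_equal(g$accuracy, probe$metrics$acc)

  # incompatible checkpoint is rejected by shape
  ds_bad <- make_synthetic_dataset(4, 0, seed = 1, duration_s = 30)
  expect_error(finetune(ck, ds_bad$labeled), "incompatible")
})

test_that("pre-training reduces the contrastive loss on smoke data", {
  wins <- vapply(1:5, function(s) {
    ds <- smoke_dataset(32, 32, seed = 100 + s)
    ck <- pretrain(ds$labeled, ds$unlabeled,
                   pretrain_config(epochs = 2, batch_size = 8, seed = s),
                   smoke_encoder_config())
    agg <- tapply(ck$log$loss_total, ck$log$epoch, mean)
    agg[["1"]] < agg[["0"]]
  }, logical(1))
  expect_gte(sum(wins), 4)
})

test_that("checkpoints save and load", {
  ds <- smoke_dataset(8, 0)
  ck <- pretrain(ds$labeled, NULL,
                 pretrain_config(epochs = 1, batch_size = 4, seed = 1),
                 smoke_encoder_config())
  path <- withr::local_tempfile()
  save_checkpoint(ck, path)
  ck2 <- load_checkpoint(path)
  expect_identical(ck2$par, ck$par)
  expect_s3_class(tidy(ck2), "tbl_df")
})
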