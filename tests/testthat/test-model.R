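test_that("encoder shapes follow the configuration arithmetic", {
  cfg <- encoder_config()
  expect_identical(cfg$n_timesteps, 60L)        # 3840 / 2^6
  par <- init_encoder(cfg, seed = 1)
  set.seed(2)
  X <- matrix(rnorm(4 * 3840), 4, 3840)
  h <- conv_extract(par, cfg, X)
  expect_identical(dim(h), c(4L, 60L, 128L))
  z <- fuse_encode(par, cfg, h)
  expect_identical(dim(z), c(4L, 256L))
  expect_true(all(abs(sqrt(rowSums(z^2)) - 1) < 1e-5))

  # determinism and batch independence
  expect_identical(conv_extract(par, cfg, X), h)
  h2 <- conv_extract(par, cfg, rbind(X, X))
  expect_identical(dim(h2), c(8L, 60L, 128L))
  expect_equal(h2[1:4, , ], h, tolerance = 1e-12)

  expect_error(conv_extract(par, cfg, X[, 1:100]), "input_length")
  expect_error(encoder_config(input_length = 100), "divisible")
})

test_that("degenerate hidden input still yields a unit representation", {
  cfg <- tiny_encoder_config()
  par <- init_encoder(cfg, seed = 3)
  # at a generic parameter point the output is bias-driven and nonzero
  par <- withr::with_seed(4, afcontrast:::tree_map(function(x) {
    x + rnorm(length(x), 0, 0.1)
  }, par))
  h0 <- array(0, c(2, 2, 4))
  z <- fuse_encode(par, cfg, h0)
  expect_false(any(is.nan(z)))
  expect_true(all(abs(sqrt(rowSums(z^2)) - 1) < 1e-5))
  expect_error(fuse_encode(par, cfg, array(0, c(2, 0, 4))), "zero time steps")
})

test_that("classifier outputs well-formed scores", {
  ccfg <- classifier_config(16L, hidden = c(8L, 4L))
  clf <- afcontrast:::init_classifier(ccfg, seed = 4)
  set.seed(5)
  Z <- matrix(rnorm(6 * 16), 6, 16)
  S <- classify(clf, Z)
  expect_identical(dim(S), c(6L, 2L))
  P <- afcontrast:::softmax_rows(S)
  expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-6)
  # row independence: permuting inputs permutes outputs
  p <- c(3, 1, 2, 6, 5, 4)
  expect_equal(classify(clf, Z[p, ]), S[p, ], tolerance = 1e-12)
})

test_that("projector is shape-preserving and strictly opt-in", {
  cfg <- tiny_encoder_config(use_projector = TRUE)
  par <- init_encoder(cfg, seed = 6)
  z <- rand_unit_rows(5, cfg$encoder_dim)
  pz <- project(par, cfg, z)
  expect_identical(dim(pz), dim(z))

  cfg_off <- tiny_encoder_config(use_projector = FALSE)
  par_off <- init_encoder(cfg_off, seed = 6)
  expect_error(project(par_off, cfg_off, z), "disabled")
  expect_null(par_off$proj)
})

test_that("encoder backward matches finite differences at a generic point", {
  ns <- asNamespace("afcontrast")
  cfg <- tiny_encoder_config()
  par <- init_encoder(cfg, seed = 2)
  # jitter away from the ReLU kinks that zero-initialized biases sit on
  par <- withr::with_seed(11, ns$tree_map(function(x) {
    x + rnorm(length(x), 0, 0.05)
  }, par))
  set.seed(9)
  B <- 3
  X <- matrix(rnorm(B * cfg$input_length), B, cfg$input_length)
  Wh <- matrix(rnorm(B * 2 * cfg$hidden_dim), B * 2, cfg$hidden_dim)
  Wz <- matrix(rnorm(B * cfg$encoder_dim), B, cfg$encoder_dim)
  lossfun <- function(p) {
    fw <- ns$encoder_forward(p, cfg, X, cache = FALSE)
    sum(fw$h * Wh) + sum(fw$z * Wz)
  }
  fw <- ns$encoder_forward(par, cfg, X, cache = TRUE)
  gr <- ns$encoder_backward(par, cfg, fw$cache, dH = Wh, dz = Wz)
  g_flat <- unlist(gr); p_flat <- unlist(par)
  expect_identical(names(g_flat), names(p_flat))
  set.seed(12)
  sel <- sort(sample(length(p_flat), 120))
  eps <- 1e-6
  num <- vapply(sel, function(k) {
    pp <- p_flat; pp[k] <- pp[k] + eps
    pm <- p_flat; pm[k] <- pm[k] - eps
    (lossfun(utils::relist(pp, par)) - lossfun(utils::relist(pm, par))) /
      (2 * eps)
  }, numeric(1))
  err <- abs(num - g_flat[sel]) / pmax(1e-4, abs(num) + abs(g_flat[sel]))
  expect_lt(max(err), 1e-4)
})

test_that("temporal-loss gradients touch only the convolutional extractor", {
  ns <- asNamespace("afcontrast")
  cfg <- tiny_encoder_config()
  par <- init_encoder(cfg, seed = 7)
  expect_length(intersect(names(unlist(par$f)), names(unlist(par$g))), 0)
  set.seed(8)
  B <- 3
  X <- matrix(rnorm(B * cfg$input_length), B, cfg$input_length)
  Xs <- matrix(rnorm(B * cfg$input_length), B, cfg$input_length)
  fw <- ns$encoder_forward(par, cfg, X)
  fs <- ns$encoder_forward(par, cfg, Xs)
  lt <- ns$temporal_loss_tm(fw$h, fs$h, B, 1.0, grad = TRUE)
  gr <- ns$encoder_backward(par, cfg, fw$cache, dH = lt$dH, dz = NULL)
  # fusion-network gradients are exactly zero; extractor gradients are not
  expect_true(all(unlist(gr$g) == 0))
  expect_gt(max(abs(unlist(gr$f))), 0)
})

test_that("perturbing one input sample moves a contiguous hidden band", {
  cfg <- encoder_config(input_length = 1280,
                        channel_plan = c(2L, 3L, 3L, 4L, 4L, 4L),
                        encoder_dim = 6L)
  par <- init_encoder(cfg, seed = 13)
  set.seed(14)
  x <- matrix(rnorm(cfg$input_length), 1, cfg$input_length)
  h0 <- conv_extract(par, cfg, x)
  x2 <- x; x2[1, 640] <- x2[1, 640] + 10
  h1 <- conv_extract(par, cfg, x2)
  changed <- which(apply(abs(h1 - h0)[1, , , drop = FALSE], 2, max) > 1e-10)
  expect_gt(length(changed), 0)
  expect_identical(changed, seq(min(changed), max(changed)))
  expect_lt(length(changed), cfg$n_timesteps)
})

test_that("full-size forward pass stays within the engineering budget", {
  cfg <- encoder_config()
  par <- init_encoder(cfg, seed = 15)
  set.seed(16)
  X <- matrix(rnorm(256 * 3840), 256, 3840)
  elapsed <- system.time(z <- encode_segments(par, cfg, X))["elapsed"]
  expect_identical(dim(z), c(256L, 256L))
  expect_lt(elapsed, 10)
})
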