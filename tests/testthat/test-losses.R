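test_that("cosine similarity matches its definition", {
  expect_equal(cosine_sim(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_error(cosine_sim(c(0, 0), c(1, 1)), "zero vector")
})

test_that("temporal loss matches closed forms and the loop oracle", {
  # single positive: denominator equals the numerator
  h1 <- array(rnorm(5), c(1, 1, 5))
  expect_equal(temporal_contrastive_loss(h1, h1, 1.0), 0)

  # orthonormal pair at T = 2, tau = 1: -log(e / (e + 2))
  h2 <- array(0, c(1, 2, 2))
  h2[1, 1, ] <- c(1, 0); h2[1, 2, ] <- c(0, 1)
  expect_equal(temporal_contrastive_loss(h2, h2, 1.0), log(1 + 2 / exp(1)),
               tolerance = 1e-9)

  set.seed(31)
  for (rep in 1:5) {
    B <- sample(2:4, 1); T_ <- sample(2:8, 1); D <- sample(3:16, 1)
    h <- array(rnorm(B * T_ * D), c(B, T_, D))
    ht <- array(rnorm(B * T_ * D), c(B, T_, D))
    tau <- runif(1, 0.2, 2)
    expect_equal(temporal_contrastive_loss(h, ht, tau),
                 ref_temporal_loss(h, ht, tau), tolerance = 1e-9)
  }
})

test_that("channel loss matches closed forms and the loop oracle", {
  z1 <- matrix(c(1, 0), 1, 2)
  expect_equal(channel_contrastive_loss(z1, z1, 0.1), 0)
  expect_equal(channel_contrastive_loss(diag(2), diag(2), 1.0),
               log(1 + 2 / exp(1)), tolerance = 1e-9)
  set.seed(32)
  for (rep in 1:5) {
    B <- sample(2:8, 1); D <- sample(3:16, 1)
    z <- rand_unit_rows(B, D); zp <- rand_unit_rows(B, D)
    tau <- runif(1, 0.1, 1.5)
    expect_equal(channel_contrastive_loss(z, zp, tau),
                 ref_channel_loss(z, zp, tau), tolerance = 1e-9)
  }
})

test_that("label loss matches the supervised contrastive oracle", {
  # three identical same-label representations: every ratio is 1/2
  reps <- matrix(rep(c(1, 2, 3) / sqrt(14), 3), 3, 3, byrow = TRUE)
  expect_equal(label_contrastive_loss(reps, c(1, 1, 1), 0.7), log(2),
               tolerance = 1e-12)

  # two samples with different labels: all positive sets empty
  expect_warning(l0 <- label_contrastive_loss(diag(2), c(0, 1), 0.1),
                 "empty positive")
  expect_identical(l0, 0)

  set.seed(33)
  for (rep in 1:5) {
    n <- sample(4:8, 1); D <- sample(3:16, 1)
    reps <- rand_unit_rows(n, D)
    labels <- sample(0:1, n, replace = TRUE)
    if (length(unique(labels)) == 1) labels[1] <- 1 - labels[1]
    tau <- runif(1, 0.1, 1)
    expect_equal(label_contrastive_loss(reps, labels, tau),
                 ref_label_loss(reps, labels, tau), tolerance = 1e-9)
  }
})

test_that("losses are invariant under joint batch permutation", {
  set.seed(34)
  B <- 6; T_ <- 4; D <- 8
  h <- array(rnorm(B * T_ * D), c(B, T_, D))
  ht <- array(rnorm(B * T_ * D), c(B, T_, D))
  z <- rand_unit_rows(B, D); zp <- rand_unit_rows(B, D)
  labels <- c(0, 1, 0, 1, 1, 0)
  p <- sample(B)
  expect_equal(temporal_contrastive_loss(h, ht, 0.8),
               temporal_contrastive_loss(h[p, , , drop = FALSE],
                                         ht[p, , , drop = FALSE], 0.8),
               tolerance = 1e-9)
  expect_equal(channel_contrastive_loss(z, zp, 0.3),
               channel_contrastive_loss(z[p, ], zp[p, ], 0.3),
               tolerance = 1e-9)
  expect_equal(label_contrastive_loss(z, labels, 0.3),
               label_contrastive_loss(z[p, ], labels[p], 0.3),
               tolerance = 1e-9)
})

test_that("high temperature drives losses to their uniform limits", {
  set.seed(35)
  B <- 5; T_ <- 6; D <- 8
  h <- array(rnorm(B * T_ * D), c(B, T_, D))
  ht <- array(rnorm(B * T_ * D), c(B, T_, D))
  # as tau -> Inf all similarities flatten: denominator has 2T - 1 terms
  expect_equal(temporal_contrastive_loss(h, ht, 1e6), log(2 * T_ - 1),
               tolerance = 1e-4)
  z <- rand_unit_rows(B, D); zp <- rand_unit_rows(B, D)
  expect_equal(channel_contrastive_loss(z, zp, 1e6), log(2 * B - 1),
               tolerance = 1e-4)
})

test_that("combined loss applies the semi-supervised switching rule", {
  set.seed(36)
  B <- 4; T_ <- 3; D <- 6
  batch <- list(
    h = array(rnorm(B * T_ * D), c(B, T_, D)),
    h_tilde = array(rnorm(B * T_ * D), c(B, T_, D)),
    z = rand_unit_rows(B, D), z_tilde = rand_unit_rows(B, D),
    z_pair = rand_unit_rows(B, D), labels = c(0, 1, 0, 1)
  )
  cfg <- loss_config()
  lab <- combined_loss(batch, cfg, is_labeled = TRUE)
  expect_equal(lab$weights, rep(1 / 3, 3))
  expect_equal(lab$total,
               (lab$temporal + lab$channel + lab$label) / 3)
  unl <- combined_loss(batch, cfg, is_labeled = FALSE)
  expect_equal(unl$weights, c(0.5, 0.5, 0))
  expect_equal(unl$total, (unl$temporal + unl$channel) / 2)
  expect_identical(unl$label, 0)

  expect_equal(sum(loss_weights(TRUE)), 1)
  expect_equal(sum(loss_weights(FALSE)), 1)

  batch$labels <- NULL
  expect_error(combined_loss(batch, cfg, is_labeled = TRUE), "labels")

  # arithmetic of the convex combination
  expect_equal((0.6 + 0.3 + 0.9) / 3, 0.6)
})

test_that("cross-entropy follows the per-class binary form", {
  # uniform prediction of a 2-class one-hot: -2 log 0.5
  expect_equal(cross_entropy_loss(matrix(c(0, 0), 1, 2),
                                  matrix(c(1, 0), 1, 2)),
               -2 * log(0.5), tolerance = 1e-9)
  # confident correct prediction is ~0
  expect_lt(cross_entropy_loss(matrix(c(50, -50), 1, 2),
                               matrix(c(1, 0), 1, 2)), 1e-5)
  # batch mean equals mean of per-sample losses
  set.seed(37)
  S <- matrix(rnorm(10), 5, 2)
  Y <- afcontrast:::one_hot(sample(0:1, 5, replace = TRUE))
  per <- vapply(1:5, function(i) {
    cross_entropy_loss(S[i, , drop = FALSE], Y[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(cross_entropy_loss(S, Y), mean(per), tolerance = 1e-9)
  expect_error(cross_entropy_loss(S, Y[1:3, ]), "mismatch")
})

test_that("analytic loss gradients match finite differences", {
  ns <- asNamespace("afcontrast")
  set.seed(38)
  B <- 3; T_ <- 4; D <- 5
  H <- matrix(rnorm(B * T_ * D), B * T_, D)
  Ht <- matrix(rnorm(B * T_ * D), B * T_, D)
  res <- ns$temporal_loss_tm(H, Ht, B, 0.9, grad = TRUE)
  gH <- num_grad(function(m) ns$temporal_loss_tm(m, Ht, B, 0.9)$loss, H)
  expect_equal(res$dH, gH, tolerance = 1e-6)

  Z <- matrix(rnorm(B * D), B, D); Zp <- matrix(rnorm(B * D), B, D)
  rc <- ns$channel_loss_grad(Z, Zp, 0.4, grad = TRUE)
  gZ <- num_grad(function(m) ns$channel_loss_grad(m, Zp, 0.4)$loss, Z)
  gZp <- num_grad(function(m) ns$channel_loss_grad(Z, m, 0.4)$loss, Zp)
  expect_equal(rc$dU, gZ, tolerance = 1e-6)
  expect_equal(rc$dV, gZp, tolerance = 1e-6)

  R <- matrix(rnorm(6 * D), 6, D)
  labs <- c(0, 1, 0, 1, 1, 0)
  rl <- ns$label_loss_grad(R, labs, 0.5, grad = TRUE)
  gR <- num_grad(function(m) ns$label_loss_grad(m, labs, 0.5)$loss, R)
  expect_equal(rl$dreps, gR, tolerance = 1e-6)
})
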