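test_that("discriminator is the temperature-scaled cosine exponential", {
  expect_equal(discriminator(c(1, 0), c(1, 0), 0.07), exp(1 / 0.07))
  expect_equal(discriminator(c(1, 0), c(0, 1), 0.5), 1)
  # scale invariance of the cosine
  expect_equal(discriminator(c(3, 0), c(1, 0), 0.07),
               discriminator(c(1, 0), c(1, 0), 0.07))
  # symmetry
  set.seed(1)
  a <- stats::rnorm(6)
  b <- stats::rnorm(6)
  expect_equal(discriminator(a, b, 0.1), discriminator(b, a, 0.1))
  expect_error(discriminator(c(0, 0), c(1, 0)), "zero vector")
  expect_error(discriminator(c(1, 0), c(1, 0, 0)), "dimension")
})

test_that("directed loss is zero at k = 1 and log k on identical embeddings", {
  set.seed(2)
  z <- matrix(stats::rnorm(8), 1)
  expect_equal(contrastive_loss_directed(z, z + 0.1, 0.07), 0)
  for (k in c(2L, 4L, 8L, 64L)) {
    Z <- matrix(1, k, 16)
    expect_equal(contrastive_loss_directed(Z, Z, 0.07), log(k))
    expect_equal(total_loss(Z, Z, 0.07), 2 * log(k))
    expect_equal(multiview_loss(list(Z, Z, Z), 0.07), 6 * log(k))
  }
})

test_that("vectorized losses match the double-loop oracle on random batches", {
  set.seed(42)
  for (rep in 1:100) {
    k <- sample(2:16, 1)
    m <- sample(2:32, 1)
    tau <- sample(c(0.05, 0.07, 0.08, 0.5), 1)
    Z1 <- matrix(stats::rnorm(k * m), k)
    Z2 <- matrix(stats::rnorm(k * m), k)
    expect_equal(contrastive_loss_directed(Z1, Z2, tau),
                 oracle_directed_loss(Z1, Z2, tau), tolerance = 1e-6)
    expect_equal(total_loss(Z1, Z2, tau), oracle_total_loss(Z1, Z2, tau),
                 tolerance = 1e-6)
  }
})

test_that("total loss is symmetric and the 2-view multiview degenerates to it", {
  set.seed(3)
  Z1 <- matrix(stats::rnorm(8 * 16), 8)
  Z2 <- matrix(stats::rnorm(8 * 16), 8)
  expect_equal(total_loss(Z1, Z2, 0.07) - total_loss(Z2, Z1, 0.07), 0,
               tolerance = 1e-9)
  expect_equal(multiview_loss(list(Z1, Z2), 0.07), total_loss(Z1, Z2, 0.07))
  Z3 <- matrix(stats::rnorm(8 * 16), 8)
  expect_equal(multiview_loss(list(Z1, Z2, Z3), 0.07),
               total_loss(Z1, Z2, 0.07) + total_loss(Z1, Z3, 0.07) +
                 total_loss(Z2, Z3, 0.07), tolerance = 1e-6)
  expect_error(multiview_loss(list(Z1), 0.07), "at least 2")
  expect_error(contrastive_loss_directed(Z1, Z2[1:4, ], 0.07), "mismatch")
})

test_that("directed loss is nonnegative and bounded by 2/tau + log k", {
  set.seed(4)
  for (rep in 1:50) {
    k <- sample(2:12, 1)
    tau <- stats::runif(1, 0.05, 1)
    Z1 <- matrix(stats::rnorm(k * 8), k)
    Z2 <- matrix(stats::rnorm(k * 8), k)
    l <- contrastive_loss_directed(Z1, Z2, tau)
    expect_gte(l, 0)
    expect_lte(l, 2 / tau + log(k))
  }
})

test_that("loss increases with temperature at fixed separated geometry", {
  # congruent cosine 1, all non-congruent cosines 0
  k <- 4L
  Z1 <- diag(1, k)
  Z2 <- diag(1, k)
  taus <- c(0.05, 0.06, 0.07, 0.08, 0.2, 0.5, 1)
  losses <- vapply(taus, function(t) contrastive_loss_directed(Z1, Z2, t), 1)
  expect_true(all(diff(losses) > 0))
})

test_that("analytic gradients match finite differences", {
  set.seed(5)
  Z1 <- matrix(stats::rnorm(4 * 8), 4)
  Z2 <- matrix(stats::rnorm(4 * 8), 4)
  g <- total_loss_grad(Z1, Z2, 0.07)
  eps <- 1e-6
  for (probe in 1:10) {
    i <- sample(4, 1)
    j <- sample(8, 1)
    Zp <- Z1; Zp[i, j] <- Zp[i, j] + eps
    Zm <- Z1; Zm[i, j] <- Zm[i, j] - eps
    fd <- (total_loss(Zp, Z2, 0.07) - total_loss(Zm, Z2, 0.07)) / (2 * eps)
    expect_equal(g$dZ1[i, j], fd, tolerance = 1e-4)
    Zp <- Z2; Zp[i, j] <- Zp[i, j] + eps
    Zm <- Z2; Zm[i, j] <- Zm[i, j] - eps
    fd2 <- (total_loss(Z1, Zp, 0.07) - total_loss(Z1, Zm, 0.07)) / (2 * eps)
    expect_equal(g$dZ2[i, j], fd2, tolerance = 1e-4)
  }
})

test_that("per-anchor diagnostics report congruent rank", {
  Z <- diag(1, 3)
  d <- contrastive_diagnostics(Z, Z, 0.07)
  expect_equal(d$congruent_rank, c(1L, 1L, 1L))
  expect_true(all(d$mean_negative_similarity < 1))
})

test_that("contrastive_config validates its fields", {
  cc <- contrastive_config(0.07, 8L)
  expect_equal(cc$temperature, 0.07)
  expect_error(contrastive_config(-1), "temperature")
  expect_error(contrastive_config(0.07, 0L), "batch_size")
})
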