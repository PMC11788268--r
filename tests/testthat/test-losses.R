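# Training objective: closed forms, oracle agreement, gradients.

make_onehot <- function(lab, C = 2) {
  y <- array(0, c(nrow(lab), ncol(lab), C))
  for (k in seq_len(C)) y[, , k] <- (lab == k - 1) * 1
  y
}

test_that("dice_loss hits its limit cases and the hand-computed example", {
  lab <- matrix(c(0, 1, 1, 0), 2, 2)
  y <- make_onehot(lab)
  expect_equal(dice_loss(y, y), 0)
  inv <- make_onehot(1 - lab)
  expect_equal(dice_loss(inv, y), 1)
  # 1x2 image, C = 2: hand evaluation gives 0.3
  p <- array(c(0.8, 0.4, 0.2, 0.6), c(1, 2, 2))
  yy <- array(c(1, 0, 0, 1), c(1, 2, 2))
  expect_equal(dice_loss(p, yy), 0.3, tolerance = 1e-12)
})

test_that("cross_entropy_loss matches closed forms and the loop oracle", {
  lab <- matrix(c(0, 1, 0, 1), 2, 2)
  y <- make_onehot(lab)
  expect_equal(cross_entropy_loss(y, y), 0, tolerance = 1e-9)
  u <- array(0.5, c(2, 2, 2))
  expect_equal(cross_entropy_loss(u, y), log(2) / 2, tolerance = 1e-12)
  set.seed(4)
  p <- array(runif(8, 0.05, 0.95), c(2, 2, 2))
  p[, , 2] <- 1 - p[, , 1]
  expect_equal(cross_entropy_loss(p, y), oracle_ce(p, y), tolerance = 1e-12)
})

test_that("segmentation_loss is the sum of its parts", {
  set.seed(6)
  lab <- rand_mask(4, 4)
  y <- make_onehot(lab)
  p <- array(runif(32, 0.01, 0.99), c(4, 4, 2))
  p[, , 2] <- 1 - p[, , 1]
  expect_equal(segmentation_loss(p, y), dice_loss(p, y) + cross_entropy_loss(p, y))
  expect_equal(segmentation_loss(y, y), 0, tolerance = 1e-9)
})

test_that("levelset_mse obeys its closed forms", {
  set.seed(2)
  a <- array(rnorm(36), c(3, 4, 3))
  expect_equal(levelset_mse(a, a), 0)
  expect_equal(levelset_mse(a + 0.7, a), 0.49, tolerance = 1e-12)
  b <- array(rnorm(36), c(3, 4, 3))
  expect_equal(levelset_mse(a, b), mean((a - b)^2))
})

test_that("curvature_loss vanishes for identical or flat fields and matches the two-step oracle", {
  phi <- signed_distance(disk_mask(32, 16, 16, 8) * 1L)
  expect_equal(curvature_loss(phi, phi), 0)
  expect_equal(curvature_loss(matrix(2, 16, 16), matrix(-1, 16, 16)), 0)
  phi_t <- signed_distance(disk_mask(128, 64, 64, 20) * 1L)
  phi_p <- signed_distance(disk_mask(128, 64, 64, 10) * 1L)
  got <- curvature_loss(phi_t, phi_p)   # symmetric in its two arguments
  want <- mean(abs(oracle_curvature(sharpen_levelset(phi_t)) -
                     oracle_curvature(sharpen_levelset(phi_p))))
  expect_gt(got, 0)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("total_loss combines components linearly in the lambdas", {
  set.seed(10)
  lab <- rand_mask(4, 4)
  y <- make_onehot(lab)
  p <- array(runif(32, 0.1, 0.9), c(4, 4, 2)); p[, , 2] <- 1 - p[, , 1]
  phi_t <- array(rnorm(32), c(4, 4, 2))
  phi_p <- phi_t + rnorm(32, sd = 0.2)
  # hand-combined components
  r <- total_loss(p, y, phi_p, phi_t, loss_weights(1, 0.1, 1e-4))
  expect_equal(r$total,
               1 * r$seg_loss + 0.1 * r$levelset_mse + 1e-4 * r$curvature_loss,
               tolerance = 1e-9)
  # stated example: components (0.5, 2, 10) with (1, 0.1, 1e-4) -> 0.701
  expect_equal(1 * 0.5 + 0.1 * 2 + 1e-4 * 10, 0.701, tolerance = 1e-12)
  # reductions
  r0 <- total_loss(p, y, phi_p, phi_t, loss_weights(1, 0, 0))
  expect_equal(r0$total, segmentation_loss(p, y), tolerance = 1e-9)
  rz <- total_loss(p, y, phi_p, phi_t, loss_weights(0, 0, 0))
  expect_equal(rz$total, 0)
  # linearity in lambda2 with everything else fixed
  r1 <- total_loss(p, y, phi_p, phi_t, loss_weights(1, 0.2, 0))
  r2 <- total_loss(p, y, phi_p, phi_t, loss_weights(1, 0.6, 0))
  expect_equal(r2$total - r0$total, 3 * (r1$total - r0$total), tolerance = 1e-9)
})

test_that("loss ranges hold on random inputs", {
  set.seed(12)
  for (t in 1:10) {
    lab <- rand_mask(5, 5)
    y <- make_onehot(lab)
    p <- array(runif(50, 0.01, 0.99), c(5, 5, 2)); p[, , 2] <- 1 - p[, , 1]
    expect_gte(dice_loss(p, y), 0); expect_lte(dice_loss(p, y), 1)
    expect_gte(cross_entropy_loss(p, y), 0)
    a <- array(rnorm(50), c(5, 5, 2)); b <- array(rnorm(50), c(5, 5, 2))
    expect_gte(curvature_loss(a, b, scale = 2), 0)
  }
})

test_that("analytic curvature-loss gradient matches finite differences", {
  set.seed(13)
  phi_t <- signed_distance(disk_mask(12, 6, 6, 3) * 1L)
  phi_p <- phi_t + matrix(rnorm(144, sd = 0.3), 12, 12)
  sc <- 2
  g <- curvature_loss_grad(phi_p, phi_t, scale = sc)
  h <- 1e-6
  for (t in 1:25) {
    i <- sample(144, 1)
    pp <- phi_p; pp[i] <- pp[i] + h
    pm <- phi_p; pm[i] <- pm[i] - h
    fd <- (curvature_loss(pp, phi_t, scale = sc) -
             curvature_loss(pm, phi_t, scale = sc)) / (2 * h)
    expect_equal(g[i], fd, tolerance = 1e-3)
  }
})

test_that("segmentation-loss gradient w.r.t. logits matches finite differences", {
  set.seed(14)
  lab <- rand_mask(4, 4)
  y <- make_onehot(lab)
  z <- array(rnorm(32), c(4, 4, 2))
  p <- shapeprior:::softmax_channels(z)
  g <- shapeprior:::seg_loss_grad_logits(p, y)
  h <- 1e-6
  for (t in 1:20) {
    i <- sample(32, 1)
    zp <- z; zp[i] <- zp[i] + h
    zm <- z; zm[i] <- zm[i] - h
    fd <- (segmentation_loss(shapeprior:::softmax_channels(zp), y) -
             segmentation_loss(shapeprior:::softmax_channels(zm), y)) / (2 * h)
    expect_equal(g[i], fd, tolerance = 1e-6)
  }
})

test_that("loss reports serialize to one CSV row per step", {
  lab <- matrix(c(0, 1, 1, 0, 1, 0, 0, 1, 1), 3, 3)
  y <- make_onehot(lab)
  reps <- list(total_loss(y, y), total_loss(y, y))
  f <- tempfile(fileext = ".csv")
  write_loss_csv(reps, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 2)
  expect_named(df, c("step", "seg", "dice", "ce", "mse", "curv", "total"))
  unlink(f)
})
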