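test_that("all losses vanish at a perfect prediction", {
  set.seed(1)
  t <- matrix(rbinom(256, 1, 0.2), 16, 16)
  expect_lt(focal_loss(t, t), 1e-6)
  expect_lt(dice_loss(t, t), 1e-6)
  expect_lt(hd_loss(t, t), 1e-6)
  expect_lt(phase1_loss(t, t), 1e-5)
})

test_that("focal loss with gamma 0 and balanced alpha is half the BCE", {
  set.seed(2)
  p <- matrix(runif(64, 0.05, 0.95), 8, 8)
  t <- matrix(rbinom(64, 1, 0.5), 8, 8)
  bce <- -mean(t * log(p) + (1 - t) * log(1 - p))
  expect_equal(2 * focal_loss(p, t, alpha = 0.5, gamma = 0), bce,
               tolerance = 1e-9)
})

test_that("focal loss matches the hand-evaluated formula", {
  p <- matrix(0.5, 2, 2)
  t <- matrix(1, 2, 2)
  expect_equal(focal_loss(p, t, alpha = 0.25, gamma = 2),
               -0.25 * 0.25 * log(0.5), tolerance = 1e-12)
})

test_that("dice loss reproduces its closed forms and limits", {
  n <- 64
  t0 <- matrix(0, 8, 8)
  p1 <- matrix(1, 8, 8)
  expect_equal(dice_loss(p1, t0, smooth = 1e-12), 1, tolerance = 1e-9)
  t_half <- matrix(rep(c(1, 0), each = 32), 8, 8)
  expect_equal(dice_loss(p1, t_half, smooth = 1e-12), 1 / 3,
               tolerance = 1e-9)
})

test_that("dice loss is invariant to consistent pixel permutation", {
  set.seed(3)
  p <- matrix(runif(100), 10, 10)
  t <- matrix(rbinom(100, 1, 0.3), 10, 10)
  perm <- sample(100)
  expect_equal(dice_loss(p, t),
               dice_loss(matrix(p[perm], 10, 10),
                         matrix(t[perm], 10, 10)))
})

test_that("hd loss is zero for empty-empty and grows with displacement", {
  z <- matrix(0, 32, 32)
  expect_equal(hd_loss(z, z), 0)
  target <- matrix(0, 32, 32); target[16, 16] <- 1
  losses <- vapply(c(1, 3, 5, 8), function(k) {
    pred <- matrix(0, 32, 32); pred[16, 16 + k] <- 1
    hd_loss(pred, target)
  }, numeric(1))
  expect_true(all(diff(losses) > 0))
  # ordering consistent with exact Hausdorff distance on the point sets
  hds <- vapply(c(1, 3, 5, 8), function(k)
    oracle_hausdorff(matrix(c(16, 16), 1), matrix(c(16, 16 + k), 1)),
    numeric(1))
  expect_equal(order(losses), order(hds))
})

test_that("phase-1 weights select the component losses", {
  set.seed(4)
  p <- matrix(runif(64, 0.1, 0.9), 8, 8)
  t <- matrix(rbinom(64, 1, 0.3), 8, 8)
  expect_equal(phase1_loss(p, t, loss_config(phase1_weights = c(1, 0))),
               focal_loss(p, t))
  expect_equal(phase1_loss(p, t, loss_config(phase1_weights = c(0, 1))),
               dice_loss(p, t))
  expect_error(loss_config(phase1_weights = c(0, 0)))
})

test_that("losses stay finite and non-negative on random inputs", {
  set.seed(5)
  for (i in 1:20) {
    p <- matrix(runif(64), 8, 8)
    t <- matrix(rbinom(64, 1, runif(1)), 8, 8)
    for (l in c(focal_loss(p, t), dice_loss(p, t), hd_loss(p, t))) {
      expect_true(is.finite(l))
      expect_gte(l, 0)
    }
  }
  expect_error(focal_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("analytic loss gradients agree with numeric differentiation", {
  set.seed(6)
  p <- matrix(runif(36, 0.2, 0.8), 6, 6)
  t <- matrix(rbinom(36, 1, 0.4), 6, 6)
  eps <- 1e-6
  for (fn in list(
    function(x, g) focal_loss(x, t, grad = g),
    function(x, g) dice_loss(x, t, grad = g),
    function(x, g) hd_loss(x, t, grad = g),
    function(x, g) phase1_loss(x, t, grad = g))) {
    an <- fn(p, TRUE)$grad
    for (idx in c(1, 17, 36)) {
      p1 <- p; p1[idx] <- p1[idx] + eps
      p2 <- p; p2[idx] <- p2[idx] - eps
      num <- (fn(p1, FALSE) - fn(p2, FALSE)) / (2 * eps)
      expect_equal(an[idx], num, tolerance = 1e-4)
    }
  }
})
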