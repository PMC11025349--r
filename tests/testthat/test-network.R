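tiny_cfg <- function() network_config(input_size = 64, width_divisor = 32)

test_that("configuration invariants are enforced", {
  expect_error(network_config(encoder_channels = c(64, 128, 256, 512,
                                                   1024, 2048)),
               "7 entries")
  expect_error(network_config(decoder_channels = rep(64, 5)), "6 entries")
  expect_error(network_config(input_size = 500), "divisible by 64")
  expect_error(network_config(width_divisor = 48), "width_divisor")
  expect_error(network_config(skip_merge = "add"), "concat")
})

test_that("forward maps tiles to same-size probability maps in [0,1]", {
  m <- build_network(tiny_cfg(), seed = 2)
  x <- matrix(runif(64 * 64), 64, 64)
  out <- net_forward(m, x)
  expect_length(out, 1)
  expect_equal(dim(out[[1]]), c(64, 64))
  expect_true(all(out[[1]] >= 0 & out[[1]] <= 1))
  expect_error(net_forward(m, matrix(0, 32, 32)), "64x64")
})

test_that("inference is deterministic and numerically sane", {
  m <- build_network(tiny_cfg(), seed = 3)
  x <- matrix(runif(64 * 64), 64, 64)
  out <- net_forward(m, list(x, x))
  expect_identical(out[[1]], out[[2]])
  z <- net_forward(m, matrix(0, 64, 64))[[1]]
  expect_true(all(is.finite(z)))
})

test_that("encoder halves resolution at every block except the first", {
  cfg <- network_config(input_size = 128, width_divisor = 8)
  m <- build_network(cfg, seed = 1)
  x <- array(runif(128 * 128), dim = c(128, 128, 1, 1))
  r <- calcseg:::net_forward_full(m, x, training = FALSE)
  res <- vapply(r$enc_shapes, `[`, 1, 1)
  expect_equal(res, c(128, 64, 32, 16, 8, 4, 2))
  chans <- vapply(r$enc_shapes, `[`, 1, 3)
  expect_equal(chans, c(64, 64, 128, 256, 512, 1024, 2048) / 8)
  expect_equal(dim(r$y)[1:2], c(128, 128))  # decoder mirrors back up
})

test_that("parameter count shrinks about quadratically with the divisor", {
  n8 <- n_params(build_network(network_config(width_divisor = 8), seed = 1))
  n16 <- n_params(build_network(network_config(width_divisor = 16),
                                seed = 1))
  ratio <- n8 / n16
  expect_gt(ratio, 3)   # ~4 expected from quadratic scaling
  expect_lt(ratio, 5)
})

test_that("one small gradient step decreases the training loss", {
  set.seed(9)
  cfg <- tiny_cfg()
  m <- build_network(cfg, seed = 4)
  x <- array(runif(64 * 64), dim = c(64, 64, 1, 1))
  t <- array(0, dim = c(64, 64, 1, 1))
  t[20:30, 20:30, 1, 1] <- 1
  fw <- calcseg:::net_forward_full(m, x, training = TRUE)
  l0 <- phase1_loss(fw$y, t, loss_config(), grad = TRUE)
  grads <- calcseg:::net_backward_full(fw$model, fw$caches, l0$grad)
  st <- calcseg:::adam_apply(fw$model$blocks, grads,
                             calcseg:::adam_init(grads), lr = 1e-3)
  m2 <- fw$model
  m2$blocks <- st$blocks
  fw2 <- calcseg:::net_forward_full(m2, x, training = TRUE)
  l1 <- phase1_loss(fw2$y, t, loss_config())
  expect_lt(l1, l0$loss)
})

test_that("backprop matches numeric gradients across block types", {
  set.seed(10)
  m <- build_network(tiny_cfg(), seed = 5)
  x <- array(runif(64 * 64 * 2), dim = c(64, 64, 1, 2))
  t <- array(rbinom(64 * 64 * 2, 1, 0.05), dim = c(64, 64, 1, 2))
  lossfun <- function(model) {
    f <- calcseg:::net_forward_full(model, x, training = TRUE)
    phase1_loss(f$y, t, loss_config())
  }
  fw <- calcseg:::net_forward_full(m, x, training = TRUE)
  lg <- phase1_loss(fw$y, t, loss_config(), grad = TRUE)
  gr <- calcseg:::net_backward_full(fw$model, fw$caches, lg$grad)
  probes <- list(
    list(g = gr$b0$conv$w[1, 1],
         set = function(mm, e) { mm$blocks$b0$conv$w[1, 1] <-
           mm$blocks$b0$conv$w[1, 1] + e; mm }),
    list(g = gr$b2$expand$w[5, 2],
         set = function(mm, e) { mm$blocks$b2$expand$w[5, 2] <-
           mm$blocks$b2$expand$w[5, 2] + e; mm }),
    list(g = gr$b2$se$w1[1, 1],
         set = function(mm, e) { mm$blocks$b2$se$w1[1, 1] <-
           mm$blocks$b2$se$w1[1, 1] + e; mm }),
    list(g = gr$d1$up$w[1, 1, 1, 1],
         set = function(mm, e) { mm$blocks$d1$up$w[1, 1, 1, 1] <-
           mm$blocks$d1$up$w[1, 1, 1, 1] + e; mm }),
    list(g = gr$d4$merge$w[2, 1],
         set = function(mm, e) { mm$blocks$d4$merge$w[2, 1] <-
           mm$blocks$d4$merge$w[2, 1] + e; mm }),
    list(g = gr$b1$bn1$gamma[2],
         set = function(mm, e) { mm$blocks$b1$bn1$gamma[2] <-
           mm$blocks$b1$bn1$gamma[2] + e; mm }),
    list(g = gr$head$conv$b[1],
         set = function(mm, e) { mm$blocks$head$conv$b[1] <-
           mm$blocks$head$conv$b[1] + e; mm }))
  eps <- 1e-5
  for (pr in probes) {
    num <- (lossfun(pr$set(m, eps)) - lossfun(pr$set(m, -eps))) / (2 * eps)
    expect_equal(pr$g, num, tolerance = 1e-4)
  }
})
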