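test_that("deep attention is a proper softmax over layer scores", {
  p <- fixture_attention()
  x <- fixture_xdeep

  # zero weights: uniform coefficients
  p0 <- p
  p0$w_deep <- matrix(0, 2, 6)
  expect_equal(deep_attention(p0, x), c(0.5, 0.5))

  # softmax closed form for logits (1, 0, 0)
  p3 <- attention_params(n_layers = 3, n_hidden = 1, n_classes = 2, seed = 1)
  p3$w_deep <- matrix(c(1, 0, 0), 3, 3)[, 1, drop = FALSE] %*% t(c(1, 0, 0))
  a <- deep_attention(p3, c(1, 0, 0))
  expect_equal(a, c(exp(1), 1, 1) / (exp(1) + 2), tolerance = 1e-12)
  expect_equal(a[1], 0.57612, tolerance = 1e-5)
  expect_equal(a[2], 0.21194, tolerance = 1e-5)

  # shift invariance of the logits
  z <- as.numeric(p$w_deep %*% x)
  expect_equal(softmax(z), softmax(z + 100))
  expect_equal(sum(deep_attention(p, x)), 1, tolerance = 1e-12)

  expect_error(deep_attention(p, c(1, 2)), "length")
})

test_that("layer collapse is the attention-weighted block sum", {
  x <- c(1, 0, 0, 0, 1, 0)   # X1 = (1,0,0), X2 = (0,1,0)
  expect_equal(collapse_layers(x, c(0, 1), 3), c(0, 1, 0))  # one-hot select
  expect_equal(collapse_layers(x, c(0.5, 0.5), 3), c(0.5, 0.5, 0))
  # identical layer states are a fixed point for any normalized weights
  xx <- c(2, 3, 4, 2, 3, 4)
  expect_equal(collapse_layers(xx, c(0.3, 0.7), 3), c(2, 3, 4))
})

test_that("spatial attention gates are independent logistics", {
  p <- fixture_attention()
  p0 <- p
  p0$w_spatial <- matrix(0, 3, 6)
  expect_equal(spatial_attention(p0, fixture_xdeep), rep(0.5, 3))

  # logistic closed form at logit 2
  p1 <- p
  p1$w_spatial <- rbind(c(2, 0, 0, 0, 0, 0), matrix(0, 2, 6))
  g <- spatial_attention(p1, c(1, 0, 0, 0, 0, 0))
  expect_equal(g[1], 0.880797, tolerance = 1e-6)

  set.seed(1)
  for (i in 1:20) {
    g <- spatial_attention(p, rnorm(6, sd = 10))
    expect_true(all(g > 0 & g < 1))
  }
})

test_that("readout chain matches an independent hand computation", {
  p <- fixture_attention()
  x <- fixture_xdeep

  # zero state: all class scores at logistic(0) = 0.5, first class wins
  r0 <- readout(p, rep(0, 6))
  expect_equal(r0$y, c(0.5, 0.5))
  expect_equal(r0$label, 1L)

  # full chain, recomputed with explicit scalar arithmetic
  z1 <- sum(p$w_deep[1, ] * x); z2 <- sum(p$w_deep[2, ] * x)
  a1 <- exp(z1) / (exp(z1) + exp(z2)); a2 <- 1 - a1
  xs <- a1 * x[1:3] + a2 * x[4:6]
  gate <- sapply(1:3, function(n) 1 / (1 + exp(-sum(p$w_spatial[n, ] * x))))
  xf <- xs * gate
  y <- sapply(1:2, function(o) 1 / (1 + exp(-sum(p$w_out[o, ] * xf))))

  r <- readout(p, x)
  expect_equal(r$a_deep, c(a1, a2), tolerance = 1e-12)
  expect_equal(r$x_s, xs, tolerance = 1e-12)
  expect_equal(r$a_spatial, gate, tolerance = 1e-12)
  expect_equal(r$x_f, xf, tolerance = 1e-12)
  expect_equal(r$y, y, tolerance = 1e-12)
  expect_equal(r$label, which.max(y))

  # attention-transparent limit: gates forced to 1 pass X_S through
  p_open <- p
  p_open$w_spatial <- matrix(1e4, 3, 6)
  r_open <- readout(p_open, x)
  expect_equal(r_open$x_f, r_open$x_s, tolerance = 1e-8)
})

test_that("analytic gradients match central finite differences", {
  p <- fixture_attention()
  set.seed(4)
  X <- matrix(rnorm(8 * 6), 8, 6)
  labels <- rep(1:2, 4)
  lg <- deeplsm:::attention_loss_grad(p, X, labels)
  h <- 1e-5
  for (block in c("w_deep", "w_spatial", "w_out")) {
    g <- lg$grads[[block]]
    for (idx in seq_len(length(p[[block]]))) {
      pp <- p; pp[[block]][idx] <- pp[[block]][idx] + h
      pm <- p; pm[[block]][idx] <- pm[[block]][idx] - h
      fd <- (deeplsm:::attention_loss_grad(pp, X, labels)$loss -
             deeplsm:::attention_loss_grad(pm, X, labels)$loss) / (2 * h)
      denom <- max(abs(fd), abs(g[idx]), 1e-2)
      expect_lt(abs(fd - g[idx]) / denom, 1e-5)
    }
  }
})

test_that("full-batch descent is monotone at small lr and inert at lr 0", {
  set.seed(9)
  X <- matrix(rnorm(12 * 6), 12, 6)
  labels <- rep(1:2, 6)
  p <- fixture_attention()

  fit0 <- train_readout(X, labels, 2, 3, lr = 0, epochs = 5, params = p)
  expect_equal(fit0$params$w_deep, p$w_deep)
  expect_equal(fit0$params$w_out, p$w_out)

  fit <- train_readout(X, labels, 2, 3, lr = 1e-3, epochs = 100, params = p)
  expect_true(all(diff(fit$loss) <= 1e-12))
})

test_that("a separable synthetic problem is learned to high accuracy", {
  set.seed(2)
  n <- 40
  X <- rbind(matrix(rnorm(n / 2 * 6, mean = 1), n / 2, 6),
             matrix(rnorm(n / 2 * 6, mean = -1), n / 2, 6))
  labels <- rep(1:2, each = n / 2)
  fit <- train_readout(X, labels, 2, 3, lr = 0.5, epochs = 500, seed = 3)
  expect_gte(fit$accuracy, 0.95)
  expect_error(train_readout(X, rep(1L, n), 2, 3), "single-class")
})
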