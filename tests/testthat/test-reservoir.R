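test_that("grid construction gives an exact 4:1 E:I split", {
  g <- build_grid(grid_spec(c(5, 5, 5), seed = 2))
  expect_equal(g$n_exc, 100)
  expect_equal(g$n_inh, 25)
  g2 <- build_grid(grid_spec(c(10, 10, 10), seed = 2))
  expect_equal(g2$n_exc, 800)
  expect_equal(g2$n_inh, 200)
  expect_equal(sum(g2$is_excitatory), 800)

  # determinism: same seed, identical labels and positions
  g3 <- build_grid(grid_spec(c(10, 10, 10), seed = 2))
  expect_identical(g2$is_excitatory, g3$is_excitatory)
  expect_identical(g2$positions, g3$positions)

  expect_error(grid_spec(c(3, 3, 3)), "divisible")
})

test_that("most-cubic factorization recovers reference shapes", {
  expect_equal(cubic_dims(1000), c(10, 10, 10))
  expect_equal(sort(cubic_dims(500)), c(5, 10, 10))
  expect_equal(prod(cubic_dims(50)), 50)
})

test_that("connection probability follows the squared-exponential law", {
  expect_equal(connection_prob(0, 0.6, 3), 0.6)
  expect_equal(connection_prob(3, 0.6, 3), 0.6 * exp(-2), tolerance = 1e-12)
  # monotone decrease with distance
  d <- seq(0, 10, by = 0.5)
  expect_true(all(diff(connection_prob(d, 1, 3)) < 0))
})

test_that("empirical connection frequencies match the law within 3 SE", {
  params <- connectivity_params()
  counts <- list(EE = c(0, 0), EI = c(0, 0)) # (connections, pairs) per D = 1
  hits <- setNames(numeric(3), 1:3)
  trials <- setNames(numeric(3), 1:3)
  for (seed in 1:25) {
    g <- build_grid(grid_spec(c(10, 5, 5), seed = seed))
    syn <- connect_recurrent(g, params, seed = seed)
    w <- as.matrix(syn$w != 0)
    d <- as.matrix(dist(g$positions))
    ee <- outer(g$is_excitatory, g$is_excitatory, "&")
    diag(ee) <- FALSE
    for (D in 1:3) {
      sel <- ee & abs(d - D) < 1e-9
      hits[D] <- hits[D] + sum(w[sel])
      trials[D] <- trials[D] + sum(sel)
    }
  }
  for (D in 1:3) {
    expect_gt(trials[D], 10000) # enough seeded draws per distance bin
    p <- connection_prob(D, params$c_max[["EE"]], params$lam[["EE"]])
    se <- sqrt(p * (1 - p) / trials[D])
    expect_lt(abs(hits[D] / trials[D] - p), 3 * se)
  }
})

test_that("recurrent topology is pure and excludes self-connections", {
  g <- tiny_grid()
  s1 <- connect_recurrent(g, connectivity_params(), seed = 9)
  s2 <- connect_recurrent(g, connectivity_params(), seed = 9)
  expect_equal(s1$w, s2$w)
  expect_true(all(Matrix::diag(s1$w) == 0))
})

test_that("input projection sampling is binomial and seeded", {
  g <- build_grid(grid_spec(c(10, 10, 10), seed = 1))
  s0 <- connect_input(100, g, 0, seed = 1)
  expect_equal(n_synapses(s0), 0)
  expect_false(any(s0$primary))

  s <- connect_input(100, g, 0.05, seed = 4)
  n_pairs <- 100 * 1000
  se <- sqrt(n_pairs * 0.05 * 0.95)
  expect_lt(abs(n_synapses(s) - n_pairs * 0.05), 3 * se)

  s2 <- connect_input(100, g, 0.05, seed = 4)
  expect_equal(s$w, s2$w)
  expect_identical(s$primary, s2$primary)
})

test_that("normalization drives incoming class sums to their targets", {
  # single incoming excitatory synapse scales to the full target
  w <- Matrix::sparseMatrix(i = 1, j = 1, x = 3, dims = c(1, 1))
  s <- synapse_set(w, sign = 1, tag = "recurrent")
  expect_equal(normalize_synapses(s)$w[1, 1], 40)

  # proportional rescale of {2, 6} to target 40
  w <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 1), x = c(2, 6),
                            dims = c(2, 1))
  s <- synapse_set(w, sign = c(1, 1), tag = "recurrent")
  expect_equal(as.numeric(normalize_synapses(s)$w[, 1]), c(10, 30))

  # a real reservoir build: every neuron's incoming E sum is 40, I sum 36
  g <- build_grid(grid_spec(c(5, 5, 4), seed = 3))
  syn <- normalize_synapses(connect_recurrent(g, connectivity_params(),
                                              seed = 3))
  we <- Matrix::colSums(syn$w[syn$sign > 0, ])
  wi <- Matrix::colSums(syn$w[syn$sign < 0, ])
  expect_true(all(abs(we[we > 0] - 40) < 1e-9))
  expect_true(all(abs(wi[wi > 0] - 36) < 1e-9))
})

test_that("weight noise model is unbiased and exact at sigma zero", {
  nz <- weight_noise(0, 0)
  w <- c(1, 2, 3)
  expect_identical(noisy_read(w, nz), w)
  expect_identical(noisy_write(w, nz), w)
  expect_error(weight_noise(-0.1, 0), "non-negative")

  nz <- weight_noise(sigma_read = 0.1, sigma_write = 0, w_scale = 1)
  set.seed(11)
  reads <- replicate(10000, noisy_read(1, nz))
  se <- 0.1 / sqrt(10000)
  expect_lt(abs(mean(reads) - 1), 3 * se)
})
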