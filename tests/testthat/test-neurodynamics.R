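test_that("forward-Euler membrane update matches hand-computed values", {
  p <- lif_params()
  st <- neuron_state(3, v_init = c(0, 10, 16.4))
  st <- lif_step(st, c(0, 20, 30), p)
  # equilibrium at rest; sub-threshold Euler step; threshold crossing
  expect_equal(st$v[1], 0)
  expect_equal(st$v[2], 10 + (-10 + 20) / 28, tolerance = 1e-12)
  expect_identical(st$spiked, c(0L, 0L, 1L))
  expect_equal(st$v[3], 0)                       # reset to rest
  expect_equal(st$refractory_remaining[3], 4)

  # refractory: no spike possible for the next 4 steps under huge drive
  for (i in 1:4) {
    st <- lif_step(st, rep(1000, 3), p)
    expect_identical(st$spiked[3], 0L)
    expect_equal(st$v[3], 0)
  }
  st <- lif_step(st, rep(1000, 3), p)
  expect_identical(st$spiked[3], 1L)
})

test_that("sub-threshold potential converges to the constant drive", {
  p <- lif_params()
  st <- neuron_state(1)
  for (i in 1:600) st <- lif_step(st, 12, p)
  expect_equal(st$v, 12, tolerance = 1e-6)
  expect_identical(st$spiked, 0L)
})

test_that("lif_step rejects bad inputs", {
  st <- neuron_state(2)
  expect_error(lif_step(st, c(NA, 1), lif_params()), "finite")
  st$refractory_remaining <- numeric(3)
  expect_error(lif_step(st, c(1, 1), lif_params()), "population size")
})

test_that("square-pulse drive follows the 3 ms bookkeeping", {
  syn <- synapse_set(Matrix::sparseMatrix(i = 1, j = 1, x = 3,
                                          dims = c(1, 2)),
                     sign = 1, tag = "recurrent")
  hist0 <- matrix(0, 3, 1)
  expect_equal(psc_drive(hist0, syn, stp_s = 1), c(0, 0))

  # one spike 1 ms ago: +3 for this and the next 2 steps, then 0
  h <- rbind(1, 0, 0)
  expect_equal(psc_drive(h, syn, stp_s = 1), c(3, 0))
  h <- rbind(0, 1, 0)
  expect_equal(psc_drive(h, syn, stp_s = 1), c(3, 0))
  h <- rbind(0, 0, 1)
  expect_equal(psc_drive(h, syn, stp_s = 1), c(3, 0))
  h <- matrix(0, 3, 1) # pulse expired
  expect_equal(psc_drive(h, syn, stp_s = 1), c(0, 0))

  # two spikes 1 ms apart superpose linearly during the overlap
  h <- rbind(1, 1, 0)
  expect_equal(psc_drive(h, syn, stp_s = 1), c(6, 0))

  # inhibitory presynaptic neuron flips the sign; efficacy scales
  syn_i <- synapse_set(Matrix::sparseMatrix(i = 1, j = 1, x = 3,
                                            dims = c(1, 2)),
                       sign = -1, tag = "recurrent")
  expect_equal(psc_drive(rbind(1, 0, 0), syn_i, stp_s = 0.5), c(-1.5, 0))
  expect_error(psc_drive(rbind(1, 0, 0), syn, stp_s = 1, pulse_ms = -1),
               "non-negative")
})

test_that("short-term plasticity follows the linear rule with clamping", {
  p <- stp_params(alpha = 0.007, beta = 0.739)
  expect_equal(stp_update(1, 1, p), 1 - 0.007 * 0.261, tolerance = 1e-12)
  expect_equal(stp_update(0.5, 0, p), 0.5 + 0.007 * 0.739, tolerance = 1e-12)
  expect_equal(stp_update(1, 0, p), 1)   # upper clamp

  # efficacy bounded in [0, 1] under arbitrary spike streams
  set.seed(7)
  for (rep in 1:20) {
    s <- runif(1)
    x <- rbinom(500, 1, runif(1))
    for (t in seq_along(x)) {
      s <- stp_update(s, x[t], p)
      expect_true(s >= 0 && s <= 1)
    }
  }
})

test_that("synaptic trace decays exactly exponentially and counts spikes", {
  p <- trace_params(tau_trace = 300)
  expect_equal(trace_update(0, 0, p), 0)
  expect_equal(trace_update(1, 0, p), exp(-1 / 300), tolerance = 1e-15)
  tr <- trace_update(0, 1, p)
  expect_equal(tr, 1)
  for (i in 1:300) tr <- trace_update(tr, 0, p)
  expect_equal(tr, exp(-1), tolerance = 1e-12)

  # closed-form agreement from an arbitrary start
  tr <- 3.7
  for (i in 1:123) tr <- trace_update(tr, 0, p)
  expect_equal(tr, 3.7 * exp(-123 / 300), tolerance = 1e-12)
})

test_that("no neuron spikes within the refractory period on a raster", {
  p <- lif_params()
  st <- neuron_state(20)
  set.seed(3)
  raster <- matrix(0L, 400, 20)
  for (t in 1:400) {
    st <- lif_step(st, runif(20, 0, 60), p)
    raster[t, ] <- st$spiked
  }
  expect_gt(sum(raster), 0)
  for (j in 1:20) {
    isi <- diff(which(raster[, j] == 1))
    if (length(isi) > 0) expect_true(all(isi > 4))
  }
})
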