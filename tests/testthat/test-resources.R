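bench <- arch_preset("benchmark")

test_that("forward-pass multiplication counts match the closed forms", {
  expect_equal(as.numeric(count_fp_mults(bench$specs$lsm)), 135000)
  expect_equal(as.numeric(count_fp_mults(bench$specs$lstm)), 9619500)
  empty <- arch_spec("lsm", h = 0)
  expect_equal(as.numeric(count_fp_mults(empty)), 0)
})

test_that("backward-pass multiplication counts match the closed forms", {
  expect_equal(as.numeric(count_bp_mults(bench$specs$`deep-lsm`)), 15000)
  expect_equal(as.numeric(count_bp_mults(bench$specs$lsm)), 15000)
  expect_equal(as.numeric(count_bp_mults(bench$specs$lstm)), 9675000)
  expect_equal(as.numeric(count_bp_mults(arch_spec("lsm", o = 0))), 0)
})

test_that("synapse breakdowns by learning rule are correct", {
  lstm <- count_synapses(bench$specs$lstm)
  expect_equal(lstm$total, 9615000)
  expect_equal(lstm$backprop, 9615000)
  expect_equal(lstm$random, 0)

  deep <- count_synapses(bench$specs$`deep-lsm`)
  expect_equal(deep$backprop, 15000)            # l * h_d * o
  expect_equal(deep$unsupervised_full, 50000)   # fully connected projections
  expect_equal(deep$unsupervised, 2500)         # density-discounted count

  deep_a <- count_synapses(bench$specs$`deep-lsm+attention`)
  expect_equal(deep_a$backprop, 759500)

  lsm_a <- count_synapses(bench$specs$`lsm+attention`)
  expect_equal(lsm_a$backprop, 2265000)
})

test_that("memory in gigabits matches the 32-bit accounting", {
  expect_equal(round(memory_gigabits(9615000), 4), 0.3077)
  expect_equal(round(memory_gigabits(139016), 4), 0.0044)
  expect_equal(memory_gigabits(0), 0)
})

test_that("energy estimates reproduce the self-consistent benchmark cells", {
  cc <- cost_constants()
  lsm <- energy_estimate(135000, 15000, 139016, cc)
  expect_equal(round(lsm$inference_uJ, 4), 0.621)
  expect_equal(round(lsm$training_uJ, 4), 0.069)
  expect_equal(round(lsm$weights_uJ, 4), 50.0458)
  expect_equal(round(lsm$total_uJ, 4), 50.7358)

  deep <- energy_estimate(110700, 15000, 108238, cc)
  expect_equal(round(deep$inference_uJ, 4), 0.5092)
  expect_equal(round(deep$weights_uJ, 4), 38.9657)
  expect_equal(round(deep$total_uJ, 4), 39.5439)

  zero <- energy_estimate(0, 0, 0, cc)
  expect_equal(zero$total_uJ, 0)
})

test_that("adding attention never decreases any count", {
  for (kind in c("deep-lsm", "lsm")) {
    plain <- arch_spec(kind)
    att <- arch_spec(kind, attention = TRUE)
    expect_gte(as.numeric(count_fp_mults(att)),
               as.numeric(count_fp_mults(plain)))
    expect_gte(as.numeric(count_bp_mults(att)),
               as.numeric(count_bp_mults(plain)))
    expect_gte(count_synapses(att)$total, count_synapses(plain)$total)
  }
})

test_that("instantiated counts agree with expectations and enumeration", {
  toy <- arch_spec("deep-lsm", n = 10, h_d = 50, w = 5, l = 2, o = 2,
                   s_in = 0.2, s_r = 0.1)
  exp_rand <- count_synapses(toy)$random

  # instantiated mode equals direct enumeration of the same sampled sets
  inst <- count_synapses(toy, mode = "instantiate", seed = 7)
  grid <- list(n = 50)
  manual <- n_synapses(connect_input(10, grid, 0.2,
                                     seed = derive_seed(7, "deep-in"))) +
    n_synapses(connect_input(5, grid, 0.2, seed = derive_seed(7, "deep-int-1"))) +
    n_synapses(connect_input(50, grid, 0.1, seed = derive_seed(7, "deep-rec-1"))) +
    n_synapses(connect_input(50, grid, 0.1, seed = derive_seed(7, "deep-rec-2")))
  expect_equal(inst$random, manual)

  # the Monte-Carlo mean sits within 3 SE of the closed-form expectation
  draws <- vapply(1:400, function(s)
    count_synapses(toy, mode = "instantiate", seed = s)$random, numeric(1))
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - exp_rand), 3 * se)
})

test_that("the benchmark resource table carries both conventions", {
  tab <- resource_table()
  expect_equal(nrow(tab), 5)
  lsm_row <- tab[tab$model == "lsm", ]
  expect_equal(lsm_row$fp_mults, 135000)
  expect_equal(lsm_row$inference_uJ, 0.621)
  expect_equal(lsm_row$memory_gb_ref, 0.0044)
  lstm_row <- tab[tab$model == "lstm", ]
  expect_equal(lstm_row$total_synapses, 9615000)
  expect_equal(lstm_row$memory_gb, 0.3077)
  deep_row <- tab[tab$model == "deep-lsm", ]
  expect_equal(deep_row$bp_mults, 15000)
  expect_equal(deep_row$weights_uJ, 38.9657)  # from the reference total
})
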