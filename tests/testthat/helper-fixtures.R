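# Small shared fixtures, built in code.

# A 20-neuron grid (4 x 5 x 1): 16 E, 4 I.
tiny_grid <- function(seed = 1L) build_grid(grid_spec(c(4, 5, 1), seed = seed))

# A compact 2-layer network for fast end-to-end tests.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_inputs = 10, n_layers = 2, hidden_size = 50, wta_size = 8,
         conn = connectivity_params(input_sparsity = 0.3), seed = 42L),
    list(...))
  do.call(deep_lsm_config, args)
}

# Feature task small enough for unit tests (short sequences, low dim).
tiny_task <- function(seed = 1L, ...) {
  synth_task_spec(n_classes = 2, n_dims = 10, len_min = 10, len_max = 40,
                  len_mean = 20, n_train = 8, n_test = 4, seed = seed, ...)
}

# Hand-sized attention fixture: L = 2, N = 3, O = 2, fixed printed weights.
fixture_attention <- function() {
  p <- attention_params(n_layers = 2, n_hidden = 3, n_classes = 2, seed = 1)
  p$w_deep <- matrix(c(0.1, -0.2, 0.3, 0.0, 0.2, -0.1,
                       -0.3, 0.1, 0.0, 0.2, -0.2, 0.1),
                     nrow = 2, byrow = TRUE)
  p$w_spatial <- matrix(c(0.2, 0.1, -0.1, 0.0, 0.3, -0.2,
                          -0.1, 0.2, 0.1, 0.3, 0.0, 0.1,
                          0.0, -0.3, 0.2, 0.1, 0.2, 0.0),
                        nrow = 3, byrow = TRUE)
  p$w_out <- matrix(c(0.5, -0.4, 0.2,
                      -0.1, 0.3, 0.6),
                    nrow = 2, byrow = TRUE)
  p
}

fixture_xdeep <- c(1.0, 0.5, 0.0, 0.2, 0.8, 1.5)
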