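#' Deep-LSM configuration
#'
#' Collects every architectural and dynamical parameter of a deep liquid
#' state machine: a stack of `n_layers` spiking reservoirs joined by
#' `n_layers - 1` winner-take-all (WTA) encoding layers, with the input
#' projected sparsely into the first reservoir.
#'
#' Amplitude scales: synaptic strengths are dimensionless; `kappa` converts
#' summed weighted spike pulses to membrane drive in mV, `input_gain` plays
#' the same role for the input projection, and `wta_in_weight` is the weight
#' of the sparse WTA-to-reservoir connections (a WTA layer emits at most one
#' spike per ms, so these carry more weight than reservoir synapses to keep
#' deeper reservoirs driven).
#'
#' @param n_inputs input dimensionality (default 100).
#' @param n_layers number of reservoirs `L` (>= 1); the network has `L - 1`
#'   WTA layers.
#' @param hidden_size neurons per reservoir (scalar or length-`L` vector;
#'   each must be divisible by 5 for the exact 4:1 E:I split).
#' @param wta_size WTA layer width.
#' @param lif,stp,trace,conn,stdp nested parameter objects ([lif_params()],
#'   [stp_params()], [trace_params()], [connectivity_params()],
#'   [stdp_params()]).
#' @param kappa current-to-potential scale for recurrent synapses (mV per
#'   unit weight).
#' @param input_gain drive scale of the input projection (mV per unit
#'   normalized feature).
#' @param wta_gain input gain of WTA layers (see [wta_layer()]).
#' @param wta_in_weight weight of WTA-to-reservoir connections.
#' @param inter_sparsity connection probability of the WTA-to-reservoir
#'   projections. Denser than the input projection by default: a WTA layer
#'   emits at most one spike per millisecond, so at the input projection's
#'   95% sparsity its code cannot keep a downstream reservoir active.
#' @param wta_scale_target synaptic-scaling sum for WTA incoming weights.
#' @param wta_theta_inc,wta_tau_theta intrinsic-plasticity increment (mV)
#'   and decay (ms) in WTA layers.
#' @param input_encoding `"current"` (normalized feature value delivered as
#'   constant drive, deterministic) or `"poisson"` (spikes at rate
#'   proportional to the normalized value).
#' @param poisson_max_rate peak Poisson rate in Hz.
#' @param frame_duration_ms timesteps each input frame is presented.
#' @param pulse_ms post-synaptic square-pulse duration (ms).
#' @param seed master seed; all construction randomness derives from it.
#' @return an object of class `deep_lsm_config`.
#' @export
deep_lsm_config <- function(n_inputs = 100, n_layers = 3, hidden_size = 500,
                            wta_size = 50,
                            lif = lif_params(), stp = stp_params(),
                            trace = trace_params(), conn = connectivity_params(),
                            stdp = stdp_params(),
                            kappa = 2, input_gain = 25, wta_gain = 60,
                            wta_in_weight = 100, inter_sparsity = 0.4,
                            wta_scale_target = 15,
                            wta_theta_inc = 1.5, wta_tau_theta = 500,
                            input_encoding = c("current", "poisson"),
                            poisson_max_rate = 200, frame_duration_ms = 1,
                            pulse_ms = 3, seed = 1L) {
  input_encoding <- match.arg(input_encoding)
  stopifnot(n_layers >= 1, n_inputs >= 1, wta_size >= 1,
            frame_duration_ms >= 1, pulse_ms >= 1, kappa > 0)
  hidden_size <- rep_len(as.integer(hidden_size), n_layers)
  structure(list(
    n_inputs = as.integer(n_inputs), n_layers = as.integer(n_layers),
    hidden_size = hidden_size, wta_size = as.integer(wta_size),
    lif = lif, stp = stp, trace = trace, conn = conn, stdp = stdp,
    kappa = kappa, input_gain = input_gain, wta_gain = wta_gain,
    wta_in_weight = wta_in_weight, inter_sparsity = inter_sparsity,
    wta_scale_target = wta_scale_target,
    wta_theta_inc = wta_theta_inc, wta_tau_theta = wta_tau_theta,
    input_encoding = input_encoding, poisson_max_rate = poisson_max_rate,
    frame_duration_ms = as.integer(frame_duration_ms),
    pulse_ms = as.integer(pulse_ms), seed = as.integer(seed)
  ), class = "deep_lsm_config")
}

#' Named deep-LSM architecture presets
#'
#' `"benchmark"`: 3 reservoirs of 500 neurons with 50-neuron WTA layers (the
#' configuration of the published resource comparison). `"reference"`: the
#' published single-table parameter set with 1000-neuron reservoirs.
#'
#' @param name `"benchmark"` or `"reference"`.
#' @param ... overrides passed on to [deep_lsm_config()].
#' @return a `deep_lsm_config`.
#' @export
deep_lsm_preset <- function(name = c("benchmark", "reference"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    benchmark = list(n_layers = 3, hidden_size = 500, wta_size = 50),
    reference = list(n_layers = 3, hidden_size = 1000, wta_size = 50)
  )
  do.call(deep_lsm_config, utils::modifyList(args, list(...)))
}

#' Construct a deep-LSM network
#'
#' Builds every reservoir (3-D grid, E/I labels, distance-dependent
#' normalized recurrent connectivity), the sparse input projection, the
#' sparse WTA-to-reservoir projections, and untrained WTA layers. The whole
#' topology is a pure function of the configuration (including its seed).
#'
#' @param config a [deep_lsm_config()].
#' @return an object of class `deep_lsm`.
#' @export
deep_lsm <- function(config) {
  stopifnot(inherits(config, "deep_lsm_config"))
  L <- config$n_layers
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    spec <- grid_spec(cubic_dims(config$hidden_size[l]),
                      seed = derive_seed(config$seed, sprintf("grid-%d", l)))
    grid <- build_grid(spec)
    rec <- connect_recurrent(grid, config$conn,
                             seed = derive_seed(config$seed,
                                                sprintf("rec-%d", l)))
    rec <- normalize_synapses(rec, config$conn$norm_targets)
    proj <- if (l == 1) {
      connect_input(config$n_inputs, grid, config$conn$input_sparsity,
                    seed = derive_seed(config$seed, "input"),
                    tag = "input", weight = 1)
    } else {
      connect_input(config$wta_size, grid, config$inter_sparsity,
                    seed = derive_seed(config$seed,
                                       sprintf("inter-%d", l)),
                    tag = "inter-layer", weight = config$wta_in_weight)
    }
    layers[[l]] <- list(grid = grid, rec = rec, proj = proj,
                        n = grid$n)
  }
  wta <- vector("list", max(L - 1, 0))
  for (k in seq_len(max(L - 1, 0))) {
    wta[[k]] <- wta_layer(
      n_pre = layers[[k]]$n, n_neurons = config$wta_size,
      lif = config$lif, stdp = config$stdp,
      scale_target = config$wta_scale_target, gain = config$wta_gain,
      theta_inc = config$wta_theta_inc, tau_theta = config$wta_tau_theta,
      seed = derive_seed(config$seed, sprintf("wta-%d", k)))
  }
  net <- structure(list(config = config, layers = layers, wta = wta,
                        encoder = NULL, state = NULL),
                   class = "deep_lsm")
  reset_state(net)
}

#' Reset the dynamical state of a deep-LSM
#'
#' Zeroes membrane potentials, refractory clocks, traces and pulse buffers,
#' and sets all short-term efficacies to 1. Learned WTA weights are kept;
#' WTA membrane state and intrinsic thresholds are reset.
#'
#' @param net a [deep_lsm()].
#' @return the network with fresh state.
#' @export
reset_state <- function(net) {
  cfg <- net$config
  L <- cfg$n_layers
  st <- list(
    layers = lapply(seq_len(L), function(l) {
      list(ns = neuron_state(net$layers[[l]]$n),
           hist = matrix(0, cfg$pulse_ms, net$layers[[l]]$n))
    }),
    inter_hist = lapply(seq_len(max(L - 1, 0)), function(k) {
      matrix(0, cfg$pulse_ms, cfg$wta_size)
    }),
    input_hist = matrix(0, cfg$pulse_ms, cfg$n_inputs)
  )
  for (k in seq_along(net$wta)) {
    net$wta[[k]]$state <- neuron_state(cfg$wta_size)
    net$wta[[k]]$intrinsic$theta <- numeric(cfg$wta_size)
  }
  net$state <- st
  net
}

#' Fit the input normalizer on training sequences
#'
#' Per-dimension min-max normalization; fitted bounds are stored in the
#' network and applied by the encoder before drive/rate conversion.
#'
#' @param net a [deep_lsm()].
#' @param sequences list of feature matrices (frames x n_inputs).
#' @return the network with a fitted encoder.
#' @export
fit_encoder <- function(net, sequences) {
  stopifnot(length(sequences) >= 1)
  all_min <- Reduce(pmin, lapply(sequences, function(s) apply(s, 2, min)))
  all_max <- Reduce(pmax, lapply(sequences, function(s) apply(s, 2, max)))
  rng <- all_max - all_min
  rng[rng == 0] <- 1
  net$encoder <- list(min = all_min, range = rng)
  net
}

#' Encode one feature frame as input-layer activity
#'
#' `"current"` mode returns the (deterministic) constant drive vector for
#' the first reservoir; `"poisson"` mode returns a binary input spike
#' vector drawn at per-channel rate proportional to the normalized feature
#' value (peak `poisson_max_rate` Hz), using the current RNG stream.
#'
#' @param net a fitted [deep_lsm()].
#' @param feature_frame numeric vector of length `n_inputs`.
#' @return for `"current"`, a drive vector over the first reservoir (mV);
#'   for `"poisson"`, a binary vector over input channels.
#' @export
encode_input <- function(net, feature_frame) {
  if (is.null(net$encoder)) {
    stop("input encoder not fitted; call fit_encoder() first", call. = FALSE)
  }
  stopifnot_finite(feature_frame, "feature_frame")
  u <- clamp((feature_frame - net$encoder$min) / net$encoder$range, 0, 1)
  if (net$config$input_encoding == "current") {
    net$config$input_gain *
      as.numeric(Matrix::crossprod(net$layers[[1]]$proj$w, u))
  } else {
    p <- u * net$config$poisson_max_rate * net$config$lif$dt / 1000
    as.integer(runif(length(u)) < p)
  }
}

# One network timestep. `ext` is the encoded input: a drive vector over the
# first reservoir ("current") or an input spike vector ("poisson"). Layers
# are updated in order; each WTA layer sees its reservoir's current spikes
# and its spike reaches the next reservoir in the same step (then persists
# for the pulse duration).
deep_lsm_step <- function(net, ext, upto_layer = NULL, noise = NULL) {
  cfg <- net$config
  L <- upto_layer %||% cfg$n_layers
  st <- net$state
  read_w <- function(w) if (is.null(noise)) w else noisy_read(w, noise)
  for (l in seq_len(L)) {
    lay <- net$layers[[l]]
    ls <- st$layers[[l]]
    drive <- cfg$kappa * as.numeric(
      Matrix::crossprod(read_w(lay$rec$w), colSums(ls$hist) * lay$rec$sign))
    if (l == 1) {
      if (cfg$input_encoding == "current") {
        drive <- drive + ext
      } else {
        st$input_hist <- rbind(ext, st$input_hist[-cfg$pulse_ms, , drop = FALSE])
        drive <- drive + cfg$input_gain * as.numeric(
          Matrix::crossprod(read_w(lay$proj$w), colSums(st$input_hist)))
      }
    } else {
      drive <- drive + cfg$kappa * as.numeric(
        Matrix::crossprod(read_w(lay$proj$w), colSums(st$inter_hist[[l - 1]])))
    }
    ns <- lif_step(ls$ns, drive, cfg$lif)
    ns$stp_s <- stp_update(ns$stp_s, ns$spiked, cfg$stp)
    ns$trace <- trace_update(ns$trace, ns$spiked, cfg$trace)
    ls$ns <- ns
    ls$hist <- rbind(ns$spiked * ns$stp_s,
                     ls$hist[-cfg$pulse_ms, , drop = FALSE])
    st$layers[[l]] <- ls
    if (l <= length(net$wta) && l <= L) {
      res <- wta_step(net$wta[[l]], ns$spiked, pre_traces = ns$trace,
                      noise = noise)
      net$wta[[l]] <- res$layer
      wspike <- integer(cfg$wta_size)
      if (!is.na(res$winner)) wspike[res$winner] <- 1L
      st$inter_hist[[l]] <- rbind(wspike,
                                  st$inter_hist[[l]][-cfg$pulse_ms, ,
                                                     drop = FALSE])
    }
  }
  net$state <- st
  net
}

#' Run a feature sequence through the deep-LSM
#'
#' Presents each frame for `frame_duration_ms` timesteps and returns the
#' final concatenated trace snapshot `X_deep = [X_1, ..., X_L]` used by the
#' attention readout. With `reset = TRUE` (default) membrane potentials,
#' traces and pulse buffers are zeroed and short-term efficacies set to 1
#' before the sequence, treating sequences as independent samples.
#'
#' @param net a fitted [deep_lsm()].
#' @param features frames x n_inputs numeric matrix.
#' @param reset reset dynamical state before the sequence.
#' @param record `"none"`, `"spikes"` or `"traces"`: optionally record
#'   per-timestep rasters for every reservoir (and WTA winners for
#'   `"spikes"`).
#' @param upto_layer simulate only reservoirs `1..upto_layer` (used during
#'   greedy layer-wise WTA training).
#' @param noise optional [weight_noise()] applied to every weight read (and
#'   write, during training).
#' @param seed RNG seed for Poisson input encoding; ignored in `"current"`
#'   mode.
#' @return a list with `net` (updated state and any trained WTA weights),
#'   `x_deep` (concatenated traces over simulated layers), and `records`
#'   (list of per-layer rasters, or `NULL`).
#' @export
run_sequence <- function(net, features, reset = TRUE, record = "none",
                         upto_layer = NULL, noise = NULL, seed = NULL) {
  features <- as.matrix(features)
  if (nrow(features) == 0) stop("empty sequence", call. = FALSE)
  if (ncol(features) != net$config$n_inputs) {
    stop("feature dimensionality does not match n_inputs", call. = FALSE)
  }
  if (reset) net <- reset_state(net)
  cfg <- net$config
  L <- upto_layer %||% cfg$n_layers
  n_steps <- nrow(features) * cfg$frame_duration_ms
  recs <- NULL
  if (record != "none") {
    recs <- lapply(seq_len(L), function(l)
      matrix(0, n_steps, net$layers[[l]]$n))
    if (record == "spikes") {
      recs$wta <- lapply(seq_len(min(L, cfg$n_layers - 1)), function(k)
        matrix(0L, n_steps, cfg$wta_size))
    }
  }
  runner <- function() {
    step_i <- 0
    for (f in seq_len(nrow(features))) {
      ext <- if (cfg$input_encoding == "current") {
        encode_input(net, features[f, ])
      } else NULL
      for (r in seq_len(cfg$frame_duration_ms)) {
        if (cfg$input_encoding == "poisson") {
          ext <- encode_input(net, features[f, ])
        }
        net <<- deep_lsm_step(net, ext, upto_layer = L, noise = noise)
        step_i <- step_i + 1
        if (!is.null(recs)) {
          for (l in seq_len(L)) {
            recs[[l]][step_i, ] <<- if (record == "spikes") {
              net$state$layers[[l]]$ns$spiked
            } else {
              net$state$layers[[l]]$ns$trace
            }
          }
          if (record == "spikes") {
            for (k in seq_along(recs$wta)) {
              recs$wta[[k]][step_i, ] <<- net$state$inter_hist[[k]][1, ]
            }
          }
        }
      }
    }
  }
  if (cfg$input_encoding == "poisson" && !is.null(seed)) {
    with_seed(seed, runner())
  } else {
    runner()
  }
  x_deep <- unlist(lapply(seq_len(L), function(l)
    net$state$layers[[l]]$ns$trace))
  list(net = net, x_deep = x_deep, records = recs)
}

#' Train the WTA layers greedily, layer by layer
#'
#' Runs the training sequences with WTA layer `k` in training mode (STDP +
#' synaptic scaling + intrinsic plasticity on each win) while earlier WTA
#' layers are frozen, for `epochs_per_layer` passes, then moves to layer
#' `k + 1`. Reservoir weights never change. Only reservoirs `1..k` are
#' simulated while training layer `k`.
#'
#' @param net a fitted [deep_lsm()].
#' @param sequences list of training feature matrices.
#' @param epochs_per_layer passes over the data per WTA layer.
#' @param noise optional [weight_noise()].
#' @return the network with trained WTA layers (training flags off).
#' @export
train_wta_layers <- function(net, sequences, epochs_per_layer = 1,
                             noise = NULL) {
  for (k in seq_along(net$wta)) {
    if (epochs_per_layer < 1) break
    net$wta[[k]]$training <- TRUE
    for (e in seq_len(epochs_per_layer)) {
      for (i in seq_along(sequences)) {
        out <- run_sequence(net, sequences[[i]], reset = TRUE,
                            upto_layer = k, noise = noise,
                            seed = derive_seed(net$config$seed,
                                               sprintf("wta-train-%d-%d-%d",
                                                       k, e, i)))
        net <- out$net
      }
    }
    net$wta[[k]]$training <- FALSE
  }
  net
}

#' Collect readout snapshots for a set of sequences
#'
#' @param net a fitted, (WTA-)trained [deep_lsm()].
#' @param sequences list of feature matrices.
#' @param noise optional [weight_noise()].
#' @return a matrix, one row per sequence, columns = concatenated traces
#'   `X_deep`.
#' @export
collect_snapshots <- function(net, sequences, noise = NULL) {
  t(vapply(seq_along(sequences), function(i) {
    run_sequence(net, sequences[[i]], reset = TRUE, noise = noise,
                 seed = derive_seed(net$config$seed,
                                    sprintf("snap-%d", i)))$x_deep
  }, numeric(sum(net$config$hidden_size))))
}

#' Per-layer mean firing rates of the last recorded run
#'
#' @param records `records` element returned by [run_sequence()] with
#'   `record = "spikes"`.
#' @return mean spikes per neuron per timestep, one value per reservoir.
#' @export
layer_rates <- function(records) {
  idx <- which(vapply(records, is.matrix, logical(1)))
  vapply(records[idx], mean, numeric(1))
}
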