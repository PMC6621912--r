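#' Spiking winner-take-all encoding layer
#'
#' A competitive layer of LIF neurons fully connected to a presynaptic
#' reservoir. At most one neuron spikes per timestep: when one or more
#' neurons reach their (intrinsic-plasticity-modulated) threshold, the one
#' with the highest membrane potential wins, emits the sole spike, and all
#' other membrane potentials are reset to rest (global inhibition). Ties go
#' to the lowest index. With training on, the winner's incoming weights are
#' updated by trace-based STDP, renormalized by synaptic scaling, and the
#' winner's threshold is raised by intrinsic plasticity.
#'
#' Incoming weights are initialized uniformly in (0, 1) and scaled so each
#' neuron's incoming sum equals `scale_target`.
#'
#' @param n_pre presynaptic (reservoir) population size.
#' @param n_neurons layer width (reference sizes 50-150).
#' @param lif a [lif_params()].
#' @param stdp an [stdp_params()].
#' @param scale_target incoming-sum target for synaptic scaling (default 15).
#' @param gain input gain converting summed weighted spikes to drive in mV.
#'   The incoming sum is held at `scale_target` by scaling, so with a
#'   fraction f of presynaptic neurons spiking the expected drive is
#'   `gain * scale_target * f`; the default puts typical reservoir activity
#'   (f around 0.05-0.15) in range of the 16.5 mV threshold.
#' @param theta_inc,tau_theta intrinsic-plasticity increment (mV) and decay
#'   constant (ms).
#' @param seed integer seed for weight initialization.
#' @return an object of class `wta_layer`.
#' @export
wta_layer <- function(n_pre, n_neurons, lif = lif_params(),
                      stdp = stdp_params(), scale_target = 15,
                      gain = 20, theta_inc = 1.5, tau_theta = 500,
                      seed = 1L) {
  stopifnot(n_pre >= 1, n_neurons >= 1)
  w <- with_seed(derive_seed(seed, "wta-init"),
                 matrix(runif(n_pre * n_neurons), n_pre, n_neurons))
  w <- apply(w, 2, synaptic_scale, target_sum = scale_target)
  structure(list(
    n_pre = n_pre, n_neurons = n_neurons,
    weights = w,
    lif = lif, stdp = stdp,
    scale_target = scale_target, gain = gain,
    state = neuron_state(n_neurons),
    intrinsic = intrinsic_state(n_neurons, v_th_base = lif$v_th,
                                theta_inc = theta_inc,
                                tau_theta = tau_theta, dt = lif$dt),
    training = FALSE
  ), class = "wta_layer")
}

#' One winner-take-all timestep
#'
#' Integrates the layer one step under drive `gain * W' x` where `x` is the
#' current presynaptic spike vector, applies the global-inhibition
#' competition, and (if `layer$training`) runs the STDP + synaptic scaling +
#' intrinsic plasticity update for the winner. Intrinsic thresholds decay
#' every step regardless of training.
#'
#' @param layer a [wta_layer()].
#' @param presyn_spikes binary spike vector of the presynaptic reservoir.
#' @param pre_traces presynaptic synaptic traces (required when training).
#' @param noise optional [weight_noise()] applied to weight reads/writes.
#' @return a list `(layer, winner)`; `winner` is the spiking neuron's index
#'   or `NA_integer_` if none fired.
#' @export
wta_step <- function(layer, presyn_spikes, pre_traces = NULL, noise = NULL) {
  if (length(presyn_spikes) != layer$n_pre) {
    stop("presynaptic spike vector does not match layer input size",
         call. = FALSE)
  }
  w <- layer$weights
  if (!is.null(noise)) w <- noisy_read(w, noise)
  drive <- layer$gain * as.numeric(crossprod(w, presyn_spikes))
  v_th_eff <- effective_threshold(layer$intrinsic)

  st <- layer$state
  n <- layer$n_neurons
  refract <- st$refractory_remaining > 0
  v <- st$v
  p <- layer$lif
  v[!refract] <- v[!refract] + (p$dt / p$tau_m) * (-v[!refract] + drive[!refract])
  v[refract] <- p$v_rest

  supra <- which(!refract & v >= v_th_eff)
  winner <- NA_integer_
  spiked <- integer(n)
  if (length(supra) > 0) {
    winner <- supra[which.max(v[supra])] # which.max -> lowest index on ties
    spiked[winner] <- 1L
    v[] <- p$v_rest # global inhibition: competitors reset with the winner
  }

  ref <- st$refractory_remaining
  ref[refract] <- pmax(ref[refract] - p$dt, 0)
  if (!is.na(winner)) ref[winner] <- p$tau_ref

  st$v <- v
  st$refractory_remaining <- ref
  st$spiked <- spiked
  layer$state <- st

  if (layer$training && !is.na(winner)) {
    if (is.null(pre_traces)) {
      stop("training requires presynaptic traces", call. = FALSE)
    }
    w_in <- layer$weights[, winner]
    if (!is.null(noise)) w_in <- noisy_read(w_in, noise)
    w_in <- stdp_update(w_in, pre_traces, layer$stdp)
    if (sum(w_in) <= 0) {
      # collapsed row: keep the previous weights and record the event
      layer$collapsed_events <- (layer$collapsed_events %||% 0) + 1
    } else {
      w_in <- synaptic_scale(w_in, layer$scale_target)
      if (!is.null(noise)) w_in <- noisy_write(w_in, noise)
      layer$weights[, winner] <- pmax(w_in, layer$stdp$w_min)
    }
  }
  layer$intrinsic <- intrinsic_update(layer$intrinsic, spiked)

  list(layer = layer, winner = winner)
}

#' Encode a reservoir spike raster through a trained WTA layer
#'
#' Inference-mode pass: resets the layer state, steps through the raster
#' rows, and returns the winner raster. Deterministic given weights and
#' inputs; every output row has at most one active unit.
#'
#' @param layer a [wta_layer()] (training flag ignored; run with training
#'   off).
#' @param reservoir_spike_raster timesteps x n_pre binary matrix.
#' @return timesteps x n_neurons binary matrix.
#' @export
encode_sequence <- function(layer, reservoir_spike_raster) {
  raster <- as.matrix(reservoir_spike_raster)
  stopifnot(ncol(raster) == layer$n_pre)
  layer$training <- FALSE
  layer$state <- neuron_state(layer$n_neurons)
  layer$intrinsic$theta <- numeric(layer$n_neurons)
  out <- matrix(0L, nrow(raster), layer$n_neurons)
  for (t in seq_len(nrow(raster))) {
    res <- wta_step(layer, raster[t, ])
    layer <- res$layer
    if (!is.na(res$winner)) out[t, res$winner] <- 1L
  }
  out
}
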