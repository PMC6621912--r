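#' Trace-based STDP parameters
#'
#' The unsupervised rule used to train winner-take-all encoding layers: when
#' a postsynaptic neuron wins (fires), every incoming weight moves by
#' `eta * (X_pre_trace - x_tar)` — potentiation for presynaptic neurons whose
#' recent activity (synaptic trace) exceeds the target level `x_tar`,
#' depression otherwise. Weights are floored at `w_min`.
#'
#' @param eta learning rate (default 5e-4). The scale matters: after
#'   synaptic scaling to a sum of 15 over a 500-neuron reservoir the mean
#'   incoming weight is 0.03, so `eta * x_tar` (the largest possible
#'   depression step) must stay well below that or a single update wipes
#'   out a neuron's weight vector.
#' @param x_tar target presynaptic-trace level (default 25; reference range
#'   25-50 depending on layer width).
#' @param w_min weight floor (default 0).
#' @return an object of class `stdp_params`.
#' @export
stdp_params <- function(eta = 5e-4, x_tar = 25, w_min = 0) {
  stopifnot(eta > 0, x_tar > 0, w_min >= 0)
  structure(list(eta = eta, x_tar = x_tar, w_min = w_min),
            class = "stdp_params")
}

#' STDP update of the winner's incoming weights
#'
#' Applied only when a postsynaptic neuron fires; a call with `winner = NULL`
#' is a no-op.
#'
#' @param weights_into_winner numeric vector of the winner's incoming
#'   weights (length = presynaptic population).
#' @param pre_traces presynaptic synaptic traces (same length).
#' @param params an [stdp_params()].
#' @return updated weight vector, floored at `w_min`.
#' @export
stdp_update <- function(weights_into_winner, pre_traces, params) {
  if (is.null(weights_into_winner)) return(NULL)
  stopifnot(length(weights_into_winner) == length(pre_traces))
  pmax(weights_into_winner + params$eta * (pre_traces - params$x_tar),
       params$w_min)
}

#' Synaptic scaling to a fixed incoming sum
#'
#' Homeostatic renormalization: a neuron's incoming weights are rescaled so
#' their sum equals `target_sum` exactly, preserving relative proportions.
#' An all-zero weight vector signals a collapsed neuron and is rejected
#' rather than silently rescaled.
#'
#' @param weights_into_neuron non-negative incoming weight vector.
#' @param target_sum positive target for the post-scaling sum (default 15,
#'   the reference value for winner-take-all layers).
#' @return scaled weights summing to `target_sum`.
#' @export
synaptic_scale <- function(weights_into_neuron, target_sum = 15) {
  s <- sum(weights_into_neuron)
  if (s <= 0) {
    stop("all incoming weights are zero: collapsed neuron cannot be rescaled",
         call. = FALSE)
  }
  weights_into_neuron / s * target_sum
}

#' Intrinsic plasticity state
#'
#' Spike-triggered threshold homeostasis: each neuron's firing threshold is
#' `v_th_base + theta`, where the offset `theta` jumps by `theta_inc` every
#' time the neuron fires and decays exponentially toward zero with time
#' constant `tau_theta` otherwise. This suppresses neurons that win too
#' often and equalizes firing opportunities across a competitive layer.
#'
#' @param n number of neurons.
#' @param v_th_base resting threshold (mV, default 16.5).
#' @param theta_inc threshold increment per spike (mV, default 1.5).
#' @param tau_theta decay constant (ms, default 500).
#' @param dt timestep (ms).
#' @return an object of class `intrinsic_state`.
#' @export
intrinsic_state <- function(n, v_th_base = 16.5, theta_inc = 1.5,
                            tau_theta = 500, dt = 1) {
  stopifnot(theta_inc >= 0, tau_theta > 0)
  structure(list(theta = numeric(n), v_th_base = v_th_base,
                 theta_inc = theta_inc, tau_theta = tau_theta,
                 decay = exp(-dt / tau_theta)),
            class = "intrinsic_state")
}

#' One intrinsic-plasticity step
#'
#' Decays every offset by `exp(-dt/tau_theta)` and adds `theta_inc` to
#' neurons that spiked this step.
#'
#' @param state an [intrinsic_state()].
#' @param spiked per-neuron binary spike flags.
#' @return the updated state.
#' @export
intrinsic_update <- function(state, spiked) {
  state$theta <- state$theta * state$decay + state$theta_inc * spiked
  state
}

#' Effective thresholds under intrinsic plasticity
#'
#' @param state an [intrinsic_state()].
#' @return per-neuron effective threshold `v_th_base + theta` (mV).
#' @export
effective_threshold <- function(state) {
  state$v_th_base + state$theta
}
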