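#' Leaky integrate-and-fire parameters
#'
#' Parameter set for a population of leaky integrate-and-fire (LIF) neurons.
#' The membrane potential `V` leaks toward the resting potential and is driven
#' by the synaptic input `I * R` (expressed directly in mV); when `V` crosses
#' the threshold the neuron emits a spike, resets to rest and becomes
#' refractory.
#'
#' Defaults are the reference configuration of the simulator: threshold
#' 16.5 mV, membrane time constant 28 ms, refractory period 4 ms, resting
#' potential 0 mV, and a 1 ms simulation timestep.
#'
#' @param v_th spike threshold (mV).
#' @param tau_m membrane time constant (ms).
#' @param tau_ref absolute refractory period (ms).
#' @param v_rest resting potential (mV).
#' @param dt simulation timestep (ms).
#' @return an object of class `lif_params`.
#' @export
lif_params <- function(v_th = 16.5, tau_m = 28, tau_ref = 4, v_rest = 0, dt = 1) {
  stopifnot(v_th > v_rest, tau_m > 0, tau_ref >= 0, dt > 0)
  structure(list(v_th = v_th, tau_m = tau_m, tau_ref = tau_ref,
                 v_rest = v_rest, dt = dt),
            class = "lif_params")
}

#' Neuron population state
#'
#' Holds, per neuron: membrane potential `v` (mV), remaining refractory time
#' (ms), the binary spike flag of the last step, the short-term-plasticity
#' efficacy `stp_s` in \[0, 1\] and the synaptic trace (a leaky spike count).
#'
#' @param n number of neurons.
#' @param v_init initial membrane potential (mV), recycled.
#' @return an object of class `neuron_state`.
#' @export
neuron_state <- function(n, v_init = 0) {
  structure(list(
    v = rep_len(v_init, n),
    refractory_remaining = numeric(n),
    spiked = integer(n),
    stp_s = rep(1, n),
    trace = numeric(n)
  ), class = "neuron_state")
}

n_neurons <- function(state) length(state$v)

#' One forward-Euler LIF timestep
#'
#' Advances membrane potentials by one timestep of the leaky
#' integrate-and-fire dynamics `tau * dV/dt = -V + I*R` using forward Euler:
#' `V <- V + (dt/tau) * (-V + drive)` for non-refractory neurons. Neurons
#' reaching `v_th` spike, reset to `v_rest`, and enter a refractory period of
#' `tau_ref` ms during which the potential is clamped at rest and the
#' countdown decrements.
#'
#' @param state a [neuron_state()].
#' @param input_drive per-neuron drive `I*R` in mV (length `n` or scalar).
#' @param params a [lif_params()].
#' @param v_th_eff optional per-neuron effective threshold overriding
#'   `params$v_th` (used by winner-take-all layers whose thresholds move under
#'   intrinsic plasticity).
#' @return the updated `neuron_state` with `spiked` flags set.
#' @export
lif_step <- function(state, input_drive, params, v_th_eff = NULL) {
  n <- n_neurons(state)
  input_drive <- rep_len(input_drive, n)
  stopifnot_finite(input_drive, "input_drive")
  if (length(state$refractory_remaining) != n) {
    stop("mismatched population size in `state`", call. = FALSE)
  }
  v_th <- if (is.null(v_th_eff)) rep_len(params$v_th, n) else rep_len(v_th_eff, n)

  refract <- state$refractory_remaining > 0
  v <- state$v
  v[!refract] <- v[!refract] +
    (params$dt / params$tau_m) * (-v[!refract] + input_drive[!refract])
  v[refract] <- params$v_rest

  spiked <- as.integer(!refract & v >= v_th)
  v[spiked == 1L] <- params$v_rest

  ref <- state$refractory_remaining
  ref[refract] <- pmax(ref[refract] - params$dt, 0)
  ref[spiked == 1L] <- params$tau_ref

  state$v <- v
  state$refractory_remaining <- ref
  state$spiked <- spiked
  state
}

#' Short-term plasticity parameters
#'
#' The linearized short-term plasticity rule
#' `S(n) = S(n-1) - alpha * (x(n) - beta)` depresses the outgoing efficacy of
#' a neuron each time it spikes (`x = 1`) and recovers it while silent
#' (`x = 0`), with constant per-step increments; `S` is clamped to \[0, 1\].
#'
#' @param alpha efficacy step size (default 0.007).
#' @param beta spike-probability baseline (default 0.739).
#' @return an object of class `stp_params`.
#' @export
stp_params <- function(alpha = 0.007, beta = 0.739) {
  stopifnot(alpha >= 0, beta >= 0, beta <= 1)
  structure(list(alpha = alpha, beta = beta), class = "stp_params")
}

#' One short-term plasticity update
#'
#' @param stp_s per-neuron efficacies in \[0, 1\].
#' @param spiked per-neuron binary spike flags.
#' @param params an [stp_params()].
#' @return updated efficacies, clamped to \[0, 1\].
#' @export
stp_update <- function(stp_s, spiked, params) {
  clamp(stp_s - params$alpha * (spiked - params$beta), 0, 1)
}

#' Synaptic trace parameters
#'
#' @param tau_trace trace decay constant in ms (default 300).
#' @param dt timestep in ms.
#' @return an object of class `trace_params`.
#' @export
trace_params <- function(tau_trace = 300, dt = 1) {
  stopifnot(tau_trace > 0, dt > 0)
  structure(list(tau_trace = tau_trace, dt = dt,
                 decay = exp(-dt / tau_trace)),
            class = "trace_params")
}

#' One synaptic-trace update
#'
#' The trace is a leaky running count of a neuron's spikes: it decays
#' exponentially with time constant `tau_trace` and is incremented by one on
#' each spike. The decay is applied in exact closed form
#' (`X' = X * exp(-dt/tau) + x`), so a silent neuron's trace follows
#' `X(0) * exp(-t/tau)` with no integration error.
#'
#' @param trace per-neuron trace values (non-negative).
#' @param spiked per-neuron binary spike flags.
#' @param params a [trace_params()].
#' @return updated traces.
#' @export
trace_update <- function(trace, spiked, params) {
  trace * params$decay + spiked
}

#' Square-pulse post-synaptic drive
#'
#' Each presynaptic spike injects a square current pulse into its
#' postsynaptic targets for exactly `pulse_ms` timesteps after the spike,
#' with magnitude `weight * S_pre * kappa` (S_pre the presynaptic short-term
#' efficacy at spike time, `kappa` a global current-to-potential scale in
#' mV per unit weight). Inhibitory presynaptic neurons contribute with
#' negative sign. Overlapping pulses add linearly.
#'
#' @param spike_history a `pulse_ms x n_pre` binary matrix, one row per
#'   timestep, row 1 the most recent (1 ms ago). Fewer rows are allowed at
#'   the start of a run.
#' @param synapses a [synapse_set()] with `n_pre` presynaptic neurons.
#' @param stp_s presynaptic efficacies: either a vector of length `n_pre`
#'   applied to all rows, or a matrix matching `spike_history` holding the
#'   efficacy at each spike's emission time.
#' @param kappa global current-to-potential scale (mV per unit weight).
#' @param pulse_ms pulse duration in timesteps (default 3).
#' @return per-postsynaptic-neuron drive in mV.
#' @export
psc_drive <- function(spike_history, synapses, stp_s, kappa = 1, pulse_ms = 3) {
  if (pulse_ms < 0) stop("pulse duration must be non-negative", call. = FALSE)
  spike_history <- as.matrix(spike_history)
  n_pre <- ncol(spike_history)
  if (n_pre != nrow(synapses$w)) {
    stop("spike history width does not match presynaptic population",
         call. = FALSE)
  }
  keep <- seq_len(min(nrow(spike_history), pulse_ms))
  eff <- if (is.matrix(stp_s)) {
    spike_history[keep, , drop = FALSE] * stp_s[keep, , drop = FALSE]
  } else {
    spike_history[keep, , drop = FALSE] * rep(stp_s, each = length(keep))
  }
  active <- colSums(eff)
  drive <- as.numeric(Matrix::crossprod(synapses$w, active * synapses$sign))
  drive * kappa
}
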