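#' Default experiment configuration
#'
#' Nested list of every tunable parameter of the simulator with its
#' reference default: neuron dynamics (threshold 16.5 mV, membrane constant
#' 28 ms, refractory 4 ms, 1 ms timestep), architecture (layer count and
#' sizes, WTA width), connectivity (per-pair C and lambda, fixed strengths,
#' input sparsity, normalization targets 40/36), plasticity (STP alpha/beta
#' 0.007/0.739, trace constant 300 ms, STDP target trace 25, WTA scaling
#' target 15, intrinsic increment 1.5 mV with 500 ms decay), amplitude
#' scales, input encoding, and the master seed.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    simulation = list(timestep_ms = 1, frame_duration_ms = 1, pulse_ms = 3,
                      seed = 1L),
    neuron = list(v_th_mv = 16.5, tau_m_ms = 28, tau_ref_ms = 4,
                  v_rest_mv = 0),
    architecture = list(n_inputs = 100L, n_layers = 3L, hidden_size = 500L,
                        wta_size = 50L),
    connectivity = list(
      c_ee = 0.6, c_ei = 1, c_ie = 1, c_ii = 0.2,
      lambda_ee = 3, lambda_ei = 3, lambda_ie = 3, lambda_ii = 3,
      w_ee = 3, w_ei = 3, w_ie = 4, w_ii = 1,
      input_sparsity = 0.05, norm_target_e = 40, norm_target_i = 36),
    stp = list(alpha = 0.007, beta = 0.739),
    trace = list(tau_trace_ms = 300),
    stdp = list(eta = 0.01, x_tar = 25),
    wta = list(scale_target = 15, theta_inc_mv = 1.5, tau_theta_ms = 500,
               gain = 60),
    amplitudes = list(kappa = 2, input_gain = 25, wta_in_weight = 100,
                      inter_sparsity = 0.4),
    input = list(encoding = "current", poisson_max_rate_hz = 200),
    readout = list(lr = 0.1, epochs = 200),
    noise = list(sigma_read = 0, sigma_write = 0)
  )
}

check_range <- function(cfg, path, lo = -Inf, hi = Inf, strict_lo = FALSE) {
  v <- cfg
  for (k in path) v <- v[[k]]
  key <- paste(path, collapse = "$")
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
    stop(sprintf("config key `%s` must be a finite number", key),
         call. = FALSE)
  }
  if (v < lo || v > hi || (strict_lo && v <= lo)) {
    stop(sprintf("config key `%s` = %g out of range [%g, %g]",
                 key, v, lo, hi), call. = FALSE)
  }
  invisible(v)
}

validate_config <- function(cfg) {
  ref <- default_config()
  walk <- function(user, base, path = character()) {
    extra <- setdiff(names(user), names(base))
    if (length(extra) > 0) {
      stop(sprintf("unknown config key(s): %s",
                   paste(paste(c(path, extra[1]), collapse = "$"),
                         collapse = ", ")), call. = FALSE)
    }
    for (k in names(user)) {
      if (is.list(base[[k]])) {
        if (!is.list(user[[k]])) {
          stop(sprintf("config key `%s` must be a section",
                       paste(c(path, k), collapse = "$")), call. = FALSE)
        }
        walk(user[[k]], base[[k]], c(path, k))
      }
    }
  }
  walk(cfg, ref)
  merged <- utils::modifyList(ref, cfg)
  check_range(merged, c("neuron", "v_th_mv"), lo = 0, strict_lo = TRUE)
  check_range(merged, c("neuron", "tau_m_ms"), lo = 0, strict_lo = TRUE)
  check_range(merged, c("neuron", "tau_ref_ms"), lo = 0)
  check_range(merged, c("simulation", "timestep_ms"), lo = 0, strict_lo = TRUE)
  check_range(merged, c("stp", "alpha"), lo = 0)
  check_range(merged, c("stp", "beta"), lo = 0, hi = 1)
  check_range(merged, c("trace", "tau_trace_ms"), lo = 0, strict_lo = TRUE)
  check_range(merged, c("connectivity", "input_sparsity"), lo = 0, hi = 1)
  check_range(merged, c("stdp", "eta"), lo = 0, strict_lo = TRUE)
  check_range(merged, c("stdp", "x_tar"), lo = 0, strict_lo = TRUE)
  check_range(merged, c("wta", "scale_target"), lo = 0, strict_lo = TRUE)
  check_range(merged, c("noise", "sigma_read"), lo = 0)
  check_range(merged, c("noise", "sigma_write"), lo = 0)
  check_range(merged, c("architecture", "n_layers"), lo = 1)
  if (merged$architecture$hidden_size %% 5 != 0) {
    stop("config key `architecture$hidden_size` must be divisible by 5 ",
         "(exact 4:1 E:I split)", call. = FALSE)
  }
  if (!merged$input$encoding %in% c("current", "poisson")) {
    stop("config key `input$encoding` must be \"current\" or \"poisson\"",
         call. = FALSE)
  }
  merged
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML configuration, rejects unknown keys and out-of-range
#' values (reporting the offending key path), and fills every omitted key
#' with its default; an empty file yields the full [default_config()].
#'
#' @param path YAML file path.
#' @return validated nested configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  validate_config(cfg)
}

#' Save a configuration as YAML
#'
#' @param cfg configuration list.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Build a [deep_lsm_config()] from an experiment configuration
#'
#' @param cfg validated configuration list (see [load_config()]).
#' @return a `deep_lsm_config`.
#' @export
config_to_network <- function(cfg) {
  cfg <- validate_config(cfg)
  dt <- cfg$simulation$timestep_ms
  deep_lsm_config(
    n_inputs = cfg$architecture$n_inputs,
    n_layers = cfg$architecture$n_layers,
    hidden_size = cfg$architecture$hidden_size,
    wta_size = cfg$architecture$wta_size,
    lif = lif_params(v_th = cfg$neuron$v_th_mv, tau_m = cfg$neuron$tau_m_ms,
                     tau_ref = cfg$neuron$tau_ref_ms,
                     v_rest = cfg$neuron$v_rest_mv, dt = dt),
    stp = stp_params(alpha = cfg$stp$alpha, beta = cfg$stp$beta),
    trace = trace_params(tau_trace = cfg$trace$tau_trace_ms, dt = dt),
    conn = connectivity_params(
      c_max = c(EE = cfg$connectivity$c_ee, EI = cfg$connectivity$c_ei,
                IE = cfg$connectivity$c_ie, II = cfg$connectivity$c_ii),
      lam = c(EE = cfg$connectivity$lambda_ee, EI = cfg$connectivity$lambda_ei,
              IE = cfg$connectivity$lambda_ie, II = cfg$connectivity$lambda_ii),
      w_fixed = c(EE = cfg$connectivity$w_ee, EI = cfg$connectivity$w_ei,
                  IE = cfg$connectivity$w_ie, II = cfg$connectivity$w_ii),
      input_sparsity = cfg$connectivity$input_sparsity,
      norm_targets = c(E = cfg$connectivity$norm_target_e,
                       I = cfg$connectivity$norm_target_i)),
    stdp = stdp_params(eta = cfg$stdp$eta, x_tar = cfg$stdp$x_tar),
    kappa = cfg$amplitudes$kappa,
    input_gain = cfg$amplitudes$input_gain,
    wta_gain = cfg$wta$gain,
    wta_in_weight = cfg$amplitudes$wta_in_weight,
    inter_sparsity = cfg$amplitudes$inter_sparsity,
    wta_scale_target = cfg$wta$scale_target,
    wta_theta_inc = cfg$wta$theta_inc_mv,
    wta_tau_theta = cfg$wta$tau_theta_ms,
    input_encoding = cfg$input$encoding,
    poisson_max_rate = cfg$input$poisson_max_rate_hz,
    frame_duration_ms = cfg$simulation$frame_duration_ms,
    pulse_ms = cfg$simulation$pulse_ms,
    seed = cfg$simulation$seed
  )
}
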