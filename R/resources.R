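#' Architecture specification for the resource model
#'
#' Describes one of three recurrent architectures — deep-LSM (a stack of `l`
#' reservoirs of width `h_d` joined by winner-take-all layers of width `w`),
#' a flat LSM of width `h`, or an LSTM of width `h` — for analytic accounting
#' of synapse counts, multiplication counts, weight memory, and energy.
#'
#' @param kind `"deep-lsm"`, `"lsm"` or `"lstm"`.
#' @param attention logical; include the two-stage attention readout.
#' @param n input size.
#' @param h_d hidden width per deep-LSM layer.
#' @param h flat hidden width (LSM/LSTM).
#' @param w winner-take-all layer width.
#' @param l number of deep-LSM hidden layers.
#' @param a spatial-attention width.
#' @param o number of output classes.
#' @param s_in input connection density (1 - sparsity).
#' @param s_r recurrent connection density.
#' @return an object of class `arch_spec`.
#' @export
arch_spec <- function(kind = c("deep-lsm", "lsm", "lstm"), attention = FALSE,
                      n = 100, h_d = 500, h = 1500, w = 50, l = 3,
                      a = 500, o = 10, s_in = 0.05, s_r = 0.05) {
  kind <- match.arg(kind)
  stopifnot(s_in >= 0, s_in <= 1, s_r >= 0, s_r <= 1,
            n >= 0, h_d >= 0, h >= 0, w >= 0, l >= 1, a >= 0, o >= 0)
  structure(list(kind = kind, attention = attention, n = n, h_d = h_d,
                 h = h, w = w, l = l, a = a, o = o, s_in = s_in, s_r = s_r),
            class = "arch_spec")
}

round_half_up <- function(x) floor(x + 0.5)

count_round <- function(x) {
  r <- round_half_up(x)
  structure(r, fractional = any(abs(x - r) > 1e-9))
}

#' Multiplications per inference step (forward pass)
#'
#' Evaluates the closed-form multiplication count of one forward pass
#' through the architecture. For the deep-LSM:
#' `s_in*n*h_d + 2(l-1)*s_in*(w*h_d) + l*s_r*h_d^2 + l*h_d*o`,
#' plus, with attention, `l*(h_d*a) + l*h_d + h_d + h_d*o` replacing the
#' plain readout term. LSM: `s_in*n*h + s_r*h^2 + h*o` (`+ h^2` with
#' attention). LSTM: `4*(n*h + h^2) + 3*h + h*o`.
#'
#' @param spec an [arch_spec()].
#' @return multiplication count (rounded half-up if densities give a
#'   fractional value; attribute `fractional` flags that case).
#' @export
count_fp_mults <- function(spec) {
  s <- spec
  x <- switch(s$kind,
    "deep-lsm" = {
      base <- s$s_in * s$n * s$h_d + 2 * (s$l - 1) * s$s_in * (s$w * s$h_d) +
        s$l * s$s_r * (s$h_d * s$h_d)
      if (s$attention) {
        base + s$l * (s$h_d * s$a) + s$l * s$h_d + s$h_d + s$h_d * s$o
      } else {
        base + s$l * s$h_d * s$o
      }
    },
    "lsm" = s$s_in * s$n * s$h + s$s_r * s$h * s$h + s$h * s$o +
      if (s$attention) s$h * s$h else 0,
    "lstm" = 4 * (s$n * s$h + s$h * s$h) + 3 * s$h + s$h * s$o
  )
  count_round(x)
}

#' Multiplications per training step (backward pass)
#'
#' Closed-form count for one gradient step of the trained portion of each
#' architecture: deep-LSM `l*(o*h_d)` (with attention
#' `3*(o*h_d) + a*h_d*l + 2*h_d + 2*l + 2*l*h_d`); LSM `h*o` (`+ h^2` with
#' attention); LSTM `2*(h*o) + 30*h + 4*(h*n) + 4*h^2`.
#'
#' @param spec an [arch_spec()].
#' @return multiplication count.
#' @export
count_bp_mults <- function(spec) {
  s <- spec
  x <- switch(s$kind,
    "deep-lsm" = if (s$attention) {
      3 * (s$o * s$h_d) + s$a * s$h_d * s$l + 2 * s$h_d + 2 * s$l +
        s$l * 2 * s$h_d
    } else {
      s$l * (s$o * s$h_d)
    },
    "lsm" = s$h * s$o + if (s$attention) s$h * s$h else 0,
    "lstm" = 2 * (s$h * s$o) + 30 * s$h + 4 * (s$h * s$n) + 4 * (s$h * s$h)
  )
  count_round(x)
}

#' Synapse counts by learning rule
#'
#' Counts the synaptic connections of an architecture grouped by how they
#' are obtained: trained by backpropagation (readout and attention weights),
#' fixed random (sparse input, recurrent and inter-layer projections, in
#' expectation under the stated densities), or trained by unsupervised STDP
#' (reservoir-to-WTA projections).
#'
#' The simulator instantiates reservoir-to-WTA projections fully connected;
#' `wta_counting = "full"` counts them that way (`(l-1)*h_d*w`), while
#' `"sparse"` (the default, matching the published benchmark accounting)
#' counts only the fraction `s_in` of them.
#'
#' @param spec an [arch_spec()].
#' @param wta_counting `"sparse"` or `"full"` accounting for the
#'   STDP-trained projections of a deep-LSM.
#' @param mode `"expected"` for closed-form expectations, `"instantiate"` to
#'   sample actual sparse projections at the stated densities and count them
#'   (deep-LSM and LSM only; small specs).
#' @param seed RNG seed for `mode = "instantiate"`.
#' @return a list with `backprop`, `random`, `unsupervised`,
#'   `unsupervised_full`, and `total` (= backprop + random + unsupervised).
#' @export
count_synapses <- function(spec, wta_counting = c("sparse", "full"),
                           mode = c("expected", "instantiate"), seed = 1L) {
  wta_counting <- match.arg(wta_counting)
  mode <- match.arg(mode)
  s <- spec
  if (s$kind == "lstm") {
    bp <- 4 * (s$n * s$h + s$h * s$h) + s$h * s$o
    out <- list(backprop = bp, random = 0, unsupervised = 0,
                unsupervised_full = 0, total = bp)
    return(out)
  }
  if (s$kind == "lsm") {
    bp <- s$h * s$o + if (s$attention) s$h * s$h else 0
    rand <- if (mode == "expected") {
      s$s_in * s$n * s$h + s$s_r * s$h * s$h
    } else {
      grid <- list(n = s$h)
      n_synapses(connect_input(s$n, grid, s$s_in,
                               seed = derive_seed(seed, "lsm-in"))) +
        n_synapses(connect_input(s$h, grid, s$s_r,
                                 seed = derive_seed(seed, "lsm-rec")))
    }
    return(list(backprop = bp, random = round_half_up(rand), unsupervised = 0,
                unsupervised_full = 0,
                total = round_half_up(bp + rand)))
  }
  # deep-lsm
  bp <- if (s$attention) {
    # deep attention (l x l*h_d) + spatial attention (a x l*h_d) + readout on
    # the collapsed state (h_d x o)
    s$l * (s$l * s$h_d) + s$a * (s$l * s$h_d) + s$h_d * s$o
  } else {
    s$l * s$h_d * s$o
  }
  n_input_pairs <- s$n * s$h_d
  n_inter_pairs <- (s$l - 1) * s$w * s$h_d
  n_rec_pairs <- s$l * s$h_d * s$h_d
  rand <- if (mode == "expected") {
    s$s_in * n_input_pairs + s$s_in * n_inter_pairs + s$s_r * n_rec_pairs
  } else {
    # sample the actual sparse projections at the stated densities and count
    grid <- list(n = s$h_d)
    cnt <- n_synapses(connect_input(s$n, grid, s$s_in,
                                    seed = derive_seed(seed, "deep-in")))
    for (k in seq_len(s$l - 1)) {
      cnt <- cnt + n_synapses(connect_input(
        s$w, grid, s$s_in, seed = derive_seed(seed, sprintf("deep-int-%d", k))))
    }
    for (k in seq_len(s$l)) {
      cnt <- cnt + n_synapses(connect_input(
        s$h_d, grid, s$s_r, seed = derive_seed(seed, sprintf("deep-rec-%d", k))))
    }
    cnt
  }
  unsup_full <- (s$l - 1) * s$h_d * s$w
  unsup_sparse <- s$s_in * unsup_full
  unsup <- if (wta_counting == "sparse") unsup_sparse else unsup_full
  list(backprop = bp,
       random = round_half_up(rand),
       unsupervised = round_half_up(unsup),
       unsupervised_full = unsup_full,
       total = round_half_up(bp + rand + unsup))
}

#' Weight memory in gigabits
#'
#' @param total_synapses synapse count.
#' @param bits bits per stored weight (default 32).
#' @return memory in Gb (`total * bits / 1e9`).
#' @export
memory_gigabits <- function(total_synapses, bits = 32) {
  total_synapses * bits / 1e9
}

#' Per-operation energy constants (45 nm reference)
#'
#' @param e_add energy per 32-bit addition (pJ).
#' @param e_mult energy per 32-bit multiplication (pJ).
#' @param e_dram energy per DRAM weight access (pJ).
#' @param bits_per_weight weight precision (bits).
#' @return an object of class `cost_constants`.
#' @export
cost_constants <- function(e_add = 0.9, e_mult = 3.7, e_dram = 360,
                           bits_per_weight = 32) {
  stopifnot(e_add > 0, e_mult > 0, e_dram > 0, bits_per_weight > 0)
  structure(list(e_add = e_add, e_mult = e_mult, e_dram = e_dram,
                 bits_per_weight = bits_per_weight),
            class = "cost_constants")
}

#' Energy estimate for one training frame
#'
#' Each multiplication is paired with one addition, so inference energy is
#' `fp_mults * (e_mult + e_add)`, training energy `bp_mults *
#' (e_mult + e_add)`, and weight-storage energy `total_synapses * e_dram`,
#' all reported in microjoules.
#'
#' @param fp_mults forward-pass multiplication count.
#' @param bp_mults backward-pass multiplication count.
#' @param total_synapses stored weight count.
#' @param constants a [cost_constants()].
#' @return list with `inference_uJ`, `training_uJ`, `weights_uJ`,
#'   `total_uJ`.
#' @export
energy_estimate <- function(fp_mults, bp_mults, total_synapses,
                            constants = cost_constants()) {
  per_op <- (constants$e_mult + constants$e_add) * 1e-6 # pJ -> uJ
  inference <- fp_mults * per_op
  training <- bp_mults * per_op
  weights <- total_synapses * constants$e_dram * 1e-6
  list(inference_uJ = inference, training_uJ = training,
       weights_uJ = weights, total_uJ = inference + training + weights)
}

#' Full resource report for one architecture
#'
#' Combines synapse, multiplication, memory and energy accounting. When the
#' closed-form multiplication formulas are known not to reproduce a
#' published benchmark count, reference counts can be supplied via
#' `counts`; the report then carries both (`fp_mults` from the formula,
#' `fp_mults_ref` as supplied) and energies computed from the reference
#' counts where given.
#'
#' @param spec an [arch_spec()].
#' @param constants a [cost_constants()].
#' @param counts optional named list overriding `fp_mults`, `bp_mults`
#'   and/or `total_synapses` with externally published reference values.
#' @param wta_counting passed to [count_synapses()].
#' @return an object of class `resource_report`.
#' @export
resource_report <- function(spec, constants = cost_constants(),
                            counts = NULL,
                            wta_counting = c("sparse", "full")) {
  wta_counting <- match.arg(wta_counting)
  syn <- count_synapses(spec, wta_counting = wta_counting)
  fp <- as.numeric(count_fp_mults(spec))
  bp <- as.numeric(count_bp_mults(spec))
  fp_ref <- counts$fp_mults %||% fp
  bp_ref <- counts$bp_mults %||% bp
  tot_ref <- counts$total_synapses %||% syn$total
  structure(list(
    spec = spec,
    synapses = syn,
    fp_mults = fp, bp_mults = bp,
    fp_mults_ref = fp_ref, bp_mults_ref = bp_ref,
    total_synapses_ref = tot_ref,
    memory_gb = memory_gigabits(syn$total, constants$bits_per_weight),
    memory_gb_ref = memory_gigabits(tot_ref, constants$bits_per_weight),
    energy = energy_estimate(fp, bp, syn$total, constants),
    energy_ref = energy_estimate(fp_ref, bp_ref, tot_ref, constants)
  ), class = "resource_report")
}

#' Benchmark architecture preset
#'
#' The reference comparison configuration: 100 inputs, a 3-layer deep-LSM of
#' 500-neuron reservoirs with 50-neuron WTA layers and a 500-unit spatial
#' attention, vs. a flat 1500-neuron LSM and a 1500-unit LSTM, 10 output
#' classes, 95% input sparsity, recurrent density 0.1076 in the deep-LSM
#' reservoirs and 0.05 in the flat LSM.
#'
#' The preset also carries the published per-frame operation counts for the
#' same configuration (`ref_counts`); where those differ from the
#' closed-form formulas, [resource_report()] reports both.
#'
#' @param name preset name; `"benchmark"` is the only preset.
#' @return a named list of [arch_spec()]s plus `ref_counts`.
#' @export
arch_preset <- function(name = "benchmark") {
  stopifnot(identical(name, "benchmark"))
  base <- list(n = 100, h_d = 500, h = 1500, w = 50, l = 3, a = 500, o = 10,
               s_in = 0.05)
  mk <- function(kind, attention, s_r) {
    do.call(arch_spec, c(list(kind = kind, attention = attention, s_r = s_r),
                         base))
  }
  list(
    specs = list(
      `deep-lsm` = mk("deep-lsm", FALSE, 0.1076),
      `deep-lsm+attention` = mk("deep-lsm", TRUE, 0.1076),
      lsm = mk("lsm", FALSE, 0.05),
      `lsm+attention` = mk("lsm", TRUE, 0.05),
      lstm = mk("lstm", FALSE, 0.05)
    ),
    # published per-frame reference counts for this configuration
    ref_counts = list(
      `deep-lsm` = list(fp_mults = 110700, bp_mults = 15000,
                        total_synapses = 108238),
      `deep-lsm+attention` = list(fp_mults = 857200, bp_mults = 773506,
                                  total_synapses = 852738),
      lsm = list(fp_mults = 135000, bp_mults = 15000,
                 total_synapses = 139016),
      `lsm+attention` = list(fp_mults = 2386500, bp_mults = 2251500,
                             total_synapses = 2389016),
      lstm = list(fp_mults = 9619500, bp_mults = 9675000,
                  total_synapses = 9615000)
    )
  )
}

#' Tabulate resource reports for a preset
#'
#' @param preset result of [arch_preset()].
#' @param constants a [cost_constants()].
#' @return a data.frame, one row per architecture, with synapse breakdown,
#'   memory (Gb, 4 d.p.) and energy (uJ, 4 d.p.) columns; `*_ref` columns
#'   use the published reference counts where the formulas disagree.
#' @export
resource_table <- function(preset = arch_preset(),
                           constants = cost_constants()) {
  rows <- lapply(names(preset$specs), function(nm) {
    rep_ <- resource_report(preset$specs[[nm]], constants,
                            counts = preset$ref_counts[[nm]])
    data.frame(
      model = nm,
      backprop = rep_$synapses$backprop,
      random = rep_$synapses$random,
      unsupervised = rep_$synapses$unsupervised,
      total_synapses = rep_$synapses$total,
      total_synapses_ref = rep_$total_synapses_ref,
      memory_gb = round(rep_$memory_gb, 4),
      memory_gb_ref = round(rep_$memory_gb_ref, 4),
      fp_mults = rep_$fp_mults,
      fp_mults_ref = rep_$fp_mults_ref,
      bp_mults = rep_$bp_mults,
      bp_mults_ref = rep_$bp_mults_ref,
      inference_uJ = round(rep_$energy_ref$inference_uJ, 4),
      training_uJ = round(rep_$energy_ref$training_uJ, 4),
      weights_uJ = round(rep_$energy_ref$weights_uJ, 4),
      total_uJ = round(rep_$energy_ref$total_uJ, 4)
    )
  })
  do.call(rbind, rows)
}
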