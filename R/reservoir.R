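#' 3-D grid specification for a reservoir
#'
#' Neurons are placed on an integer 3-D lattice and labelled excitatory or
#' inhibitory at random in an exact 4:1 ratio, so the population size must be
#' divisible by 5.
#'
#' @param dims integer vector of 3 positive lattice dimensions.
#' @param ei_ratio excitatory:inhibitory count ratio (fixed at 4).
#' @param seed integer RNG seed for the E/I label assignment.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(dims, ei_ratio = 4, seed = 1L) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  n <- prod(dims)
  if (n %% (ei_ratio + 1) != 0) {
    stop(sprintf("population size %d not divisible by %d (E:I ratio %d:1)",
                 n, ei_ratio + 1, ei_ratio), call. = FALSE)
  }
  structure(list(dims = dims, ei_ratio = ei_ratio, seed = as.integer(seed)),
            class = "grid_spec")
}

#' Most-cubic 3-D factorization of a layer size
#'
#' Utility used when a configuration gives a neuron count rather than lattice
#' dimensions: returns the factorization `a x b x c = n` minimizing the spread
#' between dimensions (e.g. 1000 -> 10 x 10 x 10, 500 -> 10 x 10 x 5).
#'
#' @param n positive integer population size.
#' @return integer vector of 3 dimensions (non-increasing).
#' @export
cubic_dims <- function(n) {
  stopifnot(n >= 1)
  best <- NULL
  best_score <- Inf
  for (a in seq_len(floor(n^(1 / 3)) + 1)) {
    if (n %% a != 0) next
    m <- n %/% a
    for (b in seq_len(floor(sqrt(m)) + 1)) {
      if (m %% b != 0) next
      d <- sort(c(a, b, m %/% b), decreasing = TRUE)
      score <- d[1] / d[3]
      if (score < best_score) {
        best <- d
        best_score <- score
      }
    }
  }
  as.integer(best)
}

#' Build a 3-D grid of excitatory/inhibitory neurons
#'
#' Places `prod(dims)` neurons on the integer lattice and assigns E/I labels
#' uniformly at random (given the seed) in an exact 4:1 ratio.
#'
#' @param spec a [grid_spec()].
#' @return a list with `positions` (n x 3 integer matrix), `is_excitatory`
#'   (logical), `n`, `n_exc`, `n_inh`, of class `neuron_grid`.
#' @export
build_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  n <- prod(spec$dims)
  positions <- as.matrix(expand.grid(
    x = seq_len(spec$dims[1]),
    y = seq_len(spec$dims[2]),
    z = seq_len(spec$dims[3])
  ))
  n_exc <- n * spec$ei_ratio / (spec$ei_ratio + 1)
  labels <- with_seed(spec$seed, sample(rep(c(TRUE, FALSE), c(n_exc, n - n_exc))))
  structure(list(positions = positions, is_excitatory = labels,
                 n = n, n_exc = n_exc, n_inh = n - n_exc,
                 dims = spec$dims),
            class = "neuron_grid")
}

#' Connectivity parameters for a reservoir
#'
#' Recurrent connections form with probability
#' `C * exp(-D/lambda)^2`, with `C` and `lambda` specific to the ordered
#' type pair (EE, EI, IE, II) and `D` the Euclidean lattice distance.
#' Weights are fixed per pair type. Incoming excitatory and inhibitory weight
#' sums are normalized to per-neuron targets so all neurons share a
#' homogeneous excitability.
#'
#' Defaults: `C` EE/EI/II/IE = 0.6/1/0.2/1, `lambda` = 3 for all pairs,
#' weights EE 3, EI 3, IE 4, II 1, input connection probability 0.05
#' (95% sparsity), normalization targets 40 (E) and 36 (I).
#'
#' @param c_max named vector of maximum connection probabilities per ordered
#'   pair, names `EE`, `EI`, `IE`, `II` (first letter = presynaptic type).
#' @param lam named vector of distance scales per pair (lattice units).
#' @param w_fixed named vector of fixed synaptic strengths per pair.
#' @param input_sparsity probability of an input-to-reservoir connection.
#' @param norm_targets named vector `c(E =, I =)` of incoming-sum targets.
#' @return an object of class `connectivity_params`.
#' @export
connectivity_params <- function(c_max = c(EE = 0.6, EI = 1, IE = 1, II = 0.2),
                                lam = c(EE = 3, EI = 3, IE = 3, II = 3),
                                w_fixed = c(EE = 3, EI = 3, IE = 4, II = 1),
                                input_sparsity = 0.05,
                                norm_targets = c(E = 40, I = 36)) {
  pairs <- c("EE", "EI", "IE", "II")
  stopifnot(all(pairs %in% names(c_max)), all(pairs %in% names(lam)),
            all(pairs %in% names(w_fixed)),
            all(c_max >= 0), all(c_max <= 1), all(lam > 0), all(w_fixed > 0),
            input_sparsity >= 0, input_sparsity <= 1,
            all(norm_targets > 0))
  structure(list(c_max = c_max[pairs], lam = lam[pairs],
                 w_fixed = w_fixed[pairs],
                 input_sparsity = input_sparsity,
                 norm_targets = norm_targets),
            class = "connectivity_params")
}

#' Sparse directed synapse set
#'
#' A projection between two populations stored as a sparse `n_pre x n_post`
#' non-negative weight matrix plus a per-presynaptic-neuron sign (+1
#' excitatory, -1 inhibitory) applied at drive computation, and a tag naming
#' the projection kind.
#'
#' @param w sparse (or dense) `n_pre x n_post` non-negative weight matrix.
#' @param sign per-presynaptic-neuron sign vector (+1/-1).
#' @param tag projection kind: `"recurrent"`, `"input"`, `"inter-layer"` or
#'   `"wta"`.
#' @return an object of class `synapse_set`.
#' @export
synapse_set <- function(w, sign = rep(1, nrow(w)),
                        tag = c("recurrent", "input", "inter-layer", "wta")) {
  tag <- match.arg(tag)
  w <- methods::as(methods::as(w, "CsparseMatrix"), "generalMatrix")
  stopifnot(length(sign) == nrow(w), all(sign %in% c(-1, 1)))
  if (any(w@x < 0)) stop("synapse weights must be non-negative; sign is per presynaptic neuron",
                         call. = FALSE)
  structure(list(w = w, sign = as.numeric(sign), tag = tag),
            class = "synapse_set")
}

#' Number of synapses in a synapse set
#' @param synapses a [synapse_set()].
#' @return integer count of non-zero connections.
#' @export
n_synapses <- function(synapses) length(synapses$w@x)

#' Eq.-style distance-dependent connection probability
#'
#' @param d Euclidean lattice distance(s).
#' @param c_max maximum connection probability.
#' @param lam distance scale.
#' @return connection probability `c_max * exp(-d/lam)^2`.
#' @export
connection_prob <- function(d, c_max, lam) {
  c_max * exp(-d / lam)^2
}

#' Sample distance-dependent recurrent connectivity
#'
#' For each ordered neuron pair (i, j), i != j, a connection i -> j forms
#' independently with probability [connection_prob()] for the pair's type
#' (presynaptic type first: an EI connection runs E -> I); its weight is the
#' fixed strength of that type. Self-connections are excluded; the i -> j and
#' j -> i draws are independent. No lattice wraparound.
#'
#' @param grid a [build_grid()] result.
#' @param params a [connectivity_params()].
#' @param seed integer RNG seed.
#' @return a `synapse_set` tagged `"recurrent"`.
#' @export
connect_recurrent <- function(grid, params, seed = 1L) {
  stopifnot(inherits(grid, "neuron_grid"))
  n <- grid$n
  pos <- grid$positions
  exc <- grid$is_excitatory
  # pair type per ordered (pre, post): EE/EI/IE/II by pre then post label
  d2 <- outer(rowSums(pos^2), rowSums(pos^2), "+") - 2 * tcrossprod(pos)
  d <- sqrt(pmax(d2, 0))
  type_idx <- matrix(0L, n, n)
  type_idx[exc, exc] <- 1L   # EE
  type_idx[exc, !exc] <- 2L  # EI
  type_idx[!exc, exc] <- 3L  # IE
  type_idx[!exc, !exc] <- 4L # II
  p <- params$c_max[type_idx] * exp(-d / params$lam[type_idx])^2
  dim(p) <- c(n, n)
  diag(p) <- 0
  keep <- with_seed(derive_seed(seed, "recurrent"),
                    matrix(runif(n * n), n, n) < p)
  idx <- which(keep, arr.ind = TRUE)
  w <- Matrix::sparseMatrix(
    i = idx[, 1], j = idx[, 2],
    x = params$w_fixed[type_idx[keep]],
    dims = c(n, n)
  )
  synapse_set(w, sign = ifelse(exc, 1, -1), tag = "recurrent")
}

#' Sample a sparse input projection
#'
#' Each (input, reservoir neuron) pair is connected independently with
#' probability `input_sparsity`; connected weights are 1 (input drive
#' amplitude is set by the encoder gain). Neurons with at least one input
#' connection are "primary", the rest "auxiliary".
#'
#' @param n_inputs number of input channels (>= 1).
#' @param grid a [build_grid()] result (or any object with `$n`).
#' @param input_sparsity connection probability.
#' @param seed integer RNG seed.
#' @param tag projection tag, `"input"` by default (inter-layer projections
#'   from winner-take-all layers reuse this sampler with tag
#'   `"inter-layer"`).
#' @param weight weight given to each sampled connection.
#' @return a `synapse_set` with attribute `primary` (logical per reservoir
#'   neuron).
#' @export
connect_input <- function(n_inputs, grid, input_sparsity, seed = 1L,
                          tag = "input", weight = 1) {
  stopifnot(n_inputs >= 1)
  n_post <- grid$n
  keep <- with_seed(derive_seed(seed, paste0(tag, "-proj")),
                    matrix(runif(n_inputs * n_post), n_inputs, n_post) < input_sparsity)
  idx <- which(keep, arr.ind = TRUE)
  w <- Matrix::sparseMatrix(i = idx[, 1], j = idx[, 2],
                            x = rep(weight, nrow(idx)),
                            dims = c(n_inputs, n_post))
  ss <- synapse_set(w, sign = rep(1, n_inputs), tag = tag)
  ss$primary <- Matrix::colSums(w) > 0
  ss
}

#' Normalize incoming synaptic sums per postsynaptic neuron
#'
#' Scales each neuron's incoming excitatory weights so they sum to the E
#' target, and incoming inhibitory weights to the I target, preserving
#' relative proportions; this keeps excitability homogeneous across the
#' population. Neurons with no incoming weight of a class are left
#' unmodified.
#'
#' @param synapses a [synapse_set()] (recurrent).
#' @param norm_targets named vector `c(E =, I =)`.
#' @return the rescaled `synapse_set`.
#' @export
normalize_synapses <- function(synapses, norm_targets = c(E = 40, I = 36)) {
  w <- synapses$w
  exc <- synapses$sign > 0
  for (cls in c("E", "I")) {
    rows <- if (cls == "E") exc else !exc
    if (!any(rows)) next
    sums <- Matrix::colSums(w[rows, , drop = FALSE])
    scale <- ifelse(sums > 0, norm_targets[[cls]] / sums, 1)
    w[rows, ] <- w[rows, , drop = FALSE] %*% Matrix::Diagonal(x = scale)
  }
  synapses$w <- methods::as(methods::as(w, "CsparseMatrix"), "generalMatrix")
  synapses
}

#' Noise model for weight storage (read/write noise)
#'
#' Emulates device noise in analog weight storage: every read returns the
#' stored weight plus zero-mean Gaussian noise of sd `sigma_read * w_scale`
#' without mutating storage, and every write stores the new value plus noise
#' of sd `sigma_write * w_scale`. With both sigmas zero the model is
#' bit-identical to noise-free operation (no RNG draws are made).
#'
#' @param sigma_read read-noise sd as a fraction of `w_scale`.
#' @param sigma_write write-noise sd as a fraction of `w_scale`.
#' @param w_scale reference weight magnitude setting the noise unit.
#' @return an object of class `weight_noise`.
#' @export
weight_noise <- function(sigma_read = 0, sigma_write = 0, w_scale = 1) {
  if (sigma_read < 0 || sigma_write < 0) {
    stop("noise sigmas must be non-negative", call. = FALSE)
  }
  structure(list(sigma_read = sigma_read, sigma_write = sigma_write,
                 w_scale = abs(w_scale)),
            class = "weight_noise")
}

#' Read weights through the noise model
#'
#' Returns a perturbed copy of the weights (sparse pattern preserved; only
#' stored entries are perturbed). `sigma_read = 0` returns the input
#' unchanged without consuming RNG state.
#'
#' @param w numeric vector/matrix or sparse matrix of weights.
#' @param noise a [weight_noise()].
#' @return perturbed weights of the same shape.
#' @export
noisy_read <- function(w, noise) {
  if (noise$sigma_read == 0) return(w)
  sd <- noise$sigma_read * noise$w_scale
  if (is(w, "sparseMatrix")) {
    w@x <- w@x + rnorm(length(w@x), 0, sd)
  } else {
    w <- w + rnorm(length(w), 0, sd)
  }
  w
}

#' Write weights through the noise model
#'
#' @param w_new weights to store.
#' @param noise a [weight_noise()].
#' @return the stored (perturbed) weights.
#' @export
noisy_write <- function(w_new, noise) {
  if (noise$sigma_write == 0) return(w_new)
  sd <- noise$sigma_write * noise$w_scale
  if (is(w_new, "sparseMatrix")) {
    w_new@x <- w_new@x + rnorm(length(w_new@x), 0, sd)
  } else {
    w_new <- w_new + rnorm(length(w_new), 0, sd)
  }
  w_new
}

#' Human-readable topology summary
#'
#' @param x a `synapse_set`.
#' @param ... unused.
#' @method print synapse_set
#' @export
print.synapse_set <- function(x, ...) {
  cat(sprintf("<synapse_set: %s, %d pre x %d post, %d synapses (%d excitatory pre)>\n",
              x$tag, nrow(x$w), ncol(x$w), n_synapses(x), sum(x$sign > 0)))
  invisible(x)
}
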