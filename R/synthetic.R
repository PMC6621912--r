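#' Synthetic sequence-classification task specification
#'
#' Generates labeled multivariate feature sequences shaped like
#' CNN-extracted, PCA-reduced video-frame features: `n_dims`-dimensional
#' frames, variable sequence lengths drawn from a log-normal distribution
#' clipped to `[len_min, len_max]` with parameters solved so the clipped
#' mean equals `len_mean` (defaults 30 / 650 / 157 frames).
#'
#' Each class is defined by a latent temporal motif — a class-specific
#' constant offset (emulating the class-conditional mean of CNN object
#' features) plus class-specific sinusoids and a shared random-walk drift —
#' projected to `n_dims` dimensions through a fixed random matrix and
#' corrupted with Gaussian observation noise. In the `temporal_order` variant all classes
#' share the same three motif segments and differ only in the order the
#' segments are played, so time-averaged features carry (almost) no class
#' information and only a temporally sensitive model can separate the
#' classes.
#'
#' @param n_classes number of classes (>= 2).
#' @param n_dims observed feature dimensionality (default 100).
#' @param len_min,len_max,len_mean sequence-length bounds and mean (frames).
#' @param latent_dim latent motif dimensionality.
#' @param noise_sd observation noise sd (default 0.3).
#' @param drift_sd random-walk drift sd per frame.
#' @param n_train,n_test sequences per split (balanced across classes).
#' @param temporal_order logical; generate the segment-order variant.
#' @param seed master seed.
#' @return an object of class `synth_task_spec`.
#' @export
synth_task_spec <- function(n_classes = 3, n_dims = 100,
                            len_min = 30, len_max = 650, len_mean = 157,
                            latent_dim = 5, noise_sd = 0.3, drift_sd = 0.02,
                            n_train = 60, n_test = 30,
                            temporal_order = FALSE, seed = 1L) {
  stopifnot(n_classes >= 2, n_dims >= 1,
            len_min >= 1, len_max > len_min,
            len_mean > len_min, len_mean < len_max,
            noise_sd >= 0, n_train >= n_classes, n_test >= n_classes)
  structure(list(n_classes = n_classes, n_dims = n_dims,
                 len_min = len_min, len_max = len_max, len_mean = len_mean,
                 latent_dim = latent_dim, noise_sd = noise_sd,
                 drift_sd = drift_sd, n_train = n_train, n_test = n_test,
                 temporal_order = temporal_order, seed = as.integer(seed)),
            class = "synth_task_spec")
}

# Solve the log-normal meanlog so that E[clamp(LN(mu, sdlog), lo, hi)] = target.
lognormal_meanlog <- function(lo, hi, target, sdlog = 0.6) {
  clipped_mean <- function(mu) {
    f <- function(x) x * stats::dlnorm(x, mu, sdlog)
    mid <- stats::integrate(f, lo, hi, rel.tol = 1e-9)$value
    p_lo <- stats::plnorm(lo, mu, sdlog)
    p_hi <- 1 - stats::plnorm(hi, mu, sdlog)
    mid + lo * p_lo + hi * p_hi
  }
  stats::uniroot(function(mu) clipped_mean(mu) - target,
                 lower = log(lo), upper = log(hi), tol = 1e-10)$root
}

draw_lengths <- function(n, spec, seed) {
  mu <- lognormal_meanlog(spec$len_min, spec$len_max, spec$len_mean)
  with_seed(seed,
            as.integer(round(clamp(rlnorm(n, mu, 0.6),
                                   spec$len_min, spec$len_max))))
}

#' Draw sequence lengths from the clipped log-normal length model
#'
#' @param n number of lengths to draw.
#' @param spec a [synth_task_spec()].
#' @param seed RNG seed (defaults to the spec's).
#' @return integer vector of lengths in `[len_min, len_max]`.
#' @export
draw_sequence_lengths <- function(n, spec, seed = spec$seed) {
  draw_lengths(n, spec, seed)
}

balanced_labels <- function(n, n_classes) {
  rep_len(seq_len(n_classes), n)
}

latent_trajectory <- function(len, class_freqs, class_phases, class_offset,
                              amp, drift_sd, latent_dim, order = NULL,
                              segments = NULL) {
  t <- seq_len(len)
  z <- matrix(0, len, latent_dim)
  if (is.null(order)) {
    for (d in seq_len(latent_dim)) {
      z[, d] <- class_offset[d] +
        amp * sin(2 * pi * class_freqs[d] * t + class_phases[d])
    }
  } else {
    # segment-order variant: the same motif segments, played in class order,
    # so the time average is class-independent by construction
    bounds <- round(seq(0, len, length.out = length(order) + 1))
    for (s in seq_along(order)) {
      idx <- (bounds[s] + 1):bounds[s + 1]
      seg <- segments[[order[s]]]
      for (d in seq_len(latent_dim)) {
        z[idx, d] <- seg$offset[d] +
          amp * sin(2 * pi * seg$freqs[d] * seq_along(idx))
      }
    }
  }
  drift <- apply(matrix(rnorm(len * latent_dim, 0, drift_sd),
                        len, latent_dim), 2, cumsum)
  z + drift
}

#' Generate a labeled synthetic sequence dataset
#'
#' Fully seeded: identical spec + seed give identical data. Class priors are
#' balanced to within one sequence in each split.
#'
#' @param spec a [synth_task_spec()].
#' @return a list with `train` and `test`, each a list of `sequences`
#'   (matrices, frames x n_dims), `labels` (integer 1..n_classes), and
#'   `lengths`; plus the `spec`.
#' @export
generate_sequences <- function(spec) {
  stopifnot(inherits(spec, "synth_task_spec"))
  k <- spec$n_classes
  ld <- spec$latent_dim

  class_freqs <- with_seed(derive_seed(spec$seed, "motifs"), {
    lapply(seq_len(k), function(cl) runif(ld, 0.01, 0.12))
  })
  class_phases <- with_seed(derive_seed(spec$seed, "phases"), {
    lapply(seq_len(k), function(cl) runif(ld, 0, 2 * pi))
  })
  class_offsets <- with_seed(derive_seed(spec$seed, "offsets"), {
    lapply(seq_len(k), function(cl) runif(ld, -1, 1))
  })
  # segment motifs and per-class orders for the temporal-order variant
  segments <- with_seed(derive_seed(spec$seed, "segments"), {
    lapply(seq_len(3), function(s) list(freqs = runif(ld, 0.01, 0.12),
                                        offset = runif(ld, -1, 1)))
  })
  orders <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2),
                 c(1, 3, 2), c(3, 2, 1), c(2, 1, 3))

  projection <- with_seed(derive_seed(spec$seed, "projection"),
                          matrix(rnorm(ld * spec$n_dims, 0, 1 / sqrt(ld)),
                                 ld, spec$n_dims))

  make_split <- function(n, tag) {
    labels <- balanced_labels(n, k)
    lengths <- draw_lengths(n, spec, derive_seed(spec$seed, paste0("len-", tag)))
    seqs <- vector("list", n)
    for (i in seq_len(n)) {
      cl <- labels[i]
      s_i <- derive_seed(spec$seed, sprintf("%s-seq-%d", tag, i))
      seqs[[i]] <- with_seed(s_i, {
        z <- if (spec$temporal_order) {
          latent_trajectory(lengths[i], NULL, NULL, NULL, amp = 1,
                            drift_sd = spec$drift_sd, latent_dim = ld,
                            order = orders[[cl]], segments = segments)
        } else {
          latent_trajectory(lengths[i], class_freqs[[cl]],
                            class_phases[[cl]], class_offsets[[cl]], amp = 1,
                            drift_sd = spec$drift_sd, latent_dim = ld)
        }
        x <- z %*% projection
        if (spec$noise_sd > 0) {
          x <- x + matrix(rnorm(length(x), 0, spec$noise_sd), nrow(x), ncol(x))
        }
        x
      })
    }
    list(sequences = seqs, labels = labels, lengths = lengths)
  }

  list(train = make_split(spec$n_train, "train"),
       test = make_split(spec$n_test, "test"),
       spec = spec)
}

#' Memoryless linear baseline on time-averaged features
#'
#' Trains linear discriminant analysis on per-sequence time-averaged
#' features and reports test accuracy. Serves as the control against which
#' temporally sensitive models are compared: on the segment-order task
#' variant the time average is class-uninformative by construction and this
#' baseline falls to chance.
#'
#' @param dataset result of [generate_sequences()].
#' @return test-set accuracy in \[0, 1\].
#' @export
linear_baseline <- function(dataset) {
  avg <- function(split) t(vapply(split$sequences, colMeans,
                                  numeric(ncol(split$sequences[[1]]))))
  xtr <- avg(dataset$train)
  xte <- avg(dataset$test)
  # project to leading PCs first: the features are a low-rank latent signal
  # plus noise, and raw columns are collinear
  pc <- stats::prcomp(xtr, rank. = min(10, ncol(xtr), nrow(xtr) - 1))
  fit <- MASS::lda(pc$x, grouping = factor(dataset$train$labels))
  pred <- predict(fit, predict(pc, xte))$class
  mean(as.integer(as.character(pred)) == dataset$test$labels)
}

#' Generate spike-train toy tasks
#'
#' Two diagnostic spike datasets: `"delayed-recall"` presents one of two cue
#' spike patterns followed by a silent delay of `delay_ms`, probing whether
#' temporal memory survives across the delay (with `delay_ms = 0` the task
#' is solvable by a memoryless readout); `"pattern-pair"` draws sequences
#' from one of two fixed Poisson rate templates, for winner-take-all
#' differentiation tests. The cue/template identity carries one bit of class
#' information by construction.
#'
#' @param task `"delayed-recall"` or `"pattern-pair"`.
#' @param n_sequences number of spike rasters to generate.
#' @param n_channels spike channels.
#' @param duration_ms raster length (ms); for delayed recall this includes
#'   the cue window and the delay.
#' @param delay_ms silent delay after the cue (delayed recall only).
#' @param rate_hz Poisson rate of active channels.
#' @param seed master seed.
#' @return list of `rasters` (duration x channels binary matrices) and
#'   `labels` (1/2).
#' @export
generate_spike_toys <- function(task = c("delayed-recall", "pattern-pair"),
                                n_sequences = 20, n_channels = 20,
                                duration_ms = 100, delay_ms = 50,
                                rate_hz = 100, seed = 1L) {
  task <- match.arg(task)
  stopifnot(n_channels >= 2, duration_ms >= 1, delay_ms >= 0)
  p_spike <- rate_hz / 1000
  labels <- balanced_labels(n_sequences, 2)
  half <- n_channels %/% 2
  rasters <- vector("list", n_sequences)
  for (i in seq_len(n_sequences)) {
    rasters[[i]] <- with_seed(derive_seed(seed, sprintf("%s-%d", task, i)), {
      r <- matrix(0L, duration_ms, n_channels)
      active <- if (labels[i] == 1) seq_len(half) else (half + 1):n_channels
      if (task == "delayed-recall") {
        cue_len <- max(1, duration_ms - delay_ms)
        r[seq_len(cue_len), active] <-
          matrix(rbinom(cue_len * length(active), 1, p_spike),
                 cue_len, length(active))
      } else {
        r[, active] <- matrix(rbinom(duration_ms * length(active), 1, p_spike),
                              duration_ms, length(active))
        other <- setdiff(seq_len(n_channels), active)
        r[, other] <- matrix(rbinom(duration_ms * length(other), 1,
                                    p_spike / 10),
                             duration_ms, length(other))
      }
      r
    })
  }
  list(rasters = rasters, labels = labels, task = task)
}

#' Write a dataset as delimited text plus a manifest
#'
#' One CSV per sequence (rows = frames, columns = feature dimensions) and a
#' `manifest.csv` with path, label and length.
#'
#' @param dataset result of [generate_sequences()].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data.frame.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (split in c("train", "test")) {
    d <- dataset[[split]]
    for (i in seq_along(d$sequences)) {
      path <- file.path(dir, sprintf("%s_%04d.csv", split, i))
      utils::write.table(d$sequences[[i]], path, sep = ",",
                         row.names = FALSE, col.names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        path = basename(path), split = split,
        label = d$labels[i], length = d$lengths[i])
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return a list with `train` and `test` splits as in
#'   [generate_sequences()].
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  out <- list()
  for (split in c("train", "test")) {
    m <- manifest[manifest$split == split, , drop = FALSE]
    seqs <- lapply(file.path(dir, m$path), function(p) {
      as.matrix(utils::read.table(p, sep = ","))
    })
    seqs <- lapply(seqs, unname)
    out[[split]] <- list(sequences = seqs, labels = m$label,
                         lengths = m$length)
  }
  out
}
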