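config_hash <- function(cfg) {
  s <- yaml::as.yaml(cfg)
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_manifest <- function(out_dir, cfg, command, metrics = list()) {
  manifest <- list(
    command = command,
    config_hash = config_hash(cfg),
    seed = cfg$simulation$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("deeplsm")),
    metrics = metrics
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop(sprintf("missing upstream artifact `%s` (run `%s` first)",
                 path, produced_by), call. = FALSE)
  }
  invisible(path)
}

#' Run one experiment stage
#'
#' Orchestrates the pipeline on disk. Stages (all resumable from the
#' artifacts of earlier stages in `out_dir`):
#' \describe{
#'   \item{synth}{generate the synthetic dataset into `out_dir/data/`.}
#'   \item{train-wta}{build the network, fit the encoder, train the WTA
#'     layers; topology and weights go to `out_dir/network/`.}
#'   \item{simulate}{collect `X_deep` snapshots for train and test splits
#'     into delimited text.}
#'   \item{train-readout}{train the attention readout on the train
#'     snapshots.}
#'   \item{evaluate}{test accuracy and confusion matrix.}
#'   \item{resources}{write the benchmark resource table (CSV + JSON).}
#' }
#' Every stage writes a `manifest.json` with the config hash, seed,
#' versions and stage metrics, so each artifact is traceable.
#'
#' @param cfg validated configuration (see [load_config()],
#'   [default_config()]).
#' @param command stage name.
#' @param out_dir working directory for artifacts.
#' @param task optional [synth_task_spec()] override for `synth`.
#' @return the stage's metrics, invisibly.
#' @export
run_experiment <- function(cfg,
                           command = c("synth", "train-wta", "simulate",
                                       "train-readout", "evaluate",
                                       "resources"),
                           out_dir = ".", task = NULL) {
  command <- match.arg(command)
  cfg <- validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(out_dir, "data")
  net_dir <- file.path(out_dir, "network")
  metrics <- list()

  if (command == "synth") {
    spec <- task %||% synth_task_spec(n_dims = cfg$architecture$n_inputs,
                                      seed = cfg$simulation$seed)
    ds <- generate_sequences(spec)
    write_dataset(ds, data_dir)
    metrics <- list(n_train = length(ds$train$sequences),
                    n_test = length(ds$test$sequences),
                    mean_length = mean(c(ds$train$lengths, ds$test$lengths)))
  } else if (command == "train-wta") {
    require_artifact(file.path(data_dir, "manifest.csv"), "synth")
    ds <- read_dataset(data_dir)
    net <- deep_lsm(config_to_network(cfg))
    net <- fit_encoder(net, ds$train$sequences)
    net <- train_wta_layers(net, ds$train$sequences, epochs_per_layer = 1)
    export_topology(net, net_dir)
    saveRDS(net, file.path(out_dir, "network.rds"))
    metrics <- list(n_layers = cfg$architecture$n_layers)
  } else if (command == "simulate") {
    require_artifact(file.path(out_dir, "network.rds"), "train-wta")
    ds <- read_dataset(data_dir)
    net <- readRDS(file.path(out_dir, "network.rds"))
    noise <- noise_from_config(cfg)
    for (split in c("train", "test")) {
      snaps <- collect_snapshots(net, ds[[split]]$sequences, noise = noise)
      utils::write.table(snaps,
                         file.path(out_dir, sprintf("snapshots_%s.csv", split)),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
    metrics <- list(snapshot_dim = sum(config_to_network(cfg)$hidden_size))
  } else if (command == "train-readout") {
    require_artifact(file.path(out_dir, "snapshots_train.csv"), "simulate")
    ds <- read_dataset(data_dir)
    snaps <- as.matrix(utils::read.table(
      file.path(out_dir, "snapshots_train.csv"), sep = ","))
    fit <- train_readout(snaps, ds$train$labels,
                         n_layers = cfg$architecture$n_layers,
                         n_hidden = cfg$architecture$hidden_size,
                         lr = cfg$readout$lr, epochs = cfg$readout$epochs,
                         seed = cfg$simulation$seed)
    saveRDS(fit$params, file.path(out_dir, "readout.rds"))
    utils::write.csv(data.frame(epoch = seq_along(fit$loss), loss = fit$loss),
                     file.path(out_dir, "loss.csv"), row.names = FALSE)
    metrics <- list(train_accuracy = fit$accuracy,
                    final_loss = fit$loss[length(fit$loss)])
  } else if (command == "evaluate") {
    require_artifact(file.path(out_dir, "readout.rds"), "train-readout")
    require_artifact(file.path(out_dir, "snapshots_test.csv"), "simulate")
    ds <- read_dataset(data_dir)
    params <- readRDS(file.path(out_dir, "readout.rds"))
    snaps <- as.matrix(utils::read.table(
      file.path(out_dir, "snapshots_test.csv"), sep = ","))
    ev <- evaluate_readout(params, snaps, ds$test$labels)
    utils::write.csv(as.data.frame.matrix(ev$confusion),
                     file.path(out_dir, "confusion.csv"))
    metrics <- list(test_accuracy = ev$accuracy)
  } else if (command == "resources") {
    tab <- resource_table()
    utils::write.csv(tab, file.path(out_dir, "resources.csv"),
                     row.names = FALSE)
    jsonlite::write_json(tab, file.path(out_dir, "resources.json"),
                         digits = NA, pretty = TRUE)
    metrics <- list(models = nrow(tab))
  }
  write_manifest(out_dir, cfg, command, metrics)
  invisible(metrics)
}

noise_from_config <- function(cfg) {
  if (cfg$noise$sigma_read == 0 && cfg$noise$sigma_write == 0) return(NULL)
  weight_noise(cfg$noise$sigma_read, cfg$noise$sigma_write, w_scale = 1)
}
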