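#' Plain-text hierarchical state container
#'
#' Serializes nested lists of numeric vectors/matrices to a directory tree:
#' groups become subdirectories, leaf datasets become delimited text files
#' (`.csv`, no headers). Sparse matrices are stored as (i, j, x) triplet
#' tables. The container is self-describing enough to round-trip with
#' [read_state_container()].
#'
#' @param object nested named list of numeric vectors, matrices or sparse
#'   matrices.
#' @param dir target directory (created; existing files overwritten).
#' @return invisibly, `dir`.
#' @export
write_state_container <- function(object, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(object)) {
    x <- object[[nm]]
    if (is.list(x) && !is(x, "sparseMatrix")) {
      write_state_container(x, file.path(dir, nm))
    } else if (is(x, "sparseMatrix")) {
      tm <- methods::as(x, "TsparseMatrix")
      df <- data.frame(i = tm@i + 1L, j = tm@j + 1L, x = tm@x)
      attr_path <- file.path(dir, paste0(nm, ".sparse.csv"))
      utils::write.csv(cbind(df, nrow = nrow(x), ncol = ncol(x)),
                       attr_path, row.names = FALSE)
    } else {
      utils::write.table(as.matrix(x), file.path(dir, paste0(nm, ".csv")),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read a state container written by [write_state_container()]
#'
#' @param dir container directory.
#' @return nested named list; dense leaves come back as matrices (a
#'   one-column matrix for vectors), sparse leaves as `dgCMatrix`.
#' @export
read_state_container <- function(dir) {
  entries <- list.files(dir, full.names = FALSE)
  out <- list()
  for (e in entries) {
    full <- file.path(dir, e)
    if (dir.exists(full)) {
      out[[e]] <- read_state_container(full)
    } else if (grepl("\\.sparse\\.csv$", e)) {
      df <- utils::read.csv(full)
      nm <- sub("\\.sparse\\.csv$", "", e)
      out[[nm]] <- Matrix::sparseMatrix(i = df$i, j = df$j, x = df$x,
                                        dims = c(df$nrow[1], df$ncol[1]))
    } else if (grepl("\\.csv$", e)) {
      nm <- sub("\\.csv$", "", e)
      out[[nm]] <- unname(as.matrix(utils::read.table(full, sep = ",")))
    }
  }
  out
}

#' Export a spike or trace raster as delimited text
#'
#' Rows are timesteps, columns neurons.
#'
#' @param raster numeric matrix.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
export_raster <- function(raster, path) {
  utils::write.table(as.matrix(raster), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize a deep-LSM topology to a state container
#'
#' Writes per-layer neuron positions, E/I labels, recurrent and projection
#' weight triplets, and learned WTA weights.
#'
#' @param net a [deep_lsm()].
#' @param dir target directory.
#' @return invisibly, `dir`.
#' @export
export_topology <- function(net, dir) {
  obj <- list()
  for (l in seq_along(net$layers)) {
    lay <- net$layers[[l]]
    obj[[sprintf("layer%d", l)]] <- list(
      positions = lay$grid$positions,
      is_excitatory = as.numeric(lay$grid$is_excitatory),
      recurrent = lay$rec$w,
      projection = lay$proj$w
    )
  }
  for (k in seq_along(net$wta)) {
    obj[[sprintf("wta%d", k)]] <- list(weights = net$wta[[k]]$weights)
  }
  write_state_container(obj, dir)
}
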