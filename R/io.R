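# Plain-text model state export/import.
#
# One directory per model: a manifest plus one CSV per parameter array (a
# dim header line, then values in column-major order) and one window CSV per
# masked layer.  Sufficient to reload a model and reproduce forward outputs
# to full double precision.

write_array_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- if (is.null(dim(x))) length(x) else dim(x)
  writeLines(paste0("# dim=", paste(d, collapse = "x")), con)
  writeLines(sprintf("%.17g", as.vector(x)), con)
  invisible(path)
}

read_array_csv <- function(path) {
  lines <- readLines(path)
  d <- as.integer(strsplit(sub("^# dim=", "", lines[1L]), "x")[[1L]])
  vals <- as.numeric(lines[-1L])
  if (length(d) == 1L) vals else array(vals, dim = d)
}

#' Save a network's state as plain text
#'
#' Writes every parameter array (weights, biases, kernels, batchnorm state)
#' and every attached window to CSV files under `dir`, plus a manifest.
#' [load_network()] restores a model whose forward outputs match the saved
#' model to full floating precision.
#'
#' @param model An `sz_network`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_network <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- c(sprintf("config_id=%s", model$config$id),
                sprintf("protocol=%s", model$config$protocol),
                sprintf("n_layers=%d", length(model$layers)),
                sprintf("sz_target_index=%d", model$sz_target_index),
                sprintf("trained=%s", model$trained))
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    manifest <- c(manifest, sprintf("layer%d=%s", i, l$type))
    for (p in c("W", "b", "K", "gamma", "beta", "running_mean",
                "running_var")) {
      if (!is.null(l[[p]])) {
        write_array_csv(l[[p]], file.path(dir, sprintf("layer%d_%s.csv", i, p)))
      }
    }
    if (!is.null(l$window)) {
      write_window_csv(l$window, file.path(dir, sprintf("layer%d_window.csv", i)))
    }
  }
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Restore a network saved by [save_network()]
#'
#' @param model An `sz_network` with the same configuration the state was
#'   saved from (supplies the layer plan; typically `build_network(config)`).
#' @param dir Directory written by [save_network()].
#' @return The model with all saved parameter arrays and windows restored.
#' @export
load_network <- function(model, dir) {
  manifest <- readLines(file.path(dir, "manifest.txt"))
  n_layers <- as.integer(sub("^n_layers=", "",
                             grep("^n_layers=", manifest, value = TRUE)))
  if (n_layers != length(model$layers)) {
    stop(sprintf("saved model has %d layers but the supplied model has %d",
                 n_layers, length(model$layers)))
  }
  for (i in seq_along(model$layers)) {
    for (p in c("W", "b", "K", "gamma", "beta", "running_mean",
                "running_var")) {
      f <- file.path(dir, sprintf("layer%d_%s.csv", i, p))
      if (file.exists(f)) {
        x <- read_array_csv(f)
        if (p %in% c("W", "K") && !is.null(dim(model$layers[[i]][[p]]))) {
          dim(x) <- dim(model$layers[[i]][[p]])
        }
        model$layers[[i]][[p]] <- x
      } else {
        model$layers[[i]][[p]] <- NULL
      }
    }
    wf <- file.path(dir, sprintf("layer%d_window.csv", i))
    if (file.exists(wf)) {
      win <- read_window_csv(wf)
      model$layers[[i]]$window <- win
      model$layers[[i]]$rho <- retained_fraction(win)
      model$layers[[i]]$mask_scaled <- NULL
    }
  }
  model$trained <- any(manifest == "trained=TRUE")
  model
}
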