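# Training, evaluation and the L1 control variant.

#' Train a network
#'
#' Mini-batch training with softmax cross-entropy loss.  Windows on masked
#' layers are constants: they are re-applied on every forward pass, so the
#' gradient at a masked raw weight is exactly zero and masked positions keep
#' their initialization for the whole run.  Training is deterministic given
#' `(seed, dataset, schedule)`.
#'
#' @param model An untrained [build_network()] model.
#' @param dataset A list with elements `train` and `test` (each an
#'   `ImageDataset`, see [make_synthetic()]); `test` is used as the
#'   validation split for the per-epoch trace.
#' @param schedule A [training_schedule()]; defaults to the configuration's
#'   schedule.
#' @param seed Optional seed (overrides `schedule$seed`) controlling
#'   shuffling, dropout and augmentation draws.
#' @param trace_every Record the trace every this many epochs (always
#'   includes the last epoch).
#' @return The fitted `sz_network`, with a `trace` data frame (`epoch`,
#'   `train_error`, `val_error`, `train_loss`).
#' @seealso [evaluate()], [predict.sz_network()]
#' @export
train <- function(model, dataset, schedule = NULL, seed = NULL,
                  trace_every = 1L) {
  if (!inherits(model, "sz_network")) stop("model must be an sz_network")
  schedule <- schedule %||% model$config$schedule
  seed <- seed %||% schedule$seed
  if (!is.null(seed)) set.seed(seed)
  ds_tr <- dataset$train
  ds_va <- dataset$test %||% dataset$val
  if (is.null(ds_tr) || is.null(ds_va)) {
    stop("dataset must have disjoint 'train' and 'test' splits")
  }
  X <- ds_tr$images
  y <- ds_tr$labels
  n <- dim(X)[1L]
  K <- model$config$n_classes
  layers <- prep_layers(model$layers)
  opt <- make_optimizer(schedule$optimizer, lr = schedule$lr,
                        decay = schedule$decay)
  trace <- list()
  for (epoch in seq_len(schedule$epochs)) {
    if (!is.null(schedule$lr_switch_epoch) &&
        epoch == schedule$lr_switch_epoch + 1L) {
      opt$lr <- schedule$lr_after
    }
    ord <- sample.int(n)
    starts <- seq(1L, n, by = schedule$batch_size)
    for (s in starts) {
      ii <- ord[s:min(s + schedule$batch_size - 1L, n)]
      Xb <- X[ii, , , , drop = FALSE]
      if (!is.null(schedule$augment)) {
        Xb <- augment_images(Xb, schedule$augment)
      }
      yb <- y[ii]
      fw <- net_forward(layers, Xb, training = TRUE)
      P <- fw$out
      picked <- P[cbind(seq_along(ii), yb + 1L)]
      loss <- -mean(log(pmax(picked, 1e-12)))
      if (!is.finite(loss)) {
        stop(training_error(epoch, loss))
      }
      Y <- matrix(0, length(ii), K)
      Y[cbind(seq_along(ii), yb + 1L)] <- 1
      dZ <- (P - Y) / length(ii)
      grads <- net_backward(layers, fw$caches, dZ)
      layers <- optimizer_step(opt, layers, grads)
      layers <- update_bn_running(layers, fw$caches)
    }
    if (epoch %% trace_every == 0L || epoch == schedule$epochs) {
      model$layers <- layers
      Ptr <- predict(model, X, type = "prob")
      trace[[length(trace) + 1L]] <- data.frame(
        epoch = epoch,
        train_error = mean((max.col(Ptr, ties.method = "first") - 1L) != y),
        val_error = eval_error(model, ds_va$images, ds_va$labels),
        train_loss = -mean(log(pmax(Ptr[cbind(seq_len(n), y + 1L)], 1e-12))))
    }
  }
  model$layers <- layers
  model$trained <- TRUE
  model$trace <- do.call(rbind, trace)
  model$schedule <- schedule
  model$seed <- seed
  model
}

training_error <- function(epoch, loss) {
  structure(
    class = c("sz_training_error", "error", "condition"),
    list(message = sprintf("training diverged at epoch %d (loss = %g)",
                           epoch, loss),
         call = NULL, epoch = epoch))
}

# Batchnorm running statistics are refreshed from the batch statistics kept
# in the forward caches (momentum update, Keras-style).
update_bn_running <- function(layers, caches) {
  for (l in seq_along(layers)) {
    if (layers[[l]]$type == "batchnorm" && !is.null(caches[[l]]$mu)) {
      m <- layers[[l]]$momentum
      layers[[l]]$running_mean <-
        m * layers[[l]]$running_mean + (1 - m) * caches[[l]]$mu
      layers[[l]]$running_var <-
        m * layers[[l]]$running_var + (1 - m) * caches[[l]]$var
    }
  }
  layers
}

eval_error <- function(model, images, labels, batch = 1024L) {
  pred <- predict(model, images, type = "class", batch = batch)
  mean(pred != labels)
}

#' Classification error on a dataset split
#'
#' `1 - top-1 accuracy`, evaluated deterministically (dropout off, batchnorm
#' in inference mode).
#'
#' @param model A (usually trained) `sz_network`.
#' @param split An `ImageDataset` (list with `images` and `labels`).
#' @return Error fraction in `[0, 1]`.
#' @export
evaluate <- function(model, split) {
  if (is.null(split$images) || is.null(split$labels) ||
      length(split$labels) == 0L) {
    stop("split must be a non-empty ImageDataset")
  }
  eval_error(model, split$images, split$labels)
}

#' Attach an evaluation window to a trained disorganized-protocol model
#'
#' Applies [disorganize()] to the model's target layer: the returned model
#' shares the trained weights, with the window masking the target layer's
#' effective weights at evaluation.  The input model is not modified.
#'
#' @param model A trained `sz_network` built from a disorganized-protocol
#'   configuration (its target layer is bias-free by construction).
#' @param window An `sz_window` matching the target layer's weight shape.
#' @return A new `sz_network` with the window attached.
#' @export
disorganize_model <- function(model, window) {
  ti <- model$sz_target_index
  if (is.na(ti)) stop("model has no evaluation-window target layer")
  lay <- model$layers[[ti]]
  masked <- disorganize(list(W = lay$W, b = lay$b,
                             activation = lay$activation), window)
  model$layers[[ti]]$window <- masked$window
  model$layers[[ti]]$rho <- retained_fraction(window)
  model$layers[[ti]]$b <- NULL
  model
}

#' L1-regularized control variant
#'
#' The conventional-regularization control: replaces the masked top layer of
#' a C-shaped configuration with a plain fully connected layer carrying an L1
#' penalty, and reports its post-training "parameter reduction" as the
#' fraction of weights with `|w| <` `zero_tolerance` (weights below the
#' tolerance are regarded as zero).
#'
#' @param config An [network_config()] with a dense top layer.
#' @param l1_strength Non-negative penalty coefficient.
#' @param zero_tolerance Magnitude below which a trained weight counts as
#'   eliminated (default 1e-4).
#' @return The modified `sz_config`; its attribute `"l1_layer"` names the
#'   penalized layer for [l1_reduction()].
#' @export
l1_variant <- function(config, l1_strength, zero_tolerance = 1e-4) {
  if (l1_strength < 0) stop("l1_strength must be non-negative")
  dense_idx <- which(vapply(config$layers, function(s) s$kind == "dense",
                            logical(1)))
  if (!length(dense_idx)) {
    stop("config has no fully connected top layer to regularize")
  }
  ti <- dense_idx[length(dense_idx)]
  config$layers[[ti]]$sz <- FALSE
  config$layers[[ti]]$sz_target <- FALSE
  config$layers[[ti]]$l1 <- l1_strength
  config$window$reduction <- 0
  attr(config, "l1_layer") <- ti
  attr(config, "zero_tolerance") <- zero_tolerance
  config
}

#' Post-training reduction reported by the L1 control
#'
#' @param model A trained `sz_network` built from an [l1_variant()] config.
#' @param zero_tolerance Magnitude threshold; defaults to the one recorded in
#'   the config.
#' @return Fraction of the penalized layer's weights with magnitude below the
#'   tolerance.
#' @export
l1_reduction <- function(model, zero_tolerance = NULL) {
  tol <- zero_tolerance %||% attr(model$config, "zero_tolerance") %||% 1e-4
  l1_layers <- which(vapply(model$layers, function(l) {
    l$type == "dense" && !is.null(l$l1) && l$l1 > 0
  }, logical(1)))
  if (!length(l1_layers)) {
    # an unpenalized model still has a well-defined report on its top hidden layer
    dense_idx <- which(vapply(model$layers, function(l) l$type == "dense",
                              logical(1)))
    l1_layers <- dense_idx[max(1L, length(dense_idx) - 1L)]
  }
  W <- model$layers[[l1_layers[1L]]]$W
  mean(abs(W) < tol)
}
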