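# Network configurations and model construction.
#
# The reference architectures:
#   A: 28x28 input -> masked dense 512 -> softmax 10 (developmental, MNIST)
#   B: 28x28 input -> FC(width) -> FC(width, bias-free, masked at evaluation)
#      -> softmax 10 (disorganized, MNIST)
#   C: conv32,conv32,pool,conv64,conv64,pool -> dense/masked 512 -> softmax 10
#      (developmental, CIFAR-10)
#   D: as C but the top layer is bias-free and masked only at evaluation
#   E: VGG16 conv stack whose last three conv layers are channel-masked
#      SzConv(512), then dense tops 4096, 4096, 1024 -> softmax 10
# plus reduced-scale presets (A-small, B-small, C-small, E-small) that keep
# the topology and window placement but shrink widths for desk-scale runs.

spec_dense <- function(units, activation = "relu", bias = TRUE, sz = FALSE,
                       sz_target = FALSE, l1 = 0) {
  list(kind = "dense", units = as.integer(units), activation = activation,
       bias = bias, sz = sz, sz_target = sz_target, l1 = l1)
}
spec_conv <- function(filters, kernel = 3L, sz = FALSE) {
  list(kind = "conv", filters = as.integer(filters), kernel = as.integer(kernel),
       sz = sz)
}
spec_maxpool <- function() list(kind = "maxpool")
spec_dropout <- function(rate) list(kind = "dropout", rate = rate)
spec_batchnorm <- function() list(kind = "batchnorm")

#' Reference network configurations and reduced-scale presets
#'
#' Builds a network configuration object: the layer plan, the window
#' placement (in-training for developmental configs, evaluation-only for
#' disorganized configs) and the default training schedule.
#'
#' Full-scale presets `"A"`–`"E"` follow the reference table: A and B are the
#' MNIST dense networks (Adam, learning rate 1e-3, batch 32), C and D the
#' CIFAR-10 convolutional networks (RMSprop, learning rate 1e-4, decay 1e-6,
#' batch 32), and E the VGG16 variant whose last three convolution layers are
#' channel-masked (Adam, 5e-4 dropping to 1e-4 after 150 epochs, batch 200,
#' augmentation on, batch normalization after each convolution and dropout
#' 0.5 after each top dense layer — the regularization placement is this
#' package's default and can be overridden via `custom` configs).
#' Reduced-scale presets `"A-small"` (hidden 32), `"B-small"`,
#' `"C-small"` (8/8/16/16 filters, top 64) and `"E-small"` (one VGG-style
#' block, one masked conv, one masked top) keep the layer topology and window
#' placement at desk scale.
#'
#' @param id Configuration id: `"A"`, `"B"`, `"C"`, `"D"`, `"E"`,
#'   `"A-small"`, `"B-small"`, `"C-small"`, `"E-small"`.
#' @param width Hidden width override (B/D-style equal-width hidden pairs and
#'   the small presets accept it; B's reference range is 64–1024).
#' @param window Window specification for the masked layers: a list with
#'   `family` (see [window_at_reduction()]), `reduction` (eliminated share in
#'   `[0, 1)`) and optionally `n_bands`.
#' @param input_shape Integer `(H, W, C)`; defaults to the preset's dataset
#'   shape (28x28x1 for A/B, 32x32x3 for C/D/E).
#' @param n_classes Number of classes (default 10).
#' @param epochs,batch_size Schedule overrides.
#' @return An object of class `sz_config`.
#' @examples
#' cfg <- network_config("A-small", window = list(family = "diagonal",
#'                                                reduction = 0.5))
#' @export
network_config <- function(id = c("A", "B", "C", "D", "E", "A-small",
                                  "B-small", "C-small", "E-small"),
                           width = NULL, window = list(family = "diagonal",
                                                       reduction = 0),
                           input_shape = NULL, n_classes = 10L,
                           epochs = NULL, batch_size = NULL) {
  id <- match.arg(id)
  window$family <- window$family %||% "diagonal"
  window$reduction <- window$reduction %||% 0
  dense_default <- c(28L, 28L, 1L)
  conv_default <- c(32L, 32L, 3L)
  cfg <- switch(id,
    "A" = list(
      protocol = "developmental", input_shape = dense_default,
      layers = list(spec_dense(512L, sz = TRUE)),
      schedule = training_schedule("adam", lr = 1e-3, batch_size = 32L,
                                   epochs = 50L)),
    "A-small" = list(
      protocol = "developmental", input_shape = dense_default,
      layers = list(spec_dense(width %||% 32L, sz = TRUE)),
      schedule = training_schedule("adam", lr = 1e-3, batch_size = 32L,
                                   epochs = 20L)),
    "B" = ,
    "B-small" = {
      w <- width %||% if (id == "B") 512L else 128L
      list(
        protocol = "disorganized", input_shape = dense_default,
        layers = list(spec_dense(w),
                      spec_dense(w, bias = FALSE, sz_target = TRUE)),
        schedule = training_schedule("adam", lr = 1e-3, batch_size = 32L,
                                     epochs = if (id == "B") 20L else 15L))
    },
    "C" = list(
      protocol = "developmental", input_shape = conv_default,
      layers = list(spec_conv(32L), spec_conv(32L), spec_maxpool(),
                    spec_conv(64L), spec_conv(64L), spec_maxpool(),
                    spec_dense(512L, sz = TRUE)),
      schedule = training_schedule("rmsprop", lr = 1e-4, decay = 1e-6,
                                   batch_size = 32L, epochs = 200L)),
    "C-small" = list(
      protocol = "developmental", input_shape = conv_default,
      layers = list(spec_conv(8L), spec_conv(8L), spec_maxpool(),
                    spec_conv(16L), spec_conv(16L), spec_maxpool(),
                    spec_dense(width %||% 64L, sz = TRUE)),
      schedule = training_schedule("rmsprop", lr = 1e-4, decay = 1e-6,
                                   batch_size = 32L, epochs = 20L)),
    "D" = list(
      protocol = "disorganized", input_shape = conv_default,
      layers = list(spec_conv(32L), spec_conv(32L), spec_maxpool(),
                    spec_conv(64L), spec_conv(64L), spec_maxpool(),
                    spec_dense(512L, bias = FALSE, sz_target = TRUE)),
      schedule = training_schedule("rmsprop", lr = 1e-4, decay = 1e-6,
                                   batch_size = 32L, epochs = 100L)),
    "E" = {
      vgg <- c(64L, 64L, NA, 128L, 128L, NA, 256L, 256L, 256L, NA,
               512L, 512L, NA)
      layers <- list()
      for (f in vgg) {
        layers <- if (is.na(f)) c(layers, list(spec_maxpool()))
        else c(layers, list(spec_conv(f), spec_batchnorm()))
      }
      layers <- c(layers,
                  list(spec_conv(512L, sz = TRUE), spec_batchnorm(),
                       spec_conv(512L, sz = TRUE), spec_batchnorm(),
                       spec_conv(512L, sz = TRUE), spec_batchnorm(),
                       spec_maxpool(),
                       spec_dense(4096L), spec_dropout(0.5),
                       spec_dense(4096L), spec_dropout(0.5),
                       spec_dense(1024L), spec_dropout(0.5)))
      list(protocol = "developmental", input_shape = conv_default,
           layers = layers,
           schedule = training_schedule("adam", lr = 5e-4, batch_size = 200L,
                                        epochs = 200L, lr_switch_epoch = 150L,
                                        lr_after = 1e-4,
                                        augment = list(flip = TRUE,
                                                       shift = 0.1)))
    },
    "E-small" = list(
      protocol = "developmental", input_shape = conv_default,
      layers = list(spec_conv(16L), spec_batchnorm(),
                    spec_conv(16L), spec_batchnorm(), spec_maxpool(),
                    spec_conv(32L, sz = TRUE), spec_batchnorm(),
                    spec_maxpool(),
                    spec_dense(width %||% 64L, sz = TRUE), spec_dropout(0.5)),
      schedule = training_schedule("adam", lr = 5e-4, batch_size = 32L,
                                   epochs = 10L,
                                   augment = list(flip = TRUE, shift = 0.1)))
  )
  if (!is.null(input_shape)) cfg$input_shape <- as.integer(input_shape)
  if (!is.null(epochs)) cfg$schedule$epochs <- as.integer(epochs)
  if (!is.null(batch_size)) cfg$schedule$batch_size <- as.integer(batch_size)
  structure(
    list(id = id, protocol = cfg$protocol, input_shape = cfg$input_shape,
         n_classes = as.integer(n_classes), layers = cfg$layers,
         window = window, schedule = cfg$schedule),
    class = "sz_config")
}

#' Training schedule
#'
#' @param optimizer `"adam"` or `"rmsprop"`.
#' @param lr Learning rate.
#' @param decay Per-step learning-rate decay (RMSprop-style
#'   `lr / (1 + decay * step)`).
#' @param batch_size,epochs Mini-batch size and epoch count.
#' @param lr_switch_epoch,lr_after Optional epoch at which the learning rate
#'   switches to `lr_after`.
#' @param augment Optional augmentation parameters (see [augment_images()]),
#'   applied to each training mini-batch.
#' @param seed Optional seed controlling shuffling, dropout and augmentation.
#' @return An object of class `sz_schedule`.
#' @export
training_schedule <- function(optimizer = c("adam", "rmsprop"), lr = 1e-3,
                              decay = 0, batch_size = 32L, epochs = 10L,
                              lr_switch_epoch = NULL, lr_after = NULL,
                              augment = NULL, seed = NULL) {
  optimizer <- match.arg(optimizer)
  stopifnot(lr > 0, decay >= 0, batch_size >= 1, epochs >= 1)
  structure(list(optimizer = optimizer, lr = lr, decay = decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 lr_switch_epoch = lr_switch_epoch, lr_after = lr_after,
                 augment = augment, seed = seed),
            class = "sz_schedule")
}

#' @export
print.sz_config <- function(x, ...) {
  cat(sprintf("network config %s (%s protocol), input %s, %d classes\n",
              x$id, x$protocol, paste(x$input_shape, collapse = "x"),
              x$n_classes))
  for (sp in x$layers) {
    cat(" -", switch(sp$kind,
      dense = sprintf("dense(%d)%s%s%s", sp$units,
                      if (sp$sz) " [windowed]" else "",
                      if (sp$sz_target) " [windowed at evaluation, bias-free]" else "",
                      if (sp$l1 > 0) sprintf(" [L1 %.g]", sp$l1) else ""),
      conv = sprintf("conv(%d, %dx%d)%s", sp$filters, sp$kernel, sp$kernel,
                     if (sp$sz) " [channel-windowed]" else ""),
      maxpool = "maxpool(2x2)", dropout = sprintf("dropout(%.2f)", sp$rate),
      batchnorm = "batchnorm"), "\n")
  }
  cat(sprintf(" - output dense(%d), softmax\n", x$n_classes))
  cat(sprintf("window: %s, reduction %.3f; schedule: %s lr %g, batch %d, %d epochs\n",
              x$window$family, x$window$reduction, x$schedule$optimizer,
              x$schedule$lr, x$schedule$batch_size, x$schedule$epochs))
  invisible(x)
}

he_init <- function(fan_in, n) {
  stats::rnorm(n, sd = sqrt(2 / fan_in))
}

#' Build a network from a configuration
#'
#' Instantiates the model: He-initialized weights (full fan-in; the window's
#' `1/rho` renormalization compensates the scale of masked layers), zero
#' biases where the layer has one, ReLU hidden activations, softmax output.
#' For developmental configs the windows of masked layers are constructed
#' here (at the configured reduction); for disorganized configs the target
#' layer is built bias-free and unmasked, and the window is attached at
#' evaluation time by [disorganize_model()].
#'
#' @param config An [network_config()].
#' @param seed Optional integer seed for the weight initialization (and the
#'   random-family window draw).
#' @return An object of class `sz_network`.
#' @export
build_network <- function(config, seed = NULL) {
  if (!inherits(config, "sz_config")) stop("config must be an sz_config")
  if (!is.null(seed)) set.seed(seed)
  shape <- config$input_shape
  layers <- list()
  cur <- shape  # (H, W, C) or flat length
  flat <- FALSE
  sz_target_index <- NA_integer_
  add_flatten <- function() {
    layers[[length(layers) + 1L]] <<- list(type = "flatten")
    cur <<- prod(cur)
    flat <<- TRUE
  }
  for (sp in config$layers) {
    if (sp$kind == "dense" && !flat) add_flatten()
    switch(sp$kind,
      dense = {
        n_in <- cur
        n_out <- sp$units
        win <- NULL
        rho <- 1
        if (sp$sz && config$window$reduction > 0) {
          win <- window_at_reduction(node_geometry(n_in, n_out),
                                     family = config$window$family,
                                     reduction = config$window$reduction,
                                     n_bands = config$window$n_bands %||% 2L)
          rho <- retained_fraction(win)
        }
        layers[[length(layers) + 1L]] <- list(
          type = "dense",
          W = matrix(he_init(n_in, n_in * n_out), n_in, n_out),
          b = if (sp$bias) numeric(n_out) else NULL,
          window = win, rho = rho, activation = sp$activation,
          l1 = sp$l1)
        if (sp$sz_target) sz_target_index <- length(layers)
        cur <- n_out
      },
      conv = {
        cin <- cur[3L]
        cout <- sp$filters
        k <- sp$kernel
        win <- NULL
        rho <- 1
        if (sp$sz && config$window$reduction > 0) {
          win <- window_at_reduction(node_geometry(cin, cout),
                                     family = config$window$family,
                                     reduction = config$window$reduction,
                                     n_bands = config$window$n_bands %||% 2L)
          rho <- retained_fraction(win)
        }
        layers[[length(layers) + 1L]] <- list(
          type = "conv",
          K = array(he_init(k * k * cin, k * k * cin * cout),
                    c(k, k, cin, cout)),
          b = numeric(cout), window = win, rho = rho, activation = "relu")
        cur <- c(cur[1:2], cout)
      },
      maxpool = {
        layers[[length(layers) + 1L]] <- list(type = "maxpool")
        cur <- c(cur[1:2] %/% 2L, cur[3L])
      },
      dropout = {
        layers[[length(layers) + 1L]] <- list(type = "dropout", rate = sp$rate)
      },
      batchnorm = {
        C <- if (flat) cur else cur[3L]
        layers[[length(layers) + 1L]] <- list(
          type = "batchnorm", gamma = rep(1, C), beta = numeric(C),
          running_mean = numeric(C), running_var = rep(1, C),
          momentum = 0.99, eps = 1e-3)
      })
  }
  if (!flat) add_flatten()
  n_in <- cur
  layers[[length(layers) + 1L]] <- list(
    type = "dense",
    W = matrix(he_init(n_in, n_in * config$n_classes), n_in, config$n_classes),
    b = numeric(config$n_classes), window = NULL, rho = 1,
    activation = "softmax", l1 = 0)
  structure(list(config = config, layers = layers,
                 sz_target_index = sz_target_index,
                 trained = FALSE, trace = NULL),
            class = "sz_network")
}

#' Number of trainable parameters in a model
#'
#' Counts raw stored parameters; masking does not delete storage, so a
#' windowed layer counts the same as its fully connected counterpart.
#'
#' @param model An `sz_network`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(model$layers, function(l) {
    length(l$W) + length(l$b) + length(l$K) +
      length(l$gamma) + length(l$beta)
  }, numeric(1)))
}

#' @export
print.sz_network <- function(x, ...) {
  cat(sprintf("sz_network (config %s, %s), %d layers, %s parameters%s\n",
              x$config$id, x$config$protocol, length(x$layers),
              format(count_params(x), big.mark = ","),
              if (x$trained) ", trained" else ", untrained"))
  invisible(x)
}

#' @export
summary.sz_network <- function(object, ...) {
  print(object)
  for (l in object$layers) {
    desc <- switch(l$type,
      flatten = "flatten",
      dense = sprintf("dense %d -> %d (%s)%s", nrow(l$W), ncol(l$W),
                      l$activation,
                      if (!is.null(l$window))
                        sprintf(", %s window reduction %.1f%%",
                                attr(l$window, "family"), 100 * (1 - l$rho))
                      else ""),
      conv = sprintf("conv %dx%dx%d -> %d%s", dim(l$K)[1L], dim(l$K)[2L],
                     dim(l$K)[3L], dim(l$K)[4L],
                     if (!is.null(l$window))
                       sprintf(", channel window reduction %.1f%%",
                               100 * (1 - l$rho))
                     else ""),
      maxpool = "maxpool 2x2", dropout = sprintf("dropout %.2f", l$rate),
      batchnorm = sprintf("batchnorm (%d channels)", length(l$gamma)))
    cat(" *", desc, "\n")
  }
  if (!is.null(object$trace)) {
    tr <- object$trace
    cat(sprintf("trained %d epochs: final train error %.4f, validation error %.4f (min %.4f at epoch %d)\n",
                nrow(tr), tr$train_error[nrow(tr)], tr$val_error[nrow(tr)],
                min(tr$val_error), which.min(tr$val_error)))
  }
  invisible(object)
}

#' @export
coef.sz_network <- function(object, ...) {
  out <- list()
  for (i in seq_along(object$layers)) {
    l <- object$layers[[i]]
    if (l$type %in% c("dense", "conv")) {
      out[[sprintf("layer%d_%s", i, l$type)]] <-
        list(weights = l$W %||% l$K, bias = l$b,
             window = l$window)
    }
  }
  out
}

#' Predicted class probabilities or labels
#'
#' @param object A trained (or untrained) `sz_network`.
#' @param newdata An image array `N x H x W x C` (or matrix of flattened
#'   inputs for dense configs), or an `ImageDataset`.
#' @param type `"prob"` for the softmax probabilities, `"class"` for 0-based
#'   predicted labels.
#' @param batch Chunk size used to bound memory.
#' @param ... Unused.
#' @return `N x K` probability matrix or integer vector of labels.
#' @export
predict.sz_network <- function(object, newdata, type = c("prob", "class"),
                               batch = 512L, ...) {
  type <- match.arg(type)
  X <- if (is.list(newdata) && !is.null(newdata$images)) newdata$images
       else newdata
  n <- if (is.null(dim(X))) 1L else dim(X)[1L]
  K <- object$config$n_classes
  out <- matrix(NA_real_, n, K)
  idx <- split(seq_len(n), ceiling(seq_len(n) / batch))
  for (ii in idx) {
    Xi <- if (length(dim(X)) == 4L) X[ii, , , , drop = FALSE]
          else X[ii, , drop = FALSE]
    out[ii, ] <- net_forward(object$layers, Xi, training = FALSE)$out
  }
  if (type == "prob") out else max.col(out, ties.method = "first") - 1L
}

#' Plot training progress
#'
#' Training and validation error per epoch, the standard view for spotting
#' overfitting (validation error turning up while training error keeps
#' falling).
#'
#' @param x A trained `sz_network`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.sz_network <- function(x, ...) {
  if (is.null(x$trace)) stop("model has no training trace; call train() first")
  tr <- x$trace
  graphics::matplot(tr$epoch, cbind(tr$train_error, tr$val_error),
                    type = "l", lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "classification error", ...)
  graphics::legend("topright", c("train", "validation"),
                   col = c("black", "red"), lty = 1, bty = "n")
  invisible(x)
}
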