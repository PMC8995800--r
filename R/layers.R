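# Masked dense and channel-masked convolution layers.
#
# A masked ("schizophrenia connection") layer keeps a raw trainable weight
# matrix W and a fixed window F.  On every forward pass the effective weights
# (W * F) / rho are used, where rho = retained_fraction(F); the 1/rho
# normalization keeps the sum of weights unchanged in expectation.  Because
# masking is applied at use time, gradients at masked positions are exactly
# zero and the raw storage is never destroyed.

#' Effective (masked, renormalized) weights
#'
#' Element-wise product of the raw weights with the window, divided by the
#' window's retained fraction `rho` so that the overall weight sum is
#' preserved: `(W * F) / rho`.
#'
#' @param W Raw weight matrix (or array).
#' @param window An `sz_window` (or matrix in `[0,1]`) of the same shape as
#'   `W`.
#' @return Matrix of effective weights; exactly 0 wherever the window is 0.
#' @examples
#' W <- matrix(c(2, 6, 4, 8), 2, 2)
#' F <- matrix(c(1, 0, 0, 1), 2, 2)
#' effective_weights(W, F)  # [[4, 0], [0, 16]]
#' @export
effective_weights <- function(W, window) {
  if (!identical(dim(W), dim(unclass(window)))) {
    stop(sprintf("shape mismatch: weights are %s but window is %s",
                 paste(dim(W), collapse = "x"),
                 paste(dim(unclass(window)), collapse = "x")))
  }
  rho <- retained_fraction(window)
  if (rho <= 0) stop("invalid window: retained fraction must be positive")
  strip_attrs((W * unclass(window)) / rho)
}

activation_fun <- function(name) {
  switch(name,
    linear = identity,
    relu = function(z) pmax(z, 0),
    softmax = function(z) {
      z <- z - apply(z, 1L, max)
      e <- exp(z)
      e / rowSums(e)
    },
    stop("unknown activation: ", name)
  )
}

#' Masked dense layer
#'
#' A fully connected layer whose weights are masked by a fixed window — the
#' "schizophrenia connection layer".  In `developmental` mode the window is
#' present throughout training; in `disorganized` mode it is attached to an
#' already-trained layer, which by the bias rule carries no bias (a bias
#' cannot be adjusted for the inter-node distance after training).
#'
#' @param W Raw weight matrix, `n_in x n_out`.
#' @param window An `sz_window` of the same shape (default full window).
#' @param b Bias vector of length `n_out`, or `NULL` for none.
#' @param mode `"developmental"` or `"disorganized"`.
#' @param activation `"relu"`, `"softmax"` or `"linear"`.
#' @return An object of class `sz_dense`.
#' @export
sz_dense_layer <- function(W, window = NULL, b = NULL,
                           mode = c("developmental", "disorganized"),
                           activation = c("linear", "relu", "softmax")) {
  mode <- match.arg(mode)
  activation <- match.arg(activation)
  W <- as.matrix(W)
  if (is.null(window)) window <- full_window(node_geometry(nrow(W), ncol(W)))
  if (!identical(dim(W), dim(unclass(window)))) {
    stop("window shape must equal weight shape")
  }
  if (!is.null(b)) {
    if (mode == "disorganized") {
      stop("disorganized-mode layers carry no bias")
    }
    if (length(b) != ncol(W)) stop("bias length must equal n_out")
  }
  structure(list(W = W, b = b, window = window, mode = mode,
                 activation = activation),
            class = "sz_dense")
}

#' @export
print.sz_dense <- function(x, ...) {
  cat(sprintf(
    "masked dense layer %d -> %d (%s, %s activation, %s window, reduction %.1f%%, bias %s)\n",
    nrow(x$W), ncol(x$W), x$mode, x$activation, attr(x$window, "family"),
    100 * (1 - retained_fraction(x$window)),
    if (is.null(x$b)) "absent" else "present"))
  invisible(x)
}

#' Forward pass through a masked dense layer
#'
#' `y = activation(x %*% effective_weights(W, F) + b)`, the bias term omitted
#' when the layer has none.
#'
#' @param x Input vector of length `n_in`, or a batch matrix `n x n_in`.
#' @param layer An [sz_dense_layer()].
#' @return Output vector of length `n_out` (or batch matrix `n x n_out`).
#' @export
sz_dense_forward <- function(x, layer) {
  vec_in <- is.null(dim(x))
  x <- if (vec_in) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(x) != nrow(layer$W)) {
    stop(sprintf("input length %d does not match layer n_in %d",
                 ncol(x), nrow(layer$W)))
  }
  z <- x %*% effective_weights(layer$W, layer$window)
  if (!is.null(layer$b)) z <- sweep(z, 2L, layer$b, `+`)
  y <- activation_fun(layer$activation)(z)
  if (vec_in) drop(y) else y
}

#' Masked convolution layer (channel-wise window)
#'
#' A convolution layer whose kernel is masked along the input-channel x
#' output-channel dimensions only — the "schizophrenia convolution layer".
#' The same `c_in x c_out` window applies identically at every spatial kernel
#' position, i.e. the band matrix is defined along the channel dimensions but
#' not along the image dimensions.
#'
#' @param K Kernel array `k_h x k_w x c_in x c_out`.
#' @param channel_window An `sz_window` of shape `c_in x c_out`.
#' @param b Bias of length `c_out`, or `NULL`.
#' @param mode,activation As for [sz_dense_layer()].
#' @return An object of class `sz_conv`.
#' @export
sz_conv_layer <- function(K, channel_window = NULL, b = NULL,
                          mode = c("developmental", "disorganized"),
                          activation = c("linear", "relu")) {
  mode <- match.arg(mode)
  activation <- match.arg(activation)
  dk <- dim(K)
  if (length(dk) != 4L) stop("kernel must be a 4-d array (kh, kw, c_in, c_out)")
  if (is.null(channel_window)) {
    channel_window <- full_window(node_geometry(dk[3L], dk[4L]))
  }
  if (!identical(dim(unclass(channel_window)), dk[3:4])) {
    stop("channel window shape must be (c_in, c_out)")
  }
  if (!is.null(b)) {
    if (mode == "disorganized") stop("disorganized-mode layers carry no bias")
    if (length(b) != dk[4L]) stop("bias length must equal c_out")
  }
  structure(list(K = K, b = b, window = channel_window, mode = mode,
                 activation = activation),
            class = "sz_conv")
}

#' Effective (channel-masked, renormalized) convolution kernel
#'
#' `K'[h, w, ci, co] = K[h, w, ci, co] * F[ci, co] / rho` for every spatial
#' position `(h, w)`, with `rho` the window's retained fraction.  The zero
#' pattern is therefore constant across the spatial extent of the kernel.
#'
#' @param K Kernel array `k_h x k_w x c_in x c_out`.
#' @param channel_window An `sz_window` of shape `c_in x c_out`.
#' @return Masked, renormalized kernel of the same shape as `K`.
#' @export
sz_conv_effective_kernel <- function(K, channel_window) {
  dk <- dim(K)
  if (length(dk) != 4L) stop("kernel must be a 4-d array (kh, kw, c_in, c_out)")
  fw <- unclass(channel_window)
  if (!identical(dim(fw), dk[3:4])) {
    stop(sprintf("shape mismatch: kernel channels are %dx%d but window is %s",
                 dk[3L], dk[4L], paste(dim(fw), collapse = "x")))
  }
  rho <- retained_fraction(channel_window)
  if (rho <= 0) stop("invalid window: retained fraction must be positive")
  strip_attrs(K * array(rep(as.vector(fw), each = dk[1L] * dk[2L]),
                        dim = dk) / rho)
}

#' Convert a trained dense layer to a disorganized masked layer
#'
#' The post-training intervention: the network is trained without any window
#' and the window is attached only for evaluation, leaving the trained
#' weights untouched.  The returned layer shares the trained weight matrix,
#' carries the window, and has no bias (per the bias rule the target layer is
#' built bias-free from the start, since a bias cannot be modified according
#' to the inter-node distance after training).
#'
#' @param layer A trained [sz_dense_layer()] (full window) or any object with
#'   a weight matrix `W`; a bias, if present, is dropped with a warning.
#' @param window The `sz_window` to attach; must match the weight shape and
#'   retain at least one weight.
#' @return A new `sz_dense` layer in `disorganized` mode.
#' @export
disorganize <- function(layer, window) {
  W <- if (is.list(layer)) layer$W else layer
  if (is.null(W)) stop("layer has no weight matrix W")
  if (!identical(dim(W), dim(unclass(window)))) {
    stop("window shape must equal the trained weight shape")
  }
  if (sum(unclass(window)) <= 0) {
    stop("invalid window: would zero all weights")
  }
  if (is.list(layer) && !is.null(layer$b) && any(layer$b != 0)) {
    warning("dropping a trained bias: disorganized-mode layers carry no bias")
  }
  activation <- if (is.list(layer) && !is.null(layer$activation)) {
    layer$activation
  } else "linear"
  sz_dense_layer(W, window = window, b = NULL, mode = "disorganized",
                 activation = activation)
}
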