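# Internal forward/backward engine.
#
# Models are lists of layer states (dense, conv, maxpool, flatten, dropout,
# batchnorm).  Dense and conv layers may carry a weight window; the window is
# a constant applied on every forward pass, so the chain rule makes the
# gradient at masked raw positions exactly zero and masked raw weights never
# move during training.  Convolutions are stride-1, odd-kernel, "same"
# padding, computed as a sum of shifted-slice matrix products.

relu_grad <- function(z) (z > 0) * 1

# drop everything but dim (window attributes would otherwise ride along
# through element-wise arithmetic)
strip_attrs <- function(x) {
  d <- dim(x)
  attributes(x) <- NULL
  dim(x) <- d
  x
}

# F / rho, expanded to the parameter's shape; cached on the layer by
# prep_layers() so the per-step masking is a single element-wise product.
scaled_mask <- function(lay) {
  if (!is.null(lay$mask_scaled)) return(lay$mask_scaled)
  if (is.null(lay$window)) return(NULL)
  if (lay$type == "dense") {
    strip_attrs(unclass(lay$window) / lay$rho)
  } else {
    dk <- dim(lay$K)
    array(rep(as.vector(unclass(lay$window)), each = dk[1L] * dk[2L]),
          dim = dk) / lay$rho
  }
}

prep_layers <- function(layers) {
  lapply(layers, function(l) {
    for (p in c("W", "b", "K", "gamma", "beta",
                "running_mean", "running_var")) {
      if (!is.null(l[[p]])) l[[p]] <- l[[p]] + 0  # private, mutable buffer
    }
    if (!is.null(l$window)) l$mask_scaled <- scaled_mask(l)
    l
  })
}

eff_dense_W <- function(lay) {
  if (is.null(lay$window)) lay$W else lay$W * scaled_mask(lay)
}

eff_conv_K <- function(lay) {
  if (is.null(lay$window)) lay$K else lay$K * scaled_mask(lay)
}

layer_forward <- function(lay, X, training) {
  switch(lay$type,
    flatten = {
      d <- dim(X)
      if (length(d) > 2L) {
        cache <- list(dims = d)
        dim(X) <- c(d[1L], prod(d[-1L]))
        list(out = X, cache = cache)
      } else {
        list(out = X, cache = list(dims = NULL))
      }
    },
    dense = {
      Weff <- eff_dense_W(lay)
      Z <- X %*% Weff
      if (!is.null(lay$b)) Z <- sweep(Z, 2L, lay$b, `+`)
      A <- switch(lay$activation,
        linear = Z,
        relu = pmax(Z, 0),
        softmax = {
          Zs <- Z - apply(Z, 1L, max)
          E <- exp(Zs)
          E / rowSums(E)
        })
      list(out = A, cache = list(X = X, Z = Z, Weff = Weff))
    },
    conv = {
      res <- conv_forward(X, eff_conv_K(lay), lay$b)
      Z <- res$Z
      A <- if (lay$activation == "relu") pmax(Z, 0) else Z
      list(out = A, cache = list(Xp = res$Xp, Z = Z))
    },
    maxpool = maxpool_forward(X),
    dropout = {
      if (training && lay$rate > 0) {
        keep <- (stats::runif(length(X)) >= lay$rate) / (1 - lay$rate)
        dim(keep) <- dim(X)
        list(out = X * keep, cache = list(mask = keep))
      } else {
        list(out = X, cache = list(mask = NULL))
      }
    },
    batchnorm = batchnorm_forward(lay, X, training),
    stop("unknown layer type: ", lay$type)
  )
}

conv_forward <- function(X, K, b) {
  dk <- dim(K)
  kh <- dk[1L]; kw <- dk[2L]; cin <- dk[3L]; cout <- dk[4L]
  dx <- dim(X)
  N <- dx[1L]; H <- dx[2L]; W <- dx[3L]
  ph <- (kh - 1L) %/% 2L
  pw <- (kw - 1L) %/% 2L
  Xp <- array(0, c(N, H + 2L * ph, W + 2L * pw, cin))
  Xp[, ph + seq_len(H), pw + seq_len(W), ] <- X
  Zf <- matrix(0, N * H * W, cout)
  for (dh in seq_len(kh)) {
    for (dw in seq_len(kw)) {
      Xs <- Xp[, dh + 0:(H - 1L), dw + 0:(W - 1L), , drop = FALSE]
      dim(Xs) <- c(N * H * W, cin)
      Zf <- Zf + Xs %*% matrix(K[dh, dw, , ], cin, cout)
    }
  }
  if (!is.null(b)) Zf <- sweep(Zf, 2L, b, `+`)
  dim(Zf) <- c(N, H, W, cout)
  list(Z = Zf, Xp = Xp)
}

conv_backward <- function(lay, dZ, cache) {
  K <- eff_conv_K(lay)
  dk <- dim(K)
  kh <- dk[1L]; kw <- dk[2L]; cin <- dk[3L]; cout <- dk[4L]
  Xp <- cache$Xp
  d <- dim(dZ)
  N <- d[1L]; H <- d[2L]; W <- d[3L]
  dZf <- dZ
  dim(dZf) <- c(N * H * W, cout)
  dKeff <- array(0, dk)
  dXp <- array(0, dim(Xp))
  for (dh in seq_len(kh)) {
    for (dw in seq_len(kw)) {
      Xs <- Xp[, dh + 0:(H - 1L), dw + 0:(W - 1L), , drop = FALSE]
      dim(Xs) <- c(N * H * W, cin)
      dKeff[dh, dw, , ] <- crossprod(Xs, dZf)
      dXs <- tcrossprod(dZf, matrix(K[dh, dw, , ], cin, cout))
      dim(dXs) <- c(N, H, W, cin)
      dXp[, dh + 0:(H - 1L), dw + 0:(W - 1L), ] <-
        dXp[, dh + 0:(H - 1L), dw + 0:(W - 1L), , drop = FALSE] + dXs
    }
  }
  dK <- if (is.null(lay$window)) dKeff else dKeff * scaled_mask(lay)
  grads <- list(K = dK)
  if (!is.null(lay$b)) grads$b <- colSums(dZf)
  ph <- (kh - 1L) %/% 2L
  pw <- (kw - 1L) %/% 2L
  dX <- dXp[, ph + seq_len(H), pw + seq_len(W), , drop = FALSE]
  list(dX = dX, grads = grads)
}

maxpool_forward <- function(X) {
  d <- dim(X)
  N <- d[1L]; H <- d[2L]; W <- d[3L]; C <- d[4L]
  if (H %% 2L || W %% 2L) stop("maxpool requires even spatial dimensions")
  i1 <- seq(1L, H, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, W, 2L); j2 <- j1 + 1L
  x11 <- X[, i1, j1, , drop = FALSE]
  x12 <- X[, i1, j2, , drop = FALSE]
  x21 <- X[, i2, j1, , drop = FALSE]
  x22 <- X[, i2, j2, , drop = FALSE]
  M <- pmax(x11, x12, x21, x22)
  list(out = M, cache = list(x11 = x11, x12 = x12, x21 = x21, x22 = x22,
                             M = M, in_dim = d))
}

maxpool_backward <- function(dOut, cache) {
  d <- cache$in_dim
  H <- d[2L]; W <- d[3L]
  i1 <- seq(1L, H, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, W, 2L); j2 <- j1 + 1L
  dX <- array(0, d)
  taken <- array(FALSE, dim(cache$M))
  for (q in list(list(cache$x11, i1, j1), list(cache$x12, i1, j2),
                 list(cache$x21, i2, j1), list(cache$x22, i2, j2))) {
    sel <- (q[[1L]] == cache$M) & !taken
    dX[, q[[2L]], q[[3L]], ] <- dOut * sel
    taken <- taken | sel
  }
  dX
}

batchnorm_forward <- function(lay, X, training) {
  d <- dim(X)
  C <- d[length(d)]
  Xf <- X
  dim(Xf) <- c(prod(d[-length(d)]), C)
  if (training) {
    mu <- colMeans(Xf)
    xc <- sweep(Xf, 2L, mu)
    v <- colMeans(xc^2)
  } else {
    mu <- lay$running_mean
    xc <- sweep(Xf, 2L, mu)
    v <- lay$running_var
  }
  inv <- 1 / sqrt(v + lay$eps)
  xhat <- sweep(xc, 2L, inv, `*`)
  Y <- sweep(sweep(xhat, 2L, lay$gamma, `*`), 2L, lay$beta, `+`)
  dim(Y) <- d
  cache <- if (training) list(xhat = xhat, inv = inv, dims = d,
                              mu = mu, var = v) else list(dims = d)
  list(out = Y, cache = cache)
}

batchnorm_backward <- function(lay, dOut, cache) {
  d <- cache$dims
  C <- d[length(d)]
  m <- prod(d[-length(d)])
  dYf <- dOut
  dim(dYf) <- c(m, C)
  dgamma <- colSums(dYf * cache$xhat)
  dbeta <- colSums(dYf)
  dxhat <- sweep(dYf, 2L, lay$gamma, `*`)
  # dX = inv/m * (m*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dXf <- sweep(m * dxhat, 2L, s1) - sweep(cache$xhat, 2L, s2, `*`)
  dXf <- sweep(dXf, 2L, cache$inv / m, `*`)
  dim(dXf) <- d
  list(dX = dXf, grads = list(gamma = dgamma, beta = dbeta))
}

layer_backward <- function(lay, grad, cache, is_output) {
  switch(lay$type,
    flatten = {
      if (!is.null(cache$dims)) dim(grad) <- cache$dims
      list(dX = grad, grads = NULL)
    },
    dense = {
      dZ <- if (is_output) grad else switch(lay$activation,
        linear = grad,
        relu = grad * relu_grad(cache$Z),
        softmax = stop("softmax is only supported at the output layer"))
      dW <- crossprod(cache$X, dZ)
      if (!is.null(lay$window)) dW <- dW * scaled_mask(lay)
      if (!is.null(lay$l1) && lay$l1 > 0) dW <- dW + lay$l1 * sign(lay$W)
      grads <- list(W = dW)
      if (!is.null(lay$b)) grads$b <- colSums(dZ)
      list(dX = tcrossprod(dZ, cache$Weff), grads = grads)
    },
    conv = {
      dZ <- if (lay$activation == "relu") grad * relu_grad(cache$Z) else grad
      conv_backward(lay, dZ, cache)
    },
    maxpool = list(dX = maxpool_backward(grad, cache), grads = NULL),
    dropout = {
      if (is.null(cache$mask)) list(dX = grad, grads = NULL)
      else list(dX = grad * cache$mask, grads = NULL)
    },
    batchnorm = batchnorm_backward(lay, grad, cache)
  )
}

net_forward <- function(layers, X, training = FALSE) {
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    res <- layer_forward(layers[[l]], X, training)
    X <- res$out
    caches[[l]] <- res$cache
  }
  list(out = X, caches = caches)
}

# grad_out is the gradient w.r.t. the output layer's pre-activation (the
# softmax/cross-entropy shortcut).  Returns per-layer parameter gradients.
net_backward <- function(layers, caches, grad_out) {
  n <- length(layers)
  grads <- vector("list", n)
  grad <- grad_out
  for (l in rev(seq_len(n))) {
    res <- layer_backward(layers[[l]], grad, caches[[l]], is_output = (l == n))
    grads[l] <- list(res$grads)  # plain [[<- would drop NULL entries
    grad <- res$dX
  }
  grads
}

# Optimizer state lives in an environment and the parameter/state buffers are
# updated in place by the compiled kernels (the training loop holds private
# copies of all trainable arrays, made by prep_layers()).
make_optimizer <- function(name = c("adam", "rmsprop"), lr, decay = 0,
                           beta1 = 0.9, beta2 = 0.999, rho = 0.9,
                           eps = 1e-7) {
  name <- match.arg(name)
  opt <- new.env(parent = emptyenv())
  opt$name <- name
  opt$lr <- lr
  opt$decay <- decay
  opt$beta1 <- beta1
  opt$beta2 <- beta2
  opt$rho <- rho
  opt$eps <- eps
  opt$t <- 0L
  opt$state <- new.env(parent = emptyenv())
  opt
}

optimizer_step <- function(opt, layers, grads) {
  opt$t <- opt$t + 1L
  lr <- if (opt$decay > 0) opt$lr / (1 + opt$decay * (opt$t - 1L)) else opt$lr
  for (l in seq_along(layers)) {
    g <- grads[[l]]
    if (is.null(g)) next
    for (p in names(g)) {
      key <- paste0(l, ".", p)
      gv <- g[[p]]
      if (opt$name == "adam") {
        st <- opt$state[[key]]
        if (is.null(st)) {
          st <- list(m = 0 * gv, v = 0 * gv)
          opt$state[[key]] <- st
        }
        adam_step_inplace(layers[[l]][[p]], st$m, st$v, gv, lr,
                          opt$beta1, opt$beta2, opt$eps, opt$t)
      } else {
        st <- opt$state[[key]]
        if (is.null(st)) {
          st <- list(a = 0 * gv)
          opt$state[[key]] <- st
        }
        rmsprop_step_inplace(layers[[l]][[p]], st$a, gv, lr, opt$rho, opt$eps)
      }
    }
  }
  layers
}
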