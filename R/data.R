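# Dataset readers, the synthetic generator and augmentation.
#
# Readers cover the two formats the reference image-classification tasks are
# distributed in: IDX (MNIST) and the CIFAR-10 binary batch format.  They
# look only at local files and never download; the synthetic generator
# provides a download-free stand-in task with the same shapes.

#' Image dataset container
#'
#' @param images `N x H x W x C` array with values in `[0, 1]`.
#' @param labels Integer vector of length `N`, values in `[0, K)`.
#' @param split `"train"` or `"test"`.
#' @param provenance Free-form origin tag (`"mnist"`, `"cifar10"`,
#'   `"synthetic"`, ...).
#' @return A list of class `ImageDataset`.
#' @export
image_dataset <- function(images, labels, split = "train",
                          provenance = "unknown") {
  if (length(dim(images)) == 3L) {
    dim(images) <- c(dim(images), 1L)
  }
  if (length(dim(images)) != 4L) {
    stop("images must be an N x H x W x C array")
  }
  if (dim(images)[1L] != length(labels)) {
    stop(sprintf("image count %d does not match label count %d",
                 dim(images)[1L], length(labels)))
  }
  if (any(images < 0 | images > 1)) stop("image values must lie in [0, 1]")
  if (any(labels < 0 | labels != round(labels))) {
    stop("labels must be non-negative integers")
  }
  structure(list(images = images, labels = as.integer(labels),
                 split = split, provenance = provenance),
            class = "ImageDataset")
}

#' @export
print.ImageDataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("ImageDataset (%s, %s split): %d images %dx%dx%d, %d classes\n",
              x$provenance, x$split, d[1L], d[2L], d[3L], d[4L],
              length(unique(x$labels))))
  invisible(x)
}

read_be_int <- function(con, n = 1L) {
  readBin(con, "integer", n = n, size = 4L, endian = "big")
}

#' Read an IDX-format array (the MNIST distribution format)
#'
#' IDX stores a big-endian header (magic number encoding the element type and
#' rank, then one 32-bit size per dimension) followed by the elements in
#' row-major order.  Unsigned-byte image tensors (magic 2051 and friends) are
#' rescaled to `[0, 1]`; 1-d label vectors (magic 2049) are returned as
#' integers.
#'
#' @param path Path to an IDX file.
#' @return Numeric array with the header's dimensions (images), or an integer
#'   vector (labels).
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (length(magic) < 4L || magic[1L] != 0 || magic[2L] != 0) {
    stop(sprintf("bad IDX magic number: found 0x%s",
                 paste(format(magic), collapse = "")))
  }
  dtype <- as.integer(magic[3L])
  ndim <- as.integer(magic[4L])
  if (dtype != 0x08L) {
    stop(sprintf("unsupported IDX element type 0x%02x (only unsigned byte is supported)",
                 dtype))
  }
  dims <- read_be_int(con, ndim)
  n <- prod(dims)
  payload <- readBin(con, "raw", n = n)
  if (length(payload) < n) {
    stop(sprintf("truncated IDX payload: expected %d bytes, found %d",
                 n, length(payload)))
  }
  vals <- as.integer(payload)
  if (ndim == 1L) return(vals)
  # file is row-major (last index fastest); R arrays are column-major
  a <- array(vals, dim = rev(dims))
  a <- aperm(a, rev(seq_len(ndim)))
  a / 255
}

#' Write an array in IDX format
#'
#' Inverse of [read_idx()]: numeric arrays in `[0, 1]` are scaled back to
#' bytes; integer vectors are written as unsigned-byte label files.  A file
#' read with [read_idx()] and written back is byte-identical.
#'
#' @param x Array (values in `[0, 1]`) or integer vector (values in 0–255).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_idx <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  dims <- if (is.null(dim(x))) length(x) else dim(x)
  ndim <- length(dims)
  writeBin(as.raw(c(0L, 0L, 0x08L, ndim)), con)
  writeBin(as.integer(dims), con, size = 4L, endian = "big")
  if (ndim == 1L) {
    bytes <- as.integer(x)
  } else {
    bytes <- as.integer(round(aperm(x, rev(seq_len(ndim))) * 255))
  }
  if (any(bytes < 0 | bytes > 255)) stop("values out of unsigned-byte range")
  writeBin(as.raw(bytes), con)
  invisible(path)
}

#' Read CIFAR-10 binary batch files
#'
#' The CIFAR-10 binary format stores records of 3073 bytes: one label byte
#' followed by the 32x32 red, green and blue planes (row-major).  All
#' `*.bin` files in `dir` (or the explicit files given) are concatenated.
#'
#' @param dir Directory containing batch files, or a character vector of
#'   file paths.
#' @param split,provenance Passed to [image_dataset()].
#' @return An `ImageDataset` of `N x 32 x 32 x 3` images in `[0, 1]`.
#' @export
read_cifar10_binary <- function(dir, split = "train", provenance = "cifar10") {
  files <- if (length(dir) == 1L && dir.exists(dir)) {
    sort(list.files(dir, pattern = "\\.bin$", full.names = TRUE))
  } else dir
  if (!length(files)) stop("no CIFAR-10 .bin batch files found in ", dir)
  rec <- 3073L
  imgs <- list()
  labs <- list()
  for (f in files) {
    sz <- file.size(f)
    if (is.na(sz) || sz %% rec != 0L) {
      stop(sprintf("file %s has %s bytes, not a multiple of the %d-byte record",
                   f, format(sz), rec))
    }
    n <- sz %/% rec
    raw <- as.integer(readBin(f, "raw", n = sz))
    m <- matrix(raw, nrow = rec)  # one record per column
    labs[[f]] <- m[1L, ]
    # planes: rows 2..3073 are R, G, B, each 32x32 row-major
    px <- array(m[-1L, ], dim = c(32L, 32L, 3L, n))  # (col, row, ch, img): first index fastest = within-row pixels
    px <- aperm(px, c(4L, 2L, 1L, 3L))               # -> (img, row, col, ch)
    imgs[[f]] <- px / 255
  }
  images <- array(0, c(sum(vapply(imgs, function(a) dim(a)[1L], numeric(1))),
                       32L, 32L, 3L))
  at <- 1L
  for (a in imgs) {
    n <- dim(a)[1L]
    images[at:(at + n - 1L), , , ] <- a
    at <- at + n
  }
  image_dataset(images, unlist(labs, use.names = FALSE), split = split,
                provenance = provenance)
}

#' Synthetic classification task specification
#'
#' Defines the download-free stand-in task: each class has a fixed smooth
#' random template image and every example is the template plus independent
#' Gaussian pixel noise, clipped to `[0, 1]`.  The default emulates an
#' MNIST-scale task — 10 classes of 28x28 grayscale images — with the noise
#' level set so that a linear classifier reaches roughly 75–85% accuracy,
#' leaving headroom for capacity and overfitting effects to show.
#'
#' @param K Number of classes.
#' @param size Image shape `(H, W, C)`.
#' @param noise_sd Pixel noise standard deviation.
#' @param n_train,n_test Examples per class in each split.
#' @param template_cells Side of the coarse random grid that is bilinearly
#'   upsampled into each class template (smaller = smoother templates).
#' @param seed Seed for templates and noise.
#' @return A list of class `SynthSpec`.
#' @export
synth_spec <- function(K = 10L, size = c(28L, 28L, 1L), noise_sd = 0.6,
                       n_train = 100L, n_test = 100L, template_cells = 4L,
                       seed = 1L) {
  stopifnot(K >= 2, noise_sd >= 0, n_train >= 1, n_test >= 1,
            template_cells >= 2, length(size) == 3L)
  structure(list(K = as.integer(K), size = as.integer(size),
                 noise_sd = noise_sd, n_train = as.integer(n_train),
                 n_test = as.integer(n_test),
                 template_cells = as.integer(template_cells),
                 seed = as.integer(seed)),
            class = "SynthSpec")
}

# Bilinear upsampling of a small matrix to (H, W).
bilinear_upsample <- function(m, H, W) {
  g <- nrow(m)
  # coarse cell centres mapped onto [1, g] coordinates of the fine grid
  xs <- seq(1, g, length.out = H)
  ys <- seq(1, g, length.out = W)
  x0 <- pmin(floor(xs), g - 1L)
  y0 <- pmin(floor(ys), g - 1L)
  fx <- xs - x0
  fy <- ys - y0
  m[cbind(rep(x0, times = W), rep(y0, each = H))] *
    outer(1 - fx, 1 - fy) +
    m[cbind(rep(x0 + 1L, times = W), rep(y0, each = H))] *
    outer(fx, 1 - fy) +
    m[cbind(rep(x0, times = W), rep(y0 + 1L, each = H))] *
    outer(1 - fx, fy) +
    m[cbind(rep(x0 + 1L, times = W), rep(y0 + 1L, each = H))] *
    outer(fx, fy)
}

synth_templates <- function(spec) {
  H <- spec$size[1L]; W <- spec$size[2L]; C <- spec$size[3L]
  tpl <- array(0, c(spec$K, H, W, C))
  for (k in seq_len(spec$K)) {
    for (ch in seq_len(C)) {
      coarse <- matrix(stats::rnorm(spec$template_cells^2),
                       spec$template_cells)
      up <- bilinear_upsample(coarse, H, W)
      up <- (up - min(up)) / max(max(up) - min(up), 1e-12)
      tpl[k, , , ch] <- up
    }
  }
  tpl
}

#' Generate a synthetic classification dataset
#'
#' Draws the class templates once from `spec$seed`, then builds disjoint
#' train and test splits of `template + N(0, noise_sd)` images clipped to
#' `[0, 1]`.  Fully reproducible: the same spec yields bit-identical data.
#'
#' @param spec A [synth_spec()].
#' @return List with `train` and `test` `ImageDataset`s and the `templates`
#'   array (`K x H x W x C`).
#' @export
make_synthetic <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "SynthSpec"))
  with_local_seed(spec$seed, {
    tpl <- synth_templates(spec)
    make_split <- function(n_per, split) {
      n <- n_per * spec$K
      H <- spec$size[1L]; W <- spec$size[2L]; C <- spec$size[3L]
      labels <- rep(0:(spec$K - 1L), each = n_per)
      images <- array(0, c(n, H, W, C))
      for (k in seq_len(spec$K)) {
        rows <- (k - 1L) * n_per + seq_len(n_per)
        noise <- array(stats::rnorm(n_per * H * W * C, sd = spec$noise_sd),
                       c(n_per, H, W, C))
        base <- aperm(array(tpl[k, , , , drop = FALSE],
                            c(1L, H, W, C))[rep(1L, n_per), , , ,
                                            drop = FALSE],
                      c(1L, 2L, 3L, 4L))
        images[rows, , , ] <- pmin(pmax(base + noise, 0), 1)
      }
      image_dataset(images, labels, split = split, provenance = "synthetic")
    }
    train <- make_split(spec$n_train, "train")
    test <- make_split(spec$n_test, "test")
    list(train = train, test = test, templates = tpl, spec = spec)
  })
}

#' Label-preserving image augmentation
#'
#' Per-image random horizontal flip and/or integer pixel shifts of up to
#' `shift` times the image size, with nearest-edge fill.
#'
#' @param images `N x H x W x C` array.
#' @param params List with `flip` (logical; flip each image with probability
#'   0.5) and `shift` (fraction of width/height, in `[0, 1)`).
#' @param seed Optional seed for the augmentation draws.
#' @return Augmented array, same shape.
#' @export
augment_images <- function(images, params = list(flip = TRUE, shift = 0.1),
                           seed = NULL) {
  shift <- params$shift %||% 0
  flip <- isTRUE(params$flip)
  if (shift >= 1) stop("shift fraction must be below 1")
  with_local_seed(seed, {
    d <- dim(images)
    N <- d[1L]; H <- d[2L]; W <- d[3L]
    maxdh <- round(shift * H)
    maxdw <- round(shift * W)
    for (i in seq_len(N)) {
      img <- images[i, , , , drop = FALSE]
      if (flip && stats::runif(1) < 0.5) {
        img <- img[, , W:1, , drop = FALSE]
      }
      if (maxdh > 0 || maxdw > 0) {
        dh <- sample(-maxdh:maxdh, 1L)
        dw <- sample(-maxdw:maxdw, 1L)
        if (dh != 0 || dw != 0) {
          src_r <- pmin(pmax(seq_len(H) - dh, 1L), H)
          src_c <- pmin(pmax(seq_len(W) - dw, 1L), W)
          img <- img[, src_r, src_c, , drop = FALSE]
        }
      }
      images[i, , , ] <- img
    }
    images
  })
}
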