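write_bytes <- function(path, bytes) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(bytes), con)
}

# big-endian 4-byte encoding of an integer
be4 <- function(x) c(x %/% 16777216, x %/% 65536 %% 256, x %/% 256 %% 256,
                     x %% 256)

test_that("IDX reader decodes hand-built image and label fixtures", {
  img_file <- tempfile()
  write_bytes(img_file, c(be4(2051), be4(1), be4(2), be4(2), 0, 128, 255, 0))
  a <- read_idx(img_file)
  expect_identical(dim(a), c(1L, 2L, 2L))
  expect_equal(a[1, , ], matrix(c(0, 128 / 255, 255 / 255, 0), 2,
                                byrow = TRUE),
               tolerance = 1e-12)
  lab_file <- tempfile()
  write_bytes(lab_file, c(be4(2049), be4(3), 7, 0, 9))
  expect_identical(read_idx(lab_file), c(7L, 0L, 9L))
})

test_that("IDX round-trips byte-identically and rejects malformed files", {
  img_file <- tempfile()
  write_bytes(img_file, c(be4(2051), be4(2), be4(3), be4(4),
                          sample(0:255, 24)))
  out <- tempfile()
  write_idx(read_idx(img_file), out)
  expect_identical(readBin(img_file, "raw", 100), readBin(out, "raw", 100))
  lab_file <- tempfile()
  write_bytes(lab_file, c(be4(2049), be4(5), 0:4))
  out2 <- tempfile()
  write_idx(read_idx(lab_file), out2)
  expect_identical(readBin(lab_file, "raw", 100), readBin(out2, "raw", 100))
  bad <- tempfile()
  write_bytes(bad, c(1, 2, 3, 4, 0, 0, 0, 0))
  expect_error(read_idx(bad), "magic")
  trunc <- tempfile()
  write_bytes(trunc, c(be4(2051), be4(1), be4(2), be4(2), 0, 1))
  expect_error(read_idx(trunc), "truncated")
})

test_that("CIFAR-10 binary batches decode labels and channel planes", {
  f <- tempfile(fileext = ".bin")
  rec1 <- c(3, rep(255, 1024), rep(0, 2048))        # red plane saturated
  rec2 <- c(7, rep(0, 2048), rep(128, 1024))        # blue plane mid-gray
  write_bytes(f, c(rec1, rec2))
  ds <- read_cifar10_binary(f)
  expect_identical(dim(ds$images), c(2L, 32L, 32L, 3L))
  expect_identical(ds$labels, c(3L, 7L))
  expect_true(all(ds$images[1, , , 1] == 1))
  expect_true(all(ds$images[1, , , 2:3] == 0))
  expect_equal(unique(as.vector(ds$images[2, , , 3])), 128 / 255)
  bad <- tempfile(fileext = ".bin")
  write_bytes(bad, rep(0, 3072))
  expect_error(read_cifar10_binary(bad), "3073")
})

test_that("synthetic datasets are reproducible, disjoint and on-template", {
  spec <- synth_spec(K = 3, size = c(10, 10, 1), noise_sd = 0.3,
                     n_train = 8, n_test = 6, seed = 21)
  ds1 <- make_synthetic(spec)
  ds2 <- make_synthetic(spec)
  expect_identical(ds1$train$images, ds2$train$images)
  expect_identical(ds1$test$labels, ds2$test$labels)
  expect_identical(dim(ds1$train$images), c(24L, 10L, 10L, 1L))
  expect_identical(dim(ds1$test$images), c(18L, 10L, 10L, 1L))
  expect_true(all(ds1$train$images >= 0 & ds1$train$images <= 1))
  # no image appears in both splits
  tr <- apply(ds1$train$images, 1, paste, collapse = ",")
  te <- apply(ds1$test$images, 1, paste, collapse = ",")
  expect_length(intersect(tr, te), 0L)
  # zero noise: every image equals its class template exactly
  clean <- make_synthetic(synth_spec(K = 2, size = c(6, 6, 1), noise_sd = 0,
                                     n_train = 3, n_test = 2, seed = 5))
  for (i in 1:6) {
    k <- clean$train$labels[i] + 1
    expect_equal(clean$train$images[i, , , 1], clean$templates[k, , , 1],
                 tolerance = 1e-15)
  }
  expect_false(identical(clean$templates[1, , , 1], clean$templates[2, , , 1]))
})

test_that("per-class mean images converge to the class template", {
  mad_at <- function(n) {
    ds <- make_synthetic(synth_spec(K = 2, size = c(8, 8, 1), noise_sd = 0.5,
                                    n_train = n, n_test = 1, seed = 77))
    k1 <- ds$train$labels == 0
    mean(abs(apply(ds$train$images[k1, , , 1, drop = FALSE], c(2, 3), mean) -
               ds$templates[1, , , 1]))
  }
  expect_lt(mad_at(200), mad_at(20))
})

test_that("augmentation is label-preserving, seeded and optional", {
  ds <- tiny_rgb_ds()
  X <- ds$train$images[1:5, , , , drop = FALSE]
  expect_identical(augment_images(X, list(flip = FALSE, shift = 0)), X)
  a1 <- augment_images(X, list(flip = TRUE, shift = 0.2), seed = 3)
  a2 <- augment_images(X, list(flip = TRUE, shift = 0.2), seed = 3)
  expect_identical(a1, a2)
  expect_identical(dim(a1), dim(X))
  # flipping twice restores the original
  flipped <- X[, , dim(X)[3]:1, , drop = FALSE]
  expect_identical(flipped[, , dim(X)[3]:1, , drop = FALSE], X)
  expect_error(augment_images(X, list(shift = 1.2)), "below 1")
})
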