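# Shared fixtures, built in code.  Kept deliberately tiny so the unit files
# stay fast; the acceptance file builds its own full-size study datasets.

# 4-class 8x8 grayscale task, moderately noisy.
tiny_ds <- function() {
  make_synthetic(synth_spec(K = 4L, size = c(8L, 8L, 1L), noise_sd = 0.5,
                            n_train = 15L, n_test = 15L, seed = 42L))
}

# 4-class 8x8 RGB task for convolutional models.
tiny_rgb_ds <- function() {
  make_synthetic(synth_spec(K = 4L, size = c(8L, 8L, 3L), noise_sd = 0.5,
                            n_train = 12L, n_test = 12L, seed = 43L))
}

tiny_config <- function(reduction = 0, width = 16L, epochs = 5L,
                        family = "diagonal") {
  network_config("A-small", width = width,
                 window = list(family = family, reduction = reduction),
                 input_shape = c(8L, 8L, 1L), n_classes = 4L, epochs = epochs)
}

# Brute-force retained count of a thresholded distance field: the
# independent oracle for the threshold solver.
brute_counts <- function(n_in, n_out) {
  d <- sort(as.vector(outer(0:(n_in - 1L), 0:(n_out - 1L), function(i, j) {
    abs(n_out / n_in * i - j) / sqrt((n_out / n_in)^2 + 1)
  })))
  unique(c(0L, vapply(unique(d), function(t) sum(d <= t + 1e-9), integer(1))))
}

# Wrap an arbitrary 0/1 (or [0,1]) matrix as a window object.
new_test_window <- function(values) {
  szlayers:::new_window(values, "custom", list())
}
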