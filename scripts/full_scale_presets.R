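#!/usr/bin/env Rscript
# Full-scale reference runs (NOT part of the test suite; multi-hour CPU cost).
#
# Reproduces the reference experiment layouts at their original scale when
# the datasets are available locally:
#   * MNIST IDX files (train-images-idx3-ubyte etc.) under --mnist
#   * CIFAR-10 binary batches (data_batch_*.bin, test_batch.bin) under --cifar
# Nothing is downloaded.  On a single desktop CPU the MNIST sweeps take hours
# and the CIFAR/VGG runs much longer; they are provided for completeness.
#
# Usage:
#   Rscript scripts/full_scale_presets.R --experiment disorganized-mnist \
#       --mnist data/mnist --sessions 100 --seed 1 --out results/full/
#   Rscript scripts/full_scale_presets.R --experiment developmental-mnist ...
#   Rscript scripts/full_scale_presets.R --experiment developmental-cifar \
#       --cifar data/cifar10 --sessions 10 ...

suppressPackageStartupMessages(library(szlayers))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(experiment = "disorganized-mnist", mnist = "data/mnist",
            cifar = "data/cifar10", sessions = NULL, seed = 1L,
            out = "results/full")
i <- 1L
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  opt[[key]] <- args[i + 1L]
  i <- i + 2L
}
opt$seed <- as.integer(opt$seed)
if (!is.null(opt$sessions)) opt$sessions <- as.integer(opt$sessions)
dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)

load_mnist <- function(dir) {
  need <- c("train-images-idx3-ubyte", "train-labels-idx1-ubyte",
            "t10k-images-idx3-ubyte", "t10k-labels-idx1-ubyte")
  paths <- file.path(dir, need)
  if (!all(file.exists(paths))) {
    stop("MNIST IDX files not found under ", dir,
         " (this script never downloads data)")
  }
  list(train = image_dataset(read_idx(paths[1]), read_idx(paths[2]),
                             "train", "mnist"),
       test = image_dataset(read_idx(paths[3]), read_idx(paths[4]),
                            "test", "mnist"))
}

load_cifar <- function(dir) {
  train_files <- file.path(dir, sprintf("data_batch_%d.bin", 1:5))
  test_file <- file.path(dir, "test_batch.bin")
  if (!all(file.exists(c(train_files, test_file)))) {
    stop("CIFAR-10 binary batches not found under ", dir)
  }
  list(train = read_cifar10_binary(train_files, "train"),
       test = read_cifar10_binary(test_file, "test"))
}

reductions <- c(0, 0.2, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9)

run <- switch(opt$experiment,
  # network B, 512-wide hidden pair, window attached at evaluation
  "disorganized-mnist" = function() {
    ds <- load_mnist(opt$mnist)
    cfg <- network_config("B")
    sweeps <- lapply(c("diagonal", "gaussian", "stripe", "centered", "random"),
                     function(fam) {
      run_disorganized_sweep(cfg, ds, reductions,
                             sessions = opt$sessions %||% 100L,
                             base_seed = opt$seed, family = fam)
    })
    summarize_sweeps(sweeps, file.path(opt$out, "sessions.csv"),
                     file.path(opt$out, "means.csv"))
  },
  # network A, masked hidden layer trained under the window
  "developmental-mnist" = function() {
    ds <- load_mnist(opt$mnist)
    cfg <- network_config("A")
    sweeps <- lapply(c("diagonal", "gaussian", "random"), function(fam) {
      run_developmental_sweep(cfg, ds, reductions,
                              sessions = opt$sessions %||% 100L,
                              base_seed = opt$seed, family = fam)
    })
    summarize_sweeps(sweeps, file.path(opt$out, "sessions.csv"),
                     file.path(opt$out, "means.csv"))
  },
  # network C, masked 512-wide top layer, RMSprop schedule
  "developmental-cifar" = function() {
    ds <- load_cifar(opt$cifar)
    cfg <- network_config("C")
    sw <- run_developmental_sweep(cfg, ds, reductions,
                                  sessions = opt$sessions %||% 10L,
                                  base_seed = opt$seed)
    summarize_sweeps(sw, file.path(opt$out, "sessions.csv"),
                     file.path(opt$out, "means.csv"))
  },
  # network D, top layer masked at evaluation only
  "disorganized-cifar" = function() {
    ds <- load_cifar(opt$cifar)
    cfg <- network_config("D")
    sw <- run_disorganized_sweep(cfg, ds, reductions,
                                 sessions = opt$sessions %||% 30L,
                                 base_seed = opt$seed)
    summarize_sweeps(sw, file.path(opt$out, "sessions.csv"),
                     file.path(opt$out, "means.csv"))
  },
  # network E (VGG16 with channel-masked last conv block), 60% reduction
  # against an unmasked control; 200 epochs per session
  "vgg-cifar" = function() {
    ds <- load_cifar(opt$cifar)
    runs <- lapply(seq_len(opt$sessions %||% 3L), function(s) {
      lapply(c(0, 0.6), function(red) {
        cfg <- network_config("E", window = list(family = "diagonal",
                                                 reduction = red))
        seed <- derive_seed(opt$seed, "developmental", "diagonal", red, s)
        fit <- train(build_network(cfg, seed = seed), ds, seed = seed)
        utils::write.csv(fit$trace,
                         file.path(opt$out,
                                   sprintf("vgg_trace_r%g_s%d.csv", red, s)),
                         row.names = FALSE)
        fit$trace
      })
    })
    invisible(runs)
  },
  stop("unknown experiment: ", opt$experiment)
)

`%||%` <- function(a, b) if (is.null(a)) b else a
run()
message("done; outputs under ", opt$out)
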