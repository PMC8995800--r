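test_that("reference config A has the documented parameter count", {
  cfg <- network_config("A")
  model <- build_network(cfg, seed = 1)
  expect_identical(count_params(model), 784 * 512 + 512 + 512 * 10 + 10)
  # masking does not delete storage
  cfg50 <- network_config("A", window = list(family = "diagonal",
                                             reduction = 0.5))
  m50 <- build_network(cfg50, seed = 1)
  expect_identical(count_params(m50), count_params(model))
  lay <- m50$layers[[2]]
  eff <- effective_weights(lay$W, lay$window)
  expect_equal(mean(eff != 0), retained_fraction(lay$window), tolerance = 0.01)
})

test_that("config B builds and runs forward at both width endpoints", {
  for (w in c(64L, 1024L)) {
    cfg <- network_config("B", width = w)
    model <- build_network(cfg, seed = 2)
    x <- array(runif(2 * 28 * 28), c(2, 28, 28, 1))
    p <- predict(model, x)
    expect_identical(dim(p), c(2L, 10L))
    expect_equal(rowSums(p), c(1, 1), tolerance = 1e-12)
    # target layer is bias-free from the start (bias rule)
    expect_null(model$layers[[model$sz_target_index]]$b)
  }
})

test_that("conv configs C/D/E produce softmax probabilities on RGB input", {
  x <- array(runif(2 * 32 * 32 * 3), c(2, 32, 32, 3))
  for (id in c("C-small", "E-small")) {
    cfg <- network_config(id, window = list(family = "diagonal",
                                            reduction = 0.4))
    p <- predict(build_network(cfg, seed = 3), x)
    expect_equal(rowSums(p), c(1, 1), tolerance = 1e-12)
  }
  d <- build_network(network_config("D"), seed = 3)
  expect_false(is.na(d$sz_target_index))
  expect_null(d$layers[[d$sz_target_index]]$b)
  # E: channel windows on the last three conv layers only, constant over space
  e <- build_network(network_config("E", window = list(family = "diagonal",
                                                       reduction = 0.6)),
                     seed = 3)
  sz_convs <- Filter(function(l) l$type == "conv" && !is.null(l$window),
                     e$layers)
  expect_length(sz_convs, 3L)
  for (l in sz_convs) {
    expect_identical(dim(unclass(l$window)), dim(l$K)[3:4])
  }
})

test_that("a full-window masked layer trains bit-identically to a plain one", {
  ds <- tiny_ds()
  cfg <- tiny_config(reduction = 0, epochs = 4)
  plain <- build_network(cfg, seed = 7)
  masked <- build_network(cfg, seed = 7)
  masked$layers[[2]]$window <- full_window(node_geometry(64, 16))
  masked$layers[[2]]$rho <- 1
  fit_p <- train(plain, ds, seed = 7)
  fit_m <- train(masked, ds, seed = 7)
  expect_equal(fit_p$trace, fit_m$trace, tolerance = 1e-12)
  expect_equal(fit_p$layers[[2]]$W, fit_m$layers[[2]]$W, tolerance = 1e-12)
})

test_that("training is deterministic given the seed and fits an easy task", {
  ds <- tiny_ds()
  cfg <- tiny_config(reduction = 0.5, epochs = 6)
  f1 <- train(build_network(cfg, seed = 5), ds, seed = 5)
  f2 <- train(build_network(cfg, seed = 5), ds, seed = 5)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$layers[[2]]$W, f2$layers[[2]]$W)
  expect_identical(nrow(f1$trace), 6L)
  expect_true(all(f1$trace$train_error >= 0 & f1$trace$train_error <= 1))
  # easy low-noise task: 32 hidden units fit it to near-zero training error
  easy <- make_synthetic(synth_spec(noise_sd = 0.3, n_train = 50, n_test = 20,
                                    seed = 9))
  fit <- train(build_network(network_config("A-small", width = 32,
                                            epochs = 30), seed = 4),
               easy, seed = 4, trace_every = 30)
  expect_lt(fit$trace$train_error[nrow(fit$trace)], 0.05)
})

test_that("evaluate is pure and sits at chance for a constant predictor", {
  ds <- tiny_ds()
  model <- build_network(tiny_config(), seed = 6)
  # zero the network: softmax is uniform, prediction constant
  for (l in seq_along(model$layers)) {
    if (!is.null(model$layers[[l]]$W)) model$layers[[l]]$W[] <- 0
  }
  err <- evaluate(model, ds$test)
  expect_equal(err, 1 - mean(ds$test$labels == 0))  # balanced: 1 - 1/K
  set.seed(99); r_before <- .Random.seed
  expect_identical(evaluate(model, ds$test), err)
  expect_identical(r_before, .Random.seed)  # no RNG consumption
  expect_error(evaluate(model, list(images = NULL, labels = NULL)),
               "non-empty")
})

test_that("masked raw weights never move during training", {
  ds <- tiny_ds()
  cfg <- tiny_config(reduction = 0.6, epochs = 8)
  init <- build_network(cfg, seed = 8)
  fit <- train(init, ds, seed = 8)
  msk <- unclass(fit$layers[[2]]$window) == 0
  expect_true(any(msk))
  expect_identical(fit$layers[[2]]$W[msk], init$layers[[2]]$W[msk])
  expect_true(all(effective_weights(fit$layers[[2]]$W,
                                    fit$layers[[2]]$window)[msk] == 0))
  expect_false(identical(fit$layers[[2]]$W[!msk], init$layers[[2]]$W[!msk]))
})

test_that("the L1 control reports reduction as the near-zero weight share", {
  expect_error(l1_variant(network_config("C-small"), -1), "non-negative")
  ds <- tiny_ds()
  base <- tiny_config(epochs = 10)
  cfg0 <- l1_variant(base, 0)
  fit0 <- train(build_network(cfg0, seed = 3), ds, seed = 3)
  expect_lt(l1_reduction(fit0), 0.05)
  # strong penalty with a small step size shrinks most weights below 1e-4
  cfg1 <- l1_variant(base, 0.5)
  sch <- training_schedule("adam", lr = 5e-5, batch_size = 8, epochs = 1000)
  fit1 <- train(build_network(cfg1, seed = 3), ds, seed = 3, schedule = sch,
                trace_every = 1e6)
  expect_gt(l1_reduction(fit1), 0.9)
  # degenerate case: an all-zero matrix is fully reduced
  fit1$layers[[2]]$W[] <- 0
  expect_identical(l1_reduction(fit1), 1)
})

test_that("model state round-trips through the plain-text archive", {
  ds <- tiny_ds()
  cfg <- tiny_config(reduction = 0.5, epochs = 3)
  fit <- train(build_network(cfg, seed = 13), ds, seed = 13)
  dir <- tempfile()
  save_network(fit, dir)
  fresh <- load_network(build_network(cfg, seed = 1), dir)
  x <- ds$test$images[1:4, , , , drop = FALSE]
  expect_equal(predict(fresh, x), predict(fit, x), tolerance = 1e-12)
})

test_that("fit methods print, summarise and plot without error", {
  ds <- tiny_ds()
  fit <- train(build_network(tiny_config(epochs = 3), seed = 14), ds,
               seed = 14)
  expect_output(print(fit), "sz_network")
  expect_output(summary(fit), "dense")
  expect_named(coef(fit)[[1]], c("weights", "bias", "window"))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
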