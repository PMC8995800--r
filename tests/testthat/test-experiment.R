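test_that("cell seeds are deterministic, distinct and 31-bit", {
  s1 <- derive_seed(1, "developmental", "diagonal", 0.5, 1)
  expect_identical(s1, derive_seed(1, "developmental", "diagonal", 0.5, 1))
  grid <- expand.grid(p = c("developmental", "disorganized"),
                      f = c("diagonal", "random"), r = c(0, 0.4, 0.7),
                      s = 1:5, stringsAsFactors = FALSE)
  seeds <- mapply(function(p, f, r, s) derive_seed(42, p, f, r, s),
                  grid$p, grid$f, grid$r, grid$s)
  expect_identical(length(unique(seeds)), nrow(grid))
  expect_true(all(seeds > 0 & seeds < 2^31))
  expect_false(derive_seed(1, "developmental", "diagonal", 0.5, 1) ==
                 derive_seed(2, "developmental", "diagonal", 0.5, 1))
})

test_that("rank-sum comparison matches the exact null distribution", {
  cmp <- wilcoxon_compare(1:10, 11:20)
  expect_equal(cmp$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(cmp$significant)
  swapped <- wilcoxon_compare(11:20, 1:10)
  expect_identical(swapped$p_value, cmp$p_value)
  same <- wilcoxon_compare(rep(0.5, 6), rep(0.5, 6))
  expect_identical(same$p_value, 1)
  expect_false(same$significant)
  expect_match(same$note, "identical")
  # large/tied samples fall back to the corrected normal approximation
  set.seed(1)
  big <- wilcoxon_compare(round(rnorm(30), 1), round(rnorm(30, 0.5), 1))
  expect_match(big$method, "approximation")
  expect_true(big$p_value > 0 && big$p_value <= 1)
  expect_error(wilcoxon_compare(numeric(0), 1:3), "non-empty")
})

test_that("disorganized sweeps train once per session and share the baseline", {
  ds <- tiny_ds()
  cfg <- network_config("B-small", width = 24, input_shape = c(8, 8, 1),
                        n_classes = 4, epochs = 3)
  sw <- run_disorganized_sweep(cfg, ds, reductions = c(0, 0.5, 0.9),
                               sessions = 2, base_seed = 3)
  expect_identical(nrow(sw$sessions), 6L)
  expect_identical(nrow(sw$means), 3L)
  # the reduction-0 cell equals a manual train/evaluate at the derived seed
  seed1 <- derive_seed(3, "disorganized", "diagonal", 0, 1)
  manual <- train(build_network(cfg, seed = seed1), ds, seed = seed1,
                  trace_every = 100)
  err0 <- sw$sessions$error[sw$sessions$reduction == 0 &
                              sw$sessions$session == 1]
  expect_identical(err0, evaluate(manual, ds$test))
  expect_true(all(sw$sessions$error >= 0 & sw$sessions$error <= 1))
  expect_identical(sw$means$reduction, c(0, 0.5, 0.9))
})

test_that("developmental sweeps train one network per cell, order-free", {
  ds <- tiny_ds()
  cfg <- tiny_config(epochs = 3, width = 12)
  sw <- run_developmental_sweep(cfg, ds, reductions = c(0, 0.5),
                                sessions = 2, base_seed = 9)
  expect_identical(nrow(sw$sessions), 4L)
  # baseline cell reproduces a conventional run at the same derived seed
  seed1 <- derive_seed(9, "developmental", "diagonal", 0, 1)
  manual <- train(build_network(cfg, seed = seed1), ds, seed = seed1,
                  trace_every = 100)
  expect_identical(sw$sessions$error[1], evaluate(manual, ds$test))
  # executing the grid in reverse order leaves every cell unchanged
  sw_rev <- run_developmental_sweep(cfg, ds, reductions = c(0.5, 0),
                                    sessions = 2, base_seed = 9)
  a <- sw$sessions[order(sw$sessions$reduction, sw$sessions$session), ]
  b <- sw_rev$sessions[order(sw_rev$sessions$reduction, sw_rev$sessions$session), ]
  expect_equal(a$error, b$error)
  expect_error(run_developmental_sweep(cfg, ds, reductions = c(0, 1)),
               "\\[0, 1\\)")
  expect_error(run_disorganized_sweep(cfg, ds), "disorganized")
})

test_that("summaries bind sweeps into deterministic long and mean tables", {
  ds <- tiny_ds()
  cfg <- tiny_config(epochs = 2, width = 12)
  sw1 <- run_developmental_sweep(cfg, ds, reductions = c(0, 0.5),
                                 sessions = 3, base_seed = 1)
  sw2 <- run_developmental_sweep(cfg, ds, reductions = c(0, 0.5),
                                 sessions = 3, base_seed = 1,
                                 family = "random")
  tab <- summarize_sweeps(list(sw1, sw2))
  expect_identical(nrow(tab$long), 12L)   # 2 sweeps x 2 reductions x 3 sessions
  expect_identical(nrow(tab$means), 4L)
  expect_true(all(tab$means$n_sessions == 3L))
  long_csv <- tempfile(fileext = ".csv")
  means_csv <- tempfile(fileext = ".csv")
  summarize_sweeps(list(sw1, sw2), long_csv, means_csv)
  re <- utils::read.csv(long_csv)
  expect_equal(re$error, tab$long$error)
  expect_identical(re$family, tab$long$family)
  cfg2 <- tiny_config(epochs = 2, width = 12)
  sw3 <- run_developmental_sweep(cfg2, ds, reductions = c(0, 0.7),
                                 sessions = 2, base_seed = 1)
  expect_error(summarize_sweeps(list(sw1, sw3)), "grids")
})
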