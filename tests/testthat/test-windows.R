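test_that("node distance is the point-to-line distance to the diagonal", {
  g55 <- node_geometry(5, 5)
  expect_identical(node_distance(3, 3, g55), 0)
  expect_equal(node_distance(2, 4, g55), 2 / sqrt(2), tolerance = 1e-12)
  # non-square: r = 64/3, |r*1 - 21| / sqrt(r^2 + 1) = 1/sqrt(4105)
  expect_equal(node_distance(1, 21, node_geometry(3, 64)), 1 / sqrt(4105),
               tolerance = 1e-12)
  expect_equal(node_distance(1, 21, node_geometry(3, 64)), 0.01561,
               tolerance = 1e-3)
  expect_error(node_distance(5, 0, g55), "index i = 5")
  expect_error(node_distance(0, -1, g55), "index j = -1")
})

test_that("distance field matches the elementwise formula and its symmetries", {
  expect_equal(as.vector(distance_field(node_geometry(1, 1))), 0)
  expect_equal(unname(distance_field(node_geometry(2, 2))[, ]),
               matrix(c(0, 1 / sqrt(2), 1 / sqrt(2), 0), 2),
               tolerance = 1e-15)
  for (n in c(3, 7, 12)) {
    d <- distance_field(node_geometry(n, n))
    expect_identical(d[, ], t(d)[, ])  # square fields are exactly symmetric
  }
  g <- node_geometry(6, 15)
  d <- distance_field(g)
  for (i in 0:5) for (j in 0:14) {
    expect_identical(d[i + 1, j + 1], node_distance(i, j, g))
  }
})

test_that("diagonal window retains exactly the band within the threshold", {
  g <- node_geometry(5, 5)
  w <- diagonal_window(g, 0.8)
  expect_equal(sum(w), 13)  # tridiagonal
  expect_equal(retained_fraction(w), 0.52)
  expect_true(all(unclass(w) %in% c(0, 1)))
  expect_true(all(diagonal_window(g, max(distance_field(g))) == 1))
  # the (0,0) cell sits on the diagonal, so a diagonal window is never empty
  expect_equal(min(colSums(unclass(diagonal_window(g, 0)))), 1)
  # channel-window case: 112 of 192 retained, 80/192 = 41.7% eliminated
  w364 <- diagonal_window(node_geometry(3, 64), 68 / sqrt(4105))
  expect_equal(sum(w364), 112)
  expect_equal(round(100 * parameter_reduction(w364), 1), 41.7)
})

test_that("gaussian window follows exp(-d^2 / (2 sigma^2))", {
  g <- node_geometry(5, 5)
  w <- gaussian_window(g, 1 / sqrt(2))
  expect_equal(diag(unclass(w)), rep(1, 5))
  expect_equal(w[1, 2], exp(-0.5), tolerance = 1e-15)
  expect_true(all(w > 0 & w <= 1))
  rf <- vapply(c(0.2, 0.5, 1, 2, 5), function(s)
    retained_fraction(gaussian_window(g, s)), numeric(1))
  expect_true(all(diff(rf) > 0))  # strictly increasing in sigma
  expect_error(gaussian_window(g, 0), "positive")
})

test_that("stripe window is a wrapped union of parallel bands", {
  g <- node_geometry(8, 8)
  mat <- function(w) szlayers:::strip_attrs(unclass(w))
  expect_identical(mat(stripe_window(g, 1, 0.8)),
                   mat(diagonal_window(g, 0.8)))
  w <- stripe_window(g, 2, 0.4)
  # independent membership oracle: distance to lines j = i, j = i +/- 4
  expected <- matrix(0, 8, 8)
  for (i in 0:7) for (j in 0:7) {
    d <- min(abs(i - j), abs(i + 4 - j), abs(i - 4 - j)) / sqrt(2)
    if (d <= 0.4) expected[i + 1, j + 1] <- 1
  }
  expect_identical(mat(w), expected)
  t0 <- 0.8
  expect_gte(retained_fraction(stripe_window(g, 3, t0)),
             retained_fraction(diagonal_window(g, t0)))
})

test_that("centered window retains a disc around the matrix centre", {
  g <- node_geometry(5, 5)
  w <- centered_window(g, 0.25)
  expect_equal(sum(w), 5)  # centre cell plus its 4-neighbourhood
  expect_equal(w[3, 3], 1)
  expect_true(all(centered_window(g, sqrt(0.5)) == 1))
  m <- szlayers:::strip_attrs(unclass(centered_window(node_geometry(6, 9), 0.3)))
  expect_identical(m, m[nrow(m):1, ncol(m):1])  # 180-degree rotation symmetry
})

test_that("random window places an exact, seeded count of ones", {
  g <- node_geometry(10, 10)
  expect_true(all(random_window(g, 1, seed = 3) == 1))
  w1 <- random_window(g, 0.3, seed = 7)
  w2 <- random_window(g, 0.3, seed = 7)
  expect_equal(sum(w1), 30)
  expect_identical(unclass(w1), unclass(w2))
  w3 <- random_window(g, 0.3, seed = 8)
  expect_false(identical(unclass(w1), unclass(w3)))
  # hypergeometric overlap expectation 30*30/100 = 9
  expect_lt(abs(sum(w1 * w3) - 9), 9)
  expect_error(random_window(node_geometry(20, 20), 1 / 1000), "zero retained")
  # seeded draw restores the global RNG state
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(random_window(g, 0.5, seed = 9)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("achievable retained counts enumerate the band-size grid", {
  expect_identical(achievable_retained_counts(node_geometry(1, 1)), c(0L, 1L))
  c55 <- achievable_retained_counts(node_geometry(5, 5))
  expect_true(all(c(5L, 13L, 25L) %in% c55))
  expect_true(112L %in% achievable_retained_counts(node_geometry(3, 64)))
  expect_error(achievable_retained_counts(node_geometry(1024, 1024), cap = 1e5),
               "cap")
})

test_that("diagonal threshold solver snaps to the nearest achievable count", {
  g <- node_geometry(3, 64)
  expect_equal(solve_diagonal_threshold(g, 1)$achieved_retained, 1)
  sol <- solve_diagonal_threshold(g, 112 / 192)
  expect_identical(sol$achieved_retained, 112 / 192)
  expect_equal(sum(diagonal_window(g, sol$threshold)), 112)
  # achieved fraction always lies on the achievable grid
  for (geom in list(node_geometry(4, 9), node_geometry(11, 5))) {
    counts <- achievable_retained_counts(geom)
    for (target in c(0.12, 0.37, 0.5, 0.81)) {
      sol <- solve_diagonal_threshold(geom, target)
      expect_true(round(sol$achieved_retained * geom$n_in * geom$n_out)
                  %in% counts)
    }
  }
  expect_error(solve_diagonal_threshold(node_geometry(40, 40), 1e-5),
               "zero")
})

test_that("gaussian sigma solver hits the target retained fraction", {
  g <- node_geometry(5, 5)
  s <- solve_gaussian_sigma(g, 0.52)
  expect_equal(sum(gaussian_window(g, s)), 13, tolerance = 2.5e-5)
  expect_identical(s, solve_gaussian_sigma(g, 0.52))
  s999 <- solve_gaussian_sigma(g, 0.999)
  expect_equal(retained_fraction(gaussian_window(g, s999)), 0.999,
               tolerance = 1.1e-6)
  # below the zero-width floor (on-diagonal fraction) there is no bracket
  expect_error(solve_gaussian_sigma(g, 0.1), "floor")
})

test_that("window_at_reduction dispatches families at the requested reduction", {
  g <- node_geometry(12, 12)
  expect_true(all(window_at_reduction(g, "diagonal", 0) == 1))
  for (fam in c("diagonal", "stripe", "centered", "random")) {
    w <- window_at_reduction(g, fam, 0.5, seed = 1)
    expect_s3_class(w, "sz_window")
    expect_lt(abs(retained_fraction(w) - 0.5), 0.1)
  }
  wg <- window_at_reduction(g, "gaussian", 0.6)
  expect_equal(retained_fraction(wg), 0.4, tolerance = 1.1e-6)
  expect_error(window_at_reduction(g, "diagonal", 1), "reduction")
})

test_that("windows round-trip through CSV with family and parameters", {
  w <- diagonal_window(node_geometry(6, 10), 0.7)
  path <- tempfile(fileext = ".csv")
  write_window_csv(w, path)
  w2 <- read_window_csv(path)
  expect_identical(unclass(w2)[, ], unclass(w)[, ])
  expect_identical(attr(w2, "family"), "diagonal")
  expect_equal(attr(w2, "params")$threshold, 0.7)
  expect_equal(retained_fraction(w2), retained_fraction(w))
})
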