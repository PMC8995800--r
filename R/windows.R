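# Weight-window construction and analysis.
#
# A window is an n_in x n_out matrix F of values in [0, 1] that is multiplied
# element-wise onto a layer's weight matrix.  Binary windows built from the
# node distance d_ij suppress connections "distal" to the weight-matrix
# diagonal; the Gaussian window damps them gradually.

#' Node geometry of a dense connection
#'
#' Describes the one-dimensional arrangement of `n_in` input (preceding-layer)
#' nodes and `n_out` output (target-layer) nodes whose weight matrix a window
#' masks.  The aspect ratio `n_out / n_in` defines the diagonal line
#' `j = r * i` of the weight matrix.
#'
#' @param n_in,n_out Positive integer node counts.
#' @return An object of class `node_geometry` with fields `n_in`, `n_out`
#'   and `r`.
#' @examples
#' node_geometry(784, 512)
#' @export
node_geometry <- function(n_in, n_out) {
  if (length(n_in) != 1L || length(n_out) != 1L ||
      !is.finite(n_in) || !is.finite(n_out) ||
      n_in < 1 || n_out < 1 || n_in != round(n_in) || n_out != round(n_out)) {
    stop("n_in and n_out must be single positive integers")
  }
  structure(
    list(n_in = as.integer(n_in), n_out = as.integer(n_out),
         r = n_out / n_in),
    class = "node_geometry"
  )
}

#' @export
print.node_geometry <- function(x, ...) {
  cat(sprintf("node geometry: %d inputs x %d outputs (r = %.6g)\n",
              x$n_in, x$n_out, x$r))
  invisible(x)
}

as_geometry <- function(geom) {
  if (inherits(geom, "node_geometry")) return(geom)
  if (is.numeric(geom) && length(geom) == 2L) {
    return(node_geometry(geom[1L], geom[2L]))
  }
  stop("geom must be a node_geometry or a length-2 integer vector")
}

#' Distance from a weight-matrix element to the diagonal
#'
#' The inter-node distance of the connection from input node `i` to output
#' node `j` is the Euclidean distance from matrix position `(i, j)` to the
#' diagonal line `j = r * i`, where the ratio r is `n_out / n_in`:
#' `d_ij = |r * i - j| / sqrt(r^2 + 1)`.  Indices are 0-based, so the first
#' element of the matrix lies on the diagonal.
#'
#' Internally the equivalent form `|n_out * i - n_in * j| / sqrt(n_in^2 +
#' n_out^2)` is used: its numerator is an exact integer, so connections at
#' mathematically equal distances compare as exactly equal, which the
#' achievable-count enumeration relies on.
#'
#' @param i,j 0-based input and output node indices (vectorized).
#' @param geom A [node_geometry()].
#' @return Non-negative distances, same length as `i`/`j`.
#' @examples
#' node_distance(2, 4, node_geometry(5, 5))  # 2/sqrt(2)
#' @export
node_distance <- function(i, j, geom) {
  geom <- as_geometry(geom)
  if (any(i < 0 | i >= geom$n_in | i != round(i))) {
    bad <- i[which(i < 0 | i >= geom$n_in | i != round(i))[1L]]
    stop(sprintf("input index i = %s out of range [0, %d)", format(bad), geom$n_in))
  }
  if (any(j < 0 | j >= geom$n_out | j != round(j))) {
    bad <- j[which(j < 0 | j >= geom$n_out | j != round(j))[1L]]
    stop(sprintf("output index j = %s out of range [0, %d)", format(bad), geom$n_out))
  }
  abs(geom$n_out * i - geom$n_in * j) / sqrt(geom$n_in^2 + geom$n_out^2)
}

#' Field of node distances over a whole weight matrix
#'
#' @param geom A [node_geometry()].
#' @return An `n_in x n_out` matrix whose `(i+1, j+1)` element is
#'   `node_distance(i, j, geom)`.
#' @export
distance_field <- function(geom) {
  geom <- as_geometry(geom)
  i <- 0:(geom$n_in - 1L)
  j <- 0:(geom$n_out - 1L)
  d <- abs(outer(geom$n_out * i, geom$n_in * j, `-`)) /
    sqrt(geom$n_in^2 + geom$n_out^2)
  attr(d, "geometry") <- geom
  d
}

new_window <- function(values, family, params) {
  if (any(values < 0 | values > 1)) {
    stop("window elements must lie in [0, 1]")
  }
  if (sum(values) <= 0) {
    stop("invalid window: every element is zero")
  }
  structure(
    values,
    family = family,
    params = params,
    retained_fraction = sum(values) / length(values),
    class = c("sz_window", class(values))
  )
}

#' @export
print.sz_window <- function(x, ...) {
  cat(sprintf(
    "%s window, %d x %d: retained fraction %.4f (parameter reduction %.1f%%)\n",
    attr(x, "family"), nrow(x), ncol(x),
    attr(x, "retained_fraction"), 100 * (1 - attr(x, "retained_fraction"))))
  p <- attr(x, "params")
  if (length(p)) {
    cat("params:", paste(names(p), vapply(p, function(v) format(v, digits = 6),
                                          ""), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Heatmap of a weight window
#'
#' Draws the window as an image with inputs on the vertical axis (first row on
#' top) and outputs on the horizontal axis, value 0 white and 1 black.
#'
#' @param x An `sz_window`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.sz_window <- function(x, ...) {
  m <- unclass(x)[nrow(x):1, , drop = FALSE]
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  col = grDevices::gray(seq(1, 0, length.out = 256)),
                  xlab = "output node", ylab = "input node",
                  main = sprintf("%s window", attr(x, "family")), ...)
  invisible(x)
}

#' Fully connected (all-ones) window
#'
#' @param geom A [node_geometry()].
#' @return An `sz_window` of ones; retained fraction 1.
#' @export
full_window <- function(geom) {
  geom <- as_geometry(geom)
  new_window(matrix(1, geom$n_in, geom$n_out), "full", list())
}

#' Diagonal (band-matrix) window
#'
#' Retains the connections whose distance from the weight-matrix diagonal is
#' at most `threshold` (inclusive) and zeroes the rest, producing a band
#' matrix.  Connections at exactly the threshold distance are retained, so
#' ties enter together and every achievable retained count is reachable.
#'
#' @param geom A [node_geometry()].
#' @param threshold Non-negative distance threshold.
#' @return A binary `sz_window` with family `"diagonal"`.
#' @examples
#' diagonal_window(node_geometry(5, 5), 0.8)  # tridiagonal, 13 ones
#' @export
diagonal_window <- function(geom, threshold) {
  geom <- as_geometry(geom)
  if (length(threshold) != 1L || !is.finite(threshold) || threshold < 0) {
    stop("threshold must be a single non-negative number")
  }
  f <- (distance_field(geom) <= threshold) * 1
  if (sum(f) == 0) {
    stop("invalid window: threshold ", format(threshold),
         " zeroes every element")
  }
  new_window(f, "diagonal", list(threshold = threshold))
}

#' Gaussian window
#'
#' Graded distance-dependent damping `f_ij = exp(-d_ij^2 / (2 sigma^2))`:
#' value 1 on the diagonal, decaying with distance at a rate set by the
#' window width `sigma` (in node-index units).
#'
#' @param geom A [node_geometry()].
#' @param sigma Positive window width.
#' @return An `sz_window` with values in (0, 1], family `"gaussian"`.
#' @export
gaussian_window <- function(geom, sigma) {
  geom <- as_geometry(geom)
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("sigma must be a single positive number")
  }
  d <- distance_field(geom)
  new_window(exp(-d^2 / (2 * sigma^2)), "gaussian", list(sigma = sigma))
}

# Minimum distance from element (i, j) to a set of parallel diagonal band
# centre lines j = r*i + offset.  Used by the stripe window and its solver.
stripe_distance_field <- function(geom, n_bands) {
  geom <- as_geometry(geom)
  offsets <- (seq_len(n_bands) - 1L) * geom$n_out / n_bands
  # wrapped copies: bands re-enter from the lower-left except the main band
  offsets <- c(offsets, offsets[-1L] - geom$n_out)
  i <- 0:(geom$n_in - 1L)
  j <- 0:(geom$n_out - 1L)
  den <- sqrt(geom$n_in^2 + geom$n_out^2)
  d <- NULL
  for (off in offsets) {
    dk <- abs(outer(geom$n_out * i, geom$n_in * (j - off), `-`)) / den
    d <- if (is.null(d)) dk else pmin(d, dk)
  }
  d
}

#' Stripe window
#'
#' Union of `n_bands` parallel diagonal bands of half-width `threshold`.
#' Band centres are offset from the main diagonal by multiples of
#' `n_out / n_bands` in the output-index direction and wrap around the matrix,
#' so every stripe runs parallel to the diagonal.  With `n_bands = 1` this is
#' identical to [diagonal_window()].  The construction is this package's
#' reading of the usual stripe-window schematic.
#'
#' @param geom A [node_geometry()].
#' @param n_bands Positive integer number of stripes.
#' @param threshold Non-negative half-width of each stripe.
#' @return A binary `sz_window` with family `"stripe"`.
#' @export
stripe_window <- function(geom, n_bands, threshold) {
  geom <- as_geometry(geom)
  if (length(n_bands) != 1L || n_bands < 1 || n_bands != round(n_bands)) {
    stop("n_bands must be a single positive integer")
  }
  if (length(threshold) != 1L || !is.finite(threshold) || threshold < 0) {
    stop("threshold must be a single non-negative number")
  }
  f <- (stripe_distance_field(geom, n_bands) <= threshold) * 1
  if (sum(f) == 0) {
    stop("invalid window: stripe threshold ", format(threshold),
         " zeroes every element")
  }
  new_window(f, "stripe", list(n_bands = as.integer(n_bands),
                               threshold = threshold))
}

# Distance of each element from the matrix centre, both index axes scaled to
# [0, 1] so the radius is comparable across non-square matrices.  Offsets are
# computed with integer numerators (|2i - (n-1)| / (2(n-1))) so mirrored
# cells compare exactly equal and the mask is exactly symmetric.
centered_distance_field <- function(geom) {
  geom <- as_geometry(geom)
  du <- if (geom$n_in > 1L) {
    abs(2 * (0:(geom$n_in - 1L)) - (geom$n_in - 1L)) / (2 * (geom$n_in - 1L))
  } else 0
  dv <- if (geom$n_out > 1L) {
    abs(2 * (0:(geom$n_out - 1L)) - (geom$n_out - 1L)) / (2 * (geom$n_out - 1L))
  } else 0
  sqrt(outer(du^2, dv^2, `+`))
}

#' Centered window
#'
#' Retains the elements within Euclidean distance `radius` of the centre of
#' the weight matrix, with both index axes rescaled to a common `[0, 1]`
#' range (so `radius = sqrt(0.5)` covers the whole matrix).  This is this
#' package's reading of the usual centered-window schematic.
#'
#' @param geom A [node_geometry()].
#' @param radius Non-negative radius in scaled index units.
#' @return A binary `sz_window` with family `"centered"`.
#' @export
centered_window <- function(geom, radius) {
  geom <- as_geometry(geom)
  if (length(radius) != 1L || !is.finite(radius) || radius < 0) {
    stop("radius must be a single non-negative number")
  }
  f <- (centered_distance_field(geom) <= radius) * 1
  if (sum(f) == 0) {
    stop("invalid window: radius ", format(radius), " zeroes every element")
  }
  new_window(f, "centered", list(radius = radius))
}

#' Random window
#'
#' Retains an exact count `round(retain_fraction * n_in * n_out)` of
#' connections at uniformly random positions.  Exact-count sampling (rather
#' than independent Bernoulli draws) keeps the reduction axis exact so that
#' window families are compared at identical retained fractions.
#'
#' @param geom A [node_geometry()].
#' @param retain_fraction Fraction of connections to keep, in (0, 1].
#' @param seed Optional integer seed; the same seed reproduces the same mask
#'   without disturbing the global random-number state.
#' @return A binary `sz_window` with family `"random"`.
#' @export
random_window <- function(geom, retain_fraction, seed = NULL) {
  geom <- as_geometry(geom)
  if (length(retain_fraction) != 1L || !is.finite(retain_fraction) ||
      retain_fraction <= 0 || retain_fraction > 1) {
    stop("retain_fraction must be in (0, 1]")
  }
  n <- geom$n_in * geom$n_out
  m <- round(retain_fraction * n)
  if (m < 1) {
    stop("invalid window: retain_fraction ", format(retain_fraction),
         " rounds to zero retained elements")
  }
  keep <- with_local_seed(seed, sample.int(n, m))
  f <- matrix(0, geom$n_in, geom$n_out)
  f[keep] <- 1
  new_window(f, "random",
             list(retain_fraction = retain_fraction, seed = seed))
}

# Evaluate an expression under a temporary RNG seed, restoring global state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Retained fraction of a window
#'
#' The ratio between the sum of window elements and the total number of
#' weights, `sum(F) / (n_in * n_out)`.  The user-facing "parameter reduction"
#' is its complement, `1 - retained_fraction`; this package stores the
#' retained fraction and reports the reduction to avoid mixing the two.
#'
#' @param window An `sz_window` (or plain numeric matrix in `[0, 1]`).
#' @return The retained fraction, in (0, 1].
#' @export
retained_fraction <- function(window) {
  sum(window) / length(window)
}

#' Parameter reduction of a window
#'
#' @param window An `sz_window`.
#' @return `1 - retained_fraction(window)`, the eliminated share of weights.
#' @export
parameter_reduction <- function(window) {
  1 - retained_fraction(window)
}

# Achievable retained counts for a thresholded field: #(d <= t) over all
# distinct values t, plus 0.  `values` is any distance-like matrix.
field_retained_counts <- function(values) {
  r <- rle(sort(as.vector(values)))
  list(counts = c(0L, as.integer(cumsum(r$lengths))),
       thresholds = c(-Inf, r$values))
}

#' Retained counts achievable by a diagonal window
#'
#' Enumerates every retained count a [diagonal_window()] can produce on the
#' given geometry: the counts `#(d_ij <= t)` as the threshold `t` sweeps the
#' distinct distance values (plus the empty count 0).  Because ties enter
#' together, thresholds between two distinct distances all give the same
#' count, so this grid is exactly the set of achievable band sizes.
#'
#' @param geom A [node_geometry()].
#' @param cap Maximum matrix size `n_in * n_out` to enumerate (guards memory);
#'   larger geometries should use [solve_gaussian_sigma()]-style continuous
#'   windows instead.
#' @return Increasing integer vector of achievable counts; first element 0,
#'   last `n_in * n_out`.
#' @examples
#' achievable_retained_counts(node_geometry(5, 5))  # includes 5, 13, 25
#' @export
achievable_retained_counts <- function(geom, cap = 1e6) {
  geom <- as_geometry(geom)
  if (as.numeric(geom$n_in) * geom$n_out > cap) {
    stop(sprintf(
      "geometry %d x %d exceeds the enumeration cap (%g elements); use the continuous Gaussian solver instead",
      geom$n_in, geom$n_out, cap))
  }
  field_retained_counts(distance_field(geom))$counts
}

solve_field_threshold <- function(values, target_retained, what = "threshold") {
  if (length(target_retained) != 1L || !is.finite(target_retained) ||
      target_retained <= 0 || target_retained > 1) {
    stop("target_retained must be in (0, 1]")
  }
  fc <- field_retained_counts(values)
  n <- length(values)
  target_count <- target_retained * n
  gap <- abs(fc$counts - target_count)
  best <- which(gap == min(gap))
  idx <- max(best)  # ties snap toward the larger retained count
  if (fc$counts[idx] == 0L) {
    stop("invalid window: nearest achievable retained count is zero")
  }
  list(threshold = fc$thresholds[idx],
       achieved_retained = fc$counts[idx] / n)
}

#' Solve the diagonal-window threshold for a target retained fraction
#'
#' Requested reduction ratios are only meaningful on the grid of achievable
#' band sizes ([achievable_retained_counts()]).  This picks the threshold
#' whose retained count is nearest to `target_retained * n_in * n_out`,
#' breaking ties toward the larger count, and reports the fraction actually
#' achieved.
#'
#' @param geom A [node_geometry()].
#' @param target_retained Requested retained fraction, in (0, 1].
#' @return A list with `threshold` (a distance value; pass to
#'   [diagonal_window()]) and `achieved_retained` (exact resulting fraction).
#' @export
solve_diagonal_threshold <- function(geom, target_retained) {
  geom <- as_geometry(geom)
  solve_field_threshold(distance_field(geom), target_retained)
}

#' Solve the Gaussian window width for a target retained fraction
#'
#' The retained fraction `sum(exp(-d^2/(2 sigma^2))) / N` is strictly
#' increasing in `sigma`, so the width matching a target fraction is found by
#' bisection to within `tol` of the target.
#'
#' @param geom A [node_geometry()].
#' @param target_retained Target retained fraction, strictly between the
#'   zero-width floor (fraction of exactly-on-diagonal elements) and 1.
#' @param tol Convergence tolerance on the retained fraction.
#' @return The window width `sigma`.
#' @export
solve_gaussian_sigma <- function(geom, target_retained, tol = 1e-6) {
  geom <- as_geometry(geom)
  if (length(target_retained) != 1L || !is.finite(target_retained) ||
      target_retained <= 0 || target_retained >= 1) {
    stop("target_retained must be strictly inside (0, 1)")
  }
  d2 <- as.vector(distance_field(geom))^2
  g <- function(sigma) mean(exp(-d2 / (2 * sigma^2)))
  lo <- 1e-9
  floor_frac <- mean(d2 == 0)
  if (target_retained <= floor_frac) {
    stop(sprintf(
      "solver bracket failed: target %.6g is at or below the zero-width floor %.6g (fraction of on-diagonal elements)",
      target_retained, floor_frac))
  }
  hi <- 1
  while (g(hi) < target_retained) {
    hi <- hi * 2
    if (hi > 1e9) {
      stop(sprintf("solver bracket failed: retained fraction %.6g at sigma = %g still below target %.6g",
                   g(hi / 2), hi / 2, target_retained))
    }
  }
  mid <- (lo + hi) / 2
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    val <- g(mid)
    if (abs(val - target_retained) <= tol) break
    if (val < target_retained) lo <- mid else hi <- mid
  }
  mid
}

#' Build a window at a requested parameter reduction
#'
#' Convenience constructor used by the sweep protocols: takes the user-facing
#' parameter reduction (eliminated share) and dispatches to the family's
#' solver so the achieved reduction is as close as the family's grid allows.
#' `reduction = 0` always yields the full window.
#'
#' @param geom A [node_geometry()].
#' @param family One of `"diagonal"`, `"gaussian"`, `"stripe"`, `"centered"`,
#'   `"random"`, `"full"`.
#' @param reduction Requested eliminated share, in `[0, 1)`.
#' @param n_bands Stripe count (stripe family only).
#' @param seed Seed (random family only).
#' @return An `sz_window`.
#' @export
window_at_reduction <- function(geom, family = c("diagonal", "gaussian",
                                                 "stripe", "centered",
                                                 "random", "full"),
                                reduction = 0, n_bands = 2L, seed = NULL) {
  family <- match.arg(family)
  geom <- as_geometry(geom)
  if (length(reduction) != 1L || !is.finite(reduction) ||
      reduction < 0 || reduction >= 1) {
    stop("reduction must be in [0, 1)")
  }
  target <- 1 - reduction
  if (reduction == 0 || family == "full") return(full_window(geom))
  switch(family,
    diagonal = diagonal_window(
      geom, solve_diagonal_threshold(geom, target)$threshold),
    gaussian = gaussian_window(geom, solve_gaussian_sigma(geom, target)),
    stripe = {
      sol <- solve_field_threshold(stripe_distance_field(geom, n_bands), target)
      stripe_window(geom, n_bands, sol$threshold)
    },
    centered = {
      sol <- solve_field_threshold(centered_distance_field(geom), target)
      centered_window(geom, sol$threshold)
    },
    random = random_window(geom, target, seed = seed)
  )
}

#' Write a window to CSV
#'
#' Dense row-major CSV with `#`-prefixed header lines recording the family,
#' construction parameters and retained fraction, so the file round-trips
#' through [read_window_csv()].
#'
#' @param window An `sz_window`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_window_csv <- function(window, path) {
  p <- attr(window, "params")
  hdr <- c(
    sprintf("# family=%s", attr(window, "family")),
    sprintf("# retained_fraction=%.17g", attr(window, "retained_fraction")),
    sprintf("# params=%s",
            paste(names(p), vapply(p, function(v) format(v, digits = 17), ""),
                  sep = "=", collapse = ";"))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(unclass(window), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a window written by [write_window_csv()]
#'
#' @param path CSV file path.
#' @return An `sz_window`.
#' @export
read_window_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^# ", key, "="), "", ln[1L])
  }
  family <- get_field("family")
  params_raw <- get_field("params")
  params <- list()
  if (!is.null(params_raw) && nzchar(params_raw)) {
    for (kv in strsplit(params_raw, ";", fixed = TRUE)[[1L]]) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1L]]
      val <- suppressWarnings(as.numeric(parts[2L]))
      params[[parts[1L]]] <- if (is.na(val)) parts[2L] else val
    }
  }
  body <- lines[!grepl("^#", lines)]
  vals <- do.call(rbind, lapply(strsplit(body, ",", fixed = TRUE), as.numeric))
  new_window(vals, family %||% "full", params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
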