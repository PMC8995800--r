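# Intervention protocols as reproducible sweeps, plus session statistics.
#
# A "session" is one independent seeded train-and-evaluate run; sweeps report
# per-cell session errors and their means, mirroring how the reference
# error-versus-reduction curves are produced.  Bookkeeping differs between
# protocols: a disorganized sweep trains once per session and re-evaluates at
# every reduction, a developmental sweep trains once per (reduction, session)
# cell.

#' Order-independent cell seed derivation
#'
#' Maps `(base_seed, protocol, family, reduction, session index)` to a
#' deterministic 31-bit seed.  Keying on the reduction value (not its
#' position in the grid) makes every cell reproducible regardless of the
#' order in which grid points are executed.
#'
#' @param base_seed Integer base seed.
#' @param protocol,family Character labels.
#' @param reduction The cell's reduction value (0 for the training run of a
#'   disorganized session).
#' @param session_index 1-based session number.
#' @return A positive integer below 2^31.
#' @export
derive_seed <- function(base_seed, protocol, family, reduction,
                        session_index) {
  key <- sprintf("%s|%s|%.10g|%d", protocol, family, reduction,
                 session_index)
  h <- as.numeric(base_seed) %% 2147483647
  for (b in utf8ToInt(key)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h) + 1L
}

new_sweep <- function(protocol, family, reductions, sessions_df, base_seed,
                      failures = list()) {
  means <- stats::aggregate(error ~ reduction, data = sessions_df, FUN = mean)
  means <- means[order(means$reduction), ]
  structure(list(protocol = protocol, family = family,
                 reductions = sort(unique(reductions)),
                 sessions = sessions_df, means = means,
                 base_seed = base_seed, failures = failures),
            class = "sz_sweep")
}

#' @export
print.sz_sweep <- function(x, ...) {
  cat(sprintf("%s sweep, %s window: %d reductions x %d sessions (base seed %d)\n",
              x$protocol, x$family, length(x$reductions),
              max(x$sessions$session), x$base_seed))
  m <- x$means
  m$mean_error <- sprintf("%.4f", m$error)
  m$error <- NULL
  print(m, row.names = FALSE)
  if (length(x$failures)) {
    cat(sprintf("%d failed (diverged) cells excluded from means\n",
                length(x$failures)))
  }
  invisible(x)
}

#' Plot a sweep as an error-versus-reduction curve
#'
#' @param x An `sz_sweep`.
#' @param add Add to an existing plot.
#' @param col Line colour.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sz_sweep <- function(x, add = FALSE, col = "red", ...) {
  m <- x$means
  if (!add) {
    graphics::plot(100 * m$reduction, m$error, type = "b", col = col,
                   xlab = "parameter reduction (%)",
                   ylab = "mean classification error",
                   main = sprintf("%s model, %s window", x$protocol,
                                  x$family), ...)
  } else {
    graphics::lines(100 * m$reduction, m$error, type = "b", col = col, ...)
  }
  invisible(x)
}

sweep_cell <- function(expr, failures, key) {
  tryCatch(list(value = expr, failures = failures),
           sz_training_error = function(e) {
             failures[[key]] <- conditionMessage(e)
             list(value = NA_real_, failures = failures)
           })
}

#' Developmental-protocol sweep
#'
#' For every reduction and session, a network is built with the window at
#' that reduction, trained fully under the mask, and evaluated — the
#' in-training intervention.  Reduction 0 is the fully connected baseline.
#' Each cell uses [derive_seed()] for its initialization and shuffling, so
#' results do not depend on execution order.  Diverged sessions are recorded
#' in `failures` and excluded from the means.
#'
#' @param config A developmental-protocol [network_config()] (A, C, E or a
#'   scaled variant).
#' @param dataset A list with `train` and `test` `ImageDataset`s.
#' @param reductions Numeric vector of eliminated shares in `[0, 1)`;
#'   include 0 to get the baseline cell.
#' @param sessions Sessions per reduction.
#' @param base_seed Integer base seed.
#' @param family Window family for the masked layers.
#' @param schedule Optional [training_schedule()] override.
#' @param trace_every Trace interval forwarded to [train()]; sweeps only
#'   need the final-epoch evaluation, so per-epoch tracing is off by default.
#' @return An `sz_sweep`: long per-session table, per-reduction means,
#'   failures.
#' @export
run_developmental_sweep <- function(config, dataset, reductions = c(0, 0.5),
                                    sessions = 3L, base_seed = 1L,
                                    family = "diagonal", schedule = NULL,
                                    trace_every = 1000000L) {
  if (config$protocol != "developmental") {
    stop("config must use the developmental protocol")
  }
  if (any(reductions < 0 | reductions >= 1)) {
    stop("reductions must lie in [0, 1)")
  }
  rows <- list()
  failures <- list()
  for (ri in seq_along(reductions)) {
    red <- reductions[ri]
    cfg <- config
    cfg$window$family <- family
    cfg$window$reduction <- red
    for (si in seq_len(sessions)) {
      seed <- derive_seed(base_seed, "developmental", family, red, si)
      res <- sweep_cell({
        model <- build_network(cfg, seed = seed)
        model <- train(model, dataset, schedule = schedule, seed = seed,
                       trace_every = trace_every)
        evaluate(model, dataset$test)
      }, failures, sprintf("r%g.s%d", red, si))
      failures <- res$failures
      rows[[length(rows) + 1L]] <- data.frame(
        protocol = "developmental", family = family, reduction = red,
        session = si, seed = seed, error = res$value)
    }
  }
  df <- do.call(rbind, rows)
  new_sweep("developmental", family, reductions,
            df[is.finite(df$error), , drop = FALSE], base_seed, failures)
}

#' Disorganized-protocol sweep
#'
#' Each session trains the network once without any window, then evaluates it
#' at every reduction in the grid by attaching the window to the trained
#' target layer ([disorganize_model()]) — the post-training intervention.
#' The reduction-0 cell is the unmasked evaluation.
#'
#' @inheritParams run_developmental_sweep
#' @param config A disorganized-protocol [network_config()] (B, D or a scaled
#'   variant).
#' @return An `sz_sweep`.
#' @export
run_disorganized_sweep <- function(config, dataset, reductions = c(0, 0.5),
                                   sessions = 3L, base_seed = 1L,
                                   family = "diagonal", schedule = NULL,
                                   trace_every = 1000000L) {
  if (config$protocol != "disorganized") {
    stop("config must use the disorganized protocol")
  }
  if (any(reductions < 0 | reductions >= 1)) {
    stop("reductions must lie in [0, 1)")
  }
  rows <- list()
  failures <- list()
  for (si in seq_len(sessions)) {
    seed <- derive_seed(base_seed, "disorganized", family, 0, si)
    res <- sweep_cell({
      model <- build_network(config, seed = seed)
      train(model, dataset, schedule = schedule, seed = seed,
            trace_every = trace_every)
    }, failures, sprintf("s%d", si))
    failures <- res$failures
    model <- res$value
    for (ri in seq_along(reductions)) {
      red <- reductions[ri]
      err <- if (!is.list(model)) NA_real_ else if (red == 0) {
        evaluate(model, dataset$test)
      } else {
        lay <- model$layers[[model$sz_target_index]]
        win <- window_at_reduction(
          node_geometry(nrow(lay$W), ncol(lay$W)), family = family,
          reduction = red, seed = derive_seed(base_seed, "disorganized",
                                              family, red, si))
        evaluate(disorganize_model(model, win), dataset$test)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        protocol = "disorganized", family = family, reduction = red,
        session = si, seed = seed, error = err)
    }
  }
  df <- do.call(rbind, rows)
  new_sweep("disorganized", family, reductions,
            df[is.finite(df$error), , drop = FALSE], base_seed, failures)
}

#' Two-sided rank-sum comparison of session errors
#'
#' Compares two samples of independent session errors with the two-sided
#' Wilcoxon rank-sum (Mann-Whitney) test: exact for small untied samples
#' (both sizes at most 12), normal approximation with tie correction
#' otherwise.  Sessions are independent runs, hence the unpaired rank-sum
#' form.  Significance is flagged at p < 0.05.
#'
#' @param errors_a,errors_b Non-empty numeric samples.
#' @param labels Length-2 character labels for reporting.
#' @return A list of class `sz_comparison`: `p_value`, `statistic` (the
#'   Mann-Whitney U for the first sample), `significant`, `method`, `note`.
#' @examples
#' wilcoxon_compare(1:10, 11:20)  # complete separation: p = 2/choose(20, 10)
#' @export
wilcoxon_compare <- function(errors_a, errors_b, labels = c("a", "b")) {
  if (!length(errors_a) || !length(errors_b)) {
    stop("both samples must be non-empty")
  }
  note <- NULL
  if (length(unique(c(errors_a, errors_b))) == 1L) {
    p <- 1
    stat <- length(errors_a) * length(errors_b) / 2
    method <- "degenerate (all values identical)"
    note <- "all values identical across both samples; test is degenerate"
  } else {
    ties <- any(duplicated(c(errors_a, errors_b)))
    use_exact <- length(errors_a) <= 12L && length(errors_b) <= 12L && !ties
    ht <- suppressWarnings(stats::wilcox.test(errors_a, errors_b,
                                              exact = use_exact,
                                              correct = !use_exact))
    p <- min(ht$p.value, 1)
    stat <- unname(ht$statistic)
    method <- if (use_exact) "exact rank-sum" else
      "rank-sum, normal approximation with tie correction"
  }
  structure(list(labels = labels, n = c(length(errors_a), length(errors_b)),
                 statistic = stat, p_value = p, significant = p < 0.05,
                 method = method, note = note),
            class = "sz_comparison")
}

#' @export
print.sz_comparison <- function(x, ...) {
  cat(sprintf("two-sided Wilcoxon rank-sum: %s (n=%d) vs %s (n=%d)\n",
              x$labels[1L], x$n[1L], x$labels[2L], x$n[2L]))
  cat(sprintf("U = %g, p = %.4g (%s)%s\n", x$statistic, x$p_value, x$method,
              if (x$significant) " *significant at 0.05*" else ""))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Tabulate one or more sweeps
#'
#' Binds sweeps that share a reduction grid into a long-format session table
#' and a per-(protocol, family, reduction) means table, both with
#' deterministic ordering, optionally written as CSV.
#'
#' @param sweeps A single `sz_sweep` or a list of them.
#' @param long_csv,means_csv Optional output paths.
#' @return List with data frames `long` and `means`.
#' @export
summarize_sweeps <- function(sweeps, long_csv = NULL, means_csv = NULL) {
  if (inherits(sweeps, "sz_sweep")) sweeps <- list(sweeps)
  grids <- lapply(sweeps, function(s) s$reductions)
  if (length(unique(vapply(grids, paste, "", collapse = ","))) != 1L) {
    stop("sweeps use different reduction grids: ",
         paste(vapply(grids, paste, "", collapse = ","), collapse = " vs "))
  }
  long <- do.call(rbind, lapply(sweeps, function(s) s$sessions))
  long <- long[order(long$protocol, long$family, long$reduction,
                     long$session), ]
  rownames(long) <- NULL
  means <- stats::aggregate(error ~ protocol + family + reduction,
                            data = long, FUN = mean)
  names(means)[names(means) == "error"] <- "mean_error"
  counts <- stats::aggregate(error ~ protocol + family + reduction,
                             data = long, FUN = length)
  means$n_sessions <- counts$error
  means <- means[order(means$protocol, means$family, means$reduction), ]
  rownames(means) <- NULL
  if (!is.null(long_csv)) utils::write.csv(long, long_csv, row.names = FALSE)
  if (!is.null(means_csv)) utils::write.csv(means, means_csv, row.names = FALSE)
  list(long = long, means = means)
}
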