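# Ensemble analysis: mean activation, oscillation amplitude/phase per
# period, convergence detection and desynchronization.

new_ensemble_summary <- function(mean_matrix, runs) {
  tb <- tibble::tibble(
    time = rep(as.integer(rownames(mean_matrix)), times = ncol(mean_matrix)),
    node = rep(colnames(mean_matrix), each = nrow(mean_matrix)),
    mean = as.vector(mean_matrix)
  )
  structure(tb, class = c("ensemble_summary", class(tb)), runs = runs)
}

#' Per-step per-node ensemble mean activation
#'
#' Averages the Boolean state of each node over all runs, giving an
#' activation probability in `[0, 1]` at every time point.
#'
#' @param ensemble A `trajectory_ensemble`.
#' @return An `ensemble_summary`: a tibble with columns `time`, `node`,
#'   `mean` (attribute `runs` records the ensemble size).
#' @export
ensemble_mean <- function(ensemble) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  mm <- apply(ensemble$values, c(2, 3), mean)
  if (is.null(dim(mm))) mm <- matrix(mm, nrow = 1L)
  dimnames(mm) <- list(0:ensemble$steps, ensemble$nodes)
  new_ensemble_summary(mm, runs = ensemble$runs)
}

summary_series <- function(summary, node) {
  s <- summary[summary$node == node, ]
  if (nrow(s) == 0L) stop(sprintf("unknown node '%s' in summary", node), call. = FALSE)
  s <- s[order(s$time), ]
  stats::setNames(s$mean, s$time)
}

#' Amplitude and phase of a mean trace within one period
#'
#' The period grid comes from the deterministic reference trajectory (the
#' cycle length of the qualitative model, see [detect_cycle()]); period `i`
#' covers time steps `[(i-1) * period_length, i * period_length - 1]`.
#' Amplitude is max - min of the mean trace within the window; phase is the
#' offset of the maximum within the window (ties broken towards the
#' earliest step).
#'
#' @param summary An `ensemble_summary`.
#' @param node Node id.
#' @param period_length Cycle length of the deterministic reference, in steps.
#' @param period_index 1-based period number.
#' @return A tibble with columns `node`, `period`, `amplitude`, `phase`.
#' @export
period_amplitude_phase <- function(summary, node, period_length, period_index) {
  stopifnot(period_length >= 1L, all(period_index >= 1L))
  series <- summary_series(summary, node)
  times <- as.integer(names(series))
  purrr::map_dfr(period_index, function(i) {
    win <- ((i - 1L) * period_length):(i * period_length - 1L)
    if (max(win) > max(times)) {
      stop(sprintf("period %d window [%d, %d] exceeds the series (max time %d)",
                   i, min(win), max(win), max(times)), call. = FALSE)
    }
    vals <- series[match(win, times)]
    tibble::tibble(node = node, period = i,
                   amplitude = max(vals) - min(vals),
                   phase = win[which.max(vals)] - min(win))
  })
}

#' Convergence of a mean trace to a steady level
#'
#' A node's trace has converged when the spread (max - min) of its trailing
#' window is at most `tolerance`; the level is the trailing-window mean.
#'
#' @param summary An `ensemble_summary`.
#' @param node Node id.
#' @param tolerance Maximal spread within the window.
#' @param window Trailing-window length in time points.
#' @return A tibble with columns `node`, `converged`, `level`.
#' @export
detect_convergence <- function(summary, node, tolerance = 0.05, window = 50L) {
  series <- summary_series(summary, node)
  if (window > length(series)) stop("window exceeds series length", call. = FALSE)
  tail_vals <- utils::tail(series, window)
  tibble::tibble(node = node,
                 converged = (max(tail_vals) - min(tail_vals)) <= tolerance,
                 level = mean(tail_vals))
}

#' First time a mean trace has converged
#'
#' Earliest time `t` such that the window of `window` points ending at `t`
#' has spread at most `tolerance`; `Inf` if the trace never converges
#' within the series.
#'
#' @inheritParams detect_convergence
#' @return A single number (time step or `Inf`).
#' @export
first_convergence_time <- function(summary, node, tolerance = 0.05, window = 50L) {
  series <- summary_series(summary, node)
  n <- length(series)
  if (window > n) stop("window exceeds series length", call. = FALSE)
  times <- as.integer(names(series))
  # running min/max over trailing windows
  for (end in window:n) {
    vals <- series[(end - window + 1L):end]
    if (max(vals) - min(vals) <= tolerance) return(times[end])
  }
  Inf
}

#' Desynchronization index of a node at a time point
#'
#' Quantifies loss of synchrony between runs as `4 * p * (1 - p)` where `p`
#' is the cross-run mean activation at `(t, node)`: 0 when all runs agree,
#' 1 at maximal disagreement (p = 0.5). Damping of the ensemble-mean
#' oscillation while individual runs still oscillate shows up as this index
#' rising over time.
#'
#' @param ensemble A `trajectory_ensemble` with at least 2 runs.
#' @param node Node id.
#' @param time Time step(s), in `0..steps`.
#' @return Numeric vector, one value per requested time, in `[0, 1]`.
#' @export
desynchronization_index <- function(ensemble, node, time) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"), ensemble$runs >= 2L)
  if (!node %in% ensemble$nodes) stop(sprintf("unknown node '%s'", node), call. = FALSE)
  if (any(time < 0 | time > ensemble$steps)) stop("time outside the simulated range", call. = FALSE)
  p <- vapply(time, function(t) mean(ensemble$values[, t + 1L, node]), numeric(1))
  4 * p * (1 - p)
}

#' Detect the cycle of a deterministic trajectory
#'
#' Finds the smallest period with which the full network state recurs at
#' the end of a deterministic synchronous trajectory, together with the
#' first time the cyclic segment is entered.
#'
#' @param trajectory A tibble from [simulate_run()] (column `time` plus one
#'   column per node).
#' @return A list with `period` (integer, `NA` if no recurrence is seen)
#'   and `start` (first time index of the detected cycle).
#' @export
detect_cycle <- function(trajectory) {
  mat <- as.matrix(trajectory[, setdiff(names(trajectory), "time")])
  keys <- apply(mat, 1L, paste, collapse = "")
  n <- length(keys)
  last <- keys[n]
  earlier <- which(keys[-n] == last)
  if (length(earlier) == 0L) return(list(period = NA_integer_, start = NA_integer_))
  prev <- max(earlier)
  period <- n - prev
  # walk back to the entry point of the cyclic segment
  start <- prev
  while (start - period >= 1L && keys[start - period] == keys[start]) {
    start <- start - 1L
  }
  list(period = as.integer(period), start = trajectory$time[start])
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> %d time points x %d nodes (runs = %s)\n",
              length(unique(x$time)), length(unique(x$node)),
              attr(x, "runs") %||% "?"))
  NextMethod()
}

#' @method tidy ensemble_summary
#' @export
tidy.ensemble_summary <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("time", "node", "mean")])
}

#' @method glance ensemble_summary
#' @export
glance.ensemble_summary <- function(x, ...) {
  tibble::tibble(time_points = length(unique(x$time)),
                 nodes = length(unique(x$node)),
                 runs = attr(x, "runs") %||% NA_integer_)
}

#' Plot ensemble-mean activation traces
#'
#' @param object An `ensemble_summary`.
#' @param nodes Optional subset of nodes to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ensemble_summary
#' @export
autoplot.ensemble_summary <- function(object, nodes = NULL, ...) {
  df <- tidy.ensemble_summary(object)
  if (!is.null(nodes)) df <- df[df$node %in% nodes, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean,
                                   colour = .data$node)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "time step", y = "mean activation", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heat-map of mean activation (nodes by time)
#'
#' @param summary An `ensemble_summary`.
#' @return A ggplot object.
#' @export
plot_state_heatmap <- function(summary) {
  df <- tidy.ensemble_summary(summary)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$node,
                                   fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "navy", high = "gold", limits = c(0, 1)) +
    ggplot2::labs(x = "time step", y = NULL, fill = "P(active)") +
    ggplot2::theme_minimal()
}

#' Write per-time metrics or means as TSV
#'
#' Long-format writer: `ensemble_summary` rows (`time`, `node`, `mean`) or
#' any metrics tibble are written with a header and tab separation.
#'
#' @param x A tibble.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_tsv_metrics <- function(x, file) {
  utils::write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Ensemble-mean trajectories in wide TSV layout
#'
#' One row per time point, one column per node, mirroring the trajectory
#' writer layout but with real-valued means.
#'
#' @param summary An `ensemble_summary`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_mean_tsv <- function(summary, file) {
  wide <- tidyr::pivot_wider(tidy.ensemble_summary(summary),
                             names_from = "node", values_from = "mean")
  utils::write.table(as.data.frame(wide, check.names = FALSE), file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

read_mean_tsv <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  mm <- as.matrix(df[, setdiff(names(df), "time"), drop = FALSE])
  rownames(mm) <- df$time
  new_ensemble_summary(mm, runs = NA_integer_)
}
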