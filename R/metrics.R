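#' Food transport efficiency series E(tau)
#'
#' The transport efficiency at time tau is the scaled average number of
#' food particles delivered to the nest per termite and per unit time,
#'
#'   E(tau) = s * sum_{t=1}^{tau} food(t) / (tau * N0),
#'
#' where `food(t)` counts nest deliveries during step t, `N0` is the colony
#' size and `s` a scaling factor (default 10000) that keeps the values away
#' from zero.
#'
#' @param food_per_step Integer vector of deliveries per step, `food(t)`.
#' @param n0 Colony size N0 (>= 1).
#' @param s Scaling factor (> 0), default 10000.
#' @return An object of class `"efficiency_series"`: list with `values`
#'   (E(tau) for tau = 1..T), `s`, `n0`.
#' @examples
#' efficiency_series(c(0, 0, 1, 1), n0 = 10)$values  # ends at 500
#' @export
efficiency_series <- function(food_per_step, n0, s = 10000) {
  if (length(n0) != 1L || !is.finite(n0) || n0 < 1)
    stop("`n0` must be a single count >= 1", call. = FALSE)
  if (length(s) != 1L || !is.finite(s) || s <= 0)
    stop("`s` must be a single positive scale", call. = FALSE)
  if (any(food_per_step < 0))
    stop("`food_per_step` entries must be non-negative", call. = FALSE)
  tau <- seq_along(food_per_step)
  structure(list(values = s * cumsum(food_per_step) / (tau * n0),
                 s = s, n0 = n0),
            class = "efficiency_series")
}

#' @export
print.efficiency_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("Efficiency series E(tau), tau = 1..%d (s = %g, N0 = %d)\n",
              n, x$s, x$n0))
  cat(sprintf("  final E(T) = %.4f, max = %.4f\n",
              x$values[n], max(x$values)))
  invisible(x)
}

#' Steady-state efficiency E
#'
#' The scalar efficiency E of a run is the arithmetic mean of E(tau) over a
#' late, converged window of the series; with the default horizon of 5000
#' steps the window is 4500 <= tau <= 5000, endpoints included.
#'
#' @param series An [efficiency_series()] object (or bare numeric vector).
#' @param window Inclusive `c(from, to)` timestep window.
#' @return Mean of E(tau) over the window.
#' @export
steady_state_E <- function(series, window = c(4500, 5000)) {
  values <- if (inherits(series, "efficiency_series")) series$values
            else as.numeric(series)
  if (length(window) != 2L || window[1] > window[2])
    stop("`window` must be c(from, to) with from <= to", call. = FALSE)
  if (window[1] < 1 || window[2] > length(values))
    stop("window [", window[1], ", ", window[2],
         "] outside series of length ", length(values), call. = FALSE)
  mean(values[window[1]:window[2]])
}

#' Spatial frequency map of traffic jams
#'
#' Tallies jam events per cell and max-normalizes the counts, so 1.0 marks
#' the cell where jams were most frequent.
#'
#' @param jam_events Data frame with a `cell` column (as in
#'   `run_sim()$jam_events`), or an integer vector of jam cells.
#' @param network The [build_network()] object the events refer to.
#' @return An object of class `"jam_map"`: data frame with one row per cell
#'   (`cell`, `tunnel_class`, `count`, `normalized`).
#' @export
jam_frequency_map <- function(jam_events, network) {
  cells <- if (is.data.frame(jam_events)) jam_events$cell else jam_events
  cells <- as.integer(cells)
  if (length(cells) && (any(cells < 0L) || any(cells >= network$n_cells)))
    stop("jam events reference cells outside the network", call. = FALSE)
  counts <- tabulate(cells + 1L, nbins = network$n_cells)
  mx <- max(counts)
  out <- data.frame(cell = 0:(network$n_cells - 1L),
                    tunnel_class = network$tunnel_class,
                    count = counts,
                    normalized = if (mx > 0L) counts / mx else
                      rep(0, network$n_cells))
  class(out) <- c("jam_map", "data.frame")
  out
}

#' @export
plot.jam_map <- function(x, ...) {
  graphics::plot(x$cell, x$normalized, type = "h", xlab = "cell",
                 ylab = "normalized jam frequency", ...)
  invisible(x)
}

#' Write a run's time series or a jam map to CSV
#'
#' @param x A `"termite_sim"` or `"jam_map"` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path) {
  if (inherits(x, "jam_map")) {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  } else if (inherits(x, "termite_sim")) {
    tt <- length(x$food_per_step)
    jam_count <- tabulate(x$jam_events$t, nbins = tt)
    utils::write.csv(
      data.frame(t = seq_len(tt), food_t = x$food_per_step,
                 E_tau = as.numeric(x$E_series$values),
                 jam_count = jam_count),
      path, row.names = FALSE)
  } else stop("don't know how to serialize objects of class ",
              paste(class(x), collapse = "/"), call. = FALSE)
  invisible(path)
}

#' Write a run summary (config echo, totals, jam events) to JSON
#'
#' @param x A `"termite_sim"` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_json <- function(x, path) {
  cfg <- x$config
  payload <- list(
    config = unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
    E = x$E,
    window = x$window,
    first_delivery = x$first_delivery,
    total_pickups = x$total_pickups,
    total_deliveries = x$total_deliveries,
    jam_events = x$jam_events)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
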