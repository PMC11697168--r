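#' Simulation configuration
#'
#' Collects every parameter of the transport simulation.  Defaults follow
#' the published model where the model states them: horizon `steps = 5000`,
#' efficiency scaling `s = 10000`, trophallaxis `transfer_prob = 0.5`, jams
#' triggered by `jam_size = 4` co-located termites with balanced headings.
#' The colony size (`n0 = 100`) and the jam immobilization time
#' (`jam_duration = 5` steps) are free model parameters; see the package
#' vignette for the rationale behind their defaults.
#'
#' @param delta Loop-tunnel position, 1 (near nest), 2 (centred) or 3 (near
#'   food); passed to [build_network()].
#' @param p1,p2,p3,p4 Branch probabilities at nodes `a`, `b`, `c`, `d`, each
#'   in `[0, 1]`.  `p1` sends food-bound termites at `a` into the loop, `p3`
#'   sends nest-bound termites at `c` into the loop, and `p2`/`p4` send
#'   termites across the zero-cost separation tunnel from `b`/`d`.
#' @param n0 Number of simulated termites (colony size), at least 1.
#' @param steps Simulation horizon T in timesteps.
#' @param s Scaling factor of the efficiency statistic (see
#'   [efficiency_series()]).
#' @param transfer_prob Probability that a food-carrying termite passes its
#'   particle to an empty termite met head-on (both then reverse).
#' @param jam_size Number of co-located free termites whose heading vectors
#'   must cancel to trigger a traffic jam.
#' @param jam_duration Timesteps a jammed termite stays immobilized.
#' @param main_length,loop_length Tunnel dimensions, see [build_network()].
#' @param seed Optional integer seed making [run_sim()] reproducible.
#'
#' @return An object of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(delta = 2, p3 = 1, p4 = 1, n0 = 20, steps = 200, seed = 1)
#' cfg
#' @export
sim_config <- function(delta = 2, p1 = 0.1, p2 = 0.1, p3 = 0.4, p4 = 0.4,
                       n0 = 100, steps = 5000, s = 10000,
                       transfer_prob = 0.5, jam_size = 4, jam_duration = 5,
                       main_length = 500, loop_length = 200, seed = NULL) {
  probs <- c(p1 = p1, p2 = p2, p3 = p3, p4 = p4)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("branch probabilities p1..p4 must lie in [0, 1]", call. = FALSE)
  if (!is.finite(transfer_prob) || transfer_prob < 0 || transfer_prob > 1)
    stop("`transfer_prob` must lie in [0, 1]", call. = FALSE)
  n0 <- as.integer(n0)
  steps <- as.integer(steps)
  if (is.na(n0) || n0 < 1L) stop("`n0` must be at least 1", call. = FALSE)
  if (is.na(steps) || steps < 1L) stop("`steps` must be at least 1",
                                       call. = FALSE)
  if (s <= 0) stop("scaling factor `s` must be positive", call. = FALSE)
  jam_size <- as.integer(jam_size)
  jam_duration <- as.integer(jam_duration)
  if (is.na(jam_size) || jam_size < 2L)
    stop("`jam_size` must be at least 2", call. = FALSE)
  if (is.na(jam_duration) || jam_duration < 0L)
    stop("`jam_duration` must be non-negative", call. = FALSE)

  structure(
    list(delta = as.integer(delta), p1 = p1, p2 = p2, p3 = p3, p4 = p4,
         n0 = n0, steps = steps, s = s, transfer_prob = transfer_prob,
         jam_size = jam_size, jam_duration = jam_duration,
         main_length = as.integer(main_length),
         loop_length = as.integer(loop_length),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Transport simulation configuration\n")
  cat(sprintf("  network     : delta = %d, main %d cells, loop %d cells\n",
              x$delta, x$main_length, x$loop_length))
  cat(sprintf("  branching   : P1 = %.2f  P2 = %.2f  P3 = %.2f  P4 = %.2f\n",
              x$p1, x$p2, x$p3, x$p4))
  cat(sprintf("  colony      : N0 = %d termites, T = %d steps\n",
              x$n0, x$steps))
  cat(sprintf("  behaviour   : transfer prob %.2f, jam at %d balanced",
              x$transfer_prob, x$jam_size))
  cat(sprintf(" termites for %d steps\n", x$jam_duration))
  cat(sprintf("  efficiency  : s = %g; seed = %s\n", x$s,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

# Precomputed movement tables: for every cell, the next cell when continuing
# along the current tunnel toward the food site or toward the nest.
# Endpoints map to themselves (resolved by handle_endpoints).
sim_engine <- function(network) {
  m <- network$main_length
  l <- network$loop_length
  lo1 <- m                     # loop cell adjacent to node a
  lo2 <- m + l - 1L            # loop cell adjacent to node c
  a <- network$nodes[["a"]]; b <- network$nodes[["b"]]
  cc <- network$nodes[["c"]]; d <- network$nodes[["d"]]

  fwd_food <- integer(m + l)
  fwd_nest <- integer(m + l)
  main <- 0:(m - 1L)
  fwd_food[main + 1L] <- pmin(main + 1L, m - 1L)
  fwd_nest[main + 1L] <- pmax(main - 1L, 0L)
  loop <- lo1:lo2
  fwd_food[loop + 1L] <- loop + 1L
  fwd_food[lo2 + 1L] <- cc
  fwd_nest[loop + 1L] <- loop - 1L
  fwd_nest[lo1 + 1L] <- a

  list(fwd_food = fwd_food, fwd_nest = fwd_nest,
       a = a, b = b, c = cc, d = d, loop_first = lo1, loop_last = lo2,
       nest = network$nest_cell, food = network$food_cell)
}

# Vectorized one-step displacement for free termites.  Each termite first
# (optionally) crosses the zero-cost separation edge if it stands on node b
# or d, at most once, then takes exactly one unit-cost move toward its goal;
# at nodes a/c the loop branch is taken with probability p1/p3 but never
# against the direction of travel.
move_cells <- function(cells, headings, eng, probs, u_sep, u_branch) {
  at_b <- cells == eng$b
  at_d <- cells == eng$d
  cells[at_b & u_sep < probs[["p2"]]] <- eng$d
  cells[at_d & u_sep < probs[["p4"]]] <- eng$b

  nxt <- eng$fwd_nest[cells + 1L]
  fb <- headings > 0L
  nxt[fb] <- eng$fwd_food[cells[fb] + 1L]
  branch_a <- cells == eng$a & headings > 0L & u_branch < probs[["p1"]]
  branch_c <- cells == eng$c & headings < 0L & u_branch < probs[["p3"]]
  nxt[branch_a] <- eng$loop_first
  nxt[branch_c] <- eng$loop_last
  as.integer(nxt)
}

#' Initialize the simulation state
#'
#' Places `n0` termites uniformly at random on main-tunnel cells with
#' uniformly random headings; no termite carries food at t = 0 and none is
#' jammed.
#'
#' @param config A [sim_config()].
#' @param network A [build_network()] object matching the configuration.
#' @return A state list with parallel vectors `cell`, `heading`
#'   (`+1` = toward food, `-1` = toward nest), `carrying`, `jam_timer`.
#' @export
init_state <- function(config, network) {
  n <- config$n0
  if (n < 1L) stop("`n0` must be positive", call. = FALSE)
  list(cell = sample(0:(network$main_length - 1L), n, replace = TRUE),
       heading = sample(c(1L, -1L), n, replace = TRUE),
       carrying = rep(FALSE, n),
       jam_timer = rep(0L, n))
}

#' Next cell for a single free termite
#'
#' One termite's displacement in one timestep: an optional zero-cost hop
#' across the separation tunnel (if it stands on node `b` or `d`, with
#' probability `p2`/`p4`) followed by one unit-cost move toward its goal,
#' taking the loop branch at node `a` (food-bound, probability `p1`) or `c`
#' (nest-bound, probability `p3`).  Branch choice never reverses the termite
#' relative to its goal.
#'
#' @param termite A list with elements `cell` and `heading` (+1 toward food,
#'   -1 toward nest).
#' @param network A [build_network()] object.
#' @param probs Named list or vector with `p1`, `p2`, `p3`, `p4`.
#' @return The cell index occupied after the move.
#' @export
choose_next_cell <- function(termite, network, probs) {
  eng <- sim_engine(network)
  move_cells(as.integer(termite$cell), as.integer(termite$heading), eng,
             as.list(probs), stats::runif(1L), stats::runif(1L))
}

# cells with more than one free termite; helper shared by encounter and jam
# phases
multi_cells <- function(cells) {
  unique(cells[duplicated(cells)])
}

#' Resolve trophallaxis encounters
#'
#' A food-carrying termite that meets an empty termite head-on (same cell,
#' opposite headings) passes its particle with probability `transfer_prob`;
#' on a transfer both termites reverse heading, otherwise they pass without
#' interacting.  Carrier/carrier and empty/empty meetings never interact.
#' When several pairings are possible on one cell, pairs are formed in
#' random order and each termite takes part in at most one encounter per
#' step.  Jammed termites do not interact.
#'
#' @param state A state list as returned by [init_state()].
#' @param transfer_prob Transfer probability (model default 0.5).
#' @return The updated state list.
#' @export
resolve_encounters <- function(state, transfer_prob = 0.5) {
  free <- which(state$jam_timer == 0L)
  if (length(free) < 2L) return(state)
  for (cl in multi_cells(state$cell[free])) {
    here <- free[state$cell[free] == cl]
    for (h in c(1L, -1L)) {
      carriers <- here[state$carrying[here] & state$heading[here] == h]
      empties <- here[!state$carrying[here] & state$heading[here] == -h]
      np <- min(length(carriers), length(empties))
      if (np == 0L) next
      if (length(carriers) > 1L) carriers <- sample(carriers)
      if (length(empties) > 1L) empties <- sample(empties)
      transfer <- stats::runif(np) < transfer_prob
      ci <- carriers[seq_len(np)][transfer]
      ei <- empties[seq_len(np)][transfer]
      state$carrying[ci] <- FALSE
      state$carrying[ei] <- TRUE
      state$heading[ci] <- -state$heading[ci]
      state$heading[ei] <- -state$heading[ei]
    }
  }
  state
}

#' Detect traffic jams and immobilize the termites involved
#'
#' A traffic jam forms on every cell occupied by at least `jam_size` free
#' termites whose heading vectors (+1 toward food, -1 toward nest) sum to
#' zero.  All free termites on a jammed cell are immobilized for
#' `jam_duration` steps; they keep their headings and resume afterwards.
#'
#' @inheritParams resolve_encounters
#' @param jam_size Minimum number of balanced termites (model default 4).
#' @param jam_duration Immobilization time in steps.
#' @return A list with the updated `state` and `jam_cells`, the cell ids on
#'   which a jam formed this step (one entry per jam event).
#' @export
detect_and_apply_jams <- function(state, jam_size = 4, jam_duration = 5) {
  free <- which(state$jam_timer == 0L)
  jam_cells <- integer(0)
  if (length(free) >= jam_size) {
    for (cl in multi_cells(state$cell[free])) {
      here <- free[state$cell[free] == cl]
      if (length(here) >= jam_size && sum(state$heading[here]) == 0L) {
        state$jam_timer[here] <- as.integer(jam_duration)
        jam_cells <- c(jam_cells, cl)
      }
    }
  }
  list(state = state, jam_cells = jam_cells)
}

#' Pickup at the food site, deposit at the nest
#'
#' Any empty termite standing on the food cell picks up one particle (the
#' food supply is unlimited) and heads back to the nest; any carrying
#' termite standing on the nest cell deposits exactly one particle and heads
#' back to the food site.  Termites at an endpoint always leave it facing
#' inward.
#'
#' @inheritParams resolve_encounters
#' @param network A [build_network()] object.
#' @return A list with the updated `state`, the number of `deliveries` this
#'   step, and the number of `pickups`.
#' @export
handle_endpoints <- function(state, network) {
  at_food <- state$cell == network$food_cell
  at_nest <- state$cell == network$nest_cell
  pickups <- sum(at_food & !state$carrying)
  deliveries <- sum(at_nest & state$carrying)
  state$carrying[at_food] <- TRUE
  state$carrying[at_nest] <- FALSE
  state$heading[at_food] <- -1L
  state$heading[at_nest] <- 1L
  list(state = state, deliveries = deliveries, pickups = pickups)
}

#' Advance the simulation by one timestep
#'
#' Phase order within a step: free termites move one unit-cost edge
#' (crossing the zero-cost separation edge in the same step at most once),
#' trophallaxis encounters are resolved, new traffic jams are detected,
#' endpoint pickup/deposit is applied, and finally the jam timers of
#' termites that started the step jammed tick down — so a termite jammed at
#' step t stands still for exactly `jam_duration` steps.
#'
#' @inheritParams resolve_encounters
#' @param network A [build_network()] object.
#' @param config A [sim_config()].
#' @param eng Internal movement tables from the network; computed when
#'   omitted.
#' @return A list with the updated `state`, `food_t` (deliveries this step),
#'   `pickups`, and `jam_cells`.
#' @export
sim_step <- function(state, network, config, eng = sim_engine(network)) {
  blocked <- state$jam_timer > 0L

  free <- which(!blocked)
  nf <- length(free)
  if (nf > 0L) {
    state$cell[free] <- move_cells(
      state$cell[free], state$heading[free], eng,
      config[c("p1", "p2", "p3", "p4")],
      stats::runif(nf), stats::runif(nf))
  }
  state <- resolve_encounters(state, config$transfer_prob)
  jam <- detect_and_apply_jams(state, config$jam_size, config$jam_duration)
  ep <- handle_endpoints(jam$state, network)
  state <- ep$state
  # tick timers only for termites that started the step jammed, so a fresh
  # jam immobilizes for the full jam_duration steps
  state$jam_timer[blocked] <- state$jam_timer[blocked] - 1L
  list(state = state, food_t = ep$deliveries, pickups = ep$pickups,
       jam_cells = jam$jam_cells)
}

#' Run a transport simulation
#'
#' Executes `config$steps` timesteps of the individual-based model and
#' summarizes the run: per-step nest deliveries `food(t)`, the efficiency
#' series E(tau), its steady-state mean E, traffic-jam events, and a food
#' conservation audit.  Runs are exactly reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param network Optional prebuilt [build_network()] object; built from the
#'   configuration when omitted.
#' @param trace If `TRUE`, also record the per-step cumulative pickup /
#'   delivery / in-transit audit (used by conservation tests).
#' @return An object of class `"termite_sim"` with elements
#'   `food_per_step`, `E_series` (an [efficiency_series()] object), `E`
#'   (steady-state efficiency), `first_delivery` (timestep of the first nest
#'   delivery, `NA` if none), `jam_events` (data frame `t`, `cell`),
#'   `total_pickups`, `total_deliveries`, `config`, and (with
#'   `trace = TRUE`) `audit`.
#' @examples
#' cfg <- sim_config(n0 = 30, steps = 600, main_length = 100,
#'                   loop_length = 40, seed = 7)
#' res <- run_sim(cfg)
#' res
#' @export
run_sim <- function(config, network = NULL, trace = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(network))
    network <- build_network(config$delta, config$main_length,
                             config$loop_length)
  if (!is.null(config$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(config$seed)
  }
  eng <- sim_engine(network)
  state <- init_state(config, network)

  tt <- config$steps
  food <- integer(tt)
  pickups <- integer(tt)
  jam_t <- integer(0)
  jam_cell <- integer(0)
  carried <- if (trace) integer(tt) else NULL

  for (t in seq_len(tt)) {
    stepped <- sim_step(state, network, config, eng)
    state <- stepped$state
    food[t] <- stepped$food_t
    pickups[t] <- stepped$pickups
    if (length(stepped$jam_cells)) {
      jam_t <- c(jam_t, rep(t, length(stepped$jam_cells)))
      jam_cell <- c(jam_cell, stepped$jam_cells)
    }
    if (trace) carried[t] <- sum(state$carrying)
  }

  es <- efficiency_series(food, config$n0, config$s)
  window <- c(ceiling(0.9 * tt), tt)
  first <- if (any(food > 0L)) which(food > 0L)[1L] else NA_integer_

  out <- list(
    food_per_step = food,
    E_series = es,
    E = steady_state_E(es, window),
    window = window,
    first_delivery = first,
    jam_events = data.frame(t = jam_t, cell = jam_cell),
    total_pickups = sum(pickups),
    total_deliveries = sum(food),
    config = config,
    network = network)
  if (trace)
    out$audit <- data.frame(t = seq_len(tt),
                            pickups = cumsum(pickups),
                            deliveries = cumsum(food),
                            carried = carried)
  structure(out, class = "termite_sim")
}

#' @export
print.termite_sim <- function(x, ...) {
  cfg <- x$config
  cat("Termite transport simulation\n")
  cat(sprintf("  delta = %d, (P1,P2,P3,P4) = (%.2f, %.2f, %.2f, %.2f), N0 = %d, T = %d\n",
              cfg$delta, cfg$p1, cfg$p2, cfg$p3, cfg$p4, cfg$n0, cfg$steps))
  cat(sprintf("  deliveries: %d (first at t = %s); pickups: %d; jam events: %d\n",
              x$total_deliveries,
              ifelse(is.na(x$first_delivery), "never", x$first_delivery),
              x$total_pickups, nrow(x$jam_events)))
  cat(sprintf("  steady-state efficiency E = %.3f (mean E(tau), %d <= tau <= %d)\n",
              x$E, x$window[1], x$window[2]))
  invisible(x)
}

#' @export
summary.termite_sim <- function(object, ...) {
  x <- object
  out <- list(
    E = x$E,
    first_delivery = x$first_delivery,
    total_deliveries = x$total_deliveries,
    total_pickups = x$total_pickups,
    in_transit = x$total_pickups - x$total_deliveries,
    jam_events = nrow(x$jam_events),
    busiest_jam_cell = if (nrow(x$jam_events))
      as.integer(names(which.max(table(x$jam_events$cell)))) else NA_integer_)
  class(out) <- "summary.termite_sim"
  out
}

#' @export
print.summary.termite_sim <- function(x, ...) {
  cat("Steady-state efficiency E :", format(x$E, digits = 4), "\n")
  cat("First delivery at t       :", x$first_delivery, "\n")
  cat("Pickups / deliveries      :", x$total_pickups, "/",
      x$total_deliveries, "(", x$in_transit, "still in transit )\n")
  cat("Traffic jam events        :", x$jam_events,
      if (!is.na(x$busiest_jam_cell))
        paste0("(busiest cell ", x$busiest_jam_cell, ")") else "", "\n")
  invisible(x)
}

#' Plot the efficiency time series of a run
#'
#' @param x A [run_sim()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.termite_sim <- function(x, ...) {
  e <- as.numeric(x$E_series$values)
  graphics::plot(seq_along(e), e, type = "l", xlab = "timestep tau",
                 ylab = "E(tau)", ...)
  graphics::abline(v = x$window[1], lty = 3)
  graphics::abline(h = x$E, lty = 3)
  invisible(x)
}
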