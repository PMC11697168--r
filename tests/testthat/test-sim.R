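test_that("initial state: full colony on the main tunnel, nobody carrying", {
  net <- mini_net()
  cfg <- mini_cfg(n0 = 50)
  set.seed(1)
  st <- init_state(cfg, net)
  expect_length(st$cell, 50)
  expect_true(all(st$cell >= 0 & st$cell < net$main_length))
  expect_false(any(st$carrying))
  expect_true(all(st$jam_timer == 0))
  expect_setequal(unique(st$heading), c(1L, -1L))
})

test_that("initial headings split 50/50 within binomial tolerance", {
  net <- mini_net()
  cfg <- mini_cfg(n0 = 200)
  set.seed(7)
  draws <- replicate(50, mean(init_state(cfg, net)$heading > 0))
  p_hat <- mean(draws)              # 10,000 Bernoulli draws in total
  expect_lt(abs(p_hat - 0.5), 3.5 * sqrt(0.25 / 10000))
})

test_that("with all branch probabilities zero a termite walks the main tunnel", {
  net <- mini_net()
  probs <- list(p1 = 0, p2 = 0, p3 = 0, p4 = 0)
  cell <- 1L
  set.seed(2)
  visited <- cell
  while (cell != net$food_cell) {
    cell <- choose_next_cell(list(cell = cell, heading = 1L), net, probs)
    visited <- c(visited, cell)
  }
  expect_equal(visited, 1:19)  # straight walk, never enters the loop
})

test_that("forced branching at node a sends a food-bound termite into the loop", {
  net <- mini_net()
  probs <- list(p1 = 1, p2 = 0, p3 = 0, p4 = 0)
  a <- net$nodes[["a"]]
  set.seed(3)
  nxt <- choose_next_cell(list(cell = a, heading = 1L), net, probs)
  expect_equal(nxt, net$main_length)  # first loop cell on the a side
  # a nest-bound termite at a never enters the loop (no reversal at nodes)
  nxt_back <- choose_next_cell(list(cell = a, heading = -1L), net, probs)
  expect_equal(nxt_back, a - 1L)
})

test_that("separation-edge usage at node b matches its probability", {
  net <- mini_net()
  probs <- list(p1 = 0, p2 = 0.3, p3 = 0, p4 = 0)
  b <- net$nodes[["b"]]
  set.seed(4)
  landed <- replicate(10000,
    choose_next_cell(list(cell = b, heading = 1L), net, probs))
  in_loop <- mean(landed >= net$main_length)  # crossed b -> d, then moved
  expect_lt(abs(in_loop - 0.3), 0.015)
})

test_that("trophallaxis: only carrier/empty head-on pairs interact", {
  base <- list(cell = c(5L, 5L), heading = c(-1L, 1L),
               carrying = c(TRUE, FALSE), jam_timer = c(0L, 0L))
  # forced transfer: particle moves, both reverse
  set.seed(5)
  st <- resolve_encounters(base, transfer_prob = 1)
  expect_equal(st$carrying, c(FALSE, TRUE))
  expect_equal(st$heading, c(1L, -1L))
  # transfer_prob 0: pass without interaction
  st0 <- resolve_encounters(base, transfer_prob = 0)
  expect_identical(st0, base)
  # carrier+carrier and empty+empty never interact
  both <- base; both$carrying <- c(TRUE, TRUE)
  expect_identical(resolve_encounters(both, 1), both)
  none <- base; none$carrying <- c(FALSE, FALSE)
  expect_identical(resolve_encounters(none, 1), none)
  # same heading: no encounter even for carrier/empty
  same <- base; same$heading <- c(1L, 1L)
  expect_identical(resolve_encounters(same, 1), same)
})

test_that("staged encounters transfer at the configured rate", {
  n <- 10000
  st <- list(cell = rep(seq_len(n), each = 2L),
             heading = rep(c(-1L, 1L), n),
             carrying = rep(c(TRUE, FALSE), n),
             jam_timer = rep(0L, 2L * n))
  set.seed(6)
  out <- resolve_encounters(st, transfer_prob = 0.5)
  rate <- mean(out$carrying[seq(2, 2 * n, by = 2)])  # receivers now carrying
  expect_lt(abs(rate - 0.5), 0.015)
})

test_that("traffic jams need a full balanced quorum on one cell", {
  mk <- function(headings, cell = 3L)
    list(cell = rep(cell, length(headings)), heading = as.integer(headings),
         carrying = rep(FALSE, length(headings)),
         jam_timer = rep(0L, length(headings)))
  jam <- detect_and_apply_jams(mk(c(1, 1, -1, -1)), jam_size = 4,
                               jam_duration = 5)
  expect_equal(jam$jam_cells, 3L)
  expect_true(all(jam$state$jam_timer == 5L))
  expect_length(detect_and_apply_jams(mk(c(1, 1, 1, 1)))$jam_cells, 0)
  expect_length(detect_and_apply_jams(mk(c(1, -1, 1)))$jam_cells, 0)
  # five termites summing to zero is impossible; six balanced ones jam
  expect_length(detect_and_apply_jams(mk(c(1, 1, 1, -1, -1, -1)))$jam_cells,
                1)
})

test_that("jammed termites sit still for jam_duration steps, then resume", {
  net <- mini_net()
  cfg <- mini_cfg(n0 = 4, jam_duration = 3, p1 = 0, p2 = 0, p3 = 0, p4 = 0)
  st <- list(cell = c(9L, 9L, 11L, 11L), heading = c(1L, 1L, -1L, -1L),
             carrying = rep(FALSE, 4L), jam_timer = rep(0L, 4L))
  set.seed(8)
  s1 <- sim_step(st, net, cfg)          # all four converge on cell 10 and jam
  expect_true(length(s1$jam_cells) == 1L)
  frozen_at <- s1$state$cell
  for (k in 1:3) {
    s1 <- sim_step(s1$state, net, cfg)
    expect_equal(s1$state$cell, frozen_at)   # immobilized
  }
  s2 <- sim_step(s1$state, net, cfg)
  expect_true(all(s2$state$cell != frozen_at))  # moving again
  expect_equal(s2$state$heading, c(1L, 1L, -1L, -1L))  # headings kept
})

test_that("endpoint rules: pickup at food, single deposit at nest", {
  net <- mini_net()
  st <- list(cell = c(net$nest_cell, net$nest_cell, net$food_cell),
             heading = c(-1L, -1L, 1L),
             carrying = c(TRUE, FALSE, FALSE),
             jam_timer = c(0L, 0L, 0L))
  out <- handle_endpoints(st, net)
  expect_equal(out$deliveries, 1)
  expect_equal(out$pickups, 1)
  expect_equal(out$state$carrying, c(FALSE, FALSE, TRUE))
  # everyone leaves an endpoint facing inward
  expect_equal(out$state$heading, c(1L, 1L, -1L))
})

test_that("a lone walker's round trip takes 2(L-1) steps per particle", {
  m <- 20L
  net <- mini_net()
  cfg <- mini_cfg(n0 = 1, p1 = 0, p2 = 0, p3 = 0, p4 = 0, steps = 200)
  st <- list(cell = 0L, heading = 1L, carrying = FALSE, jam_timer = 0L)
  set.seed(9)
  deliveries <- integer(0)
  for (t in 1:200) {
    out <- sim_step(st, net, cfg)
    st <- out$state
    if (out$food_t > 0) deliveries <- c(deliveries, t)
  }
  expect_equal(deliveries[1], 2L * (m - 1L))
  expect_equal(unique(diff(deliveries)), 2L * (m - 1L))
})

test_that("a step over an empty system does nothing", {
  net <- mini_net()
  cfg <- mini_cfg()
  st <- list(cell = integer(0), heading = integer(0),
             carrying = logical(0), jam_timer = integer(0))
  out <- sim_step(st, net, cfg)
  expect_equal(out$food_t, 0)
  expect_length(out$jam_cells, 0)
})

test_that("same configuration and seed reproduce a run exactly", {
  cfg <- mini_cfg(n0 = 30, steps = 300, seed = 77)
  a <- run_sim(cfg)
  b <- run_sim(cfg)
  expect_identical(a$food_per_step, b$food_per_step)
  expect_identical(a$jam_events, b$jam_events)
  expect_identical(a$E, b$E)
})

test_that("food is conserved at every step and deliveries are monotone", {
  cfg <- mini_cfg(n0 = 40, steps = 400, seed = 13)
  res <- run_sim(cfg, trace = TRUE)
  aud <- res$audit
  expect_true(all(aud$pickups == aud$deliveries + aud$carried))
  expect_true(all(diff(aud$deliveries) >= 0))
  expect_equal(res$total_pickups, utils::tail(aud$pickups, 1))
})

test_that("without jams and branching, colony throughput matches the round-trip rate", {
  m <- 50L
  cfg <- sim_config(delta = 1, main_length = m, loop_length = 8, n0 = 20,
                    steps = 2000, p1 = 0, p2 = 0, p3 = 0, p4 = 0,
                    transfer_prob = 0, jam_duration = 0, seed = 21)
  res <- run_sim(cfg)
  per_termite <- res$total_deliveries / cfg$n0
  expect_lt(abs(per_termite - cfg$steps / (2 * (m - 1))), 2)
})

test_that("no delivery can precede one full main-tunnel traversal", {
  # scaled geometry: the bound is main_length timesteps
  for (seed in c(1, 2)) {
    cfg <- sim_config(delta = 2, main_length = 60, loop_length = 20,
                      n0 = 30, steps = 400, seed = seed)
    res <- run_sim(cfg)
    expect_gte(res$first_delivery, 60)
    expect_true(all(res$E_series$values[1:59] == 0))
  }
})
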