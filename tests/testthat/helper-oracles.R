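# Independent oracles, deliberately implemented differently from the
# package internals.

# Hand-rolled Dijkstra over the neighbors() adjacency (the package itself
# routes shortest paths through igraph).
dijkstra_oracle <- function(net, src, dst) {
  n <- net$n_cells
  dist <- rep(Inf, n)
  done <- rep(FALSE, n)
  dist[src + 1L] <- 0
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) stop("disconnected")
    if (u - 1L == dst) return(dist[u])
    done[u] <- TRUE
    nb <- neighbors(net, u - 1L)
    for (r in seq_len(nrow(nb))) {
      v <- nb$cell[r] + 1L
      alt <- dist[u] + nb$cost[r]
      if (alt < dist[v]) dist[v] <- alt
    }
  }
}

# Breadth-first connectivity over an explicit edge list.
connected_oracle <- function(edges, n_cells) {
  adj <- vector("list", n_cells)
  for (r in seq_len(nrow(edges))) {
    f <- edges$from[r] + 1L; t <- edges$to[r] + 1L
    adj[[f]] <- c(adj[[f]], t)
    adj[[t]] <- c(adj[[t]], f)
  }
  seen <- rep(FALSE, n_cells)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    for (v in adj[[u]]) if (!seen[v]) { seen[v] <- TRUE; queue <- c(queue, v) }
  }
  all(seen)
}

# Exhaustive-search k-means objective: minimum total within-cluster sum of
# squares over every assignment of n points to k labels.
kmeans_sse_oracle <- function(x, k) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  n <- nrow(x)
  stopifnot(n <= 8L)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- as.integer(grid[r, ])
    sse <- 0
    for (g in unique(lab)) {
      pts <- x[lab == g, , drop = FALSE]
      sse <- sse + sum(sweep(pts, 2L, colMeans(pts))^2)
    }
    if (sse < best) best <- sse
  }
  best
}

# Rank-regression PRCC via lm()/cor(), independent of the package's
# qr-based path.
prcc_oracle <- function(x, y) {
  x <- as.matrix(x)
  rx <- apply(x, 2L, rank, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  vapply(seq_len(ncol(x)), function(j) {
    others <- as.data.frame(rx[, -j, drop = FALSE])
    rj <- stats::residuals(stats::lm(rx[, j] ~ ., data = others))
    rr <- stats::residuals(stats::lm(ry ~ ., data = others))
    stats::cor(rj, rr)
  }, numeric(1))
}

# Small networks/configs used across tests.
mini_net <- function(delta = 1) build_network(delta, main_length = 20,
                                              loop_length = 8)
mini_cfg <- function(...) {
  defaults <- list(delta = 1, main_length = 20, loop_length = 8, n0 = 10,
                   steps = 200, seed = 42)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Drop the bulky run-level attributes so aggregated sweep tables can be
# compared as plain data frames.
strip_sweep_attrs <- function(x) {
  attr(x, "runs") <- NULL
  attr(x, "failures") <- NULL
  class(x) <- "data.frame"
  x
}
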