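#' Build a simplified two-segment loop tunnel network
#'
#' Constructs the lattice geometry used by the transport simulation: a
#' straight main tunnel of `main_length` unit grid cells running from the
#' nest (cell 0) to the food site (cell `main_length - 1`), plus a loop
#' tunnel of `loop_length` cells attached to the main tunnel at two
#' branching nodes `a` and `c`.  A short, wide "separation tunnel" connects
#' the main tunnel's middle node `b` to the loop's middle node `d`; it is
#' traversed at zero time cost and divides the loop into two equal
#' segments.  Branch choices at `a`, `b`, `c`, `d` are governed elsewhere by
#' the probabilities `P1`--`P4` (see [sim_config()]).
#'
#' @param delta Loop position: `1` (near the nest), `2` (centred on the main
#'   tunnel), or `3` (near the food site).  With the default lengths the
#'   nodes `(a, b, c)` sit at main-tunnel cells (50, 100, 150), (200, 250,
#'   300) and (350, 400, 450) respectively; for other lengths the same
#'   fractional positions are used.
#' @param main_length Number of main-tunnel cells (default 500).
#' @param loop_length Number of loop-tunnel cells (default 200); must be even
#'   so the separation tunnel splits the loop into two equal segments.
#'
#' @return An object of class `"tunnel_network"`: a list with the cell
#'   counts, `nest_cell`, `food_cell`, the four node cells (`nodes`, named
#'   `a`, `b`, `c`, `d`), a per-cell `tunnel_class` factor
#'   (`main`/`loop1`/`loop2`), and an `edges` data frame with per-edge
#'   traversal costs (1 everywhere except the zero-cost `b`--`d` edge).
#'   Cells are 0-based indices; loop cells are numbered
#'   `main_length ... main_length + loop_length - 1` from the `a` side to
#'   the `c` side, with `d` the last cell of the first segment.
#'
#' @examples
#' net <- build_network(2)
#' net
#' neighbors(net, net$nodes[["b"]])
#' @seealso [neighbors()], [shortest_path_length()], [run_sim()]
#' @export
build_network <- function(delta, main_length = 500, loop_length = 200) {
  if (length(delta) != 1L || !delta %in% c(1L, 2L, 3L))
    stop("`delta` must be 1, 2 or 3 (loop near nest, centred, near food)",
         call. = FALSE)
  delta <- as.integer(delta)
  main_length <- as.integer(main_length)
  loop_length <- as.integer(loop_length)
  if (main_length < 4L)
    stop("`main_length` must be at least 4 cells", call. = FALSE)
  if (loop_length < 2L || loop_length %% 2L != 0L)
    stop("`loop_length` must be even and at least 2", call. = FALSE)

  frac <- switch(delta,
                 c(0.1, 0.2, 0.3),
                 c(0.4, 0.5, 0.6),
                 c(0.7, 0.8, 0.9))
  abc <- as.integer(round(frac * main_length))
  if (any(abc <= 0L) || any(abc >= main_length - 1L) || any(diff(abc) < 1L))
    stop("node layout does not fit inside the main tunnel: nodes at (",
         paste(abc, collapse = ", "), ") for main_length = ", main_length,
         call. = FALSE)

  m <- main_length
  l <- loop_length
  loop_first <- m                 # loop cell adjacent to node a
  loop_last <- m + l - 1L         # loop cell adjacent to node c
  d_cell <- m + l %/% 2L - 1L     # last cell of segment a<->d

  nodes <- c(a = abc[1L], b = abc[2L], c = abc[3L], d = d_cell)

  edges <- rbind(
    data.frame(from = 0:(m - 2L), to = 1:(m - 1L), cost = 1L),
    data.frame(from = nodes[["a"]], to = loop_first, cost = 1L),
    if (l > 1L)
      data.frame(from = loop_first:(loop_last - 1L),
                 to = (loop_first + 1L):loop_last, cost = 1L),
    data.frame(from = loop_last, to = nodes[["c"]], cost = 1L),
    data.frame(from = nodes[["b"]], to = d_cell, cost = 0L)
  )
  rownames(edges) <- NULL

  tunnel_class <- c(rep("main", m),
                    rep("loop1", l %/% 2L),
                    rep("loop2", l %/% 2L))

  structure(
    list(main_length = m,
         loop_length = l,
         delta = delta,
         nest_cell = 0L,
         food_cell = m - 1L,
         nodes = nodes,
         tunnel_class = tunnel_class,
         edges = edges,
         n_cells = m + l),
    class = "tunnel_network")
}

#' @export
print.tunnel_network <- function(x, ...) {
  cat("Two-segment loop tunnel network\n")
  cat(sprintf("  main tunnel : %d cells (nest = %d, food = %d)\n",
              x$main_length, x$nest_cell, x$food_cell))
  cat(sprintf("  loop tunnel : %d cells in two segments of %d\n",
              x$loop_length, x$loop_length %/% 2L))
  cat(sprintf("  loop position delta = %d; nodes a=%d b=%d c=%d d=%d\n",
              x$delta, x$nodes[["a"]], x$nodes[["b"]], x$nodes[["c"]],
              x$nodes[["d"]]))
  cat(sprintf("  %d edges, unit cost except zero-cost separation edge b-d\n",
              nrow(x$edges)))
  invisible(x)
}

assert_cell <- function(network, cell) {
  if (length(cell) != 1L || is.na(cell) || cell < 0L || cell >= network$n_cells)
    stop("unknown cell id: ", cell, call. = FALSE)
  invisible(as.integer(cell))
}

#' Adjacent cells and traversal costs
#'
#' @param network A [build_network()] object.
#' @param cell A 0-based cell id.
#' @return A data frame with one row per incident edge: columns `cell`
#'   (neighbour id) and `cost` (traversal cost in timesteps).
#' @export
neighbors <- function(network, cell) {
  cell <- assert_cell(network, cell)
  e <- network$edges
  out <- rbind(
    data.frame(cell = e$to[e$from == cell], cost = e$cost[e$from == cell]),
    data.frame(cell = e$from[e$to == cell], cost = e$cost[e$to == cell]))
  out[order(out$cell), , drop = FALSE]
}

as_igraph <- function(network) {
  e <- network$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$from), to = as.character(e$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(0:(network$n_cells - 1L))))
  igraph::E(g)$weight <- e$cost
  g
}

#' Minimum traversal time between two cells
#'
#' Cost-weighted shortest path (Dijkstra), so the zero-cost separation edge
#' `b`--`d` counts for nothing.  On the default network the nest-to-food
#' distance is 499 unit moves across 500 cells, which is why the first food
#' particle cannot reach the nest before timestep 500.
#'
#' @inheritParams neighbors
#' @param src,dst 0-based cell ids.
#' @return Minimum total traversal cost in timesteps (numeric scalar).
#' @export
shortest_path_length <- function(network, src, dst) {
  src <- assert_cell(network, src)
  dst <- assert_cell(network, dst)
  if (src == dst) return(0)
  g <- as_igraph(network)
  d <- igraph::distances(g, v = as.character(src), to = as.character(dst),
                         algorithm = "dijkstra")[1L, 1L]
  if (!is.finite(d)) stop("cells are disconnected; the network is corrupt",
                          call. = FALSE)
  as.numeric(d)
}

#' Serialize a tunnel network to JSON
#'
#' Writes (or returns) a JSON description of the cells, edges with costs,
#' node labels and nest/food ids, suitable for fixtures and debugging.
#'
#' @inheritParams neighbors
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
network_to_json <- function(network, path = NULL) {
  payload <- list(
    main_length = network$main_length,
    loop_length = network$loop_length,
    delta = network$delta,
    nest_cell = network$nest_cell,
    food_cell = network$food_cell,
    nodes = as.list(network$nodes),
    tunnel_class = network$tunnel_class,
    edges = network$edges)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' Rebuild a tunnel network from its JSON serialization
#'
#' @param path Path to a file written by [network_to_json()], or a JSON
#'   string.
#' @return A `"tunnel_network"` object identical to the serialized one.
#' @export
network_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  net <- build_network(x$delta, x$main_length, x$loop_length)
  # construction is deterministic, so rebuilding must reproduce the payload
  stopifnot(identical(unname(unlist(x$nodes[c("a", "b", "c", "d")])),
                      unname(net$nodes)))
  net
}
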