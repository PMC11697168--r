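#' Deterministic test fixtures
#'
#' Miniature inputs with known structure, generated reproducibly from a
#' seed:
#' \describe{
#'   \item{`"mini-tunnel"`}{A 20-cell main tunnel with an 8-cell loop and a
#'     matching small-colony configuration; honours every network
#'     invariant.}
#'   \item{`"null-sweep"`}{A sweep-like table whose `mean_E` is pure noise,
#'     independent of the probabilities: PRCC should find nothing.}
#'   \item{`"signal-sweep"`}{A sweep-like table with
#'     `mean_E = 1 - 0.5 p3 - 0.5 p4 + noise`: PRCC must recover strong
#'     negative coefficients for `p3` and `p4` and nothing for `p1`, `p2`.}
#' }
#'
#' @param name Fixture name (see above).
#' @param seed Integer seed; the same seed always yields an identical
#'   fixture.
#' @param n Rows for the sweep fixtures (default 200).
#' @return A list of class `"fixture"` with `name`, `seed`, and either
#'   `network` + `config` (mini-tunnel) or `table` (sweeps).
#' @export
make_fixture <- function(name, seed = 1, n = 200) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  out <- switch(
    name,
    "mini-tunnel" = list(
      network = build_network(1, main_length = 20, loop_length = 8),
      config = sim_config(delta = 1, main_length = 20, loop_length = 8,
                          n0 = 10, steps = 200, seed = seed)),
    "null-sweep" = {
      p <- matrix(stats::runif(n * 4), ncol = 4,
                  dimnames = list(NULL, c("p1", "p2", "p3", "p4")))
      list(table = data.frame(p, delta = 2L,
                              mean_E = stats::rnorm(n, mean = 1, sd = 0.1)))
    },
    "signal-sweep" = {
      p <- matrix(stats::runif(n * 4), ncol = 4,
                  dimnames = list(NULL, c("p1", "p2", "p3", "p4")))
      e <- 1 - 0.5 * p[, "p3"] - 0.5 * p[, "p4"] +
        stats::rnorm(n, sd = 0.02)
      list(table = data.frame(p, delta = 2L, mean_E = e))
    },
    stop("unknown fixture: ", name, call. = FALSE))
  structure(c(list(name = name, seed = seed), out), class = "fixture")
}
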