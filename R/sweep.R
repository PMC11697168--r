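#' Full factorial sweep design over branch probabilities
#'
#' Enumerates the Cartesian product of probability levels for `P1..P4`, the
#' loop positions, and replicate indices, attaching a deterministic
#' per-row seed.  With the defaults (10 levels 0.1..1.0, three loop
#' positions, 10 replicates) the design has 10^4 x 3 x 10 = 300,000 rows.
#'
#' @param levels Probability values per parameter (default
#'   `seq(0.1, 1, by = 0.1)`), all in `[0, 1]`.
#' @param deltas Loop positions to sweep (subset of 1:3).
#' @param reps Replicates per combination.
#' @param base_seed Integer from which the unique per-row seeds are derived,
#'   so rows can be executed in any order (or in parallel) reproducibly.
#' @return A `"sweep_design"` data frame with columns `p1..p4`, `delta`,
#'   `replicate`, `seed`, and attribute `provenance = "factorial"`.
#' @examples
#' nrow(factorial_design(levels = c(0.5, 1), reps = 2))  # 2^4 * 3 * 2 = 96
#' @export
factorial_design <- function(levels = seq(0.1, 1, by = 0.1),
                             deltas = 1:3, reps = 10, base_seed = 1) {
  if (length(levels) == 0L || any(!is.finite(levels)) ||
      any(levels < 0) || any(levels > 1))
    stop("`levels` must be probability values in [0, 1]", call. = FALSE)
  if (any(!deltas %in% 1:3))
    stop("`deltas` must be a subset of 1:3", call. = FALSE)
  if (reps < 1L) stop("`reps` must be at least 1", call. = FALSE)
  g <- expand.grid(p1 = levels, p2 = levels, p3 = levels, p4 = levels,
                   delta = as.integer(deltas),
                   replicate = seq_len(reps),
                   KEEP.OUT.ATTRS = FALSE)
  g$seed <- derive_seeds(base_seed, nrow(g))
  structure(g, provenance = "factorial", class = c("sweep_design",
                                                   class(g)))
}

# Deterministic, collision-free seed stream: an affine walk modulo a prime
# below 2^31, so any subset of rows reruns identically.
derive_seeds <- function(base_seed, n) {
  p <- 2147483629
  as.integer((as.numeric(base_seed) %% p + as.numeric(seq_len(n)) * 7919) %% p + 1)
}

#' Latin hypercube sample of branch probabilities
#'
#' Stratified sample in the unit hypercube: each of the `dims` dimensions is
#' split into `n_samples` equal strata and every stratum receives exactly
#' one point, uniformly placed within it (via [lhs::randomLHS()]).
#'
#' @param n_samples Number of points (and strata per dimension).
#' @param dims Number of dimensions (default 4, for `P1..P4`).
#' @param seed Optional seed.
#' @return A numeric matrix `n_samples x dims` with columns `p1..p4` (or
#'   `x1..` beyond four).
#' @export
lhs_design <- function(n_samples, dims = 4, seed = NULL) {
  if (n_samples < 1L) stop("`n_samples` must be at least 1", call. = FALSE)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  x <- lhs::randomLHS(as.integer(n_samples), as.integer(dims))
  colnames(x) <- if (dims <= 4L) c("p1", "p2", "p3", "p4")[seq_len(dims)]
                 else paste0("x", seq_len(dims))
  x
}

#' Execute a sweep design
#'
#' Runs one simulation per design row ([run_sim()] with the row's
#' probabilities, loop position and seed) and averages replicate
#' efficiencies per combination.  When a `journal` path is given, finished
#' rows are appended to it as CSV and are skipped on a rerun, so an
#' interrupted sweep resumes where it stopped; results do not depend on
#' execution order because every row carries its own seed.
#'
#' @param design A [factorial_design()]-style data frame (columns `p1..p4`,
#'   `delta`, `replicate`, `seed`).
#' @param base_config A [sim_config()] supplying everything the design does
#'   not vary (colony size, horizon, jam parameters, ...).
#' @param journal Optional CSV path used as an on-disk resume journal.
#' @param progress Print a line every `progress` rows (0 = quiet).
#' @return A `"sweep_table"` data frame with one row per
#'   `(p1, p2, p3, p4, delta)` combination: `mean_E`, `n_reps`,
#'   `jam_total`; the per-row results (including per-replicate `E`) are in
#'   `attr(, "runs")`.
#' @export
run_sweep <- function(design, base_config = sim_config(), journal = NULL,
                      progress = 0) {
  need <- c("p1", "p2", "p3", "p4", "delta", "replicate", "seed")
  if (!all(need %in% names(design)))
    stop("design must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  n <- nrow(design)
  done <- rep(NA_real_, n)
  jams <- rep(NA_real_, n)
  fails <- character(0)

  if (!is.null(journal) && file.exists(journal)) {
    j <- utils::read.csv(journal)
    keep <- j$row >= 1 & j$row <= n
    done[j$row[keep]] <- j$E[keep]
    jams[j$row[keep]] <- j$jams[keep]
  }
  if (!is.null(journal) && !file.exists(journal))
    cat("row,E,jams\n", file = journal)

  nets <- list()
  for (i in seq_len(n)) {
    if (!is.na(done[i])) next
    row <- design[i, ]
    cfg <- base_config
    cfg$p1 <- row$p1; cfg$p2 <- row$p2; cfg$p3 <- row$p3; cfg$p4 <- row$p4
    cfg$delta <- as.integer(row$delta)
    cfg$seed <- as.integer(row$seed)
    key <- as.character(cfg$delta)
    if (is.null(nets[[key]]))
      nets[[key]] <- build_network(cfg$delta, cfg$main_length,
                                   cfg$loop_length)
    res <- tryCatch(run_sim(cfg, network = nets[[key]]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      fails <- c(fails, sprintf("row %d: %s", i, conditionMessage(res)))
      next
    }
    done[i] <- res$E
    jams[i] <- nrow(res$jam_events)
    if (!is.null(journal))
      cat(sprintf("%d,%.15g,%d\n", i, done[i], jams[i]),
          file = journal, append = TRUE)
    if (progress > 0 && i %% progress == 0)
      message(sprintf("sweep: %d/%d rows done", i, n))
  }

  runs <- cbind(design, E = done, jams = jams)
  key <- interaction(design$p1, design$p2, design$p3, design$p4,
                     design$delta, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(n), key), function(ix) {
    data.frame(p1 = design$p1[ix[1]], p2 = design$p2[ix[1]],
               p3 = design$p3[ix[1]], p4 = design$p4[ix[1]],
               delta = design$delta[ix[1]],
               mean_E = mean(done[ix], na.rm = TRUE),
               n_reps = sum(!is.na(done[ix])),
               jam_total = sum(jams[ix], na.rm = TRUE))
  }))
  rownames(agg) <- NULL
  agg <- agg[order(agg$delta, agg$p1, agg$p2, agg$p3, agg$p4), ]
  rownames(agg) <- NULL
  structure(agg, runs = runs, failures = fails,
            class = c("sweep_table", "data.frame"))
}

#' @export
print.sweep_table <- function(x, ...) {
  cat(sprintf("Sweep table: %d (P1,P2,P3,P4,delta) combinations, %d runs\n",
              nrow(x), nrow(attr(x, "runs"))))
  fl <- attr(x, "failures")
  if (length(fl)) cat("  failures:", length(fl), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
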