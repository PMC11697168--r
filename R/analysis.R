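#' k-means clustering by Lloyd's algorithm
#'
#' Plain Lloyd iterations (assign each point to the nearest centroid, then
#' recompute centroids) repeated until the assignment stops changing, with
#' several random restarts keeping the solution with the smallest total
#' within-cluster sum of squares.
#'
#' @param x Numeric vector (treated as 1-D points) or matrix with one point
#'   per row.
#' @param k Number of clusters (default 3).
#' @param max_iter Iteration cap per restart.
#' @param restarts Random initializations (best kept).
#' @param seed Optional seed for the initializations.
#' @return An object of class `"cluster_assignment"`: `labels` (1..k per
#'   point), `centroids` (k x d matrix), `withinss` (total within-cluster
#'   sum of squares), `iterations`, and `sse_trace` (objective after each
#'   Lloyd iteration of the winning restart; non-increasing).
#' @details If the data contain fewer than `k` distinct points, the
#'   effective number of clusters is reduced to the number of distinct
#'   points (a constant input yields one cluster).
#' @export
kmeans_lloyd <- function(x, k = 3, max_iter = 100, restarts = 10,
                         seed = NULL) {
  x <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1L)
  n <- nrow(x)
  if (k < 1L) stop("`k` must be positive", call. = FALSE)
  if (k > n) stop("cannot form ", k, " clusters from ", n, " points",
                  call. = FALSE)
  n_distinct <- nrow(unique(x))
  k <- min(k, n_distinct)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }

  sq_dist_to <- function(centers) {
    # n x k matrix of squared Euclidean distances
    d <- outer(rowSums(x^2), rep(1, nrow(centers))) +
      outer(rep(1, n), rowSums(centers^2)) - 2 * x %*% t(centers)
    pmax(d, 0)
  }
  sse_of <- function(labels, centers) {
    sum((x - centers[labels, , drop = FALSE])^2)
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- unique(x)[sample.int(n_distinct, k), , drop = FALSE]
    labels <- max.col(-sq_dist_to(centers))
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      for (j in seq_len(k)) {
        mem <- labels == j
        if (any(mem)) {
          centers[j, ] <- colMeans(x[mem, , drop = FALSE])
        } else {
          # re-seed an emptied cluster at the point farthest from its centre
          far <- which.max(rowSums((x - centers[labels, , drop = FALSE])^2))
          centers[j, ] <- x[far, ]
          labels[far] <- j
        }
      }
      new_labels <- max.col(-sq_dist_to(centers))
      trace <- c(trace, sse_of(new_labels, centers))
      if (all(new_labels == labels)) { labels <- new_labels; break }
      labels <- new_labels
    }
    sse <- sse_of(labels, centers)
    if (is.null(best) || sse < best$withinss - 1e-12)
      best <- list(labels = labels, centroids = centers, withinss = sse,
                   iterations = it, sse_trace = trace)
  }
  structure(c(best, list(k = k)), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("k-means assignment: %d clusters, %d points, within-SS %.6g\n",
              x$k, length(x$labels), x$withinss))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Group parameter combinations by their efficiency level
#'
#' Sorts the combinations of a sweep table in descending order of mean
#' efficiency and partitions the E values into `k` groups by 1-D k-means;
#' groups are relabelled 1..k by descending centroid, so group 1 collects
#' the high-efficiency combinations.
#'
#' @param table A [run_sweep()] result, or any data frame with a `mean_E`
#'   column and the `p1..p4` columns.
#' @param k Number of groups (default 3).
#' @param ... Passed to [kmeans_lloyd()].
#' @return The table rows sorted by descending `mean_E` with an added
#'   integer `group` column.
#' @export
group_sorted_efficiencies <- function(table, k = 3, ...) {
  if (!nrow(table)) stop("empty sweep table", call. = FALSE)
  e <- table$mean_E
  cl <- kmeans_lloyd(e, k = k, ...)
  # relabel so group 1 has the highest-E centroid
  ord <- order(cl$centroids[, 1L], decreasing = TRUE)
  relabel <- match(cl$labels, ord)
  out <- as.data.frame(table)
  out$group <- relabel
  out <- out[order(out$mean_E, decreasing = TRUE), ]
  rownames(out) <- NULL
  out
}

#' Normalized histograms of branch probabilities within a group
#'
#' For each of `p1..p4`, counts the combinations falling in each of `bins`
#' equal-width intervals of `[0, 1]` and normalizes by the total count, so
#' every histogram sums to 1.  The last bin is closed at 1.
#'
#' @param combos Data frame with columns `p1..p4` (a group from
#'   [group_sorted_efficiencies()]).
#' @param bins Number of intervals (default 10).
#' @return A `bins x 4` matrix of frequencies; row names give the
#'   intervals.
#' @export
probability_histograms <- function(combos, bins = 10) {
  vars <- c("p1", "p2", "p3", "p4")
  if (!nrow(combos)) stop("empty group", call. = FALSE)
  if (!all(vars %in% names(combos)))
    stop("`combos` must have columns p1..p4", call. = FALSE)
  edges <- seq(0, 1, length.out = bins + 1L)
  out <- sapply(vars, function(v) {
    p <- combos[[v]]
    if (any(p < 0 | p > 1)) stop("probabilities outside [0, 1]",
                                 call. = FALSE)
    ix <- pmin(findInterval(p, edges, rightmost.closed = TRUE), bins)
    tabulate(ix, nbins = bins) / length(p)
  })
  rownames(out) <- sprintf("[%.1f,%.1f%s", edges[-length(edges)], edges[-1],
                           c(rep(")", bins - 1L), "]"))
  out
}

#' High / medium / low coding of a branch probability
#'
#' Discretizes probabilities into `"L"` on `[0, 0.33)`, `"M"` on
#' `[0.33, 0.66)` and `"H"` on `[0.66, 1]`, the coding used to summarize
#' tunnel paths.
#'
#' @param p Probability value(s) in `[0, 1]`.
#' @return Character vector of `"L"`, `"M"`, `"H"`.
#' @examples
#' categorize_hml(c(0.2, 0.33, 1.0))  # "L" "M" "H"
#' @export
categorize_hml <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("`p` must lie in [0, 1]", call. = FALSE)
  c("L", "M", "H")[findInterval(p, c(0, 0.33, 0.66), rightmost.closed = FALSE)]
}

# ---- t-SNE ---------------------------------------------------------------

# Conditional p_{j|i} with per-point bandwidths sigma_i found by bisection
# so that every row's perplexity 2^H(P_i) matches `perplexity`.
tsne_pmatrix <- function(x, perplexity = 30, tol = 1e-5) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  if (perplexity >= n)
    stop("`perplexity` must be smaller than the number of points",
         call. = FALSE)
  d2 <- as.matrix(stats::dist(x))^2
  target <- log(perplexity)
  p_cond <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- 0; hi <- Inf; beta <- 1  # beta = 1 / (2 sigma_i^2)
    for (iter in 1:100) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { p <- rep(1 / length(di), length(di)); break }
      p <- w / sw
      h <- -sum(p[p > 0] * log(p[p > 0]))  # Shannon entropy of row
      if (abs(h - target) < tol) break
      if (h > target) {        # too flat: narrow the kernel
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- (beta + lo) / 2
      }
    }
    p_cond[i, -i] <- p
  }
  # symmetrize and normalize to a joint distribution over pairs
  p <- (p_cond + t(p_cond))
  p <- p / sum(p)
  pmax(p, .Machine$double.xmin)
}

# Student-t (1 df) joint q_ij over pairs for a 2-D embedding y.
tsne_qmatrix <- function(y) {
  num <- 1 / (1 + as.matrix(stats::dist(y))^2)
  diag(num) <- 0
  list(q = pmax(num / sum(num), .Machine$double.xmin), num = num)
}

#' Kullback-Leibler cost and gradient of a t-SNE embedding
#'
#' `tsne_cost` evaluates C = KL(P || Q) for a joint pair distribution `p`
#' and embedding coordinates `y`; `tsne_gradient` returns its analytic
#' gradient dC/dy, the quantity descended during optimization.
#'
#' @param p Joint probability matrix from `tsne_pmatrix`.
#' @param y n x 2 embedding coordinates.
#' @return `tsne_cost`: scalar C >= 0. `tsne_gradient`: n x 2 matrix.
#' @keywords internal
#' @export
tsne_cost <- function(p, y) {
  q <- tsne_qmatrix(y)$q
  off <- row(p) != col(p)
  sum(p[off] * log(p[off] / q[off]))
}

#' @rdname tsne_cost
#' @export
tsne_gradient <- function(p, y) {
  qq <- tsne_qmatrix(y)
  stiff <- 4 * (p - qq$q) * qq$num
  g <- matrix(0, nrow(y), 2L)
  for (dim in 1:2) {
    diffs <- outer(y[, dim], y[, dim], "-")
    g[, dim] <- rowSums(stiff * diffs)
  }
  g
}

#' t-SNE embedding into two dimensions
#'
#' From-scratch t-distributed stochastic neighbour embedding: Gaussian
#' conditional probabilities in the input space with per-point bandwidths
#' matched to a target perplexity by bisection, symmetrized and normalized
#' into a joint distribution; Student-t similarities in the plane; gradient
#' descent (momentum plus adaptive per-coordinate gains, brief early
#' exaggeration) on the Kullback-Leibler divergence between the two.
#'
#' @param x Numeric matrix, one point per row.
#' @param perplexity Effective neighbourhood size; default 30, shrunk to
#'   `n/4` for small inputs.  Must be `< n`.
#' @param iterations Gradient-descent steps (default 500).
#' @param learning_rate Step size (default 100).
#' @param seed Optional seed for the initial coordinates.
#' @return An object of class `"tsne_embedding"`: `y` (n x 2 coordinates),
#'   `cost` (final KL divergence C), `cost_trace` (C every 25 iterations),
#'   `perplexity`.
#' @export
tsne <- function(x, perplexity = NULL, iterations = 500,
                 learning_rate = 100, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(perplexity)) perplexity <- if (n < 120) max(2, n / 4) else 30
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  p <- tsne_pmatrix(x, perplexity)

  y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2L)
  inc <- matrix(0, n, 2L)
  gains <- matrix(1, n, 2L)
  exaggerate <- 4
  exag_until <- min(100L, iterations %/% 4L)
  trace <- numeric(0)
  for (it in seq_len(iterations)) {
    pe <- if (it <= exag_until) p * exaggerate / sum(p * exaggerate) else p
    g <- tsne_gradient(pe, y)
    gains <- ifelse(sign(g) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    momentum <- if (it < 250) 0.5 else 0.8
    inc <- momentum * inc - learning_rate * gains * g
    y <- y + inc
    y <- sweep(y, 2L, colMeans(y))
    if (it %% 25 == 0) trace <- c(trace, tsne_cost(p, y))
  }
  structure(list(y = y, cost = tsne_cost(p, y), cost_trace = trace,
                 perplexity = perplexity),
            class = "tsne_embedding")
}

#' @export
print.tsne_embedding <- function(x, ...) {
  cat(sprintf("t-SNE embedding of %d points (perplexity %.1f), final KL cost C = %.4f\n",
              nrow(x$y), x$perplexity, x$cost))
  invisible(x)
}

#' @export
plot.tsne_embedding <- function(x, ...) {
  graphics::plot(x$y[, 1], x$y[, 2], xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  invisible(x)
}

# ---- correlation and PRCC ------------------------------------------------

#' Pearson product-moment correlation coefficient
#'
#' Hand-evaluated CC(x, y) = sum (x_i - xbar)(y_i - ybar) /
#' sqrt(sum (x_i - xbar)^2 sum (y_i - ybar)^2).
#'
#' @param x,y Equal-length numeric samples, neither constant.
#' @return Correlation in `[-1, 1]`.
#' @export
correlation_coefficient <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("`x` and `y` must have equal length >= 2", call. = FALSE)
  dx <- x - mean(x)
  dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  sum(dx * dy) / den
}

#' Partial rank correlation coefficients
#'
#' Sensitivity of an output to each input with the (linear, rank-scale)
#' influence of the other inputs removed: all columns are rank-transformed
#' (ties get average ranks); for input j, `rank(x_j)` and `rank(y)` are each
#' regressed on the remaining rank-inputs, and the PRCC of input j is the
#' Pearson correlation of the two residual vectors.  A PRCC near -1 (+1)
#' means the input monotonically decreases (increases) the output once the
#' other inputs are accounted for.
#'
#' @param x Data frame or matrix of input samples (columns `P1..P4` in the
#'   transport application), no constant columns.
#' @param y Output sample (efficiency E), same number of rows.
#' @return An object of class `"prcc_result"`: data frame with `variable`,
#'   `prcc`, and attribute `n`.
#' @examples
#' x <- matrix(runif(400), ncol = 4,
#'             dimnames = list(NULL, c("p1", "p2", "p3", "p4")))
#' prcc(x, x[, 1] - 2 * x[, 3] + rnorm(100, sd = 0.05))
#' @export
prcc <- function(x, y) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  k <- ncol(x)
  if (length(y) != n) stop("`y` must match rows of `x`", call. = FALSE)
  if (n <= k + 2L)
    stop("need more samples than inputs + 2 (", n, " <= ", k + 2, ")",
         call. = FALSE)
  const <- apply(x, 2L, function(col) length(unique(col)) == 1L)
  if (any(const))
    stop("constant input column(s): ",
         paste(colnames(x)[const], collapse = ", "), call. = FALSE)
  if (length(unique(y)) == 1L)
    stop("output `y` is constant", call. = FALSE)

  rx <- apply(x, 2L, rank, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  vars <- colnames(x)
  if (is.null(vars)) vars <- paste0("x", seq_len(k))

  coefs <- vapply(seq_len(k), function(j) {
    others <- cbind(1, rx[, -j, drop = FALSE])
    qr_o <- qr(others)
    if (qr_o$rank < ncol(others))
      stop("singular rank regression: columns {",
           paste(vars[-j], collapse = ", "), "} are collinear",
           call. = FALSE)
    res_x <- qr.resid(qr_o, rx[, j])
    res_y <- qr.resid(qr_o, ry)
    correlation_coefficient(res_x, res_y)
  }, numeric(1))

  structure(data.frame(variable = vars, prcc = coefs),
            n = n, class = c("prcc_result", "data.frame"))
}

#' @export
print.prcc_result <- function(x, ...) {
  cat(sprintf("PRCC (N = %d samples)\n", attr(x, "n")))
  print.data.frame(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Per-delta PRCC of branch probabilities against efficiency
#'
#' Convenience wrapper: stratifies a sweep table by loop position and
#' computes [prcc()] of `(p1, p2, p3, p4)` against `mean_E` within each
#' stratum.
#'
#' @param table A [run_sweep()] result (or data frame with `p1..p4`,
#'   `delta`, `mean_E`).
#' @return Data frame with columns `delta`, `variable`, `prcc`, `n`.
#' @export
prcc_sweep <- function(table) {
  out <- lapply(sort(unique(table$delta)), function(d) {
    sub <- table[table$delta == d, ]
    r <- prcc(sub[, c("p1", "p2", "p3", "p4")], sub$mean_E)
    data.frame(delta = d, variable = r$variable, prcc = r$prcc,
               n = attr(r, "n"))
  })
  do.call(rbind, out)
}
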