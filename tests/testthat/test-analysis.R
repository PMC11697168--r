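test_that("Lloyd k-means matches exhaustive search on small instances", {
  set.seed(41)
  for (rep in 1:5) {
    x <- round(runif(7, 0, 10), 2)
    fit <- kmeans_lloyd(x, k = 3, restarts = 50)
    expect_equal(fit$withinss, kmeans_sse_oracle(x, 3), tolerance = 1e-9)
  }
})

test_that("k-means objective never increases across Lloyd iterations", {
  set.seed(42)
  x <- matrix(rnorm(200), ncol = 2)
  fit <- kmeans_lloyd(x, k = 4, restarts = 3, seed = 1)
  expect_true(all(diff(fit$sse_trace) <= 1e-9))
})

test_that("k-means handles degenerate and extreme inputs", {
  x <- c(1.2, 3.4, 5.6, 7.8)
  each_own <- kmeans_lloyd(x, k = 4, seed = 1)
  expect_equal(each_own$withinss, 0)
  expect_equal(length(unique(each_own$labels)), 4L)
  blobs <- c(rnorm(20, 0, 0.01), rnorm(20, 5, 0.01), rnorm(20, 10, 0.01))
  fit <- kmeans_lloyd(blobs, k = 3, seed = 2)
  expect_equal(length(unique(fit$labels[1:20])), 1L)
  expect_equal(length(unique(fit$labels[21:40])), 1L)
  expect_equal(length(unique(fit$labels[41:60])), 1L)
  constant <- kmeans_lloyd(rep(2, 10), k = 3, seed = 3)
  expect_equal(constant$k, 1L)       # distinct-value guard
  expect_error(kmeans_lloyd(1:3, k = 5), "cannot form")
})

test_that("k-means agrees with the stats reference on a moderate instance", {
  set.seed(43)
  x <- c(rnorm(30, 0), rnorm(30, 4), rnorm(30, 9))
  mine <- kmeans_lloyd(x, k = 3, restarts = 25, seed = 4)
  ref <- stats::kmeans(x, centers = 3, nstart = 25)
  expect_equal(mine$withinss, ref$tot.withinss, tolerance = 1e-6)
})

test_that("efficiency grouping is ordered and monotone", {
  tab <- data.frame(p1 = 0.5, p2 = 0.5, p3 = 0.5, p4 = 0.5,
                    delta = 1L, mean_E = c(0.9, 0.8, 0.5, 0.4, 0.1))
  g <- group_sorted_efficiencies(tab, k = 3, restarts = 20, seed = 5)
  expect_equal(g$mean_E, sort(tab$mean_E, decreasing = TRUE))
  expect_equal(g$group, c(1L, 1L, 2L, 2L, 3L))
  # group 1 dominates group 2 dominates group 3
  expect_true(min(g$mean_E[g$group == 1]) >= max(g$mean_E[g$group == 2]))
  expect_true(min(g$mean_E[g$group == 2]) >= max(g$mean_E[g$group == 3]))
})

test_that("probability histograms are normalized frequencies over ten bins", {
  point <- data.frame(p1 = rep(0.95, 5), p2 = 0.95, p3 = 0.95, p4 = 0.95)
  h <- probability_histograms(point)
  expect_equal(unname(h[10, ]), rep(1, 4))
  expect_equal(unname(colSums(h)), rep(1, 4))
  set.seed(44)
  unif <- as.data.frame(matrix(runif(40000), ncol = 4,
                               dimnames = list(NULL, paste0("p", 1:4))))
  hu <- probability_histograms(unif)
  expect_true(all(abs(hu - 0.1) < 0.015))   # multinomial tolerance at n=1e4
  expect_equal(unname(colSums(hu)), rep(1, 4))
})

test_that("H/M/L coding uses half-open bins covering [0, 1]", {
  expect_equal(categorize_hml(c(0, 0.2, 0.32999)), c("L", "L", "L"))
  expect_equal(categorize_hml(c(0.33, 0.5, 0.65999)), c("M", "M", "M"))
  expect_equal(categorize_hml(c(0.66, 0.9, 1.0)), c("H", "H", "H"))
  expect_error(categorize_hml(1.5), "\\[0, 1\\]")
  expect_error(categorize_hml(-0.1), "\\[0, 1\\]")
})

test_that("t-SNE affinities are symmetric, normalized, and perplexity-matched", {
  set.seed(45)
  x <- matrix(rnorm(60), ncol = 3)
  p <- termitesim:::tsne_pmatrix(x, perplexity = 5)
  expect_equal(p, t(p))
  expect_equal(sum(p), 1)
  expect_true(all(p > 0))
  # identical points must not divide by zero
  expect_no_error(termitesim:::tsne_pmatrix(matrix(1, 5, 2), perplexity = 2))
})

test_that("analytic KL gradient matches central finite differences", {
  set.seed(46)
  x <- matrix(rnorm(15), ncol = 3)
  p <- termitesim:::tsne_pmatrix(x, perplexity = 2)
  y <- matrix(rnorm(10), ncol = 2)
  g <- tsne_gradient(p, y)
  h <- 1e-6
  for (i in 1:5) for (dim in 1:2) {
    yp <- y; yp[i, dim] <- yp[i, dim] + h
    ym <- y; ym[i, dim] <- ym[i, dim] - h
    fd <- (tsne_cost(p, yp) - tsne_cost(p, ym)) / (2 * h)
    expect_equal(g[i, dim], fd, tolerance = 1e-5)
  }
})

test_that("t-SNE cost is a KL divergence: non-negative and optimized downwards", {
  set.seed(47)
  x <- matrix(rnorm(90), ncol = 3)
  p <- termitesim:::tsne_pmatrix(x, perplexity = 5)
  expect_gte(tsne_cost(p, matrix(rnorm(60), ncol = 2)), 0)
  emb <- tsne(x, perplexity = 5, iterations = 300, seed = 6)
  expect_gte(emb$cost, 0)
  expect_lt(emb$cost, emb$cost_trace[1])
  expect_equal(dim(emb$y), c(30L, 2L))
})

test_that("Pearson correlation matches the closed-form and the stats reference", {
  x <- c(1.1, 2.3, 3.1, 4.0, 5.7)
  y <- c(2.0, 1.1, 4.4, 3.9, 6.2)
  expect_equal(correlation_coefficient(x, x), 1)
  expect_equal(correlation_coefficient(x, -x), -1)
  expect_equal(correlation_coefficient(x, y), stats::cor(x, y),
               tolerance = 1e-12)
  expect_equal(correlation_coefficient(x, y), 0.875256809050545,
               tolerance = 1e-12)
  expect_error(correlation_coefficient(x, rep(1, 5)), "constant")
  expect_error(correlation_coefficient(x, y[1:3]), "equal length")
})

test_that("PRCC recovers planted structure and stays bounded", {
  set.seed(48)
  x <- matrix(runif(2000), ncol = 4,
              dimnames = list(NULL, paste0("p", 1:4)))
  direct <- prcc(x, x[, 1])
  expect_gt(direct$prcc[1], 0.99)
  null <- prcc(x, runif(500))
  expect_true(all(abs(null$prcc) < 0.15))
  expect_true(all(direct$prcc >= -1 & direct$prcc <= 1))
  expect_error(prcc(cbind(x, p5 = rep(0.5, 500)), x[, 1]), "constant")
  expect_error(prcc(x[1:5, ], x[1:5, 1]), "more samples")
})

test_that("PRCC equals a brute-force residual rank correlation", {
  set.seed(49)
  for (rep in 1:3) {
    x <- matrix(runif(200), ncol = 4)
    y <- x[, 2] - 0.5 * x[, 4] + rnorm(50, sd = 0.3)
    expect_equal(prcc(x, y)$prcc, prcc_oracle(x, y), tolerance = 1e-10)
  }
})

test_that("PRCC is invariant under strictly monotone input transforms", {
  set.seed(50)
  x <- matrix(runif(400), ncol = 4)
  y <- -x[, 3] + rnorm(100, sd = 0.2)
  base <- prcc(x, y)$prcc
  warped <- x
  warped[, 3] <- exp(3 * warped[, 3])     # strictly increasing
  warped[, 1] <- warped[, 1]^3
  expect_equal(prcc(warped, y)$prcc, base, tolerance = 1e-12)
})
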