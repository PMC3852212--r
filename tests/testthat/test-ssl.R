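two_node <- function() {
  w <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(pids(2), pids(2)))
  graph_laplacian(similarity_graph(w))
}

test_that("ssl_solve matches hand-solved cases and limits", {
  # edgeless graph: f = y exactly
  L0 <- graph_laplacian(similarity_graph(matrix(0, 3, 3), pids(3)))
  y <- label_vector(c(1, -1, 0), pids(3))
  expect_equal(ssl_solve(L0, y, 1), as.numeric(y), ignore_attr = TRUE)

  # 2-node toy: (I + L) = [[2,-1],[-1,2]], inverse times (1,0) = (2/3, 1/3)
  f <- ssl_solve(two_node(), label_vector(c(1, 0), pids(2)), 1)
  expect_equal(unname(f), c(2 / 3, 1 / 3), tolerance = 1e-12)

  # mu -> 0 recovers the labels
  g <- rnd_graph(15, seed = 2)
  y <- rnd_labels(15, seed = 3)
  f <- ssl_solve(graph_laplacian(g), y, mu = 1e-8)
  expect_lt(max(abs(f - as.numeric(y))), 1e-6)
})

test_that("ssl_solve validates inputs", {
  y <- label_vector(c(1, 0), pids(2))
  expect_error(ssl_solve(two_node(), y, mu = 0), "mu")
  expect_error(ssl_solve(two_node(), label_vector(c(0, 0), pids(2))),
               "labeled")
  y3 <- label_vector(c(1, 0, -1), pids(3))
  expect_error(ssl_solve(two_node(), y3), "dimensions differ")
})

test_that("regularised solve shrinks and smooths", {
  for (s in 1:10) {
    g <- rnd_graph(12, seed = s, density = 0.6)
    L <- graph_laplacian(g)
    y <- rnd_labels(12, seed = s + 50)
    f <- ssl_solve(L, y, mu = 1)
    expect_lte(sqrt(sum(f^2)), sqrt(sum(as.numeric(y)^2)) + 1e-12)

    rough <- sapply(c(0.01, 0.1, 1, 10), function(mu) {
      f <- ssl_solve(L, y, mu)
      drop(t(f) %*% unclass(L) %*% f)
    })
    expect_true(all(diff(rough) <= 1e-10))
  }
})

test_that("closed form agrees with a convergent Jacobi iteration", {
  g <- rnd_graph(8, seed = 17, density = 0.5)
  L <- unclass(graph_laplacian(g))
  y <- as.numeric(rnd_labels(8, seed = 18))
  mu <- 0.7
  w <- unclass(g)
  d <- rowSums(w)
  f <- rep(0, 8)
  for (it in 1:10000) {
    f <- (y + mu * drop(w %*% f)) / (1 + mu * d)
  }
  closed <- ssl_solve(graph_laplacian(g), label_vector(y, pids(8)), mu)
  expect_lt(max(abs(closed - f)), 1e-8)
})

test_that("alignment combination rewards label-consistent graphs", {
  # one graph whose blocks follow the labels, one random graph
  n <- 20
  y_vec <- rep(c(1, -1), each = n / 2)
  y_vec[c(3, 13)] <- 0
  y <- label_vector(y_vec, pids(n))
  block <- outer(rep(c(1, 2), each = n / 2), rep(c(1, 2), each = n / 2),
                 "==") * 0.8
  diag(block) <- 0
  g_good <- similarity_graph(block, pids(n))
  g_rand <- rnd_graph(n, seed = 4)

  comb <- combine_graphs(list(good = g_good, rand = g_rand), y, budget = 1,
                         criterion = "alignment")
  expect_equal(sum(comb$alphas), 1, tolerance = 1e-8)
  expect_gt(comb$alphas[1], comb$alphas[2])

  # K = 1 uses the whole budget
  c1 <- combine_graphs(list(g_good), y, budget = 2, criterion = "alignment")
  expect_equal(c1$alphas, 2, tolerance = 1e-10)
})

test_that("alignment optimum matches a 1-D grid on the budget segment", {
  n <- 18
  g1 <- rnd_graph(n, seed = 7, density = 0.5)
  g2 <- rnd_graph(n, seed = 8)
  y <- rnd_labels(n, seed = 9)
  L1 <- unclass(graph_laplacian(g1)); L2 <- unclass(graph_laplacian(g2))
  quantity <- function(a) {
    drop(crossprod(as.numeric(y),
                   solve(diag(n) + a[1] * L1 + a[2] * L2, as.numeric(y))))
  }
  grid_best <- max(sapply(seq(0, 1, 0.001),
                          function(a1) quantity(c(a1, 1 - a1))))
  comb <- combine_graphs(list(g1, g2), y, budget = 1,
                         criterion = "alignment")
  expect_equal(comb$objective, grid_best, tolerance = 1e-6)
})

test_that("printed-form quadratic criterion matches 2-D grid search", {
  n <- 16
  g1 <- rnd_graph(n, seed = 11, density = 0.5)
  g2 <- rnd_graph(n, seed = 12)
  y <- rnd_labels(n, seed = 13)
  L1 <- unclass(graph_laplacian(g1)); L2 <- unclass(graph_laplacian(g2))
  quantity <- function(a1, a2) {
    drop(crossprod(as.numeric(y),
                   solve(diag(n) + a1 * L1 + a2 * L2, as.numeric(y))))
  }
  grid <- seq(0, 1, 0.01)
  best <- Inf
  for (a1 in grid) for (a2 in grid) {
    if (a1 + a2 <= 1) best <- min(best, quantity(a1, a2))
  }
  comb <- combine_graphs(list(g1, g2), y, budget = 1,
                         criterion = "quadratic")
  expect_lte(comb$objective, best + 1e-6)

  # monotone objective: a single graph absorbs the whole budget
  c1 <- combine_graphs(list(g1), y, budget = 1, criterion = "quadratic")
  expect_equal(c1$alphas, 1, tolerance = 1e-6)
})

test_that("identical graphs give a split-invariant objective", {
  g <- rnd_graph(10, seed = 21, density = 0.6)
  y <- rnd_labels(10, seed = 22)
  c2 <- combine_graphs(list(g, g), y, budget = 1)
  c1 <- combine_graphs(list(g), y, budget = 1)
  expect_equal(c2$objective, c1$objective, tolerance = 1e-8)
})

test_that("combination solutions beat (or tie) the feasible-set corners", {
  gs <- list(rnd_graph(9, seed = 31, density = 0.5),
             rnd_graph(9, seed = 32, density = 0.7),
             rnd_graph(9, seed = 33))
  y <- rnd_labels(9, seed = 34)
  Ls <- lapply(gs, function(g) unclass(graph_laplacian(g)))
  quantity <- function(a) {
    A <- diag(9)
    for (k in 1:3) A <- A + a[k] * Ls[[k]]
    drop(crossprod(as.numeric(y), solve(A, as.numeric(y))))
  }
  cq <- combine_graphs(gs, y, budget = 1, criterion = "quadratic")
  corners <- rbind(diag(3), 0)
  for (i in 1:4) expect_lte(cq$objective, quantity(corners[i, ]) + 1e-10)
  ca <- combine_graphs(gs, y, budget = 1, criterion = "alignment")
  for (i in 1:3) expect_gte(ca$objective, quantity(corners[i, ]) - 1e-10)
})

test_that("ssl_solve_combined equals the solve on the summed Laplacian", {
  g1 <- rnd_graph(11, seed = 41, density = 0.5)
  g2 <- rnd_graph(11, seed = 42, density = 0.5)
  y <- rnd_labels(11, seed = 43)
  a <- c(0.3, 0.6)
  L_sum <- unclass(graph_laplacian(g1)) * a[1] +
    unclass(graph_laplacian(g2)) * a[2]
  direct <- solve(diag(11) + L_sum, as.numeric(y))
  expect_equal(unname(ssl_solve_combined(list(g1, g2), y, a)),
               unname(direct), tolerance = 1e-12)

  # alpha = (mu, 0) reduces to the single-graph solve
  expect_equal(ssl_solve_combined(list(g1, g2), y, c(0.8, 0)),
               ssl_solve(graph_laplacian(g1), y, 0.8), tolerance = 1e-12)
  # alpha = 0 returns the labels
  expect_equal(unname(ssl_solve_combined(list(g1, g2), y, c(0, 0))),
               as.numeric(y), tolerance = 1e-12)
})

test_that("predict_labels thresholds with ties mapping to +1", {
  expect_equal(unname(predict_labels(c(0.4, -0.2))), c(1, -1))
  expect_equal(unname(predict_labels(0)), 1)
  expect_equal(unname(predict_labels(c(0.5, 0.5), threshold = 0.5)), c(1, 1))
})

test_that("graph_ssl model object supports the standard methods", {
  g <- rnd_graph(14, seed = 51, density = 0.6)
  y <- rnd_labels(14, seed = 52)
  fit <- graph_ssl(g, y, mu_smooth = 0.5)
  expect_s3_class(fit, "graph_ssl")
  expect_equal(fitted(fit), fit$scores)
  expect_equal(unname(coef(fit)), 0.5)
  expect_length(residuals(fit), sum(y != 0))
  expect_length(predict(fit), sum(y == 0))
  expect_true(all(predict(fit, type = "label", which = "all") %in% c(-1, 1)))
  expect_output(print(fit), "Graph semi-supervised fit")
  expect_output(print(summary(fit)), "Training sign accuracy")

  fit2 <- graph_ssl(list(a = g, b = rnd_graph(14, seed = 53)), y)
  expect_named(coef(fit2), c("a", "b"))
  expect_equal(sum(coef(fit2)), 1, tolerance = 1e-8)
  expect_equal(fit2$scores,
               ssl_solve_combined(list(g, rnd_graph(14, seed = 53)), y,
                                  unname(coef(fit2))))
})
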