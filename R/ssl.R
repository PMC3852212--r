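#' Closed-form graph semi-supervised solve
#'
#' Minimises the loss-plus-smoothness functional
#' \deqn{(f - y)'(f - y) + \mu f' L f}
#' whose unique minimiser is `f = (I + mu L)^{-1} y`.  The system is
#' solved through a Cholesky factorisation of the symmetric positive
#' definite matrix `I + mu L` (never by forming an explicit inverse).
#' Unlabeled patients enter with `y = 0` and receive a real-valued score
#' whose sign predicts their class.
#'
#' @param laplacian A [graph_laplacian] (or a [similarity_graph], which is
#'   converted).
#' @param labels A [label_vector] over \{-1, 0, +1\} aligned with the
#'   graph's patients.
#' @param mu Positive smoothness trade-off.
#' @return Named numeric score vector `f`, one score per patient.
#' @examples
#' w <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' g <- similarity_graph(w)
#' ssl_solve(graph_laplacian(g), label_vector(c(a = 1, b = 0)), mu = 1)
#' # -> (2/3, 1/3)
#' @export
ssl_solve <- function(laplacian, labels, mu = 1) {
  L <- as_laplacian(laplacian)
  y <- check_labels_for_graph(labels, L)
  if (length(mu) != 1 || is.na(mu) || mu <= 0) stop_arg("mu must be > 0")
  f <- spd_solve(diag(nrow(L)) + mu * unclass(L), y,
                 context = "I + mu*L (is the Laplacian valid?)")
  names(f) <- rownames(L)
  f
}

# Solve A x = b for symmetric positive definite A via Cholesky.
spd_solve <- function(A, b, context = "system matrix") {
  R <- tryCatch(chol(A), error = function(e) {
    stop_arg("linear solve failed: %s is not positive definite", context)
  })
  backsolve(R, forwardsolve(t(R), b))
}

check_labels_for_graph <- function(labels, L) {
  if (!inherits(labels, "label_vector")) {
    labels <- label_vector(labels,
                           patient_ids = names(labels) %||% rownames(L))
  }
  if (length(labels) != nrow(L)) {
    stop_arg("labels (%d) and graph (%d patients) dimensions differ",
             length(labels), nrow(L))
  }
  if (!is.null(rownames(L)) && !identical(names(labels), rownames(L))) {
    stop_arg("label patient ids do not match the graph's patient ids")
  }
  if (all(labels == 0)) stop_arg("at least one patient must be labeled")
  as.numeric(labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Optimise Laplacian combination coefficients
#'
#' Fuses `K` graphs by choosing nonnegative coefficients \eqn{\alpha} for
#' their Laplacians through the quantity
#' \deqn{Q(\alpha) = y' (I + \textstyle\sum_k \alpha_k L_k)^{-1} y,}
#' optimised by projected gradient descent with backtracking line search.
#' Two criteria are offered:
#'
#' * `criterion = "alignment"` (default) **maximises** \eqn{Q} over the
#'   simplex \eqn{\alpha_k \ge 0,\ \sum_k \alpha_k = } `budget`.
#'   \eqn{Q} is the alignment of the labels with the fused kernel
#'   \eqn{(I + \sum \alpha_k L_k)^{-1}}, so the budget flows to the
#'   graphs on which the known labels are smooth — the behaviour required
#'   for fusion to favour label-consistent graphs.  (Without the equality
#'   constraint the maximum is trivially \eqn{\alpha = 0}.)
#' * `criterion = "quadratic"` **minimises** \eqn{Q} over
#'   \eqn{\alpha_k \ge 0,\ \sum_k \alpha_k \le } `budget`.  This objective
#'   is monotone non-increasing in every \eqn{\alpha_k} and decreases
#'   fastest along Laplacians on which the labels are rough, so it
#'   saturates the budget on the densest / least label-consistent graph;
#'   it is retained for comparison and study (see the methods vignette
#'   for why it is not the fusion default).
#'
#' Both problems are convex (in the minimised function) and the solver is
#' verifiable against grid search.  When graphs are interchangeable the
#' optimal split among them is not unique and the returned coefficients
#' are one optimal choice.
#'
#' @param laplacians A list of [graph_laplacian]s (or [similarity_graph]s)
#'   on the same patients.
#' @param labels A [label_vector]; unlabeled entries are 0.
#' @param budget Positive coefficient mass (bound or total, per
#'   criterion).
#' @param criterion `"alignment"` or `"quadratic"`; see Details.
#' @param tol Convergence threshold on the objective decrease.
#' @param max_iter Iteration cap; failure to converge is an error.
#' @return List of class `graph_combination` with elements `alphas`,
#'   `objective` (the value of \eqn{Q} at the optimum), `criterion`,
#'   `iterations`, `budget`.
#' @export
combine_graphs <- function(laplacians, labels, budget = 1,
                           criterion = c("alignment", "quadratic"),
                           tol = 1e-10, max_iter = 1000) {
  criterion <- match.arg(criterion)
  if (inherits(laplacians, c("graph_laplacian", "similarity_graph"))) {
    laplacians <- list(laplacians)
  }
  Ls <- lapply(laplacians, function(l) unclass(as_laplacian(l)))
  K <- length(Ls)
  if (K < 1) stop_arg("need at least one graph")
  n <- nrow(Ls[[1]])
  if (!all(vapply(Ls, nrow, 0L) == n)) {
    stop_arg("all Laplacians must have the same dimension")
  }
  y <- check_labels_for_graph(labels, as_laplacian(laplacians[[1]]))
  if (length(budget) != 1 || budget <= 0) stop_arg("budget must be > 0")

  I_n <- diag(n)
  sgn <- if (criterion == "alignment") -1 else 1  # minimise sgn * Q
  quantity <- function(a) {
    A <- I_n
    for (k in seq_len(K)) A <- A + a[k] * Ls[[k]]
    drop(crossprod(y, spd_solve(A, y)))
  }
  objective <- function(a) sgn * quantity(a)
  gradient <- function(a) {
    A <- I_n
    for (k in seq_len(K)) A <- A + a[k] * Ls[[k]]
    u <- spd_solve(A, y)
    -sgn * vapply(Ls, function(L) drop(crossprod(u, L %*% u)), 0)
  }
  project <- if (criterion == "alignment") {
    function(a) project_simplex(a, budget)
  } else {
    function(a) project_capped_simplex(a, budget)
  }

  a <- if (criterion == "alignment") rep(budget / K, K) else rep(0, K)
  obj <- objective(a)
  step <- budget
  iter <- 0
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1
    g <- gradient(a)
    accepted <- FALSE
    while (step > 1e-16) {
      cand <- project(a - step * g)
      obj_cand <- objective(cand)
      if (obj_cand <= obj - 1e-14) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      converged <- TRUE  # no feasible descent direction left
      break
    }
    decrease <- obj - obj_cand
    a <- cand
    obj <- obj_cand
    step <- min(step * 2, 1e6)
    if (decrease < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop_arg("coefficient optimisation did not converge in %d iterations (gradient norm %.3e)",
             max_iter, sqrt(sum(gradient(a)^2)))
  }
  structure(list(alphas = a, objective = sgn * obj, criterion = criterion,
                 iterations = iter, budget = budget),
            class = "graph_combination")
}

# Euclidean projection onto the simplex {a >= 0, sum(a) = budget}.
project_simplex <- function(a, budget) {
  u <- sort(a, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - budget) / seq_along(u) > 0))
  theta <- (css[rho] - budget) / rho
  pmax(a - theta, 0)
}

# Euclidean projection onto {a >= 0, sum(a) <= budget}.
project_capped_simplex <- function(a, budget) {
  a <- pmax(a, 0)
  if (sum(a) <= budget) return(a)
  project_simplex(a, budget)
}

#' @export
print.graph_combination <- function(x, ...) {
  cat(sprintf("graph_combination (%s): K = %d, objective = %.6g (%d iterations)\n",
              x$criterion, length(x$alphas), x$objective, x$iterations))
  cat("alphas:", format(x$alphas, digits = 4), "\n")
  invisible(x)
}

#' Solve the SSL problem on a fused graph
#'
#' Computes `f = (I + sum_k alpha_k L_k)^{-1} y`, i.e. [ssl_solve()]
#' applied to the coefficient-weighted sum of Laplacians.
#'
#' @param laplacians List of [graph_laplacian]s.
#' @param labels A [label_vector].
#' @param alphas Nonnegative coefficients, one per Laplacian.
#' @return Named numeric score vector.
#' @export
ssl_solve_combined <- function(laplacians, labels, alphas) {
  if (inherits(laplacians, c("graph_laplacian", "similarity_graph"))) {
    laplacians <- list(laplacians)
  }
  Ls <- lapply(laplacians, as_laplacian)
  if (length(alphas) != length(Ls)) {
    stop_arg("need one coefficient per Laplacian")
  }
  if (any(alphas < 0)) stop_arg("coefficients must be nonnegative")
  n <- nrow(Ls[[1]])
  y <- check_labels_for_graph(labels, Ls[[1]])
  A <- diag(n)
  for (k in seq_along(Ls)) A <- A + alphas[k] * unclass(Ls[[k]])
  f <- spd_solve(A, y)
  names(f) <- rownames(Ls[[1]])
  f
}

#' Fit a graph semi-supervised classifier
#'
#' The central fitting function: propagates the known \eqn{\pm 1} labels
#' over one or several patient-similarity graphs and returns real-valued
#' scores for every patient.  With a single graph the solution is
#' `f = (I + mu_smooth * L)^{-1} y`.  With several graphs the Laplacian
#' combination coefficients are first optimised under the `mu_budget`
#' constraint (see [combine_graphs()]) and the fused system is solved.
#'
#' @param graphs A [similarity_graph] / [graph_laplacian], or a (possibly
#'   named) list of them over the same patients.
#' @param labels A [label_vector]; 0 marks the patients to predict.
#' @param mu_smooth Smoothness trade-off used when a single graph is
#'   given.
#' @param mu_budget Budget for the coefficient sum when several graphs
#'   are fused.
#' @param criterion Coefficient criterion for fused fits; see
#'   [combine_graphs()].
#' @return An object of class `graph_ssl` with components `scores`
#'   (named numeric), `alphas`, `labels`, `objective` (for fused fits),
#'   and `call`.  Methods: `print`, `summary`, `coef` (the coefficients),
#'   `fitted` (the scores), `predict`, `residuals`, `plot`.
#' @examples
#' set.seed(1)
#' x <- expression_dataset(matrix(rnorm(200) + rep(c(0, 2), each = 10), 20, 10,
#'        dimnames = list(paste0("P", 1:20), paste0("g", 1:10))))
#' g <- knn_gaussian_graph(x, k = 3)
#' y <- label_vector(c(rep(-1, 8), 0, 0, rep(1, 8), 0, 0), paste0("P", 1:20))
#' fit <- graph_ssl(g, y)
#' predict(fit, type = "label")
#' @export
graph_ssl <- function(graphs, labels, mu_smooth = 1, mu_budget = 1,
                      criterion = c("alignment", "quadratic")) {
  cl <- match.call()
  criterion <- match.arg(criterion)
  single <- inherits(graphs, c("similarity_graph", "graph_laplacian"))
  if (single) graphs <- list(graphs)
  if (!length(graphs)) stop_arg("need at least one graph")
  Ls <- lapply(graphs, as_laplacian)
  if (length(Ls) == 1) {
    alphas <- mu_smooth
    f <- ssl_solve(Ls[[1]], labels, mu = mu_smooth)
    objective <- NA_real_
  } else {
    comb <- combine_graphs(Ls, labels, budget = mu_budget,
                           criterion = criterion)
    alphas <- comb$alphas
    objective <- comb$objective
    f <- ssl_solve_combined(Ls, labels, alphas)
  }
  names(alphas) <- names(graphs) %||% paste0("graph", seq_along(Ls))
  y <- check_labels_for_graph(labels, Ls[[1]])
  structure(list(scores = f, alphas = alphas,
                 labels = label_vector(y, names(f)),
                 objective = objective, call = cl),
            class = "graph_ssl")
}

#' Threshold SSL scores into class labels
#'
#' @param solution A [graph_ssl] fit or a numeric score vector.
#' @param threshold Decision threshold; scores `>= threshold` (ties
#'   included) map to +1, the rest to -1.
#' @return Named vector over \{-1, +1\}.
#' @export
predict_labels <- function(solution, threshold = 0) {
  f <- if (inherits(solution, "graph_ssl")) solution$scores else solution
  out <- ifelse(f >= threshold, 1, -1)
  names(out) <- names(f)
  out
}

#' @export
print.graph_ssl <- function(x, ...) {
  cat("Graph semi-supervised fit\n\nCall:\n")
  print(x$call)
  y <- x$labels
  cat(sprintf("\n%d patients: %d labeled +1, %d labeled -1, %d unlabeled\n",
              length(y), sum(y == 1), sum(y == -1), sum(y == 0)))
  cat("Coefficients (alpha):\n")
  print(round(x$alphas, 4))
  invisible(x)
}

#' @export
coef.graph_ssl <- function(object, ...) object$alphas

#' @export
fitted.graph_ssl <- function(object, ...) object$scores

#' @export
residuals.graph_ssl <- function(object, ...) {
  lab <- object$labels != 0
  (as.numeric(object$labels) - object$scores)[lab]
}

#' @rdname graph_ssl
#' @param object,x A `graph_ssl` fit.
#' @param type `"score"` for the raw propagation scores, `"label"` for
#'   thresholded \eqn{\pm 1} predictions.
#' @param threshold Decision threshold for `type = "label"`.
#' @param which `"unlabeled"` (default) or `"all"` patients.
#' @param ... Unused.
#' @export
predict.graph_ssl <- function(object, type = c("score", "label"),
                              threshold = 0, which = c("unlabeled", "all"),
                              ...) {
  type <- match.arg(type)
  which <- match.arg(which)
  f <- object$scores
  if (which == "unlabeled") f <- f[object$labels == 0]
  if (type == "label") predict_labels(f, threshold) else f
}

#' @export
summary.graph_ssl <- function(object, ...) {
  y <- object$labels
  pred <- predict_labels(object$scores)
  acc <- if (any(y != 0)) mean(pred[y != 0] == y[y != 0]) else NA_real_
  out <- list(call = object$call, alphas = object$alphas,
              n = length(y), n_labeled = sum(y != 0),
              train_accuracy = acc,
              score_range = range(object$scores),
              objective = object$objective)
  class(out) <- "summary.graph_ssl"
  out
}

#' @export
print.summary.graph_ssl <- function(x, ...) {
  cat("Graph semi-supervised fit\n\nCall:\n")
  print(x$call)
  cat(sprintf("\nPatients: %d (%d labeled)\n", x$n, x$n_labeled))
  cat(sprintf("Training sign accuracy: %.3f\n", x$train_accuracy))
  cat(sprintf("Score range: [%.3f, %.3f]\n",
              x$score_range[1], x$score_range[2]))
  if (!is.na(x$objective)) {
    cat(sprintf("Combination objective: %.6g\n", x$objective))
  }
  cat("Coefficients (alpha):\n")
  print(round(x$alphas, 4))
  invisible(x)
}

#' @rdname graph_ssl
#' @export
plot.graph_ssl <- function(x, ...) {
  y <- as.numeric(x$labels)
  grp <- factor(ifelse(y == 0, "unlabeled", sprintf("%+d", y)),
                levels = c("-1", "unlabeled", "+1"))
  graphics::stripchart(split(x$scores, grp), vertical = TRUE,
                       method = "jitter", pch = 1,
                       ylab = "propagation score f",
                       xlab = "known label", ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}
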