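#' Construct a patient-similarity graph
#'
#' A similarity graph is a symmetric nonnegative patients x patients weight
#' matrix with zero diagonal.  Nodes are patients; the weight `w[i, j]`
#' encodes how strongly the two patients' molecular profiles resemble each
#' other.
#'
#' @param weights Symmetric nonnegative numeric matrix with zero diagonal.
#' @param patient_ids Character identifiers; default `rownames(weights)`.
#' @return An object of class `similarity_graph`.
#' @export
similarity_graph <- function(weights, patient_ids = rownames(weights)) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop_arg("weight matrix must be square")
  if (anyNA(weights) || any(!is.finite(weights))) {
    stop_arg("weights contain missing or non-finite entries")
  }
  if (max(abs(weights - t(weights))) > 1e-8) {
    stop_arg("weight matrix must be symmetric")
  }
  if (any(weights < 0)) stop_arg("weights must be nonnegative")
  if (any(diag(weights) != 0)) stop_arg("diagonal weights must be zero")
  if (is.null(patient_ids)) patient_ids <- paste0("P", seq_len(n))
  patient_ids <- as.character(patient_ids)
  if (length(patient_ids) != n) stop_arg("patient_ids must match dimension")
  if (anyDuplicated(patient_ids)) stop_arg("patient_ids must be unique")
  weights <- (weights + t(weights)) / 2  # remove numerical asymmetry
  dimnames(weights) <- list(patient_ids, patient_ids)
  structure(weights, class = c("similarity_graph", "matrix", "array"))
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("similarity_graph: %d patients, %d undirected edges\n",
              nrow(x), n_edges(x)))
  invisible(x)
}

#' Count undirected edges of a similarity graph
#'
#' @param graph A [similarity_graph].
#' @return Number of strictly positive upper-triangle weights.
#' @export
n_edges <- function(graph) {
  sum(graph[upper.tri(graph)] > 0)
}

#' Build a Gaussian k-nearest-neighbour patient graph
#'
#' Connects patients `i` and `j` whenever either is among the other's `k`
#' nearest neighbours in Euclidean distance (the "OR" rule, which makes the
#' graph symmetric by construction), and weights each edge by the Gaussian
#' kernel `exp(-d2 / sigma^2)` of the squared distance `d2`.
#'
#' Features are standardised (zero mean, unit variance per feature) before
#' distances are computed, so that high-variance features do not dominate;
#' set `standardize = FALSE` to use the matrix as given.  When `sigma` is
#' `NULL` the bandwidth is set by the median heuristic: `sigma^2` equals
#' the median of the nonzero squared pairwise distances.
#'
#' @param data An [expression_dataset] (patients x features).
#' @param k Number of nearest neighbours, `1 <= k < N`.  Ties in distance
#'   are broken by patient order, deterministically.
#' @param sigma Gaussian bandwidth (`> 0`), or `NULL` for the median
#'   heuristic.
#' @param standardize Standardise features before computing distances?
#' @return A [similarity_graph] with weights in \[0, 1\].
#' @examples
#' x <- expression_dataset(matrix(rnorm(40), 8, 5,
#'     dimnames = list(paste0("P", 1:8), paste0("g", 1:5))))
#' g <- knn_gaussian_graph(x, k = 2)
#' @export
knn_gaussian_graph <- function(data, k = 5, sigma = NULL, standardize = TRUE) {
  data <- as_expr(data)
  n <- nrow(data)
  if (length(k) != 1 || k < 1 || k >= n) {
    stop_arg("k must satisfy 1 <= k < N (N = %d)", n)
  }
  x <- unclass(data)
  if (standardize) x <- scale_features(x)
  d2 <- as.matrix(stats::dist(x))^2

  if (is.null(sigma)) {
    nz <- d2[upper.tri(d2)]
    nz <- nz[nz > 0]
    if (!length(nz)) nz <- 1
    sigma2 <- stats::median(nz)
  } else {
    if (sigma <= 0) stop_arg("sigma must be > 0")
    sigma2 <- sigma^2
  }

  # k nearest neighbours of each patient; order() breaks distance ties by
  # index, which keeps the construction deterministic.
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, -i])[seq_len(k)]
    nb <- seq_len(n)[-i][nb]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)  # edge if i in knn(j) OR j in knn(i)
  w <- exp(-d2 / sigma2) * adj
  diag(w) <- 0
  similarity_graph(w, rownames(data))
}

#' Graph Laplacian
#'
#' Returns `L = D - W` where `D` is the diagonal matrix of weighted node
#' degrees.  `L` is symmetric positive semi-definite with zero row sums;
#' the quadratic form `f' L f = 1/2 * sum_ij w_ij (f_i - f_j)^2` measures
#' the roughness of a score vector `f` over the graph's edges.
#'
#' @param graph A [similarity_graph].
#' @return An N x N matrix of class `graph_laplacian`.
#' @export
graph_laplacian <- function(graph) {
  if (!inherits(graph, "similarity_graph")) {
    stop_arg("graph must be a similarity_graph")
  }
  w <- unclass(graph)
  L <- diag(rowSums(w), nrow(w)) - w
  dimnames(L) <- dimnames(w)
  structure(L, class = c("graph_laplacian", "matrix", "array"))
}

as_laplacian <- function(x) {
  if (inherits(x, "graph_laplacian")) return(x)
  if (inherits(x, "similarity_graph")) return(graph_laplacian(x))
  stop_arg("expected a similarity_graph or graph_laplacian")
}

#' Randomly remove edges from a similarity graph
#'
#' Deletes exactly `round(fraction * E)` of the `E` undirected edges,
#' chosen uniformly at random, zeroing both `(i, j)` and `(j, i)` so the
#' graph stays symmetric.  Used to emulate incomplete similarity
#' information in the edge-damage experiments.
#'
#' @param graph A [similarity_graph].
#' @param fraction Proportion of undirected edges to remove, in \[0, 1\].
#' @param seed Integer seed controlling the random choice; `NULL` uses the
#'   current RNG state.
#' @return A damaged [similarity_graph].
#' @export
damage_graph <- function(graph, fraction, seed = NULL) {
  if (!inherits(graph, "similarity_graph")) {
    stop_arg("graph must be a similarity_graph")
  }
  if (length(fraction) != 1 || is.na(fraction) || fraction < 0 || fraction > 1) {
    stop_arg("fraction must lie in [0, 1]")
  }
  w <- unclass(graph)
  up <- which(upper.tri(w) & w > 0)
  n_remove <- round(fraction * length(up))
  if (n_remove > 0) {
    drop <- with_seed(seed, sample(length(up), n_remove))
    idx <- up[drop]
    w[idx] <- 0
    w <- pmin(w, t(w))  # zero the mirrored entries
  }
  similarity_graph(w, rownames(graph))
}

#' Export or import a graph as an edge list
#'
#' Three-column TSV: `patient_i`, `patient_j`, `weight`, one row per
#' undirected edge (upper triangle only).
#'
#' @param graph A [similarity_graph].
#' @param path Output path.
#' @export
write_graph_edges <- function(graph, path) {
  idx <- which(upper.tri(graph) & graph > 0, arr.ind = TRUE)
  df <- data.frame(patient_i = rownames(graph)[idx[, 1]],
                   patient_j = rownames(graph)[idx[, 2]],
                   weight = graph[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
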