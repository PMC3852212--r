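#' Inter-relation scores from miRNA-target coupling
#'
#' The inter-relation score couples two expression layers through known
#' miRNA-to-target-gene links.  For patients `i` (miRNA profile) and `j`
#' (gene profile) the primary measure (`"gr5"`) sums, over every target
#' pair `(l, m)` in the map, the product of patient `i`'s expression of
#' miRNA `l` and patient `j`'s expression of gene `m`:
#'
#' \deqn{f_{ij} = \sum_{(l,m)} \mathrm{miRNA}(i, l) \cdot \mathrm{gene}(j, m)}
#'
#' The alternative measure `"gr4"` aggregates from the gene side: each
#' gene contributes its expression in patient `j` times the mean
#' expression in patient `i` of the miRNAs targeting it; genes targeted by
#' no miRNA contribute zero.
#'
#' Features are scaled to unit variance (without centring) beforehand so
#' no single miRNA or gene dominates the sum through its measurement
#' scale, while the expression levels that the product structure relies on
#' are preserved; see the methods vignette for the rationale.  Disable
#' with `rescale = FALSE` to apply the raw sum.
#'
#' @param mirna,genes [expression_dataset]s sharing the same ordered
#'   patient list.
#' @param targets A non-empty [target_map]; pairs referencing features
#'   absent from either dataset are ignored (an all-absent map is an
#'   error).
#' @param method `"gr5"` (sum over pairs, miRNA-focused) or `"gr4"`
#'   (mean over targeting miRNAs, gene-focused).
#' @param rescale Scale each feature to unit variance first?
#' @return An object of class `inter_scores`: the N x N raw score matrix
#'   with a `method` attribute.  Pass to [normalize_scores()] to obtain a
#'   [similarity_graph].
#' @seealso [normalize_scores()], [inter_graph()]
#' @export
inter_scores <- function(mirna, genes, targets, method = c("gr5", "gr4"),
                         rescale = TRUE) {
  method <- match.arg(method)
  mirna <- as_expr(mirna, "mirna")
  genes <- as_expr(genes, "genes")
  check_same_patients(mirna, genes)
  check_nonempty_map(targets)
  targets <- restrict_map(targets, colnames(mirna), colnames(genes))
  check_nonempty_map(targets)

  m <- unclass(mirna)
  g <- unclass(genes)
  if (rescale) {
    m <- scale_features(m, center = FALSE)
    g <- scale_features(g, center = FALSE)
  }
  li <- match(targets$mirna_id, colnames(m))
  mi <- match(targets$gene_id, colnames(g))

  # Pair-indicator matrix S (miRNAs x genes); f = M S G'.  For gr4 each
  # column of S is normalised by the gene's number of targeting miRNAs.
  S <- matrix(0, ncol(m), ncol(g))
  S[cbind(li, mi)] <- 1
  if (method == "gr4") {
    n_per_gene <- colSums(S)
    S <- sweep(S, 2, pmax(n_per_gene, 1), "/")
  }
  f <- m %*% S %*% t(g)
  dimnames(f) <- list(rownames(m), rownames(g))
  structure(f, method = method, class = c("inter_scores", "matrix", "array"))
}

#' @export
print.inter_scores <- function(x, ...) {
  cat(sprintf("inter_scores (%s): %d x %d patients\n",
              attr(x, "method"), nrow(x), ncol(x)))
  invisible(x)
}

#' Normalise inter-relation scores into a similarity graph
#'
#' Z-scores the raw score matrix over all of its `N^2` entries (population
#' standard deviation), squashes through the logistic function
#' `w = 1 / (1 + exp(-Z))` so every weight lies strictly in (0, 1), then
#' symmetrises by the arithmetic mean `(W + W') / 2` and zeroes the
#' diagonal so the result is a valid [similarity_graph].
#'
#' @param scores An [inter_scores] object (or any finite numeric square
#'   matrix of scores).
#' @return A [similarity_graph].
#' @export
normalize_scores <- function(scores) {
  f <- unclass(scores)
  if (!is.matrix(f) || nrow(f) != ncol(f)) stop_arg("scores must be square")
  if (anyNA(f) || any(!is.finite(f))) stop_arg("scores must be finite")
  n2 <- length(f)
  mu <- mean(f)
  sd_pop <- sqrt(sum((f - mu)^2) / n2)
  if (sd_pop == 0) {
    stop_arg(paste("degenerate inter-relation scores (zero variance):",
                   "the target map carries no patient-level information"))
  }
  z <- (f - mu) / sd_pop
  w <- 1 / (1 + exp(-z))
  w <- (w + t(w)) / 2
  diag(w) <- 0
  similarity_graph(w, rownames(f))
}

#' Build an inter-relation patient graph
#'
#' Dispatches over the five inter-relation measures compared in the
#' framework:
#' \describe{
#'   \item{gr1}{Element-wise (Hadamard) product of the patient-patient
#'     Pearson correlation matrices of the gene and miRNA layers, passed
#'     through [normalize_scores()].}
#'   \item{gr2}{Concatenation of each patient's gene and miRNA vectors
#'     into one profile, then a Gaussian k-NN graph.}
#'   \item{gr3}{As gr2, restricted to the miRNAs and genes appearing in at
#'     least one target pair.}
#'   \item{gr4}{Gene-focused target-pair score ([inter_scores()] with
#'     `method = "gr4"`), normalised.}
#'   \item{gr5}{miRNA-focused target-pair sum ([inter_scores()] with
#'     `method = "gr5"`), normalised — the primary measure.}
#' }
#'
#' @inheritParams inter_scores
#' @param method One of `"gr1"` ... `"gr5"`.
#' @param k,sigma k-NN graph parameters, used by `gr2`/`gr3` only.
#' @return A [similarity_graph].
#' @export
inter_graph <- function(mirna, genes, targets = NULL,
                        method = c("gr5", "gr1", "gr2", "gr3", "gr4"),
                        k = 5, sigma = NULL) {
  method <- match.arg(method)
  mirna <- as_expr(mirna, "mirna")
  genes <- as_expr(genes, "genes")
  check_same_patients(mirna, genes)
  if (method %in% c("gr3", "gr4", "gr5") && is.null(targets)) {
    stop_arg("method %s requires a target map", method)
  }
  switch(method,
    gr1 = {
      check_zero_variance_patients(genes, "genes")
      check_zero_variance_patients(mirna, "mirna")
      cg <- stats::cor(t(unclass(genes)))
      cm <- stats::cor(t(unclass(mirna)))
      normalize_scores(structure(cg * cm, dimnames = dimnames(cg)))
    },
    gr2 = {
      knn_gaussian_graph(concat_layers(genes, mirna), k = k, sigma = sigma)
    },
    gr3 = {
      check_nonempty_map(targets)
      gk <- intersect(colnames(genes), targets$gene_id)
      mk <- intersect(colnames(mirna), targets$mirna_id)
      if (!length(gk) || !length(mk)) {
        stop_arg("no measured features belong to the target relations")
      }
      knn_gaussian_graph(concat_layers(select_features(genes, gk),
                                       select_features(mirna, mk)),
                         k = k, sigma = sigma)
    },
    gr4 = normalize_scores(inter_scores(mirna, genes, targets, "gr4")),
    gr5 = normalize_scores(inter_scores(mirna, genes, targets, "gr5"))
  )
}

concat_layers <- function(a, b) {
  stopifnot(identical(rownames(a), rownames(b)))
  expression_dataset(cbind(unclass(a), unclass(b)))
}

check_zero_variance_patients <- function(data, what) {
  v <- apply(unclass(data), 1, stats::var)
  if (any(v == 0)) {
    stop_arg("patient %s has zero variance across %s features; correlation undefined",
             rownames(data)[which(v == 0)[1]], what)
  }
  invisible(TRUE)
}
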