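#' Univariate t-test feature selection
#'
#' Scores every feature by a two-sample t statistic contrasting the two
#' labeled classes (unlabeled patients are ignored) and keeps the
#' `n_select` features with the largest `|t|`.  The default is the Welch
#' unequal-variance statistic; `var_equal = TRUE` gives the pooled
#' (classic Student) variant.  A feature with zero variance in both
#' classes gets `|t| = Inf` when the class means differ and 0 when they
#' are equal.  Ties in `|t|` are broken by feature order, so selection is
#' deterministic.
#'
#' @param data An [expression_dataset].
#' @param labels A [label_vector] aligned with `data`; only the \eqn{\pm 1}
#'   entries are used, and each class must contain at least two patients.
#' @param n_select Number of features to keep (`<= n_features`).
#' @param var_equal Use the pooled-variance statistic?
#' @return The dataset restricted to the selected features, in their
#'   original column order, with attributes `statistics` (named t values
#'   for all features) and `ranking` (all feature ids, strongest first).
#' @export
ttest_select <- function(data, labels, n_select, var_equal = FALSE) {
  data <- as_expr(data)
  if (!inherits(labels, "label_vector")) {
    labels <- label_vector(labels, names(labels) %||% rownames(data))
  }
  if (length(labels) != nrow(data)) {
    stop_arg("labels and data dimensions differ")
  }
  if (n_select < 1 || n_select > ncol(data)) {
    stop_arg("n_select must lie in 1..%d", ncol(data))
  }
  t_stat <- ttest_statistics(data, labels, var_equal)
  ranking <- colnames(data)[order(-abs(t_stat))]
  keep <- colnames(data) %in% ranking[seq_len(n_select)]
  out <- select_features(data, colnames(data)[keep])
  attr(out, "statistics") <- t_stat
  attr(out, "ranking") <- ranking
  out
}

# Vectorised per-feature two-sample t statistics over the labeled patients.
ttest_statistics <- function(data, labels, var_equal = FALSE) {
  x <- unclass(data)
  a <- x[labels == 1, , drop = FALSE]
  b <- x[labels == -1, , drop = FALSE]
  n1 <- nrow(a); n2 <- nrow(b)
  if (n1 < 2 || n2 < 2) {
    stop_arg("each class needs at least 2 labeled patients (have %d and %d)",
             n1, n2)
  }
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2, stats::var); v2 <- apply(b, 2, stats::var)
  se2 <- if (var_equal) {
    ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2) * (1 / n1 + 1 / n2)
  } else {
    v1 / n1 + v2 / n2
  }
  t_stat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2),
                   ifelse(m1 == m2, 0, Inf * sign(m1 - m2)))
  names(t_stat) <- colnames(x)
  t_stat
}

#' Area under the ROC curve
#'
#' Computes the AUC of real-valued scores against \eqn{\pm 1} truth as the
#' normalised Mann-Whitney statistic: the fraction of (positive, negative)
#' pairs in which the positive patient scores higher, counting ties as
#' one half.
#'
#' @param scores Numeric score vector.
#' @param truth Labels over \{-1, +1\}; both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' compute_auc(c(0.9, 0.8, 0.3, 0.1), c(1, -1, 1, -1))  # 0.75
#' @export
compute_auc <- function(scores, truth) {
  truth <- as.numeric(truth)
  if (length(scores) != length(truth)) stop_arg("length mismatch")
  if (!all(truth %in% c(-1, 1))) stop_arg("truth must lie in {-1, +1}")
  n1 <- sum(truth == 1); n0 <- sum(truth == -1)
  if (n1 == 0 || n0 == 0) {
    stop_arg("AUC undefined: both classes must be present")
  }
  r <- rank(scores)  # midranks, so ties count 1/2
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired observations (e.g. per-fold AUCs
#' of two graph variants).  Zero differences are discarded; ties among
#' the absolute differences receive midranks.  For `n <= 25` retained
#' pairs the p-value is computed from the exact distribution of the
#' positive-rank sum over all `2^n` sign assignments (a dynamic program
#' over the tied rank multiset); larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b Equal-length paired numeric vectors.
#' @return List with `statistic` (positive-rank sum `V`), `p_value`, and
#'   `n` (pairs retained after dropping zero differences).
#' @export
wilcoxon_compare <- function(a, b) {
  if (length(a) != length(b)) stop_arg("paired vectors must have equal length")
  d <- b - a
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop_arg("degenerate comparison: all paired differences are zero")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25) {
    # exact null distribution of V for this (possibly tied) rank multiset;
    # doubling makes midranks integral.
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1)  # counts[s + 1] = #assignments with 2V = s
    counts[1] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), counts[seq_len(total + 1 - rk)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    v2 <- as.integer(round(2 * v))
    p_le <- sum(probs[seq_len(v2 + 1)])
    p_ge <- sum(probs[seq.int(v2 + 1, total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = v, p_value = p, n = n)
}

#' Experiment configuration
#'
#' Bundles every tunable of the evaluation protocol: repeated stratified
#' k-fold cross-validation, per-fold t-test feature selection, graph
#' construction, edge damage, graph fusion and the choice of
#' inter-relation measure.
#'
#' @param damage_fractions Edge-damage fractions to evaluate.
#' @param n_repeats,n_folds Cross-validation protocol (default 3 x 5).
#' @param k_nn,sigma Gaussian k-NN graph parameters ([knn_gaussian_graph]);
#'   `sigma = NULL` selects the median heuristic.
#' @param mu_smooth,mu_budget SSL trade-off for single graphs and
#'   coefficient budget for fused graphs.
#' @param n_select_genes,n_select_mirnas Features kept by per-fold t-test
#'   selection on each layer.
#' @param min_votes Vote threshold applied to the target map.
#' @param gr_method Inter-relation measure, `"gr1"` ... `"gr5"`.
#' @param var_equal Pooled-variance t statistics instead of Welch?
#' @param seed Base seed; folds, damage and every other random choice are
#'   derived deterministically from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(damage_fractions = c(0, 0.1, 0.3, 0.5, 0.7, 0.9),
                              n_repeats = 3, n_folds = 5, k_nn = 5,
                              sigma = NULL, mu_smooth = 1, mu_budget = 1,
                              n_select_genes = 11, n_select_mirnas = 19,
                              min_votes = 1, gr_method = "gr5",
                              var_equal = FALSE, seed = 1) {
  if (n_folds < 2) stop_arg("n_folds must be >= 2")
  if (n_repeats < 1) stop_arg("n_repeats must be >= 1")
  if (any(damage_fractions < 0 | damage_fractions > 1)) {
    stop_arg("damage_fractions must lie in [0, 1]")
  }
  gr_method <- match.arg(gr_method, c("gr1", "gr2", "gr3", "gr4", "gr5"))
  structure(list(damage_fractions = damage_fractions, n_repeats = n_repeats,
                 n_folds = n_folds, k_nn = k_nn, sigma = sigma,
                 mu_smooth = mu_smooth, mu_budget = mu_budget,
                 n_select_genes = n_select_genes,
                 n_select_mirnas = n_select_mirnas, min_votes = min_votes,
                 gr_method = gr_method, var_equal = var_equal, seed = seed),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("experiment_config:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                if (is.null(v)) "NULL" else paste(v, collapse = " ")))
  }
  invisible(x)
}

# Seeded stratified fold assignment: within each class, patients are
# shuffled and dealt round-robin, so every fold keeps both classes as long
# as each class has >= n_folds members.
stratified_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in c(-1, 1)) {
      idx <- which(labels == cl)
      idx <- idx[sample(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

# Build the inter-relation graph for one training fold.  Map-based
# measures (gr1/gr4/gr5) use the full matrices — the target map itself
# restricts which features contribute — while the distance-based
# concatenation measures (gr2/gr3) reuse the per-fold feature selection
# to keep the Euclidean geometry informative.
fold_inter_graph <- function(method, mirna, genes, targets, y_train, cfg) {
  switch(method,
    gr2 = {
      sel_g <- ttest_select(genes, y_train, min(cfg$n_select_genes, ncol(genes)),
                            cfg$var_equal)
      sel_m <- ttest_select(mirna, y_train, min(cfg$n_select_mirnas, ncol(mirna)),
                            cfg$var_equal)
      inter_graph(sel_m, sel_g, method = "gr2", k = cfg$k_nn, sigma = cfg$sigma)
    },
    inter_graph(mirna, genes, targets, method = method,
                k = cfg$k_nn, sigma = cfg$sigma)
  )
}

#' Run the edge-damage / augmentation experiment
#'
#' The full evaluation loop: for every repeat and stratified fold, test
#' labels are masked, genes are re-selected by t test on the training
#' labels only, the original gene graph `G_O` is built, the
#' inter-relation graph `G_R` is built by the configured measure, and for
#' every damage fraction the damaged graph `G_D` and the augmented graph
#' `G_A` (fusion of `G_D` and `G_R` with coefficients optimised on the
#' training labels) are evaluated by the AUC of the propagation scores on
#' the held-out patients.
#'
#' @param cohort A [synthetic_cohort], or any list with elements
#'   `gene_expr`, `mirna_expr`, `targets`, `labels` (e.g. from
#'   [read_cohort()]).
#' @param config An [experiment_config].
#' @return An object of class `experiment_result`: list with `records`
#'   (one row per graph kind x damage fraction x repeat x fold),
#'   `summary` (per-condition mean and sd of AUC), `wilcoxon` (per
#'   fraction, paired test of `G_D` vs `G_A` over the per-fold AUCs) and
#'   `config`.
#' @export
run_damage_experiment <- function(cohort, config = experiment_config()) {
  cfg <- config
  genes <- as_expr(cohort$gene_expr, "gene_expr")
  mirna <- as_expr(cohort$mirna_expr, "mirna_expr")
  check_same_patients(mirna, genes)
  labels <- cohort$labels
  if (!inherits(labels, "label_vector")) {
    labels <- label_vector(labels, rownames(genes))
  }
  targets <- filter_by_votes(cohort$targets, cfg$min_votes)
  check_nonempty_map(targets)

  records <- list()
  for (rep_i in seq_len(cfg$n_repeats)) {
    fold <- stratified_folds(labels, cfg$n_folds,
                             derive_seed(cfg$seed, 101, rep_i))
    for (fold_i in seq_len(cfg$n_folds)) {
      test <- fold == fold_i
      y_train <- label_vector(ifelse(test, 0, as.numeric(labels)),
                              names(labels))
      truth_test <- as.numeric(labels)[test]

      sel <- ttest_select(genes, y_train, min(cfg$n_select_genes, ncol(genes)),
                          cfg$var_equal)
      g_o <- knn_gaussian_graph(sel, k = cfg$k_nn, sigma = cfg$sigma)
      g_r <- fold_inter_graph(cfg$gr_method, mirna, genes, targets,
                              y_train, cfg)

      auc_of <- function(f) compute_auc(f[test], truth_test)
      auc_go <- auc_of(ssl_solve(graph_laplacian(g_o), y_train, cfg$mu_smooth))
      auc_gr <- auc_of(ssl_solve(graph_laplacian(g_r), y_train, cfg$mu_smooth))
      l_r <- graph_laplacian(g_r)

      for (frac in cfg$damage_fractions) {
        g_d <- damage_graph(g_o, frac,
                            derive_seed(cfg$seed, 202, rep_i, fold_i,
                                        round(frac * 1000)))
        l_d <- graph_laplacian(g_d)
        auc_gd <- auc_of(ssl_solve(l_d, y_train, cfg$mu_smooth))
        comb <- combine_graphs(list(l_d, l_r), y_train,
                               budget = cfg$mu_budget)
        auc_ga <- auc_of(ssl_solve_combined(list(l_d, l_r), y_train,
                                            comb$alphas))
        records[[length(records) + 1]] <- data.frame(
          graph = c("GO", "GD", "GR", "GA"), damage_fraction = frac,
          repeat_ = rep_i, fold = fold_i,
          auc = c(auc_go, auc_gd, auc_gr, auc_ga))
      }
    }
  }
  records <- do.call(rbind, records)
  new_experiment_result(records, cfg)
}

new_experiment_result <- function(records, cfg) {
  smry <- stats::aggregate(auc ~ graph + damage_fraction, records,
                           function(x) c(mean = mean(x), sd = stats::sd(x)))
  smry <- data.frame(graph = smry$graph, damage_fraction = smry$damage_fraction,
                     mean_auc = smry$auc[, "mean"], sd_auc = smry$auc[, "sd"])
  smry <- smry[order(smry$graph, smry$damage_fraction), ]
  rownames(smry) <- NULL

  wil <- lapply(unique(records$damage_fraction), function(frac) {
    gd <- records[records$graph == "GD" & records$damage_fraction == frac, ]
    ga <- records[records$graph == "GA" & records$damage_fraction == frac, ]
    key <- order(gd$repeat_, gd$fold)
    gd <- gd[key, ]; ga <- ga[order(ga$repeat_, ga$fold), ]
    res <- tryCatch(wilcoxon_compare(gd$auc, ga$auc),
                    error = function(e) list(statistic = NA_real_,
                                             p_value = NA_real_))
    data.frame(damage_fraction = frac, mean_auc_gd = mean(gd$auc),
               mean_auc_ga = mean(ga$auc), statistic = res$statistic,
               p_value = res$p_value)
  })
  wil <- do.call(rbind, wil)

  structure(list(records = records, summary = smry, wilcoxon = wil,
                 config = cfg),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment_result: %d AUC records (%d repeats x %d folds)\n",
              nrow(x$records), x$config$n_repeats, x$config$n_folds))
  cat("\nPer-condition mean AUC:\n")
  wide <- stats::reshape(x$summary[, c("graph", "damage_fraction", "mean_auc")],
                         idvar = "damage_fraction", timevar = "graph",
                         direction = "wide")
  names(wide) <- sub("mean_auc\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  cat("\nWilcoxon signed-rank, G_D vs G_A:\n")
  print(x$wilcoxon, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.experiment_result <- function(object, ...) object$summary

#' Write experiment outputs
#'
#' Emits `results.tsv` (one row per AUC record), `summary.tsv`
#' (per-condition means and sds), `wilcoxon.tsv` (per damage fraction:
#' mean AUC of `G_D` and `G_A` plus the paired signed-rank p-value) and
#' `run.log` (all resolved parameters).
#'
#' @param result An `experiment_result`.
#' @param directory Output directory, created if needed.
#' @export
write_experiment_result <- function(result, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(directory, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(result$records, "results.tsv")
  wt(result$summary, "summary.tsv")
  wt(result$wilcoxon, "wilcoxon.tsv")
  cfg <- result$config
  lines <- vapply(names(cfg), function(nm) {
    sprintf("%s: %s", nm,
            if (is.null(cfg[[nm]])) "NULL" else paste(cfg[[nm]], collapse = " "))
  }, "")
  writeLines(c("interlink run_damage_experiment", lines),
             file.path(directory, "run.log"))
  invisible(directory)
}

#' Leave-one-feature-out AUC importance
#'
#' For a fixed set of gene features, computes the cross-validated AUC of
#' the intra-relation graph built on all of them, then repeats the same
#' protocol (same folds, same seed) with each feature removed in turn.
#' `AUC_diff = AUC(all) - AUC(all minus feature)`: large values mark
#' features whose removal hurts the model most.
#'
#' @param cohort A cohort list (as for [run_damage_experiment()]).
#' @param config An [experiment_config]; only the CV and graph settings
#'   are used (no re-selection happens — the feature set is given).
#' @param selected_features Non-empty character vector of gene ids.
#' @return Data frame with columns `feature`, `auc_without`, `auc_diff`,
#'   sorted by decreasing `auc_diff` (ties in original feature order),
#'   with the full-model AUC as attribute `auc_full`.
#' @export
auc_diff <- function(cohort, config = experiment_config(), selected_features) {
  if (!length(selected_features)) stop_arg("selected_features is empty")
  genes <- as_expr(cohort$gene_expr, "gene_expr")
  labels <- cohort$labels
  if (!inherits(labels, "label_vector")) {
    labels <- label_vector(labels, rownames(genes))
  }
  cfg <- config

  cv_auc <- function(feature_ids) {
    data <- select_features(genes, feature_ids)
    aucs <- c()
    for (rep_i in seq_len(cfg$n_repeats)) {
      fold <- stratified_folds(labels, cfg$n_folds,
                               derive_seed(cfg$seed, 101, rep_i))
      for (fold_i in seq_len(cfg$n_folds)) {
        test <- fold == fold_i
        y_train <- label_vector(ifelse(test, 0, as.numeric(labels)),
                                names(labels))
        g <- knn_gaussian_graph(data, k = cfg$k_nn, sigma = cfg$sigma)
        f <- ssl_solve(graph_laplacian(g), y_train, cfg$mu_smooth)
        aucs <- c(aucs, compute_auc(f[test], as.numeric(labels)[test]))
      }
    }
    mean(aucs)
  }

  auc_full <- cv_auc(selected_features)
  auc_without <- vapply(selected_features, function(g) {
    remaining <- setdiff(selected_features, g)
    if (!length(remaining)) stop_arg("cannot drop the only feature")
    cv_auc(remaining)
  }, 0)
  out <- data.frame(feature = selected_features,
                    auc_without = auc_without,
                    auc_diff = auc_full - auc_without,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$auc_diff, seq_len(nrow(out))), ]
  rownames(out) <- NULL
  attr(out, "auc_full") <- auc_full
  out
}

#' Compare the five inter-relation measures
#'
#' Runs the shared cross-validation protocol once per measure (identical
#' seed-derived folds, so the `G_O` baseline is the same in every run)
#' and reports the mean AUC of the reconstructed graph alone and of the
#' augmented graph fusing the undamaged `G_O` with it.
#'
#' @param cohort A cohort list (as for [run_damage_experiment()]).
#' @param config An [experiment_config]; `gr_method` is ignored (all five
#'   are run).
#' @param methods Measures to compare.
#' @return Data frame with columns `method`, `auc_gr`, `auc_ga`, with the
#'   shared baselines as attributes `auc_go` (gene graph alone) and
#'   `auc_mirna` (miRNA intra-relation graph alone).
#' @export
compare_gr_methods <- function(cohort, config = experiment_config(),
                               methods = c("gr1", "gr2", "gr3", "gr4", "gr5")) {
  cfg <- config
  genes <- as_expr(cohort$gene_expr, "gene_expr")
  mirna <- as_expr(cohort$mirna_expr, "mirna_expr")
  check_same_patients(mirna, genes)
  labels <- cohort$labels
  if (!inherits(labels, "label_vector")) {
    labels <- label_vector(labels, rownames(genes))
  }
  targets <- filter_by_votes(cohort$targets, cfg$min_votes)
  check_nonempty_map(targets)

  acc <- list()
  base_go <- c(); base_mir <- c()
  for (rep_i in seq_len(cfg$n_repeats)) {
    fold <- stratified_folds(labels, cfg$n_folds,
                             derive_seed(cfg$seed, 101, rep_i))
    for (fold_i in seq_len(cfg$n_folds)) {
      test <- fold == fold_i
      y_train <- label_vector(ifelse(test, 0, as.numeric(labels)),
                              names(labels))
      truth_test <- as.numeric(labels)[test]
      auc_of <- function(f) compute_auc(f[test], truth_test)

      sel_g <- ttest_select(genes, y_train,
                            min(cfg$n_select_genes, ncol(genes)), cfg$var_equal)
      sel_m <- ttest_select(mirna, y_train,
                            min(cfg$n_select_mirnas, ncol(mirna)), cfg$var_equal)
      g_o <- knn_gaussian_graph(sel_g, k = cfg$k_nn, sigma = cfg$sigma)
      l_o <- graph_laplacian(g_o)
      g_mir <- knn_gaussian_graph(sel_m, k = cfg$k_nn, sigma = cfg$sigma)
      base_go <- c(base_go,
                   auc_of(ssl_solve(l_o, y_train, cfg$mu_smooth)))
      base_mir <- c(base_mir,
                    auc_of(ssl_solve(graph_laplacian(g_mir), y_train,
                                     cfg$mu_smooth)))

      for (method in methods) {
        g_r <- fold_inter_graph(method, mirna, genes, targets, y_train, cfg)
        l_r <- graph_laplacian(g_r)
        auc_gr <- auc_of(ssl_solve(l_r, y_train, cfg$mu_smooth))
        comb <- combine_graphs(list(l_o, l_r), y_train, budget = cfg$mu_budget)
        auc_ga <- auc_of(ssl_solve_combined(list(l_o, l_r), y_train,
                                            comb$alphas))
        acc[[length(acc) + 1]] <- data.frame(method = method,
                                             auc_gr = auc_gr, auc_ga = auc_ga)
      }
    }
  }
  acc <- do.call(rbind, acc)
  out <- stats::aggregate(cbind(auc_gr, auc_ga) ~ method, acc, mean)
  out <- out[match(methods, out$method), ]
  rownames(out) <- NULL
  attr(out, "auc_go") <- mean(base_go)
  attr(out, "auc_mirna") <- mean(base_mir)
  out
}
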