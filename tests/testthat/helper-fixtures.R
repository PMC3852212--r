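# Small in-code fixtures shared across test files.

pids <- function(n) sprintf("P%02d", seq_len(n))

# expression_dataset filled with seeded Gaussian noise
rnd_expr <- function(n, p, seed, prefix = "f", mean = 0) {
  withr::with_seed(seed, {
    expression_dataset(matrix(rnorm(n * p, mean = mean), n, p,
                              dimnames = list(pids(n),
                                              paste0(prefix, seq_len(p)))))
  })
}

# dense random symmetric similarity graph
rnd_graph <- function(n, seed, density = 1) {
  withr::with_seed(seed, {
    w <- matrix(runif(n * n), n)
    w <- (w + t(w)) / 2
    if (density < 1) w[w > density] <- 0
    w <- (w + t(w)) / 2
    diag(w) <- 0
    similarity_graph(w, pids(n))
  })
}

rnd_labels <- function(n, seed, p_unlabeled = 0.3) {
  withr::with_seed(seed, {
    v <- sample(c(-1, 1), n, replace = TRUE)
    v[sample(n, round(p_unlabeled * n))] <- 0
    if (all(v == 0)) v[1] <- 1
    label_vector(v, pids(n))
  })
}

# brute-force pairwise-concordance AUC (independent of compute_auc)
auc_bruteforce <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == -1]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# exact two-sided signed-rank p-value by full enumeration of sign flips
wilcoxon_enumerate <- function(a, b) {
  d <- (b - a)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  v_all <- vapply(seq_len(2^n) - 1, function(mask) {
    bits <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    sum(r[bits])
  }, 0)
  p_le <- mean(v_all <= v_obs + 1e-12)
  p_ge <- mean(v_all >= v_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}

# double-loop oracle for the miRNA-focused inter-relation sum
gr5_oracle <- function(m, g, pairs) {
  n <- nrow(m)
  f <- matrix(0, n, n)
  for (t in seq_len(nrow(pairs))) {
    l <- pairs$mirna_id[t]
    mm <- pairs$gene_id[t]
    for (i in seq_len(n)) for (j in seq_len(n)) {
      f[i, j] <- f[i, j] + m[i, l] * g[j, mm]
    }
  }
  f
}

small_cohort <- function(seed = 1, ...) {
  generate_cohort(synthetic_config(n_patients = 30, n_genes = 40,
                                   n_mirnas = 12, n_target_pairs = 25,
                                   n_informative_pairs = 5,
                                   class_balance = 0.4, seed = seed, ...))
}
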