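test_that("t statistics agree with stats::t.test on ordinary features", {
  x <- rnd_expr(20, 6, seed = 61)
  y <- label_vector(rep(c(1, -1), 10), pids(20))
  for (ve in c(FALSE, TRUE)) {
    t_mine <- interlink:::ttest_statistics(x, y, var_equal = ve)
    t_ref <- apply(unclass(x), 2, function(col) {
      unname(t.test(col[as.numeric(y) == 1], col[as.numeric(y) == -1],
                    var.equal = ve)$statistic)
    })
    expect_equal(unname(t_mine), unname(t_ref), tolerance = 1e-12)
  }
})

test_that("feature selection ranks planted shifts first and keeps order", {
  withr::with_seed(71, {
    n <- 30
    shifted <- rnorm(n) + rep(c(0, 3), each = n / 2)
    noise <- rnorm(n)
    x <- expression_dataset(cbind(noise = noise, shifted = shifted),
                            pids(n), c("noise", "shifted"))
  })
  y <- label_vector(rep(c(-1, 1), each = 15), pids(30))
  sel <- ttest_select(x, y, 1)
  expect_identical(colnames(sel), "shifted")

  # constant feature scores |t| = 0 and ranks last
  x2 <- expression_dataset(cbind(unclass(x), flat = rep(2, 30)))
  sel2 <- ttest_select(x2, y, 3)
  expect_identical(colnames(sel2), c("noise", "shifted", "flat"))  # original order
  expect_equal(tail(attr(sel2, "ranking"), 1), "flat")
  expect_equal(unname(attr(sel2, "statistics")["flat"]), 0)

  expect_error(ttest_select(x, label_vector(c(1, rep(0, 29)), pids(30)), 1),
               "at least 2")
})

test_that("compute_auc is the normalised concordance count", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.3, 0.1), c(1, -1, 1, -1)), 0.75)
  expect_equal(compute_auc(4:1, c(1, 1, -1, -1)), 1)
  expect_equal(compute_auc(rep(1, 6), rep(c(1, -1), 3)), 0.5)
  expect_error(compute_auc(1:3, c(1, 1, 1)), "both classes")

  for (s in 1:100) {
    withr::with_seed(s, {
      n <- sample(6:15, 1)
      truth <- c(1, -1, sample(c(-1, 1), n - 2, replace = TRUE))
      scores <- sample(round(rnorm(n), 1))  # coarse values force ties
    })
    expect_equal(compute_auc(scores, truth), auc_bruteforce(scores, truth))
  }
})

test_that("signed-rank p-values match full enumeration for small n", {
  for (s in 1:12) {
    withr::with_seed(s, {
      n <- sample(5:12, 1)
      a <- rnorm(n)
      b <- a + rnorm(n, sd = 0.5) + 0.15
      if (s %% 3 == 0) b <- a + round(b - a, 1)  # induce tied |differences|
    })
    res <- wilcoxon_compare(a, b)
    expect_equal(res$p_value, wilcoxon_enumerate(a, b), tolerance = 1e-12)
  }
})

test_that("signed-rank test agrees with stats::wilcox.test when tie-free", {
  withr::with_seed(91, {
    a <- rnorm(15)
    b <- a + rnorm(15, 0.2)
  })
  res <- wilcoxon_compare(a, b)
  ref <- wilcox.test(b, a, paired = TRUE, exact = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)

  # a uniform shift gives the extreme statistic and the minimal exact p
  shift <- wilcoxon_compare(a, a + 0.1)
  expect_equal(shift$statistic, 15 * 16 / 2)
  expect_equal(shift$p_value, 2 / 2^15, tolerance = 1e-15)

  expect_equal(wilcoxon_compare(a, b)$p_value,
               wilcoxon_compare(b, a)$p_value, tolerance = 1e-12)
  expect_error(wilcoxon_compare(a, a), "degenerate")
})

test_that("large-sample signed-rank uses the corrected normal tail", {
  withr::with_seed(92, {
    a <- rnorm(40)
    b <- a + rnorm(40, 0.3)
  })
  res <- wilcoxon_compare(a, b)
  ref <- wilcox.test(b, a, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("stratified folds are deterministic and keep both classes", {
  y <- label_vector(c(rep(1, 9), rep(-1, 16)), pids(25))
  f1 <- interlink:::stratified_folds(y, 5, seed = 7)
  f2 <- interlink:::stratified_folds(y, 5, seed = 7)
  expect_identical(f1, f2)
  for (k in 1:5) {
    expect_true(all(c(-1, 1) %in% y[f1 != k]))  # training side
    expect_true(all(c(-1, 1) %in% y[f1 == k]))  # held-out side
  }
})

test_that("damage experiment is deterministic and bookkept correctly", {
  coh <- small_cohort(seed = 5)
  cfg <- experiment_config(damage_fractions = c(0, 0.5), n_repeats = 2,
                           n_folds = 3, n_select_genes = 6,
                           n_select_mirnas = 5, k_nn = 3, seed = 11)
  r1 <- run_damage_experiment(coh, cfg)
  r2 <- run_damage_experiment(coh, cfg)
  expect_identical(r1$records, r2$records)

  # 4 graph kinds x 2 fractions x 2 repeats x 3 folds
  expect_equal(nrow(r1$records), 4 * 2 * 2 * 3)
  expect_true(all(r1$records$auc >= 0 & r1$records$auc <= 1))

  # at zero damage G_D is G_O, fold by fold
  rec <- r1$records[r1$records$damage_fraction == 0, ]
  go <- rec[rec$graph == "GO", c("repeat_", "fold", "auc")]
  gd <- rec[rec$graph == "GD", c("repeat_", "fold", "auc")]
  expect_equal(go$auc, gd$auc)
})

test_that("augmentation never degrades the damaged graph on planted signal", {
  coh <- generate_cohort(synthetic_config(seed = 7))
  cfg <- experiment_config(damage_fractions = c(0.5, 0.9), n_repeats = 3,
                           seed = 7)
  res <- run_damage_experiment(coh, cfg)
  sm <- res$summary
  for (fr in c(0.5, 0.9)) {
    ga <- sm$mean_auc[sm$graph == "GA" & sm$damage_fraction == fr]
    gd <- sm$mean_auc[sm$graph == "GD" & sm$damage_fraction == fr]
    expect_gte(ga, gd - 1e-8)
  }
  # the planted signal itself is recovered by the gene graph
  expect_gt(sm$mean_auc[sm$graph == "GO"][1], 0.8)
})

test_that("experiment outputs are written as the four TSV/log files", {
  coh <- small_cohort(seed = 6)
  cfg <- experiment_config(damage_fractions = 0.5, n_repeats = 1,
                           n_folds = 3, n_select_genes = 6,
                           n_select_mirnas = 5, k_nn = 3, seed = 2)
  res <- run_damage_experiment(coh, cfg)
  dir <- withr::local_tempdir()
  write_experiment_result(res, dir)
  expect_setequal(list.files(dir),
                  c("results.tsv", "summary.tsv", "wilcoxon.tsv", "run.log"))
  back <- read.delim(file.path(dir, "results.tsv"))
  expect_equal(nrow(back), nrow(res$records))
  expect_output(print(res), "Wilcoxon signed-rank")
})

test_that("leave-one-feature-out importance flags the planted gene", {
  coh <- generate_cohort(synthetic_config(n_patients = 40, n_genes = 30,
                                          n_mirnas = 8, n_target_pairs = 10,
                                          n_informative_pairs = 1,
                                          effect_size = 2.5, seed = 21))
  feats <- c(coh$truth$informative_genes,
             setdiff(colnames(coh$gene_expr), coh$truth$informative_genes)[1:5])
  cfg <- experiment_config(n_repeats = 1, n_folds = 4, k_nn = 3, seed = 21)
  tab <- auc_diff(coh, cfg, feats)
  expect_equal(nrow(tab), length(feats))
  expect_identical(tab$feature[1], coh$truth$informative_genes)

  # removing one copy of a duplicated feature costs (almost) nothing
  dup <- coh
  ge <- unclass(coh$gene_expr)
  ge <- cbind(ge, copy_of_inf = ge[, coh$truth$informative_genes])
  dup$gene_expr <- expression_dataset(ge)
  tab2 <- auc_diff(dup, cfg, c(feats, "copy_of_inf"))
  expect_lt(abs(tab2$auc_diff[tab2$feature == "copy_of_inf"]), 0.05)
})

test_that("measure comparison shares folds and reduces gr4 to gr5", {
  coh <- small_cohort(seed = 9)
  # rebuild the map so each gene has exactly one targeting miRNA
  tm <- coh$targets
  keep <- !duplicated(tm$gene_id)
  coh$targets <- target_map(tm$mirna_id[keep], tm$gene_id[keep],
                            tm$votes[keep])
  cfg <- experiment_config(n_repeats = 1, n_folds = 3, n_select_genes = 6,
                           n_select_mirnas = 5, k_nn = 3, seed = 3)
  tab <- compare_gr_methods(coh, cfg, methods = c("gr4", "gr5"))
  expect_equal(tab$auc_gr[tab$method == "gr4"],
               tab$auc_gr[tab$method == "gr5"], tolerance = 1e-10)
  expect_true(is.finite(attr(tab, "auc_go")))
  expect_true(is.finite(attr(tab, "auc_mirna")))
})
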