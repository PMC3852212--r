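#' Configuration for a synthetic coupled-expression cohort
#'
#' Defines the simulated study: a shared patient set measured on a gene
#' layer and a miRNA layer, a sparse miRNA-to-target map, and a binary
#' outcome driven by a subset of "informative" miRNA-target pairs in which
#' the miRNA is shifted between classes and its target gene follows with
#' the opposite sign (repression).  Defaults mirror a modest two-class
#' survival cohort: 82 patients split 54 / 28, 200 genes, 60 miRNAs, 120
#' target pairs of which 15 carry signal.
#'
#' @param n_patients,n_genes,n_mirnas Cohort dimensions.
#' @param n_target_pairs Number of miRNA-gene pairs in the target map.
#' @param n_informative_pairs Number of pairs that carry class signal;
#'   each uses a distinct miRNA and a distinct gene.
#' @param effect_size Standardised mean shift of an informative miRNA in
#'   class +1.
#' @param repression_strength Magnitude in \[0, 1\] of the anticorrelation
#'   between an informative miRNA and its target gene.
#' @param class_balance Fraction of patients in class +1.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian measurement
#'   noise.
#' @param mirna_level,gene_level Mean baseline expression level of the
#'   two layers (log-intensity scale); per-feature baselines are drawn
#'   around these with unit spread.  Expression is level-positive, as for
#'   normalised array intensities.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 82, n_genes = 200, n_mirnas = 60,
                             n_target_pairs = 120, n_informative_pairs = 15,
                             effect_size = 1.5, repression_strength = 0.8,
                             class_balance = 28 / 82, noise_sd = 1,
                             mirna_level = 8, gene_level = 8, seed = 1) {
  cfg <- list(n_patients = n_patients, n_genes = n_genes,
              n_mirnas = n_mirnas, n_target_pairs = n_target_pairs,
              n_informative_pairs = n_informative_pairs,
              effect_size = effect_size,
              repression_strength = repression_strength,
              class_balance = class_balance, noise_sd = noise_sd,
              mirna_level = mirna_level, gene_level = gene_level,
              seed = seed)
  check_count <- function(field, minimum = 1) {
    v <- cfg[[field]]
    if (length(v) != 1 || is.na(v) || v < minimum || v != round(v)) {
      stop_arg("invalid %s: must be an integer >= %d", field, minimum)
    }
  }
  check_count("n_patients", 2)
  check_count("n_genes")
  check_count("n_mirnas")
  check_count("n_target_pairs")
  check_count("n_informative_pairs", 0)
  if (cfg$n_informative_pairs > cfg$n_target_pairs) {
    stop_arg("invalid n_informative_pairs: exceeds n_target_pairs")
  }
  if (cfg$n_target_pairs > cfg$n_genes * cfg$n_mirnas) {
    stop_arg("invalid n_target_pairs: exceeds n_genes * n_mirnas")
  }
  if (cfg$n_informative_pairs > min(cfg$n_genes, cfg$n_mirnas)) {
    stop_arg("invalid n_informative_pairs: exceeds min(n_genes, n_mirnas)")
  }
  if (cfg$class_balance <= 0 || cfg$class_balance >= 1) {
    stop_arg("invalid class_balance: must lie strictly in (0, 1)")
  }
  if (cfg$repression_strength < 0 || cfg$repression_strength > 1) {
    stop_arg("invalid repression_strength: must lie in [0, 1]")
  }
  if (cfg$noise_sd <= 0) stop_arg("invalid noise_sd: must be > 0")
  if (cfg$effect_size < 0) stop_arg("invalid effect_size: must be >= 0")
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0("synthetic_config: %d patients, %d genes, %d miRNAs, ",
                     "%d target pairs (%d informative)\n"),
              x$n_patients, x$n_genes, x$n_mirnas, x$n_target_pairs,
              x$n_informative_pairs))
  cat(sprintf("  effect %.2f, repression %.2f, class balance %.2f, seed %d\n",
              x$effect_size, x$repression_strength, x$class_balance, x$seed))
  invisible(x)
}

#' Generate a synthetic coupled miRNA / gene-expression cohort
#'
#' Patients are assigned to classes \eqn{\pm 1} according to
#' `class_balance`.  Each informative (miRNA, gene) pair is planted as:
#' the miRNA's expression is shifted by `+effect_size` in class +1, and
#' its target gene tracks the negative of the miRNA's signal (the
#' centred, class-shift-plus-noise part) scaled by `repression_strength`,
#' plus independent noise — giving the anticorrelated expression pattern
#' characteristic of miRNA-mediated repression.  All remaining features
#' are baseline plus noise, and all remaining target pairs are sampled
#' uniformly from the uninformative feature combinations with vote counts
#' uniform on 1..11.
#'
#' @param config A [synthetic_config]; the same configuration always
#'   yields the identical cohort.
#' @return A list of class `synthetic_cohort` with elements `gene_expr`,
#'   `mirna_expr` ([expression_dataset]s on the same patients), `targets`
#'   ([target_map]), `labels` (fully labeled [label_vector]) and `truth`
#'   (the planted miRNA, gene and pair identities).
#' @examples
#' coh <- generate_cohort(synthetic_config(n_patients = 20, seed = 7))
#' coh$labels
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, as.list(config))
  }
  c_ <- config
  with_seed(c_$seed, {
    n <- c_$n_patients
    patients <- sprintf("P%03d", seq_len(n))
    n_pos <- round(c_$class_balance * n)
    if (n_pos < 1 || n_pos > n - 1) {
      stop_arg("invalid class_balance: a class would be empty")
    }
    cls <- rep(-1, n)
    cls[sample(n, n_pos)] <- 1
    is_pos <- cls == 1

    mirna_ids <- sprintf("mir%03d", seq_len(c_$n_mirnas))
    gene_ids <- sprintf("g%04d", seq_len(c_$n_genes))

    ni <- c_$n_informative_pairs
    inf_mirna <- if (ni > 0) sample(c_$n_mirnas, ni) else integer(0)
    inf_gene <- if (ni > 0) sample(c_$n_genes, ni) else integer(0)

    # miRNA layer: per-feature baseline + noise (+ class shift if planted)
    mu_m <- stats::rnorm(c_$n_mirnas, c_$mirna_level, 1)
    M <- matrix(stats::rnorm(n * c_$n_mirnas, sd = c_$noise_sd),
                n, c_$n_mirnas)
    M <- sweep(M, 2, mu_m, "+")
    if (ni > 0) {
      M[is_pos, inf_mirna] <- M[is_pos, inf_mirna] + c_$effect_size
    }

    # gene layer: informative targets follow -repression * miRNA signal
    mu_g <- stats::rnorm(c_$n_genes, c_$gene_level, 1)
    G <- matrix(stats::rnorm(n * c_$n_genes, sd = c_$noise_sd),
                n, c_$n_genes)
    G <- sweep(G, 2, mu_g, "+")
    r <- c_$repression_strength
    if (ni > 0 && r > 0) {
      signal <- sweep(M[, inf_mirna, drop = FALSE], 2, mu_m[inf_mirna], "-")
      G[, inf_gene] <- sweep(sqrt(1 - r^2) * (G[, inf_gene, drop = FALSE] -
                               matrix(mu_g[inf_gene], n, ni, byrow = TRUE)) -
                               r * signal,
                             2, mu_g[inf_gene], "+")
    }

    # target map: planted pairs plus uniform filler pairs, votes 1..11
    pair_key <- function(l, m) (l - 1) * c_$n_genes + m
    inf_keys <- if (ni > 0) pair_key(inf_mirna, inf_gene) else integer(0)
    all_keys <- seq_len(c_$n_mirnas * c_$n_genes)
    filler <- sample(setdiff(all_keys, inf_keys),
                     c_$n_target_pairs - ni)
    keys <- c(inf_keys, filler)
    l_idx <- (keys - 1) %/% c_$n_genes + 1
    m_idx <- (keys - 1) %% c_$n_genes + 1
    votes <- sample(11L, length(keys), replace = TRUE)
    targets <- target_map(mirna_ids[l_idx], gene_ids[m_idx], votes)

    structure(list(
      gene_expr = expression_dataset(G, patients, gene_ids),
      mirna_expr = expression_dataset(M, patients, mirna_ids),
      targets = targets,
      labels = label_vector(cls, patients),
      truth = list(informative_mirnas = mirna_ids[inf_mirna],
                   informative_genes = gene_ids[inf_gene],
                   informative_pairs = data.frame(
                     mirna_id = mirna_ids[inf_mirna],
                     gene_id = gene_ids[inf_gene],
                     stringsAsFactors = FALSE)),
      config = c_
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d patients, %d genes, %d miRNAs, %d target pairs\n",
              nrow(x$gene_expr), ncol(x$gene_expr), ncol(x$mirna_expr),
              nrow(x$targets)))
  cat(sprintf("  classes: %d labeled +1 / %d labeled -1; %d informative pairs\n",
              sum(x$labels == 1), sum(x$labels == -1),
              nrow(x$truth$informative_pairs)))
  invisible(x)
}

#' Write or read a cohort as TSV files
#'
#' Emits `gene_expr.tsv`, `mirna_expr.tsv`, `targets.tsv` and `labels.tsv`
#' in the package's plain-text formats; `read_cohort()` reads them back.
#'
#' @param cohort A [synthetic_cohort] (or any list with the same fields).
#' @param directory Output directory, created if needed.
#' @return `write_cohort()` returns the directory invisibly;
#'   `read_cohort()` returns a list with elements `gene_expr`,
#'   `mirna_expr`, `targets`, `labels`.
#' @export
write_cohort <- function(cohort, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_arg("cannot create directory %s", directory)
  }
  write_expression(cohort$gene_expr, file.path(directory, "gene_expr.tsv"))
  write_expression(cohort$mirna_expr, file.path(directory, "mirna_expr.tsv"))
  write_target_map(cohort$targets, file.path(directory, "targets.tsv"))
  write_labels(cohort$labels, file.path(directory, "labels.tsv"))
  invisible(directory)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  gene_expr <- read_expression(file.path(directory, "gene_expr.tsv"))
  mirna_expr <- read_expression(file.path(directory, "mirna_expr.tsv"))
  list(gene_expr = gene_expr,
       mirna_expr = mirna_expr,
       targets = read_target_map(file.path(directory, "targets.tsv"),
                                 colnames(mirna_expr), colnames(gene_expr)),
       labels = read_labels(file.path(directory, "labels.tsv")))
}
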