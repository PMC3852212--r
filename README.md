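# interlink

Graph-based semi-supervised prediction of binary clinical outcome from
coupled miRNA and gene-expression profiles, with patient-similarity
graphs *reconstructed* from known miRNA → target-gene relations.

## The problem and who this is for

Transductive outcome prediction on tumour cohorts: every patient —
outcome known or unknown — is a node in a weighted patient-similarity
graph, and the known ±1 labels (e.g. short-term vs long-term survival)
are propagated over its edges.  A single expression layer gives the
ordinary *intra-relation* graph; this package additionally builds an
*inter-relation* graph that couples the miRNA and gene layers through a
target map (miRNA `l` represses gene `m`, supported by 1–11
target-prediction programs), and fuses the two graphs.  The intended
users are computational biologists studying whether prior regulatory
knowledge can compensate for incomplete expression-similarity
information — the package ships the full edge-damage experiment for
exactly that question, plus a synthetic two-layer cohort generator so
everything is testable without any data download.

## The model

Gaussian k-NN similarity between patients \(i, j\):
\(w_{ij} = \exp(-\lVert x_i - x_j\rVert^2 / \sigma^2)\) (edge if either
patient is among the other's k nearest).  With Laplacian \(L = D - W\),
label propagation solves

    min_f (f − y)ᵀ(f − y) + μ fᵀ L f   ⇒   f = (I + μL)⁻¹ y,

where unlabeled patients have \(y = 0\).  The inter-relation score
between miRNA-patient `i` and gene-patient `j` sums expression products
over target pairs,

    f_ij = Σ_{(l,m) ∈ map} miR(i, l) · gene(j, m),

then is z-normalised over all N² entries, mapped through the logistic
function into (0, 1), symmetrised, and zero-diagonalised.  Several
graphs are fused as \(f = (I + \sum_k \alpha_k L_k)^{-1} y\) with
coefficients \(\alpha\) optimised by projected gradient descent over a
budget constraint (label-alignment criterion by default; see the
methods vignette for the two criteria and why the choice matters).
Five inter-relation measures (`gr1`–`gr5`) are implemented for
comparison.

## Worked example

```r
library(interlink)

cohort <- generate_cohort(synthetic_config(seed = 42))
cohort
#> synthetic_cohort: 82 patients, 200 genes, 60 miRNAs, 120 target pairs
#>   classes: 28 labeled +1 / 54 labeled -1; 15 informative pairs

## hide the outcome of the last 22 patients, select genes on the rest
y <- cohort$labels
y_masked <- y; y_masked[61:82] <- 0
y_masked <- label_vector(y_masked, names(y))

sel <- ttest_select(cohort$gene_expr, y_masked, 11)
g_o <- knn_gaussian_graph(sel, k = 5)
g_r <- inter_graph(cohort$mirna_expr, cohort$gene_expr, cohort$targets, "gr5")

fit <- graph_ssl(list(expression = g_o, reconstructed = g_r), y_masked)
fit
#> Graph semi-supervised fit
#>
#> Call:
#> graph_ssl(graphs = list(expression = g_o, reconstructed = g_r),
#>     labels = y_masked)
#>
#> 82 patients: 22 labeled +1, 38 labeled -1, 22 unlabeled
#> Coefficients (alpha):
#>    expression reconstructed
#>             1             0

mean(predict(fit, type = "label") == as.numeric(y)[61:82])
#> [1] 0.9545455
```

The coefficients tell the scientific story: the fusion criterion gives
all weight to the expression graph, because on this planted-repression
cohort the product-based reconstructed graph links patients *across*
classes (its propagation scores rank inversely; the methods vignette
explains why coherent repression forces this).  The held-out patients
are nonetheless classified at 95% accuracy by the expression graph.

The full damage experiment, printed as the per-condition AUC table and
the paired signed-rank comparison:

```r
res <- run_damage_experiment(cohort, experiment_config(n_repeats = 1, seed = 42))
res
#> experiment_result: 120 AUC records (1 repeats x 5 folds)
#>
#> Per-condition mean AUC:
#>  damage_fraction    GA    GD    GO     GR
#>              0.0 0.983 0.983 0.983 0.0552
#>              0.1 0.977 0.977 0.983 0.0552
#>              0.3 0.983 0.983 0.983 0.0552
#>              0.5 0.988 0.988 0.983 0.0552
#>              0.7 0.929 0.929 0.983 0.0552
#>              0.9 0.826 0.826 0.983 0.0552
```

`GO` is the undamaged gene graph, `GD` the damaged one, `GR` the
reconstructed graph alone, `GA` the fused graph: accuracy decays as
edges are deleted and fusion never degrades it (`GA ≥ GD`, here through
equality because the reconstructed graph is rightly down-weighted).  A
command-line wrapper over the same functions is installed at
`inst/cli/interlink.R` (`simulate`, `run`, `compare-gr`, `auc-diff`).

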