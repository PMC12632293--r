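# gatepanel

Gene panel selection for targeted spatial transcriptomics via a gated
autoencoder.

Targeted spatial platforms (MERFISH, Xenium, seqFISH) image a few hundred
pre-selected genes at single-cell resolution; the panel is fixed before the
experiment and determines how much biology the experiment can see. Given a
single-cell RNA-seq reference, `gatepanel` selects the gene subset that best
reconstructs the *full* transcriptome, and provides a harness to score any
candidate panel against a spatial dataset.

## Method

A gating layer assigns a learnable non-negative weight $w_j$ to every gene
and modulates each cell's log-normalized expression vector element-wise,
$x_i' = w \odot x_i$. A bottleneck autoencoder (encoder $f_\theta$, mirrored
decoder $g_\phi$, LeakyReLU + dropout between affine stages) reconstructs
$\hat x_i = g_\phi(f_\theta(w \odot x_i))$, and training minimizes

$$
L(w,\theta,\phi) = \frac{1}{N}\sum_{i=1}^N \lVert x_i - \hat x_i\rVert_2^2
 + \lambda \sum_{j=1}^G w_j ,
$$

with the gates clamped to $[0,\infty)$ after every Adam step, so the second
term is a true L1 penalty that shrinks uninformative genes' gates toward
zero. Surviving gate weights rank genes by how much they contribute to
reconstructing everything else; the top-$K$ genes form the panel. $\lambda$
trades reconstruction accuracy against sparsity and can be chosen by
cross-validation (`tune_lambda()`), optionally under a panel-size budget.

Panels — from this method or any other — are evaluated against a spatial
dataset with `evaluate_panel()`: unselected genes are masked to zero, an
identical reconstruction network (same architecture, hyperparameters,
seeded initialization and cell split for every panel) is fitted, and the
held-out cells are scored with reconstruction MSE, gene-wise KL divergence,
gene-wise Pearson/Spearman correlation, Moran's I spatial autocorrelation of
the reconstruction, and the Leiden-clustering Adjusted Rand Index against
provided cell-type labels.

## Worked example

Simulated reference with known ground truth: 1000 cells, 100 genes of which
10 are informative (cell-type-driven) with one noisy copy each, 4 cell
types, plus matched spatial coordinates with a smooth gradient on the
informative genes.

```r
library(gatepanel)

cfg <- sim_config(n_cells = 1000, n_genes = 100, n_informative = 10,
                  n_cell_types = 4, redundancy = 1, seed = 2)
sim <- simulate_expression(cfg)
spatial <- simulate_spatial(cfg, sim$expr, sim$truth)

fit <- gate_ae(sim$expr, lambda = 0.01,
               config = gate_ae_config(encoder_dims = c(128, 64, 16),
                                       epochs = 100, seed = 1))
summary(fit)
#> Gated autoencoder: 1000 cells x 100 genes, lambda = 0.01
#> Non-zero gates: 100 / 100
#> Gate weight quantiles:
#>     0%    25%    50%    75%    90%   100%
#> 0.9035 0.9326 0.9410 0.9540 0.9666 0.9900
#> Top genes by gate weight:
#>  g0001  g0020  g0015  g0010  g0005  g0018  g0011  g0013  g0004  g0009
#> 0.9900 0.9891 0.9788 0.9785 0.9766 0.9765 0.9755 0.9738 0.9699 0.9687
#> Final train loss 82.6243 | validation reconstruction 83.2408 | 7.6s

panel <- select_panel(fit, mode = "topk", k = 10)
```

The ten top-gated genes are exactly the ten informative/copy genes of the
ground truth (`g0001`–`g0020` house the informative genes and their
copies). Scoring the panel against the spatial dataset:

```r
report <- evaluate_panel(panel, spatial,
                         config = gate_ae_config(encoder_dims = c(128, 64, 16),
                                                 epochs = 50, seed = 1),
                         seed = 3)
report
#> Panel evaluation [gate_ae], 10 genes:
#>   mse            0.9053
#>   kl_divergence  0.0679
#>   pearson_mean   0.1858
#>   spearman_mean  0.1643
#>   morans_i_mean  0.2241
#>   ari            0.4030
```

Reading the numbers: held-out reconstruction MSE of 0.91 against a
per-gene variance near 1 means the panel recovers the structured share of
the transcriptome — the 80 pure-noise genes in this simulation are
irreducibly unpredictable, which also caps the gene-wise correlation means
(averaged over *all* genes, noise included). The positive mean Moran's I
shows the reconstruction preserves the spatial gradient carried by the
informative genes, and the ARI confirms the 10-gene panel alone separates
the four simulated cell types.

## Package layout

* `R/` — containers and IO (`expr_matrix`, `spatial_dataset`, `gene_panel`),
  preprocessing (`filter_cells_genes`, `normalize_log_scale`), the model
  (`gate_ae` and methods, `tune_lambda`), panel utilities (`select_panel`,
  `panel_overlap`), evaluation (`masked_reconstruct`, `evaluate_panel`,
  `morans_i`, `clustering_ari`) and the synthetic generator
  (`simulate_expression`, `simulate_spatial`, `simulate_counts`,
  `fixture_small`).
* `vignettes/gene-panel-selection.Rmd` — the methods vignette: model,
  assumptions, parameter choices, generator design, limitations.
* `inst/cli/panel-tool.R` — a thin command-line wrapper
  (`select`, `evaluate`, `overlap`, `simulate`).
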