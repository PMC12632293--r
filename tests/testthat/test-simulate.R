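test_that("the generator is a pure function of its configuration", {
  cfg <- tiny_sim_cfg(seed = 12)
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(unclass(s1$expr), unclass(s2$expr))
  expect_identical(s1$truth$cell_types, s2$truth$cell_types)
  sp1 <- simulate_spatial(cfg, s1$expr, s1$truth)
  sp2 <- simulate_spatial(cfg, s2$expr, s2$truth)
  expect_identical(sp1$coords, sp2$coords)
  expect_identical(unclass(sp1$expr), unclass(sp2$expr))
  c1 <- simulate_counts(cfg)
  c2 <- simulate_counts(cfg)
  expect_identical(unclass(c1$counts), unclass(c2$counts))
})

test_that("ground truth is consistent with the emitted matrices", {
  cfg <- sim_config(n_cells = 500, n_genes = 50, n_informative = 6,
                    n_cell_types = 4, redundancy = 2, seed = 13)
  sim <- simulate_expression(cfg)
  tr <- sim$truth
  expect_length(tr$informative_genes, 6)
  expect_length(tr$copy_genes, 12)
  expect_length(tr$noise_genes, 32)
  expect_setequal(c(tr$informative_genes, tr$copy_genes, tr$noise_genes),
                  colnames(sim$expr))
  # copies correlate strongly with their parents
  for (cg in tr$copy_genes[1:4]) {
    parent <- tr$parent[cg]
    expect_gt(cor(sim$expr[, cg], sim$expr[, parent]), 0.8)
  }
  # informative genes carry more between-type variance than noise genes
  f_ratio <- function(gene) {
    fit <- stats::aov(sim$expr[, gene] ~ factor(tr$cell_types))
    summary(fit)[[1]]$`F value`[1]
  }
  f_inf <- vapply(tr$informative_genes, f_ratio, numeric(1))
  f_noise <- vapply(tr$noise_genes[1:6], f_ratio, numeric(1))
  expect_gt(min(f_inf), max(f_noise))

  expect_error(sim_config(n_genes = 10, n_informative = 5, redundancy = 2),
               class = "gp_error_infeasible_config")
})

test_that("effect_size = 0 leaves no type signal", {
  cfg <- sim_config(n_cells = 400, n_genes = 30, n_informative = 5,
                    redundancy = 1, n_cell_types = 3, effect_size = 0, seed = 14)
  sim <- simulate_expression(cfg)
  pvals <- vapply(sim$truth$informative_genes, function(gene) {
    summary(stats::aov(sim$expr[, gene] ~ factor(sim$truth$cell_types)))[[1]]$`Pr(>F)`[1]
  }, numeric(1))
  # p-values behave like a null sample: none extreme at Bonferroni level
  expect_gt(min(pvals), 0.001)
})

test_that("spatial coordinates live in the unit square; blocks segregate types", {
  cfg <- sim_config(n_cells = 300, n_genes = 20, n_informative = 3,
                    redundancy = 1, n_cell_types = 4,
                    spatial_pattern = "blocks", seed = 15)
  sim <- simulate_expression(cfg)
  sp <- simulate_spatial(cfg, sim$expr, sim$truth)
  expect_true(all(sp$coords >= 0 & sp$coords <= 1))
  # within a block, one type only
  quadrant <- paste(sp$coords[, 1] > 0.5, sp$coords[, 2] > 0.5)
  expect_true(all(vapply(split(sp$labels, quadrant),
                         function(l) length(unique(l)) == 1L, logical(1))))
})

test_that("simulated counts respect depth structure and feed the filters", {
  cfg <- tiny_sim_cfg(seed = 16)
  sim <- simulate_counts(cfg, depth = 1500, low_depth_fraction = 0.15,
                         rare_gene_fraction = 0.2)
  counts <- sim$counts
  expect_equal(expr_scale(counts), "counts")
  low <- rownames(counts) %in% sim$truth$low_depth_cells
  detected <- rowSums(counts > 0)
  expect_lt(mean(detected[low]), mean(detected[!low]))
  # mean total count tracks the drawn library sizes
  expect_lt(abs(mean(rowSums(counts)) - mean(sim$truth$library_sizes)) /
              mean(sim$truth$library_sizes), 0.05)
  # rare genes are detected in far fewer cells
  rare <- colnames(counts) %in% sim$truth$rare_genes
  expect_lt(mean(colSums(counts[, rare, drop = FALSE] > 0)),
            0.5 * mean(colSums(counts[, !rare, drop = FALSE] > 0)))
  # a detected-genes filter between the two depth regimes removes low-depth
  # cells preferentially
  thr <- floor((mean(detected[low]) + mean(detected[!low])) / 2)
  kept <- filter_cells_genes(counts, preprocess_config(min_genes_per_cell = thr,
                                                       min_cells_per_gene = 1))
  expect_lt(mean(rownames(counts)[low] %in% rownames(kept)),
            mean(rownames(counts)[!low] %in% rownames(kept)))
})
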