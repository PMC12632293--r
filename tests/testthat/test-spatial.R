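test_that("kNN graph construction: tie-breaks, boundaries, errors", {
  # 3 collinear equidistant points: the middle point ties and takes the
  # lower-index endpoint
  coords <- cbind(c(0, 1, 2), 0)
  g1 <- build_spatial_graph(coords, k = 1)
  expect_equal(g1$idx[2, ], 1L)
  # k = N - 1 is the complete graph minus self
  g2 <- build_spatial_graph(coords, k = 2)
  expect_equal(sort(g2$idx[1, ]), c(2L, 3L))
  expect_true(all(g2$idx != row(g2$idx)))
  expect_error(build_spatial_graph(coords, k = 3), class = "gp_error_bad_k")
})

test_that("morans_i matches the double-loop formula on random graphs", {
  set.seed(31)
  for (rep in 1:5) {
    coords <- matrix(runif(100), 50, 2)
    graph <- build_spatial_graph(coords, k = sample(2:8, 1))
    vals <- rnorm(50)
    expect_equal(morans_i(vals, graph), moran_loop(vals, graph),
                 tolerance = 1e-10)
  }
  expect_error(morans_i(rep(1, 50), graph), class = "gp_error_zero_variance")
})

test_that("morans_i agrees with an independent implementation (ape)", {
  skip_if_not_installed("ape")
  set.seed(32)
  coords <- matrix(runif(80), 40, 2)
  graph <- build_spatial_graph(coords, k = 5)
  w <- matrix(0, 40, 40)
  for (i in 1:40) w[i, graph$idx[i, ]] <- 1 / graph$k
  vals <- rnorm(40)
  expect_equal(morans_i(vals, graph),
               ape::Moran.I(vals, w, scaled = FALSE)$observed,
               tolerance = 1e-10)
})

test_that("closed-form extremes: checkerboard -1, two-block segregation +1", {
  # 4x4 rook grid, k = 2..4 varies; build rook adjacency by hand with
  # row-standardized weights, evaluated through the same formula
  grid <- expand.grid(x = 1:4, y = 1:4)
  vals <- (-1)^(grid$x + grid$y)        # checkerboard
  n <- 16
  z <- vals - mean(vals)
  num <- 0; wsum <- 0
  for (i in 1:n) {
    nb <- which(abs(grid$x - grid$x[i]) + abs(grid$y - grid$y[i]) == 1)
    num <- num + sum(z[i] * z[nb]) / length(nb)
    wsum <- wsum + 1
  }
  I_rook <- (n / wsum) * num / sum(z^2)
  expect_equal(I_rook, -1, tolerance = 1e-12)

  # two spatial blocks, complete-within adjacency, constant value per block
  coords2 <- rbind(cbind(runif(10, 0, 0.1), runif(10, 0, 0.1)),
                   cbind(runif(10, 10, 10.1), runif(10, 10, 10.1)))
  gb <- build_spatial_graph(coords2, k = 9)
  expect_equal(morans_i(c(rnorm(10, 5, 1e-9), rnorm(10, -5, 1e-9)), gb), 1,
               tolerance = 1e-6)
})

test_that("permutation mean of Moran's I is -1/(N-1)", {
  set.seed(33)
  n <- 50
  graph <- build_spatial_graph(matrix(runif(2 * n), n, 2), k = 4)
  vals <- rnorm(n)
  perms <- replicate(2000, morans_i(sample(vals), graph))
  se <- sd(perms) / sqrt(length(perms))
  expect_lt(abs(mean(perms) - (-1 / (n - 1))), 3 * se)
})

test_that("the spatial fixture separates gradient genes from noise genes", {
  fx <- fixture_small()
  graph <- build_spatial_graph(fx$spatial$coords, k = 6)
  grad_gene <- fx$truth$informative_genes[1]
  noise_gene <- fx$truth$noise_genes[1]
  expect_gt(morans_i(fx$spatial$expr[, grad_gene], graph), 0.5)
  expect_lt(abs(morans_i(fx$spatial$expr[, noise_gene], graph)), 0.1)

  inf_mean <- morans_i_mean(fx$spatial, graph, genes = fx$truth$informative_genes)
  noise_mean <- morans_i_mean(fx$spatial, graph, genes = fx$truth$noise_genes)
  expect_gt(as.numeric(inf_mean), as.numeric(noise_mean))

  # pattern = "none": expression is spatially random
  cfg0 <- sim_config(n_cells = 400, n_genes = 30, n_informative = 5,
                     redundancy = 1, spatial_pattern = "none", seed = 2)
  sim0 <- simulate_expression(cfg0)
  sp0 <- simulate_spatial(cfg0, sim0$expr, sim0$truth)
  g0 <- build_spatial_graph(sp0$coords, k = 6)
  moran_all <- vapply(seq_len(ncol(sp0$expr)),
                      function(j) morans_i(sp0$expr[, j], g0), numeric(1))
  expect_lt(abs(mean(moran_all) - (-1 / 399)), 0.02)
})
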