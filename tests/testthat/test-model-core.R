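test_that("gate_apply is exact element-wise modulation", {
  x <- matrix(c(3, 5, 7), 1, 3)
  expect_equal(gate_apply(c(2, 0, 1), x), matrix(c(6, 0, 7), 1, 3))
  x2 <- toy_expr(6, 4)
  expect_equal(gate_apply(rep(1, 4), x2), unclass(x2) + 0, ignore_attr = TRUE)
  expect_equal(gate_apply(rep(0, 4), x2), matrix(0, 6, 4), ignore_attr = TRUE)
  expect_error(gate_apply(c(1, 2), x2), class = "gp_error_shape")
  expect_error(gate_apply(c(-1, 1, 1, 1), x2), class = "gp_error_bad_gate")
})

test_that("forward pass matches a hand-computed two-stage composition", {
  # encoder: 2 -> 2 (LeakyReLU slope 0.3) -> 2 latent (affine only)
  # decoder: 2 -> 2 (LeakyReLU) -> 2 output (affine only)
  slope <- 0.3
  W1 <- matrix(c(1, -1, 2, 0), 2, 2); b1 <- c(0.5, -0.5)
  W2 <- matrix(c(0.5, 1, -1, 0.25), 2, 2); b2 <- c(0, 1)
  W3 <- matrix(c(2, 0, 1, 1), 2, 2); b3 <- c(-1, 0)
  W4 <- matrix(c(1, 0.5, 0, -2), 2, 2); b4 <- c(0.1, 0.2)
  stages <- list(list(W = W1, b = b1, act = TRUE),
                 list(W = W2, b = b2, act = FALSE),
                 list(W = W3, b = b3, act = TRUE),
                 list(W = W4, b = b4, act = FALSE))
  x <- matrix(c(1.5, -0.5), 1, 2)

  leaky <- function(v) ifelse(v > 0, v, slope * v)
  z1 <- as.numeric(x %*% W1 + b1); a1 <- leaky(z1)
  h <- as.numeric(a1 %*% W2 + b2)
  z3 <- as.numeric(h %*% W3 + b3); a3 <- leaky(z3)
  out_hand <- as.numeric(a3 %*% W4 + b4)

  fw <- gatepanel:::nn_forward(stages, x, slope, 0, training = FALSE)
  expect_equal(as.numeric(fw$out), out_hand, tolerance = 1e-12)

  # negative pre-activation at a hidden stage is scaled by the slope
  neg <- matrix(c(-2, 0), 1, 2)
  one <- list(list(W = diag(2), b = c(0, 0), act = TRUE),
              list(W = diag(2), b = c(0, 0), act = FALSE))
  expect_equal(as.numeric(gatepanel:::nn_forward(one, neg, slope, 0)$out),
               c(-2 * slope, 0))

  # identity configuration with non-negative input passes through unchanged
  pos <- matrix(c(2, 3), 1, 2)
  expect_equal(as.numeric(gatepanel:::nn_forward(one, pos, slope, 0)$out), c(2, 3))
})

test_that("encode/decode on a fitted model compose into predict", {
  sim <- simulate_expression(tiny_sim_cfg(seed = 2))
  fit <- gate_ae(sim$expr, lambda = 0.01, config = tiny_cfg(epochs = 10))
  h <- encode(fit)
  expect_equal(dim(h), c(nrow(sim$expr), 8L))
  expect_equal(decode(fit, h), predict(fit), ignore_attr = TRUE)
  expect_equal(dim(predict(fit)), dim(sim$expr))
})

test_that("composite_loss matches a brute-force double loop and the worked example", {
  expect_identical(composite_loss(matrix(c(1, 2), 1), matrix(0, 1, 2),
                                  c(0.5, 0.5), 1), 6)
  brute <- function(x, xhat, w, lambda) {
    acc <- 0
    for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x)))
      acc <- acc + (x[i, j] - xhat[i, j])^2
    acc / nrow(x) + lambda * sum(w)
  }
  set.seed(11)
  for (rep in 1:20) {
    x <- matrix(rnorm(35), 5, 7); xhat <- matrix(rnorm(35), 5, 7)
    w <- runif(7); lambda <- runif(1)
    expect_equal(composite_loss(x, xhat, w, lambda), brute(x, xhat, w, lambda),
                 tolerance = 1e-10)
  }
  expect_identical(composite_loss(x, x, rep(0, 7), 0), 0)
  # lambda = 0 reduces to the pure per-cell reconstruction term
  expect_equal(composite_loss(x, xhat, w, 0), sum((x - xhat)^2) / 5)
})

test_that("training is seeded-deterministic, keeps gates non-negative, reduces loss", {
  sim <- simulate_expression(tiny_sim_cfg(seed = 3))
  cfg <- tiny_cfg(seed = 7, epochs = 30)
  fit1 <- gate_ae(sim$expr, lambda = 0.02, config = cfg)
  fit2 <- gate_ae(sim$expr, lambda = 0.02, config = cfg)
  expect_identical(fit1$gate, fit2$gate)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$stages, fit2$stages)

  expect_true(all(fit1$gate >= 0))
  expect_true(all(is.finite(fit1$history$train_loss)))
  expect_true(all(is.finite(fit1$history$val_recon_loss)))
  expect_lt(tail(fit1$history$train_loss, 1), fit1$history$train_loss[1])
  expect_equal(nrow(fit1$history), cfg$epochs)
})

test_that("an overwhelming L1 penalty drives every gate to zero", {
  # Adam's per-step displacement is bounded by ~learning_rate, so the gates
  # need > 1/learning_rate optimizer steps to travel from 1 down to the clamp
  sim <- simulate_expression(tiny_sim_cfg(seed = 4))
  fit <- gate_ae(sim$expr, lambda = 1e6, config = tiny_cfg(epochs = 300))
  expect_true(all(coef(fit) < 1e-4))
})

test_that("gate weights separate structured from pure-noise genes", {
  sim <- simulate_expression(tiny_sim_cfg(seed = 1))
  fit <- gate_ae(sim$expr, lambda = 0.05, config = tiny_cfg(epochs = 60, seed = 1))
  structured <- c(sim$truth$informative_genes, sim$truth$copy_genes)
  noise <- sim$truth$noise_genes
  expect_gt(mean(coef(fit)[structured]), mean(coef(fit)[noise]))
})

test_that("stratified validation split keeps every label on both sides", {
  sim <- simulate_expression(tiny_sim_cfg(seed = 6))
  fit <- gate_ae(sim$expr, lambda = 0.01, config = tiny_cfg(epochs = 5),
                 labels = sim$truth$cell_types)
  expect_setequal(unique(sim$truth$cell_types[fit$val_idx]),
                  unique(sim$truth$cell_types))
  expect_setequal(c(fit$train_idx, fit$val_idx), seq_len(nrow(sim$expr)))
})
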