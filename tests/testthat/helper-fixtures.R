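# Shared test fixtures, built in code.

# Plain numeric matrix view of an expr_matrix (drops class and scale attr).
mat <- function(x) {
  x <- unclass(x)
  attr(x, "scale") <- NULL
  x
}

# Small random lognorm-scale matrix with ids.
toy_expr <- function(n = 10, g = 5, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(n * g), n, g,
              dimnames = list(sprintf("c%03d", seq_len(n)),
                              sprintf("g%03d", seq_len(g))))
  expr_matrix(m, "lognorm")
}

# Fast training configuration for unit tests on small simulations.
tiny_cfg <- function(seed = 1L, epochs = 40L, ...) {
  gate_ae_config(encoder_dims = c(32L, 8L), epochs = epochs,
                 batch_size = 64L, seed = seed, ...)
}

tiny_sim_cfg <- function(seed = 1L, ...) {
  sim_config(n_cells = 300L, n_genes = 40L, n_informative = 5L,
             n_cell_types = 3L, redundancy = 1L, seed = seed, ...)
}

# Independent double-loop Moran's I over an explicit weight matrix.
moran_loop <- function(values, graph) {
  n <- graph$n
  w <- matrix(0, n, n)
  if (!is.null(graph$idx)) {
    for (i in seq_len(n)) w[i, graph$idx[i, ]] <- 1 / graph$k
  } else {
    for (i in seq_len(n)) w[i, graph$nb[[i]]] <- 1 / length(graph$nb[[i]])
  }
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

# Independent contingency-table ARI.
ari_formula <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
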