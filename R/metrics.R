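# Reconstruction-fidelity metrics: MSE, gene-wise KL divergence, gene-wise
# Pearson/Spearman correlation. All operate on matched cells-by-genes
# matrices (observed vs reconstructed) on the same (log) scale.

#' Mean squared error across cells and genes
#'
#' @param x,xhat matched cells-by-genes matrices.
#' @return Mean over all `N * G` entries of the squared difference.
#' @export
mse_metric <- function(x, xhat) {
  x <- as.matrix(x); xhat <- as.matrix(xhat)
  if (!all(dim(x) == dim(xhat)))
    gp_stop("gp_error_shape", "x and xhat must have identical dimensions")
  mean((x - xhat)^2)
}

#' Gene-wise Kullback-Leibler divergence
#'
#' For every gene, the observed and reconstructed columns are turned into
#' probability distributions over cells and compared with
#' `KL(p_obs || q_rec) = sum_i p_i log(p_i / q_i)`; the result is averaged
#' over genes. Because (log-scale) expression can be negative, both columns
#' are first shifted jointly by their common minimum (when that minimum is
#' negative), then smoothed by `eps`
#' and normalized to sum to one.
#'
#' @param x,xhat matched cells-by-genes matrices (observed, reconstructed).
#' @param eps smoothing constant added after the joint min-shift.
#' @return Non-negative mean divergence over genes.
#' @export
kl_metric <- function(x, xhat, eps = 1e-8) {
  x <- as.matrix(x); xhat <- as.matrix(xhat)
  if (!all(dim(x) == dim(xhat)))
    gp_stop("gp_error_shape", "x and xhat must have identical dimensions")
  if (eps <= 0) gp_stop("gp_error_bad_config", "eps must be positive")
  if (any(!is.finite(x)) || any(!is.finite(xhat)))
    gp_stop("gp_error_non_finite", "inputs to kl_metric must be finite")
  shift <- pmin(apply(x, 2L, min), apply(xhat, 2L, min), 0)
  p <- sweep(x, 2L, shift, "-") + eps
  q <- sweep(xhat, 2L, shift, "-") + eps
  p <- sweep(p, 2L, colSums(p), "/")
  q <- sweep(q, 2L, colSums(q), "/")
  mean(colSums(p * log(p / q)))
}

#' Gene-wise Pearson and Spearman correlations
#'
#' Correlates each gene's observed and reconstructed values across cells and
#' averages over genes. Genes with zero variance in either vector have no
#' defined correlation; they are skipped and their count is attached as the
#' `n_skipped` attribute.
#'
#' @param x,xhat matched cells-by-genes matrices.
#' @return Named numeric vector `c(pearson_mean, spearman_mean)` with
#'   attribute `n_skipped`.
#' @export
correlation_metrics <- function(x, xhat) {
  x <- as.matrix(x); xhat <- as.matrix(xhat)
  if (!all(dim(x) == dim(xhat)))
    gp_stop("gp_error_shape", "x and xhat must have identical dimensions")
  sd0 <- function(m) apply(m, 2L, stats::sd) == 0
  skip <- sd0(x) | sd0(xhat)
  if (all(skip))
    gp_stop("gp_error_zero_variance", "every gene has zero variance in x or xhat")
  keep <- which(!skip)
  pear <- vapply(keep, function(j) stats::cor(x[, j], xhat[, j]), numeric(1))
  spear <- vapply(keep, function(j)
    stats::cor(x[, j], xhat[, j], method = "spearman"), numeric(1))
  out <- c(pearson_mean = mean(pear), spearman_mean = mean(spear))
  attr(out, "n_skipped") <- sum(skip)
  out
}
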