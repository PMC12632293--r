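#' Cross-validated selection of the L1 penalty strength
#'
#' k-fold cell-wise cross-validation over a grid of `lambda` values. For each
#' `lambda` and fold, a gated autoencoder is trained on the in-fold cells and
#' the held-out cells are scored with the reconstruction term only (the L1
#' penalty is a training device, not an accuracy measure). The per-`lambda`
#' summary records the mean held-out reconstruction loss and the mean number
#' of surviving gates (weights above `zero_tol`).
#'
#' The chosen `lambda` minimizes the mean held-out reconstruction loss among
#' values whose mean surviving-gate count does not exceed `budget`; the
#' default `budget = Inf` is a pure loss minimizer. Larger `lambda` buys
#' sparsity at the price of reconstruction accuracy; the budget expresses the
#' panel-size constraint of a targeted spatial experiment.
#'
#' @param x cells-by-genes log-normalized expression matrix.
#' @param grid non-empty numeric vector of candidate `lambda` values.
#' @param folds number of cross-validation folds (>= 2).
#' @param config a [gate_ae_config()]; its `seed` fixes the fold assignment
#'   and all training randomness, making the procedure deterministic.
#' @param budget maximum acceptable mean surviving-gate count.
#' @param labels optional per-cell labels for stratified folds.
#' @return An object of class `gate_ae_cv`: list with `lambda` (the chosen
#'   value) and `table` (one row per grid value: `lambda`, `mean_val_recon`,
#'   `mean_n_genes`).
#' @export
tune_lambda <- function(x, grid, folds = 5L, config = gate_ae_config(),
                        budget = Inf, labels = NULL) {
  if (length(grid) == 0L)
    gp_stop("gp_error_empty_grid", "lambda grid must be non-empty")
  if (any(grid < 0))
    gp_stop("gp_error_bad_gate", "lambda values must be non-negative")
  folds <- as.integer(folds)
  if (folds < 2L)
    gp_stop("gp_error_bad_config", "need at least 2 folds")
  xm <- unclass(as_expr_matrix(x)); attr(xm, "scale") <- NULL
  n <- nrow(xm)
  fold_id <- with_seed(config$seed, {
    if (is.null(labels)) sample(rep_len(seq_len(folds), n))
    else {
      id <- integer(n)
      for (idx in split(seq_len(n), as.factor(labels)))
        id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      id
    }
  })
  grid <- sort(unique(as.numeric(grid)))
  recon <- ngene <- matrix(NA_real_, length(grid), folds)
  for (f in seq_len(folds)) {
    in_fold <- which(fold_id != f)
    held <- which(fold_id == f)
    for (gi in seq_along(grid)) {
      cfg <- config
      cfg$seed <- config$seed + f   # same split/init for every lambda in a fold
      fit <- gate_ae(xm[in_fold, , drop = FALSE], lambda = grid[gi], config = cfg,
                     labels = if (!is.null(labels)) labels[in_fold])
      xh <- predict(fit, xm[held, , drop = FALSE])
      recon[gi, f] <- sum((xm[held, , drop = FALSE] - xh)^2) / length(held)
      ngene[gi, f] <- sum(fit$gate > config$zero_tol)
    }
  }
  tab <- data.frame(lambda = grid,
                    mean_val_recon = rowMeans(recon),
                    mean_n_genes = rowMeans(ngene))
  ok <- tab$mean_n_genes <= budget
  if (!any(ok)) {
    gp_warn("gp_warning_budget", "no lambda meets the gene budget %g; ignoring it", budget)
    ok <- rep(TRUE, nrow(tab))
  }
  cand <- tab[ok, , drop = FALSE]
  chosen <- cand$lambda[which.min(cand$mean_val_recon)]
  structure(list(lambda = chosen, table = tab, folds = folds, budget = budget),
            class = "gate_ae_cv")
}

#' @export
print.gate_ae_cv <- function(x, ...) {
  cat(sprintf("Cross-validated L1 strength (%d folds): lambda = %g\n",
              x$folds, x$lambda))
  print(transform(x$table, mean_val_recon = signif(mean_val_recon, 5),
                  mean_n_genes = round(mean_n_genes, 1)), row.names = FALSE)
  invisible(x)
}
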