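#' Preprocessing configuration
#'
#' Quality-control and normalization parameters for count-scale single-cell
#' references. Defaults follow common scRNA-seq practice for atlas-scale data:
#' cells with fewer than 200 detected genes and genes detected in fewer than
#' 100 cells are removed, libraries are rescaled to 10,000 counts, and
#' per-gene standardized values are clipped at +/- 10.
#'
#' @param min_genes_per_cell minimum number of detected (count > 0) genes a
#'   cell must have to be kept.
#' @param min_cells_per_gene minimum number of retained cells a gene must be
#'   detected in to be kept.
#' @param target_sum per-cell library size after normalization (counts).
#' @param max_abs_value clipping bound for standardized expression values.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(min_genes_per_cell = 200L,
                              min_cells_per_gene = 100L,
                              target_sum = 1e4,
                              max_abs_value = 10) {
  cfg <- list(min_genes_per_cell = as.integer(min_genes_per_cell),
              min_cells_per_gene = as.integer(min_cells_per_gene),
              target_sum = as.numeric(target_sum),
              max_abs_value = as.numeric(max_abs_value))
  if (any(unlist(cfg) <= 0))
    gp_stop("gp_error_bad_config", "all preprocess_config fields must be strictly positive")
  structure(cfg, class = "preprocess_config")
}

#' Filter low-quality cells and rarely detected genes
#'
#' Applies the cell filter first (cells must detect at least
#' `min_genes_per_cell` genes), then the gene filter on the surviving cells
#' (genes must be detected in at least `min_cells_per_gene` of them). Exactly
#' one pass of each filter is performed; the two filters are not iterated to a
#' joint fixpoint. "Detected" means a strictly positive count.
#'
#' @param x an [expr_matrix] with `scale = "counts"`.
#' @param cfg a [preprocess_config()].
#' @return The filtered [expr_matrix], still on the counts scale.
#' @export
filter_cells_genes <- function(x, cfg = preprocess_config()) {
  x <- as_expr_matrix(x, expr_scale(x))
  if (expr_scale(x) != "counts")
    gp_stop("gp_error_bad_scale", "filtering expects raw counts (scale='counts')")
  keep_cells <- rowSums(x > 0) >= cfg$min_genes_per_cell
  if (!any(keep_cells))
    gp_stop("gp_error_all_filtered", "all %d cells removed by the %d-gene cell filter",
            nrow(x), cfg$min_genes_per_cell)
  out <- x[keep_cells, , drop = FALSE]
  keep_genes <- colSums(out > 0) >= cfg$min_cells_per_gene
  if (!any(keep_genes))
    gp_stop("gp_error_all_filtered", "all %d genes removed by the %d-cell gene filter",
            ncol(x), cfg$min_cells_per_gene)
  out[, keep_genes, drop = FALSE]
}

#' Normalize, log-transform and scale a count matrix
#'
#' The standard three-step transform applied to the single-cell reference
#' before model fitting:
#' 1. library-size normalization — each cell's counts are rescaled to sum to
#'    `target_sum`;
#' 2. log transform — `log(1 + x)`, natural log;
#' 3. per-gene standardization to zero mean and unit variance across cells
#'    (population variance, i.e. divide by N), with the result clipped to
#'    `[-max_abs_value, max_abs_value]`. Zero-variance genes map to all zeros.
#'
#' @param x a filtered [expr_matrix] with `scale = "counts"`.
#' @param cfg a [preprocess_config()].
#' @return An [expr_matrix] with `scale = "lognorm"`.
#' @export
normalize_log_scale <- function(x, cfg = preprocess_config()) {
  x <- as_expr_matrix(x, expr_scale(x))
  if (expr_scale(x) != "counts")
    gp_stop("gp_error_bad_scale", "normalization expects raw counts (scale='counts')")
  totals <- rowSums(x)
  if (any(totals == 0))
    gp_stop("gp_error_zero_count_cell", "%d cells have zero total count", sum(totals == 0))
  v <- unclass(x) * (cfg$target_sum / totals)
  v <- log1p(v)
  mu <- colMeans(v)
  sdev <- sqrt(colMeans(v^2) - mu^2)
  v <- sweep(v, 2L, mu, "-")
  nz <- sdev > 0
  v[, nz] <- sweep(v[, nz, drop = FALSE], 2L, sdev[nz], "/")
  v[, !nz] <- 0
  v[v > cfg$max_abs_value] <- cfg$max_abs_value
  v[v < -cfg$max_abs_value] <- -cfg$max_abs_value
  expr_matrix(v, "lognorm")
}
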