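# Spatial autocorrelation: k-nearest-neighbor graph and Moran's I.

#' Build a k-nearest-neighbor spatial graph
#'
#' Connects every cell to its `k` nearest neighbors by Euclidean distance on
#' the section coordinates, with distance ties broken by ascending cell
#' index. Weights are row-standardized (`1/k` per neighbor), so each row of
#' the implied weight matrix sums to one and the total weight equals `N`.
#'
#' @param coords N x 2 numeric matrix of planar coordinates.
#' @param k number of neighbors per cell (`1 <= k < N`).
#' @return An object of class `spatial_graph`: list with `idx` (N x k integer
#'   neighbor matrix), `k` and `n`. No cell is its own neighbor.
#' @export
build_spatial_graph <- function(coords, k = 6L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  k <- as.integer(k)
  if (k < 1L || k >= n)
    gp_stop("gp_error_bad_k", "k = %d must satisfy 1 <= k < N = %d", k, n)
  if (any(!is.finite(coords)))
    gp_stop("gp_error_non_finite", "coordinates must be finite")
  d <- as.matrix(stats::dist(coords))
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n), method = "radix")  # stable: ties by index
    idx[i, ] <- ord[ord != i][seq_len(k)]
  }
  structure(list(idx = idx, k = k, n = n), class = "spatial_graph")
}

#' Spatial graph from an explicit neighbor list
#'
#' Builds a row-standardized `spatial_graph` from arbitrary adjacency (for
#' example rook adjacency on a grid), for use with [morans_i()] when the
#' neighborhood is not k-nearest-neighbor. Each cell's neighbors receive
#' weight `1/degree`.
#'
#' @param neighbors list of integer vectors; `neighbors[[i]]` are the
#'   neighbors of cell `i` (no self-neighbors, degree >= 1).
#' @return An object of class `spatial_graph`.
#' @export
adjacency_graph <- function(neighbors) {
  n <- length(neighbors)
  neighbors <- lapply(neighbors, as.integer)
  deg <- lengths(neighbors)
  if (any(deg < 1L))
    gp_stop("gp_error_bad_config", "every cell needs at least one neighbor")
  for (i in seq_len(n))
    if (any(neighbors[[i]] == i) || any(neighbors[[i]] < 1L | neighbors[[i]] > n))
      gp_stop("gp_error_bad_config", "invalid neighbor list at cell %d", i)
  k <- if (length(unique(deg)) == 1L) deg[1] else NA_integer_
  structure(list(nb = neighbors, idx = NULL, k = k, n = n),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> %d cells, k = %d nearest neighbors, row-standardized\n",
              x$n, x$k))
  invisible(x)
}

#' Moran's I spatial autocorrelation
#'
#' \deqn{I = \frac{N}{\sum_{ij} w_{ij}}
#'        \frac{\sum_i \sum_j w_{ij} z_i z_j}{\sum_i z_i^2}, \quad
#'        z_i = x_i - \bar x.}
#' With the row-standardized weights of [build_spatial_graph()],
#' `sum(w) = N` and the leading factor is one. Values near +1 indicate a
#' smooth spatial field, values near `-1/(N-1)` spatial randomness.
#'
#' @param values numeric vector, one value per cell of the graph.
#' @param graph a [build_spatial_graph()] result.
#' @return Moran's I (a single number).
#' @export
morans_i <- function(values, graph) {
  stopifnot(inherits(graph, "spatial_graph"))
  values <- as.numeric(values)
  if (length(values) != graph$n)
    gp_stop("gp_error_shape", "values length (%d) must equal graph size (%d)",
            length(values), graph$n)
  if (any(!is.finite(values)))
    gp_stop("gp_error_non_finite", "values must be finite")
  z <- values - mean(values)
  ss <- sum(z^2)
  if (ss == 0)
    gp_stop("gp_error_zero_variance", "values have zero variance")
  lag <- if (!is.null(graph$idx)) {
    rowSums(matrix(z[graph$idx], graph$n, graph$k)) / graph$k
  } else {
    vapply(graph$nb, function(nb) mean(z[nb]), numeric(1))
  }
  # row-standardized weights: sum(w) = N, so the N/W prefactor is 1
  sum(z * lag) / ss
}

#' Mean Moran's I over a set of genes
#'
#' Applies [morans_i()] to each gene column of an expression matrix and
#' averages. Zero-variance genes are skipped; their count is attached as the
#' `n_skipped` attribute and reported via `message()`.
#'
#' @param x cells-by-genes matrix (or [spatial_dataset], whose coordinates
#'   then provide the graph).
#' @param graph a [build_spatial_graph()]; required when `x` is a matrix.
#' @param genes optional character vector restricting the computation to a
#'   gene subset (e.g. a panel's genes).
#' @param k neighbors used when the graph is built from a [spatial_dataset].
#' @return Mean Moran's I with attribute `n_skipped`.
#' @export
morans_i_mean <- function(x, graph = NULL, genes = NULL, k = 6L) {
  if (inherits(x, "spatial_dataset")) {
    if (is.null(graph)) graph <- build_spatial_graph(x$coords, k = k)
    x <- x$expr
  }
  if (is.null(graph))
    gp_stop("gp_error_bad_config", "a spatial_graph is required for matrix input")
  xm <- as.matrix(x)
  if (!is.null(genes)) {
    missing <- setdiff(genes, colnames(xm))
    if (length(missing))
      gp_stop("gp_error_missing_gene", "genes absent from the matrix: %s",
              paste(utils::head(missing, 5L), collapse = ", "))
    xm <- xm[, genes, drop = FALSE]
  }
  vals <- rep(NA_real_, ncol(xm))
  for (j in seq_len(ncol(xm))) {
    if (stats::var(xm[, j]) == 0) next
    vals[j] <- morans_i(xm[, j], graph)
  }
  skipped <- sum(is.na(vals))
  if (skipped > 0)
    message(sprintf("morans_i_mean: skipped %d zero-variance genes", skipped))
  out <- mean(vals, na.rm = TRUE)
  attr(out, "n_skipped") <- skipped
  out
}
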