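# Cell-type separability of a panel: PCA -> kNN graph -> Leiden -> ARI.

# Shared kNN index helper (rows of `m` are observations).
knn_index <- function(m, k) {
  n <- nrow(m)
  if (k >= n) gp_stop("gp_error_bad_k", "k = %d must be < N = %d", k, n)
  d <- as.matrix(stats::dist(m))
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n), method = "radix")
    idx[i, ] <- ord[ord != i][seq_len(k)]
  }
  idx
}

#' Leiden clustering concordance with reference labels
#'
#' Measures how well a panel's genes alone separate the annotated cell types:
#' expression is restricted to the panel genes, reduced by PCA, a
#' k-nearest-neighbor cell graph is built in component space, partitioned
#' with the Leiden algorithm, and the partition is compared to the provided
#' labels with the Adjusted Rand Index (chance-corrected; 1 = identical
#' partitions, about 0 = random).
#'
#' @param panel a [gene_panel] (or character vector of gene ids).
#' @param spatial a [spatial_dataset] with non-null `labels`.
#' @param resolution Leiden resolution parameter (modularity objective).
#' @param seed integer seed for the Leiden refinement randomness.
#' @param n_pcs number of principal components (capped at `G - 1` and
#'   `N - 1`).
#' @param k_neighbors neighbors in the cell graph.
#' @return The ARI (single number) with attributes `n_clusters` and
#'   `resolution`.
#' @export
clustering_ari <- function(panel, spatial, resolution = 1, seed = 0L,
                           n_pcs = 50L, k_neighbors = 15L) {
  stopifnot(inherits(spatial, "spatial_dataset"))
  if (is.null(spatial$labels))
    gp_stop("gp_error_missing_labels", "spatial dataset has no cell-type labels")
  genes <- if (inherits(panel, "gene_panel")) panel$genes else as.character(panel)
  missing <- setdiff(genes, colnames(spatial$expr))
  if (length(missing))
    gp_stop("gp_error_missing_gene", "panel genes absent from spatial data: %s",
            paste(utils::head(missing, 5L), collapse = ", "))
  xm <- as.matrix(spatial$expr[, genes, drop = FALSE])
  n_pcs <- min(as.integer(n_pcs), ncol(xm) - 1L, nrow(xm) - 1L)
  n_pcs <- max(n_pcs, 1L)
  pcs <- stats::prcomp(xm, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  idx <- knn_index(pcs, as.integer(k_neighbors))
  n <- nrow(pcs)
  edges <- unique(t(apply(cbind(rep(seq_len(n), ncol(idx)), as.vector(idx)),
                          1L, sort)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  part <- with_seed(as.integer(seed),
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution, n_iterations = 3L))
  cl <- igraph::membership(part)
  out <- mclust::adjustedRandIndex(cl, spatial$labels)
  attr(out, "n_clusters") <- length(unique(cl))
  attr(out, "resolution") <- resolution
  out
}
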