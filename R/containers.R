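#' Expression matrix container
#'
#' Wraps a cells-by-genes numeric matrix together with its measurement scale.
#' Rows are cells, columns are genes; `rownames`/`colnames` carry the
#' identifiers. `scale = "counts"` marks raw UMI/transcript counts,
#' `scale = "lognorm"` marks log-normalized (and possibly standardized)
#' expression values.
#'
#' @param values numeric matrix, cells in rows, genes in columns, with unique
#'   row and column names.
#' @param scale `"counts"` or `"lognorm"`.
#' @return An object of class `expr_matrix`: the matrix with a `scale`
#'   attribute.
#' @examples
#' m <- matrix(rpois(6, 4), 3, 2, dimnames = list(paste0("c", 1:3), c("g1", "g2")))
#' expr_matrix(m, "counts")
#' @export
expr_matrix <- function(values, scale = c("counts", "lognorm")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    gp_stop("gp_error_non_numeric", "`values` must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    gp_stop("gp_error_empty", "expression matrix must have at least one cell and one gene")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    gp_stop("gp_error_missing_ids", "cell ids (rownames) and gene ids (colnames) are required")
  if (anyDuplicated(rownames(values)))
    gp_stop("gp_error_duplicate_ids", "duplicate cell ids")
  if (anyDuplicated(colnames(values)))
    gp_stop("gp_error_duplicate_ids", "duplicate gene ids")
  if (any(!is.finite(values)))
    gp_stop("gp_error_non_finite", "expression values must be finite (no NA/NaN/Inf)")
  if (scale == "counts" && (any(values < 0) || any(values != round(values))))
    gp_stop("gp_error_bad_counts", "scale='counts' requires non-negative integral values")
  structure(values, scale = scale, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d cells x %d genes, scale=%s\n",
              nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x object to query.
#' @export
expr_scale <- function(x) attr(x, "scale") %||% "lognorm"

# Subset while keeping class/scale; drop never allowed.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  out <- NextMethod(drop = FALSE)
  structure(out, scale = attr(x, "scale"), class = class(x))
}

as_expr_matrix <- function(x, scale = "lognorm") {
  if (inherits(x, "expr_matrix")) return(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("cell%05d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("g%05d", seq_len(ncol(x)))
  expr_matrix(as.matrix(x), scale)
}

#' Spatial expression dataset
#'
#' Couples an expression matrix with per-cell planar coordinates and optional
#' cell-type labels, the inputs needed to score a gene panel against a
#' targeted spatial transcriptomics experiment.
#'
#' @param expr an [expr_matrix] (cells x genes).
#' @param coords numeric matrix or data frame with one row per cell and two
#'   columns (x, y section coordinates, arbitrary planar units).
#' @param labels optional character/factor vector of per-cell cell-type labels.
#' @return An object of class `spatial_dataset` with elements `expr`, `coords`
#'   (N x 2 matrix) and `labels` (or `NULL`).
#' @export
spatial_dataset <- function(expr, coords, labels = NULL) {
  expr <- as_expr_matrix(expr)
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 2L)
    gp_stop("gp_error_bad_coords", "`coords` must be numeric with two columns")
  if (nrow(coords) != nrow(expr))
    gp_stop("gp_error_shape", "coords rows (%d) must match number of cells (%d)",
            nrow(coords), nrow(expr))
  if (any(!is.finite(coords)))
    gp_stop("gp_error_non_finite", "coordinates must be finite")
  if (!is.null(labels)) {
    if (length(labels) != nrow(expr))
      gp_stop("gp_error_shape", "labels length must match number of cells")
    labels <- as.character(labels)
  }
  colnames(coords) <- c("x", "y")
  rownames(coords) <- rownames(expr)
  structure(list(expr = expr, coords = coords, labels = labels),
            class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("<spatial_dataset> %d cells x %d genes, labels: %s\n",
              nrow(x$expr), ncol(x$expr),
              if (is.null(x$labels)) "none" else
                sprintf("%d types", length(unique(x$labels)))))
  invisible(x)
}

#' Gene panel
#'
#' An ordered gene subset with non-negative importance scores, the unit of
#' exchange between panel selection and panel evaluation. Genes are stored in
#' non-increasing score order; ties are broken by ascending gene id so that a
#' panel is a deterministic function of its inputs.
#'
#' @param genes character vector of unique gene ids.
#' @param scores non-negative numeric importance scores, one per gene. When
#'   omitted, descending rank placeholders (`n`, `n-1`, ..., `1`) are used.
#' @param source free-text provenance tag (e.g. the selection method's name).
#' @return An object of class `gene_panel`: a list with `genes`, `scores`,
#'   `source`.
#' @examples
#' gene_panel(c("Coro1a", "Mafb"), c(0.9, 0.4), source = "curated")
#' @export
gene_panel <- function(genes, scores = NULL, source = "") {
  genes <- as.character(genes)
  if (length(genes) == 0L)
    gp_stop("gp_error_empty_panel", "a gene panel must contain at least one gene")
  if (anyDuplicated(genes))
    gp_stop("gp_error_duplicate_ids", "duplicate genes in panel: %s",
            paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (is.null(scores)) scores <- rev(seq_along(genes))
  scores <- as.numeric(scores)
  if (length(scores) != length(genes))
    gp_stop("gp_error_shape", "scores must match genes in length")
  if (any(!is.finite(scores)) || any(scores < 0))
    gp_stop("gp_error_bad_scores", "scores must be finite and non-negative")
  ord <- order(-scores, genes, method = "radix")
  structure(list(genes = genes[ord], scores = scores[ord], source = source),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, n = 6L, ...) {
  cat(sprintf("<gene_panel> %d genes%s\n", length(x$genes),
              if (nzchar(x$source)) paste0(" [", x$source, "]") else ""))
  shown <- utils::head(seq_along(x$genes), n)
  cat(paste0("  ", format(x$genes[shown]), "  ",
             format(signif(x$scores[shown], 4)), collapse = "\n"), "\n")
  if (length(x$genes) > n) cat(sprintf("  ... and %d more\n", length(x$genes) - n))
  invisible(x)
}

#' @export
length.gene_panel <- function(x) length(x$genes)
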