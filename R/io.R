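# Reading and writing expression matrices, panels and reports.
# Delimited text only: cells as rows, genes as columns, comma default with
# tab accepted, matching the cells-x-genes convention used throughout.

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row whose first field names the cell-id column and whose
#' remaining fields are gene ids, followed by one row per cell. Comma and tab
#' separators are auto-detected.
#'
#' @param path path to a CSV/TSV file.
#' @param scale measurement scale of the stored values: `"counts"` for raw
#'   counts or `"lognorm"` for log-normalized expression.
#' @return An [expr_matrix].
#' @seealso [write_expression()]
#' @export
read_expression <- function(path, scale = c("counts", "lognorm")) {
  scale <- match.arg(scale)
  if (!file.exists(path))
    gp_stop("gp_error_missing_file", "file not found: %s", path)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    gp_stop("gp_error_empty_file", "no expression values found in %s", path)
  cell_ids <- trimws(df[[1L]])
  gene_ids <- trimws(colnames(df)[-1L])
  if (anyDuplicated(gene_ids))
    gp_stop("gp_error_duplicate_ids", "duplicate gene ids in %s: %s", path,
            paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(cell_ids))
    gp_stop("gp_error_duplicate_ids", "duplicate cell ids in %s", path)
  body <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(body), nrow = nrow(body)))
  if (any(is.na(storage) & !is.na(body) & toupper(trimws(body)) != "NAN"))
    gp_stop("gp_error_non_numeric", "non-numeric entries in %s", path)
  if (any(!is.finite(storage)))
    gp_stop("gp_error_non_finite", "NaN/Inf/missing values in %s", path)
  dimnames(storage) <- list(cell_ids, gene_ids)
  expr_matrix(storage, scale)
}

#' Write an expression matrix to delimited text
#'
#' Values are written with 17 significant digits so that
#' `read_expression(write_expression(x))` round-trips doubles exactly.
#'
#' @param x an [expr_matrix].
#' @param path output file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, sep = ",") {
  x <- as_expr_matrix(x)
  fmt <- if (expr_scale(x) == "counts") "%d" else "%.17g"
  body <- if (expr_scale(x) == "counts") {
    matrix(sprintf(fmt, as.integer(x)), nrow = nrow(x))
  } else {
    matrix(sprintf(fmt, as.numeric(x)), nrow = nrow(x))
  }
  lines <- c(
    paste(c("cell", colnames(x)), collapse = sep),
    vapply(seq_len(nrow(x)), function(i)
      paste(c(rownames(x)[i], body[i, ]), collapse = sep), character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a spatial dataset from delimited text
#'
#' @param expr_path expression matrix file (see [read_expression()]).
#' @param coords_path file with columns `cell,x,y`.
#' @param labels_path optional file with columns `cell,label`.
#' @param scale measurement scale of the expression values.
#' @return A [spatial_dataset].
#' @export
read_spatial <- function(expr_path, coords_path, labels_path = NULL,
                         scale = "lognorm") {
  expr <- read_expression(expr_path, scale = scale)
  if (!file.exists(coords_path))
    gp_stop("gp_error_missing_file", "file not found: %s", coords_path)
  co <- utils::read.table(coords_path, header = TRUE, sep = detect_sep(coords_path),
                          stringsAsFactors = FALSE)
  idx <- match(rownames(expr), as.character(co[[1L]]))
  if (anyNA(idx))
    gp_stop("gp_error_missing_ids", "coordinates missing for %d cells", sum(is.na(idx)))
  coords <- as.matrix(co[idx, 2:3])
  labels <- NULL
  if (!is.null(labels_path)) {
    lb <- utils::read.table(labels_path, header = TRUE, sep = detect_sep(labels_path),
                            stringsAsFactors = FALSE)
    lidx <- match(rownames(expr), as.character(lb[[1L]]))
    if (anyNA(lidx))
      gp_stop("gp_error_missing_ids", "labels missing for %d cells", sum(is.na(lidx)))
    labels <- as.character(lb[lidx, 2L])
  }
  spatial_dataset(expr, coords, labels)
}

#' Write a spatial dataset to delimited text
#'
#' @param x a [spatial_dataset].
#' @param expr_path,coords_path,labels_path output paths; labels are written
#'   only when present and `labels_path` is given.
#' @return `expr_path`, invisibly.
#' @export
write_spatial <- function(x, expr_path, coords_path, labels_path = NULL) {
  write_expression(x$expr, expr_path)
  co <- data.frame(cell = rownames(x$expr),
                   x = sprintf("%.17g", x$coords[, 1]),
                   y = sprintf("%.17g", x$coords[, 2]))
  utils::write.table(co, coords_path, sep = ",", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path) && !is.null(x$labels)) {
    utils::write.table(data.frame(cell = rownames(x$expr), label = x$labels),
                       labels_path, sep = ",", quote = FALSE, row.names = FALSE)
  }
  invisible(expr_path)
}

#' Restrict two expression matrices to their common genes
#'
#' Intersects the gene sets of a single-cell reference and a spatial dataset
#' and returns both matrices restricted to the shared genes in lexicographic
#' gene-id order, so that columns align across modalities. Matching is exact
#' string equality after whitespace stripping; the number of genes dropped on
#' each side is reported via `message()`.
#'
#' @param reference,spatial two [expr_matrix] objects.
#' @return A list with elements `reference` and `spatial`, both restricted to
#'   the common genes in identical column order.
#' @export
harmonize_genes <- function(reference, spatial) {
  reference <- as_expr_matrix(reference, expr_scale(reference))
  spatial <- as_expr_matrix(spatial, expr_scale(spatial))
  rg <- trimws(colnames(reference)); sg <- trimws(colnames(spatial))
  common <- sort(intersect(rg, sg), method = "radix")
  if (length(common) == 0L)
    gp_stop("gp_error_empty_intersection", "reference and spatial gene sets are disjoint")
  dropped_ref <- ncol(reference) - length(common)
  dropped_sp <- ncol(spatial) - length(common)
  if (dropped_ref + dropped_sp > 0)
    message(sprintf("harmonize_genes: %d common genes (dropped %d reference, %d spatial)",
                    length(common), dropped_ref, dropped_sp))
  list(reference = reference[, match(common, rg), drop = FALSE],
       spatial = spatial[, match(common, sg), drop = FALSE])
}

#' Read a gene panel from a text file
#'
#' One gene id per line, with an optional tab-separated score column. When
#' scores are absent, descending rank placeholders are assigned so the file
#' order is preserved.
#'
#' @param path panel file path.
#' @param source provenance tag recorded on the panel (defaults to the file
#'   name).
#' @return A [gene_panel].
#' @export
read_panel <- function(path, source = basename(path)) {
  if (!file.exists(path))
    gp_stop("gp_error_missing_file", "file not found: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    gp_stop("gp_error_empty_file", "panel file is empty: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  genes <- trimws(vapply(parts, `[[`, character(1), 1L))
  has_score <- lengths(parts) > 1L
  scores <- NULL
  if (any(has_score)) {
    if (!all(has_score))
      gp_stop("gp_error_bad_scores", "panel file mixes scored and unscored lines: %s", path)
    scores <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
    if (any(is.na(scores)))
      gp_stop("gp_error_non_numeric", "non-numeric score in panel file: %s", path)
  }
  gene_panel(genes, scores, source = source)
}

#' Write a gene panel to a text file
#'
#' @param panel a [gene_panel].
#' @param path output path; written as `gene\tscore` lines.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "gene_panel"))
  writeLines(sprintf("%s\t%.17g", panel$genes, panel$scores), path)
  invisible(path)
}
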