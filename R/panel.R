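#' Select a gene panel from fitted gate weights
#'
#' Turns a gate vector into an ordered [gene_panel]. `mode = "nonzero"` keeps
#' every gene whose gate exceeds `zero_tol` (the data-driven panel size);
#' `mode = "topk"` keeps the `k` largest-weight genes for platforms that
#' require a fixed panel size. Genes are ordered by descending weight with
#' ties broken by ascending gene id, so the panel is a deterministic function
#' of the fit. Zero-gate genes are never back-filled: if fewer than `k` gates
#' survive `zero_tol` in `topk` mode, a warning is issued and only the
#' surviving genes are returned.
#'
#' @param w a fitted [gate_ae] object or a non-negative numeric gate vector.
#' @param gene_ids gene identifiers matching `w`; taken from `names(w)` or
#'   the fit when omitted.
#' @param mode `"nonzero"` or `"topk"`.
#' @param k panel size, required for `mode = "topk"` (1 <= k <= G).
#' @param zero_tol absolute threshold below which a gate counts as zero.
#' @param source provenance tag stored on the panel.
#' @return A [gene_panel] with the gate weights as importance scores.
#' @export
select_panel <- function(w, gene_ids = NULL, mode = c("nonzero", "topk"),
                         k = NULL, zero_tol = 1e-4, source = "gate_ae") {
  mode <- match.arg(mode)
  if (inherits(w, "gate_ae")) {
    if (is.null(zero_tol)) zero_tol <- w$config$zero_tol
    w <- coef(w)
  }
  w <- stats::setNames(as.numeric(w), gene_ids %||% names(w))
  if (is.null(names(w)))
    gp_stop("gp_error_missing_ids", "gene_ids are required when w is unnamed")
  if (any(!is.finite(w)) || any(w < 0))
    gp_stop("gp_error_bad_gate", "gate weights must be finite and non-negative")
  ord <- order(-w, names(w), method = "radix")
  w <- w[ord]
  alive <- w > zero_tol
  if (mode == "nonzero") {
    if (!any(alive))
      gp_stop("gp_error_empty_panel", "no gate exceeds zero_tol = %g", zero_tol)
    return(gene_panel(names(w)[alive], unname(w[alive]), source = source))
  }
  if (is.null(k))
    gp_stop("gp_error_bad_config", "mode='topk' requires k")
  k <- as.integer(k)
  if (k < 1L || k > length(w))
    gp_stop("gp_error_bad_k", "k = %d outside 1..%d", k, length(w))
  if (sum(alive) < k) {
    gp_warn("gp_warning_short_panel",
            "only %d gates exceed zero_tol = %g (requested k = %d); not back-filling zero-gate genes",
            sum(alive), zero_tol, k)
    k <- sum(alive)
    if (k == 0L)
      gp_stop("gp_error_empty_panel", "no gate exceeds zero_tol = %g", zero_tol)
  }
  gene_panel(names(w)[seq_len(k)], unname(w[seq_len(k)]), source = source)
}

#' Pairwise overlap between gene panels
#'
#' Computes the symmetric matrix of pairwise intersection sizes between two
#' or more panels (diagonal = panel sizes) together with the intersection
#' gene lists, the numbers behind a panel-overlap (UpSet-style) comparison of
#' selection methods.
#'
#' @param panels list of [gene_panel] objects.
#' @param names optional names for the panels; defaults to their `source`
#'   tags.
#' @return An object of class `panel_overlap`: list with `counts` (symmetric
#'   integer matrix) and `intersections` (named list of gene vectors, one per
#'   unordered pair).
#' @export
panel_overlap <- function(panels, names = NULL) {
  if (!is.list(panels) || length(panels) < 2L)
    gp_stop("gp_error_bad_config", "need at least 2 panels")
  stopifnot(all(vapply(panels, inherits, logical(1), "gene_panel")))
  nm <- names %||% vapply(panels, function(p)
    if (nzchar(p$source)) p$source else "panel", character(1))
  nm <- make.unique(nm)
  m <- length(panels)
  counts <- matrix(0L, m, m, dimnames = list(nm, nm))
  inter <- list()
  for (i in seq_len(m)) {
    counts[i, i] <- length(panels[[i]]$genes)
    for (j in seq_len(m)) {
      if (j <= i) next
      shared <- intersect(panels[[i]]$genes, panels[[j]]$genes)
      counts[i, j] <- counts[j, i] <- length(shared)
      inter[[paste(nm[i], nm[j], sep = " & ")]] <- sort(shared)
    }
  }
  structure(list(counts = counts, intersections = inter), class = "panel_overlap")
}

#' @export
print.panel_overlap <- function(x, ...) {
  cat("Pairwise gene-panel overlap (diagonal = panel size):\n")
  print(x$counts)
  invisible(x)
}

#' Write a panel-overlap matrix to CSV
#'
#' @param x a [panel_overlap()] result.
#' @param counts_path CSV output for the overlap matrix.
#' @param intersections_path optional JSON output for the pairwise
#'   intersection gene lists.
#' @return `counts_path`, invisibly.
#' @export
write_overlap <- function(x, counts_path, intersections_path = NULL) {
  stopifnot(inherits(x, "panel_overlap"))
  utils::write.csv(as.data.frame(x$counts), counts_path)
  if (!is.null(intersections_path))
    jsonlite::write_json(x$intersections, intersections_path, pretty = TRUE)
  invisible(counts_path)
}
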