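# Panel evaluation: masked-input reconstruction with a shared training
# recipe, plus the seven-metric report card.

#' Fit the shared masked-input reconstructor for a panel
#'
#' Answers "given these K genes, how much of the transcriptome can be
#' recovered?". The input is the spatial expression matrix with every
#' unselected gene column set to zero; the target is the full matrix. The
#' reconstruction network has the same mirrored architecture and training
#' recipe for every panel — identical initialization, train/test cell split,
#' mini-batch order and dropout stream for a given `seed` and `config` — so
#' panels are compared under exactly the same procedure while the weights are
#' fitted per panel (a single fixed decoder could not accept different masked
#' supports). Reconstruction quality is reported on the held-out split only.
#'
#' @param panel a [gene_panel]; its genes must all be present in the spatial
#'   data.
#' @param spatial a [spatial_dataset] (log-scale expression).
#' @param config a [gate_ae_config()] supplying architecture and training
#'   hyperparameters; `val_fraction` is the held-out fraction.
#' @param seed integer seed shared across panels being compared.
#' @return An object of class `masked_recon`: list with `xhat` (deterministic
#'   reconstruction for all cells), `test_idx`/`train_idx` (the 20:80 split),
#'   `history`, the fitted `stages`, `mask`, `config`, `seed`.
#' @export
masked_reconstruct <- function(panel, spatial, config = gate_ae_config(),
                               seed = 0L) {
  stopifnot(inherits(spatial, "spatial_dataset"))
  if (!inherits(panel, "gene_panel"))
    gp_stop("gp_error_bad_config", "panel must be a gene_panel")
  xm <- unclass(spatial$expr); attr(xm, "scale") <- NULL
  missing <- setdiff(panel$genes, colnames(xm))
  if (length(missing))
    gp_stop("gp_error_missing_gene", "panel genes absent from spatial data: %s",
            paste(utils::head(missing, 5L), collapse = ", "))
  mask <- as.numeric(colnames(xm) %in% panel$genes)
  x_in <- xm * rep(mask, each = nrow(xm))
  res <- nn_train(x_in, xm,
                  encoder_dims = config$encoder_dims,
                  decoder_dims = c(config$decoder_dims, ncol(xm)),
                  leaky_slope = config$leaky_slope, dropout_p = config$dropout_p,
                  learning_rate = config$learning_rate,
                  weight_decay = config$weight_decay,
                  epochs = config$epochs, batch_size = config$batch_size,
                  val_fraction = config$val_fraction, seed = as.integer(seed),
                  lambda = 0, train_gate = FALSE)
  xhat <- nn_forward(res$stages, x_in, config$leaky_slope, 0, training = FALSE)$out
  dimnames(xhat) <- dimnames(xm)
  structure(list(xhat = xhat, train_idx = res$train_idx, test_idx = res$val_idx,
                 history = res$history, stages = res$stages,
                 init_stages = res$init_stages, mask = mask,
                 panel = panel, config = config, seed = as.integer(seed),
                 wall_seconds = res$wall_seconds),
            class = "masked_recon")
}

#' @export
print.masked_recon <- function(x, ...) {
  cat(sprintf("<masked_recon> panel of %d genes, %d cells (%d held out), %d epochs\n",
              length(x$panel$genes), nrow(x$xhat), length(x$test_idx),
              nrow(x$history)))
  invisible(x)
}

#' Score a gene panel against a spatial dataset
#'
#' The full seven-metric record card for one panel: masked-input shared-recipe
#' reconstruction ([masked_reconstruct()]), then
#' * `mse` — mean squared reconstruction error on the held-out cells;
#' * `kl_divergence` — gene-wise KL divergence between smoothed cell-wise
#'   distributions of observed vs reconstructed expression (held-out cells);
#' * `pearson_mean`, `spearman_mean` — gene-wise correlations averaged over
#'   genes (held-out cells);
#' * `morans_i_mean` — mean Moran's I of the reconstructed expression of all
#'   common genes over the held-out cells' k-nearest-neighbor graph;
#' * `ari` — Leiden-clustering Adjusted Rand Index of the panel's observed
#'   expression against the provided labels (all cells), `NA` without labels;
#' * `panel_runtime_seconds` — wall-clock cost of obtaining the panel,
#'   supplied by the caller (selection happens upstream).
#'
#' @param panel a [gene_panel].
#' @param spatial a [spatial_dataset].
#' @param config reconstruction [gate_ae_config()], shared across the panels
#'   being compared.
#' @param seed integer seed shared across panels.
#' @param resolution Leiden resolution for the ARI metric.
#' @param k_spatial neighbors for the Moran's I graph.
#' @param eps smoothing constant of the KL metric.
#' @param panel_runtime_seconds optional wall-clock seconds spent selecting
#'   the panel.
#' @param dataset_id free-text dataset identifier stored in the metadata.
#' @return An object of class `panel_report`: list with the seven metrics,
#'   `panel_size` and a `metadata` list (method, dataset id, seed, graph and
#'   clustering settings).
#' @export
evaluate_panel <- function(panel, spatial, config = gate_ae_config(),
                           seed = 0L, resolution = 1, k_spatial = 6L,
                           eps = 1e-8, panel_runtime_seconds = NA_real_,
                           dataset_id = "") {
  stopifnot(inherits(panel, "gene_panel"), inherits(spatial, "spatial_dataset"))
  rec <- masked_reconstruct(panel, spatial, config = config, seed = seed)
  test <- rec$test_idx
  x_obs <- as.matrix(spatial$expr)[test, , drop = FALSE]
  x_hat <- rec$xhat[test, , drop = FALSE]
  cors <- correlation_metrics(x_obs, x_hat)
  graph <- build_spatial_graph(spatial$coords[test, , drop = FALSE], k = k_spatial)
  moran <- morans_i_mean(x_hat, graph)
  ari <- if (is.null(spatial$labels)) NA_real_ else
    as.numeric(clustering_ari(panel, spatial, resolution = resolution, seed = seed))
  structure(list(
    mse = mse_metric(x_obs, x_hat),
    kl_divergence = kl_metric(x_obs, x_hat, eps = eps),
    pearson_mean = unname(cors["pearson_mean"]),
    spearman_mean = unname(cors["spearman_mean"]),
    morans_i_mean = as.numeric(moran),
    ari = ari,
    panel_runtime_seconds = panel_runtime_seconds,
    panel_size = length(panel$genes),
    metadata = list(method = panel$source, dataset_id = dataset_id,
                    seed = as.integer(seed), n_cells = nrow(spatial$expr),
                    n_genes = ncol(spatial$expr), n_heldout = length(test),
                    k_spatial = as.integer(k_spatial),
                    leiden_resolution = resolution,
                    recon_epochs = config$epochs)),
    class = "panel_report")
}

#' @export
print.panel_report <- function(x, ...) {
  cat(sprintf("Panel evaluation [%s], %d genes:\n", x$metadata$method, x$panel_size))
  for (key in c("mse", "kl_divergence", "pearson_mean", "spearman_mean",
                "morans_i_mean", "ari"))
    cat(sprintf("  %-14s %s\n", key,
                ifelse(is.na(x[[key]]), "NA", sprintf("%.4f", x[[key]]))))
  if (!is.na(x$panel_runtime_seconds))
    cat(sprintf("  %-14s %.1f\n", "runtime (s)", x$panel_runtime_seconds))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' Fixed key names: `mse`, `kl_divergence`, `pearson_mean`, `spearman_mean`,
#' `morans_i_mean`, `ari`, `panel_runtime_seconds`, `panel_size`, `metadata`.
#'
#' @param report a [evaluate_panel()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "panel_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    gp_stop("gp_error_missing_file", "file not found: %s", path)
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  out$ari <- out$ari %||% NA_real_
  out$panel_runtime_seconds <- out$panel_runtime_seconds %||% NA_real_
  structure(out, class = "panel_report")
}
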