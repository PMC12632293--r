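#' Model configuration for the gated autoencoder
#'
#' Architecture and optimization settings. The defaults are the reference
#' configuration used for atlas-scale gene-dimension inputs: a mirrored
#' bottleneck of 512-512-256-256-128 encoder units (decoder 256-256-512-512
#' then back to the gene dimension), LeakyReLU activations with negative slope
#' 0.3 and dropout probability 0.05 after every hidden stage, and Adam with
#' learning rate 1e-3, weight decay 1e-5, batch size 256, 1000 epochs and an
#' 80:20 train-validation split. Smaller problems (and the examples in this
#' package) use fewer epochs and narrower layers; pass them explicitly.
#'
#' @param encoder_dims integer vector of encoder layer widths; the last entry
#'   is the latent dimension.
#' @param decoder_dims integer vector of decoder layer widths excluding the
#'   final output layer (which is always the gene dimension). Default mirrors
#'   the encoder.
#' @param leaky_slope negative slope of the LeakyReLU activation.
#' @param dropout_p dropout probability after each hidden activation
#'   (training mode only).
#' @param learning_rate,weight_decay Adam settings; weight decay applies to
#'   the affine stages only, never to the gate.
#' @param epochs,batch_size training schedule; the last short mini-batch of an
#'   epoch is kept.
#' @param val_fraction fraction of cells held out for the per-epoch
#'   reconstruction-only validation loss.
#' @param seed integer seed controlling initialization, the train/validation
#'   split, mini-batch order and dropout.
#' @param zero_tol absolute threshold below which a gate weight counts as
#'   zero (numerical dust left by clamped stochastic updates).
#' @return A list of class `gate_ae_config`.
#' @export
gate_ae_config <- function(encoder_dims = c(512L, 512L, 256L, 256L, 128L),
                           decoder_dims = NULL,
                           leaky_slope = 0.3, dropout_p = 0.05,
                           learning_rate = 1e-3, weight_decay = 1e-5,
                           epochs = 1000L, batch_size = 256L,
                           val_fraction = 0.2, seed = 1L,
                           zero_tol = 1e-4) {
  encoder_dims <- as.integer(encoder_dims)
  if (length(encoder_dims) < 1L || any(encoder_dims <= 0L))
    gp_stop("gp_error_bad_config", "encoder_dims must be positive integers")
  if (is.null(decoder_dims)) decoder_dims <- rev(encoder_dims)[-1L]
  decoder_dims <- as.integer(decoder_dims)
  stopifnot(leaky_slope >= 0, dropout_p >= 0, dropout_p < 1,
            learning_rate > 0, weight_decay >= 0, epochs >= 1,
            batch_size >= 1, val_fraction > 0, val_fraction < 1, zero_tol >= 0)
  structure(list(encoder_dims = encoder_dims, decoder_dims = decoder_dims,
                 leaky_slope = leaky_slope, dropout_p = dropout_p,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, seed = as.integer(seed),
                 zero_tol = zero_tol),
            class = "gate_ae_config")
}

#' Apply a gate vector to an expression matrix
#'
#' Element-wise modulation of each cell's expression vector by the per-gene
#' gate weights: `out[i, j] = w[j] * x[i, j]`. This is the input layer of the
#' gated autoencoder; genes with zero weight are excluded from reconstruction.
#'
#' @param w non-negative numeric gate vector, one weight per gene.
#' @param x cells-by-genes numeric matrix.
#' @return Matrix of the same shape as `x`.
#' @export
gate_apply <- function(w, x) {
  x <- as.matrix(x)
  if (length(w) != ncol(x))
    gp_stop("gp_error_shape", "gate length (%d) must equal gene count (%d)",
            length(w), ncol(x))
  if (any(!is.finite(w)) || any(w < 0))
    gp_stop("gp_error_bad_gate", "gate weights must be finite and non-negative")
  x * rep(as.numeric(w), each = nrow(x))
}

#' Composite training loss: reconstruction error plus L1 gate penalty
#'
#' \deqn{L = \frac{1}{N}\sum_{i=1}^{N} \lVert x_i - \hat x_i \rVert_2^2
#'          + \lambda \sum_{j=1}^{G} w_j}
#' The squared error is summed over genes within a cell and averaged over
#' cells only; the penalty is the plain sum of the (non-negative) gate
#' weights, a true L1 norm on the feasible set.
#'
#' @param x,xhat observed and reconstructed cells-by-genes matrices.
#' @param w non-negative gate vector.
#' @param lambda non-negative L1 penalty strength.
#' @return A single non-negative number.
#' @examples
#' composite_loss(matrix(c(1, 2), 1), matrix(0, 1, 2), c(0.5, 0.5), 1) # 6
#' @export
composite_loss <- function(x, xhat, w, lambda) {
  x <- as.matrix(x); xhat <- as.matrix(xhat)
  if (!all(dim(x) == dim(xhat)))
    gp_stop("gp_error_shape", "x and xhat must have identical dimensions")
  if (length(w) != ncol(x))
    gp_stop("gp_error_shape", "gate length must equal gene count")
  if (any(!is.finite(x)) || any(!is.finite(xhat)) || any(!is.finite(w)))
    gp_stop("gp_error_non_finite", "inputs to composite_loss must be finite")
  if (lambda < 0 || any(w < 0))
    gp_stop("gp_error_bad_gate", "lambda and gate weights must be non-negative")
  sum((x - xhat)^2) / nrow(x) + lambda * sum(w)
}

#' Fit a gated autoencoder for gene panel selection
#'
#' Trains an autoencoder whose input layer multiplies every gene by a
#' learnable non-negative gate weight, minimizing mean (per-cell) squared
#' reconstruction error plus an L1 penalty `lambda * sum(w)` on the gates.
#' The L1 term drives the gates of uninformative genes to exactly zero while
#' genes needed to reconstruct the full transcriptome keep positive weight;
#' the surviving gates rank genes for panel selection (see [select_panel()]).
#'
#' Gates start at 1 (the identity mapping, no selection bias) and are clamped
#' to `[0, Inf)` after every Adam step. Weight decay is applied to the
#' encoder/decoder parameters only, so gate sparsity is governed solely by
#' `lambda`. The per-epoch validation loss is the reconstruction term alone,
#' computed in evaluation mode (no dropout) on a held-out cell split.
#'
#' @param x cells-by-genes matrix of log-normalized expression (an
#'   [expr_matrix] with `scale = "lognorm"`, or a plain numeric matrix).
#' @param lambda non-negative L1 penalty strength; see [tune_lambda()] for
#'   cross-validated selection.
#' @param config a [gate_ae_config()].
#' @param labels optional per-cell labels; when given, the train/validation
#'   split is stratified by label.
#' @return An object of class `gate_ae` with components `gate` (named
#'   non-negative weights), `history` (per-epoch train composite loss and
#'   validation reconstruction loss), `wall_seconds`, the fitted network and
#'   the training data. Supports [coef()], [predict()], [residuals()],
#'   `print`, `summary` and `plot`.
#' @examples
#' \donttest{
#' sim <- simulate_expression(sim_config(n_cells = 300, n_genes = 40,
#'                                       n_informative = 5, seed = 1))
#' cfg <- gate_ae_config(encoder_dims = c(32, 8), epochs = 50, seed = 1)
#' fit <- gate_ae(sim$expr, lambda = 0.05, config = cfg)
#' head(sort(coef(fit), decreasing = TRUE))
#' }
#' @export
gate_ae <- function(x, lambda = 0.01, config = gate_ae_config(), labels = NULL) {
  if (inherits(x, "expr_matrix") && expr_scale(x) != "lognorm")
    gp_stop("gp_error_bad_scale",
            "gate_ae expects log-normalized expression; run normalize_log_scale() first")
  xm <- unclass(as_expr_matrix(x))
  attr(xm, "scale") <- NULL
  if (nrow(xm) < 2L)
    gp_stop("gp_error_shape", "need at least 2 cells to fit")
  if (any(!is.finite(xm)))
    gp_stop("gp_error_non_finite", "expression values must be finite")
  if (lambda < 0)
    gp_stop("gp_error_bad_gate", "lambda must be non-negative")
  res <- nn_train(xm, xm,
                  encoder_dims = config$encoder_dims,
                  decoder_dims = c(config$decoder_dims, ncol(xm)),
                  leaky_slope = config$leaky_slope, dropout_p = config$dropout_p,
                  learning_rate = config$learning_rate,
                  weight_decay = config$weight_decay,
                  epochs = config$epochs, batch_size = config$batch_size,
                  val_fraction = config$val_fraction, seed = config$seed,
                  lambda = lambda, train_gate = TRUE, labels = labels)
  gate <- stats::setNames(res$gate, colnames(xm))
  structure(list(gate = gate, stages = res$stages, lambda = lambda,
                 config = config, history = res$history,
                 wall_seconds = res$wall_seconds,
                 train_idx = res$train_idx, val_idx = res$val_idx,
                 x = xm, call = match.call()),
            class = "gate_ae")
}

#' @export
print.gate_ae <- function(x, ...) {
  cat("Gated autoencoder fit\n")
  cat(sprintf("  %d cells x %d genes, lambda = %g\n", nrow(x$x), ncol(x$x), x$lambda))
  cat(sprintf("  gates > %g: %d of %d\n", x$config$zero_tol,
              sum(x$gate > x$config$zero_tol), length(x$gate)))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final train loss %.4f, validation reconstruction %.4f (%d epochs, %.1fs)\n",
                last$train_loss, last$val_recon_loss, nrow(x$history), x$wall_seconds))
  }
  invisible(x)
}

#' @export
summary.gate_ae <- function(object, ...) {
  w <- object$gate
  out <- list(
    n_cells = nrow(object$x), n_genes = length(w), lambda = object$lambda,
    n_nonzero = sum(w > object$config$zero_tol),
    gate_quantiles = stats::quantile(w, c(0, .25, .5, .75, .9, 1)),
    top_genes = utils::head(sort(w, decreasing = TRUE), 10L),
    final_train_loss = utils::tail(object$history$train_loss, 1L),
    final_val_recon = utils::tail(object$history$val_recon_loss, 1L),
    wall_seconds = object$wall_seconds)
  class(out) <- "summary.gate_ae"
  out
}

#' @export
print.summary.gate_ae <- function(x, ...) {
  cat(sprintf("Gated autoencoder: %d cells x %d genes, lambda = %g\n",
              x$n_cells, x$n_genes, x$lambda))
  cat(sprintf("Non-zero gates: %d / %d\n", x$n_nonzero, x$n_genes))
  cat("Gate weight quantiles:\n"); print(signif(x$gate_quantiles, 4))
  cat("Top genes by gate weight:\n"); print(signif(x$top_genes, 4))
  cat(sprintf("Final train loss %.4f | validation reconstruction %.4f | %.1fs\n",
              x$final_train_loss, x$final_val_recon, x$wall_seconds))
  invisible(x)
}

#' @rdname gate_ae
#' @param object a fitted `gate_ae`.
#' @param ... unused.
#' @return `coef()` returns the named non-negative gate vector.
#' @export
coef.gate_ae <- function(object, ...) object$gate

#' Reconstruct expression with a fitted gated autoencoder
#'
#' Runs the deterministic (no-dropout) forward pass: gate, encode, decode.
#'
#' @param object a fitted [gate_ae].
#' @param newdata cells-by-genes matrix over the same genes; defaults to the
#'   training data.
#' @param ... unused.
#' @return Reconstructed matrix of the same shape as `newdata`.
#' @export
predict.gate_ae <- function(object, newdata = object$x, ...) {
  xm <- as.matrix(newdata)
  if (ncol(xm) != length(object$gate))
    gp_stop("gp_error_shape", "newdata must have %d gene columns", length(object$gate))
  out <- nn_forward(object$stages, gate_apply(object$gate, xm),
                    object$config$leaky_slope, 0, training = FALSE)$out
  dimnames(out) <- dimnames(xm)
  out
}

#' @rdname predict.gate_ae
#' @export
fitted.gate_ae <- function(object, ...) predict(object)

#' @rdname predict.gate_ae
#' @return `residuals()` returns `newdata - predict(object, newdata)`.
#' @export
residuals.gate_ae <- function(object, newdata = object$x, ...) {
  as.matrix(newdata) - predict(object, newdata)
}

#' Encode cells into the latent space of a fitted model
#'
#' @param object a fitted [gate_ae] (the gate is applied first) or
#'   [masked_reconstruct()] result.
#' @param x cells-by-genes matrix.
#' @return Cells-by-latent-dimension matrix.
#' @export
encode <- function(object, x) UseMethod("encode")

#' @export
encode.gate_ae <- function(object, x = object$x) {
  n_enc <- length(object$config$encoder_dims)
  nn_forward(object$stages[seq_len(n_enc)], gate_apply(object$gate, as.matrix(x)),
             object$config$leaky_slope, 0, training = FALSE)$out
}

#' Decode latent representations back to expression space
#'
#' @param object a fitted [gate_ae].
#' @param h cells-by-latent-dimension matrix.
#' @return Cells-by-genes reconstruction.
#' @export
decode <- function(object, h) UseMethod("decode")

#' @export
decode.gate_ae <- function(object, h) {
  n_enc <- length(object$config$encoder_dims)
  nn_forward(object$stages[-seq_len(n_enc)], as.matrix(h),
             object$config$leaky_slope, 0, training = FALSE)$out
}

#' @export
plot.gate_ae <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_recon_loss), type = "l",
                    lty = 1, col = c("grey30", "firebrick"),
                    xlab = "epoch", ylab = "loss", main = "training history", ...)
  graphics::legend("topright", c("train (composite)", "validation (recon)"),
                   col = c("grey30", "firebrick"), lty = 1, bty = "n", cex = 0.8)
  w <- sort(x$gate, decreasing = TRUE)
  graphics::plot(seq_along(w), w, type = "h", col = "steelblue",
                 xlab = "gene rank", ylab = "gate weight", main = "gate weights")
  graphics::abline(h = x$config$zero_tol, lty = 3)
  invisible(x)
}
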