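# Dense feed-forward engine for the gated autoencoder.
#
# The network is a stack of affine stages W/b with LeakyReLU + dropout after
# every hidden stage; the latent stage (end of the encoder) and the output
# stage are affine-only. All heavy lifting is BLAS matrix products; gradients
# are computed by reverse-mode accumulation over the stage caches.

leaky_relu <- function(z, slope) pmax(z, 0) + slope * pmin(z, 0)

# Stage dimension chain: G -> encoder_dims -> decoder_dims (last = G).
# `act` marks stages followed by activation (+ dropout in training mode).
nn_architecture <- function(input_dim, encoder_dims, decoder_dims) {
  stopifnot(length(encoder_dims) >= 1L, length(decoder_dims) >= 1L)
  if (utils::tail(decoder_dims, 1L) != input_dim)
    gp_stop("gp_error_shape", "decoder must end at the input dimension (%d)", input_dim)
  dims <- c(input_dim, encoder_dims, decoder_dims)
  n_stage <- length(dims) - 1L
  act <- rep(TRUE, n_stage)
  act[length(encoder_dims)] <- FALSE   # latent stage: no activation
  act[n_stage] <- FALSE                # output stage: no activation
  list(dims = dims, act = act, latent_stage = length(encoder_dims))
}

# He-style initialization scaled for LeakyReLU; biases start at zero.
nn_init <- function(arch, slope) {
  lapply(seq_along(arch$act), function(j) {
    d_in <- arch$dims[j]; d_out <- arch$dims[j + 1L]
    sd <- sqrt(2 / ((1 + slope^2) * d_in))
    list(W = matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out),
         b = numeric(d_out), act = arch$act[j])
  })
}

# Forward pass. Returns the output and, when `cache = TRUE`, the per-stage
# inputs, pre-activations and dropout masks needed for backprop.
nn_forward <- function(stages, a, slope, dropout_p, training = FALSE, cache = FALSE) {
  n <- nrow(a)
  caches <- if (cache) vector("list", length(stages))
  for (j in seq_along(stages)) {
    st <- stages[[j]]
    z <- a %*% st$W + rep(st$b, each = n)
    mask <- NULL
    if (st$act) {
      out <- leaky_relu(z, slope)
      if (training && dropout_p > 0) {
        mask <- matrix((stats::runif(length(out)) >= dropout_p) / (1 - dropout_p),
                       nrow(out), ncol(out))
        out <- out * mask
      }
    } else {
      out <- z
    }
    if (cache) caches[[j]] <- list(a_in = a, z = if (st$act) z, mask = mask)
    a <- out
  }
  list(out = a, caches = caches)
}

# Reverse pass: gradient of the loss w.r.t. every W, b and the network input.
nn_backward <- function(stages, caches, d_out, slope) {
  grads <- vector("list", length(stages))
  for (j in rev(seq_along(stages))) {
    st <- stages[[j]]; ca <- caches[[j]]
    dz <- d_out
    if (st$act) {
      if (!is.null(ca$mask)) dz <- dz * ca$mask
      dz <- dz * (1 + (slope - 1) * (ca$z < 0))
    }
    grads[[j]] <- list(W = crossprod(ca$a_in, dz), b = colSums(dz))
    d_out <- tcrossprod(dz, st$W)
  }
  list(stages = grads, d_input = d_out)
}

adam_init <- function(param) list(m = param * 0, v = param * 0)

adam_update <- function(param, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# Mini-batch trainer shared by the gate-selection model and the masked
# reconstructor. Minimizes
#   (1/n_batch) * sum_i ||target_i - net(input_i)||^2 + lambda * sum_j w_j
# with Adam; the L2 weight decay applies to the affine stages only, never to
# the gate, whose shrinkage is governed solely by the explicit L1 term. After
# every optimizer step the gate is projected onto [0, Inf) by clamping, so the
# penalty is a true L1 on the feasible set and exact zeros are reachable.
nn_train <- function(x_input, x_target, encoder_dims, decoder_dims,
                     leaky_slope, dropout_p, learning_rate, weight_decay,
                     epochs, batch_size, val_fraction, seed,
                     lambda = 0, train_gate = FALSE, labels = NULL) {
  n <- nrow(x_input); g <- ncol(x_input)
  t_start <- proc.time()[["elapsed"]]
  res <- with_seed(seed, {
    arch <- nn_architecture(g, encoder_dims, decoder_dims)
    split <- split_indices(n, val_fraction, labels)
    stages <- nn_init(arch, leaky_slope)
    init_stages <- stages
    gate <- rep(1, g)
    opt <- lapply(stages, function(st) list(W = adam_init(st$W), b = adam_init(st$b)))
    opt_gate <- adam_init(gate)
    step <- 0L
    train_loss <- val_recon <- numeric(epochs)
    n_train <- length(split$train)
    x_val_in <- x_input[split$val, , drop = FALSE]
    x_val_tg <- x_target[split$val, , drop = FALSE]
    for (epoch in seq_len(epochs)) {
      ord <- sample(split$train)
      starts <- seq(1L, n_train, by = batch_size)
      epoch_loss <- 0
      for (s in starts) {
        batch <- ord[s:min(s + batch_size - 1L, n_train)]
        nb <- length(batch)
        xb <- x_input[batch, , drop = FALSE]
        xin <- if (train_gate) xb * rep(gate, each = nb) else xb
        fw <- nn_forward(stages, xin, leaky_slope, dropout_p,
                         training = TRUE, cache = TRUE)
        diff <- fw$out - x_target[batch, , drop = FALSE]
        loss <- sum(diff^2) / nb + lambda * sum(gate)
        if (!is.finite(loss))
          gp_stop("gp_error_training_diverged",
                  "non-finite training loss at epoch %d", epoch)
        bw <- nn_backward(stages, fw$caches, (2 / nb) * diff, leaky_slope)
        step <- step + 1L
        for (j in seq_along(stages)) {
          gW <- bw$stages[[j]]$W + weight_decay * stages[[j]]$W
          gb <- bw$stages[[j]]$b + weight_decay * stages[[j]]$b
          up <- adam_update(stages[[j]]$W, gW, opt[[j]]$W, learning_rate, step)
          stages[[j]]$W <- up$param; opt[[j]]$W <- up$state
          up <- adam_update(stages[[j]]$b, gb, opt[[j]]$b, learning_rate, step)
          stages[[j]]$b <- up$param; opt[[j]]$b <- up$state
        }
        if (train_gate) {
          g_gate <- colSums(bw$d_input * xb) + lambda
          up <- adam_update(gate, g_gate, opt_gate, learning_rate, step)
          gate <- pmax(up$param, 0)
          opt_gate <- up$state
        }
        epoch_loss <- epoch_loss + loss * nb
      }
      train_loss[epoch] <- epoch_loss / n_train
      vin <- if (train_gate) x_val_in * rep(gate, each = nrow(x_val_in)) else x_val_in
      vout <- nn_forward(stages, vin, leaky_slope, dropout_p, training = FALSE)$out
      val_recon[epoch] <- sum((vout - x_val_tg)^2) / nrow(x_val_tg)
    }
    list(stages = stages, init_stages = init_stages, gate = gate,
         history = data.frame(epoch = seq_len(epochs), train_loss = train_loss,
                              val_recon_loss = val_recon),
         train_idx = split$train, val_idx = split$val)
  })
  res$wall_seconds <- proc.time()[["elapsed"]] - t_start
  res
}
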