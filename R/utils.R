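# Internal helpers: classed conditions and seed hygiene.

gp_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "gatepanel_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

gp_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "gatepanel_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
# All stochastic package code goes through this so that results are a pure
# function of the supplied seed.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Train/validation split over cells, optionally stratified by label.
split_indices <- function(n, val_fraction, labels = NULL) {
  stopifnot(val_fraction > 0, val_fraction < 1)
  if (is.null(labels)) {
    val <- sample.int(n, size = max(1L, round(val_fraction * n)))
  } else {
    labels <- as.factor(labels)
    val <- unlist(lapply(split(seq_len(n), labels), function(idx) {
      take <- max(1L, round(val_fraction * length(idx)))
      if (length(idx) == 1L) return(integer(0))
      sample(idx, size = take)
    }), use.names = FALSE)
    if (length(val) == 0L) val <- sample.int(n, size = max(1L, round(val_fraction * n)))
  }
  list(train = setdiff(seq_len(n), val), val = sort(val))
}
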