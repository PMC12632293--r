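#' Simulation configuration
#'
#' Parameters of the synthetic single-cell/spatial generator used for method
#' development and testing. Genes split into three groups with known ground
#' truth: `n_informative` informative genes whose means are driven by
#' discrete cell types, `n_informative * redundancy` noisy copies of those
#' genes (emulating co-expressed gene modules that carry redundant
#' information), and pure-noise genes with no type effect. All values are on
#' the log-expression scale.
#'
#' The defaults are the standard small fixture (`fixture_small`): 2000 cells,
#' 200 genes of which 20 are informative with 2 copies each, 5 cell types,
#' type effect +/- 2 log-units, within-type noise 0.5, and a smooth spatial
#' gradient on the informative genes.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param n_informative number of informative genes; must satisfy
#'   `n_informative * (1 + redundancy) <= n_genes`.
#' @param n_cell_types number of discrete cell types (>= 1).
#' @param effect_size magnitude of the type-specific mean shift
#'   (log-expression units); each type gets a random sign per informative
#'   gene, never constant across types.
#' @param noise_sd within-type standard deviation of informative genes and of
#'   the copy noise.
#' @param redundancy number of noisy copies per informative gene.
#' @param spatial_pattern `"gradient"` (informative genes gain a smooth
#'   function of position), `"blocks"` (cell types occupy spatial blocks) or
#'   `"none"` (coordinates independent of expression).
#' @param gradient_amplitude scale of the `x + y` gradient field added to
#'   informative genes under `spatial_pattern = "gradient"`.
#' @param seed integer seed; every generator output is a pure function of the
#'   configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 2000L, n_genes = 200L, n_informative = 20L,
                       n_cell_types = 5L, effect_size = 2.0, noise_sd = 0.5,
                       redundancy = 2L, spatial_pattern = c("gradient", "blocks", "none"),
                       gradient_amplitude = 8, seed = 0L) {
  spatial_pattern <- match.arg(spatial_pattern)
  cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              n_informative = as.integer(n_informative),
              n_cell_types = as.integer(n_cell_types),
              effect_size = as.numeric(effect_size),
              noise_sd = as.numeric(noise_sd),
              redundancy = as.integer(redundancy),
              spatial_pattern = spatial_pattern,
              gradient_amplitude = as.numeric(gradient_amplitude),
              seed = as.integer(seed))
  if (cfg$n_cell_types < 1L || cfg$n_informative < 0L || cfg$noise_sd <= 0)
    gp_stop("gp_error_bad_config", "invalid simulation configuration")
  if (cfg$n_informative * (1L + cfg$redundancy) > cfg$n_genes)
    gp_stop("gp_error_infeasible_config",
            "n_informative * (1 + redundancy) = %d exceeds n_genes = %d",
            cfg$n_informative * (1L + cfg$redundancy), cfg$n_genes)
  structure(cfg, class = "sim_config")
}

# Random sign pattern over types, rejected if constant (a constant-sign gene
# would separate no types and carry less variance than a noise gene).
sign_pattern <- function(n_types) {
  if (n_types == 1L) return(1)
  repeat {
    s <- sample(c(-1, 1), n_types, replace = TRUE)
    if (length(unique(s)) > 1L) return(s)
  }
}

#' Simulate log-scale expression with known informative genes
#'
#' Cells are assigned uniformly to `n_cell_types` types. Informative gene `g`
#' has per-type mean `s[t] * effect_size` with a random non-constant sign
#' pattern `s`, plus `N(0, noise_sd)` within-type noise; each spawns
#' `redundancy` copies (parent value plus independent `N(0, noise_sd)`
#' noise); remaining genes are i.i.d. `N(0, 1)` with no type effect.
#'
#' @param cfg a [sim_config()].
#' @return A list with `expr` (an [expr_matrix], `scale = "lognorm"`) and
#'   `truth` (ground truth: `informative_genes`, `copy_genes`, `noise_genes`,
#'   `gene_module` — 0 for noise, module id otherwise —, `parent`,
#'   `cell_types`, and the configuration).
#' @export
simulate_expression <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_cells; g <- cfg$n_genes
    n_inf <- cfg$n_informative; n_cop <- n_inf * cfg$redundancy
    types <- sample.int(cfg$n_cell_types, n, replace = TRUE)
    gene_ids <- sprintf("g%04d", seq_len(g))
    x <- matrix(0, n, g, dimnames = list(sprintf("cell%05d", seq_len(n)), gene_ids))
    gene_module <- integer(g)
    parent <- rep(NA_character_, g)
    for (j in seq_len(n_inf)) {
      s <- sign_pattern(cfg$n_cell_types)
      x[, j] <- s[types] * cfg$effect_size + stats::rnorm(n, sd = cfg$noise_sd)
      gene_module[j] <- j
    }
    for (j in seq_len(n_cop)) {
      par <- ((j - 1L) %% n_inf) + 1L
      col <- n_inf + j
      x[, col] <- x[, par] + stats::rnorm(n, sd = cfg$noise_sd)
      gene_module[col] <- par
      parent[col] <- gene_ids[par]
    }
    if (n_inf + n_cop < g) {
      rest <- (n_inf + n_cop + 1L):g
      x[, rest] <- stats::rnorm(n * length(rest))
    }
    truth <- list(
      informative_genes = gene_ids[seq_len(n_inf)],
      copy_genes = if (n_cop > 0) gene_ids[n_inf + seq_len(n_cop)] else character(0),
      noise_genes = if (n_inf + n_cop < g) gene_ids[(n_inf + n_cop + 1L):g] else character(0),
      gene_module = stats::setNames(gene_module, gene_ids),
      parent = stats::setNames(parent, gene_ids),
      cell_types = paste0("type", types),
      config = cfg)
    list(expr = expr_matrix(x, "lognorm"), truth = truth)
  })
}

#' Attach spatial coordinates with controllable autocorrelation
#'
#' Places cells in the unit square and, depending on
#' `cfg$spatial_pattern`:
#' * `"gradient"` — adds `gradient_amplitude * (x + y - 1)` to every
#'   informative gene, giving them strong positive Moran's I while noise
#'   genes stay spatially random;
#' * `"blocks"` — assigns each cell type its own spatial block on a square
#'   grid (expression unchanged);
#' * `"none"` — coordinates are independent of expression.
#'
#' @param cfg the [sim_config()] used to generate `expr`.
#' @param expr the [expr_matrix] from [simulate_expression()].
#' @param truth the matching ground truth.
#' @return A [spatial_dataset] carrying the (possibly gradient-augmented)
#'   expression, coordinates in `[0, 1]^2` and the cell-type labels. The
#'   spatial field parameters are attached as attribute `field`.
#' @export
simulate_spatial <- function(cfg, expr, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 1L, {
    n <- nrow(expr)
    xm <- unclass(expr); attr(xm, "scale") <- NULL
    if (cfg$spatial_pattern == "blocks") {
      side <- ceiling(sqrt(cfg$n_cell_types))
      t_idx <- as.integer(sub("type", "", truth$cell_types)) - 1L
      bx <- t_idx %% side; by <- t_idx %/% side
      coords <- cbind(x = (bx + stats::runif(n)) / side,
                      y = (by + stats::runif(n)) / side)
    } else {
      coords <- cbind(x = stats::runif(n), y = stats::runif(n))
    }
    if (cfg$spatial_pattern == "gradient" && length(truth$informative_genes)) {
      field <- cfg$gradient_amplitude * (coords[, "x"] + coords[, "y"] - 1)
      xm[, truth$informative_genes] <-
        xm[, truth$informative_genes, drop = FALSE] + field
    }
    out <- spatial_dataset(expr_matrix(xm, "lognorm"), coords,
                           labels = truth$cell_types)
    attr(out, "field") <- list(pattern = cfg$spatial_pattern,
                               amplitude = cfg$gradient_amplitude)
    out
  })
}

#' Simulate a raw count matrix for preprocessing tests
#'
#' Turns the log-scale simulation into counts: per-cell expression is
#' exponentiated into relative rates, per-cell library sizes are drawn
#' log-normally around `depth`, and counts are Poisson. A configurable
#' fraction of cells is given a much smaller library (low-depth cells) and a
#' fraction of genes a much smaller rate (rare genes) to exercise the
#' detected-gene/detected-cell quality filters.
#'
#' @param cfg a [sim_config()].
#' @param depth median library size (counts per cell).
#' @param depth_sdlog log-normal spread of library sizes.
#' @param low_depth_fraction fraction of cells with `low_depth_factor`-scaled
#'   libraries.
#' @param low_depth_factor library multiplier for low-depth cells.
#' @param rare_gene_fraction fraction of genes with `rare_factor`-scaled
#'   rates.
#' @param rare_factor rate multiplier for rare genes.
#' @return A list with `counts` (an [expr_matrix], `scale = "counts"`) and
#'   `truth` (the log-scale ground truth plus `low_depth_cells` and
#'   `rare_genes`).
#' @export
simulate_counts <- function(cfg = sim_config(), depth = 2000, depth_sdlog = 0.3,
                            low_depth_fraction = 0.1, low_depth_factor = 0.05,
                            rare_gene_fraction = 0.1, rare_factor = 0.01) {
  stopifnot(inherits(cfg, "sim_config"))
  sim <- simulate_expression(cfg)
  with_seed(cfg$seed + 2L, {
    xm <- unclass(sim$expr); attr(xm, "scale") <- NULL
    n <- nrow(xm); g <- ncol(xm)
    rates <- exp(xm)
    rare <- sample.int(g, size = round(rare_gene_fraction * g))
    rates[, rare] <- rates[, rare, drop = FALSE] * rare_factor
    rates <- rates / rowSums(rates)
    lib <- stats::rlnorm(n, meanlog = log(depth), sdlog = depth_sdlog)
    low <- sample.int(n, size = round(low_depth_fraction * n))
    lib[low] <- lib[low] * low_depth_factor
    counts <- matrix(stats::rpois(n * g, lambda = rates * lib), n, g,
                     dimnames = dimnames(xm))
    truth <- sim$truth
    truth$low_depth_cells <- rownames(xm)[sort(low)]
    truth$rare_genes <- colnames(xm)[sort(rare)]
    truth$library_sizes <- lib
    list(counts = expr_matrix(counts, "counts"), truth = truth)
  })
}

#' The standard small synthetic fixture
#'
#' Generates the registered `fixture_small` dataset (2000 cells, 200 genes,
#' 20 informative genes with 2 noisy copies each, 5 cell types, effect size
#' 2.0, noise 0.5, spatial gradient, seed 0) used throughout the package's
#' property tests: a list with the log-scale expression, ground truth and the
#' matched spatial dataset.
#'
#' @param seed seed override (default 0, the registered fixture).
#' @return A list with `expr`, `truth`, `spatial`, `config`.
#' @export
fixture_small <- function(seed = 0L) {
  cfg <- sim_config(seed = seed)
  sim <- simulate_expression(cfg)
  spatial <- simulate_spatial(cfg, sim$expr, sim$truth)
  list(expr = sim$expr, truth = sim$truth, spatial = spatial, config = cfg)
}
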