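#' Simulation configuration
#'
#' Describes a synthetic multi-condition RNA-seq experiment: the study
#' design (conditions x replicates), a mixture of true expression
#' patterns, and the count-level noise model.  Gene base means are drawn
#' log-uniformly on `mean_log_range`; per-gene NB dispersions from
#' `Gamma(dispersion_shape, dispersion_scale)` (variance =
#' mean + dispersion * mean^2); per-sample size factors uniformly on
#' `size_factor_range`.  Within a gene, unequal adjacent blocks are
#' separated by at least `effect_size_min` fold, oriented by each
#' pattern's `ordering` tag.
#'
#' @param n_genes number of genes.
#' @param conditions condition labels, or a count (labelled `"C1"...`).
#' @param replicates_per_condition replicates per condition.
#' @param patterns list of [pattern_spec()] over the condition labels.
#' @param proportions pattern mixture proportions (sum to 1).
#' @param mean_log_range log-scale bounds for gene base means.
#' @param dispersion_shape,dispersion_scale gamma prior on the per-gene
#'   NB dispersion.
#' @param size_factor_range bounds (positive) for per-sample size factors.
#' @param effect_size_min minimum fold separation (> 1) between adjacent
#'   unequal blocks.
#' @param seed integer seed; all randomness flows from it.
#' @return Object of class `"sim_config"` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 100, conditions = 5,
#'                   replicates_per_condition = 4, seed = 1)
#' @export
sim_config <- function(n_genes,
                       conditions = 5,
                       replicates_per_condition = 4,
                       patterns = NULL,
                       proportions = NULL,
                       mean_log_range = log(c(5, 5000)),
                       dispersion_shape = 2,
                       dispersion_scale = 0.05,
                       size_factor_range = c(0.5, 2),
                       effect_size_min = 2,
                       seed = 1L) {
  if (length(conditions) == 1L && is.numeric(conditions))
    conditions <- paste0("C", seq_len(conditions))
  conditions <- as.character(conditions)
  if (anyDuplicated(conditions))
    stop("condition labels must be distinct", call. = FALSE)
  n_genes <- as.integer(n_genes)
  replicates_per_condition <- as.integer(replicates_per_condition)
  if (is.na(n_genes) || n_genes < 1L)
    stop("'n_genes' must be a positive integer", call. = FALSE)
  if (is.na(replicates_per_condition) || replicates_per_condition < 1L)
    stop("'replicates_per_condition' must be a positive integer",
         call. = FALSE)
  if (is.null(patterns)) {
    patterns <- list(EE = pattern_all_equal(conditions),
                     DE = pattern_all_unequal(conditions,
                                              ordering = "increasing"))
    if (is.null(proportions)) proportions <- c(0.9, 0.1)
  }
  if (inherits(patterns, "pattern_spec")) patterns <- list(patterns)
  check_patterns(patterns, conditions)
  if (is.null(proportions))
    proportions <- rep(1 / length(patterns), length(patterns))
  if (length(proportions) != length(patterns))
    stop("'proportions' must have one entry per pattern", call. = FALSE)
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9)
    stop("pattern proportions must be non-negative and sum to 1",
         call. = FALSE)
  if (effect_size_min <= 1)
    stop("'effect_size_min' must exceed 1", call. = FALSE)
  if (length(size_factor_range) != 2L || any(size_factor_range <= 0) ||
      diff(size_factor_range) < 0)
    stop("'size_factor_range' must be an increasing positive pair",
         call. = FALSE)
  if (length(mean_log_range) != 2L || diff(mean_log_range) < 0)
    stop("'mean_log_range' must be an increasing pair", call. = FALSE)
  if (dispersion_shape <= 0 || dispersion_scale <= 0)
    stop("dispersion prior parameters must be positive", call. = FALSE)
  structure(list(
    n_genes = n_genes, conditions = conditions,
    replicates_per_condition = replicates_per_condition,
    patterns = patterns, proportions = as.numeric(proportions),
    mean_log_range = as.numeric(mean_log_range),
    dispersion_shape = dispersion_shape,
    dispersion_scale = dispersion_scale,
    size_factor_range = as.numeric(size_factor_range),
    effect_size_min = effect_size_min,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a multi-condition count matrix with known truth
#'
#' Draws, per gene, a true pattern from the configured mixture, block-wise
#' condition means (adjacent unequal blocks at least `effect_size_min`
#' fold apart, oriented by the pattern's `ordering` tag, otherwise
#' assigned at random), a NB dispersion, and then counts
#' `x ~ NB(mean = mu * size factor, dispersion)` for every sample.
#' Identical configurations (including seed) give bitwise-identical
#' output.
#'
#' @param config a [sim_config()].
#' @return A list of class `"ebpat_sim"`:
#' \describe{
#'   \item{counts}{integer matrix, genes x samples.}
#'   \item{condition_map}{named factor, sample to condition.}
#'   \item{truth}{list with `pattern` (per-gene true pattern name),
#'     `means` (true genes x conditions mean matrix), `dispersion`
#'     (per-gene), and `size_factors` (per-sample).}
#'   \item{config}{the configuration used.}
#' }
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 50, seed = 3))
#' table(sim$truth$pattern)
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- length(config$conditions)
  R <- config$replicates_per_condition
  G <- config$n_genes
  N <- K * R
  sample_cond <- rep(config$conditions, each = R)
  sample_ids <- paste0(sample_cond, "_r", rep(seq_len(R), times = K))
  gene_ids <- sprintf("g%05d", seq_len(G))

  sf <- stats::runif(N, config$size_factor_range[1],
                     config$size_factor_range[2])
  pat_idx <- sample.int(length(config$patterns), G, replace = TRUE,
                        prob = config$proportions)
  base_mu <- exp(stats::runif(G, config$mean_log_range[1],
                              config$mean_log_range[2]))
  phi <- stats::rgamma(G, shape = config$dispersion_shape,
                       scale = config$dispersion_scale)
  phi <- pmax(phi, 1e-4)

  means <- matrix(0, G, K,
                  dimnames = list(gene_ids, config$conditions))
  for (g in seq_len(G)) {
    pat <- config$patterns[[pat_idx[g]]]
    B <- pat$n_blocks
    if (B == 1L) {
      means[g, ] <- base_mu[g]
    } else {
      # ladder of block levels: each rung at least effect_size_min fold
      # above the previous, with a random extra factor up to 2x
      steps <- config$effect_size_min *
        exp(stats::runif(B - 1L, 0, log(2)))
      levels_b <- base_mu[g] * cumprod(c(1, steps))
      levels_b <- switch(pat$ordering,
                         increasing = levels_b,
                         decreasing = rev(levels_b),
                         none = sample(levels_b))
      means[g, ] <- levels_b[pat$assign[match(config$conditions,
                                              pat$labels)]]
    }
  }

  # NB in (mean, dispersion) form converted to the (r, q) form of the
  # inference model: per-sample size r_i = (1/phi) * l_i and
  # q_k = r0 / (r0 + mu_k), so mean_i = mu_k * l_i and
  # var_i = mean_i * (1 + phi * mu_k)
  mu_sample <- means[, match(sample_cond, config$conditions), drop = FALSE]
  mu_sample <- sweep(mu_sample, 2, sf, "*")
  size_sample <- outer(1 / phi, sf)
  counts <- matrix(
    stats::rnbinom(G * N, mu = mu_sample, size = size_sample),
    nrow = G, dimnames = list(gene_ids, sample_ids))
  storage.mode(counts) <- "integer"

  pat_names <- vapply(config$patterns, function(p) p$name, character(1))
  structure(list(
    counts = counts,
    condition_map = stats::setNames(
      factor(sample_cond, levels = config$conditions), sample_ids),
    truth = list(
      pattern = stats::setNames(pat_names[pat_idx], gene_ids),
      means = means,
      dispersion = stats::setNames(phi, gene_ids),
      size_factors = stats::setNames(sf, sample_ids)
    ),
    config = config
  ), class = "ebpat_sim")
}

#' @export
print.ebpat_sim <- function(x, ...) {
  cat("Synthetic multi-condition count data\n")
  cat("  genes x samples:", nrow(x$counts), "x", ncol(x$counts), "\n")
  cat("  conditions:", paste(levels(x$condition_map), collapse = ", "),
      "(", x$config$replicates_per_condition, "replicates each )\n")
  cat("  true pattern mix:\n")
  print(round(table(x$truth$pattern) / nrow(x$counts), 3))
  invisible(x)
}

#' Simulate a phenotype table
#'
#' Generates per-donor, per-condition counts of monocyte-derived cells
#' (e.g. CD68+ macrophages per field of view) whose condition means,
#' averaged over donors, sort into the requested order when `noise_sd` is
#' small.  Base levels rise 1.6-fold per rank step from 20 cells per field
#' of view; Gaussian noise with standard deviation `noise_sd` is added and
#' values are floored at zero.
#'
#' @param order condition labels, worst to best (ascending target order).
#' @param noise_sd standard deviation of additive measurement noise, in
#'   cells per field of view.
#' @param n_donors number of donors.
#' @param marker marker name recorded in the table (e.g. `"CD68"`).
#' @param seed integer seed.
#' @return A data.frame with `n_donors * length(order)` rows and columns
#'   `donor`, `condition`, `marker`, `count`.
#' @examples
#' ph <- simulate_phenotype(c("OV90", "OVCAR4", "OVCAR3",
#'                            "OVCA432", "OVCAR5"),
#'                          noise_sd = 0, n_donors = 3, marker = "CD68")
#' derive_condition_order(ph, "CD68")
#' @export
simulate_phenotype <- function(order, noise_sd = 5, n_donors = 3,
                               marker = "CD68", seed = 1L) {
  order <- as.character(order)
  if (anyDuplicated(order))
    stop("condition labels must be distinct", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  set.seed(as.integer(seed))
  base <- 20 * 1.6^(seq_along(order) - 1)
  out <- expand.grid(donor = paste0("donor", seq_len(n_donors)),
                     condition = order, stringsAsFactors = FALSE)
  out$marker <- marker
  out$count <- pmax(0, base[match(out$condition, order)] +
                      stats::rnorm(nrow(out), 0, noise_sd))
  out
}
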