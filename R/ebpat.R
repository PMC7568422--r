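#' Negative-binomial--beta marginal log-likelihood of an equality block
#'
#' The observation model for a gene within one equality block is
#' \eqn{x_i \sim NB(r_i, q)} with a shared probability parameter
#' \eqn{q \sim Beta(\alpha, \beta)} integrated out.  The marginal
#' (prior-predictive) density of the block's counts is
#' \deqn{f(x) = \prod_i \binom{x_i + r_i - 1}{x_i} \cdot
#'   \frac{B(\alpha + \sum_i r_i,\; \beta + \sum_i x_i)}{B(\alpha, \beta)}}
#' evaluated here entirely in log space.  An empty block has marginal 1
#' (log 0), the empty product.
#'
#' @param x non-negative integer counts of the block's samples.
#' @param r positive NB size parameters, one per sample (the gene-level
#'   size `r0` already scaled by each sample's size factor).
#' @param alpha,beta positive beta-prior hyperparameters on `q`.
#' @return The log marginal density, a finite scalar.
#' @examples
#' marginal_loglik(0, 1, 1, 1)  # log(1/2)
#' @export
marginal_loglik <- function(x, r, alpha, beta) {
  if (length(x) == 0L) return(0)
  if (any(x < 0) || any(x != floor(x)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(r <= 0) || alpha <= 0 || beta <= 0)
    stop("'r', 'alpha' and 'beta' must be positive", call. = FALSE)
  if (length(r) == 1L) r <- rep(r, length(x))
  sum(lgamma(x + r) - lgamma(r) - lgamma(x + 1)) +
    lbeta(alpha + sum(r), beta + sum(x)) - lbeta(alpha, beta)
}

#' Fit the empirical-Bayes expression-pattern model
#'
#' Fits, to a genes x samples count matrix observed under K conditions, a
#' negative-binomial mixture over multi-condition equality patterns.  For
#' gene g with per-gene size \eqn{r_{0g}} and sample size factors
#' \eqn{l_i}, counts are \eqn{x_{gi} \sim NB(r_{0g} l_i, q_g)}; within each
#' equality block of a pattern the probability parameter \eqn{q_g} is
#' shared and integrated against a \eqn{Beta(\alpha, \beta)} prior (see
#' [marginal_loglik()]), and blocks are independent.  A pattern's
#' likelihood is the product of its block marginals; the posterior pattern
#' probabilities follow by Bayes' rule with mixture weights \eqn{p_k}.
#'
#' Hyperparameters are estimated empirically: \eqn{r_{0g}} by method of
#' moments from the normalized counts, \eqn{\hat r = m^2 / (v - m)} with
#' \eqn{m} the overall mean and \eqn{v} the within-condition pooled
#' variance (so between-condition signal is not mistaken for
#' overdispersion; clamped to `r0_limits`, genes with \eqn{v \le m}
#' clamped to the upper limit with a warning), and
#' \eqn{(\alpha, \beta)} and the mixture \eqn{p} by EM: the E step computes
#' posteriors via log-sum-exp, the M step sets \eqn{p_k} to the mean
#' posterior and maximizes the expected log marginal over
#' \eqn{(\alpha, \beta)} numerically.  Genes with all-zero counts are
#' dropped before fitting and recorded in the returned object.
#'
#' @param counts integer matrix, genes x samples (rownames = gene ids).
#' @param conditions sample-to-condition assignment: factor/character per
#'   column, or a named vector keyed by sample name.
#' @param patterns list of [pattern_spec()] objects over the condition
#'   labels.  Default: all set partitions for K <= 4 conditions; for
#'   K = 5, the `"p1_p6"` restriction plus the all-equal pattern.
#' @param size_factors per-sample size factors; default
#'   [median_ratio_size_factors()].
#' @param alpha,beta initial (or, with `estimate_hyper = FALSE`, fixed)
#'   beta-prior hyperparameters.
#' @param r0 optional fixed per-gene NB sizes, bypassing the
#'   method-of-moments estimate.
#' @param mixture optional initial (or fixed) pattern proportions.
#' @param estimate_hyper run EM (`TRUE`, default) or hold `alpha`, `beta`
#'   and `mixture` fixed and compute posteriors in a single E step.
#' @param max_iter,tol EM iteration cap and convergence tolerance on the
#'   largest change in `(alpha, beta, p)`.
#' @param r0_limits clamp interval for the method-of-moments `r0`.
#' @param verbose print the EM trajectory.
#' @return An object of class `"ebpat"`: a list with the fitted
#'   `alpha`, `beta`, `mixture`, per-gene `r0`, `size_factors`,
#'   `posterior` (genes x patterns, rows summing to 1), `map` (each
#'   gene's maximum-a-posteriori pattern), `condition_means` (normalized
#'   replicate-averaged means), `logLik_trace`, `converged`, `iterations`
#'   and `dropped` (all-zero gene ids).  Methods: `print`, `summary`,
#'   `coef`, `logLik`, `posterior`, `plot`, `simulate`.
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 200, conditions = c("A", "B"),
#'                                   replicates_per_condition = 4, seed = 7))
#' fit <- ebpat(sim$counts, sim$condition_map)
#' fit
#' head(posterior(fit))
#' @seealso [fdr_select()], [de_universe()], [apply_gate()]
#' @export
ebpat <- function(counts, conditions, patterns = NULL, size_factors = NULL,
                  alpha = 1, beta = 1, r0 = NULL, mixture = NULL,
                  estimate_hyper = TRUE, max_iter = 50L, tol = 1e-4,
                  r0_limits = c(1e-3, 1e4), verbose = FALSE) {
  cl <- match.call()
  counts <- as_count_matrix(counts)
  cond <- align_condition_map(conditions, counts)
  levs <- levels(cond)

  if (is.null(patterns)) {
    patterns <- if (length(levs) == 5L)
      c(list(EE = pattern_all_equal(levs)),
        enumerate_patterns(5L, "p1_p6", labels = levs))
    else enumerate_patterns(length(levs), labels = levs)
  }
  if (inherits(patterns, "pattern_spec")) patterns <- list(patterns)
  check_patterns(patterns, levs)
  pat_names <- vapply(patterns, function(p) p$name, character(1))
  if (anyDuplicated(pat_names))
    stop("pattern names must be unique", call. = FALSE)

  if (is.null(size_factors)) size_factors <- median_ratio_size_factors(counts)
  sf <- as.numeric(size_factors)
  if (length(sf) != ncol(counts) || any(sf <= 0) || any(!is.finite(sf)))
    stop("size factors must be finite, positive, one per sample",
         call. = FALSE)

  # drop all-zero genes: their marginal carries no information and the
  # method-of-moments size estimate degenerates
  zero <- rowSums(counts) == 0
  dropped <- rownames(counts)[zero]
  if (any(zero)) {
    message(sum(zero), " gene(s) with all-zero counts dropped before fitting")
    counts <- counts[!zero, , drop = FALSE]
  }
  if (nrow(counts) == 0L) stop("no genes left to fit", call. = FALSE)
  G <- nrow(counts)

  if (is.null(r0)) {
    r0 <- moments_r0(counts, sf, cond, r0_limits)
  } else {
    r0 <- rep_len(as.numeric(r0), G)
    if (any(r0 <= 0)) stop("'r0' must be positive", call. = FALSE)
  }

  p <- if (is.null(mixture)) rep(1 / length(patterns), length(patterns))
       else {
         if (length(mixture) != length(patterns))
           stop("'mixture' must have one entry per pattern", call. = FALSE)
         if (abs(sum(mixture) - 1) > 1e-9)
           stop("'mixture' must sum to 1", call. = FALSE)
         as.numeric(mixture)
       }

  bs <- pattern_block_sums(counts, sf, cond, patterns)
  # per-gene base term (NB combinatorial coefficients): identical across
  # patterns, needed only for the observed-data log-likelihood
  base <- base_loglik(counts, sf, r0)

  ll_trace <- numeric(0)
  converged <- !estimate_hyper
  iter <- 0L
  repeat {
    L <- pattern_loglik_matrix(bs, r0, alpha, beta)
    es <- posterior_from_loglik(L, p)
    ll_trace <- c(ll_trace, sum(base) + es$logLik)
    if (!estimate_hyper || length(patterns) == 1L) break
    iter <- iter + 1L

    p_new <- colMeans(es$pp)
    ab_new <- update_hyperparams(bs, r0, es$pp, alpha, beta)
    delta <- max(abs(c(ab_new - c(alpha, beta), p_new - p)))
    alpha <- ab_new[1]; beta <- ab_new[2]; p <- p_new
    if (verbose)
      message(sprintf("EM iter %d: alpha=%.4g beta=%.4g logLik=%.6g",
                      iter, alpha, beta, ll_trace[length(ll_trace)]))
    if (delta < tol) { converged <- TRUE }
    if (converged || iter >= max_iter) {
      L <- pattern_loglik_matrix(bs, r0, alpha, beta)
      es <- posterior_from_loglik(L, p)
      ll_trace <- c(ll_trace, sum(base) + es$logLik)
      break
    }
  }
  if (estimate_hyper && !converged && length(patterns) > 1L)
    warning("EM did not converge in ", max_iter,
            " iterations; returning best iterate", call. = FALSE)

  pp <- es$pp
  dimnames(pp) <- list(rownames(counts), pat_names)
  map_idx <- max.col(pp, ties.method = "first")
  names(p) <- pat_names

  structure(list(
    call = cl,
    counts = counts,
    conditions = cond,
    patterns = patterns,
    alpha = alpha, beta = beta, mixture = p,
    r0 = stats::setNames(r0, rownames(counts)),
    size_factors = stats::setNames(sf, colnames(counts)),
    posterior = pp,
    map = stats::setNames(pat_names[map_idx], rownames(counts)),
    condition_means = condition_means(counts, sf, cond),
    logLik_trace = ll_trace,
    converged = converged,
    iterations = iter,
    dropped = dropped
  ), class = "ebpat")
}

check_patterns <- function(patterns, levs) {
  if (!length(patterns)) stop("need at least one pattern", call. = FALSE)
  ok <- vapply(patterns, function(p)
    inherits(p, "pattern_spec") && setequal(p$labels, levs), logical(1))
  if (!all(ok))
    stop("every pattern must be a pattern_spec over the condition labels ",
         paste(levs, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# method-of-moments NB size from normalized counts, clamped.  The
# variance is the within-condition pooled variance, so that genuine
# between-condition signal is not mistaken for overdispersion.  Because
# r-hat = m^2 / (v - m) takes the reciprocal of a noisy (roughly
# chi-square, df degrees of freedom) excess-variance estimate, its
# expectation is inflated by about df / (df - 2); the (df - 2) / df
# factor undoes that first-order bias, which otherwise makes posteriors
# overconfident and the posterior FDR anti-conservative.
moments_r0 <- function(counts, sf, cond, r0_limits) {
  norm <- sweep(counts, 2, sf, "/")
  m <- rowMeans(norm)
  n_k <- table(cond)
  df <- sum(n_k - 1L)
  if (df > 0L) {
    ss <- 0
    for (k in levels(cond)) {
      cols <- which(cond == k)
      if (length(cols) > 1L) {
        sub <- norm[, cols, drop = FALSE]
        ss <- ss + rowSums((sub - rowMeans(sub))^2)
      }
    }
    v <- ss / df
  } else {
    # single replicate per condition: only the across-sample variance exists
    v <- apply(norm, 1, stats::var)
    df <- ncol(counts) - 1L
  }
  r0 <- m^2 / (v - m)
  if (df > 2L) r0 <- r0 * (df - 2L) / df
  bad <- !is.finite(r0) | r0 <= 0
  if (any(bad)) {
    warning(sum(bad), " gene(s) with variance <= mean; NB size clamped to ",
            r0_limits[2], call. = FALSE)
    r0[bad] <- r0_limits[2]
  }
  pmin(pmax(r0, r0_limits[1]), r0_limits[2])
}

# per-gene sum over samples of log NB combinatorial coefficients
base_loglik <- function(counts, sf, r0) {
  out <- numeric(nrow(counts))
  for (i in seq_len(ncol(counts))) {
    ri <- r0 * sf[i]
    xi <- counts[, i]
    out <- out + lgamma(xi + ri) - lgamma(ri) - lgamma(xi + 1)
  }
  out
}

# precompute, per pattern and equality block, the gene-wise count sums and
# the block's total size factor (counts pooled over the block's conditions)
pattern_block_sums <- function(counts, sf, cond, patterns) {
  lapply(patterns, function(pat) {
    lapply(seq_len(pat$n_blocks), function(b) {
      block_conds <- pat$labels[pat$assign == b]
      cols <- which(cond %in% block_conds)
      list(Sx = rowSums(counts[, cols, drop = FALSE]),
           sf_sum = sum(sf[cols]))
    })
  })
}

# genes x patterns matrix of log pattern likelihoods, excluding the
# pattern-independent combinatorial base term
pattern_loglik_matrix <- function(block_sums, r0, alpha, beta) {
  G <- length(r0)
  L <- matrix(0, G, length(block_sums))
  for (k in seq_along(block_sums)) {
    acc <- numeric(G)
    for (blk in block_sums[[k]])
      acc <- acc + lbeta(alpha + r0 * blk$sf_sum, beta + blk$Sx) -
        lbeta(alpha, beta)
    L[, k] <- acc
  }
  L
}

# E step: posteriors by log-sum-exp; also the mixture log-likelihood
posterior_from_loglik <- function(L, p) {
  lp <- sweep(L, 2, log(p), "+")
  m <- apply(lp, 1, max)
  w <- exp(lp - m)
  rs <- rowSums(w)
  list(pp = w / rs, logLik = sum(m + log(rs)))
}

# M step for (alpha, beta): maximize expected log marginal, log scale
update_hyperparams <- function(block_sums, r0, pp, alpha, beta) {
  negQ <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    L <- pattern_loglik_matrix(block_sums, r0, a, b)
    -sum(pp * L)
  }
  opt <- stats::optim(log(c(alpha, beta)), negQ, method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-8))
  exp(opt$par)
}
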