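#' Extract posterior pattern probabilities
#'
#' @param object a fitted [ebpat()] model.
#' @param ... unused.
#' @return Genes x patterns matrix of posterior probabilities; each row
#'   sums to 1.
#' @export
posterior <- function(object, ...) UseMethod("posterior")

#' @rdname posterior
#' @export
posterior.ebpat <- function(object, ...) object$posterior

#' @export
print.ebpat <- function(x, ...) {
  cat("Empirical-Bayes expression-pattern model\n")
  cat("  genes: ", nrow(x$posterior),
      if (length(x$dropped)) paste0(" (", length(x$dropped),
                                    " all-zero dropped)"), "\n", sep = "")
  cat("  conditions:", paste(levels(x$conditions), collapse = ", "), "\n")
  cat("  patterns:", paste(names(x$mixture), collapse = ", "), "\n")
  cat(sprintf("  alpha = %.4g, beta = %.4g\n", x$alpha, x$beta))
  cat("  mixture:", paste(sprintf("%s=%.3f", names(x$mixture), x$mixture),
                          collapse = ", "), "\n")
  cat("  EM:", x$iterations, "iteration(s),",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' @export
summary.ebpat <- function(object, ...) {
  map_tab <- table(factor(object$map, levels = names(object$mixture)))
  out <- list(
    n_genes = nrow(object$posterior),
    n_dropped = length(object$dropped),
    conditions = levels(object$conditions),
    alpha = object$alpha, beta = object$beta,
    mixture = object$mixture,
    map_counts = map_tab,
    r0_summary = summary(object$r0),
    converged = object$converged,
    iterations = object$iterations,
    logLik = utils::tail(object$logLik_trace, 1)
  )
  class(out) <- "summary.ebpat"
  out
}

#' @export
print.summary.ebpat <- function(x, ...) {
  cat("Empirical-Bayes expression-pattern model\n\n")
  cat("Genes fitted:", x$n_genes, " (dropped all-zero:", x$n_dropped, ")\n")
  cat("Conditions:", paste(x$conditions, collapse = ", "), "\n\n")
  cat(sprintf("Beta prior:  alpha = %.4g, beta = %.4g\n", x$alpha, x$beta))
  cat("Mixture proportions:\n")
  print(round(x$mixture, 4))
  cat("\nMAP pattern assignment counts:\n")
  print(x$map_counts)
  cat("\nPer-gene NB size (r0):\n")
  print(x$r0_summary)
  cat(sprintf("\nlog-likelihood: %.4f  (%d EM iteration(s); %s)\n",
              x$logLik, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
coef.ebpat <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta, object$mixture)
}

#' @export
logLik.ebpat <- function(object, ...) {
  ll <- utils::tail(object$logLik_trace, 1)
  # free parameters: alpha, beta, mixture simplex (per-gene r0 are plug-ins)
  attr(ll, "df") <- 2 + length(object$mixture) - 1
  attr(ll, "nobs") <- nrow(object$posterior)
  class(ll) <- "logLik"
  ll
}

#' Diagnostic plots for a fitted pattern model
#'
#' `which = "trace"` shows the EM log-likelihood trajectory (should be
#' non-decreasing); `which = "posterior"` a histogram of each gene's
#' maximum posterior pattern probability.
#'
#' @param x a fitted [ebpat()] model.
#' @param which `"trace"` or `"posterior"`.
#' @param ... passed to the underlying plotting function.
#' @return `x`, invisibly.
#' @export
plot.ebpat <- function(x, which = c("trace", "posterior"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    graphics::plot(seq_along(x$logLik_trace), x$logLik_trace, type = "b",
                   xlab = "EM evaluation", ylab = "log-likelihood", ...)
  } else {
    graphics::hist(apply(x$posterior, 1, max), breaks = 30,
                   xlab = "max posterior pattern probability",
                   main = "MAP posterior probabilities", ...)
  }
  invisible(x)
}

#' Simulate counts from a fitted pattern model
#'
#' Draws new count matrices from the fitted generative model: for each
#' gene a pattern from the fitted mixture, per equality block a
#' probability parameter `q ~ Beta(alpha, beta)`, then counts
#' `x_i ~ NB(r0 * l_i, q)` using the fitted per-gene sizes and per-sample
#' size factors.
#'
#' @param object a fitted [ebpat()] model.
#' @param nsim number of matrices to simulate.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of `nsim` count matrices with the fitted dimnames; the
#'   drawn pattern names are attached as attribute `"pattern"`.
#' @export
simulate.ebpat <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  G <- nrow(object$posterior)
  sf <- object$size_factors
  cond <- object$conditions
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    k <- sample(length(object$mixture), G, replace = TRUE,
                prob = object$mixture)
    x <- matrix(0L, G, length(sf),
                dimnames = dimnames(object$counts))
    for (g in seq_len(G)) {
      pat <- object$patterns[[k[g]]]
      for (b in seq_len(pat$n_blocks)) {
        cols <- which(cond %in% pat$labels[pat$assign == b])
        q <- stats::rbeta(1, object$alpha, object$beta)
        x[g, cols] <- stats::rnbinom(length(cols),
                                     size = object$r0[g] * sf[cols],
                                     prob = q)
      }
    }
    attr(x, "pattern") <- names(object$mixture)[k]
    out[[s]] <- x
  }
  if (nsim == 1) out[[1]] else out
}
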