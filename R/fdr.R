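#' Posterior-probability FDR selection
#'
#' Soft false-discovery-rate control on posterior pattern probabilities:
#' genes are ranked by decreasing posterior probability of the target
#' pattern, and the largest prefix whose mean posterior probability of
#' mis-assignment (1 - PP) does not exceed `fdr_level` is selected.  The
#' mean mis-assignment probability of the selected set is the estimated
#' FDR.  Ties in PP are broken by gene identifier so the selection is
#' deterministic.
#'
#' @param x a fitted [ebpat()] model, or a genes x patterns posterior
#'   matrix with gene rownames and pattern colnames.
#' @param target_pattern the pattern of interest, by name or as a
#'   [pattern_spec()].
#' @param fdr_level nominal FDR level in (0, 1); 0.05 by default.
#' @return An object of class `"ebpat_selection"`: list with `genes`
#'   (selected ids, in rank order), `n`, `estimated_fdr` (mean 1 - PP of
#'   the selected set; 0 for an empty set), `fdr_level`, `target_pattern`
#'   and `pp` (the full ranked PP vector).
#' @examples
#' pp <- cbind(EE = c(.01, .03, .10, .50), DE = c(.99, .97, .90, .50))
#' rownames(pp) <- paste0("g", 1:4)
#' fdr_select(pp, "DE", 0.05)  # selects the top 3
#' @export
fdr_select <- function(x, target_pattern, fdr_level = 0.05) {
  if (fdr_level <= 0 || fdr_level >= 1)
    stop("'fdr_level' must be in (0, 1)", call. = FALSE)
  pp_mat <- if (inherits(x, "ebpat")) x$posterior else as.matrix(x)
  tname <- if (inherits(x, "ebpat")) {
    names(x$mixture)[match_pattern(target_pattern, x$patterns)]
  } else {
    tp <- if (inherits(target_pattern, "pattern_spec")) target_pattern$name
          else as.character(target_pattern)
    if (!tp %in% colnames(pp_mat))
      stop("pattern '", tp, "' not found in the posterior table",
           call. = FALSE)
    tp
  }
  pp <- pp_mat[, tname]
  genes <- rownames(pp_mat)
  if (is.null(genes)) genes <- paste0("gene", seq_along(pp))
  ord <- order(-pp, genes)
  pp <- pp[ord]; genes <- genes[ord]
  # (1 - pp) is non-decreasing along the ranking, so the running mean is
  # too: the largest admissible prefix is a simple count
  cum_fdr <- cumsum(1 - pp) / seq_along(pp)
  n_sel <- sum(cum_fdr <= fdr_level)
  structure(list(
    genes = genes[seq_len(n_sel)],
    n = n_sel,
    estimated_fdr = if (n_sel > 0) unname(cum_fdr[n_sel]) else 0,
    fdr_level = fdr_level,
    target_pattern = tname,
    pp = stats::setNames(pp, genes)
  ), class = "ebpat_selection")
}

#' @export
print.ebpat_selection <- function(x, ...) {
  cat("Posterior-probability FDR selection\n")
  cat("  target pattern:", x$target_pattern, "\n")
  cat(sprintf("  nominal level: %.3g; estimated FDR: %.4g\n",
              x$fdr_level, x$estimated_fdr))
  cat("  genes selected:", x$n, "of", length(x$pp), "\n")
  if (x$n > 0)
    cat("  top:", paste(utils::head(x$genes, 8), collapse = ", "),
        if (x$n > 8) "...", "\n")
  invisible(x)
}

#' Differentially-expressed gene universe
#'
#' Defines the DE universe as the genes whose posterior probability of the
#' all-equal pattern falls below a threshold, i.e. genes with appreciable
#' posterior evidence of any expression difference across conditions.
#' Requires the all-equal pattern among the fitted patterns.
#'
#' @param fit a fitted [ebpat()] model.
#' @param threshold maximum PP(all-equal) for a gene to count as
#'   differentially expressed (default 0.05).
#' @param ee_pattern name of the all-equal pattern; located automatically
#'   by default.
#' @return Character vector of DE gene identifiers.
#' @export
de_universe <- function(fit, threshold = 0.05, ee_pattern = NULL) {
  stopifnot(inherits(fit, "ebpat"))
  if (is.null(ee_pattern)) {
    idx <- which(vapply(fit$patterns, function(p) p$n_blocks == 1L,
                        logical(1)))
    if (length(idx) == 0L)
      stop("no all-equal pattern among the fitted patterns", call. = FALSE)
    ee_pattern <- names(fit$mixture)[idx[1L]]
  }
  pp <- fit$posterior[, ee_pattern]
  rownames(fit$posterior)[pp < threshold]
}
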