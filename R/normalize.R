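#' Median-of-ratios size factors
#'
#' Per-sample library-size factors computed by the median-of-ratios rule:
#' for each sample, the factor is the median across reference genes of the
#' ratio of that sample's count to the gene's geometric mean across
#' samples.  Reference genes are rows with no zero count (the geometric
#' mean of a row containing a zero is zero and its log undefined).
#' Normalized counts are `counts / size factor`, column-wise.
#'
#' @param counts integer matrix, genes in rows, samples in columns.
#' @return Named numeric vector of strictly positive size factors, one per
#'   sample (class `"numeric"`, names from `colnames(counts)`).
#' @examples
#' x <- matrix(rpois(30, 20) + 1, nrow = 10)
#' median_ratio_size_factors(x)
#' @export
median_ratio_size_factors <- function(counts) {
  counts <- as_count_matrix(counts)
  ref <- rowSums(counts == 0) == 0
  if (!any(ref))
    stop("no gene has positive counts in every sample; supply a matrix ",
         "with at least one all-positive row or pre-filter to a ",
         "pseudo-reference gene set", call. = FALSE)
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- apply(logc, 2, function(lc) exp(stats::median(lc - loggeo)))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("size factor computation produced non-positive values",
         call. = FALSE)
  names(sf) <- colnames(counts)
  sf
}

#' Normalized per-condition mean counts
#'
#' Divides each sample's counts by its size factor and averages the
#' normalized counts over the replicates of each condition, giving the
#' per-gene condition means (mu1 ... muK) that the ordering gate operates
#' on.  Values are kept at full precision; round only at output.
#'
#' @param counts integer matrix, genes x samples.
#' @param factors per-sample size factors, as from
#'   [median_ratio_size_factors()]; defaults to computing them.
#' @param condition_map factor or character vector assigning each sample
#'   (column) to a condition, or a named vector keyed by sample name.
#' @return Numeric matrix, genes x conditions, columns in the order the
#'   conditions first appear in `condition_map` (or factor level order).
#' @examples
#' x <- matrix(rpois(40, 50) + 1, nrow = 10,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' condition_means(x, condition_map = c("A", "A", "B", "B"))
#' @export
condition_means <- function(counts, factors = NULL, condition_map) {
  counts <- as_count_matrix(counts)
  if (is.null(factors)) factors <- median_ratio_size_factors(counts)
  cond <- align_condition_map(condition_map, counts)
  if (length(factors) != ncol(counts))
    stop("'factors' must have one entry per sample", call. = FALSE)
  norm <- sweep(counts, 2, factors, "/")
  levs <- levels(cond)
  mu <- sapply(levs, function(k)
    rowMeans(norm[, cond == k, drop = FALSE]))
  mu <- matrix(mu, nrow = nrow(counts),
               dimnames = list(rownames(counts), levs))
  mu
}

# coerce/validate a genes-x-samples count matrix
as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix (genes x samples)",
         call. = FALSE)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("'counts' must contain non-negative integers", call. = FALSE)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  counts
}

# sample -> condition map as a factor aligned with the matrix columns,
# levels in order of first appearance
align_condition_map <- function(condition_map, counts) {
  cm <- condition_map
  if (!is.null(names(cm)) && !is.null(colnames(counts))) {
    missing <- setdiff(colnames(counts), names(cm))
    if (length(missing))
      stop("samples missing from condition map: ",
           paste(missing, collapse = ", "), call. = FALSE)
    cm <- cm[colnames(counts)]
  }
  if (length(cm) != ncol(counts))
    stop("condition map must cover every sample", call. = FALSE)
  if (anyNA(cm)) stop("condition map contains NA", call. = FALSE)
  if (is.factor(cm)) cm <- droplevels(cm)
  else cm <- factor(cm, levels = unique(as.character(cm)))
  if (any(table(cm) == 0))
    stop("every condition needs at least one sample", call. = FALSE)
  cm
}
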