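#' Expression pattern specifications
#'
#' An expression pattern is a partition of the condition labels into
#' equality blocks: conditions in the same block share a mean, conditions
#' in different blocks differ.  For five conditions there are 52 (the Bell
#' number B5) possible patterns; the classic six-pattern screen uses the
#' subset `"p1_p6"` (see [enumerate_patterns()]).
#'
#' @param assign integer vector, one entry per condition, giving the block
#'   each condition belongs to.  Canonicalised internally to restricted
#'   growth form (first block seen is 1, next new block 2, ...), so
#'   `c(2, 2, 1)` and `c(1, 1, 2)` describe the same pattern.
#' @param labels condition labels; defaults to `names(assign)` or
#'   `"C1"..."Ck"`.
#' @param name display name; defaults to a block notation such as
#'   `"{A,B}{C}"`.
#' @param ordering how a simulator should orient unequal block means:
#'   `"none"` (random assignment of levels to blocks), `"increasing"` or
#'   `"decreasing"` along the block index.  Ignored by inference.
#' @return An object of class `"pattern_spec"` with elements `assign`
#'   (named integer vector), `labels`, `name`, `ordering` and `n_blocks`.
#' @examples
#' pattern_spec(c(A = 1, B = 1, C = 2))
#' pattern_all_unequal(c("OV90", "OVCAR4", "OVCAR3"), ordering = "increasing")
#' @export
pattern_spec <- function(assign, labels = NULL, name = NULL,
                         ordering = c("none", "increasing", "decreasing")) {
  ordering <- match.arg(ordering)
  if (length(assign) < 1L)
    stop("a pattern needs at least one condition", call. = FALSE)
  if (is.null(labels)) labels <- names(assign)
  assign <- as.integer(assign)
  if (anyNA(assign))
    stop("block assignments must be integers", call. = FALSE)
  if (is.null(labels)) labels <- paste0("C", seq_along(assign))
  if (length(labels) != length(assign))
    stop("'labels' and 'assign' lengths differ", call. = FALSE)
  if (anyDuplicated(labels))
    stop("condition labels must be distinct", call. = FALSE)
  assign <- canonical_rgs(assign)
  names(assign) <- labels
  if (is.null(name)) name <- pattern_block_name(assign)
  structure(
    list(assign = assign, labels = labels, name = name,
         ordering = ordering, n_blocks = max(assign)),
    class = "pattern_spec"
  )
}

# restricted-growth canonical form: relabel blocks in order of first appearance
canonical_rgs <- function(assign) {
  match(assign, unique(assign))
}

pattern_block_name <- function(assign) {
  blocks <- split(names(assign), assign)
  paste0(vapply(blocks, function(b) paste0("{", paste(b, collapse = ","), "}"),
                character(1)), collapse = "")
}

#' @export
print.pattern_spec <- function(x, ...) {
  cat("Expression pattern ", x$name, "  (", x$n_blocks, " block",
      if (x$n_blocks > 1) "s", ")\n", sep = "")
  if (x$ordering != "none")
    cat("  simulated block means:", x$ordering, "\n")
  invisible(x)
}

#' @export
format.pattern_spec <- function(x, ...) x$name

#' @rdname pattern_spec
#' @export
pattern_all_equal <- function(labels, name = "EE") {
  pattern_spec(rep(1L, length(labels)), labels = labels, name = name)
}

#' @rdname pattern_spec
#' @export
pattern_all_unequal <- function(labels, name = "DE",
                                ordering = c("none", "increasing",
                                             "decreasing")) {
  pattern_spec(seq_along(labels), labels = labels, name = name,
               ordering = match.arg(ordering))
}

#' Enumerate expression patterns
#'
#' Enumerates all partitions of `n_conditions` condition labels into
#' equality blocks (all set partitions, counted by the Bell numbers:
#' 2 patterns for two conditions, 5 for three, 52 for five), or a named
#' restricted subset.
#'
#' The restriction `"p1_p6"` is available for exactly five conditions and
#' returns the six patterns of the classic five-cell-line screen:
#' \describe{
#'   \item{P1}{all means unequal}
#'   \item{P2}{conditions 1,2 equal; 3, 4, 5 each distinct}
#'   \item{P3}{conditions 2,3 equal; 1, 4, 5 each distinct}
#'   \item{P4}{conditions 3,4 equal; 1, 2, 5 each distinct}
#'   \item{P5}{conditions 4,5 equal; 1, 2, 3 each distinct}
#'   \item{P6}{conditions 1,2,3 equal and 4,5 equal, the two blocks differing}
#' }
#'
#' @param n_conditions number of conditions (>= 1).
#' @param restriction `NULL` for the full enumeration, or `"p1_p6"`.
#' @param labels optional condition labels (length `n_conditions`).
#' @return A list of [pattern_spec()] objects.
#' @examples
#' length(enumerate_patterns(3))            # 5
#' length(enumerate_patterns(5))            # 52
#' names5 <- c("OV90", "OVCAR4", "OVCAR3", "OVCAR5", "OVCA432")
#' sapply(enumerate_patterns(5, "p1_p6", names5), format)
#' @export
enumerate_patterns <- function(n_conditions, restriction = NULL,
                               labels = NULL) {
  n_conditions <- as.integer(n_conditions)
  if (is.na(n_conditions) || n_conditions < 1L)
    stop("'n_conditions' must be a positive integer", call. = FALSE)
  if (is.null(labels)) labels <- paste0("C", seq_len(n_conditions))
  if (length(labels) != n_conditions)
    stop("'labels' must have length n_conditions", call. = FALSE)

  if (!is.null(restriction)) {
    if (!identical(restriction, "p1_p6"))
      stop("unknown restriction: ", restriction, call. = FALSE)
    if (n_conditions != 5L)
      stop("restriction 'p1_p6' requires exactly 5 conditions",
           call. = FALSE)
    specs <- list(
      P1 = c(1L, 2L, 3L, 4L, 5L),
      P2 = c(1L, 1L, 2L, 3L, 4L),
      P3 = c(1L, 2L, 2L, 3L, 4L),
      P4 = c(1L, 2L, 3L, 3L, 4L),
      P5 = c(1L, 2L, 3L, 4L, 4L),
      P6 = c(1L, 1L, 1L, 2L, 2L)
    )
    return(mapply(function(a, nm) pattern_spec(a, labels = labels, name = nm),
                  specs, names(specs), SIMPLIFY = FALSE))
  }

  parts <- restricted_growth_strings(n_conditions)
  out <- lapply(parts, pattern_spec, labels = labels)
  names(out) <- vapply(out, function(p) p$name, character(1))
  out
}

# all restricted growth strings of length n (one per set partition)
restricted_growth_strings <- function(n) {
  out <- vector("list", 0L)
  recurse <- function(prefix, maxb) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (b in seq_len(maxb + 1L))
      recurse(c(prefix, b), max(maxb, b))
  }
  recurse(integer(0), 0L)
  out
}

# locate a pattern (by name or spec) within a fitted pattern list
match_pattern <- function(pattern, patterns) {
  nms <- vapply(patterns, function(p) p$name, character(1))
  if (inherits(pattern, "pattern_spec")) {
    hit <- which(vapply(patterns, function(p)
      identical(unname(p$assign), unname(pattern$assign)), logical(1)))
    if (length(hit) == 0L)
      stop("pattern ", pattern$name, " is not among the fitted patterns",
           call. = FALSE)
    return(hit[1L])
  }
  hit <- match(as.character(pattern), nms)
  if (is.na(hit))
    stop("pattern '", pattern, "' is not among the fitted patterns ",
         "(available: ", paste(nms, collapse = ", "), ")", call. = FALSE)
  hit
}
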