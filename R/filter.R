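#' Read an annotation table
#'
#' Tab-delimited annotation table with columns `symbol`, `relevance`
#' (link to monocyte/macrophage biology or the tumor microenvironment),
#' `secreted` (produces a soluble factor) and free-text `tags`.  Flags
#' are parsed as logical.
#'
#' @param path file path.
#' @return data.frame with unique, upper-cased symbols.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("symbol", "relevance", "secreted")
  if (!all(need %in% names(ann)))
    stop("annotation table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ann$symbol <- toupper(ann$symbol)
  if (anyDuplicated(ann$symbol))
    stop("annotation symbols must be unique", call. = FALSE)
  ann$relevance <- as.logical(ann$relevance)
  ann$secreted <- as.logical(ann$secreted)
  if (!"tags" %in% names(ann)) ann$tags <- ""
  ann
}

#' Annotation filter for candidate genes
#'
#' Joins a gene list against an annotation table (case-insensitively, on
#' canonical upper-cased symbols) and keeps the genes for which every
#' required flag is `TRUE`.  Genes absent from the annotation table are
#' excluded with a warning — absence of evidence is treated as failure,
#' and is distinguished from an empty annotation table, which is an
#' error.
#'
#' @param genes character vector of gene symbols.
#' @param annotations data.frame as from [read_annotations()] (columns
#'   `symbol` and one logical column per flag).
#' @param require character vector of flag column names that must all be
#'   `TRUE` (non-empty; default `"secreted"`).
#' @param means optional genes x conditions matrix; matched rows are
#'   appended to the output.
#' @return data.frame (the candidate table): `symbol`, the flag columns,
#'   `tags` if present, and the condition-mean columns when `means` is
#'   given.  Zero rows if nothing passes.
#' @examples
#' ann <- data.frame(symbol = c("TGFA", "LIF", "ACTB"),
#'                   relevance = TRUE, secreted = c(TRUE, TRUE, FALSE))
#' annotate_and_filter(c("TGFA", "LIF", "ACTB"), ann)
#' @export
annotate_and_filter <- function(genes, annotations, require = "secreted",
                                means = NULL) {
  if (length(require) == 0L)
    stop("'require' must name at least one flag", call. = FALSE)
  if (is.null(annotations) || nrow(annotations) == 0L)
    stop("empty annotation table: supply curation evidence before ",
         "filtering (an empty table is not 'no gene passes')",
         call. = FALSE)
  if (!all(require %in% names(annotations)))
    stop("annotation table lacks required flag column(s): ",
         paste(setdiff(require, names(annotations)), collapse = ", "),
         call. = FALSE)
  annotations$symbol <- toupper(annotations$symbol)
  genes_canon <- toupper(genes)
  hit <- match(genes_canon, annotations$symbol)
  if (anyNA(hit) && length(genes)) {
    warning("excluded (no annotation record): ",
            paste(genes[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  keep <- !is.na(hit)
  ann <- annotations[hit[keep], , drop = FALSE]
  flags_ok <- if (nrow(ann)) {
    Reduce(`&`, lapply(require, function(f) ann[[f]] %in% TRUE))
  } else logical(0)
  out <- ann[flags_ok, , drop = FALSE]
  out <- cbind(data.frame(symbol = genes[keep][flags_ok],
                          stringsAsFactors = FALSE),
               out[, setdiff(names(out), "symbol"), drop = FALSE])
  rownames(out) <- NULL
  if (!is.null(means) && nrow(out)) {
    idx <- match(toupper(out$symbol), toupper(rownames(means)))
    mu <- means[idx, , drop = FALSE]
    colnames(mu) <- paste0("mean_", colnames(mu))
    out <- cbind(out, as.data.frame(mu, row.names = NULL))
  }
  out
}
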