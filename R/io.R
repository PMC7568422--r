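#' Read and write count matrices and their sidecars
#'
#' Count matrices are tab-delimited text: a `gene` identifier column
#' followed by one integer column per sample.  The condition map is a
#' two-column tab-delimited file (`sample`, `condition`).  Simulation
#' truth is written as a tab-delimited sidecar (gene, true pattern, true
#' condition means); simulation configurations round-trip through YAML.
#'
#' @param path file path.
#' @return `read_counts()`: integer matrix with gene rownames.
#'   `read_condition_map()`: named character vector, sample to condition.
#' @name count_io
NULL

#' @rdname count_io
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "gene")
    stop("count file must have a leading 'gene' column", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  as_count_matrix(m)
}

#' @rdname count_io
#' @param counts integer matrix, genes x samples.
#' @export
write_counts <- function(counts, path) {
  counts <- as_count_matrix(counts)
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname count_io
#' @export
read_condition_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% names(df)))
    stop("condition map needs columns 'sample' and 'condition'",
         call. = FALSE)
  stats::setNames(df$condition, df$sample)
}

#' @rdname count_io
#' @param condition_map named vector, sample to condition.
#' @export
write_condition_map <- function(condition_map, path) {
  utils::write.table(
    data.frame(sample = names(condition_map),
               condition = as.character(condition_map)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname count_io
#' @param sim an `"ebpat_sim"` object from [simulate_counts()].
#' @export
write_sim_truth <- function(sim, path) {
  stopifnot(inherits(sim, "ebpat_sim"))
  df <- data.frame(gene = rownames(sim$counts),
                   pattern = unname(sim$truth$pattern),
                   dispersion = unname(sim$truth$dispersion),
                   sim$truth$means, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname count_io
#' @param config a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  lst <- unclass(config)
  lst$patterns <- lapply(config$patterns, function(p)
    list(name = p$name, assign = as.integer(p$assign),
         ordering = p$ordering))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname count_io
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  pats <- lapply(lst$patterns, function(p)
    pattern_spec(p$assign, labels = lst$conditions, name = p$name,
                 ordering = p$ordering))
  names(pats) <- vapply(pats, function(p) p$name, character(1))
  sim_config(n_genes = lst$n_genes, conditions = lst$conditions,
             replicates_per_condition = lst$replicates_per_condition,
             patterns = pats, proportions = lst$proportions,
             mean_log_range = lst$mean_log_range,
             dispersion_shape = lst$dispersion_shape,
             dispersion_scale = lst$dispersion_scale,
             size_factor_range = lst$size_factor_range,
             effect_size_min = lst$effect_size_min,
             seed = lst$seed)
}
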