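#' Run the full candidate-factor screen
#'
#' End-to-end orchestration of the screen: median-of-ratios
#' normalization, empirical-Bayes pattern fit, posterior-probability FDR
#' selection of the target pattern (intersected with the
#' differentially-expressed universe when the all-equal pattern is
#' fitted), the phenotype-derived ordering gate, and the annotation
#' filter.  Every stage writes a tab-delimited file under `out_dir`, and
#' a JSON manifest records the gene count at every funnel stage together
#' with all parameters, so re-running with identical inputs reproduces
#' identical outputs.
#'
#' @param counts count matrix or path to a tab-delimited count file
#'   (see [read_counts()]).
#' @param condition_map sample-to-condition assignment (vector, or path
#'   to a two-column file).
#' @param annotations annotation data.frame or path (see
#'   [read_annotations()]); `NULL` skips the annotation stage.
#' @param phenotype phenotype data.frame or path (columns `donor`,
#'   `condition`, `marker`, `count`); when supplied, one monotone
#'   constraint is derived per marker present and added to `constraints`.
#' @param out_dir output directory (created if needed); `NULL` disables
#'   file output.
#' @param patterns patterns to fit (default as in [ebpat()]).
#' @param target_pattern pattern whose posterior drives selection;
#'   default: the fitted pattern with the most blocks (all-unequal).
#' @param fdr_level nominal FDR level (default 0.05).
#' @param de_threshold PP(all-equal) cutoff defining the DE universe
#'   (default 0.05); ignored when no all-equal pattern is fitted.
#' @param constraints ordering constraints: a list of
#'   `"ordering_constraint"` objects, preset names, or chain strings.
#'   Empty together with no phenotype = gate disabled (all selected genes
#'   pass).
#' @param gate_mode `"any"` (pass at least one constraint) or `"all"`.
#' @param rel_tol relative tolerance applied to constraints given by
#'   name/string.
#' @param require annotation flags that must be `TRUE` (default
#'   `"secreted"`).
#' @param seed integer seed recorded in the manifest (the pipeline itself
#'   is deterministic; the seed also seeds any upstream simulation reruns).
#' @param verbose print stage progress.
#' @return The run manifest (class `"ebpat_manifest"`): a list with
#'   `funnel` (named gene counts: input, nonzero, de_universe, selected,
#'   gated, candidates), `parameters`, `estimated_fdr`, `candidates`
#'   (final symbols) and `files` (paths written).
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 300, seed = 11))
#' ann <- data.frame(symbol = rownames(sim$counts)[1:20],
#'                   relevance = TRUE, secreted = TRUE)
#' mf <- run_pipeline(sim$counts, sim$condition_map, annotations = ann,
#'                    out_dir = NULL, constraints = list())
#' mf$funnel
#' @export
run_pipeline <- function(counts, condition_map, annotations = NULL,
                         phenotype = NULL, out_dir = NULL,
                         patterns = NULL, target_pattern = NULL,
                         fdr_level = 0.05, de_threshold = 0.05,
                         constraints = list("c1_main", "c2_main"),
                         gate_mode = "any", rel_tol = 0,
                         require = "secreted", seed = 1L,
                         verbose = FALSE) {
  if (fdr_level <= 0 || fdr_level >= 1)
    stop("'fdr_level' must be in (0, 1)", call. = FALSE)
  say <- function(...) if (verbose) message("[ebpat] ", ...)

  if (is.character(counts) && length(counts) == 1L)
    counts <- read_counts(counts)
  counts <- as_count_matrix(counts)
  if (is.character(condition_map) && length(condition_map) == 1L &&
      file.exists(condition_map))
    condition_map <- read_condition_map(condition_map)
  if (is.character(annotations) && length(annotations) == 1L)
    annotations <- read_annotations(annotations)
  if (is.character(phenotype) && length(phenotype) == 1L)
    phenotype <- utils::read.delim(phenotype, stringsAsFactors = FALSE)

  n_input <- nrow(counts)

  say("normalize + fit")
  fit <- ebpat(counts, condition_map, patterns = patterns)
  n_fit <- nrow(fit$posterior)

  if (is.null(target_pattern)) {
    nb <- vapply(fit$patterns, function(p) p$n_blocks, integer(1))
    target_pattern <- names(fit$mixture)[which.max(nb)]
  }

  has_ee <- any(vapply(fit$patterns, function(p) p$n_blocks == 1L,
                       logical(1)))
  de <- if (has_ee) de_universe(fit, threshold = de_threshold)
        else rownames(fit$posterior)

  say("FDR selection at level ", fdr_level)
  sel <- fdr_select(fit, target_pattern, fdr_level)
  selected <- intersect(sel$genes, de)

  # ordering gate: presets/chains plus phenotype-derived constraints
  cons <- lapply(constraints, function(cs) {
    if (inherits(cs, "ordering_constraint")) return(cs)
    if (is.character(cs) && cs %in% c("c1_main", "c2_main",
                                      "c1_supp", "c2_supp"))
      return(constraint_preset(cs, rel_tol = rel_tol))
    parse_constraint(cs, rel_tol = rel_tol)
  })
  if (!is.null(phenotype)) {
    for (mk in unique(phenotype$marker))
      cons <- c(cons, list(phenotype_constraint(phenotype, mk,
                                                rel_tol = rel_tol)))
  }
  if (length(cons)) {
    say("ordering gate (", length(cons), " constraint(s), mode ",
        gate_mode, ")")
    gate <- apply_gate(selected, fit$condition_means, cons,
                       mode = gate_mode)
    gated <- gate$genes
  } else {
    gate <- NULL
    gated <- selected
  }

  if (!is.null(annotations)) {
    say("annotation filter (require: ", paste(require, collapse = ", "),
        ")")
    cand <- annotate_and_filter(gated, annotations, require = require,
                                means = fit$condition_means)
  } else {
    cand <- data.frame(symbol = gated, stringsAsFactors = FALSE)
  }

  funnel <- c(input = n_input, nonzero = n_fit,
              de_universe = length(de), selected = length(selected),
              gated = length(gated), candidates = nrow(cand))

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    # manifest records file names relative to out_dir, so identical runs
    # in different directories produce byte-identical manifests
    wt <- function(df, fname) {
      utils::write.table(df, file.path(out_dir, fname), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      fname
    }
    files <- c(
      size_factors = wt(data.frame(sample = names(fit$size_factors),
                                   size_factor = fit$size_factors),
                        "size_factors.tsv"),
      condition_means = wt(data.frame(gene = rownames(fit$condition_means),
                                      fit$condition_means,
                                      check.names = FALSE),
                           "condition_means.tsv"),
      posterior = wt(data.frame(gene = rownames(fit$posterior),
                                fit$posterior,
                                map = unname(fit$map),
                                check.names = FALSE),
                     "posterior.tsv"),
      selected = wt(data.frame(gene = selected), "selected.tsv"),
      candidates = wt(cand, "candidates.tsv"))
    if (!is.null(gate))
      files <- c(files, gate_report = wt(gate$report, "gate_report.tsv"))
  }

  manifest <- structure(list(
    funnel = funnel,
    parameters = list(
      patterns = names(fit$mixture),
      target_pattern = sel$target_pattern,
      fdr_level = fdr_level,
      de_threshold = if (has_ee) de_threshold else NA,
      constraints = vapply(cons, format, character(1)),
      gate_mode = gate_mode, rel_tol = rel_tol,
      require = require,
      alpha = fit$alpha, beta = fit$beta,
      mixture = as.list(fit$mixture),
      converged = fit$converged,
      seed = as.integer(seed)
    ),
    estimated_fdr = sel$estimated_fdr,
    candidates = cand$symbol,
    files = as.list(files)
  ), class = "ebpat_manifest")

  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(manifest),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest$files$manifest <- "manifest.json"
    manifest$out_dir <- out_dir
  }
  manifest
}

#' @export
print.ebpat_manifest <- function(x, ...) {
  cat("Candidate-factor screen manifest\n")
  cat("  funnel:", paste(sprintf("%s=%d", names(x$funnel), x$funnel),
                         collapse = " -> "), "\n")
  cat(sprintf("  estimated FDR of selection: %.4g\n", x$estimated_fdr))
  if (length(x$candidates))
    cat("  candidates:", paste(x$candidates, collapse = ", "), "\n")
  invisible(x)
}
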