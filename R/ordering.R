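#' Parse an ordering constraint
#'
#' An ordering constraint is a chain of relations over condition means,
#' e.g. `"OV90<=OVCAR4<=OVCAR3<=OVCAR5<=OVCA432"`: an ordered list of
#' condition labels joined by `<=`, `>=` or `=`.  Relations are evaluated
#' with a relative tolerance: `a <= b` passes iff
#' `a <= b * (1 + rel_tol) + abs_floor`, and `a = b` iff
#' `|a - b| <= rel_tol * max(a, b) + abs_floor`.  With `strict = TRUE`,
#' `a <= b` additionally requires `b` to exceed the tolerance band
#' (`b > a * (1 + rel_tol) + abs_floor`), which expresses strict
#' inequalities such as `mu1 = mu2 = mu3 < mu4 < mu5`.
#'
#' @param spec constraint text, or a preset name understood by
#'   [constraint_preset()].
#' @param rel_tol relative tolerance (>= 0; 0 = strict comparison).
#' @param abs_floor absolute tolerance floor, in normalized count units.
#' @param strict whether `<=`/`>=` exclude equality beyond tolerance.
#' @param name optional display name.
#' @return Object of class `"ordering_constraint"`: list with `labels`,
#'   `relations` (length `length(labels) - 1`, each `"<="`, `">="` or
#'   `"="`), `rel_tol`, `abs_floor`, `strict`, `name`.  `format()`
#'   round-trips to the canonical chain text.
#' @examples
#' parse_constraint("A<=B>=C=D")
#' format(constraint_preset("c2_main"))
#' @export
parse_constraint <- function(spec, rel_tol = 0, abs_floor = 0,
                             strict = FALSE, name = NULL) {
  if (rel_tol < 0 || abs_floor < 0)
    stop("tolerances must be non-negative", call. = FALSE)
  spec <- gsub("[[:space:]]", "", spec)
  tokens <- regmatches(spec, gregexpr("<=|>=|=", spec))[[1]]
  labels <- strsplit(spec, "<=|>=|=")[[1]]
  if (length(labels) < 2L || any(!nzchar(labels)) ||
      length(tokens) != length(labels) - 1L)
    stop("malformed constraint chain: '", spec, "'", call. = FALSE)
  if (anyDuplicated(labels))
    stop("constraint labels must be distinct: '", spec, "'", call. = FALSE)
  structure(list(
    labels = labels, relations = tokens,
    rel_tol = rel_tol, abs_floor = abs_floor, strict = strict,
    name = if (is.null(name)) spec else name
  ), class = "ordering_constraint")
}

#' @export
format.ordering_constraint <- function(x, ...) {
  paste0(x$labels[1],
         paste0(x$relations, x$labels[-1], collapse = ""), collapse = "")
}

#' @export
print.ordering_constraint <- function(x, ...) {
  cat("Ordering constraint", if (x$name != format(x)) paste0("[", x$name, "]"),
      "\n  ", format(x), "\n", sep = "")
  cat(sprintf("  rel_tol = %g, abs_floor = %g, strict = %s\n",
              x$rel_tol, x$abs_floor, x$strict))
  invisible(x)
}

#' Named constraint presets
#'
#' The four directionality criteria of the five-cell-line screen, over the
#' conditions OV90, OVCAR4, OVCAR3, OVCAR5, OVCA432 (in that role order):
#' \describe{
#'   \item{c1_main}{monotone non-decreasing across all five conditions.}
#'   \item{c2_main}{non-decreasing through the fourth condition, then
#'     non-increasing.}
#'   \item{c1_supp}{first three conditions equal, then strictly
#'     increasing.}
#'   \item{c2_supp}{first three equal, strict rise to the fourth, strict
#'     fall to the fifth.}
#' }
#'
#' @param name one of `"c1_main"`, `"c2_main"`, `"c1_supp"`, `"c2_supp"`.
#' @param rel_tol,abs_floor tolerances passed to [parse_constraint()].
#' @return An `"ordering_constraint"`.
#' @export
constraint_preset <- function(name, rel_tol = 0, abs_floor = 0) {
  chains <- list(
    c1_main = list("OV90<=OVCAR4<=OVCAR3<=OVCAR5<=OVCA432", FALSE),
    c2_main = list("OV90<=OVCAR4<=OVCAR3<=OVCAR5>=OVCA432", FALSE),
    c1_supp = list("OV90=OVCAR4=OVCAR3<=OVCAR5<=OVCA432", TRUE),
    c2_supp = list("OV90=OVCAR4=OVCAR3<=OVCAR5>=OVCA432", TRUE)
  )
  if (!name %in% names(chains))
    stop("unknown preset '", name, "' (available: ",
         paste(names(chains), collapse = ", "), ")", call. = FALSE)
  ch <- chains[[name]]
  parse_constraint(ch[[1]], rel_tol = rel_tol, abs_floor = abs_floor,
                   strict = ch[[2]], name = name)
}

#' Check a gene's condition means against an ordering constraint
#'
#' @param mu named numeric vector of normalized condition means covering
#'   every label in the constraint.
#' @param constraint an [parse_constraint()] object.
#' @return List: `pass` (logical), `first_violation` (index of the first
#'   violated relation, `NA` if none), `margin` (signed amount by which
#'   the first violated relation misses, 0 if none).
#' @examples
#' tgfa <- c(OV90 = 7.34, OVCAR4 = 586.50, OVCAR3 = 870.77,
#'           OVCAR5 = 1035.11, OVCA432 = 5681.16)
#' check_ordering(tgfa, constraint_preset("c1_main"))$pass  # TRUE
#' @export
check_ordering <- function(mu, constraint) {
  stopifnot(inherits(constraint, "ordering_constraint"))
  missing <- setdiff(constraint$labels, names(mu))
  if (length(missing))
    stop("condition means missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  v <- as.numeric(mu[constraint$labels])
  rt <- constraint$rel_tol; af <- constraint$abs_floor
  first_violation <- NA_integer_
  margin <- 0
  for (j in seq_along(constraint$relations)) {
    a <- v[j]; b <- v[j + 1L]
    rel <- constraint$relations[j]
    if (rel == ">=") { tmp <- a; a <- b; b <- tmp; rel <- "<=" }
    ok <- if (rel == "=") {
      abs(a - b) <= rt * max(a, b) + af
    } else if (constraint$strict) {
      b > a * (1 + rt) + af
    } else {
      a <= b * (1 + rt) + af
    }
    if (!ok) {
      first_violation <- j
      margin <- if (rel == "=") abs(a - b) else a - b
      break
    }
  }
  list(pass = is.na(first_violation), first_violation = first_violation,
       margin = margin)
}

#' Filter genes by ordering constraints
#'
#' Applies one or more ordering constraints to the normalized condition
#' means of a set of genes, retaining genes that pass at least one
#' (`mode = "any"`, the usual either-criterion usage) or all
#' (`mode = "all"`) constraints.
#'
#' @param genes gene identifiers to test (subset of `rownames(means)`).
#' @param means genes x conditions matrix of normalized condition means.
#' @param constraints a single constraint or list of them.
#' @param mode `"any"` or `"all"`.
#' @return List with `genes` (passing subset, input order preserved) and
#'   `report`, a data.frame with one row per gene x constraint:
#'   `gene`, `constraint`, `pass`, `first_violation`, `margin`.
#' @examples
#' mu <- rbind(g1 = c(A = 1, B = 2, C = 3), g2 = c(A = 3, B = 2, C = 1))
#' apply_gate(rownames(mu), mu, parse_constraint("A<=B<=C"))$genes
#' @export
apply_gate <- function(genes, means, constraints, mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (inherits(constraints, "ordering_constraint"))
    constraints <- list(constraints)
  if (length(constraints) == 0L)
    stop("at least one constraint is required", call. = FALSE)
  bad <- setdiff(genes, rownames(means))
  if (length(bad))
    stop("genes absent from the means matrix: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  cnames <- vapply(constraints, function(cs) cs$name, character(1))
  rows <- vector("list", length(genes) * length(constraints))
  pass_mat <- matrix(FALSE, length(genes), length(constraints))
  i <- 0L
  for (gi in seq_along(genes)) {
    mu <- means[genes[gi], ]
    for (ci in seq_along(constraints)) {
      res <- check_ordering(mu, constraints[[ci]])
      pass_mat[gi, ci] <- res$pass
      i <- i + 1L
      rows[[i]] <- data.frame(gene = genes[gi], constraint = cnames[ci],
                              pass = res$pass,
                              first_violation = res$first_violation,
                              margin = res$margin,
                              stringsAsFactors = FALSE)
    }
  }
  keep <- if (mode == "any") rowSums(pass_mat) > 0
          else rowSums(pass_mat) == ncol(pass_mat)
  list(genes = genes[keep],
       report = if (i > 0) do.call(rbind, rows)
                else data.frame(gene = character(), constraint = character(),
                                pass = logical(),
                                first_violation = integer(),
                                margin = numeric()))
}

#' Derive the condition ordering from a phenotype table
#'
#' Ranks conditions by their donor-averaged mean count for a marker
#' (e.g. CD68+ macrophages per field of view), ascending.  Ties are broken
#' lexicographically and flagged with a warning.
#'
#' @param phenotype data.frame with columns `donor`, `condition`,
#'   `marker`, `count` (as from [simulate_phenotype()]).
#' @param marker marker to rank by (e.g. `"CD68"` or `"CD163"`).
#' @return Character vector of condition labels, worst to best.
#' @export
derive_condition_order <- function(phenotype, marker) {
  need <- c("donor", "condition", "marker", "count")
  if (!all(need %in% names(phenotype)))
    stop("phenotype table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ph <- phenotype[phenotype$marker == marker, , drop = FALSE]
  if (nrow(ph) == 0L)
    stop("marker '", marker, "' absent from the phenotype table",
         call. = FALSE)
  donor_means <- stats::aggregate(count ~ condition + donor, ph, mean)
  cond_means <- stats::aggregate(count ~ condition, donor_means, mean)
  if (anyDuplicated(cond_means$count))
    warning("tied condition means; ties broken lexicographically",
            call. = FALSE)
  cond_means$condition[order(cond_means$count, cond_means$condition)]
}

#' Ordering constraint from a phenotype-derived ranking
#'
#' Convenience wrapper: derives the condition ranking for a marker and
#' builds the monotone non-decreasing chain along it.
#'
#' @inheritParams derive_condition_order
#' @param rel_tol,abs_floor tolerances for the resulting constraint.
#' @return An `"ordering_constraint"` named after the marker.
#' @export
phenotype_constraint <- function(phenotype, marker, rel_tol = 0,
                                 abs_floor = 0) {
  ord <- derive_condition_order(phenotype, marker)
  parse_constraint(paste(ord, collapse = "<="), rel_tol = rel_tol,
                   abs_floor = abs_floor,
                   name = paste0("monotone_", marker))
}

#' Squared univariate correlation
#'
#' Squared Pearson correlation between a candidate feature and a response
#' (equivalently, the R-squared of the simple linear regression), with the
#' direction of association.  Undefined for a constant feature, which is
#' reported as `NA`, never as 0.
#'
#' @param feature,response numeric vectors of equal length >= 3.
#' @return List with `r2` and `direction` (+1, -1, or 0 for exactly zero
#'   covariance; `NA` when undefined).
#' @examples
#' univariate_r2(1:5, c(2, 4, 5, 4, 8))
#' @export
univariate_r2 <- function(feature, response) {
  if (length(feature) != length(response) || length(feature) < 3L)
    stop("'feature' and 'response' must have equal length >= 3",
         call. = FALSE)
  if (anyNA(feature) || anyNA(response))
    stop("missing values are not supported", call. = FALSE)
  if (stats::var(response) == 0)
    stop("'response' is constant", call. = FALSE)
  if (stats::var(feature) == 0) {
    warning("constant feature: R-squared undefined, returning NA",
            call. = FALSE)
    return(list(r2 = NA_real_, direction = NA_real_))
  }
  r <- stats::cor(feature, response)
  list(r2 = r^2, direction = sign(r))
}
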