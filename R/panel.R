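#' Construct an omics panel
#'
#' An `omics_panel` bundles the three aligned line-by-feature matrices used
#' throughout the package: gene expression (available for a subset of lines),
#' metabolite levels and agronomic traits. Expression and metabolite matrices
#' may be replicate-level, in which case row names carry a `_r<k>` suffix
#' (`L001_r1`, `L001_r2`, ...); trait rows are one per line.
#'
#' @param expression numeric matrix, (replicate) rows x genes, or `NULL`.
#' @param metabolites numeric matrix, (replicate) rows x metabolites.
#' @param traits numeric matrix, lines x traits, or `NULL`.
#' @param lines character vector of all line ids (metabolome/phenome lines).
#' @param expr_lines character vector of line ids that also carry expression;
#'   must be a subset of `lines`.
#' @param replicates integer, replicates per line in the replicate-level
#'   matrices (1 when matrices are already line-level).
#' @param gene_ranges optional genes x 2 matrix (columns `min`, `max`) of
#'   observed per-gene expression ranges across `expr_lines`.
#' @return an object of class `omics_panel`.
#' @export
omics_panel <- function(expression, metabolites, traits, lines,
                        expr_lines = lines, replicates = 1L,
                        gene_ranges = NULL) {
  if (!all(expr_lines %in% lines))
    stopf("expr_lines must be a subset of lines")
  if (anyDuplicated(lines)) stopf("duplicated line ids")
  for (m in list(expression, metabolites, traits)) {
    if (!is.null(m) && anyDuplicated(colnames(m)))
      stopf("duplicated feature ids in a panel matrix")
  }
  structure(list(
    expression = expression,
    metabolites = metabolites,
    traits = traits,
    lines = lines,
    expr_lines = expr_lines,
    replicates = as.integer(replicates),
    gene_ranges = gene_ranges,
    transforms = NULL,
    report = NULL
  ), class = "omics_panel")
}

#' @export
print.omics_panel <- function(x, ...) {
  cat("omics_panel\n")
  cat(sprintf("  lines:       %d (%d with expression), %d replicate(s)\n",
              length(x$lines), length(x$expr_lines), x$replicates))
  if (!is.null(x$expression))
    cat(sprintf("  expression:  %d x %d\n", nrow(x$expression), ncol(x$expression)))
  if (!is.null(x$metabolites))
    cat(sprintf("  metabolites: %d x %d\n", nrow(x$metabolites), ncol(x$metabolites)))
  if (!is.null(x$traits))
    cat(sprintf("  traits:      %d x %d\n", nrow(x$traits), ncol(x$traits)))
  if (!is.null(x$transforms)) cat("  standardized: yes\n")
  invisible(x)
}

# line id of each replicate-level row ("L001_r2" -> "L001"; plain ids pass through)
row_line_ids <- function(rn) sub("_r[0-9]+$", "", rn)

#' Average replicate rows to one row per line
#'
#' Rows sharing a line id (after stripping the `_r<k>` suffix) are averaged;
#' missing cells are ignored in the mean. Matrices already at line level are
#' returned unchanged.
#'
#' @param panel an [omics_panel()].
#' @return the panel with line-level `expression` and `metabolites` matrices
#'   and `replicates = 1`.
#' @export
average_replicates <- function(panel) {
  avg <- function(m) {
    if (is.null(m)) return(NULL)
    ids <- row_line_ids(rownames(m))
    if (!anyDuplicated(ids)) {
      rownames(m) <- ids
      return(m)
    }
    out <- rowsum(ifelse(is.na(m), 0, m), ids, na.rm = FALSE)
    n <- rowsum((!is.na(m)) * 1, ids)
    out <- out / n
    out[n == 0] <- NA_real_
    out[order(match(rownames(out), unique(ids))), , drop = FALSE]
  }
  panel$expression <- avg(panel$expression)
  panel$metabolites <- avg(panel$metabolites)
  panel$replicates <- 1L
  panel
}

# line-level matrices restricted to a layer's lines, features as columns
layer_matrices <- function(panel, layer = c("gene", "metabolite", "trait")) {
  layer <- match.arg(layer)
  p <- if (panel$replicates > 1L) average_replicates(panel) else panel
  switch(layer,
    gene = {
      x <- p$expression[p$expr_lines, , drop = FALSE]
      list(targets = x, predictors = x)
    },
    metabolite = list(
      targets = p$metabolites[p$expr_lines, , drop = FALSE],
      predictors = p$expression[p$expr_lines, , drop = FALSE]
    ),
    trait = list(
      targets = p$traits[p$lines, , drop = FALSE],
      predictors = p$metabolites[p$lines, , drop = FALSE]
    )
  )
}
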