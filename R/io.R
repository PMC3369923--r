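#' Read a line-by-feature matrix from TSV/CSV
#'
#' Expects a header row of feature ids and a first column of line ids
#' (`.csv` files are comma-separated, everything else tab-separated).
#' Missing cells are encoded as `NA`. Duplicate line or feature ids and
#' ragged rows are rejected with informative errors.
#'
#' @param path file path.
#' @return numeric matrix with line ids as row names.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  nf <- count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(unique(nf)) > 1)
    stopf("ragged file %s: row %d has %d fields, expected %d", path,
          which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1])
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stopf("duplicate line id '%s' in %s", ids[duplicated(ids)][1], path)
  feats <- colnames(df)[-1]
  if (anyDuplicated(feats))
    stopf("duplicate feature id '%s' in %s", feats[duplicated(feats)][1], path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a line-by-feature matrix to TSV/CSV
#'
#' Inverse of [read_matrix()]; round-trips numeric values to better than
#' 1e-12 relative precision. Missing cells are written as `NA`.
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path (`.csv` for comma-separated).
#' @param id_name header for the line-id column.
#' @export
write_matrix <- function(mat, path, id_name = "line") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(rownames(mat), format(mat, digits = 17, trim = TRUE,
                                         scientific = NA),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_name, colnames(mat))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an omics panel to a directory
#'
#' Emits `expression.tsv`, `metabolites.tsv`, `traits.tsv` and a
#' `panel.json` metadata file (line ids, nesting, replicates, gene ranges).
#'
#' @param panel an [omics_panel()].
#' @param dir output directory (created if needed).
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("expression", "metabolites", "traits")) {
    if (!is.null(panel[[nm]]))
      write_matrix(panel[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  meta <- list(schema = "omicforge_panel/1", lines = panel$lines,
               expr_lines = panel$expr_lines, replicates = panel$replicates)
  if (!is.null(panel$gene_ranges))
    meta$gene_ranges <- list(gene = rownames(panel$gene_ranges),
                             min = unname(panel$gene_ranges[, "min"]),
                             max = unname(panel$gene_ranges[, "max"]))
  jsonlite::write_json(meta, file.path(dir, "panel.json"), digits = I(17),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read an omics panel written by [write_panel()]
#'
#' @param dir panel directory.
#' @return an [omics_panel()].
#' @export
read_panel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "panel.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$schema, "omicforge_panel/1"))
    stopf("unsupported panel schema: %s", meta$schema %||% "<none>")
  rd <- function(nm) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    if (file.exists(f)) read_matrix(f) else NULL
  }
  gr <- NULL
  if (!is.null(meta$gene_ranges)) {
    gr <- cbind(min = meta$gene_ranges$min, max = meta$gene_ranges$max)
    rownames(gr) <- meta$gene_ranges$gene
  }
  omics_panel(expression = rd("expression"), metabolites = rd("metabolites"),
              traits = rd("traits"), lines = meta$lines,
              expr_lines = meta$expr_lines, replicates = meta$replicates,
              gene_ranges = gr)
}

layer_to_json <- function(model) {
  if (is.null(model)) return(NULL)
  e <- model_edges(model, model$layer)
  out <- list(layer = model$layer,
              targets = rownames(model$coefficients),
              predictors = colnames(model$coefficients),
              edges = e,
              intercepts = unname(model$intercepts),
              calibration = model$calibration,
              delta = model$delta)
  if (!is.null(model$ranges))
    out$ranges <- list(gene = rownames(model$ranges),
                       min = unname(model$ranges[, "min"]),
                       max = unname(model$ranges[, "max"]))
  if (!is.null(model$fit))
    out$fit <- list(z_star = model$fit$z_star,
                    t_lasso = unname(model$fit$t_lasso),
                    bins = model$fit$bins,
                    training_r = unname(model$fit$training_r))
  out
}

layer_from_json <- function(x) {
  if (is.null(x)) return(NULL)
  nt <- length(x$targets); np <- length(x$predictors)
  e <- x$edges
  tg <- as.character(unlist(e$target) %||% character(0))
  pr <- as.character(unlist(e$predictor) %||% character(0))
  cf <- as.numeric(unlist(e$coefficient) %||% numeric(0))
  C <- sparseMatrix(i = match(tg, x$targets), j = match(pr, x$predictors),
                    x = cf, dims = c(nt, np),
                    dimnames = list(x$targets, x$predictors))
  ranges <- NULL
  if (!is.null(x$ranges)) {
    ranges <- cbind(min = x$ranges$min, max = x$ranges$max)
    rownames(ranges) <- x$ranges$gene
  }
  fit <- NULL
  if (!is.null(x$fit))
    fit <- list(z_star = x$fit$z_star,
                t_lasso = setNames(x$fit$t_lasso, x$targets),
                bins = x$fit$bins,
                training_r = setNames(x$fit$training_r, x$targets))
  layer_model(C, setNames(x$intercepts, x$targets), layer = x$layer,
              calibration = x$calibration, ranges = ranges, delta = x$delta,
              fit = fit)
}

#' Serialize a model stack to JSON
#'
#' Layers are written as edge lists (target, predictor, coefficient) plus
#' intercepts, calibration, gene ranges and fit metadata, under a schema
#' version. [load_model_stack()] reproduces predictions bit-identically.
#'
#' @param stack a [model_stack()].
#' @param path output file.
#' @export
save_model_stack <- function(stack, path) {
  stopifnot(inherits(stack, "model_stack"))
  obj <- list(schema = "omicforge_model/1",
              gene = layer_to_json(stack$gene),
              metabolite = layer_to_json(stack$metabolite),
              trait = layer_to_json(stack$trait),
              meta = stack$meta)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname save_model_stack
#' @return `load_model_stack()` returns the restored [model_stack()].
#' @export
load_model_stack <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "omicforge_model/1"))
    stopf("unsupported model schema '%s' (expected omicforge_model/1)",
          obj$schema %||% "<none>")
  model_stack(gene = layer_from_json(obj$gene),
              metabolite = layer_from_json(obj$metabolite),
              trait = layer_from_json(obj$trait),
              meta = as.list(obj$meta))
}
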