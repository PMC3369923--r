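#' LOWESS detrending against the panel mean profile
#'
#' Removes, for each sample (row), a locally weighted regression trend of its
#' deviation from the across-sample mean profile as a function of that mean
#' profile (an MA-style intensity-dependent correction with the mean profile
#' playing the role of the reference channel). Samples whose reference has no
#' spread (degenerate intensity axis, e.g. already-standardized data) are
#' returned unchanged.
#'
#' @param mat numeric matrix, samples (lines or replicates) x features; may
#'   contain `NA`.
#' @param span lowess smoother span in `(0, 1]`.
#' @return the detrended matrix.
#' @export
lowess_normalize <- function(mat, span = 0.3) {
  check_scalar_number(span, "span", 1e-6, 1)
  if (ncol(mat) < 10L) stopf("lowess_normalize needs at least 10 features (got %d)", ncol(mat))
  ref <- colMeans(mat, na.rm = TRUE)
  if (diff(range(ref, na.rm = TRUE)) < 1e-12) return(mat)
  out <- mat
  for (i in seq_len(nrow(mat))) {
    y <- mat[i, ] - ref
    ok <- !is.na(y) & !is.na(ref)
    if (sum(ok) < 10L) next
    fit <- lowess(ref[ok], y[ok], f = span)
    trend <- approx(fit$x, fit$y, xout = ref[ok], rule = 2, ties = mean)$y
    out[i, ok] <- mat[i, ok] - trend
  }
  out
}

#' Presence filtering with median imputation
#'
#' Keeps features observed in strictly more than `presence_fraction` of
#' samples (the ">80% of the arrays" convention at the default), then imputes
#' the surviving features' missing cells by the feature median.
#'
#' @param mat numeric matrix, samples x features, possibly with `NA`.
#' @param presence_fraction fraction in `[0, 1]`.
#' @return filtered matrix; dropped feature ids in attribute `"dropped"`.
#' @export
filter_present <- function(mat, presence_fraction = 0.8) {
  check_scalar_number(presence_fraction, "presence_fraction", 0, 1)
  present <- colMeans(!is.na(mat))
  keep <- present > presence_fraction
  dropped <- colnames(mat)[!keep]
  out <- mat[, keep, drop = FALSE]
  for (j in seq_len(ncol(out))) {
    nas <- is.na(out[, j])
    if (any(nas)) out[nas, j] <- median(out[, j], na.rm = TRUE)
  }
  attr(out, "dropped") <- dropped
  out
}

#' Mask unreliable cells by replicate coefficient of variation
#'
#' For each line x feature cell, the coefficient of variation (sd / |mean|)
#' across its replicate rows is computed; cells exceeding `cv_max` are set to
#' `NA`. Values are expected on their original (pre-log) scale, where the CV
#' is well defined.
#'
#' @param mat replicate-level matrix with `_r<k>`-suffixed row names.
#' @param cv_max CV cutoff (default 0.75, i.e. 75%); `Inf` disables masking.
#' @return the matrix with unreliable cells masked; masked-cell count in
#'   attribute `"masked"`.
#' @export
replicate_cv_filter <- function(mat, cv_max = 0.75) {
  if (!is.numeric(cv_max) || length(cv_max) != 1L || is.na(cv_max) || cv_max < 0)
    stopf("'cv_max' must be a single non-negative number (Inf disables masking)")
  ids <- row_line_ids(rownames(mat))
  if (is.null(rownames(mat)) || !anyDuplicated(ids))
    stopf("replicate_cv_filter needs >= 2 replicate rows per line (suffix '_r<k>')")
  tab <- table(ids)
  if (any(tab < 2)) stopf("line(s) with a single replicate: %s",
                          paste(names(tab)[tab < 2], collapse = ", "))
  masked <- 0L
  for (line in unique(ids)) {
    rows <- which(ids == line)
    mu <- colMeans(mat[rows, , drop = FALSE])
    sdv <- apply(mat[rows, , drop = FALSE], 2, sd)
    cv <- sdv / abs(mu)
    bad <- is.finite(cv) & cv > cv_max
    bad[!is.finite(cv) & sdv > 0] <- TRUE  # zero mean with spread: unreliable
    if (any(bad, na.rm = TRUE)) {
      mat[rows, which(bad)] <- NA_real_
      masked <- masked + sum(bad, na.rm = TRUE)
    }
  }
  attr(mat, "masked") <- masked
  mat
}

#' Standardize a matrix to per-feature z-scores
#'
#' Centers and scales each feature (column) to mean 0 and sd 1 across rows.
#' Zero-variance features are dropped with a warning and listed in the
#' attribute `"dropped"`; the centering/scaling parameters are stored in
#' attributes `"center"` and `"scale"` for [inverse_standardize()].
#'
#' @param mat numeric matrix, lines x features.
#' @return the standardized matrix.
#' @export
standardize_matrix <- function(mat) {
  ctr <- colMeans(mat, na.rm = TRUE)
  scl <- apply(mat, 2, sd, na.rm = TRUE)
  constant <- !is.finite(scl) | scl < 1e-12
  if (any(constant)) {
    warnf("dropping %d zero-variance feature(s): %s", sum(constant),
          paste(head(colnames(mat)[constant], 5), collapse = ", "))
  }
  keep <- which(!constant)
  out <- sweep(sweep(mat[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  attr(out, "center") <- ctr[keep]
  attr(out, "scale") <- scl[keep]
  attr(out, "dropped") <- colnames(mat)[constant]
  out
}

#' Invert [standardize_matrix()]
#'
#' @param mat a matrix produced by [standardize_matrix()] (or any matrix with
#'   matching columns), with `center`/`scale` supplied explicitly or as
#'   attributes.
#' @param center,scale per-feature parameters; default to the attributes.
#' @return matrix on the original scale.
#' @export
inverse_standardize <- function(mat, center = attr(mat, "center"),
                                scale = attr(mat, "scale")) {
  if (is.null(center) || is.null(scale))
    stopf("no center/scale parameters available")
  sweep(sweep(mat, 2, scale, "*"), 2, center, "+")
}

#' Standardize an omics panel
#'
#' Averages replicates, then z-scores every feature of each matrix across
#' lines. Transformation parameters are stored in the panel's `transforms`
#' field for inverse mapping; dropped constant features are recorded in the
#' panel `report`.
#'
#' @param panel an [omics_panel()].
#' @return the standardized line-level panel.
#' @export
standardize_panel <- function(panel) {
  p <- average_replicates(panel)
  tr <- list(); dropped <- list()
  for (nm in c("expression", "metabolites", "traits")) {
    if (is.null(p[[nm]])) next
    z <- standardize_matrix(p[[nm]])
    tr[[nm]] <- list(center = attr(z, "center"), scale = attr(z, "scale"))
    dropped[[nm]] <- attr(z, "dropped")
    attr(z, "center") <- attr(z, "scale") <- attr(z, "dropped") <- NULL
    p[[nm]] <- z
  }
  if (!is.null(p$expression)) {
    # observed per-gene range across the expression lines, on the working scale
    x <- p$expression[p$expr_lines, , drop = FALSE]
    p$gene_ranges <- cbind(min = apply(x, 2, min, na.rm = TRUE),
                           max = apply(x, 2, max, na.rm = TRUE))
  }
  p$transforms <- tr
  p$report <- c(p$report %||% list(), list(dropped_constant = dropped))
  p
}

#' Full preprocessing pipeline for a raw panel
#'
#' Applies, in fixed order: replicate-CV masking (pre-log scale), optional log
#' transform, LOWESS detrending against the mean profile, replicate
#' averaging, presence filtering with median imputation, and per-feature
#' z-scoring. Trait matrices (one row per line) skip the replicate steps.
#' Re-running the pipeline on its own output reproduces it (all steps are
#' no-ops on standardized, complete data).
#'
#' @param panel a raw [omics_panel()].
#' @param span lowess span (see [lowess_normalize()]).
#' @param presence_fraction presence cutoff (see [filter_present()]).
#' @param cv_max replicate CV cutoff, or `NULL` to skip masking.
#' @param log_base base for the log transform (e.g. 2 for array intensities),
#'   or `NULL` for data already on an additive scale.
#' @param lowess logical, apply LOWESS detrending.
#' @return standardized line-level panel; `panel$report` records parameters,
#'   masked-cell counts and dropped features (JSON-serializable).
#' @export
preprocess_panel <- function(panel, span = 0.3, presence_fraction = 0.8,
                             cv_max = NULL, log_base = NULL, lowess = TRUE) {
  report <- list(parameters = list(span = span,
                                   presence_fraction = presence_fraction,
                                   cv_max = cv_max, log_base = log_base,
                                   lowess = lowess),
                 order = c("cv_filter", "log", "lowess", "replicate_average",
                           "presence_filter", "zscore"))
  masked <- list(); dropped_absent <- list()
  for (nm in c("expression", "metabolites")) {
    m <- panel[[nm]]
    if (is.null(m)) next
    if (!is.null(cv_max) && panel$replicates > 1L) {
      m <- replicate_cv_filter(m, cv_max)
      masked[[nm]] <- attr(m, "masked"); attr(m, "masked") <- NULL
    }
    if (!is.null(log_base)) m <- log(m, base = log_base)
    if (lowess && ncol(m) >= 10L) m <- lowess_normalize(m, span)
    panel[[nm]] <- m
  }
  if (!is.null(panel$traits)) {
    m <- panel$traits
    if (!is.null(log_base)) m <- log(m, base = log_base)
    panel$traits <- m
  }
  panel <- average_replicates(panel)
  for (nm in c("expression", "metabolites", "traits")) {
    if (is.null(panel[[nm]])) next
    f <- filter_present(panel[[nm]], presence_fraction)
    dropped_absent[[nm]] <- attr(f, "dropped"); attr(f, "dropped") <- NULL
    panel[[nm]] <- f
  }
  report$masked_cells <- masked
  report$dropped_absent <- dropped_absent
  panel$report <- report
  standardize_panel(panel)
}
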