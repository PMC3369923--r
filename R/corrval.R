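#' Perturbation signatures of metabolites
#'
#' For every single-gene knockout / over-expression, the mean relative change
#' of each metabolite across lines is computed (change divided by the
#' metabolite's wild-type population sd). Perturbations moving a metabolite
#' by more than `+epsilon` join its positive signature set (Omega+), below
#' `-epsilon` its negative set (Omega-).
#'
#' @param stack fitted [model_stack()].
#' @param panel standardized line-level [omics_panel()].
#' @param epsilon relative-change threshold (> 0; 0.01 = the 1% convention).
#' @param metabolites optional subset of metabolite ids.
#' @param genes optional subset of gene ids to perturb.
#' @param lines optional subset of line ids.
#' @return named list of `perturbation_signature` objects: each has
#'   `metabolite`, `plus` and `minus` (character sets of `"gene:mode"` ids)
#'   and `epsilon`. The underlying perturbations x metabolites mean-change
#'   matrix is kept in the attribute `"delta"`.
#' @export
build_signatures <- function(stack, panel, epsilon = 0.01, metabolites = NULL,
                             genes = NULL, lines = NULL) {
  check_scalar_number(epsilon, "epsilon", 1e-12, Inf)
  ctx <- scan_context(stack, panel, lines)
  genes <- sort(genes %||% ctx$genes)
  mets <- metabolites %||% rownames(ctx$M)
  if (length(bad <- setdiff(mets, rownames(ctx$M))))
    stopf("unknown metabolite id(s): %s", paste(bad, collapse = ", "))
  pop_sd <- apply(ctx$M, 1, sd)
  pop_sd[pop_sd < 1e-12] <- 1
  combos <- expand.grid(mode = c("KO", "OE"), gene = genes,
                        stringsAsFactors = FALSE)[, c("gene", "mode")]
  combos <- combos[order(combos$gene, combos$mode), ]
  labels <- paste(combos$gene, combos$mode, sep = ":")
  D <- matrix(NA_real_, nrow(combos), length(mets),
              dimnames = list(labels, mets))
  for (k in seq_len(nrow(combos))) {
    cv <- clamp_value(stack, combos$gene[k], combos$mode[k])
    pl <- perturbed_layers(ctx, match(combos$gene[k], ctx$genes), cv)
    D[k, ] <- rowMeans(pl$M[mets, , drop = FALSE] - ctx$M[mets, , drop = FALSE]) /
      pop_sd[mets]
  }
  sigs <- lapply(mets, function(m) {
    structure(list(metabolite = m,
                   plus = labels[D[, m] > epsilon],
                   minus = labels[D[, m] < -epsilon],
                   epsilon = epsilon),
              class = "perturbation_signature")
  })
  names(sigs) <- mets
  attr(sigs, "delta") <- D
  sigs
}

#' @rdname build_signatures
#' @param metabolite a single metabolite id.
#' @export
build_signature <- function(stack, panel, metabolite, epsilon = 0.01,
                            genes = NULL, lines = NULL) {
  build_signatures(stack, panel, epsilon = epsilon, metabolites = metabolite,
                   genes = genes, lines = lines)[[metabolite]]
}

#' @export
print.perturbation_signature <- function(x, ...) {
  cat(sprintf("perturbation_signature [%s]: |Omega+| = %d, |Omega-| = %d (epsilon = %g)\n",
              x$metabolite, length(x$plus), length(x$minus), x$epsilon))
  invisible(x)
}

# normalized overlap of two perturbation sets
set_overlap <- function(a, b, method = c("min", "jaccard")) {
  method <- match.arg(method)
  if (!length(a) || !length(b)) return(0)
  inter <- length(intersect(a, b))
  switch(method,
         min = inter / min(length(a), length(b)),
         jaccard = inter / length(union(a, b)))
}

#' Predicted correlation between two metabolites from shared signatures
#'
#' `r_pred = S_same - S_opp`, where `S_same` is the larger normalized
#' intersection among the same-sign signature pairs (Omega+ with Omega+,
#' Omega- with Omega-) and `S_opp` the larger among the cross-sign pairs.
#' The default normalization divides by the smaller set (a subset
#' relationship scores 1); `method = "jaccard"` divides by the union.
#' Empty-set terms contribute 0; two fully empty signatures give `NA`.
#'
#' @param sig_a,sig_b `perturbation_signature` objects (same epsilon).
#' @param method `"min"` (default) or `"jaccard"`.
#' @return predicted correlation in `[-1, 1]`, or `NA`.
#' @export
predicted_correlation <- function(sig_a, sig_b, method = c("min", "jaccard")) {
  method <- match.arg(method)
  if (!isTRUE(all.equal(sig_a$epsilon, sig_b$epsilon)))
    stopf("signatures were built at different epsilon")
  if (!length(sig_a$plus) && !length(sig_a$minus) &&
      !length(sig_b$plus) && !length(sig_b$minus)) return(NA_real_)
  s_same <- max(set_overlap(sig_a$plus, sig_b$plus, method),
                set_overlap(sig_a$minus, sig_b$minus, method))
  s_opp <- max(set_overlap(sig_a$plus, sig_b$minus, method),
               set_overlap(sig_a$minus, sig_b$plus, method))
  s_same - s_opp
}

#' Predicted correlation matrix over a signature set
#'
#' @param signatures list of `perturbation_signature` (e.g.
#'   [build_signatures()]).
#' @inheritParams predicted_correlation
#' @return symmetric matrix with unit diagonal (`NA` where undefined).
#' @export
predicted_correlation_matrix <- function(signatures,
                                         method = c("min", "jaccard")) {
  method <- match.arg(method)
  n <- length(signatures)
  ids <- vapply(signatures, `[[`, character(1), "metabolite")
  R <- diag(1, n)
  dimnames(R) <- list(ids, ids)
  if (n < 2) return(R)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    R[i, j] <- R[j, i] <- predicted_correlation(signatures[[i]],
                                                signatures[[j]], method)
  }
  R
}

#' Precision, recall and F-score of predicted metabolite correlations
#'
#' A metabolite pair is "called" when its absolute correlation reaches the
#' cutoff `k` in the respective matrix. Precision is the fraction of
#' model-called pairs that are also empirically called, recall the fraction
#' of empirically called pairs recovered, and `F = 2PR/(P+R)`. Optionally
#' the comparison is restricted to pairs whose empirical `|r|` reaches
#' `min_emp_r` (dropping weakly correlated pairs from the universe).
#'
#' @param pred_matrix,emp_matrix symmetric correlation matrices with common
#'   labels.
#' @param cutoff_k correlation cutoff in `(0, 1)`.
#' @param min_emp_r optional floor on empirical `|r|` for the pair universe.
#' @return object of class `corr_comparison`: list with `precision`,
#'   `recall`, `f_score`, the cutoff and pair counts. Recall is `NA` when no
#'   pair is empirically called.
#' @export
precision_recall_f <- function(pred_matrix, emp_matrix, cutoff_k,
                               min_emp_r = NULL) {
  check_scalar_number(cutoff_k, "cutoff_k", 1e-12, 1 - 1e-12)
  ids <- intersect(rownames(pred_matrix), rownames(emp_matrix))
  if (length(ids) < 2) stopf("need at least 2 shared metabolites")
  P <- pred_matrix[ids, ids]; E <- emp_matrix[ids, ids]
  ut <- upper.tri(P)
  p <- P[ut]; e <- E[ut]
  keep <- !is.na(p) & !is.na(e)
  if (!is.null(min_emp_r)) keep <- keep & abs(e) >= min_emp_r
  p <- p[keep]; e <- e[keep]
  called_pred <- abs(p) >= cutoff_k
  called_emp <- abs(e) >= cutoff_k
  tp <- sum(called_pred & called_emp)
  prec <- if (sum(called_pred)) tp / sum(called_pred) else NA_real_
  rec <- if (sum(called_emp)) tp / sum(called_emp) else NA_real_
  f <- if (is.finite(prec) && is.finite(rec) && (prec + rec) > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  structure(list(precision = prec, recall = rec, f_score = f,
                 cutoff_k = cutoff_k, min_emp_r = min_emp_r,
                 n_pairs = length(p), n_called_pred = sum(called_pred),
                 n_called_emp = sum(called_emp)),
            class = "corr_comparison")
}

#' @export
print.corr_comparison <- function(x, ...) {
  cat(sprintf("corr_comparison at k = %.2f: P = %.3f, R = %.3f, F = %.3f (%d pairs)\n",
              x$cutoff_k, x$precision, x$recall, x$f_score, x$n_pairs))
  invisible(x)
}

#' Hierarchical clustering of metabolites by shared perturbations
#'
#' Builds the distance `1 - r_pred` from signatures (or `1 - r` from a
#' supplied correlation matrix) and clusters hierarchically. Undefined
#' distances are imputed to the maximum finite distance (flagged in the
#' attribute `"imputed_pairs"`).
#'
#' @param x a list of `perturbation_signature` or a symmetric correlation
#'   matrix.
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`, i.e. UPGMA).
#' @param method overlap normalization when `x` is a signature list.
#' @return an `hclust` tree; `as_newick()` serializes it.
#' @export
signature_dendrogram <- function(x, linkage = "average",
                                 method = c("min", "jaccard")) {
  R <- if (is.matrix(x)) x else predicted_correlation_matrix(x, method)
  if (nrow(R) < 3) stopf("need at least 3 metabolites to build a dendrogram")
  D <- 1 - R
  diag(D) <- 0
  nas <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
  if (nrow(nas)) {
    mx <- max(D, na.rm = TRUE)
    D[is.na(D)] <- mx
  }
  hc <- hclust(as.dist(D), method = linkage)
  if (nrow(nas))
    attr(hc, "imputed_pairs") <- data.frame(a = rownames(D)[nas[, 1]],
                                            b = colnames(D)[nas[, 2]])
  hc
}

#' Serialize a dendrogram to Newick
#'
#' @param hc an `hclust` tree (e.g. from [signature_dendrogram()]).
#' @param path optional file to write to.
#' @return the Newick string, invisibly when writing to a file.
#' @export
as_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries, with a one-sided
#' (upper-tail) permutation p-value obtained by relabeling one matrix. Thin
#' wrapper around [vegan::mantel()] with explicit seeding.
#'
#' @param dist_a,dist_b symmetric matrices or `dist` objects with matching
#'   labels.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutation stream.
#' @return list with `r`, `p`, `n_perm`. `r` is `NA` when either matrix is
#'   constant.
#' @export
mantel_test <- function(dist_a, dist_b, n_perm = 999L, seed = 1L) {
  da <- as.dist(dist_a); db <- as.dist(dist_b)
  if (length(da) != length(db)) stopf("distance matrices differ in size")
  if (anyNA(da) || anyNA(db))
    stopf("distance matrices contain NA; impute or drop undefined pairs first")
  if (sd(da) < 1e-15 || sd(db) < 1e-15) {
    warnf("constant distance matrix: Mantel r undefined")
    return(list(r = NA_real_, p = NA_real_, n_perm = n_perm))
  }
  res <- with_seed(seed, vegan::mantel(da, db, permutations = n_perm,
                                       method = "pearson"))
  list(r = unname(res$statistic), p = res$signif, n_perm = n_perm)
}

#' Overlap enrichment of proposed perturbations in engineered lines
#'
#' Scores how often the model's proposed (gene, mode) perturbations match
#' genes observed as direction-consistently altered in engineered lines
#' (knockout matches under-expression, over-expression matches
#' over-expression). Significance combines a Mann-Whitney U test of the
#' per-line observed overlaps against overlaps of random same-size
#' perturbation selections, and an empirical p-value for the mean overlap.
#'
#' @param proposed a [perturbation_set()] or character vector of
#'   `"gene:mode"` ids.
#' @param observed a data frame with columns `gene` and `direction`
#'   (`"up"`/`"down"`), or a list of such data frames (one per engineered
#'   line).
#' @param universe character vector of all gene ids perturbations are drawn
#'   from.
#' @param n_random number of random same-size selections.
#' @param seed RNG seed.
#' @return list with `overlap_pct` (mean across lines), `per_line`,
#'   `null_mean`, `p_utest`, `p_empirical`.
#' @export
overlap_enrichment <- function(proposed, observed, universe,
                               n_random = 1000L, seed = 1L) {
  if (inherits(proposed, "perturbation_set"))
    proposed <- paste(names(proposed), unclass(proposed), sep = ":")
  if (!length(proposed)) stopf("empty proposed perturbation set")
  if (is.data.frame(observed)) observed <- list(observed)
  prop_genes <- sub(":(KO|OE)$", "", proposed)
  if (length(bad <- setdiff(prop_genes, universe)))
    stopf("proposed gene(s) outside the universe: %s", paste(bad, collapse = ", "))
  match_pct <- function(pert_ids, obs) {
    if (!nrow(obs)) return(0)
    wanted <- ifelse(grepl(":KO$", pert_ids), "down", "up")
    genes <- sub(":(KO|OE)$", "", pert_ids)
    key_obs <- paste(obs$gene, obs$direction)
    100 * mean(paste(genes, wanted) %in% key_obs)
  }
  per_line <- vapply(observed, match_pct, numeric(1), pert_ids = proposed)
  s <- length(proposed)
  null_scores <- with_seed(seed, vapply(seq_len(n_random), function(b) {
    g <- sample(universe, s, replace = s > length(universe))
    m <- sample(c("KO", "OE"), s, replace = TRUE)
    mean(vapply(observed, match_pct, numeric(1),
                pert_ids = paste(g, m, sep = ":")))
  }, numeric(1)))
  p_utest <- tryCatch(
    wilcox.test(per_line, null_scores, alternative = "greater", exact = FALSE)$p.value,
    error = function(e) NA_real_)
  p_emp <- (1 + sum(null_scores >= mean(per_line))) / (n_random + 1)
  list(overlap_pct = mean(per_line), per_line = per_line,
       null_mean = mean(null_scores), null_sd = sd(null_scores),
       p_utest = p_utest, p_empirical = p_emp, n_random = n_random)
}
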