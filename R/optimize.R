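#' Define an objective over metabolites and/or traits
#'
#' A score is the weighted sum of the `maximize` features minus the weighted
#' sum of the `minimize` features ("balanced" weights `1/|set|` per side when
#' ids are given without weights). `mode` turns the raw combination into a
#' higher-is-better score: `"maximize"` keeps it, `"minimize"` negates it,
#' and `"target"` scores `-|value - target_value|` (tune-to-value). A
#' bi-objective couples a `secondary` spec through
#' `alpha * z(primary) + (1 - alpha) * z(secondary)`, with z-scores taken
#' relative to the wild-type population across lines; `alpha` 1 (or 0)
#' reduces exactly to the primary (secondary) spec alone.
#'
#' @param maximize,minimize feature ids (character) or named numeric weights;
#'   ids may refer to metabolites or traits.
#' @param mode `"maximize"`, `"minimize"` or `"target"`.
#' @param target_value required when `mode = "target"`.
#' @param secondary optional second `objective_spec` for a bi-objective.
#' @param alpha trade-off weight in `[0, 1]` for the bi-objective.
#' @return an object of class `objective_spec`.
#' @export
objective_spec <- function(maximize = NULL, minimize = NULL,
                           mode = c("maximize", "minimize", "target"),
                           target_value = NULL, secondary = NULL,
                           alpha = 0.5) {
  mode <- match.arg(mode)
  as_weights <- function(x) {
    if (is.null(x) || !length(x)) return(numeric(0))
    if (is.character(x)) return(setNames(rep(1 / length(x), length(x)), x))
    if (is.numeric(x) && !is.null(names(x))) {
      if (any(x <= 0)) stopf("objective weights must be positive")
      return(x)
    }
    stopf("maximize/minimize must be ids or named weights")
  }
  wmax <- as_weights(maximize); wmin <- as_weights(minimize)
  if (length(intersect(names(wmax), names(wmin))))
    stopf("maximize and minimize sets must be disjoint")
  if (!length(wmax) && !length(wmin)) stopf("objective needs at least one feature")
  if (mode == "target" && is.null(target_value))
    stopf("mode = 'target' requires target_value")
  check_scalar_number(alpha, "alpha", 0, 1)
  if (!is.null(secondary)) stopifnot(inherits(secondary, "objective_spec"))
  structure(list(maximize = wmax, minimize = wmin, mode = mode,
                 target_value = target_value, secondary = secondary,
                 alpha = alpha), class = "objective_spec")
}

#' @export
print.objective_spec <- function(x, ...) {
  cat(sprintf("objective_spec [%s]: maximize {%s}, minimize {%s}%s\n",
              x$mode, paste(names(x$maximize), collapse = ", "),
              paste(names(x$minimize), collapse = ", "),
              if (!is.null(x$secondary)) sprintf("; bi-objective alpha = %g", x$alpha) else ""))
  invisible(x)
}

# pull a features x lines value matrix for the ids of one side
pull_values <- function(ids, M, A) {
  out <- matrix(NA_real_, length(ids), ncol(M %||% A),
                dimnames = list(ids, colnames(M %||% A)))
  for (id in ids) {
    if (!is.null(M) && id %in% rownames(M)) out[id, ] <- M[id, ]
    else if (!is.null(A) && id %in% rownames(A)) out[id, ] <- A[id, ]
    else stopf("objective id '%s' not found among metabolites or traits", id)
  }
  out
}

# per-line scores for metabolite (M) and trait (A) matrices, features x lines
objective_scores <- function(spec, M, A, wt_stats = NULL) {
  base_scores <- function(sp) {
    s <- 0
    if (length(sp$maximize))
      s <- s + colSums(pull_values(names(sp$maximize), M, A) * sp$maximize)
    if (length(sp$minimize))
      s <- s - colSums(pull_values(names(sp$minimize), M, A) * sp$minimize)
    switch(sp$mode,
           maximize = s,
           minimize = -s,
           target = -abs(s - sp$target_value))
  }
  if (is.null(spec$secondary) || spec$alpha == 1) return(base_scores(spec))
  if (spec$alpha == 0) return(base_scores(spec$secondary))
  if (is.null(wt_stats))
    stopf("bi-objective scoring needs wild-type population statistics (wt_stats)")
  z <- function(s, st) (s - st[1]) / if (st[2] > 1e-12) st[2] else 1
  spec$alpha * z(base_scores(spec), wt_stats$primary) +
    (1 - spec$alpha) * z(base_scores(spec$secondary), wt_stats$secondary)
}

# wild-type population statistics for bi-objective z-scoring
wt_statistics <- function(spec, M_obs, A_obs) {
  if (is.null(spec$secondary)) return(NULL)
  prim <- objective_scores(objective_spec_strip(spec), M_obs, A_obs)
  sec <- objective_scores(spec$secondary, M_obs, A_obs)
  list(primary = c(mean(prim), sd(prim)), secondary = c(mean(sec), sd(sec)))
}

# the primary spec without its bi-objective coupling
objective_spec_strip <- function(spec) {
  spec$secondary <- NULL
  spec
}

#' Score a genome state under an objective
#'
#' @param spec an [objective_spec()].
#' @param state a `genome_state` (from [predict_state()]) or a list with
#'   named `metabolites` and/or `traits` vectors.
#' @param wt_stats wild-type population statistics for bi-objective scoring
#'   (list of `primary`/`secondary` mean-sd pairs); only needed for
#'   bi-objectives with `0 < alpha < 1`.
#' @return scalar score (higher is better).
#' @export
evaluate_objective <- function(spec, state, wt_stats = NULL) {
  stopifnot(inherits(spec, "objective_spec"))
  M <- if (!is.null(state$metabolites)) cbind(value = state$metabolites)
  A <- if (!is.null(state$traits)) cbind(value = state$traits)
  unname(objective_scores(spec, M, A, wt_stats))
}

#' Perturbation efficiency (percent change versus wild-type)
#'
#' `100 * (score_pert - score_wt) / |score_wt|`. When `|score_wt|` falls
#' below 1e-9 the wild-type population standard deviation is used as the
#' denominator instead (z-scored objectives cross zero routinely); affected
#' entries are flagged in the attribute `"sd_denominator"`.
#'
#' @param score_pert,score_wt numeric (vectorized over lines).
#' @param fallback_sd wild-type population sd for the near-zero fallback.
#' @return efficiency in percent.
#' @export
efficiency <- function(score_pert, score_wt, fallback_sd = NULL) {
  if (any(!is.finite(score_pert) & !is.finite(score_wt)))
    stopf("both scores non-finite")
  denom <- abs(score_wt)
  small <- denom < 1e-9
  if (any(small)) {
    if (is.null(fallback_sd) || !is.finite(fallback_sd) || fallback_sd <= 0)
      stopf("wild-type score ~ 0 and no usable fallback_sd supplied")
    denom[small] <- fallback_sd
  }
  out <- 100 * (score_pert - score_wt) / denom
  if (any(small)) attr(out, "sd_denominator") <- which(small)
  out
}

# row-wise efficiency of a score matrix against per-line wild-type scores
efficiency_rows <- function(score, s_wt, fallback_sd) {
  do.call(rbind, lapply(seq_len(nrow(score)), function(i)
    as.numeric(efficiency(score[i, ], s_wt, fallback_sd))))
}

# ---- scan machinery ---------------------------------------------------------

# observed matrices, per-line calibrations and solver inputs for a panel
scan_context <- function(stack, panel, lines = NULL) {
  stopifnot(inherits(stack, "model_stack"), !is.null(stack$gene))
  p <- if (panel$replicates > 1L) average_replicates(panel) else panel
  genes <- rownames(stack$gene$coefficients)
  lines <- lines %||% p$expr_lines
  G <- t(p$expression[lines, genes, drop = FALSE])
  W <- stack$gene$coefficients
  B <- G - as.matrix(W %*% G)  # intercept + per-line calibration, combined
  r <- shrunk_ranges(stack$gene)
  ctx <- list(stack = stack, genes = genes, lines = lines, G = G, W = W, B = B,
              lo = if (!is.null(r)) r[, "min"], hi = if (!is.null(r)) r[, "max"],
              cache = make_solver_cache(W))
  if (!is.null(stack$metabolite)) {
    mets <- rownames(stack$metabolite$coefficients)
    ctx$M <- t(p$metabolites[lines, mets, drop = FALSE])
    V <- stack$metabolite$coefficients
    ctx$eps_m <- ctx$M - (as.matrix(V %*% G) + stack$metabolite$intercepts)
  }
  if (!is.null(stack$trait) && !is.null(p$traits)) {
    trs <- rownames(stack$trait$coefficients)
    ctx$A <- t(p$traits[lines, trs, drop = FALSE])
    U <- stack$trait$coefficients
    ctx$eps_a <- ctx$A - (as.matrix(U %*% ctx$M) + stack$trait$intercepts)
  }
  ctx
}

# predicted M/A matrices (features x lines) under a clamp set
perturbed_layers <- function(ctx, clamp_idx, clamp_val) {
  sol <- solve_expression_matrix(ctx$W, ctx$B, clamp_idx, clamp_val,
                                 lo = ctx$lo, hi = ctx$hi, on_fail = "flag",
                                 cache = ctx$cache)
  G <- sol$G
  M <- A <- NULL
  if (!is.null(ctx$M)) {
    V <- ctx$stack$metabolite$coefficients
    M <- as.matrix(V %*% G) + ctx$stack$metabolite$intercepts + ctx$eps_m
  }
  if (!is.null(ctx$A)) {
    U <- ctx$stack$trait$coefficients
    A <- as.matrix(U %*% M) + ctx$stack$trait$intercepts + ctx$eps_a
  }
  list(G = G, M = M, A = A, converged = all(sol$converged))
}

pert_label <- function(genes, modes) {
  lab <- paste(genes, modes, sep = ":")
  lab <- lab[modes != "WT" & !is.na(genes)]
  if (!length(lab)) "WT" else paste(lab, collapse = "+")
}

# assemble a perturbation_scan from per-record score rows
build_scan <- function(records, score, eff, wt_scores, lines, spec, kind) {
  rownames(score) <- rownames(eff) <- records$label
  colnames(score) <- colnames(eff) <- lines
  records$mean_score <- rowMeans(score)
  records$mean_efficiency <- rowMeans(eff)
  records$min_efficiency <- apply(eff, 1, min)
  records$max_efficiency <- apply(eff, 1, max)
  records$max_property <- apply(score, 1, max)
  records$best_line <- lines[apply(eff, 1, which.max)]
  structure(list(records = records, score = score, efficiency = eff,
                 wt_scores = setNames(wt_scores, lines), lines = lines,
                 spec = spec, kind = kind),
            class = "perturbation_scan")
}

#' @export
print.perturbation_scan <- function(x, ...) {
  cat(sprintf("perturbation_scan [%s]: %d perturbations x %d lines\n",
              x$kind, nrow(x$records), length(x$lines)))
  top <- x$records[order(-x$records$mean_efficiency), ][1, ]
  cat(sprintf("  best mean efficiency: %s (%.2f%%)\n", top$label,
              top$mean_efficiency))
  invisible(x)
}

#' Exhaustive single-perturbation scan
#'
#' Evaluates every gene under knockout and over-expression, per line:
#' the perturbed steady state is solved with the gene clamped (per-line
#' calibration anchors the wild-type to the line's observed state), the
#' objective is scored, and the efficiency versus the line's wild-type score
#' recorded. A wild-type row (efficiency exactly 0) is always included.
#' Records are ordered deterministically (gene id, then KO before OE).
#'
#' @param stack fitted [model_stack()] (gene + metabolite layers at least).
#' @param spec an [objective_spec()].
#' @param panel standardized line-level [omics_panel()].
#' @param genes optional subset of gene ids to perturb (default all).
#' @param lines optional subset of line ids (default all expression lines).
#' @return an object of class `perturbation_scan`: `records` data frame plus
#'   per-line `score` and `efficiency` matrices.
#' @export
scan_single <- function(stack, spec, panel, genes = NULL, lines = NULL) {
  ctx <- scan_context(stack, panel, lines)
  genes <- sort(genes %||% ctx$genes)
  if (length(bad <- setdiff(genes, ctx$genes)))
    stopf("unknown gene id(s): %s", paste(bad, collapse = ", "))
  wt_stats <- wt_statistics(spec, ctx$M, ctx$A)
  s_wt <- objective_scores(spec, ctx$M, ctx$A, wt_stats)
  fb <- sd(s_wt)
  combos <- expand.grid(mode = c("KO", "OE"), gene = genes,
                        stringsAsFactors = FALSE)[, c("gene", "mode")]
  combos <- combos[order(combos$gene, combos$mode), ]
  n_rec <- nrow(combos) + 1L
  score <- matrix(NA_real_, n_rec, length(ctx$lines))
  score[1, ] <- s_wt
  conv <- rep(TRUE, n_rec)
  for (k in seq_len(nrow(combos))) {
    g <- combos$gene[k]; mode <- combos$mode[k]
    cv <- clamp_value(stack, g, mode)
    pl <- perturbed_layers(ctx, match(g, ctx$genes), cv)
    score[k + 1L, ] <- objective_scores(spec, pl$M, pl$A, wt_stats)
    conv[k + 1L] <- pl$converged
  }
  eff <- efficiency_rows(score, s_wt, fb)
  eff[1, ] <- 0
  records <- data.frame(
    label = c("WT", paste(combos$gene, combos$mode, sep = ":")),
    gene = c(NA_character_, combos$gene),
    mode = c("WT", combos$mode),
    converged = conv, stringsAsFactors = FALSE)
  build_scan(records, score, eff, s_wt, ctx$lines, spec, "single")
}

#' Pairwise perturbation scan
#'
#' Evaluates unordered gene pairs under the four mode combinations KO/KO,
#' KO/OE, OE/KO and OE/OE. When the number of pairs exceeds `budget`, a
#' seeded random sample of pairs is scanned instead. Degenerate
#' `(gene, wild-type)` rows — the single perturbations — are included by
#' default so the pair landscape contains the single landscape.
#'
#' @inheritParams scan_single
#' @param budget maximum number of gene pairs to evaluate (`NULL` =
#'   exhaustive).
#' @param include_singles include the degenerate (gene, WT) rows.
#' @param seed seed for budgeted pair sampling.
#' @return a `perturbation_scan` of kind `"pair"`.
#' @export
scan_pairs <- function(stack, spec, panel, genes = NULL, lines = NULL,
                       budget = NULL, include_singles = TRUE, seed = 1L) {
  ctx <- scan_context(stack, panel, lines)
  genes <- sort(genes %||% ctx$genes)
  if (!is.null(budget) && budget < 1) stopf("budget must be >= 1")
  wt_stats <- wt_statistics(spec, ctx$M, ctx$A)
  s_wt <- objective_scores(spec, ctx$M, ctx$A, wt_stats)
  fb <- sd(s_wt)
  pairs <- t(combn(genes, 2))
  if (!is.null(budget) && nrow(pairs) > budget) {
    keep <- with_seed(seed, sample(nrow(pairs), budget))
    pairs <- pairs[sort(keep), , drop = FALSE]
  }
  modes <- cbind(c("KO", "KO", "OE", "OE"), c("KO", "OE", "KO", "OE"))
  recs <- list(data.frame(label = "WT", gene1 = NA_character_, mode1 = "WT",
                          gene2 = NA_character_, mode2 = "WT",
                          stringsAsFactors = FALSE))
  if (include_singles) {
    for (g in genes) for (m in c("KO", "OE"))
      recs[[length(recs) + 1L]] <- data.frame(
        label = pert_label(g, m), gene1 = g, mode1 = m,
        gene2 = NA_character_, mode2 = "WT", stringsAsFactors = FALSE)
  }
  for (p in seq_len(nrow(pairs))) for (mc in seq_len(4))
    recs[[length(recs) + 1L]] <- data.frame(
      label = pert_label(pairs[p, ], modes[mc, ]),
      gene1 = pairs[p, 1], mode1 = modes[mc, 1],
      gene2 = pairs[p, 2], mode2 = modes[mc, 2], stringsAsFactors = FALSE)
  records <- do.call(rbind, recs)
  score <- matrix(NA_real_, nrow(records), length(ctx$lines))
  conv <- rep(TRUE, nrow(records))
  score[1, ] <- s_wt
  for (k in seq_len(nrow(records))[-1]) {
    gs <- c(records$gene1[k], records$gene2[k])
    ms <- c(records$mode1[k], records$mode2[k])
    use <- !is.na(gs) & ms != "WT"
    cv <- vapply(which(use), function(u) clamp_value(stack, gs[u], ms[u]),
                 numeric(1))
    pl <- perturbed_layers(ctx, match(gs[use], ctx$genes), cv)
    score[k, ] <- objective_scores(spec, pl$M, pl$A, wt_stats)
    conv[k] <- pl$converged
  }
  eff <- efficiency_rows(score, s_wt, fb)
  eff[1, ] <- 0
  records$converged <- conv
  build_scan(records, score, eff, s_wt, ctx$lines, spec, "pair")
}

#' Greedy multi-gene optimization
#'
#' Starting from the wild-type assignment, each round tentatively switches
#' every gene to each of knockout / over-expression / wild-type given the
#' current assignment of the others, and commits the single change with the
#' best mean score across lines. Stops when no change improves the mean
#' score by more than `tol`, or after `max_rounds` rounds. Ties are broken
#' by gene id order; the trajectory of committed scores is non-decreasing by
#' construction.
#'
#' @inheritParams scan_single
#' @param max_rounds maximum number of committed changes (>= 1).
#' @param tol minimal improvement to keep going.
#' @return list with `perturbation` (a [perturbation_set()]), `trajectory`
#'   (data frame: round, gene, mode, mean_score) and `mean_score`.
#' @export
greedy_multi <- function(stack, spec, panel, genes = NULL, lines = NULL,
                         max_rounds = 10L, tol = 1e-9) {
  if (max_rounds < 1) stopf("max_rounds must be >= 1")
  ctx <- scan_context(stack, panel, lines)
  genes <- sort(genes %||% ctx$genes)
  wt_stats <- wt_statistics(spec, ctx$M, ctx$A)
  assign <- setNames(rep("WT", length(genes)), genes)
  mean_score_of <- function(a) {
    act <- a[a != "WT"]
    if (!length(act)) {
      s <- objective_scores(spec, ctx$M, ctx$A, wt_stats)
      return(mean(s))
    }
    cv <- vapply(seq_along(act), function(i)
      clamp_value(ctx$stack, names(act)[i], act[i]), numeric(1))
    pl <- perturbed_layers(ctx, match(names(act), ctx$genes), cv)
    mean(objective_scores(spec, pl$M, pl$A, wt_stats))
  }
  current <- mean_score_of(assign)
  trajectory <- data.frame(round = 0L, gene = NA_character_, mode = "WT",
                           mean_score = current, stringsAsFactors = FALSE)
  for (round in seq_len(max_rounds)) {
    best <- list(score = current, gene = NA_character_, mode = NA_character_)
    for (g in genes) for (mode in c("KO", "OE", "WT")) {
      if (assign[g] == mode) next
      cand <- assign; cand[g] <- mode
      s <- mean_score_of(cand)
      if (s > best$score + tol) best <- list(score = s, gene = g, mode = mode)
    }
    if (is.na(best$gene)) break
    assign[best$gene] <- best$mode
    current <- best$score
    trajectory <- rbind(trajectory,
                        data.frame(round = round, gene = best$gene,
                                   mode = best$mode, mean_score = current,
                                   stringsAsFactors = FALSE))
  }
  act <- assign[assign != "WT"]
  list(perturbation = perturbation_set(ko = names(act)[act == "KO"],
                                       oe = names(act)[act == "OE"]),
       trajectory = trajectory, mean_score = current)
}

#' Rank scanned perturbations
#'
#' Stable descending sort of scan records by (i) the mean efficiency across
#' lines or (ii) the maximum objective value reached in any line (the
#' best-line property). Ties preserve the scan's deterministic gene-id order.
#'
#' @param scan a `perturbation_scan`.
#' @param criterion `"mean_efficiency"` or `"mean_max_property"`.
#' @param top optionally keep only the first `top` rows.
#' @return ranked data frame with `rank`, the perturbation columns, the
#'   ranking key, best-line efficiency and best line id.
#' @export
rank_perturbations <- function(scan,
                               criterion = c("mean_efficiency",
                                             "mean_max_property"),
                               top = NULL) {
  criterion <- match.arg(criterion)
  rec <- scan$records
  if (!nrow(rec)) return(rec)
  key <- if (criterion == "mean_efficiency") rec$mean_efficiency else rec$max_property
  ord <- order(-key)  # radix order is stable
  out <- rec[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  cols <- c("rank", setdiff(names(out), "rank"))
  out <- out[, cols]
  if (!is.null(top)) out <- head(out, top)
  out
}

#' Landscape statistics over efficiency thresholds
#'
#' For each threshold: the mean and sd (across lines) of the number of
#' perturbations whose per-line efficiency exceeds it, and the mean and sd
#' (across perturbations) of the selection probability — the fraction of
#' lines in which the perturbation exceeds the threshold. The wild-type row
#' is excluded.
#'
#' @param scan a `perturbation_scan`.
#' @param thresholds numeric efficiency thresholds (percent).
#' @return data frame with one row per threshold.
#' @export
landscape_stats <- function(scan, thresholds) {
  eff <- scan$efficiency[scan$records$label != "WT", , drop = FALSE]
  do.call(rbind, lapply(thresholds, function(th) {
    over <- eff > th
    counts <- colSums(over)
    probs <- rowMeans(over)
    data.frame(threshold = th,
               count_mean = mean(counts), count_sd = sd(counts),
               prob_mean = mean(probs), prob_sd = sd(probs))
  }))
}
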