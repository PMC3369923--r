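#' Construct a single-layer linear model
#'
#' A layer model holds a sparse targets x predictors coefficient matrix, one
#' intercept per target, a constant calibration term, and (for the gene layer)
#' per-gene observed expression ranges with a symmetric shrink fraction
#' `delta` used when clamping genes.
#'
#' @param coefficients sparse (or dense) numeric matrix, targets x predictors,
#'   with dimnames.
#' @param intercepts numeric vector, one per target.
#' @param layer one of `"gene"`, `"metabolite"`, `"trait"`.
#' @param calibration constant calibration term added to every prediction
#'   (the training-mean residual; see the vignette).
#' @param ranges optional predictors x 2 matrix (`min`, `max`) of observed
#'   gene expression ranges (gene layer only).
#' @param delta range-shrink fraction in `[0, 1)`: each interval is contracted
#'   symmetrically about its midpoint by `delta * span`.
#' @param fit optional list of fit metadata (thresholds, per-target training r).
#' @return an object of class `layer_model`.
#' @export
layer_model <- function(coefficients, intercepts,
                        layer = c("gene", "metabolite", "trait"),
                        calibration = 0, ranges = NULL, delta = 0,
                        fit = NULL) {
  layer <- match.arg(layer)
  coefficients <- methods::as(methods::as(methods::as(
    Matrix::Matrix(coefficients, sparse = TRUE), "dMatrix"), "generalMatrix"),
    "CsparseMatrix")
  if (is.null(rownames(coefficients)) || is.null(colnames(coefficients)))
    stopf("layer coefficients need target and predictor dimnames")
  if (length(intercepts) != nrow(coefficients))
    stopf("need one intercept per target")
  if (layer == "gene" && nrow(coefficients) == ncol(coefficients) &&
      any(Matrix::diag(coefficients) != 0))
    stopf("gene layer must not contain self-loops")
  check_scalar_number(delta, "delta", 0, 1 - 1e-12)
  if (!is.null(ranges)) {
    ranges <- as.matrix(ranges)
    colnames(ranges) <- c("min", "max")
    if (is.null(rownames(ranges))) rownames(ranges) <- colnames(coefficients)
  }
  structure(list(
    coefficients = coefficients,
    intercepts = setNames(as.numeric(intercepts), rownames(coefficients)),
    calibration = calibration,
    ranges = ranges,
    delta = delta,
    layer = layer,
    fit = fit
  ), class = "layer_model")
}

#' @export
print.layer_model <- function(x, ...) {
  cat(sprintf("layer_model [%s]: %d targets, %d predictors, %d edges\n",
              x$layer, nrow(x$coefficients), ncol(x$coefficients),
              length(x$coefficients@x)))
  if (!is.null(x$fit$training_r))
    cat(sprintf("  mean training r: %.3f\n", mean(x$fit$training_r, na.rm = TRUE)))
  invisible(x)
}

#' Bundle fitted layers into a model stack
#'
#' @param gene,metabolite,trait [layer_model()]s (any may be `NULL`).
#' @param meta optional list of run metadata.
#' @return an object of class `model_stack`.
#' @export
model_stack <- function(gene = NULL, metabolite = NULL, trait = NULL,
                        meta = list()) {
  structure(list(gene = gene, metabolite = metabolite, trait = trait,
                 meta = meta), class = "model_stack")
}

#' @export
print.model_stack <- function(x, ...) {
  cat("model_stack\n")
  for (l in c("gene", "metabolite", "trait")) {
    if (is.null(x[[l]])) cat(sprintf("  %s: <absent>\n", l))
    else cat(sprintf("  %-10s %4d targets, %5d edges\n", paste0(l, ":"),
                     nrow(x[[l]]$coefficients), length(x[[l]]$coefficients@x)))
  }
  invisible(x)
}

# delta-shrunk [lo, hi] bounds for the gene layer; NULL when no ranges stored
shrunk_ranges <- function(model) {
  if (is.null(model$ranges)) return(NULL)
  lo <- model$ranges[, "min"]; hi <- model$ranges[, "max"]
  half <- model$delta * (hi - lo) / 2
  cbind(min = lo + half, max = hi - half)
}

#' Clamp value of a gene under knockout or over-expression
#'
#' Knockout clamps a gene at the (delta-shrunk) minimum of its observed
#' expression range; over-expression at the maximum.
#'
#' @param model a gene-layer `layer_model` (or a `model_stack`).
#' @param gene gene id.
#' @param mode `"KO"` or `"OE"`.
#' @return the clamp value (scalar).
#' @export
clamp_value <- function(model, gene, mode = c("KO", "OE")) {
  mode <- match.arg(mode)
  if (inherits(model, "model_stack")) model <- model$gene
  r <- shrunk_ranges(model)
  if (is.null(r) || !gene %in% rownames(r))
    stopf("no recorded expression range for gene '%s'", gene)
  unname(if (mode == "KO") r[gene, "min"] else r[gene, "max"])
}

# clamp values for a perturbation_set, in model gene order
clamp_vector <- function(model, perts) {
  if (!length(perts)) return(numeric(0))
  vapply(seq_along(perts), function(i)
    clamp_value(model, names(perts)[i], unclass(perts)[i]), numeric(1))
}

# Solver cache: one sparse LU factorization of A0 = I - W, with memoized
# solutions A0^{-1} e_i. Fixing row i at a target value is a rank-one row
# replacement of A0, so clamped/bounded solves reduce to the factorization
# plus a small dense (Woodbury) correction. Reused across a whole scan.
make_solver_cache <- function(W) {
  A0 <- Diagonal(nrow(W)) - W
  lu <- tryCatch(Matrix::lu(A0), error = function(e) NULL)
  env <- new.env(parent = emptyenv())
  env$A0 <- A0
  env$lu <- lu
  env$cols <- vector("list", nrow(W))
  env
}

cache_cols <- function(cache, idx) {
  miss <- idx[vapply(cache$cols[idx], is.null, logical(1))]
  if (length(miss)) {
    E <- matrix(0, nrow(cache$A0), length(miss))
    E[cbind(miss, seq_along(miss))] <- 1
    sol <- as.matrix(Matrix::solve(cache$lu, E))
    for (j in seq_along(miss)) cache$cols[[miss[j]]] <- sol[, j]
  }
  do.call(cbind, cache$cols[idx])
}

# exact solve of g = W g + b with rows K fixed at `targets`, via the cached
# factorization and a |K| x |K| dense correction; y0 = A0^{-1} b
woodbury_fixed_rows <- function(cache, y0, b, K, targets) {
  if (!length(K)) return(y0)
  CK <- cache_cols(cache, K)
  y <- y0 + as.vector(CK %*% (targets - b[K]))
  A0K <- cache$A0[K, , drop = FALSE]
  vt_y <- y[K] - as.vector(A0K %*% y)
  vt_z <- CK[K, , drop = FALSE] - as.matrix(A0K %*% CK)
  M <- diag(length(K)) + vt_z
  corr <- tryCatch(solve(M, vt_y), error = function(e) NULL)
  if (is.null(corr)) return(NULL)
  g <- y - as.vector(CK %*% corr)
  g[K] <- targets
  g
}

# Active-set solver for one column: finds the projected fixed point of
# g = clip(W g + b, lo, hi) with clamped rows fixed, by repeatedly pinning
# bound-active genes and updating the active set from the complementarity
# conditions. Returns NULL when it fails to settle (caller falls back to the
# damped iteration).
solve_column_active_set <- function(W, b, clamp_idx, clamp_val, lo, hi,
                                    g_start, tol, cache, y0,
                                    max_rounds = 40L) {
  ng <- nrow(W)
  g <- g_start
  at_lo <- g <= lo + 1e-12
  at_hi <- g >= hi - 1e-12
  if (length(clamp_idx)) at_lo[clamp_idx] <- at_hi[clamp_idx] <- FALSE
  for (round in seq_len(max_rounds)) {
    act_lo <- which(at_lo); act_hi <- which(at_hi)
    K <- c(clamp_idx, act_lo, act_hi)
    targets <- c(clamp_val, lo[act_lo], hi[act_hi])
    dup <- duplicated(K)
    g <- woodbury_fixed_rows(cache, y0, b, K[!dup], targets[!dup])
    if (is.null(g)) return(NULL)
    u <- as.vector(W %*% g) + b
    # activate free genes pushed outside their bounds; release active genes
    # whose unconstrained update points back inside
    grow_lo <- g < lo - 1e-12 & !at_lo
    grow_hi <- g > hi + 1e-12 & !at_hi
    rel_lo <- at_lo & u > lo + 1e-12
    rel_hi <- at_hi & u < hi - 1e-12
    if (length(clamp_idx)) {
      grow_lo[clamp_idx] <- grow_hi[clamp_idx] <- FALSE
      rel_lo[clamp_idx] <- rel_hi[clamp_idx] <- FALSE
    }
    if (!any(grow_lo | grow_hi | rel_lo | rel_hi)) {
      g <- pmin(pmax(g, lo), hi)
      if (length(clamp_idx)) g[clamp_idx] <- clamp_val
      # verify with one projected sweep
      chk <- pmin(pmax(as.vector(W %*% g) + b, lo), hi)
      if (length(clamp_idx)) chk[clamp_idx] <- clamp_val
      if (max(abs(chk - g)) < tol * 10) return(g)
      return(NULL)
    }
    at_lo <- (at_lo | grow_lo) & !rel_lo
    at_hi <- (at_hi | grow_hi) & !rel_hi
  }
  NULL
}

# Core solver: columns of B are per-line intercept(+calibration) vectors.
# Solves g = W g + b with rows `clamp_idx` fixed at `clamp_val`, projecting
# free genes into [lo, hi] each sweep. Direct linear solve is used first;
# columns whose unconstrained solution violates a bound are re-solved by an
# active-set method and, where that fails to settle, by the projected damped
# fixed-point iteration.
solve_expression_matrix <- function(W, B, clamp_idx = integer(0),
                                    clamp_val = numeric(0), lo = NULL, hi = NULL,
                                    damping = 0.5, tol = 1e-10,
                                    max_iter = 10000L, method = "auto",
                                    on_fail = c("error", "flag"),
                                    cache = NULL) {
  on_fail <- match.arg(on_fail)
  ng <- nrow(W); L <- ncol(B)
  free <- setdiff(seq_len(ng), clamp_idx)
  G <- matrix(0, ng, L, dimnames = list(rownames(W), colnames(B)))
  if (length(clamp_idx)) G[clamp_idx, ] <- clamp_val
  bounded <- !is.null(lo)
  if (!length(free)) {
    return(list(G = G, iterations = 0L, residual = 0,
                converged = rep(TRUE, L)))
  }
  need_iter <- seq_len(L)
  if (method %in% c("auto", "direct")) {
    if (is.null(cache)) cache <- make_solver_cache(W)
    sol <- NULL
    Y0 <- NULL
    if (!is.null(cache$lu)) {
      Y0 <- tryCatch(as.matrix(Matrix::solve(cache$lu, B)),
                     error = function(e) NULL)
    }
    if (!is.null(Y0)) {
      if (!length(clamp_idx)) {
        sol <- Y0
      } else {
        # rank-|clamp| row replacement, shared across columns
        CK <- cache_cols(cache, clamp_idx)
        D <- clamp_val - B[clamp_idx, , drop = FALSE]
        Y <- Y0 + CK %*% D
        A0K <- cache$A0[clamp_idx, , drop = FALSE]
        vt_y <- Y[clamp_idx, , drop = FALSE] - as.matrix(A0K %*% Y)
        vt_z <- CK[clamp_idx, , drop = FALSE] - as.matrix(A0K %*% CK)
        M <- diag(length(clamp_idx)) + vt_z
        corr <- tryCatch(solve(M, vt_y), error = function(e) NULL)
        if (!is.null(corr)) {
          sol <- Y - CK %*% corr
          sol[clamp_idx, ] <- clamp_val
        }
      }
    }
    if (is.null(sol)) {
      if (method == "direct")
        warnf("singular system; falling back to projected iteration")
    } else {
      G <- sol
      dimnames(G) <- list(rownames(W), colnames(B))
      if (!bounded) {
        return(list(G = G, iterations = 0L, residual = 0,
                    converged = rep(TRUE, L)))
      }
      viol <- colSums(G[free, , drop = FALSE] < lo[free] - 1e-12) +
        colSums(G[free, , drop = FALSE] > hi[free] + 1e-12)
      need_iter <- which(viol > 0)
      if (!length(need_iter)) {
        return(list(G = G, iterations = 0L, residual = 0,
                    converged = rep(TRUE, L)))
      }
      # fast path: settle each violating column by the active-set method
      still <- integer(0)
      for (cc in need_iter) {
        start <- pmin(pmax(G[, cc], lo), hi)
        res <- solve_column_active_set(W, B[, cc], clamp_idx, clamp_val,
                                       lo, hi, start, tol,
                                       cache = cache, y0 = Y0[, cc])
        if (is.null(res)) still <- c(still, cc) else G[, cc] <- res
      }
      need_iter <- still
      if (!length(need_iter)) {
        return(list(G = G, iterations = 0L, residual = 0,
                    converged = rep(TRUE, L)))
      }
    }
  }
  # projected damped fixed-point iteration on the remaining columns
  g <- G[, need_iter, drop = FALSE]
  b <- B[, need_iter, drop = FALSE]
  if (bounded) {
    lom <- matrix(lo, ng, length(need_iter))
    him <- matrix(hi, ng, length(need_iter))
  }
  it <- 0L; resid <- Inf
  repeat {
    it <- it + 1L
    prop <- as.matrix(W %*% g) + b
    if (bounded) prop <- pmin(pmax(prop, lom), him)
    gn <- (1 - damping) * g + damping * prop
    if (length(clamp_idx)) gn[clamp_idx, ] <- clamp_val
    resid <- max(abs(gn - g))
    g <- gn
    if (resid < tol || it >= max_iter) break
  }
  G[, need_iter] <- g
  converged <- rep(TRUE, L)
  if (resid >= tol) {
    converged[need_iter] <- FALSE
    if (on_fail == "error")
      stopf("steady-state iteration did not converge (residual %.3g after %d iterations)",
            resid, it)
  }
  list(G = G, iterations = it, residual = resid, converged = converged)
}

#' Solve the gene-layer steady state under a perturbation
#'
#' Clamped genes are fixed at their knockout/over-expression clamp values; the
#' remaining genes satisfy `g = W g + intercept + calibration`, solved by a
#' direct linear solve when no expression bound is active and otherwise by a
#' projected damped fixed-point iteration (genes projected into their
#' delta-shrunk observed ranges each sweep, damping 0.5, tolerance 1e-10,
#' at most 10^4 sweeps).
#'
#' When a `baseline` expression vector is supplied, the per-line calibration
#' `baseline - W baseline - intercept` replaces the stored constant, so that
#' the empty perturbation reproduces the baseline line exactly; with
#' `one_pass = TRUE` the solver instead propagates a single pass
#' `W baseline + intercept + calibration` from the baseline (no
#' self-consistent update).
#'
#' @param model a gene-layer `layer_model` or a `model_stack`.
#' @param perts a [perturbation_set()].
#' @param baseline optional named expression vector of a reference line.
#' @param one_pass logical; see above. Requires `baseline`.
#' @param calibrate `"line"` (default when a baseline is given) or
#'   `"constant"` (the stored training-mean calibration).
#' @param bounds enforce the delta-shrunk expression ranges (if stored).
#' @param method `"auto"`, `"direct"` or `"iterate"`.
#' @param damping,tol,max_iter iteration controls.
#' @return named expression vector with attributes `iterations` and
#'   `residual`.
#' @export
solve_expression <- function(model, perts = perturbation_set(),
                             baseline = NULL, one_pass = FALSE,
                             calibrate = c("auto", "line", "constant"),
                             bounds = TRUE, method = "auto",
                             damping = 0.5, tol = 1e-10, max_iter = 10000L) {
  calibrate <- match.arg(calibrate)
  if (inherits(model, "model_stack")) model <- model$gene
  stopifnot(inherits(model, "layer_model"), model$layer == "gene")
  W <- model$coefficients
  genes <- rownames(W)
  unknown <- setdiff(names(perts), genes)
  if (length(unknown)) stopf("unknown gene id(s): %s", paste(unknown, collapse = ", "))
  if (calibrate == "auto") calibrate <- if (is.null(baseline)) "constant" else "line"
  b <- model$intercepts
  if (calibrate == "line") {
    if (is.null(baseline)) stopf("calibrate = 'line' requires a baseline expression vector")
    baseline <- baseline[genes]
    b <- b + (baseline - as.vector(W %*% baseline) - model$intercepts)
  } else {
    b <- b + model$calibration
  }
  clamp_idx <- match(names(perts), genes)
  clamp_val <- clamp_vector(model, perts)
  if (one_pass) {
    if (is.null(baseline)) stopf("one_pass = TRUE requires a baseline expression vector")
    g <- as.vector(W %*% baseline[genes]) + b
    r <- shrunk_ranges(model)
    if (bounds && !is.null(r)) g <- pmin(pmax(g, r[, "min"]), r[, "max"])
    if (length(clamp_idx)) g[clamp_idx] <- clamp_val
    names(g) <- genes
    attr(g, "iterations") <- 1L; attr(g, "residual") <- 0
    return(g)
  }
  r <- if (bounds) shrunk_ranges(model) else NULL
  sol <- solve_expression_matrix(W, matrix(b, ncol = 1), clamp_idx, clamp_val,
                                 lo = if (!is.null(r)) r[, "min"],
                                 hi = if (!is.null(r)) r[, "max"],
                                 damping = damping, tol = tol,
                                 max_iter = max_iter, method = method)
  g <- setNames(drop(sol$G), genes)
  attr(g, "iterations") <- sol$iterations
  attr(g, "residual") <- sol$residual
  g
}

#' Predict the metabolome from an expression state
#'
#' `m = V g + intercept + calibration` (linear; the calibration defaults to
#' the stored constant but a per-line vector can be supplied).
#'
#' @param stack a `model_stack` with a metabolite layer (or the layer itself).
#' @param expression named expression vector.
#' @param calibration optional calibration override (scalar or per-metabolite
#'   vector).
#' @return named metabolite vector.
#' @export
predict_metabolome <- function(stack, expression, calibration = NULL) {
  model <- if (inherits(stack, "model_stack")) stack$metabolite else stack
  stopifnot(inherits(model, "layer_model"))
  V <- model$coefficients
  if (length(expression) != ncol(V)) stopf("expression dimension mismatch")
  cal <- calibration %||% model$calibration
  setNames(as.vector(V %*% expression[colnames(V)]) + model$intercepts + cal,
           rownames(V))
}

#' Predict agronomic traits from a metabolite state
#'
#' `a = U m + intercept + calibration`.
#'
#' @param stack a `model_stack` with a trait layer (or the layer itself).
#' @param metabolome named metabolite vector.
#' @param calibration optional calibration override.
#' @return named trait vector.
#' @export
predict_traits <- function(stack, metabolome, calibration = NULL) {
  model <- if (inherits(stack, "model_stack")) stack$trait else stack
  stopifnot(inherits(model, "layer_model"))
  U <- model$coefficients
  if (length(metabolome) != ncol(U)) stopf("metabolome dimension mismatch")
  cal <- calibration %||% model$calibration
  setNames(as.vector(U %*% metabolome[colnames(U)]) + model$intercepts + cal,
           rownames(U))
}

#' Predict a full genome state under a perturbation
#'
#' Solves the gene layer (with clamps), then propagates through the
#' metabolite and trait layers. When `panel` and `line` are given, per-line
#' calibrations anchor the prediction to that line, so the empty perturbation
#' reproduces the line's observed state.
#'
#' @param stack a fitted `model_stack`.
#' @param perts a [perturbation_set()].
#' @param panel optional standardized line-level [omics_panel()].
#' @param line optional line id within `panel` (must carry expression).
#' @param ... passed to [solve_expression()].
#' @return an object of class `genome_state`: list with `expression`,
#'   `metabolites`, `traits`, `iterations`, `residual`.
#' @export
predict_state <- function(stack, perts = perturbation_set(), panel = NULL,
                          line = NULL, ...) {
  stopifnot(inherits(stack, "model_stack"))
  baseline <- NULL; cal_m <- NULL; cal_a <- NULL
  if (!is.null(panel) && !is.null(line)) {
    p <- if (panel$replicates > 1L) average_replicates(panel) else panel
    baseline <- p$expression[line, ]
    if (!is.null(stack$metabolite) && !is.null(p$metabolites)) {
      m_obs <- p$metabolites[line, colnames(p$metabolites)]
      cal_m <- m_obs[rownames(stack$metabolite$coefficients)] -
        predict_metabolome(stack, baseline, calibration = 0)
    }
    if (!is.null(stack$trait) && !is.null(p$traits) && line %in% rownames(p$traits)) {
      a_obs <- p$traits[line, ]
      m_ref <- m_obs[colnames(stack$trait$coefficients)]
      cal_a <- a_obs[rownames(stack$trait$coefficients)] -
        predict_traits(stack, m_ref, calibration = 0)
    }
  }
  g <- solve_expression(stack, perts, baseline = baseline, ...)
  m <- if (!is.null(stack$metabolite)) predict_metabolome(stack, g, calibration = cal_m)
  a <- if (!is.null(stack$trait) && !is.null(m)) predict_traits(stack, m, calibration = cal_a)
  structure(list(expression = g, metabolites = m, traits = a,
                 iterations = attr(g, "iterations"),
                 residual = attr(g, "residual"),
                 perturbation = perts),
            class = "genome_state")
}

#' @export
print.genome_state <- function(x, ...) {
  cat(sprintf("genome_state: %d genes, %d metabolites, %d traits (%d iterations, residual %.2g)\n",
              length(x$expression), length(x$metabolites %||% numeric(0)),
              length(x$traits %||% numeric(0)), x$iterations %||% 0L,
              x$residual %||% 0))
  invisible(x)
}
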