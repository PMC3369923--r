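#' Configuration for a synthetic RIL-like panel
#'
#' Describes the dimensions, nesting and noise of a simulated panel of
#' recombinant inbred lines: a full set of lines with metabolite and trait
#' measurements, a nested subset that also carries expression arrays, and
#' replicate samples per line. Defaults mirror a panel of 169 lines with 50
#' arrayed in triplicate, ~26 regulators per gene and ~18 gene predictors per
#' metabolite.
#'
#' @param n_genes,n_metabolites,n_traits feature counts (positive integers).
#' @param n_lines_full number of metabolome/phenome lines.
#' @param n_lines_expr number of lines that also carry expression
#'   (`<= n_lines_full`).
#' @param replicates replicate samples per line for expression and
#'   metabolite matrices.
#' @param predictors_per_target mean in-degree per layer; a single number or a
#'   named vector `c(gene=, metabolite=, trait=)`. Defaults: 26 regulators per
#'   gene, 18 genes per metabolite, ~70% of metabolites per trait.
#' @param noise_sd observation-noise standard deviation per layer (z-score
#'   units); a single number or a named vector as above.
#' @param coef_floor,coef_max planted coefficient magnitudes are drawn
#'   uniformly from `[coef_floor, coef_max]` with random sign; the floor keeps
#'   planted edges detectable.
#' @param spectral_radius the gene-gene matrix is rescaled to this spectral
#'   radius (< 1), guaranteeing a unique steady state.
#' @return an object of class `panel_config`.
#' @export
panel_config <- function(n_genes, n_metabolites, n_traits,
                         n_lines_full = 169L, n_lines_expr = 50L,
                         replicates = 3L,
                         predictors_per_target = NULL,
                         noise_sd = 0.3,
                         coef_floor = 0.2, coef_max = 1,
                         spectral_radius = 0.8) {
  for (nm in c("n_genes", "n_metabolites", "n_traits", "n_lines_full",
               "n_lines_expr", "replicates")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stopf("'%s' must be a positive integer", nm)
  }
  if (n_lines_expr > n_lines_full)
    stopf("n_lines_expr (%d) must be <= n_lines_full (%d)",
          n_lines_expr, n_lines_full)
  layers <- c("gene", "metabolite", "trait")
  norm3 <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) x <- setNames(rep(x, 3), layers)
    if (!all(layers %in% names(x))) stopf("'%s' needs names %s", what,
                                          paste(layers, collapse = ", "))
    x[layers]
  }
  if (is.null(predictors_per_target)) {
    predictors_per_target <- c(gene = min(26, n_genes - 1L),
                               metabolite = min(18, n_genes),
                               trait = max(1, min(round(0.7 * n_metabolites),
                                                  n_metabolites)))
  }
  k <- norm3(predictors_per_target, "predictors_per_target")
  if (any(k < 1)) stopf("predictors_per_target must be >= 1 in every layer")
  avail <- c(gene = n_genes - 1L, metabolite = n_genes, trait = n_metabolites)
  bad <- k > avail
  if (any(bad))
    stopf("infeasible config: predictors_per_target[%s] = %g exceeds the %g available predictors",
          names(which(bad))[1], k[bad][1], avail[bad][1])
  noise_sd <- norm3(noise_sd, "noise_sd")
  if (any(noise_sd < 0)) stopf("noise_sd must be non-negative")
  check_scalar_number(coef_floor, "coef_floor", 0)
  check_scalar_number(coef_max, "coef_max", coef_floor)
  check_scalar_number(spectral_radius, "spectral_radius", 0, 1 - 1e-9)
  structure(list(
    n_genes = as.integer(n_genes), n_metabolites = as.integer(n_metabolites),
    n_traits = as.integer(n_traits), n_lines_full = as.integer(n_lines_full),
    n_lines_expr = as.integer(n_lines_expr), replicates = as.integer(replicates),
    predictors_per_target = k, noise_sd = noise_sd,
    coef_floor = coef_floor, coef_max = coef_max,
    spectral_radius = spectral_radius
  ), class = "panel_config")
}

# one sparse random layer: n_targets x n_predictors, Poisson in-degrees around k
random_layer <- function(n_targets, n_predictors, k, coef_floor, coef_max,
                         exclude_self = FALSE, min_degree = 1L,
                         target_names, predictor_names) {
  i <- j <- integer(0)
  max_deg <- n_predictors - as.integer(exclude_self)
  degs <- pmin(pmax(rpois(n_targets, k), min_degree), max_deg)
  for (t in seq_len(n_targets)) {
    pool <- seq_len(n_predictors)
    if (exclude_self) pool <- pool[pool != t]
    picked <- if (degs[t] > 0) sample(pool, degs[t]) else integer(0)
    i <- c(i, rep.int(t, length(picked)))
    j <- c(j, picked)
  }
  x <- sample(c(-1, 1), length(i), replace = TRUE) *
    runif(length(i), coef_floor, coef_max)
  sparseMatrix(i = i, j = j, x = x, dims = c(n_targets, n_predictors),
               dimnames = list(target_names, predictor_names))
}

#' Plant a ground-truth three-layer linear model
#'
#' Draws sparse coefficient matrices for the gene->gene, gene->metabolite and
#' metabolite->trait layers with Poisson-distributed in-degrees around the
#' configured means, coefficient magnitudes uniform on
#' `[coef_floor, coef_max]` with random sign, and the gene->gene matrix
#' rescaled to the configured spectral radius so the steady state is unique.
#' Every metabolite keeps at least one gene predictor and every trait at least
#' one metabolite predictor.
#'
#' @param config a [panel_config()].
#' @param seed integer seed; identical `(config, seed)` give an identical truth.
#' @return an object of class `ground_truth` with sparse matrices `W` (genes x
#'   genes), `V` (metabolites x genes), `U` (traits x metabolites), per-target
#'   `intercepts`, the per-layer `noise_sd` and the achieved spectral radius.
#' @export
generate_ground_truth <- function(config, seed = 1L) {
  stopifnot(inherits(config, "panel_config"))
  with_seed(seed, {
    gn <- sprintf("g%03d", seq_len(config$n_genes))
    mn <- sprintf("m%02d", seq_len(config$n_metabolites))
    tn <- sprintf("t%02d", seq_len(config$n_traits))
    k <- config$predictors_per_target
    W <- random_layer(config$n_genes, config$n_genes, k[["gene"]],
                      config$coef_floor, config$coef_max,
                      exclude_self = TRUE, min_degree = 0L,
                      target_names = gn, predictor_names = gn)
    rad <- spectral_radius(W)
    if (rad > 0) W <- W * (config$spectral_radius / rad)
    V <- random_layer(config$n_metabolites, config$n_genes, k[["metabolite"]],
                      config$coef_floor, config$coef_max,
                      min_degree = 1L, target_names = mn, predictor_names = gn)
    U <- random_layer(config$n_traits, config$n_metabolites, k[["trait"]],
                      config$coef_floor, config$coef_max,
                      min_degree = 1L, target_names = tn, predictor_names = mn)
    intercepts <- list(gene = setNames(rnorm(config$n_genes, 0, 0.5), gn),
                       metabolite = setNames(rnorm(config$n_metabolites, 0, 0.5), mn),
                       trait = setNames(rnorm(config$n_traits, 0, 0.5), tn))
    structure(list(
      W = drop0(W), V = drop0(V), U = drop0(U),
      intercepts = intercepts,
      noise_sd = config$noise_sd,
      spectral_radius = spectral_radius(W),
      gene_names = gn, metabolite_names = mn, trait_names = tn,
      seed = as.integer(seed)
    ), class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d genes, %d metabolites, %d traits\n",
              length(x$gene_names), length(x$metabolite_names),
              length(x$trait_names)))
  cat(sprintf("  edges: %d gene-gene, %d gene-metabolite, %d metabolite-trait\n",
              length(x$W@x), length(x$V@x), length(x$U@x)))
  cat(sprintf("  spectral radius of W: %.3f\n", x$spectral_radius))
  invisible(x)
}

#' Edge list of a planted truth or fitted layer
#'
#' @param x a `ground_truth`, `layer_model` or `model_stack`.
#' @param layer which layer to extract.
#' @return data frame with columns `target`, `predictor`, `coefficient`.
#' @export
model_edges <- function(x, layer = c("gene", "metabolite", "trait")) {
  layer <- match.arg(layer)
  M <- if (inherits(x, "ground_truth")) {
    switch(layer, gene = x$W, metabolite = x$V, trait = x$U)
  } else if (inherits(x, "model_stack")) {
    x[[layer]]$coefficients
  } else if (inherits(x, "layer_model")) {
    x$coefficients
  } else stopf("unsupported object of class %s", class(x)[1])
  s <- Matrix::summary(M)
  data.frame(target = rownames(M)[s$i], predictor = colnames(M)[s$j],
             coefficient = s$x, stringsAsFactors = FALSE)
}

# solve (I - W) G = B for all columns of B (unclamped steady states)
steady_solve <- function(W, B) {
  A <- Diagonal(nrow(W)) - W
  as.matrix(Matrix::solve(A, B))
}

#' Simulate a RIL-like omics panel from a planted truth
#'
#' For each line an exogenous standard-normal input (plus gene-layer noise)
#' perturbs every gene; the gene steady state solves
#' `g = W g + intercept + e + noise`, metabolites follow
#' `m = V g + intercept + noise` and traits `a = U m + intercept + noise`.
#' Replicate copies of expression and metabolites add Gaussian noise at one
#' third of the line-level sd. Expression is emitted only for the nested subset of
#' `n_lines_expr` lines; per-gene observed line-level (min, max) values across
#' those lines are recorded as `gene_ranges`.
#'
#' @param truth a [generate_ground_truth()] result.
#' @param config the [panel_config()] the truth was drawn for.
#' @param seed integer seed; the panel is bit-reproducible under it.
#' @return an [omics_panel()]; the attribute `"latent"` keeps the noise-free
#'   line-level layers and exogenous inputs for diagnostics and oracles.
#' @export
simulate_panel <- function(truth, config, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "panel_config"))
  if (length(truth$gene_names) != config$n_genes ||
      length(truth$metabolite_names) != config$n_metabolites ||
      length(truth$trait_names) != config$n_traits)
    stopf("truth dimensions do not match config")
  rad <- spectral_radius(truth$W)
  if (rad >= 1)
    stopf("ground truth has spectral radius %.3f >= 1: steady state does not converge", rad)
  nf <- config$n_lines_full; ne <- config$n_lines_expr
  ng <- config$n_genes; nm <- config$n_metabolites; nt <- config$n_traits
  reps <- config$replicates
  ns <- config$noise_sd
  lines <- sprintf("L%03d", seq_len(nf))
  expr_lines <- lines[seq_len(ne)]
  with_seed(seed, {
    # per-line input: exogenous standard-normal variation plus gene-layer noise,
    # both entering the steady-state equation g = W g + intercept + e + eta
    E <- matrix(rnorm(ng * nf), ng, nf) +
      matrix(rnorm(ng * nf, sd = ns[["gene"]]), ng, nf)
    G <- steady_solve(truth$W, truth$intercepts$gene + E)
    Gobs <- G
    M <- as.matrix(truth$V %*% G) + truth$intercepts$metabolite +
      matrix(rnorm(nm * nf, sd = ns[["metabolite"]]), nm, nf)
    A <- as.matrix(truth$U %*% M) + truth$intercepts$trait +
      matrix(rnorm(nt * nf, sd = ns[["trait"]]), nt, nf)
    dimnames(G) <- dimnames(Gobs) <- list(truth$gene_names, lines)
    dimnames(M) <- list(truth$metabolite_names, lines)
    dimnames(A) <- list(truth$trait_names, lines)
    rep_rows <- function(line_mat, sd_rep, keep_lines) {
      base <- t(line_mat[, keep_lines, drop = FALSE])
      out <- do.call(rbind, lapply(seq_len(reps), function(r) {
        base + matrix(rnorm(length(base), sd = sd_rep), nrow(base), ncol(base))
      }))
      rownames(out) <- as.vector(vapply(seq_len(reps), function(r)
        paste0(keep_lines, "_r", r), character(length(keep_lines))))
      ord <- order(rep(seq_along(keep_lines), reps), rep(seq_len(reps),
                                                         each = length(keep_lines)))
      out[ord, , drop = FALSE]
    }
    expr <- rep_rows(Gobs, ns[["gene"]] / 3, expr_lines)
    mets <- rep_rows(M, ns[["metabolite"]] / 3, lines)
    # observed range of diversity: per-gene min/max of the replicate-averaged
    # expression across the arrayed lines
    expr_avg <- rowsum(expr, row_line_ids(rownames(expr))) / reps
    gr <- cbind(min = apply(expr_avg, 2, min), max = apply(expr_avg, 2, max))
    panel <- omics_panel(expression = expr, metabolites = mets, traits = t(A),
                         lines = lines, expr_lines = expr_lines,
                         replicates = reps, gene_ranges = gr)
    attr(panel, "latent") <- list(E = E, G = G, Gobs = Gobs, M = M, A = A)
    panel
  })
}

#' Define a perturbation set
#'
#' Assigns genes to knockout (`KO`: clamp at range minimum) or over-expression
#' (`OE`: clamp at range maximum); unlisted genes stay wild-type.
#'
#' @param ko,oe character vectors of gene ids.
#' @return named character vector of modes, class `perturbation_set`.
#' @export
perturbation_set <- function(ko = character(), oe = character()) {
  if (length(intersect(ko, oe)))
    stopf("gene(s) %s assigned to both KO and OE",
          paste(intersect(ko, oe), collapse = ", "))
  x <- c(setNames(rep("KO", length(ko)), ko), setNames(rep("OE", length(oe)), oe))
  structure(x, class = "perturbation_set")
}

#' @export
print.perturbation_set <- function(x, ...) {
  if (!length(x)) cat("perturbation_set: wild-type (empty)\n")
  else cat("perturbation_set:", paste(names(x), unclass(x), sep = ":",
                                      collapse = ", "), "\n")
  invisible(x)
}

#' Simulate engineered lines with genes clamped in the ground-truth system
#'
#' Clamps the listed genes at their recorded range minimum (KO) or maximum
#' (OE) and solves the remaining genes self-consistently in the planted
#' system, line by line, with the same exogenous-input and noise mechanism as
#' [simulate_panel()]. Clamped genes take exactly their clamp value in every
#' replicate (the lesion is genetic, not a measurement).
#'
#' @param truth a `ground_truth`.
#' @param gene_ranges genes x 2 matrix (`min`, `max`), e.g. from a simulated
#'   wild-type panel's `gene_ranges`.
#' @param perturbation a [perturbation_set()] (possibly empty = wild-type).
#' @param n_lines number of engineered lines to simulate.
#' @param replicates replicate samples per line.
#' @param seed integer seed.
#' @return an [omics_panel()] whose lines all carry expression.
#' @export
make_engineered_lines <- function(truth, gene_ranges, perturbation,
                                  n_lines = 50L, replicates = 3L, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  genes <- truth$gene_names
  unknown <- setdiff(names(perturbation), genes)
  if (length(unknown))
    stopf("unknown gene id(s) in perturbation: %s", paste(unknown, collapse = ", "))
  if (is.null(rownames(gene_ranges))) rownames(gene_ranges) <- genes
  ng <- length(genes); nm <- length(truth$metabolite_names)
  nt <- length(truth$trait_names); ns <- truth$noise_sd
  lines <- sprintf("E%03d", seq_len(n_lines))
  clamp_idx <- match(names(perturbation), genes)
  clamp_val <- ifelse(unclass(perturbation) == "KO",
                      gene_ranges[names(perturbation), "min"],
                      gene_ranges[names(perturbation), "max"])
  with_seed(seed, {
    E <- matrix(rnorm(ng * n_lines), ng, n_lines) +
      matrix(rnorm(ng * n_lines, sd = ns[["gene"]]), ng, n_lines)
    B <- truth$intercepts$gene + E
    if (length(clamp_idx)) {
      free <- setdiff(seq_len(ng), clamp_idx)
      G <- matrix(0, ng, n_lines)
      G[clamp_idx, ] <- clamp_val
      A_ff <- Diagonal(length(free)) - truth$W[free, free, drop = FALSE]
      rhs <- B[free, , drop = FALSE] +
        as.matrix(truth$W[free, clamp_idx, drop = FALSE] %*% G[clamp_idx, , drop = FALSE])
      G[free, ] <- as.matrix(Matrix::solve(A_ff, rhs))
    } else {
      G <- steady_solve(truth$W, B)
    }
    Gobs <- G
    M <- as.matrix(truth$V %*% G) + truth$intercepts$metabolite +
      matrix(rnorm(nm * n_lines, sd = ns[["metabolite"]]), nm, n_lines)
    A <- as.matrix(truth$U %*% M) + truth$intercepts$trait +
      matrix(rnorm(nt * n_lines, sd = ns[["trait"]]), nt, n_lines)
    dimnames(Gobs) <- list(genes, lines)
    dimnames(M) <- list(truth$metabolite_names, lines)
    dimnames(A) <- list(truth$trait_names, lines)
    rep_rows <- function(line_mat, sd_rep, fixed_rows = integer(0)) {
      base <- t(line_mat)
      out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
        noise <- matrix(rnorm(length(base), sd = sd_rep), nrow(base), ncol(base))
        noise[, fixed_rows] <- 0
        base + noise
      }))
      rownames(out) <- as.vector(vapply(seq_len(replicates), function(r)
        paste0(lines, "_r", r), character(length(lines))))
      ord <- order(rep(seq_along(lines), replicates))
      out[ord, , drop = FALSE]
    }
    expr <- rep_rows(Gobs, ns[["gene"]] / 3, fixed_rows = clamp_idx)
    mets <- rep_rows(M, ns[["metabolite"]] / 3)
    panel <- omics_panel(expression = expr, metabolites = mets, traits = t(A),
                         lines = lines, expr_lines = lines,
                         replicates = replicates, gene_ranges = gene_ranges)
    attr(panel, "latent") <- list(E = E, G = G, Gobs = Gobs, M = M, A = A)
    attr(panel, "perturbation") <- perturbation
    panel
  })
}

#' Wrap a planted truth as a predictive model stack
#'
#' Useful for oracle tests and validation studies where the exact coefficients
#' are known: the returned stack predicts with the planted coefficients and
#' intercepts, zero calibration, and the supplied gene ranges.
#'
#' @param truth a `ground_truth`.
#' @param gene_ranges genes x 2 range matrix (e.g. from a simulated panel).
#' @param delta range-shrink fraction passed to the gene layer.
#' @return a [model_stack()].
#' @export
truth_stack <- function(truth, gene_ranges = NULL, delta = 0) {
  model_stack(
    gene = layer_model(truth$W, truth$intercepts$gene, layer = "gene",
                       ranges = gene_ranges, delta = delta),
    metabolite = layer_model(truth$V, truth$intercepts$metabolite,
                             layer = "metabolite"),
    trait = layer_model(truth$U, truth$intercepts$trait, layer = "trait")
  )
}
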