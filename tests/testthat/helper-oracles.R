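# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately naive (plain loops, brute force) so the
# package implementations are checked against a different code path.

# naive damped fixed-point iteration with clamped rows, no bounds
naive_fixed_point <- function(W, b, clamp_idx = integer(0),
                              clamp_val = numeric(0), iters = 100000L,
                              damping = 0.5) {
  g <- rep(0, nrow(W))
  if (length(clamp_idx)) g[clamp_idx] <- clamp_val
  W <- as.matrix(W)
  for (i in seq_len(iters)) {
    g_new <- (1 - damping) * g + damping * (as.vector(W %*% g) + b)
    if (length(clamp_idx)) g_new[clamp_idx] <- clamp_val
    if (max(abs(g_new - g)) < 1e-14) { g <- g_new; break }
    g <- g_new
  }
  g
}

# random stable gene-layer model with wide (inactive) bounds; normalized in
# the induced infinity norm so every clamped free block is contractive too
random_stable_gene_model <- function(n_genes, density = 0.2, radius = 0.7,
                                     range_width = 1e6) {
  W <- matrix(0, n_genes, n_genes)
  mask <- matrix(runif(n_genes^2) < density, n_genes, n_genes)
  diag(mask) <- FALSE
  W[mask] <- runif(sum(mask), -1, 1)
  rad <- max(rowSums(abs(W)))
  if (rad > 0) W <- W * (radius / rad)
  gn <- sprintf("g%03d", seq_len(n_genes))
  dimnames(W) <- list(gn, gn)
  ranges <- cbind(min = rep(-range_width, n_genes),
                  max = rep(range_width, n_genes))
  rownames(ranges) <- gn
  layer_model(W, rnorm(n_genes), layer = "gene", ranges = ranges)
}

# small additive (W = 0) model stack: metabolite/trait responses are exactly
# linear in the gene clamps, so brute-force optima are analytic
toy_additive_stack <- function(n_genes, n_mets = 2, v_coef = NULL,
                               ranges = NULL, seed = 1) {
  set.seed(seed)
  gn <- sprintf("g%03d", seq_len(n_genes))
  mn <- sprintf("m%02d", seq_len(n_mets))
  W <- matrix(0, n_genes, n_genes, dimnames = list(gn, gn))
  V <- if (is.null(v_coef)) matrix(rnorm(n_mets * n_genes), n_mets, n_genes) else v_coef
  dimnames(V) <- list(mn, gn)
  if (is.null(ranges)) {
    ranges <- cbind(min = rep(-1, n_genes), max = rep(1, n_genes))
    rownames(ranges) <- gn
  }
  model_stack(
    gene = layer_model(W, rep(0, n_genes), layer = "gene", ranges = ranges),
    metabolite = layer_model(V, rep(0, n_mets), layer = "metabolite")
  )
}

# minimal line-level panel matching a stack's feature names
toy_panel_for_stack <- function(stack, n_lines = 3, seed = 1, spread = 0.5) {
  set.seed(seed)
  gn <- rownames(stack$gene$coefficients)
  mn <- if (!is.null(stack$metabolite)) rownames(stack$metabolite$coefficients)
  lines <- sprintf("L%02d", seq_len(n_lines))
  G <- matrix(runif(length(gn) * n_lines, -spread, spread), n_lines,
              length(gn), dimnames = list(lines, gn))
  M <- NULL
  if (!is.null(mn)) {
    V <- as.matrix(stack$metabolite$coefficients)
    M <- G %*% t(V) +
      matrix(stack$metabolite$intercepts, n_lines, length(mn), byrow = TRUE)
    colnames(M) <- mn
  }
  omics_panel(expression = G, metabolites = M, traits = NULL, lines = lines,
              expr_lines = lines, replicates = 1L,
              gene_ranges = stack$gene$ranges)
}

# per-line objective value of an additive toy under an assignment, computed
# analytically: metabolites shift by V %*% (clamp - g_obs) on clamped genes
additive_objective <- function(stack, spec, panel, assignment) {
  V <- as.matrix(stack$metabolite$coefficients)
  gn <- colnames(V)
  G <- t(panel$expression[, gn, drop = FALSE])
  M0 <- t(panel$metabolites[, rownames(V), drop = FALSE])
  act <- assignment[assignment != "WT"]
  M <- M0
  if (length(act)) {
    for (i in seq_along(act)) {
      g <- names(act)[i]
      cv <- if (act[i] == "KO") stack$gene$ranges[g, "min"] else stack$gene$ranges[g, "max"]
      M <- M + V[, g] %o% (cv - G[g, ])
    }
  }
  w <- rep(0, nrow(V)); names(w) <- rownames(V)
  w[names(spec$maximize)] <- spec$maximize
  w[names(spec$minimize)] <- -spec$minimize
  as.vector(t(M) %*% w)
}

# exhaustive search over all 3^n assignments of an additive toy
brute_force_optimum <- function(stack, spec, panel) {
  gn <- rownames(stack$gene$coefficients)
  modes <- c("WT", "KO", "OE")
  grid <- do.call(expand.grid, rep(list(modes), length(gn)))
  best <- -Inf; best_assign <- NULL
  for (i in seq_len(nrow(grid))) {
    a <- setNames(as.character(unlist(grid[i, ])), gn)
    s <- mean(additive_objective(stack, spec, panel, a))
    if (s > best) { best <- s; best_assign <- a }
  }
  list(score = best, assignment = best_assign)
}

# tiny planted system + standardized panel for integration-style tests
small_planted_panel <- function(seed = 5, n_genes = 40, n_mets = 8,
                                n_traits = 3, n_full = 60, n_expr = 35,
                                noise = 0.3,
                                k = c(gene = 4, metabolite = 3, trait = 2)) {
  cfg <- panel_config(n_genes = n_genes, n_metabolites = n_mets,
                      n_traits = n_traits, n_lines_full = n_full,
                      n_lines_expr = n_expr, replicates = 3,
                      predictors_per_target = k, noise_sd = noise)
  truth <- generate_ground_truth(cfg, seed = seed)
  panel <- simulate_panel(truth, cfg, seed = seed)
  list(cfg = cfg, truth = truth, panel = panel,
       std = standardize_panel(panel))
}
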