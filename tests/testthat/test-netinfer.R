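test_that("MI z-scores rank an identical predictor top and zero out constants", {
  set.seed(1)
  n <- 50
  Y <- cbind(t1 = rnorm(n))
  X <- cbind(same = Y[, 1], indep = rnorm(n), const = rep(1, n))
  scr <- mi_zscores(Y, X)
  expect_s3_class(scr, "candidate_screen")
  expect_equal(which.max(scr$z["t1", ]), c(same = 1L))
  expect_equal(scr$mi["t1", "const"], 0)
  expect_equal(scr$z["t1", "const"], 0)
  expect_error(mi_zscores(Y, X, bins = 1), "bins")
  expect_error(mi_zscores(Y, X, bins = 30), "bins")
  expect_error(mi_zscores(Y[1:10, , drop = FALSE], X[1:10, ]), "20 lines")
})

test_that("independent normals rarely exceed z = 2 and self-pairs are excluded", {
  set.seed(2)
  n <- 500
  M <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, sprintf("f%02d", 1:12)))
  scr <- mi_zscores(M, M)
  expect_true(all(is.na(diag(scr$z))))
  frac <- mean(scr$z >= 2, na.rm = TRUE)
  expect_lt(frac, 0.10)
})

test_that("candidate selection respects the threshold at both extremes", {
  set.seed(3)
  Y <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("x", 1:6)))
  scr <- mi_zscores(Y, X)
  all_kept <- select_candidates(scr, 0)
  expect_true(all(lengths(all_kept) == 6))
  none <- select_candidates(scr, Inf)
  expect_true(all(lengths(none) == 0))
  expect_setequal(attr(none, "empty_targets"), c("a", "b", "c"))
})

test_that("LASSO on an orthonormal design obeys the soft-threshold rule", {
  set.seed(4)
  n <- 64; p <- 8
  raw <- matrix(rnorm(n * p), n, p)
  Q <- qr.Q(qr(scale(raw, scale = FALSE)))
  X <- Q * sqrt(n)  # columns: mean ~0, crossprod(X)/n = I
  colnames(X) <- paste0("x", 1:p)
  beta <- c(2, -1.5, 0.8, 0.4, 0, 0, 0, 0)
  y <- as.vector(X %*% beta)  # noiseless for an exact rule
  lam <- 0.5
  b_ols <- as.vector(crossprod(X, y - mean(y))) / n
  expected_support <- colnames(X)[abs(b_ols) > lam]
  fit <- lasso_refit(y, X, t_lasso = lam)
  expect_setequal(fit$support, expected_support)
  # OLS refit on the support reproduces the planted coefficients
  expect_equal(unname(fit$coefficients[order(names(fit$coefficients))]),
               beta[abs(b_ols) > lam], tolerance = 1e-8)
})

test_that("full shrinkage gives the empty model; planted support is recovered", {
  set.seed(5)
  n <- 100
  X <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, sprintf("c%02d", 1:20)))
  y <- 1.2 * X[, 3] - 0.9 * X[, 7] + 0.7 * X[, 11] + rnorm(n, sd = 0.1)
  big <- lasso_refit(y, X, t_lasso = 100)
  expect_length(big$support, 0)
  expect_equal(big$intercept, mean(y))
  mod <- lasso_refit(y, X, t_lasso = 0.05)
  expect_true(all(c("c03", "c07", "c11") %in% mod$support))
  # empty candidate set degenerates to the intercept model
  none <- lasso_refit(y, X[, 0, drop = FALSE], t_lasso = 0.1)
  expect_equal(none$intercept, mean(y))
})

test_that("fitted layers recover a noiseless planted panel", {
  pp <- small_planted_panel(seed = 31, noise = 0, n_expr = 40, n_full = 60)
  # with the screen wide open the LASSO+OLS chain recovers the linear map
  m0 <- fit_layer(pp$std, "metabolite", z_star = 0, t_lasso = "cv_min", seed = 1)
  expect_true(all(m0$fit$training_r > 0.99))
  m <- fit_layer(pp$std, "metabolite", z_star = 1, t_lasso = "cv", seed = 1)
  g <- fit_layer(pp$std, "gene", z_star = 2, t_lasso = "cv", seed = 1)
  expect_true(all(Matrix::diag(g$coefficients) == 0))  # no self-loops
  # screening-then-LASSO never selects a predictor below the z threshold
  scr <- mi_zscores(layer_matrices(pp$std, "metabolite")$targets,
                    layer_matrices(pp$std, "metabolite")$predictors)
  edges <- model_edges(m, "metabolite")
  z_of_edges <- mapply(function(t, p) scr$z[t, p], edges$target, edges$predictor)
  expect_true(all(z_of_edges >= 1))
})

test_that("refit on the true support reproduces planted coefficients exactly", {
  pp <- small_planted_panel(seed = 32, noise = 0, n_expr = 40, n_full = 60)
  p <- average_replicates(pp$panel)  # unstandardized: planted scale
  X <- p$expression[p$expr_lines, ]
  M <- p$metabolites[p$expr_lines, ]
  tl <- split(model_edges(pp$truth, "metabolite")$predictor,
              model_edges(pp$truth, "metabolite")$target)
  for (met in names(tl)[1:4]) {
    fit <- lasso_refit(M[, met], X[, tl[[met]], drop = FALSE], t_lasso = 0)
    planted <- setNames(as.matrix(pp$truth$V)[met, tl[[met]]], tl[[met]])
    expect_equal(fit$coefficients[names(planted)], planted, tolerance = 1e-8)
  }
})

test_that("cross-validation is seeded, honest and pessimistic vs training", {
  pp <- small_planted_panel(seed = 33)
  m <- fit_layer(pp$std, "metabolite", z_star = 1, t_lasso = "cv", seed = 1)
  cv1 <- cross_validate(pp$std, "metabolite", k_folds = 5, z_star = 1, seed = 7)
  cv2 <- cross_validate(pp$std, "metabolite", k_folds = 5, z_star = 1, seed = 7)
  expect_identical(cv1$per_target, cv2$per_target)
  expect_gt(mean(m$fit$training_r, na.rm = TRUE), cv1$mean_cv_r)
  expect_error(cross_validate(pp$std, "metabolite", k_folds = 1), "k_folds")
})

test_that("pure-noise targets cross-validate to r ~ 0", {
  set.seed(44)
  n <- 60
  lines <- sprintf("L%03d", 1:n)
  X <- matrix(rnorm(n * 30), n, 30, dimnames = list(lines, sprintf("g%03d", 1:30)))
  Y <- matrix(rnorm(n * 5), n, 5, dimnames = list(lines, sprintf("m%02d", 1:5)))
  pan <- omics_panel(expression = X, metabolites = Y, traits = NULL,
                     lines = lines, expr_lines = lines, replicates = 1)
  cv <- cross_validate(pan, "metabolite", k_folds = 5, z_star = 1, seed = 1)
  expect_lt(abs(cv$mean_cv_r), 2 / sqrt(n))
})

test_that("bootstrap PPV/FPR handles the exact, disjoint and null cases", {
  universe <- sprintf("g%03d", 1:50)
  ref <- list(m1 = universe[1:10], m2 = universe[11:15])
  exact <- bootstrap_ppv_fpr(ref, ref, universe, n_boot = 500, seed = 1)
  expect_equal(exact$ppv, 1)
  expect_equal(exact$fpr, 0)
  expect_lte(exact$p_ppv, 1 / 100)
  disjoint <- bootstrap_ppv_fpr(list(m1 = universe[21:30], m2 = universe[31:35]),
                                ref, universe, n_boot = 500, seed = 1)
  expect_equal(disjoint$ppv, 0)
  # null PPV mean matches the hypergeometric expectation |R| / |U|
  expect_lt(abs(exact$null_ppv_mean - mean(c(10, 5) / 50)),
            2 * exact$null_ppv_sd + 1e-9)
  # empty inferred support: PPV undefined, reported missing
  empty <- bootstrap_ppv_fpr(list(m1 = character(0)),
                             list(m1 = universe[1:5]), universe,
                             n_boot = 100, seed = 1)
  expect_true(is.na(empty$ppv))
})

test_that("degree diagnostics: constant degrees, power-law MLE, empty model", {
  gn <- sprintf("g%03d", 1:30)
  W <- matrix(0, 30, 30, dimnames = list(gn, gn))
  for (i in 1:30) W[i, setdiff(seq_len(30), i)[1:5]] <- 1
  m <- layer_model(W, rep(0, 30), layer = "gene")
  d <- degree_powerlaw(m)
  expect_equal(d$mean_degree, 5)
  empty <- layer_model(matrix(0, 30, 30, dimnames = list(gn, gn)),
                       rep(0, 30), layer = "gene")
  d0 <- degree_powerlaw(empty)
  expect_equal(d0$mean_degree, 0)
  expect_true(is.na(d0$exponent))
  # sampling oracle: in-degrees drawn from a discrete power law, exponent 2.5
  set.seed(8)
  alpha <- 2.5
  n_nodes <- 1000
  xs <- 1:900
  pmf <- xs^(-alpha); pmf <- pmf / sum(pmf)
  deg <- sample(xs, n_nodes, replace = TRUE, prob = pmf)
  gn2 <- sprintf("n%04d", 1:n_nodes)
  W2 <- Matrix::sparseMatrix(
    i = rep(seq_len(n_nodes), deg),
    j = unlist(lapply(seq_len(n_nodes), function(i)
      sample(setdiff(seq_len(n_nodes), i), deg[i]))),
    x = 1, dims = c(n_nodes, n_nodes), dimnames = list(gn2, gn2))
  d2 <- degree_powerlaw(layer_model(W2, rep(0, n_nodes), layer = "gene"))
  expect_lt(abs(d2$exponent - alpha), 0.2)
})

test_that("noise robustness curve starts at the training r and decays", {
  pp <- small_planted_panel(seed = 35)
  m <- fit_layer(pp$std, "metabolite", z_star = 1, t_lasso = "cv", seed = 1)
  curve <- noise_robustness(pp$std, m, noise_levels = c(0, 0.5, 2, 50),
                            seed = 2, n_rep = 5)
  expect_equal(curve$mean_r[1], mean(m$fit$training_r, na.rm = TRUE),
               tolerance = 1e-10)
  expect_true(all(diff(curve$mean_r) < 0.05))  # non-increasing up to MC noise
  expect_lt(abs(curve$mean_r[4]), 0.1)         # huge noise: r ~ 0
})

test_that("threshold sweep reports CV performance per operating point", {
  pp <- small_planted_panel(seed = 36, n_genes = 25, n_mets = 5,
                            n_expr = 30, n_full = 40)
  sw <- sweep_inference(pp$std, "metabolite", z_grid = c(1, 2),
                        t_grid = "cv", k_folds = 4, seed = 1)
  expect_equal(nrow(sw), 2)
  expect_true(all(c("z_star", "t_lasso", "mean_cv_r", "mean_support") %in%
                    colnames(sw)))
  expect_false(is.unsorted(rev(sw$mean_cv_r)))
})
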