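sig <- function(met, plus = character(0), minus = character(0), eps = 0.01) {
  structure(list(metabolite = met, plus = plus, minus = minus, epsilon = eps),
            class = "perturbation_signature")
}

test_that("signature membership follows the planted linear effects", {
  # additive toy: effect of clamping g on metabolite m is v_mg * (clamp - g_obs)
  V <- rbind(m01 = c(2, 0, 0), m02 = c(0, -1.5, 0), m03 = c(0, 0, 0))
  colnames(V) <- sprintf("g%03d", 1:3)
  stack <- toy_additive_stack(3, n_mets = 3, v_coef = V)
  panel <- toy_panel_for_stack(stack, n_lines = 5, seed = 2)
  sigs <- build_signatures(stack, panel, epsilon = 0.01)
  # positive coefficient: OE raises, KO lowers
  expect_true("g001:OE" %in% sigs$m01$plus)
  expect_true("g001:KO" %in% sigs$m01$minus)
  # negative coefficient: reversed
  expect_true("g002:OE" %in% sigs$m02$minus)
  expect_true("g002:KO" %in% sigs$m02$plus)
  # metabolite with zero coefficients: both sets empty
  expect_length(sigs$m03$plus, 0)
  expect_length(sigs$m03$minus, 0)
  # analytic oracle for the mean relative change
  D <- attr(sigs, "delta")
  G <- t(panel$expression)
  pop_sd <- sd(panel$metabolites[, "m01"])
  expected <- mean(2 * (stack$gene$ranges["g001", "max"] - G["g001", ])) / pop_sd
  expect_equal(unname(D["g001:OE", "m01"]), expected, tolerance = 1e-10)
  expect_error(build_signature(stack, panel, "nope"), "unknown metabolite")
})

test_that("predicted correlation handles identical, mirrored and disjoint sets", {
  a <- sig("a", plus = c("g1:OE", "g2:KO"), minus = c("g3:OE"))
  expect_equal(predicted_correlation(a, a), 1)
  mirror <- sig("b", plus = c("g3:OE"), minus = c("g1:OE", "g2:KO"))
  expect_equal(predicted_correlation(a, mirror), -1)
  disj <- sig("c", plus = c("g8:OE"), minus = c("g9:KO"))
  expect_equal(predicted_correlation(a, disj), 0)
  # symmetry
  half <- sig("d", plus = c("g1:OE"), minus = character(0))
  expect_equal(predicted_correlation(a, half), predicted_correlation(half, a))
  # subset normalization: a subset relationship scores 1 under "min"
  expect_equal(predicted_correlation(a, half, method = "min"), 1)
  expect_lt(predicted_correlation(a, half, method = "jaccard"), 1)
  # fully empty pair is undefined
  e1 <- sig("e1"); e2 <- sig("e2")
  expect_true(is.na(predicted_correlation(e1, e2)))
})

test_that("shared-predictor metabolites rank above unrelated ones (AUC)", {
  aucs <- sapply(1:8, function(seed) {
    set.seed(seed)
    n_genes <- 30
    gn <- sprintf("g%03d", 1:n_genes)
    # two groups of metabolites: within-group share >= 80% of signed predictors
    base1 <- sample(gn, 10); base2 <- setdiff(gn, base1)[1:10]
    coef1 <- runif(10, 0.5, 1) * sign(rnorm(10))
    coef2 <- runif(10, 0.5, 1) * sign(rnorm(10))
    V <- matrix(0, 4, n_genes, dimnames = list(sprintf("m%02d", 1:4), gn))
    V[1, base1] <- coef1
    V[2, base1[1:8]] <- coef1[1:8]   # 80% shared, same signs
    V[3, base2] <- coef2
    V[4, base2[1:8]] <- coef2[1:8]
    stack <- toy_additive_stack(n_genes, n_mets = 4, v_coef = V)
    panel <- toy_panel_for_stack(stack, n_lines = 10, seed = seed)
    R <- predicted_correlation_matrix(build_signatures(stack, panel, 0.01))
    shared <- c(R["m01", "m02"], R["m03", "m04"])
    unrelated <- c(R["m01", "m03"], R["m01", "m04"], R["m02", "m03"],
                   R["m02", "m04"])
    mean(outer(shared, unrelated, ">") + 0.5 * outer(shared, unrelated, "=="))
  })
  expect_gt(mean(aucs), 0.9)
})

test_that("precision/recall/F arithmetic is exact on fixtures", {
  # three pairs: called by both, model only, empirical only -> P = R = 0.5
  mets <- c("a", "b", "c", "d")
  P <- diag(1, 4); dimnames(P) <- list(mets, mets)
  E <- P
  P["a", "b"] <- P["b", "a"] <- 0.9; E["a", "b"] <- E["b", "a"] <- 0.9  # both
  P["a", "c"] <- P["c", "a"] <- 0.8; E["a", "c"] <- E["c", "a"] <- 0.1  # model
  P["b", "c"] <- P["c", "b"] <- 0.1; E["b", "c"] <- E["c", "b"] <- 0.85 # emp
  cc <- precision_recall_f(P, E, cutoff_k = 0.5)
  expect_equal(cc$precision, 0.5)
  expect_equal(cc$recall, 0.5)
  expect_equal(cc$f_score, 0.5)
  # F from P = 0.6, R = 0.3 is 0.4 (harmonic mean)
  expect_equal(2 * 0.6 * 0.3 / (0.6 + 0.3), 0.4)
  # perfect prediction
  perfect <- precision_recall_f(E, E, cutoff_k = 0.5)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f_score, 1)
  # restriction to strong empirical pairs changes the universe
  cc2 <- precision_recall_f(P, E, cutoff_k = 0.5, min_emp_r = 0.5)
  expect_equal(cc2$n_pairs, 2)
  expect_equal(cc2$precision, 1)
})

test_that("dendrograms join identical signatures first and serialize to Newick", {
  s1 <- sig("x", plus = c("g1:OE", "g2:OE"))
  s2 <- sig("y", plus = c("g1:OE", "g2:OE"))
  s3 <- sig("z", plus = c("g9:KO"))
  hc <- signature_dendrogram(list(s1, s2, s3))
  grp <- stats::cutree(hc, k = 2)
  expect_setequal(names(grp)[grp == grp[["x"]]], c("x", "y"))
  expect_equal(hc$height[1], 0)
  nw <- as_newick(hc)
  expect_match(nw, "^\\(")
  expect_equal(sort(ape::read.tree(text = nw)$tip.label), c("x", "y", "z"))
  # ultrametric distances are reproduced exactly by average linkage
  D <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hc2 <- signature_dendrogram(1 - D, linkage = "average")  # 1 - (1 - D) = D
  expect_equal(as.matrix(stats::cophenetic(hc2))[c("a", "b", "c"), c("a", "b", "c")],
               D)
})

test_that("Mantel test: identity, affine invariance and permutation p", {
  set.seed(30)
  d <- as.matrix(dist(matrix(rnorm(15 * 3), 15, 3)))
  m <- mantel_test(d, d, n_perm = 199, seed = 1)
  expect_equal(m$r, 1)
  expect_equal(m$p, 1 / 200)
  aff <- mantel_test(d, 3 * d + 2, n_perm = 99, seed = 1)
  expect_equal(aff$r, 1, tolerance = 1e-12)
  expect_warning(res <- mantel_test(d * 0 + 1 - diag(15), d, n_perm = 99),
                 "constant")
  expect_true(is.na(res$r))
})

test_that("overlap enrichment scores direction-consistent matches", {
  universe <- sprintf("g%02d", 1:30)
  proposed <- perturbation_set(ko = c("g01", "g02"), oe = c("g03"))
  # all proposals match: KO genes down, OE genes up
  obs_all <- data.frame(gene = c("g01", "g02", "g03"),
                        direction = c("down", "down", "up"))
  res <- overlap_enrichment(proposed, obs_all, universe, n_random = 200, seed = 1)
  expect_equal(res$overlap_pct, 100)
  expect_lt(res$p_empirical, 0.05)
  # observed empty: overlap 0
  res0 <- overlap_enrichment(proposed, obs_all[0, ], universe,
                             n_random = 50, seed = 1)
  expect_equal(res0$overlap_pct, 0)
  # direction mismatch does not count
  obs_wrong <- data.frame(gene = "g01", direction = "up")
  res1 <- overlap_enrichment(proposed, obs_wrong, universe,
                             n_random = 50, seed = 1)
  expect_equal(res1$overlap_pct, 0)
  expect_error(overlap_enrichment(perturbation_set(), obs_all, universe),
               "empty proposed")
  # random proposals: expected overlap ~ |observed| / (2 |universe|)
  set.seed(4)
  many_obs <- data.frame(gene = universe[1:10], direction = "down")
  r2 <- overlap_enrichment(perturbation_set(ko = sample(universe, 10)),
                           many_obs, universe, n_random = 500, seed = 2)
  expect_lt(abs(r2$null_mean - 100 * (10 / 30) / 2), 5)
})
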