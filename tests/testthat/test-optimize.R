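test_that("objective scoring: single trait, balanced symmetry, target mode", {
  state <- list(metabolites = c(m1 = 2, m2 = 2, m3 = 5), traits = c(t1 = 7))
  expect_equal(evaluate_objective(objective_spec(maximize = "t1"), state), 7)
  # equal values with balanced weights cancel
  bal <- objective_spec(maximize = "m1", minimize = "m2")
  expect_equal(evaluate_objective(bal, state), 0)
  # weighted combination
  wspec <- objective_spec(maximize = c(m3 = 2), minimize = c(m1 = 1))
  expect_equal(evaluate_objective(wspec, state), 2 * 5 - 2)
  # target mode scores the negative distance to the target
  tg <- objective_spec(maximize = "m3", mode = "target", target_value = 4)
  expect_equal(evaluate_objective(tg, state), -1)
  # alpha = 1 bi-objective reduces to the primary spec alone
  bi <- objective_spec(maximize = "m3", secondary = objective_spec(maximize = "t1"),
                       alpha = 1)
  expect_equal(evaluate_objective(bi, state), 5)
  expect_error(evaluate_objective(objective_spec(maximize = "nope"), state),
               "not found")
  expect_error(objective_spec(maximize = "a", minimize = "a"), "disjoint")
})

test_that("efficiency arithmetic matches the relative-change convention", {
  expect_equal(efficiency(3.2731, 1), 227.31, tolerance = 1e-10)
  expect_equal(efficiency(1, 1), 0)
  expect_equal(efficiency(-1, -2), 50)        # sign handled by |denominator|
  expect_equal(efficiency(0.5, 0, fallback_sd = 2), 25,
               ignore_attr = TRUE)  # sd fallback, flagged
  expect_equal(attr(efficiency(0.5, 0, fallback_sd = 2), "sd_denominator"), 1L)
  expect_error(efficiency(0.5, 0), "fallback_sd")
  expect_error(efficiency(NaN, NaN), "non-finite")
})

test_that("single scan enumerates 2 x genes records plus an exact wild-type row", {
  stack <- toy_additive_stack(10, seed = 2)
  panel <- toy_panel_for_stack(stack, n_lines = 4, seed = 3)
  spec <- objective_spec(maximize = "m01")
  sc <- scan_single(stack, spec, panel)
  expect_equal(nrow(sc$records), 21)  # WT + 10 genes x 2 modes
  expect_equal(sc$records$label[1], "WT")
  expect_true(all(sc$efficiency[1, ] == 0))
  # efficiency of the empty perturbation is 0 for every line & objective
  spec2 <- objective_spec(maximize = "m01", minimize = "m02")
  sc2 <- scan_single(stack, spec2, panel)
  expect_true(all(sc2$efficiency[1, ] == 0))
})

test_that("a gene that alone feeds the objective wins the single scan", {
  V <- matrix(0, 1, 5, dimnames = list("m01", sprintf("g%03d", 1:5)))
  V["m01", "g003"] <- 1
  stack <- toy_additive_stack(5, n_mets = 1, v_coef = V)
  panel <- toy_panel_for_stack(stack, n_lines = 3, seed = 1)
  sc <- scan_single(stack, objective_spec(maximize = "m01"), panel)
  best <- rank_perturbations(sc, "mean_efficiency")[1, ]
  expect_equal(best$label, "g003:OE")
})

test_that("single scan agrees with an independent per-line enumeration oracle", {
  set.seed(11)
  # coupled gene layer, bounds wide enough that projection never activates
  n <- 12
  gn <- sprintf("g%03d", 1:n)
  W <- matrix(runif(n * n, -1, 1) * (matrix(runif(n * n), n, n) < 0.3), n, n)
  diag(W) <- 0
  W <- W * (0.3 / max(rowSums(abs(W))))
  dimnames(W) <- list(gn, gn)
  ranges <- cbind(min = rep(-10, n), max = rep(10, n)); rownames(ranges) <- gn
  V <- matrix(rnorm(4 * n), 4, n, dimnames = list(sprintf("m%02d", 1:4), gn))
  stack <- model_stack(
    gene = layer_model(W, rep(0, n), layer = "gene", ranges = ranges),
    metabolite = layer_model(V, rnorm(4), layer = "metabolite"))
  panel <- toy_panel_for_stack(stack, n_lines = 8, seed = 12)
  spec <- objective_spec(maximize = c("m01", "m02"), minimize = "m03")
  sc <- scan_single(stack, spec, panel)
  # oracle: per line, clamp + direct linear solve + layer propagation by hand
  genes <- rownames(W)
  for (lab in c("g005:KO", "g011:OE")) {
    g <- sub(":.*", "", lab); mode <- sub(".*:", "", lab)
    cv <- if (mode == "KO") stack$gene$ranges[g, "min"] else stack$gene$ranges[g, "max"]
    for (line in panel$expr_lines[c(1, 7)]) {
      gobs <- panel$expression[line, genes]
      b <- gobs - as.vector(W %*% gobs)   # per-line calibration absorbed
      free <- setdiff(seq_along(genes), match(g, genes))
      gsol <- numeric(length(genes)); gsol[match(g, genes)] <- cv
      A <- diag(length(free)) - W[free, free]
      gsol[free] <- solve(A, b[free] + W[free, match(g, genes)] * cv)
      m_obs <- panel$metabolites[line, rownames(V)]
      eps_m <- m_obs - (as.vector(V %*% gobs) + stack$metabolite$intercepts)
      m_pred <- as.vector(V %*% gsol) + stack$metabolite$intercepts + eps_m
      names(m_pred) <- rownames(V)
      s_oracle <- m_pred["m01"] / 2 + m_pred["m02"] / 2 - m_pred["m03"]
      expect_equal(unname(sc$score[lab, line]), unname(s_oracle),
                   tolerance = 1e-8)
    }
  }
})

test_that("pair scan combinatorics and additivity on independent pathways", {
  stack <- toy_additive_stack(5, seed = 4)
  panel <- toy_panel_for_stack(stack, n_lines = 3, seed = 5)
  spec <- objective_spec(maximize = "m01")
  sc <- scan_pairs(stack, spec, panel, include_singles = FALSE)
  expect_equal(nrow(sc$records), 1 + choose(5, 2) * 4)  # WT + 10 pairs x 4
  sc_full <- scan_pairs(stack, spec, panel, include_singles = TRUE)
  expect_equal(nrow(sc_full$records), 1 + 10 + 40)
  # additive model: pair score = WT + single effects summed
  singles <- scan_single(stack, spec, panel)
  eff1 <- sweep(singles$score, 2, singles$score[1, ])
  for (lab in c("g001:KO+g002:OE", "g003:OE+g004:OE")) {
    parts <- strsplit(lab, "+", fixed = TRUE)[[1]]
    pred <- singles$score[1, ] + eff1[parts[1], ] + eff1[parts[2], ]
    expect_equal(unname(sc_full$score[lab, ]), unname(pred), tolerance = 1e-8)
  }
  # the exhaustive pair scan (with degenerate singles) dominates the singles
  expect_gte(max(sc_full$records$mean_score), max(singles$records$mean_score))
  expect_error(scan_pairs(stack, spec, panel, budget = 0), "budget")
})

test_that("budgeted pair sampling is seeded and within budget", {
  stack <- toy_additive_stack(8, seed = 6)
  panel <- toy_panel_for_stack(stack, n_lines = 3, seed = 6)
  spec <- objective_spec(maximize = "m01")
  s1 <- scan_pairs(stack, spec, panel, budget = 5, seed = 9, include_singles = FALSE)
  s2 <- scan_pairs(stack, spec, panel, budget = 5, seed = 9, include_singles = FALSE)
  expect_identical(s1$records, s2$records)
  expect_equal(nrow(s1$records), 1 + 5 * 4)
})

test_that("greedy search reaches the brute-force optimum on additive toys", {
  for (seed in c(3, 8)) {
    stack <- toy_additive_stack(6, n_mets = 2, seed = seed)
    panel <- toy_panel_for_stack(stack, n_lines = 3, seed = seed + 1)
    spec <- objective_spec(maximize = "m01", minimize = "m02")
    gm <- greedy_multi(stack, spec, panel, max_rounds = 12)
    bf <- brute_force_optimum(stack, spec, panel)
    expect_equal(gm$mean_score, bf$score, tolerance = 1e-8)
    expect_true(all(diff(gm$trajectory$mean_score) > 0))
  }
})

test_that("greedy never falls below the best single perturbation", {
  pp <- small_planted_panel(seed = 50, n_genes = 8, n_mets = 3, n_traits = 1,
                            n_full = 12, n_expr = 10,
                            k = c(gene = 2, metabolite = 2, trait = 1))
  stack <- truth_stack(pp$truth, gene_ranges = pp$panel$gene_ranges)
  panel <- average_replicates(pp$panel)
  spec <- objective_spec(maximize = "m01")
  sc <- scan_single(stack, spec, panel)
  gm <- greedy_multi(stack, spec, panel, max_rounds = 10)
  expect_gte(gm$mean_score + 1e-9, max(sc$records$mean_score))
  # on a single-gene model one round reproduces the scan winner
  one <- greedy_multi(stack, spec, panel, genes = "g003", max_rounds = 1)
  sc3 <- scan_single(stack, spec, panel, genes = "g003")
  expect_equal(one$mean_score, max(sc3$records$mean_score), tolerance = 1e-9)
})

test_that("ranking is stable, criterion-sensitive and tie-preserving", {
  rec <- data.frame(label = c("a:KO", "b:KO", "c:KO"),
                    gene = c("a", "b", "c"), mode = "KO", converged = TRUE,
                    stringsAsFactors = FALSE)
  score <- rbind(c(0, 0), c(5, 0), c(2, 2))
  eff <- rbind(c(5, 3), c(5, 3), c(1, 1))
  scan <- structure(list(records = cbind(rec,
                                         mean_score = rowMeans(score),
                                         mean_efficiency = rowMeans(eff),
                                         min_efficiency = apply(eff, 1, min),
                                         max_efficiency = apply(eff, 1, max),
                                         max_property = apply(score, 1, max),
                                         best_line = "L1"),
                         score = score, efficiency = eff,
                         lines = c("L1", "L2")), class = "perturbation_scan")
  by_eff <- rank_perturbations(scan, "mean_efficiency")
  expect_equal(by_eff$label, c("a:KO", "b:KO", "c:KO"))  # tie keeps input order
  by_max <- rank_perturbations(scan, "mean_max_property")
  expect_equal(by_max$label[1], "b:KO")  # high max, despite tie on efficiency
})

test_that("landscape statistics match a hand count on a two-line fixture", {
  eff <- rbind(c(10, -5), c(3, 4), c(-1, -1))
  rec <- data.frame(label = c("p1", "p2", "p3"), stringsAsFactors = FALSE)
  scan <- structure(list(records = rec, efficiency = eff,
                         lines = c("L1", "L2")), class = "perturbation_scan")
  ls <- landscape_stats(scan, thresholds = c(-100, 2, 100))
  # below all efficiencies: every perturbation counts in every line
  expect_equal(ls$count_mean[1], 3)
  expect_equal(ls$prob_mean[1], 1)
  # threshold 2: line 1 has {10, 3}, line 2 has {4} -> counts (2, 1)
  expect_equal(ls$count_mean[2], 1.5)
  expect_equal(ls$count_sd[2], sd(c(2, 1)))
  # p1 exceeds in 1/2 lines, p2 in 2/2, p3 in 0/2
  expect_equal(ls$prob_mean[2], mean(c(0.5, 1, 0)))
  # above all: empty landscape
  expect_equal(ls$count_mean[3], 0)
  expect_equal(ls$prob_mean[3], 0)
})
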