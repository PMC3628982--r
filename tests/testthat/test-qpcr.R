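test_that("standard curve fit and inversion recover known dilutions", {
  x <- -4:0
  curve <- fit_standard_curve(x, -3.3219 * x + 30)
  expect_equal(curve$slope, -3.3219, tolerance = 1e-6)
  expect_equal(curve$intercept, 30, tolerance = 1e-6)
  expect_equal(curve$efficiency, 1, tolerance = 1e-4)
  expect_equal(curve$r_squared, 1)
  # noise-free inversion is exact across the dilution range
  expect_equal(quantify_sample(-3.3219 * x + 30, curve), 10^x)
  expect_equal(quantify_sample(curve$intercept, curve), 1)
  expect_equal(quantify_sample(curve$intercept + curve$slope, curve), 10)
  # degenerate inputs
  expect_error(fit_standard_curve(c(0, 1), c(30, 27)), ">= 3 distinct")
  expect_error(fit_standard_curve(-4:0, rep(30, 5)), "zero slope")
  pos <- fit_standard_curve(-4:0, 3.3 * (-4:0) + 30)
  expect_error(quantify_sample(25, pos), "negative")
})

test_that("noisy standards recover the slope within sampling error", {
  set.seed(21)
  x <- rep(-4:0, each = 3)
  slope_hat <- replicate(50, {
    ct <- -3.3219 * x + 30 + rnorm(length(x), 0, 0.1)
    fit_standard_curve(x, ct)$slope
  })
  se <- 0.1 / sqrt(sum((x - mean(x))^2))
  expect_true(mean(abs(slope_hat + 3.3219) < 3 * se) > 0.9)
})

test_that("relative expression is a plain ratio with a guarded reference", {
  expect_equal(relative_expression(2, 2), 1)
  expect_equal(relative_expression(4, 2), 2)
  expect_error(relative_expression(1, 0), "positive")
  # scale invariance: rescaling the standard units cancels
  expect_equal(relative_expression(4 * 7, 2 * 7), relative_expression(4, 2))
})

test_that("Levene gate selects Student or Welch appropriately", {
  r <- levene_gate_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$levene_p, 1)
  expect_equal(r$t_p, 1)
  expect_equal(r$variant, "student")
  # equal means, variance ratio 10 at n = 10: Levene rejects -> Welch
  set.seed(31)
  a <- rnorm(10, 5, 1); b <- rnorm(10, 5, 10)
  expect_equal(levene_gate_t_test(a, b)$variant, "welch")
  # similar variances -> Student
  set.seed(32)
  expect_equal(levene_gate_t_test(rnorm(10), rnorm(10))$variant, "student")
  # complete separation with zero variance: bounded p with warning
  expect_warning(r0 <- levene_gate_t_test(c(0, 0, 0), c(5, 5, 5)),
                 "zero variance")
  expect_lt(r0$t_p, 1e-300)
  expect_error(levene_gate_t_test(1, c(1, 2)), "at least 2")
})

test_that("two-way ANOVA decomposes side and day effects", {
  grid <- expand.grid(side = c("dorsal", "ventral"), day = c(4, 8),
                      rep = 1:3)
  # all cells identical -> F = 0, p = 1 everywhere
  r0 <- two_way_anova(rep(1, nrow(grid)), grid$side, grid$day)
  expect_equal(r0$f_value, rep(0, 3))
  expect_equal(r0$p_value, rep(1, 3))
  # additive effects: side +2, day +1, sigma 0.1 -> side and day detected
  set.seed(41)
  y <- 1 + 2 * (grid$side == "dorsal") + 1 * (grid$day == 8) +
    rnorm(nrow(grid), 0, 0.1)
  r <- two_way_anova(y, grid$side, grid$day)
  expect_lt(r$p_value[r$term == "side"], 0.05)
  expect_lt(r$p_value[r$term == "day"], 0.05)
  # interaction p is not spuriously small under additivity (across seeds)
  pint <- vapply(1:30, function(s) {
    set.seed(100 + s)
    y <- 1 + 2 * (grid$side == "dorsal") + (grid$day == 8) +
      rnorm(nrow(grid), 0, 0.5)
    two_way_anova(y, grid$side, grid$day)$p_value[3]
  }, numeric(1))
  expect_lte(mean(pint < 0.05), 0.2)
  # single replicate per cell and unbalanced designs are rejected
  g1 <- expand.grid(side = c("dorsal", "ventral"), day = c(4, 8))
  expect_error(two_way_anova(rnorm(4), g1$side, g1$day), "replicates")
  expect_error(two_way_anova(rnorm(5), c(rep("dorsal", 3), "ventral",
                                         "ventral"),
                             c(4, 8, 4, 8, 4)), "nbalanced")
})

test_that("full qPCR workflow recovers a planted 8:1 dorsal gene", {
  spec <- simulation_spec(seed = 51)
  qp <- simulate_qpcr(spec)
  res <- qpcr_analyze(qp$samples, qp$standards)
  expect_equal(res$curves$TBX5$efficiency, 1, tolerance = 1e-4)
  sub <- res$expression[res$expression$gene == "TBX5" &
                          res$expression$day == 4, ]
  dv <- sub$rel_expr[sub$side == "dorsal"]
  vv <- sub$rel_expr[sub$side == "ventral"]
  ratio <- mean(dv) / mean(vv)
  # delta-method SE of the ratio from replicate spread
  se <- ratio * sqrt(stats::var(dv) / (3 * mean(dv)^2) +
                       stats::var(vv) / (3 * mean(vv)^2))
  expect_lt(abs(ratio - 8), 2 * se + 1e-9)
  # side effect significant for the planted genes
  an <- res$anova
  expect_lt(an$p_value[an$gene == "TBX5" & an$term == "side"], 0.05)
  expect_lt(an$p_value[an$gene == "NTN1" & an$term == "side"], 0.05)
  # dorsal/ventral t-test flags both days
  tt <- res$t_tests[res$t_tests$gene == "TBX5", ]
  expect_true(all(tt$t_p < 0.05))
  # noise-free generation recovers true relative levels exactly
  spec0 <- simulation_spec(seed = 52, qpcr_sigma_ct = 0)
  qp0 <- simulate_qpcr(spec0)
  res0 <- suppressWarnings(qpcr_analyze(qp0$samples, qp0$standards))
  s0 <- res0$expression[res0$expression$gene == "TBX5" &
                          res0$expression$day == 4, ]
  expect_equal(mean(s0$rel_expr[s0$side == "dorsal"]) /
                 mean(s0$rel_expr[s0$side == "ventral"]), 8,
               tolerance = 1e-9)
})
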