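test_that("equal cell means give zero effect sums of squares", {
  y <- c(1, 2, 1, 2, 1, 2, 1, 2)
  a <- rep(c("WT", "APPPS1"), each = 4)
  b <- rep(c("HEM", "HEM", "KO", "KO"), 2)
  at <- two_way_anova(y, a, b)
  expect_lt(max(at$sum_sq[1:3]), 1e-12)
  expect_gt(at$sum_sq[4], 0)
})

test_that("Type III SS match the model-comparison oracle to 1e-10", {
  # balanced cells {10,12},{20,22},{30,32},{40,42}
  y <- c(10, 12, 20, 22, 30, 32, 40, 42)
  a <- rep(c("WT", "APPPS1"), each = 4)
  b <- rep(c("HEM", "HEM", "KO", "KO"), 2)
  at <- two_way_anova(y, a, b)
  or <- oracle_type3(y, a, b)
  expect_equal(unname(at$sum_sq[1:3]), unname(or$ss), tolerance = 1e-12)
  expect_equal(unname(at$F[1:3]), unname(or$F), tolerance = 1e-12)
  expect_equal(unname(at$p[1:3]), unname(or$p), tolerance = 1e-12)

  # unbalanced design with known generating effects
  withr::with_seed(77, {
    a <- rep(c("WT", "WT", "APPPS1", "APPPS1"), times = c(3, 5, 4, 6))
    b <- c(rep(c("HEM", "KO"), c(3, 5)), rep(c("HEM", "KO"), c(4, 6)))
    y <- rnorm(18) + 2 * (a == "APPPS1") + 1.2 * (b == "KO") +
      0.8 * (a == "APPPS1" & b == "KO")
    at <- two_way_anova(y, a, b)
    or <- oracle_type3(y, a, b)
    expect_lt(max(abs(at$sum_sq[1:3] - or$ss)), 1e-10)
    expect_lt(max(abs(at$F[1:3] - or$F)), 1e-10)
    expect_lt(max(abs(at$p[1:3] - or$p)), 1e-10)
    expect_equal(at$df, c(1, 1, 1, 14))
  })
})

test_that("Type III SS are invariant to relabelling factor levels", {
  withr::with_seed(5, {
    a <- rep(c("WT", "WT", "APPPS1", "APPPS1"), times = c(3, 6, 5, 4))
    b <- c(rep(c("HEM", "KO"), c(3, 6)), rep(c("HEM", "KO"), c(5, 4)))
    y <- rnorm(18, 10, 2)
    at1 <- two_way_anova(y, a, b)
    relab <- c(WT = "zWT", APPPS1 = "aAPP")
    at2 <- two_way_anova(y, unname(relab[a]), b)
    expect_equal(at1$sum_sq, at2$sum_sq, tolerance = 1e-12)
    # balanced designs: Type III equals the sequential decomposition
    ab <- rep(c("WT", "APPPS1"), each = 8)
    bb <- rep(rep(c("HEM", "KO"), each = 4), 2)
    yb <- rnorm(16)
    at3 <- two_way_anova(yb, ab, bb)
    seq_ss <- stats::anova(stats::lm(yb ~ factor(ab) * factor(bb)))[["Sum Sq"]]
    expect_equal(unname(at3$sum_sq), unname(seq_ss), tolerance = 1e-10)
  })
})

test_that("degenerate ANOVA inputs are rejected or flagged", {
  expect_error(two_way_anova(1:6, rep("WT", 6), rep(c("HEM", "KO"), 3)),
               "two observed levels")
  a <- c("WT", "WT", "APPPS1", "APPPS1", "WT")
  b <- c("HEM", "HEM", "HEM", "HEM", "KO")
  expect_error(two_way_anova(rnorm(5), a, b), "empty design cell")
  expect_error(two_way_anova(rnorm(4), c("WT", "WT", "APPPS1", "APPPS1"),
                             c("HEM", "KO", "HEM", "KO")), "residual degrees")
  # zero residual variance -> flagged, p undefined
  y <- c(1, 1, 2, 2, 3, 3, 4, 4)
  at <- two_way_anova(y, rep(c("WT", "APPPS1"), each = 4),
                      rep(c("HEM", "HEM", "KO", "KO"), 2))
  expect_true(attr(at, "zero_residual"))
  expect_true(all(is.na(at$p[1:3])))
})

test_that("Sidak adjustment follows its closed form and orderings", {
  withr::with_seed(19, {
    g <- rep(c("WT.HEM", "WT.KO", "APPPS1.HEM", "APPPS1.KO"), each = 5)
    y <- rnorm(20) + 3 * (g == "APPPS1.KO")
    res <- sidak_pairwise(y, g)
    expect_equal(res$m, rep(4, 4))
    expect_equal(res$p_adj, pmin(1 - (1 - res$p_raw)^4, 1), tolerance = 1e-12)
    expect_true(all(res$p_adj >= res$p_raw))

    one <- sidak_pairwise(y, g, comparisons = list(c("APPPS1.KO", "APPPS1.HEM")))
    expect_equal(one$p_adj, one$p_raw)                 # m = 1 identity

    expect_equal(1 - (1 - 0.01)^4, 0.03940399, tolerance = 1e-12)  # m = 4
    expect_error(sidak_pairwise(y, g, comparisons = list(c("A", "B"))),
                 "unknown group")
  })
  # identical data in a pair: zero difference, p = 1
  y2 <- rep(c(5, 6, 5, 6), each = 3)
  g2 <- rep(c("WT.HEM", "WT.KO", "APPPS1.HEM", "APPPS1.KO"), each = 3)
  res2 <- sidak_pairwise(y2, g2, comparisons = list(c("APPPS1.HEM", "WT.HEM")))
  expect_equal(res2$mean_diff, 0)
  expect_equal(res2$p_raw, 1)
  expect_equal(res2$p_adj, 1)
})

test_that("sidak p_adj is monotone in p_raw and in m", {
  p <- seq(0.001, 0.9, length.out = 40)
  for (m in c(1, 2, 4, 8)) {
    padj <- 1 - (1 - p)^m
    expect_true(all(diff(padj) > 0))
    expect_true(all(padj >= p - 1e-15 & padj <= 1))
  }
  expect_true(all((1 - (1 - 0.2)^(1:6)) == cummax(1 - (1 - 0.2)^(1:6))))
})

test_that("unpaired t matches the closed form and its invariances", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  got <- unpaired_t(x, y)
  # closed-form pooled-variance computation
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_expected <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(got$t, t_expected, tolerance = 1e-12)
  expect_equal(got$df, 4)
  expect_equal(got$p, 2 * pt(abs(t_expected), 4, lower.tail = FALSE),
               tolerance = 1e-12)

  same <- unpaired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1)

  scaled <- unpaired_t(10 * x, 10 * y)
  expect_equal(scaled$t, got$t, tolerance = 1e-12)
  expect_equal(scaled$p, got$p, tolerance = 1e-12)

  w <- unpaired_t(c(1, 2, 3, 9), c(4, 5, 6), welch = TRUE)
  expect_false(w$df == 5)           # Welch df is non-integer here
  deg <- unpaired_t(c(2, 2), c(2, 2))
  expect_true(deg$degenerate)
  expect_error(unpaired_t(1, c(2, 3)), "n >= 2")
})

test_that("Mann-Whitney handles the enumerated and tied examples", {
  r1 <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r1$U, 0)
  expect_equal(r1$p, 1 / 3)                   # 2 of the 6 labelings as extreme
  expect_equal(r1$method, "exact")

  r2 <- mann_whitney(5, 5)
  expect_equal(r2$U, 0.5)
  expect_equal(r2$p, 1)
})

test_that("exact Mann-Whitney p equals full enumeration on random samples", {
  withr::with_seed(23, {
    for (i in 1:4) {
      x <- round(rnorm(5), 2); y <- round(rnorm(5), 2)
      got <- mann_whitney(x, y)
      expect_equal(got$method, "exact")
      expect_equal(got$p, oracle_mw_exact(x, y), tolerance = 1e-12)
    }
    # with ties in the pooled sample
    x <- c(1, 1, 2, 3); y <- c(1, 2, 2, 4)
    expect_equal(mann_whitney(x, y)$p, oracle_mw_exact(x, y), tolerance = 1e-12)
    # untied exact agrees with the classical exact distribution
    x <- rnorm(6); y <- rnorm(5)
    expect_equal(mann_whitney(x, y)$p,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  })
})

test_that("large samples fall back to the corrected normal approximation", {
  withr::with_seed(29, {
    x <- rnorm(12); y <- rnorm(13, 1)
    got <- mann_whitney(x, y)
    expect_equal(got$method, "normal")
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    # U statistics complement: U_x + U_y = n_x * n_y
    expect_equal(mann_whitney(x, y)$U + mann_whitney(y, x)$U, 12 * 13)
  })
})

test_that("the stats plan gates post-hoc tests on omnibus significance", {
  gm_null <- c(WT.HEM = 2, WT.KO = 2, APPPS1.HEM = 2, APPPS1.KO = 2)
  gm_eff <- c(WT.HEM = 0.2, WT.KO = 0.3, APPPS1.HEM = 1.8, APPPS1.KO = 3.9)
  mk_tab <- function(gm, seed) {
    tb <- simulate_metric_table(gm, n_per_group = 6, cv = 0.2, seed = seed)
    tb$metric <- "vascular_gfap_pct"; tb$region <- "cortex"
    tb
  }
  # strong effects: omnibus significant, comparisons emitted
  res_eff <- run_stats_plan(mk_tab(gm_eff, 1))
  r <- res_eff[["vascular_gfap_pct/cortex"]]
  expect_s3_class(r$anova, "anova_table")
  expect_false(r$gated_out)
  expect_equal(nrow(r$posthoc), 4)

  # null data at a seed with non-significant omnibus: gated out
  seeds <- 1:20
  gated <- NULL
  for (s in seeds) {
    rr <- run_stats_plan(mk_tab(gm_null, s))[["vascular_gfap_pct/cortex"]]
    if (!is.null(rr$gated_out) && rr$gated_out) { gated <- rr; break }
  }
  expect_false(is.null(gated))
  expect_null(gated$posthoc)
  # the gate can be disabled
  rr2 <- run_stats_plan(mk_tab(gm_null, s), posthoc_gate = FALSE)
  expect_equal(nrow(rr2[["vascular_gfap_pct/cortex"]]$posthoc), 4)

  # two-group plans route to t / Mann-Whitney on transgenic animals
  tb <- mk_tab(gm_eff, 3); tb$metric <- "caa_area_pct"
  res_mw <- run_stats_plan(tb, plan = c(caa_area_pct = "mannwhitney"))
  expect_equal(res_mw[["caa_area_pct/cortex"]]$test, "mannwhitney")
  expect_true(is.numeric(res_mw[["caa_area_pct/cortex"]]$result$U))
})
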