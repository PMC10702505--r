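test_that("identical groups give H = 0, p = 1", {
  r <- kruskal_wallis(list(rep(2, 5), rep(2, 6), rep(2, 4), rep(2, 5)))
  expect_equal(r$H, 0)
  expect_equal(r$p, 1)
})

test_that("the H statistic matches exhaustive rank computation", {
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  # brute-force oracle: ranks are 1..9 with no ties
  N <- 9
  rbar <- c(mean(1:3), mean(4:6), mean(7:9))
  H_oracle <- 12 / (N * (N + 1)) * sum(3 * rbar^2) - 3 * (N + 1)
  r <- kruskal_wallis(groups)
  expect_equal(r$H, H_oracle)
})

test_that("the gate suppresses post hoc tests", {
  set.seed(1)
  vals <- rnorm(120)
  g <- rep(1:4, each = 30)
  r <- posthoc_mwu(vals, g)
  if (r$p > 0.05) {
    expect_true(r$gated)
    expect_equal(nrow(r$pairs), 0)
  }
  # force a gated case deterministically
  r2 <- posthoc_mwu(c(1, 2, 3, 2, 1, 3, 2, 1, 3), rep(1:3, each = 3))
  expect_true(r2$gated)
})

test_that("disjoint small samples give the exact U = 0 p-value", {
  r <- posthoc_mwu(c(1:5, 6:10), rep(c("a", "b"), each = 5), gate_p = 1)
  pr <- r$pairs
  expect_equal(pr$U, 0)                      # all b above all a
  expect_equal(pr$p_raw, 2 / choose(10, 5))  # exact enumeration
  expect_equal(pr$p_adj, pr$p_raw)           # single pair family
})

test_that("Bonferroni adjustment never lowers a p-value and caps at one", {
  set.seed(42)
  for (i in 1:10) {
    vals <- rnorm(4 * 20, mean = rep(c(0, 0.2, 0.6, 1), each = 20))
    r <- posthoc_mwu(vals, rep(1:4, each = 20), gate_p = 1)
    expect_true(all(r$pairs$p_adj >= r$pairs$p_raw))
    expect_true(all(r$pairs$p_adj <= 1))
    expect_equal(nrow(r$pairs), 6)
    # stars consistent with the adjusted thresholds
    stars <- r$pairs$stars
    expect_true(all(stars[r$pairs$p_adj >= 0.05] == "ns"))
    expect_true(all(stars[r$pairs$p_adj < 1e-4] == "****"))
  }
})

test_that("identical pairs adjust to p = 1", {
  vals <- c(rep(1:6, 2), 7:12)
  g <- rep(1:3, each = 6)
  r <- posthoc_mwu(vals, g, gate_p = 1)
  expect_equal(r$pairs$p_adj[r$pairs$group1 == 1 & r$pairs$group2 == 2], 1)
})

test_that("two-group Kruskal-Wallis tracks the Mann-Whitney test", {
  set.seed(7)
  ps <- t(replicate(30, {
    x <- rnorm(15)
    y <- rnorm(15, runif(1, 0, 1))
    kw <- kruskal_wallis(c(x, y), rep(1:2, each = 15))$p
    mw <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = FALSE))$p.value
    c(kw, mw)
  }))
  expect_gt(cor(ps[, 1], ps[, 2], method = "spearman"), 0.99)
})

test_that("correlation maps are symmetric with unit diagonal", {
  d <- data.frame(x = 1:20, y = 2 * (1:20) + 1, z = -(1:20),
                  w = rnorm(20))
  pm <- pearson_map(d, c("x", "y", "z", "w"))
  expect_equal(pm$r["x", "y"], 1)
  expect_equal(pm$r["x", "z"], -1)
  expect_equal(diag(pm$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(pm$r, t(pm$r))
  expect_true(all(abs(pm$r) <= 1 + 1e-12))
  d$c <- rep(1, 20)
  pm2 <- pearson_map(d, c("x", "c"))
  expect_true(is.na(pm2$r["x", "c"]))
})

test_that("the synthetic cohort encodes the expected correlation signs", {
  co <- generate_cohort(cohort_spec(seed = 1))
  m <- two_stage_match(co)
  imp <- impute_structural(m$cohort)
  pm <- pearson_map(imp, c("emph_frac", "fibr_frac", "fev1_fvc",
                           "bv5_tbv", "normal_frac"))
  expect_lt(pm$r["emph_frac", "fev1_fvc"], 0)
  expect_lt(pm$r["bv5_tbv", "fibr_frac"], 0)
  expect_gt(pm$r["bv5_tbv", "normal_frac"], 0)
})

test_that("cohort_tests runs the per-variable chain", {
  co <- generate_cohort(cohort_spec(seed = 1))
  res <- cohort_tests(co[co$category != 3, ],
                      c("WT_Trachea", "Dh_Trachea", "emph_frac"))
  expect_true(all(c("variable", "H", "p_kw", "p_adj") %in% names(res)))
  # wall thickness and emphysema differ across categories by construction
  expect_lt(res$p_kw[res$variable == "WT_Trachea"][1], 0.05)
  expect_lt(res$p_kw[res$variable == "emph_frac"][1], 0.05)
})
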