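# minimal propensity_model for driving greedy_match directly
toy_model <- function(treat_scores, control_scores) {
  d <- data.frame(
    id = seq_len(length(treat_scores) + length(control_scores)),
    .treat = rep(1:0, c(length(treat_scores), length(control_scores))),
    score = c(treat_scores, control_scores))
  structure(list(data = d), class = "propensity_model")
}

test_that("greedy matching takes the nearest unused control", {
  m <- greedy_match(toy_model(0.5, c(0.3, 0.45)), use_caliper = FALSE)
  expect_equal(m$pairs$control_id, 3L)          # the 0.45 control
  expect_equal(nrow(m$pairs), 1)
})

test_that("the caliper refuses distant pairs and drops the subject", {
  m <- greedy_match(toy_model(0.5, 0.9), use_caliper = TRUE, caliper = 0.1)
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$dropped, 1L)
})

test_that("exhausted controls leave treatment subjects unmatched", {
  m <- greedy_match(toy_model(c(0.5, 0.6, 0.7), c(0.55, 0.65)),
                    use_caliper = FALSE)
  expect_equal(nrow(m$pairs), 2)
  expect_length(m$dropped, 1)
  expect_false(any(duplicated(m$pairs$control_id)))
})

test_that("greedy order is descending score with id tie-break", {
  m <- greedy_match(toy_model(c(0.4, 0.4, 0.8), c(0.8, 0.4, 0.41)),
                    use_caliper = FALSE)
  # subject 3 (score .8) first -> control 4 (.8); then subject 1 before 2
  expect_equal(m$pairs$treat_id, c(3L, 1L, 2L))
  expect_equal(m$pairs$control_id[1], 4L)
  expect_equal(m$pairs$control_id[2], 5L)       # 0.4 matched to 0.4
})

test_that("propensity fit recovers the confounding direction", {
  set.seed(10)
  n <- 400
  base <- data.frame(id = seq_len(2 * n), category = rep(c(1, 0), each = n),
                     height = rnorm(2 * n, 165, 6),
                     smoking = rbinom(2 * n, 1, 0.8),
                     copd = rbinom(2 * n, 1, 0.5))
  base$age <- rnorm(2 * n, 70, 7) + 10 * (base$category == 1)
  fp <- fit_propensity(base, 1, 0)
  expect_gt(coef(fp$fit)[["age"]], 0)
  expect_true(all(fp$data$score > 0 & fp$data$score < 1))
  # identical distributions: coefficients near zero
  base$age <- rnorm(2 * n, 70, 7)
  fp0 <- fit_propensity(base, 1, 0)
  se <- summary(fp0$fit)$coefficients[-1, 2]
  expect_true(all(abs(coef(fp0$fit)[-1]) < 3.5 * se))
})

test_that("known logistic coefficients are recovered at n = 500", {
  set.seed(77)
  n <- 1000
  d <- data.frame(id = seq_len(n), age = rnorm(n, 70, 7),
                  height = rnorm(n, 165, 6), smoking = rbinom(n, 1, 0.8),
                  copd = rbinom(n, 1, 0.6))
  beta <- c(int = -8, age = 0.1, height = 0, smoking = 0.5, copd = 0.8)
  eta <- beta["int"] + beta["age"] * d$age + beta["smoking"] * d$smoking +
    beta["copd"] * d$copd
  d$category <- rbinom(n, 1, plogis(eta))
  fp <- fit_propensity(d, 1, 0)
  ci <- suppressMessages(confint.default(fp$fit))
  expect_true(ci["age", 1] < beta["age"] && beta["age"] < ci["age", 2])
  expect_true(ci["copd", 1] < beta["copd"] && beta["copd"] < ci["copd", 2])
})

test_that("perfect separation is reported as an error", {
  d <- data.frame(id = 1:40, category = rep(c(1, 0), each = 20),
                  age = c(rnorm(20, 90, 1), rnorm(20, 40, 1)),
                  height = rnorm(40, 165, 6), smoking = rbinom(40, 1, 0.5),
                  copd = rbinom(40, 1, 0.5))
  expect_error(suppressWarnings(fit_propensity(d, 1, 0)), "separat")
})

test_that("pairwise SMD reproduces the printed balance columns", {
  expect_equal(round(smd_binary_counts(c(37, 38, 39, 39), rep(43, 4)), 3),
               0.085)
  expect_equal(round(smd_binary_counts(c(91, 88, 49, 9, 90),
                                       c(110, 108, 54, 10, 98)), 3), 0.171)
  expect_equal(round(smd_binary_counts(c(0, 1, 0, 0, 2),
                                       c(110, 108, 54, 10, 98)), 3), 0.111)
})

test_that("SMD handles identical groups, zero variance and small groups", {
  d <- data.frame(g = rep(1:2, each = 10), x = rep(c(1, 2), 10),
                  b = rep(0, 20))
  s <- smd(d, c("x", "b"), group = "g")
  expect_equal(s$smd, c(0, 0))
  expect_true(all(s$balanced))
  d2 <- data.frame(g = c(1, 2, 2), x = c(1, 2, 3))
  expect_error(smd(d2, "x", group = "g"), "2 observations")
  pw <- attr(smd(d, "x", group = "g"), "pairwise")
  expect_equal(dim(pw$x), c(2, 2))
})

test_that("matching on equal scores balances everything", {
  set.seed(3)
  base <- data.frame(age = rnorm(60, 70, 7), height = rnorm(60, 165, 6),
                     smoking = rbinom(60, 1, 0.8), copd = rbinom(60, 1, 0.5))
  d <- rbind(base, base)
  d$category <- rep(c(1, 0), each = 60)
  d$id <- seq_len(120)
  fp <- fit_propensity(d, 1, 0)
  g <- greedy_match(fp, use_caliper = TRUE)
  expect_equal(nrow(g$pairs), 60)
  matched <- d[d$id %in% c(g$pairs$treat_id, g$pairs$control_id), ]
  s <- smd(matched, c("age", "height", "smoking", "copd"))
  expect_true(all(s$smd < 1e-8))
})

test_that("two-stage matching returns equal-sized groups", {
  co <- generate_cohort(cohort_spec(seed = 1))
  m <- two_stage_match(co)
  expect_length(unique(m$n_per_group), 1)
  expect_setequal(names(m$groups), c("0", "1", "2", "4"))
  # one-to-one: no control reused within a stage
  for (a in m$audit)
    expect_false(any(duplicated(a$pairs$control_id)))
  expect_equal(sort(unique(m$cohort$category)), c(0, 1, 2, 4))
})

test_that("an unconfounded cohort retains nearly the whole smallest group", {
  co <- generate_cohort(cohort_spec(confounding_scale = 0,
                                    effect_scale = 0, seed = 12))
  m <- two_stage_match(co)
  # greedy caliper matching may drop a couple of boundary subjects even
  # under exchangeability; near-complete retention is the contract
  expect_gte(unname(m$n_per_group[["2"]]), 51)
})

test_that("empty categories are refused by the matcher", {
  co <- generate_cohort(cohort_spec(seed = 1))
  expect_error(two_stage_match(co[co$category != 4, ]), "category 4")
})
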