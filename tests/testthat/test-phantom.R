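test_that("cylinder voxelization matches the analytic volume", {
  spec <- cylinder_spec(r_in = 4, wall = 1.5, len = 40, spacing = 0.5)
  v <- generate_volume(spec)
  analytic <- pi * 4^2 * 40 / prod(v$spacing)
  expect_lt(abs(sum(v$airway_mask) / analytic - 1), 0.05)
})

test_that("zero-noise two-class mixture is recovered exactly", {
  spec <- phantom_spec(dim = c(40, 40, 40), spacing = rep(0.75, 3),
                       airway = NULL,
                       mixture = c(emphysema = 0.2, normal = 0.8),
                       noise_sd = 0, seed = 3)
  r <- classify_parenchyma(generate_volume(spec))
  expect_identical(r$fractions[["emphysema"]], 0.2)
  expect_identical(r$fractions[["normal"]], 0.8)
  expect_identical(r$unclassified, 0)
})

test_that("volume generation is bit-identical for the same seed", {
  spec <- phantom_spec(dim = c(32, 32, 32), spacing = rep(0.75, 3),
                       airway = NULL, noise_sd = 20, seed = 42)
  v1 <- generate_volume(spec)
  v2 <- generate_volume(spec)
  expect_identical(v1$hu, v2$hu)
  expect_identical(v1$labels, v2$labels)
  spec2 <- phantom_spec(dim = c(32, 32, 32), spacing = rep(0.75, 3),
                        airway = NULL, noise_sd = 20, seed = 43)
  expect_false(identical(generate_volume(spec2)$hu, v1$hu))
})

test_that("out-of-grid branches error naming the branch", {
  spec <- cylinder_spec(len = 200)
  expect_error(generate_volume(spec), "Trachea")
})

test_that("airway/vessel overlap errors unless the policy flag is set", {
  ves <- data.frame(name = "v1", parent = "", dx = 0, dy = 0, dz = -1,
                    length_mm = 20, r_mm = 1)
  spec <- phantom_spec(dim = c(48, 48, 48), spacing = rep(0.5, 3),
                       airway = one_branch("Trachea", "", c(0, 0, -1),
                                           20, 3, 1),
                       vessel = ves, mixture = c(normal = 1), noise_sd = 0,
                       seed = 1, vessel_origin = c(12, 12, 22))
  expect_error(generate_volume(spec), "overlap")
  spec$allow_overlap <- TRUE
  v <- generate_volume(spec)
  expect_gt(sum(v$airway_mask), 0)
})

test_that("anisotropic volumes resample to isotropic spacing", {
  spec <- phantom_spec_table1(airway = one_branch("Trachea", "",
                                                  c(0, 0, -1), 60, 4, 1.5),
                              mixture = c(normal = 1), noise_sd = 0,
                              seed = 2)
  v <- generate_volume(spec)
  expect_equal(v$spacing, c(0.75, 0.75, 3))
  iso <- resample_isotropic(v)
  expect_equal(iso$spacing, rep(0.75, 3))
  # tube volume is approximately preserved
  vol_before <- sum(v$airway_mask) * prod(v$spacing)
  vol_after <- sum(iso$airway_mask) * prod(iso$spacing)
  expect_lt(abs(vol_after / vol_before - 1), 0.1)
})

test_that("cohort generation is deterministic and structured", {
  co1 <- generate_cohort(cohort_spec(seed = 5))
  co2 <- generate_cohort(cohort_spec(seed = 5))
  expect_identical(co1, co2)
  expect_equal(nrow(co1), sum(cohort_spec()$n))
  expect_setequal(unique(co1$category), 0:4)
  # demographics are always complete
  expect_false(anyNA(co1[c("age", "height", "smoking", "copd")]))
})

test_that("default cohort is confounded: pre-matching age SMD > 0.1", {
  co <- generate_cohort(cohort_spec(seed = 1))
  s <- smd(co, c("age", "height", "smoking", "copd"))
  expect_gt(s$smd[s$variable == "age"], 0.1)
})

test_that("null cohort (no confounding, large n) is balanced", {
  co <- generate_cohort(cohort_spec(n = rep(500, 5), confounding_scale = 0,
                                    effect_scale = 0, seed = 9))
  s <- smd(co, c("age", "height", "smoking", "copd"))
  expect_true(all(s$smd < 0.1))
})

test_that("zero missingness rate leaves no gaps", {
  co <- generate_cohort(cohort_spec(n = rep(20, 5),
                                    missing_rate = rep(0, 5), seed = 2))
  expect_false(anyNA(co[structural_columns(co)]))
})

test_that("missingness increases with category under the defaults", {
  co <- generate_cohort(cohort_spec(seed = 4))
  fr <- sapply(c(0, 4), function(k)
    mean(is.na(co[co$category == k, structural_columns(co)])))
  expect_gt(fr[2], fr[1])
})

test_that("empty categories are refused", {
  expect_error(generate_cohort(cohort_spec(n = c(10, 0, 10, 10, 10))),
               "category")
})
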