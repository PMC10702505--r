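make_lung <- function(hu_values) {
  n <- length(hu_values)
  hu <- array(100, c(n, 1, 2))          # second slab stays outside the mask
  hu[, 1, 1] <- hu_values
  mask <- array(FALSE, c(n, 1, 2))
  mask[, 1, 1] <- TRUE
  volume_grid(hu, rep(1, 3), lung_mask = mask)
}

test_that("the seven-voxel worked example lands in the printed intervals", {
  v <- make_lung(c(-960, -800, -600, -300, -100, 40, 100))
  r <- classify_parenchyma(v)
  expect_equal(unname(r$fractions),
               c(1, 1, 1, 1, 2) / 7)    # emph, normal, ggo, semi, conso
  expect_equal(r$unclassified, 1 / 7)
  expect_equal(r$fibrosis, 2 / 7)
})

test_that("uniform air-density lung is pure emphysema", {
  r <- classify_parenchyma(make_lung(rep(-1000, 5)))
  expect_equal(r$fractions[["emphysema"]], 1)
  expect_equal(sum(r$fractions), 1)
})

test_that("exclusive fractions plus unclassified sum to one exactly", {
  spec <- phantom_spec(dim = c(48, 48, 48), spacing = rep(0.75, 3),
                       airway = NULL,
                       mixture = c(emphysema = 0.13, normal = 0.5,
                                   ggo = 0.17, semiconsolidation = 0.1,
                                   consolidation = 0.1),
                       noise_sd = 25, seed = 8)
  r <- classify_parenchyma(generate_volume(spec))
  expect_equal(sum(r$fractions) + r$unclassified, 1, tolerance = 1e-12)
  expect_lte(r$fibrosis, r$fractions[["semiconsolidation"]] +
               r$fractions[["consolidation"]] + 1e-12)
})

test_that("generator mixtures are recovered under low noise", {
  mix <- c(emphysema = 0.1, normal = 0.6, ggo = 0.1,
           semiconsolidation = 0.1, consolidation = 0.1)
  spec <- phantom_spec(dim = c(64, 64, 64), spacing = rep(0.75, 3),
                       airway = NULL, mixture = mix, noise_sd = 5, seed = 2)
  r <- classify_parenchyma(generate_volume(spec))
  expect_true(all(abs(r$fractions - mix) < 0.01))
})

test_that("raising the emphysema weight raises the measured fraction", {
  meas <- sapply(c(0.1, 0.2, 0.3), function(w) {
    spec <- phantom_spec(dim = c(32, 32, 32), spacing = rep(0.75, 3),
                         airway = NULL, mixture = c(emphysema = w),
                         noise_sd = 10, seed = 6)
    classify_parenchyma(generate_volume(spec))$fractions[["emphysema"]]
  })
  expect_true(all(diff(meas) > 0))
})

test_that("the HU scheme is configurable without code change", {
  v <- make_lung(c(-980, -930, -800))
  default <- classify_parenchyma(v)
  wide <- classify_parenchyma(v, hu_class_scheme(
    breaks = c(-900.5, -700.5, -500.5, -200.5, 60.5)))
  expect_equal(default$fractions[["emphysema"]], 1 / 3)
  expect_equal(wide$fractions[["emphysema"]], 2 / 3)
  expect_error(hu_class_scheme(breaks = c(-900, -950, -500, -200, 60)),
               "increasing")
})

test_that("histograms count every lung voxel once per 1-HU bin", {
  v <- make_lung(rep(-900, 11))
  h <- hu_histogram(v)
  expect_equal(sum(h$count), 11)
  expect_equal(h$count[h$hu == -900], 11)
  # two-level phantom: two spikes at the generator levels
  spec <- phantom_spec(dim = c(24, 24, 24), spacing = rep(1, 3),
                       airway = NULL,
                       mixture = c(emphysema = 0.3, normal = 0.7),
                       noise_sd = 0, seed = 1)
  vv <- generate_volume(spec)
  hh <- hu_histogram(vv)
  expect_setequal(hh$hu[hh$count > 0], c(-1000, -825))
  expect_equal(sum(hh$count), sum(vv$lung_mask))
})

test_that("noisy class means sit at the generator HU levels", {
  spec <- phantom_spec(dim = c(48, 48, 48), spacing = rep(1, 3),
                       airway = NULL, mixture = c(normal = 1),
                       noise_sd = 20, seed = 3)
  v <- generate_volume(spec)
  m <- mean(v$hu[v$labels == 12L])      # normal-lung code
  n <- sum(v$labels == 12L)
  expect_lt(abs(m - (-825)), 3 * 20 / sqrt(n))
})

test_that("degenerate inputs are refused", {
  v <- make_lung(c(-900, -800))
  v$lung_mask[] <- FALSE
  expect_error(classify_parenchyma(v), "empty")
  expect_error(hu_histogram(v), "empty")
  hu <- array(-900, c(2, 1, 1))
  mask <- array(TRUE, c(2, 1, 1))
  v2 <- volume_grid(hu, rep(1, 3), lung_mask = mask)
  v2$hu[1] <- NaN
  expect_error(classify_parenchyma(v2), "1 lung voxel")
})
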