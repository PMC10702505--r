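test_that("bifurcation angle follows the dot-product definition", {
  expect_equal(bifurcation_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(bifurcation_angle(c(1, 0, 0), c(1, 1, 0) / sqrt(2)), 45)
  expect_equal(bifurcation_angle(c(1, 0, 0), c(-1, 0, 0)), 180)
  expect_equal(bifurcation_angle(c(2, 0, 0), c(0, 3, 0)), 90)  # any norm
  expect_error(bifurcation_angle(c(0, 0, 0), c(1, 0, 0)), "zero")
})

test_that("hydraulic diameter and circularity match closed forms", {
  # circle radius 1
  expect_equal(hydraulic_diameter(pi, 2 * pi), 2)
  expect_equal(circularity(pi, 2 * pi), 1)
  # square side a
  a <- 2.7
  expect_equal(hydraulic_diameter(a^2, 4 * a), a)
  expect_equal(circularity(a^2, 4 * a), pi / 4)
  # ellipse 2:1, perimeter by numeric arc-length integration (the oracle)
  A <- 2 * pi
  Pe <- integrate(function(t) sqrt(4 * sin(t)^2 + cos(t)^2), 0, 2 * pi,
                  rel.tol = 1e-10)$value
  expect_equal(hydraulic_diameter(A, Pe), 4 * A / Pe)
  expect_equal(circularity(A, Pe), 4 * pi * A / Pe^2)
  expect_lt(circularity(A, Pe), 1)
  expect_error(hydraulic_diameter(0, 1), "positive")
  expect_error(circularity(1, -1), "positive")
})

test_that("wall thickness averages outer minus inner radius over rays", {
  sec <- list(r_in = rep(2, 16), r_out = rep(3, 16))
  expect_equal(wall_thickness(sec), 1)
  sec$r_out <- rep(2, 16)
  expect_equal(wall_thickness(sec), 0)
  # rays with outer < inner are discarded
  sec <- list(r_in = c(rep(2, 15), 5), r_out = c(rep(3, 15), 1))
  expect_equal(wall_thickness(sec), 1)
  expect_error(wall_thickness(list(r_in = rep(2, 4), r_out = rep(3, 4))),
               "8 rays")
  expect_error(wall_thickness(list(r_in = rep(5, 16), r_out = rep(1, 16))),
               "discarded")
})

test_that("cylinder cross-sections recover area, perimeter and wall", {
  v <- generate_volume(cylinder_spec(r_in = 4, wall = 1.5, spacing = 0.5))
  tr <- skeletonize(v)
  secs <- extract_cross_sections(v, tr, 1)
  expect_gt(length(secs), 10)
  A <- vapply(secs, `[[`, numeric(1), "A")
  Pe <- vapply(secs, `[[`, numeric(1), "Pe_in")
  expect_lt(abs(mean(A) / (pi * 16) - 1), 0.05)
  expect_lt(abs(mean(Pe) / (2 * pi * 4) - 1), 0.05)
  # isoperimetric bound with discretization slack
  expect_true(all(circularity(A, Pe) <= 1.05))
  wt <- vapply(secs, wall_thickness, numeric(1))
  expect_lt(abs(mean(wt) - 1.5), 0.25)            # half a voxel
})

test_that("sections stay perpendicular to a tilted cylinder", {
  dirv <- c(sin(pi / 6), 0, -cos(pi / 6))
  spec <- cylinder_spec(r_in = 4, wall = 1.5, dir = dirv,
                        dim = c(96, 48, 96), root_origin = c(14, 12, 43))
  v <- generate_volume(spec)
  tr <- skeletonize(v)
  secs <- extract_cross_sections(v, tr, 1)
  A <- vapply(secs, `[[`, numeric(1), "A")
  expect_lt(abs(mean(A) / (pi * 16) - 1), 0.05)
})

test_that("metrics are invariant under a rigid rotation of the phantom", {
  v0 <- generate_volume(cylinder_spec())
  base <- branch_metrics(v0, skeletonize(v0))
  set.seed(21)
  u <- c(rnorm(2, 0, 0.3), -1)
  spec <- cylinder_spec(dir = u, dim = c(96, 96, 96),
                        root_origin = c(20, 24, 43))
  v <- generate_volume(spec)
  m <- branch_metrics(v, skeletonize(v))
  expect_lt(abs(m$Dh_mm / base$Dh_mm - 1), 0.05)
  expect_lt(abs(m$Cr / base$Cr - 1), 0.05)
  # wall thickness is measured to half-voxel accuracy, so orientation
  # agreement is held to the same half-voxel bound
  expect_lt(abs(m$WT_mm - base$WT_mm), 0.25)
})

test_that("geometry errors shrink as the voxel size halves", {
  errs <- sapply(c(1.0, 0.5), function(sp) {
    v <- generate_volume(cylinder_spec(spacing = sp))
    m <- branch_metrics(v, skeletonize(v))
    c(dh = abs(m$Dh_mm - 8), wt = abs(m$WT_mm - 1.5))
  })
  # non-increasing error, with a floor at 2% of the true value: below
  # that the single-phantom error is discretization noise, not bias
  expect_lte(errs["dh", 2], max(errs["dh", 1], 0.02 * 8))
  expect_lte(errs["wt", 2], max(errs["wt", 1], 0.02 * 1.5))
})

test_that("a single-branch tree reports one row without theta", {
  v <- generate_volume(cylinder_spec())
  m <- branch_metrics(v, skeletonize(v))
  expect_equal(nrow(m), 1)
  expect_true(is.na(m$theta_deg))
  expect_false(is.na(m$Dh_mm))
})

test_that("an occluded branch keeps its row with missing metrics", {
  spec <- y_spec()
  v <- generate_volume(spec)
  tr <- skeletonize(v)
  # simulate an opacity: fill one daughter's lumen with soft-tissue HU
  kids <- which(vapply(tr$branches, function(b) b$parent, integer(1)) == 1)
  occl <- kids[1]
  pts <- tr$branches[[occl]]$points_mm
  mid <- pts[ceiling(nrow(pts) / 2), ]
  # flood a box around the branch midpoint with soft-tissue HU
  ctr <- round(mid / v$spacing + 0.5)
  rng <- function(c0, n) max(1, c0 - 16):min(n, c0 + 16)
  v$hu[rng(ctr[1], dim(v$hu)[1]), rng(ctr[2], dim(v$hu)[2]),
       rng(ctr[3], dim(v$hu)[3])] <- -100
  m <- branch_metrics(v, tr)
  expect_equal(nrow(m), 3)
  expect_true(is.na(m$Dh_mm[m$branch_id == occl]))
  expect_equal(m$n_sections[m$branch_id == occl], 0)
})

test_that("lobe aggregation averages member branches and drops theta", {
  m <- data.frame(branch_id = 1:4,
                  label = c("Trachea", "sRUL_1", "sRUL_2", NA),
                  subgroup = c(NA, "sRUL", "sRUL", NA),
                  theta_deg = c(80, NA, NA, NA),
                  Dh_mm = c(16, 4, 6, 3), WT_mm = c(2, 1, 1.4, 1),
                  Cr = c(0.95, 0.9, 0.94, 0.8), n_sections = c(9, 4, 4, 2))
  agg <- aggregate_lobes(m)
  expect_setequal(agg$label, c("Trachea", "sRUL"))
  expect_equal(agg$Dh_mm[agg$label == "sRUL"], 5)
  expect_equal(agg$WT_mm[agg$label == "sRUL"], 1.2)
  expect_true(is.na(agg$theta_deg[agg$label == "sRUL"]))
})
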