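# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state.  All stochastic generators in the package route through this so a
# single integer seed makes outputs reproducible.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# linear index <-> (i,j,k) voxel coordinates (1-based)
idx_to_ijk <- function(idx, dim) {
  idx0 <- idx - 1L
  i <- idx0 %% dim[1]
  j <- (idx0 %/% dim[1]) %% dim[2]
  k <- idx0 %/% (dim[1] * dim[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

ijk_to_idx <- function(ijk, dim) {
  (ijk[, 3] - 1L) * dim[1] * dim[2] + (ijk[, 2] - 1L) * dim[1] + ijk[, 1]
}

# voxel centers: voxel (1,1,1) is centered at spacing/2, so the grid spans
# [0, dim * spacing] in mm
ijk_to_mm <- function(ijk, spacing) {
  sweep(ijk - 0.5, 2, spacing, `*`)
}

mm_to_ijk_frac <- function(mm, spacing) {
  sweep(mm, 2, spacing, `/`) + 0.5
}

# Trilinear interpolation of a 3-D array at mm coordinates (n x 3 matrix).
# Points outside the grid return `outside`.
interp_trilinear <- function(arr, spacing, mm, outside = NA_real_) {
  d <- dim(arr)
  fc <- mm_to_ijk_frac(mm, spacing)
  i0 <- floor(fc)
  fr <- fc - i0
  out <- rep(outside, nrow(mm))
  ok <- fc[, 1] >= 1 & fc[, 1] <= d[1] & fc[, 2] >= 1 & fc[, 2] <= d[2] &
    fc[, 3] >= 1 & fc[, 3] <= d[3]
  if (!any(ok)) return(out)
  i0 <- pmin(pmax(i0[ok, , drop = FALSE], 1), rep(d - 1, each = sum(ok)))
  fr <- fc[ok, , drop = FALSE] - i0
  fr <- pmin(pmax(fr, 0), 1)
  acc <- numeric(sum(ok))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wgt <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    idx <- ijk_to_idx(cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz), d)
    acc <- acc + wgt * arr[idx]
  }
  out[ok] <- acc
  out
}

# unit vector; errors on (near-)zero input
unitize <- function(v, what = "direction vector") {
  nv <- sqrt(sum(v^2))
  if (!is.finite(nv) || nv < 1e-12)
    stop(what, " has zero length", call. = FALSE)
  v / nv
}

# orthonormal frame (u, w) spanning the plane perpendicular to unit normal
plane_frame <- function(normal) {
  a <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitize(pracma_cross(normal, a))
  w <- pracma_cross(normal, u)
  list(u = u, w = w)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# polygon area (shoelace) and perimeter from planar points in angular order
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_perimeter <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(sqrt((x - x[j])^2 + (y - y[j])^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
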