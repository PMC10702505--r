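#' Bifurcation angle between two daughter branches
#'
#' The angle between the direction vectors of the two daughters of a
#' bifurcation, in degrees.
#'
#' @param d1,d2 direction vectors (any nonzero length-3 vectors).
#' @return Angle in degrees, in \[0, 180\].
#' @export
bifurcation_angle <- function(d1, d2) {
  u1 <- unitize(d1, "first daughter direction")
  u2 <- unitize(d2, "second daughter direction")
  acos(pmin(pmax(sum(u1 * u2), -1), 1)) * 180 / pi
}

#' Hydraulic diameter of a cross-section
#'
#' \eqn{D_h = 4A / Pe}; equals the diameter for a circular section.
#'
#' @param A luminal area in mm^2 (> 0).
#' @param Pe luminal perimeter in mm (> 0).
#' @return Hydraulic diameter in mm.
#' @export
hydraulic_diameter <- function(A, Pe) {
  if (any(!is.finite(A)) || any(!is.finite(Pe)) || any(A <= 0) ||
      any(Pe <= 0))
    stop("A and Pe must be strictly positive")
  4 * A / Pe
}

#' Circularity of a cross-section
#'
#' \eqn{Cr = 4 \pi A / Pe^2}; 1 for a circle (isoperimetric equality),
#' < 1 for any other exact shape.
#'
#' @inheritParams hydraulic_diameter
#' @return Dimensionless circularity.
#' @export
circularity <- function(A, Pe) {
  if (any(!is.finite(A)) || any(!is.finite(Pe)) || any(A <= 0) ||
      any(Pe <= 0))
    stop("A and Pe must be strictly positive")
  4 * pi * A / Pe^2
}

# position at arc length s along a polyline (linear interpolation)
path_pos <- function(p, arc, s) {
  i <- findInterval(s, arc, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(p) - 1L)
  f <- (s - arc[i]) / pmax(arc[i + 1] - arc[i], 1e-12)
  p[i, , drop = FALSE] * (1 - f) + p[i + 1, , drop = FALSE] * f
}

# position and unit tangent at arc length s; the tangent is a finite
# difference over +-h mm so residual voxel-scale zigzag of the polyline
# does not tilt the section planes
path_at <- function(p, arc, s, h = 2) {
  L <- arc[length(arc)]
  pos <- path_pos(p, arc, s)
  a <- path_pos(p, arc, max(s - h, 0))
  b <- path_pos(p, arc, min(s + h, L))
  tg <- b - a
  nv <- sqrt(rowSums(tg^2))
  if (any(nv < 1e-9)) {
    tg <- p[nrow(p), , drop = FALSE] - p[1, , drop = FALSE]
    nv <- sqrt(rowSums(tg^2))
  }
  list(pos = pos, tangent = tg / nv)
}

#' Extract luminal/wall cross-sections along a branch
#'
#' Planes are placed perpendicular to the local centerline tangent, every
#' voxel along the middle third of the branch (the thirds next to the
#' junctions are skipped to avoid junction flare).  In each plane, radial
#' HU profiles are cast from the centerline on `n_rays` rays; the inner
#' (lumen) radius is the first crossing of the `lumen_hu` threshold
#' (default -500 HU) and the outer wall radius is the half-maximum
#' descent of the wall attenuation peak.  Area and perimeters come from
#' the sub-voxel polygon through the per-ray boundary points.
#'
#' @param volume a [volume_grid()] with HU values.
#' @param tree an `airway_tree`.
#' @param branch branch id (integer) or label (character).
#' @param n_rays number of radial rays per section (default 64).
#' @param lumen_hu HU threshold crossing defining the lumen boundary.
#' @param wall_search_mm how far beyond the lumen boundary to look for the
#'   wall peak and its descent.
#' @param min_valid_frac minimum fraction of rays that must find a lumen
#'   boundary for the section to be kept.
#' @return List of cross-sections, each a list with `origin`, `normal`,
#'   `A`, `Pe_in`, `Pe_out`, `r_in`, `r_out` (per-ray radii, NA where a
#'   ray failed).  Skipped sections are counted in attribute `n_skipped`.
#' @export
extract_cross_sections <- function(volume, tree, branch, n_rays = 64,
                                   lumen_hu = -500, wall_search_mm = 5,
                                   min_valid_frac = 0.75) {
  stopifnot(inherits(volume, "volume_grid"), inherits(tree, "airway_tree"))
  b <- find_branch(tree, branch)
  p <- b$points_mm
  if (nrow(p) < 3) stop("branch has fewer than 3 skeleton points")
  arc <- c(0, cumsum(sqrt(rowSums((p[-1, , drop = FALSE] -
                                     p[-nrow(p), , drop = FALSE])^2))))
  L <- arc[length(arc)]
  step_s <- min(volume$spacing)
  ss <- seq(L / 3, 2 * L / 3, by = step_s)
  if (!length(ss)) ss <- L / 2
  step_r <- 0.25 * min(volume$spacing)
  rr <- seq(step_r, max(4 * b$radius_mm + wall_search_mm, 6), by = step_r)
  ang <- seq(0, 2 * pi, length.out = n_rays + 1)[-(n_rays + 1)]

  sections <- list()
  n_skipped <- 0L
  for (s in ss) {
    at <- path_at(p, arc, s)
    o <- at$pos[1, ]; nv <- at$tangent[1, ]
    fr <- plane_frame(nv)
    r_in <- r_out <- rep(NA_real_, n_rays)
    for (a in seq_len(n_rays)) {
      dirv <- cos(ang[a]) * fr$u + sin(ang[a]) * fr$w
      hu <- interp_trilinear(volume$hu, volume$spacing,
                             cbind(o[1] + rr * dirv[1],
                                   o[2] + rr * dirv[2],
                                   o[3] + rr * dirv[3]),
                             outside = NA_real_)
      last <- which(is.na(hu))[1]
      m <- if (is.na(last)) length(hu) else last - 1L
      if (m < 4L) next
      prof <- hu[seq_len(m)]
      if (prof[1] >= lumen_hu) next           # centerline not in lumen
      k <- which(prof >= lumen_hu)[1]
      if (is.na(k)) next
      f <- (lumen_hu - prof[k - 1]) / (prof[k] - prof[k - 1])
      r_in[a] <- rr[k - 1] + f * (rr[k] - rr[k - 1])
      # wall peak and half-maximum descent
      win <- which(rr > r_in[a] & rr <= r_in[a] + wall_search_mm & rr <= rr[m])
      if (length(win) < 3) next
      pk <- win[which.max(prof[win])]
      if (prof[pk] < lumen_hu) next           # no wall signal
      beyond <- win[win > pk]
      if (length(beyond) < 2) next
      floorv <- min(prof[beyond])
      thr <- (prof[pk] + floorv) / 2
      kk <- beyond[which(prof[beyond] <= thr)[1]]
      if (is.na(kk) || kk <= pk) next
      f2 <- (thr - prof[kk - 1]) / (prof[kk] - prof[kk - 1])
      r_out[a] <- rr[kk - 1] + f2 * (rr[kk] - rr[kk - 1])
    }
    ok <- which(!is.na(r_in))
    if (length(ok) < min_valid_frac * n_rays) {
      n_skipped <- n_skipped + 1L
      next
    }
    # angular moving average regularizes the voxel-scale jitter of the
    # per-ray radii, which otherwise inflates the polygon perimeter
    r_in <- circular_smooth(r_in)
    r_out <- circular_smooth(r_out)
    ok <- which(!is.na(r_in))
    x <- r_in[ok] * cos(ang[ok]); y <- r_in[ok] * sin(ang[ok])
    A <- polygon_area(x, y)
    Pe_in <- polygon_perimeter(x, y)
    oko <- which(!is.na(r_out))
    Pe_out <- if (length(oko) >= min_valid_frac * n_rays)
      polygon_perimeter(r_out[oko] * cos(ang[oko]),
                        r_out[oko] * sin(ang[oko])) else NA_real_
    sections[[length(sections) + 1L]] <-
      structure(list(origin = o, normal = nv, A = A, Pe_in = Pe_in,
                     Pe_out = Pe_out, r_in = r_in, r_out = r_out,
                     n_rays = n_rays), class = "cross_section")
  }
  attr(sections, "n_skipped") <- n_skipped
  sections
}

# circular moving average over ray angle, ignoring missing rays
circular_smooth <- function(r, window = 3) {
  n <- length(r)
  if (n < window || all(is.na(r))) return(r)
  h <- (window - 1) %/% 2
  out <- r
  for (i in seq_len(n)) {
    if (is.na(r[i])) next
    idx <- ((i - h - 1):(i + h - 1)) %% n + 1
    out[i] <- mean(r[idx], na.rm = TRUE)
  }
  out
}

#' Mean airway wall thickness of a cross-section
#'
#' Mean over rays of (outer radius - inner radius); equals
#' \eqn{(D_{out} - D_{in})/2} for concentric circles.  Rays with outer <
#' inner are discarded.
#'
#' @param section a `cross_section` from [extract_cross_sections()] (or a
#'   list with `r_in`/`r_out` per-ray radii).
#' @return Wall thickness in mm.
#' @export
wall_thickness <- function(section) {
  ok <- which(!is.na(section$r_in) & !is.na(section$r_out))
  if (length(ok) < 8)
    stop("wall thickness needs inner and outer radii on at least 8 rays")
  d <- section$r_out[ok] - section$r_in[ok]
  d <- d[d >= 0]
  if (!length(d)) stop("all rays discarded (outer < inner)")
  mean(d)
}

find_branch <- function(tree, branch) {
  if (is.character(branch)) {
    labs <- vapply(tree$branches, function(b) b$label %||% NA_character_,
                   character(1))
    i <- match(branch, labs)
    if (is.na(i)) stop("no branch labeled ", branch)
    tree$branches[[i]]
  } else tree$branches[[branch]]
}

#' Per-branch structural metrics
#'
#' For every branch: the bifurcation angle theta (only for branches with
#' two daughters, or three for trifurcations, where it is the mean of the
#' three pairwise daughter angles), and the mean over the branch's valid
#' cross-sections of hydraulic diameter, wall thickness and circularity.
#' A branch with no valid section keeps an `NA` row (missing metrics feed
#' the imputation stage; this is not an error).
#'
#' @param volume a [volume_grid()].
#' @param tree a (preferably labeled) `airway_tree`.
#' @param ... passed to [extract_cross_sections()].
#' @return data.frame with columns `branch_id`, `label`, `subgroup`,
#'   `theta_deg`, `Dh_mm`, `WT_mm`, `Cr`, `n_sections`.
#' @export
branch_metrics <- function(volume, tree, ...) {
  stopifnot(inherits(tree, "airway_tree"))
  parent <- vapply(tree$branches, function(b) b$parent, integer(1))
  out <- lapply(seq_along(tree$branches), function(i) {
    b <- tree$branches[[i]]
    kids <- which(parent == i)
    theta <- NA_real_
    if (length(kids) %in% c(2L, 3L)) {
      cmb <- utils::combn(kids, 2)
      theta <- mean(apply(cmb, 2, function(pr)
        bifurcation_angle(tree$branches[[pr[1]]]$direction,
                          tree$branches[[pr[2]]]$direction)))
    }
    secs <- tryCatch(extract_cross_sections(volume, tree, i, ...),
                     error = function(e) list())
    dh <- cr <- wt <- ns <- NA_real_
    if (length(secs)) {
      A <- vapply(secs, `[[`, numeric(1), "A")
      Pe <- vapply(secs, `[[`, numeric(1), "Pe_in")
      dh <- mean(hydraulic_diameter(A, Pe))
      cr <- mean(circularity(A, Pe))
      wts <- vapply(secs, function(s)
        tryCatch(wall_thickness(s), error = function(e) NA_real_),
        numeric(1))
      wt <- if (all(is.na(wts))) NA_real_ else mean(wts, na.rm = TRUE)
      ns <- length(secs)
    }
    data.frame(branch_id = i,
               label = b$label %||% NA_character_,
               subgroup = b$subgroup %||% NA_character_,
               theta_deg = theta, Dh_mm = dh, WT_mm = wt, Cr = cr,
               n_sections = ifelse(is.na(ns), 0L, ns))
  })
  do.call(rbind, out)
}

#' Reporting table: central branches plus lobe-subgroup aggregates
#'
#' Collapses [branch_metrics()] output to the reporting units: the eight
#' central branches keep their own rows (with theta), and each lobe
#' subgroup contributes one row with the mean hydraulic diameter, wall
#' thickness and circularity of its member branches (no theta, matching
#' how segmental airways are summarized per lobe).
#'
#' @param metrics output of [branch_metrics()].
#' @return data.frame with one row per reporting unit.
#' @export
aggregate_lobes <- function(metrics) {
  central <- metrics[!is.na(metrics$label) & is.na(metrics$subgroup), ]
  central <- central[, c("label", "theta_deg", "Dh_mm", "WT_mm", "Cr",
                         "n_sections")]
  segs <- metrics[!is.na(metrics$subgroup), ]
  if (nrow(segs)) {
    agg <- do.call(rbind, lapply(split(segs, segs$subgroup), function(g)
      data.frame(label = g$subgroup[1], theta_deg = NA_real_,
                 Dh_mm = mean(g$Dh_mm, na.rm = TRUE),
                 WT_mm = mean(g$WT_mm, na.rm = TRUE),
                 Cr = mean(g$Cr, na.rm = TRUE),
                 n_sections = sum(g$n_sections))))
    central <- rbind(central, agg)
  }
  rownames(central) <- NULL
  central
}
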