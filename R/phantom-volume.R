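#' Default HU class scheme constants used by the phantom
#'
#' Tissue HU levels for the synthetic volumes: airway lumen at air
#' attenuation, airway wall at soft-tissue attenuation, vessels slightly
#' above water, and each exclusive parenchymal class at a representative
#' level inside its HU interval (interval midpoint; emphysema, whose
#' interval is unbounded below, sits at air).
#'
#' @return Named numeric vector of HU levels.
#' @export
phantom_hu_levels <- function() {
  c(lumen = -1000, wall = 0, vessel = 100,
    emphysema = -1000, normal = -825, ggo = -600,
    semiconsolidation = -350, consolidation = -70)
}

#' Default synthetic airway tree
#'
#' A rooted tube tree with 31 branches: the 26 anatomically labeled ones
#' (Trachea, left/right main bronchus, Bronint, the four lobar
#' trifurcations, and 18 segmental leaves in five lobe subgroups with the
#' anatomical segment counts sRUL=3, sRML=2, sRLL=5, sLUL=4, sLLL=4) plus
#' five unlabeled intermediate stems where the anatomy requires an extra
#' bifurcation.  Directions are unit-normalized internally; the convention
#' is +x toward the patient's left and +z superior.
#'
#' @param scale multiply all lengths and radii (default 1, sized for a
#'   96 mm field of view).
#' @return data.frame with columns `name`, `parent`, `dx`, `dy`, `dz`,
#'   `length_mm`, `r_in_mm`, `wall_mm`, `label` (`NA` for unlabeled
#'   stems) and `subgroup` (lobe subgroup of segmental leaves).
#' @export
airway_tree_default <- function(scale = 1) {
  b <- function(name, parent, d, len, r, w, label = name, subgroup = NA) {
    data.frame(name = name, parent = parent, dx = d[1], dy = d[2], dz = d[3],
               length_mm = len, r_in_mm = r, wall_mm = w,
               label = label, subgroup = subgroup,
               stringsAsFactors = FALSE)
  }
  rbind(
    b("Trachea", "", c(0, 0, -1), 18, 3.5, 1.0),
    b("RMB", "Trachea", c(-0.76, 0.10, -0.65), 11, 2.6, 0.8),
    b("LMB", "Trachea", c(0.80, 0.12, -0.60), 13, 2.4, 0.8),
    b("TriRUL", "RMB", c(-0.74, -0.10, 0.66), 8, 1.7, 0.6),
    b("Bronint", "RMB", c(-0.24, 0.06, -0.97), 9, 2.1, 0.7),
    b("sRUL_1", "TriRUL", c(-0.30, -0.20, 0.93), 7, 1.1, 0.5, subgroup = "sRUL"),
    b("sRUL_2", "TriRUL", c(-0.90, 0.17, 0.40), 7, 1.1, 0.5, subgroup = "sRUL"),
    b("sRUL_3", "TriRUL", c(-0.55, -0.75, 0.37), 7, 1.1, 0.5, subgroup = "sRUL"),
    b("rml_stem", "Bronint", c(-0.33, -0.77, -0.55), 6, 1.4, 0.5, label = NA),
    b("TriRLL", "Bronint", c(-0.18, 0.33, -0.93), 7, 1.8, 0.6),
    b("sRML_1", "rml_stem", c(-0.70, -0.60, -0.40), 6.5, 1.0, 0.45, subgroup = "sRML"),
    b("sRML_2", "rml_stem", c(0.10, -0.85, -0.50), 6.5, 1.0, 0.45, subgroup = "sRML"),
    b("sRLL_1", "TriRLL", c(-0.20, 0.90, -0.40), 6.5, 1.0, 0.45, subgroup = "sRLL"),
    b("sRLL_2", "TriRLL", c(0.25, -0.50, -0.83), 6.5, 1.0, 0.45, subgroup = "sRLL"),
    b("rll_bstem", "TriRLL", c(-0.50, 0.10, -0.86), 5.5, 1.4, 0.5, label = NA),
    b("sRLL_3", "rll_bstem", c(-0.85, -0.40, -0.35), 6, 1.0, 0.45, subgroup = "sRLL"),
    b("rll_lpstem", "rll_bstem", c(-0.10, 0.35, -0.93), 5, 1.2, 0.45, label = NA),
    b("sRLL_4", "rll_lpstem", c(-0.70, 0.45, -0.55), 6, 0.95, 0.4, subgroup = "sRLL"),
    b("sRLL_5", "rll_lpstem", c(0.35, 0.55, -0.76), 6, 0.95, 0.4, subgroup = "sRLL"),
    b("TriLUL", "LMB", c(0.72, -0.25, 0.65), 8, 1.7, 0.6),
    b("TriLLB", "LMB", c(0.42, 0.30, -0.86), 8, 1.8, 0.6),
    b("sLUL_1", "TriLUL", c(0.30, 0.10, 0.95), 7, 1.1, 0.45, subgroup = "sLUL"),
    b("sLUL_2", "TriLUL", c(0.80, -0.55, 0.25), 7, 1.1, 0.45, subgroup = "sLUL"),
    b("lul_lstem", "TriLUL", c(0.75, -0.30, -0.59), 5, 1.3, 0.5, label = NA),
    b("sLUL_3", "lul_lstem", c(0.85, -0.50, -0.15), 6, 0.95, 0.4, subgroup = "sLUL"),
    b("sLUL_4", "lul_lstem", c(0.30, -0.40, -0.87), 6, 0.95, 0.4, subgroup = "sLUL"),
    b("sLLL_1", "TriLLB", c(0.30, 0.90, -0.30), 6.5, 1.0, 0.45, subgroup = "sLLL"),
    b("sLLL_2", "TriLLB", c(0.00, -0.35, -0.94), 6.5, 1.0, 0.45, subgroup = "sLLL"),
    b("lll_bstem", "TriLLB", c(0.60, 0.25, -0.76), 5, 1.3, 0.5, label = NA),
    b("sLLL_3", "lll_bstem", c(0.95, 0.10, -0.30), 6, 0.95, 0.4, subgroup = "sLLL"),
    b("sLLL_4", "lll_bstem", c(0.30, 0.65, -0.70), 6, 0.95, 0.4, subgroup = "sLLL")
  ) -> tr
  tr$length_mm <- tr$length_mm * scale
  tr$r_in_mm <- tr$r_in_mm * scale
  tr$wall_mm <- tr$wall_mm * scale
  tr
}

#' Phantom specification
#'
#' Describes a synthetic CT volume: grid geometry, an airway tube tree, a
#' vessel tube tree, a parenchymal HU mixture, tissue HU levels and noise.
#'
#' @param dim grid shape in voxels (length 3).
#' @param spacing voxel spacing in mm (length 3); the `table1` preset in
#'   [phantom_spec_table1()] uses 3 mm slices.
#' @param airway airway branch table as in [airway_tree_default()], or
#'   `NULL` for no airway.
#' @param vessel vessel branch table (columns `name`, `parent`, `dx`,
#'   `dy`, `dz`, `length_mm`, `r_mm`), or `NULL`.
#' @param mixture named fractions of the exclusive parenchymal classes
#'   (`emphysema`, `normal`, `ggo`, `semiconsolidation`, `consolidation`);
#'   must sum to at most 1, any remainder is assigned to `normal`.
#' @param hu_levels named HU level per tissue, see [phantom_hu_levels()].
#' @param noise_sd Gaussian HU noise standard deviation (default 20 HU).
#' @param seed integer seed driving all random draws.
#' @param root_origin mm position of the airway root start (default top
#'   center of the grid); vessels root at `root_origin + c(8, 8, 0)` mm
#'   unless `vessel_origin` is given.
#' @param vessel_origin optional mm position of the vessel root start.
#' @param allow_overlap if `FALSE` (default), overlapping airway and
#'   vessel tubes raise an error.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(128, 128, 128),
                         spacing = c(0.75, 0.75, 0.75),
                         airway = airway_tree_default(),
                         vessel = NULL,
                         mixture = c(emphysema = 0.05, normal = 0.85,
                                     ggo = 0.04, semiconsolidation = 0.04,
                                     consolidation = 0.02),
                         hu_levels = phantom_hu_levels(),
                         noise_sd = 20,
                         seed = 1,
                         root_origin = NULL,
                         vessel_origin = NULL,
                         allow_overlap = FALSE) {
  stopifnot(length(dim) == 3, all(dim >= 4), length(spacing) == 3,
            all(spacing > 0), noise_sd >= 0)
  classes <- c("emphysema", "normal", "ggo", "semiconsolidation",
               "consolidation")
  if (length(mixture)) {
    if (is.null(names(mixture)) || !all(names(mixture) %in% classes))
      stop("mixture names must be among: ", paste(classes, collapse = ", "))
    if (any(mixture < 0) || sum(mixture) > 1 + 1e-9)
      stop("mixture fractions must be nonnegative and sum to at most 1")
  }
  for (tab in list(airway, vessel)) {
    if (!is.null(tab)) {
      rcol <- intersect(c("r_in_mm", "r_mm"), names(tab))
      if (any(tab[[rcol[1]]] <= 0) || any(tab$length_mm <= 0))
        stop("branch radii and lengths must be strictly positive")
    }
  }
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 airway = airway, vessel = vessel, mixture = mixture,
                 hu_levels = hu_levels, noise_sd = noise_sd, seed = seed,
                 root_origin = root_origin, vessel_origin = vessel_origin,
                 allow_overlap = allow_overlap),
            class = "phantom_spec")
}

#' Anisotropic acquisition preset (thick 3 mm slices)
#'
#' Same defaults as [phantom_spec()] but with in-plane 0.75 mm spacing and
#' 3 mm slice thickness, emulating a thick-slice clinical protocol.  Use
#' [resample_isotropic()] before geometry extraction.
#'
#' @param ... overrides passed to [phantom_spec()].
#' @export
phantom_spec_table1 <- function(...) {
  phantom_spec(dim = c(128, 128, 32), spacing = c(0.75, 0.75, 3), ...)
}

# resolve branch start/end positions from a branch table; errors if a tube
# (including its wall) leaves the grid
resolve_tree <- function(tab, dim, spacing, origin, what = "airway") {
  ext <- dim * spacing
  rcol <- if ("r_in_mm" %in% names(tab)) "r_in_mm" else "r_mm"
  wall <- if ("wall_mm" %in% names(tab)) tab$wall_mm else rep(0, nrow(tab))
  pos <- list()
  tab$x0 <- tab$y0 <- tab$z0 <- tab$x1 <- tab$y1 <- tab$z1 <- NA_real_
  for (i in seq_len(nrow(tab))) {
    d <- unitize(c(tab$dx[i], tab$dy[i], tab$dz[i]),
                 paste0("direction of branch ", tab$name[i]))
    tab[i, c("dx", "dy", "dz")] <- d
    p0 <- if (!nzchar(tab$parent[i])) origin else {
      j <- match(tab$parent[i], tab$name)
      if (is.na(j) || j >= i)
        stop("parent of branch ", tab$name[i],
             " must be defined earlier in the table")
      c(tab$x1[j], tab$y1[j], tab$z1[j])
    }
    p1 <- p0 + d * tab$length_mm[i]
    r <- tab[[rcol]][i] + wall[i]
    # radial extent of a capped cylinder along grid axis a is r*sqrt(1-u_a^2)
    rad <- r * sqrt(pmax(0, 1 - d^2))
    if (any(pmin(p0, p1) - rad < 0) || any(pmax(p0, p1) + rad > ext))
      stop("branch ", tab$name[i], " extends outside the grid")
    tab[i, c("x0", "y0", "z0")] <- p0
    tab[i, c("x1", "y1", "z1")] <- p1
  }
  tab
}

# mark voxels inside the tubes of a resolved branch table; returns a list
# of logical arrays: `inner` (distance <= r) and, if wall present, `wall`
voxelize_tubes <- function(tab, dim, spacing) {
  rcol <- if ("r_in_mm" %in% names(tab)) "r_in_mm" else "r_mm"
  has_wall <- "wall_mm" %in% names(tab)
  inner <- array(FALSE, dim)
  wallm <- if (has_wall) array(FALSE, dim) else NULL
  for (i in seq_len(nrow(tab))) {
    p0 <- c(tab$x0[i], tab$y0[i], tab$z0[i])
    p1 <- c(tab$x1[i], tab$y1[i], tab$z1[i])
    r <- tab[[rcol]][i]
    rw <- r + if (has_wall) tab$wall_mm[i] else 0
    lo <- pmax(ceiling((pmin(p0, p1) - rw) / spacing - 0.5) + 1L, 1L)
    hi <- pmin(floor((pmax(p0, p1) + rw) / spacing - 0.5) + 1L, dim)
    if (any(lo > hi)) next
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    cx <- (ii - 0.5) * spacing[1] - p0[1]
    cy <- (jj - 0.5) * spacing[2] - p0[2]
    cz <- (kk - 0.5) * spacing[3] - p0[3]
    u <- (p1 - p0) / tab$length_mm[i]
    # flat-capped cylinder: axial coordinate t = (c - p0).u must lie in
    # [0, L] and the radial distance sqrt(|c - p0|^2 - t^2) within radius
    tu <- outer(c(outer(cx * u[1], cy * u[2], `+`)), cz * u[3], `+`)
    n2 <- outer(c(outer(cx^2, cy^2, `+`)), cz^2, `+`)
    d2 <- pmax(n2 - tu^2, 0)
    inseg <- tu >= 0 & tu <= tab$length_mm[i]
    sub <- inseg & d2 <= r^2
    subw <- if (has_wall) (inseg & d2 <= rw^2 & !sub) else NULL
    # plain-vector OR: both sides enumerate the block in storage order
    inner[ii, jj, kk] <- as.vector(inner[ii, jj, kk]) | as.vector(sub)
    if (has_wall)
      wallm[ii, jj, kk] <- as.vector(wallm[ii, jj, kk]) | as.vector(subw)
  }
  if (has_wall) wallm <- wallm & !inner
  list(inner = inner, wall = wallm)
}

#' Generate a synthetic CT volume from a phantom specification
#'
#' Voxelizes the airway tube tree (lumen and wall annulus) and the vessel
#' tube tree, assigns every remaining voxel to a parenchymal class by a
#' deterministic largest-remainder allocation of the mixture fractions
#' (randomly placed, seeded), and draws HU per tissue with Gaussian noise.
#' The random stream order is: (1) parenchymal class placement, (2) HU
#' noise in voxel storage order — so a given seed yields a bit-identical
#' volume.
#'
#' @param spec a [phantom_spec()].
#' @return A [volume_grid()] whose `labels` array is the ground truth and
#'   whose `truth` field carries the resolved branch tables.
#' @export
generate_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dim <- spec$dim; spacing <- spec$spacing
  ext <- dim * spacing
  origin <- spec$root_origin %||% c(ext[1] / 2, ext[2] / 2, ext[3] - 2)

  labels <- array(0L, dim)
  air_tab <- ves_tab <- NULL
  if (!is.null(spec$airway) && nrow(spec$airway)) {
    air_tab <- resolve_tree(spec$airway, dim, spacing, origin, "airway")
    vx <- voxelize_tubes(air_tab, dim, spacing)
    labels[vx$wall] <- 2L
    labels[vx$inner] <- 1L
  }
  if (!is.null(spec$vessel) && nrow(spec$vessel)) {
    vorigin <- spec$vessel_origin %||% (origin + c(8, 8, 0))
    ves_tab <- resolve_tree(spec$vessel, dim, spacing, vorigin, "vessel")
    vv <- voxelize_tubes(ves_tab, dim, spacing)
    clash <- vv$inner & labels > 0L
    if (any(clash) && !spec$allow_overlap)
      stop("airway and vessel tubes overlap in ", sum(clash),
           " voxels; set allow_overlap = TRUE to let the airway win")
    labels[vv$inner & labels == 0L] <- 3L
  }

  # parenchyma: largest-remainder integer allocation of the mixture
  classes <- c("emphysema", "normal", "ggo", "semiconsolidation",
               "consolidation")
  frac <- setNames(numeric(5), classes)
  frac[names(spec$mixture)] <- spec$mixture
  frac["normal"] <- frac["normal"] + (1 - sum(frac))
  paren_idx <- which(labels == 0L)
  n_par <- length(paren_idx)
  tgt <- frac * n_par
  cnt <- floor(tgt)
  rem <- n_par - sum(cnt)
  if (rem > 0) {
    ord <- order(tgt - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }

  hu <- array(0, dim)
  lev <- spec$hu_levels
  with_seed(spec$seed, {
    if (n_par > 0) {
      perm <- sample.int(n_par)
      cls <- rep.int(seq_along(classes), cnt)
      labels[paren_idx[perm]] <- 10L + cls
    }
    base <- numeric(length(labels))
    base[labels == 1L] <- lev[["lumen"]]
    base[labels == 2L] <- lev[["wall"]]
    base[labels == 3L] <- lev[["vessel"]]
    for (k in seq_along(classes))
      base[labels == 10L + k] <- lev[[classes[k]]]
    hu[] <- base + if (spec$noise_sd > 0)
      rnorm(length(base), 0, spec$noise_sd) else 0
  })

  volume_grid(hu, spacing,
              lung_mask = array(labels >= 11L, dim),
              airway_mask = array(labels == 1L, dim),
              vessel_mask = array(labels == 3L, dim),
              labels = labels,
              truth = list(airway = air_tab, vessel = ves_tab,
                           mixture = frac, spec = spec))
}

#' Resample a volume to isotropic voxels
#'
#' Thick-slice acquisitions are resampled to the minimum in-plane spacing
#' before geometry extraction (perpendicular-plane sampling is ill-posed
#' on 3 mm slices).  HU is interpolated trilinearly; masks and labels by
#' nearest neighbor.
#'
#' @param vol a [volume_grid()].
#' @param target target isotropic spacing in mm (default: minimum of the
#'   current spacings).
#' @return A [volume_grid()] with isotropic spacing.
#' @export
resample_isotropic <- function(vol, target = min(vol$spacing)) {
  stopifnot(inherits(vol, "volume_grid"), target > 0)
  if (all(abs(vol$spacing - target) < 1e-9)) return(vol)
  old_dim <- dim(vol$hu)
  new_dim <- pmax(2L, as.integer(round(old_dim * vol$spacing / target)))
  sp <- rep(target, 3)
  gx <- ((seq_len(new_dim[1]) - 0.5) * sp[1])
  gy <- ((seq_len(new_dim[2]) - 0.5) * sp[2])
  gz <- ((seq_len(new_dim[3]) - 0.5) * sp[3])
  mm <- cbind(rep(gx, times = new_dim[2] * new_dim[3]),
              rep(rep(gy, each = new_dim[1]), times = new_dim[3]),
              rep(gz, each = new_dim[1] * new_dim[2]))
  hu <- array(interp_trilinear(vol$hu, vol$spacing, mm, outside = min(vol$hu)),
              new_dim)
  nn <- function(arr) {
    if (is.null(arr)) return(NULL)
    ijk <- round(mm_to_ijk_frac(mm, vol$spacing))
    ijk <- pmin(pmax(ijk, 1L), rep(old_dim, each = nrow(ijk)))
    array(arr[ijk_to_idx(ijk, old_dim)], new_dim)
  }
  volume_grid(hu, sp, lung_mask = nn(vol$lung_mask),
              airway_mask = nn(vol$airway_mask),
              vessel_mask = nn(vol$vessel_mask), labels = nn(vol$labels),
              truth = vol$truth)
}
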