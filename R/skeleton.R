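#' Extract a rooted 1-D centerline tree from a tubular mask
#'
#' Centerlines are grown by iterative farthest-point geodesic front
#' propagation: starting from the root voxel, the geodesically farthest
#' mask voxel is found (multi-source shortest path over the 26-connected
#' voxel graph with metric edge lengths in mm), its shortest path back to
#' the current skeleton is traced, recentered onto the lumen axis (each
#' point moves to the centroid of its perpendicular boundary contour) and
#' accepted as a new branch when it is longer than both `min_branch_mm`
#' and `spur_factor` times the tube radius at its attachment point.
#' Shorter paths are radial spurs toward the tube wall; they are
#' suppressed (their voxels join the propagation sources so the tracer
#' moves on) and never enter the tree.  The procedure yields a rooted
#' tree directly — no thinning, cycle removal or pruning pass is needed.
#' Finally, branch segments are split at the junctions where children
#' attach; junction positions closer than the local discretization
#' scatter are merged, so a trifurcation is reported as one node with
#' three daughters rather than two bifurcations a voxel apart.
#'
#' @param x a [volume_grid()] (its `airway_mask` is used) or a logical
#'   3-D array.
#' @param spacing voxel spacing in mm (required when `x` is an array).
#' @param min_branch_mm shortest branch the tracer may create (default 3).
#' @param spur_factor multiple of the attachment-point radius below which
#'   a candidate path is considered a wall spur (default 2).
#' @param root_mm optional mm coordinates of the tree root; by default the
#'   root is the largest-radius mask voxel of the most superior occupied
#'   slab (for an airway mask, the top of the trachea).
#' @param recenter logical; recenter paths onto the lumen axis.
#' @param max_branches safety cap on tracer iterations.
#' @return An object of class `airway_tree`: a list with `branches` (each
#'   with `id`, `parent`, `points_mm`, `length_mm`, `radius_mm`,
#'   `direction`, `label`), `spacing`, `dim` and `root_mm`.
#' @export
skeletonize <- function(x, spacing = NULL, min_branch_mm = 3,
                        spur_factor = 2, root_mm = NULL, recenter = TRUE,
                        max_branches = 400) {
  if (inherits(x, "volume_grid")) {
    mask <- x$airway_mask
    if (is.null(mask)) stop("volume has no airway_mask")
    spacing <- x$spacing
  } else {
    mask <- x
    if (is.null(spacing)) stop("spacing must be given with a raw mask")
  }
  dm <- dim(mask)
  if (!any(mask)) stop("mask is empty")

  comp <- connected_components(mask, dm, spacing)
  if (length(comp$sizes) > 1)
    stop("mask has ", length(comp$sizes),
         " connected components (sizes: ",
         paste(sort(comp$sizes, decreasing = TRUE), collapse = ", "),
         "); a single-component mask is required")

  edt <- array(edt3d_cpp(mask, dm, spacing), dm)
  voxdiag <- sqrt(sum(spacing^2))
  maskn <- array(as.numeric(mask), dm)

  root <- if (!is.null(root_mm)) {
    cand <- which(mask)
    mm <- ijk_to_mm(idx_to_ijk(cand, dm), spacing)
    cand[which.min(colSums((t(mm) - root_mm)^2))]
  } else {
    # most superior occupied slab; its centroid voxel (the distance
    # transform is flat across a blunt tube end, so a max would pick an
    # arbitrary off-axis voxel)
    idx <- which(mask)
    kk <- idx_to_ijk(idx, dm)[, 3]
    top <- idx[kk >= max(kk) - 1L]
    tm <- ijk_to_mm(idx_to_ijk(top, dm), spacing)
    ctr <- colMeans(tm)
    top[which.min(colSums((t(tm) - ctr)^2))]
  }

  segmap <- array(0L, dm)        # voxel -> owning segment
  rowmap <- array(0L, dm)        # voxel -> row in that segment's polyline
  covflag <- array(FALSE, dm)    # rejected-spur voxels (extra sources)
  seg_poly <- list()
  seg_parent <- list()           # c(parent_seg, parent_row); NULL for first
  seg_arc <- list()              # cumulative arc length per polyline row
  seg_guard <- list()            # c(start_guard, end_guard) in mm

  poly_arc <- function(poly) {
    n <- nrow(poly)
    c(0, cumsum(sqrt(rowSums((poly[-1, , drop = FALSE] -
                                poly[-n, , drop = FALSE])^2))))
  }
  poly_edt <- function(poly) {
    ijk <- pmin(pmax(round(mm_to_ijk_frac(poly, spacing)), 1L),
                rep(dm, each = nrow(poly)))
    edt[ijk_to_idx(ijk, dm)]
  }
  # no junction can sit inside the cap region at a tube's blunt end: the
  # distance transform is depressed there, so attachments that close to a
  # segment's distal tip (or to the root end) are cap-corner spurs
  end_guards <- function(poly, arc) {
    e <- poly_edt(poly)
    L <- arc[length(arc)]
    g_end <- 1.5 * max(e[arc >= L - 4]) + voxdiag
    g_start <- 1.5 * max(e[arc <= 4]) + voxdiag
    c(g_start, g_end)
  }

  snap_poly <- function(poly, sid) {
    ijk <- pmin(pmax(round(mm_to_ijk_frac(poly, spacing)), 1L),
                rep(dm, each = nrow(poly)))
    idx <- ijk_to_idx(ijk, dm)
    new <- mask[idx] & segmap[idx] <= 0L
    segmap[idx[new]] <<- sid
    rowmap[idx[new]] <<- which(new)
  }

  segmap[root] <- -1L            # provisional root marker
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    if (n_iter > max_branches) break
    sources <- unique(c(which(segmap != 0L), which(covflag)))
    g <- geodesic_cpp(mask, dm, spacing, sources)
    d <- g$dist
    d[!is.finite(d)] <- -1
    v <- which.max(d)
    if (d[v] < min_branch_mm) break
    path <- integer(0)
    w <- v
    while (segmap[w] == 0L && !covflag[w]) {
      path <- c(path, w)
      w <- g$pred[w]
    }
    if (covflag[w] && segmap[w] == 0L) {
      # reached a suppressed spur: treat the candidate as spur territory
      covflag[path] <- TRUE
      next
    }
    attach_vox <- w
    thr <- max(min_branch_mm, spur_factor * edt[attach_vox] + voxdiag)
    if (d[v] < thr) {
      covflag[path] <- TRUE
      next
    }
    if (segmap[attach_vox] > 0L) {
      s <- segmap[attach_vox]
      a <- seg_arc[[s]][rowmap[attach_vox]]
      L <- seg_arc[[s]][length(seg_arc[[s]])]
      in_end_cap <- a > L - seg_guard[[s]][2]
      in_root_cap <- is.null(seg_parent[[s]]) && a < seg_guard[[s]][1]
      if (in_end_cap || in_root_cap) {
        covflag[path] <- TRUE
        next
      }
    }
    path <- rev(path)
    poly <- ijk_to_mm(idx_to_ijk(path, dm), spacing)
    # prepend the attachment point for geometric continuity
    apoint <- if (segmap[attach_vox] > 0L)
      seg_poly[[segmap[attach_vox]]][rowmap[attach_vox], ]
    else ijk_to_mm(idx_to_ijk(attach_vox, dm), spacing)[1, ]
    poly <- rbind(apoint, poly)
    if (recenter && nrow(poly) >= 3)
      poly <- recenter_path(poly, maskn, spacing, passes = 3)
    poly <- smooth_path(poly)
    sid <- length(seg_poly) + 1L
    seg_poly[[sid]] <- poly
    seg_parent[sid] <- list(if (segmap[attach_vox] > 0L)
      c(segmap[attach_vox], rowmap[attach_vox]) else NULL)
    seg_arc[[sid]] <- poly_arc(poly)
    seg_guard[[sid]] <- end_guards(poly, seg_arc[[sid]])
    snap_poly(poly, sid)
    if (sid == 1L && segmap[root] == -1L) {
      segmap[root] <- 1L
      rowmap[root] <- 1L
    }
  }
  segmap[segmap == -1L] <- 0L
  if (!length(seg_poly))
    stop("no branch found: mask thinner/shorter than min_branch_mm?")

  branches <- assemble_branches(seg_poly, seg_parent, edt, dm, spacing,
                                voxdiag)
  # near a blunt tube end the centerline is ill-defined (the contour
  # centroid drifts into the cap corner): trim leaf tails where the local
  # radius collapses below 60% of the branch interior radius
  is_parent <- seq_along(branches) %in%
    vapply(branches, function(b) b$parent, integer(1))
  for (b in seq_along(branches)) {
    if (!is_parent[b])
      branches[[b]]$points_mm <- trim_blunt_tail(branches[[b]]$points_mm,
                                                 edt, dm, spacing)
  }
  for (b in seq_along(branches)) {
    p <- branches[[b]]$points_mm
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] -
                           p[-nrow(p), , drop = FALSE])^2))
    branches[[b]]$length_mm <- sum(seg)
    par_r <- if (branches[[b]]$parent > 0L)
      branches[[branches[[b]]$parent]]$radius_mm else branches[[b]]$radius_mm
    branches[[b]]$direction <- branch_direction(p, branches[[b]]$radius_mm,
                                                par_r, spacing)
    branches[[b]]$direction_global <- global_direction(p,
                                                       branches[[b]]$radius_mm)
    branches[[b]]$label <- NA_character_
    branches[[b]]$subgroup <- NA_character_
  }
  structure(list(branches = branches, spacing = spacing, dim = dm,
                 root_mm = ijk_to_mm(idx_to_ijk(root, dm), spacing)[1, ]),
            class = "airway_tree")
}

# connected components of a mask by repeated geodesic flood fill
connected_components <- function(mask, dm, spacing) {
  remaining <- which(mask)
  sizes <- integer(0)
  while (length(remaining)) {
    g <- geodesic_cpp(mask, dm, spacing, remaining[1])
    inside <- is.finite(g$dist[remaining])
    sizes <- c(sizes, sum(inside))
    remaining <- remaining[!inside]
    if (length(sizes) > 64) stop("mask has more than 64 components")
  }
  list(sizes = sizes)
}

# Split traced segments into branches at the junctions where children
# attach.  Attachment positions within the local merge distance of each
# other (or of a segment end) collapse onto one node, so trifurcations
# stay single nodes.
assemble_branches <- function(seg_poly, seg_parent, edt, dm, spacing,
                              voxdiag) {
  ns <- length(seg_poly)
  arcs <- lapply(seg_poly, function(p) {
    n <- nrow(p)
    c(0, cumsum(sqrt(rowSums((p[-1, , drop = FALSE] -
                                p[-n, , drop = FALSE])^2))))
  })
  loc_edt <- function(s, row) {
    ijk <- pmin(pmax(round(mm_to_ijk_frac(seg_poly[[s]][row, , drop = FALSE],
                                          spacing)), 1L),
                rep(dm, each = 1))
    edt[ijk_to_idx(ijk, dm)]
  }
  # daughters cutting the junction corner attach up to about two local
  # radii before the true junction, so nodes that close are one junction
  merge_thr <- function(s, row) max(2.5 * voxdiag, 2.2 * loc_edt(s, row))

  # resolve each segment's attachment to a (seg, row) node, snapping
  # attachments near a segment end to that end and near a segment start
  # to the parent's own node
  resolve <- function(s, row) {
    repeat {
      a <- arcs[[s]][row]
      thr <- merge_thr(s, row)
      n <- nrow(seg_poly[[s]])
      if (a > arcs[[s]][n] - thr) return(c(s, n))
      if (a < thr) {
        if (is.null(seg_parent[[s]])) return(c(s, 1L))
        pr <- seg_parent[[s]]
        s <- pr[1]; row <- pr[2]
        next
      }
      return(c(s, row))
    }
  }
  att <- lapply(seq_len(ns), function(s) {
    if (is.null(seg_parent[[s]])) NULL
    else resolve(seg_parent[[s]][1], seg_parent[[s]][2])
  })

  # cluster interior attachment rows per segment
  cuts <- vector("list", ns)
  for (s in seq_len(ns)) {
    rows <- sort(unique(vapply(
      Filter(function(a) !is.null(a) && a[1] == s &&
               a[2] > 1L && a[2] < nrow(seg_poly[[s]]), att),
      function(a) a[2], integer(1))))
    if (!length(rows)) { cuts[[s]] <- integer(0); next }
    grp <- list(rows[1])
    for (r in rows[-1]) {
      last <- grp[[length(grp)]]
      thr <- max(2.5 * voxdiag,
                 2.2 * max(loc_edt(s, last[1]), loc_edt(s, r)))
      if (arcs[[s]][r] - arcs[[s]][last[1]] < thr)
        grp[[length(grp)]] <- c(last, r)
      else grp[[length(grp) + 1L]] <- r
    }
    reps <- vapply(grp, function(g) g[ceiling(length(g) / 2)], integer(1))
    names(reps) <- NULL
    cuts[[s]] <- reps
    # remap clustered attachments to their representative
    for (k in seq_len(ns)) {
      a <- att[[k]]
      if (!is.null(a) && a[1] == s && a[2] > 1L &&
          a[2] < nrow(seg_poly[[s]])) {
        for (gi in seq_along(grp))
          if (a[2] %in% grp[[gi]]) att[[k]] <- c(s, reps[gi])
      }
    }
  }

  # build branch pieces; record which branch ends at each node
  branches <- list()
  end_branch <- vector("list", ns)       # per segment: named by row
  for (s in seq_len(ns)) {
    n <- nrow(seg_poly[[s]])
    bounds <- unique(c(1L, cuts[[s]], n))
    bounds <- sort(bounds)
    prev_branch <- NA_integer_           # branch ending at previous bound
    for (j in seq_len(length(bounds) - 1L)) {
      rows <- bounds[j]:bounds[j + 1L]
      if (length(rows) < 2L) next
      bid <- length(branches) + 1L
      branches[[bid]] <- list(
        id = bid,
        seg = s, start_row = bounds[j], end_row = bounds[j + 1L],
        points_mm = seg_poly[[s]][rows, , drop = FALSE])
      branches[[bid]]$.parent_node <- if (j == 1L) att[[s]] else NULL
      branches[[bid]]$.prev <- prev_branch
      prev_branch <- bid
      end_branch[[s]] <- c(end_branch[[s]],
                           stats::setNames(bid, bounds[j + 1L]))
    }
  }
  # resolve parents
  for (b in seq_along(branches)) {
    br <- branches[[b]]
    if (!is.na(br$.prev)) {
      branches[[b]]$parent <- br$.prev
    } else if (is.null(br$.parent_node)) {
      branches[[b]]$parent <- 0L
    } else {
      nd <- br$.parent_node
      eb <- end_branch[[nd[1]]]
      hit <- eb[as.character(nd[2])]
      if (is.na(hit)) {
        # attachment at a segment start that is the tree root
        hit <- if (length(eb)) unname(eb[1]) else 0L
        branches[[b]]$parent <- if (nd[2] <= 1L) 0L else unname(hit)
      } else branches[[b]]$parent <- unname(hit)
    }
  }
  # mean radius along each branch from the distance transform; endpoints
  # sit near junctions or blunt tube ends where the transform is
  # depressed, so average over the interior when possible
  for (b in seq_along(branches)) {
    p <- branches[[b]]$points_mm
    ijk <- pmin(pmax(round(mm_to_ijk_frac(p, spacing)), 1L),
                rep(dm, each = nrow(p)))
    ed <- edt[ijk_to_idx(ijk, dm)]
    nn <- length(ed)
    inner <- if (nn >= 8) ed[ceiling(nn / 4):floor(3 * nn / 4)] else ed
    branches[[b]]$radius_mm <- mean(inner)
    branches[[b]]$.prev <- branches[[b]]$.parent_node <- NULL
    branches[[b]]$seg <- branches[[b]]$start_row <-
      branches[[b]]$end_row <- NULL
  }
  # exactly one root
  roots <- which(vapply(branches, function(b) b$parent == 0L, logical(1)))
  if (length(roots) != 1L)
    stop("internal error: centerline produced ", length(roots), " roots")
  branches
}

# drop trailing leaf-path points whose distance-transform value has
# collapsed relative to the branch interior (blunt-end cap shadow)
trim_blunt_tail <- function(p, edt, dm, spacing) {
  n <- nrow(p)
  if (n < 5) return(p)
  ijk <- pmin(pmax(round(mm_to_ijk_frac(p, spacing)), 1L),
              rep(dm, each = n))
  ed <- edt[ijk_to_idx(ijk, dm)]
  keep <- which(ed >= 0.6 * max(ed))
  last <- max(keep[length(keep)], 3L)
  p[seq_len(last), , drop = FALSE]
}

# moving-average smoothing of a polyline, endpoints fixed
smooth_path <- function(p, window = 3) {
  n <- nrow(p)
  if (n < window + 2) return(p)
  h <- (window - 1) %/% 2
  out <- p
  for (i in 2:(n - 1)) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    out[i, ] <- colMeans(p[lo:hi, , drop = FALSE])
  }
  out
}

# move each path point to the centroid of its perpendicular lumen contour
recenter_path <- function(p, maskn, spacing, n_rays = 16, passes = 2,
                          r_max = 20) {
  step <- 0.3 * min(spacing)
  ang <- seq(0, 2 * pi, length.out = n_rays + 1)[-(n_rays + 1)]
  rr <- seq(step, r_max, by = step)
  for (pass in seq_len(passes)) {
    p <- smooth_path(p)
    n <- nrow(p)
    for (i in seq_len(n)) {
      t0 <- if (i == 1) p[2, ] - p[1, ]
      else if (i == n) p[n, ] - p[n - 1, ]
      else p[i + 1, ] - p[i - 1, ]
      nv <- sqrt(sum(t0^2))
      if (nv < 1e-9) next
      t0 <- t0 / nv
      fr <- plane_frame(t0)
      bx <- by <- numeric(0)
      ok <- 0L
      for (a in ang) {
        dirv <- cos(a) * fr$u + sin(a) * fr$w
        smp <- interp_trilinear(maskn, spacing,
                                cbind(p[i, 1] + rr * dirv[1],
                                      p[i, 2] + rr * dirv[2],
                                      p[i, 3] + rr * dirv[3]),
                                outside = 0)
        cross <- which(smp < 0.5)
        if (!length(cross)) next
        k <- cross[1]
        r0 <- if (k == 1) rr[1] / 2 else {
          f <- (0.5 - smp[k - 1]) / (smp[k] - smp[k - 1])
          rr[k - 1] + f * (rr[k] - rr[k - 1])
        }
        bx <- c(bx, r0 * cos(a)); by <- c(by, r0 * sin(a))
        ok <- ok + 1L
      }
      if (ok >= n_rays * 0.75) {
        p[i, ] <- p[i, ] + mean(bx) * fr$u + mean(by) * fr$w
      }
    }
  }
  p
}

# principal direction of the proximal part of a branch, skipping the
# junction-flare zone (the flare extends about one parent radius past the
# branch origin) and spanning about 5 mm of centerline so voxel-scale
# zigzag averages out
branch_direction <- function(p, radius_mm, parent_radius_mm, spacing,
                             span_mm = 5) {
  n <- nrow(p)
  if (n < 2) return(c(NA_real_, NA_real_, NA_real_))
  arc <- c(0, cumsum(sqrt(rowSums((p[-1, , drop = FALSE] -
                                     p[-n, , drop = FALSE])^2))))
  L <- arc[n]
  a0 <- min(1.6 * max(radius_mm, parent_radius_mm), L / 3)
  a1 <- max(a0 + 2, min(a0 + span_mm, L - 1.0 * radius_mm))
  idx <- which(arc >= a0 & arc <= a1)
  if (length(idx) < 3) idx <- which(arc >= a0)
  if (length(idx) < 3) idx <- seq_len(n)
  q <- p[idx, , drop = FALSE]
  qc <- sweep(q, 2, colMeans(q))
  sv <- svd(qc, nu = 0, nv = 1)
  d <- sv$v[, 1]
  if (sum(d * (q[nrow(q), ] - q[1, ])) < 0) d <- -d
  unitize(d)
}

# end-to-end branch direction, trimming about one radius at each end
# (blunt-end caps and junction flares bend the extreme path points)
global_direction <- function(p, radius_mm) {
  n <- nrow(p)
  if (n < 2) return(c(NA_real_, NA_real_, NA_real_))
  arc <- c(0, cumsum(sqrt(rowSums((p[-1, , drop = FALSE] -
                                     p[-n, , drop = FALSE])^2))))
  L <- arc[n]
  trim <- min(2.5 * radius_mm, L / 4)
  idx <- which(arc >= trim & arc <= L - trim)
  if (length(idx) < 2) idx <- seq_len(n)
  q <- p[idx, , drop = FALSE]
  qc <- sweep(q, 2, colMeans(q))
  d <- svd(qc, nu = 0, nv = 1)$v[, 1]
  if (sum(d * (q[nrow(q), ] - q[1, ])) < 0) d <- -d
  unitize(d)
}

#' @export
print.airway_tree <- function(x, ...) {
  lab <- vapply(x$branches, function(b) b$label %||% NA_character_,
                character(1))
  cat("<airway_tree> ", length(x$branches), " branches (",
      sum(!is.na(lab)), " labeled)\n", sep = "")
  invisible(x)
}

#' Branch summary of an airway tree
#'
#' @param x an `airway_tree`.
#' @param ... unused.
#' @return data.frame with one row per branch: id, parent, label,
#'   length_mm, mean radius and direction components.
#' @export
as.data.frame.airway_tree <- function(x, ...) {
  do.call(rbind, lapply(x$branches, function(b)
    data.frame(id = b$id, parent = b$parent,
               label = b$label %||% NA_character_,
               length_mm = b$length_mm, radius_mm = b$radius_mm,
               dx = b$direction[1], dy = b$direction[2],
               dz = b$direction[3])))
}
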