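# Phantom builders shared across test files.  Everything is generated in
# code; no fixture files.

deg_between <- function(a, b) {
  acos(pmin(1, pmax(-1, sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}

one_branch <- function(name, parent, d, len, r, w) {
  data.frame(name = name, parent = parent, dx = d[1], dy = d[2], dz = d[3],
             length_mm = len, r_in_mm = r, wall_mm = w, label = name,
             subgroup = NA, stringsAsFactors = FALSE)
}

# straight cylinder along -z, 0.5 mm voxels unless overridden
cylinder_spec <- function(r_in = 4, wall = 1.5, len = 40, spacing = 0.5,
                          dir = c(0, 0, -1), dim = NULL, noise_sd = 0,
                          seed = 7, root_origin = NULL) {
  if (is.null(dim)) dim <- round(c(24, 24, 48) / spacing)
  phantom_spec(dim = dim, spacing = rep(spacing, 3),
               airway = one_branch("Trachea", "", dir, len, r_in, wall),
               mixture = c(normal = 1), noise_sd = noise_sd, seed = seed,
               root_origin = root_origin)
}

# symmetric Y: parent plus two daughters with a known included angle
y_spec <- function(angle = 70, spacing = 0.5, seed = 3) {
  h <- angle / 2 * pi / 180
  d1 <- c(sin(h), 0, -cos(h))
  d2 <- c(-sin(h), 0, -cos(h))
  phantom_spec(dim = round(c(48, 24, 48) / spacing),
               spacing = rep(spacing, 3),
               airway = rbind(
                 one_branch("Trachea", "", c(0, 0, -1), 16, 3, 1),
                 one_branch("A", "Trachea", d1, 14, 2, 0.8),
                 one_branch("B", "Trachea", d2, 14, 2, 0.8)),
               mixture = c(normal = 1), noise_sd = 0, seed = seed)
}

# trifurcation: three daughters at polar angle 35 deg, azimuths 120 deg
# apart; every pairwise included angle is acos(cos^2(35) + sin^2(35)/(-2))
trifurcation_spec <- function(polar = 35, spacing = 0.5, seed = 5) {
  ph <- polar * pi / 180
  dd <- lapply(c(0, 120, 240) * pi / 180, function(az)
    c(sin(ph) * cos(az), sin(ph) * sin(az), -cos(ph)))
  phantom_spec(dim = round(c(48, 48, 48) / spacing),
               spacing = rep(spacing, 3),
               airway = rbind(
                 one_branch("Trachea", "", c(0, 0, -1), 14, 2.2, 0.8),
                 one_branch("A", "Trachea", dd[[1]], 12, 1.4, 0.6),
                 one_branch("B", "Trachea", dd[[2]], 12, 1.4, 0.6),
                 one_branch("C", "Trachea", dd[[3]], 12, 1.4, 0.6)),
               mixture = c(normal = 1), noise_sd = 0, seed = seed)
}

trifurcation_pair_angle <- function(polar = 35) {
  c2 <- cos(polar * pi / 180)^2
  s2 <- sin(polar * pi / 180)^2
  acos(c2 - s2 / 2) * 180 / pi
}

# build a mask of axis-aligned cylinders directly (for vessel tests)
mask_with_cylinders <- function(dm, sp, cylinders) {
  mask <- array(FALSE, dm)
  x <- ((seq_len(dm[1])) - 0.5) * sp
  y <- ((seq_len(dm[2])) - 0.5) * sp
  z <- ((seq_len(dm[3])) - 0.5) * sp
  for (cy in cylinders) {
    d2 <- outer((x - cy$ctr[1])^2, (y - cy$ctr[2])^2, `+`)
    for (k in which(z >= cy$z[1] & z <= cy$z[2]))
      mask[, , k] <- mask[, , k] | (d2 <= cy$r^2)
  }
  mask
}

# small random vessel tree spec inside a 24 mm cube
random_vessel_spec <- function(seed) {
  set.seed(seed)
  nb <- sample(3:6, 1)
  tab <- data.frame(name = "v1", parent = "", dx = 0, dy = 0, dz = -1,
                    length_mm = runif(1, 4, 6), r_mm = runif(1, 0.8, 1.5),
                    stringsAsFactors = FALSE)
  for (i in 2:nb) {
    par <- tab$name[sample.int(nrow(tab), 1)]
    d <- c(runif(2, -0.6, 0.6), -runif(1, 0.5, 1))
    tab <- rbind(tab, data.frame(
      name = paste0("v", i), parent = par, dx = d[1], dy = d[2], dz = d[3],
      length_mm = runif(1, 3, 5),
      r_mm = runif(1, 0.5, tab$r_mm[tab$name == par])))
  }
  phantom_spec(dim = c(48, 48, 48), spacing = rep(0.5, 3), airway = NULL,
               vessel = tab, mixture = c(normal = 1), noise_sd = 0,
               seed = seed, vessel_origin = c(12, 12, 22))
}
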