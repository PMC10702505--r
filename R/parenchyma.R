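#' Hounsfield-unit class scheme for parenchymal classification
#'
#' The default scheme partitions lung HU into five mutually exclusive
#' classes — emphysema (under -950 HU), normal lung (-950 to -701), ground
#' glass opacity (-700 to -501), semi consolidation (-500 to -201) and
#' consolidation (-200 to 60) — plus an overlapping, report-only fibrosis
#' class (-500 to 0 HU) that spans parts of the semi consolidation and
#' consolidation ranges.  The printed integer bounds have 1-HU gaps; they
#' are extended to continuous HU by half-open intervals at the half-unit
#' (e.g. normal = \[-950.5, -700.5)), which reproduces the integer table
#' exactly and leaves no gaps.  Voxels above 60 HU are reported as
#' unclassified.
#'
#' @param breaks numeric upper bounds (half-open) of the exclusive
#'   classes, in increasing order; the classes are `(-Inf, b1)`,
#'   `[b1, b2)`, ..., `[b_{k-1}, b_k)`, and HU at or above the last break
#'   is unclassified.
#' @param names one class name per interval (same length as `breaks`).
#' @param fibrosis length-2 numeric range of the overlapping fibrosis
#'   class.
#' @return An object of class `hu_class_scheme`.
#' @export
hu_class_scheme <- function(breaks = c(-950.5, -700.5, -500.5, -200.5, 60.5),
                            names = c("emphysema", "normal", "ggo",
                                      "semiconsolidation", "consolidation"),
                            fibrosis = c(-500.5, 0.5)) {
  if (length(names) != length(breaks))
    stop("need one class name per break (classes are (-Inf, b1), [b1, b2), ...)")
  if (is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing")
  if (fibrosis[1] < breaks[2] || fibrosis[2] > breaks[length(breaks)])
    stop("fibrosis range must lie inside the abnormal-density classes")
  structure(list(breaks = breaks, names = names, fibrosis = fibrosis),
            class = "hu_class_scheme")
}

#' Classify lung voxels into HU density classes
#'
#' Every lung-mask voxel is assigned to exactly one exclusive class (or to
#' "unclassified" above the last break); the overlapping fibrosis class is
#' counted independently over its own HU range and reported alongside.
#' Fractions are exact ratios of voxel counts, so the exclusive fractions
#' plus the unclassified fraction sum to 1 exactly.
#'
#' @param volume a [volume_grid()] with a nonempty `lung_mask`.
#' @param scheme a [hu_class_scheme()].
#' @param exclude_airways if `TRUE` (default) airway lumen/wall voxels are
#'   excluded from the lung mask when an airway mask is available (the
#'   phantom generator already excludes them).
#' @return An object of class `parenchyma_report`: list with `fractions`
#'   (named, exclusive classes), `unclassified`, `fibrosis`, `n_lung`,
#'   `counts` and `histogram` (see [hu_histogram()]).
#' @export
classify_parenchyma <- function(volume, scheme = hu_class_scheme(),
                                exclude_airways = TRUE) {
  stopifnot(inherits(volume, "volume_grid"))
  mask <- volume$lung_mask
  if (is.null(mask) || !any(mask)) stop("lung mask is empty")
  if (exclude_airways && !is.null(volume$airway_mask))
    mask <- mask & !volume$airway_mask
  hu <- volume$hu[mask]
  nbad <- sum(!is.finite(hu))
  if (nbad > 0) stop(nbad, " lung voxels have non-finite HU")
  n <- length(hu)
  cls <- findInterval(hu, scheme$breaks)        # 0 = first class
  counts <- tabulate(cls + 1L, nbins = length(scheme$breaks) + 1L)
  names(counts) <- c(scheme$names, "unclassified")
  fib_n <- sum(hu >= scheme$fibrosis[1] & hu < scheme$fibrosis[2])
  structure(list(
    fractions = counts[scheme$names] / n,
    unclassified = counts[["unclassified"]] / n,
    fibrosis = fib_n / n,
    n_lung = n,
    counts = counts,
    histogram = hu_histogram_values(hu)),
    class = "parenchyma_report")
}

#' @export
print.parenchyma_report <- function(x, ...) {
  cat("<parenchyma_report> ", x$n_lung, " lung voxels\n", sep = "")
  fr <- c(x$fractions, unclassified = x$unclassified, fibrosis = x$fibrosis)
  for (i in seq_along(fr))
    cat(sprintf("  %-18s %.4f\n", names(fr)[i], fr[i]))
  invisible(x)
}

hu_histogram_values <- function(hu, range = c(-1024L, 200L)) {
  b <- pmin(pmax(round(hu), range[1]), range[2])
  data.frame(hu = seq(range[1], range[2]),
             count = tabulate(b - range[1] + 1L,
                              nbins = range[2] - range[1] + 1L))
}

#' Voxel-count-per-HU histogram of the lung
#'
#' Integer counts per 1-HU bin over \[-1024, 200\] (values outside the
#' range are clamped into the end bins), summing to the lung voxel count.
#'
#' @inheritParams classify_parenchyma
#' @return data.frame with columns `hu` and `count`.
#' @export
hu_histogram <- function(volume, exclude_airways = TRUE) {
  stopifnot(inherits(volume, "volume_grid"))
  mask <- volume$lung_mask
  if (is.null(mask) || !any(mask)) stop("lung mask is empty")
  if (exclude_airways && !is.null(volume$airway_mask))
    mask <- mask & !volume$airway_mask
  hu <- volume$hu[mask]
  if (any(!is.finite(hu))) stop("non-finite HU inside the lung mask")
  hu_histogram_values(hu)
}
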