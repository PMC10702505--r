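#' CT-like volume container
#'
#' A `volume_grid` bundles a 3-D Hounsfield-unit (HU) array with its voxel
#' spacing in mm and the masks the analysis modules consume: the lung
#' (parenchyma) mask, the airway lumen mask and the vessel mask, plus an
#' optional integer ground-truth label array for phantoms.
#'
#' Label codes used by the phantom generator: 1 airway lumen, 2 airway
#' wall, 3 vessel, 11-15 the five exclusive parenchymal classes
#' (emphysema, normal, ground-glass opacity, semi consolidation,
#' consolidation).
#'
#' @param hu 3-D numeric array of HU values.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param lung_mask,airway_mask,vessel_mask optional logical arrays of the
#'   same dimension as `hu`.
#' @param labels optional integer array of ground-truth tissue codes.
#' @param truth optional list of generator ground truth (airway/vessel
#'   branch tables with realized endpoints).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(hu, spacing, lung_mask = NULL, airway_mask = NULL,
                        vessel_mask = NULL, labels = NULL, truth = NULL) {
  if (length(dim(hu)) != 3) stop("hu must be a 3-D array")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers (mm)")
  if (any(!is.finite(hu))) stop("HU values must be finite")
  for (m in list(lung_mask, airway_mask, vessel_mask, labels)) {
    if (!is.null(m) && !identical(dim(m), dim(hu)))
      stop("all masks must match the HU grid dimensions")
  }
  structure(
    list(hu = hu, spacing = as.numeric(spacing),
         lung_mask = lung_mask, airway_mask = airway_mask,
         vessel_mask = vessel_mask, labels = labels, truth = truth),
    class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$hu)
  cat("<volume_grid> ", paste(d, collapse = " x "), " voxels, spacing ",
      paste(signif(x$spacing, 4), collapse = " x "), " mm\n", sep = "")
  cat("  HU range: [", round(min(x$hu)), ", ", round(max(x$hu)), "]\n",
      sep = "")
  for (m in c("lung_mask", "airway_mask", "vessel_mask"))
    if (!is.null(x[[m]]))
      cat("  ", m, ": ", sum(x[[m]]), " voxels\n", sep = "")
  invisible(x)
}

#' Write a volume (and its masks) as NIfTI files
#'
#' Writes `hu.nii.gz`, and when present `labels.nii.gz`, `lung_mask.nii.gz`,
#' `airway_mask.nii.gz`, `vessel_mask.nii.gz`, with the voxel spacing
#' recorded in the NIfTI header.
#'
#' @param vol a [volume_grid()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_volume <- function(vol, dir) {
  stopifnot(inherits(vol, "volume_grid"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(arr, name, datatype) {
    img <- RNifti::asNifti(arr, datatype = datatype)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")))
  }
  wr(vol$hu, "hu", "int16")
  if (!is.null(vol$labels)) wr(vol$labels, "labels", "uint8")
  for (m in c("lung_mask", "airway_mask", "vessel_mask"))
    if (!is.null(vol[[m]])) wr(vol[[m]] + 0L, m, "uint8")
  invisible(dir)
}

#' Read a volume written by [write_volume()]
#'
#' @param dir directory containing `hu.nii.gz` and optional mask files.
#' @return A [volume_grid()].
#' @export
read_volume <- function(dir) {
  rd <- function(name) {
    f <- file.path(dir, paste0(name, ".nii.gz"))
    if (!file.exists(f)) return(NULL)
    img <- RNifti::readNifti(f)
    list(arr = array(as.numeric(img), dim = dim(img)),
         spacing = RNifti::pixdim(img)[1:3])
  }
  hu <- rd("hu")
  if (is.null(hu)) stop("no hu.nii.gz in ", dir)
  msk <- function(name) {
    r <- rd(name)
    if (is.null(r)) NULL else array(r$arr > 0, dim = dim(r$arr))
  }
  lab <- rd("labels")
  volume_grid(hu$arr, hu$spacing,
              lung_mask = msk("lung_mask"),
              airway_mask = msk("airway_mask"),
              vessel_mask = msk("vessel_mask"),
              labels = if (is.null(lab)) NULL else
                array(as.integer(lab$arr), dim = dim(lab$arr)))
}
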