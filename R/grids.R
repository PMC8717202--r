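#' Voxel grid container
#'
#' A light container for 3-D rasters: a named list holding `spacing`
#' (voxel size in micrometers, length 3), an optional integer `labels`
#' array (0 = background, 1 = healthy, 2 = tumor) and an optional numeric
#' `expression` array (receptor-expression-like intensity, arbitrary
#' units). All arrays share `dim`. Grids are 0-based index + spacing +
#' origin; physical coordinates are never 1-based.
#'
#' @param dim integer length-3 grid dimensions (voxels).
#' @param spacing numeric length-3 voxel size in micrometers.
#' @param labels optional integer array of cell-type labels.
#' @param expression optional numeric array of expression intensity.
#' @param origin physical coordinate of the voxel (0,0,0) corner, um.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(dim, spacing, labels = NULL, expression = NULL,
                       origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim <= 0L))
    stop("`dim` must be three positive integers", call. = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes (um)", call. = FALSE)
  if (!is.null(labels) && !identical(dim(labels), as.integer(dim)))
    stop("`labels` dimensions do not match `dim`", call. = FALSE)
  if (!is.null(expression) && !identical(dim(expression), as.integer(dim)))
    stop("`expression` dimensions do not match `dim`", call. = FALSE)
  structure(list(dim = dim, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 labels = labels, expression = expression),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("voxel_grid:", paste(x$dim, collapse = " x "), "voxels,",
      paste(signif(x$spacing, 4), collapse = " x "), "um\n")
  if (!is.null(x$labels)) {
    tf <- tumor_fraction(x)
    cat(sprintf("  tissue voxels: %d, tumor fraction %.3f\n",
                sum(x$labels > 0L), tf))
  }
  invisible(x)
}

#' Tumor fraction of a labeled grid
#'
#' Fraction of tissue voxels (label > 0) carrying the tumor label.
#'
#' @param grid a `voxel_grid` with labels.
#' @return numeric scalar in `[0, 1]`.
#' @export
tumor_fraction <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"), !is.null(grid$labels))
  n_tissue <- sum(grid$labels > 0L)
  if (n_tissue == 0L) return(NA_real_)
  sum(grid$labels == 2L) / n_tissue
}

#' Voxel volume and mass
#'
#' Voxel volume in cubic micrometers and mass in kilograms assuming unit
#' (water) density.
#'
#' @param spacing voxel size, um (length 3).
#' @return list with `volume_um3` and `mass_kg`.
#' @export
voxel_mass <- function(spacing) {
  v <- prod(spacing)                 # um^3
  list(volume_um3 = v, mass_kg = v * 1e-18 * 1000)  # 1 um^3 = 1e-18 m^3
}

#' Read and write 3-D rasters
#'
#' Rasters are stored as NIfTI volumes with the voxel spacing (um) carried
#' in the pixdim fields. `write_raster()` accepts a bare array plus
#' spacing, or any object with `$values`/`$spacing` fields.
#'
#' @param x numeric 3-D array.
#' @param path output/input file path (`.nii` or `.nii.gz`).
#' @param spacing voxel size in um, length 3.
#' @return `read_raster()` returns a list with `values` and `spacing`.
#' @export
write_raster <- function(x, path, spacing) {
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  list(values = vals, spacing = unname(RNifti::pixdim(img)))
}
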