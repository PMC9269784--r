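#' Construct a voxel mask
#'
#' A `voxel_mask` is a binary 3D occupancy grid on an anisotropic voxel
#' lattice: the region of interest (ROI) of one lesion. The grid is stored
#' in (x, y, z) axis order; `spacing` gives the physical edge length of a
#' voxel along each axis in mm. Masks are analysed in the file's own voxel
#' lattice: no resampling and no reorientation to anatomical axes is ever
#' applied, because the axis-aligned bounding box that underlies the form
#' factors is defined in image space.
#'
#' @param grid 3D array; nonzero entries are foreground and are binarized
#'   to 1.
#' @param spacing Numeric length-3, mm per voxel along (x, y, z); all
#'   components must be strictly positive and finite.
#' @param origin Numeric length-3, physical coordinate of the first voxel
#'   (mm). Informational only.
#' @return An object of class `voxel_mask` with elements `grid`
#'   (integer 0/1 array), `spacing`, and `origin`.
#' @examples
#' g <- array(0L, c(5, 5, 5)); g[2:4, 2:4, 2:4] <- 1L
#' m <- voxel_mask(g, spacing = c(1.37, 1.37, 3.27))
#' @export
voxel_mask <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(grid)) != 3L)
    stop("mask grid must be a 3D array, got ", length(dim(grid)), " dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive finite values (mm)")
  storage.mode(grid) <- "integer"
  grid[] <- as.integer(grid != 0L)  # binarization (idempotent)
  structure(list(grid = grid, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %s voxels, %d foreground, spacing (%g, %g, %g) mm\n",
              paste(dim(x$grid), collapse = "x"), sum(x$grid),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

n_foreground <- function(mask) sum(mask$grid)

stopifnot_nonempty <- function(mask) {
  if (n_foreground(mask) == 0L)
    stop("empty ROI: mask contains no foreground voxels")
}

#' Read a binary ROI mask from NIfTI or NRRD
#'
#' Reads a 3D scalar volume, binarizes it (nonzero to 1), and attaches the
#' voxel spacing from the header. The volume is interpreted on its stored
#' (x, y, z) lattice.
#'
#' @param path Path to a `.nii`, `.nii.gz`, or `.nrrd` file.
#' @param format `"auto"` (by extension), `"nifti"`, or `"nrrd"`.
#' @return A [voxel_mask].
#' @export
read_mask <- function(path, format = c("auto", "nifti", "nrrd")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    lower <- tolower(path)
    format <- if (grepl("\\.nrrd$", lower)) "nrrd"
      else if (grepl("\\.nii(\\.gz)?$", lower)) "nifti"
      else stop("cannot infer mask format from extension of ", path)
  }
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
      stop("expected a 3D volume, got ", length(d), "D in ", path)
    spc <- RNifti::pixdim(img)[seq_len(3)]
    if (any(!is.finite(spc)) || any(spc <= 0))
      stop("missing or non-positive voxel spacing in NIfTI header of ", path)
    voxel_mask(array(as.numeric(img), dim = d), spacing = spc)
  } else {
    vol <- read_nrrd(path)
    if (length(dim(vol$data)) != 3L)
      stop("expected a 3D volume, got ", length(dim(vol$data)), "D in ", path)
    if (is.null(vol$spacing) || any(!is.finite(vol$spacing)) ||
        any(vol$spacing <= 0))
      stop("missing or non-positive voxel spacing in NRRD header of ", path)
    voxel_mask(vol$data, spacing = vol$spacing)
  }
}

#' Write a binary ROI mask to NIfTI or NRRD
#'
#' Round-trip safe: `read_mask(write_mask(m))` recovers the grid bit-exactly
#' and the spacing to double precision (NIfTI headers store spacing as
#' single-precision floats; NRRD keeps full precision).
#'
#' @param mask A [voxel_mask].
#' @param path Output path.
#' @param format `"nifti"` or `"nrrd"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, format = c("auto", "nifti", "nrrd")) {
  format <- match.arg(format)
  if (format == "auto") {
    lower <- tolower(path)
    format <- if (grepl("\\.nrrd$", lower)) "nrrd" else "nifti"
  }
  if (format == "nifti") {
    img <- RNifti::asNifti(mask$grid)
    RNifti::pixdim(img) <- mask$spacing
    RNifti::writeNifti(img, path)
  } else {
    write_nrrd(mask$grid, path, spacing = mask$spacing)
  }
  if (!file.exists(path)) stop("failed to write mask to ", path)
  invisible(path)
}

#' Validate a mask and optionally keep only its largest component
#'
#' Raises on an empty mask. With `require_single_component = TRUE` the
#' largest 26-connected foreground component is retained and the number of
#' discarded components is reported via a message. The default keeps the
#' ROI exactly as delineated, since manual delineations are analysed
#' without post-processing.
#'
#' @param mask A [voxel_mask].
#' @param require_single_component Keep only the largest 26-connected
#'   component? Default `FALSE`.
#' @return A [voxel_mask].
#' @export
validate_mask <- function(mask, require_single_component = FALSE) {
  stopifnot_nonempty(mask)
  if (!require_single_component) return(mask)
  labels <- .label_components26(mask$grid, dim(mask$grid))
  sizes <- tabulate(labels[labels > 0L])
  if (length(sizes) > 1L) {
    keep <- which.max(sizes)
    message(sprintf("validate_mask: removed %d smaller component(s), kept %d voxels",
                    length(sizes) - 1L, sizes[keep]))
    g <- mask$grid
    g[] <- as.integer(labels == keep)
    mask$grid <- g
  }
  mask
}
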