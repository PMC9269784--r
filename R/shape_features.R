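#' Axis-aligned bounding-box dimensions of a mask
#'
#' Computes the side lengths of the rectangular axis-aligned bounding box
#' of the ROI in physical units. Per axis the side is
#' `(max_index - min_index + 1) * spacing`, i.e. the full voxel extents
#' rather than center-to-center distance, so a single-voxel lesion has a
#' box of one full voxel. The three sides sorted in descending order are
#' the length `l`, breadth `b`, and thickness `t` of the lesion, the raw
#' material of all form factors.
#'
#' @param mask A [voxel_mask].
#' @return Named numeric vector `c(l, b, t)` in mm, with `l >= b >= t > 0`.
#' @examples
#' g <- array(0L, c(25, 15, 10)); g[3:22, 3:12, 3:7] <- 1L
#' bounding_box_dims(voxel_mask(g))  # c(l = 20, b = 10, t = 5)
#' @export
bounding_box_dims <- function(mask) {
  stopifnot_nonempty(mask)
  idx <- which(mask$grid == 1L, arr.ind = TRUE)
  extents <- (apply(idx, 2, max) - apply(idx, 2, min) + 1) * mask$spacing
  sides <- sort(extents, decreasing = TRUE)
  c(l = sides[[1]], b = sides[[2]], t = sides[[3]])
}

check_dims <- function(dims) {
  if (length(dims) != 3L || any(!is.finite(dims)) || any(dims <= 0))
    stop("box dimensions must be three positive finite values (mm)")
  l <- dims[[1]]; b <- dims[[2]]; t <- dims[[3]]
  if (l < b || b < t)
    stop("box dimensions must satisfy l >= b >= t; got (",
         paste(signif(dims, 6), collapse = ", "), ")")
  c(l = l, b = b, t = t)
}

#' Angelidakis elongation, flatness, and compactness
#'
#' Three-part decomposition of overall form into elongated (rod-like),
#' flat (platy), and compact (equant) fractions:
#' `ael = (l - b) / (l + b + t)`, `afl = 2 (b - t) / (l + b + t)`,
#' `aco = 3 t / (l + b + t)`. Each lies in \[0, 1\] and the three sum to 1
#' exactly, so they can be read as percentages of an overall shape class.
#'
#' @param dims Box dimensions `c(l, b, t)` with `l >= b >= t > 0`, e.g.
#'   from [bounding_box_dims()].
#' @return Named numeric vector `c(ael, afl, aco)`.
#' @examples
#' angelidakis_indices(c(4, 2, 1))  # (2/7, 2/7, 3/7)
#' @export
angelidakis_indices <- function(dims) {
  d <- check_dims(dims)
  s <- sum(d)
  c(ael = (d[["l"]] - d[["b"]]) / s,
    afl = 2 * (d[["b"]] - d[["t"]]) / s,
    aco = 3 * d[["t"]] / s)
}

#' Kong elongation and flatness
#'
#' `kel = 1 - b / l` and `kfl = 1 - t / b`; both vanish for an equant
#' (cube-like) shape and approach 1 for extreme rods / plates.
#'
#' @inheritParams angelidakis_indices
#' @return Named numeric vector `c(kel, kfl)`, each in \[0, 1).
#' @export
kong_indices <- function(dims) {
  d <- check_dims(dims)
  c(kel = 1 - d[["b"]] / d[["l"]],
    kfl = 1 - d[["t"]] / d[["b"]])
}

#' Maximum projection sphericity
#'
#' The Sneed-Folk form factor `(t^2 / (l b))^(1/3)`, in (0, 1]; equals 1
#' for an equant shape.
#'
#' @inheritParams angelidakis_indices
#' @return Scalar in (0, 1].
#' @export
max_projection_sphericity <- function(dims) {
  d <- check_dims(dims)
  (d[["t"]]^2 / (d[["l"]] * d[["b"]]))^(1 / 3)
}

#' Voxel volume of a mask
#'
#' Foreground voxel count times the physical volume of one voxel.
#'
#' @param mask A [voxel_mask].
#' @return Volume in mm^3.
#' @export
voxel_volume <- function(mask) {
  stopifnot_nonempty(mask)
  n_foreground(mask) * prod(mask$spacing)
}

#' Triangulated isosurface of a binary mask
#'
#' Extracts a closed triangle mesh of the ROI boundary at iso-level 0.5,
#' scaled by the voxel spacing. The binary volume is padded with a
#' zero-voxel margin so the mesh always closes, and (by default) smoothed
#' with a Gaussian of `smoothing_sigma` voxels before extraction: the
#' midpoint surface of a raw binary volume carries a staircase bias that
#' overestimates curved surface areas by several percent, and a one-voxel
#' smoothing removes it while leaving flat faces in place. Set
#' `smoothing_sigma = 0` for the raw binary isosurface (used internally
#' for the maximum 3D diameter, where smoothing would erode corners). If
#' the ROI is too small to survive smoothing the raw isosurface is
#' returned instead.
#'
#' The extraction marches the six Kuhn tetrahedra of each grid cell
#' (marching-cubes family); the subdivision tiles the lattice
#' consistently, so shared faces agree and the surface is closed.
#'
#' @param mask A [voxel_mask].
#' @param smoothing_sigma Gaussian sigma in voxels; 0 disables smoothing.
#' @param iso Iso-level, default 0.5.
#' @return A list of class `lesion_mesh` with `vertices` (n x 3 matrix,
#'   mm, in the mask's physical frame) and `triangles` (m x 3 integer
#'   matrix of 1-based vertex indices).
#' @export
surface_mesh <- function(mask, smoothing_sigma = 1, iso = 0.5) {
  stopifnot_nonempty(mask)
  pad <- as.integer(ceiling(3 * max(smoothing_sigma, 0))) + 1L
  d <- dim(mask$grid)
  field <- array(0, d + 2L * pad)
  field[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    mask$grid
  if (smoothing_sigma > 0) {
    sm <- .gaussian_smooth3d(field, dim(field), smoothing_sigma)
    if (max(sm) >= iso) field <- sm
    # else: ROI thinner than the kernel; fall back to the binary field
  }
  res <- .mt_isosurface(as.numeric(field), dim(field), mask$spacing, iso)
  res$vertices <- sweep(res$vertices, 2, pad * mask$spacing)
  class(res) <- "lesion_mesh"
  res
}

#' @export
print.lesion_mesh <- function(x, ...) {
  cat(sprintf("<lesion_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Surface area of a lesion
#'
#' Sum of triangle areas of the surface mesh. Accepts either a mesh from
#' [surface_mesh()] or a [voxel_mask] (meshed with default settings). A
#' voxel-face mode (`method = "voxel"`, mask input only) instead counts
#' exposed voxel faces; it is exact for axis-aligned solids but
#' overestimates curved surfaces, and is provided for sensitivity
#' analysis.
#'
#' @param x A `lesion_mesh` or a [voxel_mask].
#' @param method `"mesh"` (default) or `"voxel"`.
#' @return Area in mm^2.
#' @export
surface_area <- function(x, method = c("mesh", "voxel")) {
  method <- match.arg(method)
  if (method == "voxel") {
    if (!inherits(x, "voxel_mask"))
      stop("voxel-face area requires a voxel_mask input")
    return(voxel_face_area(x))
  }
  if (inherits(x, "voxel_mask")) x <- surface_mesh(x)
  v <- x$vertices
  f <- x$triangles
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

voxel_face_area <- function(mask) {
  stopifnot_nonempty(mask)
  g <- mask$grid
  d <- dim(g)
  s <- mask$spacing
  pad <- array(0L, d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- g
  shift_pairs <- function(axis) {
    n <- dim(pad)[axis]
    lo <- slice.index(pad, axis) <= n - 1L
    hi <- slice.index(pad, axis) >= 2L
    sum(abs(pad[lo] - pad[hi]))  # exposed faces perpendicular to `axis`
  }
  face_areas <- c(s[2] * s[3], s[1] * s[3], s[1] * s[2])
  sum(vapply(1:3, shift_pairs, numeric(1)) * face_areas)
}

#' Maximum 3D diameter of a lesion
#'
#' The largest pairwise Euclidean distance between vertices of the raw
#' (unsmoothed) binary isosurface, in mm, found by exhaustive pairwise
#' search over the deduplicated vertex set in compiled code. Always at
#' least the bounding-box length `l`, and exact for solid axis-aligned
#' cuboids (a single voxel yields its diagonal
#' `sqrt(sx^2 + sy^2 + sz^2)`). On curved shapes the surface vertices of
#' the voxelized solid lie up to half a voxel diagonal outside the
#' analytic surface, so the estimate carries a small positive bias that
#' vanishes linearly with the voxel size.
#'
#' @param mask A [voxel_mask].
#' @return Diameter in mm.
#' @export
max_3d_diameter <- function(mask) {
  mesh <- surface_mesh(mask, smoothing_sigma = 0)
  .max_pairwise_dist(mesh$vertices)
}

#' Sphericity
#'
#' `pi^(1/3) * (6 V)^(2/3) / A`: the ratio of the surface area of a
#' sphere with the lesion's volume to the lesion's actual surface area.
#' Equals 1 for a perfect sphere and decreases with surface irregularity.
#' Discretization can push the estimate marginally above 1; such values
#' are clipped to 1 with a warning.
#'
#' @param volume Volume in mm^3 (> 0).
#' @param area Surface area in mm^2 (> 0).
#' @return Scalar in (0, 1].
#' @export
sphericity <- function(volume, area) {
  if (!is.finite(volume) || !is.finite(area) || volume <= 0 || area <= 0)
    stop("sphericity requires positive, finite volume and area")
  s <- pi^(1 / 3) * (6 * volume)^(2 / 3) / area
  if (s > 1) {
    warning(sprintf("sphericity %.4f > 1 (discretization); clipped to 1", s))
    s <- 1
  }
  s
}

#' Volume density
#'
#' Lesion volume divided by the volume of its axis-aligned bounding box,
#' `V / (l b t)`, in (0, 1]; equals 1 for a solid cuboid and pi/6 for an
#' ideal axis-aligned ellipsoid.
#'
#' @param volume Volume in mm^3 (> 0).
#' @inheritParams angelidakis_indices
#' @return Scalar in (0, 1].
#' @export
volume_density <- function(volume, dims) {
  d <- check_dims(dims)
  if (!is.finite(volume) || volume <= 0)
    stop("volume_density requires a positive finite volume")
  volume / prod(d)
}

#' Extract all eleven shape features from a mask
#'
#' Computes the full feature vector of one lesion: maximum 3D diameter,
#' surface area, voxel volume, the Angelidakis decomposition (ael, afl,
#' aco), Kong elongation and flatness (kel, kfl), maximum projection
#' sphericity (mps), sphericity, and volume density (vdn). The
#' Angelidakis triple sums to 1 exactly for every lesion.
#'
#' @param mask A [voxel_mask].
#' @param area_method `"mesh"` (default) or `"voxel"`; see
#'   [surface_area()].
#' @return Named numeric vector of length 11 (see [feature_names()]).
#' @examples
#' m <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(8, 5, 3),
#'                                spacing = c(1, 1, 1)))
#' extract_all(m)
#' @export
extract_all <- function(mask, area_method = c("mesh", "voxel")) {
  area_method <- match.arg(area_method)
  stopifnot_nonempty(mask)
  dims <- bounding_box_dims(mask)
  vol <- voxel_volume(mask)
  area <- surface_area(mask, method = area_method)
  ang <- angelidakis_indices(dims)
  kong <- kong_indices(dims)
  c(max3ddiam = max_3d_diameter(mask),
    surfarea = area,
    volume = vol,
    ang,
    kong,
    mps = max_projection_sphericity(dims),
    sphericity = sphericity(vol, area),
    vdn = volume_density(vol, dims))
}

#' Extract features from a list of masks into a cohort-style table
#'
#' @param masks A list of [voxel_mask] objects.
#' @param lesion_ids Optional character vector of lesion identifiers.
#' @param area_method Passed to [extract_all()].
#' @return A tibble with `lesion_id` plus the 11 feature columns.
#' @export
extract_features <- function(masks, lesion_ids = NULL,
                             area_method = c("mesh", "voxel")) {
  area_method <- match.arg(area_method)
  if (is.null(lesion_ids))
    lesion_ids <- sprintf("lesion_%03d", seq_along(masks))
  rows <- t(vapply(masks, extract_all, numeric(length(FEATURE_NAMES)),
                   area_method = area_method))
  out <- tibble::as_tibble(as.data.frame(rows))
  names(out) <- FEATURE_NAMES
  tibble::add_column(out, lesion_id = as.character(lesion_ids),
                     .before = 1)
}
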