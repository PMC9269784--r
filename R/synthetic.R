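#' Specification of a geometric voxel phantom
#'
#' Describes an analytic solid to be voxelized: an ellipsoid, a cuboid
#' (box with half-sides `semi_axes`), or a superellipsoid
#' `|x/a|^e + |y/b|^e + |z/c|^e <= 1`. Phantoms have known closed-form
#' dimensions, volumes, and form factors, so they serve as oracles for
#' the feature-extraction stage.
#'
#' @param shape `"ellipsoid"`, `"cuboid"`, or `"superellipsoid"`.
#' @param semi_axes Numeric length-3, mm; need not be sorted.
#' @param spacing Voxel spacing (sx, sy, sz) in mm.
#' @param rotation Optional length-3 Euler angles (radians; intrinsic
#'   rotations about z, then y, then x) applied to the solid.
#' @param exponent Superellipsoid exponent (default 4).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("ellipsoid", "cuboid", "superellipsoid"),
                         semi_axes, spacing = c(1, 1, 1), rotation = NULL,
                         exponent = 4) {
  shape <- match.arg(shape)
  semi_axes <- as.numeric(semi_axes)
  spacing <- as.numeric(spacing)
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    stop("semi_axes must be three positive values (mm)")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive values (mm)")
  if (!is.null(rotation) && length(rotation) != 3L)
    stop("rotation must be NULL or three Euler angles (radians)")
  structure(list(shape = shape, semi_axes = semi_axes, spacing = spacing,
                 rotation = rotation, exponent = exponent),
            class = "phantom_spec")
}

euler_matrix <- function(angles) {
  cz <- cos(angles[1]); sz <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cx <- cos(angles[3]); sx <- sin(angles[3])
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  rz %*% ry %*% rx
}

#' Voxelize a phantom
#'
#' A voxel is foreground iff its center lies inside the analytic solid.
#' Per axis, the lattice is aligned so that the solid's ideal span is
#' realized exactly when it is a whole number of voxels: axes whose ideal
#' diameter spans an even number of voxels get centers offset half a
#' spacing from the solid's center, odd spans get a center voxel. This
#' keeps voxel centers off the analytic surface and makes bounding-box
#' dimensions exact for lattice-commensurate solids. Deterministic given
#' the spec.
#'
#' @param spec A [phantom_spec()].
#' @return A [voxel_mask].
#' @examples
#' m <- make_phantom(phantom_spec("cuboid", semi_axes = c(10, 5, 2.5)))
#' voxel_volume(m)  # exactly 20 * 10 * 5 = 1000 mm^3
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  half <- if (is.null(spec$rotation)) spec$semi_axes
    else rep(sqrt(sum(spec$semi_axes^2)), 3)  # bounding radius when rotated
  m <- half / spec$spacing  # ideal half-span in voxels
  odd_span <- round(2 * m) %% 2 == 1
  n <- as.integer(ifelse(odd_span, 2 * ceiling(m) + 3, 2 * (ceiling(m) + 1)))
  centers <- lapply(1:3, function(a) {
    if (odd_span[a]) (seq_len(n[a]) - (n[a] + 1) / 2) * spec$spacing[a]
    else (seq_len(n[a]) - n[a] / 2 - 0.5) * spec$spacing[a]
  })
  px <- rep(centers[[1]], times = n[2] * n[3])
  py <- rep(rep(centers[[2]], each = n[1]), times = n[3])
  pz <- rep(centers[[3]], each = n[1] * n[2])
  pts <- cbind(px, py, pz)
  if (!is.null(spec$rotation))
    pts <- pts %*% euler_matrix(spec$rotation)  # world -> solid frame
  q <- sweep(abs(pts), 2, spec$semi_axes, "/")
  inside <- switch(spec$shape,
    ellipsoid = rowSums(q^2) <= 1,
    cuboid = q[, 1] <= 1 & q[, 2] <= 1 & q[, 3] <= 1,
    superellipsoid = rowSums(q^spec$exponent) <= 1)
  if (!any(inside))
    stop("degenerate phantom: solid smaller than one voxel at this spacing")
  voxel_mask(array(as.integer(inside), dim = n), spacing = spec$spacing)
}

#' Beta distribution matched to a mean and SD
#'
#' Returns the shape parameters of the beta distribution whose analytic
#' mean and SD equal the targets exactly; the natural emulator for the
#' dimensionless shape features, whose support is \[0, 1\].
#'
#' @param mean Target mean in (0, 1).
#' @param sd Target SD; must satisfy `sd^2 < mean * (1 - mean)`.
#' @return A list with `shape1`, `shape2`, `mean`, `sd`.
#' @examples
#' moment_matched_beta(0.5, sqrt(1 / 12))  # shape1 = shape2 = 1 (uniform)
#' @export
moment_matched_beta <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) stop("mean must lie in (0, 1)")
  if (sd <= 0 || sd^2 >= mean * (1 - mean))
    stop(sprintf(
      "infeasible beta moments: need sd^2 < mean*(1-mean) = %.4g, got %.4g",
      mean * (1 - mean), sd^2))
  nu <- mean * (1 - mean) / sd^2 - 1
  list(shape1 = mean * nu, shape2 = (1 - mean) * nu, mean = mean, sd = sd)
}

#' Lognormal distribution matched to a mean and SD
#'
#' Returns `meanlog`/`sdlog` of the lognormal whose analytic mean and SD
#' equal the targets exactly; the emulator for the positive, right-skewed
#' size features (diameter, area, volume), and able to represent cohorts
#' whose SD exceeds the mean.
#'
#' @param mean Target mean (> 0).
#' @param sd Target SD (> 0).
#' @return A list with `meanlog`, `sdlog`, `mean`, `sd`.
#' @export
moment_matched_lognormal <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) stop("mean and sd must be positive")
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2), mean = mean, sd = sd)
}

#' Calibration of a synthetic two-group feature cohort
#'
#' Bundles per-feature, per-class target moments with group sizes.
#' Dimensionless features are validated for beta feasibility at
#' construction.
#'
#' @param moments A data frame with columns `feature`, `class`
#'   (`"benign"`/`"malignant"`), `mean`, `sd`.
#' @param n_benign,n_malignant Group sizes (>= 2).
#' @param dataset Dataset identifier carried into simulated cohorts.
#' @return A list of class `cohort_calibration`.
#' @seealso [load_calibration()] for the built-in SSR-1 and LUNGx
#'   calibrations.
#' @export
cohort_calibration <- function(moments, n_benign, n_malignant,
                               dataset = "synthetic") {
  need <- c("feature", "class", "mean", "sd")
  if (!all(need %in% names(moments)))
    stop("moments must have columns: ", paste(need, collapse = ", "))
  if (n_benign < 2L || n_malignant < 2L)
    stop("group sizes must be at least 2")
  if (any(moments$sd <= 0)) stop("all target SDs must be positive")
  for (i in seq_len(nrow(moments))) {
    f <- moments$feature[i]
    if (f %in% SIZE_FEATURES)
      moment_matched_lognormal(moments$mean[i], moments$sd[i])
    else
      moment_matched_beta(moments$mean[i], moments$sd[i])
  }
  structure(list(moments = tibble::as_tibble(moments[, need]),
                 n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant),
                 dataset = dataset),
            class = "cohort_calibration")
}

#' Load a cohort calibration
#'
#' `"SSR1"` and `"LUNGx"` name the two built-in calibrations shipped
#' under `inst/extdata/` (the published group means, SDs, and sizes of
#' the two lung-lesion datasets); any other value is treated as a path to
#' a calibration CSV with columns `feature,class,mean,sd` plus `.size`
#' rows carrying the group sizes in the `mean` column.
#'
#' @param name `"SSR1"`, `"LUNGx"`, or a file path.
#' @return A `cohort_calibration`.
#' @export
load_calibration <- function(name) {
  path <- if (toupper(name) %in% c("SSR1", "LUNGX")) {
    system.file("extdata",
                sprintf("calibration_%s.csv", tolower(name)),
                package = "lesionshape", mustWork = TRUE)
  } else name
  if (!file.exists(path)) stop("calibration file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  sizes <- raw[raw$feature == ".size", ]
  moments <- raw[raw$feature != ".size", ]
  if (nrow(sizes) != 2L)
    stop("calibration file must contain one .size row per class")
  dataset <- if (toupper(name) %in% c("SSR1", "LUNGX")) toupper(name)
    else tools::file_path_sans_ext(basename(path))
  cohort_calibration(moments,
                     n_benign = sizes$mean[sizes$class == "benign"],
                     n_malignant = sizes$mean[sizes$class == "malignant"],
                     dataset = dataset)
}

#' Published univariate screening results shipped for re-analysis
#'
#' Returns the printed per-feature two-group p-values and significance
#' flags of the named dataset, as published (p-values below the printing
#' precision appear as `"<0.001"`). Used to check the Benjamini-Hochberg
#' stage against the published flag pattern.
#'
#' @param name `"SSR1"` or `"LUNGx"`.
#' @return A tibble with columns `feature`, `p_printed` (character),
#'   `significant_printed` (logical).
#' @export
load_univariate_reference <- function(name = c("SSR1", "LUNGx")) {
  name <- match.arg(name)
  path <- system.file("extdata",
                      sprintf("univariate_reference_%s.csv", tolower(name)),
                      package = "lesionshape", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::tibble(feature = raw$feature,
                 p_printed = as.character(raw$p_value),
                 significant_printed = raw$significant == "yes")
}

#' Simulate a two-group feature cohort from a calibration
#'
#' Samples every feature independently within class from its
#' moment-matched distribution (beta for dimensionless features,
#' lognormal for size features). Marginal moments converge to the
#' calibration targets; cross-feature identities (such as the Angelidakis
#' sum-to-one) are *not* enforced, since the published calibration gives
#' marginal moments only — use [simulate_geometric_cohort()] when
#' internally consistent lesions are required.
#'
#' @param calibration A `cohort_calibration`.
#' @param seed Integer seed; the simulation is deterministic given
#'   `(calibration, seed)`.
#' @return A cohort tibble with columns `lesion_id`, `dataset`, `label`,
#'   and one column per calibrated feature.
#' @export
simulate_cohort <- function(calibration, seed = 1L) {
  stopifnot(inherits(calibration, "cohort_calibration"))
  mom <- calibration$moments
  feats <- unique(mom$feature)
  n <- c(benign = calibration$n_benign, malignant = calibration$n_malignant)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  cols <- lapply(feats, function(f) {
    unlist(lapply(c("benign", "malignant"), function(cl) {
      row <- mom[mom$feature == f & mom$class == cl, ]
      if (nrow(row) != 1L)
        stop("calibration needs exactly one (", f, ", ", cl, ") row")
      if (f %in% SIZE_FEATURES) {
        p <- moment_matched_lognormal(row$mean, row$sd)
        rlnorm(n[[cl]], p$meanlog, p$sdlog)
      } else {
        p <- moment_matched_beta(row$mean, row$sd)
        rbeta(n[[cl]], p$shape1, p$shape2)
      }
    }))
  })
  names(cols) <- feats
  out <- tibble::as_tibble(cols)
  tibble::add_column(
    out,
    lesion_id = sprintf("%s_%03d", tolower(calibration$dataset),
                        seq_len(sum(n))),
    dataset = calibration$dataset,
    label = rep(c("benign", "malignant"), times = n),
    .before = 1)
}

# save/restore the global RNG state so simulation seeds stay local
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate an internally consistent cohort of ellipsoid lesions
#'
#' Draws per-lesion box dimensions (l, b, t), voxelizes the matching
#' axis-aligned ellipsoid phantom, and extracts all eleven features, so
#' every cross-feature identity holds per lesion. The default parameters
#' encode the study finding the pipeline is meant to detect: benign
#' lesions are on average flatter (lower thickness-to-breadth ratio),
#' malignant lesions more equant, while the size distribution is
#' identical in the two arms (so size features carry no class signal and
#' the form factors do).
#'
#' Length `l` is lognormal; the ratios `b/l` and `t/b` are affine-mapped
#' beta draws confined to `ratio_range`, keeping every lesion at least a
#' few voxels thick at the default 1 mm spacing.
#'
#' @param n_benign,n_malignant Lesions per arm.
#' @param spacing Voxel spacing in mm.
#' @param seed Integer seed.
#' @param length_mean,length_sd Moments of the lognormal length draw (mm).
#' @param bl_shape Beta shape pair for `b/l` (both arms).
#' @param tb_shape_benign,tb_shape_malignant Beta shape pairs for `t/b`;
#'   the defaults make benign lesions flatter.
#' @param ratio_range Affine range the ratio draws are mapped into.
#' @param dataset Dataset identifier.
#' @return A list with `masks` (list of [voxel_mask]) and `cohort` (a
#'   cohort tibble).
#' @export
simulate_geometric_cohort <- function(n_benign = 15L, n_malignant = 15L,
                                      spacing = c(1, 1, 1), seed = 1L,
                                      length_mean = 24, length_sd = 5,
                                      bl_shape = c(6, 2),
                                      tb_shape_benign = c(2, 6),
                                      tb_shape_malignant = c(6, 2),
                                      ratio_range = c(0.2, 0.95),
                                      dataset = "geometric") {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- c(benign = n_benign, malignant = n_malignant)
  lab <- rep(c("benign", "malignant"), times = n)
  lp <- moment_matched_lognormal(length_mean, length_sd)
  l <- rlnorm(sum(n), lp$meanlog, lp$sdlog)
  map <- function(u) ratio_range[1] + diff(ratio_range) * u
  bl <- map(rbeta(sum(n), bl_shape[1], bl_shape[2]))
  tb <- numeric(sum(n))
  tb[lab == "benign"] <- map(rbeta(n_benign, tb_shape_benign[1],
                                   tb_shape_benign[2]))
  tb[lab == "malignant"] <- map(rbeta(n_malignant, tb_shape_malignant[1],
                                      tb_shape_malignant[2]))
  b <- l * bl
  t <- b * tb
  masks <- lapply(seq_len(sum(n)), function(i) {
    make_phantom(phantom_spec("ellipsoid",
                              semi_axes = c(l[i], b[i], t[i]) / 2,
                              spacing = spacing))
  })
  cohort <- extract_features(masks,
                             lesion_ids = sprintf("%s_%03d", dataset,
                                                  seq_len(sum(n))))
  cohort <- tibble::add_column(cohort, dataset = dataset, label = lab,
                               .after = "lesion_id")
  list(masks = masks, cohort = cohort)
}
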