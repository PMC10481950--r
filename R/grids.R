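#' @useDynLib organmotion, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd quantile ks.test var setNames median dist
#' @importFrom utils write.csv modifyList tail packageVersion
#' @importFrom tools md5sum
NULL

#' Grid specification
#'
#' Defines the voxel lattice shared by images, label maps and vector fields:
#' integer shape (voxels), physical spacing (mm per voxel) and physical
#' origin (mm). Voxel indices are 0-based; the physical position of voxel
#' (i, j, k) is `origin + c(i, j, k) * spacing` (voxel-centre convention).
#'
#' @param shape integer triple (nx, ny, nz), all >= 1.
#' @param spacing positive triple, mm per voxel. Default 2 mm isotropic.
#' @param origin numeric triple, mm. Default 0.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 1L))
    stop("grid_spec: 'shape' must be three integers >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid_spec: 'spacing' must be three positive numbers (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("grid_spec: 'origin' must be three finite numbers (mm)")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec %dx%dx%d @ %g/%g/%g mm, origin (%g, %g, %g) mm>\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(sprintf("grid mismatch: %s must share one grid (got %s vs %s voxels)",
                 what, paste(a$shape, collapse = "x"),
                 paste(b$shape, collapse = "x")))
  invisible(TRUE)
}

#' Scalar image volume
#'
#' A 3D intensity grid. Intensities are dimensionless; after normalisation
#' they lie in \[0, 1\].
#'
#' @param values 3D numeric array matching `grid$shape`.
#' @param grid a [grid_spec()].
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("image_volume: values dimensions do not match the grid shape")
  if (any(!is.finite(values)))
    stop("image_volume: all intensity values must be finite")
  structure(list(grid = grid, values = values), class = "image_volume")
}

#' Integer organ label volume
#'
#' One integer label per voxel in `{0, ..., K}`; 0 is background and labels
#' `1..K` correspond (in order) to `organ_names`. Exactly one label per
#' voxel, i.e. organs do not overlap.
#'
#' @param labels 3D integer array matching `grid$shape`.
#' @param grid a [grid_spec()].
#' @param organ_names character vector of K organ names.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, grid,
                         organ_names = c("prostate", "vesicles",
                                         "bladder", "rectum")) {
  stopifnot(inherits(grid, "grid_spec"))
  labels <- array(as.integer(labels), dim = dim(as.array(labels)))
  if (!identical(as.integer(dim(labels)), grid$shape))
    stop("label_volume: label dimensions do not match the grid shape")
  K <- length(organ_names)
  if (any(labels < 0L) || any(labels > K))
    stop(sprintf("label_volume: labels must lie in [0, %d]", K))
  structure(list(grid = grid, labels = labels, organ_names = organ_names),
            class = "label_volume")
}

#' 3D vector field (stationary velocity or displacement)
#'
#' One 3-vector per voxel, stored in voxel units. `kind` is immutable
#' metadata preventing accidental mixing of velocities and displacements.
#'
#' @param vectors 4D array `(nx, ny, nz, 3)`, voxel units.
#' @param grid a [grid_spec()].
#' @param kind `"velocity"` or `"displacement"`.
#' @return An object of class `vector_field`.
#' @export
vector_field <- function(vectors, grid, kind = c("velocity", "displacement")) {
  stopifnot(inherits(grid, "grid_spec"))
  kind <- match.arg(kind)
  vectors <- as.array(vectors)
  if (length(dim(vectors)) != 4L ||
      !identical(as.integer(dim(vectors)[1:3]), grid$shape) ||
      dim(vectors)[4] != 3L)
    stop("vector_field: vectors must have dim (nx, ny, nz, 3) matching the grid")
  if (any(!is.finite(vectors)))
    stop("vector_field: all components must be finite")
  structure(list(grid = grid, vectors = vectors, kind = kind),
            class = "vector_field")
}

voxel_volume_cm3 <- function(grid) prod(grid$spacing) / 1000

#' Binary mask of one organ
#'
#' @param s a [label_volume()].
#' @param organ one of `s$organ_names`.
#' @return 3D logical array, TRUE where the voxel carries that organ's label.
#' @export
organ_mask <- function(s, organ) {
  stopifnot(inherits(s, "label_volume"))
  id <- match(organ, s$organ_names)
  if (is.na(id))
    stop(sprintf("unknown organ '%s'; valid organs: %s", organ,
                 paste(s$organ_names, collapse = ", ")))
  s$labels == id
}

#' Organ volume in cubic centimetres
#'
#' Counts TRUE voxels and multiplies by the voxel volume (product of the
#' grid spacings).
#'
#' @param mask 3D logical array.
#' @param grid the [grid_spec()] the mask lives on.
#' @return volume in cm^3.
#' @export
organ_volume <- function(mask, grid) {
  if (!identical(as.integer(dim(mask)), grid$shape))
    stop("organ_volume: mask and grid shapes disagree")
  sum(mask) * voxel_volume_cm3(grid)
}

#' Centre of mass of a binary mask, in physical coordinates
#'
#' Unweighted mean of the voxel-centre physical positions over TRUE voxels.
#'
#' @param mask 3D logical array (must be non-empty).
#' @param grid the [grid_spec()] the mask lives on.
#' @return 3-vector, mm.
#' @export
center_of_mass <- function(mask, grid) {
  if (!identical(as.integer(dim(mask)), grid$shape))
    stop("center_of_mass: mask and grid shapes disagree")
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("center_of_mass: empty mask, centre of mass undefined")
  # arr.ind is 1-based; physical position uses 0-based indices
  grid$origin + colMeans(idx - 1) * grid$spacing
}

#' Volume change and centre-of-mass shift for one organ
#'
#' Compares a planning and a repeat label volume on the same grid.
#' The scalar shift is the mean of the absolute coordinate components of
#' the shift vector.
#'
#' @param s_plan,s_rep planning and repeat [label_volume()] on one grid.
#' @param organ organ name, present in both volumes.
#' @return list of class `deformation_stats` with fields `organ`,
#'   `volume_change_cm3`, `volume_change_pct`, `com_shift_vector_mm`,
#'   `com_shift_scalar_mm`.
#' @export
deformation_stats <- function(s_plan, s_rep, organ) {
  stopifnot(inherits(s_plan, "label_volume"), inherits(s_rep, "label_volume"))
  stop_if_grid_mismatch(s_plan$grid, s_rep$grid, "label volumes")
  m1 <- organ_mask(s_plan, organ)
  m2 <- organ_mask(s_rep, organ)
  if (!any(m1) || !any(m2))
    stop(sprintf("deformation_stats: organ '%s' absent from %s volume", organ,
                 if (!any(m1)) "the planning" else "the repeat"))
  v1 <- organ_volume(m1, s_plan$grid)
  v2 <- organ_volume(m2, s_rep$grid)
  shift <- center_of_mass(m2, s_rep$grid) - center_of_mass(m1, s_plan$grid)
  structure(list(organ = organ,
                 volume_change_cm3 = v2 - v1,
                 volume_change_pct = 100 * (v2 - v1) / v1,
                 com_shift_vector_mm = shift,
                 com_shift_scalar_mm = mean(abs(shift))),
            class = "deformation_stats")
}

#' @export
print.deformation_stats <- function(x, ...) {
  cat(sprintf("<%s: dV = %+.2f cm3 (%+.1f%%), COM shift (%.2f, %.2f, %.2f) mm, scalar %.2f mm>\n",
              x$organ, x$volume_change_cm3, x$volume_change_pct,
              x$com_shift_vector_mm[1], x$com_shift_vector_mm[2],
              x$com_shift_vector_mm[3], x$com_shift_scalar_mm))
  invisible(x)
}

# one-hot encoding of a label volume: (nx,ny,nz,K+1) with channel 1 =
# background; used by label warping and as network input (background
# channel dropped there).
label_onehot <- function(s) {
  K <- length(s$organ_names)
  sh <- s$grid$shape
  oh <- array(0, dim = c(sh, K + 1L))
  for (k in 0:K) oh[, , , k + 1L] <- as.numeric(s$labels == k)
  oh
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
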