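# NIfTI I/O for volumes and vector fields, JSON manifests, and the
# population directory layout used by the command line interface. The
# NIfTI dialect is restricted to axis-aligned geometries (diagonal
# positive affine); oblique files are rejected with a clear message.

axis_aligned_xform <- function(img, path) {
  m <- RNifti::xform(img)
  rot <- m[1:3, 1:3]
  offd <- rot - diag(diag(rot))
  if (max(abs(offd)) > 1e-4 || any(diag(rot) <= 0))
    stop(sprintf(paste0("'%s' has an oblique or flipped affine; only ",
                        "axis-aligned positive-spacing NIfTI volumes are ",
                        "supported - resample the volume first"), path))
  list(spacing = unname(diag(rot)), origin = unname(m[1:3, 4]))
}

nifti_grid <- function(img, path) {
  xf <- axis_aligned_xform(img, path)
  grid_spec(dim(img)[1:3], spacing = xf$spacing, origin = xf$origin)
}

#' Read a NIfTI volume as an image or label volume
#'
#' @param path NIfTI file (.nii or .nii.gz) with a 3D payload and an
#'   axis-aligned affine.
#' @param type `"image"`, `"label"`, or `"auto"` (labels are detected as
#'   whole-valued volumes with few distinct values).
#' @param normalize min-max rescale intensities to \[0, 1\] on read
#'   (images only).
#' @param organ_names organ names for label volumes (labels must lie in
#'   `0..K`).
#' @return an [image_volume()] or [label_volume()].
#' @export
read_volume <- function(path, type = c("auto", "image", "label"),
                        normalize = FALSE,
                        organ_names = c("prostate", "vesicles", "bladder",
                                        "rectum")) {
  type <- match.arg(type)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop(sprintf("'%s': expected a 3D payload, got %dD; volumes must be single 3D scalar grids",
                 path, length(dim(img))))
  arr <- array(as.vector(img), dim = dim(img))
  grid <- nifti_grid(img, path)
  if (type == "auto") {
    whole <- all(arr == round(arr))
    type <- if (whole && length(unique(as.vector(arr))) <= 32L) "label"
      else "image"
  }
  if (type == "label") {
    K <- length(organ_names)
    if (any(arr != round(arr)))
      stop(sprintf("'%s': label volumes must be integer-valued", path))
    if (any(arr < 0) || any(arr > K))
      stop(sprintf("'%s': labels must lie in [0, %d] for %d organs (found %g..%g)",
                   path, K, K, min(arr), max(arr)))
    return(label_volume(array(as.integer(arr), dim(arr)), grid, organ_names))
  }
  if (normalize) {
    rng <- range(arr)
    arr <- if (diff(rng) > 0) (arr - rng[1]) / diff(rng) else arr * 0
  }
  image_volume(arr, grid)
}

write_nifti_atomic <- function(img, path) {
  tmp <- file.path(dirname(path), paste0(".tmp.", basename(path)))
  RNifti::writeNifti(img, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write an image or label volume as NIfTI
#'
#' Spacing and origin go into the pixdim and (diagonal) sform; label
#' volumes are stored as uint8, intensities as float32. Writes are atomic
#' (temp file + rename).
#'
#' @param obj an [image_volume()] or [label_volume()].
#' @param path destination path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
write_volume <- function(obj, path) {
  if (inherits(obj, "image_volume")) {
    arr <- obj$values
    dtype <- "float"
  } else if (inherits(obj, "label_volume")) {
    arr <- obj$labels
    dtype <- "uint8"
  } else stop("write_volume: obj must be an image_volume or label_volume")
  img <- RNifti::asNifti(structure(arr, pixdim = obj$grid$spacing),
                         datatype = dtype, internal = FALSE)
  m <- diag(c(obj$grid$spacing, 1))
  m[1:3, 4] <- obj$grid$origin
  RNifti::sform(img) <- structure(m, code = 2L)
  write_nifti_atomic(img, path)
}

field_sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".json")
}

#' Read / write a 3-channel displacement or velocity field
#'
#' Fields are 4D NIfTI volumes `(nx, ny, nz, 3)`; the kind (velocity or
#' displacement) and units are recorded in a JSON sidecar next to the
#' file. Components are stored in voxel units by default; with
#' `units = "mm"` they are scaled by the spacing on write and scaled back
#' on read.
#'
#' @param path NIfTI file path.
#' @param field a [vector_field()] (write).
#' @param units `"voxels"` (default) or `"mm"`.
#' @return `read_field` returns a [vector_field()].
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L || dim(img)[4] != 3L)
    stop(sprintf("'%s': a vector field needs a 4D payload with 3 channels (got %s)",
                 path, paste(dim(img), collapse = "x")))
  arr <- array(as.vector(img), dim = dim(img))
  grid <- nifti_grid(img, path)
  side <- field_sidecar_path(path)
  meta <- if (file.exists(side)) jsonlite::read_json(side)
    else list(kind = "displacement", units = "voxels")
  if (identical(meta$units, "mm"))
    for (a in 1:3) arr[, , , a] <- arr[, , , a] / grid$spacing[a]
  vector_field(arr, grid, kind = meta$kind)
}

#' @rdname read_field
#' @export
write_field <- function(field, path, units = c("voxels", "mm")) {
  stopifnot(inherits(field, "vector_field"))
  units <- match.arg(units)
  arr <- field$vectors
  if (units == "mm")
    for (a in 1:3) arr[, , , a] <- arr[, , , a] * field$grid$spacing[a]
  img <- RNifti::asNifti(structure(arr, pixdim = field$grid$spacing),
                         datatype = "double", internal = FALSE)
  m <- diag(c(field$grid$spacing, 1))
  m[1:3, 4] <- field$grid$origin
  RNifti::sform(img) <- structure(m, code = 2L)
  write_nifti_atomic(img, path)
  write_json_atomic(list(kind = field$kind, units = units,
                         format = "organmotion-field-1"),
                    field_sidecar_path(path))
  invisible(path)
}

write_json_atomic <- function(obj, path) {
  tmp <- file.path(dirname(path), paste0(".tmp.", basename(path)))
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

write_csv_atomic <- function(df, path) {
  tmp <- file.path(dirname(path), paste0(".tmp.", basename(path)))
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a population to a directory (NIfTI volumes + JSON manifest)
#'
#' Layout: `manifest.json` plus one sub-directory per patient holding the
#' planning pair, every repeat pair, and the ground-truth velocity field
#' of each repeat (forward/pull displacements are recomputed on load by
#' exponentiation, which is deterministic).
#'
#' @param pop a `synthetic_population` from [generate_population()].
#' @param dir destination directory.
#' @return the directory, invisibly.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (case in pop$cases) {
    pd <- file.path(dir, case$patient_id)
    dir.create(pd, showWarnings = FALSE)
    write_volume(case$planning$image, file.path(pd, "planning_image.nii.gz"))
    write_volume(case$planning$labels, file.path(pd, "planning_labels.nii.gz"))
    for (r in seq_along(case$repeats)) {
      write_volume(case$repeats[[r]]$image,
                   file.path(pd, sprintf("rep_%02d_image.nii.gz", r)))
      write_volume(case$repeats[[r]]$labels,
                   file.path(pd, sprintf("rep_%02d_labels.nii.gz", r)))
      write_field(case$truth[[r]]$velocity,
                  file.path(pd, sprintf("truth_%02d_velocity.nii.gz", r)))
    }
  }
  manifest <- pop$manifest
  manifest$layout <- "organmotion-population-1"
  write_json_atomic(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Load a population directory written by [write_population()]
#'
#' @param dir population directory containing `manifest.json`.
#' @param dcfg a [diffeo_config()] used to re-exponentiate the stored
#'   truth velocities.
#' @return a `synthetic_population` (without the per-patient law objects,
#'   which live only in the manifest).
#' @export
load_population <- function(dir, dcfg = diffeo_config()) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  cases <- vector("list", mf$n_patients)
  for (i in seq_len(mf$n_patients)) {
    pinfo <- if (is.data.frame(mf$patients)) as.list(mf$patients[i, ])
      else mf$patients[[i]]
    id <- pinfo$id
    pd <- file.path(dir, id)
    planning <- list(
      image = read_volume(file.path(pd, "planning_image.nii.gz"), "image"),
      labels = read_volume(file.path(pd, "planning_labels.nii.gz"), "label"))
    reps <- list()
    truths <- list()
    r <- 1L
    while (file.exists(file.path(pd, sprintf("rep_%02d_image.nii.gz", r)))) {
      reps[[r]] <- list(
        image = read_volume(file.path(pd, sprintf("rep_%02d_image.nii.gz", r)), "image"),
        labels = read_volume(file.path(pd, sprintf("rep_%02d_labels.nii.gz", r)), "label"))
      v <- read_field(file.path(pd, sprintf("truth_%02d_velocity.nii.gz", r)))
      truths[[r]] <- list(velocity = v,
                          displacement_fwd = exponentiate(v, dcfg),
                          displacement_pull = invert_velocity(v, dcfg))
      r <- r + 1L
    }
    cases[[i]] <- structure(
      list(patient_id = id, planning = planning, repeats = reps,
           truth = truths, split = pinfo$split),
      class = "patient_case")
  }
  structure(list(cases = cases, manifest = mf),
            class = "synthetic_population")
}
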