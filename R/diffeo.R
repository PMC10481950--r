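#' Diffeomorphism configuration
#'
#' Controls the scaling-and-squaring exponentiation of stationary velocity
#' fields and how images/labels are interpolated when warped.
#'
#' @param squaring_steps integer S >= 1: the velocity is scaled by 2^-S and
#'   the resulting small displacement is self-composed S times. Default 7
#'   (scale by 1/128). A warning is issued outside \[4, 10\].
#' @param interpolation_boundary boundary handling for interpolation; only
#'   `"clamp"` (clamp-to-edge) is provided.
#' @param label_warp_mode label warping strategy; only
#'   `"onehot_linear_argmax"` (one-hot channels, trilinear interpolation,
#'   argmax for the hard map) is provided.
#' @return An object of class `diffeo_config`.
#' @export
diffeo_config <- function(squaring_steps = 7L,
                          interpolation_boundary = "clamp",
                          label_warp_mode = "onehot_linear_argmax") {
  squaring_steps <- as.integer(squaring_steps)
  if (!is.finite(squaring_steps) || squaring_steps < 1L)
    stop("diffeo_config: squaring_steps must be an integer >= 1")
  if (squaring_steps < 4L || squaring_steps > 10L)
    warning(sprintf("squaring_steps = %d is outside the validated range [4, 10]",
                    squaring_steps))
  interpolation_boundary <- match.arg(interpolation_boundary, "clamp")
  label_warp_mode <- match.arg(label_warp_mode, "onehot_linear_argmax")
  structure(list(squaring_steps = squaring_steps,
                 interpolation_boundary = interpolation_boundary,
                 label_warp_mode = label_warp_mode),
            class = "diffeo_config")
}

# raw-array trilinear sample: src (nx,ny,nz,C), disp (nx,ny,nz,3), voxels
sample_at <- function(src, disp) {
  cpp_trilerp_fwd(src, as.integer(dim(src)), disp)
}

# scaling and squaring on a raw 4D velocity array; returns the displacement
# and (optionally) the intermediate fields needed for reverse mode
exp_fwd <- function(v, steps, cache = FALSE) {
  u <- v / 2^steps
  us <- if (cache) vector("list", steps) else NULL
  for (s in seq_len(steps)) {
    if (cache) us[[s]] <- u
    u <- u + sample_at(u, u)
  }
  if (cache) list(u = u, us = us, steps = steps) else u
}

exp_bwd <- function(cache, du) {
  for (s in rev(seq_len(cache$steps))) {
    u <- cache$us[[s]]
    g <- cpp_trilerp_bwd(u, as.integer(dim(u)), u, du)
    du <- du + g$dsrc + g$ddisp
  }
  du / 2^cache$steps
}

#' Exponentiate a stationary velocity field
#'
#' Computes the diffeomorphic displacement `u` with map `p -> p + u(p)` as
#' `exp(v)` by scaling and squaring: `v` is scaled by `2^-S` and the
#' resulting displacement self-composed S times, each composition evaluated
#' with trilinear interpolation and clamped boundaries.
#'
#' @param v a [vector_field()] of kind `"velocity"`.
#' @param cfg a [diffeo_config()].
#' @return a [vector_field()] of kind `"displacement"`.
#' @export
exponentiate <- function(v, cfg = diffeo_config()) {
  stopifnot(inherits(v, "vector_field"))
  if (v$kind != "velocity")
    stop("exponentiate: input must be a velocity field (got kind = '",
         v$kind, "')")
  u <- exp_fwd(v$vectors, cfg$squaring_steps)
  vector_field(u, v$grid, kind = "displacement")
}

#' Inverse transformation of a velocity field
#'
#' Returns `exp(-v)`; composing with `exp(v)` recovers the identity up to
#' interpolation error.
#'
#' @inheritParams exponentiate
#' @return a displacement [vector_field()].
#' @export
invert_velocity <- function(v, cfg = diffeo_config()) {
  stopifnot(inherits(v, "vector_field"))
  if (v$kind != "velocity")
    stop("invert_velocity: input must be a velocity field")
  exponentiate(vector_field(-v$vectors, v$grid, "velocity"), cfg)
}

#' Compose two displacement fields
#'
#' Returns the displacement `u` of the composed map `phi1 o phi2`, i.e.
#' `u(p) = u2(p) + u1(p + u2(p))` with trilinear sampling of `u1`.
#'
#' @param u1,u2 displacement [vector_field()]s on one grid.
#' @return a displacement [vector_field()].
#' @export
compose_displacements <- function(u1, u2) {
  stopifnot(inherits(u1, "vector_field"), inherits(u2, "vector_field"))
  if (u1$kind != "displacement" || u2$kind != "displacement")
    stop("compose_displacements: both inputs must be displacement fields")
  stop_if_grid_mismatch(u1$grid, u2$grid, "displacement fields")
  vector_field(u2$vectors + sample_at(u1$vectors, u2$vectors),
               u1$grid, "displacement")
}

#' Warp an image with a displacement field
#'
#' The output voxel at position `p` is the trilinear sample of the input at
#' `p + u(p)`; samples outside the grid use clamp-to-edge boundaries.
#'
#' @param x an [image_volume()].
#' @param u a displacement [vector_field()] on the same grid.
#' @return the warped [image_volume()].
#' @export
warp_image <- function(x, u) {
  stopifnot(inherits(x, "image_volume"), inherits(u, "vector_field"))
  if (u$kind != "displacement")
    stop("warp_image: u must be a displacement field")
  stop_if_grid_mismatch(x$grid, u$grid, "image and field")
  src <- array(x$values, dim = c(x$grid$shape, 1L))
  out <- sample_at(src, u$vectors)
  image_volume(array(out, dim = x$grid$shape), x$grid)
}

#' Warp a label volume with a displacement field
#'
#' Each class (including background) is warped as a one-hot channel with
#' trilinear interpolation; the hard output is the per-voxel argmax and the
#' soft channels are retained for differentiable DICE losses.
#'
#' @param s a [label_volume()].
#' @param u a displacement [vector_field()] on the same grid.
#' @param return_soft also return the soft one-hot channels.
#' @return the warped [label_volume()]; if `return_soft`, a list with
#'   elements `labels` (hard) and `soft` (array `(nx,ny,nz,K+1)`, channel 1
#'   = background).
#' @export
warp_labels <- function(s, u, return_soft = FALSE) {
  stopifnot(inherits(s, "label_volume"), inherits(u, "vector_field"))
  if (u$kind != "displacement")
    stop("warp_labels: u must be a displacement field")
  stop_if_grid_mismatch(s$grid, u$grid, "labels and field")
  soft <- sample_at(label_onehot(s), u$vectors)
  hard <- max.col(matrix(soft, ncol = dim(soft)[4]), ties.method = "first") - 1L
  out <- label_volume(array(hard, dim = s$grid$shape), s$grid, s$organ_names)
  if (return_soft) list(labels = out, soft = soft) else out
}

# central difference along axis 'a' of a 3D array, one-sided at the edges
central_diff <- function(f, a) {
  n <- dim(f)[a]
  d <- array(0, dim = dim(f))
  if (n == 1L) return(d)
  if (a == 1L) {
    if (n > 2L) d[2:(n - 1), , ] <- (f[3:n, , ] - f[1:(n - 2), , ]) / 2
    d[1, , ] <- f[2, , ] - f[1, , ]
    d[n, , ] <- f[n, , ] - f[n - 1, , ]
  } else if (a == 2L) {
    if (n > 2L) d[, 2:(n - 1), ] <- (f[, 3:n, ] - f[, 1:(n - 2), ]) / 2
    d[, 1, ] <- f[, 2, ] - f[, 1, ]
    d[, n, ] <- f[, n, ] - f[, n - 1, ]
  } else {
    if (n > 2L) d[, , 2:(n - 1)] <- (f[, , 3:n] - f[, , 1:(n - 2)]) / 2
    d[, , 1] <- f[, , 2] - f[, , 1]
    d[, , n] <- f[, , n] - f[, , n - 1]
  }
  d
}

#' Jacobian determinant map of a deformation
#'
#' Determinant of the spatial Jacobian of the map `phi(p) = p + u(p)`,
#' evaluated with central differences (one-sided at the grid boundary), in
#' voxel units. Identity gives 1 everywhere; values <= 0 indicate local
#' folding.
#'
#' @param u a displacement [vector_field()].
#' @return 3D numeric array of determinants.
#' @export
jacobian_determinant <- function(u) {
  stopifnot(inherits(u, "vector_field"))
  if (u$kind != "displacement")
    stop("jacobian_determinant: u must be a displacement field")
  J <- vector("list", 9)
  for (comp in 1:3) {
    f <- u$vectors[, , , comp]
    for (ax in 1:3) {
      g <- central_diff(f, ax)
      if (ax == comp) g <- g + 1
      J[[(comp - 1) * 3 + ax]] <- g
    }
  }
  # rows = components of phi, columns = derivative axes
  a11 <- J[[1]]; a12 <- J[[2]]; a13 <- J[[3]]
  a21 <- J[[4]]; a22 <- J[[5]]; a23 <- J[[6]]
  a31 <- J[[7]]; a32 <- J[[8]]; a33 <- J[[9]]
  a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
}

#' Fraction of folded voxels
#'
#' Fraction of voxels whose Jacobian determinant is <= 0, i.e. where the
#' deformation locally reverses orientation (physically impossible
#' anatomy). Diffeomorphic fields give exactly 0.
#'
#' @param u a displacement [vector_field()].
#' @param exclude_boundary drop the one-voxel boundary shell (where the
#'   one-sided differences live) from the statistic. Default FALSE.
#' @return fraction in \[0, 1\].
#' @export
folding_fraction <- function(u, exclude_boundary = FALSE) {
  det <- jacobian_determinant(u)
  if (exclude_boundary) {
    sh <- dim(det)
    if (all(sh > 2L))
      det <- det[2:(sh[1] - 1), 2:(sh[2] - 1), 2:(sh[3] - 1)]
  }
  mean(det <= 0)
}
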