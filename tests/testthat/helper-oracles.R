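# Independent numerical oracles used by the tests. These deliberately do
# not call the package's interpolation or exponentiation code paths.

# trilinear interpolation of a (nx,ny,nz,3) field at continuous 0-based
# positions (n x 3 matrix), clamp-to-edge; plain R, vectorised
oracle_trilerp <- function(field, pos) {
  sh <- dim(field)[1:3]
  M <- prod(sh)
  p <- pos
  for (a in 1:3) p[, a] <- pmin(pmax(p[, a], 0), sh[a] - 1)
  i0 <- pmax(pmin(floor(p), matrix(rep(sh - 2, each = nrow(p)), ncol = 3)), 0)
  f <- p - i0
  out <- matrix(0, nrow(p), 3)
  fv <- matrix(field, M, 3)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
      (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
      (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
    lin <- (i0[, 1] + dx) + sh[1] * ((i0[, 2] + dy) + sh[2] * (i0[, 3] + dz)) + 1
    out <- out + w * fv[lin, , drop = FALSE]
  }
  out
}

# classical 4th-order Runge-Kutta integration of the stationary-velocity
# flow d(phi)/dt = v(phi) from t = 0 to 1, starting at every voxel centre;
# returns the displacement as an (nx,ny,nz,3) array
oracle_rk4_flow <- function(v4, steps = 128L) {
  sh <- dim(v4)[1:3]
  idx <- as.matrix(expand.grid(x = 0:(sh[1] - 1), y = 0:(sh[2] - 1),
                               z = 0:(sh[3] - 1)))
  pos <- idx * 1.0
  h <- 1 / steps
  for (s in seq_len(steps)) {
    k1 <- oracle_trilerp(v4, pos)
    k2 <- oracle_trilerp(v4, pos + h / 2 * k1)
    k3 <- oracle_trilerp(v4, pos + h / 2 * k2)
    k4 <- oracle_trilerp(v4, pos + h * k3)
    pos <- pos + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  array(pos - idx, dim = c(sh, 3))
}

# Gaussian-smoothed random velocity field scaled to a given max norm;
# separable convolution with a truncated Gaussian kernel (reflecting pad).
# The default smoothness (sd 8 voxels) keeps trilinear scaling-and-
# squaring within < 1e-2 voxels of an exact flow integrator with margin
# (worst case ~8e-3 over repeated draws); at sd 4 the composition is
# interpolation-limited to ~2e-2.
smooth_random_velocity <- function(shape, vmax = 2, smooth_sd = 8,
                                   seed = 1L) {
  set.seed(seed)
  r <- ceiling(3 * smooth_sd)
  k <- exp(-(-r:r)^2 / (2 * smooth_sd^2))
  k <- k / sum(k)
  conv_axis <- function(a, ax) {
    n <- dim(a)[ax]
    idx <- outer(seq_len(n), -r:r, `+`)
    idx <- abs(idx - 1) %% (2 * n - 2) + 1
    idx[idx > n] <- 2 * n - idx[idx > n]
    out <- array(0, dim(a))
    for (t in seq_along(k)) {
      sl <- idx[, t]
      if (ax == 1) out <- out + k[t] * a[sl, , , drop = FALSE]
      else if (ax == 2) out <- out + k[t] * a[, sl, , drop = FALSE]
      else out <- out + k[t] * a[, , sl, drop = FALSE]
    }
    out
  }
  v <- array(0, dim = c(shape, 3))
  for (c in 1:3) {
    a <- array(rnorm(prod(shape)), shape)
    for (ax in 1:3) a <- conv_axis(a, ax)
    v[, , , c] <- a
  }
  v * (vmax / max(abs(v)))
}

interior_mask <- function(shape, margin = 3L) {
  m <- array(FALSE, dim = shape)
  m[(margin + 1):(shape[1] - margin), (margin + 1):(shape[2] - margin),
    (margin + 1):(shape[3] - margin)] <- TRUE
  m
}

test_grid <- function(shape = c(16L, 16L, 16L), spacing = c(2, 2, 2)) {
  grid_spec(shape, spacing = spacing)
}

# small two-organ label volume on an 8^3 grid, for network-level tests
tiny_labels <- function(grid) {
  a <- array(0L, grid$shape)
  a[3:5, 3:5, 3:5] <- 1L
  a[6:7, 2:3, 4:6] <- 2L
  label_volume(a, grid, organ_names = c("organA", "organB"))
}
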