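#' Loss configuration
#'
#' Hyper-parameters of the training objective. The minimised total is
#' `-lambda * CC - meanDICE + kappa * R + kl_weight * KL`, where CC is the
#' local squared cross-correlation (averaged over voxels), meanDICE the
#' soft multi-organ DICE, R the spatial gradient penalty on the
#' displacement (averaged over voxels) and KL the divergence between
#' posterior and prior. The image and smoothness terms are voxel-averaged
#' rather than summed so that the defaults `lambda = 1000`, `kappa = 0.1`
#' stay meaningful relative to a DICE term of order one, independently of
#' the grid size.
#'
#' @param lambda_cc positive weight of the cross-correlation term (default 1000).
#' @param dice_weight weight of the mean-DICE term (default 1, the printed
#'   objective). Under voxel-averaged normalisation the similarity term
#'   dominates the contour term by three orders of magnitude and saturates
#'   once images align to within the texture correlation length; raising
#'   `dice_weight` until the two terms' displacement gradients are of
#'   comparable size restores the contour alignment pressure.
#' @param kappa positive weight of the spatial gradient penalty (default 0.1).
#' @param cc_window odd window size n of the local n^3 correlation (default 9).
#' @param cc_epsilon small positive stabiliser in the CC denominator.
#' @param kl_weight weight of the KL term (default 1).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(lambda_cc = 1000, dice_weight = 1, kappa = 0.1,
                        cc_window = 9L, cc_epsilon = 1e-5, kl_weight = 1) {
  cc_window <- as.integer(cc_window)
  if (cc_window < 3L || cc_window %% 2L == 0L)
    stop("loss_config: cc_window must be an odd integer >= 3")
  if (lambda_cc < 0 || kappa < 0 || dice_weight < 0)
    stop("loss_config: lambda_cc, dice_weight and kappa must be non-negative")
  if (cc_epsilon <= 0) stop("loss_config: cc_epsilon must be positive")
  structure(list(lambda_cc = lambda_cc, dice_weight = dice_weight,
                 kappa = kappa, cc_window = cc_window,
                 cc_epsilon = cc_epsilon, kl_weight = kl_weight),
            class = "loss_config")
}

# window statistics shared by the CC value and gradient; a and b are 3D
# arrays. Windows are restricted to in-grid voxels (the divisor is the
# actual window count, not n^3), so the grid boundary does not inject
# artificial zero-correlation structure - on small grids the boundary
# shell is a large fraction of the volume.
cc_stats <- function(a, b, n, eps) {
  dim3 <- as.integer(dim(a))
  W <- cpp_boxsum(array(1, dim3), dim3, n)
  Sa <- cpp_boxsum(a, dim3, n)
  Sb <- cpp_boxsum(b, dim3, n)
  Sab <- cpp_boxsum(a * b, dim3, n)
  Saa <- cpp_boxsum(a * a, dim3, n)
  Sbb <- cpp_boxsum(b * b, dim3, n)
  cross <- Sab - Sa * Sb / W
  va <- Saa - Sa * Sa / W
  vb <- Sbb - Sb * Sb / W
  den <- va * vb + eps
  list(Sa = Sa, Sb = Sb, cross = cross, va = va, vb = vb, den = den,
       pervox = cross * cross / den, W = W, dim3 = dim3)
}

#' Local squared cross-correlation between two images
#'
#' For every voxel, the squared correlation coefficient of the two images
#' over the surrounding n^3 window (squared covariance over the product of
#' the window variances, stabilised by epsilon), averaged over all voxels.
#' Windows are clipped to the grid (the divisor is the in-grid window
#' count), so the boundary contributes genuine image statistics rather
#' than padding artefacts. The statistic lies in \[0, 1\], is symmetric,
#' and is invariant to affine rescaling of either image's intensities.
#'
#' @param y_hat,y [image_volume()]s on one grid.
#' @param n odd window size (default 9).
#' @param epsilon denominator stabiliser.
#' @return scalar in \[0, 1\].
#' @export
local_cross_correlation <- function(y_hat, y, n = 9L, epsilon = 1e-5) {
  stopifnot(inherits(y_hat, "image_volume"), inherits(y, "image_volume"))
  stop_if_grid_mismatch(y_hat$grid, y$grid, "images")
  n <- as.integer(n)
  if (n %% 2L == 0L || n < 3L)
    stop("local_cross_correlation: window size n must be odd and >= 3")
  mean(cc_stats(y_hat$values, y$values, n, epsilon)$pervox)
}

# gradient of mean-per-voxel CC w.r.t. the first image (raw arrays)
cc_backward <- function(a, b, n, eps) {
  st <- cc_stats(a, b, n, eps)
  M <- prod(st$dim3)
  alpha <- 2 * st$cross / st$den
  beta <- 2 * st$cross^2 * st$vb / st$den^2
  g <- b * cpp_boxsum(alpha, st$dim3, n) -
    cpp_boxsum(alpha * st$Sb / st$W, st$dim3, n) -
    a * cpp_boxsum(beta, st$dim3, n) +
    cpp_boxsum(beta * st$Sa / st$W, st$dim3, n)
  g / M
}

#' DICE overlap score
#'
#' `2|a n b| / (|a| + |b|)` for binary masks; for soft masks the
#' cardinalities are sums of products / sums of values. Two empty masks
#' score 1 by convention.
#'
#' @param a,b binary or soft (values in \[0,1\]) 3D arrays of one shape.
#' @return scalar in \[0, 1\].
#' @export
dice_score <- function(a, b) {
  a <- as.array(a) * 1.0
  b <- as.array(b) * 1.0
  if (!identical(dim(a), dim(b)))
    stop("dice_score: masks must share one grid/shape")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a * b) / denom
}

#' Mean per-organ DICE of a soft one-hot prediction
#'
#' Unweighted mean of the per-organ DICE between the soft predicted
#' channels and the hard one-hot target, background excluded.
#'
#' @param s_hat_soft array `(nx,ny,nz,K+1)` of soft one-hot channels
#'   (channel 1 = background), e.g. from [warp_labels()].
#' @param s_true target [label_volume()] with K organs.
#' @return scalar in \[0, 1\].
#' @export
mean_organ_dice <- function(s_hat_soft, s_true) {
  stopifnot(inherits(s_true, "label_volume"))
  K <- length(s_true$organ_names)
  if (length(dim(s_hat_soft)) != 4L || dim(s_hat_soft)[4] != K + 1L)
    stop(sprintf("mean_organ_dice: expected %d soft channels (background + %d organs)",
                 K + 1L, K))
  if (!identical(as.integer(dim(s_hat_soft)[1:3]), s_true$grid$shape))
    stop("mean_organ_dice: channel grid does not match the target labels")
  d <- numeric(K)
  for (k in seq_len(K))
    d[k] <- dice_score(s_hat_soft[, , , k + 1L], s_true$labels == k)
  mean(d)
}

# gradient of mean-organ soft DICE w.r.t. the soft channels; target as
# one-hot (K+1 channels); returns array like s_hat_soft (background zero)
mean_organ_dice_backward <- function(s_hat_soft, t_onehot) {
  K <- dim(t_onehot)[4] - 1L
  g <- array(0, dim = dim(s_hat_soft))
  for (k in seq_len(K)) {
    p <- s_hat_soft[, , , k + 1L]
    t <- t_onehot[, , , k + 1L]
    A <- sum(p) + sum(t)
    if (A == 0) next
    S <- sum(p * t)
    g[, , , k + 1L] <- (2 * t / A - 2 * S / A^2) / K
  }
  g
}

#' Spatial gradient penalty of a displacement field
#'
#' Mean over voxels of the Frobenius norm of the 3x3 spatial Jacobian of
#' the displacement (not of the full map, so the identity transform incurs
#' zero penalty), with forward differences and a zero-padded last slice.
#'
#' @param u a displacement [vector_field()] or a raw `(nx,ny,nz,3)` array.
#' @return non-negative scalar (voxel units).
#' @export
gradient_penalty <- function(u) {
  uv <- if (inherits(u, "vector_field")) u$vectors else as.array(u)
  gp_fwd(uv)$value
}

fwd_diff <- function(f, a) {
  n <- dim(f)[a]
  d <- array(0, dim = dim(f))
  if (n == 1L) return(d)
  if (a == 1L) d[1:(n - 1), , ] <- f[2:n, , ] - f[1:(n - 1), , ]
  else if (a == 2L) d[, 1:(n - 1), ] <- f[, 2:n, ] - f[, 1:(n - 1), ]
  else d[, , 1:(n - 1)] <- f[, , 2:n] - f[, , 1:(n - 1)]
  d
}

# adjoint of fwd_diff: given weight w on each difference, scatter +w at
# p+e_a and -w at p (zero where the difference was zero-padded)
fwd_diff_adj <- function(w, a) {
  n <- dim(w)[a]
  d <- array(0, dim = dim(w))
  if (n == 1L) return(d)
  if (a == 1L) {
    d[2:n, , ] <- w[1:(n - 1), , ]
    d[1:(n - 1), , ] <- d[1:(n - 1), , ] - w[1:(n - 1), , ]
  } else if (a == 2L) {
    d[, 2:n, ] <- w[, 1:(n - 1), ]
    d[, 1:(n - 1), ] <- d[, 1:(n - 1), ] - w[, 1:(n - 1), ]
  } else {
    d[, , 2:n] <- w[, , 1:(n - 1)]
    d[, , 1:(n - 1)] <- d[, , 1:(n - 1)] - w[, , 1:(n - 1)]
  }
  d
}

gp_fwd <- function(uv) {
  d <- as.integer(dim(uv))
  r <- cpp_gp_fwd(uv, d)
  list(value = r$value, nrm = r$nrm, u = uv, d = d)
}

gp_bwd <- function(cache) {
  cpp_gp_bwd(cache$u, cache$d, cache$nrm)
}

#' Diagonal Gaussian over latent variables
#'
#' @param mean numeric N-vector.
#' @param variance positive numeric N-vector (the diagonal covariance).
#' @return An object of class `latent_gaussian`.
#' @export
latent_gaussian <- function(mean, variance) {
  mean <- as.numeric(mean)
  variance <- as.numeric(variance)
  if (length(mean) != length(variance) || length(mean) < 1L)
    stop("latent_gaussian: mean and variance must have equal length >= 1")
  if (any(!is.finite(mean)) || any(!is.finite(variance)) || any(variance <= 0))
    stop("latent_gaussian: variances must be positive and all values finite")
  structure(list(mean = mean, variance = variance, N = length(mean)),
            class = "latent_gaussian")
}

#' KL divergence between diagonal Gaussians
#'
#' Closed form `0.5 * sum(log(vp/vq) + (vq + (mq - mp)^2)/vp - 1)`, summed
#' over the latent dimensions. Non-negative, zero iff q = p.
#'
#' @param q,p [latent_gaussian()]s of equal dimension (q is the posterior,
#'   p the prior).
#' @return scalar >= 0.
#' @export
kl_diag_gaussians <- function(q, p) {
  stopifnot(inherits(q, "latent_gaussian"), inherits(p, "latent_gaussian"))
  if (q$N != p$N)
    stop("kl_diag_gaussians: distributions must have equal dimension")
  0.5 * sum(log(p$variance / q$variance) +
              (q$variance + (q$mean - p$mean)^2) / p$variance - 1)
}

# gradients of the KL w.r.t. (mu_q, var_q, mu_p, var_p)
kl_backward <- function(q, p) {
  dmu <- (q$mean - p$mean) / p$variance
  list(dmq = dmu,
       dvq = 0.5 * (1 / p$variance - 1 / q$variance),
       dmp = -dmu,
       dvp = 0.5 * (1 / p$variance -
                      (q$variance + (q$mean - p$mean)^2) / p$variance^2))
}

#' Combined training loss
#'
#' Evaluates every term of the objective and their weighted combination
#' `total = -lambda*cc - dice + kappa*smooth + kl_weight*kl`. The CC
#' likelihood and DICE enter with negative sign because larger similarity
#' must lower the minimised loss.
#'
#' @param y_hat warped (predicted) [image_volume()].
#' @param y target repeat [image_volume()].
#' @param s_hat_soft soft one-hot channels of the warped planning labels.
#' @param s_y target repeat [label_volume()].
#' @param u predicted displacement [vector_field()].
#' @param q posterior [latent_gaussian()].
#' @param p prior [latent_gaussian()].
#' @param cfg a [loss_config()].
#' @return list of class `loss_breakdown` with fields `cc_term`,
#'   `dice_term`, `smooth_term`, `kl_term`, `total`.
#' @export
total_loss <- function(y_hat, y, s_hat_soft, s_y, u, q, p, cfg = loss_config()) {
  cc <- local_cross_correlation(y_hat, y, cfg$cc_window, cfg$cc_epsilon)
  dice <- mean_organ_dice(s_hat_soft, s_y)
  sm <- gradient_penalty(u)
  kl <- kl_diag_gaussians(q, p)
  dw <- cfg$dice_weight %||% 1
  structure(list(cc_term = cc, dice_term = dice, smooth_term = sm,
                 kl_term = kl,
                 total = -cfg$lambda_cc * cc - dw * dice + cfg$kappa * sm +
                   cfg$kl_weight * kl),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss: total %.4f | cc %.4f dice %.4f smooth %.5f kl %.4f>\n",
              x$total, x$cc_term, x$dice_term, x$smooth_term, x$kl_term))
  invisible(x)
}
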