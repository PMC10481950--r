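#' Network architecture configuration
#'
#' The model comprises three parametric maps sharing one topology family:
#' the Encoder (planning image + one-hot organ channels -> coarse feature
#' volume r and the anatomy-conditioned prior), the Inference network
#' (planning + repeat pair -> posterior; identical topology with doubled
#' input channels) and the Generator (r + latent sample -> full-resolution
#' stationary velocity field). Towers use three conv blocks (3x3x3 kernel,
#' group normalisation, rectifier, 2x max pool), so the coarse grid is the
#' input grid divided by 8; a final convolution with `feature_channels`
#' channels yields r, mapped to the prior/posterior moments by two
#' fully-connected heads. The Generator injects the latent vector as one
#' additional coarse channel (learned affine map), then applies three
#' nearest-neighbour-upsampling conv blocks and two head convolutions.
#'
#' @param N latent dimension (>= 1).
#' @param conv_channels channels of every conv block (default 32).
#' @param feature_channels channels of the coarse feature volume r (default 4).
#' @param gen_head_channels channels of the two generator head convolutions;
#'   the last entry must be 3 (a 3-vector per voxel).
#' @param gn_groups group count of the group normalisation; must divide
#'   `conv_channels` (default 8).
#' @param n_organs number of foreground organ classes K (input channels are
#'   1 intensity + K one-hot organ channels; background implicit).
#' @param logvar_clamp log-variance heads are clamped to +/- this value
#'   before exponentiation, for numerical stability.
#' @param posterior_logvar_max upper clamp of the inference network's
#'   log-variance head (default 0: posterior sd at most 1). The posterior
#'   conditions on both scans, so its genuine uncertainty is small;
#'   without the bound the KL term inflates the posterior variance toward
#'   the prior's, the generator learns to ignore latent noise of that
#'   scale, and prior samples decode to under-sized deformations.
#' @return An object of class `network_config`.
#' @export
network_config <- function(N = 8L, conv_channels = 32L, feature_channels = 4L,
                           gen_head_channels = c(16L, 3L), gn_groups = 8L,
                           n_organs = 4L, logvar_clamp = 10,
                           posterior_logvar_max = 0,
                           latent_injection = c("tiled", "affine_channel")) {
  latent_injection <- match.arg(latent_injection)
  N <- as.integer(N)
  if (N < 1L) stop("network_config: N must be >= 1")
  if (conv_channels %% gn_groups != 0L)
    stop("network_config: gn_groups must divide conv_channels")
  if (tail(gen_head_channels, 1) != 3L)
    stop("network_config: the final generator head must have 3 channels")
  structure(list(N = N, conv_channels = as.integer(conv_channels),
                 kernel = 3L, levels = 3L,
                 feature_channels = as.integer(feature_channels),
                 gen_head_channels = as.integer(gen_head_channels),
                 gn_groups = as.integer(gn_groups),
                 n_organs = as.integer(n_organs),
                 logvar_clamp = logvar_clamp,
                 posterior_logvar_max = posterior_logvar_max,
                 latent_injection = latent_injection),
            class = "network_config")
}

check_grid_divisible <- function(shape) {
  if (any(shape %% 8L != 0L))
    stop(sprintf(paste0("grid shape %s is not divisible by 8 along every ",
                        "axis; resample or pad the volumes (three pooling ",
                        "halvings require multiples of 8)"),
                 paste(shape, collapse = "x")))
  invisible(TRUE)
}

he_init <- function(dims, fan_in, scale = 1) {
  array(rnorm(prod(dims), sd = scale * sqrt(2 / fan_in)), dim = dims)
}

init_tower <- function(P, pfx, Cin, cfg, cv) {
  C <- cfg$conv_channels
  f <- cfg$feature_channels
  N <- cfg$N
  cins <- c(Cin, C, C)
  for (i in 1:3) {
    nm <- paste0(pfx, ".b", i)
    P[[paste0(nm, ".W")]] <- he_init(c(3, 3, 3, cins[i], C), 27 * cins[i])
    P[[paste0(nm, ".b")]] <- numeric(C)
    P[[paste0(nm, ".g")]] <- rep(1, C)
    P[[paste0(nm, ".be")]] <- numeric(C)
  }
  P[[paste0(pfx, ".feat.W")]] <- he_init(c(3, 3, 3, C, f), 27 * C)
  P[[paste0(pfx, ".feat.b")]] <- numeric(f)
  nin <- f * cv
  P[[paste0(pfx, ".mu.W")]] <- matrix(rnorm(N * nin, sd = 0.01), N, nin)
  P[[paste0(pfx, ".mu.b")]] <- numeric(N)
  P[[paste0(pfx, ".lv.W")]] <- matrix(rnorm(N * nin, sd = 0.01), N, nin)
  P[[paste0(pfx, ".lv.b")]] <- numeric(N)
  P
}

#' Initialise model parameters
#'
#' Creates a fresh (untrained) model bound to one grid shape: the
#' fully-connected heads and the latent injection layer are sized by the
#' coarse grid, so parameters are specific to the input resolution.
#' Weights use He initialisation; the final velocity convolution starts
#' near zero so the initial transformation is close to the identity; the
#' variance heads start near unit variance.
#'
#' @param cfg a [network_config()].
#' @param grid a [grid_spec()] whose shape is divisible by 8.
#' @param seed integer seed for the initialisation stream.
#' @return An object of class `motion_model` (fields `params`, `network`,
#'   `grid`, `version`).
#' @export
init_model_parameters <- function(cfg = network_config(), grid, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  check_grid_divisible(grid$shape)
  coarse <- grid$shape %/% 8L
  cv <- prod(coarse)
  C <- cfg$conv_channels
  f <- cfg$feature_channels
  K <- cfg$n_organs
  with_seed(seed, {
    P <- list()
    P <- init_tower(P, "enc", 1L + K, cfg, cv)
    P <- init_tower(P, "inf", 2L * (1L + K), cfg, cv)
    # posterior starts sharp (sd ~ 0.1) with an O(1)-spread mean head,
    # while the prior starts near a standard normal: early posterior
    # samples then carry pair information instead of pure noise, which
    # counteracts latent collapse
    P[["inf.lv.b"]][] <- -4.6
    P[["inf.mu.W"]] <- P[["inf.mu.W"]] * 25
    if (cfg$latent_injection == "affine_channel") {
      P[["gen.z.W"]] <- matrix(rnorm(cv * cfg$N, sd = sqrt(1 / cfg$N)), cv, cfg$N)
      P[["gen.z.b"]] <- numeric(cv)
    }
    zch <- if (cfg$latent_injection == "tiled") cfg$N else 1L
    cins <- c(f + zch, C, C)
    for (i in 1:3) {
      nm <- paste0("gen.u", i)
      P[[paste0(nm, ".W")]] <- he_init(c(3, 3, 3, cins[i], C), 27 * cins[i])
      P[[paste0(nm, ".b")]] <- numeric(C)
      P[[paste0(nm, ".g")]] <- rep(1, C)
      P[[paste0(nm, ".be")]] <- numeric(C)
    }
    H1 <- cfg$gen_head_channels[1]
    P[["gen.h1.W"]] <- he_init(c(3, 3, 3, C, H1), 27 * C)
    P[["gen.h1.b"]] <- numeric(H1)
    P[["gen.h2.W"]] <- array(rnorm(27 * H1 * 3, sd = 0.01), c(3, 3, 3, H1, 3))
    P[["gen.h2.b"]] <- numeric(3)
    structure(list(params = P, network = cfg, grid = grid,
                   version = "organmotion-checkpoint-1"),
              class = "motion_model")
  })
}

#' @export
print.motion_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<motion_model: N = %d latents, %d conv channels, grid %s, %d parameters>\n",
              x$network$N, x$network$conv_channels,
              paste(x$grid$shape, collapse = "x"), np))
  invisible(x)
}

# shared Encoder/Inference tower; xin4 is the channel-last input stack
tower_fwd <- function(P, pfx, xin4, cfg, keep = TRUE) {
  G <- cfg$gn_groups
  b1 <- block_fwd(xin4, P, paste0(pfx, ".b1"), G)
  p1 <- cpp_maxpool2(b1$out, as.integer(dim(b1$out)))
  b2 <- block_fwd(p1$out, P, paste0(pfx, ".b2"), G)
  p2 <- cpp_maxpool2(b2$out, as.integer(dim(b2$out)))
  b3 <- block_fwd(p2$out, P, paste0(pfx, ".b3"), G)
  p3 <- cpp_maxpool2(b3$out, as.integer(dim(b3$out)))
  ft <- conv_fwd(p3$out, P[[paste0(pfx, ".feat.W")]],
                 P[[paste0(pfx, ".feat.b")]], keep = keep)
  rflat <- as.numeric(ft$out)
  mu <- fc_fwd(rflat, P[[paste0(pfx, ".mu.W")]], P[[paste0(pfx, ".mu.b")]])
  lv_raw <- fc_fwd(rflat, P[[paste0(pfx, ".lv.W")]], P[[paste0(pfx, ".lv.b")]])
  cl <- cfg$logvar_clamp
  hi <- if (pfx == "inf") min(cl, cfg$posterior_logvar_max %||% cl) else cl
  lv <- clamp01(lv_raw, -cl, hi)
  cache <- if (keep)
    list(b1 = b1, p1 = p1, b2 = b2, p2 = p2, b3 = b3, p3 = p3, ft = ft,
         rflat = rflat, lv_raw = lv_raw,
         d1 = dim(b1$out), d2 = dim(b2$out), d3 = dim(b3$out))
  else NULL
  list(r = ft$out, mu = mu, lv = lv, cache = cache)
}

tower_bwd <- function(P, pfx, cache, cfg, dr4, dmu, dlv, grads) {
  cl <- cfg$logvar_clamp
  hi <- if (pfx == "inf") min(cl, cfg$posterior_logvar_max %||% cl) else cl
  dlv <- dlv * (cache$lv_raw > -cl & cache$lv_raw < hi)
  Wmu <- P[[paste0(pfx, ".mu.W")]]
  Wlv <- P[[paste0(pfx, ".lv.W")]]
  grads[[paste0(pfx, ".mu.W")]] <- dmu %o% cache$rflat
  grads[[paste0(pfx, ".mu.b")]] <- dmu
  grads[[paste0(pfx, ".lv.W")]] <- dlv %o% cache$rflat
  grads[[paste0(pfx, ".lv.b")]] <- dlv
  drflat <- as.numeric(crossprod(Wmu, dmu)) + as.numeric(crossprod(Wlv, dlv))
  dft <- array(drflat, dim = dim(cache$ft$out))
  if (!is.null(dr4)) dft <- dft + dr4
  cb <- conv_bwd(cache$ft, dft, P[[paste0(pfx, ".feat.W")]])
  grads[[paste0(pfx, ".feat.W")]] <- cb$dW
  grads[[paste0(pfx, ".feat.b")]] <- cb$db
  g <- cpp_maxpool2_bwd(cb$dx, cache$p3$argmax, as.integer(cache$d3))
  bb <- block_bwd(cache$b3, g, P, paste0(pfx, ".b3"), grads)
  grads <- bb$grads
  g <- cpp_maxpool2_bwd(bb$dx, cache$p2$argmax, as.integer(cache$d2))
  bb <- block_bwd(cache$b2, g, P, paste0(pfx, ".b2"), grads)
  grads <- bb$grads
  g <- cpp_maxpool2_bwd(bb$dx, cache$p1$argmax, as.integer(cache$d1))
  bb <- block_bwd(cache$b1, g, P, paste0(pfx, ".b1"), grads)
  bb$grads
}

gen_fwd <- function(P, r4, z, cfg, keep = TRUE) {
  G <- cfg$gn_groups
  cd <- dim(r4)[1:3]
  if (cfg$latent_injection == "tiled") {
    # one constant coarse channel per latent coordinate
    zvol <- array(rep(z, each = prod(cd)), dim = c(cd, length(z)))
  } else {
    zvol <- array(fc_fwd(z, P[["gen.z.W"]], P[["gen.z.b"]]),
                  dim = c(cd, 1L))
  }
  x0 <- concat_channels(r4, zvol)
  s1 <- cpp_upsample2(x0, as.integer(dim(x0)))
  b1 <- block_fwd(s1, P, "gen.u1", G)
  s2 <- cpp_upsample2(b1$out, as.integer(dim(b1$out)))
  b2 <- block_fwd(s2, P, "gen.u2", G)
  s3 <- cpp_upsample2(b2$out, as.integer(dim(b2$out)))
  b3 <- block_fwd(s3, P, "gen.u3", G)
  h1 <- conv_fwd(b3$out, P[["gen.h1.W"]], P[["gen.h1.b"]], keep = keep)
  r1 <- relu_fwd(h1$out)
  h2 <- conv_fwd(r1$out, P[["gen.h2.W"]], P[["gen.h2.b"]], keep = keep)
  cache <- if (keep)
    list(x0 = x0, b1 = b1, b2 = b2, b3 = b3, h1 = h1, r1mask = r1$mask,
         h2 = h2, d0 = dim(x0), du1 = dim(b1$out), du2 = dim(b2$out), z = z)
  else NULL
  list(v = h2$out, cache = cache)
}

gen_bwd <- function(P, cache, cfg, dv, grads) {
  cb <- conv_bwd(cache$h2, dv, P[["gen.h2.W"]])
  grads[["gen.h2.W"]] <- cb$dW
  grads[["gen.h2.b"]] <- cb$db
  g <- cb$dx * cache$r1mask
  cb <- conv_bwd(cache$h1, g, P[["gen.h1.W"]])
  grads[["gen.h1.W"]] <- cb$dW
  grads[["gen.h1.b"]] <- cb$db
  bb <- block_bwd(cache$b3, cb$dx, P, "gen.u3", grads)
  g <- cpp_upsample2_bwd(bb$dx, as.integer(cache$du2))
  bb <- block_bwd(cache$b2, g, P, "gen.u2", bb$grads)
  g <- cpp_upsample2_bwd(bb$dx, as.integer(cache$du1))
  bb <- block_bwd(cache$b1, g, P, "gen.u1", bb$grads)
  grads <- bb$grads
  dx0 <- cpp_upsample2_bwd(bb$dx, as.integer(cache$d0))
  N <- length(cache$z)
  if (cfg$latent_injection == "tiled") {
    Fch <- dim(dx0)[4] - N
    dr4 <- dx0[, , , seq_len(Fch), drop = FALSE]
    dz <- vapply(seq_len(N), function(i) sum(dx0[, , , Fch + i]), numeric(1))
  } else {
    Fch <- dim(dx0)[4] - 1L
    dr4 <- dx0[, , , seq_len(Fch), drop = FALSE]
    dzvol <- as.numeric(dx0[, , , Fch + 1L])
    grads[["gen.z.W"]] <- dzvol %o% cache$z
    grads[["gen.z.b"]] <- dzvol
    dz <- as.numeric(crossprod(P[["gen.z.W"]], dzvol))
  }
  list(grads = grads, dr4 = dr4, dz = dz)
}

# builds the channel-last input stack for the encoder (1 + K channels) and
# the inference network (doubled: planning stack plus the repeat-minus-
# planning difference stack). Encoding the repeat as a difference is an
# invertible re-parameterisation of the same inputs that makes the
# deformation signal first-order visible: for an identical pair the
# second half is exactly zero, so inference features separate anatomical
# change from static anatomy from the first gradient step on.
stack_inputs <- function(x, s_x, y = NULL, s_y = NULL) {
  K <- length(s_x$organ_names)
  oh_x <- label_onehot(s_x)[, , , -1L, drop = FALSE]
  a <- concat_channels(array(x$values, c(x$grid$shape, 1L)), oh_x)
  if (is.null(y)) return(a)
  oh_y <- label_onehot(s_y)[, , , -1L, drop = FALSE]
  b <- concat_channels(array(y$values, c(y$grid$shape, 1L)), oh_y)
  concat_channels(a, b - a)
}

#' Encoder forward pass
#'
#' Deterministically maps a planning image and organ labels to (i) the
#' coarse feature volume r of shape `(feature_channels, nx/8, ny/8, nz/8)`
#' and (ii) the anatomy-conditioned diagonal Gaussian prior over the
#' latent variables.
#'
#' @param model a `motion_model` (see [init_model_parameters()]).
#' @param x planning [image_volume()].
#' @param s_x planning [label_volume()].
#' @return list with `r` (channel-first 4D array) and `prior`
#'   ([latent_gaussian()]).
#' @export
encoder_forward <- function(model, x, s_x) {
  stopifnot(inherits(model, "motion_model"))
  stop_if_grid_mismatch(model$grid, x$grid, "model and image")
  check_grid_divisible(x$grid$shape)
  tw <- tower_fwd(model$params, "enc", stack_inputs(x, s_x), model$network,
                  keep = FALSE)
  list(r = aperm(tw$r, c(4, 1, 2, 3)),
       prior = latent_gaussian(tw$mu, exp(tw$lv)))
}

#' Inference network forward pass
#'
#' Deterministically maps a planning/repeat pair (images and labels) to the
#' approximate posterior over the latent variables.
#'
#' @inheritParams encoder_forward
#' @param y,s_y repeat image and labels on the same grid.
#' @return posterior [latent_gaussian()].
#' @export
inference_forward <- function(model, x, s_x, y, s_y) {
  stopifnot(inherits(model, "motion_model"))
  stop_if_grid_mismatch(x$grid, y$grid, "planning and repeat volumes")
  stop_if_grid_mismatch(model$grid, x$grid, "model and volumes")
  tw <- tower_fwd(model$params, "inf", stack_inputs(x, s_x, y, s_y),
                  model$network, keep = FALSE)
  latent_gaussian(tw$mu, exp(tw$lv))
}

#' Reparameterised draw from a latent Gaussian
#'
#' `z = mean + sqrt(variance) * eps` with standard normal `eps` from a
#' seeded stream; the caller's RNG state is untouched when a seed is given.
#'
#' @param d a [latent_gaussian()].
#' @param seed optional integer seed for reproducible draws.
#' @return numeric N-vector.
#' @export
sample_latent <- function(d, seed = NULL) {
  stopifnot(inherits(d, "latent_gaussian"))
  with_seed(seed, d$mean + sqrt(d$variance) * rnorm(d$N))
}

#' Generator forward pass
#'
#' Maps the coarse feature volume r and a latent vector z to a
#' full-resolution stationary velocity field. z is injected as one
#' additional coarse channel through a learned affine layer; three
#' upsampling conv blocks and two head convolutions follow.
#'
#' @param model a `motion_model`.
#' @param r channel-first feature volume from [encoder_forward()].
#' @param z numeric latent vector of length `model$network$N`.
#' @return a velocity [vector_field()] on the model grid.
#' @export
generator_forward <- function(model, r, z) {
  stopifnot(inherits(model, "motion_model"))
  if (length(z) != model$network$N)
    stop(sprintf("generator_forward: z has length %d but the model has N = %d",
                 length(z), model$network$N))
  r4 <- aperm(r, c(2, 3, 4, 1))
  gf <- gen_fwd(model$params, r4, as.numeric(z), model$network, keep = FALSE)
  vector_field(gf$v, model$grid, "velocity")
}
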