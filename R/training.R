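#' Training configuration
#'
#' @param epochs number of passes over the training pairs (default 1000).
#' @param learning_rate Adam step size (default 0.001).
#' @param batch_size pairs per gradient step (default 4).
#' @param loss a [loss_config()] (defaults lambda = 1000, kappa = 0.1).
#' @param network a [network_config()].
#' @param diffeo a [diffeo_config()].
#' @param seed master seed; derived streams cover initialisation, data
#'   order and the per-step posterior draws.
#' @param val_fraction fraction of patients held out for validation
#'   (grouped by patient so no patient straddles the split).
#' @param clip_norm global gradient-norm clip (default 1).
#' @param warmup_epochs number of initial epochs trained in deterministic
#'   autoencoder mode (posterior mean instead of a sample, KL weight 0).
#'   The joint system otherwise tends to collapse the latent channel
#'   before the generator learns to decode it; after the warm-up the full
#'   single-sample variational objective is optimised. Default 0
#'   (variational from the first step).
#' @param ignition_min_gain minimum training-CC improvement over the
#'   warm-up for the run to count as ignited; a stagnant warm-up is
#'   restarted from a fresh derived seed (whether the joint optimisation
#'   takes off is initialisation-dependent). Default 0.004.
#' @param max_restarts maximum number of warm-up restarts (default 2).
#' @param warmup_kl_weight KL weight during the warm-up epochs (default
#'   0.05): a small anchor that keeps the posterior-mean codes at a
#'   moderate scale without collapsing them - with no anchor the codes
#'   can blow up and saturate the generator's normalisation blocks
#'   before the decoder learns to use them.
#' @param latent_head_init `"pca"` (default) initialises the posterior
#'   mean head on the whitened top principal directions of the inference
#'   features over the training pairs, so the initial codes are spread,
#'   consistent and deformation-dominated (the inference stack encodes
#'   the repeat as a difference image); `"random"` keeps the random
#'   initialisation. With random projections, whether the joint
#'   optimisation learns to use the latent at all depends on the luck of
#'   the projection; the deterministic initialisation removes that.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment constants (defaults).
#' @param verbose print one line per epoch.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 1000L, learning_rate = 0.001,
                         batch_size = 4L, loss = loss_config(),
                         network = network_config(), diffeo = diffeo_config(),
                         seed = 1L, val_fraction = 0.1, clip_norm = 1,
                         warmup_epochs = 0L, ignition_min_gain = 0.004,
                         max_restarts = 2L, warmup_kl_weight = 0.05,
                         latent_head_init = c("pca", "random"),
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8, verbose = FALSE) {
  if (epochs < 1L) stop("train_config: epochs must be >= 1")
  if (learning_rate <= 0) stop("train_config: learning_rate must be positive")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), loss = loss,
                 network = network, diffeo = diffeo, seed = as.integer(seed),
                 val_fraction = val_fraction, clip_norm = clip_norm,
                 warmup_epochs = as.integer(warmup_epochs),
                 ignition_min_gain = ignition_min_gain,
                 max_restarts = as.integer(max_restarts),
                 warmup_kl_weight = warmup_kl_weight,
                 latent_head_init = match.arg(latent_head_init),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, verbose = verbose),
            class = "train_config")
}

# precomputed channel stacks for one planning-repeat pair
make_pair_tensors <- function(pair, K) {
  sh <- pair$x$grid$shape
  o_x <- label_onehot(pair$sx)
  t_y <- label_onehot(pair$sy)
  list(enc_in = stack_inputs(pair$x, pair$sx),
       inf_in = stack_inputs(pair$x, pair$sx, pair$y, pair$sy),
       x_src = array(pair$x$values, c(sh, 1L)),
       y3 = pair$y$values, o_x = o_x, t_y = t_y, sh = sh)
}

cc_val_grad <- function(a, b, n, eps, want_grad = TRUE) {
  st <- cc_stats(a, b, n, eps)
  M <- prod(st$dim3)
  value <- mean(st$pervox)
  if (!want_grad) return(list(value = value, grad = NULL))
  alpha <- 2 * st$cross / st$den
  beta <- 2 * st$cross^2 * st$vb / st$den^2
  g <- (b * cpp_boxsum(alpha, st$dim3, n) -
          cpp_boxsum(alpha * st$Sb / st$W, st$dim3, n) -
          a * cpp_boxsum(beta, st$dim3, n) +
          cpp_boxsum(beta * st$Sa / st$W, st$dim3, n)) / M
  list(value = value, grad = g)
}

soft_dice_val <- function(soft, t_y) {
  K <- dim(t_y)[4] - 1L
  d <- numeric(K)
  for (k in seq_len(K)) {
    p <- soft[, , , k + 1L]
    t <- t_y[, , , k + 1L]
    A <- sum(p) + sum(t)
    d[k] <- if (A == 0) 1 else 2 * sum(p * t) / A
  }
  mean(d)
}

# full forward (and optional backward) pass for one pair; eps is the
# standard-normal draw for the reparameterised posterior sample, or NULL
# to use the posterior mean
pair_pass <- function(P, tn, cfg, eps = NULL, want_grad = TRUE) {
  ncfg <- cfg$network
  lcfg <- cfg$loss
  S <- cfg$diffeo$squaring_steps
  N <- ncfg$N
  tw_q <- tower_fwd(P, "inf", tn$inf_in, ncfg, keep = want_grad)
  vq <- exp(tw_q$lv)
  z <- if (is.null(eps)) tw_q$mu else tw_q$mu + sqrt(vq) * eps
  tw_e <- tower_fwd(P, "enc", tn$enc_in, ncfg, keep = want_grad)
  vp <- exp(tw_e$lv)
  gf <- gen_fwd(P, tw_e$r, z, ncfg, keep = want_grad)
  ex <- exp_fwd(gf$v, S, cache = want_grad)
  u <- if (want_grad) ex$u else ex
  dim4 <- as.integer(c(tn$sh, 1L))
  yhat <- cpp_trilerp_fwd(tn$x_src, dim4, u)
  soft <- cpp_trilerp_fwd(tn$o_x, as.integer(dim(tn$o_x)), u)
  cc <- cc_val_grad(array(yhat, tn$sh), tn$y3, lcfg$cc_window,
                    lcfg$cc_epsilon, want_grad)
  dice <- soft_dice_val(soft, tn$t_y)
  gpc <- gp_fwd(u)
  q <- latent_gaussian(tw_q$mu, vq)
  p <- latent_gaussian(tw_e$mu, vp)
  kl <- kl_diag_gaussians(q, p)
  dw <- lcfg$dice_weight %||% 1
  breakdown <- structure(
    list(cc_term = cc$value, dice_term = dice, smooth_term = gpc$value,
         kl_term = kl,
         total = -lcfg$lambda_cc * cc$value - dw * dice +
           lcfg$kappa * gpc$value + lcfg$kl_weight * kl),
    class = "loss_breakdown")
  if (!want_grad) return(list(breakdown = breakdown))

  dyhat <- array(-lcfg$lambda_cc * cc$grad, dim4)
  dsoft <- -dw * mean_organ_dice_backward(soft, tn$t_y)
  wib <- cpp_trilerp_bwd(tn$x_src, dim4, u, dyhat)
  wlb <- cpp_trilerp_bwd(tn$o_x, as.integer(dim(tn$o_x)), u, dsoft)
  du <- wib$ddisp + wlb$ddisp + lcfg$kappa * gp_bwd(gpc)
  dv <- exp_bwd(ex, du)
  gb <- gen_bwd(P, gf$cache, ncfg, dv, list())
  kb <- kl_backward(q, p)
  klw <- lcfg$kl_weight
  dmq <- klw * kb$dmq + gb$dz
  dlvq <- klw * kb$dvq * vq
  if (!is.null(eps)) dlvq <- dlvq + gb$dz * 0.5 * sqrt(vq) * eps
  grads <- tower_bwd(P, "inf", tw_q$cache, ncfg, NULL, dmq, dlvq, gb$grads)
  grads <- tower_bwd(P, "enc", tw_e$cache, ncfg, gb$dr4,
                     klw * kb$dmp, klw * kb$dvp * vp, grads)
  list(breakdown = breakdown, grads = grads)
}

add_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

grad_global_norm <- function(g) {
  sqrt(sum(vapply(g, function(a) sum(a * a), numeric(1))))
}

adam_update <- function(P, g, st, lr, b1, b2, eps) {
  st$t <- st$t + 1L
  c1 <- 1 - b1^st$t
  c2 <- 1 - b2^st$t
  for (nm in names(g)) {
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g[[nm]]
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g[[nm]]^2
    P[[nm]] <- P[[nm]] - lr * (st$m[[nm]] / c1) /
      (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(P = P, st = st)
}

# one clipped Adam step on a fixed batch; used by train_model and directly
# testable as a smoke property
train_step <- function(P, tensors, cfg, st, eps_mat) {
  acc <- NULL
  tot <- NULL
  for (i in seq_along(tensors)) {
    ps <- pair_pass(P, tensors[[i]], cfg,
                    eps = if (is.null(eps_mat)) NULL else eps_mat[, i],
                    want_grad = TRUE)
    acc <- add_grads(acc, ps$grads)
    tot <- if (is.null(tot)) unlist(ps$breakdown) else tot + unlist(ps$breakdown)
  }
  B <- length(tensors)
  for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / B
  gn <- grad_global_norm(acc)
  if (is.finite(gn) && gn > cfg$clip_norm)
    for (nm in names(acc)) acc[[nm]] <- acc[[nm]] * (cfg$clip_norm / gn)
  upd <- adam_update(P, acc, st, cfg$learning_rate,
                     cfg$adam_beta1, cfg$adam_beta2, cfg$adam_eps)
  list(P = upd$P, st = upd$st, mean_breakdown = tot / B, grad_norm = gn)
}

dataset_pairs <- function(dataset) {
  pairs <- list()
  for (case in dataset) {
    if (length(case$repeats) < 1L)
      stop("train_model: every patient case needs at least one repeat")
    for (rep in case$repeats)
      pairs[[length(pairs) + 1L]] <-
        list(x = case$planning$image, sx = case$planning$labels,
             y = rep$image, sy = rep$labels, patient = case$patient_id)
  }
  pairs
}

#' Train the generative motion model
#'
#' Optimises encoder, inference network and generator jointly by
#' minimising the combined objective with Adam, one reparameterised
#' posterior sample per pair and step, gradient-norm clipping, and a
#' patient-grouped validation split; the returned parameters are those of
#' the epoch with the lowest validation loss.
#'
#' @param dataset list of patient cases as produced by
#'   [generate_population()] (each case: `planning` with `image`/`labels`,
#'   `repeats` a list of the same, `patient_id`).
#' @param cfg a [train_config()].
#' @return list of class `train_result` with `model` (a `motion_model`),
#'   `history` (per-epoch data.frame of loss terms) and `config`.
#' @export
train_model <- function(dataset, cfg = train_config()) {
  if (length(dataset) < 1L) stop("train_model: dataset is empty")
  pairs <- dataset_pairs(dataset)
  grid <- pairs[[1]]$x$grid
  K <- cfg$network$n_organs
  set.seed(cfg$seed)
  patients <- unique(vapply(pairs, `[[`, character(1), "patient"))
  if (length(patients) >= 2L && cfg$val_fraction > 0) {
    nval <- max(1L, round(cfg$val_fraction * length(patients)))
    val_pat <- sample(patients, nval)
    val_idx <- which(vapply(pairs, `[[`, character(1), "patient") %in% val_pat)
    train_idx <- setdiff(seq_along(pairs), val_idx)
  } else {
    train_idx <- seq_along(pairs)
    val_idx <- train_idx
  }
  # channel stacks are rebuilt per use: caching them for every pair keeps
  # hundreds of MB live and every garbage collection then scans it, which
  # costs far more than the rebuild
  get_tensors <- function(i) make_pair_tensors(pairs[[i]], K)
  N <- cfg$network$N
  cfg_warm <- cfg
  cfg_warm$loss$kl_weight <- cfg$warmup_kl_weight %||% 0

  # deterministic data-driven initialisation of the posterior mean head:
  # whitened top principal directions of the inference features over the
  # training pairs (see ?train_config)
  pca_head_init <- function(P) {
    if (length(train_idx) < 3L) return(P)  # PCA needs a few pairs
    feats <- t(vapply(train_idx, function(i) {
      tn <- get_tensors(i)
      as.numeric(tower_fwd(P, "inf", tn$inf_in, cfg$network,
                           keep = FALSE)$r)
    }, numeric(ncol(P[["inf.mu.W"]]))))
    mu <- colMeans(feats)
    nc <- min(N, nrow(feats) - 1L, ncol(feats))
    if (nc < 1L) return(P)
    pc <- stats::prcomp(feats, center = TRUE, rank. = nc)
    W <- P[["inf.mu.W"]]
    W[seq_len(nc), ] <- t(pc$rotation[, seq_len(nc), drop = FALSE]) /
      pmax(pc$sdev[seq_len(nc)], 1e-8)
    P[["inf.mu.W"]] <- W
    P[["inf.mu.b"]] <- -as.numeric(W %*% mu)
    P
  }

  fresh_state <- function(seed) {
    model <- init_model_parameters(cfg$network, grid, seed = seed)
    P <- model$params
    if (identical(cfg$latent_head_init %||% "random", "pca"))
      P <- pca_head_init(P)
    list(model = model, P = P,
         st = list(m = lapply(P, function(a) a * 0),
                   v = lapply(P, function(a) a * 0), t = 0L))
  }

  run_epochs <- function(state, epochs, warm_flags, hist_rows, best) {
    P <- state$P
    st <- state$st
    aborted <- FALSE
    for (e in seq_along(epochs)) {
      epoch <- epochs[e]
      warm <- warm_flags[e]
      cfg_e <- if (warm) cfg_warm else cfg
      order <- sample(train_idx)
      tr_sum <- NULL
      nb <- 0L
      for (b0 in seq(1, length(order), by = cfg$batch_size)) {
        idx <- order[b0:min(b0 + cfg$batch_size - 1L, length(order))]
        eps_mat <- if (warm) NULL
          else matrix(rnorm(N * length(idx)), N, length(idx))
        stp <- train_step(P, lapply(idx, get_tensors), cfg_e, st, eps_mat)
        if (!all(is.finite(stp$mean_breakdown))) {
          warning(sprintf(paste0("non-finite loss at epoch %d; aborting and ",
                                 "returning the best checkpoint (epoch %d)"),
                          epoch, best$epoch))
          aborted <- TRUE
          break
        }
        P <- stp$P
        st <- stp$st
        tr_sum <- if (is.null(tr_sum)) stp$mean_breakdown
          else tr_sum + stp$mean_breakdown
        nb <- nb + 1L
      }
      if (aborted) break
      tr <- tr_sum / nb
      val_sum <- NULL
      for (i in val_idx) {
        ps <- pair_pass(P, get_tensors(i), cfg, eps = NULL, want_grad = FALSE)
        val_sum <- if (is.null(val_sum)) unlist(ps$breakdown)
          else val_sum + unlist(ps$breakdown)
      }
      vl <- val_sum / length(val_idx)
      hist_rows[[length(hist_rows) + 1L]] <-
        c(epoch = epoch, setNames(tr, paste0("train_", names(tr))),
          setNames(vl, paste0("val_", names(vl))))
      if (vl[["total"]] < best$val)
        best <- list(val = vl[["total"]], P = P, epoch = epoch)
      if (cfg$verbose)
        message(sprintf("epoch %3d | train %10.4f | val %10.4f | cc %.4f dice %.4f kl %.3f",
                        epoch, tr[["total"]], vl[["total"]], tr[["cc_term"]],
                        tr[["dice_term"]], tr[["kl_term"]]))
    }
    list(P = P, st = st, hist_rows = hist_rows, best = best,
         aborted = aborted)
  }

  warm_n <- min(cfg$warmup_epochs, cfg$epochs)
  restarts <- 0L
  repeat {
    state <- fresh_state(cfg$seed + 1L + 101L * restarts)
    hist_rows <- list()
    best <- list(val = Inf, P = state$P, epoch = 0L)
    if (warm_n == 0L) {
      warm_run <- list(P = state$P, st = state$st, hist_rows = hist_rows,
                       best = best, aborted = FALSE)
      break
    }
    warm_run <- run_epochs(state, seq_len(warm_n), rep(TRUE, warm_n),
                           hist_rows, best)
    if (warm_run$aborted) break
    # ignition check: the warm-up must visibly move the reconstruction
    # similarity; a stagnant warm-up means the latent pathway never took
    # off for this initialisation (a known failure mode of the joint
    # optimisation) and the run is restarted from a fresh seed
    cc_gain <- warm_run$hist_rows[[length(warm_run$hist_rows)]][["train_cc_term"]] -
      warm_run$hist_rows[[1L]][["train_cc_term"]]
    if (cc_gain >= cfg$ignition_min_gain || restarts >= cfg$max_restarts)
      break
    restarts <- restarts + 1L
    if (cfg$verbose)
      message(sprintf("warm-up stagnant (cc gain %.4f); restart %d",
                      cc_gain, restarts))
  }
  model <- fresh_state(cfg$seed + 1L + 101L * restarts)$model
  out <- warm_run
  if (!out$aborted && cfg$epochs > warm_n) {
    out <- run_epochs(list(P = out$P, st = out$st),
                      (warm_n + 1L):cfg$epochs,
                      rep(FALSE, cfg$epochs - warm_n),
                      out$hist_rows, out$best)
  }
  model$params <- out$best$P
  history <- as.data.frame(do.call(rbind, out$hist_rows))
  structure(list(model = model, history = history, config = cfg,
                 best_epoch = out$best$epoch, aborted = out$aborted,
                 restarts = restarts),
            class = "train_result")
}

#' Reconstruct a repeat anatomy through the posterior
#'
#' Runs the inference network on a planning/repeat pair, takes the
#' posterior mean latent (the mode of the deformation distribution),
#' generates the velocity field, exponentiates it and warps the planning
#' image and labels. Deterministic.
#'
#' @param model a trained `motion_model`.
#' @param x,s_x planning image and labels.
#' @param y,s_y repeat image and labels.
#' @param cfg a [diffeo_config()].
#' @return list with `u` (pull-back displacement used for warping),
#'   `u_forward` (the forward displacement `exp(-v)`, mapping planning
#'   points to their repeat positions), `y_hat`, `s_hat`, `soft`, `v`,
#'   `z`, `posterior`, `prior`.
#' @export
reconstruct_repeat <- function(model, x, s_x, y, s_y, cfg = diffeo_config()) {
  q <- inference_forward(model, x, s_x, y, s_y)
  enc <- encoder_forward(model, x, s_x)
  v <- generator_forward(model, enc$r, q$mean)
  u <- exponentiate(v, cfg)
  u_fwd <- invert_velocity(v, cfg)
  y_hat <- warp_image(x, u)
  wl <- warp_labels(s_x, u, return_soft = TRUE)
  list(u = u, u_forward = u_fwd, y_hat = y_hat, s_hat = wl$labels,
       soft = wl$soft, v = v, z = q$mean, posterior = q, prior = enc$prior)
}

#' Sample anatomies from the anatomy-conditioned prior
#'
#' Draws latent vectors from the encoder's prior for the given planning
#' anatomy, generates a deformation per draw, warps the planning volumes
#' and summarises each sample with per-organ volume changes and
#' centre-of-mass shifts plus the folding fraction of the field.
#'
#' @param model a trained `motion_model`.
#' @param x,s_x planning image and labels.
#' @param n_samples number of prior draws (>= 1).
#' @param seed seed of the sampling stream (caller RNG untouched).
#' @param cfg a [diffeo_config()].
#' @param organs organ names to summarise (default: all).
#' @param keep_fields also return each sample's displacement field and
#'   warped volumes (memory heavy).
#' @param zero_variance diagnostic mode: use the prior mean for every draw.
#' @return list with `stats` (data.frame: sample, organ, volume_change_cm3,
#'   volume_change_pct, com shift columns, folding), `z` (n x N matrix of
#'   draws) and optionally `samples`.
#' @export
sample_anatomy <- function(model, x, s_x, n_samples = 100L, seed = 1L,
                           cfg = diffeo_config(), organs = NULL,
                           keep_fields = FALSE, zero_variance = FALSE) {
  stopifnot(n_samples >= 1L)
  enc <- encoder_forward(model, x, s_x)
  prior <- enc$prior
  N <- prior$N
  if (is.null(organs)) organs <- s_x$organ_names
  eps <- with_seed(seed, matrix(rnorm(n_samples * N), n_samples, N))
  if (zero_variance) eps[] <- 0
  zmat <- sweep(sweep(eps, 2, sqrt(prior$variance), `*`), 2, prior$mean, `+`)
  rows <- list()
  samples <- if (keep_fields) vector("list", n_samples) else NULL
  grid <- s_x$grid
  vv <- voxel_volume_cm3(grid)
  com0 <- lapply(organs, function(o) center_of_mass(organ_mask(s_x, o), grid))
  names(com0) <- organs
  vol0 <- vapply(organs, function(o) organ_volume(organ_mask(s_x, o), grid),
                 numeric(1))
  for (i in seq_len(n_samples)) {
    v <- generator_forward(model, enc$r, zmat[i, ])
    u <- exponentiate(v, cfg)
    wl <- warp_labels(s_x, u, return_soft = TRUE)
    fold <- folding_fraction(u)
    for (org in organs) {
      ds <- deformation_stats(s_x, wl$labels, org)
      k <- match(org, s_x$organ_names)
      soft_k <- wl$soft[, , , k + 1L]
      com_soft <- weighted_com(soft_k, grid) - com0[[org]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample = i, organ = org,
        volume_change_cm3 = ds$volume_change_cm3,
        volume_change_pct = ds$volume_change_pct,
        com_shift_x_mm = ds$com_shift_vector_mm[1],
        com_shift_y_mm = ds$com_shift_vector_mm[2],
        com_shift_z_mm = ds$com_shift_vector_mm[3],
        com_shift_scalar_mm = ds$com_shift_scalar_mm,
        volume_soft_cm3 = sum(soft_k) * vv,
        volume_change_soft_pct = 100 * (sum(soft_k) * vv - vol0[[org]]) /
          vol0[[org]],
        com_shift_soft_x_mm = com_soft[1],
        com_shift_soft_y_mm = com_soft[2],
        com_shift_soft_z_mm = com_soft[3],
        com_shift_soft_scalar_mm = mean(abs(com_soft)),
        folding = fold)
    }
    if (keep_fields)
      samples[[i]] <- list(u = u, labels = wl$labels, y = warp_image(x, u))
  }
  out <- list(stats = do.call(rbind, rows), z = zmat, prior = prior)
  if (keep_fields) out$samples <- samples
  out
}

#' Save / load a model checkpoint
#'
#' Single-archive checkpoint holding a format version, the network
#' configuration, the grid and every parameter array; the round trip is
#' exact.
#'
#' @param model a `motion_model`.
#' @param path file path.
#' @return `load_checkpoint` returns the `motion_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "motion_model"))
  tmp <- paste0(path, ".tmp")
  saveRDS(model, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "motion_model") ||
      !identical(model$version, "organmotion-checkpoint-1"))
    stop("load_checkpoint: not an organmotion checkpoint (or wrong version)")
  model
}
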