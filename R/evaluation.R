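#' Sample points on an organ surface
#'
#' Finds every exposed voxel face of the mask (faces whose 6-neighbour is
#' outside the mask) and samples L points uniformly over them (with
#' replacement), each point uniformly placed within its face. Reproducible
#' per seed.
#'
#' @param mask non-empty 3D logical array.
#' @param grid the [grid_spec()] the mask lives on.
#' @param L number of points.
#' @param seed integer seed.
#' @return list of class `surface_point_set`: `points` (L x 3 matrix, mm),
#'   `correspondence_ids` (1..L).
#' @export
extract_surface_points <- function(mask, grid, L = 1000L, seed = 1L) {
  if (!any(mask)) stop("extract_surface_points: empty mask")
  sh <- dim(mask)
  # neighbour value at +/- 1 along an axis; out-of-grid counts as outside
  nbr <- function(m, ax, dir) {
    out <- array(FALSE, dim = sh)
    if (ax == 1L) { if (dir > 0) out[-sh[1], , ] <- m[-1, , ] else out[-1, , ] <- m[-sh[1], , ] }
    if (ax == 2L) { if (dir > 0) out[, -sh[2], ] <- m[, -1, ] else out[, -1, ] <- m[, -sh[2], ] }
    if (ax == 3L) { if (dir > 0) out[, , -sh[3]] <- m[, , -1] else out[, , -1] <- m[, , -sh[3]] }
    out
  }
  faces <- NULL
  for (ax in 1:3) for (dir in c(-1L, 1L)) {
    exposed <- mask & !nbr(mask, ax, dir)
    idx <- which(exposed, arr.ind = TRUE)
    if (nrow(idx) > 0)
      faces <- rbind(faces, cbind(idx, ax = ax, dir = dir))
  }
  with_seed(seed, {
    pick <- sample(nrow(faces), L, replace = TRUE)
    f <- faces[pick, , drop = FALSE]
    # face centre is half a voxel out along (ax, dir); jitter in-plane
    pts <- (f[, 1:3] - 1)
    for (a in 1:3) {
      off <- ifelse(f[, "ax"] == a, 0.5 * f[, "dir"], runif(L, -0.5, 0.5))
      pts[, a] <- pts[, a] + off
    }
    pts <- sweep(sweep(pts, 2, grid$spacing, `*`), 2, grid$origin, `+`)
    colnames(pts) <- c("x", "y", "z")
    structure(list(points = pts, correspondence_ids = seq_len(L)),
              class = "surface_point_set")
  })
}

# trilinear sample of a displacement field (voxel units) at continuous
# voxel coordinates (L x 3, 0-based); clamped to the grid
field_at_points <- function(u, pts_vox) {
  uv <- if (inherits(u, "vector_field")) u$vectors else u
  sh <- dim(uv)[1:3]
  p <- pts_vox
  for (a in 1:3) p[, a] <- pmin(pmax(p[, a], 0), sh[a] - 1)
  i0 <- pmin(floor(p), matrix(rep(sh - 2, each = nrow(p)), ncol = 3))
  i0 <- pmax(i0, 0)
  f <- p - i0
  out <- matrix(0, nrow(p), 3)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (ifelse(dx == 1, f[, 1], 1 - f[, 1])) *
      (ifelse(dy == 1, f[, 2], 1 - f[, 2])) *
      (ifelse(dz == 1, f[, 3], 1 - f[, 3]))
    lin <- (i0[, 1] + dx) + sh[1] * ((i0[, 2] + dy) + sh[2] * (i0[, 3] + dz)) + 1
    M <- prod(sh)
    for (c in 1:3) out[, c] <- out[, c] + w * uv[lin + (c - 1) * M]
  }
  out
}

#' Mean surface error between corresponding points under a deformation
#'
#' Warps each planning surface point by the (forward) displacement field,
#' sampled trilinearly at the point's sub-voxel position, and returns the
#' mean and sd of the Euclidean distances to the corresponding repeat
#' points (matched by `correspondence_ids`).
#'
#' @param planning_pts,repeat_pts [extract_surface_points()] sets with
#'   bijective correspondence ids (on synthetic data the repeat points are
#'   the truth-warped planning points).
#' @param u forward displacement [vector_field()] (use the identity field
#'   or `u = NULL` for the no-model baseline).
#' @param grid the [grid_spec()] of the field.
#' @return list of class `surface_error_result`: `mean`, `sd`, `per_point`
#'   (mm).
#' @export
surface_error <- function(planning_pts, repeat_pts, u, grid) {
  stopifnot(inherits(planning_pts, "surface_point_set"),
            inherits(repeat_pts, "surface_point_set"))
  if (is.null(planning_pts$correspondence_ids) ||
      is.null(repeat_pts$correspondence_ids))
    stop(paste0("surface_error: correspondence ids are required; for ",
                "correspondence-free sets use surface_distance_nearest(), ",
                "which is a different (lower-bounding) metric"))
  m <- match(planning_pts$correspondence_ids, repeat_pts$correspondence_ids)
  if (any(is.na(m)) ||
      length(unique(repeat_pts$correspondence_ids)) !=
        length(repeat_pts$correspondence_ids))
    stop("surface_error: correspondence ids must be bijective between the sets")
  target <- repeat_pts$points[m, , drop = FALSE]
  warped <- planning_pts$points
  if (!is.null(u)) {
    pts_vox <- sweep(sweep(planning_pts$points, 2, grid$origin, `-`),
                     2, grid$spacing, `/`)
    disp_mm <- sweep(field_at_points(u, pts_vox), 2, grid$spacing, `*`)
    warped <- warped + disp_mm
  }
  d <- sqrt(rowSums((target - warped)^2))
  structure(list(mean = mean(d), sd = stats::sd(d), per_point = d),
            class = "surface_error_result")
}

#' Nearest-point surface distance (correspondence-free)
#'
#' Mean over points in `a` of the distance to the nearest point of `b`.
#' This bounds the corresponding-point surface error from below and is
#' reported under its own name to keep the metrics distinguishable.
#'
#' @param a,b `surface_point_set`s.
#' @return list with `mean`, `sd`, `per_point` (mm).
#' @export
surface_distance_nearest <- function(a, b) {
  pa <- a$points
  pb <- b$points
  d <- numeric(nrow(pa))
  step <- 2000L
  for (s in seq(1, nrow(pa), by = step)) {
    i <- s:min(s + step - 1L, nrow(pa))
    cross <- outer(rowSums(pa[i, , drop = FALSE]^2), rowSums(pb^2), `+`) -
      2 * pa[i, , drop = FALSE] %*% t(pb)
    d[i] <- sqrt(pmax(apply(cross, 1, min), 0))
  }
  list(mean = mean(d), sd = stats::sd(d), per_point = d)
}

# truth-corresponding surface point pair for one synthetic repeat: repeat
# points are the planning points moved by the stored forward truth field
truth_surface_pair <- function(case, rep_idx, organ = "prostate", L = 1000L,
                               seed = 1L) {
  grid <- case$planning$labels$grid
  pts <- extract_surface_points(organ_mask(case$planning$labels, organ),
                                grid, L, seed)
  u_t <- case$truth[[rep_idx]]$displacement_fwd
  pts_vox <- sweep(sweep(pts$points, 2, grid$origin, `-`), 2, grid$spacing, `/`)
  disp_mm <- sweep(field_at_points(u_t, pts_vox), 2, grid$spacing, `*`)
  rep_pts <- structure(list(points = pts$points + disp_mm,
                            correspondence_ids = pts$correspondence_ids),
                       class = "surface_point_set")
  list(planning = pts, repeat_pts = rep_pts)
}

#' Reconstruction accuracy table across latent dimensions
#'
#' For each trained checkpoint (and the no-model baseline `"0"`, for which
#' the planning scan itself is the prediction), evaluates every
#' planning-repeat pair of the given cases: image cross-correlation,
#' per-organ hard DICE of the warped planning labels against the repeat
#' labels, and the corresponding-point prostate surface error against the
#' ground-truth correspondences.
#'
#' @param models named list of `motion_model`s; names are the latent
#'   dimensions; entry `"0"` (or NULL elements) denote the identity
#'   baseline.
#' @param test_cases list of patient cases (with stored `truth`).
#' @param L surface points per pair.
#' @param seed seed for the surface sampling.
#' @param cc_window CC window (default 9).
#' @return list of class `reconstruction_report`: `per_pair` data.frame
#'   and `summary` (mean and sd by N and metric).
#' @export
reconstruction_report <- function(models, test_cases, L = 600L, seed = 1L,
                                  cc_window = 9L) {
  rows <- list()
  for (nm in names(models)) {
    model <- models[[nm]]
    for (case in test_cases) {
      x <- case$planning$image
      sx <- case$planning$labels
      organs <- sx$organ_names
      for (ri in seq_along(case$repeats)) {
        y <- case$repeats[[ri]]$image
        sy <- case$repeats[[ri]]$labels
        if (is.null(model)) {
          y_hat <- x
          s_hat <- sx
          u_fwd <- NULL
        } else {
          rec <- reconstruct_repeat(model, x, sx, y, sy)
          y_hat <- rec$y_hat
          s_hat <- rec$s_hat
          u_fwd <- rec$u_forward
        }
        sp <- truth_surface_pair(case, ri, "prostate", L, seed)
        se <- surface_error(sp$planning, sp$repeat_pts, u_fwd, x$grid)
        row <- data.frame(N = nm, patient = case$patient_id, rep = ri,
                          cc = local_cross_correlation(y_hat, y, cc_window),
                          surface_error_mm = se$mean,
                          surface_error_sd_mm = se$sd)
        for (org in organs)
          row[[paste0("dice_", org)]] <-
            dice_score(organ_mask(s_hat, org), organ_mask(sy, org))
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  per_pair <- do.call(rbind, rows)
  metrics <- setdiff(names(per_pair), c("N", "patient", "rep"))
  summary <- do.call(rbind, lapply(split(per_pair, per_pair$N), function(d) {
    out <- data.frame(N = d$N[1])
    for (m in metrics) {
      out[[paste0(m, "_mean")]] <- mean(d[[m]])
      out[[paste0(m, "_sd")]] <- stats::sd(d[[m]])
    }
    out
  }))
  structure(list(per_pair = per_pair, summary = summary),
            class = "reconstruction_report")
}

# soft-channel deformation summaries of the real (stored) repeats
real_repeat_stats <- function(case) {
  sx <- case$planning$labels
  grid <- sx$grid
  organs <- sx$organ_names
  vv <- voxel_volume_cm3(grid)
  rows <- list()
  for (ri in seq_along(case$repeats)) {
    wl <- warp_labels(sx, case$truth[[ri]]$displacement_pull,
                      return_soft = TRUE)
    for (org in organs) {
      k <- match(org, organs)
      soft_k <- wl$soft[, , , k + 1L]
      com0 <- center_of_mass(organ_mask(sx, org), grid)
      cs <- weighted_com(soft_k, grid) - com0
      ds <- deformation_stats(sx, case$repeats[[ri]]$labels, org)
      vol0 <- organ_volume(organ_mask(sx, org), grid)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = ri, organ = org,
        volume_change_cm3 = ds$volume_change_cm3,
        volume_change_pct = ds$volume_change_pct,
        com_shift_scalar_mm = ds$com_shift_scalar_mm,
        volume_change_soft_pct = 100 * (sum(soft_k) * vv - vol0) / vol0,
        com_shift_soft_scalar_mm = mean(abs(cs)))
    }
  }
  do.call(rbind, rows)
}

#' Real-versus-sampled deformation distributions per test patient
#'
#' For each case: summarises the stored (real) repeats and `n_samples`
#' prior draws with per-organ volume changes and centre-of-mass shifts,
#' and compares the two distributions with two-sample Kolmogorov-Smirnov
#' statistics. The continuous soft-channel statistics are used for the KS
#' comparison (the argmax-mask statistics step in whole-voxel increments
#' at this grid resolution); both are reported. Optionally writes
#' histogram PNGs.
#'
#' @param model a trained `motion_model`.
#' @param test_cases list of patient cases.
#' @param n_samples prior draws per patient (default 100).
#' @param seed sampling seed.
#' @param organs organ names to compare (default prostate/bladder/rectum).
#' @param plot_dir optional directory for histogram PNGs.
#' @return list of class `generative_report`: `summary` (per patient and
#'   quantity: real and sampled mean/sd, KS D and p), `real`, `sampled`.
#' @export
generative_report <- function(model, test_cases, n_samples = 100L, seed = 1L,
                              organs = c("prostate", "bladder", "rectum"),
                              plot_dir = NULL) {
  summaries <- list()
  reals <- list()
  sampleds <- list()
  for (case in test_cases) {
    real <- real_repeat_stats(case)
    samp <- sample_anatomy(model, case$planning$image, case$planning$labels,
                           n_samples = n_samples, seed = seed,
                           organs = organs)$stats
    reals[[case$patient_id]] <- real
    sampleds[[case$patient_id]] <- samp
    for (org in organs) {
      r <- real[real$organ == org, ]
      s <- samp[samp$organ == org, ]
      for (q in c("com_shift_soft_scalar_mm", "volume_change_soft_pct")) {
        ks <- suppressWarnings(stats::ks.test(s[[q]], r[[q]]))
        summaries[[length(summaries) + 1L]] <- data.frame(
          patient = case$patient_id, organ = org, quantity = q,
          real_mean = mean(r[[q]]), real_sd = stats::sd(r[[q]]),
          sampled_mean = mean(s[[q]]), sampled_sd = stats::sd(s[[q]]),
          ks_D = unname(ks$statistic), ks_p = ks$p.value)
      }
      if (!is.null(plot_dir)) {
        dir.create(plot_dir, recursive = TRUE, showWarnings = FALSE)
        fn <- file.path(plot_dir, sprintf("%s_%s_com_shift.png",
                                          case$patient_id, org))
        grDevices::png(fn, width = 640, height = 480)
        rng <- range(c(r$com_shift_soft_scalar_mm, s$com_shift_soft_scalar_mm))
        br <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = 20)
        graphics::hist(s$com_shift_soft_scalar_mm, breaks = br,
                       col = grDevices::rgb(1, .6, 0, .5),
                       main = sprintf("%s %s COM shift", case$patient_id, org),
                       xlab = "COM shift (mm)")
        graphics::hist(r$com_shift_soft_scalar_mm, breaks = br,
                       col = grDevices::rgb(0, .4, 1, .5), add = TRUE)
        grDevices::dev.off()
      }
    }
  }
  structure(list(summary = do.call(rbind, summaries), real = reals,
                 sampled = sampleds, seed = seed),
            class = "generative_report")
}

#' Deformations triggered by one latent variable
#'
#' Holds every latent coordinate at the prior mean except one, which is
#' offset by multiples of the prior standard deviation; generates the
#' anatomy for each value and summarises the per-organ deformation
#' statistics relative to the planning anatomy.
#'
#' @param model a trained `motion_model`.
#' @param x,s_x planning image and labels.
#' @param variable latent index in 1..N.
#' @param offsets offsets in prior-sd units (default -1.5 .. 1.5 in steps
#'   of 0.5; includes 0, the prior-mean reference).
#' @param cfg a [diffeo_config()].
#' @return data.frame of class `traversal_result`: one row per (offset,
#'   organ) with hard and soft deformation statistics.
#' @export
latent_traversal <- function(model, x, s_x, variable,
                             offsets = seq(-1.5, 1.5, by = 0.5),
                             cfg = diffeo_config()) {
  enc <- encoder_forward(model, x, s_x)
  N <- enc$prior$N
  if (variable < 1L || variable > N)
    stop(sprintf("latent_traversal: variable must be in 1..%d", N))
  grid <- s_x$grid
  vv <- voxel_volume_cm3(grid)
  organs <- s_x$organ_names
  rows <- list()
  for (off in offsets) {
    z <- enc$prior$mean
    z[variable] <- z[variable] + off * sqrt(enc$prior$variance[variable])
    v <- generator_forward(model, enc$r, z)
    u <- exponentiate(v, cfg)
    wl <- warp_labels(s_x, u, return_soft = TRUE)
    for (org in organs) {
      ds <- deformation_stats(s_x, wl$labels, org)
      k <- match(org, organs)
      soft_k <- wl$soft[, , , k + 1L]
      vol0 <- organ_volume(organ_mask(s_x, org), grid)
      cs <- weighted_com(soft_k, grid) - center_of_mass(organ_mask(s_x, org), grid)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = variable, offset = off, organ = org,
        volume_change_cm3 = ds$volume_change_cm3,
        volume_change_pct = ds$volume_change_pct,
        com_shift_scalar_mm = ds$com_shift_scalar_mm,
        volume_change_soft_pct = 100 * (sum(soft_k) * vv - vol0) / vol0,
        com_shift_soft_scalar_mm = mean(abs(cs)))
    }
  }
  structure(do.call(rbind, rows), class = c("traversal_result", "data.frame"))
}

#' Leave-one-out nearest-neighbour label agreement
#'
#' Fraction of tail samples whose nearest neighbour (Euclidean, excluding
#' self) carries the same small/large label; approximately 0.5 for labels
#' unrelated to the latent geometry.
#'
#' @param z matrix of latent vectors (rows = samples).
#' @param labels 0/1 labels, one per row of z.
#' @return agreement fraction in \[0, 1\].
#' @export
nn_label_agreement <- function(z, labels) {
  z <- as.matrix(z)
  n <- nrow(z)
  stopifnot(length(labels) == n, n >= 3L)
  d2 <- as.matrix(stats::dist(z))^2
  diag(d2) <- Inf
  nn <- apply(d2, 1, which.min)
  mean(labels[nn] == labels)
}

# spectral neighbour embedding (Laplacian eigenmap) of the latent vectors
spectral_embedding <- function(z, k = 10L) {
  z <- as.matrix(z)
  n <- nrow(z)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(z))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1L)]
    sigma <- stats::median(d[i, nb]) + 1e-12
    W[i, nb] <- exp(-(d[i, nb] / sigma)^2)
  }
  W <- pmax(W, t(W))
  Dg <- rowSums(W)
  Lsym <- diag(n) - diag(1 / sqrt(Dg + 1e-12)) %*% W %*% diag(1 / sqrt(Dg + 1e-12))
  ev <- eigen(Lsym, symmetric = TRUE)
  idx <- order(ev$values)
  coords <- ev$vectors[, idx[2:3], drop = FALSE]
  colnames(coords) <- c("dim1", "dim2")
  coords
}

#' Latent-space structure: 2D embedding and tail-label separability
#'
#' Collects the posterior-mean latent vector of every planning-repeat pair
#' in the dataset, labels each pair by the magnitude of its deformation
#' statistics (prostate COM shift; per-organ absolute volume change) and
#' by static anatomy (per-organ planning volume), keeping only the tails
#' below the 10% / above the 90% percentile of each quantity. Produces a
#' spectral neighbour embedding for visualisation and, as the quantitative
#' summary, the leave-one-out nearest-neighbour label agreement per
#' labelling.
#'
#' @param model a trained `motion_model`.
#' @param dataset list of patient cases (>= 10 pairs in total).
#' @param lower,upper tail percentiles (defaults 0.1 / 0.9).
#' @param knn neighbourhood size of the embedding graph.
#' @return list of class `latent_structure_report`: `latents`, `pair_info`,
#'   `agreement` (data.frame: labelling, type, agreement, n_tail),
#'   `embedding` (2D coordinates), `tails` (per labelling: index + label).
#' @export
latent_structure_report <- function(model, dataset, lower = 0.1, upper = 0.9,
                                    knn = 10L) {
  pairs <- dataset_pairs(dataset)
  if (length(pairs) < 10L)
    stop("latent_structure_report: need at least 10 planning-repeat pairs for percentile labelling")
  zs <- matrix(0, length(pairs), model$network$N)
  info <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    q <- inference_forward(model, p$x, p$sx, p$y, p$sy)
    zs[i, ] <- q$mean
    ds_p <- deformation_stats(p$sx, p$sy, "prostate")
    ds_b <- deformation_stats(p$sx, p$sy, "bladder")
    ds_r <- deformation_stats(p$sx, p$sy, "rectum")
    info[[i]] <- data.frame(
      patient = p$patient,
      comshift_prostate = ds_p$com_shift_scalar_mm,
      dvol_prostate = abs(ds_p$volume_change_cm3),
      dvol_bladder = abs(ds_b$volume_change_cm3),
      dvol_rectum = abs(ds_r$volume_change_cm3),
      size_prostate = organ_volume(organ_mask(p$sx, "prostate"), p$sx$grid),
      size_bladder = organ_volume(organ_mask(p$sx, "bladder"), p$sx$grid),
      size_rectum = organ_volume(organ_mask(p$sx, "rectum"), p$sx$grid))
  }
  info <- do.call(rbind, info)
  labellings <- c(comshift_prostate = "deformation",
                  dvol_prostate = "deformation",
                  dvol_bladder = "deformation", dvol_rectum = "deformation",
                  size_prostate = "size", size_bladder = "size",
                  size_rectum = "size")
  agreement <- list()
  tails <- list()
  for (nm in names(labellings)) {
    vals <- info[[nm]]
    qs <- stats::quantile(vals, c(lower, upper), type = 8)
    idx <- which(vals <= qs[1] | vals >= qs[2])
    lab <- as.integer(vals[idx] >= qs[2])
    ag <- if (length(idx) >= 3L && length(unique(lab)) == 2L)
      nn_label_agreement(zs[idx, , drop = FALSE], lab) else NA_real_
    agreement[[nm]] <- data.frame(labelling = nm, type = labellings[[nm]],
                                  agreement = ag, n_tail = length(idx))
    tails[[nm]] <- list(index = idx, label = lab)
  }
  structure(list(latents = zs, pair_info = info,
                 agreement = do.call(rbind, agreement),
                 embedding = spectral_embedding(zs, knn), tails = tails),
            class = "latent_structure_report")
}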