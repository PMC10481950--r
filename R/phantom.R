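#' Pelvic phantom configuration
#'
#' Geometry and intensity model of the synthetic planning anatomy: a
#' spherical prostate with seminal-vesicle lobe superior-posterior to it,
#' a larger bladder anterior-superior, and a rectal tube running
#' cranio-caudally posterior to the prostate. Organs are placed at fixed
#' relative positions (with a small per-patient jitter) and sized by
#' per-patient draws from the configured ranges; overlaps are resolved by
#' precedence (prostate > vesicles > bladder > rectum) so labels never
#' overlap. Intensities are tissue plateaus plus smooth texture noise in
#' \[0, 1\]; the rectum interior is masked to `rectum_mask_value`,
#' emulating the clinical practice of overriding stochastic rectal filling
#' with a fixed low density.
#'
#' @param grid a [grid_spec()]; default 32x32x24 voxels at 2 mm (use
#'   64x64x48 to mirror a clinical crop).
#' @param prostate_radius_mm,bladder_radius_mm,rectum_radius_mm min/max of
#'   the uniform per-patient radius draws, mm.
#' @param vesicle_axes_mm ellipsoid semi-axes of the vesicle lobe, mm.
#' @param intensity named tissue plateau levels in \[0, 1\].
#' @param texture_sd standard deviation of the smooth texture noise.
#' @param rectum_mask_value intensity assigned to the rectum interior
#'   (default 0, the minimum of the normalised range).
#' @param center_jitter_vox uniform per-patient centre jitter, voxels.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid = grid_spec(c(32L, 32L, 24L)),
                           prostate_radius_mm = c(9, 11),
                           bladder_radius_mm = c(10, 12),
                           rectum_radius_mm = c(5, 8),
                           vesicle_axes_mm = c(7, 3.5, 4.5),
                           intensity = c(background = 0.45, prostate = 0.60,
                                         vesicles = 0.52, bladder = 0.30),
                           texture_sd = 0.04,
                           rectum_mask_value = 0,
                           center_jitter_vox = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  if (any(intensity < 0) || any(intensity > 1) ||
      rectum_mask_value < 0 || rectum_mask_value > 1)
    stop("phantom_config: intensity levels must lie in [0, 1]")
  structure(list(grid = grid, prostate_radius_mm = prostate_radius_mm,
                 bladder_radius_mm = bladder_radius_mm,
                 rectum_radius_mm = rectum_radius_mm,
                 vesicle_axes_mm = vesicle_axes_mm, intensity = intensity,
                 texture_sd = texture_sd,
                 rectum_mask_value = rectum_mask_value,
                 center_jitter_vox = center_jitter_vox),
            class = "phantom_config")
}

# 0-based voxel coordinate arrays of a grid
coord_arrays <- function(shape) {
  list(I = array(rep(0:(shape[1] - 1), times = shape[2] * shape[3]), shape),
       J = array(rep(rep(0:(shape[2] - 1), each = shape[1]), shape[3]), shape),
       K = array(rep(0:(shape[3] - 1), each = shape[1] * shape[2]), shape))
}

# weight-averaged centre of mass of a non-negative 3D weight array, mm.
# For soft (trilinearly warped) one-hot channels this is continuous in the
# displacement, unlike the argmax-mask COM which jumps in voxel steps when
# a whole boundary face crosses the 0.5 threshold together.
weighted_com <- function(w, grid) {
  s <- sum(w)
  if (s <= 0) stop("weighted_com: empty weight array")
  co <- coord_arrays(dim(w))
  grid$origin + c(sum(co$I * w), sum(co$J * w), sum(co$K * w)) / s * grid$spacing
}

# approximate Gaussian smoothing by three passes of a width-3 box filter
smooth3 <- function(a, passes = 3L) {
  d <- as.integer(dim(a))
  for (i in seq_len(passes)) a <- cpp_boxsum(a, d, 3L) / 27
  a
}

#' Generate one planning phantom
#'
#' Deterministic per seed. Returns the planning image, label volume and a
#' `meta` list with the drawn centres (voxel coordinates) and sizes.
#'
#' @param cfg a [phantom_config()].
#' @param seed integer seed.
#' @return list with `image` ([image_volume()]), `labels`
#'   ([label_volume()]) and `meta`.
#' @export
generate_phantom <- function(cfg = phantom_config(), seed = 1L) {
  with_seed(seed, {
    sh <- cfg$grid$shape
    sp <- cfg$grid$spacing
    jit <- function() runif(3, -cfg$center_jitter_vox, cfg$center_jitter_vox)
    c_p <- sh * c(0.50, 0.55, 0.42) + jit()
    c_v <- sh * c(0.50, 0.68, 0.64) + jit()
    c_b <- sh * c(0.50, 0.34, 0.62) + jit()
    c_r <- c(sh[1] * 0.50, sh[2] * 0.74, sh[3] / 2) + c(jit()[1:2], 0)
    r_p <- runif(1, cfg$prostate_radius_mm[1], cfg$prostate_radius_mm[2]) / sp[1]
    r_b <- runif(1, cfg$bladder_radius_mm[1], cfg$bladder_radius_mm[2]) / sp[1]
    r_r <- runif(1, cfg$rectum_radius_mm[1], cfg$rectum_radius_mm[2]) / sp[1]
    ax_v <- cfg$vesicle_axes_mm * runif(3, 0.9, 1.1) / sp
    z_lo <- 2
    z_hi <- sh[3] - 3
    # fit check: every organ needs a >= 2-voxel margin to the grid boundary
    ext <- rbind(
      c(c_p - r_p, sh - 1 - (c_p + r_p)),
      c(c_v - ax_v, sh - 1 - (c_v + ax_v)),
      c(c_b - c(r_b, r_b, 0.8 * r_b), sh - 1 - (c_b + c(r_b, r_b, 0.8 * r_b))),
      c(c_r[1] - r_r, c_r[2] - r_r, z_lo,
        sh[1] - 1 - (c_r[1] + r_r), sh[2] - 1 - (c_r[2] + r_r), sh[3] - 1 - z_hi))
    if (any(ext < 1.5))
      stop("generate_phantom: configured organs cannot fit inside the grid with a 2-voxel margin")
    co <- coord_arrays(sh)
    ell <- function(cc, ax) ((co$I - cc[1]) / ax[1])^2 +
      ((co$J - cc[2]) / ax[2])^2 + ((co$K - cc[3]) / ax[3])^2 <= 1
    m_p <- ell(c_p, rep(r_p, 3))
    m_v <- ell(c_v, ax_v)
    m_b <- ell(c_b, c(r_b, r_b, 0.8 * r_b))
    m_r <- (((co$I - c_r[1])^2 + (co$J - c_r[2])^2) <= r_r^2) &
      co$K >= z_lo & co$K <= z_hi
    lab <- array(0L, sh)
    # precedence prostate > vesicles > bladder > rectum: later assignments win
    lab[m_r] <- 4L
    lab[m_b] <- 3L
    lab[m_v] <- 2L
    lab[m_p] <- 1L
    lv <- label_volume(lab, cfg$grid)
    tex <- array(rnorm(prod(sh)), sh)
    tex <- smooth3(tex)
    tex <- tex / stats::sd(tex) * cfg$texture_sd
    img <- array(cfg$intensity[["background"]], sh)
    img[lab == 1L] <- cfg$intensity[["prostate"]]
    img[lab == 2L] <- cfg$intensity[["vesicles"]]
    img[lab == 3L] <- cfg$intensity[["bladder"]]
    img <- smooth3(img, passes = 1L) + tex
    img[lab == 4L] <- cfg$rectum_mask_value
    img <- clamp01(img, 0, 1)
    list(image = image_volume(img, cfg$grid), labels = lv,
         meta = list(centers = list(prostate = c_p, vesicles = c_v,
                                    bladder = c_b, rectum = c_r),
                     prostate_radius_vox = r_p, bladder_radius_vox = r_b,
                     rectum_radius_vox = r_r, vesicle_axes_vox = ax_v,
                     rectum_z_vox = c(z_lo, z_hi)))
  })
}

#' Motion model configuration
#'
#' Defines the correlated, patient-specific deformation modes of the
#' synthetic population: bladder filling (fractional volume change),
#' rectum filling (fractional volume change), and a prostate translation,
#' with bladder filling pushing the prostate posterior-inferiorly and
#' rectum filling rotating it about the left-right axis. Each mode has a
#' population mean (scaled by the patient's planning organ volume, the
#' anatomy-to-motion link the encoder can learn), a between-patient sd of
#' the patient mean, and a within-patient sd; within-patient draws share a
#' common factor so bladder and rectum changes co-occur. Draws are
#' truncated at `truncate_sd` standard deviations so that the composed
#' velocity respects `v_max` (the bound keeping exponentiation
#' well-conditioned).
#'
#' @param bladder_fill,rectum_fill lists `mean_frac`, `between_sd`,
#'   `within_sd` (fractional volume change; the mean is multiplied by the
#'   patient organ volume over `ref_cm3`).
#' @param prostate_shift list `between_sd_mm`, `within_sd_mm`, `aniso`
#'   (per-axis weights; y = anterior-posterior dominates).
#' @param coupling list `bladder_to_prostate` (fraction of the bladder
#'   boundary velocity applied as prostate translation away from the
#'   bladder) and `rectum_rotation` (radians per unit log fill factor).
#' @param common_factor within-patient loading in \[0, 1) shared across
#'   modes (bladder fill co-occurring with rectum emptying).
#' @param smoothness multiplier on the spatial envelope widths, voxels.
#' @param v_max maximum allowed |velocity|, voxels (error if exceeded).
#' @param truncate_sd truncation of the normal draws, in sd units.
#' @param seed default population seed.
#' @return An object of class `motion_config`.
#' @export
motion_config <- function(bladder_fill = list(mean_frac = 0.08,
                                              between_sd = 0.05,
                                              within_sd = 0.12,
                                              ref_cm3 = 5.6),
                          rectum_fill = list(mean_frac = 0.05,
                                             between_sd = 0.05,
                                             within_sd = 0.15,
                                             ref_cm3 = 5.0),
                          prostate_shift = list(between_sd_mm = 0.5,
                                                within_sd_mm = 1.0,
                                                aniso = c(0.4, 1, 0.8)),
                          coupling = list(bladder_to_prostate = 0.45,
                                          rectum_rotation = 0.2),
                          common_factor = 0.6, smoothness = 1,
                          v_max = 3, truncate_sd = 2, seed = 1L) {
  if (common_factor < 0 || common_factor >= 1)
    stop("motion_config: common_factor must lie in [0, 1)")
  structure(list(bladder_fill = bladder_fill, rectum_fill = rectum_fill,
                 prostate_shift = prostate_shift, coupling = coupling,
                 common_factor = common_factor, smoothness = smoothness,
                 v_max = v_max, truncate_sd = truncate_sd,
                 seed = as.integer(seed)),
            class = "motion_config")
}

rtnorm <- function(n, sd, cap) {
  if (sd == 0) return(numeric(n))
  pmin(pmax(rnorm(n, sd = sd), -cap * sd), cap * sd)
}

#' Patient-specific motion law
#'
#' Draws the patient-level mean amplitudes once (from the between-patient
#' distribution) and records the within-patient spread. The bladder and
#' rectum mode means scale with the patient's planning organ volumes, so
#' motion statistics are predictable from the planning anatomy.
#'
#' @param motion_cfg a [motion_config()].
#' @param patient_seed integer seed of the patient draw.
#' @param planning planning [label_volume()] containing bladder and rectum.
#' @return list of class `motion_law` with patient mean amplitudes and
#'   within-patient sds.
#' @export
sample_patient_motion_law <- function(motion_cfg, patient_seed, planning) {
  stopifnot(inherits(planning, "label_volume"))
  for (org in c("bladder", "rectum"))
    if (!any(organ_mask(planning, org)))
      stop(sprintf("sample_patient_motion_law: organ '%s' missing from the planning labels", org))
  vb <- organ_volume(organ_mask(planning, "bladder"), planning$grid)
  vr <- organ_volume(organ_mask(planning, "rectum"), planning$grid)
  mc <- motion_cfg
  cap <- mc$truncate_sd
  with_seed(patient_seed, {
    mu_b <- mc$bladder_fill$mean_frac * vb / mc$bladder_fill$ref_cm3 +
      rtnorm(1, mc$bladder_fill$between_sd, cap)
    mu_r <- mc$rectum_fill$mean_frac * vr / mc$rectum_fill$ref_cm3 +
      rtnorm(1, mc$rectum_fill$between_sd, cap)
    mu_s <- rtnorm(3, 1, cap) * mc$prostate_shift$between_sd_mm *
      mc$prostate_shift$aniso
    structure(list(mu_bladder = mu_b, mu_rectum = mu_r, mu_shift_mm = mu_s,
                   within = list(bladder = mc$bladder_fill$within_sd,
                                 rectum = mc$rectum_fill$within_sd,
                                 shift_mm = mc$prostate_shift$within_sd_mm),
                   rho = mc$common_factor,
                   aniso = mc$prostate_shift$aniso,
                   truncate_sd = mc$truncate_sd,
                   planning_bladder_cm3 = vb, planning_rectum_cm3 = vr),
              class = "motion_law")
  })
}

#' Draw repeat amplitudes from a patient law
#'
#' Within-patient draws share a common factor (`rho`): a fuller bladder
#' tends to co-occur with an emptier rectum and a posterior-inferior
#' prostate push, the correlated-movement structure the model is meant to
#' recover.
#'
#' @param law a `motion_law` from [sample_patient_motion_law()].
#' @param n number of repeats.
#' @param seed integer seed.
#' @return data.frame with one row per repeat: `bladder_frac`,
#'   `rectum_frac`, `shift_x_mm`, `shift_y_mm`, `shift_z_mm`.
#' @export
draw_repeat_amplitudes <- function(law, n, seed = 1L) {
  rho <- law$rho
  res <- sqrt(1 - rho^2)
  cap <- law$truncate_sd
  dir_c <- c(0, 0.7, -0.7)
  with_seed(seed, {
    eta0 <- rtnorm(n, 1, cap)
    b <- law$mu_bladder + law$within$bladder *
      (rho * eta0 + res * rtnorm(n, 1, cap))
    r <- law$mu_rectum - law$within$rectum *
      (rho * eta0 - res * rtnorm(n, 1, cap))
    sh <- matrix(0, n, 3)
    for (a in 1:3)
      sh[, a] <- law$mu_shift_mm[a] + law$within$shift_mm * law$aniso[a] *
        (rho * eta0 * dir_c[a] + res * rtnorm(n, 1, cap))
    data.frame(bladder_frac = b, rectum_frac = r,
               shift_x_mm = sh[, 1], shift_y_mm = sh[, 2], shift_z_mm = sh[, 3])
  })
}

# geometry of the deformation modes, derived from the planning labels
mode_geometry <- function(labels) {
  g <- labels$grid
  to_vox <- function(com) (com - g$origin) / g$spacing
  m_b <- organ_mask(labels, "bladder")
  m_r <- organ_mask(labels, "rectum")
  m_p <- organ_mask(labels, "prostate")
  c_b <- to_vox(center_of_mass(m_b, g))
  c_p <- to_vox(center_of_mass(m_p, g))
  c_r <- to_vox(center_of_mass(m_r, g))
  R_b <- (3 * sum(m_b) / (4 * pi))^(1 / 3)
  r_p <- (3 * sum(m_p) / (4 * pi))^(1 / 3)
  kz <- range(which(apply(m_r, 3, any))) - 1L
  Lz <- diff(kz) + 1L
  R_r <- sqrt(sum(m_r) / (pi * Lz))
  list(c_b = c_b, c_p = c_p, c_r = c_r, R_b = R_b, r_p = r_p, R_r = R_r,
       z_range = kz, m_p = m_p)
}

# fixed spatial basis fields of the deformation modes (voxel units);
# the truth velocity is a coefficient-weighted sum of these
velocity_basis <- function(labels, mcfg) {
  geo <- mode_geometry(labels)
  sh <- labels$grid$shape
  co <- coord_arrays(sh)
  sm <- mcfg$smoothness
  radial_profile <- function(d, R, lin, tail) {
    ifelse(d <= lin * R, d / R,
           lin * exp(-((d - lin * R) / (tail * R * sm))^2 / 2))
  }
  # bladder: radial, linear (pure dilation) out to 1.2 R then decaying
  db <- sqrt((co$I - geo$c_b[1])^2 + (co$J - geo$c_b[2])^2 +
               (co$K - geo$c_b[3])^2)
  pb <- radial_profile(db, geo$R_b, 1.2, 0.4) / pmax(db, 1e-6)
  B_bl <- array(0, c(sh, 3))
  B_bl[, , , 1] <- pb * (co$I - geo$c_b[1])
  B_bl[, , , 2] <- pb * (co$J - geo$c_b[2])
  B_bl[, , , 3] <- pb * (co$K - geo$c_b[3])
  # rectum: radial in the axial plane with a taper at the tube ends
  dr <- sqrt((co$I - geo$c_r[1])^2 + (co$J - geo$c_r[2])^2)
  zmid <- mean(geo$z_range)
  zhalf <- diff(geo$z_range) / 2
  tz <- exp(-pmax(abs(co$K - zmid) - (zhalf - 2), 0)^2 / (2 * 2^2))
  pr <- radial_profile(dr, geo$R_r, 1.4, 0.7) * tz / pmax(dr, 1e-6)
  B_re <- array(0, c(sh, 3))
  B_re[, , , 1] <- pr * (co$I - geo$c_r[1])
  B_re[, , , 2] <- pr * (co$J - geo$c_r[2])
  # prostate envelope: translation (3 bases) and left-right-axis rotation
  dp2 <- (co$I - geo$c_p[1])^2 + (co$J - geo$c_p[2])^2 + (co$K - geo$c_p[3])^2
  env <- exp(-dp2 / (2 * (1.6 * geo$r_p * sm)^2))
  B_tx <- array(0, c(sh, 3)); B_tx[, , , 1] <- env
  B_ty <- array(0, c(sh, 3)); B_ty[, , , 2] <- env
  B_tz <- array(0, c(sh, 3)); B_tz[, , , 3] <- env
  B_ro <- array(0, c(sh, 3))
  B_ro[, , , 2] <- -env * (co$K - geo$c_p[3])
  B_ro[, , , 3] <- env * (co$J - geo$c_p[2])
  list(bases = list(bladder = B_bl, rectum = B_re, tx = B_tx, ty = B_ty,
                    tz = B_tz, rot = B_ro),
       geometry = geo)
}

# mode coefficients for one amplitude row. Volume changes are commanded
# exactly in velocity space: a radial field that is linear inside radius R
# with boundary velocity R*log(F)/3 (sphere) or R*log(F)/2 (tube)
# exponentiates to a dilation with volume factor exactly F.
basis_coefficients <- function(amp, basis, mcfg, spacing) {
  geo <- basis$geometry
  a_b <- geo$R_b * log1p(amp$bladder_frac) / 3
  a_r <- geo$R_r * log1p(amp$rectum_frac) / 2
  dir_bp <- as.numeric(geo$c_p - geo$c_b)
  dir_bp <- dir_bp / sqrt(sum(dir_bp^2))
  t_vox <- as.numeric(c(amp$shift_x_mm, amp$shift_y_mm, amp$shift_z_mm)) /
    spacing + mcfg$coupling$bladder_to_prostate * a_b * dir_bp
  theta <- mcfg$coupling$rectum_rotation * log1p(amp$rectum_frac)
  c(bladder = a_b, rectum = a_r, tx = t_vox[1], ty = t_vox[2],
    tz = t_vox[3], rot = theta)
}

truth_velocity <- function(amp, basis, mcfg, grid) {
  cf <- basis_coefficients(amp, basis, mcfg, grid$spacing)
  v <- 0
  for (nm in names(basis$bases)) v <- v + cf[[nm]] * basis$bases[[nm]]
  vmax <- max(abs(v))
  if (vmax > mcfg$v_max)
    stop(sprintf("truth velocity |v| = %.2f voxels exceeds the configured bound %.1f",
                 vmax, mcfg$v_max))
  vector_field(v, grid, "velocity")
}

#' Generate one repeat anatomy from a planning phantom
#'
#' Builds the analytic mode velocity field for the given amplitudes,
#' exponentiates it (so the ground truth is diffeomorphic with zero
#' folding by construction) and warps the planning image and labels. The
#' repeat labels ARE the warped planning labels, so the model-facing task
#' is exactly the recovery of the warp.
#'
#' @param planning list with `image` and `labels` (see [generate_phantom()]).
#' @param amplitudes one-row data.frame from [draw_repeat_amplitudes()].
#' @param motion_cfg a [motion_config()].
#' @param seed unused (generation is deterministic given the amplitudes);
#'   kept for interface stability.
#' @param dcfg a [diffeo_config()].
#' @param basis optional precomputed [velocity_basis] (internal reuse).
#' @return list with `image`, `labels` and `truth` (fields `velocity`,
#'   `displacement_fwd` = exp(v) mapping planning points to repeat
#'   positions, `displacement_pull` = exp(-v) used for the image warp, and
#'   `amplitudes`).
#' @export
generate_repeat <- function(planning, amplitudes, motion_cfg = motion_config(),
                            seed = NULL, dcfg = diffeo_config(),
                            basis = NULL) {
  stopifnot(all(is.finite(unlist(amplitudes))))
  grid <- planning$labels$grid
  if (is.null(basis)) basis <- velocity_basis(planning$labels, motion_cfg)
  v <- truth_velocity(amplitudes, basis, motion_cfg, grid)
  u_fwd <- exponentiate(v, dcfg)
  u_pull <- invert_velocity(v, dcfg)
  img <- warp_image(planning$image, u_pull)
  wl <- warp_labels(planning$labels, u_pull, return_soft = TRUE)
  lab <- wl$labels
  rid <- match("rectum", lab$organ_names)
  img$values[lab$labels == rid] <- min(planning$image$values)
  # continuous (soft-channel) prostate COM shift of the ground truth
  pid <- match("prostate", lab$organ_names)
  com0 <- center_of_mass(organ_mask(planning$labels, "prostate"), grid)
  com1 <- weighted_com(wl$soft[, , , pid + 1L], grid)
  list(image = img, labels = lab,
       truth = list(velocity = v, displacement_fwd = u_fwd,
                    displacement_pull = u_pull, amplitudes = amplitudes,
                    prostate_com_shift_mm = com1 - com0,
                    prostate_com_scalar_mm = mean(abs(com1 - com0))))
}

#' Generate a synthetic population of patients
#'
#' Deterministic per seed: each patient gets a phantom, a patient-specific
#' motion law (anatomy-linked), and `repeats_per_patient` repeat
#' anatomies with stored ground-truth deformations. The last `n_test`
#' patients are held out entirely as the test split.
#'
#' @param n_patients number of patients (>= 1).
#' @param repeats_per_patient repeats per patient.
#' @param phantom_cfg a [phantom_config()].
#' @param motion_cfg a [motion_config()].
#' @param seed master seed.
#' @param n_test patients held out as the test split (default 2).
#' @return list with `cases` (list of patient cases: `patient_id`,
#'   `planning`, `repeats`, `truth`, `law`, `split`) and `manifest`.
#' @export
generate_population <- function(n_patients, repeats_per_patient = 8L,
                                phantom_cfg = phantom_config(),
                                motion_cfg = motion_config(),
                                seed = 1L, n_test = 2L) {
  stopifnot(n_patients >= 1L)
  n_test <- min(n_test, max(0L, n_patients - 1L))
  cases <- vector("list", n_patients)
  man_pat <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    pseed <- seed + 1000L * i
    ph <- generate_phantom(phantom_cfg, seed = pseed)
    law <- sample_patient_motion_law(motion_cfg, pseed + 1L, ph$labels)
    amps <- draw_repeat_amplitudes(law, repeats_per_patient, seed = pseed + 2L)
    basis <- velocity_basis(ph$labels, motion_cfg)
    reps <- vector("list", repeats_per_patient)
    truths <- vector("list", repeats_per_patient)
    for (r in seq_len(repeats_per_patient)) {
      gr <- generate_repeat(ph, amps[r, ], motion_cfg, dcfg = diffeo_config(),
                            basis = basis)
      reps[[r]] <- list(image = gr$image, labels = gr$labels)
      truths[[r]] <- gr$truth
    }
    split <- if (i > n_patients - n_test) "test" else "train"
    cases[[i]] <- structure(
      list(patient_id = sprintf("P%03d", i), planning = ph, repeats = reps,
           truth = truths, law = law, basis_geometry = basis$geometry,
           split = split),
      class = "patient_case")
    man_pat[[i]] <- list(id = sprintf("P%03d", i), seed = pseed,
                         split = split,
                         bladder_cm3 = law$planning_bladder_cm3,
                         rectum_cm3 = law$planning_rectum_cm3,
                         amplitudes = lapply(seq_len(nrow(amps)),
                                             function(r) as.list(amps[r, ])))
  }
  manifest <- list(tool = "organmotion", seed = seed,
                   n_patients = n_patients,
                   repeats_per_patient = repeats_per_patient,
                   grid = list(shape = phantom_cfg$grid$shape,
                               spacing = phantom_cfg$grid$spacing,
                               origin = phantom_cfg$grid$origin),
                   n_test = n_test, patients = man_pat)
  structure(list(cases = cases, manifest = manifest),
            class = "synthetic_population")
}

#' Draws from a patient's ground-truth centre-of-mass shift law
#'
#' Reference distribution of the prostate COM-shift scalar implied by a
#' patient's motion law, computed without touching the label-warping,
#' argmax or mask-measurement pipeline: fresh amplitudes are drawn from
#' the patient law and mapped to the mean forward displacement of the
#' prostate voxels. With `method = "exponential"` (default) the mode
#' velocity is exponentiated and averaged over the prostate mask; with
#' `method = "linear"` the closed-form first-order response (mean mode
#' basis over the prostate) is used instead, which is cheaper but ignores
#' the second-order transport term of the exponential map.
#'
#' @param case a patient case from [generate_population()].
#' @param motion_cfg the [motion_config()] used for the population.
#' @param n number of draws.
#' @param seed integer seed.
#' @param method `"exponential"` or `"linear"`.
#' @param dcfg a [diffeo_config()] (exponential method only).
#' @return numeric vector of n COM-shift scalars, mm.
#' @export
com_shift_law_draws <- function(case, motion_cfg, n = 100L, seed = 1L,
                                method = c("exponential", "linear"),
                                dcfg = diffeo_config()) {
  method <- match.arg(method)
  basis <- velocity_basis(case$planning$labels, motion_cfg)
  m_p <- basis$geometry$m_p
  amps <- draw_repeat_amplitudes(case$law, n, seed = seed)
  grid <- case$planning$labels$grid
  sp <- grid$spacing
  out <- numeric(n)
  if (method == "linear") {
    resp <- sapply(basis$bases, function(b)
      c(mean(b[, , , 1][m_p]), mean(b[, , , 2][m_p]), mean(b[, , , 3][m_p])))
    for (i in seq_len(n)) {
      cf <- basis_coefficients(amps[i, ], basis, motion_cfg, sp)
      dcom_vox <- as.numeric(resp %*% cf[colnames(resp)])
      out[i] <- mean(abs(dcom_vox * sp))
    }
  } else {
    for (i in seq_len(n)) {
      v <- truth_velocity(amps[i, ], basis, motion_cfg, grid)
      u <- exp_fwd(v$vectors, dcfg$squaring_steps)
      dcom_vox <- c(mean(u[, , , 1][m_p]), mean(u[, , , 2][m_p]),
                    mean(u[, , , 3][m_p]))
      out[i] <- mean(abs(dcom_vox * sp))
    }
  }
  out
}
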