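test_that("phantom generation is deterministic with four disjoint organs", {
  cfg <- phantom_config()
  a <- generate_phantom(cfg, seed = 7)
  b <- generate_phantom(cfg, seed = 7)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$labels$labels, b$labels$labels)
  for (org in a$labels$organ_names)
    expect_gt(sum(organ_mask(a$labels, org)), 0)
  # disjoint by construction: one integer label per voxel
  expect_setequal(unique(as.vector(a$labels$labels)), 0:4)
  expect_gte(min(a$image$values), 0)
  expect_lte(max(a$image$values), 1)
})

test_that("prostate volume matches the drawn radius within 5%", {
  for (seed in c(3, 17, 91)) {
    ph <- generate_phantom(phantom_config(), seed = seed)
    r_mm <- ph$meta$prostate_radius_vox * ph$labels$grid$spacing[1]
    analytic <- 4 / 3 * pi * r_mm^3 / 1000
    measured <- organ_volume(organ_mask(ph$labels, "prostate"), ph$labels$grid)
    expect_lt(abs(measured - analytic) / analytic, 0.05)
  }
})

test_that("the rectum interior carries the configured mask intensity", {
  ph <- generate_phantom(phantom_config(), seed = 5)
  expect_equal(max(ph$image$values[organ_mask(ph$labels, "rectum")]), 0)
})

test_that("the patient motion law is anatomy-linked and patient-reproducible", {
  mc <- motion_config()
  big <- generate_phantom(phantom_config(bladder_radius_mm = c(11.8, 12)), 4)
  small <- generate_phantom(phantom_config(bladder_radius_mm = c(10, 10.2)), 4)
  law_big <- sample_patient_motion_law(mc, 99, big$labels)
  law_small <- sample_patient_motion_law(mc, 99, small$labels)
  expect_gt(law_big$mu_bladder, law_small$mu_bladder)
  expect_identical(law_big$mu_shift_mm,
                   sample_patient_motion_law(mc, 99, big$labels)$mu_shift_mm)
  nolabels <- label_volume(array(0L, big$labels$grid$shape), big$labels$grid)
  expect_error(sample_patient_motion_law(mc, 1, nolabels), "bladder")
})

test_that("zero within-patient spread gives identical repeat amplitudes", {
  mc <- motion_config(bladder_fill = list(mean_frac = 0.08, between_sd = 0.05,
                                          within_sd = 0, ref_cm3 = 5.6),
                      rectum_fill = list(mean_frac = 0.05, between_sd = 0.05,
                                         within_sd = 0, ref_cm3 = 5),
                      prostate_shift = list(between_sd_mm = 0.5,
                                            within_sd_mm = 0,
                                            aniso = c(0.4, 1, 0.8)))
  ph <- generate_phantom(phantom_config(), seed = 2)
  law <- sample_patient_motion_law(mc, 5, ph$labels)
  amps <- draw_repeat_amplitudes(law, 6, seed = 8)
  expect_equal(max(apply(amps, 2, function(x) diff(range(x)))), 0)
})

test_that("between-patient spread of the law matches its configuration", {
  mc <- motion_config()
  ph <- generate_phantom(phantom_config(), seed = 31)
  mus <- vapply(1:100, function(i)
    sample_patient_motion_law(mc, 5000 + i, ph$labels)$mu_rectum, numeric(1))
  # truncation at 2 sd shrinks the sd of a normal to ~0.88 sigma
  expect_lt(abs(sd(mus) - 0.88 * mc$rectum_fill$between_sd),
            0.2 * mc$rectum_fill$between_sd)
})

test_that("zero amplitudes reproduce the planning anatomy with an identity truth field", {
  ph <- generate_phantom(phantom_config(), seed = 6)
  amp <- data.frame(bladder_frac = 0, rectum_frac = 0, shift_x_mm = 0,
                    shift_y_mm = 0, shift_z_mm = 0)
  gr <- generate_repeat(ph, amp, motion_config())
  expect_identical(gr$labels$labels, ph$labels$labels)
  expect_equal(max(abs(gr$truth$displacement_fwd$vectors)), 0)
  expect_equal(max(abs(gr$image$values - ph$image$values)), 0)
})

test_that("a commanded bladder filling is realised within 4%", {
  # a +20% fill moves the bladder boundary by only ~0.3 voxels at this
  # resolution, which the argmax label map cannot resolve (the 0.5-level
  # of the interpolated indicator is lattice-locked below half a voxel);
  # the realised change is measured on the continuous soft channels
  ph <- generate_phantom(phantom_config(), seed = 9)
  amp <- data.frame(bladder_frac = 0.2, rectum_frac = 0, shift_x_mm = 0,
                    shift_y_mm = 0, shift_z_mm = 0)
  gr <- generate_repeat(ph, amp, motion_config())
  wl <- warp_labels(ph$labels, gr$truth$displacement_pull, return_soft = TRUE)
  k <- match("bladder", ph$labels$organ_names)
  v0 <- sum(organ_mask(ph$labels, "bladder"))
  soft_dv <- 100 * (sum(wl$soft[, , , k + 1]) - v0) / v0
  expect_lt(abs(soft_dv - 20), 4)
  # the analytic forward map realises the expansion exactly: its mean
  # Jacobian determinant over the bladder is the commanded factor
  det_mean <- mean(jacobian_determinant(gr$truth$displacement_fwd)[
    organ_mask(ph$labels, "bladder")])
  expect_lt(abs(det_mean - 1.2), 0.03)
})

test_that("oversized amplitudes are rejected by the velocity bound", {
  ph <- generate_phantom(phantom_config(), seed = 10)
  amp <- data.frame(bladder_frac = 6, rectum_frac = 0, shift_x_mm = 9,
                    shift_y_mm = -9, shift_z_mm = 9)
  expect_error(generate_repeat(ph, amp, motion_config()), "exceeds")
})

test_that("population generation is deterministic with the commanded layout", {
  pop1 <- generate_population(3, 4, seed = 21, n_test = 1)
  pop2 <- generate_population(3, 4, seed = 21, n_test = 1)
  expect_equal(length(pop1$cases), 3)
  expect_equal(sum(vapply(pop1$cases, function(cs) length(cs$repeats),
                          integer(1))), 12)
  expect_identical(jsonlite::toJSON(pop1$manifest, auto_unbox = TRUE, digits = NA),
                   jsonlite::toJSON(pop2$manifest, auto_unbox = TRUE, digits = NA))
  expect_identical(vapply(pop1$cases, `[[`, character(1), "split"),
                   c("train", "train", "test"))
  # truths and repeats correspond one to one
  expect_equal(length(pop1$cases[[1]]$truth), 4)
})

test_that("every synthetic ground-truth deformation is fold-free", {
  pop <- generate_population(3, 3, seed = 33, n_test = 1)
  for (cs in pop$cases) for (tr in cs$truth) {
    expect_equal(folding_fraction(tr$displacement_fwd), 0)
    expect_equal(folding_fraction(tr$displacement_pull), 0)
  }
})

test_that("warped planning labels are the stored repeat labels by construction", {
  pop <- generate_population(2, 2, seed = 44, n_test = 1)
  cs <- pop$cases[[1]]
  w <- warp_labels(cs$planning$labels, cs$truth[[1]]$displacement_pull)
  expect_identical(w$labels, cs$repeats[[1]]$labels$labels)
  for (org in cs$planning$labels$organ_names)
    expect_equal(dice_score(organ_mask(w, org),
                            organ_mask(cs$repeats[[1]]$labels, org)), 1)
})

test_that("pooled ground-truth COM-shift scalars follow the patient laws", {
  pop <- bench_population()
  mc <- motion_config()
  meas <- unlist(lapply(pop$cases, function(cs)
    vapply(cs$truth, `[[`, numeric(1), "prostate_com_scalar_mm")))
  laws <- unlist(lapply(seq_along(pop$cases), function(i)
    com_shift_law_draws(pop$cases[[i]], mc, n = 100, seed = 700 + i)))
  ks <- suppressWarnings(stats::ks.test(meas, laws))
  expect_gt(ks$p.value, 0.01)
})
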