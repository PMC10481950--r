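sphere_mask <- function(g, ctr, r) {
  co <- organmotion:::coord_arrays(g$shape)
  (co$I - ctr[1])^2 + (co$J - ctr[2])^2 + (co$K - ctr[3])^2 <= r^2
}

test_that("surface points lie on the mask boundary and are seed-reproducible", {
  g <- grid_spec(c(24, 24, 24), spacing = c(1, 1, 1))
  m <- sphere_mask(g, c(11.5, 11.5, 11.5), 8)
  pts <- extract_surface_points(m, g, L = 500, seed = 3)
  expect_equal(nrow(pts$points), 500)
  d <- sqrt(rowSums(sweep(pts$points, 2, c(11.5, 11.5, 11.5))^2))
  expect_lt(max(abs(d - 8)), sqrt(3) / 2 * g$spacing[1] + 0.5)
  pts2 <- extract_surface_points(m, g, L = 500, seed = 3)
  expect_identical(pts$points, pts2$points)
  # L larger than the face count still yields L points (with replacement)
  tiny <- array(FALSE, g$shape); tiny[5, 5, 5] <- TRUE
  expect_equal(nrow(extract_surface_points(tiny, g, L = 40, seed = 1)$points), 40)
  expect_error(extract_surface_points(array(FALSE, g$shape), g), "empty")
})

test_that("surface error recovers pure translations and needs correspondences", {
  g <- grid_spec(c(16, 16, 16), spacing = c(2, 2, 2))
  m <- sphere_mask(g, c(7.5, 7.5, 7.5), 5)
  pts <- extract_surface_points(m, g, L = 300, seed = 2)
  moved <- structure(list(points = sweep(pts$points, 2, c(-3, 0, 0)),
                          correspondence_ids = pts$correspondence_ids),
                     class = "surface_point_set")
  se <- surface_error(pts, moved, NULL, g)
  expect_equal(se$mean, 3)
  expect_equal(se$sd, 0)
  bad <- structure(list(points = moved$points, correspondence_ids = NULL),
                   class = "surface_point_set")
  expect_error(surface_error(pts, bad, NULL, g), "nearest")
})

test_that("warping surface points by the truth field reproduces the correspondences", {
  pop <- generate_population(1, 1, seed = 77, n_test = 0)
  cs <- pop$cases[[1]]
  sp <- organmotion:::truth_surface_pair(cs, 1, "prostate", L = 300, seed = 4)
  se <- surface_error(sp$planning, sp$repeat_pts,
                      cs$truth[[1]]$displacement_fwd, cs$planning$image$grid)
  expect_lt(se$mean, 0.05)
  # identity baseline error equals the mean truth displacement magnitude
  se_id <- surface_error(sp$planning, sp$repeat_pts, NULL,
                         cs$planning$image$grid)
  expect_gt(se_id$mean, se$mean)
})

test_that("nearest-point distance bounds the corresponding-point error from below", {
  g <- grid_spec(c(16, 16, 16), spacing = c(2, 2, 2))
  m <- sphere_mask(g, c(7.5, 7.5, 7.5), 5)
  a <- extract_surface_points(m, g, L = 200, seed = 5)
  b <- structure(list(points = sweep(a$points, 2, c(-2, 0, 0)),
                      correspondence_ids = a$correspondence_ids),
                 class = "surface_point_set")
  nn <- surface_distance_nearest(a, b)
  ce <- surface_error(a, b, NULL, g)
  expect_lte(nn$mean, ce$mean + 1e-9)
})

test_that("the reconstruction report's no-model row scores the planning scan itself", {
  pop <- generate_population(1, 2, seed = 55, n_test = 0)
  rep_tab <- reconstruction_report(list("0" = NULL), pop$cases, L = 200, seed = 1)
  cs <- pop$cases[[1]]
  for (ri in 1:2) {
    row <- rep_tab$per_pair[rep_tab$per_pair$rep == ri, ]
    expect_equal(row$cc,
                 local_cross_correlation(cs$planning$image,
                                         cs$repeats[[ri]]$image))
    expect_equal(row$dice_prostate,
                 dice_score(organ_mask(cs$planning$labels, "prostate"),
                            organ_mask(cs$repeats[[ri]]$labels, "prostate")))
    expect_true(all(row[, grep("dice", names(row))] >= 0 &
                      row[, grep("dice", names(row))] <= 1))
  }
  expect_true(all(rep_tab$per_pair$cc >= 0 & rep_tab$per_pair$cc <= 1))
})

test_that("latent traversal returns the requested offsets with a zero reference row", {
  g <- grid_spec(c(32L, 32L, 24L))
  ph <- generate_phantom(phantom_config(grid = g), seed = 12)
  model <- init_model_parameters(
    network_config(N = 4, conv_channels = 4, gn_groups = 2,
                   gen_head_channels = c(4, 3)), g, seed = 2)
  tr <- latent_traversal(model, ph$image, ph$labels, variable = 2,
                         offsets = c(-1, 0, 1))
  expect_equal(nrow(tr), 3 * 4)
  expect_setequal(unique(tr$offset), c(-1, 0, 1))
  expect_error(latent_traversal(model, ph$image, ph$labels, variable = 9),
               "1..4")
  # the reference row equals the prior-mean anatomy's stats
  enc <- encoder_forward(model, ph$image, ph$labels)
  v <- generator_forward(model, enc$r, enc$prior$mean)
  wl <- warp_labels(ph$labels, exponentiate(v))
  ref <- tr[tr$offset == 0 & tr$organ == "prostate", ]
  expect_equal(ref$volume_change_cm3,
               deformation_stats(ph$labels, wl, "prostate")$volume_change_cm3)
})

test_that("nearest-neighbour agreement is calibrated at one half for random labels", {
  set.seed(8)
  z <- matrix(rnorm(60 * 4), 60, 4)
  ag <- replicate(200, nn_label_agreement(z, sample(rep(0:1, 30))))
  expect_gt(mean(ag), 0.38)
  expect_lt(mean(ag), 0.62)
  # perfectly separable labels reach agreement 1
  z2 <- rbind(matrix(rnorm(40, 5), 10, 4), matrix(rnorm(40, -5), 10, 4))
  expect_equal(nn_label_agreement(z2, rep(c(1, 0), each = 10)), 1)
})

test_that("KS distance of a distribution against itself is zero", {
  x <- rnorm(50)
  ks <- suppressWarnings(stats::ks.test(x, x))
  expect_equal(unname(ks$statistic), 0)
})

test_that("the latent structure report needs enough pairs and labels only the tails", {
  pop <- generate_population(2, 2, seed = 66, n_test = 0)
  g <- pop$cases[[1]]$planning$labels$grid
  model <- init_model_parameters(
    network_config(N = 4, conv_channels = 4, gn_groups = 2,
                   gen_head_channels = c(4, 3)), g, seed = 3)
  expect_error(latent_structure_report(model, pop$cases), "10")
  pop2 <- generate_population(3, 4, seed = 66, n_test = 0)
  rep2 <- latent_structure_report(model, pop2$cases)
  expect_equal(nrow(rep2$latents), 12)
  expect_equal(dim(rep2$embedding), c(12, 2))
  for (nm in names(rep2$tails)) {
    n_tail <- length(rep2$tails[[nm]]$index)
    expect_lte(n_tail, 12)
    expect_gte(n_tail, 2)  # both tails non-empty
  }
  expect_setequal(unique(rep2$agreement$type), c("deformation", "size"))
})
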