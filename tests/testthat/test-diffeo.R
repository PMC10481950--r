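test_that("exponentiation handles the trivial and constant cases", {
  g <- test_grid(c(12, 12, 12))
  v0 <- vector_field(array(0, c(g$shape, 3)), g, "velocity")
  u0 <- exponentiate(v0)
  expect_equal(max(abs(u0$vectors)), 0)
  expect_identical(u0$kind, "displacement")
  expect_error(exponentiate(u0), "velocity")

  vc <- array(0, c(g$shape, 3))
  vc[, , , 1] <- 0.7; vc[, , , 2] <- -0.4; vc[, , , 3] <- 0.2
  u <- exponentiate(vector_field(vc, g, "velocity"))
  int <- interior_mask(g$shape, 2L)
  for (c in 1:3)
    expect_lt(max(abs(u$vectors[, , , c][int] - vc[1, 1, 1, c])), 1e-6)
})

test_that("scaling and squaring matches RK4 flow integration on smooth fields", {
  for (seed in 1:3) {
    v <- smooth_random_velocity(c(16, 16, 16), vmax = 2, seed = seed)
    g <- test_grid(c(16, 16, 16))
    u <- exponentiate(vector_field(v, g, "velocity"))
    u_oracle <- oracle_rk4_flow(v, steps = 128L)
    expect_lt(max(abs(u$vectors - u_oracle)), 1e-2)
  }
})

test_that("image warping follows the trilinear pull-back contract", {
  g <- test_grid(c(10, 10, 10))
  set.seed(2)
  x <- image_volume(array(runif(prod(g$shape)), g$shape), g)
  u0 <- vector_field(array(0, c(g$shape, 3)), g, "displacement")
  expect_identical(warp_image(x, u0)$values, x$values)

  u1 <- array(0, c(g$shape, 3)); u1[, , , 1] <- 1
  w1 <- warp_image(x, vector_field(u1, g, "displacement"))
  expect_equal(w1$values[1:9, , ], x$values[2:10, , ])
  expect_equal(w1$values[10, , ], x$values[10, , ])  # clamped edge repeats

  uh <- array(0, c(g$shape, 3)); uh[, , , 1] <- 0.5
  wh <- warp_image(x, vector_field(uh, g, "displacement"))
  expect_equal(wh$values[1:9, , ], (x$values[1:9, , ] + x$values[2:10, , ]) / 2)

  g2 <- test_grid(c(8, 8, 8))
  expect_error(warp_image(x, vector_field(array(0, c(g2$shape, 3)), g2,
                                          "displacement")), "grid mismatch")
})

test_that("label warping is exact under integer shifts and keeps soft partition of unity", {
  g <- test_grid(c(12, 12, 12))
  lab <- array(0L, g$shape)
  lab[4:7, 4:7, 4:7] <- 1L
  lab[8:9, 8:9, 8:9] <- 3L
  s <- label_volume(lab, g)
  u0 <- vector_field(array(0, c(g$shape, 3)), g, "displacement")
  expect_identical(warp_labels(s, u0)$labels, s$labels)

  u1 <- array(0, c(g$shape, 3)); u1[, , , 2] <- 1
  w <- warp_labels(s, vector_field(u1, g, "displacement"))
  expect_identical(w$labels[, 1:11, ], s$labels[, 2:12, ])

  v <- smooth_random_velocity(c(12, 12, 12), vmax = 1.5, seed = 5)
  u <- exponentiate(vector_field(v, g, "velocity"))
  soft <- warp_labels(s, u, return_soft = TRUE)$soft
  sums <- apply(soft, 1:3, sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
})

test_that("composition has the identity element and the semigroup property", {
  g <- test_grid(c(16, 16, 16))
  v <- smooth_random_velocity(c(16, 16, 16), vmax = 1.5, seed = 7)
  u <- exponentiate(vector_field(v, g, "velocity"))
  zero <- vector_field(array(0, c(g$shape, 3)), g, "displacement")
  expect_equal(compose_displacements(u, zero)$vectors, u$vectors)
  expect_equal(compose_displacements(zero, u)$vectors, u$vectors)

  ta <- array(0, c(g$shape, 3)); ta[, , , 1] <- 1
  tb <- array(0, c(g$shape, 3)); tb[, , , 3] <- 2
  comp <- compose_displacements(vector_field(ta, g, "displacement"),
                                vector_field(tb, g, "displacement"))
  int <- interior_mask(g$shape, 3L)
  expect_lt(max(abs(comp$vectors[, , , 1][int] - 1)), 1e-9)
  expect_lt(max(abs(comp$vectors[, , , 3][int] - 2)), 1e-9)

  uh <- exponentiate(vector_field(v / 2, g, "velocity"))
  u2 <- compose_displacements(uh, uh)
  expect_lt(max(abs(u2$vectors - u$vectors)), 1e-2)
})

test_that("inversion undoes the forward transformation", {
  g <- test_grid(c(16, 16, 16))
  v0 <- vector_field(array(0, c(g$shape, 3)), g, "velocity")
  expect_equal(max(abs(invert_velocity(v0)$vectors)), 0)

  vc <- array(0.6, c(g$shape, 3))
  ui <- invert_velocity(vector_field(vc, g, "velocity"))
  int <- interior_mask(g$shape, 2L)
  expect_lt(max(abs(ui$vectors[, , , 1][int] + 0.6)), 1e-6)

  v <- smooth_random_velocity(c(16, 16, 16), vmax = 2, seed = 11)
  vf <- vector_field(v, g, "velocity")
  rt <- compose_displacements(exponentiate(vf), invert_velocity(vf))
  for (c in 1:3)
    expect_lt(max(abs(rt$vectors[, , , c][int])), 5e-2)
})

test_that("jacobian determinants detect affine scaling exactly", {
  g <- test_grid(c(12, 12, 12))
  u0 <- vector_field(array(0, c(g$shape, 3)), g, "displacement")
  expect_equal(max(abs(jacobian_determinant(u0) - 1)), 0)

  co <- organmotion:::coord_arrays(g$shape)
  ua <- array(0, c(g$shape, 3))
  ua[, , , 1] <- 0.1 * co$I; ua[, , , 2] <- 0.1 * co$J; ua[, , , 3] <- 0.1 * co$K
  det <- jacobian_determinant(vector_field(ua, g, "displacement"))
  int <- interior_mask(g$shape, 1L)
  expect_lt(max(abs(det[int] - 1.1^3)), 1e-6)
})

test_that("folding is detected for a constructed overlap and absent after exponentiation", {
  g <- test_grid(c(12, 12, 12))
  u0 <- vector_field(array(0, c(g$shape, 3)), g, "displacement")
  expect_equal(folding_fraction(u0), 0)

  # swap two adjacent slabs: voxels at x-index 5 jump to 7 and vice versa
  uf <- array(0, c(g$shape, 3))
  uf[6, , , 1] <- 2; uf[7, , , 1] <- -2
  expect_gt(folding_fraction(vector_field(uf, g, "displacement")), 0)

  for (seed in 1:25) {
    v <- smooth_random_velocity(c(12, 12, 12), vmax = 2.5, seed = seed)
    u <- exponentiate(vector_field(v, g, "velocity"))
    expect_equal(folding_fraction(u), 0)
  }
})
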