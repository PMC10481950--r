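# small configuration used throughout: 2 organs, narrow towers
small_net <- function(N = 4L) {
  network_config(N = N, conv_channels = 4L, gn_groups = 2L, n_organs = 2L,
                 gen_head_channels = c(4L, 3L))
}

small_inputs <- function(g, seed = 1) {
  set.seed(seed)
  list(x = image_volume(array(runif(prod(g$shape)), g$shape), g),
       s = tiny_labels(g))
}

test_that("the encoder produces the contract feature shape at the clinical grid size", {
  g <- grid_spec(c(64L, 64L, 48L))
  set.seed(1)
  x <- image_volume(array(runif(prod(g$shape)), g$shape), g)
  lab <- array(0L, g$shape); lab[20:40, 20:40, 16:32] <- 1L
  lab[42:50, 20:30, 16:30] <- 3L
  s <- label_volume(lab, g)
  model <- init_model_parameters(network_config(N = 8), g, seed = 1)
  enc <- encoder_forward(model, x, s)
  expect_equal(dim(enc$r), c(4L, 8L, 8L, 6L))
  expect_true(all(enc$prior$variance > 0))
  expect_equal(enc$prior$N, 8L)
})

test_that("encoder and inference are deterministic with positive variances", {
  g <- grid_spec(c(16L, 16L, 16L))
  inp <- small_inputs(g)
  model <- init_model_parameters(small_net(), g, seed = 3)
  e1 <- encoder_forward(model, inp$x, inp$s)
  e2 <- encoder_forward(model, inp$x, inp$s)
  expect_identical(e1$r, e2$r)
  expect_identical(e1$prior$mean, e2$prior$mean)
  inp2 <- small_inputs(g, seed = 2)
  q1 <- inference_forward(model, inp$x, inp$s, inp2$x, inp2$s)
  q2 <- inference_forward(model, inp$x, inp$s, inp2$x, inp2$s)
  expect_identical(q1$mean, q2$mean)
  expect_true(all(q1$variance > 0) && all(is.finite(q1$variance)))
})

test_that("the coarse grid is the input grid over 8, and indivisible grids are rejected", {
  g <- grid_spec(c(32L, 32L, 24L))
  inp <- list(x = image_volume(array(0.5, g$shape), g),
              s = label_volume(array(0L, g$shape) + 0L, g,
                               organ_names = c("organA", "organB")))
  model <- init_model_parameters(small_net(), g, seed = 4)
  enc <- encoder_forward(model, inp$x, inp$s)
  expect_equal(dim(enc$r), c(4L, 4L, 4L, 3L))
  expect_error(init_model_parameters(small_net(), grid_spec(c(30L, 32L, 24L))),
               "divisible")
})

test_that("latent dimension is honoured from 1 to 32", {
  g <- grid_spec(c(16L, 16L, 16L))
  inp <- small_inputs(g)
  for (N in c(1L, 4L, 32L)) {
    model <- init_model_parameters(small_net(N), g, seed = 5)
    q <- inference_forward(model, inp$x, inp$s, inp$x, inp$s)
    expect_equal(q$N, N)
    expect_length(sample_latent(q, seed = 1), N)
  }
})

test_that("reparameterised sampling is seeded, collapses with variance, and is calibrated", {
  d <- latent_gaussian(c(2, -1), c(1e-18, 1e-18))
  expect_equal(sample_latent(d, seed = 1), c(2, -1), tolerance = 1e-6)
  d2 <- latent_gaussian(c(0.5, 1.5), c(2, 0.25))
  expect_identical(sample_latent(d2, seed = 7), sample_latent(d2, seed = 7))
  zz <- t(vapply(1:200, function(i) sample_latent(d2, seed = i), numeric(2)))
  expect_lt(abs(mean(zz[, 1]) - 0.5), 4 * sqrt(2) / sqrt(200))
  expect_lt(abs(mean(zz[, 2]) - 1.5), 4 * 0.5 / sqrt(200))
  expect_lt(abs(sd(zz[, 1]) - sqrt(2)), 4 * sqrt(2) / sqrt(2 * 200))
})

test_that("the generator maps (r, z) to a full-resolution velocity field deterministically", {
  g <- grid_spec(c(16L, 16L, 16L))
  inp <- small_inputs(g)
  model <- init_model_parameters(small_net(), g, seed = 6)
  enc <- encoder_forward(model, inp$x, inp$s)
  z <- sample_latent(enc$prior, seed = 2)
  v1 <- generator_forward(model, enc$r, z)
  v2 <- generator_forward(model, enc$r, z)
  expect_identical(v1$vectors, v2$vectors)
  expect_equal(dim(v1$vectors), c(16L, 16L, 16L, 3L))
  expect_identical(v1$kind, "velocity")
  expect_error(generator_forward(model, enc$r, c(z, 0)), "length")
})

test_that("the full pipeline maps a planning anatomy to a warped anatomy within the time budget", {
  g <- grid_spec(c(32L, 32L, 24L))
  ph <- generate_phantom(phantom_config(grid = g), seed = 3)
  model <- init_model_parameters(network_config(N = 8), g, seed = 7)
  run_once <- function() {
    enc <- encoder_forward(model, ph$image, ph$labels)
    z <- sample_latent(enc$prior, seed = 1)
    v <- generator_forward(model, enc$r, z)
    u <- exponentiate(v)
    warp_image(ph$image, u)
  }
  run_once()  # warm allocator and code paths
  t0 <- Sys.time()
  y <- run_once()
  dt <- as.numeric(Sys.time() - t0, units = "secs")
  expect_equal(dim(y$values), g$shape)
  expect_lt(dt, 1)
})

test_that("the end-to-end training gradient matches finite differences", {
  g <- grid_spec(c(8L, 8L, 8L))
  ncfg <- network_config(N = 2, conv_channels = 4, gn_groups = 2, n_organs = 2,
                         gen_head_channels = c(4, 3))
  cfg <- train_config(network = ncfg, seed = 3, diffeo = diffeo_config(4),
                      loss = loss_config(lambda_cc = 10, kappa = 0.5,
                                         cc_window = 3))
  set.seed(17)
  x <- image_volume(array(runif(512), g$shape), g)
  y <- image_volume(array(runif(512), g$shape), g)
  sx <- tiny_labels(g)
  sy0 <- array(0L, g$shape); sy0[4:6, 3:5, 3:5] <- 1L; sy0[6:7, 3:4, 4:6] <- 2L
  sy <- label_volume(sy0, g, organ_names = c("organA", "organB"))
  model <- init_model_parameters(ncfg, g, seed = 11)
  P <- model$params
  # push sample positions off the voxel lattice, away from the trilinear
  # kinks where the subgradient and the central difference disagree
  P[["gen.h2.b"]] <- c(0.37, -0.23, 0.29)
  P[["gen.h2.W"]] <- P[["gen.h2.W"]] * 50
  tn <- organmotion:::make_pair_tensors(list(x = x, sx = sx, y = y, sy = sy), 2L)
  eps <- c(0.3, -0.7)
  ps <- organmotion:::pair_pass(P, tn, cfg, eps = eps, want_grad = TRUE)
  f <- function(PP) organmotion:::pair_pass(PP, tn, cfg, eps = eps,
                                            want_grad = FALSE)$breakdown$total
  h <- 1e-5
  set.seed(23)
  for (nm in c("enc.b1.W", "enc.mu.W", "enc.lv.b", "inf.b2.W", "inf.b3.g",
               "inf.mu.W", "inf.lv.W", "gen.u1.W", "gen.u2.be",
               "gen.u3.W", "gen.h1.W", "gen.h2.W", "enc.feat.W")) {
    for (t in sample(length(P[[nm]]), 2)) {
      P2 <- P; P2[[nm]][t] <- P2[[nm]][t] + h
      P3 <- P; P3[[nm]][t] <- P3[[nm]][t] - h
      num <- (f(P2) - f(P3)) / (2 * h)
      expect_equal(ps$grads[[nm]][t], num,
                   tolerance = 1e-3 * max(1, abs(num)),
                   label = sprintf("grad of %s[%d]", nm, t))
    }
  }
})
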