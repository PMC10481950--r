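textured_image <- function(g, seed = 1) {
  set.seed(seed)
  image_volume(array(runif(prod(g$shape)), g$shape), g)
}

test_that("local cross-correlation is 1 for identical images, affine-invariant, and near 0 for noise", {
  g <- test_grid(c(16, 16, 16))
  y <- textured_image(g, 1)
  self_cc <- local_cross_correlation(y, y, n = 5)
  expect_gt(self_cc, 0.999)
  expect_lte(self_cc, 1)

  y2 <- image_volume(pmin(pmax(2 * y$values + 0.3, -10), 10) * 0 +
                       (2 * y$values + 0.3), g)
  expect_lt(abs(local_cross_correlation(y2, y, n = 5) - self_cc), 1e-3)
  # symmetry
  a <- textured_image(g, 2); b <- textured_image(g, 3)
  expect_equal(local_cross_correlation(a, b), local_cross_correlation(b, a))

  g32 <- test_grid(c(32, 32, 32))
  n1 <- textured_image(g32, 4); n2 <- textured_image(g32, 5)
  expect_lt(local_cross_correlation(n1, n2, n = 9), 0.05)
  expect_error(local_cross_correlation(n1, n2, n = 8), "odd")
})

test_that("DICE matches hand-counted overlaps and the empty convention", {
  a <- array(FALSE, c(12, 12, 12)); a[1:10, 1:10, 1:10] <- TRUE
  b <- array(FALSE, c(12, 12, 12)); b[6:15 - 3, 1:10, 1:10] <- TRUE
  expect_equal(dice_score(a, a), 1)
  expect_equal(dice_score(a, !a), 0)
  # two 10x10x10 cubes overlapping in a 5x10x10 slab
  c1 <- array(FALSE, c(20, 12, 12)); c1[1:10, 1:10, 1:10] <- TRUE
  c2 <- array(FALSE, c(20, 12, 12)); c2[6:15, 1:10, 1:10] <- TRUE
  expect_equal(dice_score(c1, c2), 2 * 500 / 2000)
  expect_equal(dice_score(a & FALSE, a & FALSE), 1)
})

test_that("mean organ DICE averages organs and excludes background", {
  g <- test_grid(c(8, 8, 8))
  s <- tiny_labels(g)
  oh <- organmotion:::label_onehot(s)
  expect_equal(mean_organ_dice(oh, s), 1)
  # organA perfect, organB fully missed
  oh2 <- oh
  oh2[, , , 3] <- 0
  d <- mean_organ_dice(oh2, s)
  expect_equal(d, 0.5)
  expect_error(mean_organ_dice(oh[, , , 1:2], s), "channels")
})

test_that("gradient penalty vanishes for constant fields and matches an independent evaluation", {
  g <- test_grid(c(10, 10, 10))
  uc <- array(0, c(g$shape, 3)); uc[, , , 1] <- 1.3; uc[, , , 2] <- -0.2
  expect_equal(gradient_penalty(vector_field(uc, g, "displacement")), 0)

  # independent second implementation via apply/diff
  indep_gp <- function(u4) {
    sh <- dim(u4)[1:3]
    s2 <- array(0, sh)
    for (comp in 1:3) for (ax in 1:3) {
      d <- array(0, sh)
      n <- sh[ax]
      idx1 <- lapply(sh, seq_len); idx1[[ax]] <- 1:(n - 1)
      idx2 <- idx1; idx2[[ax]] <- 2:n
      d1 <- do.call(`[`, c(list(u4[, , , comp]), idx2))
      d0 <- do.call(`[`, c(list(u4[, , , comp]), idx1))
      dd <- array(0, sh)
      dd <- do.call(`[<-`, c(list(dd), idx1, list(d1 - d0)))
      s2 <- s2 + dd^2
    }
    mean(sqrt(s2))
  }
  co <- organmotion:::coord_arrays(g$shape)
  ul <- array(0, c(g$shape, 3)); ul[, , , 1] <- 0.25 * co$I
  got <- gradient_penalty(vector_field(ul, g, "displacement"))
  expect_equal(got, indep_gp(ul))
  expect_equal(got, 0.25 * (9 / 10))  # zero-padded last slice lowers the mean

  set.seed(9)
  ur <- array(rnorm(prod(g$shape) * 3, sd = 0.3), c(g$shape, 3))
  expect_equal(gradient_penalty(vector_field(ur, g, "displacement")),
               indep_gp(ur), tolerance = 1e-12)
})

test_that("KL divergence matches the closed form and a Monte-Carlo estimate", {
  q <- latent_gaussian(c(0.3, -1), c(0.5, 2))
  expect_equal(kl_diag_gaussians(q, q), 0)
  expect_equal(kl_diag_gaussians(latent_gaussian(1, 1), latent_gaussian(0, 1)),
               0.5)
  expect_error(latent_gaussian(0, -1), "positive")
  expect_error(kl_diag_gaussians(q, latent_gaussian(0, 1)), "dimension")

  set.seed(11)
  for (i in 1:3) {
    mq <- rnorm(3); vq <- exp(rnorm(3)); mp <- rnorm(3); vp <- exp(rnorm(3))
    q <- latent_gaussian(mq, vq); p <- latent_gaussian(mp, vp)
    n <- 1e5
    z <- matrix(rnorm(3 * n, mean = mq, sd = sqrt(vq)), nrow = 3)
    lq <- colSums(dnorm(z, mq, sqrt(vq), log = TRUE))
    lp <- colSums(dnorm(z, mp, sqrt(vp), log = TRUE))
    mc <- mean(lq - lp)
    se <- sd(lq - lp) / sqrt(n)
    expect_lt(abs(kl_diag_gaussians(q, p) - mc), 3 * se)
  }
})

test_that("KL is additive over independent dimensions", {
  q1 <- latent_gaussian(0.5, 0.7); p1 <- latent_gaussian(0, 1)
  q2 <- latent_gaussian(-0.2, 1.4); p2 <- latent_gaussian(0.1, 0.9)
  q12 <- latent_gaussian(c(0.5, -0.2), c(0.7, 1.4))
  p12 <- latent_gaussian(c(0, 0.1), c(1, 0.9))
  expect_equal(kl_diag_gaussians(q12, p12),
               kl_diag_gaussians(q1, p1) + kl_diag_gaussians(q2, p2))
})

test_that("total loss combines its terms consistently and attains the perfect-fit optimum", {
  g <- test_grid(c(8, 8, 8))
  y <- textured_image(g, 21)
  s <- tiny_labels(g)
  u0 <- vector_field(array(0, c(g$shape, 3)), g, "displacement")
  q <- latent_gaussian(c(0, 0), c(1, 1))
  cfg <- loss_config(cc_window = 5)
  oh <- organmotion:::label_onehot(s)
  lb <- total_loss(y, y, oh, s, u0, q, q, cfg)
  expect_equal(lb$dice_term, 1)
  expect_equal(lb$kl_term, 0)
  expect_equal(lb$smooth_term, 0)
  expect_equal(lb$total, -cfg$lambda_cc * lb$cc_term - 1, tolerance = 1e-12)
  expect_gt(lb$cc_term, 0.999)

  # term switching: lambda = 0, kappa = 0, kl_weight = 0 leaves -meanDICE
  cfg0 <- loss_config(lambda_cc = 0, kappa = 0, kl_weight = 0, cc_window = 5)
  q2 <- latent_gaussian(c(1, 2), c(2, 0.5))
  lb0 <- total_loss(y, y, oh, s, u0, q2, q, cfg0)
  expect_equal(lb0$total, -lb0$dice_term)

  # self-consistency on arbitrary inputs
  set.seed(3)
  v <- smooth_random_velocity(c(8, 8, 8), vmax = 1, seed = 3)
  u <- exponentiate(vector_field(v, g, "velocity"))
  y2 <- textured_image(g, 22)
  soft <- warp_labels(s, u, return_soft = TRUE)$soft
  lb2 <- total_loss(y2, y, soft, s, u, q2, q, cfg)
  expect_equal(lb2$total,
               -cfg$lambda_cc * lb2$cc_term - lb2$dice_term +
                 cfg$kappa * lb2$smooth_term + cfg$kl_weight * lb2$kl_term)
})

test_that("analytic loss gradients match finite differences", {
  # these gradients drive training; check each against central differences
  set.seed(13)
  sh <- c(7, 6, 5)
  a <- array(runif(prod(sh)), sh)
  b <- array(runif(prod(sh)), sh)
  ga <- organmotion:::cc_backward(a, b, 3L, 1e-5)
  f <- function(aa) mean(organmotion:::cc_stats(aa, b, 3L, 1e-5)$pervox)
  h <- 1e-6
  for (t in sample(length(a), 8)) {
    a2 <- a; a2[t] <- a2[t] + h; a3 <- a; a3[t] <- a3[t] - h
    expect_equal(ga[t], (f(a2) - f(a3)) / (2 * h), tolerance = 1e-4)
  }

  K <- 2L
  soft <- array(runif(prod(sh) * (K + 1)), c(sh, K + 1))
  tn <- array(0, c(sh, K + 1))
  tn[, , , 2] <- (a > 0.5) * 1.0
  tn[, , , 3] <- (a <= 0.2) * 1.0
  tn[, , , 1] <- 1 - tn[, , , 2] - tn[, , , 3]
  gd <- organmotion:::mean_organ_dice_backward(soft, tn)
  fd <- function(ss) {
    d <- numeric(K)
    for (k in seq_len(K)) {
      p <- ss[, , , k + 1]; tt <- tn[, , , k + 1]
      d[k] <- 2 * sum(p * tt) / (sum(p) + sum(tt))
    }
    mean(d)
  }
  for (t in sample(length(soft), 8)) {
    s2 <- soft; s2[t] <- s2[t] + h; s3 <- soft; s3[t] <- s3[t] - h
    expect_equal(gd[t], (fd(s2) - fd(s3)) / (2 * h), tolerance = 1e-4)
  }

  u <- array(rnorm(prod(sh) * 3, sd = 0.5), c(sh, 3))
  cache <- organmotion:::gp_fwd(u)
  gu <- organmotion:::gp_bwd(cache)
  fg <- function(uu) organmotion:::gp_fwd(uu)$value
  for (t in sample(length(u), 8)) {
    u2 <- u; u2[t] <- u2[t] + h; u3 <- u; u3[t] <- u3[t] - h
    expect_equal(gu[t], (fg(u2) - fg(u3)) / (2 * h), tolerance = 1e-4)
  }
})
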