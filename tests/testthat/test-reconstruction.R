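# Feature-inversion reconstruction and the texture/structure losses.

make_conv_stack <- function(vals, P = 2, Q = 2, K = 1, name = "c") {
  specs <- stats::setNames(list(layer_spec(name, "convolutional", P, Q, K)),
                           name)
  feature_stack(stats::setNames(list(matrix(vals, nrow = 1)), name), specs)
}

test_that("channel statistics follow the direct arithmetic", {
  # constant map: mean c, variance 0
  st <- channel_stats(matrix(3.2, 4, 1))
  expect_equal(st$mu, 3.2)
  expect_equal(st$delta, 0)
  # 2x2 map (1, 2, 3, 4): mean 2.5, population variance 1.25
  st2 <- channel_stats(matrix(c(1, 2, 3, 4), 4, 1))
  expect_equal(st2$mu, 2.5)
  expect_equal(st2$delta, 1.25)
  # cross-covariance against a loop oracle, multi-channel
  set.seed(61)
  U <- matrix(rnorm(12), 4, 3)
  Uh <- matrix(rnorm(12), 4, 3)
  st3 <- channel_stats(U, Uh)
  for (k in 1:3) {
    mu <- sum(U[, k]) / 4
    muh <- sum(Uh[, k]) / 4
    cc <- sum(U[, k] * Uh[, k]) / 4 - mu * muh
    expect_equal(st3$cross[k], cc, tolerance = 1e-12)
    expect_equal(st3$delta[k], sum((U[, k] - mu)^2) / 4, tolerance = 1e-12)
  }
})

test_that("feature MSE follows the normalized-by-target-norm rule", {
  set.seed(62)
  specs <- list(a = layer_spec("a", "fully_connected", 1, 1, 5),
                b = layer_spec("b", "fully_connected", 1, 1, 3))
  u <- feature_stack(list(a = matrix(rnorm(5), 1), b = matrix(rnorm(3), 1)),
                     specs)
  p <- feature_stack(list(a = matrix(rnorm(5), 1), b = matrix(rnorm(3), 1)),
                     specs)
  expect_equal(feature_mse_loss(u, u)$total, 0)
  # all-zero prediction: each layer contributes exactly 1 -> total = L
  zero <- feature_stack(list(a = matrix(0, 1, 5), b = matrix(0, 1, 3)), specs)
  expect_equal(feature_mse_loss(zero, u)$total, 2)
  # loop oracle
  oracle <- 0
  for (nm in c("a", "b")) {
    oracle <- oracle +
      sum((p$layers[[nm]] - u$layers[[nm]])^2) / sum(u$layers[[nm]]^2)
  }
  expect_equal(feature_mse_loss(p, u)$total, oracle, tolerance = 1e-12)
})

test_that("texture loss follows the printed ratio", {
  eps <- 1e-6
  # zero-mean maps: ratio = eps / eps = 1, contribution -alpha
  z <- make_conv_stack(c(-1, 1, -1, 1))
  expect_equal(texture_loss(z, z, epsilon = eps)$total, -1, tolerance = 1e-9)
  # mu(u) = mu(uhat) = 1 with eps -> 0: ratio -> 1/2
  ones <- make_conv_stack(rep(1, 4))
  expect_equal(texture_loss(ones, ones, epsilon = 1e-12)$total, -0.5,
               tolerance = 1e-9)
  # random two-channel case vs loop oracle
  set.seed(63)
  specs <- list(c = layer_spec("c", "convolutional", 2, 2, 2))
  U <- matrix(rnorm(8), 1)
  Uh <- matrix(rnorm(8), 1)
  su <- feature_stack(list(c = U), specs)
  sh <- feature_stack(list(c = Uh), specs)
  got <- texture_loss(su, sh, epsilon = eps)$total
  oracle <- 0
  for (k in 1:2) {
    mu <- mean(U[1, (k - 1) * 4 + 1:4])
    muh <- mean(Uh[1, (k - 1) * 4 + 1:4])
    oracle <- oracle - 0.5 * (mu * muh + eps) / (mu^2 + muh^2 + eps)
  }
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("structure loss follows the printed ratio and sign behavior", {
  eps <- 1e-6
  # identical zero-variance maps: ratio = 1, contribution -beta
  const <- make_conv_stack(rep(2, 4))
  expect_equal(structure_loss(const, const, epsilon = eps)$total, -1,
               tolerance = 1e-9)
  # identical maps with variance d: ratio = (d + eps) / (2 d + eps)
  u <- make_conv_stack(c(1, 2, 3, 4))
  d <- 1.25
  expect_equal(structure_loss(u, u, epsilon = eps)$total,
               -(d + eps) / (2 * d + eps), tolerance = 1e-9)
  # sign flip: cross-covariance of (u, -u) is -d -> positive contribution
  neg <- make_conv_stack(-c(-1.5, -0.5, 0.5, 1.5))
  pos <- make_conv_stack(c(-1.5, -0.5, 0.5, 1.5))
  expect_gt(structure_loss(pos, neg, epsilon = eps)$total, 0)
  # random maps vs loop oracle
  set.seed(64)
  specs <- list(c = layer_spec("c", "convolutional", 3, 2, 2))
  U <- matrix(rnorm(12), 1)
  Uh <- matrix(rnorm(12), 1)
  got <- structure_loss(feature_stack(list(c = U), specs),
                        feature_stack(list(c = Uh), specs),
                        epsilon = eps)$total
  oracle <- 0
  for (k in 1:2) {
    a <- U[1, (k - 1) * 6 + 1:6]
    b <- Uh[1, (k - 1) * 6 + 1:6]
    dk <- mean(a * b) - mean(a) * mean(b)
    oracle <- oracle - 0.5 * (dk + eps) /
      (mean((a - mean(a))^2) + mean((b - mean(b))^2) + eps)
  }
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("similarity losses are symmetric, permutation-invariant, finite", {
  set.seed(65)
  specs <- list(c = layer_spec("c", "convolutional", 2, 2, 3))
  U <- matrix(rnorm(12), 1)
  Uh <- matrix(rnorm(12), 1)
  su <- feature_stack(list(c = U), specs)
  sh <- feature_stack(list(c = Uh), specs)
  expect_equal(texture_loss(su, sh)$total, texture_loss(sh, su)$total)
  expect_equal(structure_loss(su, sh)$total, structure_loss(sh, su)$total)
  # joint channel permutation leaves both losses unchanged
  perm <- c(3, 1, 2)
  scramble <- function(v) {
    m <- matrix(v, nrow = 4)
    as.vector(m[, perm])
  }
  sup <- feature_stack(list(c = matrix(scramble(U), 1)), specs)
  shp <- feature_stack(list(c = matrix(scramble(Uh), 1)), specs)
  expect_equal(texture_loss(sup, shp)$total, texture_loss(su, sh)$total,
               tolerance = 1e-12)
  expect_equal(structure_loss(sup, shp)$total, structure_loss(su, sh)$total,
               tolerance = 1e-12)
  # all-zero maps are finite for every positive epsilon
  z <- feature_stack(list(c = matrix(0, 1, 12)), specs)
  for (eps in c(1e-12, 1e-6, 1)) {
    expect_true(is.finite(texture_loss(z, z, epsilon = eps)$total))
    expect_true(is.finite(structure_loss(z, z, epsilon = eps)$total))
  }
})

test_that("similarity gradients match finite differences", {
  set.seed(66)
  U <- matrix(rnorm(8), 4, 2)
  Uh <- matrix(rnorm(8), 4, 2)
  eps <- 1e-6
  gt <- ncconvert:::texture_grad(U, Uh, 0.5, eps)
  gs <- ncconvert:::structure_grad(U, Uh, 0.5, eps)
  str_at <- function(M) {
    tot <- 0
    for (k in 1:2) {
      a <- U[, k]; b <- M[, k]
      dk <- mean(a * b) - mean(a) * mean(b)
      tot <- tot - 0.5 / 2 * (dk + eps) /
        (mean((a - mean(a))^2) + mean((b - mean(b))^2) + eps)
    }
    tot
  }
  tex_full <- function(M) {
    tot <- 0
    for (k in 1:2) {
      mu <- mean(U[, k]); muh <- mean(M[, k])
      tot <- tot - 0.5 / 2 * (mu * muh + eps) / (mu^2 + muh^2 + eps)
    }
    tot
  }
  h <- 1e-6
  for (idx in c(1, 5, 8)) {
    up <- Uh; up[idx] <- up[idx] + h
    dn <- Uh; dn[idx] <- dn[idx] - h
    expect_equal(gt[idx], (tex_full(up) - tex_full(dn)) / (2 * h),
                 tolerance = 1e-4)
    expect_equal(gs[idx], (str_at(up) - str_at(dn)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("optimization at the truth is a fixed point with zero loss", {
  ex <- tiny_extractor()
  w <- tiny_world()
  img <- array(w$images[1, , , ], dim = c(16, 16, 3))
  u <- extract_features(ex, img)
  res <- reconstruct_image(u, ex,
                           config = reconstruction_config(
                             iterations = 5, lambda_tex = 0, lambda_str = 0),
                           init = as.vector(img))
  expect_equal(res$trajectory$total[1], 0, tolerance = 1e-18)
  expect_equal(as.vector(res$image), as.vector(img), tolerance = 1e-10)
})

test_that("reconstruction runs its full schedule and never ends above init", {
  ex <- tiny_extractor()
  w <- tiny_world()
  img <- array(w$images[2, , , ], dim = c(16, 16, 3))
  u <- extract_features(ex, img)
  cfg <- reconstruction_config(iterations = 60, seed = 8)
  res <- reconstruct_image(u, ex, config = cfg)
  expect_equal(nrow(res$trajectory), 60)
  expect_lte(res$best_total, res$trajectory$total[1])
  expect_true(all(res$image >= 0 & res$image <= 1))
})

test_that("feature inversion recovers the source image's features", {
  ex <- tiny_extractor()
  w <- tiny_world()
  img <- array(w$images[3, , , ], dim = c(16, 16, 3))
  u <- extract_features(ex, img)
  res <- reconstruct_image(u, ex,
                           config = reconstruction_config(iterations = 200,
                                                          seed = 12))
  uh <- extract_features(ex, res$image)
  for (nm in names(u$layers)) {
    expect_gt(cor(as.vector(uh$layers[[nm]]), as.vector(u$layers[[nm]])),
              0.9)
  }
})
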